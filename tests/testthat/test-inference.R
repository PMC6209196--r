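test_that("the candidate set has 10 models with the conventional K values", {
  sp <- candidate_models("log10_speed")
  tr <- candidate_models("behavior")
  expect_equal(nrow(sp), 10)
  expect_equal(nrow(tr), 10)
  expect_true(all(grepl("\\(1 \\+ time_of_day \\| wolf_id\\)", sp$formula_text)))
  expect_true(all(grepl("\\(1 \\| wolf_id\\)", tr$formula_text)))
  k_sp <- setNames(sp$K, sp$name)
  expect_equal(unname(k_sp[c("null", "time_of_day", "snowfall_category",
                             "cat_tod", "cat_tod_depth", "cat_x_tod",
                             "cat_x_tod_depth")]),
               c(5, 6, 11, 12, 13, 18, 19))
  k_tr <- setNames(tr$K, tr$name)
  expect_equal(unname(k_tr[c("null", "snowfall_category", "cat_x_tod",
                             "cat_x_tod_depth")]),
               c(2, 8, 15, 16))
  # interaction specs contain both main effects (marginality)
  expect_match(sp$fixed[sp$name == "cat_x_tod"], "\\*")
})

test_that("fitted K equals fixed coefficients plus variance parameters", {
  lmm <- make_lmm_data(n_wolves = 8, n_per = 60)
  glm_d <- make_glmm_data(n_wolves = 8, n_per = 60)
  sp <- candidate_models("log10_speed")
  tr <- candidate_models("behavior")
  f_null <- fit_speed_model(lmm, sp[sp$name == "null", ])
  f_tod <- fit_speed_model(lmm, sp[sp$name == "time_of_day", ])
  expect_equal(f_null$K, 5) # 1 fixed + 2 RE var + 1 corr + residual
  expect_equal(f_tod$K, 6)
  g_null <- fit_travel_model(glm_d, tr[tr$name == "null", ])
  g_tod <- fit_travel_model(glm_d, tr[tr$name == "time_of_day", ])
  expect_equal(g_null$K, 2) # 1 fixed + 1 RE variance
  expect_equal(g_tod$K, 3)
  expect_equal(f_tod$AIC, 2 * f_tod$K - 2 * f_tod$logL, tolerance = 1e-9)
})

test_that("selection arithmetic: AIC, weights, evidence ratios, ordering", {
  tab <- aic_table(K = c(16, 13, 3), logL = c(-10769.14, -3501.95, -100),
                   formula_text = c("a", "b", "c"))
  expect_equal(tab$AIC[tab$formula_text == "a"], 21570.28)
  expect_equal(tab$AIC[tab$formula_text == "b"], 7029.90)
  expect_equal(sum(tab$akaike_weight), 1, tolerance = 1e-12)
  expect_equal(tab$delta_AIC[1], 0)
  expect_true(all(diff(tab$AIC) >= 0))
  expect_equal(tab$evidence_ratio[1], 1)

  one <- aic_table(K = 4, logL = -10)
  expect_equal(one$akaike_weight, 1)
  expect_equal(one$delta_AIC, 0)

  w <- akaike_weights(c(0, 2))
  expect_equal(w, c(1, exp(-1)) / (1 + exp(-1)), tolerance = 1e-12)
})

test_that("parsimony selection prefers the simplest model within the window", {
  tab <- aic_table(K = c(12, 18, 13, 19, 6), logL = c(-10, -8.2, -9.9, -8.1, -30),
                   formula_text = c("m12", "m18", "m13", "m19", "m6"))
  # deltas small for the first four, m6 far behind
  best <- select_best(tab, parsimony_window = 4)
  expect_equal(best$formula_text, "m12")
  # only rank 1 inside the window
  tab2 <- aic_table(K = c(5, 9), logL = c(-10, -20), formula_text = c("a", "b"))
  expect_equal(select_best(tab2, 4)$formula_text, "a")
})

test_that("back-transformation maps link-scale estimates to ratio scales", {
  expect_equal(back_transform(1.081, "log10"), 12.049, tolerance = 0.005)
  expect_equal(back_transform(0.107, "log10"), 1.280, tolerance = 0.005)
  expect_equal(back_transform(-0.467, "logit"), 0.627, tolerance = 0.005)
  expect_equal(back_transform(0.563, "logit"), 1.756, tolerance = 0.005)
  expect_equal(back_transform(0, "log10"), 1)
  expect_equal(back_transform(0, "logit"), 1)
  expect_error(back_transform(1, "identity"))
})

test_that("GLMM with negligible random variance agrees with plain logistic regression", {
  d <- make_glmm_data(n_wolves = 12, n_per = 120, ranef_sd = 0, seed = 5)
  spec <- candidate_models("behavior")[3, ] # time_of_day
  g <- fit_travel_model(d, spec)
  plain <- stats::glm(I(behavior == "travel") ~ time_of_day,
                      data = d, family = stats::binomial)
  se <- summary(plain)$coefficients[, 2]
  expect_lt(max(abs(lme4::fixef(g$fit) - stats::coef(plain)) / se), 2)
})

test_that("adding a term never decreases the maximized log-likelihood", {
  sim <- simulate_dataset(small_sim(seed = 41))
  thin <- thin_to_interval(sim$tracks$fixes, 30)
  steps <- suppressMessages(compute_steps(thin))
  ctr <- daily_centroids(thin)
  steps <- label_time_of_day(steps, ctr)
  steps <- suppressMessages(classify_steps(steps, reference_cutoff_mpm))
  sd <- build_snow_daily(sim$snow$readings, sim$snow$deployments)
  wd <- suppressMessages(join_wolf_day(ctr, sd, sim$snow$deployments))
  ev <- dplyr::select(dplyr::filter(wd, is_event %in% TRUE), wolf_id, camera_day)
  days <- dplyr::distinct(dplyr::select(steps, wolf_id, camera_day))
  cats <- assign_snowfall_categories(days, ev)
  ctl <- suppressWarnings(sample_controls(days, ev, 3, seed = 2))
  an <- suppressMessages(build_analysis_dataset(steps, cats, ctl, wd))

  fits <- suppressMessages(suppressWarnings(fit_candidates(an, "behavior")))
  ll <- vapply(fits, `[[`, numeric(1), "logL")
  nested <- list(c("null", "time_of_day"), c("null", "snowfall_category"),
                 c("time_of_day", "cat_tod"), c("cat_tod", "cat_x_tod"),
                 c("cat_tod", "cat_tod_depth"), c("cat_x_tod", "cat_x_tod_depth"))
  for (p in nested) {
    if (all(p %in% names(ll))) {
      expect_gte(ll[[p[2]]] + 1e-6, ll[[p[1]]])
    }
  }
  tab <- selection_table(fits)
  expect_equal(sum(tab$akaike_weight), 1, tolerance = 1e-12)
  expect_equal(tab$delta_AIC[1], 0)
})

test_that("the bootstrap is seeded, validates its level and reports failures", {
  d <- make_lmm_data(n_wolves = 8, n_per = 80, seed = 9)
  spec <- candidate_models("log10_speed")[3, ] # time_of_day
  f <- fit_speed_model(d, spec)
  expect_error(parametric_bootstrap_ci(f, n_sim = 10, level = 0), "level")
  expect_error(parametric_bootstrap_ci(f, n_sim = 10, level = 1.2), "level")
  ci1 <- suppressWarnings(parametric_bootstrap_ci(f, n_sim = 30, seed = 42))
  ci2 <- suppressWarnings(parametric_bootstrap_ci(f, n_sim = 30, seed = 42))
  expect_identical(ci1, ci2)
  expect_true(all(ci1$ci_lower <= ci1$beta & ci1$beta <= ci1$ci_upper))
  expect_true(all(ci1$transformed > 0))
  expect_equal(attr(ci1, "link"), "log10")
  expect_true(attr(ci1, "n_fail") >= 0)
})
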