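# Candidate mixed models for travel speed (LMM on log10 speed, travel
# steps only) and travel probability (binomial GLMM), AIC selection with
# Akaike weights and evidence ratios, a parsimony rule for nested models
# within a few AIC units of the top model, and parametric-bootstrap CIs.

.FIXED_TERMS <- list(
  null = character(0),
  snow_depth = "snow_depth_cm",
  time_of_day = "time_of_day",
  snowfall_category = "snowfall_category",
  tod_depth = c("time_of_day", "snow_depth_cm"),
  cat_depth = c("snowfall_category", "snow_depth_cm"),
  cat_tod = c("snowfall_category", "time_of_day"),
  cat_tod_depth = c("snowfall_category", "time_of_day", "snow_depth_cm"),
  cat_x_tod = "snowfall_category * time_of_day",
  cat_x_tod_depth = c("snowfall_category * time_of_day", "snow_depth_cm")
)

# number of fixed coefficients with a 7-level category and 2-level
# time-of-day (intercept included)
.N_FIXED <- c(null = 1, snow_depth = 2, time_of_day = 2, snowfall_category = 7,
              tod_depth = 3, cat_depth = 8, cat_tod = 8, cat_tod_depth = 9,
              cat_x_tod = 14, cat_x_tod_depth = 15)

#' The ten-model candidate set
#'
#' All combinations of `snowfall_category`, `time_of_day` and
#' `snow_depth`, with the category-by-time-of-day interaction (always
#' accompanied by its main effects) in the two richest models. The speed
#' response takes a by-wolf random intercept and random `time_of_day`
#' slope; the travel response a by-wolf random intercept.
#'
#' @param response `"log10_speed"` (travel-speed LMM) or `"behavior"`
#'   (travel-probability GLMM).
#' @return A tibble with one row per candidate: `name`, `formula_text`,
#'   `fixed`, `random`, `K` (fixed coefficients plus variance-covariance
#'   parameters, plus residual variance for the LMM).
#' @export
candidate_models <- function(response = c("log10_speed", "behavior")) {
  response <- match.arg(response)
  random <- if (response == "log10_speed") {
    "(1 + time_of_day | wolf_id)"
  } else {
    "(1 | wolf_id)"
  }
  # LMM: 2 RE variances + 1 correlation + residual; GLMM: 1 RE variance
  k_var <- if (response == "log10_speed") 4L else 1L
  tibble::tibble(
    name = names(.FIXED_TERMS),
    fixed = vapply(.FIXED_TERMS, function(tt) {
      if (length(tt) == 0) "1" else paste(tt, collapse = " + ")
    }, character(1)),
    formula_text = paste(response, "~", .data$fixed, "+", random),
    random = random,
    K = unname(.N_FIXED[.data$name]) + k_var
  )
}

.relevel_analysis <- function(data) {
  data$snowfall_category <- factor(data$snowfall_category,
                                   levels = snowfall_category_levels)
  data$time_of_day <- factor(as.character(data$time_of_day),
                             levels = c("day", "night"))
  data
}

.count_K <- function(fit) {
  length(lme4::fixef(fit)) + length(lme4::getME(fit, "theta")) +
    as.integer(lme4::isLMM(fit))
}

.conv_warning <- function(fit) {
  msgs <- fit@optinfo$conv$lme4$messages
  !is.null(msgs) && any(grepl("failed to converge", msgs))
}

# A restart from the first optimum with a second optimizer usually clears
# spurious max|grad| warnings (the bobyqa/NM gradient checks are known to
# flag false positives near flat optima). The restarted fit replaces the
# original only if it is warning-free and at the same deviance.
.restart_if_needed <- function(fit) {
  if (!.conv_warning(fit)) return(fit)
  fit2 <- tryCatch({
    if (lme4::isLMM(fit)) {
      suppressMessages(suppressWarnings(stats::update(
        fit, start = lme4::getME(fit, "theta"),
        control = lme4::lmerControl(optimizer = "Nelder_Mead"))))
    } else {
      suppressMessages(suppressWarnings(stats::update(
        fit,
        start = list(theta = lme4::getME(fit, "theta"),
                     fixef = lme4::getME(fit, "beta")),
        control = lme4::glmerControl(optimizer = "Nelder_Mead",
                                     optCtrl = list(maxfun = 1e5)))))
    }
  }, error = function(e) NULL)
  if (!is.null(fit2) && !.conv_warning(fit2) &&
      abs(as.numeric(logLik(fit2)) - as.numeric(logLik(fit))) < 1e-3) {
    return(fit2)
  }
  fit
}

.wrap_fit <- function(fit, spec) {
  ll <- as.numeric(logLik(fit))
  K <- .count_K(fit)
  conv <- !.conv_warning(fit)
  structure(
    list(spec = spec, fit = fit, K = K, logL = ll, AIC = 2 * K - 2 * ll,
         converged = conv, singular = lme4::isSingular(fit)),
    class = "wolf_fit"
  )
}

#' @export
print.wolf_fit <- function(x, ...) {
  cat(sprintf("%s  [K = %d, logL = %.2f, AIC = %.2f%s]\n",
              x$spec$formula_text, x$K, x$logL, x$AIC,
              if (!x$converged) ", NOT CONVERGED" else ""))
  invisible(x)
}

#' Fit one candidate travel-speed model
#'
#' Linear mixed model on log10 travel speed, maximum likelihood (not
#' REML: AIC compares fixed-effect structures). Rows are restricted to
#' travel steps; models including snow depth use depth-complete cases and
#' are fitted with depth centered at its sample mean (`$depth_center`):
#' the slope per cm and the likelihood are unchanged, and the near
#' collinearity of a ~constant depth column with the intercept is removed.
#' Reference levels are `day_of_snowfall` and `day`, so the intercept is
#' the event-day daytime mean.
#'
#' @param data analysis rows ([build_analysis_dataset()] output).
#' @param spec one row of [candidate_models()]`("log10_speed")`.
#' @return A `wolf_fit` object.
#' @export
fit_speed_model <- function(data, spec) {
  data <- .relevel_analysis(data)
  if ("behavior" %in% names(data)) data <- filter(data, .data$behavior == "travel")
  ctr <- NULL
  if (grepl("snow_depth_cm", spec$formula_text)) {
    data <- filter(data, !is.na(.data$snow_depth_cm))
    ctr <- mean(data$snow_depth_cm)
    data$snow_depth_cm <- data$snow_depth_cm - ctr
  }
  fit <- lme4::lmer(stats::as.formula(spec$formula_text), data = data, REML = FALSE)
  out <- .wrap_fit(.restart_if_needed(fit), spec)
  out$depth_center <- ctr
  out
}

#' Fit one candidate travel-probability model
#'
#' Binomial GLMM (travel = 1, rest = 0) with a by-wolf random intercept,
#' Laplace approximation by default. Reference levels as in
#' [fit_speed_model()].
#'
#' @param data analysis rows; `behavior` coded `"rest"`/`"travel"` or 0/1.
#' @param spec one row of [candidate_models()]`("behavior")`.
#' @param nAGQ passed to [lme4::glmer()] (1 = Laplace).
#' @return A `wolf_fit` object.
#' @export
fit_travel_model <- function(data, spec, nAGQ = 1) {
  data <- .relevel_analysis(data)
  if (is.character(data$behavior) || is.factor(data$behavior)) {
    data$behavior <- as.integer(as.character(data$behavior) == "travel")
  }
  ctr <- NULL
  if (grepl("snow_depth_cm", spec$formula_text)) {
    data <- filter(data, !is.na(.data$snow_depth_cm))
    ctr <- mean(data$snow_depth_cm)
    data$snow_depth_cm <- data$snow_depth_cm - ctr
  }
  fit <- lme4::glmer(stats::as.formula(spec$formula_text), data = data,
                     family = stats::binomial, nAGQ = nAGQ,
                     control = lme4::glmerControl(optimizer = "bobyqa",
                                                  optCtrl = list(maxfun = 1e5)))
  out <- .wrap_fit(.restart_if_needed(fit), spec)
  out$depth_center <- ctr
  out
}

#' Fit the full candidate set
#' @param data analysis rows.
#' @param response `"log10_speed"` or `"behavior"`.
#' @param ... passed to the single-model fitters.
#' @return A list of `wolf_fit` objects (non-converged fits dropped with
#'   a warning).
#' @export
fit_candidates <- function(data, response = c("log10_speed", "behavior"), ...) {
  response <- match.arg(response)
  specs <- candidate_models(response)
  fitter <- if (response == "log10_speed") fit_speed_model else fit_travel_model
  fits <- lapply(seq_len(nrow(specs)), function(i) {
    tryCatch(fitter(data, specs[i, ], ...),
             error = function(e) {
               warn(sprintf("Model '%s' failed: %s", specs$name[i], conditionMessage(e)))
               NULL
             })
  })
  names(fits) <- specs$name
  keep <- vapply(fits, function(f) !is.null(f) && f$converged, logical(1))
  if (any(!keep)) {
    warn(sprintf("Dropping %d non-converged candidate model(s): %s",
                 sum(!keep), paste(specs$name[!keep], collapse = ", ")))
  }
  fits[keep]
}

#' AIC selection table from parameter counts and log-likelihoods
#'
#' The arithmetic core of model selection: AIC = 2K - 2 logL, delta vs the
#' minimum, Akaike weights w_i = exp(-delta_i/2) / sum_j exp(-delta_j/2),
#' and evidence ratios w_best / w_i, sorted by AIC.
#'
#' @param K integer vector of parameter counts.
#' @param logL numeric vector of maximized log-likelihoods.
#' @param formula_text optional labels.
#' @return tibble `rank,formula_text,K,logL,AIC,delta_AIC,akaike_weight,
#'   evidence_ratio`.
#' @export
aic_table <- function(K, logL, formula_text = NULL) {
  stopifnot(length(K) == length(logL), length(K) >= 1)
  if (is.null(formula_text)) formula_text <- paste0("model_", seq_along(K))
  K <- unname(K)
  logL <- unname(logL)
  aic <- 2 * K - 2 * logL
  out <- tibble::tibble(formula_text = unname(formula_text), K = as.integer(K),
                        logL = logL, AIC = aic) %>%
    arrange(.data$AIC) %>%
    mutate(
      rank = row_number(),
      delta_AIC = .data$AIC - min(.data$AIC),
      akaike_weight = exp(-.data$delta_AIC / 2) / sum(exp(-.data$delta_AIC / 2)),
      evidence_ratio = max(.data$akaike_weight) / .data$akaike_weight
    ) %>%
    select("rank", "formula_text", "K", "logL", "AIC", "delta_AIC",
           "akaike_weight", "evidence_ratio")
  out
}

#' Akaike weights from delta-AIC values
#' @param delta_aic numeric vector of AIC differences from the best model.
#' @return Weights summing to 1.
#' @export
akaike_weights <- function(delta_aic) {
  w <- exp(-delta_aic / 2)
  w / sum(w)
}

#' Model-selection table for a set of fitted candidates
#' @param fits list of `wolf_fit` objects ([fit_candidates()] output).
#' @return The [aic_table()] of the fits, with a `name` column.
#' @export
selection_table <- function(fits) {
  stopifnot(length(fits) >= 1)
  tab <- aic_table(
    K = vapply(fits, `[[`, numeric(1), "K"),
    logL = vapply(fits, `[[`, numeric(1), "logL"),
    formula_text = vapply(fits, function(f) f$spec$formula_text, character(1))
  )
  nm <- vapply(fits, function(f) f$spec$name, character(1))
  tab$name <- nm[match(tab$formula_text,
                       vapply(fits, function(f) f$spec$formula_text, character(1)))]
  tab
}

#' Parsimony selection among near-best models
#'
#' Among models within `parsimony_window` AIC units of the best, returns
#' the one with fewest parameters (ties broken by smaller AIC): a more
#' complex model close to the top model is not considered supported when
#' a nested simpler model achieves nearly the same likelihood.
#'
#' @param table an [aic_table()]/[selection_table()] result.
#' @param parsimony_window AIC window (default 4).
#' @return The selected row of `table`.
#' @export
select_best <- function(table, parsimony_window = 4) {
  stopifnot(nrow(table) >= 1)
  cand <- filter(table, .data$delta_AIC <= parsimony_window)
  cand <- arrange(cand, .data$K, .data$AIC)
  cand[1, ]
}

#' Back-transform a link-scale coefficient
#'
#' `log10` link: 10^beta, the multiplicative effect on speed in m/min.
#' `logit` link: exp(beta), the odds ratio for travelling.
#'
#' @param beta coefficient(s) on the link scale.
#' @param link `"log10"` or `"logit"`.
#' @return Transformed value(s).
#' @export
back_transform <- function(beta, link = c("log10", "logit")) {
  link <- match.arg(link)
  switch(link, log10 = 10^beta, logit = exp(beta))
}

#' Parametric-bootstrap confidence intervals for fixed effects
#'
#' Simulates responses from the fitted model (new random effects and, for
#' the LMM, residual noise), refits, and takes percentile intervals of the
#' fixed-effect draws. Refit failures are dropped and counted; a warning
#' is raised when more than 10% fail.
#'
#' @param fit a `wolf_fit` object.
#' @param n_sim number of simulations (default 5000).
#' @param level confidence level in (0, 1).
#' @param seed integer seed.
#' @return tibble `term,beta,se,ci_lower,ci_upper,transformed,
#'   transformed_lower,transformed_upper` with attributes `n_fail` and
#'   `link`.
#' @export
parametric_bootstrap_ci <- function(fit, n_sim = 5000, level = 0.95, seed = 1) {
  stopifnot(inherits(fit, "wolf_fit"))
  if (!is.numeric(level) || level <= 0 || level >= 1) {
    abort("level must lie strictly between 0 and 1")
  }
  m <- fit$fit
  link <- if (lme4::isLMM(m)) "log10" else "logit"
  beta <- lme4::fixef(m)
  se <- sqrt(diag(as.matrix(stats::vcov(m))))
  sims <- withr::with_seed(seed, simulate(m, nsim = n_sim))
  draws <- matrix(NA_real_, nrow = n_sim, ncol = length(beta))
  for (i in seq_len(n_sim)) {
    bi <- tryCatch(
      lme4::fixef(suppressMessages(suppressWarnings(lme4::refit(m, sims[[i]])))),
      error = function(e) NULL)
    if (!is.null(bi) && length(bi) == length(beta)) draws[i, ] <- bi
  }
  ok <- stats::complete.cases(draws)
  n_fail <- n_sim - sum(ok)
  if (n_fail > 0.1 * n_sim) {
    warn(sprintf("%d of %d bootstrap refits failed", n_fail, n_sim))
  }
  if (sum(ok) < 2) abort("Too few successful bootstrap refits to form an interval")
  alpha <- (1 - level) / 2
  qs <- apply(draws[ok, , drop = FALSE], 2, quantile, probs = c(alpha, 1 - alpha))
  out <- tibble::tibble(
    term = names(beta),
    beta = unname(beta),
    se = unname(se),
    ci_lower = qs[1, ],
    ci_upper = qs[2, ],
    transformed = back_transform(unname(beta), link),
    transformed_lower = back_transform(qs[1, ], link),
    transformed_upper = back_transform(qs[2, ], link)
  )
  attr(out, "n_fail") <- n_fail
  attr(out, "link") <- link
  out
}
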