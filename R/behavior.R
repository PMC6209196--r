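# Rest/travel segmentation. Pooled log10 step speeds are bimodal: a slow
# mode (stationary GPS jitter while resting or at kill sites) and a fast
# mode (directed travel). A two-component Gaussian mixture is fitted by
# EM and the density intersection between the component means is the
# classification threshold.

#' Floor speeds and transform to log10
#'
#' Zero-distance steps have undefined log speed; speeds are floored at a
#' small epsilon comparable to GPS jitter before the log transform.
#'
#' @param speed_mpm speeds in m/min.
#' @param floor_mpm lower floor (default 0.01 m/min).
#' @return log10 speeds.
#' @export
log10_speed <- function(speed_mpm, floor_mpm = 0.01) {
  stopifnot(floor_mpm > 0)
  log10(pmax(speed_mpm, floor_mpm))
}

#' Fit a two-component Gaussian mixture to log10 speeds
#'
#' Plain EM for a univariate two-component normal mixture with a single
#' deterministic initialization: means at the 25th and 75th percentiles,
#' equal weights, pooled SD for both components. Converged when the
#' log-likelihood improves by less than `tol`. Components are returned
#' ordered so `mu1 < mu2` (rest before travel).
#'
#' @param x log10 speeds (finite; at least 100 values recommended).
#' @param tol convergence tolerance on the log-likelihood (default 1e-8).
#' @param max_iter maximum EM iterations.
#' @return An object of class `speed_mixture`: list with `w1`, `w2`,
#'   `mu1`, `mu2`, `sd1`, `sd2`, `loglik`, `n_iter`, `converged`, `n`.
#' @export
fit_mixture <- function(x, tol = 1e-8, max_iter = 2000) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 2 || length(unique(x)) < 2) {
    abort("fit_mixture() needs at least two distinct finite values.")
  }
  if (n < 100) {
    warn(sprintf("fit_mixture() called with n = %d < 100; estimates may be unstable", n))
  }
  mu <- unname(quantile(x, c(0.25, 0.75)))
  if (mu[1] == mu[2]) mu <- mu + c(-1, 1) * sd(x) / 10
  s <- rep(max(sd(x), 1e-3), 2)
  w <- c(0.5, 0.5)
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0
  for (iter in seq_len(max_iter)) {
    d1 <- w[1] * dnorm(x, mu[1], s[1])
    d2 <- w[2] * dnorm(x, mu[2], s[2])
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    ll <- sum(log(tot))
    if (is.finite(ll) && abs(ll - ll_old) < tol) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    r <- d1 / tot
    n1 <- sum(r)
    n2 <- n - n1
    if (n1 < 1e-8 || n2 < 1e-8) break # one component collapsed
    w <- c(n1, n2) / n
    mu <- c(sum(r * x) / n1, sum((1 - r) * x) / n2)
    s <- sqrt(c(sum(r * (x - mu[1])^2) / n1, sum((1 - r) * (x - mu[2])^2) / n2))
    s <- pmax(s, 1e-6)
  }
  if (!converged) {
    abort(sprintf(
      "EM did not converge in %d iterations (last logL %.6f, mu = %.3f/%.3f, w = %.3f/%.3f)",
      max_iter, ll_old, mu[1], mu[2], w[1], w[2]))
  }
  ord <- order(mu)
  structure(
    list(w1 = w[ord[1]], w2 = w[ord[2]],
         mu1 = mu[ord[1]], mu2 = mu[ord[2]],
         sd1 = s[ord[1]], sd2 = s[ord[2]],
         loglik = ll, n_iter = iter, converged = TRUE, n = n),
    class = "speed_mixture"
  )
}

#' @export
print.speed_mixture <- function(x, ...) {
  cat("Two-component Gaussian mixture on log10 speed (n =", x$n, ")\n")
  cat(sprintf("  rest:   w = %.3f, mu = %.3f, sd = %.3f\n", x$w1, x$mu1, x$sd1))
  cat(sprintf("  travel: w = %.3f, mu = %.3f, sd = %.3f\n", x$w2, x$mu2, x$sd2))
  cat(sprintf("  logL = %.3f after %d EM iterations\n", x$loglik, x$n_iter))
  invisible(x)
}

#' Density intersection of a two-component mixture
#'
#' Solves w1 N(x; mu1, sd1) = w2 N(x; mu2, sd2) exactly: taking logs gives
#' a quadratic in x (linear when the SDs are equal) and the root strictly
#' between the two means is the classification cutoff.
#'
#' As a sharpness diagnostic, the returned cutoff carries `band_log10`:
#' the interval around the intersection where the two weighted component
#' log-densities differ by less than 1 (within a factor e of each other).
#' A wide band means the modes overlap heavily and single-step labels
#' near the cutoff are unreliable.
#'
#' @param mixture a `speed_mixture` (or any list with the same fields).
#' @return list of class `speed_cutoff` with `value_log10`, `value_mpm`
#'   and `band_log10` (length 2).
#' @export
find_intersection <- function(mixture) {
  w1 <- mixture$w1; w2 <- mixture$w2
  mu1 <- mixture$mu1; mu2 <- mixture$mu2
  sd1 <- mixture$sd1; sd2 <- mixture$sd2
  stopifnot(mu1 < mu2, sd1 > 0, sd2 > 0, w1 > 0, w2 > 0)
  if (isTRUE(all.equal(sd1, sd2))) {
    s2 <- ((sd1 + sd2) / 2)^2
    root <- (mu1 + mu2) / 2 + s2 * log(w1 / w2) / (mu2 - mu1)
    roots <- root
  } else {
    a <- 1 / (2 * sd2^2) - 1 / (2 * sd1^2)
    b <- mu1 / sd1^2 - mu2 / sd2^2
    cc <- mu2^2 / (2 * sd2^2) - mu1^2 / (2 * sd1^2) + log((w1 * sd2) / (w2 * sd1))
    disc <- b^2 - 4 * a * cc
    if (disc < 0) {
      abort("Densities do not intersect between the means; consider a quantile-based fallback cutoff.")
    }
    roots <- c((-b + sqrt(disc)) / (2 * a), (-b - sqrt(disc)) / (2 * a))
  }
  inside <- roots[roots > mu1 & roots < mu2]
  if (length(inside) == 0) {
    abort(paste0("No density intersection strictly between the component means ",
                 "(extreme weight imbalance); consider a quantile-based fallback cutoff."))
  }
  value <- inside[1]
  # +/-1 log-density band: |log(w1 f1) - log(w2 f2)| <= 1 around the root
  ldiff <- function(x) {
    log(w1) + dnorm(x, mu1, sd1, log = TRUE) -
      log(w2) - dnorm(x, mu2, sd2, log = TRUE)
  }
  lo <- tryCatch(stats::uniroot(function(x) abs(ldiff(x)) - 1,
                                c(mu1, value))$root, error = function(e) mu1)
  hi <- tryCatch(stats::uniroot(function(x) abs(ldiff(x)) - 1,
                                c(value, mu2))$root, error = function(e) mu2)
  structure(list(value_log10 = value, value_mpm = 10^value,
                 band_log10 = c(lo, hi)),
            class = "speed_cutoff")
}

#' @export
print.speed_cutoff <- function(x, ...) {
  cat(sprintf("Rest/travel cutoff: %.3f log10(m/min) = %.3f m/min\n",
              x$value_log10, x$value_mpm))
  invisible(x)
}

#' Label steps as rest or travel
#'
#' Steps with speed at or above the cutoff are "travel"; below it, "rest".
#'
#' @param steps step tibble with `speed_mpm`.
#' @param cutoff_mpm cutoff in m/min (a number or a `speed_cutoff`);
#'   defaults to the published [reference_cutoff_mpm].
#' @return `steps` with a `behavior` column (`"rest"`/`"travel"`).
#' @export
classify_steps <- function(steps, cutoff_mpm = reference_cutoff_mpm) {
  if (inherits(cutoff_mpm, "speed_cutoff")) cutoff_mpm <- cutoff_mpm$value_mpm
  stopifnot(is.numeric(cutoff_mpm), length(cutoff_mpm) == 1, cutoff_mpm > 0)
  out <- mutate(steps,
                behavior = ifelse(.data$speed_mpm >= cutoff_mpm, "travel", "rest"))
  tab <- table(out$behavior)
  inform(sprintf("Classified %d steps: %d rest, %d travel (cutoff %.3f m/min)",
                 nrow(out), sum(out$behavior == "rest"),
                 sum(out$behavior == "travel"), cutoff_mpm))
  out
}

#' Histogram of log10 speeds with fitted mixture densities
#'
#' Mirrors the diagnostic figure used to justify two-state segmentation:
#' the pooled log10-speed histogram, the two fitted normal components and
#' the cutoff at their intersection.
#'
#' @param x log10 speeds.
#' @param mixture a fitted `speed_mixture`.
#' @param cutoff optional `speed_cutoff` to draw as a vertical line.
#' @param bins histogram bins.
#' @return A ggplot object.
#' @export
plot_speed_mixture <- function(x, mixture, cutoff = NULL, bins = 60) {
  df <- tibble::tibble(x = x[is.finite(x)])
  grid <- tibble::tibble(g = seq(min(df$x), max(df$x), length.out = 400))
  grid$rest <- mixture$w1 * dnorm(grid$g, mixture$mu1, mixture$sd1)
  grid$travel <- mixture$w2 * dnorm(grid$g, mixture$mu2, mixture$sd2)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = bins, fill = "grey80", colour = "grey50") +
    ggplot2::geom_line(data = grid, ggplot2::aes(x = .data$g, y = .data$rest),
                       colour = "steelblue", linewidth = 1) +
    ggplot2::geom_line(data = grid, ggplot2::aes(x = .data$g, y = .data$travel),
                       colour = "firebrick", linewidth = 1) +
    ggplot2::labs(x = expression(log[10] ~ "speed (m/min)"), y = "Density")
  if (!is.null(cutoff)) {
    p <- p + ggplot2::geom_vline(xintercept = cutoff$value_log10, linetype = 2)
  }
  p
}
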