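#' Titration series
#'
#' Concentration-intensity pairs from a fluorimetric titration.
#'
#' @param concentrations Ligand concentrations in uM, positive and strictly
#'   increasing.
#' @param intensities Gated fluorescence intensities, a.u.
#' @return Object of class `titration_series`: data frame with columns
#'   `concentration` and `intensity`.
#' @export
titration_series <- function(concentrations, intensities) {
  if (length(concentrations) != length(intensities))
    stop("concentrations and intensities must have the same length")
  if (any(concentrations <= 0)) stop("concentrations must be positive")
  if (is.unsorted(concentrations, strictly = TRUE))
    stop("concentrations must be strictly increasing")
  out <- data.frame(concentration = concentrations, intensity = intensities)
  class(out) <- c("titration_series", "data.frame")
  out
}

#' Read a titration series from two-column text
#'
#' @param path Path to a file with rows `concentration_uM intensity`
#'   (comma or whitespace delimited; `#` comments allowed).
#' @return A [titration_series()].
#' @export
read_titration <- function(path) {
  cols <- read_two_column(path, min_cols = 2L, max_cols = 2L)
  ord <- order(cols[[1L]])
  titration_series(cols[[1L]][ord], cols[[2L]][ord])
}

binding_model <- function(conc, Kd, Imax) Imax * conc / (Kd + conc)

#' Fit the one-site saturation-binding isotherm
#'
#' Constrained nonlinear least squares fit of
#' \eqn{I = I_{max} [L] / (K_d + [L])} via Levenberg-Marquardt
#' ([minpack.lm::nlsLM]) with positivity bounds. Initialisation:
#' `Imax0 = max(I)`, `Kd0 =` the concentration whose intensity is nearest
#' `Imax0 / 2`. Standard errors come from the local linearisation; with
#' `n_boot > 0`, 95% intervals come from a seeded residual bootstrap
#' (percentile method), otherwise from Wald +/- 1.96 SE.
#'
#' @param series A [titration_series()] with at least 3 points. A warning is
#'   issued when the concentration grid does not span both the rising and the
#'   flattening part of the curve (no point below the fitted Kd, or none
#'   beyond twice the fitted Kd).
#' @param n_boot Bootstrap replicate count (default 1000; 0 disables).
#' @param seed Integer seed for the bootstrap (required when `n_boot > 0`).
#' @param k_points Points per end used by [saturation_by_tangents()]
#'   (default 3).
#' @return Object of class `binding_fit`: list with `Kd`, `Imax` (uM, a.u.),
#'   `se_Kd`, `se_Imax`, `ci_Kd`, `ci_Imax` (95%), `residual_sd`,
#'   `saturation_conc` (uM, tangent-intersection estimate), `n_boot`, `seed`,
#'   `series`, and `fitted` (fitted intensities).
#' @examples
#' s <- synth_titration(titration_design(true_Kd = 17, true_Imax = 95))
#' fit_binding(s, n_boot = 0)
#' @export
fit_binding <- function(series, n_boot = 1000, seed = NULL, k_points = 3) {
  if (!inherits(series, "titration_series"))
    stop("series must be a titration_series")
  conc <- series$concentration; I <- series$intensity
  if (length(conc) < 3L) stop("at least 3 titration points are required")
  if (max(I) <= 0 || stats::sd(I) == 0)
    stop("intensities carry no signal; Kd is not identifiable")
  if (n_boot > 0 && is.null(seed)) stop("bootstrap requires a seed")
  fit <- fit_binding_core(conc, I)
  # span check against the fitted Kd: the grid should sample the rising part
  # (points below Kd) and the flattening part (points beyond ~2 Kd)
  if (max(conc) < 2 * fit$Kd || min(conc) > fit$Kd)
    warning("titration does not span both rising and flattening regions; ",
            "fit may be poorly constrained")
  resid_sd <- sqrt(sum((I - binding_model(conc, fit$Kd, fit$Imax))^2) /
                     max(1, length(conc) - 2))
  if (n_boot > 0) {
    boot <- with_local_seed(seed, {
      fitted0 <- binding_model(conc, fit$Kd, fit$Imax)
      res0 <- I - fitted0
      reps <- matrix(NA_real_, n_boot, 2)
      for (b in seq_len(n_boot)) {
        Ib <- fitted0 + sample(res0, replace = TRUE)
        fb <- try(fit_binding_core(conc, Ib), silent = TRUE)
        if (!inherits(fb, "try-error")) reps[b, ] <- c(fb$Kd, fb$Imax)
      }
      reps[stats::complete.cases(reps), , drop = FALSE]
    })
    ci_Kd <- unname(stats::quantile(boot[, 1], c(0.025, 0.975)))
    ci_Imax <- unname(stats::quantile(boot[, 2], c(0.025, 0.975)))
  } else {
    ci_Kd <- fit$Kd + c(-1.96, 1.96) * fit$se_Kd
    ci_Imax <- fit$Imax + c(-1.96, 1.96) * fit$se_Imax
  }
  out <- structure(list(
    Kd = fit$Kd, Imax = fit$Imax,
    se_Kd = fit$se_Kd, se_Imax = fit$se_Imax,
    ci_Kd = ci_Kd, ci_Imax = ci_Imax,
    residual_sd = resid_sd,
    saturation_conc = NA_real_,
    n_boot = n_boot, seed = seed,
    series = series,
    fitted = binding_model(conc, fit$Kd, fit$Imax)
  ), class = "binding_fit")
  # NA when the series is too short for two disjoint k-point secants
  out$saturation_conc <- tryCatch(
    saturation_by_tangents(out, series, k_points = k_points),
    error = function(e) NA_real_)
  out
}

# Core constrained LM fit; errors on non-convergence with the last iterate.
fit_binding_core <- function(conc, I) {
  Imax0 <- max(I)
  Kd0 <- conc[which.min(abs(I - Imax0 / 2))]
  fit <- minpack.lm::nlsLM(
    I ~ Imax * conc / (Kd + conc),
    start = list(Kd = Kd0, Imax = Imax0),
    lower = c(Kd = 1e-9, Imax = 1e-9),
    control = minpack.lm::nls.lm.control(ftol = 1e-12, ptol = 1e-12,
                                         maxiter = 500))
  info <- fit$convInfo
  if (!is.null(info) && !info$isConv)
    stop(sprintf("binding fit did not converge (last iterate Kd = %.4g, Imax = %.4g)",
                 stats::coef(fit)[["Kd"]], stats::coef(fit)[["Imax"]]))
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(Kd = NA_real_, Imax = NA_real_))
  list(Kd = cf[["Kd"]], Imax = cf[["Imax"]],
       se_Kd = se[["Kd"]], se_Imax = se[["Imax"]])
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf(paste0("One-site binding fit:\n",
                     "  Kd   = %.3g +/- %.2g uM   (95%% CI %.3g-%.3g)\n",
                     "  Imax = %.3g +/- %.2g a.u. (95%% CI %.3g-%.3g)\n",
                     "  residual sd = %.3g; saturation (tangent intersection) = %.3g uM\n"),
              x$Kd, x$se_Kd, x$ci_Kd[1], x$ci_Kd[2],
              x$Imax, x$se_Imax, x$ci_Imax[1], x$ci_Imax[2],
              x$residual_sd, x$saturation_conc))
  invisible(x)
}

#' Saturation concentration by intersection of tangents
#'
#' Empirical version of the graphical construction that intersects a line
#' through the initial (rising) part of the fitted binding curve with a line
#' through its final (plateau) part: ordinary least squares lines are fitted
#' through the first and last `k_points` of the fitted curve evaluated at the
#' measured concentrations, and the abscissa of their intersection is
#' returned. (For the analytic tangent at the origin and the exact plateau of
#' a hyperbola the intersection is at \eqn{[L] = K_d}; secants through
#' measured points land above that.)
#'
#' @param fit A [binding_fit][fit_binding()] (used for its fitted curve), or
#'   `NULL` to use the raw intensities in `series`.
#' @param series The [titration_series()] supplying the concentration grid.
#' @param k_points Number of points per end (default 3; >= 2).
#' @return Intersection abscissa in uM.
#' @export
saturation_by_tangents <- function(fit, series, k_points = 3) {
  if (!inherits(series, "titration_series"))
    stop("series must be a titration_series")
  conc <- series$concentration
  y <- if (is.null(fit)) series$intensity else
    binding_model(conc, fit$Kd, fit$Imax)
  n <- length(conc)
  if (k_points < 2) stop("k_points must be >= 2")
  if (2 * k_points > n) stop("k_points too large for ", n, " points")
  head_i <- seq_len(k_points); tail_i <- seq.int(n - k_points + 1L, n)
  l1 <- stats::coef(stats::lm(y[head_i] ~ conc[head_i]))
  l2 <- stats::coef(stats::lm(y[tail_i] ~ conc[tail_i]))
  dslope <- l1[[2]] - l2[[2]]
  if (abs(dslope) < 1e-12 * max(abs(l1[[2]]), abs(l2[[2]]), 1))
    stop("tangent lines are parallel; no intersection")
  (l2[[1]] - l1[[1]]) / dslope
}
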