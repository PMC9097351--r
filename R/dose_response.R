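#' Fit the Chou-Talalay median-effect model to single-agent data
#'
#' The median-effect equation `fa/fu = (D/Dm)^m` (with `fu = 1 - fa`)
#' linearizes to `log10(fa/fu) = m * log10(D) - m * log10(Dm)`. The fit is
#' ordinary least squares on these coordinates, the classical approach of
#' median-effect analysis software. `Dm` is the dose giving 50% effect and
#' `m` the sigmoidicity of the dose-effect curve.
#'
#' @param doses Positive doses (uM).
#' @param fa Fractions affected in (0, 1); wells with `fa` outside
#'   `(eps, 1 - eps)` are excluded from the fit and counted.
#' @param eps Usable-range clip for `fa` (default 0.005).
#' @return An object of class `me_fit` with elements `Dm`, `m`, `r`
#'   (correlation coefficient of the median-effect plot), `n_points`,
#'   `excluded_points` and `extrapolated` (TRUE when all usable points
#'   lie on one side of fa = 0.5, so Dm is an extrapolation).
#' @examples
#' d <- c(0.25, 0.5, 1, 2, 4)
#' fit <- median_effect_fit(d, d / (d + 1))  # Dm = 1, m = 1
#' @export
median_effect_fit <- function(doses, fa, eps = 0.005) {
  stopifnot(length(doses) == length(fa))
  ok <- is.finite(doses) & is.finite(fa) & doses > 0 &
    fa > eps & fa < 1 - eps
  excluded <- sum(!ok)
  if (sum(ok) < 2) {
    abort(sprintf("median-effect fit needs >= 2 usable points; %d excluded",
                  excluded), "insufficient_data_error")
  }
  x <- log10(doses[ok])
  y <- log10(fa[ok] / (1 - fa[ok]))
  fit <- stats::lm(y ~ x)
  m <- unname(stats::coef(fit)[2])
  b <- unname(stats::coef(fit)[1])
  if (!is.finite(m) || m == 0) {
    abort("median-effect slope is zero or undefined (degenerate data)",
          "insufficient_data_error")
  }
  r <- if (stats::sd(y) == 0) 1 else stats::cor(x, y)
  structure(list(Dm = 10^(-b / m), m = m, r = r,
                 n_points = sum(ok), excluded_points = excluded,
                 extrapolated = all(fa[ok] < 0.5) || all(fa[ok] > 0.5)),
            class = "me_fit")
}

#' @export
print.me_fit <- function(x, ...) {
  cat(sprintf("<me_fit> Dm = %.4g uM, m = %.3f, r = %.4f (%d points, %d excluded)%s\n",
              x$Dm, x$m, x$r, x$n_points, x$excluded_points,
              if (x$extrapolated) " [Dm extrapolated]" else ""))
  invisible(x)
}

#' Predicted fraction affected at a dose
#'
#' @param object An `me_fit`.
#' @param dose Doses (uM), `>= 0`.
#' @param ... Unused.
#' @return `fa = 1 / (1 + (Dm / D)^m)`; 0 at dose 0.
#' @export
predict.me_fit <- function(object, dose, ...) {
  ifelse(dose > 0, 1 / (1 + (object$Dm / dose)^object$m), 0)
}

#' Single-agent dose producing a given effect
#'
#' Inverts the median-effect equation: `Dx = Dm * (fa / (1 - fa))^(1/m)`,
#' the dose of the fitted agent alone that yields fraction affected `fa`.
#'
#' @param fit An `me_fit`.
#' @param fa Fraction(s) affected, strictly in (0, 1).
#' @return Dose(s) in uM.
#' @export
ed_dose <- function(fit, fa) {
  if (any(fa <= 0 | fa >= 1)) {
    abort("fa must lie strictly in (0, 1)", "out_of_range_error")
  }
  fit$Dm * (fa / (1 - fa))^(1 / fit$m)
}

#' Combination index for one combination well
#'
#' Chou-Talalay combination index in the two-term (mutually exclusive)
#' form: `CI = d1/Dx1 + d2/Dx2`, where `Dx_i` is the dose of drug i alone
#' producing the observed combination effect `fa`. CI < 1 indicates
#' synergy, CI = 1 additivity (Loewe), CI > 1 antagonism. With one dose
#' zero the expression degenerates to the remaining single-agent term.
#' The three-term mutually-nonexclusive form adds the cross product
#' `(d1 * d2) / (Dx1 * Dx2)` and is available via `form`.
#'
#' @param fit1,fit2 Single-agent [median_effect_fit()] results.
#' @param d1,d2 Doses (uM) of drugs 1 and 2 in the well; not both zero.
#' @param fa Observed fraction affected, strictly in (0, 1).
#' @param form `"mutually_exclusive"` (default) or
#'   `"mutually_nonexclusive"`.
#' @param tol Half-width of the additivity band used for the class label.
#' @return A one-row data frame: `d1, d2, fa, Dx1, Dx2, ci, class`.
#' @export
combination_index <- function(fit1, fit2, d1, d2, fa,
                              form = c("mutually_exclusive",
                                       "mutually_nonexclusive"),
                              tol = 1e-8) {
  form <- match.arg(form)
  if (!is_number(fa) || fa <= 0 || fa >= 1) {
    abort("fa must lie strictly in (0, 1)", "out_of_range_error")
  }
  if (d1 < 0 || d2 < 0 || (d1 == 0 && d2 == 0)) {
    abort("doses must be non-negative and not both zero",
          "validation_error")
  }
  dx1 <- ed_dose(fit1, fa)
  dx2 <- ed_dose(fit2, fa)
  ci <- d1 / dx1 + d2 / dx2
  if (form == "mutually_nonexclusive" && d1 > 0 && d2 > 0) {
    ci <- ci + (d1 * d2) / (dx1 * dx2)
  }
  cls <- if (ci < 1 - tol) "synergistic"
         else if (ci > 1 + tol) "antagonistic" else "additive"
  data.frame(d1 = d1, d2 = d2, fa = fa, Dx1 = dx1, Dx2 = dx2,
             ci = ci, class = cls)
}

#' Fa-CI curve for a checkerboard matrix
#'
#' Computes a per-well combination index for every combination well of a
#' normalized matrix, using `fa = 1 - viability / 100`. Wells with `fa`
#' outside the usable range `(eps, 1 - eps)` are dropped and counted in
#' the `dropped` attribute. Points are ordered by `fa` ascending, the
#' layout of an Fa-CI dot plot.
#'
#' @param mat A [dose_matrix()].
#' @param fit1,fit2 Median-effect fits for compounds a (rows) and b
#'   (columns). If omitted, they are fitted from the matrix's own
#'   single-agent margins.
#' @param eps Usable-range clip for `fa`.
#' @param form CI form, see [combination_index()].
#' @return Data frame `fa, d1, d2, Dx1, Dx2, ci` with attribute `dropped`.
#' @export
fa_ci_curve <- function(mat, fit1 = NULL, fit2 = NULL, eps = 0.005,
                        form = "mutually_exclusive") {
  if (is.null(fit1)) {
    fit1 <- median_effect_fit(mat$doses_a[-1],
                              1 - mat$viability[-1, 1] / 100, eps = eps)
  }
  if (is.null(fit2)) {
    fit2 <- median_effect_fit(mat$doses_b[-1],
                              1 - mat$viability[1, -1] / 100, eps = eps)
  }
  na <- length(mat$doses_a); nb <- length(mat$doses_b)
  rows <- list(); dropped <- 0L
  for (i in 2:na) for (j in 2:nb) {
    fa <- 1 - mat$viability[i, j] / 100
    if (fa <= eps || fa >= 1 - eps) { dropped <- dropped + 1L; next }
    rows[[length(rows) + 1L]] <-
      combination_index(fit1, fit2, mat$doses_a[i], mat$doses_b[j], fa,
                        form = form)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(d1 = numeric(), d2 = numeric(), fa = numeric(),
               Dx1 = numeric(), Dx2 = numeric(), ci = numeric(),
               class = character())
  out <- out[order(out$fa), c("fa", "d1", "d2", "Dx1", "Dx2", "ci", "class")]
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}

#' Four-parameter logistic (4PL) dose-response fit
#'
#' Fits `v(d) = bottom + (top - bottom) / (1 + (d / ic50)^hill)` by
#' nonlinear least squares (Levenberg-Marquardt). The reported IC50 is
#' the relative (inflection-point) IC50, the GraphPad-style convention.
#'
#' @param doses Doses (uM), >= 4 distinct positive levels.
#' @param viability Percent viability at each dose.
#' @return An object of class `hill_fit` with `ic50`, `hill`, `top`,
#'   `bottom`, and `residual_sd`. A non-positive fitted `hill` (viability
#'   increasing with dose) raises a `hill_sign_warning`.
#' @export
hill_fit <- function(doses, viability) {
  stopifnot(length(doses) == length(viability))
  ok <- is.finite(doses) & is.finite(viability) & doses > 0
  d <- doses[ok]; v <- viability[ok]
  if (length(unique(d)) < 4) {
    abort("4PL fit needs >= 4 positive dose levels", "insufficient_data_error")
  }
  start <- c(top = max(v), bottom = min(v),
             lic50 = log(d[which.min(abs(v - (max(v) + min(v)) / 2))]),
             hill = if (stats::cor(log(d), v) > 0) -1 else 1)
  resid_fn <- function(p) {
    v - (p["bottom"] + (p["top"] - p["bottom"]) /
           (1 + (d / exp(p["lic50"]))^p["hill"]))
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(start, fn = resid_fn,
                       control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) {
      abort(sprintf("4PL fit failed to converge: %s", conditionMessage(e)),
            "fit_failure_error")
    })
  if (fit$info == 0 || fit$info == 5) {
    abort(sprintf("4PL fit failed to converge: %s", fit$message),
          "fit_failure_error")
  }
  p <- as.list(stats::coef(fit))
  if (p$hill <= 0) {
    warn("fitted Hill slope is non-positive (viability increases with dose)",
         "hill_sign_warning")
  }
  structure(list(ic50 = exp(p$lic50), hill = p$hill, top = p$top,
                 bottom = p$bottom,
                 residual_sd = sqrt(fit$deviance /
                                      max(1, length(v) - 4))),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("<hill_fit> IC50 = %.4g uM, hill = %.3f, top = %.1f, bottom = %.1f\n",
              x$ic50, x$hill, x$top, x$bottom))
  invisible(x)
}
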