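# Goodness-of-fit metrics (least-squares AIC, reduced chi-square, Sy.x,
# R^2) and cross-model ranking used to pick the best linearization per
# VOI.

#' Least-squares Akaike information criterion
#'
#' `AIC = n log(SSR/n) + 2 p`, the form appropriate when the model is fit
#' by unweighted least squares with unknown noise variance.  No
#' small-sample correction is applied (with 5-7 frames and up to 4
#' coefficients the AICc denominator `n - p - 2` degenerates); see
#' [aicc()] for the corrected variant where it is defined.
#'
#' @param n Number of points used in the fit (`n > p`).
#' @param p Number of regression coefficients (`>= 1`).
#' @param ssr Sum of squared residuals (`>= 0`).
#' @return The AIC value; an exact fit (`ssr == 0`) returns `-Inf` with
#'   attribute `exact_fit = TRUE`.
#' @export
aic_ls <- function(n, p, ssr) {
  if (p < 1 || n <= p)
    stop("need n > p >= 1")
  if (!is.finite(ssr) || ssr < 0)
    stop("ssr must be finite and non-negative")
  if (ssr == 0)
    return(structure(-Inf, exact_fit = TRUE))
  n * log(ssr / n) + 2 * p
}

#' Small-sample corrected AIC
#'
#' `AICc = AIC + 2 p (p + 1) / (n - p - 2)` for least-squares fits
#' (variance counts as an extra parameter); requires `n > p + 2`.
#'
#' @inheritParams aic_ls
#' @return The AICc value.
#' @export
aicc <- function(n, p, ssr) {
  if (n <= p + 2)
    stop("AICc needs n > p + 2; with n points and p coefficients the correction is undefined")
  aic_ls(n, p, ssr) + 2 * p * (p + 1) / (n - p - 2)
}

#' Reduced chi-square of a weighted fit
#'
#' `sum((r_i / sigma_i)^2) / (n - p)`; values near 1 indicate residuals
#' consistent with the stated measurement errors, values below 1 an
#' overestimated (or over-fit) error.
#'
#' @param residuals Residual vector.
#' @param sigmas Per-point measurement SDs, positive; recycled if scalar.
#' @param p Number of regression coefficients.
#' @return The reduced chi-square.
#' @export
reduced_chi_square <- function(residuals, sigmas, p) {
  n <- length(residuals)
  if (n <= p)
    stop("need more residuals than coefficients")
  sigmas <- rep_len(as.numeric(sigmas), n)
  if (any(!is.finite(sigmas)) || any(sigmas <= 0))
    stop("sigmas must be positive")
  sum((residuals / sigmas)^2) / (n - p)
}

#' Standard deviation of the residuals (Sy.x)
#'
#' `sqrt(SSR / (n - p))`.
#'
#' @param residuals Residual vector.
#' @param p Number of regression coefficients.
#' @return Sy.x.
#' @export
sy_x <- function(residuals, p) {
  n <- length(residuals)
  if (n <= p)
    stop("need more residuals than coefficients")
  sqrt(sum(residuals^2) / (n - p))
}

#' Coefficient of determination
#'
#' `R^2 = 1 - SSR/SST` with the total sum of squares about the observed
#' mean.
#'
#' @param observed Observed values (non-constant, length >= 2).
#' @param fitted Fitted values.
#' @return R squared.
#' @export
r_squared <- function(observed, fitted) {
  if (length(observed) < 2L || length(observed) != length(fitted))
    stop("need >= 2 observed/fitted pairs of equal length")
  sst <- sum((observed - mean(observed))^2)
  if (sst == 0)
    stop("R^2 undefined: observed values are constant")
  1 - sum((observed - fitted)^2) / sst
}

#' Goodness-of-fit report for a graphical fit
#'
#' Residuals are taken in each model's own regression domain: tissue
#' activity C(T) for MA1/MA2, the transformed ordinate for the Logan
#' plot.  When no measurement SDs are supplied, the reduced chi-square
#' uses a constant sigma equal to Sy.x of the fit itself (making it 1 by
#' construction); supply the true noise SDs to obtain an informative
#' value.
#'
#' @param fit A `vt_fit` from [fit_vt()].
#' @param sigmas Optional per-frame measurement SDs (recycled if scalar).
#' @return A one-row data frame of class `gof_report`: `voi`, `model`,
#'   `n`, `p`, `ssr`, `aic`, `chi2_reduced`, `sy_x`, `r2`, `vt`,
#'   `t_star`.
#' @export
gof_report <- function(fit, sigmas = NULL) {
  stopifnot(inherits(fit, "vt_fit"))
  r <- fit$residuals
  n <- fit$n_points
  p <- fit$p
  ssr <- sum(r^2)
  syx <- sy_x(r, p)
  chi2 <- if (is.null(sigmas)) {
    if (syx > 0) reduced_chi_square(r, syx, p) else 0
  } else {
    reduced_chi_square(r, sigmas, p)
  }
  r2 <- tryCatch(r_squared(fit$observed, fit$fitted), error = function(e) NA_real_)
  out <- data.frame(voi = fit$voi, model = fit$model, n = n, p = p,
                    ssr = ssr, aic = as.numeric(aic_ls(n, p, ssr)),
                    chi2_reduced = chi2, sy_x = syx, r2 = r2,
                    vt = fit$vt, t_star = fit$t_star,
                    stringsAsFactors = FALSE)
  class(out) <- c("gof_report", "data.frame")
  out
}

#' Rank competing graphical fits of one VOI
#'
#' Fits are ranked primarily by AIC (ascending); ties are broken by Sy.x
#' and then by distance of the reduced chi-square from 1.  The ranking is
#' deterministic (stable within ties).
#'
#' @param fits A list of `vt_fit` objects for the same VOI.
#' @param sigmas Optional measurement SDs passed to [gof_report()].
#' @return An object of class `vt_model_comparison`: list with `table`
#'   (ranked [gof_report()] rows) and `best` (model id of the top-ranked
#'   fit).
#' @export
compare_models <- function(fits, sigmas = NULL) {
  if (inherits(fits, "vt_fit")) fits <- list(fits)
  stopifnot(length(fits) >= 1L, all(vapply(fits, inherits, TRUE, "vt_fit")))
  tab <- do.call(rbind, lapply(fits, gof_report, sigmas = sigmas))
  ord <- order(tab$aic, tab$sy_x, abs(tab$chi2_reduced - 1))
  tab <- tab[ord, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  structure(list(table = tab, best = tab$model[1L]),
            class = "vt_model_comparison")
}

#' @export
print.vt_model_comparison <- function(x, ...) {
  cat(sprintf("Model comparison (best: %s)\n", x$best))
  print(as.data.frame(x$table), row.names = FALSE, digits = 4)
  invisible(x)
}
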