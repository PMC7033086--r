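# Metabolite correction of plasma samples and bi-exponential modeling of
# the arterial input function Cp(t).  The fitted curve extrapolates the
# sparse sampling window (<= 50 min) out to the 1 h and 2 h boron
# estimation times.

#' Parent (unmetabolized) tracer fraction in plasma
#'
#' The measured metabolite fraction is linearly interpolated between the
#' configured time points and held constant outside the measured range;
#' the parent fraction is its complement.
#'
#' @param t Time(s) post-injection, minutes, non-negative.
#' @param config A [study_config()].
#' @return Parent fraction(s) in `(0, 1]`.
#' @examples
#' parent_fraction(20, study_config())  # 1 - 0.02324
#' @export
parent_fraction <- function(t, config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  t <- as.numeric(t)
  if (any(!is.finite(t)) || any(t < 0))
    stop("`t` must be non-negative")
  mf <- config$metabolite_fractions
  if (nrow(mf) == 1L) {
    frac <- rep(mf[1L, 2L], length(t))
  } else {
    frac <- stats::approx(mf[, 1L], mf[, 2L], xout = t, rule = 2)$y
  }
  1 - frac
}

#' Correct plasma samples for radiolabeled metabolites
#'
#' Multiplies each plasma sample by the parent fraction at its sampling
#' time; whole-blood values are left unchanged.
#'
#' @param series A [blood_samples()] object (raw plasma).
#' @param config A [study_config()].
#' @return A [blood_samples()] object with metabolite-corrected plasma.
#' @export
correct_for_metabolites <- function(series, config = study_config()) {
  stopifnot(inherits(series, "blood_samples"))
  blood_samples(time = series$time,
                whole_blood = series$whole_blood,
                plasma = series$plasma * parent_fraction(series$time, config))
}

# evaluate A1 e^(-l1 t) + A2 e^(-l2 t)
.biexp_eval <- function(p, t) {
  p$A1 * exp(-p$lambda1 * t) + p$A2 * exp(-p$lambda2 * t)
}

#' Fit a bi-exponential clearance model to post-peak plasma samples
#'
#' Unweighted nonlinear least squares of
#' `A1 exp(-lambda1 t) + A2 exp(-lambda2 t)` to the samples at
#' `t >= t_fit_start`, with positivity bounds on all parameters.  Starting
#' values come from a deterministic grid of log-spaced decay-rate pairs
#' (amplitudes solved linearly at each grid point), so the fit involves no
#' random numbers.  The fast component is returned first
#' (`lambda1 >= lambda2`).
#'
#' @param series A [blood_samples()] object (plasma column is fitted) or a
#'   data frame with `time` and `plasma` columns.  A `time == 0`
#'   background row is ignored.
#' @param t_fit_start Start of the clearance window in minutes, or
#'   `"auto"` (default) for the time of the maximum plasma sample.
#' @return An object of class `biexp_params`: list with `A1`, `A2`
#'   (kBq/ml), `lambda1`, `lambda2` (1/min) and `t_fit_start`.
#' @export
fit_biexponential <- function(series, t_fit_start = "auto") {
  tt <- series$time
  yy <- series$plasma
  keep <- tt > 0
  tt <- tt[keep]
  yy <- yy[keep]
  if (identical(t_fit_start, "auto"))
    t_fit_start <- tt[which.max(yy)]
  sel <- tt >= t_fit_start - 1e-9
  tt <- tt[sel]
  yy <- yy[sel]
  if (length(tt) < 4L)
    stop(sprintf("bi-exponential fit needs >= 4 samples at t >= %.3g min (got %d)",
                 t_fit_start, length(tt)))
  if (all(yy == 0))
    stop("bi-exponential fit: all plasma samples are zero")

  # deterministic multi-start: log-spaced decay-rate pairs, linear
  # amplitude solve at each, keep the best as the nls start
  l1_grid <- exp(seq(log(0.03), log(2), length.out = 6))
  l2_grid <- exp(seq(log(0.001), log(0.3), length.out = 6))
  best <- NULL
  for (l1 in l1_grid) for (l2 in l2_grid) {
    if (l1 <= l2) next
    X <- cbind(exp(-l1 * tt), exp(-l2 * tt))
    amp <- tryCatch(stats::lm.fit(X, yy)$coefficients, error = function(e) NULL)
    if (is.null(amp) || any(!is.finite(amp))) next
    amp <- pmax(amp, 0)
    ssr <- sum((yy - X %*% amp)^2)
    if (is.null(best) || ssr < best$ssr)
      best <- list(A1 = amp[[1L]], A2 = amp[[2L]], l1 = l1, l2 = l2, ssr = ssr)
  }
  if (is.null(best))
    stop("bi-exponential fit: no feasible starting values")

  df <- data.frame(t = tt, y = yy)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A1 * exp(-l1 * t) + A2 * exp(-l2 * t),
                      data = df,
                      start = list(A1 = max(best$A1, 1e-6),
                                   A2 = max(best$A2, 1e-6),
                                   l1 = best$l1, l2 = best$l2),
                      lower = c(0, 0, 1e-8, 1e-8),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) e)
  if (inherits(fit, "error"))
    stop(sprintf(paste0("bi-exponential fit did not converge: %s ",
                        "[n = %d, grid-start SSR = %.4g, ",
                        "start (A1, A2, l1, l2) = %.4g, %.4g, %.4g, %.4g]"),
                 conditionMessage(fit), length(tt), best$ssr,
                 best$A1, best$A2, best$l1, best$l2))
  cf <- stats::coef(fit)
  p <- list(A1 = cf[["A1"]], A2 = cf[["A2"]],
            lambda1 = cf[["l1"]], lambda2 = cf[["l2"]],
            t_fit_start = t_fit_start)
  if (p$lambda1 < p$lambda2) {  # fast term first
    p <- list(A1 = p$A2, A2 = p$A1, lambda1 = p$lambda2, lambda2 = p$lambda1,
              t_fit_start = t_fit_start)
  }
  structure(p, class = "biexp_params")
}

#' @export
print.biexp_params <- function(x, ...) {
  cat(sprintf("Bi-exponential clearance: %.4g exp(-%.4g t) + %.4g exp(-%.4g t)  (t >= %.3g min)\n",
              x$A1, x$lambda1, x$A2, x$lambda2, x$t_fit_start))
  invisible(x)
}

#' Build the metabolite-corrected plasma input function
#'
#' Corrects the plasma samples for metabolites, fits the bi-exponential
#' clearance model to the post-peak samples, and assembles the hybrid
#' input curve used by all graphical analyses: piecewise-linear
#' interpolation through (0, 0) and the corrected samples inside the
#' sampled window, and the bi-exponential extrapolation beyond the last
#' sample, rescaled so the two pieces join continuously.
#'
#' @param series A [blood_samples()] object (raw plasma).
#' @param config A [study_config()].
#' @param t_fit_start Passed to [fit_biexponential()].
#' @return An object of class `plasma_input` with elements `samples`
#'   (corrected series), `biexp` ([fit_biexponential()] result), `scale`
#'   (junction continuity factor) and `t_last`.
#' @seealso [predict.plasma_input()], [plasma_integral()]
#' @export
fit_input_function <- function(series, config = study_config(),
                               t_fit_start = "auto") {
  corrected <- correct_for_metabolites(series, config)
  biexp <- fit_biexponential(corrected, t_fit_start)
  pos <- corrected$time > 0
  knots_t <- c(0, corrected$time[pos])
  knots_y <- c(0, corrected$plasma[pos])
  t_last <- knots_t[length(knots_t)]
  y_last <- knots_y[length(knots_y)]
  model_last <- .biexp_eval(biexp, t_last)
  scale <- if (model_last > 0) y_last / model_last else 0
  structure(list(samples = corrected, biexp = biexp,
                 knots_t = knots_t, knots_y = knots_y,
                 scale = scale, t_last = t_last),
            class = "plasma_input")
}

#' Evaluate the plasma input curve
#'
#' @param object A `plasma_input` from [fit_input_function()].
#' @param t Time(s) in minutes, non-negative.
#' @param ... Unused.
#' @return Plasma activity in kBq/ml; piecewise-linear inside the sampled
#'   window (with Cp(0) = 0), continuity-rescaled bi-exponential beyond
#'   the last sample.
#' @export
predict.plasma_input <- function(object, t, ...) {
  t <- as.numeric(t)
  if (any(!is.finite(t)) || any(t < 0))
    stop("`t` must be non-negative")
  out <- numeric(length(t))
  inside <- t <= object$t_last
  if (any(inside))
    out[inside] <- stats::approx(object$knots_t, object$knots_y,
                                 xout = t[inside])$y
  if (any(!inside))
    out[!inside] <- object$scale * .biexp_eval(object$biexp, t[!inside])
  pmax(out, 0)
}

#' Cumulative integral of the plasma input curve
#'
#' Computes the running integral of the hybrid plasma curve from 0 to
#' each requested time in closed form: exact trapezoid over the
#' piecewise-linear sample segment plus the analytic integral of the
#' rescaled bi-exponential tail.
#'
#' @param object A `plasma_input`.
#' @param t Time(s) in minutes, non-negative.
#' @return Integral(s) in kBq.min/ml.
#' @export
plasma_integral <- function(object, t) {
  stopifnot(inherits(object, "plasma_input"))
  t <- as.numeric(t)
  if (any(!is.finite(t)) || any(t < 0))
    stop("`t` must be non-negative")
  kt <- object$knots_t
  ky <- object$knots_y
  seg <- diff(kt) * (ky[-1L] + ky[-length(ky)]) / 2
  cum <- c(0, cumsum(seg))  # exact integral at each knot
  out <- numeric(length(t))
  inside <- t <= object$t_last
  if (any(inside)) {
    ti <- t[inside]
    idx <- findInterval(ti, kt, rightmost.closed = TRUE)
    y_at <- stats::approx(kt, ky, xout = ti)$y
    out[inside] <- cum[idx] + (ti - kt[idx]) * (ky[idx] + y_at) / 2
  }
  if (any(!inside)) {
    to <- t[!inside]
    p <- object$biexp
    s <- object$scale
    tl <- object$t_last
    tail1 <- p$A1 / p$lambda1 * (exp(-p$lambda1 * tl) - exp(-p$lambda1 * to))
    tail2 <- p$A2 / p$lambda2 * (exp(-p$lambda2 * tl) - exp(-p$lambda2 * to))
    out[!inside] <- cum[length(cum)] + s * (tail1 + tail2)
  }
  out
}

#' @export
print.plasma_input <- function(x, ...) {
  cat(sprintf("Plasma input function: %d samples to %.3g min; ",
              sum(x$samples$time > 0), x$t_last))
  print(x$biexp)
  invisible(x)
}

#' @export
plot.plasma_input <- function(x, t_max = 120, ...) {
  tt <- seq(0, t_max, length.out = 400)
  graphics::plot(tt, predict(x, tt), type = "l",
                 xlab = "time (min)", ylab = "plasma activity (kBq/ml)",
                 main = "Metabolite-corrected plasma input", ...)
  graphics::points(x$samples$time, x$samples$plasma, pch = 16)
  graphics::abline(v = x$t_last, lty = 3)
  invisible(x)
}
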