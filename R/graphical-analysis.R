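# Graphical (linearized) estimation of the total distribution volume Vt
# for reversible tracers: Logan plot, Ichise MA1 and Ichise MA2, with
# automatic equilibration-time (t*) selection for the Logan and MA1
# plots.

#' Running integral by the trapezoid rule
#'
#' Computes the cumulative integral of a sampled curve at each of its own
#' sample times.  When the first time is positive, the curve is anchored
#' at (0, 0) and the first segment contributes the corresponding
#' triangle.
#'
#' @param times Strictly increasing sample times (min), non-negative.
#' @param values Sampled values (same length).
#' @return Running integral evaluated at each `times`.
#' @export
cumulative_integral <- function(times, values) {
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) != length(values) || length(times) == 0L)
    stop("`times` and `values` must be equal-length, non-empty")
  if (any(!is.finite(times)) || any(!is.finite(values)))
    stop("non-finite input")
  if (any(times < 0))
    stop("times must be non-negative")
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("times must be strictly increasing")
  if (times[1L] > 0) {
    tt <- c(0, times)
    vv <- c(0, values)
  } else {
    tt <- times
    vv <- values
  }
  cum <- c(0, cumsum(diff(tt) * (vv[-1L] + vv[-length(vv)]) / 2))
  cum[(length(cum) - length(times) + 1L):length(cum)]
}

#' Two-tissue-compartment rate constants
#'
#' @param K1 Plasma-to-tissue transport, ml/ml/min.
#' @param k2 Tissue-to-plasma efflux, 1/min, positive.
#' @param k3,k4 Exchange with the second tissue compartment, 1/min;
#'   `k3 > 0` requires `k4 > 0`.
#' @return An object of class `rate_constants`.
#' @export
rate_constants <- function(K1, k2, k3 = 0, k4 = 0) {
  vals <- c(K1 = K1, k2 = k2, k3 = k3, k4 = k4)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("rate constants must be finite and non-negative")
  if (k2 <= 0)
    stop("k2 must be positive")
  if (k3 > 0 && k4 <= 0)
    stop("k3 > 0 requires k4 > 0")
  structure(as.list(vals), class = "rate_constants")
}

#' Closed-form total distribution volume from rate constants
#'
#' `Vt = K1/k2` for a one-tissue model and `Vt = (K1/k2) (1 + k3/k4)` for
#' the two-tissue model; this is the ground-truth oracle used for
#' simulation testing.
#'
#' @param rates A [rate_constants()] object.
#' @return Vt in ml/ml.
#' @export
vt_from_rates <- function(rates) {
  stopifnot(inherits(rates, "rate_constants"))
  if (rates$k2 == 0)
    stop("k2 must be positive")
  if (rates$k3 == 0) rates$K1 / rates$k2
  else rates$K1 / rates$k2 * (1 + rates$k3 / rates$k4)
}

#' Running tissue integral from frame-averaged activity
#'
#' Each PET frame value is the time-average of the activity over the
#' frame, so the within-frame integral is exactly the frame value times
#' the frame duration.  The running integral of a TAC up to each frame
#' midpoint is therefore assembled as: a linear rise from (0, 0) to the
#' first frame start (zero-width on the usual schedule), the exact sum of
#' complete frames, trapezoids across the short inter-frame gaps, and
#' half of the current frame.  This is substantially more accurate than
#' a midpoint trapezoid for curves that change quickly relative to the
#' frame spacing.
#'
#' @param tissue A [tissue_tac()].
#' @return Running integral of C(t) at each frame midpoint, kBq.min/ml.
#' @export
tissue_integral <- function(tissue) {
  stopifnot(inherits(tissue, "tissue_tac"))
  st <- tissue$schedule$start
  du <- tissue$schedule$duration
  act <- tissue$activity
  n <- length(st)
  cum_at_start <- numeric(n)
  acc <- if (st[1L] > 0) st[1L] * act[1L] / 2 else 0
  cum_at_start[1L] <- acc
  if (n > 1L) for (j in seq_len(n - 1L)) {
    acc <- acc + act[j] * du[j]
    gap <- st[j + 1L] - (st[j] + du[j])
    acc <- acc + gap * (act[j] + act[j + 1L]) / 2
    cum_at_start[j + 1L] <- acc
  }
  cum_at_start + act * du / 2
}

# regression ingredients shared by all three linearizations
.graphical_data <- function(tissue, input) {
  mid <- frame_midpoints(tissue$schedule)
  ct <- tissue$activity
  int_cp <- plasma_integral(input, mid)
  int_ct <- tissue_integral(tissue)
  list(mid = mid, ct = ct, int_cp = int_cp, int_ct = int_ct)
}

.n_coef <- c(logan = 2L, ma1 = 2L, ma2 = 4L)

.new_vt_fit <- function(model, voi, vt, coef, t_star, converged, idx, mid,
                        observed, fitted, flags = character()) {
  structure(list(model = model, voi = voi, vt = vt, coef = coef,
                 t_star = t_star, t_star_converged = converged,
                 n_points = length(idx), frames_used = idx,
                 midpoints = mid[idx], observed = observed, fitted = fitted,
                 residuals = observed - fitted, p = .n_coef[[model]],
                 flags = flags),
            class = "vt_fit")
}

#' Estimate Vt by a graphical analysis
#'
#' Fits one of the three linearizations for reversible tracers over the
#' frames whose midpoints lie at or after the equilibration time `t_star`:
#'
#' * `"logan"`: ordinary least squares of `int C / C(T)` on
#'   `int Cp / C(T)`; Vt is the slope, `b` the intercept.
#' * `"ma1"`: multilinear regression `C(T) = -(Vt/b) int Cp + (1/b) int C`;
#'   Vt is minus the ratio of the coefficients.
#' * `"ma2"`: multilinear regression of `C(T)` on the double integrals of
#'   Cp and C and the single integrals of C and Cp (coefficients
#'   `gamma1..gamma4`); `Vt = -gamma1/gamma2` and `gamma4` estimates K1.
#'
#' All integrals start at (0, 0); tissue integrals use the trapezoid rule
#' over mid-frame time stamps and plasma integrals use the closed-form
#' integral of the hybrid input curve.
#'
#' @param tissue A [tissue_tac()].
#' @param input A `plasma_input` from [fit_input_function()].
#' @param model `"logan"`, `"ma1"` or `"ma2"`.
#' @param t_star Equilibration time in minutes.  `NULL` (default) selects
#'   it automatically via [find_t_star()] for Logan/MA1 and uses 20 min
#'   for MA2, which needs no equilibration but is conventionally
#'   restricted to the later frames.
#' @param max_rel_error Passed to [find_t_star()] when `t_star` is
#'   automatic.
#' @return An object of class `vt_fit`; see [summary.vt_fit()],
#'   [gof_report()].
#' @examples
#' cfg <- sim_config(noise_cv = 0)
#' study <- make_study_fixture(cfg)
#' inp <- fit_input_function(study$blood)
#' fit_vt(study$tacs$pancreas, inp, model = "ma2")
#' @export
fit_vt <- function(tissue, input, model = c("logan", "ma1", "ma2"),
                   t_star = NULL, max_rel_error = 0.01) {
  model <- match.arg(model)
  stopifnot(inherits(tissue, "tissue_tac"), inherits(input, "plasma_input"))
  converged <- TRUE
  if (is.null(t_star) || identical(t_star, "auto")) {
    if (model == "ma2") {
      t_star <- 20
    } else {
      sel <- find_t_star(tissue, input, model, max_rel_error = max_rel_error)
      t_star <- sel$t_star
      converged <- sel$converged
    }
  }
  d <- .graphical_data(tissue, input)
  idx <- which(d$mid >= t_star - 1e-9)
  p <- .n_coef[[model]]
  if (length(idx) < p + 1L)
    stop(sprintf("%s fit needs >= %d frames with midpoint >= t* = %.3g min (got %d)",
                 model, p + 1L, t_star, length(idx)))

  # identity guard: tissue curve numerically equal to the plasma curve
  cp_mid <- predict(input, d$mid)
  if (model %in% c("logan", "ma1") &&
      max(abs(d$ct - cp_mid)) <= 1e-12 * max(cp_mid, 1)) {
    obs <- if (model == "logan") d$int_ct[idx] / d$ct[idx] else d$ct[idx]
    return(.new_vt_fit(model, tissue$voi, vt = 1,
                       coef = c(Vt = 1, b = 0), t_star = t_star,
                       converged = converged, idx = idx, mid = d$mid,
                       observed = obs, fitted = obs,
                       flags = "identity"))
  }

  if (model == "logan") {
    if (any(d$ct[idx] <= 0))
      stop(sprintf("Logan fit: C(T) is zero in frame %d (midpoint %.2f min)",
                   idx[which(d$ct[idx] <= 0)[1L]],
                   d$mid[idx[which(d$ct[idx] <= 0)[1L]]]))
    x <- d$int_cp[idx] / d$ct[idx]
    y <- d$int_ct[idx] / d$ct[idx]
    X <- cbind(1, x)
    if (qr(X)$rank < 2L)
      stop("Logan fit: singular design matrix")
    beta <- stats::lm.fit(X, y)$coefficients
    vt <- beta[[2L]]
    fitted <- as.numeric(X %*% beta)
    return(.new_vt_fit("logan", tissue$voi, vt,
                       coef = c(Vt = vt, b = beta[[1L]]),
                       t_star, converged, idx, d$mid, y, fitted))
  }

  if (model == "ma1") {
    X <- cbind(d$int_cp[idx], d$int_ct[idx])
    if (qr(X)$rank < 2L)
      stop("MA1 fit: singular design matrix")
    beta <- stats::lm.fit(X, d$ct[idx])$coefficients
    if (!is.finite(beta[[2L]]) || beta[[2L]] == 0)
      stop("MA1 fit: degenerate coefficient on the tissue integral")
    vt <- -beta[[1L]] / beta[[2L]]
    fitted <- as.numeric(X %*% beta)
    return(.new_vt_fit("ma1", tissue$voi, vt,
                       coef = c(Vt = vt, b = 1 / beta[[2L]],
                                beta1 = beta[[1L]], beta2 = beta[[2L]]),
                       t_star, converged, idx, d$mid, d$ct[idx], fitted))
  }

  # MA2: double integrals by trapezoid over the running single integrals,
  # same (0, 0) origin
  iint_cp <- cumulative_integral(d$mid, d$int_cp)
  iint_ct <- cumulative_integral(d$mid, d$int_ct)
  X <- cbind(iint_cp, iint_ct, d$int_ct, d$int_cp)[idx, , drop = FALSE]
  if (qr(X)$rank < 4L)
    stop("MA2 fit: singular design matrix")
  gam <- stats::lm.fit(X, d$ct[idx])$coefficients
  if (!is.finite(gam[[2L]]) || gam[[2L]] == 0)
    stop("MA2 fit: degenerate gamma2 coefficient")
  flags <- character()
  if (gam[[2L]] >= 0)
    flags <- "unphysical-fit"
  vt <- -gam[[1L]] / gam[[2L]]
  fitted <- as.numeric(X %*% gam)
  .new_vt_fit("ma2", tissue$voi, vt,
              coef = c(Vt = vt, gamma1 = gam[[1L]], gamma2 = gam[[2L]],
                       gamma3 = gam[[3L]], gamma4 = gam[[4L]],
                       K1 = gam[[4L]]),
              t_star, converged, idx, d$mid, d$ct[idx], fitted,
              flags = flags)
}

#' Select the equilibration time t*
#'
#' Scans the frame midpoints from the earliest feasible one and returns
#' the smallest t* at which the chosen graphical plot is linear: the
#' maximum relative deviation of the regression,
#' `max |fitted - observed| / |fitted|` over the frames used, must not
#' exceed `max_rel_error` (default 1%).  If no midpoint qualifies, the
#' latest feasible t* is returned with `converged = FALSE`.
#'
#' @param tissue A [tissue_tac()].
#' @param input A `plasma_input`.
#' @param model `"logan"` or `"ma1"` (MA2 uses a fixed conventional t*).
#' @param max_rel_error Maximum allowed relative regression error.
#' @return List with `t_star` (min), `converged` (logical) and
#'   `max_rel_error_attained`.
#' @export
find_t_star <- function(tissue, input, model = c("logan", "ma1"),
                        max_rel_error = 0.01) {
  model <- match.arg(model)
  mid <- frame_midpoints(tissue$schedule)
  p <- .n_coef[[model]]
  n_cand <- length(mid) - p
  if (n_cand < 1L)
    stop(sprintf("t* search needs >= %d frames", p + 1L))
  last_ok <- NULL
  for (i in seq_len(n_cand)) {
    fit <- tryCatch(fit_vt(tissue, input, model, t_star = mid[i]),
                    error = function(e) NULL)
    if (is.null(fit)) next
    denom <- abs(fit$fitted)
    rel <- ifelse(denom > 0, abs(fit$residuals) / denom, Inf)
    err <- max(rel)
    last_ok <- list(t_star = mid[i], converged = FALSE,
                    max_rel_error_attained = err)
    if (err <= max_rel_error) {
      last_ok$converged <- TRUE
      return(last_ok)
    }
  }
  if (is.null(last_ok))
    stop(sprintf("t* search: no feasible %s fit at any candidate", model))
  last_ok
}

# --- vt_fit methods ---------------------------------------------------------

#' @export
print.vt_fit <- function(x, ...) {
  cat(sprintf("%s fit, VOI '%s': Vt = %.4g ml/ml (t* = %.3g min, %d frames%s)\n",
              toupper(x$model), x$voi, x$vt, x$t_star, x$n_points,
              if (x$t_star_converged) "" else ", t* not converged"))
  if (length(x$flags))
    cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.vt_fit <- function(object, ...) object$coef

#' @export
residuals.vt_fit <- function(object, ...) object$residuals

#' @export
fitted.vt_fit <- function(object, ...) object$fitted

#' Summarize a graphical Vt fit
#'
#' @param object A `vt_fit`.
#' @param sigmas Optional per-frame measurement SDs for the reduced
#'   chi-square (see [gof_report()]).
#' @param ... Unused.
#' @return A list of class `summary.vt_fit` with the fit and its
#'   goodness-of-fit report.
#' @export
summary.vt_fit <- function(object, sigmas = NULL, ...) {
  structure(list(fit = object, gof = gof_report(object, sigmas = sigmas)),
            class = "summary.vt_fit")
}

#' @export
print.summary.vt_fit <- function(x, ...) {
  print(x$fit)
  cat("Coefficients:\n")
  print(x$fit$coef)
  cat("Goodness of fit:\n")
  print(x$gof, row.names = FALSE)
  invisible(x)
}

#' Plot a graphical Vt fit
#'
#' For the Logan plot, draws the transformed variables and the fitted
#' line; for MA1/MA2, draws observed and fitted tissue activity against
#' mid-frame time.
#'
#' @param x A `vt_fit`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.vt_fit <- function(x, ...) {
  if (x$model == "logan") {
    xx <- (x$observed - x$residuals - x$coef[["b"]]) / x$coef[["Vt"]]
    graphics::plot(xx, x$observed, pch = 16,
                   xlab = expression(integral(Cp * dt) / C(T)),
                   ylab = expression(integral(C * dt) / C(T)),
                   main = sprintf("Logan plot, %s (Vt = %.3g)", x$voi, x$vt),
                   ...)
    graphics::abline(x$coef[["b"]], x$coef[["Vt"]])
  } else {
    graphics::plot(x$midpoints, x$observed, pch = 16,
                   xlab = "time (min)", ylab = "C(T) (kBq/ml)",
                   main = sprintf("%s fit, %s (Vt = %.3g)",
                                  toupper(x$model), x$voi, x$vt), ...)
    graphics::lines(x$midpoints, x$fitted)
  }
  invisible(x)
}
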