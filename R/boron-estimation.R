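# Conversion of Vt and plasma activity into tissue boron-10
# concentration (ppm) for the therapeutic 10B-BPA-fructose protocol.
# The chain is: tissue activity T = P * Vt; molar concentration M = T/S;
# tracer-dose boron B = MW_B * M * 1e6 ppm (1 g of tissue taken as 1 ml);
# therapeutic-dose boron H = B * (dose/I) * (MW_FBPA / MW_BPA-fr).

#' Tissue tracer activity from plasma activity and Vt
#'
#' @param P Plasma activity, kBq/ml, non-negative.
#' @param V Total distribution volume, ml/ml, non-negative.
#' @return Tissue activity `T = P * V`, kBq/ml.
#' @export
tissue_activity <- function(P, V) {
  if (any(P < 0) || any(V < 0))
    stop("P and V must be non-negative")
  P * V
}

#' Tracer activity to molar concentration
#'
#' @param T_act Tissue activity, kBq/ml.
#' @param S Specific radioactivity, kBq/mol, positive.
#' @return Molar concentration `T/S`, mol/ml.
#' @export
activity_to_molar <- function(T_act, S) {
  if (any(!is.finite(S)) || any(S <= 0))
    stop("specific activity S must be positive")
  T_act / S
}

#' Molar tracer concentration to boron-10 ppm
#'
#' One FBPA molecule carries one boron-10 atom; with tissue density taken
#' as 1 g/ml, ppm is micrograms of boron-10 per gram of tissue.
#'
#' @param M Molar concentration, mol/ml.
#' @param mw_boron Boron-10 molecular weight, g/mol (default 10).
#' @return Boron concentration in ppm.
#' @export
molar_to_ppm <- function(M, mw_boron = 10) {
  if (any(!is.finite(mw_boron)) || any(mw_boron <= 0))
    stop("mw_boron must be positive")
  mw_boron * M * 1e6
}

#' Scale tracer-dose boron to the therapeutic dose
#'
#' `H = B * (dose / I) * (MW_FBPA / MW_BPA-fr)`; with the default study
#' constants the multiplier is about 17142.4.
#'
#' @param B Boron concentration at the tracer dose, ppm.
#' @param config A [study_config()].
#' @return Boron concentration at the therapeutic dose, ppm.
#' @seealso [therapeutic_multiplier()]
#' @export
scale_to_therapeutic <- function(B, config = study_config()) {
  B * therapeutic_multiplier(config)
}

#' The tracer-to-therapeutic dose multiplier H/B
#'
#' @param config A [study_config()].
#' @return `(therapeutic dose / injected tracer mass) * (MW_FBPA / MW_BPA-fr)`.
#' @export
therapeutic_multiplier <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  config$therapeutic_dose_g / config$injected_dose_g *
    config$mw_fbpa / config$mw_bpa
}

#' Plasma activity to therapeutic-dose boron ppm
#'
#' Runs the activity-to-ppm chain on a plasma activity value (Vt = 1).
#'
#' @param P Plasma activity, kBq/ml.
#' @param config A [study_config()].
#' @return Therapeutic-dose boron, ppm.
#' @export
ppm_from_activity <- function(P, config = study_config()) {
  scale_to_therapeutic(
    molar_to_ppm(activity_to_molar(P, config$specific_activity),
                 config$mw_boron),
    config)
}

#' Therapeutic-dose boron ppm to implied plasma activity
#'
#' Inverts the chain: `H -> B -> M -> T` (kBq/ml).
#'
#' @param H Therapeutic-dose boron, ppm.
#' @param config A [study_config()].
#' @return Implied activity, kBq/ml.
#' @export
activity_from_ppm <- function(H, config = study_config()) {
  B <- H / therapeutic_multiplier(config)
  M <- B / (config$mw_boron * 1e6)
  M * config$specific_activity
}

#' Estimate tissue boron-10 concentration at the therapeutic dose
#'
#' Chains tissue activity, molar conversion, ppm conversion and
#' therapeutic-dose scaling for one or more organs.  The chain is linear
#' in plasma activity, so the tissue value always satisfies
#' `H_tissue = Vt * H_plasma`.
#'
#' @param vt Named numeric vector of Vt values (ml/ml), one per organ.
#' @param plasma Either a `plasma_input` (activity is evaluated at each
#'   `time`) or a numeric vector of plasma boron ppm values at the
#'   therapeutic dose, one per `time` (recycled if scalar).
#' @param time Time(s) post-injection in minutes.
#' @param config A [study_config()].
#' @return A data frame of class `boron_estimate` with one row per organ
#'   and time: `voi`, `time`, `vt`, `tissue_kBq_ml`, `molar_mol_ml`,
#'   `boron_tracer_ppm` and `boron_therapy_ppm`, sorted within each time
#'   by descending therapeutic boron.
#' @examples
#' estimate_boron(c(pancreas = 0.94, lung = 0.16), plasma = 14.9, time = 60)
#' @export
estimate_boron <- function(vt, plasma, time, config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  vt <- unlist(vt)
  if (is.null(names(vt)))
    names(vt) <- paste0("voi", seq_along(vt))
  if (any(!is.finite(vt)) || any(vt < 0))
    stop("Vt values must be finite and non-negative")
  time <- as.numeric(time)
  if (any(!is.finite(time)) || any(time < 0))
    stop("`time` must be non-negative")
  if (inherits(plasma, "plasma_input")) {
    P <- predict(plasma, time)
  } else {
    H_plasma <- rep_len(as.numeric(plasma), length(time))
    if (any(!is.finite(H_plasma)) || any(H_plasma < 0))
      stop("plasma ppm values must be finite and non-negative")
    P <- activity_from_ppm(H_plasma, config)
  }
  rows <- lapply(seq_along(time), function(i) {
    T_act <- tissue_activity(P[i], vt)
    M <- activity_to_molar(T_act, config$specific_activity)
    B <- molar_to_ppm(M, config$mw_boron)
    H <- scale_to_therapeutic(B, config)
    d <- data.frame(voi = names(vt), time = time[i], vt = as.numeric(vt),
                    tissue_kBq_ml = as.numeric(T_act),
                    molar_mol_ml = as.numeric(M),
                    boron_tracer_ppm = as.numeric(B),
                    boron_therapy_ppm = as.numeric(H),
                    stringsAsFactors = FALSE)
    d[order(-d$boron_therapy_ppm), , drop = FALSE]
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("boron_estimate", "data.frame")
  out
}

#' @export
print.boron_estimate <- function(x, digits = 3, ...) {
  cat("Estimated tissue boron-10 at the therapeutic dose (ppm):\n")
  print(data.frame(voi = x$voi, time_min = x$time, vt = round(x$vt, 3),
                   boron_ppm = round(x$boron_therapy_ppm, 1)),
        row.names = FALSE)
  invisible(x)
}
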