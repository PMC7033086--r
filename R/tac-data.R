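# Domain containers for dynamic PET data: frame schedules, tissue
# time-activity curves (TACs), blood sample series, and study-level
# constants.  Times are minutes internally; activities are kBq/ml and
# assumed decay-corrected to the start of the first scan.

#' PET frame schedule
#'
#' A set of non-overlapping acquisition frames, stored as start times and
#' durations in minutes.
#'
#' @param start Numeric vector of frame start times, strictly increasing.
#' @param duration Numeric vector of frame durations (same length), all
#'   positive; frames must not overlap.
#' @param unit Unit of the supplied times, `"min"` (default) or `"s"`.
#' @return An object of class `frame_schedule` with elements `start` and
#'   `duration`, both in minutes.
#' @seealso [frame_midpoints()], [default_schedule()]
#' @examples
#' sched <- frame_schedule(start = c(0, 500.5, 1001), duration = rep(455, 3),
#'                         unit = "s")
#' frame_midpoints(sched)
#' @export
frame_schedule <- function(start, duration, unit = c("min", "s")) {
  unit <- match.arg(unit)
  start <- as.numeric(start)
  duration <- as.numeric(duration)
  if (length(start) == 0L || length(start) != length(duration))
    stop("`start` and `duration` must be non-empty vectors of equal length")
  if (any(!is.finite(start)) || any(!is.finite(duration)))
    stop("frame times must be finite")
  if (unit == "s") {
    start <- start / 60
    duration <- duration / 60
  }
  if (any(start < 0))
    stop("frame start times must be non-negative")
  if (length(start) > 1L && any(diff(start) <= 0))
    stop("frame start times must be strictly increasing")
  if (any(duration <= 0))
    stop("frame durations must be positive")
  ends <- start + duration
  if (length(start) > 1L && any(start[-1L] < ends[-length(ends)] - 1e-9))
    stop("frames must not overlap")
  structure(list(start = start, duration = duration),
            class = "frame_schedule")
}

#' @export
print.frame_schedule <- function(x, ...) {
  cat(sprintf("PET frame schedule: %d frames, %.2f-%.2f min\n",
              length(x$start), x$start[1L],
              x$start[length(x$start)] + x$duration[length(x$duration)]))
  invisible(x)
}

#' Number of frames in a schedule
#' @param schedule A [frame_schedule()].
#' @return Integer frame count.
#' @export
n_frames <- function(schedule) {
  stopifnot(inherits(schedule, "frame_schedule"))
  length(schedule$start)
}

#' The 7-frame whole-body acquisition schedule
#'
#' Seven repeated whole-body scans of 455 s each, separated by 45.5 s
#' transfer gaps, as used for dynamic 18F-FBPA imaging.
#'
#' @param n_frames Number of frames (default 7).
#' @param frame_s Frame acquisition time in seconds (default 455).
#' @param gap_s Inter-frame gap in seconds (default 45.5).
#' @return A [frame_schedule()].
#' @export
default_schedule <- function(n_frames = 7L, frame_s = 455, gap_s = 45.5) {
  frame_schedule(start = (seq_len(n_frames) - 1) * (frame_s + gap_s),
                 duration = rep(frame_s, n_frames), unit = "s")
}

#' Mid-frame time stamps
#'
#' Frame activity values are conventionally plotted and regressed at the
#' middle of each scan; all graphical analyses in this package time-stamp
#' frames this way.
#'
#' @param schedule A [frame_schedule()].
#' @return Numeric vector of frame midpoints in minutes.
#' @export
frame_midpoints <- function(schedule) {
  stopifnot(inherits(schedule, "frame_schedule"))
  schedule$start + schedule$duration / 2
}

#' Tissue time-activity curve
#'
#' One volume of interest's decay-corrected activity concentration per
#' frame, C(t), in kBq/ml.
#'
#' @param voi Character label of the volume of interest.
#' @param schedule A [frame_schedule()].
#' @param activity Numeric vector, one non-negative value per frame.
#' @return An object of class `tissue_tac`.
#' @export
tissue_tac <- function(voi, schedule, activity) {
  stopifnot(inherits(schedule, "frame_schedule"))
  activity <- as.numeric(activity)
  if (length(activity) != n_frames(schedule))
    stop(sprintf("VOI '%s': activity length (%d) != frame count (%d)",
                 voi, length(activity), n_frames(schedule)))
  if (any(!is.finite(activity)))
    stop(sprintf("VOI '%s': activity contains missing or non-finite values",
                 voi))
  if (any(activity < 0))
    stop(sprintf("VOI '%s': activity must be non-negative", voi))
  structure(list(voi = as.character(voi), schedule = schedule,
                 activity = activity),
            class = "tissue_tac")
}

#' @export
print.tissue_tac <- function(x, ...) {
  cat(sprintf("Tissue TAC '%s': %d frames, peak %.3g kBq/ml at %.1f min\n",
              x$voi, n_frames(x$schedule), max(x$activity),
              frame_midpoints(x$schedule)[which.max(x$activity)]))
  invisible(x)
}

#' Blood sample series
#'
#' Manually sampled whole-blood and plasma activity concentrations.  A
#' `time == 0` row is interpreted as the pre-injection background sample:
#' it is stored but excluded from all curve fits (it is zero by
#' construction and would distort the clearance model).
#'
#' @param time Sample times in minutes, non-negative and strictly
#'   increasing.
#' @param whole_blood Whole-blood activity, kBq/ml, non-negative.
#' @param plasma Plasma activity, kBq/ml, non-negative.
#' @return A data frame of class `blood_samples` with columns `time`,
#'   `whole_blood`, `plasma`.
#' @export
blood_samples <- function(time, whole_blood, plasma) {
  time <- as.numeric(time)
  whole_blood <- as.numeric(whole_blood)
  plasma <- as.numeric(plasma)
  n <- length(time)
  if (n == 0L || length(whole_blood) != n || length(plasma) != n)
    stop("`time`, `whole_blood` and `plasma` must be equal-length, non-empty")
  if (any(!is.finite(time)) || any(!is.finite(whole_blood)) ||
      any(!is.finite(plasma)))
    stop("blood samples contain missing or non-finite values")
  if (any(time < 0))
    stop("sample times must be non-negative")
  if (anyDuplicated(time))
    stop("duplicate sample times")
  if (n > 1L && any(diff(time) <= 0))
    stop("sample times must be strictly increasing")
  if (any(whole_blood < 0) || any(plasma < 0))
    stop("activities must be non-negative")
  structure(data.frame(time = time, whole_blood = whole_blood,
                       plasma = plasma),
            class = c("blood_samples", "data.frame"))
}

#' Study configuration constants
#'
#' Tracer and protocol constants used for metabolite correction and for
#' the conversion of tracer activity into boron-10 concentration at the
#' therapeutic 10B-BPA-fructose dose.  Defaults are the published study
#' values: mean injected 18F-FBPA mass 0.00102 g, mean specific
#' radioactivity 4.41e10 kBq/mol (44.1 GBq/mmol), plasma metabolite
#' fractions 2.324% at 20 min and 3.966% at 50 min, therapeutic dose 30 g,
#' and molecular weights 10 (boron-10), 226.9 (FBPA) and 389.3
#' (BPA-fructose) g/mol.
#'
#' @param injected_dose_g Injected tracer mass I, grams.
#' @param specific_activity Specific radioactivity S, kBq/mol.
#' @param metabolite_fractions Two-column matrix (time min, metabolite
#'   fraction in `[0, 1)`).
#' @param therapeutic_dose_g Therapeutic 10B-BPA-fructose dose, grams.
#' @param mw_boron,mw_fbpa,mw_bpa Molecular weights, g/mol.
#' @return An object of class `study_config`.
#' @export
study_config <- function(injected_dose_g = 0.00102,
                         specific_activity = 4.41e10,
                         metabolite_fractions = cbind(time = c(20, 50),
                                                      fraction = c(0.02324,
                                                                   0.03966)),
                         therapeutic_dose_g = 30,
                         mw_boron = 10, mw_fbpa = 226.9, mw_bpa = 389.3) {
  metabolite_fractions <- as.matrix(metabolite_fractions)
  if (ncol(metabolite_fractions) != 2L || nrow(metabolite_fractions) < 1L)
    stop("`metabolite_fractions` must be a (time, fraction) matrix with >= 1 row")
  if (any(metabolite_fractions[, 2L] < 0) ||
      any(metabolite_fractions[, 2L] >= 1))
    stop("metabolite fractions must lie in [0, 1)")
  if (any(diff(metabolite_fractions[, 1L]) <= 0) && nrow(metabolite_fractions) > 1L)
    stop("metabolite fraction times must be strictly increasing")
  vals <- c(injected_dose_g, specific_activity, therapeutic_dose_g,
            mw_boron, mw_fbpa, mw_bpa)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all study constants must be positive")
  structure(list(injected_dose_g = injected_dose_g,
                 specific_activity = specific_activity,
                 metabolite_fractions = metabolite_fractions,
                 therapeutic_dose_g = therapeutic_dose_g,
                 mw_boron = mw_boron, mw_fbpa = mw_fbpa, mw_bpa = mw_bpa),
            class = "study_config")
}

# --- file readers / writers -------------------------------------------------

# choose field separator from the file extension; .csv -> comma, else tab
.table_sep <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

# parse a `<name>_s` / `<name>_min` header into (name, factor-to-minutes)
.time_unit_factor <- function(colname) {
  if (grepl("_s$", colname)) 1 / 60
  else if (grepl("_min$", colname)) 1
  else NA_real_
}

#' Read a tissue TAC table
#'
#' Expects a delimited text table whose first two columns give frame start
#' and end times (`start_s`/`end_s` or `start_min`/`end_min`) followed by
#' one activity column (kBq/ml) per VOI.
#'
#' @param path Path to a TSV (default) or CSV file.
#' @return A named list of [tissue_tac()] objects, one per VOI column.
#' @seealso [write_tac_table()]
#' @export
read_tac_table <- function(path) {
  if (!file.exists(path))
    stop(sprintf("TAC file not found: '%s'", path))
  tab <- utils::read.table(path, header = TRUE, sep = .table_sep(path),
                           check.names = FALSE, stringsAsFactors = FALSE)
  nm <- names(tab)
  i_start <- grep("^start_(s|min)$", nm)
  i_end <- grep("^end_(s|min)$", nm)
  if (length(i_start) != 1L || length(i_end) != 1L)
    stop("TAC table must have exactly one 'start_s|start_min' and one 'end_s|end_min' column")
  f_start <- .time_unit_factor(nm[i_start])
  f_end <- .time_unit_factor(nm[i_end])
  start <- as.numeric(tab[[i_start]]) * f_start
  end <- as.numeric(tab[[i_end]]) * f_end
  sched <- frame_schedule(start = start, duration = end - start)
  voi_cols <- setdiff(seq_along(nm), c(i_start, i_end))
  if (length(voi_cols) == 0L)
    stop("TAC table contains no VOI columns")
  out <- lapply(voi_cols, function(j) {
    v <- suppressWarnings(as.numeric(tab[[j]]))
    if (all(is.na(v)))
      stop(sprintf("VOI column '%s' is empty", nm[j]))
    tissue_tac(nm[j], sched, v)
  })
  names(out) <- nm[voi_cols]
  out
}

#' Write a tissue TAC table
#'
#' @param tacs A named list of [tissue_tac()] objects sharing one schedule.
#' @param path Output path; `.csv` writes comma-separated, anything else
#'   tab-separated.
#' @param unit Time unit for the start/end columns, `"s"` (default) or
#'   `"min"`.
#' @return `path`, invisibly.
#' @export
write_tac_table <- function(tacs, path, unit = c("s", "min")) {
  unit <- match.arg(unit)
  if (inherits(tacs, "tissue_tac")) tacs <- list(tacs)
  stopifnot(length(tacs) >= 1L, all(vapply(tacs, inherits, TRUE, "tissue_tac")))
  sched <- tacs[[1L]]$schedule
  for (tc in tacs)
    if (max(abs(tc$schedule$start - sched$start)) > 1e-9)
      stop("all TACs must share the same frame schedule")
  f <- if (unit == "s") 60 else 1
  tab <- data.frame(start = sched$start * f,
                    end = (sched$start + sched$duration) * f)
  names(tab) <- paste0(c("start_", "end_"), unit)
  for (tc in tacs) tab[[tc$voi]] <- tc$activity
  utils::write.table(format(tab, digits = 15, trim = TRUE, scientific = FALSE),
                     path, sep = .table_sep(path), quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a blood sample table
#'
#' Expects columns `time_min` (or `time_s`), `whole_blood_kBq_ml` and
#' `plasma_kBq_ml`.
#'
#' @param path Path to a TSV (default) or CSV file.
#' @return A [blood_samples()] object (times in minutes).
#' @seealso [write_blood_samples()]
#' @export
read_blood_samples <- function(path) {
  if (!file.exists(path))
    stop(sprintf("blood sample file not found: '%s'", path))
  tab <- utils::read.table(path, header = TRUE, sep = .table_sep(path),
                           check.names = FALSE, stringsAsFactors = FALSE)
  nm <- names(tab)
  i_time <- grep("^time_(s|min)$", nm)
  if (length(i_time) != 1L)
    stop("blood table must have exactly one 'time_s|time_min' column")
  i_wb <- grep("^whole_blood", nm)
  i_pl <- grep("^plasma", nm)
  if (length(i_pl) != 1L)
    stop("blood table is missing the plasma column ('plasma_kBq_ml')")
  if (length(i_wb) != 1L)
    stop("blood table is missing the whole-blood column ('whole_blood_kBq_ml')")
  blood_samples(time = as.numeric(tab[[i_time]]) * .time_unit_factor(nm[i_time]),
                whole_blood = as.numeric(tab[[i_wb]]),
                plasma = as.numeric(tab[[i_pl]]))
}

#' Write a blood sample table
#'
#' @param series A [blood_samples()] object.
#' @param path Output path; `.csv` writes comma-separated, else
#'   tab-separated.
#' @return `path`, invisibly.
#' @export
write_blood_samples <- function(series, path) {
  stopifnot(inherits(series, "blood_samples"))
  tab <- data.frame(time_min = series$time,
                    whole_blood_kBq_ml = series$whole_blood,
                    plasma_kBq_ml = series$plasma)
  utils::write.table(format(tab, digits = 15, trim = TRUE, scientific = FALSE),
                     path, sep = .table_sep(path), quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
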