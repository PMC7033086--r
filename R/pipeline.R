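# End-to-end study orchestration: read data, build the input function,
# fit every model per VOI, rank models, estimate organ boron at the
# requested times, and write report tables.

# tiny polynomial hash of a deparsed object, for the report manifest
.config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

.resolve_tacs <- function(tac) {
  if (is.character(tac)) return(read_tac_table(tac))
  if (inherits(tac, "tissue_tac")) {
    out <- list(tac)
    names(out) <- tac$voi
    return(out)
  }
  stopifnot(is.list(tac), all(vapply(tac, inherits, TRUE, "tissue_tac")))
  if (is.null(names(tac)))
    names(tac) <- vapply(tac, `[[`, "", "voi")
  tac
}

.resolve_blood <- function(blood) {
  if (is.character(blood)) return(read_blood_samples(blood))
  stopifnot(inherits(blood, "blood_samples"))
  blood
}

#' Run the full Vt and boron estimation study
#'
#' For a single subject: builds the metabolite-corrected plasma input
#' function, fits each requested graphical model to every VOI (logging
#' the chosen t* and any fit warnings), ranks the models by mean AIC
#' across VOIs, and converts the selected model's Vt values plus the
#' plasma curve into organ boron-10 concentrations at the requested
#' times.  A fit failure in one VOI is recorded and does not abort the
#' others.
#'
#' @param tac Path to a TAC table, a [tissue_tac()], or a list of them.
#' @param blood Path to a blood sample table or a [blood_samples()].
#' @param config A [study_config()].
#' @param models Models to fit, subset of `c("logan", "ma1", "ma2")`.
#' @param t_star Named list of t* settings per model; `"auto"` triggers
#'   [find_t_star()] (MA2 defaults to 20 min).
#' @param max_rel_error Relative-error criterion for automatic t*.
#' @param boron_times Times (min) at which organ boron is estimated.
#' @return An object of class `study_report`: list with `input`, `fits`
#'   (VOI -> model -> `vt_fit` or error message), `gof` (all
#'   goodness-of-fit rows), `vt_table` (VOI x model Vt), `model_aic`
#'   (mean AIC per model), `selected_model`, `boron` (a
#'   [estimate_boron()] table) and `log`.
#' @export
run_study <- function(tac, blood, config = study_config(),
                      models = c("logan", "ma1", "ma2"),
                      t_star = list(logan = "auto", ma1 = "auto", ma2 = 20),
                      max_rel_error = 0.01,
                      boron_times = c(60, 120)) {
  models <- match.arg(models, several.ok = TRUE)
  tacs <- .resolve_tacs(tac)
  series <- .resolve_blood(blood)
  log_lines <- character()
  say <- function(fmt, ...) {
    log_lines <<- c(log_lines, sprintf(fmt, ...))
  }

  input <- fit_input_function(series, config)
  say("input function: %s; junction scale %.4f",
      sub("\n$", "", paste(utils::capture.output(print(input$biexp)),
                           collapse = " ")), input$scale)

  fits <- list()
  gof_rows <- list()
  for (voi in names(tacs)) {
    fits[[voi]] <- list()
    for (m in models) {
      ts <- t_star[[m]]
      if (is.null(ts)) ts <- if (m == "ma2") 20 else "auto"
      fit <- tryCatch(
        fit_vt(tacs[[voi]], input, model = m,
               t_star = if (identical(ts, "auto")) NULL else ts,
               max_rel_error = max_rel_error),
        error = function(e) conditionMessage(e))
      fits[[voi]][[m]] <- fit
      if (inherits(fit, "vt_fit")) {
        say("%s / %s: Vt = %.4g, t* = %.3g min, n = %d%s%s",
            voi, m, fit$vt, fit$t_star, fit$n_points,
            if (fit$t_star_converged) "" else " [t* not converged]",
            if (length(fit$flags)) paste0(" [", paste(fit$flags,
                                                      collapse = ", "),
                                          "]") else "")
        gof_rows[[length(gof_rows) + 1L]] <- gof_report(fit)
      } else {
        say("%s / %s: FAILED (%s)", voi, m, fit)
      }
    }
  }
  gof <- if (length(gof_rows)) do.call(rbind, gof_rows) else
    data.frame()

  # Vt table: one row per VOI, one column per model
  vt_table <- data.frame(voi = names(tacs), stringsAsFactors = FALSE)
  for (m in models) {
    vt_table[[paste0("vt_", m)]] <- vapply(names(tacs), function(v) {
      f <- fits[[v]][[m]]
      if (inherits(f, "vt_fit")) f$vt else NA_real_
    }, numeric(1L))
    vt_table[[paste0("t_star_", m)]] <- vapply(names(tacs), function(v) {
      f <- fits[[v]][[m]]
      if (inherits(f, "vt_fit")) f$t_star else NA_real_
    }, numeric(1L))
  }

  model_aic <- vapply(models, function(m) {
    a <- gof$aic[gof$model == m]
    if (length(a)) mean(a) else NA_real_
  }, numeric(1L))
  names(model_aic) <- models
  selected <- if (all(is.na(model_aic))) NA_character_ else
    models[which.min(model_aic)]
  say("mean AIC by model: %s",
      paste(sprintf("%s = %.3g", models, model_aic), collapse = ", "))
  say("selected model: %s", selected)

  boron <- NULL
  if (!is.na(selected)) {
    vt_sel <- vt_table[[paste0("vt_", selected)]]
    names(vt_sel) <- vt_table$voi
    ok <- is.finite(vt_sel) & vt_sel >= 0
    if (any(!ok))
      say("boron table: dropping VOIs without a valid Vt: %s",
          paste(names(vt_sel)[!ok], collapse = ", "))
    if (any(ok))
      boron <- estimate_boron(vt_sel[ok], input, boron_times, config)
  }

  structure(list(input = input, fits = fits, gof = gof,
                 vt_table = vt_table, model_aic = model_aic,
                 selected_model = selected, boron = boron,
                 boron_times = boron_times, config = config,
                 log = log_lines),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("Study report: %d VOIs, models %s; selected %s\n",
              nrow(x$vt_table),
              paste(names(x$model_aic), collapse = "/"),
              x$selected_model))
  cat("Mean AIC by model:\n")
  print(round(x$model_aic, 2))
  vt_cols <- grep("^vt_", names(x$vt_table), value = TRUE)
  cat("Vt (ml/ml):\n")
  print(x$vt_table[, c("voi", vt_cols)], row.names = FALSE, digits = 3)
  if (!is.null(x$boron)) {
    cat("\n")
    print(x$boron)
  }
  invisible(x)
}

#' Aggregate study reports across subjects
#'
#' Unweighted mean and sample standard deviation (n - 1) of the per-model
#' Vt values and of the therapeutic boron estimates across subjects.
#'
#' @param reports A list of `study_report` objects over the same VOIs.
#' @return List with `vt` (voi x model mean/sd columns) and `boron`
#'   (voi x time mean/sd), of class `study_aggregate`.
#' @export
aggregate_studies <- function(reports) {
  stopifnot(length(reports) >= 1L,
            all(vapply(reports, inherits, TRUE, "study_report")))
  vois <- reports[[1L]]$vt_table$voi
  vt_cols <- grep("^vt_", names(reports[[1L]]$vt_table), value = TRUE)
  vt <- data.frame(voi = vois, stringsAsFactors = FALSE)
  for (cn in vt_cols) {
    mat <- sapply(reports, function(r)
      r$vt_table[[cn]][match(vois, r$vt_table$voi)])
    mat <- matrix(mat, nrow = length(vois))
    vt[[paste0(cn, "_mean")]] <- rowMeans(mat)
    vt[[paste0(cn, "_sd")]] <- apply(mat, 1L, stats::sd)
  }
  boron <- NULL
  if (!is.null(reports[[1L]]$boron)) {
    times <- unique(reports[[1L]]$boron$time)
    rows <- list()
    for (tm in times) {
      mat <- sapply(reports, function(r) {
        b <- r$boron[r$boron$time == tm, ]
        b$boron_therapy_ppm[match(vois, b$voi)]
      })
      mat <- matrix(mat, nrow = length(vois))
      rows[[length(rows) + 1L]] <-
        data.frame(voi = vois, time = tm,
                   boron_ppm_mean = rowMeans(mat),
                   boron_ppm_sd = apply(mat, 1L, stats::sd),
                   stringsAsFactors = FALSE)
    }
    boron <- do.call(rbind, rows)
  }
  structure(list(vt = vt, boron = boron, n_subjects = length(reports)),
            class = "study_aggregate")
}

#' Write report tables to disk
#'
#' Writes `vt.csv` (VOI by model), `gof.csv` (all goodness-of-fit rows),
#' `boron.csv` (therapeutic boron estimates), `run.log` and
#' `manifest.json` (package version, configuration hash, selected model).
#' Outputs contain no timestamps, so re-running on identical inputs
#' reproduces the files byte for byte.
#'
#' @param report A `study_report` from [run_study()].
#' @param dir Output directory (created if missing).
#' @return Named list of the written paths, invisibly.
#' @export
report_tables <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- list(vt = file.path(dir, "vt.csv"),
                gof = file.path(dir, "gof.csv"),
                boron = file.path(dir, "boron.csv"),
                log = file.path(dir, "run.log"),
                manifest = file.path(dir, "manifest.json"))
  utils::write.csv(report$vt_table, paths$vt, row.names = FALSE)
  gof <- if (nrow(report$gof)) as.data.frame(report$gof) else
    data.frame(voi = character(), model = character(), n = integer(),
               p = integer(), ssr = numeric(), aic = numeric(),
               chi2_reduced = numeric(), sy_x = numeric(), r2 = numeric(),
               vt = numeric(), t_star = numeric())
  utils::write.csv(gof, paths$gof, row.names = FALSE)
  boron <- if (!is.null(report$boron)) as.data.frame(report$boron) else
    data.frame(voi = character(), time = numeric(), vt = numeric(),
               tissue_kBq_ml = numeric(), molar_mol_ml = numeric(),
               boron_tracer_ppm = numeric(), boron_therapy_ppm = numeric())
  utils::write.csv(boron, paths$boron, row.names = FALSE)
  writeLines(report$log, paths$log)
  manifest <- list(package = "fbpakin",
                   version = as.character(utils::packageVersion("fbpakin")),
                   config_hash = .config_hash(report$config),
                   models = names(report$model_aic),
                   selected_model = report$selected_model,
                   boron_times = report$boron_times)
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(paths)
}
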