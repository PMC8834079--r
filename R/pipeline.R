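#' Pipeline run configuration
#'
#' Exactly one input source per channel: either paths to trace/absorbance
#' files or a simulation request (group specs + replicate count). Omitted
#' channels are skipped with a warning at run time.
#'
#' @param simulate Logical; when `TRUE` the dataset is generated with
#'   [make_dataset()] from `group_specs`.
#' @param group_specs Group specifications for simulation (default
#'   [default_group_specs()]).
#' @param n_replicates Replicates per simulated group.
#' @param trace_files,absorbance_file Input paths when `simulate = FALSE`.
#' @param marker_times OJIP marker times, us.
#' @param mr_windows MR slope windows, ms (see [mr_slopes()]).
#' @param df_windows DF feature search windows, ms.
#' @param pigment_dialect Solvent dialect for the pigment equations.
#' @param alpha Significance level for group comparisons.
#' @param seed Master seed for simulation.
#' @param out_dir Output directory for result files.
#' @return A list of class `run_config`.
#' @export
run_config <- function(simulate = TRUE,
                       group_specs = default_group_specs(),
                       n_replicates = 3L,
                       trace_files = NULL, absorbance_file = NULL,
                       marker_times = c(20, 300, 2000, 30000),
                       mr_windows = list(oxidation = c(0.7, 20),
                                         rereduction = c(20, 300)),
                       df_windows = list(I1 = c(2, 20), I2 = c(20, 300)),
                       pigment_dialect = "acetone80", alpha = 0.05,
                       seed = 1L, out_dir = tempfile("ojip_run_")) {
  if (simulate && (!is.null(trace_files) || !is.null(absorbance_file))) {
    ojip_abort("set either simulate = TRUE or input paths, not both",
               "ojip_config_error")
  }
  if (!simulate && is.null(trace_files)) {
    ojip_abort("simulate = FALSE requires trace_files", "ojip_config_error")
  }
  structure(as.list(environment()), class = "run_config")
}

#' Run the full analysis pipeline
#'
#' simulate (or load) -> analyze each channel -> compare groups -> write
#' Table-style CSVs. Every result file carries the seed and a hash of the
#' configuration in a header comment so a run can be matched to its
#' configuration. Stage failures are recorded in the returned `log` and in
#' the `status` field (`"ok"`, `"partial"`, `"failed"`); partial results
#' are still written.
#'
#' @param config A [run_config()].
#' @return A list of class `run_result` with elements `pigment_table`,
#'   `jip_table`, `mr_table`, `df_table`, `comparisons` (named list of
#'   comparison tables), `flux_summary`, `files`, `log`, `status`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- character()
  note <- function(...) log <<- c(log, sprintf(...))
  failed <- FALSE

  if (config$simulate) {
    ds <- make_dataset(config$group_specs, config$n_replicates,
                       seed = config$seed,
                       dialect = config$pigment_dialect)
    traces <- ds$traces
    absorbances <- ds$absorbances
    note("simulated %d traces, %d absorbance records (seed %d)",
         length(traces), nrow(absorbances), config$seed)
  } else {
    traces <- do.call(c, lapply(config$trace_files,
                                function(p) read_traces(p)))
    absorbances <- if (!is.null(config$absorbance_file)) {
      read_absorbances(config$absorbance_file)
    } else NULL
    note("loaded %d traces from %d file(s)", length(traces),
         length(config$trace_files))
  }

  channel_of <- vapply(traces, function(tr) tr$channel, character(1))
  is_decay <- vapply(traces, function(tr) grepl("_decay$", tr$replicate),
                     logical(1))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      failed <<- TRUE
      note("stage %s failed: %s", name, conditionMessage(e))
      NULL
    })
  }

  pf <- traces[channel_of == "PF"]
  jip <- if (length(pf) > 0L) {
    stage("jip", jip_table(pf, marker_times = config$marker_times))
  } else {
    note("no PF traces; JIP stage skipped")
    ojip_warn("no PF traces; JIP stage skipped", "ojip_stage_skipped_warning")
    NULL
  }

  mr_tr <- traces[channel_of == "MR"]
  mr <- if (length(mr_tr) > 0L) {
    stage("mr", mr_table(mr_tr, windows = config$mr_windows))
  } else {
    note("no MR traces; MR stage skipped")
    ojip_warn("no MR traces; MR stage skipped", "ojip_stage_skipped_warning")
    NULL
  }

  df_ind <- traces[channel_of == "DF" & !is_decay]
  df_dec <- traces[channel_of == "DF" & is_decay]
  df <- if (length(df_ind) > 0L) {
    stage("df", df_table(df_ind,
                         decay_traces = if (length(df_dec) == length(df_ind))
                           df_dec else NULL,
                         windows = config$df_windows))
  } else {
    note("no DF traces; DF stage skipped")
    ojip_warn("no DF traces; DF stage skipped", "ojip_stage_skipped_warning")
    NULL
  }

  pig <- if (!is.null(absorbances) && nrow(absorbances) > 0L) {
    stage("pigments", pigment_table(absorbances,
                                    dialect = config$pigment_dialect))
  } else {
    note("no absorbance records; pigment stage skipped")
    NULL
  }

  comparisons <- list()
  for (nm in c("jip", "mr", "df", "pigments")) {
    tab <- switch(nm, jip = jip, mr = mr, df = df, pigments = pig)
    if (!is.null(tab) && length(unique(tab$group)) >= 2L) {
      cmp <- stage(paste0("compare_", nm),
                   compare_tables(tab, alpha = config$alpha))
      if (!is.null(cmp)) comparisons[[nm]] <- cmp
    }
  }

  flux <- if (!is.null(comparisons$jip)) {
    stage("flux_summary", render_flux_summary(comparisons$jip))
  } else NULL

  # write result files with a provenance header
  header <- sprintf("# seed=%d config_hash=%s", config$seed,
                    rlang::hash(config[setdiff(names(config), "out_dir")]))
  files <- character()
  emit <- function(tab, name) {
    if (is.null(tab)) return()
    path <- file.path(config$out_dir, paste0(name, ".csv"))
    con <- file(path, "w", encoding = "UTF-8")
    writeLines(header, con)
    utils::write.csv(tab, con, row.names = FALSE)
    close(con)
    files <<- c(files, path)
  }
  emit(pig, "pigment_table")
  emit(jip, "jip_table")
  emit(mr, "mr_table")
  emit(df, "df_table")
  for (nm in names(comparisons)) emit(comparisons[[nm]], paste0("compare_", nm))
  emit(flux, "flux_summary")
  writeLines(c(header, log), file.path(config$out_dir, "run.log"))
  files <- c(files, file.path(config$out_dir, "run.log"))

  ran <- c(jip = !is.null(jip), mr = !is.null(mr), df = !is.null(df))
  status <- if (failed) "failed" else if (all(ran)) "ok" else "partial"
  structure(list(pigment_table = pig, jip_table = jip, mr_table = mr,
                 df_table = df, comparisons = comparisons,
                 flux_summary = flux, files = files, log = log,
                 status = status),
            class = "run_result")
}

#' Energy-flux summary panel
#'
#' Renders the per-reaction-centre and per-cross-section energy fluxes from
#' a JIP comparison table as a grouped panel of means with significance
#' markers — the tabular counterpart of the usual pipeline-model column
#' charts. Values echo the comparison table; nothing is recomputed. Fluxes
#' missing from the input appear as `NA` rows.
#'
#' @param jip_comparison Output of [compare_tables()] on a [jip_table()].
#' @return Data frame with columns `basis` (`"per_RC"`/`"per_CSM"`),
#'   `flux`, one mean and one display column per group, `significant`.
#' @export
render_flux_summary <- function(jip_comparison) {
  panel <- data.frame(
    basis = rep(c("per_RC", "per_CSM"), each = 5L),
    flux = c("ABS_RC", "TR0_RC", "ET0_RC", "RE0_RC", "DI0_RC",
             "ABS_CSM", "TR0_CSM", "ET0_CSM", "RE0_CSM", "DI0_CSM"),
    stringsAsFactors = FALSE)
  keep <- c(grep("^(mean|display)_", names(jip_comparison), value = TRUE),
            "significant")
  idx <- match(panel$flux, jip_comparison$parameter)
  for (col in keep) panel[[col]] <- jip_comparison[[col]][idx]
  panel
}
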