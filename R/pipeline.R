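#' Read a run configuration from YAML
#'
#' Missing fields fall back to the documented defaults; the synthetic
#' generator section (`synth`) is passed to [synth_config()].
#'
#' @param path YAML file path, or NULL for an all-default configuration.
#' @param overrides named list merged over the file contents (e.g. a seed
#'   from the command line).
#' @return a `run_config` list: synth (a [synth_config()]), band, alpha,
#'   q10_threshold, mid_temp_c, seed.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  raw <- utils::modifyList(raw, overrides)
  seed <- if (!is.null(raw$seed)) as.integer(raw$seed) else 1L
  synth_args <- if (!is.null(raw$synth)) raw$synth else list()
  if (is.null(synth_args$seed)) synth_args$seed <- seed
  cfg <- list(
    synth = do.call(synth_config, synth_args),
    band = if (!is.null(raw$band)) as.numeric(raw$band) else c(0.8, 1.8),
    alpha = if (!is.null(raw$alpha)) raw$alpha else 0.05,
    q10_threshold = if (!is.null(raw$q10_threshold)) raw$q10_threshold
      else 3.5,
    mid_temp_c = raw$mid_temp_c,
    seed = seed
  )
  class(cfg) <- "run_config"
  cfg
}

# tidy CSV with a commented provenance header (seed, config hash, version)
write_output_csv <- function(df, path, seed, config_hash) {
  header <- c(
    sprintf("# winterq %s", as.character(utils::packageVersion("winterq"))),
    sprintf("# seed: %s", seed),
    sprintf("# config_hash: %s", config_hash)
  )
  writeLines(header, path)
  suppressWarnings(utils::write.table(df, path, sep = ",", row.names = FALSE,
                                      append = TRUE, qmethod = "double"))
  invisible(path)
}

#' Run the behavioural cooling-trial pipeline
#'
#' Reduces behavioural tables (observed or synthetic) to cold steady states
#' per metric and phase, transition temperatures, and a summary report:
#' the analysis of an acute 1 deg C per day cooling trial.
#'
#' @param config a `run_config` from [read_run_config()].
#' @param behaviour,feeding optional observed tables (see
#'   [generate_behavior_trial()] for schemas); when NULL, synthetic tables
#'   are generated from `config$synth`.
#' @param out_dir optional directory; when given, all result tables plus the
#'   markdown/JSON report are written there.
#' @param active_phase diel phase used for steady-state detection (the phase
#'   in which the species is active; default "day").
#' @return list(steady_states, transitions, report) invisibly.
#' @export
run_experiment1_pipeline <- function(config, behaviour = NULL, feeding = NULL,
                                     out_dir = NULL, active_phase = "day") {
  stopifnot(inherits(config, "run_config"))
  if (is.null(behaviour)) {
    trial <- generate_behavior_trial(config$synth)
    behaviour <- trial$behaviour
    feeding <- trial$feeding
  }
  metrics <- intersect(c("activity", "shelter_fraction", "vigilance"),
                       names(behaviour))
  steady <- list()
  for (metr in metrics) {
    d <- behaviour[behaviour$phase == active_phase,
                   c("fish_id", "temp_c", metr)]
    names(d)[3] <- "value"
    res <- detect_cold_steady_state(d, alpha = config$alpha)
    steady[[metr]] <- data.frame(metric = metr, phase = active_phase,
                                 threshold_temp_c = res$threshold_temp_c,
                                 n_fish = res$n_fish,
                                 stringsAsFactors = FALSE)
  }
  transitions <- list()
  act <- behaviour[behaviour$phase == active_phase,
                   c("fish_id", "temp_c", "activity")]
  names(act)[3] <- "value"
  tr_act <- mean_transition_temperature(act)
  transitions$inactive <- data.frame(
    metric = "inactive", mean_temp_c = tr_act$mean_temp_c, sem = tr_act$sem,
    n_transitioned = tr_act$n_transitioned, n_total = tr_act$n_total,
    population_transitioned = tr_act$population_transitioned)
  if (!is.null(feeding)) {
    fd <- feeding[, c("fish_id", "temp_c", "feeding_fraction")]
    names(fd)[3] <- "value"
    tr_fd <- mean_transition_temperature(fd)
    transitions$fasting <- data.frame(
      metric = "fasting", mean_temp_c = tr_fd$mean_temp_c, sem = tr_fd$sem,
      n_transitioned = tr_fd$n_transitioned, n_total = tr_fd$n_total,
      population_transitioned = tr_fd$population_transitioned)
  } else {
    warning("run_experiment1_pipeline: no feeding table; fasting metrics ",
            "skipped", call. = FALSE)
  }
  steady_df <- do.call(rbind, steady)
  trans_df <- do.call(rbind, transitions)
  rownames(steady_df) <- rownames(trans_df) <- NULL
  report <- make_report(list(steady_states = steady_df,
                             transitions = trans_df),
                        title = "Behavioural cooling trial")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    h <- rlang::hash(config)
    write_output_csv(steady_df, file.path(out_dir, "steady_states.csv"),
                     config$seed, h)
    write_output_csv(trans_df, file.path(out_dir, "transitions.csv"),
                     config$seed, h)
    writeLines(report$markdown, file.path(out_dir, "report.md"))
    jsonlite::write_json(report$json, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(steady_states = steady_df, transitions = trans_df,
                 report = report))
}

#' Run the respirometry + thermal-sensitivity pipeline
#'
#' End-to-end analysis of a simultaneous activity/metabolic-rate experiment:
#' activity-oxygen-uptake pairs (observed or synthetic) are reduced to SMR by
#' every estimation method, Q10 is computed per fish over the standard
#' temperature intervals, and the metabolic-rate-depression verdict is issued
#' against the configured threshold.
#'
#' @param config a `run_config`.
#' @param pairs optional observed pair table (fish_id, condition, temp_c,
#'   phase, activity, mo2); when NULL, generated from `config$synth`.
#' @param out_dir optional output directory (tables + report written there).
#' @return list(pairs, smr, q10, verdict, report) invisibly.
#' @export
run_experiment2_pipeline <- function(config, pairs = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(pairs)) pairs <- generate_pairs(config$synth)$pairs
  smr <- smr_all_methods(pairs, band = config$band, alpha = config$alpha)
  intervals <- default_intervals(unique(pairs[c("condition", "temp_c")]),
                                 mid_temp_c = config$mid_temp_c)
  q10_tab <- q10_per_fish(smr, intervals, threshold = config$q10_threshold)
  full <- q10_tab[q10_tab$label == "full_cooling" &
                    q10_tab$method == "extrapolated_individual", ]
  if (nrow(full) != 1) {
    stop("pipeline stage 'q10': no full-cooling extrapolated result",
         call. = FALSE)
  }
  pf <- attr(q10_tab, "per_fish")[["full_cooling.extrapolated_individual"]]
  verdict <- classify_mrd(full$mean_q10, pf$q10,
                          threshold = config$q10_threshold)
  report <- make_report(list(smr = smr, q10 = q10_tab,
                             verdict = data.frame(
                               interval = "full_cooling",
                               mean_q10 = verdict$mean_q10,
                               mrd_flag = verdict$mrd_flag,
                               verdict = verdict$verdict)),
                        title = "Activity-controlled thermal sensitivity")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    h <- rlang::hash(config)
    write_output_csv(pairs, file.path(out_dir, "pairs.csv"), config$seed, h)
    write_output_csv(smr, file.path(out_dir, "smr_estimates.csv"),
                     config$seed, h)
    q10_plain <- q10_tab
    attr(q10_plain, "per_fish") <- NULL
    write_output_csv(q10_plain, file.path(out_dir, "q10.csv"), config$seed, h)
    writeLines(report$markdown, file.path(out_dir, "report.md"))
    jsonlite::write_json(report$json, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(pairs = pairs, smr = smr, q10 = q10_tab, verdict = verdict,
                 report = report))
}

#' Render result tables as a markdown report with a JSON twin
#'
#' @param results named list of data.frames (empty/NULL entries are omitted).
#' @param title report title.
#' @return list(markdown = character vector of lines, json = list mirroring
#'   the same numbers).
#' @export
make_report <- function(results, title = "winterq report") {
  results <- Filter(function(x) !is.null(x) && nrow(x) > 0, results)
  if (!length(results)) {
    stop("make_report: at least one non-empty result table required",
         call. = FALSE)
  }
  md <- c(paste("#", title), "")
  json <- list()
  for (nm in names(results)) {
    df <- results[[nm]]
    md <- c(md, paste("##", nm), "",
            paste("|", paste(names(df), collapse = " | "), "|"),
            paste("|", paste(rep("---", ncol(df)), collapse = " | "), "|"))
    for (i in seq_len(nrow(df))) {
      cells <- vapply(df[i, ], function(v) {
        if (is.numeric(v)) format(v, digits = 6) else as.character(v)
      }, character(1))
      md <- c(md, paste("|", paste(cells, collapse = " | "), "|"))
    }
    md <- c(md, "")
    json[[nm]] <- df
  }
  list(markdown = md, json = json)
}
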