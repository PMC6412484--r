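#' Whole-pipeline configuration
#'
#' Bundles the stage configurations and global options; the whole object is
#' validated on construction, before any computation.
#'
#' @param preprocess A [preprocess_config()].
#' @param detector A [detector_config()].
#' @param phenotype A [phenotype_config()].
#' @param ensemble An [ensemble_config()].
#' @param side Primary side the detector runs on (default `"right"`).
#' @param muscle Detection device muscle (default `"TA"`).
#' @param mode `"offline"` (zero-phase filtering, whole-recording
#'   normalization) or `"streaming"` (causal filtering; normalization from
#'   a calibration prefix).
#' @param calibration_s Calibration prefix length used by streaming
#'   normalization (seconds, default 10).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(preprocess = preprocess_config(),
                            detector = detector_config(),
                            phenotype = phenotype_config(),
                            ensemble = ensemble_config(),
                            side = "right", muscle = "TA",
                            mode = c("offline", "streaming"),
                            calibration_s = 10) {
  mode <- match.arg(mode)
  stopifnot(inherits(preprocess, "preprocess_config"),
            inherits(detector, "detector_config"),
            inherits(phenotype, "phenotype_config"),
            inherits(ensemble, "ensemble_config"))
  side <- match.arg(side, c("right", "left"))
  muscle <- match.arg(muscle, c("TA", "GC"))
  if (mode == "streaming") preprocess$mode <- "streaming"
  structure(list(preprocess = preprocess, detector = detector,
                 phenotype = phenotype, ensemble = ensemble, side = side,
                 muscle = muscle, mode = mode,
                 calibration_s = calibration_s),
            class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML or JSON file
#'
#' The file may hold blocks `preprocess`, `detector`, `phenotype`,
#' `ensemble` plus top-level `side`, `muscle`, `mode`, `calibration_s`;
#' any omitted field keeps its default. Unknown keys raise a validation
#' error so typos cannot silently fall back to defaults.
#'
#' @param path Path to a YAML (or JSON) configuration file.
#' @return A validated [pipeline_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path))
    stop("load_config: no such file: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known_blocks <- c("preprocess", "detector", "phenotype", "ensemble",
                    "side", "muscle", "mode", "calibration_s")
  unknown <- setdiff(names(raw), known_blocks)
  if (length(unknown))
    stop("load_config: unknown configuration key(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  build <- function(ctor, block) {
    args <- raw[[block]]
    if (is.null(args)) return(ctor())
    ok <- names(formals(ctor))
    bad <- setdiff(names(args), ok)
    if (length(bad))
      stop("load_config: unknown key(s) in '", block, "': ",
           paste(bad, collapse = ", "), call. = FALSE)
    do.call(ctor, args)
  }
  top <- raw[intersect(names(raw), c("side", "muscle", "mode",
                                     "calibration_s"))]
  do.call(pipeline_config,
          c(list(preprocess = build(preprocess_config, "preprocess"),
                 detector = build(detector_config, "detector"),
                 phenotype = build(phenotype_config, "phenotype"),
                 ensemble = build(ensemble_config, "ensemble")),
            top))
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
}

#' Run the complete analysis pipeline and build the agenda report
#'
#' Full chain on one session: detection (step windows, R index, episode
#' aggregation) on the primary side's device, phenotype index and label for
#' every episode at least 2 s long, and gastrocnemius activity decoding,
#' summarized as one "agenda" row per episode plus session totals.
#'
#' @param session A [recording_session()] or a path readable by
#'   [read_trace_file()].
#' @param config A [pipeline_config()] or a path readable by
#'   [load_config()].
#' @param out_dir Optional directory: when given, `steps.csv`,
#'   `episodes.csv`, `agenda.csv` and `totals.csv` are written there
#'   (deterministic bytes for identical inputs).
#' @return A list of class `agenda_report` with `agenda` (per-episode data
#'   frame: `start_s`, `end_s`, `n_windows`, `median_R`, `PI`, `phenotype`,
#'   `gc_fraction_stretching`), `totals` (episode count, FOG time fraction),
#'   `detection` and `gc_activity`.
#' @export
run_pipeline <- function(session, config = pipeline_config(),
                         out_dir = NULL) {
  if (is.character(config)) config <- load_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(session))
    session <- .stage("read", read_trace_file(session))
  stopifnot(inherits(session, "recording_session"))

  det <- .stage("detect",
                detect_fog(session, side = config$side,
                           muscle = config$muscle,
                           pre_cfg = config$preprocess,
                           cfg = config$detector))
  eps <- det$episodes
  n_eps <- nrow(eps)

  PI <- rep(NA_real_, n_eps)
  label <- rep(NA_character_, n_eps)
  for (j in seq_len(n_eps)) {
    if (eps$end_s[j] - eps$start_s[j] >= 2) {
      ph <- .stage("phenotype",
                   phenotype_episode(session, eps$start_s[j], eps$end_s[j],
                                     cfg = config$phenotype,
                                     pre_cfg = config$preprocess,
                                     muscle = config$muscle))
      PI[j] <- ph$PI
      label[j] <- ph$label
    }
  }

  gc_act <- .stage("muscle",
                   activity_type(get_trace(session, config$side, "GC",
                                           "semg_raw"),
                                 pre_cfg = config$preprocess))
  gc_frac <- vapply(seq_len(n_eps), function(j) {
    n <- length(gc_act$type_values)
    t <- gc_act$t0 + (seq_len(n) - 1) / gc_act$fs
    sel <- t >= eps$start_s[j] & t < eps$end_s[j]
    if (!any(sel)) return(NA_real_)
    mean(gc_act$labels[sel] == "stretching")
  }, numeric(1))

  agenda <- data.frame(start_s = eps$start_s, end_s = eps$end_s,
                       n_windows = eps$n_windows, median_R = eps$median_R,
                       PI = PI, phenotype = label,
                       gc_fraction_stretching = gc_frac)
  dur <- trace_duration(session$traces[[1]])
  totals <- list(n_episodes = n_eps,
                 fog_time_fraction =
                   if (n_eps) sum(eps$end_s - eps$start_s) / dur else 0)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    .write_csv <- function(df, name) {
      p <- file.path(out_dir, name)
      con <- file(p, "w"); on.exit(close(con), add = TRUE)
      writeLines(paste(names(df), collapse = ","), con)
      if (nrow(df))
        writeLines(do.call(paste, c(lapply(df, function(col)
          if (is.numeric(col)) sprintf("%.15g", col) else
            as.character(col)), sep = ",")), con)
    }
    steps <- as.data.frame(det$steps)
    steps$label <- as.character(steps$label)
    .write_csv(steps[c("start_s", "end_s", "min_gyro", "max_abs",
                       "t_max_abs", "R", "label")], "steps.csv")
    .write_csv(as.data.frame(eps), "episodes.csv")
    .write_csv(agenda, "agenda.csv")
    .write_csv(data.frame(n_episodes = totals$n_episodes,
                          fog_time_fraction = totals$fog_time_fraction),
               "totals.csv")
  }
  structure(list(agenda = agenda, totals = totals, detection = det,
                 gc_activity = gc_act, config = config),
            class = "agenda_report")
}

#' @export
print.agenda_report <- function(x, ...) {
  cat(sprintf("<agenda_report> %d episode(s), %.1f%% of time in FOG\n",
              x$totals$n_episodes, 100 * x$totals$fog_time_fraction))
  if (nrow(x$agenda)) print(format(x$agenda, digits = 3))
  invisible(x)
}

#' Evaluate detection against reference annotations
#'
#' Runs the detection chain and compares the per-step labels with the
#' reference intervals, reporting step-level sensitivity/specificity and a
#' scatter table (one row per non-stance window: index, R, predicted label,
#' reference label) suitable for re-plotting.
#'
#' @param session A [recording_session()] or trace-file path.
#' @param annotations An [annotation_set()] or annotation-file path; must
#'   be non-empty.
#' @param config A [pipeline_config()] or config-file path.
#' @return A list of class `fog_evaluation` with `confusion`
#'   (a `fog_confusion`), `scatter` (data frame) and `detection`.
#' @export
evaluate_command <- function(session, annotations,
                             config = pipeline_config()) {
  if (is.character(config)) config <- load_config(config)
  if (is.character(session))
    session <- .stage("read", read_trace_file(session))
  if (is.character(annotations))
    annotations <- .stage("read", read_annotations(annotations))
  if (nrow(annotations) == 0L)
    stop("evaluate_command: empty annotation set", call. = FALSE)
  det <- .stage("detect",
                detect_fog(session, side = config$side,
                           muscle = config$muscle,
                           pre_cfg = config$preprocess,
                           cfg = config$detector))
  conf <- .stage("evaluate", evaluate_step_level(det$steps, annotations))
  scatter <- conf$windows
  scatter$window_index <- seq_len(nrow(scatter))
  structure(list(confusion = conf, scatter = scatter, detection = det),
            class = "fog_evaluation")
}

#' @export
print.fog_evaluation <- function(x, ...) {
  print(x$confusion)
  invisible(x)
}
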