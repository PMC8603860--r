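#' Write a recording to CSV
#'
#' Long format, one row per frame x landmark: columns `time_s`,
#' `landmark`, `x_mm`, `y_mm`, `z_mm`, `valid` (0/1). Dropout frames are
#' written with empty coordinate fields. UTF-8, '.' decimal separator.
#'
#' @param rec a [recording()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  nms <- names(rec$landmarks)
  n <- length(rec$time_s)
  df <- data.frame(
    time_s = rep(rec$time_s, each = length(nms)),
    landmark = rep(nms, times = n),
    x_mm = as.vector(t(sapply(nms, function(nm) rec$landmarks[[nm]][, 1]))),
    y_mm = as.vector(t(sapply(nms, function(nm) rec$landmarks[[nm]][, 2]))),
    z_mm = as.vector(t(sapply(nms, function(nm) rec$landmarks[[nm]][, 3]))),
    valid = rep(as.integer(rec$valid), each = length(nms)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a recording from CSV
#'
#' Parses the long CSV format written by [write_recording()], validating
#' the schema and reporting malformed rows with their line numbers.
#'
#' @param path input file path.
#' @param device_id device label to attach; defaults to the file name
#'   without extension.
#' @param nominal_rate nominal frame rate; if `NULL`, estimated as the
#'   reciprocal of the median timestamp step, rounded to the nearest
#'   frame/s.
#' @param subject_id optional subject label.
#' @return A [recording()].
#' @export
read_recording <- function(path, device_id = NULL, nominal_rate = NULL,
                           subject_id = NA_character_) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(device_id)) {
    device_id <- tools::file_path_sans_ext(basename(path))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (nrow(df) == 0L) stop("empty recording file: ", path, call. = FALSE)
  required <- c("time_s", "landmark", "x_mm", "y_mm", "z_mm", "valid")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("schema error in ", path, ": missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  lines <- seq_len(nrow(df)) + 1L  # header is line 1
  num <- function(col) {
    x <- df[[col]]
    v <- suppressWarnings(as.numeric(x))
    bad <- is.na(v) & !is.na(x) & nzchar(trimws(x))
    if (any(bad)) {
      stop("parse error in ", path, ": non-numeric '", col, "' on line(s) ",
           paste(utils::head(lines[bad], 5), collapse = ", "), call. = FALSE)
    }
    v
  }
  time_s <- num("time_s")
  x <- num("x_mm"); y <- num("y_mm"); z <- num("z_mm")
  valid_col <- num("valid")
  if (any(is.na(time_s)) || !all(valid_col %in% c(0, 1))) {
    stop("parse error in ", path, ": time_s must be numeric and valid 0/1",
         call. = FALSE)
  }
  nms <- unique(df$landmark)
  times <- sort(unique(time_s))
  idx <- function(nm) {
    sel <- df$landmark == nm
    i <- match(times, time_s[sel])
    if (any(is.na(i))) {
      stop("parse error in ", path, ": landmark '", nm,
           "' missing for some timestamps", call. = FALSE)
    }
    cbind(x = x[sel][i], y = y[sel][i], z = z[sel][i])
  }
  landmarks <- stats::setNames(lapply(nms, idx), nms)
  valid <- valid_col[match(times, time_s)] == 1
  if (is.null(nominal_rate)) {
    nominal_rate <- round(1 / stats::median(diff(times)))
  }
  recording(device_id, nominal_rate, times, valid, landmarks,
            subject_id = subject_id)
}

#' Write / read a protocol annotation (JSON)
#'
#' @param ann an [protocol_annotation()].
#' @param path file path.
#' @return `write_annotation` returns `path` invisibly; `read_annotation`
#'   returns an `annotation` object.
#' @export
write_annotation <- function(ann, path) {
  jsonlite::write_json(
    list(subject_id = ann$subject_id, target_deg = ann$target_deg,
         movements = ann$movements, holds = ann$holds),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_annotation
#' @export
read_annotation <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  required <- c("subject_id", "target_deg", "movements", "holds")
  missing <- setdiff(required, names(j))
  if (length(missing) > 0L) {
    stop("annotation ", path, " missing field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  structure(list(subject_id = j$subject_id, target_deg = j$target_deg,
                 movements = j$movements,
                 holds = as.data.frame(j$holds)),
            class = "annotation")
}

#' Write a table as TSV
#'
#' Plain TSV (tab separator, no quoting, no row names), the package's
#' output format for measurement and summary tables.
#'
#' @param df a data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' @rdname write_tsv
#' @param ... passed to [utils::read.delim()].
#' @export
read_tsv <- function(path, ...) {
  utils::read.delim(path, stringsAsFactors = FALSE, ...)
}

#' Write a simulated cohort to disk
#'
#' One CSV per device per subject (`<id>_emt.csv`, `<id>_depth.csv`), one
#' annotation JSON per subject, and a manifest JSON recording every
#' generator parameter and seed for full reproducibility.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in cohort$subjects) {
    write_recording(s$rec_emt, file.path(dir, paste0(s$subject_id, "_emt.csv")))
    write_recording(s$rec_depth,
                    file.path(dir, paste0(s$subject_id, "_depth.csv")))
    write_annotation(s$annotation,
                     file.path(dir, paste0(s$subject_id, "_annotation.json")))
  }
  manifest <- list(
    seed = cohort$seed,
    n_subjects = length(cohort$subjects),
    subjects = vapply(cohort$subjects, `[[`, "", "subject_id"),
    protocol = unclass(cohort$protocol),
    population = unclass(cohort$population),
    device_emt = device_manifest(cohort$device_emt),
    device_depth = device_manifest(cohort$device_depth))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

device_manifest <- function(d) {
  list(device_id = d$device_id, rate = d$rate,
       attenuation = as.list(d$attenuation),
       noise_sd_mm = d$noise_sd_mm, dropout_prob = d$dropout_prob,
       dropout_burst = d$dropout_burst,
       world_rotation = apply(d$world_rotation, 1, as.numeric,
                              simplify = FALSE),
       world_offset_mm = d$world_offset_mm)
}

# Known run-configuration schema; unknown keys are fatal (silent typos
# would corrupt comparisons).
config_schema <- function() {
  list(
    seed = NULL, n_subjects = NULL,
    protocol = c("movements", "target_deg", "hold_s", "transition_s",
                 "lead_s"),
    population = c("undershoot_mean", "undershoot_sd", "movement_sd_deg",
                   "jitter_sd_deg", "jitter_tau_s"),
    device_emt = c("rate", "attenuation", "noise_sd_mm", "dropout_prob",
                   "dropout_burst"),
    device_depth = c("rate", "attenuation", "noise_sd_mm", "dropout_prob",
                     "dropout_burst"),
    analysis = c("turn_axis", "window_s", "gap_frames", "speed_threshold",
                 "min_hold_s", "hysteresis_s"),
    stats = c("tested_movements", "exact_limit"))
}

#' Read and validate a run configuration (YAML)
#'
#' Strict validation: any key not in the documented schema is an error.
#'
#' @param path YAML file path.
#' @return A named list of configuration sections.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  schema <- config_schema()
  unknown <- setdiff(names(cfg), names(schema))
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (sec in names(cfg)) {
    allowed <- schema[[sec]]
    if (!is.null(allowed) && is.list(cfg[[sec]])) {
      bad <- setdiff(names(cfg[[sec]]), allowed)
      if (length(bad) > 0L) {
        stop("unknown config key(s) in '", sec, "': ",
             paste(bad, collapse = ", "), call. = FALSE)
      }
    }
  }
  if (!is.null(cfg$seed) && cfg$seed != as.integer(cfg$seed)) {
    stop("config seed must be an integer", call. = FALSE)
  }
  # YAML 1.1 reads a bare y/n as a boolean; map it back to the axis label
  if (isTRUE(cfg$analysis$turn_axis)) cfg$analysis$turn_axis <- "y"
  cfg
}
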