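# mandatory column contracts of the on-disk tables
stride_table_mandatory <- c("stride_index", "rfc_s", "lfo_s", "lfc_s",
                            "rfo_s", "stride_end_s", "sla")

check_columns <- function(df, mandatory, what, path) {
  missing_cols <- setdiff(mandatory, names(df))
  if (length(missing_cols)) {
    abort(sprintf("%s '%s' is missing mandatory column(s): %s",
                  what, path, paste(missing_cols, collapse = ", ")))
  }
  invisible(df)
}

#' Write / read a stride table as TSV
#'
#' Tab-separated with a header; numeric values are written with full
#' round-trip precision. Reading validates the mandatory columns
#' (`stride_index`, event times, `sla`) and warns about unknown ones.
#'
#' @param strides Stride tibble.
#' @param path File path.
#' @return `write_stride_table` returns `path` invisibly;
#'   `read_stride_table` returns a tibble.
#' @export
write_stride_table <- function(strides, path) {
  check_columns(strides, stride_table_mandatory, "stride table", path)
  readr::write_tsv(strides, path)
  invisible(path)
}

#' @rdname write_stride_table
#' @export
read_stride_table <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(df, stride_table_mandatory, "stride table", path)
  known <- c(stride_table_mandatory, "abnormal", "step_length_fast",
             "step_length_slow", "sla_normalized", "belt_speed_fast",
             "belt_speed_slow", "belt_symmetry", "phase_label",
             "subcondition", "is_asymmetric", "error_size_class",
             "cycle_s", "belt_left", "belt_right", "p", "x", "subject")
  unknown <- setdiff(names(df), known)
  if (length(unknown)) {
    warn(paste0("unknown stride-table column(s): ",
                paste(unknown, collapse = ", ")))
  }
  df
}

#' Write / read a session container
#'
#' A session is stored as a directory: one TSV per signal stream
#' (`grf.tsv`, `markers.tsv`, `sources.tsv`), the schedule and generator
#' configuration as JSON, and the ground truth (when present) as TSV.
#'
#' @param session A `gait_session`.
#' @param dir Directory to create/use.
#' @return `write_session` returns `dir` invisibly; `read_session` a
#'   `gait_session`.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (stream in c("grf", "markers", "sources")) {
    if (!is.null(session[[stream]])) {
      readr::write_tsv(session[[stream]], file.path(dir, paste0(stream, ".tsv")))
    }
  }
  sched <- session$schedule
  jsonlite::write_json(list(
    phases = as.data.frame(sched),
    sample_rate_grf = attr(sched, "sample_rate_grf"),
    sample_rate_markers = attr(sched, "sample_rate_markers"),
    sample_rate_sources = attr(sched, "sample_rate_sources"),
    subject_id = session$subject_id
  ), file.path(dir, "schedule.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(session$config)) {
    cfg <- session$config
    cfg$burst_spec <- as.data.frame(cfg$burst_spec)
    jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(session$truth)) {
    readr::write_tsv(session$truth$strides, file.path(dir, "truth_strides.tsv"))
    readr::write_tsv(tibble::tibble(is_asymmetric = session$truth$flags),
                     file.path(dir, "truth_flags.tsv"))
    readr::write_tsv(session$truth$effect_windows,
                     file.path(dir, "truth_effect_windows.tsv"))
  }
  invisible(dir)
}

#' @rdname write_session
#' @export
read_session <- function(dir) {
  sj <- jsonlite::read_json(file.path(dir, "schedule.json"),
                            simplifyVector = TRUE)
  schedule <- new_belt_schedule(sj$phases,
                                sample_rate_grf = sj$sample_rate_grf,
                                sample_rate_markers = sj$sample_rate_markers,
                                sample_rate_sources = sj$sample_rate_sources)
  session <- list(schedule = schedule, subject_id = sj$subject_id)
  for (stream in c("grf", "markers", "sources")) {
    f <- file.path(dir, paste0(stream, ".tsv"))
    if (file.exists(f)) {
      session[[stream]] <- readr::read_tsv(f, show_col_types = FALSE,
                                           progress = FALSE)
    }
  }
  cfgf <- file.path(dir, "config.json")
  if (file.exists(cfgf)) {
    cj <- jsonlite::read_json(cfgf, simplifyVector = TRUE)
    cj$burst_spec <- tibble::as_tibble(cj$burst_spec)
    session$config <- structure(cj, class = "synthetic_config")
  }
  tf <- file.path(dir, "truth_strides.tsv")
  if (file.exists(tf)) {
    session$truth <- list(
      strides = readr::read_tsv(tf, show_col_types = FALSE, progress = FALSE),
      flags = readr::read_tsv(file.path(dir, "truth_flags.tsv"),
                              show_col_types = FALSE,
                              progress = FALSE)$is_asymmetric,
      effect_windows = readr::read_tsv(file.path(dir, "truth_effect_windows.tsv"),
                                       show_col_types = FALSE, progress = FALSE)
    )
  }
  structure(session, class = "gait_session")
}

#' Write / read time-frequency maps as a directory container
#'
#' Maps are stored as a directory holding `maps.json` (frequency grid,
#' canonical latencies, per-map metadata) and one TSV matrix per map
#' (frequencies in rows, canonical time columns), preserving grids and
#' values exactly.
#'
#' @param maps Named list of `tf_map` objects.
#' @param dir Directory to create/use.
#' @return `write_maps` returns `dir` invisibly; `read_maps` a named list
#'   of `tf_map`s.
#' @export
write_maps <- function(maps, dir) {
  stopifnot(length(maps) > 0, !is.null(names(maps)))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ref <- maps[[1]]
  meta <- list(
    freqs = ref$freqs,
    canonical_latencies = as.list(ref$canonical_latencies),
    n_times = length(ref$times),
    maps = unname(purrr::imap(maps, function(m, nm) {
      list(name = nm, file = paste0(nm, ".tsv"), n_strides = m$n_strides)
    }))
  )
  jsonlite::write_json(meta, file.path(dir, "maps.json"),
                       auto_unbox = TRUE, digits = NA)
  for (nm in names(maps)) {
    vals <- tibble::as_tibble(maps[[nm]]$values, .name_repair = "minimal")
    names(vals) <- paste0("t", seq_along(vals))
    readr::write_tsv(vals, file.path(dir, paste0(nm, ".tsv")))
  }
  invisible(dir)
}

#' @rdname write_maps
#' @export
read_maps <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "maps.json"),
                              simplifyVector = TRUE)
  lat <- unlist(meta$canonical_latencies)
  out <- list()
  for (i in seq_len(nrow(meta$maps))) {
    vals <- as.matrix(readr::read_tsv(file.path(dir, meta$maps$file[i]),
                                      show_col_types = FALSE,
                                      progress = FALSE))
    dimnames(vals) <- NULL
    out[[meta$maps$name[i]]] <- new_tf_map(vals, meta$freqs, lat,
                                           meta$maps$n_strides[i])
  }
  out
}
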