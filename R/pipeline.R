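#' Pipeline configuration
#'
#' Collects every tunable parameter of the full analysis with the field's
#' standard defaults: theta 4-7, alpha 8-12 and beta 13-30 Hz bands, a
#' 2-SD asymmetric-stride criterion over a 30-stride reference window,
#' 2-50 Hz wavelet grid, and cluster permutation at alpha = 0.05.
#'
#' @param schedule A `belt_schedule` (defaults to the full study protocol).
#' @param synthetic A `synthetic_config`, or `NULL` when sessions are
#'   supplied from disk.
#' @param grf_cutoff Low-pass cutoff of the force filter (Hz).
#' @param grf_target_rate Force resampling target (Hz).
#' @param contact_threshold Foot-contact force threshold (N).
#' @param latency_sd Abnormal-latency SD multiplier.
#' @param criterion_k SD multiplier of the asymmetric-stride criterion.
#' @param freqs Spectral frequency grid (Hz).
#' @param n_time_cols Canonical gait-cycle grid columns.
#' @param pad_ratio Zero-padding factor of the wavelet convolution FFT.
#' @param regions Source regions to analyse (`NULL`: every burst-spec
#'   region).
#' @param contrasts Subcondition labels contrasted against `reference`.
#' @param reference Reference subcondition of the spectral contrasts.
#' @param alpha,cluster_alpha,n_perm,n_boot Cluster-statistics parameters.
#' @param seed Seed of every stochastic stage.
#' @param bands Named list of frequency bands (Hz).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(schedule = split_belt_protocol(),
                            synthetic = synthetic_config(),
                            grf_cutoff = 6,
                            grf_target_rate = 512,
                            contact_threshold = 10,
                            latency_sd = 4,
                            criterion_k = 2,
                            freqs = default_freqs(),
                            n_time_cols = 200,
                            pad_ratio = 2,
                            regions = NULL,
                            contrasts = c("early_ramp", "mid_ramp",
                                          "late_ramp", "early_split",
                                          "late_split"),
                            reference = "pre_gradual",
                            alpha = 0.05,
                            cluster_alpha = 0.05,
                            n_perm = 15000,
                            n_boot = 3000,
                            seed = 1L,
                            bands = list(theta = c(4, 7),
                                         alpha = c(8, 12),
                                         beta = c(13, 30))) {
  cfg <- list(schedule = schedule, synthetic = synthetic,
              grf_cutoff = grf_cutoff, grf_target_rate = grf_target_rate,
              contact_threshold = contact_threshold,
              latency_sd = latency_sd, criterion_k = criterion_k,
              freqs = freqs, n_time_cols = n_time_cols,
              pad_ratio = pad_ratio,
              regions = regions, contrasts = contrasts,
              reference = reference, alpha = alpha,
              cluster_alpha = cluster_alpha, n_perm = n_perm,
              n_boot = n_boot, seed = as.integer(seed), bands = bands)
  validate_pipeline_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_pipeline_config <- function(cfg) {
  if (!inherits(cfg$schedule, "belt_schedule")) {
    abort("config$schedule must be a belt_schedule")
  }
  if (!is.null(cfg$synthetic)) {
    if (!inherits(cfg$synthetic, "synthetic_config")) {
      abort("config$synthetic must be a synthetic_config or NULL")
    }
    if (cfg$synthetic$n_subjects < 1L) {
      abort("config requires at least 1 subject")
    }
  }
  if (cfg$alpha <= 0 || cfg$alpha >= 1) abort("alpha must lie in (0, 1)")
  if (cfg$cluster_alpha <= 0 || cfg$cluster_alpha >= 1) {
    abort("cluster_alpha must lie in (0, 1)")
  }
  if (cfg$n_perm < 1) abort("n_perm must be positive")
  invisible(cfg)
}

#' Full stride-level analysis of one session
#'
#' Runs the behavioural path on one session: force filtering and gait-event
#' detection, abnormal-latency flagging, step lengths, SLA and its
#' baseline normalization, marker-based belt speeds with cleaning, belt
#' symmetry, subcondition assignment, asymmetric-stride flags (criterion
#' from the last 30 strides before the gradual ramp) and the
#' large/small-error median split.
#'
#' @param session A `gait_session`.
#' @param config A `pipeline_config`.
#' @return A stride tibble (one row per stride).
#' @export
stride_table <- function(session, config = pipeline_config(
  schedule = session$schedule, synthetic = session$config)) {
  grf <- filter_grf(session$grf, cutoff = config$grf_cutoff,
                    target_rate = config$grf_target_rate)
  events <- detect_gait_events(grf, threshold = config$contact_threshold)
  if (!nrow(events)) abort("no strides detected in session")
  events <- flag_abnormal_latencies(events, k = config$latency_sd)
  st <- compute_step_lengths(session$markers, events)
  st$sla <- compute_sla(st$step_length_fast, st$step_length_slow)
  st <- estimate_belt_speeds(session$markers, st)
  if (nrow(st) >= 6L) {
    st$belt_speed_fast <- condition_belt_series(st$belt_speed_fast)
    st$belt_speed_slow <- condition_belt_series(st$belt_speed_slow)
  }
  st$belt_symmetry <- compute_belt_symmetry(st$belt_speed_fast,
                                            st$belt_speed_slow)
  st <- assign_subconditions(st, session$schedule)
  base_idx <- which(st$subcondition == "pre_abrupt")
  if (length(base_idx)) {
    st$sla_normalized <- normalize_sla(st$sla, base_idx)
  } else {
    st$sla_normalized <- st$sla
  }
  ref_idx <- which(st$subcondition == "pre_gradual")
  if (length(ref_idx) >= 30L) {
    crit <- asymmetry_criterion(st$sla[ref_idx], k = config$criterion_k)
    st$is_asymmetric <- detect_asymmetric_strides(st$sla, crit)
  } else {
    st$is_asymmetric <- FALSE
  }
  st$error_size_class <- median_split_errors(st$sla, st$is_asymmetric)
  st
}

#' Run the full split-belt analysis pipeline
#'
#' Simulates (or accepts) a cohort of sessions, then runs gait-event
#' detection, the stride-level behavioural analysis, subcondition binning,
#' per-region gait-cycle spectral maps, cluster-based permutation contrasts
#' of each gradual subcondition against the reference, and the cohort
#' performance regression. All seeds and parameters are recorded in the
#' returned manifest, which suffices to reproduce the run.
#'
#' @param config A `pipeline_config`.
#' @param sessions Optional list of `gait_session`s; when `NULL` a cohort
#'   is simulated from `config$synthetic`.
#' @param out Optional output directory; when given, stride tables,
#'   condition maps, cluster summaries and the manifest are written there.
#' @return A `splitgait_report`: list with `stride_tables`, `latencies`,
#'   `condition_maps` (region -> condition -> list of per-subject maps),
#'   `contrasts` (region -> condition -> `cluster_result` with effect
#'   sizes), `performance`, and `manifest`.
#' @export
run_pipeline <- function(config, sessions = NULL, out = NULL) {
  validate_pipeline_config(config)
  if (is.null(sessions)) {
    if (is.null(config$synthetic)) {
      abort("config has no synthetic generator and no sessions were supplied")
    }
    sessions <- simulate_cohort(config$schedule, config$synthetic)
  }
  if (!length(sessions)) abort("no sessions to analyse")

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }

  sessions <- rlang::set_names(sessions,
                               purrr::map_chr(sessions, "subject_id"))
  tables <- stage("behavior", purrr::map(sessions, stride_table,
                                         config = config))
  lat <- stage("canonical_latencies", canonical_latencies(tables))

  regions <- config$regions %||%
    setdiff(names(sessions[[1]]$sources %||% tibble::tibble(time = 0)),
            "time")
  conds <- c(config$reference, config$contrasts)

  condition_maps <- stage("spectral", {
    purrr::map(rlang::set_names(regions), function(reg) {
      per_subj <- purrr::map2(sessions, tables, function(sess, st) {
        groups <- purrr::map(rlang::set_names(conds), function(cc) {
          which(st$subcondition == cc & !st$abnormal)
        })
        session_ersp(sess$sources, st, groups, lat,
                     freqs = config$freqs, n_cols = config$n_time_cols,
                     region = reg, pad_ratio = config$pad_ratio)
      })
      purrr::map(rlang::set_names(conds), function(cc) {
        maps <- purrr::map(per_subj, cc)
        maps[!purrr::map_lgl(maps, is.null)]
      })
    })
  })

  contrasts <- stage("cluster_stats", {
    purrr::map(rlang::set_names(regions), function(reg) {
      ref_maps <- condition_maps[[reg]][[config$reference]]
      purrr::map(rlang::set_names(config$contrasts), function(cc) {
        cond_maps <- condition_maps[[reg]][[cc]]
        shared <- intersect(names(ref_maps), names(cond_maps))
        if (length(shared) < 2L) return(NULL)
        res <- paired_cluster_permutation(
          cond_maps[shared], ref_maps[shared],
          alpha = config$alpha, cluster_alpha = config$cluster_alpha,
          n_perm = config$n_perm, seed = config$seed)
        sig <- res$clusters$cluster[res$clusters$p < config$alpha]
        res$effect_sizes <- purrr::map(rlang::set_names(sig), function(id) {
          pix <- res$labels == id
          ci <- bootstrap_ci(cond_maps[shared], ref_maps[shared], pix,
                             n_boot = config$n_boot, seed = config$seed)
          tibble::tibble(cluster = id, max_d = ci$estimate,
                         d_lower = ci$lower, d_upper = ci$upper)
        })
        res
      })
    })
  })

  performance <- stage("performance", {
    perf <- purrr::imap(tables, function(st, id) {
      abrupt_sla <- st$sla[st$phase_label == "abrupt_split"]
      grad_sla_flags <- st$is_asymmetric[st$phase_label %in%
                                           c("ramp", "split_hold")]
      tibble::tibble(
        subject = id,
        strides_to_steady_state = if (length(abrupt_sla) >= 40) {
          detect_steady_state(abrupt_sla)
        } else NA_integer_,
        pct_asymmetric = pct_asymmetric(grad_sla_flags)
      )
    })
    perf <- dplyr::bind_rows(perf)
    if (nrow(perf) >= 2L && !anyNA(perf$strides_to_steady_state)) {
      performance_metrics(perf)
    } else {
      list(scores = perf, fit = NULL)
    }
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("splitgait")),
    seed = config$seed,
    n_subjects = length(sessions),
    regions = regions,
    reference = config$reference,
    contrasts = config$contrasts,
    alpha = config$alpha, cluster_alpha = config$cluster_alpha,
    n_perm = config$n_perm, n_boot = config$n_boot,
    grf_cutoff = config$grf_cutoff,
    grf_target_rate = config$grf_target_rate,
    contact_threshold = config$contact_threshold,
    criterion_k = config$criterion_k,
    freqs = config$freqs,
    n_time_cols = config$n_time_cols,
    canonical_latencies = as.list(lat),
    bands = config$bands
  )

  report <- structure(list(
    stride_tables = tables,
    latencies = lat,
    condition_maps = condition_maps,
    contrasts = contrasts,
    performance = performance,
    manifest = manifest
  ), class = "splitgait_report")

  if (!is.null(out)) write_report(report, out)
  report
}

write_report <- function(report, out) {
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  for (id in names(report$stride_tables)) {
    write_stride_table(report$stride_tables[[id]],
                       file.path(out, paste0("strides_", id, ".tsv")))
  }
  for (reg in names(report$condition_maps)) {
    grand <- purrr::compact(purrr::map(report$condition_maps[[reg]],
                                       function(m) {
      if (length(m)) average_maps(m, "across_subjects") else NULL
    }))
    if (length(grand)) write_maps(grand, file.path(out, paste0("maps_", reg)))
  }
  summaries <- purrr::imap(report$contrasts, function(conds, reg) {
    purrr::imap(conds, function(res, cc) {
      if (is.null(res)) return(NULL)
      cl <- res$clusters
      cl$effect_sizes <- NULL
      list(condition = cc, clusters = cl,
           effect_sizes = dplyr::bind_rows(res$effect_sizes))
    })
  })
  jsonlite::write_json(list(manifest = report$manifest,
                            contrasts = summaries),
                       file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(out)
}

#' @export
print.splitgait_report <- function(x, ...) {
  cat(sprintf("<splitgait_report> %d subject(s), regions: %s\n",
              length(x$stride_tables),
              paste(names(x$condition_maps), collapse = ", ")))
  for (reg in names(x$contrasts)) {
    for (cc in names(x$contrasts[[reg]])) {
      res <- x$contrasts[[reg]][[cc]]
      if (is.null(res)) next
      nsig <- sum(res$clusters$p < res$alpha)
      cat(sprintf("  %s / %s: %d significant cluster(s)\n", reg, cc, nsig))
    }
  }
  invisible(x)
}
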