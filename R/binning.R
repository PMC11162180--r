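#' Assign strides to protocol subconditions
#'
#' Labels each stride of a session with the analysis subcondition defined by
#' the schedule:
#' * `pre_abrupt`, `pre_gradual`: the last 30 strides ending before the
#'   abrupt onset and the gradual ramp onset, respectively;
#' * `early_ramp`, `mid_ramp`, `late_ramp`: 30-stride bins at the start,
#'   centre and end of the gradual ramp (the middle bin is centred on the
#'   ramp midpoint, so the three bins need not be contiguous);
#' * `early_split`, `late_split`: first and last 30 strides of the 2:1 hold
#'   following the ramp, a stride qualifying only when its entire duration
#'   lies after the belts reach terminal speed;
#' * `post1_initial`/`post1_early`/`post1_late` and
#'   `post2_initial`/`post2_early`/`post2_late`: strides 1-10, 11-40 and the
#'   last 30 strides of each tied post-adaptation block;
#' * everything else: `unbinned`.
#'
#' A phase holding fewer strides than its bin specification triggers an
#' error naming the phase.
#'
#' @param strides Stride or gait-event tibble with `rfc_s` and
#'   `stride_end_s`.
#' @param schedule The session's `belt_schedule`.
#' @return `strides` with columns `phase_label` (the schedule phase
#'   containing the stride onset) and `subcondition` appended.
#' @export
assign_subconditions <- function(strides, schedule) {
  pt <- phase_times(schedule)
  n <- nrow(strides)
  lab <- rep("unbinned", n)

  phase_of <- findInterval(strides$rfc_s, pt$start_s,
                           rightmost.closed = FALSE, all.inside = TRUE)
  phase_label <- pt$phase[phase_of]

  start_of <- function(phase) pt$start_s[match(phase, pt$phase)]
  end_of <- function(phase) pt$end_s[match(phase, pt$phase)]
  need <- function(idx, m, phase) {
    if (length(idx) < m) {
      abort(sprintf("phase '%s' holds %d strides; %d required for its bins",
                    phase, length(idx), m))
    }
  }
  assign_last30_before <- function(t0, label, phase) {
    if (is.na(t0)) return(invisible(NULL))
    idx <- which(strides$stride_end_s <= t0)
    need(idx, 30L, phase)
    lab[tail(idx, 30)] <<- label
    invisible(NULL)
  }

  for (post in c("post1", "post2")) {
    if (!post %in% pt$phase) next
    idx <- which(strides$rfc_s >= start_of(post) &
                   strides$stride_end_s <= end_of(post))
    need(idx, 70L, post)
    lab[idx[1:10]] <- paste0(post, "_initial")
    lab[idx[11:40]] <- paste0(post, "_early")
    lab[tail(idx, 30)] <- paste0(post, "_late")
  }
  if ("ramp" %in% pt$phase) {
    ramp_idx <- which(strides$rfc_s >= start_of("ramp") &
                        strides$stride_end_s <= end_of("ramp"))
    need(ramp_idx, 90L, "ramp")
    lab[head(ramp_idx, 30)] <- "early_ramp"
    lab[tail(ramp_idx, 30)] <- "late_ramp"
    mid_t <- (start_of("ramp") + end_of("ramp")) / 2
    centre <- which.min(abs(strides$rfc_s[ramp_idx] +
                              (strides$stride_end_s[ramp_idx] -
                                 strides$rfc_s[ramp_idx]) / 2 - mid_t))
    # centre the middle bin on the ramp midpoint without touching the
    # early (first 30) or late (last 30) bins
    mid_from <- min(max(centre - 14L, 31L), length(ramp_idx) - 59L)
    lab[ramp_idx[mid_from:(mid_from + 29L)]] <- "mid_ramp"
  }
  if ("split_hold" %in% pt$phase) {
    hold_idx <- which(strides$rfc_s >= start_of("split_hold") &
                        strides$stride_end_s <= end_of("split_hold"))
    need(hold_idx, 60L, "split_hold")
    lab[head(hold_idx, 30)] <- "early_split"
    lab[tail(hold_idx, 30)] <- "late_split"
  }
  # reference bins are assigned last: the gradual reference window (the 30
  # strides preceding the ramp) coincides with the tail of the first post
  # block, and the reference label takes precedence there
  if ("abrupt_onset" %in% pt$phase) {
    assign_last30_before(start_of("abrupt_onset"), "pre_abrupt",
                         "pre-abrupt reference")
  }
  if ("ramp" %in% pt$phase) {
    assign_last30_before(start_of("ramp"), "pre_gradual",
                         "pre-gradual reference")
  }

  strides$phase_label <- phase_label
  strides$subcondition <- lab
  strides
}

#' Match abrupt-adaptation error strides to gradual-adaptation errors
#'
#' Selects the first `n` asymmetric strides that occur during the full 2:1
#' split of gradual adaptation, then extracts the abrupt-adaptation
#' asymmetric strides whose |SLA| lies within the mean plus or minus
#' `k` standard deviations of those gradual errors; abrupt candidates are
#' restricted to the 2:1 split period, so perturbation magnitude is equal
#' and error size comparable across the two schedules.
#'
#' @param gradual Stride tibble of gradual full-split strides (rows of a
#'   stride table with `phase_label == "split_hold"`), holding `sla` and
#'   `is_asymmetric`.
#' @param abrupt Stride tibble of abrupt 2:1 strides
#'   (`phase_label == "abrupt_split"`).
#' @param n Number of gradual error strides to anchor the match (30).
#' @param k SD multiplier of the match window.
#' @return List with `gradual` (the anchor strides), `abrupt` (the matched
#'   strides), and the match window `mu`, `sigma`, `k`.
#' @export
match_abrupt_errors <- function(gradual, abrupt, n = 30, k = 2) {
  for (tbl in list(gradual, abrupt)) {
    if (!all(c("sla", "is_asymmetric") %in% names(tbl))) {
      abort("stride tables need columns 'sla' and 'is_asymmetric'")
    }
  }
  ganchor <- gradual[gradual$is_asymmetric & !is.na(gradual$sla), ]
  if (!nrow(ganchor)) abort("no asymmetric strides in the gradual table")
  if (nrow(ganchor) < n) {
    warn(sprintf("only %d qualifying gradual strides (requested %d); using all",
                 nrow(ganchor), n))
  }
  ganchor <- head(ganchor, n)
  mu <- mean(abs(ganchor$sla))
  sigma <- sd(abs(ganchor$sla))
  if (is.na(sigma)) sigma <- 0
  ok <- abrupt$is_asymmetric & !is.na(abrupt$sla) &
    abs(abs(abrupt$sla) - mu) <= k * sigma
  list(gradual = ganchor, abrupt = abrupt[ok, ],
       mu = mu, sigma = sigma, k = k)
}
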