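#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a time-frequency map into a long tibble
#'
#' @param x A `tf_map`.
#' @param ... Unused.
#' @return Tibble with `freq_hz`, `time_pct`, `power_db`.
#' @export
tidy.tf_map <- function(x, ...) {
  tibble::tibble(
    freq_hz = rep(x$freqs, times = length(x$times)),
    time_pct = rep(x$times, each = length(x$freqs)),
    power_db = as.vector(x$values)
  )
}

#' One-row summary of a time-frequency map
#'
#' @param x A `tf_map`.
#' @param ... Unused.
#' @export
glance.tf_map <- function(x, ...) {
  tibble::tibble(
    n_freqs = length(x$freqs),
    n_times = length(x$times),
    n_strides = x$n_strides,
    min_db = min(x$values),
    max_db = max(x$values)
  )
}

#' Tidy the clusters of a permutation test
#'
#' @param x A `cluster_result`.
#' @param ... Unused.
#' @return The cluster tibble (`cluster`, `sign`, `n_pixels`, `stat`, `p`)
#'   with a `significant` column.
#' @export
tidy.cluster_result <- function(x, ...) {
  cl <- x$clusters
  cl$significant <- cl$p < x$alpha
  cl
}

#' One-row summary of a permutation test
#'
#' @param x A `cluster_result`.
#' @param ... Unused.
#' @export
glance.cluster_result <- function(x, ...) {
  tibble::tibble(
    n_subjects = x$n_subjects,
    n_perm = x$n_perm,
    alpha = x$alpha,
    cluster_alpha = x$cluster_alpha,
    n_clusters = nrow(x$clusters),
    n_significant = sum(x$clusters$p < x$alpha),
    min_p = if (nrow(x$clusters)) min(x$clusters$p) else NA_real_
  )
}

#' Tidy per-subject adaptation-performance scores
#'
#' @param x A `performance_summary`.
#' @param ... Unused.
#' @export
tidy.performance_summary <- function(x, ...) x$scores

#' Regression summary of the performance association
#'
#' @param x A `performance_summary`.
#' @param ... Unused.
#' @return One-row tibble with `slope`, `intercept`, `r_squared`,
#'   `adj_r_squared`, `p_value`, `n`.
#' @export
glance.performance_summary <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(
    slope = coef(x$fit)[["gradual_score"]],
    intercept = coef(x$fit)[["(Intercept)"]],
    r_squared = s$r.squared,
    adj_r_squared = s$adj.r.squared,
    p_value = stats::pf(s$fstatistic[1], s$fstatistic[2], s$fstatistic[3],
                        lower.tail = FALSE),
    n = nrow(x$scores)
  )
}
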