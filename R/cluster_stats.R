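# Connected-component labelling of a logical matrix under 4- or
# 8-connectivity; returns an integer matrix (0 = background). Uses
# vectorized label min-propagation with path halving: labels are pixel
# indices that only decrease, so convergence to the component minima is
# monotone and takes O(log diameter) passes.
label_components <- function(mask, adjacency = c("4", "8")) {
  adjacency <- match.arg(adjacency)
  nr <- nrow(mask)
  nc <- ncol(mask)
  idx <- which(mask)
  labels <- integer(nr * nc)
  if (!length(idx)) return(matrix(labels, nr, nc))
  m <- length(idx)
  pos <- integer(nr * nc)
  pos[idx] <- seq_len(m)
  rows <- ((idx - 1L) %% nr) + 1L
  offs <- list(c(-1L, 0L), c(0L, -1L))
  if (adjacency == "8") offs <- c(offs, list(c(-1L, -1L), c(-1L, 1L)))
  # per-offset edge lists; within one offset every pixel appears at most
  # once on each side, so vectorized min-assignment loses no update
  edges <- list()
  for (o in offs) {
    r2 <- rows + o[1]
    lin <- idx + o[1] + o[2] * nr
    valid <- r2 >= 1L & r2 <= nr & lin >= 1L & lin <= nr * nc
    nb <- integer(m)
    nb[valid] <- pos[lin[valid]]
    sel <- nb > 0L
    if (any(sel)) edges[[length(edges) + 1L]] <- cbind(which(sel), nb[sel])
  }
  lab <- seq_len(m)
  if (length(edges)) {
    repeat {
      old <- lab
      for (e in edges) {
        # each side of an offset's edge set indexes a pixel at most once,
        # but a pixel may sit on both sides; take mins against the current
        # labels so neither assignment masks the other
        mn <- pmin(lab[e[, 1]], lab[e[, 2]])
        lab[e[, 1]] <- mn
        lab[e[, 2]] <- pmin(lab[e[, 2]], mn)
      }
      lab <- pmin(lab, lab[lab])   # path halving
      if (identical(lab, old)) break
    }
  }
  labels[idx] <- match(lab, unique(lab))
  matrix(labels, nr, nc)
}

# paired t statistics of a difference matrix (subjects x pixels) under a
# sign-flip vector; uses the sign-invariant sum of squares for speed
paired_t <- function(D, signs, ssq) {
  n <- nrow(D)
  m <- as.vector(crossprod(D, signs)) / n
  v <- (ssq - n * m^2) / (n - 1)
  v[v < .Machine$double.eps] <- NA_real_
  m / sqrt(v / n)
}

# max |cluster maxsum| (or max size) over positive and negative clusters
max_cluster_stat <- function(tmat, crit, adjacency, statistic) {
  best <- 0
  for (sgn in c(1, -1)) {
    mask <- !is.na(tmat) & sgn * tmat > crit
    if (!any(mask)) next
    lab <- label_components(mask, adjacency)
    ids <- lab[lab > 0L]
    stat <- if (statistic == "maxsum") {
      abs(vapply(split(tmat[lab > 0L], ids), sum, numeric(1)))
    } else {
      as.numeric(tabulate(ids))
    }
    best <- max(best, stat)
  }
  best
}

#' Paired cluster-based permutation test on time-frequency maps
#'
#' Per pixel, a paired t statistic of the within-subject difference A - B
#' is computed; pixels whose |t| exceeds the two-tailed critical value at
#' `cluster_alpha` form clusters under the declared adjacency in the
#' (frequency, time) plane, separately for positive and negative t. Each
#' cluster's statistic is the sum of t values inside it (`maxsum`; cluster
#' size is available as an alternative). The null distribution is the
#' maximum absolute cluster statistic over `n_perm` random within-subject
#' sign flips of the differences, and the Monte-Carlo p-value of a cluster
#' is `(1 + #(null >= observed)) / (1 + n_perm)`, so p is never 0. Clusters
#' with p below `alpha` form the significant mask. The max-cluster null
#' controls the family-wise error over the whole plane.
#'
#' @param maps_a,maps_b Lists of `tf_map` objects or matrices, one per
#'   subject, subjects in the same order.
#' @param alpha Significance threshold on the cluster p-values.
#' @param cluster_alpha Two-tailed per-pixel threshold forming clusters.
#' @param n_perm Number of sign-flip permutations.
#' @param seed Seed for the permutation draw.
#' @param adjacency `"4"` (rook) or `"8"` (queen) pixel connectivity.
#' @param statistic `"maxsum"` (sum of t) or `"size"` (pixel count).
#' @return A `cluster_result`: list with `clusters` (tibble: `cluster`,
#'   `sign`, `n_pixels`, `stat`, `p`), `significant_mask` (logical
#'   matrix), `t` (the observed t matrix), `labels` (pixel-to-cluster
#'   integer matrix), and the test parameters.
#' @export
paired_cluster_permutation <- function(maps_a, maps_b,
                                       alpha = 0.05, cluster_alpha = 0.05,
                                       n_perm = 15000, seed = 1L,
                                       adjacency = c("4", "8"),
                                       statistic = c("maxsum", "size")) {
  adjacency <- match.arg(adjacency)
  statistic <- match.arg(statistic)
  as_mat <- function(m) if (inherits(m, "tf_map")) m$values else m
  A <- purrr::map(maps_a, as_mat)
  B <- purrr::map(maps_b, as_mat)
  if (length(A) != length(B)) abort("conditions must have the same subjects")
  n <- length(A)
  if (n < 2L) abort("need at least 2 subjects")
  if (n < 5L) warn("fewer than 5 subjects; permutation null is very coarse")
  if (n_perm < 100L) warn("n_perm < 100 gives a very coarse p-value")
  dims <- dim(A[[1]])
  ok <- purrr::every(c(A, B), function(m) identical(dim(m), dims))
  if (!ok) abort("all maps must share the same grid")

  D <- do.call(rbind, purrr::map(seq_len(n), function(i) {
    as.vector(A[[i]] - B[[i]])
  }))
  ssq <- colSums(D^2)
  crit <- qt(1 - cluster_alpha / 2, df = n - 1)

  t_obs <- matrix(paired_t(D, rep(1, n), ssq), dims[1], dims[2])

  # observed clusters
  clusters <- list()
  labels <- matrix(0L, dims[1], dims[2])
  next_id <- 1L
  for (sgn in c(1, -1)) {
    mask <- !is.na(t_obs) & sgn * t_obs > crit
    if (!any(mask)) next
    lab <- label_components(mask, adjacency)
    for (id in seq_len(max(lab))) {
      pix <- lab == id
      stat <- if (statistic == "maxsum") sum(t_obs[pix]) else sum(pix)
      clusters[[next_id]] <- tibble::tibble(
        cluster = next_id, sign = sgn, n_pixels = sum(pix),
        stat = stat)
      labels[pix] <- next_id
      next_id <- next_id + 1L
    }
  }
  clusters <- dplyr::bind_rows(clusters)

  if (nrow(clusters)) {
    set.seed(seed)
    null_max <- numeric(n_perm)
    for (b in seq_len(n_perm)) {
      signs <- sample(c(-1, 1), n, replace = TRUE)
      t_b <- matrix(paired_t(D, signs, ssq), dims[1], dims[2])
      null_max[b] <- max_cluster_stat(t_b, crit, adjacency, statistic)
    }
    clusters$p <- vapply(abs(clusters$stat), function(s) {
      (1 + sum(null_max >= s)) / (1 + n_perm)
    }, numeric(1))
  } else {
    clusters <- tibble::tibble(cluster = integer(), sign = numeric(),
                               n_pixels = integer(), stat = numeric(),
                               p = numeric())
  }

  sig_ids <- clusters$cluster[clusters$p < alpha]
  structure(list(
    clusters = clusters,
    significant_mask = matrix(labels %in% sig_ids, dims[1], dims[2]),
    t = t_obs,
    labels = labels,
    alpha = alpha, cluster_alpha = cluster_alpha,
    n_perm = n_perm, seed = seed,
    adjacency = adjacency, statistic = statistic,
    n_subjects = n
  ), class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d subject(s), %d permutation(s), alpha %.3g\n",
              x$n_subjects, x$n_perm, x$alpha))
  if (nrow(x$clusters)) print(x$clusters) else cat("no supra-threshold clusters\n")
  invisible(x)
}

#' Maximum paired Cohen's d over a pixel cluster
#'
#' Per pixel of the cluster, the paired effect size is
#' `mean(A - B) / sd(A - B)` across subjects; the value returned is the
#' maximum absolute d, carrying its sign. Pixels with zero difference SD
#' are skipped; if every pixel is skipped an error is raised.
#'
#' @param maps_a,maps_b Per-subject `tf_map`s or matrices.
#' @param pixels Logical matrix selecting the cluster's pixels (e.g.
#'   `result$labels == id`).
#' @return Signed maximum Cohen's d.
#' @export
max_cohens_d <- function(maps_a, maps_b, pixels) {
  as_mat <- function(m) if (inherits(m, "tf_map")) m$values else m
  A <- purrr::map(maps_a, as_mat)
  B <- purrr::map(maps_b, as_mat)
  stopifnot(length(A) == length(B))
  sel <- which(pixels)
  if (!length(sel)) abort("cluster pixel set is empty")
  D <- do.call(rbind, purrr::map(seq_along(A), function(i) {
    (A[[i]] - B[[i]])[sel]
  }))
  mu <- colMeans(D)
  s <- apply(D, 2, sd)
  usable <- is.finite(s) & s > 0
  if (!any(usable)) abort("all cluster pixels have zero difference SD")
  d <- mu[usable] / s[usable]
  d[which.max(abs(d))]
}

#' Bootstrap confidence interval for the maximum Cohen's d
#'
#' Resamples subjects with replacement, recomputes the maximum Cohen's d on
#' the fixed pixel set, and returns the percentile interval. Degenerate
#' resamples consisting of one subject only are redrawn.
#'
#' @inheritParams max_cohens_d
#' @param n_boot Number of bootstrap resamples.
#' @param seed Seed of the resampling.
#' @param conf Interval coverage.
#' @return List with `estimate`, `lower`, `upper`, `n_boot`.
#' @export
bootstrap_ci <- function(maps_a, maps_b, pixels, n_boot = 3000,
                         seed = 1L, conf = 0.95) {
  if (n_boot < 100L) warn("n_boot < 100 gives an unstable interval")
  est <- max_cohens_d(maps_a, maps_b, pixels)
  n <- length(maps_a)
  set.seed(seed)
  stat <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    repeat {
      take <- sample.int(n, n, replace = TRUE)
      if (length(unique(take)) > 1L) break
    }
    stat[b] <- tryCatch(
      max_cohens_d(maps_a[take], maps_b[take], pixels),
      error = function(e) NA_real_
    )
  }
  qs <- stats::quantile(stat, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        na.rm = TRUE, names = FALSE)
  list(estimate = est, lower = qs[1], upper = qs[2], n_boot = n_boot)
}
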