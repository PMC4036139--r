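# Prototypical-movement clustering: hierarchical pre-scan, k-means++/Lloyd
# fits, replicate-stability and silhouette-quality selection of the cluster
# count, mirror-pair detection and label assignment.

as_z_matrix <- function(zdata) {
  z <- as.matrix(zdata)
  if (!is.numeric(z)) stopf("zdata must be numeric")
  z
}

#' Hierarchical pre-scan for a candidate cluster-count interval
#'
#' Agglomerates a seeded subsample with the Ward criterion (squared Euclidean
#' merge costs) and returns the interval of cluster counts bracketing the
#' largest relative jumps in merge cost (top decile of the jump ratios over
#' `2..max_k`). The interval motivates, rather than constrains, the k-means
#' scan.
#'
#' @param zdata numeric matrix of z-scored kinematic triples.
#' @param max_k largest cluster count considered.
#' @param subsample subsample size for the dendrogram.
#' @param seed integer seed for the subsample.
#' @return list with `k_range` (candidate interval), `candidates` (the k
#'   values in the top decile) and `jumps` (per-k relative merge-cost jump).
#' @export
hierarchical_k_range <- function(zdata, max_k = 50, subsample = 5000, seed = 1) {
  z <- as_z_matrix(zdata)
  n <- nrow(z)
  m <- min(subsample, n)
  if (m < max_k) stopf("subsample (%d) smaller than max_k (%d)", m, max_k)
  zs <- if (m < n) with_seed_(seed, z[sample.int(n, m), , drop = FALSE]) else z
  hc <- stats::hclust(stats::dist(zs), method = "ward.D2")
  h <- hc$height  # ascending merge costs; merge j leaves m - j clusters
  ks <- 2:min(max_k, m - 1L)
  # cost of merging from k clusters to k - 1, relative to the previous merge
  cost_k <- h[m - ks + 1L]
  cost_prev <- h[m - ks]
  jumps <- cost_k / pmax(cost_prev, .Machine$double.eps)
  cand <- ks[jumps >= stats::quantile(jumps, 0.9)]
  list(k_range = range(cand), candidates = cand,
       jumps = stats::setNames(jumps, ks))
}

#' Fit k-means with k-means++ seeding and Lloyd iterations
#'
#' Seeds with greedy k-means++ (each center drawn from the squared-distance
#' distribution over several candidates, keeping the potential-minimizing
#' one) and runs Lloyd iterations (squared Euclidean distance) to convergence
#' (cost change below `tol`, unchanged assignments, or `max_iter`
#' iterations). `n_init` independent seedings are fitted and the lowest-cost
#' solution kept, the standard guard against local optima. Every point is
#' assigned to its nearest centroid, ties to the lowest centroid index. A
#' cluster that empties is re-seeded at the point farthest from its centroid;
#' the number of such repairs is reported.
#'
#' @param zdata numeric matrix of points (rows).
#' @param k number of clusters; must not exceed the number of distinct points.
#' @param seed integer seed.
#' @param n_init number of independent seedings (best-of by cost).
#' @param max_iter,tol Lloyd stopping parameters.
#' @param init optional explicit initial centers (k x d matrix); bypasses
#'   seeding and `n_init`.
#' @return list with `centers`, `labels` (1-based), `cost` (total
#'   within-cluster sum of squares), `iterations`, `n_reseeds`.
#' @export
kmeans_fit <- function(zdata, k, seed = 1, n_init = 10, max_iter = 300,
                       tol = 1e-8, init = NULL) {
  z <- as_z_matrix(zdata)
  if (!is.null(init))
    return(.lloyd_kmeans(z, as.matrix(init), as.integer(max_iter), tol))
  if (k > nrow(unique(z))) stopf("k (%d) exceeds the number of distinct points", k)
  with_seed_(seed, .kmeans_cpp(z, as.integer(k), as.integer(n_init),
                               as.integer(max_iter), tol))
}

#' Scan cluster counts by replicate stability and silhouette quality
#'
#' For each `k`, fits `n_replicates` seeded k-means runs, each on its own
#' seeded subsample of at most `fit_subsample` points (a resampling-based
#' stability design: a cluster structure is considered stable when
#' independent fits on different subsamples induce the same partition of the
#' full dataset). Every replicate's centroids label the full dataset by
#' nearest-centroid prediction; stability is the mean pairwise adjusted Rand
#' index between these full-data partitions, and quality is the mean
#' silhouette width over replicates, evaluated on one fixed seeded subsample.
#' The selected cluster count is the largest `k` whose stability is at least
#' `stability_threshold` and whose quality lies within `quality_margin`
#' (relative) of the running maximum over the scanned `k`.
#'
#' @param zdata numeric matrix of z-scored kinematic triples.
#' @param k_range integer vector of cluster counts (default `2:50`).
#' @param n_replicates replicate fits per `k` (>= 2).
#' @param seed master seed; replicate seeds are derived by fixed offsets.
#' @param fit_subsample maximum points per replicate fit.
#' @param n_init independent seedings per replicate fit (best-of by cost).
#' @param quality_subsample size of the fixed silhouette subsample.
#' @param stability_threshold minimum mean pairwise adjusted Rand index.
#' @param quality_margin relative margin below the running quality maximum.
#' @return object of class `kscan_result`: list with `selected_k`, `table`
#'   (per-k stability/quality) and the selection trace.
#' @export
evaluate_k_scan <- function(zdata, k_range = 2:50, n_replicates = 20, seed = 1,
                            fit_subsample = 10000, n_init = 5,
                            quality_subsample = 2000,
                            stability_threshold = 0.9, quality_margin = 0.05) {
  z <- as_z_matrix(zdata)
  if (length(k_range) < 1L) stopf("empty k_range")
  if (n_replicates < 2L) stopf("need at least 2 replicates")
  k_range <- sort(unique(as.integer(k_range)))
  n <- nrow(z)
  sub <- with_seed_(seed, sample.int(n, min(quality_subsample, n)))
  dsub <- stats::dist(z[sub, , drop = FALSE])

  stability <- quality <- numeric(length(k_range))
  for (ki in seq_along(k_range)) {
    k <- k_range[ki]
    labs <- lapply(seq_len(n_replicates), function(r) {
      rseed <- child_seed(seed, k, r)
      zr <- if (n > fit_subsample)
        z[with_seed_(child_seed(rseed, 7), sample.int(n, fit_subsample)), ,
          drop = FALSE]
      else z
      fit <- kmeans_fit(zr, k, seed = rseed, n_init = n_init)
      .nearest_centroid(z, fit$centers)
    })
    pairs <- utils::combn(n_replicates, 2L)
    stability[ki] <- mean(apply(pairs, 2L, function(p)
      mclust::adjustedRandIndex(labs[[p[1]]], labs[[p[2]]])))
    quality[ki] <- mean(vapply(labs, function(l) {
      ls <- l[sub]
      if (length(unique(ls)) < 2L) return(0)
      mean(cluster::silhouette(ls, dsub)[, "sil_width"])
    }, numeric(1)))
  }
  run_max <- cummax(quality)
  eligible <- stability >= stability_threshold &
    quality >= run_max - quality_margin * abs(run_max)
  selected_k <- if (any(eligible)) max(k_range[eligible])
                else k_range[which.max(quality)]
  structure(list(
    selected_k = selected_k,
    table = data.frame(k = k_range, stability = stability, quality = quality,
                       running_max_quality = run_max, eligible = eligible),
    n_replicates = n_replicates, seed = seed,
    stability_threshold = stability_threshold, quality_margin = quality_margin
  ), class = "kscan_result")
}

#' @export
print.kscan_result <- function(x, ...) {
  cat(sprintf("k-scan over k = %d..%d (%d replicates): selected k = %d\n",
              min(x$table$k), max(x$table$k), x$n_replicates, x$selected_k))
  invisible(x)
}

#' Detect mirror-imaged centroid pairs
#'
#' Greedy best matching over unordered centroid pairs with score
#' `|d_thrust| + |slip_i + slip_j| + |yaw_i + yaw_j|`; pairs are accepted in
#' increasing score order while the score stays below `tol`. Unpaired
#' centroids (e.g. the low-velocity and backward prototypes) remain
#' singletons. An empty pairing is valid.
#'
#' @param centroids matrix with columns thrust, slip, yaw (any consistent
#'   units; z-units when called on a fitted model).
#' @param tol score threshold for accepting a pair.
#' @return two-column matrix of paired row indices (possibly zero rows).
#' @export
find_mirror_pairs <- function(centroids, tol = 0.5) {
  ctr <- as.matrix(centroids)
  k <- nrow(ctr)
  if (k < 2L) return(matrix(integer(0), 0, 2, dimnames = list(NULL, c("pm_a", "pm_b"))))
  cand <- t(utils::combn(k, 2L))
  score <- abs(ctr[cand[, 1], 1] - ctr[cand[, 2], 1]) +
    abs(ctr[cand[, 1], 2] + ctr[cand[, 2], 2]) +
    abs(ctr[cand[, 1], 3] + ctr[cand[, 2], 3])
  ord <- order(score)
  used <- logical(k)
  out <- matrix(integer(0), 0, 2)
  for (i in ord) {
    if (score[i] >= tol) break
    a <- cand[i, 1]; b <- cand[i, 2]
    if (!used[a] && !used[b]) {
      out <- rbind(out, c(a, b))
      used[a] <- used[b] <- TRUE
    }
  }
  colnames(out) <- c("pm_a", "pm_b")
  out
}

#' Fit the prototypical-movement model
#'
#' Full clustering stage: fits the z-scaler, optionally runs the hierarchical
#' pre-scan and the replicate k-scan to choose the cluster count (or uses a
#' fixed `k`), fits the final k-means partition, detects mirror pairs and
#' renumbers the PMs canonically: unpaired prototypes first (by increasing
#' thrust, so the backward prototype is PM 01), then mirror pairs by
#' increasing rotational amplitude, the positive-slip member first.
#'
#' @param kin a `kinematic_series` (or data frame with thrust/slip/yaw).
#' @param k fixed cluster count; if `NULL`, selected by [evaluate_k_scan()].
#' @param k_range,n_replicates scan parameters, see [evaluate_k_scan()].
#' @param seed master seed.
#' @param mirror_tol tolerance for [find_mirror_pairs()] in z-units.
#' @param hierarchical if `TRUE`, run [hierarchical_k_range()] and keep its
#'   candidate interval in the model (reported, not constraining).
#' @param ... further arguments passed to [evaluate_k_scan()].
#' @return object of class `pm_model`: scaler, selected k, centroids in z and
#'   raw units, mirror pairing, per-PM data fractions, and the scan traces.
#' @export
fit_pm_model <- function(kin, k = NULL, k_range = 2:50, n_replicates = 20,
                         seed = 1, mirror_tol = 0.5, hierarchical = TRUE, ...) {
  scaler <- fit_scaler(kin)
  z <- apply_scaler(scaler, kin)
  hier <- if (hierarchical) hierarchical_k_range(z, max_k = max(k_range), seed = seed)
          else NULL
  kscan <- NULL
  if (is.null(k)) {
    kscan <- evaluate_k_scan(z, k_range = k_range, n_replicates = n_replicates,
                             seed = seed, ...)
    k <- kscan$selected_k
  }
  fit <- kmeans_fit(z, k, seed = child_seed(seed, 999))
  ctr <- fit$centers
  # score mirror pairs on SD-normalised raw centroids: the joint
  # translational z-shift would otherwise offset the slip antisymmetry
  ctr_raw <- invert_scaler(scaler, ctr)
  ctr_scaled <- sweep(ctr_raw, 2L, c(scaler$trans_sd, scaler$trans_sd,
                                     scaler$yaw_sd), "/")
  pairs <- find_mirror_pairs(ctr_scaled, tol = mirror_tol)

  # canonical PM order: singletons by thrust ascending, pairs by |yaw|,
  # positive-slip member first
  paired <- sort(as.vector(pairs))
  singles <- setdiff(seq_len(k), paired)
  ord <- singles[order(ctr[singles, 1])]
  if (nrow(pairs)) {
    pair_yaw <- abs(ctr[pairs[, 1], 3]) + abs(ctr[pairs[, 2], 3])
    for (i in order(pair_yaw)) {
      a <- pairs[i, 1]; b <- pairs[i, 2]
      if (ctr[a, 2] < ctr[b, 2]) { tmp <- a; a <- b; b <- tmp }
      ord <- c(ord, a, b)
    }
  }
  remap <- match(seq_len(k), ord)  # old id -> new id
  ctr <- ctr[ord, , drop = FALSE]
  rownames(ctr) <- NULL
  labels <- remap[fit$labels]
  pairs_new <- if (nrow(pairs)) {
    p <- cbind(remap[pairs[, 1]], remap[pairs[, 2]])
    t(apply(p, 1L, sort))
  } else pairs
  if (length(pairs_new)) colnames(pairs_new) <- c("pm_a", "pm_b")

  model <- structure(list(
    selected_k = k,
    scaler = scaler,
    centroids_z = ctr,
    centroids_raw = invert_scaler(scaler, ctr),
    mirror_pairs = pairs_new,
    data_fraction = as.vector(tabulate(labels, k)) / length(labels),
    kscan = kscan,
    hierarchical_range = hier,
    seed = seed
  ), class = "pm_model")
  model
}

#' @export
print.pm_model <- function(x, ...) {
  cat(sprintf("pm_model: k = %d prototypical movements, %d mirror pairs\n",
              x$selected_k, nrow(x$mirror_pairs)))
  tab <- data.frame(pm = seq_len(x$selected_k),
                    round(x$centroids_raw, 2),
                    fraction = round(x$data_fraction, 3))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Assign kinematic records to prototypical movements
#'
#' Nearest-centroid labels in z-space (squared Euclidean; ties broken toward
#' the lowest PM id). Deterministic.
#'
#' @param model a `pm_model`.
#' @param kin a `kinematic_series`/data frame with raw thrust/slip/yaw, or a
#'   numeric matrix already in z-units (`z = TRUE`).
#' @param z set to `TRUE` if `kin` is already z-scored.
#' @return integer vector of PM labels.
#' @export
assign_pms <- function(model, kin, z = FALSE) {
  zz <- if (z) as_z_matrix(kin) else apply_scaler(model$scaler, kin)
  if (ncol(zz) != ncol(model$centroids_z)) stopf("dimension mismatch")
  .nearest_centroid(zz, model$centroids_z)
}

#' Identify the backward-thrust prototype (PM 01)
#'
#' @param model a `pm_model`.
#' @return the PM id of the unpaired prototype with the lowest raw thrust.
#' @export
pm01_id <- function(model) {
  paired <- as.vector(model$mirror_pairs)
  singles <- setdiff(seq_len(model$selected_k), paired)
  if (!length(singles)) singles <- seq_len(model$selected_k)
  singles[which.min(model$centroids_raw[singles, 1])]
}
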