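# Spatial and electromotor analytics: instantaneous EOD frequency and
# per-night z-scoring, occupancy and mean-value maps, distance profiles,
# approach/departure conditionals, distance-referenced averages, post-chain
# transition shifts and the group statistics.

#' Instantaneous EOD frequency
#'
#' The frequency at frame `n` is the reciprocal of the preceding inter-pulse
#' interval, `1 / (t_n - t_(n-1))`; the first frame is masked (`NA`).
#'
#' @param eod_times strictly increasing EOD time stamps in seconds.
#' @return numeric vector of frequencies in Hz, same length as `eod_times`.
#' @export
instantaneous_feod <- function(eod_times) {
  if (length(eod_times) < 2L) stopf("need at least 2 pulses")
  d <- diff(eod_times)
  if (any(d == 0)) stopf("duplicate EOD timestamps")
  if (any(d < 0)) stopf("EOD timestamps must be increasing")
  c(NA_real_, 1 / d)
}

#' Z-score EOD frequencies per recording night
#'
#' Each night's frequencies are centred and scaled with that night's own mean
#' and SD, accounting for changes in basal emission frequency between nights.
#'
#' @param freqs numeric vector of instantaneous frequencies (NA allowed).
#' @param night_ids per-frame night identifier.
#' @return numeric vector of z-scored frequencies.
#' @export
zscore_per_night <- function(freqs, night_ids) {
  mu <- stats::ave(freqs, night_ids, FUN = function(v) mean(v, na.rm = TRUE))
  sg <- stats::ave(freqs, night_ids, FUN = function(v) stats::sd(v, na.rm = TRUE))
  if (any(sg == 0, na.rm = TRUE)) stopf("a night has constant EOD frequency")
  (freqs - mu) / sg
}

#' Spatial occupancy and mean-value maps
#'
#' Bins positions into a square grid (1 cm bins by default). The occupancy
#' grid holds the cumulative frame count per bin; if `values` are given, a
#' second grid holds their per-bin mean, with empty bins masked (`NA`).
#' Positions outside the extent are dropped and their count reported.
#'
#' @param x,y positions in cm.
#' @param values optional per-frame values (e.g. instantaneous fEOD).
#' @param extent `c(xmin, xmax, ymin, ymax)` in cm.
#' @param bin bin width in cm (> 0).
#' @return list with `counts` (matrix, rows = x bins, cols = y bins),
#'   `mean` (or `NULL`), `xbreaks`, `ybreaks`, `n_dropped`.
#' @export
occupancy_and_value_maps <- function(x, y, values = NULL,
                                     extent = c(-32, 32, -24, 24), bin = 1) {
  if (bin <= 0) stopf("bin width must be > 0")
  xb <- seq(extent[1], extent[2], by = bin)
  yb <- seq(extent[3], extent[4], by = bin)
  inside <- x >= extent[1] & x <= extent[2] & y >= extent[3] & y <= extent[4]
  n_dropped <- sum(!inside)
  if (n_dropped) message(sprintf("dropping %d positions outside the map extent", n_dropped))
  xi <- cut(x[inside], xb, include.lowest = TRUE, labels = FALSE)
  yi <- cut(y[inside], yb, include.lowest = TRUE, labels = FALSE)
  counts <- matrix(0L, length(xb) - 1L, length(yb) - 1L)
  tab <- table(factor(xi, seq_len(nrow(counts))), factor(yi, seq_len(ncol(counts))))
  counts[] <- as.integer(tab)
  mean_grid <- NULL
  if (!is.null(values)) {
    mean_grid <- matrix(NA_real_, nrow(counts), ncol(counts))
    v <- values[inside]
    agg <- tapply(v, list(factor(xi, seq_len(nrow(counts))),
                          factor(yi, seq_len(ncol(counts)))),
                  mean, na.rm = TRUE)
    mean_grid[] <- agg
  }
  list(counts = counts, mean = mean_grid, xbreaks = xb, ybreaks = yb,
       n_dropped = n_dropped)
}

#' Relative frequency of a flag as a function of object distance
#'
#' Per 1-cm distance bin, the fraction of frames bearing the flag among all
#' frames in that bin (the per-bin conditional), the flagged count relative
#' to the size of the complete dataset (the whole-dataset normalisation), and
#' the denominator histogram. Empty bins are masked.
#'
#' @param flags logical per-frame flag (e.g. "labelled PM 07").
#' @param distances per-frame object distance in cm.
#' @param bin distance bin width in cm.
#' @return data frame: `bin_lo`, `bin_mid`, `n_total`, `n_flagged`,
#'   `frac` (flagged / bin total, `NA` for empty bins) and `rel_total`
#'   (flagged / overall frame count).
#' @export
distance_profile <- function(flags, distances, bin = 1) {
  if (bin <= 0) stopf("bin width must be > 0")
  edges <- seq(0, max(distances) + bin, by = bin)
  bi <- findInterval(distances, edges, rightmost.closed = TRUE)
  nb <- length(edges) - 1L
  n_total <- tabulate(bi, nb)
  n_flag <- tabulate(bi[flags], nb)
  data.frame(bin_lo = edges[-length(edges)],
             bin_mid = edges[-length(edges)] + bin / 2,
             n_total = n_total, n_flagged = n_flag,
             frac = ifelse(n_total > 0, n_flag / n_total, NA_real_),
             rel_total = n_flag / length(distances))
}

#' Spatial conditional for object approach (or departure)
#'
#' Keeps occurrences whose final-frame object distance is below `d_max` and
#' smaller than their initial-frame distance ("object approach"); with
#' `invert = TRUE`, keeps occurrences starting below `d_max` whose distance
#' increases ("object departure"). The two subsets are disjoint for any
#' occurrence set.
#'
#' @param occurrences data frame with `start`, `end` record indices.
#' @param distances per-record object distance in cm.
#' @param d_max distance limit in cm (default 4, the head-cube criterion).
#' @param invert select departures instead of approaches.
#' @return the filtered subset of `occurrences` with `d_first`, `d_last`
#'   columns added.
#' @export
approach_filter <- function(occurrences, distances, d_max = 4, invert = FALSE) {
  d1 <- distances[occurrences$start]
  d2 <- distances[occurrences$end]
  keep <- if (invert) d1 < d_max & d2 > d1 else d2 < d_max & d2 < d1
  out <- occurrences[which(keep), , drop = FALSE]
  out$d_first <- d1[which(keep)]
  out$d_last <- d2[which(keep)]
  out
}

#' Distance-referenced average over occurrences
#'
#' Pools the frames of all occurrences, bins them by object distance (1-cm
#' bins) and reports the per-bin mean, SD, t-based 95 percent confidence
#' interval and contributing frame count of a signal; bins with fewer than
#' two frames have their spread masked.
#'
#' @param values per-record signal values.
#' @param occurrences data frame with `start`, `end` record indices.
#' @param distances per-record object distance in cm.
#' @param bin distance bin width in cm.
#' @return data frame: `bin_lo`, `bin_mid`, `mean`, `sd`, `ci_lo`, `ci_hi`,
#'   `n`.
#' @export
distance_referenced_average <- function(values, occurrences, distances, bin = 1) {
  if (!nrow(occurrences)) stopf("need at least one occurrence")
  rows <- unlist(lapply(seq_len(nrow(occurrences)),
                        function(i) occurrences$start[i]:occurrences$end[i]))
  v <- values[rows]
  d <- distances[rows]
  edges <- seq(0, max(d) + bin, by = bin)
  bi <- findInterval(d, edges, rightmost.closed = TRUE)
  nb <- length(edges) - 1L
  n <- tabulate(bi, nb)
  m <- s <- rep(NA_real_, nb)
  agg_m <- tapply(v, factor(bi, seq_len(nb)), mean)
  agg_s <- tapply(v, factor(bi, seq_len(nb)), stats::sd)
  m[] <- agg_m; s[] <- agg_s
  s[n < 2L] <- NA_real_
  half <- ifelse(n >= 2L, stats::qt(0.975, pmax(n - 1L, 1L)) * s / sqrt(n), NA_real_)
  data.frame(bin_lo = edges[-length(edges)], bin_mid = edges[-length(edges)] + bin / 2,
             mean = m, sd = s, ci_lo = m - half, ci_hi = m + half, n = n)
}

#' Post-chain transition shift with a permutation null
#'
#' Compares the PM composition of the `horizon` records following each chain
#' end against a null built by placing the same number of windows at
#' uniformly random valid positions. Windows running past a segment end are
#' truncated. Two-sided empirical p-values per PM are Holm-corrected.
#'
#' @param labels integer PM label vector.
#' @param chain_ends record indices of chain ends (windows start one record
#'   later).
#' @param horizon window length in records (default 10).
#' @param n_perm number of permutation draws (default 999).
#' @param seed integer seed.
#' @param segment optional contiguity marker; windows truncate at segment
#'   ends.
#' @return data frame: `pm`, `observed` (frequency in post-chain windows),
#'   `expected` (permutation mean), `excess`, `p`, `p_holm`.
#' @export
post_chain_transitions <- function(labels, chain_ends, horizon = 10,
                                   n_perm = 999, seed = 1, segment = NULL) {
  n <- length(labels)
  if (is.null(segment)) segment <- rep(1L, n)
  if (any(chain_ends < 1L | chain_ends > n)) stopf("invalid chain end index")
  seg_end <- stats::ave(seq_len(n), segment, FUN = max)
  window_rows <- function(starts) {
    unlist(lapply(starts, function(s0) {
      if (s0 > n) return(integer(0))
      s0:min(s0 + horizon - 1L, seg_end[s0], n)
    }))
  }
  alphabet <- sort(unique(labels[!is.na(labels)]))
  freq_of <- function(rows) {
    l <- labels[rows]
    l <- l[!is.na(l)]
    tabulate(match(l, alphabet), length(alphabet)) / max(length(l), 1L)
  }
  obs <- freq_of(window_rows(chain_ends + 1L))
  nw <- length(chain_ends)
  perm <- with_seed_(seed, {
    vapply(seq_len(n_perm), function(b)
      freq_of(window_rows(sample.int(n, nw, replace = TRUE))), numeric(length(alphabet)))
  })
  perm <- matrix(perm, nrow = length(alphabet))
  expected <- rowMeans(perm)
  p <- vapply(seq_along(alphabet), function(i) {
    dev <- abs(perm[i, ] - expected[i])
    (1 + sum(dev >= abs(obs[i] - expected[i]))) / (n_perm + 1)
  }, numeric(1))
  data.frame(pm = alphabet, observed = obs, expected = expected,
             excess = obs - expected, p = p,
             p_holm = stats::p.adjust(p, "holm"))
}

#' Nonparametric group comparison
#'
#' Two groups: exact/asymptotic Wilcoxon rank-sum (Mann-Whitney U) test. More
#' than two groups: Kruskal-Wallis omnibus test with tie correction followed
#' by Dunn pairwise z-statistics with Holm adjustment. Groups with fewer than
#' two values are excluded (with a message).
#'
#' @param values numeric vector.
#' @param group_labels group identifier per value.
#' @return list with `omnibus` (test name, statistic, p), `pairwise` (data
#'   frame of contrasts; `NULL` for two groups) and `medians`.
#' @export
group_compare <- function(values, group_labels) {
  g <- as.character(group_labels)
  sizes <- table(g)
  small <- names(sizes)[sizes < 2L]
  if (length(small)) {
    message(sprintf("excluding groups with < 2 values: %s", paste(small, collapse = ", ")))
    keep <- !(g %in% small)
    values <- values[keep]; g <- g[keep]
  }
  groups <- sort(unique(g))
  if (length(groups) < 2L) stopf("need at least 2 groups with >= 2 values")
  med <- tapply(values, g, stats::median)

  if (length(groups) == 2L) {
    exact <- !anyDuplicated(values) && length(values) < 50
    wt <- stats::wilcox.test(values[g == groups[1]], values[g == groups[2]],
                             exact = exact)
    return(list(omnibus = list(test = "wilcoxon_rank_sum",
                               statistic = unname(wt$statistic), p = wt$p.value),
                pairwise = NULL, medians = med))
  }
  kw <- stats::kruskal.test(values, factor(g))
  # Dunn post hoc on the pooled ranks with tie correction
  N <- length(values)
  rk <- rank(values)
  ties <- table(rk)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  rbar <- tapply(rk, g, mean)
  nn <- table(g)
  cmb <- utils::combn(groups, 2L)
  zz <- apply(cmb, 2L, function(pair) {
    se <- sqrt((N * (N + 1) / 12 - tie_corr) *
                 (1 / nn[[pair[1]]] + 1 / nn[[pair[2]]]))
    (rbar[[pair[1]]] - rbar[[pair[2]]]) / se
  })
  pw <- data.frame(group_a = cmb[1, ], group_b = cmb[2, ], z = zz,
                   p = 2 * stats::pnorm(-abs(zz)))
  pw$p_holm <- stats::p.adjust(pw$p, "holm")
  list(omnibus = list(test = "kruskal_wallis",
                      statistic = unname(kw$statistic), p = kw$p.value),
       pairwise = pw, medians = med)
}
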