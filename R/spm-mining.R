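# Markov sequence mining: run collapsing, transition probabilities,
# best-first enumeration of the most probable transition chains
# (super-prototypical movements), mirror/composition reduction, occurrence
# matching and condition contrasts.

#' Collapse label runs to a token sequence
#'
#' Merges consecutive equal labels into single tokens carrying their frame
#' span, so that adjacent tokens always differ. Segments given by `segment`
#' are collapsed independently. The collapse is lossless: the original label
#' sequence is recovered by expanding each token over its span.
#'
#' @param labels integer vector of PM labels.
#' @param segment optional contiguity marker; tokens never span segments.
#' @return data frame with `token`, `start`, `end` (1-based inclusive row
#'   indices into `labels`) and `segment`.
#' @export
collapse_runs <- function(labels, segment = NULL) {
  n <- length(labels)
  if (is.null(segment)) segment <- rep(1L, n)
  r <- rle(paste(segment, labels))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(token = labels[starts], start = starts, end = ends,
             segment = segment[starts])
}

#' Estimate the PM transition model
#'
#' Counts first-order transitions between run-collapsed tokens, pooled over
#' segments (self-transitions are absent by construction). Conditional rows
#' `P(next | current)` are normalised; rows without outgoing transitions are
#' flagged and excluded from sequence enumeration. Token stationary
#' frequencies are token counts over the total token count.
#'
#' @param tokens a data frame from [collapse_runs()] (with `token` and
#'   `segment`), or a list of integer token sequences.
#' @param alphabet optional integer vector of PM ids fixing the state space.
#' @return object of class `pm_transition_model`: `alphabet`, `counts`
#'   (matrix), `P` (row-conditional probabilities), `stationary`,
#'   `dangling` (states without outgoing transitions), plus `enrichment`,
#'   the ratio `P(i -> j) / stationary(j)` kept as a descriptive variant.
#' @export
transition_matrix <- function(tokens, alphabet = NULL) {
  seqs <- if (is.data.frame(tokens)) {
    unname(split(tokens$token, tokens$segment))
  } else tokens
  all_tok <- unlist(seqs, use.names = FALSE)
  if (is.null(alphabet)) alphabet <- sort(unique(all_tok))
  m <- length(alphabet)
  counts <- matrix(0, m, m, dimnames = list(alphabet, alphabet))
  n_trans <- 0L
  for (s in seqs) {
    if (length(s) < 2L) next
    a <- match(s[-length(s)], alphabet)
    b <- match(s[-1L], alphabet)
    tab <- table(factor(a, levels = seq_len(m)), factor(b, levels = seq_len(m)))
    counts <- counts + as.matrix(tab)
    n_trans <- n_trans + length(a)
  }
  if (n_trans < 1L) stopf("need at least one observed transition")
  rs <- rowSums(counts)
  P <- counts / ifelse(rs > 0, rs, 1)
  P[rs == 0, ] <- NA_real_
  stationary <- as.vector(tabulate(match(all_tok, alphabet), m)) / length(all_tok)
  names(stationary) <- alphabet
  enrich <- sweep(P, 2L, ifelse(stationary > 0, stationary, NA_real_), "/")
  structure(list(alphabet = alphabet, counts = counts, P = P,
                 stationary = stationary, enrichment = enrich,
                 dangling = alphabet[rs == 0]),
            class = "pm_transition_model")
}

#' @export
print.pm_transition_model <- function(x, ...) {
  cat(sprintf("pm_transition_model over %d PMs, %d transitions observed\n",
              length(x$alphabet), sum(x$counts)))
  print(round(x$P, 3))
  invisible(x)
}

# binary max-heap over (priority desc, lexicographic sequence asc)
heap_new <- function() new.env(parent = emptyenv())

#' Enumerate the most probable transition sequences (SPMs)
#'
#' The overall probability of a token sequence `s0 ... sn` is
#' `stationary(s0) * prod(P(s[i+1] | s[i]))`. Candidate sequences (no
#' self-transitions, states without outgoing transitions excluded mid-chain)
#' are explored by best-first search with an admissible bound: a partial
#' sequence is scored by its probability times the exact maximal achievable
#' extension product (computed by dynamic programming), so completed
#' sequences pop in exact rank order and the search returns the exhaustive
#' top `top_n` without enumerating all `m * (m-1)^n` chains. Ties are broken
#' lexicographically.
#'
#' @param model a `pm_transition_model`.
#' @param n_transitions chain length in transitions (default 5, i.e. 6
#'   tokens).
#' @param top_n number of sequences to return (default 100); fewer if not
#'   that many have positive probability.
#' @return data frame of class `spm_sequences`: `rank`, `sequence`
#'   (dash-separated tokens), `probability`, with the token vectors in
#'   attribute-free list column `tokens`.
#' @export
enumerate_top_spms <- function(model, n_transitions = 5, top_n = 100) {
  if (n_transitions < 1L) stopf("n_transitions must be >= 1")
  alpha <- model$alphabet
  m <- length(alpha)
  P <- model$P
  P[is.na(P)] <- 0
  diag(P) <- 0  # no self-transitions after run collapsing

  # B[s, r]: maximal probability product achievable in r further transitions
  B <- matrix(1, m, n_transitions + 1L)
  if (n_transitions >= 1L) for (r in seq_len(n_transitions)) {
    B[, r + 1L] <- vapply(seq_len(m), function(s) max(P[s, ] * B[, r]), numeric(1))
  }

  seq_key <- function(s) paste(sprintf("%03d", s), collapse = "-")
  # frontier kept as parallel vectors; O(N log N) via repeated max lookup
  # (frontier stays small: at most top_n * m live partial sequences matter)
  pri <- numeric(0); keys <- character(0); seqs <- list(); lens <- integer(0)
  push <- function(p, s) {
    pri[length(pri) + 1L] <<- p
    keys[length(keys) + 1L] <<- seq_key(s)
    seqs[[length(seqs) + 1L]] <<- s
    lens[length(lens) + 1L] <<- length(s)
  }
  pop_best <- function() {
    best <- which(pri == max(pri))
    i <- best[order(keys[best])][1L]
    out <- list(p = pri[i], s = seqs[[i]])
    pri <<- pri[-i]; keys <<- keys[-i]; seqs[[i]] <<- NULL; lens <<- lens[-i]
    out
  }

  for (s in seq_len(m)) {
    p <- model$stationary[s] * B[s, n_transitions + 1L]
    if (p > 0) push(p, s)
  }
  res_tokens <- list(); res_prob <- numeric(0)
  while (length(pri) && length(res_prob) < top_n) {
    node <- pop_best()
    s <- node$s
    r_left <- n_transitions + 1L - length(s)
    if (r_left == 0L) {
      res_tokens[[length(res_tokens) + 1L]] <- alpha[s]
      res_prob <- c(res_prob, node$p)
      next
    }
    cur_p <- node$p / B[s[length(s)], r_left + 1L]  # realized prefix probability
    for (nx in seq_len(m)) {
      step <- P[s[length(s)], nx]
      if (step > 0) {
        p <- cur_p * step * B[nx, r_left]
        if (p > 0) push(p, c(s, nx))
      }
    }
  }
  out <- data.frame(rank = seq_along(res_prob),
                    sequence = vapply(res_tokens, paste, character(1), collapse = "-"),
                    probability = res_prob)
  out$tokens <- res_tokens
  class(out) <- c("spm_sequences", "data.frame")
  out
}

# map each PM to its mirror-pool label ("7/8" for a pair, "1" for a singleton)
mirror_pool_map <- function(alphabet, mirror_pairs) {
  pool <- stats::setNames(as.character(alphabet), alphabet)
  if (!is.null(mirror_pairs) && nrow(mirror_pairs)) {
    for (i in seq_len(nrow(mirror_pairs))) {
      a <- mirror_pairs[i, 1]; b <- mirror_pairs[i, 2]
      lab <- paste(sort(c(a, b)), collapse = "/")
      pool[as.character(a)] <- lab
      pool[as.character(b)] <- lab
    }
  }
  pool
}

#' Reduce enumerated sequences to an SPM catalog
#'
#' Two merging steps remove redundancy from the ranked sequences: first every
#' token is mapped to its mirror-pool id, discarding the left/right
#' directional information of slip and yaw; then sequences built from the
#' same tokens in the same number (equal composition multiset, e.g.
#' A-A-A-B-A-A and A-A-B-A-A-A) are combined. Each catalog entry keeps its
#' member sequences, sums their probabilities, and uses the mirror-collapsed
#' sequence of its highest-probability member as the canonical form. Both
#' steps conserve total probability.
#'
#' @param sequences an `spm_sequences` data frame from
#'   [enumerate_top_spms()].
#' @param mirror_pairs two-column matrix of mirror-paired PM ids (e.g. from a
#'   `pm_model`).
#' @return object of class `spm_catalog`: data frame with `entry`,
#'   `canonical`, `composition`, `probability`, `n_members` and list column
#'   `members`; ordered by decreasing probability.
#' @export
reduce_spms <- function(sequences, mirror_pairs = NULL) {
  toks <- sequences$tokens
  alphabet <- sort(unique(unlist(toks)))
  pool <- mirror_pool_map(alphabet, mirror_pairs)
  pooled <- lapply(toks, function(s) unname(pool[as.character(s)]))
  comp <- vapply(pooled, function(s) paste(sort(s), collapse = " "), character(1))
  groups <- split(seq_along(comp), comp)
  entries <- lapply(groups, function(ix) {
    best <- ix[which.max(sequences$probability[ix])]
    list(canonical = paste(pooled[[best]], collapse = "-"),
         composition = comp[best],
         probability = sum(sequences$probability[ix]),
         members = sequences$sequence[ix],
         canonical_tokens = pooled[[best]])
  })
  ord <- order(vapply(entries, `[[`, numeric(1), "probability"), decreasing = TRUE)
  entries <- entries[ord]
  out <- data.frame(entry = seq_along(entries),
                    canonical = vapply(entries, `[[`, character(1), "canonical"),
                    composition = vapply(entries, `[[`, character(1), "composition"),
                    probability = vapply(entries, `[[`, numeric(1), "probability"),
                    n_members = vapply(entries, function(e) length(e$members), integer(1)))
  out$members <- lapply(entries, `[[`, "members")
  out$canonical_tokens <- lapply(entries, `[[`, "canonical_tokens")
  class(out) <- c("spm_catalog", "data.frame")
  out
}

#' @export
print.spm_catalog <- function(x, ...) {
  cat(sprintf("spm_catalog: %d entries (from %d raw sequences)\n",
              nrow(x), sum(x$n_members)))
  print(data.frame(entry = x$entry, canonical = x$canonical,
                   probability = signif(x$probability, 3),
                   n_members = x$n_members), row.names = FALSE)
  invisible(x)
}

#' Locate occurrences of a catalog entry in a label sequence
#'
#' Slides over the mirror-collapsed token sequence of `labels`; every window
#' of `n_transitions + 1` tokens equal to the entry's canonical
#' mirror-collapsed sequence yields one occurrence spanning the first token's
#' first frame to the last token's last frame. Overlapping occurrences are
#' allowed and flagged.
#'
#' @param labels integer PM label vector.
#' @param entry one row of an `spm_catalog` (or the catalog plus `which`).
#' @param mirror_pairs pairing matrix used when the catalog was built.
#' @param segment optional contiguity marker.
#' @return data frame with `start`, `end` (1-based inclusive record indices),
#'   `n_tokens` and `overlaps_previous`.
#' @export
match_occurrences <- function(labels, entry, mirror_pairs = NULL, segment = NULL) {
  canonical <- if (is.data.frame(entry)) entry$canonical_tokens[[1L]]
               else entry$canonical_tokens
  L <- length(canonical)
  tok <- collapse_runs(labels, segment)
  pool <- mirror_pool_map(sort(unique(labels[!is.na(labels)])), mirror_pairs)
  ptok <- unname(pool[as.character(tok$token)])
  hits <- integer(0)
  for (seg in unique(tok$segment)) {
    ix <- which(tok$segment == seg)
    if (length(ix) < L) next
    for (w in seq_len(length(ix) - L + 1L)) {
      if (all(ptok[ix[w:(w + L - 1L)]] == canonical)) hits <- c(hits, ix[w])
    }
  }
  out <- data.frame(start = tok$start[hits], end = tok$end[hits + L - 1L],
                    n_tokens = rep(L, length(hits)))
  out$overlaps_previous <- c(FALSE, out$start[-1L] <= out$end[-nrow(out)])[seq_len(nrow(out))]
  out
}

#' Contrast SPM occurrence frequencies between two conditions
#'
#' The relative frequency of an entry in a condition is the number of records
#' covered by at least one of its occurrences divided by the total number of
#' records in that condition. The per-entry difference `freq_a - freq_b` is
#' reported with its sign.
#'
#' @param catalog an `spm_catalog`.
#' @param labels_a,labels_b PM label vectors of the two conditions.
#' @param mirror_pairs pairing matrix used when the catalog was built.
#' @param segment_a,segment_b optional contiguity markers.
#' @return data frame with `entry`, `canonical`, `freq_a`, `freq_b`, `diff`.
#' @export
condition_contrast <- function(catalog, labels_a, labels_b, mirror_pairs = NULL,
                               segment_a = NULL, segment_b = NULL) {
  if (!length(labels_a) || !length(labels_b)) stopf("empty condition dataset")
  freq_one <- function(labels, segment, i) {
    occ <- match_occurrences(labels, catalog[i, ], mirror_pairs, segment)
    if (!nrow(occ)) return(0)
    covered <- unique(unlist(lapply(seq_len(nrow(occ)),
                                    function(j) occ$start[j]:occ$end[j])))
    length(covered) / length(labels)
  }
  fa <- vapply(seq_len(nrow(catalog)), function(i) freq_one(labels_a, segment_a, i),
               numeric(1))
  fb <- vapply(seq_len(nrow(catalog)), function(i) freq_one(labels_b, segment_b, i),
               numeric(1))
  data.frame(entry = catalog$entry, canonical = catalog$canonical,
             freq_a = fa, freq_b = fb, diff = fa - fb)
}
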