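# Independent brute-force oracles and small fixture builders used across the
# test files. Oracles deliberately share no code with the implementation.

# all maximal runs of `pm` of length >= min_len, by exhaustive scanning over
# every (start, end) pair
oracle_runs <- function(labels, pm, min_len, segment = NULL) {
  n <- length(labels)
  if (is.null(segment)) segment <- rep(1L, n)
  out <- NULL
  for (s in seq_len(n)) {
    for (e in s:n) {
      if (any(labels[s:e] != pm) || length(unique(segment[s:e])) > 1L) next
      left_ok <- s == 1L || labels[s - 1L] != pm || segment[s - 1L] != segment[s]
      right_ok <- e == n || labels[e + 1L] != pm || segment[e + 1L] != segment[e]
      if (left_ok && right_ok && (e - s + 1L) >= min_len)
        out <- rbind(out, c(s, e))
    }
  }
  out
}

# exhaustive k-means: minimal total within-cluster sum of squares over all
# assignments of n points to k clusters (n small)
oracle_kmeans_cost <- function(x, k) {
  n <- nrow(x)
  grid <- do.call(expand.grid, rep(list(seq_len(k)), n))
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    a <- as.integer(grid[r, ])
    if (length(unique(a)) < k) next
    cost <- 0
    for (j in seq_len(k)) {
      pts <- x[a == j, , drop = FALSE]
      ctr <- colMeans(pts)
      cost <- cost + sum(sweep(pts, 2, ctr)^2)
    }
    best <- min(best, cost)
  }
  best
}

# direct silhouette computation from the definition
oracle_silhouette <- function(x, labels) {
  n <- nrow(x)
  dmat <- as.matrix(stats::dist(x))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    if (sum(own) == 1L) { s[i] <- 0; next }
    a <- mean(dmat[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(g) mean(dmat[i, labels == g]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  s
}

# exhaustive SPM enumeration: all sequences without self-transitions
oracle_spms <- function(model, n_transitions) {
  m <- length(model$alphabet)
  P <- model$P
  P[is.na(P)] <- 0
  grid <- do.call(expand.grid, rep(list(seq_len(m)), n_transitions + 1L))
  out <- NULL
  for (r in seq_len(nrow(grid))) {
    s <- as.integer(grid[r, ])
    if (any(s[-1L] == s[-length(s)])) next
    p <- model$stationary[s[1L]]
    for (i in seq_len(n_transitions)) p <- p * P[s[i], s[i + 1L]]
    if (p > 0)
      out <- rbind(out, data.frame(
        sequence = paste(model$alphabet[s], collapse = "-"), probability = p))
  }
  out[order(-out$probability, out$sequence), ]
}

# pure Gaussian mixture from a prototype table (no behavioral structure)
mixture_kinematics <- function(n, pt = default_prototype_table(),
                               weights = NULL, seed = 1) {
  withr::with_seed(seed, {
    w <- if (is.null(weights)) rep(1 / nrow(pt), nrow(pt)) else weights
    pm <- sample(pt$pm, n, TRUE, w)
    i <- match(pm, pt$pm)
    data.frame(thrust = stats::rnorm(n, pt$thrust[i], pt$sd_thrust[i]),
               slip = stats::rnorm(n, pt$slip[i], pt$sd_slip[i]),
               yaw = stats::rnorm(n, pt$yaw[i], pt$sd_yaw[i]),
               gt_pm = pm)
  })
}

# z-scored prototype centroids for a given scaler
prototype_centroids_z <- function(pt, scaler) {
  apply_scaler(scaler, data.frame(thrust = pt$thrust, slip = pt$slip,
                                  yaw = pt$yaw))
}

prototype_model <- function(pt, scaler) {
  structure(list(selected_k = nrow(pt), scaler = scaler,
                 centroids_z = prototype_centroids_z(pt, scaler),
                 centroids_raw = cbind(thrust = pt$thrust, slip = pt$slip,
                                       yaw = pt$yaw),
                 mirror_pairs = cbind(pm_a = c(3, 5, 7, 9),
                                      pm_b = c(4, 6, 8, 10)),
                 data_fraction = rep(0.1, nrow(pt))),
            class = "pm_model")
}
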