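blob <- function(n, center, sd = 0.2, seed = 1) {
  withr::with_seed(seed, matrix(stats::rnorm(n * 3, rep(center, each = n), sd),
                                n, 3))
}

test_that("hierarchical pre-scan brackets the natural cluster count", {
  x4 <- rbind(blob(40, c(0, 0, 0), seed = 1), blob(40, c(8, 0, 0), seed = 2),
              blob(40, c(0, 8, 0), seed = 3), blob(40, c(0, 0, 8), seed = 4))
  r <- hierarchical_k_range(x4, max_k = 20, subsample = 160, seed = 5)
  expect_true(r$k_range[1] <= 4 && 4 <= r$k_range[2])

  # single blob: degenerates toward small k, no crash
  r1 <- hierarchical_k_range(blob(200, c(0, 0, 0), sd = 1, seed = 6),
                             max_k = 20, seed = 5)
  expect_true(all(is.finite(r1$k_range)))

  # two tight clouds far apart: the 2 -> 1 merge is the unique dominant jump
  x2 <- rbind(blob(4, c(0, 0, 0), sd = 0.01, seed = 7),
              blob(4, c(50, 0, 0), sd = 0.01, seed = 8))
  r2 <- hierarchical_k_range(x2, max_k = 5, subsample = 8, seed = 5)
  expect_equal(unname(which.max(r2$jumps)), match("2", names(r2$jumps)))
  expect_true(2 %in% r2$candidates)

  expect_error(hierarchical_k_range(x2, max_k = 20, subsample = 8), "smaller")
})

test_that("k-means solves exact and brute-force-verifiable cases", {
  x <- rbind(matrix(0, 50, 3), matrix(10, 50, 3))
  f <- kmeans_fit(x, 2, seed = 1)
  expect_equal(f$cost, 0)
  expect_equal(sort(f$centers[, 1]), c(0, 10))

  f1 <- kmeans_fit(matrix(stats::rnorm(30), 10, 3), 1, seed = 1)
  expect_equal(as.vector(f1$centers), colMeans(matrix(f1$centers, 1, 3)))

  withr::with_seed(8, {
    x9 <- rbind(blob(3, c(0, 0, 0), 0.3, 1), blob(3, c(5, 1, 0), 0.3, 2),
                blob(3, c(1, 6, 2), 0.3, 3))
    f9 <- kmeans_fit(x9, 3, seed = 2, n_init = 10)
    expect_equal(f9$cost, oracle_kmeans_cost(x9, 3), tolerance = 1e-9)
  })

  # independent cross-check against the reference k-means implementation
  withr::with_seed(9, {
    xr <- matrix(stats::rnorm(600), 200, 3)
    ours <- kmeans_fit(xr, 4, seed = 3, n_init = 10)
    ref <- stats::kmeans(xr, 4, nstart = 25, iter.max = 100)
    expect_lt(ours$cost, ref$tot.withinss * 1.02)
  })
})

test_that("Lloyd iterations never increase the cost from a given start", {
  withr::with_seed(10, {
    x <- matrix(stats::rnorm(300), 100, 3)
    init <- x[1:5, ]
    f <- kmeans_fit(x, 5, init = init)
    d0 <- vapply(seq_len(nrow(x)), function(i)
      min(colSums((t(init) - x[i, ])^2)), numeric(1))
    expect_lte(f$cost, sum(d0))
  })
})

test_that("the k-scan selects two clusters for two separated blobs", {
  x <- rbind(blob(150, c(0, 0, 0), 0.5, 11), blob(150, c(6, 0, 0), 0.5, 12))
  ks <- evaluate_k_scan(x, k_range = 2:6, n_replicates = 4, seed = 7,
                        quality_subsample = 60)
  expect_equal(ks$selected_k, 2L)
  expect_true(all(ks$table$quality[1] >= ks$table$quality[-1]))

  # silhouette quality agrees with direct computation on the fixed subsample
  sub <- withr::with_seed(7, sample.int(nrow(x), 60))
  f <- kmeans_fit(x, 2, seed = 1)
  sil <- oracle_silhouette(x[sub, ], f$labels[sub])
  direct <- mean(cluster::silhouette(f$labels[sub],
                                     stats::dist(x[sub, ]))[, "sil_width"])
  expect_equal(direct, mean(sil), tolerance = 1e-9)
})

test_that("duplicated replicate partitions give stability exactly 1", {
  # two blobs so separated that every replicate finds the same partition
  x <- rbind(blob(100, c(0, 0, 0), 0.1, 13), blob(100, c(50, 0, 0), 0.1, 14))
  ks <- evaluate_k_scan(x, k_range = 2, n_replicates = 3, seed = 9)
  expect_equal(ks$table$stability, 1)
})

test_that("mirror pairs are detected by the greedy matcher", {
  ctr <- rbind(c(5, 3, 40), c(5, -3, -40))
  expect_equal(nrow(find_mirror_pairs(ctr, tol = 0.5)), 1L)
  same <- rbind(c(5, 3, 40), c(5, 3, 40))
  expect_equal(nrow(find_mirror_pairs(same, tol = 0.5)), 0L)

  # the generator's 4 pairs + 2 singletons, SD-normalised as in fit_pm_model
  pt <- default_prototype_table()
  kin <- mixture_kinematics(4000, pt, seed = 15)
  sc <- fit_scaler(kin)
  cs <- cbind(pt$thrust / sc$trans_sd, pt$slip / sc$trans_sd, pt$yaw / sc$yaw_sd)
  pairs <- find_mirror_pairs(cs, tol = 0.5)
  expect_equal(nrow(pairs), 4L)
  expect_setequal(apply(pairs, 1, paste, collapse = "-"),
                  c("3-4", "5-6", "7-8", "9-10"))
})

test_that("assignment is nearest-centroid with lowest-id tie-break", {
  pt <- default_prototype_table()
  kin <- mixture_kinematics(2000, pt, seed = 16)
  sc <- fit_scaler(kin)
  model <- prototype_model(pt, sc)

  # points at the centroids map to their own PM
  at_ctr <- as.data.frame(model$centroids_raw)
  expect_equal(assign_pms(model, at_ctr), 1:10)

  # an equidistant point goes to the lowest PM id
  mid <- colMeans(model$centroids_z[1:2, ])
  two <- structure(list(scaler = sc, centroids_z = model$centroids_z[1:2, ]),
                   class = "pm_model")
  expect_equal(assign_pms(two, matrix(mid, 1), z = TRUE), 1L)

  expect_error(assign_pms(model, matrix(0, 2, 2), z = TRUE), "mismatch")

  # generated labels are recovered under low emission noise
  lab <- assign_pms(model, kin)
  expect_gte(mean(lab == kin$gt_pm), 0.95)
})

test_that("mirror-symmetric data yields a slip/yaw-antisymmetric centroid set", {
  withr::with_seed(18, {
    half <- cbind(stats::rnorm(400, 8, 1), stats::rnorm(400, 5, 1),
                  stats::rnorm(400, 120, 15))
    x <- rbind(half, cbind(half[, 1], -half[, 2], -half[, 3]))
    x <- scale(x, center = FALSE, scale = c(5, 5, 100))
    f <- kmeans_fit(x, 2, seed = 4)
    expect_equal(f$centers[1, 1], f$centers[2, 1], tolerance = 0.05)
    expect_equal(f$centers[1, 2], -f$centers[2, 2], tolerance = 0.05)
    expect_equal(f$centers[1, 3], -f$centers[2, 3], tolerance = 0.05)
    expect_lt(abs(diff(tabulate(f$labels, 2))), 3 * sqrt(800 * 0.25))
  })
})

test_that("fit_pm_model renumbers PMs canonically and finds the backward PM", {
  pt <- default_prototype_table()
  kin <- mixture_kinematics(6000, pt, seed = 19)
  m <- fit_pm_model(kin, k = 10, seed = 20, hierarchical = FALSE)
  expect_equal(m$selected_k, 10L)
  expect_equal(nrow(m$mirror_pairs), 4L)
  expect_equal(pm01_id(m), 1L)
  expect_lt(m$centroids_raw[1, "thrust"], 0)
  # paired centroids satisfy the mirror relation within tolerance
  for (r in seq_len(nrow(m$mirror_pairs))) {
    a <- m$mirror_pairs[r, 1]; b <- m$mirror_pairs[r, 2]
    expect_equal(m$centroids_raw[a, "thrust"], m$centroids_raw[b, "thrust"],
                 tolerance = 0.5)
    expect_equal(m$centroids_raw[a, "slip"], -m$centroids_raw[b, "slip"],
                 tolerance = 0.5)
    expect_equal(m$centroids_raw[a, "yaw"], -m$centroids_raw[b, "yaw"],
                 tolerance = 8)
  }
  expect_equal(sum(m$data_fraction), 1)
  # fitted data fractions track the generating fractions per PM
  gt_frac <- as.vector(table(factor(kin$gt_pm, 1:10))) / nrow(kin)
  expect_lt(max(abs(m$data_fraction - gt_frac)), 0.01)
})
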