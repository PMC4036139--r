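test_that("instantaneous fEOD is the reciprocal preceding inter-pulse interval", {
  expect_equal(instantaneous_feod(c(0, 0.05, 0.09)), c(NA, 20, 25))
  f <- instantaneous_feod(seq(0, 1, by = 0.04))
  expect_true(all(abs(f[-1] - 25) < 1e-9))
  expect_error(instantaneous_feod(c(0, 0.1, 0.1)), "duplicate")
})

test_that("per-night z-scoring centers every night at zero", {
  f <- c(stats::rnorm(50, 20, 2), stats::rnorm(50, 30, 4))
  night <- rep(c("n1", "n2"), each = 50)
  z <- zscore_per_night(f, night)
  expect_equal(mean(z[night == "n1"]), 0, tolerance = 1e-12)
  expect_equal(mean(z[night == "n2"]), 0, tolerance = 1e-12)
  expect_equal(stats::sd(z[night == "n1"]), 1, tolerance = 1e-12)
})

test_that("occupancy and mean maps bin, mask and conserve counts", {
  m <- occupancy_and_value_maps(rep(0.5, 7), rep(0.5, 7),
                                extent = c(0, 4, 0, 4), bin = 1)
  expect_equal(sum(m$counts), 7L)
  expect_equal(m$counts[1, 1], 7L)

  m2 <- occupancy_and_value_maps(c(0.5, 0.6), c(0.5, 0.5), values = c(1, 3),
                                 extent = c(0, 4, 0, 4), bin = 1)
  expect_equal(m2$mean[1, 1], 2)
  expect_true(all(is.na(m2$mean[m2$counts == 0])))

  withr::with_seed(301, {
    x <- stats::runif(500, -5, 5)
    y <- stats::runif(500, -5, 5)
    m3 <- occupancy_and_value_maps(x, y, values = rep(7, 500),
                                   extent = c(-4, 4, -4, 4), bin = 1)
    expect_equal(sum(m3$counts) + m3$n_dropped, 500L)
    expect_true(all(m3$mean[m3$counts > 0] == 7))  # constant signal, constant map
  })
  expect_error(occupancy_and_value_maps(1, 1, bin = 0), "bin")
})

test_that("distance profiles count fractions per bin and partition to one", {
  d <- c(0.5, 0.5, 1.5, 1.5, 1.5, 2.5, 2.5, 2.5, 2.5, 3.5)
  fl <- c(TRUE, FALSE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE)
  pr <- distance_profile(fl, d, bin = 1)
  expect_equal(pr$frac[1:4], c(1 / 2, 2 / 3, 1 / 4, 1))
  expect_equal(pr$n_total[1:4], c(2L, 3L, 4L, 1L))
  expect_equal(pr$rel_total[1:4], c(1, 2, 1, 1) / 10)

  expect_true(all(distance_profile(rep(TRUE, 10), d)$frac[1:4] == 1))
  expect_true(all(distance_profile(rep(FALSE, 10), d)$frac[1:4] == 0))

  # mutually exclusive exhaustive flags sum to 1 in every occupied bin
  withr::with_seed(302, {
    dd <- stats::runif(300, 0, 20)
    g <- sample(1:3, 300, TRUE)
    tot <- Reduce(`+`, lapply(1:3, function(i)
      distance_profile(g == i, dd)$frac))
    expect_true(all(abs(tot[!is.na(tot)] - 1) < 1e-12))
  })
})

test_that("approach and departure conditionals match a direct scan and are disjoint", {
  occ <- data.frame(start = c(1, 5, 9), end = c(4, 8, 12))
  d <- c(12, 10, 8, 3.5, 6, 7, 8, 9, 3, 4, 5, 6)
  ap <- approach_filter(occ, d, d_max = 4)
  expect_equal(ap$start, 1)  # ends at 3.5 cm having started at 12 cm
  dep <- approach_filter(occ, d, d_max = 4, invert = TRUE)
  expect_equal(dep$start, 9)  # starts at 3 cm and moves away

  # entirely-far occurrences yield an empty set
  far <- approach_filter(data.frame(start = 5, end = 8), d, d_max = 4)
  expect_equal(nrow(far), 0L)

  withr::with_seed(303, {
    dd <- stats::runif(200, 0, 20)
    st <- sort(sample(1:190, 20))
    oc <- data.frame(start = st, end = pmin(st + sample(3:8, 20, TRUE), 200))
    got <- approach_filter(oc, dd, d_max = 6)
    want <- oc[dd[oc$end] < 6 & dd[oc$end] < dd[oc$start], ]
    expect_equal(got$start, want$start)
    gotd <- approach_filter(oc, dd, d_max = 6, invert = TRUE)
    expect_equal(length(intersect(got$start, gotd$start)), 0L)
  })
})

test_that("distance-referenced averages are flat for constant signals", {
  occ <- data.frame(start = c(1, 11), end = c(10, 20))
  d <- stats::runif(20, 0, 10)
  tr <- distance_referenced_average(rep(4, 20), occ, d)
  expect_true(all(tr$mean[tr$n > 0] == 4))
  # a single-frame bin has its spread masked
  one <- distance_referenced_average(1:5, data.frame(start = 1, end = 5),
                                     c(0.5, 0.5, 0.5, 0.5, 9.5))
  expect_true(is.na(one$sd[one$n == 1][1]))
})

test_that("post-chain transition nulls are calibrated and detect enrichment", {
  # homogeneous labels: excess 0, p near 1
  res <- post_chain_transitions(rep(1L, 200), chain_ends = c(20, 60, 100),
                                n_perm = 99, seed = 5)
  expect_equal(res$excess, 0)
  expect_gt(res$p, 0.9)

  # constructed enrichment: PM 2 always follows chain ends, rare elsewhere
  lab <- rep(1L, 300)
  ends <- c(50, 120, 190, 260)
  for (e in ends) lab[(e + 1):(e + 10)] <- 2L
  res2 <- post_chain_transitions(lab, ends, horizon = 10, n_perm = 199, seed = 6)
  r2 <- res2[res2$pm == 2L, ]
  expect_gt(r2$excess, 0.5)
  expect_lte(r2$p, 0.01)

  # the permutation mean matches the global PM frequency
  withr::with_seed(7, {
    lab3 <- sample(1:3, 400, TRUE)
    res3 <- post_chain_transitions(lab3, c(50, 150, 250), n_perm = 499, seed = 8)
    glob <- as.vector(table(lab3)) / 400
    expect_equal(res3$expected, glob, tolerance = 0.05)
  })
})

test_that("group comparisons use exact ranks and flag only shifted groups", {
  g <- group_compare(c(1, 2, 3, 101, 102, 103), rep(c("a", "b"), each = 3))
  expect_equal(g$omnibus$p, 0.1)  # exact two-sided rank-sum at n = 3, 3

  same <- withr::with_seed(9, stats::rnorm(30))
  gs <- group_compare(c(same, same), rep(c("a", "b"), each = 30))
  expect_gt(gs$omnibus$p, 0.9)

  withr::with_seed(10, {
    v <- c(stats::rnorm(20), stats::rnorm(20), stats::rnorm(20, 5))
    gl <- rep(c("a", "b", "c"), each = 20)
    g3 <- group_compare(v, gl)
    expect_equal(g3$omnibus$test, "kruskal_wallis")
    expect_lt(g3$omnibus$p, 0.001)
    pw <- g3$pairwise
    involves_c <- pw$group_a == "c" | pw$group_b == "c"
    expect_true(all(pw$p_holm[involves_c] < 1e-4))
    expect_true(all(pw$p_holm[!involves_c] > 0.01))
  })
})
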