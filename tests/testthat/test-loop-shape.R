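test_that("resampled loops have the prescribed structure", {
  loop <- make_participant_loop(1)
  expect_equal(dim(unclass(loop)), c(1000L, 2L))
  expect_identical(attr(loop, "boundaries"), c(1L, 251L, 501L, 751L))
})

test_that("resampling preserves values at target times and linear segments", {
  # signals sampled exactly at the 1000 target times are preserved bitwise
  ev <- valve_events(0, 250, 500, 750)
  cycle <- 1000
  tt <- seq(0, 999, by = 1) # the resampling grid itself
  set.seed(5)
  eps <- cumsum(rnorm(1000, 0, 0.1))
  pr <- abs(cumsum(rnorm(1000, 0, 0.5))) + 10
  loop <- resample_loop(strain_trace(tt, eps, cycle_length = cycle),
                        pressure_curve(tt, pr, cycle_length = cycle), ev,
                        cycle_length = cycle)
  expect_identical(unname(unclass(loop)[, 1]), eps)
  expect_identical(unname(unclass(loop)[, 2]), pr)

  # strain linear in time within a segment stays linear, same endpoints
  ev2 <- std_events()
  t2 <- seq(0, 908, by = 4)
  s2 <- strain_trace(t2, -0.02 * t2, cycle_length = 909)
  p2 <- pressure_curve(t2, 100 - 0.05 * t2, cycle_length = 909)
  loop2 <- unclass(resample_loop(s2, p2, ev2, cycle_length = 909))
  seg1 <- loop2[1:250, 1] # MVC..AVO strain samples
  expect_equal(seg1[1], -0.02 * 25, tolerance = 1e-12)
  expect_equal(diff(seg1), rep(diff(seg1)[1], 249), tolerance = 1e-9)
})

test_that("segment boundaries equal event-time interpolants from an oracle", {
  for (seed in c(2, 9)) {
    set.seed(seed)
    cycle <- 909
    ev <- std_events()
    t <- sort(runif(300, 0, cycle - 1e-6))
    t <- c(0, t) # ensure support from cycle start
    eps <- -15 + 5 * sin(2 * pi * t / cycle + 1) + 2 * cos(4 * pi * t / cycle)
    pr <- 80 + 30 * sin(2 * pi * t / cycle)
    loop <- unclass(resample_loop(strain_trace(t, eps, cycle_length = cycle),
                                  pressure_curve(t, pr, cycle_length = cycle),
                                  ev, cycle_length = cycle))
    evt <- c(ev$mvc, ev$avo, ev$avc, ev$mvo)
    expect_equal(loop[c(1, 251, 501, 751), 1],
                 approx(t, eps, xout = evt)$y, tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_equal(loop[c(1, 251, 501, 751), 2],
                 approx(t, pr, xout = evt)$y, tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("mean loops average pointwise with correct bands", {
  l1 <- make_random_loop(1)
  m1 <- mean_loop(list(l1))
  expect_equal(m1$mean, unclass(l1), ignore_attr = TRUE)
  expect_true(all(m1$band == 0))

  l2 <- make_random_loop(2)
  m2 <- mean_loop(list(l1, l2))
  expect_equal(m2$mean, (unclass(l1) + unclass(l2)) / 2, ignore_attr = TRUE)

  # loops identical up to axis-wise +/- c offsets: band SD = c per axis
  c_off <- c(0.7, 3)
  la <- unclass(l1); lb <- unclass(l1)
  la[, 1] <- la[, 1] + c_off[1]; lb[, 1] <- lb[, 1] - c_off[1]
  la[, 2] <- la[, 2] + c_off[2]; lb[, 2] <- lb[, 2] - c_off[2]
  mo <- mean_loop(list(la, lb))
  expect_equal(unname(mo$band[, 1]), rep(sqrt(2) * c_off[1], 1000),
               tolerance = 1e-9)
  expect_equal(unname(mo$band[, 2]), rep(sqrt(2) * c_off[2], 1000),
               tolerance = 1e-9)
  expect_error(mean_loop(list()), "non-empty")
})

test_that("DTW distance matches closed forms and the enumeration oracle", {
  l <- make_random_loop(3)
  expect_identical(dtw_distance(l, l), 0)
  # single-point sequences: plain Euclidean norm
  expect_equal(dtw_distance(matrix(c(0, 0), 1), matrix(c(3, 4), 1)), 5)
  # toy sequences vs exhaustive path enumeration
  set.seed(17)
  for (rep in 1:20) {
    A <- matrix(rnorm(2 * sample(1:5, 1)), ncol = 2)
    B <- matrix(rnorm(2 * sample(1:5, 1)), ncol = 2)
    expect_equal(dtw_distance(A, B), dtw_enumerate(A, B), tolerance = 1e-12)
  }
})

test_that("DTW is symmetric and bounded by any explicit path cost", {
  a <- make_random_loop(4); b <- make_random_loop(5)
  expect_equal(dtw_distance(a, b), dtw_distance(b, a), tolerance = 1e-12)
  # the identity alignment is one admissible path, so it upper-bounds DTW
  A <- unclass(a); B <- unclass(b)
  ident_cost <- sum(sqrt(rowSums((A - B)^2)))
  expect_lte(dtw_distance(a, b), ident_cost + 1e-9)
  expect_gte(dtw_distance(a, b), 0)
})

test_that("Procrustes disparity is similarity-invariant and matches oracles", {
  a <- make_random_loop(6)
  expect_equal(procrustes_distance(a, a), 0, tolerance = 1e-12)
  # rotate 90 degrees, scale x2, translate: disparity 0
  A <- unclass(a)
  R <- matrix(c(0, 1, -1, 0), 2, 2)
  B <- 2 * A %*% R + matrix(c(5, -3), nrow(A), 2, byrow = TRUE)
  expect_equal(procrustes_distance(a, B), 0, tolerance = 1e-10)

  # small configurations vs the rotation-angle/scale grid-search oracle
  set.seed(23)
  for (rep in 1:5) {
    P <- matrix(rnorm(8), 4, 2)
    Q <- matrix(rnorm(8), 4, 2)
    expect_equal(procrustes_distance(P, Q), procrustes_grid_oracle(P, Q),
                 tolerance = 1e-3)
  }
  expect_error(procrustes_distance(matrix(1, 4, 2), matrix(rnorm(8), 4, 2)),
               "degenerate")
  expect_error(procrustes_distance(matrix(rnorm(6), 3, 2),
                                   matrix(rnorm(8), 4, 2)), "equal point")
})

test_that("Procrustes agrees with an independent implementation", {
  skip_if_not_installed("vegan")
  # proper-rotation case so reflection handling cannot differ
  a <- unclass(make_random_loop(7))
  th <- 0.6
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  b <- 1.3 * a %*% R + 2
  b[, 1] <- b[, 1] + 0.5 * sin(seq_len(nrow(b)) / 50) # mild shape distortion
  ours <- procrustes_distance(a, b)
  ref <- vegan::procrustes(a, b, symmetric = TRUE)$ss
  expect_equal(ours, ref, tolerance = 1e-8)
})

test_that("permutation test honours its p-value contracts", {
  base <- make_random_loop(8)
  loops <- c(replicate(5, base, simplify = FALSE),
             replicate(5, base, simplify = FALSE))
  labels <- rep(c("a", "b"), each = 5)
  res <- permutation_test(loops, labels, n_perm = 50, seed = 2,
                          mode = "age_group")
  expect_equal(res$observed$dtw, 0)
  expect_equal(res$p_dtw, 1)
  expect_equal(res$p_combined, 1)

  # combined rule: larger p for age groups, smaller for reproducibility
  l2 <- lapply(1:12, make_participant_loop)
  lab2 <- rep(c("young", "old"), each = 6)
  r_age <- permutation_test(l2, lab2, n_perm = 99, seed = 5, mode = "age_group")
  r_rep <- permutation_test(l2, lab2, n_perm = 99, seed = 5,
                            mode = "reproducibility")
  expect_identical(r_age$p_combined, max(r_age$p_dtw, r_age$p_procrustes))
  expect_identical(r_rep$p_combined, min(r_rep$p_dtw, r_rep$p_procrustes))
  expect_identical(r_age$p_dtw, r_rep$p_dtw) # same seed, same permutations

  # reproducible for a fixed seed
  r2 <- permutation_test(l2, lab2, n_perm = 99, seed = 5, mode = "age_group")
  expect_identical(r_age$p_dtw, r2$p_dtw)
  expect_identical(r_age$p_procrustes, r2$p_procrustes)

  expect_error(permutation_test(l2, rep(c("a", "b", "c"), each = 4),
                                n_perm = 10), "two groups")
})

test_that("permutation p falls with effect size on two-group designs", {
  # same-population groups vs strongly separated groups
  null_loops <- lapply(1:12, function(i) make_participant_loop(i + 100))
  lab <- rep(c("g1", "g2"), each = 6)
  p_null <- permutation_test(null_loops, lab, n_perm = 99, seed = 3)$p_dtw

  shifted <- null_loops
  for (i in 7:12) {
    m <- unclass(shifted[[i]])
    m[, 2] <- m[, 2] * 1.6 + 30 # much higher pressure in group 2
    shifted[[i]] <- m
  }
  p_eff <- permutation_test(shifted, lab, n_perm = 99, seed = 3)$p_dtw
  expect_lte(p_eff, p_null)
  expect_lte(p_eff, 0.05)
})
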