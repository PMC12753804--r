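test_that("k-means microstates: exhaustively checkable 1D case and determinism", {
  Y <- matrix(c(0, 0.1, 10, 10.1), ncol = 1)
  km <- kmeans_cluster(Y, k = 2, seed = 1)
  expect_setequal(round(sort(km$centers[, 1]), 6), c(0.05, 10.05))
  expect_equal(km$labels[1], km$labels[2])
  expect_false(km$labels[1] == km$labels[3])
  # k = n: zero within-cluster variance
  km2 <- kmeans_cluster(Y, k = 4, seed = 2)
  expect_equal(sort(km2$centers[, 1]), sort(Y[, 1]), ignore_attr = TRUE)
  # same seed, same labels
  set.seed(99)
  Yr <- matrix(rnorm(600), ncol = 2)
  expect_identical(kmeans_cluster(Yr, 5, seed = 3)$labels,
                   kmeans_cluster(Yr, 5, seed = 3)$labels)
  expect_error(kmeans_cluster(Yr, 1000, seed = 1), "fewer frames")
})

test_that("count matrices are sliding-window, per-trajectory and validated", {
  expect_equal(count_matrix(c(1L, 2L, 1L, 2L), tau = 1),
               matrix(c(0, 1, 2, 0), 2))
  expect_error(count_matrix(c(1L, 2L), tau = 2), "not longer")
  expect_error(count_matrix(c(1L, 2L, 1L), tau = 0), "positive")
  a <- c(1L, 1L, 2L); b <- c(2L, 1L, 1L)
  expect_equal(count_matrix(list(a, b), tau = 1),
               count_matrix(a, 1, k = 2) + count_matrix(b, 1, k = 2))
})

test_that("reversible MLE hits the closed form and detailed balance", {
  C <- matrix(c(90, 10, 10, 90), 2)
  m <- estimate_reversible_T(C)
  expect_equal(m$T, matrix(c(0.9, 0.1, 0.1, 0.9), 2), tolerance = 1e-9)
  expect_equal(m$pi, c(0.5, 0.5), tolerance = 1e-9)
  # random counts: output satisfies detailed balance to 1e-8
  set.seed(11)
  Cr <- matrix(rpois(36, 20), 6)
  mr <- estimate_reversible_T(Cr)
  flux <- mr$pi * mr$T
  expect_lt(max(abs(flux - t(flux))), 1e-8)
  expect_equal(rowSums(mr$T), rep(1, 6), tolerance = 1e-12)
  # disconnected blocks: trimmed to the larger one with a warning
  Cd <- matrix(0, 5, 5)
  Cd[1:3, 1:3] <- 5; Cd[4:5, 4:5] <- 5
  expect_warning(md <- estimate_reversible_T(Cd), "trimming")
  expect_equal(md$active, 1:3)
})

test_that("implied timescales follow the closed form and scale with dt", {
  T <- matrix(c(0.95, 0.05, 0.05, 0.95), 2)
  its <- implied_timescales(T, tau = 1, dt_s = 1)
  expect_equal(its$timescale_s[1], -1 / log(0.9), tolerance = 1e-12)
  its2 <- implied_timescales(T, tau = 1, dt_s = 2)
  expect_equal(its2$timescale_s, 2 * its$timescale_s)
  # identity: no decaying mode below 1 - only numerically; a pure identity
  # matrix has all eigenvalues at 1, leaving no reportable timescale
  its3 <- implied_timescales(diag(2), tau = 1, dt_s = 1)
  expect_equal(nrow(its3), 0)
  # negative eigenvalue: undefined timescale reported as NA
  T4 <- matrix(c(0.1, 0.9, 0.9, 0.1), 2)
  its4 <- implied_timescales(T4, tau = 1, dt_s = 1)
  expect_true(is.na(its4$timescale_s[1]))
})

test_that("macrostate-count selection keys on the largest spectral gap", {
  mk <- function(ts) data.frame(eigenvalue = NA, timescale_s = ts)
  expect_identical(select_n_macrostates(mk(c(100, 90, 80, 1, 0.9)), 10), 4L)
  expect_identical(select_n_macrostates(mk(c(5, 5, 5, 5)), 10), 2L)
  expect_identical(select_n_macrostates(mk(c(10, 0.1, 0.09)), 10), 2L)
  # max_m restricts the candidate gaps to the leading timescales
  expect_identical(select_n_macrostates(mk(c(100, 90, 80, 1, 0.9)), 3), 3L)
})

test_that("Chapman-Kolmogorov holds for Markov data and fails for periodic labels", {
  P <- matrix(c(0.95, 0.05, 0.02, 0.98), 2, byrow = TRUE)
  s <- simulate_state_sequence(P, 2e5, seed = 21, start = 1L)
  C <- count_matrix(s, 1)
  m <- estimate_reversible_T(C)
  ck <- ck_test(m, s, tau = 1, multiples = c(1L, 2L, 5L))
  expect_lt(ck$max_abs_deviation[1], 1e-12)   # k = 1 is exact by construction
  expect_lt(max(ck$max_abs_deviation), 0.02)  # sampling-error band
  # deterministic period-3 labels are strongly non-Markovian: the lag-1
  # model predicts T^2 = [[.75,.25],[.5,.5]] but the direct lag-2 estimate
  # reproduces the lag-1 matrix
  sp <- rep(c(1L, 1L, 2L), 700)
  Cp <- count_matrix(sp, 1)
  mp <- estimate_reversible_T(Cp)
  ckp <- ck_test(mp, sp, tau = 1, multiples = c(1L, 2L))
  expect_gt(ckp$max_abs_deviation[2], 0.2)
})

test_that("PCCA+ agrees with brute force on block chains", {
  # 4-state chain with two metastable 2-blocks
  T4 <- matrix(0.005, 4, 4)
  T4[1:2, 1:2] <- 0.495; T4[3:4, 3:4] <- 0.495
  C4 <- round(T4 * 4000)   # symmetric counts consistent with T
  m4 <- estimate_reversible_T(C4)
  mac <- pcca_coarse_grain(m4, 2)
  expect_true(all(rowSums(mac$chi) - 1 < 1e-9))
  expect_true(all(mac$chi >= 0 & mac$chi <= 1 + 1e-12))
  got <- mac$crisp
  expect_identical(got[1], got[2])
  expect_identical(got[3], got[4])
  expect_false(got[1] == got[3])
  # brute-force oracle: over all 2-partitions, the metastability (trace of
  # the pi-weighted coarse matrix) is maximized by {1,2}/{3,4}
  parts <- list(c(1, 1, 1, 2), c(1, 1, 2, 1), c(1, 2, 1, 1), c(2, 1, 1, 1),
                c(1, 1, 2, 2), c(1, 2, 1, 2), c(1, 2, 2, 1))
  metastability <- vapply(parts, function(p) {
    M <- cbind(p == 1, p == 2) * 1
    W <- t(M) %*% (m4$pi * m4$T) %*% M / as.vector(t(M) %*% m4$pi)
    sum(diag(W))
  }, 0)
  expect_identical(parts[[which.max(metastability)]], c(1, 1, 2, 2))
  # m = k: memberships approach an identity permutation
  mac_k <- pcca_coarse_grain(m4, 4)
  expect_true(all(apply(mac_k$chi, 1, max) > 0.9))
  expect_identical(sort(mac_k$crisp), 1:4)
  expect_error(pcca_coarse_grain(m4, 1), "at least 2")
})

test_that("MFPTs solve the first-passage system and match Monte Carlo", {
  # two-state chain: p(1->2) = 0.1 -> MFPT = 10 steps
  P <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, byrow = TRUE)
  C <- round(P * c(10000, 10000))
  m <- estimate_reversible_T(C)
  mac <- pcca_coarse_grain(m, 2)
  kin <- mfpt_and_rates(m, mac, tau = 1, dt_s = 1)
  i1 <- mac$crisp[1]; i2 <- mac$crisp[2]
  expect_equal(kin$mfpt_s[i1, i2], 1 / m$T[1, 2], tolerance = 1e-6)
  expect_equal(diag(kin$mfpt_s), c(0, 0))
  expect_equal(kin$rate_hz[i1, i2], m$T[1, 2], tolerance = 1e-6)
  # 3-state linear chain vs Monte-Carlo first-passage oracle
  P3 <- matrix(c(0.8, 0.2, 0,
                 0.1, 0.8, 0.1,
                 0, 0.3, 0.7), 3, byrow = TRUE)
  m3 <- list(T = P3, pi = helimsm:::stationary_distribution(P3),
             active = 1:3)
  class(m3) <- "helimsm_msm"
  mac3 <- list(crisp = 1:3, m = 3)
  kin3 <- mfpt_and_rates(m3, mac3, tau = 1, dt_s = 1)
  set.seed(33)
  mc <- replicate(4000, {
    s <- 1L; t <- 0L
    while (s != 3L) { s <- sample.int(3, 1, prob = P3[s, ]); t <- t + 1L }
    t
  })
  expect_equal(kin3$mfpt_s[1, 3], mean(mc), tolerance = 0.02)
})

test_that("pathway decomposition finds the maximum-probability path", {
  # two states: both on path, no traps
  mac2 <- list(T_coarse = matrix(c(0.9, 0.1, 0.1, 0.9), 2), m = 2)
  d2 <- decompose_pathway(mac2, 1, 2)
  expect_identical(d2$on_path, c(1L, 2L))
  expect_length(d2$traps, 0)
  # hand-built 5-state graph vs exhaustive enumeration of simple paths
  T5 <- matrix(1e-6, 5, 5)
  T5[1, 2] <- 0.3; T5[2, 3] <- 0.2; T5[3, 5] <- 0.25
  T5[1, 4] <- 0.05; T5[4, 5] <- 0.4
  diag(T5) <- 0; T5 <- T5 / rowSums(T5)
  mac5 <- list(T_coarse = T5, m = 5)
  got <- decompose_pathway(mac5, 1, 5)
  paths <- list(c(1, 2, 3, 5), c(1, 4, 5), c(1, 2, 3, 4, 5),
                c(1, 4, 3, 5), c(1, 2, 4, 5), c(1, 4, 2, 3, 5),
                c(1, 2, 4, 3, 5), c(1, 4, 3, 2, 5), c(1, 3, 5),
                c(1, 2, 5), c(1, 5), c(1, 3, 4, 5), c(1, 3, 2, 4, 5),
                c(1, 2, 3, 4, 5))
  prob <- vapply(paths, function(p)
    prod(T5[cbind(p[-length(p)], p[-1])]), 0)
  expect_identical(got$on_path, as.integer(paths[[which.max(prob)]]))
  expect_setequal(got$traps, setdiff(1:5, got$on_path))
  expect_error(decompose_pathway(mac5, 2, 2), "differ")
})

test_that("estimators are equivariant under microstate relabeling", {
  set.seed(44)
  C <- matrix(rpois(25, 15), 5)
  perm <- sample(5)
  m1 <- estimate_reversible_T(C)
  m2 <- estimate_reversible_T(C[perm, perm])
  expect_equal(sort(implied_timescales(m1, 1, 1)$eigenvalue),
               sort(implied_timescales(m2, 1, 1)$eigenvalue),
               tolerance = 1e-9)
  expect_equal(m1$pi, m2$pi[order(perm)], tolerance = 1e-9)
})
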