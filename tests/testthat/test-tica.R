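test_that("feature specs pair the strided Calpha set and respect include_dna", {
  fx <- xpd_fx()
  spec <- build_feature_spec(fx$topology, stride = 1, include_dna = FALSE)
  n_ca <- sum(fx$topology$atoms$atom_name == "CA" &
              fx$topology$atoms$domain_label != "DNA")
  expect_equal(nrow(spec$pairs), choose(n_ca, 2))
  dna_ids <- fx$topology$atoms$atom_id[fx$topology$atoms$domain_label == "DNA"]
  expect_false(any(spec$pairs %in% dna_ids))
  spec2 <- build_feature_spec(fx$topology, stride = 2, include_dna = FALSE)
  expect_equal(length(spec2$atom_ids), ceiling(n_ca / 2))
  specd <- build_feature_spec(fx$topology, stride = 1, include_dna = TRUE)
  n_p <- sum(fx$topology$atoms$domain_label == "DNA" &
             fx$topology$atoms$atom_name == "P")
  expect_equal(nrow(specd$pairs), choose(n_ca + n_p, 2))
  # no self pairs, unique pairs
  expect_true(all(specd$pairs[, 1] != specd$pairs[, 2]))
  expect_false(anyDuplicated(specd$pairs) > 0)
})

test_that("distance features match direct recomputation", {
  topo <- toy_topology(4)
  f1 <- rbind(c(0, 0, 0), c(3, 4, 0), c(1, 1, 1), c(2, 2, 2))
  f2 <- f1 + 1     # rigid translation: identical distances
  traj <- toy_trajectory(list(f1, f2))
  spec <- structure(list(pairs = rbind(c(1L, 2L), c(3L, 4L)),
                         atom_ids = 1:4), class = "helimsm_feature_spec")
  X <- compute_features(traj, spec)
  expect_equal(X[1, 1], 5)                 # 3-4-5 triangle
  expect_equal(X[1, ], X[2, ])             # constant columns
  set.seed(7)
  f3 <- matrix(rnorm(12), 4, 3)
  X3 <- compute_features(toy_trajectory(list(f3)), spec)
  expect_equal(X3[1, 2], sqrt(sum((f3[3, ] - f3[4, ])^2)))
  bad <- structure(list(pairs = rbind(c(1L, 9L)), atom_ids = c(1L, 9L)),
                   class = "helimsm_feature_spec")
  expect_error(compute_features(traj, bad), "out of range")
})

test_that("TICA recovers autocorrelations and the slow direction", {
  mix <- ar1_mixture(60000)
  mod <- fit_tica(mix$X, lag = 1, n_components = 2)
  expect_equal(mod$eigenvalues[1], 0.9, tolerance = 0.05)
  expect_equal(mod$eigenvalues[2], 0.5, tolerance = 0.08)
  # IC1 aligned with the slow latent signal
  Y <- tica_project(mod, mix$X)
  expect_gt(abs(cor(Y[, 1], mix$Z[, 1])), 0.98)
  # training projections have unit variance
  expect_equal(apply(Y, 2, var), c(1, 1), tolerance = 1e-2)
})

test_that("white noise has no slow components", {
  set.seed(2)
  X <- matrix(rnorm(20000 * 4), ncol = 4)
  mod <- fit_tica(X, lag = 1, n_components = 4)
  expect_lt(max(abs(mod$eigenvalues)), 0.05)
})

test_that("duplicated feature columns are handled by regularization", {
  mix <- ar1_mixture(20000, seed = 3)
  Xd <- cbind(mix$X, mix$X[, 1])
  expect_no_error(mod <- fit_tica(Xd, lag = 1, n_components = 2))
  mod0 <- fit_tica(mix$X, lag = 1, n_components = 2)
  expect_equal(mod$eigenvalues, mod0$eigenvalues, tolerance = 1e-3)
})

test_that("the symmetrized estimator is invariant to time reversal and bounded", {
  mix <- ar1_mixture(30000, seed = 5)
  mod_f <- fit_tica(mix$X, lag = 2, n_components = 3)
  mod_r <- fit_tica(mix$X[rev(seq_len(nrow(mix$X))), ], lag = 2,
                    n_components = 3)
  expect_equal(mod_f$eigenvalues, mod_r$eigenvalues, tolerance = 1e-10)
  expect_true(all(abs(mod_f$eigenvalues) <= 1 + 1e-6))
  # reversible fixture chains: eigenvalues within [-1, 1] too
  f <- xpd_fx()$fixture
  lab <- simulate_state_sequence(f, 4000, seed = 8)
  tr <- emit_trajectory(lab, f, sigma = 0.2, seed = 8)
  spec <- build_feature_spec(xpd_fx()$topology, stride = 10)
  X <- compute_features(tr, spec)
  m <- fit_tica(X, lag = 5, n_components = 10)
  expect_true(all(abs(m$eigenvalues) <= 1 + 1e-6))
})

test_that("projection agrees with the explicit matrix product", {
  mix <- ar1_mixture(5000, seed = 9)
  mod <- fit_tica(mix$X, lag = 1, n_components = 2)
  Y <- tica_project(mod, mix$X)
  Yo <- sweep(mix$X[, mod$kept, drop = FALSE], 2, mod$mean_kept) %*%
    mod$components[mod$kept, , drop = FALSE]
  expect_equal(Y, Yo)
  # constant trajectory projects to zero... relative to its own mean
  const <- matrix(5, 10, 3)
  Yc <- tica_project(mod, const)
  expect_equal(Yc, matrix(Yc[1, ], 10, 2, byrow = TRUE))
})

test_that("slow-mode recovery: IC1 separates a 2-state mixture better than any feature", {
  P <- matrix(c(0.99, 0.01, 0.01, 0.99), 2, byrow = TRUE)
  s <- simulate_state_sequence(P, 20000, seed = 3, start = 1L)
  mu <- rbind(c(0, 0, 0), c(1.2, -0.8, 0.5))
  set.seed(4)
  X <- mu[s, ] + matrix(rnorm(20000 * 3), ncol = 3)
  mod <- fit_tica(X, lag = 5, n_components = 2)
  Y <- tica_project(mod, X)
  sep <- function(v) {
    abs(mean(v[s == 1]) - mean(v[s == 2])) /
      sqrt(0.5 * (var(v[s == 1]) + var(v[s == 2])))
  }
  expect_gt(sep(Y[, 1]), max(apply(X, 2, sep)))
})

test_that("free-energy surfaces are Boltzmann inversions with zero minimum", {
  # all samples in one tight cluster: one occupied bin at F = 0
  Y1 <- matrix(rep(c(0.5, 0.5), each = 100), ncol = 2)
  fes1 <- free_energy_surface(Y1, kT = 0.6, bins = 10)
  occ <- which(!is.na(fes1$F))
  expect_equal(fes1$F[occ], 0)
  # two uniform blocks with weights 3:1 -> per-bin dF = kT ln 3
  set.seed(6)
  n1 <- 90000; n2 <- 30000
  Y2 <- rbind(cbind(runif(n1, -2, -1), runif(n1, 0, 1)),
              cbind(runif(n2, 1, 2), runif(n2, 0, 1)))
  fes2 <- free_energy_surface(Y2, kT = 0.6, bins = 20)
  f_min <- min(fes2$F, na.rm = TRUE)
  expect_equal(f_min, 0)
  # typical (median) bin of the light block vs the heavy block
  right <- fes2$F[fes2$x_edges[-length(fes2$x_edges)] > 0.99, ]
  left <- fes2$F[fes2$x_edges[-length(fes2$x_edges)] < -1.01, ]
  dF <- median(right, na.rm = TRUE) - median(left, na.rm = TRUE)
  expect_equal(dF, 0.6 * log(3), tolerance = 0.1)
  # doubling all counts leaves F unchanged
  fes3 <- free_energy_surface(rbind(Y2, Y2), kT = 0.6, bins = 20)
  expect_equal(fes3$F, fes2$F, tolerance = 1e-12)
  expect_error(free_energy_surface(Y2[0, , drop = FALSE]), "no frames")
})
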