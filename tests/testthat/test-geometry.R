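rotation_from_angles <- function(a) {
  Rx <- matrix(c(1, 0, 0, 0, cos(a[1]), -sin(a[1]), 0, sin(a[1]), cos(a[1])), 3,
               byrow = TRUE)
  Ry <- matrix(c(cos(a[2]), 0, sin(a[2]), 0, 1, 0, -sin(a[2]), 0, cos(a[2])), 3,
               byrow = TRUE)
  Rz <- matrix(c(cos(a[3]), -sin(a[3]), 0, sin(a[3]), cos(a[3]), 0, 0, 0, 1), 3,
               byrow = TRUE)
  Rx %*% Ry %*% Rz
}

three_domain_topo <- function() {
  atoms <- data.frame(
    atom_id = 1:3, atom_name = "CA", element = "C", residue_name = "ALA",
    residue_number = 1:3, chain_id = "P",
    domain_label = c("FeS", "RecA1", "Arch"),
    hbond_donor = FALSE, hbond_acceptor = FALSE, charge_class = "neutral",
    aromatic_ring_id = NA_character_, nonpolar = FALSE, mass = 1,
    stringsAsFactors = FALSE)
  new_topology(atoms)
}

test_that("domain geometry: right angles, collinearity and COM means", {
  topo <- three_domain_topo()
  g <- domain_geometry(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)), topo)
  expect_equal(g$theta, 90)
  expect_equal(g$d_arch_fes, sqrt(2))
  g2 <- domain_geometry(rbind(c(-1, 0, 0), c(0, 0, 0), c(2, 0, 0)), topo)
  expect_equal(g2$theta, 180)
  # unit masses: COM is the arithmetic mean
  topo2 <- three_domain_topo()
  topo2$atoms$domain_label <- c("FeS", "FeS", "RecA1")
  topo2$atoms$mass <- 1
  fr <- rbind(c(0, 0, 0), c(2, 0, 0), c(5, 5, 5))
  expect_equal(helimsm:::domain_com(fr, topo2, "FeS"), c(1, 0, 0))
  # invariance under rigid rotation + translation
  fx <- xpd_fx()
  X <- fx$fixture$templates$S1
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3)
  X2 <- sweep(X %*% R, 2, c(5, -3, 11), "+")
  g1 <- domain_geometry(X, fx$topology)
  g2 <- domain_geometry(X2, fx$topology)
  expect_equal(g1$theta, g2$theta, tolerance = 1e-9)
  expect_equal(g1$d_arch_fes, g2$d_arch_fes, tolerance = 1e-9)
})

test_that("constriction width reduces to wall separation and is symmetric", {
  # two flat parallel walls, 6.1 A apart, 3 matched atoms per wall
  atoms <- data.frame(
    atom_id = 1:6, atom_name = "SC", element = "C", residue_name = "ALA",
    residue_number = 1:6, chain_id = "P", domain_label = "other",
    hbond_donor = FALSE, hbond_acceptor = FALSE, charge_class = "neutral",
    aromatic_ring_id = NA_character_, nonpolar = FALSE, mass = 12,
    stringsAsFactors = FALSE)
  topo <- new_topology(atoms)
  fr <- rbind(c(0, 0, 0), c(4, 0, 0), c(8, 0, 0),
              c(0, 6.1, 0), c(4, 6.1, 0), c(8, 6.1, 0))
  defn <- list(wall_a = 1:3, wall_b = 4:6)
  expect_equal(constriction_width(fr, defn, topo), 6.1)
  # symmetry under wall exchange
  expect_equal(constriction_width(fr, list(wall_a = 4:6, wall_b = 1:3), topo),
               6.1)
  # single-atom walls 5 A apart
  defn1 <- list(wall_a = 1, wall_b = 4)
  fr1 <- fr; fr1[4, ] <- c(0, 5, 0)
  expect_equal(constriction_width(fr1, defn1, topo), 5)
  expect_error(constriction_width(fr, list(wall_a = integer(0), wall_b = 1),
                                  topo), "empty")
  # noisy fixture frames: per-state mean within 3 standard errors
  fx <- xpd_fx()
  f <- fx$fixture
  tr <- emit_trajectory(rep("S1", 300), f, sigma = 0.2, seed = 31)
  w <- vapply(1:300, function(i)
    constriction_width(get_frame(tr, i), f$constrictions$c2, fx$topology), 0)
  expect_lt(abs(mean(w) - 6.1), 3 * sd(w) / sqrt(300) + 0.02)
})

test_that("macrostate centroids minimize mean pairwise RMSD", {
  fx <- xpd_fx()
  f <- fx$fixture
  # identical frames: any member, RMSD 0
  tr0 <- emit_trajectory(rep("S1", 4), f, sigma = 0, seed = 1)
  c0 <- macrostate_centroid(tr0, rep("S1", 4), "S1", fx$topology)
  expect_equal(c0$coordinates, f$templates$S1)
  # 3 frames with pairwise distances (small, small, large): the hub frame
  # wins; the perturbation moves only half the Calpha set so that the
  # superposition cannot absorb it
  base <- f$templates$S1
  ca <- which(fx$topology$atoms$atom_name == "CA")
  half <- ca[seq(1, length(ca), by = 2)]
  f1 <- base
  f2 <- base; f2[half, 1] <- f2[half, 1] + 1     # ~0.5 A RMSD from hub
  f3 <- base; f3[half, 1] <- f3[half, 1] - 1     # mirror image: far from f2
  tr3 <- toy_trajectory(list(f2, f1, f3))
  c3 <- macrostate_centroid(tr3, rep("A", 3), "A", fx$topology)
  expect_identical(c3$frame_index, 2L)
  # seeded subsampling is reproducible
  trn <- emit_trajectory(rep("S1", 30), f, sigma = 0.3, seed = 5)
  a <- macrostate_centroid(trn, rep("S1", 30), "S1", fx$topology,
                           max_members = 10, seed = 7)
  b <- macrostate_centroid(trn, rep("S1", 30), "S1", fx$topology,
                           max_members = 10, seed = 7)
  expect_identical(a$frame_index, b$frame_index)
  expect_error(macrostate_centroid(trn, rep("S1", 30), "S9", fx$topology),
               "no frames")
})

test_that("displacement fields vanish under rigid motion and localize translations", {
  fx <- xpd_fx()
  X <- fx$fixture$templates$S1
  d0 <- displacement_field(X, X, fx$topology)
  expect_equal(max(abs(as.matrix(d0[, c("dx", "dy", "dz")]))), 0)
  # pure rigid rotation/translation is absorbed by the superposition
  th <- 0.4
  R <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3)
  Xr <- sweep(X %*% R, 2, c(3, 3, 3), "+")
  dr <- displacement_field(X, Xr, fx$topology)
  expect_lt(max(abs(as.matrix(dr[, c("dx", "dy", "dz")]))), 1e-8)
  # translating one domain: its mean vector equals the translation minus
  # the global-fit residual, matching an explicit least-squares oracle
  shift <- c(2, 0, 0)
  Xs <- X
  arch <- fx$topology$atoms$domain_label == "Arch"
  Xs[arch, ] <- sweep(Xs[arch, ], 2, shift, "+")
  ds <- displacement_field(X, Xs, fx$topology)
  # oracle: optimal rigid fit by direct minimization over rotations
  ca_idx <- which(fx$topology$atoms$atom_name == "CA")
  A <- X[ca_idx, ]; B <- Xs[ca_idx, ]
  obj <- function(p) {
    Rx <- rotation_from_angles(p[1:3])
    sum((sweep(B %*% Rx, 2, p[4:6], "+") - A)^2)
  }
  opt <- optim(rep(0, 6), obj, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))
  Bf <- sweep(B %*% rotation_from_angles(opt$par[1:3]), 2, opt$par[4:6], "+")
  oracle <- Bf - A
  got <- as.matrix(ds[, c("dx", "dy", "dz")])
  expect_equal(got, oracle, tolerance = 1e-4, ignore_attr = TRUE)
  # the Arch rows carry the translation (minus the part absorbed by the
  # global fit); other domains move only by the fit residual
  arch_rows <- ds$domain == "Arch"
  expect_gt(mean(got[arch_rows, 1]), 1.2)
  expect_lt(max(abs(colMeans(got[!arch_rows, , drop = FALSE]))), 0.8)
  expect_error(displacement_field(X[-1, ], X, fx$topology), "mismatch")
})

test_that("the DNA register detector counts nucleotide advances", {
  fx <- xpd_fx()
  f <- fx$fixture
  lm <- c(f$constrictions$c1$wall_a, f$constrictions$c2$wall_b)
  X <- f$templates$S1
  expect_identical(dna_register_offset(X, X, fx$topology, lm), 0L)
  # constructed 2-nucleotide advance: DNA shifted two lattice sites forward
  dna <- fx$topology$atoms$domain_label == "DNA"
  Y2 <- X
  Y2[dna, 1] <- Y2[dna, 1] + 2 * 6.5
  expect_identical(dna_register_offset(X, Y2, fx$topology, lm), 2L)
  # degenerate strand (all nucleotides collapsed): ambiguous, error
  Yd <- X
  Yd[dna, ] <- matrix(rep(c(1, 2, 3), each = sum(dna)), ncol = 3)
  expect_error(dna_register_offset(Yd, Yd, fx$topology, lm), "ambiguous")
})
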