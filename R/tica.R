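# Distance featurization, time-lagged independent component analysis, and
# 2D free-energy surfaces.
#
# Features are Euclidean distances between Calpha atoms (protein) and P
# atoms (ssDNA). TICA solves the generalized eigenproblem C_tau v =
# lambda C_0 v with a symmetrized lagged covariance, which keeps the
# eigenvalues real and in [-1, 1] up to numerical tolerance.

#' Build a distance feature specification
#'
#' All unique pairs among every `stride`-th Calpha atom, plus (when
#' `include_dna`) the DNA P atoms and their pairs with the Calpha set.
#' Excluding the DNA restricts the projection to the protein conformational
#' space, in which the two apo registers of the translocation cycle overlap.
#'
#' @param topology `helimsm_topology`
#' @param stride keep every stride-th Calpha (default 1)
#' @param include_dna include P atoms and protein-DNA pairs
#' @return object of class `helimsm_feature_spec` (fields `pairs`, an m x 2
#'   matrix of atom ids, and `atom_ids`)
#' @export
build_feature_spec <- function(topology, stride = 1L, include_dna = TRUE) {
  a <- topology$atoms
  ca <- a$atom_id[a$atom_name == "CA" & a$domain_label != "DNA"]
  if (length(ca) == 0) stop("no Calpha atoms in topology")
  ca <- ca[seq(1L, length(ca), by = stride)]
  ids <- ca
  if (include_dna) {
    p <- a$atom_id[a$domain_label == "DNA" & a$atom_name == "P"]
    ids <- c(ca, p)
  }
  if (length(ids) < 2) stop("need at least two feature atoms")
  pairs <- t(utils::combn(ids, 2))
  structure(list(pairs = pairs, atom_ids = ids, stride = stride,
                 include_dna = include_dna),
            class = "helimsm_feature_spec")
}

#' Compute the distance feature matrix of a trajectory
#'
#' @param traj `helimsm_trajectory`
#' @param spec `helimsm_feature_spec`
#' @return frames x features matrix of distances (Angstrom)
#' @export
compute_features <- function(traj, spec) {
  co <- traj$coordinates
  if (max(spec$pairs) > dim(co)[2]) stop("feature atom id out of range")
  m <- nrow(spec$pairs)
  X <- matrix(0, dim(co)[1], m)
  for (p in seq_len(m)) {
    i <- spec$pairs[p, 1]; j <- spec$pairs[p, 2]
    X[, p] <- sqrt((co[, i, 1] - co[, j, 1])^2 +
                   (co[, i, 2] - co[, j, 2])^2 +
                   (co[, i, 3] - co[, j, 3])^2)
  }
  X
}

# accumulate instantaneous and lagged second moments over trajectory chunks
tica_moments <- function(chunks, lag) {
  d <- ncol(chunks[[1]])
  s0 <- numeric(d); n0 <- 0
  C0 <- matrix(0, d, d); Ct <- matrix(0, d, d)
  for (X in chunks) {
    n <- nrow(X)
    if (n <= lag + 1) stop("chunk shorter than lag + 1")
    s0 <- s0 + colSums(X); n0 <- n0 + n
  }
  mu <- s0 / n0
  npairs <- 0
  for (X in chunks) {
    Xc <- sweep(X, 2, mu)
    n <- nrow(X)
    A <- Xc[1:(n - lag), , drop = FALSE]
    B <- Xc[(1 + lag):n, , drop = FALSE]
    C0 <- C0 + crossprod(A) + crossprod(B)
    Ct <- Ct + crossprod(A, B)
    npairs <- npairs + (n - lag)
  }
  list(mean = mu, C0 = C0 / (2 * npairs),
       Ct = (Ct + t(Ct)) / (2 * npairs))
}

#' Fit a time-lagged independent component model
#'
#' Mean-free features; C0 is the instantaneous covariance (averaged over
#' both ends of each lagged pair), C_tau the symmetrized lagged covariance
#' 0.5 (C(tau) + C(tau)^T). Solves C_tau v = lambda C0 v by whitening with
#' the regularized eigendecomposition of C0; components are scaled so the
#' training projections have unit variance. Zero-variance features are
#' dropped (with a message); near-singular C0 is regularized with
#' eps = 1e-10 trace(C0)/dim.
#'
#' @param X frames x features matrix, or a list of such matrices (one per
#'   trajectory; no lagged pairs cross trajectory boundaries)
#' @param lag lag time in frames
#' @param n_components number of components kept (default 10)
#' @return object of class `helimsm_tica` with fields `eigenvalues`,
#'   `components` (features x n), `mean`, `lag`, `norms`
#' @export
fit_tica <- function(X, lag, n_components = 10L) {
  chunks <- if (is.list(X)) X else list(X)
  if (any(vapply(chunks, nrow, 0L) <= lag + 1))
    stop("need frames > lag + 1")
  d <- ncol(chunks[[1]])
  # drop zero-variance columns before estimating
  v <- Reduce(`+`, lapply(chunks, function(x)
    colSums(sweep(x, 2, colMeans(x))^2)))
  keep <- which(v > 1e-12)
  if (length(keep) < d)
    message(sprintf("dropping %d zero-variance feature(s)", d - length(keep)))
  chunks <- lapply(chunks, function(x) x[, keep, drop = FALSE])
  mom <- tica_moments(chunks, lag)
  C0 <- mom$C0
  eps <- 1e-10 * sum(diag(C0)) / ncol(C0)
  e0 <- eigen(C0 + diag(eps, ncol(C0)), symmetric = TRUE)
  pos <- e0$values > max(e0$values) * 1e-10
  W <- e0$vectors[, pos, drop = FALSE] %*%
    diag(1 / sqrt(e0$values[pos]), sum(pos))
  M <- t(W) %*% mom$Ct %*% W
  M <- (M + t(M)) / 2
  es <- eigen(M, symmetric = TRUE)
  n_components <- min(n_components, ncol(M))
  ord <- order(es$values, decreasing = TRUE)[seq_len(n_components)]
  lambda <- es$values[ord]
  V <- W %*% es$vectors[, ord, drop = FALSE]   # generalized eigenvectors
  # unit-variance scaling of the training projections: var = v' C0 v = 1
  # already ensured by whitening (v = W u with |u| = 1), up to eps
  comp <- matrix(0, d, n_components)
  comp[keep, ] <- V
  structure(list(eigenvalues = lambda, components = comp, mean_kept = mom$mean,
                 kept = keep, lag = lag, n_components = n_components),
            class = "helimsm_tica")
}

#' @export
print.helimsm_tica <- function(x, ...) {
  cat(sprintf("TICA model: lag %d, %d components; eigenvalues: %s\n",
              x$lag, x$n_components,
              paste(sprintf("%.3f", head(x$eigenvalues, 5)), collapse = " ")))
  invisible(x)
}

#' Project features onto the independent components
#'
#' @param model `helimsm_tica`
#' @param X frames x features matrix (same feature set as used in fitting)
#' @return frames x n_components projection matrix
#' @export
tica_project <- function(model, X) {
  if (ncol(X) != nrow(model$components))
    stop("feature dimension mismatch")
  Xk <- sweep(X[, model$kept, drop = FALSE], 2, model$mean_kept)
  Xk %*% model$components[model$kept, , drop = FALSE]
}

#' 2D free-energy surface over the first two independent components
#'
#' Bins the (IC1, IC2) projections, converts bin probabilities to free
#' energies F = -kT ln(p / p_max), so the most occupied bin has F = 0 and
#' unoccupied bins are NA.
#'
#' @param Y projection matrix (first two columns are used)
#' @param kT thermal energy in kcal/mol (0.596 at 300 K)
#' @param bins number of bins per axis
#' @return list with `F` (bins x bins, kcal/mol, NA where unoccupied),
#'   `x_edges`, `y_edges`, `kT`
#' @export
free_energy_surface <- function(Y, kT = 0.596, bins = 60L) {
  if (nrow(Y) < 1) stop("no frames")
  y1 <- Y[, 1]; y2 <- Y[, 2]
  xe <- seq(min(y1), max(y1), length.out = bins + 1)
  ye <- seq(min(y2), max(y2), length.out = bins + 1)
  ix <- pmin(pmax(findInterval(y1, xe, all.inside = TRUE), 1L), bins)
  iy <- pmin(pmax(findInterval(y2, ye, all.inside = TRUE), 1L), bins)
  H <- matrix(0, bins, bins)
  for (t in seq_along(ix)) H[ix[t], iy[t]] <- H[ix[t], iy[t]] + 1
  Fmat <- matrix(NA_real_, bins, bins)
  occ <- H > 0
  Fmat[occ] <- -kT * log(H[occ] / max(H))
  list(F = Fmat, x_edges = xe, y_edges = ye, kT = kT)
}

#' Write a free-energy surface as a plain-text matrix with bin-edge header
#' @param fes result of [free_energy_surface()]
#' @param path output file
#' @export
write_fes <- function(fes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("# kT", fes$kT),
               paste("# x_edges", paste(signif(fes$x_edges, 8), collapse = " ")),
               paste("# y_edges", paste(signif(fes$y_edges, 8), collapse = " "))),
             con)
  utils::write.table(fes$F, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
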