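# Markov state model construction and validation: microstate clustering,
# reversible maximum-likelihood transition matrices, implied timescales,
# Chapman-Kolmogorov validation, PCCA+ macrostates, mean first-passage
# times, and the pathway-versus-trap decomposition.

#' k-means microstate clustering with k-means++ initialization
#'
#' @param Y frames x d projection matrix
#' @param k number of microstates
#' @param seed RNG seed (initialization and Lloyd iterations are then
#'   deterministic)
#' @param iter_max Lloyd iteration cap
#' @return object of class `helimsm_microstates` with `centers`, `labels`
#' @export
kmeans_cluster <- function(Y, k, seed, iter_max = 100L) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  if (n < k) stop("fewer frames than requested microstates")
  set.seed(seed)
  # k-means++ seeding
  centers <- matrix(0, k, ncol(Y))
  i1 <- sample.int(n, 1)
  centers[1, ] <- Y[i1, ]
  d2 <- rowSums(sweep(Y, 2, centers[1, ])^2)
  if (k > 1) {
    for (j in 2:k) {
      probs <- d2 / sum(d2)
      ij <- if (all(d2 == 0)) sample.int(n, 1) else sample.int(n, 1, prob = probs)
      centers[j, ] <- Y[ij, ]
      d2 <- pmin(d2, rowSums(sweep(Y, 2, centers[j, ])^2))
    }
  }
  km <- suppressWarnings(
    kmeans(Y, centers = centers, iter.max = iter_max, algorithm = "Lloyd"))
  structure(list(centers = km$centers, labels = km$cluster, k = k,
                 seed = seed),
            class = "helimsm_microstates")
}

#' Assign frames to the nearest microstate center
#' @param model `helimsm_microstates`
#' @param Y frames x d matrix
#' @return integer labels
#' @export
assign_microstates <- function(model, Y) {
  Y <- as.matrix(Y)
  cs <- rowSums(model$centers^2)
  d2 <- outer(rowSums(Y^2), cs, "+") - 2 * Y %*% t(model$centers)
  max.col(-d2, ties.method = "first")
}

#' Transition count matrix at a lag
#'
#' Sliding-window counts; multiple trajectories are counted independently so
#' no pair crosses a trajectory boundary.
#'
#' @param labels integer label vector or list of vectors (one per trajectory)
#' @param tau lag in frames (> 0)
#' @param k number of states (defaults to max label)
#' @return k x k count matrix
#' @export
count_matrix <- function(labels, tau, k = NULL) {
  if (tau <= 0) stop("tau must be positive")
  seqs <- if (is.list(labels)) labels else list(labels)
  if (any(vapply(seqs, length, 0L) <= tau))
    stop("label sequence not longer than the lag")
  if (is.null(k)) k <- max(vapply(seqs, max, 0L))
  C <- matrix(0, k, k)
  for (s in seqs) C <- C + count_pairs_cpp(as.integer(s), as.integer(k),
                                           as.integer(tau))
  C
}

# largest connected component of the symmetrized count graph
largest_component <- function(C) {
  k <- nrow(C)
  A <- (C + t(C)) > 0
  diag(A) <- TRUE
  comp <- integer(k); cur <- 0L
  for (s in seq_len(k)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s; comp[s] <- cur
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(A[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  sizes <- tabulate(comp)
  which(comp == which.max(sizes))
}

#' Reversible maximum-likelihood transition matrix
#'
#' Restricts the counts to their largest connected component (ergodic
#' trimming, reported via a warning when states are dropped), then runs the
#' standard fixed-point iteration for the detailed-balance-constrained MLE:
#' x_ij <- (c_ij + c_ji) / (c_i/x_i + c_j/x_j), normalized, until the
#' largest entry change is below `tol`. The stationary distribution is the
#' row sum of x.
#'
#' @param C count matrix
#' @param tol fixed-point tolerance (default 1e-10)
#' @param max_iter iteration cap
#' @return object of class `helimsm_msm`: `T` (row-stochastic), `pi`,
#'   `active` (indices into the original state set), `C`
#' @export
estimate_reversible_T <- function(C, tol = 1e-10, max_iter = 10000L) {
  keep <- largest_component(C)
  if (length(keep) < nrow(C))
    warning(sprintf("ergodic trimming: %d of %d states kept",
                    length(keep), nrow(C)))
  C2 <- C[keep, keep, drop = FALSE]
  if (sum(C2) == 0) stop("empty count matrix after trimming")
  k <- nrow(C2)
  csym <- C2 + t(C2)
  ci <- rowSums(C2)
  x <- csym / sum(csym)
  for (it in seq_len(max_iter)) {
    xs <- rowSums(x)
    denom <- outer(ci / xs, ci / xs, "+")
    xn <- ifelse(csym > 0, csym / denom, 0)
    xn <- xn / sum(xn)
    delta <- max(abs(xn - x))
    x <- xn
    if (delta < tol) break
  }
  pi0 <- rowSums(x)
  T <- x / pi0
  structure(list(T = T, pi = pi0, active = keep, C = C2, reversible = TRUE),
            class = "helimsm_msm")
}

#' @export
print.helimsm_msm <- function(x, ...) {
  cat(sprintf("reversible MSM: %d states, max detailed-balance violation %.2e\n",
              nrow(x$T), max(abs(x$pi * x$T - t(x$pi * x$T)))))
  invisible(x)
}

#' Implied timescales of a transition matrix
#'
#' t_i = -(tau dt) / ln(lambda_i) for the real eigenvalues in (0, 1); the
#' stationary eigenvalue is excluded; negative or complex eigenvalues have
#' no defined timescale and are reported as NA.
#'
#' @param msm `helimsm_msm` (or bare transition matrix)
#' @param tau lag in frames used to estimate the matrix
#' @param dt_s physical time per frame in seconds
#' @param n number of timescales (default all)
#' @return data.frame with `eigenvalue`, `timescale_s` (sorted by timescale,
#'   longest first)
#' @export
implied_timescales <- function(msm, tau, dt_s, n = NULL) {
  T <- if (inherits(msm, "helimsm_msm")) msm$T else msm
  ev <- eigen(T, only.values = TRUE)$values
  re <- Re(ev)[abs(Im(ev)) < 1e-8]
  re <- sort(re, decreasing = TRUE)
  re <- re[re < 1 - 1e-12]          # exclude the stationary mode
  if (!is.null(n)) re <- head(re, n)
  ts <- rep(NA_real_, length(re))
  ts[re > 0] <- -(tau * dt_s) / log(re[re > 0])
  data.frame(eigenvalue = re, timescale_s = ts)
}

#' Select the macrostate count from the implied-timescale spectrum
#'
#' m = 1 + index of the largest ratio t_i / t_(i+1) among the leading
#' `max_m` timescales; ties resolve to the smallest index. Undefined (NA)
#' timescales act as a floor equal to the lag time.
#'
#' @param its data.frame from [implied_timescales()]
#' @param max_m largest m considered
#' @param floor_s value substituted for undefined timescales (e.g. the lag)
#' @return integer macrostate count
#' @export
select_n_macrostates <- function(its, max_m, floor_s = NULL) {
  ts <- its$timescale_s
  if (is.null(floor_s))
    floor_s <- min(ts[!is.na(ts)], na.rm = TRUE) / 10
  ts[is.na(ts)] <- floor_s
  ts <- head(ts, max_m)
  if (length(ts) < 2) stop("need at least two timescales")
  ratios <- ts[-length(ts)] / ts[-1]
  as.integer(which.max(ratios) + 1L)
}

#' Chapman-Kolmogorov test
#'
#' Compares T(k tau) estimated directly from the data against T(tau)^k,
#' aggregated over macrostates when a membership is supplied. Reports the
#' maximum absolute deviation per multiple.
#'
#' @param msm `helimsm_msm` estimated at lag `tau`
#' @param labels label sequence(s) used for estimation
#' @param tau base lag (frames)
#' @param multiples integer multiples of tau to test
#' @param memberships optional k x m crisp membership (columns of 0/1); by
#'   default microstates are compared directly
#' @return data.frame with `multiple`, `max_abs_deviation`
#' @export
ck_test <- function(msm, labels, tau, multiples = c(1L, 2L, 4L),
                    memberships = NULL) {
  k_full <- if (is.list(labels)) max(vapply(labels, max, 0L)) else max(labels)
  agg <- function(T, pi0) {
    if (is.null(memberships)) return(T)
    M <- memberships
    W <- t(M) %*% (pi0 * T) %*% M
    sw <- as.vector(t(M) %*% pi0)
    W / sw
  }
  out <- lapply(multiples, function(kk) {
    Ck <- count_matrix(labels, tau * kk, k = k_full)
    mk <- estimate_reversible_T(Ck)
    # align on common active sets
    common <- intersect(msm$active, mk$active)
    i1 <- match(common, msm$active); i2 <- match(common, mk$active)
    Tk_pred <- matpow(msm$T, kk)[i1, i1, drop = FALSE]
    Tk_pred <- Tk_pred / rowSums(Tk_pred)
    Tk_est <- mk$T[i2, i2, drop = FALSE]
    Tk_est <- Tk_est / rowSums(Tk_est)
    mm <- if (is.null(memberships)) NULL else memberships[common, , drop = FALSE]
    memberships_local <- mm
    A <- if (is.null(memberships_local)) Tk_pred else {
      pi1 <- msm$pi[i1] / sum(msm$pi[i1])
      t(memberships_local) %*% (pi1 * Tk_pred) %*% memberships_local /
        as.vector(t(memberships_local) %*% pi1)
    }
    B <- if (is.null(memberships_local)) Tk_est else {
      pi2 <- mk$pi[i2] / sum(mk$pi[i2])
      t(memberships_local) %*% (pi2 * Tk_est) %*% memberships_local /
        as.vector(t(memberships_local) %*% pi2)
    }
    data.frame(multiple = kk, max_abs_deviation = max(abs(A - B)))
  })
  do.call(rbind, out)
}

matpow <- function(M, k) {
  R <- diag(nrow(M))
  while (k > 0) {
    if (k %% 2 == 1) R <- R %*% M
    M <- M %*% M
    k <- k %/% 2
  }
  R
}

#' PCCA+ fuzzy coarse-graining into metastable macrostates
#'
#' Inner-simplex PCCA+: the top-m right eigenvectors span a simplex whose
#' vertices are located by successive farthest-point selection; memberships
#' are the barycentric coordinates, clipped to \[0, 1\] and renormalized.
#' The coarse transition matrix is the stationary-weighted projection
#' (chi' diag(pi) T chi) / (chi' diag(pi) chi).
#'
#' @param msm `helimsm_msm` (reversible, irreducible)
#' @param m number of macrostates (>= 2)
#' @return object of class `helimsm_macrostates`: `chi` (k x m), `crisp`
#'   (argmax assignment), `T_coarse`, `pi_coarse`
#' @export
pcca_coarse_grain <- function(msm, m) {
  if (m < 2) stop("m must be at least 2")
  T <- msm$T; pi0 <- msm$pi
  k <- nrow(T)
  if (m > k) stop("more macrostates than microstates")
  # reversible T is self-adjoint under the pi inner product: symmetrize
  S <- diag(sqrt(pi0)) %*% T %*% diag(1 / sqrt(pi0))
  S <- (S + t(S)) / 2
  es <- eigen(S, symmetric = TRUE)
  ord <- order(es$values, decreasing = TRUE)[seq_len(m)]
  if (any(es$values[ord] < -1 - 1e-8)) stop("invalid spectrum")
  psi <- diag(1 / sqrt(pi0)) %*% es$vectors[, ord, drop = FALSE]
  # normalize sign/scale: first column is constant
  psi[, 1] <- 1
  # successive farthest-point vertex search in eigenvector space
  verts <- integer(m)
  d <- rowSums(psi^2)
  verts[1] <- which.max(d)
  shifted <- sweep(psi, 2, psi[verts[1], ])
  for (j in 2:m) {
    # orthogonalize against span of previously found vertex directions
    if (j > 2) {
      Q <- qr.Q(qr(t(shifted[verts[2:(j - 1)], , drop = FALSE])))
      proj <- shifted %*% Q %*% t(Q)
      resid <- shifted - proj
    } else resid <- shifted
    verts[j] <- which.max(rowSums(resid^2))
  }
  A <- tryCatch(solve(psi[verts, , drop = FALSE]),
                error = function(e) stop("degenerate simplex vertices"))
  chi <- psi %*% A
  chi[chi < 0] <- 0
  chi <- chi / rowSums(chi)
  crisp <- max.col(chi, ties.method = "first")
  D <- pi0 * chi                      # diag(pi) chi
  T_coarse <- t(chi) %*% (pi0 * T) %*% chi
  norm <- t(chi) %*% D
  T_coarse <- solve(norm, T_coarse)
  T_coarse[T_coarse < 0] <- 0
  T_coarse <- T_coarse / rowSums(T_coarse)
  pi_coarse <- as.vector(t(chi) %*% pi0)
  structure(list(chi = chi, crisp = crisp, T_coarse = T_coarse,
                 pi_coarse = pi_coarse, m = m),
            class = "helimsm_macrostates")
}

#' Mean first-passage times between macrostates
#'
#' MFPT(A -> B) solves the first-passage linear system on the microstate
#' chain (m_i = tau dt + sum_{j not in B} T_ij m_j, m_B = 0) and aggregates
#' start states by the stationary distribution restricted to macrostate A.
#' Rates are reciprocal MFPTs.
#'
#' @param msm `helimsm_msm` (microstate chain)
#' @param macro `helimsm_macrostates`
#' @param tau lag (frames) of the chain
#' @param dt_s seconds per frame
#' @return list with `mfpt_s` (m x m, seconds; 0 diagonal) and `rate_hz`
#' @export
mfpt_and_rates <- function(msm, macro, tau, dt_s) {
  T <- msm$T; pi0 <- msm$pi
  m <- macro$m
  k <- nrow(T)
  step <- tau * dt_s
  M <- matrix(0, m, m)
  for (b in seq_len(m)) {
    Bset <- which(macro$crisp == b)
    if (length(Bset) == 0) stop("macrostate with no microstates: ", b)
    keep <- setdiff(seq_len(k), Bset)
    mvec <- numeric(k)
    if (length(keep) > 0) {
      sol <- tryCatch(
        solve(diag(length(keep)) - T[keep, keep, drop = FALSE],
              rep(step, length(keep))),
        error = function(e) stop("target macrostate unreachable"))
      mvec[keep] <- sol
    }
    for (a in seq_len(m)) {
      if (a == b) next
      Aset <- which(macro$crisp == a)
      w <- pi0[Aset] / sum(pi0[Aset])
      M[a, b] <- sum(w * mvec[Aset])
    }
  }
  R <- ifelse(M > 0, 1 / M, NA_real_)
  diag(R) <- NA_real_
  list(mfpt_s = M, rate_hz = R)
}

#' Pathway-versus-trap decomposition of a coarse chain
#'
#' The on-path states form the maximum-probability path from source to sink
#' on the coarse transition matrix: the shortest path under edge weight
#' -ln T_ij (absent edges where T_ij = 0). All other macrostates are
#' kinetic traps.
#'
#' @param macro `helimsm_macrostates`
#' @param source,sink macrostate indices
#' @return list with `on_path` (ordered indices) and `traps`
#' @export
decompose_pathway <- function(macro, source, sink) {
  if (source == sink) stop("source must differ from sink")
  T <- macro$T_coarse
  m <- nrow(T)
  W <- ifelse(T > 0, -log(T), Inf)
  diag(W) <- Inf
  # Dijkstra
  dist <- rep(Inf, m); prev <- rep(NA_integer_, m)
  dist[source] <- 0
  done <- rep(FALSE, m)
  for (iter in seq_len(m)) {
    u <- which(!done & dist == min(dist[!done]))[1]
    if (!is.finite(dist[u])) break
    done[u] <- TRUE
    for (v in which(is.finite(W[u, ]))) {
      alt <- dist[u] + W[u, v]
      if (alt < dist[v] - 1e-15) { dist[v] <- alt; prev[v] <- u }
    }
  }
  if (!is.finite(dist[sink])) stop("sink unreachable from source")
  path <- as.integer(sink)
  while (path[1] != source) path <- c(prev[path[1]], path)
  list(on_path = as.integer(path), traps = setdiff(seq_len(m), path))
}
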