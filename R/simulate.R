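# Sampling state sequences from a fixture kernel and emitting coarse-grained
# coordinate trajectories around the state templates.

#' Simulate a state-label sequence from a kinetic fixture
#'
#' Draws a discrete-time Markov chain from the fixture's per-frame kernel.
#' By default the chain starts from a draw of the stationary distribution.
#'
#' @param fixture `helimsm_fixture` (or a bare row-stochastic matrix)
#' @param n_frames sequence length (>= 2)
#' @param seed RNG seed
#' @param start optional start state id (or index when a bare matrix is given)
#' @return character vector of state ids (or integer indices for a matrix)
#' @export
simulate_state_sequence <- function(fixture, n_frames, seed, start = NULL) {
  stopifnot(n_frames >= 2)
  P <- if (inherits(fixture, "helimsm_fixture")) fixture$P else fixture
  if (any(abs(rowSums(P) - 1) > 1e-8)) stop("kernel rows must sum to 1")
  set.seed(seed)
  if (is.null(start)) {
    pi0 <- stationary_distribution(P)
    s0 <- sample.int(nrow(P), 1, prob = pi0)
  } else if (inherits(fixture, "helimsm_fixture") && is.character(start)) {
    s0 <- match(start, fixture$state_ids)
    if (is.na(s0)) stop("unknown start state: ", start)
  } else {
    s0 <- as.integer(start)
  }
  idx <- sample_chain_cpp(P, as.integer(n_frames), s0)
  if (inherits(fixture, "helimsm_fixture")) fixture$state_ids[idx] else idx
}

#' Emit a coordinate trajectory for a state sequence
#'
#' Frame t is the template of state t plus isotropic Gaussian positional
#' noise of standard deviation `sigma` per coordinate (the stand-in for
#' thermal fluctuation within a metastable state).
#'
#' @param sequence character vector of state ids
#' @param fixture `helimsm_fixture`
#' @param sigma noise standard deviation in Angstrom (>= 0)
#' @param seed RNG seed
#' @param frame_interval_s physical time per emitted frame, seconds
#'   (defaults to the fixture kernel step)
#' @return `helimsm_trajectory`
#' @export
emit_trajectory <- function(sequence, fixture, sigma = 0.2, seed = 1L,
                            frame_interval_s = fixture$dt_s) {
  stopifnot(sigma >= 0)
  idx <- match(sequence, fixture$state_ids)
  if (anyNA(idx)) stop("unknown state label in sequence: ",
                       paste(unique(sequence[is.na(idx)]), collapse = ","))
  nat <- nrow(fixture$templates[[1]])
  nf <- length(idx)
  set.seed(seed)
  coords <- array(0, dim = c(nf, nat, 3))
  for (t in seq_len(nf)) {
    coords[t, , ] <- fixture$templates[[idx[t]]]
  }
  if (sigma > 0)
    coords <- coords + array(rnorm(length(coords), sd = sigma), dim(coords))
  new_trajectory(coords, frame_interval_s * 1e12)  # seconds -> picoseconds
}

#' Generate a seeded multi-trajectory ensemble, streaming per trajectory
#'
#' Emulates the study design of unbiased runs launched from replicas spread
#' along the transition path: trajectory starts cycle round-robin through
#' the fixture states. The underlying kinetic chain is sampled at the
#' fixture frame step and frames are saved every `save_stride` steps, so a
#' trajectory of `n_frames` spans `n_frames * save_stride * dt` seconds.
#' `callback(i, traj, labels)` is invoked once per trajectory so that
#' downstream feature extraction can run without holding all coordinates.
#'
#' @param fixture `helimsm_fixture`
#' @param n_traj number of trajectories
#' @param n_frames saved frames per trajectory
#' @param seed master seed; trajectory i uses seed + i
#' @param sigma emission noise (Angstrom)
#' @param save_stride kinetic steps between saved frames
#' @param callback function(i, traj, labels); labels are the ground-truth
#'   state ids of the saved frames
#' @return invisible NULL
#' @export
emit_ensemble <- function(fixture, n_traj, n_frames, seed, sigma = 0.2,
                          save_stride = 1L, callback) {
  ns <- length(fixture$state_ids)
  for (i in seq_len(n_traj)) {
    start <- fixture$state_ids[((i - 1L) %% ns) + 1L]
    lab <- simulate_state_sequence(fixture, n_frames * save_stride,
                                   seed = seed + i, start = start)
    lab <- lab[seq(1L, length(lab), by = save_stride)]
    traj <- emit_trajectory(lab, fixture, sigma = sigma, seed = seed + 100000L + i,
                            frame_interval_s = fixture$dt_s * save_stride)
    callback(i, traj, lab)
  }
  invisible(NULL)
}
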