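# Domain-level geometric descriptors: centers of mass, the Arch<->Fe-S
# distance d_A-F and opening angle theta, constriction channel widths, state
# centroid structures, Calpha displacement fields, and the ssDNA register.

domain_com <- function(xyz, topology, label) {
  idx <- which(topology$atoms$domain_label == label)
  if (length(idx) == 0) stop("empty domain: ", label)
  m <- topology$atoms$mass[idx]
  colSums(xyz[idx, , drop = FALSE] * m) / sum(m)
}

domain_geometry_xyz <- function(xyz, topology) {
  com_fes <- domain_com(xyz, topology, "FeS")
  com_r1 <- domain_com(xyz, topology, "RecA1")
  com_arch <- domain_com(xyz, topology, "Arch")
  d_af <- sqrt(sum((com_arch - com_fes)^2))
  v1 <- com_fes - com_r1
  v2 <- com_arch - com_r1
  cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  cosang <- max(-1, min(1, cosang))
  list(com = list(FeS = com_fes, RecA1 = com_r1, Arch = com_arch),
       d_arch_fes = d_af, theta = acos(cosang) * 180 / pi)
}

#' Domain geometry descriptors for one frame
#'
#' Mass-weighted centers of mass per domain, the Arch-to-Fe-S
#' center-of-mass distance d_A-F, and the angle theta subtended at the RecA1
#' center of mass by the Fe-S and Arch centers. Opening of the 3' end of the
#' DNA groove upon ATP binding shows up as a concerted increase of both.
#'
#' @param frame atoms x 3 coordinate matrix (Angstrom)
#' @param topology `helimsm_topology` with RecA1, Arch and FeS atoms
#' @return list with `com` (per-domain centers), `d_arch_fes` (Angstrom) and
#'   `theta` (degrees, in \[0, 180\])
#' @export
domain_geometry <- function(frame, topology) {
  stopifnot(nrow(frame) == n_atoms(topology), ncol(frame) == 3)
  domain_geometry_xyz(frame, topology)
}

#' Per-frame domain geometry over a trajectory
#' @param traj `helimsm_trajectory`
#' @param topology matching topology
#' @return data.frame with columns `frame`, `d_arch_fes`, `theta`
#' @export
domain_geometry_series <- function(traj, topology) {
  out <- t(vapply(seq_len(n_frames(traj)), function(i) {
    g <- domain_geometry(get_frame(traj, i), topology)
    c(g$d_arch_fes, g$theta)
  }, numeric(2)))
  data.frame(frame = seq_len(nrow(out)), d_arch_fes = out[, 1],
             theta = out[, 2])
}

resolve_residue_atoms <- function(topology, residues, chain = "P") {
  idx <- which(topology$atoms$chain_id == chain &
               topology$atoms$residue_number %in% residues)
  split(idx, topology$atoms$residue_number[idx])
}

#' Constriction channel width for one frame
#'
#' The width is the symmetrized directed mean of minima: for each residue of
#' wall A take the minimum heavy-atom distance to any wall-B atom, average
#' over wall-A residues, repeat with the roles swapped, and average the two
#' directed means. On two parallel walls of matched atoms this reduces to
#' the wall separation; the min makes it robust to single displaced atoms.
#'
#' @param frame atoms x 3 coordinate matrix
#' @param definition list with `wall_a`, `wall_b` (residue number vectors)
#' @param topology `helimsm_topology`
#' @return width in Angstrom
#' @export
constriction_width <- function(frame, definition, topology) {
  ga <- resolve_residue_atoms(topology, definition$wall_a)
  gb <- resolve_residue_atoms(topology, definition$wall_b)
  if (length(ga) == 0 || length(gb) == 0) stop("empty constriction wall")
  bidx <- unlist(gb); aidx <- unlist(ga)
  dmin_to <- function(groups, other_idx) {
    other <- frame[other_idx, , drop = FALSE]
    vapply(groups, function(idx) {
      g <- frame[idx, , drop = FALSE]
      d2 <- outer(rowSums(g^2), rowSums(other^2), "+") -
        2 * g %*% t(other)
      sqrt(max(0, min(d2)))
    }, 0)
  }
  mean(c(mean(dmin_to(ga, bidx)), mean(dmin_to(gb, aidx))))
}

#' Per-frame width series with per-group summaries
#'
#' @param traj `helimsm_trajectory`
#' @param definition constriction definition (wall residue sets)
#' @param topology matching topology
#' @param groups optional per-frame grouping (e.g. macrostate labels)
#' @return list with `width` (per-frame vector) and, when `groups` is given,
#'   `by_group` (data.frame of mean and sd per group)
#' @export
width_series <- function(traj, definition, topology, groups = NULL) {
  w <- vapply(seq_len(n_frames(traj)), function(i)
    constriction_width(get_frame(traj, i), definition, topology), 0)
  out <- list(width = w)
  if (!is.null(groups)) {
    stopifnot(length(groups) == length(w))
    agg <- aggregate(w, list(group = groups),
                     function(v) c(mean = mean(v), sd = sd(v), n = length(v)))
    out$by_group <- data.frame(group = agg$group, mean = agg$x[, "mean"],
                               sd = agg$x[, "sd"], n = agg$x[, "n"])
  }
  out
}

#' Representative (centroid) frame of a macrostate
#'
#' Among the frames assigned to `state`, returns the member minimizing the
#' mean Calpha RMSD (after optimal superposition) to all other members. For
#' states larger than `max_members` a seeded subsample is used.
#'
#' @param traj `helimsm_trajectory`
#' @param labels per-frame state labels
#' @param state the state whose centroid is wanted
#' @param topology matching topology (Calpha atoms are used)
#' @param max_members subsample cap (default 500)
#' @param seed subsampling seed
#' @return list with `frame_index` (into the trajectory) and `coordinates`
#' @export
macrostate_centroid <- function(traj, labels, state, topology,
                                max_members = 500L, seed = 1L) {
  members <- which(labels == state)
  if (length(members) == 0) stop("state has no frames: ", state)
  if (length(members) > max_members) {
    set.seed(seed)
    members <- sort(sample(members, max_members))
  }
  ca <- which(topology$atoms$atom_name == "CA")
  if (length(ca) == 0) ca <- seq_len(n_atoms(topology))
  n <- length(members)
  frames <- lapply(members, function(i) get_frame(traj, i)[ca, , drop = FALSE])
  total <- numeric(n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      r <- kabsch_rmsd(frames[[i]], frames[[j]])
      total[i] <- total[i] + r
      total[j] <- total[j] + r
    }
  }
  best <- members[which.min(total)]
  list(frame_index = best, coordinates = get_frame(traj, best))
}

# optimal rigid superposition (Kabsch, via SVD); returns rotated+translated B
kabsch_fit <- function(A, B) {
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  s <- svd(t(B0) %*% A0)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sweep(B0 %*% t(R), 2, ca, "+")
}

kabsch_rmsd <- function(A, B) {
  Bf <- kabsch_fit(A, B)
  sqrt(mean(rowSums((A - Bf)^2)))
}

#' Calpha displacement field between two structures
#'
#' Superposes structure B onto A with an optimal rigid fit over all Calpha
#' atoms (Kabsch), then reports the per-Calpha vector B - A. This is the
#' quantity drawn as "porcupine" arrows for inter-state transitions.
#'
#' @param centroid_a,centroid_b atoms x 3 coordinate matrices on the same
#'   topology
#' @param topology `helimsm_topology`
#' @return data.frame: `atom_id`, `residue_number`, `domain`, `dx`,`dy`,`dz`
#' @export
displacement_field <- function(centroid_a, centroid_b, topology) {
  if (!all(dim(centroid_a) == dim(centroid_b)) ||
      nrow(centroid_a) != n_atoms(topology))
    stop("topology mismatch between structures")
  ca <- which(topology$atoms$atom_name == "CA")
  if (length(ca) == 0) stop("no Calpha atoms in topology")
  A <- centroid_a[ca, , drop = FALSE]
  Bf <- kabsch_fit(A, centroid_b[ca, , drop = FALSE])
  d <- Bf - A
  data.frame(atom_id = topology$atoms$atom_id[ca],
             residue_number = topology$atoms$residue_number[ca],
             domain = topology$atoms$domain_label[ca],
             dx = d[, 1], dy = d[, 2], dz = d[, 3])
}

#' ssDNA register offset between two frames
#'
#' Determines by how many nucleotides the ssDNA has advanced between two
#' structures, relative to protein-fixed landmarks (the constriction wall
#' residues). Both frames are superposed on the landmark atoms; the offset
#' maximizing the correspondence of nucleotide positions (candidate k
#' matches nucleotide i of Y to nucleotide i + k of X) is returned.
#' Positive offsets are advances toward the 3' exit.
#'
#' @param frame_x,frame_y atoms x 3 coordinate matrices on the same topology
#' @param topology `helimsm_topology` with a DNA chain
#' @param landmarks protein residue numbers used as the fixed frame
#' @param max_offset candidate range (default 3)
#' @return integer offset
#' @export
dna_register_offset <- function(frame_x, frame_y, topology, landmarks,
                                max_offset = 3L) {
  a <- topology$atoms
  lm <- which(a$chain_id == "P" & a$residue_number %in% landmarks)
  if (length(lm) >= 3) {
    # superpose on the landmarks, then apply the transform to all of frame_y
    ca <- colMeans(frame_x[lm, , drop = FALSE])
    cb <- colMeans(frame_y[lm, , drop = FALSE])
    A0 <- sweep(frame_x[lm, , drop = FALSE], 2, ca)
    B0 <- sweep(frame_y[lm, , drop = FALSE], 2, cb)
    s <- svd(t(B0) %*% A0)
    d <- sign(det(s$v %*% t(s$u)))
    rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
    frame_y <- sweep(sweep(frame_y, 2, cb) %*% t(rot), 2, ca, "+")
  }
  dna_p <- which(a$domain_label == "DNA" & a$atom_name == "P")
  if (length(dna_p) == 0) stop("no DNA P atoms")
  nt <- a$residue_number[dna_p]
  n <- length(nt)
  cand <- seq.int(-max_offset, max_offset)
  score <- vapply(cand, function(k) {
    ix <- match(nt + k, nt)
    ok <- !is.na(ix)
    if (sum(ok) < max(2, n - max_offset)) return(Inf)
    mean(sqrt(rowSums((frame_y[dna_p[ok], , drop = FALSE] -
                       frame_x[dna_p[ix[ok]], , drop = FALSE])^2)))
  }, 0)
  best <- which(score == min(score))
  if (length(best) > 1)
    stop("ambiguous DNA register offset; candidates: ",
         paste(cand[best], collapse = ", "))
  as.integer(cand[best])
}
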