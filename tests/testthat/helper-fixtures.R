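# Small in-code fixtures shared across test files.

# minimal topology: n unclassified carbon atoms in one ALA chain
toy_topology <- function(n = 2, chain = "A") {
  new_topology(data.frame(
    atom_id = seq_len(n), atom_name = paste0("C", seq_len(n)), element = "C",
    residue_name = "ALA", residue_number = seq_len(n), chain_id = chain,
    domain_label = "other", hbond_donor = FALSE, hbond_acceptor = FALSE,
    charge_class = "neutral", aromatic_ring_id = NA_character_,
    nonpolar = FALSE, mass = 12.0, stringsAsFactors = FALSE))
}

# a trajectory with explicit coordinates (list of atoms x 3 matrices)
toy_trajectory <- function(frames, dt_ps = 1) {
  coords <- array(0, dim = c(length(frames), nrow(frames[[1]]), 3))
  for (i in seq_along(frames)) coords[i, , ] <- frames[[i]]
  new_trajectory(coords, dt_ps)
}

# write a minimal PDB file, one model per coordinate matrix
write_toy_pdb <- function(path, models, resnames = NULL, atomnames = NULL,
                          serials = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(models[[1]])
  if (is.null(resnames)) resnames <- rep("ALA", n)
  if (is.null(atomnames)) atomnames <- rep("CA", n)
  if (is.null(serials)) serials <- seq_len(n)
  for (m in seq_along(models)) {
    writeLines(sprintf("MODEL     %4d", m), con)
    xyz <- models[[m]]
    writeLines(sprintf(
      "ATOM  %5d  %-3s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
      serials, atomnames, resnames, seq_len(n),
      xyz[, 1], xyz[, 2], xyz[, 3]), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  path
}

# topology with one hbond donor/acceptor pair and optional explicit hydrogen
hbond_topology <- function(with_h = FALSE) {
  n <- if (with_h) 3 else 2
  atoms <- data.frame(
    atom_id = seq_len(n),
    atom_name = c("ND", "OA", if (with_h) "HD")[seq_len(n)],
    element = c("N", "O", if (with_h) "H")[seq_len(n)],
    residue_name = "ALA", residue_number = c(1L, 2L, if (with_h) 1L)[seq_len(n)],
    chain_id = "A", domain_label = "other",
    hbond_donor = c(TRUE, FALSE, if (with_h) FALSE)[seq_len(n)],
    hbond_acceptor = c(FALSE, TRUE, if (with_h) FALSE)[seq_len(n)],
    charge_class = "neutral", aromatic_ring_id = NA_character_,
    nonpolar = FALSE, mass = 14.0, stringsAsFactors = FALSE)
  # keep residue numbering monotone within the chain
  atoms <- atoms[order(atoms$residue_number), ]
  atoms$atom_id <- seq_len(n)
  new_topology(atoms)
}

# two phenylalanine-like rings (6 atoms each) for pi-stacking tests
ring_topology <- function() {
  atoms <- do.call(rbind, lapply(1:2, function(r) {
    data.frame(
      atom_id = 0L, atom_name = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
      element = "C", residue_name = "PHE", residue_number = r, chain_id = "A",
      domain_label = "other", hbond_donor = FALSE, hbond_acceptor = FALSE,
      charge_class = "neutral", aromatic_ring_id = "R1", nonpolar = TRUE,
      stringsAsFactors = FALSE)
  }))
  atoms$atom_id <- seq_len(nrow(atoms))
  atoms$mass <- 12.0
  new_topology(atoms)
}

# hexagonal ring coordinates centered at `center`, radius 1.4 A in xy plane
ring_coords <- function(center) {
  th <- seq(0, 2 * pi, length.out = 7)[-7]
  cbind(center[1] + 1.4 * cos(th), center[2] + 1.4 * sin(th),
        rep(center[3], 6))
}

# charged pair topology (Arg-like N+ / Asp-like O-)
salt_topology <- function() {
  atoms <- data.frame(
    atom_id = 1:2, atom_name = c("NH1", "OD1"), element = c("N", "O"),
    residue_name = c("ARG", "ASP"), residue_number = 1:2, chain_id = "A",
    domain_label = "other", hbond_donor = c(TRUE, FALSE),
    hbond_acceptor = c(FALSE, TRUE),
    charge_class = c("positive", "negative"),
    aromatic_ring_id = NA_character_, nonpolar = FALSE, mass = 14,
    stringsAsFactors = FALSE)
  new_topology(atoms)
}

# cached fixtures (building them is cheap but not free)
xpd_fx <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- build_xpd_fixture()
    val
  }
})
ding_fx <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- build_ding_fixture()
    val
  }
})

# expected curated contacts of a fixture state as residue-tag keys
expected_contact_keys <- function(fixture_data, state) {
  f <- fixture_data$fixture
  ct <- f$contacts
  on <- vapply(ct$states, function(ss) state %in% ss, TRUE)
  off <- f$observables$dna_offset[f$observables$state == state]
  keys <- character(0)
  for (i in which(on)) {
    ak <- ct$anchor_key[i]
    if (startsWith(ak, "site:")) {
      j <- as.integer(sub("site:(\\d+):.*", "\\1", ak))
      partner <- sprintf("D:%d", j - off)
    } else if (startsWith(ak, "L:")) {
      partner <- sprintf("L:%s", sub("L:(\\d+):.*", "\\1", ak))
    } else {
      partner <- sprintf("P:%s", sub("P:(\\d+):.*", "\\1", ak))
    }
    me <- sprintf("P:%d", ct$resno[i])
    pair <- sort(c(me, partner))
    keys <- c(keys, paste(pair[1], pair[2], ct$type[i]))
  }
  unique(keys)
}

event_keys <- function(events) paste(events$res_a, events$res_b, events$type)

frame2 <- function(d) rbind(c(0, 0, 0), c(d, 0, 0))

# two independent AR(1) processes with known lag-1 autocorrelations, mixed
# into a 3-dimensional feature space
ar1_mixture <- function(n, a1 = 0.9, a2 = 0.5, seed = 1) {
  set.seed(seed)
  z1 <- as.vector(stats::filter(rnorm(n, sd = sqrt(1 - a1^2)), a1,
                                method = "recursive"))
  z2 <- as.vector(stats::filter(rnorm(n, sd = sqrt(1 - a2^2)), a2,
                                method = "recursive"))
  Z <- cbind(z1, z2)
  M <- matrix(c(1, 0.3, -0.2, 1, 0.5, 0.7), 2, 3)
  list(X = Z %*% M, Z = Z, M = M)
}
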