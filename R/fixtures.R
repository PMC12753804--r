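# Coarse-grained helicase-ssDNA fixtures with embedded ground truth.
#
# Geometry conventions (shared by the XPD-like and DinG-like systems):
#  * the ssDNA threads along +x through a groove; lattice "sites" j = 1..14
#    sit at x = 6.5*(j-1); nucleotide i occupies site i + register_offset
#  * Constriction 1 (5' end) spans sites 2-5, the bridge sites 6-8,
#    Constriction 2 (3' end) sites 9-12; both constrictions are walled by
#    two matched rows of side-chain pseudo-atoms whose row separation IS the
#    channel width, so the width metric recovers the embedded value exactly
#  * each protein domain is a cluster of CA pseudo-atoms that moves rigidly
#    between states; cited residues additionally carry one side-chain
#    pseudo-atom ("SC") whose position realizes the state's contact pattern:
#    at the "on" distance for contacts present in the state, retracted
#    otherwise
#  * the ATP/ADP ligand and Mg are parked in bulk solvent in apo states and
#    placed in the RecA1-RecA2 pocket in nucleotide-bound states.

SITE_SPACING <- 6.5
site_x <- function(j) SITE_SPACING * (j - 1)

# distances used to realize typed contacts (cutoffs 3.2/3.5/4.5 A)
CONTACT_ON <- c(hbond = 2.65, salt_bridge = 2.65, hydrophobic = 3.6,
                pi_stack = 2.9)
CONTACT_OFF_SHIFT <- 4.5   # added to the on distance when a contact is off

# ---- kinetic kernel ----------------------------------------------------------

#' Calibrate a linear-chain transition kernel with attached traps
#'
#' Builds a discrete-time transition matrix over `n` on-path states
#' (1 <-> 2 <-> ... <-> n) plus one trap per entry of `trap_host`, such that
#' the stepwise mean first-passage times MFPT(i -> i+1) equal `step_mfpt_s`
#' exactly and the on-path stationary mass is uniform. Backward edge
#' probabilities equal the forward probability of the same edge (detailed
#' balance with equal neighbor masses); trap entry/exit probabilities are
#' given per trap. The calibration is closed-form: with u_i = 1 +
#' p_back_i * m_(i-1) + q_i/r_i, the forward probability is u_i / m_i
#' (m in frames).
#'
#' @param step_mfpt_s stepwise MFPT targets in seconds, length n-1
#' @param dt_s frame interval in seconds
#' @param trap_host on-path state index each trap attaches to
#' @param trap_entry,trap_exit per-frame entry/exit probabilities per trap
#' @return list with `P` (row-stochastic), `n_path`, `trap_host`
#' @export
calibrate_chain <- function(step_mfpt_s, dt_s, trap_host = integer(0),
                            trap_entry = numeric(0), trap_exit = numeric(0)) {
  stopifnot(length(trap_host) == length(trap_entry),
            length(trap_host) == length(trap_exit))
  m <- step_mfpt_s / dt_s
  n <- length(m) + 1L
  nt <- length(trap_host)
  qr <- numeric(n)
  qr[trap_host] <- trap_entry / trap_exit
  pf <- numeric(n); pb <- numeric(n)
  for (i in seq_len(n - 1L)) {
    pf[i] <- (1 + pb[i] * (if (i > 1) m[i - 1] else 0) + qr[i]) / m[i]
    pb[i + 1L] <- pf[i]
  }
  N <- n + nt
  P <- matrix(0, N, N)
  for (i in seq_len(n)) {
    if (i < n) P[i, i + 1L] <- pf[i]
    if (i > 1) P[i, i - 1L] <- pb[i]
  }
  for (t in seq_len(nt)) {
    P[trap_host[t], n + t] <- trap_entry[t]
    P[n + t, trap_host[t]] <- trap_exit[t]
  }
  diag(P) <- 1 - rowSums(P)
  if (any(diag(P) < 0)) stop("calibration produced negative self-probability")
  P
}

# analytic MFPT (frames) between states of a discrete chain
chain_mfpt <- function(P, target) {
  N <- nrow(P)
  keep <- setdiff(seq_len(N), target)
  m <- solve(diag(length(keep)) - P[keep, keep, drop = FALSE],
             rep(1, length(keep)))
  out <- numeric(N)
  out[keep] <- m
  out
}

#' Analytic mean first-passage times of a kinetic fixture
#'
#' Solves the linear first-passage system on the fixture's exact kernel.
#'
#' @param fixture a `helimsm_fixture`
#' @param from,to state ids (e.g. `"S1"`, `"S2"`)
#' @return MFPT in seconds
#' @export
fixture_mfpt <- function(fixture, from, to) {
  i <- match(from, fixture$state_ids)
  j <- match(to, fixture$state_ids)
  if (is.na(i) || is.na(j)) stop("unknown state id")
  chain_mfpt(fixture$P, j)[i] * fixture$dt_s
}

stationary_distribution <- function(P) {
  e <- eigen(t(P))
  k <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, k])
  v <- abs(v)
  v / sum(v)
}

# ---- generic fixture assembly ------------------------------------------------

# spec: list describing one system; see xpd_fixture_spec()
build_fixture_from_spec <- function(spec) {
  ## ---- atom table -----------------------------------------------------------
  rows <- list()
  addatom <- function(key, name, element, resname, resno, chain, donor = FALSE,
                      acc = FALSE, charge = "neutral", np = FALSE, mass = 50) {
    rows[[key]] <<- data.frame(
      key = key, atom_name = name, element = element, residue_name = resname,
      residue_number = resno, chain_id = chain, hbond_donor = donor,
      hbond_acceptor = acc, charge_class = charge, nonpolar = np, mass = mass,
      stringsAsFactors = FALSE)
  }
  aa1 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
           E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
           M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
           Y = "TYR", V = "VAL")
  sc_class <- function(code) {
    switch(code,
      R = , K = list(donor = TRUE, acc = FALSE, charge = "positive", np = FALSE),
      D = , E = list(donor = FALSE, acc = TRUE, charge = "negative", np = FALSE),
      S = , T = , Q = , N = list(donor = TRUE, acc = TRUE, charge = "neutral", np = FALSE),
      H = list(donor = TRUE, acc = TRUE, charge = "neutral", np = TRUE),
      Y = , W = , F = list(donor = (code == "Y"), acc = FALSE,
                           charge = "neutral", np = TRUE),
      list(donor = FALSE, acc = FALSE, charge = "neutral", np = TRUE))
  }
  # protein residues: body (CA only) and cited (CA + SC)
  prot <- spec$residues   # data.frame: resno, code, role ("body"/"sc")
  prot <- prot[order(prot$resno), ]
  for (i in seq_len(nrow(prot))) {
    rn <- prot$resno[i]; code <- prot$code[i]
    resname <- aa1[[code]]
    addatom(sprintf("P:%d:CA", rn), "CA", "C", resname, rn, "P", mass = 110)
    if (prot$role[i] == "sc") {
      cl <- sc_class(code)
      ov <- spec$sc_overrides[[as.character(rn)]]
      if (!is.null(ov)) {
        if (!is.null(ov$nonpolar)) cl$np <- ov$nonpolar
        if (!is.null(ov$donor)) cl$donor <- ov$donor
        if (!is.null(ov$acceptor)) cl$acc <- ov$acceptor
      }
      addatom(sprintf("P:%d:SC", rn), "SC", "C", resname, rn, "P",
              donor = cl$donor, acc = cl$acc, charge = cl$charge,
              np = cl$np, mass = 55)
    }
  }
  # ssDNA: 12 nucleotides, P + C1' + base-centroid pseudo-atoms
  dna_seq <- rep(c("DT", "DA", "DC", "DG"), 3)
  for (i in 1:12) {
    addatom(sprintf("D:%d:P", i), "P", "P", dna_seq[i], i, "D",
            acc = TRUE, charge = "negative", mass = 95)
    addatom(sprintf("D:%d:C1'", i), "C1'", "C", dna_seq[i], i, "D",
            np = TRUE, mass = 80)
    addatom(sprintf("D:%d:BAS", i), "BAS", "C", dna_seq[i], i, "D",
            np = TRUE, mass = 130)
  }
  # ligand: ATP pseudo-atoms + Mg (parked in solvent in apo states)
  addatom("L:901:PG", "PG", "P", "ATP", 901, "L", acc = TRUE,
          charge = "negative", mass = 95)
  addatom("L:901:PB", "PB", "P", "ATP", 901, "L", acc = TRUE,
          charge = "negative", mass = 95)
  addatom("L:901:O3", "O3", "O", "ATP", 901, "L", acc = TRUE, mass = 16)
  addatom("L:901:ADE", "ADE", "C", "ATP", 901, "L", np = TRUE, mass = 130)
  addatom("L:902:MG", "MG", "MG", "MG", 902, "L", charge = "positive",
          mass = 24)
  atoms <- do.call(rbind, unname(rows))
  ord <- order(match(atoms$chain_id, c("P", "D", "L")), atoms$residue_number,
               atoms$atom_name)
  atoms <- atoms[ord, ]
  atoms$atom_id <- seq_len(nrow(atoms))
  key_index <- setNames(atoms$atom_id, atoms$key)
  atoms$domain_label <- "other"
  atoms$aromatic_ring_id <- NA_character_
  atoms$key <- NULL
  topology <- new_topology(atoms[, c("atom_id", "atom_name", "element",
                                     "residue_name", "residue_number",
                                     "chain_id", "domain_label", "hbond_donor",
                                     "hbond_acceptor", "charge_class",
                                     "aromatic_ring_id", "nonpolar", "mass")])
  topology <- annotate_domains(topology, spec$domain_ranges)

  ## ---- per-state template coordinates ---------------------------------------
  nat <- n_atoms(topology)
  states <- spec$states
  state_ids <- names(states)
  pos_key <- function(X, key) X[key_index[[key]], ]
  set_key <- function(X, key, v) { X[key_index[[key]], ] <- v; X }

  dna_region <- function(j) {
    if (j <= 5) "c1" else if (j <= 8) "bridge" else "c2"
  }
  site_pos <- function(st, j) {
    reg <- dna_region(j)
    y <- switch(reg, c1 = 0, bridge = 0, c2 = spec$c2_dna_y)
    z <- if (reg == "bridge") st$bridge_z else 0
    c(site_x(j), y, z)
  }

  build_template <- function(st) {
    X <- matrix(0, nat, 3)
    # domain bodies: lattice offsets around per-state centers
    for (dom in names(spec$body_layout)) {
      lay <- spec$body_layout[[dom]]
      ctr <- spec$domain_centers[[dom]] + st$domain_shift[[dom]]
      for (i in seq_along(lay$resno)) {
        X <- set_key(X, sprintf("P:%d:CA", lay$resno[i]), ctr + lay$offsets[i, ])
      }
    }
    # constriction walls: matched rows of SC atoms; CA parked behind the wall
    for (cn in names(spec$constrictions)) {
      cdef <- spec$constrictions[[cn]]
      w <- st$widths[[cn]]
      yA <- cdef$y_mid - w / 2
      yB <- cdef$y_mid + w / 2
      for (i in seq_along(cdef$wall_a)) {
        ka <- sprintf("P:%d:SC", cdef$wall_a[i])
        X <- set_key(X, ka, c(cdef$wall_x[i], yA, 0))
        X <- set_key(X, sprintf("P:%d:CA", cdef$wall_a[i]),
                     c(cdef$wall_x[i], yA - 4, 0))
      }
      for (i in seq_along(cdef$wall_b)) {
        kb <- sprintf("P:%d:SC", cdef$wall_b[i])
        X <- set_key(X, kb, c(cdef$wall_x[i], yB, 0))
        X <- set_key(X, sprintf("P:%d:CA", cdef$wall_b[i]),
                     c(cdef$wall_x[i], yB + 4, 0))
      }
    }
    # ssDNA: nucleotide i occupies site i + register offset
    for (i in 1:12) {
      s0 <- site_pos(st, i + st$dna_offset)
      X <- set_key(X, sprintf("D:%d:P", i), s0)
      X <- set_key(X, sprintf("D:%d:C1'", i), s0 + c(0.9, 1.1, 0.6))
      X <- set_key(X, sprintf("D:%d:BAS", i),
                   s0 + c(0.4, spec$bas_y_offset(i + st$dna_offset), 1.1))
    }
    # ligand pose
    lig <- if (st$ligand == "none") spec$ligand_solvent else spec$ligand_pocket
    for (nm in names(lig)) X <- set_key(X, nm, lig[[nm]])
    if (st$ligand %in% c("none", "adp"))  # terminal phosphate released
      X <- set_key(X, "L:901:PG", spec$ligand_solvent[["L:901:PG"]] + c(0, 0, 5))
    if (st$ligand != "atp")
      X <- set_key(X, "L:902:MG", spec$ligand_solvent[["L:902:MG"]] + c(10, 6, 0))
    # pinned side chains (contact anchors with fixed domain-frame positions)
    ps <- spec$pinned_sc
    for (i in seq_len(nrow(ps))) {
      ctr <- spec$domain_centers[[ps$domain[i]]] + st$domain_shift[[ps$domain[i]]]
      X <- set_key(X, ps$key[i], ctr + c(ps$ox[i], ps$oy[i], ps$oz[i]))
    }
    # side chains of cited residues without contact rows sit near their CA
    ct <- spec$contacts
    mover_keys <- unique(ct$mover_key)
    sc_rows <- which(topology$atoms$atom_name == "SC")
    sc_keys <- sprintf("P:%d:SC", topology$atoms$residue_number[sc_rows])
    placed <- c(mover_keys, ps$key,
                unlist(lapply(spec$constrictions, function(cd)
                  sprintf("P:%d:SC", c(cd$wall_a, cd$wall_b)))))
    for (i in seq_along(sc_rows)) {
      if (!(sc_keys[i] %in% placed)) {
        ca <- key_index[[sub(":SC$", ":CA", sc_keys[i])]]
        X[sc_rows[i], ] <- X[ca, ] + c(0, 1.5, 0.8)
      }
    }
    # contact side chains: at the on-distance for contacts present in the
    # state, retracted otherwise. When a mover has several rows, rows that
    # are "on" in this state take precedence over its "off" rows.
    row_on <- vapply(ct$states, function(ss) st$id %in% ss, TRUE)
    has_on <- tapply(row_on, ct$mover_key, any)
    for (i in seq_len(nrow(ct))) {
      on <- row_on[i]
      if (!on && isTRUE(has_on[[ct$mover_key[i]]])) next
      anchor_key <- ct$anchor_key[i]
      ligand_anchor <- startsWith(anchor_key, "L:")
      if (!on && ligand_anchor) {
        # nucleotide absent or released: side chain relaxes toward its CA
        ca <- key_index[[sub(":SC$", ":CA", ct$mover_key[i])]]
        X <- set_key(X, ct$mover_key[i], X[ca, ] + c(0.9, 1.8, 1.2))
        next
      }
      d <- CONTACT_ON[[ct$type[i]]] + if (on) 0 else CONTACT_OFF_SHIFT
      if (startsWith(anchor_key, "site:")) {
        j <- as.integer(sub("site:(\\d+):.*", "\\1", anchor_key))
        anm <- sub("site:\\d+:", "", anchor_key)
        s0 <- site_pos(st, j)
        apos <- s0 + switch(anm, "P" = c(0, 0, 0), "C1'" = c(0.9, 1.1, 0.6),
                            "BAS" = c(0.4, spec$bas_y_offset(j), 1.1))
      } else {
        apos <- pos_key(X, anchor_key)
      }
      phi <- ct$phi[i] * pi / 180
      dirv <- c(0.18, cos(phi), sin(phi))
      dirv <- dirv / sqrt(sum(dirv^2))
      X <- set_key(X, ct$mover_key[i], apos + dirv * d)
    }
    # trap states: rigidly displace one domain relative to the host template
    if (!is.null(st$trap_shift)) {
      dom_rows <- which(topology$atoms$domain_label == st$trap_shift$domain)
      X[dom_rows, ] <- X[dom_rows, ] +
        rep(st$trap_shift$delta, each = length(dom_rows))
    }
    X
  }

  templates <- lapply(states, function(st) build_template(st))
  names(templates) <- state_ids

  ## ---- kinetics -------------------------------------------------------------
  P <- calibrate_chain(spec$step_mfpt_s, spec$dt_s, spec$trap_host,
                       spec$trap_entry, spec$trap_exit)
  n_path <- length(spec$step_mfpt_s) + 1L
  stopifnot(nrow(P) == length(state_ids))

  observables <- data.frame(
    state = state_ids,
    w1 = vapply(states, function(s) s$widths$c1, 0),
    w2 = vapply(states, function(s) s$widths$c2, 0),
    dna_offset = vapply(states, function(s) s$dna_offset, 0L),
    ligand = vapply(states, function(s) s$ligand, ""),
    row.names = NULL)
  # embedded domain-geometry descriptors, measured on the templates
  dg <- t(vapply(templates, function(X) {
    g <- domain_geometry_xyz(X, topology)
    c(g$d_arch_fes, g$theta)
  }, numeric(2)))
  observables$d_arch_fes <- dg[, 1]
  observables$theta <- dg[, 2]

  fixture <- structure(list(
    system = spec$system,
    state_ids = state_ids,
    on_path = state_ids[seq_len(n_path)],
    traps = state_ids[-seq_len(n_path)],
    P = P,
    dt_s = spec$dt_s,
    templates = templates,
    observables = observables,
    contacts = spec$contacts,
    constrictions = lapply(spec$constrictions, function(cd)
      list(wall_a = cd$wall_a, wall_b = cd$wall_b)),
    domain_ranges = spec$domain_ranges,
    apo_state = spec$apo_state,
    atp_state = spec$atp_state,
    marker_sites = c(marker1 = 2L, marker2 = 9L)),
    class = "helimsm_fixture")
  list(topology = topology, fixture = fixture)
}

#' @export
print.helimsm_fixture <- function(x, ...) {
  cat(sprintf("helimsm %s fixture: %d states (%d on-path, %d traps), dt = %g s\n",
              x$system, length(x$state_ids), length(x$on_path),
              length(x$traps), x$dt_s))
  invisible(x)
}

# shared body lattice: deterministic low-discrepancy offsets within a radius
body_offsets <- function(n, radius = 8) {
  g <- (1 + sqrt(5)) / 2
  i <- seq_len(n)
  th <- 2 * pi * (i / g %% 1)
  ph <- acos(1 - 2 * (i - 0.5) / n)
  r <- radius * ((i %% 3) + 1) / 3
  cbind(r * sin(ph) * cos(th), r * sin(ph) * sin(th), r * cos(ph))
}

contact_row <- function(resno, anchor, type, states, phi) {
  data.frame(resno = resno, mover_key = sprintf("P:%d:SC", resno),
             anchor_key = anchor, type = type, phi = phi,
             states = I(list(states)), stringsAsFactors = FALSE)
}

#' Export a fixture as multi-model PDB plus JSON sidecar
#'
#' Writes the state templates as one multi-model PDB (one MODEL per state,
#' in state order) and a JSON sidecar with the transition kernel, frame
#' step, state bookkeeping and embedded observables.
#'
#' @param fixture_data list(topology, fixture) from a fixture builder
#' @param dir output directory (created if needed)
#' @return invisible vector of written paths
#' @export
export_fixture <- function(fixture_data, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f <- fixture_data$fixture
  nat <- n_atoms(fixture_data$topology)
  coords <- array(0, dim = c(length(f$templates), nat, 3))
  for (i in seq_along(f$templates)) coords[i, , ] <- f$templates[[i]]
  traj <- new_trajectory(coords, frame_interval = f$dt_s * 1e12)
  pdb_path <- file.path(dir, paste0(f$system, "_templates.pdb"))
  write_multimodel_pdb(traj, fixture_data$topology, pdb_path)
  side <- list(system = f$system, state_ids = f$state_ids,
               on_path = f$on_path, traps = f$traps, dt_s = f$dt_s,
               kernel = f$P, observables = f$observables,
               marker_sites = f$marker_sites)
  json_path <- file.path(dir, paste0(f$system, "_fixture.json"))
  jsonlite::write_json(side, json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(c(pdb_path, json_path))
}
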