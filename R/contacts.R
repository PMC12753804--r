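# Typed interaction detection (hydrogen bonds, salt bridges, pi stacking,
# hydrophobic contacts) and per-macrostate persistence analysis.

#' Interaction criteria
#'
#' Defaults follow the standard MD contact definitions: hydrogen bonds at
#' donor-acceptor heavy-atom distance <= 3.2 A with donor-H-acceptor angle
#' >= 135 deg; salt bridges <= 3.2 A between oppositely charged atoms;
#' pi stacking at aromatic ring-centroid distance <= 3.5 A; hydrophobic
#' contacts <= 4.5 A between side-chain nonpolar atoms. A contact is
#' persistent when present in at least 75% of a state's frames. All bounds
#' are inclusive.
#'
#' @param hbond_dist,hbond_angle,salt_bridge_dist,pi_stack_dist,hydrophobic_dist
#'   cutoffs (Angstrom; angle in degrees)
#' @param persistence_threshold fraction in (0, 1]
#' @return list of criteria
#' @export
interaction_criteria <- function(hbond_dist = 3.2, hbond_angle = 135,
                                 salt_bridge_dist = 3.2, pi_stack_dist = 3.5,
                                 hydrophobic_dist = 4.5,
                                 persistence_threshold = 0.75) {
  stopifnot(hbond_dist > 0, salt_bridge_dist > 0, pi_stack_dist > 0,
            hydrophobic_dist > 0, persistence_threshold > 0,
            persistence_threshold <= 1)
  list(hbond_dist = hbond_dist, hbond_angle = hbond_angle,
       salt_bridge_dist = salt_bridge_dist, pi_stack_dist = pi_stack_dist,
       hydrophobic_dist = hydrophobic_dist,
       persistence_threshold = persistence_threshold)
}

# residue tag: chain:resno
res_tag <- function(atoms, idx) paste(atoms$chain_id[idx],
                                      atoms$residue_number[idx], sep = ":")

# candidate atom pairs for each detector, computed once per topology
contact_candidates <- function(topology, criteria) {
  a <- topology$atoms
  pair_grid <- function(i, j) {
    if (length(i) == 0 || length(j) == 0) return(NULL)
    g <- expand.grid(i = i, j = j)
    g <- g[a$chain_id[g$i] != a$chain_id[g$j] |
           a$residue_number[g$i] != a$residue_number[g$j], ]
    g
  }
  don <- which(a$hbond_donor)
  acc <- which(a$hbond_acceptor)
  pos <- which(a$charge_class == "positive")
  neg <- which(a$charge_class == "negative")
  np <- which(a$nonpolar & !(a$atom_name %in% c("CA", "N", "C", "O")))
  list(hbond = pair_grid(don, acc),
       salt_bridge = pair_grid(pos, neg),
       hydrophobic = {
         g <- pair_grid(np, np)
         if (!is.null(g)) g[g$i < g$j, ] else NULL
       })
}

ring_centroids <- function(frame, topology) {
  a <- topology$atoms
  rid <- which(!is.na(a$aromatic_ring_id))
  if (length(rid) == 0) return(NULL)
  grp <- paste(a$chain_id[rid], a$residue_number[rid], a$aromatic_ring_id[rid])
  ug <- unique(grp)
  cent <- t(vapply(ug, function(g) {
    colMeans(frame[rid[grp == g], , drop = FALSE])
  }, numeric(3)))
  first <- rid[match(ug, grp)]
  list(xyz = cent, chain = a$chain_id[first],
       resno = a$residue_number[first])
}

#' Detect typed contacts in one frame
#'
#' All four detectors are applied; multiple atom-pair hits of one type
#' within one residue pair count once (contacts are reported at residue
#' resolution). When no explicit hydrogen is present the
#' donor-hydrogen-acceptor angle is evaluated with an idealized hydrogen on
#' the donor-acceptor axis (angle 180 deg) and the event is flagged
#' `heavy_atom_only`.
#'
#' @param frame atoms x 3 coordinate matrix
#' @param topology `helimsm_topology`
#' @param criteria from [interaction_criteria()]
#' @return data.frame: `res_a`, `res_b` (chain:resno, a < b), `type`,
#'   `heavy_atom_only`
#' @export
detect_contacts_frame <- function(frame, topology, criteria = interaction_criteria(),
                                  candidates = NULL) {
  a <- topology$atoms
  if (is.null(candidates)) candidates <- contact_candidates(topology, criteria)
  events <- list()
  dist_of <- function(g) sqrt(rowSums((frame[g$i, , drop = FALSE] -
                                       frame[g$j, , drop = FALSE])^2))
  add_events <- function(g, hits, type, heavy = FALSE) {
    if (is.null(g) || !any(hits)) return()
    i <- g$i[hits]; j <- g$j[hits]
    ra <- res_tag(a, i); rb <- res_tag(a, j)
    swap <- ra > rb
    tmp <- ra[swap]; ra[swap] <- rb[swap]; rb[swap] <- tmp
    df <- unique(data.frame(res_a = ra, res_b = rb, type = type,
                            heavy_atom_only = heavy,
                            stringsAsFactors = FALSE))
    events[[length(events) + 1L]] <<- df
  }
  # hydrogen bonds: explicit H atoms are used for the angle when present
  g <- candidates$hbond
  if (!is.null(g)) {
    d <- dist_of(g)
    hits <- d <= criteria$hbond_dist
    if (any(hits)) {
      hyd <- which(a$element == "H")
      if (length(hyd) > 0) {
        ok <- logical(sum(hits)); hk <- which(hits)
        for (m in seq_along(hk)) {
          i <- g$i[hk[m]]; j <- g$j[hk[m]]
          # hydrogens on the donor residue within covalent range of the donor
          cand_h <- hyd[a$chain_id[hyd] == a$chain_id[i] &
                        a$residue_number[hyd] == a$residue_number[i]]
          if (length(cand_h) > 0) {
            dh <- sqrt(rowSums((frame[cand_h, , drop = FALSE] -
                                matrix(frame[i, ], length(cand_h), 3,
                                       byrow = TRUE))^2))
            cand_h <- cand_h[dh <= 1.3]
          }
          if (length(cand_h) == 0) { ok[m] <- TRUE; next }  # idealized H
          ang <- vapply(cand_h, function(h) {
            v1 <- frame[i, ] - frame[h, ]
            v2 <- frame[j, ] - frame[h, ]
            cc <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
            acos(max(-1, min(1, cc))) * 180 / pi
          }, 0)
          ok[m] <- any(ang >= criteria$hbond_angle - 1e-9)
        }
        heavy_flag <- FALSE
        hits[which(hits)] <- ok
      } else heavy_flag <- TRUE
      add_events(g, hits, "hbond", heavy = length(hyd) == 0)
    }
  }
  g <- candidates$salt_bridge
  if (!is.null(g)) add_events(g, dist_of(g) <= criteria$salt_bridge_dist,
                              "salt_bridge")
  g <- candidates$hydrophobic
  if (!is.null(g)) add_events(g, dist_of(g) <= criteria$hydrophobic_dist,
                              "hydrophobic")
  # pi stacking between aromatic ring centroids
  rc <- ring_centroids(frame, topology)
  if (!is.null(rc) && nrow(rc$xyz) >= 2) {
    n <- nrow(rc$xyz)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        same <- rc$chain[i] == rc$chain[j] & rc$resno[i] == rc$resno[j]
        if (same) next
        d <- sqrt(sum((rc$xyz[i, ] - rc$xyz[j, ])^2))
        if (d <= criteria$pi_stack_dist) {
          ra <- paste(rc$chain[i], rc$resno[i], sep = ":")
          rb <- paste(rc$chain[j], rc$resno[j], sep = ":")
          if (ra > rb) { tmp <- ra; ra <- rb; rb <- tmp }
          events[[length(events) + 1L]] <-
            data.frame(res_a = ra, res_b = rb, type = "pi_stack",
                       heavy_atom_only = FALSE, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(events) == 0)
    return(data.frame(res_a = character(0), res_b = character(0),
                      type = character(0), heavy_atom_only = logical(0),
                      stringsAsFactors = FALSE))
  unique(do.call(rbind, events))
}

#' Detect contacts over a trajectory
#'
#' @param traj `helimsm_trajectory`
#' @param topology matching topology
#' @param criteria interaction criteria
#' @return data.frame of events with a `frame` column
#' @export
detect_contacts <- function(traj, topology, criteria = interaction_criteria()) {
  candidates <- contact_candidates(topology, criteria)
  out <- lapply(seq_len(n_frames(traj)), function(f) {
    ev <- detect_contacts_frame(get_frame(traj, f), topology, criteria,
                                candidates)
    if (nrow(ev) > 0) ev$frame <- f
    ev
  })
  out <- out[vapply(out, nrow, 0L) > 0]
  if (length(out) == 0)
    return(data.frame(res_a = character(0), res_b = character(0),
                      type = character(0), heavy_atom_only = logical(0),
                      frame = integer(0)))
  do.call(rbind, out)
}

#' Per-macrostate contact persistence table
#'
#' For every (contact, state): fraction = frames containing the contact /
#' frames assigned to the state; the contact is persistent when the
#' fraction reaches the threshold. Contacts absent from a state are omitted
#' from that state's rows.
#'
#' @param events data.frame from [detect_contacts()] (with `frame`)
#' @param macrostate_labels per-frame state labels (length = frame count)
#' @param criteria interaction criteria (persistence threshold)
#' @return object of class `helimsm_contact_table`: data.frame `state`,
#'   `res_a`, `res_b`, `type`, `fraction`, `persistent`
#' @export
persistence_table <- function(events, macrostate_labels,
                              criteria = interaction_criteria()) {
  n_by_state <- table(macrostate_labels)
  if (any(n_by_state == 0)) stop("macrostate with zero frames")
  if (nrow(events) == 0) {
    tab <- data.frame(state = character(0), res_a = character(0),
                      res_b = character(0), type = character(0),
                      fraction = numeric(0), persistent = logical(0))
    class(tab) <- c("helimsm_contact_table", "data.frame")
    return(tab)
  }
  ev <- events
  ev$state <- as.character(macrostate_labels[ev$frame])
  key <- paste(ev$state, ev$res_a, ev$res_b, ev$type, sep = "|")
  cnt <- table(key)
  parts <- do.call(rbind, strsplit(names(cnt), "|", fixed = TRUE))
  tab <- data.frame(state = parts[, 1], res_a = parts[, 2],
                    res_b = parts[, 3], type = parts[, 4],
                    fraction = as.vector(cnt) /
                      as.vector(n_by_state[parts[, 1]]),
                    stringsAsFactors = FALSE)
  tab$persistent <- tab$fraction >= criteria$persistence_threshold
  tab <- tab[order(tab$state, -tab$fraction), ]
  rownames(tab) <- NULL
  class(tab) <- c("helimsm_contact_table", "data.frame")
  tab
}

contact_residues <- function(tags) {
  as.integer(sub("^[^:]+:", "", tags))
}
contact_chains <- function(tags) sub(":.*$", "", tags)

#' Restrict a contact table to an interface between two groups
#'
#' @param table `helimsm_contact_table`
#' @param group_a,group_b disjoint residue selections: lists with `chain`
#'   and `residues` (residue numbers), or a domain label string (all
#'   residues of that domain, requires `topology`)
#' @param topology needed when groups are domain labels
#' @return filtered contact table (one partner in each group)
#' @export
interface_filter <- function(table, group_a, group_b, topology = NULL) {
  resolve <- function(g) {
    if (is.character(g) && length(g) == 1) {
      stopifnot(!is.null(topology))
      a <- topology$atoms
      idx <- a$domain_label == g
      list(chain = unique(a$chain_id[idx]),
           residues = unique(a$residue_number[idx]),
           tags = unique(paste(a$chain_id[idx], a$residue_number[idx],
                               sep = ":")))
    } else {
      list(tags = paste(g$chain, g$residues, sep = ":"))
    }
  }
  ta <- resolve(group_a)$tags
  tb <- resolve(group_b)$tags
  if (length(intersect(ta, tb)) > 0) stop("groups overlap")
  keep <- (table$res_a %in% ta & table$res_b %in% tb) |
          (table$res_a %in% tb & table$res_b %in% ta)
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Gained / lost / retained persistent contacts between two states
#'
#' @param table `helimsm_contact_table`
#' @param state_x,state_y state labels present in the table
#' @return list of data.frames `gained` (persistent in Y only), `lost`
#'   (persistent in X only), `retained`
#' @export
contact_diff <- function(table, state_x, state_y) {
  pick <- function(s) {
    t2 <- table[table$state == s & table$persistent, c("res_a", "res_b", "type")]
    paste(t2$res_a, t2$res_b, t2$type, sep = "|")
  }
  px <- pick(state_x); py <- pick(state_y)
  unpack <- function(keys) {
    if (length(keys) == 0)
      return(data.frame(res_a = character(0), res_b = character(0),
                        type = character(0)))
    p <- do.call(rbind, strsplit(keys, "|", fixed = TRUE))
    data.frame(res_a = p[, 1], res_b = p[, 2], type = p[, 3],
               stringsAsFactors = FALSE)
  }
  list(gained = unpack(setdiff(py, px)),
       lost = unpack(setdiff(px, py)),
       retained = unpack(intersect(px, py)))
}

#' Persistent protein-DNA contact counts at the two constrictions
#'
#' Counts, per macrostate, the persistent protein-DNA contacts whose
#' protein partner belongs to each constriction's member residue set. The
#' reciprocal switch of these counts between the apo and ATP-bound states
#' is the structural signature of alternating grip.
#'
#' @param table `helimsm_contact_table`
#' @param members list of two integer vectors (`c1`, `c2`) of protein
#'   residue numbers lining each constriction
#' @param dna_chain chain id of the DNA (default "D")
#' @return data.frame `state`, `c1`, `c2`
#' @export
constriction_contact_counts <- function(table, members, dna_chain = "D") {
  states <- sort(unique(table$state))
  cnt <- function(s, set) {
    t2 <- table[table$state == s & table$persistent, ]
    ca <- contact_chains(t2$res_a); cb <- contact_chains(t2$res_b)
    ra <- contact_residues(t2$res_a); rb <- contact_residues(t2$res_b)
    pd <- (ca == dna_chain & cb != dna_chain & rb %in% set) |
          (cb == dna_chain & ca != dna_chain & ra %in% set)
    sum(pd)
  }
  data.frame(state = states,
             c1 = vapply(states, cnt, 0, set = members$c1),
             c2 = vapply(states, cnt, 0, set = members$c2))
}
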