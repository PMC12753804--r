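#' @useDynLib helimsm, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats kmeans rnorm runif sd setNames aggregate
#' @importFrom utils read.csv write.csv head tail modifyList
NULL

DOMAIN_LEVELS <- c("RecA1", "RecA2", "Arch", "FeS", "DNA", "other")
DNA_RESNAMES <- c("DA", "DC", "DG", "DT", "A", "C", "G", "T", "U", "DU")

#' Construct a topology
#'
#' A topology is the static description of the molecular system: one row per
#' atom with identity, residue bookkeeping, a structural-domain label
#' (RecA1/RecA2/Arch/FeS for the helicase, DNA for the nucleic acid, `other`
#' for everything else), and the chemical classes used by the typed contact
#' detectors (hydrogen-bond donor/acceptor flags, charge class, aromatic ring
#' membership, nonpolar flag).
#'
#' @param atoms data.frame with columns `atom_id`, `atom_name`, `element`,
#'   `residue_name`, `residue_number`, `chain_id`, `domain_label`,
#'   `hbond_donor`, `hbond_acceptor`, `charge_class`, `aromatic_ring_id`,
#'   `nonpolar`, `mass`.
#' @return object of class `helimsm_topology`
#' @export
new_topology <- function(atoms) {
  required <- c("atom_id", "atom_name", "element", "residue_name",
                "residue_number", "chain_id", "domain_label", "hbond_donor",
                "hbond_acceptor", "charge_class", "aromatic_ring_id",
                "nonpolar", "mass")
  missing <- setdiff(required, names(atoms))
  if (length(missing) > 0)
    stop("topology atoms missing columns: ", paste(missing, collapse = ", "))
  if (anyDuplicated(atoms$atom_id))
    stop("duplicate atom_id in topology")
  if (!all(atoms$atom_id == seq_len(nrow(atoms))))
    stop("atom_ids must be dense 1..n in order")
  if (!all(atoms$domain_label %in% DOMAIN_LEVELS))
    stop("invalid domain_label")
  if (!all(atoms$charge_class %in% c("positive", "negative", "neutral")))
    stop("invalid charge_class")
  # residue numbering monotone within each chain
  for (ch in unique(atoms$chain_id)) {
    rn <- atoms$residue_number[atoms$chain_id == ch]
    if (is.unsorted(rn)) stop("residue numbering not monotone in chain ", ch)
  }
  rid <- !is.na(atoms$aromatic_ring_id)
  if (any(rid)) {
    grp <- paste(atoms$chain_id, atoms$residue_number,
                 atoms$aromatic_ring_id)[rid]
    if (any(table(grp) < 5))
      stop("aromatic ring groups must contain at least 5 atoms")
  }
  structure(list(atoms = atoms), class = "helimsm_topology")
}

#' @export
print.helimsm_topology <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("helimsm topology: %d atoms, %d residues, chains %s\n",
              nrow(a), length(unique(paste(a$chain_id, a$residue_number))),
              paste(unique(a$chain_id), collapse = ",")))
  tab <- table(a$domain_label)
  cat("  domains:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  invisible(x)
}

n_atoms <- function(topology) nrow(topology$atoms)

#' Construct a trajectory
#'
#' @param coordinates numeric array frames x atoms x 3, in Angstrom.
#' @param frame_interval time between frames in picoseconds.
#' @param topology optional `helimsm_topology`; when given the atom count is
#'   checked.
#' @return object of class `helimsm_trajectory`
#' @export
new_trajectory <- function(coordinates, frame_interval, topology = NULL) {
  if (length(dim(coordinates)) != 3 || dim(coordinates)[3] != 3)
    stop("coordinates must be a frames x atoms x 3 array")
  if (!all(is.finite(coordinates))) stop("non-finite coordinates")
  if (!is.numeric(frame_interval) || frame_interval <= 0)
    stop("frame_interval must be positive (picoseconds)")
  if (!is.null(topology) && dim(coordinates)[2] != n_atoms(topology))
    stop("atom count mismatch between coordinates and topology")
  structure(list(coordinates = coordinates,
                 frame_interval = frame_interval),
            class = "helimsm_trajectory")
}

#' @export
print.helimsm_trajectory <- function(x, ...) {
  d <- dim(x$coordinates)
  cat(sprintf("helimsm trajectory: %d frames x %d atoms, dt = %g ps\n",
              d[1], d[2], x$frame_interval))
  invisible(x)
}

n_frames <- function(traj) dim(traj$coordinates)[1]

#' One frame of a trajectory as an atoms x 3 matrix
#' @param traj a `helimsm_trajectory`
#' @param i frame index (1-based)
#' @export
get_frame <- function(traj, i) {
  stopifnot(i >= 1, i <= n_frames(traj))
  matrix(traj$coordinates[i, , ], ncol = 3)
}

# ---- chemical classification -------------------------------------------------

#' Residue chemistry table
#'
#' Loads the packaged residue/atom chemical-class table covering the 20
#' standard amino acids and DNA nucleotides. Charge conventions follow
#' physiological-pH defaults: Arg/Lys side chains positive, Asp/Glu negative,
#' His neutral (donor and acceptor on both ring nitrogens), phosphate oxygens
#' negative.
#'
#' @return data.frame with columns `residue_name`, `atom_name`,
#'   `hbond_donor`, `hbond_acceptor`, `charge_class`, `aromatic_ring_id`,
#'   `nonpolar`
#' @export
chem_class_table <- function() {
  path <- system.file("extdata", "chem_classes.csv", package = "helimsm")
  read.csv(path, stringsAsFactors = FALSE,
           colClasses = c(aromatic_ring_id = "character"))
}

ELEMENT_MASSES <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                    P = 30.974, S = 32.06, FE = 55.845, MG = 24.305,
                    X = 12.0)

element_mass <- function(element) {
  m <- ELEMENT_MASSES[toupper(element)]
  m[is.na(m)] <- ELEMENT_MASSES[["X"]]
  unname(m)
}

classify_atoms <- function(atoms, rules = chem_class_table()) {
  key <- paste(atoms$residue_name, atoms$atom_name)
  rkey <- paste(rules$residue_name, rules$atom_name)
  idx <- match(key, rkey)
  known_res <- atoms$residue_name %in% unique(rules$residue_name)
  unknown <- unique(atoms$residue_name[!known_res])
  if (length(unknown) > 0)
    warning("unknown residues classified with neutral defaults: ",
            paste(unknown, collapse = ", "))
  atoms$hbond_donor <- ifelse(is.na(idx), FALSE, rules$hbond_donor[idx])
  atoms$hbond_acceptor <- ifelse(is.na(idx), FALSE, rules$hbond_acceptor[idx])
  atoms$charge_class <- ifelse(is.na(idx), "neutral", rules$charge_class[idx])
  ring <- rules$aromatic_ring_id[idx]
  ring[!is.na(ring) & ring == ""] <- NA
  atoms$aromatic_ring_id <- ring
  atoms$nonpolar <- ifelse(is.na(idx), FALSE, rules$nonpolar[idx])
  atoms
}

# ---- PDB I/O -----------------------------------------------------------------

#' Read a PDB file into a topology
#'
#' Parses ATOM/HETATM records (first MODEL only) and attaches chemical
#' classes from a residue chemistry table. Unknown residues receive neutral,
#' non-donor defaults with a warning.
#'
#' @param path PDB file path
#' @param annotation_rules residue chemistry table (see [chem_class_table()])
#' @return a `helimsm_topology` (all atoms labeled `other`/`DNA`; use
#'   [annotate_domains()] to assign helicase domains)
#' @export
read_pdb_topology <- function(path, annotation_rules = chem_class_table()) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  a <- pdb$atom
  if (anyDuplicated(a$eleno))
    stop("duplicate atom serial within a model: ",
         paste(unique(a$eleno[duplicated(a$eleno)]), collapse = ","))
  elem <- a$elesy
  if (is.null(elem) || all(is.na(elem)) || all(elem == ""))
    elem <- substr(trimws(a$elety), 1, 1)
  atoms <- data.frame(
    atom_id = seq_len(nrow(a)),
    atom_name = trimws(a$elety),
    element = trimws(elem),
    residue_name = trimws(a$resid),
    residue_number = a$resno,
    chain_id = ifelse(is.na(a$chain) | a$chain == "", "A", a$chain),
    domain_label = "other",
    stringsAsFactors = FALSE)
  atoms$domain_label[atoms$residue_name %in% DNA_RESNAMES] <- "DNA"
  atoms <- classify_atoms(atoms, annotation_rules)
  atoms$mass <- element_mass(atoms$element)
  new_topology(atoms)
}

#' Read a multi-model PDB as a trajectory
#'
#' @param path PDB file path with one MODEL block per frame
#' @param topology matching `helimsm_topology`
#' @param frame_interval picoseconds between models
#' @return a `helimsm_trajectory`, frames ordered by MODEL index
#' @export
read_multimodel_trajectory <- function(path, topology, frame_interval) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  nat <- ncol(xyz) / 3
  if (nrow(xyz) < 1) stop("zero models in ", path)
  if (nat != n_atoms(topology)) {
    # identify the first offending model for the error message
    stop(sprintf("atom-count mismatch: topology has %d atoms, model 1 has %d",
                 n_atoms(topology), nat))
  }
  nf <- nrow(xyz)
  coords <- array(0, dim = c(nf, nat, 3))
  for (i in seq_len(nf)) coords[i, , ] <- matrix(xyz[i, ], ncol = 3, byrow = TRUE)
  new_trajectory(coords, frame_interval, topology)
}

#' Write a trajectory as a multi-model PDB
#'
#' Fixed-column PDB dialect with 3-decimal coordinates; one MODEL per frame.
#'
#' @param traj `helimsm_trajectory`
#' @param topology matching `helimsm_topology`
#' @param path output file
#' @export
write_multimodel_pdb <- function(traj, topology, path) {
  a <- topology$atoms
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(n_frames(traj))) {
    writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- get_frame(traj, f)
    rec <- ifelse(a$domain_label == "DNA" | a$residue_name %in% DNA_RESNAMES |
                  nchar(a$residue_name) <= 3, "ATOM  ", "HETATM")
    lines <- sprintf("%-6s%5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                     rec, a$atom_id %% 100000,
                     substr(a$atom_name, 1, 4), substr(a$residue_name, 1, 3),
                     substr(a$chain_id, 1, 1), a$residue_number %% 10000,
                     xyz[, 1], xyz[, 2], xyz[, 3], 1.0, 0.0,
                     substr(a$element, 1, 2))
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Assign helicase domain labels by residue ranges
#'
#' Atoms whose (chain, residue) falls inside a range get that range's label;
#' DNA residues are auto-labeled `DNA`; remaining protein atoms are labeled
#' `other`. Ranges are 1-based and inclusive on both ends.
#'
#' @param topology `helimsm_topology`
#' @param ranges data.frame with columns `chain`, `start_res`, `end_res`,
#'   `label`
#' @return topology with `domain_label` filled in
#' @export
annotate_domains <- function(topology, ranges) {
  a <- topology$atoms
  if (nrow(ranges) > 0) {
    if (!all(ranges$label %in% setdiff(DOMAIN_LEVELS, c("DNA", "other"))))
      stop("range labels must be RecA1/RecA2/Arch/FeS")
    for (ch in unique(ranges$chain)) {
      r <- ranges[ranges$chain == ch, , drop = FALSE]
      r <- r[order(r$start_res), , drop = FALSE]
      if (any(r$end_res < r$start_res)) stop("range with end < start")
      if (nrow(r) > 1 && any(r$start_res[-1] <= r$end_res[-nrow(r)]))
        stop("overlapping ranges in chain ", ch)
    }
  }
  lab <- rep("other", nrow(a))
  is_dna <- a$residue_name %in% DNA_RESNAMES
  lab[is_dna] <- "DNA"
  if (nrow(ranges) > 0) {
    for (i in seq_len(nrow(ranges))) {
      hit <- !is_dna & a$chain_id == ranges$chain[i] &
        a$residue_number >= ranges$start_res[i] &
        a$residue_number <= ranges$end_res[i]
      lab[hit] <- ranges$label[i]
    }
  }
  a$domain_label <- lab
  topology$atoms <- a
  topology
}
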