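# Atoms are kept as a data.frame (one row per heavy atom) with columns:
#   serial, element, x, y, z, formal_charge, hb_class, residue_tag
# This mirrors the atom-table style of bio3d and keeps vectorised geometry
# cheap. hb_class is one of "donor", "acceptor", "both", "nonpolar".

HB_CLASSES <- c("donor", "acceptor", "both", "nonpolar")

new_atom_table <- function(serial, element, x, y, z,
                           formal_charge = 0L,
                           hb_class = NA_character_,
                           residue_tag = NA_character_) {
  df <- data.frame(
    serial = as.integer(serial),
    element = as.character(element),
    x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
    formal_charge = as.integer(formal_charge),
    hb_class = as.character(hb_class),
    residue_tag = as.character(residue_tag),
    stringsAsFactors = FALSE
  )
  if (any(!is.finite(df$x) | !is.finite(df$y) | !is.finite(df$z)))
    stop("atom coordinates must be finite")
  df
}

atom_coords <- function(atoms) as.matrix(atoms[, c("x", "y", "z")])

#' Construct a receptor binding-site object
#'
#' A `receptor_site` is an ordered set of heavy atoms; the ordering is stable
#' and interaction-profile columns refer to it by atom serial.
#'
#' @param atoms atom table (see [read_receptor()]).
#' @param source_id identifier of the structure the atoms came from.
#' @return An object of class `receptor_site`.
#' @export
receptor_site <- function(atoms, source_id = "receptor") {
  stopifnot(is.data.frame(atoms))
  if (nrow(atoms) == 0L) stop("empty structure: receptor has no heavy atoms")
  if (anyDuplicated(atoms$serial))
    stop("receptor atom serials must be unique")
  if (any(atoms$element == "H"))
    stop("receptor_site must not contain hydrogen atoms")
  structure(list(atoms = atoms, source_id = source_id),
            class = "receptor_site")
}

#' @export
print.receptor_site <- function(x, ...) {
  cat(sprintf("<receptor_site> %s: %d heavy atoms, %d residues\n",
              x$source_id, nrow(x$atoms),
              length(unique(x$atoms$residue_tag))))
  invisible(x)
}

#' Construct a docked ligand pose
#'
#' @param pose_id character identifier.
#' @param atoms heavy-atom table.
#' @param bonds data.frame with columns `i`, `j` (1-based atom indices) and
#'   `order` (bond order).
#' @param docked_energy docked (predicted binding) energy, kcal/mol.
#' @return An object of class `ligand_pose`.
#' @export
ligand_pose <- function(pose_id, atoms, bonds, docked_energy) {
  stopifnot(is.data.frame(atoms), is.data.frame(bonds))
  if (nrow(atoms) == 0L) stop("empty pose: no heavy atoms")
  if (any(atoms$element == "H")) stop("ligand_pose must not contain hydrogens")
  if (!is.finite(docked_energy)) stop("docked_energy must be finite")
  if (nrow(bonds)) {
    bad <- bonds$i < 1 | bonds$j < 1 | bonds$i > nrow(atoms) |
      bonds$j > nrow(atoms)
    if (any(bad)) stop("bond references a missing atom")
    if (any(bonds$i == bonds$j)) stop("self-bonds are not allowed")
  }
  structure(list(pose_id = as.character(pose_id), atoms = atoms,
                 bonds = bonds, docked_energy = as.numeric(docked_energy)),
            class = "ligand_pose")
}

#' @export
print.ligand_pose <- function(x, ...) {
  cat(sprintf("<ligand_pose> %s: %d heavy atoms, %d bonds, E = %.2f kcal/mol\n",
              x$pose_id, nrow(x$atoms), nrow(x$bonds), x$docked_energy))
  invisible(x)
}

pdb_charge_to_int <- function(chg) {
  # PDB columns 79-80 hold e.g. "1+", "2-"; bio3d reports them as strings
  out <- integer(length(chg))
  ok <- !is.na(chg) & nzchar(trimws(chg))
  for (k in which(ok)) {
    s <- trimws(chg[k])
    sign <- if (grepl("-", s, fixed = TRUE)) -1L else 1L
    num <- suppressWarnings(as.integer(gsub("[^0-9]", "", s)))
    out[k] <- if (is.na(num)) 0L else sign * num
  }
  out
}

#' Read a receptor structure from a PDB file
#'
#' Parses ATOM/HETATM records of the first model, keeps a single location per
#' atom (blank or 'A' altLoc), strips hydrogens, reads formal charges from
#' columns 79-80 (0 when absent) and assigns hydrogen-bond classes from the
#' residue/atom-name rule table (see [assign_hb_classes()]).
#'
#' @param path path to a PDB file.
#' @param source_id identifier stored on the result; defaults to the file name.
#' @return A [receptor_site()].
#' @export
read_receptor <- function(path, source_id = basename(path)) {
  if (!file.exists(path)) stop("cannot read receptor file: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = TRUE,
                                     verbose = FALSE)),
    error = function(e) stop("failed to parse PDB '", path, "': ",
                             conditionMessage(e)))
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0L)
    stop("empty structure: no ATOM/HETATM records in ", path)
  elem <- gsub("[^A-Za-z]", "", trimws(at$elesy))
  # fall back to the atom name when the element column is blank (common in
  # minimal PDB files)
  blank <- is.na(elem) | !nzchar(elem)
  elem[blank] <- gsub("[^A-Za-z].*$", "",
                      gsub("^[0-9 ]+", "", at$elety[blank]))
  elem <- normalise_element(elem)
  keep <- elem != "H" & elem != "D"
  at <- at[keep, , drop = FALSE]
  elem <- elem[keep]
  if (nrow(at) == 0L) stop("empty structure: no heavy atoms in ", path)
  ins <- ifelse(is.na(at$insert), "", at$insert)
  tag <- sprintf("%s:%s:%s%s", ifelse(is.na(at$chain), "_", at$chain),
                 at$resid, at$resno, ins)
  atoms <- new_atom_table(at$eleno, elem, at$x, at$y, at$z,
                          formal_charge = pdb_charge_to_int(at$charge),
                          residue_tag = tag)
  atoms$atom_name <- trimws(at$elety)
  atoms <- assign_hb_classes(atoms)
  receptor_site(atoms, source_id = source_id)
}

normalise_element <- function(e) {
  e <- trimws(e)
  ifelse(nchar(e) > 1,
         paste0(toupper(substr(e, 1, 1)), tolower(substr(e, 2, nchar(e)))),
         toupper(e))
}

# --- SDF / MOL2 pose reading ------------------------------------------------

# V2000 atom-block charge codes (field 4): 0 none, 1..3 = +3..+1, 4 radical,
# 5..7 = -1..-3. "M  CHG" lines supersede these when present.
v2000_charge_code <- function(code) {
  code <- as.integer(code)
  out <- integer(length(code))
  out[code %in% 1:3] <- 4L - code[code %in% 1:3]
  out[code %in% 5:7] <- 4L - code[code %in% 5:7]
  out
}

# ChemmineR discards "M  CHG" lines, so recover them per record from the raw
# text (records are aligned with read.SDFset output by $$$$ order).
sdf_record_charges <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec_end <- grep("^\\$\\$\\$\\$", lines)
  rec_start <- c(1L, head(rec_end, -1L) + 1L)
  if (!length(rec_end)) { rec_start <- 1L; rec_end <- length(lines) }
  lapply(seq_along(rec_end), function(k) {
    rec <- lines[rec_start[k]:rec_end[k]]
    chg <- grep("^M  CHG", rec, value = TRUE)
    out <- list()
    for (ln in chg) {
      f <- as.integer(strsplit(trimws(substring(ln, 7)), "\\s+")[[1]])
      n <- f[1]
      for (p in seq_len(n)) out[[length(out) + 1L]] <- f[c(2 * p, 2 * p + 1)]
    }
    out
  })
}

pose_from_sdf <- function(sdf, mchg, pose_id, energy) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elem <- normalise_element(gsub("_[0-9]+$", "", rownames(ab)))
  n <- nrow(ab)
  charge <- integer(n)
  # atom-block charge code column is C8 in ChemmineR's matrix when present
  if ("C8" %in% colnames(ab)) charge <- v2000_charge_code(ab[, "C8"])
  for (fc in mchg) if (fc[1] >= 1 && fc[1] <= n) charge[fc[1]] <- fc[2]
  bonds <- data.frame(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
                      order = as.integer(bb[, 3]))
  atoms <- new_atom_table(seq_len(n), elem, ab[, 1], ab[, 2], ab[, 3],
                          formal_charge = charge)
  # strip hydrogens and remap bonds onto the heavy-atom indexing
  heavy <- which(atoms$element != "H" & atoms$element != "D")
  if (!length(heavy)) stop("empty pose: molecule '", pose_id,
                           "' has no heavy atoms")
  map <- match(seq_len(n), heavy)
  bonds <- bonds[bonds$i %in% heavy & bonds$j %in% heavy, , drop = FALSE]
  bonds$i <- map[bonds$i]; bonds$j <- map[bonds$j]
  atoms <- atoms[heavy, , drop = FALSE]
  atoms$serial <- seq_len(nrow(atoms))
  rownames(atoms) <- NULL
  atoms <- assign_hb_classes(atoms, bonds = bonds)
  ligand_pose(pose_id, atoms, bonds, energy)
}

#' Read docked ligand poses from an SDF (or MOL2) file
#'
#' Hydrogens are stripped on load; formal charges are taken from `M CHG`
#' lines or the atom-block charge code (0 when absent); per-pose docked
#' energies are read from a named SDF data field. MOL2 input is converted to
#' SDF via OpenBabel (ChemmineOB) and read through the same path.
#'
#' @param path SDF (`.sdf`/`.sd`/`.mol`) or MOL2 (`.mol2`) file.
#' @param energy_field name of the SDF property holding the docked energy.
#' @param default_energy if non-`NULL`, used when the energy field is absent;
#'   otherwise a missing field is an error.
#' @return List of [ligand_pose()] objects, in file order, with unique
#'   `pose_id`s derived from molecule titles.
#' @export
read_poses <- function(path, energy_field = "docked_energy",
                       default_energy = NULL) {
  if (!file.exists(path)) stop("cannot read pose file: ", path)
  if (grepl("\\.mol2$", path, ignore.case = TRUE)) {
    if (!requireNamespace("ChemmineOB", quietly = TRUE))
      stop("MOL2 input requires the ChemmineOB package")
    tmp <- tempfile(fileext = ".sdf")
    on.exit(unlink(tmp), add = TRUE)
    # "3": keep the 3D coordinates instead of regenerating a 2D layout
    ChemmineOB::convertFormatFile("MOL2", "SDF", path, tmp,
                                  options = data.frame(names = "3",
                                                       args = ""))
    path <- tmp
  }
  sdfs <- suppressWarnings(ChemmineR::read.SDFset(path))
  valid <- ChemmineR::validSDF(sdfs)
  if (!any(valid)) stop("no valid molecule records in ", path)
  charges <- sdf_record_charges(path)[valid]
  sdfs <- sdfs[which(valid)]
  titles <- vapply(ChemmineR::SDFset2SDF(sdfs), function(s)
    trimws(ChemmineR::header(s)[[1]]), character(1))
  titles[!nzchar(titles)] <- sprintf("mol%d", which(!nzchar(titles)))
  ids <- make.unique(titles, sep = "_")
  out <- vector("list", length(sdfs))
  for (k in seq_along(out)) {
    sdf <- sdfs[[k]]
    db <- ChemmineR::datablock(sdf)
    if (energy_field %in% names(db)) {
      energy <- suppressWarnings(as.numeric(db[[energy_field]]))
      if (is.na(energy)) stop("non-numeric energy field in record ", k)
    } else if (!is.null(default_energy)) {
      energy <- default_energy
    } else {
      stop("record ", k, " ('", ids[k], "') lacks energy field '",
           energy_field, "'; set default_energy to override")
    }
    out[[k]] <- pose_from_sdf(sdf, charges[[k]], ids[k], energy)
  }
  out
}

# --- hydrogen-bond donor/acceptor classification ----------------------------

# Residue/atom-name rules for protein atoms (hydrogens are absent, so donor
# character is inferred from standard amino-acid chemistry).
PROTEIN_HB_RULES <- list(
  donor = c("LYS:NZ", "ARG:NE", "ARG:NH1", "ARG:NH2", "TRP:NE1",
            "ASN:ND2", "GLN:NE2"),
  acceptor = c("ASP:OD1", "ASP:OD2", "GLU:OE1", "GLU:OE2",
               "ASN:OD1", "GLN:OE1", "MET:SD", "CYS:SG"),
  both = c("SER:OG", "THR:OG1", "TYR:OH", "HIS:ND1", "HIS:NE2",
           "HOH:O", "WAT:O")
)

classify_protein_atom <- function(element, resname, atom_name) {
  key <- paste0(resname, ":", atom_name)
  if (key %in% PROTEIN_HB_RULES$donor) return("donor")
  if (key %in% PROTEIN_HB_RULES$acceptor) return("acceptor")
  if (key %in% PROTEIN_HB_RULES$both) return("both")
  if (element == "N") {
    if (atom_name == "N") return("donor")      # backbone amide
    return("donor")
  }
  if (element == "O") return("acceptor")        # backbone carbonyl, OXT, misc
  if (element == "S") return("acceptor")
  "nonpolar"
}

classify_ligand_atom <- function(k, atoms, bonds) {
  elem <- atoms$element[k]
  chg <- atoms$formal_charge[k]
  deg_rows <- bonds$i == k | bonds$j == k
  total_order <- sum(bonds$order[deg_rows])
  n_nbr <- sum(deg_rows)
  if (elem == "N") {
    # implicit hydrogens: standard valence 3 (+1 per positive charge)
    if (total_order < 3L + max(0L, chg)) return("donor")
    return(if (chg > 0) "donor" else "acceptor")
  }
  if (elem == "O") {
    if (chg < 0) return("acceptor")                      # carboxylate/oxide
    if (n_nbr >= 2) return("acceptor")                   # ether/ester
    if (any(bonds$order[deg_rows] >= 2)) return("acceptor")  # carbonyl
    return("both")                                       # hydroxyl (implicit H)
  }
  if (elem == "S") return("acceptor")
  "nonpolar"
}

#' Assign hydrogen-bond donor/acceptor classes to atoms
#'
#' Classes are inferred from heavy-atom context only (hydrogens are stripped
#' on load): for ligand atoms the bonded graph fixes implicit-hydrogen counts
#' (N below its valence is a donor; singly-bonded neutral O is a hydroxyl,
#' class "both"; carbonyl/ether/charged O and S are acceptors); for receptor
#' atoms a residue/atom-name table encodes standard amino-acid chemistry.
#' Carbon, phosphorus, halogens and unknown elements are "nonpolar" (unknown
#' elements with a warning). The assignment is deterministic and idempotent.
#'
#' @param atoms atom table.
#' @param bonds optional bond table (`i`, `j`, `order`); when supplied the
#'   ligand valence rules are used, otherwise the receptor name rules.
#' @return The atom table with `hb_class` filled in.
#' @export
assign_hb_classes <- function(atoms, bonds = NULL) {
  known <- c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I")
  unknown <- setdiff(unique(atoms$element), c(known, "H", "D"))
  if (length(unknown))
    warning("unknown element(s) classed nonpolar: ",
            paste(unknown, collapse = ", "))
  cls <- character(nrow(atoms))
  if (is.null(bonds)) {
    resname <- sub("^[^:]*:", "", atoms$residue_tag)
    resname <- sub(":.*$", "", sub("[0-9].*$", "", resname))
    an <- if ("atom_name" %in% names(atoms)) atoms$atom_name
          else atoms$element
    for (k in seq_len(nrow(atoms)))
      cls[k] <- classify_protein_atom(atoms$element[k], resname[k], an[k])
  } else {
    for (k in seq_len(nrow(atoms)))
      cls[k] <- classify_ligand_atom(k, atoms, bonds)
  }
  atoms$hb_class <- cls
  atoms
}

#' Extract the ligand binding site from a receptor
#'
#' Membership is residue-level: every atom of any residue having at least one
#' atom within `radius` of at least one reference-ligand atom is returned, in
#' the receptor's original atom order. The default 10 Angstrom radius follows
#' common lead-discovery practice (8-12 Angstrom pockets).
#'
#' @param receptor a [receptor_site()].
#' @param reference_ligand a [ligand_pose()] (or atom table) anchoring the
#'   site, typically the crystallographic bound ligand.
#' @param radius cutoff radius in Angstrom.
#' @return A [receptor_site()] restricted to the binding-site residues.
#' @export
extract_binding_site <- function(receptor, reference_ligand, radius = 10) {
  stopifnot(inherits(receptor, "receptor_site"), radius > 0)
  lig_atoms <- if (inherits(reference_ligand, "ligand_pose"))
    reference_ligand$atoms else reference_ligand
  if (NROW(lig_atoms) == 0L) stop("reference ligand is empty")
  d <- cross_distances(atom_coords(receptor$atoms), atom_coords(lig_atoms))
  near <- apply(d, 1L, min) <= radius
  keep_res <- unique(receptor$atoms$residue_tag[near])
  keep <- receptor$atoms$residue_tag %in% keep_res
  if (!any(keep)) stop("empty binding site at radius ", radius)
  receptor_site(receptor$atoms[keep, , drop = FALSE],
                source_id = paste0(receptor$source_id, ":site"))
}

# Euclidean cross-distance matrix between two coordinate sets (rows = points)
cross_distances <- function(a, b) {
  a2 <- rowSums(a^2); b2 <- rowSums(b^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}
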