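# Piecewise-linear potential (PLP) interaction profiles.
#
# Every docked pose is converted into a real-valued vector indexed by
# binding-site atoms: entry j is the summed pairwise energy that protein
# atom j receives from all ligand heavy atoms, i.e.
#   E_j = sum_i [ f_PLP(r_ij; params[class(i,j)]) + 332.0 q_i q_j / r_ij ],
# where the pair class is "hbond" when one atom is a donor (or both) and the
# other an acceptor (or both), and "steric" otherwise.

#' PLP parameter set for one interaction class
#'
#' The potential is a trapezoidal well defined by four breakpoint distances
#' and two energies: value `V5` (repulsive contact penalty) at r = 0 falling
#' linearly to 0 at `V1`; 0 at `V1` falling to the well depth `V6` at `V2`;
#' flat `V6` on `[V2, V3]`; rising linearly back to 0 at `V4`; 0 beyond `V4`.
#'
#' @param V1,V2,V3,V4 breakpoint distances in Angstrom, strictly increasing.
#' @param V5 contact penalty, kcal/mol, >= 0.
#' @param V6 well depth, kcal/mol, <= 0.
#' @return An object of class `plp_params`.
#' @export
plp_params <- function(V1, V2, V3, V4, V5, V6) {
  v <- c(V1 = V1, V2 = V2, V3 = V3, V4 = V4, V5 = V5, V6 = V6)
  if (any(!is.finite(v))) stop("PLP parameters must be finite")
  if (!(V1 < V2 && V2 < V3 && V3 < V4))
    stop("invalid PLP parameters: need V1 < V2 < V3 < V4")
  if (V5 < 0 || V6 > 0)
    stop("invalid PLP parameters: need V5 >= 0 and V6 <= 0")
  structure(as.list(v), class = "plp_params")
}

#' Default PLP parameters (hydrogen-bond and steric classes)
#'
#' Reads the parameter file shipped with the package
#' (`inst/extdata/plp_params.json`), which follows the published GEMDOCK/PLP
#' convention: a narrow deep well for hydrogen bonds and a wider shallow well
#' for steric contacts. Any value can be overridden by editing a copy of the
#' file or constructing [plp_params()] directly.
#'
#' @param path optional path to an alternative JSON parameter file with
#'   top-level keys `hbond` and `steric`.
#' @return Named list with elements `hbond` and `steric`, each a
#'   [plp_params()], plus `es_cutoff` and `epsilon` defaults from the file.
#' @export
default_plp_params <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "plp_params.json", package = "tscc",
                        mustWork = TRUE)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(
    hbond = do.call(plp_params, as.list(cfg$plp$hbond)),
    steric = do.call(plp_params, as.list(cfg$plp$steric)),
    es_cutoff = cfg$plp$es_cutoff,
    epsilon = cfg$plp$epsilon
  )
}

#' Piecewise-linear pair potential
#'
#' @param r distance(s) in Angstrom, >= 0; vectorised.
#' @param params a [plp_params()].
#' @return Energy in kcal/mol, continuous in r, zero beyond `V4`.
#' @export
plp_energy <- function(r, params) {
  if (!inherits(params, "plp_params")) params <- do.call(plp_params, params)
  if (any(r < 0)) stop("distances must be non-negative")
  V1 <- params$V1; V2 <- params$V2; V3 <- params$V3; V4 <- params$V4
  V5 <- params$V5; V6 <- params$V6
  e <- numeric(length(r))
  seg <- r < V1
  e[seg] <- V5 * (V1 - r[seg]) / V1
  seg <- r >= V1 & r < V2
  e[seg] <- V6 * (r[seg] - V1) / (V2 - V1)
  seg <- r >= V2 & r <= V3
  e[seg] <- V6
  seg <- r > V3 & r < V4
  e[seg] <- V6 * (V4 - r[seg]) / (V4 - V3)
  e
}

#' Coulomb electrostatic pair energy
#'
#' `332.0 * q_i * q_j / r` kcal/mol between formally charged atom pairs
#' within the cutoff; zero when either charge is zero or r exceeds the
#' cutoff. 332.0 converts e^2/Angstrom to kcal/mol.
#'
#' @param q_i,q_j formal charges in elementary-charge units; vectorised.
#' @param r distance(s) in Angstrom, > 0.
#' @param cutoff hard distance cutoff in Angstrom.
#' @return Energy in kcal/mol.
#' @export
electrostatic_energy <- function(q_i, q_j, r, cutoff = 12) {
  if (any(r <= 0)) stop("degenerate geometry: overlapping atoms (r = 0)")
  e <- 332.0 * q_i * q_j / r
  e[q_i == 0 | q_j == 0 | r > cutoff] <- 0
  e
}

#' Classify an atom pair as hydrogen-bonding or steric
#'
#' A pair is class `"hbond"` when one member can donate and the other accept
#' (class "both" counts as either); every other pair is `"steric"`. The
#' classification is symmetric in its arguments.
#'
#' @param class_a,class_b hb classes (`donor`/`acceptor`/`both`/`nonpolar`);
#'   vectorised.
#' @return Character vector of `"hbond"` / `"steric"`.
#' @export
classify_pair <- function(class_a, class_b) {
  donor_a <- class_a %in% c("donor", "both")
  donor_b <- class_b %in% c("donor", "both")
  acc_a <- class_a %in% c("acceptor", "both")
  acc_b <- class_b %in% c("acceptor", "both")
  ifelse((donor_a & acc_b) | (donor_b & acc_a), "hbond", "steric")
}

#' Interaction-energy profile of one docked pose
#'
#' Computes, for every binding-site atom j, the total PLP + electrostatic
#' energy summed over all ligand heavy atoms.
#'
#' @param site a [receptor_site()].
#' @param pose a [ligand_pose()].
#' @param params per-class PLP parameters as returned by
#'   [default_plp_params()] (elements `hbond`, `steric`).
#' @param es_cutoff electrostatic cutoff in Angstrom.
#' @param include_electrostatics set `FALSE` to profile the PLP term alone.
#' @return An object of class `interaction_profile`: list with `pose_id` and
#'   `energies`, a named numeric vector keyed by site atom serial.
#' @export
atom_profile <- function(site, pose, params = default_plp_params(),
                         es_cutoff = 12, include_electrostatics = TRUE) {
  stopifnot(inherits(site, "receptor_site"), inherits(pose, "ligand_pose"))
  pa <- site$atoms; la <- pose$atoms
  r <- cross_distances(atom_coords(pa), atom_coords(la))  # site x ligand
  if (any(r == 0)) {
    idx <- which(r == 0, arr.ind = TRUE)[1, ]
    stop(sprintf(
      "degenerate geometry: site atom %s overlaps ligand atom %s",
      pa$serial[idx[1]], la$serial[idx[2]]))
  }
  cls <- outer(pa$hb_class, la$hb_class, classify_pair)
  e <- matrix(0, nrow(pa), nrow(la))
  hb <- cls == "hbond"
  e[hb] <- plp_energy(r[hb], params$hbond)
  e[!hb] <- plp_energy(r[!hb], params$steric)
  if (include_electrostatics) {
    qq <- outer(pa$formal_charge, la$formal_charge)
    es <- 332.0 * qq / r
    es[qq == 0 | r > es_cutoff] <- 0
    e <- e + es
  }
  energies <- rowSums(e)
  names(energies) <- pa$serial
  structure(list(pose_id = pose$pose_id, energies = energies),
            class = "interaction_profile")
}

#' Stack interaction profiles into a pose-by-atom matrix
#'
#' Receptor atoms never touched by any pose (|E| < `epsilon` everywhere) are
#' dropped; the surviving columns are the "involved atoms". Retained values
#' are unmodified and row order follows the input profiles.
#'
#' @param profiles list of `interaction_profile` objects sharing one site.
#' @param epsilon involvement tolerance in kcal/mol.
#' @param atom_labels optional character labels (e.g.
#'   `chain:resname:resnum:atomname`) for the columns, named by atom serial.
#' @return An object of class `profile_matrix`: list with `values` (poses x
#'   atoms matrix), `pose_ids`, `atom_serials`.
#' @export
build_profile_matrix <- function(profiles, epsilon = 1e-6,
                                 atom_labels = NULL) {
  stopifnot(length(profiles) >= 1L)
  serials <- names(profiles[[1]]$energies)
  for (p in profiles)
    if (!identical(names(p$energies), serials))
      stop("profiles do not share a receptor site")
  m <- do.call(rbind, lapply(profiles, `[[`, "energies"))
  rownames(m) <- vapply(profiles, `[[`, character(1), "pose_id")
  keep <- apply(abs(m) >= epsilon, 2L, any)
  if (!any(keep)) stop("empty matrix: no involved atoms at epsilon ", epsilon)
  m <- m[, keep, drop = FALSE]
  kept_serials <- serials[keep]
  if (!is.null(atom_labels))
    colnames(m) <- unname(atom_labels[kept_serials])
  structure(list(values = m, pose_ids = rownames(m),
                 atom_serials = kept_serials),
            class = "profile_matrix")
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat(sprintf("<profile_matrix> %d poses x %d involved atoms\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Write a profile matrix as TSV
#'
#' Header row holds atom labels (or serials), one row per pose.
#' @param pm a `profile_matrix`.
#' @param path output file.
#' @export
write_profile_matrix <- function(pm, path) {
  df <- data.frame(pose_id = pm$pose_ids, pm$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
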