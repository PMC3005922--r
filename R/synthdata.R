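# Deterministic synthetic fixtures: a point-atom spherical pocket, docked
# pose sets drawn from geometrically distinct binding modes, and families of
# small molecular graphs sharing scaffolds. Everything is reproducible from
# the spec seed, so the full pipeline can be exercised without external data.

#' Synthetic-data specification
#'
#' @param n_site_atoms heavy atoms in the toy pocket.
#' @param n_modes number of distinct binding modes.
#' @param poses_per_mode docked poses generated per mode.
#' @param noise_sigma isotropic per-pose coordinate jitter, Angstrom.
#' @param n_scaffolds number of molecular scaffold families.
#' @param molecules_per_scaffold compounds per family.
#' @param seed integer random seed; identical spec + seed give identical
#'   output.
#' @return An object of class `synth_spec`.
#' @export
synth_spec <- function(n_site_atoms = 32L, n_modes = 2L,
                       poses_per_mode = 10L, noise_sigma = 0.25,
                       n_scaffolds = 2L, molecules_per_scaffold = 10L,
                       seed = 42L) {
  stopifnot(n_site_atoms >= 1, n_modes >= 1, poses_per_mode >= 1,
            noise_sigma >= 0, n_scaffolds >= 1, molecules_per_scaffold >= 1)
  structure(list(n_site_atoms = as.integer(n_site_atoms),
                 n_modes = as.integer(n_modes),
                 poses_per_mode = as.integer(poses_per_mode),
                 noise_sigma = noise_sigma,
                 n_scaffolds = as.integer(n_scaffolds),
                 molecules_per_scaffold = as.integer(molecules_per_scaffold),
                 seed = as.integer(seed)),
            class = "synth_spec")
}

# run code under a derived seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed %% .Machine$integer.max)
  force(code)
}

POCKET_RADIUS <- 8    # Angstrom; site atoms sit on this shell
ANCHOR_RADIUS <- 3.0  # ligand anchors sit this far from the pocket centre
LIGAND_BALL <- 2.0    # ligand atoms stay within this radius of their anchor

#' Generate a toy point-atom receptor pocket
#'
#' Heavy atoms are spread over a sphere of radius 8 Angstrom (golden-spiral
#' layout with a little seeded jitter), grouped into 4-atom pseudo-residues.
#' Elements cycle through C/N/O/S so that donor, acceptor, "both"
#' (a SER-like hydroxyl) and nonpolar classes all occur, and the first N/O
#' pair carries formal charges +1/-1.
#'
#' @param spec a [synth_spec()].
#' @return A [receptor_site()].
#' @export
make_receptor <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  n <- spec$n_site_atoms
  with_seed(spec$seed * 7L + 1L, {
    k <- seq_len(n)
    phi <- acos(1 - 2 * (k - 0.5) / n)
    theta <- pi * (1 + sqrt(5)) * (k - 0.5)
    r <- POCKET_RADIUS + stats::rnorm(n, 0, 0.15)
    x <- r * sin(phi) * cos(theta)
    y <- r * sin(phi) * sin(theta)
    z <- r * cos(phi)
    elements <- rep(c("C", "N", "O", "S"), length.out = n)
    charge <- integer(n)
    charge[match("N", elements)] <- 1L
    charge[match("O", elements)] <- -1L
    resno <- (k - 1L) %/% 4L + 1L
    resname <- rep("SYN", n)
    atom_name <- paste0(elements, (k - 1L) %% 4L + 1L)
    # one SER-like hydroxyl so the "both" class occurs
    o_first <- match("O", elements)
    if (!is.na(o_first)) {
      resname[resno == resno[o_first]] <- "SER"
      atom_name[o_first] <- "OG"
    }
    atoms <- new_atom_table(k, elements, x, y, z, formal_charge = charge,
                            residue_tag = sprintf("A:%s:%d", resname, resno))
    atoms$atom_name <- atom_name
    atoms <- assign_hb_classes(atoms)
    receptor_site(atoms, source_id = sprintf("synth-%d", spec$seed))
  })
}

mode_anchor <- function(mode, n_modes) {
  ang <- 2 * pi * (mode - 1) / n_modes
  ANCHOR_RADIUS * c(cos(ang), sin(ang), 0)
}

# fixed direction template of a binding mode: a mode is a conserved
# interaction geometry, so every compound docked in that mode places its
# atoms along the same (mode-seeded) direction sequence
mode_dirs <- function(seed, mode, n = 64L) {
  with_seed(seed * 101L + mode, {
    m <- matrix(stats::rnorm(3L * n), n, 3L)
    m / sqrt(rowSums(m^2))
  })
}

# embed a bond graph in 3D as a breadth-first tree rooted at `anchor`,
# step length 1.5 Angstrom, taking the step direction for the k-th placed
# atom from the mode's template; growth is clamped to a small ball around
# the anchor so every embedding stays a localized binding mode
embed_graph <- function(g, anchor, dirs, pocket = LIGAND_BALL) {
  n <- length(g$node_types)
  coords <- matrix(NA_real_, n, 3L)
  d <- topo_distances(g)
  root <- 1L
  coords[root, ] <- anchor
  ord <- order(d[root, ])
  for (k in ord[-1]) {
    nbrs <- c(g$edges[g$edges[, 2] == k, 1], g$edges[g$edges[, 1] == k, 2])
    parent <- nbrs[which(!is.na(coords[nbrs, 1]))[1]]
    if (is.na(parent)) parent <- root  # disconnected: keep near anchor
    dir <- dirs[(k - 1L) %% nrow(dirs) + 1L, ]
    pos <- coords[parent, ] + 1.5 * dir
    if (sqrt(sum((pos - anchor)^2)) > pocket) {
      pull <- anchor - coords[parent, ]
      pull <- pull / max(sqrt(sum(pull^2)), 1e-6)
      tangent <- dir - sum(dir * pull) * pull
      dir <- pull + 0.8 * tangent
      dir <- dir / sqrt(sum(dir^2))
      pos <- coords[parent, ] + 1.5 * dir
    }
    coords[k, ] <- pos
  }
  coords
}

default_pose_graph <- function() {
  # trivial chain ligand: C-C-N-O-C-C with a charged amine variant handled
  # by the caller; chain bonds let the same object flow through both stages
  mol_graph(c("C", "C", "N", "O", "C", "C"),
            cbind(1:5, 2:6))
}

graph_to_pose <- function(g, coords, pose_id, energy, charge = NULL) {
  n <- length(g$node_types)
  if (is.null(charge)) charge <- integer(n)
  atoms <- new_atom_table(seq_len(n), g$node_types,
                          coords[, 1], coords[, 2], coords[, 3],
                          formal_charge = charge)
  bonds <- data.frame(i = as.integer(g$edges[, 1]),
                      j = as.integer(g$edges[, 2]),
                      order = 1L)
  atoms <- assign_hb_classes(atoms, bonds = bonds)
  ligand_pose(pose_id, atoms, bonds, energy)
}

#' Generate a multi-mode synthetic pose set
#'
#' Each binding mode anchors a small chain ligand in a distinct angular
#' sub-region of the pocket; poses within a mode differ by isotropic
#' Gaussian jitter of `noise_sigma` and by their (uniform, reproducible)
#' docked energies. The first pose of every mode carries a +1 amine charge
#' so charged interactions are exercised.
#'
#' @param spec a [synth_spec()].
#' @param site the receptor from [make_receptor()] (fixes the geometry
#'   convention; not otherwise used).
#' @return List with `poses` (list of [ligand_pose()]) and `mode`
#'   (integer ground-truth labels, named by pose id).
#' @export
make_pose_set <- function(spec, site) {
  stopifnot(inherits(spec, "synth_spec"))
  with_seed(spec$seed * 7L + 2L, {
    g <- default_pose_graph()
    base <- lapply(seq_len(spec$n_modes), function(m)
      embed_graph(g, mode_anchor(m, spec$n_modes),
                  mode_dirs(spec$seed, m)))
    poses <- list(); mode <- integer(0)
    for (m in seq_len(spec$n_modes)) {
      for (p in seq_len(spec$poses_per_mode)) {
        coords <- base[[m]]
        if (spec$noise_sigma > 0)
          coords <- coords + matrix(stats::rnorm(length(coords), 0,
                                                 spec$noise_sigma),
                                    ncol = 3L)
        id <- sprintf("m%d_p%02d", m, p)
        # protonation is a compound property shared by all of a compound's
        # poses; odd-numbered modes dock the protonated amine form, even
        # modes the neutral form, so charged pairs occur without a charge
        # column common to every pose
        charge <- integer(length(g$node_types))
        if (m %% 2L == 1L) charge[3L] <- 1L
        energy <- stats::runif(1, -12, -6)
        poses[[id]] <- graph_to_pose(g, coords, id, energy, charge)
        mode <- c(mode, m)
      }
    }
    names(mode) <- names(poses)
    list(poses = poses, mode = mode)
  })
}

#' Generate scaffold-sharing molecular graph families
#'
#' Family k is built around a 6-ring scaffold whose 1- and 4-positions carry
#' that family's marker heteroatom (N, O, S, P, ... cycled), extended by a
#' 3-carbon tail; members differ by 1-3 random single-atom decorations. The
#' marker makes within-family atom-pair fingerprints systematically closer
#' than across-family ones.
#'
#' @param spec a [synth_spec()].
#' @return List with `graphs` (named list of [mol_graph()]) and `family`
#'   (integer labels, named by molecule id).
#' @export
make_molecule_families <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  markers <- rep(c("N", "O", "S", "P", "F", "Cl", "Br", "I"),
                 length.out = spec$n_scaffolds)
  with_seed(spec$seed * 7L + 3L, {
    graphs <- list(); family <- integer(0)
    for (f in seq_len(spec$n_scaffolds)) {
      het <- markers[f]
      types <- c(het, "C", "C", het, "C", "C", "C", "C", "C")
      edges <- rbind(cbind(1:5, 2:6), c(6, 1),      # ring
                     c(2, 7), c(7, 8), c(8, 9))     # tail
      for (c_idx in seq_len(spec$molecules_per_scaffold)) {
        t2 <- types; e2 <- edges
        n_dec <- sample(1:3, 1)
        for (d in seq_len(n_dec)) {
          at <- sample(seq_along(types), 1)
          t2 <- c(t2, sample(c("C", het), 1))
          e2 <- rbind(e2, c(at, length(t2)))
        }
        id <- sprintf("f%d_c%02d", f, c_idx)
        graphs[[id]] <- mol_graph(t2, e2)
        family <- c(family, f)
      }
    }
    names(family) <- names(graphs)
    list(graphs = graphs, family = family)
  })
}

#' Generate a complete synthetic screening dataset
#'
#' Crosses binding modes with scaffold families: every compound of every
#' family is docked (synthetically) into every mode's pocket sub-region, one
#' pose per (mode, compound). Optionally writes `receptor.pdb`, `poses.sdf`
#' and `labels.tsv` to `out_dir`.
#'
#' @param spec a [synth_spec()].
#' @param out_dir optional output directory.
#' @return List with `site`, `poses`, `labels` (data.frame pose_id / mode /
#'   family), and `files` when written.
#' @export
make_tscc_dataset <- function(spec, out_dir = NULL) {
  stopifnot(inherits(spec, "synth_spec"))
  site <- make_receptor(spec)
  fams <- make_molecule_families(spec)
  with_seed(spec$seed * 7L + 4L, {
    poses <- list(); labels <- NULL
    for (m in seq_len(spec$n_modes)) {
      anchor <- mode_anchor(m, spec$n_modes)
      dirs <- mode_dirs(spec$seed, m)
      for (id in names(fams$graphs)) {
        g <- fams$graphs[[id]]
        coords <- embed_graph(g, anchor, dirs)
        if (spec$noise_sigma > 0)
          coords <- coords + matrix(stats::rnorm(length(coords), 0,
                                                 spec$noise_sigma),
                                    ncol = 3L)
        pid <- sprintf("m%d_%s", m, id)
        energy <- stats::runif(1, -12, -6)
        poses[[pid]] <- graph_to_pose(g, coords, pid, energy)
        labels <- rbind(labels, data.frame(
          pose_id = pid, mode = m, family = unname(fams$family[id])))
      }
    }
    files <- character(0)
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      files <- c(receptor = file.path(out_dir, "receptor.pdb"),
                 poses = file.path(out_dir, "poses.sdf"),
                 labels = file.path(out_dir, "labels.tsv"))
      write_receptor_pdb(site, files[["receptor"]])
      write_poses_sdf(poses, files[["poses"]])
      utils::write.table(labels, files[["labels"]], sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    list(site = site, poses = poses, labels = labels, files = files)
  })
}

# --- plain-text writers -----------------------------------------------------

#' Write a receptor site as a PDB file
#'
#' Fixed-width ATOM records including the element (columns 77-78) and formal
#' charge (columns 79-80) fields, so charges survive a round trip through
#' [read_receptor()].
#'
#' @param site a [receptor_site()].
#' @param path output file.
#' @export
write_receptor_pdb <- function(site, path) {
  stopifnot(inherits(site, "receptor_site"))
  a <- site$atoms
  an <- if ("atom_name" %in% names(a)) a$atom_name else a$element
  parts <- strsplit(a$residue_tag, ":", fixed = TRUE)
  chain <- vapply(parts, `[`, character(1), 1L)
  resname <- vapply(parts, `[`, character(1), 2L)
  resno <- as.integer(vapply(parts, `[`, character(1), 3L))
  chg <- ifelse(a$formal_charge == 0, "  ",
                sprintf("%d%s", abs(a$formal_charge),
                        ifelse(a$formal_charge > 0, "+", "-")))
  lines <- sprintf(
    "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s%2s",
    a$serial, substr(an, 1, 4), substr(resname, 1, 3), chain, resno,
    a$x, a$y, a$z, 1.00, 0.00, toupper(a$element), chg)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Write ligand poses as an SDF (V2000) file
#'
#' Includes `M CHG` lines for formal charges and a `docked_energy` property
#' per record, matching what [read_poses()] expects.
#'
#' @param poses list of [ligand_pose()].
#' @param path output file.
#' @param energy_field property name for the docked energy.
#' @export
write_poses_sdf <- function(poses, path, energy_field = "docked_energy") {
  out <- character(0)
  for (p in poses) {
    a <- p$atoms; b <- p$bonds
    rec <- c(p$pose_id, "  tscc", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                     nrow(a), nrow(b)),
             sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                     a$x, a$y, a$z, a$element),
             if (nrow(b)) sprintf("%3d%3d%3d  0", b$i, b$j, b$order))
    charged <- which(a$formal_charge != 0L)
    if (length(charged))
      rec <- c(rec, paste0(sprintf("M  CHG%3d", length(charged)),
                           paste0(sprintf("%4d%4d", charged,
                                          a$formal_charge[charged]),
                                  collapse = "")))
    rec <- c(rec, "M  END",
             sprintf(">  <%s>", energy_field),
             format(p$docked_energy, digits = 10), "", "$$$$")
    out <- c(out, rec)
  }
  writeLines(out, path)
  invisible(path)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two flat clusterings of the same
#' items; 1 means identical partitions, 0 the chance level.
#'
#' @param a,b cluster label vectors of equal length (any label type).
#' @return ARI in `[-1, 1]`.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors differ in length")
  if (length(a) < 2L) return(1)
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}
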