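# Text fixtures are built in code at test time; nothing binary is stored.

# A 3-residue receptor: 20 atoms of which 2 are hydrogens, one altLoc A/B
# duplicated atom, and one formally charged atom (GLU OE2 marked 1-).
write_fixture_pdb <- function(path = tempfile(fileext = ".pdb")) {
  lines <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N  ",
    "ATOM      2  CA  ALA A   1       1.450   0.000   0.000  1.00  0.00           C  ",
    "ATOM      3  C   ALA A   1       2.000   1.400   0.000  1.00  0.00           C  ",
    "ATOM      4  O   ALA A   1       1.300   2.400   0.000  1.00  0.00           O  ",
    "ATOM      5  CB  ALA A   1       2.000  -1.000   1.000  1.00  0.00           C  ",
    "ATOM      6  HB1 ALA A   1       2.500  -1.800   0.500  1.00  0.00           H  ",
    "ATOM      7  N   GLU A   2       3.300   1.500   0.200  1.00  0.00           N  ",
    "ATOM      8  CA  GLU A   2       4.000   2.800   0.300  1.00  0.00           C  ",
    "ATOM      9  C   GLU A   2       5.500   2.600   0.400  1.00  0.00           C  ",
    "ATOM     10  O   GLU A   2       6.000   1.500   0.500  1.00  0.00           O  ",
    "ATOM     11  CB AGLU A   2       3.600   3.600   1.500  0.50  0.00           C  ",
    "ATOM     12  CB BGLU A   2       3.700   3.700   1.600  0.50  0.00           C  ",
    "ATOM     13  CG  GLU A   2       3.900   5.000   1.600  1.00  0.00           C  ",
    "ATOM     14  CD  GLU A   2       3.500   5.800   2.800  1.00  0.00           C  ",
    "ATOM     15  OE1 GLU A   2       2.700   5.300   3.600  1.00  0.00           O  ",
    "ATOM     16  OE2 GLU A   2       4.000   6.900   3.000  1.00  0.00           O1-",
    "ATOM     17  HG  GLU A   2       4.900   5.100   1.300  1.00  0.00           H  ",
    "ATOM     18  N   SER A   3       6.300   3.700   0.400  1.00  0.00           N  ",
    "ATOM     19  CA  SER A   3       7.750   3.600   0.500  1.00  0.00           C  ",
    "ATOM     20  OG  SER A   3       8.300   4.900   0.600  1.00  0.00           O  ",
    "END")
  writeLines(lines, path)
  path
}

sdf_record <- function(title, atoms, bonds, energy = NULL, chg = NULL,
                       energy_field = "docked_energy") {
  rec <- c(title, "  fixture", "",
           sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                   nrow(atoms), nrow(bonds)),
           sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                   atoms$x, atoms$y, atoms$z, atoms$el),
           if (nrow(bonds)) sprintf("%3d%3d%3d  0",
                                    bonds$i, bonds$j, bonds$order))
  if (!is.null(chg))
    rec <- c(rec, paste0(sprintf("M  CHG%3d", nrow(chg)),
                         paste0(sprintf("%4d%4d", chg$atom, chg$charge),
                                collapse = "")))
  rec <- c(rec, "M  END")
  if (!is.null(energy))
    rec <- c(rec, sprintf(">  <%s>", energy_field), as.character(energy), "")
  c(rec, "$$$$")
}

# Three poses with energies -8.1 / -7.2 / -9.0; pose 2 carries explicit
# hydrogens; pose 3 carries a +1 charged nitrogen via M CHG.
write_fixture_sdf <- function(path = tempfile(fileext = ".sdf"),
                              energy_field = "docked_energy",
                              drop_energy_on = integer(0)) {
  a1 <- data.frame(el = c("C", "C", "O"),
                   x = c(0, 1.5, 2.2), y = c(0, 0, 1.1), z = 0)
  b1 <- data.frame(i = c(1, 2), j = c(2, 3), order = c(1, 2))
  a2 <- data.frame(el = c("C", "N", "H", "H"),
                   x = c(0, 1.4, -0.6, 2.0), y = c(0, 0, 0.9, 0.8), z = 0)
  b2 <- data.frame(i = c(1, 1, 2), j = c(2, 3, 4), order = 1)
  a3 <- data.frame(el = c("C", "N", "C", "C", "C"),
                   x = c(0, 1.5, 2.6, 1.6, 1.4), y = c(0, 0, 1, -1.4, 0.9),
                   z = c(0, 0, 0, 0.3, -1))
  b3 <- data.frame(i = c(1, 2, 2, 2), j = c(2, 3, 4, 5), order = 1)
  recs <- c(
    sdf_record("pose1", a1, b1,
               if (!(1 %in% drop_energy_on)) -8.1, energy_field = energy_field),
    sdf_record("pose2", a2, b2,
               if (!(2 %in% drop_energy_on)) -7.2, energy_field = energy_field),
    sdf_record("pose3", a3, b3,
               if (!(3 %in% drop_energy_on)) -9.0,
               chg = data.frame(atom = 2, charge = 1),
               energy_field = energy_field))
  writeLines(recs, path)
  path
}

# hand-placed toy complex used by the interaction oracles: 2 site atoms,
# 2 ligand atoms with mixed classes and one charged pair
toy_site <- function() {
  atoms <- tscc:::new_atom_table(
    serial = c(10L, 20L), element = c("O", "C"),
    x = c(0, 4), y = 0, z = 0,
    formal_charge = c(-1L, 0L),
    residue_tag = c("A:GLU:1", "A:ALA:2"))
  atoms$hb_class <- c("acceptor", "nonpolar")
  atoms$atom_name <- c("OE1", "CB")
  receptor_site(atoms, source_id = "toy")
}

toy_pose <- function(dx = 0, dy = 0, id = "toy1", energy = -5) {
  atoms <- tscc:::new_atom_table(
    serial = 1:2, element = c("N", "C"),
    x = c(2.8 + dx, 5.2 + dx), y = c(0.5 + dy, -0.3 + dy), z = 0,
    formal_charge = c(1L, 0L))
  atoms$hb_class <- c("donor", "nonpolar")
  bonds <- data.frame(i = 1L, j = 2L, order = 1L)
  ligand_pose(id, atoms, bonds, energy)
}

# --- independent oracles ----------------------------------------------------

# piecewise-linear potential via linear interpolation of the breakpoint
# table (independent of the arithmetic in plp_energy)
oracle_plp <- function(r, p) {
  f <- stats::approxfun(c(0, p$V1, p$V2, p$V3, p$V4, p$V4 + 1e6),
                        c(p$V5, 0, p$V6, p$V6, 0, 0))
  f(r)
}

# brute-force per-atom interaction profile: explicit double loop
oracle_profile <- function(site, pose, params, es_cutoff = 12) {
  pa <- site$atoms; la <- pose$atoms
  out <- numeric(nrow(pa))
  for (j in seq_len(nrow(pa))) {
    for (i in seq_len(nrow(la))) {
      r <- sqrt((pa$x[j] - la$x[i])^2 + (pa$y[j] - la$y[i])^2 +
                  (pa$z[j] - la$z[i])^2)
      cls <- classify_pair(pa$hb_class[j], la$hb_class[i])
      p <- if (cls == "hbond") params$hbond else params$steric
      e <- oracle_plp(r, p)
      if (pa$formal_charge[j] != 0 && la$formal_charge[i] != 0 &&
          r <= es_cutoff)
        e <- e + 332.0 * pa$formal_charge[j] * la$formal_charge[i] / r
      out[j] <- out[j] + e
    }
  }
  names(out) <- pa$serial
  out
}

# naive average-linkage clustering: recomputes every cross-pair mean with
# explicit loops each step; merges the minimum pair (first in scan order)
oracle_upgma <- function(d, ids = rownames(d)) {
  clusters <- lapply(seq_along(ids), function(i) i)
  partitions <- list(); heights <- numeric(0)
  while (length(clusters) > 1L) {
    best_d <- Inf; best <- NULL
    for (p in seq_len(length(clusters) - 1L)) {
      for (q in (p + 1L):length(clusters)) {
        s <- 0
        for (i in clusters[[p]]) for (j in clusters[[q]])
          s <- s + d[i, j]
        avg <- s / (length(clusters[[p]]) * length(clusters[[q]]))
        if (avg < best_d) { best_d <- avg; best <- c(p, q) }
      }
    }
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    clusters[[best[1]]] <- merged
    clusters[[best[2]]] <- NULL
    heights <- c(heights, best_d)
    partitions[[length(partitions) + 1L]] <- sort(ids[merged])
  }
  list(heights = heights, partitions = partitions)
}

# the partition (sorted leaf-label sets) created by each merge of a tree
tree_partitions <- function(tree) {
  labs <- tree$labels
  sets <- list()
  get_leaves <- function(node) {
    if (node < 0) return(labs[-node])
    sets[[node]]
  }
  for (step in seq_len(nrow(tree$merge))) {
    sets[[step]] <- sort(c(get_leaves(tree$merge[step, 1]),
                           get_leaves(tree$merge[step, 2])))
  }
  sets
}

# exhaustive threshold sweep over a dense candidate set
oracle_threshold <- function(intra, inter) {
  u <- sort(unique(c(intra, inter)))
  cands <- sort(unique(c(u[1], u, (u[-1] + u[-length(u)]) / 2,
                         u[length(u)] + 1)))
  acc <- vapply(cands, function(t)
    (sum(intra < t) + sum(inter >= t)) / (length(intra) + length(inter)),
    numeric(1))
  list(best_acc = max(acc), cands = cands, acc = acc)
}

random_mol_graph <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  types <- sample(c("C", "N", "O", "S"), n, replace = TRUE)
  # random spanning tree keeps the graph connected, then extra edges
  edges <- cbind(2:n, vapply(2:n, function(k) sample(k - 1L, 1L), integer(1)))
  extra <- if (n >= 4 && stats::runif(1) < 0.5) {
    pair <- sample(n, 2L)
    matrix(pair, 1L)
  }
  mol_graph(types, rbind(edges, extra))
}
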