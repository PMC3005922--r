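# The two-stage combinatorial clustering pipeline.
#
# Stage 1 clusters docked poses by their protein-ligand interaction profiles
# (correlation distance, UPGMA, cut at the interaction reference threshold).
# Stage 2 re-clusters the compounds of each stage-1 cluster by binary
# atom-pair descriptors (Tanimoto distance, UPGMA, cut at the structural
# reference threshold) and selects the lowest-docked-energy member of each
# structural sub-cluster as its representative.

#' Pipeline configuration
#'
#' @param stage1_threshold correlation-distance cut for interaction
#'   clustering; default 0.39, the reference threshold learned on known
#'   actives by maximum discrimination between similar and non-similar
#'   binding modes.
#' @param stage2_threshold Tanimoto-distance cut for structural clustering;
#'   default 0.55, the analogous atom-pair reference threshold.
#' @param site_radius binding-site cutoff radius in Angstrom (default 10).
#' @param plp per-class PLP parameters ([default_plp_params()] by default).
#' @param es_cutoff electrostatic cutoff in Angstrom.
#' @param epsilon involved-atom tolerance in kcal/mol.
#' @param energy_field SDF property name holding docked energies.
#' @param include_electrostatics include the Coulomb term in profiles.
#' @param n_bins atom-pair topological distance bins.
#' @param clusters optional integer vector restricting stage 2 to the given
#'   stage-1 cluster labels (default: all clusters).
#' @param seed seed for any sampling utilities.
#' @return An object of class `tscc_config`.
#' @export
tscc_config <- function(stage1_threshold = 0.39,
                        stage2_threshold = 0.55,
                        site_radius = 10,
                        plp = default_plp_params(),
                        es_cutoff = plp$es_cutoff,
                        epsilon = plp$epsilon,
                        energy_field = "docked_energy",
                        include_electrostatics = TRUE,
                        n_bins = 15L,
                        clusters = NULL,
                        seed = 1L) {
  if (stage1_threshold < 0 || stage1_threshold > 2)
    stop("stage1_threshold must lie in [0, 2] (correlation distance)")
  if (stage2_threshold < 0 || stage2_threshold > 1)
    stop("stage2_threshold must lie in [0, 1] (Tanimoto distance)")
  if (is.null(es_cutoff)) es_cutoff <- 12
  if (is.null(epsilon)) epsilon <- 1e-6
  structure(list(stage1_threshold = stage1_threshold,
                 stage2_threshold = stage2_threshold,
                 site_radius = site_radius, plp = plp,
                 es_cutoff = es_cutoff, epsilon = epsilon,
                 energy_field = energy_field,
                 include_electrostatics = include_electrostatics,
                 n_bins = as.integer(n_bins), clusters = clusters,
                 seed = as.integer(seed)),
            class = "tscc_config")
}

site_atom_labels <- function(site) {
  a <- site$atoms
  an <- if ("atom_name" %in% names(a)) a$atom_name else a$element
  labels <- sprintf("%s:%s", a$residue_tag, an)
  names(labels) <- as.character(a$serial)
  labels
}

#' Stage 1: interaction-profile clustering of docked poses
#'
#' @param site binding-site [receptor_site()].
#' @param poses list of [ligand_pose()].
#' @param cfg a [tscc_config()].
#' @return List with `profiles` ([build_profile_matrix()] result),
#'   `distances`, `tree`, `assignment`.
#' @export
run_stage1 <- function(site, poses, cfg = tscc_config()) {
  stopifnot(length(poses) >= 2L)
  profs <- lapply(poses, function(p)
    atom_profile(site, p, params = cfg$plp, es_cutoff = cfg$es_cutoff,
                 include_electrostatics = cfg$include_electrostatics))
  pm <- build_profile_matrix(profs, epsilon = cfg$epsilon,
                             atom_labels = site_atom_labels(site))
  D <- pairwise_distances(pm$values, metric = "correlation")
  tree <- upgma(D)
  assignment <- cut_tree(tree, cfg$stage1_threshold)
  list(profiles = pm, distances = D, tree = tree, assignment = assignment)
}

#' Stage 2: structural sub-clustering and representative selection
#'
#' @param members list of [ligand_pose()] belonging to one stage-1 cluster.
#' @param cfg a [tscc_config()].
#' @return List with `tree` (NULL for a single member), `assignment`,
#'   and `representatives`, a data.frame (sub_cluster, pose_id,
#'   docked_energy, n_members). Ties in energy go to the lexicographically
#'   smallest pose id.
#' @export
run_stage2 <- function(members, cfg = tscc_config()) {
  stopifnot(length(members) >= 1L)
  ids <- vapply(members, `[[`, character(1), "pose_id")
  energies <- vapply(members, `[[`, numeric(1), "docked_energy")
  if (length(members) == 1L) {
    assignment <- structure(list(
      cluster = stats::setNames(1L, ids), cut_height = cfg$stage2_threshold),
      class = "cluster_assignment")
    reps <- data.frame(sub_cluster = 1L, pose_id = ids,
                       docked_energy = energies, n_members = 1L)
    return(list(tree = NULL, assignment = assignment,
                representatives = reps))
  }
  graphs <- lapply(members, as_mol_graph)
  names(graphs) <- ids
  dm <- descriptor_matrix(graphs, n_bins = cfg$n_bins)
  D <- pairwise_distances(dm$values, metric = "tanimoto")
  tree <- upgma(D)
  assignment <- cut_tree(tree, cfg$stage2_threshold)
  reps <- select_representatives(assignment, ids, energies)
  list(tree = tree, assignment = assignment, representatives = reps)
}

# lowest-energy member per sub-cluster; energy ties broken by pose id
select_representatives <- function(assignment, ids, energies) {
  cl <- assignment$cluster[ids]
  out <- lapply(sort(unique(cl)), function(k) {
    in_k <- which(cl == k)
    ord <- in_k[order(energies[in_k], ids[in_k])]
    data.frame(sub_cluster = k, pose_id = ids[ord[1]],
               docked_energy = energies[ord[1]],
               n_members = length(in_k))
  })
  do.call(rbind, out)
}

# one pose per compound: keep the lowest-energy pose of each compound id
# (compound id = pose_id prefix before the last "_pose" suffix, or the
# pose_id itself when no such suffix is present)
keep_best_pose <- function(poses) {
  ids <- vapply(poses, `[[`, character(1), "pose_id")
  cmp <- sub("_pose[0-9]+$", "", ids)
  energies <- vapply(poses, `[[`, numeric(1), "docked_energy")
  keep <- unlist(lapply(split(seq_along(poses), cmp), function(idx)
    idx[order(energies[idx], ids[idx])][1]))
  poses[sort(keep)]
}

#' Run the full two-stage combinatorial clustering
#'
#' Reads the receptor and docked poses, extracts the binding site (anchored
#' on `reference_ligand`, or on the union of all pose atoms when none is
#' given), keeps the lowest-energy pose per compound, clusters poses by
#' interaction profile (stage 1), sub-clusters every stage-1 cluster by
#' atom-pair structure (stage 2), and selects the lowest-energy
#' representative of every sub-cluster.
#'
#' @param receptor_path PDB file.
#' @param poses_path SDF or MOL2 file with per-pose energies.
#' @param cfg a [tscc_config()].
#' @param out_dir if non-`NULL`, artifacts are written there:
#'   `stage1_profiles.tsv`, `stage1_tree.nwk`, `stage1_clusters.tsv`,
#'   `stage2_<k>_tree.nwk`, `stage2_<k>_clusters.tsv`,
#'   `representatives.tsv`, `report.json`.
#' @param reference_ligand optional [ligand_pose()] anchoring the site.
#' @return An object of class `tscc_report`: list with `stage1`, `stage2`
#'   (per-cluster results), `representatives` data.frame (stage1_cluster,
#'   sub_cluster, pose_id, docked_energy, n_members), and `files`.
#' @export
run_tscc <- function(receptor_path, poses_path, cfg = tscc_config(),
                     out_dir = NULL, reference_ligand = NULL) {
  receptor <- tryCatch(read_receptor(receptor_path),
                       error = function(e) stop("[stage 1/receptor] ",
                                                conditionMessage(e)))
  poses <- tryCatch(
    read_poses(poses_path, energy_field = cfg$energy_field),
    error = function(e) stop("[stage 1/poses] ", conditionMessage(e)))
  poses <- keep_best_pose(poses)
  anchor <- if (is.null(reference_ligand)) {
    do.call(rbind, lapply(poses, `[[`, "atoms"))
  } else reference_ligand
  site <- tryCatch(
    extract_binding_site(receptor, anchor, radius = cfg$site_radius),
    error = function(e) stop("[stage 1/site] ", conditionMessage(e)))
  s1 <- tryCatch(run_stage1(site, poses, cfg),
                 error = function(e) stop("[stage 1] ",
                                          conditionMessage(e)))
  ids <- vapply(poses, `[[`, character(1), "pose_id")
  labels <- s1$assignment$cluster[ids]
  wanted <- sort(unique(labels))
  if (!is.null(cfg$clusters)) wanted <- intersect(wanted, cfg$clusters)
  s2 <- lapply(wanted, function(k) {
    tryCatch(run_stage2(poses[labels == k], cfg),
             error = function(e) stop("[stage 2/cluster ", k, "] ",
                                      conditionMessage(e)))
  })
  names(s2) <- as.character(wanted)
  reps <- do.call(rbind, lapply(wanted, function(k) {
    r <- s2[[as.character(k)]]$representatives
    cbind(stage1_cluster = k, r)
  }))
  rownames(reps) <- NULL
  files <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    fp <- function(name) file.path(out_dir, name)
    write_profile_matrix(s1$profiles, fp("stage1_profiles.tsv"))
    writeLines(to_newick(s1$tree), fp("stage1_tree.nwk"))
    write_assignment(s1$assignment, fp("stage1_clusters.tsv"))
    files <- c(fp("stage1_profiles.tsv"), fp("stage1_tree.nwk"),
               fp("stage1_clusters.tsv"))
    for (k in wanted) {
      r <- s2[[as.character(k)]]
      if (!is.null(r$tree)) {
        writeLines(to_newick(r$tree), fp(sprintf("stage2_%d_tree.nwk", k)))
        files <- c(files, fp(sprintf("stage2_%d_tree.nwk", k)))
      }
      write_assignment(r$assignment,
                       fp(sprintf("stage2_%d_clusters.tsv", k)))
      files <- c(files, fp(sprintf("stage2_%d_clusters.tsv", k)))
    }
    utils::write.table(reps, fp("representatives.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    report <- list(
      n_poses = length(poses),
      n_site_atoms = nrow(site$atoms),
      n_involved_atoms = ncol(s1$profiles$values),
      stage1_threshold = cfg$stage1_threshold,
      stage2_threshold = cfg$stage2_threshold,
      n_stage1_clusters = max(s1$assignment$cluster),
      n_representatives = nrow(reps),
      representatives = reps)
    jsonlite::write_json(report, fp("report.json"), auto_unbox = TRUE,
                         digits = NA, dataframe = "rows")
    files <- c(files, fp("representatives.tsv"), fp("report.json"))
  }
  structure(list(stage1 = s1, stage2 = s2, representatives = reps,
                 site = site, poses = poses, config = cfg, files = files),
            class = "tscc_report")
}

#' @export
print.tscc_report <- function(x, ...) {
  cat(sprintf(
    "<tscc_report> %d poses -> %d interaction clusters -> %d representatives\n",
    length(x$poses), max(x$stage1$assignment$cluster),
    nrow(x$representatives)))
  invisible(x)
}
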