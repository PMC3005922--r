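# Binary atom-pair topological descriptors.
#
# Each molecule is a heavy-atom bond graph; a descriptor bit is keyed by
# (unordered atom-type pair, shortest bond-path length capped at 15 bins).
# With the 10-type element alphabet this gives 55 x 15 = 825 bits per
# molecule; presence is recorded, not counts.

#' Default 10-letter atom-type alphabet
#'
#' Elements `C N O S P F Cl Br I` plus `X` for any other heavy element.
#' @export
AP_ALPHABET <- c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I", "X")

#' Construct a molecular bond graph
#'
#' @param node_types character vector of atom-type codes.
#' @param edges two-column matrix/data.frame of 1-based undirected bonded
#'   pairs (bond order is irrelevant for topological distances).
#' @param alphabet atom-type alphabet; types outside it map to its last
#'   ("other") letter.
#' @return An object of class `mol_graph`.
#' @export
mol_graph <- function(node_types, edges, alphabet = AP_ALPHABET) {
  node_types <- as.character(node_types)
  node_types[!(node_types %in% alphabet)] <- alphabet[length(alphabet)]
  edges <- as.matrix(edges)[, 1:2, drop = FALSE]
  storage.mode(edges) <- "integer"
  if (nrow(edges)) {
    if (any(edges < 1L | edges > length(node_types)))
      stop("edge references a missing node")
    if (any(edges[, 1] == edges[, 2])) stop("self-loops are not allowed")
    # deduplicate undirected edges
    key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    edges <- edges[!duplicated(key), , drop = FALSE]
  }
  structure(list(node_types = node_types, edges = edges,
                 alphabet = alphabet),
            class = "mol_graph")
}

#' Convert a ligand pose to its bond graph
#'
#' @param pose a [ligand_pose()].
#' @param alphabet atom-type alphabet.
#' @return A [mol_graph()].
#' @export
as_mol_graph <- function(pose, alphabet = AP_ALPHABET) {
  stopifnot(inherits(pose, "ligand_pose"))
  mol_graph(pose$atoms$element,
            cbind(pose$bonds$i, pose$bonds$j), alphabet)
}

#' Topological distance matrix of a bond graph
#'
#' Shortest path lengths in bond counts (unweighted breadth-first search via
#' igraph); `Inf` marks pairs in different connected components.
#'
#' @param g a [mol_graph()].
#' @return Symmetric integer-valued matrix with zero diagonal.
#' @export
topo_distances <- function(g) {
  stopifnot(inherits(g, "mol_graph"))
  n <- length(g$node_types)
  ig <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(g$edges))
    ig <- igraph::add_edges(ig, t(g$edges))
  igraph::distances(ig, algorithm = "unweighted")
}

ap_keys <- function(alphabet = AP_ALPHABET, n_bins = 15L) {
  T <- length(alphabet)
  keys <- character(0)
  for (a in seq_len(T)) for (b in a:T)
    keys <- c(keys, sprintf("%s-%s-%d", alphabet[a], alphabet[b],
                            seq_len(n_bins)))
  keys
}

#' Binary atom-pair descriptor of a molecule
#'
#' Sets bit (type_i, type_j, bin(d_ij)) for every unordered pair of distinct,
#' mutually reachable atoms, where d_ij is the shortest bond-path length and
#' bin(d) = min(d, n_bins) (long-range pairs fold into the last bin rather
#' than being discarded). With the default 10-type alphabet and 15 bins the
#' vector length is 55 x 15 = 825.
#'
#' @param g a [mol_graph()].
#' @param n_bins number of topological distance bins.
#' @return Named integer (0/1) vector of class `ap_vector`, key order
#'   lexicographic over (type pair in alphabet order, bin).
#' @export
atom_pair_descriptor <- function(g, n_bins = 15L) {
  stopifnot(inherits(g, "mol_graph"))
  alphabet <- g$alphabet
  keys <- ap_keys(alphabet, n_bins)
  bits <- integer(length(keys))
  names(bits) <- keys
  n <- length(g$node_types)
  if (n >= 2L) {
    d <- topo_distances(g)
    ti <- match(g$node_types, alphabet)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      if (!is.finite(d[i, j])) next
      a <- min(ti[i], ti[j]); b <- max(ti[i], ti[j])
      bin <- min(d[i, j], n_bins)
      key <- sprintf("%s-%s-%d", alphabet[a], alphabet[b], bin)
      bits[key] <- 1L
    }
  }
  structure(bits, class = "ap_vector")
}

#' Stack atom-pair descriptors and drop all-zero columns
#'
#' @param mols list of [mol_graph()] objects (or [ligand_pose()]s, converted
#'   on the fly); names become row ids.
#' @param n_bins number of distance bins.
#' @return List with `values` (binary molecules x keys matrix, all-zero
#'   columns removed) and `keys` (retained descriptor keys), class
#'   `descriptor_matrix`.
#' @export
descriptor_matrix <- function(mols, n_bins = 15L) {
  stopifnot(length(mols) >= 1L)
  mols <- lapply(mols, function(m)
    if (inherits(m, "ligand_pose")) as_mol_graph(m) else m)
  rows <- lapply(mols, atom_pair_descriptor, n_bins = n_bins)
  m <- do.call(rbind, lapply(rows, unclass))
  ids <- names(mols)
  if (is.null(ids)) ids <- sprintf("mol%d", seq_along(mols))
  rownames(m) <- ids
  keep <- colSums(m) > 0L
  if (!any(keep)) stop("all descriptor columns are zero")
  m <- m[, keep, drop = FALSE]
  structure(list(values = m, keys = colnames(m)),
            class = "descriptor_matrix")
}

#' @export
print.descriptor_matrix <- function(x, ...) {
  cat(sprintf("<descriptor_matrix> %d molecules x %d retained atom-pair bits\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Write a descriptor matrix as TSV
#' @param dm a `descriptor_matrix`.
#' @param path output file.
#' @export
write_descriptor_matrix <- function(dm, path) {
  df <- data.frame(mol_id = rownames(dm$values), dm$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
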