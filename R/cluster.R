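# Distance metrics and UPGMA hierarchical clustering.
#
# UPGMA is implemented directly (naive recompute form) rather than through
# stats::hclust because the pipeline requires a fixed, platform-independent
# tie-break rule for equal cluster distances; hclust's average linkage is
# used in the test suite as an independent cross-check on tie-free inputs.

#' Correlation distance between two real vectors
#'
#' `1 - Pearson r`, in `[0, 2]` (0 = perfectly correlated interaction
#' profiles, 2 = perfectly anticorrelated). Zero-variance input is handled by
#' convention: two identical constant vectors are at distance 0; any other
#' pair involving a constant vector is at distance 1 (r taken as 0), keeping
#' the clustering total where the Pearson formula is undefined. The sample
#' (n-1) standard deviation is used.
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return Distance in `[0, 2]`.
#' @export
correlation_distance <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 2L) stop("need vectors of length >= 2")
  if (identical(as.numeric(x), as.numeric(y))) return(0)
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx == 0 || sy == 0) {
    if (isTRUE(all.equal(x, y))) return(0)
    return(1)
  }
  # clamp one-ulp excursions of cor() so the metric range is exact
  min(max(1 - stats::cor(x, y), 0), 2)
}

#' Tanimoto distance between two binary vectors
#'
#' `1 - |X intersect Y| / |X union Y|` on ON bits, in `[0, 1]`. Two all-zero
#' vectors are identical objects and get distance 0.
#'
#' @param x,y binary (0/1) vectors of equal length.
#' @return Distance in `[0, 1]`.
#' @export
tanimoto_distance <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  x <- x != 0; y <- y != 0
  u <- sum(x | y)
  if (u == 0L) return(0)
  1 - sum(x & y) / u
}

#' Pairwise distance matrix over matrix rows
#'
#' @param rows numeric matrix; row names become item ids.
#' @param metric `"correlation"` or `"tanimoto"`.
#' @return An object of class `dist_matrix`: list with `ids` and symmetric
#'   zero-diagonal matrix `d`.
#' @export
pairwise_distances <- function(rows, metric = c("correlation", "tanimoto")) {
  metric <- match.arg(metric)
  rows <- as.matrix(rows)
  if (nrow(rows) < 2L) stop("need at least 2 rows")
  if (metric == "tanimoto" && !all(rows %in% c(0, 1)))
    stop("tanimoto metric requires a binary matrix")
  f <- if (metric == "correlation") correlation_distance else tanimoto_distance
  n <- nrow(rows)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    d[i, j] <- d[j, i] <- f(rows[i, ], rows[j, ])
  ids <- rownames(rows)
  if (is.null(ids)) ids <- sprintf("item%d", seq_len(n))
  dimnames(d) <- list(ids, ids)
  dist_matrix(ids, d)
}

#' Construct a distance-matrix object
#' @param ids item labels.
#' @param d symmetric non-negative matrix with zero diagonal.
#' @return `dist_matrix` object.
#' @export
dist_matrix <- function(ids, d) {
  d <- as.matrix(d)
  stopifnot(length(ids) == nrow(d), nrow(d) == ncol(d))
  if (any(!is.finite(d))) stop("distances must be finite")
  if (any(abs(d - t(d)) > 1e-12)) stop("distance matrix must be symmetric")
  if (any(diag(d) != 0)) stop("distance matrix diagonal must be zero")
  dimnames(d) <- list(ids, ids)
  structure(list(ids = as.character(ids), d = d), class = "dist_matrix")
}

# lexicographic comparison key for a candidate merge pair: smallest member
# id, then largest member id, then the full sorted member list
pair_key <- function(members_p, members_q) {
  u <- sort(c(members_p, members_q))
  c(u[1], u[length(u)], paste(u, collapse = "\r"))
}

key_less <- function(a, b) {
  for (k in seq_along(a)) {
    if (a[k] < b[k]) return(TRUE)
    if (a[k] > b[k]) return(FALSE)
  }
  FALSE
}

#' UPGMA (average-linkage) hierarchical clustering
#'
#' Repeatedly merges the pair of clusters with the smallest inter-cluster
#' distance, defined as the unweighted arithmetic mean of all cross-pair
#' leaf distances; the merge height is that mean. Equal minimal distances
#' are broken deterministically by the lexicographically smallest
#' (min member id, max member id) of the merged pair.
#'
#' @param D a [dist_matrix()] (or plain symmetric matrix with dimnames).
#' @return An object of class `c("cluster_tree", "hclust")` with the usual
#'   `merge`, `height`, `labels`, `order` components, so that `stats` and
#'   `ape` tree machinery apply.
#' @export
upgma <- function(D) {
  if (!inherits(D, "dist_matrix")) {
    m <- as.matrix(D)
    ids <- rownames(m)
    if (is.null(ids)) ids <- sprintf("item%d", seq_len(nrow(m)))
    D <- dist_matrix(ids, m)
  }
  n <- length(D$ids)
  if (n < 2L) stop("need at least 2 items to cluster")
  d0 <- D$d
  ids <- D$ids
  # active clusters: leaf index sets, merge-node index (-leaf / +merge)
  members <- as.list(seq_len(n))
  node <- -seq_len(n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    k <- length(members)
    best <- NULL
    for (p in seq_len(k - 1L)) for (q in (p + 1L):k) {
      dpq <- mean(d0[members[[p]], members[[q]]])
      if (is.null(best) || dpq < best$d ||
          (dpq == best$d &&
           key_less(pair_key(ids[members[[p]]], ids[members[[q]]]),
                    best$key))) {
        best <- list(p = p, q = q, d = dpq,
                     key = pair_key(ids[members[[p]]], ids[members[[q]]]))
      }
    }
    p <- best$p; q <- best$q
    # child with the smallest member id first: fixes leaf order in exports
    if (min(ids[members[[p]]]) <= min(ids[members[[q]]]))
      merge[step, ] <- c(node[p], node[q])
    else merge[step, ] <- c(node[q], node[p])
    height[step] <- best$d
    members[[p]] <- sort(c(members[[p]], members[[q]]))
    node[p] <- step
    members[[q]] <- NULL
    node <- node[-q]
  }
  tree <- structure(list(merge = merge, height = height,
                         order = tree_leaf_order(merge),
                         labels = ids, method = "average",
                         dist.method = "user",
                         call = match.call()),
                    class = c("cluster_tree", "hclust"))
  tree
}

# left-to-right leaf ordering of an hclust merge matrix
tree_leaf_order <- function(merge) {
  expand <- function(node) {
    if (node < 0) return(-node)
    c(expand(merge[node, 1]), expand(merge[node, 2]))
  }
  expand(nrow(merge))
}

#' Cut a cluster tree at a height threshold
#'
#' Clusters are the connected leaf sets obtained after removing merges
#' strictly above `t`. Labels are deterministic: clusters are numbered 1..k
#' in order of their smallest member id.
#'
#' @param tree a tree from [upgma()].
#' @param t cut height, >= 0.
#' @return An object of class `cluster_assignment`: list with `cluster`
#'   (named integer vector, one label per item) and `cut_height`.
#' @export
cut_tree <- function(tree, t) {
  stopifnot(inherits(tree, "hclust"), t >= 0)
  raw <- stats::cutree(tree, h = t)
  labs <- names(raw)
  # renumber so cluster 1 contains the smallest item id, etc.
  min_id <- vapply(split(labs, raw), min, character(1))
  new_of_old <- rank(min_id, ties.method = "first")
  cluster <- as.integer(new_of_old[as.character(raw)])
  names(cluster) <- labs
  structure(list(cluster = cluster, cut_height = t),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment> %d items in %d clusters (cut at %.4g)\n",
              length(x$cluster), max(x$cluster), x$cut_height))
  invisible(x)
}

#' Export a cluster tree as a Newick string
#'
#' Branch lengths are ultrametric: every leaf sits at depth (root merge
#' height)/2, the standard dendrogram-to-phylogram conversion.
#'
#' @param tree a tree from [upgma()].
#' @return Newick string terminated by `;`.
#' @export
to_newick <- function(tree) {
  stopifnot(inherits(tree, "hclust"))
  ape::write.tree(ape::as.phylo(tree))
}

#' Write a distance matrix as TSV
#' @param D a [dist_matrix()].
#' @param path output file.
#' @export
write_dist_matrix <- function(D, path) {
  df <- data.frame(id = D$ids, D$d, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a flat cluster assignment as two-column TSV
#' @param assignment a `cluster_assignment`.
#' @param path output file.
#' @export
write_assignment <- function(assignment, path) {
  df <- data.frame(id = names(assignment$cluster),
                   cluster = unname(assignment$cluster))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
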