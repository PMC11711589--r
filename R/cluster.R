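#' Euclidean distance matrix between the rows of a matrix
#'
#' @param m Numeric entity x feature matrix with >= 2 rows and no missing
#'   values (impute upstream).
#' @return Symmetric matrix with zero diagonal, row/col names from `m`.
#' @export
euclidean_distance_matrix <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 2L) stop("need at least 2 entities")
  if (anyNA(m)) stop("missing values: impute before computing distances")
  as.matrix(stats::dist(m, method = "euclidean"))
}

#' Complete-linkage hierarchical clustering
#'
#' Standard agglomerative clustering with the complete (maximum) linkage
#' criterion on a Euclidean (or any) distance matrix, as performed by
#' [stats::hclust()]. Leaves are ordered by label before agglomeration so
#' that exact ties in the distance matrix are broken toward the pair with
#' the smallest leaf labels, making the dendrogram deterministic.
#'
#' @param d Symmetric distance matrix (or `dist`) with labeled entities.
#' @return An `hclust` object (method "complete").
#' @export
hcluster_complete <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (is.null(rownames(d))) {
    rownames(d) <- colnames(d) <- paste0("L", seq_len(nrow(d)))
  }
  ord <- order(rownames(d))
  d <- d[ord, ord, drop = FALSE]
  stats::hclust(stats::as.dist(d), method = "complete")
}

#' Cophenetic distance matrix of a dendrogram
#'
#' Entry (i, j) is the merge height at which leaves i and j first join; the
#' resulting matrix is ultrametric.
#'
#' @param tree An `hclust` object.
#' @return Symmetric matrix over the leaf labels.
#' @export
cophenetic_distances <- function(tree) {
  stopifnot(inherits(tree, "hclust"))
  as.matrix(stats::cophenetic(tree))
}

#' Cophenetic correlation between two dendrograms
#'
#' Pearson correlation between the vectorized upper triangles of the two
#' cophenetic matrices, with leaves aligned by label. Measures how
#' faithfully the two trees agree on pairwise relatedness; a tree against
#' itself gives exactly 1.
#'
#' @param t1,t2 `hclust` objects (or precomputed cophenetic/patristic
#'   distance matrices with identical label sets).
#' @param method "pearson" (default) or "spearman".
#' @return Correlation in [-1, 1]; NA with a warning when either vector has
#'   zero variance.
#' @export
cophenetic_correlation <- function(t1, t2, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  m1 <- if (inherits(t1, "hclust")) cophenetic_distances(t1) else as.matrix(t1)
  m2 <- if (inherits(t2, "hclust")) cophenetic_distances(t2) else as.matrix(t2)
  l1 <- rownames(m1); l2 <- rownames(m2)
  if (!setequal(l1, l2)) {
    stop("leaf sets differ: ",
         paste(c(setdiff(l1, l2), setdiff(l2, l1)), collapse = ", "))
  }
  m2 <- m2[l1, l1]
  v1 <- m1[upper.tri(m1)]
  v2 <- m2[upper.tri(m2)]
  if (length(v1) < 2L || stats::sd(v1) == 0 || stats::sd(v2) == 0) {
    warning("zero variance in a cophenetic vector; correlation undefined")
    return(NA_real_)
  }
  stats::cor(v1, v2, method = method)
}

#' Cluster strains from a presence/absence matrix
#'
#' Strains (columns) are clustered by Euclidean distance on their 0/1 gene
#' (or motif) profiles with complete linkage; strains differing in k entries
#' are at distance sqrt(k).
#'
#' @param m Logical or 0/1 matrix, entities (genes/motifs) x strains.
#' @return An `hclust` object over the strains.
#' @export
presence_absence_cluster <- function(m) {
  m <- t(as.matrix(m) * 1)
  hcluster_complete(euclidean_distance_matrix(m))
}

#' Patristic distance matrix from a Newick tree file
#'
#' Reads a precomputed phylogeny (e.g. a core-gene tree built elsewhere) and
#' returns its leaf-to-leaf path-length distances, directly usable in
#' [cophenetic_correlation()].
#'
#' @param path Path to a Newick file.
#' @return Symmetric matrix over the tip labels.
#' @export
read_tree_distances <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse Newick file: ", path)
  ape::cophenetic.phylo(tree)
}

#' Export a dendrogram as Newick
#'
#' Merge heights become node depths, so branch lengths reflect the
#' agglomeration heights.
#'
#' @param tree An `hclust` object.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_dendrogram_newick <- function(tree, path) {
  phy <- ape::as.phylo(tree)
  ape::write.tree(phy, file = path)
  invisible(path)
}
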