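#' Pearson-correlation distance between footprints
#'
#' `d(x, y) = 1 - r(x, y)` between the footprint vectors (columns) of the
#' median-RN matrix, so identical footprints are at distance 0 and
#' perfectly anti-correlated ones at distance 2. Branch lengths of the
#' dendrogram built from this matrix directly reflect footprint
#' dissimilarity.
#'
#' @param fp Numeric matrix, members x conditions (e.g. from
#'   [median_footprint()]).
#' @param centered If TRUE (default) the standard centered Pearson r; if
#'   FALSE the uncentered correlation (cosine similarity) offered by
#'   Cluster-3.0-family tools.
#' @return A symmetric `dist`-compatible matrix (conditions x conditions).
#' @export
pearson_distance <- function(fp, centered = TRUE) {
  fp <- as.matrix(fp)
  if (ncol(fp) < 2L) stop("need at least 2 conditions")
  if (nrow(fp) < 3L) stop("need at least 3 panel members")
  if (centered) {
    v <- apply(fp, 2L, stats::var)
    if (any(v == 0))
      stop("zero-variance footprint for condition(s): ",
           paste(colnames(fp)[v == 0], collapse = ", "))
    r <- cor(fp)
  } else {
    nrm <- sqrt(colSums(fp^2))
    if (any(nrm == 0))
      stop("all-zero footprint for condition(s): ",
           paste(colnames(fp)[nrm == 0], collapse = ", "))
    r <- crossprod(fp) / tcrossprod(nrm)
  }
  d <- 1 - r
  d[abs(d) < .Machine$double.eps^0.75] <- 0
  diag(d) <- 0
  d
}

#' Hierarchical clustering of footprints with Newick export
#'
#' Agglomerative clustering of the condition-wise distance matrix
#' (average linkage by default, the Cluster-3.0/TreeView family default;
#' single and complete linkage available). Conditions are ordered
#' lexicographically before clustering so equal-height merges resolve
#' reproducibly. The rooted dendrogram is serialized to Newick with
#' branch lengths derived from merge heights.
#'
#' @param d Symmetric distance matrix (e.g. from [pearson_distance()]) or
#'   a `dist` object.
#' @param linkage One of "average", "single", "complete".
#' @return A `footprint_tree`: list with `hclust`, `phylo` (ape), `newick`
#'   (string), `dist` (the input matrix), `linkage`.
#' @export
footprint_tree <- function(d, linkage = c("average", "single", "complete")) {
  linkage <- match.arg(linkage)
  m <- as.matrix(d)
  if (is.null(rownames(m)))
    rownames(m) <- colnames(m) <- paste0("C", seq_len(nrow(m)))
  if (nrow(m) == 1L) {
    warning("single condition: trivial one-leaf tree")
    nwk <- paste0(rownames(m)[1L], ";")
    return(structure(list(hclust = NULL, phylo = NULL, newick = nwk,
                          dist = m, linkage = linkage),
                     class = "footprint_tree"))
  }
  ord <- order(rownames(m))
  m <- m[ord, ord, drop = FALSE]
  hc <- hclust(as.dist(m), method = linkage)
  ph <- ape::as.phylo(hc)
  structure(list(hclust = hc, phylo = ph,
                 newick = ape::write.tree(ph),
                 dist = m, linkage = linkage),
            class = "footprint_tree")
}

#' @export
print.footprint_tree <- function(x, ...) {
  cat("Footprint tree (", x$linkage, " linkage, ", nrow(x$dist),
      " conditions)\n", sep = "")
  cat(" ", x$newick, "\n")
  invisible(x)
}

#' Write the Newick tree and distance matrix
#'
#' @param tree A `footprint_tree`.
#' @param dir Output directory; writes `tree.nwk` and `distance.tsv`.
#' @export
write_tree_files <- function(tree, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(tree$newick, file.path(dir, "tree.nwk"))
  write.table(data.frame(condition = rownames(tree$dist), tree$dist,
                         check.names = FALSE),
              file.path(dir, "distance.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(dir)
}

#' Squared Pearson correlation between replicate footprints
#'
#' Reproducibility statistic between two replicate RN vectors.
#'
#' @param rep_a,rep_b Numeric vectors of equal length (>= 3).
#' @return r-squared in `[0, 1]`.
#' @export
replicate_r2 <- function(rep_a, rep_b) {
  stopifnot(length(rep_a) == length(rep_b), length(rep_a) >= 3L)
  if (stats::var(rep_a) == 0 || stats::var(rep_b) == 0)
    stop("zero-variance replicate vector")
  cor(rep_a, rep_b)^2
}

#' Export a Cluster-3.0-style .cdt/.gtr pair
#'
#' Writes the footprint matrix and condition dendrogram in the tab-delimited
#' format read by TreeView-family viewers: conditions as clustered rows
#' (GIDs, described by the .gtr tree), panel members as columns. Node
#' scores in the .gtr are `1 - merge height`, i.e. the Pearson correlation
#' at which the pair joined.
#'
#' @param fp Members x conditions matrix (as clustered).
#' @param tree A `footprint_tree` over the conditions of `fp`.
#' @param prefix Output path prefix; writes `<prefix>.cdt` and
#'   `<prefix>.gtr`.
#' @export
write_cdt_gtr <- function(fp, tree, prefix) {
  stopifnot(inherits(tree, "footprint_tree"), !is.null(tree$hclust))
  hc <- tree$hclust
  labels <- hc$labels
  fp <- as.matrix(fp)[, labels, drop = FALSE]

  gid <- paste0("GENE", seq_along(labels), "X")
  node <- paste0("NODE", seq_along(hc$height), "X")
  ref <- function(k) if (k < 0) gid[-k] else node[k]
  gtr <- vapply(seq_along(hc$height), function(i) {
    paste(node[i], ref(hc$merge[i, 1L]), ref(hc$merge[i, 2L]),
          format(1 - hc$height[i], digits = 6), sep = "\t")
  }, "")
  writeLines(gtr, paste0(prefix, ".gtr"))

  ordl <- hc$order
  header <- paste(c("GID", "UNIQID", "NAME", "GWEIGHT", rownames(fp)),
                  collapse = "\t")
  eweight <- paste(c("EWEIGHT", "", "", "",
                     rep("1", nrow(fp))), collapse = "\t")
  body <- vapply(ordl, function(i) {
    paste(c(gid[i], labels[i], labels[i], "1",
            format(fp[, labels[i]], digits = 6)), collapse = "\t")
  }, "")
  writeLines(c(header, eweight, body), paste0(prefix, ".cdt"))
  invisible(prefix)
}
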