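#' Mean methylation profile per cell type
#'
#' Averages beta-values over subjects, giving the J x K matrix of cell-type
#' mean profiles used to infer the cell lineage.
#'
#' @param data A [meth_dataset].
#' @return Numeric matrix, cell types in rows, probes in columns.
#' @export
cell_type_means <- function(data) {
  stopifnot(inherits(data, "meth_dataset"))
  # beta is K x n x J; average over subjects
  means <- apply(data$beta, c(1L, 3L), mean)  # K x J
  t(means)
}

#' Infer cell lineage by hierarchical clustering
#'
#' Agglomerative clustering of cell-type mean methylation profiles under
#' Euclidean distance. Rows are ordered lexicographically by label before
#' clustering so that distance ties resolve deterministically.
#'
#' @param means J x K matrix of per-cell-type mean profiles, rownames = cell
#'   types (from [cell_type_means()]).
#' @param linkage One of `"complete"` (default), `"single"`, `"upgma"`,
#'   `"wpgma"`.
#' @return A `lineage_tree`: leaf labels, the (J-1) x 2 merge matrix with
#'   merge heights, the linkage label, and the underlying `hclust` object.
#' @export
infer_lineage <- function(means,
                          linkage = c("complete", "single", "upgma", "wpgma")) {
  linkage <- match.arg(linkage)
  stopifnot(is.matrix(means), nrow(means) >= 2L, !is.null(rownames(means)))
  means <- means[order(rownames(means)), , drop = FALSE]
  method <- c(complete = "complete", single = "single",
              upgma = "average", wpgma = "mcquitty")[[linkage]]
  hc <- hclust(dist(means, method = "euclidean"), method = method)
  structure(
    list(leaves = rownames(means),
         merges = cbind(hc$merge, height = hc$height),
         linkage = linkage,
         hclust = hc),
    class = "lineage_tree"
  )
}

#' @export
print.lineage_tree <- function(x, ...) {
  cat("<lineage_tree> ", length(x$leaves), " cell types, ",
      x$linkage, " linkage\n  leaves: ",
      paste(x$leaves, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Serialize a lineage tree as Newick
#'
#' Merge heights are converted to branch lengths (ultrametric tree).
#'
#' @param tree A `lineage_tree`.
#' @param path Optional file to write to.
#' @return The Newick string, invisibly if written to a file.
#' @export
lineage_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "lineage_tree"))
  phy <- ape::as.phylo(tree$hclust)
  txt <- ape::write.tree(phy)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Plot a cell lineage dendrogram
#'
#' @param tree A `lineage_tree`.
#' @param ... Passed to `plot.hclust`.
#' @return The tree, invisibly.
#' @export
plot_lineage <- function(tree, ...) {
  stopifnot(inherits(tree, "lineage_tree"))
  plot(tree$hclust, xlab = "", sub = "",
       main = paste0("Cell lineage (", tree$linkage, " linkage)"), ...)
  invisible(tree)
}
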