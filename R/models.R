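#' Construct a candidate cell-partition model
#'
#' A candidate model is a partition of the cell types into disjoint groups
#' sharing a mean methylation level. Cell-specific groups carry their own
#' mean; the pooled remainder is the reference partition against which
#' differential methylation is estimated.
#'
#' @param name Model label.
#' @param partition List of character vectors: disjoint, non-empty groups of
#'   cell-type labels covering every cell type.
#' @param cell_types Character vector fixing the row order of the design
#'   matrix. Defaults to the sorted union of the partition.
#' @param reference Index of the reference (pooled) partition, or `NA` for
#'   the saturated and null models.
#'
#' @return An object of class `candidate_model` with the partition, its
#'   reference index, the J x P one-hot design matrix and partition sizes.
#' @export
#' @examples
#' candidate_model("CD4_T", list("CD4", c("CD8", "CD14", "CD19")),
#'                 reference = 2)
candidate_model <- function(name, partition, cell_types = NULL,
                            reference = NA_integer_) {
  stopifnot(is.character(name), length(name) == 1L, is.list(partition))
  partition <- lapply(partition, as.character)
  if (any(lengths(partition) == 0L)) {
    stop("candidate_model: empty partition group in model '", name, "'")
  }
  members <- unlist(partition, use.names = FALSE)
  if (anyDuplicated(members)) {
    stop("candidate_model: cell type assigned to more than one group in '",
         name, "'")
  }
  if (is.null(cell_types)) cell_types <- sort(members)
  if (!setequal(members, cell_types)) {
    stop("candidate_model: partition of '", name,
         "' does not cover the cell types exactly")
  }
  if (!is.na(reference)) {
    reference <- as.integer(reference)
    stopifnot(reference >= 1L, reference <= length(partition))
  }
  J <- length(cell_types)
  P <- length(partition)
  design <- matrix(0L, nrow = J, ncol = P,
                   dimnames = list(cell_types, paste0("p", seq_len(P))))
  for (p in seq_len(P)) design[match(partition[[p]], cell_types), p] <- 1L
  structure(
    list(name = name, partition = partition,
         reference = if (is.na(reference)) NA_integer_ else reference,
         design = design, sizes = lengths(partition),
         cell_types = cell_types),
    class = "candidate_model"
  )
}

#' @export
print.candidate_model <- function(x, ...) {
  groups <- vapply(seq_along(x$partition), function(p) {
    g <- paste0("{", paste(x$partition[[p]], collapse = ","), "}")
    if (!is.na(x$reference) && p == x$reference) paste0(g, "*") else g
  }, character(1))
  cat("<candidate_model> ", x$name, ": ", paste(groups, collapse = ","),
      "\n", sep = "")
  invisible(x)
}

# canonical key identifying a set-partition irrespective of group order
partition_key <- function(partition) {
  groups <- vapply(partition, function(g) paste(sort(g), collapse = ","),
                   character(1))
  paste(sort(groups), collapse = ";")
}

#' Bundle candidate models with a prior
#'
#' @param models List of [candidate_model()] objects over the same cell
#'   types, with pairwise-distinct partitions.
#' @param prior Prior probability per model; defaults to equal weights.
#'
#' @return A `model_set` object.
#' @export
model_set <- function(models, prior = NULL) {
  stopifnot(is.list(models), length(models) >= 1L)
  if (!all(vapply(models, inherits, logical(1), "candidate_model"))) {
    stop("model_set: all elements must be candidate_model objects")
  }
  ct <- models[[1L]]$cell_types
  for (m in models) {
    if (!identical(m$cell_types, ct)) {
      stop("model_set: models disagree on cell types or their order")
    }
  }
  keys <- vapply(models, function(m) partition_key(m$partition), character(1))
  if (anyDuplicated(keys)) {
    stop("model_set: duplicate set-partitions: ",
         paste(unique(keys[duplicated(keys)]), collapse = " | "))
  }
  nm <- vapply(models, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("model_set: duplicate model names")
  if (is.null(prior)) prior <- rep(1 / length(models), length(models))
  stopifnot(length(prior) == length(models), all(prior >= 0))
  if (abs(sum(prior) - 1) > 1e-8) stop("model_set: prior must sum to 1")
  names(models) <- nm
  structure(list(models = models, prior = setNames(prior, nm),
                 cell_types = ct),
            class = "model_set")
}

#' @export
print.model_set <- function(x, ...) {
  cat("<model_set> ", length(x$models), " candidate models over ",
      length(x$cell_types), " cell types\n", sep = "")
  for (m in x$models) print(m)
  invisible(x)
}

#' @export
length.model_set <- function(x) length(x$models)

#' Enumerate candidate models from a cell lineage tree
#'
#' One single-cell model per leaf (that cell type gets its own mean, all
#' others pooled into the reference), one multi-cell model per internal
#' non-root node (member cell types each get their own mean, non-members
#' pooled), plus the null model (one common mean) and the saturated model
#' ("All", every cell type its own mean). Models whose set-partitions
#' coincide are deduplicated, keeping the Null/All/node-model name over a
#' leaf-model name; retained models receive an equal prior. For the
#' six-cell-type blood lineage this yields twelve distinct models.
#'
#' @param tree A [lineage_tree] from [infer_lineage()].
#'
#' @return A [model_set()].
#' @export
#' @examples
#' means <- rbind(A = c(0.1, 0.2), B = c(0.12, 0.22), C = c(0.8, 0.9))
#' enumerate_candidate_models(infer_lineage(means))
enumerate_candidate_models <- function(tree) {
  stopifnot(inherits(tree, "lineage_tree"))
  ct <- tree$leaves
  J <- length(ct)

  pooled_model <- function(name, members) {
    rest <- setdiff(ct, members)
    part <- c(as.list(members), if (length(rest)) list(rest))
    candidate_model(name, part, cell_types = ct,
                    reference = if (length(rest)) length(part) else NA)
  }

  cand <- list(
    candidate_model("Null", list(ct), cell_types = ct),
    candidate_model("All", as.list(ct), cell_types = ct)
  )
  # internal non-root nodes, in merge order (root = last merge)
  merges <- tree$merges
  if (nrow(merges) > 1L) {
    for (node in seq_len(nrow(merges) - 1L)) {
      members <- node_leaves(merges, node, ct)
      cand <- c(cand, list(pooled_model(paste(members, collapse = "+"),
                                        members)))
    }
  }
  for (leaf in ct) cand <- c(cand, list(pooled_model(leaf, leaf)))

  keys <- vapply(cand, function(m) partition_key(m$partition), character(1))
  model_set(cand[!duplicated(keys)])
}

# leaf labels under internal node `node` of an hclust-style merge matrix
node_leaves <- function(merges, node, labels) {
  stack <- node
  leaves <- integer(0)
  while (length(stack)) {
    k <- stack[[1L]]
    stack <- stack[-1L]
    for (child in merges[k, 1:2]) {
      if (child < 0) leaves <- c(leaves, -child) else stack <- c(stack, child)
    }
  }
  sort(labels[leaves])
}

#' Tabulate a model set
#'
#' @param x A `model_set`.
#' @param ... Unused.
#' @return A tibble with one row per model: name, number of partitions,
#'   the partition written as `{..},{..}*` (asterisk marking the reference
#'   partition), and the prior probability.
#' @method tidy model_set
#' @export
tidy.model_set <- function(x, ...) {
  tibble::tibble(
    model = vapply(x$models, `[[`, character(1), "name"),
    n_partitions = vapply(x$models, function(m) length(m$partition), 0L),
    partition = vapply(x$models, function(m) {
      paste(vapply(seq_along(m$partition), function(p) {
        g <- paste0("{", paste(m$partition[[p]], collapse = ","), "}")
        if (!is.na(m$reference) && p == m$reference) paste0(g, "*") else g
      }, character(1)), collapse = ",")
    }, character(1)),
    prior = unname(x$prior)
  )
}
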