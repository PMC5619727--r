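#' Validate a marker panel against external cell-sorted data
#'
#' For each training probe present in the validation data, the validation
#' mean difference (average beta of the cell-specific partition minus
#' average beta of the reference partition, each restricted to the cell
#' types available in the validation samples) is compared with the training
#' 95% credible interval (coverage) and with the training methylation state
#' (sign concordance). Cell types absent from the validation data are
#' handled by marginalising: only the available cell types of each
#' partition enter the validation average, which requires at least one
#' available cell type per compared partition.
#'
#' @param training Tibble from [differential_posterior()] (per-probe,
#'   per-partition training summaries).
#' @param validation_data A [meth_dataset] of validation samples.
#' @param model The [candidate_model()] the summaries were computed under.
#' @param baseline Baseline partition index for models without a reference.
#' @return A `validation_report`: per-probe tibble (`probe_id`,
#'   `partition`, `training_mean`, `ci_low`, `ci_high`,
#'   `validation_difference`, `covered`, `state_concordant`) and a summary
#'   tibble of percentages per partition plus, for multi-partition models,
#'   a joint (all partitions covered / concordant) row.
#' @export
validate_panel <- function(training, validation_data, model,
                           baseline = NULL) {
  stopifnot(is.data.frame(training), inherits(validation_data, "meth_dataset"),
            inherits(model, "candidate_model"))
  ref <- model$reference
  if (is.na(ref)) {
    if (is.null(baseline)) {
      stop("validate_panel: model has no reference partition; supply `baseline`")
    }
    ref <- as.integer(baseline)
  }
  avail <- validation_data$cell_types
  part_avail <- lapply(model$partition, intersect, avail)
  if (!length(part_avail[[ref]])) {
    stop("validate_panel: no validation cell types in the reference partition")
  }

  probes <- intersect(unique(training$probe_id), validation_data$probes)
  if (!length(probes)) {
    warning("validate_panel: no overlapping probes; empty report")
    return(structure(list(per_probe = tibble::tibble(),
                          summary = tibble::tibble()),
                     class = "validation_report"))
  }
  idx <- match(probes, validation_data$probes)
  # validation per-cell-type means, K' x J
  vmeans <- apply(validation_data$beta[idx, , , drop = FALSE], c(1L, 3L), mean)
  if (is.null(dim(vmeans))) {
    vmeans <- matrix(vmeans, nrow = length(idx),
                     dimnames = list(NULL, validation_data$cell_types))
  }
  ref_mean <- partition_mean(vmeans, part_avail[[ref]], avail)

  part_label <- vapply(model$partition, paste, character(1), collapse = ",")
  per_probe <- training |>
    dplyr::filter(.data$probe_id %in% probes) |>
    dplyr::rowwise() |>
    dplyr::mutate(p_idx = match(.data$partition, part_label)) |>
    dplyr::ungroup()
  if (anyNA(per_probe$p_idx)) {
    stop("validate_panel: training partitions do not match the model")
  }
  comparable <- lengths(part_avail)[per_probe$p_idx] > 0L
  if (any(!comparable)) {
    warning("validate_panel: ", sum(!comparable), " row(s) dropped: no ",
            "validation cell types in the compared partition")
    per_probe <- per_probe[comparable, , drop = FALSE]
  }

  k <- match(per_probe$probe_id, probes)
  vdiff <- vapply(seq_len(nrow(per_probe)), function(r) {
    partition_mean(vmeans[k[r], , drop = FALSE],
                   part_avail[[per_probe$p_idx[r]]], avail) - ref_mean[k[r]]
  }, numeric(1))

  per_probe <- per_probe |>
    dplyr::transmute(
      probe_id = .data$probe_id, partition = .data$partition,
      training_mean = .data$posterior_mean,
      ci_low = .data$ci_low, ci_high = .data$ci_high,
      state = .data$state,
      validation_difference = vdiff,
      covered = vdiff >= .data$ci_low & vdiff <= .data$ci_high,
      state_concordant = (.data$state == "hypomethylated" & vdiff < 0) |
        (.data$state == "hypermethylated" & vdiff > 0)
    )

  by_part <- per_probe |>
    dplyr::group_by(.data$partition) |>
    dplyr::summarise(n = dplyr::n(),
                     pct_covered = 100 * mean(.data$covered),
                     pct_concordant = 100 * mean(.data$state_concordant),
                     .groups = "drop")
  summary <- by_part
  if (dplyr::n_distinct(per_probe$partition) > 1L) {
    joint <- per_probe |>
      dplyr::group_by(.data$probe_id) |>
      dplyr::summarise(covered = all(.data$covered),
                       concordant = all(.data$state_concordant),
                       .groups = "drop")
    summary <- dplyr::bind_rows(
      by_part,
      tibble::tibble(partition = "joint", n = nrow(joint),
                     pct_covered = 100 * mean(joint$covered),
                     pct_concordant = 100 * mean(joint$concordant))
    )
  }
  structure(list(per_probe = per_probe, summary = summary),
            class = "validation_report")
}

# mean beta over the available cell types of one partition
partition_mean <- function(vmeans, cells, avail) {
  cols <- match(cells, avail)
  if (length(cols) == 1L) vmeans[, cols]
  else rowMeans(vmeans[, cols, drop = FALSE])
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report> ", nrow(x$per_probe), " probe-partition rows\n",
      sep = "")
  if (nrow(x$summary)) print(x$summary)
  invisible(x)
}

#' Cross-tabulate genomic features of a marker panel
#'
#' Tallies the genomic-feature annotation (1stExon, 3'UTR, 5'UTR, Body,
#' Intergenic, TSS1500, TSS200) of the panel's probes; percentages are over
#' annotated probes and sum to 100. Probes absent from the annotation are
#' counted as unannotated and reported via a warning and the
#' `n_unannotated` attribute.
#'
#' @param panel A `marker_panel` or a character vector of probe ids.
#' @param annotation Data frame with columns `probe_id` and `feature`
#'   (values from the fixed vocabulary).
#' @return Tibble with `feature`, `n`, `percent` (empty, with a warning,
#'   for an empty panel).
#' @export
cross_tabulate_features <- function(panel, annotation) {
  probes <- if (inherits(panel, "marker_panel")) panel$probes$probe_id
            else as.character(panel)
  vocab <- c("1stExon", "3'UTR", "5'UTR", "Body", "Intergenic",
             "TSS1500", "TSS200")
  stopifnot(is.data.frame(annotation),
            all(c("probe_id", "feature") %in% names(annotation)))
  if (anyDuplicated(annotation$probe_id)) {
    stop("cross_tabulate_features: duplicated probe_id in annotation")
  }
  if (!all(annotation$feature %in% vocab)) {
    stop("cross_tabulate_features: feature outside the vocabulary: ",
         paste(setdiff(unique(annotation$feature), vocab), collapse = ", "))
  }
  if (!length(probes)) {
    warning("cross_tabulate_features: empty panel")
    out <- tibble::tibble(feature = character(), n = integer(),
                          percent = numeric())
    attr(out, "n_unannotated") <- 0L
    return(out)
  }
  feat <- annotation$feature[match(probes, annotation$probe_id)]
  n_unann <- sum(is.na(feat))
  if (n_unann) {
    warning("cross_tabulate_features: ", n_unann,
            " probe(s) absent from the annotation (counted as unannotated)")
  }
  feat <- feat[!is.na(feat)]
  counts <- table(factor(feat, levels = vocab))
  out <- tibble::tibble(
    feature = vocab,
    n = as.integer(counts),
    percent = if (length(feat)) 100 * as.integer(counts) / length(feat)
              else rep(NA_real_, length(vocab))
  )
  attr(out, "n_unannotated") <- n_unann
  out
}
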