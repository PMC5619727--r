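#' The six sorted blood cell types used throughout
#'
#' @return Character vector of cell-type labels.
#' @export
blood_cell_types <- function() {
  c("CD14_Mono", "CD16_Neu", "CD19_B", "CD4_T", "CD56_NK", "CD8_T")
}

#' Candidate models for the blood cell lineage
#'
#' The twelve candidate partitions implied by the hematopoietic lineage of
#' the six sorted cell types (myeloid branch CD14+ monocytes / CD16+
#' neutrophils; lymphoid branch CD19+ B cells and, nested, CD56+ NK and the
#' T cells): the null and saturated models, one single-cell model per cell
#' type, and the multi-cell Myeloid, Pan T, Lymphocyte-II (T cells + NK)
#' and Lymphocyte-I (all lymphocytes) models. In each model except "All"
#' the pooled non-members form the reference partition.
#'
#' @param cell_types Labels for (monocytes, neutrophils, B, CD4 T, NK,
#'   CD8 T), in that role order; default [blood_cell_types()].
#' @return A [model_set()].
#' @export
blood_cell_models <- function(cell_types = blood_cell_types()) {
  stopifnot(length(cell_types) == 6L)
  ct <- sort(cell_types)
  mono <- cell_types[1L]; neu <- cell_types[2L]; b <- cell_types[3L]
  cd4 <- cell_types[4L]; nk <- cell_types[5L]; cd8 <- cell_types[6L]
  pooled <- function(name, members) {
    rest <- setdiff(ct, members)
    candidate_model(name, c(as.list(sort(members)), list(rest)),
                    cell_types = ct, reference = length(members) + 1L)
  }
  model_set(c(
    list(candidate_model("Null", list(ct), cell_types = ct),
         candidate_model("All", as.list(ct), cell_types = ct),
         pooled("Myeloid", c(mono, neu)),
         pooled("Pan_T", c(cd4, cd8)),
         pooled("Lymphocyte_II", c(cd4, cd8, nk)),
         pooled("Lymphocyte_I", c(b, cd4, cd8, nk))),
    lapply(ct, function(j) pooled(j, j))
  ))
}

#' Simulation configuration
#'
#' Defines the generative conditions: per probe a candidate model is drawn
#' from `model_mixture`; the reference partition sits at a baseline level,
#' each cell-specific partition is offset by `effect_size` with a random
#' sign; subjects observe the cell-type means plus i.i.d. Gaussian noise,
#' clipped to \[0, 1\]. Optional sex effects add a mean shift to one
#' partition in females.
#'
#' @param cell_types Cell-type labels; default [blood_cell_types()].
#' @param models A [model_set()]; default [blood_cell_models()].
#' @param K Number of probes, default 2000.
#' @param n_per_sex Named subject counts, default `c(F = 5, M = 6)` (the
#'   training cohort sizes).
#' @param model_mixture Named probability per model; default 90% null with
#'   the remaining 10% spread equally over the other models.
#' @param effect_size Partition-mean offset: scalar (default 0.3) or a
#'   range `c(lo, hi)` sampled per partition.
#' @param baseline Reference level: scalar or range, default `c(0.2, 0.8)`
#'   (keeps clipping rare at sigma <= 0.05).
#' @param sigma Within-CpG noise sd, default 0.02.
#' @param sex_shift `NULL` (none) or `list(delta =, prob =)`: with
#'   probability `prob` a probe gets a `delta` shift, applied in females to
#'   one randomly chosen partition of its generating model.
#' @param seed Integer seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(cell_types = blood_cell_types(), models = NULL,
                       K = 2000L, n_per_sex = c(F = 5L, M = 6L),
                       model_mixture = NULL, effect_size = 0.3,
                       baseline = c(0.2, 0.8), sigma = 0.02,
                       sex_shift = NULL, seed = 1L) {
  if (is.null(models)) {
    models <- if (length(cell_types) == 6L) blood_cell_models(cell_types)
              else stop("sim_config: supply `models` for non-default cell types")
  }
  stopifnot(inherits(models, "model_set"), K >= 1L, sigma > 0,
            all(n_per_sex >= 2L), all(c("F", "M") %in% names(n_per_sex)))
  nm <- names(models$models)
  if (is.null(model_mixture)) {
    model_mixture <- setNames(rep(0.1 / (length(nm) - 1L), length(nm)), nm)
    model_mixture["Null"] <- 0.9
  }
  stopifnot(setequal(names(model_mixture), nm), all(model_mixture >= 0))
  if (abs(sum(model_mixture) - 1) > 1e-8) {
    stop("sim_config: model_mixture must sum to 1")
  }
  if (!is.null(sex_shift)) {
    stopifnot(is.list(sex_shift), sex_shift$delta >= 0,
              sex_shift$prob >= 0, sex_shift$prob <= 1)
  }
  structure(list(cell_types = sort(cell_types), models = models, K = as.integer(K),
                 n_per_sex = n_per_sex, model_mixture = model_mixture[nm],
                 effect_size = effect_size, baseline = baseline,
                 sigma = sigma, sex_shift = sex_shift,
                 seed = as.integer(seed)),
            class = "sim_config")
}

draw_level <- function(spec, n) {
  if (length(spec) == 1L) rep(spec, n) else runif(n, spec[1L], spec[2L])
}

#' Generate a synthetic cell-sorted methylation study
#'
#' @param config A [sim_config()].
#' @return List with `F` and `M` [meth_dataset]s, `truth` (a `sim_truth`:
#'   per-probe generating model and sex-effect flags plus the true per-sex
#'   cell-type mean matrices), the model set, and clipping counts.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ct <- config$cell_types
  J <- length(ct); K <- config$K
  models <- config$models
  nm <- names(models$models)

  assignment <- sample(nm, K, replace = TRUE, prob = config$model_mixture)
  probe_ids <- sprintf("cg%06d", seq_len(K))
  means <- matrix(NA_real_, K, J, dimnames = list(probe_ids, ct))
  base <- draw_level(config$baseline, K)

  for (m in nm) {
    rows <- which(assignment == m)
    if (!length(rows)) next
    mod <- models$models[[m]]
    ref <- mod$reference
    for (p in seq_along(mod$partition)) {
      cols <- match(mod$partition[[p]], ct)
      if (!is.na(ref) && p == ref) {
        lev <- base[rows]
      } else if (is.na(ref) && length(mod$partition) == 1L) {
        lev <- base[rows]                     # null model: one common level
      } else {
        sign <- sample(c(-1, 1), length(rows), replace = TRUE)
        lev <- base[rows] + sign * draw_level(config$effect_size, length(rows))
      }
      means[rows, cols] <- lev
    }
  }
  means <- pmin(pmax(means, 0), 1)
  # truth records the coarsest candidate consistent with the drawn means:
  # random +/- offsets can make partitions coincide (or clipping can merge
  # levels), in which case the realized pattern IS that of a coarser model
  assignment <- coarsest_consistent_model(means, models)

  # sex effects: shift one random partition of the generating model, females
  sex_flag <- rep(FALSE, K)
  sex_part <- rep(NA_character_, K)
  means_f <- means
  if (!is.null(config$sex_shift)) {
    hit <- runif(K) < config$sex_shift$prob
    for (k in which(hit)) {
      mod <- models$models[[assignment[k]]]
      # shift a cell-specific partition (the target of sex-effect inference);
      # the null model has only its single pooled partition
      eligible <- if (is.na(mod$reference)) seq_along(mod$partition)
                  else setdiff(seq_along(mod$partition), mod$reference)
      p <- eligible[sample.int(length(eligible), 1L)]
      cols <- match(mod$partition[[p]], ct)
      means_f[k, cols] <- pmin(pmax(means_f[k, cols] + config$sex_shift$delta,
                                    0), 1)
      sex_flag[k] <- TRUE
      sex_part[k] <- paste(mod$partition[[p]], collapse = ",")
    }
  }

  clipped <- c(F = 0L, M = 0L)
  make_sex <- function(mu, sex) {
    n <- config$n_per_sex[[sex]]
    noise <- array(rnorm(K * n * J, sd = config$sigma), dim = c(K, n, J))
    # expand K x J means to K x n x J
    beta <- aperm(array(mu, dim = c(K, J, n)), c(1L, 3L, 2L)) + noise
    nclip <- sum(beta < 0 | beta > 1)
    clipped[sex] <<- nclip
    beta <- pmin(pmax(beta, 0), 1)
    dimnames(beta) <- list(probe_ids, paste0(tolower(sex), seq_len(n)), ct)
    meth_dataset(beta, sex = sex)
  }
  data_f <- make_sex(means_f, "F")
  data_m <- make_sex(means, "M")
  total <- K * J * sum(config$n_per_sex[c("F", "M")])
  if (sum(clipped) / total > 0.10) {
    warning("simulate_dataset: ", signif(100 * sum(clipped) / total, 3),
            "% of values clipped to [0,1]; config likely unrealistic")
  }

  truth <- structure(
    list(probes = tibble::tibble(probe_id = probe_ids, model = assignment,
                                 baseline = base, sex_effect = sex_flag,
                                 sex_effect_partition = sex_part),
         means = list(F = means_f, M = means),
         cell_types = ct),
    class = "sim_truth"
  )
  list(F = data_f, M = data_m, truth = truth, models = models,
       config = config, clipped = clipped)
}

# For each probe (row of the K x J mean matrix), the name of the candidate
# model with fewest partitions whose grouping the mean vector respects
# exactly (constant within every partition group). Ties broken by model
# order. The saturated model is always consistent, so a match exists.
coarsest_consistent_model <- function(means, models) {
  ct <- colnames(means)
  ord <- order(vapply(models$models, function(m) length(m$partition), 0L))
  out <- rep(NA_character_, nrow(means))
  todo <- rep(TRUE, nrow(means))
  for (m in ord) {
    mod <- models$models[[m]]
    if (!any(todo)) break
    ok <- todo
    for (grp in mod$partition) {
      if (length(grp) == 1L || !any(ok)) next
      cols <- match(grp, ct)
      block <- means[, cols, drop = FALSE]
      spread <- apply(block, 1L, max) - apply(block, 1L, min)
      ok <- ok & (spread == 0)
    }
    out[ok] <- mod$name
    todo <- todo & !ok
  }
  out
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("<sim_truth> ", nrow(x$probes), " probes; model counts:\n", sep = "")
  print(table(x$probes$model))
  invisible(x)
}

#' Serialize / restore simulation truth
#'
#' @param truth A `sim_truth`.
#' @param path TSV path.
#' @return `write_truth` returns the path invisibly; `read_truth` the
#'   restored `sim_truth`.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "sim_truth"))
  wide <- truth$probes
  for (s in c("F", "M")) {
    mm <- tibble::as_tibble(truth$means[[s]])
    names(mm) <- paste0("mean_", s, "_", truth$cell_types)
    wide <- dplyr::bind_cols(wide, mm)
  }
  write_tsv_with_header(wide, path)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, comment = "#",
                         progress = FALSE)
  ct <- sub("^mean_F_", "", grep("^mean_F_", names(tbl), value = TRUE))
  means <- lapply(c(F = "F", M = "M"), function(s) {
    m <- as.matrix(tbl[, paste0("mean_", s, "_", ct)])
    dimnames(m) <- list(tbl$probe_id, ct)
    m
  })
  structure(
    list(probes = tbl[, c("probe_id", "model", "baseline", "sex_effect",
                          "sex_effect_partition")],
         means = means, cell_types = ct),
    class = "sim_truth"
  )
}

#' Recovery metrics of a fit and marker panels against simulation truth
#'
#' @param truth A `sim_truth`.
#' @param fit A `meth_fit` on the simulated data.
#' @param panels Named list of `marker_panel`s (from
#'   [select_all_markers()]); optional.
#' @param sex_effects Tibble from [sex_effect_posterior()] (any models,
#'   row-bound); optional.
#' @return List of tibbles: `modal` (per-probe modal model vs truth),
#'   `confusion`, `accuracy`, `panel_metrics` (per-model precision, recall,
#'   realized false-discovery proportion; empty panels count recall 0 and
#'   FDP 0), `fdp` (pooled over non-null panels), and `sex_effect`
#'   (sensitivity/specificity) when supplied.
#' @export
recovery_report <- function(truth, fit, panels = NULL, sex_effects = NULL) {
  stopifnot(inherits(truth, "sim_truth"), inherits(fit, "meth_fit"))
  idx <- match(fit$probes, truth$probes$probe_id)
  if (anyNA(idx)) stop("recovery_report: fit probes not in truth")
  true_model <- truth$probes$model[idx]
  modal <- colnames(fit$posterior_probs)[max.col(fit$posterior_probs,
                                                 ties.method = "first")]
  modal_tbl <- tibble::tibble(probe_id = fit$probes, true_model = true_model,
                              modal_model = modal)
  confusion <- modal_tbl |>
    dplyr::count(.data$true_model, .data$modal_model, name = "n")
  accuracy <- mean(modal == true_model)

  out <- list(modal = modal_tbl, confusion = confusion,
              accuracy = tibble::tibble(modal_model_accuracy = accuracy))
  if (!is.null(panels)) {
    pm <- purrr::map_dfr(names(panels), function(m) {
      sel <- panels[[m]]$probes$probe_id
      truth_m <- truth$probes$probe_id[truth$probes$model == m]
      tp <- length(intersect(sel, truth_m))
      tibble::tibble(
        model = m, n_selected = length(sel), n_true = length(truth_m),
        precision = if (length(sel)) tp / length(sel) else NA_real_,
        recall = if (length(truth_m)) tp / length(truth_m)
                 else NA_real_,
        fdp = if (length(sel)) 1 - tp / length(sel) else 0
      )
    })
    pm$recall[pm$n_selected == 0L & pm$n_true > 0L] <- 0
    out$panel_metrics <- pm
    nonnull <- pm[pm$model != "Null", , drop = FALSE]
    n_sel <- sum(nonnull$n_selected)
    n_false <- sum(nonnull$n_selected * nonnull$fdp)
    out$fdp <- tibble::tibble(
      n_selected = n_sel,
      pooled_fdp = if (n_sel) n_false / n_sel else 0
    )
  }
  if (!is.null(sex_effects)) {
    decl <- sex_effects |>
      dplyr::distinct(.data$probe_id, .data$declared)
    tt <- dplyr::left_join(
      decl,
      truth$probes[, c("probe_id", "sex_effect")], by = "probe_id")
    out$sex_effect <- tibble::tibble(
      sensitivity = if (any(tt$sex_effect)) {
        mean(tt$declared[tt$sex_effect])
      } else NA_real_,
      specificity = if (any(!tt$sex_effect)) {
        mean(!tt$declared[!tt$sex_effect])
      } else NA_real_
    )
  }
  out
}
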