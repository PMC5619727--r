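#' Read a probe-by-sample beta-value matrix
#'
#' The first column holds probe identifiers, the header row sample
#' identifiers, and the body methylation beta-values in \[0, 1\].
#'
#' @param path Path to a delimited text file.
#' @param delimiter Field delimiter, default tab.
#' @return A tibble with `probe_id` first, one numeric column per sample.
#' @export
load_beta_matrix <- function(path, delimiter = "\t") {
  tbl <- readr::read_delim(path, delim = delimiter, show_col_types = FALSE,
                           comment = "#", progress = FALSE)
  names(tbl)[1L] <- "probe_id"
  tbl$probe_id <- as.character(tbl$probe_id)
  if (ncol(tbl) < 2L) stop("load_beta_matrix: no sample columns in ", path)
  dup <- unique(tbl$probe_id[duplicated(tbl$probe_id)])
  if (length(dup)) {
    stop("load_beta_matrix: duplicated probe_id: ",
         paste(head(dup, 5L), collapse = ", "))
  }
  vals <- as.matrix(tbl[, -1L])
  if (!is.numeric(vals)) stop("load_beta_matrix: non-numeric beta values")
  bad <- which(!is.na(vals) & (vals < 0 | vals > 1), arr.ind = TRUE)
  if (nrow(bad)) {
    cells <- apply(head(bad, 5L), 1L, function(ij) {
      paste0(tbl$probe_id[ij[1L]], "/", colnames(vals)[ij[2L]],
             "=", signif(vals[ij[1L], ij[2L]], 4))
    })
    stop("load_beta_matrix: beta values outside [0,1]: ",
         paste(cells, collapse = ", "))
  }
  tbl
}

#' Validate a sample sheet
#'
#' @param sheet Data frame with columns `sample_id`, `subject_id`,
#'   `cell_type`, `sex` (values `"F"`/`"M"`).
#' @return The sheet as a tibble, validated.
#' @export
validate_sample_sheet <- function(sheet) {
  sheet <- tibble::as_tibble(sheet)
  need <- c("sample_id", "subject_id", "cell_type", "sex")
  missing <- setdiff(need, names(sheet))
  if (length(missing)) {
    stop("sample sheet is missing columns: ", paste(missing, collapse = ", "))
  }
  if (is.logical(sheet$sex)) {
    # a single-sex CSV column of "F" parses as logical
    sheet$sex <- ifelse(sheet$sex, "T", "F")
  }
  sheet <- dplyr::mutate(sheet, dplyr::across(dplyr::all_of(need), as.character))
  if (anyDuplicated(sheet$sample_id)) {
    stop("sample sheet: duplicated sample_id: ",
         paste(unique(sheet$sample_id[duplicated(sheet$sample_id)]),
               collapse = ", "))
  }
  if (!all(sheet$sex %in% c("F", "M"))) {
    stop("sample sheet: sex must be 'F' or 'M'")
  }
  combo <- paste(sheet$subject_id, sheet$cell_type, sheet$sex, sep = "\r")
  if (anyDuplicated(combo)) {
    stop("sample sheet: duplicate (subject_id, cell_type, sex) combination")
  }
  for (s in unique(sheet$sex)) {
    if (length(unique(sheet$cell_type[sheet$sex == s])) < 2L) {
      stop("sample sheet: fewer than 2 cell types for sex ", s)
    }
  }
  sheet
}

#' Assemble a per-sex methylation dataset
#'
#' Builds the K x n x J beta tensor for one sex from a beta table and a
#' sample sheet. Subjects missing any cell type are dropped (with a
#' message), as are probes with any missing value; the model has no
#' missing-data mechanism.
#'
#' @param beta_table Probe-by-sample tibble from [load_beta_matrix()].
#' @param sheet Sample sheet (see [validate_sample_sheet()]).
#' @param sex `"F"` or `"M"`.
#' @param cell_type_order Optional explicit cell-type ordering (e.g. a
#'   lineage ordering); default lexicographic.
#' @return A `meth_dataset`: probe ids, subjects, cell types, sex, and the
#'   beta array indexed probe x subject x cell type.
#' @export
assemble_dataset <- function(beta_table, sheet, sex,
                             cell_type_order = NULL) {
  sheet <- validate_sample_sheet(sheet)
  stopifnot(sex %in% c("F", "M"))
  sheet <- sheet[sheet$sex == sex, , drop = FALSE]
  if (!nrow(sheet)) stop("assemble_dataset: no samples for sex ", sex)
  absent <- setdiff(sheet$sample_id, names(beta_table)[-1L])
  if (length(absent)) {
    stop("assemble_dataset: sample_id not in beta table: ",
         paste(absent, collapse = ", "))
  }

  cell_types <- sort(unique(sheet$cell_type))
  if (!is.null(cell_type_order)) {
    if (!setequal(cell_type_order, cell_types)) {
      stop("assemble_dataset: cell_type_order does not match observed cell types")
    }
    cell_types <- cell_type_order
  }
  for (j in cell_types) {
    if (!any(sheet$cell_type == j)) {
      stop("assemble_dataset: cell type observed for no subject: ", j)
    }
  }

  # subjects with a sample for every cell type
  subj_tab <- table(sheet$subject_id, sheet$cell_type)
  complete <- rownames(subj_tab)[apply(subj_tab[, cell_types, drop = FALSE] > 0,
                                       1L, all)]
  dropped_subj <- setdiff(unique(sheet$subject_id), complete)
  if (length(dropped_subj)) {
    message("assemble_dataset: dropped ", length(dropped_subj),
            " subject(s) missing >=1 cell type: ",
            paste(dropped_subj, collapse = ", "))
  }
  if (length(complete) < 2L) {
    stop("assemble_dataset: fewer than 2 complete subjects for sex ", sex)
  }
  subjects <- sort(complete)

  probes <- beta_table$probe_id
  K <- length(probes); n <- length(subjects); J <- length(cell_types)
  beta <- array(NA_real_, dim = c(K, n, J),
                dimnames = list(probes, subjects, cell_types))
  for (j in seq_len(J)) {
    for (i in seq_len(n)) {
      sid <- sheet$sample_id[sheet$subject_id == subjects[i] &
                               sheet$cell_type == cell_types[j]]
      beta[, i, j] <- beta_table[[sid]]
    }
  }
  keep <- !apply(is.na(beta), 1L, any)
  if (any(!keep)) {
    message("assemble_dataset: dropped ", sum(!keep),
            " probe(s) with missing values")
    beta <- beta[keep, , , drop = FALSE]
    probes <- probes[keep]
  }
  if (!length(probes)) stop("assemble_dataset: no complete probes remain")

  meth_dataset(beta, sex = sex,
               n_dropped_subjects = length(dropped_subj),
               n_dropped_probes = sum(!keep))
}

#' Construct a methylation dataset from a beta array
#'
#' @param beta K x n x J numeric array with dimnames (probes, subjects,
#'   cell types), all values in \[0, 1\], no missing entries.
#' @param sex `"F"` or `"M"`.
#' @param n_dropped_subjects,n_dropped_probes Assembly bookkeeping.
#' @return A `meth_dataset`.
#' @export
meth_dataset <- function(beta, sex, n_dropped_subjects = 0L,
                         n_dropped_probes = 0L) {
  stopifnot(is.array(beta), length(dim(beta)) == 3L,
            !is.null(dimnames(beta)), sex %in% c("F", "M"))
  if (anyNA(beta)) stop("meth_dataset: missing beta values")
  if (any(beta < 0 | beta > 1)) stop("meth_dataset: beta values outside [0,1]")
  if (dim(beta)[3L] < 2L) stop("meth_dataset: need >=2 cell types")
  if (dim(beta)[2L] < 2L) stop("meth_dataset: need >=2 subjects")
  structure(
    list(probes = dimnames(beta)[[1L]],
         subjects = dimnames(beta)[[2L]],
         cell_types = dimnames(beta)[[3L]],
         beta = beta, sex = sex,
         n_dropped_subjects = as.integer(n_dropped_subjects),
         n_dropped_probes = as.integer(n_dropped_probes)),
    class = "meth_dataset"
  )
}

#' @export
print.meth_dataset <- function(x, ...) {
  cat("<meth_dataset> sex ", x$sex, ": ", length(x$probes), " probes x ",
      length(x$subjects), " subjects x ", length(x$cell_types),
      " cell types\n", sep = "")
  invisible(x)
}

#' @export
dim.meth_dataset <- function(x) dim(x$beta)

#' Long-format view of a methylation dataset
#'
#' @param x A `meth_dataset`.
#' @param ... Unused.
#' @return Tibble with columns probe_id, subject_id, cell_type, sex, beta.
#' @method as_tibble meth_dataset
#' @export
as_tibble.meth_dataset <- function(x, ...) {
  grid <- expand.grid(probe_id = x$probes, subject_id = x$subjects,
                      cell_type = x$cell_types,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  tibble::as_tibble(grid) |>
    dplyr::mutate(sex = x$sex, beta = as.vector(x$beta))
}

#' Write a dataset back to a beta matrix + sample sheet
#'
#' Inverse of [assemble_dataset()]: sample ids are formed as
#' `<subject>_<cell type>`.
#'
#' @param data A `meth_dataset`.
#' @param beta_path,sheet_path Output paths (TSV and CSV).
#' @param header Optional character vector of '#'-prefixed metadata lines.
#' @return Invisibly, a list with the beta tibble and the sheet.
#' @export
write_dataset <- function(data, beta_path, sheet_path, header = NULL) {
  stopifnot(inherits(data, "meth_dataset"))
  K <- length(data$probes)
  wide <- matrix(aperm(data$beta, c(1L, 3L, 2L)), nrow = K)
  ids <- as.vector(outer(data$cell_types, data$subjects,
                         function(j, i) paste(i, j, sep = "_")))
  colnames(wide) <- ids
  tbl <- dplyr::bind_cols(tibble::tibble(probe_id = data$probes),
                          tibble::as_tibble(wide))
  write_tsv_with_header(tbl, beta_path, header)
  sheet <- tibble::tibble(
    sample_id = ids,
    subject_id = rep(data$subjects, each = length(data$cell_types)),
    cell_type = rep(data$cell_types, times = length(data$subjects)),
    sex = data$sex
  )
  readr::write_csv(sheet, sheet_path, progress = FALSE)
  invisible(list(beta = tbl, sheet = sheet))
}

#' Write a TSV with a '#'-prefixed metadata header block
#'
#' @param x Data frame.
#' @param path Output path.
#' @param header Character vector of metadata lines (prefixed with `# ` if
#'   not already).
#' @export
write_tsv_with_header <- function(x, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header) && length(header)) {
    header <- ifelse(startsWith(header, "#"), header, paste("#", header))
    writeLines(header, con)
  }
  writeLines(paste(names(x), collapse = "\t"), con)
  body <- do.call(paste, c(lapply(x, format_tsv_field), list(sep = "\t")))
  if (length(body)) writeLines(body, con)
  invisible(path)
}

format_tsv_field <- function(v) {
  if (is.numeric(v)) {
    vapply(v, function(x) format(x, digits = 10, trim = TRUE), character(1))
  } else {
    as.character(v)
  }
}

#' Standard metadata header for output files
#'
#' @param ... Named values recorded as `# name: value` lines.
#' @return Character vector of header lines.
#' @export
output_header <- function(...) {
  vals <- list(...)
  c(paste0("# cellmeth ",
           as.character(utils::packageVersion("cellmeth"))),
    vapply(names(vals), function(nm) {
      paste0("# ", nm, ": ", paste(format(vals[[nm]], digits = 8),
                                   collapse = ", "))
    }, character(1)))
}
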