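# Plain-text readers and writers for the pipeline's tabular interchange
# formats. TSV for PSM tables and count matrices, CSV for TMA, WB and MRM
# inputs; truth tables from the generators travel as sidecar TSVs whose
# extra columns carry a `truth_` prefix.

#' Read a PSM table from TSV
#'
#' Expected columns: \code{spectrum_id}, \code{peptide}, \code{accessions}
#' (";"-joined), \code{charge}, \code{xcorr}, \code{delta_cn},
#' \code{is_decoy}. When \code{is_decoy} is absent it is derived from the
#' accession prefix.
#'
#' @param path file path.
#' @param decoy_prefix accession prefix marking reversed-database entries.
#' @return data frame of PSM records.
#' @export
read_psm_table <- function(path, decoy_prefix = "REV_") {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("spectrum_id", "peptide", "accessions", "charge", "xcorr",
            "delta_cn")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("PSM table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (is.null(df$is_decoy))
    df$is_decoy <- startsWith(df$accessions, decoy_prefix)
  df$is_decoy <- as.logical(df$is_decoy)
  df
}

#' Write a PSM table to TSV
#' @param psms data frame of PSM records.
#' @param path file path.
#' @export
write_psm_table <- function(psms, path) {
  utils::write.table(psms, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Read a spectral-count matrix with its cohort labels
#'
#' The matrix TSV has proteins as rows (first column \code{protein_id}) and
#' samples as columns; the sidecar TSV maps \code{sample_id} to
#' \code{group}.
#'
#' @param path matrix TSV path.
#' @param group_path sidecar TSV path with columns \code{sample_id},
#'   \code{group}.
#' @return list with \code{counts} (integer matrix) and \code{group}
#'   (named character vector).
#' @export
read_count_matrix <- function(path, group_path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "protein_id")
    stop("first column of the count matrix must be 'protein_id'")
  counts <- as.matrix(df[, -1, drop = FALSE])
  rownames(counts) <- df$protein_id
  storage.mode(counts) <- "integer"
  gr <- utils::read.delim(group_path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(gr)))
    stop("group sidecar needs columns sample_id, group")
  miss <- setdiff(colnames(counts), gr$sample_id)
  if (length(miss)) stop("no group label for sample(s): ",
                         paste(miss, collapse = ", "))
  group <- stats::setNames(gr$group, gr$sample_id)[colnames(counts)]
  list(counts = counts, group = group)
}

#' Write a spectral-count matrix, cohort labels and optional truth sidecar
#'
#' @param sim a \code{\link{generate_count_matrix}} result (or any list
#'   with \code{counts}, \code{group} and optionally \code{truth}).
#' @param path matrix TSV path.
#' @param group_path sidecar TSV path for sample-to-group labels.
#' @param truth_path optional sidecar TSV path for the ground-truth table.
#' @export
write_count_matrix <- function(sim, path, group_path, truth_path = NULL) {
  df <- data.frame(protein_id = rownames(sim$counts), sim$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  gr <- data.frame(sample_id = names(sim$group), group = unname(sim$group))
  utils::write.table(gr, group_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(truth_path) && !is.null(sim$truth))
    utils::write.table(sim$truth, truth_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(NULL)
}

#' Read TMA section readings from CSV
#'
#' Columns: \code{case_id}, \code{tissue}, \code{rater}, \code{percent},
#' \code{intensity}.
#' @param path file path.
#' @return data frame suitable for \code{\link{quick_score}}.
#' @export
read_tma_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("case_id", "tissue", "rater", "percent", "intensity")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("TMA CSV missing column(s): ",
                         paste(miss, collapse = ", "))
  df
}

#' Read western-blot densitometry from CSV
#'
#' Columns: \code{sample_id}, \code{group}, \code{membrane_id}, \code{iod},
#' \code{is_calibration}.
#' @param path file path.
#' @return data frame suitable for \code{\link{wb_normalize}}.
#' @export
read_wb_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "membrane_id", "iod", "is_calibration")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("WB CSV missing column(s): ",
                         paste(miss, collapse = ", "))
  df$is_calibration <- as.logical(df$is_calibration)
  df
}

#' Read long-format MRM transition measurements from CSV
#'
#' Columns: \code{sample_id}, \code{peptide}, \code{transition_id},
#' \code{label}, \code{area}, and optionally \code{group} and
#' \code{qc_pass}.
#' @param path file path.
#' @return data frame suitable for \code{\link{compute_ratios}}.
#' @export
read_mrm_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "peptide", "transition_id", "label", "area")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("MRM CSV missing column(s): ",
                         paste(miss, collapse = ", "))
  if (!is.null(df$qc_pass)) df$qc_pass <- as.logical(df$qc_pass)
  df
}
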