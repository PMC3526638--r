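# Target-decoy filtering of peptide-spectrum matches (PSMs) and naive
# protein-level FDR estimation. A PSM table holds one row per candidate
# assignment of a peptide to a spectrum with its SEQUEST-style scores
# (Xcorr, deltaCn), charge state and decoy status.

DELTACN_MIN <- 0.1  # required of every accepted PSM regardless of charge

passing_mask <- function(psms, thresholds) {
  obs <- unique(psms$charge)
  missing <- setdiff(as.character(obs), names(thresholds))
  if (length(missing))
    stop("no Xcorr threshold supplied for charge state(s): ",
         paste(missing, collapse = ", "))
  thr <- unname(thresholds[as.character(psms$charge)])
  psms$delta_cn >= DELTACN_MIN & psms$xcorr >= thr
}

#' Estimate PSM-level FDR at given per-charge Xcorr thresholds
#'
#' Applies the joint filter deltaCn >= 0.1 and Xcorr >= threshold[charge] and
#' returns the target-decoy estimate (number of passing decoys) / (number of
#' passing targets). The estimate assumes decoy matches occur at the same
#' rate as incorrect target matches.
#'
#' @param psms data frame of PSM records with columns \code{charge},
#'   \code{xcorr}, \code{delta_cn}, \code{is_decoy}.
#' @param thresholds named numeric vector, one Xcorr cutoff per charge state
#'   (names are charge values as character).
#' @return the estimated FDR; 0 when no target passes.
#' @export
estimate_psm_fdr <- function(psms, thresholds) {
  if (anyNA(psms$xcorr) || anyNA(psms$delta_cn))
    stop("PSMs with missing xcorr or delta_cn")
  pass <- passing_mask(psms, thresholds)
  n_target <- sum(pass & !psms$is_decoy)
  if (n_target == 0) return(0)
  sum(pass & psms$is_decoy) / n_target
}

#' Choose per-charge Xcorr thresholds for a PSM FDR target
#'
#' For each observed charge state, scans the observed Xcorr values of that
#' charge (after the deltaCn >= 0.1 filter) and returns the smallest score
#' at which the charge-specific target-decoy FDR falls below
#' \code{fdr_target}. The search is over observed values only, so it is
#' finite, exact and reproducible; raising \code{fdr_target} can only lower
#' (never raise) the thresholds.
#'
#' @param psms data frame of PSM records.
#' @param fdr_target desired PSM FDR, in (0, 1).
#' @return named numeric vector of thresholds, one per charge state.
#' @export
select_thresholds <- function(psms, fdr_target) {
  stopifnot(fdr_target > 0, fdr_target < 1)
  keep <- psms$delta_cn >= DELTACN_MIN
  if (!any(keep)) stop("no PSMs pass the deltaCn filter")
  psms <- psms[keep, , drop = FALSE]
  charges <- sort(unique(psms$charge))
  thr <- vapply(charges, function(ch) {
    sub <- psms[psms$charge == ch, , drop = FALSE]
    cand <- sort(unique(sub$xcorr))
    # counts of targets/decoys at score >= candidate, by reverse cumulation
    ord <- order(sub$xcorr, decreasing = TRUE)
    x <- sub$xcorr[ord]; dec <- sub$is_decoy[ord]
    n_dec <- cumsum(dec); n_tar <- cumsum(!dec)
    # number of PSMs with score >= each candidate (ties grouped)
    idx <- length(x) - findInterval(cand, sort(x), left.open = TRUE)
    fdr <- ifelse(n_tar[idx] == 0, 0, n_dec[idx] / n_tar[idx])
    ok <- which(fdr < fdr_target)
    if (!length(ok))
      stop("no Xcorr threshold achieves FDR < ", fdr_target,
           " for charge ", ch)
    cand[min(ok)]
  }, numeric(1))
  stats::setNames(thr, as.character(charges))
}

#' Group passing PSMs into parsimonious protein groups
#'
#' Greedy parsimony in the spirit of protein-inference summarizers:
#' accessions are ranked by how many still-unexplained peptides they cover;
#' the best accession claims its remaining peptides as one group, accessions
#' whose full peptide set is identical are co-listed in that group, and
#' accessions whose peptides are all explained by earlier groups are
#' absorbed. Ties are broken by lexicographic accession order, so the result
#' is deterministic. Every passing PSM is assigned to exactly one group.
#'
#' @param psms data frame of threshold-filtered PSM records with columns
#'   \code{peptide}, \code{accessions} (";"-joined when a peptide maps to
#'   several accessions), \code{is_decoy}.
#' @return data frame of protein groups: \code{group_id}, \code{accessions}
#'   (";"-joined), \code{n_peptides}, \code{psm_count}, \code{is_decoy}.
#' @export
group_proteins <- function(psms) {
  if (nrow(psms) == 0)
    return(data.frame(group_id = character(), accessions = character(),
                      n_peptides = integer(), psm_count = integer(),
                      is_decoy = logical(), stringsAsFactors = FALSE))
  acc_list <- strsplit(psms$accessions, ";", fixed = TRUE)
  pep_acc <- unique(data.frame(
    peptide = rep(psms$peptide, lengths(acc_list)),
    accession = unlist(acc_list), stringsAsFactors = FALSE))
  peps_by_acc <- split(pep_acc$peptide, pep_acc$accession)
  peps_by_acc <- lapply(peps_by_acc, unique)
  full_key <- vapply(peps_by_acc, function(p) paste(sort(p), collapse = "\r"),
                     character(1))

  remaining <- unique(pep_acc$peptide)
  claimed_by <- character(0)   # peptide -> group_id
  groups <- list()
  accs <- sort(names(peps_by_acc))
  alive <- stats::setNames(rep(TRUE, length(accs)), accs)
  gid <- 0L
  while (length(remaining) > 0) {
    cover <- vapply(accs, function(a)
      if (alive[a]) sum(peps_by_acc[[a]] %in% remaining) else 0L, integer(1))
    best <- accs[which.max(cover)]  # which.max takes the first = lexicographic
    if (cover[best] == 0L) break
    members <- accs[alive & full_key[accs] == full_key[best]]
    claimed <- intersect(peps_by_acc[[best]], remaining)
    gid <- gid + 1L
    groups[[gid]] <- list(group_id = sprintf("PG%04d", gid),
                          accessions = members, peptides = claimed)
    claimed_by[claimed] <- sprintf("PG%04d", gid)
    remaining <- setdiff(remaining, claimed)
    alive[members] <- FALSE
    # absorb accessions with nothing left to explain
    alive[accs[alive][vapply(accs[alive], function(a)
      !any(peps_by_acc[[a]] %in% remaining), logical(1))]] <- FALSE
  }

  psm_group <- claimed_by[psms$peptide]
  counts <- table(psm_group)
  is_decoy_acc <- function(a) grepl("^REV_|^DECOY_|^rev_", a)
  out <- do.call(rbind, lapply(groups, function(g) {
    data.frame(group_id = g$group_id,
               accessions = paste(g$accessions, collapse = ";"),
               n_peptides = length(g$peptides),
               psm_count = as.integer(counts[g$group_id]),
               is_decoy = all(is_decoy_acc(g$accessions)),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Naive target-decoy protein-level FDR
#'
#' Approximates the expected number of false positive protein
#' identifications by the number of decoy protein groups:
#' FDR = (decoy groups) / (target groups).
#'
#' @param groups data frame from \code{\link{group_proteins}}.
#' @return a list of class \code{fdr_result}: \code{protein_fdr},
#'   \code{n_target_proteins}, \code{n_decoy_proteins}.
#' @export
estimate_protein_fdr <- function(groups) {
  n_dec <- sum(groups$is_decoy)
  n_tar <- sum(!groups$is_decoy)
  if (n_tar == 0) {
    warning("no target protein groups; protein FDR defined as 0")
    fdr <- 0
  } else fdr <- n_dec / n_tar
  structure(list(protein_fdr = fdr, n_target_proteins = n_tar,
                 n_decoy_proteins = n_dec), class = "fdr_result")
}

#' @export
print.fdr_result <- function(x, ...) {
  cat(sprintf("Protein-level target-decoy FDR: %.4f (%d targets, %d decoys)\n",
              x$protein_fdr, x$n_target_proteins, x$n_decoy_proteins))
  invisible(x)
}

#' Run the full PSM-to-protein filtering chain
#'
#' Selects per-charge Xcorr thresholds at the requested PSM FDR, filters,
#' groups proteins parsimoniously and reports the protein-level FDR.
#'
#' @param psms data frame of PSM records.
#' @param psm_fdr_target PSM-level FDR target (default 0.01).
#' @return a list with \code{thresholds}, \code{psm_fdr}, \code{groups}
#'   (targets and decoys), and \code{protein_fdr} (an \code{fdr_result}).
#' @export
filter_psms <- function(psms, psm_fdr_target = 0.01) {
  thresholds <- select_thresholds(psms, psm_fdr_target)
  pass <- passing_mask(psms, thresholds)
  psm_fdr <- estimate_psm_fdr(psms, thresholds)
  groups <- group_proteins(psms[pass, , drop = FALSE])
  list(thresholds = thresholds, psm_fdr = psm_fdr, groups = groups,
       protein_fdr = estimate_protein_fdr(groups))
}
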