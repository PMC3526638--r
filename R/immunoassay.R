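# Verification-phase scoring of immunoassays: tissue-microarray (TMA) quick
# scores Q = P x I from pathologist readings, and western-blot densitometry
# normalized against a pooled calibration sample run on every membrane.

#' Bin a positive-cell percentage into a P score (0-9)
#'
#' Ten bins: [0, 5) -> 0, [5, 15) -> 1, [15, 25) -> 2, ..., [75, 85) -> 8
#' and [85, 100] -> 9. The interior bins are one decade (10 percentage
#' points) wide; the bottom bin covers 0-5% and the top bin 85-100%.
#'
#' @param percent numeric vector of percentages in [0, 100].
#' @return integer P scores in 0..9.
#' @export
percent_to_pscore <- function(percent) {
  if (any(percent < 0 | percent > 100))
    stop("percent must lie in [0, 100]")
  findInterval(percent, seq(5, 85, by = 10))
}

#' Quick scores Q = P x I for TMA sections
#'
#' Collapses per-rater readings of a section into the quick score: under
#' \code{combine = "average_raw"} (default) the raw percentages and raw
#' intensities are averaged across raters first, the averaged percentage is
#' binned into P and multiplied by the averaged intensity I; under
#' \code{"average_q"} each rater's own Q = P x I is computed and the Qs are
#' averaged. Q ranges from 0 (no staining) to 27 (homogeneous, strong
#' staining). Averaged intensities need not be integer, so Q may be
#' fractional; the 0-27 bound still holds.
#'
#' @param sections data frame with columns \code{case_id}, \code{tissue},
#'   \code{rater}, \code{percent} (0-100), \code{intensity} (0-3).
#' @param combine rater-combination rule, "average_raw" or "average_q".
#' @return data frame with one row per (case_id, tissue): averaged
#'   \code{percent} and \code{intensity}, \code{p_score}, \code{q_score}.
#' @export
quick_score <- function(sections, combine = c("average_raw", "average_q")) {
  combine <- match.arg(combine)
  need <- c("case_id", "tissue", "rater", "percent", "intensity")
  if (!all(need %in% names(sections)))
    stop("sections must have columns: ", paste(need, collapse = ", "))
  if (nrow(sections) == 0) stop("no rater readings supplied")
  if (any(!sections$intensity %in% 0:3))
    stop("intensity must lie in {0, 1, 2, 3}")
  key <- interaction(sections$case_id, sections$tissue, drop = TRUE)
  agg <- function(v) tapply(v, key, mean)
  pct <- agg(sections$percent)
  ity <- agg(sections$intensity)
  p <- stats::setNames(percent_to_pscore(pct), names(pct))
  if (combine == "average_raw") {
    q <- stats::setNames(p * ity, names(pct))
  } else {
    q_rater <- percent_to_pscore(sections$percent) * sections$intensity
    q <- tapply(q_rater, key, mean)
  }
  first <- !duplicated(key)
  k <- as.character(key[first])
  out <- data.frame(case_id = sections$case_id[first],
                    tissue = sections$tissue[first],
                    percent = as.numeric(pct[k]),
                    intensity = as.numeric(ity[k]),
                    p_score = as.integer(p[k]),
                    q_score = as.numeric(q[k]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Paired tumor vs. adjacent-normal comparison of quick scores
#'
#' Pairs each case's tumor and adjacent-normal Q scores, drops incomplete
#' pairs (e.g. a section lost during processing) and tests the paired
#' differences with a Wilcoxon signed-rank test (default) or a paired t
#' test. When every difference is zero the p-value is defined as 1.
#'
#' @param scores data frame from \code{\link{quick_score}} containing both
#'   tissues.
#' @param test "wilcoxon" or "t".
#' @param alternative "two.sided" (default), "greater" (tumor > normal) or
#'   "less".
#' @return list with \code{n_pairs}, \code{median_difference},
#'   \code{statistic}, \code{p_value}, \code{direction}.
#' @export
paired_compare <- function(scores, test = c("wilcoxon", "t"),
                           alternative = "two.sided") {
  test <- match.arg(test)
  tum <- scores[scores$tissue == "tumor", c("case_id", "q_score")]
  nor <- scores[scores$tissue == "adjacent_normal", c("case_id", "q_score")]
  m <- merge(tum, nor, by = "case_id", suffixes = c("_tumor", "_normal"))
  m <- m[stats::complete.cases(m), , drop = FALSE]
  if (nrow(m) < 5) stop("need at least 5 complete tumor/normal pairs")
  d <- m$q_score_tumor - m$q_score_normal
  if (all(d == 0)) {
    return(list(n_pairs = nrow(m), median_difference = 0,
                statistic = NA_real_, p_value = 1, direction = "none"))
  }
  ht <- if (test == "wilcoxon") {
    suppressWarnings(stats::wilcox.test(d, alternative = alternative,
                                        exact = FALSE, correct = TRUE))
  } else {
    stats::t.test(d, alternative = alternative)
  }
  list(n_pairs = nrow(m), median_difference = stats::median(d),
       statistic = unname(ht$statistic), p_value = ht$p.value,
       direction = if (stats::median(d) > 0) "tumor_higher"
                   else if (stats::median(d) < 0) "normal_higher" else "none")
}

#' Normalize western-blot densitometry against a pooled calibration sample
#'
#' Every membrane (WB run) carries one lane of the same pooled calibration
#' sample; dividing each sample's integrated optical density (IOD) by the
#' calibration IOD of its own membrane cancels multiplicative between-run
#' factors and makes values comparable across membranes. A two-sample t
#' test then compares the normalized values between groups.
#'
#' @param measurements data frame with columns \code{sample_id},
#'   \code{group}, \code{membrane_id}, \code{iod}, \code{is_calibration}
#'   (logical; exactly one TRUE row per membrane).
#' @param group1,group2 character vectors of group labels forming the two
#'   sides of the comparison; by default the two observed labels (error if
#'   more than two and none specified).
#' @return list with \code{normalized} (the measurement rows plus a
#'   \code{normalized} column, calibration rows excluded) and \code{test}
#'   (t statistic, p-value and group means), or test = NULL when a single
#'   group is present.
#' @export
wb_normalize <- function(measurements, group1 = NULL, group2 = NULL) {
  need <- c("sample_id", "group", "membrane_id", "iod", "is_calibration")
  if (!all(need %in% names(measurements)))
    stop("measurements must have columns: ", paste(need, collapse = ", "))
  if (any(measurements$iod <= 0)) stop("IOD values must be positive")
  cal <- measurements[measurements$is_calibration, , drop = FALSE]
  membranes <- unique(measurements$membrane_id)
  n_cal <- table(factor(cal$membrane_id, levels = membranes))
  if (any(n_cal != 1))
    stop("every membrane needs exactly one calibration measurement; bad: ",
         paste(names(n_cal)[n_cal != 1], collapse = ", "))
  cal_iod <- stats::setNames(cal$iod, cal$membrane_id)
  out <- measurements[!measurements$is_calibration, , drop = FALSE]
  out$normalized <- out$iod / unname(cal_iod[out$membrane_id])

  labels <- unique(out$group)
  if (is.null(group1) && is.null(group2)) {
    if (length(labels) == 2) { group1 <- labels[1]; group2 <- labels[2] }
    else if (length(labels) > 2)
      stop("more than two groups present; specify group1/group2")
  }
  test <- NULL
  if (!is.null(group1) && !is.null(group2)) {
    v1 <- out$normalized[out$group %in% group1]
    v2 <- out$normalized[out$group %in% group2]
    ht <- stats::t.test(v1, v2)
    test <- list(group1 = group1, group2 = group2,
                 mean1 = mean(v1), mean2 = mean(v2),
                 statistic = unname(ht$statistic), p_value = ht$p.value)
  }
  list(normalized = out, test = test)
}
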