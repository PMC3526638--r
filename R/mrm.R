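# Targeted verification by stable-isotope-dilution multiple reaction
# monitoring (SID-MRM): light/heavy transition ratios, base-3 dilution
# calibration curves, LOQ/LOD rules, transition selection and conversion of
# area ratios to absolute serum concentrations.

log3 <- function(x) log(x, base = 3)

#' Light/heavy area ratios per (sample, peptide, transition)
#'
#' Pairs the light (endogenous, 12C) and heavy (spiked, 13C) peak areas of
#' each transition and returns their ratio. Rows failing an upstream QC flag
#' (\code{qc_pass == FALSE}) are excluded before pairing. A light area of 0
#' yields ratio 0 with \code{below_lod = TRUE}.
#'
#' @param measurements long data frame with columns \code{sample_id},
#'   \code{peptide}, \code{transition_id}, \code{label} ("light"/"heavy"),
#'   \code{area}, and optionally \code{qc_pass}.
#' @return data frame \code{sample_id}, \code{peptide},
#'   \code{transition_id}, \code{light_area}, \code{heavy_area},
#'   \code{ratio}, \code{below_lod}.
#' @export
compute_ratios <- function(measurements) {
  need <- c("sample_id", "peptide", "transition_id", "label", "area")
  if (!all(need %in% names(measurements)))
    stop("measurements must have columns: ", paste(need, collapse = ", "))
  if (!is.null(measurements$qc_pass))
    measurements <- measurements[measurements$qc_pass, , drop = FALSE]
  if (!all(measurements$label %in% c("light", "heavy")))
    stop("label must be 'light' or 'heavy'")
  if (any(measurements$area < 0)) stop("areas must be non-negative")
  wide <- stats::reshape(
    measurements[, c(need)], direction = "wide",
    idvar = c("sample_id", "peptide", "transition_id"),
    timevar = "label", v.names = "area")
  if (anyNA(wide$area.heavy))
    stop("missing heavy partner for some (sample, peptide, transition)")
  if (anyNA(wide$area.light))
    stop("missing light partner for some (sample, peptide, transition)")
  if (any(wide$area.heavy == 0)) stop("zero heavy area")
  out <- data.frame(sample_id = wide$sample_id, peptide = wide$peptide,
                    transition_id = wide$transition_id,
                    light_area = wide$area.light,
                    heavy_area = wide$area.heavy,
                    ratio = wide$area.light / wide$area.heavy,
                    stringsAsFactors = FALSE)
  out$below_lod <- out$light_area == 0
  rownames(out) <- NULL
  out
}

#' Fit a base-3 dilution calibration curve
#'
#' Ordinary least squares of log3(observed light/heavy area ratio) on
#' log3(nominal light/heavy amount ratio), fitted on the per-point replicate
#' means — the space in which SID-MRM response curves are drawn. Also
#' reports the per-point replicate CV of the ratio, the Pearson correlation
#' of the fitted points and the anchor point whose observed mean ratio is
#' closest to 1 (the point at which the endogenous amount is read off during
#' assay characterization).
#'
#' @param series data frame with columns \code{point_index},
#'   \code{replicate_id}, \code{nominal_light_fmol},
#'   \code{spike_heavy_fmol}, \code{light_area}, \code{heavy_area}.
#' @param peptide,transition_id optional identifiers carried through.
#' @param space "log3" (default) fits in log3-log3 space; "linear" fits
#'   observed ratio on nominal ratio directly.
#' @return a list of class \code{calibration_curve}: \code{points} (one row
#'   per dilution point: nominal amount and ratio, mean observed ratio,
#'   replicate CV), \code{slope}, \code{intercept}, \code{pearson_r},
#'   \code{anchor_index}, \code{anchor_ratio}, \code{space},
#'   \code{spike_fmol}. LOQ/LOD slots are filled by
#'   \code{\link{determine_loq}} / \code{\link{determine_lod}}.
#' @export
fit_calibration <- function(series, peptide = NA_character_,
                            transition_id = NA_character_,
                            space = c("log3", "linear")) {
  space <- match.arg(space)
  need <- c("point_index", "replicate_id", "nominal_light_fmol",
            "spike_heavy_fmol", "light_area", "heavy_area")
  if (!all(need %in% names(series)))
    stop("series must have columns: ", paste(need, collapse = ", "))
  series$ratio <- series$light_area / series$heavy_area
  pts <- split(series, series$point_index)
  if (length(pts) < 3) stop("need at least 3 dilution points")
  points <- do.call(rbind, lapply(pts, function(d) {
    data.frame(point_index = d$point_index[1],
               nominal_light_fmol = d$nominal_light_fmol[1],
               nominal_ratio = d$nominal_light_fmol[1] / d$spike_heavy_fmol[1],
               mean_ratio = mean(d$ratio),
               replicate_cv = if (nrow(d) > 1)
                 stats::sd(d$ratio) / mean(d$ratio) else NA_real_,
               n_replicates = nrow(d))
  }))
  points <- points[order(points$nominal_light_fmol), , drop = FALSE]
  rownames(points) <- NULL
  if (space == "log3") {
    x <- log3(points$nominal_ratio); y <- log3(points$mean_ratio)
  } else {
    x <- points$nominal_ratio; y <- points$mean_ratio
  }
  fit <- stats::lm(y ~ x)
  anchor <- which.min(abs(points$mean_ratio - 1))
  structure(list(peptide = peptide, transition_id = transition_id,
                 points = points,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 pearson_r = stats::cor(x, y),
                 anchor_index = anchor,
                 anchor_ratio = points$mean_ratio[anchor],
                 space = space,
                 spike_fmol = series$spike_heavy_fmol[1],
                 loq_fmol = NA_real_, lod_fmol = NA_real_),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(
    "Calibration (%s space): slope %.4f, intercept %.4f, R %.5f, %d points\n",
    x$space, x$slope, x$intercept, x$pearson_r, nrow(x$points)))
  if (!is.na(x$loq_fmol)) cat(sprintf("  LOQ %.3g fmol\n", x$loq_fmol))
  if (!is.na(x$lod_fmol)) cat(sprintf("  LOD %.3g fmol\n", x$lod_fmol))
  invisible(x)
}

pearson_from_point <- function(curve, i) {
  pts <- curve$points[i:nrow(curve$points), , drop = FALSE]
  if (nrow(pts) < 2) return(NA_real_)
  if (nrow(pts) == 2) return(1)  # two points define a line exactly
  if (curve$space == "log3")
    stats::cor(log3(pts$nominal_ratio), log3(pts$mean_ratio))
  else stats::cor(pts$nominal_ratio, pts$mean_ratio)
}

#' Limit of quantification from a calibration curve
#'
#' Scans the dilution points from the most dilute upward and returns the
#' lowest concentration that (a) was measured with a replicate CV below
#' \code{cv_max} and (b) keeps acceptable linearity, i.e. the Pearson
#' correlation of the curve restricted to that point and above exceeds
#' \code{r_min}. Returns NA (with a warning) when no point qualifies.
#'
#' @param curve a \code{\link{fit_calibration}} result.
#' @param cv_max maximum acceptable replicate CV (fraction, default 0.20).
#' @param r_min minimum Pearson correlation (default 0.99).
#' @return the LOQ in fmol (NA when not quantifiable); assign it to the
#'   curve's \code{loq_fmol} slot to enable the LOQ tie-break in
#'   \code{\link{select_best_transition}}.
#' @export
determine_loq <- function(curve, cv_max = 0.20, r_min = 0.99) {
  stopifnot(inherits(curve, "calibration_curve"))
  pts <- curve$points
  if (anyNA(pts$replicate_cv))
    stop("replicate CV unavailable for some dilution points")
  for (i in seq_len(nrow(pts))) {
    r <- pearson_from_point(curve, i)
    if (!is.na(r) && pts$replicate_cv[i] < cv_max && r > r_min)
      return(pts$nominal_light_fmol[i])
  }
  warning("no dilution point satisfies the LOQ rules; not quantifiable")
  NA_real_
}

#' Limit of detection at signal-to-noise 3
#'
#' Interpolates the concentration at which the analyte's signal-to-noise
#' ratio equals 3, working in log-log space where a proportional response is
#' linear. With a single (concentration, S/N) pair, strict proportionality
#' is assumed; below the measured range the two lowest points are
#' extrapolated.
#'
#' @param conc_fmol concentrations (fmol), sorted or not.
#' @param snr signal-to-noise ratio at each concentration (> 0, monotone
#'   non-decreasing in concentration).
#' @param target_snr the defining signal-to-noise ratio (default 3).
#' @return the LOD in fmol.
#' @export
determine_lod <- function(conc_fmol, snr, target_snr = 3) {
  stopifnot(length(conc_fmol) == length(snr), length(snr) >= 1,
            all(conc_fmol > 0), all(snr > 0))
  o <- order(conc_fmol)
  conc_fmol <- conc_fmol[o]; snr <- snr[o]
  if (max(snr) < target_snr)
    stop("signal-to-noise never reaches ", target_snr)
  if (length(snr) == 1)  # proportionality through the origin
    return(conc_fmol * target_snr / snr)
  lx <- log(conc_fmol); ly <- log(snr)
  lt <- log(target_snr)
  if (snr[1] >= target_snr) {  # extrapolate below range from two lowest points
    slope <- (ly[2] - ly[1]) / (lx[2] - lx[1])
    return(exp(lx[1] + (lt - ly[1]) / slope))
  }
  i <- max(which(snr < target_snr))
  slope <- (ly[i + 1] - ly[i]) / (lx[i + 1] - lx[i])
  exp(lx[i] + (lt - ly[i]) / slope)
}

#' Inter-assay coefficient of variation
#'
#' 100 x sample standard deviation / mean over replicate measurements of
#' the same sample, the standard reproducibility metric for repeated
#' processing + MRM runs.
#'
#' @param replicates numeric vector (>= 2 values, non-zero mean).
#' @return the CV as a percentage.
#' @export
interassay_cv <- function(replicates) {
  stopifnot(length(replicates) >= 2)
  m <- mean(replicates)
  if (m == 0) stop("mean of replicates is zero; CV undefined")
  100 * stats::sd(replicates) / m
}

#' Select the best transition for absolute quantification
#'
#' Among calibration curves of the same peptide, picks the transition with
#' the best linearity (highest Pearson R); ties are broken by lower LOQ,
#' then by higher mean heavy area (stronger signal).
#'
#' @param curves list of \code{calibration_curve} objects; for the LOQ
#'   tie-break their \code{loq_fmol} slots should be set.
#' @param heavy_means optional numeric vector of mean heavy areas, one per
#'   curve, for the final tie-break.
#' @return the \code{transition_id} of the selected curve.
#' @export
select_best_transition <- function(curves, heavy_means = NULL) {
  stopifnot(length(curves) >= 1)
  r <- vapply(curves, function(cv) cv$pearson_r, numeric(1))
  loq <- vapply(curves, function(cv)
    if (is.null(cv$loq_fmol) || is.na(cv$loq_fmol)) Inf else cv$loq_fmol,
    numeric(1))
  hm <- if (is.null(heavy_means)) rep(0, length(curves)) else heavy_means
  best <- order(-r, loq, -hm)[1]
  curves[[best]]$transition_id
}

#' Absolute concentration from an observed area ratio
#'
#' Inverts the fitted calibration line to convert an observed light/heavy
#' area ratio into a nominal amount ratio, multiplies by the heavy spike to
#' get fmol on column, and converts to a serum concentration using the
#' serum-equivalent volume loaded on column and the protein molar mass:
#' ug/mL = fmol x (molar mass in g/mol) / (volume in uL) x 1e-6.
#'
#' @param ratio observed light/heavy area ratio (> 0).
#' @param curve a \code{\link{fit_calibration}} result.
#' @param spike_fmol heavy spike on column (fmol); defaults to the curve's.
#' @param serum_volume_ul serum-equivalent volume on column (default 0.1).
#' @param molar_mass_da protein molar mass (g/mol).
#' @return data frame with \code{ratio}, \code{fmol_on_column},
#'   \code{serum_conc_ug_per_ml}, \code{extrapolated} (TRUE when the ratio
#'   falls outside the calibrated range).
#' @export
absolute_concentration <- function(ratio, curve, spike_fmol = NULL,
                                   serum_volume_ul = 0.1,
                                   molar_mass_da = NULL) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (any(ratio <= 0)) stop("ratio must be positive")
  if (is.null(spike_fmol)) spike_fmol <- curve$spike_fmol
  if (curve$space == "log3") {
    nominal_ratio <- 3^((log3(ratio) - curve$intercept) / curve$slope)
  } else {
    nominal_ratio <- (ratio - curve$intercept) / curve$slope
  }
  fmol <- nominal_ratio * spike_fmol
  rng <- range(curve$points$mean_ratio)
  out <- data.frame(ratio = ratio,
                    fmol_on_column = fmol,
                    extrapolated = ratio < rng[1] | ratio > rng[2])
  if (!is.null(molar_mass_da))
    out$serum_conc_ug_per_ml <- fmol * molar_mass_da / serum_volume_ul * 1e-6
  out
}

#' Molar masses (Da) of the verified serum glycoproteins
#'
#' Sequence molar masses of alpha-1B-glycoprotein (A1BG) and leucine-rich
#' alpha-2-glycoprotein (LRG1), used as defaults when converting on-column
#' amounts to serum concentrations.
#' @export
protein_molar_masses <- c(A1BG = 54254, LRG1 = 38178)

#' Cohort statistics for MRM concentrations
#'
#' Compares per-sample concentrations between a cancer and a control cohort
#' (two-sample t test and ROC per protein), fits the combined
#' logistic-regression panel over all proteins, and screens demographic
#' variables: binary demographics by two-sample t test on concentration,
#' continuous ones (age) by Pearson correlation.
#'
#' @param records data frame with columns \code{sample_id}, \code{protein},
#'   \code{group}, \code{concentration}; one row per sample x protein.
#' @param case_group label of the positive (cancer) cohort; default the
#'   first group encountered.
#' @param demographics optional data frame keyed by \code{sample_id} with
#'   additional binary or numeric columns.
#' @return list with \code{per_protein} (t statistic, p, AUC and CI per
#'   protein), \code{panel} (a \code{panel_model} over all proteins) and
#'   \code{demographic_tests} (data frame protein x variable with p-values
#'   or correlations).
#' @export
cohort_stats <- function(records, case_group = NULL, demographics = NULL) {
  need <- c("sample_id", "protein", "group", "concentration")
  if (!all(need %in% names(records)))
    stop("records must have columns: ", paste(need, collapse = ", "))
  groups <- unique(records$group)
  if (length(groups) != 2) stop("exactly two cohorts required")
  if (is.null(case_group)) case_group <- groups[1]
  proteins <- unique(records$protein)

  wide <- stats::reshape(records[, need], direction = "wide",
                         idvar = c("sample_id", "group"), timevar = "protein",
                         v.names = "concentration")
  conc_cols <- paste0("concentration.", proteins)
  y <- as.integer(wide$group == case_group)

  per_protein <- do.call(rbind, lapply(proteins, function(pr) {
    v <- wide[[paste0("concentration.", pr)]]
    ht <- stats::t.test(v[y == 1], v[y == 0])
    rc <- roc_auc(v, y)
    data.frame(protein = pr, mean_case = mean(v[y == 1]),
               mean_control = mean(v[y == 0]),
               t_statistic = unname(ht$statistic), p_value = ht$p.value,
               auc = rc$auc, auc_ci_low = rc$ci_low,
               auc_ci_high = rc$ci_high, stringsAsFactors = FALSE)
  }))

  feats <- wide[, conc_cols, drop = FALSE]
  names(feats) <- proteins
  panel <- logistic_panel(feats, y)

  demo <- NULL
  if (!is.null(demographics)) {
    dd <- merge(wide[, c("sample_id", conc_cols)], demographics,
                by = "sample_id")
    vars <- setdiff(names(demographics), "sample_id")
    demo <- do.call(rbind, lapply(proteins, function(pr) {
      v <- dd[[paste0("concentration.", pr)]]
      do.call(rbind, lapply(vars, function(vn) {
        z <- dd[[vn]]
        if (is.numeric(z) && length(unique(z)) > 2) {
          ct <- stats::cor.test(v, z)
          data.frame(protein = pr, variable = vn, type = "pearson",
                     estimate = unname(ct$estimate), p_value = ct$p.value,
                     stringsAsFactors = FALSE)
        } else {
          lv <- unique(z)
          if (length(lv) != 2)
            stop("demographic '", vn, "' is neither binary nor numeric")
          ht <- stats::t.test(v[z == lv[1]], v[z == lv[2]])
          data.frame(protein = pr, variable = vn, type = "ttest",
                     estimate = unname(ht$statistic), p_value = ht$p.value,
                     stringsAsFactors = FALSE)
        }
      }))
    }))
    rownames(demo) <- NULL
  }
  list(per_protein = per_protein, panel = panel, demographic_tests = demo)
}
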