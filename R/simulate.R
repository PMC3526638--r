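# Synthetic cohorts with known ground truth for every stage of the pipeline:
# spectral-count matrices, target/decoy PSM tables, stable-isotope-dilution
# MRM dilution series + cohorts, and paired tissue-microarray scores.
# All generators take an explicit seed; none touches the global RNG state
# beyond a local set.seed().

#' Configuration for the spectral-count matrix generator
#'
#' Describes a discovery cohort of serum samples profiled by spectral
#' counting. Protein base abundances are drawn log-uniformly over
#' \code{abundance_range_orders} decades, mimicking the wide dynamic range of
#' the serum proteome; counts are negative binomial (Poisson-gamma), which
#' accommodates the overdispersion typical of spectral counts.
#'
#' @param n_proteins number of proteins in the matrix.
#' @param n_per_group named integer vector of samples per cohort; names are
#'   the cohort labels. Default \code{c(N = 5, AD = 8, SCC = 5)}, i.e. 13
#'   cancer sera (8 adenocarcinoma + 5 squamous) against 5 healthy controls.
#' @param abundance_range_orders decades of protein dynamic range (default 6).
#' @param frac_differential fraction of proteins with a planted group shift.
#' @param log2_fold log2 fold change applied to differential proteins in the
#'   non-reference (cancer) cohorts. \code{0} plants no effective shift.
#' @param depth_per_sample expected total spectral counts per sample.
#' @param depth_cv coefficient of variation of per-sample sequencing depth.
#' @param dispersion negative-binomial dispersion (variance = mu + dispersion
#'   * mu^2); must be positive.
#' @param reference_group cohort label treated as the unshifted baseline.
#' @param seed integer seed.
#' @return an object of class \code{count_sim_config}.
#' @export
count_sim_config <- function(n_proteins = 600,
                             n_per_group = c(N = 5, AD = 8, SCC = 5),
                             abundance_range_orders = 6,
                             frac_differential = 0.15,
                             log2_fold = 1.5,
                             depth_per_sample = 35000,
                             depth_cv = 0.1,
                             dispersion = 0.15,
                             reference_group = "N",
                             seed = 1L) {
  stopifnot(n_proteins >= 1, all(n_per_group >= 1), length(n_per_group) >= 2,
            !is.null(names(n_per_group)), abundance_range_orders > 0,
            frac_differential >= 0, frac_differential <= 1,
            log2_fold >= 0, depth_per_sample > 0, depth_cv >= 0)
  if (dispersion <= 0) stop("dispersion must be > 0")
  if (!reference_group %in% names(n_per_group))
    stop("reference_group must be one of the cohort labels")
  structure(list(n_proteins = as.integer(n_proteins),
                 n_per_group = n_per_group,
                 abundance_range_orders = abundance_range_orders,
                 frac_differential = frac_differential,
                 log2_fold = log2_fold,
                 depth_per_sample = depth_per_sample,
                 depth_cv = depth_cv,
                 dispersion = dispersion,
                 reference_group = reference_group,
                 seed = as.integer(seed)),
            class = "count_sim_config")
}

#' Simulate a protein-by-sample spectral-count matrix with ground truth
#'
#' Draws protein base abundances log-uniformly over the configured dynamic
#' range, applies the planted fold change to a fixed subset of proteins in
#' every non-reference cohort, scales by a lognormal per-sample depth factor,
#' and samples counts from a negative binomial.
#'
#' @param cfg a \code{\link{count_sim_config}}.
#' @return a list with elements
#'   \item{counts}{integer matrix, proteins x samples;}
#'   \item{group}{named character vector mapping sample to cohort;}
#'   \item{truth}{data frame with \code{protein_id},
#'     \code{truth_differential} and \code{truth_log2_fold}.}
#' @export
generate_count_matrix <- function(cfg) {
  stopifnot(inherits(cfg, "count_sim_config"))
  set.seed(cfg$seed)
  p <- cfg$n_proteins
  groups <- rep(names(cfg$n_per_group), cfg$n_per_group)
  n <- length(groups)
  sample_ids <- paste0(groups, "_", unlist(lapply(cfg$n_per_group, seq_len)))

  base <- 10^stats::runif(p, 0, cfg$abundance_range_orders)
  n_diff <- round(cfg$frac_differential * p)
  diff_idx <- seq_len(n_diff)
  # half up-, half down-regulated in cancer, as in real differential panels
  sign_fold <- rep(c(1, -1), length.out = n_diff)
  lfc <- numeric(p)
  lfc[diff_idx] <- cfg$log2_fold * sign_fold

  depth_factor <- stats::rlnorm(n, -0.5 * log(1 + cfg$depth_cv^2),
                                sqrt(log(1 + cfg$depth_cv^2)))
  rel <- base / sum(base)
  mu <- outer(rel * cfg$depth_per_sample, depth_factor)
  shifted <- groups != cfg$reference_group
  if (any(shifted) && n_diff > 0)
    mu[diff_idx, shifted] <- mu[diff_idx, shifted] * 2^lfc[diff_idx]

  counts <- matrix(stats::rnbinom(p * n, mu = mu, size = 1 / cfg$dispersion),
                   nrow = p, ncol = n)
  protein_ids <- sprintf("PROT%04d", seq_len(p))
  dimnames(counts) <- list(protein_ids, sample_ids)
  group <- stats::setNames(groups, sample_ids)
  truth <- data.frame(protein_id = protein_ids,
                      truth_differential = seq_len(p) %in% diff_idx &
                        cfg$log2_fold > 0,
                      truth_log2_fold = ifelse(cfg$log2_fold > 0, lfc, 0),
                      stringsAsFactors = FALSE)
  list(counts = counts, group = group, truth = truth)
}

#' Configuration for the target/decoy PSM table generator
#'
#' Emulates the score landscape of a SEQUEST-style search against a composite
#' forward + reversed database. Target PSMs are a mixture of a correct
#' (high-scoring) and an incorrect population; decoy scores are drawn from
#' the same distribution as incorrect targets, which is the equal-chance
#' assumption underlying target-decoy FDR estimation.
#'
#' @param n_targets,n_decoys numbers of target and decoy PSMs.
#' @param frac_correct fraction of target PSMs that are correct matches.
#' @param xcorr_correct,xcorr_incorrect named lists with per-charge
#'   \code{mean} and \code{sd} (charges "2" and "3") for the Xcorr score.
#' @param deltacn_correct,deltacn_incorrect \code{c(mean, sd)} for deltaCn of
#'   each population; values are clamped to [0, 1].
#' @param n_true_proteins size of the pool of real proteins that correct PSMs
#'   map to; the default 647 matches the scale of a deep serum proteome.
#' @param peptides_per_protein peptides per real protein (default 7,
#'   roughly the unique-peptides-per-protein ratio of such a proteome).
#' @param decoy_prefix accession prefix marking reversed-database entries.
#' @param seed integer seed.
#' @return an object of class \code{psm_sim_config}.
#' @export
psm_sim_config <- function(n_targets = 10000,
                           n_decoys = 4000,
                           frac_correct = 0.6,
                           xcorr_correct = list(`2` = c(mean = 4.5, sd = 0.8),
                                                `3` = c(mean = 5.3, sd = 0.9)),
                           xcorr_incorrect = list(`2` = c(mean = 1.7, sd = 0.5),
                                                  `3` = c(mean = 2.2, sd = 0.6)),
                           deltacn_correct = c(mean = 0.35, sd = 0.10),
                           deltacn_incorrect = c(mean = 0.08, sd = 0.06),
                           n_true_proteins = 647,
                           peptides_per_protein = 7,
                           decoy_prefix = "REV_",
                           seed = 1L) {
  if (frac_correct < 0 || frac_correct > 1)
    stop("frac_correct must lie in [0, 1]")
  stopifnot(n_targets >= 1, n_decoys >= 0, n_true_proteins >= 1,
            peptides_per_protein >= 1)
  structure(list(n_targets = as.integer(n_targets),
                 n_decoys = as.integer(n_decoys),
                 frac_correct = frac_correct,
                 xcorr_correct = xcorr_correct,
                 xcorr_incorrect = xcorr_incorrect,
                 deltacn_correct = deltacn_correct,
                 deltacn_incorrect = deltacn_incorrect,
                 n_true_proteins = as.integer(n_true_proteins),
                 peptides_per_protein = as.integer(peptides_per_protein),
                 decoy_prefix = decoy_prefix,
                 seed = as.integer(seed)),
            class = "psm_sim_config")
}

draw_scores <- function(n, charge, params_by_charge) {
  m <- vapply(as.character(charge), function(ch) params_by_charge[[ch]]["mean"],
              numeric(1))
  s <- vapply(as.character(charge), function(ch) params_by_charge[[ch]]["sd"],
              numeric(1))
  pmax(stats::rnorm(n, m, s), 0)
}

#' Simulate a PSM table with hidden correctness labels
#'
#' Correct target PSMs map to peptides of a fixed pool of real proteins;
#' incorrect targets and decoys are random single-peptide matches spread over
#' wide accession spaces, so false protein identifications are mostly
#' singletons, as in real searches.
#'
#' @param cfg a \code{\link{psm_sim_config}}.
#' @return a data frame of PSM records (\code{spectrum_id}, \code{peptide},
#'   \code{accessions}, \code{charge}, \code{xcorr}, \code{delta_cn},
#'   \code{is_decoy}) plus the hidden column \code{truth_correct}.
#' @export
generate_psm_table <- function(cfg) {
  stopifnot(inherits(cfg, "psm_sim_config"))
  set.seed(cfg$seed)
  nt <- cfg$n_targets; nd <- cfg$n_decoys
  n_correct <- round(cfg$frac_correct * nt)
  correct <- c(rep(TRUE, n_correct), rep(FALSE, nt - n_correct))

  charge_t <- sample(c(2L, 3L), nt, replace = TRUE)
  charge_d <- if (nd > 0) sample(c(2L, 3L), nd, replace = TRUE) else integer(0)

  xcorr_t <- numeric(nt)
  xcorr_t[correct] <- draw_scores(n_correct, charge_t[correct], cfg$xcorr_correct)
  xcorr_t[!correct] <- draw_scores(nt - n_correct, charge_t[!correct],
                                   cfg$xcorr_incorrect)
  xcorr_d <- draw_scores(nd, charge_d, cfg$xcorr_incorrect)

  clamp01 <- function(x) pmin(pmax(x, 0), 1)
  dcn_t <- numeric(nt)
  dcn_t[correct] <- clamp01(stats::rnorm(n_correct, cfg$deltacn_correct["mean"],
                                         cfg$deltacn_correct["sd"]))
  dcn_t[!correct] <- clamp01(stats::rnorm(nt - n_correct,
                                          cfg$deltacn_incorrect["mean"],
                                          cfg$deltacn_incorrect["sd"]))
  dcn_d <- clamp01(stats::rnorm(nd, cfg$deltacn_incorrect["mean"],
                                cfg$deltacn_incorrect["sd"]))

  # correct targets: peptides belonging to real proteins
  prot_idx <- sample.int(cfg$n_true_proteins, n_correct, replace = TRUE)
  pep_idx <- sample.int(cfg$peptides_per_protein, n_correct, replace = TRUE)
  pep_correct <- sprintf("PEP%04d_%02d", prot_idx, pep_idx)
  acc_correct <- sprintf("SP%04d", prot_idx)

  # incorrect matches: random peptide/accession pairs over a wide space,
  # identical mechanism for incorrect targets and decoys
  n_wrong <- nt - n_correct
  acc_space <- max(cfg$n_true_proteins * 10, 1000)
  pep_wrong <- sprintf("XPEP%06d", sample.int(10 * acc_space, n_wrong + nd,
                                              replace = TRUE))
  acc_wrong_t <- sprintf("SP%04d", cfg$n_true_proteins +
                           sample.int(acc_space, n_wrong, replace = TRUE))
  acc_wrong_d <- if (nd > 0)
    paste0(cfg$decoy_prefix,
           sprintf("SP%04d", sample.int(acc_space + cfg$n_true_proteins,
                                        nd, replace = TRUE)))
  else character(0)

  peptide <- character(nt); accession <- character(nt)
  peptide[correct] <- pep_correct
  accession[correct] <- acc_correct
  peptide[!correct] <- pep_wrong[seq_len(n_wrong)]
  accession[!correct] <- acc_wrong_t

  df <- data.frame(
    spectrum_id = sprintf("scan%06d", seq_len(nt + nd)),
    peptide = c(peptide, pep_wrong[n_wrong + seq_len(nd)]),
    accessions = c(accession, acc_wrong_d),
    charge = c(charge_t, charge_d),
    xcorr = c(xcorr_t, xcorr_d),
    delta_cn = c(dcn_t, dcn_d),
    is_decoy = c(rep(FALSE, nt), rep(TRUE, nd)),
    truth_correct = c(correct, rep(FALSE, nd)),
    stringsAsFactors = FALSE)
  df[sample.int(nrow(df)), , drop = FALSE]
}

#' Configuration for the stable-isotope-dilution MRM generator
#'
#' Emulates a targeted assay in which a heavy-labeled reference peptide is
#' spiked at a constant amount while the light (endogenous-surrogate) peptide
#' is diluted along an exact base-3 geometric series. Measurement noise is
#' multiplicative lognormal, independent between the light and heavy
#' channels. Dilution points below a configurable knee receive strongly
#' inflated light-channel noise so the series has a true limit of
#' quantification.
#'
#' @param true_conc_fmol endogenous light amount on column (fmol) in the
#'   control cohort.
#' @param spike_heavy_fmol constant heavy spike (fmol).
#' @param dilution_base base of the geometric dilution series (default 3).
#' @param n_dilution_points number of dilution points (default 8, spanning a
#'   base^(n-1)-fold concentration range).
#' @param n_replicates replicates per dilution point.
#' @param replicate_cv fractional replicate coefficient of variation of each
#'   channel away from the noise floor.
#' @param knee_index dilution point (1 = most dilute) from which the series
#'   is clean; points below it get \code{low_conc_cv} light-channel noise.
#'   \code{1} disables the planted knee.
#' @param low_conc_cv fractional CV of the light channel below the knee;
#'   the default 1.0 reflects the below-LOQ regime where the analyte signal
#'   sits at the noise floor and scatters on the order of its own magnitude.
#' @param cohort_sizes named integer vector of cohort sample counts, default
#'   \code{c(cancer = 70, control = 30)}.
#' @param group_fold multiplicative shift of the light amount in the first
#'   (cancer) cohort.
#' @param response_per_fmol detector response (area units per fmol).
#' @param seed integer seed.
#' @return an object of class \code{mrm_sim_config}.
#' @export
mrm_sim_config <- function(true_conc_fmol = 30,
                           spike_heavy_fmol = 30,
                           dilution_base = 3L,
                           n_dilution_points = 8L,
                           n_replicates = 5L,
                           replicate_cv = 0.05,
                           knee_index = 3L,
                           low_conc_cv = 1.0,
                           cohort_sizes = c(cancer = 70, control = 30),
                           group_fold = 2,
                           response_per_fmol = 1000,
                           seed = 1L) {
  if (replicate_cv < 0) stop("replicate_cv must be >= 0")
  stopifnot(true_conc_fmol > 0, spike_heavy_fmol > 0, dilution_base >= 2,
            n_dilution_points >= 3, n_replicates >= 2,
            knee_index >= 1, knee_index <= n_dilution_points,
            low_conc_cv >= 0, all(cohort_sizes >= 1), group_fold > 0,
            response_per_fmol > 0)
  structure(list(true_conc_fmol = true_conc_fmol,
                 spike_heavy_fmol = spike_heavy_fmol,
                 dilution_base = as.integer(dilution_base),
                 n_dilution_points = as.integer(n_dilution_points),
                 n_replicates = as.integer(n_replicates),
                 replicate_cv = replicate_cv,
                 knee_index = as.integer(knee_index),
                 low_conc_cv = low_conc_cv,
                 cohort_sizes = cohort_sizes,
                 group_fold = group_fold,
                 response_per_fmol = response_per_fmol,
                 seed = as.integer(seed)),
            class = "mrm_sim_config")
}

rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sigma2 <- log(1 + cv^2)
  stats::rlnorm(n, -sigma2 / 2, sqrt(sigma2))  # mean exactly 1
}

#' Simulate an MRM dilution series and measurement cohort
#'
#' The dilution series is anchored so that the middle point has a nominal
#' light:heavy ratio of 1; nominal light amounts form an exact geometric
#' sequence in the dilution base. Cohort samples carry the configured fold
#' change in the cancer group.
#'
#' @param cfg an \code{\link{mrm_sim_config}}.
#' @return a list with elements
#'   \item{dilution}{data frame \code{point_index}, \code{replicate_id},
#'     \code{nominal_light_fmol}, \code{spike_heavy_fmol},
#'     \code{light_area}, \code{heavy_area};}
#'   \item{cohort}{data frame \code{sample_id}, \code{group},
#'     \code{light_area}, \code{heavy_area};}
#'   \item{truth}{list with the planted knee concentration, per-sample
#'     on-column amounts and the planted fold.}
#' @export
generate_mrm_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "mrm_sim_config"))
  set.seed(cfg$seed)
  k <- cfg$n_dilution_points
  anchor <- ceiling(k / 2)
  nominal <- cfg$spike_heavy_fmol * as.numeric(cfg$dilution_base)^(seq_len(k) - anchor)

  idx <- rep(seq_len(k), each = cfg$n_replicates)
  rep_id <- rep(seq_len(cfg$n_replicates), times = k)
  light_cv <- ifelse(idx < cfg$knee_index, cfg$low_conc_cv, cfg$replicate_cv)
  sigma2 <- log(1 + light_cv^2)
  light_noise <- ifelse(light_cv == 0, 1,
                        stats::rlnorm(length(idx), -sigma2 / 2, sqrt(sigma2)))
  light_area <- cfg$response_per_fmol * nominal[idx] * light_noise
  heavy_area <- cfg$response_per_fmol * cfg$spike_heavy_fmol *
    rlnorm_cv(length(idx), cfg$replicate_cv)
  dilution <- data.frame(point_index = idx, replicate_id = rep_id,
                         nominal_light_fmol = nominal[idx],
                         spike_heavy_fmol = cfg$spike_heavy_fmol,
                         light_area = light_area, heavy_area = heavy_area)

  groups <- rep(names(cfg$cohort_sizes), cfg$cohort_sizes)
  n <- length(groups)
  fold <- ifelse(groups == names(cfg$cohort_sizes)[1], cfg$group_fold, 1)
  amount <- cfg$true_conc_fmol * fold
  cohort <- data.frame(
    sample_id = paste0(groups, "_", unlist(lapply(cfg$cohort_sizes, seq_len))),
    group = groups,
    light_area = cfg$response_per_fmol * amount * rlnorm_cv(n, cfg$replicate_cv),
    heavy_area = cfg$response_per_fmol * cfg$spike_heavy_fmol *
      rlnorm_cv(n, cfg$replicate_cv),
    stringsAsFactors = FALSE)

  list(dilution = dilution, cohort = cohort,
       truth = list(knee_fmol = nominal[cfg$knee_index],
                    amount_fmol = stats::setNames(amount, cohort$sample_id),
                    group_fold = cfg$group_fold))
}

#' Configuration for the paired tissue-microarray cohort generator
#'
#' @param n_pairs number of tumor/adjacent-normal section pairs.
#' @param tumor_percent_mean,tumor_percent_sd,normal_percent_mean,normal_percent_sd
#'   mean and SD of the percentage of positive cells per tissue class;
#'   draws are clamped to [0, 100].
#' @param tumor_intensity_probs,normal_intensity_probs probabilities over
#'   staining intensities \{0, 1, 2, 3\}.
#' @param n_pathologists number of independent raters per section.
#' @param seed integer seed.
#' @return an object of class \code{tma_sim_config}.
#' @export
tma_sim_config <- function(n_pairs = 89,
                           tumor_percent_mean = 60, tumor_percent_sd = 20,
                           normal_percent_mean = 20, normal_percent_sd = 15,
                           tumor_intensity_probs = c(0.05, 0.15, 0.40, 0.40),
                           normal_intensity_probs = c(0.30, 0.40, 0.20, 0.10),
                           n_pathologists = 2,
                           seed = 1L) {
  check_probs <- function(p) {
    if (length(p) != 4 || any(p < 0) || abs(sum(p) - 1) > 1e-8)
      stop("intensity probabilities must be 4 non-negative values summing to 1")
  }
  check_probs(tumor_intensity_probs); check_probs(normal_intensity_probs)
  stopifnot(n_pairs >= 1, n_pathologists >= 1)
  structure(list(n_pairs = as.integer(n_pairs),
                 tumor_percent_mean = tumor_percent_mean,
                 tumor_percent_sd = tumor_percent_sd,
                 normal_percent_mean = normal_percent_mean,
                 normal_percent_sd = normal_percent_sd,
                 tumor_intensity_probs = tumor_intensity_probs,
                 normal_intensity_probs = normal_intensity_probs,
                 n_pathologists = as.integer(n_pathologists),
                 seed = as.integer(seed)),
            class = "tma_sim_config")
}

#' Simulate a paired tumor/normal TMA cohort
#'
#' Each section is read independently by each pathologist: the percentage of
#' positive cells is Gaussian (clamped to [0, 100]) and the staining
#' intensity categorical over \{0, 1, 2, 3\}.
#'
#' @param cfg a \code{\link{tma_sim_config}}.
#' @return a long data frame with columns \code{case_id}, \code{tissue}
#'   (tumor / adjacent_normal), \code{rater}, \code{percent},
#'   \code{intensity}.
#' @export
generate_tma_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "tma_sim_config"))
  set.seed(cfg$seed)
  grid <- expand.grid(rater = seq_len(cfg$n_pathologists),
                      tissue = c("tumor", "adjacent_normal"),
                      case_id = sprintf("case%03d", seq_len(cfg$n_pairs)),
                      stringsAsFactors = FALSE)
  tum <- grid$tissue == "tumor"
  n <- nrow(grid)
  percent <- numeric(n)
  percent[tum] <- stats::rnorm(sum(tum), cfg$tumor_percent_mean,
                               cfg$tumor_percent_sd)
  percent[!tum] <- stats::rnorm(sum(!tum), cfg$normal_percent_mean,
                                cfg$normal_percent_sd)
  percent <- pmin(pmax(percent, 0), 100)
  intensity <- integer(n)
  intensity[tum] <- sample(0:3, sum(tum), replace = TRUE,
                           prob = cfg$tumor_intensity_probs)
  intensity[!tum] <- sample(0:3, sum(!tum), replace = TRUE,
                            prob = cfg$normal_intensity_probs)
  data.frame(case_id = grid$case_id, tissue = grid$tissue,
             rater = grid$rater, percent = percent, intensity = intensity,
             stringsAsFactors = FALSE)
}
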