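# SID-MRM quantification: ratios, calibration fitting, LOQ/LOD rules,
# transition selection and the conversion to absolute concentrations.

noiseless_series <- function(n_points = 8, base = 3, spike = 30,
                             n_reps = 3, resp = 1000) {
  nominal <- spike * base^(seq_len(n_points) - ceiling(n_points / 2))
  idx <- rep(seq_len(n_points), each = n_reps)
  data.frame(point_index = idx, replicate_id = rep(seq_len(n_reps), n_points),
             nominal_light_fmol = nominal[idx], spike_heavy_fmol = spike,
             light_area = resp * nominal[idx], heavy_area = resp * spike)
}

test_that("light/heavy ratios are computed and QC-gated as defined", {
  m <- data.frame(sample_id = rep("s1", 4), peptide = rep("PEP", 4),
                  transition_id = rep(c("t1", "t2"), each = 2),
                  label = rep(c("light", "heavy"), 2),
                  area = c(500, 500, 0, 400))
  r <- compute_ratios(m)
  expect_equal(r$ratio[r$transition_id == "t1"], 1)
  expect_equal(r$ratio[r$transition_id == "t2"], 0)
  expect_true(r$below_lod[r$transition_id == "t2"])
  expect_false(r$below_lod[r$transition_id == "t1"])

  expect_error(compute_ratios(m[-2, ]), "heavy")
  m_zero <- transform(m, area = c(500, 0, 10, 400))
  expect_error(compute_ratios(m_zero), "zero heavy")
  m_qc <- cbind(m, qc_pass = c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(nrow(compute_ratios(m_qc)), 1)
})

test_that("noiseless ratios reproduce nominal dilution factors exactly", {
  mrm <- generate_mrm_dataset(mrm_sim_config(replicate_cv = 0, knee_index = 1,
                                             seed = 71L))
  d <- mrm$dilution
  long <- rbind(
    data.frame(sample_id = paste0("p", d$point_index, "_r", d$replicate_id),
               peptide = "PEP", transition_id = "t1", label = "light",
               area = d$light_area),
    data.frame(sample_id = paste0("p", d$point_index, "_r", d$replicate_id),
               peptide = "PEP", transition_id = "t1", label = "heavy",
               area = d$heavy_area))
  r <- compute_ratios(long)
  key <- as.integer(sub("p(\\d+)_r.*", "\\1", r$sample_id))
  nominal <- d$nominal_light_fmol[match(key, d$point_index)] / d$spike_heavy_fmol[1]
  expect_equal(r$ratio, nominal, tolerance = 1e-12)
})

test_that("a noiseless calibration fits slope 1, intercept 0, R = 1", {
  cv <- fit_calibration(noiseless_series())
  expect_equal(cv$slope, 1, tolerance = 1e-10)
  expect_equal(cv$intercept, 0, tolerance = 1e-10)
  expect_equal(cv$pearson_r, 1, tolerance = 1e-12)
  # the point with ratio exactly 1 anchors the amount assignment
  expect_equal(cv$points$mean_ratio[cv$anchor_index], 1)
  expect_equal(cv$points$nominal_ratio[cv$anchor_index], 1)
  expect_error(fit_calibration(noiseless_series(n_points = 2)), "3 dilution")
})

test_that("calibration recovers its parameters under replicate noise", {
  ok <- 0
  for (s in 1:100) {
    mrm <- generate_mrm_dataset(mrm_sim_config(replicate_cv = 0.05,
                                               knee_index = 1,
                                               seed = 700L + s))
    cv <- fit_calibration(mrm$dilution)
    if (cv$slope > 0.97 && cv$slope < 1.03 && cv$pearson_r > 0.99) ok <- ok + 1
  }
  expect_gte(ok / 100, 0.95)
})

test_that("LOQ scanning implements the CV and linearity rules", {
  # all points clean -> LOQ is the lowest concentration
  mrm <- generate_mrm_dataset(mrm_sim_config(knee_index = 1, seed = 72L))
  cv <- fit_calibration(mrm$dilution)
  expect_equal(determine_loq(cv), min(cv$points$nominal_light_fmol))

  # curvature at the bottom two points (replicate CV fine) -> third point
  ser <- noiseless_series()
  flat <- ser$point_index <= 2
  ser$light_area[flat] <- 1000 * ser$nominal_light_fmol[ser$point_index == 3][1]
  # tiny replicate jitter so CVs are defined but negligible
  set.seed(73); ser$light_area <- ser$light_area * (1 + rnorm(nrow(ser), 0, 1e-4))
  cv2 <- fit_calibration(ser)
  expect_equal(determine_loq(cv2),
               sort(unique(ser$nominal_light_fmol))[3])

  # nothing quantifiable -> NA with a warning
  bad <- cv2; bad$points$replicate_cv[] <- 0.5
  expect_warning(out <- determine_loq(bad), "not quantifiable")
  expect_true(is.na(out))
})

test_that("the planted noise knee is recovered as the LOQ", {
  hits <- 0
  for (s in 1:100) {
    mrm <- generate_mrm_dataset(mrm_sim_config(seed = 800L + s))
    cv <- fit_calibration(mrm$dilution)
    if (isTRUE(all.equal(determine_loq(cv), mrm$truth$knee_fmol)))
      hits <- hits + 1
  }
  expect_gte(hits / 100, 0.9)
})

test_that("LOD interpolation honors S/N = 3", {
  # S/N exactly 3 at a measured point
  expect_equal(determine_lod(c(1, 2, 4), c(1.5, 3, 6)), 2)
  # proportionality from a single point: S/N 30 at c -> LOD c/10
  expect_equal(determine_lod(8, 30), 0.8)
  # extrapolation below a proportional series
  expect_equal(determine_lod(c(10, 20), c(30, 60)), 1)
  expect_error(determine_lod(c(1, 2), c(0.5, 1)), "never reaches")
  # noisy proportional response lands within 1.5x of truth
  set.seed(74)
  conc <- 2^(0:7)
  snr <- conc * 1.5 * rlnorm(8, 0, 0.15)   # true LOD = 2
  lod <- determine_lod(conc, snr)
  expect_gt(lod, 2 / 1.5); expect_lt(lod, 2 * 1.5)
})

test_that("inter-assay CV is the percent sd/mean with its invariances", {
  expect_equal(interassay_cv(c(9, 10, 11)), 10)
  expect_equal(interassay_cv(c(7, 7, 7)), 0)
  x <- c(4.1, 3.8, 4.4, 4.0, 4.2)
  expect_equal(interassay_cv(1000 * x), interassay_cv(x))
  expect_error(interassay_cv(5), ">= 2")
  expect_error(interassay_cv(c(-1, 1)), "mean")
  # estimates center on the generating CV
  set.seed(75)
  est <- replicate(500, interassay_cv(rlnorm(5, 0, sqrt(log(1 + 0.02^2)))))
  expect_lt(abs(mean(est) - 2), 0.2)
})

test_that("best-transition selection ranks by linearity, then LOQ", {
  mk <- function(r, loq, id) {
    cv <- fit_calibration(noiseless_series(), transition_id = id)
    cv$pearson_r <- r; cv$loq_fmol <- loq
    cv
  }
  expect_equal(select_best_transition(list(mk(0.995, 5, "only"))), "only")
  expect_equal(select_best_transition(list(mk(0.999, 5, "a"),
                                           mk(0.98, 1, "b"))), "a")
  expect_equal(select_best_transition(list(mk(0.999, 2, "a"),
                                           mk(0.999, 7, "b"))), "a")
  expect_equal(select_best_transition(list(mk(0.999, 2, "a"),
                                           mk(0.999, 2, "b")),
                                      heavy_means = c(10, 50)), "b")
})

test_that("absolute concentration inverts the calibration line", {
  cv <- fit_calibration(noiseless_series(spike = 10))
  one <- absolute_concentration(1.0, cv, spike_fmol = 10)
  expect_equal(one$fmol_on_column, 10, tolerance = 1e-9)
  three <- absolute_concentration(3.0, cv, spike_fmol = 10)
  expect_equal(three$fmol_on_column, 30, tolerance = 1e-9)
  expect_error(absolute_concentration(-1, cv), "positive")

  # round trip at machine precision in the noiseless limit
  planted <- c(0.2, 5, 42, 900)
  ratios <- planted / 10
  back <- absolute_concentration(ratios, cv, spike_fmol = 10)
  expect_equal(back$fmol_on_column, planted, tolerance = 1e-9)
  # 0.2 and 900 fmol fall outside the calibrated 3^-3..3^4 ratio range
  expect_equal(back$extrapolated, c(TRUE, FALSE, FALSE, TRUE))

  # serum conversion: fmol x molar mass / volume x 1e-6
  rec <- absolute_concentration(1, cv, spike_fmol = 10,
                                serum_volume_ul = 0.1,
                                molar_mass_da = protein_molar_masses["A1BG"])
  expect_equal(rec$serum_conc_ug_per_ml,
               10 * 54254 / 0.1 * 1e-6)
})

test_that("LOQ rises when low-concentration noise worsens", {
  loq_at <- function(low_cv) {
    vals <- vapply(1:30, function(s) {
      mrm <- generate_mrm_dataset(mrm_sim_config(knee_index = 4,
                                                 low_conc_cv = low_cv,
                                                 seed = 900L + s))
      cv <- fit_calibration(mrm$dilution)
      suppressWarnings(determine_loq(cv))
    }, numeric(1))
    mean(vals, na.rm = TRUE)
  }
  expect_gt(loq_at(1.0), loq_at(0.05))
})

test_that("cohort statistics recover the planted fold and discriminate", {
  mrm <- generate_mrm_dataset(mrm_sim_config(group_fold = 2, seed = 76L))
  cal <- fit_calibration(mrm$dilution)
  ratio <- mrm$cohort$light_area / mrm$cohort$heavy_area
  conc <- absolute_concentration(ratio, cal,
                                 molar_mass_da = protein_molar_masses["A1BG"])
  fold <- mean(conc$fmol_on_column[mrm$cohort$group == "cancer"]) /
    mean(conc$fmol_on_column[mrm$cohort$group == "control"])
  expect_gt(fold, 1.8); expect_lt(fold, 2.2)

  recs <- data.frame(sample_id = mrm$cohort$sample_id, protein = "A1BG",
                     group = mrm$cohort$group,
                     concentration = conc$serum_conc_ug_per_ml)
  mrm2 <- generate_mrm_dataset(mrm_sim_config(group_fold = 1.5, seed = 77L))
  ratio2 <- mrm2$cohort$light_area / mrm2$cohort$heavy_area
  conc2 <- absolute_concentration(ratio2, cal,
                                  molar_mass_da = protein_molar_masses["LRG1"])
  recs2 <- data.frame(sample_id = mrm2$cohort$sample_id, protein = "LRG1",
                      group = mrm2$cohort$group,
                      concentration = conc2$serum_conc_ug_per_ml)
  set.seed(78)
  demo <- data.frame(sample_id = mrm$cohort$sample_id,
                     sex = sample(c("F", "M"), 100, replace = TRUE),
                     age = rnorm(100, 60, 8))
  cs <- cohort_stats(rbind(recs, recs2), case_group = "cancer",
                     demographics = demo)
  expect_true(all(cs$per_protein$p_value < 0.01))
  expect_true(all(cs$per_protein$auc > 0.8))
  expect_gte(cs$panel$roc$auc, max(cs$per_protein$auc) - 0.02)
  # null demographics stay non-significant
  expect_true(all(cs$demographic_tests$p_value > 0.001))
})
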