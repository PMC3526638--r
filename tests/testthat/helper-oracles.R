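# Independent oracles used across the suite. Each is a deliberately naive
# implementation (brute force, enumeration or closed form) kept separate
# from the package code it checks.

# AUC as the Mann-Whitney rank statistic, ties counted one half
oracle_rank_auc <- function(score, label) {
  pos <- score[label == 1]
  neg <- score[label == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# closed-form AUC of the unit-variance binormal model with mean shift delta
oracle_binormal_auc <- function(delta) pnorm(delta / sqrt(2))

# exact two-group permutation p-value of the |t| statistic by full
# enumeration of all label splits
oracle_exact_perm_p <- function(v1, v2) {
  pooled <- c(v1, v2)
  n1 <- length(v1)
  tstat <- function(idx) {
    a <- pooled[idx]; b <- pooled[-idx]
    sp <- sqrt(((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
                 (length(a) + length(b) - 2) *
                 (1 / length(a) + 1 / length(b)))
    if (sp == 0) 0 else abs((mean(a) - mean(b)) / sp)
  }
  obs <- tstat(seq_len(n1))
  splits <- combn(length(pooled), n1, simplify = FALSE)
  mean(vapply(splits, tstat, numeric(1)) >= obs - 1e-12)
}

# brute-force per-charge threshold search: try every observed score as the
# cutoff and keep the smallest one meeting the FDR target
oracle_select_threshold <- function(psms, charge, fdr_target) {
  sub <- psms[psms$charge == charge & psms$delta_cn >= 0.1, ]
  best <- Inf
  for (t in sort(unique(sub$xcorr), decreasing = TRUE)) {
    pass <- sub$xcorr >= t
    nt <- sum(pass & !sub$is_decoy)
    fdr <- if (nt == 0) 0 else sum(pass & sub$is_decoy) / nt
    if (fdr < fdr_target) best <- t
  }
  best
}

# small dense PSM data frame builder for hand-made tables
make_psms <- function(xcorr, is_decoy, charge = 2L, delta_cn = 0.3,
                      peptide = NULL, accessions = NULL) {
  n <- length(xcorr)
  data.frame(spectrum_id = paste0("s", seq_len(n)),
             peptide = if (is.null(peptide)) paste0("pep", seq_len(n)) else peptide,
             accessions = if (is.null(accessions)) paste0("ACC", seq_len(n)) else accessions,
             charge = rep_len(charge, n),
             xcorr = xcorr,
             delta_cn = rep_len(delta_cn, n),
             is_decoy = is_decoy,
             stringsAsFactors = FALSE)
}
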