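# Discovery-phase label-free quantification on spectral counts: the
# relative enrichment factor Re, permutation ANOVA/t tests, log2-quantile
# normalization, clustering and PCA.

#' Relative enrichment factor Re
#'
#' For protein f in sample s, Re = (n_f / n) / (N_f / N): the protein's
#' share of the sample's peptide hits relative to its share over the whole
#' cohort. Here n_f is the count of protein f in sample s, n the sample's
#' total count, N_f the protein's total over all samples and N the grand
#' total. Re > 1 marks within-sample enrichment; a zero count gives Re = 0.
#' Proteins never observed (N_f = 0) are dropped. The weighted sum
#' \eqn{\sum_f (N_f/N) Re_{fs} = 1} holds exactly for every sample.
#'
#' @param counts non-negative integer matrix, proteins x samples.
#' @return numeric matrix of Re values with the same dimnames (minus dropped
#'   all-zero proteins).
#' @export
enrichment_factor <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (all(counts == 0)) stop("all-zero count matrix")
  nf_tot <- rowSums(counts)
  counts <- counts[nf_tot > 0, , drop = FALSE]
  nf_tot <- nf_tot[nf_tot > 0]
  n_s <- colSums(counts)
  if (any(n_s == 0)) stop("sample(s) with zero total counts: ",
                          paste(colnames(counts)[n_s == 0], collapse = ", "))
  N <- sum(counts)
  share_sample <- sweep(counts, 2, n_s, "/")
  share_global <- nf_tot / N
  sweep(share_sample, 1, share_global, "/")
}

# pooled-variance two-sample t statistic per row; constant rows give 0
row_t_stat <- function(x, g1, g2) {
  n1 <- length(g1); n2 <- length(g2)
  m1 <- rowMeans(x[, g1, drop = FALSE]); m2 <- rowMeans(x[, g2, drop = FALSE])
  ss1 <- rowSums((x[, g1, drop = FALSE] - m1)^2)
  ss2 <- rowSums((x[, g2, drop = FALSE] - m2)^2)
  sp <- sqrt((ss1 + ss2) / (n1 + n2 - 2) * (1 / n1 + 1 / n2))
  t <- (m1 - m2) / sp
  t[!is.finite(t)] <- 0
  t
}

# one-way F statistic per row; constant rows give 0
row_f_stat <- function(x, idx_by_group) {
  k <- length(idx_by_group); n <- ncol(x)
  gm <- rowMeans(x)
  ss_b <- 0; ss_w <- 0
  for (idx in idx_by_group) {
    m <- rowMeans(x[, idx, drop = FALSE])
    ss_b <- ss_b + length(idx) * (m - gm)^2
    ss_w <- ss_w + rowSums((x[, idx, drop = FALSE] - m)^2)
  }
  f <- (ss_b / (k - 1)) / (ss_w / (n - k))
  f[!is.finite(f)] <- 0
  f
}

#' Permutation test per protein
#'
#' Tests each row of \code{values} for a group difference by permuting the
#' sample labels jointly across all rows. The p-value uses the add-one
#' correction p = (1 + #\{permuted |stat| >= observed |stat|\}) /
#' (n_perm + 1), so it is never exactly zero. The statistic is a
#' pooled-variance two-sample t ("t", exactly two groups required) or a
#' one-way ANOVA F ("F", two or more groups). Rows that are constant within
#' the permutation distribution get p = 1.
#'
#' @param values numeric matrix, proteins x samples (e.g. Re values or
#'   normalized counts).
#' @param group factor or character vector of cohort labels per sample.
#' @param n_perm number of random permutations (>= 1).
#' @param statistic "t" or "F".
#' @param seed integer seed for the permutation stream.
#' @return numeric vector of p-values, one per row.
#' @export
permutation_test <- function(values, group, n_perm = 10000,
                             statistic = c("t", "F"), seed = 1L) {
  statistic <- match.arg(statistic)
  values <- as.matrix(values)
  group <- as.character(group)
  stopifnot(ncol(values) == length(group), n_perm >= 1)
  tab <- table(group)
  if (any(tab < 2)) stop("every compared group needs >= 2 samples")
  if (statistic == "t" && length(tab) != 2)
    stop("statistic 't' requires exactly two groups")
  lv <- names(tab)
  stat_fun <- if (statistic == "t") {
    function(g) row_t_stat(values, which(g == lv[1]), which(g == lv[2]))
  } else {
    function(g) row_f_stat(values, split(seq_along(g), g))
  }
  obs <- abs(stat_fun(group))
  set.seed(seed)
  exceed <- integer(nrow(values))
  for (b in seq_len(n_perm)) {
    perm <- sample(group)
    exceed <- exceed + (abs(stat_fun(perm)) >= obs)
  }
  (1 + exceed) / (n_perm + 1)
}

#' Flag significantly differential proteins
#'
#' Combines a per-protein ANOVA p-value with pairwise t-test p-values at a
#' raw (uncorrected) significance level, mirroring discovery-phase filters
#' that list every protein differential in at least one contrast. Under
#' \code{rule = "or"} (default) a protein is flagged when the ANOVA p or any
#' pairwise p is below \code{alpha}; \code{"and"} requires both.
#'
#' @param p_anova numeric vector of ANOVA p-values (may be NULL when only
#'   pairwise tests were run).
#' @param p_ttest numeric matrix of pairwise p-values, proteins x contrasts
#'   (may be NULL).
#' @param alpha raw significance level in (0, 1), default 0.01.
#' @param rule "or" or "and".
#' @return data frame with \code{significant} and \code{which_test}
#'   ("anova", "ttest", "both" or "none").
#' @export
filter_significant <- function(p_anova = NULL, p_ttest = NULL, alpha = 0.01,
                               rule = c("or", "and")) {
  rule <- match.arg(rule)
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (is.null(p_anova) && is.null(p_ttest)) stop("no p-values supplied")
  chk <- function(p) if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  if (!is.null(p_anova)) chk(p_anova)
  if (!is.null(p_ttest)) { p_ttest <- as.matrix(p_ttest); chk(p_ttest) }
  hit_a <- if (is.null(p_anova)) NULL else p_anova < alpha
  hit_t <- if (is.null(p_ttest)) NULL else
    apply(p_ttest < alpha, 1, any, na.rm = TRUE)
  if (is.null(hit_a)) hit_a <- hit_t
  if (is.null(hit_t)) hit_t <- hit_a
  sig <- if (rule == "or") hit_a | hit_t else hit_a & hit_t
  which_test <- ifelse(hit_a & hit_t, "both",
                       ifelse(hit_a, "anova", ifelse(hit_t, "ttest", "none")))
  data.frame(significant = sig, which_test = which_test,
             stringsAsFactors = FALSE)
}

#' Log2 transform plus quantile normalization of spectral counts
#'
#' Transforms each cell to log2(count + 1), then forces every sample column
#' onto the common reference distribution formed by the per-rank means of
#' the column-sorted values. Tied values within a column receive the mean of
#' the reference values over their rank range, so the map is well defined
#' and order preserving.
#'
#' @param counts non-negative matrix, proteins x samples.
#' @return normalized numeric matrix of the same dimensions.
#' @export
normalize_log_quantile <- function(counts) {
  x <- log2(as.matrix(counts) + 1)
  if (nrow(x) == 0 || ncol(x) == 0) return(x)
  ref <- rowMeans(apply(x, 2, sort))
  out <- x
  for (j in seq_len(ncol(x))) {
    v <- x[, j]
    rmin <- rank(v, ties.method = "min")
    rmax <- rank(v, ties.method = "max")
    out[, j] <- vapply(seq_along(v),
                       function(i) mean(ref[rmin[i]:rmax[i]]), numeric(1))
  }
  out
}

#' Hierarchical clustering of samples
#'
#' Agglomerative clustering of the sample columns of a normalized matrix
#' (Euclidean distance, average linkage by default) with a k-cluster cut.
#'
#' @param x numeric matrix, proteins x samples (normalized).
#' @param k number of clusters for the cut (default 2, separating cancer
#'   from control in a two-cohort design).
#' @param method linkage passed to \code{\link[stats]{hclust}}.
#' @param dist_method distance passed to \code{\link[stats]{dist}}.
#' @return list with \code{hclust} (the tree) and \code{cluster} (named
#'   integer labels from \code{\link[stats]{cutree}}).
#' @export
hierarchical_cluster <- function(x, k = 2, method = "average",
                                 dist_method = "euclidean") {
  x <- as.matrix(x)
  if (ncol(x) < 2) stop("need at least two samples")
  if (ncol(x) < k) stop("fewer samples than clusters requested")
  hc <- stats::hclust(stats::dist(t(x), method = dist_method),
                      method = method)
  list(hclust = hc, cluster = stats::cutree(hc, k = k))
}

#' Principal component analysis with protein loadings (bi-plot data)
#'
#' Column-centered PCA of samples over proteins. Returns per-sample scores
#' and per-protein loadings so both can be drawn on one bi-plot. Component
#' signs follow a deterministic convention: within each component the
#' largest-magnitude loading is made positive.
#'
#' @param x numeric matrix, proteins x samples (normalized).
#' @return list with \code{scores} (samples x components), \code{loadings}
#'   (proteins x components) and \code{var_explained} (fraction per
#'   component).
#' @export
pca_biplot <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2 || nrow(x) < 2) stop("need >= 2 samples and >= 2 proteins")
  if (all(apply(x, 1, stats::var) == 0)) stop("zero-variance data")
  pc <- stats::prcomp(t(x), center = TRUE, scale. = FALSE)
  flip <- vapply(seq_len(ncol(pc$rotation)), function(j) {
    l <- pc$rotation[, j]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  flip[flip == 0] <- 1
  scores <- sweep(pc$x, 2, flip, "*")
  loadings <- sweep(pc$rotation, 2, flip, "*")
  list(scores = scores, loadings = loadings,
       var_explained = pc$sdev^2 / sum(pc$sdev^2))
}

#' Per-protein LFQ statistics table
#'
#' Convenience wrapper running the full discovery-phase statistics: Re
#' values, a permutation ANOVA across all cohorts (when more than two), a
#' permutation t test per pairwise contrast, and the significance filter.
#'
#' @param counts protein x sample count matrix.
#' @param group cohort label per sample.
#' @param n_perm permutations per test.
#' @param alpha raw significance level.
#' @param rule combination rule for \code{\link{filter_significant}}.
#' @param seed integer seed.
#' @return data frame with per-protein mean Re per cohort, p-values and
#'   significance flags.
#' @export
lfq_stats <- function(counts, group, n_perm = 10000, alpha = 0.01,
                      rule = "or", seed = 1L) {
  re <- enrichment_factor(counts)
  group <- as.character(group)
  lv <- unique(group)
  re_means <- sapply(lv, function(g)
    rowMeans(re[, group == g, drop = FALSE]))
  colnames(re_means) <- paste0("re_mean_", lv)
  p_anova <- if (length(lv) > 2)
    permutation_test(re, group, n_perm, "F", seed = seed) else NULL
  contrasts <- utils::combn(lv, 2, simplify = FALSE)
  p_t <- sapply(seq_along(contrasts), function(i) {
    ct <- contrasts[[i]]
    sel <- group %in% ct
    permutation_test(re[, sel, drop = FALSE], group[sel], n_perm, "t",
                     seed = seed + i)
  })
  colnames(p_t) <- vapply(contrasts, function(ct)
    paste0("p_t_", ct[1], "_vs_", ct[2]), character(1))
  flags <- filter_significant(p_anova, p_t, alpha, rule)
  out <- data.frame(protein_id = rownames(re), re_means,
                    stringsAsFactors = FALSE)
  if (!is.null(p_anova)) out$p_anova <- p_anova
  cbind(out, p_t, flags)
}
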