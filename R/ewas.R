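#' Per-CpG association scan
#'
#' For every CpG, correlates the beta value with the contrast variable and
#' maps the correlation to a t-statistic, two-sided p-value, and a signed
#' standard-normal-scale Z:
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)`, `p` from the t distribution with
#' `n - 2` degrees of freedom, `z = sign(r) * qnorm(1 - p/2)` capped at
#' |z| <= 40 so p-value underflow never produces infinite quantiles.
#'
#' Contrasts: `"age"` uses young vs old-control samples with numeric age as
#' the regressor (falling back to the old-group indicator when fewer than 3
#' distinct ages exist); `"treatment"` uses old-control (0) vs old-treated
#' (1). Zero-variance CpGs get `r = 0, p = 1, z = 0` and are counted in a
#' message.
#'
#' @param beta CpG x sample matrix.
#' @param sample_sheet validated sample sheet for the columns of `beta`.
#' @param contrast `"age"` or `"treatment"`.
#' @return data.frame with columns `cpg_id`, `r`, `t`, `p`, `z`, `n`.
#' @export
ewas_scan <- function(beta, sample_sheet, contrast = c("age", "treatment")) {
  contrast <- match.arg(contrast)
  beta <- validate_beta_matrix(beta)
  sample_sheet <- validate_sample_sheet(sample_sheet)
  sheet <- sample_sheet[match(colnames(beta), sample_sheet$sample_id), ]
  if (any(is.na(sheet$sample_id)))
    abort("sample sheet does not cover every matrix column")

  if (contrast == "age") {
    keep <- sheet$group %in% c("young", "old_control")
    xval <- sheet$age_years[keep]
    if (length(unique(xval)) < 3L)
      xval <- as.numeric(sheet$group[keep] == "old_control")
  } else {
    keep <- sheet$group %in% c("old_control", "old_treated")
    xval <- as.numeric(sheet$group[keep] == "old_treated")
  }
  b <- beta[, keep, drop = FALSE]
  n <- ncol(b)
  if (n < 4L) abort("contrast '%s' has only %d samples; need >= 4", contrast, n)
  res <- row_cor_stats(b, xval)
  if (res$n_degenerate > 0)
    message(sprintf("%d zero-variance CpG(s) set to z = 0, p = 1",
                    res$n_degenerate))
  data.frame(cpg_id = rownames(b), r = res$r, t = res$t, p = res$p,
             z = res$z, n = n, row.names = NULL)
}

# vectorized per-row Pearson correlation of a matrix against one covariate,
# with the r -> t -> p -> z mapping; shared by ewas_scan and the
# permutation test
row_cor_stats <- function(b, xval) {
  n <- ncol(b)
  xc <- xval - mean(xval)
  bc <- b - rowMeans(b)
  ss_b <- rowSums(bc^2)
  ss_x <- sum(xc^2)
  degenerate <- ss_b == 0
  r <- numeric(nrow(b))
  ok <- !degenerate
  r[ok] <- (bc[ok, , drop = FALSE] %*% xc) / sqrt(ss_b[ok] * ss_x)
  r <- pmin(pmax(r, -1), 1)
  t <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, 0))
  p <- 2 * pt(abs(t), df = n - 2, lower.tail = FALSE)
  z <- abs(z_from_p(p, sign_of = 1)) * sign(r)
  t[degenerate] <- NA_real_
  p[degenerate] <- 1
  z[degenerate] <- 0
  list(r = r, t = t, p = p, z = z, n_degenerate = sum(degenerate))
}

#' Classify CpGs by joint age and treatment significance
#'
#' With `z* = qnorm(1 - alpha/2)`: a CpG is `rejuvenated` (rescued) when
#' both |z| pass the threshold with opposite signs, `aggravated` (aged) when
#' both pass with the same sign, `age_only` / `treat_only` when exactly one
#' passes, `null` otherwise.
#'
#' @param z_age,z_treat signed Z vectors of equal length.
#' @param alpha two-sided significance level (headline default 0.01).
#' @return character vector of labels.
#' @export
classify_cpgs <- function(z_age, z_treat, alpha = 0.01) {
  stopifnot(length(z_age) == length(z_treat), alpha > 0, alpha < 1)
  zs <- qnorm(1 - alpha / 2)
  sig_a <- abs(z_age) >= zs
  sig_t <- abs(z_treat) >= zs
  label <- rep("null", length(z_age))
  label[sig_a & !sig_t] <- "age_only"
  label[!sig_a & sig_t] <- "treat_only"
  both <- sig_a & sig_t
  label[both & sign(z_age) != sign(z_treat)] <- "rejuvenated"
  label[both & sign(z_age) == sign(z_treat)] <- "aggravated"
  label
}

#' Joint EWAS table for the age and treatment contrasts
#'
#' Runs [ewas_scan()] for both contrasts and attaches the
#' [classify_cpgs()] label.
#'
#' @param beta CpG x sample matrix.
#' @param sample_sheet validated sample sheet.
#' @param alpha significance level for the classification.
#' @return data.frame (class `ewas_table`) with per-CpG
#'   `r_age, z_age, p_age, r_treat, z_treat, p_treat, label`.
#' @export
ewas_table <- function(beta, sample_sheet, alpha = 0.01) {
  a <- ewas_scan(beta, sample_sheet, "age")
  tr <- ewas_scan(beta, sample_sheet, "treatment")
  out <- data.frame(cpg_id = a$cpg_id,
                    r_age = a$r, z_age = a$z, p_age = a$p,
                    r_treat = tr$r, z_treat = tr$z, p_treat = tr$p)
  out$label <- classify_cpgs(out$z_age, out$z_treat, alpha)
  class(out) <- c("ewas_table", "data.frame")
  out
}

#' Count significant and overlapping CpGs
#'
#' Venn-style tallies from the classification labels: CpGs significant for
#' age, for treatment, their intersection, and the rejuvenated/aggravated
#' split of the intersection.
#'
#' @param labels character vector of [classify_cpgs()] labels.
#' @return named numeric vector with `n_age_significant`,
#'   `n_treat_significant`, `n_overlap`, `n_rejuvenated`, `n_aggravated`.
#' @export
overlap_summary <- function(labels) {
  tab <- table(factor(labels, levels = c("rejuvenated", "aggravated",
                                         "age_only", "treat_only", "null")))
  c(n_age_significant = unname(tab["rejuvenated"] + tab["aggravated"] +
                                 tab["age_only"]),
    n_treat_significant = unname(tab["rejuvenated"] + tab["aggravated"] +
                                   tab["treat_only"]),
    n_overlap = unname(tab["rejuvenated"] + tab["aggravated"]),
    n_rejuvenated = unname(tab["rejuvenated"]),
    n_aggravated = unname(tab["aggravated"]))
}

#' Correlation between age and treatment Z-statistics
#'
#' A negative correlation indicates that the treatment pushes CpG
#' methylation against its age drift, i.e. CpG-level rejuvenation.
#'
#' @param z_age,z_treat signed Z vectors.
#' @param subset `"all"` CpGs or `"significant"` (in either contrast at
#'   `alpha`).
#' @param alpha threshold used when `subset = "significant"`.
#' @return list with `r`, `p` (two-sided, via the t transform) and `n`.
#' @export
reversal_correlation <- function(z_age, z_treat,
                                 subset = c("all", "significant"),
                                 alpha = 0.01) {
  subset <- match.arg(subset)
  stopifnot(length(z_age) == length(z_treat))
  if (subset == "significant") {
    zs <- qnorm(1 - alpha / 2)
    keep <- abs(z_age) >= zs | abs(z_treat) >= zs
    z_age <- z_age[keep]; z_treat <- z_treat[keep]
  }
  if (length(z_age) < 3L) abort("need at least 3 CpGs for a correlation")
  ct <- stats::cor.test(z_age, z_treat, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(z_age))
}

#' Permutation-calibrated reversal significance
#'
#' The age scan (young vs old control) and the treatment scan (old control
#' vs old treated) share the control animals, so control-sample noise alone
#' induces a negative correlation between the two Z vectors even when the
#' treatment does nothing. The naive t-transform p of
#' [reversal_correlation()] is therefore anti-conservative for the question
#' "does the treatment reverse aging". This test calibrates it: the
#' treated/control labels are permuted among the old animals, `z_treat` and
#' the correlation are recomputed for each permutation — reproducing the
#' shared-control artifact under a true treatment null — and the one-sided
#' p is the rank of the observed correlation among the permuted ones. Both
#' Z vectors are recomputed per permutation (the age scan's control set is
#' the permuted one), since old animals are exchangeable under the null.
#'
#' @param beta CpG x sample matrix.
#' @param sample_sheet validated sample sheet.
#' @param n_perm number of label permutations (default 199, so the smallest
#'   attainable p is 0.005).
#' @param seed seed for the permutation draws.
#' @return list with `r` (observed), `p` (one-sided, negative direction),
#'   `p_naive` (t-transform p from [reversal_correlation()]), `null_mean`
#'   (mean permuted correlation, i.e. the artifact's size) and `n_perm`.
#' @export
reversal_permutation_test <- function(beta, sample_sheet, n_perm = 199,
                                      seed = 1L) {
  beta <- validate_beta_matrix(beta)
  sample_sheet <- validate_sample_sheet(sample_sheet)
  sheet <- sample_sheet[match(colnames(beta), sample_sheet$sample_id), ]
  young <- which(sheet$group == "young")
  old <- which(sheet$group %in% c("old_control", "old_treated"))
  b_old <- beta[, old, drop = FALSE]
  x_obs <- as.numeric(sheet$group[old] == "old_treated")
  r_of <- function(x) {
    b_age <- cbind(beta[, young, drop = FALSE], b_old[, x == 0, drop = FALSE])
    z_age <- row_cor_stats(b_age, rep(c(0, 1), c(length(young), sum(x == 0))))$z
    cor(z_age, row_cor_stats(b_old, x)$z)
  }
  r_obs <- r_of(x_obs)
  set.seed(seed)
  r_null <- vapply(seq_len(n_perm), function(i) r_of(sample(x_obs)),
                   numeric(1))
  z_age_obs <- ewas_scan(beta, sample_sheet, "age")$z
  z_trt_obs <- row_cor_stats(b_old, x_obs)$z
  list(r = r_obs,
       p = (1 + sum(r_null <= r_obs)) / (n_perm + 1),
       p_naive = reversal_correlation(z_age_obs, z_trt_obs)$p,
       null_mean = mean(r_null), n_perm = n_perm)
}

#' Top EWAS hits with nearest-gene labels
#'
#' Orders a scan by ascending p (ties broken by chromosome then start
#' position), annotates the nearest gene, and marks the methylation
#' direction from the sign of Z.
#'
#' @param scan data.frame from [ewas_scan()] (columns `cpg_id, p, z`).
#' @param annotation validated CpG annotation covering the scanned CpGs.
#' @param k rows to return (default 15); the whole table when `k` exceeds it.
#' @return data.frame with `cpg_id, chrom, start, nearest_gene, p, z,
#'   direction`.
#' @export
top_hits <- function(scan, annotation, k = 15) {
  annotation <- validate_cpg_annotation(annotation)
  idx <- match(scan$cpg_id, annotation$cpg_id)
  if (any(is.na(idx))) abort("annotation does not cover every scanned CpG")
  out <- data.frame(cpg_id = scan$cpg_id,
                    chrom = annotation$chrom[idx],
                    start = annotation$start[idx],
                    nearest_gene = annotation$nearest_gene[idx],
                    p = scan$p, z = scan$z,
                    direction = ifelse(scan$z >= 0, "gain", "loss"))
  ord <- order(out$p, out$chrom, out$start)
  head(out[ord, , drop = FALSE], n = min(k, nrow(out)))
}
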