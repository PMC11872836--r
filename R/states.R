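#' Trimmed mean
#'
#' Drops the `floor(trim * n)` smallest and largest values and averages the
#' rest. The statistic used to summarize all CpGs of a chromatin state into
#' one per-sample methylation level, robust to outlying probes.
#'
#' @param values numeric vector, non-empty.
#' @param trim fraction trimmed from each tail, in \[0, 0.5).
#' @return the trimmed mean.
#' @export
#' @examples
#' trimmed_mean(c(0, 1, 2, 3, 100), trim = 0.2)  # 2
trimmed_mean <- function(values, trim = 0.05) {
  if (length(values) == 0L) abort("trimmed_mean of empty input")
  if (!is.numeric(trim) || trim < 0 || trim >= 0.5)
    abort("trim must lie in [0, 0.5)")
  n <- length(values)
  k <- floor(trim * n)
  if (n - 2 * k < 1L) abort("trimming leaves no values")
  s <- sort(values)
  mean(s[(k + 1L):(n - k)])
}

#' Chromatin-state aging and treatment effects
#'
#' Collapses the CpG x sample matrix to a state x sample matrix of trimmed
#' means, then scores each state with two signed Z-statistics computed from
#' Welch t-tests on the per-sample state means: `z_age` (old control vs
#' young; positive = methylation gain with age) and `z_treat` (old treated
#' vs old control; positive = methylation gain under treatment). Using
#' samples, not CpGs, as the analysis unit avoids pseudo-replication.
#' States with fewer than `min_cpgs` CpGs, or whose trimmed means are
#' constant across all samples, are flagged ineligible.
#'
#' @param beta CpG x sample matrix; every CpG must be annotated.
#' @param annotation validated CpG annotation.
#' @param sample_sheet validated sample sheet.
#' @param trim trimmed-mean tail fraction (default 0.05).
#' @param min_cpgs minimum CpGs for a state to be eligible (default 10).
#' @return object of class `state_summary`: `$summary` data.frame (`state`,
#'   `n_cpgs`, `z_age`, `p_age`, `z_treat`, `p_treat`, `eligible`,
#'   `flagged`) and `$means` (state x sample trimmed-mean matrix).
#' @export
state_effects <- function(beta, annotation, sample_sheet, trim = 0.05,
                          min_cpgs = 10) {
  beta <- validate_beta_matrix(beta)
  annotation <- validate_cpg_annotation(annotation)
  sample_sheet <- validate_sample_sheet(sample_sheet)
  idx <- match(rownames(beta), annotation$cpg_id)
  if (any(is.na(idx)))
    abort("annotation lacks %d matrix CpG(s)", sum(is.na(idx)))
  state <- annotation$chromatin_state[idx]
  states <- sort(unique(state))

  means <- t(vapply(states, function(s) {
    apply(beta[state == s, , drop = FALSE], 2L, trimmed_mean, trim = trim)
  }, numeric(ncol(beta))))
  rownames(means) <- states

  sheet <- sample_sheet[match(colnames(beta), sample_sheet$sample_id), ]
  grp <- function(g) colnames(beta)[sheet$group == g]
  young <- grp("young"); ctrl <- grp("old_control"); trt <- grp("old_treated")
  if (length(young) < 2 || length(ctrl) < 2 || length(trt) < 2)
    abort("each group needs >= 2 samples for state-level Z")

  score <- function(s, a_ids, b_ids) {
    w <- welch_test(means[s, a_ids], means[s, b_ids])
    c(z = unname(z_from_p(w$p, sign_of = w$mean_diff)), p = w$p,
      flagged = as.numeric(w$flagged && w$t == 0))
  }
  agez <- t(vapply(states, score, numeric(3), a_ids = ctrl, b_ids = young))
  trz <- t(vapply(states, score, numeric(3), a_ids = trt, b_ids = ctrl))

  n_cpgs <- as.integer(table(factor(state, levels = states)))
  flagged <- agez[, "flagged"] > 0 | trz[, "flagged"] > 0
  summary <- data.frame(state = states, n_cpgs = n_cpgs,
                        z_age = agez[, "z"], p_age = agez[, "p"],
                        z_treat = trz[, "z"], p_treat = trz[, "p"],
                        eligible = n_cpgs >= min_cpgs & !flagged,
                        flagged = flagged, row.names = NULL)
  if (any(flagged))
    message(sprintf("%d state(s) with constant trimmed means flagged",
                    sum(flagged)))
  structure(list(summary = summary, means = means, trim = trim,
                 min_cpgs = min_cpgs), class = "state_summary")
}

#' @export
print.state_summary <- function(x, ...) {
  cat(sprintf("<state_summary> %d states, trim %.2g, min %d CpGs\n",
              nrow(x$summary), x$trim, x$min_cpgs))
  print(x$summary, digits = 3)
  invisible(x)
}

#' State-level reversal correlation and classification
#'
#' Correlates aging and treatment Z-statistics across eligible chromatin
#' states; a strongly negative r says the treatment moves state-level
#' methylation against its age drift. Each state is also classified by its
#' sign pattern at `|z| >= z_threshold`:
#' `gain_reversed` (age gain, treatment loss), `loss_mitigated` (age loss,
#' treatment gain), `concordant` (both significant, same sign), `neutral`
#' otherwise.
#'
#' @param state_summary a [state_effects()] result.
#' @param z_threshold significance threshold on |z| (default the two-sided
#'   0.05 quantile, 1.96).
#' @return list with `r`, `p`, `n_states`, and `$classification` data.frame.
#' @export
state_reversal <- function(state_summary, z_threshold = qnorm(0.975)) {
  stopifnot(inherits(state_summary, "state_summary"))
  s <- state_summary$summary
  el <- s[s$eligible, , drop = FALSE]
  if (nrow(el) < 3L)
    abort("need >= 3 eligible states for a reversal correlation (got %d)",
          nrow(el))
  ct <- stats::cor.test(el$z_age, el$z_treat, method = "pearson")

  cls <- rep("neutral", nrow(s))
  sig <- abs(s$z_age) >= z_threshold & abs(s$z_treat) >= z_threshold
  cls[sig & s$z_age > 0 & s$z_treat < 0] <- "gain_reversed"
  cls[sig & s$z_age < 0 & s$z_treat > 0] <- "loss_mitigated"
  cls[sig & sign(s$z_age) == sign(s$z_treat)] <- "concordant"
  list(r = unname(ct$estimate), p = ct$p.value, n_states = nrow(el),
       classification = data.frame(state = s$state, z_age = s$z_age,
                                   z_treat = s$z_treat, eligible = s$eligible,
                                   class = cls))
}
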