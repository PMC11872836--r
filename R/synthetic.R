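#' Default chromatin-state vocabulary
#'
#' A compact subset of a universal chromatin-state map: transcription start
#' sites (TSS), bivalent promoters (BivProm), Polycomb Repressive Complex 2
#' targets (PRC2), enhancers (Enh), transcribed regions (Tx),
#' heterochromatin (HET) and quiescent chromatin (Quies).
#' @export
STATE_LEVELS <- c("TSS", "BivProm", "PRC2", "Enh", "Tx", "HET", "Quies")

# states whose age drift is a methylation gain / loss
GAIN_STATES <- c("BivProm", "TSS", "PRC2")
LOSS_STATES <- c("HET", "Quies")

default_state_proportions <- c(TSS = 0.08, BivProm = 0.07, PRC2 = 0.05,
                               Enh = 0.15, Tx = 0.25, HET = 0.20, Quies = 0.20)

# P(island | state): CpG islands concentrate in bivalent/TSS chromatin
ISLAND_PROB <- c(TSS = 0.70, BivProm = 0.80, PRC2 = 0.60, Enh = 0.20,
                 Tx = 0.15, HET = 0.05, Quies = 0.05)

# P(region_class | state); rows sum to 1
REGION_PROB <- rbind(
  TSS     = c(promoter = 0.70, exon = 0.10, intron = 0.10, intergenic = 0.03,
              `5'UTR` = 0.05, `3'UTR` = 0.02),
  BivProm = c(promoter = 0.65, exon = 0.10, intron = 0.10, intergenic = 0.05,
              `5'UTR` = 0.08, `3'UTR` = 0.02),
  PRC2    = c(promoter = 0.40, exon = 0.10, intron = 0.20, intergenic = 0.20,
              `5'UTR` = 0.05, `3'UTR` = 0.05),
  Enh     = c(promoter = 0.10, exon = 0.10, intron = 0.40, intergenic = 0.30,
              `5'UTR` = 0.05, `3'UTR` = 0.05),
  Tx      = c(promoter = 0.05, exon = 0.35, intron = 0.40, intergenic = 0.05,
              `5'UTR` = 0.05, `3'UTR` = 0.10),
  HET     = c(promoter = 0.02, exon = 0.05, intron = 0.20, intergenic = 0.70,
              `5'UTR` = 0.01, `3'UTR` = 0.02),
  Quies   = c(promoter = 0.02, exon = 0.05, intron = 0.26, intergenic = 0.65,
              `5'UTR` = 0.01, `3'UTR` = 0.01))

#' Specify a synthetic aging-methylome cohort
#'
#' Bundles every knob of the generator into a validated design object. The
#' defaults emulate the study design the package targets: a rat hippocampus
#' cohort of 6 young (3.5 months), 6 old control and 8 old treated animals
#' (25.3 months), with age-dependent methylation gain in bivalent/TSS/PRC2
#' and island CpGs, loss in heterochromatin/quiescent and intergenic CpGs,
#' and a treatment that reverses a fraction of the age-affected CpGs.
#'
#' @param n_cpgs number of CpGs to simulate.
#' @param state_proportions named fractions over the chromatin-state
#'   vocabulary; must sum to 1.
#' @param group_sizes named counts for `young`, `old_control`, `old_treated`
#'   (each >= 2).
#' @param age_young,age_old group ages in years.
#' @param age_effect_fraction fraction of CpGs carrying a true age effect.
#' @param delta_age absolute age effect size per affected CpG, on the
#'   logit-beta scale over the full young-to-old age span.
#' @param reversal_fraction fraction of age-affected CpGs whose age effect
#'   the treatment reverses.
#' @param reversal_strength fraction of the (old-age) age effect removed in
#'   treated samples at reversed CpGs; 1 restores the young expectation.
#' @param noise_sd standard deviation of logit-scale measurement noise.
#' @param species species label for the sample sheet.
#' @param max_lifespan_years species maximum lifespan (rat: 3.8 years).
#' @param seed integer seed; the generator is fully deterministic given the
#'   design.
#' @return a `simulation_design` list.
#' @export
simulation_design <- function(n_cpgs = 5000,
                              state_proportions = default_state_proportions,
                              group_sizes = c(young = 6, old_control = 6,
                                              old_treated = 8),
                              age_young = 3.5 / 12,
                              age_old = 25.3 / 12,
                              age_effect_fraction = 0.2,
                              delta_age = 1.0,
                              reversal_fraction = 0.6,
                              reversal_strength = 1.0,
                              noise_sd = 0.15,
                              species = "rat",
                              max_lifespan_years = 3.8,
                              seed = 1L) {
  if (!is_count(n_cpgs) || n_cpgs < 1) abort("n_cpgs must be a positive count")
  if (is.null(names(state_proportions)) ||
      !all(names(state_proportions) %in% STATE_LEVELS))
    abort("state_proportions names must be a subset of: %s",
          paste(STATE_LEVELS, collapse = ", "))
  if (abs(sum(state_proportions) - 1) > 1e-9)
    abort("state_proportions must sum to 1 (got %.12g)",
          sum(state_proportions))
  if (!all(GROUP_LEVELS %in% names(group_sizes)))
    abort("group_sizes needs entries for %s", paste(GROUP_LEVELS, collapse = ", "))
  if (any(group_sizes[GROUP_LEVELS] < 2))
    abort("every group size must be >= 2")
  fr <- c(age_effect_fraction, reversal_fraction, reversal_strength)
  if (any(fr < 0 | fr > 1)) abort("fractions must lie in [0, 1]")
  if (age_old <= age_young) abort("age_old must exceed age_young")
  if (noise_sd < 0) abort("noise_sd must be non-negative")
  if (max_lifespan_years <= age_old)
    abort("max_lifespan_years must exceed age_old")
  structure(list(n_cpgs = as.integer(n_cpgs),
                 state_proportions = state_proportions,
                 group_sizes = group_sizes[GROUP_LEVELS],
                 age_young = age_young, age_old = age_old,
                 age_effect_fraction = age_effect_fraction,
                 delta_age = delta_age,
                 reversal_fraction = reversal_fraction,
                 reversal_strength = reversal_strength,
                 noise_sd = noise_sd, species = species,
                 max_lifespan_years = max_lifespan_years,
                 seed = as.integer(seed)),
            class = "simulation_design")
}

#' Simulate a CpG annotation
#'
#' Draws chromatin states from the design's proportions, then island flags
#' and region classes from state-conditional probabilities (bivalent/TSS
#' chromatin enriched for islands and promoters; heterochromatin/quiescent
#' for intergenic positions). Coordinates, synthetic gene symbols and signed
#' TSS distances are assigned deterministically from the seed.
#'
#' @param design a [simulation_design()].
#' @param seed overrides `design$seed` when given.
#' @return a `cpg_annotation` data.frame with `design$n_cpgs` rows.
#' @export
simulate_annotation <- function(design, seed = design$seed) {
  stopifnot(inherits(design, "simulation_design"))
  set.seed(seed)
  n <- design$n_cpgs
  props <- design$state_proportions
  state <- sample(names(props), n, replace = TRUE, prob = props)
  island <- runif(n) < ISLAND_PROB[state]
  region <- vapply(state, function(s)
    sample(colnames(REGION_PROB), 1L, prob = REGION_PROB[s, ]), character(1))
  chrom <- paste0("chr", sample(1:20, n, replace = TRUE))
  start <- sample.int(1e8L, n, replace = TRUE)
  # TSS distance scale depends on region: promoters hug the TSS,
  # intergenic CpGs sit tens of kb away
  scale_bp <- c(promoter = 600, exon = 8000, intron = 15000,
                intergenic = 120000, `5'UTR` = 400, `3'UTR` = 12000)
  tss <- round(rnorm(n, 0, scale_bp[region]))
  gene <- sprintf("GENE%05d", sample.int(max(50L, n %/% 10L), n, replace = TRUE))
  validate_cpg_annotation(data.frame(
    cpg_id = sprintf("cg%06d", seq_len(n)),
    chrom = chrom, start = start, end = start + 2L,
    nearest_gene = gene, tss_distance = as.integer(tss),
    region_class = unname(region), island = unname(island),
    chromatin_state = state))
}

# contextual age direction: +1 gain, -1 loss, 0 neutral
age_direction_for <- function(ann) {
  gain <- ann$chromatin_state %in% GAIN_STATES | ann$island
  loss <- !gain & (ann$chromatin_state %in% LOSS_STATES |
                     ann$region_class == "intergenic")
  ifelse(gain, 1L, ifelse(loss, -1L, 0L))
}

#' Simulate a methylation cohort with planted aging and reversal effects
#'
#' Generative model on the logit-beta scale, for CpG j and sample i:
#' \deqn{logit(\beta_{ij}) = m_j + a_j A'_i + r_j T_i + \epsilon_{ij}}
#' where \eqn{A'_i} is age standardized to \[0,1\] over the young-to-old
#' span, \eqn{T_i} indicates the treated group, \eqn{\epsilon \sim
#' N(0, noise\_sd)}, and \eqn{a_j = \pm\delta} for age-affected CpGs with the
#' sign set by chromatin context (gain in BivProm/TSS/PRC2 or island CpGs,
#' loss in HET/Quies or intergenic CpGs). For reversed CpGs
#' \eqn{r_j = -reversal\_strength \cdot a_j} (the age effect at old age),
#' otherwise 0. Betas are clipped to \[0.001, 0.999\].
#'
#' Age-affected CpGs are drawn from the CpGs whose context gives them a
#' nonzero direction, so `age_effect_fraction * n_cpgs` is the exact number
#' of causal CpGs (an error is raised if the context rule leaves too few
#' eligible CpGs).
#'
#' CpG-level truth (baseline methylation, the causal set and the reversed
#' set) is seeded by `design$seed`, while animal-level noise is seeded by
#' `cohort_seed`: two cohorts simulated from the same design with different
#' `cohort_seed`s are independent animals measured on the *same* CpGs, which
#' is what training a clock on one cohort and applying it to another
#' requires.
#'
#' @param design a [simulation_design()].
#' @param annotation optionally, a pre-built annotation for the same design;
#'   defaults to `simulate_annotation(design)`.
#' @param cohort_seed seed for the animal-level draws (defaults to
#'   `design$seed`, making the full output a pure function of the design).
#' @return list with `beta` (matrix), `sample_sheet`, `truth` (data.frame:
#'   `cpg_id`, `has_age_effect`, `age_direction`, `is_reversed`) and
#'   `annotation`.
#' @export
simulate_cohort <- function(design, annotation = NULL,
                            cohort_seed = design$seed) {
  stopifnot(inherits(design, "simulation_design"))
  if (is.null(annotation)) annotation <- simulate_annotation(design)
  stopifnot(nrow(annotation) == design$n_cpgs)
  set.seed(design$seed + 1L)
  n <- design$n_cpgs
  gs <- design$group_sizes

  sheet <- validate_sample_sheet(data.frame(
    sample_id = c(sprintf("Y%02d", seq_len(gs["young"])),
                  sprintf("C%02d", seq_len(gs["old_control"])),
                  sprintf("T%02d", seq_len(gs["old_treated"]))),
    age_years = rep(c(design$age_young, design$age_old, design$age_old), gs),
    group = rep(GROUP_LEVELS, gs),
    species = design$species,
    max_lifespan_years = design$max_lifespan_years))

  dir <- age_direction_for(annotation)
  n_causal <- round(design$age_effect_fraction * n)
  eligible <- which(dir != 0L)
  if (length(eligible) < n_causal)
    abort("only %d CpGs are eligible for an age effect; %d requested",
          length(eligible), n_causal)
  causal <- sort(sample(eligible, n_causal))
  a <- numeric(n)
  a[causal] <- design$delta_age * dir[causal]
  reversed <- sort(sample(causal, round(design$reversal_fraction * n_causal)))
  r <- numeric(n)
  r[reversed] <- -design$reversal_strength * a[reversed]

  m <- rnorm(n, 0, 1)

  age_std <- (sheet$age_years - design$age_young) /
    (design$age_old - design$age_young)
  treated <- as.numeric(sheet$group == "old_treated")

  set.seed(cohort_seed + 2L)
  eta <- outer(m, rep(1, nrow(sheet))) + outer(a, age_std) +
    outer(r, treated)
  if (design$noise_sd > 0)
    eta <- eta + matrix(rnorm(length(eta), 0, design$noise_sd), nrow = n)
  beta <- pmin(pmax(plogis(eta), 0.001), 0.999)
  dimnames(beta) <- list(annotation$cpg_id, sheet$sample_id)

  truth <- data.frame(
    cpg_id = annotation$cpg_id,
    has_age_effect = a != 0,
    age_direction = ifelse(a > 0, "gain", ifelse(a < 0, "loss", "none")),
    is_reversed = r != 0)

  list(beta = validate_beta_matrix(beta), sample_sheet = sheet,
       truth = truth, annotation = annotation)
}
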