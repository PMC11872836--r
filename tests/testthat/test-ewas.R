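ewas_sheet <- function(n_young = 6, n_ctrl = 6, n_trt = 8) {
  validate_sample_sheet(data.frame(
    sample_id = c(sprintf("y%d", seq_len(n_young)),
                  sprintf("c%d", seq_len(n_ctrl)),
                  sprintf("t%d", seq_len(n_trt))),
    age_years = rep(c(0.3, 2.1, 2.1), c(n_young, n_ctrl, n_trt)),
    group = rep(c("young", "old_control", "old_treated"),
                c(n_young, n_ctrl, n_trt)),
    species = "rat", max_lifespan_years = 3.8))
}

test_that("ewas_scan matches a per-CpG cor.test oracle", {
  set.seed(21)
  sheet <- ewas_sheet()
  beta <- matrix(runif(50 * 20), nrow = 50,
                 dimnames = list(sprintf("cg%02d", 1:50), sheet$sample_id))
  for (ctr in c("age", "treatment")) {
    scan <- ewas_scan(beta, sheet, ctr)
    keep <- if (ctr == "age") sheet$group %in% c("young", "old_control")
            else sheet$group %in% c("old_control", "old_treated")
    x <- if (ctr == "age") as.numeric(sheet$group[keep] == "old_control")
         else as.numeric(sheet$group[keep] == "old_treated")
    for (j in c(1, 17, 50)) {
      ct <- cor.test(beta[j, keep], x)
      expect_equal(scan$r[j], unname(ct$estimate), tolerance = 1e-12)
      expect_equal(scan$p[j], ct$p.value, tolerance = 1e-12)
      expect_equal(scan$z[j],
                   sign(scan$r[j]) * qnorm(1 - ct$p.value / 2),
                   tolerance = 1e-10)
    }
  }
})

test_that("the r -> t -> p -> z mapping agrees with the reference CDFs", {
  sheet <- ewas_sheet(6, 6, 2)
  set.seed(8)
  beta <- matrix(runif(20 * 12), nrow = 20,
                 dimnames = list(sprintf("cg%02d", 1:20), sheet$sample_id[1:12]))
  scan <- ewas_scan(beta, sheet, "age")
  t_ref <- scan$r * sqrt(12 - 2) / sqrt(1 - scan$r^2)
  expect_equal(scan$t, t_ref, tolerance = 1e-12)
  expect_equal(scan$p, 2 * pt(abs(t_ref), 10, lower.tail = FALSE),
               tolerance = 1e-12)
  # the specific r = 0.5 point: t = 1.8257, p = 0.09785, z = 1.6553 (frozen)
  t5 <- 0.5 * sqrt(10) / sqrt(0.75)
  expect_equal(t5, 1.8257418584, tolerance = 1e-9)
  expect_equal(2 * pt(t5, 10, lower.tail = FALSE), 0.0978546143,
               tolerance = 1e-9)
  expect_equal(qnorm(1 - 0.0978546143 / 2), 1.6553446125, tolerance = 1e-8)
})

test_that("zero-variance CpGs follow the degenerate policy", {
  sheet <- ewas_sheet()
  beta <- matrix(runif(3 * 20), nrow = 3,
                 dimnames = list(c("cg1", "cgflat", "cg3"), sheet$sample_id))
  beta["cgflat", ] <- 0.4
  expect_message(scan <- ewas_scan(beta, sheet, "age"), "1 zero-variance")
  i <- which(scan$cpg_id == "cgflat")
  expect_equal(scan$r[i], 0)
  expect_equal(scan$p[i], 1)
  expect_equal(scan$z[i], 0)
  expect_true(is.na(scan$t[i]))
})

test_that("classification follows the sign logic and is symmetric", {
  expect_identical(classify_cpgs(3, -3, 0.01), "rejuvenated")
  expect_identical(classify_cpgs(3, 3, 0.01), "aggravated")
  expect_identical(classify_cpgs(3, -1, 0.01), "age_only")
  expect_identical(classify_cpgs(-1, 3, 0.01), "treat_only")
  expect_identical(classify_cpgs(1, -1, 0.01), "null")
  # boundary: |z| exactly at the threshold counts as significant
  zs <- qnorm(1 - 0.05 / 2)
  expect_identical(classify_cpgs(zs, 0, 0.05), "age_only")

  set.seed(31)
  za <- rnorm(500, sd = 2); zt <- rnorm(500, sd = 2)
  l1 <- classify_cpgs(za, zt, 0.01)
  l2 <- classify_cpgs(zt, za, 0.01)
  swap <- c(rejuvenated = "rejuvenated", aggravated = "aggravated",
            age_only = "treat_only", treat_only = "age_only", null = "null")
  expect_identical(unname(swap[l1]), l2)
})

test_that("overlap_summary equals a brute-force tally", {
  labs <- rep(c("rejuvenated", "aggravated", "age_only"), c(3, 1, 5))
  s <- overlap_summary(labs)
  expect_equal(unname(s["n_overlap"]), 4)
  expect_equal(unname(s["n_rejuvenated"]), 3)
  expect_equal(unname(s["n_age_significant"]), 9)
  expect_equal(unname(s["n_treat_significant"]), 4)

  expect_true(all(overlap_summary(character(0)) == 0))

  set.seed(5)
  labs <- sample(c("rejuvenated", "aggravated", "age_only", "treat_only",
                   "null"), 1000, replace = TRUE)
  s <- overlap_summary(labs)
  expect_equal(unname(s["n_rejuvenated"]), sum(labs == "rejuvenated"))
  expect_equal(unname(s["n_overlap"]),
               sum(labs %in% c("rejuvenated", "aggravated")))
  expect_equal(unname(s["n_age_significant"]),
               sum(labs %in% c("rejuvenated", "aggravated", "age_only")))
})

test_that("reversal_correlation behaves at its limits and under the null", {
  z <- rnorm(100)
  expect_equal(reversal_correlation(z, -z)$r, -1)
  set.seed(77)
  za <- rnorm(10000); zt <- rnorm(10000)
  expect_lt(abs(reversal_correlation(za, zt)$r), 0.05)
  expect_error(reversal_correlation(1:2, 2:1), "at least 3")
})

test_that("the permutation reversal test is calibrated where the naive p is not", {
  d <- tiny_design(n_cpgs = 1000, reversal_fraction = 0, seed = 55)
  co <- simulate_cohort(d)
  pt1 <- reversal_permutation_test(co$beta, co$sample_sheet, seed = 1)
  pt2 <- reversal_permutation_test(co$beta, co$sample_sheet, seed = 1)
  expect_identical(pt1, pt2)
  # the shared-control artifact: permuted correlations are themselves
  # negative on average, and the observed r sits inside that null
  expect_lt(pt1$null_mean, -0.1)
  expect_gt(pt1$p, 0.05)
  expect_lt(pt1$p_naive, 0.05)  # the naive p is fooled by the artifact

  # with a real planted reversal the observed r falls below every permutation
  d2 <- tiny_design(n_cpgs = 1000, reversal_fraction = 0.6, seed = 55)
  co2 <- simulate_cohort(d2)
  pt3 <- reversal_permutation_test(co2$beta, co2$sample_sheet, seed = 1)
  expect_equal(pt3$p, 1 / 200)
  expect_lt(pt3$r, pt1$r)
})

test_that("top_hits orders by p with the documented positional tie-break", {
  ann <- validate_cpg_annotation(data.frame(
    cpg_id = c("cgA", "cgB", "cgC", "cgD"),
    chrom = c("chr2", "chr1", "chr1", "chr3"),
    start = c(100L, 500L, 200L, 50L), end = c(102L, 502L, 202L, 52L),
    nearest_gene = c("G1", "G2", "G3", "G4"),
    tss_distance = c(0L, -100L, 100L, 5L),
    region_class = "promoter", island = TRUE, chromatin_state = "TSS"))
  scan <- data.frame(cpg_id = c("cgA", "cgB", "cgC", "cgD"),
                     p = c(0.5, 0.01, 0.01, 0.2), z = c(1, -2, 2, 1))
  th <- top_hits(scan, ann, k = 3)
  # cgB and cgC tie at p = 0.01; chr1:200 (cgC) precedes chr1:500 (cgB)
  expect_identical(th$cpg_id, c("cgC", "cgB", "cgD"))
  expect_identical(th$direction, c("gain", "loss", "gain"))
  expect_identical(nrow(top_hits(scan, ann, k = 50)), 4L)
})

test_that("noiseless full reversal labels every reversed CpG rejuvenated", {
  d <- tiny_design(n_cpgs = 400, noise_sd = 0, reversal_fraction = 1,
                   reversal_strength = 1, seed = 13)
  co <- simulate_cohort(d)
  tab <- suppressMessages(ewas_table(co$beta, co$sample_sheet, alpha = 0.01))
  rev <- co$truth$is_reversed
  expect_true(all(tab$label[rev] == "rejuvenated"))
  # |z| grows as p shrinks (monotone transform at fixed sign)
  ord <- order(tab$p_age)
  expect_true(all(diff(abs(tab$z_age[ord])) <= 1e-9))
})
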