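test_that("relative_age matches the printed species constants and inverts", {
  expect_equal(relative_age(1.9, 3.8), 0.5)
  expect_equal(relative_age(0, 122), 0)
  expect_equal(relative_age(122, 122), 1.0)
  expect_error(relative_age(1, 0), "positive")
  ages <- runif(50, 0.01, 100)
  expect_equal(relative_age(ages, 7.3) * 7.3, ages)
})

make_linear_cohort <- function(n = 30, seed = 1) {
  set.seed(seed)
  ages <- runif(n, 1, 9)
  beta <- rbind(cg1 = ages / 10,
                matrix(runif(20 * n), nrow = 20,
                       dimnames = list(sprintf("cgN%02d", 1:20), NULL)))
  colnames(beta) <- sprintf("s%02d", seq_len(n))
  list(beta = beta, ages = ages)
}

test_that("fit_clock recovers an exact linear age signal", {
  d <- make_linear_cohort()
  m <- fit_clock(d$beta, d$ages, lambda = 1e-6, alpha = 0.5)
  preds <- apply_clock(m, d$beta)
  expect_gte(cor(preds, d$ages), 0.999)
  expect_lte(max(abs(preds - d$ages)), 0.01)
})

test_that("a dominating penalty collapses to the intercept-only model", {
  d <- make_linear_cohort()
  m <- fit_clock(d$beta, d$ages, lambda = 1e6, alpha = 0.5)
  expect_length(m$coefficients, 0L)
  expect_equal(unname(apply_clock(m, d$beta)),
               rep(mean(d$ages), ncol(d$beta)))
})

test_that("duplicating an informative CpG leaves predictions unchanged", {
  # exact prediction invariance holds for the lasso (the L1 penalty is
  # indifferent to how weight splits across identical columns); the ridge
  # component rewards splitting, so mixed penalties are only invariant in
  # the lambda -> 0 limit
  d <- make_linear_cohort()
  dup <- rbind(d$beta, cg1dup = d$beta["cg1", ])
  m1 <- fit_clock(d$beta, d$ages, lambda = 1e-3, alpha = 1, thresh = 1e-14)
  m2 <- fit_clock(dup, d$ages, lambda = 1e-3, alpha = 1, thresh = 1e-14)
  expect_equal(apply_clock(m2, dup), apply_clock(m1, d$beta),
               tolerance = 1e-6)
  m3 <- fit_clock(d$beta, d$ages, lambda = 1e-6, alpha = 0.5, thresh = 1e-14)
  m4 <- fit_clock(dup, d$ages, lambda = 1e-6, alpha = 0.5, thresh = 1e-14)
  expect_equal(apply_clock(m4, dup), apply_clock(m3, d$beta),
               tolerance = 1e-4)
})

test_that("constant CpGs are dropped with a message and lambda is checked", {
  d <- make_linear_cohort()
  withconst <- rbind(d$beta, cgconst = rep(0.5, ncol(d$beta)))
  expect_message(m <- fit_clock(withconst, d$ages, lambda = 1e-3),
                 "dropped 1 constant")
  expect_false("cgconst" %in% names(m$coefficients))
  expect_error(fit_clock(d$beta, d$ages, lambda = -1), "non-negative")
})

test_that("apply_clock does the transform arithmetic and reports missing CpGs", {
  beta <- matrix(c(0.5, 0.25), nrow = 1,
                 dimnames = list("cg1", c("s1", "s2")))
  m0 <- clock_model(intercept = 2.0)
  expect_equal(unname(apply_clock(m0, beta)), c(2, 2))

  m1 <- clock_model(intercept = 0, coefficients = c(cg1 = 1),
                    transform = "relative_age", max_lifespan_years = 3.8)
  expect_equal(apply_clock(m1, beta)[["s1"]], 1.9)

  m2 <- clock_model(intercept = 0, coefficients = c(cg1 = 1, cgX = 1, cgY = 2))
  expect_error(apply_clock(m2, beta), "lacks 2 clock CpG")
})

test_that("identity clocks are affine: mixtures average predictions", {
  d <- make_linear_cohort(seed = 3)
  m <- fit_clock(d$beta, d$ages, lambda = 1e-3)
  mix <- (d$beta[, 1] + d$beta[, 2]) / 2
  mixmat <- matrix(mix, ncol = 1, dimnames = list(rownames(d$beta), "mix"))
  p <- apply_clock(m, d$beta[, 1:2])
  expect_equal(unname(apply_clock(m, mixmat)), mean(p), tolerance = 1e-9)
})

test_that("compare_groups matches the Welch oracle and handles edge cases", {
  sheet <- validate_sample_sheet(data.frame(
    sample_id = c(sprintf("c%d", 1:6), sprintf("t%d", 1:8)),
    age_years = 2.1,
    group = rep(c("old_control", "old_treated"), c(6, 8)),
    species = "rat", max_lifespan_years = 3.8))
  ctrl <- c(2.0, 2.2, 2.1, 1.9, 2.3, 2.0)
  trt <- c(1.8, 1.7, 2.0, 1.6, 1.9, 1.8, 1.7, 2.1)
  preds <- setNames(c(ctrl, trt), sheet$sample_id)
  cmp <- compare_groups(preds, sheet)
  # frozen from an independent Welch computation
  expect_equal(cmp$t, -3.0673101585, tolerance = 1e-8)
  expect_equal(cmp$df, 11.5925763714, tolerance = 1e-8)
  expect_equal(cmp$two_sided_p, 0.0101266072, tolerance = 1e-7)
  expect_equal(cmp$one_sided_p, cmp$two_sided_p / 2)
  # and against stats::t.test directly
  tt <- t.test(trt, ctrl)
  expect_equal(cmp$t, unname(tt$statistic))
  expect_equal(cmp$two_sided_p, tt$p.value)

  # identical groups with internal variance: t = 0, two-sided p = 1
  preds2 <- setNames(c(1, 2, 3, 2, 2, 2, 1, 2, 3, 2, 2, 2, 2, 2),
                     sheet$sample_id)
  cmp2 <- compare_groups(preds2, sheet)
  expect_equal(cmp2$t, 0)
  expect_equal(cmp2$two_sided_p, 1)

  # near-complete separation
  preds3 <- setNames(c(1, 1, 1, 1, 1, 1,
                       0, 0, 0, 0, 0, 0, 1e-9, -1e-9), sheet$sample_id)
  expect_lt(compare_groups(preds3, sheet)$two_sided_p, 1e-6)

  # degenerate zero-variance groups error rather than returning NaN
  preds4 <- setNames(rep(c(1, 0), c(6, 8)), sheet$sample_id)
  expect_error(compare_groups(preds4, sheet), "zero variance")
})
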