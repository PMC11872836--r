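test_that("fisher_2x2 matches exhaustive enumeration and stats::fisher.test", {
  ft <- fisher_2x2(5, 5, 5, 5)
  expect_equal(ft$odds_ratio, 1)
  expect_equal(ft$p, 1)

  ft <- fisher_2x2(10, 0, 0, 10)
  expect_identical(ft$odds_ratio, Inf)
  expect_equal(ft$p, enum_fisher_p(10, 0, 0, 10), tolerance = 1e-12)

  ft <- fisher_2x2(1, 9, 11, 3)
  expect_equal(ft$odds_ratio, (1 * 3) / (9 * 11))
  expect_equal(ft$p, enum_fisher_p(1, 9, 11, 3), tolerance = 1e-12)

  set.seed(14)
  for (i in 1:25) {
    cells <- as.numeric(rmultinom(1, sample(8:30, 1), rep(0.25, 4)))
    if (sum(cells) == 0) next
    ours <- fisher_2x2(cells[1], cells[2], cells[3], cells[4])
    ref <- stats::fisher.test(matrix(cells, 2, byrow = TRUE))
    expect_equal(ours$p, ref$p.value, tolerance = 1e-9)
    expect_equal(ours$p, enum_fisher_p(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-12)
  }
  expect_error(fisher_2x2(0, 0, 0, 0), "all-zero")
})

test_that("fisher_2x2 is transpose-invariant and OR inverts under row swap", {
  set.seed(15)
  for (i in 1:10) {
    ab <- sample(0:15, 4, replace = TRUE)
    if (sum(ab) == 0) next
    f1 <- fisher_2x2(ab[1], ab[2], ab[3], ab[4])
    f2 <- fisher_2x2(ab[1], ab[3], ab[2], ab[4])  # transpose
    f3 <- fisher_2x2(ab[3], ab[4], ab[1], ab[2])  # row swap
    expect_equal(f1$p, f2$p, tolerance = 1e-12)
    expect_equal(f1$odds_ratio, f2$odds_ratio)
    if (is.finite(f1$odds_ratio) && f1$odds_ratio > 0)
      expect_equal(f3$odds_ratio, 1 / f1$odds_ratio)
  }
})

test_that("hypergeom_enrichment equals closed-form and enumerated tails", {
  expect_equal(hypergeom_enrichment(5, 5, 5, 10), 1 / 252, tolerance = 1e-12)
  expect_equal(hypergeom_enrichment(0, 8, 12, 30), 1)

  set.seed(16)
  for (i in 1:25) {
    N <- sample(5:30, 1)
    K <- sample(0:N, 1)
    n <- sample(0:N, 1)
    k <- sample(max(0, n + K - N):min(K, n), 1)
    expect_equal(hypergeom_enrichment(k, K, n, N),
                 enum_hyper_upper(k, K, n, N), tolerance = 1e-12)
    expect_equal(hypergeom_enrichment(k, K, n, N, tail = "lower"),
                 1 - enum_hyper_upper(k + 1, K, n, N), tolerance = 1e-12)
  }
  expect_error(hypergeom_enrichment(6, 5, 5, 10), "invalid")
})

test_that("TSS-position enrichment flags a planted promoter concentration", {
  ann <- simulate_annotation(tiny_design(n_cpgs = 3000, seed = 19))
  promoter_bin <- ann$cpg_id[ann$tss_distance > -1000 & ann$tss_distance <= 0]
  hits <- promoter_bin[seq_len(min(80, length(promoter_bin)))]
  res <- tss_position_enrichment(hits, ann)
  hot <- res[res$bin == "(-1e+03,0]", ]
  expect_gt(hot$odds_ratio, 1)
  expect_lt(hot$p, 0.001)
  expect_true(all(res$p > 0 & res$p <= 1))
  expect_error(tss_position_enrichment("cg_not_there", ann), "background")
})

test_that("significance stars follow the threshold table", {
  expect_identical(p_stars(c(0.04, 0.004, 4e-4, 4e-5, 0.2)),
                   c("*", "**", "***", "****", ""))
})

test_that("island comparison matches the shared Welch machinery", {
  set.seed(20)
  z <- rnorm(1000)
  island <- rep(c(TRUE, FALSE), 500)
  res <- island_status_comparison(z, island)
  tt <- t.test(z[island], z[!island])
  expect_equal(res$t, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(res$p, tt$p.value, tolerance = 1e-12)
  expect_lt(abs(res$t), 3)

  # a planted +1 shift in islands is overwhelmingly detectable
  z2 <- c(rnorm(500, 1), rnorm(500, 0))
  expect_lt(island_status_comparison(z2, rep(c(TRUE, FALSE), each = 500))$p,
            1e-10)
})

test_that("state enrichment detects planted hits and is flat on full sets", {
  ann <- simulate_annotation(tiny_design(n_cpgs = 2000, seed = 23))
  biv <- ann$cpg_id[ann$chromatin_state == "BivProm"]
  res <- state_enrichment(head(biv, 50), ann)
  expect_lt(res$p[res$state == "BivProm"], 0.01)
  expect_identical(res$tail[res$state == "BivProm"], "upper")
  expect_identical(res$tail[res$state == "Quies"], "lower")

  res_all <- state_enrichment(ann$cpg_id, ann)
  expect_true(all(res_all$fold == 1))

  # tiny background agrees with the enumeration oracle
  small <- ann[1:20, ]
  hits <- small$cpg_id[c(1, 3, 5, 7)]
  res_s <- state_enrichment(hits, small)
  for (i in seq_len(nrow(res_s))) {
    k <- res_s$n_hits[i]; K <- res_s$n_state[i]
    if (res_s$tail[i] == "upper")
      expect_equal(res_s$p[i], enum_hyper_upper(k, K, 4, 20),
                   tolerance = 1e-12)
    else
      expect_equal(res_s$p[i], 1 - enum_hyper_upper(k + 1, K, 4, 20),
                   tolerance = 1e-12)
  }
})
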