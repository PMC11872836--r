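#' Fisher's exact test for a 2x2 table
#'
#' Odds ratio is the sample cross-product `(a*d)/(b*c)` (reported as `Inf`
#' when `b*c = 0` with `a*d > 0`). The two-sided p-value is computed by
#' summing, over the hypergeometric distribution with the table's margins,
#' the probabilities of all tables no more likely than the observed one.
#'
#' @param a,b,c,d non-negative integer cell counts, laid out as
#'   rows = condition 1/2, columns = outcome 1/2 (`a` = row 1, col 1).
#' @return list with `odds_ratio` and `p`.
#' @export
#' @examples
#' fisher_2x2(5, 5, 5, 5)  # OR 1, p 1
fisher_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells)))
    abort("cells must be non-negative integers")
  if (sum(cells) == 0) abort("all-zero 2x2 table")
  odds_ratio <- if (b * c == 0) {
    if (a * d > 0) Inf else NaN
  } else (a * d) / (b * c)

  m <- a + b          # row-1 total
  n2 <- c + d         # row-2 total
  k <- a + c          # column-1 total
  support <- max(0, k - n2):min(k, m)
  probs <- stats::dhyper(support, m, n2, k)
  p_obs <- stats::dhyper(a, m, n2, k)
  p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  list(odds_ratio = odds_ratio, p = p)
}

#' Hypergeometric enrichment test
#'
#' `P[X >= k]` for `X ~ Hypergeom(N, K, n)`: drawing `n` hits from a
#' background of `N` CpGs of which `K` belong to the category. Depletion is
#' assessed with the lower tail `P[X <= k]`.
#'
#' @param k observed hits in the category.
#' @param K category size in the background.
#' @param n number of hits drawn.
#' @param N background size.
#' @param tail `"upper"` (enrichment, default) or `"lower"` (depletion).
#' @return tail probability.
#' @export
#' @examples
#' hypergeom_enrichment(5, 5, 5, 10)  # 1/252
hypergeom_enrichment <- function(k, K, n, N, tail = c("upper", "lower")) {
  tail <- match.arg(tail)
  stopifnot(k >= 0, K >= 0, n >= 0, N >= 0)
  if (k > min(K, n) || n > N || K > N)
    abort("invalid hypergeometric parameters (need k <= min(K, n), n <= N, K <= N)")
  if (tail == "upper")
    stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  else
    stats::phyper(k, K, N - K, n, lower.tail = TRUE)
}

default_tss_breaks <- c(-Inf, -50e3, -5e3, -1e3, 0, 1e3, 5e3, 50e3, Inf)

#' TSS-position enrichment of EWAS hits
#'
#' Bins the signed TSS distance of every background CpG, and tests each bin
#' with a 2x2 Fisher exact test of (hit vs non-hit) x (in-bin vs
#' out-of-bin). The background is the full set of scanned CpGs carried by
#' `annotation`.
#'
#' @param hits character vector of hit CpG ids (one methylation direction).
#' @param annotation validated CpG annotation of all scanned CpGs.
#' @param breaks bin edges in bp over the TSS-distance axis (default eight
#'   bins from -50 kb to +50 kb and beyond).
#' @return data.frame per bin: `bin`, `n_hits`, `n_background`,
#'   `odds_ratio`, `p`, `stars`.
#' @export
tss_position_enrichment <- function(hits, annotation,
                                    breaks = default_tss_breaks) {
  annotation <- validate_cpg_annotation(annotation)
  if (!all(hits %in% annotation$cpg_id))
    abort("every hit must be present in the annotation background")
  is_hit <- annotation$cpg_id %in% hits
  bin <- cut(annotation$tss_distance, breaks = breaks, right = TRUE)
  res <- lapply(levels(bin), function(bl) {
    inb <- !is.na(bin) & bin == bl
    ft <- fisher_2x2(sum(is_hit & inb), sum(is_hit & !inb),
                     sum(!is_hit & inb), sum(!is_hit & !inb))
    data.frame(bin = bl, n_hits = sum(is_hit & inb),
               n_background = sum(inb),
               odds_ratio = ft$odds_ratio, p = ft$p, stars = p_stars(ft$p))
  })
  do.call(rbind, res)
}

#' Compare EWAS Z-statistics by CpG-island status
#'
#' Welch two-sample t-test of signed Z between island and non-island CpGs;
#' a positive mean difference means island CpGs carry larger (more
#' methylation-gaining) statistics.
#'
#' @param z numeric vector of signed Z-statistics.
#' @param island logical vector of the same length.
#' @return list with `mean_diff` (island minus non-island), `t`, `df`, `p`,
#'   and group sizes.
#' @export
island_status_comparison <- function(z, island) {
  stopifnot(length(z) == length(island), is.logical(island))
  if (sum(island) < 2L || sum(!island) < 2L)
    abort("need >= 2 island and >= 2 non-island CpGs")
  w <- welch_test(z[island], z[!island])
  list(mean_diff = w$mean_diff, t = w$t, df = w$df, p = w$p,
       n_island = sum(island), n_other = sum(!island))
}

#' Chromatin-state enrichment of EWAS hits
#'
#' For every chromatin state, a hypergeometric test of hit membership
#' against the scanned background: `N` background CpGs, `K` in the state,
#' `n` hits, `k` hits in the state. Fold is the ratio of hit to background
#' state fractions; states with fold >= 1 are tested for enrichment (upper
#' tail), the rest for depletion (lower tail).
#'
#' @param hits character vector of hit CpG ids (one methylation direction).
#' @param annotation validated CpG annotation of all scanned CpGs.
#' @return data.frame per state: `state`, `n_hits`, `n_state`, `fold`, `p`,
#'   `tail`, `stars`.
#' @export
state_enrichment <- function(hits, annotation) {
  annotation <- validate_cpg_annotation(annotation)
  if (!all(hits %in% annotation$cpg_id))
    abort("every hit must be present in the annotation background")
  if (length(hits) == 0L) abort("empty hit set")
  N <- nrow(annotation)
  n <- length(hits)
  is_hit <- annotation$cpg_id %in% hits
  states <- sort(unique(annotation$chromatin_state))
  res <- lapply(states, function(s) {
    ins <- annotation$chromatin_state == s
    K <- sum(ins); k <- sum(ins & is_hit)
    fold <- (k / n) / (K / N)
    tail <- if (fold >= 1) "upper" else "lower"
    p <- hypergeom_enrichment(k, K, n, N, tail = tail)
    data.frame(state = s, n_hits = k, n_state = K, fold = fold, p = p,
               tail = tail, stars = p_stars(p))
  })
  do.call(rbind, res)
}
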