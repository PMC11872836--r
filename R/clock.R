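#' Construct an epigenetic clock model
#'
#' An epigenetic clock is an affine function of beta values,
#' `score = intercept + sum_j w_j beta_j`, followed by an output transform:
#' `identity` (score is age in years) or `relative_age` (score is
#' age / maximum species lifespan; predictions are mapped back to years by
#' multiplying with `max_lifespan_years`).
#'
#' @param intercept numeric scalar, in transformed-age units.
#' @param coefficients named numeric vector of CpG weights (sparse: only
#'   nonzero terms need be present).
#' @param transform `"identity"` or `"relative_age"`.
#' @param max_lifespan_years species maximum lifespan in years; required iff
#'   `transform = "relative_age"`.
#' @return object of class `clock_model`.
#' @export
clock_model <- function(intercept, coefficients = numeric(0),
                        transform = c("identity", "relative_age"),
                        max_lifespan_years = NULL) {
  transform <- match.arg(transform)
  if (!is.numeric(intercept) || length(intercept) != 1L || !is.finite(intercept))
    abort("intercept must be a finite scalar")
  if (length(coefficients)) {
    if (is.null(names(coefficients)) || anyDuplicated(names(coefficients)))
      abort("coefficients must be uniquely named by CpG id")
    coefficients <- coefficients[coefficients != 0]
  }
  if (transform == "relative_age") {
    if (is.null(max_lifespan_years) || max_lifespan_years <= 0)
      abort("relative_age transform requires max_lifespan_years > 0")
  }
  structure(list(intercept = intercept, coefficients = coefficients,
                 transform = transform,
                 max_lifespan_years = max_lifespan_years),
            class = "clock_model")
}

#' @export
print.clock_model <- function(x, ...) {
  cat(sprintf("<clock_model> %s transform, %d CpG coefficients\n",
              x$transform, length(x$coefficients)))
  cat(sprintf("  intercept: %.6g", x$intercept))
  if (!is.null(x$max_lifespan_years))
    cat(sprintf("  max lifespan: %.3g years", x$max_lifespan_years))
  cat("\n")
  invisible(x)
}

#' Relative age transform
#'
#' Relative age is chronological age divided by the maximum lifespan of the
#' species (122 years for humans, 3.8 years for rats), putting species on a
#' shared \[0, 1\] scale so one clock can serve several of them.
#'
#' @param age age in years, non-negative.
#' @param max_lifespan species maximum lifespan in years, positive.
#' @return `age / max_lifespan`.
#' @export
#' @examples
#' relative_age(1.9, 3.8)  # 0.5
relative_age <- function(age, max_lifespan) {
  if (any(max_lifespan <= 0)) abort("max_lifespan must be positive")
  if (any(age < 0)) abort("age must be non-negative")
  age / max_lifespan
}

#' Train an elastic-net epigenetic clock
#'
#' Fits the penalized regression
#' \deqn{\min_{b_0, w} \frac{1}{2n}\sum_i (y_i - b_0 - \sum_j w_j x_{ij})^2
#'   + \lambda [\alpha \|w\|_1 + \tfrac{1-\alpha}{2} \|w\|_2^2]}
#' of transformed age on beta values (unstandardized predictors: betas
#' already share the \[0,1\] scale). When `lambda` is `NULL` it is chosen by
#' seeded k-fold cross-validation. Constant CpG rows are dropped with a
#' message. The fit is deterministic given its arguments.
#'
#' @param beta CpG x sample matrix of betas.
#' @param ages numeric vector of chronological ages (years), one per column.
#' @param transform output transform, see [clock_model()].
#' @param max_lifespan_years required for `relative_age`.
#' @param lambda penalty; `NULL` for cross-validated choice.
#' @param alpha elastic-net mixing (1 = lasso, 0 = ridge).
#' @param nfolds folds for the internal cross-validation.
#' @param seed seed controlling fold assignment.
#' @param ... further arguments for [glmnet::glmnet()] (e.g. `thresh` to
#'   tighten coordinate-descent convergence).
#' @return a [clock_model()].
#' @export
fit_clock <- function(beta, ages, transform = c("identity", "relative_age"),
                      max_lifespan_years = NULL, lambda = NULL, alpha = 0.5,
                      nfolds = 5, seed = 1L, ...) {
  transform <- match.arg(transform)
  beta <- validate_beta_matrix(beta)
  if (length(ages) != ncol(beta))
    abort("ages length (%d) must match sample count (%d)",
          length(ages), ncol(beta))
  if (ncol(beta) < 4L) abort("need at least 4 samples to fit a clock")
  if (any(!is.finite(ages))) abort("ages must be finite")
  if (!is.null(lambda) && lambda < 0) abort("lambda must be non-negative")

  y <- if (transform == "relative_age") {
    if (is.null(max_lifespan_years)) abort("relative_age needs max_lifespan_years")
    relative_age(ages, max_lifespan_years)
  } else ages

  x <- t(beta)
  const <- apply(x, 2L, function(v) diff(range(v)) == 0)
  if (any(const)) {
    message(sprintf("dropped %d constant CpG(s) before fitting", sum(const)))
    x <- x[, !const, drop = FALSE]
  }
  if (ncol(x) < 1L) abort("no variable CpGs left to fit on")

  if (is.null(lambda)) {
    set.seed(seed)
    foldid <- sample(rep_len(seq_len(nfolds), nrow(x)))
    cv <- glmnet::cv.glmnet(x, y, alpha = alpha, standardize = FALSE,
                            foldid = foldid, ...)
    lambda <- cv$lambda.min
    fit <- cv$glmnet.fit
  } else {
    fit <- glmnet::glmnet(x, y, alpha = alpha, standardize = FALSE, ...)
  }
  cf <- as.matrix(glmnet::coef.glmnet(fit, s = lambda, exact = TRUE,
                                      x = x, y = y, alpha = alpha,
                                      standardize = FALSE, ...))
  w <- cf[-1, 1]
  w <- w[w != 0]
  clock_model(intercept = cf[1, 1], coefficients = w, transform = transform,
              max_lifespan_years = max_lifespan_years)
}

#' Apply an epigenetic clock to a beta matrix
#'
#' Computes the linear score for every sample and inverts the output
#' transform, returning DNAm age estimates in years. Every CpG carried by
#' the model must be present in the matrix.
#'
#' @param model a [clock_model()].
#' @param beta CpG x sample matrix.
#' @return named numeric vector of predicted ages (years).
#' @export
apply_clock <- function(model, beta) {
  stopifnot(inherits(model, "clock_model"))
  beta <- validate_beta_matrix(beta)
  need <- names(model$coefficients)
  missing <- setdiff(need, rownames(beta))
  if (length(missing))
    abort("matrix lacks %d clock CpG(s): %s%s", length(missing),
          paste(head(missing, 5), collapse = ", "),
          if (length(missing) > 5) ", ..." else "")
  score <- rep(model$intercept, ncol(beta))
  if (length(need))
    score <- score + drop(crossprod(beta[need, , drop = FALSE],
                                    model$coefficients))
  names(score) <- colnames(beta)
  if (model$transform == "relative_age")
    score <- score * model$max_lifespan_years
  score
}

#' Compare DNAm age between two groups
#'
#' Welch (unequal-variance) two-sample t-test of predicted ages, reporting
#' both the two-sided p-value and the one-sided p-value for the
#' pre-registered rejuvenation direction (first group's mean below the
#' second group's).
#'
#' @param predictions named numeric vector of DNAm ages (names = sample ids).
#' @param sample_sheet a validated sample sheet covering those samples.
#' @param contrast character of length 2: the hypothesized-lower group first
#'   (default `c("old_treated", "old_control")`).
#' @return object of class `group_comparison`: per-group n, mean, standard
#'   error, plus `t`, `df`, `two_sided_p`, `one_sided_p`.
#' @export
compare_groups <- function(predictions, sample_sheet,
                           contrast = c("old_treated", "old_control")) {
  sample_sheet <- validate_sample_sheet(sample_sheet)
  stopifnot(length(contrast) == 2L, all(contrast %in% GROUP_LEVELS))
  pick <- function(g) {
    ids <- sample_sheet$sample_id[sample_sheet$group == g]
    v <- predictions[intersect(names(predictions), ids)]
    if (length(v) < 2L) abort("group '%s' has fewer than 2 predictions", g)
    v
  }
  x <- pick(contrast[1]); y <- pick(contrast[2])
  if (sd(x) == 0 && sd(y) == 0)
    abort("both groups have zero variance; comparison undefined")
  w <- welch_test(x, y)
  one_sided <- if (w$mean_diff < 0) w$p / 2 else 1 - w$p / 2
  structure(list(groups = contrast, n = c(length(x), length(y)),
                 means = c(w$mean_x, w$mean_y),
                 se = c(sd(x) / sqrt(length(x)), sd(y) / sqrt(length(y))),
                 t = w$t, df = w$df, two_sided_p = w$p,
                 one_sided_p = one_sided),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s (n=%d, mean %.4g +/- %.3g SE) vs %s (n=%d, mean %.4g +/- %.3g SE)\n",
              x$groups[1], x$n[1], x$means[1], x$se[1],
              x$groups[2], x$n[2], x$means[2], x$se[2]))
  cat(sprintf("  Welch t = %.4g (df %.3g), two-sided p = %.4g, one-sided p = %.4g\n",
              x$t, x$df, x$two_sided_p, x$one_sided_p))
  invisible(x)
}
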