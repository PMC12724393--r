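# Statistical models for regional and age comparisons.
#
# The toolkit mirrors a typical mtDNA aging analysis: ordinary least squares
# with covariates, exponential (log-linear) regression on ln(metric + 0.01),
# rank-based regression with Wilcoxon scores for non-parametric group
# comparisons, Kruskal-Wallis with Dunn post hoc tests, Yates-corrected
# chi-squared for 2x2 tables, and Bonferroni multiplicity control.

.as_design <- function(design_terms) {
  design <- as.data.frame(design_terms)
  if (ncol(design) == 0L) stop("design has no terms", call. = FALSE)
  const <- vapply(design, function(x) {
    is.numeric(x) && length(unique(x)) == 1L
  }, logical(1))
  if (any(const)) {
    stop("constant design column(s) besides the intercept: ",
         paste(names(design)[const], collapse = ", "), call. = FALSE)
  }
  design
}

.regression_result <- function(coefficients, se, p, model_kind, n,
                               pseudo_count = NA_real_) {
  structure(
    list(coefficients = coefficients, standard_errors = se, p_values = p,
         model_kind = model_kind, n = n, pseudo_count = pseudo_count),
    class = "mt_regression"
  )
}

#' @export
print.mt_regression <- function(x, ...) {
  cat(x$model_kind, "regression, n =", x$n, "\n")
  print(data.frame(estimate = x$coefficients, se = x$standard_errors,
                   p = x$p_values))
  invisible(x)
}

#' Ordinary least squares with covariates
#'
#' Fits `response ~ .` over the design terms and reports per-coefficient
#' estimates, standard errors and two-sided t-test p-values. A constant
#' response is handled as the degenerate case: all slopes 0 with p = 1.
#'
#' @param response Numeric response vector.
#' @param design_terms Data.frame (or named list) of predictor columns.
#' @return An `mt_regression` with `model_kind = "ols"`.
#' @export
ols_fit <- function(response, design_terms) {
  design <- .as_design(design_terms)
  n <- length(response)
  if (n <= ncol(design)) {
    stop("need more observations than design terms", call. = FALSE)
  }
  if (stats::var(response) == 0) {
    est <- c("(Intercept)" = response[1L],
             stats::setNames(rep(0, ncol(design)), names(design)))
    se <- stats::setNames(rep(0, length(est)), names(est))
    p <- stats::setNames(c(0, rep(1, ncol(design))), names(est))
    return(.regression_result(est, se, p, "ols", n))
  }
  dat <- cbind(data.frame(.response = response), design)
  fit <- stats::lm(.response ~ ., data = dat)
  if (any(is.na(stats::coef(fit)))) {
    stop("rank-deficient design", call. = FALSE)
  }
  sm <- summary(fit)$coefficients
  .regression_result(sm[, 1L], sm[, 2L], sm[, 4L], "ols", n)
}

#' Exponential (log-linear) regression of a deletion metric on age
#'
#' Fits ordinary least squares on `ln(metric + pseudo_count)`, the standard
#' model for deletion burden growth with age. The small pseudo-count keeps
#' zero burdens finite.
#'
#' @param metric Non-negative metric vector (e.g. cumulative deletion
#'   read %).
#' @param age Age in years.
#' @param covariates Optional data.frame of additional covariate columns
#'   (e.g. benchmark coverage, sex).
#' @param pseudo_count Added inside the log (default 0.01).
#' @return An `mt_regression` with `model_kind = "log_linear"`; the age term
#'   is named `"age"`.
#' @export
exp_regression <- function(metric, age, covariates = NULL,
                           pseudo_count = 0.01) {
  if (any(metric < 0)) {
    stop("metric must be non-negative", call. = FALSE)
  }
  stopifnot(pseudo_count > 0)
  design <- data.frame(age = age)
  if (!is.null(covariates)) design <- cbind(design, as.data.frame(covariates))
  out <- ols_fit(log(metric + pseudo_count), design)
  out$model_kind <- "log_linear"
  out$pseudo_count <- pseudo_count
  out
}

#' Metric change across an age bin
#'
#' For an OLS fit the change over a bin is `slope * width`. For a log-linear
#' fit it is the difference of back-transformed predictions at the bin edges,
#' evaluated at a covariate profile:
#' `[exp(eta(age + width)) - pc] - [exp(eta(age)) - pc]`.
#'
#' @param result An `mt_regression` from [ols_fit()] or [exp_regression()].
#' @param age_start Left edge of the bin (years).
#' @param width Bin width in years (default 15).
#' @param covariate_profile Named list/vector of covariate values at which to
#'   evaluate a log-linear fit (every non-age, non-intercept term must be
#'   supplied; not used for plain OLS).
#' @return Metric change over the bin (same units as the metric).
#' @examples
#' fit <- ols_fit(c(1, 2, 3), data.frame(age = c(0, 1, 2)))
#' bin_delta(fit, 30)  # slope 1 * width 15
#' @export
bin_delta <- function(result, age_start, width = 15,
                      covariate_profile = NULL) {
  stopifnot(inherits(result, "mt_regression"))
  if (!result$model_kind %in% c("ols", "log_linear")) {
    stop("bin_delta requires an ols or log_linear fit", call. = FALSE)
  }
  if (result$model_kind == "ols") {
    return(unname(result$coefficients["age"]) * width)
  }
  terms <- setdiff(names(result$coefficients), c("(Intercept)", "age"))
  profile <- unlist(covariate_profile)
  missing <- setdiff(terms, names(profile))
  if (length(missing) > 0L) {
    stop("missing covariate values in profile: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  eta <- function(age) {
    unname(result$coefficients["(Intercept)"] +
             result$coefficients["age"] * age +
             if (length(terms) > 0L)
               sum(result$coefficients[terms] * profile[terms]) else 0)
  }
  exp(eta(age_start + width)) - exp(eta(age_start))
}

## ---------------------------------------------------------------------------
## rank-based (Wilcoxon-score) regression
## ---------------------------------------------------------------------------

# Jaeckel's dispersion with Wilcoxon scores a(i) = sqrt(12) (i/(n+1) - 1/2)
.jaeckel_dispersion <- function(beta, y, X) {
  e <- y - X %*% beta
  n <- length(e)
  a <- sqrt(12) * (rank(e, ties.method = "average") / (n + 1) - 0.5)
  sum(a * e)
}

# Koul-Sievers-McKean window estimate of the scale parameter tau for
# Wilcoxon scores: tau = 1 / (sqrt(12) * f_D(0)), with f_D the density of a
# pairwise residual difference at zero, estimated with a shrinking
# delta-quantile bandwidth and a degrees-of-freedom correction.
.ksm_tau <- function(residuals, p, delta = 0.8) {
  n <- length(residuals)
  d <- abs(outer(residuals, residuals, "-"))
  d <- d[upper.tri(d)]
  h <- stats::quantile(d, delta, names = FALSE) / n^(1 / 5)
  if (h <= 0) h <- max(d[d > 0], .Machine$double.eps)
  f0 <- mean(d <= h) / (2 * h)
  sqrt(n / (n - p - 1)) / (sqrt(12) * f0)
}

#' Rank-based regression with Wilcoxon scores
#'
#' Estimates slopes by minimising Jaeckel's dispersion of the residuals under
#' Wilcoxon scores, a non-parametric alternative to least squares that is
#' robust to outliers and skew. The intercept is the median of the residuals;
#' Wald p-values use the Koul-Sievers-McKean window estimate of the scale
#' parameter tau. With a single binary predictor the slope equals the
#' Hodges-Lehmann estimate of the two-group shift.
#'
#' @param response Numeric response vector (n >= 10).
#' @param design_terms Data.frame of predictor columns (at least one).
#' @return An `mt_regression` with `model_kind = "rank_based"`.
#' @export
rank_fit <- function(response, design_terms) {
  design <- .as_design(design_terms)
  y <- as.numeric(response)
  n <- length(y)
  if (n < 10L) stop("rank_fit requires n >= 10", call. = FALSE)
  X <- as.matrix(design)
  storage.mode(X) <- "double"
  p <- ncol(X)
  ls <- stats::lm.fit(cbind(1, X), y)
  start <- ls$coefficients[-1L]
  obj <- function(b) .jaeckel_dispersion(b, y, X)
  if (p == 1L) {
    # exact minimiser of the piecewise-linear dispersion: the weighted
    # median of pairwise slopes with weights |x_j - x_i| (Jaeckel's simple
    # regression solution; reduces to Hodges-Lehmann for a binary predictor)
    x <- X[, 1L]
    ij <- utils::combn(n, 2L)
    dx <- x[ij[2L, ]] - x[ij[1L, ]]
    keep <- dx != 0
    slopes <- (y[ij[2L, ]] - y[ij[1L, ]])[keep] / dx[keep]
    w <- abs(dx[keep])
    ord <- order(slopes)
    slopes <- slopes[ord]; w <- w[ord]
    cw <- cumsum(w); half <- sum(w) / 2
    l <- which(cw >= half - 1e-12)[1L]
    u <- which(cw > half + 1e-12)[1L]
    if (is.na(u)) u <- length(slopes)
    opt <- list(par = (slopes[l] + slopes[u]) / 2)
    opt$value <- obj(opt$par)
  } else {
    opt <- stats::optim(start, obj, method = "Nelder-Mead",
                        control = list(reltol = 1e-10, maxit = 5000L))
    opt <- stats::optim(opt$par, obj, method = "Nelder-Mead",
                        control = list(reltol = 1e-10, maxit = 5000L))
  }
  if (!is.finite(opt$value)) {
    stop("dispersion minimisation failed to converge", call. = FALSE)
  }
  beta <- opt$par
  e <- as.numeric(y - X %*% beta)
  alpha <- stats::median(e)
  tau <- .ksm_tau(e - alpha, p)
  Xc <- sweep(X, 2L, colMeans(X))
  cov_beta <- tau^2 * solve(crossprod(Xc))
  se_beta <- sqrt(diag(cov_beta))
  t_beta <- beta / se_beta
  p_beta <- 2 * stats::pt(-abs(t_beta), df = n - p - 1)
  est <- c("(Intercept)" = alpha, stats::setNames(beta, colnames(X)))
  se <- c("(Intercept)" = NA_real_, stats::setNames(se_beta, colnames(X)))
  pv <- c("(Intercept)" = NA_real_, stats::setNames(p_beta, colnames(X)))
  .regression_result(est, se, pv, "rank_based", n)
}

## ---------------------------------------------------------------------------
## group comparisons
## ---------------------------------------------------------------------------

#' Kruskal-Wallis test with Dunn's post hoc comparisons
#'
#' Computes the tie-corrected Kruskal-Wallis H statistic and all pairwise
#' Dunn z tests on the pooled ranks, with Bonferroni-adjusted pairwise
#' p-values.
#'
#' @param groups Named list of numeric vectors (>= 2 non-empty groups).
#' @return A `group_comparison`: list with `H_statistic`, `p_value`,
#'   `pairwise` (data.frame: `group_i`, `group_j`, `z`, `raw_p`,
#'   `adjusted_p`) and `adjustment = "bonferroni"`.
#' @export
kruskal_dunn <- function(groups) {
  if (length(groups) < 2L || any(lengths(groups) == 0L)) {
    stop("need at least two non-empty groups", call. = FALSE)
  }
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups) %||% seq_along(groups), lengths(groups)))
  N <- length(x)
  if (length(unique(x)) == 1L) {
    pairs <- utils::combn(levels(g), 2L)
    pairwise <- data.frame(group_i = pairs[1L, ], group_j = pairs[2L, ],
                           z = 0, raw_p = 1, adjusted_p = 1,
                           stringsAsFactors = FALSE)
    return(structure(list(H_statistic = 0, p_value = 1, pairwise = pairwise,
                          adjustment = "bonferroni"),
                     class = "group_comparison"))
  }
  kw <- stats::kruskal.test(x, g)
  r <- rank(x)
  tie_tab <- table(x)
  tie_term <- sum(tie_tab^3 - tie_tab) / (12 * (N - 1))
  mean_ranks <- tapply(r, g, mean)
  ns <- tapply(r, g, length)
  pairs <- utils::combn(levels(g), 2L)
  m <- ncol(pairs)
  z <- numeric(m); raw_p <- numeric(m)
  for (k in seq_len(m)) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    v <- (N * (N + 1) / 12 - tie_term) * (1 / ns[[i]] + 1 / ns[[j]])
    z[k] <- if (v > 0) (mean_ranks[[i]] - mean_ranks[[j]]) / sqrt(v) else 0
    raw_p[k] <- 2 * stats::pnorm(-abs(z[k]))
  }
  pairwise <- data.frame(group_i = pairs[1L, ], group_j = pairs[2L, ],
                         z = z, raw_p = raw_p,
                         adjusted_p = pmin(1, raw_p * m),
                         stringsAsFactors = FALSE)
  structure(
    list(H_statistic = unname(kw$statistic), p_value = kw$p.value,
         pairwise = pairwise, adjustment = "bonferroni"),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("Kruskal-Wallis H =", signif(x$H_statistic, 5),
      ", p =", signif(x$p_value, 4), "\n")
  print(x$pairwise)
  invisible(x)
}

#' Yates-corrected chi-squared test for a 2x2 table
#'
#' Pearson's chi-squared with continuity correction,
#' `sum((max(0, |O - E| - 0.5))^2 / E)`, compared against chi-squared with one
#' degree of freedom.
#'
#' @param table_2x2 2x2 matrix of non-negative counts with positive margins.
#' @return List with `statistic` and `p_value`.
#' @examples
#' chisq_yates(matrix(c(73, 9, 6, 12), nrow = 2))
#' @export
chisq_yates <- function(table_2x2) {
  m <- as.matrix(table_2x2)
  if (!all(dim(m) == c(2L, 2L)) || any(m < 0)) {
    stop("need a 2x2 table of non-negative counts", call. = FALSE)
  }
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("zero margin in 2x2 table", call. = FALSE)
  }
  ct <- suppressWarnings(stats::chisq.test(m, correct = TRUE))
  list(statistic = unname(ct$statistic), p_value = ct$p.value)
}

#' Bonferroni significance threshold
#'
#' @param alpha Family-wise error rate (0 < alpha <= 1).
#' @param m Number of tests (>= 1).
#' @return The per-test threshold `alpha / m`.
#' @examples
#' bonferroni(0.05, 38)  # genome-wide threshold for 38 tests
#' @export
bonferroni <- function(alpha, m) {
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]", call. = FALSE)
  if (m < 1) stop("m must be >= 1", call. = FALSE)
  alpha / m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
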