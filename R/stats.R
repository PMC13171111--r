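#' Cohen's d with pooled standard deviation
#'
#' Standardised mean difference `(mean(a) - mean(b)) / s_pooled` with
#' `s_pooled = sqrt(((n_a-1) s_a^2 + (n_b-1) s_b^2) / (n_a + n_b - 2))`.
#' No small-sample (Hedges) correction is applied; the sign follows
#' first-argument-minus-second, so `cohens_d(a, b) == -cohens_d(b, a)`.
#'
#' @param a,b Numeric samples, each with at least 2 values.
#' @return Scalar d. If the pooled SD is zero with unequal means, `Inf`
#'   with the sign of the mean difference is returned with a warning; zero
#'   pooled SD with equal means is an error (undefined).
#' @export
cohens_d <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L)
    stop("each sample needs at least 2 values")
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  diff <- mean(a) - mean(b)
  if (sp2 <= 0) {
    if (diff == 0) stop("Cohen's d undefined: both samples degenerate with equal means")
    warning("zero pooled SD with unequal means; reporting signed infinity")
    return(sign(diff) * Inf)
  }
  diff / sqrt(sp2)
}

#' Mann-Whitney U test (Wilcoxon rank-sum)
#'
#' Two-sample rank-sum test. The p-value is exact (permutation
#' distribution of the rank sum) when both samples have at most
#' `exact_max` observations and there are no ties; otherwise the normal
#' approximation with continuity and tie correction is used.
#'
#' @param a,b Non-empty numeric samples.
#' @param alternative One of "two.sided", "less", "greater".
#' @param exact_max Largest per-group size for which the exact distribution
#'   is used (default 8).
#' @return List with `U` (statistic for the first sample), `p`, and
#'   `method` ("exact" or "normal").
#' @export
mann_whitney_u <- function(a, b, alternative = "two.sided", exact_max = 8L) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0L || length(b) == 0L) stop("samples must be non-empty")
  ties <- anyDuplicated(c(a, b)) > 0L
  use_exact <- !ties && length(a) <= exact_max && length(b) <= exact_max
  wt <- suppressWarnings(
    wilcox.test(a, b, alternative = alternative,
                exact = use_exact, correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value,
       method = if (use_exact) "exact" else "normal")
}

#' Subsampled rank-test procedure
#'
#' With very large per-cell samples, raw rank-test p-values become
#' arbitrarily small; this procedure repeatedly subsamples a fixed number
#' of cells per group, runs the two-sided Mann-Whitney U test and Cohen's
#' d on each draw, and summarises the resulting distributions by their
#' medians. Default 200 iterations of 100 cells per group.
#'
#' @param a,b Numeric samples, each of length >= `n_per_group`.
#' @param n_iter Number of subsample iterations.
#' @param n_per_group Cells drawn (without replacement) per group per
#'   iteration.
#' @param seed Integer seed; the procedure is deterministic given it.
#' @return List of class `subsample_result`: `p_values`, `d_values`
#'   (length `n_iter`), `median_p`, `median_d`, `n_iter`, `n_per_group`,
#'   `seed`. d follows the first-minus-second sign convention.
#' @export
subsampled_test <- function(a, b, n_iter = 200L, n_per_group = 100L, seed = 1L) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < n_per_group || length(b) < n_per_group)
    stop("each group must have at least `n_per_group` observations")
  rng <- local_rng(seed)
  p_values <- numeric(n_iter)
  d_values <- numeric(n_iter)
  for (i in seq_len(n_iter)) {
    sa <- a[sample.int(length(a), n_per_group)]
    sb <- b[sample.int(length(b), n_per_group)]
    p_values[i] <- suppressWarnings(
      wilcox.test(sa, sb, exact = FALSE, correct = TRUE)$p.value)
    d_values[i] <- cohens_d(sa, sb)
  }
  rng()
  structure(list(p_values = p_values, d_values = d_values,
                 median_p = median(p_values), median_d = median(d_values),
                 n_iter = n_iter, n_per_group = n_per_group, seed = seed),
            class = "subsample_result")
}

#' Covariate-adjusted pairwise group contrasts
#'
#' Fits the linear model `response ~ group + covariate (+ averaging
#' factor)` and reports all pairwise group contrasts on covariate-adjusted
#' estimated marginal means, averaged over the levels of the averaging
#' factor. Each contrast carries its standard error, t statistic, Cohen's
#' d (adjusted mean difference over residual SD), a Tukey-adjusted p
#' (studentized-range, family = number of comparisons) and a Bonferroni-
#' adjusted p clamped to 1.
#'
#' @param table Data frame of per-cell features.
#' @param response Name of the numeric response column.
#' @param group Name of the grouping factor (e.g. age group).
#' @param covariate Optional name of a numeric covariate (e.g. nuclear
#'   area); `NULL` for a plain ANOVA-style comparison.
#' @param averaging Optional name of a factor whose levels are averaged
#'   over (e.g. brain area).
#' @return Data frame with one row per contrast: `group_a`, `group_b`,
#'   `mean_diff`, `se`, `t_stat`, `cohens_d`, `p_tukey`, `p_bonf`.
#' @export
adjusted_group_contrasts <- function(table, response, group,
                                     covariate = NULL, averaging = NULL) {
  stopifnot(is.data.frame(table))
  for (v in c(response, group, covariate, averaging))
    if (!v %in% names(table)) stop("column not found: ", v)
  df <- table
  df[[group]] <- factor(df[[group]])
  if (nlevels(df[[group]]) < 2L) stop("need at least 2 groups")
  if (any(tabulate(df[[group]]) < 2L)) stop("every group needs >= 2 rows")
  rhs <- group
  if (!is.null(covariate)) rhs <- paste(rhs, "+", covariate)
  if (!is.null(averaging)) {
    df[[averaging]] <- factor(df[[averaging]])
    rhs <- paste(rhs, "+", averaging)
  }
  fit <- lm(stats::as.formula(paste(response, "~", rhs)), data = df)
  if (any(is.na(coef(fit)))) stop("singular design")
  emm <- emmeans::emmeans(fit, specs = group)
  tuk <- as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                         adjust = "tukey"))
  bon <- as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                         adjust = "bonferroni"))
  eff <- as.data.frame(emmeans::eff_size(emm, sigma = sigma(fit),
                                         edf = df.residual(fit)))
  sides <- strsplit(as.character(tuk$contrast), " - ", fixed = TRUE)
  strip <- function(x) gsub("[()]", "", x)
  out <- data.frame(
    group_a = strip(vapply(sides, `[`, "", 1L)),
    group_b = strip(vapply(sides, `[`, "", 2L)),
    mean_diff = tuk$estimate,
    se = tuk$SE,
    t_stat = tuk$t.ratio,
    cohens_d = eff$effect.size,
    p_tukey = tuk$p.value,
    p_bonf = pmin(bon$p.value, 1),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# Solve the exchangeable-GEE working model y = X beta for one set of
# cluster blocks. V_i^{-1} for R = (1-alpha) I + alpha J has the closed
# form (I - alpha/(1+(n_i-1)alpha) J) / (1-alpha), up to the scale phi
# which cancels in the estimating equations.
gee_solve <- function(X, y, cluster, alpha) {
  p <- ncol(X)
  A <- matrix(0, p, p)   # sum X' V^-1 X
  bvec <- numeric(p)     # sum X' V^-1 y
  idx <- split(seq_along(y), cluster)
  for (ii in idx) {
    Xi <- X[ii, , drop = FALSE]
    yi <- y[ii]
    ni <- length(ii)
    c2 <- alpha / (1 + (ni - 1) * alpha)
    # V^-1 z = (z - c2 * sum(z) 1) / (1 - alpha)
    VinvX <- (Xi - matrix(c2 * colSums(Xi), ni, p, byrow = TRUE)) / (1 - alpha)
    A <- A + crossprod(Xi, VinvX)
    bvec <- bvec + crossprod(VinvX, yi)
  }
  beta <- solve(A, bvec)
  list(beta = beta, A = A, idx = idx)
}

#' Gaussian GEE fit with cluster-robust (sandwich) inference
#'
#' Marginal linear model for clustered observations estimated by
#' generalized estimating equations with identity link and Gaussian
#' variance, using either an independence or exchangeable working
#' correlation. Standard errors are robust (sandwich) and valid under
#' working-correlation misspecification; p-values are Wald tests against
#' a t reference with `n_clusters - p` degrees of freedom, guarding
#' against anticonservative inference with few clusters.
#'
#' @param y Numeric response.
#' @param X Numeric design matrix (without intercept; one is added), or a
#'   single numeric vector.
#' @param cluster Cluster identifiers (e.g. biological replicate), same
#'   length as `y`.
#' @param working Working correlation: "exchangeable" (default) or
#'   "independence".
#' @param max_iter,tol Iteration control for the exchangeable fit.
#' @return List of class `gee_fit`: `coefficients`, `slope`, `intercept`,
#'   `robust_se` (for the slope when `X` is a single predictor, otherwise
#'   a vector), `p_value`, `df` (Wald-t degrees of freedom), `alpha`
#'   (estimated working correlation), `working`, `n_clusters`.
#' @export
gee_fit <- function(y, X, cluster,
                    working = c("exchangeable", "independence"),
                    max_iter = 50L, tol = 1e-8) {
  working <- match.arg(working)
  y <- as.numeric(y)
  if (is.null(dim(X))) X <- matrix(as.numeric(X), ncol = 1L,
                                   dimnames = list(NULL, "x"))
  cluster <- as.character(cluster)
  stopifnot(length(y) == nrow(X), length(cluster) == length(y))
  keep <- complete.cases(y, X)
  y <- y[keep]; X <- X[keep, , drop = FALSE]; cluster <- cluster[keep]
  n_clusters <- length(unique(cluster))
  if (n_clusters < 2L && working == "exchangeable" &&
      any(table(cluster) > 1L))
    stop("exchangeable working correlation needs >= 2 clusters")
  if (any(apply(X, 2, function(col) stats::var(col) == 0)))
    stop("constant predictor")
  Xd <- cbind(`(Intercept)` = 1, X)
  p <- ncol(Xd)
  alpha <- 0
  fit <- gee_solve(Xd, y, cluster, alpha)
  if (working == "exchangeable") {
    for (iter in seq_len(max_iter)) {
      res <- y - Xd %*% fit$beta
      phi <- sum(res^2) / (length(y) - p)
      num <- 0; denom <- 0
      for (ii in fit$idx) {
        ri <- res[ii]
        ni <- length(ri)
        if (ni > 1L) {
          num <- num + (sum(ri)^2 - sum(ri^2)) / 2
          denom <- denom + ni * (ni - 1) / 2
        }
      }
      alpha_new <- if (denom > p) num / ((denom - p) * phi) else 0
      alpha_new <- max(min(alpha_new, 0.99), 0)
      fit_new <- gee_solve(Xd, y, cluster, alpha_new)
      done <- max(abs(fit_new$beta - fit$beta)) < tol &&
        abs(alpha_new - alpha) < tol
      fit <- fit_new; alpha <- alpha_new
      if (done) break
    }
  }
  beta <- drop(fit$beta)
  res <- y - Xd %*% fit$beta
  # sandwich: A^-1 (sum X'V^-1 e e' V^-1 X) A^-1
  M <- matrix(0, p, p)
  for (ii in fit$idx) {
    Xi <- Xd[ii, , drop = FALSE]
    ri <- res[ii]
    ni <- length(ii)
    c2 <- alpha / (1 + (ni - 1) * alpha)
    Vinvr <- (ri - c2 * sum(ri)) / (1 - alpha)
    g <- crossprod(Xi, Vinvr)
    M <- M + tcrossprod(g)
  }
  Ainv <- solve(fit$A)
  vcov_robust <- Ainv %*% M %*% Ainv
  se <- sqrt(diag(vcov_robust))
  z <- beta / se
  # t reference with cluster-based degrees of freedom: the usual guard
  # against anticonservative sandwich inference with few clusters
  df_t <- max(n_clusters - p, 1)
  pvals <- 2 * pt(-abs(z), df = df_t)
  structure(list(coefficients = beta,
                 slope = unname(beta[2L]),
                 intercept = unname(beta[1L]),
                 robust_se = unname(se[2L]),
                 robust_se_all = se,
                 p_value = unname(pvals[2L]),
                 p_values_all = pvals,
                 vcov = vcov_robust,
                 df = df_t,
                 alpha = alpha, working = working,
                 n_clusters = n_clusters),
            class = "gee_fit")
}

#' GEE slope test for a single predictor
#'
#' Convenience wrapper around [gee_fit()] testing whether the
#' population-average slope relating `y` to `x` is zero, accounting for
#' intra-cluster dependence (cells sharing a biological replicate).
#'
#' @param y,x Numeric vectors.
#' @param cluster_ids Cluster identifiers.
#' @param working Working correlation structure.
#' @return A `gee_fit` (see [gee_fit()]); `slope`, `robust_se`, `p_value`
#'   refer to the coefficient on `x`.
#' @export
gee_slope <- function(y, x, cluster_ids,
                      working = c("exchangeable", "independence")) {
  gee_fit(y, matrix(as.numeric(x), ncol = 1, dimnames = list(NULL, "x")),
          cluster_ids, working = match.arg(working))
}

#' Cluster-robust two-group mean contrast via GEE
#'
#' Estimates the marginal mean difference between two groups (first level
#' minus second) with cluster-robust inference, e.g. interneuron versus
#' pyramidal marker intensities with replicate clustering.
#'
#' @param y Numeric response.
#' @param group Two-level factor (or coercible); the contrast is
#'   level 1 minus level 2.
#' @param cluster_ids Cluster identifiers; both groups must be present in
#'   at least 2 clusters.
#' @param working Working correlation structure.
#' @return List with `estimate` (mean difference), `robust_se`, `p_value`,
#'   `levels`, and the underlying `gee_fit`.
#' @export
gee_group_contrast <- function(y, group, cluster_ids,
                               working = c("exchangeable", "independence")) {
  group <- factor(group)
  if (nlevels(group) != 2L) stop("`group` must have exactly 2 levels")
  for (lev in levels(group)) {
    if (length(unique(cluster_ids[group == lev])) < 2L)
      stop("group '", lev, "' present in fewer than 2 clusters")
  }
  # indicator for level 1, so the coefficient is mean(level1) - mean(level2)
  x <- as.numeric(group == levels(group)[1L])
  fit <- gee_fit(y, matrix(x, ncol = 1, dimnames = list(NULL, "group")),
                 cluster_ids, working = match.arg(working))
  list(estimate = fit$slope, robust_se = fit$robust_se,
       p_value = fit$p_value, levels = levels(group), fit = fit)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' False-discovery-rate adjustment with monotonicity enforcement; values
#' are returned in the input order and clamped to `[0, 1]`.
#'
#' @param p_list Numeric vector of p-values.
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p_list) p.adjust(p_list, method = "BH")

#' Bonferroni adjustment
#'
#' @param p_list Numeric vector of p-values.
#' @param family Family size (defaults to `length(p_list)`).
#' @return Adjusted p-values clamped to 1.
#' @export
bonferroni_adjust <- function(p_list, family = length(p_list)) {
  pmin(p_list * family, 1)
}

#' Pearson correlation with two-sided p
#'
#' Descriptive product-moment correlation at the single-cell level; the
#' cluster-aware inferential path is [gee_slope()].
#'
#' @param x,y Numeric vectors, n >= 3, both varying.
#' @return List with `r`, `p`, `n`.
#' @export
pearson_r <- function(x, y) {
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (stats::var(x) == 0 || stats::var(y) == 0) stop("constant input")
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}
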