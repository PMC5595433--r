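#' Median-of-ratios size factors
#'
#' Per-sample scaling factors: for each sample, the median over genes (with
#' strictly positive counts in every sample) of that sample's count divided
#' by the gene's geometric mean across samples. Factors are rescaled to
#' geometric mean 1 so fold changes are interpretable relative to the
#' average library.
#'
#' @param m A [count_matrix()] or numeric matrix (genes x samples).
#' @return Named positive numeric vector of per-sample size factors with
#'   geometric mean 1.
#' @export
size_factors_median_of_ratios <- function(m) {
  x <- unclass(m)
  if (ncol(x) < 2L) os_stop("need >= 2 samples to estimate size factors")
  pos <- rowSums(x > 0) == ncol(x)
  if (!any(pos)) {
    os_stop("no gene has positive counts in all samples; ",
            "a pseudo-reference fallback is not implemented")
  }
  lx <- log(x[pos, , drop = FALSE])
  lgm <- rowMeans(lx)
  lsf <- apply(lx - lgm, 2L, stats::median)
  sf <- exp(lsf - mean(lsf))
  names(sf) <- colnames(x)
  sf
}

# internal: row variances with denominator n - 1
row_vars <- function(x) {
  n <- ncol(x)
  if (n < 2L) return(rep(NA_real_, nrow(x)))
  mu <- rowMeans(x)
  rowSums((x - mu)^2) / (n - 1)
}

#' Method-of-moments negative-binomial dispersion
#'
#' Per-gene dispersion `alpha` in the NB parameterisation
#' `Var = mu + alpha * mu^2`, estimated on size-factor-normalised counts as
#' `max(0, (s^2 - mu) / mu^2)` within each group and combined as a
#' degrees-of-freedom-weighted average across the two groups, then floored
#' at 1e-8 to keep the Wald weights well-defined. No shrinkage toward a
#' mean-dispersion trend is applied.
#'
#' @param m A [count_matrix()] or numeric matrix.
#' @param size_factors Output of [size_factors_median_of_ratios()].
#' @param groups Two-level factor (or vector) of length `ncol(m)`.
#' @return Named numeric vector of per-gene dispersions (>= 1e-8).
#' @export
estimate_dispersion <- function(m, size_factors, groups) {
  x <- unclass(m)
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L) os_stop("exactly two groups are required")
  tab <- table(groups)
  if (any(tab < 2L)) {
    os_stop("each group needs >= 2 samples (pool samples across time or ",
            "tissue upstream to gain replicates): ",
            paste(names(tab)[tab < 2], collapse = ", "))
  }
  norm <- sweep(x, 2L, size_factors, "/")
  alpha <- rep(0, nrow(x))
  wsum <- 0
  for (lev in levels(groups)) {
    sub <- norm[, groups == lev, drop = FALSE]
    mu <- rowMeans(sub)
    v <- row_vars(sub)
    a <- ifelse(mu > 0, (v - mu) / mu^2, 0)
    w <- ncol(sub) - 1L
    alpha <- alpha + w * pmax(a, 0)
    wsum <- wsum + w
  }
  alpha <- pmax(alpha / wsum, 1e-8)
  names(alpha) <- rownames(x)
  alpha
}

#' Negative-binomial Wald test for a two-group contrast
#'
#' Fits, per gene, an NB generalised linear model with log link, an
#' intercept, a group indicator (second factor level vs first) and
#' `log(size factor)` offsets, at fixed gene-wise dispersion. The Wald
#' statistic is the coefficient over its standard error from the expected
#' Fisher information, referred to the standard normal (large-sample
#' reference, two-sided). `log2_fold_change` is the coefficient divided by
#' `ln 2`; positive values mean higher expression in the second level.
#' All-zero genes get `p_value = 1`, `log2_fold_change = 0` and are flagged
#' in the `all_zero` column.
#'
#' @param m A [count_matrix()] or numeric matrix.
#' @param size_factors Per-sample size factors.
#' @param dispersions Per-gene NB dispersions.
#' @param groups Two-level factor of length `ncol(m)`.
#' @return Data frame with columns `gene`, `base_mean`, `log2_fold_change`,
#'   `dispersion`, `stat`, `p_value`, `all_zero`.
#' @export
nb_wald_test <- function(m, size_factors, dispersions, groups) {
  y <- unclass(m)
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L) os_stop("exactly two groups are required")
  if (any(table(groups) < 2L)) os_stop("each group needs >= 2 samples")
  n <- ncol(y)
  G <- nrow(y)
  g2 <- as.numeric(groups == levels(groups)[2L])
  off <- matrix(log(size_factors), G, n, byrow = TRUE)
  norm <- sweep(y, 2L, size_factors, "/")
  base_mean <- rowMeans(norm)
  alpha <- rep_len(dispersions, G)

  eps <- 1e-4
  muA <- pmax(rowMeans(norm[, g2 == 0, drop = FALSE]), eps)
  muB <- pmax(rowMeans(norm[, g2 == 1, drop = FALSE]), eps)
  b1 <- log(muA)
  b2 <- log(muB) - b1
  g2row <- matrix(g2, G, n, byrow = TRUE)

  for (iter in 1:60) {
    eta <- off + b1 + b2 * g2row
    mu <- pmin(exp(eta), 1e12)
    W <- mu / (1 + alpha * mu)
    z <- (eta - off) + (y - mu) / mu
    Wz <- W * z
    a <- rowSums(W)
    b <- rowSums(W * g2row)
    u <- rowSums(Wz)
    v <- rowSums(Wz * g2row)
    wA <- pmax(a - b, 1e-12)
    bB <- pmax(b, 1e-12)
    b1_new <- (u - v) / wA
    b2_new <- pmin(pmax(v / bB - b1_new, -30), 30)
    delta <- max(abs(b1_new - b1), abs(b2_new - b2))
    b1 <- b1_new
    b2 <- b2_new
    if (delta < 1e-10) break
  }
  eta <- off + b1 + b2 * g2row
  mu <- pmin(exp(eta), 1e12)
  W <- mu / (1 + alpha * mu)
  a <- rowSums(W)
  b <- rowSums(W * g2row)
  det <- pmax(b * (a - b), 1e-300)
  se <- sqrt(a / det)
  stat <- b2 / se
  p <- 2 * stats::pnorm(-abs(stat))

  all_zero <- rowSums(y) == 0
  stat[all_zero] <- 0
  p[all_zero] <- 1
  b2[all_zero] <- 0

  data.frame(gene = rownames(y), base_mean = base_mean,
             log2_fold_change = b2 / log(2), dispersion = alpha,
             stat = stat, p_value = p, all_zero = all_zero,
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment (monotone,
#' order-preserving with the input).
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Vector of BH-adjusted q-values in input order.
#' @export
adjust_bh <- function(p_values) {
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    os_stop("p-values must lie in [0, 1] with no missing values")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Two-group negative-binomial differential expression
#'
#' One-call wrapper over the full simplified pipeline: median-of-ratios
#' size factors, method-of-moments gene-wise dispersion, NB Wald test and
#' BH adjustment. Deliberately omits DESeq2's dispersion-trend shrinkage,
#' Cook's-distance outlier handling, independent filtering and fold-change
#' shrinkage; results carry a `method = "nb_wald_simple"` attribute to make
#' that explicit.
#'
#' @param m A [count_matrix()] of tag counts.
#' @param groups Two-level factor of length `ncol(m)`; fold changes are the
#'   second level relative to the first.
#' @param alpha Significance level on the q-value; default 0.05.
#' @return A `de_result` data frame: `gene`, `base_mean`,
#'   `log2_fold_change`, `dispersion`, `stat`, `p_value`, `q_value`,
#'   `direction` (`up_in_A` / `up_in_B` / `ns`), `all_zero`.
#' @export
nb_de <- function(m, groups, alpha = 0.05) {
  check_fraction(alpha, "alpha")
  groups <- as.factor(groups)
  sf <- size_factors_median_of_ratios(m)
  disp <- estimate_dispersion(m, sf, groups)
  res <- nb_wald_test(m, sf, disp, groups)
  res$q_value <- adjust_bh(res$p_value)
  sig <- res$q_value <= alpha
  res$direction <- ifelse(!sig, "ns",
                          ifelse(res$log2_fold_change < 0, "up_in_A", "up_in_B"))
  if (any(sig & res$log2_fold_change == 0)) {
    os_warn("significant gene with numerically zero fold change flagged as 'ns'")
    res$direction[sig & res$log2_fold_change == 0] <- "ns"
  }
  structure(res, class = c("de_result", "data.frame"),
            method = "nb_wald_simple",
            levels = levels(groups), alpha = alpha,
            size_factors = sf)
}

#' @export
print.de_result <- function(x, ...) {
  lv <- attr(x, "levels")
  alpha <- attr(x, "alpha")
  n_sig <- sum(x$q_value <= alpha)
  cat(sprintf("de_result [%s]: %s vs %s, %d genes, %d significant at q <= %g\n",
              attr(x, "method"), lv[1L], lv[2L], nrow(x), n_sig, alpha))
  cat(sprintf("  up in %s: %d | up in %s: %d\n",
              lv[1L], sum(x$direction == "up_in_A"),
              lv[2L], sum(x$direction == "up_in_B")))
  invisible(x)
}

#' @export
summary.de_result <- function(object, ...) {
  lv <- attr(object, "levels")
  structure(list(method = attr(object, "method"), levels = lv,
                 alpha = attr(object, "alpha"), n_genes = nrow(object),
                 n_significant = sum(object$q_value <= attr(object, "alpha")),
                 n_up_in_A = sum(object$direction == "up_in_A"),
                 n_up_in_B = sum(object$direction == "up_in_B"),
                 size_factors = attr(object, "size_factors")),
            class = "summary.de_result")
}

#' @export
print.summary.de_result <- function(x, ...) {
  cat(sprintf("NB Wald differential expression (%s): %s vs %s\n",
              x$method, x$levels[1L], x$levels[2L]))
  cat(sprintf("  %d genes; %d significant at q <= %g (%d up in %s, %d up in %s)\n",
              x$n_genes, x$n_significant, x$alpha,
              x$n_up_in_A, x$levels[1L], x$n_up_in_B, x$levels[2L]))
  cat("  size factors:", paste(sprintf("%.3f", x$size_factors), collapse = " "), "\n")
  invisible(x)
}

#' Partition significant genes by direction of change
#'
#' @param results A `de_result` (or data frame with `gene`, `q_value`,
#'   `log2_fold_change`).
#' @param alpha Significance level on the q-value.
#' @return List of two [gene_set()]s, `up_in_A` (negative fold change,
#'   higher in the first group) and `up_in_B`.
#' @export
differential_transcripts <- function(results, alpha = 0.05) {
  check_fraction(alpha, "alpha")
  sig <- results$q_value <= alpha
  lv <- attr(results, "levels") %||% c("A", "B")
  list(up_in_A = gene_set(paste0("up_in_", lv[1L]),
                          results$gene[sig & results$log2_fold_change < 0]),
       up_in_B = gene_set(paste0("up_in_", lv[2L]),
                          results$gene[sig & results$log2_fold_change > 0]))
}
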