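test_that("median-of-ratios size factors match closed forms", {
  a <- c(10, 20, 5, 40)
  m <- count_matrix(matrix(c(a, a), 4, 2,
                           dimnames = list(paste0("g", 1:4), c("s1", "s2"))))
  expect_equal(unname(size_factors_median_of_ratios(m)), c(1, 1))

  m2 <- count_matrix(matrix(c(a, 2 * a), 4, 2,
                            dimnames = dimnames(m)))
  expect_equal(unname(size_factors_median_of_ratios(m2)),
               c(1 / sqrt(2), sqrt(2)))

  m3 <- count_matrix(matrix(c(4, 9), 1, 2,
                            dimnames = list("g1", c("s1", "s2"))))
  expect_equal(unname(size_factors_median_of_ratios(m3)), c(4 / 6, 9 / 6))

  zeros <- count_matrix(matrix(c(0, 5, 3, 0), 2, 2,
                               dimnames = list(c("g1", "g2"), c("s1", "s2"))))
  expect_error(size_factors_median_of_ratios(zeros), "pseudo-reference")
})

test_that("size factors agree with a brute-force oracle and behave under scaling", {
  set.seed(11)
  for (i in 1:15) {
    m <- rand_counts(G = sample(10:40, 1), n = sample(2:6, 1))
    sf <- size_factors_median_of_ratios(m)
    expect_equal(unname(sf), unname(size_factor_oracle(unclass(m))),
                 tolerance = 1e-12)
    expect_equal(exp(mean(log(sf))), 1, tolerance = 1e-9)

    # permuting gene order changes nothing
    perm <- unclass(m)[sample(nrow(m)), , drop = FALSE]
    expect_equal(unname(size_factors_median_of_ratios(count_matrix(perm))),
                 unname(sf))

    # scaling sample j by c multiplies factor j by c^((n-1)/n) after centering
    n <- ncol(m)
    j <- sample(n, 1)
    cc <- runif(1, 0.5, 3)
    scaled <- unclass(m)
    scaled[, j] <- scaled[, j] * cc
    sf2 <- size_factors_median_of_ratios(count_matrix(scaled))
    expect_equal(sf2[[j]], sf[[j]] * cc^((n - 1) / n), tolerance = 1e-9)
  }
})

test_that("size factors agree with the reference bioconductor estimator", {
  skip_if_not_installed("DESeq2")
  set.seed(21)
  m <- rand_counts(G = 60, n = 5)
  sf <- size_factors_median_of_ratios(m)
  ref <- DESeq2::estimateSizeFactorsForMatrix(unclass(m))
  # the reference centers by geometric mean of location estimates too
  expect_equal(unname(sf), unname(ref / exp(mean(log(ref)))), tolerance = 1e-9)
})

test_that("method-of-moments dispersion recovers simulated truth", {
  grp <- factor(rep(c("A", "B"), each = 25))
  set.seed(31)
  pois <- matrix(rpois(50 * 50, 80), 50, 50,
                 dimnames = list(paste0("g", 1:50), paste0("s", 1:50)))
  disp <- estimate_dispersion(count_matrix(pois), rep(1, 50), grp)
  expect_lt(median(disp), 0.01)

  grp200 <- factor(rep(c("A", "B"), each = 100))
  nb <- matrix(rnbinom(60 * 200, mu = 100, size = 1 / 0.5), 60, 200,
               dimnames = list(paste0("g", 1:60), paste0("t", 1:200)))
  disp2 <- estimate_dispersion(count_matrix(nb), rep(1, 200), grp200)
  expect_gt(median(disp2), 0.3)
  expect_lt(median(disp2), 0.7)

  const <- matrix(7, 3, 6, dimnames = list(paste0("g", 1:3), paste0("s", 1:6)))
  disp3 <- estimate_dispersion(count_matrix(const), rep(1, 6),
                               factor(rep(c("A", "B"), each = 3)))
  expect_true(all(disp3 <= 1e-8))

  expect_error(estimate_dispersion(count_matrix(const), rep(1, 6),
                                   factor(c("A", rep("B", 5)))),
               ">= 2 samples")
})

test_that("the NB Wald test is calibrated under the null", {
  set.seed(41)
  G <- 2000
  mu <- exp(rnorm(G, log(100), 1))
  y <- matrix(rnbinom(G * 20, mu = rep(mu, 20), size = 1 / 0.2), G, 20,
              dimnames = list(sprintf("g%04d", 1:G), sprintf("s%02d", 1:20)))
  grp <- factor(rep(c("A", "B"), each = 10))
  res <- nb_de(count_matrix(y), grp)
  rate <- mean(res$p_value <= 0.05)
  expect_gte(rate, 0.025)
  expect_lte(rate, 0.10)
})

test_that("planted fold changes are recovered and labels swap cleanly", {
  set.seed(51)
  G <- 400; nde <- 40
  mu <- exp(rnorm(G, log(100), 0.5))
  fold <- rep(1, G); fold[seq_len(nde)] <- 8
  y <- cbind(matrix(rnbinom(G * 5, mu = rep(mu, 5), size = 1 / 0.1), G, 5),
             matrix(rnbinom(G * 5, mu = rep(mu * fold, 5), size = 1 / 0.1), G, 5))
  dimnames(y) <- list(sprintf("g%03d", 1:G), sprintf("s%02d", 1:10))
  grp <- factor(rep(c("A", "B"), each = 5))
  m <- count_matrix(y)
  res <- nb_de(m, grp)
  expect_lt(abs(median(res$log2_fold_change[seq_len(nde)]) - 3), 0.75)

  flipped <- nb_de(m, factor(grp, levels = c("B", "A")))
  expect_equal(flipped$log2_fold_change, -res$log2_fold_change, tolerance = 1e-9)
  expect_equal(flipped$p_value, res$p_value, tolerance = 1e-9)
})

test_that("all-zero genes are flagged, not tested", {
  y <- rbind(g0 = rep(0, 6),
             g1 = c(10, 12, 9, 50, 60, 55),
             g2 = c(20, 22, 19, 21, 20, 18))
  colnames(y) <- paste0("s", 1:6)
  grp <- factor(rep(c("A", "B"), each = 3))
  sf <- rep(1, 6)
  res <- nb_wald_test(count_matrix(y), sf, c(1e-8, 0.01, 0.01), grp)
  expect_identical(res$p_value[1], 1)
  expect_identical(res$log2_fold_change[1], 0)
  expect_true(res$all_zero[1])
  expect_false(any(res$all_zero[-1]))
})

test_that("BH adjustment matches the brute-force step-up oracle", {
  expect_equal(adjust_bh(0.03), 0.03)
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_bh(c(1, 1)), c(1, 1))
  expect_error(adjust_bh(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(61)
  for (i in 1:20) {
    p <- runif(sample(1:50, 1))
    expect_equal(adjust_bh(p), bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("significant genes partition cleanly by direction", {
  res <- data.frame(gene = c("g1", "g2", "g3"),
                    q_value = c(0.01, 0.2, 0.04),
                    log2_fold_change = c(-2, 3, 1),
                    stringsAsFactors = FALSE)
  parts <- differential_transcripts(res)
  expect_identical(parts$up_in_A$genes, "g1")
  expect_identical(parts$up_in_B$genes, "g3")
  expect_identical(length(parts$up_in_A$genes) + length(parts$up_in_B$genes),
                   sum(res$q_value <= 0.05))

  none <- differential_transcripts(transform(res, q_value = 0.9))
  expect_length(none$up_in_A$genes, 0)
  expect_length(none$up_in_B$genes, 0)
})
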