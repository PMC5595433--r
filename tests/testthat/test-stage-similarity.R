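mk_call <- function(expressed, all_genes, label, species) {
  vals <- stats::setNames(ifelse(all_genes %in% expressed, 100, 0), all_genes)
  suppressWarnings(call_expressed(expression_profile(vals, label, species)))
}

test_that("expressed-ortholog intersection bridges species", {
  map <- ortholog_map(c("a1", "a2", "a3"), c("b1", "b2", "b3"))
  csA <- mk_call(c("a1", "a2"), c("a1", "a2", "a3"), "A", "marsupial")
  csB <- mk_call("b1", c("b1", "b2", "b3"), "B", "eutherian")
  uni <- intersect_expressed(list(csA, csB), map, "marsupial")
  expect_identical(uni$gene_a, "a1")
  expect_identical(uni$gene_b, "b1")

  same <- intersect_expressed(list(csA, csA), map, "marsupial")
  expect_setequal(same$gene_a, c("a1", "a2"))

  csB2 <- mk_call("b3", c("b1", "b2", "b3"), "B2", "eutherian")
  expect_error(intersect_expressed(list(csA, csB2), map, "marsupial"),
               "empty expressed-ortholog intersection")
})

test_that("ranking runs highest-first with average ties and monotone invariance", {
  pr <- profile_of(c(9, 5, 1), c("g1", "g2", "g3"), "p", "sp")
  expect_equal(unname(rank_profile(pr, c("g1", "g2", "g3"))$ranks), c(1, 2, 3))

  tied <- profile_of(c(7, 7, 1), c("g1", "g2", "g3"), "t", "sp")
  expect_equal(unname(rank_profile(tied, c("g1", "g2", "g3"))$ranks),
               c(1.5, 1.5, 3))

  set.seed(71)
  vals <- rexp(20)
  genes <- sprintf("g%02d", 1:20)
  r1 <- rank_profile(profile_of(vals, genes, "a", "sp"), genes)
  r2 <- rank_profile(profile_of(log1p(vals)^3, genes, "b", "sp"), genes)
  expect_identical(r1$ranks, stats::setNames(r2$ranks, names(r1$ranks)))

  expect_error(rank_profile(pr, c("g1", "gX")), "absent from profile")
})

test_that("spearman_rho equals rank-then-Pearson and handles edge cases", {
  genes <- paste0("g", 1:5)
  x <- rank_profile(profile_of(c(1, 2, 3, 4, 5), genes, "x", "sp"), genes)
  y <- rank_profile(profile_of(c(2, 1, 4, 3, 5), genes, "y", "sp"), genes)
  expect_equal(spearman_rho(x, x), 1.0)
  rev_y <- rank_profile(profile_of(c(5, 4, 3, 2, 1), genes, "r", "sp"), genes)
  expect_equal(spearman_rho(x, rev_y), -1.0)
  # Sum d^2 = 4, n = 5: rho = 1 - 6*4/(5*24) = 0.8 (frozen from the
  # no-ties closed form, cross-checked against cor(method = "spearman"))
  expect_equal(spearman_rho(x, y), 0.8)
  expect_equal(spearman_rho(x, y),
               cor(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5), method = "spearman"))

  set.seed(81)
  for (i in 1:20) {
    n <- sample(5:50, 1)
    g <- sprintf("h%02d", seq_len(n))
    a <- sample(0:5, n, replace = TRUE) + rbinom(n, 1, 0.5) * runif(n)
    b <- sample(0:5, n, replace = TRUE) + rbinom(n, 1, 0.5) * runif(n)
    if (sd(a) == 0 || sd(b) == 0) next
    ra <- rank_profile(profile_of(a, g, "a", "sp"), g)
    rb <- rank_profile(profile_of(b, g, "b", "sp"), g)
    expect_equal(spearman_rho(ra, rb), cor(a, b, method = "spearman"),
                 tolerance = 1e-12)
  }

  short <- rank_profile(profile_of(c(1, 2), c("g1", "g2"), "s", "sp"),
                        c("g1", "g2"))
  expect_error(spearman_rho(short, short), "universe size < 3")
  flat <- rank_profile(profile_of(rep(4, 4), paste0("g", 1:4), "f", "sp"),
                       paste0("g", 1:4))
  expect_error(spearman_rho(flat, flat), "degenerate profile")
})

test_that("the similarity grid is complete, self-consistent and order-invariant", {
  genes_a <- sprintf("a%02d", 1:30)
  genes_b <- sprintf("b%02d", 1:30)
  map <- ortholog_map(genes_a, genes_b)
  set.seed(91)
  vals <- rexp(30, 1 / 50)
  qp <- profile_of(vals, genes_a, "q1", "marsupial")
  rp <- profile_of(vals + rnorm(30, 0, 1e-9), genes_b, "r1", "eutherian")
  csA <- mk_call(genes_a, genes_a, "A", "marsupial")
  csB <- mk_call(genes_b, genes_b, "B", "eutherian")
  sim <- similarity_matrix(list(qp), list(rp), list(), list(csA, csB),
                           map, "marsupial")
  expect_identical(dim(sim$rho), c(1L, 1L))
  expect_equal(sim$rho[1, 1], 1.0, tolerance = 1e-6)
  expect_identical(sim$n_genes, 30L)

  # permuting the gene order of the inputs leaves every cell unchanged
  perm <- sample(30)
  qp2 <- profile_of(vals[perm], genes_a[perm], "q1", "marsupial")
  sim2 <- similarity_matrix(list(qp2), list(rp), list(), list(csA, csB),
                            map, "marsupial")
  expect_identical(sim$rho, sim2$rho)
})

test_that("argmax stage picks the planted stage, breaking ties early", {
  x <- structure(list(rho = matrix(c(0.2, 0.9, 0.4), 1, 3,
                                   dimnames = list("d21", c("e8.0", "e10.5", "term"))),
                      n_genes = 100L,
                      reference_labels = c("e8.0", "e10.5", "term"),
                      control_labels = character(0)),
                 class = "stage_cor_matrix")
  b <- best_matching_stage(x)
  expect_identical(b$best_stage, "e10.5")
  expect_false(b$tie)

  x$rho[1, ] <- c(0.9, 0.9, 0.1)
  b2 <- best_matching_stage(x)
  expect_identical(b2$best_stage, "e8.0")
  expect_true(b2$tie)
})

test_that("control contrast uses strict margins", {
  x <- structure(list(rho = matrix(c(0.5, 0.6, 0.3), 1, 3,
                                   dimnames = list("q", c("s1", "s2", "heart"))),
                      n_genes = 50L, reference_labels = c("s1", "s2"),
                      control_labels = "heart"),
                 class = "stage_cor_matrix")
  cc <- control_contrast(x)
  expect_equal(cc$margin, 0.2)
  expect_true(cc$reference_beats_control)

  x$rho[1, "heart"] <- 0.7
  expect_false(control_contrast(x)$reference_beats_control)

  x$rho[1, "heart"] <- 0.5
  cc3 <- control_contrast(x)
  expect_equal(cc3$margin, 0)
  expect_false(cc3$reference_beats_control)

  x$control_labels <- character(0)
  expect_error(control_contrast(x), "no control columns")
})

test_that("a planted query maps back to its stage through the full machinery", {
  cfg <- sim_config(n_genes = 1500, organ_program_size = 60, early_size = 68,
                    late_size = 14, query_early = 18, query_late = 4,
                    coopted_size = 20, eutherian_only_size = 25,
                    n_de_genes = 40,
                    query_stage_map = c(d21 = "e9.5", d23 = "e12.5",
                                        d25 = "e17.0"),
                    seed = 202)
  truth <- generate_truth(cfg)
  qp <- simulate_query_placenta(truth)
  series <- simulate_reference_series(truth)
  heart <- simulate_count_dataset(truth, "eutherian", "heart")

  md <- rbind(qp$metadata, series$metadata, heart$metadata)
  tp_prof <- lapply(c("d21", "d23", "d25"), function(tp) {
    average_replicates(qp$counts, md, list(timepoint = tp), label = tp)
  })
  stage_prof <- lapply(cfg$reference_stages, function(s) {
    average_replicates(series$counts, md, list(timepoint = s), label = s)
  })
  heart_prof <- expression_profile(rowMeans(unclass(heart$counts)),
                                   "heart", "eutherian")
  calls <- list(
    call_expressed(expression_profile(rowMeans(unclass(qp$counts)),
                                      "qp", "marsupial")),
    call_expressed(expression_profile(rowMeans(unclass(series$counts)),
                                      "series", "eutherian")),
    call_expressed(heart_prof))
  sim <- similarity_matrix(tp_prof, stage_prof, list(heart_prof), calls,
                           truth$map, "marsupial")
  best <- best_matching_stage(sim)
  expect_identical(stats::setNames(best$best_stage, best$query),
                   cfg$query_stage_map)
  expect_true(all(control_contrast(sim)$reference_beats_control))
})
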