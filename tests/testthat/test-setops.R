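test_that("stage-partition counts cross programs against query orthologs", {
  early_b <- sprintf("e%03d", 1:340)
  late_b <- sprintf("l%03d", 1:70)
  all_b <- c(early_b, late_b)
  all_a <- paste0("A_", all_b)
  map <- ortholog_map(all_a, all_b)
  query <- paste0("A_", c(early_b[1:90], late_b[1:10]))
  tab <- stage_partition_counts(gene_set("early", early_b),
                                gene_set("late", late_b), query, map)
  expect_identical(as.vector(t(tab)), c(90L, 250L, 10L, 60L))

  none <- stage_partition_counts(gene_set("early", early_b),
                                 gene_set("late", late_b), character(0), map)
  expect_identical(as.vector(t(none)), c(0L, 340L, 0L, 70L))

  all_q <- stage_partition_counts(gene_set("early", early_b),
                                  gene_set("late", late_b), all_a, map)
  expect_identical(as.vector(t(all_q)), c(340L, 0L, 70L, 0L))

  expect_error(stage_partition_counts(gene_set("early", early_b),
                                      gene_set("late", c(early_b[1], late_b)),
                                      query, map),
               "overlap")
})

test_that("chi-square matches the hand-computed expected-count oracle", {
  tab <- matrix(c(90, 250, 10, 60), 2, 2, byrow = TRUE)
  # oracle: expected counts from marginals, Pearson sum by hand
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat_oracle <- sum((tab - expected)^2 / expected)
  res <- chi_square_independence(tab)
  expect_equal(res$statistic, stat_oracle, tolerance = 1e-12)
  expect_equal(res$statistic, 4.6735, tolerance = 1e-4)
  expect_equal(res$p_value, pchisq(stat_oracle, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_lt(res$p_value, 0.05)

  yat <- chi_square_independence(tab, yates = TRUE)
  stat_yates <- sum((abs(tab - expected) - 0.5)^2 / expected)
  expect_equal(yat$statistic, stat_yates, tolerance = 1e-12)
  expect_equal(yat$statistic, 4.0361, tolerance = 1e-4)
  expect_lt(yat$p_value, 0.05)

  flat <- matrix(c(20, 80, 10, 40), 2, 2, byrow = TRUE)
  res_flat <- chi_square_independence(flat)
  expect_equal(res_flat$statistic, 0, tolerance = 1e-12)
  expect_equal(res_flat$p_value, 1)

  swapped <- chi_square_independence(tab[2:1, ])
  expect_equal(swapped$statistic, res$statistic)

  expect_error(chi_square_independence(matrix(c(0, 0, 5, 5), 2, 2)),
               "zero marginal")
})

test_that("convergence screens follow their set formulas", {
  map <- ortholog_map(paste0("a", 1:5), paste0("b", 1:5))
  sc <- shared_coopted(placenta_A = c("a1", "a2", "a3"),
                       placenta_B = c("b1", "b2"),
                       organ_A = c("a1", "a2"),
                       organ_B = "b2", map)
  expect_identical(sc$gene_set$genes, "a1")
  expect_identical(sc$orthologs_b, "b1")

  all_b <- paste0("b", 1:5)
  sc2 <- shared_coopted(paste0("a", 1:5), all_b, paste0("a", 1:5), all_b, map)
  expect_length(sc2$gene_set$genes, 0)

  eo <- eutherian_only_shared(placenta_B = c("b1", "b2"),
                              organ_A = c("a1", "a2"),
                              placenta_A = "a2",
                              organ_B = character(0), map)
  expect_identical(eo$gene_set$genes, "a1")

  eo2 <- eutherian_only_shared(c("b1", "b2"), c("a1", "a2"),
                               paste0("a", 1:5), character(0), map)
  expect_length(eo2$gene_set$genes, 0)
})

test_that("screens equal exhaustive membership enumeration on random instances", {
  set.seed(111)
  for (i in 1:25) {
    n <- sample(20:120, 1)
    ga <- sprintf("qa%03d", seq_len(n))
    gb <- sprintf("qb%03d", seq_len(n))
    map <- ortholog_map(ga, gb)
    pick <- function(g) sample(g, rbinom(1, length(g), runif(1, 0.2, 0.8)))
    A_pl <- pick(ga); A_org <- pick(ga)
    B_pl <- pick(gb); B_org <- pick(gb)

    sc <- shared_coopted(A_pl, B_pl, A_org, B_org, map)
    expect_identical(sc$gene_set$genes,
                     screen_oracle(ga, map, A_pl, B_pl, A_org, B_org,
                                   "shared_coopted"))
    eo <- eutherian_only_shared(B_pl, A_org, A_pl, B_org, map)
    expect_identical(eo$gene_set$genes,
                     screen_oracle(ga, map, A_pl, B_pl, A_org, B_org,
                                   "eutherian_only"))

    # conservation: the exclusion splits the three-way intersection exactly
    tri <- intersect(intersect(A_pl, orth_b_to_a(B_pl, map)), A_org)
    inB <- intersect(tri, orth_b_to_a(B_org, map))
    expect_identical(length(sc$gene_set$genes) + length(inB), length(tri))

    # idempotence: re-running on its own output plus originals is stable
    sc2 <- shared_coopted(A_pl, B_pl, A_org, B_org, map)
    expect_identical(sc2$gene_set$genes, sc$gene_set$genes)
  }
})

test_that("control screens substitute organ slots into the same formula", {
  map <- ortholog_map(paste0("a", 1:6), paste0("b", 1:6))
  A_pl <- c("a1", "a2", "a3"); B_pl <- c("b1", "b2", "b3")
  A_mam <- c("a1", "a3"); B_mam <- "b3"
  primary <- shared_coopted(A_pl, B_pl, A_mam, B_mam, map)
  ctrl <- control_screens("shared_coopted", A_pl, B_pl,
                          list(mammary_again = list(organ_A = A_mam,
                                                    organ_B = B_mam),
                               empty = list(organ_A = character(0),
                                            organ_B = "b1")),
                          map)
  expect_identical(ctrl$count[ctrl$tissue == "mammary_again"],
                   length(primary$gene_set$genes))
  expect_identical(ctrl$count[ctrl$tissue == "empty"], 0L)
})

test_that("ORA p-values are exact hypergeometric tails", {
  universe <- sprintf("u%03d", 1:40)
  query <- gene_set("q", universe[1:10])
  hit <- gene_set("hit", universe[1:10])
  miss <- gene_set("miss", universe[31:40])
  other <- gene_set("other", universe[6:25])
  res <- ora_fisher(query, list(hit, miss, other), universe)
  expect_identical(res$overlap[res$annotation == "hit"], 10L)
  expect_equal(res$p_value[res$annotation == "hit"], min(res$p_value))
  expect_gte(res$p_value[res$annotation == "miss"], 0.5)

  for (i in seq_len(nrow(res))) {
    expect_equal(res$p_value[i],
                 hyper_tail_oracle(res$overlap[i], res$set_size[i],
                                   res$universe_size[i], res$query_size[i]),
                 tolerance = 1e-12)
  }
  expect_equal(res$q_value, bh_oracle(res$p_value), tolerance = 1e-12)

  expect_error(ora_fisher(gene_set("q", "absent"), list(hit), universe),
               "outside the universe")
  expect_error(ora_fisher(query, list(hit), character(0)), "empty universe")
})
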