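#' Stage-partition contingency table
#'
#' Crosses the reference species' early and late organ-specific programs
#' against presence in the query organ: `a` = early-program genes with an
#' expressed query ortholog, `b` = the remaining early genes, `c`/`d`
#' likewise for the late program. Programs are given in the reference
#' (species-B) namespace; the query expressed set is translated through the
#' ortholog map before intersecting.
#'
#' @param early_program,late_program [gene_set()]s in species-B namespace;
#'   must be disjoint.
#' @param query_expressed Character vector of expressed genes in species-A
#'   namespace.
#' @param map An [ortholog_map()].
#' @return 2x2 integer matrix (rows `early`/`late`, columns
#'   `expressed`/`not_expressed`) with attribute `n_unmappable`.
#' @export
stage_partition_counts <- function(early_program, late_program,
                                   query_expressed, map) {
  early <- early_program$genes
  late <- late_program$genes
  if (length(intersect(early, late))) {
    os_stop("early and late programs overlap: ",
            paste(utils::head(intersect(early, late), 5L), collapse = ", "))
  }
  orth <- orth_a_to_b(query_expressed, map)
  a <- length(intersect(early, orth))
  c_ <- length(intersect(late, orth))
  tab <- matrix(as.integer(c(a, length(early) - a, c_, length(late) - c_)),
                nrow = 2L, byrow = TRUE,
                dimnames = list(program = c("early", "late"),
                                query = c("expressed", "not_expressed")))
  attr(tab, "n_unmappable") <- attr(orth, "n_unmappable")
  tab
}

#' Pearson chi-square test of independence on a 2x2 table
#'
#' One degree of freedom; expected counts from the marginals; p-value from
#' the chi-square upper tail. The Yates continuity correction is off by
#' default and available behind a flag (both variants are valid here; the
#' uncorrected form is the classical Pearson statistic).
#'
#' @param table 2x2 matrix of non-negative counts.
#' @param yates Apply the continuity correction? Default `FALSE`.
#' @return List with `statistic`, `p_value`, `df`, `expected`, `yates`.
#' @export
chi_square_independence <- function(table, yates = FALSE) {
  tab <- as.matrix(table)
  if (!all(dim(tab) == 2L)) os_stop("need a 2x2 table")
  if (any(tab < 0) || anyNA(tab)) os_stop("counts must be non-negative and complete")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    os_stop("zero marginal: a row or column of the table is empty")
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected <= 0)) os_stop("expected cell count not positive")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = yates))
  list(statistic = unname(ct$statistic), p_value = unname(ct$p.value),
       df = unname(ct$parameter), expected = expected, yates = yates)
}

# internal: resolve the four screen inputs into species-A namespace,
# tracking unmappable genes of B-namespace sets
screen_sets_to_a <- function(sets_a, sets_b, map) {
  unmappable <- integer(0)
  b_in_a <- lapply(names(sets_b), function(nm) {
    tr <- orth_b_to_a(sets_b[[nm]], map)
    unmappable[[nm]] <<- attr(tr, "n_unmappable")
    tr
  })
  names(b_in_a) <- names(sets_b)
  list(a = sets_a, b = b_in_a, unmappable = unmappable)
}

# internal: build a convergence_screen result object
new_screen_result <- function(screen_name, genes_a, map, inputs, unmappable) {
  genes_a <- sort(unique(genes_a))
  orth_b <- map$gene_b[match(genes_a, map$gene_a)]
  structure(list(screen_name = screen_name,
                 gene_set = gene_set(screen_name, genes_a),
                 orthologs_b = orth_b,
                 inputs = inputs,
                 unmappable = unmappable,
                 control_screens = NULL),
            class = "convergence_screen")
}

#' @export
print.convergence_screen <- function(x, ...) {
  cat(sprintf("convergence_screen '%s': %d genes\n",
              x$screen_name, length(x$gene_set$genes)))
  for (role in names(x$inputs)) {
    cat(sprintf("  %-14s %s (%d genes)\n", role, x$inputs[[role]]$label,
                x$inputs[[role]]$size))
  }
  if (!is.null(x$control_screens)) {
    cat("  control screens:",
        paste(x$control_screens$tissue, x$control_screens$count,
              sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Shared co-opted genes: three-way intersection minus one exclusion
#'
#' Genes expressed in the species-A organ of interest, the species-B
#' homologous organ and a second species-A organ, but not in the
#' corresponding species-B organ:
#' `(placenta_A intersect placenta_B intersect organ_A) setdiff organ_B`.
#' The motivating case is genes shared by both species' placentas and the
#' query species' mammary gland but absent from the reference mammary
#' gland — candidates for convergent co-option between placentation and
#' lactation. Results are reported in species-A identifiers with the B
#' ortholog attached.
#'
#' @param placenta_A,organ_A Expressed sets (character) in species-A
#'   namespace.
#' @param placenta_B,organ_B Expressed sets in species-B namespace.
#' @param map An [ortholog_map()].
#' @param screen_name Label for the result.
#' @return A `convergence_screen` object.
#' @export
shared_coopted <- function(placenta_A, placenta_B, organ_A, organ_B, map,
                           screen_name = "shared_coopted") {
  res <- screen_sets_to_a(list(placenta_A = placenta_A, organ_A = organ_A),
                          list(placenta_B = placenta_B, organ_B = organ_B), map)
  genes <- setdiff(intersect(intersect(res$a$placenta_A, res$b$placenta_B),
                             res$a$organ_A),
                   res$b$organ_B)
  inputs <- list(
    placenta_A = list(label = "shared-in", size = length(placenta_A)),
    placenta_B = list(label = "shared-in", size = length(placenta_B)),
    organ_A = list(label = "shared-in", size = length(organ_A)),
    organ_B = list(label = "excluded-from", size = length(organ_B)))
  new_screen_result(screen_name, genes, map, inputs, res$unmappable)
}

#' Reference-placenta-only sharing screen
#'
#' Genes expressed in the species-B placenta and the species-A second organ
#' but in neither the species-A placenta nor the species-B second organ:
#' `(placenta_B intersect organ_A) setdiff (placenta_A union organ_B)`.
#' The motivating case is genes used by the eutherian placenta and the
#' marsupial mammary gland only — late fetal-support functions carried by
#' different organs in the two lineages.
#'
#' @inheritParams shared_coopted
#' @return A `convergence_screen` object.
#' @export
eutherian_only_shared <- function(placenta_B, organ_A, placenta_A, organ_B,
                                  map, screen_name = "eutherian_only_shared") {
  res <- screen_sets_to_a(list(placenta_A = placenta_A, organ_A = organ_A),
                          list(placenta_B = placenta_B, organ_B = organ_B), map)
  genes <- setdiff(intersect(res$b$placenta_B, res$a$organ_A),
                   union(res$a$placenta_A, res$b$organ_B))
  inputs <- list(
    placenta_B = list(label = "shared-in", size = length(placenta_B)),
    organ_A = list(label = "shared-in", size = length(organ_A)),
    placenta_A = list(label = "excluded-from", size = length(placenta_A)),
    organ_B = list(label = "excluded-from", size = length(organ_B)))
  new_screen_result(screen_name, genes, map, inputs, res$unmappable)
}

#' Control screens with substituted organ pairs
#'
#' Re-runs the identical set formula with the organ slots replaced by
#' control tissues (e.g. liver, testis), giving the by-chance gene counts
#' against which the primary screen is judged.
#'
#' @param screen `"shared_coopted"` or `"eutherian_only_shared"`.
#' @param placenta_A,placenta_B As in the primary screen.
#' @param control_organ_pairs Named list; each element is
#'   `list(organ_A = <set>, organ_B = <set>)` for one control tissue.
#' @param map An [ortholog_map()].
#' @return Data frame with columns `tissue`, `count`.
#' @export
control_screens <- function(screen = c("shared_coopted", "eutherian_only_shared"),
                            placenta_A, placenta_B, control_organ_pairs, map) {
  screen <- match.arg(screen)
  fn <- if (screen == "shared_coopted") shared_coopted else eutherian_only_shared
  counts <- vapply(names(control_organ_pairs), function(tissue) {
    pair <- control_organ_pairs[[tissue]]
    r <- if (screen == "shared_coopted") {
      fn(placenta_A, placenta_B, pair$organ_A, pair$organ_B, map,
         screen_name = paste0(screen, ":", tissue))
    } else {
      fn(placenta_B, pair$organ_A, placenta_A, pair$organ_B, map,
         screen_name = paste0(screen, ":", tissue))
    }
    length(r$gene_set$genes)
  }, integer(1))
  data.frame(tissue = names(control_organ_pairs), count = counts,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Hypergeometric over-representation analysis
#'
#' One-sided hypergeometric (equivalently one-sided Fisher) enrichment of a
#' query gene list in each annotation set, against a stated universe, with
#' BH adjustment across annotation sets. A generic ORA; no GO-graph
#' propagation and no web-service scoring.
#'
#' @param query A [gene_set()] (or character vector); must lie within
#'   `universe`.
#' @param annotations List of [gene_set()]s; each is intersected with the
#'   universe before testing.
#' @param universe Character vector of background genes.
#' @return An `ora_result` data frame: `annotation`, `overlap`, `set_size`,
#'   `query_size`, `universe_size`, `odds_ratio`, `p_value`, `q_value`.
#' @export
ora_fisher <- function(query, annotations, universe) {
  qg <- if (inherits(query, "gene_set")) query$genes else unique(as.character(query))
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) os_stop("empty universe")
  if (!all(qg %in% universe)) {
    os_stop("query contains gene(s) outside the universe: ",
            paste(utils::head(setdiff(qg, universe), 5L), collapse = ", "))
  }
  N <- length(universe)
  k <- length(qg)
  rows <- lapply(annotations, function(ann) {
    genes <- intersect(ann$genes, universe)
    K <- length(genes)
    ov <- length(intersect(qg, genes))
    p <- if (K == 0L) 1 else stats::phyper(ov - 1L, K, N - K, k, lower.tail = FALSE)
    a <- ov; b <- k - ov; c_ <- K - ov; d <- N - K - k + ov
    or <- if (b == 0L || c_ == 0L) Inf else (a * d) / (b * c_)
    if (a == 0L) or <- 0
    data.frame(annotation = ann$name, overlap = ov, set_size = K,
               query_size = k, universe_size = N, odds_ratio = or,
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- adjust_bh(out$p_value)
  structure(out, class = c("ora_result", "data.frame"))
}

#' @export
print.ora_result <- function(x, ...) {
  cat(sprintf("ora_result: %d annotation sets, universe %d, query %d\n",
              nrow(x), x$universe_size[1L], x$query_size[1L]))
  ord <- order(x$p_value)
  print.data.frame(utils::head(x[ord, c("annotation", "overlap", "set_size",
                                        "odds_ratio", "p_value", "q_value")], 10L),
                   row.names = FALSE, digits = 4)
  invisible(x)
}
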