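#' Common expressed ortholog universe across call sets
#'
#' Intersects the expressed gene sets of several datasets, bridging species
#' via the one-to-one ortholog map: a gene survives only if it (or its
#' ortholog) is called expressed in every supplied dataset. Genes of the
#' second species without an ortholog are dropped (absence of mapping is
#' not evidence of absence of expression); per-dataset unmappable counts
#' are attached.
#'
#' @param call_sets List of `expression_call` objects (see
#'   [call_expressed()]); each carries its species.
#' @param map An [ortholog_map()] whose `gene_a` column is in
#'   `species_a`'s namespace.
#' @param species_a Species label whose identifiers populate `gene_a`.
#' @return Data frame with columns `gene_a`, `gene_b`: the common universe
#'   in species-A namespace with the B ortholog attached. Attribute
#'   `n_unmappable` records dropped genes per dataset.
#' @export
intersect_expressed <- function(call_sets, map, species_a) {
  if (length(call_sets) < 2L) os_stop("need >= 2 call sets to intersect")
  sizes <- integer(length(call_sets))
  unmappable <- integer(length(call_sets))
  universe <- NULL
  for (i in seq_along(call_sets)) {
    cs <- call_sets[[i]]
    genes_a <- if (identical(cs$species, species_a)) {
      cs$expressed
    } else {
      tr <- orth_b_to_a(cs$expressed, map)
      unmappable[i] <- attr(tr, "n_unmappable")
      tr
    }
    sizes[i] <- length(genes_a)
    universe <- if (is.null(universe)) genes_a else intersect(universe, genes_a)
  }
  if (length(universe) == 0L) {
    labs <- vapply(call_sets, `[[`, character(1), "label")
    os_stop("empty expressed-ortholog intersection; per-dataset sizes (in A namespace): ",
            paste(labs, sizes, sep = "=", collapse = ", "))
  }
  universe <- sort(universe)
  idx <- match(universe, map$gene_a)
  out <- data.frame(gene_a = universe, gene_b = map$gene_b[idx],
                    stringsAsFactors = FALSE)
  names(unmappable) <- vapply(call_sets, `[[`, character(1), "label")
  attr(out, "n_unmappable") <- unmappable
  out
}

#' Rank a profile from highest to lowest expression
#'
#' Rank 1 is the most highly expressed gene; ties receive the average of
#' the spanned ranks. Ranking makes downstream correlation invariant to any
#' strictly monotone transform of the expression scale, which is what lets
#' microarray intensities and tag counts be compared at all.
#'
#' @param profile An [expression_profile()].
#' @param universe Character vector of gene ids (subset of the profile's
#'   genes) defining the common comparison universe and its order.
#' @return A `ranked_profile`: list with `ranks` (named numeric),
#'   `source_label`.
#' @export
rank_profile <- function(profile, universe) {
  missing <- setdiff(universe, names(profile$values))
  if (length(missing)) {
    os_stop("universe gene(s) absent from profile '", profile$label, "': ",
            paste(utils::head(missing, 5L), collapse = ", "))
  }
  r <- rank(-profile$values[universe], ties.method = "average")
  names(r) <- universe
  structure(list(ranks = r, source_label = profile$label),
            class = "ranked_profile")
}

#' Tie-safe Spearman correlation of two ranked profiles
#'
#' Pearson correlation of the rank vectors. The `1 - 6*sum(d^2)/(n(n^2-1))`
#' shortcut is deliberately not used: it is biased under ties, and ties are
#' guaranteed here (zero counts).
#'
#' @param x,y `ranked_profile` objects over the same universe.
#' @return Spearman's rho in `[-1, 1]`.
#' @export
spearman_rho <- function(x, y) {
  if (!setequal(names(x$ranks), names(y$ranks))) {
    os_stop("profiles ranked over different universes")
  }
  xr <- x$ranks
  yr <- y$ranks[names(xr)]
  if (length(xr) < 3L) os_stop("universe size < 3: correlation is meaningless")
  if (stats::sd(xr) == 0 || stats::sd(yr) == 0) {
    os_stop("degenerate profile: all ranks tied")
  }
  stats::cor(xr, yr)
}

#' Stage-similarity matrix of Spearman correlations
#'
#' Computes the common expressed-ortholog universe once across all supplied
#' call sets (so every cell is comparable), ranks every profile on it, and
#' fills the complete grid of Spearman correlations between query profiles
#' (rows) and reference plus control profiles (columns). Control columns
#' (e.g. an adult control organ) separate organ-specific from merely
#' species-specific conservation.
#'
#' @param query_profiles List of [expression_profile()]s (query organ
#'   timepoints).
#' @param reference_profiles List of profiles for the reference
#'   developmental series, in stage order.
#' @param control_profiles Optional list of control-organ profiles.
#' @param call_sets List of `expression_call`s defining the universe (see
#'   [intersect_expressed()]).
#' @param map An [ortholog_map()].
#' @param species_a Species whose namespace is the map's `gene_a` column.
#' @return A `stage_cor_matrix`: list with `rho` (matrix, query rows,
#'   reference + control columns), `n_genes`, `reference_labels`,
#'   `control_labels`.
#' @export
similarity_matrix <- function(query_profiles, reference_profiles,
                              control_profiles = list(),
                              call_sets, map, species_a) {
  universe <- intersect_expressed(call_sets, map, species_a)
  rank_on <- function(p) {
    genes <- if (identical(p$species, species_a)) universe$gene_a else universe$gene_b
    pr <- profile_subset(p, genes)
    rank(-pr, ties.method = "average")
  }
  q <- vapply(query_profiles, rank_on, numeric(nrow(universe)))
  rc <- c(reference_profiles, control_profiles)
  r <- vapply(rc, rank_on, numeric(nrow(universe)))
  colnames(q) <- vapply(query_profiles, `[[`, character(1), "label")
  colnames(r) <- vapply(rc, `[[`, character(1), "label")
  rho <- stats::cor(q, r)  # Pearson on tie-averaged ranks == Spearman
  structure(list(rho = rho, n_genes = nrow(universe),
                 reference_labels = vapply(reference_profiles, `[[`,
                                           character(1), "label"),
                 control_labels = vapply(control_profiles, `[[`,
                                         character(1), "label"),
                 universe = universe),
            class = "stage_cor_matrix")
}

# internal: profile values for the given genes, order preserved
profile_subset <- function(p, genes) {
  missing <- setdiff(genes, names(p$values))
  if (length(missing)) {
    os_stop("profile '", p$label, "' lacks ", length(missing),
            " universe gene(s), e.g. ", missing[1L])
  }
  p$values[genes]
}

#' @export
print.stage_cor_matrix <- function(x, digits = 3, ...) {
  cat(sprintf("stage_cor_matrix: %d query x %d reference/control profiles on %d shared expressed orthologs\n",
              nrow(x$rho), ncol(x$rho), x$n_genes))
  if (length(x$control_labels)) {
    cat("  control columns:", paste(x$control_labels, collapse = ", "), "\n")
  }
  print(round(x$rho, digits))
  invisible(x)
}

#' @export
plot.stage_cor_matrix <- function(x, main = "Stage similarity (Spearman rho)", ...) {
  rho <- x$rho
  image(seq_len(ncol(rho)), seq_len(nrow(rho)), t(rho),
        col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
        axes = FALSE, xlab = "", ylab = "", main = main, ...)
  axis(1, seq_len(ncol(rho)), colnames(rho), las = 2, cex.axis = 0.8)
  axis(2, seq_len(nrow(rho)), rownames(rho), las = 2, cex.axis = 0.8)
  box()
  invisible(x)
}

#' Best-matching reference stage per query profile
#'
#' For each query row (or one named query), the non-control reference
#' column with maximal rho. Exact ties are broken toward the earliest
#' reference stage (column order is stage order) and flagged.
#'
#' @param x A `stage_cor_matrix`.
#' @param query_label Optional single query row label; default all rows.
#' @return Data frame with columns `query`, `best_stage`, `rho`, `tie`.
#' @export
best_matching_stage <- function(x, query_label = NULL) {
  refs <- x$reference_labels
  rows <- if (is.null(query_label)) rownames(x$rho) else query_label
  if (!all(rows %in% rownames(x$rho))) {
    os_stop("query row not found: ", setdiff(rows, rownames(x$rho))[1L])
  }
  out <- lapply(rows, function(qr) {
    v <- x$rho[qr, refs]
    best <- which(v == max(v))
    data.frame(query = qr, best_stage = refs[best[1L]], rho = unname(v[best[1L]]),
               tie = length(best) > 1L, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Reference-vs-control contrast per query profile
#'
#' For each query row, the margin `min(reference rho) - max(control rho)`.
#' A positive margin means the reference series beats the control organ at
#' every stage — evidence of organ-specific rather than merely
#' species-specific conservation. Equality gives margin 0 and `FALSE`
#' (strict inequality).
#'
#' @param x A `stage_cor_matrix` with at least one control column.
#' @return Data frame with columns `query`, `margin`,
#'   `reference_beats_control`.
#' @export
control_contrast <- function(x) {
  if (length(x$control_labels) == 0L) {
    os_stop("no control columns in similarity matrix")
  }
  refs <- x$reference_labels
  ctrl <- x$control_labels
  out <- lapply(rownames(x$rho), function(qr) {
    margin <- min(x$rho[qr, refs]) - max(x$rho[qr, ctrl])
    data.frame(query = qr, margin = margin,
               reference_beats_control = margin > 0,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Long-format export of a stage-similarity matrix
#'
#' @param x A `stage_cor_matrix`.
#' @return Data frame with columns `query`, `reference`, `rho`,
#'   `is_control`, `n_genes`.
#' @export
similarity_long <- function(x) {
  grid <- expand.grid(query = rownames(x$rho), reference = colnames(x$rho),
                      stringsAsFactors = FALSE)
  grid$rho <- x$rho[cbind(grid$query, grid$reference)]
  grid$is_control <- as.integer(grid$reference %in% x$control_labels)
  grid$n_genes <- x$n_genes
  grid
}
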