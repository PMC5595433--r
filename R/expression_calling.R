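#' Construct an expression profile
#'
#' A per-dataset summary: one non-negative mean value per gene, obtained by
#' averaging replicates of one dataset (a species/organ/timepoint
#' combination, or a pooled group of samples).
#'
#' @param values Named non-negative numeric vector (one value per gene).
#' @param label Dataset label, e.g. `"query:placenta:d21"`.
#' @param species Species label the gene namespace belongs to.
#' @return An `expression_profile`.
#' @export
expression_profile <- function(values, label, species) {
  if (is.null(names(values)) || anyDuplicated(names(values))) {
    os_stop("profile values need unique gene names")
  }
  if (anyNA(values) || any(values < 0)) os_stop("profile values must be non-negative and complete")
  structure(list(values = values, label = as.character(label),
                 species = as.character(species)),
            class = "expression_profile")
}

#' @export
print.expression_profile <- function(x, ...) {
  cat(sprintf("expression_profile '%s' (%s): %d genes, grand mean %.4g\n",
              x$label, x$species, length(x$values), mean(x$values)))
  invisible(x)
}

#' Average replicates of one dataset into an expression profile
#'
#' Selects the samples whose metadata match every field of `group` and takes
#' the per-gene arithmetic mean of their columns.
#'
#' @param m A [count_matrix()].
#' @param metadata Metadata data frame (see [read_sample_metadata()]).
#' @param group Named list of metadata filters, e.g.
#'   `list(species = "query", organ = "placenta", timepoint = "d21")`.
#'   Fields set to `NULL` are ignored.
#' @param label Optional profile label; defaults to the group fields joined
#'   by `":"`.
#' @return An [expression_profile()].
#' @export
average_replicates <- function(m, metadata, group, label = NULL) {
  keep <- rep(TRUE, nrow(metadata))
  for (field in names(group)) {
    if (is.null(group[[field]])) next
    if (!field %in% names(metadata)) os_stop("unknown metadata field: ", field)
    keep <- keep & !is.na(metadata[[field]]) & metadata[[field]] %in% group[[field]]
  }
  ids <- intersect(metadata$sample_id[keep], colnames(m))
  if (length(ids) == 0L) {
    os_stop("group selects 0 samples: ",
            paste(names(group), vapply(group, paste, character(1), collapse = "|"),
                  sep = "=", collapse = ", "))
  }
  species <- unique(metadata$species[metadata$sample_id %in% ids])
  if (length(species) != 1L) os_stop("group spans more than one species")
  if (is.null(label)) {
    label <- paste(vapply(group, paste, character(1), collapse = "+"), collapse = ":")
  }
  expression_profile(rowMeans(unclass(m)[, ids, drop = FALSE]), label, species)
}

#' Combine cell-fraction profiles into one tissue profile
#'
#' Per-gene mean of the input profiles (e.g. basal and luminal mammary
#' fractions combined to represent whole-gland function). The mean rather
#' than the sum keeps the result on the same scale as single-fraction
#' datasets; because expression calling is scale-invariant, the choice does
#' not affect the expressed/not-expressed partition.
#'
#' @param profiles List of [expression_profile()] objects sharing one gene
#'   universe and species.
#' @param label Optional label; defaults to the input labels joined by `"+"`.
#' @return An [expression_profile()].
#' @export
combine_cell_fractions <- function(profiles, label = NULL) {
  if (length(profiles) == 0L) os_stop("no profiles to combine")
  if (length(profiles) == 1L) return(profiles[[1L]])
  ref <- names(profiles[[1L]]$values)
  for (p in profiles[-1L]) {
    if (!setequal(names(p$values), ref)) {
      os_stop("mismatched gene universes across cell-fraction profiles")
    }
  }
  species <- unique(vapply(profiles, `[[`, character(1), "species"))
  if (length(species) != 1L) os_stop("cell fractions must come from one species")
  vals <- rowMeans(vapply(profiles, function(p) p$values[ref], numeric(length(ref))))
  names(vals) <- ref
  if (is.null(label)) {
    label <- paste(vapply(profiles, `[[`, character(1), "label"), collapse = "+")
  }
  expression_profile(vals, label, species)
}

#' Call genes expressed or not expressed by the 1%-of-mean rule
#'
#' The dataset-wide grand mean of the per-gene values is computed and genes
#' at or above `fraction` times that grand mean are called expressed; genes
#' strictly below are called not expressed. Equality survives ("below"
#' excludes, so a value exactly at the threshold is expressed). The
#' threshold is per dataset, so the partition is invariant to global
#' rescaling of the profile. An all-zero profile calls every gene not
#' expressed, with a warning: presence on zero evidence would be
#' meaningless even though `0 >= 0`.
#'
#' @param profile An [expression_profile()].
#' @param fraction Threshold fraction of the grand mean; default 0.01.
#' @return An `expression_call` with fields `label`, `species`, `expressed`,
#'   `not_expressed`, `threshold_used`, `fraction`.
#' @export
call_expressed <- function(profile, fraction = 0.01) {
  check_fraction(fraction, "fraction")
  v <- profile$values
  if (length(v) == 0L) os_stop("empty profile")
  grand <- mean(v)
  if (grand == 0) {
    os_warn("all-zero profile '", profile$label, "': every gene called not expressed")
    thr <- 0
    expressed <- character(0)
    not_expressed <- names(v)
  } else {
    thr <- fraction * grand
    expressed <- names(v)[v >= thr]
    not_expressed <- names(v)[v < thr]
  }
  structure(list(label = profile$label, species = profile$species,
                 expressed = expressed, not_expressed = not_expressed,
                 threshold_used = thr, fraction = fraction),
            class = "expression_call")
}

#' @export
print.expression_call <- function(x, ...) {
  cat(sprintf("expression_call '%s' (%s): %d expressed / %d not (threshold %.4g)\n",
              x$label, x$species, length(x$expressed), length(x$not_expressed),
              x$threshold_used))
  invisible(x)
}

#' Export an expression call set as a two-column table
#'
#' @param call An `expression_call`.
#' @return Data frame with columns `gene` and `expressed` (0/1).
#' @export
call_table <- function(call) {
  genes <- c(call$expressed, call$not_expressed)
  data.frame(gene = genes,
             expressed = as.integer(genes %in% call$expressed),
             stringsAsFactors = FALSE)
}

#' Convert an expression call set to a gene set of expressed genes
#'
#' @param call An `expression_call`.
#' @return A [gene_set()] of the expressed genes.
#' @export
call_gene_set <- function(call) {
  gene_set(call$label, call$expressed,
           sprintf("expressed at >= %g of grand mean", call$fraction))
}
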