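#' Construct a count matrix
#'
#' A `count_matrix` is a plain numeric matrix (genes in rows, samples in
#' columns) carrying a `platform` attribute: `"tag_count"` for 3'-tag style
#' read counts (one read per transcript, no length normalisation) or
#' `"microarray"` for intensity-scale values. Values must be non-negative
#' and complete; gene and sample identifiers must be unique. Missing values
#' are an error, never imputed: the downstream analysis is presence- and
#' rank-based, and silent imputation would corrupt ranks.
#'
#' @param values Numeric matrix with unique rownames (genes) and colnames
#'   (samples).
#' @param platform `"tag_count"` or `"microarray"`.
#' @return A `count_matrix` object.
#' @export
count_matrix <- function(values, platform = c("tag_count", "microarray")) {
  platform <- match.arg(platform)
  if (!is.matrix(values) || !is.numeric(values)) {
    os_stop("`values` must be a numeric matrix")
  }
  if (nrow(values) == 0L) os_stop("no genes parsed: count matrix has zero rows")
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    os_stop("count matrix needs gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(values))) {
    dup <- unique(rownames(values)[duplicated(rownames(values))])
    os_stop("duplicate gene id: ", paste(dup, collapse = ", "))
  }
  if (anyDuplicated(colnames(values))) {
    dup <- unique(colnames(values)[duplicated(colnames(values))])
    os_stop("duplicate sample id: ", paste(dup, collapse = ", "))
  }
  if (anyNA(values)) os_stop("missing expression value (NA); missing cells are errors, not imputed")
  if (any(values < 0)) os_stop("negative expression value")
  structure(values, platform = platform, class = c("count_matrix", "matrix", "array"))
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples [%s]\n",
              nrow(x), ncol(x), attr(x, "platform")))
  cat("total signal:", format(sum(x)), "\n")
  invisible(x)
}

#' Platform tag of a count matrix
#' @param x A `count_matrix`.
#' @return `"tag_count"` or `"microarray"`.
#' @export
platform <- function(x) attr(x, "platform") %||% "tag_count"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a gene-by-sample count table
#'
#' Expects a tab-separated file whose first column holds gene identifiers
#' and whose header row holds sample identifiers. Gene identifiers are
#' treated as opaque case-sensitive strings; no symbol conversion is
#' attempted. Ragged rows, duplicate gene ids, negative or missing values
#' are hard errors.
#'
#' @param path File path.
#' @param platform `"tag_count"` or `"microarray"`.
#' @return A [count_matrix()].
#' @export
read_count_matrix <- function(path, platform = c("tag_count", "microarray")) {
  platform <- match.arg(platform)
  if (!file.exists(path)) os_stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) os_stop("no genes parsed from ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  width <- length(header)
  if (width < 2L) os_stop("no sample columns in ", path)
  body <- fields[-1L]
  widths <- lengths(body)
  if (any(widths != width)) {
    os_stop(sprintf("ragged row in %s: line %d has %d fields, expected %d",
                    path, which(widths != width)[1L] + 1L,
                    widths[widths != width][1L], width))
  }
  genes <- vapply(body, `[[`, character(1), 1L)
  vals <- matrix(NA_real_, nrow = length(body), ncol = width - 1L,
                 dimnames = list(genes, header[-1L]))
  for (j in seq_len(width - 1L)) {
    col <- vapply(body, `[[`, character(1), j + 1L)
    num <- suppressWarnings(as.numeric(col))
    if (anyNA(num)) {
      os_stop(sprintf("non-numeric or missing value '%s' in %s column %s",
                      col[is.na(num)][1L], path, header[j + 1L]))
    }
    vals[, j] <- num
  }
  m <- count_matrix(vals, platform)
  message(sprintf("read %d genes x %d samples from %s [%s]",
                  nrow(m), ncol(m), path, platform))
  m
}

#' Read a sample-metadata table
#'
#' Tab-separated with required columns `sample_id`, `species`, `organ`,
#' `replicate` and optional `tissue_compartment`, `timepoint`. Replicates
#' are 1-based integers; `sample_id` must be unique.
#'
#' @param path File path.
#' @return A data frame of per-sample metadata.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) os_stop("file not found: ", path)
  md <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("sample_id", "species", "organ", "replicate")
  missing <- setdiff(required, names(md))
  if (length(missing)) {
    os_stop("metadata missing required column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(md$sample_id)) {
    os_stop("duplicate sample_id in metadata: ",
            paste(unique(md$sample_id[duplicated(md$sample_id)]), collapse = ", "))
  }
  if (anyNA(md$replicate) || any(md$replicate < 1) ||
      any(md$replicate != round(md$replicate))) {
    os_stop("replicate must be an integer >= 1")
  }
  for (opt in c("tissue_compartment", "timepoint")) {
    if (!opt %in% names(md)) md[[opt]] <- NA_character_
  }
  md
}

#' Construct a one-to-one ortholog map
#'
#' Pairs of (species-A gene, species-B gene). Strictly one-to-one: a gene
#' appearing in more than one pair on either side is rejected. Resolving
#' multi-mapping orthology is deliberately out of scope; the map supplied
#' by the user carries that burden.
#'
#' @param gene_a,gene_b Character vectors of equal length.
#' @return An `ortholog_map` (data frame with columns `gene_a`, `gene_b`).
#' @export
ortholog_map <- function(gene_a, gene_b) {
  gene_a <- as.character(gene_a)
  gene_b <- as.character(gene_b)
  if (length(gene_a) != length(gene_b)) os_stop("gene_a and gene_b differ in length")
  for (side in list(gene_a, gene_b)) {
    if (anyDuplicated(side)) {
      os_stop("non-unique mapping for ",
              paste(unique(side[duplicated(side)]), collapse = ", "))
    }
  }
  structure(data.frame(gene_a = gene_a, gene_b = gene_b,
                       stringsAsFactors = FALSE),
            class = c("ortholog_map", "data.frame"))
}

#' Read a two-column ortholog map
#'
#' @param path Path to a headerless two-column TSV (species-A gene,
#'   species-B gene).
#' @return An [ortholog_map()]. An empty file yields a size-0 map with a
#'   warning.
#' @export
read_ortholog_map <- function(path) {
  if (!file.exists(path)) os_stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    os_warn("empty ortholog map: ", path)
    return(ortholog_map(character(0), character(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) != 2L)) {
    os_stop("ortholog map must have exactly 2 tab-separated columns (line ",
            which(lengths(fields) != 2L)[1L], ")")
  }
  ortholog_map(vapply(fields, `[[`, character(1), 1L),
               vapply(fields, `[[`, character(1), 2L))
}

#' Translate gene identifiers across the ortholog map
#'
#' Genes without an ortholog are dropped (absence of a mapping is not
#' evidence about expression); the number dropped is attached as the
#' `n_unmappable` attribute.
#'
#' @param genes Character vector of gene ids.
#' @param map An [ortholog_map()].
#' @return Character vector of ortholog ids in the other namespace, with
#'   attribute `n_unmappable`.
#' @name orth-translate
NULL

#' @rdname orth-translate
#' @export
orth_a_to_b <- function(genes, map) {
  idx <- match(genes, map$gene_a)
  out <- map$gene_b[idx[!is.na(idx)]]
  attr(out, "n_unmappable") <- sum(is.na(idx))
  out
}

#' @rdname orth-translate
#' @export
orth_b_to_a <- function(genes, map) {
  idx <- match(genes, map$gene_b)
  out <- map$gene_a[idx[!is.na(idx)]]
  attr(out, "n_unmappable") <- sum(is.na(idx))
  out
}

#' Construct a gene set
#'
#' @param name Set label.
#' @param genes Character vector; duplicates are collapsed.
#' @param description Free-text description.
#' @return A `gene_set` (list with `name`, `description`, `genes`).
#' @export
gene_set <- function(name, genes, description = "") {
  genes <- as.character(genes)
  structure(list(name = as.character(name),
                 description = as.character(description),
                 genes = unique(genes)),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("gene_set '%s' (%d genes): %s\n", x$name, length(x$genes),
              paste(utils::head(x$genes, 5L), collapse = ", ")))
  invisible(x)
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then gene ids, tab-separated.
#' Duplicate genes within a line are collapsed with a warning; a line with
#' fewer than three fields is a hard error.
#'
#' @param path File path.
#' @return Named list of [gene_set()] objects, preserving file order.
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) os_stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) {
      os_stop(sprintf("GMT line %d has %d fields; need name, description and >= 1 gene",
                      i, length(f)))
    }
    genes <- f[-(1:2)]
    if (anyDuplicated(genes)) {
      os_warn(sprintf("GMT set '%s': %d duplicate gene(s) collapsed",
                      f[1L], sum(duplicated(genes))))
    }
    out[[i]] <- gene_set(f[1L], genes, f[2L])
  }
  names(out) <- vapply(out, `[[`, character(1), "name")
  out
}

#' Write gene sets in GMT format
#'
#' @param sets List of [gene_set()] objects.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gene_sets <- function(sets, path) {
  lines <- vapply(sets, function(s) {
    paste(c(s$name, s$description, s$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a result table as TSV
#'
#' Deterministic: columns in the order given, tab-separated, no quoting,
#' full double precision (15 significant digits) so a write-read round trip
#' reproduces values to better than 1e-12 relative error. Byte-identical
#' output for identical input.
#'
#' @param rows A data frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_result_table <- function(rows, path) {
  if (!is.data.frame(rows)) os_stop("`rows` must be a data.frame")
  dir <- dirname(path)
  if (!dir.exists(dir)) os_stop("unwritable path (no such directory): ", dir)
  out <- rows
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]])) {
      out[[j]] <- vapply(out[[j]], function(v) {
        if (is.na(v)) "NA" else format(v, digits = 15, scientific = NA, trim = TRUE)
      }, character(1))
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}

#' Write a count matrix as TSV
#'
#' Inverse of [read_count_matrix()]: first column `gene`, one column per
#' sample.
#'
#' @param m A [count_matrix()] (or numeric matrix with dimnames).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_count_matrix <- function(m, path) {
  df <- data.frame(gene = rownames(m), as.data.frame(unclass(m)[, , drop = FALSE]),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_result_table(df, path)
}
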