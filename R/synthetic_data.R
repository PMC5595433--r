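#' Simulation configuration
#'
#' Parameters of the two-species, multi-organ, multi-timepoint synthetic
#' expression study. The defaults encode the study design the package is
#' built around: a marsupial-like query species with a short 3'-tag count
#' placenta series (two compartments, three gestational days, 4 + 6
#' samples) and lactating mammary timepoints, and a eutherian-like
#' reference species with a microarray developmental placenta series plus
#' tag-count organ datasets (placenta, mammary basal/luminal fractions,
#' liver, testis, heart). Planted set sizes mirror the scale of the
#' biological programs being emulated: 300-gene organ programs, a 340-gene
#' early and 70-gene late placenta-specific program (of which the query
#' expresses 90 and 10 ortholog subsets), a 77-gene co-opted set and a
#' 108-gene reference-placenta-only set.
#'
#' @param n_genes Number of ortholog pairs (default 5000).
#' @param n_replicates Replicates per plain organ dataset (default 3).
#' @param library_size Mean tag-count library size (default 1e6).
#' @param library_size_cv Coefficient of variation of library size.
#' @param dispersion_range NB dispersion `alpha` range, `Var = mu + alpha
#'   mu^2` (default 0.05-0.5, gene-wise uniform).
#' @param organ_program_size Genes per organ-specific program.
#' @param early_size,late_size Early/late placenta-specific program sizes.
#' @param query_early,query_late How many early/late program genes the
#'   query placenta expresses (defaults 90 and 10).
#' @param coopted_size Planted convergently co-opted set size (default 77).
#' @param eutherian_only_size Planted reference-placenta + query-mammary
#'   set size (default 108).
#' @param n_de_genes Planted differentially expressed genes per contrast.
#' @param de_log2fc True absolute log2 fold change (default 2, i.e.
#'   4-fold), half up, half down.
#' @param baseline_log_mean,baseline_log_sd Gene baseline log-expression
#'   distribution (natural log; defaults log(50) and 0.8, i.e. roughly a
#'   100-fold active dynamic range, keeping the active lower tail clear of
#'   the 1%-of-mean presence threshold).
#' @param stage_decorrelation Per-stage sd of the log-mean random walk that
#'   decorrelates successive reference stages (default 0.4).
#' @param organ_effect_sd Sd of per-(gene, organ) log effects that make
#'   organs transcriptionally distinct (default 0.8: perturbs ranks across
#'   organs without routinely carrying active genes across the presence
#'   threshold).
#' @param timepoint_effect_sd Sd of per-(gene, timepoint) deviations of the
#'   query series from its planted reference stage (default 0.3).
#' @param silenced_factor Silenced NB mean as a fraction of the gene's
#'   active mean (default 1e-3, i.e. 0.1%): not structurally zero, so the
#'   1%-of-mean rule's boundary stays exercised.
#' @param microarray_offset,microarray_scale,microarray_sd Affine-log
#'   transform and Gaussian noise of the microarray intensities: intensity
#'   `= offset + scale * log2(mean + 1) + N(0, sd)`.
#' @param reference_stages Ordered reference stage labels.
#' @param late_from First stage of the "late" half of the series.
#' @param query_stage_map Named character: planted reference stage for each
#'   query placenta timepoint.
#' @param species_query,species_reference Species labels.
#' @param seed Master seed; every simulated sample derives its own RNG
#'   stream from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 5000,
                       n_replicates = 3,
                       library_size = 1e6,
                       library_size_cv = 0.2,
                       dispersion_range = c(0.05, 0.5),
                       organ_program_size = 300,
                       early_size = 340,
                       late_size = 70,
                       query_early = 90,
                       query_late = 10,
                       coopted_size = 77,
                       eutherian_only_size = 108,
                       n_de_genes = 200,
                       de_log2fc = 2,
                       baseline_log_mean = log(50),
                       baseline_log_sd = 0.8,
                       stage_decorrelation = 0.4,
                       organ_effect_sd = 0.8,
                       timepoint_effect_sd = 0.3,
                       silenced_factor = 1e-3,
                       microarray_offset = 4,
                       microarray_scale = 1.2,
                       microarray_sd = 0.25,
                       reference_stages = c("e8.0", "e9.5", "e10.5", "e12.5",
                                            "e15.0", "e17.0", "e19.0", "term"),
                       late_from = "e12.5",
                       query_stage_map = c(d21 = "e10.5", d23 = "e10.5",
                                           d25 = "e10.5"),
                       species_query = "marsupial",
                       species_reference = "eutherian",
                       seed = 1) {
  cfg <- as.list(environment())
  organs <- c("placenta", "mammary", "liver", "testis", "heart")
  planted <- length(organs) * organ_program_size + early_size + late_size +
    coopted_size + eutherian_only_size + 2L * n_de_genes
  if (planted >= n_genes) {
    os_stop(sprintf("infeasible sizes: planted sets need %d genes but n_genes = %d",
                    planted, n_genes))
  }
  for (nm in c("library_size", "library_size_cv", "stage_decorrelation",
               "baseline_log_sd", "organ_effect_sd", "timepoint_effect_sd",
               "microarray_sd")) {
    if (cfg[[nm]] < 0) os_stop("`", nm, "` must be non-negative")
  }
  check_fraction(silenced_factor, "silenced_factor")
  if (any(dispersion_range <= 0) || diff(dispersion_range) < 0) {
    os_stop("dispersion_range must be positive and increasing")
  }
  if (!late_from %in% reference_stages) os_stop("late_from not in reference_stages")
  if (!all(query_stage_map %in% reference_stages)) {
    os_stop("query_stage_map points at unknown reference stage(s)")
  }
  if (query_early > early_size || query_late > late_size) {
    os_stop("query-expressed program subsets exceed program sizes")
  }
  cfg$organs <- organs
  structure(cfg, class = "sim_config")
}

#' Generate planted ground truth
#'
#' Deterministically (given the config seed) assigns every ortholog pair a
#' role — housekeeping, one organ-specific program, the early or late
#' placenta-specific program, the co-opted set, the reference-placenta-only
#' set, or a planted DE gene — and draws all latent quantities: gene
#' baselines, NB dispersions, the stage-wise log-mean random walk of the
#' reference series, organ effects and query timepoint effects.
#'
#' @param config A [sim_config()].
#' @return A `synthetic_truth` list; planted sets are pairwise disjoint and
#'   every planted gene has an ortholog.
#' @export
generate_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_genes
  with_seed(stream_seed(config$seed, "truth"), {
    gene_a <- sprintf("mar%05d", seq_len(n))
    gene_b <- sprintf("eut%05d", seq_len(n))
    map <- ortholog_map(gene_a, gene_b)

    role <- rep("hk", n)
    pool <- sample.int(n)
    take <- function(k) {
      idx <- pool[seq_len(k)]
      pool <<- pool[-seq_len(k)]
      idx
    }
    organ_idx <- lapply(config$organs, function(o) take(config$organ_program_size))
    names(organ_idx) <- config$organs
    for (o in config$organs) role[organ_idx[[o]]] <- paste0("organ:", o)
    early_idx <- take(config$early_size); role[early_idx] <- "early"
    late_idx <- take(config$late_size); role[late_idx] <- "late"
    coopt_idx <- take(config$coopted_size); role[coopt_idx] <- "coopted"
    eo_idx <- take(config$eutherian_only_size); role[eo_idx] <- "eutherian_only"
    dec_idx <- take(config$n_de_genes); role[dec_idx] <- "de_compartment"
    des_idx <- take(config$n_de_genes); role[des_idx] <- "de_stage"

    query_early_idx <- sort(sample(early_idx, config$query_early))
    query_late_idx <- sort(sample(late_idx, config$query_late))

    baseline_log <- stats::rnorm(n, config$baseline_log_mean, config$baseline_log_sd)
    dispersion <- stats::runif(n, config$dispersion_range[1L],
                               config$dispersion_range[2L])
    S <- length(config$reference_stages)
    steps <- matrix(stats::rnorm(n * S, 0, config$stage_decorrelation), n, S)
    stage_logmean <- baseline_log + t(apply(steps, 1L, cumsum))
    colnames(stage_logmean) <- config$reference_stages
    organ_effect <- matrix(stats::rnorm(n * length(config$organs), 0,
                                        config$organ_effect_sd),
                           n, length(config$organs),
                           dimnames = list(NULL, config$organs))
    tps <- unique(c(names(config$query_stage_map), c("d36", "d60", "d95")))
    tp_effect <- matrix(stats::rnorm(n * length(tps), 0,
                                     config$timepoint_effect_sd),
                        n, length(tps), dimnames = list(NULL, tps))

    sign_c <- rep(c(1, -1), length.out = config$n_de_genes)
    sign_s <- rep(c(1, -1), length.out = config$n_de_genes)
    de_truth <- rbind(
      data.frame(gene_a = gene_a[dec_idx], contrast = "compartment",
                 log2fc = sign_c * config$de_log2fc, stringsAsFactors = FALSE),
      data.frame(gene_a = gene_a[des_idx], contrast = "stage",
                 log2fc = sign_s * config$de_log2fc, stringsAsFactors = FALSE))

    structure(list(
      config = config, map = map, gene_a = gene_a, gene_b = gene_b,
      role = role,
      organ_programs = lapply(config$organs, function(o) {
        gene_set(paste0("organ_", o), gene_a[organ_idx[[o]]],
                 paste0(o, "-specific program"))
      }) |> stats::setNames(config$organs),
      stage_programs = list(
        early = gene_set("early_placenta", gene_b[early_idx],
                         "reference placenta-specific, pre-midgestation"),
        late = gene_set("late_placenta", gene_b[late_idx],
                        "reference placenta-specific, post-midgestation")),
      query_early = gene_a[query_early_idx],
      query_late = gene_a[query_late_idx],
      coopted = gene_set("coopted", gene_a[coopt_idx],
                         "expressed in both placentas and query mammary, silent in reference mammary"),
      eutherian_only = gene_set("eutherian_only", gene_a[eo_idx],
                                "expressed in reference placenta and query mammary only"),
      de_truth = de_truth,
      baseline_log = baseline_log, dispersion = dispersion,
      stage_logmean = stage_logmean, organ_effect = organ_effect,
      tp_effect = tp_effect,
      seed = config$seed), class = "synthetic_truth")
  })
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("synthetic_truth: %d ortholog pairs (seed %d)\n",
              length(x$gene_a), x$seed))
  cat("  roles:", paste(names(table(x$role)), table(x$role),
                        sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# internal: stage index helper
stage_index <- function(config, stage) match(stage, config$reference_stages)

# internal: logical expressed-in vector over the A-indexed gene universe
expressed_in <- function(truth, species, organ, timepoint = NULL) {
  cfg <- truth$config
  role <- truth$role
  n <- length(role)
  on <- role %in% c("hk", "de_compartment", "de_stage")
  on <- on | role == paste0("organ:", organ)
  is_query <- identical(species, cfg$species_query)
  if (organ == "placenta") {
    if (is_query) {
      on <- on | truth$gene_a %in% truth$query_early
      on <- on | truth$gene_a %in% truth$query_late
      on <- on | role == "coopted"
    } else {
      boundary <- stage_index(cfg, cfg$late_from)
      si <- stage_index(cfg, timepoint %||% "term")
      if (is.na(si)) os_stop("unknown reference stage: ", timepoint)
      if (si < boundary) on <- on | role == "early" else on <- on | role == "late"
      on <- on | role == "coopted"
      on <- on | role == "eutherian_only"
    }
  }
  if (organ == "mammary" && is_query) {
    on <- on | role == "coopted"
    on <- on | role == "eutherian_only"
  }
  on
}

# internal: relative NB means for one dataset; silenced genes sit at
# silenced_factor times their own active mean
relative_means <- function(truth, species, organ, timepoint = NULL,
                           compartment = NULL) {
  cfg <- truth$config
  is_query <- identical(species, cfg$species_query)
  if (organ == "placenta" && is_query) {
    stage <- cfg$query_stage_map[[timepoint]]
    lm <- truth$stage_logmean[, stage] + truth$tp_effect[, timepoint]
    stage_group <- if (timepoint %in% c("d25")) "late" else "early"
    de <- truth$de_truth
    half <- log(2) / 2
    idx_c <- match(de$gene_a[de$contrast == "compartment"], truth$gene_a)
    fc_c <- de$log2fc[de$contrast == "compartment"]
    if (!is.null(compartment)) {
      lm[idx_c] <- lm[idx_c] + ifelse(compartment == "TOM", half, -half) * fc_c
    }
    idx_s <- match(de$gene_a[de$contrast == "stage"], truth$gene_a)
    fc_s <- de$log2fc[de$contrast == "stage"]
    lm[idx_s] <- lm[idx_s] + ifelse(stage_group == "late", half, -half) * fc_s
  } else if (organ == "placenta") {
    lm <- truth$stage_logmean[, timepoint %||% "term"]
  } else {
    tp_adj <- if (!is.null(timepoint) && timepoint %in% colnames(truth$tp_effect)) {
      truth$tp_effect[, timepoint]
    } else 0
    lm <- truth$baseline_log + truth$organ_effect[, organ] + tp_adj
  }
  mu <- exp(lm)
  on <- expressed_in(truth, species, organ, timepoint)
  mu[!on] <- mu[!on] * cfg$silenced_factor
  mu
}

#' Simulate one tag-count dataset
#'
#' Negative-binomial counts (mean = library size times the gene's relative
#' expression given its planted role; gene-wise dispersion) for one
#' (species, organ, timepoint, compartment) dataset. Fully deterministic:
#' each replicate draws from its own RNG stream derived from the master
#' seed and the sample's identity, so regenerating a replicate reproduces
#' it exactly and different replicates differ.
#'
#' @param truth A `synthetic_truth`.
#' @param species,organ,timepoint,compartment Dataset identity (timepoint
#'   and compartment optional).
#' @param n_replicates Number of replicates; defaults to the config value.
#' @return List with `counts` (a tag-count [count_matrix()]) and `metadata`
#'   rows.
#' @export
simulate_count_dataset <- function(truth, species, organ, timepoint = NULL,
                                   compartment = NULL, n_replicates = NULL) {
  cfg <- truth$config
  n_replicates <- n_replicates %||% cfg$n_replicates
  mu_rel <- relative_means(truth, species, organ, timepoint, compartment)
  mu_rel <- mu_rel / sum(mu_rel)
  sdlog <- sqrt(log(1 + cfg$library_size_cv^2))
  cols <- matrix(0, length(mu_rel), n_replicates)
  ids <- character(n_replicates)
  for (r in seq_len(n_replicates)) {
    id <- paste(c(species, organ, timepoint, compartment, paste0("rep", r)),
                collapse = "_")
    ids[r] <- id
    cols[, r] <- with_seed(
      stream_seed(cfg$seed, "counts", species, organ,
                  timepoint %||% "", compartment %||% "", r), {
        lib <- stats::rlnorm(1, log(cfg$library_size) - sdlog^2 / 2, sdlog)
        stats::rnbinom(length(mu_rel), mu = lib * mu_rel,
                       size = 1 / truth$dispersion)
      })
  }
  genes <- if (identical(species, cfg$species_query)) truth$gene_a else truth$gene_b
  dimnames(cols) <- list(genes, ids)
  md <- data.frame(sample_id = ids, species = species, organ = organ,
                   tissue_compartment = compartment %||% NA_character_,
                   timepoint = timepoint %||% NA_character_,
                   replicate = seq_len(n_replicates),
                   stringsAsFactors = FALSE)
  list(counts = count_matrix(cols, "tag_count"), metadata = md)
}

#' Simulate the query placenta compartment/stage design
#'
#' Ten tag-count samples over two compartments (BOM-like avascular, 4
#' samples; TOM-like vascularised, 6 samples) and three gestational
#' timepoints (d21, d23 early; d25 late: 4 early vs 6 late), the pooling
#' design under which both two-group contrasts have replication.
#'
#' @param truth A `synthetic_truth`.
#' @return List with `counts` (genes x 10) and `metadata`.
#' @export
simulate_query_placenta <- function(truth) {
  design <- data.frame(
    compartment = c("BOM", "BOM", "BOM", "BOM", "TOM", "TOM", "TOM",
                    "TOM", "TOM", "TOM"),
    timepoint = c("d21", "d23", "d25", "d25", "d21", "d23", "d25", "d25",
                  "d25", "d25"),
    replicate = c(1L, 1L, 1L, 2L, 1L, 1L, 1L, 2L, 3L, 4L),
    stringsAsFactors = FALSE)
  sp <- truth$config$species_query
  parts <- lapply(seq_len(nrow(design)), function(i) {
    d <- design[i, ]
    one <- simulate_count_dataset(truth, sp, "placenta", d$timepoint,
                                  d$compartment, n_replicates = d$replicate)
    list(col = unclass(one$counts)[, d$replicate],
         md = one$metadata[d$replicate, ])
  })
  cols <- vapply(parts, `[[`, numeric(length(truth$gene_a)), "col")
  md <- do.call(rbind, lapply(parts, `[[`, "md"))
  rownames(md) <- NULL
  dimnames(cols) <- list(truth$gene_a, md$sample_id)
  list(counts = count_matrix(cols, "tag_count"), metadata = md)
}

#' Simulate the reference microarray developmental series
#'
#' One intensity column per reference stage: an affine-log (strictly
#' monotone) transform of the underlying stage means plus Gaussian noise.
#' Early-program genes are active only before the midgestation boundary
#' and late-program genes only from it on; housekeeping genes drift by the
#' configured random walk, so adjacent stages are more rank-correlated
#' than distant ones. The deliberate monotone distortion of the scale is
#' what forces the rank-based pipeline to prove platform invariance.
#'
#' @param truth A `synthetic_truth`.
#' @return List with `counts` (a microarray [count_matrix()], one column
#'   per stage) and `metadata` (one row per stage, `timepoint` = stage).
#' @export
simulate_reference_series <- function(truth) {
  cfg <- truth$config
  stages <- cfg$reference_stages
  cols <- vapply(stages, function(s) {
    mu <- relative_means(truth, cfg$species_reference, "placenta", s)
    with_seed(stream_seed(cfg$seed, "series", s), {
      pmax(cfg$microarray_offset + cfg$microarray_scale * log2(mu + 1) +
             stats::rnorm(length(mu), 0, cfg$microarray_sd), 0)
    })
  }, numeric(length(truth$gene_b)))
  ids <- paste0("series_", stages)
  dimnames(cols) <- list(truth$gene_b, ids)
  md <- data.frame(sample_id = ids, species = cfg$species_reference,
                   organ = "placenta", tissue_compartment = NA_character_,
                   timepoint = stages, replicate = 1L,
                   stringsAsFactors = FALSE)
  list(counts = count_matrix(cols, "microarray"), metadata = md)
}

#' Simulate the full two-species study
#'
#' All datasets the pipeline consumes: the query placenta design, query
#' mammary timepoints, query liver and testis, reference placenta (term),
#' reference mammary basal and luminal fractions, reference liver, testis
#' and heart, plus the reference microarray series.
#'
#' @param truth A `synthetic_truth`.
#' @return List with `counts` (named list of [count_matrix()]), `series`
#'   (microarray matrix) and `metadata` (all samples combined).
#' @export
simulate_study <- function(truth) {
  cfg <- truth$config
  q <- cfg$species_query
  r <- cfg$species_reference
  qp <- simulate_query_placenta(truth)
  mam <- lapply(c("d36", "d60", "d95"), function(tp) {
    simulate_count_dataset(truth, q, "mammary", tp, n_replicates = 2)
  })
  qm <- list(
    counts = count_matrix(do.call(cbind, lapply(mam, function(x) unclass(x$counts))),
                          "tag_count"),
    metadata = do.call(rbind, lapply(mam, `[[`, "metadata")))
  sets <- list(
    query_placenta = qp,
    query_mammary = qm,
    query_liver = simulate_count_dataset(truth, q, "liver"),
    query_testis = simulate_count_dataset(truth, q, "testis"),
    reference_placenta = simulate_count_dataset(truth, r, "placenta", "term"),
    reference_mammary_basal = simulate_count_dataset(truth, r, "mammary",
                                                     compartment = "basal"),
    reference_mammary_luminal = simulate_count_dataset(truth, r, "mammary",
                                                       compartment = "luminal"),
    reference_liver = simulate_count_dataset(truth, r, "liver"),
    reference_testis = simulate_count_dataset(truth, r, "testis"),
    reference_heart = simulate_count_dataset(truth, r, "heart"))
  series <- simulate_reference_series(truth)
  metadata <- rbind(do.call(rbind, lapply(sets, `[[`, "metadata")),
                    series$metadata)
  rownames(metadata) <- NULL
  list(counts = lapply(sets, `[[`, "counts"), series = series$counts,
       metadata = metadata)
}

#' Export a synthetic study as a loadable fixture tree
#'
#' Writes every dataset as TSV, the ortholog map, the early/late program
#' GMT, an annotation GMT (organ programs and planted sets), the planted
#' truth as JSON, and a ready-to-run pipeline configuration YAML. Re-export
#' with the same truth is byte-identical.
#'
#' @param truth A `synthetic_truth`.
#' @param dir Output directory (created if needed).
#' @param study Optional pre-simulated [simulate_study()] result.
#' @return Invisibly, the path of the written `config.yaml`.
#' @export
export_fixture <- function(truth, dir, study = NULL) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE)) {
    os_stop("unwritable path: ", dir)
  }
  study <- study %||% simulate_study(truth)
  dir.create(file.path(dir, "counts"), showWarnings = FALSE)
  ds_entries <- list()
  for (nm in names(study$counts)) {
    rel <- file.path("counts", paste0(nm, ".tsv"))
    write_count_matrix(study$counts[[nm]], file.path(dir, rel))
    ds_entries[[nm]] <- list(role = nm, counts = rel, platform = "tag_count")
  }
  write_count_matrix(study$series, file.path(dir, "series.tsv"))
  ds_entries[["reference_series"]] <- list(role = "reference_series",
                                           counts = "series.tsv",
                                           platform = "microarray")
  write_result_table(study$metadata, file.path(dir, "metadata.tsv"))
  # ortholog map is headerless on disk
  map_lines <- paste(truth$map$gene_a, truth$map$gene_b, sep = "\t")
  writeLines(map_lines, file.path(dir, "ortholog_map.tsv"))
  write_gene_sets(truth$stage_programs, file.path(dir, "programs.gmt"))
  ann <- c(truth$organ_programs,
           list(coopted = truth$coopted, eutherian_only = truth$eutherian_only))
  write_gene_sets(ann, file.path(dir, "annotations.gmt"))
  truth_json <- list(
    seed = truth$seed,
    query_stage_map = as.list(truth$config$query_stage_map),
    query_early = truth$query_early,
    query_late = truth$query_late,
    coopted = truth$coopted$genes,
    eutherian_only = truth$eutherian_only$genes,
    de_truth = truth$de_truth,
    organ_programs = lapply(truth$organ_programs, `[[`, "genes"),
    stage_programs = lapply(truth$stage_programs, `[[`, "genes"))
  jsonlite::write_json(truth_json, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  cfg <- truth$config
  roles <- c("query_placenta", "query_mammary", "reference_placenta",
             "reference_mammary_basal", "reference_mammary_luminal",
             "reference_series", "control_query_liver",
             "control_reference_liver", "control_query_testis",
             "control_reference_testis", "stage_control")
  role_src <- c(query_placenta = "query_placenta",
                query_mammary = "query_mammary",
                reference_placenta = "reference_placenta",
                reference_mammary_basal = "reference_mammary_basal",
                reference_mammary_luminal = "reference_mammary_luminal",
                reference_series = "reference_series",
                control_query_liver = "query_liver",
                control_reference_liver = "reference_liver",
                control_query_testis = "query_testis",
                control_reference_testis = "reference_testis",
                stage_control = "reference_heart")
  datasets <- lapply(roles, function(role) {
    e <- ds_entries[[role_src[[role]]]]
    list(role = role, counts = e$counts, platform = e$platform)
  })
  config <- list(
    seed = truth$seed,
    species = list(query = cfg$species_query, reference = cfg$species_reference),
    parameters = list(expression_fraction = 0.01, de_alpha = 0.05,
                      yates = FALSE, allow_missing_control = FALSE),
    paths = list(metadata = "metadata.tsv", ortholog_map = "ortholog_map.tsv",
                 programs_gmt = "programs.gmt",
                 annotations_gmt = "annotations.gmt"),
    stage_split = list(early = c("d21", "d23"), late = "d25"),
    datasets = datasets)
  yaml::write_yaml(config, file.path(dir, "config.yaml"))
  invisible(file.path(dir, "config.yaml"))
}
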