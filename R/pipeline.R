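PIPELINE_ROLES <- c("query_placenta", "query_mammary", "reference_placenta",
                    "reference_mammary_basal", "reference_mammary_luminal",
                    "reference_series", "stage_control",
                    "control_query_liver", "control_reference_liver",
                    "control_query_testis", "control_reference_testis")

#' Validate a pipeline configuration file
#'
#' Reads a YAML configuration, checks every declared dataset role, path and
#' parameter, and reports *all* problems at once rather than failing on the
#' first. Relative paths are resolved against the config file's directory.
#'
#' @param path Path to a YAML config (see the fixture written by
#'   [export_fixture()] for the schema).
#' @return A validated `pipeline_config` list.
#' @export
validate_config <- function(path) {
  if (!file.exists(path)) os_stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  errs <- character(0)
  add_err <- function(...) errs <<- c(errs, paste0(...))

  for (key in c("species", "parameters", "paths", "stage_split", "datasets")) {
    if (is.null(cfg[[key]])) add_err("missing top-level key: ", key)
  }
  if (length(errs)) os_stop("invalid config:\n  - ", paste(errs, collapse = "\n  - "))

  for (sp in c("query", "reference")) {
    if (is.null(cfg$species[[sp]])) add_err("species: missing '", sp, "' label")
  }
  p <- cfg$parameters
  frac <- p$expression_fraction %||% 0.01
  alpha <- p$de_alpha %||% 0.05
  if (!is.numeric(frac) || frac <= 0 || frac >= 1) {
    add_err("parameters.expression_fraction out of range (0, 1): ", frac)
  }
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    add_err("parameters.de_alpha out of range (0, 1): ", alpha)
  }
  for (key in c("metadata", "ortholog_map", "programs_gmt", "annotations_gmt")) {
    fp <- cfg$paths[[key]]
    if (is.null(fp)) {
      add_err("paths: missing '", key, "'")
    } else {
      full <- file.path(base, fp)
      if (!file.exists(full)) add_err("paths.", key, ": no such file: ", fp)
      cfg$paths[[key]] <- full
    }
  }
  if (is.null(cfg$stage_split$early) || is.null(cfg$stage_split$late)) {
    add_err("stage_split needs 'early' and 'late' timepoint lists")
  }

  roles <- vapply(cfg$datasets, function(d) d$role %||% NA_character_, character(1))
  if (anyNA(roles)) add_err("dataset entry without a role")
  dup <- unique(roles[duplicated(roles)])
  for (d in dup) {
    add_err("role '", d, "' claimed by ", sum(roles == d), " datasets (",
            paste(vapply(cfg$datasets[roles == d], `[[`, character(1), "counts"),
                  collapse = ", "), ")")
  }
  for (need in PIPELINE_ROLES) {
    if (need == "stage_control" && isTRUE(p$allow_missing_control)) next
    if (!need %in% roles) add_err("missing dataset role: ", need)
  }
  for (i in seq_along(cfg$datasets)) {
    fp <- cfg$datasets[[i]]$counts
    if (is.null(fp)) {
      add_err("dataset '", roles[i], "': no counts path")
    } else {
      full <- file.path(base, fp)
      if (!file.exists(full)) add_err("dataset '", roles[i], "': no such file: ", fp)
      cfg$datasets[[i]]$counts <- full
    }
    cfg$datasets[[i]]$platform <- cfg$datasets[[i]]$platform %||% "tag_count"
    if (!cfg$datasets[[i]]$platform %in% c("tag_count", "microarray")) {
      add_err("dataset '", roles[i], "': unknown platform '",
              cfg$datasets[[i]]$platform, "'")
    }
  }
  if (length(errs)) {
    os_stop("invalid config:\n  - ", paste(errs, collapse = "\n  - "))
  }
  names(cfg$datasets) <- roles
  cfg$parameters$expression_fraction <- frac
  cfg$parameters$de_alpha <- alpha
  cfg$parameters$yates <- isTRUE(p$yates)
  cfg$parameters$allow_missing_control <- isTRUE(p$allow_missing_control)
  cfg$base_dir <- base
  structure(cfg, class = "pipeline_config")
}

# internal: fail with the stage name attached
run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    os_stop("pipeline stage '", stage, "' failed: ", conditionMessage(e))
  })
}

#' Run the full comparative analysis
#'
#' Orchestrates, in fixed order (presence calls are consumed by everything
#' downstream, so the flow is linear and needs no workflow engine):
#' expression calling for every dataset, differential expression for the
#' compartment and stage contrasts of the query placenta, the rank-based
#' stage-similarity matrix with the control organ, the best-stage
#' assignment and reference-vs-control contrast, the early/late
#' stage-partition chi-square, the convergence screens with liver/testis
#' controls, and over-representation analysis of the screen hits. Writes
#' result TSVs, a machine-readable `summary.json`, a sidecar manifest with
#' input hashes and parameters, and a run log. Deterministic: identical
#' inputs produce identical result tables and summary.
#'
#' @param config A `pipeline_config` from [validate_config()], or a path to
#'   a config YAML.
#' @param out_dir Output directory.
#' @return Invisibly, the summary list (also written as JSON).
#' @export
run_full_analysis <- function(config, out_dir) {
  if (is.character(config)) config <- validate_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  par <- config$parameters
  qsp <- config$species$query

  log_lines <- c(sprintf("orthostage %s | R %s",
                         as.character(utils::packageVersion("orthostage")),
                         paste(R.version$major, R.version$minor, sep = ".")),
                 sprintf("run started %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
                 sprintf("parameters: fraction=%g alpha=%g yates=%s",
                         par$expression_fraction, par$de_alpha, par$yates))

  md <- run_stage("io", read_sample_metadata(config$paths$metadata))
  map <- run_stage("io", read_ortholog_map(config$paths$ortholog_map))
  programs <- run_stage("io", read_gene_sets(config$paths$programs_gmt))
  if (!any(grepl("early", names(programs))) ||
      !any(grepl("late", names(programs)))) {
    os_stop("programs GMT must contain an 'early' and a 'late' set")
  }
  annotations <- run_stage("io", read_gene_sets(config$paths$annotations_gmt))
  counts <- run_stage("io", {
    lapply(config$datasets, function(d) {
      suppressMessages(read_count_matrix(d$counts, d$platform))
    })
  })

  ## ---- expression calling ------------------------------------------------
  calls <- run_stage("expression_calling", {
    pooled_profile <- function(role) {
      m <- counts[[role]]
      ids <- colnames(m)
      sub <- md[md$sample_id %in% ids, ]
      species <- unique(sub$species)
      expression_profile(rowMeans(unclass(m)), role, species)
    }
    profs <- lapply(names(counts), pooled_profile)
    names(profs) <- names(counts)
    mam_combined <- combine_cell_fractions(
      list(profs$reference_mammary_basal, profs$reference_mammary_luminal),
      label = "reference_mammary")
    profs$reference_mammary <- mam_combined
    lapply(profs, call_expressed, fraction = par$expression_fraction)
  })
  profiles <- run_stage("expression_calling", {
    qp <- counts$query_placenta
    sub <- md[md$sample_id %in% colnames(qp), ]
    tps <- sort(unique(sub$timepoint))
    qp_tp <- lapply(tps, function(tp) {
      average_replicates(qp, md, list(timepoint = tp), label = tp)
    })
    names(qp_tp) <- tps
    ser <- counts$reference_series
    ssub <- md[md$sample_id %in% colnames(ser), ]
    stages <- ssub$timepoint[match(colnames(ser), ssub$sample_id)]
    ref_stage <- lapply(stages, function(s) {
      average_replicates(ser, md, list(timepoint = s, organ = "placenta"),
                         label = s)
    })
    names(ref_stage) <- stages
    ctrl <- if ("stage_control" %in% names(counts)) {
      expression_profile(rowMeans(unclass(counts$stage_control)),
                         "stage_control", config$species$reference)
    } else NULL
    list(query_tp = qp_tp, ref_stage = ref_stage, control = ctrl)
  })

  ## ---- differential expression ------------------------------------------
  de <- run_stage("differential_expression", {
    qp <- counts$query_placenta
    sub <- md[match(colnames(qp), md$sample_id), ]
    comp <- factor(sub$tissue_compartment)
    stage_grp <- factor(ifelse(sub$timepoint %in% config$stage_split$early,
                               "early", "late"), levels = c("early", "late"))
    list(compartment = nb_de(qp, comp, alpha = par$de_alpha),
         stage = nb_de(qp, stage_grp, alpha = par$de_alpha))
  })

  ## ---- stage similarity --------------------------------------------------
  has_ctrl <- !is.null(profiles$control)
  sim <- run_stage("stage_similarity", {
    call_sets <- list(calls$query_placenta, calls$reference_series)
    if (has_ctrl) call_sets <- c(call_sets, list(calls$stage_control))
    similarity_matrix(profiles$query_tp, profiles$ref_stage,
                      if (has_ctrl) list(profiles$control) else list(),
                      call_sets = call_sets, map = map, species_a = qsp)
  })
  best <- run_stage("stage_similarity", best_matching_stage(sim))
  ctrl_res <- if (has_ctrl) {
    run_stage("stage_similarity", control_contrast(sim))
  } else {
    data.frame(query = rownames(sim$rho), margin = NA_real_,
               reference_beats_control = NA, stringsAsFactors = FALSE)
  }

  ## ---- stage-partition enrichment ---------------------------------------
  early_set <- programs[[grep("early", names(programs))[1L]]]
  late_set <- programs[[grep("late", names(programs))[1L]]]
  partition <- run_stage("setops_convergence", {
    stage_partition_counts(early_set, late_set,
                           calls$query_placenta$expressed, map)
  })
  chisq <- run_stage("setops_convergence", {
    list(uncorrected = chi_square_independence(partition, yates = FALSE),
         yates = chi_square_independence(partition, yates = TRUE))
  })

  ## ---- convergence screens ----------------------------------------------
  screens <- run_stage("setops_convergence", {
    A_pl <- calls$query_placenta$expressed
    B_pl <- calls$reference_placenta$expressed
    A_mam <- calls$query_mammary$expressed
    B_mam <- calls$reference_mammary$expressed
    ctrl_pairs <- list(
      liver = list(organ_A = calls$control_query_liver$expressed,
                   organ_B = calls$control_reference_liver$expressed),
      testis = list(organ_A = calls$control_query_testis$expressed,
                    organ_B = calls$control_reference_testis$expressed))
    sc <- shared_coopted(A_pl, B_pl, A_mam, B_mam, map)
    sc$control_screens <- control_screens("shared_coopted", A_pl, B_pl,
                                          ctrl_pairs, map)
    eo <- eutherian_only_shared(B_pl, A_mam, A_pl, B_mam, map)
    eo$control_screens <- control_screens("eutherian_only_shared", A_pl, B_pl,
                                          ctrl_pairs, map)
    universe <- sort(unique(c(A_pl, A_mam, orth_b_to_a(B_pl, map),
                              orth_b_to_a(B_mam, map))))
    list(shared_coopted = sc, eutherian_only = eo, universe = universe)
  })
  ora <- run_stage("setops_convergence", {
    list(shared_coopted = ora_fisher(screens$shared_coopted$gene_set,
                                     annotations, screens$universe),
         eutherian_only = ora_fisher(screens$eutherian_only$gene_set,
                                     annotations, screens$universe))
  })

  ## ---- outputs -----------------------------------------------------------
  run_stage("io", {
    for (nm in names(calls)) {
      write_result_table(call_table(calls[[nm]]),
                         file.path(out_dir, paste0("calls_", nm, ".tsv")))
    }
    for (nm in names(de)) {
      df <- as.data.frame(de[[nm]])
      write_result_table(df, file.path(out_dir, paste0("de_", nm, ".tsv")))
    }
    wide <- data.frame(query = rownames(sim$rho), sim$rho, check.names = FALSE)
    write_result_table(wide, file.path(out_dir, "stage_similarity.tsv"))
    write_result_table(similarity_long(sim),
                       file.path(out_dir, "stage_similarity_long.tsv"))
    write_result_table(best, file.path(out_dir, "best_stage.tsv"))
    write_result_table(ctrl_res, file.path(out_dir, "control_contrast.tsv"))
    part_df <- data.frame(program = rownames(partition),
                          expressed = partition[, 1L],
                          not_expressed = partition[, 2L])
    write_result_table(part_df, file.path(out_dir, "stage_partition.tsv"))
    for (nm in c("shared_coopted", "eutherian_only")) {
      s <- screens[[nm]]
      write_result_table(data.frame(gene = s$gene_set$genes,
                                    ortholog = s$orthologs_b,
                                    stringsAsFactors = FALSE),
                         file.path(out_dir, paste0("screen_", nm, ".tsv")))
      write_result_table(s$control_screens,
                         file.path(out_dir, paste0("screen_", nm, "_controls.tsv")))
      write_result_table(as.data.frame(ora[[nm]]),
                         file.path(out_dir, paste0("ora_", nm, ".tsv")))
    }
  })

  de_sum <- lapply(de, function(d) {
    s <- summary(d)
    list(n_significant = s$n_significant, up_in_first = s$n_up_in_A,
         up_in_second = s$n_up_in_B, levels = s$levels)
  })
  summary_list <- list(
    parameters = par[c("expression_fraction", "de_alpha", "yates")],
    n_expressed = lapply(calls, function(cs) length(cs$expressed)),
    differential_expression = de_sum,
    stage_similarity = list(
      n_genes = sim$n_genes,
      best_stage = stats::setNames(as.list(best$best_stage), best$query),
      best_rho = stats::setNames(as.list(best$rho), best$query),
      control_margin = stats::setNames(as.list(ctrl_res$margin), ctrl_res$query),
      reference_beats_control = if (has_ctrl) {
        all(ctrl_res$reference_beats_control)
      } else "skipped"),
    stage_partition = list(
      table = list(early_expressed = partition[1, 1], early_not = partition[1, 2],
                   late_expressed = partition[2, 1], late_not = partition[2, 2]),
      chi_square = list(statistic = chisq$uncorrected$statistic,
                        p_value = chisq$uncorrected$p_value),
      chi_square_yates = list(statistic = chisq$yates$statistic,
                              p_value = chisq$yates$p_value)),
    screens = list(
      shared_coopted = list(
        n_genes = length(screens$shared_coopted$gene_set$genes),
        controls = stats::setNames(
          as.list(screens$shared_coopted$control_screens$count),
          screens$shared_coopted$control_screens$tissue)),
      eutherian_only = list(
        n_genes = length(screens$eutherian_only$gene_set$genes),
        controls = stats::setNames(
          as.list(screens$eutherian_only$control_screens$count),
          screens$eutherian_only$control_screens$tissue))))
  jsonlite::write_json(summary_list, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  inputs <- c(config$paths$metadata, config$paths$ortholog_map,
              config$paths$programs_gmt, config$paths$annotations_gmt,
              vapply(config$datasets, `[[`, character(1), "counts"))
  manifest <- data.frame(
    input = basename(inputs),
    md5 = unname(tools::md5sum(inputs)),
    stringsAsFactors = FALSE)
  manifest$producing_module <- "pipeline"
  manifest$expression_fraction <- par$expression_fraction
  manifest$de_alpha <- par$de_alpha
  write_result_table(manifest, file.path(out_dir, "manifest.tsv"))
  log_lines <- c(log_lines,
                 sprintf("inputs: %d files hashed", length(inputs)),
                 sprintf("run finished %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")))
  writeLines(log_lines, file.path(out_dir, "log.txt"))
  invisible(summary_list)
}
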