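# End-to-end orchestration: DE -> priority lists -> target integration
# (optionally provenance-restricted), with deterministic report files and
# a YAML-configured command-line front end.

.cfg_get <- function(config, path, default = NULL) {
  node <- config
  for (key in path) {
    if (is.null(node[[key]])) return(default)
    node <- node[[key]]
  }
  node
}

.input_hashes <- function(paths) {
  paths <- paths[!vapply(paths, is.null, logical(1))]
  if (length(paths) == 0) return("no-files")
  h <- tools::md5sum(unlist(paths))
  paste(sprintf("%s=%s", basename(names(h)), unname(h)), collapse = ",")
}

.pipeline_log <- function(...) {
  message(sprintf("[mirtriage] %s", sprintf(...)))
}

#' Validate and normalize a pipeline configuration
#'
#' @param config nested list (e.g. from `yaml::read_yaml`) with an
#'   `inputs` section (paths `expression`, `sample_sheet`, `targets`,
#'   `protein_de`, optional `mrna_de`, `origin_calls`), optional `filter`,
#'   `target_filter`, `top_k`, `apply_mrna_filter`, `comparison_match`,
#'   `priority` (`"top_and_both"` or `"all_de"`) and `out_dir` entries.
#' @return the config with defaults filled in; errors on missing files
#'   before any computation.
#' @export
validate_pipeline_config <- function(config) {
  stopifnot(is.list(config))
  required <- c("expression", "sample_sheet", "targets", "protein_de")
  for (key in required) {
    path <- .cfg_get(config, c("inputs", key))
    if (is.null(path)) {
      stop(sprintf("configuration error: inputs$%s is required", key),
           call. = FALSE)
    }
    if (!file.exists(path)) {
      stop(sprintf("configuration error: inputs$%s file '%s' does not exist",
                   key, path), call. = FALSE)
    }
  }
  for (key in c("mrna_de", "origin_calls")) {
    path <- .cfg_get(config, c("inputs", key))
    if (!is.null(path) && !file.exists(path)) {
      stop(sprintf("configuration error: inputs$%s file '%s' does not exist",
                   key, path), call. = FALSE)
    }
  }
  config$filter <- utils::modifyList(
    list(fc_min = 1.5, p_max = 0.05, f_fdr_max = 0.005,
         species_prefix = "hsa"),
    .cfg_get(config, "filter", list()))
  config$target_filter <- utils::modifyList(
    list(min_prob = 0.95, region = "3UTR", validated_only = TRUE),
    .cfg_get(config, "target_filter", list()))
  if (is.null(config$top_k)) config$top_k <- 10
  if (is.null(config$apply_mrna_filter)) config$apply_mrna_filter <- TRUE
  if (is.null(config$comparison_match)) config$comparison_match <- "either"
  if (is.null(config$priority)) config$priority <- "top_and_both"
  if (!config$priority %in% c("top_and_both", "all_de")) {
    stop("configuration error: priority must be 'top_and_both' or 'all_de'",
         call. = FALSE)
  }
  if (is.null(config$out_dir)) {
    stop("configuration error: out_dir is required", call. = FALSE)
  }
  config
}

#' Run the full tri-omics triage pipeline
#'
#' Executes moderated differential expression on the miRNA matrix, builds
#' the priority miRNA set, filters predicted targets, matches priority
#' miRNAs to inversely expressed proteins, optionally eliminates
#' mRNA-concordant hits and restricts F1vT protein entries to
#' human-not-murine identifications, and writes every stage's table to
#' `out_dir` with a deterministic provenance header (input hashes and
#' parameters; no timestamps), so reruns on identical inputs are
#' byte-identical.
#'
#' @param config nested configuration list, see
#'   [validate_pipeline_config()].
#' @return invisibly, the report bundle: `de` ([run_de()] output),
#'   `de_filtered`, `priority`, `targets_filtered`, `hits_all`, `hits`
#'   (after optional mRNA elimination), `multi_target`, and `files`.
#' @export
run_pipeline <- function(config) {
  config <- validate_pipeline_config(config)
  inputs <- config$inputs
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stamp <- sprintf("mirtriage run | inputs %s | filter fc>=%g p<%g f_fdr<%g prefix=%s | targets prob>=%g region=%s validated=%s | top_k=%d mrna_filter=%s match=%s priority=%s",
                   .input_hashes(inputs), config$filter$fc_min,
                   config$filter$p_max, config$filter$f_fdr_max,
                   config$filter$species_prefix,
                   config$target_filter$min_prob, config$target_filter$region,
                   config$target_filter$validated_only, config$top_k,
                   config$apply_mrna_filter, config$comparison_match,
                   config$priority)

  .pipeline_log("stage de: reading expression matrix")
  em <- read_expression_matrix(inputs$expression, inputs$sample_sheet)
  spec <- filter_spec(config$filter$fc_min, config$filter$p_max,
                      config$filter$f_fdr_max, config$filter$species_prefix)
  de <- run_de(em, spec)
  de_filtered <- list(TvN = de_filter(de$TvN, spec),
                      F1vT = de_filter(de$F1vT, spec))
  .pipeline_log("stage de: %d/%d features pass the cascade (TvN/F1vT)",
                nrow(de_filtered$TvN), nrow(de_filtered$F1vT))

  priority <- if (config$priority == "top_and_both") {
    priority_universe(de_filtered$TvN, de_filtered$F1vT, k = config$top_k)
  } else {
    rbind(data.frame(mirna_id = de_filtered$TvN$feature_id,
                     comparison = "TvN",
                     fold_change = de_filtered$TvN$fold_change,
                     p_value = de_filtered$TvN$p_value,
                     stringsAsFactors = FALSE),
          data.frame(mirna_id = de_filtered$F1vT$feature_id,
                     comparison = "F1vT",
                     fold_change = de_filtered$F1vT$fold_change,
                     p_value = de_filtered$F1vT$p_value,
                     stringsAsFactors = FALSE))
  }

  .pipeline_log("stage integrate: reading targets and protein tables")
  targets <- read_target_table(inputs$targets)
  targets_filtered <- filter_targets(targets,
                                     config$target_filter$min_prob,
                                     config$target_filter$region,
                                     config$target_filter$validated_only)
  missing_mirnas <- setdiff(unique(targets_filtered$mirna_id),
                            priority$mirna_id)
  if (length(missing_mirnas) > 0) {
    .pipeline_log("warning: %d target-table miRNA id(s) absent from the priority set",
                  length(missing_mirnas))
  }
  protein_de <- read_protein_de_table(inputs$protein_de)
  if (!is.null(inputs$origin_calls)) {
    calls <- read_report(inputs$origin_calls)
    human <- calls$protein_id[calls$category == "human_not_murine"]
    drop <- protein_de$comparison == "F1vT" &
      !(protein_de$gene_symbol %in% human)
    if (any(drop)) {
      .pipeline_log("provenance: dropping %d F1vT protein entr(ies) not called human-not-murine",
                    sum(drop))
    }
    protein_de <- protein_de[!drop, , drop = FALSE]
  }
  hits_all <- inverse_hits(priority, targets_filtered, protein_de,
                           comparison_match = config$comparison_match)
  hits <- if (isTRUE(config$apply_mrna_filter) &&
              !is.null(inputs$mrna_de)) {
    mrna_concordance_filter(hits_all, read_mrna_de_table(inputs$mrna_de))
  } else {
    hits_all
  }
  multi_target <- multi_target_summary(hits)
  .pipeline_log("stage integrate: %d hits, %d multi-target miRNAs",
                nrow(hits), nrow(multi_target))

  files <- list()
  emit <- function(df, name, sort = TRUE) {
    path <- file.path(out_dir, name)
    write_report(df, path, provenance = stamp, sort = sort)
    files[[name]] <<- path
  }
  emit(de$TvN, "de_TvN.tsv")
  emit(de$F1vT, "de_F1vT.tsv")
  emit(de_filtered$TvN, "de_filtered_TvN.tsv", sort = FALSE)
  emit(de_filtered$F1vT, "de_filtered_F1vT.tsv", sort = FALSE)
  emit(priority, "priority.tsv", sort = FALSE)
  emit(hits[, c("mirna_id", "gene_symbol", "comparison", "fraction",
                "mirna_fc", "protein_fc")], "hits.tsv")
  emit(multi_target, "multi_target_summary.tsv", sort = FALSE)
  invisible(list(de = de, de_filtered = de_filtered, priority = priority,
                 targets_filtered = targets_filtered, hits_all = hits_all,
                 hits = hits, multi_target = multi_target, files = files))
}

#' Write a simulated dataset to a directory in the pipeline's input schemas
#'
#' @param sim [simulate_triomics()] result.
#' @param out_dir output directory (created if needed).
#' @return named list of file paths (`expression`, `sample_sheet`,
#'   `targets`, `protein_de`, `mrna_de`, `truth_edges`, `truth_de`).
#' @export
write_simulation <- function(sim, out_dir) {
  stopifnot(inherits(sim, "triomics_sim"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  em <- sim$expression
  expr_df <- cbind(data.frame(feature_id = rownames(em$values),
                              stringsAsFactors = FALSE),
                   as.data.frame(em$values, optional = TRUE))
  sheet <- data.frame(sample_id = colnames(em$values),
                      group = unname(em$group_of), stringsAsFactors = FALSE)
  paths <- list(
    expression = file.path(out_dir, "expression.tsv"),
    sample_sheet = file.path(out_dir, "sample_sheet.tsv"),
    targets = file.path(out_dir, "targets.tsv"),
    protein_de = file.path(out_dir, "protein_de.tsv"),
    mrna_de = file.path(out_dir, "mrna_de.tsv"),
    truth_edges = file.path(out_dir, "truth_edges.tsv"),
    truth_de = file.path(out_dir, "truth_de.tsv"))
  write_report(expr_df, paths$expression, sort = FALSE)
  write_report(sheet, paths$sample_sheet, sort = FALSE)
  write_report(sim$targets, paths$targets)
  write_report(sim$protein_de, paths$protein_de)
  write_report(sim$mrna_de, paths$mrna_de)
  write_report(sim$truth$edges, paths$truth_edges)
  write_report(sim$truth$de, paths$truth_de)
  paths
}

# Minimal --key value / --flag argument parser for the CLI wrapper.
.parse_args <- function(argv) {
  out <- list()
  i <- 1
  while (i <= length(argv)) {
    arg <- argv[i]
    if (!startsWith(arg, "--")) {
      stop(sprintf("unexpected argument '%s'", arg), call. = FALSE)
    }
    key <- gsub("-", "_", substring(arg, 3))
    if (i < length(argv) && !startsWith(argv[i + 1], "--")) {
      out[[key]] <- argv[i + 1]
      i <- i + 2
    } else {
      out[[key]] <- TRUE
      i <- i + 1
    }
  }
  out
}

#' Command-line entry point
#'
#' Subcommand interface used by the `exec/mirtriage` script:
#' `simulate` (write a synthetic dataset), `de`, `prioritize`, `integrate`,
#' `provenance` (each stage standalone on files), and `run-all` (the full
#' pipeline from a YAML config). Every subcommand routes through the
#' exported package functions, so stage outputs on disk compose to the same
#' bundle as a single `run-all`.
#'
#' @param argv character vector of command-line arguments (subcommand
#'   first).
#' @return invisibly, the subcommand's result.
#' @export
pipeline_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  if (length(argv) == 0) {
    stop(paste("usage: mirtriage <simulate|de|prioritize|integrate|provenance|run-all> [--options];",
               "see ?pipeline_main"), call. = FALSE)
  }
  cmd <- argv[1]
  opts <- .parse_args(argv[-1])
  need <- function(key) {
    if (is.null(opts[[key]])) {
      stop(sprintf("%s: --%s is required", cmd, gsub("_", "-", key)),
           call. = FALSE)
    }
    opts[[key]]
  }
  result <- switch(
    cmd,
    "simulate" = {
      cfg <- sim_config(seed = as.integer(if (is.null(opts$seed)) 1
                                          else opts$seed))
      if (!is.null(opts$noise_sd)) cfg$noise_sd <- as.numeric(opts$noise_sd)
      if (!is.null(opts$n_mirna)) cfg$n_mirna <- as.integer(opts$n_mirna)
      sim <- simulate_triomics(cfg)
      write_simulation(sim, need("out"))
    },
    "de" = {
      em <- read_expression_matrix(need("expression"), need("sample_sheet"))
      de <- run_de(em)
      out <- need("out")
      dir.create(out, showWarnings = FALSE, recursive = TRUE)
      write_report(de$TvN, file.path(out, "de_TvN.tsv"))
      write_report(de$F1vT, file.path(out, "de_F1vT.tsv"))
      spec <- filter_spec()
      write_report(de_filter(de$TvN, spec),
                   file.path(out, "de_filtered_TvN.tsv"), sort = FALSE)
      write_report(de_filter(de$F1vT, spec),
                   file.path(out, "de_filtered_F1vT.tsv"), sort = FALSE)
      de
    },
    "prioritize" = {
      tvn <- read_report(need("de_tvn"))
      f1vt <- read_report(need("de_f1vt"))
      k <- as.integer(if (is.null(opts$top_k)) 10 else opts$top_k)
      pr <- priority_universe(tvn, f1vt, k = k)
      out <- need("out")
      dir.create(out, showWarnings = FALSE, recursive = TRUE)
      write_report(pr, file.path(out, "priority.tsv"), sort = FALSE)
      pr
    },
    "integrate" = {
      priority <- read_priority_table(need("priority"))
      targets <- filter_targets(read_target_table(need("targets")))
      protein_de <- read_protein_de_table(need("protein_de"))
      match_mode <- if (is.null(opts$comparison_match)) "either"
                    else opts$comparison_match
      hits <- inverse_hits(priority, targets, protein_de,
                           comparison_match = match_mode)
      if (!is.null(opts$mrna_de)) {
        hits <- mrna_concordance_filter(hits,
                                        read_mrna_de_table(opts$mrna_de))
      }
      out <- need("out")
      dir.create(out, showWarnings = FALSE, recursive = TRUE)
      write_report(hits, file.path(out, "hits.tsv"))
      write_report(multi_target_summary(hits),
                   file.path(out, "multi_target_summary.tsv"), sort = FALSE)
      hits
    },
    "provenance" = {
      evidence <- read_peptide_evidence(need("evidence"))
      classified <- classify_peptides(evidence, need("human_db"),
                                      need("mouse_db"),
                                      merge_il = isTRUE(opts$merge_il))
      calls <- call_protein_origin(classified)
      out <- need("out")
      dir.create(out, showWarnings = FALSE, recursive = TRUE)
      write_report(calls, file.path(out, "origin_calls.tsv"))
      calls
    },
    "run-all" = {
      config <- yaml::read_yaml(need("config"))
      if (!is.null(opts$out_dir)) config$out_dir <- opts$out_dir
      run_pipeline(config)
    },
    stop(sprintf("unknown subcommand '%s'", cmd), call. = FALSE))
  invisible(result)
}
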