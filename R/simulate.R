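# Synthetic tri-omics generator with planted ground truth: three-cohort
# log-normal miRNA expression with planted DE, miRNA->protein regulatory
# edges producing inverse protein changes (no concordant mRNA),
# transcriptional decoy proteins with concordant mRNA, decoy target
# predictions failing at least one filter rule, and non-human feature ids.

#' Configuration for the synthetic tri-omics generator
#'
#' Defaults emulate the study conditions the pipeline is designed for:
#' cohorts of 5 adjacent-normal, 7 tumor and 8 first-passage xenograft
#' samples; a few hundred miRNA probe sets with log-normal baseline signal;
#' moderate planted fractions of DE miRNAs per comparison with log2 effects
#' between 0.7 and 3; and a tenth of the features carrying a non-human
#' (`mmu-`) id, as on a multi-species array.
#'
#' @param n_mirna number of miRNA features (default 300).
#' @param n_genes number of protein-coding genes in the protein/mRNA layers
#'   (default 400).
#' @param group_sizes named integer vector, samples per cohort
#'   (default `c(N = 5, T = 7, F1 = 8)`).
#' @param baseline_log2_mean,baseline_log2_sd baseline log2 signal
#'   distribution (defaults 7, 1).
#' @param de_fraction_tvn,de_fraction_f1vt fraction of features planted DE
#'   in each comparison (defaults 0.15, 0.2).
#' @param both_same_direction_count features planted DE with the same sign
#'   in both comparisons (default 6; counted inside both fractions).
#' @param effect_range absolute planted log2 shift range (default
#'   `c(0.7, 3)`), sign random.
#' @param noise_sd per-sample Gaussian noise on the log2 scale
#'   (default 0.3).
#' @param targets_per_de_mirna mean number of regulated target genes per
#'   DE miRNA (Poisson; default 3).
#' @param decoy_target_count predicted-target records violating at least
#'   one filter rule (default 100).
#' @param regulated_protein_gain beta: a regulated protein's |log2 change|
#'   is `beta * |miRNA effect|`, with opposite sign (default 0.8).
#' @param transcriptional_decoy_fraction fraction of genes given
#'   same-direction protein and mRNA changes wired to a DE miRNA, so they
#'   would be false attributions without the mRNA filter (default 0.1).
#' @param non_human_fraction fraction of features with an `mmu-` id
#'   (default 0.1).
#' @param seed integer seed driving every draw (default 1).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_mirna = 300, n_genes = 400,
                       group_sizes = c(N = 5, T = 7, F1 = 8),
                       baseline_log2_mean = 7, baseline_log2_sd = 1,
                       de_fraction_tvn = 0.15, de_fraction_f1vt = 0.2,
                       both_same_direction_count = 6,
                       effect_range = c(0.7, 3), noise_sd = 0.3,
                       targets_per_de_mirna = 3, decoy_target_count = 100,
                       regulated_protein_gain = 0.8,
                       transcriptional_decoy_fraction = 0.1,
                       non_human_fraction = 0.1, seed = 1) {
  cfg <- list(n_mirna = n_mirna, n_genes = n_genes,
              group_sizes = group_sizes,
              baseline_log2_mean = baseline_log2_mean,
              baseline_log2_sd = baseline_log2_sd,
              de_fraction_tvn = de_fraction_tvn,
              de_fraction_f1vt = de_fraction_f1vt,
              both_same_direction_count = both_same_direction_count,
              effect_range = effect_range, noise_sd = noise_sd,
              targets_per_de_mirna = targets_per_de_mirna,
              decoy_target_count = decoy_target_count,
              regulated_protein_gain = regulated_protein_gain,
              transcriptional_decoy_fraction = transcriptional_decoy_fraction,
              non_human_fraction = non_human_fraction, seed = seed)
  with(cfg, {
    stopifnot(n_mirna >= 1, n_genes >= 1,
              all(group_sizes >= 2), length(group_sizes) == 3,
              de_fraction_tvn >= 0, de_fraction_tvn <= 1,
              de_fraction_f1vt >= 0, de_fraction_f1vt <= 1,
              both_same_direction_count >= 0,
              length(effect_range) == 2, effect_range[1] > 0,
              effect_range[2] >= effect_range[1],
              noise_sd >= 0, regulated_protein_gain > 0,
              transcriptional_decoy_fraction >= 0,
              transcriptional_decoy_fraction <= 1,
              non_human_fraction >= 0, non_human_fraction <= 1)
  })
  n_tvn <- round(cfg$de_fraction_tvn * n_mirna)
  n_f1vt <- round(cfg$de_fraction_f1vt * n_mirna)
  if (both_same_direction_count > min(n_tvn, n_f1vt) && n_tvn + n_f1vt > 0) {
    stop("sim_config: both_same_direction_count exceeds a comparison's DE count",
         call. = FALSE)
  }
  if (n_tvn + n_f1vt - both_same_direction_count > n_mirna) {
    stop("sim_config: more planted DE features than features", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

.runif_sign <- function(n) sample(c(-1, 1), n, replace = TRUE)

#' Generate a synthetic tri-omics dataset with ground truth
#'
#' All randomness flows from a single generator seeded once from
#' `config$seed`, so identical configurations reproduce byte-identical
#' outputs.
#'
#' @param config [sim_config()].
#' @return list of class `triomics_sim`: `expression`
#'   (`expression_matrix`), `targets`, `protein_de`, `mrna_de`
#'   (data.frames in the io schemas) and `truth`, a list with `de`
#'   (feature, comparison, sign, log2 effect), `edges`
#'   (mirna, gene, comparison), `mechanism` (named vector per gene:
#'   `mirna_regulated` / `transcriptional` / `null`) and the `config`.
#' @export
simulate_triomics <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_mirna
  n_mmu <- round(config$non_human_fraction * n)
  prefix <- rep("hsa", n)
  if (n_mmu > 0) prefix[sample.int(n, n_mmu)] <- "mmu"
  feature_ids <- sprintf("%s-miR-sim-%04d", prefix, seq_len(n))

  # --- planted DE sets ----------------------------------------------------
  n_tvn <- round(config$de_fraction_tvn * n)
  n_f1vt <- round(config$de_fraction_f1vt * n)
  n_both <- config$both_same_direction_count
  idx <- sample.int(n)  # random feature order; carve DE sets from the front
  both_idx <- idx[seq_len(n_both)]
  tvn_only_idx <- idx[n_both + seq_len(max(n_tvn - n_both, 0))]
  f1vt_only_idx <- idx[n_both + length(tvn_only_idx) +
                         seq_len(max(n_f1vt - n_both, 0))]
  draw_effect <- function(k) {
    stats::runif(k, config$effect_range[1], config$effect_range[2])
  }
  delta_tvn <- numeric(n); delta_f1vt <- numeric(n)
  both_sign <- .runif_sign(n_both)
  delta_tvn[both_idx] <- both_sign * draw_effect(n_both)
  delta_f1vt[both_idx] <- both_sign * draw_effect(n_both)
  delta_tvn[tvn_only_idx] <- .runif_sign(length(tvn_only_idx)) *
    draw_effect(length(tvn_only_idx))
  delta_f1vt[f1vt_only_idx] <- .runif_sign(length(f1vt_only_idx)) *
    draw_effect(length(f1vt_only_idx))

  # --- expression matrix --------------------------------------------------
  sizes <- config$group_sizes
  groups <- rep(names(sizes), sizes)
  sample_ids <- unlist(lapply(names(sizes), function(g) {
    sprintf("%s_%02d", g, seq_len(sizes[[g]]))
  }))
  baseline <- stats::rnorm(n, config$baseline_log2_mean,
                           config$baseline_log2_sd)
  mu <- cbind(N = baseline, T = baseline + delta_tvn,
              F1 = baseline + delta_tvn + delta_f1vt)
  values <- mu[, groups, drop = FALSE] +
    matrix(stats::rnorm(n * length(groups), 0, config$noise_sd),
           nrow = n)
  dimnames(values) <- list(feature_ids, sample_ids)
  em <- expression_matrix(values, stats::setNames(groups, sample_ids))

  # --- regulatory edges and regulated proteins ----------------------------
  gene_pool <- sprintf("GENE%04d", seq_len(config$n_genes))
  mechanism <- stats::setNames(rep("null", config$n_genes), gene_pool)
  de_rows <- rbind(
    if (n_both > 0 || length(tvn_only_idx) > 0)
      data.frame(feature_id = feature_ids[c(both_idx, tvn_only_idx)],
                 comparison = "TvN",
                 effect_log2 = delta_tvn[c(both_idx, tvn_only_idx)],
                 stringsAsFactors = FALSE),
    if (n_both > 0 || length(f1vt_only_idx) > 0)
      data.frame(feature_id = feature_ids[c(both_idx, f1vt_only_idx)],
                 comparison = "F1vT",
                 effect_log2 = delta_f1vt[c(both_idx, f1vt_only_idx)],
                 stringsAsFactors = FALSE))
  if (is.null(de_rows)) {
    de_rows <- data.frame(feature_id = character(), comparison = character(),
                          effect_log2 = numeric(), stringsAsFactors = FALSE)
  }
  de_rows$sign <- sign(de_rows$effect_log2)

  hsa_de <- unique(de_rows$feature_id[startsWith(de_rows$feature_id, "hsa")])
  edges <- data.frame(mirna_id = character(), gene_symbol = character(),
                      comparison = character(), effect_log2 = numeric(),
                      stringsAsFactors = FALSE)
  free_genes <- gene_pool
  for (m in hsa_de) {
    k <- min(stats::rpois(1, config$targets_per_de_mirna), length(free_genes))
    if (k == 0) next
    genes <- free_genes[seq_len(k)]
    free_genes <- free_genes[-seq_len(k)]
    mechanism[genes] <- "mirna_regulated"
    m_rows <- de_rows[de_rows$feature_id == m, , drop = FALSE]
    for (j in seq_len(nrow(m_rows))) {
      edges <- rbind(edges, data.frame(
        mirna_id = m, gene_symbol = genes,
        comparison = m_rows$comparison[j],
        effect_log2 = m_rows$effect_log2[j], stringsAsFactors = FALSE))
    }
  }

  rand_fraction <- function(k) sample(.fractions, k, replace = TRUE)
  protein_de <- data.frame(gene_symbol = character(),
                           comparison = character(), fraction = character(),
                           fold_change = numeric(), p_value = numeric(),
                           stringsAsFactors = FALSE)
  if (nrow(edges) > 0) {
    protein_de <- data.frame(
      gene_symbol = edges$gene_symbol, comparison = edges$comparison,
      fraction = rand_fraction(nrow(edges)),
      fold_change = signed_fc(-sign(edges$effect_log2) *
                                config$regulated_protein_gain *
                                abs(edges$effect_log2)),
      p_value = stats::runif(nrow(edges), 1e-6, 0.01),
      stringsAsFactors = FALSE)
  }

  # --- transcriptional decoys (concordant protein + mRNA) -----------------
  n_decoy_genes <- round(config$transcriptional_decoy_fraction *
                           config$n_genes)
  n_decoy_genes <- min(n_decoy_genes, length(free_genes))
  mrna_de <- data.frame(gene_symbol = character(), comparison = character(),
                        fold_change = numeric(), p_value = numeric(),
                        stringsAsFactors = FALSE)
  true_targets <- unique(edges[, c("mirna_id", "gene_symbol")])
  decoy_gene_targets <- NULL
  if (n_decoy_genes > 0 && length(hsa_de) > 0) {
    decoy_genes <- free_genes[seq_len(n_decoy_genes)]
    free_genes <- free_genes[-seq_len(n_decoy_genes)]
    mechanism[decoy_genes] <- "transcriptional"
    host <- sample(hsa_de, n_decoy_genes, replace = TRUE)
    host_rows <- de_rows[match(host, de_rows$feature_id), , drop = FALSE]
    prot_log2 <- -host_rows$sign * draw_effect(n_decoy_genes)
    protein_de <- rbind(protein_de, data.frame(
      gene_symbol = decoy_genes, comparison = host_rows$comparison,
      fraction = rand_fraction(n_decoy_genes),
      fold_change = signed_fc(prot_log2),
      p_value = stats::runif(n_decoy_genes, 1e-6, 0.01),
      stringsAsFactors = FALSE))
    mrna_de <- data.frame(
      gene_symbol = decoy_genes, comparison = host_rows$comparison,
      fold_change = signed_fc(sign(prot_log2) * draw_effect(n_decoy_genes)),
      p_value = stats::runif(n_decoy_genes, 1e-6, 0.01),
      stringsAsFactors = FALSE)
    decoy_gene_targets <- data.frame(mirna_id = host,
                                     gene_symbol = decoy_genes,
                                     stringsAsFactors = FALSE)
  }

  # --- target-prediction table -------------------------------------------
  label <- character(0)
  if (nrow(true_targets) > 0) label <- rep("sim-true", nrow(true_targets))
  if (!is.null(decoy_gene_targets)) {
    label <- c(label, rep("sim-transcriptional", nrow(decoy_gene_targets)))
  }
  passing_pairs <- rbind(true_targets, decoy_gene_targets)
  targets <- data.frame(mirna_id = character(), gene_symbol = character(),
                        binding_probability = numeric(), region = character(),
                        validated = logical(), source = character(),
                        stringsAsFactors = FALSE)
  if (!is.null(passing_pairs) && nrow(passing_pairs) > 0) {
    targets <- data.frame(
      mirna_id = passing_pairs$mirna_id,
      gene_symbol = passing_pairs$gene_symbol,
      binding_probability = stats::runif(nrow(passing_pairs), 0.95, 1),
      region = "3UTR", validated = TRUE, source = label,
      stringsAsFactors = FALSE)
  }
  if (config$decoy_target_count > 0) {
    k <- config$decoy_target_count
    fail_mode <- sample(c("prob", "region", "validated"), k, replace = TRUE)
    decoys <- data.frame(
      mirna_id = sample(feature_ids, k, replace = TRUE),
      gene_symbol = sample(gene_pool, k, replace = TRUE),
      binding_probability = ifelse(fail_mode == "prob",
                                   stats::runif(k, 0.5, 0.949),
                                   stats::runif(k, 0.95, 1)),
      region = ifelse(fail_mode == "region",
                      sample(c("5UTR", "CDS"), k, replace = TRUE), "3UTR"),
      validated = fail_mode != "validated",
      source = "sim-decoy", stringsAsFactors = FALSE)
    targets <- rbind(targets, decoys)
  }

  truth <- list(de = de_rows[order(de_rows$comparison, de_rows$feature_id), ,
                             drop = FALSE],
                edges = edges[order(edges$mirna_id, edges$gene_symbol,
                                    edges$comparison), , drop = FALSE],
                mechanism = mechanism, config = config)
  rownames(truth$de) <- NULL
  rownames(truth$edges) <- NULL
  structure(list(expression = em, targets = targets, protein_de = protein_de,
                 mrna_de = mrna_de, truth = truth),
            class = "triomics_sim")
}

#' Recovery metrics against the planted ground truth
#'
#' Scores a hit list from the pipeline against the generator's planted
#' edges: edge recall (recovered planted edges over planted edges whose
#' miRNA was called DE), edge precision (planted over emitted hits) and,
#' when DE tables are supplied, DE sensitivity and specificity per
#' comparison for human-prefixed features.
#'
#' @param truth `truth` element of a [simulate_triomics()] result.
#' @param hits attribution hits from [inverse_hits()] /
#'   [mrna_concordance_filter()].
#' @param de optional [run_de()] result (or a list with `TvN`/`F1vT`
#'   data.frames carrying `feature_id` and `passes_filter`). When absent,
#'   recall is computed over all planted edges.
#' @return list with `edge_recall`, `edge_precision` (`NaN` with
#'   `no_hits = TRUE` when the hit list is empty), `n_planted_edges`,
#'   `n_recovered`, and per-comparison `de_sensitivity`/`de_specificity`
#'   (`NA` without `de`).
#' @export
truth_report <- function(truth, hits, de = NULL) {
  stopifnot(is.list(truth), is.data.frame(hits))
  edges <- truth$edges
  called <- function(cmp) {
    if (is.null(de)) return(unique(edges$mirna_id[edges$comparison == cmp]))
    tab <- de[[cmp]]
    if ("passes_filter" %in% names(tab)) tab$feature_id[tab$passes_filter]
    else tab$feature_id
  }
  eligible <- edges[edges$mirna_id %in% c(called("TvN"), called("F1vT")) &
                      mapply(function(m, cmp) m %in% called(cmp),
                             edges$mirna_id, edges$comparison), ,
                    drop = FALSE]
  edge_key <- function(df) paste(df$mirna_id, df$gene_symbol, df$comparison,
                                 sep = "\r")
  hit_keys <- unique(edge_key(hits))
  recovered <- edge_key(eligible) %in% hit_keys
  recall <- if (nrow(eligible) == 0) NA_real_ else mean(recovered)
  planted_keys <- edge_key(edges)
  precision <- if (nrow(hits) == 0) NaN else mean(hit_keys %in% planted_keys)
  de_metrics <- function(cmp) {
    if (is.null(de)) return(c(sensitivity = NA_real_, specificity = NA_real_))
    tab <- de[[cmp]]
    universe <- tab$feature_id[startsWith(tab$feature_id, "hsa")]
    truth_pos <- intersect(universe,
                           truth$de$feature_id[truth$de$comparison == cmp])
    calls <- intersect(called(cmp), universe)
    tp <- length(intersect(calls, truth_pos))
    fp <- length(setdiff(calls, truth_pos))
    neg <- length(universe) - length(truth_pos)
    c(sensitivity = if (length(truth_pos) == 0) NA_real_
      else tp / length(truth_pos),
      specificity = if (neg == 0) NA_real_ else 1 - fp / neg)
  }
  list(edge_recall = recall, edge_precision = precision,
       no_hits = nrow(hits) == 0,
       n_planted_edges = nrow(edges), n_eligible_edges = nrow(eligible),
       n_recovered = sum(recovered),
       TvN = de_metrics("TvN"), F1vT = de_metrics("F1vT"))
}
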