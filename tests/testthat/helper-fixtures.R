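# Shared fixture builders. Everything is constructed in code; the only
# on-disk fixtures are the published-cohort tables in inst/extdata.

fixture_path <- function(name) {
  system.file("extdata", name, package = "mirtriage", mustWork = TRUE)
}

# Small three-group expression matrix with optional planted shifts.
toy_matrix <- function(n_features = 20, sizes = c(N = 3, T = 3, F1 = 3),
                       noise_sd = 0.2, shifts = NULL, seed = 1,
                       prefix = "hsa") {
  set.seed(seed)
  groups <- rep(names(sizes), sizes)
  samples <- sprintf("s%02d", seq_along(groups))
  base <- rnorm(n_features, 7, 1)
  mu <- cbind(N = base, T = base, F1 = base)
  if (!is.null(shifts)) {
    for (i in seq_len(nrow(shifts))) {
      f <- shifts$feature[i]
      if (shifts$comparison[i] == "TvN") {
        mu[f, c("T", "F1")] <- mu[f, c("T", "F1")] + shifts$delta[i]
      } else {
        mu[f, "F1"] <- mu[f, "F1"] + shifts$delta[i]
      }
    }
  }
  values <- mu[, groups] + matrix(rnorm(n_features * length(groups), 0,
                                        noise_sd), nrow = n_features)
  dimnames(values) <- list(sprintf("%s-miR-t%03d", prefix,
                                   seq_len(n_features)), samples)
  expression_matrix(values, setNames(groups, samples))
}

# Write a data.frame as a plain TSV (no provenance header).
write_tsv <- function(df, path) {
  write_report(df, path, sort = FALSE)
  path
}

# Degrees-of-freedom-zero prior: moderated statistics collapse to the
# classical pooled-variance ones.
prior_d0_zero <- structure(list(d0 = 0, s0_sq = 1), class = "ebayes_prior")

make_prior <- function(d0, s0_sq) {
  structure(list(d0 = d0, s0_sq = s0_sq), class = "ebayes_prior")
}

# Independent brute-force step-up BH oracle.
bh_oracle <- function(p) {
  n <- length(p)
  ord <- order(p)
  adj <- numeric(n)
  for (i in seq_len(n)) {
    js <- seq(i, n)
    adj[ord[i]] <- min(1, min(p[ord[js]] * n / js))
  }
  adj
}

# Brute-force triple-loop oracle for inverse_hits (comparison_match rules
# re-derived independently, row by row).
inverse_hits_oracle <- function(priority, targets, protein_de,
                                comparison_match = "either") {
  rows <- list()
  pairs <- unique(targets[, c("mirna_id", "gene_symbol")])
  for (i in seq_len(nrow(pairs))) {
    m <- pairs$mirna_id[i]; g <- pairs$gene_symbol[i]
    m_rows <- priority[priority$mirna_id == m, , drop = FALSE]
    if (nrow(m_rows) == 0) next
    p_rows <- protein_de[protein_de$gene_symbol == g, , drop = FALSE]
    for (j in seq_len(nrow(p_rows))) {
      cp <- p_rows$comparison[j]
      same <- m_rows[m_rows$comparison == cp, , drop = FALSE]
      fc <- if (nrow(same) > 0) same$fold_change[1]
            else if (comparison_match == "either") m_rows$fold_change[1]
            else NA_real_
      if (is.na(fc)) next
      if (sign(fc) * sign(p_rows$fold_change[j]) < 0) {
        rows[[length(rows) + 1]] <- data.frame(
          mirna_id = m, gene_symbol = g, comparison = cp,
          fraction = p_rows$fraction[j], mirna_fc = fc,
          protein_fc = p_rows$fold_change[j], stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(mirna_id = character(), gene_symbol = character(),
                      comparison = character(), fraction = character(),
                      mirna_fc = numeric(), protein_fc = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$mirna_id, out$gene_symbol, out$comparison, out$fraction), ,
      drop = FALSE]
}

# Random toy inputs for integration property tests.
random_integration_inputs <- function(seed) {
  set.seed(seed)
  mirnas <- sprintf("hsa-miR-r%02d", 1:6)
  genes <- sprintf("G%02d", 1:8)
  priority <- data.frame(
    mirna_id = sample(mirnas, 5),
    comparison = sample(c("TvN", "F1vT"), 5, replace = TRUE),
    fold_change = sample(c(-1, 1), 5, replace = TRUE) * runif(5, 1.5, 8),
    p_value = runif(5, 1e-4, 0.04), stringsAsFactors = FALSE)
  priority <- priority[!duplicated(paste(priority$mirna_id,
                                         priority$comparison)), ]
  targets <- data.frame(
    mirna_id = sample(mirnas, 10, replace = TRUE),
    gene_symbol = sample(genes, 10, replace = TRUE),
    binding_probability = runif(10, 0.95, 1), region = "3UTR",
    validated = TRUE, source = NA_character_, stringsAsFactors = FALSE)
  grid <- expand.grid(gene_symbol = genes, comparison = c("TvN", "F1vT"),
                      fraction = c("membrane", "cytosolic"),
                      stringsAsFactors = FALSE)
  grid <- grid[sample(nrow(grid), 16), ]
  protein_de <- data.frame(
    grid, fold_change = sample(c(-1, 1), 16, replace = TRUE) *
      runif(16, 1.2, 6),
    p_value = runif(16, 1e-4, 0.05), stringsAsFactors = FALSE)
  list(priority = priority, targets = targets, protein_de = protein_de)
}

# Synthetic species databases built from known peptide blocks.
provenance_fixture <- function() {
  human_only <- c("MKTAYIAKQR", "WDENNPFY")
  mouse_only <- c("CCHHGKTW", "YYFMDDNK")
  shared <- c("AAAGGGSSSR", "TTTVVVPPK")
  list(human_only = human_only, mouse_only = mouse_only, shared = shared,
       human_db = c(h1 = paste0(human_only[1], shared[1]),
                    h2 = paste0(shared[2], human_only[2])),
       mouse_db = c(m1 = paste0(mouse_only[1], shared[1]),
                    m2 = paste0(shared[2], mouse_only[2])))
}

# Long-format priority table from a run_de result's passing features.
de_priority_long <- function(de) {
  rbind(
    data.frame(mirna_id = de$TvN$feature_id[de$TvN$passes_filter],
               comparison = "TvN",
               fold_change = de$TvN$fold_change[de$TvN$passes_filter],
               p_value = de$TvN$p_value[de$TvN$passes_filter],
               stringsAsFactors = FALSE),
    data.frame(mirna_id = de$F1vT$feature_id[de$F1vT$passes_filter],
               comparison = "F1vT",
               fold_change = de$F1vT$fold_change[de$F1vT$passes_filter],
               p_value = de$F1vT$p_value[de$F1vT$passes_filter],
               stringsAsFactors = FALSE))
}
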