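# Target filtering and inverse-expression attribution: match priority
# miRNAs to inversely expressed predicted target proteins per comparison
# and subcellular fraction, eliminate proteins whose mRNA moved with them
# (transcriptionally explained), and summarize multi-target miRNAs.

#' Filter predicted miRNA-target interactions
#'
#' Keeps interactions with binding probability at or above the threshold,
#' a binding site in the requested region, and (optionally) validated
#' catalogue support.
#'
#' @param targets data.frame from [read_target_table()].
#' @param min_prob minimum binding probability, inclusive (default 0.95).
#' @param region binding-site region to keep (default `"3UTR"`).
#' @param validated_only keep only validated interactions (default `TRUE`).
#' @return the surviving rows.
#' @export
filter_targets <- function(targets, min_prob = 0.95, region = "3UTR",
                           validated_only = TRUE) {
  stopifnot(is.data.frame(targets))
  keep <- targets$binding_probability >= min_prob &
    targets$region == region
  if (validated_only) keep <- keep & targets$validated
  out <- targets[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Per-miRNA fold-change lookup: comparison -> fc, or the fc of the only
# comparison the miRNA is DE in ("borrowed" direction).
.mirna_fc_for <- function(priority) {
  split(stats::setNames(priority$fold_change, priority$comparison),
        priority$mirna_id)
}

#' Match priority miRNAs to inversely expressed target proteins
#'
#' For every filtered target pair (miRNA m, gene g) and every protein DE
#' entry of g, emits one attribution hit per (m, g, comparison, fraction)
#' when the protein moved in the direction opposite to the miRNA
#' (`sign(mirna_fc) * sign(protein_fc) < 0`).
#'
#' Direction matching: the protein entry is judged against the miRNA's fold
#' change in the protein's comparison when the miRNA is differentially
#' expressed there. With `comparison_match = "either"` (default), a protein
#' entry in a comparison where the miRNA is not DE is judged against the
#' miRNA's own-comparison fold change, so a miRNA altered in only one
#' comparison can claim a target protein observed in the other — the
#' behaviour of the published integration tables. `"same"` restricts hits
#' to protein entries in the miRNA's own DE comparison(s).
#'
#' @param priority data.frame with columns `mirna_id`, `comparison`,
#'   `fold_change` (long format; see [priority_universe()] or
#'   [read_priority_table()]).
#' @param targets filtered target table (see [filter_targets()]).
#' @param protein_de data.frame from [read_protein_de_table()].
#' @param comparison_match `"either"` (default) or `"same"`, see above.
#' @return data.frame of hits: `mirna_id`, `gene_symbol`, `comparison`
#'   (the protein entry's), `fraction`, `mirna_fc` (the fold change used for
#'   the sign test), `protein_fc`, `protein_p`, `mrna_status` (initialized
#'   to `"absent"`; see [mrna_concordance_filter()]). Sorted by miRNA, gene,
#'   comparison, fraction.
#' @export
inverse_hits <- function(priority, targets, protein_de,
                         comparison_match = c("either", "same")) {
  comparison_match <- match.arg(comparison_match)
  stopifnot(all(c("mirna_id", "comparison", "fold_change") %in%
                  names(priority)),
            all(c("mirna_id", "gene_symbol") %in% names(targets)),
            all(c("gene_symbol", "comparison", "fraction", "fold_change",
                  "p_value") %in% names(protein_de)))
  empty <- data.frame(mirna_id = character(), gene_symbol = character(),
                      comparison = character(), fraction = character(),
                      mirna_fc = numeric(), protein_fc = numeric(),
                      protein_p = numeric(), mrna_status = character(),
                      stringsAsFactors = FALSE)
  if (nrow(priority) == 0 || nrow(targets) == 0 || nrow(protein_de) == 0) {
    return(empty)
  }
  pairs <- unique(targets[, c("mirna_id", "gene_symbol")])
  pairs <- pairs[pairs$mirna_id %in% priority$mirna_id, , drop = FALSE]
  fc_of <- .mirna_fc_for(priority)
  cand <- merge(pairs, protein_de, by = "gene_symbol")
  if (nrow(cand) == 0) return(empty)
  mirna_fc <- rep(NA_real_, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    fcs <- fc_of[[cand$mirna_id[i]]]
    cp <- cand$comparison[i]
    if (cp %in% names(fcs)) {
      mirna_fc[i] <- fcs[[cp]]
    } else if (comparison_match == "either") {
      mirna_fc[i] <- fcs[[1]]  # the miRNA's own (only) DE comparison
    }
  }
  keep <- !is.na(mirna_fc) & sign(mirna_fc) * sign(cand$fold_change) < 0
  out <- data.frame(mirna_id = cand$mirna_id[keep],
                    gene_symbol = cand$gene_symbol[keep],
                    comparison = cand$comparison[keep],
                    fraction = cand$fraction[keep],
                    mirna_fc = mirna_fc[keep],
                    protein_fc = cand$fold_change[keep],
                    protein_p = cand$p_value[keep],
                    mrna_status = rep("absent", sum(keep)),
                    stringsAsFactors = FALSE)
  out <- out[order(out$mirna_id, out$gene_symbol, out$comparison,
                   out$fraction, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Eliminate transcriptionally explained hits by mRNA concordance
#'
#' For each attribution hit, looks up the gene's mRNA DE entry in the hit's
#' comparison. A same-sign mRNA change marks the protein change as
#' transcriptionally explained (`concordant`) and removes the hit; an
#' opposite-sign entry (`discordant`) or no entry (`absent`) retains it.
#' Concordance is judged against the protein's sign, not the miRNA's.
#'
#' @param hits data.frame from [inverse_hits()].
#' @param mrna_de data.frame from [read_mrna_de_table()].
#' @return the surviving hits with `mrna_status` set; eliminated rows are
#'   attached as `attr(,"eliminated")`.
#' @export
mrna_concordance_filter <- function(hits, mrna_de) {
  stopifnot(is.data.frame(hits))
  if (nrow(hits) == 0) {
    attr(hits, "eliminated") <- hits
    return(hits)
  }
  key <- paste(mrna_de$gene_symbol, mrna_de$comparison, sep = "\r")
  mrna_fc <- stats::setNames(mrna_de$fold_change, key)
  hit_key <- paste(hits$gene_symbol, hits$comparison, sep = "\r")
  fc <- unname(mrna_fc[hit_key])
  status <- ifelse(is.na(fc), "absent",
                   ifelse(sign(fc) == sign(hits$protein_fc),
                          "concordant", "discordant"))
  hits$mrna_status <- status
  out <- hits[status != "concordant", , drop = FALSE]
  rownames(out) <- NULL
  eliminated <- hits[status == "concordant", , drop = FALSE]
  rownames(eliminated) <- NULL
  attr(out, "eliminated") <- eliminated
  out
}

#' Summarize miRNAs targeting multiple proteins
#'
#' Counts, per miRNA, the distinct gene symbols among its attribution hits
#' across all comparisons and fractions, and reports the miRNAs reaching
#' the threshold, sorted by count descending then miRNA id.
#'
#' @param hits data.frame of attribution hits.
#' @param min_proteins minimum distinct target proteins to report
#'   (default 2).
#' @return data.frame with `mirna_id`, `n_distinct_proteins`, `proteins`
#'   (comma-separated, sorted).
#' @export
multi_target_summary <- function(hits, min_proteins = 2) {
  stopifnot(is.data.frame(hits))
  if (nrow(hits) == 0) {
    return(data.frame(mirna_id = character(), n_distinct_proteins = integer(),
                      proteins = character(), stringsAsFactors = FALSE))
  }
  genes <- lapply(split(hits$gene_symbol, hits$mirna_id),
                  function(g) sort(unique(g)))
  out <- data.frame(mirna_id = names(genes),
                    n_distinct_proteins = vapply(genes, length, integer(1)),
                    proteins = vapply(genes, paste, character(1),
                                      collapse = ","),
                    stringsAsFactors = FALSE)
  out <- out[out$n_distinct_proteins >= min_proteins, , drop = FALSE]
  out <- out[order(-out$n_distinct_proteins, out$mirna_id, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
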