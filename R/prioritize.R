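# Priority views over the filtered DE tables: largest changes up and down
# per comparison, and miRNAs moving in the same direction in both
# comparisons.

#' Top-k features by fold-change magnitude in one direction
#'
#' Ranks the rows of a filtered DE table of one comparison by absolute
#' signed fold change, descending, within the requested direction. Ties are
#' broken by ascending p-value, then lexicographic feature id. Fewer than
#' `k` rows of the requested sign returns them all.
#'
#' @param de_table data.frame with columns `feature_id` (or `mirna_id`),
#'   `fold_change`, `p_value`; rows are expected to have passed
#'   [de_filter()].
#' @param k number of rows to keep (default 10).
#' @param direction `"up"` (fold change >= 1) or `"down"` (<= -1).
#' @return the selected rows in rank order, with a `direction` column.
#' @export
top_k <- function(de_table, k = 10, direction = c("up", "down")) {
  direction <- match.arg(direction)
  if (!is.numeric(k) || length(k) != 1 || k < 1) {
    stop("top_k: k must be a single number >= 1", call. = FALSE)
  }
  id_col <- if ("feature_id" %in% names(de_table)) "feature_id" else "mirna_id"
  stopifnot(all(c(id_col, "fold_change", "p_value") %in% names(de_table)))
  rows <- if (direction == "up") de_table$fold_change > 0
          else de_table$fold_change < 0
  out <- de_table[rows, , drop = FALSE]
  ord <- order(-abs(out$fold_change), out$p_value, out[[id_col]],
               method = "radix")
  out <- out[ord, , drop = FALSE][seq_len(min(k, nrow(out))), , drop = FALSE]
  out$direction <- rep(direction, nrow(out))
  rownames(out) <- NULL
  out
}

#' miRNAs differentially expressed in the same direction in both comparisons
#'
#' Intersects two filtered DE tables (one per comparison) and keeps the
#' features whose fold changes share the same sign in both. The result
#' carries both comparisons' fold changes and p-values and is sorted by the
#' first table's fold change, descending.
#'
#' @param de_a,de_b data.frames with `feature_id` (or `mirna_id`),
#'   `fold_change`, `p_value`, each already passing [de_filter()].
#' @param labels length-2 character: comparison tags for the two tables
#'   (default `c("TvN", "F1vT")`), used to suffix the output columns.
#' @return data.frame with columns `feature_id`, `fold_change_<a>`,
#'   `p_value_<a>`, `fold_change_<b>`, `p_value_<b>`, `direction`.
#' @export
same_direction <- function(de_a, de_b, labels = c("TvN", "F1vT")) {
  stopifnot(length(labels) == 2)
  pick <- function(df) {
    id_col <- if ("feature_id" %in% names(df)) "feature_id" else "mirna_id"
    data.frame(feature_id = df[[id_col]], fold_change = df$fold_change,
               p_value = df$p_value, stringsAsFactors = FALSE)
  }
  a <- pick(de_a); b <- pick(de_b)
  m <- merge(a, b, by = "feature_id", suffixes = paste0("_", labels))
  fc_a <- m[[paste0("fold_change_", labels[1])]]
  fc_b <- m[[paste0("fold_change_", labels[2])]]
  m <- m[sign(fc_a) == sign(fc_b), , drop = FALSE]
  m$direction <- ifelse(m[[paste0("fold_change_", labels[1])]] > 0,
                        "up-both", "down-both")
  m <- m[order(-m[[paste0("fold_change_", labels[1])]], m$feature_id,
               method = "radix"), , drop = FALSE]
  rownames(m) <- NULL
  m
}

#' Priority universe for downstream integration
#'
#' The union of the top-k up and down lists of both comparisons and the
#' same-direction list, deduplicated by (miRNA, comparison), in the long
#' format accepted by [inverse_hits()]: one row per (miRNA, comparison)
#' carrying that comparison's fold change and p-value.
#'
#' @param de_tvn,de_f1vt filtered DE tables for the two comparisons.
#' @param k top-list size per direction (default 10).
#' @return data.frame with columns `mirna_id`, `comparison`, `fold_change`,
#'   `p_value`.
#' @export
priority_universe <- function(de_tvn, de_f1vt, k = 10) {
  long <- function(df, comparison) {
    if (nrow(df) == 0) {
      return(data.frame(mirna_id = character(), comparison = character(),
                        fold_change = numeric(), p_value = numeric(),
                        stringsAsFactors = FALSE))
    }
    id_col <- if ("feature_id" %in% names(df)) "feature_id" else "mirna_id"
    data.frame(mirna_id = df[[id_col]], comparison = comparison,
               fold_change = df$fold_change, p_value = df$p_value,
               stringsAsFactors = FALSE)
  }
  tops <- rbind(long(top_k(de_tvn, k, "up"), "TvN"),
                long(top_k(de_tvn, k, "down"), "TvN"),
                long(top_k(de_f1vt, k, "up"), "F1vT"),
                long(top_k(de_f1vt, k, "down"), "F1vT"))
  both <- same_direction(de_tvn, de_f1vt)
  if (nrow(both) > 0) {
    tops <- rbind(tops,
                  data.frame(mirna_id = both$feature_id, comparison = "TvN",
                             fold_change = both$fold_change_TvN,
                             p_value = both$p_value_TvN,
                             stringsAsFactors = FALSE),
                  data.frame(mirna_id = both$feature_id, comparison = "F1vT",
                             fold_change = both$fold_change_F1vT,
                             p_value = both$p_value_F1vT,
                             stringsAsFactors = FALSE))
  }
  out <- tops[!duplicated(paste(tops$mirna_id, tops$comparison, sep = "\r")), ,
              drop = FALSE]
  out <- out[order(out$comparison, out$mirna_id, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
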