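#' @keywords internal
"_PACKAGE"

# Closed vocabularies shared across modules.
.comparisons <- c("TvN", "F1vT")
.fractions <- c("membrane", "cytosolic")
.groups <- c("N", "T", "F1")
.regions <- c("3UTR", "5UTR", "CDS")

.read_tsv <- function(path, required, what = "table") {
  if (!file.exists(path)) {
    stop(sprintf("%s file not found: '%s'", what, path), call. = FALSE)
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          comment.char = "#", stringsAsFactors = FALSE,
                          check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop(sprintf("%s '%s' is missing required column(s): %s",
                 what, path, paste(missing, collapse = ", ")), call. = FALSE)
  }
  df
}

.check_numeric_column <- function(x, column, what) {
  bad <- which(!is.finite(suppressWarnings(as.numeric(x))))
  if (length(bad) > 0) {
    stop(sprintf("%s: non-numeric or non-finite value '%s' in column '%s' (row %d)",
                 what, as.character(x[bad[1]]), column, bad[1]), call. = FALSE)
  }
  as.numeric(x)
}

.check_comparison <- function(x, what) {
  bad <- setdiff(unique(x), .comparisons)
  if (length(bad) > 0) {
    stop(sprintf("%s: unknown comparison label '%s' (must be one of %s)",
                 what, bad[1], paste(.comparisons, collapse = ", ")),
         call. = FALSE)
  }
  x
}

.check_signed_fc_column <- function(fc, what) {
  bad <- which(abs(fc) < 1)
  if (length(bad) > 0) {
    stop(sprintf(paste0("%s: fold_change %g (row %d) lies in (-1,1); signed ",
                        "linear fold changes use -x for x-fold down, so ",
                        "|fold_change| >= 1"),
                 what, fc[bad[1]], bad[1]), call. = FALSE)
  }
  fc
}

.check_p_column <- function(p, what) {
  bad <- which(!(p > 0 & p <= 1))
  if (length(bad) > 0) {
    stop(sprintf("%s: p_value %g (row %d) outside (0, 1]", what, p[bad[1]],
                 bad[1]), call. = FALSE)
  }
  p
}

#' Read a log2 expression matrix with its sample sheet
#'
#' Reads a features-by-samples TSV of log2 signal intensities together with a
#' sample sheet assigning every sample to one of the cohorts N (adjacent
#' normal), T (tumor) or F1 (first-passage patient-derived xenograft).
#'
#' @param path TSV with a `feature_id` column followed by one column per
#'   sample; cells are log2 signal values.
#' @param sample_sheet TSV with columns `sample_id` and `group`; groups must
#'   come from `{N, T, F1}`.
#' @return An object of class `expression_matrix`: a list with `values`
#'   (numeric matrix, features x samples, dimnames set), and `group_of`
#'   (named character vector, sample id -> group). Sample order is preserved
#'   from the matrix file.
#' @examples
#' mat <- tempfile(fileext = ".tsv"); sheet <- tempfile(fileext = ".tsv")
#' writeLines(c("feature_id\ts1\ts2\ts3\ts4",
#'              "hsa-miR-21-3p\t7.1\t7.3\t9.0\t9.2",
#'              "hsa-miR-375\t8.0\t8.1\t6.5\t6.4"), mat)
#' writeLines(c("sample_id\tgroup", "s1\tN", "s2\tN", "s3\tT", "s4\tT"), sheet)
#' em <- read_expression_matrix(mat, sheet)
#' em$group_of
#' @export
read_expression_matrix <- function(path, sample_sheet) {
  df <- .read_tsv(path, "feature_id", "expression matrix")
  sheet <- .read_tsv(sample_sheet, c("sample_id", "group"), "sample sheet")
  feature_ids <- as.character(df$feature_id)
  dup <- feature_ids[duplicated(feature_ids)]
  if (length(dup) > 0) {
    stop(sprintf("expression matrix: duplicate feature id '%s'", dup[1]),
         call. = FALSE)
  }
  sample_ids <- setdiff(names(df), "feature_id")
  if (length(sample_ids) == 0) {
    stop("expression matrix has no sample columns", call. = FALSE)
  }
  if (anyDuplicated(sheet$sample_id)) {
    stop(sprintf("sample sheet: duplicate sample id '%s'",
                 sheet$sample_id[duplicated(sheet$sample_id)][1]),
         call. = FALSE)
  }
  bad_group <- setdiff(unique(sheet$group), .groups)
  if (length(bad_group) > 0) {
    stop(sprintf("sample sheet: unknown group '%s' (must be one of %s)",
                 bad_group[1], paste(.groups, collapse = ", ")), call. = FALSE)
  }
  unassigned <- setdiff(sample_ids, sheet$sample_id)
  if (length(unassigned) > 0) {
    stop(sprintf("sample '%s' in the matrix is absent from the sample sheet",
                 unassigned[1]), call. = FALSE)
  }
  values <- matrix(NA_real_, nrow = length(feature_ids),
                   ncol = length(sample_ids),
                   dimnames = list(feature_ids, sample_ids))
  for (s in sample_ids) {
    values[, s] <- .check_numeric_column(df[[s]], s, "expression matrix")
  }
  group_of <- stats::setNames(as.character(sheet$group),
                              as.character(sheet$sample_id))[sample_ids]
  expression_matrix(values, group_of)
}

#' Construct an expression matrix object from in-memory values
#'
#' @param values numeric matrix (features x samples) of log2 signals with
#'   rownames (feature ids) and colnames (sample ids).
#' @param group_of named character vector mapping every sample id to one of
#'   `N`, `T`, `F1`.
#' @return `expression_matrix` object (see [read_expression_matrix()]).
#' @export
expression_matrix <- function(values, group_of) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("expression matrix values need feature rownames and sample colnames",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(values)) || anyDuplicated(colnames(values))) {
    stop("expression matrix: feature and sample ids must be unique",
         call. = FALSE)
  }
  if (any(!is.finite(values))) {
    stop("expression matrix: all log2 values must be finite", call. = FALSE)
  }
  group_of <- group_of[colnames(values)]
  if (any(is.na(group_of))) {
    stop("every sample must be assigned to exactly one group", call. = FALSE)
  }
  if (length(setdiff(unique(group_of), .groups)) > 0) {
    stop(sprintf("groups must come from {%s}", paste(.groups, collapse = ", ")),
         call. = FALSE)
  }
  structure(list(values = values, group_of = group_of),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d features x %d samples (groups: %s)\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s=%d", names(table(x$group_of)),
                            table(x$group_of)), collapse = ", ")))
  invisible(x)
}

#' Read a predicted miRNA-target interaction table
#'
#' One row per predicted interaction, as exported from a target-prediction
#' resource: miRNA id, gene symbol, binding probability, binding-site region
#' and whether the interaction has validated (catalogue) support.
#'
#' @param path TSV with columns `mirna_id`, `gene_symbol`,
#'   `binding_probability`, `region`, `validated` (and optionally `source`).
#'   The `validated` column accepts `0/1/true/false` case-insensitively.
#' @return data.frame with typed columns; `validated` is logical.
#' @export
read_target_table <- function(path) {
  df <- .read_tsv(path, c("mirna_id", "gene_symbol", "binding_probability",
                          "region", "validated"), "target table")
  if (nrow(df) == 0) {
    return(data.frame(mirna_id = character(), gene_symbol = character(),
                      binding_probability = numeric(), region = character(),
                      validated = logical(), source = character(),
                      stringsAsFactors = FALSE))
  }
  prob <- .check_numeric_column(df$binding_probability, "binding_probability",
                                "target table")
  bad <- which(prob < 0 | prob > 1)
  if (length(bad) > 0) {
    stop(sprintf("target table: binding_probability %g (row %d) outside [0, 1]",
                 prob[bad[1]], bad[1]), call. = FALSE)
  }
  region <- as.character(df$region)
  bad_region <- setdiff(unique(region), .regions)
  if (length(bad_region) > 0) {
    stop(sprintf("target table: unknown region '%s' (must be one of %s)",
                 bad_region[1], paste(.regions, collapse = ", ")),
         call. = FALSE)
  }
  v_raw <- tolower(trimws(as.character(df$validated)))
  validated <- rep(NA, length(v_raw))
  validated[v_raw %in% c("1", "true")] <- TRUE
  validated[v_raw %in% c("0", "false")] <- FALSE
  if (any(is.na(validated))) {
    stop(sprintf("target table: validated flag '%s' not one of 0/1/true/false",
                 v_raw[which(is.na(validated))[1]]), call. = FALSE)
  }
  data.frame(mirna_id = as.character(df$mirna_id),
             gene_symbol = as.character(df$gene_symbol),
             binding_probability = prob, region = region,
             validated = validated,
             source = if ("source" %in% names(df)) as.character(df$source)
                      else NA_character_,
             stringsAsFactors = FALSE)
}

#' Read a protein differential-expression table
#'
#' One row per protein change in one (comparison, subcellular fraction) cell:
#' signed linear fold change and p-value. Fold changes follow the signed
#' convention (-1.5 means 1.5-fold down); values in (-1, 1) are rejected.
#'
#' @param path TSV with columns `gene_symbol`, `comparison` (`TvN`/`F1vT`),
#'   `fraction` (`membrane`/`cytosolic`), `fold_change`, `p_value`.
#' @return validated data.frame; `(gene_symbol, comparison, fraction)` is
#'   unique within the file.
#' @export
read_protein_de_table <- function(path) {
  df <- .read_tsv(path, c("gene_symbol", "comparison", "fraction",
                          "fold_change", "p_value"), "protein DE table")
  out <- data.frame(gene_symbol = as.character(df$gene_symbol),
                    comparison = .check_comparison(as.character(df$comparison),
                                                   "protein DE table"),
                    fraction = as.character(df$fraction),
                    fold_change = numeric(nrow(df)), p_value = numeric(nrow(df)),
                    stringsAsFactors = FALSE)
  bad_fr <- setdiff(unique(out$fraction), .fractions)
  if (length(bad_fr) > 0) {
    stop(sprintf("protein DE table: unknown fraction '%s' (must be one of %s)",
                 bad_fr[1], paste(.fractions, collapse = ", ")), call. = FALSE)
  }
  if (nrow(df) > 0) {
    fc <- .check_numeric_column(df$fold_change, "fold_change",
                                "protein DE table")
    out$fold_change <- .check_signed_fc_column(fc, "protein DE table")
    p <- .check_numeric_column(df$p_value, "p_value", "protein DE table")
    out$p_value <- .check_p_column(p, "protein DE table")
    key <- paste(out$gene_symbol, out$comparison, out$fraction, sep = "\r")
    if (anyDuplicated(key)) {
      d <- out[duplicated(key), , drop = FALSE][1, ]
      stop(sprintf("protein DE table: duplicate entry for (%s, %s, %s)",
                   d$gene_symbol, d$comparison, d$fraction), call. = FALSE)
    }
  }
  out
}

#' Read an mRNA differential-expression table
#'
#' Like [read_protein_de_table()] but without the fraction dimension:
#' columns `gene_symbol`, `comparison`, `fold_change`, `p_value`.
#'
#' @param path TSV path.
#' @return validated data.frame; `(gene_symbol, comparison)` unique.
#' @export
read_mrna_de_table <- function(path) {
  df <- .read_tsv(path, c("gene_symbol", "comparison", "fold_change",
                          "p_value"), "mRNA DE table")
  out <- data.frame(gene_symbol = as.character(df$gene_symbol),
                    comparison = .check_comparison(as.character(df$comparison),
                                                   "mRNA DE table"),
                    fold_change = numeric(nrow(df)), p_value = numeric(nrow(df)),
                    stringsAsFactors = FALSE)
  if (nrow(df) > 0) {
    fc <- .check_numeric_column(df$fold_change, "fold_change", "mRNA DE table")
    out$fold_change <- .check_signed_fc_column(fc, "mRNA DE table")
    p <- .check_numeric_column(df$p_value, "p_value", "mRNA DE table")
    out$p_value <- .check_p_column(p, "mRNA DE table")
    key <- paste(out$gene_symbol, out$comparison, sep = "\r")
    if (anyDuplicated(key)) {
      d <- out[duplicated(key), , drop = FALSE][1, ]
      stop(sprintf("mRNA DE table: duplicate entry for (%s, %s)",
                   d$gene_symbol, d$comparison), call. = FALSE)
    }
  }
  out
}

#' Read a priority-miRNA table
#'
#' One row per (miRNA, comparison) with its signed fold change and p-value;
#' the format written for the priority lists and accepted by
#' [inverse_hits()].
#'
#' @param path TSV with columns `mirna_id`, `comparison`, `fold_change`,
#'   `p_value`.
#' @return validated data.frame; `(mirna_id, comparison)` unique.
#' @export
read_priority_table <- function(path) {
  df <- .read_tsv(path, c("mirna_id", "comparison", "fold_change", "p_value"),
                  "priority table")
  out <- data.frame(mirna_id = as.character(df$mirna_id),
                    comparison = .check_comparison(as.character(df$comparison),
                                                   "priority table"),
                    fold_change = numeric(nrow(df)), p_value = numeric(nrow(df)),
                    stringsAsFactors = FALSE)
  if (nrow(df) > 0) {
    fc <- .check_numeric_column(df$fold_change, "fold_change", "priority table")
    out$fold_change <- .check_signed_fc_column(fc, "priority table")
    p <- .check_numeric_column(df$p_value, "p_value", "priority table")
    out$p_value <- .check_p_column(p, "priority table")
    key <- paste(out$mirna_id, out$comparison, sep = "\r")
    if (anyDuplicated(key)) {
      stop(sprintf("priority table: duplicate entry for (%s, %s)",
                   out$mirna_id[duplicated(key)][1],
                   out$comparison[duplicated(key)][1]), call. = FALSE)
    }
  }
  out
}

# Format a vector for deterministic TSV output. Doubles are written with the
# fewest significant digits (15..17) that reparse to the identical value, so
# write/read round trips are exact.
.format_field <- function(x) {
  if (is.double(x)) {
    out <- as.character(x)
    for (digits in c(15L, 16L, 17L)) {
      bad <- which(!is.na(x) & suppressWarnings(as.numeric(out)) != x)
      if (length(bad) == 0) break
      out[bad] <- sprintf(paste0("%.", digits, "g"), x[bad])
    }
    out
  } else {
    as.character(x)
  }
}

#' Write a report table deterministically
#'
#' Writes any stage's record table as TSV with a stable column order (as
#' given) and a stable row sort (lexicographic over all columns, left to
#' right), so reruns on identical records are byte-identical. Numeric fields
#' are written with enough digits to reparse exactly. An optional provenance
#' header is written as a single `#`-prefixed comment line that the package's
#' readers skip.
#'
#' @param records data.frame of records (may have zero rows).
#' @param path output file path.
#' @param provenance optional single string recorded as a `# ...` header line
#'   (keep it free of timestamps if byte-identical reruns are wanted).
#' @param sort if `TRUE` (default) rows are sorted lexicographically by all
#'   columns; set `FALSE` to preserve a ranking already encoded in row order.
#' @return invisibly, the path.
#' @export
write_report <- function(records, path, provenance = NULL, sort = TRUE) {
  stopifnot(is.data.frame(records))
  cols <- lapply(records, .format_field)
  n <- nrow(records)
  if (sort && n > 1) {
    ord <- do.call(order, c(unname(cols), list(method = "radix")))
    cols <- lapply(cols, function(x) x[ord])
  }
  lines <- character(0)
  if (!is.null(provenance)) lines <- paste0("# ", provenance)
  lines <- c(lines, paste(names(records), collapse = "\t"))
  if (n > 0) {
    body <- do.call(paste, c(unname(cols), list(sep = "\t")))
    lines <- c(lines, body)
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Read back a report written by [write_report()]
#'
#' Generic TSV reader skipping `#` comment lines; columns are type-converted
#' (numeric, logical, character) the same way the writer formatted them.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_report <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          comment.char = "#", stringsAsFactors = FALSE,
                          check.names = FALSE)
  df
}
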