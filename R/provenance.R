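# Human/murine provenance of xenograft protein identifications from
# peptide evidence: exact substring matching of identifying peptides
# against the two proteome databases, then a per-protein category call.

.aa_alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Read peptide evidence
#'
#' @param path TSV with columns `protein_id`, `peptide_sequence`
#'   (uppercase amino-acid strings over the 20 standard residues).
#' @return validated data.frame.
#' @export
read_peptide_evidence <- function(path) {
  df <- .read_tsv(path, c("protein_id", "peptide_sequence"),
                  "peptide evidence")
  peptide_evidence(as.character(df$protein_id),
                   as.character(df$peptide_sequence))
}

#' Construct validated peptide evidence
#'
#' @param protein_id character vector of protein accessions.
#' @param peptide_sequence uppercase peptide strings, one per row.
#' @return data.frame with the two columns, validated.
#' @export
peptide_evidence <- function(protein_id, peptide_sequence) {
  stopifnot(length(protein_id) == length(peptide_sequence))
  peptide_sequence <- as.character(peptide_sequence)
  if (any(nchar(peptide_sequence) == 0)) {
    stop("peptide evidence: empty peptide sequence", call. = FALSE)
  }
  letters_used <- unique(strsplit(paste(peptide_sequence, collapse = ""),
                                  "")[[1]])
  bad <- setdiff(letters_used, .aa_alphabet)
  if (length(bad) > 0) {
    stop(sprintf("peptide evidence: non-standard residue '%s'", bad[1]),
         call. = FALSE)
  }
  data.frame(protein_id = as.character(protein_id),
             peptide_sequence = peptide_sequence, stringsAsFactors = FALSE)
}

# Load a protein database as a plain character vector of sequences.
.load_db <- function(db, what) {
  seqs <- if (is.character(db) && length(db) == 1 && file.exists(db)) {
    as.character(Biostrings::readAAStringSet(db))
  } else if (inherits(db, "AAStringSet")) {
    as.character(db)
  } else if (is.character(db)) {
    db
  } else {
    stop(sprintf("%s: expected a FASTA path, AAStringSet or character vector",
                 what), call. = FALSE)
  }
  if (length(seqs) == 0) {
    stop(sprintf("%s database is empty", what), call. = FALSE)
  }
  seqs
}

#' Classify identifying peptides as human-only, mouse-only or shared
#'
#' Exact substring matching of each peptide against every sequence of the
#' human and mouse proteome databases — no enzymatic-digest modelling or
#' mass tolerance, mirroring manual scrutiny of identifying peptides.
#'
#' @param evidence data.frame from [peptide_evidence()] /
#'   [read_peptide_evidence()].
#' @param human_db,mouse_db FASTA path, `Biostrings::AAStringSet`, or
#'   character vector of protein sequences; must be non-empty.
#' @param merge_il treat isoleucine and leucine as equivalent
#'   (mass-spectrometry convention) before matching; default `FALSE`.
#' @return the evidence with an `origin` column in
#'   `{human_only, mouse_only, shared, unmatched}`; unmatched peptides
#'   trigger a warning.
#' @export
classify_peptides <- function(evidence, human_db, mouse_db,
                              merge_il = FALSE) {
  stopifnot(is.data.frame(evidence),
            all(c("protein_id", "peptide_sequence") %in% names(evidence)))
  hs <- .load_db(human_db, "human")
  mm <- .load_db(mouse_db, "mouse")
  peps <- evidence$peptide_sequence
  if (merge_il) {
    hs <- gsub("I", "L", hs, fixed = TRUE)
    mm <- gsub("I", "L", mm, fixed = TRUE)
    peps <- gsub("I", "L", peps, fixed = TRUE)
  }
  in_db <- function(pep, db) any(grepl(pep, db, fixed = TRUE))
  in_h <- vapply(peps, in_db, logical(1), db = hs, USE.NAMES = FALSE)
  in_m <- vapply(peps, in_db, logical(1), db = mm, USE.NAMES = FALSE)
  origin <- ifelse(in_h & in_m, "shared",
                   ifelse(in_h, "human_only",
                          ifelse(in_m, "mouse_only", "unmatched")))
  if (any(origin == "unmatched")) {
    warning(sprintf("%d peptide(s) matched neither database (e.g. '%s')",
                    sum(origin == "unmatched"),
                    evidence$peptide_sequence[origin == "unmatched"][1]),
            call. = FALSE)
  }
  evidence$origin <- origin
  evidence
}

#' Call the species-of-origin category per protein
#'
#' At least one human-only peptide and no mouse-only peptide gives
#' `human_not_murine`; the mirror case gives `murine_not_human`; everything
#' else — all peptides shared, or conflicting species-unique evidence —
#' is `ambiguous`. Unmatched peptides are ignored for the call, but a
#' protein with no matched peptide at all is an error.
#'
#' @param classified output of [classify_peptides()].
#' @return data.frame with one row per protein: `protein_id`, `category`,
#'   `n_human_only`, `n_mouse_only`, `n_shared`.
#' @export
call_protein_origin <- function(classified) {
  stopifnot(is.data.frame(classified),
            all(c("protein_id", "origin") %in% names(classified)))
  per <- split(classified$origin, classified$protein_id)
  no_match <- names(per)[vapply(per, function(o) all(o == "unmatched"),
                                logical(1))]
  if (length(no_match) > 0) {
    stop(sprintf("protein(s) with only unmatched peptides: %s",
                 paste(no_match, collapse = ", ")), call. = FALSE)
  }
  calls <- lapply(per, function(o) {
    nh <- sum(o == "human_only"); nm <- sum(o == "mouse_only")
    ns <- sum(o == "shared")
    category <- if (nh >= 1 && nm == 0) "human_not_murine"
                else if (nm >= 1 && nh == 0) "murine_not_human"
                else "ambiguous"
    data.frame(category = category, n_human_only = nh, n_mouse_only = nm,
               n_shared = ns, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, calls)
  out <- cbind(data.frame(protein_id = names(per), stringsAsFactors = FALSE),
               out)
  out <- out[order(out$protein_id, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}
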