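# Scoring chosen so substitution-only variants of equal-length amplicons
# align without gaps, making percent identity exact Hamming arithmetic.
default_scoring <- function() {
  list(match = 1, mismatch = -1, gap_open = 2, gap_extend = 0.5)
}

scoring_matrix <- function(scoring) {
  b <- c("A", "C", "G", "T", "N")
  m <- matrix(scoring$mismatch, 5, 5, dimnames = list(b, b))
  diag(m) <- scoring$match
  # N is an unknown base: scored as a mismatch even against itself
  m["N", ] <- scoring$mismatch
  m[, "N"] <- scoring$mismatch
  m
}

#' Global-alignment percent identity
#'
#' Aligns two amplicon fragments end to end (Needleman-Wunsch, via
#' Biostrings) and reports percent identity with the alignment length --
#' gap columns included -- as the denominator.  `N` never counts as an
#' identical column.
#'
#' @param query,ref Nucleotide strings over `A`, `C`, `G`, `T`, `N`.
#' @param scoring List with `match`, `mismatch`, `gap_open`, `gap_extend`
#'   (penalties positive).  Defaults: +1 / -1 / 2 / 0.5.
#' @param end_gap_free If `TRUE`, use semi-global alignment (terminal gaps
#'   unpenalised) for length-variant inputs.
#' @return A list of class `alignment_result`: `aligned_query`,
#'   `aligned_ref`, `n_identical`, `alignment_length`, `identity_pct`.
#' @export
align_identity <- function(query, ref, scoring = default_scoring(),
                           end_gap_free = FALSE) {
  if (!nzchar(query) || !nzchar(ref)) stop("empty sequence")
  validate_sequence_set(stats::setNames(c(query, ref), c("q", "r")))
  aln <- Biostrings::pairwiseAlignment(
    query, ref,
    substitutionMatrix = scoring_matrix(scoring),
    gapOpening = abs(scoring$gap_open),
    gapExtension = abs(scoring$gap_extend),
    type = if (end_gap_free) "overlap" else "global")
  aq <- as.character(Biostrings::alignedPattern(aln))
  ar <- as.character(Biostrings::alignedSubject(aln))
  qc <- strsplit(aq, "")[[1]]
  rc <- strsplit(ar, "")[[1]]
  ident <- sum(qc == rc & qc %in% c("A", "C", "G", "T"))
  len <- length(qc)
  structure(list(aligned_query = aq, aligned_ref = ar,
                 n_identical = ident, alignment_length = len,
                 identity_pct = 100 * ident / len),
            class = "alignment_result")
}

# Vectorised engine: one query against a set of references.
identity_vs_set <- function(query, refs, scoring = default_scoring(),
                            end_gap_free = FALSE) {
  subj <- Biostrings::DNAStringSet(refs)
  aln <- Biostrings::pairwiseAlignment(
    rep(Biostrings::DNAStringSet(query), length(subj)), subj,
    substitutionMatrix = scoring_matrix(scoring),
    gapOpening = abs(scoring$gap_open),
    gapExtension = abs(scoring$gap_extend),
    type = if (end_gap_free) "overlap" else "global")
  len <- Biostrings::nchar(aln)
  if (!any(grepl("N", c(query, refs), fixed = TRUE))) {
    # fast path: nmatch() counts identical columns; valid because no
    # ambiguous base can inflate it
    n_ident <- Biostrings::nmatch(aln)
  } else {
    aq <- as.character(Biostrings::alignedPattern(aln))
    ar <- as.character(Biostrings::alignedSubject(aln))
    n_ident <- mapply(function(a, b) {
      x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
      sum(x == y & x %in% c("A", "C", "G", "T"))
    }, aq, ar, USE.NAMES = FALSE)
  }
  data.frame(biomarker_id = names(refs),
             n_identical = n_ident,
             alignment_length = len,
             identity_pct = 100 * n_ident / len,
             stringsAsFactors = FALSE)
}

#' Top-hit match of a query against biomarker references
#'
#' Returns the reference with maximal percent identity.  Ties are broken
#' deterministically: larger identical-column count first, then the
#' lexicographically smallest reference id.
#'
#' @param query A nucleotide string.
#' @param refs Named character vector of reference sequences.
#' @param threshold Match threshold in percent identity (default 97;
#'   inclusive, i.e. exactly 97.0 is a match).
#' @inheritParams align_identity
#' @return One-row data frame: `biomarker_id`, `identity_pct`, `is_match`.
#' @export
top_hit <- function(query, refs, threshold = 97,
                    scoring = default_scoring(), end_gap_free = FALSE) {
  if (!length(refs)) stop("empty reference set")
  res <- identity_vs_set(query, refs, scoring, end_gap_free)
  ord <- order(-res$identity_pct, -res$n_identical, res$biomarker_id)
  best <- res[ord[1], c("biomarker_id", "identity_pct"), drop = FALSE]
  best$is_match <- best$identity_pct >= threshold
  rownames(best) <- NULL
  best
}

#' Match consumer-gut ASVs to biomarker sequences
#'
#' Computes the top-hit biomarker for every query ASV and keeps those at or
#' above the identity threshold.
#'
#' @param queries Named character vector of consumer-gut ASV sequences.
#' @param biomarkers Named character vector of biomarker sequences.
#' @inheritParams top_hit
#' @return Data frame with columns `query_asv_id`, `biomarker_id`,
#'   `identity_pct` (matching queries only), with attributes
#'   `n_matched_queries` and `n_biomarkers_hit`.
#' @export
match_all <- function(queries, biomarkers, threshold = 97,
                      scoring = default_scoring(), end_gap_free = FALSE) {
  if (!length(queries) || !length(biomarkers))
    stop("both query and biomarker sets must be non-empty")
  rows <- lapply(names(queries), function(q) {
    hit <- top_hit(queries[[q]], biomarkers, threshold, scoring, end_gap_free)
    if (!hit$is_match) return(NULL)
    data.frame(query_asv_id = q, biomarker_id = hit$biomarker_id,
               identity_pct = hit$identity_pct, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(query_asv_id = character(), biomarker_id = character(),
                      identity_pct = numeric(), stringsAsFactors = FALSE)
  attr(out, "n_matched_queries") <- nrow(out)
  attr(out, "n_biomarkers_hit") <- length(unique(out$biomarker_id))
  out
}
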