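#' Filter matched biomarkers to those informative of carrion consumption
#'
#' A biomarker-matched gut ASV could simply be part of the resident GI
#' microbiome.  The exclusion filter keeps only matched ASVs that are
#' present (count >= 1) in at least one rat unambiguously shown to have
#' consumed bird and absent from every rat unambiguously shown not to
#' have.  Ambiguous rats are excluded from the filter entirely.
#'
#' @param matches Match table from [match_all()].
#' @param rat_table [asv_table()] of the consumer-gut samples.
#' @param calls Diet-call data frame from [call_diet_all()].
#' @return A list of class `informative_set`: `map` (data frame
#'   `query_asv_id`, `biomarker_id`, `identity_pct` for the informative
#'   subset) and provenance counts `n_matched_before`,
#'   `n_informative_after`, `n_biomarkers_hit`.
#' @export
find_informative <- function(matches, rat_table, calls) {
  stopifnot(inherits(rat_table, "asv_table"))
  consumed <- calls$sample_id[calls$status == "consumed"]
  not_consumed <- calls$sample_id[calls$status == "not_consumed"]
  if (!length(consumed) && !length(not_consumed))
    stop("no unambiguous rats: the informative filter needs confirmed ",
         "consumers and non-consumers")
  present <- function(asv, samples) {
    samples <- intersect(samples, rownames(rat_table$counts))
    if (!length(samples) || !asv %in% colnames(rat_table$counts)) return(FALSE)
    any(rat_table$counts[samples, asv] > 0)
  }
  keep <- vapply(matches$query_asv_id, function(a) {
    present(a, consumed) && !present(a, not_consumed)
  }, TRUE)
  map <- matches[keep, , drop = FALSE]
  rownames(map) <- NULL
  structure(list(map = map,
                 n_matched_before = nrow(matches),
                 n_informative_after = nrow(map),
                 n_biomarkers_hit = length(unique(map$biomarker_id))),
            class = "informative_set")
}

#' @export
print.informative_set <- function(x, ...) {
  cat(sprintf("<informative_set> %d of %d matched ASVs informative (%d biomarkers)\n",
              x$n_informative_after, x$n_matched_before, x$n_biomarkers_hit))
  invisible(x)
}

informative_count <- function(informative, rat_table, sample) {
  asvs <- intersect(informative$map$query_asv_id, colnames(rat_table$counts))
  if (!length(asvs) || !sample %in% rownames(rat_table$counts)) return(0L)
  sum(rat_table$counts[sample, asvs] > 0)
}

#' Classify confirmed bird consumers as likely scavengers
#'
#' A rat confirmed (by diet analysis) to have consumed bird is flagged
#' `carrion_likely` when its gut microbiome carries at least one
#' informative decayed-tissue biomarker ASV, and `predation_or_unknown`
#' otherwise.  Rats confirmed not to have consumed bird are `unresolved`
#' (the method makes no claim about them).
#'
#' @inheritParams find_informative
#' @param informative An `informative_set` from [find_informative()].
#' @return Data frame: `sample_id`, `sample_type`, `diet_status`,
#'   `carrion_flag`, `n_informative_asvs`, `supporting_asvs`
#'   (semicolon-joined ids).  Ambiguous rats are reported `unresolved`
#'   here; see [resolve_ambiguous()] for the exploratory rule.
#' @export
call_scavenging <- function(calls, informative, rat_table) {
  rows <- lapply(seq_len(nrow(calls)), function(i) {
    sid <- calls$sample_id[i]
    n <- informative_count(informative, rat_table, sid)
    asvs <- intersect(informative$map$query_asv_id, colnames(rat_table$counts))
    sup <- if (n > 0 && sid %in% rownames(rat_table$counts))
      asvs[rat_table$counts[sid, asvs] > 0] else character()
    flag <- if (calls$status[i] == "consumed") {
      if (n >= 1) "carrion_likely" else "predation_or_unknown"
    } else "unresolved"
    data.frame(sample_id = sid, sample_type = calls$sample_type[i],
               diet_status = calls$status[i], carrion_flag = flag,
               n_informative_asvs = n,
               supporting_asvs = paste(sup, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Exploratory resolution of ambiguous diet calls
#'
#' Rats whose diet assays were ambiguous can be suggested as carrion
#' consumers when their microbiome carries at least `min_asvs` (default 2)
#' informative biomarker ASVs.  This is an exploratory rule: the output is
#' labelled as such and should not be read as a confirmed diet call.
#'
#' @inheritParams call_scavenging
#' @param min_asvs Minimum number of informative ASVs required (>= 1).
#' @return Data frame over the ambiguous rats only, with `carrion_flag`
#'   `"suggested_carrion"` or `"unresolved"` and an `exploratory = TRUE`
#'   column.
#' @export
resolve_ambiguous <- function(calls, informative, rat_table, min_asvs = 2) {
  if (min_asvs < 1) stop("min_asvs must be >= 1")
  amb <- calls[calls$status == "ambiguous", , drop = FALSE]
  rows <- lapply(seq_len(nrow(amb)), function(i) {
    sid <- amb$sample_id[i]
    n <- informative_count(informative, rat_table, sid)
    data.frame(sample_id = sid, sample_type = amb$sample_type[i],
               diet_status = "ambiguous",
               carrion_flag = if (n >= min_asvs) "suggested_carrion" else "unresolved",
               n_informative_asvs = n, exploratory = TRUE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(sample_id = character(), sample_type = character(),
                      diet_status = character(), carrion_flag = character(),
                      n_informative_asvs = integer(), exploratory = logical())
  out
}

#' Cohort-level summary of diet and scavenging calls
#'
#' @param calls Diet-call data frame ([call_diet_all()]).
#' @param scav_calls Scavenging-call data frame ([call_scavenging()]).
#' @param species Optional named character vector mapping sample id to the
#'   consumed bird species (taken from `calls$species` when absent).
#' @return A list of class `cohort_report`: diet-status counts, carrion
#'   counts by sample type, distinct species consumed and with carrion
#'   evidence, and whole-cohort percentages (rounded to integers).
#' @export
summarize_cohort <- function(calls, scav_calls, species = NULL) {
  if (is.null(species))
    species <- stats::setNames(calls$species, calls$sample_id)
  n <- nrow(calls)
  n_consumed <- sum(calls$status == "consumed")
  n_not <- sum(calls$status == "not_consumed")
  n_amb <- sum(calls$status == "ambiguous")
  carrion <- scav_calls[scav_calls$carrion_flag == "carrion_likely", , drop = FALSE]
  by_type <- table(carrion$sample_type)
  sp_consumed <- unique(stats::na.omit(species[calls$sample_id[calls$status == "consumed"]]))
  sp_carrion <- unique(stats::na.omit(species[carrion$sample_id]))
  structure(list(
    n_samples = n,
    n_consumed = n_consumed, n_not_consumed = n_not, n_ambiguous = n_amb,
    n_carrion = nrow(carrion),
    carrion_by_type = by_type,
    n_species_consumed = length(sp_consumed),
    species_consumed = sort(sp_consumed),
    n_species_carrion = length(sp_carrion),
    species_carrion = sort(sp_carrion),
    pct_consumed = if (n) round(100 * n_consumed / n) else 0,
    pct_carrion = if (n) round(100 * nrow(carrion) / n) else 0
  ), class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf(paste0(
    "<cohort_report> %d samples: %d consumed bird (%d%%), %d not, %d ambiguous\n",
    "  likely carrion: %d rats (%d%%)"),
    x$n_samples, x$n_consumed, x$pct_consumed, x$n_not_consumed,
    x$n_ambiguous, x$n_carrion, x$pct_carrion))
  if (length(x$carrion_by_type))
    cat(" [", paste(sprintf("%s: %d", names(x$carrion_by_type),
                            x$carrion_by_type), collapse = ", "), "]", sep = "")
  cat(sprintf("\n  species consumed: %d (%s); with carrion evidence: %d (%s)\n",
              x$n_species_consumed, paste(x$species_consumed, collapse = ", "),
              x$n_species_carrion, paste(x$species_carrion, collapse = ", ")))
  invisible(x)
}
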