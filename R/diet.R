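PRIMER_PAIRS <- c("COI_BirdF1_AWCintR2", "Cytb_CorL_Cor3")

#' Site species roster
#'
#' The set of bird species expected at the study sites, used to accept or
#' reject Sanger species assignments, plus a genus-level fallback for
#' roster species lacking public reference sequences: a confident hit to an
#' off-roster congener (here *Lophura nycthemera*) is attributed to the
#' unique roster member of that genus (*Lophura leucomelanos*).
#'
#' @param species Character vector of expected species.
#' @param genus_fallback Named character vector: genus -> roster species.
#' @return A list of class `species_roster`.
#' @export
species_roster <- function(species = c("Myadestes obscurus",
                                       "Zosterops japonicus",
                                       "Lophura leucomelanos",
                                       "Meleagris gallopavo",
                                       "Chasiempis sandwichensis"),
                           genus_fallback = c(Lophura = "Lophura leucomelanos")) {
  if (length(genus_fallback)) {
    if (is.null(names(genus_fallback)) || any(names(genus_fallback) == ""))
      stop("genus_fallback must be named by genus")
    if (!all(genus_fallback %in% species))
      stop("genus_fallback targets must be roster species")
    if (anyDuplicated(names(genus_fallback)))
      stop("each fallback genus must map to exactly one species")
  }
  structure(list(species = species, genus_fallback = genus_fallback),
            class = "species_roster")
}

#' Assign a bird species from confident sequence-search hits
#'
#' A species is recorded only when every hit passing the e-value cutoff
#' (strict `< 1e-50`) names the same taxon with query coverage strictly
#' above 95, and that taxon is on the site roster or resolves through the
#' genus fallback.
#'
#' @param hits Data frame with columns `taxon`, `e_value`,
#'   `query_coverage_pct` (zero rows allowed).
#' @param roster A [species_roster()].
#' @param e_max E-value acceptance cutoff (default `1e-50`).
#' @param min_coverage Query-coverage cutoff in percent (default 95,
#'   strict).
#' @return List with `species` (character or `NA`) and `reason` (one of
#'   `"confirmed"`, `"no_confident_hit"`, `"low_quality"`, `"mixed"`,
#'   `"non_bird_taxon"`).
#' @export
assign_species <- function(hits, roster = species_roster(),
                           e_max = 1e-50, min_coverage = 95) {
  stopifnot(inherits(roster, "species_roster"))
  if (is.null(hits) || nrow(hits) == 0)
    return(list(species = NA_character_, reason = "no_confident_hit"))
  if (any(hits$e_value < 0)) stop("negative e-value")
  keep <- hits[hits$e_value < e_max, , drop = FALSE]
  if (nrow(keep) == 0)
    return(list(species = NA_character_, reason = "no_confident_hit"))
  taxa <- unique(keep$taxon)
  if (length(taxa) > 1)
    return(list(species = NA_character_, reason = "mixed"))
  if (any(keep$query_coverage_pct <= min_coverage))
    return(list(species = NA_character_, reason = "low_quality"))
  tax <- taxa[1]
  if (tax %in% roster$species)
    return(list(species = tax, reason = "confirmed"))
  genus <- strsplit(tax, " ")[[1]][1]
  if (genus %in% names(roster$genus_fallback))
    return(list(species = unname(roster$genus_fallback[genus]),
                reason = "confirmed"))
  list(species = NA_character_, reason = "non_bird_taxon")
}

parse_top_taxa <- function(s) {
  if (is.na(s) || !nzchar(s)) {
    return(data.frame(taxon = character(), e_value = numeric(),
                      query_coverage_pct = numeric(), stringsAsFactors = FALSE))
  }
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
  data.frame(taxon = gsub("_", " ", vapply(parts, `[`, "", 1)),
             e_value = as.numeric(vapply(parts, `[`, "", 2)),
             query_coverage_pct = as.numeric(vapply(parts, `[`, "", 3)),
             stringsAsFactors = FALSE)
}

#' Call bird-consumption status for one sample
#'
#' Applies the three-way rule to the per-primer assay evidence for a rat
#' sample:
#' * **consumed** -- at least one assay produced a high-quality Sanger read
#'   (quality > 50) whose confident hits resolve to a roster species;
#' * **not_consumed** -- no PCR band in any replicate of either primer pair
#'   (requires at least two band-negative replicates per pair, four tests
#'   in total, to protect against false negatives);
#' * **ambiguous** -- anything else: a band with a low-quality or mixed
#'   trace, a confident non-bird hit, or conflicting confident species
#'   between the two loci.
#'
#' @param sample_id Sample identifier.
#' @param assays Data frame of assay evidence for this sample, columns
#'   `primer_pair`, `replicate`, `band_in_size_range` (logical),
#'   `quality_pct` (numeric or `NA`), `mixed_trace` (logical), `top_taxa`
#'   (string `"taxon:evalue:coverage;..."`, `_` for spaces in taxa, empty
#'   when nothing was sequenced).
#' @param roster A [species_roster()].
#' @param min_quality Sanger quality threshold in percent (default 50,
#'   strict >).
#' @inheritParams assign_species
#' @return List of class `diet_call`: `sample_id`, `status`, `species`
#'   (`NA` unless consumed), `reason`.
#' @export
call_diet <- function(sample_id, assays, roster = species_roster(),
                      min_quality = 50, e_max = 1e-50, min_coverage = 95) {
  miss <- setdiff(PRIMER_PAIRS, unique(assays$primer_pair))
  if (length(miss))
    stop("sample ", sample_id, " lacks assays for primer pair(s): ",
         paste(miss, collapse = ", "))
  assays$band_in_size_range <- as.logical(assays$band_in_size_range)
  assays$mixed_trace <- as.logical(assays$mixed_trace)

  species_found <- character()
  reasons <- character()
  for (i in seq_len(nrow(assays))) {
    a <- assays[i, ]
    if (!a$band_in_size_range) next
    if (is.na(a$quality_pct) || a$quality_pct <= min_quality) {
      reasons <- c(reasons, "low_quality"); next
    }
    if (isTRUE(a$mixed_trace)) {
      reasons <- c(reasons, "mixed"); next
    }
    asg <- assign_species(parse_top_taxa(a$top_taxa), roster, e_max, min_coverage)
    if (!is.na(asg$species)) species_found <- c(species_found, asg$species)
    else reasons <- c(reasons, asg$reason)
  }

  if (length(unique(species_found)) > 1) {
    call <- list(sample_id = sample_id, status = "ambiguous",
                 species = NA_character_, reason = "mixed")
  } else if (length(species_found) >= 1) {
    call <- list(sample_id = sample_id, status = "consumed",
                 species = species_found[1], reason = "confirmed")
  } else if (!any(assays$band_in_size_range)) {
    per_pair <- table(factor(assays$primer_pair, levels = PRIMER_PAIRS))
    if (nrow(assays) < 4 || any(per_pair < 2))
      stop("sample ", sample_id, ": 'not consumed' requires >=2 band-negative ",
           "replicates per primer pair (four tests)")
    call <- list(sample_id = sample_id, status = "not_consumed",
                 species = NA_character_, reason = "no_amplification")
  } else {
    reason <- if (length(reasons)) reasons[1] else "low_quality"
    call <- list(sample_id = sample_id, status = "ambiguous",
                 species = NA_character_, reason = reason)
  }
  structure(call, class = "diet_call")
}

#' Call diet status for a whole evidence table
#'
#' @param evidence Data frame of assay evidence for many samples: the
#'   columns of [call_diet()]'s `assays` plus `sample_id` and
#'   `sample_type`.
#' @inheritParams call_diet
#' @return Data frame with one row per sample: `sample_id`, `sample_type`,
#'   `status`, `species`, `reason`.
#' @export
call_diet_all <- function(evidence, roster = species_roster(),
                          min_quality = 50, e_max = 1e-50, min_coverage = 95) {
  ids <- unique(evidence$sample_id)
  rows <- lapply(ids, function(sid) {
    sub <- evidence[evidence$sample_id == sid, , drop = FALSE]
    cl <- call_diet(sid, sub, roster, min_quality, e_max, min_coverage)
    data.frame(sample_id = sid, sample_type = sub$sample_type[1],
               status = cl$status, species = cl$species, reason = cl$reason,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Diet-call contingency table
#'
#' @param calls Data frame from [call_diet_all()] (needs `sample_type` and
#'   `status`).
#' @return Integer matrix, sample types in rows, statuses (`consumed`,
#'   `not_consumed`, `ambiguous`) in columns, with a `total` margin row
#'   and column.
#' @export
summarize_diet <- function(calls) {
  statuses <- c("consumed", "not_consumed", "ambiguous")
  types <- sort(unique(calls$sample_type))
  m <- matrix(0L, nrow = length(types), ncol = length(statuses),
              dimnames = list(types, statuses))
  if (nrow(calls)) {
    tab <- table(factor(calls$sample_type, levels = types),
                 factor(calls$status, levels = statuses))
    m[] <- as.integer(tab)
  }
  m <- rbind(m, total = colSums(m))
  cbind(m, total = rowSums(m))
}
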