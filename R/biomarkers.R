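#' Pool presence by sampling day
#'
#' Merges the replicate decomposition sites: an ASV is "present" on a day
#' if it has a count of at least 1 in any tissue sample collected on that
#' day.  Input should already be control-cleaned and singleton-filtered.
#'
#' @param x An [asv_table()] of chicken-tissue samples, each with a day
#'   label in its metadata.
#' @return A named list mapping ASV id to the character vector of day
#'   labels on which it was observed.  ASVs never observed are omitted.
#' @export
pool_presence_by_day <- function(x) {
  stopifnot(inherits(x, "asv_table"))
  day <- as.character(x$metadata$day)
  if (any(is.na(day)))
    stop("sample(s) without a day label: ",
         paste(x$metadata$sample_id[is.na(day)], collapse = ", "))
  pres <- x$counts > 0
  # day x ASV presence: OR across samples sharing a day
  day_pres <- rowsum(pres + 0L, group = day) > 0
  prof <- lapply(colnames(pres), function(a) {
    d <- rownames(day_pres)[day_pres[, a]]
    d[order(match(d, DAY_LABELS))]
  })
  names(prof) <- colnames(pres)
  prof[vapply(prof, length, 1L) > 0]
}

#' Classify decay-status biomarkers
#'
#' An ASV is a fresh-tissue biomarker when its pooled day occupancy lies
#' entirely within the fresh window (day 0 lab, day 0 field, day 1), and a
#' decayed-tissue biomarker when it lies entirely within the decayed window
#' (days 2, 4, 7, 11).  ASVs observed in both windows are biomarkers of
#' neither.
#'
#' @param profile Occupancy profile from [pool_presence_by_day()].
#' @return A list of class `biomarker_set` with elements `fresh_ids`,
#'   `decayed_ids`, and `first_detection_day` (named character vector over
#'   all classified biomarkers; D0_LAB sorts before D0_FIELD, then field
#'   days in time order).
#' @export
classify_biomarkers <- function(profile) {
  if (!length(profile)) stop("empty occupancy profile")
  occ_in <- function(days, window) all(days %in% window)
  fresh <- names(profile)[vapply(profile, occ_in, TRUE, window = FRESH_WINDOW)]
  decayed <- names(profile)[vapply(profile, occ_in, TRUE, window = DECAYED_WINDOW)]
  ids <- c(fresh, decayed)
  first <- vapply(profile[ids], function(d) d[which.min(match(d, DAY_LABELS))], "")
  structure(list(fresh_ids = fresh, decayed_ids = decayed,
                 first_detection_day = first),
            class = "biomarker_set")
}

#' @export
print.biomarker_set <- function(x, ...) {
  cat(sprintf("<biomarker_set> %d fresh, %d decayed\n",
              length(x$fresh_ids), length(x$decayed_ids)))
  invisible(x)
}

#' Summarise a biomarker set
#'
#' @param b A `biomarker_set` from [classify_biomarkers()].
#' @return Named integer vector `c(n_fresh, n_decayed, n_total)`.
#' @export
biomarker_summary <- function(b) {
  stopifnot(inherits(b, "biomarker_set"))
  if (length(intersect(b$fresh_ids, b$decayed_ids)))
    stop("invalid biomarker_set: fresh and decayed sets overlap")
  c(n_fresh = length(b$fresh_ids),
    n_decayed = length(b$decayed_ids),
    n_total = length(b$fresh_ids) + length(b$decayed_ids))
}
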