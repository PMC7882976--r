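#' Day labels of the decomposition time series
#'
#' The seven categorical sampling days: a laboratory control at day 0 plus
#' field collections on days 0, 1, 2, 4, 7 and 11.  The "fresh" window is
#' \{D0_LAB, D0_FIELD, D1\}; the "decayed" window is \{D2, D4, D7, D11\}.
#' The two windows are disjoint and exhaustive.
#'
#' @format Character vectors of day labels.
#' @name day-windows
NULL

#' @rdname day-windows
#' @export
DAY_LABELS <- c("D0_LAB", "D0_FIELD", "D1", "D2", "D4", "D7", "D11")

#' @rdname day-windows
#' @export
FRESH_WINDOW <- c("D0_LAB", "D0_FIELD", "D1")

#' @rdname day-windows
#' @export
DECAYED_WINDOW <- c("D2", "D4", "D7", "D11")

SAMPLE_TYPES <- c("chicken_tissue", "rat_feces", "rat_stomach", "negative_control")

#' Construct an ASV count table
#'
#' Bundles a samples-by-ASVs count matrix with per-sample metadata and
#' validates the invariants every downstream stage relies on: non-negative
#' integer counts, unique identifiers, and metadata rows aligned with the
#' matrix rows.
#'
#' @param counts Integer matrix, samples in rows, ASVs in columns.  Row and
#'   column names are taken as sample and ASV identifiers.
#' @param metadata Data frame with columns `sample_id`, `sample_type`
#'   (one of `"chicken_tissue"`, `"rat_feces"`, `"rat_stomach"`,
#'   `"negative_control"`), `site`, `day` (a day label or `NA`) and
#'   `is_control` (logical).  One row per sample, matched by `sample_id`.
#' @return An object of class `asv_table`: a list with elements `counts`
#'   (integer matrix) and `metadata` (data frame, rows ordered as the
#'   matrix rows).  Per-sample read depths are available via [depths()].
#' @export
asv_table <- function(counts, metadata) {
  if (!is.matrix(counts)) stop("`counts` must be a matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("`counts` must have sample row names and ASV column names")
  if (anyDuplicated(rownames(counts))) stop("duplicate sample ids in counts")
  if (anyDuplicated(colnames(counts))) stop("duplicate ASV ids in counts")
  if (any(is.na(counts))) stop("missing values in counts")
  if (any(counts < 0)) stop("negative counts are not allowed")
  if (any(counts != round(counts))) stop("counts must be integers")
  storage.mode(counts) <- "integer"

  req <- c("sample_id", "sample_type", "site", "day", "is_control")
  miss <- setdiff(req, names(metadata))
  if (length(miss)) stop("metadata lacks columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(metadata$sample_id)) stop("duplicate sample ids in metadata")
  absent <- setdiff(rownames(counts), metadata$sample_id)
  if (length(absent))
    stop("samples lacking metadata: ", paste(absent, collapse = ", "))
  bad_type <- setdiff(unique(metadata$sample_type), SAMPLE_TYPES)
  if (length(bad_type))
    stop("unknown sample_type: ", paste(bad_type, collapse = ", "))
  bad_day <- setdiff(stats::na.omit(unique(as.character(metadata$day))), DAY_LABELS)
  if (length(bad_day))
    stop("unknown day label: ", paste(bad_day, collapse = ", "))

  metadata <- metadata[match(rownames(counts), metadata$sample_id), req, drop = FALSE]
  rownames(metadata) <- NULL
  metadata$is_control <- as.logical(metadata$is_control)
  structure(list(counts = counts, metadata = metadata), class = "asv_table")
}

#' @export
print.asv_table <- function(x, ...) {
  cat(sprintf("<asv_table> %d samples x %d ASVs\n",
              nrow(x$counts), ncol(x$counts)))
  tt <- table(x$metadata$sample_type)
  cat("  sample types:", paste(sprintf("%s=%d", names(tt), tt), collapse = ", "), "\n")
  invisible(x)
}

#' @rdname asv_table
#' @param x An `asv_table`.
#' @export
depths <- function(x) {
  stopifnot(inherits(x, "asv_table"))
  rowSums(x$counts)
}

#' @rdname asv_table
#' @export
sample_ids <- function(x) rownames(x$counts)

#' @rdname asv_table
#' @export
asv_ids <- function(x) colnames(x$counts)

# subset rows/columns, keeping metadata aligned
subset_table <- function(x, samples = NULL, asvs = NULL) {
  counts <- x$counts
  if (!is.null(samples)) counts <- counts[samples, , drop = FALSE]
  if (!is.null(asvs)) counts <- counts[, asvs, drop = FALSE]
  meta <- x$metadata[match(rownames(counts), x$metadata$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  structure(list(counts = counts, metadata = meta), class = "asv_table")
}

#' Read and write ASV tables
#'
#' The on-disk format is a tab-separated count matrix (first column = sample
#' id, remaining header fields = ASV ids) plus a sidecar metadata TSV with
#' columns `sample_id`, `sample_type`, `site`, `day`, `is_control`.
#'
#' @param path Path to the count matrix TSV.
#' @param metadata_path Path to the metadata TSV.
#' @return [load_asv_table()] returns a validated [asv_table()].
#' @export
load_asv_table <- function(path, metadata_path) {
  raw <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stop("count table needs a sample column plus >=1 ASV column")
  ids <- as.character(raw[[1]])
  mat <- as.matrix(raw[, -1, drop = FALSE])
  if (!is.numeric(mat)) {
    bad <- which(!apply(raw[, -1, drop = FALSE], 2, function(v) {
      suppressWarnings(!any(is.na(as.numeric(v))))
    }))
    stop("malformed numeric cell(s) in column(s): ",
         paste(colnames(raw)[-1][bad], collapse = ", "))
  }
  rownames(mat) <- ids
  meta <- utils::read.delim(metadata_path, stringsAsFactors = FALSE,
                            na.strings = c("NA", ""))
  meta$day <- as.character(meta$day)
  asv_table(mat, meta)
}

#' @rdname load_asv_table
#' @param x An `asv_table` to write.
#' @export
write_asv_table <- function(x, path, metadata_path) {
  stopifnot(inherits(x, "asv_table"))
  df <- data.frame(sample_id = rownames(x$counts), x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(x$metadata, metadata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(x)
}

#' Read sequence and tree inputs
#'
#' `load_fasta()` reads ASV representative sequences into a named character
#' vector (the package's sequence-set representation), validating the
#' alphabet (`A`, `C`, `G`, `T`, with `N` tolerated and treated as a
#' mismatch downstream) and a configurable length band.  `load_newick()`
#' reads a phylogeny with `ape`, midpoint-rooting unrooted inputs.
#'
#' @param path File path.
#' @param min_len,max_len Accepted sequence length band (nt).
#' @return A named character vector of uppercase sequences.
#' @export
load_fasta <- function(path, min_len = 300, max_len = 500) {
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(ss))
  validate_sequence_set(seqs, min_len = min_len, max_len = max_len)
  seqs
}

validate_sequence_set <- function(seqs, min_len = 1, max_len = Inf) {
  if (!length(seqs)) stop("empty sequence set")
  if (is.null(names(seqs)) || any(names(seqs) == ""))
    stop("all sequences must be named")
  if (anyDuplicated(names(seqs)))
    stop("duplicate sequence id(s): ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  if (any(grepl("[^ACGTN]", seqs)))
    stop("sequences contain characters outside {A,C,G,T,N}")
  len <- nchar(seqs)
  if (any(len < min_len | len > max_len))
    stop("sequence length outside the accepted band [",
         min_len, ", ", max_len, "]: ",
         paste(names(seqs)[len < min_len | len > max_len], collapse = ", "))
  invisible(seqs)
}

#' @rdname load_fasta
#' @param seqs Named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::DNAStringSet(seqs)
  names(ss) <- names(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(seqs)
}

#' @rdname load_fasta
#' @param expected_leaves Optional character vector; if supplied, the tree's
#'   tip labels must contain all of these identifiers.
#' @return `load_newick()` returns a rooted `ape::phylo` with branch lengths.
#' @export
load_newick <- function(path, expected_leaves = NULL) {
  tree <- ape::read.tree(path)
  if (is.null(tree$edge.length)) stop("tree lacks branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  if (!ape::is.rooted(tree)) {
    tree <- midpoint_root(tree)
    message("unrooted input tree was midpoint-rooted")
  }
  if (!is.null(expected_leaves)) {
    miss <- setdiff(expected_leaves, tree$tip.label)
    if (length(miss))
      stop("tree is missing leaves for ASV(s): ", paste(miss, collapse = ", "))
  }
  tree
}

midpoint_root <- function(tree) phangorn::midpoint(tree)

#' Remove contaminant ASVs flagged by negative controls
#'
#' Any ASV with a nonzero count in any negative-control sample is removed
#' from every sample, and the control samples themselves are dropped.  This
#' is the strictest defensible contaminant rule for sequencing runs that
#' carried extraction and PCR blanks.
#'
#' @param x An [asv_table()].
#' @return An `asv_table` without control samples or control-detected ASVs.
#'   With no control samples present the table is returned unchanged.
#' @export
remove_control_asvs <- function(x) {
  stopifnot(inherits(x, "asv_table"))
  is_ctrl <- x$metadata$is_control | x$metadata$sample_type == "negative_control"
  if (!any(is_ctrl)) return(x)
  ctrl_counts <- x$counts[is_ctrl, , drop = FALSE]
  contaminated <- colSums(ctrl_counts > 0) > 0
  subset_table(x,
               samples = rownames(x$counts)[!is_ctrl],
               asvs = colnames(x$counts)[!contaminated])
}

#' Drop singleton ASVs
#'
#' Retains exactly the ASVs observed (count >= 1) in at least two samples.
#' Applied before day pooling, mirroring the read-processing convention for
#' denoised amplicon tables.
#'
#' @param x An [asv_table()].
#' @return The filtered `asv_table`.
#' @export
filter_singletons <- function(x) {
  stopifnot(inherits(x, "asv_table"))
  keep <- colSums(x$counts > 0) >= 2
  subset_table(x, asvs = colnames(x$counts)[keep])
}

#' Drop low-coverage samples
#'
#' @param x An [asv_table()].
#' @param min_depth Minimum per-sample read count to retain (default 2000).
#' @return The filtered `asv_table`, with attribute `"dropped"` holding a
#'   data frame of removed samples and their depths.
#' @export
filter_low_depth <- function(x, min_depth = 2000) {
  stopifnot(inherits(x, "asv_table"), min_depth >= 0)
  d <- depths(x)
  drop <- d < min_depth
  if (all(drop))
    stop("min_depth = ", min_depth, " removes every sample (max depth ",
         max(d), ")")
  if (any(drop))
    message("dropping ", sum(drop), " low-depth sample(s): ",
            paste(sprintf("%s (%d reads)", names(d)[drop], d[drop]),
                  collapse = ", "))
  out <- subset_table(x, samples = names(d)[!drop])
  attr(out, "dropped") <- data.frame(sample_id = names(d)[drop],
                                     depth = unname(d[drop]))
  out
}

#' Total-sum scaling
#'
#' Converts counts to within-sample proportions (each row divided by its
#' read depth), the normalisation used before abundance-weighted
#' dissimilarities such as Bray-Curtis.
#'
#' @param x An [asv_table()].
#' @return A numeric matrix of proportions; every row sums to 1.
#' @export
total_sum_scale <- function(x) {
  stopifnot(inherits(x, "asv_table"))
  d <- depths(x)
  if (any(d == 0))
    stop("zero-depth sample(s) ", paste(names(d)[d == 0], collapse = ", "),
         "; remove them with filter_low_depth() first")
  sweep(x$counts, 1, d, "/")
}
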