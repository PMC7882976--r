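#' Load the packaged study tables
#'
#' Three small tables from the Hawaii rat-scavenging study ship with the
#' package as plain TSV so downstream bookkeeping (diet-call contingency
#' totals, informative-biomarker counts, carrion-rat counts) can be
#' recomputed without the deposited sequencing data:
#'
#' * `table1` — detection of bird DNA in 51 rat samples by sample type
#'   (feces / stomach) and diet status (yes / no / ambiguous).
#' * `table2` — the 15 informative rat-gut ASVs, the 7 decayed-tissue
#'   biomarkers they matched, percent similarity, taxonomy and per-ASV rat
#'   counts.
#' * `table3` — per-primer Sanger species assignments for the 20
#'   bird-consuming samples, with raw off-roster hits (the *Lophura*
#'   genus fallback) and a flag for rats carrying decayed-tissue
#'   biomarkers (likely carrion consumption).
#'
#' @param name One of `"table1"`, `"table2"`, `"table3"`.
#' @return A data frame.
#' @export
load_paper_fixture <- function(name = c("table1", "table2", "table3")) {
  name <- match.arg(name)
  path <- system.file("extdata", "tables", paste0(name, ".tsv"),
                      package = "scavtrace", mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = c("NA"))
  if (name == "table1" && sum(df$n) != 51L)
    stop("corrupt fixture: table1 sample sizes must sum to 51")
  df
}
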