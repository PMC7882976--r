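# Small in-code fixture builders shared across test files.

make_table <- function(counts, sample_type = "rat_feces", site = "K01",
                       day = NA_character_, is_control = FALSE,
                       sample_ids = NULL, asv_ids = NULL) {
  if (!is.matrix(counts)) counts <- matrix(counts, nrow = length(sample_type))
  if (is.null(sample_ids))
    sample_ids <- sprintf("s%02d", seq_len(nrow(counts)))
  if (is.null(asv_ids))
    asv_ids <- sprintf("a%02d", seq_len(ncol(counts)))
  dimnames(counts) <- list(sample_ids, asv_ids)
  meta <- data.frame(
    sample_id = sample_ids,
    sample_type = rep_len(sample_type, nrow(counts)),
    site = rep_len(site, nrow(counts)),
    day = rep_len(day, nrow(counts)),
    is_control = rep_len(is_control, nrow(counts)),
    stringsAsFactors = FALSE)
  asv_table(counts, meta)
}

random_table <- function(n_samples, n_asvs, seed, max_count = 20, ...) {
  set.seed(seed)
  counts <- matrix(rpois(n_samples * n_asvs, 1.2) *
                     rbinom(n_samples * n_asvs, 1, 0.5),
                   n_samples, n_asvs)
  counts[counts > max_count] <- max_count
  make_table(counts, ...)
}

random_seq <- function(len, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# evidence rows for one sample covering both primer pairs
evidence_rows <- function(sample_id, sample_type = "feces",
                          band = c(FALSE, FALSE, FALSE, FALSE),
                          quality = rep(NA_real_, 4),
                          mixed = rep(FALSE, 4),
                          taxa = rep("", 4)) {
  data.frame(sample_id = sample_id, sample_type = sample_type,
             primer_pair = rep(c("COI_BirdF1_AWCintR2", "Cytb_CorL_Cor3"),
                               each = 2),
             replicate = rep(1:2, 2),
             band_in_size_range = band, quality_pct = quality,
             mixed_trace = mixed, top_taxa = taxa,
             stringsAsFactors = FALSE)
}

small_pipeline_configs <- function(seed = 7, ambiguous = 0,
                                   detection = 1, sporadic = 0, spanning = 0) {
  list(
    decomposition = decomposition_config(
      n_sites = 4, n_fresh_only = 3, n_decayed_only = 10,
      n_spanning = spanning, n_sporadic = sporadic,
      detection_prob = detection, mean_depth = 500, seed = seed),
    cohort = cohort_config(
      n_rats = 20, n_feces = 11, n_stomach = 9, frac_consumed = 0.5,
      frac_scavenger = 0.5, frac_ambiguous = ambiguous,
      n_carrion_variants = 6, n_biomarkers_used = 4, n_confounders = 2,
      n_resident = 30, mean_depth = 2000, seed = seed + 1))
}
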