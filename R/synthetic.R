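# Run code under a given RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, code) {
  if (is.null(seed)) stop("seed is mandatory for every stochastic step")
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a random 16S amplicon fragment
#'
#' Uniform-random nucleotide string, the stand-in for a V3-V5 amplicon
#' (default 425 nt).  Deterministic for a given seed.
#'
#' @param length Fragment length in nt (>= 50).
#' @param seed Integer seed.
#' @return A character scalar over `A`, `C`, `G`, `T`.
#' @export
generate_16s_fragment <- function(length = 425, seed) {
  if (length < 50) stop("fragment length must be >= 50 nt")
  with_seed(seed,
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = ""))
}

#' Introduce a fixed number of substitutions
#'
#' Substitution-only mutation: the output differs from the input at exactly
#' `n_subs` positions (each replacement differs from the original base), so
#' percent identity against the parent is exactly
#' `(length - n_subs) / length`.
#'
#' @param seq Nucleotide string.
#' @param n_subs Number of substitutions (0 to `nchar(seq)`).
#' @param seed Integer seed.
#' @return The mutated string.
#' @export
mutate_sequence <- function(seq, n_subs, seed) {
  len <- nchar(seq)
  if (n_subs > len) stop("n_subs exceeds sequence length")
  if (n_subs == 0) return(seq)
  with_seed(seed, {
    chars <- strsplit(seq, "")[[1]]
    pos <- sample.int(len, n_subs)
    for (p in pos)
      chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
    paste(chars, collapse = "")
  })
}

#' Configuration for a synthetic decomposition experiment
#'
#' Defaults mirror the field design the pipeline targets: tissue sampled at
#' 10 replicate sites over the seven day labels, a handful of fresh-window
#' colonisers, a large decayed-window bloom, plus spanning and sporadic
#' taxa that are biomarkers of neither window.
#'
#' @param n_sites Replicate sites (default 10).
#' @param n_fresh_only,n_decayed_only,n_spanning,n_sporadic Taxon class
#'   counts (defaults 2 / 42 / 20 / 6).
#' @param mean_depth Mean per-sample read depth (default 3193).
#' @param depth_sdlog Lognormal sdlog of depth variation (default
#'   `log(16)/4`, i.e. roughly a 16-fold spread over +/- 2 sd).
#' @param detection_prob Probability a taxon is detected in a given sample
#'   of its occupancy window (default 0.9).
#' @param nb_size Negative-binomial size (inverse overdispersion) for
#'   nonzero counts (default 2).
#' @param fragment_length Amplicon length in nt (default 425).
#' @param seed Integer seed (mandatory).
#' @return A list of class `decomposition_config`.
#' @export
decomposition_config <- function(n_sites = 10, n_fresh_only = 2,
                                 n_decayed_only = 42, n_spanning = 20,
                                 n_sporadic = 6, mean_depth = 3193,
                                 depth_sdlog = log(16) / 4,
                                 detection_prob = 0.9, nb_size = 2,
                                 fragment_length = 425, seed) {
  stopifnot(n_sites >= 1, n_fresh_only >= 0, n_decayed_only >= 0,
            n_spanning >= 0, n_sporadic >= 0,
            detection_prob > 0, detection_prob <= 1)
  if (missing(seed)) stop("seed is mandatory")
  structure(as.list(environment()), class = "decomposition_config")
}

# random non-empty subset of a window
sample_window <- function(days) {
  k <- sample.int(length(days), 1)
  sort_days(sample(days, k))
}
sort_days <- function(d) d[order(match(d, DAY_LABELS))]

#' Simulate a tissue-decomposition experiment
#'
#' Builds one sample per (site, day) -- including per-site lab controls at
#' day 0 -- with taxa occupying day windows by class: fresh-only taxa occur
#' only in the fresh window, decayed-only taxa only in the decayed window,
#' spanning taxa in both, sporadic taxa anywhere.  Nonzero counts are
#' 1 + negative binomial with a day-dependent mean (later days bloom);
#' detection within a taxon's window is Bernoulli.
#'
#' @param config A [decomposition_config()].
#' @return List with `table` ([asv_table()]), `sequences` (named character
#'   vector), and `truth` (data frame `asv_id`, `class`, `window`
#'   (slash-joined day labels)).
#' @export
generate_decomposition_experiment <- function(config) {
  stopifnot(inherits(config, "decomposition_config"))
  with_seed(config$seed, {
    classes <- rep(c("fresh_only", "decayed_only", "spanning", "sporadic"),
                   c(config$n_fresh_only, config$n_decayed_only,
                     config$n_spanning, config$n_sporadic))
    n_taxa <- length(classes)
    if (!n_taxa) stop("config generates zero taxa")
    ids <- sprintf("ASV%03d", seq_len(n_taxa))
    windows <- lapply(classes, function(cl) {
      switch(cl,
        fresh_only = sample_window(FRESH_WINDOW),
        decayed_only = sample_window(DECAYED_WINDOW),
        spanning = sort_days(c(sample(FRESH_WINDOW, 1), sample(DECAYED_WINDOW, 1),
                               sample(DAY_LABELS, sample.int(3, 1) - 1))),
        sporadic = sample_window(DAY_LABELS))
    })
    names(windows) <- ids

    samples <- expand.grid(site = sprintf("K%02d", seq_len(config$n_sites)),
                           day = DAY_LABELS, stringsAsFactors = FALSE)
    sample_id <- sprintf("T_%s_%s", samples$site, samples$day)
    day_factor <- c(D0_LAB = 0.3, D0_FIELD = 0.3, D1 = 0.6,
                    D2 = 1, D4 = 2, D7 = 3, D11 = 3)
    # relative mean abundance per taxon
    base_mu <- stats::rgamma(n_taxa, shape = 1.2, rate = 1) + 0.2
    depth_scale <- stats::rlnorm(nrow(samples),
                                 log(config$mean_depth) - config$depth_sdlog^2 / 2,
                                 config$depth_sdlog)
    counts <- matrix(0L, nrow(samples), n_taxa,
                     dimnames = list(sample_id, ids))
    for (j in seq_len(n_taxa)) {
      in_win <- samples$day %in% windows[[j]]
      det <- in_win & stats::runif(nrow(samples)) <= config$detection_prob
      if (any(det)) {
        mu <- base_mu[j] * day_factor[samples$day[det]] *
          depth_scale[det] / config$mean_depth * 20
        counts[det, j] <- 1L + stats::rnbinom(sum(det), mu = mu,
                                              size = config$nb_size)
      }
    }
    seqs <- vapply(seq_len(n_taxa), function(j)
      generate_16s_fragment(config$fragment_length,
                            seed = config$seed * 1000L + j), "")
    names(seqs) <- ids
    meta <- data.frame(sample_id = sample_id, sample_type = "chicken_tissue",
                       site = samples$site, day = samples$day,
                       is_control = FALSE, stringsAsFactors = FALSE)
    truth <- data.frame(asv_id = ids, class = classes,
                        window = vapply(windows, paste, "", collapse = "/"),
                        stringsAsFactors = FALSE)
    list(table = asv_table(counts, meta), sequences = seqs, truth = truth)
  })
}

#' Configuration for a synthetic consumer cohort
#'
#' Defaults reproduce the cohort structure the pipeline targets: 51 rats
#' (28 fecal, 23 stomach) across 18 forest fragments, roughly half of them
#' bird consumers, a 20/51 evidence-ambiguity rate, 15 planted
#' carrion-derived gut ASVs drawn from up to 7 decayed biomarkers at most
#' 3% diverged, and confounder lookalikes planted in non-consumers so the
#' informative filter has real work to do.  Resident-community size and
#' concentration are desk-scale choices documented in the methods
#' vignette.
#'
#' @param n_rats Cohort size (default 51).
#' @param n_feces,n_stomach Sample-type split (defaults 28 / 23).
#' @param n_kipuka Number of forest-fragment sites (default 18).
#' @param frac_consumed Fraction of rats that truly consumed bird
#'   (default 0.5).
#' @param frac_scavenger Fraction of consumers that scavenged (default
#'   0.45).
#' @param frac_ambiguous Fraction of rats whose diet evidence is made
#'   ambiguous (default `20/51`).
#' @param n_carrion_variants Size of the shared pool of planted
#'   carrion-derived gut ASVs (default 15).
#' @param n_biomarkers_used Distinct source biomarkers behind the pool
#'   (default 7).
#' @param max_divergence Maximum planted divergence as a fraction of
#'   length (default 0.03; must stay below `1 - threshold/100` of the
#'   matcher for plants to match).
#' @param n_confounders Lookalike variants planted in non-consumers
#'   (default 3).
#' @param n_resident Resident-pool richness (default 120).
#' @param concentration Dirichlet concentration of per-rat resident
#'   compositions (default 50).
#' @param mean_depth,depth_sdlog Per-rat depth model (defaults 24121,
#'   `log(16)/4`).
#' @param fragment_length Amplicon length (default 425).
#' @param seed Integer seed (mandatory).
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_rats = 51, n_feces = 28, n_stomach = 23,
                          n_kipuka = 18, frac_consumed = 0.5,
                          frac_scavenger = 0.45, frac_ambiguous = 20 / 51,
                          n_carrion_variants = 15, n_biomarkers_used = 7,
                          max_divergence = 0.03, n_confounders = 3,
                          n_resident = 120, concentration = 50,
                          mean_depth = 24121, depth_sdlog = log(16) / 4,
                          fragment_length = 425, seed) {
  stopifnot(n_rats >= 2, n_feces + n_stomach == n_rats,
            frac_consumed >= 0, frac_consumed <= 1,
            frac_scavenger >= 0, frac_scavenger <= 1,
            frac_ambiguous >= 0, frac_ambiguous <= 1,
            n_carrion_variants >= 1, n_resident >= 1)
  if (max_divergence > 1 - 97 / 100 + 1e-12)
    stop("max_divergence exceeds the 3% margin of the 97% matching threshold; ",
         "planted variants would not be guaranteed to match")
  if (missing(seed)) stop("seed is mandatory")
  structure(as.list(environment()), class = "cohort_config")
}

#' Simulate a consumer cohort with planted carrion biomarkers
#'
#' Each rat receives a resident gut community drawn Dirichlet-multinomial
#' from a shared pool.  Truth-scavengers additionally carry at least one
#' planted carrion ASV -- a `<= max_divergence` substitution mutant of a
#' decayed-tissue biomarker, drawn from a pool shared across scavengers so
#' plants survive singleton filtering.  Confounder lookalikes (also within
#' the matching threshold) are planted in at least one confirmed
#' non-consumer, so the informative filter must remove them.  Per-rat diet
#' evidence is generated consistent with truth, with the configured
#' fraction of rats given ambiguous evidence (band present, low quality).
#'
#' @param config A [cohort_config()].
#' @param biomarkers Named character vector of decayed-tissue biomarker
#'   sequences.
#' @return List with `table` ([asv_table()]), `sequences`, `evidence`
#'   (assay data frame for [call_diet_all()]), and `truth` (list with
#'   per-rat data frame `rats`, per-ASV data frame `asvs`, and
#'   `planted_map` mapping planted ASV id to source biomarker id).
#' @export
generate_rat_cohort <- function(config, biomarkers) {
  stopifnot(inherits(config, "cohort_config"))
  if (!length(biomarkers)) stop("biomarker sequence set must be non-empty")
  with_seed(config$seed, {
    n <- config$n_rats
    rat_ids <- c(sprintf("F%03d", seq_len(config$n_feces)),
                 sprintf("S%03d", seq_len(config$n_stomach)))
    type <- rep(c("rat_feces", "rat_stomach"),
                c(config$n_feces, config$n_stomach))
    kipuka <- sample(sprintf("K%02d", seq_len(config$n_kipuka)), n, replace = TRUE)

    n_consumed <- round(config$frac_consumed * n)
    consumed <- rep(FALSE, n)
    consumed[sample.int(n, n_consumed)] <- TRUE
    n_scav <- round(config$frac_scavenger * n_consumed)
    scavenged <- rep(FALSE, n)
    if (n_scav > 0)
      scavenged[sample(which(consumed), n_scav)] <- TRUE
    ambiguous <- rep(FALSE, n)
    n_amb <- round(config$frac_ambiguous * n)
    if (n_amb > 0) ambiguous[sample.int(n, n_amb)] <- TRUE

    len <- config$fragment_length
    max_subs <- floor(config$max_divergence * len)

    # planted carrion pool: variants of up to n_biomarkers_used biomarkers
    src_pool <- names(biomarkers)[
      rep_len(seq_len(min(config$n_biomarkers_used, length(biomarkers))),
              config$n_carrion_variants)]
    carrion_ids <- sprintf("carrion%02d", seq_len(config$n_carrion_variants))
    carrion_seqs <- vapply(seq_along(carrion_ids), function(i)
      mutate_sequence(biomarkers[[src_pool[i]]],
                      sample.int(max_subs + 1, 1) - 1,
                      seed = config$seed * 1000L + i), "")
    names(carrion_seqs) <- carrion_ids
    planted_map <- stats::setNames(src_pool, carrion_ids)

    conf_ids <- character(0); conf_seqs <- character(0)
    if (config$n_confounders > 0) {
      conf_src <- rep_len(names(biomarkers), config$n_confounders)
      conf_ids <- sprintf("confound%02d", seq_len(config$n_confounders))
      conf_seqs <- vapply(seq_along(conf_ids), function(i)
        mutate_sequence(biomarkers[[conf_src[i]]],
                        sample.int(max_subs + 1, 1) - 1,
                        seed = config$seed * 2000L + i), "")
      names(conf_seqs) <- conf_ids
    }

    res_ids <- sprintf("resident%03d", seq_len(config$n_resident))
    res_seqs <- vapply(seq_along(res_ids), function(i)
      generate_16s_fragment(len, seed = config$seed * 3000L + i), "")
    names(res_seqs) <- res_ids

    all_ids <- c(res_ids, carrion_ids, conf_ids)
    counts <- matrix(0L, n, length(all_ids),
                     dimnames = list(rat_ids, all_ids))

    # resident communities: Dirichlet-multinomial around a shared pool
    pool_props <- stats::rgamma(config$n_resident, shape = 0.8, rate = 1)
    pool_props <- pool_props / sum(pool_props)
    depths_r <- stats::rlnorm(n, log(config$mean_depth) - config$depth_sdlog^2 / 2,
                              config$depth_sdlog)
    for (i in seq_len(n)) {
      alpha <- config$concentration * pool_props
      p <- stats::rgamma(config$n_resident, shape = alpha, rate = 1)
      p <- p / sum(p)
      counts[i, res_ids] <- as.integer(
        stats::rmultinom(1, size = round(depths_r[i]), prob = p))
    }

    # plant carrion variants: round-robin over a shared subset so every
    # variant a scavenger depends on occurs in >= 2 rats when possible
    scav_idx <- which(scavenged)
    if (length(scav_idx)) {
      n_shared <- max(1, min(config$n_carrion_variants,
                             floor(length(scav_idx) / 2)))
      for (k in seq_along(scav_idx)) {
        i <- scav_idx[k]
        picks <- carrion_ids[1 + (k - 1) %% n_shared]
        extra <- sample(carrion_ids, sample.int(2, 1) - 1)
        for (a in unique(c(picks, extra)))
          counts[i, a] <- counts[i, a] + 1L + stats::rpois(1, 30)
      }
    }
    # confounders: each planted in one confirmed non-consumer and one consumer
    clear_not <- which(!consumed & !ambiguous)
    clear_yes <- which(consumed & !ambiguous)
    for (k in seq_along(conf_ids)) {
      targets <- c(if (length(clear_not)) sample(clear_not, 1),
                   if (length(clear_yes)) sample(clear_yes, 1))
      for (i in targets)
        counts[i, conf_ids[k]] <- counts[i, conf_ids[k]] + 1L + stats::rpois(1, 20)
    }

    evidence <- make_diet_evidence(rat_ids, type, consumed, ambiguous)

    meta <- data.frame(sample_id = rat_ids, sample_type = type,
                       site = kipuka, day = NA_character_,
                       is_control = FALSE, stringsAsFactors = FALSE)
    seqs <- c(res_seqs, carrion_seqs, conf_seqs)
    truth_rats <- data.frame(sample_id = rat_ids, sample_type = type,
                             consumed = consumed, scavenged = scavenged,
                             evidence_ambiguous = ambiguous,
                             stringsAsFactors = FALSE)
    truth_asvs <- data.frame(
      asv_id = all_ids,
      class = rep(c("resident", "planted_carrion", "confounder"),
                  c(length(res_ids), length(carrion_ids), length(conf_ids))),
      stringsAsFactors = FALSE)
    list(table = asv_table(counts, meta), sequences = seqs,
         evidence = evidence,
         truth = list(rats = truth_rats, asvs = truth_asvs,
                      planted_map = planted_map))
  })
}

DETECTED_BIRDS <- c("Zosterops japonicus", "Myadestes obscurus",
                    "Meleagris gallopavo", "Lophura leucomelanos")

# Evidence rows consistent with truth labels.  Consumers get one
# high-quality positive assay (off-roster Lophura hits exercise the genus
# fallback); non-consumers get four band-negative tests; ambiguous rats get
# a band with an unusable trace.
make_diet_evidence <- function(rat_ids, type, consumed, ambiguous) {
  rows <- list()
  for (i in seq_along(rat_ids)) {
    base <- expand.grid(primer_pair = PRIMER_PAIRS, replicate = 1:2,
                        stringsAsFactors = FALSE)
    base$sample_id <- rat_ids[i]
    base$sample_type <- type[i]
    base$band_in_size_range <- FALSE
    base$quality_pct <- NA_real_
    base$mixed_trace <- FALSE
    base$top_taxa <- ""
    if (ambiguous[i]) {
      base$band_in_size_range[1] <- TRUE
      base$quality_pct[1] <- 30
    } else if (consumed[i]) {
      sp <- sample(DETECTED_BIRDS, 1,
                   prob = c(0.5, 0.25, 0.1, 0.15))
      hit <- if (sp == "Lophura leucomelanos") "Lophura_nycthemera"
             else gsub(" ", "_", sp)
      base$band_in_size_range[1] <- TRUE
      base$quality_pct[1] <- 90
      base$top_taxa[1] <- sprintf("%s:1e-80:98", hit)
    }
    rows[[i]] <- base
  }
  out <- do.call(rbind, rows)
  out[, c("sample_id", "sample_type", "primer_pair", "replicate",
          "band_in_size_range", "quality_pct", "mixed_trace", "top_taxa")]
}

#' Generate a random rooted tree over ASV identifiers
#'
#' Random binary rooted topology with exponential branch lengths, used as
#' the phylogeny input for Faith's PD and UniFrac on synthetic data.
#'
#' @param asv_ids Character vector of at least two tip identifiers.
#' @param seed Integer seed.
#' @param rate Rate of the exponential branch-length distribution.
#' @return A rooted `ape::phylo`.
#' @export
generate_tree <- function(asv_ids, seed, rate = 10) {
  if (length(asv_ids) < 2) stop("need at least two identifiers")
  with_seed(seed, {
    tr <- ape::rtree(length(asv_ids), rooted = TRUE,
                     br = function(n) stats::rexp(n, rate = rate))
    tr$tip.label <- sample(asv_ids)
    tr
  })
}
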