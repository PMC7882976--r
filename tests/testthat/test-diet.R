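hit_df <- function(taxa, e = 1e-80, cov = 98) {
  data.frame(taxon = taxa, e_value = rep_len(e, length(taxa)),
             query_coverage_pct = rep_len(cov, length(taxa)),
             stringsAsFactors = FALSE)
}

test_that("species assignment accepts only unanimous confident roster hits", {
  r <- species_roster()
  ok <- assign_species(hit_df(rep("Zosterops japonicus", 3)), r)
  expect_equal(ok$species, "Zosterops japonicus")
  expect_equal(ok$reason, "confirmed")

  # off-roster congener resolves through the genus fallback
  fb <- assign_species(hit_df("Lophura nycthemera"), r)
  expect_equal(fb$species, "Lophura leucomelanos")

  # a confident non-bird top hit is rejected with a reason
  worm <- assign_species(hit_df("Lumbricus terrestris"), r)
  expect_true(is.na(worm$species))
  expect_equal(worm$reason, "non_bird_taxon")

  # disagreement among confident hits
  mx <- assign_species(hit_df(c("Zosterops japonicus", "Myadestes obscurus")), r)
  expect_equal(mx$reason, "mixed")

  # e-value and coverage gates are strict
  weak_e <- assign_species(hit_df("Zosterops japonicus", e = 1e-40), r)
  expect_equal(weak_e$reason, "no_confident_hit")
  weak_cov <- assign_species(hit_df("Zosterops japonicus", cov = 95), r)
  expect_equal(weak_cov$reason, "low_quality")
  expect_equal(assign_species(hit_df(character(0)), r)$reason,
               "no_confident_hit")
})

test_that("roster validation rejects inconsistent fallbacks", {
  expect_error(species_roster(species = "A b",
                              genus_fallback = c(X = "X y")),
               "roster species")
  expect_error(species_roster(species = c("A b", "A c"),
                              genus_fallback = c("A b")), "named")
})

test_that("diet calls follow the consumed / not-consumed / ambiguous rule", {
  # one high-quality sequenced band with a roster species -> consumed
  ev <- evidence_rows("r1", band = c(TRUE, FALSE, FALSE, FALSE),
                      quality = c(90, NA, NA, NA),
                      taxa = c("Zosterops_japonicus:1e-80:98", "", "", ""))
  cl <- call_diet("r1", ev)
  expect_equal(cl$status, "consumed")
  expect_equal(cl$species, "Zosterops japonicus")

  # four band-negative tests -> not consumed
  neg <- call_diet("r2", evidence_rows("r2"))
  expect_equal(neg$status, "not_consumed")
  expect_equal(neg$reason, "no_amplification")
  expect_true(is.na(neg$species))

  # band present but unusable trace -> ambiguous / low_quality
  amb <- call_diet("r3", evidence_rows("r3",
                                       band = c(TRUE, FALSE, FALSE, FALSE),
                                       quality = c(30, NA, NA, NA)))
  expect_equal(amb$status, "ambiguous")
  expect_equal(amb$reason, "low_quality")

  # high quality but non-bird taxon -> ambiguous
  worm <- call_diet("r4", evidence_rows("r4",
                                        band = c(TRUE, FALSE, FALSE, FALSE),
                                        quality = c(85, NA, NA, NA),
                                        taxa = c("Lumbricus_terrestris:1e-80:99",
                                                 "", "", "")))
  expect_equal(worm$status, "ambiguous")
  expect_equal(worm$reason, "non_bird_taxon")
})

test_that("diet-call preconditions are enforced", {
  half <- evidence_rows("r5")[1:2, ]  # only the COI pair
  expect_error(call_diet("r5", half), "Cytb")
  # claiming not-consumed needs two band-negative replicates per pair
  short <- evidence_rows("r6")[c(1, 3), ]
  short$replicate <- 1
  expect_error(call_diet("r6", short), "four tests")
})

test_that("conflicting confident species across loci yield ambiguous/mixed", {
  ev <- evidence_rows("r7",
                      band = c(TRUE, FALSE, TRUE, FALSE),
                      quality = c(90, NA, 90, NA),
                      taxa = c("Zosterops_japonicus:1e-80:98", "",
                               "Myadestes_obscurus:1e-80:98", ""))
  cl <- call_diet("r7", ev)
  expect_equal(cl$status, "ambiguous")
  expect_equal(cl$reason, "mixed")
})

test_that("adding a passing assay can only move a call toward consumed", {
  base <- evidence_rows("r8", band = c(TRUE, FALSE, FALSE, FALSE),
                        quality = c(30, NA, NA, NA))
  expect_equal(call_diet("r8", base)$status, "ambiguous")
  more <- base
  more$band_in_size_range[3] <- TRUE
  more$quality_pct[3] <- 95
  more$top_taxa[3] <- "Myadestes_obscurus:1e-90:99"
  expect_equal(call_diet("r8", more)$status, "consumed")
})

test_that("contingency summaries count by type and status with margins", {
  expect_true(all(summarize_diet(data.frame(sample_type = character(),
                                            status = character())) == 0))
  calls <- data.frame(
    sample_type = c("feces", "feces", "stomach", "stomach", "stomach"),
    status = c("consumed", "ambiguous", "consumed", "consumed",
               "not_consumed"),
    stringsAsFactors = FALSE)
  tab <- summarize_diet(calls)
  expect_equal(tab["feces", "consumed"], 1)
  expect_equal(tab["stomach", "consumed"], 2)
  expect_equal(tab["total", "total"], 5)
  expect_equal(tab["total", "ambiguous"], 1)
})
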