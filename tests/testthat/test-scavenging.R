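calls_df <- function(ids, status, type = "rat_feces") {
  data.frame(sample_id = ids, sample_type = rep_len(type, length(ids)),
             status = status,
             species = rep_len(NA_character_, length(ids)),
             reason = rep_len("x", length(ids)),
             stringsAsFactors = FALSE)
}

matches_df <- function(asvs, bms = "BM1") {
  data.frame(query_asv_id = asvs, biomarker_id = rep_len(bms, length(asvs)),
             identity_pct = 99, stringsAsFactors = FALSE)
}

test_that("the informative filter removes resident-microbiome candidates", {
  # a01 present in a consumer and in a non-consumer -> excluded;
  # a02 present only in consumers -> retained;
  # a03 present only in a non-consumer -> excluded
  counts <- cbind(a01 = c(3, 2, 0), a02 = c(5, 0, 0), a03 = c(0, 4, 0))
  x <- make_table(counts, sample_ids = c("yes1", "no1", "amb1"),
                  asv_ids = colnames(counts))
  calls <- calls_df(c("yes1", "no1", "amb1"),
                    c("consumed", "not_consumed", "ambiguous"))
  inf <- find_informative(matches_df(c("a01", "a02", "a03")), x, calls)
  expect_equal(inf$map$query_asv_id, "a02")
  expect_equal(inf$n_matched_before, 3)
  expect_equal(inf$n_informative_after, 1)
  expect_lte(inf$n_informative_after, inf$n_matched_before)

  expect_error(find_informative(matches_df("a01"), x,
                                calls_df("amb1", "ambiguous")),
               "unambiguous")
})

test_that("an ASV seen only in ambiguous rats is not informative", {
  counts <- cbind(a01 = c(0, 0, 6))
  x <- make_table(counts, sample_ids = c("yes1", "no1", "amb1"),
                  asv_ids = "a01")
  calls <- calls_df(c("yes1", "no1", "amb1"),
                    c("consumed", "not_consumed", "ambiguous"))
  inf <- find_informative(matches_df("a01"), x, calls)
  expect_equal(nrow(inf$map), 0)
})

test_that("scavenging calls partition consumers by informative presence", {
  counts <- cbind(a02 = c(5, 0, 0, 2))
  x <- make_table(counts, sample_ids = c("yes1", "yes2", "no1", "amb1"),
                  asv_ids = "a02")
  calls <- calls_df(c("yes1", "yes2", "no1", "amb1"),
                    c("consumed", "consumed", "not_consumed", "ambiguous"))
  inf <- find_informative(matches_df("a02"), x, calls)
  sc <- call_scavenging(calls, inf, x)
  expect_equal(sc$carrion_flag[sc$sample_id == "yes1"], "carrion_likely")
  expect_equal(sc$carrion_flag[sc$sample_id == "yes2"], "predation_or_unknown")
  expect_equal(sc$carrion_flag[sc$sample_id == "no1"], "unresolved")
  expect_equal(sc$supporting_asvs[sc$sample_id == "yes1"], "a02")
})

test_that("the ambiguous rule needs min_asvs informative ASVs and is monotone", {
  counts <- cbind(a01 = c(2, 0, 3, 1), a02 = c(4, 0, 2, 0))
  x <- make_table(counts, sample_ids = c("yes1", "no1", "amb2", "amb1"),
                  asv_ids = colnames(counts))
  calls <- calls_df(c("yes1", "no1", "amb2", "amb1"),
                    c("consumed", "not_consumed", "ambiguous", "ambiguous"))
  inf <- find_informative(matches_df(c("a01", "a02"), c("BM1", "BM2")), x, calls)
  expect_equal(nrow(inf$map), 2)

  r2 <- resolve_ambiguous(calls, inf, x, min_asvs = 2)
  expect_equal(r2$carrion_flag[r2$sample_id == "amb2"], "suggested_carrion")
  expect_equal(r2$carrion_flag[r2$sample_id == "amb1"], "unresolved")
  expect_true(all(r2$exploratory))
  expect_setequal(r2$sample_id, c("amb2", "amb1"))

  r3 <- resolve_ambiguous(calls, inf, x, min_asvs = 3)
  expect_lte(sum(r3$carrion_flag == "suggested_carrion"),
             sum(r2$carrion_flag == "suggested_carrion"))
  expect_error(resolve_ambiguous(calls, inf, x, min_asvs = 0), ">= 1")
})

test_that("cohort summaries count species and carrion rats", {
  calls <- calls_df(c("y1", "y2", "n1", "a1"),
                    c("consumed", "consumed", "not_consumed", "ambiguous"),
                    type = c("rat_feces", "rat_stomach", "rat_feces",
                             "rat_feces"))
  calls$species <- c("Zosterops japonicus", "Myadestes obscurus", NA, NA)
  scav <- data.frame(sample_id = c("y1", "y2", "n1", "a1"),
                     sample_type = calls$sample_type,
                     diet_status = calls$status,
                     carrion_flag = c("carrion_likely", "predation_or_unknown",
                                      "unresolved", "unresolved"),
                     stringsAsFactors = FALSE)
  rep <- summarize_cohort(calls, scav)
  expect_equal(rep$n_consumed, 2)
  expect_equal(rep$n_carrion, 1)
  expect_equal(rep$n_species_consumed, 2)
  expect_equal(rep$species_carrion, "Zosterops japonicus")
  expect_equal(rep$pct_consumed, 50)

  empty <- summarize_cohort(calls_df(character(), character()),
                            scav[0, ])
  expect_equal(empty$n_samples, 0)
  expect_equal(empty$n_carrion, 0)
})

test_that("the end-to-end pipeline is deterministic and recovers truth", {
  cfgs <- small_pipeline_configs(seed = 7)
  r1 <- run_pipeline(cfgs$decomposition, cfgs$cohort)
  r2 <- run_pipeline(cfgs$decomposition, cfgs$cohort)
  expect_identical(r1$matches, r2$matches)
  expect_identical(r1$scavenging, r2$scavenging)
  expect_identical(unclass(r1$report), unclass(r2$report))

  truth <- r1$cohort$truth$rats
  called <- r1$scavenging$sample_id[r1$scavenging$carrion_flag ==
                                      "carrion_likely"]
  expect_setequal(called, truth$sample_id[truth$scavenged])
  # no not-consumed rat ever receives a carrion call
  not_ids <- truth$sample_id[!truth$consumed]
  expect_false(any(called %in% not_ids))
  # exclusion soundness, re-asserted on outputs
  inf_asvs <- r1$informative$map$query_asv_id
  not_rows <- r1$rat_table$counts[intersect(not_ids,
                                            rownames(r1$rat_table$counts)),
                                  inf_asvs, drop = FALSE]
  expect_true(all(not_rows == 0))
})
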