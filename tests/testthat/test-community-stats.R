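test_that("richness counts ASVs present per sample", {
  x <- make_table(matrix(c(0, 3, 1,
                           2, 0, 0), 2, 3, byrow = TRUE))
  expect_equal(unname(richness(x)), c(2, 1))
})

test_that("Faith's PD sums the minimal root-spanning subtree", {
  # rooted cherry-plus-outgroup: ((a:1,b:1):0.5,c:2);
  tr <- ape::read.tree(text = "((a:1,b:1):0.5,c:2);")
  x <- make_table(matrix(c(1, 0, 0,
                           1, 1, 0,
                           1, 1, 1,
                           0, 0, 1), 4, 3, byrow = TRUE),
                  asv_ids = c("a", "b", "c"))
  pd <- unname(faith_pd(x, tr))
  expect_equal(pd, c(1.5, 2.5, 4.5, 2))

  miss <- make_table(matrix(1L, 1, 1), asv_ids = "zz")
  expect_error(faith_pd(miss, tr), "zz")
})

test_that("Faith's PD agrees with picante on random tables", {
  skip_if_not_installed("picante")
  set.seed(12)
  tr <- generate_tree(sprintf("t%02d", 1:12), seed = 4)
  x <- random_table(8, 12, seed = 5, asv_ids = tr$tip.label)
  x$counts[, 1] <- x$counts[, 1] + 1L
  ours <- faith_pd(x, tr)
  ref <- picante::pd(x$counts, tr, include.root = TRUE)$PD
  expect_equal(unname(ours), ref, tolerance = 1e-10)
})

test_that("Jaccard and Bray-Curtis agree with vegan", {
  skip_if_not_installed("vegan")
  x <- random_table(7, 20, seed = 6)
  x$counts[, 1] <- x$counts[, 1] + 1L
  dj <- beta_distance(x, "jaccard")
  ref_j <- as.matrix(vegan::vegdist(x$counts, "jaccard", binary = TRUE))
  expect_equal(unclass(dj), ref_j, tolerance = 1e-12,
               ignore_attr = TRUE)
  db <- beta_distance(x, "bray_curtis")
  ref_b <- as.matrix(vegan::vegdist(total_sum_scale(x), "bray"))
  expect_equal(unclass(db), ref_b, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("distances satisfy metric-style invariants", {
  tr <- generate_tree(sprintf("t%02d", 1:10), seed = 8)
  x <- random_table(6, 10, seed = 9, asv_ids = tr$tip.label)
  x$counts[, 1] <- x$counts[, 1] + 1L
  for (metric in c("jaccard", "bray_curtis", "unweighted_unifrac")) {
    d <- beta_distance(x, metric, tree = tr)
    expect_equal(d, t(d))
    expect_true(all(diag(d) == 0))
    expect_true(all(d >= 0 & d <= 1))
  }
  # identical samples are at distance zero under every metric
  y <- make_table(rbind(c(1, 2, 0), c(1, 2, 0)),
                  asv_ids = c("t01", "t02", "t03"))
  for (metric in c("jaccard", "bray_curtis"))
    expect_equal(beta_distance(y, metric)[1, 2], 0)
})

test_that("unweighted UniFrac matches hand accounting and picante", {
  # star tree, disjoint communities -> all observed branch unshared
  star <- ape::read.tree(text = "((a:1,b:1):0,(c:1,d:1):0);")
  x <- make_table(rbind(c(1, 1, 0, 0), c(0, 0, 1, 1)),
                  asv_ids = c("a", "b", "c", "d"))
  expect_equal(beta_distance(x, "unweighted_unifrac", tree = star)[1, 2], 1)

  # hand-worked cherry tree: ((a:1,b:2):0.5,(c:1,d:1):3);
  # sample1 = {a,c}, sample2 = {a,d}
  # shared: a's branch (1), both cherry stems (0.5 + 3); unique: c (1), d (1)
  tr <- ape::read.tree(text = "((a:1,b:2):0.5,(c:1,d:1):3);")
  x2 <- make_table(rbind(c(1, 0, 1, 0), c(1, 0, 0, 1)),
                   asv_ids = c("a", "b", "c", "d"))
  got <- beta_distance(x2, "unweighted_unifrac", tree = tr)[1, 2]
  expect_equal(got, 2 / 6.5)

  skip_if_not_installed("picante")
  rt <- generate_tree(sprintf("t%02d", 1:9), seed = 13)
  x3 <- random_table(6, 9, seed = 14, asv_ids = rt$tip.label)
  x3$counts[, 1] <- x3$counts[, 1] + 1L
  ours <- beta_distance(x3, "unweighted_unifrac", tree = rt)
  ref <- as.matrix(picante::unifrac(x3$counts, rt))
  ref <- ref[rownames(ours), colnames(ours)]
  expect_equal(unclass(ours), ref, tolerance = 1e-10, ignore_attr = TRUE)

  expect_error(beta_distance(x3, "unweighted_unifrac"), "tree")
})

test_that("PERMANOVA F and R2 agree with vegan::adonis2", {
  skip_if_not_installed("vegan")
  x <- random_table(12, 25, seed = 15)
  x$counts[, 1] <- x$counts[, 1] + 1L
  g <- rep(c("A", "B"), each = 6)
  d <- beta_distance(x, "jaccard")
  ours <- permanova(d, g, n_perm = 99, seed = 2, max_exact = 10)
  ref <- vegan::adonis2(stats::as.dist(d) ~ g, permutations = 99)
  expect_equal(ours$pseudo_F, ref$F[1], tolerance = 1e-10)
  expect_equal(ours$R2, ref$R2[1], tolerance = 1e-10)
})

test_that("PERMANOVA p matches exhaustive enumeration at small n", {
  x <- random_table(7, 15, seed = 16)
  x$counts[, 1] <- x$counts[, 1] + 1L
  g <- c("A", "A", "A", "B", "B", "B", "B")
  d <- beta_distance(x, "bray_curtis")
  res <- permanova(d, g)   # choose(7,3)=35 -> exact path
  expect_true(res$exact)
  # independent brute force in test code
  D2 <- d^2
  f_of <- function(gg) {
    sst <- sum(D2[lower.tri(D2)]) / 7
    ssw <- 0
    for (lev in unique(gg)) {
      i <- which(gg == lev)
      ssw <- ssw + sum(D2[i, i][lower.tri(D2[i, i])]) / length(i)
    }
    ((sst - ssw) / 1) / (ssw / 5)
  }
  sets <- combn(7, 3)
  fs <- apply(sets, 2, function(i) {
    gg <- rep("B", 7); gg[i] <- "A"; f_of(gg)
  })
  expect_equal(res$p_value, mean(fs >= f_of(g) - 1e-12))
  expect_equal(res$pseudo_F, f_of(g))
})

test_that("perfectly separated identical groups get the minimal exact p", {
  # two internally identical, mutually distant groups of three
  d <- matrix(1, 6, 6); d[1:3, 1:3] <- 0; d[4:6, 4:6] <- 0; diag(d) <- 0
  rownames(d) <- colnames(d) <- paste0("s", 1:6)
  res <- permanova(d, rep(c("A", "B"), each = 3))
  expect_true(res$exact)
  # only the two label arrangements reproducing the true partition reach F
  expect_equal(res$p_value, 2 / choose(6, 3))
})

test_that("PERMDISP matches vegan::betadisper and detects dispersion", {
  skip_if_not_installed("vegan")
  x <- random_table(14, 30, seed = 17)
  x$counts[, 1] <- x$counts[, 1] + 1L
  g <- rep(c("A", "B"), each = 7)
  d <- beta_distance(x, "jaccard")
  ours <- permdisp(d, g, n_perm = 199, seed = 3)
  bd <- vegan::betadisper(stats::as.dist(d), g, type = "centroid")
  expect_equal(unname(ours$distances), unname(bd$distances),
               tolerance = 1e-8)
  expect_equal(ours$F, anova(bd)$`F value`[1], tolerance = 1e-8)

  # one tight and one diffuse group -> small p
  set.seed(18)
  tight <- matrix(rnorm(10 * 4, sd = 0.05), 10)
  diffuse <- matrix(rnorm(10 * 4, sd = 2), 10)
  dd <- as.matrix(stats::dist(rbind(tight, diffuse)))
  rownames(dd) <- colnames(dd) <- paste0("s", 1:20)
  res <- permdisp(dd, rep(c("T", "D"), each = 10), n_perm = 499, seed = 4)
  expect_lt(res$p_value, 0.05)
})

test_that("permuting labels leaves the pooled centroid distances intact", {
  x <- random_table(10, 12, seed = 19)
  x$counts[, 1] <- x$counts[, 1] + 1L
  d <- beta_distance(x, "jaccard")
  g <- rep(c("A", "B"), each = 5)
  z1 <- sort(permdisp(d, g, n_perm = 9, seed = 1)$distances)
  # distances to own-group centroids are fixed inputs to the permutation,
  # so reruns with different permutation seeds agree
  z2 <- sort(permdisp(d, g, n_perm = 9, seed = 99)$distances)
  expect_equal(z1, z2)
})

test_that("indicator values match closed forms", {
  # present in all of group 1, absent from group 2 -> stat 1
  pres <- rbind(matrix(1L, 5, 1), matrix(0L, 5, 1))
  colnames(pres) <- "tax1"
  g <- rep(c("g1", "g2"), each = 5)
  r <- indval(pres, g, n_perm = 199, seed = 1, min_prevalence = 0)
  expect_equal(r$stat, 1)
  expect_equal(r$group, "g1")

  # present everywhere in both equal groups -> sqrt(0.5), p = 1
  all1 <- matrix(1L, 10, 1, dimnames = list(NULL, "tax1"))
  r2 <- indval(all1, g, n_perm = 199, seed = 1, min_prevalence = 0)
  expect_equal(r2$stat, sqrt(0.5), tolerance = 1e-12)
  expect_equal(r2$p_value, 1)

  # the 7/11 vs 2/20 configuration: stat 0.74 to two decimals
  pres3 <- matrix(0L, 31, 1, dimnames = list(NULL, "tax1"))
  pres3[1:7, 1] <- 1L
  pres3[11 + 1:2, 1] <- 1L
  g3 <- rep(c("no", "yes"), c(11, 20))
  r3 <- indval(pres3, g3, n_perm = 999, seed = 2, min_prevalence = 0)
  expect_equal(round(r3$stat, 2), 0.74)
  expect_equal(r3$group, "no")
  b1 <- 7 / 11
  expect_equal(r3$stat, sqrt(b1 / (b1 + 0.1) * b1), tolerance = 1e-12)
  expect_lt(r3$p_value, 0.05)
})

test_that("the prevalence prefilter and two-group restriction apply", {
  pres <- cbind(rare = c(1L, rep(0L, 9)), common = rep(1L, 10))
  g <- rep(c("g1", "g2"), each = 5)
  r <- indval(pres, g, n_perm = 99, seed = 1, min_prevalence = 0.15)
  expect_equal(r$taxon, "common")
  expect_error(indval(pres, rep(c("a", "b", "c"), c(4, 3, 3)), seed = 1),
               "two groups")
})

test_that("Benjamini-Hochberg adjustment matches hand values and p.adjust", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  set.seed(20)
  for (rep in 1:5) {
    p <- runif(sample(3:40, 1))
    q <- bh_fdr(p)
    expect_equal(q, p.adjust(p, "BH"))
    expect_true(all(q >= p - 1e-12))
  }
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
})
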