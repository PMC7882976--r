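# For every edge of a rooted tree, which tips descend from it.
# Returns a logical matrix edges x tips, rows in tree$edge order.
edge_tip_matrix <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  M <- matrix(FALSE, nnode, ntip)
  M[cbind(seq_len(ntip), seq_len(ntip))] <- TRUE
  po <- ape::reorder.phylo(tree, "postorder")$edge
  for (r in seq_len(nrow(po)))
    M[po[r, 1], ] <- M[po[r, 1], ] | M[po[r, 2], ]
  out <- M[tree$edge[, 2], , drop = FALSE]
  colnames(out) <- tree$tip.label
  out
}

check_tree_covers <- function(tree, asvs) {
  miss <- setdiff(asvs, tree$tip.label)
  if (length(miss))
    stop("tree is missing leaves for ASV(s): ", paste(miss, collapse = ", "))
  if (!ape::is.rooted(tree)) stop("a rooted tree is required")
  if (is.null(tree$edge.length)) stop("tree lacks branch lengths")
}

#' Per-sample ASV richness
#'
#' @param x An [asv_table()].
#' @return Named integer vector: number of ASVs with count >= 1 per sample.
#' @export
richness <- function(x) {
  stopifnot(inherits(x, "asv_table"))
  rowSums(x$counts > 0)
}

#' Faith's phylogenetic diversity
#'
#' Total branch length of the minimal subtree connecting each sample's
#' observed ASVs to the root: the sum of lengths of every edge with at
#' least one observed descendant tip.
#'
#' @param x An [asv_table()].
#' @param tree Rooted `ape::phylo` whose tips cover the table's ASVs.
#' @return Named numeric vector of PD values per sample.
#' @export
faith_pd <- function(x, tree) {
  stopifnot(inherits(x, "asv_table"))
  check_tree_covers(tree, asv_ids(x))
  etm <- edge_tip_matrix(tree)
  pres <- x$counts > 0
  vapply(rownames(pres), function(s) {
    obs <- colnames(pres)[pres[s, ]]
    if (!length(obs)) return(0)
    on_path <- rowSums(etm[, obs, drop = FALSE]) > 0
    sum(tree$edge.length[on_path])
  }, 0)
}

#' Pairwise community dissimilarity
#'
#' Three dissimilarities on a common interface:
#' * `jaccard` -- presence-absence, `1 - |A intersect B| / |A union B|`;
#' * `bray_curtis` -- on total-sum-scaled proportions,
#'   `sum |x_i - y_i| / sum (x_i + y_i)`;
#' * `unweighted_unifrac` -- presence-absence, branch length unique to one
#'   community divided by branch length observed in either, on a rooted
#'   tree.
#'
#' @param x An [asv_table()]; every sample must contain at least one read.
#' @param metric One of `"jaccard"`, `"bray_curtis"`,
#'   `"unweighted_unifrac"`.
#' @param tree Rooted `ape::phylo`; required for UniFrac.
#' @return A symmetric numeric matrix in `[0, 1]` with zero diagonal and
#'   attribute `"metric"`.
#' @export
beta_distance <- function(x, metric = c("jaccard", "bray_curtis",
                                        "unweighted_unifrac"),
                          tree = NULL) {
  stopifnot(inherits(x, "asv_table"))
  metric <- match.arg(metric)
  if (any(depths(x) == 0))
    stop("sample(s) with zero reads: ",
         paste(sample_ids(x)[depths(x) == 0], collapse = ", "),
         "; distances are undefined for empty communities")
  n <- nrow(x$counts)
  ids <- sample_ids(x)
  d <- matrix(0, n, n, dimnames = list(ids, ids))

  if (metric == "jaccard") {
    pres <- x$counts > 0
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      a <- pres[i, ]; b <- pres[j, ]
      d[i, j] <- d[j, i] <- 1 - sum(a & b) / sum(a | b)
    }
  } else if (metric == "bray_curtis") {
    p <- total_sum_scale(x)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- sum(abs(p[i, ] - p[j, ])) / sum(p[i, ] + p[j, ])
    }
  } else {
    if (is.null(tree)) stop("unweighted UniFrac requires a rooted tree")
    check_tree_covers(tree, asv_ids(x))
    etm <- edge_tip_matrix(tree)[, asv_ids(x), drop = FALSE]
    pres <- x$counts > 0
    # edges x samples: does the edge subtend any taxon observed in sample?
    on_path <- etm %*% t(pres + 0) > 0
    len <- tree$edge.length
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      ai <- on_path[, i]; aj <- on_path[, j]
      union_len <- sum(len[ai | aj])
      d[i, j] <- d[j, i] <- sum(len[xor(ai, aj)]) / union_len
    }
  }
  attr(d, "metric") <- metric
  d
}
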