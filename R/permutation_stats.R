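# One-way pseudo-F from squared distances and an integer group index.
pseudo_f <- function(D2, g) {
  n <- nrow(D2)
  a <- length(unique(g))
  sst <- sum(D2[lower.tri(D2)]) / n
  ssw <- 0
  for (lev in unique(g)) {
    idx <- which(g == lev)
    if (length(idx) > 1)
      ssw <- ssw + sum(D2[idx, idx][lower.tri(D2[idx, idx])]) / length(idx)
  }
  ssa <- sst - ssw
  list(F = (ssa / (a - 1)) / (ssw / (n - a)), R2 = ssa / sst,
       ssa = ssa, ssw = ssw, sst = sst)
}

check_grouping <- function(dm, groups) {
  if (nrow(dm) != length(groups)) stop("groups must match the distance matrix")
  g <- as.integer(factor(groups))
  tab <- table(g)
  if (length(tab) < 2) stop("need at least two groups")
  if (any(tab < 2)) stop("every group needs at least two samples")
  g
}

#' PERMANOVA: permutational multivariate analysis of variance
#'
#' One-factor PERMANOVA in Anderson's formulation: the pseudo-F statistic
#' is computed from among- and within-group sums of squared
#' inter-sample distances, and its significance by permuting group
#' labels.  The reported p-value uses the `(count + 1) / (n_perm + 1)`
#' convention; when the label-arrangement space is small (at most
#' `max_exact` arrangements for two groups) the test enumerates it
#' exactly instead.
#'
#' @param dm Symmetric distance matrix (e.g. from [beta_distance()]).
#' @param groups Group labels, one per sample.
#' @param n_perm Number of label permutations (default 999).
#' @param seed Integer seed for the permutations.
#' @param max_exact Enumerate exactly when the two-group arrangement count
#'   is at most this (default 10000).
#' @return List of class `permanova_result`: `pseudo_F`, `R2`, `p_value`,
#'   `n_permutations`, `exact`.
#' @export
permanova <- function(dm, groups, n_perm = 999, seed = 1, max_exact = 10000) {
  g <- check_grouping(dm, groups)
  D2 <- dm^2
  obs <- pseudo_f(D2, g)
  n <- length(g)
  two_groups <- length(unique(g)) == 2
  n_arr <- if (two_groups) choose(n, sum(g == g[1])) else Inf
  if (two_groups && n_arr <= max_exact) {
    sets <- utils::combn(n, sum(g == 1))
    fs <- apply(sets, 2, function(idx) {
      gp <- rep(2L, n); gp[idx] <- 1L
      pseudo_f(D2, gp)$F
    })
    p <- mean(fs >= obs$F - 1e-12)
    n_used <- ncol(sets); exact <- TRUE
  } else {
    fs <- with_seed(seed, replicate(n_perm, pseudo_f(D2, sample(g))$F))
    p <- (sum(fs >= obs$F - 1e-12) + 1) / (n_perm + 1)
    n_used <- n_perm; exact <- FALSE
  }
  structure(list(pseudo_F = obs$F, R2 = obs$R2, p_value = p,
                 n_permutations = n_used, exact = exact),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.3f, R2 = %.1f%%, p = %.4g (%s, %d perms)\n",
              x$pseudo_F, 100 * x$R2, x$p_value,
              if (x$exact) "exact" else "Monte Carlo", x$n_permutations))
  invisible(x)
}

# Distances of each sample to its group centroid in the principal
# coordinate embedding, with Anderson's (2006) correction for negative
# eigenvalues (imaginary axes subtract).
centroid_distances <- function(dm, g) {
  n <- nrow(dm)
  J <- diag(n) - matrix(1 / n, n, n)
  G <- -0.5 * J %*% (dm^2) %*% J
  e <- eigen((G + t(G)) / 2, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-8
  pos <- e$values > tol
  neg <- e$values < -tol
  Xp <- e$vectors[, pos, drop = FALSE] %*% diag(sqrt(e$values[pos]),
                                                sum(pos))
  Xn <- e$vectors[, neg, drop = FALSE] %*% diag(sqrt(-e$values[neg]),
                                                sum(neg))
  d2 <- numeric(n)
  for (lev in unique(g)) {
    idx <- which(g == lev)
    cp <- colMeans(Xp[idx, , drop = FALSE])
    cn <- colMeans(Xn[idx, , drop = FALSE])
    dp <- rowSums(sweep(Xp[idx, , drop = FALSE], 2, cp)^2)
    dn <- rowSums(sweep(Xn[idx, , drop = FALSE], 2, cn)^2)
    d2[idx] <- dp - dn
  }
  sqrt(pmax(d2, 0))
}

anova_f <- function(z, g) {
  n <- length(z); a <- length(unique(g))
  gm <- mean(z)
  ssa <- sum(tapply(z, g, function(v) length(v) * (mean(v) - gm)^2))
  ssw <- sum(tapply(z, g, function(v) sum((v - mean(v))^2)))
  (ssa / (a - 1)) / (ssw / (n - a))
}

#' PERMDISP: homogeneity of multivariate dispersions
#'
#' Tests whether groups differ in spread: each sample's distance to its
#' group centroid is computed in the principal-coordinate embedding of the
#' distance matrix (negative eigenvalues subtracting, per Anderson 2006),
#' then an ANOVA F on those distances is assessed by permuting group
#' labels.
#'
#' @inheritParams permanova
#' @return List of class `permdisp_result`: `F`, `p_value`,
#'   `n_permutations`, `distances` (per-sample distance to own-group
#'   centroid).
#' @export
permdisp <- function(dm, groups, n_perm = 999, seed = 1) {
  g <- check_grouping(dm, groups)
  z <- centroid_distances(dm, g)
  f_obs <- anova_f(z, g)
  fs <- with_seed(seed, replicate(n_perm, anova_f(z, sample(g))))
  p <- (sum(fs >= f_obs - 1e-12) + 1) / (n_perm + 1)
  structure(list(F = f_obs, p_value = p, n_permutations = n_perm,
                 distances = stats::setNames(z, rownames(dm))),
            class = "permdisp_result")
}

#' @export
print.permdisp_result <- function(x, ...) {
  cat(sprintf("PERMDISP: F = %.3f, p = %.4g (%d perms)\n",
              x$F, x$p_value, x$n_permutations))
  invisible(x)
}

#' Group-equalized indicator-value analysis (presence-absence, two groups)
#'
#' For each taxon and group g, fidelity `B_g` is the fraction of group-g
#' samples containing the taxon and specificity `A_g = B_g / (B_g +
#' B_other)` (the group-size-equalized form, so unequal group sizes do not
#' bias specificity).  The indicator statistic is
#' `max_g sqrt(A_g * B_g)`; a value of 1 means present in every sample of
#' one group and absent from the other.  Significance is assessed by
#' permuting group labels; p-values are Benjamini-Hochberg adjusted across
#' taxa.
#'
#' @param x An [asv_table()] (presence is count >= 1) or a logical/0-1
#'   samples-by-taxa matrix.
#' @param groups Two-level group labels, one per sample.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed.
#' @param min_prevalence Drop taxa present in fewer than this fraction of
#'   samples before testing (default 0.15).
#' @param alpha,min_stat Indicator-classification thresholds (defaults
#'   .05 and 0.7): a taxon is flagged when `p < alpha` and
#'   `stat > min_stat`.
#' @return Data frame, one row per retained taxon: `taxon`, `group` (the
#'   maximizing level), `A`, `B`, `stat`, `p_value`, `q_value`,
#'   `indicator`.
#' @export
indval <- function(x, groups, n_perm = 999, seed = 1,
                   min_prevalence = 0.15, alpha = 0.05, min_stat = 0.7) {
  pres <- if (inherits(x, "asv_table")) x$counts > 0 else x > 0
  g <- factor(groups)
  if (nlevels(g) != 2)
    stop("indval supports exactly two groups")
  if (nrow(pres) != length(g)) stop("groups must match the table rows")
  keep <- colMeans(pres) >= min_prevalence
  pres <- pres[, keep, drop = FALSE]
  if (!ncol(pres)) stop("no taxa pass the prevalence filter")

  stat_fun <- function(gg) {
    b1 <- colMeans(pres[gg == levels(g)[1], , drop = FALSE])
    b2 <- colMeans(pres[gg == levels(g)[2], , drop = FALSE])
    tot <- b1 + b2
    a1 <- ifelse(tot > 0, b1 / tot, 0)
    a2 <- ifelse(tot > 0, b2 / tot, 0)
    s1 <- sqrt(a1 * b1); s2 <- sqrt(a2 * b2)
    list(stat = pmax(s1, s2), which = ifelse(s1 >= s2, 1L, 2L),
         A = ifelse(s1 >= s2, a1, a2), B = ifelse(s1 >= s2, b1, b2))
  }
  obs <- stat_fun(g)
  perm_ge <- with_seed(seed, {
    cnt <- integer(ncol(pres))
    for (k in seq_len(n_perm)) {
      s <- stat_fun(sample(g))$stat
      cnt <- cnt + (s >= obs$stat - 1e-12)
    }
    cnt
  })
  p <- (perm_ge + 1) / (n_perm + 1)
  q <- bh_fdr(p)
  data.frame(taxon = colnames(pres),
             group = levels(g)[obs$which],
             A = unname(obs$A), B = unname(obs$B),
             stat = unname(obs$stat),
             p_value = unname(p), q_value = unname(q),
             indicator = unname(p < alpha & obs$stat > min_stat),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values: `q_(i) = min_{j >= i} m * p_(j) / j`, capped
#' at 1, returned in the input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted q-values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(p)
  if (!m) return(numeric(0))
  ord <- order(p)
  q_sorted <- pmin(1, rev(cummin(rev(m * p[ord] / seq_len(m)))))
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}
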