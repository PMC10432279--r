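#' Exact binomial proportion confidence interval
#'
#' Clopper-Pearson interval from Beta quantiles: lower bound
#' `qbeta(alpha/2, k, N-k+1)` (0 when k = 0), upper bound
#' `qbeta(1-alpha/2, k+1, N-k)` (1 when k = N). Also formats the ratio
#' k:(N-k) reduced to x:1, as conventional for sex ratios.
#'
#' @param k number of successes (e.g. males)
#' @param n number of trials (e.g. sexed individuals)
#' @param level confidence level (default 0.95)
#' @return list of class `proportion_ci`: k, n, estimate, lower, upper,
#'   level, ratio (string)
#' @export
proportion_ci <- function(k, n, level = 0.95) {
  if (n <= 0) stop_pmrkin("n must be > 0")
  if (k < 0 || k > n) stop_pmrkin("need 0 <= k <= n")
  alpha <- 1 - level
  lower <- if (k == 0) 0 else stats::qbeta(alpha / 2, k, n - k + 1)
  upper <- if (k == n) 1 else stats::qbeta(1 - alpha / 2, k + 1, n - k)
  ratio <- if (k == n) sprintf("%d:0", k)
           else sprintf("%.3g:1", k / (n - k))
  structure(list(k = k, n = n, estimate = k / n, lower = lower, upper = upper,
                 level = level, ratio = ratio), class = "proportion_ci")
}

#' @export
print.proportion_ci <- function(x, ...) {
  cat(sprintf("%d/%d = %.3f (ratio %s), %g%% CI = %.1f-%.1f%%\n",
              x$k, x$n, x$estimate, x$ratio, 100 * x$level,
              100 * x$lower, 100 * x$upper))
  invisible(x)
}

#' Occupation duration from generation counts
#'
#' Converts a range of generation counts to calendar years at the
#' standard anthropological generation interval of 28 years.
#'
#' @param generations numeric vector (e.g. `c(3, 4)` for 3-4 generations)
#' @param generation_years years per generation (default 28)
#' @return vector of years, same length as `generations`
#' @export
occupation_duration <- function(generations, generation_years = 28) {
  if (any(generations < 0) || generation_years < 0)
    stop_pmrkin("generation counts and interval must be non-negative")
  generations * generation_years
}

#' Permutation test of within-category grave distance
#'
#' Tests whether the pairs of one relationship category (for example
#' father and subadult son) are buried closer together than expected.
#' The statistic is the mean Euclidean distance over the category's
#' pairs; the null distribution permutes individual identities (i.e.
#' shuffles the coordinates over individuals) and recomputes the same
#' pair set. The p-value is one-sided for proximity with the add-one
#' correction: p = (1 + #{null <= observed}) / (1 + n_perm).
#'
#' @param coords data.frame with columns id, grave_x, grave_y
#' @param pairs data.frame with columns id1, id2, category
#' @param category the category label to test
#' @param n_perm number of permutations (>= 99)
#' @return list of class `distance_test`: category, n_pairs, mean_dist,
#'   p_value, n_perm, degenerate flag
#' @export
category_distance_test <- function(coords, pairs, category, n_perm = 9999) {
  if (n_perm < 99) stop_pmrkin("n_perm must be >= 99")
  sel <- pairs[pairs$category == category, , drop = FALSE]
  if (nrow(sel) == 0) stop_pmrkin("no pairs in category '%s'", category)
  ids <- coords$id
  if (!all(c(sel$id1, sel$id2) %in% ids))
    stop_pmrkin("pair member without coordinates")
  xy <- as.matrix(coords[, c("grave_x", "grave_y")])
  i1 <- match(sel$id1, ids); i2 <- match(sel$id2, ids)
  pair_mean <- function(m) mean(sqrt(rowSums((m[i1, , drop = FALSE] -
                                              m[i2, , drop = FALSE])^2)))
  obs <- pair_mean(xy)
  degenerate <- all(stats::dist(xy) == 0)
  null <- vapply(seq_len(n_perm), function(b) pair_mean(xy[sample(nrow(xy)), ,
                                                           drop = FALSE]), 0)
  p <- (1 + sum(null <= obs)) / (1 + n_perm)
  structure(list(category = category, n_pairs = nrow(sel), mean_dist = obs,
                 p_value = p, n_perm = n_perm, degenerate = degenerate),
            class = "distance_test")
}

#' @export
print.distance_test <- function(x, ...) {
  cat(sprintf("Category '%s': %d pairs, mean distance %.2f m, p = %.4g (%d permutations)%s\n",
              x$category, x$n_pairs, x$mean_dist, x$p_value, x$n_perm,
              if (x$degenerate) " [degenerate layout]" else ""))
  invisible(x)
}

#' Mantel test of two distance matrices
#'
#' Pearson correlation of the upper triangles, with significance by
#' jointly permuting the rows and columns of the second matrix. The
#' p-value is one-sided for positive association with the add-one
#' correction.
#'
#' @param a,b square symmetric distance matrices with zero diagonal
#' @param n_perm number of permutations
#' @return list of class `mantel_result`: r, p_value, n, n_perm
#' @export
mantel_test <- function(a, b, n_perm = 9999) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b)) || nrow(a) != ncol(a))
    stop_pmrkin("matrices must be square and of equal size")
  if (any(abs(a - t(a)) > 1e-8) || any(abs(b - t(b)) > 1e-8))
    stop_pmrkin("matrices must be symmetric")
  ut <- upper.tri(a)
  if (stats::sd(a[ut]) == 0 || stats::sd(b[ut]) == 0)
    stop_pmrkin("constant distance matrix: correlation undefined")
  r <- stats::cor(a[ut], b[ut])
  null <- vapply(seq_len(n_perm), function(i) {
    p <- sample(nrow(b))
    stats::cor(a[ut], b[p, p][ut])
  }, 0)
  p <- (1 + sum(null >= r)) / (1 + n_perm)
  structure(list(r = r, p_value = p, n = nrow(a), n_perm = n_perm),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel test: r = %.3f, p = %.4g (%d individuals, %d permutations)\n",
              x$r, x$p_value, x$n, x$n_perm))
  invisible(x)
}

#' Haplogroup diversity and transmission summary
#'
#' Counts the distinct mitochondrial and Y haplogroups in the cohort
#' and, within assembled pedigrees, measures how far each mitochondrial
#' label was transmitted down the maternal line (the length in
#' mother-to-child links of the longest same-label maternal chain).
#' Under female exogamy each in-migrating mother contributes a fresh
#' lineage, so the modal transmission depth is one generation.
#'
#' @param metadata metadata data.frame with mt_hg / y_hg columns
#' @param pedigrees optional `pedigree_set` or list of `pedigree_graph`
#' @return list: `n_individuals_mt`, `n_mt`, `n_individuals_y`, `n_y`,
#'   `mt_depth` (named vector: per mt label, maximum maternal chain
#'   length in transmissions; only labels observed on a mother)
#' @export
haplogroup_summary <- function(metadata, pedigrees = NULL) {
  md <- metadata
  out <- list(n_individuals_mt = sum(!is.na(md$mt_hg)),
              n_mt = length(unique(stats::na.omit(md$mt_hg))),
              n_individuals_y = sum(!is.na(md$y_hg)),
              n_y = length(unique(stats::na.omit(md$y_hg))),
              mt_depth = stats::setNames(numeric(0), character(0)))
  if (is.null(pedigrees)) return(out)
  graphs <- if (inherits(pedigrees, "pedigree_set")) pedigrees$graphs else pedigrees
  depth <- list()
  for (g in graphs) {
    mo <- g$edges[g$edges$role == "MOTHER", , drop = FALSE]
    lab <- stats::setNames(g$nodes$mt_hg, g$nodes$id)
    # chain length ending at each node, following same-label mother links
    len <- stats::setNames(rep(0L, nrow(g$nodes)), g$nodes$id)
    ord <- g$nodes$id[order(g$nodes$generation)]
    for (id in ord) {
      m <- mo$parent[mo$child == id]
      if (length(m) == 1 && !is.na(lab[id]) && !is.na(lab[m]) &&
          lab[id] == lab[m])
        len[id] <- len[m] + 1L
    }
    for (id in names(len)[len > 0]) {
      l <- lab[[id]]
      depth[[l]] <- max(depth[[l]] %||% 0L, len[[id]])
    }
  }
  out$mt_depth <- unlist(depth) %||% stats::setNames(numeric(0), character(0))
  out
}
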