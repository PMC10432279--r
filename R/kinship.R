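#' Pairwise mismatch rate of two pseudo-haploid individuals
#'
#' Counts the sites non-missing in both individuals (overlap n) and the
#' sites at which the calls differ (mismatches k); the pairwise mismatch
#' rate is k/n with binomial standard error sqrt(pmr(1-pmr)/n). Pairs
#' with overlap below `min_overlap` are flagged LOW_OVERLAP.
#'
#' @param geno pseudo-haploid call matrix (individuals x sites; 0/1/NA)
#' @param i,j individual ids (rownames of `geno`)
#' @param min_overlap minimum overlap for a confident comparison
#' @return list with id1, id2, n, k, pmr, se, flag ("" or "LOW_OVERLAP")
#' @export
pairwise_mismatch <- function(geno, i, j, min_overlap = 5000) {
  if (!all(c(i, j) %in% rownames(geno))) stop_pmrkin("unknown individual id")
  a <- geno[i, ]; b <- geno[j, ]
  both <- !is.na(a) & !is.na(b)
  n <- sum(both)
  k <- sum(a[both] != b[both])
  pmr <- if (n > 0) k / n else NA_real_
  se <- if (n > 0) sqrt(pmr * (1 - pmr) / n) else NA_real_
  list(id1 = min(i, j), id2 = max(i, j), n = n, k = k, pmr = pmr, se = se,
       flag = if (n < min_overlap) "LOW_OVERLAP" else "")
}

# overlap and mismatch counts for all pairs at once via matrix products
pmr_counts <- function(geno) {
  obs <- !is.na(geno)
  A <- geno; A[!obs] <- 0L
  A1 <- A * obs                 # ALT indicator on observed sites
  A0 <- (1L - A) * obs          # REF indicator on observed sites
  n <- tcrossprod(obs * 1L)
  k <- tcrossprod(A1, A0) + tcrossprod(A0, A1)
  list(n = n, k = k)
}

#' Background (unrelated-pair) mismatch rate
#'
#' Robust estimate of the population background PMR p0. Close kin pull
#' the pair PMR down, never up, so the unrelated mode is anchored at a
#' high quantile of the pair PMR distribution (default the 95th
#' percentile, which tolerates cohorts dominated by one family); pairs
#' whose PMR falls below 0.90625 times the anchor — the midpoint
#' between the normalised second- and third-degree expectations, i.e.
#' provisional close kin — are dropped and p0 is the median of the
#' remainder. The anchor, not the refined median, defines the cut on
#' every iteration: re-thresholding against the shrinking median is a
#' downward ratchet that progressively admits second-degree pairs.
#'
#' @param pairs data.frame with columns n, k, pmr (one row per pair)
#' @param min_overlap pairs with n below this are ignored
#' @param kin_threshold drop pairs with pmr below this multiple of the
#'   anchor
#' @param init_quantile quantile of the PMR distribution used as anchor
#' @param max_iter retained for interface stability; the anchored
#'   estimate converges in one pass
#' @return list of class `background_rate`: p0, n_pairs (used), iterations
#' @export
estimate_background <- function(pairs, min_overlap = 5000,
                                kin_threshold = 0.90625,
                                init_quantile = 0.95, max_iter = 10) {
  usable <- pairs[pairs$n >= min_overlap & is.finite(pairs$pmr), , drop = FALSE]
  if (nrow(usable) < 3)
    stop_pmrkin("background estimation needs >= 3 pairs with overlap >= %d",
                min_overlap)
  anchor <- stats::quantile(usable$pmr, init_quantile, names = FALSE)
  keep <- usable$pmr >= kin_threshold * anchor
  p0 <- stats::median(usable$pmr[keep])
  it <- 1L
  if (!is.finite(p0) || p0 <= 0 || p0 >= 1)
    stop_pmrkin("degenerate background rate p0 = %g", p0)
  structure(list(p0 = p0, n_pairs = sum(keep), iterations = it),
            class = "background_rate")
}

#' Expected mismatch rate for a relatedness degree
#'
#' Under pseudo-haploid sampling the probability that the two sampled
#' alleles are identical by descent equals the kinship coefficient
#' phi = 2^-(d+2) for degree d, so the expected PMR is
#' \deqn{p_d = p_0 (1 - 2^{-(d+1)})}
#' giving p0/2 for degree 0 (same individual or identical twins),
#' 0.75 p0 for first degree, 0.875 p0 for second degree, and p0 for
#' unrelated pairs.
#'
#' @param degree integer degree(s) >= 0, or "UNRELATED"
#' @param p0 background rate in (0,1)
#' @return expected mismatch rate(s)
#' @export
expected_pmr <- function(degree, p0) {
  if (!is.finite(p0) || p0 <= 0 || p0 >= 1) stop_pmrkin("invalid p0 = %g", p0)
  vapply(as.character(degree), function(d) {
    if (d == "UNRELATED") return(p0)
    dd <- suppressWarnings(as.numeric(d))
    if (is.na(dd) || dd < 0) stop_pmrkin("invalid degree '%s'", d)
    p0 * (1 - 2^-(dd + 1))
  }, 0)
}

#' Binomial posterior over relatedness degree classes
#'
#' Given a pair's overlap n and mismatch count k, evaluates the binomial
#' likelihood of k at the expected rate of each candidate class
#' (degree 0, 1, 2, ..., UNRELATED) and returns normalised posterior
#' probabilities under the supplied prior. Computation is in log space.
#' Ties are broken towards the more distant class (conservative against
#' false kin claims) with a warning.
#'
#' @param n overlap (sites compared)
#' @param k mismatching sites
#' @param p0 background rate
#' @param classes candidate classes (default `c("0","1","2","UNRELATED")`)
#' @param prior prior weights over classes (default uniform)
#' @return list of class `degree_posterior`: `posterior` (named numeric),
#'   `call` (chosen class), `n`, `k`, `p0`
#' @export
classify_degree <- function(n, k, p0, classes = c("0", "1", "2", "UNRELATED"),
                            prior = NULL) {
  if (k > n || k < 0) stop_pmrkin("need 0 <= k <= n")
  if (is.null(prior)) prior <- rep(1 / length(classes), length(classes))
  if (length(prior) != length(classes)) stop_pmrkin("prior length mismatch")
  rates <- expected_pmr(classes, p0)
  logpost <- log(prior) +
    if (n == 0) 0 else stats::dbinom(k, n, rates, log = TRUE)
  post <- exp(logpost - logsumexp(logpost))
  names(post) <- classes
  best <- which(post == max(post))
  if (length(best) > 1) {
    warning("posterior tie broken towards the more distant class", call. = FALSE)
    best <- best[length(best)]   # classes ordered nearest -> most distant
  }
  structure(list(posterior = post, call = classes[best], n = n, k = k, p0 = p0),
            class = "degree_posterior")
}

#' Chromosome-windowed mismatch rates for a pair
#'
#' Tiles each chromosome into fixed genetic-length windows and computes
#' the per-window overlap, mismatch count and PMR. Windows with fewer
#' than `min_sites` overlapping sites are flagged unusable and excluded
#' from downstream model comparison.
#'
#' @param geno call matrix
#' @param i,j individual ids
#' @param panel a [snp_panel()] with genetic positions
#' @param window_cm window length in centimorgans (default 20)
#' @param min_sites minimum overlapping sites per usable window
#' @return data.frame of class `window_series`: chrom, win_start, win_end
#'   (Morgans), n_w, k_w, pmr_w, usable
#' @export
windowed_pmr <- function(geno, i, j, panel, window_cm = 20, min_sites = 50) {
  if (!all(c(i, j) %in% rownames(geno))) stop_pmrkin("unknown individual id")
  if (nrow(panel) != ncol(geno)) stop_pmrkin("panel/geno size mismatch")
  a <- geno[i, ]; b <- geno[j, ]
  both <- !is.na(a) & !is.na(b)
  mism <- both
  mism[both] <- a[both] != b[both]
  wlen <- window_cm / 100
  chroms <- unique(panel$chrom)
  win <- floor(panel$gpos / wlen)
  gid <- (match(panel$chrom, chroms) - 1L) * 100000L + win
  agg <- rowsum(cbind(n = as.integer(both), k = as.integer(mism)), gid,
                reorder = TRUE)
  uid <- sort(unique(gid))
  n_w <- agg[, "n"]; k_w <- agg[, "k"]
  out <- data.frame(chrom = chroms[uid %/% 100000L + 1L],
                    win_start = (uid %% 100000L) * wlen,
                    win_end = (uid %% 100000L + 1L) * wlen,
                    n_w = n_w, k_w = k_w,
                    pmr_w = ifelse(n_w > 0, k_w / n_w, NA_real_),
                    usable = n_w >= min_sites,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (!any(out$usable)) stop_pmrkin("no usable windows for pair %s-%s", i, j)
  class(out) <- c("window_series", "data.frame")
  out
}

#' Parent-offspring versus full-sibling discrimination
#'
#' For a pair already classified first degree, compares two models of the
#' windowed mismatch series. Parent-offspring pairs share exactly one
#' haplotype everywhere, so every window has rate 0.75 p0. Full siblings
#' are IBD 0/1/2 in 1/4, 1/2, 1/4 of the genome, so each window's count is
#' modelled as the mixture
#' \deqn{k_w \sim 1/4\,Bin(n_w, p_0) + 1/2\,Bin(n_w, 0.75 p_0) + 1/4\,Bin(n_w, 0.5 p_0)}
#' The decision is the sign of the summed per-window log likelihood
#' ratio (positive favours parent-offspring); its magnitude is the
#' log-Bayes factor under equal model priors.
#'
#' @param series a [windowed_pmr()] result
#' @param p0 background rate
#' @param min_windows minimum usable windows; fewer gives INDETERMINATE
#' @return list of class `po_sib_call`: `call` (PARENT_OFFSPRING, SIBLING
#'   or INDETERMINATE), `log_bf`, `n_windows`
#' @export
classify_po_vs_sibling <- function(series, p0, min_windows = 10) {
  use <- series[series$usable, , drop = FALSE]
  if (nrow(use) < min_windows)
    return(structure(list(call = "INDETERMINATE", log_bf = NA_real_,
                          n_windows = nrow(use)), class = "po_sib_call"))
  ll_po <- stats::dbinom(use$k_w, use$n_w, 0.75 * p0, log = TRUE)
  mix <- cbind(log(0.25) + stats::dbinom(use$k_w, use$n_w, p0, log = TRUE),
               log(0.50) + stats::dbinom(use$k_w, use$n_w, 0.75 * p0, log = TRUE),
               log(0.25) + stats::dbinom(use$k_w, use$n_w, 0.50 * p0, log = TRUE))
  ll_sib <- apply(mix, 1, logsumexp)
  log_bf <- sum(ll_po - ll_sib)
  structure(list(call = if (log_bf > 0) "PARENT_OFFSPRING" else "SIBLING",
                 log_bf = log_bf, n_windows = nrow(use)),
            class = "po_sib_call")
}

#' Estimate pairwise kinship for a cohort
#'
#' The package's central estimator. Computes mismatch statistics for all
#' unordered pairs of individuals, estimates the unrelated background
#' rate internally, assigns each pair a binomial posterior over degree
#' classes, and, for pairs called first degree, discriminates
#' parent-offspring from full siblings using chromosome-windowed
#' mismatch rates.
#'
#' @param geno pseudo-haploid call matrix (individuals x sites; 0/1/NA)
#' @param panel a [snp_panel()] describing the sites
#' @param metadata optional metadata data.frame (carried through to the
#'   result for downstream pedigree assembly)
#' @param min_overlap minimum pair overlap for classification
#' @param window_cm genetic window length for the first-degree sub-call
#' @param classes degree classes for the posterior
#' @param prior prior over classes (default uniform)
#' @param min_window_sites minimum overlapping sites per usable window
#' @return object of class `kinship`: list with `pairs` (one row per
#'   pair: ids, n, k, pmr, se, norm_pmr, posterior columns, call,
#'   po_sib_call, log_bf, flags), `background`, `classes`, and the inputs'
#'   dimensions
#' @seealso [classify_degree()], [classify_po_vs_sibling()]
#' @export
estimate_kinship <- function(geno, panel, metadata = NULL, min_overlap = 5000,
                             window_cm = 20, classes = c("0", "1", "2", "UNRELATED"),
                             prior = NULL, min_window_sites = 50) {
  if (nrow(geno) < 2) stop_pmrkin("need at least two individuals")
  if (nrow(panel) != ncol(geno)) stop_pmrkin("panel/geno size mismatch")
  ids <- sort(rownames(geno))
  cnt <- pmr_counts(geno)
  pairs_idx <- utils::combn(ids, 2)
  n <- cnt$n[cbind(pairs_idx[1, ], pairs_idx[2, ])]
  k <- cnt$k[cbind(pairs_idx[1, ], pairs_idx[2, ])]
  tab <- data.frame(id1 = pairs_idx[1, ], id2 = pairs_idx[2, ],
                    n = n, k = k, pmr = ifelse(n > 0, k / n, NA_real_),
                    stringsAsFactors = FALSE)
  tab$se <- ifelse(tab$n > 0, sqrt(tab$pmr * (1 - tab$pmr) / tab$n), NA_real_)
  bg <- estimate_background(tab, min_overlap = min_overlap)
  tab$norm_pmr <- tab$pmr / bg$p0

  post <- matrix(NA_real_, nrow(tab), length(classes),
                 dimnames = list(NULL, paste0("P_", sub("UNRELATED", "unrel", classes))))
  call <- character(nrow(tab)); flags <- character(nrow(tab))
  po_sib <- rep(NA_character_, nrow(tab)); log_bf <- rep(NA_real_, nrow(tab))
  for (r in seq_len(nrow(tab))) {
    if (tab$n[r] < min_overlap) {
      call[r] <- "LOW_OVERLAP"; flags[r] <- "LOW_OVERLAP"
      next
    }
    dp <- classify_degree(tab$n[r], tab$k[r], bg$p0, classes = classes,
                          prior = prior)
    post[r, ] <- dp$posterior
    call[r] <- dp$call
    if (dp$call == "1") {
      ws <- try(windowed_pmr(geno, tab$id1[r], tab$id2[r], panel,
                             window_cm = window_cm,
                             min_sites = min_window_sites), silent = TRUE)
      if (inherits(ws, "try-error")) {
        po_sib[r] <- "INDETERMINATE"; flags[r] <- "NO_WINDOWS"
      } else {
        ps <- classify_po_vs_sibling(ws, bg$p0)
        po_sib[r] <- ps$call; log_bf[r] <- ps$log_bf
        if (ps$call == "INDETERMINATE") flags[r] <- "FEW_WINDOWS"
      }
    }
  }
  tab <- cbind(tab, post)
  tab$call <- call; tab$po_sib_call <- po_sib; tab$log_bf <- log_bf
  tab$flags <- flags
  structure(list(pairs = tab, background = bg, classes = classes,
                 n_individuals = nrow(geno), n_sites = ncol(geno),
                 metadata = metadata, min_overlap = min_overlap),
            class = "kinship")
}

#' @export
print.kinship <- function(x, ...) {
  cat(sprintf("Pairwise kinship estimates: %d individuals, %d sites, %d pairs\n",
              x$n_individuals, x$n_sites, nrow(x$pairs)))
  cat(sprintf("Background mismatch rate p0 = %.4f (%d pairs, %d iterations)\n",
              x$background$p0, x$background$n_pairs, x$background$iterations))
  tb <- table(x$pairs$call)
  cat("Degree calls:\n")
  print(tb)
  invisible(x)
}

#' @export
summary.kinship <- function(object, ...) {
  p <- object$pairs
  related <- p[!p$call %in% c("UNRELATED", "LOW_OVERLAP"), , drop = FALSE]
  out <- list(p0 = object$background$p0,
              n_pairs = nrow(p),
              calls = table(p$call),
              related = related[order(related$norm_pmr),
                                c("id1", "id2", "n", "pmr", "norm_pmr",
                                  "call", "po_sib_call", "log_bf")])
  class(out) <- "summary.kinship"
  out
}

#' @export
print.summary.kinship <- function(x, ...) {
  cat(sprintf("Background rate p0 = %.4f over %d pairs\n", x$p0, x$n_pairs))
  print(x$calls)
  if (nrow(x$related)) {
    cat("\nRelated pairs (sorted by normalised PMR):\n")
    print(x$related, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' @export
as.data.frame.kinship <- function(x, ...) x$pairs

#' Diagnostic plot of a kinship fit
#'
#' Normalised PMR against pair overlap, with horizontal reference lines at
#' the expected normalised rates of each degree class (0.5, 0.75, 0.875, 1).
#'
#' @param x a `kinship` object
#' @param ... passed to [graphics::plot()]
#' @export
plot.kinship <- function(x, ...) {
  p <- x$pairs[is.finite(x$pairs$norm_pmr), ]
  graphics::plot(p$n, p$norm_pmr, xlab = "pair overlap (sites)",
                 ylab = "normalised PMR",
                 col = ifelse(p$call == "UNRELATED", "grey40", "firebrick"),
                 pch = 16, ...)
  graphics::abline(h = c(0.5, 0.75, 0.875, 1), lty = 3, col = "grey60")
  invisible(x)
}

#' Export a kinship table to TSV
#' @param x a `kinship` object
#' @param path output file
#' @export
write_kinship <- function(x, path) {
  utils::write.table(x$pairs, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}
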