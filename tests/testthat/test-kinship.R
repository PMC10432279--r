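test_that("pairwise mismatch counts match a naive per-site loop", {
  set.seed(1)
  n <- 1000
  a <- sample(c(0L, 1L, NA), n, replace = TRUE, prob = c(0.45, 0.45, 0.1))
  b <- sample(c(0L, 1L, NA), n, replace = TRUE, prob = c(0.45, 0.45, 0.1))
  geno <- rbind(A = a, B = b)
  pm <- pairwise_mismatch(geno, "A", "B", min_overlap = 100)
  # oracle: explicit loop
  n0 <- 0L; k0 <- 0L
  for (s in seq_len(n)) {
    if (!is.na(a[s]) && !is.na(b[s])) {
      n0 <- n0 + 1L
      if (a[s] != b[s]) k0 <- k0 + 1L
    }
  }
  expect_equal(pm$n, n0)
  expect_equal(pm$k, k0)
  expect_equal(pm$pmr, k0 / n0)
  # symmetry
  pm2 <- pairwise_mismatch(geno, "B", "A", min_overlap = 100)
  expect_equal(pm[c("n", "k", "pmr")], pm2[c("n", "k", "pmr")])
  # matrix-product path agrees with the per-pair path
  cnt <- pmrkin:::pmr_counts(geno)
  expect_equal(unname(cnt$n["A", "B"]), n0)
  expect_equal(unname(cnt$k["A", "B"]), k0)
})

test_that("degenerate call vectors give mismatch rates zero and one", {
  geno <- rbind(A = rep(0L, 100), B = rep(0L, 100), C = rep(1L, 100))
  expect_equal(pairwise_mismatch(geno, "A", "B", 10)$pmr, 0)
  expect_equal(pairwise_mismatch(geno, "A", "C", 10)$pmr, 1)
  expect_identical(pairwise_mismatch(geno, "A", "B", 1000)$flag, "LOW_OVERLAP")
})

test_that("background estimation recovers the unrelated rate", {
  # constant pmr across pairs is returned exactly
  const <- data.frame(n = rep(10000, 5), k = 2500, pmr = 0.25)
  expect_equal(estimate_background(const)$p0, 0.25)
  # all pairs unrelated at simulated rate ~0.24
  set.seed(2)
  n <- 20000
  k <- rbinom(30, n, 0.24)
  tab <- data.frame(n = n, k = k, pmr = k / n)
  bg <- estimate_background(tab)
  expect_lt(abs(bg$p0 - 0.24), 3 * sqrt(0.24 * 0.76 / n))
  # robust to one parent-offspring pair among twenty unrelated
  set.seed(3)
  k20 <- rbinom(20, n, 0.24)
  tab20 <- data.frame(n = n, k = k20, pmr = k20 / n)
  kpo <- rbinom(1, n, 0.18)
  tabpo <- rbind(tab20, data.frame(n = n, k = kpo, pmr = kpo / n))
  expect_equal(estimate_background(tabpo)$p0, estimate_background(tab20)$p0,
               tolerance = 0.01)
  expect_error(estimate_background(tab[1:2, ]), ">= 3 pairs")
})

test_that("expected mismatch rates halve the kin signal per degree", {
  p0 <- 0.25
  expect_equal(unname(expected_pmr(0, p0)), 0.5 * p0)
  expect_equal(unname(expected_pmr(1, p0)), 0.75 * p0)
  expect_equal(unname(expected_pmr(2, p0)), 0.875 * p0)
  expect_equal(unname(expected_pmr("UNRELATED", p0)), p0)
  # strictly increasing in degree, approaching p0, for any valid p0
  for (p in c(0.1, 0.25, 0.4)) {
    v <- expected_pmr(0:6, p)
    expect_true(all(diff(v) > 0))
    expect_lt(max(v), p)
    # normalised values are independent of p0
    expect_equal(unname(v / p), 1 - 2^-(1:7))
  }
  expect_error(expected_pmr(1, 0), "invalid p0")
})

test_that("Monte Carlo allele draws confirm the degree-rate model", {
  # oracle: draw two pseudo-haploid observations per relationship from
  # explicit diploid genotypes and count mismatches
  set.seed(4)
  S <- 60000
  f <- pmrkin:::draw_founder_freqs(S, c(0.5, 0.5), c(0.05, 0.95))
  p0_th <- mean(2 * f * (1 - f))
  dip <- function() rbind(rbinom(S, 1, f), rbinom(S, 1, f))
  draw <- function(d) d[cbind(sample(1:2, S, TRUE), 1:S)]
  se <- sqrt(0.25 / S) * 3
  # same individual sampled twice: half the unrelated rate
  a <- dip()
  expect_lt(abs(mean(draw(a) != draw(a)) - 0.5 * p0_th), se)
  # parent-offspring: child inherits one allele from the parent
  p1 <- dip(); p2 <- dip()
  child <- rbind(draw(p1), draw(p2))
  expect_lt(abs(mean(draw(p1) != draw(child)) - 0.75 * p0_th), se)
  # half siblings (second degree): shared father, unrelated mothers
  c1 <- rbind(draw(p1), draw(dip()))
  c2 <- rbind(draw(p1), draw(dip()))
  expect_lt(abs(mean(draw(c1) != draw(c2)) - 0.875 * p0_th), se)
  # unrelated
  expect_lt(abs(mean(draw(p1) != draw(p2)) - p0_th), se)
})

test_that("degree posteriors are normalised, consistent and conservative", {
  # frozen oracle: direct pmf evaluation at the four class rates
  p0 <- 0.25; n <- 100000
  dp1 <- classify_degree(n, 18750, p0)     # k/n = 0.75 p0 exactly
  expect_identical(dp1$call, "1")
  expect_gt(dp1$posterior[["1"]], 0.99)
  dpu <- classify_degree(n, 25000, p0)     # k/n = p0
  expect_identical(dpu$call, "UNRELATED")
  manual <- stats::dbinom(18750, n, c(0.125, 0.1875, 0.21875, 0.25))
  expect_equal(unname(dp1$posterior), manual / sum(manual), tolerance = 1e-9)
  # posterior sums to one for random inputs
  set.seed(5)
  for (r in 1:20) {
    nn <- sample(1000:50000, 1)
    kk <- rbinom(1, nn, runif(1, 0.1, 0.3))
    expect_equal(sum(classify_degree(nn, kk, p0)$posterior), 1, tolerance = 1e-9)
  }
  # zero overlap: uniform posterior (flat likelihood), distant tie-break
  dp0 <- suppressWarnings(classify_degree(0, 0, p0))
  expect_equal(unname(dp0$posterior), rep(0.25, 4))
  expect_identical(dp0$call, "UNRELATED")
  # consistency: at a fixed rate 0.875 p0 the mass on degree 2 grows with n
  mass <- vapply(c(2000, 20000, 200000), function(nn)
    classify_degree(nn, round(0.875 * p0 * nn), p0)$posterior[["2"]], 0)
  expect_true(all(diff(mass) > -1e-12))
  expect_gt(mass[3], mass[1])
  expect_gt(mass[3], 0.999)
})

test_that("genome windowing tiles chromosomes and conserves counts", {
  # 1 Morgan chromosome with 20 cM windows gives five windows
  set.seed(6)
  panel <- tiny_panel(n = 500, morgans = 0.999)
  geno <- rbind(A = rbinom(500, 1, 0.5), B = rbinom(500, 1, 0.5))
  geno[sample(1000, 100)] <- NA
  ws <- windowed_pmr(geno, "A", "B", panel, window_cm = 20, min_sites = 10)
  expect_equal(nrow(ws), 5)
  expect_equal(ws$win_end - ws$win_start, rep(0.2, 5))
  # conservation against the pair-level counts
  pm <- pairwise_mismatch(geno, "A", "B", min_overlap = 10)
  expect_equal(sum(ws$n_w), pm$n)
  expect_equal(sum(ws$k_w), pm$k)
  expect_error(windowed_pmr(geno, "A", "B", panel, min_sites = 1000),
               "no usable windows")
})

test_that("window likelihoods separate parent-offspring from siblings", {
  p0 <- 0.25
  n_w <- rep(2000L, 40)
  # oracle: windows exactly at the parent-offspring rate
  mk <- function(k_w) data.frame(chrom = "1", win_start = 0, win_end = 0.2,
                                 n_w = n_w, k_w = k_w, pmr_w = k_w / n_w,
                                 usable = TRUE)
  po <- classify_po_vs_sibling(mk(round(0.75 * p0 * n_w)), p0)
  expect_identical(po$call, "PARENT_OFFSPRING")
  expect_gt(po$log_bf, 0)
  # windows alternating at the sibling IBD mixture rates (1/4, 1/2, 1/4)
  rates <- rep(c(1, 0.75, 0.75, 0.5), 10) * p0
  sib <- classify_po_vs_sibling(mk(round(rates * n_w)), p0)
  expect_identical(sib$call, "SIBLING")
  expect_lt(sib$log_bf, 0)
  # too few usable windows
  few <- mk(round(0.75 * p0 * n_w))[1:5, ]
  expect_identical(classify_po_vs_sibling(few, p0)$call, "INDETERMINATE")
})

test_that("the cohort estimator recovers simulated relationships", {
  sim <- shared_sim()
  kin <- estimate_kinship(sim$geno, sim$panel, metadata = sim$metadata,
                          min_overlap = 2000)
  expect_s3_class(kin, "kinship")
  tab <- merge(kin$pairs, sim$truth, by = c("id1", "id2"))
  expect_equal(nrow(tab), nrow(sim$truth))
  # no unrelated pair ever called first degree
  expect_equal(sum(tab$degree == "UNRELATED" & tab$call == "1"), 0)
  # strong majority of close kin recovered at this desk scale
  d12 <- tab[tab$degree %in% c("1", "2"), ]
  expect_gt(mean(d12$call == d12$degree), 0.9)
  # posteriors normalised for all classified pairs
  pc <- as.matrix(tab[tab$call != "LOW_OVERLAP",
                      c("P_0", "P_1", "P_2", "P_unrel")])
  expect_true(all(abs(rowSums(pc) - 1) < 1e-9))
  # duplicate observation of one individual is called degree 0
  dup <- sample_pseudohaploid(sim$drop, sim$config,
                              ids = rownames(sim$geno)[1])
  rownames(dup) <- "DUP1"
  kin2 <- estimate_kinship(rbind(sim$geno, dup), sim$panel, min_overlap = 2000)
  r <- kin2$pairs[kin2$pairs$id1 == "DUP1" | kin2$pairs$id2 == "DUP1", ]
  self <- r[r$id1 == rownames(sim$geno)[1] | r$id2 == rownames(sim$geno)[1], ]
  expect_identical(self$call, "0")
  # table is deterministic given identical input
  kin3 <- estimate_kinship(sim$geno, sim$panel, metadata = sim$metadata,
                           min_overlap = 2000)
  expect_identical(kin$pairs, kin3$pairs)
})

test_that("kinship methods print, summarise and export", {
  sim <- shared_sim()
  kin <- estimate_kinship(sim$geno, sim$panel, min_overlap = 2000)
  expect_output(print(kin), "Background mismatch rate")
  expect_output(print(summary(kin)), "Related pairs")
  expect_identical(as.data.frame(kin), kin$pairs)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_kinship(kin, f)
  re <- utils::read.table(f, header = TRUE, sep = "\t")
  expect_equal(nrow(re), nrow(kin$pairs))
  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(kin))
})
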