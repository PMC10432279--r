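#' Genetic sex from chromosome read counts
#'
#' Determines genetic sex from the number of reads mapping to the Y
#' chromosome relative to the autosomes, each normalised per target base.
#' The normalised Y rate is
#' \deqn{r_Y = \frac{reads_Y / size_Y}{reads_{aut} / size_{aut}}}
#' with autosomal reads and target sizes pooled. A sample with
#' \eqn{r_Y < 0.05} is called XX, \eqn{r_Y > 0.4} XY, and anything in
#' between is flagged INDETERMINATE.
#'
#' @param profile data.frame with columns `chrom` (labels "1".."22", "X",
#'   "Y"), `reads` (mapped read counts) and `target_bp` (target sizes in
#'   base pairs)
#' @param female_max,male_min Y-rate thresholds for the XX and XY calls
#' @return list with `sex` (XX/XY/INDETERMINATE), `r_y` and, when X counts
#'   are present, `r_x`
#' @export
determine_sex <- function(profile, female_max = 0.05, male_min = 0.4) {
  need <- c("chrom", "reads", "target_bp")
  if (!all(need %in% names(profile)))
    stop_pmrkin("read-count profile needs columns %s", paste(need, collapse = ", "))
  if (any(profile$reads < 0) || any(profile$target_bp <= 0))
    stop_pmrkin("read counts must be >= 0 and target sizes > 0")
  aut <- profile$chrom %in% as.character(1:22)
  if (!any(aut) || sum(profile$reads[aut]) == 0)
    stop_pmrkin("zero autosomal coverage: sex cannot be determined")
  aut_rate <- sum(profile$reads[aut]) / sum(profile$target_bp[aut])
  rate_of <- function(ch) {
    i <- which(profile$chrom == ch)
    if (length(i) == 0) return(NA_real_)
    (profile$reads[i] / profile$target_bp[i]) / aut_rate
  }
  r_y <- rate_of("Y")
  if (is.na(r_y)) stop_pmrkin("no Y-chromosome row in read-count profile")
  sex <- if (r_y < female_max) "XX" else if (r_y > male_min) "XY" else "INDETERMINATE"
  list(sex = sex, r_y = r_y, r_x = rate_of("X"))
}

#' Coverage quality filter
#'
#' Excludes individuals covered at fewer than `min_sites` SNPs (strictly
#' below the threshold; an individual with exactly `min_sites` non-missing
#' calls is retained).
#'
#' @param geno pseudo-haploid call matrix (individuals x sites, NA missing)
#' @param min_sites minimum number of non-missing calls (default 20000)
#' @return list with `retained` (ids passing), `excluded` (ids failing) and
#'   `n_sites` (named vector of non-missing call counts for all individuals)
#' @export
filter_low_coverage <- function(geno, min_sites = 20000) {
  if (nrow(geno) == 0) stop_pmrkin("empty genotype matrix")
  n_sites <- rowSums(!is.na(geno))
  keep <- n_sites >= min_sites
  list(retained = rownames(geno)[keep],
       excluded = rownames(geno)[!keep],
       n_sites = n_sites)
}
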