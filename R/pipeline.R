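#' Run the full analysis pipeline
#'
#' Orchestrates the stages end to end: simulate (or load) a dataset,
#' apply the coverage filter, estimate pairwise kinship, assemble
#' pedigrees, and compute the demographic and spatial statistics. All
#' randomness derives from the single `seed`; each stage gets its own
#' sub-seed so stages can be rerun alone. Outputs are written to
#' `out_dir` together with a manifest (input hashes, seed, package
#' version).
#'
#' @param config list (or path to a JSON file) with entries:
#'   `simulate` (logical; if TRUE a community is simulated with
#'   `sim` parameters passed to [sim_config()]), `prefix` (EIGENSTRAT
#'   prefix when `simulate` is FALSE), `metadata` (TSV path, idem),
#'   `min_sites` (coverage filter), `min_overlap`, `window_cm`, `n_perm`
#' @param out_dir output directory
#' @param seed integer master seed
#' @return invisibly, a list with the kinship fit, pedigree set,
#'   demography results and the manifest
#' @export
run_pipeline <- function(config = list(), out_dir = "pmrkin_out", seed = 1) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  known <- c("simulate", "sim", "prefix", "metadata", "min_sites",
             "min_overlap", "window_cm", "n_perm")
  unknown <- setdiff(names(config), known)
  if (length(unknown)) stop_pmrkin("unknown config keys: %s",
                                   paste(unknown, collapse = ", "))
  simulate <- config$simulate %||% TRUE
  min_sites <- config$min_sites %||% 20000
  min_overlap <- config$min_overlap %||% 5000
  window_cm <- config$window_cm %||% 20
  n_perm <- config$n_perm %||% 999
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage_seed <- function(k) (seed * 1000L + k) %% .Machine$integer.max

  inputs <- character(0)
  if (simulate) {
    message("stage simulate: generating synthetic community")
    cfg <- do.call(sim_config, config$sim %||% list())
    sim <- simulate_community(cfg, seed = stage_seed(1L))
    write_simulation(sim, out_dir, prefix = "sim")
    panel <- sim$panel; geno <- sim$geno; md <- sim$metadata
  } else {
    if (is.null(config$prefix)) stop_pmrkin("stage load: config$prefix missing")
    for (ext in c(".geno", ".snp", ".ind"))
      if (!file.exists(paste0(config$prefix, ext)))
        stop_pmrkin("stage load: file not found: %s%s", config$prefix, ext)
    es <- read_eigenstrat(config$prefix)
    panel <- es$panel; geno <- es$geno
    md <- read_metadata(config$metadata)
    inputs <- c(paste0(config$prefix, c(".geno", ".snp", ".ind")), config$metadata)
    sim <- NULL
  }

  message("stage qc: coverage filter")
  qc <- filter_low_coverage(geno, min_sites = min_sites)
  geno <- geno[qc$retained, , drop = FALSE]

  message("stage kinship: pairwise estimation")
  set.seed(stage_seed(2L))
  kin <- estimate_kinship(geno, panel, metadata = md,
                          min_overlap = min_overlap, window_cm = window_cm)
  write_kinship(kin, file.path(out_dir, "relatedness.tsv"))

  message("stage pedigree: assembly")
  units <- seed_nuclear_units(kin, md)
  peds <- expand_pedigrees(units, kin, md)
  for (i in seq_along(peds$graphs))
    export_pedigree(peds$graphs[[i]], file.path(out_dir, sprintf("pedigree_%02d", i)),
                    family = sprintf("FAM%02d", i))

  message("stage demography: statistics")
  set.seed(stage_seed(3L))
  demo <- list()
  adult <- md[!is.na(md$age_class) & md$age_class == "ADULT" &
              md$sex %in% c("XX", "XY"), , drop = FALSE]
  if (nrow(adult) > 0)
    demo$adult_sex_ci <- proportion_ci(sum(adult$sex == "XY"), nrow(adult))
  demo$haplogroups <- haplogroup_summary(md, peds)
  if (all(c("grave_x", "grave_y") %in% names(md)) &&
      any(!is.na(md$grave_x))) {
    have <- md$id[!is.na(md$grave_x) & md$id %in% rownames(geno)]
    if (length(have) >= 4) {
      coord <- md[match(have, md$id), c("id", "grave_x", "grave_y")]
      sp <- as.matrix(stats::dist(coord[, c("grave_x", "grave_y")]))
      dimnames(sp) <- list(have, have)
      gd <- norm_pmr_dist(kin, have)
      demo$mantel <- mantel_test(sp, gd, n_perm = n_perm)
    }
  }
  jsonlite::write_json(
    list(adult_sex_ci = demo$adult_sex_ci %||% NULL,
         n_mt = demo$haplogroups$n_mt, n_y = demo$haplogroups$n_y,
         mantel = if (!is.null(demo$mantel))
           list(r = demo$mantel$r, p = demo$mantel$p_value) else NULL),
    file.path(out_dir, "demography.json"), auto_unbox = TRUE, digits = NA,
    force = TRUE)

  manifest <- list(seed = seed,
                   package_version = as.character(utils::packageVersion("pmrkin")),
                   inputs = as.list(tools::md5sum(inputs)),
                   parameters = list(min_sites = min_sites,
                                     min_overlap = min_overlap,
                                     window_cm = window_cm, n_perm = n_perm))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(kinship = kin, pedigrees = peds, demography = demo,
                 manifest = manifest, sim = sim))
}

#' Normalised-PMR distance matrix for a set of individuals
#'
#' Genetic distance for spatial comparisons: the pairwise normalised PMR
#' as a symmetric matrix with zero diagonal.
#'
#' @param kin a [estimate_kinship()] result
#' @param ids individuals (must appear in the kinship table)
#' @return symmetric numeric matrix
#' @export
norm_pmr_dist <- function(kin, ids) {
  p <- kin$pairs
  m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  key <- pair_key(p$id1, p$id2)
  for (a in seq_along(ids)) for (b in seq_len(a - 1L)) {
    r <- match(pair_key(ids[a], ids[b]), key)
    if (is.na(r)) stop_pmrkin("pair %s-%s not in kinship table", ids[a], ids[b])
    m[a, b] <- m[b, a] <- p$norm_pmr[r]
  }
  m
}
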