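# shared fixtures, built in code at load time

# small single-chromosome panel with evenly spread sites
tiny_panel <- function(n = 100, morgans = 0.9, chrom = "1") {
  pos <- seq(1000L, by = 1000L, length.out = n)
  snp_panel(rep(chrom, n), pos,
            gpos = seq(0, morgans, length.out = n),
            ref = rep("A", n), alt = rep("G", n))
}

# hand-built three-generation pedigree used by orientation / kinship tests:
# founder couple P1 x P2 -> children C1 (son), C2 (daughter, stays);
# C1 x M1 (in-migrant) -> G1 (son), G2 (daughter)
toy_pedigree <- function() {
  ped <- data.frame(
    id = c("P1", "P2", "C1", "C2", "M1", "G1", "G2"),
    sex = c("XY", "XX", "XY", "XX", "XX", "XY", "XX"),
    generation = c(1L, 1L, 2L, 2L, 2L, 3L, 3L),
    father = c(NA, NA, "P1", "P1", NA, "C1", "C1"),
    mother = c(NA, NA, "P2", "P2", NA, "M1", "M1"),
    sampled = TRUE,
    age_class = c("ADULT", "ADULT", "ADULT", "ADULT", "ADULT", "SUBADULT", "ADULT"),
    mt_hg = c("MT01", "MT02", "MT02", "MT02", "MT03", "MT03", "MT03"),
    y_hg = c("Y01", NA, "Y01", NA, NA, "Y01", NA),
    birth_order = 1L,
    stringsAsFactors = FALSE)
  class(ped) <- c("true_pedigree", "data.frame")
  ped
}

# moderate community shared across kinship/pedigree/pipeline tests
shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_generations = 4, n_snps = 30000)
      s <- 1
      repeat {
        set.seed(s)
        ped <- generate_pedigree(cfg)
        if (sum(ped$sampled) >= 14 && sum(ped$sampled) <= 25) break
        s <- s + 1
      }
      cache <<- simulate_community(cfg, seed = s)
    }
    cache
  }
})
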