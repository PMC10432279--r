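#' Simulation configuration
#'
#' Parameters of the synthetic burial-community generator. The defaults
#' describe a patrilocal, patrilineal community with female exogamy:
#' sons stay and reproduce on site, daughters out-migrate with high
#' probability, and every union's mother is an unrelated in-migrating
#' founder carrying a fresh mitochondrial lineage. Genotypes are dropped
#' through the pedigree with Haldane (no-interference) recombination and
#' observed as low-coverage pseudo-haploid calls.
#'
#' @param n_generations number of generations G (founders are generation 1)
#' @param mean_offspring Poisson mean number of children per union
#' @param p_daughter_migrates probability an adult daughter out-migrates
#'   (and is therefore not buried/sampled on site)
#' @param p_subadult_death probability a child dies before adulthood
#'   (buried as SUBADULT, never reproduces)
#' @param endogamy_prob probability a union's mother is taken from resident
#'   adult women instead of a new unrelated in-migrant
#' @param n_founder_couples founder couples in generation 1
#' @param n_snps total SNPs across the genome
#' @param n_chrom number of autosomes
#' @param morgans_per_chrom genetic length of each chromosome (Morgans)
#' @param bp_per_chrom physical length of each chromosome (bp)
#' @param founder_beta shape parameters (a, b) of the Beta law for founder
#'   ALT allele frequencies
#' @param freq_bounds truncation interval for allele frequencies
#' @param coverage Poisson mean per-site read coverage; `Inf` means every
#'   site is covered
#' @param error_rate per-read probability that the sampled allele is
#'   flipped to the other allele
#' @param sigma_within within-lineage-cluster Gaussian scatter of grave
#'   coordinates (metres)
#' @param cluster_spacing distance between lineage cluster centres (metres)
#' @param father_son_shrink factor in [0,1) by which a subadult son's grave
#'   is pulled towards his father's (0 = buried at the father's spot)
#' @param max_retries pedigree regeneration attempts before declaring
#'   extinction
#' @return a list of class `sim_config`
#' @export
sim_config <- function(n_generations = 4,
                       mean_offspring = 3,
                       p_daughter_migrates = 0.8,
                       p_subadult_death = 0.2,
                       endogamy_prob = 0,
                       n_founder_couples = 1,
                       n_snps = 50000,
                       n_chrom = 22,
                       morgans_per_chrom = 1.5,
                       bp_per_chrom = 1e8,
                       founder_beta = c(0.5, 0.5),
                       freq_bounds = c(0.05, 0.95),
                       coverage = 1.0,
                       error_rate = 0.01,
                       sigma_within = 3,
                       cluster_spacing = 15,
                       father_son_shrink = 0.3,
                       max_retries = 20) {
  cfg <- as.list(environment())
  probs <- c(cfg$p_daughter_migrates, cfg$p_subadult_death, cfg$endogamy_prob,
             cfg$error_rate)
  if (any(probs < 0 | probs > 1)) stop_pmrkin("sim_config: probabilities must be in [0,1]")
  if (cfg$n_generations < 1) stop_pmrkin("sim_config: n_generations must be >= 1")
  if (cfg$mean_offspring <= 0) stop_pmrkin("sim_config: mean_offspring must be > 0")
  if (cfg$morgans_per_chrom <= 0) stop_pmrkin("sim_config: genetic length must be > 0")
  class(cfg) <- "sim_config"
  cfg
}

#' Simulated SNP panel
#'
#' Draws a panel of biallelic sites spread over equal-length autosomes,
#' with physical positions uniform on each chromosome and genetic
#' positions proportional to physical position (a linear genetic map).
#'
#' @param config a [sim_config()]
#' @return a [snp_panel()]
#' @export
sim_panel <- function(config = sim_config()) {
  per_chrom <- diff(round(seq(0, config$n_snps, length.out = config$n_chrom + 1)))
  chrom <- rep(as.character(seq_len(config$n_chrom)), per_chrom)
  pos <- unlist(lapply(per_chrom, function(m)
    sort(sample.int(config$bp_per_chrom, m))), use.names = FALSE)
  gpos <- (pos / config$bp_per_chrom) * config$morgans_per_chrom
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, length(pos), replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
  snp_panel(chrom, pos, gpos, ref, unname(alt))
}

new_node <- function(id, sex, generation, father, mother, sampled, age_class,
                     mt_hg, y_hg, birth_order) {
  data.frame(id = id, sex = sex, generation = generation,
             father = father, mother = mother, sampled = sampled,
             age_class = age_class, mt_hg = mt_hg, y_hg = y_hg,
             birth_order = birth_order, stringsAsFactors = FALSE)
}

#' Generate a ground-truth pedigree
#'
#' Forward simulation of a patrilineal community: generation-1 founder
#' couple(s); every resident adult male forms one union whose mother is a
#' newly created unrelated in-migrant (fresh mitochondrial label) unless
#' the endogamy probability fires and a resident unpartnered adult woman
#' exists; offspring counts are Poisson; daughters who reach adulthood
#' out-migrate (unsampled) with the configured probability, sons remain.
#' Mitochondrial labels follow the maternal line, Y labels the paternal
#' line. If no member of the final generation exists the pedigree went
#' extinct and generation is retried up to `max_retries` times.
#'
#' @param config a [sim_config()]
#' @return a `data.frame` of class `true_pedigree`: one row per node with
#'   id, sex, generation, father, mother, sampled, age_class, mt_hg, y_hg,
#'   birth_order
#' @export
generate_pedigree <- function(config = sim_config()) {
  for (attempt in seq_len(config$max_retries)) {
    ped <- generate_pedigree_once(config)
    if (max(ped$generation) == config$n_generations) {
      class(ped) <- c("true_pedigree", "data.frame")
      return(ped)
    }
  }
  stop_pmrkin("pedigree extinct before generation %d in %d attempts",
              config$n_generations, config$max_retries)
}

generate_pedigree_once <- function(config) {
  nodes <- list()
  counters <- c(id = 0L, mt = 0L, y = 0L)
  next_id <- function() { counters["id"] <<- counters["id"] + 1L
                          sprintf("I%03d", counters["id"]) }
  next_mt <- function() { counters["mt"] <<- counters["mt"] + 1L
                          sprintf("MT%02d", counters["mt"]) }
  next_y  <- function() { counters["y"] <<- counters["y"] + 1L
                          sprintf("Y%02d", counters["y"]) }

  for (k in seq_len(config$n_founder_couples)) {
    nodes[[length(nodes) + 1L]] <- new_node(next_id(), "XY", 1L, NA, NA, TRUE,
                                            "ADULT", next_mt(), next_y(), k)
    nodes[[length(nodes) + 1L]] <- new_node(next_id(), "XX", 1L, NA, NA, TRUE,
                                            "ADULT", next_mt(), NA, k)
  }
  ped <- do.call(rbind, nodes)
  partnered <- character(0)  # women already in a union

  for (g in seq_len(config$n_generations - 1L)) {
    fathers <- ped$id[ped$sex == "XY" & ped$generation == g &
                      ped$age_class == "ADULT" & ped$sampled]
    if (g == 1L) {
      mothers <- ped$id[ped$sex == "XX" & ped$generation == 1L]
      mothers <- mothers[seq_along(fathers)]
      partnered <- c(partnered, mothers)
    } else {
      mothers <- character(length(fathers))
      for (i in seq_along(fathers)) {
        resident <- ped$id[ped$sex == "XX" & ped$age_class == "ADULT" &
                           ped$sampled & !ped$id %in% partnered &
                           ped$generation < g + 1L]
        if (length(resident) > 0 && stats::runif(1) < config$endogamy_prob) {
          mothers[i] <- sort(resident)[1]
        } else {
          m <- new_node(next_id(), "XX", g, NA, NA, TRUE, "ADULT",
                        next_mt(), NA, 0L)
          ped <- rbind(ped, m)
          mothers[i] <- m$id
        }
        partnered <- c(partnered, mothers[i])
      }
    }
    for (i in seq_along(fathers)) {
      n_off <- stats::rpois(1, config$mean_offspring)
      if (n_off == 0) next
      mt <- ped$mt_hg[ped$id == mothers[i]]
      y  <- ped$y_hg[ped$id == fathers[i]]
      for (b in seq_len(n_off)) {
        sex <- if (stats::runif(1) < 0.5) "XY" else "XX"
        died_young <- stats::runif(1) < config$p_subadult_death
        age <- if (died_young) "SUBADULT" else "ADULT"
        sampled <- TRUE
        if (!died_young && sex == "XX" &&
            stats::runif(1) < config$p_daughter_migrates) sampled <- FALSE
        ped <- rbind(ped, new_node(next_id(), sex, g + 1L, fathers[i],
                                   mothers[i], sampled, age, mt,
                                   if (sex == "XY") y else NA, b))
      }
    }
  }
  rownames(ped) <- NULL
  ped
}

#' Pairwise kinship coefficients over a pedigree
#'
#' Standard recursive kinship computed in generation order: founders are
#' mutually unrelated and non-inbred; for a non-founder a and any earlier
#' node b, phi(a,b) = (phi(father(a),b) + phi(mother(a),b)) / 2, and
#' phi(a,a) = (1 + phi(father(a), mother(a))) / 2.
#'
#' @param ped a pedigree data.frame with columns id, father, mother,
#'   generation
#' @return symmetric matrix of kinship coefficients, ids as dimnames
#' @export
kinship_matrix <- function(ped) {
  n <- nrow(ped)
  K <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  idx <- stats::setNames(seq_len(n), ped$id)
  ord <- order(ped$generation, ped$id)
  seen <- integer(0)
  for (a in ord) {
    f <- ped$father[a]; m <- ped$mother[a]
    if (is.na(f)) {
      K[a, a] <- 0.5
    } else {
      fi <- idx[[f]]; mi <- idx[[m]]
      if (length(seen))
        K[a, seen] <- K[seen, a] <- 0.5 * (K[fi, seen] + K[mi, seen])
      K[a, a] <- 0.5 * (1 + K[fi, mi])
    }
    seen <- c(seen, a)
  }
  K
}

is_ancestor <- function(ped, anc, node) {
  idx <- stats::setNames(seq_len(nrow(ped)), ped$id)
  stack <- node
  while (length(stack)) {
    cur <- stack[[1]]; stack <- stack[-1]
    parents <- c(ped$father[idx[[cur]]], ped$mother[idx[[cur]]])
    parents <- parents[!is.na(parents)]
    if (anc %in% parents) return(TRUE)
    stack <- c(stack, parents)
  }
  FALSE
}

phi_to_degree <- function(phi) {
  if (phi <= 0) return("UNRELATED")
  as.character(round(-log2(2 * phi)))
}

#' True relatedness degree of a pair
#'
#' Degree class derived from the pedigree kinship coefficient phi:
#' phi = 1/2 is degree 0 (same individual / identical twin), 1/4 first
#' degree, 1/8 second, 1/16 third and so on; phi = 0 is UNRELATED. The
#' lineal flag is true iff one member is an ancestor of the other
#' (parent, grandparent, ...), false for collateral kin of the same
#' degree (siblings, avuncular, cousins).
#'
#' @param ped a `true_pedigree`
#' @param i,j node ids
#' @return list with `degree` (character: "0","1",... or "UNRELATED"),
#'   `phi`, and `lineal`
#' @export
true_degree <- function(ped, i, j) {
  if (!all(c(i, j) %in% ped$id)) stop_pmrkin("unknown node id")
  K <- kinship_matrix(ped)
  phi <- if (i == j) 0.5 else K[i, j]
  list(degree = phi_to_degree(phi), phi = phi,
       lineal = i != j && (is_ancestor(ped, i, j) || is_ancestor(ped, j, i)))
}

#' True degrees for all sampled pairs
#' @param ped a `true_pedigree`
#' @param ids ids to tabulate (default: all sampled nodes)
#' @return data.frame id1, id2 (lexicographic), phi, degree, lineal
#' @export
true_degree_table <- function(ped, ids = ped$id[ped$sampled]) {
  K <- kinship_matrix(ped)
  ids <- sort(ids)
  pairs <- utils::combn(ids, 2)
  idx <- stats::setNames(seq_len(nrow(ped)), ped$id)
  anc <- ancestor_sets(ped)
  lineal <- mapply(function(a, b) (a %in% anc[[b]]) || (b %in% anc[[a]]),
                   pairs[1, ], pairs[2, ])
  phi <- K[cbind(pairs[1, ], pairs[2, ])]
  data.frame(id1 = pairs[1, ], id2 = pairs[2, ], phi = phi,
             degree = vapply(phi, phi_to_degree, ""),
             lineal = lineal, stringsAsFactors = FALSE)
}

# id -> character vector of all ancestors
ancestor_sets <- function(ped) {
  idx <- stats::setNames(seq_len(nrow(ped)), ped$id)
  out <- stats::setNames(vector("list", nrow(ped)), ped$id)
  for (a in order(ped$generation, ped$id)) {
    parents <- c(ped$father[a], ped$mother[a])
    parents <- parents[!is.na(parents)]
    out[[ped$id[a]]] <- unique(c(parents, unlist(out[parents])))
  }
  out
}

# truncated-Beta allele frequencies for founder haplotypes
draw_founder_freqs <- function(n, shape, bounds) {
  lo <- stats::pbeta(bounds[1], shape[1], shape[2])
  hi <- stats::pbeta(bounds[2], shape[1], shape[2])
  stats::qbeta(stats::runif(n, lo, hi), shape[1], shape[2])
}

# one meiosis: Haldane model. Crossovers per chromosome ~ Poisson(L),
# breakpoints uniform on the genetic map, no interference.
meiosis <- function(haps, labs, chrom_sites, gpos, morgans) {
  S <- ncol(haps)
  gam <- integer(S); glab <- integer(S)
  for (sites in chrom_sites) {
    nc <- stats::rpois(1, morgans)
    start <- sample.int(2L, 1L)
    if (nc == 0L) {
      h <- rep.int(start, length(sites))
    } else {
      breaks <- sort(stats::runif(nc, 0, morgans))
      h <- (start - 1L + findInterval(gpos[sites], breaks)) %% 2L + 1L
    }
    pick <- cbind(h, sites)
    gam[sites] <- haps[pick]
    glab[sites] <- labs[pick]
  }
  list(hap = gam, lab = glab)
}

#' Drop genes through a pedigree
#'
#' Forward gene-dropping: founder haplotypes are drawn site-wise
#' Bernoulli(ALT frequency) with frequencies from the configured
#' truncated Beta law; each child receives one recombined gamete per
#' parent under the Haldane model (Poisson crossover count per
#' chromosome, breakpoints uniform on the genetic map, no interference).
#' Alongside the alleles, each haplotype carries founder-haplotype
#' ancestry labels, which are the exact IBD ground truth for any pair.
#'
#' @param ped a `true_pedigree`
#' @param panel a [snp_panel()]
#' @param config a [sim_config()]
#' @param freqs optional pre-drawn founder ALT frequencies (one per site);
#'   drawn from the configured law when NULL
#' @param ids nodes to simulate (default: sampled nodes and all their
#'   ancestors, which covers every transmission path)
#' @return list of class `gene_drop` with `haps` (per id: 2 x n_sites
#'   0/1 matrix), `anc` (same shape, integer founder-haplotype labels)
#'   and `freqs` (founder ALT frequencies)
#' @export
drop_genes <- function(ped, panel, config = sim_config(), ids = NULL,
                       freqs = NULL) {
  if (is.null(panel$gpos)) stop_pmrkin("panel has no genetic positions")
  if (is.null(ids)) {
    anc <- ancestor_sets(ped)
    keep <- ped$sampled
    ids <- unique(c(ped$id[keep], unlist(anc[ped$id[keep]])))
  }
  # every ancestor of a simulated node must be simulated too
  need <- unique(c(ids, unlist(ancestor_sets(ped)[ids])))
  sub <- ped[ped$id %in% need, , drop = FALSE]
  sub <- sub[order(sub$generation, sub$id), , drop = FALSE]

  S <- nrow(panel)
  chrom_sites <- split(seq_len(S), panel$chrom)
  if (is.null(freqs))
    freqs <- draw_founder_freqs(S, config$founder_beta, config$freq_bounds)
  haps <- list(); labs <- list()
  next_lab <- 0L
  for (r in seq_len(nrow(sub))) {
    id <- sub$id[r]
    if (is.na(sub$father[r])) {
      h <- rbind(stats::rbinom(S, 1L, freqs), stats::rbinom(S, 1L, freqs))
      l <- rbind(rep.int(next_lab + 1L, S), rep.int(next_lab + 2L, S))
      next_lab <- next_lab + 2L
    } else {
      gf <- meiosis(haps[[sub$father[r]]], labs[[sub$father[r]]],
                    chrom_sites, panel$gpos, config$morgans_per_chrom)
      gm <- meiosis(haps[[sub$mother[r]]], labs[[sub$mother[r]]],
                    chrom_sites, panel$gpos, config$morgans_per_chrom)
      h <- rbind(gf$hap, gm$hap)
      l <- rbind(gf$lab, gm$lab)
    }
    haps[[id]] <- h; labs[[id]] <- l
  }
  structure(list(haps = haps[ids], anc = labs[ids], freqs = freqs),
            class = "gene_drop")
}

#' Pseudo-haploid sampling of simulated diploids
#'
#' Observes each diploid genome as low-coverage pseudo-haploid data: the
#' per-site read count is Poisson(coverage); zero reads give a missing
#' call, otherwise one of the two chromosome copies is chosen uniformly
#' and its allele is flipped with the per-read error probability.
#'
#' @param drop a [drop_genes()] result
#' @param config a [sim_config()]
#' @param ids individuals to observe (default: all in `drop`)
#' @return pseudo-haploid call matrix (individuals x sites; 0/1/NA)
#' @export
sample_pseudohaploid <- function(drop, config = sim_config(), ids = names(drop$haps)) {
  S <- ncol(drop$haps[[1]])
  geno <- matrix(NA_integer_, length(ids), S, dimnames = list(ids, NULL))
  for (id in ids) {
    covered <- if (is.infinite(config$coverage)) rep(TRUE, S)
               else stats::rpois(S, config$coverage) > 0L
    copy <- sample.int(2L, S, replace = TRUE)
    call <- drop$haps[[id]][cbind(copy, seq_len(S))]
    if (config$error_rate > 0) {
      flip <- stats::rbinom(S, 1L, config$error_rate) == 1L
      call[flip] <- 1L - call[flip]
    }
    call[!covered] <- NA_integer_
    geno[id, ] <- call
  }
  geno
}

# patriline cluster key: walk the paternal line up to the generation-2
# ancestor (clusters split at the sons of the founders); a gen-2 daughter
# joins her father's cluster, an in-migrant mother her partner's.
patriline_cluster <- function(ped) {
  idx <- stats::setNames(seq_len(nrow(ped)), ped$id)
  root <- function(r) {
    while (!is.na(ped$father[r]) && ped$generation[r] > 2L)
      r <- idx[[ped$father[r]]]
    if (ped$generation[r] == 2L && ped$sex[r] == "XX" && !is.na(ped$father[r]))
      r <- idx[[ped$father[r]]]
    ped$id[r]
  }
  cl <- character(nrow(ped))
  for (r in seq_len(nrow(ped))) {
    if (!is.na(ped$father[r])) {
      cl[r] <- root(r)
    } else if (ped$sex[r] == "XX") {
      kids <- which(!is.na(ped$mother) & ped$mother == ped$id[r])
      cl[r] <- if (length(kids)) root(idx[[ped$father[kids[1]]]]) else ped$id[r]
    } else {
      cl[r] <- ped$id[r]  # founder father: his own line
    }
  }
  stats::setNames(cl, ped$id)
}

#' Grave coordinates for sampled individuals
#'
#' Each patriline cluster (the descendants of one generation-2 male line,
#' plus its in-migrating mothers) gets a centre on a grid with the
#' configured spacing; members scatter around it with isotropic Gaussian
#' noise. Subadult sons with a sampled father are then pulled towards the
#' father's grave by the proximity shrink factor.
#'
#' @param ped a `true_pedigree`
#' @param config a [sim_config()]
#' @return data.frame id, grave_x, grave_y (metres) for sampled nodes
#' @export
place_graves <- function(ped, config = sim_config()) {
  samp <- ped[ped$sampled, , drop = FALSE]
  if (nrow(samp) == 0) stop_pmrkin("pedigree has no sampled nodes")
  cl <- patriline_cluster(ped)[samp$id]
  clusters <- sort(unique(cl))
  ncols <- ceiling(sqrt(length(clusters)))
  centre <- data.frame(
    cluster = clusters,
    cx = ((seq_along(clusters) - 1L) %% ncols) * config$cluster_spacing,
    cy = ((seq_along(clusters) - 1L) %/% ncols) * config$cluster_spacing)
  m <- match(cl, centre$cluster)
  x <- centre$cx[m] + stats::rnorm(nrow(samp), 0, config$sigma_within)
  y <- centre$cy[m] + stats::rnorm(nrow(samp), 0, config$sigma_within)
  names(x) <- names(y) <- samp$id
  for (r in seq_len(nrow(samp))) {
    f <- samp$father[r]
    if (samp$age_class[r] == "SUBADULT" && samp$sex[r] == "XY" &&
        !is.na(f) && f %in% samp$id) {
      x[r] <- x[f] + config$father_son_shrink * (x[r] - x[f])
      y[r] <- y[f] + config$father_son_shrink * (y[r] - y[f])
    }
  }
  data.frame(id = samp$id, grave_x = unname(x), grave_y = unname(y),
             stringsAsFactors = FALSE)
}

#' Simulate a complete burial community
#'
#' End-to-end generator: pedigree, SNP panel, gene dropping, pseudo-haploid
#' observation of the sampled (buried) individuals, grave coordinates and
#' a metadata table, together with the true pairwise degrees.
#'
#' @param config a [sim_config()]
#' @param seed optional integer seed for full reproducibility
#' @return list of class `pmr_sim`: `config`, `pedigree`, `panel`, `drop`,
#'   `geno` (sampled individuals only), `metadata`, `truth`
#' @export
simulate_community <- function(config = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ped <- generate_pedigree(config)
  panel <- sim_panel(config)
  drop <- drop_genes(ped, panel, config)
  samp_ids <- ped$id[ped$sampled]
  geno <- sample_pseudohaploid(drop, config, ids = intersect(names(drop$haps), samp_ids))
  graves <- place_graves(ped, config)
  samp <- ped[ped$sampled, , drop = FALSE]
  md <- data.frame(id = samp$id, sex = samp$sex, age_class = samp$age_class,
                   age_min = ifelse(samp$age_class == "SUBADULT", 0, 20),
                   age_max = ifelse(samp$age_class == "SUBADULT", 15, 60),
                   mt_hg = samp$mt_hg, y_hg = samp$y_hg,
                   stringsAsFactors = FALSE)
  md <- merge(md, graves, by = "id", sort = TRUE)
  structure(list(config = config, pedigree = ped, panel = panel, drop = drop,
                 geno = geno, metadata = md,
                 truth = true_degree_table(ped)),
            class = "pmr_sim")
}

#' Write a simulated community to disk
#'
#' Writes the EIGENSTRAT trio, the metadata TSV, the true-degree table,
#' per-haplotype founder-ancestry segments (BED-like: chrom, start, end,
#' founder haplotype label) and the configuration as JSON.
#'
#' @param sim a [simulate_community()] result
#' @param dir output directory (created if needed)
#' @param prefix file name prefix
#' @return invisibly, the output directory
#' @export
write_simulation <- function(sim, dir, prefix = "sim") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- file.path(dir, prefix)
  sex <- sim$pedigree$sex[match(rownames(sim$geno), sim$pedigree$id)]
  write_eigenstrat(sim$panel, sim$geno, p, sex = sex)
  write_metadata(sim$metadata, paste0(p, "_meta.tsv"))
  utils::write.table(sim$truth, paste0(p, "_truth.tsv"), quote = FALSE,
                     sep = "\t", row.names = FALSE)
  seg <- ancestry_segments(sim$drop, sim$panel)
  utils::write.table(seg, paste0(p, "_ancestry.tsv"), quote = FALSE,
                     sep = "\t", row.names = FALSE)
  cfg <- unclass(sim$config)
  jsonlite::write_json(cfg, paste0(p, "_config.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

# collapse per-site founder-ancestry labels to segments
ancestry_segments <- function(drop, panel) {
  out <- list()
  for (id in names(drop$anc)) {
    for (h in 1:2) {
      lab <- drop$anc[[id]][h, ]
      for (ch in unique(panel$chrom)) {
        sites <- which(panel$chrom == ch)
        r <- rle(lab[sites])
        ends <- cumsum(r$lengths)
        starts <- c(1L, utils::head(ends, -1) + 1L)
        out[[length(out) + 1L]] <- data.frame(
          id = id, hap = h, chrom = ch,
          start_bp = panel$pos[sites[starts]],
          end_bp = panel$pos[sites[ends]],
          founder_hap = r$values, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

#' Simulate a single first-degree pair
#'
#' Generates one parent-offspring or full-sibling duo, or two unrelated
#' individuals, observed as pseudo-haploid data: a founder couple is
#' drawn, children are produced by gene dropping, and the requested duo
#' is sampled. Useful for calibration studies at large site counts
#' without holding a whole community in memory.
#'
#' @param type "po" (father and child), "sib" (two full siblings),
#'   "gp" (grandfather and grandchild, a second-degree pair),
#'   "unrelated" (two founders) or "self" (two independent
#'   pseudo-haploid observations of one founder genome)
#' @param panel a [snp_panel()]
#' @param config a [sim_config()]
#' @param freqs optional pre-drawn founder ALT frequencies
#' @return list: `geno` (2 x sites call matrix, rownames "A"/"B"),
#'   `drop` (the underlying [drop_genes()] object)
#' @export
simulate_pair <- function(type = c("po", "sib", "gp", "unrelated", "self"),
                          panel, config = sim_config(), freqs = NULL) {
  type <- match.arg(type)
  founders <- rbind(
    new_node("F1", "XY", 1L, NA, NA, TRUE, "ADULT", "MT01", "Y01", 1L),
    new_node("F2", "XX", 1L, NA, NA, TRUE, "ADULT", "MT02", NA, 1L))
  child <- new_node("C1", "XY", 2L, "F1", "F2", TRUE, "ADULT", "MT02", "Y01", 1L)
  ped <- switch(type,
    self = ,
    unrelated = founders,
    po = rbind(founders, child),
    sib = rbind(founders, child,
                new_node("C2", "XX", 2L, "F1", "F2", TRUE, "ADULT", "MT02", NA, 2L)),
    gp = rbind(founders, child,
               new_node("F3", "XX", 2L, NA, NA, TRUE, "ADULT", "MT03", NA, 1L),
               new_node("G1", "XY", 3L, "C1", "F3", TRUE, "ADULT", "MT03", "Y01", 1L)))
  class(ped) <- c("true_pedigree", "data.frame")
  drop <- drop_genes(ped, panel, config, ids = ped$id, freqs = freqs)
  duo <- switch(type, po = c("F1", "C1"), sib = c("C1", "C2"),
                gp = c("F1", "G1"), unrelated = c("F1", "F2"),
                self = c("F1", "F1"))
  geno <- rbind(sample_pseudohaploid(drop, config, ids = duo[1]),
                sample_pseudohaploid(drop, config, ids = duo[2]))
  rownames(geno) <- c("A", "B")
  list(geno = geno, drop = drop)
}

#' IBD state per site for a simulated pair
#'
#' Exact identity-by-descent state (0, 1 or 2 shared founder haplotypes)
#' at every site, from the gene-dropping ancestry labels.
#'
#' @param drop a [drop_genes()] result
#' @param i,j individual ids
#' @return integer vector of per-site IBD states
#' @export
ibd_states <- function(drop, i, j) {
  a <- drop$anc[[i]]; b <- drop$anc[[j]]
  if (is.null(a) || is.null(b)) stop_pmrkin("unknown id in gene drop")
  m11 <- a[1, ] == b[1, ]; m12 <- a[1, ] == b[2, ]
  m21 <- a[2, ] == b[1, ]; m22 <- a[2, ] == b[2, ]
  ibd2 <- (m11 & m22) | (m12 & m21)
  as.integer(ibd2) + as.integer(!ibd2 & (m11 | m12 | m21 | m22)) * 1L +
    as.integer(ibd2)
}
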