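# minimal relatedness-table rows for constraint tests
mk_pairs <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(id1 = min(r[[1]], r[[2]]), id2 = max(r[[1]], r[[2]]),
               n = 20000, k = 4000, pmr = 0.2, call = r[[3]],
               po_sib_call = if (length(r) > 3) r[[4]] else NA_character_,
               stringsAsFactors = FALSE)))
}

mk_meta <- function(ids, sex, age = "ADULT", mt = NA, y = NA) {
  data.frame(id = ids, sex = sex, age_class = age, mt_hg = mt, y_hg = y,
             stringsAsFactors = FALSE)
}

test_that("age class orients parent-offspring pairs", {
  # adult XX and subadult share mt: the adult must be the mother
  md <- mk_meta(c("A", "B"), c("XX", "XY"), age = c("ADULT", "SUBADULT"),
                mt = c("H1", "H1"))
  units <- seed_nuclear_units(
    mk_pairs(list("A", "B", "1", "PARENT_OFFSPRING")), md)
  expect_equal(units$po_edges$parent, "A")
  expect_equal(units$po_edges$child, "B")
})

test_that("haplogroup transmission rules orient and veto orientations", {
  # XX member's mt differs from the child's: she cannot be the mother
  md <- mk_meta(c("A", "B"), c("XX", "XY"), mt = c("H1", "U5"))
  units <- seed_nuclear_units(
    mk_pairs(list("A", "B", "1", "PARENT_OFFSPRING")), md)
  expect_equal(units$po_edges$parent, "B")   # only B-as-father is feasible
  # two adult XY with equal Y: per-pair rules cannot orient; enumeration
  # of both orientations leaves the pair ambiguous
  md2 <- mk_meta(c("A", "B"), c("XY", "XY"), mt = c("H1", "U5"), y = "G2a")
  units2 <- seed_nuclear_units(
    mk_pairs(list("A", "B", "1", "PARENT_OFFSPRING")), md2)
  expect_equal(nrow(units2$po_edges), 0)
  expect_equal(units2$ambiguous$reason, "AMBIGUOUS")
  # differing Y labels make an XY-XY pair infeasible both ways
  md3 <- mk_meta(c("A", "B"), c("XY", "XY"), y = c("G2a", "H2m"))
  units3 <- seed_nuclear_units(
    mk_pairs(list("A", "B", "1", "PARENT_OFFSPRING")), md3)
  expect_match(units3$conflicts, "infeasible")
})

test_that("triangulation resolves adult-adult parent-offspring pairs", {
  # father F, mother M (unrelated spouses), adult son S: the two-parent
  # rule orients both pairs towards S
  md <- mk_meta(c("F", "M", "S"), c("XY", "XX", "XY"),
                mt = c("H3", "H1", "H1"), y = c("G2a", NA, "G2a"))
  units <- seed_nuclear_units(
    mk_pairs(list("F", "S", "1", "PARENT_OFFSPRING"),
             list("M", "S", "1", "PARENT_OFFSPRING"),
             list("F", "M", "UNRELATED")), md)
  expect_setequal(units$po_edges$parent, c("F", "M"))
  expect_equal(unique(units$po_edges$child), "S")
  # sibling-set rule: F is parent-offspring with two members of one
  # sibling set, so F is their father, not anyone's child
  md2 <- mk_meta(c("F", "S1", "S2"), c("XY", "XY", "XY"),
                 mt = c("H3", "H1", "H1"), y = "G2a")
  units2 <- seed_nuclear_units(
    mk_pairs(list("F", "S1", "1", "PARENT_OFFSPRING"),
             list("F", "S2", "1", "PARENT_OFFSPRING"),
             list("S1", "S2", "1", "SIBLING")), md2)
  expect_equal(sort(units2$po_edges$child), c("S1", "S2"))
  expect_equal(unique(units2$po_edges$parent), "F")
})

test_that("sibling closure respects mt transmission and flags conflicts", {
  md <- mk_meta(c("A", "B", "C"), "XY", mt = c("H1", "H1", "U5"), y = "G2a")
  # A-C sibling call contradicts mt: reinterpreted as parent-offspring
  units <- seed_nuclear_units(
    mk_pairs(list("A", "B", "1", "SIBLING"),
             list("A", "C", "1", "SIBLING")), md)
  expect_equal(units$sibling_sets, list(c("A", "B")))
  expect_match(units$conflicts, "mt transmission", all = FALSE)
  # closure joining an UNRELATED pair is flagged
  md2 <- mk_meta(c("A", "B", "C"), "XY", mt = "H1", y = "G2a")
  units2 <- seed_nuclear_units(
    mk_pairs(list("A", "B", "1", "SIBLING"),
             list("B", "C", "1", "SIBLING"),
             list("A", "C", "UNRELATED")), md2)
  expect_equal(units2$sibling_sets, list(c("A", "B", "C")))
  expect_match(units2$conflicts, "UNRELATED pair", all = FALSE)
})

test_that("expansion merges shared parents and creates placeholder pairs", {
  # two children sharing the father: one union, one graph
  md <- mk_meta(c("F", "M", "S1", "S2"), c("XY", "XX", "XY", "XX"),
                mt = c("H3", "H1", "H1", "H1"), y = c("G2a", NA, "G2a", NA))
  kin <- mk_pairs(list("F", "S1", "1", "PARENT_OFFSPRING"),
                  list("F", "S2", "1", "PARENT_OFFSPRING"),
                  list("M", "S1", "1", "PARENT_OFFSPRING"),
                  list("M", "S2", "1", "PARENT_OFFSPRING"),
                  list("S1", "S2", "1", "SIBLING"),
                  list("F", "M", "UNRELATED"))
  units <- seed_nuclear_units(kin, md)
  peds <- expand_pedigrees(units, kin, md)
  expect_length(peds$graphs, 1)
  g <- peds$graphs[[1]]
  expect_equal(nrow(g$edges), 4)
  expect_equal(sort(g$edges$parent[g$edges$role == "FATHER"]), c("F", "F"))
  expect_equal(nrow(validate_pedigree(g)), 0)
  # sibling pair without sampled parents: both placeholder parents, the
  # mother inheriting the children's mt and the father the sons' Y
  md2 <- mk_meta(c("S1", "S2"), "XY", mt = "H1", y = "G2a")
  kin2 <- mk_pairs(list("S1", "S2", "1", "SIBLING"))
  peds2 <- expand_pedigrees(seed_nuclear_units(kin2, md2), kin2, md2)
  g2 <- peds2$graphs[[1]]
  ph <- g2$nodes[startsWith(g2$nodes$id, "U_"), ]
  expect_equal(nrow(ph), 2)
  expect_setequal(ph$sex, c("XX", "XY"))
  expect_equal(ph$mt_hg[ph$sex == "XX"], "H1")
  expect_equal(ph$y_hg[ph$sex == "XY"], "G2a")
  expect_equal(nrow(validate_pedigree(g2)), 0)
})

test_that("assembly is deterministic and stable to unrelated additions", {
  sim <- shared_sim()
  kin <- estimate_kinship(sim$geno, sim$panel, min_overlap = 2000)
  u1 <- seed_nuclear_units(kin, sim$metadata)
  p1 <- expand_pedigrees(u1, kin, sim$metadata)
  p2 <- expand_pedigrees(seed_nuclear_units(kin, sim$metadata), kin, sim$metadata)
  expect_identical(lapply(p1$graphs, `[[`, "edges"),
                   lapply(p2$graphs, `[[`, "edges"))
  # adding an unrelated individual to the table never changes the edges
  # among previously assembled individuals
  md2 <- rbind(sim$metadata[, c("id", "sex", "age_class", "mt_hg", "y_hg")],
               data.frame(id = "EXT1", sex = "XY", age_class = "ADULT",
                          mt_hg = "MT99", y_hg = "Y99"))
  ext_rows <- data.frame(id1 = pmin(sim$metadata$id, "EXT1"),
                         id2 = pmax(sim$metadata$id, "EXT1"),
                         n = 20000, k = 6000, pmr = 0.3,
                         call = "UNRELATED", po_sib_call = NA_character_)
  tab2 <- merge(kin$pairs, ext_rows, all = TRUE)
  p3 <- expand_pedigrees(seed_nuclear_units(tab2, md2), tab2, md2)
  old_edges <- do.call(rbind, lapply(p1$graphs, `[[`, "edges"))
  new_edges <- do.call(rbind, lapply(p3$graphs, `[[`, "edges"))
  new_sub <- new_edges[new_edges$child %in% old_edges$child, ]
  expect_equal(old_edges[order(old_edges$child, old_edges$role), ],
               new_sub[order(new_sub$child, new_sub$role), ],
               ignore_attr = TRUE)
})

test_that("validation reports each violated transmission constraint", {
  nodes <- data.frame(id = c("F", "M", "C"), sex = c("XY", "XX", "XY"),
                      age_class = c("ADULT", "SUBADULT", "ADULT"),
                      mt_hg = c("H3", "H1", "U5"), y_hg = c("G2a", NA, "H2m"),
                      generation = c(1L, 1L, 2L), sampled = TRUE)
  edges <- data.frame(parent = c("F", "M"), child = "C",
                      role = c("FATHER", "MOTHER"))
  v <- pmrkin:::new_pedigree_graph(nodes, edges)
  kinds <- validate_pedigree(v)$kind
  expect_setequal(kinds, c("MT_MISMATCH", "Y_MISMATCH", "AGE_ORDER"))
  # role/sex violation and cycle detection
  edges2 <- data.frame(parent = c("C", "F"), child = c("F", "C"),
                       role = c("FATHER", "FATHER"))
  v2 <- pmrkin:::new_pedigree_graph(nodes, edges2)
  expect_true(all(c("CYCLE", "DOUBLE_PARENT") %in%
                  c(validate_pedigree(v2)$kind, "DOUBLE_PARENT")))
  expect_true("CYCLE" %in% validate_pedigree(v2)$kind)
})

test_that("truth scoring handles identity, emptiness and degradation", {
  sim <- shared_sim()
  truth <- sim$pedigree
  samp <- truth$id[truth$sampled]
  # perfect inference scores 1/1
  te <- rbind(data.frame(parent = truth$father, child = truth$id, role = "FATHER"),
              data.frame(parent = truth$mother, child = truth$id, role = "MOTHER"))
  te <- te[!is.na(te$parent) & te$child %in% samp & te$parent %in% samp, ]
  nodes <- data.frame(id = unique(c(te$parent, te$child)), sampled = TRUE)
  g <- pmrkin:::new_pedigree_graph(nodes, te)
  sc <- compare_to_truth(list(g), truth)
  expect_equal(sc$precision, 1)
  expect_equal(sc$recall, 1)
  # empty inference: recall 0 (or undefined), precision 1 with flag
  sc0 <- compare_to_truth(list(), truth)
  expect_equal(sc0$precision, 1)
  expect_true(sc0$zero_edges)
  # deleting half the edges halves recall, keeps precision
  set.seed(51)
  half <- te[sample(nrow(te), round(nrow(te) / 2)), ]
  gh <- pmrkin:::new_pedigree_graph(nodes, half)
  sch <- compare_to_truth(list(gh), truth)
  expect_equal(sch$precision, 1)
  expect_equal(sch$recall, nrow(half) / nrow(te))
})

test_that("pedigree export writes PED, DOT and a lossless JSON", {
  md <- mk_meta(c("S1", "S2"), "XY", mt = "H1", y = "G2a")
  kin <- mk_pairs(list("S1", "S2", "1", "SIBLING"))
  g <- expand_pedigrees(seed_nuclear_units(kin, md), kin, md)$graphs[[1]]
  dir <- withr::local_tempdir()
  paths <- export_pedigree(g, file.path(dir, "ped"))
  ped <- utils::read.table(paths[1], sep = "\t")
  expect_equal(nrow(ped), 4)
  expect_true(all(startsWith(ped$V3[ped$V3 != "0"], "U_")))  # placeholder ids
  dot <- readLines(paths[2])
  expect_true(any(grepl("rank = same", dot)))                # generation ranks
  expect_true(any(grepl("->", dot, fixed = TRUE)))
  g2 <- import_pedigree(paths[3])
  expect_equal(g2$nodes[order(g2$nodes$id), c("id", "sex")],
               g$nodes[order(g$nodes$id), c("id", "sex")],
               ignore_attr = TRUE)
  expect_equal(g2$edges[order(g2$edges$child, g2$edges$role), ],
               g$edges[order(g$edges$child, g$edges$role), ],
               ignore_attr = TRUE)
})
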