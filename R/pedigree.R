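#' @name pedigree_graph
#' @title Pedigree graph representation
#' @description A pedigree graph is a list with `nodes` (data.frame: id,
#' sampled, sex, age_class, mt_hg, y_hg, generation) and `edges`
#' (data.frame: parent, child, role MOTHER/FATHER). Placeholder nodes for
#' inferred unsampled parents carry ids prefixed `"U_"`. Invariants: at
#' most one MOTHER and one FATHER edge into any node, MOTHER endpoints
#' XX, FATHER endpoints XY, no cycles, and haplogroup transmission
#' (mitochondrial along MOTHER edges, Y along FATHER edges to XY
#' children) consistent whenever both labels are known.
NULL

new_pedigree_graph <- function(nodes, edges) {
  structure(list(nodes = nodes, edges = edges), class = "pedigree_graph")
}

#' @export
print.pedigree_graph <- function(x, ...) {
  ph <- startsWith(x$nodes$id, "U_")
  cat(sprintf("Pedigree graph: %d sampled + %d placeholder individuals, %d parent edges\n",
              sum(!ph), sum(ph), nrow(x$edges)))
  if (length(x$nodes$generation) && any(!is.na(x$nodes$generation)))
    cat(sprintf("Generations: %d\n", max(x$nodes$generation, na.rm = TRUE)))
  invisible(x)
}

# orientation feasibility of 'parent of child' under the transmission rules
po_orientation_ok <- function(parent, child, md) {
  p <- md[md$id == parent, ]; c <- md[md$id == child, ]
  if (nrow(p) == 0 || nrow(c) == 0) return(NA)
  if (!is.na(p$age_class) && p$age_class == "SUBADULT") return(FALSE)
  if (p$sex == "XX" && !is.na(p$mt_hg) && !is.na(c$mt_hg) &&
      p$mt_hg != c$mt_hg) return(FALSE)
  if (p$sex == "XY" && c$sex == "XY" && !is.na(p$y_hg) && !is.na(c$y_hg) &&
      p$y_hg != c$y_hg) return(FALSE)
  TRUE
}

#' Seed nuclear family units from a relatedness table
#'
#' Orients first-degree parent-offspring pairs and forms sibling sets.
#' Orientation uses, in order of authority, the haplogroup transmission
#' rules (an XX candidate whose mitochondrial label differs from the
#' other member's cannot be the mother; an XY-XY pair with differing Y
#' labels cannot be father and son) and age classes (a SUBADULT cannot
#' be a parent). A pair feasible in both directions is resolved by
#' triangulation against the rest of the table: (a) the two-parent rule
#' — if a third individual is also parent-offspring with one member and
#' UNRELATED to the other, the two outer individuals must be the
#' parents; (b) the sibling-set rule — an individual parent-offspring
#' with two or more members of one sibling set is their parent. Pairs
#' that remain unresolved are flagged AMBIGUOUS; pairs feasible in
#' neither direction are conflicts.
#'
#' Sibling sets are the transitive closure of SIBLING calls, after
#' excluding SIBLING pairs whose mitochondrial labels differ (full
#' siblings share a mother; such pairs are reinterpreted as
#' parent-offspring and logged). A closure that joins two members called
#' UNRELATED is flagged.
#'
#' @param kin a [estimate_kinship()] result (or its `pairs` data.frame)
#' @param metadata metadata data.frame (id, sex, age_class, mt_hg, y_hg)
#' @return list of class `nuclear_units`: `po_edges` (parent, child),
#'   `ambiguous` (id1, id2, reason), `sibling_sets` (list of id vectors),
#'   `conflicts` (character messages)
#' @export
seed_nuclear_units <- function(kin, metadata) {
  pairs <- if (inherits(kin, "kinship")) kin$pairs else kin
  md <- validate_metadata(metadata)
  deg1 <- pairs[pairs$call == "1", , drop = FALSE]
  po <- deg1[!is.na(deg1$po_sib_call) & deg1$po_sib_call == "PARENT_OFFSPRING", ,
             drop = FALSE]
  sib <- deg1[!is.na(deg1$po_sib_call) & deg1$po_sib_call == "SIBLING", ,
              drop = FALSE]
  conflicts <- character(0)

  # full siblings share the maternal line: a SIBLING call with differing
  # known mt labels must in fact be parent-offspring
  if (nrow(sib)) {
    mt1 <- md$mt_hg[match(sib$id1, md$id)]
    mt2 <- md$mt_hg[match(sib$id2, md$id)]
    bad <- !is.na(mt1) & !is.na(mt2) & mt1 != mt2
    if (any(bad)) {
      conflicts <- c(conflicts, sprintf(
        "SIBLING call %s-%s contradicts mt transmission; reinterpreted as parent-offspring",
        sib$id1[bad], sib$id2[bad]))
      po <- rbind(po, sib[bad, , drop = FALSE])
      sib <- sib[!bad, , drop = FALSE]
    }
  }

  # transitive closure of sibling calls by union-find
  all_sib_ids <- sort(unique(c(sib$id1, sib$id2)))
  uf <- stats::setNames(all_sib_ids, all_sib_ids)
  find <- function(x) { while (uf[[x]] != x) x <- uf[[x]]; x }
  for (r in order(sib$id1, sib$id2)) {
    a <- find(sib$id1[r]); b <- find(sib$id2[r])
    if (a != b) uf[[max(a, b)]] <- min(a, b)
  }
  sets <- if (length(all_sib_ids))
    unname(lapply(split(all_sib_ids, vapply(all_sib_ids, find, "")), sort))
  else list()

  unrel_key <- pair_key(pairs$id1[pairs$call == "UNRELATED"],
                        pairs$id2[pairs$call == "UNRELATED"])
  po_key <- pair_key(po$id1, po$id2)
  sib_set_of <- stats::setNames(rep(NA_integer_, length(all_sib_ids)), all_sib_ids)
  for (s in seq_along(sets)) sib_set_of[sets[[s]]] <- s

  # triangulation support for 'a is parent of b'
  parent_support <- function(a, b) {
    # two-parent rule: some x is PO with b and UNRELATED to a
    others <- c(po$id1[po$id2 == b], po$id2[po$id1 == b])
    others <- setdiff(others, a)
    if (any(pair_key(a, others) %in% unrel_key)) return(TRUE)
    # sibling-set rule: a is PO with >= 2 members of b's sibling set
    s <- sib_set_of[b]
    if (!is.na(s)) {
      n_po <- sum(pair_key(a, sets[[s]]) %in% po_key)
      if (n_po >= 2) return(TRUE)
    }
    FALSE
  }

  po_edges <- list(); ambiguous <- list()
  add_edge <- function(p, ch)
    po_edges[[length(po_edges) + 1L]] <<- data.frame(parent = p, child = ch,
                                                     stringsAsFactors = FALSE)
  for (r in order(po$id1, po$id2)) {
    i <- po$id1[r]; j <- po$id2[r]
    ij <- po_orientation_ok(i, j, md)   # i parent of j
    ji <- po_orientation_ok(j, i, md)
    if (is.na(ij) || is.na(ji)) {
      ambiguous[[length(ambiguous) + 1L]] <-
        data.frame(id1 = i, id2 = j, reason = "NO_METADATA")
    } else if (ij && !ji) {
      add_edge(i, j)
    } else if (ji && !ij) {
      add_edge(j, i)
    } else if (ij && ji) {
      si <- parent_support(i, j); sj <- parent_support(j, i)
      if (si && !sj) add_edge(i, j)
      else if (sj && !si) add_edge(j, i)
      else ambiguous[[length(ambiguous) + 1L]] <-
        data.frame(id1 = i, id2 = j, reason = "AMBIGUOUS")
    } else {
      conflicts <- c(conflicts,
                     sprintf("PO pair %s-%s infeasible in both orientations", i, j))
    }
  }

  # closure conflicts: members of one set called UNRELATED
  for (s in sets) {
    if (length(s) < 2) next
    cmb <- utils::combn(s, 2)
    bad <- pair_key(cmb[1, ], cmb[2, ]) %in% unrel_key
    if (any(bad))
      conflicts <- c(conflicts,
                     sprintf("sibling closure {%s} contains UNRELATED pair %s-%s",
                             paste(s, collapse = ","),
                             cmb[1, which(bad)[1]], cmb[2, which(bad)[1]]))
  }
  structure(list(
    po_edges = if (length(po_edges)) do.call(rbind, po_edges)
               else data.frame(parent = character(0), child = character(0)),
    ambiguous = if (length(ambiguous)) do.call(rbind, ambiguous)
                else data.frame(id1 = character(0), id2 = character(0),
                                reason = character(0)),
    sibling_sets = sets,
    conflicts = conflicts), class = "nuclear_units")
}

# graph degree between two ids from assembled edges (kinship through the
# edge set); returns "UNRELATED" when no connection
graph_degree <- function(nodes, edges, i, j) {
  ped <- data.frame(id = nodes$id,
                    father = NA_character_, mother = NA_character_,
                    stringsAsFactors = FALSE)
  for (r in seq_len(nrow(edges))) {
    col <- if (edges$role[r] == "FATHER") "father" else "mother"
    ped[[col]][ped$id == edges$child[r]] <- edges$parent[r]
  }
  ped$generation <- graph_generations(nodes, edges)[ped$id]
  K <- kinship_matrix(ped)
  phi_to_degree(K[i, j])
}

graph_generations <- function(nodes, edges) {
  gen <- stats::setNames(rep(1L, nrow(nodes)), nodes$id)
  # longest path from founders, iterated to fixpoint (graphs are small)
  for (it in seq_len(nrow(nodes) + 1L)) {
    changed <- FALSE
    for (r in seq_len(nrow(edges))) {
      g <- gen[[edges$parent[r]]] + 1L
      if (gen[[edges$child[r]]] < g) { gen[[edges$child[r]]] <- g; changed <- TRUE }
    }
    if (!changed) break
  }
  gen
}

#' Expand nuclear units into pedigrees
#'
#' Deterministic greedy assembly: sibling sets and oriented
#' parent-offspring edges are merged into graphs (processed in
#' lexicographic order); the identified XY parent of any sibling-set
#' member becomes FATHER of the whole set (likewise the XX parent as
#' MOTHER), vetoed if that parent is called UNRELATED to another member;
#' sibling sets and children with a missing parent receive placeholder
#' parents (ids prefixed `"U_"`), always completing the mother/father
#' pair. A placeholder mother inherits the children's shared
#' mitochondrial label and a placeholder father the XY children's Y
#' label. Second-degree calls act as cross-checks, not edges: an
#' assembled pair whose graph distance contradicts its called degree by
#' more than one degree is reported as a conflict.
#'
#' @param units a [seed_nuclear_units()] result
#' @param kin the [estimate_kinship()] result (or its pairs table)
#' @param metadata metadata data.frame
#' @return list of class `pedigree_set`: `graphs` (list of
#'   `pedigree_graph`, one per connected component with >= 2 members),
#'   `conflicts` (character), `unplaced` (ids in metadata not in any graph)
#' @export
expand_pedigrees <- function(units, kin, metadata) {
  pairs <- if (inherits(kin, "kinship")) kin$pairs else kin
  md <- validate_metadata(metadata)
  conflicts <- units$conflicts
  unrel_key <- pair_key(pairs$id1[pairs$call == "UNRELATED"],
                        pairs$id2[pairs$call == "UNRELATED"])

  # family units: sibling sets, plus singleton children of PO edges;
  # processed as a queue because an evicted member becomes a new unit
  fam <- units$sibling_sets
  in_set <- unlist(fam)
  for (ch in sort(setdiff(units$po_edges$child, in_set)))
    fam[[length(fam) + 1L]] <- ch
  fam <- fam[order(vapply(fam, `[`, "", 1))]

  nodes <- md[, intersect(c("id", "sex", "age_class", "mt_hg", "y_hg"), names(md))]
  nodes$sampled <- TRUE
  edges <- data.frame(parent = character(0), child = character(0),
                      role = character(0), stringsAsFactors = FALSE)
  placeholder_n <- 0L
  new_placeholder <- function(sex, mt = NA, y = NA) {
    placeholder_n <<- placeholder_n + 1L
    id <- sprintf("U_%03d", placeholder_n)
    nodes <<- rbind(nodes, data.frame(id = id, sex = sex, age_class = "ADULT",
                                      mt_hg = mt, y_hg = y, sampled = FALSE))
    id
  }

  while (length(fam)) {
    set <- fam[[1]]; fam <- fam[-1]
    # candidate parents: oriented PO parents of any member
    cand <- units$po_edges[units$po_edges$child %in% set, , drop = FALSE]
    # a member UNRELATED to a well-supported parent candidate (>= 2 PO
    # links into the set) cannot be a full sibling of the rest: evict it
    supp_tab <- table(cand$parent)
    for (p in names(supp_tab)[supp_tab >= 2]) {
      out <- set[pair_key(p, set) %in% unrel_key]
      if (length(out)) {
        conflicts <- c(conflicts, sprintf(
          "members {%s} evicted from sibling set {%s}: UNRELATED to parent %s",
          paste(out, collapse = ","), paste(set, collapse = ","), p))
        set <- setdiff(set, out)
        for (o in out) fam[[length(fam) + 1L]] <- o
        cand <- units$po_edges[units$po_edges$child %in% set, , drop = FALSE]
      }
    }
    if (length(set) == 0) next
    for (role_sex in c("FATHER", "MOTHER")) {
      sx <- if (role_sex == "FATHER") "XY" else "XX"
      cand_p <- sort(unique(cand$parent[md$sex[match(cand$parent, md$id)] == sx]))
      # veto parents called UNRELATED to any set member
      ok <- vapply(cand_p, function(p)
        !any(pair_key(p, set) %in% unrel_key), TRUE)
      cand_p <- cand_p[ok]
      if (length(cand_p) > 1) {
        support <- vapply(cand_p, function(p) sum(cand$parent == p), 0L)
        keep <- cand_p[order(-support, cand_p)][1]
        conflicts <- c(conflicts,
                       sprintf("multiple %s candidates {%s} for set {%s}; kept %s",
                               role_sex, paste(cand_p, collapse = ","),
                               paste(set, collapse = ","), keep))
        cand_p <- keep
      }
      if (length(cand_p) == 0) {
        mt <- if (role_sex == "MOTHER") {
          mts <- unique(stats::na.omit(md$mt_hg[match(set, md$id)]))
          if (length(mts) == 1) mts else NA
        } else NA
        y <- if (role_sex == "FATHER") {
          xy <- set[md$sex[match(set, md$id)] == "XY"]
          ys <- unique(stats::na.omit(md$y_hg[match(xy, md$id)]))
          if (length(ys) == 1) ys else NA
        } else NA
        cand_p <- new_placeholder(sx, mt = mt, y = y)
      }
      for (ch in set)
        edges <- rbind(edges, data.frame(parent = cand_p, child = ch,
                                         role = role_sex))
    }
  }
  edges <- unique(edges[order(edges$child, edges$role), , drop = FALSE])

  # split into connected components
  comp <- components_of(nodes$id, edges)
  graphs <- list()
  for (cids in comp) {
    if (length(cids) < 2) next
    cn <- nodes[nodes$id %in% cids, , drop = FALSE]
    ce <- edges[edges$child %in% cids, , drop = FALSE]
    cn$generation <- graph_generations(cn, ce)[cn$id]
    g <- new_pedigree_graph(cn[order(cn$generation, cn$id), ],
                            ce[order(ce$child, ce$role), ])
    graphs[[length(graphs) + 1L]] <- g
  }

  # degree cross-checks (1st and 2nd degree calls vs graph distance)
  for (g in graphs) {
    called <- pairs[pairs$call %in% c("1", "2") &
                    pairs$id1 %in% g$nodes$id & pairs$id2 %in% g$nodes$id, ,
                    drop = FALSE]
    for (r in seq_len(nrow(called))) {
      gd <- graph_degree(g$nodes, g$edges, called$id1[r], called$id2[r])
      cd <- called$call[r]
      if (gd != "UNRELATED" &&
          abs(as.numeric(gd) - as.numeric(cd)) > 1)
        conflicts <- c(conflicts,
                       sprintf("pair %s-%s called degree %s but assembled at degree %s",
                               called$id1[r], called$id2[r], cd, gd))
    }
  }

  placed <- unique(unlist(lapply(graphs, function(g) g$nodes$id)))
  structure(list(graphs = graphs, conflicts = conflicts,
                 unplaced = sort(setdiff(md$id, placed))),
            class = "pedigree_set")
}

components_of <- function(ids, edges) {
  uf <- stats::setNames(ids, ids)
  find <- function(x) { while (uf[[x]] != x) x <- uf[[x]]; x }
  link <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) uf[[max(ra, rb)]] <<- min(ra, rb)
  }
  for (r in seq_len(nrow(edges))) link(edges$parent[r], edges$child[r])
  roots <- vapply(ids, find, "")
  unname(lapply(split(ids, roots), sort))
}

#' Validate a pedigree graph
#'
#' Checks every structural and transmission invariant and returns one row
#' per violation: DOUBLE_PARENT (more than one mother or father),
#' SEX_ROLE (mother not XX / father not XY), CYCLE, MT_MISMATCH (child's
#' mitochondrial label differs from the mother's), Y_MISMATCH (XY child's
#' Y label differs from the father's), AGE_ORDER (subadult parent). An
#' empty result means the graph is consistent.
#'
#' @param graph a `pedigree_graph`
#' @return data.frame with columns kind, ids, message (zero rows if valid)
#' @export
validate_pedigree <- function(graph) {
  nodes <- graph$nodes; edges <- graph$edges
  v <- list()
  add <- function(kind, ids, msg)
    v[[length(v) + 1L]] <<- data.frame(kind = kind,
                                       ids = paste(ids, collapse = ","),
                                       message = msg, stringsAsFactors = FALSE)
  for (ch in unique(edges$child)) {
    for (role in c("MOTHER", "FATHER")) {
      p <- edges$parent[edges$child == ch & edges$role == role]
      if (length(p) > 1)
        add("DOUBLE_PARENT", c(ch, p),
            sprintf("%s has %d %s edges", ch, length(p), role))
    }
  }
  look <- function(id, col) {
    i <- match(id, nodes$id)
    if (is.na(i)) NA else nodes[[col]][i]
  }
  for (r in seq_len(nrow(edges))) {
    p <- edges$parent[r]; ch <- edges$child[r]; role <- edges$role[r]
    psex <- look(p, "sex")
    want <- if (role == "MOTHER") "XX" else "XY"
    if (!is.na(psex) && psex != want)
      add("SEX_ROLE", c(p, ch), sprintf("%s parent %s has sex %s", role, p, psex))
    if (identical(look(p, "age_class"), "SUBADULT"))
      add("AGE_ORDER", c(p, ch), sprintf("subadult %s is a parent of %s", p, ch))
    if (role == "MOTHER") {
      pm <- look(p, "mt_hg"); cm <- look(ch, "mt_hg")
      if (!is.na(pm) && !is.na(cm) && pm != cm)
        add("MT_MISMATCH", c(p, ch),
            sprintf("child %s mt %s != mother %s mt %s", ch, cm, p, pm))
    }
    if (role == "FATHER" && identical(look(ch, "sex"), "XY")) {
      py <- look(p, "y_hg"); cy <- look(ch, "y_hg")
      if (!is.na(py) && !is.na(cy) && py != cy)
        add("Y_MISMATCH", c(p, ch),
            sprintf("XY child %s Y %s != father %s Y %s", ch, cy, p, py))
    }
  }
  # cycle check: DFS over parent->child edges
  if (has_cycle(nodes$id, edges))
    add("CYCLE", character(0), "parent-child relation contains a cycle")
  if (length(v)) do.call(rbind, v)
  else data.frame(kind = character(0), ids = character(0),
                  message = character(0), stringsAsFactors = FALSE)
}

has_cycle <- function(ids, edges) {
  colour <- stats::setNames(rep(0L, length(ids)), ids)  # 0 new, 1 open, 2 done
  kids <- split(edges$child, edges$parent)
  visit <- function(x) {
    if (colour[[x]] == 1L) return(TRUE)
    if (colour[[x]] == 2L) return(FALSE)
    colour[[x]] <<- 1L
    for (k in kids[[x]] %||% character(0)) if (visit(k)) return(TRUE)
    colour[[x]] <<- 2L
    FALSE
  }
  any(vapply(ids, visit, TRUE))
}

#' Score inferred pedigrees against simulation truth
#'
#' Compares inferred parent edges with the true pedigree. Placeholder
#' parents are matched to unsampled true parents greedily by the overlap
#' of their child sets. Precision is the fraction of inferred edges that
#' exist in truth, recall the fraction of true parent edges (restricted
#' to sampled children whose parent is sampled or matched) that were
#' recovered. An empty inference has recall 0 and precision reported as
#' 1 with a zero-edge flag.
#'
#' @param inferred a `pedigree_set` (or list of `pedigree_graph`)
#' @param truth a `true_pedigree`
#' @return list: `precision`, `recall`, `n_inferred`, `n_truth`,
#'   `zero_edges`, `placeholder_map`
#' @export
compare_to_truth <- function(inferred, truth) {
  graphs <- if (inherits(inferred, "pedigree_set")) inferred$graphs else inferred
  edges <- do.call(rbind, c(lapply(graphs, function(g) g$edges),
                            list(data.frame(parent = character(0),
                                            child = character(0),
                                            role = character(0)))))
  samp <- truth$id[truth$sampled]
  if (!any(edges$child %in% truth$id) && nrow(edges) > 0)
    stop_pmrkin("inferred and true id spaces are disjoint")

  # true parent edges with sampled child
  te <- rbind(data.frame(parent = truth$father, child = truth$id, role = "FATHER"),
              data.frame(parent = truth$mother, child = truth$id, role = "MOTHER"))
  te <- te[!is.na(te$parent) & te$child %in% samp, , drop = FALSE]

  # match placeholders to unsampled true parents by child-set overlap
  ph <- unique(edges$parent[startsWith(edges$parent, "U_")])
  unsamp_parents <- unique(te$parent[!te$parent %in% samp])
  ph_children <- lapply(ph, function(p) edges$child[edges$parent == p])
  tru_children <- lapply(unsamp_parents, function(p) te$child[te$parent == p])
  names(ph_children) <- ph; names(tru_children) <- unsamp_parents
  map <- character(0)
  if (length(ph) && length(unsamp_parents)) {
    ov <- outer(ph, unsamp_parents, Vectorize(function(a, b)
      length(intersect(ph_children[[a]], tru_children[[b]]))))
    dimnames(ov) <- list(ph, unsamp_parents)
    while (any(ov > 0)) {
      best <- which(ov == max(ov), arr.ind = TRUE)[1, ]
      map[ph[best[1]]] <- unsamp_parents[best[2]]
      ov[best[1], ] <- -1; ov[, best[2]] <- -1
    }
  }
  mapped_parent <- ifelse(edges$parent %in% names(map),
                          map[edges$parent], edges$parent)
  inf_key <- paste(mapped_parent, edges$child)
  tru_key <- paste(te$parent, te$child)
  # recall denominator: true edges whose parent is sampled or matched
  te_scoreable <- te$parent %in% samp | te$parent %in% map
  tp <- sum(inf_key %in% tru_key)
  precision <- if (nrow(edges) == 0) 1 else tp / nrow(edges)
  recall <- if (sum(te_scoreable) == 0) NA_real_
            else sum(tru_key[te_scoreable] %in% inf_key) / sum(te_scoreable)
  list(precision = precision, recall = recall,
       n_inferred = nrow(edges), n_truth = sum(te_scoreable),
       zero_edges = nrow(edges) == 0, placeholder_map = map)
}

#' Export a pedigree graph
#'
#' Writes a PED/FAM-style table (family, id, father, mother, sex,
#' sampled; placeholder ids keep their `U_` prefix), a Graphviz DOT file
#' with one rank per generation, and a lossless JSON representation.
#'
#' @param graph a `pedigree_graph`
#' @param prefix output path prefix (writes `<prefix>.ped`, `.dot`, `.json`)
#' @param family family identifier for the PED file
#' @return invisibly, the three paths
#' @export
export_pedigree <- function(graph, prefix, family = "FAM1") {
  nodes <- graph$nodes; edges <- graph$edges
  father <- stats::setNames(rep("0", nrow(nodes)), nodes$id)
  mother <- father
  for (r in seq_len(nrow(edges))) {
    if (edges$role[r] == "FATHER") father[edges$child[r]] <- edges$parent[r]
    else mother[edges$child[r]] <- edges$parent[r]
  }
  ped <- data.frame(family = family, id = nodes$id,
                    father = unname(father[nodes$id]),
                    mother = unname(mother[nodes$id]),
                    sex = c(XY = 1, XX = 2, INDETERMINATE = 0)[nodes$sex],
                    sampled = as.integer(nodes$sampled))
  paths <- paste0(prefix, c(".ped", ".dot", ".json"))
  utils::write.table(ped, paths[1], quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)

  rank_lines <- vapply(sort(unique(nodes$generation)), function(g)
    sprintf("  { rank = same; %s }",
            paste(sprintf('"%s"', nodes$id[nodes$generation == g]),
                  collapse = "; ")), "")
  edge_lines <- sprintf('  "%s" -> "%s" [label="%s"];',
                        edges$parent, edges$child, substr(edges$role, 1, 1))
  node_lines <- sprintf('  "%s" [shape=%s, style=%s];', nodes$id,
                        ifelse(nodes$sex == "XY", "box",
                               ifelse(nodes$sex == "XX", "ellipse", "diamond")),
                        ifelse(nodes$sampled, "solid", "dashed"))
  writeLines(c("digraph pedigree {", node_lines, rank_lines, edge_lines, "}"),
             paths[2])
  jsonlite::write_json(list(nodes = nodes, edges = edges), paths[3],
                       auto_unbox = FALSE, digits = NA, na = "null")
  invisible(paths)
}

#' Re-import a pedigree graph written by [export_pedigree()]
#' @param path the `.json` path
#' @return a `pedigree_graph`
#' @export
import_pedigree <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_pedigree_graph(as.data.frame(x$nodes), as.data.frame(x$edges))
}
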