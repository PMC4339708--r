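test_that("binding rules classify the textbook basic regions", {
  # H5 + E9 + R12 + R13, five basic residues -> G-box
  g <- classify_binding(dom_from(row_with_basic("ARARHAAAEAARR")))
  expect_true(g$gbox_rule_raw)
  expect_equal(g$category, "G_BOX_BINDER")
  # all-A basic region -> non-binding HLH
  n <- classify_binding(dom_from(row_with_basic("AAAAAAAAAAAAA")))
  expect_equal(n$category, "NON_BINDING_HLH")
  expect_equal(n$basic_count, 0)
  # E9 + R12 without the G-box residues -> plain E-box binder
  e <- classify_binding(dom_from(row_with_basic("AAAAAAAAEAARA")))
  expect_equal(e$category, "E_BOX_BINDER")
  expect_false(e$gbox_rule_raw)
  # no E9 but 5 basic residues -> candidate non-E-box binder
  x <- classify_binding(dom_from(row_with_basic("RKRKRAAAAAAAA")))
  expect_equal(x$category, "NON_EBOX_BINDER")
  # E9 without R12, >= 5 basic: binder with ebox_rule FALSE
  y <- classify_binding(dom_from(row_with_basic("RKRKRAAAEAAAA")))
  expect_true(y$e9)
  expect_false(y$ebox_rule)
  expect_equal(y$category, "NON_EBOX_BINDER")
})

test_that("every domain gets exactly one category and the census nests", {
  set.seed(66)
  calls <- lapply(1:120, function(i) {
    classify_binding(dom_from(row_with_basic(rand_protein(13))))
  })
  cats <- vapply(calls, `[[`, "", "category")
  expect_true(all(cats %in% c("G_BOX_BINDER", "E_BOX_BINDER",
                              "NON_EBOX_BINDER", "NON_BINDING_HLH")))
  cen <- binding_census(calls)
  cnt <- setNames(cen$count, cen$statistic)
  expect_lte(cnt[["G_BOX_BINDER"]], cnt[["e9_r12"]])
  expect_lte(cnt[["e9_r12"]], cnt[["e9"]])
  expect_equal(sum(cnt[c("G_BOX_BINDER", "E_BOX_BINDER", "NON_EBOX_BINDER",
                         "NON_BINDING_HLH")]), 120)
  # permutation invariance
  cen2 <- binding_census(rev(calls))
  expect_equal(cen2, cen)
})

test_that("p-distances match a brute recount and Poisson correction applies", {
  m <- rbind(a = strsplit("AAAA", "")[[1]], b = strsplit("AAAV", "")[[1]])
  D <- pairwise_distances(m)
  expect_equal(unname(D["a", "b"]), 0.25)
  expect_equal(unname(diag(D)), c(0, 0))
  Dp <- pairwise_distances(m, model = "poisson")
  expect_equal(unname(Dp["a", "b"]), -log(1 - 0.25))
  set.seed(77)
  rows <- rbind(x = sample(c(AA_ALPHABET, "-"), 40, replace = TRUE),
                y = sample(c(AA_ALPHABET, "-"), 40, replace = TRUE))
  D2 <- pairwise_distances(rows)
  shared <- rows["x", ] != "-" & rows["y", ] != "-"
  expect_equal(unname(D2["x", "y"]),
               sum(rows["x", shared] != rows["y", shared]) / sum(shared))
  # zero shared columns is an error
  m0 <- rbind(p = c("A", "-"), q = c("-", "A"))
  expect_error(pairwise_distances(m0), "undefined-distance")
})

test_that("neighbor-joining reproduces closed forms and additive trees", {
  # 3 taxa: star with closed-form branch lengths
  d3 <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  t3 <- nj_tree(d3)
  bl <- setNames(t3$edge.length, t3$tip.label[t3$edge[, 2]])
  expect_equal(bl[["A"]], 1)
  expect_equal(bl[["B"]], 1)
  expect_equal(bl[["C"]], 3)
  expect_error(nj_tree(d3[1:2, 1:2]), "3 taxa")
  # the 4-taxon worked example: topology AB|CD, internal branch 1
  d4 <- matrix(c(0, 3, 5, 6, 3, 0, 6, 7, 5, 6, 0, 7, 6, 7, 7, 0), 4,
               dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  t4 <- nj_tree(d4)
  expect_equal(sort(t4$edge.length), c(1, 1, 2, 3, 4))
  # AB form a cherry
  pair <- t4$edge[t4$edge[, 1] == t4$edge[t4$edge[, 2] == which(t4$tip.label == "A"), 1], 2]
  expect_setequal(t4$tip.label[pair[pair <= 4]], c("A", "B"))
  # recovered distances are exactly additive
  expect_equal(unname(cophenetic(t4)[rownames(d4), colnames(d4)]), unname(d4))
  # property: NJ recovers random additive topologies (cross-checked with ape)
  for (s in 1:20) {
    set.seed(900 + s)
    nt <- sample(5:8, 1)
    rt <- ape::rtree(nt)
    rt$edge.length <- runif(nrow(rt$edge), 0.1, 1)
    D <- cophenetic(rt)
    D <- D[sort(rownames(D)), sort(rownames(D))]
    mine <- nj_tree(D)
    expect_equal(phangorn::RF.dist(ape::unroot(rt), mine), 0)
    expect_equal(phangorn::RF.dist(ape::nj(as.dist(D)), mine), 0)
  }
})

test_that("family assignment picks the nearest reference with margins and motifs", {
  refs_seq <- vapply(c("Ia", "X", "XV"), family_consensus, "")
  f <- tempfile(fileext = ".afa")
  writeLines(as.vector(rbind(paste0(">", names(refs_seq), "|ref_", names(refs_seq)),
                             refs_seq)), f)
  refs <- read_family_references(f)
  # exact match: distance 0, unambiguous
  a <- assign_family(dom_from(refs_seq[["X"]], "q1"), refs)
  expect_equal(a$family, "X")
  expect_equal(a$distance, 0)
  expect_false(a$ambiguous)
  # exactly equidistant between two families, no motifs: ambiguous,
  # tie broken to the lexicographically smaller family label
  cons <- bhlhscan:::CANONICAL_CONSENSUS
  refA <- cons
  refB <- paste0(substr(cons, 1, 19), "WW", substr(cons, 22, 55))
  query <- paste0(substr(cons, 1, 19), "W", substr(cons, 21, 55))  # 1 from each
  f2 <- tempfile(fileext = ".afa")
  writeLines(c(">FamA|rA", refA, ">FamB|rB", refB), f2)
  refs2 <- read_family_references(f2)
  b <- assign_family(dom_from(query, "q2"), refs2)
  expect_equal(b$family, "FamA")
  expect_equal(b$distance, 1 / 55)
  expect_equal(b$margin, 0)
  expect_true(b$ambiguous)
  # a diagnostic motif rescues the otherwise ambiguous call
  hits <- data.frame(motif = "Motif40", bit_score = 50, evalue = 1e-12,
                     env_start = 0, env_end = 29)
  cc <- assign_family(dom_from(query, "q2"), refs2, motif_hits = hits,
                      motif_family_map = c(Motif40 = "FamA"))
  expect_false(cc$ambiguous)
  expect_equal(cc$motif_support, "Motif40")
  # invariance to reference order
  refs_rev <- refs[3:1, ]
  attr(refs_rev, "residues") <- attr(refs, "residues")[3:1, ]
  a2 <- assign_family(dom_from(refs_seq[["X"]], "q1"), refs_rev)
  expect_equal(a2$family, a$family)
  expect_equal(a2$distance, a$distance)
  expect_error(assign_family(dmix, refs[0, ]), "no references")
})
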