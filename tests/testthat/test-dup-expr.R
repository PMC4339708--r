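test_that("homeolog grouping takes the transitive closure over qualifying pairs", {
  genes <- c("a", "b", "c", "d", "e")
  ev <- data.frame(gene_a = c("a", "b"), gene_b = c("b", "c"),
                   pident = c(95, 93), block_id = c("B1", "B1"))
  gr <- group_homeologs(genes, ev)
  sizes <- vapply(gr, `[[`, 0L, "copy_number")
  expect_equal(sort(sizes), c(1, 1, 3))
  expect_equal(gr[[1]]$members, c("a", "b", "c"))
  # identity boundary is inclusive >=
  ev2 <- data.frame(gene_a = c("a", "a"), gene_b = c("b", "c"),
                    pident = c(89.9, 90), block_id = "B1")
  gr2 <- group_homeologs(genes, ev2, min_identity = 90)
  expect_equal(sort(vapply(gr2, `[[`, 0L, "copy_number")), c(1, 1, 1, 2))
  # require_block drops pairs without a shared block
  ev3 <- data.frame(gene_a = "a", gene_b = "b", pident = 99, block_id = NA)
  expect_equal(max(vapply(group_homeologs(genes, ev3), `[[`, 0L, "copy_number")), 1)
  expect_equal(max(vapply(group_homeologs(genes, ev3, require_block = FALSE),
                          `[[`, 0L, "copy_number")), 2)
  expect_error(group_homeologs(genes[1:2], ev), "unknown genes")
  # empty evidence: all singletons
  expect_length(group_homeologs(genes, ev[0, ]), 5)
})

test_that("grouping is order-independent and always a partition", {
  set.seed(99)
  for (k in 1:15) {
    genes <- paste0("g", 1:12)
    n_ev <- sample(0:15, 1)
    ev <- data.frame(gene_a = sample(genes, n_ev, replace = TRUE),
                     gene_b = sample(genes, n_ev, replace = TRUE),
                     pident = runif(n_ev, 80, 100),
                     block_id = rep("B", n_ev))
    ev <- ev[ev$gene_a != ev$gene_b, , drop = FALSE]
    g1 <- group_homeologs(genes, ev)
    g2 <- group_homeologs(genes, ev[sample(nrow(ev)), , drop = FALSE])
    key <- function(g) sort(vapply(g, function(x) paste(x$members, collapse = ","), ""))
    expect_equal(key(g1), key(g2))
    expect_equal(sort(unlist(lapply(g1, `[[`, "members"))), sort(genes))
  }
})

test_that("copy-number histogram conserves genes and matches a recount", {
  genes <- paste0("g", 1:9)
  ev <- data.frame(gene_a = c("g1", "g3", "g4"), gene_b = c("g2", "g4", "g5"),
                   pident = 99, block_id = "B")
  gr <- group_homeologs(genes, ev)
  h <- copy_number_histogram(gr)
  expect_equal(attr(h, "total_genes"), 9)
  expect_equal(h$n_genes[h$copy_number == 1], 4)
  expect_equal(h$n_genes[h$copy_number == 2], 2)
  expect_equal(h$n_genes[h$copy_number == 3], 3)
  expect_equal(attr(h, "multi_copy_genes"), 5)
  expect_equal(sum(h$copy_number * h$n_groups), 9)
})

test_that("reciprocal best hits require mutuality and honor filters", {
  row12 <- function(q, s, pid, ev, bs)
    sprintf("%s\t%s\t%.1f\t100\t0\t0\t1\t100\t1\t100\t%g\t%.1f", q, s, pid, ev, bs)
  fa <- tempfile(); fb <- tempfile()
  writeLines(c(row12("x", "y", 80, 1e-50, 200),
               row12("x", "z", 60, 1e-20, 90),
               row12("w", "y", 55, 1e-30, 120)), fa)
  writeLines(c(row12("y", "x", 80, 1e-50, 200),
               row12("z", "x", 60, 1e-20, 90)), fb)
  ab <- read_similarity_table(fa); ba <- read_similarity_table(fb)
  rbh <- reciprocal_best_hits(ab, ba)
  expect_equal(rbh$a, "x")
  expect_equal(rbh$b, "y")
  # x->y best but y->z best: nothing
  writeLines(row12("y", "z", 90, 1e-60, 300), fb)
  rbh2 <- reciprocal_best_hits(ab, read_similarity_table(fb))
  expect_equal(nrow(rbh2), 0)
  # e-value filter at 1e-25 excludes a 1e-24 hit
  writeLines(row12("x", "y", 80, 1e-24, 200), fa)
  writeLines(row12("y", "x", 80, 1e-24, 200), fb)
  rbh3 <- reciprocal_best_hits(read_similarity_table(fa),
                               read_similarity_table(fb), max_evalue = 1e-25)
  expect_equal(nrow(rbh3), 0)
  # malformed row reports the line number
  writeLines(c(row12("x", "y", 80, 1e-50, 200), "x\ty\tnot12"), fa)
  expect_error(read_similarity_table(fa), "line 2")
})

test_that("RBH is symmetric under table swap", {
  row <- function(q, s, pid, ev, bs)
    data.frame(qseqid = q, sseqid = s, pident = pid, length = 100L,
               mismatch = 0L, gapopen = 0L, qstart = 1L, qend = 100L,
               sstart = 1L, send = 100L, evalue = ev, bitscore = bs)
  ab <- rbind(row("x", "y", 80, 1e-50, 200), row("u", "v", 70, 1e-40, 150),
              row("u", "y", 60, 1e-10, 50))
  ba <- rbind(row("y", "x", 80, 1e-50, 200), row("v", "u", 70, 1e-40, 150))
  r1 <- reciprocal_best_hits(ab, ba)
  r2 <- reciprocal_best_hits(ba, ab)
  expect_equal(sort(paste(r1$a, r1$b)), sort(paste(r2$b, r2$a)))
})

test_that("expression categories follow the precedence rules", {
  prof <- function(root = 0, nodule = 0, leaf = 0, seed_early = 0, seed_mid = 0,
                   seed_late = 0, pod_wall = 0)
    c(root = root, nodule = nodule, leaf = leaf, seed_early = seed_early,
      seed_mid = seed_mid, seed_late = seed_late, pod_wall = pod_wall)
  expect_equal(classify_expression(prof())$category, "NOT_EXPRESSED")
  expect_equal(classify_expression(prof(root = 10, nodule = 50))$category,
               "NODULE_PREFERENTIAL")
  # seed 60 vs max other 10 at fold 5: boundary inclusive (60 >= 50... use 50)
  expect_equal(classify_expression(prof(root = 10, leaf = 10, seed_mid = 50))$category,
               "SEED_ENRICHED")
  expect_equal(classify_expression(prof(root = 10, leaf = 10, seed_mid = 49.9))$category,
               "UBIQUITOUS")
  expect_equal(classify_expression(prof(pod_wall = 7))$category, "POD_WALL_ONLY")
  expect_equal(classify_expression(prof(root = 3))$category, "TISSUE_RESTRICTED")
  expect_equal(classify_expression(prof(root = 5, leaf = 5, seed_late = 2))$category,
               "UBIQUITOUS")
  expect_error(classify_expression(c(stem = 5)), "vocabulary error")
})

test_that("every profile gets exactly one category and detection is monotone", {
  set.seed(111)
  for (k in 1:60) {
    v <- round(runif(7, 0, 30) * rbinom(7, 1, 0.6), 3)
    names(v) <- c("root", "nodule", "leaf", "seed_early", "seed_mid",
                  "seed_late", "pod_wall")
    call1 <- classify_expression(v, detect_threshold = 1)
    expect_true(call1$category %in% c("NOT_EXPRESSED", "POD_WALL_ONLY",
                                      "NODULE_PREFERENTIAL", "SEED_ENRICHED",
                                      "UBIQUITOUS", "TISSUE_RESTRICTED"))
    call2 <- classify_expression(v, detect_threshold = 5)
    if (call1$category == "NOT_EXPRESSED") expect_false(call2$expressed)
  }
})

test_that("expression census conserves counts", {
  prof <- c(root = 5, nodule = 0, leaf = 5, seed_early = 0, seed_mid = 5,
            seed_late = 0, pod_wall = 0)
  calls <- list(classify_expression(prof, gene_id = "u1"),
                classify_expression(prof * 0, gene_id = "z1"),
                classify_expression(prof, gene_id = "u2"))
  cen <- expression_census(calls)
  expect_equal(sum(cen$count), 3)
  expect_equal(cen$count[cen$category == "UBIQUITOUS"], 2)
  expect_equal(cen$count[cen$category == "NOT_EXPRESSED"], 1)
  expect_equal(attr(cen, "expressed"), 2)
})
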