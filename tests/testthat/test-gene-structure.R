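# Minimal GFF3 writer for hand-traced fixtures (1-based inclusive, as the
# format specifies).
write_toy_gff <- function(rows, path = tempfile(fileext = ".gff3")) {
  writeLines(c("##gff-version 3", rows), path)
  path
}

test_that("GFF3 coordinates convert once to 0-based half-open", {
  p <- write_toy_gff(c(
    "chr1\ttoy\tgene\t101\t160\t.\t+\t.\tID=gA",
    "chr1\ttoy\tmRNA\t101\t160\t.\t+\t.\tID=gA.t1;Parent=gA",
    "chr1\ttoy\texon\t101\t130\t.\t+\t.\tParent=gA.t1",
    "chr1\ttoy\texon\t141\t160\t.\t+\t.\tParent=gA.t1",
    "chr1\ttoy\tCDS\t101\t130\t.\t+\t0\tParent=gA.t1",
    "chr1\ttoy\tCDS\t141\t160\t.\t+\t0\tParent=gA.t1"))
  gm <- read_gene_models(p)[["gA"]]
  expect_equal(gm$strand, "+")
  expect_equal(unname(gm$cds[, "start"]), c(100, 140))
  expect_equal(unname(gm$cds[, "end"]), c(130, 160))
  # minus-strand: transcription order is descending genomic order
  pm <- write_toy_gff(c(
    "chr1\ttoy\tgene\t101\t160\t.\t-\t.\tID=gB",
    "chr1\ttoy\tmRNA\t101\t160\t.\t-\t.\tID=gB.t1;Parent=gB",
    "chr1\ttoy\texon\t101\t130\t.\t-\t.\tParent=gB.t1",
    "chr1\ttoy\texon\t141\t160\t.\t-\t.\tParent=gB.t1",
    "chr1\ttoy\tCDS\t101\t130\t.\t-\t0\tParent=gB.t1",
    "chr1\ttoy\tCDS\t141\t160\t.\t-\t0\tParent=gB.t1"))
  gb <- read_gene_models(pm)[["gB"]]
  expect_equal(unname(gb$cds[, "start"]), c(140, 100))
})

# build a plus- or minus-strand two-exon gene whose protein is the canonical
# consensus with flanks, splitting after `aa_break` residues (phase 0)
toy_split_gene <- function(aa_break, strand = "+") {
  prot <- paste0("MMMMM", bhlhscan:::CANONICAL_CONSENSUS, "WWWW")
  ct <- bhlhscan:::.codon_table()
  cds <- paste(c(unname(ct$primary[strsplit(prot, "")[[1]]]), "TAA"), collapse = "")
  nt1 <- 3 * aa_break
  len <- nchar(cds)
  e1 <- nt1; e2 <- len - nt1; intron <- 90
  if (strand == "+") {
    c1 <- c(1001, 1000 + e1); c2 <- c(1001 + e1 + intron, 1000 + e1 + intron + e2)
  } else {
    tot <- e1 + intron + e2
    c1 <- c(1001 + tot - e1, 1000 + tot)          # first transcribed exon: high coords
    c2 <- c(1001, 1000 + e2)
  }
  rows <- c(
    sprintf("chr\ttoy\tgene\t%d\t%d\t.\t%s\t.\tID=gS", 1001, 1000 + e1 + intron + e2, strand),
    sprintf("chr\ttoy\tmRNA\t%d\t%d\t.\t%s\t.\tID=gS.t1;Parent=gS", 1001, 1000 + e1 + intron + e2, strand),
    sprintf("chr\ttoy\texon\t%d\t%d\t.\t%s\t.\tParent=gS.t1", min(c1), max(c1), strand),
    sprintf("chr\ttoy\texon\t%d\t%d\t.\t%s\t.\tParent=gS.t1", min(c2), max(c2), strand),
    sprintf("chr\ttoy\tCDS\t%d\t%d\t.\t%s\t0\tParent=gS.t1", min(c1), max(c1), strand),
    sprintf("chr\ttoy\tCDS\t%d\t%d\t.\t%s\t0\tParent=gS.t1", min(c2), max(c2), strand))
  list(gm = read_gene_models(write_toy_gff(rows))[["gS"]], prot = prot)
}

canon_hit_dom <- function(prot) {
  h <- build_profile(motif_alignment("canon", paste0("c", 1:3),
                                     rep(bhlhscan:::CANONICAL_CONSENSUS, 3)))
  hit <- viterbi_search(h, prot, target_id = "gS")
  list(hit = hit, dom = map_to_canonical(hit))
}

test_that("introns project to the canonical position of the 5' codon", {
  # split after 22 residues: 5 flank + canonical 1-17 -> splice sits between
  # canonical 17 and 18, phase 0
  tg <- toy_split_gene(22, "+")
  hd <- canon_hit_dom(tg$prot)
  pl <- project_introns(tg$gm, hd$hit, hd$dom)
  expect_equal(nrow(pl), 1)
  expect_equal(pl$domain_position, 17)
  expect_equal(pl$codon_phase, 0)
  # the mirror-image minus-strand gene projects identically
  tgm <- toy_split_gene(22, "-")
  plm <- project_introns(tgm$gm, hd$hit, hd$dom)
  expect_equal(plm, pl)
  # single-exon gene: no introns
  one <- toy_split_gene(22, "+")
  one$gm$cds <- matrix(c(0L, 195L), 1, dimnames = list(NULL, c("start", "end")))
  expect_equal(nrow(project_introns(one$gm, hd$hit, hd$dom)), 0)
  # CDS length not a multiple of 3 is a gene-model error
  bad <- one$gm
  bad$cds <- matrix(c(0L, 196L), 1, dimnames = list(NULL, c("start", "end")))
  expect_error(project_introns(bad, hd$hit, hd$dom), "gene-model error")
  # CDS/protein disagreement is a consistency error
  short <- one$gm
  short$cds <- matrix(c(0L, 99L), 1, dimnames = list(NULL, c("start", "end")))
  expect_error(project_introns(short, hd$hit, hd$dom), "consistency error")
})

test_that("projection round-trips generated placements on both strands", {
  b <- small_bundle()
  gms <- read_gene_models(b$gff)
  h <- build_profile(read_motif_alignment(b$training))
  scheme <- canonical_scheme(model_map = h$match_columns)
  man <- b$proteome$manifest
  clean <- man[man$fate == "clean", ]
  defs <- intron_pattern_def()
  n_checked <- 0
  for (i in seq_len(nrow(clean))) {
    g <- clean$gene_id[i]
    prot <- b$proteome$proteins[[g]]
    hit <- viterbi_search(h, prot, target_id = g)
    dom <- map_to_canonical(hit, scheme)
    pl <- project_introns(gms[[g]], hit, dom)
    truth <- bhlhscan:::.pattern_positions(clean$intron_pattern[i], defs)
    expect_equal(pl$domain_position, sort(unname(truth)))
    expect_true(all(pl$codon_phase == 0))
    n_checked <- n_checked + 1
  }
  expect_gte(n_checked, 20)
})

test_that("pattern classification follows the matched-canonical rules", {
  defs <- intron_pattern_def()
  pl <- function(pos) data.frame(intron_index = seq_along(pos),
                                 protein_pos = pos, domain_position = pos,
                                 codon_phase = rep(0L, length(pos)))
  cv <- defs$canonical
  expect_equal(classify_pattern(pl(unname(cv)), defs)$pattern, "A")
  expect_equal(classify_pattern(pl(integer()), defs)$pattern, "NONE")
  expect_equal(classify_pattern(pl(unname(cv[c("c1", "c3")])), defs)$pattern, "C")
  expect_equal(classify_pattern(pl(unname(cv[c("c1", "c2")])), defs)$pattern, "B")
  expect_equal(classify_pattern(pl(unname(cv[c("c2", "c3")])), defs)$pattern, "E")
  expect_equal(classify_pattern(pl(unname(cv["c2"])), defs)$pattern, "D")
  expect_equal(classify_pattern(pl(defs$alt_position), defs)$pattern, "F")
  expect_equal(classify_pattern(pl(defs$g_positions), defs)$pattern, "G")
  expect_equal(classify_pattern(pl(defs$g_positions[1]), defs)$pattern, "H")
  expect_equal(classify_pattern(pl(c(unname(cv), 47)), defs)$pattern, "OTHER")
  # classification depends only on the matched set: jitter within tolerance
  set.seed(88)
  for (k in 1:40) {
    subset <- sample(c("c1", "c2", "c3"), sample(1:3, 1))
    jit <- unname(cv[subset]) + sample(-defs$tolerance:defs$tolerance,
                                       length(subset), replace = TRUE)
    got <- classify_pattern(pl(sort(jit)), defs)
    expect_equal(got$matched_canonicals, sort(subset))
    expect_equal(got$pattern,
                 classify_pattern(pl(sort(unname(cv[subset]))), defs)$pattern)
  }
})

test_that("pattern census counts sum and percentages close to 100", {
  defs <- intron_pattern_def()
  pl <- function(pos) data.frame(intron_index = seq_along(pos),
                                 protein_pos = pos, domain_position = pos,
                                 codon_phase = rep(0L, length(pos)))
  calls <- c(
    lapply(1:99, function(i) classify_pattern(pl(unname(defs$canonical)), defs, paste0("a", i))),
    lapply(1:39, function(i) classify_pattern(pl(integer()), defs, paste0("n", i))),
    lapply(1:181, function(i) classify_pattern(pl(unname(defs$canonical["c1"])), defs, paste0("d", i)))
  )
  cen <- pattern_census(calls)
  expect_equal(sum(cen$count), 319)
  expect_equal(cen$count[cen$pattern == "A"], 99)
  expect_equal(cen$pct[cen$pattern == "A"], 31.0)
  expect_equal(cen$pct[cen$pattern == "NONE"], 12.2)
  expect_lt(abs(sum(cen$pct) - 100), 0.1 * nrow(cen))
  single <- pattern_census(calls[1])
  expect_equal(single$pct[single$pattern == "A"], 100)
})
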