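test_that("build_profile turns counts into Laplace probabilities", {
  # degenerate single-row alignment: modal residue per state
  h1 <- build_profile(motif_alignment("one", "s", "ACD"))
  expect_equal(h1$L, 3)
  expect_equal(AA_ALPHABET[apply(h1$match_emissions, 1, which.max)],
               c("A", "C", "D"))
  # hand-computed (count+1)/(n+20) for a column {A, A, C}
  h2 <- build_profile(motif_alignment("t", c("a", "b", "c"), c("A", "A", "C")))
  expect_equal(unname(h2$match_emissions[1, "A"]), 3 / 23)
  expect_equal(unname(h2$match_emissions[1, "C"]), 2 / 23)
  expect_equal(unname(h2$match_emissions[1, "D"]), 1 / 23)
})

test_that("gap-majority columns become insert states", {
  h <- build_profile(motif_alignment("g", paste0("r", 1:4),
                                     c("A-D", "A-D", "A-D", "ACD")),
                     match_threshold = 0.5)
  expect_equal(h$L, 2)
  expect_equal(h$match_columns, c(1L, 3L))
  expect_error(build_profile(motif_alignment("g", "a", "ACD"), match_threshold = 0),
               "match_threshold")
})

test_that("emissions and transitions normalize for fuzzed alignments", {
  set.seed(101)
  for (k in 1:25) {
    nc <- sample(3:10, 1); nr <- sample(2:8, 1)
    rows <- replicate(nr, paste(ifelse(runif(nc) < 0.2, "-",
                                       sample(AA_ALPHABET, nc, replace = TRUE)),
                                collapse = ""))
    h <- try(build_profile(motif_alignment("f", paste0("r", 1:nr), rows)),
             silent = TRUE)
    if (inherits(h, "try-error")) next  # all-gap threshold corner
    expect_equal(unname(rowSums(h$match_emissions)), rep(1, h$L), tolerance = 1e-9)
    expect_equal(unname(rowSums(h$insert_emissions)), rep(1, h$L), tolerance = 1e-9)
    expect_equal(unname(rowSums(h$transitions[, c("MM", "MI", "MD"), drop = FALSE])),
                 rep(1, h$L), tolerance = 1e-9)
    expect_equal(unname(rowSums(h$transitions[, c("IM", "II"), drop = FALSE])),
                 rep(1, h$L), tolerance = 1e-9)
    expect_equal(unname(rowSums(h$transitions[, c("DM", "DD"), drop = FALSE])),
                 rep(1, h$L), tolerance = 1e-9)
  }
})

test_that("local search finds a planted motif with the right coordinates", {
  h <- build_profile(motif_alignment("hlh", paste0("s", 1:5), rep("HLH", 5)))
  hit <- viterbi_search(h, "AAHLHAA", target_id = "q")
  expect_equal(hit$model_start, 1)
  expect_equal(hit$model_end, 3)
  expect_equal(hit$env_start, 2)  # 0-based half-open
  expect_equal(hit$env_end, 5)
  expect_gt(hit$bit_score, 0)
  expect_error(viterbi_search(h, "AAB*"), "alphabet error")
  # X scores as background: finite score, no error
  expect_s3_class(viterbi_search(h, "XXHLHXX"), "domain_hit")
})

test_that("Viterbi equals exhaustive path enumeration on small instances", {
  set.seed(202)
  for (k in 1:60) {
    h <- random_small_model(gap_prob = if (k %% 2) 0.25 else 0)
    prot <- rand_protein(sample(1:6, 1))
    expect_equal(viterbi_search(h, prot)$bit_score, brute_force_score(h, prot),
                 tolerance = 1e-9)
  }
})

test_that("training rows score positive and flank padding never lowers the score", {
  set.seed(303)
  rows <- replicate(4, rand_protein(12))
  rows <- c(rows, rows[1], rows[1])  # >= 3 identical rows
  h <- build_profile(motif_alignment("tr", paste0("r", seq_along(rows)), rows))
  s0 <- viterbi_search(h, rows[1])$bit_score
  expect_gt(s0, 0)
  padded <- paste0(rand_protein(30), rows[1], rand_protein(30))
  expect_gte(viterbi_search(h, padded)$bit_score, s0 - 1e-9)
})

test_that("Gumbel calibration is deterministic, monotone and self-consistent", {
  h <- build_profile(motif_alignment("hlh", paste0("s", 1:5), rep("HLHRRK", 5)))
  c1 <- calibrate_evalues(h, length = 60, n_shuffles = 120, seed = 7)
  c2 <- calibrate_evalues(h, length = 60, n_shuffles = 120, seed = 7)
  expect_identical(c1$mu, c2$mu)
  expect_identical(c1$lambda, c2$lambda)
  expect_gt(c1$lambda, 0)
  # strictly decreasing E-value in score
  e <- evalue_from_score(seq(0, 20, by = 0.5), c1)
  expect_true(all(diff(e) < 0))
  # E at the median shuffled score, scaled to the shuffle count, ~ n/2
  scores <- withr::with_seed(7L, vapply(seq_len(120), function(i)
    viterbi_search(h, rand_protein(60))$bit_score, 0))
  e_med <- evalue_from_score(stats::median(scores), c1, n_targets = 120)
  expect_lt(abs(e_med - 60) / 60, 0.2)
  expect_error(calibrate_evalues(h, n_shuffles = 50, seed = 1), "n_shuffles")
  # degenerate distribution: uniform emissions score every sequence 0
  h1 <- build_profile(motif_alignment("u", paste0("r", 1:20), AA_ALPHABET))
  expect_error(calibrate_evalues(h1, length = 5, n_shuffles = 100, seed = 1),
               "calibration error")
})

test_that("motif scanning reports the planted motif and nothing under the null", {
  m40 <- toupper("GLCLVPVScTqqVgseNGADYWAPayggg")
  vars <- withr::with_seed(11L, replicate(2, {
    cc <- strsplit(m40, "")[[1]]
    i <- sample(seq_along(cc), 1); cc[i] <- sample(setdiff(AA_ALPHABET, cc[i]), 1)
    paste(cc, collapse = "")
  }))
  h <- build_profile(motif_alignment("Motif40", paste0("m", 1:3), c(m40, vars)))
  cal <- calibrate_evalues(h, length = 400, n_shuffles = 150, seed = 13)
  prot <- withr::with_seed(17L, {
    bg <- rand_protein(300)
    paste0(substr(bg, 1, 150), m40, substr(bg, 151, 300))
  })
  hits <- scan_motifs(prot, list(h), list(Motif40 = cal))
  expect_equal(hits$motif, "Motif40")
  expect_lt(hits$evalue, 1e-7)
  ng <- regexpr("NGADYWAP", prot)[1]
  expect_lte(hits$env_start, ng - 1)   # envelope covers the conserved block
  expect_gte(hits$env_end, ng + 7)
  expect_equal(nrow(scan_motifs(prot, list())), 0)
  # null model: uniform-random proteins essentially never reach E < 1e-4
  fp <- sum(vapply(1:40, function(s) {
    p <- withr::with_seed(4000L + s, rand_protein(300))
    hh <- scan_motifs(p, list(h), list(Motif40 = cal))
    nrow(hh) > 0 && hh$evalue < 1e-4
  }, TRUE))
  expect_lte(fp, 2)
})

test_that("profile JSON serialization round-trips exactly", {
  set.seed(404)
  rows <- replicate(5, paste(ifelse(runif(8) < 0.2, "-",
                                    sample(AA_ALPHABET, 8, replace = TRUE)),
                             collapse = ""))
  h <- build_profile(motif_alignment("io", paste0("r", 1:5), rows))
  f <- tempfile(fileext = ".json")
  write_profile_json(h, f)
  h2 <- read_profile_json(f)
  expect_equal(h2$match_emissions, h$match_emissions)
  expect_equal(h2$insert_emissions, h$insert_emissions)
  expect_equal(h2$transitions, h$transitions)
  expect_equal(h2$match_columns, h$match_columns)
  expect_equal(h2$L, h$L)
})
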