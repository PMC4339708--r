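# Exhaustive local-alignment scorer: enumerates every match-entry ..
# match-exit state path and returns the maximal log2-odds score.
# Independent of the package's dynamic-programming search.
brute_force_score <- function(hmm, protein) {
  seq_idx <- match(strsplit(toupper(protein), "")[[1]], AA_ALPHABET)
  n <- length(seq_idx); L <- hmm$L
  lo_m <- log2(sweep(hmm$match_emissions, 2, hmm$background, "/"))
  lo_i <- log2(sweep(hmm$insert_emissions, 2, hmm$background, "/"))
  lt <- log2(hmm$transitions)
  best <- -Inf
  rec <- function(state, j, i, sc) {
    if (state == "M") {
      best <<- max(best, sc)
      if (j < L && i < n) rec("M", j + 1, i + 1, sc + lt[j, "MM"] + lo_m[j + 1, seq_idx[i + 1]])
      if (j < L && i < n) rec("I", j, i + 1, sc + lt[j, "MI"] + lo_i[j, seq_idx[i + 1]])
      if (j < L) rec("D", j + 1, i, sc + lt[j, "MD"])
    } else if (state == "I") {
      if (j < L && i < n) rec("M", j + 1, i + 1, sc + lt[j, "IM"] + lo_m[j + 1, seq_idx[i + 1]])
      if (i < n) rec("I", j, i + 1, sc + lt[j, "II"] + lo_i[j, seq_idx[i + 1]])
    } else {
      if (j < L) {
        if (i < n) rec("M", j + 1, i + 1, sc + lt[j, "DM"] + lo_m[j + 1, seq_idx[i + 1]])
        rec("D", j + 1, i, sc + lt[j, "DD"])
      }
    }
  }
  for (i0 in seq_len(n)) for (j0 in seq_len(L)) rec("M", j0, i0, lo_m[j0, seq_idx[i0]])
  best
}

# random small model (possibly with insert columns) for oracle fuzzing
random_small_model <- function(max_L = 4, gap_prob = 0) {
  repeat {
    nc <- sample(2:5, 1); nr <- sample(3:6, 1)
    rows <- replicate(nr, paste(ifelse(runif(nc) < gap_prob, "-",
                                       sample(AA_ALPHABET, nc, replace = TRUE)),
                                collapse = ""))
    h <- try(build_profile(motif_alignment("t", paste0("r", 1:nr), rows)),
             silent = TRUE)
    if (!inherits(h, "try-error") && h$L <= max_L) return(h)
  }
}
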