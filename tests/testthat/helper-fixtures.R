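# Shared small fixtures, built in code.

rand_protein <- function(n) paste(sample(AA_ALPHABET, n, replace = TRUE), collapse = "")

# canonical domain straight from a 55-character row (no gaps unless given)
dom_from <- function(row, id = "dom") canonical_domain_from_row(id, row)

# a canonical row with a chosen basic region, consensus elsewhere
row_with_basic <- function(basic13) {
  stopifnot(nchar(basic13) == 13)
  paste0(basic13, substr(bhlhscan:::CANONICAL_CONSENSUS, 14, 55))
}

# small synthetic bundle shared by the pipeline tests (built once per run)
.small_bundle_cache <- new.env(parent = emptyenv())
small_bundle <- function() {
  if (is.null(.small_bundle_cache$b)) {
    dir <- file.path(tempdir(), "bhlh_small_bundle")
    cfg <- generator_config(seed = 23, n_bhlh = 30, n_decoys = 20,
                            n_internal_stop = 2, n_truncated = 2)
    .small_bundle_cache$b <- generate_bundle(cfg, dir)
  }
  .small_bundle_cache$b
}

small_run_config <- function(b = small_bundle(), ...) {
  run_config(proteins = b$proteins, cds = b$cds, gff = b$gff,
             training = b$training, motifs = b$motifs,
             family_refs = b$family_refs, evidence = b$evidence,
             expression = b$expression, seed = 5, n_shuffles = 100, ...)
}

.small_result_cache <- new.env(parent = emptyenv())
small_result <- function() {
  if (is.null(.small_result_cache$r))
    .small_result_cache$r <- run_pipeline(small_run_config())
  .small_result_cache$r
}
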