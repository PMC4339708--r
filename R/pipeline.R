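## End-to-end orchestration: scan -> curate -> map -> binding -> introns ->
## families -> homeologs -> expression -> censuses, emitting the per-gene
## ledger and summary reports.

#' Pipeline run configuration
#'
#' Input paths and every stage threshold, with defaults equal to the
#' documented module defaults. The configuration is serialized verbatim
#' into the output directory of [run_pipeline()].
#'
#' @param proteins,cds,gff,training,motifs,family_refs,evidence,expression
#'   input file paths (as written by [generate_bundle()]; `cds`, `gff`,
#'   `evidence`, `expression`, `motifs` may be NULL to skip those stages).
#' @param seed integer seed for E-value calibration.
#' @param out optional output directory; when given, the ledger, censuses,
#'   tree and config are written there.
#' @param match_threshold,pseudocount model build parameters.
#' @param calibration_length,n_shuffles E-value calibration parameters.
#' @param max_domain_evalue E-value at or below which a scanned protein is
#'   called domain-positive (default 1e-3).
#' @param min_identity,require_block homeolog grouping parameters.
#' @param detect_threshold,enrich_fold expression parameters.
#' @param margin_threshold,motif_max_evalue family-assignment parameters.
#' @param pattern_defs an [intron_pattern_def()].
#' @param enforce_cutoffs opt-in curation mismatch cutoffs.
#' @return an object of class `run_config`.
#' @export
run_config <- function(proteins, cds = NULL, gff = NULL, training,
                       motifs = NULL, family_refs = NULL, evidence = NULL,
                       expression = NULL, seed = 1L, out = NULL,
                       match_threshold = 0.5, pseudocount = "laplace",
                       calibration_length = 400L, n_shuffles = 200L,
                       max_domain_evalue = 1e-3, min_identity = 90,
                       require_block = TRUE, detect_threshold = 1,
                       enrich_fold = 5, margin_threshold = 0.05,
                       motif_max_evalue = 1e-7,
                       pattern_defs = intron_pattern_def(),
                       enforce_cutoffs = FALSE) {
  structure(list(proteins = proteins, cds = cds, gff = gff,
                 training = training, motifs = motifs,
                 family_refs = family_refs, evidence = evidence,
                 expression = expression, seed = as.integer(seed), out = out,
                 match_threshold = match_threshold, pseudocount = pseudocount,
                 calibration_length = calibration_length,
                 n_shuffles = n_shuffles,
                 max_domain_evalue = max_domain_evalue,
                 min_identity = min_identity, require_block = require_block,
                 detect_threshold = detect_threshold,
                 enrich_fold = enrich_fold,
                 margin_threshold = margin_threshold,
                 motif_max_evalue = motif_max_evalue,
                 pattern_defs = pattern_defs,
                 enforce_cutoffs = enforce_cutoffs),
            class = "run_config")
}

#' Load a run configuration from YAML
#' @param path YAML file whose keys mirror [run_config()] arguments.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

read_fasta_named <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
}

#' Run the full bHLH annotation pipeline
#'
#' Stages, in order: build the domain model from the training alignment and
#' calibrate E-values (seeded); scan every protein; curate; map hits onto
#' the canonical scheme; classify DNA binding; project and classify intron
#' patterns; scan motifs and assign families; group homeologs; categorize
#' expression; assemble the per-gene ledger and the summary censuses, plus
#' a neighbor-joining tree of the curated domains. Per-record failures are
#' collected, not fatal.
#'
#' @param cfg a [run_config()].
#' @return an object of class `pipeline_result`: `ledger` (data frame, one
#'   row per input protein, sorted by gene_id), `censuses` (list), `tree`
#'   (phylo or NULL), `calls` (per-gene detail lists), `errors` (data frame
#'   stage/record/message), `config`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  errors <- data.frame(stage = character(), record = character(),
                       message = character(), stringsAsFactors = FALSE)
  note <- function(stage, record, e) {
    errors[nrow(errors) + 1L, ] <<- c(stage, record, conditionMessage(e))
  }

  proteins <- read_fasta_named(cfg$proteins)
  proteins <- proteins[order(names(proteins))]
  n_db <- length(proteins)

  train <- read_motif_alignment(cfg$training)
  hmm <- build_profile(train, match_threshold = cfg$match_threshold,
                       pseudocount = cfg$pseudocount)
  calib <- calibrate_evalues(hmm, length = cfg$calibration_length,
                             n_shuffles = cfg$n_shuffles, seed = cfg$seed)
  scheme <- canonical_scheme(model_map = hmm$match_columns)

  motif_models <- list()
  motif_calibs <- list()
  if (!is.null(cfg$motifs)) {
    maln <- read_motif_alignment(cfg$motifs)
    mm <- build_profile(maln, match_threshold = cfg$match_threshold,
                        pseudocount = cfg$pseudocount)
    motif_models[[mm$name]] <- mm
    motif_calibs[[mm$name]] <- calibrate_evalues(mm, length = cfg$calibration_length,
                                                 n_shuffles = cfg$n_shuffles,
                                                 seed = cfg$seed + 1L)
  }
  refs <- if (!is.null(cfg$family_refs)) read_family_references(cfg$family_refs) else NULL
  gms <- if (!is.null(cfg$gff)) read_gene_models(cfg$gff) else NULL
  rtab <- read_residue_table()

  expr_mat <- if (!is.null(cfg$expression)) read_expression_matrix(cfg$expression) else NULL
  groups <- NULL
  if (!is.null(cfg$evidence)) {
    ev <- read.delim(cfg$evidence, stringsAsFactors = FALSE)
    groups <- group_homeologs(names(proteins), ev,
                              min_identity = cfg$min_identity,
                              require_block = cfg$require_block)
    # restrict reporting to genes with any domain evidence later; grouping
    # itself runs over the full gene set
  }
  group_of <- if (!is.null(groups)) {
    g <- character()
    for (k in seq_along(groups)) g[groups[[k]]$members] <- sprintf("HG%04d", k)
    g
  } else NULL
  copy_of <- if (!is.null(groups)) {
    cn <- integer()
    for (k in seq_along(groups)) cn[groups[[k]]$members] <- groups[[k]]$copy_number
    cn
  } else NULL

  calls <- list()
  ledger_rows <- list()
  for (g in names(proteins)) {
    prot <- proteins[[g]]
    rec <- list(gene_id = g)
    hit <- dom <- bind <- fam <- patt <- expr_call <- NULL
    scan_ok <- !grepl("[^ACDEFGHIKLMNPQRSTVWYX*]", prot)
    prot_clean <- gsub("*", "", prot, fixed = TRUE)
    tryCatch({
      hit <- viterbi_search(hmm, prot_clean, calibration = calib,
                            n_targets = n_db, target_id = g)
    }, error = function(e) note("scan", g, e))
    domain_positive <- !is.null(hit) && !is.na(hit$evalue) &&
      hit$evalue <= cfg$max_domain_evalue
    if (domain_positive) {
      tryCatch(dom <- map_to_canonical(hit, scheme),
               error = function(e) note("map", g, e))
    }
    verdict <- curate(prot, hit = if (domain_positive) hit else NULL,
                      dom = dom, table = rtab,
                      enforce_cutoffs = cfg$enforce_cutoffs)
    motif_hits <- NULL
    if (length(motif_models) && domain_positive) {
      tryCatch(motif_hits <- scan_motifs(prot_clean, motif_models, motif_calibs,
                                         n_targets = n_db),
               error = function(e) note("motifs", g, e))
    }
    if (verdict$passed && !is.null(dom)) {
      bind <- classify_binding(dom)
      if (!is.null(gms) && g %in% names(gms)) {
        tryCatch({
          pl <- project_introns(gms[[g]], hit, dom)
          patt <- classify_pattern(pl, cfg$pattern_defs, gene_id = g)
        }, error = function(e) note("introns", g, e))
      }
      if (!is.null(refs)) {
        tryCatch(fam <- assign_family(dom, refs, motif_hits = motif_hits,
                                      intron_pattern = if (!is.null(patt)) patt$pattern else NULL,
                                      margin_threshold = cfg$margin_threshold,
                                      motif_max_evalue = cfg$motif_max_evalue),
                 error = function(e) note("family", g, e))
      }
    }
    if (!is.null(expr_mat) && g %in% rownames(expr_mat)) {
      tryCatch(expr_call <- classify_expression(expr_mat[g, ],
                                                detect_threshold = cfg$detect_threshold,
                                                enrich_fold = cfg$enrich_fold,
                                                gene_id = g),
               error = function(e) note("expression", g, e))
    }
    calls[[g]] <- list(hit = hit, dom = dom, verdict = verdict, bind = bind,
                       fam = fam, patt = patt, expr = expr_call,
                       motif_hits = motif_hits,
                       domain_positive = domain_positive)
    ledger_rows[[g]] <- data.frame(
      gene_id = g,
      curation_passed = verdict$passed,
      curation_reasons = paste(verdict$reasons, collapse = ";"),
      domain_positive = domain_positive,
      bit_score = if (!is.null(hit)) round(hit$bit_score, 2) else NA_real_,
      evalue = if (!is.null(hit)) signif(hit$evalue, 3) else NA_real_,
      env_start = if (!is.null(hit)) hit$env_start else NA_integer_,
      env_end = if (!is.null(hit)) hit$env_end else NA_integer_,
      loop_length = if (!is.null(dom)) dom$loop_length else NA_integer_,
      basic_count = if (!is.null(bind)) bind$basic_count else NA_integer_,
      hk5 = if (!is.null(bind)) isTRUE(bind$hk5) else NA,
      e9 = if (!is.null(bind)) isTRUE(bind$e9) else NA,
      r12 = if (!is.null(bind)) isTRUE(bind$r12) else NA,
      r13 = if (!is.null(bind)) isTRUE(bind$r13) else NA,
      gbox_rule_raw = if (!is.null(bind)) bind$gbox_rule_raw else NA,
      binding_category = if (!is.null(bind)) bind$category else NA_character_,
      family = if (!is.null(fam)) fam$family else NA_character_,
      family_distance = if (!is.null(fam)) round(fam$distance, 4) else NA_real_,
      family_margin = if (!is.null(fam)) round(fam$margin, 4) else NA_real_,
      family_ambiguous = if (!is.null(fam)) fam$ambiguous else NA,
      motif_support = if (!is.null(fam)) paste(fam$motif_support, collapse = ";") else "",
      intron_pattern = if (!is.null(patt)) patt$pattern else NA_character_,
      matched_canonicals = if (!is.null(patt)) paste(patt$matched_canonicals, collapse = ";") else "",
      homeolog_group = if (!is.null(group_of)) unname(group_of[g]) else NA_character_,
      copy_number = if (!is.null(copy_of)) unname(copy_of[g]) else NA_integer_,
      expression_category = if (!is.null(expr_call)) expr_call$category else NA_character_,
      expressed = if (!is.null(expr_call)) expr_call$expressed else NA,
      stringsAsFactors = FALSE)
  }
  ledger <- do.call(rbind, ledger_rows[order(names(ledger_rows))])
  rownames(ledger) <- NULL

  ok <- vapply(calls, function(x) !is.null(x$bind), TRUE)
  doms <- lapply(calls[ok], `[[`, "dom")
  censuses <- list(
    binding = if (any(ok)) binding_census(lapply(calls[ok], `[[`, "bind")) else NULL,
    conservation = if (any(ok)) conservation_profile(doms) else NULL,
    pattern = {
      pats <- Filter(Negate(is.null), lapply(calls, `[[`, "patt"))
      if (length(pats)) pattern_census(pats) else NULL
    },
    family_sizes = {
      fams <- Filter(Negate(is.null), lapply(calls, `[[`, "fam"))
      if (length(fams)) {
        tb <- table(vapply(fams, `[[`, "", "family"))
        data.frame(family = names(tb), count = as.integer(tb))
      } else NULL
    },
    copy_number = if (!is.null(groups)) {
      # histogram restricted to domain-positive genes, the family of interest
      pos_genes <- names(calls)[vapply(calls, `[[`, TRUE, "domain_positive")]
      sub <- lapply(groups, function(gr) {
        mm <- intersect(gr$members, pos_genes)
        if (length(mm)) structure(list(members = mm, copy_number = length(mm)),
                                  class = "homeolog_group") else NULL
      })
      copy_number_histogram(Filter(Negate(is.null), sub))
    } else NULL,
    expression = {
      ex <- Filter(Negate(is.null), lapply(calls, `[[`, "expr"))
      if (length(ex)) expression_census(ex) else NULL
    })

  tree <- NULL
  if (sum(ok) >= 3) {
    tryCatch({
      dm <- pairwise_distances(doms)
      tree <- nj_tree(dm)
    }, error = function(e) note("tree", "all", e))
  }

  res <- structure(list(ledger = ledger, censuses = censuses, tree = tree,
                        calls = calls, errors = errors, config = cfg,
                        calibration = calib),
                   class = "pipeline_result")
  if (!is.null(cfg$out)) write_pipeline_result(res, cfg$out)
  res
}

#' Write a pipeline result to an output directory
#'
#' Emits the versioned ledger TSV ("bhlh-ledger/1" header comment), the
#' census tables, the Newick tree and the serialized configuration.
#' Percentages carry 1 decimal, distances 4, scores 2.
#'
#' @param res a `pipeline_result`.
#' @param dir output directory.
#' @export
write_pipeline_result <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ledger_path <- file.path(dir, "ledger.tsv")
  con <- file(ledger_path, "w")
  writeLines("# bhlh-ledger/1", con)
  suppressWarnings(write.table(res$ledger, con, sep = "\t", quote = FALSE,
                               row.names = FALSE, append = TRUE))
  close(con)
  for (nm in names(res$censuses)) {
    tab <- res$censuses[[nm]]
    if (is.null(tab)) next
    if (inherits(tab, "conservation_profile")) attr(tab, "freq") <- NULL
    write.table(as.data.frame(tab), file.path(dir, paste0("census_", nm, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(res$tree)) ape::write.tree(res$tree, file.path(dir, "domains.nwk"))
  cfg <- res$config
  cfg$pattern_defs <- unclass(cfg$pattern_defs)
  yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  if (nrow(res$errors))
    write.table(res$errors, file.path(dir, "errors.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Validate pipeline inputs
#'
#' Structural checks with line-level diagnostics: FASTA alphabet and record
#' structure, GFF3 coordinate sanity, similarity/evidence/expression TSV
#' shape, and protein/CDS cross-file length consistency. Never mutates the
#' inputs.
#'
#' @param cfg a [run_config()].
#' @return data frame with columns file, line, problem (zero rows when
#'   everything is clean).
#' @export
validate_inputs <- function(cfg) {
  out <- data.frame(file = character(), line = integer(), problem = character(),
                    stringsAsFactors = FALSE)
  add <- function(file, line, problem) {
    out[nrow(out) + 1L, ] <<- list(file, as.integer(line), problem)
  }
  check_fasta <- function(path, dna = FALSE) {
    if (!file.exists(path)) { add(path, NA, "unreadable file"); return(NULL) }
    lines <- readLines(path)
    if (!length(lines) || !startsWith(lines[1], ">"))
      add(path, 1, "does not start with a FASTA header")
    pat <- if (dna) "[^ACGTN]" else "[^ACDEFGHIKLMNPQRSTVWYX*]"
    bad <- which(!startsWith(lines, ">") & grepl(pat, toupper(lines)))
    for (b in head(bad, 10)) add(path, b, "invalid sequence character")
    lines
  }
  prot_lines <- check_fasta(cfg$proteins)
  if (!is.null(cfg$cds)) check_fasta(cfg$cds, dna = TRUE)
  if (!is.null(cfg$gff)) {
    if (!file.exists(cfg$gff)) add(cfg$gff, NA, "unreadable file") else {
      lines <- readLines(cfg$gff)
      body <- which(!startsWith(lines, "#") & nzchar(lines))
      for (b in body) {
        f <- strsplit(lines[b], "\t", fixed = TRUE)[[1]]
        if (length(f) != 9) { add(cfg$gff, b, "not 9 tab-separated fields"); next }
        s <- suppressWarnings(as.integer(f[4])); e <- suppressWarnings(as.integer(f[5]))
        if (is.na(s) || is.na(e)) add(cfg$gff, b, "non-numeric coordinates")
        else if (e < s) add(cfg$gff, b, "end < start")
        if (!f[7] %in% c("+", "-", ".")) add(cfg$gff, b, "invalid strand")
      }
    }
  }
  if (!is.null(cfg$evidence) && file.exists(cfg$evidence)) {
    ev <- read.delim(cfg$evidence, stringsAsFactors = FALSE)
    need <- c("gene_a", "gene_b", "pident")
    if (!all(need %in% names(ev))) add(cfg$evidence, 1, "missing required columns")
  } else if (!is.null(cfg$evidence)) add(cfg$evidence, NA, "unreadable file")
  if (!is.null(cfg$expression) && !file.exists(cfg$expression))
    add(cfg$expression, NA, "unreadable file")
  # cross-file: CDS length must be 3*len or 3*(len+1) of the protein
  if (!is.null(cfg$cds) && file.exists(cfg$cds) && !is.null(prot_lines)) {
    prots <- read_fasta_named(cfg$proteins)
    cds <- read_fasta_named(cfg$cds)
    common <- intersect(names(prots), names(cds))
    for (g in common) {
      pl <- nchar(prots[[g]]); cl <- nchar(cds[[g]])
      if (!(cl == 3 * pl || cl == 3 * (pl + 1)))
        add(cfg$cds, NA, sprintf("protein/CDS length mismatch for %s (%d aa vs %d nt)",
                                 g, pl, cl))
    }
  }
  out
}
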