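## Homeolog grouping (union-find over identity evidence), copy-number
## histograms, reciprocal-best-hit ortholog matching on tabular similarity
## hits, and expression categorization.

#' Group genes into homeologous sets
#'
#' Transitive closure (union-find) over evidence pairs passing the identity
#' threshold (inclusive) and, if required, the shared-duplication-block
#' flag. Genes without qualifying evidence become singletons.
#'
#' @param genes character vector of all gene ids.
#' @param evidence data frame with columns gene_a, gene_b, pident and
#'   (optionally) block_id; a pair is in the same block when both block ids
#'   are non-missing and equal.
#' @param min_identity percent identity threshold (default 90, `>=`).
#' @param require_block require same duplication block (default TRUE).
#' @return list of `homeolog_group` objects (`members`, `copy_number`),
#'   sorted by first member; groups partition `genes`.
#' @export
group_homeologs <- function(genes, evidence, min_identity = 90,
                            require_block = TRUE) {
  genes <- as.character(genes)
  if (nrow(evidence)) {
    unknown <- setdiff(unique(c(evidence$gene_a, evidence$gene_b)), genes)
    if (length(unknown))
      stop(sprintf("input error: evidence names unknown genes: %s",
                   paste(unknown, collapse = ", ")), call. = FALSE)
  }
  parent <- setNames(seq_along(genes), genes)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union_ <- function(a, b) {
    ra <- find(match(a, genes)); rb <- find(match(b, genes))
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
  }
  if (nrow(evidence)) {
    ok <- evidence$pident >= min_identity
    if (require_block) {
      same_block <- if ("block_id" %in% names(evidence)) {
        !is.na(evidence$block_id) & nzchar(as.character(evidence$block_id))
      } else rep(FALSE, nrow(evidence))
      ok <- ok & same_block
    }
    for (k in which(ok)) union_(evidence$gene_a[k], evidence$gene_b[k])
  }
  roots <- vapply(seq_along(genes), find, 0L)
  split_members <- split(genes, roots)
  groups <- lapply(unname(split_members), function(mm) {
    mm <- sort(mm)
    structure(list(members = mm, copy_number = length(mm)),
              class = "homeolog_group")
  })
  groups[order(vapply(groups, function(g) g$members[1], ""))]
}

#' Copy-number histogram of homeolog groups
#'
#' @param groups list of `homeolog_group` objects.
#' @return data frame with columns copy_number, n_groups, n_genes, plus
#'   attributes `total_genes` and `multi_copy_genes`.
#' @export
copy_number_histogram <- function(groups) {
  cn <- vapply(groups, `[[`, 0L, "copy_number")
  tab <- table(cn)
  out <- data.frame(copy_number = as.integer(names(tab)),
                    n_groups = as.integer(tab))
  out$n_genes <- out$copy_number * out$n_groups
  attr(out, "total_genes") <- sum(out$n_genes)
  attr(out, "multi_copy_genes") <- sum(out$n_genes[out$copy_number > 1])
  out
}

#' Read a 12-column tabular similarity file
#'
#' Tab-separated with the standard column semantics: qseqid sseqid pident
#' length mismatch gapopen qstart qend sstart send evalue bitscore.
#'
#' @param path file path.
#' @return data frame with those column names.
#' @export
read_similarity_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 0L) != 12)
  if (length(bad))
    stop(sprintf("parse error: line %d of '%s' has %d fields, expected 12",
                 bad[1], path, length(parts[[bad[1]]])), call. = FALSE)
  m <- do.call(rbind, parts)
  out <- data.frame(qseqid = m[, 1], sseqid = m[, 2],
                    pident = as.numeric(m[, 3]), length = as.integer(m[, 4]),
                    mismatch = as.integer(m[, 5]), gapopen = as.integer(m[, 6]),
                    qstart = as.integer(m[, 7]), qend = as.integer(m[, 8]),
                    sstart = as.integer(m[, 9]), send = as.integer(m[, 10]),
                    evalue = as.numeric(m[, 11]), bitscore = as.numeric(m[, 12]),
                    stringsAsFactors = FALSE)
  if (anyNA(out$pident) || anyNA(out$evalue) || anyNA(out$bitscore))
    stop(sprintf("parse error: non-numeric field in '%s'", path), call. = FALSE)
  out
}

## best hit per query: max bit score, tie -> min e-value, tie -> lexicographic subject
.best_hits <- function(hits) {
  ord <- order(hits$qseqid, -hits$bitscore, hits$evalue, hits$sseqid)
  h <- hits[ord, , drop = FALSE]
  h[!duplicated(h$qseqid), , drop = FALSE]
}

#' Reciprocal best hits between two similarity tables
#'
#' A pair (x, y) is reported iff y is x's best hit in `ab` and x is y's best
#' hit in `ba`, both hits passing the filters. Best = maximal bit score,
#' ties to minimal e-value, then lexicographic subject id.
#'
#' @param ab,ba data frames as from [read_similarity_table()].
#' @param max_evalue keep hits with `evalue <= max_evalue` (default `Inf`;
#'   to apply the conventional "less than 1e-25" rule pass a value just
#'   under it or rely on <=, which excludes 1e-24 at max 1e-25 either way).
#' @param min_identity keep hits with `pident > min_identity` (default 0).
#' @return data frame with columns a, b, pident_ab, evalue_ab, bitscore_ab,
#'   sorted by a.
#' @export
reciprocal_best_hits <- function(ab, ba, max_evalue = Inf, min_identity = 0) {
  if (!nrow(ab) || !nrow(ba)) stop("input error: empty similarity table", call. = FALSE)
  filt <- function(h) h[h$evalue <= max_evalue & h$pident > min_identity, , drop = FALSE]
  ab <- filt(ab); ba <- filt(ba)
  if (!nrow(ab) || !nrow(ba))
    return(data.frame(a = character(), b = character(), pident_ab = numeric(),
                      evalue_ab = numeric(), bitscore_ab = numeric()))
  best_ab <- .best_hits(ab)
  best_ba <- .best_hits(ba)
  back <- setNames(best_ba$sseqid, best_ba$qseqid)
  keep <- !is.na(back[best_ab$sseqid]) & back[best_ab$sseqid] == best_ab$qseqid
  keep[is.na(keep)] <- FALSE
  out <- best_ab[keep, c("qseqid", "sseqid", "pident", "evalue", "bitscore")]
  names(out) <- c("a", "b", "pident_ab", "evalue_ab", "bitscore_ab")
  rownames(out) <- NULL
  out[order(out$a), , drop = FALSE]
}

EXPRESSION_CATEGORIES <- c("NOT_EXPRESSED", "POD_WALL_ONLY", "NODULE_PREFERENTIAL",
                           "SEED_ENRICHED", "UBIQUITOUS", "TISSUE_RESTRICTED")

EXPRESSION_TISSUES <- c("root", "nodule", "leaf", "seed_early", "seed_mid",
                        "seed_late", "pod_wall")

#' Read an expression matrix (genes x tissues TSV)
#' @param path TSV with a header row of tissue labels and gene ids in the
#'   first column.
#' @return numeric matrix, rownames = gene ids.
#' @export
read_expression_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- df[[1]]
  m
}

#' Categorize an expression profile
#'
#' A tissue is detected when abundance >= `detect_threshold`. Categories, in
#' precedence order: NOT_EXPRESSED (nothing detected), POD_WALL_ONLY (pod
#' wall is the only detected tissue), NODULE_PREFERENTIAL (detected in
#' nodule, all aerial tissues — leaf, pod wall, seed stages — below the
#' detection threshold), SEED_ENRICHED (maximal seed abundance at least
#' `enrich_fold` times the maximal non-seed abundance, boundary inclusive),
#' UBIQUITOUS (detected in root, leaf and at least one seed stage),
#' TISSUE_RESTRICTED (everything else that is expressed).
#'
#' @param profile named numeric vector of abundances (names from the tissue
#'   vocabulary: root, nodule, leaf, seed_early, seed_mid, seed_late,
#'   pod_wall; any `seed`-prefixed label counts as a seed stage).
#' @param detect_threshold detection cutoff in normalized units (default 1).
#' @param enrich_fold seed-enrichment fold (default 5).
#' @param gene_id recorded in the call.
#' @return an object of class `expression_call`: `gene_id`, `expressed`,
#'   `tissues_detected`, `category`.
#' @export
classify_expression <- function(profile, detect_threshold = 1, enrich_fold = 5,
                                gene_id = NA_character_) {
  tn <- names(profile)
  known <- tn %in% EXPRESSION_TISSUES | startsWith(tn, "seed")
  if (!all(known))
    stop(sprintf("vocabulary error: unknown tissue label(s): %s",
                 paste(tn[!known], collapse = ", ")), call. = FALSE)
  if (any(profile < 0)) stop("input error: negative abundance", call. = FALSE)
  det <- profile >= detect_threshold
  detected <- tn[det]
  seed <- startsWith(tn, "seed")
  aerial <- tn %in% c("leaf", "pod_wall") | seed
  category <- if (!any(det)) "NOT_EXPRESSED"
    else if (identical(detected, "pod_wall")) "POD_WALL_ONLY"
    else if (isTRUE(det[match("nodule", tn)]) &&
             (!any(aerial) || max(profile[aerial]) < detect_threshold)) "NODULE_PREFERENTIAL"
    else if (any(seed & det) &&
             max(profile[seed]) >= enrich_fold * max(0, profile[!seed])) "SEED_ENRICHED"
    else if (isTRUE(det[match("root", tn)]) && isTRUE(det[match("leaf", tn)]) &&
             any(seed & det)) "UBIQUITOUS"
    else "TISSUE_RESTRICTED"
  structure(list(gene_id = gene_id, expressed = any(det),
                 tissues_detected = detected, category = category),
            class = "expression_call")
}

#' Census of expression categories
#'
#' Counts per category plus the expressed total, with percentages to one
#' decimal; permutation-invariant.
#'
#' @param calls list of `expression_call` objects.
#' @return data frame with columns category, count, pct; attribute
#'   `expressed` holds the expressed total.
#' @export
expression_census <- function(calls) {
  if (length(calls) < 1) stop("input error: no calls", call. = FALSE)
  cat_ <- factor(vapply(calls, `[[`, "", "category"), levels = EXPRESSION_CATEGORIES)
  tab <- table(cat_)
  out <- data.frame(category = names(tab), count = as.integer(tab),
                    pct = fmt_pct(as.integer(tab) / length(calls)),
                    stringsAsFactors = FALSE)
  attr(out, "expressed") <- sum(vapply(calls, `[[`, TRUE, "expressed"))
  out
}
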