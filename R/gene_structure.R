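## Gene models, intron projection into canonical domain coordinates, and
## intron-pattern classification (A-H / NONE / OTHER).

#' Read gene models from GFF3
#'
#' GFF3 is 1-based inclusive; coordinates are converted once, on input, to
#' 0-based half-open. Exons and CDS segments are stored in transcription
#' order (reversed for minus-strand genes).
#'
#' @param path GFF3 file with gene/mRNA/exon/CDS features.
#' @return named list of `gene_model` objects: `gene_id`, `seq_id`,
#'   `strand`, `exons` and `cds` (matrices with columns start/end, 0-based
#'   half-open, transcription order), `cds_phase`.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  need <- c("type", "seqnames", "start", "end", "strand")
  stopifnot(all(need %in% names(df)))
  cds <- df[df$type == "CDS", , drop = FALSE]
  exons <- df[df$type == "exon", , drop = FALSE]
  gene_of <- function(d) {
    # Parent is "mRNA:<gene>.t1"-style or plain; fall back over ID/Parent
    p <- if ("Parent" %in% names(d)) vapply(d$Parent, function(x) x[1], "") else d$ID
    sub("\\.t\\d+$", "", sub("^mRNA:", "", p))
  }
  cds$gene <- gene_of(cds)
  exons$gene <- gene_of(exons)
  out <- list()
  for (g in unique(cds$gene)) {
    cg <- cds[cds$gene == g, , drop = FALSE]
    eg <- exons[exons$gene == g, , drop = FALSE]
    strand <- as.character(cg$strand[1])
    dec <- strand == "-"
    ord <- order(cg$start, decreasing = dec)
    cg <- cg[ord, , drop = FALSE]
    eg <- eg[order(eg$start, decreasing = dec), , drop = FALSE]
    mk <- function(d) cbind(start = d$start - 1L, end = d$end)
    out[[g]] <- structure(list(gene_id = g,
                               seq_id = as.character(cg$seqnames[1]),
                               strand = strand,
                               exons = if (nrow(eg)) mk(eg) else mk(cg),
                               cds = mk(cg),
                               cds_phase = if ("phase" %in% names(cg))
                                 as.integer(as.character(cg$phase)) else
                                 rep(NA_integer_, nrow(cg))),
                          class = "gene_model")
  }
  out
}

#' Project introns of a gene model into canonical domain coordinates
#'
#' Each intron between consecutive CDS segments is assigned the canonical
#' position of the codon immediately 5' of the splice (the codon containing
#' the last exonic base) and the codon phase (exonic bases of the
#' interrupted codon, 0/1/2). Strand-aware: segments are already stored in
#' transcription order. Introns outside the mapped domain are excluded.
#'
#' @param gm a `gene_model`.
#' @param protein_hit the `domain_hit` for the translated protein (used for
#'   length consistency only).
#' @param dom the `canonical_domain` mapped from that hit.
#' @return data frame with columns intron_index, protein_pos,
#'   domain_position, codon_phase (possibly zero rows).
#' @export
project_introns <- function(gm, protein_hit, dom) {
  stopifnot(inherits(gm, "gene_model"), inherits(dom, "canonical_domain"))
  seg_len <- gm$cds[, "end"] - gm$cds[, "start"]
  cds_len <- sum(seg_len)
  if (cds_len %% 3 != 0)
    stop(sprintf("gene-model error: CDS length %d of '%s' is not a multiple of 3",
                 cds_len, gm$gene_id), call. = FALSE)
  plen <- protein_hit$protein_length
  if (!(cds_len == 3 * plen || cds_len == 3 * (plen + 1)))
    stop(sprintf("consistency error: CDS of '%s' (%d nt) does not translate to %d residues",
                 gm$gene_id, cds_len, plen), call. = FALSE)
  out <- data.frame(intron_index = integer(), protein_pos = integer(),
                    domain_position = integer(), codon_phase = integer())
  if (length(seg_len) < 2) return(out)
  cum <- cumsum(seg_len)
  for (k in seq_len(length(seg_len) - 1)) {
    nb <- cum[k]                      # exonic bases 5' of intron k
    aa <- as.integer(ceiling(nb / 3)) # codon containing the last exonic base
    phase <- as.integer(nb %% 3)
    cp <- which(dom$protein_pos == aa)
    if (length(cp) == 1) {
      out <- rbind(out, data.frame(intron_index = k, protein_pos = aa,
                                   domain_position = cp, codon_phase = phase))
    }
  }
  out
}

#' Intron pattern definitions
#'
#' The three conserved intron positions (`c1 < c2 < c3`), the alternative
#' pattern-F position, the two pattern-G positions, a matching tolerance in
#' canonical columns, and the subset map naming the two-intron patterns.
#' The concrete default positions are package configuration (the patterns
#' are defined by representative genes, not by published coordinates) and
#' sit in the anchored, non-loop canonical columns.
#'
#' @param c1,c2,c3 conserved canonical intron positions.
#' @param alt_position the pattern-F position.
#' @param g_positions the two pattern-G positions (pattern H = first only).
#' @param tolerance match tolerance in canonical columns (default 2).
#' @param two_subset_map named map from canonical subsets to letters.
#' @return an object of class `intron_pattern_def`.
#' @export
intron_pattern_def <- function(c1 = 10, c2 = 27, c3 = 44, alt_position = 17,
                               g_positions = c(21, 50), tolerance = 2,
                               two_subset_map = c("c1,c2" = "B", "c1,c3" = "C",
                                                  "c2,c3" = "E")) {
  pos <- c(c1, c2, c3, alt_position, g_positions)
  if (anyDuplicated(pos)) stop("input error: pattern positions must be distinct", call. = FALSE)
  if (tolerance < 0) stop("input error: tolerance must be >= 0", call. = FALSE)
  structure(list(canonical = c(c1 = c1, c2 = c2, c3 = c3),
                 alt_position = alt_position,
                 g_positions = g_positions,
                 tolerance = tolerance,
                 two_subset_map = two_subset_map),
            class = "intron_pattern_def")
}

INTRON_PATTERNS <- c(LETTERS[1:8], "NONE", "OTHER")

#' Classify the intron pattern of a gene
#'
#' An intron matches a defined position when within `tolerance` canonical
#' columns. All three conserved introns (and nothing else) is pattern A;
#' two of them map through the configured subset map (B/C/E); exactly one is
#' D; a single intron at the alternative position is F; both pattern-G
#' positions are G; the first of them alone is H; no in-domain introns is
#' NONE; anything else is OTHER.
#'
#' @param placements data frame from [project_introns()].
#' @param defs an [intron_pattern_def()].
#' @param gene_id recorded in the call.
#' @return an object of class `intron_pattern_call`: `gene_id`, `pattern`,
#'   `matched_canonicals` (character subset of c1/c2/c3), `placements`.
#' @export
classify_pattern <- function(placements, defs = intron_pattern_def(),
                             gene_id = NA_character_) {
  stopifnot(inherits(defs, "intron_pattern_def"))
  pos <- placements$domain_position
  match_to <- function(p, targets) {
    d <- abs(targets - p)
    if (min(d) <= defs$tolerance) names(targets)[which.min(d)] else NA_character_
  }
  canon_hit <- if (length(pos)) vapply(pos, match_to, "", targets = defs$canonical)
               else character()
  matched <- sort(unique(canon_hit[!is.na(canon_hit)]))
  extras <- pos[is.na(canon_hit)]
  n_in <- length(pos)
  pattern <- if (n_in == 0) "NONE"
    else if (length(extras) == 0 && length(matched) == 3 && n_in == 3) "A"
    else if (length(extras) == 0 && length(matched) == 2 && n_in == 2)
      unname(defs$two_subset_map[paste(matched, collapse = ",")])
    else if (length(extras) == 0 && length(matched) == 1 && n_in == 1) "D"
    else if (length(matched) == 0 && n_in == 1 &&
             abs(extras[1] - defs$alt_position) <= defs$tolerance) "F"
    else if (length(matched) == 0 && n_in == 2 &&
             all(vapply(defs$g_positions, function(g)
               any(abs(extras - g) <= defs$tolerance), TRUE))) "G"
    else if (length(matched) == 0 && n_in == 1 &&
             abs(extras[1] - defs$g_positions[1]) <= defs$tolerance) "H"
    else "OTHER"
  if (is.na(pattern)) pattern <- "OTHER"
  structure(list(gene_id = gene_id, pattern = pattern,
                 matched_canonicals = matched, placements = placements),
            class = "intron_pattern_call")
}

#' Census of intron patterns
#'
#' Counts and percentages (1 decimal) per pattern label over a set of
#' calls; permutation-invariant; counts sum to the input size.
#'
#' @param calls list of `intron_pattern_call` objects.
#' @return data frame with columns pattern, count, pct.
#' @export
pattern_census <- function(calls) {
  if (length(calls) < 1) stop("input error: no calls", call. = FALSE)
  pat <- factor(vapply(calls, `[[`, "", "pattern"), levels = INTRON_PATTERNS)
  tab <- table(pat)
  data.frame(pattern = names(tab), count = as.integer(tab),
             pct = fmt_pct(as.integer(tab) / length(calls)),
             stringsAsFactors = FALSE)
}
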