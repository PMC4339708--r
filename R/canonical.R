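## The canonical bHLH coordinate scheme and the package's reference
## consensus. Positions 1-13 are the basic region, 14-28 the first helix,
## 29-40 the (nominally 12-column, biologically 5-14 residue) loop, 41-55
## the second helix. Second-helix numbering follows the package's own
## canonical alignment, not an external convention.

## 55-residue canonical consensus used by the residue table defaults and the
## synthetic generator. Rule positions: H5, E9, R12, R13; hydrophobic
## anchors: L23, V45, L52, L55.
CANONICAL_CONSENSUS <- paste0(
  "ADRRHAESERRRR",     # basic 1-13
  "IAEYIRELQLENQRL",   # helix1 14-28
  "GSDKASDMGSVL",      # loop 29-40
  "ADTCVEYIQSLLAQL"    # helix2 41-55
)

#' The canonical bHLH position scheme
#'
#' Fixed coordinate frame the package maps every domain hit onto: a
#' 13-residue basic region, a 15-residue first helix, a loop of nominal
#' width 12 columns (real loops run 5-14 residues; shorter loops leave gap
#' columns, longer ones insertions), and a 15-residue second helix.
#'
#' @param model_map optional integer vector mapping model match states to
#'   canonical positions (defaults to the identity for models built from a
#'   55-column canonical alignment).
#' @return an object of class `canonical_scheme` with spans `basic`,
#'   `helix1`, `loop`, `helix2`, total width `n`, and `model_map`.
#' @export
canonical_scheme <- function(model_map = NULL) {
  structure(list(basic = 1:13, helix1 = 14:28, loop = 29:40, helix2 = 41:55,
                 n = 55L, loop_range = c(5L, 14L), model_map = model_map),
            class = "canonical_scheme")
}

#' Map a domain hit onto the canonical bHLH scheme
#'
#' Walks the hit's Viterbi state path: match states place residues at
#' canonical positions, deletions leave gaps, insertions inside the loop
#' extend the loop length. Domains whose loop falls outside 5-14 residues
#' are flagged atypical, not rejected.
#'
#' @param hit a `domain_hit` from [viterbi_search()].
#' @param scheme a [canonical_scheme()].
#' @return an object of class `canonical_domain`: `target_id`, `residues`
#'   (length-55 character vector, `-` for gap), `protein_pos` (1-based
#'   protein coordinate per canonical position, NA at gaps), `loop_length`,
#'   `atypical_loop`, `hit`.
#' @export
map_to_canonical <- function(hit, scheme = canonical_scheme()) {
  stopifnot(inherits(hit, "domain_hit"), inherits(scheme, "canonical_scheme"))
  map <- scheme$model_map
  if (is.null(map)) map <- seq_len(max(hit$state_path$model))
  path <- hit$state_path
  res <- rep("-", scheme$n)
  ppos <- rep(NA_integer_, scheme$n)
  n_loop_ins <- 0L
  loop_lo <- min(scheme$loop); loop_hi <- max(scheme$loop)
  for (k in seq_len(nrow(path))) {
    st <- path$state[k]; j <- path$model[k]
    cp <- if (j >= 1 && j <= length(map)) map[j] else NA_integer_
    if (st == "M" && !is.na(cp) && cp >= 1 && cp <= scheme$n) {
      res[cp] <- path$residue[k]
      ppos[cp] <- path$seqpos[k]
    } else if (st == "I" && !is.na(cp) && cp >= (loop_lo - 1L) && cp <= loop_hi) {
      # insertion anchored at or inside the loop span
      n_loop_ins <- n_loop_ins + 1L
    }
  }
  if (all(res == "-"))
    stop("mapping error: hit covers no canonical positions", call. = FALSE)
  loop_length <- sum(res[scheme$loop] != "-") + n_loop_ins
  structure(list(target_id = hit$target_id,
                 residues = res,
                 protein_pos = ppos,
                 loop_length = loop_length,
                 atypical_loop = loop_length < scheme$loop_range[1] ||
                                 loop_length > scheme$loop_range[2],
                 scheme = scheme,
                 hit = hit),
            class = "canonical_domain")
}

#' @export
print.canonical_domain <- function(x, ...) {
  cat(sprintf("<canonical_domain %s: %s | loop %d%s>\n", x$target_id,
              paste(x$residues, collapse = ""), x$loop_length,
              if (x$atypical_loop) " (atypical)" else ""))
  invisible(x)
}

#' Build a canonical domain directly from a 55-column gapped row
#'
#' For alignment-based census work where no search hit exists (e.g. rows of
#' an externally supplied canonical alignment).
#'
#' @param id sequence identifier.
#' @param row 55-character gapped residue string.
#' @param scheme a [canonical_scheme()].
#' @return a `canonical_domain`.
#' @export
canonical_domain_from_row <- function(id, row, scheme = canonical_scheme()) {
  cc <- check_aligned_row(row, id, 1L)
  if (length(cc) != scheme$n)
    stop(sprintf("input error: row '%s' has %d columns, expected %d", id,
                 length(cc), scheme$n), call. = FALSE)
  structure(list(target_id = id, residues = cc,
                 protein_pos = ifelse(cc == "-", NA_integer_, cumsum(cc != "-")),
                 loop_length = sum(cc[scheme$loop] != "-"),
                 atypical_loop = sum(cc[scheme$loop] != "-") < scheme$loop_range[1],
                 scheme = scheme, hit = NULL),
            class = "canonical_domain")
}

#' Convert a canonical motif alignment into canonical domains
#'
#' Interprets each row of a 55-column alignment (e.g. read from aligned
#' FASTA or PHYLIP) as one canonical bHLH domain.
#'
#' @param aln a [motif_alignment()] with exactly 55 columns.
#' @param scheme a [canonical_scheme()].
#' @return list of `canonical_domain` objects.
#' @export
domains_from_alignment <- function(aln, scheme = canonical_scheme()) {
  stopifnot(inherits(aln, "motif_alignment"))
  lapply(seq_along(aln$ids), function(i)
    canonical_domain_from_row(aln$ids[i], aln$seqs[i], scheme))
}
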