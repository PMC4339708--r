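## Conservation statistics, basic-residue counts, canonical-motif mismatch
## counts and curation verdicts over canonical domains.

#' Count basic residues in the basic region
#'
#' Residues from `basic_set` at canonical positions 1-13; gaps never count.
#' The default set {R, K, H} includes H because it participates in the
#' H/K5 rule; the set is configurable.
#'
#' @param dom a `canonical_domain`.
#' @param basic_set residues counted as basic.
#' @return integer count.
#' @export
count_basic_residues <- function(dom, basic_set = c("R", "K", "H")) {
  stopifnot(inherits(dom, "canonical_domain"))
  sum(dom$residues[dom$scheme$basic] %in% basic_set)
}

#' Per-position conservation profile of a domain set
#'
#' Residue frequencies are computed over non-gap residues at each canonical
#' position. Tiers: `"100"` for fully conserved positions, `">=30"` for a
#' consensus residue at 30% or more, `"<30"` otherwise.
#'
#' @param domains list of `canonical_domain` objects.
#' @return an object of class `conservation_profile`: a data frame with
#'   columns position, region, consensus, frequency, n_obs, tier, plus a
#'   `freq` attribute holding the 55 x 20 frequency matrix.
#' @export
conservation_profile <- function(domains) {
  if (length(domains) < 1) stop("input error: no domains", call. = FALSE)
  scheme <- domains[[1]]$scheme
  mat <- do.call(rbind, lapply(domains, `[[`, "residues"))
  freq <- matrix(0, scheme$n, 20, dimnames = list(NULL, AA_ALPHABET))
  consensus <- character(scheme$n)
  fmax <- numeric(scheme$n)
  nobs <- integer(scheme$n)
  for (p in seq_len(scheme$n)) {
    col <- mat[, p]
    col <- col[col != "-"]
    nobs[p] <- length(col)
    if (!length(col)) { consensus[p] <- "-"; next }
    f <- table(factor(col, levels = AA_ALPHABET)) / length(col)
    freq[p, ] <- as.numeric(f)
    # ties broken to the lexicographically smaller residue
    consensus[p] <- AA_ALPHABET[which.max(f)]
    fmax[p] <- max(f)
  }
  region <- rep(NA_character_, scheme$n)
  region[scheme$basic] <- "basic"; region[scheme$helix1] <- "helix1"
  region[scheme$loop] <- "loop"; region[scheme$helix2] <- "helix2"
  tier <- ifelse(fmax >= 1 - 1e-9, "100", ifelse(fmax >= 0.3, ">=30", "<30"))
  out <- data.frame(position = seq_len(scheme$n), region = region,
                    consensus = consensus, frequency = fmax, n_obs = nobs,
                    tier = tier, stringsAsFactors = FALSE)
  attr(out, "freq") <- freq
  class(out) <- c("conservation_profile", class(out))
  out
}

#' Canonical residue table (core 11 / defined 19 positions)
#'
#' The 11 core and 19 defined canonical positions with their allowed
#' residues, against which mismatch counts are computed. The shipped default
#' is reconstructed from the package's own canonical consensus (the original
#' reference table is not published in a machine-readable form) and is
#' labelled as such in the file.
#'
#' @param path TSV with columns `position`, `allowed`, `core`
#'   (TRUE/FALSE). Default: the table shipped with the package.
#' @return an object of class `canonical_residue_table`: data frame with
#'   columns position, allowed (character, one-letter codes concatenated),
#'   core (logical).
#' @export
read_residue_table <- function(path = system.file("extdata", "canonical_residues.tsv",
                                                  package = "bhlhscan")) {
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(all(c("position", "allowed", "core") %in% names(tab)))
  tab$core <- as.logical(tab$core)
  if (sum(tab$core) != 11 || nrow(tab) != 19)
    stop("input error: residue table must have 19 positions, 11 of them core",
         call. = FALSE)
  if (anyDuplicated(tab$position))
    stop("input error: duplicated positions in residue table", call. = FALSE)
  class(tab) <- c("canonical_residue_table", class(tab))
  tab
}

#' Count mismatches to the canonical residue table
#'
#' A position mismatches when the domain residue is absent from the allowed
#' set; a gap always mismatches. The core-11 positions are a subset of the
#' defined-19 positions, so `core11 <= defined19` holds for every input.
#'
#' @param dom a `canonical_domain`.
#' @param table a [read_residue_table()] table.
#' @return named integer vector `c(core11 = , defined19 = )`.
#' @export
count_canonical_mismatches <- function(dom, table = read_residue_table()) {
  stopifnot(inherits(dom, "canonical_domain"))
  mism <- vapply(seq_len(nrow(table)), function(i) {
    r <- dom$residues[table$position[i]]
    r == "-" || !(r %in% chars(table$allowed[i]))
  }, TRUE)
  c(core11 = sum(mism[table$core]), defined19 = sum(mism))
}

#' Curate a protein and its domain hit
#'
#' Flags in-frame stop codons (`*` anywhere before the final residue; a
#' trailing `*` is a normal translation artifact) and incomplete domains
#' (no hit at all, or a mapped domain with no aligned residue in the basic
#' region, first helix, or second helix). Mismatch counts to the canonical
#' residue table are recorded; the historical cutoffs (6 core / 11 defined)
#' are reported but only enforced when `enforce_cutoffs = TRUE`.
#'
#' @param protein residue string (may contain `*`).
#' @param hit `domain_hit` or NULL.
#' @param dom `canonical_domain` or NULL.
#' @param table residue table for mismatch counting.
#' @param enforce_cutoffs opt-in enforcement (default FALSE).
#' @param core_cutoff,defined_cutoff the recorded cutoffs.
#' @return an object of class `curation_verdict`: `target_id`, `passed`,
#'   `reasons`, `core11_mismatches`, `defined19_mismatches`.
#' @export
curate <- function(protein, hit = NULL, dom = NULL, table = read_residue_table(),
                   enforce_cutoffs = FALSE, core_cutoff = 6, defined_cutoff = 11) {
  reasons <- character()
  cc <- chars(protein)
  if ("*" %in% cc[-length(cc)]) reasons <- c(reasons, "internal_stop")
  incomplete <- is.null(hit) || is.null(dom)
  if (!incomplete) {
    sch <- dom$scheme
    spans <- list(sch$basic, sch$helix1, sch$helix2)
    incomplete <- any(vapply(spans, function(s) all(dom$residues[s] == "-"), TRUE))
  }
  if (incomplete) reasons <- c(reasons, "incomplete_domain")
  mm <- if (!is.null(dom)) count_canonical_mismatches(dom, table)
        else c(core11 = NA_integer_, defined19 = NA_integer_)
  if (enforce_cutoffs && !is.null(dom) &&
      (mm["core11"] >= core_cutoff || mm["defined19"] >= defined_cutoff)) {
    reasons <- c(reasons, "mismatch_cutoff")
  }
  structure(list(target_id = if (!is.null(hit)) hit$target_id
                 else if (!is.null(dom)) dom$target_id else NA_character_,
                 passed = length(reasons) == 0,
                 reasons = reasons,
                 core11_mismatches = unname(mm["core11"]),
                 defined19_mismatches = unname(mm["defined19"])),
            class = "curation_verdict")
}
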