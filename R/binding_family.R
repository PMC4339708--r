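## DNA-binding classification from basic-region residue rules, census
## tables, pairwise distances, neighbor-joining and nearest-reference
## subfamily assignment.

BINDING_CATEGORIES <- c("G_BOX_BINDER", "E_BOX_BINDER", "NON_EBOX_BINDER",
                        "NON_BINDING_HLH")

#' Predict the DNA-binding class of a bHLH domain
#'
#' Reads the rule residues at canonical positions 5, 9, 12 and 13 and the
#' basic-residue count over positions 1-13. Rules: E9 + R12 predicts E-box
#' binding; H/K5 + E9 + R13 (the raw G-box rule) narrows E-box binders to
#' G-box binders; domains without E9 are non-E-box binders when they retain
#' five or more basic residues and non-binding HLH proteins otherwise. A gap
#' at a rule position never satisfies the rule. The rare E9-without-R12
#' configuration is kept as a binder (category by basic count) with its flag
#' combination preserved; `ebox_rule` is FALSE for it.
#'
#' @param dom a `canonical_domain` with positions 1-13 mapped.
#' @param basic_set residues counted as basic (default R, K, H).
#' @return an object of class `binding_call`: `target_id`, flags `hk5`,
#'   `e9`, `r12`, `r13` (TRUE/FALSE/NA for gap), `basic_count`,
#'   `gbox_rule_raw`, `ebox_rule`, `category`.
#' @export
classify_binding <- function(dom, basic_set = c("R", "K", "H")) {
  stopifnot(inherits(dom, "canonical_domain"))
  r <- dom$residues
  flag <- function(pos, allowed) {
    if (r[pos] == "-") NA else r[pos] %in% allowed
  }
  hk5 <- flag(5, c("H", "K")); e9 <- flag(9, "E")
  r12 <- flag(12, "R"); r13 <- flag(13, "R")
  basic <- count_basic_residues(dom, basic_set)
  gbox_raw <- isTRUE(hk5) && isTRUE(e9) && isTRUE(r13)
  ebox <- isTRUE(e9) && isTRUE(r12)
  category <- if (ebox && gbox_raw) "G_BOX_BINDER"
    else if (ebox) "E_BOX_BINDER"
    else if (basic >= 5) "NON_EBOX_BINDER"
    else "NON_BINDING_HLH"
  structure(list(target_id = dom$target_id, hk5 = hk5, e9 = e9, r12 = r12,
                 r13 = r13, basic_count = basic, gbox_rule_raw = gbox_raw,
                 ebox_rule = ebox, category = category),
            class = "binding_call")
}

#' Census of binding calls
#'
#' Counts and percentages (1 decimal) of the rule flags and categories over
#' a set of binding calls; permutation-invariant. `gbox_rule_raw` (H/K5 +
#' E9 + R13 exactly as the rule is stated) is what reproduces family-wide
#' G-box candidate counts; the `G_BOX_BINDER` category additionally requires
#' R12 so that G-box binders stay a subset of E-box binders.
#'
#' @param calls list of `binding_call` objects.
#' @return data frame with columns statistic, count, pct.
#' @export
binding_census <- function(calls) {
  if (length(calls) < 1) stop("input error: no calls", call. = FALSE)
  n <- length(calls)
  g <- function(f) vapply(calls, function(x) isTRUE(x[[f]]), TRUE)
  basic <- vapply(calls, `[[`, 0, "basic_count")
  cat_ <- vapply(calls, `[[`, "", "category")
  e9 <- g("e9"); r12 <- g("r12")
  rows <- list(
    c("n", n),
    c("e9", sum(e9)),
    c("e9_r12", sum(e9 & r12)),
    c("gbox_rule_raw", sum(g("gbox_rule_raw"))),
    c("e9_not_r12", sum(e9 & !r12)),
    c("no_e9_basic_ge5", sum(!e9 & basic >= 5)),
    c("basic_le4", sum(!e9 & basic <= 4))
  )
  for (cat in BINDING_CATEGORIES) rows[[length(rows) + 1]] <- c(cat, sum(cat_ == cat))
  out <- data.frame(statistic = vapply(rows, `[`, "", 1),
                    count = as.integer(vapply(rows, `[`, "", 2)),
                    stringsAsFactors = FALSE)
  out$pct <- fmt_pct(out$count / n)
  out
}

#' Pairwise distances between aligned canonical domains
#'
#' p-distance (mismatches over shared non-gap columns), optionally
#' Poisson-corrected (`-ln(1 - p)`). Pairs sharing fewer than 20 columns
#' are flagged in the `"low_overlap"` attribute; a pair with zero shared
#' columns is an error.
#'
#' @param domains list of `canonical_domain` objects on an identical column
#'   set, or a character matrix of aligned rows.
#' @param model `"p"` (default) or `"poisson"`.
#' @return symmetric matrix with zero diagonal; attributes `model` and
#'   `low_overlap` (data frame of flagged pairs).
#' @export
pairwise_distances <- function(domains, model = c("p", "poisson")) {
  model <- match.arg(model)
  m <- if (is.matrix(domains)) domains
       else do.call(rbind, lapply(domains, `[[`, "residues"))
  ids <- if (is.matrix(domains)) rownames(domains)
         else vapply(domains, `[[`, "", "target_id")
  n <- nrow(m)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  low <- NULL
  for (i in seq_len(n)) for (j in seq_len(n)) if (j > i) {
    shared <- m[i, ] != "-" & m[j, ] != "-"
    ns <- sum(shared)
    if (ns == 0)
      stop(sprintf("undefined-distance error: '%s' and '%s' share no columns",
                   ids[i], ids[j]), call. = FALSE)
    p <- sum(m[i, shared] != m[j, shared]) / ns
    d <- if (model == "poisson") {
      if (p >= 1) stop("undefined-distance error: p-distance 1 cannot be Poisson-corrected",
                       call. = FALSE)
      -log(1 - p)
    } else p
    D[i, j] <- D[j, i] <- d
    if (ns < 20) low <- rbind(low, data.frame(a = ids[i], b = ids[j], shared = ns))
  }
  attr(D, "model") <- model
  attr(D, "low_overlap") <- low
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor-joining agglomeration with a deterministic tie-break
#' (smallest Q, ties resolved to the lexicographically smallest joined
#' pair). Exactly recovers the generating topology on additive matrices.
#'
#' @param dm symmetric distance matrix with row/column names (>= 3 taxa).
#' @return an [ape::read.tree()] `phylo` object (unrooted, branch lengths).
#' @export
nj_tree <- function(dm) {
  ids <- rownames(dm)
  if (is.null(ids)) ids <- colnames(dm)
  n <- nrow(dm)
  if (n < 3) stop("input error: neighbor-joining needs at least 3 taxa", call. = FALSE)
  stopifnot(nrow(dm) == ncol(dm))
  D <- dm
  # working labels double as growing Newick fragments
  lab <- ids
  key <- ids   # lexicographic tie-break keys (smallest member of each cluster)
  fmt <- function(x) formatC(x, digits = 10, format = "g")
  while (nrow(D) > 3) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    pk <- apply(cand, 1, function(ij) {
      k <- sort(c(key[ij[1]], key[ij[2]])); paste(k, collapse = "\r")
    })
    pick <- cand[order(pk)[1], ]
    i <- pick[1]; j <- pick[2]
    vi <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    vj <- D[i, j] - vi
    newlab <- sprintf("(%s:%s,%s:%s)", lab[i], fmt(vi), lab[j], fmt(vj))
    newkey <- min(key[i], key[j])
    dnew <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]), c(dnew[keep], 0))
    lab <- c(lab[keep], newlab)
    key <- c(key[keep], newkey)
    D <- D2
  }
  d12 <- D[1, 2]; d13 <- D[1, 3]; d23 <- D[2, 3]
  v1 <- (d12 + d13 - d23) / 2
  v2 <- (d12 + d23 - d13) / 2
  v3 <- (d13 + d23 - d12) / 2
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);", lab[1], fmt(v1), lab[2], fmt(v2),
                 lab[3], fmt(v3))
  ape::read.tree(text = nwk)
}

#' Read labelled family reference domains
#'
#' Aligned FASTA whose headers encode the family as `FAMILY|id`.
#'
#' @param path aligned FASTA.
#' @return data frame with columns family, id and a `residues` character
#'   matrix attribute (one aligned row per reference).
#' @export
read_family_references <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  hdr <- strsplit(names(ss), "|", fixed = TRUE)
  fam <- vapply(hdr, `[`, "", 1)
  id <- vapply(hdr, function(h) paste(h[-1], collapse = "|"), "")
  m <- do.call(rbind, lapply(as.character(ss), function(s) check_aligned_row(s, s, 1L)))
  rownames(m) <- id
  out <- data.frame(family = fam, id = id, stringsAsFactors = FALSE)
  attr(out, "residues") <- m
  out
}

#' Assign a bHLH subfamily by distance to reference exemplars
#'
#' The family of the minimum-distance reference wins; the margin to the best
#' reference of any *other* family measures confidence. An assignment is
#' ambiguous when the margin falls below `margin_threshold` and no
#' family-diagnostic motif corroborates the winner. Distance ties (within
#' 1e-12) are broken to the lexicographically smaller family label. A family
#' is never returned unless a reference for it was supplied.
#'
#' @param dom a `canonical_domain`.
#' @param references a [read_family_references()] table.
#' @param motif_hits optional data frame from [scan_motifs()].
#' @param intron_pattern optional intron-pattern label, recorded in the
#'   assignment for downstream corroboration (not used in the distance call).
#' @param margin_threshold subst/site margin below which the call is
#'   ambiguous without motif support (default 0.05).
#' @param motif_family_map named character vector mapping diagnostic motif
#'   names to family labels (default: Motif40 -> X).
#' @param motif_max_evalue motif corroboration threshold (default 1e-7).
#' @param model distance model passed to the per-pair computation.
#' @return an object of class `family_assignment`: `target_id`, `family`,
#'   `nearest_reference`, `distance`, `margin`, `motif_support`,
#'   `intron_pattern`, `ambiguous`.
#' @export
assign_family <- function(dom, references, motif_hits = NULL,
                          intron_pattern = NULL, margin_threshold = 0.05,
                          motif_family_map = c(Motif40 = "X"),
                          motif_max_evalue = 1e-7,
                          model = c("p", "poisson")) {
  model <- match.arg(model)
  if (nrow(references) < 1) stop("input error: no references", call. = FALSE)
  refs <- attr(references, "residues")
  q <- dom$residues
  dist_one <- function(row) {
    shared <- q != "-" & row != "-"
    if (!sum(shared)) return(NA_real_)
    p <- sum(q[shared] != row[shared]) / sum(shared)
    if (model == "poisson") -log(1 - p) else p
  }
  d <- apply(refs, 1, dist_one)
  # ties within 1e-12 break to the smaller family label
  ord <- order(round(d, 12), references$family, references$id)
  best <- ord[1]
  fam <- references$family[best]
  other <- which(references$family != fam)
  margin <- if (length(other)) min(d[other], na.rm = TRUE) - d[best] else Inf
  support <- character()
  if (!is.null(motif_hits) && nrow(motif_hits)) {
    ok <- motif_hits$motif %in% names(motif_family_map) &
      motif_family_map[motif_hits$motif] == fam &
      (is.na(motif_hits$evalue) | motif_hits$evalue <= motif_max_evalue)
    ok[is.na(ok)] <- FALSE
    support <- motif_hits$motif[ok]
  }
  ambiguous <- margin < margin_threshold && length(support) == 0
  structure(list(target_id = dom$target_id, family = fam,
                 nearest_reference = references$id[best],
                 distance = unname(d[best]), margin = unname(margin),
                 motif_support = support,
                 intron_pattern = intron_pattern,
                 ambiguous = ambiguous),
            class = "family_assignment")
}
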