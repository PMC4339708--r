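## Synthetic gene-family generator: proteomes with planted HLH domains of
## known binding class and family, decoys, gene models with chosen intron
## patterns, homeolog copies at controlled CDS identity, and expression
## matrices with planted tissue specificity — all with a ground-truth
## manifest, byte-identical under a fixed seed.

#' Subfamily labels used by the generator and reference set
#'
#' Fifteen of the classical plant bHLH subfamily labels. Family XIV is
#' deliberately absent (soybean lacks it), so no synthetic gene or
#' reference ever carries it.
#' @export
FAMILY_SET <- c("Ia", "Ib", "II", "III", "IV", "V", "VI", "VIIa/b", "VIII",
                "IX", "X", "XI", "XII", "XIII", "XV")

RULE_POSITIONS <- c(5L, 9L, 12L, 13L)
ANCHOR_POSITIONS <- c(23L, 45L, 52L, 55L)

#' Generator configuration
#'
#' Defaults emulate the reported composition of the soybean bHLH family:
#' binding-category mix ~58/18/3/21%, intron patterns A 31% / D 43% /
#' B+C+E 4% / F+G+H+other ~9% / none 12%, homeolog copy-number spectrum
#' over {1,2,3,4,6}, and expression categories with ~88% of genes showing
#' expression. All mixes are configurable; the seed is mandatory.
#'
#' @param seed integer seed driving every random draw.
#' @param n_bhlh number of bHLH genes (default 200).
#' @param n_decoys number of domain-free decoy proteins (default 300).
#' @param mutation_rate per-site amino-acid substitution rate away from the
#'   family consensus at non-rule positions (default 0.05).
#' @param family_mix named probabilities over [FAMILY_SET] (default uniform).
#' @param binding_mix named probabilities over binding categories.
#' @param intron_mix named probabilities over intron patterns A-H/NONE/OTHER.
#' @param copy_spectrum named probabilities of a gene living in a group of
#'   the given copy number.
#' @param target_identity percent CDS identity of homeolog copies to the
#'   group's first member (default 95, tolerance ±1).
#' @param expression_mix named probabilities over expression categories.
#' @param expression_noise multiplicative log-normal noise sd (default 0.10).
#' @param n_internal_stop,n_truncated planted curation failures (default 5 each).
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(seed,
                             n_bhlh = 200L,
                             n_decoys = 300L,
                             mutation_rate = 0.05,
                             family_mix = NULL,
                             binding_mix = c(G_BOX_BINDER = 0.583,
                                             E_BOX_BINDER = 0.182,
                                             NON_EBOX_BINDER = 0.025,
                                             NON_BINDING_HLH = 0.210),
                             intron_mix = c(A = 0.310, B = 0.013, C = 0.013,
                                            D = 0.430, E = 0.014, F = 0.029,
                                            G = 0.029, H = 0.020, NONE = 0.122,
                                            OTHER = 0.020),
                             copy_spectrum = c(`1` = 0.33, `2` = 0.42,
                                               `3` = 0.07, `4` = 0.16,
                                               `6` = 0.02),
                             target_identity = 95,
                             expression_mix = c(NOT_EXPRESSED = 0.119,
                                                UBIQUITOUS = 0.414,
                                                TISSUE_RESTRICTED = 0.395,
                                                NODULE_PREFERENTIAL = 0.016,
                                                SEED_ENRICHED = 0.047,
                                                POD_WALL_ONLY = 0.009),
                             expression_noise = 0.10,
                             n_internal_stop = 5L,
                             n_truncated = 5L) {
  if (missing(seed)) stop("config error: seed is mandatory", call. = FALSE)
  if (is.null(family_mix))
    family_mix <- setNames(rep(1 / length(FAMILY_SET), length(FAMILY_SET)), FAMILY_SET)
  for (mx in list(family_mix, binding_mix, intron_mix, copy_spectrum, expression_mix)) {
    if (abs(sum(mx) - 1) > 1e-6)
      stop("config error: a mix does not sum to 1", call. = FALSE)
  }
  structure(list(seed = as.integer(seed), n_bhlh = as.integer(n_bhlh),
                 n_decoys = as.integer(n_decoys), mutation_rate = mutation_rate,
                 family_mix = family_mix, binding_mix = binding_mix,
                 intron_mix = intron_mix, copy_spectrum = copy_spectrum,
                 target_identity = target_identity,
                 expression_mix = expression_mix,
                 expression_noise = expression_noise,
                 n_internal_stop = as.integer(n_internal_stop),
                 n_truncated = as.integer(n_truncated)),
            class = "generator_config")
}

## substitute positions (never to the same residue); protect_idx untouched
.mutate_chars <- function(cc, rate, protect_idx = integer()) {
  idx <- setdiff(seq_along(cc), protect_idx)
  hit <- idx[runif(length(idx)) < rate]
  for (i in hit) cc[i] <- sample(setdiff(AA_ALPHABET, cc[i]), 1)
  cc
}

#' Family consensus domain
#'
#' Deterministic 55-residue consensus per subfamily: the canonical
#' consensus with a fixed set of family-specific substitutions outside the
#' rule and anchor positions (~15% of helix/loop columns differ between
#' families).
#'
#' @param family a label from [FAMILY_SET].
#' @return 55-character residue string.
#' @export
family_consensus <- function(family) {
  i <- match(family, FAMILY_SET)
  if (is.na(i)) stop(sprintf("config error: unknown family '%s'", family), call. = FALSE)
  withr::with_seed(74000L + i, {
    cc <- chars(CANONICAL_CONSENSUS)
    mutable <- setdiff(14:55, ANCHOR_POSITIONS)
    at <- sort(sample(mutable, 8))
    for (p in at) cc[p] <- sample(setdiff(AA_ALPHABET, cc[p]), 1)
    paste(cc, collapse = "")
  })
}

## per-category basic-region template applied over a family consensus
.apply_binding_category <- function(cc, category) {
  switch(category,
    G_BOX_BINDER = {
      cc[5] <- sample(c("H", "K"), 1); cc[9] <- "E"; cc[12] <- "R"; cc[13] <- "R"
    },
    E_BOX_BINDER = {
      cc[5] <- "A"; cc[9] <- "E"; cc[12] <- "R"; cc[13] <- "Q"
    },
    NON_EBOX_BINDER = {
      cc[9] <- "Q"; cc[5] <- "H"; cc[12] <- "R"; cc[13] <- "R"
    },
    NON_BINDING_HLH = {
      cc[1:13] <- chars("ADRSANQSQRASQ")  # two basic residues, no E9
    },
    stop(sprintf("config error: unknown binding category '%s'", category),
         call. = FALSE)
  )
  cc
}

## canonical-position -> within-domain offset map for a loop of length d
.domain_layout <- function(d) {
  off <- rep(NA_integer_, 55)
  off[1:28] <- 1:28
  k <- min(d, 12L)
  if (k > 0) off[29:(28 + k)] <- 28L + seq_len(k)
  extra <- max(0L, d - 12L)           # insertions sit between loop and helix2
  off[41:55] <- 28L + d + 1:15
  attr(off, "domain_length") <- 28L + d + 15L
  attr(off, "n_insert") <- extra
  off
}

#' Generate one synthetic bHLH domain
#'
#' Starts from the family consensus, stamps the basic-region template of
#' the requested binding category (rule positions 5/9/12/13 are set exactly
#' and protected from mutation), draws the hydrophobic anchors 23/45/52/55
#' with probability 0.97, draws a loop length uniformly in 5-14, and
#' mutates the remaining positions at `mutation_rate`.
#'
#' @param family a [FAMILY_SET] label.
#' @param binding_category one of the four binding categories.
#' @param mutation_rate per-site substitution rate.
#' @param seed optional integer; when given the draw is deterministic.
#' @param loop_length optional fixed loop length (otherwise drawn).
#' @param basic_count optional requested basic-residue count, checked for
#'   consistency with the category (config error if contradictory).
#' @return list with `seq` (ungapped residue string), `row` (55-column
#'   gapped canonical row), `loop_length`, `offsets` (canonical ->
#'   within-domain offsets), `category`, `family`.
#' @export
generate_domain <- function(family, binding_category, mutation_rate = 0.05,
                            seed = NULL, loop_length = NULL, basic_count = NULL) {
  if (!is.null(basic_count)) {
    need_binder <- binding_category %in% c("G_BOX_BINDER", "E_BOX_BINDER",
                                           "NON_EBOX_BINDER")
    if (need_binder && basic_count <= 4)
      stop("config error: a DNA-binding category needs > 4 basic residues",
           call. = FALSE)
    if (!need_binder && basic_count >= 5)
      stop("config error: NON_BINDING_HLH needs <= 4 basic residues", call. = FALSE)
  }
  run <- function() {
    cc <- chars(family_consensus(family))
    cc <- .apply_binding_category(cc, binding_category)
    cc[23] <- if (runif(1) < 0.97) "L" else sample(AA_ALPHABET, 1)
    for (p in c(45L, 52L)) {
      cc[p] <- if (runif(1) < 0.97) sample(c("I", "L", "V"), 1) else sample(AA_ALPHABET, 1)
    }
    cc[55] <- if (runif(1) < 0.97) "L" else sample(AA_ALPHABET, 1)
    protect <- if (binding_category == "NON_BINDING_HLH") c(1:13) else RULE_POSITIONS
    cc <- .mutate_chars(cc, mutation_rate, protect_idx = protect)
    d <- if (is.null(loop_length)) sample(5:14, 1) else as.integer(loop_length)
    loop_res <- cc[29:40]
    kept <- loop_res[seq_len(min(d, 12L))]
    extra <- if (d > 12) sample(AA_ALPHABET, d - 12L, replace = TRUE) else character()
    seqc <- c(cc[1:28], kept, extra, cc[41:55])
    row <- cc
    if (d < 12) row[(28 + d + 1):40] <- "-"
    row[29:(28 + min(d, 12L))] <- kept
    list(seq = paste(seqc, collapse = ""), row = paste(row, collapse = ""),
         loop_length = d, offsets = .domain_layout(d),
         category = binding_category, family = family)
  }
  if (!is.null(seed)) withr::with_seed(as.integer(seed), run()) else run()
}

## sample a category vector from a named mix, deterministically under the
## ambient RNG, with counts as close to n * mix as rounding allows
.mix_counts <- function(mix, n) {
  cnt <- floor(mix * n)
  rem <- n - sum(cnt)
  if (rem > 0) {
    frac <- mix * n - cnt
    add <- order(frac, names(mix), decreasing = TRUE)[seq_len(rem)]
    cnt[add] <- cnt[add] + 1
  }
  cnt
}

#' Generate a synthetic proteome with ground truth
#'
#' Plans homeolog groups from the copy-number spectrum (group members share
#' family, binding category, intron pattern and domain ancestry), embeds
#' generated domains in random flanks, plants Motif 40 in the C-terminal
#' flank of every Family X gene, adds domain-free decoys and the configured
#' curation failures (an internal `*`; a domain truncated before the second
#' helix).
#'
#' @param cfg a [generator_config()].
#' @return list with `proteins` (named residue strings, sorted by id),
#'   `manifest` (ground-truth data frame), `domains` (per-gene generated
#'   domain objects), `groups` (named list: group id -> member ids).
#' @export
generate_proteome <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  withr::with_seed(cfg$seed, {
    n <- cfg$n_bhlh
    ids <- if (n > 0) sprintf("synb%04d", seq_len(n)) else character()
    # --- plan homeolog groups
    copy_sizes <- as.integer(names(cfg$copy_spectrum))
    gene_target <- .mix_counts(cfg$copy_spectrum, n)
    group_plan <- integer()
    for (k in order(copy_sizes, decreasing = TRUE)) {
      cs <- copy_sizes[k]
      if (cs <= 1) next
      ng <- gene_target[k] %/% cs
      group_plan <- c(group_plan, rep(cs, ng))
    }
    assigned <- sum(group_plan)
    n_singles <- n - assigned
    sizes <- c(group_plan, rep(1L, n_singles))
    # --- plant curation failures on trailing singleton genes
    n_fail <- cfg$n_internal_stop + cfg$n_truncated
    if (n_fail > n_singles)
      stop("config error: not enough singleton genes for the planted failures",
           call. = FALSE)
    group_ids <- sprintf("HG%04d", seq_along(sizes))
    members <- split(ids, rep(seq_along(sizes), sizes))
    names(members) <- group_ids
    fate <- setNames(rep("clean", n), ids)
    if (n_fail > 0) {
      tail_ids <- ids[seq.int(n - n_fail + 1L, n)]
      if (cfg$n_internal_stop > 0)
        fate[tail_ids[seq_len(cfg$n_internal_stop)]] <- "internal_stop"
      if (cfg$n_truncated > 0)
        fate[tail_ids[cfg$n_internal_stop + seq_len(cfg$n_truncated)]] <- "truncated_domain"
    }
    # --- per-group draws
    fam_draw <- sample(names(cfg$family_mix), length(sizes), replace = TRUE,
                       prob = cfg$family_mix)
    bind_pool <- sample(rep(names(cfg$binding_mix), .mix_counts(cfg$binding_mix, length(sizes))))
    intr_pool <- sample(rep(names(cfg$intron_mix), .mix_counts(cfg$intron_mix, length(sizes))))
    expr_draw <- sample(rep(names(cfg$expression_mix), .mix_counts(cfg$expression_mix, n)))
    motif40 <- toupper("GLCLVPVScTqqVgseNGADYWAPayggg")

    proteins <- character(0)
    manifest <- list()
    domains <- list()
    expr_i <- 0L
    for (gi in seq_along(sizes)) {
      g_fam <- fam_draw[gi]; g_bind <- bind_pool[gi]; g_pat <- intr_pool[gi]
      d_anc <- generate_domain(g_fam, g_bind, cfg$mutation_rate)
      flank_n <- paste(sample(AA_ALPHABET, sample(40:150, 1), replace = TRUE), collapse = "")
      flank_c <- paste(sample(AA_ALPHABET, sample(40:150, 1), replace = TRUE), collapse = "")
      if (g_fam == "X") {
        # plant the diagnostic motif a fixed distance into the C flank
        flank_c <- paste0(substr(flank_c, 1, 10), motif40,
                          substr(flank_c, 11, nchar(flank_c)))
      }
      for (m in members[[group_ids[gi]]]) {
        dm <- if (m == members[[group_ids[gi]]][1]) d_anc else {
          # copies diverge from the first member at the same rate, same loop;
          # rule positions (whole basic region for non-binders) stay fixed
          keep <- if (g_bind == "NON_BINDING_HLH") 1:13 else RULE_POSITIONS
          vcc <- .mutate_chars(chars(d_anc$seq), cfg$mutation_rate,
                               protect_idx = unname(d_anc$offsets[keep]))
          list(seq = paste(vcc, collapse = ""),
               row = {
                 rr <- chars(d_anc$row); nz <- which(rr != "-")
                 rr[nz] <- vcc[stats::na.omit(d_anc$offsets)]
                 paste(rr, collapse = "")
               },
               loop_length = d_anc$loop_length, offsets = d_anc$offsets,
               category = g_bind, family = g_fam)
        }
        expr_i <- expr_i + 1L
        g_fate <- fate[[m]]
        prot <- paste0(flank_n, dm$seq, flank_c)
        dstart <- nchar(flank_n) + 1L
        dend <- nchar(flank_n) + nchar(dm$seq)
        if (g_fate == "internal_stop") {
          prot <- paste0(substr(prot, 1, 12), "*", substr(prot, 13, nchar(prot)))
          dstart <- dstart + 1L; dend <- dend + 1L
        } else if (g_fate == "truncated_domain") {
          # cut inside the loop: basic + helix1 present, helix2 missing
          cut <- nchar(flank_n) + 30L
          prot <- substr(prot, 1, cut)
          dend <- cut
        }
        proteins[m] <- prot
        domains[[m]] <- dm
        manifest[[m] ] <- data.frame(
          gene_id = m, fate = g_fate, family = g_fam,
          binding_category = g_bind,
          intron_pattern = if (g_fate == "clean") g_pat else "NONE",
          homeolog_group = group_ids[gi], copy_number = sizes[gi],
          expression_category = expr_draw[expr_i],
          domain_start = dstart, domain_end = dend,
          loop_length = dm$loop_length, protein_length = nchar(prot),
          stringsAsFactors = FALSE)
      }
    }
    for (k in seq_len(cfg$n_decoys)) {
      m <- sprintf("synd%04d", k)
      proteins[m] <- paste(sample(AA_ALPHABET, sample(200:500, 1), replace = TRUE),
                           collapse = "")
      manifest[[m]] <- data.frame(
        gene_id = m, fate = "decoy", family = NA_character_,
        binding_category = NA_character_, intron_pattern = NA_character_,
        homeolog_group = NA_character_, copy_number = NA_integer_,
        expression_category = NA_character_,
        domain_start = NA_integer_, domain_end = NA_integer_,
        loop_length = NA_integer_, protein_length = nchar(proteins[m]),
        stringsAsFactors = FALSE)
    }
    manifest <- do.call(rbind, manifest[order(names(manifest))])
    rownames(manifest) <- NULL
    proteins <- proteins[order(names(proteins))]
    list(proteins = proteins, manifest = manifest, domains = domains,
         groups = members, config = cfg)
  })
}

## deterministic codon table: lexicographically first codon per amino acid,
## remaining codons as the synonymous pool
.codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  by_aa <- split(names(gc), gc)
  list(primary = vapply(by_aa, function(x) sort(x)[1], ""),
       pool = lapply(by_aa, sort))
}

## canonical positions at which each intron pattern plants introns
.pattern_positions <- function(pattern, defs) {
  cv <- defs$canonical
  switch(pattern,
    A = unname(cv), B = unname(cv[c("c1", "c2")]), C = unname(cv[c("c1", "c3")]),
    D = unname(cv["c1"]), E = unname(cv[c("c2", "c3")]),
    F = defs$alt_position, G = defs$g_positions, H = defs$g_positions[1],
    NONE = integer(),
    OTHER = c(unname(cv), 47L),
    stop(sprintf("config error: pattern '%s' has no defined positions", pattern),
         call. = FALSE))
}

#' Generate GFF3 gene models and CDS consistent with a synthetic proteome
#'
#' Reverse-translates each protein with a deterministic codon table and
#' inserts introns (phase 0) after the codons of the planted canonical
#' positions. Every gene sits on its own scaffold; strands alternate so
#' both orientations are exercised. Decoys and truncated genes are
#' single-exon.
#'
#' @param proteome output of [generate_proteome()].
#' @param defs an [intron_pattern_def()] giving the canonical positions.
#' @return list with `gff` (character vector of GFF3 lines), `cds` (named
#'   DNA strings, including the stop codon).
#' @export
generate_gene_models <- function(proteome, defs = intron_pattern_def()) {
  ct <- .codon_table()
  manifest <- proteome$manifest
  gff <- c("##gff-version 3")
  cds_out <- character()
  withr::with_seed(proteome$config$seed + 1L, {
    for (i in seq_len(nrow(manifest))) {
      g <- manifest$gene_id[i]
      prot <- proteome$proteins[[g]]
      aa <- chars(prot)
      codons <- unname(ct$primary[aa])
      codons[aa == "*"] <- "TAA"
      cds <- paste(c(codons, "TAA"), collapse = "")
      cds_out[g] <- cds
      plen <- nchar(cds)
      # intron protein positions from the planted pattern
      ipos <- integer()
      if (!is.na(manifest$fate[i]) && manifest$fate[i] %in% c("clean")) {
        pat <- manifest$intron_pattern[i]
        dm <- proteome$domains[[g]]
        canon <- .pattern_positions(pat, defs)
        off <- dm$offsets
        ipos <- sort(manifest$domain_start[i] - 1L + off[canon])
        ipos <- ipos[!is.na(ipos)]
      }
      cut_nt <- 3L * ipos                      # phase-0 splice after these codons
      bounds <- c(0L, cut_nt, plen)
      seg_len <- diff(bounds)
      intron_len <- if (length(ipos)) 100L + 7L * seq_along(ipos) else integer()
      strand <- if (i %% 2 == 0) "-" else "+"
      gstart <- 1001L
      span <- sum(seg_len) + sum(intron_len)
      # transcription-order offsets -> genomic intervals (1-based inclusive)
      tx_start <- cumsum(c(0L, head(seg_len, -1) + intron_len))
      if (strand == "+") {
        s <- gstart + tx_start
        e <- s + seg_len - 1L
      } else {
        e <- gstart + span - 1L - tx_start
        s <- e - seg_len + 1L
      }
      phase <- (3L - (cumsum(c(0L, head(seg_len, -1))) %% 3L)) %% 3L
      seqid <- paste0("scaf_", g)
      lines <- c(
        sprintf("%s\tbhlhsim\tgene\t%d\t%d\t.\t%s\t.\tID=%s", seqid, gstart,
                gstart + span - 1L, strand, g),
        sprintf("%s\tbhlhsim\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.t1;Parent=%s", seqid,
                gstart, gstart + span - 1L, strand, g, g),
        sprintf("%s\tbhlhsim\texon\t%d\t%d\t.\t%s\t.\tParent=%s.t1",
                seqid, pmin(s, e), pmax(s, e), strand, g),
        sprintf("%s\tbhlhsim\tCDS\t%d\t%d\t.\t%s\t%d\tParent=%s.t1",
                seqid, pmin(s, e), pmax(s, e), strand, phase, g)
      )
      gff <- c(gff, lines)
    }
  })
  list(gff = gff, cds = cds_out[order(names(cds_out))])
}

## percent identity of two equal-length ungapped sequences
.seq_identity <- function(a, b) {
  ca <- chars(a); cb <- chars(b)
  stopifnot(length(ca) == length(cb))
  100 * mean(ca == cb)
}

#' Tune homeolog CDS identity and generate evidence + expression tables
#'
#' Applies synonymous codon substitutions to non-first group members until
#' their CDS identity to the first member reaches the configured target
#' (±1%), emits homeolog-evidence rows (all within-group pairs with their
#' measured identities and the group's duplication-block id), and draws the
#' expression matrix from the planted categories with multiplicative
#' log-normal noise.
#'
#' @param proteome output of [generate_proteome()].
#' @param models output of [generate_gene_models()] for the same proteome.
#' @return list with `cds` (tuned named DNA strings), `evidence` (data
#'   frame gene_a/gene_b/pident/block_id), `expression` (numeric matrix,
#'   genes x tissues).
#' @export
generate_homeologs_and_expression <- function(proteome, models) {
  cfg <- proteome$config
  ct <- .codon_table()
  cds <- models$cds
  evidence <- list()
  withr::with_seed(cfg$seed + 2L, {
    for (gid in names(proteome$groups)) {
      mem <- proteome$groups[[gid]]
      if (length(mem) < 2) next
      ref <- cds[[mem[1]]]
      for (m in mem[-1]) {
        cur <- chars(cds[[m]])
        refc <- chars(ref)
        target <- cfg$target_identity
        ident <- 100 * mean(cur == refc)
        # walk codons in random order, swapping to a synonymous alternative
        n_cod <- length(cur) %/% 3L
        order_cod <- sample(n_cod)
        k <- 1L
        while (ident > target + 1 && k <= n_cod) {
          ci <- order_cod[k]; k <- k + 1L
          idx <- (3L * (ci - 1L) + 1L):(3L * ci)
          cod <- paste(cur[idx], collapse = "")
          aa <- as.character(Biostrings::GENETIC_CODE[cod])
          if (is.na(aa)) next
          alts <- setdiff(ct$pool[[aa]], cod)
          if (!length(alts)) next
          cur[idx] <- chars(sample(alts, 1))
          ident <- 100 * mean(cur == refc)
        }
        cds[[m]] <- paste(cur, collapse = "")
      }
      pairs <- utils::combn(mem, 2)
      for (pc in seq_len(ncol(pairs))) {
        a <- pairs[1, pc]; b <- pairs[2, pc]
        evidence[[length(evidence) + 1]] <- data.frame(
          gene_a = a, gene_b = b,
          pident = round(.seq_identity(cds[[a]], cds[[b]]), 2),
          block_id = paste0("BLK_", gid), stringsAsFactors = FALSE)
      }
    }
    evidence <- if (length(evidence)) do.call(rbind, evidence)
      else data.frame(gene_a = character(), gene_b = character(),
                      pident = numeric(), block_id = character())
    # --- expression
    manifest <- proteome$manifest
    bh <- manifest[manifest$fate != "decoy", , drop = FALSE]
    tmpl <- list(
      NOT_EXPRESSED       = c(0, 0, 0, 0, 0, 0, 0),
      UBIQUITOUS          = c(20, 5, 20, 5, 20, 5, 5),
      TISSUE_RESTRICTED   = c(20, 0, 0, 0, 0, 0, 0),
      NODULE_PREFERENTIAL = c(10, 50, 0, 0, 0, 0, 0),
      SEED_ENRICHED       = c(10, 0, 8, 40, 100, 60, 0),
      POD_WALL_ONLY       = c(0, 0, 0, 0, 0, 0, 20))
    tissues <- EXPRESSION_TISSUES[c(1, 2, 3, 4, 5, 6, 7)]
    # template order: root nodule leaf seed_early seed_mid seed_late pod_wall
    expr <- matrix(0, nrow(bh), 7, dimnames = list(bh$gene_id, tissues))
    for (r in seq_len(nrow(bh))) {
      base <- tmpl[[bh$expression_category[r]]]
      noise <- exp(rnorm(7, 0, cfg$expression_noise))
      expr[r, ] <- round(base * noise, 3)
    }
  })
  list(cds = cds[order(names(cds))], evidence = evidence, expression = expr)
}

#' Generate and write a complete synthetic analysis bundle
#'
#' Writes, with fixed formatting and sorted record order (byte-identical
#' under a fixed seed): the proteome FASTA, tuned CDS FASTA, GFF3 gene
#' models, a 55-column training alignment of family consensus domains (3
#' rows per family), the Motif 40 alignment (Stockholm), labelled family
#' reference domains, homeolog evidence TSV, expression TSV, and the
#' ground-truth manifest JSON (schema "bhlh-truth/1").
#'
#' @param cfg a [generator_config()].
#' @param dir output directory (created if needed).
#' @return invisibly, a named list of the file paths plus the in-memory
#'   objects (`proteome`, `models`, `aux`).
#' @export
generate_bundle <- function(cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  proteome <- generate_proteome(cfg)
  models <- generate_gene_models(proteome)
  aux <- generate_homeologs_and_expression(proteome, models)
  p <- function(f) file.path(dir, f)

  write_fasta <- function(x, path) {
    writeLines(as.vector(rbind(paste0(">", names(x)), unname(x))), path)
  }
  write_fasta(proteome$proteins, p("proteins.faa"))
  write_fasta(aux$cds, p("cds.fna"))
  writeLines(models$gff, p("genes.gff3"))

  # training alignment: per family the consensus plus two 5%-divergent rows
  train <- withr::with_seed(cfg$seed + 3L, {
    ids <- character(); seqs <- character()
    for (f in FAMILY_SET) {
      cons <- family_consensus(f)
      safe <- gsub("[^A-Za-z]", "_", f)
      ids <- c(ids, sprintf("train_%s_%d", safe, 1:3))
      seqs <- c(seqs, cons,
                paste(.mutate_chars(chars(cons), 0.05, RULE_POSITIONS), collapse = ""),
                paste(.mutate_chars(chars(cons), 0.05, RULE_POSITIONS), collapse = ""))
    }
    motif_alignment("HLH_domain", ids, seqs)
  })
  write_motif_alignment(train, p("domain_training.afa"))

  motif40 <- toupper("GLCLVPVScTqqVgseNGADYWAPayggg")
  m40 <- withr::with_seed(cfg$seed + 4L, {
    v1 <- paste(.mutate_chars(chars(motif40), 0.05), collapse = "")
    v2 <- paste(.mutate_chars(chars(motif40), 0.05), collapse = "")
    c(motif40, v1, v2)
  })
  writeLines(c("# STOCKHOLM 1.0", "#=GF ID Motif40",
               sprintf("m40_%d  %s", 1:3, m40), "//"), p("motifs.sto"))

  refs <- vapply(FAMILY_SET, family_consensus, "")
  write_fasta(setNames(refs, sprintf("%s|ref_%s", FAMILY_SET,
                                     gsub("[^A-Za-z]", "_", FAMILY_SET))),
              p("family_refs.afa"))

  ev <- aux$evidence
  ev$pident <- sprintf("%.2f", ev$pident)
  write.table(ev, p("homeolog_evidence.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  expr_df <- data.frame(gene_id = rownames(aux$expression),
                        aux$expression, check.names = FALSE)
  expr_df[-1] <- lapply(expr_df[-1], function(x) sprintf("%.3f", x))
  write.table(expr_df, p("expression.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  jsonlite::write_json(
    list(schema = "bhlh-truth/1",
         seed = cfg$seed,
         n_bhlh = cfg$n_bhlh, n_decoys = cfg$n_decoys,
         mutation_rate = cfg$mutation_rate,
         target_identity = cfg$target_identity,
         expression_noise = cfg$expression_noise,
         background = "uniform over the 20 amino acids",
         genes = proteome$manifest),
    p("manifest.json"), auto_unbox = TRUE, digits = NA, na = "null")

  invisible(list(dir = dir,
                 proteins = p("proteins.faa"), cds = p("cds.fna"),
                 gff = p("genes.gff3"), training = p("domain_training.afa"),
                 motifs = p("motifs.sto"), family_refs = p("family_refs.afa"),
                 evidence = p("homeolog_evidence.tsv"),
                 expression = p("expression.tsv"), manifest = p("manifest.json"),
                 proteome = proteome, models = models, aux = aux))
}

#' Read a ground-truth manifest written by [generate_bundle()]
#' @param path manifest.json path.
#' @return the per-gene ground-truth data frame.
#' @export
read_manifest <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$schema, "bhlh-truth/1"))
    stop("input error: not a bhlh-truth/1 document", call. = FALSE)
  doc$genes
}
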