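## Profile hidden Markov models: build from a motif alignment, local Viterbi
## search, empirical E-value calibration, and multi-model motif scanning.
## This is the package's own implementation (match/insert/delete nodes,
## log2-odds scoring); it is not a wrapper around an external search tool.

#' Build a profile HMM from a motif alignment
#'
#' Columns whose gap fraction is below `match_threshold` become match states;
#' the remaining columns feed the insert state of the preceding match node.
#' Counts are turned into probabilities with the named pseudocount scheme.
#'
#' @param aln a [motif_alignment()].
#' @param match_threshold columns with gap fraction < this value become match
#'   states. Default 0.5, the conventional rule.
#' @param pseudocount `"laplace"` (add 1 to emission counts, 0.1 to
#'   transition counts; default) or `"none"` (raw frequencies; zero
#'   probabilities possible and scored as -Inf).
#' @param background length-20 background distribution; default uniform.
#' @return an object of class `profile_hmm` with elements `name`, `L`,
#'   `match_emissions` (L x 20), `insert_emissions` (L x 20), `transitions`
#'   (L x 7, columns MM MI MD IM II DM DD; row j = out of node j),
#'   `background`, `match_columns` (alignment column of each match state) and
#'   `build_metadata`.
#' @export
build_profile <- function(aln, match_threshold = 0.5,
                          pseudocount = c("laplace", "none"),
                          background = uniform_background()) {
  pseudocount <- match.arg(pseudocount)
  stopifnot(inherits(aln, "motif_alignment"))
  if (!(match_threshold > 0 && match_threshold <= 1))
    stop("input error: match_threshold must be in (0, 1]", call. = FALSE)
  m <- alignment_matrix(aln)
  nrow_aln <- nrow(m)
  gap_frac <- colMeans(m == "-")
  is_match <- gap_frac < match_threshold
  L <- sum(is_match)
  if (L < 1) stop("input error: no match columns at this threshold", call. = FALSE)
  match_cols <- which(is_match)
  # node index of each column: for match columns their rank; for insert
  # columns the rank of the last match column to their left (0 = before all)
  node_of_col <- cumsum(is_match)

  e_pc <- if (pseudocount == "laplace") 1 else 0
  t_pc <- if (pseudocount == "laplace") 0.1 else 0

  count_residues <- function(cols_chars) {
    tab <- table(factor(cols_chars[cols_chars %in% AA_ALPHABET], levels = AA_ALPHABET))
    as.numeric(tab)
  }

  match_em <- matrix(0, L, 20, dimnames = list(NULL, AA_ALPHABET))
  for (k in seq_len(L)) {
    cnt <- count_residues(m[, match_cols[k]])
    match_em[k, ] <- (cnt + e_pc) / (sum(cnt) + 20 * e_pc)
  }
  insert_em <- matrix(0, L, 20, dimnames = list(NULL, AA_ALPHABET))
  for (k in seq_len(L)) {
    ins_cols <- which(!is_match & node_of_col == k)
    cnt <- if (length(ins_cols)) count_residues(as.vector(m[, ins_cols, drop = FALSE])) else rep(0, 20)
    insert_em[k, ] <- (cnt + e_pc) / (sum(cnt) + 20 * e_pc)
  }
  if (pseudocount == "none") {
    # avoid 0/0 on empty insert columns: fall back to background
    empty <- rowSums(insert_em) == 0 | !is.finite(rowSums(insert_em))
    insert_em[empty, ] <- matrix(background, sum(empty), 20, byrow = TRUE)
  }

  # per-row state-event sequences over nodes -> transition counts
  tnames <- c("MM", "MI", "MD", "IM", "II", "DM", "DD")
  tc <- matrix(0, L, 7, dimnames = list(NULL, tnames))
  for (r in seq_len(nrow_aln)) {
    events <- list()  # sequence of (state, node)
    for (col in seq_len(ncol(m))) {
      res <- m[r, col]
      if (is_match[col]) {
        events[[length(events) + 1]] <- c(if (res == "-") "D" else "M", node_of_col[col])
      } else if (res != "-" && node_of_col[col] >= 1 && node_of_col[col] < L) {
        events[[length(events) + 1]] <- c("I", node_of_col[col])
      }
    }
    if (length(events) < 2) next
    for (k in seq_len(length(events) - 1)) {
      a <- events[[k]]; b <- events[[k + 1]]
      from_node <- as.integer(a[2])
      key <- paste0(a[1], b[1])
      if (key %in% tnames && from_node >= 1 && from_node <= L) {
        tc[from_node, key] <- tc[from_node, key] + 1
      }
      # D followed by I (or I by D) has no plan-7 edge; those adjacencies are skipped
    }
  }

  trans <- matrix(0, L, 7, dimnames = list(NULL, tnames))
  for (j in seq_len(L)) {
    mrow <- tc[j, c("MM", "MI", "MD")] + t_pc
    irow <- tc[j, c("IM", "II")] + t_pc
    drow <- tc[j, c("DM", "DD")] + t_pc
    if (sum(mrow) == 0) mrow <- c(1, 0, 0)
    if (sum(irow) == 0) irow <- c(1, 0)
    if (sum(drow) == 0) drow <- c(1, 0)
    trans[j, c("MM", "MI", "MD")] <- mrow / sum(mrow)
    trans[j, c("IM", "II")] <- irow / sum(irow)
    trans[j, c("DM", "DD")] <- drow / sum(drow)
  }
  # terminal node: match exits the model; no insert/delete continuation
  trans[L, ] <- c(1, 0, 0, 1, 0, 1, 0)

  structure(list(name = aln$name, L = L,
                 match_emissions = match_em,
                 insert_emissions = insert_em,
                 transitions = trans,
                 background = setNames(as.numeric(background), AA_ALPHABET),
                 match_columns = match_cols,
                 build_metadata = list(match_threshold = match_threshold,
                                       pseudocount = pseudocount,
                                       n_rows = nrow_aln,
                                       n_columns = aln$n_columns)),
            class = "profile_hmm")
}

#' @export
print.profile_hmm <- function(x, ...) {
  cat(sprintf("<profile_hmm '%s': L=%d, pseudocount=%s>\n",
              x$name, x$L, x$build_metadata$pseudocount))
  invisible(x)
}

## log2 with -Inf clamped so the C++ core never sees NaN arithmetic
.log2c <- function(x) {
  out <- suppressWarnings(log2(x))
  out[!is.finite(out)] <- -1e30
  out
}

#' Search a protein with a profile HMM (local Viterbi)
#'
#' Maximum-log-odds local alignment with free entry into and exit from any
#' match state. By default every best hit is reported whatever its score
#' (no reporting floor), so that downstream curation — not the search — does
#' the filtering.
#'
#' @param hmm a [build_profile()] model.
#' @param protein residue string. `X` is scored as a background wildcard;
#'   any other non-standard symbol is an alphabet error.
#' @param calibration optional [calibrate_evalues()] fit used to attach an
#'   E-value to the hit.
#' @param n_targets database size the E-value is scaled to (default 1).
#' @param report_floor minimum bit score to report; default `-Inf`.
#' @param target_id identifier stored in the hit.
#' @return a `domain_hit` (list with `target_id`, `env_start`/`env_end`
#'   0-based half-open on the protein, `model_start`/`model_end` 1-based
#'   match-state coordinates, `bit_score`, `evalue` (NA without calibration),
#'   `state_path` data frame, `protein_length`), or `NULL` if the best score
#'   is below `report_floor`.
#' @export
viterbi_search <- function(hmm, protein, calibration = NULL, n_targets = 1,
                           report_floor = -Inf, target_id = NA_character_) {
  stopifnot(inherits(hmm, "profile_hmm"))
  if (nchar(protein) < 1) stop("input error: empty protein", call. = FALSE)
  seq <- encode_protein(protein, context = if (is.na(target_id)) "protein" else target_id)
  bg <- hmm$background
  match_lo <- .log2c(sweep(hmm$match_emissions, 2, bg, "/"))
  ins_lo <- .log2c(sweep(hmm$insert_emissions, 2, bg, "/"))
  trans_lo <- .log2c(hmm$transitions)
  res <- viterbi_local(match_lo, ins_lo, trans_lo, seq)
  if (!is.finite(res$score) || res$score < report_floor) return(NULL)
  path <- data.frame(state = c("M", "I", "D")[res$state],
                     model = res$model,
                     seqpos = ifelse(res$seqpos == 0, NA_integer_, res$seqpos))
  pc <- chars(toupper(protein))
  path$residue <- ifelse(is.na(path$seqpos), "-", pc[path$seqpos])
  emitted <- path$seqpos[!is.na(path$seqpos)]
  mpos <- path$model[path$state == "M"]
  ev <- if (!is.null(calibration)) {
    evalue_from_score(res$score, calibration, n_targets = n_targets)
  } else NA_real_
  structure(list(target_id = target_id,
                 env_start = min(emitted) - 1L,
                 env_end = max(emitted),
                 model_start = min(mpos), model_end = max(mpos),
                 bit_score = res$score,
                 evalue = ev,
                 state_path = path,
                 protein_length = nchar(protein),
                 model_name = hmm$name),
            class = "domain_hit")
}

#' @export
print.domain_hit <- function(x, ...) {
  cat(sprintf("<domain_hit %s: env [%d,%d), model %d-%d, %.2f bits, E=%s>\n",
              x$target_id, x$env_start, x$env_end, x$model_start, x$model_end,
              x$bit_score, format(x$evalue, digits = 3)))
  invisible(x)
}

#' Calibrate an empirical Gumbel E-value model for a profile HMM
#'
#' Scores `n_shuffles` background sequences of the given length and fits a
#' Gumbel (type-I extreme value) distribution to the maximal bit scores by
#' the method of moments: `lambda = pi / (sd * sqrt(6))`,
#' `mu = mean - gamma / lambda`. Deterministic given the seed.
#'
#' @param hmm a [build_profile()] model.
#' @param length length of each shuffled background sequence (default 400,
#'   a typical full-length transcription-factor protein).
#' @param n_shuffles number of background sequences (>= 100; default 200).
#' @param seed integer seed (mandatory).
#' @return an object of class `gumbel_calibration` with `mu`, `lambda`,
#'   `n_shuffles`, `length`, `seed`.
#' @export
calibrate_evalues <- function(hmm, length = 400, n_shuffles = 200, seed) {
  if (missing(seed)) stop("input error: seed is mandatory", call. = FALSE)
  if (n_shuffles < 100) stop("input error: n_shuffles must be >= 100", call. = FALSE)
  scores <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_shuffles), function(i) {
      s <- paste(sample(AA_ALPHABET, length, replace = TRUE, prob = hmm$background),
                 collapse = "")
      viterbi_search(hmm, s)$bit_score
    }, 0)
  })
  s <- stats::sd(scores)
  if (!is.finite(s) || s == 0)
    stop("calibration error: degenerate score distribution", call. = FALSE)
  lambda <- pi / (s * sqrt(6))
  mu <- mean(scores) - 0.5772156649015329 / lambda
  structure(list(mu = mu, lambda = lambda, n_shuffles = as.integer(n_shuffles),
                 length = length, seed = as.integer(seed)),
            class = "gumbel_calibration")
}

#' E-value of a bit score under a Gumbel calibration
#'
#' `E = n_targets * P(S >= s)` with the fitted Gumbel right tail; strictly
#' decreasing in the score.
#'
#' @param score bit score(s).
#' @param calibration a [calibrate_evalues()] fit.
#' @param n_targets database size to scale to (default 1).
#' @export
evalue_from_score <- function(score, calibration, n_targets = 1) {
  stopifnot(inherits(calibration, "gumbel_calibration"))
  p <- -expm1(-exp(-calibration$lambda * (score - calibration$mu)))
  n_targets * p
}

#' Scan a protein with a set of motif models
#'
#' One best hit per motif. By default no threshold is applied (all scores
#' are reported); family corroboration applies its own threshold downstream.
#'
#' @param protein residue string.
#' @param models list of [build_profile()] models.
#' @param calibrations optional named list of [calibrate_evalues()] fits,
#'   keyed by model name.
#' @param n_targets database scale for E-values.
#' @param max_evalue optional reporting threshold.
#' @return data frame with columns motif, bit_score, evalue, env_start,
#'   env_end (0-based half-open). Zero rows for an empty model list.
#' @export
scan_motifs <- function(protein, models, calibrations = NULL, n_targets = 1,
                        max_evalue = Inf) {
  out <- data.frame(motif = character(), bit_score = numeric(),
                    evalue = numeric(), env_start = integer(),
                    env_end = integer(), stringsAsFactors = FALSE)
  for (hmm in models) {
    cal <- if (!is.null(calibrations)) calibrations[[hmm$name]] else NULL
    hit <- viterbi_search(hmm, protein, calibration = cal, n_targets = n_targets)
    if (is.null(hit)) next
    if (!is.na(hit$evalue) && hit$evalue > max_evalue) next
    out <- rbind(out, data.frame(motif = hmm$name, bit_score = hit$bit_score,
                                 evalue = hit$evalue, env_start = hit$env_start,
                                 env_end = hit$env_end, stringsAsFactors = FALSE))
  }
  out
}

#' Serialize a profile HMM to JSON (schema "bhlh-hmm/1")
#' @param hmm a [build_profile()] model.
#' @param path output file.
#' @export
write_profile_json <- function(hmm, path) {
  doc <- list(schema = "bhlh-hmm/1", name = hmm$name, L = hmm$L,
              alphabet = paste(AA_ALPHABET, collapse = ""),
              match_emissions = unname(apply(hmm$match_emissions, 1, as.numeric, simplify = FALSE)),
              insert_emissions = unname(apply(hmm$insert_emissions, 1, as.numeric, simplify = FALSE)),
              transitions = unname(apply(hmm$transitions, 1, as.numeric, simplify = FALSE)),
              background = as.numeric(hmm$background),
              match_columns = hmm$match_columns,
              build_metadata = hmm$build_metadata)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a profile HMM from its JSON serialization
#' @param path file written by [write_profile_json()].
#' @export
read_profile_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$schema, "bhlh-hmm/1"))
    stop("input error: not a bhlh-hmm/1 document", call. = FALSE)
  tnames <- c("MM", "MI", "MD", "IM", "II", "DM", "DD")
  as_matrix <- function(x, ncol, cn) {
    m <- if (is.list(x)) do.call(rbind, lapply(x, as.numeric)) else as.matrix(x)
    dimnames(m) <- list(NULL, cn)
    m
  }
  structure(list(name = doc$name, L = as.integer(doc$L),
                 match_emissions = as_matrix(doc$match_emissions, 20, AA_ALPHABET),
                 insert_emissions = as_matrix(doc$insert_emissions, 20, AA_ALPHABET),
                 transitions = as_matrix(doc$transitions, 7, tnames),
                 background = setNames(as.numeric(doc$background), AA_ALPHABET),
                 match_columns = as.integer(doc$match_columns),
                 build_metadata = doc$build_metadata),
            class = "profile_hmm")
}
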