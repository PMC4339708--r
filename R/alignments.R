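## Motif/domain alignment container and readers (aligned FASTA, Stockholm,
## PHYLIP). FASTA goes through Biostrings, PHYLIP through phangorn; Stockholm
## has no reader in the R stack used here, so a minimal parser for sequence
## lines (markup lines are skipped) is provided.

#' Construct a motif alignment
#'
#' A named multiple alignment over the 20 amino acids plus gap. All rows must
#' have equal length and there must be at least one row.
#'
#' @param name label of the motif/domain family.
#' @param ids character vector of sequence identifiers.
#' @param seqs character vector of gapped rows (same length as `ids`).
#' @return an object of class `motif_alignment` with elements `name`, `ids`,
#'   `seqs` (uppercase, `.` normalized to `-`) and `n_columns`.
#' @export
motif_alignment <- function(name, ids, seqs) {
  if (length(seqs) < 1) stop("input error: empty alignment", call. = FALSE)
  if (length(ids) != length(seqs)) stop("ids and seqs lengths differ", call. = FALSE)
  rows <- lapply(seq_along(seqs), function(i) check_aligned_row(seqs[i], ids[i], i))
  nc <- unique(vapply(rows, length, 1L))
  if (length(nc) != 1) stop("input error: alignment rows have unequal lengths", call. = FALSE)
  structure(list(name = name, ids = as.character(ids),
                 seqs = vapply(rows, paste, "", collapse = ""),
                 n_columns = nc),
            class = "motif_alignment")
}

#' @export
print.motif_alignment <- function(x, ...) {
  cat(sprintf("<motif_alignment '%s': %d rows x %d columns>\n",
              x$name, length(x$ids), x$n_columns))
  invisible(x)
}

## alignment as a character matrix (rows x columns)
alignment_matrix <- function(aln) {
  m <- do.call(rbind, lapply(aln$seqs, chars))
  rownames(m) <- aln$ids
  m
}

#' Read a motif alignment from aligned FASTA or Stockholm
#'
#' Format is chosen from the file content (`# STOCKHOLM` header) unless
#' forced. Gap characters `-` and `.` are accepted.
#'
#' @param path file path.
#' @param name motif name; defaults to the Stockholm `#=GF ID` when present,
#'   otherwise the file base name.
#' @param format `"auto"`, `"fasta"` or `"stockholm"`.
#' @return a [motif_alignment()].
#' @export
read_motif_alignment <- function(path, name = NULL, format = c("auto", "fasta", "stockholm")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path, n = 1L)
    format <- if (grepl("^# STOCKHOLM", first)) "stockholm" else "fasta"
  }
  if (format == "fasta") {
    ss <- Biostrings::readBStringSet(path)
    if (is.null(name)) name <- tools::file_path_sans_ext(basename(path))
    return(motif_alignment(name, names(ss), as.character(ss)))
  }
  lines <- readLines(path)
  id_line <- grep("^#=GF\\s+ID\\s+", lines, value = TRUE)
  if (is.null(name)) {
    name <- if (length(id_line)) sub("^#=GF\\s+ID\\s+", "", id_line[1])
            else tools::file_path_sans_ext(basename(path))
  }
  seq_lines <- lines[!grepl("^#", lines) & !grepl("^//", lines) & nzchar(trimws(lines))]
  if (!length(seq_lines)) stop("input error: empty alignment", call. = FALSE)
  parts <- strsplit(trimws(seq_lines), "\\s+")
  ids <- vapply(parts, `[`, "", 1L)
  seqs <- vapply(parts, function(p) paste(p[-1], collapse = ""), "")
  # interleaved blocks: concatenate by id, preserving first-seen order
  ord <- unique(ids)
  seqs <- vapply(ord, function(i) paste(seqs[ids == i], collapse = ""), "")
  motif_alignment(name, ord, unname(seqs))
}

#' Write a motif alignment as aligned FASTA
#' @param aln a [motif_alignment()].
#' @param path output file.
#' @export
write_motif_alignment <- function(aln, path) {
  writeLines(as.vector(rbind(paste0(">", aln$ids), aln$seqs)), path)
  invisible(path)
}

#' Read a protein alignment in PHYLIP format
#'
#' Sequential and interleaved dialects with relaxed whitespace-delimited
#' names up to 50 characters (long gene-model identifiers are common in
#' plant annotation sets). Each of the first `n` lines must start a record;
#' continuation lines are appended to the shortest incomplete sequence,
#' which resolves both dialects without a format flag.
#'
#' @param path file path.
#' @param name motif/set name (defaults to file base name).
#' @return a [motif_alignment()].
#' @export
read_phylip_alignment <- function(path, name = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  if (length(hdr) != 2 || anyNA(hdr))
    stop("input error: malformed PHYLIP header", call. = FALSE)
  n <- hdr[1]; m <- hdr[2]
  if (length(lines) < n + 1)
    stop("input error: PHYLIP file truncated", call. = FALSE)
  ids <- character(n); seqs <- character(n)
  for (i in seq_len(n)) {
    tok <- strsplit(trimws(lines[i + 1]), "\\s+")[[1]]
    ids[i] <- tok[1]
    seqs[i] <- paste(tok[-1], collapse = "")
  }
  extra <- lines[-seq_len(n + 1)]
  for (ln in extra) {
    lens <- nchar(seqs)
    if (all(lens >= m)) break
    open <- which(lens < m)
    i <- open[which.min(lens[open])]
    seqs[i] <- paste0(seqs[i], gsub("\\s+", "", ln))
  }
  if (any(nchar(seqs) != m))
    stop("input error: PHYLIP sequence lengths disagree with the header",
         call. = FALSE)
  if (is.null(name)) name <- tools::file_path_sans_ext(basename(path))
  motif_alignment(name, ids, seqs)
}

#' Write a protein alignment in (relaxed sequential) PHYLIP format
#' @param aln a [motif_alignment()].
#' @param path output file.
#' @export
write_phylip_alignment <- function(aln, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(" %d %d", length(aln$ids), aln$n_columns), con)
  writeLines(sprintf("%-50s  %s", aln$ids, aln$seqs), con)
  invisible(path)
}
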