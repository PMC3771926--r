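# Sequence sets, substitution matrices and tabular file adapters.
#
# A sequence set is represented as a named character vector: names are the
# unique sequence identifiers, values the amino-acid strings over the
# 20-letter alphabet plus X. All file coordinates are 1-based inclusive;
# internal interval arithmetic uses the same convention throughout.

validate_sequences <- function(seqs) {
  if (length(seqs) == 0) return(invisible(seqs))
  ids <- names(seqs)
  if (is.null(ids) || any(!nzchar(ids))) {
    stop("every sequence must carry a non-empty id", call. = FALSE)
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    stop("duplicate sequence id(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  if (any(grepl("-", seqs, fixed = TRUE))) {
    stop("sequences must not contain gap characters", call. = FALSE)
  }
  invisible(seqs)
}

# Map residue letters outside the 20-letter alphabet (B, Z, J, U, O, ...)
# to X, uppercasing first.
normalize_residues <- function(x) {
  x <- toupper(x)
  gsub(sprintf("[^%s]", paste(AA20, collapse = "")), "X", x)
}

#' Read protein sequences from a FASTA file
#'
#' Identifiers are the first whitespace-delimited token of each header.
#' Letters outside the 20-residue alphabet are mapped to `X`; gap
#' characters are rejected. Duplicate identifiers are an error.
#'
#' @param path Path to a FASTA file (plain or gzipped).
#' @return Named character vector of residue strings.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0) return(setNames(character(0), character(0)))
  if (!startsWith(trimws(lines[nonblank[1]]), ">")) {
    stop("malformed FASTA record at line ", nonblank[1],
         ": expected a '>' header", call. = FALSE)
  }
  set <- Biostrings::readBStringSet(path, format = "fasta")
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  seqs <- setNames(normalize_residues(as.character(set)), ids)
  if (any(!nzchar(seqs))) {
    stop("empty sequence record(s): ",
         paste(ids[!nzchar(seqs)], collapse = ", "), call. = FALSE)
  }
  validate_sequences(seqs)
  seqs
}

#' Write protein sequences to a FASTA file
#'
#' @param seqs Named character vector of residue strings.
#' @param path Output path.
#' @param width Line width for wrapping residues.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60) {
  validate_sequences(seqs)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1, max(nchar(s), 1), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Drop sequences with outlier lengths
#'
#' Sequences shorter than `min_len` or longer than `max_len` residues are
#' treated as outliers (fragments and other database artifacts) and
#' removed; bounds are inclusive. The defaults keep lengths in
#' 100..10000.
#'
#' @param seqs Named character vector of residue strings.
#' @param min_len,max_len Inclusive length bounds.
#' @return Filtered sequence set, input order preserved.
#' @export
length_filter <- function(seqs, min_len = 100, max_len = 10000) {
  stopifnot(min_len >= 1, max_len >= min_len)
  keep <- nchar(seqs) >= min_len & nchar(seqs) <= max_len
  if (any(!keep)) {
    message("length_filter: removed ", sum(!keep), " of ", length(seqs),
            " sequences outside [", min_len, ", ", max_len, "]")
  }
  seqs[keep]
}

#' Load a bundled substitution matrix
#'
#' Returns the published matrix (from Biostrings) restricted to the 20
#' amino acids plus X.
#'
#' @param name Matrix name, e.g. `"BLOSUM50"` or `"BLOSUM62"`.
#' @return Symmetric numeric matrix with dimnames over the residue
#'   alphabet plus X.
#' @export
load_matrix <- function(name) {
  available <- c("BLOSUM45", "BLOSUM50", "BLOSUM62", "BLOSUM80",
                 "BLOSUM100", "PAM30", "PAM40", "PAM70", "PAM120",
                 "PAM250")
  if (!name %in% available) {
    stop("unknown substitution matrix '", name, "'; available: ",
         paste(available, collapse = ", "), call. = FALSE)
  }
  env <- new.env()
  utils::data(list = name, package = "Biostrings", envir = env)
  m <- get(name, envir = env)
  m[AAX, AAX]
}

canonical_pairs <- function(id1, id2) {
  swap <- id1 > id2
  tmp <- id1[swap]
  id1[swap] <- id2[swap]
  id2[swap] <- tmp
  list(id1 = id1, id2 = id2)
}

#' Read a pairwise similarity table
#'
#' Accepts either the 3-column dialect (query id, subject id, e-value) or
#' the standard 12-column tabular alignment-report dialect (e-value in
#' column 11). Per unordered pair the minimum e-value is kept; self pairs
#' are dropped.
#'
#' @param path Path to a tab-separated file.
#' @return Data frame with columns `id1`, `id2`, `evalue`; `id1 < id2`.
#' @export
read_similarity_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  if (length(lines) == 0) {
    return(data.frame(id1 = character(0), id2 = character(0),
                      evalue = numeric(0), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  get_row <- function(i) {
    f <- fields[[i]]
    ev_col <- if (length(f) >= 11) 11L else 3L
    if (length(f) < 3) {
      stop("similarity table line ", i, ": fewer than 3 columns",
           call. = FALSE)
    }
    ev <- suppressWarnings(as.numeric(f[ev_col]))
    if (is.na(ev)) {
      stop("similarity table line ", i, ": non-numeric e-value '",
           f[ev_col], "'", call. = FALSE)
    }
    c(f[1], f[2], ev)
  }
  rows <- vapply(seq_along(fields), get_row, character(3))
  df <- data.frame(id1 = rows[1, ], id2 = rows[2, ],
                   evalue = as.numeric(rows[3, ]),
                   stringsAsFactors = FALSE)
  df <- df[df$id1 != df$id2, , drop = FALSE]
  if (nrow(df) == 0) return(df[, c("id1", "id2", "evalue")])
  cp <- canonical_pairs(df$id1, df$id2)
  df$id1 <- cp$id1
  df$id2 <- cp$id2
  key <- paste(df$id1, df$id2, sep = "\r")
  ev <- tapply(df$evalue, key, min)
  parts <- strsplit(names(ev), "\r", fixed = TRUE)
  out <- data.frame(id1 = vapply(parts, `[`, character(1), 1L),
                    id2 = vapply(parts, `[`, character(1), 2L),
                    evalue = as.numeric(ev), stringsAsFactors = FALSE)
  out <- out[order(out$id1, out$id2), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a pairwise similarity table
#'
#' @param sim Data frame with columns `id1`, `id2`, `evalue`.
#' @param path Output path (tab-separated, 3 columns, no header).
#' @return `path`, invisibly.
#' @export
write_similarity_table <- function(sim, path) {
  write.table(sim[, c("id1", "id2", "evalue")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read region annotations
#'
#' Tab-separated columns: sequence id, start, end, label; positions are
#' 1-based inclusive.
#'
#' @param path Path to a tab-separated annotation file.
#' @return Data frame with columns `seq_id`, `start`, `end`, `label`.
#' @export
read_annotations <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE, quote = "",
                   col.names = c("seq_id", "start", "end", "label"),
                   colClasses = c("character", "integer", "integer",
                                  "character"),
                   stringsAsFactors = FALSE)
  if (nrow(df) > 0 && any(df$start < 1 | df$end < df$start)) {
    stop("invalid annotation interval(s): start must be >= 1 and <= end",
         call. = FALSE)
  }
  df
}

#' Write region annotations
#'
#' @param ann Data frame with columns `seq_id`, `start`, `end`, `label`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ann, path) {
  write.table(ann[, c("seq_id", "start", "end", "label")], path,
              sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Residue composition of a sequence set
#'
#' @param seqs Named character vector of residue strings.
#' @return Named numeric vector over the 20 amino acids, summing to 1.
#'   `X` residues are ignored. Falls back to a standard background
#'   composition when the set is empty.
#' @export
residue_composition <- function(seqs) {
  if (length(seqs) == 0) return(ROBINSON_FREQS)
  tab <- table(factor(split_chars(paste(seqs, collapse = "")),
                      levels = AA20))
  n <- sum(tab)
  if (n == 0) return(ROBINSON_FREQS)
  as.numeric(tab) / n -> p
  setNames(p, AA20)
}
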