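# Per-clique multiple alignment, residue conservation scoring,
# median-filter smoothing, and conserved-region extraction.
#
# An alignment is a named character vector of equal-length gapped strings.

aln_matrix <- function(al) {
  m <- do.call(rbind, strsplit(al, "", fixed = TRUE))
  rownames(m) <- names(al)
  m
}

aln_collapse <- function(m) {
  setNames(apply(m, 1, paste, collapse = ""), rownames(m))
}

validate_alignment <- function(al) {
  if (length(al) == 0) stop("empty alignment", call. = FALSE)
  w <- nchar(al)
  if (length(unique(w)) != 1) {
    bad <- names(al)[w != w[1]]
    stop("ragged alignment row(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  invisible(al)
}

# residue frequency matrix of an alignment block: 21 x n_columns, each
# column divided by the number of rows (gaps carry no mass)
profile_freqs <- function(m) {
  L <- ncol(m)
  f <- matrix(0, nrow = length(AAX), ncol = L, dimnames = list(AAX, NULL))
  for (a in AAX) f[a, ] <- colSums(m == a)
  f / nrow(m)
}

#' Progressive multiple sequence alignment
#'
#' Global progressive alignment: a UPGMA guide tree is built from
#' pairwise-identity distances, and profiles are merged bottom-up by
#' affine-gap profile-profile alignment with expected sum-of-pairs
#' column scores. Terminal gaps are not penalised, so sequences sharing
#' a core region embedded in flanks of unequal length align on the
#' core. Deterministic for a fixed input order.
#'
#' @param seqs Named character vector of at least 2 residue strings.
#' @param matrix Substitution matrix name or matrix.
#' @param gap_open,gap_extend Positive gap penalties.
#' @return Named character vector of gapped rows (an alignment).
#' @export
progressive_msa <- function(seqs, matrix = "BLOSUM62", gap_open = 10,
                            gap_extend = 1) {
  if (length(seqs) < 2) {
    stop("progressive_msa needs at least 2 sequences", call. = FALSE)
  }
  validate_sequences(seqs)
  m <- if (is.character(matrix)) load_matrix(matrix) else matrix
  n <- length(seqs)
  # pairwise fractional-identity distances for the guide tree
  D <- matrix(0, n, n)
  set <- Biostrings::AAStringSet(seqs)
  for (i in seq_len(n - 1)) {
    js <- (i + 1):n
    aln <- Biostrings::pairwiseAlignment(
      set[js], set[[i]], type = "overlap", substitutionMatrix = m,
      gapOpening = gap_open, gapExtension = gap_extend)
    d <- 1 - Biostrings::pid(aln) / 100
    d[!is.finite(d)] <- 1  # no aligned overlap at all
    D[i, js] <- d
    D[js, i] <- d
  }
  tree <- stats::hclust(stats::as.dist(D), method = "average")

  blocks <- lapply(seq_len(n), function(i) aln_matrix(seqs[i]))
  merged <- vector("list", n - 1)
  for (k in seq_len(n - 1)) {
    pick <- function(x) if (x < 0) blocks[[-x]] else merged[[x]]
    A <- pick(tree$merge[k, 1])
    B <- pick(tree$merge[k, 2])
    S <- crossprod(profile_freqs(A), m[AAX, AAX] %*% profile_freqs(B))
    path <- nw_affine_path(S, gap_open, gap_extend, TRUE)
    take <- function(block, idx) {
      out <- matrix(GAP, nrow = nrow(block), ncol = ncol(path),
                    dimnames = list(rownames(block), NULL))
      hit <- idx > 0
      out[, hit] <- block[, idx[hit], drop = FALSE]
      out
    }
    merged[[k]] <- rbind(take(A, path[1, ]), take(B, path[2, ]))
  }
  out <- aln_collapse(merged[[n - 1]])
  out[names(seqs)]
}

#' Read a multiple alignment from file
#'
#' Accepts aligned FASTA or Clustal format (auto-detected from the first
#' line). Row ids are the first whitespace-delimited header token.
#'
#' @param path Path to the alignment file.
#' @param format `"auto"`, `"fasta"` or `"clustal"`.
#' @return Named character vector of gapped rows.
#' @export
read_alignment <- function(path, format = c("auto", "fasta", "clustal")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path, n = 50, warn = FALSE)
    first <- first[nzchar(trimws(first))][1]
    format <- if (grepl("^(CLUSTAL|MUSCLE)", first)) "clustal" else "fasta"
  }
  if (format == "clustal") {
    ma <- Biostrings::readAAMultipleAlignment(path, format = "clustal")
    al <- as.character(ma)
  } else {
    set <- Biostrings::readBStringSet(path, format = "fasta")
    al <- as.character(set)
  }
  names(al) <- vapply(strsplit(names(al), "\\s+"), `[`, character(1), 1L)
  al <- toupper(al)
  al <- gsub("\\.", GAP, al)
  validate_alignment(al)
  al
}

#' Write a multiple alignment as aligned FASTA
#'
#' @param al Named character vector of gapped rows.
#' @param path Output path.
#' @param width Line width.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(al, path, width = 60) {
  validate_alignment(al)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(al)) {
    writeLines(paste0(">", names(al)[i]), con)
    s <- al[[i]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Divergence-based sequence weights
#'
#' Each row is weighted proportionally to its mean pairwise distance
#' (one minus fractional identity over mutually non-gap columns) to all
#' other rows, down-weighting clusters of near-identical sequences.
#' When all rows are identical the weights fall back to uniform.
#'
#' @param al Alignment (named character vector, >= 2 rows).
#' @return Numeric weights summing to 1, named by row id.
#' @export
sequence_weights <- function(al) {
  validate_alignment(al)
  if (length(al) < 2) stop("need >= 2 rows", call. = FALSE)
  m <- aln_matrix(al)
  n <- nrow(m)
  gap <- m == GAP
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      shared <- !gap[i, ] & !gap[j, ]
      dij <- if (!any(shared)) 1 else {
        1 - sum(m[i, shared] == m[j, shared]) / sum(shared)
      }
      d[i, j] <- dij
      d[j, i] <- dij
    }
  }
  w <- rowSums(d) / (n - 1)
  if (sum(w) <= 0) w <- rep(1, n)
  setNames(w / sum(w), names(al))
}

# Substitution matrix mapped to a [0,1] stereochemical similarity,
# anchored so that a chance residue pair scores ~0 and any identical
# pair scores exactly 1:
#   Mut(a,b) = (M(a,b) - E) / sqrt((M(a,a) - E) (M(b,b) - E))
# where E is the expected pair score under the background composition.
# A plain min-max rescaling would map chance pairs to ~0.23 for BLOSUM62
# (above the 0.2 conservation threshold), turning densely aligned but
# unrelated linker columns into fake conserved runs; anchoring at E
# removes that artifact while preserving score order. X (unknown)
# contributes no conservation evidence and scores 0 against everything.
normalized_mutation_matrix <- function(m) {
  block <- m[AA20, AA20]
  p <- ROBINSON_FREQS[AA20]
  e_bg <- as.numeric(t(p) %*% block %*% p)
  d <- diag(block) - e_bg
  mut_block <- (block - e_bg) / sqrt(outer(d, d))
  mut <- matrix(0, length(AAX), length(AAX), dimnames = list(AAX, AAX))
  mut[AA20, AA20] <- pmin(pmax(mut_block, 0), 1)
  mut
}

#' Per-column residue conservation scores
#'
#' Weighted sum-of-pairs stereochemical conservation: for column x,
#' `score = sum_{i<j} w_i w_j Mut(x_i, x_j) / sum_{i<j} w_i w_j`, where
#' `Mut` maps the substitution matrix to `[0, 1]` similarity anchored
#' at the chance expectation (a chance pair scores ~0, any identical
#' pair exactly 1). Pairs involving a gap or an unknown residue
#' contribute 0, and an all-gap column scores 0, so 0 means no
#' conservation and 1 full conservation.
#'
#' @param al Alignment (named character vector, >= 2 rows).
#' @param matrix Substitution matrix name or matrix (default BLOSUM62).
#' @param weights Optional row weights; defaults to
#'   [sequence_weights()].
#' @return Numeric vector of scores in `[0, 1]`, one per column.
#' @export
conservation_scores <- function(al, matrix = "BLOSUM62", weights = NULL) {
  validate_alignment(al)
  if (length(al) < 2) stop("need >= 2 rows", call. = FALSE)
  m <- if (is.character(matrix)) load_matrix(matrix) else matrix
  mut <- normalized_mutation_matrix(m)
  if (is.null(weights)) weights <- sequence_weights(al)
  cm <- aln_matrix(al)
  L <- ncol(cm)
  # weighted residue mass per column, per symbol
  W <- matrix(0, nrow = length(AAX), ncol = L, dimnames = list(AAX, NULL))
  for (a in AAX) W[a, ] <- colSums(weights * (cm == a))
  # sum_{i<j} w_i w_j Mut = (W' Mut W - sum_i w_i^2 Mut(x_i,x_i)) / 2
  total <- colSums((mut %*% W) * W)
  diag_mut <- diag(mut)
  selfterm <- numeric(L)
  for (a in AAX) selfterm <- selfterm + diag_mut[a] * colSums(
    (weights^2) * (cm == a))
  num <- (total - selfterm) / 2
  denom <- (sum(weights)^2 - sum(weights^2)) / 2
  scores <- num / denom
  pmin(pmax(scores, 0), 1)
}

#' One-dimensional median filter with zero padding
#'
#' Each position is replaced by the upper median (the
#' `floor(w/2) + 1`-th order statistic) of the `w = frame + 1` values in
#' the window centred on it; positions outside the track contribute
#' zeros. With the default frame of 50 the window holds 51 values (25
#' on each side plus the centre) and the filter is the standard sliding
#' median.
#'
#' @param track Numeric vector of conservation scores.
#' @param frame Neighbourhood size; the window holds `frame + 1` values.
#' @return Filtered numeric vector, same length as `track`.
#' @export
median_filter <- function(track, frame = 50) {
  stopifnot(frame >= 2)
  n <- length(track)
  if (n == 0) return(track)
  w <- frame + 1
  left <- ceiling(frame / 2)
  right <- frame - left
  padded <- c(rep(0, left), track, rep(0, right))
  k <- floor(w / 2) + 1  # upper median
  vapply(seq_len(n), function(p) {
    sort(padded[p:(p + w - 1)], partial = k)[k]
  }, numeric(1))
}

#' Extract conserved regions from a smoothed conservation track
#'
#' Maximal runs of positions whose score strictly exceeds the threshold;
#' runs shorter than `min_len` are discarded.
#'
#' @param track Numeric conservation track (typically median-filtered).
#' @param threshold Conservation score threshold (strict; default 0.2).
#' @param min_len Minimum region length in columns (default 20).
#' @return Data frame with columns `start`, `end` (1-based inclusive
#'   column intervals), sorted and non-overlapping.
#' @export
extract_regions <- function(track, threshold = 0.2, min_len = 20) {
  stopifnot(threshold > 0, threshold < 1, min_len >= 1)
  r <- rle(track > threshold)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths >= min_len
  data.frame(start = starts[keep], end = ends[keep])
}

#' Build a region profile from an alignment span
#'
#' Collects per-column residue and gap counts over the alignment rows
#' for a column interval, and maps the interval to each row's ungapped
#' residue coordinates. Rows whose mapped span holds fewer than one
#' residue are excluded from the member list.
#'
#' @param al Alignment (named character vector).
#' @param span Integer vector `c(start, end)` of alignment columns.
#' @param clique_id,region_id Identifier strings carried in the profile.
#' @return A `region_profile`: list with `region_id`, `clique_id`,
#'   `span`, `n_rows`, `counts` (22 x width matrix over residues + gap)
#'   and `members` (data frame `seq_id`, `start`, `end`, 1-based
#'   residue coordinates).
#' @export
build_profile <- function(al, span, clique_id = "", region_id = "") {
  validate_alignment(al)
  stopifnot(length(span) == 2, span[1] >= 1, span[2] >= span[1],
            span[2] <= nchar(al[[1]]))
  m <- aln_matrix(al)
  block <- m[, span[1]:span[2], drop = FALSE]
  syms <- c(AAX, GAP)
  counts <- matrix(0L, nrow = length(syms), ncol = ncol(block),
                   dimnames = list(syms, NULL))
  for (a in syms) counts[a, ] <- colSums(block == a)
  nongap_before <- if (span[1] > 1) {
    rowSums(m[, seq_len(span[1] - 1), drop = FALSE] != GAP)
  } else rep(0L, nrow(m))
  nongap_in <- rowSums(block != GAP)
  keep <- nongap_in >= 1
  members <- data.frame(
    seq_id = rownames(m)[keep],
    start = as.integer(nongap_before[keep] + 1),
    end = as.integer(nongap_before[keep] + nongap_in[keep]),
    stringsAsFactors = FALSE)
  rownames(members) <- NULL
  structure(list(region_id = region_id, clique_id = clique_id,
                 span = as.integer(span), n_rows = nrow(m),
                 counts = counts, members = members),
            class = "region_profile")
}
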