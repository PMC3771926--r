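# All-against-all local alignment, empirical e-value calibration, and
# thresholding into a binary connectivity graph.

as_aa <- function(x) Biostrings::AAString(x)

#' Smith-Waterman local alignment of two sequences
#'
#' Optimal local alignment under affine gaps (a gap of length L costs
#' `gap_open + L * gap_extend`). Defaults mirror the classic
#' SSEARCH-style setup: BLOSUM50 with gap penalties 10/2.
#'
#' @param a,b Residue strings.
#' @param matrix Substitution matrix name or matrix (see [load_matrix()]).
#' @param gap_open,gap_extend Positive gap penalties.
#' @return List with `score` and 1-based inclusive spans `a_start`,
#'   `a_end`, `b_start`, `b_end` (all 0 when no positive-scoring local
#'   alignment exists).
#' @export
smith_waterman <- function(a, b, matrix = "BLOSUM50", gap_open = 10,
                           gap_extend = 2) {
  stopifnot(gap_open > 0, gap_extend > 0, nchar(a) > 0, nchar(b) > 0)
  m <- if (is.character(matrix)) load_matrix(matrix) else matrix
  aln <- Biostrings::pairwiseAlignment(
    as_aa(a), as_aa(b), type = "local", substitutionMatrix = m,
    gapOpening = gap_open, gapExtension = gap_extend)
  sc <- Biostrings::score(aln)
  if (sc <= 0) {
    return(list(score = 0, a_start = 0L, a_end = 0L,
                b_start = 0L, b_end = 0L))
  }
  pr <- aln@pattern@range
  sr <- aln@subject@range
  list(score = sc,
       a_start = as.integer(BiocGenerics::start(pr)),
       a_end = as.integer(BiocGenerics::end(pr)),
       b_start = as.integer(BiocGenerics::start(sr)),
       b_end = as.integer(BiocGenerics::end(sr)))
}

#' Maximum-likelihood fit of a Gumbel distribution
#'
#' Fits location `mu` and scale `beta` of the extreme-value distribution
#' to observed optimal local alignment scores, by the standard
#' fixed-point iteration on the scale parameter.
#'
#' @param x Numeric vector of observations (length >= 10).
#' @return List with `mu` and `beta`.
#' @export
fit_gumbel <- function(x) {
  stopifnot(length(x) >= 10, is.numeric(x))
  beta <- stats::sd(x) * sqrt(6) / pi
  if (beta <= 0) stop("degenerate sample: zero variance", call. = FALSE)
  for (it in 1:200) {
    w <- exp(-(x - max(x)) / beta)
    beta_new <- mean(x) - sum(x * w) / sum(w)
    if (beta_new <= 0) break
    if (abs(beta_new - beta) < 1e-10) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  mu <- -beta * (log(mean(exp(-(x - max(x)) / beta))) - max(x) / beta)
  list(mu = mu, beta = beta)
}

#' Convert a local alignment score to an e-value
#'
#' Karlin-Altschul style estimate: `E = K * len_a * db_residues *
#' exp(-lambda * score)`.
#'
#' @param score Alignment raw score.
#' @param len_a Query length in residues.
#' @param db_residues Total residue count of the search space.
#' @param lambda,K Gumbel calibration constants (see
#'   [calibrate_evalue()]).
#' @return Non-negative e-value (vectorised over `score`).
#' @export
estimate_evalue <- function(score, len_a, db_residues, lambda, K) {
  stopifnot(lambda > 0, K > 0)
  K * len_a * db_residues * exp(-lambda * score)
}

#' Calibrate e-value constants from shuffled decoys
#'
#' Aligns random decoy sequence pairs drawn from a residue composition
#' and fits a Gumbel distribution to the optimal local scores by maximum
#' likelihood. With decoys of lengths m and n, `lambda = 1/beta` and
#' `K = exp(mu/beta) / (m * n)`.
#'
#' @param composition Named amino-acid frequency vector (defaults to a
#'   standard background composition).
#' @param matrix,gap_open,gap_extend Alignment parameters being
#'   calibrated.
#' @param n_pairs Number of decoy pairs.
#' @param decoy_length Length of each decoy sequence.
#' @param seed RNG seed.
#' @return List with `lambda` and `K`.
#' @export
calibrate_evalue <- function(composition = NULL, matrix = "BLOSUM50",
                             gap_open = 10, gap_extend = 2,
                             n_pairs = 300, decoy_length = 200,
                             seed = 1) {
  if (is.null(composition)) composition <- ROBINSON_FREQS
  m <- if (is.character(matrix)) load_matrix(matrix) else matrix
  scores <- with_seed(seed, {
    draw <- function() paste(sample(names(composition), decoy_length,
                                    replace = TRUE, prob = composition),
                             collapse = "")
    a <- Biostrings::AAStringSet(replicate(n_pairs, draw()))
    b <- Biostrings::AAStringSet(replicate(n_pairs, draw()))
    Biostrings::pairwiseAlignment(a, b, type = "local",
                                  substitutionMatrix = m,
                                  gapOpening = gap_open,
                                  gapExtension = gap_extend,
                                  scoreOnly = TRUE)
  })
  fit <- fit_gumbel(scores)
  list(lambda = 1 / fit$beta,
       K = exp(fit$mu / fit$beta) / (decoy_length * decoy_length))
}

# Shipped calibration constants, derived with calibrate_evalue() on
# random sequences of standard background composition (2000 pairs of
# 200-mers). Keyed by "<matrix>:<gap_open>:<gap_extend>".
DEFAULT_CALIBRATIONS <- list(
  "BLOSUM50:10:2" = list(lambda = 0.1830, K = 0.0283),
  "BLOSUM62:10:1" = list(lambda = 0.2851, K = 0.0572),
  "BLOSUM62:11:1" = list(lambda = 0.2994, K = 0.0723)
)

resolve_calibration <- function(matrix_name, gap_open, gap_extend,
                                calibration = NULL) {
  if (!is.null(calibration)) return(calibration)
  key <- paste(matrix_name, gap_open, gap_extend, sep = ":")
  cal <- DEFAULT_CALIBRATIONS[[key]]
  if (is.null(cal)) {
    stop("no e-value calibration for ", key,
         "; run calibrate_evalue() and pass the result as `calibration`",
         call. = FALSE)
  }
  cal
}

#' All-against-all pairwise similarity map
#'
#' Aligns every unordered sequence pair locally and converts scores to
#' e-values. Entries with e-values above `evalue_cap` are omitted to
#' bound memory. The query length in the e-value formula is the shorter
#' sequence of the pair, making the map symmetric in its inputs.
#'
#' @param seqs Named character vector of residue strings (length >= 2).
#' @inheritParams smith_waterman
#' @param calibration Optional list with `lambda`, `K`; defaults to the
#'   shipped calibration for the matrix/penalty combination.
#' @param evalue_cap Storage cap; pairs with larger e-values are dropped.
#' @return Data frame with columns `id1`, `id2`, `evalue` (`id1 < id2`).
#' @export
all_against_all <- function(seqs, matrix = "BLOSUM50", gap_open = 10,
                            gap_extend = 2, calibration = NULL,
                            evalue_cap = 10) {
  stopifnot(length(seqs) >= 2)
  validate_sequences(seqs)
  mname <- if (is.character(matrix)) matrix else "custom"
  m <- if (is.character(matrix)) load_matrix(matrix) else matrix
  cal <- resolve_calibration(mname, gap_open, gap_extend, calibration)
  db_residues <- sum(nchar(seqs))
  n <- length(seqs)
  ids <- names(seqs)
  out <- vector("list", n - 1)
  set <- Biostrings::AAStringSet(seqs)
  for (i in seq_len(n - 1)) {
    js <- (i + 1):n
    scores <- Biostrings::pairwiseAlignment(
      set[js], set[[i]], type = "local", substitutionMatrix = m,
      gapOpening = gap_open, gapExtension = gap_extend, scoreOnly = TRUE)
    len_a <- pmin(nchar(seqs[[i]]), nchar(seqs[js]))
    ev <- estimate_evalue(scores, len_a, db_residues, cal$lambda, cal$K)
    keep <- ev <= evalue_cap
    if (any(keep)) {
      out[[i]] <- data.frame(id1 = ids[i], id2 = ids[js][keep],
                             evalue = ev[keep], stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(df)) {
    return(data.frame(id1 = character(0), id2 = character(0),
                      evalue = numeric(0), stringsAsFactors = FALSE))
  }
  cp <- canonical_pairs(df$id1, df$id2)
  df$id1 <- cp$id1
  df$id2 <- cp$id2
  df <- df[order(df$id1, df$id2), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Threshold a similarity map into a connectivity graph
#'
#' Keeps an edge for every pair with e-value at or below the threshold
#' (inclusive); all sequences appear as vertices even when isolated.
#'
#' @param sim Similarity map data frame (`id1`, `id2`, `evalue`).
#' @param ids Character vector of all dataset sequence ids.
#' @param threshold E-value threshold (default 0.01).
#' @return An undirected `igraph` graph with named vertices.
#' @export
threshold_connectivity <- function(sim, ids, threshold = 0.01) {
  stopifnot(threshold > 0)
  keep <- sim$evalue <= threshold & sim$id1 != sim$id2
  edges <- sim[keep, c("id1", "id2"), drop = FALSE]
  igraph::graph_from_data_frame(edges, directed = FALSE,
                                vertices = data.frame(name = ids))
}
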