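# PSSM construction, profile-vs-sequence search, consensus generation,
# redundant-region merging, and association-table assembly.

# Consensus with the retained profile column indices: columns whose gap
# count reaches 50% of the rows are dropped; per kept column the most
# frequent residue wins, ties resolving to the alphabetically first
# (A..Y, then X).
consensus_info <- function(profile) {
  counts <- profile$counts
  keep <- which(counts[GAP, ] < 0.5 * profile$n_rows)
  if (length(keep) == 0) {
    stop("degenerate profile ", profile$region_id,
         ": every column is majority-gap", call. = FALSE)
  }
  res <- counts[AAX, keep, drop = FALSE]
  letters <- AAX[apply(res, 2, which.max)]
  list(seq = paste(letters, collapse = ""), cols = keep)
}

#' Non-gapped consensus sequence of a region profile
#'
#' @param profile A `region_profile` (see [build_profile()]).
#' @return Consensus residue string; majority-gap columns are dropped.
#' @export
consensus <- function(profile) consensus_info(profile)$seq

#' Build a position-specific scoring matrix from a region profile
#'
#' Log-odds scores with background pseudocounts over the
#' consensus-retained columns:
#' `score(col, a) = log2((count + pc * bg(a)) / ((N + pc) * bg(a)))`
#' where `N` is the column's non-gap residue count. `X` scores 0.
#'
#' @param profile A `region_profile`.
#' @param background Named amino-acid frequency vector (strictly
#'   positive, sums to 1); defaults to a standard background.
#' @param pseudocount Total pseudocount weight (default 1).
#' @return A `pssm`: list with `region_id`, `scores` (n_positions x 21
#'   matrix over residues + X) and `cols` (source profile columns).
#' @export
build_pssm <- function(profile, background = NULL, pseudocount = 1) {
  if (is.null(background)) background <- ROBINSON_FREQS
  stopifnot(all(background > 0), abs(sum(background) - 1) < 1e-6,
            pseudocount > 0)
  info <- consensus_info(profile)
  bg <- background[AA20]
  # spread ambiguous (X) residues over the background composition
  xspread <- outer(bg, profile$counts["X", info$cols])
  counts <- profile$counts[AA20, info$cols, drop = FALSE] + xspread
  ncol_res <- colSums(profile$counts[AAX, info$cols, drop = FALSE])
  num <- counts + pseudocount * bg
  sc <- log2(sweep(num, 2, ncol_res + pseudocount, "/") / bg)
  scores <- cbind(t(sc), X = 0)
  colnames(scores) <- AAX
  structure(list(region_id = profile$region_id, scores = scores,
                 cols = info$cols),
            class = "pssm")
}

#' Calibrate PSSM search statistics on shuffled decoys
#'
#' Scores the PSSM against residue-shuffled decoys drawn from the
#' dataset and fits a Gumbel distribution to the optimal local scores,
#' exactly as in the pairwise calibration.
#'
#' @param pssm A `pssm`.
#' @param seqs Dataset sequences to shuffle into decoys.
#' @param n_decoys Number of decoys.
#' @param gap_open,gap_extend Gap penalties for the profile search.
#' @param seed RNG seed.
#' @return List with `lambda` and `K`.
#' @export
calibrate_pssm <- function(pssm, seqs, n_decoys = 60, gap_open = 10,
                           gap_extend = 2, seed = 1) {
  stopifnot(length(seqs) >= 1)
  picks_scores <- with_seed(seed, {
    picks <- sample(seq_along(seqs), n_decoys, replace = TRUE)
    vapply(picks, function(i) {
      decoy <- paste(sample(split_chars(seqs[[i]])), collapse = "")
      pssm_score_one(pssm, decoy, gap_open, gap_extend)[1]
    }, numeric(1))
  })
  fit <- fit_gumbel(picks_scores)
  mean_len <- mean(nchar(seqs))
  list(lambda = 1 / fit$beta,
       K = exp(fit$mu / fit$beta) / (nrow(pssm$scores) * mean_len))
}

# best local alignment of a PSSM against one sequence:
# c(score, pssm_start, pssm_end, seq_start, seq_end)
pssm_score_one <- function(pssm, seq, gap_open, gap_extend) {
  idx <- match(split_chars(seq), AAX)
  idx[is.na(idx)] <- match("X", AAX)
  S <- t(pssm$scores)[idx, , drop = FALSE]  # L_seq x n_positions
  r <- sw_affine_best(t(S), gap_open, gap_extend)
  r
}

#' Search a PSSM against a sequence set
#'
#' Locally aligns the position-specific scores against every sequence
#' under affine gaps and reports the single best hit per sequence when
#' its e-value is at or below the threshold. One search pass only; the
#' profile is never re-estimated from the hits.
#'
#' @param pssm A `pssm`.
#' @param seqs Named character vector of residue strings.
#' @param evalue_threshold Significance threshold (default 1e-5).
#' @param gap_open,gap_extend Gap penalties.
#' @param calibration List with `lambda`, `K` from [calibrate_pssm()].
#' @param db_residues Total residue count of the search space; defaults
#'   to `sum(nchar(seqs))`.
#' @return Data frame of hits: `region_id`, `seq_id`, `evalue`,
#'   `start`, `end` (1-based inclusive span on the sequence).
#' @export
pssm_search <- function(pssm, seqs, evalue_threshold = 1e-5,
                        gap_open = 10, gap_extend = 2,
                        calibration, db_residues = NULL) {
  validate_sequences(seqs)
  if (is.null(db_residues)) db_residues <- sum(nchar(seqs))
  n_pos <- nrow(pssm$scores)
  rows <- lapply(names(seqs), function(id) {
    r <- pssm_score_one(pssm, seqs[[id]], gap_open, gap_extend)
    if (r[1] <= 0) return(NULL)
    ev <- estimate_evalue(r[1], n_pos, db_residues,
                          calibration$lambda, calibration$K)
    if (ev > evalue_threshold) return(NULL)
    data.frame(region_id = pssm$region_id, seq_id = id, evalue = ev,
               start = as.integer(r[4]), end = as.integer(r[5]),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    return(data.frame(region_id = character(0), seq_id = character(0),
                      evalue = numeric(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

# map aligned consensus positions between two profiles from a Biostrings
# local pairwise alignment; returns a two-column matrix of consensus
# position pairs plus the aligned span lengths
consensus_alignment_map <- function(ca, cb, m, gap_open, gap_extend) {
  aln <- Biostrings::pairwiseAlignment(
    as_aa(ca), as_aa(cb), type = "local", substitutionMatrix = m,
    gapOpening = gap_open, gapExtension = gap_extend)
  pa <- split_chars(as.character(Biostrings::alignedPattern(aln)))
  pb <- split_chars(as.character(Biostrings::alignedSubject(aln)))
  ia <- as.integer(BiocGenerics::start(aln@pattern@range)) - 1L
  ib <- as.integer(BiocGenerics::start(aln@subject@range)) - 1L
  pos_a <- integer(0)
  pos_b <- integer(0)
  for (k in seq_along(pa)) {
    if (pa[k] != GAP) ia <- ia + 1L
    if (pb[k] != GAP) ib <- ib + 1L
    if (pa[k] != GAP && pb[k] != GAP) {
      pos_a <- c(pos_a, ia)
      pos_b <- c(pos_b, ib)
    }
  }
  list(score = Biostrings::score(aln), map = cbind(pos_a, pos_b),
       a_span = c(as.integer(BiocGenerics::start(aln@pattern@range)),
                  as.integer(BiocGenerics::end(aln@pattern@range))),
       b_span = c(as.integer(BiocGenerics::start(aln@subject@range)),
                  as.integer(BiocGenerics::end(aln@subject@range))))
}

merge_two_profiles <- function(long, short, map_ls) {
  counts <- long$counts
  cols_l <- consensus_info(long)$cols
  cols_s <- consensus_info(short)$cols
  for (r in seq_len(nrow(map_ls))) {
    col_l <- cols_l[map_ls[r, 1]]
    col_s <- cols_s[map_ls[r, 2]]
    counts[, col_l] <- counts[, col_l] + short$counts[, col_s]
  }
  members <- unique(rbind(long$members, short$members))
  rownames(members) <- NULL
  structure(list(
    region_id = min(long$region_id, short$region_id),
    clique_id = paste(unique(c(long$clique_id, short$clique_id)),
                      collapse = "+"),
    span = long$span, n_rows = long$n_rows + short$n_rows,
    counts = counts, members = members,
    assoc = sort(unique(c(long$assoc, short$assoc)))),
    class = "region_profile")
}

#' Merge redundant conserved regions
#'
#' Consensus sequences of all regions are aligned all-against-all
#' (Smith-Waterman). Significantly aligned pairs (e-value at or below
#' `align_threshold`) are merged when the aligned overlap covers the
#' shorter consensus entirely (containment) or more than
#' `overlap_fraction` of it; slight overlaps are left alone. The merged
#' profile sums per-column counts over aligned columns (unaligned
#' flanks of the longer profile carry through) and its association set
#' is the union of the two. Pairs are processed in ascending e-value
#' order, repeating until no pair qualifies. This step reunites family
#' members split across random groups upstream, which is what lets
#' families with more than `max_group` members be detected.
#'
#' @param profiles List of `region_profile`s, each optionally carrying
#'   an `assoc` character vector of associated sequence ids.
#' @param align_threshold E-value threshold for consensus alignment
#'   significance (default 0.01).
#' @param overlap_fraction Minimum overlap of the shorter consensus
#'   (default 0.9).
#' @param matrix,gap_open,gap_extend Alignment parameters for the
#'   consensus alignments.
#' @param calibration Optional e-value calibration (lambda, K).
#' @return List with `profiles` (merged list, canonical order) and
#'   `map` (named character vector, input region id -> output region
#'   id).
#' @export
merge_regions <- function(profiles, align_threshold = 0.01,
                          overlap_fraction = 0.9, matrix = "BLOSUM50",
                          gap_open = 10, gap_extend = 2,
                          calibration = NULL) {
  mname <- if (is.character(matrix)) matrix else "custom"
  m <- if (is.character(matrix)) load_matrix(matrix) else matrix
  cal <- resolve_calibration(mname, gap_open, gap_extend, calibration)
  for (i in seq_along(profiles)) {
    if (is.null(profiles[[i]]$assoc)) {
      profiles[[i]]$assoc <- sort(unique(profiles[[i]]$members$seq_id))
    }
  }
  map <- setNames(vapply(profiles, `[[`, character(1), "region_id"),
                  vapply(profiles, `[[`, character(1), "region_id"))

  repeat {
    k <- length(profiles)
    if (k < 2) break
    cons <- vapply(profiles, consensus, character(1))
    db_res <- sum(nchar(cons))
    best <- NULL
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        res <- consensus_alignment_map(cons[i], cons[j], m, gap_open,
                                       gap_extend)
        if (res$score <= 0) next
        ev <- estimate_evalue(res$score,
                              min(nchar(cons[i]), nchar(cons[j])),
                              db_res, cal$lambda, cal$K)
        if (ev > align_threshold) next
        shorter_is_a <- nchar(cons[i]) <= nchar(cons[j])
        short_len <- min(nchar(cons[i]), nchar(cons[j]))
        span <- if (shorter_is_a) res$a_span else res$b_span
        covered <- span[2] - span[1] + 1
        if (covered < nchar(cons[if (shorter_is_a) i else j]) &&
            covered <= overlap_fraction * short_len) next
        if (is.null(best) || ev < best$ev) {
          best <- list(i = i, j = j, ev = ev, res = res,
                       shorter_is_a = shorter_is_a)
        }
      }
    }
    if (is.null(best)) break
    i <- best$i; j <- best$j
    if (best$shorter_is_a) {
      long <- profiles[[j]]; short <- profiles[[i]]
      map_ls <- best$res$map[, c(2, 1), drop = FALSE]
    } else {
      long <- profiles[[i]]; short <- profiles[[j]]
      map_ls <- best$res$map[, c(1, 2), drop = FALSE]
    }
    merged <- merge_two_profiles(long, short, map_ls)
    map[map %in% c(long$region_id, short$region_id)] <- merged$region_id
    profiles <- c(profiles[-c(i, j)], list(merged))
  }
  ord <- order(vapply(profiles, `[[`, character(1), "region_id"))
  list(profiles = profiles[ord], map = map)
}

#' Binary sequence-by-region association table
#'
#' @param hits Hits data frame (`region_id`, `seq_id`, ...).
#' @param seq_ids All dataset sequence ids (table rows).
#' @param region_ids All region ids (table columns).
#' @return Integer 0/1 matrix, rows = sequences, columns = regions;
#'   repeated hits of a region on a sequence collapse to a single 1.
#' @export
association_table <- function(hits, seq_ids, region_ids) {
  tab <- matrix(0L, nrow = length(seq_ids), ncol = length(region_ids),
                dimnames = list(seq_ids, region_ids))
  if (nrow(hits) > 0) {
    keep <- hits$seq_id %in% seq_ids & hits$region_id %in% region_ids
    tab[cbind(hits$seq_id[keep], hits$region_id[keep])] <- 1L
  }
  tab
}

#' Cluster sequences from the association table
#'
#' Two sequences are linked when they share at least one conserved
#' region; clusters are the connected components of that relation.
#' Sequences with all-zero rows become singletons.
#'
#' @param tab Binary association matrix (see [association_table()]).
#' @return List of character vectors (sorted member ids), ordered by
#'   decreasing size then lexicographically.
#' @export
cluster_from_associations <- function(tab) {
  ids <- rownames(tab)
  # a star per region column yields the same connected components as
  # the full co-membership clique
  edges <- do.call(rbind, lapply(seq_len(ncol(tab)), function(j) {
    memb <- ids[tab[, j] > 0]
    if (length(memb) < 2) return(NULL)
    cbind(memb[1], memb[-1])
  }))
  g <- igraph::graph_from_data_frame(
    if (is.null(edges)) data.frame(a = character(0), b = character(0))
    else data.frame(a = edges[, 1], b = edges[, 2]),
    directed = FALSE, vertices = data.frame(name = ids))
  connected_components(g)
}
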