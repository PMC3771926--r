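# Multiple alignment, conservation scoring, median filtering and region
# extraction.

# score an alignment of two gapped rows under affine gaps with free end
# gaps, for comparison against a pairwise aligner
score_two_row_alignment <- function(al, m, open, ext) {
  a <- strsplit(al[[1]], "")[[1]]
  b <- strsplit(al[[2]], "")[[1]]
  gapped <- a == "-" | b == "-"
  # trim free terminal gap columns; a fully staggered pair scores 0
  core <- which(!gapped)
  if (length(core) == 0) return(0)
  keep <- min(core):max(core)
  a <- a[keep]
  b <- b[keep]
  score <- 0
  in_gap <- FALSE
  for (k in seq_along(a)) {
    if (a[k] == "-" || b[k] == "-") {
      score <- score - ext - if (in_gap) 0 else open
      in_gap <- TRUE
    } else {
      score <- score + m[a[k], b[k]]
      in_gap <- FALSE
    }
  }
  score
}

test_that("identical sequences align gap-free and fully conserved", {
  seqs <- setNames(rep("MKTAYIAKQRQISFVKSHFSRQLEERLGLIE", 4),
                   paste0("s", 1:4))
  al <- progressive_msa(seqs)
  expect_false(any(grepl("-", al, fixed = TRUE)))
  expect_true(all(conservation_scores(al) == 1))
  expect_error(progressive_msa(seqs[1]), "at least 2")
})

test_that("two-sequence alignment reproduces the pairwise aligner score", {
  b62 <- load_matrix("BLOSUM62")
  set.seed(6)
  for (rep in 1:5) {
    seqs <- random_sequences(2, 40, seed = 600 + rep)
    al <- progressive_msa(seqs)
    want <- Biostrings::score(Biostrings::pairwiseAlignment(
      Biostrings::AAString(seqs[[1]]), Biostrings::AAString(seqs[[2]]),
      type = "overlap", substitutionMatrix = b62, gapOpening = 10,
      gapExtension = 1))
    # ends-free alignment can always fall back to the empty (fully
    # staggered) alignment at score 0
    expect_equal(score_two_row_alignment(al, b62, 10, 1), max(want, 0))
  }
})

test_that("de-gapping alignment rows recovers the input residues", {
  ds <- generate_dataset(n_families = 1, members_per_family = 6,
                         multi_domain_fraction = 0, remote_fraction = 0,
                         seed = 13)
  al <- progressive_msa(ds$sequences)
  expect_identical(gsub("-", "", al)[names(ds$sequences)], ds$sequences)
  expect_equal(length(unique(nchar(al))), 1)
})

test_that("alignment files round-trip in FASTA and parse in Clustal", {
  al <- c(r1 = "MKT-AYI", r2 = "MKTPAYI")
  path <- withr::local_tempfile(fileext = ".afa")
  write_alignment(al, path)
  expect_identical(read_alignment(path), al)

  clustal <- withr::local_tempfile(fileext = ".aln")
  writeLines(c("CLUSTAL W (1.83) multiple sequence alignment", "", "",
               "r1              MKT-AYI", "r2              MKTPAYI",
               "", ""), clustal)
  expect_identical(read_alignment(clustal), al)

  ragged <- withr::local_tempfile(fileext = ".afa")
  writeLines(c(">r1", "MKT-AYI", ">r2", "MKTPAYIII"), ragged)
  expect_error(read_alignment(ragged), "r2")
})

test_that("divergent rows receive larger weights", {
  same <- c(a = "MKTAYIAKQR", b = "MKTAYIAKQR", c = "MKTAYIAKQR")
  expect_equal(unname(sequence_weights(same)), rep(1 / 3, 3))
  two <- c(a = "MKTAYI", b = "MKTWYI")
  expect_equal(unname(sequence_weights(two)), c(0.5, 0.5))
  three <- c(a = "MKTAYIAKQR", b = "MKTAYIAKQR", c = "WWPGYIDEQR")
  w <- sequence_weights(three)
  expect_gt(w[["c"]], max(w[["a"]], w[["b"]]))
  expect_equal(sum(w), 1)
})

test_that("conservation scores match the double-sum oracle and bracket [0,1]", {
  al <- c(r1 = "AAWGC-TSSF",
          r2 = "AAWGCPTSVF",
          r3 = "AVWG--TSIF",
          r4 = "AAFGCPASSF",
          r5 = "AAWGC-TS-F")
  w <- sequence_weights(al)
  mut <- conregid:::normalized_mutation_matrix(load_matrix("BLOSUM62"))
  mut_full <- matrix(0, 22, 22,
                     dimnames = list(c(rownames(mut), "-"),
                                     c(colnames(mut), "-")))
  mut_full[rownames(mut), colnames(mut)] <- mut
  got <- conservation_scores(al)
  rows <- do.call(rbind, strsplit(al, ""))
  for (col in seq_len(ncol(rows))) {
    expect_equal(got[col],
                 oracle_column_conservation(rows[, col], w, mut_full),
                 tolerance = 1e-12, label = paste("column", col))
  }
  expect_true(all(got >= 0 & got <= 1))
  # identical column scores exactly 1, all-gap column 0
  al2 <- c(r1 = "A-", r2 = "A-", r3 = "A-")
  expect_equal(unname(conservation_scores(al2)), c(1, 0))
  # row-permutation invariance
  expect_equal(conservation_scores(al[c(3, 1, 5, 2, 4)]), got)
})

test_that("median filter equals the sort-window oracle and obeys its invariants", {
  set.seed(41)
  for (rep in 1:10) {
    n <- sample(60:300, 1)
    frame <- sample(c(4, 10, 50), 1)
    track <- round(runif(n), 3)
    got <- median_filter(track, frame)
    expect_equal(got, oracle_median_filter(track, frame))
    # output values are members of the window multiset (incl. pad zeros)
    expect_true(all(got %in% c(0, track)))
  }
  # constant track survives; all-zero stays zero; idempotent on constants
  ones <- rep(1, 200)
  expect_equal(median_filter(ones, 50), ones)
  expect_equal(median_filter(rep(0, 100), 50), rep(0, 100))
  # monotone: raising scores never lowers the filtered track
  base <- runif(150)
  raised <- pmin(base + runif(150, 0, 0.3), 1)
  expect_true(all(median_filter(raised, 50) >= median_filter(base, 50)))
})

test_that("region extraction applies the strict threshold and minimum length", {
  track <- rep(0, 500)
  track[100:118] <- 1  # 19-long run: below min length
  expect_equal(nrow(extract_regions(median_filter(track), 0.2, 20)), 0)

  # exactly-at-threshold positions are not conserved (strict inequality)
  t2 <- rep(0.2, 100)
  expect_equal(nrow(extract_regions(t2, 0.2, 20)), 0)

  # ideal planted run of 30 survives smoothing exactly
  t3 <- rep(0, 500)
  t3[200:229] <- 1
  reg <- extract_regions(median_filter(t3), 0.2, 20)
  expect_equal(nrow(reg), 1)
  expect_equal(c(reg$start, reg$end), c(200L, 229L))

  # ideal planted run of 24 is erased entirely by the filter
  t4 <- rep(0, 500)
  t4[200:223] <- 1
  expect_equal(sum(median_filter(t4) > 0.2), 0)
})

test_that("recovered boundaries of ideal planted regions deviate by at most 3 columns", {
  for (len in c(30, 60, 120)) {
    track <- rep(0, 500)
    start <- 150
    track[start:(start + len - 1)] <- 1
    reg <- extract_regions(median_filter(track), 0.2, 20)
    expect_equal(nrow(reg), 1)
    expect_lte(abs(reg$start - start), 3)
    expect_lte(abs(reg$end - (start + len - 1)), 3)
  }
})

test_that("profiles count residues and map spans to residue coordinates", {
  al <- setNames(rep(paste(rep("ACDEFGHIKLMNPQRSTVWYACDEF", 2),
                           collapse = ""), 4), paste0("s", 1:4))
  p <- build_profile(al, c(6, 30), clique_id = "C1", region_id = "R1")
  expect_true(all(colSums(p$counts) == 4))
  expect_true(all(apply(p$counts, 2, max) == 4))
  expect_equal(p$members$start, rep(6L, 4))
  expect_equal(p$members$end, rep(30L, 4))

  # a row with gaps inside the span maps to a shorter residue interval
  al2 <- c(a = "MKTAYIAKQR", b = "MKT--IAKQR")
  p2 <- build_profile(al2, c(2, 7))
  expect_equal(p2$members$start, c(2L, 2L))
  expect_equal(p2$members$end, c(7L, 5L))
  expect_equal(sum(p2$counts["-", ]), 2)
  expect_true(all(colSums(p2$counts) == 2))
})

test_that("a planted 60-residue domain in flanks is recovered with Jaccard >= 0.8", {
  ds <- generate_dataset(n_families = 1, members_per_family = 10,
                         multi_domain_fraction = 0, remote_fraction = 0,
                         domain_length_range = c(60, 60),
                         seed = 55)
  al <- progressive_msa(ds$sequences)
  track <- median_filter(conservation_scores(al))
  reg <- extract_regions(track)
  expect_equal(nrow(reg), 1)
  p <- build_profile(al, c(reg$start, reg$end))
  expect_setequal(p$members$seq_id, names(ds$sequences))
  for (k in seq_len(nrow(p$members))) {
    truth <- ds$annotations[
      ds$annotations$seq_id == p$members$seq_id[k], ]
    inter <- min(truth$end, p$members$end[k]) -
      max(truth$start, p$members$start[k]) + 1
    uni <- max(truth$end, p$members$end[k]) -
      min(truth$start, p$members$start[k]) + 1
    expect_gte(inter / uni, 0.8)
  }
})
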