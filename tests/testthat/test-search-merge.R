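# Consensus, PSSM construction and search, region merging, association
# table and final clustering.

# build a region_profile directly from a small alignment block
toy_profile <- function(rows, region_id = "R1", clique_id = "C1") {
  al <- setNames(rows, paste0("s", seq_along(rows)))
  build_profile(al, c(1, nchar(rows[1])), clique_id, region_id)
}

test_that("consensus emits the majority residue and drops majority-gap columns", {
  p <- toy_profile(rep("MKTAYIAKQR", 4))
  expect_identical(consensus(p), "MKTAYIAKQR")

  # tie A vs V -> alphabetically first
  p2 <- toy_profile(c("AW", "AW", "VW", "VW"))
  expect_identical(consensus(p2), "AW")

  # 25 columns, 5 of them majority-gap -> 20-residue consensus
  core <- "ACDEFGHIKLMNPQRSTVWY"
  with_gaps <- c(paste0(core, "-----"),
                 paste0(core, "-----"),
                 paste0(core, "WWWWW"))
  p3 <- toy_profile(with_gaps)
  expect_identical(consensus(p3), core)

  all_gap <- toy_profile(c("---", "---"))
  expect_error(consensus(all_gap), "degenerate")
})

test_that("PSSM log-odds have the expected sign pattern and limits", {
  p <- toy_profile(rep("WWWWWWWWWWWWWWWWWWWWWWWWW", 8))
  pssm <- build_pssm(p)
  expect_true(all(pssm$scores[, "W"] > 0))
  expect_true(all(pssm$scores[, "A"] < 0))
  expect_true(all(pssm$scores[, "X"] == 0))

  # counts proportional to the background, large N -> scores near 0
  bg <- rep(1 / 20, 20)
  names(bg) <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  counts <- matrix(0L, 22, 1,
                   dimnames = list(c(names(bg), "X", "-"), NULL))
  counts[names(bg), 1] <- 50L
  prof <- structure(list(region_id = "R9", clique_id = "C9",
                         span = c(1L, 1L), n_rows = 1000L,
                         counts = counts,
                         members = data.frame(seq_id = "s1", start = 1L,
                                              end = 1L)),
                    class = "region_profile")
  pssm_flat <- build_pssm(prof, background = bg)
  expect_lt(max(abs(pssm_flat$scores[, names(bg)])), 0.05)

  # toy column {A:3, G:1}, uniform background, pseudocount 1
  p3 <- toy_profile(c("A", "A", "A", "G"))
  pssm3 <- build_pssm(p3, background = bg, pseudocount = 1)
  expect_equal(unname(pssm3$scores[1, "A"]),
               log2((3 + 1 / 20) / ((4 + 1) * (1 / 20))))
  expect_equal(unname(pssm3$scores[1, "G"]),
               log2((1 + 1 / 20) / ((4 + 1) * (1 / 20))))
  expect_equal(unname(pssm3$scores[1, "C"]),
               log2((0 + 1 / 20) / ((4 + 1) * (1 / 20))))
})

test_that("profile search recovers its own members and rejects shuffled decoys", {
  ds <- generate_dataset(n_families = 1, members_per_family = 10,
                         multi_domain_fraction = 0, remote_fraction = 0,
                         seed = 19)
  al <- progressive_msa(ds$sequences)
  reg <- extract_regions(median_filter(conservation_scores(al)))
  p <- build_profile(al, c(reg$start[1], reg$end[1]), "C1", "R1")
  pssm <- build_pssm(p, background = residue_composition(ds$sequences))
  cal <- calibrate_pssm(pssm, ds$sequences, seed = 7)
  hits <- pssm_search(pssm, ds$sequences, calibration = cal)

  # every member recovered, hit covering >= 90% of its recorded span
  expect_setequal(hits$seq_id, names(ds$sequences))
  for (k in seq_len(nrow(p$members))) {
    h <- hits[hits$seq_id == p$members$seq_id[k], ]
    span_len <- p$members$end[k] - p$members$start[k] + 1
    covered <- min(h$end, p$members$end[k]) -
      max(h$start, p$members$start[k]) + 1
    expect_gte(covered / span_len, 0.9)
    # hit spans lie within the sequence
    expect_gte(h$start, 1)
    expect_lte(h$end, nchar(ds$sequences[[h$seq_id]]))
  }

  # residue-shuffled decoys: at least 95 of 100 score no hit at 1e-5
  set.seed(23)
  decoys <- setNames(vapply(
    sample(names(ds$sequences), 100, replace = TRUE),
    function(id) {
      paste(sample(strsplit(ds$sequences[[id]], "")[[1]]), collapse = "")
    }, character(1)), paste0("d", 1:100))
  dh <- pssm_search(pssm, decoys, calibration = cal)
  expect_lte(nrow(dh), 5)

  # hit count is monotone in the e-value threshold
  h_loose <- pssm_search(pssm, ds$sequences, evalue_threshold = 1e-2,
                         calibration = cal)
  expect_gte(nrow(h_loose), nrow(hits))
})

test_that("duplicate regions merge with association union; slight overlaps do not", {
  seg <- "WQDEFGHIKLMNPWRSTVWYWCDEFGHIKW"
  x <- toy_profile(rep(seg, 5), region_id = "R1")
  y <- toy_profile(rep(seg, 4), region_id = "R2")
  x$assoc <- paste0("p", 1:5)
  y$assoc <- paste0("p", 4:7)
  out <- merge_regions(list(x, y))
  expect_equal(length(out$profiles), 1)
  expect_setequal(out$profiles[[1]]$assoc, paste0("p", 1:7))
  expect_equal(unname(out$map), c("R1", "R1"))
  # counts added: 5 + 4 rows per column
  expect_true(all(colSums(out$profiles[[1]]$counts) == 9))

  # containment: short region inside the long one merges too
  long <- toy_profile(rep(paste0("ACDEFGHIKLMNPQRSTVWY", seg,
                                 "YVWTSRQPNMLKIHGFEDCA"), 3),
                      region_id = "R1")
  short <- toy_profile(rep(seg, 3), region_id = "R2")
  long$assoc <- paste0("p", 1:5)
  short$assoc <- paste0("p", 4:7)
  out2 <- merge_regions(list(long, short))
  expect_equal(length(out2$profiles), 1)
  expect_setequal(out2$profiles[[1]]$assoc, paste0("p", 1:7))
  # unaligned flanks of the longer profile carry through
  expect_equal(ncol(out2$profiles[[1]]$counts), ncol(long$counts))

  # regions sharing only a short overlap stay separate
  a <- toy_profile(rep("MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQAPILSRVGDGTQDNLSGAEKAVQVKVK", 4),
                   region_id = "R1")
  b <- toy_profile(rep("GAEKAVQVKVKALPDAQFEVVHSLAKWKRQTLGQHDFSAGEGLYTHMKALRPDEDRLSPL", 4),
                   region_id = "R2")
  a$assoc <- "p1"
  b$assoc <- "p2"
  out3 <- merge_regions(list(a, b))
  expect_equal(length(out3$profiles), 2)

  # fixpoint: merging the merged output changes nothing
  again <- merge_regions(out2$profiles)
  expect_equal(length(again$profiles), length(out2$profiles))
  expect_identical(again$profiles[[1]]$counts, out2$profiles[[1]]$counts)
})

test_that("association table is binary with one row per sequence", {
  hits <- data.frame(
    region_id = c("R1", "R1", "R2", "R2", "R2"),
    seq_id = c("s1", "s2", "s2", "s3", "s2"),
    evalue = 1e-9, start = 1L, end = 10L)
  tab <- association_table(hits, paste0("s", 1:4), c("R1", "R2"))
  expect_equal(dim(tab), c(4L, 2L))
  expect_true(all(tab %in% 0:1))
  expect_equal(tab["s2", ], c(R1 = 1L, R2 = 1L))  # repeats collapse
  expect_equal(sum(tab["s4", ]), 0)

  empty <- association_table(hits[0, ], paste0("s", 1:3), "R1")
  expect_true(all(empty == 0))
})

test_that("association clustering links sequences sharing a region", {
  tab <- matrix(0L, 6, 2, dimnames = list(paste0("s", 1:6), c("R1", "R2")))
  tab[1:3, 1] <- 1L
  tab[4:6, 2] <- 1L
  expect_equal(cluster_from_associations(tab),
               list(c("s1", "s2", "s3"), c("s4", "s5", "s6")))

  # a bridge sequence chains the two groups
  tab2 <- tab
  tab2["s3", 2] <- 1L
  expect_equal(cluster_from_associations(tab2), list(paste0("s", 1:6)))

  # all-zero table -> all singletons
  tab0 <- matrix(0L, 3, 1, dimnames = list(paste0("s", 1:3), "R1"))
  expect_equal(lengths(cluster_from_associations(tab0)), rep(1L, 3))
})
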