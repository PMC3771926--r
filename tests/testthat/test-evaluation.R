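# Clustering and region-recovery metrics.

test_that("precision and recall follow their set definitions", {
  expect_equal(precision_recall(letters[1:5], letters[1:5]),
               c(precision = 1, recall = 1))
  # TP=3, FP=1, FN=2
  expect_equal(precision_recall(c("a", "b", "c", "x"), letters[1:5]),
               c(precision = 0.75, recall = 0.6))
  expect_equal(precision_recall(c("x", "y"), c("a", "b")),
               c(precision = 0, recall = 0))
  expect_equal(precision_recall(character(0), c("a", "b")),
               c(precision = 0, recall = 0))
})

test_that("combined F-score weights families by size and takes best matches", {
  fams <- list(A = letters[1:5], B = letters[6:10])
  expect_equal(combined_fscore(fams, fams), 1)

  # two families of 5 lumped into one cluster of 10: P=0.5, R=1 -> 2/3
  expect_equal(combined_fscore(list(letters[1:10]), fams), 2 / 3)

  # splitting a correct cluster strictly lowers F
  split_cl <- list(letters[1:3], letters[4:5], letters[6:10])
  expect_lt(combined_fscore(split_cl, fams), 1)

  # invariant under relabeling (list order) of clusters and families
  set.seed(14)
  ids <- paste0("q", 1:12)
  memb <- sample(1:3, 12, replace = TRUE)
  cl_memb <- sample(1:4, 12, replace = TRUE)
  fams2 <- split(ids, memb)
  cls2 <- split(ids, cl_memb)
  f1 <- combined_fscore(cls2, fams2)
  expect_equal(combined_fscore(rev(cls2), rev(fams2)), f1)
  expect_gte(f1, 0)
  expect_lte(f1, 1)
})

test_that("combined F-score equals the exhaustive pairwise oracle", {
  set.seed(91)
  for (rep in 1:20) {
    n <- sample(6:12, 1)
    ids <- paste0("u", seq_len(n))
    fams <- split(ids, sample(1:3, n, replace = TRUE))
    cls <- split(ids, sample(1:4, n, replace = TRUE))
    expect_equal(combined_fscore(cls, fams),
                 oracle_fscore(cls, fams, n))
  }
})

test_that("hit metrics count TP/FN/FP per the reference definitions", {
  ref <- data.frame(seq_id = c("s1", "s1", "s2"),
                    label = c("D1", "D2", "D1"))
  expect_equal(hit_metrics(ref, ref),
               c(sensitivity = 1, precision = 1))

  # a missing reference hit is FN; an extra prediction is FP
  pred <- data.frame(seq_id = c("s1", "s1", "s2"),
                     label = c("D1", "D3", "D1"))
  m <- hit_metrics(pred, ref)
  expect_equal(m[["sensitivity"]], 2 / 3)
  expect_equal(m[["precision"]], 2 / 3)

  # 20-sequence fixture: 2 reference hits dropped, 1 spurious added
  ref20 <- data.frame(seq_id = paste0("t", 1:20), label = "DOM")
  pred20 <- rbind(ref20[-c(3, 17), ],
                  data.frame(seq_id = "t5", label = "WRONG"))
  m20 <- hit_metrics(pred20, ref20)
  expect_equal(m20[["sensitivity"]], 18 / 20)
  expect_equal(m20[["precision"]], 18 / 19)

  # precision only counts sequences with at least one reference hit
  pred_extra <- rbind(pred20,
                      data.frame(seq_id = "unannotated", label = "DOM"))
  expect_equal(hit_metrics(pred_extra, ref20), m20)

  # unlabeled predictions (no paired reference region) are ignored
  pred_na <- rbind(pred20, data.frame(seq_id = "t1", label = NA))
  expect_equal(hit_metrics(pred_na, ref20), m20)
})

test_that("residue metrics equal the per-position bitmap oracle", {
  # reference [1,100] vs predicted [51,150]: TP=FN=FP=50
  ref <- data.frame(seq_id = "s1", start = 1L, end = 100L)
  pred <- data.frame(seq_id = "s1", start = 51L, end = 150L)
  expect_equal(residue_metrics(pred, ref),
               c(sensitivity = 0.5, precision = 0.5))
  expect_equal(residue_metrics(pred, pred),
               c(sensitivity = 1, precision = 1))

  set.seed(63)
  lens <- c(s1 = 200L, s2 = 150L, s3 = 300L)
  rand_ann <- function() {
    do.call(rbind, lapply(names(lens), function(id) {
      k <- sample(0:3, 1)
      if (k == 0) return(NULL)
      starts <- sort(sample(seq_len(lens[[id]] - 30), k))
      data.frame(seq_id = id, start = starts,
                 end = pmin(starts + sample(10:60, k, replace = TRUE),
                            lens[[id]]))
    }))
  }
  for (rep in 1:10) {
    a <- rand_ann()
    b <- rand_ann()
    got <- residue_metrics(a, b)
    want <- oracle_residue_metrics(a, b, lens)
    expect_equal(got, want)
    # swapping roles exchanges sensitivity and precision
    swapped <- residue_metrics(b, a)
    expect_equal(swapped[["sensitivity"]], got[["precision"]])
    expect_equal(swapped[["precision"]], got[["sensitivity"]])
  }
})

test_that("ROC knee lands at the separation point and handles noise", {
  # perfectly separated scores
  scores <- c(rnorm(50, 0, 0.1), rnorm(50, 5, 0.1))
  labels <- rep(c(0, 1), each = 50)
  knee <- roc_knee(scores, labels)
  expect_equal(attr(knee, "tpr"), 1)
  expect_equal(attr(knee, "fpr"), 0)

  expect_error(roc_knee(scores, rep(1, 100)), "both classes")

  # labels independent of scores: knee distance near sqrt(2)/2
  set.seed(8)
  s <- runif(4000)
  l <- rbinom(4000, 1, 0.5)
  k <- roc_knee(s, l)
  d <- sqrt(attr(k, "fpr")^2 + (1 - attr(k, "tpr"))^2)
  expect_lt(abs(d - sqrt(2) / 2), 0.05)

  # two-Gaussian scores: knee near the analytic equal-distance point
  set.seed(9)
  s2 <- c(rnorm(4000, 0, 1), rnorm(4000, 2, 1))
  l2 <- rep(c(0, 1), each = 4000)
  k2 <- roc_knee(s2, l2)
  expect_lt(abs(as.numeric(k2) - 1), 0.15)
})
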