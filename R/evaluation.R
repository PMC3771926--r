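# Clustering and region-recovery evaluation: size-weighted combined
# F-score, hit-count sensitivity/precision, residue-count metrics, and
# ROC-knee threshold calibration.

#' Precision and recall of a cluster against a reference family
#'
#' `TP = |cluster n family|`, `FP = |cluster \ family|`,
#' `FN = |family \ cluster|`; `P = TP/(TP+FP)` (0 for an empty
#' cluster), `R = TP/(TP+FN)`.
#'
#' @param cluster,family Character vectors of member ids; `family` must
#'   be non-empty.
#' @return Named numeric vector `c(precision, recall)`.
#' @export
precision_recall <- function(cluster, family) {
  stopifnot(length(family) > 0)
  tp <- length(intersect(cluster, family))
  fp <- length(setdiff(cluster, family))
  fn <- length(setdiff(family, cluster))
  p <- if (tp + fp == 0) 0 else tp / (tp + fp)
  r <- tp / (tp + fn)
  c(precision = p, recall = r)
}

#' Size-weighted combined F-score of a clustering
#'
#' For each reference family i the best-matching cluster is found by
#' maximising the harmonic mean of precision and recall over all
#' clusters j, and families are combined weighted by size:
#' `F = sum_i (n_i / n) * max_j 2 P_ij R_ij / (P_ij + R_ij)`, with the
#' harmonic term defined as 0 when `P + R = 0`. `n` is the total number
#' of sequences under evaluation.
#'
#' @param clusters List of character vectors (predicted clusters).
#' @param families List of character vectors (reference families).
#' @param n Total number of sequences; defaults to the number of
#'   distinct ids across the families.
#' @return Combined F-score in `[0, 1]`.
#' @export
combined_fscore <- function(clusters, families, n = NULL) {
  stopifnot(length(families) > 0)
  if (is.null(n)) n <- length(unique(unlist(families)))
  total <- 0
  for (fam in families) {
    best <- 0
    for (cl in clusters) {
      pr <- precision_recall(cl, fam)
      s <- pr[["precision"]] + pr[["recall"]]
      h <- if (s == 0) 0 else 2 * pr[["precision"]] * pr[["recall"]] / s
      if (h > best) best <- h
    }
    total <- total + length(fam) / n * best
  }
  total
}

#' Hit-count sensitivity and precision
#'
#' Each hit is a (sequence id, label) pair. A predicted hit matching a
#' reference hit on the same sequence is a true positive; reference
#' hits missing from the predictions are false negatives; predicted
#' hits absent from the reference are false positives. Precision is
#' computed only over sequences that have at least one reference hit.
#'
#' @param predicted,reference Data frames with columns `seq_id` and
#'   `label`. Predicted rows with `NA` labels (regions paired with no
#'   reference label) are ignored.
#' @return Named numeric vector `c(sensitivity, precision)`.
#' @export
hit_metrics <- function(predicted, reference) {
  pred <- predicted[!is.na(predicted$label), c("seq_id", "label")]
  ref <- reference[, c("seq_id", "label")]
  pred_keys <- unique(paste(pred$seq_id, pred$label, sep = "\r"))
  ref_keys <- unique(paste(ref$seq_id, ref$label, sep = "\r"))
  tp <- sum(ref_keys %in% pred_keys)
  fn <- sum(!ref_keys %in% pred_keys)
  ref_seqs <- unique(ref$seq_id)
  pred_on_ref <- pred_keys[vapply(strsplit(pred_keys, "\r", fixed = TRUE),
                                  `[`, character(1), 1L) %in% ref_seqs]
  fp <- sum(!pred_on_ref %in% ref_keys)
  tp_on_ref <- sum(pred_on_ref %in% ref_keys)
  c(sensitivity = if (tp + fn == 0) 0 else tp / (tp + fn),
    precision = if (tp_on_ref + fp == 0) 0 else tp_on_ref / (tp_on_ref + fp))
}

#' Residue-count sensitivity and precision
#'
#' Per sequence and residue position: covered by both annotation sets
#' is a true positive, reference-only a false negative, predicted-only
#' a false positive; counts aggregate over all sequences.
#'
#' @param predicted,reference Annotation data frames with columns
#'   `seq_id`, `start`, `end` (1-based inclusive).
#' @return Named numeric vector `c(sensitivity, precision)`.
#' @export
residue_metrics <- function(predicted, reference) {
  covered <- function(ann) {
    if (nrow(ann) == 0) return(character(0))
    unlist(lapply(seq_len(nrow(ann)), function(i) {
      paste(ann$seq_id[i], ann$start[i]:ann$end[i], sep = "\r")
    }))
  }
  pred <- unique(covered(predicted))
  ref <- unique(covered(reference))
  tp <- sum(ref %in% pred)
  fn <- length(ref) - tp
  fp <- sum(!pred %in% ref)
  c(sensitivity = if (tp + fn == 0) 0 else tp / (tp + fn),
    precision = if (tp + fp == 0) 0 else tp / (tp + fp))
}

#' ROC knee threshold
#'
#' Sweeps candidate thresholds over the observed score values
#' (classifying scores strictly above the threshold as positive),
#' computes the true- and false-positive rates, and returns the
#' threshold whose ROC point is closest (Euclidean) to the ideal corner
#' (FPR = 0, TPR = 1). Ties resolve to the lower threshold.
#'
#' @param scores Numeric vector.
#' @param labels Binary (0/1 or logical) vector; both classes must be
#'   present.
#' @return The knee threshold, with attributes `tpr` and `fpr`.
#' @export
roc_knee <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  if (length(unique(labels)) < 2) {
    stop("roc_knee needs both classes present", call. = FALSE)
  }
  stopifnot(length(scores) == length(labels))
  cand <- sort(unique(c(min(scores) - 1, scores)))
  npos <- sum(labels == 1)
  nneg <- sum(labels == 0)
  best_t <- cand[1]
  best_d <- Inf
  best_pt <- c(0, 0)
  for (t in cand) {
    pos <- scores > t
    tpr <- sum(pos & labels == 1) / npos
    fpr <- sum(pos & labels == 0) / nneg
    d <- sqrt(fpr^2 + (1 - tpr)^2)
    if (d < best_d - 1e-12) {
      best_d <- d
      best_t <- t
      best_pt <- c(tpr, fpr)
    }
  }
  structure(best_t, tpr = best_pt[1], fpr = best_pt[2])
}
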