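# Independent brute-force oracles used to cross-check the package
# implementations. Deliberately slow and literal.

# quadratic affine-gap Smith-Waterman (Gotoh), scores only
oracle_sw_score <- function(a, b, m, open, ext) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A)
  p <- length(B)
  M <- matrix(0, n + 1, p + 1)
  X <- matrix(-Inf, n + 1, p + 1)
  Y <- matrix(-Inf, n + 1, p + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(p + 1)) {
      X[i, j] <- max(M[i - 1, j] - open - ext, X[i - 1, j] - ext)
      Y[i, j] <- max(M[i, j - 1] - open - ext, Y[i, j - 1] - ext)
      diag_best <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
      M[i, j] <- max(0, diag_best + m[A[i - 1], B[j - 1]])
      best <- max(best, M[i, j])
    }
  }
  best
}

# transitive-closure connected components (Floyd-Warshall style)
oracle_components <- function(adj) {
  n <- nrow(adj)
  reach <- adj | diag(n)
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      if (reach[i, k]) reach[i, ] <- reach[i, ] | reach[k, ]
    }
  }
  unique(apply(reach, 1, function(r) paste(which(r), collapse = ",")))
}

# exhaustive maximal-clique enumeration over all vertex subsets
oracle_cliques <- function(adj) {
  n <- nrow(adj)
  is_clique <- function(v) {
    if (length(v) < 2) return(FALSE)
    all(adj[t(combn(v, 2))])
  }
  cliques <- list()
  for (size in 2:n) {
    for (v in combn(n, size, simplify = FALSE)) {
      if (!is_clique(v)) next
      extendable <- any(vapply(setdiff(seq_len(n), v), function(u) {
        all(adj[u, v])
      }, logical(1)))
      if (!extendable) cliques[[length(cliques) + 1]] <- v
    }
  }
  cliques
}

# naive sliding-window upper median with zero padding
oracle_median_filter <- function(track, frame) {
  w <- frame + 1
  left <- ceiling(frame / 2)
  right <- frame - left
  padded <- c(rep(0, left), track, rep(0, right))
  k <- floor(w / 2) + 1
  sapply(seq_along(track), function(p) {
    sort(padded[p:(p + w - 1)])[k]
  })
}

# double-sum weighted sum-of-pairs conservation for one column
oracle_column_conservation <- function(chars, weights, mut) {
  num <- 0
  den <- 0
  n <- length(chars)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      den <- den + weights[i] * weights[j]
      if (chars[i] != "-" && chars[j] != "-") {
        num <- num + weights[i] * weights[j] * mut[chars[i], chars[j]]
      }
    }
  }
  unname(num / den)
}

# combined F-score by explicit enumeration of every (family, cluster)
# pair
oracle_fscore <- function(clusters, families, n) {
  total <- 0
  for (fam in families) {
    h <- vapply(clusters, function(cl) {
      tp <- length(intersect(cl, fam))
      p <- if (length(cl) == 0) 0 else tp / length(cl)
      r <- tp / length(fam)
      if (p + r == 0) 0 else 2 * p * r / (p + r)
    }, numeric(1))
    total <- total + length(fam) / n * max(h)
  }
  total
}

# per-position bitmap residue overlap metrics
oracle_residue_metrics <- function(predicted, reference, seq_lengths) {
  tp <- fn <- fp <- 0
  for (id in names(seq_lengths)) {
    pred <- rep(FALSE, seq_lengths[[id]])
    ref <- rep(FALSE, seq_lengths[[id]])
    pr <- predicted[predicted$seq_id == id, , drop = FALSE]
    rr <- reference[reference$seq_id == id, , drop = FALSE]
    for (k in seq_len(nrow(pr))) pred[pr$start[k]:pr$end[k]] <- TRUE
    for (k in seq_len(nrow(rr))) ref[rr$start[k]:rr$end[k]] <- TRUE
    tp <- tp + sum(pred & ref)
    fn <- fn + sum(!pred & ref)
    fp <- fp + sum(pred & !ref)
  }
  c(sensitivity = tp / (tp + fn), precision = tp / (tp + fp))
}

random_sequences <- function(n, len, seed) {
  set.seed(seed)
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  stats::setNames(
    replicate(n, paste(sample(aa, len, replace = TRUE), collapse = "")),
    paste0("s", seq_len(n)))
}

# igraph handle on an adjacency matrix with vertex names "n1", "n2", ...
graph_from_adj <- function(adj) {
  dimnames(adj) <- list(paste0("n", seq_len(nrow(adj))),
                        paste0("n", seq_len(nrow(adj))))
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
}
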