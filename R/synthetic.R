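# Planted-domain synthetic datasets with ground truth, so every pipeline
# stage is testable without external databases.

draw_residues <- function(n, composition = ROBINSON_FREQS) {
  paste(sample(names(composition), n, replace = TRUE,
               prob = composition), collapse = "")
}

# uniform draw from an inclusive integer range; safe for degenerate
# ranges (sample(60:60, 1) would draw from 1..60)
sample_range <- function(rng) {
  rng[1] + sample.int(rng[2] - rng[1] + 1L, 1L) - 1L
}

.make_domain <- function(id, length, composition, tolerance) {
  list(id = id,
       consensus = draw_residues(length, composition),
       tolerance = rep_len(tolerance, length))
}

#' Generate a planted-domain model
#'
#' A domain model is a consensus residue string drawn from a background
#' composition plus a per-position substitution tolerance in `[0, 1]`
#' modulating how readily each position mutates in emitted members.
#'
#' @param length Consensus length (25 to 300 residues).
#' @param seed RNG seed.
#' @param composition Residue composition for the consensus.
#' @param tolerance Per-position substitution tolerance, recycled to
#'   the consensus length (default 1: all positions equally mutable).
#' @return A `domain_model`: list with `id`, `consensus`, `tolerance`.
#' @export
make_domain <- function(length, seed = 1, composition = ROBINSON_FREQS,
                        tolerance = 1) {
  if (length < 25 || length > 300) {
    stop("domain length must be in [25, 300]", call. = FALSE)
  }
  with_seed(seed, .make_domain("D1", length, composition, tolerance))
}

.emit_member <- function(model, mutation_rate, indel_rate, composition) {
  chars <- split_chars(model$consensus)
  L <- length(chars)
  # point substitutions to a random different residue
  sub <- runif(L) < mutation_rate * model$tolerance
  if (any(sub)) {
    chars[sub] <- vapply(chars[sub], function(orig) {
      pool <- setdiff(names(composition), orig)
      sample(pool, 1, prob = composition[pool])
    }, character(1))
  }
  # short indels (1-3 residues), half insertions half deletions
  out <- character(0)
  mapping <- rep(NA_integer_, L)
  i <- 1
  while (i <= L) {
    ev <- runif(1)
    if (ev < indel_rate / 2) {           # deletion
      i <- i + sample(1:3, 1)
    } else {
      out <- c(out, chars[i])
      mapping[i] <- length(out)
      if (ev < indel_rate) {             # insertion after this residue
        ins <- split_chars(draw_residues(sample(1:3, 1), composition))
        out <- c(out, ins)
      }
      i <- i + 1
    }
  }
  list(segment = paste(out, collapse = ""), mapping = mapping)
}

#' Emit a mutated member copy of a domain model
#'
#' Applies point substitutions at `mutation_rate` (per residue, scaled
#' by the model's positional tolerance) and short 1-3 residue indels at
#' `indel_rate`. The mapping records, for each consensus position, its
#' 1-based coordinate in the emitted segment (`NA` when deleted).
#'
#' @param model A `domain_model` (see [make_domain()]).
#' @param mutation_rate,indel_rate Per-residue event probabilities in
#'   `[0, 0.5]`.
#' @param seed RNG seed.
#' @param composition Residue composition for substitutions/insertions.
#' @return List with `segment` (residue string) and `mapping` (integer
#'   vector over consensus positions).
#' @export
emit_member <- function(model, mutation_rate = 0.1, indel_rate = 0.02,
                        seed = 1, composition = ROBINSON_FREQS) {
  stopifnot(mutation_rate >= 0, mutation_rate <= 0.5,
            indel_rate >= 0, indel_rate <= 0.5)
  with_seed(seed, .emit_member(model, mutation_rate, indel_rate,
                               composition))
}

#' Generate a planted-domain dataset with ground truth
#'
#' Each family contributes `members_per_family` sequences carrying a
#' mutated copy of the family domain embedded in random flanks. A
#' fraction of sequences additionally carries domains of other families
#' (the multi-domain chaining stressor: each such sequence holds up to
#' 3 domains from distinct families, consecutively with random
#' linkers), and a fraction are remote members emitted at an elevated
#' mutation rate, emulating remote homologs whose pairwise alignments
#' fall below significance but that profile searches can still
#' recover. Fully deterministic for a fixed seed.
#'
#' @param n_families Number of domain families.
#' @param members_per_family Sequences per family.
#' @param multi_domain_fraction Fraction of sequences carrying extra
#'   domains from other families.
#' @param remote_fraction Fraction of each family emitted at
#'   `remote_mutation_rate`.
#' @param flank_length_range Integer range for flank/linker lengths.
#' @param seed RNG seed.
#' @param domain_length_range Integer range for domain consensus
#'   lengths.
#' @param mutation_rate Per-residue substitution rate of ordinary
#'   members.
#' @param remote_mutation_rate Elevated rate for remote members.
#' @param indel_rate Per-residue indel rate.
#' @param composition Background residue composition.
#' @return List with `sequences` (named character vector),
#'   `annotations` (data frame `seq_id`, `start`, `end`, `label`),
#'   `families` (named list: domain id -> member sequence ids) and
#'   `models` (the domain models).
#' @export
generate_dataset <- function(n_families = 6, members_per_family = 30,
                             multi_domain_fraction = 0.1,
                             remote_fraction = 0.15,
                             flank_length_range = c(40, 150),
                             seed = 1,
                             domain_length_range = c(80, 160),
                             mutation_rate = 0.1,
                             remote_mutation_rate = 0.3,
                             indel_rate = 0.02,
                             composition = ROBINSON_FREQS) {
  stopifnot(n_families >= 1, members_per_family >= 1,
            multi_domain_fraction >= 0, multi_domain_fraction <= 1,
            remote_fraction >= 0, remote_fraction <= 1)
  with_seed(seed, {
    models <- lapply(seq_len(n_families), function(i) {
      len <- sample_range(domain_length_range)
      .make_domain(sprintf("D%02d", i), len, composition, 1)
    })
    names(models) <- vapply(models, `[[`, character(1), "id")

    ids <- as.vector(t(outer(seq_len(n_families),
                             seq_len(members_per_family),
                             function(i, j) sprintf("F%02d_M%02d", i, j))))
    fam_of <- rep(seq_len(n_families), each = members_per_family)
    n_total <- length(ids)

    # remote members drawn per family; multi-domain carriers drawn from
    # the ordinary (non-remote) pool so remoteness and chaining are
    # separate stressors
    remote <- logical(n_total)
    for (f in seq_len(n_families)) {
      ix <- which(fam_of == f)
      n_rem <- round(remote_fraction * length(ix))
      if (n_rem > 0) remote[sample(ix, n_rem)] <- TRUE
    }
    n_multi <- round(multi_domain_fraction * n_total)
    multi <- rep(FALSE, n_total)
    pool <- which(!remote)
    if (n_multi > 0) multi[sample(pool, min(n_multi, length(pool)))] <- TRUE

    flank <- function() {
      draw_residues(sample_range(flank_length_range), composition)
    }

    seqs <- character(n_total)
    ann <- vector("list", n_total)
    for (s in seq_len(n_total)) {
      f <- fam_of[s]
      rate <- if (remote[s]) remote_mutation_rate else mutation_rate
      doms <- f
      if (multi[s]) {
        extra <- min(2, n_families - 1)
        doms <- c(f, sample(setdiff(seq_len(n_families), f), extra))
      }
      parts <- character(0)
      rows <- list()
      pos <- 0
      for (d in doms) {
        lead <- flank()
        seg <- .emit_member(models[[d]], rate, indel_rate, composition)
        parts <- c(parts, lead, seg$segment)
        start <- pos + nchar(lead) + 1
        end <- start + nchar(seg$segment) - 1
        rows[[length(rows) + 1]] <- data.frame(
          seq_id = ids[s], start = start, end = end,
          label = models[[d]]$id, stringsAsFactors = FALSE)
        pos <- end
      }
      parts <- c(parts, flank())
      seqs[s] <- paste(parts, collapse = "")
      ann[[s]] <- do.call(rbind, rows)
    }
    names(seqs) <- ids
    annotations <- do.call(rbind, ann)
    rownames(annotations) <- NULL
    families <- lapply(names(models), function(d) {
      sort(unique(annotations$seq_id[annotations$label == d]))
    })
    names(families) <- names(models)
    list(sequences = seqs, annotations = annotations,
         families = families, models = models)
  })
}
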