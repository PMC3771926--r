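# End-to-end pipeline: align -> group -> conserve -> search -> merge ->
# table -> cluster, with per-stage artifacts on disk, resumability and a
# run manifest. All randomness flows from the single config seed.

#' Pipeline configuration
#'
#' Collects every tunable threshold of the pipeline with its default:
#' connectivity e-value 0.01, maximum clique-search group size 100,
#' fractional Hamming threshold 0.3, median-filter frame 50,
#' conservation threshold 0.2, minimum region length 20 columns,
#' profile-search e-value 1e-5, merge e-value 0.01 and overlap fraction
#' 0.9; BLOSUM50 with gaps 10/2 for local alignment and BLOSUM62 with
#' gaps 10/1 for alignment/conservation scoring.
#'
#' @param seed Master RNG seed; every stochastic stage derives its
#'   stream from it.
#' @param evalue_connectivity Pairwise e-value threshold for the
#'   connectivity graph.
#' @param max_group Maximum component size fed to clique enumeration.
#' @param hamming_threshold Fractional Hamming threshold for redundant
#'   clique elimination.
#' @param frame Median-filter neighbourhood size (window = frame + 1).
#' @param conservation_threshold Smoothed-score threshold for conserved
#'   positions.
#' @param min_region_length Minimum conserved region length (columns).
#' @param search_evalue E-value threshold of the PSSM search.
#' @param merge_evalue E-value threshold for consensus alignments in
#'   the merge step.
#' @param overlap_fraction Minimum overlap of the shorter consensus for
#'   a merge.
#' @param align_matrix,gap_open,gap_extend Pairwise local alignment
#'   parameters.
#' @param score_matrix,msa_gap_open,msa_gap_extend Multiple alignment
#'   and conservation scoring parameters.
#' @param evalue_cap Storage cap of the similarity map.
#' @param min_seq_length,max_seq_length Input length filter bounds.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1,
                            evalue_connectivity = 0.01,
                            max_group = 100,
                            hamming_threshold = 0.3,
                            frame = 50,
                            conservation_threshold = 0.2,
                            min_region_length = 20,
                            search_evalue = 1e-5,
                            merge_evalue = 0.01,
                            overlap_fraction = 0.9,
                            align_matrix = "BLOSUM50",
                            gap_open = 10,
                            gap_extend = 2,
                            score_matrix = "BLOSUM62",
                            msa_gap_open = 10,
                            msa_gap_extend = 1,
                            evalue_cap = 10,
                            min_seq_length = 100,
                            max_seq_length = 10000) {
  cfg <- as.list(environment())
  stopifnot(cfg$evalue_connectivity > 0, cfg$max_group >= 2,
            cfg$hamming_threshold > 0, cfg$hamming_threshold < 1,
            cfg$frame >= 2, cfg$conservation_threshold > 0,
            cfg$conservation_threshold < 1, cfg$min_region_length >= 1,
            cfg$search_evalue > 0, cfg$merge_evalue > 0,
            cfg$overlap_fraction > 0, cfg$overlap_fraction <= 1)
  structure(cfg, class = "pipeline_config")
}

#' Write / read a pipeline configuration
#'
#' @param config A `pipeline_config`.
#' @param path JSON file path.
#' @return `path` (write) or the configuration (read).
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- jsonlite::fromJSON(path)
  do.call(pipeline_config, cfg)
}

PIPELINE_STAGES <- c("align", "group", "conserve", "search", "merge",
                     "table", "cluster")

artifact <- function(outdir, name) file.path(outdir, name)

require_artifact <- function(outdir, name, stage) {
  p <- artifact(outdir, name)
  if (!file.exists(p)) {
    stop("stage '", stage, "' needs missing upstream artifact: ", name,
         call. = FALSE)
  }
  p
}

profiles_to_json <- function(profiles, path) {
  payload <- lapply(profiles, function(p) {
    list(region_id = p$region_id, clique_id = p$clique_id,
         span = p$span, n_rows = p$n_rows,
         counts = unname(p$counts), members = p$members,
         assoc = if (is.null(p$assoc)) character(0) else p$assoc)
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

profiles_from_json <- function(path) {
  payload <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE,
                                simplifyMatrix = TRUE)
  n <- length(payload$region_id)
  span_of <- function(i) {
    if (is.matrix(payload$span)) payload$span[i, ] else payload$span[[i]]
  }
  lapply(seq_len(n), function(i) {
    counts <- payload$counts[[i]]
    rownames(counts) <- c(AAX, GAP)
    members <- payload$members[[i]]
    structure(list(region_id = payload$region_id[i],
                   clique_id = payload$clique_id[i],
                   span = as.integer(span_of(i)),
                   n_rows = payload$n_rows[i],
                   counts = counts,
                   members = members,
                   assoc = as.character(unlist(payload$assoc[[i]]))),
              class = "region_profile")
  })
}

read_hits <- function(path) {
  read.table(path, sep = "\t", header = TRUE,
             colClasses = c("character", "character", "numeric",
                            "integer", "integer"),
             stringsAsFactors = FALSE)
}

write_hits <- function(hits, path) {
  write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

stage_align <- function(outdir, config) {
  seqs <- read_fasta(artifact(outdir, "input.fasta"))
  sim <- all_against_all(seqs, matrix = config$align_matrix,
                         gap_open = config$gap_open,
                         gap_extend = config$gap_extend,
                         evalue_cap = config$evalue_cap)
  write_similarity_table(sim, artifact(outdir, "sim.tsv"))
}

stage_group <- function(outdir, config) {
  seqs <- read_fasta(artifact(outdir, "input.fasta"))
  sim <- read_similarity_table(
    require_artifact(outdir, "sim.tsv", "group"))
  g <- threshold_connectivity(sim, names(seqs),
                              config$evalue_connectivity)
  comps <- connected_components(g)
  nonsingle <- comps[lengths(comps) >= 2]
  cliques <- list()
  for (ci in seq_along(nonsingle)) {
    groups <- split_large_components(nonsingle[[ci]], config$max_group,
                                     stage_seed(config$seed, 200 + ci))
    for (grp in groups) {
      if (length(grp) < 2) next
      cliques <- c(cliques, maximal_cliques(g, grp))
    }
  }
  n_raw <- length(cliques)
  cliques <- eliminate_redundant(cliques, config$hamming_threshold)
  jsonlite::write_json(
    list(n_components = length(comps),
         n_singletons = sum(lengths(comps) == 1),
         n_cliques_raw = n_raw,
         cliques = cliques),
    artifact(outdir, "cliques.json"), digits = NA, auto_unbox = TRUE)
}

stage_conserve <- function(outdir, config) {
  seqs <- read_fasta(artifact(outdir, "input.fasta"))
  cl <- jsonlite::fromJSON(
    require_artifact(outdir, "cliques.json", "conserve"))
  cliques <- cl$cliques
  if (is.matrix(cliques)) cliques <- split(cliques, row(cliques))
  profiles <- list()
  for (ci in seq_along(cliques)) {
    members <- unlist(cliques[[ci]])
    al <- progressive_msa(seqs[members], matrix = config$score_matrix,
                          gap_open = config$msa_gap_open,
                          gap_extend = config$msa_gap_extend)
    track <- conservation_scores(al, matrix = config$score_matrix)
    smooth <- median_filter(track, config$frame)
    spans <- extract_regions(smooth, config$conservation_threshold,
                             config$min_region_length)
    for (ri in seq_len(nrow(spans))) {
      profiles <- c(profiles, list(build_profile(
        al, c(spans$start[ri], spans$end[ri]),
        clique_id = sprintf("C%04d", ci),
        region_id = "")))
    }
  }
  for (i in seq_along(profiles)) {
    profiles[[i]]$region_id <- sprintf("R%04d", i)
  }
  profiles_to_json(profiles, artifact(outdir, "profiles.json"))
  regions <- do.call(rbind, c(lapply(profiles, function(p) {
    data.frame(region_id = p$region_id, clique_id = p$clique_id,
               seq_id = p$members$seq_id, start = p$members$start,
               end = p$members$end, stringsAsFactors = FALSE)
  }), list(make.row.names = FALSE)))
  if (is.null(regions)) {
    regions <- data.frame(region_id = character(0),
                          clique_id = character(0),
                          seq_id = character(0), start = integer(0),
                          end = integer(0))
  }
  write.table(regions, artifact(outdir, "regions.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
}

stage_search <- function(outdir, config) {
  seqs <- read_fasta(artifact(outdir, "input.fasta"))
  profiles <- profiles_from_json(
    require_artifact(outdir, "profiles.json", "search"))
  background <- residue_composition(seqs)
  db_residues <- sum(nchar(seqs))
  hits <- lapply(seq_along(profiles), function(i) {
    pssm <- build_pssm(profiles[[i]], background = background)
    cal <- calibrate_pssm(pssm, seqs,
                          gap_open = config$gap_open,
                          gap_extend = config$gap_extend,
                          seed = stage_seed(config$seed, 500 + i))
    pssm_search(pssm, seqs, config$search_evalue,
                gap_open = config$gap_open,
                gap_extend = config$gap_extend,
                calibration = cal, db_residues = db_residues)
  })
  hits <- do.call(rbind, hits)
  write_hits(hits, artifact(outdir, "hits.tsv"))
}

stage_merge <- function(outdir, config) {
  profiles <- profiles_from_json(
    require_artifact(outdir, "profiles.json", "merge"))
  hits <- read_hits(require_artifact(outdir, "hits.tsv", "merge"))
  for (i in seq_along(profiles)) {
    rid <- profiles[[i]]$region_id
    profiles[[i]]$assoc <- sort(unique(hits$seq_id[hits$region_id == rid]))
  }
  merged <- merge_regions(profiles,
                          align_threshold = config$merge_evalue,
                          overlap_fraction = config$overlap_fraction,
                          matrix = config$align_matrix,
                          gap_open = config$gap_open,
                          gap_extend = config$gap_extend)
  profiles_to_json(merged$profiles,
                   artifact(outdir, "profiles_merged.json"))
  hits$region_id <- unname(merged$map[hits$region_id])
  hits <- hits[order(hits$region_id, hits$seq_id, hits$evalue), ,
               drop = FALSE]
  hits <- hits[!duplicated(hits[, c("region_id", "seq_id")]), ,
               drop = FALSE]
  rownames(hits) <- NULL
  write_hits(hits, artifact(outdir, "hits_merged.tsv"))
}

stage_table <- function(outdir, config) {
  seqs <- read_fasta(artifact(outdir, "input.fasta"))
  profiles <- profiles_from_json(
    require_artifact(outdir, "profiles_merged.json", "table"))
  hits <- read_hits(require_artifact(outdir, "hits_merged.tsv", "table"))
  region_ids <- vapply(profiles, `[[`, character(1), "region_id")
  tab <- association_table(hits, names(seqs), region_ids)
  df <- data.frame(seq_id = rownames(tab), tab, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, artifact(outdir, "association.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
}

stage_cluster <- function(outdir, config) {
  tab <- read_association(artifact(outdir, "association.tsv"))
  clusters <- cluster_from_associations(tab)
  df <- do.call(rbind, lapply(seq_along(clusters), function(i) {
    data.frame(seq_id = clusters[[i]], cluster = i,
               stringsAsFactors = FALSE)
  }))
  write.table(df, artifact(outdir, "clusters.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
}

#' Read an association table artifact
#'
#' @param path Path to `association.tsv` as written by the pipeline.
#' @return Binary integer matrix, rows = sequences, columns = regions.
#' @export
read_association <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  tab <- as.matrix(df[, -1, drop = FALSE])
  mode(tab) <- "integer"
  rownames(tab) <- df$seq_id
  tab
}

write_manifest <- function(outdir, config) {
  seqs <- read_fasta(artifact(outdir, "input.fasta"))
  sim <- read_similarity_table(artifact(outdir, "sim.tsv"))
  cl <- jsonlite::fromJSON(artifact(outdir, "cliques.json"))
  profiles <- profiles_from_json(artifact(outdir, "profiles.json"))
  merged <- profiles_from_json(artifact(outdir, "profiles_merged.json"))
  hits <- read_hits(artifact(outdir, "hits_merged.tsv"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("conregid")),
    config = unclass(config),
    counts = list(
      sequences = length(seqs),
      similarity_pairs = nrow(sim),
      components = cl$n_components,
      singletons = cl$n_singletons,
      cliques_raw = cl$n_cliques_raw,
      cliques = if (is.matrix(cl$cliques)) nrow(cl$cliques)
                else length(cl$cliques),
      regions_raw = length(profiles),
      regions_merged = length(merged),
      hits = nrow(hits)))
  jsonlite::write_json(manifest, artifact(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run the full conserved-region discovery pipeline
#'
#' Executes align, group, conserve, search, merge, table and cluster in
#' order, writing each stage's artifact into `outdir`: `sim.tsv`,
#' `cliques.json`, `regions.tsv`, `profiles.json`, `hits.tsv`,
#' `profiles_merged.json`, `hits_merged.tsv`, `association.tsv`,
#' `clusters.tsv` and `manifest.json`. Identical runs with the same
#' seed produce identical artifacts.
#'
#' @param input Path to a FASTA file, or a named character vector of
#'   residue strings.
#' @param outdir Output directory (created if needed).
#' @param config A `pipeline_config`.
#' @param apply_length_filter Drop sequences outside the configured
#'   length window before analysis (default TRUE).
#' @return `outdir`, invisibly.
#' @export
run_pipeline <- function(input, outdir, config = pipeline_config(),
                         apply_length_filter = TRUE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seqs <- if (is.character(input) && length(input) == 1 &&
              file.exists(input) && is.null(names(input))) {
    read_fasta(input)
  } else {
    validate_sequences(input)
    input
  }
  if (apply_length_filter) {
    seqs <- length_filter(seqs, config$min_seq_length,
                          config$max_seq_length)
  }
  if (length(seqs) < 2) {
    stop("pipeline needs at least 2 sequences after filtering",
         call. = FALSE)
  }
  write_fasta(seqs, artifact(outdir, "input.fasta"))
  write_config(config, artifact(outdir, "config.json"))
  for (stage in PIPELINE_STAGES) {
    run_stage(stage, outdir, config)
  }
  write_manifest(outdir, config)
  invisible(outdir)
}

run_stage <- function(stage, outdir, config) {
  message("conregid: stage ", stage)
  switch(stage,
         align = stage_align(outdir, config),
         group = stage_group(outdir, config),
         conserve = stage_conserve(outdir, config),
         search = stage_search(outdir, config),
         merge = stage_merge(outdir, config),
         table = stage_table(outdir, config),
         cluster = stage_cluster(outdir, config),
         stop("unknown stage: ", stage, call. = FALSE))
}

#' Resume the pipeline from a named stage
#'
#' Recomputes from the named stage onward using the artifacts already
#' stored in `outdir`; missing upstream artifacts are an error naming
#' the artifact.
#'
#' @param stage One of `"align"`, `"group"`, `"conserve"`, `"search"`,
#'   `"merge"`, `"table"`, `"cluster"`.
#' @param outdir Pipeline output directory holding `config.json`.
#' @return `outdir`, invisibly.
#' @export
resume_pipeline <- function(stage, outdir) {
  stage <- match.arg(stage, PIPELINE_STAGES)
  config <- read_config(
    require_artifact(outdir, "config.json", stage))
  require_artifact(outdir, "input.fasta", stage)
  from <- match(stage, PIPELINE_STAGES)
  for (s in PIPELINE_STAGES[from:length(PIPELINE_STAGES)]) {
    run_stage(s, outdir, config)
  }
  write_manifest(outdir, config)
  invisible(outdir)
}

#' Evaluate pipeline output against reference annotations
#'
#' Pairs each merged region with the reference label it overlaps most
#' (by residue count over all hit spans; regions with no overlap stay
#' unlabelled), then computes hit-count sensitivity/precision,
#' residue-count sensitivity/precision, and the combined F-score of
#' the region association sets against the reference families (the
#' per-label member sets).
#'
#' @param outdir Pipeline output directory.
#' @param reference Annotation data frame (`seq_id`, `start`, `end`,
#'   `label`).
#' @return List with `hit` and `residue` metric vectors, `fscore`, and
#'   the `region_labels` pairing.
#' @export
evaluate_pipeline <- function(outdir, reference) {
  hits <- read_hits(artifact(outdir, "hits_merged.tsv"))
  tab <- read_association(artifact(outdir, "association.tsv"))

  overlap_len <- function(s1, e1, s2, e2) {
    pmax(0L, pmin(e1, e2) - pmax(s1, s2) + 1L)
  }
  labels <- sort(unique(reference$label))
  region_ids <- colnames(tab)
  region_labels <- setNames(rep(NA_character_, length(region_ids)),
                            region_ids)
  for (rid in region_ids) {
    h <- hits[hits$region_id == rid, , drop = FALSE]
    if (nrow(h) == 0) next
    ov <- vapply(labels, function(lab) {
      r <- reference[reference$label == lab, , drop = FALSE]
      total <- 0L
      for (k in seq_len(nrow(h))) {
        rr <- r[r$seq_id == h$seq_id[k], , drop = FALSE]
        if (nrow(rr) > 0) {
          total <- total + sum(overlap_len(h$start[k], h$end[k],
                                           rr$start, rr$end))
        }
      }
      total
    }, numeric(1))
    if (max(ov) > 0) region_labels[rid] <- labels[which.max(ov)]
  }

  predicted_hits <- data.frame(seq_id = hits$seq_id,
                               label = region_labels[hits$region_id],
                               stringsAsFactors = FALSE)
  hit <- hit_metrics(predicted_hits, reference)
  residue <- residue_metrics(
    hits[, c("seq_id", "start", "end")],
    reference[, c("seq_id", "start", "end")])
  families <- lapply(labels, function(lab) {
    sort(unique(reference$seq_id[reference$label == lab]))
  })
  names(families) <- labels
  clusters <- lapply(seq_len(ncol(tab)), function(j) {
    rownames(tab)[tab[, j] > 0]
  })
  # families may overlap (multi-domain sequences belong to several), so
  # weight by total family membership to keep the score in [0, 1]
  fscore <- combined_fscore(clusters, families,
                            n = sum(lengths(families)))
  list(hit = hit, residue = residue, fscore = fscore,
       region_labels = region_labels)
}
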