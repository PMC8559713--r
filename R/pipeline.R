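# Pipeline orchestration: writing/loading the simulated dataset in the
# package's on-disk formats (GTF, FASTA, TSV), and the analysis stages the
# command-line interface dispatches to. Every stage writes TSV tables and a
# structured log line with input/output row counts.

.log_stage <- function(stage, ...) {
  kv <- c(...)
  message(sprintf("[%s] %s", stage,
                  paste(names(kv), kv, sep = "=", collapse = " ")))
}

#' Default pipeline configuration
#'
#' Every analysis threshold is a config key; defaults are the values used
#' throughout the package documentation.
#'
#' @param simulation A [simulation_config()] (or list of overrides).
#' @return Nested configuration list.
#' @export
default_config <- function(simulation = list()) {
  sim <- do.call(simulation_config, simulation)
  list(
    simulation = unclass(sim),
    npidr = list(threshold = 0.1, n_bins = 20),
    classify = list(tau_threshold = 0.9, trsf_tau_threshold = 0.5,
                    aire_fc = 2, aire_p = 0.05, count_depth = 5,
                    dispersion = 0.1),
    census = list(detection_thresholds = c(0, 0.1, 0.5, 1, 2, 5),
                  target_sample = "mTEC_mature_r1",
                  exclude_from_ancova = "testis"),
    junctions = list(min_reads = 1, dispersion = 0.1, fc_threshold = 2,
                     p_threshold = 0.05, tec_sample = "mTEC_mature_r1"),
    events = list(delta_threshold = 0.2, fdr_threshold = 0.05,
                  min_reads = 10, min_total_tpm = 1, microexon_cutoff = 30,
                  exon_length_floor = 50),
    aire = list(fc_threshold = 2, p_threshold = 0.05, dispersion = 0.1,
                count_depth = 5),
    motifs = list(motif = "WGCAUGM", n_perm = 1000, fdr = 0.05,
                  window_intron = 250, window_exon = 50, smooth = 31)
  )
}

#' Read a pipeline configuration from YAML
#'
#' Missing keys fall back to [default_config()] values.
#'
#' @param path YAML file path.
#' @return Configuration list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  base <- default_config(if (is.null(user$simulation)) list()
                         else user$simulation)
  for (section in setdiff(names(base), "simulation")) {
    if (!is.null(user[[section]])) {
      for (k in names(user[[section]])) {
        if (!k %in% names(base[[section]])) {
          stop("unknown config key: ", section, "$", k)
        }
        base[[section]][[k]] <- user[[section]][[k]]
      }
    }
  }
  base$input_dir <- user$input_dir
  base
}

#' Write a simulated dataset to a directory
#'
#' GTF annotation, FASTA genome, TPM/count TSVs, detection pools and truth
#' tables, in the formats the analysis stages read back.
#'
#' @param sim Output of [simulate_dataset()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_gtf(sim$annotation, file.path(dir, "annotation.gtf"))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sim$genome),
                              file.path(dir, "genome.fa"))
  write_tsv(sim$samples, file.path(dir, "samples.tsv"))
  write_expression_tsv(sim$transcript_tpm,
                       file.path(dir, "transcript_tpm.tsv"))
  write_expression_tsv(sim$gene_tpm, file.path(dir, "gene_tpm.tsv"))
  write_tsv(cbind(sim$junctions$junctions, sim$junctions$counts),
            file.path(dir, "junction_counts.tsv"))
  write_tsv(data.frame(event_id = rownames(sim$events$inclusion),
                       sim$events$inclusion, check.names = FALSE),
            file.path(dir, "event_inclusion.tsv"))
  write_tsv(data.frame(event_id = rownames(sim$events$skipping),
                       sim$events$skipping, check.names = FALSE),
            file.path(dir, "event_skipping.tsv"))
  write_tsv(data.frame(sample_id = colnames(sim$events$inclusion),
                       condition = sim$events$conditions),
            file.path(dir, "event_conditions.tsv"))
  pools <- do.call(rbind, lapply(names(sim$pools), function(s) {
    rbind(data.frame(sample_id = s, replicate = 1L,
                     transcript_id = sim$pools[[s]]$rep1),
          data.frame(sample_id = s, replicate = 2L,
                     transcript_id = sim$pools[[s]]$rep2))
  }))
  write_tsv(pools, file.path(dir, "detection_pools.tsv"))
  write_tsv(sim$gene_truth, file.path(dir, "truth_genes.tsv"))
  write_tsv(sim$exon_truth, file.path(dir, "truth_exons.tsv"))
  write_tsv(sim$events$event_truth, file.path(dir, "truth_events.tsv"))
  invisible(dir)
}

#' Load a simulated dataset written by [write_simulation()]
#' @param dir Directory containing the dataset files.
#' @return List mirroring [simulate_dataset()] output (without `config`).
#' @export
load_simulation <- function(dir) {
  need <- function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p)) stop("missing input file: ", p)
    p
  }
  samples <- read_tsv(need("samples.tsv"))
  ann <- read_gtf(need("annotation.gtf"))
  genome_set <- Biostrings::readDNAStringSet(need("genome.fa"))
  genome <- stats::setNames(as.character(genome_set), names(genome_set))
  tx <- read_expression_tsv(need("transcript_tpm.tsv"), samples,
                            "transcript", "TPM")
  ge <- read_expression_tsv(need("gene_tpm.tsv"), samples, "gene", "TPM")
  jdf <- read_tsv(need("junction_counts.tsv"))
  meta_cols <- c("gene_id", "chrom", "donor", "acceptor", "strand")
  jc <- junction_counts(jdf[meta_cols],
                        as.matrix(jdf[setdiff(names(jdf), meta_cols)]))
  inc <- read_tsv(need("event_inclusion.tsv"))
  skp <- read_tsv(need("event_skipping.tsv"))
  conds <- read_tsv(need("event_conditions.tsv"))
  im <- as.matrix(inc[, -1, drop = FALSE]); rownames(im) <- inc$event_id
  sm <- as.matrix(skp[, -1, drop = FALSE]); rownames(sm) <- skp$event_id
  pools_df <- read_tsv(need("detection_pools.tsv"))
  pools <- lapply(split(pools_df, pools_df$sample_id), function(d) {
    list(rep1 = d$transcript_id[d$replicate == 1],
         rep2 = d$transcript_id[d$replicate == 2])
  })
  list(annotation = ann, genome = genome, samples = samples,
       transcript_tpm = tx, gene_tpm = ge, junctions = jc,
       events = list(inclusion = im, skipping = sm,
                     conditions = conds$condition),
       pools = pools,
       gene_truth = read_tsv(need("truth_genes.tsv")),
       exon_truth = read_tsv(need("truth_exons.tsv")),
       event_truth = read_tsv(need("truth_events.tsv")))
}

# pseudo-counts for the NB tests: TPM scaled to a configured depth
.tpm_to_counts <- function(values, depth) {
  round(values * depth)
}

# ---------------------------------------------------------------------------
# analysis stages (each: dataset + config -> list of result tables)

stage_filter <- function(data, cfg) {
  out <- list(curves = list(), accepted = list())
  for (s in names(data$pools)) {
    p <- data$pools[[s]]
    uni <- union(p$rep1, p$rep2)
    if (length(uni) == 0) next
    expr <- data$transcript_tpm$values[, s]
    curve <- compute_npidr(p$rep1, p$rep2, expr, n_bins = cfg$npidr$n_bins)
    acc <- filter_reproducible(curve, uni, expr,
                               threshold = cfg$npidr$threshold)
    out$curves[[s]] <- cbind(sample_id = s, curve$bins)
    out$accepted[[s]] <- data.frame(sample_id = s, transcript_id = sort(acc),
                                    stringsAsFactors = FALSE)
  }
  res <- list(npidr_curves = do.call(rbind, out$curves),
              accepted_transcripts = do.call(rbind, out$accepted))
  .log_stage("filter", samples = length(out$accepted),
             accepted = nrow(res$accepted_transcripts))
  res
}

stage_classify <- function(data, cfg) {
  peri <- data$samples$sample_id[data$samples$tissue != "mTEC"]
  gx <- data$gene_tpm$values[, peri, drop = FALSE]
  restricted <- classify_restricted(gx,
                                    tau_threshold = cfg$classify$tau_threshold)
  ko <- data$samples$sample_id[data$samples$condition == "aireKO"]
  pos <- data$samples$sample_id[data$samples$condition == "mature"]
  counts <- .tpm_to_counts(data$gene_tpm$values[, c(ko, pos), drop = FALSE],
                           cfg$classify$count_depth)
  aire_tab <- aire_differential(counts, ko, pos,
                                dispersion = cfg$classify$dispersion)
  aire_flags <- classify_aire(aire_tab, fc_threshold = cfg$classify$aire_fc,
                              p_threshold = cfg$classify$aire_p)
  classification <- categorize_genes(restricted, aire_flags)
  tx_restricted <- classify_restricted(
    data$transcript_tpm$values[, peri, drop = FALSE],
    tau_threshold = cfg$classify$tau_threshold)
  .log_stage("classify", genes = nrow(classification),
             tra = sum(classification$is_tra),
             aire_tra = sum(classification$category == "Aire-TRA"))
  list(classification = classification, aire_differential = aire_tab,
       restricted_transcripts = tx_restricted)
}

stage_census <- function(data, cfg, classification, tx_restricted) {
  det <- detect(data$transcript_tpm, 0)
  universe <- names(data$annotation$transcripts)
  curve <- detection_fraction_curve(data$transcript_tpm, universe,
                                    cfg$census$detection_thresholds)
  iso <- isoform_fraction(det, data$annotation, classification)
  itra <- split(classification$gene_id[classification$is_tra],
                classification$itra_tissue[classification$is_tra])
  entropy <- entropy_census(data$transcript_tpm, data$annotation, itra)
  as_frac <- multi_isoform_as_fraction(det, data$gene_tpm, data$annotation,
                                       itra)
  restricted_sets <- split(
    tx_restricted$feature_id[tx_restricted$restricted],
    tx_restricted$home_tissue[tx_restricted$restricted])
  peri_rep <- peripheral_representation(restricted_sets, det,
                                        cfg$census$target_sample)
  dcounts <- data.frame(
    sample_id = colnames(det),
    genes = as.integer(colSums(rowsum((det * 1),
      vapply(data$annotation$transcripts[rownames(det)], `[[`, "",
             "gene_id")) > 0)),
    transcripts = as.integer(colSums(det)),
    group = ifelse(data$samples$tissue == "mTEC", "TEC", "peripheral"),
    stringsAsFactors = FALSE)
  anc <- tryCatch(
    gene_transcript_ancova(dcounts,
                           exclude = cfg$census$exclude_from_ancova),
    error = function(e) NULL)
  ancova_tab <- if (is.null(anc)) NULL else {
    data.frame(group = names(anc$slopes), slope = unname(anc$slopes),
               interaction_p = anc$interaction_p)
  }
  .log_stage("census", samples = ncol(det),
             multi_isoform_rows = nrow(iso))
  list(detection_curve = curve, isoform_fraction = iso,
       entropy = entropy, as_fraction_by_quartile = as_frac,
       peripheral_representation = peri_rep$representation,
       detected_counts = dcounts, ancova = ancova_tab)
}

stage_junctions <- function(data, cfg, classification) {
  tissues <- setdiff(unique(data$samples$tissue), "mTEC")
  enr <- list(); genes <- list()
  for (ts in tissues) {
    res <- differential_junction_census(
      data$junctions, cfg$junctions$tec_sample, ts, classification,
      min_reads = cfg$junctions$min_reads,
      dispersion = cfg$junctions$dispersion,
      fc_threshold = cfg$junctions$fc_threshold,
      p_threshold = cfg$junctions$p_threshold)
    row <- res$enrichment[res$enrichment$tissue == ts, , drop = FALSE]
    if (nrow(row) == 1) {
      row$comparison <- ts
      enr[[ts]] <- row
    }
    genes[[ts]] <- cbind(comparison = ts, res$gene_table)
  }
  enrichment <- do.call(rbind, enr)
  rownames(enrichment) <- NULL
  .log_stage("junctions", tissues = length(tissues),
             enriched = sum(enrichment$p < 0.05))
  list(junction_enrichment = enrichment,
       junction_genes = do.call(rbind, genes))
}

stage_events <- function(data, cfg, classification) {
  ev <- enumerate_events(data$annotation)
  diff <- differential_events(data$events$inclusion, data$events$skipping,
                              data$events$conditions,
                              delta_threshold = cfg$events$delta_threshold,
                              fdr_threshold = cfg$events$fdr_threshold,
                              min_reads = cfg$events$min_reads)
  tal <- tally_events(diff, ev, classification)
  # PSI matrices: count-based for the simulated event counts, TPM-ratio
  # across the expression panel for pattern/microexon analyses
  psi_tpm <- psi_matrix_from_tpm(ev, data$transcript_tpm,
                                 min_total = cfg$events$min_total_tpm)
  se <- ev[ev$type == "SE", , drop = FALSE]
  tec <- data$samples$sample_id[data$samples$tissue == "mTEC"]
  peri <- data$samples$sample_id[data$samples$tissue != "mTEC"]
  se_psi <- psi_tpm[se$event_id, , drop = FALSE]
  patterns <- exon_inclusion_patterns(
    se_psi, tec, peri, se$cassette_length,
    length_floor = cfg$events$exon_length_floor)
  micro <- microexon_summary(ev, psi_tpm,
                             cutoff = cfg$events$microexon_cutoff)
  .log_stage("events", events = nrow(ev),
             significant = sum(diff$significant, na.rm = TRUE))
  list(events = ev, diff_splice = diff, event_tally = tal$counts,
       psi = data.frame(event_id = rownames(psi_tpm), psi_tpm,
                        check.names = FALSE),
       exon_patterns = data.frame(
         event_id = rownames(patterns), patterns, check.names = FALSE),
       microexon_summary = micro$summary)
}

#' TPM-ratio PSI matrix for an event table
#'
#' @param events Event table from [enumerate_events()].
#' @param expr Transcript-level `expression_matrix` (TPM).
#' @param min_total Minimum denominator TPM (default 1).
#' @return Numeric matrix (events x samples).
#' @export
psi_matrix_from_tpm <- function(events, expr, min_total = 1) {
  out <- matrix(NA_real_, nrow = nrow(events), ncol = ncol(expr$values),
                dimnames = list(events$event_id, colnames(expr$values)))
  for (i in seq_len(nrow(events))) {
    inc <- strsplit(events$inclusion[i], ",")[[1]]
    exc <- strsplit(events$exclusion[i], ",")[[1]]
    inc <- intersect(inc, rownames(expr$values))
    exc <- intersect(exc, rownames(expr$values))
    for (j in seq_len(ncol(expr$values))) {
      out[i, j] <- psi_from_tpm(expr$values[inc, j], expr$values[exc, j],
                                min_total = min_total)
    }
  }
  out
}

stage_aire <- function(data, cfg) {
  ko <- data$samples$sample_id[data$samples$condition == "aireKO"]
  pos <- data$samples$sample_id[data$samples$condition == "mature"]
  counts <- .tpm_to_counts(
    data$transcript_tpm$values[, c(ko, pos), drop = FALSE],
    cfg$aire$count_depth)
  usage <- transcript_usage_test(counts, ko, pos,
                                 dispersion = cfg$aire$dispersion,
                                 fc_threshold = cfg$aire$fc_threshold,
                                 p_threshold = cfg$aire$p_threshold)
  structures <- classify_structures(data$annotation)
  m <- match(usage$transcript_id, structures$transcript_id)
  usage$gene_id <- vapply(data$annotation$transcripts[usage$transcript_id],
                          `[[`, "", "gene_id")
  aire_genes <- unique(usage$gene_id[usage$aire_regulated])
  in_scope <- usage$gene_id %in% aire_genes
  grp_a <- usage$aire_regulated & in_scope
  grp_b <- !usage$aire_regulated & in_scope
  lt <- NULL
  if (sum(grp_a) >= 2 && sum(grp_b) >= 2) {
    st <- structures[m, ]
    tests <- length_shift_tests(st$total[grp_a], st$total[grp_b],
                                parts_a = st[grp_a, ],
                                parts_b = st[grp_b, ])
    lt <- data.frame(metric = c("total_ks_D", "total_ks_p",
                                "total_wilcox_p", "total_mean_diff",
                                "total_pct_diff"),
                     value = c(tests$ks$statistic, tests$ks$p,
                               tests$wilcox_p, tests$mean_diff,
                               tests$pct_diff))
    lt <- rbind(lt, data.frame(
      metric = paste0(rep(tests$parts$part, each = 2), "_",
                      rep(c("mean_diff", "pct_diff"), 3)),
      value = as.vector(rbind(tests$parts$mean_diff,
                              tests$parts$pct_diff))))
  }
  .log_stage("aire", transcripts = nrow(usage),
             regulated = sum(usage$aire_regulated))
  list(transcript_usage = usage, structure_classes = structures,
       length_tests = lt)
}

stage_motifs <- function(data, cfg, seed) {
  set.seed(seed + 4L)
  mo <- cfg$motifs
  truth <- data$exon_truth
  mk_flanks <- function(rows) {
    exon_flanks(rows, data$genome, up_len = mo$window_intron,
                down_len = mo$window_intron, exon_len = mo$window_exon)
  }
  bg <- mk_flanks(truth[truth$class == "unregulated", , drop = FALSE])
  out <- list()
  for (cls in c("enhanced", "repressed")) {
    rows <- truth[truth$class == cls, , drop = FALSE]
    if (nrow(rows) == 0) next
    prof <- permutation_enrichment(mk_flanks(rows), bg, motif = mo$motif,
                                   n_perm = mo$n_perm, fdr = mo$fdr,
                                   smooth = mo$smooth)
    out[[cls]] <- cbind(exon_set = cls, prof)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  .log_stage("motifs", profiles = length(out),
             significant_offsets = sum(res$significant))
  list(motif_profiles = res)
}
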