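# Synthetic multi-tissue splicing dataset with planted ground truth.
#
# The generator emulates the study design this package analyzes: a panel of
# peripheral tissues (one high-depth pool each) plus a TEC-like cell type
# with immature / mature / Aire-knockout conditions (2 replicates each);
# tissue-restricted antigen (TRA) genes expressed in a single home tissue
# and promiscuously (weakly, with a restricted isoform repertoire) in the
# TEC-like sample; Aire-dependent TRA genes reduced in the knockout; and
# cassette exons whose flanking introns carry the RBFOX WGCAUGM motif at an
# elevated rate when the exon is splicing-enhanced (downstream intron) or
# repressed (upstream intron). Every dataset is fully determined by
# (config, seed).

.TISSUE_NAMES <- c("brain", "testis", "liver", "heart", "kidney", "lung",
                   "spleen", "muscle", "thyroid", "adrenal", "ovary",
                   "pancreas", "stomach", "intestine", "colon", "skin",
                   "bladder", "uterus", "eye", "bone", "fat")

#' Simulation configuration
#'
#' All tunable parameters of the synthetic dataset, with defaults chosen to
#' mirror the study conditions at desk scale (see the methods vignette).
#'
#' @param n_tissues Number of peripheral tissues (>= 3, default 8).
#' @param n_genes Number of genes (default 200).
#' @param isoforms_min,isoforms_max Isoforms per gene (default 2..5).
#' @param frac_tra Fraction of genes that are tissue-restricted (0.3).
#' @param frac_aire Fraction of TRA genes that are Aire-dependent (0.4).
#' @param tec_isoform_fraction Fraction of a TRA gene's isoforms expressed
#'   in the TEC-like mature sample (0.5).
#' @param tec_expression_factor TRA expression in the TEC-like sample
#'   relative to the home tissue (0.2).
#' @param aire_ko_fold Gene-level fold reduction target for Aire-TRA genes
#'   in the knockout (4). Realized per transcript: the gene's long classical
#'   isoform drops `aire_tx_fold`-fold, the remaining isoforms
#'   `aire_other_fold`-fold.
#' @param aire_tx_fold Knockout fold reduction of the Aire-dependent (first,
#'   long classical) isoform of an Aire-TRA gene (8).
#' @param aire_other_fold Knockout fold reduction of the other isoforms of
#'   an Aire-TRA gene (1.5; below the 2-fold call threshold).
#' @param aire_t1_share Usage share of the first isoform in Aire-TRA genes
#'   (0.6), so the gene-level knockout reduction exceeds 2-fold.
#' @param micro_psi_target,micro_psi_background Planted microexon inclusion
#'   (PSI) in the microexon home tissue (first tissue of the panel, 0.9)
#'   versus everywhere else including the TEC-like samples (0.05).
#' @param planted_delta_psi Planted |delta PSI| for regulated events (0.4).
#' @param frac_regulated_events Fraction of SE events regulated (0.2).
#' @param event_coverage Read coverage per event and sample (100).
#' @param n_replicates Replicates per TEC condition / event condition (2).
#' @param microexon_fraction Fraction of cassette exons that are microexons
#'   (<= 30 nt; default 0.2).
#' @param frac_enhanced,frac_repressed Fractions of cassette exons splicing-
#'   enhanced / repressed by the RBFOX-like factor (0.25 each).
#' @param motif_enrichment_rate Planted motifs per kb in the signal window
#'   of regulated exons (5).
#' @param motif_background_rate Planted motifs per kb in all other flanking
#'   windows (0.5).
#' @param extra_junctions_min,extra_junctions_max Range of additional
#'   home-tissue-specific splice junctions per TRA gene (default 60..140),
#'   emulating the extensive alternative splicing peripheral tissues apply
#'   to their specialty genes beyond the annotated isoform set.
#' @param extra_junction_mu Mean read support per extra junction in the home
#'   tissue (20).
#' @param noise NB dispersion for counts (0.1).
#' @param tissue_noise_sd Log-normal sd of per-sample expression noise (0.2).
#' @param dropout Logical: expression-dependent detection dropout in the
#'   replicate pools (TRUE).
#' @param dropout_midpoint log10(TPM) at 50% detection probability (1.2,
#'   placing the irreproducible stratum in the weak tail of the synthetic
#'   TPM distribution).
#' @param dropout_slope Logistic slope of detection vs log10(TPM) (4).
#' @param seed Integer seed recorded in all outputs (1).
#' @return List of class `sim_config`.
#' @export
simulation_config <- function(n_tissues = 8, n_genes = 200,
                              isoforms_min = 2, isoforms_max = 5,
                              frac_tra = 0.3, frac_aire = 0.4,
                              tec_isoform_fraction = 0.5,
                              tec_expression_factor = 0.2,
                              aire_ko_fold = 4,
                              aire_tx_fold = 8, aire_other_fold = 1.5,
                              aire_t1_share = 0.6,
                              micro_psi_target = 0.9,
                              micro_psi_background = 0.05,
                              planted_delta_psi = 0.4,
                              frac_regulated_events = 0.2,
                              event_coverage = 100,
                              n_replicates = 2,
                              microexon_fraction = 0.2,
                              frac_enhanced = 0.25, frac_repressed = 0.25,
                              motif_enrichment_rate = 5,
                              motif_background_rate = 0.5,
                              extra_junctions_min = 60,
                              extra_junctions_max = 140,
                              extra_junction_mu = 20,
                              noise = 0.1, tissue_noise_sd = 0.2,
                              dropout = TRUE, dropout_midpoint = 1.2,
                              dropout_slope = 4, seed = 1) {
  cfg <- as.list(environment())
  fr <- c("frac_tra", "frac_aire", "tec_isoform_fraction",
          "planted_delta_psi", "frac_regulated_events",
          "microexon_fraction", "frac_enhanced", "frac_repressed")
  for (f in fr) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop(f, " must lie in [0, 1]")
  }
  if (n_tissues < 3) stop("n_tissues must be >= 3")
  if (n_tissues > length(.TISSUE_NAMES)) {
    stop("at most ", length(.TISSUE_NAMES), " tissues supported")
  }
  if (isoforms_min < 1 || isoforms_max < isoforms_min) {
    stop("invalid isoform range")
  }
  structure(cfg, class = "sim_config")
}

#' Tissue names of a configuration
#' @param cfg A `sim_config`.
#' @return Character vector of peripheral tissue names.
#' @export
sim_tissues <- function(cfg) .TISSUE_NAMES[seq_len(cfg$n_tissues)]

# one random WGCAUGM instance (DNA alphabet)
.motif_instance <- function() {
  paste0(sample(c("A", "T"), 1), "GCATG", sample(c("A", "C"), 1))
}

.revcomp <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

#' Generate the synthetic annotation, genome and exon/motif truth
#'
#' Builds multi-exon genes whose isoforms realize SE, A5, A3, RI, MX, AF and
#' AL events. One internal cassette exon per gene is designated the
#' "regulated" exon and assigned an enhanced / repressed / unregulated
#' class; WGCAUGM instances are written into the downstream (enhanced) or
#' upstream (repressed) intron window at `motif_enrichment_rate` per kb, and
#' into all other flank windows at `motif_background_rate` per kb. Motif
#' planting replaces bases in place and never shifts coordinates.
#'
#' @param cfg A [simulation_config()].
#' @return List with `annotation`, `genome` (named character), and
#'   `exon_truth` (per cassette exon: gene, coordinates, class,
#'   microexon flag, planted motif counts).
#' @export
make_annotation <- function(cfg) {
  set.seed(cfg$seed)
  genes_per_chrom <- 50
  n_chrom <- ceiling(cfg$n_genes / genes_per_chrom)
  margin <- 1500
  txs <- list()
  exon_truth <- list()
  chrom_len <- integer(n_chrom)
  plant <- list()  # per chrom: data.frame(pos, seq)
  for (ci in seq_len(n_chrom)) plant[[ci]] <- list()

  for (g in seq_len(cfg$n_genes)) {
    gid <- sprintf("G%04d", g)
    chrom_i <- (g - 1) %/% genes_per_chrom + 1
    chrom <- paste0("chr", chrom_i)
    offset <- chrom_len[chrom_i] + margin
    strand <- sample(c("+", "-"), 1)
    n_ex <- 8
    micro <- stats::runif(1) < cfg$microexon_fraction
    ex_len <- sample(80:300, n_ex, replace = TRUE)
    ex_len[4] <- if (micro) sample(9:30, 1) else sample(60:120, 1)
    in_len <- sample(600:1000, n_ex - 1, replace = TRUE)
    starts <- offset + cumsum(c(0, ex_len[-n_ex] + in_len))
    ends <- starts + ex_len
    base_ex <- cbind(starts, ends)
    gene_end <- ends[n_ex]
    chrom_len[chrom_i] <- gene_end + 1300 + margin

    # CDS span: inside exon 1 to inside exon 8 (both UTRs present)
    u5 <- sample(20:60, 1); u3 <- sample(40:120, 1)
    cds <- c(starts[1] + min(u5, ex_len[1] - 10),
             ends[n_ex] - min(u3, ex_len[n_ex] - 10))

    n_iso <- sample(cfg$isoforms_min:cfg$isoforms_max, 1)
    # isoform 1: full chain with a 1 kb 3'-extended last exon -- the long
    # "classical" isoform whose production Aire favors
    t1_ex <- base_ex
    if (strand == "+") t1_ex[n_ex, 2] <- t1_ex[n_ex, 2] + 1000
    else t1_ex[1, 1] <- t1_ex[1, 1] - 1000
    iso_ex <- list(t1_ex)
    if (n_iso >= 2) iso_ex[[2]] <- base_ex[-4, ]  # skip cassette -> SE
    mods <- sample(c("SE2", "A5", "A3", "RI", "MX", "AF", "AL"))
    k <- 3
    mi <- 1
    while (k <= n_iso && mi <= length(mods)) {
      ex <- base_ex
      ex <- switch(mods[mi],
        SE2 = ex[-6, ],
        A5 = { ex[2, 2] <- ex[2, 2] + 60; ex },
        A3 = { ex[7, 1] <- ex[7, 1] - 60; ex },
        RI = { ex[5, 2] <- ex[6, 2]; ex[-6, ] },
        MX = { ex[6, ] <- c(ex[6, 2] + 100, ex[6, 2] + 190); ex },
        AF = rbind(c(starts[1] - 500, starts[1] - 380), ex[-1, ]),
        AL = rbind(ex[-n_ex, ], c(gene_end + 1100, gene_end + 1220)))
      iso_ex[[k]] <- ex
      k <- k + 1; mi <- mi + 1
    }
    for (i in seq_along(iso_ex)) {
      ex <- iso_ex[[i]]
      cds_i <- c(max(cds[1], ex[1, 1] + 1), min(cds[2], ex[nrow(ex), 2] - 1))
      if (cds_i[2] <= cds_i[1]) cds_i <- NULL
      if (i >= 2 && !is.null(cds_i)) {
        # non-primary isoforms: mixed transcript structures (classical /
        # missing a UTR / no annotated CDS)
        draw <- stats::runif(1)
        if (draw < 0.2) {
          cds_i <- NULL
        } else if (draw < 0.6) {
          # drop the 3' UTR (CDS runs to the transcript end)
          if (strand == "+") cds_i[2] <- ex[nrow(ex), 2]
          else cds_i[1] <- ex[1, 1]
        }
      }
      txs[[length(txs) + 1]] <- transcript_model(
        sprintf("%s.T%d", gid, i), gid, chrom, strand, ex, cds = cds_i)
    }

    # cassette exon truth + motif planting in its flanking windows
    cls <- sample(c("enhanced", "repressed", "unregulated"), 1,
                  prob = c(cfg$frac_enhanced, cfg$frac_repressed,
                           1 - cfg$frac_enhanced - cfg$frac_repressed))
    cass <- base_ex[4, ]
    win <- 250
    # sense-strand up/downstream windows in genomic coordinates
    if (strand == "+") {
      up_win <- c(cass[1] - win, cass[1]); dn_win <- c(cass[2], cass[2] + win)
    } else {
      up_win <- c(cass[2], cass[2] + win); dn_win <- c(cass[1] - win, cass[1])
    }
    rate_of <- function(which_win) {
      sig <- (cls == "enhanced" && which_win == "dn") ||
        (cls == "repressed" && which_win == "up")
      if (sig) cfg$motif_enrichment_rate else cfg$motif_background_rate
    }
    n_up <- stats::rpois(1, rate_of("up") * win / 1000)
    n_dn <- stats::rpois(1, rate_of("dn") * win / 1000)
    for (spec_ in list(list(w = up_win, n = n_up),
                       list(w = dn_win, n = n_dn))) {
      if (spec_$n == 0) next
      pos <- sort(sample(seq(spec_$w[1], spec_$w[2] - 7), spec_$n))
      # drop overlapping placements
      keep <- c(TRUE, diff(pos) >= 7)
      for (p in pos[keep]) {
        inst <- .motif_instance()
        if (strand == "-") inst <- .revcomp(inst)
        plant[[chrom_i]][[length(plant[[chrom_i]]) + 1]] <-
          list(pos = p, seq = inst)
      }
    }
    exon_truth[[gid]] <- data.frame(
      gene_id = gid, chrom = chrom, strand = strand,
      start = cass[1], end = cass[2], length = cass[2] - cass[1],
      class = cls, microexon = micro,
      n_motifs_up = n_up, n_motifs_dn = n_dn, stringsAsFactors = FALSE)
  }

  genome <- character(n_chrom)
  names(genome) <- paste0("chr", seq_len(n_chrom))
  for (ci in seq_len(n_chrom)) {
    L <- chrom_len[ci] + margin
    s <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    for (pl in plant[[ci]]) {
      s[(pl$pos + 1):(pl$pos + 7)] <- strsplit(pl$seq, "")[[1]]
    }
    genome[ci] <- paste(s, collapse = "")
  }
  truth <- do.call(rbind, exon_truth)
  rownames(truth) <- NULL
  list(annotation = annotation(txs), genome = genome, exon_truth = truth)
}

#' Generate expression matrices, junction counts and the gene truth table
#'
#' TRA genes are expressed only in their home tissue among the peripheral
#' panel (tau = 1 by construction before noise), promiscuously at
#' `tec_expression_factor` of the home level in the TEC-like mature sample
#' where only `tec_isoform_fraction` of their isoforms are produced.
#' Aire-dependent TRA genes drop `aire_ko_fold`-fold in the knockout.
#' Junction counts are derived from transcript abundances through each
#' transcript's junction set with NB noise.
#'
#' @param cfg A [simulation_config()].
#' @param ann The [annotation()] from [make_annotation()].
#' @param exon_truth Optional cassette-exon truth table from
#'   [make_annotation()]; when given, microexon genes receive the planted
#'   tissue-specific inclusion pattern (high PSI in the first panel tissue,
#'   low everywhere else).
#' @return List with `transcript_tpm` and `gene_tpm` (`expression_matrix`),
#'   `junctions` (`junction_counts`), `gene_truth` data frame, and
#'   `samples` metadata.
#' @export
make_expression <- function(cfg, ann, exon_truth = NULL) {
  set.seed(cfg$seed + 1L)
  tissues <- sim_tissues(cfg)
  tec_conditions <- c("mature", "immature", "aireKO")
  tec_ids <- unlist(lapply(tec_conditions, function(cd) {
    paste0("mTEC_", cd, "_r", seq_len(cfg$n_replicates))
  }))
  samples <- rbind(
    data.frame(sample_id = tissues, tissue = tissues, condition = "pool",
               replicate = 1L, stringsAsFactors = FALSE),
    data.frame(sample_id = tec_ids, tissue = "mTEC",
               condition = rep(tec_conditions, each = cfg$n_replicates),
               replicate = rep(seq_len(cfg$n_replicates),
                               length(tec_conditions)),
               stringsAsFactors = FALSE))

  gene_ids <- names(ann$genes)
  n_genes <- length(gene_ids)
  n_tra <- round(cfg$frac_tra * n_genes)
  tra_genes <- sort(sample(gene_ids, n_tra))
  aire_genes <- sort(sample(tra_genes, round(cfg$frac_aire * n_tra)))
  home <- stats::setNames(rep(tissues, length.out = n_tra), tra_genes)

  base_expr <- stats::setNames(stats::rlnorm(n_genes, log(50), 0.8),
                               gene_ids)
  tids <- names(ann$transcripts)
  tx_gene <- vapply(ann$transcripts, `[[`, "", "gene_id")
  t1_ids <- vapply(ann$genes, `[`, "", 1)  # first (long classical) isoform
  aire_t1 <- t1_ids[aire_genes]
  aire_other <- setdiff(unlist(ann$genes[aire_genes]), aire_t1)

  # microexon genes: non-TRA genes whose cassette exon is <= 30 nt get a
  # planted tissue-specific inclusion pattern
  micro_genes <- character(0)
  if (!is.null(exon_truth)) {
    micro_genes <- setdiff(exon_truth$gene_id[exon_truth$microexon],
                           tra_genes)
  }
  micro_tissue <- tissues[1]

  # fixed per-gene isoform usage proportions
  iso_prop <- stats::setNames(numeric(length(tids)), tids)
  tec_on <- stats::setNames(rep(TRUE, length(tids)), tids)
  for (g in gene_ids) {
    gt <- ann$genes[[g]]
    w <- stats::rgamma(length(gt), 2)
    w <- w / sum(w)
    if (g %in% aire_genes && length(gt) >= 2) {
      # concentrate usage on the Aire-dependent long isoform
      w <- c(cfg$aire_t1_share,
             (1 - cfg$aire_t1_share) * w[-1] / sum(w[-1]))
    }
    iso_prop[gt] <- w
    if (g %in% tra_genes && length(gt) >= 2) {
      k <- max(1, round(cfg$tec_isoform_fraction * length(gt)))
      on <- if (g %in% aire_genes) {
        c(gt[1], sample(gt[-1], k - 1))  # Aire drives the long isoform
      } else {
        sample(gt, k)
      }
      tec_on[setdiff(gt, on)] <- FALSE
    }
  }

  vals <- matrix(0, nrow = length(tids), ncol = nrow(samples),
                 dimnames = list(tids, samples$sample_id))
  for (si in seq_len(nrow(samples))) {
    sm <- samples[si, ]
    gx <- numeric(n_genes); names(gx) <- gene_ids
    if (sm$condition == "pool") {
      gx[] <- base_expr
      off <- tra_genes[home[tra_genes] != sm$tissue]
      gx[off] <- 0
    } else {
      gx[] <- base_expr
      tec_fac <- cfg$tec_expression_factor *
        switch(sm$condition, mature = 1, immature = 0.3, aireKO = 1)
      gx[tra_genes] <- base_expr[tra_genes] * tec_fac
    }
    prop <- iso_prop
    # planted microexon inclusion: high in its home tissue, low elsewhere
    for (g in micro_genes) {
      gt <- ann$genes[[g]]
      if (length(gt) < 2) next
      psi <- if (sm$sample_id == micro_tissue) cfg$micro_psi_target
             else cfg$micro_psi_background
      inc <- gt[-2]  # isoform 2 is the cassette-skipping form
      prop[inc] <- psi * iso_prop[inc] / sum(iso_prop[inc])
      prop[gt[2]] <- 1 - psi
    }
    tx <- stats::setNames(gx[tx_gene] * prop, tids)
    if (sm$condition %in% c("aireKO", "immature")) {
      tx[aire_t1] <- tx[aire_t1] / cfg$aire_tx_fold
      tx[aire_other] <- tx[aire_other] / cfg$aire_other_fold
    }
    if (sm$tissue == "mTEC") tx <- tx * tec_on
    noise <- stats::rlnorm(length(tx), 0, cfg$tissue_noise_sd)
    tx <- tx * noise
    vals[, si] <- tx / sum(tx) * 1e6
  }
  tx_expr <- expression_matrix(vals, samples, feature_level = "transcript",
                               unit = "TPM")
  gvals <- rowsum(vals, tx_gene)
  gene_expr <- expression_matrix(gvals, samples, feature_level = "gene",
                                 unit = "TPM")

  # junction counts via each transcript's intron set
  jmap <- list()
  for (tid in tids) {
    t <- ann$transcripts[[tid]]
    intr <- transcript_introns(t)
    if (nrow(intr) == 0) next
    keys <- paste(t$gene_id, t$chrom, intr[, 1], intr[, 2], t$strand,
                  sep = "|")
    for (ki in seq_along(keys)) {
      jmap[[keys[ki]]] <- c(jmap[[keys[ki]]], tid)
    }
  }
  jkeys <- sort(names(jmap))
  meta <- do.call(rbind, strsplit(jkeys, "|", fixed = TRUE))
  jdf <- data.frame(gene_id = meta[, 1], chrom = meta[, 2],
                    donor = as.numeric(meta[, 3]),
                    acceptor = as.numeric(meta[, 4]), strand = meta[, 5],
                    stringsAsFactors = FALSE)
  depth <- 2  # reads per TPM unit for junction support
  jcounts <- matrix(0L, nrow = length(jkeys), ncol = nrow(samples),
                    dimnames = list(NULL, samples$sample_id))
  for (si in seq_len(nrow(samples))) {
    tpm <- vals[, si]
    mu <- vapply(jkeys, function(k) sum(tpm[jmap[[k]]]) * depth, 0)
    jcounts[, si] <- if (cfg$noise > 0) {
      stats::rnbinom(length(mu), mu = mu, size = 1 / cfg$noise)
    } else {
      as.integer(round(mu))
    }
  }
  # home-tissue junction diversity: peripheral tissues splice their
  # specialty (iTRA) genes far beyond the annotated isoform set, so each TRA
  # gene carries additional junctions supported only in its home tissue
  extra_df <- list(); extra_counts <- list()
  for (g in tra_genes) {
    t1 <- ann$transcripts[[ann$genes[[g]][1]]]
    span <- c(t1$exons[1, 1], t1$exons[nrow(t1$exons), 2])
    k <- sample(cfg$extra_junctions_min:cfg$extra_junctions_max, 1)
    pos <- matrix(sort(sample(seq(span[1], span[2]), 2 * k)), ncol = 2,
                  byrow = TRUE)
    pos <- pos[pos[, 2] > pos[, 1], , drop = FALSE]
    row_counts <- matrix(0L, nrow = nrow(pos), ncol = nrow(samples),
                         dimnames = list(NULL, samples$sample_id))
    mu <- rep(cfg$extra_junction_mu, nrow(pos))
    row_counts[, home[g]] <- if (cfg$noise > 0) {
      stats::rnbinom(nrow(pos), mu = mu, size = 1 / cfg$noise)
    } else {
      as.integer(round(mu))
    }
    extra_df[[g]] <- data.frame(gene_id = g, chrom = t1$chrom,
                                donor = pos[, 1], acceptor = pos[, 2],
                                strand = t1$strand, stringsAsFactors = FALSE)
    extra_counts[[g]] <- row_counts
  }
  if (length(extra_df) > 0) {
    jdf <- rbind(jdf, do.call(rbind, extra_df))
    jcounts <- rbind(jcounts, do.call(rbind, extra_counts))
  }
  gene_truth <- data.frame(
    gene_id = gene_ids,
    category = ifelse(gene_ids %in% aire_genes, "Aire-TRA",
                      ifelse(gene_ids %in% tra_genes, "non-Aire-TRA",
                             "non-TRA")),
    home_tissue = ifelse(gene_ids %in% tra_genes, home[gene_ids],
                         NA_character_),
    t1_transcript = t1_ids[gene_ids],
    base_expr = base_expr, stringsAsFactors = FALSE)
  list(transcript_tpm = tx_expr, gene_tpm = gene_expr,
       junctions = junction_counts(jdf, jcounts),
       gene_truth = gene_truth, samples = samples)
}

#' Generate per-event inclusion/skipping counts for two conditions
#'
#' SE events are enumerated from the annotation; a configured fraction are
#' regulated with |delta PSI| = `planted_delta_psi` (random direction),
#' the rest share PSI across conditions. Counts are
#' binomial(`event_coverage`, PSI) per replicate.
#'
#' @param cfg A [simulation_config()].
#' @param ann The [annotation()].
#' @return List with `inclusion` and `skipping` integer matrices
#'   (events x samples), `conditions`, and `event_truth` (per event:
#'   regulated flag, true PSI per condition, true delta).
#' @export
make_event_counts <- function(cfg, ann) {
  set.seed(cfg$seed + 2L)
  ev <- enumerate_events(ann)
  ev <- ev[ev$type == "SE", , drop = FALSE]
  n <- nrow(ev)
  if (n == 0) stop("annotation yields no SE events")
  psi1 <- stats::runif(n, 0.2, 0.8)
  regulated <- rep(FALSE, n)
  regulated[sample.int(n, round(cfg$frac_regulated_events * n))] <- TRUE
  dir <- sample(c(-1, 1), n, replace = TRUE)
  psi2 <- ifelse(regulated,
                 pmin(0.98, pmax(0.02, psi1 + dir * cfg$planted_delta_psi)),
                 psi1)
  nr <- cfg$n_replicates
  conditions <- rep(c("c1", "c2"), each = nr)
  sample_ids <- paste0(conditions, "_r", rep(seq_len(nr), 2))
  inc <- matrix(0L, n, 2 * nr, dimnames = list(ev$event_id, sample_ids))
  skp <- inc
  for (j in seq_len(2 * nr)) {
    psi <- if (conditions[j] == "c1") psi1 else psi2
    inc[, j] <- stats::rbinom(n, cfg$event_coverage, psi)
    skp[, j] <- cfg$event_coverage - inc[, j]
  }
  list(inclusion = inc, skipping = skp, conditions = conditions,
       event_truth = data.frame(event_id = ev$event_id,
                                regulated = regulated, psi_c1 = psi1,
                                psi_c2 = psi2, true_delta = psi2 - psi1,
                                stringsAsFactors = FALSE))
}

#' Generate two detection replicates per sample with expression-dependent
#' dropout
#'
#' Detection probability for an expressed transcript is logistic in
#' log10(TPM): `plogis(slope * (log10(TPM) - midpoint))`; unexpressed
#' transcripts are never detected. With `dropout = FALSE` both replicates
#' contain every expressed transcript.
#'
#' @param cfg A [simulation_config()].
#' @param expr Transcript-level `expression_matrix` in TPM.
#' @return Named list (per sample) of lists with `rep1`, `rep2` (character
#'   id vectors).
#' @export
make_replicate_pools <- function(cfg, expr) {
  set.seed(cfg$seed + 3L)
  out <- list()
  for (s in colnames(expr$values)) {
    tpm <- expr$values[, s]
    expressed <- names(tpm)[tpm > 0]
    if (cfg$dropout) {
      p <- stats::plogis(cfg$dropout_slope *
                           (log10(tpm[expressed]) - cfg$dropout_midpoint))
      r1 <- expressed[stats::runif(length(expressed)) < p]
      r2 <- expressed[stats::runif(length(expressed)) < p]
    } else {
      r1 <- expressed; r2 <- expressed
    }
    out[[s]] <- list(rep1 = r1, rep2 = r2)
  }
  out
}

#' Generate the full synthetic dataset
#'
#' Convenience wrapper running [make_annotation()], [make_expression()],
#' [make_event_counts()] and [make_replicate_pools()] under one seed.
#'
#' @param cfg A [simulation_config()].
#' @return List with all generator outputs plus `config`.
#' @export
simulate_dataset <- function(cfg = simulation_config()) {
  anng <- make_annotation(cfg)
  ex <- make_expression(cfg, anng$annotation, anng$exon_truth)
  evc <- make_event_counts(cfg, anng$annotation)
  pools <- make_replicate_pools(cfg, ex$transcript_tpm)
  c(anng, ex, list(events = evc, pools = pools, config = cfg))
}
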