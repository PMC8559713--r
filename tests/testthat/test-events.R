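# Event enumeration, PSI computation, differential splicing, exon patterns
# and microexons.

test_that("a cleanly skipped internal exon yields exactly one SE event", {
  ann <- annotation(list(
    transcript_model("t1", "g", "chr1", "+",
                     rbind(c(0, 100), c(200, 300), c(400, 500))),
    transcript_model("t2", "g", "chr1", "+",
                     rbind(c(0, 100), c(400, 500)))))
  ev <- enumerate_events(ann)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$type, "SE")
  expect_equal(ev$inclusion, "t1")
  expect_equal(ev$exclusion, "t2")
  expect_equal(ev$cassette_length, 100)
})

test_that("single-transcript genes yield no events", {
  ann <- annotation(list(
    transcript_model("t1", "g", "chr1", "+",
                     rbind(c(0, 100), c(200, 300)))))
  expect_equal(nrow(enumerate_events(ann)), 0)
})

test_that("alternative donors on the plus strand are A5 events", {
  ann <- annotation(list(
    transcript_model("t1", "g", "chr1", "+",
                     rbind(c(0, 200), c(500, 600))),
    transcript_model("t2", "g", "chr1", "+",
                     rbind(c(0, 250), c(500, 600)))))
  ev <- enumerate_events(ann)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$type, "A5")
  # inclusion form uses the shorter intron (more exonic sequence)
  expect_equal(ev$inclusion, "t2")
  # the same geometry on the minus strand is an A3 event
  ann_m <- annotation(list(
    transcript_model("t1", "g", "chr1", "-",
                     rbind(c(0, 200), c(500, 600))),
    transcript_model("t2", "g", "chr1", "-",
                     rbind(c(0, 250), c(500, 600)))))
  expect_equal(enumerate_events(ann_m)$type, "A3")
})

test_that("RI, MX, AF and AL geometries are recognized", {
  ri <- annotation(list(
    transcript_model("t1", "g", "chr1", "+",
                     rbind(c(0, 100), c(200, 300))),
    transcript_model("t2", "g", "chr1", "+", rbind(c(0, 300)))))
  ev <- enumerate_events(ri)
  expect_equal(ev$type, "RI")
  expect_equal(ev$inclusion, "t2")  # retained form is the inclusion form

  mx <- annotation(list(
    transcript_model("t1", "g", "chr1", "+",
                     rbind(c(0, 100), c(200, 250), c(500, 600))),
    transcript_model("t2", "g", "chr1", "+",
                     rbind(c(0, 100), c(300, 350), c(500, 600)))))
  evmx <- enumerate_events(mx)
  expect_true("MX" %in% evmx$type)

  af <- annotation(list(
    transcript_model("t1", "g", "chr1", "+",
                     rbind(c(0, 100), c(500, 600), c(800, 900))),
    transcript_model("t2", "g", "chr1", "+",
                     rbind(c(200, 300), c(500, 600), c(800, 900)))))
  expect_equal(enumerate_events(af)$type, "AF")
  # alternative first exons on the minus strand are alternative LAST exons
  af_m <- annotation(list(
    transcript_model("t1", "g", "chr1", "-",
                     rbind(c(0, 100), c(500, 600), c(800, 900))),
    transcript_model("t2", "g", "chr1", "-",
                     rbind(c(200, 300), c(500, 600), c(800, 900)))))
  expect_equal(enumerate_events(af_m)$type, "AL")
})

test_that("SE enumeration matches the brute-force oracle on random genes", {
  cfg <- simulation_config(n_tissues = 4, n_genes = 60, seed = 61)
  ann <- make_annotation(cfg)$annotation
  ev <- enumerate_events(ann)
  se <- ev[ev$type == "SE", ]
  got <- sort(paste("SE", se$gene_id,
                    gsub(";", " ", se$coords)))
  expect_equal(got, oracle_se_events(ann))
})

test_that("PSI formulas match their closed forms", {
  expect_equal(psi_from_tpm(6, 2), 0.75)
  expect_true(is.na(psi_from_tpm(0.3, 0.2, min_total = 1)))
  expect_equal(psi_from_tpm(0, 5), 0)
  expect_equal(psi_from_counts(30, 10, min_reads = 10), 0.75)
  expect_equal(psi_from_counts(10, 10, len_inclusion = 2, len_skipping = 1),
               1 / 3)
  expect_equal(psi_from_counts(0, 50), 0)
  expect_true(is.na(psi_from_counts(3, 2, min_reads = 10)))
  expect_error(psi_from_counts(-1, 5), "non-negative")
  expect_error(psi_from_counts(5, 5, len_inclusion = 0), "> 0")
})

test_that("differential splicing recovers planted delta PSI", {
  cfg <- simulation_config(n_tissues = 4, n_genes = 400, seed = 62,
                           planted_delta_psi = 0.4)
  anng <- make_annotation(cfg)
  evc <- make_event_counts(cfg, anng$annotation)
  res <- differential_events(evc$inclusion, evc$skipping, evc$conditions)
  truth <- evc$event_truth
  m <- match(res$event_id, truth$event_id)
  # sensitivity >= 0.8 on regulated events at FDR 0.05, |dPSI| > 0.2
  reg <- truth$regulated[m]
  expect_gte(mean(res$significant[reg], na.rm = TRUE), 0.8)
  # estimated delta tracks the planted delta with small bias
  bias <- mean(res$delta_psi[reg] - truth$true_delta[m][reg], na.rm = TRUE)
  expect_lt(abs(bias), 0.03)
  # identical conditions -> no calls
  null_res <- differential_events(evc$inclusion[, c(1, 2, 1, 2)],
                                  evc$skipping[, c(1, 2, 1, 2)],
                                  evc$conditions)
  expect_true(all(!null_res$significant, na.rm = TRUE))
  expect_error(differential_events(evc$inclusion, evc$skipping,
                                   rep("c1", 4)), "two conditions")
})

test_that("differential splicing controls the false discovery rate", {
  cfg <- simulation_config(n_tissues = 4, n_genes = 400, seed = 63,
                           frac_regulated_events = 0)
  anng <- make_annotation(cfg)
  evc <- make_event_counts(cfg, anng$annotation)
  res <- differential_events(evc$inclusion, evc$skipping, evc$conditions,
                             delta_threshold = 0)
  expect_lte(mean(res$padj < 0.05, na.rm = TRUE), 0.07)
})

test_that("exon inclusion pattern gates follow the PSI thresholds", {
  psi <- rbind(
    kept = c(0.05, 0.06, 0.9, 0.1),
    max_gate = c(0.05, 0.25, 0.9, 0.1),
    never_in = c(0.05, 0.06, 0.3, 0.1),
    short = c(0.05, 0.06, 0.9, 0.1))
  colnames(psi) <- c("tec1", "tec2", "brain", "liver")
  out <- exon_inclusion_patterns(psi, c("tec1", "tec2"),
                                 c("brain", "liver"),
                                 exon_lengths = c(80, 80, 80, 40))
  expect_equal(rownames(out), "kept")
  expect_equal(colnames(out), c("brain", "liver"))
})

test_that("microexons use the inclusive 30 nt boundary", {
  events <- data.frame(
    event_id = c("e30", "e31"), gene_id = "g", chrom = "c", strand = "+",
    type = "SE", coords = "x", inclusion = "a", exclusion = "b",
    cassette_length = c(30, 31))
  psi <- matrix(c(0.5, 0.9), 2, 1, dimnames = list(c("e30", "e31"), "s"))
  ms <- microexon_summary(events, psi)
  expect_equal(rownames(ms$psi), "e30")
  expect_equal(ms$summary$median, 0.5)
})

test_that("planted microexon inclusion is tissue-specific", {
  cfg <- simulation_config(n_tissues = 5, n_genes = 300,
                           microexon_fraction = 0.3, seed = 64)
  sim <- simulate_dataset(cfg)
  ev <- enumerate_events(sim$annotation)
  psi <- psi_matrix_from_tpm(ev, sim$transcript_tpm)
  micro_genes <- sim$exon_truth$gene_id[sim$exon_truth$microexon]
  non_tra <- sim$gene_truth$gene_id[sim$gene_truth$category == "non-TRA"]
  keep <- ev$type == "SE" & ev$cassette_length <= 30 &
    ev$gene_id %in% intersect(micro_genes, non_tra)
  ms <- microexon_summary(ev[keep, ], psi[keep, , drop = FALSE])
  med <- stats::setNames(ms$summary$median, ms$summary$sample_id)
  expect_gte(med[["brain"]], 0.8)
  others <- setdiff(names(med), "brain")
  expect_true(all(med[others] <= 0.1, na.rm = TRUE))
})
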