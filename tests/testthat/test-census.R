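# Detection census: fractions, isoform fractions, entropy, ANCOVA,
# quartile splicing fractions and peripheral representation.

.census_expr <- function(values, tissues = colnames(values)) {
  samples <- data.frame(sample_id = colnames(values), tissue = tissues,
                        condition = "pool", replicate = 1L)
  expression_matrix(values, samples)
}

test_that("detection is strict and fraction curves are monotone", {
  m <- matrix(c(0, 0.01, 1, 5), 2, 2,
              dimnames = list(c("t1", "t2"), c("s1", "s2")))
  ex <- .census_expr(m)
  det <- detect(ex, 0)
  expect_false(det["t1", "s1"])  # value 0 at threshold 0 is not detected
  expect_true(det["t2", "s1"])
  expect_error(detect(ex, -1), ">= 0")
  curve <- detection_fraction_curve(ex, c("t1", "t2", "t3"),
                                    thresholds = c(0, 0.1, 1))
  s2 <- curve[curve$sample_id == "s2", ]
  expect_equal(s2$fraction, c(2 / 3, 2 / 3, 1 / 3))
  for (s in unique(curve$sample_id)) {
    f <- curve$fraction[curve$sample_id == s]
    expect_true(all(diff(f) <= 0))
  }
  expect_error(detection_fraction_curve(ex, character(0)), "empty")
})

test_that("detection fraction arithmetic is exact", {
  set.seed(30)
  vals <- matrix(stats::rexp(1000), ncol = 1,
                 dimnames = list(paste0("t", 1:1000), "s1"))
  vals[sample(1000, 399), 1] <- 0
  ex <- .census_expr(vals)
  curve <- detection_fraction_curve(ex, rownames(vals), thresholds = 0)
  expect_equal(curve$fraction, 0.601)
})

test_that("isoform fractions count detected isoforms per multi-isoform gene", {
  ann <- annotation(list(
    transcript_model("g1.t1", "g1", "c", "+", rbind(c(0, 100))),
    transcript_model("g1.t2", "g1", "c", "+", rbind(c(0, 150))),
    transcript_model("g1.t3", "g1", "c", "+", rbind(c(0, 200))),
    transcript_model("g1.t4", "g1", "c", "+", rbind(c(0, 250))),
    transcript_model("g2.t1", "g2", "c", "+", rbind(c(0, 100)))))
  m <- matrix(c(5, 1, 0, 0, 9), ncol = 1,
              dimnames = list(paste0(c(rep("g1.t", 4), "g2.t"),
                                     c(1:4, 1)), "s1"))
  det <- detect(.census_expr(m), 0)
  suppressMessages(fr <- isoform_fraction(det, ann))
  expect_equal(nrow(fr), 1)  # single-isoform gene excluded
  expect_equal(fr$fraction, 0.5)
})

test_that("splice entropy matches closed forms", {
  expect_equal(splice_entropy(c(7, 0, 0)), 0)
  expect_equal(splice_entropy(rep(3, 4)), 2)
  expect_equal(splice_entropy(c(0.5, 0.25, 0.25)), 1.5)
  expect_true(is.na(splice_entropy(c(0, 0))))
  # bounded by log2(k), zero iff a single isoform carries all mass
  set.seed(31)
  for (i in 1:20) {
    k <- sample(2:8, 1)
    x <- stats::rexp(k)
    h <- splice_entropy(x)
    expect_lte(h, log2(k) + 1e-12)
    expect_gte(h, 0)
  }
})

test_that("ANCOVA recovers planted slopes and nulls", {
  set.seed(32)
  # null: both groups share slope 3 -> estimates near 3
  genes <- rep(seq(2000, 6000, length.out = 10), 2)
  tx <- 3 * genes + stats::rnorm(20, 0, 50)
  d <- data.frame(sample_id = paste0("s", 1:20), genes = genes,
                  transcripts = tx,
                  group = rep(c("peripheral", "TEC"), each = 10))
  fit <- gene_transcript_ancova(d)
  expect_equal(unname(fit$slopes), c(3, 3), tolerance = 0.1)
  # planted slope deficit 3.0 vs 2.0 at low noise -> interaction p < 0.01
  tx2 <- ifelse(d$group == "TEC", 2 * genes, 3 * genes) +
    stats::rnorm(20, 0, 50)
  d2 <- d; d2$transcripts <- tx2
  fit2 <- gene_transcript_ancova(d2)
  expect_lt(fit2$interaction_p, 0.01)
  expect_equal(unname(fit2$slopes["peripheral"]), 3, tolerance = 0.1)
  expect_equal(unname(fit2$slopes["TEC"]), 2, tolerance = 0.1)
  # exclusions are honoured and tiny groups rejected
  expect_error(gene_transcript_ancova(d[c(1, 11), ]), ">= 3 samples")
})

test_that("ANCOVA null interaction p-values are roughly uniform", {
  set.seed(33)
  ps <- replicate(100, {
    genes <- stats::runif(12, 2000, 6000)
    d <- data.frame(sample_id = paste0("s", 1:12), genes = genes,
                    transcripts = 3 * genes + stats::rnorm(12, 0, 200),
                    group = rep(c("a", "b"), each = 6))
    gene_transcript_ancova(d)$interaction_p
  })
  expect_gt(mean(ps), 0.3)
  expect_lte(mean(ps < 0.05), 0.12)
})

test_that("quartile splicing fraction and peripheral representation", {
  ann <- annotation(unlist(lapply(1:8, function(i) {
    lapply(1:2, function(j) {
      transcript_model(sprintf("g%d.t%d", i, j), sprintf("g%d", i), "c",
                       "+", rbind(c(0, 100 * j)))
    })
  }), recursive = FALSE))
  tids <- names(ann$transcripts)
  vals <- matrix(stats::rexp(length(tids)) + 1, ncol = 1,
                 dimnames = list(tids, "s1"))
  # genes g5..g8: second isoform off
  vals[paste0("g", 5:8, ".t2"), 1] <- 0
  ex <- .census_expr(vals)
  det <- detect(ex, 0)
  gvals <- rowsum(vals, sub("\\..*", "", rownames(vals)))
  gex <- .census_expr(gvals)
  fr <- multi_isoform_as_fraction(det, gex, ann,
                                  list(all = paste0("g", 1:8)))
  # half of the genes have > 1 isoform detected overall
  expect_equal(sum(fr$n_genes * fr$fraction_as), 4)
  # peripheral representation: 6 of 8 restricted transcripts detected
  sets <- list(brain = c(paste0("g", 1:6, ".t1"), "g5.t2", "g6.t2"))
  det2 <- det
  pr <- peripheral_representation(sets, det2, "s1")
  expect_equal(pr$representation$fraction, 6 / 8)
  pr_empty <- peripheral_representation(list(x = character(0)), det2, "s1")
  expect_true(is.na(pr_empty$representation$fraction))
})

test_that("uniquely detected novel transcripts are counted per panel sample", {
  m <- matrix(c(1, 0, 0,
                1, 1, 0,
                0, 0, 2), nrow = 3, byrow = TRUE,
              dimnames = list(c("n1", "n2", "n3"), c("s1", "s2", "s3")))
  ex <- .census_expr(m)
  det <- detect(ex, 0)
  pr <- peripheral_representation(list(t = "n1"), det, "s1",
                                  panel = c("s1", "s2", "s3"),
                                  novel_ids = c("n1", "n2", "n3"))
  expect_equal(pr$unique_novel$n_unique_novel, c(1, 0, 1))
})

test_that("TEC isoform restriction is recovered by the census", {
  cfg <- simulation_config(n_tissues = 5, n_genes = 500, seed = 41)
  sim <- simulate_dataset(cfg)
  det <- detect(sim$transcript_tpm, 0)
  peri <- sim$samples$sample_id[sim$samples$tissue != "mTEC"]
  cl <- classify_restricted(sim$gene_tpm$values[, peri], 0.9)
  cats <- categorize_genes(cl)
  suppressMessages(fr <- isoform_fraction(det, sim$annotation, cats))
  tra <- fr[fr$category != "non-TRA", ]
  tec <- tra[tra$sample_id == "mTEC_mature_r1", ]
  # fraction detected in the TEC-like sample recovers the planted 0.5
  tec_expr <- tec[tec$n_detected > 0, ]
  expect_lt(abs(median(tec_expr$fraction) - cfg$tec_isoform_fraction), 0.05)
  # and sits below the home-tissue fraction
  truth <- sim$gene_truth
  home <- truth$home_tissue[match(tra$gene_id, truth$gene_id)]
  at_home <- tra[!is.na(home) & tra$sample_id == home, ]
  expect_gt(median(at_home$fraction), median(tec_expr$fraction))
})
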