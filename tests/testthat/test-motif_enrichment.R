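# IUPAC scanning, positional coverage and permutation enrichment.

test_that("IUPAC scanning finds all overlapping matches with U/T equivalence", {
  expect_equal(scan_iupac("TGCATGC", "WGCAUGM"), 0L)
  expect_equal(length(scan_iupac("GGCATGC", "WGCAUGM")), 0L)
  expect_equal(scan_iupac("AGCATGAAGCATGC", "WGCAUGM"), c(0L, 7L))
  expect_equal(scan_iupac("AGCAUGA", "WGCAUGM"), 0L)  # RNA input
  expect_equal(scan_iupac("AAAA", "AAA"), c(0L, 1L))  # overlapping
  expect_error(scan_iupac("ACGT", "WXC"), "invalid IUPAC")
})

test_that("positional coverage is 0 without motifs and 1 around planted ones", {
  genome <- c(chr1 = strrep("C", 4000))
  exons <- data.frame(chrom = "chr1", start = c(1000, 2000, 3000),
                      end = c(1100, 2100, 3100), strand = "+")
  flanks <- exon_flanks(exons, genome)
  cov0 <- positional_coverage(flanks, "WGCAUGM")
  expect_true(all(cov0$coverage == 0))
  expect_error(positional_coverage(list(), "WGCAUGM"), "empty")

  # plant a motif 50 nt into every downstream intron
  g <- strsplit(genome[["chr1"]], "")[[1]]
  for (e in exons$end) g[(e + 50 + 1):(e + 50 + 7)] <-
    strsplit("TGCATGC", "")[[1]]
  flanks2 <- exon_flanks(exons, c(chr1 = paste(g, collapse = "")))
  cov <- positional_coverage(flanks2, "WGCAUGM")
  dn <- cov[cov$segment == "downstream", ]
  expect_equal(dn$coverage[dn$offset == 50], 1)
  # the smoothing window spreads coverage ~15 nt either side
  expect_equal(dn$coverage[dn$offset == 40], 1)
  expect_equal(dn$coverage[dn$offset == 100], 0)
  up <- cov[cov$segment == "upstream", ]
  expect_true(all(up$coverage == 0))
})

test_that("coverage is invariant to exon input order and strand-aware", {
  set.seed(80)
  genome <- c(chr1 = paste(sample(c("A", "C", "G", "T"), 6000,
                                  replace = TRUE), collapse = ""))
  exons <- data.frame(chrom = "chr1",
                      start = c(1000, 2500, 4000),
                      end = c(1150, 2650, 4120),
                      strand = c("+", "-", "+"))
  f1 <- exon_flanks(exons, genome)
  f2 <- exon_flanks(exons[c(3, 1, 2), ], genome)
  c1 <- positional_coverage(f1, "WGCAUGM")
  c2 <- positional_coverage(f2, "WGCAUGM")
  expect_equal(c1, c2)
  # a minus-strand exon's downstream flank is the reverse complement of the
  # genomic sequence to its left
  fl <- f1[[2]]
  lhs <- substr(genome[["chr1"]], 2500 - 250 + 1, 2500)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(lhs)))
  expect_equal(fl$downstream, rc)
})

test_that("windowed coverage equals a brute-force per-exon overlap check", {
  set.seed(81)
  genome <- c(chr1 = paste(sample(c("A", "C", "G", "T"), 20000,
                                  replace = TRUE), collapse = ""))
  exons <- data.frame(chrom = "chr1",
                      start = seq(2000, 17000, by = 1500),
                      end = seq(2000, 17000, by = 1500) + 120,
                      strand = "+")
  flanks <- exon_flanks(exons, genome, up_len = 100, down_len = 100,
                        exon_len = 40)
  cov <- positional_coverage(flanks, "WGCAUGM", smooth = 31)
  dn <- cov[cov$segment == "downstream", ]
  # brute force on the downstream segment
  for (off in c(0, 10, 50, 99)) {
    hits <- vapply(flanks, function(fl) {
      pos <- scan_iupac(fl$downstream, "WGCAUGM")
      any(pos + 7 > off - 15 & pos < off + 15 + 1)
    }, TRUE)
    expect_equal(dn$coverage[dn$offset == off], mean(hits))
  }
})

test_that("permutation enrichment flags only the planted window", {
  cfg <- simulation_config(n_tissues = 4, n_genes = 350, seed = 82,
                           motif_enrichment_rate = 5,
                           motif_background_rate = 0.5)
  anng <- make_annotation(cfg)
  truth <- anng$exon_truth
  mk <- function(rows) exon_flanks(rows, anng$genome)
  bg <- mk(truth[truth$class == "unregulated", ])
  set.seed(83)
  prof <- permutation_enrichment(mk(truth[truth$class == "enhanced", ]),
                                 bg, n_perm = 300)
  sig_rate <- tapply(prof$significant, prof$segment, mean)
  expect_gt(sig_rate[["downstream"]], 0.3)
  expect_lt(sig_rate[["upstream"]], 0.1)
  prof_r <- permutation_enrichment(mk(truth[truth$class == "repressed", ]),
                                   bg, n_perm = 300)
  sig_r <- tapply(prof_r$significant, prof_r$segment, mean)
  expect_gt(sig_r[["upstream"]], 0.3)
  # the unplanted intronic side shows at most residual signal (smoothing
  # correlates neighboring offsets, so the BH mask is not exactly nominal
  # at this modest exon count)
  expect_lt(sig_r[["downstream"]], sig_r[["upstream"]] / 2)
  expect_lt(sig_r[["downstream"]], 0.25)
})

test_that("permutation p-values are bounded below and deterministic by seed", {
  set.seed(84)
  genome <- c(chr1 = paste(sample(c("A", "C", "G", "T"), 30000,
                                  replace = TRUE), collapse = ""))
  starts <- seq(1000, 28000, by = 900)
  exons <- data.frame(chrom = "chr1", start = starts, end = starts + 100,
                      strand = "+")
  flanks <- exon_flanks(exons, genome, up_len = 60, down_len = 60,
                        exon_len = 20)
  tgt <- flanks[1:10]; bg <- flanks[11:31]
  set.seed(1); p1 <- permutation_enrichment(tgt, bg, n_perm = 100)
  set.seed(1); p2 <- permutation_enrichment(tgt, bg, n_perm = 100)
  expect_identical(p1, p2)
  expect_true(all(p1$p >= 1 / 101, na.rm = TRUE))
  expect_warning(permutation_enrichment(tgt, bg, n_perm = 50), "100")
})

test_that("null targets drawn from the background are rarely significant", {
  set.seed(85)
  genome <- c(chr1 = paste(sample(c("A", "C", "G", "T"), 60000,
                                  replace = TRUE), collapse = ""))
  starts <- seq(1000, 58000, by = 700)
  exons <- data.frame(chrom = "chr1", start = starts, end = starts + 100,
                      strand = "+")
  flanks <- exon_flanks(exons, genome, up_len = 100, down_len = 100,
                        exon_len = 30)
  rates <- vapply(1:3, function(i) {
    pick <- sample(length(flanks), 25)
    prof <- permutation_enrichment(flanks[pick], flanks[-pick],
                                   n_perm = 150)
    mean(prof$significant, na.rm = TRUE)
  }, 0)
  expect_lte(mean(rates), 0.05)
})
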