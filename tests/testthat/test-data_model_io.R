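# Transcript models, GTF round trips and UTR/CDS arithmetic.

test_that("GTF coordinates convert to 0-based half-open on read", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    paste("chr1", "src", "exon", "101", "200", ".", "+", ".",
          'gene_id "g1"; transcript_id "t1"; gene_biotype "protein_coding";',
          sep = "\t"),
    paste("chr1", "src", "exon", "301", "400", ".", "+", ".",
          'gene_id "g1"; transcript_id "t1"; gene_biotype "protein_coding";',
          sep = "\t")), gtf)
  ann <- read_gtf(gtf)
  t1 <- ann$transcripts[["t1"]]
  expect_equal(unname(t1$exons[1, ]), c(100, 200))
  expect_equal(transcript_length(t1), 200)
})

test_that("GTF write/read round trip preserves structure byte-for-byte", {
  ann <- toy_annotation()
  f1 <- tempfile(fileext = ".gtf"); f2 <- tempfile(fileext = ".gtf")
  write_gtf(ann, f1)
  ann2 <- read_gtf(f1)
  expect_equal(names(ann2$transcripts), sort(names(ann$transcripts)))
  for (tid in names(ann$transcripts)) {
    expect_equal(ann2$transcripts[[tid]]$exons,
                 ann$transcripts[[tid]]$exons, ignore_attr = TRUE)
    expect_equal(ann2$transcripts[[tid]]$strand,
                 ann$transcripts[[tid]]$strand)
    expect_equal(ann2$transcripts[[tid]]$cds, ann$transcripts[[tid]]$cds)
  }
  write_gtf(ann2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("GTF reader agrees with rtracklayer on exon coordinates", {
  ann <- toy_annotation()
  f <- tempfile(fileext = ".gtf")
  write_gtf(ann, f)
  gr <- rtracklayer::import(f)
  ex <- gr[gr$type == "exon" & gr$transcript_id == "tA.1"]
  expect_equal(GenomicRanges::start(ex) - 1, ann$transcripts$tA.1$exons[, 1],
               ignore_attr = TRUE)
  expect_equal(GenomicRanges::end(ex), ann$transcripts$tA.1$exons[, 2],
               ignore_attr = TRUE)
})

test_that("malformed GTF lines are rejected with the line number", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c("# header",
               "chr1\tsrc\texon\t101"), gtf)
  expect_error(read_gtf(gtf), "line 2")
  writeLines(c(paste("chr1", "s", "exon", "10", "5", ".", "+", ".",
                     'gene_id "g"; transcript_id "t";', sep = "\t")), gtf)
  expect_error(read_gtf(gtf), "bad coordinates")
})

test_that("a transcript spanning two chromosomes is rejected", {
  gtf <- tempfile(fileext = ".gtf")
  at <- 'gene_id "g1"; transcript_id "t1";'
  writeLines(c(
    paste("chr1", "s", "exon", "1", "100", ".", "+", ".", at, sep = "\t"),
    paste("chr2", "s", "exon", "1", "100", ".", "+", ".", at, sep = "\t")),
    gtf)
  expect_error(read_gtf(gtf), "multiple chromosomes")
})

test_that("transcript model invariants are enforced", {
  expect_error(transcript_model("t", "g", "c", "+", rbind(c(10, 5))),
               "end <= start")
  expect_error(transcript_model("t", "g", "c", "+",
                                rbind(c(0, 100), c(50, 150))),
               "overlapping")
  expect_error(transcript_model("t", "g", "c", "*", rbind(c(0, 100))),
               "strand")
  expect_error(transcript_model("t", "g", "c", "+", rbind(c(0, 100)),
                                cds = c(150, 250)), "cds")
  expect_error(annotation(list(
    transcript_model("t", "g", "c", "+", rbind(c(0, 100))),
    transcript_model("t", "g", "c", "+", rbind(c(0, 100))))),
    "duplicate")
})

test_that("transcript_parts splits coding transcripts strand-aware", {
  # single-exon transcript, length 300, CDS covering the middle 200
  t_plus <- transcript_model("t", "g", "c", "+", rbind(c(0, 300)),
                             cds = c(50, 250))
  p <- transcript_parts(t_plus)
  expect_equal(c(p$utr5, p$cds, p$utr3), c(50, 200, 50))
  expect_true(p$coding)

  # on the minus strand the 5' end is the rightmost base
  t_minus <- transcript_model("t", "g", "c", "-", rbind(c(0, 300)),
                              cds = c(50, 250))
  pm <- transcript_parts(t_minus)
  expect_equal(c(pm$utr5, pm$cds, pm$utr3), c(50, 200, 50))

  t_skew <- transcript_model("t", "g", "c", "-", rbind(c(0, 300)),
                             cds = c(30, 250))
  ps <- transcript_parts(t_skew)
  expect_equal(c(ps$utr5, ps$cds, ps$utr3), c(50, 220, 30))

  # CDS spanning the entire transcript
  t_full <- transcript_model("t", "g", "c", "+", rbind(c(0, 300)),
                             cds = c(0, 300))
  expect_equal(unlist(transcript_parts(t_full)[c("utr5", "cds", "utr3")]),
               c(utr5 = 0, cds = 300, utr3 = 0))

  # non-coding
  t_nc <- transcript_model("t", "g", "c", "+", rbind(c(0, 300)))
  pn <- transcript_parts(t_nc)
  expect_false(pn$coding)
  expect_equal(c(pn$utr5, pn$cds, pn$utr3), c(0, 0, 0))
})

test_that("transcript_parts conserves length over multi-exon transcripts", {
  set.seed(42)
  for (i in 1:20) {
    n_ex <- sample(2:6, 1)
    starts <- cumsum(sample(50:200, n_ex)) + (0:(n_ex - 1)) * 300
    ends <- starts + sample(50:200, n_ex, replace = TRUE)
    lo <- starts[1] + 5
    hi <- ends[n_ex] - 5
    t <- transcript_model("t", "g", "c", sample(c("+", "-"), 1),
                          cbind(starts, ends), cds = c(lo, hi))
    p <- transcript_parts(t)
    expect_equal(p$utr5 + p$cds + p$utr3, transcript_length(t))
  }
})

test_that("minus-strand UTRs come from the rightmost exon side", {
  # two exons, CDS ends 20 nt into the right exon: on '-' that is the 5' UTR
  t <- transcript_model("t", "g", "c", "-",
                        rbind(c(0, 100), c(200, 300)), cds = c(50, 280))
  p <- transcript_parts(t)
  expect_equal(p$utr5, 20)
  expect_equal(p$utr3, 50)
})

test_that("expression matrix validates inputs and TSV round trips", {
  samples <- data.frame(sample_id = c("s1", "s2"), tissue = c("a", "b"),
                        condition = "pool", replicate = 1L)
  m <- matrix(c(1, 0, 2.5, 3), 2, 2,
              dimnames = list(c("f1", "f2"), NULL))
  ex <- expression_matrix(m, samples)
  expect_equal(colnames(ex$values), c("s1", "s2"))
  expect_error(expression_matrix(-m, samples), "non-negative")
  f <- tempfile(fileext = ".tsv")
  write_expression_tsv(ex, f)
  back <- read_expression_tsv(f, samples)
  expect_equal(back$values, ex$values)
})
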