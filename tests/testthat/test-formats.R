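test_that("GTF exon lines parse into transcripts with biotype and expression", {
  f <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tstringtie\texon\t100\t200\t.\t+\t.\tgene_id "g1"; transcript_id "t1"; FPKM "3.5";',
    'chr1\tstringtie\texon\t300\t450\t.\t+\t.\tgene_id "g1"; transcript_id "t1"; FPKM "3.5";'
  ), f)
  ann <- read_gtf(f)
  expect_equal(n_transcripts(ann), 1L)
  tx <- tx_table(ann)
  expect_equal(tx$exonic_length, 101L + 151L)
  expect_equal(tx$expression, 3.5)
  expect_equal(tx$start, 100L)
  expect_equal(tx$end, 450L)
  expect_equal(tx$biotype, "unknown")
})

test_that("GTF attribute priority is configurable and falls through", {
  f <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tx\texon\t1\t300\t.\t+\t.\tgene_id "g"; transcript_id "t"; gene_type "lincRNA"; TPM "7"; cov "2";'
  ), f)
  ann <- read_gtf(f)
  expect_equal(tx_table(ann)$biotype, "lincRNA")
  expect_equal(tx_table(ann)$expression, 7)  # FPKM absent, TPM next
  ann2 <- read_gtf(f, expression_keys = "cov")
  expect_equal(tx_table(ann2)$expression, 2)
})

test_that("malformed GTF errors carry line numbers and invariants are enforced", {
  f <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tx\texon\t1\t300\t.\t+\t.\tgene_id "g"; transcript_id "t";',
    "only-two\tfields"), f)
  expect_error(read_gtf(f), "line 2")

  f2 <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tx\texon\t1\t100\t.\t+\t.\tgene_id "g"; transcript_id "t";',
    'chr1\tx\texon\t200\t300\t.\t-\t.\tgene_id "g"; transcript_id "t";'), f2)
  expect_error(read_gtf(f2), "conflicting chrom/strand")

  f3 <- withr::local_tempfile(fileext = ".gtf")
  writeLines('chr1\tx\texon\t1\t300\t.\t+\t.\tgene_id "g";', f3)
  expect_error(read_gtf(f3), "transcript_id")
})

test_that("transcript lines without exons are dropped with a warning", {
  f <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tx\ttranscript\t1\t300\t.\t+\t.\tgene_id "g"; transcript_id "ghost";',
    'chr1\tx\texon\t500\t800\t.\t+\t.\tgene_id "g2"; transcript_id "t2";'), f)
  expect_warning(ann <- read_gtf(f), "no exon lines")
  expect_equal(tx_table(ann)$transcript_id, "t2")
})

test_that("GTF write/read round-trip preserves all transcript fields", {
  truth <- small_truth()
  ann <- truth$samples$s1$assembled
  f <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(ann, f)
  back <- read_gtf(f, biotype_keys = "transcript_type",
                   source_sample = "s1")
  expect_equal(n_transcripts(back), n_transcripts(ann))
  a <- tx_table(ann); b <- tx_table(back)
  b <- b[match(a$transcript_id, b$transcript_id), ]
  expect_equal(b$start, a$start)
  expect_equal(b$end, a$end)
  expect_equal(b$strand, a$strand)
  expect_equal(b$n_exons, a$n_exons)
  expect_equal(b$exonic_length, a$exonic_length)
  expect_equal(b$expression, a$expression, tolerance = 1e-9)
  # second round trip is exact
  f2 <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(back, f2)
  expect_equal(readLines(f2), readLines(f))
})

test_that("written GTF agrees with an independent GTF reader", {
  ann <- tiny_known()
  f <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(ann, f)
  gr <- rtracklayer::import(f, format = "gtf")
  ex <- gr[gr$type == "exon"]
  got <- data.frame(start = GenomicRanges::start(ex),
                    end = GenomicRanges::end(ex),
                    id = ex$transcript_id)
  got <- got[order(got$id, got$start), ]
  want <- exon_table(ann)
  want <- want[order(want$transcript_id, want$start), ]
  expect_equal(got$start, want$start)
  expect_equal(got$end, want$end)
  expect_equal(got$id, want$transcript_id)
})

test_that("BED coordinates convert 0-based half-open to 1-based inclusive", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t99\t200", f)
  track <- read_bed(f)
  gr <- track$intervals
  expect_equal(GenomicRanges::start(gr), 100L)
  expect_equal(GenomicRanges::end(gr), 200L)
  expect_equal(IRanges::width(gr), 101L)

  # empty file
  f2 <- withr::local_tempfile(fileext = ".bed")
  writeLines(character(0), f2)
  expect_length(read_bed(f2)$intervals, 0L)

  # end <= start errors with line number
  f3 <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t10\t20", "chr1\t30\t30"), f3)
  expect_error(read_bed(f3), "line 2")
})

test_that("BED round-trip is the identity", {
  truth <- small_truth()
  f <- withr::local_tempfile(fileext = ".bed")
  write_bed(truth$repeats, f)
  back <- read_bed(f)
  expect_equal(GenomicRanges::start(back$intervals),
               GenomicRanges::start(truth$repeats$intervals))
  expect_equal(GenomicRanges::end(back$intervals),
               GenomicRanges::end(truth$repeats$intervals))
  f2 <- withr::local_tempfile(fileext = ".bed")
  write_bed(back, f2)
  expect_equal(readLines(f2), readLines(f))
})

test_that("fragment tables and SAM templates read into fragment records", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tstart\tend\tstrand\tsample_id",
               "chr1\t100\t249\t+\ts1",
               "chr1\t500\t649\t-\ts1",
               "chr2\t10\t159\t+\ts2"), f)
  fr <- read_fragments(f)
  expect_equal(nrow(fr), 3L)
  expect_equal(fr$end[1], 249L)

  # SAM: properly-paired template of length 300 starting at 1000
  sam <- withr::local_tempfile(fileext = ".sam")
  writeLines(c(
    "@SQ\tSN:chr1\tLN:100000",
    "r1\t99\tchr1\t1000\t60\t100M\t=\t1200\t300\t*\t*",
    "r1\t147\tchr1\t1200\t60\t100M\t=\t1000\t-300\t*\t*"), sam)
  fs <- read_fragments(sam, sample_id = "s1")
  expect_equal(nrow(fs), 1L)
  expect_equal(fs$start, 1000L)
  expect_equal(fs$end, 1299L)

  # empty stream
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines("chrom\tstart\tend\tstrand\tsample_id", f2)
  expect_equal(nrow(read_fragments(f2)), 0L)
})

test_that("chromosome-name validation warns on disjoint naming", {
  expect_warning(check_chromosome_names(c("chr1", "chr2"), c("1", "2")),
                 "zero chromosome names")
  expect_silent(check_chromosome_names(c("chr1"), c("chr1", "chr9")))
})
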