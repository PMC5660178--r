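mk_cand_ann <- function(rows, sample_id) {
  rows$source_sample <- sample_id
  annotation_set(rows)
}

test_that("identical intron chains merge to the union span", {
  chain <- function(id, lead) data.frame(
    chrom = "c", start = c(1000L - lead, 2000L, 3000L),
    end = c(1400L, 2400L, 3400L), strand = "+",
    transcript_id = id, gene_id = paste0(id, "g"), biotype = "novel")
  a <- mk_cand_ann(chain("tA", 0L), "s1")
  b <- mk_cand_ann(chain("tB", 50L), "s2")   # 50 bp longer at the 5' end
  m <- merge_candidates(list(s1 = a, s2 = b))
  expect_equal(n_transcripts(m$ann), 1L)
  tx <- tx_table(m$ann)
  expect_equal(tx$start, 950L)
  expect_equal(tx$end, 3400L)
  expect_equal(tx$n_exons, 3L)
  # introns preserved exactly
  expect_equal(unname(intron_chain_keys(m$ann)),
               "c:+:1401-1999;2401-2999")
  expect_equal(nrow(m$provenance[[tx$transcript_id]]), 2L)
})

test_that("single-exon candidates cluster by transitive same-strand overlap", {
  a <- mk_cand_ann(data.frame(
    chrom = "c", start = c(100L, 450L), end = c(500L, 900L), strand = "+",
    transcript_id = c("x1", "x2"), gene_id = c("x1g", "x2g"),
    biotype = "novel"), "s1")
  b <- mk_cand_ann(data.frame(
    chrom = "c", start = 880L, end = 1300L, strand = "+",
    transcript_id = "y1", gene_id = "y1g", biotype = "novel"), "s2")
  m <- merge_candidates(list(s1 = a, s2 = b))
  expect_equal(n_transcripts(m$ann), 1L)  # 100-500 ~ 450-900 ~ 880-1300
  expect_equal(tx_table(m$ann)$start, 100L)
  expect_equal(tx_table(m$ann)$end, 1300L)

  # opposite strand does not cluster
  b2 <- mk_cand_ann(data.frame(
    chrom = "c", start = 880L, end = 1300L, strand = "-",
    transcript_id = "y1", gene_id = "y1g", biotype = "novel"), "s2")
  m2 <- merge_candidates(list(s1 = a, s2 = b2))
  expect_equal(n_transcripts(m2$ann), 2L)
})

test_that("single-sample merge is a pass-through with renaming only", {
  a <- mk_cand_ann(data.frame(
    chrom = "c", start = c(100L, 450L), end = c(500L, 900L), strand = "+",
    transcript_id = c("x1", "x2"), gene_id = c("x1g", "x2g"),
    biotype = "novel"), "s1")
  m <- merge_candidates(list(s1 = a))
  expect_equal(n_transcripts(m$ann), 2L)   # overlapping but NOT merged
  expect_true(all(grepl("^NOVEL\\.", tx_table(m$ann)$transcript_id)))
})

test_that("merge is idempotent, order-invariant and conserves provenance", {
  truth <- small_truth()
  sc <- test_scorers()
  per_sample <- lapply(truth$samples, function(s) {
    ext <- extract_candidates(s$assembled, truth$known, "stranded")
    casc <- run_cascade(ext$candidates, truth$repeats, truth$known,
                        ext$known_expression)
    score_candidates(casc$candidates, truth$genome, sc$scorer_a,
                     sc$scorer_b)
  })
  m1 <- merge_candidates(per_sample)
  n_in <- sum(vapply(per_sample, function(cs) sum(cs$status == "PASSED"),
                     1L))
  expect_equal(sum(vapply(m1$provenance, nrow, 1L)), n_in)

  # permutation invariance
  m2 <- merge_candidates(per_sample[c(3, 1, 2)])
  expect_equal(exon_table(m2$ann), exon_table(m1$ann))

  # idempotence: merging the merged annotation is a fixed point
  m3 <- merge_candidates(list(merged = m1$ann))
  expect_equal(exon_table(m3$ann)[c("chrom", "start", "end", "strand",
                                    "transcript_id")],
               exon_table(m1$ann)[c("chrom", "start", "end", "strand",
                                    "transcript_id")])

  # every planted survivor collapses to exactly one merged transcript
  surv <- truth$planted$transcript_id[truth$planted$should_survive]
  expect_equal(n_transcripts(m1$ann), length(surv))
  expect_true(all(vapply(m1$provenance, nrow, 1L) ==
                    length(truth$samples)))
})

test_that("mixing stranded and unstranded candidate sets is an error", {
  a <- mk_cand_ann(data.frame(
    chrom = "c", start = 100L, end = 500L, strand = "+",
    transcript_id = "x", gene_id = "xg", biotype = "novel"), "s1")
  b <- mk_cand_ann(data.frame(
    chrom = "c", start = 900L, end = 1300L, strand = ".",
    transcript_id = "y", gene_id = "yg", biotype = "novel"), "s2")
  expect_error(merge_candidates(list(s1 = a, s2 = b)),
               "stranded and unstranded")
})

test_that("nearest-gene annotation anchors TSS to TSS with signed distance", {
  known <- annotation_set(data.frame(
    chrom = "c", start = c(10000L, 40000L), end = c(12000L, 42000L),
    strand = "+", transcript_id = c("gA.t", "gB.t"),
    gene_id = c("gA", "gB"), biotype = "protein_coding"))
  lnc <- one_tx("c", 12500L, 13000L, "+", id = "L1")
  # closest TSS wins; signed distance = gene TSS - lncRNA TSS
  out <- annotate_nearest_gene(lnc, known)
  expect_equal(out$nearest_gene_id, "gA")
  expect_equal(out$distance_bp, -2500)
  # span overlap forces distance 0 (the antisense intronic case)
  lnc2 <- one_tx("c", 10500L, 11000L, "-", id = "L2")
  out2 <- annotate_nearest_gene(lnc2, known)
  expect_equal(out2$distance_bp, 0)
  expect_equal(out2$orientation, "antisense")
  # no coding gene on the chromosome: empty annotation
  lnc3 <- one_tx("cX", 100L, 700L, "+", id = "L3")
  out3 <- annotate_nearest_gene(lnc3, known)
  expect_true(is.na(out3$nearest_gene_id))
  expect_true(is.na(out3$distance_bp))
})

test_that("nearest-gene matches brute-force all-pairs minimization", {
  set.seed(17)
  truth <- small_truth()
  n <- 0L
  for (i in seq_len(500)) {
    chrom <- sample(c("synthA", "synthB"), 1)
    s <- sample.int(75000L, 1)
    lnc_row <- data.frame(chrom = chrom, start = s, end = s + 599L,
                          strand = sample(c("+", "-"), 1))
    lnc <- one_tx(chrom, lnc_row$start, lnc_row$end, lnc_row$strand,
                  id = "q")
    got <- annotate_nearest_gene(lnc, truth$known)
    want <- oracle_nearest(lnc_row, truth$known)
    if (is.null(want)) {
      expect_true(is.na(got$nearest_gene_id))
    } else if (got$nearest_gene_id != want$gene_id ||
               got$distance_bp != want$distance) {
      fail(sprintf("case %d: got %s/%d, oracle %s/%d", i,
                   got$nearest_gene_id, got$distance_bp, want$gene_id,
                   want$distance))
    }
    n <- n + 1L
  }
  expect_equal(n, 500L)
})

test_that("span-gap distance mode reports gap lengths", {
  known <- annotation_set(data.frame(
    chrom = "c", start = 10000L, end = 12000L, strand = "+",
    transcript_id = "gA.t", gene_id = "gA", biotype = "protein_coding"))
  lnc <- one_tx("c", 13000L, 13500L, "+", id = "L1")
  out <- annotate_nearest_gene(lnc, known, method = "span_gap")
  expect_equal(out$distance_bp, -1000)  # gene ends 1000 bp upstream
})
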