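test_that("withholding draws a seeded fraction of eligible lincRNAs", {
  # 90 eligible single-exon lincRNAs, none overlapping anything
  ex <- data.frame(chrom = "c", start = 2000L * (1:90),
                   end = 2000L * (1:90) + 599L, strand = "+",
                   transcript_id = sprintf("L%03d", 1:90),
                   gene_id = sprintf("G%03d", 1:90), biotype = "lincRNA")
  known <- annotation_set(ex)
  wh <- withhold(known, fraction = 1 / 3, seed = 5)
  expect_length(wh$eligible_ids, 90L)
  expect_equal(n_transcripts(wh$withheld), 30L)
  expect_equal(n_transcripts(wh$reduced), 60L)
  # partition: withheld and reduced are disjoint and exhaustive
  expect_length(intersect(wh$withheld$tx$transcript_id,
                          wh$reduced$tx$transcript_id), 0L)
  expect_setequal(c(wh$withheld$tx$transcript_id,
                    wh$reduced$tx$transcript_id), ex$transcript_id)
  # determinism
  wh2 <- withhold(known, fraction = 1 / 3, seed = 5)
  expect_identical(wh$withheld$tx$transcript_id,
                   wh2$withheld$tx$transcript_id)
  wh3 <- withhold(known, fraction = 1 / 3, seed = 6)
  expect_false(identical(wh$withheld$tx$transcript_id,
                         wh3$withheld$tx$transcript_id))
})

test_that("eligibility screen drops short, repeat-buried and overlapping lincRNAs", {
  ex <- rbind(
    data.frame(chrom = "c", start = 1000L, end = 1149L, strand = "+",
               transcript_id = "short", gene_id = "g1", biotype = "lincRNA"),
    data.frame(chrom = "c", start = 5000L, end = 5999L, strand = "+",
               transcript_id = "buried", gene_id = "g2", biotype = "lincRNA"),
    data.frame(chrom = "c", start = 9000L, end = 9999L, strand = "+",
               transcript_id = "overlaps_coding", gene_id = "g3",
               biotype = "lincRNA"),
    data.frame(chrom = "c", start = 9500L, end = 10400L, strand = "-",
               transcript_id = "cod", gene_id = "g4",
               biotype = "protein_coding"),
    data.frame(chrom = "c", start = 20000L * (1:6), end = 20000L * (1:6) + 800L,
               strand = "+", transcript_id = sprintf("ok%d", 1:6),
               gene_id = sprintf("g%d", 5:10), biotype = "lincRNA"))
  known <- annotation_set(ex)
  repeats <- repeat_track(GenomicRanges::GRanges(
    "c", IRanges::IRanges(5000L, 5999L)))
  wh <- withhold(known, fraction = 1 / 3, seed = 1, repeats = repeats)
  expect_setequal(wh$eligible_ids, sprintf("ok%d", 1:6))
})

test_that("recovery statuses come from overlap fraction and first-failing filter", {
  truth <- small_truth()
  sc <- test_scorers()
  s1 <- truth$samples$s1
  ext <- extract_candidates(s1$assembled, truth$known, "stranded")
  casc <- run_cascade(ext$candidates, truth$repeats, truth$known,
                      ext$known_expression)
  cands <- score_candidates(casc$candidates, truth$genome, sc$scorer_a,
                            sc$scorer_b)

  # planted transcripts treated as "withheld": the clean ones self-match
  surv <- truth$planted[truth$planted$should_survive, ]
  wh_ann <- subset_transcripts(truth$planted_ann, surv$transcript_id)
  st <- match_recovered(wh_ann, cands)
  linc <- surv$transcript_id[surv$intended_class == "LINCRNA"]
  anti <- surv$transcript_id[surv$intended_class == "OVERLAP_ANTISENSE"]
  expect_true(all(st[linc] == "RECOVERED_LINCRNA"))
  expect_true(all(st[anti] == "RECOVERED_OVERLAP"))

  # decoys attribute to the filter that removed their matching candidate
  dec <- truth$planted[!truth$planted$should_survive, ]
  wh_dec <- subset_transcripts(truth$planted_ann, dec$transcript_id)
  std <- match_recovered(wh_dec, cands)
  lab <- c(length = "FILTERED_LENGTH", `repeat` = "FILTERED_REPEAT",
           expression = "FILTERED_EXPRESSION",
           coding_potential = "FILTERED_CODING")
  expect_equal(unname(std[dec$transcript_id]),
               unname(lab[dec$failure_reason]))

  # a transcript nothing overlaps is NOT_ASSEMBLED
  ghost <- one_tx("synthA", 1L, 250L, "+", id = "ghost")
  expect_equal(unname(match_recovered(ghost, cands)), "NOT_ASSEMBLED")

  # with fragments supplied, an uncovered transcript is NOT_COVERED
  expect_equal(unname(match_recovered(ghost, cands,
                                      fragments = s1$fragments)),
               "NOT_COVERED")
})

test_that("exonic overlap fractions match per-base brute force on random pairs", {
  set.seed(41)
  for (i in seq_len(200)) {
    a <- random_exons("c", 20000L, sample(1:3, 1), sample(150:500, 1), 300L,
                      strand = "+")
    b <- random_exons("c", 20000L, sample(1:3, 1), sample(150:500, 1), 300L,
                      strand = "+")
    wa <- one_tx("c", a$start, a$end, "+", id = "w")
    cb <- one_tx("c", b$start, b$end, "+", id = "k")
    got <- lncscout:::exonic_overlap_fractions(wa, cb)
    want <- oracle_exonic_overlap(a, b)
    got_frac <- if (nrow(got)) got$fraction else 0
    if (abs(got_frac - want) > 1e-12) {
      fail(sprintf("case %d: got %.6f, oracle %.6f", i, got_frac, want))
    }
  }
  succeed()
})

test_that("the recovery funnel aggregates and conserves", {
  # worked example: 86 assembled, 66 + 12 recovered, 1 repeat, 7 expression
  statuses <- c(rep("RECOVERED_LINCRNA", 66), rep("RECOVERED_OVERLAP", 12),
                rep("FILTERED_REPEAT", 1), rep("FILTERED_EXPRESSION", 7))
  rep_ <- recall_report(statuses, n_withheld = 1793, n_covered = 102)
  expect_equal(rep_$n_assembled, 86L)
  expect_equal(rep_$recall_pct, 90.7)

  # all recovered
  expect_equal(recall_report(rep("RECOVERED_LINCRNA", 5))$recall_pct, 100)

  # nothing assembled: recall undefined
  expect_true(is.na(recall_report(rep("NOT_ASSEMBLED", 4))$recall_pct))

  # conservation on random status vectors
  set.seed(3)
  pool <- c("RECOVERED_LINCRNA", "RECOVERED_OVERLAP", "FILTERED_REPEAT",
            "FILTERED_EXPRESSION", "FILTERED_LENGTH", "FILTERED_CODING",
            "NOT_ASSEMBLED", "NOT_COVERED")
  for (i in 1:20) {
    st <- sample(pool, sample(10:200, 1), replace = TRUE)
    r <- recall_report(st)
    expect_equal(r$n_assembled,
                 r$n_recovered_lincrna + r$n_recovered_overlap +
                   r$n_filtered_repeat + r$n_filtered_expression +
                   r$n_filtered_other)
    expect_lte(r$n_assembled, r$n_covered)
    expect_lte(r$n_covered, r$n_withheld)
  }
})

test_that("intron-chain matching recovers exact structures only", {
  truth <- small_truth()
  sc <- test_scorers()
  s1 <- truth$samples$s1
  ext <- extract_candidates(s1$assembled, truth$known, "stranded")
  casc <- run_cascade(ext$candidates, truth$repeats, truth$known,
                      ext$known_expression)
  cands <- score_candidates(casc$candidates, truth$genome, sc$scorer_a,
                            sc$scorer_b)
  surv <- truth$planted[truth$planted$should_survive &
                          truth$planted$n_exons > 1L, ]
  wh <- subset_transcripts(truth$planted_ann, surv$transcript_id)
  st <- match_recovered(wh, cands, rule = "intron_chain")
  expect_true(all(grepl("^RECOVERED", st)))

  # perturb the withheld introns: no longer an exact chain
  ex <- exon_table(wh)
  ex$start <- ex$start + ifelse(seq_len(nrow(ex)) %% 2 == 0, 13L, 0L)
  st2 <- match_recovered(annotation_set(ex), cands, rule = "intron_chain")
  expect_false(any(grepl("^RECOVERED", st2)))
})
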