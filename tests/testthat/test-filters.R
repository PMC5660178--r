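test_that("length filter applies strict boundaries", {
  run_len <- function(len, n_exons) {
    starts <- if (n_exons == 1) 1000L else c(1000L, 3000L)
    widths <- if (n_exons == 1) len else c(100L, len - 100L)
    cand <- one_candidate(starts = starts, ends = starts + widths - 1L)
    tr <- length_filter(cand)$trace
    tr$passed[tr$filter == "length"]
  }
  expect_false(run_len(199L, 1))   # shorter than 200 bp: removed
  expect_true(run_len(200L, 1))    # boundary passes ("shorter than" strict)
  expect_true(run_len(200L, 2))
  expect_false(run_len(199L, 2))
  expect_true(run_len(10000L, 1))  # boundary passes ("greater than" strict)
  expect_false(run_len(10001L, 1))
  expect_true(run_len(12000L, 2))  # upper bound scoped to single-exon
})

test_that("repeat filter exempts multi-exon and fails buried single-exon", {
  repeats <- repeat_track(GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(1L, 100000L)))
  multi <- one_candidate(starts = c(1000L, 3000L), ends = c(1399L, 3399L))
  tr <- repeat_filter(multi, repeats)$trace
  expect_true(tr$passed[tr$filter == "repeat"])
  expect_match(tr$detail[tr$filter == "repeat"], "exempt")

  single <- one_candidate(starts = 1000L, ends = 1999L)
  tr2 <- repeat_filter(single, repeats)$trace
  expect_false(tr2$passed[tr2$filter == "repeat"])

  # fraction 0 config: any overlap fails
  half <- repeat_track(GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(1000L, 1000L)))
  tr3 <- repeat_filter(single, half,
                       filter_config(repeat_overlap_max_fraction = 0))$trace
  expect_false(tr3$passed[tr3$filter == "repeat"])
})

test_that("repeat-overlap fractions match per-base brute force on random candidates", {
  set.seed(23)
  truth <- small_truth()
  for (i in seq_len(200)) {
    ex <- random_exons(sample(c("synthA", "synthB"), 1), 70000L,
                       n_exons = sample(1:2, 1), exon_len = sample(200:800, 1),
                       gap_len = 300L)
    ann <- one_tx(ex$chrom[1], ex$start, ex$end, ex$strand[1],
                  id = sprintf("r%d", i))
    got <- unname(repeat_overlap_fraction(ann, truth$repeats))
    want <- oracle_repeat_fraction(ex, truth$repeats)
    if (abs(got - want) > 1e-12) {
      fail(sprintf("case %d: got %.6f, oracle %.6f", i, got, want))
    }
  }
  succeed()
})

test_that("expression cutoffs follow the type-7 quantile convention", {
  known <- cached("known_quant", {
    # 100 single-exon + 30 multi-exon known transcripts
    ex <- rbind(
      data.frame(chrom = "c", start = 1000L * (1:100), end = 1000L * (1:100) + 500L,
                 strand = "+", transcript_id = sprintf("s%03d", 1:100),
                 gene_id = sprintf("gs%03d", 1:100), biotype = "lincRNA"),
      do.call(rbind, lapply(1:30, function(i) {
        s <- 200000L + 2000L * i
        data.frame(chrom = "c", start = c(s, s + 800L), end = c(s + 300L, s + 1100L),
                   strand = "+", transcript_id = sprintf("m%03d", c(i, i)),
                   gene_id = sprintf("gm%03d", c(i, i)), biotype = "lincRNA")
      })))
    annotation_set(ex)
  })
  expr <- c(stats::setNames(as.numeric(1:100), sprintf("s%03d", 1:100)),
            stats::setNames(as.numeric(1:30), sprintf("m%03d", 1:30)))
  cut <- derive_expression_cutoffs(known, expr)
  expect_equal(cut$single_exon_low, 5.95)   # type-7 quantile of 1..100 at .05
  expect_equal(cut$single_exon_high, 95.05)
  expect_equal(cut$multi_exon_low,
               unname(stats::quantile(1:30, 0.05, type = 7)))
  expect_equal(cut$n_known_single, 100L)

  # degenerate: identical expression collapses the band
  cut2 <- derive_expression_cutoffs(known, rep(3.3, 130) |>
                                      stats::setNames(names(expr)))
  expect_equal(cut2$single_exon_low, 3.3)
  expect_equal(cut2$single_exon_high, 3.3)

  # quantile equivariance: scaling expression scales the cutoffs
  cut3 <- derive_expression_cutoffs(known, expr * 7)
  expect_equal(cut3$single_exon_low, cut$single_exon_low * 7)
  expect_equal(cut3$single_exon_high, cut$single_exon_high * 7)
  expect_equal(cut3$multi_exon_low, cut$multi_exon_low * 7)

  # no expressed reference at all
  expect_error(derive_expression_cutoffs(known, expr * 0), "no expressed")
})

test_that("expression filter bounds single-exon on both sides, multi-exon below only", {
  cut <- expression_cutoffs(5.95, 95.05, 2.45)
  run_expr <- function(fpkm, n_exons) {
    starts <- if (n_exons == 1) 1000L else c(1000L, 3000L)
    ends <- starts + 299L
    cand <- one_candidate(starts = starts, ends = ends, expression = fpkm)
    tr <- expression_filter(cand, cut)$trace
    tr$passed[tr$filter == "expression"]
  }
  expect_true(run_expr(50, 1))     # mid-range passes
  expect_false(run_expr(100, 1))   # above the high cutoff: noise-prone
  expect_false(run_expr(1, 1))
  expect_true(run_expr(1e6, 2))    # no upper bound for multi-exon
  expect_false(run_expr(1, 2))

  cand <- one_candidate(expression = NA_real_)
  tr <- expression_filter(cand, cut)$trace
  expect_false(tr$passed)
  expect_match(tr$detail, "no expression value")
})

test_that("cascade counts conserve and attribute first failures", {
  truth <- small_truth()
  s1 <- truth$samples$s1
  ext <- extract_candidates(s1$assembled, truth$known, "stranded")
  casc <- run_cascade(ext$candidates, truth$repeats, truth$known,
                      ext$known_expression)
  cnt <- casc$counts
  expect_equal(unname(cnt["input"]),
               unname(cnt["passed"] + cnt["failed_length"] +
                        cnt["failed_repeat"] + cnt["failed_expression"]))
  # decoys planted for each cascade filter appear in its first-failure count
  m <- s1$truth_map
  kinds <- truth$planted$kind[match(m[names(casc$first_failure)],
                                    truth$planted$transcript_id)]
  ff <- casc$first_failure
  expect_true(all(ff[kinds %in% c("decoy_short", "decoy_long")] == "length"))
  expect_true(all(ff[kinds == "decoy_repeat"] == "repeat"))
  expect_true(all(ff[kinds %in% c("decoy_low_expr", "decoy_high_expr")] ==
                    "expression"))
  expect_true(all(is.na(ff[kinds %in% c("clean_multi", "clean_single",
                                        "antisense", "decoy_coding")])))

  # reordering candidates does not change counts
  ids <- rev(names(ext$candidates$status))
  cand2 <- candidate_set(subset_transcripts(ext$candidates$ann, ids),
                         ext$candidates$class)
  casc2 <- run_cascade(cand2, truth$repeats, truth$known,
                       ext$known_expression)
  expect_equal(casc2$counts, casc$counts)
})

test_that("tightening thresholds never increases survivors", {
  truth <- small_truth()
  s1 <- truth$samples$s1
  ext <- extract_candidates(s1$assembled, truth$known, "stranded")
  n_passed <- function(cfg) {
    unname(run_cascade(ext$candidates, truth$repeats, truth$known,
                       ext$known_expression, cfg = cfg)$counts["passed"])
  }
  base <- n_passed(filter_config())
  expect_lte(n_passed(filter_config(min_length_bp = 400L)), base)
  expect_lte(n_passed(filter_config(repeat_overlap_max_fraction = 0)), base)
  expect_lte(n_passed(filter_config(
    single_exon_expr_quantiles = c(0.2, 0.8))), base)
})

test_that("samples with different expression depths get different cutoffs", {
  truth <- small_truth()
  cuts <- lapply(names(truth$samples), function(sid) {
    ext <- extract_candidates(truth$samples[[sid]]$assembled, truth$known,
                              "stranded")
    derive_expression_cutoffs(truth$known, ext$known_expression,
                              sample_id = sid)
  })
  lows <- vapply(cuts, `[[`, 1.0, "single_exon_low")
  expect_gt(length(unique(lows)), 1L)
  # depth factors 1, 0.5, 2: the shallow sample has the lowest cutoff
  expect_equal(which.min(lows), 2L)
})
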