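# Shared fixtures, generated once per test run and cached. Sizes are kept
# small so the whole suite stays fast; the generator itself is exercised at
# its defaults in the end-to-end tests.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# small but complete bundle: every planted class and decoy kind present
small_truth <- function() {
  cached("small_truth", synth_generate(
    genome_size = 160000L, n_coding = 12L,
    n_known_linc_multi = 8L, n_known_linc_single = 22L,
    n_known_antisense = 3L,
    n_novel_multi = 3L, n_novel_single = 3L, n_novel_antisense = 3L,
    n_decoy_short = 2L, n_decoy_long = 2L, n_decoy_repeat = 2L,
    n_decoy_low_expr = 2L, n_decoy_high_expr = 2L, n_decoy_coding = 2L,
    n_bg_repeats = 8L, n_samples = 3L, frag_rate = 10, seed = 101L))
}

# defaults: the full study conditions (3 samples, ~40 planted novels+decoys)
default_truth <- function() cached("default_truth", synth_generate(seed = 42L))

test_scorers <- function() cached("scorers", default_scorers(seed = 1L))

# a minimal hand-built annotation: one coding gene, one known lincRNA
tiny_known <- function() {
  annotation_set(data.frame(
    chrom = "chr1",
    start = c(10000L, 11000L, 12000L, 30000L),
    end = c(10299L, 11299L, 12299L, 30599L),
    strand = c("+", "+", "+", "-"),
    transcript_id = c("COD1", "COD1", "COD1", "LINC1"),
    gene_id = c("G1", "G1", "G1", "G2"),
    biotype = c(rep("protein_coding", 3), "lincRNA")))
}

one_tx <- function(chrom, starts, ends, strand, id = "cand1",
                   expression = NA_real_, biotype = "novel") {
  annotation_set(data.frame(
    chrom = chrom, start = as.integer(starts), end = as.integer(ends),
    strand = strand, transcript_id = id, gene_id = paste0(id, ".G"),
    biotype = biotype, expression = expression))
}

# single-candidate CandidateSet with a given exonic structure
one_candidate <- function(chrom = "chr1", starts = 1000L, ends = 1599L,
                          strand = "+", id = "cand1",
                          expression = NA_real_, class = "LINCRNA") {
  ann <- one_tx(chrom, starts, ends, strand, id, expression)
  candidate_set(ann, stats::setNames(class, id))
}
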