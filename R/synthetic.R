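#' Synthetic transcriptome fixtures with planted ground truth
#'
#' The generator emulates everything the discovery pipeline consumes: a
#' random genome, a reference annotation with multi-exon protein-coding
#' genes (codon-biased ORFs painted into their exons), known lincRNAs
#' (multi- and single-exon) and known antisense lncRNAs inside coding
#' introns, a repeat track, planted novel transcripts with known intended
#' class, decoys engineered to fail exactly one filter each, per-sample
#' assembled GTFs with expression values, and fragment records drawn
#' proportional to expression x length. Every feature is placed in its own
#' genomic slot so no unintended overlaps arise, and the intended class of
#' every planted novel is re-verified against the classifier at
#' generation time.
#'
#' @param genome_size total genome length in bp (split over two
#'   chromosomes).
#' @param n_coding number of protein-coding genes (3 exons each).
#' @param n_known_linc_multi,n_known_linc_single known lincRNA counts.
#' @param n_known_antisense known antisense lncRNAs inside coding introns.
#' @param n_novel_multi,n_novel_single clean intergenic planted novels.
#' @param n_novel_antisense planted antisense novels (single-exon, inside
#'   coding introns, opposite strand).
#' @param n_decoy_short,n_decoy_long,n_decoy_repeat,n_decoy_low_expr,n_decoy_high_expr,n_decoy_coding
#'   decoy counts per intended failure mode.
#' @param n_bg_repeats background repeat intervals (placed clear of
#'   transcripts).
#' @param n_samples number of samples.
#' @param depth_factors per-sample depth scaling of expression (recycled
#'   to `n_samples`); emulates variable sequencing depth.
#' @param expression_model `"lognormal"` (default: per-transcript
#'   log-normal baselines, meanlog `expr_meanlog`, sdlog `expr_sdlog`,
#'   with per-sample noise) or `"constant"` (every transcript at the same
#'   level — a degenerate control where no expression filtering occurs).
#' @param expr_meanlog,expr_sdlog log-normal parameters of the known
#'   transcript expression baseline.
#' @param detect_min minimum expression for a known transcript to appear
#'   in a sample's assembly (emulates assembler detection limits).
#' @param frag_rate expected fragments per expression unit per kb.
#' @param seed integer seed; the whole bundle is deterministic given it.
#' @return a `SyntheticTruth` list: `params`, `genome`
#'   ([Biostrings::DNAStringSet]), `known` (`AnnotationSet`), `repeats`
#'   (`RepeatTrack`), `planted` (data.frame with intended class,
#'   `should_survive` and `failure_reason`), `planted_ann`, `samples`
#'   (per sample: `assembled` AnnotationSet, `fragments` data.frame,
#'   `truth_map` assembled id -> origin id), and `expression` matrices.
#' @export
synth_generate <- function(genome_size = 420000L,
                           n_coding = 30L,
                           n_known_linc_multi = 20L,
                           n_known_linc_single = 25L,
                           n_known_antisense = 5L,
                           n_novel_multi = 6L,
                           n_novel_single = 6L,
                           n_novel_antisense = 5L,
                           n_decoy_short = 4L,
                           n_decoy_long = 4L,
                           n_decoy_repeat = 4L,
                           n_decoy_low_expr = 4L,
                           n_decoy_high_expr = 4L,
                           n_decoy_coding = 4L,
                           n_bg_repeats = 15L,
                           n_samples = 3L,
                           depth_factors = c(1, 0.5, 2),
                           expression_model = c("lognormal", "constant"),
                           expr_meanlog = 1.5,
                           expr_sdlog = 0.8,
                           detect_min = 0.3,
                           frag_rate = 20,
                           seed = 1L) {
  expression_model <- match.arg(expression_model)
  set.seed(seed)
  depth_factors <- rep_len(depth_factors, n_samples)
  chrom_len <- c(synthA = ceiling(genome_size / 2),
                 synthB = floor(genome_size / 2))
  genome <- lapply(chrom_len, function(n) {
    sample(c("A", "C", "G", "T"), n, replace = TRUE)
  })

  # --- sequential slot placer: no two features overlap unless intended;
  # alternates chromosomes so both carry known and novel features ---
  cursors <- stats::setNames(rep(1L, length(chrom_len)), names(chrom_len))
  next_chrom <- 0L
  place <- function(width) {
    gap <- sample(300:800, 1L)
    for (k in seq_along(chrom_len)) {
      next_chrom <<- next_chrom + 1L
      chr <- names(chrom_len)[(next_chrom - 1L) %% length(chrom_len) + 1L]
      pos <- cursors[[chr]] + gap
      if (pos + width - 1L <= chrom_len[[chr]]) {
        cursors[[chr]] <<- pos + width - 1L
        return(list(chrom = chr, start = pos))
      }
    }
    stop("synthetic genome too small to place all features; ",
         "increase genome_size")
  }

  exon_rows <- list()
  add_tx <- function(tid, gid, chrom, ex_start, ex_end, strand, biotype) {
    exon_rows[[length(exon_rows) + 1L]] <<- data.frame(
      chrom = chrom, start = ex_start, end = ex_end, strand = strand,
      transcript_id = tid, gene_id = gid, biotype = biotype,
      stringsAsFactors = FALSE)
  }

  # codon-biased mRNA: favored codons dominate, giving the hexamer and
  # Fickett signal the coding-potential scorers learn
  favored <- c("GAG", "GCC", "AAG", "CTG", "GAC", "ATC", "GTG", "ACC",
               "CAG", "TTC", "AAC", "GGC", "TAC", "CGC", "AGC", "CCC")
  other_codons <- setdiff(
    apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                      c("A", "C", "G", "T")), 1, paste, collapse = ""),
    c("TAA", "TAG", "TGA", favored))
  make_orf <- function(n_codons) {
    body <- sample(c(favored, other_codons), n_codons, replace = TRUE,
                   prob = c(rep(8, length(favored)),
                            rep(1, length(other_codons))))
    paste0("ATG", paste(body, collapse = ""), "TAA")
  }
  paint <- function(chrom, ex_start, ex_end, strand, mrna) {
    gseq <- if (strand == "-") {
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(mrna)))
    } else mrna
    chars <- strsplit(gseq, "", fixed = TRUE)[[1]]
    off <- 0L
    for (k in seq_along(ex_start)) {
      w <- ex_end[k] - ex_start[k] + 1L
      genome[[chrom]][ex_start[k]:ex_end[k]] <<- chars[(off + 1L):(off + w)]
      off <- off + w
    }
  }
  # keep noncoding sequence free of chance long ORFs
  scrub_orfs <- function(chrom, ex_start, ex_end, max_orf = 150L) {
    for (tries in 1:50) {
      spliced <- paste(unlist(lapply(seq_along(ex_start), function(k) {
        paste(genome[[chrom]][ex_start[k]:ex_end[k]], collapse = "")
      })), collapse = "")
      fwd <- longest_orf(spliced)$length
      rev_ <- longest_orf(as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(spliced))))$length
      if (max(fwd, rev_) <= max_orf) return(invisible(NULL))
      k <- sample(seq_along(ex_start), 1L)
      genome[[chrom]][ex_start[k]:ex_end[k]] <<-
        sample(c("A", "C", "G", "T"), ex_end[k] - ex_start[k] + 1L,
               replace = TRUE)
    }
    stop("could not scrub ORFs from a noncoding feature")
  }

  coding_introns <- list()  # reusable intron slots for antisense features
  rand_strand <- function() sample(c("+", "-"), 1L)

  # --- protein-coding genes: 3 exons x 300 bp, introns 700 bp ---
  for (i in seq_len(n_coding)) {
    slot <- place(300L * 3L + 700L * 2L)
    s <- slot$start
    ex_start <- c(s, s + 1000L, s + 2000L)
    ex_end <- ex_start + 299L
    strand <- rand_strand()
    add_tx(sprintf("CODT%03d", i), sprintf("CODG%03d", i), slot$chrom,
           ex_start, ex_end, strand, "protein_coding")
    paint(slot$chrom, ex_start, ex_end, strand, make_orf(298L))
    coding_introns[[i]] <- list(chrom = slot$chrom, strand = strand,
                                istart = ex_end[1] + 1L,
                                iend = ex_start[2] - 1L)
  }

  noncoding_feats <- list()  # to scrub after placement
  add_noncoding <- function(tid, gid, chrom, ex_start, ex_end, strand,
                            biotype) {
    add_tx(tid, gid, chrom, ex_start, ex_end, strand, biotype)
    noncoding_feats[[length(noncoding_feats) + 1L]] <<-
      list(chrom = chrom, ex_start = ex_start, ex_end = ex_end)
  }

  # --- known lincRNAs ---
  for (i in seq_len(n_known_linc_multi)) {
    slot <- place(200L * 3L + 400L * 2L)
    s <- slot$start
    ex_start <- c(s, s + 600L, s + 1200L)
    add_noncoding(sprintf("LINCM%03d", i), sprintf("LINCMG%03d", i),
                  slot$chrom, ex_start, ex_start + 199L, rand_strand(),
                  "lincRNA")
  }
  for (i in seq_len(n_known_linc_single)) {
    slot <- place(600L)
    add_noncoding(sprintf("LINCS%03d", i), sprintf("LINCSG%03d", i),
                  slot$chrom, slot$start, slot$start + 599L, rand_strand(),
                  "lincRNA")
  }
  intron_pool <- sample(seq_along(coding_introns))
  take_intron <- function() {
    if (!length(intron_pool)) stop("not enough coding introns for antisense features")
    i <- intron_pool[1L]; intron_pool <<- intron_pool[-1L]
    coding_introns[[i]]
  }
  for (i in seq_len(n_known_antisense)) {
    intr <- take_intron()
    s <- intr$istart + 150L
    add_noncoding(sprintf("ASKN%03d", i), sprintf("ASKNG%03d", i),
                  intr$chrom, s, s + 399L,
                  if (intr$strand == "+") "-" else "+", "antisense")
  }

  # --- planted novels and decoys ---
  planted <- list()
  add_planted <- function(tid, kind, intended_class, should_survive,
                          failure_reason, chrom, ex_start, ex_end, strand,
                          scrub = TRUE) {
    planted[[length(planted) + 1L]] <<- list(
      transcript_id = tid, kind = kind, intended_class = intended_class,
      should_survive = should_survive, failure_reason = failure_reason,
      chrom = chrom, ex_start = list(ex_start), ex_end = list(ex_end),
      strand = strand)
    if (scrub) {
      noncoding_feats[[length(noncoding_feats) + 1L]] <<-
        list(chrom = chrom, ex_start = ex_start, ex_end = ex_end)
    }
  }
  for (i in seq_len(n_novel_multi)) {
    slot <- place(250L * 3L + 500L * 2L)
    s <- slot$start
    ex_start <- c(s, s + 750L, s + 1500L)
    add_planted(sprintf("NOVM%03d", i), "clean_multi", "LINCRNA", TRUE, NA,
                slot$chrom, ex_start, ex_start + 249L, rand_strand())
  }
  for (i in seq_len(n_novel_single)) {
    slot <- place(700L)
    add_planted(sprintf("NOVS%03d", i), "clean_single", "LINCRNA", TRUE, NA,
                slot$chrom, slot$start, slot$start + 699L, rand_strand())
  }
  for (i in seq_len(n_novel_antisense)) {
    intr <- take_intron()
    s <- intr$istart + 100L
    add_planted(sprintf("NOVA%03d", i), "antisense", "OVERLAP_ANTISENSE",
                TRUE, NA, intr$chrom, s, s + 449L,
                if (intr$strand == "+") "-" else "+")
  }
  for (i in seq_len(n_decoy_short)) {
    slot <- place(150L)
    add_planted(sprintf("DSHT%03d", i), "decoy_short", "LINCRNA", FALSE,
                "length", slot$chrom, slot$start, slot$start + 149L,
                rand_strand())
  }
  for (i in seq_len(n_decoy_long)) {
    slot <- place(10400L)
    # chance ORFs are left in place: the length filter removes this decoy
    # before coding potential is ever consulted
    add_planted(sprintf("DLNG%03d", i), "decoy_long", "LINCRNA", FALSE,
                "length", slot$chrom, slot$start, slot$start + 10399L,
                rand_strand(), scrub = FALSE)
  }
  repeat_rows <- list()
  for (i in seq_len(n_decoy_repeat)) {
    slot <- place(600L)
    add_planted(sprintf("DREP%03d", i), "decoy_repeat", "LINCRNA", FALSE,
                "repeat", slot$chrom, slot$start, slot$start + 599L,
                rand_strand())
    repeat_rows[[length(repeat_rows) + 1L]] <- data.frame(
      chrom = slot$chrom, start = slot$start, end = slot$start + 599L)
  }
  for (i in seq_len(n_decoy_low_expr)) {
    slot <- place(600L)
    add_planted(sprintf("DLOW%03d", i), "decoy_low_expr", "LINCRNA", FALSE,
                "expression", slot$chrom, slot$start, slot$start + 599L,
                rand_strand())
  }
  for (i in seq_len(n_decoy_high_expr)) {
    slot <- place(600L)
    add_planted(sprintf("DHGH%03d", i), "decoy_high_expr", "LINCRNA", FALSE,
                "expression", slot$chrom, slot$start, slot$start + 599L,
                rand_strand())
  }
  for (i in seq_len(n_decoy_coding)) {
    slot <- place(900L)
    strand <- rand_strand()
    add_planted(sprintf("DCOD%03d", i), "decoy_coding", "LINCRNA", FALSE,
                "coding_potential", slot$chrom, slot$start,
                slot$start + 899L, strand, scrub = FALSE)
    paint(slot$chrom, slot$start, slot$start + 899L, strand, make_orf(298L))
  }
  for (i in seq_len(n_bg_repeats)) {
    w <- sample(300:800, 1L)
    slot <- place(w)
    repeat_rows[[length(repeat_rows) + 1L]] <- data.frame(
      chrom = slot$chrom, start = slot$start, end = slot$start + w - 1L)
  }

  for (f in noncoding_feats) scrub_orfs(f$chrom, f$ex_start, f$ex_end)

  known <- annotation_set(do.call(rbind, exon_rows))
  empty_exons <- data.frame(
    chrom = character(), start = integer(), end = integer(),
    strand = character(), transcript_id = character(),
    gene_id = character(), biotype = character())
  planted_df <- do.call(rbind, lapply(planted, function(p) {
    data.frame(transcript_id = p$transcript_id, kind = p$kind,
               intended_class = p$intended_class,
               should_survive = p$should_survive,
               failure_reason = p$failure_reason, chrom = p$chrom,
               start = min(p$ex_start[[1]]), end = max(p$ex_end[[1]]),
               strand = p$strand, n_exons = length(p$ex_start[[1]]),
               stringsAsFactors = FALSE)
  }))
  if (is.null(planted_df)) {
    planted_df <- data.frame(
      transcript_id = character(), kind = character(),
      intended_class = character(), should_survive = logical(),
      failure_reason = character(), chrom = character(),
      start = integer(), end = integer(), strand = character(),
      n_exons = integer())
  }
  planted_ex <- do.call(rbind, lapply(planted, function(p) {
    data.frame(chrom = p$chrom, start = p$ex_start[[1]], end = p$ex_end[[1]],
               strand = p$strand, transcript_id = p$transcript_id,
               gene_id = paste0(p$transcript_id, ".G"), biotype = "novel",
               stringsAsFactors = FALSE)
  }))
  planted_ann <- annotation_set(if (is.null(planted_ex)) empty_exons else
    planted_ex)
  rep_df <- if (length(repeat_rows)) do.call(rbind, repeat_rows) else
    data.frame(chrom = character(), start = integer(), end = integer())
  repeats <- repeat_track(GenomicRanges::GRanges(
    rep_df$chrom, IRanges::IRanges(rep_df$start, rep_df$end)))

  # generation-time sanity check: planted geometry matches intended class
  cls <- classify_transcripts(planted_ann, known, mode = "stranded")
  if (!all(cls[planted_df$transcript_id] == planted_df$intended_class)) {
    stop("internal error: planted geometry does not match intended class")
  }

  # --- per-sample expression, assembly and fragments ---
  ktx <- known$tx
  n_known <- nrow(ktx)
  base <- if (expression_model == "constant") rep(5, n_known) else
    stats::rlnorm(n_known, expr_meanlog, expr_sdlog)
  known_expr <- matrix(0, n_known, n_samples,
                       dimnames = list(ktx$transcript_id,
                                       paste0("s", seq_len(n_samples))))
  for (s in seq_len(n_samples)) {
    noise <- if (expression_model == "constant") 1 else
      stats::rlnorm(n_known, 0, 0.2)
    known_expr[, s] <- base * depth_factors[s] * noise
  }
  planted_expr <- matrix(0, nrow(planted_df), n_samples,
                         dimnames = list(planted_df$transcript_id,
                                         colnames(known_expr)))
  samples <- list()
  for (s in seq_len(n_samples)) {
    sid <- colnames(known_expr)[s]
    detected <- known_expr[, s] >= detect_min
    expr_s <- known_expr[detected, s]
    nex_s <- ktx$n_exons[detected]
    single_ref <- expr_s[nex_s == 1L]
    multi_ref <- expr_s[nex_s > 1L]
    q_single <- stats::quantile(single_ref, c(0.05, 0.5, 0.95), type = 7,
                                names = FALSE)
    q_multi <- stats::quantile(multi_ref, c(0.05, 0.5), type = 7,
                               names = FALSE)
    for (j in seq_len(nrow(planted_df))) {
      planted_expr[j, s] <- switch(planted_df$kind[j],
        decoy_low_expr = 0.25 * q_single[1],
        decoy_high_expr = 4 * q_single[3],
        if (planted_df$n_exons[j] == 1L) q_single[2] else q_multi[2])
    }

    # assembled GTF: re-emitted detected knowns + all planted novels,
    # with fresh assembler-style ids
    k_ids <- ktx$transcript_id[detected]
    n_assembled <- length(k_ids) + nrow(planted_df)
    strg <- sprintf("STRG.%d", seq_len(n_assembled))
    origin <- c(k_ids, planted_df$transcript_id)
    truth_map <- stats::setNames(origin, paste0(strg, ".1"))
    known_ex <- exon_table(known)
    planted_exx <- exon_table(planted_ann)
    asm_rows <- list()
    for (k in seq_along(origin)) {
      oid <- origin[k]
      if (k <= length(k_ids)) {
        src <- known_ex[known_ex$transcript_id == oid, , drop = FALSE]
        expr_val <- known_expr[oid, s]
      } else {
        src <- planted_exx[planted_exx$transcript_id == oid, , drop = FALSE]
        expr_val <- planted_expr[oid, s]
      }
      asm_rows[[k]] <- data.frame(
        chrom = src$chrom, start = src$start, end = src$end,
        strand = src$strand, transcript_id = paste0(strg[k], ".1"),
        gene_id = strg[k], biotype = "assembled", expression = expr_val,
        source_sample = sid, stringsAsFactors = FALSE)
    }
    assembled <- annotation_set(do.call(rbind, asm_rows))

    # fragments ~ Poisson(expression x kb x rate), placed inside exons
    frag_rows <- list()
    atx <- assembled$tx
    aex <- exon_table(assembled)
    for (k in seq_len(nrow(atx))) {
      lam <- atx$expression[k] * atx$exonic_length[k] / 1000 * frag_rate
      nf <- stats::rpois(1L, lam)
      if (!nf) next
      exi <- aex[aex$transcript_id == atx$transcript_id[k], , drop = FALSE]
      wsel <- sample(nrow(exi), nf, replace = TRUE,
                     prob = exi$end - exi$start + 1L)
      fs <- exi$start[wsel] +
        floor(stats::runif(nf) * pmax(1L, exi$end[wsel] - exi$start[wsel] - 148L))
      fe <- pmin(fs + 149L, exi$end[wsel])
      frag_rows[[k]] <- data.frame(chrom = exi$chrom[1L], start = fs,
                                   end = fe, strand = atx$strand[k],
                                   sample_id = sid,
                                   stringsAsFactors = FALSE)
    }
    fragments <- if (length(frag_rows)) do.call(rbind, frag_rows) else
      data.frame(chrom = character(), start = integer(), end = integer(),
                 strand = character(), sample_id = character())
    rownames(fragments) <- NULL
    samples[[sid]] <- list(assembled = assembled, fragments = fragments,
                           truth_map = truth_map)
  }

  genome_dss <- Biostrings::DNAStringSet(vapply(genome, paste,
                                                collapse = "", ""))
  names(genome_dss) <- names(chrom_len)
  structure(list(
    params = list(genome_size = genome_size, n_samples = n_samples,
                  depth_factors = depth_factors,
                  expression_model = expression_model,
                  frag_rate = frag_rate, seed = seed),
    genome = genome_dss, known = known, repeats = repeats,
    planted = planted_df, planted_ann = planted_ann,
    known_expression = known_expr, planted_expression = planted_expr,
    samples = samples, seed = seed
  ), class = "SyntheticTruth")
}

#' @export
print.SyntheticTruth <- function(x, ...) {
  cat(sprintf(
    "SyntheticTruth: %d-bp genome, %d known transcripts, %d planted (%d should survive), %d samples\n",
    sum(Biostrings::width(x$genome)), n_transcripts(x$known),
    nrow(x$planted), sum(x$planted$should_survive), length(x$samples)))
  invisible(x)
}

#' Generate coding/noncoding training sequences
#'
#' Coding sequences are random backgrounds almost fully covered by a
#' planted codon-biased ORF; noncoding sequences are mononucleotide
#' shuffles of the coding set, which preserves base composition but
#' destroys the codon and hexamer structure — so the scorers must learn
#' the positional signal, not GC content.
#'
#' @param n_per_class sequences per class.
#' @param min_codons,max_codons ORF body size range.
#' @param seed integer seed.
#' @return list with character vectors `coding` and `noncoding`.
#' @export
synth_training_sequences <- function(n_per_class = 200L, min_codons = 80L,
                                     max_codons = 250L, seed = 1L) {
  set.seed(seed)
  favored <- c("GAG", "GCC", "AAG", "CTG", "GAC", "ATC", "GTG", "ACC",
               "CAG", "TTC", "AAC", "GGC", "TAC", "CGC", "AGC", "CCC")
  other_codons <- setdiff(
    apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                      c("A", "C", "G", "T")), 1, paste, collapse = ""),
    c("TAA", "TAG", "TGA", favored))
  coding <- vapply(seq_len(n_per_class), function(i) {
    nc <- sample(min_codons:max_codons, 1L)
    body <- sample(c(favored, other_codons), nc, replace = TRUE,
                   prob = c(rep(8, length(favored)),
                            rep(1, length(other_codons))))
    pad5 <- paste(sample(c("A", "C", "G", "T"), sample(10:60, 1L), TRUE),
                  collapse = "")
    pad3 <- paste(sample(c("A", "C", "G", "T"), sample(10:60, 1L), TRUE),
                  collapse = "")
    paste0(pad5, "ATG", paste(body, collapse = ""), "TAA", pad3)
  }, "")
  noncoding <- vapply(coding, function(s) {
    paste(sample(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, "", USE.NAMES = FALSE)
  list(coding = coding, noncoding = noncoding)
}

#' Write a synthetic fixture bundle to disk
#'
#' Emits the exact formats the pipeline consumes: `genome.fa`,
#' `known.gtf`, `repeats.bed`, per-sample `assembled_<s>.gtf` and
#' `fragments_<s>.tsv`, plus a machine-readable `truth.json` manifest with
#' record counts, the planted-novel table and per-sample truth maps.
#'
#' @param truth a [synth_generate()] result.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the manifest list.
#' @export
write_fixture_bundle <- function(truth, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir)
  }
  p <- function(f) file.path(out_dir, f)
  Biostrings::writeXStringSet(truth$genome, p("genome.fa"))
  write_gtf(truth$known, p("known.gtf"))
  write_bed(truth$repeats, p("repeats.bed"))
  files <- list(
    genome = list(file = "genome.fa",
                  n = length(truth$genome)),
    known = list(file = "known.gtf", n = n_transcripts(truth$known)),
    repeats = list(file = "repeats.bed",
                   n = length(truth$repeats$intervals))
  )
  for (sid in names(truth$samples)) {
    s <- truth$samples[[sid]]
    write_gtf(s$assembled, p(sprintf("assembled_%s.gtf", sid)))
    write_fragments(s$fragments, p(sprintf("fragments_%s.tsv", sid)))
    files[[paste0("assembled_", sid)]] <- list(
      file = sprintf("assembled_%s.gtf", sid),
      n = n_transcripts(s$assembled))
    files[[paste0("fragments_", sid)]] <- list(
      file = sprintf("fragments_%s.tsv", sid), n = nrow(s$fragments))
  }
  manifest <- list(
    seed = truth$seed,
    params = truth$params,
    files = files,
    planted = truth$planted,
    truth_maps = lapply(truth$samples, function(s) as.list(s$truth_map))
  )
  jsonlite::write_json(manifest, p("truth.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
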