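#' Coding-potential features and scorers
#'
#' Coding potential is assessed with two independent feature-based logistic
#' scorers whose calls are combined by union (sensitivity) or intersection
#' (specificity) at a configurable threshold. Scorer A uses
#' {ORF length, ORF coverage, Fickett statistic, hexamer usage bias};
#' scorer B uses a disjoint feature subset
#' {Fickett statistic, GC content, stop-codon density}, emulating the
#' complementarity of two independent coding-potential programs.
#' Both output P(noncoding) between 0 and 1.
#' @name coding-potential
NULL

# Classical position/composition lookup tables (TESTCODE-style): for each
# base, the asymmetry of its codon-position usage and its overall content
# are converted to coding probabilities via threshold lookup, then combined
# with per-base weights. Scores range from ~0.2 to ~1.1; higher = more
# coding-like.
.fickett <- list(
  position_prob = list(
    A = c(0.94, 0.68, 0.84, 0.93, 0.58, 0.68, 0.45, 0.34, 0.20, 0.22),
    C = c(0.80, 0.70, 0.70, 0.81, 0.66, 0.48, 0.51, 0.33, 0.30, 0.23),
    G = c(0.90, 0.88, 0.74, 0.64, 0.53, 0.48, 0.27, 0.16, 0.08, 0.08),
    T = c(0.97, 0.97, 0.91, 0.68, 0.69, 0.44, 0.54, 0.20, 0.09, 0.09)),
  position_weight = c(A = 0.26, C = 0.18, G = 0.31, T = 0.33),
  position_para = c(1.9, 1.8, 1.7, 1.6, 1.5, 1.4, 1.3, 1.2, 1.1, 0.0),
  content_prob = list(
    A = c(0.28, 0.49, 0.44, 0.55, 0.62, 0.49, 0.67, 0.65, 0.81, 0.21),
    C = c(0.82, 0.64, 0.51, 0.64, 0.59, 0.59, 0.43, 0.44, 0.39, 0.31),
    G = c(0.40, 0.54, 0.47, 0.64, 0.64, 0.73, 0.41, 0.41, 0.33, 0.29),
    T = c(0.28, 0.24, 0.39, 0.40, 0.55, 0.75, 0.56, 0.69, 0.51, 0.58)),
  content_weight = c(A = 0.11, C = 0.12, G = 0.15, T = 0.14),
  content_para = c(0.33, 0.31, 0.29, 0.27, 0.25, 0.23, 0.21, 0.19, 0.17, 0.0)
)

.fickett_lookup <- function(value, para, prob) {
  i <- which(value >= para)[1L]
  if (is.na(i)) i <- length(prob)
  prob[i]
}

#' Fickett position/composition statistic
#'
#' The classical nucleotide statistic discriminating coding from noncoding
#' sequence: for each base, the asymmetry of its usage across the three
#' codon positions and its overall content are mapped through published
#' lookup tables and combined with per-base weights.
#' @param seq a character string over `{A, C, G, T, N}`.
#' @return the Fickett score (roughly 0.2–1.35; higher = more coding-like).
#' @export
fickett_score <- function(seq) {
  seq <- toupper(seq)
  if (!nchar(seq)) stop("empty sequence")
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(chars)
  score <- 0
  for (base in c("A", "C", "G", "T")) {
    hits <- chars == base
    pos_counts <- vapply(0:2, function(p) {
      sum(hits[seq.int(p + 1L, n, by = 3L)])
    }, numeric(1))
    pos_value <- max(pos_counts) / (min(pos_counts) + 1)
    content <- sum(hits) / n
    score <- score +
      .fickett_lookup(pos_value, .fickett$position_para,
                      .fickett$position_prob[[base]]) *
        .fickett$position_weight[[base]] +
      .fickett_lookup(content, .fickett$content_para,
                      .fickett$content_prob[[base]]) *
        .fickett$content_weight[[base]]
  }
  unname(score)
}

#' Longest open reading frame
#'
#' Searches the three forward frames of the sense sequence for the longest
#' ATG-to-stop span (stop codon included in the length). ORFs without an
#' in-frame stop codon are not counted.
#' @param seq a character string over `{A, C, G, T, N}`.
#' @return a list: `length` (nt; 0 if none), `start`, `end` (1-based
#'   positions in `seq`, NA if none).
#' @export
longest_orf <- function(seq) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (!n) stop("empty sequence")
  best <- list(length = 0L, start = NA_integer_, end = NA_integer_)
  stops <- c("TAA", "TAG", "TGA")
  for (frame in 0:2) {
    ncod <- (n - frame) %/% 3L
    if (ncod < 2L) next
    starts <- frame + 1L + 3L * (seq_len(ncod) - 1L)
    codons <- substring(seq, starts, starts + 2L)
    is_start <- codons == "ATG"
    is_stop <- codons %in% stops
    open_from <- NA_integer_
    for (i in seq_len(ncod)) {
      if (is.na(open_from) && is_start[i]) open_from <- i
      if (!is.na(open_from) && is_stop[i]) {
        len <- (i - open_from + 1L) * 3L
        if (len > best$length) {
          best <- list(length = len, start = starts[open_from],
                       end = starts[i] + 2L)
        }
        open_from <- NA_integer_
      }
    }
  }
  best
}

#' Build a hexamer usage table
#'
#' Estimates in-frame hexamer frequencies from coding and noncoding
#' training sequences (sliding window, step 3, frame 0) and stores the
#' log-ratio `log((f_coding + eps) / (f_noncoding + eps))` per hexamer.
#' @param coding_seqs,noncoding_seqs character vectors of training
#'   sequences.
#' @param eps pseudo-frequency guarding empty cells.
#' @return named numeric vector of log-ratios over all 4096 hexamers.
#' @export
build_hexamer_table <- function(coding_seqs, noncoding_seqs, eps = 1e-6) {
  count_class <- function(seqs) {
    tab <- integer(0)
    for (s in seqs) {
      h <- inframe_hexamers(s)
      if (length(h)) {
        t1 <- table(h)
        tab <- c(tab, t1)
      }
    }
    tapply(as.integer(tab), names(tab), sum)
  }
  fc <- count_class(coding_seqs)
  fn <- count_class(noncoding_seqs)
  all_h <- sort(unique(c(names(fc), names(fn))))
  get_freq <- function(counts) {
    v <- rep(0, length(all_h)); names(v) <- all_h
    v[names(counts)] <- as.numeric(counts)
    v / max(sum(v), 1)
  }
  log((get_freq(fc) + eps) / (get_freq(fn) + eps))
}

inframe_hexamers <- function(seq) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n < 6L) return(character(0))
  starts <- seq.int(1L, n - 5L, by = 3L)
  h <- substring(seq, starts, starts + 5L)
  h[!grepl("[^ACGT]", h)]
}

#' Extract coding-potential features from a transcript sequence
#'
#' Computes the full feature set both scorers draw on: longest forward-frame
#' ORF length and coverage, Fickett statistic, hexamer usage bias (mean
#' log-ratio over the in-frame hexamers of the longest ORF, or of the whole
#' sequence in frame 0 when there is no ORF), GC content, and stop-codon
#' density (stop codons per codon scanned across the three forward frames).
#'
#' @param seq a character string over `{A, C, G, T, N}` — the transcript's
#'   sense strand.
#' @param hexamer_table a [build_hexamer_table()] result, or `NULL`
#'   (hexamer bias reported as 0).
#' @return a one-row `data.frame` of features.
#' @export
extract_features <- function(seq, hexamer_table = NULL) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (!n) stop("empty sequence")
  orf <- longest_orf(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  gc <- sum(chars %in% c("G", "C")) / n

  stops <- c("TAA", "TAG", "TGA")
  stop_n <- 0L; cod_n <- 0L
  for (frame in 0:2) {
    ncod <- (n - frame) %/% 3L
    if (ncod < 1L) next
    starts <- frame + 1L + 3L * (seq_len(ncod) - 1L)
    codons <- substring(seq, starts, starts + 2L)
    stop_n <- stop_n + sum(codons %in% stops)
    cod_n <- cod_n + ncod
  }

  hex_seq <- if (orf$length > 0L) substr(seq, orf$start, orf$end) else seq
  hb <- 0
  if (!is.null(hexamer_table)) {
    h <- inframe_hexamers(hex_seq)
    h <- h[h %in% names(hexamer_table)]
    if (length(h)) hb <- mean(hexamer_table[h])
  }

  data.frame(
    longest_orf_length_nt = orf$length,
    orf_coverage = orf$length / n,
    fickett_score = fickett_score(seq),
    hexamer_bias = hb,
    gc_content = gc,
    stop_codon_density = if (cod_n) stop_n / cod_n else 0
  )
}

feature_matrix <- function(seqs, hexamer_table, features) {
  df <- do.call(rbind, lapply(seqs, extract_features, hexamer_table = hexamer_table))
  df$log_orf_length <- log1p(df$longest_orf_length_nt)
  as.matrix(df[, features, drop = FALSE])
}

#' Train a logistic noncoding-probability scorer
#'
#' Fits a logistic regression of class (noncoding = 1) on the selected
#' features and returns a scorer whose [predict_noncoding()] output is the
#' calibrated probability that a sequence is noncoding. Training is
#' deterministic given the seed. Scorer A (`features = "orf"`) uses
#' ORF length, ORF coverage, Fickett and hexamer bias and trains its own
#' hexamer table from the input; scorer B (`features = "composition"`)
#' uses Fickett, GC content and stop-codon density only.
#'
#' @param coding_seqs,noncoding_seqs character vectors, at least 50 per
#'   class.
#' @param features `"orf"` or `"composition"`, or an explicit character
#'   vector of feature names.
#' @param seed integer seed (reserved for stochastic extensions; the
#'   logistic fit itself is deterministic).
#' @return a `NoncodingScorer` with elements `model` (glm coefficients),
#'   `features`, `hexamer_table` and `train_auc`.
#' @export
train_scorer <- function(coding_seqs, noncoding_seqs,
                         features = c("orf", "composition"), seed = 1L) {
  if (length(features) == 1L && features %in% c("orf", "composition")) {
    features <- switch(features,
      orf = c("log_orf_length", "orf_coverage", "fickett_score", "hexamer_bias"),
      composition = c("fickett_score", "gc_content", "stop_codon_density"))
  }
  if (!length(coding_seqs) || !length(noncoding_seqs)) {
    stop("both coding and noncoding training sequences are required")
  }
  set.seed(seed)
  hex <- if ("hexamer_bias" %in% features) {
    build_hexamer_table(coding_seqs, noncoding_seqs)
  } else NULL
  x <- feature_matrix(c(coding_seqs, noncoding_seqs), hex, features)
  y <- c(rep(0L, length(coding_seqs)), rep(1L, length(noncoding_seqs)))
  dat <- data.frame(y = y, x)
  fit <- suppressWarnings(stats::glm(y ~ ., data = dat,
                                     family = stats::binomial()))
  p <- stats::predict(fit, type = "response")
  auc <- rank_auc(p, y)
  structure(list(coefficients = stats::coef(fit), features = features,
                 hexamer_table = hex, train_auc = auc),
            class = "NoncodingScorer")
}

# Mann-Whitney AUC of scores for the positive class
rank_auc <- function(score, label) {
  r <- rank(score)
  n1 <- sum(label == 1); n0 <- sum(label == 0)
  if (!n1 || !n0) return(NA_real_)
  (sum(r[label == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @export
print.NoncodingScorer <- function(x, ...) {
  cat("NoncodingScorer on {", paste(x$features, collapse = ", "),
      sprintf("}, training AUC %.3f\n", x$train_auc))
  invisible(x)
}

#' Predict noncoding probabilities
#' @param scorer a [train_scorer()] result.
#' @param seqs character vector of transcript sense-strand sequences.
#' @return numeric vector of P(noncoding) in `[0, 1]`.
#' @export
predict_noncoding <- function(scorer, seqs) {
  if (!length(seqs)) return(numeric(0))
  x <- feature_matrix(seqs, scorer$hexamer_table, scorer$features)
  beta <- scorer$coefficients
  beta[is.na(beta)] <- 0
  eta <- beta[1] + x %*% beta[colnames(x)]
  stats::plogis(as.numeric(eta))
}

#' Combine two noncoding calls
#'
#' Union mode calls a transcript noncoding when either scorer exceeds the
#' threshold (sensitivity); intersection mode requires both (specificity).
#' The comparison is strictly greater-than. Missing scores count as 0
#' (that scorer fails the transcript).
#'
#' @param score_a,score_b noncoding probabilities in `[0, 1]`.
#' @param threshold cutoff in `[0.5, 1]`; default 0.9.
#' @param mode `"union"` or `"intersection"`.
#' @return logical vector: is the transcript called noncoding.
#' @export
combine_calls <- function(score_a, score_b, threshold = 0.9,
                          mode = c("union", "intersection")) {
  mode <- match.arg(mode)
  if (threshold < 0.5 || threshold > 1) {
    stop("threshold must be in [0.5, 1]")
  }
  score_a[is.na(score_a)] <- 0
  score_b[is.na(score_b)] <- 0
  stopifnot(all(score_a >= 0 & score_a <= 1),
            all(score_b >= 0 & score_b <= 1))
  if (mode == "union") score_a > threshold | score_b > threshold
  else score_a > threshold & score_b > threshold
}

#' Spliced transcript sequences from a genome
#'
#' Concatenates each transcript's exon sequences in genomic order and
#' reverse-complements the result for minus-strand transcripts, yielding
#' the sense-strand sequence. Unstranded transcripts are returned in the
#' plus orientation (callers score both orientations).
#' @param ann an `AnnotationSet`.
#' @param genome a [Biostrings::DNAStringSet] or FASTA path.
#' @return named character vector of sequences keyed by transcript id.
#' @export
spliced_sequences <- function(ann, genome) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  tx <- ann$tx
  missing_chr <- setdiff(unique(tx$chrom), names(genome))
  if (length(missing_chr)) {
    stop("chromosome(s) missing from genome FASTA: ",
         paste(missing_chr, collapse = ", "), "; affected transcripts: ",
         paste(utils::head(tx$transcript_id[tx$chrom %in% missing_chr], 5L),
               collapse = ", "))
  }
  ex <- exon_table(ann)
  out <- character(nrow(tx))
  names(out) <- tx$transcript_id
  for (i in seq_len(nrow(tx))) {
    exi <- ex[ex$transcript_id == tx$transcript_id[i], , drop = FALSE]
    exi <- exi[order(exi$start), , drop = FALSE]
    parts <- Biostrings::extractAt(
      genome[[tx$chrom[i]]], IRanges::IRanges(exi$start, exi$end))
    s <- as.character(Biostrings::DNAString(paste(as.character(parts), collapse = "")))
    if (tx$strand[i] == "-") {
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    }
    out[i] <- s
  }
  out
}

#' Score candidates for coding potential
#'
#' Scores each candidate's spliced sequence with both scorers, combines the
#' calls, and finalizes the candidate ledger: candidates called noncoding
#' get status `PASSED`, the rest `FILTERED`, with a `"coding_potential"`
#' trace entry recording both scores. Candidates already `FILTERED` by the
#' cascade keep that status (the scores are still recorded for reporting).
#' Unstranded candidates are scored in both orientations and the minimum
#' noncoding probability per scorer is used (conservative: a strong ORF on
#' either strand counts against the candidate).
#'
#' @param cands a `CandidateSet`.
#' @param genome a [Biostrings::DNAStringSet] or FASTA path.
#' @param scorer_a,scorer_b [train_scorer()] results.
#' @param threshold noncoding-probability cutoff (strict `>`), default 0.9.
#' @param mode `"union"` or `"intersection"`.
#' @return the `CandidateSet` with scores, trace and final statuses.
#' @export
score_candidates <- function(cands, genome, scorer_a, scorer_b,
                             threshold = 0.9,
                             mode = c("union", "intersection")) {
  mode <- match.arg(mode)
  tx <- cands$ann$tx
  if (!nrow(tx)) return(cands)
  seqs <- spliced_sequences(cands$ann, genome)
  sa <- predict_noncoding(scorer_a, seqs)
  sb <- predict_noncoding(scorer_b, seqs)
  unstranded <- tx$strand == "."
  if (any(unstranded)) {
    rc <- vapply(seqs[unstranded], function(s) {
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    }, "")
    sa[unstranded] <- pmin(sa[unstranded], predict_noncoding(scorer_a, rc))
    sb[unstranded] <- pmin(sb[unstranded], predict_noncoding(scorer_b, rc))
  }
  call <- combine_calls(sa, sb, threshold, mode)
  cands$scores <- data.frame(transcript_id = tx$transcript_id,
                             score_a = sa, score_b = sb, noncoding = call,
                             stringsAsFactors = FALSE)
  cands <- append_trace(cands, tx$transcript_id, "coding_potential", call,
                        sprintf("P(noncoding) A=%.3f B=%.3f, %s at >%.2f",
                                sa, sb, mode, threshold))
  pending <- cands$status[tx$transcript_id] == "PENDING"
  cands$status[tx$transcript_id[pending & call]] <- "PASSED"
  cands$status[tx$transcript_id[pending & !call]] <- "FILTERED"
  cands
}
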