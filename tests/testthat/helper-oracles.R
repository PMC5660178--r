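# Independent brute-force oracles. These deliberately avoid the package's
# interval machinery (GenomicRanges indexes) and recompute every quantity
# by direct per-base or all-pairs scans.

# per-base overlap of two exon tables on one chromosome, optional strand rule
bases_of <- function(ex_df) {
  unlist(lapply(seq_len(nrow(ex_df)), function(i) {
    ex_df$start[i]:ex_df$end[i]
  }))
}

# brute-force classification of one transcript against a reference
oracle_classify <- function(tx_exons, tx_strand, known, mode,
                            overlap_level = "span") {
  ktx <- tx_table(known)
  kex <- exon_table(known)
  chrom <- tx_exons$chrom[1]
  # structure-level KNOWN: single-exon contained in a known single-exon
  # span on the same strand (intron-chain identity is checked separately)
  if (nrow(tx_exons) == 1L) {
    contained <- ktx$chrom == chrom & ktx$n_exons == 1L &
      (ktx$strand == tx_strand | ktx$strand == "." | tx_strand == ".") &
      ktx$start <= tx_exons$start[1] & ktx$end >= tx_exons$end[1]
    if (any(contained)) return("KNOWN")
  }
  if (!chrom %in% ktx$chrom) return("LINCRNA")
  cand_bases <- if (overlap_level == "span") {
    min(tx_exons$start):max(tx_exons$end)
  } else bases_of(tx_exons)
  hit_strands <- character(0)
  for (i in seq_len(nrow(ktx))) {
    if (ktx$chrom[i] != chrom) next
    k_bases <- if (overlap_level == "span") {
      ktx$start[i]:ktx$end[i]
    } else bases_of(kex[kex$transcript_id == ktx$transcript_id[i], ])
    if (length(intersect(cand_bases, k_bases))) {
      hit_strands <- c(hit_strands, ktx$strand[i])
    }
  }
  if (!length(hit_strands)) return("LINCRNA")
  if (mode == "unstranded") return("REJECTED_SENSE_OVERLAP")
  same <- hit_strands == tx_strand | hit_strands == "." | tx_strand == "."
  if (any(same)) "REJECTED_SENSE_OVERLAP" else "OVERLAP_ANTISENSE"
}

# brute-force repeat-overlap fraction of one transcript
oracle_repeat_fraction <- function(ex_df, repeats) {
  rg <- repeats$intervals
  rep_bases <- unlist(lapply(seq_along(rg), function(i) {
    if (as.character(GenomicRanges::seqnames(rg))[i] != ex_df$chrom[1]) {
      return(integer(0))
    }
    GenomicRanges::start(rg)[i]:GenomicRanges::end(rg)[i]
  }))
  ex_bases <- bases_of(ex_df)
  length(intersect(ex_bases, unique(rep_bases))) / length(ex_bases)
}

# brute-force fragment assignment against gene exon unions
oracle_assign <- function(frag, features, mode) {
  tx <- tx_table(features)
  ex <- exon_table(features)
  ex$gene_id <- tx$gene_id[match(ex$transcript_id, tx$transcript_id)]
  hit_genes <- character(0)
  for (g in unique(ex$gene_id)) {
    exg <- ex[ex$gene_id == g & ex$chrom == frag$chrom, , drop = FALSE]
    if (!nrow(exg)) next
    g_strand <- tx$strand[tx$gene_id == g][1]
    if (mode == "stranded" && frag$strand != "." && g_strand != "." &&
        frag$strand != g_strand) next
    if (length(intersect(frag$start:frag$end, bases_of(exg)))) {
      hit_genes <- c(hit_genes, g)
    }
  }
  if (length(hit_genes) == 1L) hit_genes else
    if (length(hit_genes) > 1L) "AMBIGUOUS" else "UNASSIGNED"
}

# brute-force nearest coding gene by all-pairs minimization
oracle_nearest <- function(lnc_row, known) {
  ktx <- tx_table(known)
  cod <- ktx[ktx$biotype == "protein_coding", , drop = FALSE]
  genes <- do.call(rbind, lapply(split(cod, cod$gene_id), function(g) {
    data.frame(gene_id = g$gene_id[1], chrom = g$chrom[1],
               start = min(g$start), end = max(g$end),
               strand = g$strand[1])
  }))
  genes <- genes[genes$chrom == lnc_row$chrom, , drop = FALSE]
  if (!nrow(genes)) return(NULL)
  ltss <- if (lnc_row$strand == "-") lnc_row$end else lnc_row$start
  gtss <- ifelse(genes$strand == "-", genes$end, genes$start)
  d <- gtss - ltss
  ov <- genes$start <= lnc_row$end & genes$end >= lnc_row$start
  d[ov] <- 0
  ord <- order(abs(d), genes$gene_id)
  list(gene_id = genes$gene_id[ord[1]], distance = d[ord[1]])
}

# brute-force longest ATG..stop ORF by full enumeration
oracle_longest_orf <- function(seq) {
  n <- nchar(seq)
  best <- 0L
  stops <- c("TAA", "TAG", "TGA")
  for (i in seq_len(max(0L, n - 5L))) {
    if (substr(seq, i, i + 2L) != "ATG") next
    j <- i + 3L
    while (j + 2L <= n) {
      if (substr(seq, j, j + 2L) %in% stops) {
        best <- max(best, j + 2L - i + 1L)
        break
      }
      j <- j + 3L
    }
  }
  best
}

# brute-force fraction of a transcript's exonic bases covered by another's
oracle_exonic_overlap <- function(ex_a, ex_b) {
  if (ex_a$chrom[1] != ex_b$chrom[1]) return(0)
  length(intersect(bases_of(ex_a), bases_of(ex_b))) / length(bases_of(ex_a))
}

random_exons <- function(chrom, max_pos, n_exons, exon_len, gap_len,
                         strand = sample(c("+", "-"), 1)) {
  start <- sample(seq_len(max_pos), 1)
  starts <- start + cumsum(c(0, rep(exon_len + gap_len, n_exons - 1)))
  data.frame(chrom = chrom, start = as.integer(starts),
             end = as.integer(starts + exon_len - 1L), strand = strand)
}
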