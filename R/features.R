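# Native per-variant feature extractors: splice-site geometry, sequence
# context, codon usage, translation efficiency, and motif-based splicing
# features. Missing values are returned as NA and zero-imputed downstream.

#' Distance to the nearest splice site (DSP)
#'
#' Distance in nucleotides from the variant to the nearest splice site of its
#' hosting exon; a variant on the boundary base scores 0. Exon ends at the
#' transcript terminus (the 5' end of the first exon, the 3' end of the last)
#' are not splice sites and are excluded while an internal boundary exists.
#'
#' @param ctx A `"coding_context"` from [project_variant()].
#' @param tx The hosting `"transcript"`.
#' @return Integer distance, or `NA` for a single-exon transcript.
#' @export
dsp <- function(ctx, tx) {
  ex <- tx$exons
  n <- nrow(ex)
  if (n == 1L) return(NA_integer_)
  gi <- if (tx$strand == "+") ctx$exon_index + 1L else n - ctx$exon_index
  pos <- ctx$variant$pos
  d <- c(pos - ex$start[gi], ex$end[gi] - pos)
  internal <- c(gi > 1L, gi < n)   # genomic-left / genomic-right boundary
  min(d[internal])
}

#' Minimum splice distance as a proportion of half the exon (MDE)
#'
#' [dsp()] divided by half the hosting exon's length; lies in \[0, 1\] for
#' interior positions of internal exons.
#' @inheritParams dsp
#' @return Numeric, or `NA` when DSP is undefined.
#' @export
mde <- function(ctx, tx) {
  d <- dsp(ctx, tx)
  if (is.na(d)) return(NA_real_)
  d / (ctx$exon_len / 2)
}

#' Position of the variant across its exon (DVE)
#'
#' The 0-based offset of the variant from the exon's 5' end in transcript
#' orientation, divided by `exon_len - 1`; 0 at the 5'-most base, 1 at the
#' 3'-most. A length-1 exon yields 0.
#' @inheritParams dsp
#' @return Numeric in \[0, 1\].
#' @export
dve <- function(ctx, tx) {
  ex <- tx$exons
  gi <- if (tx$strand == "+") ctx$exon_index + 1L else nrow(ex) - ctx$exon_index
  pos <- ctx$variant$pos
  offset <- if (tx$strand == "+") pos - ex$start[gi] else ex$end[gi] - pos
  if (ctx$exon_len == 1L) return(0)
  offset / (ctx$exon_len - 1L)
}

#' CpG dinucleotide context
#'
#' TRUE iff the reference dinucleotide containing the variant position — either
#' `[pos-1, pos]` or `[pos, pos+1]` on the genome's plus strand — is CG. At a
#' contig edge only the existing neighbour is examined.
#'
#' @param ctx A `"coding_context"`.
#' @param genome A `"genome_seq"`.
#' @return Logical scalar.
#' @export
cpg_context <- function(ctx, genome) {
  seq <- genome[[ctx$variant$contig]]
  pos <- ctx$variant$pos
  left <- if (pos > 1L) substring(seq, pos - 1L, pos) else ""
  right <- if (pos < nchar(seq)) substring(seq, pos, pos + 1L) else ""
  left == "CG" || right == "CG"
}

#' Relative position within the coding sequence
#'
#' `cds_pos / CDS length`, in (0, 1]: how far along the mRNA coding region the
#' variant falls.
#' @inheritParams dsp
#' @return Numeric in (0, 1].
#' @export
relative_mrna_position <- function(ctx, tx) {
  ctx$cds_pos / cds_length(tx)
}

#' Variant-induced change in RSCU
#'
#' `RSCU(alt codon) - RSCU(ref codon)`; antisymmetric under exchanging the
#' alleles. Defined for synonymous contexts only.
#'
#' @param ctx A `"coding_context"` (must be synonymous).
#' @param rscu Named codon -> RSCU vector from [rscu_table()].
#' @return Numeric.
#' @export
delta_rscu <- function(ctx, rscu) {
  if (!is_synonymous(ctx)) {
    stop("delta RSCU is defined for synonymous variants only")
  }
  unname(rscu[ctx$alt_codon] - rscu[ctx$ref_codon])
}

#' Translation-efficiency feature (log tRNA adaptation weight)
#'
#' The natural log of the tRNA adaptation weight of the variant (alternate)
#' codon; with `delta = TRUE`, the log-ratio
#' `ln w(alt) - ln w(ref)` is returned instead. Weights come from
#' [tai_weights()] and are strictly positive, so the log is always finite.
#'
#' @param ctx A `"coding_context"`.
#' @param weights Named codon -> weight vector from [tai_weights()].
#' @param delta Return the alt-vs-ref log-ratio instead of the alt log-weight.
#' @return Numeric.
#' @export
te_feature <- function(ctx, weights, delta = FALSE) {
  v <- log(unname(weights[ctx$alt_codon]))
  if (delta) v <- v - log(unname(weights[ctx$ref_codon]))
  v
}

# Coding-strand sequence around the variant: flank nt each side, clipped at
# contig bounds. Returns the string plus the variant's 1-based offset in it
# and the coding-strand ref/alt bases.
variant_context_seq <- function(ctx, tx, genome, flank) {
  seq <- genome[[tx$contig]]
  pos <- ctx$variant$pos
  lo <- max(1L, pos - flank)
  hi <- min(nchar(seq), pos + flank)
  s <- substring(seq, lo, hi)
  off <- pos - lo + 1L
  ref <- ctx$variant$ref
  alt <- ctx$variant$alt
  if (tx$strand == "-") {
    s <- revcomp(s)
    off <- nchar(s) - off + 1L
    ref <- comp_base(ref)
    alt <- comp_base(alt)
  }
  list(seq = s, offset = off, ref = ref, alt = alt)
}

score_pwm_window <- function(mat, window) {
  ri <- match(strsplit(window, "")[[1L]], c("A", "C", "G", "T"))
  if (anyNA(ri)) return(NA_real_)
  sum(mat[cbind(ri, seq_along(ri))])
}

#' Maximum splice-site score over variant-overlapping windows (MES)
#'
#' Slides both the donor and the acceptor log-odds matrix over every window on
#' the coding strand that overlaps the variant position, scoring each window
#' as the sum of per-column log-odds, and returns the maximum over all windows
#' and both matrices. With `use_alt = TRUE` the alternate base is substituted
#' at the variant position before scoring, so the ref/alt difference measures
#' splice-site creation or destruction.
#'
#' @param ctx A `"coding_context"`.
#' @param tx The hosting `"transcript"`.
#' @param genome A `"genome_seq"`.
#' @param model A `"splice_model"`.
#' @param use_alt Score the alternate allele sequence instead of the reference.
#' @return Numeric maximum score, or `NA` if no complete window exists.
#' @export
max_splice_site_score <- function(ctx, tx, genome, model = default_splice_model(),
                                  use_alt = FALSE) {
  wmax <- max(ncol(model$donor), ncol(model$acceptor))
  sc <- variant_context_seq(ctx, tx, genome, flank = wmax - 1L)
  s <- sc$seq
  if (use_alt) substring(s, sc$offset, sc$offset) <- sc$alt
  best <- -Inf
  for (mat in list(model$donor, model$acceptor)) {
    w <- ncol(mat)
    first <- max(1L, sc$offset - w + 1L)
    last <- min(nchar(s) - w + 1L, sc$offset)
    if (first > last) next
    for (st in first:last) {
      v <- score_pwm_window(mat, substring(s, st, st + w - 1L))
      if (!is.na(v) && v > best) best <- v
    }
  }
  if (is.infinite(best)) NA_real_ else best
}

count_motif_hits <- function(window, motifs) {
  n <- nchar(window)
  if (motifs$kind == "hexamer-list") {
    if (n < 6L) return(0L)
    starts <- 1:(n - 5L)
    sum(substring(window, starts, starts + 5L) %in% motifs$hexamers)
  } else {
    total <- 0L
    for (p in motifs$pwms) {
      w <- ncol(p$mat)
      if (n < w) next
      for (st in 1:(n - w + 1L)) {
        v <- score_pwm_window(p$mat, substring(window, st, st + w - 1L))
        if (!is.na(v) && v >= p$threshold) total <- total + 1L
      }
    }
    total
  }
}

#' Density of splicing-enhancer hexamers in an exon
#'
#' The fraction of length-6 windows of the exon sequence that belong to the
#' hexamer set: `hits / (len - 5)`. Sequences shorter than 6 nt score 0.
#'
#' @param exon_seq Exon sequence (coding strand).
#' @param motifs A hexamer-list `"motif_set"`.
#' @return Numeric density in \[0, 1\].
#' @export
ese_density <- function(exon_seq, motifs) {
  stopifnot(motifs$kind == "hexamer-list")
  n <- nchar(exon_seq)
  if (n < 6L) return(0)
  count_motif_hits(exon_seq, motifs) / (n - 5L)
}

#' Motif hits gained and lost by a variant
#'
#' Counts motif matches (hexamer membership, or PWM score at or above its
#' threshold) in the reference and alternate windows;
#' `lost = max(hits_ref - hits_alt, 0)` and
#' `gained = max(hits_alt - hits_ref, 0)`.
#'
#' @param ref_window,alt_window Equal-length sequences differing at most at
#'   one position.
#' @param motifs A `"motif_set"`.
#' @return Named integer vector `c(gained =, lost =)`.
#' @export
motif_gain_loss <- function(ref_window, alt_window, motifs) {
  if (nchar(ref_window) != nchar(alt_window)) {
    stop("ref and alt windows differ in length")
  }
  hr <- count_motif_hits(ref_window, motifs)
  ha <- count_motif_hits(alt_window, motifs)
  c(gained = max(ha - hr, 0L), lost = max(hr - ha, 0L))
}

#' Reference and alternate sequence windows around a variant
#'
#' An 11-nt window (5 nt each side by default) centred on the variant on the
#' coding strand, truncated at the hosting exon's boundaries, so every hexamer
#' overlapping the variant within the exon is covered.
#'
#' @inheritParams max_splice_site_score
#' @param flank Flank width in nt on each side.
#' @return List with `ref` and `alt` window strings.
#' @export
variant_windows <- function(ctx, tx, genome, flank = 5L) {
  ex <- tx$exons
  gi <- if (tx$strand == "+") ctx$exon_index + 1L else nrow(ex) - ctx$exon_index
  pos <- ctx$variant$pos
  lo <- max(ex$start[gi], pos - flank)
  hi <- min(ex$end[gi], pos + flank)
  s <- substring(genome[[tx$contig]], lo, hi)
  off <- pos - lo + 1L
  ref <- ctx$variant$ref; alt <- ctx$variant$alt
  if (tx$strand == "-") {
    s <- revcomp(s)
    off <- nchar(s) - off + 1L
    ref <- comp_base(ref); alt <- comp_base(alt)
  }
  stopifnot(substring(s, off, off) == ref)
  a <- s
  substring(a, off, off) <- alt
  list(ref = s, alt = a)
}

# Full hosting-exon sequence on the coding strand.
exon_sequence <- function(ctx, tx, genome) {
  ex <- tx$exons
  gi <- if (tx$strand == "+") ctx$exon_index + 1L else nrow(ex) - ctx$exon_index
  s <- substring(genome[[tx$contig]], ex$start[gi], ex$end[gi])
  if (tx$strand == "-") s <- revcomp(s)
  s
}
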