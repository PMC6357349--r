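# Reference I/O, transcript models, and projection of variants into codon space.
# Coordinates are 1-based closed throughout (the IRanges convention); BED input,
# which is 0-based half-open, is converted at parse time.

#' Read a reference genome from FASTA
#'
#' @param path Path to a FASTA file.
#' @return A named character vector of uppercase DNA sequences, one element per
#'   contig, with class `"genome_seq"`. Contig order follows the file.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">c1", "acgt"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  seqs <- tryCatch(Biostrings::readDNAStringSet(path),
                   error = function(e) stop("malformed FASTA '", path, "': ",
                                            conditionMessage(e)))
  nm <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(nm)) {
    stop("duplicate contig name(s) in FASTA: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  out <- toupper(as.character(seqs))
  names(out) <- nm
  bad <- grepl("[^ACGTN]", out)
  if (any(bad)) {
    stop("contig(s) with bases outside {A,C,G,T,N}: ",
         paste(nm[bad], collapse = ", "))
  }
  structure(out, class = "genome_seq")
}

#' Construct a transcript model
#'
#' A strand-aware gene model: ordered exons plus a CDS span. Used to project
#' variants into coding coordinates and to measure splice-site geometry.
#'
#' @param id,gene Transcript and gene identifiers.
#' @param contig Contig name.
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column data.frame (`start`, `end`), 1-based inclusive
#'   genomic intervals; reordered to ascending genomic start.
#' @param cds_start,cds_end Genomic CDS bounds (`cds_start <= cds_end`
#'   regardless of strand).
#' @return An object of class `"transcript"`.
#' @export
transcript <- function(id, gene, contig, strand, exons, cds_start, cds_end) {
  stopifnot(strand %in% c("+", "-"), is.data.frame(exons),
            all(c("start", "end") %in% names(exons)))
  exons <- exons[order(exons$start), c("start", "end"), drop = FALSE]
  rownames(exons) <- NULL
  if (any(exons$end < exons$start)) stop("exon with end < start in ", id)
  if (nrow(exons) > 1L &&
      any(exons$start[-1L] <= exons$end[-nrow(exons)])) {
    stop("overlapping exons in transcript ", id)
  }
  tx <- structure(list(id = id, gene = gene, contig = contig, strand = strand,
                       exons = exons, cds_start = cds_start, cds_end = cds_end),
                  class = "transcript")
  cds <- cds_intervals(tx)
  if (nrow(cds) == 0L) stop("CDS span outside exons in transcript ", id)
  covered <- sum(cds$end - cds$start + 1L)
  # CDS bounds must themselves fall in exons
  in_exon <- function(p) any(p >= exons$start & p <= exons$end)
  if (!in_exon(cds_start) || !in_exon(cds_end)) {
    stop("CDS boundary outside exon union in transcript ", id)
  }
  if (covered %% 3L != 0L) {
    stop("CDS length ", covered, " not divisible by 3 in transcript ", id)
  }
  tx
}

#' @export
print.transcript <- function(x, ...) {
  cat(sprintf("<transcript %s (%s) %s:%s %d exon(s), CDS %d..%d (%d nt)>\n",
              x$id, x$gene, x$contig, x$strand, nrow(x$exons),
              x$cds_start, x$cds_end, cds_length(x)))
  invisible(x)
}

# Exon intervals clipped to the CDS span, ascending genomic order.
cds_intervals <- function(tx) {
  s <- pmax(tx$exons$start, tx$cds_start)
  e <- pmin(tx$exons$end, tx$cds_end)
  keep <- s <= e
  data.frame(start = s[keep], end = e[keep])
}

cds_length <- function(tx) {
  iv <- cds_intervals(tx)
  sum(iv$end - iv$start + 1L)
}

# Contiguous CDS sequence on the coding strand.
cds_sequence <- function(tx, genome) {
  iv <- cds_intervals(tx)
  seq <- genome[[tx$contig]]
  parts <- substring(seq, iv$start, iv$end)
  s <- paste(parts, collapse = "")
  if (tx$strand == "-") s <- revcomp(s)
  s
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

comp_base <- function(b) c(A = "T", C = "G", G = "C", T = "A", N = "N")[[b]]

#' Read transcript models from a GTF/GFF file
#'
#' Builds one [transcript()] per `transcript_id` from its `exon` and `CDS`
#' rows. Transcripts whose CDS length is not a multiple of three are skipped
#' with a warning (truncated or non-standard models).
#'
#' @param path Path to a GTF/GFF2 file with `exon` and `CDS` features carrying
#'   `transcript_id` and `gene_id` attributes.
#' @return A named list of `"transcript"` objects.
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) stop("GTF file not found: ", path)
  gr <- rtracklayer::import(path, format = "gtf")
  meta <- S4Vectors::mcols(gr)
  if (is.null(meta$transcript_id) || anyNA(meta$transcript_id)) {
    stop("GTF rows without a transcript_id attribute in ", path)
  }
  keep <- meta$type %in% c("exon", "CDS")
  gr <- gr[keep]
  meta <- S4Vectors::mcols(gr)
  out <- list()
  for (txid in unique(meta$transcript_id)) {
    sel <- meta$transcript_id == txid
    sub <- gr[sel]
    typ <- S4Vectors::mcols(sub)$type
    ex <- sub[typ == "exon"]
    cds <- sub[typ == "CDS"]
    if (length(ex) == 0L || length(cds) == 0L) {
      warning("transcript ", txid, " lacks exon or CDS rows; skipped")
      next
    }
    gene <- S4Vectors::mcols(sub)$gene_id[1L]
    tx <- tryCatch(
      transcript(id = txid,
                 gene = if (is.null(gene) || is.na(gene)) txid else gene,
                 contig = as.character(GenomicRanges::seqnames(sub))[1L],
                 strand = as.character(BiocGenerics::strand(ex))[1L],
                 exons = data.frame(start = GenomicRanges::start(ex),
                                    end = GenomicRanges::end(ex)),
                 cds_start = min(GenomicRanges::start(cds)),
                 cds_end = max(GenomicRanges::end(cds))),
      error = function(e) {
        warning("transcript ", txid, " skipped: ", conditionMessage(e))
        NULL
      })
    if (!is.null(tx)) out[[txid]] <- tx
  }
  out
}

#' Read biallelic SNVs from a VCF file
#'
#' Multiallelic rows are decomposed into one variant per alternate allele;
#' indels and symbolic alleles are dropped with a message reporting counts.
#'
#' @param path Path to a VCF (v4.x) file.
#' @return A data.frame with columns `contig`, `pos` (1-based), `ref`, `alt`,
#'   `label` (`"unknown"`; see [read_labels()] to attach labels).
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  v <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) {
    return(data.frame(contig = character(), pos = integer(), ref = character(),
                      alt = character(), label = character()))
  }
  alts <- strsplit(fix$ALT, ",", fixed = TRUE)
  n_alt <- lengths(alts)
  out <- data.frame(contig = rep(fix$CHROM, n_alt),
                    pos = rep(as.integer(fix$POS), n_alt),
                    ref = rep(fix$REF, n_alt),
                    alt = unlist(alts),
                    stringsAsFactors = FALSE)
  snv <- nchar(out$ref) == 1L & nchar(out$alt) == 1L &
    out$ref %in% c("A", "C", "G", "T") & out$alt %in% c("A", "C", "G", "T") &
    out$ref != out$alt
  n_drop <- sum(!snv)
  if (n_drop > 0L) {
    message(n_drop, " non-SNV allele(s) (indel/symbolic) skipped in ", path)
  }
  out <- out[snv, , drop = FALSE]
  rownames(out) <- NULL
  out$label <- "unknown"
  out
}

#' Read variant labels from a TSV file
#'
#' @param path TSV with columns `contig`, `pos`, `ref`, `alt`, `label`
#'   (`deleterious`/`benign`/`unknown`).
#' @param variants Optional variant data.frame to merge the labels into.
#' @return The labels data.frame, or `variants` with its `label` column filled.
#' @export
read_labels <- function(path, variants = NULL) {
  lab <- read.table(path, header = TRUE, sep = "\t",
                    colClasses = c("character", "integer", "character",
                                   "character", "character"))
  need <- c("contig", "pos", "ref", "alt", "label")
  if (!all(need %in% names(lab))) {
    stop("label TSV must have columns ", paste(need, collapse = ", "))
  }
  bad <- !lab$label %in% c("deleterious", "benign", "unknown")
  if (any(bad)) stop("unrecognised label(s): ",
                     paste(unique(lab$label[bad]), collapse = ", "))
  if (is.null(variants)) return(lab)
  key <- function(d) paste(d$contig, d$pos, d$ref, d$alt, sep = ":")
  m <- match(key(variants), key(lab))
  variants$label <- ifelse(is.na(m), "unknown", lab$label[m])
  variants
}

#' Project a variant into coding (codon) coordinates
#'
#' Locates the variant within the transcript's CDS, reports the reference and
#' alternate codon on the coding strand (reverse-complemented for minus-strand
#' transcripts), and the hosting exon.
#'
#' @param variant One-row variant data.frame (`contig`, `pos`, `ref`, `alt`).
#' @param tx A `"transcript"`.
#' @param genome A `"genome_seq"` from [read_fasta()].
#' @return A list of class `"coding_context"` with fields `variant`,
#'   `transcript_id`, `cds_pos` (1-based within the CDS), `codon_index`
#'   (0-based), `pos_in_codon` (0/1/2), `ref_codon`, `alt_codon`, `ref_aa`,
#'   `alt_aa`, `exon_index` (0-based, transcript order), `exon_len`.
#' @export
project_variant <- function(variant, tx, genome) {
  if (variant$contig != tx$contig) {
    stop("variant on ", variant$contig, " but transcript on ", tx$contig)
  }
  pos <- variant$pos
  gbase <- substring(genome[[tx$contig]], pos, pos)
  if (gbase != variant$ref) {
    stop("reference mismatch at ", variant$contig, ":", pos,
         " (genome ", gbase, ", variant ref ", variant$ref, ")")
  }
  iv <- cds_intervals(tx)
  hit <- which(pos >= iv$start & pos <= iv$end)
  if (length(hit) == 0L) {
    stop("variant ", variant$contig, ":", pos, " not in CDS of ", tx$id)
  }
  # bases preceding pos within the CDS, in genomic orientation
  before <- sum(pmax(0L, pmin(iv$end, pos - 1L) - iv$start + 1L))
  total <- sum(iv$end - iv$start + 1L)
  cds_pos <- if (tx$strand == "+") before + 1L else total - before
  codon_index <- (cds_pos - 1L) %/% 3L
  pos_in_codon <- (cds_pos - 1L) %% 3L

  cds_seq <- cds_sequence(tx, genome)
  ref_codon <- substring(cds_seq, 3L * codon_index + 1L, 3L * codon_index + 3L)
  ref_cod_strand <- if (tx$strand == "+") variant$ref else comp_base(variant$ref)
  alt_cod_strand <- if (tx$strand == "+") variant$alt else comp_base(variant$alt)
  stopifnot(substring(ref_codon, pos_in_codon + 1L, pos_in_codon + 1L) ==
              ref_cod_strand)
  alt_codon <- ref_codon
  substring(alt_codon, pos_in_codon + 1L, pos_in_codon + 1L) <- alt_cod_strand

  # hosting exon (full exon, not CDS-clipped), transcript orientation
  ex <- tx$exons
  ehit <- which(pos >= ex$start & pos <= ex$end)
  exon_index <- if (tx$strand == "+") ehit - 1L else nrow(ex) - ehit
  structure(list(variant = variant, transcript_id = tx$id,
                 cds_pos = cds_pos, codon_index = codon_index,
                 pos_in_codon = pos_in_codon,
                 ref_codon = ref_codon, alt_codon = alt_codon,
                 ref_aa = translate_codon(ref_codon),
                 alt_aa = translate_codon(alt_codon),
                 exon_index = exon_index,
                 exon_len = ex$end[ehit] - ex$start[ehit] + 1L),
            class = "coding_context")
}

translate_codon <- function(codon) {
  if (grepl("N", codon, fixed = TRUE)) {
    stop("ambiguous base in codon ", codon)
  }
  Biostrings::GENETIC_CODE[[codon]]
}

#' Is a projected variant synonymous?
#'
#' True iff reference and alternate codon encode the same amino acid under the
#' standard genetic code (stop-to-stop changes count as synonymous).
#'
#' @param ctx A `"coding_context"` from [project_variant()].
#' @return Logical scalar.
#' @export
is_synonymous <- function(ctx) {
  identical(translate_codon(ctx$ref_codon), translate_codon(ctx$alt_codon))
}

#' Pick the canonical transcript for a variant
#'
#' Among transcripts whose CDS contains the variant, the one with the longest
#' CDS; ties are broken by lexicographically smallest transcript id.
#'
#' @param variant One-row variant data.frame.
#' @param transcripts List of `"transcript"` objects.
#' @return A `"transcript"`.
#' @export
choose_canonical_transcript <- function(variant, transcripts) {
  host <- Filter(function(tx) {
    if (tx$contig != variant$contig) return(FALSE)
    iv <- cds_intervals(tx)
    any(variant$pos >= iv$start & variant$pos <= iv$end)
  }, transcripts)
  if (length(host) == 0L) {
    stop("variant ", variant$contig, ":", variant$pos,
         " is not in any coding region")
  }
  lens <- vapply(host, cds_length, integer(1L))
  ids <- vapply(host, function(tx) tx$id, character(1L))
  ord <- order(-lens, ids)
  host[[ord[1L]]]
}

# Genomic position of a CDS coordinate; inverse of the projection arithmetic.
cds_to_genomic <- function(tx, cds_pos) {
  iv <- cds_intervals(tx)
  widths <- iv$end - iv$start + 1L
  total <- sum(widths)
  stopifnot(cds_pos >= 1L, cds_pos <= total)
  offset <- if (tx$strand == "+") cds_pos else total - cds_pos + 1L
  cum <- cumsum(widths)
  i <- which(offset <= cum)[1L]
  prior <- if (i == 1L) 0L else cum[i - 1L]
  iv$start[i] + (offset - prior) - 1L
}
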