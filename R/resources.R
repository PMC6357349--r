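# Motif, codon-usage and tRNA resources: constructors, file readers, and the
# derived per-codon tables (RSCU, tRNA adaptation weights).

SENSE_CODONS <- local({
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
})

#' Construct a motif set
#'
#' Either a hexamer list (exonic splicing enhancers and similar 6-mer motif
#' collections) or a collection of log-odds position weight matrices with match
#' thresholds (SR-protein binding motifs and similar).
#'
#' @param hexamers Character vector of 6-mers over A/C/G/T (hexamer-list kind).
#' @param pwms List of PWM entries, each a list with `name`, `mat` (4 x width
#'   numeric matrix, rows A,C,G,T, log-odds) and `threshold` (PWM kind).
#' @return An object of class `"motif_set"` with a `kind` field.
#' @export
motif_set <- function(hexamers = NULL, pwms = NULL) {
  if (is.null(hexamers) == is.null(pwms)) {
    stop("supply exactly one of 'hexamers' or 'pwms'")
  }
  if (!is.null(hexamers)) {
    hexamers <- toupper(hexamers)
    bad <- nchar(hexamers) != 6L | grepl("[^ACGT]", hexamers)
    if (any(bad)) stop("invalid hexamer(s): ",
                       paste(unique(hexamers[bad]), collapse = ", "))
    return(structure(list(kind = "hexamer-list", hexamers = unique(hexamers)),
                     class = "motif_set"))
  }
  for (p in pwms) {
    stopifnot(is.matrix(p$mat), nrow(p$mat) == 4L, is.finite(p$threshold))
  }
  structure(list(kind = "PWM", pwms = pwms), class = "motif_set")
}

#' Read a hexamer motif list
#'
#' One 6-mer per line; blank lines and `#` comments are ignored.
#' @param path File path.
#' @return A hexamer-list `"motif_set"`.
#' @export
read_hexamers <- function(path) {
  ln <- readLines(path)
  ln <- trimws(sub("#.*$", "", ln))
  motif_set(hexamers = ln[nzchar(ln)])
}

#' Write a hexamer motif list
#' @param motifs A hexamer-list `"motif_set"`.
#' @param path File path.
#' @export
write_hexamers <- function(motifs, path) {
  stopifnot(motifs$kind == "hexamer-list")
  writeLines(motifs$hexamers, path)
}

# PWM text block format:
#   >name <width> <threshold>
#   four whitespace-separated rows (A, C, G, T) of <width> log-odds values
read_pwm_block <- function(lines) {
  hdr <- strsplit(sub("^>", "", lines[1L]), "\\s+")[[1L]]
  width <- as.integer(hdr[2L])
  rows <- lapply(lines[2:5], function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1L]]))
  if (any(vapply(rows, length, integer(1L)) != width) || anyNA(unlist(rows))) {
    stop("malformed PWM block for '", hdr[1L], "'")
  }
  mat <- do.call(rbind, rows)
  rownames(mat) <- c("A", "C", "G", "T")
  list(name = hdr[1L], mat = mat, threshold = as.numeric(hdr[3L]))
}

#' Read position weight matrices
#'
#' Each block: a header line `>name width threshold` followed by four rows of
#' log-odds values (A, C, G, T order).
#' @param path File path.
#' @return A PWM `"motif_set"`.
#' @export
read_pwms <- function(path) {
  ln <- readLines(path)
  ln <- ln[nzchar(trimws(ln))]
  starts <- grep("^>", ln)
  if (length(starts) == 0L) stop("no PWM blocks in ", path)
  pwms <- lapply(starts, function(i) read_pwm_block(ln[i:(i + 4L)]))
  motif_set(pwms = pwms)
}

#' @rdname read_pwms
#' @param motifs A PWM `"motif_set"`.
#' @export
write_pwms <- function(motifs, path) {
  stopifnot(motifs$kind == "PWM")
  con <- file(path, "w")
  on.exit(close(con))
  for (p in motifs$pwms) {
    writeLines(sprintf(">%s %d %g", p$name, ncol(p$mat), p$threshold), con)
    for (r in 1:4) writeLines(paste(format(p$mat[r, ], trim = TRUE), collapse = " "), con)
  }
  invisible(path)
}

#' Construct a splice-site model
#'
#' Donor and acceptor log-odds matrices with their exonic offsets: the number
#' of matrix columns that fall inside the exon (3 of 9 for the canonical donor
#' geometry, 3 of 23 for the acceptor).
#'
#' @param donor,acceptor 4 x width numeric matrices (rows A,C,G,T).
#' @param donor_exonic,acceptor_exonic Exonic column counts.
#' @return An object of class `"splice_model"`.
#' @export
splice_model <- function(donor, acceptor, donor_exonic = 3L, acceptor_exonic = 3L) {
  stopifnot(nrow(donor) == 4L, nrow(acceptor) == 4L,
            donor_exonic < ncol(donor), acceptor_exonic < ncol(acceptor))
  rownames(donor) <- rownames(acceptor) <- c("A", "C", "G", "T")
  structure(list(donor = donor, acceptor = acceptor,
                 donor_exonic = as.integer(donor_exonic),
                 acceptor_exonic = as.integer(acceptor_exonic)),
            class = "splice_model")
}

# Log-odds matrix from a consensus string: consensus base probability p,
# remainder split evenly; background 0.25.
consensus_pwm <- function(consensus, p = 0.85) {
  w <- nchar(consensus)
  mat <- matrix(log((1 - p) / 3 / 0.25), nrow = 4L, ncol = w,
                dimnames = list(c("A", "C", "G", "T"), NULL))
  for (i in seq_len(w)) {
    b <- substring(consensus, i, i)
    if (b == "N") mat[, i] <- 0 else mat[b, i] <- log(p / 0.25)
  }
  mat
}

#' Default splice-site model
#'
#' A synthetic log-odds model built from the canonical human donor
#' (`CAG|GTAAGT`, width 9, 3 exonic columns) and acceptor (polypyrimidine
#' tract + `AG|` + 3 exonic columns, width 23) consensus sequences. Intended
#' as a pluggable placeholder: substitute matrices derived from real splice
#' site alignments for production use.
#' @return A `"splice_model"`.
#' @export
default_splice_model <- function() {
  donor <- consensus_pwm("CAGGTAAGT")
  # acceptor: 18 pyrimidine positions, near-invariant AG, then 3 exonic columns
  acc <- consensus_pwm(paste0(strrep("T", 18L), "AG", "NNN"), p = 0.55)
  acc["C", 1:18] <- log(0.35 / 0.25)   # C tolerated in the tract
  acc["A", 19L] <- log(0.9 / 0.25); acc["G", 20L] <- log(0.9 / 0.25)
  splice_model(donor = donor, acceptor = acc,
               donor_exonic = 3L, acceptor_exonic = 3L)
}

#' Read a codon-usage table
#'
#' Two-column TSV `codon<TAB>count`. All 61 sense codons must be present
#' (zero counts allowed).
#' @param path File path.
#' @return Named numeric vector of class `"codon_usage"` over the sense codons.
#' @export
read_codon_usage <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t",
                  colClasses = c("character", "numeric"))
  codon_usage(stats::setNames(d[[2L]], toupper(d[[1L]])))
}

#' @rdname read_codon_usage
#' @param counts Named numeric vector codon -> non-negative count.
#' @export
codon_usage <- function(counts) {
  missing_cod <- setdiff(SENSE_CODONS, names(counts))
  if (length(missing_cod) > 0L) {
    stop("codon usage table missing ", length(missing_cod), " sense codon(s), e.g. ",
         paste(head(missing_cod, 3L), collapse = ", "))
  }
  if (any(counts < 0)) stop("negative codon count")
  structure(counts[SENSE_CODONS], class = "codon_usage")
}

#' Relative synonymous codon usage (RSCU)
#'
#' RSCU of a codon is its count divided by the mean count of its synonymous
#' family. Single-codon families (Met, Trp) are fixed at 1; a family with zero
#' total yields 0 for all members.
#'
#' @param usage A `"codon_usage"` table.
#' @return Named numeric vector codon -> RSCU over the 61 sense codons.
#' @export
rscu_table <- function(usage) {
  aa <- Biostrings::GENETIC_CODE[SENSE_CODONS]
  out <- stats::setNames(numeric(length(SENSE_CODONS)), SENSE_CODONS)
  for (a in unique(aa)) {
    fam <- SENSE_CODONS[aa == a]
    if (length(fam) == 1L) { out[fam] <- 1; next }
    tot <- sum(usage[fam])
    out[fam] <- if (tot > 0) usage[fam] / (tot / length(fam)) else 0
  }
  out
}

#' Read a tRNA gene-copy table
#'
#' Two-column TSV `anticodon<TAB>copies` (anticodon written 5'->3' as DNA).
#' @param path File path.
#' @return Named integer vector of class `"trna_table"`.
#' @export
read_trna_table <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t",
                  colClasses = c("character", "numeric"))
  trna_table(stats::setNames(d[[2L]], toupper(d[[1L]])))
}

#' @rdname read_trna_table
#' @param copies Named numeric vector anticodon -> gene copy number.
#' @export
trna_table <- function(copies) {
  if (any(copies < 0)) stop("negative tRNA copy number")
  if (all(copies == 0)) stop("tRNA table has no anticodon with copies > 0")
  bad <- nchar(names(copies)) != 3L | grepl("[^ACGT]", names(copies))
  if (any(bad)) stop("invalid anticodon(s): ",
                     paste(names(copies)[bad], collapse = ", "))
  structure(copies, class = "trna_table")
}

#' Default wobble-pairing penalty table
#'
#' Codon-anticodon pairing classes at the wobble position (codon position 3 vs
#' anticodon position 1) with selective penalties `s` in \[0,1\]: Watson-Crick
#' pairs carry s = 0; the non-WC rows use the standard tRNA-adaptation-index
#' constraint values (G:U 0.41, I:C 0.28, I:A 0.9999, U:G 0.68), treating
#' anticodon A at the wobble position as inosine.
#' @return data.frame with columns `codon3`, `anticodon1`, `s`.
#' @export
default_wobble <- function() {
  data.frame(
    codon3     = c("T", "C", "A", "G", "T", "C", "A", "G"),
    anticodon1 = c("A", "G", "T", "C", "G", "A", "A", "T"),
    s          = c(0,   0,   0,   0,   0.41, 0.28, 0.9999, 0.68),
    stringsAsFactors = FALSE)
}

#' Per-codon tRNA adaptation weights
#'
#' For each sense codon, the absolute adaptiveness is
#' `W = sum over decoding anticodons of (1 - s) * copies`, where the decoding
#' anticodons are those whose positions 2-3 Watson-Crick pair the codon's
#' positions 1-2 and whose wobble position appears in the pairing table.
#' Weights are `w = W / max(W)`; codons with no decoder receive the geometric
#' mean of the nonzero weights (the usual convention).
#'
#' @param trna A `"trna_table"`.
#' @param wobble Pairing table as from [default_wobble()].
#' @return Named numeric vector codon -> weight in (0, 1].
#' @export
tai_weights <- function(trna, wobble = default_wobble()) {
  W <- stats::setNames(numeric(length(SENSE_CODONS)), SENSE_CODONS)
  for (codon in SENSE_CODONS) {
    c1 <- substring(codon, 1L, 1L); c2 <- substring(codon, 2L, 2L)
    c3 <- substring(codon, 3L, 3L)
    # anticodon positions 3 and 2 pair codon positions 1 and 2 (antiparallel)
    a3 <- comp_base(c1); a2 <- comp_base(c2)
    rows <- wobble[wobble$codon3 == c3, , drop = FALSE]
    for (i in seq_len(nrow(rows))) {
      anticodon <- paste0(rows$anticodon1[i], a2, a3)
      cp <- trna[anticodon]
      if (!is.na(cp) && cp > 0) W[codon] <- W[codon] + (1 - rows$s[i]) * cp
    }
  }
  if (all(W == 0)) stop("no codon is decoded by the supplied tRNA table")
  w <- W / max(W)
  nz <- w[w > 0]
  w[w == 0] <- exp(mean(log(nz)))
  w
}
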