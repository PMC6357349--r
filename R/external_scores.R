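# Ingestion of precomputed genome-track scores (conservation, splicing-change
# z-scores, and similar) and annotation-track overlaps. Scores the pipeline
# cannot compute natively enter through these tables.

#' Load a score table from TSV
#'
#' Position-keyed tables (`contig`, `pos`, `score`) hold per-position values
#' such as phyloP conservation; allele-keyed tables (`contig`, `pos`, `ref`,
#' `alt`, `score`) hold per-substitution values such as splicing-change
#' z-scores. Keys are stored as published — no strand normalisation.
#'
#' @param path TSV file with a header row.
#' @param keying `"position"` or `"allele"`.
#' @return An object of class `"score_table"`.
#' @export
load_score_tsv <- function(path, keying = c("position", "allele")) {
  keying <- match.arg(keying)
  d <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- if (keying == "position") c("contig", "pos", "score") else
    c("contig", "pos", "ref", "alt", "score")
  if (!identical(names(d)[seq_along(need)], need) || ncol(d) != length(need)) {
    stop("score TSV '", path, "' must have exactly columns: ",
         paste(need, collapse = ", "))
  }
  if (nrow(d) > 0L && (!is.numeric(d$score) || anyNA(d$score) ||
                       any(!is.finite(d$score)))) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(d$score))))[1L]
    stop("non-numeric or non-finite score at data line ", bad, " of ", path)
  }
  score_table(d, keying)
}

#' @rdname load_score_tsv
#' @param entries data.frame with the columns listed above.
#' @export
score_table <- function(entries, keying = c("position", "allele")) {
  keying <- match.arg(keying)
  key <- if (keying == "position") paste(entries$contig, entries$pos) else
    paste(entries$contig, entries$pos, entries$ref, entries$alt)
  if (anyDuplicated(key)) {
    stop("duplicate ", keying, " key(s) in score table, e.g. ",
         key[duplicated(key)][1L])
  }
  structure(list(keying = keying,
                 values = stats::setNames(entries$score, key)),
            class = "score_table")
}

#' Look up a per-position score
#'
#' @param table A position-keyed `"score_table"`.
#' @param contig,pos Query position (1-based).
#' @return The score, or `NA` when the key is absent (imputed downstream).
#' @export
lookup_position_score <- function(table, contig, pos) {
  if (table$keying != "position") {
    stop("table is allele-keyed; use lookup_allele_score()")
  }
  unname(table$values[paste(contig, pos)])
}

#' Look up a per-substitution score
#'
#' @param table An allele-keyed `"score_table"`.
#' @param contig,pos,ref,alt Query substitution (1-based position).
#' @return The score, or `NA` when the key is absent.
#' @export
lookup_allele_score <- function(table, contig, pos, ref, alt) {
  if (table$keying != "allele") {
    stop("table is position-keyed; use lookup_position_score()")
  }
  unname(table$values[paste(contig, pos, ref, alt)])
}

#' Read an annotation track from BED
#'
#' BED intervals (0-based half-open) are converted to 1-based closed on load.
#' Used for boolean overlap features: transcription-factor binding sites,
#' histone marks, open chromatin and similar functional-region tracks.
#'
#' @param path BED3+ file.
#' @param name Track name; defaults to the file's base name without extension.
#' @return An object of class `"interval_track"` wrapping a `GRanges` index.
#' @export
read_bed <- function(path, name = NULL) {
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  ln <- readLines(path)
  ln <- ln[nzchar(trimws(ln))]
  ln <- ln[!grepl("^(#|track|browser)", ln)]
  if (length(ln) == 0L) {
    gr <- GenomicRanges::GRanges()
  } else {
    parts <- strsplit(ln, "\t", fixed = TRUE)
    if (any(lengths(parts) < 3L)) {
      stop("BED line with fewer than 3 fields at line ",
           which(lengths(parts) < 3L)[1L], " of ", path)
    }
    start0 <- as.integer(vapply(parts, `[[`, "", 2L))
    end0 <- as.integer(vapply(parts, `[[`, "", 3L))
    bad <- is.na(start0) | is.na(end0) | start0 >= end0
    if (any(bad)) {
      stop("invalid BED interval (start >= end or non-integer) at line ",
           which(bad)[1L], " of ", path)
    }
    gr <- GenomicRanges::GRanges(
      seqnames = vapply(parts, `[[`, "", 1L),
      ranges = IRanges::IRanges(start = start0 + 1L, end = end0))
  }
  interval_track(gr, name)
}

#' @rdname read_bed
#' @param granges A `GRanges` of 1-based closed intervals.
#' @export
interval_track <- function(granges, name) {
  structure(list(name = name, granges = granges,
                 index = build_point_index(granges)),
            class = "interval_track")
}

# Per-contig point-query index: intervals sorted by start with a running
# maximum of ends, so a point-in-any-interval test is a single binary search.
build_point_index <- function(gr) {
  contigs <- as.character(GenomicRanges::seqnames(gr))
  idx <- list()
  for (ctg in unique(contigs)) {
    s <- GenomicRanges::start(gr)[contigs == ctg]
    e <- GenomicRanges::end(gr)[contigs == ctg]
    o <- order(s)
    idx[[ctg]] <- list(starts = s[o], maxend = cummax(e[o]))
  }
  idx
}

#' Does a position fall inside a track?
#'
#' Binary search on the per-contig interval index; agrees with a naive linear
#' overlap scan.
#'
#' @param track An `"interval_track"`.
#' @param contig,pos Query position (1-based).
#' @return Logical scalar.
#' @export
in_track <- function(track, contig, pos) {
  ix <- track$index[[contig]]
  if (is.null(ix)) return(FALSE)
  i <- findInterval(pos, ix$starts)
  i >= 1L && ix$maxend[i] >= pos
}
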