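# Assembly of per-variant feature vectors into a variants x features matrix,
# zero-imputation of missing values, and z-score normalisation. Imputation
# happens on the raw scale before normalisation, and normalisation parameters
# are fitted on training rows only and frozen for any later data.

#' Construct a feature matrix
#'
#' @param values Numeric matrix, variants x features, with row names (variant
#'   ids `contig:pos:ref:alt`) and unique column names; `NA` marks missing.
#' @param labels Optional numeric vector per variant: 1 = deleterious,
#'   0 = benign, `NA` = unknown.
#' @return An object of class `"feature_matrix"` with fields `ids`, `features`,
#'   `values`, `missing` (logical mask), `labels`, `norm` (`NULL` until
#'   [zscore_apply()]).
#' @export
feature_matrix <- function(values, labels = NULL) {
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            !is.null(colnames(values)))
  if (anyDuplicated(colnames(values))) stop("duplicate feature names")
  if (anyDuplicated(rownames(values))) stop("duplicate variant ids")
  if (!is.null(labels)) {
    stopifnot(length(labels) == nrow(values))
    labels <- as.numeric(labels)
  }
  structure(list(ids = rownames(values), features = colnames(values),
                 values = values, missing = is.na(values),
                 labels = labels, norm = NULL),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  lab <- if (is.null(x$labels)) "unlabelled" else
    sprintf("%d deleterious / %d benign", sum(x$labels == 1, na.rm = TRUE),
            sum(x$labels == 0, na.rm = TRUE))
  cat(sprintf("<feature_matrix %d variants x %d features (%s)%s; %d missing cell(s)>\n",
              nrow(x$values), ncol(x$values), lab,
              if (is.null(x$norm)) "" else ", normalised", sum(x$missing)))
  invisible(x)
}

# Row/column subset that keeps mask, labels and normalisation state aligned.
fm_subset <- function(fm, rows = NULL, cols = NULL) {
  if (is.null(rows)) rows <- seq_along(fm$ids)
  if (is.null(cols)) cols <- fm$features
  v <- fm$values[rows, cols, drop = FALSE]
  out <- feature_matrix(v, labels = if (is.null(fm$labels)) NULL else fm$labels[rows])
  out$missing <- fm$missing[rows, cols, drop = FALSE]
  out$norm <- if (is.null(fm$norm)) NULL else
    list(mean = fm$norm$mean[cols], sd = fm$norm$sd[cols])
  out
}

#' Assemble a feature matrix from variants
#'
#' Projects each variant onto its canonical transcript, verifies synonymous
#' status, and evaluates every configured extractor. Non-synonymous or
#' non-coding variants are excluded and listed in the `"rejected"` attribute.
#'
#' @param variants Variant data.frame (`contig`, `pos`, `ref`, `alt`, optional
#'   `label`).
#' @param gene_models List of `"transcript"` objects (see [read_gtf()]).
#' @param genome A `"genome_seq"`.
#' @param extractors Named list of functions `function(ctx, tx, genome)`
#'   returning a numeric or logical scalar (`NA` = missing); see
#'   [default_extractors()]. Column order follows this list.
#' @return A `"feature_matrix"` with one row per accepted variant.
#' @export
assemble <- function(variants, gene_models, genome, extractors) {
  if (nrow(variants) == 0L) stop("no variants to assemble")
  stopifnot(length(extractors) > 0L, !is.null(names(extractors)))
  ids <- paste(variants$contig, variants$pos, variants$ref, variants$alt,
               sep = ":")
  vals <- matrix(NA_real_, nrow = nrow(variants), ncol = length(extractors),
                 dimnames = list(ids, names(extractors)))
  keep <- logical(nrow(variants))
  reasons <- character(0)
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, , drop = FALSE]
    ctx <- tryCatch({
      tx <- choose_canonical_transcript(v, gene_models)
      ctx <- project_variant(v, tx, genome)
      if (!is_synonymous(ctx)) stop("not synonymous (", ctx$ref_aa, " -> ",
                                    ctx$alt_aa, ")")
      list(ctx = ctx, tx = tx)
    }, error = function(e) e)
    if (inherits(ctx, "error")) {
      reasons <- c(reasons, paste0(ids[i], ": ", conditionMessage(ctx)))
      next
    }
    keep[i] <- TRUE
    for (f in names(extractors)) {
      x <- extractors[[f]](ctx$ctx, ctx$tx, genome)
      vals[i, f] <- if (is.na(x)) NA_real_ else as.numeric(x)
    }
  }
  if (!any(keep)) stop("all variants rejected:\n",
                       paste(reasons, collapse = "\n"))
  if (length(reasons) > 0L) {
    message(length(reasons), " variant(s) rejected (non-coding or non-synonymous)")
  }
  labels <- NULL
  if (!is.null(variants$label) && any(variants$label != "unknown")) {
    labels <- ifelse(variants$label == "deleterious", 1,
                     ifelse(variants$label == "benign", 0, NA))[keep]
  }
  fm <- feature_matrix(vals[keep, , drop = FALSE], labels = labels)
  attr(fm, "rejected") <- reasons
  fm
}

#' Impute missing feature values to zero
#'
#' Missing cells are set to 0 on the raw scale, before normalisation; the
#' missing mask is retained for reporting.
#' @param fm A `"feature_matrix"`.
#' @return The matrix with no remaining `NA` values.
#' @export
impute_missing <- function(fm) {
  fm$values[is.na(fm$values)] <- 0
  fm
}

#' Fit z-score normalisation parameters
#'
#' Per-feature mean and sample standard deviation (denominator `n - 1`) over
#' the rows of the matrix. Fit on training rows only; apply the frozen
#' parameters to any held-out data.
#' @param fm A `"feature_matrix"` (impute first: see [impute_missing()]).
#' @return A list with named numeric vectors `mean` and `sd`.
#' @export
zscore_fit <- function(fm) {
  if (nrow(fm$values) < 2L) stop("need at least 2 rows to fit normalisation")
  list(mean = colMeans(fm$values),
       sd = apply(fm$values, 2L, stats::sd))
}

#' Apply z-score normalisation
#'
#' `(x - mean) / sd` per feature; features with zero training variance are set
#' to 0.
#' @param fm A `"feature_matrix"`.
#' @param params Parameters from [zscore_fit()] (typically fitted on the
#'   training rows).
#' @return The normalised matrix, with `norm` recording the parameters used.
#' @export
zscore_apply <- function(fm, params) {
  unknown <- setdiff(names(params$mean), fm$features)
  if (length(unknown) > 0L) {
    stop("normalisation parameters for unknown feature(s): ",
         paste(unknown, collapse = ", "))
  }
  missing_p <- setdiff(fm$features, names(params$mean))
  if (length(missing_p) > 0L) {
    stop("no normalisation parameters for feature(s): ",
         paste(missing_p, collapse = ", "))
  }
  mu <- params$mean[fm$features]
  sdv <- params$sd[fm$features]
  centred <- sweep(fm$values, 2L, mu, "-")
  scaled <- sweep(centred, 2L, ifelse(sdv > 0, sdv, 1), "/")
  scaled[, sdv == 0] <- 0
  fm$values <- scaled
  fm$norm <- list(mean = mu, sd = sdv)
  fm
}

#' Write / read a feature matrix as TSV
#'
#' First column `variant_id` (`contig:pos:ref:alt`), then one named column per
#' feature; missing values are written as `NA`. Labels travel separately as a
#' two-column TSV (`variant_id`, `label` with 1 = deleterious, 0 = benign).
#'
#' @param fm A `"feature_matrix"`.
#' @param path Output TSV path.
#' @param labels_path Optional path for the labels TSV.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(fm, path, labels_path = NULL) {
  v <- fm$values
  v[fm$missing] <- NA
  d <- data.frame(variant_id = fm$ids, v, check.names = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(labels_path)) {
    if (is.null(fm$labels)) stop("matrix has no labels to write")
    write.table(data.frame(variant_id = fm$ids, label = fm$labels),
                labels_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path, labels_path = NULL) {
  d <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                  stringsAsFactors = FALSE)
  if (names(d)[1L] != "variant_id") stop("first column must be variant_id")
  v <- as.matrix(d[, -1L, drop = FALSE])
  rownames(v) <- d$variant_id
  labels <- NULL
  if (!is.null(labels_path)) {
    l <- read.table(labels_path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
    labels <- l$label[match(d$variant_id, l$variant_id)]
  }
  feature_matrix(v, labels = labels)
}

#' Default feature extractors
#'
#' Builds the named extractor list for [assemble()] from a resource bundle:
#' the native splice-geometry, sequence, codon-usage and translation-efficiency
#' features, plus one column per configured score table (position- or
#' allele-keyed) and one boolean column per annotation track.
#'
#' @param ese Hexamer-list `"motif_set"` of exonic splicing enhancers
#'   (`ese_dens` column) or `NULL` to omit.
#' @param sr `"motif_set"` of SR-protein binding motifs (`SR_lost` column) or
#'   `NULL`.
#' @param splice A `"splice_model"` for the `MES` column or `NULL`.
#' @param tai Codon weights from [tai_weights()] for the `TE` column or `NULL`.
#' @param rscu Codon -> RSCU vector from [rscu_table()] for the `dRSCU`
#'   column or `NULL`.
#' @param position_scores Named list of position-keyed `"score_table"`s; each
#'   becomes one column under its list name (e.g. `verPhyloP`).
#' @param allele_scores Named list of allele-keyed `"score_table"`s (e.g.
#'   `dPSIZ`).
#' @param tracks List of `"interval_track"`s; each becomes one boolean column
#'   under its track name (e.g. `TFBS`).
#' @param sequence Include the basic sequence/geometry columns `DSP`, `MDE`,
#'   `DVE`, `CpG`, `RMP`.
#' @return Named list of extractor functions, in stable column order.
#' @export
default_extractors <- function(ese = NULL, sr = NULL, splice = NULL, tai = NULL,
                               rscu = NULL, position_scores = list(),
                               allele_scores = list(), tracks = list(),
                               sequence = TRUE) {
  ex <- list()
  if (sequence) {
    ex$DSP <- function(ctx, tx, genome) dsp(ctx, tx)
    ex$MDE <- function(ctx, tx, genome) mde(ctx, tx)
    ex$DVE <- function(ctx, tx, genome) dve(ctx, tx)
    ex$CpG <- function(ctx, tx, genome) cpg_context(ctx, genome)
    ex$RMP <- function(ctx, tx, genome) relative_mrna_position(ctx, tx)
  }
  if (!is.null(ese)) {
    force(ese)
    ex$ese_dens <- function(ctx, tx, genome)
      ese_density(exon_sequence(ctx, tx, genome), ese)
  }
  if (!is.null(splice)) {
    force(splice)
    ex$MES <- function(ctx, tx, genome)
      max_splice_site_score(ctx, tx, genome, splice, use_alt = TRUE)
  }
  if (!is.null(sr)) {
    force(sr)
    ex$SR_lost <- function(ctx, tx, genome) {
      w <- variant_windows(ctx, tx, genome)
      unname(motif_gain_loss(w$ref, w$alt, sr)["lost"])
    }
  }
  if (!is.null(tai)) {
    force(tai)
    ex$TE <- function(ctx, tx, genome) te_feature(ctx, tai)
  }
  if (!is.null(rscu)) {
    force(rscu)
    ex$dRSCU <- function(ctx, tx, genome) delta_rscu(ctx, rscu)
  }
  for (nm in names(position_scores)) {
    local({
      tab <- position_scores[[nm]]
      ex[[nm]] <<- function(ctx, tx, genome)
        lookup_position_score(tab, ctx$variant$contig, ctx$variant$pos)
    })
  }
  for (nm in names(allele_scores)) {
    local({
      tab <- allele_scores[[nm]]
      ex[[nm]] <<- function(ctx, tx, genome)
        lookup_allele_score(tab, ctx$variant$contig, ctx$variant$pos,
                            ctx$variant$ref, ctx$variant$alt)
    })
  }
  for (tr in tracks) {
    local({
      t2 <- tr
      ex[[t2$name]] <<- function(ctx, tx, genome)
        in_track(t2, ctx$variant$contig, ctx$variant$pos)
    })
  }
  ex
}
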