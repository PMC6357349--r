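# Synthetic fixture generator: a toy genome with multi-exon genes on both
# strands, motif/codon/tRNA resources, labelled synonymous variant sets with
# controllable class signal, and class-shifted score tables and annotation
# tracks. Signal is injected at the feature level (variant placement plus
# simulated tracks) — this is a testing device emulating the structure of
# curated variant sets, not a biological mutation model.

BASES <- c("A", "C", "G", "T")

# All synonymous single-base substitutions of the standard code:
# codon, 0-based position-in-codon, coding-strand alt base, alt codon.
SYN_SUBS <- local({
  gc <- Biostrings::GENETIC_CODE
  rows <- list()
  for (codon in names(gc)) {
    if (gc[[codon]] == "*") next
    for (pic in 0:2) {
      refb <- substring(codon, pic + 1L, pic + 1L)
      for (alt in setdiff(BASES, refb)) {
        altc <- codon
        substring(altc, pic + 1L, pic + 1L) <- alt
        if (gc[[altc]] == gc[[codon]]) {
          rows[[length(rows) + 1L]] <-
            data.frame(codon = codon, pic = pic, alt_base = alt,
                       alt_codon = altc, stringsAsFactors = FALSE)
        }
      }
    }
  }
  do.call(rbind, rows)
})

#' Effect sizes for the synthetic generator
#'
#' Class-conditional shifts between deleterious and benign variants:
#' `cons_shift`/`gerp_shift`/`dpsiz_shift` are the deleterious-class means (in
#' SD units) of the two simulated conservation tables and the splicing-change
#' z-score table (benign mean 0, SD 1); `tfbs_del`/`tfbs_ben` and `histone_del`/`histone_ben` are the
#' per-class probabilities of lying in the corresponding annotation track;
#' `splice_window` places deleterious variants within that many nt of an
#' internal splice site (0 = uniform placement); `ese_planted` restricts
#' deleterious variants to enhancer-dense exons; `te_min` makes deleterious
#' variants adopt the least tRNA-adapted synonymous codon. `default_effects()`
#' gives the standard study conditions; `null_effects()` switches every signal
#' off for null-calibration runs.
#'
#' @return Named list of effect parameters.
#' @export
default_effects <- function() {
  list(cons_shift = 2, gerp_shift = 1.2, dpsiz_shift = 1.5,
       tfbs_del = 0.55, tfbs_ben = 0.08,
       histone_del = 0.45, histone_ben = 0.10,
       splice_window = 6L, ese_planted = TRUE, te_min = TRUE)
}

#' @rdname default_effects
#' @export
null_effects <- function() {
  list(cons_shift = 0, gerp_shift = 0, dpsiz_shift = 0,
       tfbs_del = 0.10, tfbs_ben = 0.10,
       histone_del = 0.10, histone_ben = 0.10,
       splice_window = 0L, ese_planted = FALSE, te_min = FALSE)
}

#' Synthetic-dataset configuration
#'
#' Defaults give the standard study conditions: 300 deleterious and 300 benign
#' synonymous variants (600 in total) over 60 five-exon genes, with the
#' default effect sizes and a 5% missing rate in the simulated score tables.
#'
#' @param seed Master seed; every stage derives its RNG stream from it.
#' @param n_genes Number of genes (alternating strands).
#' @param exons_per_gene Exons per gene.
#' @param exon_len_range,intron_len_range Length ranges in nt (introns must
#'   fit the embedded splice consensus, i.e. be at least 30 nt).
#' @param n_pos,n_neg Deleterious / benign variant counts.
#' @param effects Effect-size list; see [default_effects()].
#' @param missing_rate Fraction of score-table keys omitted (exercises
#'   zero-imputation).
#' @param dir Optional directory; when set, every stage also writes its
#'   standard-format files there.
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1L, n_genes = 60L, exons_per_gene = 5L,
                       exon_len_range = c(90L, 150L),
                       intron_len_range = c(80L, 140L),
                       n_pos = 300L, n_neg = 300L,
                       effects = default_effects(),
                       missing_rate = 0.05, dir = NULL) {
  stopifnot(n_genes >= 1L, exons_per_gene >= 1L, n_pos >= 1L, n_neg >= 1L,
            missing_rate >= 0, missing_rate <= 1,
            all(vapply(effects, function(x) all(is.finite(as.numeric(x))),
                       logical(1L))))
  if (intron_len_range[1L] < 30L) stop("introns must be at least 30 nt")
  structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 exons_per_gene = as.integer(exons_per_gene),
                 exon_len_range = as.integer(exon_len_range),
                 intron_len_range = as.integer(intron_len_range),
                 n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 effects = effects, missing_rate = missing_rate, dir = dir),
            class = "sim_config")
}

rand_dna <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

#' Simulate a reference: genome, gene models and resources
#'
#' Generates one contig carrying `n_genes` multi-exon genes on alternating
#' strands. Coding sequences are built codon-wise from the sense codons (so
#' translations contain no internal stop); donor (`GTAAGT`) and acceptor
#' (pyrimidine tract + `AG`) consensus sequences are embedded in the intronic
#' ends so splice-site matrix scores carry genuine positional signal. An ESE
#' hexamer set is harvested from a random half of the exons (making those
#' exons enhancer-dense), and random SR hexamers, codon-usage counts and tRNA
#' gene copies complete the resource bundle. With `config$dir` set, writes
#' `genome.fa`, `genes.gtf`, `ese_hexamers.txt`, `sr_hexamers.txt`,
#' `codon_usage.tsv` and `trna_copies.tsv`.
#'
#' @param config A `"sim_config"`.
#' @return List: `genome`, `transcripts`, `ese`, `sr`, `usage`, `trna`,
#'   `splice`, `tai` (codon weights), `exon_info` (per-exon ESE density).
#' @export
simulate_reference <- function(config) {
  set.seed(config$seed)
  n_ex <- config$exons_per_gene
  contig_parts <- character(0)
  cursor <- 0L
  transcripts <- list()
  for (g in seq_len(config$n_genes)) {
    strand <- if (g %% 2L == 1L) "+" else "-"
    ex_len <- sample(seq(config$exon_len_range[1L], config$exon_len_range[2L]),
                     n_ex, replace = TRUE)
    ex_len[n_ex] <- ex_len[n_ex] - (sum(ex_len) %% 3L)
    in_len <- if (n_ex > 1L)
      sample(seq(config$intron_len_range[1L], config$intron_len_range[2L]),
             n_ex - 1L, replace = TRUE) else integer(0)
    n_codons <- sum(ex_len) %/% 3L
    cds <- paste(sample(SENSE_CODONS, n_codons, replace = TRUE), collapse = "")
    # gene in coding orientation: exons are slices of the CDS
    parts <- character(0)
    offs <- cumsum(c(0L, ex_len))
    coding_iv <- matrix(0L, nrow = n_ex, ncol = 2L)
    pos_in_gene <- 0L
    for (j in seq_len(n_ex)) {
      exon_seq <- substring(cds, offs[j] + 1L, offs[j + 1L])
      parts <- c(parts, exon_seq)
      coding_iv[j, ] <- c(pos_in_gene + 1L, pos_in_gene + ex_len[j])
      pos_in_gene <- pos_in_gene + ex_len[j]
      if (j < n_ex) {
        intr <- rand_dna(in_len[j])
        substring(intr, 1L, 6L) <- "GTAAGT"
        tract <- paste(sample(c("T", "C"), 18L, replace = TRUE,
                              prob = c(0.75, 0.25)), collapse = "")
        substring(intr, in_len[j] - 19L, in_len[j]) <- paste0(tract, "AG")
        parts <- c(parts, intr)
        pos_in_gene <- pos_in_gene + in_len[j]
      }
    }
    gene_coding <- paste(parts, collapse = "")
    G <- nchar(gene_coding)
    spacer <- rand_dna(150L)
    gene_genomic <- if (strand == "+") gene_coding else revcomp(gene_coding)
    if (strand == "-") {
      coding_iv <- cbind(G - coding_iv[, 2L] + 1L, G - coding_iv[, 1L] + 1L)
    }
    gene_start <- cursor + 150L   # 0-based offset of gene within contig
    exons <- data.frame(start = gene_start + coding_iv[, 1L],
                        end = gene_start + coding_iv[, 2L])
    id <- sprintf("tx%02d", g)
    transcripts[[id]] <- transcript(
      id = id, gene = sprintf("gene%02d", g), contig = "chrS",
      strand = strand, exons = exons,
      cds_start = min(exons$start), cds_end = max(exons$end))
    contig_parts <- c(contig_parts, spacer, gene_genomic)
    cursor <- cursor + 150L + G
  }
  genome <- structure(c(chrS = paste(contig_parts, collapse = "")),
                      class = "genome_seq")

  # harvest ESE hexamers from a random half of the exons
  exon_info <- do.call(rbind, lapply(transcripts, function(tx) {
    n <- nrow(tx$exons)
    data.frame(tx = tx$id, exon_index = 0:(n - 1L), stringsAsFactors = FALSE)
  }))
  rownames(exon_info) <- NULL
  exon_seqs <- mapply(function(txid, ei) {
    tx <- transcripts[[txid]]
    gi <- if (tx$strand == "+") ei + 1L else nrow(tx$exons) - ei
    s <- substring(genome[["chrS"]], tx$exons$start[gi], tx$exons$end[gi])
    if (tx$strand == "-") revcomp(s) else s
  }, exon_info$tx, exon_info$exon_index)
  planted <- sample(nrow(exon_info), nrow(exon_info) %/% 2L)
  harvest <- unlist(lapply(exon_seqs[planted], function(s) {
    st <- sample(nchar(s) - 5L, 5L)
    substring(s, st, st + 5L)
  }))
  ese <- motif_set(hexamers = head(unique(harvest), 60L))
  sr <- motif_set(hexamers = unique(vapply(seq_len(20L), function(i)
    rand_dna(6L), character(1L))))
  exon_info$ese_density <- vapply(exon_seqs, ese_density, numeric(1L),
                                  motifs = ese)

  usage <- codon_usage(stats::setNames(
    sample(5:100, length(SENSE_CODONS), replace = TRUE), SENSE_CODONS))
  anticodons <- unique(vapply(SENSE_CODONS, revcomp, character(1L)))
  trna <- trna_table(stats::setNames(
    pmax(sample(0:12, length(anticodons), replace = TRUE), 0), anticodons))
  splice <- default_splice_model()
  ref <- list(genome = genome, transcripts = transcripts, ese = ese, sr = sr,
              usage = usage, trna = trna, splice = splice,
              tai = tai_weights(trna), exon_info = exon_info)
  if (!is.null(config$dir)) write_reference_files(ref, config$dir)
  ref
}

write_reference_files <- function(ref, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ss <- Biostrings::DNAStringSet(unclass(ref$genome))
  Biostrings::writeXStringSet(ss, file.path(dir, "genome.fa"), width = 70L)
  con <- file(file.path(dir, "genes.gtf"), "w")
  for (tx in ref$transcripts) {
    for (type in c("exon", "CDS")) {
      for (j in seq_len(nrow(tx$exons))) {
        writeLines(paste(tx$contig, "synforest", type, tx$exons$start[j],
                         tx$exons$end[j], ".", tx$strand, ".",
                         sprintf('gene_id "%s"; transcript_id "%s";',
                                 tx$gene, tx$id),
                         sep = "\t"), con)
      }
    }
  }
  close(con)
  write_hexamers(ref$ese, file.path(dir, "ese_hexamers.txt"))
  write_hexamers(ref$sr, file.path(dir, "sr_hexamers.txt"))
  write.table(data.frame(codon = names(unclass(ref$usage)),
                         count = as.numeric(ref$usage)),
              file.path(dir, "codon_usage.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(anticodon = names(unclass(ref$trna)),
                         copies = as.numeric(ref$trna)),
              file.path(dir, "trna_copies.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

# Catalogue of every synonymous single-base substitution in a reference:
# one row per (position, alt), with splice distance, exon ESE density and the
# tRNA weight of the alternate codon.
syn_catalogue <- function(ref) {
  out <- lapply(ref$transcripts, function(tx) {
    iv <- cds_intervals(tx)
    gpos_all <- unlist(Map(seq, iv$start, iv$end))
    if (tx$strand == "-") gpos_all <- rev(gpos_all)
    cds <- cds_sequence(tx, ref$genome)
    n_cod <- nchar(cds) %/% 3L
    codons <- substring(cds, 3L * (0:(n_cod - 1L)) + 1L, 3L * (0:(n_cod - 1L)) + 3L)
    d <- merge(data.frame(ci = 0:(n_cod - 1L), codon = codons,
                          stringsAsFactors = FALSE),
               SYN_SUBS, by = "codon")
    if (nrow(d) == 0L) return(NULL)
    cds_pos <- 3L * d$ci + d$pic + 1L
    gpos <- gpos_all[cds_pos]
    refb <- substring(d$codon, d$pic + 1L, d$pic + 1L)
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    if (tx$strand == "-") {
      g_ref <- comp[refb]; g_alt <- comp[d$alt_base]
    } else {
      g_ref <- refb; g_alt <- d$alt_base
    }
    ex <- tx$exons
    gi <- findInterval(gpos, ex$start)
    left_int <- gi > 1L
    right_int <- gi < nrow(ex)
    dl <- ifelse(left_int, gpos - ex$start[gi], Inf)
    dr <- ifelse(right_int, ex$end[gi] - gpos, Inf)
    exon_index <- if (tx$strand == "+") gi - 1L else nrow(ex) - gi
    info <- ref$exon_info[ref$exon_info$tx == tx$id, ]
    dens <- info$ese_density[match(exon_index, info$exon_index)]
    data.frame(tx = tx$id, gpos = gpos, ref = unname(g_ref),
               alt = unname(g_alt), alt_codon = d$alt_codon,
               w_alt = unname(ref$tai[d$alt_codon]),
               dsp = pmin(dl, dr), ese_density = dens,
               stringsAsFactors = FALSE)
  })
  cat <- do.call(rbind, out)
  rownames(cat) <- NULL
  cat[order(cat$gpos, cat$alt), ]
}

#' Simulate labelled synonymous variants
#'
#' Every emitted variant is synonymous by construction (drawn from the
#' catalogue of synonymous substitutions of the reference). Deleterious
#' variants follow the configured effect sizes: placed within
#' `splice_window` nt of an internal splice site, restricted to
#' enhancer-dense exons (`ese_planted`), and adopting the least tRNA-adapted
#' synonymous codon (`te_min`); benign variants are placed uniformly with a
#' random synonymous alternate. With `config$dir` set, writes `variants.vcf`
#' and `labels.tsv`.
#'
#' @param config A `"sim_config"`.
#' @param ref A reference from [simulate_reference()].
#' @return Variant data.frame (`contig`, `pos`, `ref`, `alt`, `label`),
#'   sorted by position.
#' @export
simulate_variants <- function(config, ref) {
  set.seed(config$seed + 1L)
  cat <- syn_catalogue(ref)
  eff <- config$effects
  elig <- cat
  if (eff$splice_window > 0L) {
    elig <- elig[elig$dsp <= eff$splice_window, ]
  }
  if (isTRUE(eff$ese_planted)) {
    elig <- elig[elig$ese_density >= median(ref$exon_info$ese_density), ]
  }
  pick_variants <- function(pool, n, minimise_w) {
    pos_avail <- unique(pool$gpos)
    if (length(pos_avail) < n) {
      stop("cannot place ", n, " variants: only ", length(pos_avail),
           " eligible sites (enlarge the reference or relax effects)")
    }
    chosen <- sample(pos_avail, n)
    do.call(rbind, lapply(chosen, function(p) {
      rows <- pool[pool$gpos == p, ]
      i <- if (minimise_w) which.min(rows$w_alt) else sample(nrow(rows), 1L)
      rows[i, ]
    }))
  }
  del <- pick_variants(elig, config$n_pos, isTRUE(eff$te_min))
  ben_pool <- cat[!cat$gpos %in% del$gpos, ]
  ben <- pick_variants(ben_pool, config$n_neg, FALSE)
  v <- rbind(
    data.frame(contig = "chrS", pos = del$gpos, ref = del$ref, alt = del$alt,
               label = "deleterious", stringsAsFactors = FALSE),
    data.frame(contig = "chrS", pos = ben$gpos, ref = ben$ref, alt = ben$alt,
               label = "benign", stringsAsFactors = FALSE))
  v <- v[order(v$pos), ]
  rownames(v) <- NULL
  if (!is.null(config$dir)) {
    dir.create(config$dir, recursive = TRUE, showWarnings = FALSE)
    write_vcf(v, ref, file.path(config$dir, "variants.vcf"))
    write.table(v, file.path(config$dir, "labels.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  v
}

write_vcf <- function(variants, ref, path) {
  con <- file(path, "w")
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=chrS,length=%d>",
                       nchar(ref$genome[["chrS"]])),
               paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", sep = "\t")), con)
  writeLines(paste(variants$contig, variants$pos, ".", variants$ref,
                   variants$alt, ".", ".", ".", sep = "\t"), con)
  close(con)
  invisible(path)
}

#' Simulate score tables and annotation tracks
#'
#' Two conservation tables (`cons`, `gerp`; position-keyed), splicing-change
#' z-scores (`dPSIZ`, allele-keyed) and a pure-noise position table (`noise`)
#' are drawn from
#' class-shifted standard normals per the configured effect sizes; a fraction
#' `missing_rate` of keys is omitted from each table to exercise
#' zero-imputation. Boolean annotation tracks (`TFBS`, `histone`) cover each
#' variant with class-dependent probability. With `config$dir` set, writes
#' `cons.tsv`, `gerp.tsv`, `dpsiz.tsv`, `noise.tsv`, `tfbs.bed` and
#' `histone.bed`.
#'
#' @param config A `"sim_config"`.
#' @param variants Labelled variants from [simulate_variants()].
#' @return List of three position-keyed `"score_table"`s (`cons`, `gerp`,
#'   `noise`), one allele-keyed `"score_table"` (`dpsiz`) and two
#'   `"interval_track"`s (`tfbs`, `histone`).
#' @export
simulate_score_tables <- function(config, variants) {
  set.seed(config$seed + 2L)
  eff <- config$effects
  n <- nrow(variants)
  is_del <- variants$label == "deleterious"
  shift <- function(amount) rnorm(n, mean = ifelse(is_del, amount, 0), sd = 1)
  drop_some <- function(d) d[runif(nrow(d)) >= config$missing_rate, ,
                             drop = FALSE]
  cons_df <- drop_some(data.frame(contig = variants$contig,
                                  pos = variants$pos,
                                  score = shift(eff$cons_shift)))
  gerp_df <- drop_some(data.frame(contig = variants$contig,
                                  pos = variants$pos,
                                  score = shift(eff$gerp_shift)))
  noise_df <- drop_some(data.frame(contig = variants$contig,
                                   pos = variants$pos,
                                   score = rnorm(n)))
  dpsiz_df <- drop_some(data.frame(contig = variants$contig,
                                   pos = variants$pos, ref = variants$ref,
                                   alt = variants$alt,
                                   score = shift(eff$dpsiz_shift)))
  make_track <- function(p_del, p_ben, name) {
    covered <- runif(n) < ifelse(is_del, p_del, p_ben)
    gr <- GenomicRanges::GRanges(
      variants$contig[covered],
      IRanges::IRanges(start = pmax(1L, variants$pos[covered] - 2L),
                       end = variants$pos[covered] + 2L))
    interval_track(GenomicRanges::reduce(gr), name)
  }
  out <- list(cons = score_table(cons_df, "position"),
              gerp = score_table(gerp_df, "position"),
              noise = score_table(noise_df, "position"),
              dpsiz = score_table(dpsiz_df, "allele"),
              tfbs = make_track(eff$tfbs_del, eff$tfbs_ben, "TFBS"),
              histone = make_track(eff$histone_del, eff$histone_ben,
                                   "histone"))
  if (!is.null(config$dir)) {
    dir.create(config$dir, recursive = TRUE, showWarnings = FALSE)
    write.table(cons_df, file.path(config$dir, "cons.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(gerp_df, file.path(config$dir, "gerp.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(noise_df, file.path(config$dir, "noise.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(dpsiz_df, file.path(config$dir, "dpsiz.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write_bed <- function(track, path) {
      gr <- track$granges
      d <- data.frame(contig = as.character(GenomicRanges::seqnames(gr)),
                      start0 = GenomicRanges::start(gr) - 1L,
                      end0 = GenomicRanges::end(gr))
      write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
                  col.names = FALSE)
    }
    write_bed(out$tfbs, file.path(config$dir, "tfbs.bed"))
    write_bed(out$histone, file.path(config$dir, "histone.bed"))
  }
  out
}

#' Simulate a complete labelled dataset
#'
#' Runs [simulate_reference()], [simulate_variants()] and
#' [simulate_score_tables()], then assembles the default ten-feature synthetic
#' matrix: `DSP`, `ese_dens`, `MES`, `TE`, `cons`, `gerp`, `dPSIZ`, `TFBS`,
#' `histone`, `noise` — nine signal-bearing features plus one pure-noise
#' column.
#'
#' @param config A `"sim_config"`.
#' @return List: `ref`, `variants`, `tables`, `extractors`, and `fm` (the raw
#'   labelled `"feature_matrix"`, missing values not yet imputed).
#' @export
simulate_dataset <- function(config = sim_config()) {
  ref <- simulate_reference(config)
  variants <- simulate_variants(config, ref)
  tables <- simulate_score_tables(config, variants)
  extractors <- c(
    list(DSP = function(ctx, tx, genome) dsp(ctx, tx)),
    default_extractors(ese = ref$ese, splice = ref$splice, tai = ref$tai,
                       position_scores = list(cons = tables$cons,
                                              gerp = tables$gerp,
                                              noise = tables$noise),
                       allele_scores = list(dPSIZ = tables$dpsiz),
                       tracks = list(tables$tfbs, tables$histone),
                       sequence = FALSE))
  fm <- assemble(variants, ref$transcripts, ref$genome, extractors)
  list(ref = ref, variants = variants, tables = tables,
       extractors = extractors, fm = fm)
}
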