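test_that("read_fasta uppercases, folds lines and rejects duplicates", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">c1 description", "acgt"), fa)
  g <- read_fasta(fa)
  expect_identical(unclass(g), c(c1 = "ACGT"))

  writeLines(c(">c1", "AC", "GT", ">c2", "NNTT"), fa)
  g <- read_fasta(fa)
  expect_identical(unclass(g), c(c1 = "ACGT", c2 = "NNTT"))

  writeLines(c(">c1", "AC", ">c1", "GG"), fa)
  expect_error(read_fasta(fa), "duplicate contig")
})

test_that("read_gtf builds strand-aware transcripts and skips broken CDS", {
  gtf <- withr::local_tempfile(fileext = ".gtf")
  attr1 <- 'gene_id "G1"; transcript_id "T1";'
  writeLines(c(
    paste("c1", "src", "exon", 11, 22, ".", "+", ".", attr1, sep = "\t"),
    paste("c1", "src", "exon", 31, 42, ".", "+", ".", attr1, sep = "\t"),
    paste("c1", "src", "CDS", 11, 22, ".", "+", ".", attr1, sep = "\t"),
    paste("c1", "src", "CDS", 31, 42, ".", "+", ".", attr1, sep = "\t")), gtf)
  txs <- read_gtf(gtf)
  expect_length(txs, 1L)
  expect_identical(txs$T1$exons$start, c(11L, 31L))
  expect_identical(txs$T1$gene, "G1")

  # minus strand: exon rows in any order still come out ascending
  attr2 <- 'gene_id "G2"; transcript_id "T2";'
  writeLines(c(
    paste("c1", "src", "exon", 31, 42, ".", "-", ".", attr2, sep = "\t"),
    paste("c1", "src", "exon", 11, 22, ".", "-", ".", attr2, sep = "\t"),
    paste("c1", "src", "CDS", 11, 22, ".", "-", ".", attr2, sep = "\t"),
    paste("c1", "src", "CDS", 31, 42, ".", "-", ".", attr2, sep = "\t")), gtf)
  txs <- read_gtf(gtf)
  expect_identical(txs$T2$strand, "-")
  expect_identical(txs$T2$exons$start, c(11L, 31L))

  # CDS length 10 (not divisible by 3) -> transcript skipped with a warning
  writeLines(c(
    paste("c1", "src", "exon", 11, 20, ".", "+", ".", attr1, sep = "\t"),
    paste("c1", "src", "CDS", 11, 20, ".", "+", ".", attr1, sep = "\t")), gtf)
  expect_warning(txs <- read_gtf(gtf), "skipped")
  expect_length(txs, 0L)
})

test_that("read_vcf decomposes multiallelic rows and keeps only SNVs", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "##contig=<ID=c1,length=100>",
               paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", sep = "\t"),
               paste("c1", 5, ".", "A", "G", ".", ".", ".", sep = "\t"),
               paste("c1", 9, ".", "C", "T,G", ".", ".", ".", sep = "\t"),
               paste("c1", 20, ".", "AC", "A", ".", ".", ".", sep = "\t")),
             vcf)
  expect_message(v <- read_vcf(vcf), "skipped")
  expect_identical(nrow(v), 3L)           # 1 + 2 decomposed, indel dropped
  expect_identical(v$pos, c(5L, 9L, 9L))
  expect_identical(v$alt, c("G", "T", "G"))
  expect_true(all(v$label == "unknown"))
})

test_that("variant projection reports coding-strand codons on both strands", {
  fp <- fixture_plus()
  # pos 16 = cds_pos 6: codon GAA (index 1), position-in-codon 2
  ctx <- project_variant(fix_variant("c1", 16L, "A", "G"), fp$tx, fp$genome)
  expect_identical(ctx$cds_pos, 6L)
  expect_identical(ctx$codon_index, 1L)
  expect_identical(ctx$pos_in_codon, 2L)
  expect_identical(ctx$ref_codon, "GAA")
  expect_identical(ctx$alt_codon, "GAG")
  expect_identical(ctx$exon_index, 0L)

  # cds_pos 4 (pos 14): codon_index 1, pos_in_codon 0
  ctx4 <- project_variant(fix_variant("c1", 14L, "G", "A"), fp$tx, fp$genome)
  expect_identical(ctx4$codon_index, 1L)
  expect_identical(ctx4$pos_in_codon, 0L)

  # minus-strand twin encodes the same CDS: its cds_pos 6 sits at genomic
  # 37 - 5 = 32; genomic ref is the complement T, alt C -> same codons
  fm <- fixture_minus()
  ctxm <- project_variant(fix_variant("c2", 32L, "T", "C"), fm$tx, fm$genome)
  expect_identical(ctxm$cds_pos, 6L)
  expect_identical(ctxm$ref_codon, "GAA")
  expect_identical(ctxm$alt_codon, "GAG")
  expect_identical(ctxm$exon_index, 0L)

  expect_error(project_variant(fix_variant("c1", 25L, "A", "G"), fp$tx,
                               fp$genome), "not in CDS")
  expect_error(project_variant(fix_variant("c1", 16L, "C", "G"), fp$tx,
                               fp$genome), "reference mismatch")
})

test_that("projection round-trips through cds_to_genomic on both strands", {
  sim <- small_sim()
  for (txid in c("tx01", "tx02")) {       # one gene per strand
    tx <- sim$ref$transcripts[[txid]]
    L <- synforest:::cds_length(tx)
    for (cp in c(1L, 2L, 17L, L %/% 2L, L)) {
      gpos <- synforest:::cds_to_genomic(tx, cp)
      base <- substring(sim$ref$genome[["chrS"]], gpos, gpos)
      alt <- setdiff(c("A", "C", "G", "T"), base)[1L]
      ctx <- project_variant(fix_variant("chrS", gpos, base, alt), tx,
                             sim$ref$genome)
      expect_identical(ctx$cds_pos, cp)
    }
  }
})

test_that("simulated coding sequences translate without internal stops", {
  sim <- small_sim()
  for (tx in sim$ref$transcripts) {
    cds <- synforest:::cds_sequence(tx, sim$ref$genome)
    expect_identical(nchar(cds) %% 3L, 0L)
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds)))
    expect_false(grepl("\\*", substr(aa, 1, nchar(aa) - 1L)))
  }
})

test_that("synonymous status follows the standard genetic code", {
  expect_true(is_synonymous(fake_ctx(1L, ref_codon = "GAA",
                                     alt_codon = "GAG")))
  expect_false(is_synonymous(fake_ctx(1L, ref_codon = "GAA",
                                      alt_codon = "GAC")))
  expect_true(is_synonymous(fake_ctx(1L, ref_codon = "TAA",
                                     alt_codon = "TAG")))  # stop <-> stop
  expect_error(is_synonymous(fake_ctx(1L, ref_codon = "GNA",
                                      alt_codon = "GAA")), "ambiguous")
})

test_that("canonical transcript choice is longest CDS with id tie-break", {
  fp <- fixture_plus()
  short <- transcript(id = "T0", gene = "G1", contig = "c1", strand = "+",
                      exons = data.frame(start = 11L, end = 22L),
                      cds_start = 11L, cds_end = 22L)
  v <- fix_variant("c1", 16L, "A", "G")
  expect_identical(choose_canonical_transcript(v, list(short, fp$tx))$id, "T1")

  twin <- fp$tx
  twin$id <- "T9"
  expect_identical(choose_canonical_transcript(v, list(twin, fp$tx))$id, "T1")
  expect_error(choose_canonical_transcript(fix_variant("c1", 2L, "A", "G"),
                                           list(fp$tx)), "not in any coding")
})

test_that("labels TSV merges onto variants by key", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("contig\tpos\tref\talt\tlabel",
               "c1\t16\tA\tG\tdeleterious"), tsv)
  v <- read_labels(tsv, fix_variant("c1", 16L, "A", "G"))
  expect_identical(v$label, "deleterious")
  writeLines(c("contig\tpos\tref\talt\tlabel", "c1\t16\tA\tG\tbad"), tsv)
  expect_error(read_labels(tsv), "unrecognised label")
})
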