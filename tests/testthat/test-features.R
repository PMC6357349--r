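test_that("splice-distance features follow the documented conventions", {
  tx <- fixture_geometry_tx()
  # internal exon 1001..1100, variant at 1005: nearest boundary 4 nt away
  expect_identical(dsp(fake_ctx(1005L), tx), 4L)
  expect_identical(dsp(fake_ctx(1001L), tx), 0L)       # boundary base
  expect_equal(mde(fake_ctx(1005L), tx), 4 / 50)       # dsp / (len/2)
  expect_equal(mde(fake_ctx(1001L), tx), 0)
  expect_equal(dve(fake_ctx(1005L), tx), 4 / 99)
  expect_equal(dve(fake_ctx(1001L), tx), 0)
  expect_equal(dve(fake_ctx(1100L), tx), 1)

  # first exon of a plus-strand transcript: genomic start is the transcript
  # terminus, so only the 3' boundary counts
  expect_identical(dsp(fake_ctx(905L, exon_index = 0L, exon_len = 60L), tx),
                   55L)

  single <- transcript(id = "S", gene = "S", contig = "cg", strand = "+",
                       exons = data.frame(start = 2001L, end = 2060L),
                       cds_start = 2001L, cds_end = 2060L)
  expect_true(is.na(dsp(fake_ctx(2010L, exon_index = 0L, exon_len = 60L),
                        single)))
  expect_true(is.na(mde(fake_ctx(2010L, exon_index = 0L, exon_len = 60L),
                        single)))
})

test_that("splice-distance features are invariant under coordinate shifts", {
  for (shift in c(0L, 5000L, 1234567L)) {
    tx <- fixture_geometry_tx(shift)
    ctx <- fake_ctx(1005L + shift)
    expect_identical(dsp(ctx, tx), 4L)
    expect_equal(mde(ctx, tx), 0.08)
    expect_equal(dve(ctx, tx), 4 / 99)
  }
})

test_that("CpG context inspects both flanking dinucleotides", {
  g <- structure(c(c = "ACGT"), class = "genome_seq")
  expect_true(cpg_context(fake_ctx(2L, contig = "c"), g))   # the C of CG
  expect_true(cpg_context(fake_ctx(3L, contig = "c"), g))   # the G of CG
  g2 <- structure(c(c = "AATT"), class = "genome_seq")
  for (p in 1:4) expect_false(cpg_context(fake_ctx(p, contig = "c"), g2))
  # contig edges evaluate only the existing neighbour
  g3 <- structure(c(c = "CG"), class = "genome_seq")
  expect_true(cpg_context(fake_ctx(1L, contig = "c"), g3))
  expect_true(cpg_context(fake_ctx(2L, contig = "c"), g3))
})

test_that("relative mRNA position spans (0, 1] over the CDS", {
  tx <- fixture_geometry_tx()      # CDS length 240
  expect_equal(relative_mrna_position(fake_ctx(901L, cds_pos = 1L), tx),
               1 / 240)
  expect_equal(relative_mrna_position(fake_ctx(1240L, cds_pos = 240L), tx), 1)
  # middle base of a 2-codon CDS
  tx2 <- transcript(id = "M", gene = "M", contig = "cg", strand = "+",
                    exons = data.frame(start = 1L, end = 6L),
                    cds_start = 1L, cds_end = 6L)
  expect_equal(relative_mrna_position(fake_ctx(3L, cds_pos = 3L), tx2), 0.5)
})

test_that("RSCU normalises within synonymous families", {
  counts <- stats::setNames(rep(10, length(synforest:::SENSE_CODONS)),
                            synforest:::SENSE_CODONS)
  r <- rscu_table(codon_usage(counts))
  expect_true(all(abs(r - 1) < 1e-12))            # uniform table

  counts["GAA"] <- 30; counts["GAG"] <- 10        # 2-codon Glu family
  r <- rscu_table(codon_usage(counts))
  expect_equal(unname(r["GAA"]), 1.5)
  expect_equal(unname(r["GAG"]), 0.5)
  expect_equal(unname(r["ATG"]), 1)               # single-codon family

  counts["GAA"] <- 0; counts["GAG"] <- 0          # all-zero family
  r <- rscu_table(codon_usage(counts))
  expect_equal(unname(r[c("GAA", "GAG")]), c(0, 0))
})

test_that("RSCU sums to family size for random usage tables", {
  aa <- Biostrings::GENETIC_CODE[synforest:::SENSE_CODONS]
  set.seed(11)
  for (i in 1:20) {
    counts <- stats::setNames(sample(0:50, length(aa), replace = TRUE),
                              names(aa))
    r <- rscu_table(codon_usage(counts))
    for (a in unique(aa)) {
      fam <- names(aa)[aa == a]
      if (sum(counts[fam]) > 0) {
        expect_equal(sum(r[fam]), length(fam))
      }
    }
  }
})

test_that("delta RSCU is antisymmetric and synonymous-only", {
  counts <- stats::setNames(rep(10, length(synforest:::SENSE_CODONS)),
                            synforest:::SENSE_CODONS)
  counts["GAA"] <- 30; counts["GAG"] <- 10
  r <- rscu_table(codon_usage(counts))
  fwd <- fake_ctx(1L, ref_codon = "GAA", alt_codon = "GAG")
  rev <- fake_ctx(1L, ref_codon = "GAG", alt_codon = "GAA")
  expect_equal(delta_rscu(fwd, r), -1)
  expect_equal(delta_rscu(rev, r), 1)
  expect_equal(delta_rscu(fake_ctx(1L, ref_codon = "GGA", alt_codon = "GGC"),
                          r), 0)
  expect_error(delta_rscu(fake_ctx(1L, ref_codon = "GAA", alt_codon = "GAC"),
                          r), "synonymous")
})

test_that("tRNA adaptation weights follow copy numbers with wobble fallback", {
  wc_only <- default_wobble()[1:4, ]   # Watson-Crick rows, s = 0
  # sole decoders: TTC <- anticodon GAA (10 copies), TAC <- GTA (5 copies)
  w <- tai_weights(trna_table(c(GAA = 10, GTA = 5)), wobble = wc_only)
  expect_equal(unname(w["TTC"]), 1)
  expect_equal(unname(w["TAC"]), 0.5)
  # undecoded codons get the geometric mean of the nonzero weights
  expect_equal(unname(w["GGG"]), sqrt(1 * 0.5))
  w2 <- tai_weights(trna_table(c(GAA = 16, GTA = 4)), wobble = wc_only)
  expect_equal(unname(w2["GGG"]), 0.5)   # gm of {1, 0.25}
  # single decoded codon
  w3 <- tai_weights(trna_table(c(GAA = 7)), wobble = wc_only)
  expect_equal(unname(w3["TTC"]), 1)
  expect_true(all(w3 > 0 & w3 <= 1))

  # wobble: anticodon GAA also reads TTT (G:U, s = 0.41)
  w4 <- tai_weights(trna_table(c(GAA = 10)))
  expect_equal(unname(w4["TTT"] / w4["TTC"]), 1 - 0.41)

  expect_error(trna_table(c(GAA = 0)), "copies")
  expect_true(all(tai_weights(small_sim()$ref$trna) > 0))
  expect_equal(max(tai_weights(small_sim()$ref$trna)), 1)
})

test_that("translation-efficiency feature is the log alt-codon weight", {
  w <- c(GAA = 1.0, GAG = 0.5)
  expect_equal(te_feature(fake_ctx(1L, ref_codon = "GAA",
                                   alt_codon = "GAA"), w), 0)
  expect_equal(te_feature(fake_ctx(1L, ref_codon = "GAA",
                                   alt_codon = "GAG"), w), log(0.5))
  expect_equal(te_feature(fake_ctx(1L, ref_codon = "GAG",
                                   alt_codon = "GAA"), w, delta = TRUE),
               -log(0.5))
})

test_that("splice-site scan maximises over variant-overlapping windows", {
  donor <- matrix(log(0.05 / 0.25), 4, 3,
                  dimnames = list(c("A", "C", "G", "T"), NULL))
  donor["G", 1] <- donor["T", 2] <- donor["A", 3] <- log(0.85 / 0.25)
  model <- splice_model(donor = donor, acceptor = donor, donor_exonic = 1L,
                        acceptor_exonic = 1L)
  g <- structure(c(cg = "CCCCGTACCCC"), class = "genome_seq")
  tx <- list(contig = "cg", strand = "+")
  # GTA at positions 5..7 is the consensus; variant at 6 overlaps it
  ctx <- fake_ctx(6L, ref = "T", alt = "C")
  expect_equal(max_splice_site_score(ctx, tx, g, model),
               3 * log(0.85 / 0.25))
  # alt destroys the consensus: best window now scores strictly less
  expect_lt(max_splice_site_score(ctx, tx, g, model, use_alt = TRUE),
            max_splice_site_score(ctx, tx, g, model))
  # alt equal to ref leaves the score unchanged
  ctx_same <- fake_ctx(6L, ref = "T", alt = "T")
  expect_equal(max_splice_site_score(ctx_same, tx, g, model, use_alt = TRUE),
               max_splice_site_score(ctx_same, tx, g, model))
  # the maximum dominates every individual window score
  set.seed(3)
  for (i in 1:10) {
    seq <- paste(sample(c("A", "C", "G", "T"), 15, replace = TRUE),
                 collapse = "")
    g2 <- structure(c(cg = seq), class = "genome_seq")
    ctx2 <- fake_ctx(8L, ref = substring(seq, 8, 8),
                     alt = substring(seq, 8, 8))
    best <- max_splice_site_score(ctx2, tx, g2, model)
    for (st in 6:8) {
      expect_gte(best, synforest:::score_pwm_window(
        donor, substring(seq, st, st + 2)))
    }
  }
})

test_that("ESE density counts hexamer windows", {
  ms <- motif_set(hexamers = "GAAGAA")
  expect_equal(ese_density("GAAGAAGAA", ms), 0.5)    # 2 hits in 4 windows
  expect_equal(ese_density("CCCCCCCCC", ms), 0)
  expect_equal(ese_density("GAAGA", ms), 0)          # shorter than a hexamer
  # reverse-closed (palindromic-set) invariance
  pal <- motif_set(hexamers = c("GAATTC", "CTTAAG"))
  s <- "AGAATTCTTAAGGA"
  rev_s <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
  expect_equal(ese_density(s, pal), ese_density(rev_s, pal))
})

test_that("motif gain/loss counts hits symmetrically", {
  ms <- motif_set(hexamers = "GAAGAA")
  ref <- "CCGAAGAACC"                      # one hit
  alt <- "CCGAAGTACC"                      # destroyed
  expect_identical(motif_gain_loss(ref, alt, ms),
                   c(gained = 0L, lost = 1L))
  expect_identical(motif_gain_loss(alt, ref, ms),
                   c(gained = 1L, lost = 0L))
  expect_identical(motif_gain_loss(ref, ref, ms),
                   c(gained = 0L, lost = 0L))
  expect_error(motif_gain_loss("AAA", "AAAA", ms), "length")
  # PWM kind: threshold at the consensus score
  mat <- matrix(-1, 4, 3, dimnames = list(c("A", "C", "G", "T"), NULL))
  mat["G", 1] <- mat["T", 2] <- mat["A", 3] <- 1
  pw <- motif_set(pwms = list(list(name = "m", mat = mat, threshold = 3)))
  expect_identical(motif_gain_loss("CGTAC", "CGCAC", pw),
                   c(gained = 0L, lost = 1L))
})

test_that("variant windows truncate at exon boundaries on both strands", {
  fp <- fixture_plus()
  ctx <- project_variant(fix_variant("c1", 16L, "A", "G"), fp$tx, fp$genome)
  w <- variant_windows(ctx, fp$tx, fp$genome, flank = 5L)
  expect_identical(nchar(w$ref), 11L)
  expect_identical(substring(w$ref, 6L, 6L), "A")
  expect_identical(substring(w$alt, 6L, 6L), "G")
  # near the exon edge the window is clipped: pos 12 has one exonic base left
  ctx2 <- project_variant(fix_variant("c1", 12L, "T", "C"), fp$tx, fp$genome)
  w2 <- variant_windows(ctx2, fp$tx, fp$genome, flank = 5L)
  expect_identical(nchar(w2$ref), 7L)
  # minus-strand twin yields the coding-strand window
  fmx <- fixture_minus()
  ctxm <- project_variant(fix_variant("c2", 32L, "T", "C"), fmx$tx,
                          fmx$genome)
  wm <- variant_windows(ctxm, fmx$tx, fmx$genome, flank = 5L)
  expect_identical(wm$ref, w$ref)
  expect_identical(wm$alt, w$alt)
})

test_that("hexamer and PWM resources round-trip through their file formats", {
  hx <- withr::local_tempfile(fileext = ".txt")
  write_hexamers(motif_set(hexamers = c("GAAGAA", "CCTTCC")), hx)
  ms <- read_hexamers(hx)
  expect_setequal(ms$hexamers, c("GAAGAA", "CCTTCC"))
  expect_error(motif_set(hexamers = "GAAG"), "invalid hexamer")

  pf <- withr::local_tempfile(fileext = ".pwm")
  mat <- matrix(round(rnorm(12), 3), 4,
                dimnames = list(c("A", "C", "G", "T"), NULL))
  write_pwms(motif_set(pwms = list(list(name = "m1", mat = mat,
                                        threshold = 1.5))), pf)
  back <- read_pwms(pf)
  expect_equal(back$pwms[[1]]$mat, mat, ignore_attr = TRUE)
  expect_equal(back$pwms[[1]]$threshold, 1.5)

  cu <- withr::local_tempfile(fileext = ".tsv")
  counts <- stats::setNames(seq_along(synforest:::SENSE_CODONS),
                            synforest:::SENSE_CODONS)
  write.table(data.frame(codon = names(counts), count = counts), cu,
              sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(as.numeric(read_codon_usage(cu)), unname(counts))

  tt <- withr::local_tempfile(fileext = ".tsv")
  write.table(data.frame(anticodon = c("GAA", "GTA"), copies = c(10, 5)), tt,
              sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(unname(unclass(read_trna_table(tt))), c(10, 5))
})
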