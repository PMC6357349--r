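# Hand-built fixtures shared across test files. The two-transcript toy pair
# encodes the SAME coding sequence on opposite strands, so strand-symmetry
# properties can be asserted by comparing projections across the pair.

# 8 sense codons, no stops: ATG GAA GAG TGC CTG CTA AGC TAC
FIX_CDS <- "ATGGAAGAGTGCCTGCTAAGCTAC"

# plus-strand: c1 = 10 nt prefix | exon1 (11..22) | 8 nt intron | exon2
# (31..42) | 8 nt suffix
fixture_plus <- function() {
  genome <- structure(
    c(c1 = paste0("AAAAACCCCC", substr(FIX_CDS, 1, 12), "GTAAGCAG",
                  substr(FIX_CDS, 13, 24), "GGGGTTTT")),
    class = "genome_seq")
  tx <- transcript(id = "T1", gene = "G1", contig = "c1", strand = "+",
                   exons = data.frame(start = c(11L, 31L), end = c(22L, 42L)),
                   cds_start = 11L, cds_end = 42L)
  list(genome = genome, tx = tx)
}

# minus-strand twin: same CDS, gene reverse-complemented onto c2 at 6..37
fixture_minus <- function() {
  gene_coding <- paste0(substr(FIX_CDS, 1, 12), "GTAAGCAG",
                        substr(FIX_CDS, 13, 24))
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(gene_coding)))
  genome <- structure(c(c2 = paste0("TTTTT", rc, "AAAAAAAA")),
                      class = "genome_seq")
  # coding exon1 = coding offsets 1..12 -> genomic 26..37; exon2 -> 6..17
  tx <- transcript(id = "T2", gene = "G2", contig = "c2", strand = "-",
                   exons = data.frame(start = c(6L, 26L), end = c(17L, 37L)),
                   cds_start = 6L, cds_end = 37L)
  list(genome = genome, tx = tx)
}

fix_variant <- function(contig, pos, ref, alt, label = "unknown") {
  data.frame(contig = contig, pos = pos, ref = ref, alt = alt, label = label,
             stringsAsFactors = FALSE)
}

# three-exon transcript for splice-geometry arithmetic: internal exon
# 1001..1100 hosts the variants; CDS length 240
fixture_geometry_tx <- function(shift = 0L) {
  transcript(id = "TG", gene = "GG", contig = "cg", strand = "+",
             exons = data.frame(start = c(901L, 1001L, 1161L) + shift,
                                end = c(960L, 1100L, 1240L) + shift),
             cds_start = 901L + shift, cds_end = 1240L + shift)
}

# minimal coding_context for geometry/sequence extractors that only touch a
# few fields
fake_ctx <- function(pos, exon_index = 1L, exon_len = 100L, contig = "cg",
                     ref = "A", alt = "G", cds_pos = 1L,
                     ref_codon = "GAA", alt_codon = "GAG") {
  structure(list(variant = list(contig = contig, pos = pos, ref = ref,
                                alt = alt),
                 transcript_id = "TG", cds_pos = cds_pos,
                 codon_index = (cds_pos - 1L) %/% 3L,
                 pos_in_codon = (cds_pos - 1L) %% 3L,
                 ref_codon = ref_codon, alt_codon = alt_codon,
                 ref_aa = Biostrings::GENETIC_CODE[ref_codon][[1L]],
                 alt_aa = Biostrings::GENETIC_CODE[alt_codon][[1L]],
                 exon_index = exon_index, exon_len = exon_len),
            class = "coding_context")
}

# Gaussian two-class feature matrix: `informative` shifted columns plus
# `noise` pure-noise columns; used by the learning-module tests where genomic
# structure is irrelevant.
gaussian_fm <- function(n_per_class = 30L, informative = 2L, noise = 1L,
                        shift = 2, seed = 42L) {
  set.seed(seed)
  n <- 2L * n_per_class
  labels <- rep(c(1, 0), each = n_per_class)
  cols <- list()
  for (i in seq_len(informative)) {
    cols[[sprintf("inf%d", i)]] <- rnorm(n, mean = labels * shift)
  }
  for (i in seq_len(noise)) {
    cols[[sprintf("noise%d", i)]] <- rnorm(n)
  }
  v <- do.call(cbind, cols)
  rownames(v) <- sprintf("v%03d", seq_len(n))
  feature_matrix(v, labels = labels)
}

# small end-to-end simulated dataset, built once per test run
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_dataset(sim_config(seed = 7, n_genes = 16,
                                            n_pos = 50, n_neg = 50))
    }
    cache
  }
})
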