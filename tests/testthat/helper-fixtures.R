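# Shared fixtures, built in code at test time.

# Twelve phased markers on a 1,078 kb chromosome with the centromere at
# 151 kb: two left-arm markers and a right-arm ladder whose spacing around
# the selectable locus (301 kb) reproduces the geometry of a
# PCR-RFLP-genotyped heterozygous interval bounded distally by a repeat
# array (most distal marker 450 kb).
CEN12 <- 151000

fig3_like_map <- function() {
  pos <- c(30e3, 40e3, 158e3, 199e3, 227e3, 292e3,
           297.3e3, 301e3, 306e3, 350e3, 400e3, 450e3)
  marker_map(chrom = "chr12", pos = pos,
             allele_M = rep(c("A", "T"), 6),
             allele_P = rep(c("G", "C"), 6))
}

# calls vector over fig3_like_map markers, all heterozygous
all_het_calls <- function(map) {
  calls <- rep("H", nrow(map))
  names(calls) <- map$marker_id
  calls
}

# a single biallelic site across n tetrads, each segregating its two
# alleles according to 'split' (e.g. c(2, 2) or c(3, 1))
make_site <- function(n_tetrads = 14, split = c(2, 2),
                      alleles = c("A", "G"), odd_tetrad = NULL,
                      odd_split = c(3, 1)) {
  calls <- character(0)
  tet <- character(0)
  for (t in seq_len(n_tetrads)) {
    s <- if (!is.null(odd_tetrad) && t == odd_tetrad) odd_split else split
    calls <- c(calls, rep(alleles[1], s[1]), rep(alleles[2], s[2]))
    tet <- c(tet, rep(sprintf("t%02d", t), 4))
  }
  names(calls) <- sprintf("t%02d_s%d", rep(seq_len(n_tetrads), each = 4), 1:4)
  names(tet) <- names(calls)
  list(calls = calls, tetrad_of = tet)
}

# small dense single-chromosome genome for phasing / scanning tests
dense_config <- function(n_markers_per_kb = 1, length_bp = 1e5) {
  sim_genome_config(
    chromosomes = data.frame(name = "chrA", length = length_bp,
                             centromere = round(length_bp / 5)),
    het_blocks = data.frame(chrom = "chrA", start = 1, end = length_bp),
    marker_density = n_markers_per_kb)
}
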