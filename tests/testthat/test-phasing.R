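test_that("2:2 filter keeps clean biallelic sites and drops violations", {
  ok <- make_site(14, c(2, 2))
  expect_true(site_high_confidence(ok$calls, ok$tetrad_of)$keep)

  gc_like <- make_site(14, c(2, 2), odd_tetrad = 7, odd_split = c(3, 1))
  res <- site_high_confidence(gc_like$calls, gc_like$tetrad_of)
  expect_false(res$keep)
  expect_equal(res$reason, "non-2:2 tetrad")

  tri <- make_site(3, c(2, 2))
  tri$calls[1] <- "T"  # third allele
  expect_equal(site_high_confidence(tri$calls, tri$tetrad_of)$reason,
               "not biallelic")

  mono <- make_site(3, c(4, 0))
  expect_equal(site_high_confidence(mono$calls, mono$tetrad_of)$reason,
               "monomorphic")

  # three incomplete tetrads exceed the default allowance of two
  sparse <- make_site(5, c(2, 2))
  sparse$calls[c(1, 5, 9)] <- NA
  expect_equal(site_high_confidence(sparse$calls, sparse$tetrad_of)$reason,
               "insufficient data")
  expect_true(site_high_confidence(sparse$calls, sparse$tetrad_of,
                                   max_missing_tetrads = 3)$keep)

  empty <- make_site(2, c(2, 2))
  empty$calls[] <- NA
  expect_error(site_high_confidence(empty$calls, empty$tetrad_of), "no calls")
})

test_that("every retained marker recounts as 2:2 in every complete tetrad", {
  p <- simulate_parent(dense_config(), seed = 11)
  tet <- simulate_tetrads(p$map, n_tetrads = 14, crossover_rate = 1,
                          error_rate = 0.02, missing_rate = 0.01, seed = 12)
  flt <- filter_hetsnp_sites(tet$alleles, tet$tetrad_of)
  kept <- which(flt$keep)
  for (i in kept) {
    row <- tet$alleles[i, ]
    al <- sort(unique(row[!is.na(row)]))
    for (tt in unique(tet$tetrad_of)) {
      four <- row[names(tet$tetrad_of)[tet$tetrad_of == tt]]
      if (anyNA(four)) next
      expect_identical(as.integer(table(factor(four, levels = al))),
                       c(2L, 2L))
    }
  }
})

test_that("error-injected drop fraction equals a brute-force recount", {
  # independent recount written from the definition, via table()
  brute_keep <- function(row, tetrad_of, max_missing = 2) {
    obs <- row[!is.na(row)]
    if (length(obs) == 0) return(FALSE)
    al <- unique(obs)
    if (length(al) != 2) return(FALSE)
    incomplete <- 0
    for (tt in unique(tetrad_of)) {
      four <- row[names(tetrad_of)[tetrad_of == tt]]
      if (length(four) < 4 || anyNA(four)) { incomplete <- incomplete + 1; next }
      tab <- table(four)
      if (length(tab) != 2 || any(tab != 2)) return(FALSE)
    }
    incomplete <= max_missing && incomplete < length(unique(tetrad_of))
  }
  p <- simulate_parent(dense_config(1, 1e6), seed = 21)  # ~1,000 sites
  expect_gt(nrow(p$map), 800)
  tet <- simulate_tetrads(p$map, n_tetrads = 14, crossover_rate = 1,
                          error_rate = 0.02, seed = 22)
  flt <- filter_hetsnp_sites(tet$alleles, tet$tetrad_of)
  expected <- vapply(seq_len(nrow(tet$alleles)), function(i) {
    row <- tet$alleles[i, ]
    names(row) <- colnames(tet$alleles)
    brute_keep(row, tet$tetrad_of)
  }, logical(1))
  expect_identical(flt$keep, expected)
  expect_gt(sum(!flt$keep), 0)  # 2% error at 56 spores must drop sites
})

test_that("perfectly linked markers phase into one block at confidence 1", {
  alleles <- rbind(rep(c("A", "G"), each = 4),
                   rep(c("T", "C"), each = 4))
  colnames(alleles) <- sprintf("t%02d_s%d", rep(1:2, each = 4), 1:4)
  rownames(alleles) <- c("m1", "m2")
  map <- phase_chromosome(alleles, pos = c(100, 200), chrom = "chr1")
  expect_equal(unique(map$block), 1L)
  expect_equal(map$confidence[2], 1.0)
  # canonical: first marker lex-smaller allele (A) is M, and T rides with A
  expect_equal(map$allele_M, c("A", "T"))
  expect_equal(map$allele_P, c("G", "C"))
})

test_that("phasing recovers planted phase up to a global flip per block", {
  cfg <- dense_config(1, 1e5)  # ~100 markers
  for (seed in c(31, 32, 33)) {
    p <- simulate_parent(cfg, seed = seed)
    tet <- simulate_tetrads(p$map, n_tetrads = 14, crossover_rate = 1,
                            seed = seed + 100)
    got <- phase_chromosome(tet$alleles, p$map$pos, "chrA")
    stopifnot(nrow(got) == nrow(p$map))
    agree <- got$allele_M == p$map$allele_M
    # orient each block to the planted map, then count matches
    frac <- mean(unlist(lapply(split(agree, got$block), function(a) {
      if (mean(a) >= 0.5) a else !a
    })))
    expect_gte(frac, 0.99)
  }
})

test_that("zero crossovers and zero error give exact phase, confidence 1", {
  p <- simulate_parent(dense_config(0.5, 5e4), seed = 41)
  tet <- simulate_tetrads(p$map, n_tetrads = 3, crossover_rate = 0, seed = 42)
  got <- phase_chromosome(tet$alleles, p$map$pos, "chrA")
  expect_equal(unique(got$block), 1L)
  expect_true(all(got$confidence[-1] == 1))
  agree <- got$allele_M == p$map$allele_M
  expect_true(all(agree) || all(!agree))
})

test_that("phased map is invariant under a global allele swap", {
  p <- simulate_parent(dense_config(0.5, 1e5), seed = 51)
  tet <- simulate_tetrads(p$map, n_tetrads = 14, crossover_rate = 1, seed = 52)
  a <- tet$alleles
  mm <- p$map$allele_M[match(rownames(a), p$map$marker_id)]
  pp <- p$map$allele_P[match(rownames(a), p$map$marker_id)]
  swapped <- ifelse(a == mm, pp, mm)
  dimnames(swapped) <- dimnames(a)
  m1 <- phase_chromosome(a, p$map$pos, "chrA")
  m2 <- phase_chromosome(swapped, p$map$pos, "chrA")
  expect_identical(as.data.frame(m1), as.data.frame(m2))
})

test_that("a 50/50 adjacency breaks the chain into unphaseable blocks", {
  # marker 2 agrees with marker 1 in exactly half the spores
  m1 <- rep(c("A", "G"), each = 4)
  m2 <- c("T", "T", "C", "C", "T", "T", "C", "C")
  alleles <- rbind(m1, m2)
  colnames(alleles) <- sprintf("t%02d_s%d", rep(1:2, each = 4), 1:4)
  map <- phase_chromosome(alleles, pos = c(100, 200), chrom = "chr1")
  expect_equal(map$block, c(1L, 2L))
  expect_true(map$unphaseable[2])
  expect_true(is.na(map$confidence[2]))
})

test_that("encoding against a map round-trips and flags foreign alleles", {
  mp <- marker_map("chr1", c(100, 200, 300),
                   allele_M = c("A", "T", "G"), allele_P = c("G", "C", "A"))
  # haploid trivial vectors
  allM <- stats::setNames(mp$allele_M, mp$marker_id)
  expect_equal(unname(encode_against_map(allM, mp, "haploid")),
               rep("M", 3))
  # diploid all-het
  both <- stats::setNames(paste(mp$allele_M, mp$allele_P, sep = "/"),
                          mp$marker_id)
  expect_equal(unname(encode_against_map(both, mp, "diploid")),
               rep("H", 3))
  # random planted mosaics round-trip through decode -> encode
  set.seed(61)
  for (i in 1:20) {
    phase <- sample(c("M", "P", NA), 3, replace = TRUE)
    calls <- decode_phase(phase, mp)
    back <- encode_against_map(calls[!is.na(calls)], mp, "haploid")
    expect_equal(unname(back), phase)
  }
  expect_error(encode_against_map(c(chr1_100 = "T"), mp, "haploid"),
               "allele mismatch")
  expect_error(encode_against_map(c(chr1_100 = "A/T"), mp, "diploid"),
               "allele mismatch")
})
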