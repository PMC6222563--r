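carrier_matrix <- function(a_carriers, alpha_carriers, n_a = 6, n_alpha = 6) {
  carriers <- c(stats::setNames(seq_len(n_a) <= a_carriers,
                                sprintf("a%d", seq_len(n_a))),
                stats::setNames(seq_len(n_alpha) <= alpha_carriers,
                                sprintf("b%d", seq_len(n_alpha))))
  mt <- stats::setNames(rep(c("a", "alpha"), c(n_a, n_alpha)), names(carriers))
  simulate_cross_matrix(carriers, mt)
}

test_that("a 2-by-4 carrier split yields 8 rough / 28 smooth and is recovered", {
  m <- carrier_matrix(2, 4)
  expect_equal(sum(m == "R"), 8)
  expect_equal(sum(m == "S"), 28)
  inf <- infer_carriers(m)
  expect_true(inf$consistent)
  expect_setequal(inf$confirmed_carriers, c("a1", "a2", "b1", "b2", "b3", "b4"))
  expect_setequal(inf$confirmed_noncarriers,
                  c("a3", "a4", "a5", "a6", "b5", "b6"))
  expect_length(inf$unknown, 0)
})

test_that("an all-rough matrix confirms every haploid as carrier", {
  m <- carrier_matrix(6, 6)
  expect_equal(sum(m == "R"), 36)
  inf <- infer_carriers(m)
  expect_true(inf$consistent)
  expect_length(inf$confirmed_carriers, 12)
})

test_that("an all-smooth matrix identifies nobody but stays consistent", {
  m <- carrier_matrix(0, 0)
  inf <- infer_carriers(m)
  expect_true(inf$consistent)
  expect_length(inf$confirmed_carriers, 0)
  expect_length(inf$confirmed_noncarriers, 0)
  expect_length(inf$unknown, 12)
})

test_that("a smooth cross between two confirmed carriers is a witnessed inconsistency", {
  m <- carrier_matrix(2, 2)
  m["a1", "b1"] <- "S"  # contradicts carrier x carrier -> rough
  inf <- infer_carriers(m)
  expect_false(inf$consistent)
  expect_false(is.null(inf$witness))
  expect_equal(inf$witness$phenotype, "S")
})

test_that("consistent inferences replay to reproduce every tested cell", {
  set.seed(71)
  for (i in 1:25) {
    truth <- c(stats::setNames(stats::runif(6) < 0.5, sprintf("a%d", 1:6)),
               stats::setNames(stats::runif(6) < 0.5, sprintf("b%d", 1:6)))
    mt <- stats::setNames(rep(c("a", "alpha"), each = 6), names(truth))
    m <- simulate_cross_matrix(truth, mt)
    m[sample(length(m), 5)] <- NA  # some crosses untested
    if (all(is.na(m))) next
    inf <- infer_carriers(m)
    expect_true(inf$consistent)
    # confirmed sets must agree with the generating assignment
    expect_true(all(truth[inf$confirmed_carriers]))
    expect_false(any(truth[inf$confirmed_noncarriers]))
    # replay: assign unknowns FALSE, check every tested cell
    assign <- stats::setNames(names(truth) %in% inf$confirmed_carriers,
                              names(truth))
    assign[inf$unknown] <- truth[inf$unknown]
    for (a in rownames(m)) for (b in colnames(m)) {
      if (is.na(m[a, b])) next
      expect_equal(m[a, b], if (assign[a] && assign[b]) "R" else "S")
    }
  }
})

test_that("strict co-segregation passes only clean oriented splits", {
  mp <- marker_map("chr1", c(100, 200, 300),
                   allele_M = c("A", "A", "A"), allele_P = c("G", "G", "G"))
  v <- rbind(s1 = c("M", "M", "M"), s2 = c("M", "P", "M"),
             s3 = c("P", "P", NA), s4 = c("P", "M", "P"))
  colnames(v) <- mp$marker_id
  sc <- cosegregation_scan(v, mp, c("s1", "s2"), c("s3", "s4"))
  expect_equal(sc$pass, c(TRUE, FALSE, FALSE))  # marker 3: missing call
  expect_equal(sc$orientation[1], "group1=M")
  # mirror orientation passes with the flipped label
  sc2 <- cosegregation_scan(v, mp, c("s3", "s4"), c("s1", "s2"))
  expect_equal(sc2$pass, sc$pass)
  expect_equal(sc2$orientation[1], "group1=P")
  # tolerating the missing call lets marker 3 pass
  sc3 <- cosegregation_scan(v, mp, c("s1", "s2"), c("s3", "s4"),
                            max_missing = 1)
  expect_true(sc3$pass[3])
  expect_error(cosegregation_scan(v, mp, c("s1", "zz"), c("s3", "s4")),
               "index mismatch")
})

test_that("raising max_missing never removes a passing marker", {
  p <- simulate_parent(dense_config(0.5, 1e5), seed = 81)
  tet <- simulate_tetrads(p$map, n_tetrads = 3, crossover_rate = 1,
                          missing_rate = 0.1, seed = 82)
  enc <- encode_cohort(tet$alleles, p$map, "haploid")
  g1 <- rownames(enc)[1:6]; g2 <- rownames(enc)[7:12]
  prev <- rep(FALSE, nrow(p$map))
  for (mm in 0:4) {
    sc <- cosegregation_scan(enc, p$map, g1, g2, max_missing = mm)
    expect_true(all(sc$pass[prev]))
    prev <- sc$pass
  }
})

test_that("scan matches a per-marker brute force and brackets the planted locus", {
  cfg <- sim_genome_config_jay270(marker_density = 0.05)  # 16 chromosomes
  p <- simulate_parent(cfg, seed = 91)
  tet <- simulate_tetrads(p$map, n_tetrads = 3, crossover_rate = 1, seed = 92)
  locus <- p$map$marker_id[which(p$map$chrom == "chr12")[5]]
  carr <- carriers_at_marker(tet$phase, locus)
  enc <- encode_cohort(tet$alleles, p$map, "haploid")
  g1 <- names(carr)[carr]; g2 <- names(carr)[!carr]
  expect_length(g1, 6)  # 2:2 segregation over 3 tetrads
  sc <- cosegregation_scan(enc, p$map, g1, g2)

  brute <- vapply(seq_len(nrow(p$map)), function(j) {
    a <- enc[g1, j]; b <- enc[g2, j]
    if (anyNA(c(a, b))) return(FALSE)
    (all(a == "M") && all(b == "P")) || (all(a == "P") && all(b == "M"))
  }, logical(1))
  expect_identical(sc$pass, brute)

  reg <- merge_candidate_regions(sc, p$map)
  locus_pos <- p$map$pos[p$map$marker_id == locus]
  hit <- reg$chrom == "chr12" & reg$start_pos <= locus_pos &
    reg$end_pos >= locus_pos
  expect_equal(sum(hit), 1)
})

test_that("passing runs merge into regions split by failing markers", {
  mp <- marker_map("chr1", c(10e3, 12e3, 15e3, 20e3),
                   allele_M = rep("A", 4), allele_P = rep("G", 4))
  sc <- data.frame(marker_id = mp$marker_id, chrom = mp$chrom, pos = mp$pos,
                   pass = c(TRUE, TRUE, FALSE, TRUE),
                   orientation = c("group1=M", "group1=M", NA, "group1=M"),
                   n_missing = 0L, stringsAsFactors = FALSE)
  reg <- merge_candidate_regions(sc, mp)
  expect_equal(nrow(reg), 2)
  expect_equal(reg$start_pos, c(10e3, 20e3))
  expect_equal(reg$end_pos, c(12e3, 20e3))
  expect_equal(reg$n_markers, c(2L, 1L))

  # flank extension moves boundaries to midpoints with failing neighbours
  rege <- merge_candidate_regions(sc, mp, extend_to_flanks = TRUE)
  expect_equal(rege$end_pos[1], (12e3 + 15e3) / 2)
  expect_equal(rege$start_pos[2], (15e3 + 20e3) / 2)

  # gene overlap counting (any shared bp)
  genes <- data.frame(chrom = "chr1",
                      start = c(9e3, 11.5e3, 19e3, 30e3),
                      end = c(9.5e3, 13e3, 21e3, 31e3))
  regg <- merge_candidate_regions(sc, mp, genes = genes)
  expect_equal(regg$n_genes, c(1L, 1L))

  none <- sc; none$pass <- FALSE; none$orientation <- NA
  expect_equal(nrow(merge_candidate_regions(none, mp)), 0)
})
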