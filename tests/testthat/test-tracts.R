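test_that("endpoint midpoints are the average of the flanking markers", {
  expect_equal(endpoint_midpoint(227000, 292000), 259500)
  expect_equal(endpoint_midpoint(292000, 227000), 259500)
  expect_error(endpoint_midpoint(1e5, 1e5), "differ")
})

test_that("a one-marker event is bounded by its immediate flanking markers", {
  mp <- fig3_like_map()
  calls <- all_het_calls(mp)
  calls["chr12_301000"] <- "M"  # selected locus only
  ct <- call_tracts(calls, mp, CEN12)
  expect_equal(nrow(ct$tracts), 1)
  tr <- ct$tracts[1, ]
  expect_equal(tr$direction, "M")
  expect_false(tr$reaches_last_marker)
  expect_equal(tr$min_span_bp, 0)
  expect_equal(tr$max_span_bp, 8700)  # 306.0 kb - 297.3 kb flanks
  expect_equal(tr$endpoint_proximal_bp, (297300 + 301000) / 2)
  cls <- classify_clone(ct, mp, CEN12, "chr12_301000", "M")
  expect_equal(cls$class, "simple")
  expect_false(cls$coincident)
})

test_that("a terminal tract plus an opposite-arm event is simple and coincident", {
  mp <- fig3_like_map()
  calls <- all_het_calls(mp)
  calls[mp$pos >= 292000] <- "M"          # right arm, to the last marker
  calls[mp$pos < CEN12] <- "P"            # unselected left-arm event
  ct <- call_tracts(calls, mp, CEN12)
  expect_equal(nrow(ct$tracts), 2)
  right <- ct$tracts[ct$tracts$arm == "right", ]
  expect_true(right$reaches_last_marker)
  expect_equal(right$endpoint_proximal_bp, (227000 + 292000) / 2)
  expect_true(is.na(right$endpoint_distal_bp))
  left <- ct$tracts[ct$tracts$arm == "left", ]
  expect_equal(left$direction, "P")
  expect_equal(ct$arm_status[["left"]], "uninformative")  # no left-arm het
  cls <- classify_clone(ct, mp, CEN12, "chr12_301000", "M")
  expect_equal(cls$class, "simple")
  expect_true(cls$coincident)
})

test_that("all-heterozygous clones carry no tract; interruption is complex", {
  mp <- fig3_like_map()
  expect_equal(nrow(call_tracts(all_het_calls(mp), mp, CEN12)$tracts), 0)
  calls <- all_het_calls(mp)
  calls[c("chr12_297300", "chr12_306000")] <- "M"  # M, H, M around the locus
  calls["chr12_301000"] <- "H"
  ct <- call_tracts(calls, mp, CEN12)
  expect_equal(nrow(ct$tracts), 2)
  cls <- classify_clone(ct, mp, CEN12, "chr12_301000", "M")
  expect_equal(cls$class, "complex")
  # homozygosity against the direction of selection is complex too
  calls2 <- all_het_calls(mp)
  calls2["chr12_301000"] <- "P"
  cls2 <- classify_clone(call_tracts(calls2, mp, CEN12), mp, CEN12,
                         "chr12_301000", "M")
  expect_equal(cls2$class, "complex")
})

test_that("missing calls are transparent unless asked to break runs", {
  mp <- fig3_like_map()
  calls <- all_het_calls(mp)
  calls[c("chr12_292000", "chr12_301000")] <- "M"
  calls["chr12_297300"] <- NA  # genotyping gap inside the run
  ct <- call_tracts(calls, mp, CEN12)
  expect_equal(nrow(ct$tracts), 1)
  expect_equal(ct$tracts$first_hom_pos, 292000)
  expect_equal(ct$tracts$last_hom_pos, 301000)
  # proximal endpoint uses the nearest informative marker, not the gap
  expect_equal(ct$tracts$endpoint_proximal_bp, (227000 + 292000) / 2)
  split <- call_tracts(calls, mp, CEN12, missing_breaks = TRUE)
  expect_equal(nrow(split$tracts), 2)
})

test_that("an arm without markers or without het calls is reported as such", {
  mp <- as_marker_map(as.data.frame(fig3_like_map())[-(1:2), ])  # right arm only
  calls <- rep("H", nrow(mp)); names(calls) <- mp$marker_id
  ct <- call_tracts(calls, mp, CEN12)
  expect_equal(ct$arm_status[["left"]], "no markers")
  expect_equal(ct$arm_status[["right"]], "ok")
})

test_that("endpoint tallies match brute-force binning into half-open intervals", {
  iv <- data.frame(left_pos = c(151000, 158000, 199000, 227000, 292000),
                   right_pos = c(158000, 199000, 227000, 292000, 297300))
  # marker-position endpoint goes to the interval ending there
  tab <- tally_endpoints(c(158000), iv)
  expect_equal(tab$O, c(1L, 0L, 0L, 0L, 0L))
  expect_equal(tally_endpoints(numeric(0), iv)$O, rep(0L, 5))
  set.seed(121)
  eps <- stats::runif(43, 140000, 300000)
  expect_warning(tab <- tally_endpoints(eps, iv), "outside")
  brute <- vapply(seq_len(5), function(j)
    sum(eps > iv$left_pos[j] & eps <= iv$right_pos[j]), numeric(1))
  expect_equal(tab$O, as.integer(brute))
  expect_equal(sum(tab$O) + attr(tab, "n_outside"), 43L)
  expect_equal(tab$L, iv$right_pos - iv$left_pos)
})

test_that("the interval-size chi-square follows the J-1 df convention", {
  # counts exactly proportional to interval sizes: no signal
  L <- c(10, 20, 30, 40)
  flat <- suppressWarnings(chisq_size_model(c(1, 2, 3, 4), L))
  expect_equal(flat$chi2, 0)
  expect_equal(flat$p, 1)
  expect_equal(flat$df, 3L)
  # conservation: expected counts sum to observed
  set.seed(131)
  for (i in 1:15) {
    J <- sample(3:8, 1)
    O <- stats::rpois(J, 20); L <- stats::runif(J, 1, 100)
    if (sum(O) == 0) next
    got <- suppressWarnings(chisq_size_model(O, L))
    E <- sum(O) * L / sum(L)
    expect_equal(sum(got$expected), sum(O))
    expect_equal(got$chi2, sum((O - E)^2 / E))  # textbook formula
    expect_equal(got$p, exp(stats::pchisq(got$chi2, J - 1, lower.tail = FALSE,
                                          log.p = TRUE)))
  }
  expect_warning(chisq_size_model(c(1, 1, 1), c(1, 1, 1)), "below 5")
  expect_error(chisq_size_model(c(0, 0), c(1, 1)), "no endpoints")
})

test_that("the homolog-homogeneity test is symmetric with J-1 df", {
  A <- c(5, 9, 2, 8, 19); B <- c(6, 8, 3, 9, 17)
  got <- chisq_homogeneity(A, B)
  expect_equal(got$df, 4L)
  swapped <- chisq_homogeneity(B, A)
  expect_equal(got$chi2, swapped$chi2)
  expect_equal(got$p, swapped$p)
  same <- chisq_homogeneity(A, A)
  expect_equal(same$chi2, 0)
  expect_equal(same$p, 1)
})

test_that("simulated crossover clones are simple and bracket their breakpoints", {
  mp <- as_marker_map(as.data.frame(fig3_like_map())[-(1:2), ])
  sel <- "chr12_301000"
  cohort <- simulate_loh_cohort(60, mp, CEN12, sel, "M",
                                mix = c(crossover = 1, gene_conversion = 0,
                                        contraction = 0), seed = 141)
  for (i in seq_along(cohort$clones)) {
    cl <- cohort$clones[[i]]
    ct <- call_tracts(cl$calls, mp, CEN12)
    cls <- classify_clone(ct, mp, CEN12, sel, "M")
    expect_equal(cls$class, "simple")
    tr <- ct$tracts[1, ]
    expect_lte(tr$min_span_bp, ifelse(is.na(tr$max_span_bp), Inf,
                                      tr$max_span_bp))
    # true breakpoint lies in the called endpoint's marker interval,
    # so the midpoint errs by at most half the local marker spacing
    bp <- cl$truth$breakpoint
    flank_left <- max(c(CEN12, mp$pos[mp$pos < tr$first_hom_pos]))
    expect_gte(bp, flank_left)
    expect_lte(bp, tr$first_hom_pos)
    if (!is.na(tr$endpoint_proximal_bp))
      expect_lte(abs(tr$endpoint_proximal_bp - bp),
                 (tr$first_hom_pos - flank_left) / 2)
  }
})

test_that("tract span BED export writes min and max intervals", {
  mp <- fig3_like_map()
  calls <- all_het_calls(mp)
  calls[c("chr12_292000", "chr12_297300", "chr12_301000")] <- "M"
  ct <- call_tracts(calls, mp, CEN12)
  path <- tempfile(fileext = ".bed")
  write_tracts_bed(ct$tracts, path, clone_id = "cl1")
  bed <- utils::read.delim(path, header = FALSE)
  expect_equal(nrow(bed), 2)
  expect_true(all(bed$V2 < bed$V3))
  unlink(path)
})
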