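#' Midpoint endpoint between two flanking markers
#'
#' The resolution of a genotyped LOH tract boundary is one inter-marker
#' interval; the conventional point estimate of the tract endpoint is the
#' midpoint between the outermost homozygous marker and the adjacent
#' heterozygous marker.
#'
#' @param left_marker_pos,right_marker_pos the two marker positions (bp);
#'   argument order does not matter, equal positions are an error.
#' @return Midpoint in bp.
#' @examples
#' endpoint_midpoint(227000, 292000)  # 259500
#' @export
endpoint_midpoint <- function(left_marker_pos, right_marker_pos) {
  if (left_marker_pos == right_marker_pos)
    abort("marker positions must differ")
  (left_marker_pos + right_marker_pos) / 2
}

#' Call LOH tracts from per-marker diploid genotypes
#'
#' Resolves a clone's ordered per-marker calls (`H` heterozygous, `M`/`P`
#' homozygous for one homolog, `NA` missing) into maximal runs of
#' same-direction homozygosity, reported per chromosome arm relative to a
#' supplied centromere position. Missing calls are transparent: they never
#' break a run and never start or end one (a genotyping gap should not
#' fabricate a tract interruption; set `missing_breaks = TRUE` for the
#' conservative alternative).
#'
#' Each tract's endpoints are the midpoints between its outermost
#' homozygous markers and the adjacent informative markers. A run touching
#' the arm's most distal marker is flagged `reaches_last_marker`: with no
#' heterozygous marker beyond it, a very long interstitial event cannot be
#' distinguished from one running to the telomere. Span bounds are
#' reported as (`min_span_bp`, `max_span_bp`): the distance between the
#' outermost homozygous markers, and the distance between the flanking
#' informative markers (or the chromosome end, when `chrom_length` is
#' given and the run is terminal).
#'
#' @param calls character vector of calls over the map's markers (map
#'   order), values `"H"`, `"M"`, `"P"`, `NA`.
#' @param map [marker_map] restricted to one chromosome.
#' @param centromere centromere position (bp) on that chromosome.
#' @param chrom_length optional chromosome length (bp) for terminal
#'   max-span bounds.
#' @param missing_breaks treat missing calls as run-breaking (default
#'   `FALSE`).
#' @return A list with `tracts` (data frame: `chrom`, `arm`, `direction`,
#'   `first_hom_pos`, `last_hom_pos`, `endpoint_proximal_bp`,
#'   `endpoint_distal_bp`, `endpoint_bp` = the centromere-proximal one,
#'   `reaches_last_marker`, `min_span_bp`, `max_span_bp`, `n_markers`) and
#'   `arm_status` (named `"left"`/`"right"`: `"ok"`, `"uninformative"` (no
#'   heterozygous call), or `"no markers"`).
#' @export
call_tracts <- function(calls, map, centromere, chrom_length = NA,
                        missing_breaks = FALSE) {
  stopifnot(length(calls) == nrow(map))
  if (length(unique(map$chrom)) != 1)
    abort("call_tracts expects a single-chromosome map")
  if (missing_breaks) calls[is.na(calls)] <- "B"  # break token
  arms <- ifelse(map$pos < centromere, "left", "right")
  res <- lapply(c("left", "right"), function(arm) {
    idx <- which(arms == arm)
    if (length(idx) == 0)
      return(list(status = "no markers", tracts = NULL))
    pos <- map$pos[idx]
    val <- calls[idx]
    inf <- which(!is.na(val))          # informative (non-missing) markers
    if (length(inf) == 0)
      return(list(status = "uninformative", tracts = NULL))
    status <- if (any(val[inf] == "H")) "ok" else "uninformative"
    v <- val[inf]
    runs <- rle(v)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    hom <- which(runs$values %in% c("M", "P"))
    if (length(hom) == 0) return(list(status = status, tracts = NULL))
    tr <- do.call(rbind, lapply(hom, function(k) {
      i1 <- inf[starts[k]]; i2 <- inf[ends[k]]       # arm-local indices
      p1 <- pos[i1]; p2 <- pos[i2]
      # flanking informative markers terminating the run
      left_flank <- if (starts[k] > 1) pos[inf[starts[k] - 1L]] else NA_real_
      right_flank <- if (ends[k] < length(inf)) pos[inf[ends[k] + 1L]] else NA_real_
      ep_left <- if (!is.na(left_flank)) endpoint_midpoint(left_flank, p1) else NA_real_
      ep_right <- if (!is.na(right_flank)) endpoint_midpoint(p2, right_flank) else NA_real_
      # distal = away from the centromere
      if (arm == "right") {
        prox <- ep_left; dist <- ep_right
        terminal <- i2 == length(pos)
        flank_prox <- left_flank; flank_dist <- right_flank
      } else {
        prox <- ep_right; dist <- ep_left
        terminal <- i1 == 1L
        flank_prox <- right_flank; flank_dist <- left_flank
      }
      max_span <- if (!is.na(flank_prox) && !is.na(flank_dist)) {
        abs(flank_dist - flank_prox)
      } else if (!is.na(flank_prox) && terminal && !is.na(chrom_length)) {
        if (arm == "right") chrom_length - flank_prox else flank_prox - 1
      } else NA_real_
      data.frame(chrom = map$chrom[1], arm = arm,
                 direction = runs$values[k],
                 first_hom_pos = p1, last_hom_pos = p2,
                 endpoint_proximal_bp = prox, endpoint_distal_bp = dist,
                 endpoint_bp = prox,
                 reaches_last_marker = terminal,
                 min_span_bp = p2 - p1, max_span_bp = max_span,
                 n_markers = ends[k] - starts[k] + 1L,
                 stringsAsFactors = FALSE)
    }))
    list(status = status, tracts = tr)
  })
  tracts <- do.call(rbind, lapply(res, `[[`, "tracts"))
  if (is.null(tracts))
    tracts <- data.frame(chrom = character(), arm = character(),
                         direction = character(), first_hom_pos = numeric(),
                         last_hom_pos = numeric(),
                         endpoint_proximal_bp = numeric(),
                         endpoint_distal_bp = numeric(),
                         endpoint_bp = numeric(),
                         reaches_last_marker = logical(),
                         min_span_bp = numeric(), max_span_bp = numeric(),
                         n_markers = integer(), stringsAsFactors = FALSE)
  rownames(tracts) <- NULL
  list(tracts = tracts,
       arm_status = c(left = res[[1]]$status, right = res[[2]]$status))
}

#' Classify a clone's LOH pattern
#'
#' A clone is `"simple"` when the selected arm carries exactly one tract,
#' in the direction of selection, containing the selected marker —
#' the signature of a single crossover/BIR or gene-conversion event.
#' Anything else on the selected arm (interrupted runs, homozygosity for
#' the homolog opposite to selection) is `"complex"`. Tracts on the other
#' arm do not change the class but set `coincident = TRUE`: an independent
#' unselected event on the same chromosome.
#'
#' @param called result of [call_tracts()].
#' @param map the single-chromosome [marker_map] used for calling.
#' @param centromere centromere position (bp).
#' @param selected_marker_id id of the marker carrying the selection
#'   cassette.
#' @param selected_direction `"M"` or `"P"`: the homolog whose retention
#'   was selected.
#' @return List with `class` (`"simple"` or `"complex"`), `coincident`
#'   (logical) and `selected_arm`.
#' @export
classify_clone <- function(called, map, centromere,
                           selected_marker_id, selected_direction) {
  sel <- match(selected_marker_id, map$marker_id)
  if (is.na(sel)) abort("selected marker %s not in map", selected_marker_id)
  sel_pos <- map$pos[sel]
  sel_arm <- if (sel_pos < centromere) "left" else "right"
  tr <- called$tracts
  on_sel <- tr[tr$arm == sel_arm, , drop = FALSE]
  other <- tr[tr$arm != sel_arm, , drop = FALSE]
  simple <- nrow(on_sel) == 1 &&
    on_sel$direction == selected_direction &&
    on_sel$first_hom_pos <= sel_pos && sel_pos <= on_sel$last_hom_pos
  list(class = if (simple) "simple" else "complex",
       coincident = nrow(other) > 0,
       selected_arm = sel_arm)
}

#' Tally tract endpoints into marker-delimited intervals
#'
#' Bins centromere-proximal tract endpoints into half-open intervals
#' `(left_pos, right_pos]` delimited by genotyped markers. Endpoints
#' falling outside every interval are excluded with a warning.
#'
#' @param endpoints numeric vector of endpoint positions (bp).
#' @param intervals data frame with columns `left_pos`, `right_pos`
#'   (half-open, `left_pos < right_pos`), non-overlapping.
#' @return An `endpoint_table`: the intervals with `L` (length bp) and `O`
#'   (observed endpoint count), plus attribute `n_outside`.
#' @export
tally_endpoints <- function(endpoints, intervals) {
  stopifnot(all(c("left_pos", "right_pos") %in% names(intervals)))
  if (any(intervals$left_pos >= intervals$right_pos))
    abort("intervals must satisfy left_pos < right_pos")
  O <- integer(nrow(intervals))
  outside <- 0L
  for (e in endpoints) {
    hit <- which(intervals$left_pos < e & e <= intervals$right_pos)
    if (length(hit) == 0) outside <- outside + 1L
    else O[hit[1]] <- O[hit[1]] + 1L
  }
  if (outside > 0)
    warning(sprintf("%d endpoint(s) outside the interval set were excluded",
                    outside))
  out <- intervals
  out$L <- intervals$right_pos - intervals$left_pos
  out$O <- O
  attr(out, "n_outside") <- outside
  class(out) <- c("endpoint_table", "data.frame")
  out
}

#' Chi-square test of the interval-size endpoint model
#'
#' Null model: tract endpoints fall into intervals in proportion to the
#' intervals' physical lengths, `E_j = sum(O) * L_j / sum(L)`. The
#' goodness-of-fit statistic `sum((O - E)^2 / E)` is referred to a
#' chi-square distribution with `J - 1` degrees of freedom. Rejection
#' suggests endpoint clustering — e.g. a recombination initiation hotspot.
#'
#' @param O observed endpoint counts per interval.
#' @param L interval lengths (bp or any proportional unit).
#' @return List of class `chisq_result`: `chi2`, `df`, `p`, `expected`.
#'   A warning is issued when any expected count is below 5.
#' @export
chisq_size_model <- function(O, L) {
  stopifnot(length(O) == length(L), length(O) >= 2)
  if (sum(O) <= 0) abort("no endpoints to test")
  if (any(L <= 0)) abort("interval lengths must be > 0")
  E <- sum(O) * L / sum(L)
  if (any(E < 5))
    warning("expected count(s) below 5; chi-square approximation is rough")
  chi2 <- sum((O - E)^2 / E)
  df <- length(O) - 1L
  structure(list(chi2 = chi2, df = df,
                 p = stats::pchisq(chi2, df, lower.tail = FALSE),
                 expected = E), class = "chisq_result")
}

#' Chi-square homogeneity test of two endpoint distributions
#'
#' 2 x J contingency test comparing the interval distributions of
#' endpoints from two experiments (e.g. selections on the two reciprocal
#' homolog insertions); `df = J - 1`, symmetric in its arguments.
#'
#' @param O_A,O_B observed endpoint counts per interval for the two
#'   experiments (same interval set, same order).
#' @return List of class `chisq_result`: `chi2`, `df`, `p`.
#' @export
chisq_homogeneity <- function(O_A, O_B) {
  stopifnot(length(O_A) == length(O_B), length(O_A) >= 2)
  tab <- rbind(O_A, O_B)
  keep <- colSums(tab) > 0
  tab <- tab[, keep, drop = FALSE]
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  structure(list(chi2 = unname(res$statistic), df = unname(res$parameter),
                 p = unname(res$p.value)), class = "chisq_result")
}

#' @export
print.chisq_result <- function(x, ...) {
  cat(sprintf("chi-square = %.4g, df = %d, p = %.4g\n", x$chi2, x$df, x$p))
  invisible(x)
}

#' Export tract span bounds as BED intervals
#'
#' Writes each tract's minimal (outermost homozygous markers) and maximal
#' (flanking informative markers) span as BED6-like rows (0-based,
#' half-open), one pair per tract.
#'
#' @param tracts tract data frame from [call_tracts()].
#' @param path output file path.
#' @param clone_id label used in the BED name column.
#' @return `path`, invisibly.
#' @export
write_tracts_bed <- function(tracts, path, clone_id = "clone") {
  rows <- do.call(rbind, lapply(seq_len(nrow(tracts)), function(i) {
    t <- tracts[i, ]
    mx_start <- if (!is.na(t$max_span_bp)) t$endpoint_proximal_bp else NA
    rbind(
      data.frame(chrom = t$chrom, start = t$first_hom_pos - 1,
                 end = t$last_hom_pos,
                 name = sprintf("%s_%s_min", clone_id, t$direction),
                 score = 0, strand = "."),
      if (!is.na(t$endpoint_proximal_bp) && !is.na(t$endpoint_distal_bp))
        data.frame(chrom = t$chrom,
                   start = floor(t$endpoint_proximal_bp) - 1,
                   end = ceiling(t$endpoint_distal_bp),
                   name = sprintf("%s_%s_max", clone_id, t$direction),
                   score = 0, strand = "."))
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
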