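#' High-confidence heterozygous site filter
#'
#' Mendelian quality control for candidate heterozygous sites genotyped
#' across four-spore tetrads. A site is kept only if it is biallelic and
#' every complete tetrad (all four spores called) segregates its two alleles
#' exactly 2:2 — the expectation for a true heterozygous site in an
#' error-free meiosis. Tetrads with any missing spore call are ignored, up
#' to `max_missing_tetrads` of them; a site with more incomplete tetrads
#' than that (or with no complete tetrad at all) is dropped as
#' under-supported rather than risk calling phase from thin data.
#'
#' @param calls named character vector of observed allele symbols, one per
#'   spore (`NA` = missing). Names are spore ids.
#' @param tetrad_of named vector mapping each spore id to its tetrad id.
#' @param max_missing_tetrads maximum number of incomplete tetrads tolerated
#'   before the site is dropped (default 2).
#' @return A list with elements `keep` (logical) and `reason` (one of
#'   `"ok"`, `"monomorphic"`, `"not biallelic"`, `"non-2:2 tetrad"`,
#'   `"insufficient data"`).
#' @seealso [filter_hetsnp_sites()] for the matrix version.
#' @examples
#' tet <- rep(c("t1", "t2"), each = 4)
#' names(tet) <- paste0("s", 1:8)
#' calls <- c(s1 = "A", s2 = "A", s3 = "G", s4 = "G",
#'            s5 = "G", s6 = "A", s7 = "G", s8 = "A")
#' site_high_confidence(calls, tet)$keep  # TRUE: both tetrads 2:2
#' @export
site_high_confidence <- function(calls, tetrad_of, max_missing_tetrads = 2) {
  if (length(calls) == 0 || all(is.na(calls))) abort("no calls")
  if (is.null(names(calls))) abort("'calls' must be named by spore id")
  spores <- names(calls)
  if (!all(spores %in% names(tetrad_of)))
    abort("spore(s) missing from tetrad assignment")
  alleles <- unique(calls[!is.na(calls)])
  if (length(alleles) > 2) return(list(keep = FALSE, reason = "not biallelic"))
  if (length(alleles) < 2) return(list(keep = FALSE, reason = "monomorphic"))
  by_tet <- split(calls, tetrad_of[spores])
  complete <- vapply(by_tet, function(x) length(x) == 4L && !anyNA(x), logical(1))
  if (sum(!complete) > max_missing_tetrads || !any(complete))
    return(list(keep = FALSE, reason = "insufficient data"))
  for (tet in by_tet[complete]) {
    if (sum(tet == alleles[1]) != 2L)
      return(list(keep = FALSE, reason = "non-2:2 tetrad"))
  }
  list(keep = TRUE, reason = "ok")
}

#' Filter a site-by-spore allele matrix to high-confidence sites
#'
#' Applies [site_high_confidence()] to every row of an allele call matrix.
#'
#' @param alleles character matrix, sites in rows (row names = site ids),
#'   spores in columns (column names = spore ids), `NA` = missing call.
#' @inheritParams site_high_confidence
#' @return A data frame with columns `site`, `keep`, `reason`, one row per
#'   input site, in input order.
#' @export
filter_hetsnp_sites <- function(alleles, tetrad_of, max_missing_tetrads = 2) {
  stopifnot(is.matrix(alleles))
  if (is.null(colnames(alleles))) abort("allele matrix must have spore column names")
  site_ids <- rownames(alleles) %||% as.character(seq_len(nrow(alleles)))
  res <- lapply(seq_len(nrow(alleles)), function(i) {
    row <- alleles[i, ]
    names(row) <- colnames(alleles)
    if (all(is.na(row))) return(list(keep = FALSE, reason = "no calls"))
    site_high_confidence(row, tetrad_of, max_missing_tetrads)
  })
  data.frame(site = site_ids,
             keep = vapply(res, `[[`, logical(1), "keep"),
             reason = vapply(res, `[[`, character(1), "reason"),
             stringsAsFactors = FALSE)
}

#' Phase one chromosome by greedy adjacent-marker linkage
#'
#' Assigns the two alleles of each retained heterozygous marker to the two
#' parental homologs (M/P) by chaining adjacent markers: across four-spore
#' tetrads, crossovers between neighbouring markers are rare, so the allele
#' pairing that makes adjacent-marker alleles co-segregate in the largest
#' fraction of spores is taken as the in-phase pairing. The agreement
#' fraction at each adjacency is reported as that marker's phasing
#' confidence. An adjacency with agreement exactly 1/2 carries no linkage
#' information: the chain is broken there and the marker starts a new phase
#' block flagged unphaseable relative to its predecessor.
#'
#' Because the M/P labels are arbitrary, the orientation of each block is
#' canonicalized: the lexicographically smaller allele of the first marker
#' of the block is assigned to M. Relabelling allele symbols consistently,
#' or swapping every spore's alleles at all markers, therefore yields the
#' identical map.
#'
#' @param alleles character matrix of allele calls for one chromosome,
#'   sites in rows (ordered or orderable by `pos`), spores in columns.
#'   Every row must be biallelic (apply [filter_hetsnp_sites()] first).
#' @param pos numeric vector of 1-based marker positions, one per row.
#' @param chrom chromosome id (scalar).
#' @return A [marker_map] fragment with extra columns `block` (phase block
#'   index), `confidence` (agreement fraction of the adjacency linking the
#'   marker to its predecessor; `NA` for the first marker of a block) and
#'   `unphaseable` (logical: block break caused by a 50/50 adjacency).
#' @export
phase_chromosome <- function(alleles, pos, chrom) {
  stopifnot(is.matrix(alleles), length(pos) == nrow(alleles))
  if (nrow(alleles) < 2) abort("phasing needs >= 2 markers")
  if (ncol(alleles) < 8) abort("phasing needs >= 2 tetrads (>= 8 spores)")
  ord <- order(pos)
  alleles <- alleles[ord, , drop = FALSE]
  pos <- pos[ord]
  n <- nrow(alleles)

  # per-site sorted allele pair and spore codes (0 = lex-smaller allele)
  pair <- t(apply(alleles, 1, function(x) sort(unique(x[!is.na(x)]))[1:2]))
  if (anyNA(pair)) abort("non-biallelic site passed to phase_chromosome")
  code <- matrix(NA_integer_, n, ncol(alleles))
  for (i in seq_len(n)) {
    code[i, ] <- match(alleles[i, ], pair[i, ]) - 1L
    if (any(!is.na(alleles[i, ]) & is.na(code[i, ])))
      abort("allele outside site's two alleles at row %d", i)
  }

  # adjacency agreement and relative orientation
  confidence <- rep(NA_real_, n)
  unphaseable <- rep(FALSE, n)
  block <- integer(n); block[1] <- 1L
  rel <- integer(n); rel[1] <- 0L   # orientation relative to block start
  for (i in 2:n) {
    both <- !is.na(code[i - 1, ]) & !is.na(code[i, ])
    if (!any(both)) {
      agree <- 0.5
    } else {
      agree <- mean(code[i - 1, both] == code[i, both])
    }
    if (agree == 0.5) {
      block[i] <- block[i - 1] + 1L
      rel[i] <- 0L
      unphaseable[i] <- TRUE
      confidence[i] <- NA_real_
    } else {
      block[i] <- block[i - 1]
      flip <- agree < 0.5
      rel[i] <- if (flip) 1L - rel[i - 1] else rel[i - 1]
      confidence[i] <- max(agree, 1 - agree)
    }
  }

  # canonical orientation: block's first marker lex-smaller allele -> M.
  # rel == 0 means same orientation as block start, so M = pair[,1] there.
  allele_M <- ifelse(rel == 0L, pair[, 1], pair[, 2])
  allele_P <- ifelse(rel == 0L, pair[, 2], pair[, 1])

  df <- data.frame(chrom = chrom, pos = pos,
                   marker_id = paste0(chrom, "_", pos),
                   allele_M = allele_M, allele_P = allele_P,
                   block = block, confidence = confidence,
                   unphaseable = unphaseable,
                   stringsAsFactors = FALSE)
  as_marker_map(df, filters = "biallelic;2:2")
}

#' Build a phased map from tetrad allele calls, genome-wide
#'
#' Convenience wrapper: filters sites with [filter_hetsnp_sites()] and
#' phases each chromosome with [phase_chromosome()].
#'
#' @param sites data frame with columns `chrom` and `pos` describing the
#'   rows of `alleles`.
#' @inheritParams filter_hetsnp_sites
#' @return A list with `map` (the combined [marker_map]), `filter` (the
#'   per-site filter table) and `n_tetrads`.
#' @export
build_phased_map <- function(sites, alleles, tetrad_of, max_missing_tetrads = 2) {
  stopifnot(nrow(sites) == nrow(alleles))
  flt <- filter_hetsnp_sites(alleles, tetrad_of, max_missing_tetrads)
  keep <- flt$keep
  frags <- lapply(split(seq_len(nrow(sites))[keep], sites$chrom[keep]),
                  function(idx) {
                    if (length(idx) < 2) return(NULL)
                    phase_chromosome(alleles[idx, , drop = FALSE],
                                     sites$pos[idx], sites$chrom[idx][1])
                  })
  frags <- frags[!vapply(frags, is.null, logical(1))]
  map <- as_marker_map(do.call(rbind, lapply(frags, as.data.frame)),
                       n_tetrads = length(unique(tetrad_of)),
                       filters = "biallelic;2:2")
  list(map = map, filter = flt, n_tetrads = length(unique(tetrad_of)))
}

#' Encode raw allele calls against a phased map
#'
#' Translates a sample's observed alleles into homolog space. Haploid calls
#' become `M`, `P` or `NA`; diploid calls (unordered pairs written
#' `"A/G"`) become `M` (homozygous M), `P` (homozygous P), `H`
#' (heterozygous) or `NA`. An allele not present in the map at its marker
#' is an error, not a silent missing value.
#'
#' @param calls named character vector, `marker_id -> allele` for haploids
#'   or `marker_id -> "a1/a2"` for diploids; markers absent from `calls`
#'   are encoded `NA`.
#' @param map a [marker_map].
#' @param ploidy `"haploid"` or `"diploid"`.
#' @return Character vector over the markers of `map` (in map order, named
#'   by marker id) with values `"M"`, `"P"`, `"H"` (diploid only), `NA`.
#' @examples
#' mp <- marker_map("chr1", c(100, 200), allele_M = c("A", "T"),
#'                  allele_P = c("G", "C"))
#' encode_against_map(c(chr1_100 = "A", chr1_200 = "C"), mp, "haploid")
#' encode_against_map(c(chr1_100 = "A/G"), mp, "diploid")
#' @export
encode_against_map <- function(calls, map, ploidy = c("haploid", "diploid")) {
  ploidy <- match.arg(ploidy)
  out <- rep(NA_character_, nrow(map))
  names(out) <- map$marker_id
  idx <- match(names(calls), map$marker_id)
  if (anyNA(idx))
    abort("call(s) at marker(s) absent from map: %s",
          paste(utils::head(names(calls)[is.na(idx)], 3), collapse = ", "))
  for (k in seq_along(calls)) {
    a <- calls[[k]]
    if (is.na(a) || a == "-" || a == "") next
    i <- idx[k]
    if (ploidy == "haploid") {
      out[i] <- if (a == map$allele_M[i]) "M"
                else if (a == map$allele_P[i]) "P"
                else abort("allele mismatch at marker %s: '%s' not in {%s,%s}",
                           map$marker_id[i], a, map$allele_M[i], map$allele_P[i])
    } else {
      ab <- sort(strsplit(a, "/", fixed = TRUE)[[1]])
      if (length(ab) != 2)
        abort("diploid call at marker %s must be 'a1/a2', got '%s'",
              map$marker_id[i], a)
      known <- ab %in% c(map$allele_M[i], map$allele_P[i])
      if (!all(known))
        abort("allele mismatch at marker %s: '%s'", map$marker_id[i],
              ab[!known][1])
      out[i] <- if (ab[1] == ab[2]) {
        if (ab[1] == map$allele_M[i]) "M" else "P"
      } else "H"
    }
  }
  out
}

#' Encode a cohort of samples against a map
#'
#' @param alleles character matrix of raw calls, sites in rows matching the
#'   map's markers (row names = marker ids), samples in columns.
#' @inheritParams encode_against_map
#' @return Character matrix, samples in rows, markers in columns, suitable
#'   for [cosegregation_scan()] or [write_phase_matrix()].
#' @export
encode_cohort <- function(alleles, map, ploidy = c("haploid", "diploid")) {
  ploidy <- match.arg(ploidy)
  stopifnot(is.matrix(alleles))
  if (is.null(rownames(alleles)))
    abort("allele matrix must have marker_id row names")
  t(apply(alleles, 2, function(col) {
    names(col) <- rownames(alleles)
    encode_against_map(col[!is.na(col)], map, ploidy)
  }))
}

#' Decode a phase vector back to allele symbols
#'
#' Inverse of [encode_against_map()] for haploid vectors: `M`/`P` calls are
#' replaced by the mapped allele symbols.
#'
#' @param phase character vector over the map's markers (`"M"`, `"P"`, `NA`).
#' @param map a [marker_map].
#' @return Named character vector of allele symbols.
#' @export
decode_phase <- function(phase, map) {
  stopifnot(length(phase) == nrow(map))
  out <- ifelse(phase == "M", map$allele_M,
                ifelse(phase == "P", map$allele_P, NA_character_))
  names(out) <- map$marker_id
  out
}
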