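#' Synthetic genome configuration
#'
#' Describes the diploid genome the generator emulates: chromosomes with
#' lengths and centromere positions, heterozygous blocks interspersed with
#' homozygous runs (the signature of ancestral LOH), and a marker density
#' within heterozygous blocks. The default is a deliberately small genome
#' — three 500 kb chromosomes, one 150 kb heterozygous block each — sized
#' so every downstream analysis runs in seconds; [sim_genome_config_jay270()]
#' scales the same structure to a 16-chromosome, ~12,000-marker genome.
#'
#' @param chromosomes data frame with columns `name`, `length`,
#'   `centromere` (bp). Default: `chr01`-`chr03`, 500 kb, centromere at
#'   100 kb.
#' @param het_blocks data frame with columns `chrom`, `start`, `end`
#'   delimiting heterozygous blocks. Default: one 150-300 kb block per
#'   chromosome (on the right arm, mirroring a centromere-proximal
#'   heterozygous interval bounded by homozygous sequence).
#' @param marker_density expected heterozygous markers per kb inside het
#'   blocks (> 0; default 0.1).
#' @return List of class `sim_genome_config`.
#' @export
sim_genome_config <- function(chromosomes = NULL, het_blocks = NULL,
                              marker_density = 0.1) {
  if (is.null(chromosomes))
    chromosomes <- data.frame(name = sprintf("chr%02d", 1:3),
                              length = 5e5, centromere = 1e5,
                              stringsAsFactors = FALSE)
  if (is.null(het_blocks))
    het_blocks <- data.frame(chrom = chromosomes$name,
                             start = 15e4, end = 30e4,
                             stringsAsFactors = FALSE)
  stopifnot(marker_density > 0,
            all(c("name", "length", "centromere") %in% names(chromosomes)),
            all(c("chrom", "start", "end") %in% names(het_blocks)))
  if (!all(het_blocks$chrom %in% chromosomes$name))
    abort("het block on unknown chromosome")
  ln <- chromosomes$length[match(het_blocks$chrom, chromosomes$name)]
  if (any(het_blocks$start < 1 | het_blocks$end > ln))
    abort("het blocks must lie within their chromosome")
  structure(list(chromosomes = chromosomes, het_blocks = het_blocks,
                 marker_density = marker_density),
            class = "sim_genome_config")
}

#' @rdname sim_genome_config
#' @details The 16-chromosome preset uses budding-yeast-like chromosome
#'   lengths and centromere positions and alternates 50 kb heterozygous
#'   with 30 kb homozygous blocks, giving roughly 12,000 markers at its
#'   default density of 1.65 markers/kb.
#' @export
sim_genome_config_jay270 <- function(marker_density = 1.65) {
  len_kb <- c(230, 813, 317, 1532, 577, 270, 1091, 563,
              440, 746, 667, 1078, 924, 784, 1091, 948)
  cen_kb <- c(151, 238, 114, 450, 152, 149, 497, 106,
              356, 436, 440, 151, 268, 629, 327, 556)
  chrom <- data.frame(name = sprintf("chr%02d", 1:16),
                      length = len_kb * 1e3, centromere = cen_kb * 1e3,
                      stringsAsFactors = FALSE)
  blocks <- do.call(rbind, lapply(seq_len(16), function(i) {
    starts <- seq(1e4, chrom$length[i] - 5e4, by = 8e4)
    data.frame(chrom = chrom$name[i], start = starts, end = starts + 5e4,
               stringsAsFactors = FALSE)
  }))
  sim_genome_config(chrom, blocks, marker_density)
}

#' Simulate a phased parent genome
#'
#' Places heterozygous markers only inside the configured heterozygous
#' blocks — marker counts per block are Poisson with mean
#' `density * block length` — and assigns each marker a random pair of
#' distinct nucleotide alleles to the M and P homolog.
#'
#' @param config a [sim_genome_config()].
#' @param seed optional integer seed.
#' @return List with `map` (a [marker_map]) and `truth` (the config and
#'   per-block marker counts).
#' @export
simulate_parent <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_genome_config"))
  set_seed_if(seed)
  blocks <- config$het_blocks
  rows <- lapply(seq_len(nrow(blocks)), function(i) {
    len_kb <- (blocks$end[i] - blocks$start[i]) / 1000
    n <- stats::rpois(1, config$marker_density * len_kb)
    if (n == 0) return(NULL)
    pos <- sort(sample(seq(blocks$start[i], blocks$end[i]), n))
    al <- t(vapply(seq_len(n), function(j) sample(c("A", "C", "G", "T"), 2),
                   character(2)))
    data.frame(chrom = blocks$chrom[i], pos = pos,
               allele_M = al[, 1], allele_P = al[, 2],
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    map <- as_marker_map(data.frame(chrom = character(), pos = numeric(),
                                    allele_M = character(),
                                    allele_P = character(),
                                    stringsAsFactors = FALSE))
  } else {
    map <- as_marker_map(do.call(rbind, rows))
  }
  list(map = map,
       truth = list(config = config,
                    n_markers = nrow(map)))
}

#' Simulate four-spore tetrads from a phased parent
#'
#' Each meiosis duplicates the M and P haplotypes into four chromatids,
#' applies crossovers (Poisson number per chromosome, uniform positions, no
#' interference) in a way that preserves exact 2:2 segregation at every
#' site, optionally overlays non-reciprocal gene-conversion tracts (which
#' break 2:2 locally), and finally injects per-call genotyping error
#' (allele flips) and missingness. Crossovers are realized on two
#' complementary spore pairs, so before error injection every marker
#' segregates 2:2 by construction.
#'
#' @param map a [marker_map] from [simulate_parent()].
#' @param n_tetrads number of tetrads (default 14).
#' @param crossover_rate expected crossovers per chromosome per meiosis
#'   (default 1).
#' @param gc_rate expected gene-conversion events per chromosome per
#'   meiosis (default 0).
#' @param gc_mean_kb mean conversion tract length in kb (default 2).
#' @param error_rate per-call probability of reporting the opposite allele
#'   (default 0).
#' @param missing_rate per-call probability of a missing call (default 0).
#' @param chrom_lengths optional named vector of chromosome lengths for
#'   crossover placement; defaults to each chromosome's last marker + 1 kb.
#' @param seed optional integer seed.
#' @return List with `alleles` (character matrix, markers x spores,
#'   observed allele symbols with `NA` missing), `phase` (truth matrix in
#'   `"M"`/`"P"` before error/missingness), `tetrad_of` (named vector
#'   spore -> tetrad), `crossovers` (data frame: `tetrad`, `chrom`,
#'   `pattern`, `pos`) and `map`.
#' @export
simulate_tetrads <- function(map, n_tetrads = 14, crossover_rate = 1,
                             gc_rate = 0, gc_mean_kb = 2,
                             error_rate = 0, missing_rate = 0,
                             chrom_lengths = NULL, seed = NULL) {
  stopifnot(nrow(map) > 0, n_tetrads >= 1)
  set_seed_if(seed)
  chroms <- unique(map$chrom)
  if (is.null(chrom_lengths)) {
    chrom_lengths <- vapply(chroms, function(ch)
      max(map$pos[map$chrom == ch]) + 1000, numeric(1))
  }
  spores <- as.vector(vapply(seq_len(n_tetrads),
                             function(t) sprintf("t%02d_s%d", t, 1:4),
                             character(4)))
  tetrad_of <- rep(sprintf("t%02d", seq_len(n_tetrads)), each = 4)
  names(tetrad_of) <- spores

  phase <- matrix(NA_character_, nrow(map), 4 * n_tetrads,
                  dimnames = list(map$marker_id, spores))
  co_log <- list()
  for (t in seq_len(n_tetrads)) {
    cols <- (t - 1) * 4 + 1:4
    for (ch in chroms) {
      idx <- which(map$chrom == ch)
      pos <- map$pos[idx]
      L <- chrom_lengths[[ch]]
      k <- stats::rpois(1, crossover_rate)
      bp <- if (k > 0) sort(stats::runif(k, 1, L)) else numeric(0)
      pat <- if (k > 0) sample(c(1L, 2L), k, replace = TRUE) else integer(0)
      # two complementary spore pairs; each crossover toggles one pattern
      start <- sample(c("M", "P"), 2, replace = TRUE)
      hap <- function(which_pat) {
        tog <- vapply(pos, function(p) sum(bp[pat == which_pat] < p) %% 2L,
                      integer(1))
        ifelse(xor(start[which_pat] == "P", tog == 1L), "P", "M")
      }
      h1 <- hap(1L); h2 <- hap(2L)
      opp <- function(h) ifelse(h == "M", "P", "M")
      four <- cbind(h1, opp(h1), h2, opp(h2))[, sample(4), drop = FALSE]
      # gene conversions: copy the opposite homolog over a short tract
      n_gc <- stats::rpois(1, gc_rate)
      if (n_gc > 0) {
        for (g in seq_len(n_gc)) {
          sp <- sample(4, 1)
          center <- stats::runif(1, 1, L)
          len <- stats::rexp(1, 1 / (gc_mean_kb * 1000))
          hit <- pos >= center - len / 2 & pos <= center + len / 2
          four[hit, sp] <- opp(four[hit, sp])
        }
      }
      phase[idx, cols] <- four
      if (k > 0)
        co_log[[length(co_log) + 1]] <-
          data.frame(tetrad = sprintf("t%02d", t), chrom = ch,
                     pattern = pat, pos = bp, stringsAsFactors = FALSE)
    }
  }
  crossovers <- if (length(co_log) > 0) do.call(rbind, co_log) else
    data.frame(tetrad = character(), chrom = character(),
               pattern = integer(), pos = numeric(), stringsAsFactors = FALSE)

  # phase -> observed alleles, then error and missingness
  alleles <- matrix(NA_character_, nrow(map), length(spores),
                    dimnames = list(map$marker_id, spores))
  for (j in seq_along(spores)) {
    alleles[, j] <- ifelse(phase[, j] == "M", map$allele_M, map$allele_P)
  }
  if (error_rate > 0) {
    flip <- matrix(stats::runif(length(alleles)) < error_rate,
                   nrow(alleles), ncol(alleles))
    other <- ifelse(alleles == map$allele_M, map$allele_P, map$allele_M)
    alleles[flip] <- other[flip]
  }
  if (missing_rate > 0) {
    drop <- matrix(stats::runif(length(alleles)) < missing_rate,
                   nrow(alleles), ncol(alleles))
    alleles[drop] <- NA_character_
  }
  list(alleles = alleles, phase = phase, tetrad_of = tetrad_of,
       crossovers = crossovers, map = map)
}

#' Assign mating types within tetrads
#'
#' Mating type segregates 2:2 in each tetrad; two spores are drawn as MATa
#' and two as MATalpha, uniformly at random.
#'
#' @param tetrad_of named vector spore -> tetrad.
#' @param seed optional integer seed.
#' @return Named character vector, values `"a"` / `"alpha"`.
#' @export
assign_mating_types <- function(tetrad_of, seed = NULL) {
  set_seed_if(seed)
  out <- character(length(tetrad_of))
  names(out) <- names(tetrad_of)
  for (tet in unique(tetrad_of)) {
    sp <- names(tetrad_of)[tetrad_of == tet]
    a <- sample(sp, 2)
    out[sp] <- ifelse(sp %in% a, "a", "alpha")
  }
  out
}

#' Carrier status at a marker
#'
#' Which spores inherited the homolog carrying a recessive mutant allele:
#' the allele model is a marker (e.g. an A8/A7 homopolymer) whose mutant
#' allele rides one homolog.
#'
#' @param phase truth or encoded phase matrix, markers x spores.
#' @param marker_id the causal marker.
#' @param mutant_homolog `"M"` or `"P"`.
#' @return Named logical vector over spores.
#' @export
carriers_at_marker <- function(phase, marker_id, mutant_homolog = "M") {
  if (!marker_id %in% rownames(phase))
    abort("marker %s not in phase matrix", marker_id)
  phase[marker_id, ] == mutant_homolog
}

#' Simulate an all-pairs cross phenotype matrix
#'
#' Crosses every MATa haploid to every MATalpha haploid and scores the
#' diploid ROUGH exactly when both parents carry the recessive mutant
#' allele — the single-gene recessive phenotype rule.
#'
#' @param carriers named logical vector: does each haploid carry the
#'   mutant allele.
#' @param mating_type named character vector (`"a"` / `"alpha"`) over the
#'   same haploids.
#' @return Character matrix (rows MATa, columns MATalpha) of `"R"`/`"S"`.
#' @export
simulate_cross_matrix <- function(carriers, mating_type) {
  stopifnot(!is.null(names(carriers)),
            all(names(carriers) %in% names(mating_type)))
  a_ids <- names(carriers)[mating_type[names(carriers)] == "a"]
  alpha_ids <- names(carriers)[mating_type[names(carriers)] == "alpha"]
  if (length(a_ids) == 0 || length(alpha_ids) == 0)
    abort("need haploids of both mating types")
  m <- outer(carriers[a_ids], carriers[alpha_ids],
             function(x, y) ifelse(x & y, "R", "S"))
  dimnames(m) <- list(a_ids, alpha_ids)
  m
}

#' Simulate one LOH clone
#'
#' Generates the per-marker genotype calls of a clone selected for loss of
#' one homolog at a marker, under one of three mechanisms:
#' \describe{
#'   \item{crossover}{(also covering BIR) — a breakpoint is drawn between
#'     the centromere and the selected marker (uniformly, or weighted by
#'     supplied interval weights to emulate a hotspot) and every marker
#'     from the breakpoint to the chromosome end on the selected arm
#'     becomes homozygous for the selected homolog: a terminal tract.}
#'   \item{gene_conversion}{an interstitial tract with exponentially
#'     distributed length (mean `gc_mean_kb`) placed to contain the
#'     selected marker.}
#'   \item{contraction}{a point event at the selected marker only (the
#'     homopolymer-contraction mimic).}
#' }
#' The selection constraint — the clone is homozygous for
#' `selected_direction` at `selected_marker_id` — holds by construction.
#'
#' @param map single-chromosome [marker_map].
#' @param centromere centromere position (bp).
#' @param selected_marker_id marker under selection.
#' @param selected_direction `"M"` or `"P"`.
#' @param mechanism `"crossover"`, `"gene_conversion"` or `"contraction"`.
#' @param interval_weights optional data frame (`left_pos`, `right_pos`,
#'   `weight`) biasing crossover breakpoint placement between centromere
#'   and selected marker.
#' @param gc_mean_kb mean gene-conversion tract length (kb).
#' @param seed optional integer seed.
#' @return List with `calls` (named vector over the map's markers:
#'   `"H"`, `"M"`, `"P"`), `truth` (mechanism and breakpoint position(s))
#'   and the selection parameters.
#' @export
simulate_loh_clone <- function(map, centromere, selected_marker_id,
                               selected_direction = "M",
                               mechanism = c("crossover", "gene_conversion",
                                             "contraction"),
                               interval_weights = NULL, gc_mean_kb = 20,
                               seed = NULL) {
  mechanism <- match.arg(mechanism)
  if (length(unique(map$chrom)) != 1)
    abort("simulate_loh_clone expects a single-chromosome map")
  sel <- match(selected_marker_id, map$marker_id)
  if (is.na(sel)) abort("selected marker %s not in map", selected_marker_id)
  sel_pos <- map$pos[sel]
  right_arm <- sel_pos > centromere
  set_seed_if(seed)
  calls <- rep("H", nrow(map))
  names(calls) <- map$marker_id
  if (mechanism == "crossover") {
    if (is.null(interval_weights)) {
      bp <- if (right_arm) stats::runif(1, centromere, sel_pos)
            else stats::runif(1, sel_pos, centromere)
    } else {
      w <- interval_weights
      i <- sample(nrow(w), 1, prob = w$weight)
      bp <- stats::runif(1, w$left_pos[i], w$right_pos[i])
    }
    hom <- if (right_arm) map$pos >= bp else map$pos <= bp
    calls[hom] <- selected_direction
    truth <- list(mechanism = mechanism, breakpoint = bp)
  } else if (mechanism == "gene_conversion") {
    len <- stats::rexp(1, 1 / (gc_mean_kb * 1000))
    start <- sel_pos - stats::runif(1) * len
    end <- start + len
    calls[map$pos >= start & map$pos <= end] <- selected_direction
    truth <- list(mechanism = mechanism, breakpoint = c(start, end))
  } else {
    calls[sel] <- selected_direction
    truth <- list(mechanism = mechanism, breakpoint = sel_pos)
  }
  list(calls = calls, truth = truth,
       selected_marker_id = selected_marker_id,
       selected_direction = selected_direction)
}

#' Simulate a cohort of LOH clones
#'
#' Draws each clone's mechanism from a mixture and simulates it with
#' [simulate_loh_clone()]. The default mixture is dominated by terminal
#' crossover/BIR-type events with occasional interstitial conversions and
#' point contractions, matching the spectrum typically recovered from
#' selected LOH clones.
#'
#' @inheritParams simulate_loh_clone
#' @param n number of clones.
#' @param mix named numeric vector of mechanism proportions (must sum
#'   to 1) over `crossover`, `gene_conversion`, `contraction`.
#' @return List with `clones` (list of [simulate_loh_clone()] results),
#'   `calls` (matrix clones x markers) and `mechanisms`.
#' @export
simulate_loh_cohort <- function(n, map, centromere, selected_marker_id,
                                selected_direction = "M",
                                mix = c(crossover = 0.9,
                                        gene_conversion = 0.05,
                                        contraction = 0.05),
                                interval_weights = NULL, gc_mean_kb = 20,
                                seed = NULL) {
  if (abs(sum(mix) - 1) > 1e-8) abort("mechanism proportions must sum to 1")
  set_seed_if(seed)
  mechs <- sample(names(mix), n, replace = TRUE, prob = mix)
  clones <- lapply(mechs, function(mech)
    simulate_loh_clone(map, centromere, selected_marker_id,
                       selected_direction, mech,
                       interval_weights = interval_weights,
                       gc_mean_kb = gc_mean_kb))
  calls <- do.call(rbind, lapply(clones, `[[`, "calls"))
  rownames(calls) <- sprintf("clone%03d", seq_len(n))
  list(clones = clones, calls = calls, mechanisms = mechs)
}
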