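#' Template concentration from droplet counts
#'
#' Droplet digital PCR partitions the template into ~20,000 droplets; the
#' fraction of positive droplets recovers the mean number of template
#' copies per droplet by the Poisson correction
#' \deqn{\lambda = -\ln(1 - positives/total).}
#' A plate with every droplet positive is saturated and carries no
#' concentration information.
#'
#' @param positives number of positive droplets.
#' @param total total droplets read (> 0).
#' @param v_d droplet volume in nL (default 0.85, instrument-typical);
#'   affects only the volumetric concentration, not copy-number ratios.
#' @return List with `lambda` (copies per droplet) and `conc_per_ul`
#'   (copies per microliter, `lambda / v_d * 1000`).
#' @examples
#' conc_from_droplets(10000, 20000)$lambda  # ln 2
#' @export
conc_from_droplets <- function(positives, total, v_d = 0.85) {
  stopifnot(total > 0, positives >= 0)
  if (positives > total) abort("positives exceed total droplets")
  if (positives == total) abort("saturated: all droplets positive")
  lambda <- -log(1 - positives / total)
  list(lambda = lambda, conc_per_ul = lambda / v_d * 1000)
}

#' Copy number via the two-reference normalizer
#'
#' Estimates the copy number of a target locus per diploid genome by
#' normalizing its concentration to the average of two reference loci of
#' known two-copy status, divided by 2:
#' \deqn{CN = \lambda_{target} / (\tfrac{1}{2}(\lambda_{ref1} + \lambda_{ref2}) / 2).}
#' The ratio is invariant to any common scaling of the three inputs
#' (template amount, droplet volume). An integer call is attached when the
#' estimate lies within `band` of an integer.
#'
#' @param target_lambda,ref1_lambda,ref2_lambda concentrations (copies per
#'   droplet or any common unit); reference concentrations must be > 0.
#' @param band half-width of the integer acceptance band (default 0.3).
#' @return List with `CN` (unrounded), `CN_integer` (nearest integer, or
#'   `NA` when outside the band) and `normalizer`.
#' @examples
#' copy_number(0.5, 0.5, 0.5)$CN  # 2: target at reference concentration
#' @export
copy_number <- function(target_lambda, ref1_lambda, ref2_lambda, band = 0.3) {
  if (ref1_lambda <= 0 || ref2_lambda <= 0)
    abort("reference concentrations must be > 0")
  stopifnot(target_lambda >= 0)
  normalizer <- mean(c(ref1_lambda, ref2_lambda)) / 2
  cn <- target_lambda / normalizer
  nearest <- round(cn)
  list(CN = cn,
       CN_integer = if (abs(cn - nearest) <= band) as.integer(nearest)
                    else NA_integer_,
       normalizer = normalizer)
}

#' Simulate droplet partitioning
#'
#' Poisson partitioning of template into droplets: each droplet is
#' positive when it received at least one copy, so
#' `positives ~ Binomial(total, 1 - exp(-lambda))`.
#'
#' @param lambda copies per droplet.
#' @param total droplets.
#' @param seed optional integer seed.
#' @return Number of positive droplets.
#' @export
simulate_droplets <- function(lambda, total, seed = NULL) {
  stopifnot(lambda >= 0, total >= 1)
  set_seed_if(seed)
  stats::rbinom(1, total, 1 - exp(-lambda))
}

#' Run a ddPCR assay table
#'
#' Processes a droplet-count table (one row per amplicon) into per-amplicon
#' concentrations and per-target copy-number calls against two named
#' reference amplicons.
#'
#' @param assay data frame with columns `amplicon_id`, `role` (`"target"`,
#'   `"reference"` or `"single-copy-control"`; controls are treated as
#'   targets), `positives`, `total`.
#' @param refs character vector of exactly two reference amplicon ids;
#'   defaults to the rows with `role == "reference"`.
#' @param v_d droplet volume in nL.
#' @return List with `lambda` (named vector), `normalizer` and `calls`
#'   (data frame: `target_id`, `CN`, `CN_integer`).
#' @export
ddpcr_assay <- function(assay, refs = NULL, v_d = 0.85) {
  req <- c("amplicon_id", "role", "positives", "total")
  miss <- setdiff(req, names(assay))
  if (length(miss) > 0)
    abort("assay table missing column(s): %s", paste(miss, collapse = ", "))
  lambda <- vapply(seq_len(nrow(assay)), function(i)
    conc_from_droplets(assay$positives[i], assay$total[i], v_d)$lambda,
    numeric(1))
  names(lambda) <- assay$amplicon_id
  if (is.null(refs)) refs <- assay$amplicon_id[assay$role == "reference"]
  if (length(refs) != 2)
    abort("exactly two reference amplicons are required, got %d", length(refs))
  if (!all(refs %in% assay$amplicon_id))
    abort("reference amplicon(s) not in table: %s",
          paste(setdiff(refs, assay$amplicon_id), collapse = ", "))
  targets <- setdiff(assay$amplicon_id, refs)
  calls <- do.call(rbind, lapply(targets, function(tid) {
    cn <- copy_number(lambda[[tid]], lambda[[refs[1]]], lambda[[refs[2]]])
    data.frame(target_id = tid, CN = cn$CN, CN_integer = cn$CN_integer,
               stringsAsFactors = FALSE)
  }))
  rownames(calls) <- NULL
  list(lambda = lambda,
       normalizer = mean(lambda[refs]) / 2,
       calls = calls)
}

#' Read a ddPCR droplet-count table
#'
#' CSV columns: `amplicon_id`, `role`, `positives`, `total`.
#'
#' @param path file path.
#' @return Data frame.
#' @export
read_ddpcr_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("amplicon_id", "role", "positives", "total")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0)
    abort("ddPCR table missing column(s): %s", paste(miss, collapse = ", "))
  df
}
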