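#' Scale plate counts to whole-culture values
#'
#' Converts colony counts observed on a plate back to whole-culture mutant
#' counts (selective plates) and viable population sizes (permissive
#' plates): `count * dilution / plated_fraction`. Mutant counts are rounded
#' half-up to whole cells; population sizes are left unrounded.
#'
#' @param selective_count,permissive_count colonies counted on the
#'   selective and permissive plates.
#' @param selective_dilution,permissive_dilution dilution factors (>= 1;
#'   e.g. 100 for a 10^-2 dilution).
#' @param selective_fraction,permissive_fraction fraction of the (diluted)
#'   culture spread on the plate.
#' @return A list with vectors `r` (whole-culture mutant counts) and `N`
#'   (viable cells per culture).
#' @examples
#' counts_from_plating(30, 100, 0.01, 250, 1e4, 0.1)
#' @export
counts_from_plating <- function(selective_count, selective_dilution,
                                selective_fraction,
                                permissive_count, permissive_dilution,
                                permissive_fraction) {
  if (any(selective_dilution < 1) || any(permissive_dilution < 1))
    abort("dilution factors must be >= 1")
  if (any(selective_count < 0) || any(permissive_count < 0))
    abort("colony counts must be >= 0")
  if (any(permissive_count == 0))
    abort("cannot estimate N: zero permissive colonies")
  list(r = round_half_up(selective_count * selective_dilution / selective_fraction),
       N = permissive_count * permissive_dilution / permissive_fraction)
}

#' Read a fluctuation-assay plating table
#'
#' CSV columns: `culture_id`, `selective_count`, `selective_dilution`,
#' `selective_plated_fraction`, `permissive_count`, `permissive_dilution`,
#' `permissive_plated_fraction`.
#'
#' @param path file path.
#' @return Data frame with the input columns plus whole-culture `r` and `N`.
#' @export
read_fluctuation_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("culture_id", "selective_count", "selective_dilution",
           "selective_plated_fraction", "permissive_count",
           "permissive_dilution", "permissive_plated_fraction")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0)
    abort("fluctuation table missing column(s): %s", paste(miss, collapse = ", "))
  sc <- counts_from_plating(df$selective_count, df$selective_dilution,
                            df$selective_plated_fraction,
                            df$permissive_count, df$permissive_dilution,
                            df$permissive_plated_fraction)
  df$r <- sc$r
  df$N <- sc$N
  df
}

#' Lea-Coulson method-of-the-median estimate of m
#'
#' Solves the Lea-Coulson median equation
#' \deqn{\tilde r / m - \ln m = 1.24}
#' for the expected number of mutational events per culture `m`, where
#' `\tilde r` is the median of the per-culture mutant counts. The left-hand
#' side is strictly decreasing in `m`, so the root is unique; it is found
#' by bracketed root search to a relative tolerance of 1e-9, and `m` is
#' strictly increasing in the median count.
#'
#' @param r numeric vector of whole-culture mutant counts (or a
#'   pre-computed median if of length 1).
#' @return The estimate `m` (> 0).
#' @examples
#' lc_median_m(1.24)  # exactly m = 1
#' @export
lc_median_m <- function(r) {
  r_med <- stats::median(r)
  if (!is.finite(r_med) || r_med < 0) abort("invalid mutant counts")
  if (r_med == 0)
    abort("median zero: method of the median undefined (consider a p0 method)")
  f <- function(m) r_med / m - log(m) - 1.24
  upper <- max(r_med * 10, 10)
  lower <- min(r_med / 1e6, 1e-9)
  stats::uniroot(f, c(lower, upper),
                 tol = max(1e-12 * upper, .Machine$double.eps))$root
}

#' Dispersion of ln m for the method of the median
#'
#' Empirical-fit estimator of the standard deviation of `ln m` used by the
#' FALCOR lineage of fluctuation calculators:
#' \deqn{\hat\sigma_{\ln m} = 1.225\, m^{-0.315} / \sqrt{C}}
#' where `C` is the number of parallel cultures. The fit was calibrated by
#' simulation for moderate `m`; see the package vignette for a coverage
#' assessment.
#'
#' @param m expected mutational events per culture.
#' @param C number of cultures.
#' @return `sigma_lnm`, the dispersion of `ln m`.
#' @export
sigma_lnm <- function(m, C) {
  stopifnot(m > 0, C >= 1)
  1.225 * m^(-0.315) / sqrt(C)
}

#' LOH/mutation rate with 95% confidence interval
#'
#' Converts the per-culture event number `m` into a per-cell-division rate
#' `mu = m / N_mean` and attaches a 95% confidence interval computed on the
#' log scale: `exp(ln m +/- 1.96 sigma) / N_mean` with `sigma` from
#' [sigma_lnm()]. With fewer than two cultures the CI is undefined (`NA`)
#' but the point estimate is still returned.
#'
#' @param m expected mutational events per culture.
#' @param N_mean cells per culture (mean of per-culture viable counts).
#' @param C number of cultures (for the CI).
#' @return List with `mu`, `ci_low`, `ci_high`, `sigma_lnm`.
#' @export
loh_rate <- function(m, N_mean, C) {
  stopifnot(N_mean > 0, m >= 0)
  mu <- m / N_mean
  if (C < 2 || m == 0)
    return(list(mu = mu, ci_low = NA_real_, ci_high = NA_real_,
                sigma_lnm = NA_real_))
  s <- sigma_lnm(m, C)
  list(mu = mu,
       ci_low = exp(log(m) - 1.96 * s) / N_mean,
       ci_high = exp(log(m) + 1.96 * s) / N_mean,
       sigma_lnm = s)
}

#' Full fluctuation-assay rate estimate
#'
#' Runs the whole estimation chain on one experiment: median mutant count,
#' Lea-Coulson `m`, rate `mu = m / N_mean` and its 95% CI.
#'
#' @param r whole-culture mutant counts, one per culture.
#' @param N per-culture viable population sizes (recycled if scalar).
#' @param label optional experiment label.
#' @param center how to summarize per-culture `N` into `N_mean`:
#'   `"mean"` (default) or `"median"`.
#' @return An object of class `rate_estimate`: list with `label`,
#'   `r_median`, `m`, `N_mean`, `mu`, `ci_low`, `ci_high`, `sigma_lnm`,
#'   `C`, and the per-culture data.
#' @export
fluctuation_estimate <- function(r, N, label = NULL,
                                 center = c("mean", "median")) {
  center <- match.arg(center)
  if (length(N) == 1) N <- rep(N, length(r))
  stopifnot(length(N) == length(r))
  if (any(N <= 0)) abort("population sizes must be > 0")
  C <- length(r)
  r_med <- stats::median(r)
  m <- lc_median_m(r)
  N_mean <- if (center == "mean") mean(N) else stats::median(N)
  rate <- loh_rate(m, N_mean, C)
  structure(list(label = label, C = C, r_median = r_med, m = m,
                 N_mean = N_mean, mu = rate$mu,
                 ci_low = rate$ci_low, ci_high = rate$ci_high,
                 sigma_lnm = rate$sigma_lnm,
                 r = r, N = N), class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  if (!is.null(x$label)) cat("Experiment:", x$label, "\n")
  cat(sprintf("  C = %d cultures, median r = %g, N_mean = %.3g\n",
              x$C, x$r_median, x$N_mean))
  cat(sprintf("  m = %.4g events/culture\n", x$m))
  cat(sprintf("  rate mu = %.3g per cell division (95%% CI %.3g - %.3g)\n",
              x$mu, x$ci_low, x$ci_high))
  invisible(x)
}

#' Median mutant frequency
#'
#' The median per-culture mutant frequency `median(r) / N_mean` — the
#' quantity a selection plate reports directly, as opposed to the rate,
#' which corrects for jackpot cultures.
#'
#' @param r whole-culture mutant counts.
#' @param N_mean cells per culture.
#' @return Median frequency (events per cell).
#' @export
median_frequency <- function(r, N_mean) {
  stopifnot(N_mean > 0)
  stats::median(r) / N_mean
}

#' Compare two fluctuation experiments
#'
#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test on the per-culture
#' mutant frequencies `r_i / N_i` of two experiments; exact for combined
#' n <= 20 without ties, normal approximation with tie correction
#' otherwise. With `on = "counts"` the raw counts are compared instead.
#'
#' @param exp_a,exp_b lists with elements `r` and `N` (e.g. the output of
#'   [fluctuation_estimate()] or [read_fluctuation_csv()] rows).
#' @param on `"frequencies"` (default) or `"counts"`.
#' @return List with `p_value`, `statistic` (the Mann-Whitney U for the
#'   first sample) and `method`.
#' @export
compare_experiments <- function(exp_a, exp_b,
                                on = c("frequencies", "counts")) {
  on <- match.arg(on)
  val <- function(e) {
    if (length(e$N) == 1) e$N <- rep(e$N, length(e$r))
    if (on == "frequencies") e$r / e$N else e$r
  }
  x <- val(exp_a); y <- val(exp_b)
  if (length(x) < 3 || length(y) < 3)
    abort("each experiment needs >= 3 cultures")
  if (length(unique(c(x, y))) == 1)
    return(list(p_value = 1, statistic = length(x) * length(y) / 2,
                method = "all values tied"))
  exact <- (length(x) + length(y)) <= 20 && !anyDuplicated(c(x, y))
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided",
                       exact = exact, correct = !exact))
  list(p_value = min(1, wt$p.value), statistic = unname(wt$statistic),
       method = wt$method)
}

#' Normalize a rate per kilobase of selectable interval
#'
#' LOH events selected at a marker can initiate anywhere between the
#' centromere and the selection cassette, so interval-to-interval
#' comparisons divide the absolute rate by the centromere-to-cassette
#' distance.
#'
#' @param mu absolute rate (events per cell division).
#' @param cen_to_marker_kb distance in kb between the centromere and the
#'   selection cassette (> 0).
#' @return List with `mu`, `cen_to_marker_kb`, `mu_per_kb`.
#' @export
normalized_rate_per_kb <- function(mu, cen_to_marker_kb) {
  if (!is_scalar_number(cen_to_marker_kb) || cen_to_marker_kb <= 0)
    abort("cen_to_marker_kb must be a positive number")
  list(mu = mu, cen_to_marker_kb = cen_to_marker_kb,
       mu_per_kb = mu / cen_to_marker_kb)
}

#' Rate of two coincident independent events
#'
#' Under independence, the rate of observing two events in the same cell
#' division lineage is the product of the single-event rates; the nearest
#' order of magnitude is reported alongside.
#'
#' @param mu1,mu2 single-event rates.
#' @return List with `rate` (= `mu1 * mu2`) and `order_of_magnitude`
#'   (power of ten nearest to the rate on the log scale; `NA` for rate 0).
#' @examples
#' coincident_rate(1.5e-5, 1.5e-5)  # ~1e-10
#' @export
coincident_rate <- function(mu1, mu2) {
  stopifnot(mu1 >= 0, mu2 >= 0)
  rate <- mu1 * mu2
  list(rate = rate,
       order_of_magnitude = if (rate > 0) round(log10(rate)) else NA_real_)
}

#' Simulate Luria-Delbruck fluctuation cultures
#'
#' Draws per-culture mutant counts under the Lea-Coulson model with
#' deterministic clone growth: the number of mutational events per culture
#' is Poisson with mean `m = mu * N`, and a mutation arising when the
#' population is a fraction `u` of its final size grows into a clone of
#' `floor(1/u)` mutant cells (`u ~ Uniform(0,1]`), capped at `N`. The
#' culture's mutant count is the sum of its clone sizes. With
#' `growth = "stochastic"` clone sizes are instead geometric-tailed
#' (exponentially distributed growth delay), the classical
#' stochastic-growth refinement.
#'
#' The model assumes mutations are rare during growth; `mu * N > N / 10`
#' (i.e. `mu > 0.1`) is rejected as outside the model.
#'
#' @param mu per-division event rate (0 <= mu << 1).
#' @param N final cells per culture (>= 1).
#' @param C number of cultures.
#' @param seed optional integer seed for reproducibility.
#' @param growth `"deterministic"` (default) or `"stochastic"`.
#' @return Integer-valued numeric vector of `C` mutant counts.
#' @examples
#' simulate_cultures(1e-7, 1e6, 10, seed = 1)
#' @export
simulate_cultures <- function(mu, N, C, seed = NULL,
                              growth = c("deterministic", "stochastic")) {
  growth <- match.arg(growth)
  stopifnot(mu >= 0, N >= 1, C >= 1)
  if (mu * N > N / 10) abort("model invalid: mutations not rare (mu > 0.1)")
  set_seed_if(seed)
  m <- mu * N
  K <- stats::rpois(C, m)
  total <- sum(K)
  r <- numeric(C)
  if (total > 0) {
    u <- stats::runif(total)
    clone <- if (growth == "deterministic") {
      pmin(N, floor(1 / u))
    } else {
      # stochastic (Yule) clone growth: size ~ Geometric(u), mean 1/u
      pmin(N, stats::rgeom(total, u) + 1)
    }
    grp <- rep.int(seq_len(C), K)
    sums <- rowsum(clone, grp)
    r[as.integer(rownames(sums))] <- sums
  }
  r
}
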