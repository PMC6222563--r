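#' Read tetrad allele calls from TSV
#'
#' Tab-separated table with columns `chrom`, `pos`, optionally
#' `marker_id`, then one column per spore named `t<k>_s<j>` (tetrad k,
#' spore j); cells are allele symbols or `-` for missing.
#'
#' @param path file path.
#' @return List with `sites` (data frame `chrom`, `pos`, `marker_id`),
#'   `alleles` (matrix markers x spores) and `tetrad_of`.
#' @export
read_tetrad_calls <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("chrom", "pos") %in% names(df)))
    abort("tetrad table needs 'chrom' and 'pos' columns")
  if (is.null(df$marker_id)) df$marker_id <- paste0(df$chrom, "_", df$pos)
  spore_cols <- grep("^t[0-9]+_s[0-9]+$", names(df), value = TRUE)
  if (length(spore_cols) == 0) abort("no spore columns (t<k>_s<j>) found")
  alleles <- as.matrix(df[, spore_cols, drop = FALSE])
  alleles[alleles == "-"] <- NA_character_
  rownames(alleles) <- df$marker_id
  tetrad_of <- sub("_s[0-9]+$", "", spore_cols)
  names(tetrad_of) <- spore_cols
  list(sites = df[, c("chrom", "pos", "marker_id")], alleles = alleles,
       tetrad_of = tetrad_of)
}

#' @keywords internal
write_tetrad_calls <- function(sites, alleles, path) {
  out <- alleles
  out[is.na(out)] <- "-"
  df <- cbind(sites, as.data.frame(out, stringsAsFactors = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Generate a complete synthetic data set
#'
#' Emits every input the pipeline stages consume, plus a truth record:
#' a phased marker map, tetrad allele calls and their encoded phase
#' matrix, an all-pairs cross phenotype matrix for twelve haploids (three
#' tetrads) with a planted recessive locus, genotypes of an LOH clone
#' cohort with endpoint intervals, a fluctuation-assay plating table, and
#' a ddPCR droplet-count table.
#'
#' @param outdir output directory (created if needed).
#' @param config a [sim_genome_config()].
#' @param n_tetrads tetrads to simulate (default 14).
#' @param n_clones LOH clones in the cohort (default 20).
#' @param mu,N,C fluctuation-assay parameters: per-division rate, cells
#'   per culture, number of cultures.
#' @param seed integer seed; the whole data set is a deterministic
#'   function of it.
#' @param crossover_rate,error_rate,missing_rate meiosis parameters passed
#'   to [simulate_tetrads()].
#' @return Invisibly, a list of the generated objects and file paths.
#' @export
simulate_all <- function(outdir, config = sim_genome_config(),
                         n_tetrads = 14, n_clones = 20,
                         mu = 1.5e-5, N = 5.75e7, C = 24,
                         crossover_rate = 1, error_rate = 0,
                         missing_rate = 0, seed = 7) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  set_seed_if(seed)
  paths <- list()

  parent <- simulate_parent(config)
  map <- parent$map
  if (nrow(map) < 4) abort("simulated map too sparse; raise marker_density")
  paths$map <- file.path(outdir, "map.tsv")
  write_marker_map(map, paths$map)

  tet <- simulate_tetrads(map, n_tetrads = n_tetrads,
                          crossover_rate = crossover_rate,
                          error_rate = error_rate,
                          missing_rate = missing_rate)
  sites <- data.frame(chrom = map$chrom, pos = map$pos,
                      marker_id = map$marker_id, stringsAsFactors = FALSE)
  paths$tetrads <- file.path(outdir, "tetrad_calls.tsv")
  write_tetrad_calls(sites, tet$alleles, paths$tetrads)

  phase_obs <- encode_cohort(tet$alleles, map, "haploid")
  paths$genotypes <- file.path(outdir, "spore_phase.tsv")
  write_phase_matrix(phase_obs, paths$genotypes)

  # recessive locus: middle marker of the first chromosome, mutant on M
  ch1 <- map$marker_id[map$chrom == map$chrom[1]]
  locus <- ch1[ceiling(length(ch1) / 2)]
  twelve <- names(tet$tetrad_of)[tet$tetrad_of %in%
                                   sprintf("t%02d", 1:3)]
  mt <- assign_mating_types(tet$tetrad_of[twelve])
  carriers <- carriers_at_marker(tet$phase, locus)[twelve]
  cross <- simulate_cross_matrix(carriers, mt)
  paths$cross_matrix <- file.path(outdir, "cross_matrix.csv")
  write_cross_matrix(cross, paths$cross_matrix)

  # LOH clone cohort on the locus chromosome
  chrom1 <- map$chrom[1]
  cmap <- as_marker_map(as.data.frame(map)[map$chrom == chrom1, ])
  cen <- config$chromosomes$centromere[config$chromosomes$name == chrom1]
  cohort <- simulate_loh_cohort(n_clones, cmap, cen, locus)
  clone_mat <- cohort$calls
  paths$clones <- file.path(outdir, "clone_genotypes.tsv")
  write_phase_matrix(clone_mat, paths$clones)

  # endpoint intervals: markers between centromere and the selected marker
  sel_pos <- cmap$pos[cmap$marker_id == locus]
  ivp <- c(cen, cmap$pos[cmap$pos > cen & cmap$pos <= sel_pos])
  intervals <- data.frame(chrom = chrom1,
                          left_pos = utils::head(ivp, -1),
                          right_pos = ivp[-1], stringsAsFactors = FALSE)
  paths$intervals <- file.path(outdir, "intervals.tsv")
  utils::write.table(intervals, paths$intervals, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  # fluctuation assay: whole cultures plated neat on selection, a fixed
  # dilution on permissive plates
  r <- simulate_cultures(mu, N, C)
  fluct <- data.frame(culture_id = sprintf("c%02d", seq_len(C)),
                      selective_count = r, selective_dilution = 1,
                      selective_plated_fraction = 1,
                      permissive_count = round(N / 1e5),
                      permissive_dilution = 1e5,
                      permissive_plated_fraction = 1)
  paths$fluctuation <- file.path(outdir, "fluctuation.csv")
  utils::write.csv(fluct, paths$fluctuation, row.names = FALSE, quote = FALSE)

  # ddPCR: two 2-copy references, a 2-copy target, a 1-copy control
  lam <- c(CEN_L = 0.5, CEN_R = 0.5, TARGET = 0.5, ONECOPY = 0.25)
  role <- c("reference", "reference", "target", "single-copy-control")
  dd <- data.frame(amplicon_id = names(lam), role = role,
                   positives = vapply(lam, function(l)
                     simulate_droplets(l, 20000), numeric(1)),
                   total = 20000, stringsAsFactors = FALSE)
  paths$ddpcr <- file.path(outdir, "ddpcr.csv")
  utils::write.csv(dd, paths$ddpcr, row.names = FALSE, quote = FALSE)

  truth <- list(seed = seed, locus = locus, mutant_homolog = "M",
                centromere = stats::setNames(as.list(config$chromosomes$centromere),
                                             config$chromosomes$name),
                clone_mechanisms = cohort$mechanisms,
                clone_breakpoints = lapply(cohort$clones,
                                           function(cl) cl$truth$breakpoint),
                fluct = list(mu = mu, N = N, C = C),
                ddpcr_lambda = as.list(lam),
                n_markers = nrow(map))
  paths$truth <- file.path(outdir, "truth.json")
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(map = map, tetrads = tet, cross = cross, cohort = cohort,
                 fluctuation = fluct, ddpcr = dd, truth = truth,
                 paths = paths))
}

parse_centromere <- function(x) {
  # "chr12:151000" or list(chrom =, pos =)
  if (is.list(x)) return(x)
  parts <- strsplit(x, ":", fixed = TRUE)[[1]]
  if (length(parts) != 2) abort("centromere must be 'chrom:pos'")
  list(chrom = parts[1], pos = as.numeric(parts[2]))
}

check_inputs <- function(paths) {
  missing <- paths[!vapply(paths, file.exists, logical(1))]
  if (length(missing) > 0)
    abort("input file(s) not found: %s",
          paste(unlist(missing), collapse = ", "))
  invisible(paths)
}

result_envelope <- function(config_hash, inputs, seed, results) {
  list(tool = "lohkit",
       version = as.character(utils::packageVersion("lohkit")),
       schema = 1L,
       seed = seed,
       config_hash = config_hash,
       input_md5 = as.list(inputs),
       results = results)
}

#' Run pipeline stages from a configuration
#'
#' Orchestrates the analysis stages end-to-end. The configuration is a
#' list (or a YAML file with the same structure) with elements:
#' \describe{
#'   \item{stages}{character vector among `"phase"`, `"carriers"`,
#'     `"mapscan"`, `"fluct"`, `"tracts"`, `"ddpcr"`.}
#'   \item{inputs}{named list of input file paths (`tetrads`, `map`,
#'     `genotypes`, `cross_matrix`, `fluctuation`, `clones`, `intervals`,
#'     `ddpcr`, `gff` as required by the selected stages).}
#'   \item{params}{named list: `max_missing_tetrads`, `max_missing`,
#'     `group1`, `group2`, `centromere` (`"chrom:pos"`), `refs`,
#'     `cen_to_marker_kb`.}
#'   \item{seed}{integer, recorded in every output.}
#' }
#' Each stage writes `<stage>.json` into `outdir` containing the tool
#' version, a hash of the configuration, md5 checksums of its inputs, the
#' seed and the stage results; given the same config and inputs the
#' outputs are byte-identical. Inputs are never modified.
#'
#' @param config list or path to a YAML file.
#' @param outdir output directory.
#' @return Named list of per-stage result lists, invisibly.
#' @export
run_pipeline <- function(config, outdir) {
  if (is.character(config)) {
    check_inputs(list(config = config))
    config_hash <- unname(tools::md5sum(config))
    config <- yaml::read_yaml(config)
  } else {
    tmp <- tempfile()
    on.exit(unlink(tmp), add = TRUE)
    writeLines(yaml::as.yaml(config), tmp)
    config_hash <- unname(tools::md5sum(tmp))
  }
  stages <- config$stages %||% abort("config has no 'stages'")
  inputs <- config$inputs %||% list()
  params <- config$params %||% list()
  seed <- config$seed %||% NA_integer_
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  need <- function(key) {
    p <- inputs[[key]] %||% abort("stage needs input '%s'", key)
    check_inputs(list(p))
    p
  }
  md5 <- function(paths) vapply(paths, function(p) unname(tools::md5sum(p)),
                                character(1))
  out <- list()
  for (stage in stages) {
    res <- switch(
      stage,
      phase = {
        p <- need("tetrads")
        td <- read_tetrad_calls(p)
        built <- build_phased_map(td$sites, td$alleles, td$tetrad_of,
                                  params$max_missing_tetrads %||% 2)
        map_path <- file.path(outdir, "map.tsv")
        write_marker_map(built$map, map_path)
        result_envelope(config_hash, md5(c(tetrads = p)), seed,
                        list(n_sites = nrow(td$sites),
                             n_kept = sum(built$filter$keep),
                             n_markers = nrow(built$map),
                             drop_reasons = as.list(table(
                               built$filter$reason[!built$filter$keep])),
                             map = basename(map_path)))
      },
      carriers = {
        p <- need("cross_matrix")
        inf <- infer_carriers(read_cross_matrix(p))
        result_envelope(config_hash, md5(c(cross_matrix = p)), seed,
                        inf[c("confirmed_carriers", "confirmed_noncarriers",
                              "unknown", "consistent")])
      },
      mapscan = {
        pm <- need("map"); pg <- need("genotypes")
        map <- read_marker_map(pm)
        vec <- read_phase_matrix(pg, "haploid")
        vec <- vec[, map$marker_id, drop = FALSE]
        scan <- cosegregation_scan(vec, map,
                                   params$group1 %||% abort("mapscan needs params$group1"),
                                   params$group2 %||% abort("mapscan needs params$group2"),
                                   params$max_missing %||% 0)
        genes <- if (!is.null(inputs$gff)) read_gff_genes(need("gff"))
        regions <- merge_candidate_regions(scan, map, genes)
        reg_path <- file.path(outdir, "regions.tsv")
        utils::write.table(regions, reg_path, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        result_envelope(config_hash, md5(c(map = pm, genotypes = pg)), seed,
                        list(n_pass = sum(scan$pass),
                             n_regions = nrow(regions),
                             regions = basename(reg_path)))
      },
      fluct = {
        p <- need("fluctuation")
        df <- read_fluctuation_csv(p)
        est <- fluctuation_estimate(df$r, df$N)
        res <- est[c("C", "r_median", "m", "N_mean", "mu",
                     "ci_low", "ci_high", "sigma_lnm")]
        res$median_frequency <- median_frequency(df$r, est$N_mean)
        if (!is.null(params$cen_to_marker_kb))
          res$mu_per_kb <- normalized_rate_per_kb(
            est$mu, params$cen_to_marker_kb)$mu_per_kb
        result_envelope(config_hash, md5(c(fluctuation = p)), seed, res)
      },
      tracts = {
        pm <- need("map"); pc <- need("clones")
        map <- read_marker_map(pm)
        cen <- parse_centromere(params$centromere %||%
                                  abort("tracts needs params$centromere"))
        cmap <- as_marker_map(as.data.frame(map)[map$chrom == cen$chrom, ])
        clones <- read_phase_matrix(pc, "diploid")
        clones <- clones[, cmap$marker_id, drop = FALSE]
        per_clone <- lapply(rownames(clones), function(id) {
          ct <- call_tracts(clones[id, ], cmap, cen$pos)
          list(clone = id, n_tracts = nrow(ct$tracts),
               tracts = ct$tracts)
        })
        eps <- unlist(lapply(per_clone, function(x)
          x$tracts$endpoint_bp[!is.na(x$tracts$endpoint_bp)]))
        res <- list(n_clones = nrow(clones),
                    n_tracts = sum(vapply(per_clone, `[[`, numeric(1),
                                          "n_tracts")),
                    endpoints = eps)
        if (!is.null(inputs$intervals)) {
          iv <- utils::read.delim(need("intervals"))
          tab <- tally_endpoints(eps, iv)
          ch <- chisq_size_model(tab$O, tab$L)
          res$size_model <- list(O = tab$O, L = tab$L, chi2 = ch$chi2,
                                 df = ch$df, p = ch$p)
        }
        result_envelope(config_hash, md5(c(map = pm, clones = pc)), seed, res)
      },
      ddpcr = {
        p <- need("ddpcr")
        dd <- ddpcr_assay(read_ddpcr_csv(p), refs = params$refs)
        result_envelope(config_hash, md5(c(ddpcr = p)), seed,
                        list(lambda = as.list(dd$lambda),
                             normalizer = dd$normalizer,
                             calls = dd$calls))
      },
      abort("unknown stage '%s'", stage)
    )
    jsonlite::write_json(res, file.path(outdir, paste0(stage, ".json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    out[[stage]] <- res
  }
  invisible(out)
}
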