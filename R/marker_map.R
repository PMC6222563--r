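#' Phased heterozygous-marker maps
#'
#' A `marker_map` is an ordered table of phased heterozygous SNP markers: one
#' row per marker with its chromosome, 1-based position, a unique marker id,
#' and the two alleles assigned to the arbitrarily labelled maternal (M) and
#' paternal (P) homologs. It is the coordinate system every downstream
#' analysis (co-segregation scans, LOH tract calling) is indexed on.
#'
#' Invariants enforced by the constructor: positions strictly increasing
#' within each chromosome, no duplicated positions or marker ids, and
#' `allele_M != allele_P` at every marker (a marker where both homologs carry
#' the same allele is not heterozygous and cannot be phased).
#'
#' @param chrom character vector of chromosome ids.
#' @param pos integer vector of 1-based marker positions.
#' @param marker_id character vector of unique marker ids. Defaults to
#'   `"<chrom>_<pos>"`.
#' @param allele_M,allele_P allele symbols (single bases or short indel
#'   tokens such as `"A8"`/`"A7"`) on the M and P homolog.
#' @param n_tetrads,filters provenance metadata: number of tetrads the map
#'   was phased from and a character vector describing filters applied.
#' @return An object of class `marker_map`: a `data.frame` with columns
#'   `chrom`, `pos`, `marker_id`, `allele_M`, `allele_P` (plus any extra
#'   columns such as phasing confidence), rows sorted by chromosome then
#'   position, with provenance stored in attributes.
#' @examples
#' marker_map(chrom = "chr12", pos = c(158e3, 199e3),
#'            allele_M = c("A", "T"), allele_P = c("G", "C"))
#' @export
marker_map <- function(chrom, pos, allele_M, allele_P,
                       marker_id = paste0(chrom, "_", pos),
                       n_tetrads = NA_integer_, filters = character()) {
  df <- data.frame(chrom = as.character(chrom), pos = as.numeric(pos),
                   marker_id = as.character(marker_id),
                   allele_M = as.character(allele_M),
                   allele_P = as.character(allele_P),
                   stringsAsFactors = FALSE)
  as_marker_map(df, n_tetrads = n_tetrads, filters = filters)
}

#' Coerce a data frame to a marker map
#'
#' @param df data frame with columns `chrom`, `pos`, `allele_M`, `allele_P`
#'   and optionally `marker_id`.
#' @inheritParams marker_map
#' @return A validated `marker_map`.
#' @export
as_marker_map <- function(df, n_tetrads = NA_integer_, filters = character()) {
  req <- c("chrom", "pos", "allele_M", "allele_P")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0)
    abort("marker map is missing column(s): %s", paste(missing_cols, collapse = ", "))
  if (is.null(df$marker_id))
    df$marker_id <- if (nrow(df) == 0) character(0)
                    else paste0(df$chrom, "_", df$pos)
  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  rownames(df) <- NULL
  if (nrow(df) > 0) {
    if (any(df$pos < 1)) abort("marker positions must be >= 1")
    dup <- unlist(lapply(split(df$pos, df$chrom), function(p) duplicated(p)))
    if (any(dup)) abort("duplicated marker positions within a chromosome")
    if (anyDuplicated(df$marker_id)) abort("duplicated marker_id in map")
    same <- df$allele_M == df$allele_P
    if (any(same))
      abort("allele_M equals allele_P at marker(s): %s",
            paste(utils::head(df$marker_id[same], 3), collapse = ", "))
  }
  structure(df,
            n_tetrads = n_tetrads, filters = filters,
            class = c("marker_map", "data.frame"))
}

#' @export
print.marker_map <- function(x, ...) {
  cat(sprintf("Phased marker map: %d markers on %d chromosome(s)\n",
              nrow(x), length(unique(x$chrom))))
  if (!is.na(attr(x, "n_tetrads")))
    cat(sprintf("  phased from %d tetrads\n", attr(x, "n_tetrads")))
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat(sprintf("  ... %d more markers\n", nrow(x) - 10L))
  invisible(x)
}

#' Read / write a marker map as TSV
#'
#' The on-disk format is a tab-separated table with a header and columns
#' `chrom`, `pos`, `marker_id`, `allele_M`, `allele_P` (extra columns are
#' kept).
#'
#' @param path file path.
#' @return `read_marker_map()` returns a `marker_map`;
#'   `write_marker_map()` returns `path` invisibly.
#' @export
read_marker_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  as_marker_map(df)
}

#' @param map a `marker_map`.
#' @rdname read_marker_map
#' @export
write_marker_map <- function(map, path) {
  utils::write.table(as.data.frame(map), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Import a phased marker map from a VCF with phased genotypes
#'
#' Reads a VCF whose single diploid sample carries phased genotypes
#' (`GT` of the form `0|1` or `1|0`) and converts the phased heterozygous
#' biallelic records into a [marker_map]. The dialect is: the left-hand
#' haplotype of the phased genotype is the M homolog, so `0|1` assigns
#' M = REF, P = ALT and `1|0` the reverse. Unphased, homozygous or
#' multi-allelic records are dropped with a message.
#'
#' @param path path to a VCF file (requires the \pkg{vcfR} package).
#' @param sample sample name; defaults to the first sample.
#' @return A `marker_map`.
#' @export
read_marker_map_vcf <- function(path, sample = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    abort("reading VCF maps requires the 'vcfR' package")
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(sample)) sample <- colnames(gt)[1]
  g <- gt[, sample]
  chrom <- fix[, "CHROM"]; pos <- as.numeric(fix[, "POS"])
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  usable <- g %in% c("0|1", "1|0") & !grepl(",", alt)
  if (any(!usable))
    message(sum(!usable), " record(s) dropped (not phased biallelic het)")
  m <- ifelse(g[usable] == "0|1", ref[usable], alt[usable])
  p <- ifelse(g[usable] == "0|1", alt[usable], ref[usable])
  marker_map(chrom = chrom[usable], pos = pos[usable],
             allele_M = m, allele_P = p)
}

#' Read / write encoded genotype matrices
#'
#' Phase-encoded genotype matrices are stored as TSV with samples in rows:
#' the first column is `sample_id`, the remaining columns are marker ids,
#' and cells are `M`, `P`, `H` (heterozygous, diploid files only) or `-`
#' (missing). `read_phase_matrix()` returns a character matrix with sample
#' row names, marker column names and `NA` for missing; haploid files
#' containing `H` are rejected.
#'
#' @param path file path.
#' @param ploidy `"haploid"` or `"diploid"`; haploid matrices must not
#'   contain `H` calls.
#' @return a character matrix (values `"M"`, `"P"`, `"H"`, `NA`).
#' @export
read_phase_matrix <- function(path, ploidy = c("haploid", "diploid")) {
  ploidy <- match.arg(ploidy)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "sample_id")
    abort("genotype matrix must have 'sample_id' as its first column")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$sample_id
  m[m == "-"] <- NA_character_
  bad <- setdiff(unique(as.vector(m[!is.na(m)])), c("M", "P", "H"))
  if (length(bad) > 0)
    abort("invalid genotype code(s): %s", paste(bad, collapse = ", "))
  if (ploidy == "haploid" && any(m == "H", na.rm = TRUE))
    abort("haploid genotype matrix contains 'H' calls")
  m
}

#' @param mat character matrix as returned by `read_phase_matrix()`.
#' @rdname read_phase_matrix
#' @export
write_phase_matrix <- function(mat, path) {
  out <- mat
  out[is.na(out)] <- "-"
  df <- data.frame(sample_id = rownames(out), out,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
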