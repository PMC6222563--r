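#' Infer recessive-allele carriers from an all-pairs cross matrix
#'
#' Given the phenotypes of all tested MATa x MATalpha diploids, infers which
#' haploid parents carry a recessive mutant allele under a single-gene
#' model: a diploid shows the mutant (ROUGH) phenotype iff both parents
#' carry the recessive allele. Carriers are confirmed by participation in
#' at least one ROUGH cross; a haploid is a confirmed non-carrier if it
#' made a SMOOTH diploid with a confirmed carrier. Haploids supporting
#' neither deduction stay unknown — in particular, an all-SMOOTH matrix
#' identifies nobody (one whole mating type could still carry the allele).
#'
#' Consistency of the single-gene recessive model is checked exactly: the
#' forced assignment above must reproduce every tested cell, i.e. no SMOOTH
#' cross may join two confirmed carriers and no haploid may be forced both
#' ways. Inconsistency is a reported state (with a witness cross), not an
#' error.
#'
#' @param matrix character matrix of phenotypes; rows MATa haploids, columns
#'   MATalpha haploids (both named), cells `"R"` (rough), `"S"` (smooth) or
#'   `NA` (untested).
#' @return A list of class `carrier_inference`:
#'   `confirmed_carriers`, `confirmed_noncarriers`, `unknown` (character
#'   vectors partitioning the haploid ids), `consistent` (logical) and
#'   `witness` (a `data.frame` row describing one violating cross, or
#'   `NULL`).
#' @examples
#' m <- matrix("S", 2, 2, dimnames = list(c("a1", "a2"), c("b1", "b2")))
#' m["a1", "b1"] <- "R"
#' infer_carriers(m)
#' @export
infer_carriers <- function(matrix) {
  stopifnot(is.matrix(matrix))
  if (is.null(rownames(matrix)) || is.null(colnames(matrix)))
    abort("cross matrix must have row and column names")
  if (length(intersect(rownames(matrix), colnames(matrix))) > 0)
    abort("MATa and MATalpha ids must be disjoint")
  vals <- unique(as.vector(matrix[!is.na(matrix)]))
  if (length(vals) == 0) abort("cross matrix has no tested cell")
  if (!all(vals %in% c("R", "S")))
    abort("phenotypes must be 'R', 'S' or NA, got: %s",
          paste(setdiff(vals, c("R", "S")), collapse = ", "))
  ids <- c(rownames(matrix), colnames(matrix))

  rough <- which(matrix == "R", arr.ind = TRUE)
  carriers <- unique(c(rownames(matrix)[rough[, 1]],
                       colnames(matrix)[rough[, 2]]))
  smooth <- which(matrix == "S", arr.ind = TRUE)
  smooth_df <- data.frame(MATa = rownames(matrix)[smooth[, 1]],
                          MATalpha = colnames(matrix)[smooth[, 2]],
                          stringsAsFactors = FALSE)
  noncarriers <- unique(c(
    smooth_df$MATa[smooth_df$MATalpha %in% carriers],
    smooth_df$MATalpha[smooth_df$MATa %in% carriers]))

  # consistency: forced sets must not collide, and no smooth cross between
  # two confirmed carriers (rough crosses satisfy the rule by construction)
  witness <- NULL
  clash <- intersect(carriers, noncarriers)
  if (length(clash) > 0) {
    i <- which(smooth_df$MATa == clash[1] | smooth_df$MATalpha == clash[1])[1]
    witness <- data.frame(MATa = smooth_df$MATa[i],
                          MATalpha = smooth_df$MATalpha[i],
                          phenotype = "S", stringsAsFactors = FALSE)
  } else {
    both <- smooth_df$MATa %in% carriers & smooth_df$MATalpha %in% carriers
    if (any(both)) {
      i <- which(both)[1]
      witness <- data.frame(MATa = smooth_df$MATa[i],
                            MATalpha = smooth_df$MATalpha[i],
                            phenotype = "S", stringsAsFactors = FALSE)
    }
  }
  consistent <- is.null(witness)
  noncarriers <- setdiff(noncarriers, carriers)
  structure(list(
    confirmed_carriers = sort(carriers),
    confirmed_noncarriers = sort(noncarriers),
    unknown = sort(setdiff(ids, c(carriers, noncarriers))),
    consistent = consistent,
    witness = witness), class = "carrier_inference")
}

#' @export
print.carrier_inference <- function(x, ...) {
  cat("Carrier inference (single-gene recessive model)\n")
  cat("  consistent:", x$consistent, "\n")
  cat("  carriers:   ", paste(x$confirmed_carriers, collapse = ", "), "\n")
  cat("  non-carriers:", paste(x$confirmed_noncarriers, collapse = ", "), "\n")
  cat("  unknown:    ", paste(x$unknown, collapse = ", "), "\n")
  if (!is.null(x$witness))
    cat("  witness: ", x$witness$MATa, "x", x$witness$MATalpha,
        "=", x$witness$phenotype, "\n")
  invisible(x)
}

#' Strict co-segregation scan over a phased map
#'
#' For each marker of a phased map, tests whether one homolog's allele is
#' carried by every haploid in `group1` while the other homolog's allele is
#' carried by every haploid in `group2` — the strict criterion for a marker
#' linked to a trait that cleanly separates the two groups. Missing calls
#' never count as agreement: a marker passes only when the total number of
#' missing calls across both groups is at most `max_missing` and every
#' non-missing call fits one orientation.
#'
#' @param vectors character matrix of phase-encoded genotypes: samples in
#'   rows (named), markers in columns in map order, values `"M"`, `"P"`,
#'   `NA` (a stray `"H"` counts as disagreement for haploid data).
#' @param map the [marker_map] the columns are indexed on.
#' @param group1,group2 disjoint non-empty character vectors of sample ids.
#' @param max_missing maximum missing calls tolerated per marker across both
#'   groups (default 0: fully strict).
#' @return Data frame with one row per marker: `marker_id`, `chrom`, `pos`,
#'   `pass`, `orientation` (`"group1=M"` or `"group1=P"` for passing
#'   markers, `NA` otherwise) and `n_missing`.
#' @export
cosegregation_scan <- function(vectors, map, group1, group2, max_missing = 0) {
  stopifnot(is.matrix(vectors))
  if (ncol(vectors) != nrow(map))
    abort("index mismatch: %d vector columns vs %d map markers",
          ncol(vectors), nrow(map))
  if (!is.null(colnames(vectors)) &&
      !identical(colnames(vectors), map$marker_id))
    abort("index mismatch: vector columns are not the map's markers in order")
  if (length(group1) == 0 || length(group2) == 0)
    abort("both groups must be non-empty")
  if (length(intersect(group1, group2)) > 0)
    abort("groups must be disjoint")
  missing_ids <- setdiff(c(group1, group2), rownames(vectors))
  if (length(missing_ids) > 0)
    abort("index mismatch: sample(s) not in vectors: %s",
          paste(missing_ids, collapse = ", "))

  g1 <- vectors[group1, , drop = FALSE]
  g2 <- vectors[group2, , drop = FALSE]
  n_missing <- colSums(is.na(g1)) + colSums(is.na(g2))
  all_of <- function(m, val) colSums(m == val, na.rm = TRUE) + colSums(is.na(m)) == nrow(m)
  has_call <- function(m) colSums(!is.na(m)) > 0
  informative <- has_call(g1) & has_call(g2) & n_missing <= max_missing
  ori1 <- all_of(g1, "M") & all_of(g2, "P") & informative  # group1 = M
  ori2 <- all_of(g1, "P") & all_of(g2, "M") & informative  # group1 = P
  pass <- ori1 | ori2
  data.frame(marker_id = map$marker_id, chrom = map$chrom, pos = map$pos,
             pass = pass,
             orientation = ifelse(ori1, "group1=M",
                                  ifelse(ori2, "group1=P", NA_character_)),
             n_missing = as.integer(n_missing),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Merge passing markers into candidate regions
#'
#' Maximal runs of consecutive passing markers (same chromosome, same
#' orientation) become candidate regions. By default the span is reported
#' marker-to-marker, from the first to the last passing marker;
#' `extend_to_flanks = TRUE` instead extends each side to the midpoint
#' towards the nearest failing marker (or leaves the boundary at the
#' passing marker when there is none).
#'
#' @param scan result of [cosegregation_scan()].
#' @param map the [marker_map] the scan was run on.
#' @param genes optional gene annotation: data frame with columns `chrom`,
#'   `start`, `end` (and optionally `gene_id`); `n_genes` counts genes
#'   overlapping the region span by at least one bp.
#' @param extend_to_flanks logical; see above.
#' @return Data frame with columns `chrom`, `start_pos`, `end_pos`,
#'   `n_markers`, `orientation` and (when `genes` is supplied) `n_genes`.
#'   Zero passing markers yield a zero-row data frame.
#' @export
merge_candidate_regions <- function(scan, map, genes = NULL,
                                    extend_to_flanks = FALSE) {
  stopifnot(nrow(scan) == nrow(map))
  empty <- data.frame(chrom = character(), start_pos = numeric(),
                      end_pos = numeric(), n_markers = integer(),
                      orientation = character(), stringsAsFactors = FALSE)
  if (!any(scan$pass)) {
    if (!is.null(genes)) empty$n_genes <- integer()
    return(empty)
  }
  # run id increments whenever pass/orientation/chrom changes
  key <- paste(scan$chrom, scan$pass, scan$orientation)
  run <- cumsum(c(TRUE, key[-1] != key[-length(key)]))
  out <- do.call(rbind, lapply(split(seq_len(nrow(scan)), run), function(idx) {
    if (!scan$pass[idx[1]]) return(NULL)
    first <- idx[1]; last <- idx[length(idx)]
    start <- map$pos[first]; end <- map$pos[last]
    if (extend_to_flanks) {
      same_chrom <- which(map$chrom == map$chrom[first])
      prev <- same_chrom[same_chrom < first]
      nxt <- same_chrom[same_chrom > last]
      if (length(prev) > 0) start <- (map$pos[max(prev)] + start) / 2
      if (length(nxt) > 0) end <- (end + map$pos[min(nxt)]) / 2
    }
    data.frame(chrom = map$chrom[first], start_pos = start, end_pos = end,
               n_markers = length(idx),
               orientation = scan$orientation[first],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  if (!is.null(genes)) {
    out$n_genes <- vapply(seq_len(nrow(out)), function(i) {
      sum(genes$chrom == out$chrom[i] &
            genes$start <= out$end_pos[i] &
            genes$end >= out$start_pos[i])
    }, integer(1))
  }
  out
}

#' Read gene intervals from a GFF3 file
#'
#' Extracts `gene` features from a GFF3 annotation into the plain interval
#' table [merge_candidate_regions()] consumes. Requires \pkg{rtracklayer}.
#'
#' @param path path to a GFF3 file.
#' @return Data frame with columns `chrom`, `start`, `end`, `gene_id`.
#' @export
read_gff_genes <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    abort("reading GFF3 requires the 'rtracklayer' package")
  gr <- as.data.frame(rtracklayer::import(path))
  gr <- gr[gr$type == "gene", , drop = FALSE]
  data.frame(chrom = as.character(gr$seqnames),
             start = gr$start, end = gr$end,
             gene_id = if (!is.null(gr$ID)) as.character(gr$ID)
                       else as.character(seq_len(nrow(gr))),
             stringsAsFactors = FALSE)
}

#' Read / write a cross phenotype matrix as CSV
#'
#' Rows are MATa haploids (first column `MATa`), columns MATalpha haploids;
#' cells `R`, `S` or `NA` for untested crosses.
#'
#' @param path file path.
#' @return `read_cross_matrix()` returns a character matrix.
#' @export
read_cross_matrix <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m[m == ""] <- NA_character_
  m
}

#' @param matrix character cross matrix.
#' @rdname read_cross_matrix
#' @export
write_cross_matrix <- function(matrix, path) {
  df <- data.frame(MATa = rownames(matrix), matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}
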