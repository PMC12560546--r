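#' Read an ABH genotype table
#'
#' Parses a tab-separated genotype file with markers in columns and
#' individuals in rows: the first row is a header of marker names and the
#' first column holds individual identifiers.  Every cell must be one of the
#' four call symbols `A`, `B`, `H`, `-` (see [genotype_calls()]); anything
#' else, a duplicated identifier, or a ragged row is an error that names the
#' offending position.
#'
#' @param path Path to a tab-separated genotype file.
#' @return A tibble whose first column `individual` holds the individual ids
#'   and whose remaining columns (one per marker, in file order) hold
#'   character genotype calls.
#' @seealso [read_marker_map()], [population_summary()], [write_genotypes()]
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("id\tm1\tm2", "i1\tA\tH", "i2\tB\t-", "i3\tH\tH"), f)
#' read_genotypes(f)
#' @export
read_genotypes <- function(path) {
  rows <- read_tsv_rows(path)
  if (length(rows) < 2L) {
    abort(sprintf("genotype file '%s' must have a header row and at least one individual", path))
  }
  header <- rows[[1L]]
  markers <- header[-1L]
  if (length(markers) == 0L) abort("genotype file has no marker columns")
  if (anyDuplicated(markers)) {
    abort(sprintf("duplicate marker id '%s' in genotype header", markers[duplicated(markers)][1L]))
  }
  body <- rows[-1L]
  widths <- lengths(body)
  expected <- length(header)
  if (any(widths != expected)) {
    bad <- which(widths != expected)[1L]
    abort(sprintf(
      "ragged genotype file: row %d has %d fields, expected %d",
      bad + 1L, widths[bad], expected
    ))
  }
  ids <- vapply(body, `[[`, character(1L), 1L)
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate individual id '%s' in genotype file", ids[duplicated(ids)][1L]))
  }
  calls <- matrix("", nrow = length(body), ncol = length(markers))
  for (i in seq_along(body)) calls[i, ] <- body[[i]][-1L]
  bad <- !(calls %in% CALL_LEVELS)
  if (any(bad)) {
    idx <- which(bad)[1L]
    rc <- arrayInd(idx, dim(calls))
    abort(sprintf(
      "invalid genotype call '%s' at row %d (individual '%s'), column %d (marker '%s'): calls must be one of %s",
      calls[idx], rc[1L] + 1L, ids[rc[1L]], rc[2L] + 1L, markers[rc[2L]],
      paste0("'", CALL_LEVELS, "'", collapse = ", ")
    ))
  }
  colnames(calls) <- markers
  out <- as_tibble(as.data.frame(calls, stringsAsFactors = FALSE, check.names = FALSE))
  dplyr::bind_cols(tibble(individual = ids), out)
}

#' Read a marker map
#'
#' Parses the two-column tab-separated marker file: first column the
#' chromosome name, second the marker name, in the same order as the marker
#' columns of the genotype file.  A header line is tolerated and skipped when
#' the file's first chromosome label never reappears (detected by second-row
#' lookahead).  Entries of one chromosome must be contiguous; file order is
#' authoritative and never re-sorted.
#'
#' @param path Path to a two-column tab-separated file.
#' @return A tibble with columns `chrom` and `marker`, in file order.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("chr1\tm1", "chr1\tm2", "chr2\tm3"), f)
#' read_marker_map(f)
#' @export
read_marker_map <- function(path) {
  rows <- read_tsv_rows(path)
  if (length(rows) == 0L) abort(sprintf("marker file '%s' is empty", path))
  widths <- lengths(rows)
  if (any(widths != 2L)) {
    bad <- which(widths != 2L)[1L]
    abort(sprintf("marker file row %d has %d columns, expected 2 (chromosome, marker)", bad, widths[bad]))
  }
  chrom <- vapply(rows, `[[`, character(1L), 1L)
  marker <- vapply(rows, `[[`, character(1L), 2L)
  # Header lookahead: the first line is treated as a header iff its first
  # field never reappears as a chromosome label.  A single-marker chromosome
  # listed first is indistinguishable from a header under this rule; the
  # downstream marker-count consistency check fails loudly in that case.
  if (length(chrom) > 1L && !(chrom[1L] %in% chrom[-1L])) {
    chrom <- chrom[-1L]
    marker <- marker[-1L]
  }
  if (anyDuplicated(marker)) {
    abort(sprintf("duplicate marker '%s' in marker file", marker[duplicated(marker)][1L]))
  }
  blocks <- rle(chrom)$values
  if (anyDuplicated(blocks)) {
    split_chrom <- blocks[duplicated(blocks)][1L]
    abort(sprintf(
      "chromosome '%s' is split into non-contiguous blocks in the marker file; markers of one chromosome must be consecutive",
      split_chrom
    ))
  }
  tibble(chrom = chrom, marker = marker)
}

#' Summarise a genotype table against its marker map
#'
#' Checks that the genotype table and marker map describe the same markers in
#' the same order (name and position must both agree; the first discordant
#' position is reported), then returns population-level summaries: the
#' overall missing-call fraction and the per-individual heterozygosity rate.
#'
#' @param geno Genotype tibble from [read_genotypes()] or [simulate_f2()].
#' @param map Marker-map tibble from [read_marker_map()].
#' @param het_denominator How the heterozygosity rate is computed: `"nonmissing"`
#'   (default) divides the H count by the number of non-missing calls,
#'   `"all"` by the full marker count.
#' @return A list with elements `n_individuals`, `n_markers`,
#'   `missing_fraction`, and `het` (a tibble `individual`, `het_rate`).
#' @examples
#' sim <- simulate_f2(5, sim_chromosomes(2, length_cm = 50, n_markers = 4), seed = 1)
#' population_summary(sim$genotypes, sim$map)
#' @export
population_summary <- function(geno, map, het_denominator = c("nonmissing", "all")) {
  het_denominator <- match.arg(het_denominator)
  check_geno_map(geno, map)
  codes <- geno_codes(geno)
  if (nrow(codes) == 0L) abort("genotype table has no individuals")
  list(
    n_individuals = nrow(codes),
    n_markers = ncol(codes),
    missing_fraction = mean(codes == 4L),
    het = tibble(
      individual = rownames(codes),
      het_rate = het_rate_codes(codes, het_denominator)
    )
  )
}

# Shared consistency check: marker names of the genotype table must equal the
# marker column of the map, position by position.
check_geno_map <- function(geno, map) {
  stopifnot(is.data.frame(geno), is.data.frame(map))
  gm <- colnames(geno)[-1L]
  mm <- map$marker
  if (length(gm) != length(mm)) {
    abort(sprintf(
      "genotype table has %d markers but marker map has %d", length(gm), length(mm)
    ))
  }
  diff <- which(gm != mm)
  if (length(diff)) {
    abort(sprintf(
      "marker order mismatch at position %d: genotype table has '%s', marker map has '%s'",
      diff[1L], gm[diff[1L]], mm[diff[1L]]
    ))
  }
  invisible(TRUE)
}

#' Write genotype and marker-map tables
#'
#' Serialise the tab-separated formats consumed by [read_genotypes()] and
#' [read_marker_map()]; a written table re-reads cell-for-cell identical.
#'
#' @param geno Genotype tibble.
#' @param map Marker-map tibble.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_genotypes <- function(geno, path) {
  readr::write_tsv(geno, path, col_names = TRUE)
  invisible(path)
}

#' @rdname write_genotypes
#' @export
write_marker_map <- function(map, path) {
  readr::write_tsv(map[, c("chrom", "marker")], path, col_names = FALSE)
  invisible(path)
}

# Strict line reader: splits on tabs, drops trailing blank lines only.
read_tsv_rows <- function(path) {
  if (!file.exists(path)) abort(sprintf("file '%s' does not exist", path))
  lines <- readLines(path, warn = FALSE)
  while (length(lines) && !nzchar(lines[length(lines)])) lines <- lines[-length(lines)]
  strsplit(lines, "\t", fixed = TRUE)
}
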