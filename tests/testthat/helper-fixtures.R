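# Fixture builders and independent oracles shared across the test files.

# Genotype tibble from per-individual call strings, e.g.
# geno_tbl(i1 = "AHB-", i2 = "BBHA").
geno_tbl <- function(..., markers = NULL) {
  rows <- list(...)
  calls <- do.call(rbind, lapply(rows, function(s) strsplit(s, "")[[1]]))
  markers <- markers %||% paste0("m", seq_len(ncol(calls)))
  colnames(calls) <- markers
  dplyr::bind_cols(
    tibble::tibble(individual = names(rows)),
    tibble::as_tibble(as.data.frame(calls, stringsAsFactors = FALSE, check.names = FALSE))
  )
}

# Single-chromosome marker map matching a genotype tibble.
map_for <- function(geno, chrom = "chr1") {
  tibble::tibble(chrom = chrom, marker = colnames(geno)[-1])
}

write_tmp_lines <- function(lines) {
  f <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent recombination oracle: per chromosome, minimal number of
# haplotype-origin switches over exhaustive enumeration of all H-locus
# orientations (a|b vs b|a).  Missing calls are dropped before counting.
oracle_recombinations <- function(calls, chrom) {
  total <- 0L
  for (ch in unique(chrom)) {
    s <- calls[chrom == ch]
    s <- s[s != "-"]
    if (length(s) < 2L) next
    hpos <- which(s == "H")
    h1 <- ifelse(s == "B", 1L, 0L)
    h2 <- h1
    best <- Inf
    for (mask in 0:(2^length(hpos) - 1L)) {
      if (length(hpos)) {
        ori <- bitwAnd(mask, bitwShiftL(1L, seq_along(hpos) - 1L)) > 0L
        h1[hpos] <- as.integer(ori)
        h2[hpos] <- as.integer(!ori)
      }
      best <- min(best, sum(abs(diff(h1))) + sum(abs(diff(h2))))
    }
    total <- total + best
  }
  total
}

# Brute-force pair score: per-locus classification through classify_locus()
# plus a plain named lookup, independent of the matrix-product engine.
oracle_pair_score <- function(g1, g2, table) {
  s <- stats::setNames(table$score, table$combo)
  sum(s[classify_locus(g1, g2)])
}
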