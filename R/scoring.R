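#' Score a pair of genotypes for complementarity
#'
#' Sums per-locus combination scores over the marker panel: the final score
#' of a pair is `sum(table[classify_locus(g1, g2)])`.  Alongside the score,
#' counts the invariable loci (class `A/A` or `B/B`: the pair is fixed
#' homozygous there, so all their progeny will be too) and the loci where at
#' least one member is heterozygous (these bound the similarity range from
#' below).
#'
#' @param geno1,geno2 Character vectors of genotype calls of equal length.
#' @param table A score table from [score_table()] (default `SET3`).
#' @return A one-row tibble: `final_score`, `n_invariable`, `n_het_union`,
#'   `n_markers`.
#' @examples
#' pair_score(c("A", "H", "A"), c("B", "H", "H"))
#' @export
pair_score <- function(geno1, geno2, table = score_table("SET3")) {
  if (length(geno1) != length(geno2)) {
    abort(sprintf(
      "genotype length mismatch: %d vs %d markers", length(geno1), length(geno2)
    ))
  }
  if (length(geno1) == 0L) abort("genotypes must cover at least one marker")
  table <- score_table(table)
  c1 <- encode_calls(geno1, "call in geno1")
  c2 <- encode_calls(geno2, "call in geno2")
  lut <- score_lookup(table)
  tibble(
    final_score = sum(lut[cbind(c1, c2)]),
    n_invariable = sum((c1 == 1L & c2 == 1L) | (c1 == 2L & c2 == 2L)),
    n_het_union = sum(c1 == 3L | c2 == 3L),
    n_markers = length(c1)
  )
}

#' Ideal score of a marker panel
#'
#' The final score a fully complementary pair would attain: every locus in
#' the A/B class, i.e. `n_markers * table["A/B"]`.  Final scores are compared
#' against a user-chosen fraction of this value during filtering.
#'
#' @param n_markers Number of markers in the panel (>= 1).
#' @inheritParams pair_score
#' @return A single number.
#' @examples
#' ideal_score(62)
#' @export
ideal_score <- function(n_markers, table = score_table("SET3")) {
  if (!is.numeric(n_markers) || length(n_markers) != 1L || n_markers < 1) {
    abort("n_markers must be a single count >= 1")
  }
  table <- score_table(table)
  n_markers * table$score[table$combo == "A/B"]
}

#' Similarity range of a candidate pair to the original hybrid
#'
#' Bounds, as percentages of the marker panel, how closely the resynthesized
#' genotype from a selected pair can match the original hybrid.  The upper
#' end removes only the invariable markers:
#' `(n_markers - n_invariable) * 100 / n_markers`; the lower end additionally
#' removes every locus where at least one member of the pair is heterozygous:
#' `(n_markers - n_invariable - n_het_union) * 100 / n_markers`.
#'
#' @param n_markers Total marker count.
#' @param n_invariable Count of invariable (A/A or B/B) loci in the pair.
#' @param n_het_union Count of loci where at least one member is H.
#' @return A one-row tibble with `lower_pct` and `upper_pct`.
#' @examples
#' similarity_range(50, 4, 10) # upper 92, lower 72
#' @export
similarity_range <- function(n_markers, n_invariable, n_het_union) {
  if (any(n_invariable + n_het_union > n_markers)) {
    abort("n_invariable + n_het_union exceeds n_markers")
  }
  if (any(n_invariable < 0 | n_het_union < 0 | n_markers < 1)) {
    abort("counts must be non-negative and n_markers >= 1")
  }
  tibble(
    lower_pct = (n_markers - n_invariable - n_het_union) * 100 / n_markers,
    upper_pct = (n_markers - n_invariable) * 100 / n_markers
  )
}
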