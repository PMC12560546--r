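# Recombination-event counting on phased, map-ordered genotypes.
#
# A genotype sequence along a chromosome constrains the two parental
# haplotypes: A fixes both to one parent, B to the other, H leaves the
# orientation of the heterozygote free.  The count returned is the minimum
# total number of haplotype-origin switches over all H orientations, which
# reduces to a per-transition cost between consecutive non-missing calls:
# same class 0; A<->H or B<->H 1; A<->B 2 (both haplotypes switch).  Costs
# within runs of H are 0 (phase assumed preserved) and no transition is
# counted across a chromosome boundary.  The correctness of the reduction is
# checked against an exhaustive enumeration oracle in the test suite.

TRANSITION_COST <- matrix(
  c(
    0, 2, 1,
    2, 0, 1,
    1, 1, 0
  ),
  nrow = 3L, byrow = TRUE, dimnames = list(c("A", "B", "H"), c("A", "B", "H"))
)

#' Count recombination events in one phased genotype
#'
#' Estimates the number of crossover events carried by an individual from
#' its phased, map-ordered ABH genotype: within each chromosome, consecutive
#' non-missing calls are scanned and each transition contributes its minimal
#' haplotype-switch cost (`A`/`B` to `H` or back: 1; `A` to `B`: 2 -- both
#' haplotypes change origin).  Missing calls are skipped, so inserting `-`
#' anywhere never changes the count, and chromosome boundaries contribute
#' nothing.  Only meaningful when the genotype data are phased; the caller
#' is responsible for asserting phase.
#'
#' @param geno Character vector of calls aligned to `map`.
#' @param map Marker-map tibble (`chrom`, `marker`) of the same length.
#' @return A non-negative integer count.
#' @examples
#' map <- tibble::tibble(chrom = "chr1", marker = paste0("m", 1:4))
#' count_recombinations(c("A", "A", "B", "B"), map)
#' @export
count_recombinations <- function(geno, map) {
  if (length(geno) != nrow(map)) {
    abort(sprintf(
      "genotype has %d calls but the marker map lists %d markers",
      length(geno), nrow(map)
    ))
  }
  codes <- encode_calls(geno, "call")
  count_recombinations_codes(codes, map$chrom)
}

# Core on integer codes; `chrom` gives the chromosome label per marker.
count_recombinations_codes <- function(codes, chrom) {
  keep <- codes != 4L
  codes <- codes[keep]
  chrom <- chrom[keep]
  if (length(codes) < 2L) return(0L)
  from <- codes[-length(codes)]
  to <- codes[-1L]
  same_chrom <- chrom[-length(chrom)] == chrom[-1L]
  sum(TRANSITION_COST[cbind(from, to)] * same_chrom)
}

#' Recombination counts for a pair of phased genotypes
#'
#' Counts recombination events in each member of a candidate pair and their
#' sum.  Among pairs with equal final scores, those with the fewest total
#' recombination events are usually the most desirable parents: every
#' breakpoint implies a homozygous DNA segment in the resynthesized hybrids,
#' since it is highly unlikely that both members recombined at the same
#' position.
#'
#' @param geno1,geno2 Character call vectors aligned to `map`.
#' @inheritParams count_recombinations
#' @return A one-row tibble: `rec1`, `rec2`, `rec_total`.
#' @examples
#' map <- tibble::tibble(chrom = "chr1", marker = paste0("m", 1:4))
#' pair_recombination(c("A", "A", "B", "B"), c("B", "B", "B", "B"), map)
#' @export
pair_recombination <- function(geno1, geno2, map) {
  r1 <- count_recombinations(geno1, map)
  r2 <- count_recombinations(geno2, map)
  tibble(rec1 = r1, rec2 = r2, rec_total = r1 + r2)
}
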