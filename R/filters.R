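# Individual- and pair-level filters.  Boundary semantics are inclusive on
# the accepting side throughout: an individual exactly at max_het is kept, a
# pair exactly at min_score_fraction * ideal or at max_invariable_fraction is
# accepted.  Score comparisons carry a 1e-9 absolute guard so that an exact
# boundary (e.g. 0.8 * 62 = 49.6) is not lost to floating-point rounding.

SCORE_EPS <- 1e-9

REASON_HET <- "HET_RATE"
REASON_SCORE <- "LOW_SCORE"
REASON_INVARIABLE <- "INVARIABLE_EXCESS"

#' Heterozygosity rate of genotype sequences
#'
#' The fraction of heterozygous (`H`) calls.  With
#' `denominator = "nonmissing"` (the default) the H count is divided by the
#' number of non-missing calls, which is robust to per-individual differences
#' in missing-data rate; with `"all"` it is divided by the full marker count.
#' An individual whose calls are all missing has no defined rate and raises
#' an error.
#'
#' @param geno A character vector of calls, or a genotype tibble (first
#'   column individual ids), in which case a tibble of per-individual rates
#'   is returned.
#' @param denominator `"nonmissing"` or `"all"`.
#' @return A single proportion for a call vector; a tibble `individual`,
#'   `het_rate` for a genotype tibble.
#' @examples
#' het_rate(c("A", "H", "B", "H"))
#' het_rate(c("H", "-", "A", "-")) # 1 H over 2 non-missing calls
#' @export
het_rate <- function(geno, denominator = c("nonmissing", "all")) {
  denominator <- match.arg(denominator)
  if (is.data.frame(geno)) {
    codes <- geno_codes(geno)
    return(tibble(
      individual = rownames(codes),
      het_rate = het_rate_codes(codes, denominator)
    ))
  }
  codes <- encode_calls(geno, "call")
  het_rate_codes(matrix(codes, nrow = 1L), denominator)[1L]
}

# Row-wise het rates on an integer-coded matrix; errors if any row is all
# missing (rate undefined).
het_rate_codes <- function(codes, denominator = "nonmissing") {
  if (ncol(codes) == 0L) abort("genotype sequence is empty")
  n_het <- rowSums(codes == 3L)
  n_obs <- rowSums(codes != 4L)
  if (any(n_obs == 0L)) {
    who <- rownames(codes)[which(n_obs == 0L)[1L]] %||% "<unnamed>"
    abort(sprintf(
      "heterozygosity rate undefined for individual '%s': all calls missing", who
    ))
  }
  denom <- if (denominator == "all") ncol(codes) else n_obs
  unname(n_het / denom)
}

#' Filter individuals by heterozygosity rate
#'
#' First stage of the selection pipeline: only individuals whose
#' heterozygosity rate does not exceed `max_het` are retained (the boundary
#' value itself is kept).  In an ideal F2 population a threshold of 0.5
#' discards roughly half of the individuals.
#'
#' @param geno Genotype tibble.
#' @param max_het Maximum tolerated heterozygosity rate, default 0.5.
#' @inheritParams het_rate
#' @return A list with `kept` (character vector of retained individual ids,
#'   input order), `rejected` (tibble `subject`, `reason`, `observed`,
#'   `threshold`), and `het` (tibble of all per-individual rates).
#' @examples
#' g <- tibble::tibble(
#'   individual = c("i1", "i2", "i3"),
#'   m1 = c("A", "H", "H"), m2 = c("H", "H", "H"), m3 = c("B", "A", "H")
#' )
#' filter_individuals(g, max_het = 0.5)$kept
#' @export
filter_individuals <- function(geno, max_het = 0.5,
                               denominator = c("nonmissing", "all")) {
  denominator <- match.arg(denominator)
  if (!is.numeric(max_het) || max_het < 0 || max_het > 1) {
    abort("max_het must be a proportion in [0, 1]")
  }
  rates <- het_rate(geno, denominator)
  keep <- rates$het_rate <= max_het
  list(
    kept = rates$individual[keep],
    rejected = tibble(
      subject = rates$individual[!keep],
      reason = rep(REASON_HET, sum(!keep)),
      observed = rates$het_rate[!keep],
      threshold = rep(max_het, sum(!keep))
    ),
    het = rates
  )
}

#' Evaluate a scored pair against the pair-level filters
#'
#' Applies the two pair filters in pipeline order: a pair whose final score
#' falls below `min_score_fraction * ideal` is rejected as `LOW_SCORE`
#' (checked first -- in the full engine this early discard avoids any
#' further work on the pair); otherwise a pair whose invariable-locus
#' fraction `n_invariable / n_markers` exceeds `max_invariable_fraction` is
#' rejected as `INVARIABLE_EXCESS`; otherwise it is accepted.
#'
#' @param ps One-row tibble from [pair_score()].
#' @param ideal Ideal score of the panel, from [ideal_score()].
#' @param min_score_fraction Minimum accepted fraction of the ideal score,
#'   default 0.8.
#' @param max_invariable_fraction Maximum accepted invariable fraction,
#'   default 0.1; typical values range from 0 (discard any pair with a
#'   homozygous-identical marker) to 0.1.
#' @return `NULL` if the pair is accepted, otherwise a one-row rejection
#'   tibble (`reason`, `observed`, `threshold`).
#' @examples
#' ps <- pair_score(c("A", "H", "B"), c("B", "A", "A"))
#' evaluate_pair(ps, ideal = 3)
#' @export
evaluate_pair <- function(ps, ideal, min_score_fraction = 0.8,
                          max_invariable_fraction = 0.1) {
  stopifnot(is.data.frame(ps), nrow(ps) == 1L)
  if (ps$final_score < min_score_fraction * ideal - SCORE_EPS) {
    return(tibble(
      reason = REASON_SCORE,
      observed = ps$final_score,
      threshold = min_score_fraction * ideal
    ))
  }
  inv_frac <- ps$n_invariable / ps$n_markers
  if (inv_frac > max_invariable_fraction + SCORE_EPS) {
    return(tibble(
      reason = REASON_INVARIABLE,
      observed = inv_frac,
      threshold = max_invariable_fraction
    ))
  }
  NULL
}
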