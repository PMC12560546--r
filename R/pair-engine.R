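#' Number of unidirectional pairwise comparisons
#'
#' For `k` retained individuals the engine evaluates `k * (k - 1) / 2`
#' unordered pairs.
#'
#' @param k Number of individuals (>= 0).
#' @return A count.
#' @examples
#' n_comparisons(418)
#' @export
n_comparisons <- function(k) {
  stopifnot(is.numeric(k), all(k >= 0))
  k * (k - 1) / 2
}

#' Select complementary pairs from a genotyped selfing population
#'
#' Runs the full selection pipeline: (1) individuals with a heterozygosity
#' rate above `max_het` are discarded; (2) every unordered pair of the
#' retained individuals is scored by summing per-locus combination scores
#' (see [pair_score()] and [score_table()]); (3) pairs scoring below
#' `min_score_fraction` of the ideal score are discarded early, and of the
#' rest those whose invariable-locus fraction exceeds
#' `max_invariable_fraction` are discarded; (4) accepted pairs are annotated
#' with per-member heterozygosity, the similarity range to the original
#' hybrid and -- when `phased = TRUE` -- recombination-event counts, then
#' sorted by descending final score with deterministic tie-breaking
#' (ascending total recombination count when phased, then ascending pair
#' ids).  The pair stream is split into contiguous chunks that are evaluated
#' independently; because the final sort is global, the result is identical
#' for any number of workers or chunking of the stream.
#'
#' @param geno Genotype tibble (first column `individual`).
#' @param map Marker-map tibble (`chrom`, `marker`) matching `geno`.
#' @param table Score table: a name (`"SET1"`, `"SET2"`, `"SET3"`) or a
#'   tibble from [score_table()] / [read_score_table()].
#' @param max_het Individual heterozygosity ceiling (inclusive), default 0.5.
#' @param min_score_fraction Minimum accepted fraction of the ideal score
#'   (inclusive), default 0.8.
#' @param max_invariable_fraction Maximum accepted invariable-locus fraction
#'   (inclusive), default 0.1.
#' @param phased Set `TRUE` only if the genotype calls are phased along each
#'   chromosome; adds recombination counts (`rec1`, `rec2`, `rec_total`) to
#'   the result.  ABH coding cannot self-certify phase, so this is a user
#'   assertion, never inferred.
#' @param workers Number of parallel workers (>= 1).  Results are identical
#'   for any value.
#' @param het_denominator Heterozygosity-rate convention, see [het_rate()].
#' @param low_score_cap When the total pair count exceeds this cap,
#'   individual `LOW_SCORE` rejections are aggregated into a count instead
#'   of enumerated, keeping the discard records bounded.  Default `1e6`.
#' @return An object of class `resyn_selection`: a list with `accepted`
#'   (tibble of accepted pairs, sorted), `rejected` (tibble of discard
#'   records), `stats` (named counts per pipeline stage) and `config` (the
#'   applied arguments, defaults included).  `tidy()` returns the accepted
#'   tibble, `glance()` the stats as a one-row tibble, and `autoplot()`
#'   draws the genotype profiles of the top pairs.
#' @examples
#' sim <- simulate_f2(60, sim_chromosomes(3, 100, 12), seed = 7)
#' sel <- run_selection(sim$genotypes, sim$map,
#'   min_score_fraction = 0.6, phased = TRUE
#' )
#' head(tidy(sel))
#' glance(sel)
#' @export
run_selection <- function(geno, map, table = "SET3",
                          max_het = 0.5,
                          min_score_fraction = 0.8,
                          max_invariable_fraction = 0.1,
                          phased = FALSE,
                          workers = 1L,
                          het_denominator = c("nonmissing", "all"),
                          low_score_cap = 1e6) {
  het_denominator <- match.arg(het_denominator)
  if (!is.numeric(workers) || length(workers) != 1L || workers < 1) {
    abort("workers must be a count >= 1")
  }
  workers <- as.integer(workers)
  table <- score_table(table)
  check_geno_map(geno, map)

  flt <- filter_individuals(geno, max_het, het_denominator)
  codes_all <- geno_codes(geno)
  keep_idx <- match(flt$kept, rownames(codes_all))
  codes <- codes_all[keep_idx, , drop = FALSE]
  k <- nrow(codes)
  m <- ncol(codes)
  ideal <- ideal_score(m, table)
  total_pairs <- n_comparisons(k)
  enumerate_low <- total_pairs <= low_score_cap

  chunks <- pair_chunks(k, workers)
  eval_chunk <- make_chunk_evaluator(
    codes, table, ideal, min_score_fraction, max_invariable_fraction,
    enumerate_low
  )
  results <-
    if (workers > 1L && .Platform$OS.type == "unix" &&
        requireNamespace("parallel", quietly = TRUE)) {
      parallel::mclapply(chunks, eval_chunk, mc.cores = workers)
    } else {
      lapply(chunks, eval_chunk)
    }

  acc <- bind_rows(purrr::map(results, "accepted"))
  low <- bind_rows(purrr::map(results, "low"))
  inv <- bind_rows(purrr::map(results, "invariable"))
  n_low <- sum(purrr::map_dbl(results, "n_low"))

  ids <- rownames(codes)
  het_lookup <- setNames(flt$het$het_rate, flt$het$individual)
  rec_lookup <- if (phased) {
    vapply(seq_len(nrow(codes_all)), function(i) {
      count_recombinations_codes(codes_all[i, ], map$chrom)
    }, numeric(1L)) |> setNames(rownames(codes_all))
  }

  accepted <- annotate_pairs(
    acc, ids, m, het_lookup, rec_lookup, phased
  )

  pair_subject <- function(d) {
    if (nrow(d) == 0L) return(character(0L))
    a <- ids[d$i]; b <- ids[d$j]
    swap <- b < a
    paste(ifelse(swap, b, a), ifelse(swap, a, b), sep = "|")
  }
  rejected <- bind_rows(
    flt$rejected,
    if (enumerate_low && nrow(low)) tibble(
      subject = pair_subject(low), reason = REASON_SCORE,
      observed = low$final_score, threshold = min_score_fraction * ideal
    ),
    if (nrow(inv)) tibble(
      subject = pair_subject(inv), reason = REASON_INVARIABLE,
      observed = inv$inv_frac, threshold = max_invariable_fraction
    )
  )
  if (is.null(rejected)) {
    rejected <- tibble(
      subject = character(), reason = character(),
      observed = numeric(), threshold = numeric()
    )
  }

  structure(
    list(
      accepted = accepted,
      rejected = rejected,
      stats = list(
        n_individuals = nrow(codes_all),
        n_markers = m,
        n_rejected_het = nrow(flt$rejected),
        n_retained = k,
        pairs_evaluated = total_pairs,
        n_rejected_low_score = n_low,
        n_rejected_invariable = nrow(inv),
        n_accepted = nrow(accepted),
        low_score_enumerated = enumerate_low
      ),
      config = list(
        score_set = attr(table, "score_set") %||% "custom",
        score_table = table,
        max_het = max_het,
        min_score_fraction = min_score_fraction,
        max_invariable_fraction = max_invariable_fraction,
        ideal_score = ideal,
        phased = phased,
        workers = workers,
        het_denominator = het_denominator,
        low_score_cap = low_score_cap
      )
    ),
    class = "resyn_selection"
  )
}

# Split the i-index space of the pair stream (i < j over k individuals) into
# contiguous chunks of roughly ceil(total / (8 * workers)) pairs each.
pair_chunks <- function(k, workers) {
  if (k < 2L) return(list())
  i_all <- seq_len(k - 1L)
  total <- n_comparisons(k)
  target <- ceiling(total / (8L * workers))
  cum <- cumsum(k - i_all)
  grp <- ceiling(cum / target)
  unname(split(i_all, grp))
}

# Build the closure evaluating one chunk of i-rows against all j > i.  Per
# combination class c, the k x m indicator A_c and the score-weighted matrix
# W_c (W_c[i, l] = score of the class of (call_il, c)) reduce the pairwise
# score to four matrix products: score(i, j) = sum_c W_c[i, ] . A_c[j, ].
make_chunk_evaluator <- function(codes, table, ideal, min_score_fraction,
                                 max_invariable_fraction, enumerate_low) {
  k <- nrow(codes)
  m <- ncol(codes)
  lut <- score_lookup(table)
  ind <- lapply(1:4, function(c) matrix(as.numeric(codes == c), nrow = k))
  t_ind <- lapply(ind, t)
  w <- lapply(1:4, function(c) matrix(lut[cbind(as.vector(codes), c)], nrow = k))
  n_het <- unname(rowSums(codes == 3L))
  thr <- min_score_fraction * ideal

  function(rows) {
    nb <- length(rows)
    score_b <- matrix(0, nb, k)
    for (c in 1:4) score_b <- score_b + w[[c]][rows, , drop = FALSE] %*% t_ind[[c]]
    inv_b <- ind[[1L]][rows, , drop = FALSE] %*% t_ind[[1L]] +
      ind[[2L]][rows, , drop = FALSE] %*% t_ind[[2L]]
    hh_b <- ind[[3L]][rows, , drop = FALSE] %*% t_ind[[3L]]

    j <- sequence(k - rows, from = rows + 1L)
    r_local <- rep.int(seq_len(nb), k - rows)
    i <- rows[r_local]
    sel <- cbind(r_local, j)
    fs <- score_b[sel]
    ninv <- inv_b[sel]
    nhu <- n_het[i] + n_het[j] - hh_b[sel]

    low <- fs < thr - SCORE_EPS
    inv_frac <- ninv / m
    invex <- !low & inv_frac > max_invariable_fraction + SCORE_EPS
    ok <- !low & !invex
    list(
      accepted = tibble(
        i = i[ok], j = j[ok], final_score = fs[ok],
        n_invariable = ninv[ok], n_het_union = nhu[ok]
      ),
      low = if (enumerate_low) {
        tibble(i = i[low], j = j[low], final_score = fs[low])
      } else {
        tibble(i = integer(), j = integer(), final_score = numeric())
      },
      n_low = sum(low),
      invariable = tibble(i = i[invex], j = j[invex], inv_frac = inv_frac[invex])
    )
  }
}

# Attach ids, het rates, similarity range and recombination counts to the
# raw accepted-pair index tibble, canonicalise id order and sort.
annotate_pairs <- function(acc, ids, n_markers, het_lookup, rec_lookup, phased) {
  if (nrow(acc) == 0L) {
    out <- tibble(
      id1 = character(), id2 = character(), final_score = numeric(),
      n_invariable = numeric(), het1 = numeric(), het2 = numeric(),
      similarity_lower_pct = numeric(), similarity_upper_pct = numeric()
    )
    if (phased) {
      out$rec1 <- numeric(); out$rec2 <- numeric(); out$rec_total <- numeric()
    }
    return(out)
  }
  a <- ids[acc$i]
  b <- ids[acc$j]
  swap <- b < a
  id1 <- ifelse(swap, b, a)
  id2 <- ifelse(swap, a, b)
  sim <- similarity_range(n_markers, acc$n_invariable, acc$n_het_union)
  out <- tibble(
    id1 = id1, id2 = id2,
    final_score = acc$final_score,
    n_invariable = acc$n_invariable,
    het1 = unname(het_lookup[id1]),
    het2 = unname(het_lookup[id2]),
    similarity_lower_pct = sim$lower_pct,
    similarity_upper_pct = sim$upper_pct
  )
  if (phased) {
    out$rec1 <- unname(rec_lookup[id1])
    out$rec2 <- unname(rec_lookup[id2])
    out$rec_total <- out$rec1 + out$rec2
  }
  key_rec <- if (phased) out$rec_total else rep(0, nrow(out))
  ord <- order(-out$final_score, key_rec, out$id1, out$id2, method = "radix")
  out[ord, ]
}

#' @export
print.resyn_selection <- function(x, ...) {
  s <- x$stats
  cat("Complementary-pair selection\n")
  cat(sprintf(
    "  %d individuals x %d markers; %d retained after het filter (max_het = %g, %s denominator)\n",
    s$n_individuals, s$n_markers, s$n_retained,
    x$config$max_het, x$config$het_denominator
  ))
  cat(sprintf(
    "  %s pairs evaluated (score set %s, ideal score %g): %s below %g%% of ideal, %d over invariable cap, %d accepted\n",
    format(s$pairs_evaluated, big.mark = ","), x$config$score_set,
    x$config$ideal_score, format(s$n_rejected_low_score, big.mark = ","),
    100 * x$config$min_score_fraction, s$n_rejected_invariable, s$n_accepted
  ))
  if (s$n_accepted > 0L) {
    cat("  top pairs:\n")
    print(head(x$accepted, 5L))
  }
  invisible(x)
}

#' Tidy the accepted pairs of a selection
#'
#' @param x A `resyn_selection` object.
#' @param ... Unused.
#' @return `tidy()` returns the accepted-pairs tibble (sorted); `glance()`
#'   a one-row tibble of pipeline stage counts.
#' @method tidy resyn_selection
#' @export
tidy.resyn_selection <- function(x, ...) x$accepted

#' @rdname tidy.resyn_selection
#' @method glance resyn_selection
#' @export
glance.resyn_selection <- function(x, ...) {
  as_tibble(x$stats[c(
    "n_individuals", "n_markers", "n_rejected_het", "n_retained",
    "pairs_evaluated", "n_rejected_low_score", "n_rejected_invariable",
    "n_accepted"
  )])
}
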