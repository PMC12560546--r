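# Seeded F2 meiosis simulator.
#
# Gametes from a fully heterozygous F1 are simulated under the Haldane model:
# the crossover count on a chromosome of length L cM is Poisson with mean
# L/100 (no interference, no obligate chiasma), crossover positions are
# uniform, the starting parental origin is a or b with probability 1/2, and
# the origin flips at every crossover.  An F2 individual is the union of two
# independent gametes; the two gametes are returned as exact phased
# haplotypes, so simulated recombination counts can be validated against the
# crossovers actually drawn.

#' Describe the chromosomes of a simulated genome
#'
#' Convenience constructor for the chromosome table consumed by
#' [simulate_f2()]: `n` chromosomes of equal length carrying equidistant
#' markers.  Markers are placed at positions `(i + 0.5) / m * L` for
#' `i = 0 .. m-1`, so none sits exactly on a chromosome end.
#'
#' @param n Number of chromosomes.
#' @param length_cm Chromosome length in centiMorgans.
#' @param n_markers Markers per chromosome.
#' @param prefix Chromosome-name prefix.
#' @return A tibble with columns `name`, `length_cm`, `n_markers`.
#' @examples
#' sim_chromosomes(10, length_cm = 100, n_markers = 50)
#' @export
sim_chromosomes <- function(n, length_cm = 100, n_markers = 50, prefix = "chr") {
  stopifnot(n >= 1, length_cm > 0, n_markers >= 1)
  tibble(
    name = sprintf("%s%02d", prefix, seq_len(n)),
    length_cm = length_cm,
    n_markers = n_markers
  )
}

# Marker positions in cM for one chromosome: equidistant, offset from ends.
marker_positions <- function(length_cm, n_markers) {
  (seq_len(n_markers) - 0.5) / n_markers * length_cm
}

#' Simulate one gamete along a chromosome
#'
#' Draws a single meiotic product under the Haldane model and reads off the
#' parental origin (`"a"` or `"b"`) at each marker position.  The number of
#' crossovers drawn is attached as attribute `n_crossovers`.
#'
#' @param length_cm Chromosome length in cM (> 0).
#' @param positions_cm Ordered marker positions within `[0, length_cm]`.
#' @return Character vector over `{"a", "b"}`, one element per marker, with
#'   attribute `n_crossovers`.
#' @examples
#' set.seed(1)
#' simulate_gamete(100, c(25, 50, 75))
#' @export
simulate_gamete <- function(length_cm, positions_cm) {
  stopifnot(length_cm > 0, all(positions_cm >= 0 & positions_cm <= length_cm))
  n_x <- rpois(1L, length_cm / 100)
  xpos <- sort(runif(n_x, 0, length_cm))
  start <- sample(0:1, 1L)
  parity <- (start + findInterval(positions_cm, xpos)) %% 2L
  structure(c("a", "b")[parity + 1L], n_crossovers = n_x)
}

# Vectorised version: G gametes at once for one chromosome.  Returns a
# G x n_markers integer matrix of origins (0 = a, 1 = b) with the per-gamete
# crossover counts as attribute.  Same model as simulate_gamete().
simulate_gametes <- function(length_cm, positions_cm, n_gametes) {
  m <- length(positions_cm)
  n_x <- rpois(n_gametes, length_cm / 100)
  start <- sample(0:1, n_gametes, replace = TRUE)
  counts_below <- matrix(0L, n_gametes, m)
  total <- sum(n_x)
  if (total > 0L) {
    pos <- runif(total, 0, length_cm)
    gid <- rep.int(seq_len(n_gametes), n_x)
    below <- rowsum(1L * outer(pos, positions_cm, `<`), gid)
    counts_below[as.integer(rownames(below)), ] <- below
  }
  structure((start + counts_below) %% 2L, n_crossovers = n_x)
}

#' Simulate an F2 population from a fully heterozygous F1
#'
#' Generates ABH genotypes for `n_individuals` F2 plants: each individual is
#' the union of two independent gametes drawn by the Haldane meiosis model
#' (see [simulate_gamete()]).  Per marker, genotypes segregate 1:2:1
#' (A : H : B) and linkage decays with map distance according to the Haldane
#' map function r = (1 - exp(-2d))/2.  Missing calls can be injected at a
#' configurable rate.  The output is deterministic for a fixed `seed` and is
#' written/read losslessly by [write_genotypes()] / [read_genotypes()].
#'
#' @param n_individuals Population size.
#' @param chromosomes Chromosome table from [sim_chromosomes()] (columns
#'   `name`, `length_cm`, `n_markers`).
#' @param missing_rate Probability that any one call is replaced by `-`.
#' @param seed Optional integer seed; when supplied the global RNG state is
#'   left untouched.
#' @return A list: `genotypes` (tibble, first column `individual`),
#'   `map` (tibble `chrom`, `marker`), `positions` (tibble `chrom`,
#'   `marker`, `pos_cm`), and `haplotypes` (list of two character matrices
#'   over `{"a","b"}`, the exact phased gametes of every individual).
#' @examples
#' sim <- simulate_f2(20, sim_chromosomes(2, 100, 10), seed = 42)
#' sim$genotypes[1:3, 1:5]
#' @export
simulate_f2 <- function(n_individuals, chromosomes, missing_rate = 0, seed = NULL) {
  stopifnot(
    n_individuals >= 1,
    all(c("name", "length_cm", "n_markers") %in% names(chromosomes)),
    missing_rate >= 0, missing_rate <= 1
  )
  with_seed(seed, {
    per_chrom <- purrr::pmap(chromosomes, function(name, length_cm, n_markers, ...) {
      pos <- marker_positions(length_cm, n_markers)
      list(
        name = name,
        pos = pos,
        hap1 = simulate_gametes(length_cm, pos, n_individuals),
        hap2 = simulate_gametes(length_cm, pos, n_individuals)
      )
    })
    hap1 <- do.call(cbind, purrr::map(per_chrom, "hap1"))
    hap2 <- do.call(cbind, purrr::map(per_chrom, "hap2"))
    map <- tibble(
      chrom = rep.int(chromosomes$name, chromosomes$n_markers),
      marker = unlist(purrr::map(per_chrom, function(pc) {
        sprintf("%s_m%03d", pc$name, seq_along(pc$pos))
      }))
    )
    positions <- mutate(map, pos_cm = unlist(purrr::map(per_chrom, "pos")))
    ids <- sprintf("F2_%05d", seq_len(n_individuals))

    # 0+0 -> A, 0+1 -> H, 1+1 -> B
    calls <- matrix(
      c("A", "H", "B")[hap1 + hap2 + 1L],
      nrow = n_individuals,
      dimnames = list(ids, map$marker)
    )
    if (missing_rate > 0) {
      calls[runif(length(calls)) < missing_rate] <- CALL_MISSING
    }
    geno <- dplyr::bind_cols(
      tibble(individual = ids),
      as_tibble(as.data.frame(calls, stringsAsFactors = FALSE, check.names = FALSE))
    )
    dimnames(hap1) <- dimnames(hap2) <- list(ids, map$marker)
    list(
      genotypes = geno,
      map = map,
      positions = positions,
      haplotypes = list(
        hap1 = matrix(c("a", "b")[hap1 + 1L], nrow = n_individuals, dimnames = dimnames(hap1)),
        hap2 = matrix(c("a", "b")[hap2 + 1L], nrow = n_individuals, dimnames = dimnames(hap2))
      )
    )
  })
}

#' Inject missing calls into a genotype table
#'
#' Replaces each genotype call independently by `-` with probability `rate`,
#' mimicking genotyping dropout.
#'
#' @param geno Genotype tibble.
#' @param rate Per-cell missingness probability in `[0, 1]`.
#' @param seed Optional integer seed.
#' @return The genotype tibble with calls masked.
#' @examples
#' sim <- simulate_f2(10, sim_chromosomes(1, 50, 10), seed = 1)
#' masked <- inject_missing(sim$genotypes, 0.05, seed = 2)
#' @export
inject_missing <- function(geno, rate, seed = NULL) {
  stopifnot(rate >= 0, rate <= 1)
  if (rate == 0) return(geno)
  with_seed(seed, {
    m <- geno_matrix(geno)
    m[runif(length(m)) < rate] <- CALL_MISSING
    dplyr::bind_cols(
      tibble(individual = as.character(geno[[1L]])),
      as_tibble(as.data.frame(m, stringsAsFactors = FALSE, check.names = FALSE))
    )
  })
}

# Evaluate `expr` under a private RNG stream when `seed` is non-NULL,
# restoring (or removing) the caller's .Random.seed afterwards.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
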