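# Per-locus combination classes and score tables.
#
# The 4x4 ordered call pairs collapse into ten unordered combination classes.
# A score table maps each class to a value in [0, 1]; the pair score of two
# individuals is the sum of per-locus scores over the marker panel.

# Canonical class labels, ordered by call precedence A < B < H < -.
COMBO_LEVELS <- c(
  "A/A", "B/B", "H/H", "-/-", "H/-", "A/-", "B/-", "A/H", "B/H", "A/B"
)

BUILTIN_SCORE_SETS <- list(
  SET1 = c(
    "A/A" = 0, "B/B" = 0, "H/H" = 0.5, "-/-" = 0, "H/-" = 0.5,
    "A/-" = 0, "B/-" = 0, "A/H" = 0.75, "B/H" = 0.75, "A/B" = 1.0
  ),
  SET2 = c(
    "A/A" = 0, "B/B" = 0, "H/H" = 0.25, "-/-" = 0, "H/-" = 0.25,
    "A/-" = 0.5, "B/-" = 0.5, "A/H" = 0.5, "B/H" = 0.5, "A/B" = 1.0
  ),
  SET3 = c(
    "A/A" = 0, "B/B" = 0, "H/H" = 0.5, "-/-" = 0.5, "H/-" = 0.625,
    "A/-" = 0.75, "B/-" = 0.75, "A/H" = 0.75, "B/H" = 0.75, "A/B" = 1.0
  )
)

#' Classify the genotype combination of a pair at one locus
#'
#' Maps an (unordered) pair of calls to one of the ten combination classes
#' `A/A`, `B/B`, `H/H`, `-/-`, `H/-`, `A/-`, `B/-`, `A/H`, `B/H`, `A/B`.
#' Classification is symmetric: `classify_locus(x, y)` equals
#' `classify_locus(y, x)`.  Vectorised over both arguments.
#'
#' @param call1,call2 Character vectors of genotype calls in `{A,B,H,-}`.
#' @return Character vector of canonical class labels.
#' @examples
#' classify_locus("A", "B")
#' classify_locus(c("H", "-"), c("-", "-"))
#' @export
classify_locus <- function(call1, call2) {
  c1 <- encode_calls(call1, "call")
  c2 <- encode_calls(call2, "call")
  lo <- pmin(c1, c2)
  hi <- pmax(c1, c2)
  paste(CALL_LEVELS[lo], CALL_LEVELS[hi], sep = "/")
}

#' Built-in and user-defined score tables
#'
#' `score_table()` returns one of the three built-in score sets as a tibble
#' with columns `combo` and `score`.  `SET1` is intolerant to missing data,
#' `SET2` favours homozygous A/B combinations (low tolerance to
#' heterozygotes), and `SET3` -- the package default -- is tolerant to both
#' missing calls and heterozygous genotypes.  `read_score_table()` loads a
#' user override from a two-column tab-separated file (`class<TAB>value`);
#' all ten classes must be present with values in \[0, 1\].
#'
#' @param name One of `"SET1"`, `"SET2"`, `"SET3"`, or an existing score
#'   table tibble (returned unchanged after validation).
#' @return A tibble with columns `combo` (the ten class labels) and `score`.
#' @examples
#' score_table("SET3")
#' @export
score_table <- function(name = "SET3") {
  if (is.data.frame(name)) {
    out <- validate_score_table(name, label = "custom")
    attr(out, "score_set") <- attr(name, "score_set", exact = TRUE) %||% "custom"
    return(out)
  }
  if (!is.character(name) || length(name) != 1L || !name %in% names(BUILTIN_SCORE_SETS)) {
    abort(sprintf(
      "unknown score table %s: valid names are %s",
      encodeString(as.character(name)[1L], quote = "'"),
      paste0("'", names(BUILTIN_SCORE_SETS), "'", collapse = ", ")
    ))
  }
  s <- BUILTIN_SCORE_SETS[[name]]
  out <- tibble(combo = names(s), score = unname(s))
  attr(out, "score_set") <- name
  out
}

#' @param path Path to a two-column tab-separated score file.
#' @rdname score_table
#' @export
read_score_table <- function(path) {
  rows <- read_tsv_rows(path)
  widths <- lengths(rows)
  if (any(widths != 2L)) {
    abort(sprintf("score-table file row %d has %d columns, expected 2 (class, value)", which(widths != 2L)[1L], widths[widths != 2L][1L]))
  }
  tab <- tibble(
    combo = vapply(rows, `[[`, character(1L), 1L),
    score = suppressWarnings(as.numeric(vapply(rows, `[[`, character(1L), 2L)))
  )
  if (anyNA(tab$score)) {
    abort(sprintf("non-numeric score for class '%s'", tab$combo[is.na(tab$score)][1L]))
  }
  validate_score_table(tab, label = path)
}

validate_score_table <- function(tab, label = "score table") {
  if (!all(c("combo", "score") %in% names(tab))) {
    abort(sprintf("%s must have columns 'combo' and 'score'", label))
  }
  missing_cls <- setdiff(COMBO_LEVELS, tab$combo)
  extra_cls <- setdiff(tab$combo, COMBO_LEVELS)
  if (length(extra_cls)) {
    abort(sprintf("%s has unknown combination class '%s'", label, extra_cls[1L]))
  }
  if (length(missing_cls)) {
    abort(sprintf(
      "%s is missing %d combination class(es): %s",
      label, length(missing_cls), paste(missing_cls, collapse = ", ")
    ))
  }
  if (anyDuplicated(tab$combo)) {
    abort(sprintf("%s lists class '%s' more than once", label, tab$combo[duplicated(tab$combo)][1L]))
  }
  if (any(tab$score < 0 | tab$score > 1)) {
    bad <- which(tab$score < 0 | tab$score > 1)[1L]
    abort(sprintf("score for class '%s' is %g, outside [0, 1]", tab$combo[bad], tab$score[bad]))
  }
  tibble(combo = tab$combo, score = tab$score)
}

# 4x4 lookup matrix of per-locus scores indexed by integer call codes.
score_lookup <- function(table) {
  s <- setNames(table$score, table$combo)
  m <- matrix(0, 4L, 4L, dimnames = list(CALL_LEVELS, CALL_LEVELS))
  for (i in 1:4) {
    for (j in 1:4) {
      lo <- min(i, j); hi <- max(i, j)
      m[i, j] <- s[[paste(CALL_LEVELS[lo], CALL_LEVELS[hi], sep = "/")]]
    }
  }
  m
}
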