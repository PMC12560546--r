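test_that("locus classification is symmetric and covers all sixteen ordered pairs", {
  calls <- genotype_calls()
  grid <- expand.grid(c1 = calls, c2 = calls, stringsAsFactors = FALSE)
  cls <- classify_locus(grid$c1, grid$c2)
  expect_equal(cls, classify_locus(grid$c2, grid$c1))
  expect_setequal(unique(cls), score_table("SET3")$combo)
  expect_equal(classify_locus("A", "B"), "A/B")
  expect_equal(classify_locus("H", "-"), "H/-")
  expect_equal(classify_locus("-", "-"), "-/-")
  expect_error(classify_locus("A", "N"), "invalid call")
})

test_that("built-in score tables carry the published score sets", {
  set1 <- score_table("SET1")
  set2 <- score_table("SET2")
  set3 <- score_table("SET3")
  lut <- function(t) stats::setNames(t$score, t$combo)
  expect_equal(lut(set1), c(
    "A/A" = 0, "B/B" = 0, "H/H" = 0.5, "-/-" = 0, "H/-" = 0.5,
    "A/-" = 0, "B/-" = 0, "A/H" = 0.75, "B/H" = 0.75, "A/B" = 1.0
  ))
  expect_equal(lut(set2), c(
    "A/A" = 0, "B/B" = 0, "H/H" = 0.25, "-/-" = 0, "H/-" = 0.25,
    "A/-" = 0.5, "B/-" = 0.5, "A/H" = 0.5, "B/H" = 0.5, "A/B" = 1.0
  ))
  expect_equal(lut(set3), c(
    "A/A" = 0, "B/B" = 0, "H/H" = 0.5, "-/-" = 0.5, "H/-" = 0.625,
    "A/-" = 0.75, "B/-" = 0.75, "A/H" = 0.75, "B/H" = 0.75, "A/B" = 1.0
  ))
  expect_error(score_table("SET4"), "unknown score table 'SET4'.*SET1")
})

test_that("custom score tables are read and validated", {
  tab <- score_table("SET2")
  f <- write_tmp_lines(sprintf("%s\t%g", tab$combo, tab$score))
  expect_equal(read_score_table(f), tab, ignore_attr = TRUE)

  expect_error(
    read_score_table(write_tmp_lines(c("A/B\t1.0"))),
    "missing 9 combination class"
  )
  expect_error(
    read_score_table(write_tmp_lines(sprintf("%s\t%g", tab$combo, c(1.5, tab$score[-1])))),
    "outside \\[0, 1\\]"
  )
  expect_error(
    read_score_table(write_tmp_lines(c(sprintf("%s\t%g", tab$combo, tab$score), "X/Y\t0.5"))),
    "unknown combination class 'X/Y'"
  )
})

test_that("pair scores sum per-locus table values and count invariable/het loci", {
  ps <- pair_score(c("A", "H", "A"), c("B", "H", "H"), score_table("SET3"))
  expect_equal(ps$final_score, 1.0 + 0.5 + 0.75)
  expect_equal(ps$n_invariable, 0L)
  expect_equal(ps$n_het_union, 2L)

  for (set in c("SET1", "SET2", "SET3")) {
    full <- pair_score(rep("A", 62), rep("B", 62), score_table(set))
    expect_equal(full$final_score, 62)
    expect_equal(full$n_invariable, 0L)
    ident <- pair_score(rep("A", 10), rep("A", 10), score_table(set))
    expect_equal(ident$final_score, 0)
    expect_equal(ident$n_invariable, 10L)
  }
  expect_error(pair_score(c("A", "B"), "A"), "length mismatch")
})

test_that("pair scoring is symmetric, additive and matches a plain lookup oracle", {
  set.seed(42)
  tabs <- lapply(c("SET1", "SET2", "SET3"), score_table)
  for (rep in 1:25) {
    n <- sample(3:40, 1)
    g1 <- sample(genotype_calls(), n, replace = TRUE)
    g2 <- sample(genotype_calls(), n, replace = TRUE)
    tab <- tabs[[sample.int(3, 1)]]
    a <- pair_score(g1, g2, tab)
    expect_equal(a, pair_score(g2, g1, tab))
    expect_equal(a$final_score, oracle_pair_score(g1, g2, tab))
    expect_lte(a$final_score, ideal_score(n, tab))
    cut <- sample(n - 1, 1)
    expect_equal(
      a$final_score,
      pair_score(g1[1:cut], g2[1:cut], tab)$final_score +
        pair_score(g1[-(1:cut)], g2[-(1:cut)], tab)$final_score
    )
  }
})

test_that("ideal score is the marker count times the A/B score", {
  expect_equal(ideal_score(62, score_table("SET3")), 62)
  expect_equal(ideal_score(500, score_table("SET1")), 500)
  expect_equal(ideal_score(1, score_table("SET2")), 1)
  halved <- score_table("SET3")
  halved$score[halved$combo == "A/B"] <- 0.5
  expect_equal(ideal_score(10, halved), 5)
  expect_error(ideal_score(0), "count >= 1")
})

test_that("similarity range implements the invariable/heterozygous penalties", {
  expect_equal(
    similarity_range(50, 4, 10),
    tibble::tibble(lower_pct = 72, upper_pct = 92)
  )
  expect_equal(
    similarity_range(40, 0, 0),
    tibble::tibble(lower_pct = 100, upper_pct = 100)
  )
  expect_equal(
    similarity_range(10, 10, 0),
    tibble::tibble(lower_pct = 0, upper_pct = 0)
  )
  expect_error(similarity_range(10, 8, 5), "exceeds n_markers")
})
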