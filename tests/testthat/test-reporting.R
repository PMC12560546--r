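fixture_selection <- function(phased = TRUE) {
  sim <- simulate_f2(60, sim_chromosomes(3, 90, 8), missing_rate = 0.02, seed = 55)
  list(
    sim = sim,
    sel = run_selection(sim$genotypes, sim$map,
      min_score_fraction = 0.55, phased = phased
    )
  )
}

test_that("accepted-pairs files carry 8 unphased or 11 phased columns and re-derive from raw data", {
  fx <- fixture_selection(phased = TRUE)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_accepted_pairs(fx$sel, f)
  tab <- readr::read_tsv(f, show_col_types = FALSE)
  expect_equal(ncol(tab), 11L)
  expect_gt(nrow(tab), 0L)
  expect_equal(nrow(tab), fx$sel$stats$n_accepted)

  # recompute one row end-to-end from the genotype table
  calls <- as.matrix(fx$sim$genotypes[, -1])
  rownames(calls) <- fx$sim$genotypes$individual
  row <- tab[1, ]
  ps <- pair_score(calls[row$id1, ], calls[row$id2, ], score_table("SET3"))
  expect_equal(row$final_score, as.numeric(sprintf("%.2f", ps$final_score)))
  expect_equal(row$n_invariable, ps$n_invariable)
  expect_equal(
    row$rec_total,
    pair_recombination(calls[row$id1, ], calls[row$id2, ], fx$sim$map)$rec_total
  )

  unphased <- fixture_selection(phased = FALSE)
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_accepted_pairs(unphased$sel, f2)
  expect_equal(ncol(readr::read_tsv(f2, show_col_types = FALSE)), 8L)
})

test_that("an empty selection writes a header-only pairs file", {
  g <- geno_tbl(i1 = "AABB", i2 = "AABB", i3 = "ABAB")
  sel <- run_selection(g, map_for(g), min_score_fraction = 0.99)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_accepted_pairs(sel, f)
  expect_length(readLines(f), 1L)
})

test_that("discard files annotate every rejection with reason and thresholds", {
  g <- geno_tbl(
    keepA = "ABABABAB",
    keepB = "BABABABA",
    hothet = "HHHHHHAB",
    selfish = "ABABABAB"
  )
  sel <- run_selection(g, map_for(g),
    max_het = 0.5, min_score_fraction = 0.8, max_invariable_fraction = 0
  )
  f <- withr::local_tempfile(fileext = ".tsv")
  write_discarded(sel, f)
  tab <- readr::read_tsv(f, show_col_types = FALSE)
  expect_equal(names(tab), c("subject", "reason", "observed", "threshold"))
  expect_true("hothet" %in% tab$subject[tab$reason == "HET_RATE"])
  expect_equal(sum(tab$reason == "HET_RATE"), 1L)
  # keepA vs selfish: identical, fully complementary to keepB; keepA|selfish is all-invariable
  expect_true(any(tab$reason %in% c("LOW_SCORE", "INVARIABLE_EXCESS")))

  # cap notice appears when low-score rejections are aggregated
  sim <- simulate_f2(30, sim_chromosomes(2, 100, 10), seed = 2)
  capped <- run_selection(sim$genotypes, sim$map,
    min_score_fraction = 0.95, low_score_cap = 5
  )
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_discarded(capped, f2)
  expect_true(any(grepl("not enumerated", readLines(f2))))
})

test_that("run logs print applied defaults and consistent stage statistics", {
  fx <- fixture_selection()
  f <- withr::local_tempfile(fileext = ".log")
  write_run_log(fx$sel, f)
  log <- readLines(f)
  expect_true(any(grepl("^score_set: SET3$", log)))
  expect_true(any(grepl("^max_het: 0.5$", log)))
  expect_true(any(grepl("^min_score_fraction: 0.55$", log)))
  s <- fx$sel$stats
  expect_true(any(grepl(
    sprintf("^pairs_evaluated: %s$", format(s$pairs_evaluated, big.mark = ",")), log
  )))
  expect_equal(s$pairs_evaluated, n_comparisons(s$n_retained))

  # identical reruns differ only in the timestamp line
  sel2 <- run_selection(fx$sim$genotypes, fx$sim$map,
    min_score_fraction = 0.55, phased = TRUE
  )
  f2 <- withr::local_tempfile(fileext = ".log")
  write_run_log(sel2, f2)
  log2 <- readLines(f2)
  keep <- !grepl("^generated:", log)
  expect_identical(log[keep], log2[!grepl("^generated:", log2)])
})

test_that("top-pairs figures render grouped chromosome panels to png and pdf", {
  fx <- fixture_selection()
  p <- autoplot(fx$sel, geno = fx$sim$genotypes, map = fx$sim$map, n_pairs = 3)
  expect_s3_class(p, "ggplot")
  built <- ggplot2::ggplot_build(p)
  # 3 pairs -> 6 individual rows
  expect_equal(length(unique(built$data[[1]]$y)), 6L)

  prefix <- withr::local_tempfile()
  paths <- plot_top_pairs(fx$sim$genotypes, fx$sim$map, fx$sel, prefix)
  expect_true(all(file.exists(paste0(prefix, ".top_pairs.", c("png", "pdf")))))

  empty <- run_selection(fx$sim$genotypes, fx$sim$map, min_score_fraction = 1)
  expect_message(
    out <- plot_top_pairs(fx$sim$genotypes, fx$sim$map, empty, prefix),
    "skipped"
  )
  expect_length(out, 0L)
})

test_that("write_selection produces the four products under one prefix", {
  fx <- fixture_selection()
  prefix <- file.path(withr::local_tempdir(), "run1")
  paths <- write_selection(fx$sel, fx$sim$genotypes, fx$sim$map, prefix)
  expect_true(all(file.exists(paste0(prefix, c(
    ".pairs.tsv", ".discarded.tsv", ".log", ".top_pairs.png", ".top_pairs.pdf"
  )))))
})
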