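test_that("comparison counts follow k(k-1)/2", {
  expect_equal(n_comparisons(418), 87153)
  expect_equal(n_comparisons(2), 1)
  expect_equal(n_comparisons(0), 0)
  expect_equal(n_comparisons(4900), 12002550)
})

test_that("the engine agrees with naive per-pair scoring and filtering", {
  sim <- simulate_f2(30, sim_chromosomes(2, 100, 8), missing_rate = 0.05, seed = 17)
  tab <- score_table("SET2")
  sel <- run_selection(sim$genotypes, sim$map,
    table = tab, max_het = 0.6,
    min_score_fraction = 0.5, max_invariable_fraction = 0.2, phased = TRUE
  )
  calls <- as.matrix(sim$genotypes[, -1])
  rownames(calls) <- sim$genotypes$individual
  ideal <- ideal_score(ncol(calls), tab)

  flt <- filter_individuals(sim$genotypes, 0.6)
  expected_pairs <- n_comparisons(length(flt$kept))
  expect_equal(sel$stats$pairs_evaluated, expected_pairs)
  # conservation: accepted + rejected pairs partition the evaluated pairs
  expect_equal(
    nrow(sel$accepted) + sel$stats$n_rejected_low_score + sel$stats$n_rejected_invariable,
    expected_pairs
  )

  # every accepted pair reproduces the naive computation exactly
  for (r in seq_len(min(nrow(sel$accepted), 15))) {
    row <- sel$accepted[r, ]
    g1 <- calls[row$id1, ]
    g2 <- calls[row$id2, ]
    ps <- pair_score(g1, g2, tab)
    expect_equal(row$final_score, ps$final_score)
    expect_equal(row$n_invariable, ps$n_invariable)
    expect_null(evaluate_pair(ps, ideal, 0.5, 0.2))
    sim_rng <- similarity_range(ps$n_markers, ps$n_invariable, ps$n_het_union)
    expect_equal(row$similarity_lower_pct, sim_rng$lower_pct)
    expect_equal(row$similarity_upper_pct, sim_rng$upper_pct)
    pr <- pair_recombination(g1, g2, sim$map)
    expect_equal(row$rec_total, pr$rec_total)
  }

  # every rejected pair record reproduces its reason
  pair_rej <- dplyr::filter(sel$rejected, reason != "HET_RATE")
  for (r in seq_len(min(nrow(pair_rej), 15))) {
    ids <- strsplit(pair_rej$subject[r], "|", fixed = TRUE)[[1]]
    ps <- pair_score(calls[ids[1], ], calls[ids[2], ], tab)
    verdict <- evaluate_pair(ps, ideal, 0.5, 0.2)
    expect_equal(verdict$reason, pair_rej$reason[r])
  }
})

test_that("results are sorted by score with recombination and id tie-breaks", {
  sim <- simulate_f2(50, sim_chromosomes(2, 100, 10), seed = 29)
  sel <- run_selection(sim$genotypes, sim$map,
    min_score_fraction = 0.3, max_invariable_fraction = 1, phased = TRUE
  )
  acc <- sel$accepted
  expect_true(all(diff(acc$final_score) <= 1e-12))
  ties <- which(abs(diff(acc$final_score)) < 1e-12)
  expect_true(all(acc$rec_total[ties] <= acc$rec_total[ties + 1]))
  expect_true(all(acc$id1 < acc$id2))
})

test_that("output is identical for any worker count and chunking", {
  sim <- simulate_f2(200, sim_chromosomes(4, 100, 25), missing_rate = 0.02, seed = 31)
  runs <- lapply(c(1, 2, 4), function(w) {
    run_selection(sim$genotypes, sim$map,
      min_score_fraction = 0.5, phased = TRUE, workers = w
    )
  })
  ser <- lapply(runs, function(sel) {
    f <- tempfile()
    write_accepted_pairs(sel, f)
    on.exit(unlink(f))
    readLines(f)
  })
  expect_identical(ser[[1]], ser[[2]])
  expect_identical(ser[[1]], ser[[3]])
  expect_identical(runs[[1]]$rejected, runs[[2]]$rejected)
  expect_identical(runs[[1]]$stats, runs[[3]]$stats)
  expect_error(run_selection(sim$genotypes, sim$map, workers = 0), "workers")
})

test_that("identical individuals yield no accepted pair and degenerate cases are handled", {
  g <- geno_tbl(i1 = "AABB", i2 = "AABB")
  mm <- map_for(g)
  sel <- run_selection(g, mm, min_score_fraction = 0.5, max_invariable_fraction = 1)
  expect_equal(nrow(sel$accepted), 0L)
  expect_equal(sel$stats$n_rejected_low_score, 1)

  # single retained individual: no pairs at all
  solo <- run_selection(g[1, ], mm)
  expect_equal(solo$stats$pairs_evaluated, 0)
  expect_equal(nrow(solo$accepted), 0L)
})

test_that("low-score rejections collapse to a count above the enumeration cap", {
  sim <- simulate_f2(40, sim_chromosomes(2, 100, 10), seed = 41)
  capped <- run_selection(sim$genotypes, sim$map,
    min_score_fraction = 0.9, low_score_cap = 10
  )
  full <- run_selection(sim$genotypes, sim$map, min_score_fraction = 0.9)
  expect_false(capped$stats$low_score_enumerated)
  expect_equal(capped$stats$n_rejected_low_score, full$stats$n_rejected_low_score)
  expect_false(any(capped$rejected$reason == "LOW_SCORE"))
  expect_identical(capped$accepted, full$accepted)
})
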