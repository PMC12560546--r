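# Serialisation of the four run products: accepted pairs, annotated
# discards, run log, and the top-pairs genotype figure.

#' Write the accepted-pairs table
#'
#' Tab-separated, one row per accepted pair in engine order: `id1`, `id2`,
#' `final_score` (2 decimals), `n_invariable`, `het1`, `het2` (4 decimals),
#' `similarity_lower_pct`, `similarity_upper_pct` (2 decimals); runs on
#' phased data add `rec1`, `rec2`, `rec_total`.  An empty selection yields a
#' header-only file.
#'
#' @param sel A `resyn_selection` from [run_selection()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_accepted_pairs <- function(sel, path) {
  stopifnot(inherits(sel, "resyn_selection"))
  acc <- sel$accepted
  out <- tibble(
    id1 = acc$id1,
    id2 = acc$id2,
    final_score = sprintf("%.2f", acc$final_score),
    n_invariable = as.integer(acc$n_invariable),
    het1 = sprintf("%.4f", acc$het1),
    het2 = sprintf("%.4f", acc$het2),
    similarity_lower_pct = sprintf("%.2f", acc$similarity_lower_pct),
    similarity_upper_pct = sprintf("%.2f", acc$similarity_upper_pct)
  )
  if (sel$config$phased) {
    out$rec1 <- as.integer(acc$rec1)
    out$rec2 <- as.integer(acc$rec2)
    out$rec_total <- as.integer(acc$rec_total)
  }
  readr::write_tsv(out, path)
  invisible(path)
}

#' Write the discard records
#'
#' Tab-separated: `subject` (individual id or `id1|id2`), `reason`
#' (`HET_RATE`, `LOW_SCORE`, `INVARIABLE_EXCESS`), `observed`, `threshold`.
#' When the run's pair count exceeded the `LOW_SCORE` enumeration cap, the
#' individual low-score rows are replaced by a single aggregated row whose
#' subject states the count and the cap.
#'
#' @inheritParams write_accepted_pairs
#' @return The path, invisibly.
#' @export
write_discarded <- function(sel, path) {
  stopifnot(inherits(sel, "resyn_selection"))
  rej <- mutate(
    sel$rejected,
    observed = sprintf("%.4f", .data$observed),
    threshold = sprintf("%.4f", .data$threshold)
  )
  if (!sel$stats$low_score_enumerated && sel$stats$n_rejected_low_score > 0) {
    rej <- bind_rows(rej, tibble(
      subject = sprintf(
        "[%s pairs not enumerated: total pairs exceeded the cap of %s]",
        format(sel$stats$n_rejected_low_score, big.mark = ",", scientific = FALSE),
        format(sel$config$low_score_cap, big.mark = ",", scientific = FALSE)
      ),
      reason = REASON_SCORE,
      observed = "NA",
      threshold = sprintf("%.4f", sel$config$min_score_fraction * sel$config$ideal_score)
    ))
  }
  readr::write_tsv(rej, path)
  invisible(path)
}

#' Write the run log
#'
#' Human-readable account of a selection run: every argument as applied
#' (defaults included), the per-stage filtering statistics, the similarity
#' range of the best pair in the conventional `lower--upper%` form, and a
#' timestamp.  Two runs on identical inputs differ only in the timestamp
#' line.
#'
#' @inheritParams write_accepted_pairs
#' @return The path, invisibly.
#' @export
write_run_log <- function(sel, path) {
  stopifnot(inherits(sel, "resyn_selection"))
  cfg <- sel$config
  s <- sel$stats
  lines <- c(
    "# complementary-pair selection run log",
    sprintf("generated: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")),
    "",
    "## arguments (defaults included)",
    sprintf("score_set: %s", cfg$score_set),
    sprintf("score_table: %s", paste(
      sprintf("%s=%g", cfg$score_table$combo, cfg$score_table$score),
      collapse = " "
    )),
    sprintf("max_het: %g", cfg$max_het),
    sprintf("het_denominator: %s", cfg$het_denominator),
    sprintf("min_score_fraction: %g", cfg$min_score_fraction),
    sprintf("max_invariable_fraction: %g", cfg$max_invariable_fraction),
    sprintf("phased: %s", cfg$phased),
    sprintf("workers: %d", cfg$workers),
    sprintf("low_score_cap: %g", cfg$low_score_cap),
    "",
    "## filtering statistics",
    sprintf("individuals: %d", s$n_individuals),
    sprintf("markers: %d", s$n_markers),
    sprintf("ideal_score: %g", cfg$ideal_score),
    sprintf("rejected_het_rate: %d", s$n_rejected_het),
    sprintf("retained_individuals: %d", s$n_retained),
    sprintf("pairs_evaluated: %s", format(s$pairs_evaluated, big.mark = ",", scientific = FALSE)),
    sprintf("rejected_low_score: %s", format(s$n_rejected_low_score, big.mark = ",", scientific = FALSE)),
    sprintf("rejected_invariable_excess: %d", s$n_rejected_invariable),
    sprintf("accepted_pairs: %d", s$n_accepted)
  )
  if (s$n_accepted > 0L) {
    best <- sel$accepted[1L, ]
    lines <- c(lines, sprintf(
      "best_pair: %s|%s score %.2f similarity %.0f-%.0f%%",
      best$id1, best$id2, best$final_score,
      best$similarity_lower_pct, best$similarity_upper_pct
    ))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Genotype profiles of the top-ranked pairs
#'
#' `autoplot()` draws the ABH genotype profile of every individual in the
#' top `n_pairs` accepted pairs (up to 20 rows, grouped by pair, best pair
#' at the top), with markers along the x axis grouped into chromosome
#' panels and each cell coloured by call class.  `plot_top_pairs()` renders
#' the same figure to `<prefix>.top_pairs.png` and `.pdf`; with no accepted
#' pairs it writes nothing and emits a message.
#'
#' @param object A `resyn_selection`.
#' @param geno,map The genotype and marker-map tibbles the selection was
#'   run on.
#' @param n_pairs Number of top pairs to draw (default 10).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot resyn_selection
#' @export
autoplot.resyn_selection <- function(object, geno, map, n_pairs = 10, ...) {
  acc <- head(object$accepted, n_pairs)
  if (nrow(acc) == 0L) abort("no accepted pairs to plot")
  acc$rank <- seq_len(nrow(acc))
  long <- acc |>
    select("rank", "id1", "id2") |>
    tidyr::pivot_longer(c("id1", "id2"), names_to = "member", values_to = "individual") |>
    arrange(.data$rank, .data$member)
  # one display row per pair member, even if an individual recurs in pairs
  long$row <- sprintf("pair %02d: %s", long$rank, long$individual)
  calls <- geno_matrix(geno)
  cells <- tibble(
    row = rep(long$row, each = ncol(calls)),
    marker = rep(colnames(calls), times = nrow(long)),
    call = as.vector(t(calls[long$individual, , drop = FALSE]))
  ) |>
    left_join(map, by = "marker") |>
    mutate(
      marker = factor(.data$marker, levels = map$marker),
      chrom = factor(.data$chrom, levels = unique(map$chrom)),
      row = factor(.data$row, levels = rev(unique(long$row))),
      call = factor(.data$call, levels = CALL_LEVELS)
    )
  ggplot2::ggplot(cells, ggplot2::aes(x = .data$marker, y = .data$row, fill = .data$call)) +
    ggplot2::geom_tile(colour = "white", linewidth = 0.2) +
    ggplot2::facet_grid(
      cols = ggplot2::vars(.data$chrom),
      scales = "free_x", space = "free_x"
    ) +
    ggplot2::scale_fill_manual(
      values = c("A" = "#3B6FB6", "B" = "#C03A2B", "H" = "#E8C34A", "-" = "grey75"),
      drop = FALSE, name = "call"
    ) +
    ggplot2::labs(
      x = NULL, y = NULL,
      title = sprintf("Genotype profiles of the top %d pairs", nrow(acc))
    ) +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(
      axis.text.x = ggplot2::element_blank(),
      panel.grid = ggplot2::element_blank(),
      panel.spacing.x = ggplot2::unit(2, "pt")
    )
}

#' @param sel A `resyn_selection`.
#' @param path_prefix Output prefix; `.top_pairs.png` and `.top_pairs.pdf`
#'   are appended.
#' @rdname autoplot.resyn_selection
#' @export
plot_top_pairs <- function(geno, map, sel, path_prefix, n_pairs = 10) {
  if (nrow(sel$accepted) == 0L) {
    message("no accepted pairs: top-pairs figure skipped")
    return(invisible(character(0L)))
  }
  p <- autoplot(sel, geno = geno, map = map, n_pairs = n_pairs)
  n_rows <- min(n_pairs, nrow(sel$accepted)) * 2
  h <- max(2, 0.35 * n_rows + 1.2)
  paths <- paste0(path_prefix, ".top_pairs.", c("png", "pdf"))
  ggplot2::ggsave(paths[1L], p, width = 10, height = h, dpi = 150)
  ggplot2::ggsave(paths[2L], p, width = 10, height = h)
  invisible(paths)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Write all selection run products under one prefix
#'
#' Convenience wrapper producing the four run artifacts:
#' `<prefix>.pairs.tsv`, `<prefix>.discarded.tsv`, `<prefix>.log` and (when
#' pairs were accepted) `<prefix>.top_pairs.png/.pdf`.
#'
#' @inheritParams plot_top_pairs
#' @param figure Draw the top-pairs figure (default `TRUE`).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_selection <- function(sel, geno, map, path_prefix, figure = TRUE) {
  paths <- c(
    pairs = write_accepted_pairs(sel, paste0(path_prefix, ".pairs.tsv")),
    discarded = write_discarded(sel, paste0(path_prefix, ".discarded.tsv")),
    log = write_run_log(sel, paste0(path_prefix, ".log"))
  )
  if (figure && nrow(sel$accepted) > 0L) {
    fig <- plot_top_pairs(geno, map, sel, path_prefix)
    paths <- c(paths, figure_png = fig[1L], figure_pdf = fig[2L])
  } else if (figure) {
    message("no accepted pairs: top-pairs figure skipped")
  }
  invisible(paths)
}
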