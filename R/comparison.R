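#' Published fine/coarse pathway pair definitions
#'
#' Six example pathway pairings of a fine-grained annotation (EcoCyc) with
#' its coarse counterpart (KEGG), as published: four amino-acid biosynthesis
#' pathways plus purine and pyrimidine metabolism. Each row records the two
#' pathway sizes (`n_fine`, `n_coarse`), the two pathway-assigned gene
#' totals (`N_fine` = 1096 for EcoCyc, `N_coarse` = 1686 for KEGG), the two
#' Bonferroni multiplicities (`m_fine` = 354, `m_coarse` = 119), and the
#' number of significant figures the published table prints
#' (`sig_digits`).
#'
#' @return A tibble with one row per pathway pair.
#' @export
granularity_pairs <- function() {
  readr::read_tsv(
    system.file("extdata", "ecocyc_kegg_pairs.tsv", package = "granora"),
    show_col_types = FALSE
  )
}

#' Published reference p-values for the fine/coarse pairs
#'
#' The published per-row p-values for every pair in [granularity_pairs()]:
#' for each count `k` of significant genes (all lying in the pathway, so
#' `K = k`), the raw and Bonferroni-corrected p-values on the fine (EcoCyc,
#' N = 1096, m = 354) and coarse (KEGG, N = 1686, m = 119) sides, at the
#' published precision.
#'
#' @return A tibble with columns `label`, `k`, `p_fine`, `p_fine_corrected`,
#'   `p_coarse`, `p_coarse_corrected`.
#' @export
reference_pvalues <- function() {
  readr::read_tsv(
    system.file("extdata", "ecocyc_kegg_reference_pvalues.tsv", package = "granora"),
    show_col_types = FALSE
  )
}

#' Build a fine-vs-coarse enrichment comparison
#'
#' For each pathway pair, computes enrichment p-values for `k = n_fine`
#' down to 1 significant genes under the regime where every significant
#' gene lies in the pathway (`K = k`), on both the fine and coarse side,
#' with Bonferroni correction by each side's own multiplicity. The
#' `log10_ratio` column is \eqn{\log_{10}(p_{coarse}/p_{fine})} on raw
#' p-values — the orders-of-magnitude divergence attributable to pathway
#' granularity.
#'
#' @param pairs A tibble of pair specs with columns `label`, `n_fine`,
#'   `n_coarse`, `N_fine`, `N_coarse`, `m_fine`, `m_coarse` (defaults to
#'   [granularity_pairs()]). Extra columns are ignored.
#' @return A `pair_comparison` tibble with one row per (pair, k).
#' @examples
#' build_comparison() |> dplyr::filter(label == "cysteine")
#' @export
build_comparison <- function(pairs = granularity_pairs()) {
  pairs <- as_tibble(pairs)
  needed <- c("label", "n_fine", "n_coarse", "N_fine", "N_coarse",
              "m_fine", "m_coarse")
  missing <- setdiff(needed, names(pairs))
  if (length(missing) > 0L) {
    abort(sprintf("`pairs` lacks column(s): %s.", paste(missing, collapse = ", ")))
  }
  if (any(pairs$n_fine > pairs$N_fine) || any(pairs$n_coarse > pairs$N_coarse)) {
    abort("Pathway sizes must not exceed their universe totals.")
  }
  rows <- pmap(pairs[needed], function(label, n_fine, n_coarse,
                                       N_fine, N_coarse, m_fine, m_coarse) {
    k <- seq(n_fine, 1L)
    tibble(
      label = label,
      k = k,
      p_fine_raw = enrichment_pvalue(k, k, n_fine, N_fine),
      p_coarse_raw = enrichment_pvalue(k, k, n_coarse, N_coarse)
    ) |>
      mutate(
        p_fine_corrected = bonferroni(.data$p_fine_raw, m_fine),
        p_coarse_corrected = bonferroni(.data$p_coarse_raw, m_coarse),
        log10_ratio = orders_of_magnitude(.data$p_fine_raw, .data$p_coarse_raw)
      ) |>
      select("label", "k", "p_fine_raw", "p_fine_corrected",
             "p_coarse_raw", "p_coarse_corrected", "log10_ratio")
  })
  structure(
    list_rbind(rows),
    class = c("pair_comparison", class(tibble()))
  )
}

#' Orders of magnitude between two p-values
#'
#' \eqn{\log_{10}(p_b / p_a)}: how many decades larger (positive) or
#' smaller (negative) `p_b` is than `p_a`.
#'
#' @param p_a,p_b Probabilities in (0, 1].
#' @return Numeric vector.
#' @examples
#' orders_of_magnitude(2.03e-30, 3.49e-21) # about 9.2
#' @export
orders_of_magnitude <- function(p_a, p_b) {
  assert_probability(p_a, "p_a")
  assert_probability(p_b, "p_b")
  log10(p_b) - log10(p_a)
}

#' Verify computed comparison tables against published values
#'
#' Recomputes every cell of the fine/coarse comparison tables and checks it
#' against the published value at the published precision (each computed
#' value is rounded to the table's number of significant figures before
#' comparison; bit-exact string matching across typography is impossible,
#' rounding to printed precision is the meaningful test).
#'
#' @param pairs Pair specs, as in [build_comparison()]; must carry a
#'   `sig_digits` column.
#' @param reference Published values, shaped like [reference_pvalues()].
#' @return A `table_verification` tibble with one row per cell: `label`,
#'   `k`, `column`, `computed`, `printed`, `match`. Summarize with
#'   [glance()]; `attr(x, "n_mismatch")` gives the mismatch count.
#' @examples
#' verify_reference_tables() |> glance()
#' @export
verify_reference_tables <- function(pairs = granularity_pairs(),
                                    reference = reference_pvalues()) {
  if (!"sig_digits" %in% names(pairs)) {
    abort("`pairs` must carry a `sig_digits` column for printed precision.")
  }
  computed <- build_comparison(pairs) |>
    rename(p_fine = "p_fine_raw", p_coarse = "p_coarse_raw")
  cols <- c("p_fine", "p_fine_corrected", "p_coarse", "p_coarse_corrected")
  long_computed <- tidyr::pivot_longer(
    computed[c("label", "k", cols)], all_of(cols),
    names_to = "column", values_to = "computed"
  )
  long_printed <- tidyr::pivot_longer(
    as_tibble(reference), all_of(cols),
    names_to = "column", values_to = "printed"
  )
  cells <- dplyr::inner_join(long_printed, long_computed,
                             by = c("label", "k", "column")) |>
    left_join(as_tibble(pairs)[c("label", "sig_digits")], by = "label") |>
    mutate(match = signif_equal(.data$computed, .data$printed, .data$sig_digits)) |>
    arrange(.data$label, desc(.data$k), .data$column)
  if (nrow(cells) < nrow(long_printed)) {
    abort("Some published cells have no computed counterpart; check `pairs`.")
  }
  structure(
    cells,
    class = c("table_verification", class(tibble())),
    n_mismatch = sum(!cells$match)
  )
}

#' @method glance table_verification
#' @export
glance.table_verification <- function(x, ...) {
  tibble(
    n_cells = nrow(x),
    n_mismatch = sum(!x$match),
    all_match = all(x$match)
  )
}

#' Plot a fine-vs-coarse comparison
#'
#' Raw enrichment p-values (log10 scale) against the significant-gene count
#' for both sides of each pair; the vertical gap between the curves is the
#' granularity effect.
#'
#' @param object A `pair_comparison` from [build_comparison()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pair_comparison
#' @export
autoplot.pair_comparison <- function(object, ...) {
  d <- tidyr::pivot_longer(
    as_tibble(object)[c("label", "k", "p_fine_raw", "p_coarse_raw")],
    c("p_fine_raw", "p_coarse_raw"),
    names_to = "side", values_to = "p"
  ) |>
    mutate(side = ifelse(.data$side == "p_fine_raw", "fine", "coarse"))
  ggplot2::ggplot(d, ggplot2::aes(.data$k, .data$p, colour = .data$side)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~label, scales = "free") +
    ggplot2::labs(
      x = "significant genes in pathway (k = K)",
      y = "enrichment p-value",
      colour = "annotation"
    ) +
    ggplot2::theme_minimal()
}
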