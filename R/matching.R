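#' Significance of the overlap between two gene sets
#'
#' Hypergeometric upper-tail probability of observing at least the
#' realized overlap between two gene sets drawn from a shared universe:
#' `enrichment_pvalue(k = |A ∩ B|, K = |A|, n = |B|, N = universe_size)`.
#' Symmetric in its two set arguments.
#'
#' @param set_a,set_b Character vectors of gene identifiers.
#' @param universe_size Size of the joint universe both sets live in; must
#'   be at least `|A ∪ B|`.
#' @return A probability in (0, 1]. Disjoint sets give exactly 1
#'   (`P(X >= 0) = 1`).
#' @examples
#' overlap_pvalue(paste0("g", 1:4), paste0("g", 3:8), universe_size = 20)
#' @export
overlap_pvalue <- function(set_a, set_b, universe_size) {
  set_a <- unique(as.character(set_a))
  set_b <- unique(as.character(set_b))
  if (!is_count(universe_size) || length(universe_size) != 1L) {
    abort("`universe_size` must be a single non-negative integer.")
  }
  if (universe_size < length(union(set_a, set_b))) {
    abort("`universe_size` is smaller than the union of the two sets.")
  }
  enrichment_pvalue(
    k = length(intersect(set_a, set_b)),
    K = length(set_a),
    n = length(set_b),
    N = universe_size
  )
}

#' Match analogous pathways across two databases
#'
#' Declares a fine pathway and a coarse pathway analogous when their gene
#' sets overlap significantly within the joint universe (the union of both
#' databases' assigned genes). Candidate pairs must satisfy
#' `n_fine >= min_fine_genes` and an overlap p-value at most
#' `overlap_alpha` (after Bonferroni correction over all candidate pairs,
#' unless `correction = "none"`). With `one_to_one = TRUE` candidates are
#' resolved greedily into unique pairs: sorted by overlap p-value (rounded
#' to `tie_sig_digits` significant figures, so "comparable" p-values tie),
#' then by smallest combined gene count, then lexicographically by ids, and
#' accepted only when neither endpoint is already used. The total order
#' makes the output deterministic.
#'
#' @param fine_db,coarse_db [pathway_db()] objects sharing a gene
#'   namespace.
#' @param min_fine_genes Minimum fine-pathway size (default 3).
#' @param overlap_alpha Significance cutoff for "highly significant"
#'   overlap (default 0.05).
#' @param correction `"bonferroni"` (over all candidate pairs; default) or
#'   `"none"`.
#' @param one_to_one Enforce unique pairing (default `TRUE`).
#' @param tie_sig_digits Significant figures at which overlap p-values are
#'   considered comparable for tie-breaking (default 2).
#' @return A `pathway_match` tibble with columns `fine_id`, `coarse_id`,
#'   `n_fine`, `n_coarse`, `overlap`, `overlap_p`, `overlap_p_adj`,
#'   `size_ratio` (`n_coarse / n_fine`), `combined_size`.
#' @export
match_pathways <- function(fine_db, coarse_db, min_fine_genes = 3L,
                           overlap_alpha = 0.05,
                           correction = c("bonferroni", "none"),
                           one_to_one = TRUE, tie_sig_digits = 2L) {
  stopifnot(inherits(fine_db, "pathway_db"), inherits(coarse_db, "pathway_db"))
  correction <- match.arg(correction)
  fine_genes <- assigned_genes(fine_db)
  coarse_genes <- assigned_genes(coarse_db)
  if (length(intersect(fine_genes, coarse_genes)) == 0L) {
    abort("The two databases share no gene identifiers; cannot match.")
  }
  universe_n <- length(union(fine_genes, coarse_genes))

  fine <- fine_db[lengths(fine_db$genes) >= min_fine_genes, ]
  if (nrow(fine) == 0L) {
    abort(sprintf("No fine pathway has at least %d genes.", min_fine_genes))
  }
  n_tests <- nrow(fine) * nrow(coarse_db)

  cand <- tidyr::expand_grid(fi = seq_len(nrow(fine)), ci = seq_len(nrow(coarse_db)))
  cand <- mutate(
    cand,
    fine_id = fine$pathway_id[.data$fi],
    coarse_id = coarse_db$pathway_id[.data$ci],
    n_fine = lengths(fine$genes)[.data$fi],
    n_coarse = lengths(coarse_db$genes)[.data$ci],
    overlap = map2_int(.data$fi, .data$ci, function(i, j) {
      length(intersect(fine$genes[[i]], coarse_db$genes[[j]]))
    })
  )
  # overlap 0 can never be significant (p = 1); skip the tail computation
  cand <- filter(cand, .data$overlap > 0L)
  cand$overlap_p <- enrichment_pvalue(
    k = cand$overlap, K = cand$n_fine, n = cand$n_coarse, N = universe_n
  )
  cand$overlap_p_adj <- if (correction == "bonferroni") {
    bonferroni(cand$overlap_p, n_tests)
  } else {
    cand$overlap_p
  }
  cand <- cand |>
    filter(.data$overlap_p_adj <= overlap_alpha) |>
    mutate(
      size_ratio = .data$n_coarse / .data$n_fine,
      combined_size = .data$n_fine + .data$n_coarse
    ) |>
    arrange(signif(.data$overlap_p, tie_sig_digits), .data$combined_size,
            .data$fine_id, .data$coarse_id) |>
    select("fine_id", "coarse_id", "n_fine", "n_coarse", "overlap",
           "overlap_p", "overlap_p_adj", "size_ratio", "combined_size")

  if (one_to_one && nrow(cand) > 0L) {
    used_fine <- character(0); used_coarse <- character(0)
    keep <- logical(nrow(cand))
    for (i in seq_len(nrow(cand))) {
      if (!(cand$fine_id[i] %in% used_fine) &&
          !(cand$coarse_id[i] %in% used_coarse)) {
        keep[i] <- TRUE
        used_fine <- c(used_fine, cand$fine_id[i])
        used_coarse <- c(used_coarse, cand$coarse_id[i])
      }
    }
    cand <- cand[keep, ]
  }
  structure(
    cand,
    class = c("pathway_match", class(tibble())),
    universe_size = universe_n,
    n_tests = n_tests,
    overlap_alpha = overlap_alpha,
    correction = correction,
    one_to_one = one_to_one
  )
}

#' Summary statistics of matched-pair size ratios
#'
#' @param pairs A `pathway_match` from [match_pathways()] (or any data
#'   frame with a `size_ratio` column); must contain at least one pair.
#' @return A one-row tibble: `n_pairs`, `mean_ratio`, `median_ratio`,
#'   `q25`, `q75`.
#' @export
size_ratio_summary <- function(pairs) {
  pairs <- as_tibble(pairs)
  if (nrow(pairs) == 0L) abort("Need at least one matched pair.")
  tibble(
    n_pairs = nrow(pairs),
    mean_ratio = mean(pairs$size_ratio),
    median_ratio = median(pairs$size_ratio),
    q25 = unname(quantile(pairs$size_ratio, 0.25)),
    q75 = unname(quantile(pairs$size_ratio, 0.75))
  )
}

#' Precision and recall of matching against a known pairing
#'
#' Scores a [match_pathways()] result against a ground-truth mapping (for
#' synthetic databases, the fine-to-coarse containment retained by
#' [coarsen_db()]). Precision is the fraction of accepted pairs present in
#' the truth. Recall depends on the matching mode: in one-to-one mode each
#' coarse pathway can be matched at most once, so recall is the fraction of
#' coarse pathways matched to one of their true members; otherwise it is
#' the fraction of all true pairs recovered.
#'
#' @param pairs A `pathway_match`.
#' @param truth A data frame with columns `fine_id`, `coarse_id`.
#' @return A one-row tibble: `n_accepted`, `n_true`, `precision`, `recall`.
#' @export
match_recovery <- function(pairs, truth) {
  stopifnot(inherits(pairs, "pathway_match"))
  truth <- as_tibble(truth)[c("fine_id", "coarse_id")]
  key <- function(d) paste(d$fine_id, d$coarse_id, sep = "\r")
  accepted <- key(pairs)
  true_keys <- key(truth)
  correct <- accepted %in% true_keys
  recall <- if (isTRUE(attr(pairs, "one_to_one"))) {
    matched_coarse <- unique(pairs$coarse_id[correct])
    length(matched_coarse) / length(unique(truth$coarse_id))
  } else {
    sum(true_keys %in% accepted) / length(true_keys)
  }
  tibble(
    n_accepted = nrow(pairs),
    n_true = nrow(truth),
    precision = if (nrow(pairs) == 0L) NA_real_ else mean(correct),
    recall = recall
  )
}

#' @method glance pathway_match
#' @export
glance.pathway_match <- function(x, ...) {
  dplyr::bind_cols(
    size_ratio_summary(x),
    tibble(
      universe_size = attr(x, "universe_size"),
      n_tests = attr(x, "n_tests"),
      correction = attr(x, "correction")
    )
  )
}

#' Plot matched-pair size ratios
#'
#' @param object A `pathway_match` from [match_pathways()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pathway_match
#' @export
autoplot.pathway_match <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(.data$size_ratio)) +
    ggplot2::geom_histogram(bins = 30) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2) +
    ggplot2::labs(
      x = "coarse / fine size ratio", y = "matched pairs",
      title = "Analogous-pathway size ratios"
    ) +
    ggplot2::theme_minimal()
}
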