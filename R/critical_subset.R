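#' Critical subset size: minimum significant genes for enrichment
#'
#' The inverse enrichment question: given a pathway of size `n` in a
#' universe of `N` pathway-assigned genes, and a sample of `K` significant
#' genes, how many of the pathway's genes must be in the sample for the
#' pathway to reach a fixed (already-adjusted) p-value threshold? Because
#' the upper tail is strictly decreasing in `k`, the answer is found by
#' binary search over `k` in `1..min(n, K)`.
#'
#' @param n Pathway size(s).
#' @param N Total pathway-assigned genes.
#' @param K Significant-sample size(s).
#' @param threshold Adjusted p-value threshold, in (0, 1).
#'
#' `n`, `N` and `K` are recycled to a common length.
#'
#' @return Integer vector: the minimum `k` with
#'   `enrichment_pvalue(k, K, n, N) <= threshold`, or `NA_integer_` when
#'   even `k = min(n, K)` does not reach the threshold (the sentinel is
#'   never 0 or `n + 1`, so downstream summaries can exclude it
#'   explicitly).
#' @examples
#' critical_subset_size(n = 3, N = 1096, K = 100, threshold = 0.05 / 354)
#' @export
critical_subset_size <- function(n, N, K, threshold) {
  len <- max(length(n), length(N), length(K))
  n <- rep_len(n, len); N <- rep_len(N, len); K <- rep_len(K, len)
  if (!is_count(n) || !is_count(N) || !is_count(K)) {
    abort("n, N, K must be non-negative integers.")
  }
  if (any(n < 1) || any(n > N) || any(K < 1) || any(K > N)) {
    abort("Need 1 <= n <= N and 1 <= K <= N.")
  }
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      !is.finite(threshold) || threshold <= 0 || threshold >= 1) {
    abort("`threshold` must be a single probability strictly inside (0, 1).")
  }
  n <- as.integer(n); N <- as.integer(N); K <- as.integer(K)
  vapply(seq_len(len), function(j) {
    hi <- min(n[j], K[j])
    if (enrichment_pvalue(hi, K[j], n[j], N[j]) > threshold) {
      return(NA_integer_)
    }
    lo <- 1L
    # invariant: p(hi) <= threshold; p(lo - 1) > threshold (tail monotone in k)
    while (lo < hi) {
      mid <- (lo + hi) %/% 2L
      if (enrichment_pvalue(mid, K[j], n[j], N[j]) <= threshold) {
        hi <- mid
      } else {
        lo <- mid + 1L
      }
    }
    hi
  }, integer(1))
}

#' Critical-subset profiles for every pathway in a database
#'
#' Enumerates [critical_subset_size()] for each pathway over a grid of
#' sample sizes `K`, at the threshold `rank * alpha / m` — the BH step-up
#' threshold at the given rank. At rank 1 (the default) this coincides with
#' the Bonferroni bound `alpha / m`, appropriate when the rank of the hit
#' among the `m` pathway tests is unknown.
#'
#' @param db A [pathway_db()].
#' @param sample_sizes Grid of significant-sample sizes `K`.
#' @param alpha Family-wise / FDR significance level.
#' @param rank BH rank used to form the threshold (default 1).
#' @param m Multiplicity; defaults to the number of pathways in `db`.
#' @return A `critical_profile` tibble with columns `pathway_id`, `n`,
#'   `sample_size`, `critical_k`, `representation_rate`
#'   (`critical_k / n`; `NA` where unreachable), and attributes
#'   `threshold`, `alpha`, `rank`, `m`, `N`, `db_name`.
#' @examples
#' db <- pathway_db(list(a = paste0("g", 1:5), b = paste0("g", 6:20)))
#' profile_database(db, sample_sizes = c(5, 10), alpha = 0.05)
#' @export
profile_database <- function(db, sample_sizes = seq(50L, 500L, by = 50L),
                             alpha = 0.05, rank = 1L, m = NULL) {
  stopifnot(inherits(db, "pathway_db"))
  m_used <- m %||% nrow(db)
  profile_pathway_sizes(
    pathway_sizes(db)[c("pathway_id", "n")],
    N = length(assigned_genes(db)),
    sample_sizes = sample_sizes,
    alpha = alpha, rank = rank, m = m_used,
    db_name = attr(db, "db_name")
  )
}

#' Critical-subset profiles from pathway sizes alone
#'
#' The critical-subset computation needs only each pathway's size, not its
#' membership, so annotations distributed as per-pathway gene counts (a
#' two-column table of pathway id and size) are accepted directly.
#'
#' @param sizes A data frame with columns `pathway_id` and `n`.
#' @param N Total pathway-assigned genes of the annotation.
#' @param db_name Label recorded on the result.
#' @inheritParams profile_database
#' @return A `critical_profile` tibble; see [profile_database()].
#' @export
profile_pathway_sizes <- function(sizes, N, sample_sizes = seq(50L, 500L, by = 50L),
                                  alpha = 0.05, rank = 1L, m = nrow(sizes),
                                  db_name = "db") {
  sizes <- as_tibble(sizes)
  if (!all(c("pathway_id", "n") %in% names(sizes))) {
    abort("`sizes` must have columns `pathway_id` and `n`.")
  }
  if (!is_count(sample_sizes) || any(sample_sizes < 1) || any(sample_sizes > N)) {
    abort("`sample_sizes` must be integers within 1..N.")
  }
  if (!is_count(rank) || rank < 1 || rank > m) {
    abort("`rank` must be an integer in 1..m.")
  }
  threshold <- rank * alpha / m
  if (threshold >= 1) abort("Derived threshold rank * alpha / m must be < 1.")
  grid <- tidyr::expand_grid(
    sizes[c("pathway_id", "n")],
    sample_size = as.integer(sort(unique(sample_sizes)))
  )
  grid$critical_k <- critical_subset_size(
    n = grid$n, N = N, K = grid$sample_size, threshold = threshold
  )
  grid$representation_rate <- grid$critical_k / grid$n
  structure(
    grid,
    class = c("critical_profile", class(tibble())),
    threshold = threshold, alpha = alpha, rank = as.integer(rank),
    m = m, N = N, db_name = db_name
  )
}

#' @method glance critical_profile
#' @export
glance.critical_profile <- function(x, ...) {
  reachable <- !is.na(x$critical_k)
  tibble(
    db = attr(x, "db_name"),
    n_pathways = length(unique(x$pathway_id)),
    n_grid = length(unique(x$sample_size)),
    threshold = attr(x, "threshold"),
    prop_reachable = mean(reachable),
    median_critical_k = median(x$critical_k[reachable]),
    median_representation_rate = median(x$representation_rate[reachable])
  )
}

#' Ratios of critical subset sizes between paired pathways
#'
#' For matched fine/coarse pathway pairs, computes the per-sample-size
#' ratio `critical_k(coarse) / critical_k(fine)` wherever both sides reach
#' significance, and the median ratio per pair over those grid points.
#' Ratios above 1 mean the coarse annotation needs more significant genes
#' to call the same biology enriched.
#'
#' @param fine,coarse `critical_profile` objects on the same sample-size
#'   grid.
#' @param pairs A data frame with columns `fine_id`, `coarse_id` naming the
#'   pathway pairing. If `NULL`, both profiles must contain a single
#'   pathway, which are paired with each other.
#' @return A `profile_ratio` tibble with per-grid-point rows (`fine_id`,
#'   `coarse_id`, `sample_size`, `critical_fine`, `critical_coarse`,
#'   `ratio`); summarize per pair with [ratio_medians()] or [glance()].
#' @export
ratio_profiles <- function(fine, coarse, pairs = NULL) {
  stopifnot(inherits(fine, "critical_profile"), inherits(coarse, "critical_profile"))
  if (!setequal(unique(fine$sample_size), unique(coarse$sample_size))) {
    abort("`fine` and `coarse` must be profiled on the same sample-size grid.")
  }
  if (is.null(pairs)) {
    fid <- unique(fine$pathway_id); cid <- unique(coarse$pathway_id)
    if (length(fid) != 1L || length(cid) != 1L) {
      abort("Supply `pairs` unless each profile contains exactly one pathway.")
    }
    pairs <- tibble(fine_id = fid, coarse_id = cid)
  }
  pairs <- as_tibble(pairs)[c("fine_id", "coarse_id")]
  f <- as_tibble(fine)[c("pathway_id", "sample_size", "critical_k")] |>
    rename(fine_id = "pathway_id", critical_fine = "critical_k")
  g <- as_tibble(coarse)[c("pathway_id", "sample_size", "critical_k")] |>
    rename(coarse_id = "pathway_id", critical_coarse = "critical_k")
  out <- pairs |>
    dplyr::inner_join(f, by = "fine_id") |>
    dplyr::inner_join(g, by = c("coarse_id", "sample_size")) |>
    filter(!is.na(.data$critical_fine), !is.na(.data$critical_coarse)) |>
    mutate(ratio = .data$critical_coarse / .data$critical_fine) |>
    arrange(.data$fine_id, .data$coarse_id, .data$sample_size)
  if (nrow(out) == 0L) {
    abort("No sample size at which both paired pathways reach significance.")
  }
  structure(out, class = c("profile_ratio", class(tibble())))
}

#' Median critical-subset ratio per pathway pair
#'
#' @param x A `profile_ratio` from [ratio_profiles()].
#' @return A tibble with one row per pair: `fine_id`, `coarse_id`,
#'   `n_points`, `median_ratio`.
#' @export
ratio_medians <- function(x) {
  stopifnot(inherits(x, "profile_ratio"))
  as_tibble(x) |>
    group_by(.data$fine_id, .data$coarse_id) |>
    summarise(
      n_points = dplyr::n(),
      median_ratio = median(.data$ratio),
      .groups = "drop"
    )
}

#' @method glance profile_ratio
#' @export
glance.profile_ratio <- function(x, ...) {
  med <- ratio_medians(x)
  tibble(
    n_pairs = nrow(med),
    n_points = nrow(x),
    median_ratio = median(x$ratio),
    median_of_pair_medians = median(med$median_ratio),
    prop_pairs_above_1 = mean(med$median_ratio > 1)
  )
}

#' Plot critical-subset profiles
#'
#' Critical subset size against sample size, one line per pathway
#' (unreachable grid points are dropped).
#'
#' @param object A `critical_profile` from [profile_database()].
#' @param max_pathways Cap on the number of pathways drawn.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot critical_profile
#' @export
autoplot.critical_profile <- function(object, max_pathways = 30, ...) {
  keep <- head(unique(object$pathway_id), max_pathways)
  d <- as_tibble(object) |>
    filter(.data$pathway_id %in% keep, !is.na(.data$critical_k))
  ggplot2::ggplot(d, ggplot2::aes(.data$sample_size, .data$critical_k,
                                  group = .data$pathway_id)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::labs(
      x = "sample size K (significant genes)",
      y = "critical subset size",
      title = sprintf("Critical subsets: %s", attr(object, "db_name"))
    ) +
    ggplot2::theme_minimal()
}
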