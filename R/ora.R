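#' Hypergeometric probability mass for an enrichment query
#'
#' Probability that exactly `k` of the `K` significant genes fall in a
#' pathway of size `n`, drawing without replacement from `N`
#' pathway-assigned genes:
#' \deqn{P(k) = \binom{K}{k}\binom{N-K}{n-k} / \binom{N}{n}.}
#' Computed in log space via `lchoose()` so that masses far below double
#' underflow on the linear scale are still exact to full relative precision.
#'
#' @param k Significant genes observed in the pathway.
#' @param K Total significant genes.
#' @param n Pathway size.
#' @param N Total pathway-assigned genes (the universe size).
#'
#' All four arguments are recycled to a common length.
#'
#' @return Numeric vector of probabilities in \[0, 1\].
#' @examples
#' hypergeom_pmf(k = 0, K = 2, n = 3, N = 6) # 4/20
#' @export
hypergeom_pmf <- function(k, K, n, N) {
  q <- validate_query(k, K, n, N)
  exp(lchoose(q$K, q$k) + lchoose(q$N - q$K, q$n - q$k) - lchoose(q$N, q$n))
}

validate_query <- function(k, K, n, N) {
  len <- max(length(k), length(K), length(n), length(N))
  k <- rep_len(k, len); K <- rep_len(K, len)
  n <- rep_len(n, len); N <- rep_len(N, len)
  for (v in list(k, K, n, N)) {
    if (!is_count(v)) abort("k, K, n, N must be non-negative integers.")
  }
  if (any(n > N) || any(K > N) || any(k > pmin(n, K))) {
    abort("Enrichment query out of range: need k <= min(n, K), n <= N, K <= N.")
  }
  if (any(N < 1)) abort("N must be at least 1.")
  list(k = k, K = K, n = n, N = N)
}

#' Upper-tail hypergeometric enrichment p-value
#'
#' The probability of observing `k` *or more* significant genes in the
#' pathway by chance:
#' \deqn{P(X \ge k) = \sum_{i=k}^{\min(n,K)} \binom{K}{i}\binom{N-K}{n-i} / \binom{N}{n}.}
#' The sum is accumulated from log-scale masses with the maximum factored
#' out, so values down to the smallest normal double retain at least six
#' significant figures. When `k` is at or below the lower support bound
#' `max(0, n + K - N)` the tail is exactly 1.
#'
#' @inheritParams hypergeom_pmf
#' @return Numeric vector of p-values in (0, 1].
#' @examples
#' # 3 significant genes, all in a 3-gene pathway, 1096 assigned genes:
#' enrichment_pvalue(k = 3, K = 3, n = 3, N = 1096)
#' @export
enrichment_pvalue <- function(k, K, n, N) {
  q <- validate_query(k, K, n, N)
  vapply(seq_along(q$k), function(j) {
    k <- q$k[j]; K <- q$K[j]; n <- q$n[j]; N <- q$N[j]
    if (k <= max(0L, n + K - N)) return(1)
    i <- k:min(n, K)
    min(1, sum_exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)))
  }, numeric(1))
}

#' Bonferroni correction
#'
#' Multiplies each p-value by the number of tests `m` (here, the number of
#' pathways in the annotation) and caps at 1 — the worst-case family-wise
#' correction.
#'
#' @param p Raw p-values in (0, 1].
#' @param m Number of tests (pathways), `m >= 1`.
#' @return Corrected p-values.
#' @export
bonferroni <- function(p, m) {
  assert_probability(p)
  if (!is_count(m) || any(m < 1)) abort("`m` must be a positive integer.")
  pmin(1, p * m)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up FDR adjustment of a vector of p-values (delegates to
#' [stats::p.adjust()]). The rank-1 adjusted value equals the Bonferroni
#' value `p * m` when that p-value is the unique minimum and no later step
#' undercuts it: BH always penalizes the smallest p-value by the full
#' multiplicity.
#'
#' @param p Raw p-values in (0, 1].
#' @return Adjusted p-values, each `>=` the raw value.
#' @export
bh_adjust <- function(p) {
  assert_probability(p)
  p.adjust(p, method = "BH")
}

#' Over-representation analysis of a gene set against a pathway database
#'
#' Tests every pathway for over-representation of `significant` genes using
#' the exact upper-tail hypergeometric statistic. Under the
#' pathway-assigned-universe convention (the default), `N` is the number of
#' genes assigned to at least one pathway and `K` counts only significant
#' genes inside that universe; significant genes outside the universe are
#' dropped with a warning.
#'
#' @param db A [pathway_db()].
#' @param significant Character vector of significant gene identifiers.
#' @param universe `"assigned"` (default; pathway-assigned genes) or
#'   `"declared"` (the database's declared universe).
#' @param m Multiplicity for the Bonferroni column; defaults to the number
#'   of pathways in `db`.
#'
#' @return An `ora_result` tibble, one row per pathway, sorted by `p_raw`,
#'   with columns `pathway_id`, `name`, `k`, `n`, `K`, `N`, `p_raw`,
#'   `p_bonferroni`, `p_bh` and attribute `m_used`.
#' @examples
#' db <- pathway_db(list(a = c("g1", "g2", "g3"), b = c("g4", "g5")))
#' enrich(db, c("g1", "g2"))
#' @export
enrich <- function(db, significant, universe = c("assigned", "declared"), m = NULL) {
  stopifnot(inherits(db, "pathway_db"))
  universe <- match.arg(universe)
  uni <- if (universe == "assigned") assigned_genes(db) else db_universe(db)
  significant <- unique(as.character(significant))
  inside <- intersect(significant, uni)
  dropped <- length(significant) - length(inside)
  if (length(inside) == 0L) {
    abort("No significant gene lies in the universe; nothing to test.")
  }
  if (dropped > 0L) {
    warn(sprintf(
      "%d significant gene(s) outside the %s universe dropped; K reduced to %d.",
      dropped, universe, length(inside)
    ))
  }
  N <- length(uni)
  K <- length(inside)
  m_used <- m %||% nrow(db)
  res <- tibble(
    pathway_id = db$pathway_id,
    name = db$name,
    k = vapply(db$genes, function(g) length(intersect(g, inside)), integer(1)),
    n = lengths(db$genes),
    K = K,
    N = N
  )
  res$p_raw <- enrichment_pvalue(res$k, res$K, res$n, res$N)
  res$p_bonferroni <- bonferroni(res$p_raw, m_used)
  res$p_bh <- bh_adjust(res$p_raw)
  res <- arrange(res, .data$p_raw, .data$pathway_id)
  structure(
    res,
    class = c("ora_result", class(tibble())),
    db_name = attr(db, "db_name"),
    m_used = m_used
  )
}

#' @method tidy ora_result
#' @export
tidy.ora_result <- function(x, ...) as_tibble(unclass_result(x))

#' @method glance ora_result
#' @export
glance.ora_result <- function(x, alpha = 0.05, ...) {
  tibble(
    db = attr(x, "db_name") %||% NA_character_,
    n_pathways = nrow(x),
    m_used = attr(x, "m_used"),
    K = x$K[1L],
    N = x$N[1L],
    sig_raw = sum(x$p_raw <= alpha),
    sig_bonferroni = sum(x$p_bonferroni <= alpha),
    sig_bh = sum(x$p_bh <= alpha)
  )
}

unclass_result <- function(x) {
  class(x) <- class(tibble())
  x
}

#' Plot an ORA result
#'
#' Dot plot of the most enriched pathways on the -log10 scale, raw and
#' Bonferroni-corrected.
#'
#' @param object An `ora_result` from [enrich()].
#' @param top Number of top pathways to display.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ora_result
#' @export
autoplot.ora_result <- function(object, top = 20, ...) {
  d <- head(as_tibble(unclass_result(object)), top)
  d <- tidyr::pivot_longer(
    d, c("p_raw", "p_bonferroni"),
    names_to = "statistic", values_to = "p"
  )
  d$pathway_id <- factor(d$pathway_id, levels = rev(unique(d$pathway_id)))
  ggplot2::ggplot(d, ggplot2::aes(-log10(.data$p), .data$pathway_id,
                                  colour = .data$statistic)) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = expression(-log[10] ~ p), y = NULL,
      title = sprintf("Over-representation: %s", attr(object, "db_name") %||% "")
    ) +
    ggplot2::theme_minimal()
}
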