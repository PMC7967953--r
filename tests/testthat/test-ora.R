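test_that("pmf matches exact rational values and normalizes", {
  expect_identical(hypergeom_pmf(1, 1, 1, 1), 1)
  # C(2,0) C(4,3) / C(6,3) = 4/20
  expect_equal(hypergeom_pmf(0, 2, 3, 6), 0.2, tolerance = 1e-12)
  k <- 0:5
  expect_equal(sum(hypergeom_pmf(k, 5, 7, 20)), 1, tolerance = 1e-12)
  expect_error(hypergeom_pmf(4, 3, 5, 10), "out of range")
})

test_that("tail p-value agrees with exhaustive subset enumeration", {
  # every significant-gene subset enumerated; fraction touching the pathway
  expect_equal(enrichment_pvalue(1, 2, 3, 6), enum_tail_pvalue(1, 2, 3, 6))
  expect_equal(enum_tail_pvalue(1, 2, 3, 6), 0.8) # 12 of the 15 pairs
  for (tuple in list(c(2, 3, 4, 9), c(1, 4, 4, 8), c(3, 5, 6, 11))) {
    expect_equal(
      enrichment_pvalue(tuple[1], tuple[2], tuple[3], tuple[4]),
      enum_tail_pvalue(tuple[1], tuple[2], tuple[3], tuple[4]),
      tolerance = 1e-12
    )
  }
})

test_that("tail reproduces published single-pathway values", {
  expect_equal(signif(enrichment_pvalue(3, 3, 3, 1096), 2), 4.6e-9)
  expect_equal(signif(enrichment_pvalue(1, 1, 34, 1686), 2), 2.0e-2)
})

test_that("P(X >= 0) is exactly one and the tail is monotone in k", {
  expect_identical(enrichment_pvalue(0, 5, 7, 20), 1)
  # k at the lower support bound: tail still exactly 1
  expect_identical(enrichment_pvalue(2, 9, 3, 10), 1)
  p <- enrichment_pvalue(0:5, 5, 7, 20)
  expect_true(all(diff(p) < 0))
})

test_that("K = k closed form holds to ten significant figures", {
  # falling-factorial ratio n!/(n-k)! / (N!/(N-k)!)
  ff <- function(a, k) prod(a - seq_len(k) + 1)
  for (case in list(c(3, 3, 1096), c(5, 13, 1686), c(10, 10, 1096))) {
    k <- case[1]; n <- case[2]; N <- case[3]
    expect_equal(
      enrichment_pvalue(k, k, n, N),
      ff(n, k) / ff(N, k),
      tolerance = 1e-10
    )
  }
})

test_that("log-space tail matches phyper to 6+ significant figures down to 1e-40", {
  cases <- list(
    c(13, 13, 13, 1096),  # ~2e-30
    c(25, 30, 40, 3000),  # deep tail
    c(10, 10, 78, 1686),
    c(40, 60, 45, 5000)   # ~1e-40 scale
  )
  for (q in cases) {
    mine <- enrichment_pvalue(q[1], q[2], q[3], q[4])
    ref <- stats::phyper(q[1] - 1, q[2], q[4] - q[2], q[3], lower.tail = FALSE)
    expect_equal(mine, ref, tolerance = 1e-7)
  }
})

test_that("universe growth sharpens the p-value in the K = k regime", {
  Ns <- c(200L, 500L, 1096L, 1686L, 4000L)
  p <- enrichment_pvalue(3, 3, 34, Ns)
  expect_true(all(diff(p) < 0))
})

test_that("pathway-size monotonicity holds on randomized tuples", {
  withr::local_seed(421)
  for (i in 1:500) {
    N <- rint(20L, 2000L)
    k <- rint(1L, 10L)
    n1 <- rint(k, N - 2L)
    n2 <- rint(n1 + 1L, N - 1L)
    # keep the larger pathway off its support bound so tails are < 1
    K_max <- N - n2 + k - 1L
    if (K_max < k) next
    K <- rint(k, min(K_max, N))
    expect_true(smaller_pathway_wins(k, K, n1, n2, N))
  }
})

test_that("bonferroni multiplies and caps", {
  expect_equal(signif(bonferroni(enrichment_pvalue(3, 3, 3, 1096), 354), 2), 1.6e-6)
  expect_identical(bonferroni(enrichment_pvalue(1, 1, 34, 1686), 119), 1)
  expect_identical(bonferroni(1, 5), 1)
})

test_that("BH adjustment is the standard step-up", {
  expect_equal(bh_adjust(0.02), 0.02)
  # hand step-up: 0.03*3/3, 0.02*3/2, 0.01*3/1 then cummin from the top
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  # rank-1 penalty equals the full multiplicity when the rest are large
  p <- c(1e-6, 0.5, 0.6, 0.7, 0.8)
  expect_equal(bh_adjust(p)[1], 1e-6 * 5)
})

test_that("enrich() reproduces the published cell and orders corrections", {
  db <- ecocyc_scale_db()
  res <- enrich(db, c("g0001", "g0002", "g0003"), m = 354)
  expect_equal(db_summary(db)$n_assigned_genes, 1096L)
  row <- res[res$pathway_id == "target", ]
  expect_equal(row$k, 3L)
  expect_equal(row$K, 3L)
  expect_equal(signif(row$p_raw, 2), 4.6e-9)
  expect_equal(signif(row$p_bonferroni, 2), 1.6e-6)
  expect_true(all(res$p_raw <= res$p_bh + 1e-15))
  expect_true(all(res$p_bh <= res$p_bonferroni + 1e-15))
})

test_that("enrich() handles disjoint pathways, stray genes, and empty input", {
  db <- toy_db()
  res <- enrich(db, c("g1", "g2"))
  pwB <- res[res$pathway_id == "pwB", ]
  expect_equal(pwB$k, 0L)
  expect_identical(pwB$p_raw, 1)

  expect_warning(res2 <- enrich(db, c("g1", "not-a-gene")), "dropped")
  expect_equal(res2$K[1], 1L)
  expect_error(
    suppressWarnings(enrich(db, "not-a-gene")),
    "No significant gene"
  )
})

test_that("enrich() equals exhaustive enumeration on a tiny database", {
  db <- pathway_db(
    list(p1 = c("g1", "g2", "g3"), p2 = c("g4", "g5", "g6")),
    name = "tiny"
  )
  sig <- c("g1", "g4")
  res <- enrich(db, sig)
  # pathway p1 occupies genes 1..3 of the 6-gene universe; overlap 1, K = 2
  expect_equal(
    res$p_raw[res$pathway_id == "p1"],
    enum_tail_pvalue(1, 2, 3, 6),
    tolerance = 1e-12
  )
  expect_equal(
    res$p_raw[res$pathway_id == "p2"],
    enum_tail_pvalue(1, 2, 3, 6),
    tolerance = 1e-12
  )
})

test_that("ora_result supports tidy, glance and autoplot", {
  res <- enrich(toy_db(), c("g1", "g3"))
  expect_s3_class(tidy(res), "tbl_df")
  g <- glance(res)
  expect_equal(g$n_pathways, 2L)
  expect_s3_class(autoplot(res), "ggplot")
})
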