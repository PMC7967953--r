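test_that("generation is deterministic given the seed", {
  s <- synthetic_scenario(n_fine_pathways = 25)
  a <- generate_fine_db(s, seed = 9)
  b <- generate_fine_db(s, seed = 9)
  expect_identical(tibble::as_tibble(a), tibble::as_tibble(b))
  c <- generate_fine_db(s, seed = 10)
  expect_false(identical(tibble::as_tibble(a), tibble::as_tibble(c)))
})

test_that("zero overlap noise yields pairwise-disjoint pathways", {
  db <- generate_fine_db(synthetic_scenario(n_fine_pathways = 50), seed = 2)
  all_genes <- unlist(db$genes)
  expect_false(any(duplicated(all_genes)))
  expect_equal(db_summary(db)$n_assigned_genes, sum(lengths(db$genes)))
})

test_that("a tight universe forces sharing and respects N <= universe", {
  s <- synthetic_scenario(n_fine_pathways = 354, universe_size = 1096,
                          overlap_noise = 0.7)
  db <- generate_fine_db(s, seed = 3)
  expect_lte(db_summary(db)$n_assigned_genes, 1096L)
  expect_equal(db_summary(db)$m, 354L)
  # the same universe without sharing cannot pack 354 pathways of size >= 3
  expect_error(
    generate_fine_db(
      synthetic_scenario(n_fine_pathways = 354, universe_size = 1096),
      seed = 3
    ),
    "Infeasible packing"
  )
})

test_that("coarsening with factor one reproduces the fine gene sets", {
  fine <- generate_fine_db(synthetic_scenario(n_fine_pathways = 12), seed = 4)
  coarse <- coarsen_db(fine, grouping_factor = 1, seed = 5)
  expect_equal(nrow(coarse), nrow(fine))
  mapping <- attr(coarse, "mapping")
  for (i in seq_len(nrow(mapping))) {
    f <- fine$genes[[match(mapping$fine_id[i], fine$pathway_id)]]
    c <- coarse$genes[[match(mapping$coarse_id[i], coarse$pathway_id)]]
    expect_setequal(f, c)
  }
})

test_that("full grouping produces a single mosaic of all processes", {
  fine <- generate_fine_db(synthetic_scenario(n_fine_pathways = 21), seed = 6)
  coarse <- coarsen_db(fine, grouping_factor = 21, seed = 7)
  expect_equal(nrow(coarse), 1L)
  expect_setequal(coarse$genes[[1]], assigned_genes(fine))
})

test_that("coarse gene sets are exactly the unions of their members", {
  fine <- generate_fine_db(
    synthetic_scenario(n_fine_pathways = 30, overlap_noise = 0.3,
                       universe_size = 250),
    seed = 8
  )
  coarse <- coarsen_db(fine, grouping_factor = 3, seed = 9)
  mapping <- attr(coarse, "mapping")
  for (cid in coarse$pathway_id) {
    members <- mapping$fine_id[mapping$coarse_id == cid]
    expected <- unique(unlist(fine$genes[match(members, fine$pathway_id)]))
    got <- coarse$genes[[match(cid, coarse$pathway_id)]]
    expect_setequal(got, expected)
  }
})

test_that("the mean-size ratio recovers the grouping factor within 10%", {
  for (g in c(2, 3.5)) {
    fine <- generate_fine_db(synthetic_scenario(n_fine_pathways = 280), seed = 13)
    coarse <- coarsen_db(fine, grouping_factor = g, seed = 14)
    ratio <- mean(lengths(coarse$genes)) / mean(lengths(fine$genes))
    expect_lt(abs(ratio - g) / g, 0.1)
  }
})

test_that("perturbed-pathway sampling builds the expected significant set", {
  db <- generate_fine_db(synthetic_scenario(n_fine_pathways = 20), seed = 15)
  target <- db$pathway_id[5]
  sig <- sample_significant_genes(db, target, within_fraction = 1,
                                  background_count = 0, seed = 16)
  expect_setequal(sig, db$genes[[5]])
  res <- enrich(db, sig)
  expect_equal(res$pathway_id[1], target) # minimum p in the database

  expect_error(
    sample_significant_genes(db, character(0), within_fraction = 0,
                             background_count = 0),
    "empty"
  )
  with_bg <- sample_significant_genes(db, target, within_fraction = 0.5,
                                      background_count = 10, seed = 17)
  expect_equal(length(with_bg),
               ceiling(0.5 * length(db$genes[[5]])) + 10)
})

test_that("mosaic dilution: contained fine pathway always beats its mosaic", {
  fine <- generate_fine_db(synthetic_scenario(n_fine_pathways = 40), seed = 18)
  coarse <- coarsen_db(fine, grouping_factor = 4, seed = 19)
  mapping <- attr(coarse, "mapping")
  # equal universes: run both enrichments against the shared declared universe
  for (rep in 1:5) {
    target <- fine$pathway_id[rep * 7]
    # background-free sampling keeps k equal on both sides, the regime the
    # size-monotonicity corollary covers
    sig <- sample_significant_genes(fine, target, within_fraction = 0.6,
                                    background_count = 0, seed = 20 + rep)
    its_coarse <- mapping$coarse_id[mapping$fine_id == target]
    pf <- enrich(fine, sig, universe = "declared")
    pc <- enrich(coarse, sig, universe = "declared")
    expect_lte(
      pf$p_raw[pf$pathway_id == target],
      pc$p_raw[pc$pathway_id == its_coarse]
    )
  }
})

test_that("mosaic false-positive sets touch each member process once", {
  fine <- generate_fine_db(synthetic_scenario(n_fine_pathways = 16), seed = 21)
  coarse <- coarsen_db(fine, grouping_factor = 4, seed = 22)
  mapping <- attr(coarse, "mapping")
  cid <- coarse$pathway_id[1]
  sig <- mosaic_gene_set(fine, mapping, cid, genes_per_fine = 1, seed = 23)
  members <- mapping$fine_id[mapping$coarse_id == cid]
  expect_equal(length(sig), length(members))
  per_fine <- vapply(
    fine$genes[match(members, fine$pathway_id)],
    function(g) length(intersect(g, sig)), integer(1)
  )
  expect_true(all(per_fine == 1L))
})

test_that("scenario validation rejects impossible settings", {
  expect_error(synthetic_scenario(overlap_noise = 1), "overlap_noise")
  expect_error(synthetic_scenario(grouping_factor = 0.5), "grouping_factor")
  expect_error(synthetic_scenario(size_min = 5, size_max = 3), "size_min")
})
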