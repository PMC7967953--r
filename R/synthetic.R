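#' Define a dual-granularity synthetic annotation scenario
#'
#' Describes how to build a fine-grained pathway database (many small,
#' mostly disjoint pathways, EcoCyc-like) whose coarse counterpart is then
#' produced by [coarsen_db()] as unions of fine pathways (KEGG-map-like
#' mosaic pathways). Defaults mirror the published scale of the fine
#' annotation: 354 pathways with sizes uniform on 3..13, grouped about 3.5
#' fine pathways per coarse pathway so the coarse/fine mean-size ratio is
#' about 3.5.
#'
#' With `universe_size = NULL` the universe is exactly the genes the
#' generator assigns, so at `overlap_noise = 0` the fine pathways tile the
#' universe disjointly (the configuration used for ground-truth recovery
#' tests). A smaller explicit universe forces gene re-use across pathways
#' and requires `overlap_noise > 0` to be feasible; real annotations
#' (e.g. 1096 genes shared across 354 pathways) are of this kind.
#'
#' @param n_fine_pathways Number of fine pathways.
#' @param size_min,size_max Fine pathway sizes are drawn uniformly from
#'   `size_min:size_max`.
#' @param grouping_factor Average number of fine pathways merged into one
#'   coarse pathway (may be fractional; groups alternate between the two
#'   nearest integers).
#' @param universe_size Optional explicit universe size; `NULL` means
#'   "exactly the assigned genes".
#' @param overlap_noise Fraction of each pathway's genes drawn from genes
#'   already assigned to earlier pathways (cross-pathway sharing), in
#'   \[0, 1).
#' @return A `synthetic_scenario` list.
#' @export
synthetic_scenario <- function(n_fine_pathways = 354L, size_min = 3L,
                               size_max = 13L, grouping_factor = 3.5,
                               universe_size = NULL, overlap_noise = 0) {
  if (!is_count(n_fine_pathways) || n_fine_pathways < 1) {
    abort("`n_fine_pathways` must be a positive integer.")
  }
  if (!is_count(size_min) || !is_count(size_max) ||
      size_min < 1 || size_max < size_min) {
    abort("Need 1 <= size_min <= size_max.")
  }
  if (!is.numeric(grouping_factor) || grouping_factor < 1 ||
      grouping_factor > n_fine_pathways) {
    abort("`grouping_factor` must lie in [1, n_fine_pathways].")
  }
  if (!is.numeric(overlap_noise) || overlap_noise < 0 || overlap_noise >= 1) {
    abort("`overlap_noise` must lie in [0, 1).")
  }
  if (!is.null(universe_size) && !is_count(universe_size)) {
    abort("`universe_size` must be NULL or a non-negative integer.")
  }
  structure(
    list(
      n_fine_pathways = as.integer(n_fine_pathways),
      size_min = as.integer(size_min),
      size_max = as.integer(size_max),
      grouping_factor = grouping_factor,
      universe_size = universe_size,
      overlap_noise = overlap_noise
    ),
    class = "synthetic_scenario"
  )
}

#' Generate a fine-grained synthetic pathway database
#'
#' Draws pathway sizes uniformly from the scenario's size range and
#' assigns genes mostly disjointly: for each pathway a fraction
#' `overlap_noise` of its genes is re-drawn from genes already assigned to
#' earlier pathways, the remainder from never-assigned genes. Generation is
#' deterministic given `seed` and touches no global RNG state after
#' returning.
#'
#' @param scenario A [synthetic_scenario()].
#' @param seed Integer seed.
#' @return A [pathway_db()] named `"synthetic_fine"`, with pathway ids
#'   `F001, F002, ...` and a declared universe.
#' @examples
#' db <- generate_fine_db(synthetic_scenario(n_fine_pathways = 10), seed = 1)
#' db_summary(db)
#' @export
generate_fine_db <- function(scenario, seed = 1L) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  withr::local_seed(seed)
  s <- scenario
  sizes <- sample(s$size_min:s$size_max, s$n_fine_pathways, replace = TRUE)
  # worst case every gene is fresh; cap the pool at the declared universe
  pool_n <- s$universe_size %||% sum(sizes)
  pool <- sprintf("g%05d", seq_len(pool_n))
  unused <- sample(pool)
  used <- character(0)
  genes <- vector("list", s$n_fine_pathways)
  for (i in seq_along(genes)) {
    n_shared <- min(floor(sizes[i] * s$overlap_noise), length(used))
    n_fresh <- sizes[i] - n_shared
    if (n_fresh > length(unused)) {
      abort(sprintf(
        paste0(
          "Infeasible packing: pathway %d needs %d fresh genes but only %d ",
          "remain in a universe of %d; increase universe_size or overlap_noise."
        ),
        i, n_fresh, length(unused), pool_n
      ))
    }
    shared <- if (n_shared > 0L) sample(used, n_shared) else character(0)
    fresh <- unused[seq_len(n_fresh)]
    unused <- unused[-seq_len(n_fresh)]
    used <- c(used, fresh)
    genes[[i]] <- c(fresh, shared)
  }
  ids <- sprintf("F%03d", seq_along(genes))
  pathway_db(
    tibble(pathway_id = ids, name = paste("fine pathway", ids), genes = genes),
    name = "synthetic_fine",
    universe = if (is.null(s$universe_size)) sort(used) else pool
  )
}

#' Coarsen a fine database into mosaic pathways
#'
#' Builds a coarse annotation of the same gene universe by merging random
#' disjoint groups of fine pathways into single "mosaic" pathways — the
#' structure of large KEGG-style maps, where one entry unions many distinct
#' biological processes. The fine-to-coarse containment is retained as
#' ground truth in the `"mapping"` attribute.
#'
#' @param fine A fine [pathway_db()].
#' @param grouping_factor Average fine pathways per coarse pathway;
#'   fractional values alternate the two nearest integer group sizes
#'   (`1` reproduces the fine gene sets unchanged).
#' @param seed Integer seed for the random grouping.
#' @return A [pathway_db()] named `"synthetic_coarse"` with ids
#'   `C001, ...`; `attr(, "mapping")` is a tibble `fine_id` -> `coarse_id`.
#' @export
coarsen_db <- function(fine, grouping_factor = 3.5, seed = 1L) {
  stopifnot(inherits(fine, "pathway_db"))
  n_fine <- nrow(fine)
  if (!is.numeric(grouping_factor) || grouping_factor < 1 ||
      grouping_factor > n_fine) {
    abort("`grouping_factor` must lie in [1, number of fine pathways].")
  }
  withr::local_seed(seed)
  perm <- sample(n_fine)
  # Bresenham-style group sizes: cumulative targets i * g, so sizes
  # alternate floor(g)/ceiling(g) and average to g
  n_groups <- ceiling(n_fine / grouping_factor)
  bounds <- pmin(round(seq_len(n_groups) * grouping_factor), n_fine)
  bounds[n_groups] <- n_fine
  group_sizes <- diff(c(0, bounds))
  group <- rep(seq_len(n_groups), times = group_sizes)
  mapping <- tibble(
    fine_id = fine$pathway_id[perm],
    coarse_id = sprintf("C%03d", group)
  )
  members <- split(fine$genes[perm], mapping$coarse_id)
  coarse_ids <- names(members)
  coarse_genes <- lapply(members, function(gs) sort(unique(unlist(gs))))
  db <- pathway_db(
    tibble(
      pathway_id = coarse_ids,
      name = paste("coarse pathway", coarse_ids),
      genes = unname(coarse_genes)
    ),
    name = "synthetic_coarse",
    universe = db_universe(fine)
  )
  attr(db, "mapping") <- arrange(mapping, .data$fine_id)
  db
}

#' Sample a significant-gene set from perturbed pathways
#'
#' Emulates the input to over-representation analysis: a perturbation
#' concentrates significance in chosen pathways (a fraction of each
#' perturbed pathway's genes is declared significant), plus background
#' significant genes drawn uniformly from the rest of the universe.
#' Deterministic given `seed`.
#'
#' @param db A [pathway_db()].
#' @param perturbed_ids Pathway ids to perturb (may be empty).
#' @param within_fraction Fraction of each perturbed pathway's genes that
#'   are significant, in \[0, 1\] (rounded up per pathway).
#' @param background_count Significant genes drawn uniformly from universe
#'   genes outside all perturbed pathways.
#' @param seed Integer seed.
#' @return Character vector of significant gene identifiers.
#' @export
sample_significant_genes <- function(db, perturbed_ids, within_fraction = 1,
                                     background_count = 0L, seed = 1L) {
  stopifnot(inherits(db, "pathway_db"))
  if (!is.numeric(within_fraction) || within_fraction < 0 || within_fraction > 1) {
    abort("`within_fraction` must lie in [0, 1].")
  }
  if (!is_count(background_count)) {
    abort("`background_count` must be a non-negative integer.")
  }
  missing <- setdiff(perturbed_ids, db$pathway_id)
  if (length(missing) > 0L) {
    abort(sprintf("Unknown pathway id(s): %s.", paste(missing, collapse = ", ")))
  }
  withr::local_seed(seed)
  idx <- match(perturbed_ids, db$pathway_id)
  within <- unlist(lapply(idx, function(i) {
    g <- db$genes[[i]]
    take <- ceiling(within_fraction * length(g))
    if (take == 0L) character(0) else sample(g, take)
  }))
  pool <- setdiff(db_universe(db), unlist(db$genes[idx]))
  if (background_count > length(pool)) {
    abort(sprintf(
      "background_count = %d exceeds the %d universe genes outside the perturbed pathways.",
      background_count, length(pool)
    ))
  }
  background <- if (background_count > 0L) sample(pool, background_count) else character(0)
  out <- unique(c(within, background))
  if (length(out) == 0L) {
    abort("The sampled significant-gene set is empty; raise within_fraction or background_count.")
  }
  sort(out)
}

#' Construct a mosaic false-positive gene set
#'
#' Picks a few genes from *each* fine pathway inside one coarse mosaic
#' pathway. No single fine process is strongly perturbed, yet the mosaic
#' pathway accumulates all the hits — the scenario in which a coarse
#' annotation calls enrichment while the fine annotation (correctly) does
#' not.
#'
#' @param fine A fine [pathway_db()].
#' @param mapping Ground-truth containment tibble (`fine_id`, `coarse_id`),
#'   e.g. `attr(coarsen_db(fine), "mapping")`.
#' @param coarse_id The mosaic pathway to target.
#' @param genes_per_fine Genes sampled from each member fine pathway.
#' @param seed Integer seed.
#' @return Character vector of significant gene identifiers.
#' @export
mosaic_gene_set <- function(fine, mapping, coarse_id, genes_per_fine = 1L,
                            seed = 1L) {
  stopifnot(inherits(fine, "pathway_db"))
  mapping <- as_tibble(mapping)
  members <- mapping$fine_id[mapping$coarse_id == coarse_id]
  if (length(members) == 0L) {
    abort(sprintf("No fine pathway maps to coarse id '%s'.", coarse_id))
  }
  withr::local_seed(seed)
  idx <- match(members, fine$pathway_id)
  sort(unique(unlist(lapply(idx, function(i) {
    g <- fine$genes[[i]]
    sample(g, min(genes_per_fine, length(g)))
  }))))
}
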