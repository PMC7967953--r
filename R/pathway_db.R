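#' Construct a pathway database
#'
#' A `pathway_db` is a tibble with one row per pathway and columns
#' `pathway_id` (unique identifier), `name` (free-text description) and
#' `genes` (list-column of character vectors, the member gene identifiers).
#' Gene identifiers are treated as opaque, case-sensitive strings; an
#' optional normalizer (trim whitespace, uppercase) is off by default.
#'
#' The gene universe is the reference set against which enrichment draws are
#' modeled. By convention it defaults to the genes assigned to at least one
#' pathway (the union of all gene sets, size `N`); a larger user-declared
#' universe may be supplied, in which case every pathway must be a subset of
#' it.
#'
#' @param x A tibble/data.frame with columns `pathway_id`, `name`, `genes`
#'   (list of character vectors), or a named list of character gene vectors
#'   (names become pathway ids).
#' @param name Label for the database (e.g. `"EcoCyc"`).
#' @param universe Optional character vector declaring the gene universe.
#'   Defaults to the union of all pathway gene sets.
#' @param normalize If `TRUE`, trim whitespace and uppercase all gene
#'   identifiers (including the universe).
#'
#' @return A `pathway_db` tibble with attributes `db_name` and `universe`.
#' @examples
#' db <- pathway_db(list(pw1 = c("a", "b"), pw2 = c("b", "c")), name = "toy")
#' db_summary(db)
#' @export
pathway_db <- function(x, name = "db", universe = NULL, normalize = FALSE) {
  if (is.list(x) && !is.data.frame(x)) {
    if (is.null(names(x)) || any(names(x) == "")) {
      abort("When `x` is a list, every element must be named by pathway id.")
    }
    x <- tibble(
      pathway_id = names(x),
      name = names(x),
      genes = unname(lapply(x, as.character))
    )
  }
  x <- as_tibble(x)
  required <- c("pathway_id", "name", "genes")
  missing <- setdiff(required, names(x))
  if (length(missing) > 0L) {
    abort(sprintf("`x` lacks column(s): %s.", paste(missing, collapse = ", ")))
  }
  x <- x[required]
  x$pathway_id <- as.character(x$pathway_id)
  x$name <- as.character(x$name)
  if (normalize) {
    x$genes <- lapply(x$genes, function(g) toupper(trimws(g)))
    if (!is.null(universe)) universe <- toupper(trimws(universe))
  }
  dup_within <- vapply(x$genes, anyDuplicated, integer(1)) > 0L
  if (any(dup_within)) {
    warn(sprintf(
      "Duplicate gene identifiers within pathway(s) %s; deduplicated.",
      paste(x$pathway_id[dup_within], collapse = ", ")
    ))
    x$genes <- lapply(x$genes, unique)
  }
  out <- structure(
    x,
    class = c("pathway_db", class(tibble())),
    db_name = name,
    universe = if (is.null(universe)) NULL else sort(unique(as.character(universe)))
  )
  validate_pathway_db(out)
}

validate_pathway_db <- function(db) {
  if (nrow(db) == 0L) abort("A pathway database must contain at least one pathway.")
  dup <- unique(db$pathway_id[duplicated(db$pathway_id)])
  if (length(dup) > 0L) {
    abort(sprintf("Duplicate pathway id(s): %s.", paste(dup, collapse = ", ")))
  }
  sizes <- lengths(db$genes)
  if (any(sizes == 0L)) {
    abort(sprintf(
      "Empty gene set for pathway(s): %s.",
      paste(db$pathway_id[sizes == 0L], collapse = ", ")
    ))
  }
  uni <- attr(db, "universe")
  if (!is.null(uni)) {
    if (length(uni) == 0L) abort("Declared universe is empty but pathways are not.")
    stray <- setdiff(unique(unlist(db$genes)), uni)
    if (length(stray) > 0L) {
      abort(sprintf(
        "%d pathway gene(s) are absent from the declared universe (e.g. %s).",
        length(stray), paste(head(stray, 3L), collapse = ", ")
      ))
    }
  }
  db
}

#' @export
print.pathway_db <- function(x, ...) {
  s <- db_summary(x)
  cat(sprintf(
    "<pathway_db '%s'> %d pathways, %d assigned genes (universe %d)\n",
    attr(x, "db_name"), s$m, s$n_assigned_genes, s$universe_size
  ))
  NextMethod()
}

#' Genes assigned to at least one pathway
#'
#' @param db A [pathway_db()].
#' @return Sorted character vector; its length is the enrichment total `N`
#'   under the pathway-assigned-universe convention.
#' @export
assigned_genes <- function(db) {
  stopifnot(inherits(db, "pathway_db"))
  sort(unique(unlist(db$genes)))
}

#' The gene universe of a database
#'
#' The declared universe if one was given, otherwise the pathway-assigned
#' genes.
#' @inheritParams assigned_genes
#' @return Character vector of gene identifiers.
#' @export
db_universe <- function(db) {
  attr(db, "universe") %||% assigned_genes(db)
}

#' Summarize a pathway database annotation
#'
#' Reports the pathway count `m` (the multiplicity used for multiple-testing
#' correction), the number of pathway-assigned genes `N`, the declared
#' universe size, and the pathway-size distribution.
#'
#' @inheritParams assigned_genes
#' @return A one-row tibble with columns `db`, `m`, `n_assigned_genes`,
#'   `universe_size`, `size_min`, `size_median`, `size_mean`, `size_max`.
#' @examples
#' pathway_db(list(a = c("g1", "g2"), b = c("g2", "g3"))) |> db_summary()
#' @export
db_summary <- function(db) {
  stopifnot(inherits(db, "pathway_db"))
  sizes <- lengths(db$genes)
  # everything computed up front: inside tibble() the first column (`db`)
  # would shadow the database argument for later columns
  label <- attr(db, "db_name")
  m <- nrow(db)
  n_assigned <- length(assigned_genes(db))
  universe_n <- length(db_universe(db))
  tibble(
    db = label,
    m = m,
    n_assigned_genes = n_assigned,
    universe_size = universe_n,
    size_min = min(sizes),
    size_median = median(sizes),
    size_mean = mean(sizes),
    size_max = max(sizes)
  )
}

#' Per-pathway sizes
#'
#' @inheritParams assigned_genes
#' @return A tibble with columns `pathway_id`, `name`, `n`.
#' @export
pathway_sizes <- function(db) {
  stopifnot(inherits(db, "pathway_db"))
  tibble(pathway_id = db$pathway_id, name = db$name, n = lengths(db$genes))
}

#' @method tidy pathway_db
#' @export
tidy.pathway_db <- function(x, ...) pathway_sizes(x)

#' @method glance pathway_db
#' @export
glance.pathway_db <- function(x, ...) db_summary(x)

#' Read a GMT gene-set file
#'
#' Standard GMT: one pathway per line, tab-separated fields
#' `id`, `description`, then one or more gene identifiers. The second column
#' is never parsed as a gene. Duplicate genes within a line are deduplicated
#' with a warning.
#'
#' @param path Path to a GMT file.
#' @param name Database label; defaults to the file name.
#' @inheritParams pathway_db
#' @return A [pathway_db()].
#' @export
read_gmt <- function(path, name = NULL, universe = NULL, normalize = FALSE) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) abort(sprintf("GMT file is empty: %s", path))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad) > 0L) {
    abort(sprintf(
      "Malformed GMT line %d in %s: fewer than 3 tab-separated fields.",
      bad[1L], path
    ))
  }
  pathway_db(
    tibble(
      pathway_id = vapply(fields, `[[`, character(1), 1L),
      name = vapply(fields, `[[`, character(1), 2L),
      genes = lapply(fields, function(f) f[-(1:2)])
    ),
    name = name %||% basename(path),
    universe = universe,
    normalize = normalize
  )
}

#' Write a pathway database to GMT
#'
#' @inheritParams assigned_genes
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(db, path) {
  stopifnot(inherits(db, "pathway_db"))
  lines <- vapply(
    seq_len(nrow(db)),
    function(i) paste(c(db$pathway_id[i], db$name[i], db$genes[[i]]), collapse = "\t"),
    character(1)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a plain-text gene list
#'
#' One identifier per line; blank lines and `#` comments are ignored;
#' duplicates are removed. The returned set is order-insensitive (sorted).
#'
#' @param path Path to the list file.
#' @param normalize If `TRUE`, trim and uppercase identifiers.
#' @return Character vector of unique gene identifiers.
#' @export
read_gene_list <- function(path, normalize = FALSE) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    abort(sprintf("Gene list %s contains no identifiers.", path))
  }
  if (normalize) lines <- toupper(lines)
  sort(unique(lines))
}
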