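#' Best-hit ortholog identity statistics
#'
#' For every query protein, the best percent identity over the target set is
#' computed with [pairwise_identity()]; the summary reports the range and the
#' unweighted arithmetic mean, both at full precision and rounded to the
#' nearest integer percent (the convention used when ortholog conservation
#' is quoted, e.g. "94-99% identity, mean 98%").
#'
#' @param queries,targets Non-empty protein-record tibbles.
#' @return An object of class `ortholog_stats`: `per_query` (tibble `id`,
#'   `best_target`, `identity`), `min`, `max`, `mean`, `mean_rounded`.
#' @export
ortholog_stats <- function(queries, targets) {
  validate_protein_records(queries, "queries")
  validate_protein_records(targets, "targets")
  if (nrow(queries) == 0 || nrow(targets) == 0) {
    abort("`queries` and `targets` must be non-empty.")
  }
  per_query <- purrr::map_dfr(seq_len(nrow(queries)), function(i) {
    ids <- vapply(targets$sequence, function(t) {
      pairwise_identity(queries$sequence[i], t)
    }, 0)
    best <- which.max(ids)
    tibble(id = queries$id[i], best_target = targets$id[best],
           identity = ids[[best]])
  })
  structure(
    list(per_query = per_query,
         min = min(per_query$identity), max = max(per_query$identity),
         mean = mean(per_query$identity),
         mean_rounded = as.integer(round(mean(per_query$identity)))),
    class = "ortholog_stats"
  )
}

#' @export
print.ortholog_stats <- function(x, ...) {
  cat("<ortholog statistics>\n")
  cat(sprintf("  %d queries; best-hit identity %.0f-%.0f%% (mean %d%%)\n",
              nrow(x$per_query), x$min, x$max, x$mean_rounded))
  invisible(x)
}

#' Repertoire summary and between-species comparisons
#'
#' Summarises a species-by-family count matrix: per-family counts and
#' presence per species, per-family totals, and — for requested species
#' pairs — the relative repertoire difference `100 * (a - b) / b` rounded to
#' the nearest integer percent (so 51 arctic-lamprey tarl genes versus 32 in
#' the sea lamprey reads as +59%). A zero denominator yields an undefined
#' marker (`NA` with `undefined = TRUE`), not an error.
#'
#' @param counts Count tibble (first column `species`).
#' @param pairs Optional tibble with columns `species_a`, `species_b`,
#'   `family` requesting relative comparisons.
#' @return An object of class `repertoire_report`: `counts_long` (species,
#'   family, count, present), `family_totals` (family, n_species_present,
#'   total_genes), `comparisons` (the requested pairs with `count_a`,
#'   `count_b`, `pct_diff`, `undefined`).
#' @examples
#' rep <- repertoire_report(
#'   taar_repertoire(),
#'   pairs = tibble::tibble(species_a = "Lec", species_b = "Pm", family = "tarl")
#' )
#' rep$comparisons
#' @export
repertoire_report <- function(counts, pairs = NULL) {
  validate_count_matrix(counts)
  counts_long <- counts |>
    tidyr::pivot_longer(-"species", names_to = "family", values_to = "count") |>
    mutate(present = .data$count >= 1L)
  family_totals <- counts_long |>
    group_by(.data$family) |>
    summarise(n_species_present = sum(.data$present),
              total_genes = sum(.data$count), .groups = "drop")
  comparisons <- NULL
  if (!is.null(pairs)) {
    need <- c("species_a", "species_b", "family")
    if (!all(need %in% names(pairs))) {
      abort("`pairs` needs columns species_a, species_b, family.")
    }
    comparisons <- purrr::pmap_dfr(pairs[need], function(species_a, species_b, family) {
      a <- lookup_count(counts, species_a, family)
      b <- lookup_count(counts, species_b, family)
      undefined <- b == 0
      tibble(species_a = species_a, species_b = species_b, family = family,
             count_a = a, count_b = b,
             pct_diff = if (undefined) NA_integer_ else
               as.integer(round(100 * (a - b) / b)),
             undefined = undefined)
    })
  }
  structure(
    list(counts_long = counts_long, family_totals = family_totals,
         comparisons = comparisons),
    class = "repertoire_report"
  )
}

lookup_count <- function(counts, species, family) {
  if (!species %in% counts$species) {
    abort(paste0("unknown species: ", species))
  }
  if (!family %in% names(counts)) {
    abort(paste0("unknown family: ", family))
  }
  counts[[family]][match(species, counts$species)]
}

#' @export
print.repertoire_report <- function(x, ...) {
  cat("<repertoire report>\n")
  print(x$family_totals)
  if (!is.null(x$comparisons)) {
    cat("comparisons:\n")
    print(x$comparisons)
  }
  invisible(x)
}
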