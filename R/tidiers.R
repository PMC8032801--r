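#' Tidy a Dollo reconstruction
#'
#' @param x A `dollo_recon`.
#' @param ... Unused.
#' @return A tibble with one row per tree node: `node`, `label`, `is_tip`,
#'   `state` (0/1 presence).
#' @method tidy dollo_recon
#' @export
tidy.dollo_recon <- function(x, ...) {
  ntip <- length(x$tree$tip.label)
  tibble(
    node = seq_along(x$states),
    label = names(x$states),
    is_tip = seq_along(x$states) <= ntip,
    state = unname(x$states)
  )
}

#' Summarise a Dollo reconstruction
#'
#' @param x A `dollo_recon`.
#' @param ... Unused.
#' @return One-row tibble: `family`, `gain_label`, `min_losses`,
#'   `n_present`, `overridden`.
#' @method glance dollo_recon
#' @export
glance.dollo_recon <- function(x, ...) {
  tibble(
    family = x$family,
    gain_label = x$gain_label,
    min_losses = x$min_losses,
    n_present = length(x$present),
    overridden = !is.null(x$override)
  )
}

#' Tidy ortholog statistics (per-query best hits)
#' @param x An `ortholog_stats` object.
#' @param ... Unused.
#' @return The per-query tibble (`id`, `best_target`, `identity`).
#' @method tidy ortholog_stats
#' @export
tidy.ortholog_stats <- function(x, ...) x$per_query

#' Summarise ortholog statistics
#' @param x An `ortholog_stats` object.
#' @param ... Unused.
#' @return One-row tibble: `n_queries`, `min`, `max`, `mean`, `mean_rounded`.
#' @method glance ortholog_stats
#' @export
glance.ortholog_stats <- function(x, ...) {
  tibble(n_queries = nrow(x$per_query), min = x$min, max = x$max,
         mean = x$mean, mean_rounded = x$mean_rounded)
}

#' Tidy a repertoire report (long counts)
#' @param x A `repertoire_report`.
#' @param ... Unused.
#' @return The long count tibble (`species`, `family`, `count`, `present`).
#' @method tidy repertoire_report
#' @export
tidy.repertoire_report <- function(x, ...) x$counts_long

#' Tidy a candidate set (retained hit rows)
#' @param x A `candidate_set`.
#' @param ... Unused.
#' @return The retained hits tibble.
#' @method tidy candidate_set
#' @export
tidy.candidate_set <- function(x, ...) x$retained

#' Summarise a candidate set
#' @param x A `candidate_set`.
#' @param ... Unused.
#' @return One-row tibble: `n_retained`, `stop_reason`, `stop_rank`.
#' @method glance candidate_set
#' @export
glance.candidate_set <- function(x, ...) {
  tibble(n_retained = nrow(x$retained), stop_reason = x$stop_reason,
         stop_rank = x$stop_rank)
}
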