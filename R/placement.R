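#' Classify candidate leaves by their position in a labelled reference tree
#'
#' Every leaf of `tree` is either a reference (appears in `labels`) or a
#' candidate. For each candidate the classifier walks from its leaf toward
#' the root and takes the first ancestor clade containing at least one
#' reference leaf. If that clade holds a single reference label, the
#' candidate gets it; if it holds several, the label of the nearest
#' reference leaf by patristic distance wins; an exact patristic tie between
#' distinct labels yields `UNKNOWN`. The result is invariant under child
#' reordering and uniform branch-length scaling, and passing a reference
#' leaf through as a candidate returns its own label.
#'
#' @param tree Rooted `phylo`. Without branch lengths, unit lengths are used
#'   for the distance fallback.
#' @param labels Tibble with columns `leaf`, `label` giving the reference
#'   labels (e.g. class II TAAR clades, lamprey TARL, out-group).
#' @return A tibble with columns `candidate`, `label`, `method`
#'   (`"clade"` when the enclosing clade was pure, `"nearest"` when the
#'   patristic fallback decided, `"tie"` for `UNKNOWN`).
#' @export
classify_by_placement <- function(tree, labels) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) abort("tree must be rooted.")
  if (!is.data.frame(labels) || !all(c("leaf", "label") %in% names(labels))) {
    abort("`labels` must be a tibble with columns leaf, label.")
  }
  if (nrow(labels) == 0) abort("tree has no reference leaves.")
  missing <- setdiff(labels$leaf, tree$tip.label)
  if (length(missing)) {
    abort(paste0("reference leaves not in tree: ", paste(missing, collapse = ", ")))
  }
  ntip <- length(tree$tip.label)
  ref_idx <- match(labels$leaf, tree$tip.label)
  ref_label <- setNames(labels$label, labels$leaf)
  candidates <- setdiff(tree$tip.label, labels$leaf)
  if (!length(candidates)) {
    return(tibble(candidate = character(), label = character(), method = character()))
  }

  work <- tree
  if (is.null(work$edge.length)) work$edge.length <- rep(1, nrow(work$edge))
  tipdist <- ape::cophenetic.phylo(work)
  parent <- setNames(tree$edge[, 1], tree$edge[, 2])
  # tips under each internal node
  tips_under <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) tips_under[[i]] <- i
  for (e in ape::postorder(tree)) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    tips_under[[p]] <- c(tips_under[[p]], tips_under[[ch]])
  }

  one <- function(cand) {
    node <- match(cand, tree$tip.label)
    repeat {
      pn <- parent[as.character(node)]
      if (is.na(pn)) break
      node <- unname(pn)
      refs_in <- intersect(tips_under[[node]], ref_idx)
      if (length(refs_in)) {
        labs <- unique(ref_label[tree$tip.label[refs_in]])
        if (length(labs) == 1) {
          return(tibble(candidate = cand, label = unname(labs), method = "clade"))
        }
        d <- tipdist[cand, tree$tip.label[refs_in]]
        best <- d == min(d)
        best_labs <- unique(ref_label[tree$tip.label[refs_in][best]])
        if (length(best_labs) == 1) {
          return(tibble(candidate = cand, label = unname(best_labs),
                        method = "nearest"))
        }
        return(tibble(candidate = cand, label = "UNKNOWN", method = "tie"))
      }
    }
    tibble(candidate = cand, label = "UNKNOWN", method = "tie")
  }
  purrr::map_dfr(candidates, one)
}

#' Identity shortcut screen for highly conserved families
#'
#' Jawed-fish TARL genes are conserved enough (roughly 95% identity between
#' close relatives, still about 85% between remote ones) that a candidate can
#' be pre-labelled by its best identity against known family members. This is
#' a screen only — the final label always comes from
#' [classify_by_placement()].
#'
#' @param candidates Protein-record tibble of candidates.
#' @param references Protein-record tibble of known family members
#'   (non-empty).
#' @param config A [pipeline_config()] supplying `tarl_identity_floor`.
#' @return A tibble with columns `id`, `max_identity` (percent) and
#'   `shortcut` (`TRUE` iff `max_identity >= 100 * tarl_identity_floor`).
#' @export
tarl_identity_shortcut <- function(candidates, references,
                                   config = pipeline_config()) {
  validate_protein_records(candidates, "candidates")
  validate_protein_records(references, "references")
  if (nrow(references) == 0) abort("`references` must be non-empty.")
  best <- vapply(candidates$sequence, function(s) {
    max(vapply(references$sequence, function(r) pairwise_identity(s, r), 0))
  }, 0)
  tibble(id = candidates$id,
         max_identity = unname(best),
         shortcut = unname(best) >= 100 * config$tarl_identity_floor)
}
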