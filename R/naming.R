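#' Name genes by phylogenetic position
#'
#' Implements the naming convention for newly annotated repertoires:
#' subfamilies are numbered `1..k` from least-derived (subfamily ancestor
#' closest to the root) to most-derived, and genes within a subfamily are
#' lettered `a, b, c, ...` in order of divergence, the least-derived gene
#' (shortest root path) taking `a`. Names are formatted
#' `<SpeciesPrefix>-<family><number><letter>`, e.g. the least-derived gene of
#' the first tarl subfamily in the arctic lamprey is `Lec-tarl1a`. Naming is
#' deterministic (ties broken lexicographically) and injective within a
#' species and family, and adding a new most-derived gene never renames
#' existing ones.
#'
#' @param family_tree Rooted `phylo` of the genes of one family. Without
#'   branch lengths, unit lengths are used for derivedness.
#' @param species_prefix Single prefix string, or named character vector
#'   mapping tip label to prefix.
#' @param family Family name used in the gene names (e.g. `"tarl"`).
#' @param subfamilies Optional named vector/list mapping tip label to a
#'   subfamily id (the pre-delimited partition). When `NULL`, subfamilies
#'   default to the maximal duplication-free clades (no species occurs twice
#'   inside a subfamily) — an automatic delimitation that is convenient but
#'   experimental.
#' @return A tibble with columns `gene`, `subfamily`, `letter`, `name`.
#' @examples
#' tr <- read_newick(text = "((gA:1,gB:1):1,gC:3);")
#' assign_names(tr, "Lec", "tarl",
#'              subfamilies = c(gA = 1, gB = 1, gC = 2))
#' @export
assign_names <- function(family_tree, species_prefix, family,
                         subfamilies = NULL) {
  stopifnot(inherits(family_tree, "phylo"))
  tips <- family_tree$tip.label
  ntip <- length(tips)
  prefix <- if (is.null(names(species_prefix))) {
    setNames(rep(species_prefix[1], ntip), tips)
  } else {
    species_prefix[tips]
  }
  if (anyNA(prefix)) abort("species_prefix missing for some tips.")

  if (ntip == 1) {
    return(tibble(gene = tips, subfamily = 1L, letter = "a",
                  name = paste0(prefix[1], "-", family, "1a")))
  }

  work <- family_tree
  if (is.null(work$edge.length)) work$edge.length <- rep(1, nrow(work$edge))
  depth <- ape::node.depth.edgelength(work)   # root-path length per node

  part <- if (is.null(subfamilies)) {
    auto_subfamilies(family_tree)
  } else {
    unlist(subfamilies)[tips]
  }
  if (anyNA(part)) abort("subfamily partition missing for some tips.")

  # subfamily derivedness: root-path length of the subfamily ancestor
  sub_ids <- unique(part[order(part)])
  sub_depth <- vapply(sub_ids, function(sid) {
    members <- tips[part == sid]
    node <- if (length(members) == 1) match(members, tips) else
      ape::getMRCA(family_tree, members)
    depth[node]
  }, 0)
  sub_minleaf <- vapply(sub_ids, function(sid) min(tips[part == sid]), "")
  sub_order <- order(sub_depth, sub_minleaf)
  number <- setNames(seq_along(sub_ids), sub_ids[sub_order])

  rows <- purrr::map_dfr(seq_along(sub_ids), function(k) {
    sid <- sub_ids[sub_order][k]
    members <- tips[part == sid]
    d <- depth[match(members, tips)]
    ord <- order(d, members)
    tibble(gene = members[ord], subfamily = k,
           letter = int_to_letters(seq_along(members)))
  })
  rows |>
    mutate(name = paste0(prefix[.data$gene], "-", family,
                         .data$subfamily, .data$letter)) |>
    arrange(match(.data$gene, tips))
}

# Maximal clades with no species repeated (species = part of the tip label
# after the last underscore when present, else the whole label).
auto_subfamilies <- function(tree) {
  tips <- tree$tip.label
  ntip <- length(tips)
  species <- sub("^g[0-9]+_", "", tips)
  tips_under <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) tips_under[[i]] <- i
  for (e in ape::postorder(tree)) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    tips_under[[p]] <- c(tips_under[[p]], tips_under[[ch]])
  }
  dup_free <- vapply(seq_len(ntip + tree$Nnode), function(v) {
    sp <- species[tips_under[[v]]]
    !anyDuplicated(sp)
  }, TRUE)
  parent <- setNames(tree$edge[, 1], tree$edge[, 2])
  maximal <- vapply(seq_len(ntip + tree$Nnode), function(v) {
    if (!dup_free[v]) return(FALSE)
    p <- parent[as.character(v)]
    is.na(p) || !dup_free[unname(p)]
  }, TRUE)
  part <- setNames(rep(NA_integer_, ntip), tips)
  k <- 0L
  for (v in which(maximal)) {
    k <- k + 1L
    part[tips[tips_under[[v]]]] <- k
  }
  part
}

int_to_letters <- function(i) {
  vapply(i, function(x) {
    out <- ""
    repeat {
      out <- paste0(letters[(x - 1) %% 26 + 1], out)
      x <- (x - 1) %/% 26
      if (x == 0) break
    }
    out
  }, "")
}
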