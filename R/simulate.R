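#' Simulation parameters for the gene-family generator
#'
#' Defaults describe a moderately dynamic receptor family: a single ancestral
#' gene, duplication and loss rates of 0.3 and 0.2 events per gene per unit
#' branch length (giving leaf repertoires of the handful-of-genes magnitude
#' observed for class II receptor subfamilies), 330-aa proteins matching the
#' packaged fingerprint anchor, and a substitution rate of 0.5 events per
#' site per unit branch length.
#'
#' @param lambda_dup Duplication rate per gene per unit branch length.
#' @param mu_loss Loss rate per gene per unit branch length.
#' @param n0 Gene count at the species-tree root (single ancestral gain).
#' @param seq_len_aa Protein length in amino acids; must cover the motif.
#' @param subst_rate Substitution events per site per unit branch length;
#'   each event replaces the residue uniformly over the 20 amino acids
#'   (silent events allowed).
#' @param seed Integer seed; identical parameters and seed give
#'   byte-identical output.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(lambda_dup = 0.3, mu_loss = 0.2, n0 = 1L,
                       seq_len_aa = 330L, subst_rate = 0.5, seed = 1L) {
  stopifnot(lambda_dup >= 0, mu_loss >= 0, n0 >= 1, seq_len_aa >= 1)
  structure(
    list(lambda_dup = lambda_dup, mu_loss = mu_loss, n0 = as.integer(n0),
         seq_len_aa = as.integer(seq_len_aa), subst_rate = subst_rate,
         seed = as.integer(seed)),
    class = "sim_params"
  )
}

#' Simulate gene-family evolution on a species tree
#'
#' A linear birth-death process runs independently for every gene lineage
#' along every branch of the species tree: waiting times are exponential with
#' rate `lambda_dup + mu_loss` per lineage; an event is a duplication with
#' probability `lambda_dup / (lambda_dup + mu_loss)`, otherwise a loss. The
#' family starts with `n0` genes at the root (one ancestral gain), so
#' simulated families satisfy the single-origin assumption of Dollo
#' parsimony by construction.
#'
#' @param species_tree Rooted `phylo` with branch lengths.
#' @param params A [sim_params()] object.
#' @return A list of class `sim_truth` with elements:
#'   * `events`: tibble (`event` ∈ duplication/loss, `branch` = label of the
#'     child node of the species-tree edge, `time` along the branch,
#'     `lineage` = gene lineage id; duplications log the new daughter id),
#'   * `genealogy`: `phylo` of surviving genes (leaf `g<id>_<species>`), or
#'     `NULL` if the family went extinct,
#'   * `counts`: one-column count tibble (`species`, `fam`),
#'   * `params`, `species_tree`.
#' @examples
#' tr <- read_newick(text = "((A:1,B:1):1,C:2);")
#' truth <- simulate_family(tr, sim_params(seed = 7))
#' truth$counts
#' @export
simulate_family <- function(species_tree, params = sim_params()) {
  stopifnot(inherits(species_tree, "phylo"), inherits(params, "sim_params"))
  if (is.null(species_tree$edge.length)) {
    abort("species tree must have branch lengths.")
  }
  if (!ape::is.rooted(species_tree)) abort("species tree must be rooted.")
  set.seed(params$seed)
  lam <- params$lambda_dup
  mu <- params$mu_loss
  ntip <- length(species_tree$tip.label)
  node_label <- famflux_node_labels(species_tree)
  children_of <- split(species_tree$edge[, 2], species_tree$edge[, 1])
  edge_len <- setNames(species_tree$edge.length, species_tree$edge[, 2])

  env <- new.env(parent = emptyenv())
  env$next_id <- 0L
  env$events <- list()
  new_id <- function() {
    env$next_id <- env$next_id + 1L
    env$next_id
  }
  log_event <- function(event, branch_node, time, lineage) {
    env$events[[length(env$events) + 1L]] <-
      tibble(event = event, branch = node_label[branch_node],
             time = time, lineage = paste0("g", lineage))
  }

  # Simulate one lineage from `pos` time units into the branch ending at
  # `node`; returns a genealogy subtree (label/time/children) or NULL.
  sim_branch <- function(lineage, node, pos, t_entry) {
    len <- edge_len[[as.character(node)]]
    repeat {
      rate <- lam + mu
      wait <- if (rate > 0) rexp(1, rate) else Inf
      if (pos + wait >= len) break
      pos <- pos + wait
      if (runif(1) < lam / rate) {
        daughter <- new_id()
        log_event("duplication", node, pos, daughter)
        left <- sim_branch(lineage, node, pos, t_entry + pos)
        right <- sim_branch(daughter, node, pos, t_entry + pos)
        kids <- Filter(Negate(is.null), list(left, right))
        if (length(kids) == 0) return(NULL)
        if (length(kids) == 1) return(kids[[1]])
        return(list(time = t_entry + pos, children = kids))
      } else {
        log_event("loss", node, pos, lineage)
        return(NULL)
      }
    }
    at_node(lineage, node, t_entry + len)
  }

  # Lineage arrives at a species-tree node (leaf or speciation).
  at_node <- function(lineage, node, t_now) {
    if (node <= ntip) {
      return(list(label = paste0("g", lineage, "_", species_tree$tip.label[node]),
                  time = t_now))
    }
    kids <- children_of[[as.character(node)]]
    sub <- lapply(kids, function(k) sim_branch(lineage, k, 0, t_now))
    sub <- Filter(Negate(is.null), sub)
    if (length(sub) == 0) return(NULL)
    if (length(sub) == 1) return(sub[[1]])
    list(time = t_now, children = sub)
  }

  root <- ntip + 1L
  root_genes <- lapply(seq_len(params$n0), function(i) at_node(new_id(), root, 0))
  root_genes <- Filter(Negate(is.null), root_genes)

  genealogy <- NULL
  if (length(root_genes) > 0) {
    top <- if (length(root_genes) == 1) root_genes[[1]] else
      list(time = 0, children = root_genes)
    frag <- genealogy_newick(top, parent_time = 0)
    if (!is.null(top$label)) frag <- paste0("(", frag, ")")  # single survivor
    genealogy <- read_newick(text = paste0(frag, ";"))
  }

  leaves <- if (is.null(genealogy)) character() else genealogy$tip.label
  leaf_species <- sub("^g[0-9]+_", "", leaves)
  counts <- tibble(species = species_tree$tip.label) |>
    left_join(tibble(species = leaf_species) |> dplyr::count(.data$species, name = "fam"),
              by = "species") |>
    mutate(fam = as.integer(ifelse(is.na(.data$fam), 0L, .data$fam)))

  events <- if (length(env$events)) bind_rows(env$events) else
    tibble(event = character(), branch = character(),
           time = numeric(), lineage = character())

  structure(
    list(events = events, genealogy = genealogy, counts = counts,
         params = params, species_tree = species_tree),
    class = "sim_truth"
  )
}

# Serialize the nested genealogy structure to Newick with branch lengths
# taken from node-time differences.
genealogy_newick <- function(node, parent_time) {
  bl <- format(node$time - parent_time, digits = 10, scientific = FALSE)
  if (!is.null(node$label)) {
    return(paste0(node$label, ":", bl))
  }
  inner <- vapply(node$children, genealogy_newick, "", parent_time = node$time)
  paste0("(", paste(inner, collapse = ","), "):", bl)
}

famflux_node_labels <- function(tree) {
  ntip <- length(tree$tip.label)
  internal <- if (!is.null(tree$node.label) && all(nzchar(tree$node.label))) {
    tree$node.label
  } else {
    paste0("node", seq_len(tree$Nnode) + ntip)
  }
  c(tree$tip.label, internal)
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("<simulated gene family>\n")
  cat("  events:", nrow(x$events),
      sprintf("(%d duplications, %d losses)\n",
              sum(x$events$event == "duplication"),
              sum(x$events$event == "loss")))
  cat("  surviving genes:", sum(x$counts$fam), "across",
      sum(x$counts$fam > 0), "species\n")
  invisible(x)
}

#' Replay leaf counts from a simulated event log
#'
#' Along any root-to-leaf path every duplication adds one gene and every loss
#' removes one, so the leaf count equals `n0` plus the per-edge event balance
#' summed over the path. Used to verify the simulator's internal consistency.
#'
#' @param truth A `sim_truth` object.
#' @return A count tibble (`species`, `fam`) recomputed from the event log.
#' @export
replay_counts <- function(truth) {
  stopifnot(inherits(truth, "sim_truth"))
  tree <- truth$species_tree
  labels <- famflux_node_labels(tree)
  balance <- truth$events |>
    group_by(.data$branch) |>
    summarise(delta = sum(ifelse(.data$event == "duplication", 1L, -1L)),
              .groups = "drop")
  delta <- setNames(rep(0L, length(labels)), labels)
  delta[balance$branch] <- balance$delta
  ntip <- length(tree$tip.label)
  parent <- setNames(tree$edge[, 1], tree$edge[, 2])
  count_for <- function(tip) {
    total <- truth$params$n0
    node <- tip
    repeat {
      p <- parent[as.character(node)]
      if (is.na(p)) break
      total <- total + delta[[labels[node]]]
      node <- unname(p)
    }
    total
  }
  tibble(species = tree$tip.label,
         fam = vapply(seq_len(ntip), count_for, integer(1)))
}

#' Simulate protein sequences along a gene genealogy
#'
#' The root sequence is drawn uniformly over the 20 amino acids (methionine
#' forced at position 1 so sequences are embeddable as coding regions); the
#' fingerprint motif columns are forced to the class-defining residues and
#' held invariant; every other site experiences substitution events at
#' `subst_rate` per unit branch length, each replacing the residue uniformly
#' over the 20 amino acids. Under this model the expected per-site match
#' probability for two leaves separated by path length `T` is
#' `exp(-r T) + (1 - exp(-r T)) / 20`.
#'
#' @param truth A `sim_truth` with a non-`NULL` genealogy.
#' @param params The [sim_params()] used (supplies length, rate, seed).
#' @param motif_class One of `"TAAR"`, `"TARL_JAWED"`, `"NONTAAR"`.
#' @param profile Fingerprint profile defining motif columns and residues.
#' @param nontaar_residue Residue used at the second critical column for the
#'   `NONTAAR` class (anything other than the TARL residue).
#' @return A protein-record tibble, one row per surviving gene.
#' @export
simulate_sequences <- function(truth, params = truth$params,
                               motif_class = c("TAAR", "TARL_JAWED", "NONTAAR"),
                               profile = taar_fingerprint_profile(),
                               nontaar_residue = "A") {
  stopifnot(inherits(truth, "sim_truth"))
  motif_class <- match.arg(motif_class)
  if (is.null(truth$genealogy)) abort("family is extinct: no genealogy to evolve.")
  if (params$seq_len_aa < max(profile$columns$column_index)) {
    abort("seq_len_aa is shorter than the motif span.")
  }
  set.seed(params$seed + 1L)
  aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  len <- params$seq_len_aa

  fixed_res <- switch(motif_class,
    TAAR = profile$columns$residue_taar,
    TARL_JAWED = profile$columns$residue_tarl_jawed,
    NONTAAR = {
      r <- profile$columns$residue_tarl_jawed
      r[which(profile$columns$is_critical)[2]] <- nontaar_residue
      r
    }
  )
  fixed_pos <- c(1L, profile$columns$column_index)
  fixed_val <- c("M", fixed_res)

  root_seq <- sample(aa20, len, replace = TRUE)
  root_seq[fixed_pos] <- fixed_val
  variable <- setdiff(seq_len(len), fixed_pos)

  tree <- truth$genealogy
  r <- params$subst_rate
  if (length(tree$tip.label) == 1) {
    s <- root_seq
    bl <- sum(tree$edge.length)
    if (length(variable) && bl > 0 && r > 0) {
      hit <- variable[runif(length(variable)) < 1 - exp(-r * bl)]
      if (length(hit)) s[hit] <- sample(aa20, length(hit), replace = TRUE)
    }
    seqs <- setNames(list(s), tree$tip.label)
  } else {
    ntip <- length(tree$tip.label)
    seq_at <- vector("list", ntip + tree$Nnode)
    seq_at[[ntip + 1L]] <- root_seq
    ord <- rev(ape::postorder(tree))
    for (e in ord) {
      p <- tree$edge[e, 1]; child <- tree$edge[e, 2]
      bl <- tree$edge.length[e]
      s <- seq_at[[p]]
      if (length(variable) && bl > 0 && r > 0) {
        hit <- variable[runif(length(variable)) < 1 - exp(-r * bl)]
        if (length(hit)) s[hit] <- sample(aa20, length(hit), replace = TRUE)
      }
      seq_at[[child]] <- s
    }
    seqs <- setNames(seq_at[seq_len(ntip)], tree$tip.label)
  }
  protein_records(
    id = names(seqs),
    sequence = vapply(seqs, paste, "", collapse = ""),
    species = sub("^g[0-9]+_", "", names(seqs)),
    family_label = motif_class
  )
}

# Fixed back-translation: one codon per amino acid, chosen once for
# reproducibility (codon-usage realism is irrelevant to the tested logic).
famflux_codon_table <- c(
  A = "GCT", R = "CGT", N = "AAT", D = "GAT", C = "TGT", Q = "CAA",
  E = "GAA", G = "GGT", H = "CAT", I = "ATT", L = "CTT", K = "AAA",
  M = "ATG", F = "TTT", P = "CCT", S = "TCT", T = "ACT", W = "TGG",
  Y = "TAT", V = "GTT"
)

#' Embed a protein's coding sequence in a synthetic genomic fragment
#'
#' Back-translates the record (fixed one-codon-per-amino-acid table), adds a
#' stop codon, and flanks the coding region with random sequence constrained
#' so that ORF completion is deterministic: the upstream flank contains no
#' in-frame ATG and no in-frame stop within the extension window, the
#' downstream flank no in-frame stop. The returned hit interval is
#' deliberately truncated strictly inside the coding region (in frame), so
#' that [complete_orf()] must extend in both directions to recover the
#' protein.
#'
#' @param record One row of a protein-record tibble; the sequence must start
#'   with `M` and contain no `X` or internal `*`.
#' @param flank_nt Flank length in nucleotides (each side), `>= 0`.
#' @param strand `"+"` to embed on the forward strand, `"-"` to embed the
#'   reverse complement (the interval is still reported in forward-strand
#'   coordinates with the strand flag, the convention used by hit tables).
#' @param seed Integer seed for flanks and truncation.
#' @return A list with `genomic` (nucleotide string), `interval` (one-row
#'   tibble: `start`, `end` 0-based half-open, `strand`), and `cds` (the
#'   true coding interval including the stop codon, forward-strand coords).
#' @export
embed_in_genome <- function(record, flank_nt = 500L, strand = c("+", "-"),
                            seed = 1L) {
  strand <- match.arg(strand)
  stopifnot(flank_nt >= 0)
  seq <- as_sequence(record)
  if (!startsWith(seq, "M")) abort("record must start with methionine (M).")
  if (grepl("[X*]", seq)) abort("record must not contain X or internal stops.")
  L <- nchar(seq)
  if (L < 10) abort("record too short to truncate an interior hit interval.")
  set.seed(seed)

  cds <- paste0(paste(famflux_codon_table[strsplit(seq, "")[[1]]], collapse = ""), "TAA")
  stops <- c("TAA", "TAG", "TGA")
  codons64 <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                                c("A", "C", "G", "T"))[, 3:1], 1, paste, collapse = "")
  up_pool <- setdiff(codons64, c(stops, "ATG"))
  down_pool <- setdiff(codons64, stops)

  n_codons <- ceiling(flank_nt / 3)
  up <- paste(sample(up_pool, n_codons, replace = TRUE), collapse = "")
  up <- substr(up, nchar(up) - flank_nt + 1, nchar(up))   # trim from the left
  down <- paste(sample(down_pool, n_codons, replace = TRUE), collapse = "")
  down <- substr(down, 1, flank_nt)                       # trim from the right

  genomic <- paste0(up, cds, down)
  cds_start <- nchar(up)                                  # 0-based
  cds_end <- cds_start + nchar(cds)

  # truncate the hit strictly inside the coding part (in frame)
  max_trim <- max(1L, min(4L, (L - 2L) %/% 2L))
  k5 <- sample.int(max_trim, 1)
  k3 <- sample.int(max_trim, 1)
  hit_start <- cds_start + 3L * k5
  hit_end <- cds_end - 3L - 3L * k3   # stay inside the codons before the stop

  if (strand == "-") {
    genomic <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(genomic)))
    glen <- nchar(genomic)
    new_hit <- c(glen - hit_end, glen - hit_start)
    new_cds <- c(glen - cds_end, glen - cds_start)
    hit_start <- new_hit[1]; hit_end <- new_hit[2]
    cds_start <- new_cds[1]; cds_end <- new_cds[2]
  }

  list(
    genomic = genomic,
    interval = tibble(start = as.integer(hit_start), end = as.integer(hit_end),
                      strand = strand),
    cds = tibble(start = as.integer(cds_start), end = as.integer(cds_end),
                 strand = strand)
  )
}
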