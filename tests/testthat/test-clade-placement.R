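ref_labels <- function(...) {
  x <- c(...)
  tibble::tibble(leaf = names(x), label = unname(x))
}

test_that("placement assigns by smallest reference-bearing clade", {
  tr <- read_newick(text = "(((cand1,refII:1):1,(refI_a:1,refI_b:1):1):1,out:3);")
  labs <- ref_labels(refII = "classII", refI_a = "classI", refI_b = "classI",
                     out = "outgroup")
  res <- classify_by_placement(tr, labs)
  expect_equal(res$label[res$candidate == "cand1"], "classII")
  expect_equal(res$method[res$candidate == "cand1"], "clade")

  # candidate inside a pure 5-reference clade
  tr2 <- read_newick(text = "(((L1,(L2,(cand,(L3,(L4,L5))))),other),out);")
  labs2 <- ref_labels(L1 = "TARL_lamprey", L2 = "TARL_lamprey",
                      L3 = "TARL_lamprey", L4 = "TARL_lamprey",
                      L5 = "TARL_lamprey", other = "classII", out = "outgroup")
  res2 <- classify_by_placement(tr2, labs2)
  expect_equal(res2$label[res2$candidate == "cand"], "TARL_lamprey")
})

test_that("mixed clades fall back to patristic nearest; exact ties are UNKNOWN", {
  # candidate sister to nothing pure: first reference-bearing clade holds both
  tr <- read_newick(text = "((cand:1,(a:0.5,b:2):1):1,out:4);")
  labs <- ref_labels(a = "X", b = "Y", out = "outgroup")
  res <- classify_by_placement(tr, labs)
  expect_equal(res$label[res$candidate == "cand"], "X")   # a is closer
  expect_equal(res$method[res$candidate == "cand"], "nearest")

  tie <- read_newick(text = "((cand:1,(a:1,b:1):1):1,out:4);")
  res_tie <- classify_by_placement(tie, ref_labels(a = "X", b = "Y",
                                                   out = "outgroup"))
  expect_equal(res_tie$label[res_tie$candidate == "cand"], "UNKNOWN")
  expect_equal(res_tie$method[res_tie$candidate == "cand"], "tie")
})

test_that("placement is invariant to ladderization and branch scaling", {
  tr <- read_newick(text = "(((c1:1,r1:2):1,(r2:1,(c2:0.5,r3:1):0.7):1):1,out:5);")
  labs <- ref_labels(r1 = "A", r2 = "B", r3 = "B", out = "outgroup")
  base <- classify_by_placement(tr, labs) |> dplyr::arrange(candidate)

  ladder <- ape::ladderize(tr)
  scaled <- tr
  scaled$edge.length <- scaled$edge.length * 7.3
  for (variant in list(ladder, scaled)) {
    res <- classify_by_placement(variant, labs) |> dplyr::arrange(candidate)
    expect_equal(res$label, base$label)
  }
})

test_that("reference leaves passed through as candidates keep their labels", {
  # duplicate each reference as an unlabeled sister candidate
  tr <- read_newick(text = "(((r1:1,r1c:1):1,(r2:1,r2c:1):1):1,out:3);")
  labs <- ref_labels(r1 = "A", r2 = "B", out = "outgroup")
  res <- classify_by_placement(tr, labs)
  expect_equal(res$label[res$candidate == "r1c"], "A")
  expect_equal(res$label[res$candidate == "r2c"], "B")
})

test_that("grafted candidates are recovered at benchmark accuracy", {
  # reference tree: two labeled clades of 5 + outgroup
  mk_clade <- function(prefix) {
    sprintf("((%s1:1,%s2:1):1,(%s3:1,(%s4:1,%s5:1):1):1)",
            prefix, prefix, prefix, prefix, prefix)
  }
  nwk <- sprintf("((%s:2,%s:2):1,out:6);", mk_clade("A"), mk_clade("B"))
  base <- read_newick(text = nwk)
  labs <- ref_labels(setNames(
    c(rep("alpha", 5), rep("beta", 5), "outgroup"),
    c(paste0("A", 1:5), paste0("B", 1:5), "out")
  ))
  n_seeds <- 50
  n_cand <- 100
  correct <- 0L; total <- 0L
  for (seed in seq_len(n_seeds)) {
    set.seed(seed)
    tr <- base
    truth <- character()
    for (k in seq_len(n_cand)) {
      target_clade <- sample(c("A", "B"), 1)
      target_tip <- paste0(target_clade, sample(1:5, 1))
      cand_id <- sprintf("cand%03d", k)
      tip <- list(edge = matrix(c(2L, 1L), 1), tip.label = cand_id,
                  edge.length = runif(1, 0.1, 0.8), Nnode = 1L)
      class(tip) <- "phylo"
      where <- match(target_tip, tr$tip.label)
      pend_len <- tr$edge.length[tr$edge[, 2] == where]
      tr <- ape::bind.tree(tr, tip, where = where,
                           position = runif(1, 0.05, 0.95) * pend_len)
      truth[cand_id] <- c(A = "alpha", B = "beta")[target_clade]
    }
    res <- classify_by_placement(tr, labs)
    res <- res[res$candidate %in% names(truth), ]
    correct <- correct + sum(res$label == truth[res$candidate])
    total <- total + nrow(res)
  }
  expect_gte(correct / total, 0.99)
})

test_that("identity shortcut screens by best identity with a strict floor", {
  refs <- protein_records(c("t1", "t2"),
                          c(strrep("MKTWLAVGHR", 100),
                            strrep("MKTWLAVGHK", 100)))
  # identical to a reference
  cand <- protein_records("c1", strrep("MKTWLAVGHR", 100))
  out <- tarl_identity_shortcut(cand, refs)
  expect_true(out$shortcut)
  expect_equal(out$max_identity, 100)

  # 84.9% to every reference: below the 85% floor
  base <- strsplit(strrep("MKTWLAVGHR", 100), "")[[1]]
  v <- base; v[seq_len(151)] <- "C"
  low <- protein_records("c2", paste(v, collapse = ""))
  out_low <- tarl_identity_shortcut(low, refs)
  expect_equal(out_low$max_identity, 84.9)
  expect_false(out_low$shortcut)

  # boundary: exactly 85% passes
  v85 <- base; v85[seq_len(150)] <- "C"
  out85 <- tarl_identity_shortcut(protein_records("c3", paste(v85, collapse = "")),
                                  refs)
  expect_equal(out85$max_identity, 85)
  expect_true(out85$shortcut)
})

test_that("shortcut and placement agree on a conserved simulated family", {
  tr <- read_newick(text = "((A:0.1,B:0.1):0.1,(C:0.1,D:0.1):0.1);")
  pars <- sim_params(lambda_dup = 0.5, mu_loss = 0, n0 = 1,
                     subst_rate = 0.1, seed = 31)
  truth <- simulate_family(tr, pars)
  seqs <- simulate_sequences(truth, pars, motif_class = "TARL_JAWED")
  refs <- seqs[seqs$species == "A", ]
  cands <- seqs[seqs$species != "A", ]
  expect_gte(nrow(refs), 1)
  expect_gte(nrow(cands), 2)
  short <- tarl_identity_shortcut(cands, refs)
  expect_true(all(short$shortcut))
})

test_that("gene naming follows derivedness and stays stable under growth", {
  # single gene
  single <- read_newick(text = "(g1:1);")
  expect_equal(assign_names(single, "Lec", "tarl")$name, "Lec-tarl1a")

  # two subfamilies: numbering from least-derived, letters by root path
  tr <- read_newick(text = "((x:1,y:2):3,(p:1,q:1):1);")
  nm <- assign_names(tr, "Lec", "tarl",
                     subfamilies = c(x = "s1", y = "s1", p = "s2", q = "s2"))
  # subfamily {p,q} ancestor is closer to the root -> number 1
  expect_equal(nm$name[nm$gene == "p"], "Lec-tarl1a")
  expect_equal(nm$name[nm$gene == "x"], "Lec-tarl2a")
  expect_equal(nm$name[nm$gene == "y"], "Lec-tarl2b")
  expect_equal(anyDuplicated(nm$name), 0L)

  # adding a new most-derived gene never renames existing genes
  tr2 <- read_newick(text = "((x:1,(y:2,z:4):0.1):3,(p:1,q:1):1);")
  nm2 <- assign_names(tr2, "Lec", "tarl",
                      subfamilies = c(x = "s1", y = "s1", z = "s1",
                                      p = "s2", q = "s2"))
  old <- nm[order(nm$gene), c("gene", "name")]
  new_sub <- nm2[nm2$gene %in% old$gene, c("gene", "name")]
  expect_equal(new_sub[order(new_sub$gene), ], old)
  expect_equal(nm2$name[nm2$gene == "z"], "Lec-tarl2c")
})
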