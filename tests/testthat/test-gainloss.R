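test_that("Dollo handles the canonical base cases", {
  tr <- read_newick(text = "(((A,B),C),D);")

  all_present <- dollo_reconstruct(tr, c("A", "B", "C", "D"))
  expect_equal(all_present$min_losses, 0)
  expect_equal(all_present$gain_node, length(tr$tip.label) + 1L)  # root

  # an interior absent leaf costs exactly its pendant edge
  one_absent <- dollo_reconstruct(tr, c("A", "B", "D"))
  expect_equal(one_absent$min_losses, 1)
  expect_equal(one_absent$losses$child_label, "C")
  expect_equal(one_absent$losses$n_leaves_lost, 1)

  # an absent leaf outside the MRCA of the present leaves costs nothing:
  # the gain simply sits lower in the tree
  basal_absent <- dollo_reconstruct(tr, c("A", "B", "C"))
  expect_equal(basal_absent$min_losses, 0)

  expect_error(dollo_reconstruct(tr, character()), "no present leaf")
  expect_error(dollo_reconstruct(tr, c("A", "Z")), "not in tree")
})

test_that("Dollo equals the exhaustive single-gain oracle", {
  # exhaustive over all rooted topologies with <= 5 leaves x all patterns
  for (n in 3:5) {
    trees <- phangorn::allTrees(n, rooted = TRUE,
                                tip.label = LETTERS[seq_len(n)])
    for (ti in seq_along(trees)) {
      tr <- trees[[ti]]
      for (mask in seq_len(2^n - 1)) {
        present <- LETTERS[seq_len(n)][bitwAnd(mask, 2^(seq_len(n) - 1)) > 0]
        got <- dollo_reconstruct(tr, present)$min_losses
        want <- dollo_brute(tr, present)
        expect_equal(got, want,
                     info = paste("n", n, "tree", ti, "pattern", mask))
      }
    }
  }
  # random topologies at n = 6..8 x all patterns (full enumeration of
  # topologies is quadrillions of cases; sampled here)
  set.seed(99)
  for (n in 6:8) {
    for (rep in 1:20) {
      tr <- ape::rtree(n, tip.label = LETTERS[seq_len(n)])
      for (mask in seq_len(2^n - 1)) {
        present <- LETTERS[seq_len(n)][bitwAnd(mask, 2^(seq_len(n) - 1)) > 0]
        expect_equal(dollo_reconstruct(tr, present)$min_losses,
                     dollo_brute(tr, present))
      }
    }
  }
})

test_that("Dollo ignores branch lengths and leaf order", {
  set.seed(12)
  tr <- ape::rtree(12)
  present <- sample(tr$tip.label, 5)
  base <- dollo_reconstruct(tr, present)

  scaled <- tr
  scaled$edge.length <- scaled$edge.length * 100
  expect_equal(dollo_reconstruct(scaled, present)$min_losses, base$min_losses)

  nolen <- tr
  nolen$edge.length <- NULL
  expect_equal(dollo_reconstruct(nolen, present)$min_losses, base$min_losses)

  rot <- ape::ladderize(tr)
  rotated <- dollo_reconstruct(rot, present)
  expect_equal(rotated$min_losses, base$min_losses)
  expect_equal(sort(rotated$losses$child_label[rotated$losses$n_leaves_lost == 1]),
               sort(base$losses$child_label[base$losses$n_leaves_lost == 1]))
})

test_that("gain overrides recompute losses and keep an audit trail", {
  tr <- read_newick(text = "(((A,B),C),D);")
  rec <- dollo_reconstruct(tr, c("A", "B"))
  expect_equal(rec$min_losses, 0)

  # identity override is a no-op
  same <- apply_override(rec, rec$gain_node)
  expect_equal(same$min_losses, rec$min_losses)
  expect_equal(same$override$delta, 0)
  expect_equal(same$states, rec$states)

  # one node rootward exposes C as a newly observable loss
  labels <- names(rec$states)
  root_child <- rec$gain_node  # MRCA(A,B)
  up <- famflux:::node_ancestry(tr, root_child)[1]
  moved <- apply_override(rec, up)
  expect_equal(moved$min_losses, 1)
  expect_equal(moved$losses$child_label, "C")
  expect_equal(moved$override$delta, 1)

  # root override exposes C and D
  root <- length(tr$tip.label) + 1L
  at_root <- apply_override(rec, root)
  expect_equal(at_root$min_losses, 2)
  expect_setequal(at_root$losses$child_label, c("C", "D"))

  # a non-ancestor target is refused
  expect_error(apply_override(rec, match("D", labels)), "ancestor")
})

test_that("Dollo lower-bounds true simulated losses, with equality when clean", {
  tr <- read_newick(text = "(((A:1,B:1):1,(C:1,D:1):1):1,(E:2,F:2):1);")
  for (seed in 1:20) {
    truth <- simulate_family(tr, sim_params(lambda_dup = 0.4, mu_loss = 0.3,
                                            n0 = 1, seed = seed))
    present <- truth$counts$species[truth$counts$fam > 0]
    n_true_losses <- sum(truth$events$event == "loss")
    if (!length(present)) next
    rec <- dollo_reconstruct(tr, present)
    expect_lte(rec$min_losses, n_true_losses)
  }
  # no duplications, single origin: every loss kills a whole clade, and when
  # presence spans the root the reconstruction recovers the count exactly
  for (seed in 1:30) {
    truth <- simulate_family(tr, sim_params(lambda_dup = 0, mu_loss = 0.25,
                                            n0 = 1, seed = seed + 1000))
    present <- truth$counts$species[truth$counts$fam > 0]
    if (!length(present)) next
    rec <- dollo_reconstruct(tr, present)
    n_true <- sum(truth$events$event == "loss")
    expect_lte(rec$min_losses, n_true)
    if (rec$gain_node == length(tr$tip.label) + 1L) {
      expect_equal(rec$min_losses, n_true, info = paste("seed", seed))
    }
  }
})

test_that("presence thresholding and tidiers expose the reconstruction", {
  counts <- taar_repertoire()
  pres <- presence_from_counts(counts, "taar12")
  expect_true("Cc" %in% pres)
  expect_false("Ch" %in% pres)
  expect_error(presence_from_counts(counts, "nope"), "not in count matrix")

  tr <- read_newick(text = "(((A,B),C),D);")
  rec <- dollo_reconstruct(tr, c("A", "C"), family = "demo")
  td <- tidy(rec)
  expect_equal(nrow(td), 4 + tr$Nnode)
  expect_equal(td$state[td$label == "B"], 0)
  gl <- glance(rec)
  expect_equal(gl$min_losses, 1)
  expect_equal(gl$family, "demo")
  expect_false(gl$overridden)
})

test_that("ortholog statistics summarise best-hit identities", {
  a <- protein_records(c("q1", "q2"),
                       c(strrep("MKTWLAVGHR", 10), strrep("MKTWLAVGHK", 10)))
  self <- ortholog_stats(a, a)
  expect_true(all(self$per_query$identity == 100))
  expect_equal(self$mean, 100)

  # constructed best identities {90, 100} -> range 90-100, mean 95
  targets <- protein_records(
    c("t1", "t2"),
    c(strrep("MKTWLAVGHR", 1), paste0(strrep("MKTWLAVGHR", 1), ""))
  )
  q90 <- protein_records(c("q1", "q2"),
                         c("MKTWLAVGHR", "MKTWLAVGHC"))
  st <- ortholog_stats(q90, targets)
  expect_equal(sort(st$per_query$identity), c(90, 100))
  expect_equal(st$min, 90)
  expect_equal(st$max, 100)
  expect_equal(st$mean, 95)
  expect_equal(st$mean_rounded, 95L)

  expect_error(ortholog_stats(a[0, ], a), "non-empty")
})

test_that("repertoire report computes relative differences as printed", {
  counts <- tibble::tibble(species = c("Lec", "Pm", "Eq", "Zero"),
                           tarl = c(51L, 32L, 32L, 0L))
  rep <- repertoire_report(counts, pairs = tibble::tibble(
    species_a = c("Lec", "Eq", "Lec"),
    species_b = c("Pm", "Pm", "Zero"),
    family = "tarl"
  ))
  cmp <- rep$comparisons
  expect_equal(cmp$pct_diff[1], 59L)          # 100*(51-32)/32 rounded
  expect_equal(cmp$pct_diff[2], 0L)
  expect_true(is.na(cmp$pct_diff[3]))
  expect_true(cmp$undefined[3])
  expect_equal(rep$family_totals$n_species_present, 3)
  expect_equal(rep$family_totals$total_genes, 115)
})
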