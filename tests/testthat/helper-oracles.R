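# Independent oracles used by the test suite. These deliberately do not
# share code with the package implementation.

# Gotoh global alignment (affine gaps: a gap of length L costs open + L*ext)
# with deterministic traceback preference diagonal > up > left.
gotoh_align <- function(a, b, open = 12, ext = 2) {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  S <- e$BLOSUM62
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  M <- X <- Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- -(open + i * ext)
  for (j in seq_len(m)) Y[1, j + 1] <- -(open + j * ext)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- S[av[i], bv[j]]
      M[i + 1, j + 1] <- s + max(M[i, j], X[i, j], Y[i, j])
      X[i + 1, j + 1] <- max(M[i, j + 1] - open - ext, X[i, j + 1] - ext,
                             Y[i, j + 1] - open - ext)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - open - ext, X[i + 1, j] - open - ext,
                             Y[i + 1, j] - ext)
    }
  }
  score <- max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
  # traceback
  oa <- character(); ob <- character()
  i <- n; j <- m
  state <- which.max(c(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1]))
  while (i > 0 || j > 0) {
    if (state == 1) {
      s <- S[av[i], bv[j]]
      prev <- c(M[i, j], X[i, j], Y[i, j])
      state <- which.max(prev)
      oa <- c(av[i], oa); ob <- c(bv[j], ob)
      i <- i - 1; j <- j - 1
    } else if (state == 2) {
      cand <- c(M[i, j + 1] - open - ext, X[i, j + 1] - ext,
                Y[i, j + 1] - open - ext)
      state <- which.max(cand)
      oa <- c(av[i], oa); ob <- c("-", ob)
      i <- i - 1
    } else {
      cand <- c(M[i + 1, j] - open - ext, X[i + 1, j] - open - ext,
                Y[i + 1, j] - ext)
      state <- which.max(cand)
      oa <- c("-", oa); ob <- c(bv[j], ob)
      j <- j - 1
    }
    if (i == 0 && j > 0) state <- 3
    if (j == 0 && i > 0) state <- 2
  }
  list(score = score, a = paste(oa, collapse = ""), b = paste(ob, collapse = ""))
}

# Exhaustive minimum-loss search over all single-gain ancestral labelings.
dollo_brute <- function(tree, present) {
  ntip <- length(tree$tip.label)
  nn <- tree$Nnode
  leafstate <- as.integer(tree$tip.label %in% present)
  best <- Inf
  for (mask in 0:(2^nn - 1)) {
    internal <- as.integer(intToBits(mask))[seq_len(nn)]
    state <- c(leafstate, internal)
    gains <- state[ntip + 1]
    losses <- 0L
    for (e in seq_len(nrow(tree$edge))) {
      p <- state[tree$edge[e, 1]]; ch <- state[tree$edge[e, 2]]
      if (p == 0 && ch == 1) gains <- gains + 1L
      if (p == 1 && ch == 0) losses <- losses + 1L
    }
    if (gains == 1L && losses < best) best <- losses
  }
  best
}

# Random related protein pair: common ancestor plus point substitutions and
# short indels, the regime ortholog identity comparisons operate in.
random_protein_pair <- function(len = 100, sub_p = 0.12, n_indel = 1) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  anc <- sample(aa, len, replace = TRUE)
  mutate_one <- function(x) {
    hit <- runif(length(x)) < sub_p
    x[hit] <- sample(aa, sum(hit), replace = TRUE)
    for (k in seq_len(n_indel)) {
      pos <- sample(seq_len(length(x) - 5), 1)
      w <- sample(1:3, 1)
      if (runif(1) < 0.5) x <- x[-(pos:(pos + w - 1))]
      else x <- append(x, sample(aa, w, replace = TRUE), after = pos)
    }
    x
  }
  list(a = paste(mutate_one(anc), collapse = ""),
       b = paste(mutate_one(anc), collapse = ""))
}
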