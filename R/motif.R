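#' Read a fingerprint-motif profile
#'
#' A profile describes the conserved fingerprint motif used to discriminate
#' TAAR from taar-like (TARL) receptors: an anchor (reference) sequence, the
#' motif column indices on that anchor, and the residues expected at the two
#' critical columns per class. In TAARs the critical positions carry Y and W;
#' jawed-fish TARLs carry N and S; an N paired with anything else marks a
#' non-TAAR aminergic-type sequence.
#'
#' @param profile_tsv Path to a TSV with columns `column_index`,
#'   `residue_taar`, `residue_tarl_jawed`, `is_critical`.
#' @param anchor_fasta Path to a single-entry FASTA holding the anchor.
#' @return A list of class `fingerprint_profile` with elements `anchor`
#'   (string), `columns` (tibble) and `critical` (two column indices).
#' @export
read_fingerprint_profile <- function(profile_tsv, anchor_fasta) {
  cols <- readr::read_tsv(
    profile_tsv, comment = "#", progress = FALSE,
    col_types = readr::cols(
      column_index = readr::col_integer(),
      residue_taar = readr::col_character(),
      residue_tarl_jawed = readr::col_character(),
      is_critical = readr::col_logical()
    )
  )
  anchor_rec <- read_protein_fasta(anchor_fasta)
  if (nrow(anchor_rec) != 1) abort("anchor FASTA must hold exactly one sequence.")
  anchor <- anchor_rec$sequence
  if (sum(cols$is_critical) != 2) abort("profile must designate exactly two critical columns.")
  if (any(cols$column_index < 1 | cols$column_index > nchar(anchor))) {
    abort("motif columns fall outside the anchor sequence.")
  }
  structure(
    list(anchor = anchor, columns = cols,
         critical = cols$column_index[cols$is_critical]),
    class = "fingerprint_profile"
  )
}

#' Default (synthetic) fingerprint profile
#'
#' The published motif is only available graphically, so the packaged default
#' is a curated synthetic stand-in: a random anchor carrying a ten-column
#' motif near the C-terminus whose two critical columns follow the published
#' rule structure (Y/W for TAAR, N/S for jawed-fish TARL). It separates the
#' classes produced by [simulate_sequences()] exactly; it cannot classify
#' real receptor sequences.
#'
#' @return A `fingerprint_profile`.
#' @export
taar_fingerprint_profile <- function() {
  read_fingerprint_profile(
    famflux_extdata("fingerprint_profile_synthetic.tsv"),
    famflux_extdata("fingerprint_anchor_synthetic.fasta")
  )
}

#' @export
print.fingerprint_profile <- function(x, ...) {
  cat("<fingerprint profile>\n")
  cat("  anchor length:", nchar(x$anchor), "aa\n")
  cat("  motif columns:", paste(x$columns$column_index, collapse = ", "), "\n")
  cat("  critical columns:", paste(x$critical, collapse = ", "), "\n")
  invisible(x)
}

#' Classify protein records by the fingerprint motif
#'
#' Each record is globally aligned to the profile anchor; the residues at the
#' two critical motif columns are read through the alignment column map and
#' matched against the class rules: (Y, W) → `TAAR`; (N, S) → `TARL_JAWED`;
#' N paired with anything else → `NON_TAAR`; any other pattern → `UNKNOWN`.
#' Records whose alignment score falls below `score_floor` are reported as
#' `UNALIGNABLE` rather than raising an error.
#'
#' @param records A protein-record tibble.
#' @param profile A `fingerprint_profile` (default: packaged synthetic one).
#' @param score_floor Minimum global alignment score for a record to count
#'   as alignable to the anchor. The default, minus two points per anchor
#'   residue, accepts any roughly full-length sequence (unrelated
#'   same-length proteins score about -0.5 to -1 per column under the motif
#'   scoring) while rejecting fragments and junk, whose terminal gap
#'   penalties push the score far lower.
#' @return A tibble with one row per record: `id`, `label`, `score`, and a
#'   `motif` string giving the record residues at all motif columns (in
#'   anchor coordinates; `-` where the record has a gap).
#' @export
fingerprint_classify <- function(records, profile = taar_fingerprint_profile(),
                                 score_floor = NULL) {
  validate_protein_records(records)
  stopifnot(inherits(profile, "fingerprint_profile"))
  if (is.null(score_floor)) score_floor <- -2 * nchar(profile$anchor)
  crit <- sort(profile$critical)
  crit_rule <- profile$columns[match(crit, profile$columns$column_index), ]

  one <- function(id, seq) {
    aln <- align_global(profile$anchor, gsub("*", "", seq, fixed = TRUE),
                        scoring = famflux_motif_scoring())
    if (aln$score < score_floor) {
      return(tibble(id = id, label = "UNALIGNABLE", score = aln$score,
                    motif = NA_character_))
    }
    res <- residues_at_anchor_columns(aln$a, aln$b, profile$columns$column_index)
    r <- res[match(crit, profile$columns$column_index)]
    y <- crit_rule$residue_taar[1]; w <- crit_rule$residue_taar[2]
    n <- crit_rule$residue_tarl_jawed[1]; s <- crit_rule$residue_tarl_jawed[2]
    label <-
      if (r[1] == y && r[2] == w) "TAAR"
      else if (r[1] == n && r[2] == s) "TARL_JAWED"
      else if (r[1] == n) "NON_TAAR"
      else "UNKNOWN"
    tibble(id = id, label = label, score = aln$score,
           motif = paste(res, collapse = ""))
  }
  purrr::map2_dfr(records$id, records$sequence, one)
}

# Read the subject residues aligned to given 1-based anchor positions.
residues_at_anchor_columns <- function(aligned_anchor, aligned_subject, positions) {
  ca <- strsplit(aligned_anchor, "")[[1]]
  cb <- strsplit(aligned_subject, "")[[1]]
  anchor_pos <- cumsum(ca != "-")
  vapply(positions, function(p) {
    col <- match(p, anchor_pos)
    if (is.na(col) || ca[col] == "-") "-" else cb[col]
  }, "")
}

#' Strip gap-rich columns from an alignment
#'
#' A column is removed iff its gap fraction (gap count / row count) is
#' greater than or equal to `tolerance`. At the conventional 90% tolerance
#' level a column with 9 gaps among 10 rows is removed. Row order is
#' preserved and the retained original column indices are returned so
#' coordinates can be mapped back.
#'
#' @param aln A protein-record tibble whose `sequence` strings are aligned
#'   (equal length, `-` for gaps).
#' @param tolerance Gap fraction threshold in `(0, 1]`.
#' @return A list with `alignment` (same tibble, stripped sequences),
#'   `removed` (original indices of dropped columns) and `kept` (original
#'   indices of retained columns).
#' @export
strip_gap_columns <- function(aln, tolerance = 0.90) {
  validate_protein_records(aln, "aln")
  if (nrow(aln) == 0) abort("empty alignment.")
  stopifnot(tolerance > 0, tolerance <= 1)
  widths <- nchar(aln$sequence)
  if (length(unique(widths)) != 1) abort("alignment rows must have equal length.")
  m <- do.call(rbind, strsplit(aln$sequence, ""))
  gap_frac <- colMeans(m == "-")
  drop <- gap_frac >= tolerance
  stripped <- apply(m[, !drop, drop = FALSE], 1, paste, collapse = "")
  if (!sum(!drop)) stripped <- rep("", nrow(aln))
  out <- aln
  out$sequence <- stripped
  list(alignment = out,
       removed = which(drop),
       kept = which(!drop))
}

#' Neighbor-joining tree from protein records
#'
#' Test-plumbing tree builder: pairwise distances are `1 - identity / 100`
#' from [pairwise_identity()], and the topology comes from neighbor joining.
#' Records are ordered lexicographically by id first so ties resolve
#' deterministically. Maximum-likelihood tree building is deliberately out of
#' scope; this exists so placement experiments can run without external
#' tools.
#'
#' @param records A protein-record tibble with at least three rows.
#' @return An unrooted `phylo` with record ids as tip labels.
#' @export
nj_tree <- function(records) {
  validate_protein_records(records)
  if (nrow(records) < 3) abort("need at least 3 records for a tree.")
  records <- arrange(records, .data$id)
  n <- nrow(records)
  d <- matrix(0, n, n, dimnames = list(records$id, records$id))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      d[i, j] <- d[j, i] <-
        1 - pairwise_identity(records$sequence[i], records$sequence[j]) / 100
    }
  }
  ape::nj(stats::as.dist(d))
}
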