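#' Apply the search stopping rule to a ranked hit table
#'
#' Rows are scanned in their ranked order (ascending e-value). Scanning stops
#' *before* the first row whose e-value exceeds `evalue_stop`, or immediately
#' *after* observing `consecutive_offtarget_stop` consecutive rows flagged
#' `OTHER`, whichever comes first; if neither fires the table is exhausted.
#' Rows flagged `TARGET_CLASS` or `UNKNOWN` seen before stopping are
#' retained (ambiguous hits are validated downstream by phylogeny rather
#' than discarded); `UNKNOWN` rows also break a run of `OTHER` rows.
#'
#' The rule is prefix-monotone: once a stop has fired, appending rows can
#' change neither the retained set nor the stop rank.
#'
#' @param hits A hit-table tibble (see [read_hit_table()]), sorted by
#'   ascending e-value. An unsorted table is an error, not silently
#'   re-sorted.
#' @param config A [pipeline_config()].
#' @return A list of class `candidate_set`: `retained` (tibble of retained
#'   hit rows with their 0-based `rank`), `stop_reason` (one of
#'   `EVALUE_FLOOR`, `CONSECUTIVE_OFFTARGET`, `EXHAUSTED`) and `stop_rank`
#'   (number of rows scanned; every retained row has `rank < stop_rank`).
#' @export
apply_stopping_rule <- function(hits, config = pipeline_config()) {
  validate_hit_table(hits)
  stopifnot(inherits(config, "famflux_config"))
  n <- nrow(hits)
  retained_idx <- integer()
  stop_reason <- "EXHAUSTED"
  stop_rank <- n
  run <- 0L
  for (i in seq_len(n)) {
    if (hits$evalue[i] > config$evalue_stop) {
      stop_reason <- "EVALUE_FLOOR"
      stop_rank <- i - 1L
      break
    }
    if (hits$class_flag[i] == "OTHER") {
      run <- run + 1L
    } else {
      run <- 0L
      retained_idx <- c(retained_idx, i)
    }
    if (run >= config$consecutive_offtarget_stop) {
      stop_reason <- "CONSECUTIVE_OFFTARGET"
      stop_rank <- i
      break
    }
  }
  retained <- hits[retained_idx, , drop = FALSE]
  if (!"rank" %in% names(retained)) retained$rank <- retained_idx - 1L
  structure(
    list(retained = as_tibble(retained), stop_reason = stop_reason,
         stop_rank = as.integer(stop_rank)),
    class = "candidate_set"
  )
}

#' @export
print.candidate_set <- function(x, ...) {
  cat("<candidate set>\n")
  cat("  retained hits:", nrow(x$retained), "\n")
  cat("  stop reason:", x$stop_reason, "at rank", x$stop_rank, "\n")
  invisible(x)
}

stop_codons <- c("TAA", "TAG", "TGA")

#' Complete an open reading frame by bounded genomic extension
#'
#' Starting from a hit interval (0-based half-open, frame taken from the
#' interval start), searches upstream — up to `orf_extension_nt` — for the
#' farthest in-frame ATG not separated from the hit by an in-frame stop, and
#' downstream — up to `orf_extension_nt` beyond the interval — for the first
#' in-frame stop codon. When several starts exist the farthest (longest open
#' frame) is chosen; the completed coding region is translated, excluding
#' the stop. On the reverse strand the same procedure runs on the reverse
#' complement. Window exhaustion yields an incompletion (`NO_START` /
#' `NO_STOP`), not an error.
#'
#' @param genomic Nucleotide string (A/C/G/T).
#' @param start,end Hit interval, 0-based half-open, forward-strand
#'   coordinates.
#' @param strand `"+"` or `"-"`.
#' @param config A [pipeline_config()] supplying `orf_extension_nt`.
#' @return A list of class `orf_result`: `status` (`"complete"` or
#'   `"incomplete"`), `reason` (`NA`, `"NO_START"` or `"NO_STOP"`),
#'   `protein` (amino-acid string or `NA`), and `cds_start`/`cds_end` (the
#'   coding interval including the stop codon, forward-strand coordinates).
#' @export
complete_orf <- function(genomic, start, end, strand = c("+", "-"),
                         config = pipeline_config()) {
  strand <- match.arg(strand)
  genomic <- toupper(as.character(genomic))
  glen <- nchar(genomic)
  if (start < 0 || end > glen || start >= end) {
    abort("hit interval out of bounds.")
  }
  if (strand == "-") {
    genomic <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(genomic)))
    tmp <- c(glen - end, glen - start)
    start <- tmp[1]; end <- tmp[2]
  }
  ext <- config$orf_extension_nt
  codon_at <- function(p) substr(genomic, p + 1, p + 3)  # p 0-based

  # upstream: farthest in-frame ATG, blocked by the first in-frame stop
  best_start <- NA_integer_
  p <- start
  while (p >= 0 && start - p <= ext && p + 3 <= glen) {
    cd <- codon_at(p)
    if (p < start && cd %in% stop_codons) break
    if (cd == "ATG") best_start <- p
    p <- p - 3L
  }
  if (is.na(best_start)) {
    return(orf_result("incomplete", "NO_START", NA, NA, NA, strand, glen))
  }

  # downstream: first in-frame stop, window ends ext nt past the interval
  q <- best_start + 3L
  limit <- min(glen - 3L, end + ext - 3L)
  stop_at <- NA_integer_
  while (q <= limit) {
    if (codon_at(q) %in% stop_codons) {
      stop_at <- q
      break
    }
    q <- q + 3L
  }
  if (is.na(stop_at)) {
    return(orf_result("incomplete", "NO_STOP", NA, NA, NA, strand, glen))
  }

  cds <- substr(genomic, best_start + 1, stop_at)
  protein <- as.character(Biostrings::translate(Biostrings::DNAString(cds)))
  orf_result("complete", NA_character_, protein,
             best_start, stop_at + 3L, strand, glen)
}

orf_result <- function(status, reason, protein, cds_start, cds_end, strand, glen) {
  if (strand == "-" && status == "complete") {
    tmp <- c(glen - cds_end, glen - cds_start)
    cds_start <- tmp[1]; cds_end <- tmp[2]
  }
  structure(
    list(status = status, reason = reason, protein = protein,
         cds_start = cds_start, cds_end = cds_end, strand = strand),
    class = "orf_result"
  )
}

#' @export
print.orf_result <- function(x, ...) {
  cat("<ORF completion:", x$status,
      if (!is.na(x$reason)) paste0("(", x$reason, ")") else "", ">\n")
  if (x$status == "complete") {
    cat("  protein:", nchar(x$protein), "aa; CDS", x$cds_start, "-", x$cds_end,
        "strand", x$strand, "\n")
  }
  invisible(x)
}

#' Minimum-length filter for candidate proteins
#'
#' Partitions records into those with at least `min_len_aa` residues
#' (inclusive threshold; stop characters excluded from the count) and those
#' below it. The partition is exhaustive and disjoint.
#'
#' @param records A protein-record tibble.
#' @param config A [pipeline_config()] supplying `min_len_aa`.
#' @return A list with tibbles `kept` and `rejected`.
#' @export
length_filter <- function(records, config = pipeline_config()) {
  validate_protein_records(records)
  n_res <- nchar(gsub("*", "", records$sequence, fixed = TRUE))
  keep <- n_res >= config$min_len_aa
  list(kept = records[keep, , drop = FALSE],
       rejected = records[!keep, , drop = FALSE])
}
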