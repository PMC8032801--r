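#' Build a protein-record tibble
#'
#' The tabular currency for protein sequences in famflux: one row per
#' sequence with an identifier, species tag, amino-acid string, an optional
#' family/class label and a pseudogene flag. A record is flagged as a
#' pseudogene iff its sequence contains an internal stop (`*`); a terminal
#' `*` is stripped on construction.
#'
#' @param id Character vector of unique, non-empty identifiers.
#' @param sequence Character vector of amino-acid sequences (20 letters plus
#'   `X` and `*`), uppercased on construction.
#' @param species Species tag per record (recycled if length 1).
#' @param family_label Family/class label; `NA` when unassigned.
#'
#' @return A tibble with columns `id`, `species`, `sequence`, `family_label`,
#'   `pseudogene`.
#' @examples
#' protein_records(c("g1", "g2"), c("MKT", "MK*T"), species = "Dr")
#' @export
protein_records <- function(id, sequence, species = NA_character_,
                            family_label = NA_character_) {
  id <- as.character(id)
  sequence <- toupper(as.character(sequence))
  if (length(id) != length(sequence)) {
    abort("`id` and `sequence` must have the same length.")
  }
  if (any(!nzchar(id)) || anyNA(id)) abort("record ids must be non-empty.")
  if (anyDuplicated(id)) {
    abort(paste0("duplicate record id(s): ",
                 paste(unique(id[duplicated(id)]), collapse = ", ")))
  }
  sequence <- sub("\\*$", "", sequence)
  if (any(!nzchar(sequence))) abort("sequences must be non-empty.")
  # '-' permitted so aligned rows travel in the same tabular shape
  bad <- grepl("[^ACDEFGHIKLMNPQRSTVWYX*-]", sequence)
  if (any(bad)) {
    abort(paste0("invalid residue letters in record(s): ",
                 paste(id[bad], collapse = ", ")))
  }
  tibble(
    id = id,
    species = rep_len(as.character(species), length(id)),
    sequence = sequence,
    family_label = rep_len(as.character(family_label), length(id)),
    pseudogene = grepl("\\*", sequence)
  )
}

#' Read protein sequences from FASTA
#'
#' Headers are parsed as `id|species` (first two `|`-separated fields) or as
#' a bare id (species becomes `NA`). Sequences are uppercased; internal stop
#' codons (`*`) are preserved and set the pseudogene flag; a terminal `*` is
#' stripped.
#'
#' @param path Path to a FASTA file of amino-acid sequences.
#' @return A protein-record tibble (see [protein_records()]). An empty file
#'   yields a zero-row tibble.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">g1|Dr", "MKT"), f)
#' read_protein_fasta(f)
#' @export
read_protein_fasta <- function(path) {
  stopifnot(file.exists(path))
  if (file.size(path) == 0) {
    return(protein_records(character(), character()))
  }
  aa <- Biostrings::readAAStringSet(path)
  headers <- names(aa)
  if (is.null(headers) || any(!nzchar(trimws(headers)))) {
    abort(paste0("malformed FASTA header in ", path))
  }
  first_tok <- vapply(strsplit(trimws(headers), "\\s+"), `[[`, "", 1)
  parts <- strsplit(first_tok, "|", fixed = TRUE)
  ids <- vapply(parts, `[[`, "", 1)
  species <- vapply(parts, function(p) if (length(p) >= 2) p[[2]] else NA_character_, "")
  protein_records(ids, as.character(aa), species = species)
}

#' Write protein records to FASTA
#'
#' Headers are written as `id|species` when the species tag is present,
#' otherwise as the bare id.
#'
#' @param records A protein-record tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_protein_fasta <- function(records, path) {
  validate_protein_records(records)
  headers <- ifelse(is.na(records$species), records$id,
                    paste0(records$id, "|", records$species))
  aa <- Biostrings::AAStringSet(setNames(records$sequence, headers))
  Biostrings::writeXStringSet(aa, filepath = path)
  invisible(path)
}

validate_protein_records <- function(records, arg = "records") {
  if (!is.data.frame(records) ||
      !all(c("id", "sequence") %in% names(records))) {
    abort(sprintf("`%s` must be a protein-record tibble (columns id, sequence).", arg))
  }
  if (anyDuplicated(records$id)) abort(sprintf("`%s` has duplicate ids.", arg))
  invisible(records)
}
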