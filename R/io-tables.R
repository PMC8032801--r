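#' Read a species-by-family gene-count matrix
#'
#' Tab-separated: header row holds family tags, first column holds species
#' tags. Counts must be non-negative integers; any missing or malformed cell
#' is an error naming the offending species and family. Lines starting with
#' `#` are ignored.
#'
#' @param path Path to a TSV file.
#' @return A tibble whose first column is `species` and whose remaining
#'   integer columns are gene families.
#' @examples
#' counts <- taar_repertoire()
#' counts[counts$species == "Cc", ]
#' @export
read_count_matrix <- function(path) {
  stopifnot(file.exists(path))
  df <- readr::read_tsv(path, comment = "#", col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  if (ncol(df) < 1) abort("count matrix needs at least a species column.")
  names(df)[1] <- "species"
  if (anyDuplicated(df$species)) abort("duplicate species tags in count matrix.")
  if (anyDuplicated(names(df))) abort("duplicate family tags in count matrix.")
  fam <- setdiff(names(df), "species")
  for (f in fam) {
    v <- df[[f]]
    bad <- is.na(v) | !grepl("^[0-9]+$", v)
    if (any(bad)) {
      abort(sprintf("invalid count for species '%s', family '%s'.",
                    df$species[which(bad)[1]], f))
    }
    df[[f]] <- as.integer(v)
  }
  as_tibble(df)
}

#' Write a count matrix to TSV
#' @param counts Count tibble as returned by [read_count_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(counts, path) {
  validate_count_matrix(counts)
  readr::write_tsv(counts, path, progress = FALSE)
  invisible(path)
}

validate_count_matrix <- function(counts) {
  if (!is.data.frame(counts) || names(counts)[1] != "species") {
    abort("`counts` must be a tibble with first column `species`.")
  }
  fam <- setdiff(names(counts), "species")
  for (f in fam) {
    v <- counts[[f]]
    if (anyNA(v) || any(v < 0) || any(v != as.integer(v))) {
      abort(sprintf("family '%s' has negative, missing or non-integer counts.", f))
    }
  }
  if (anyDuplicated(counts$species)) abort("duplicate species tags.")
  invisible(counts)
}

hit_flags <- c("TARGET_CLASS", "OTHER", "UNKNOWN")

#' Read a ranked homology-hit table
#'
#' Tab-separated with columns `query`, `subject`, `start`, `end`, `strand`,
#' `evalue`, `class_flag`. Coordinates are 0-based half-open on the forward
#' strand; `strand` is `+` or `-`; `class_flag` is one of `TARGET_CLASS`,
#' `OTHER`, `UNKNOWN`. Rows must be sorted by ascending e-value (the order in
#' which a homology search reports them); this is validated, not repaired.
#'
#' @param path Path to a TSV file.
#' @return A hit-table tibble with an added 0-based `rank` column.
#' @export
read_hit_table <- function(path) {
  stopifnot(file.exists(path))
  df <- readr::read_tsv(
    path, comment = "#", progress = FALSE,
    col_types = readr::cols(
      query = readr::col_character(), subject = readr::col_character(),
      start = readr::col_integer(), end = readr::col_integer(),
      strand = readr::col_character(), evalue = readr::col_double(),
      class_flag = readr::col_character()
    )
  )
  validate_hit_table(df)
  df$rank <- seq_len(nrow(df)) - 1L
  as_tibble(df)
}

validate_hit_table <- function(hits) {
  need <- c("query", "subject", "start", "end", "strand", "evalue", "class_flag")
  if (!is.data.frame(hits) || !all(need %in% names(hits))) {
    abort(paste0("hit table must have columns: ", paste(need, collapse = ", ")))
  }
  if (nrow(hits) == 0) return(invisible(hits))
  if (any(hits$start >= hits$end)) abort("hit intervals must satisfy start < end.")
  if (any(hits$evalue <= 0)) abort("e-values must be positive.")
  if (!all(hits$strand %in% c("+", "-"))) abort("strand must be '+' or '-'.")
  if (!all(hits$class_flag %in% hit_flags)) {
    abort(paste0("class_flag must be one of ", paste(hit_flags, collapse = ", ")))
  }
  if (is.unsorted(hits$evalue)) {
    abort("hit table rows must be sorted by ascending e-value.")
  }
  invisible(hits)
}

#' Packaged repertoire matrix of taar/tarl gene counts
#'
#' The published species-by-family count matrix of `tarl`, `taar12`, `taar13`
#' and other class II `taar` genes across 76 aquatic vertebrate genomes,
#' transcribed as printed (including the channel-catfish `taar13` count of 8,
#' which disagrees with the running text's "seven"; the printed table wins
#' and the discrepancy is preserved, not corrected).
#'
#' @return A count tibble (`species`, `tarl`, `taar12`, `taar13`, `other`).
#' @export
taar_repertoire <- function() {
  read_count_matrix(famflux_extdata("table1_counts.tsv"))
}

#' Species metadata for the packaged repertoire matrix
#'
#' Maps each species abbreviation to its scientific name and phylogenetic
#' group (including whether it belongs to Percomorphaceae, the clade over
#' which taar13 loss events are counted).
#'
#' @return A tibble with columns `species`, `scientific_name`,
#'   `vernacular_name`, `group`, `percomorphaceae` (logical).
#' @export
taar_species_groups <- function() {
  readr::read_tsv(famflux_extdata("table1_species.tsv"), comment = "#",
                  col_types = readr::cols(
                    percomorphaceae = readr::col_logical(),
                    .default = readr::col_character()
                  ),
                  progress = FALSE)
}

#' Species tree for the packaged repertoire matrix
#'
#' A rooted topology over the 76 repertoire species, hand-encoded from
#' published fish phylogenies (lampreys, cartilaginous fish, then ray-finned
#' fish through to Percomorphaceae). Branch lengths are not meaningful; the
#' gain/loss machinery uses topology only. The encoding is the package's own
#' synthetic reconstruction, shipped as
#' `extdata/species_tree_synthetic.nwk`.
#'
#' @return A `phylo` object with the repertoire species abbreviations as
#'   tip labels.
#' @export
taar_species_tree <- function() {
  read_newick(famflux_extdata("species_tree_synthetic.nwk"))
}

famflux_extdata <- function(file) {
  path <- system.file("extdata", file, package = "famflux")
  if (!nzchar(path)) abort(paste0("packaged file not found: ", file))
  path
}
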