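#' Pipeline configuration
#'
#' Bundles the numeric thresholds of the annotation pipeline. Defaults are the
#' values used throughout receptor repertoire mining: a 200-aa minimum
#' candidate length, an e-value search floor of 1e-10, a stop after ten
#' consecutive off-target hits, up to 2 kb of genomic extension per direction
#' when completing an open reading frame, gap-column stripping at the 90%
#' tolerance level, and an 85% identity floor for the jawed-fish TARL
#' shortcut.
#'
#' @param min_len_aa Minimum candidate length in amino acids (inclusive).
#' @param evalue_stop E-value floor: scanning a ranked hit table stops before
#'   the first row whose e-value exceeds this threshold.
#' @param consecutive_offtarget_stop Number of consecutive off-target hits
#'   that terminates the scan.
#' @param orf_extension_nt Maximum genomic extension (nucleotides, each
#'   direction) when searching for start/stop codons.
#' @param gap_tolerance Fraction of gaps at which an alignment column is
#'   removed (a column is dropped iff its gap fraction is `>=` this value).
#' @param tarl_identity_floor Identity fraction above which a candidate passes
#'   the TARL similarity screen.
#' @param seed Integer seed recorded in the config for downstream use.
#'
#' @return A list of class `famflux_config`.
#' @examples
#' cfg <- pipeline_config()
#' cfg$min_len_aa
#' @export
pipeline_config <- function(min_len_aa = 200L,
                            evalue_stop = 1e-10,
                            consecutive_offtarget_stop = 10L,
                            orf_extension_nt = 2000L,
                            gap_tolerance = 0.90,
                            tarl_identity_floor = 0.85,
                            seed = 1L) {
  stopifnot(
    min_len_aa >= 1, evalue_stop > 0,
    consecutive_offtarget_stop >= 1, orf_extension_nt >= 0,
    gap_tolerance > 0, gap_tolerance <= 1,
    tarl_identity_floor > 0, tarl_identity_floor <= 1
  )
  structure(
    list(
      min_len_aa = as.integer(min_len_aa),
      evalue_stop = evalue_stop,
      consecutive_offtarget_stop = as.integer(consecutive_offtarget_stop),
      orf_extension_nt = as.integer(orf_extension_nt),
      gap_tolerance = gap_tolerance,
      tarl_identity_floor = tarl_identity_floor,
      seed = as.integer(seed)
    ),
    class = "famflux_config"
  )
}

#' @export
print.famflux_config <- function(x, ...) {
  cat("<famflux pipeline config>\n")
  for (nm in names(x)) cat(sprintf("  %-27s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
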