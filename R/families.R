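## The ten universal single-copy marker gene (MG) families used for mOTU
## construction and profiling.  Exactly ten labels per database; unknown
## labels are rejected at parse time.

.MG_FAMILIES <- c(
  "COG0012", "COG0016", "COG0018", "COG0172", "COG0215",
  "COG0495", "COG0525", "COG0533", "COG0541", "COG0552"
)

#' Marker gene family labels
#'
#' The ten universal, single-copy, protein-coding phylogenetic marker gene
#' families on which mOTU databases are built.  All sequence input is keyed
#' by these labels.
#'
#' @return Character vector of the 10 family identifiers.
#' @export
#' @examples
#' mg_families()
mg_families <- function() .MG_FAMILIES

.check_family <- function(family) {
  bad <- setdiff(family, .MG_FAMILIES)
  if (length(bad) > 0) {
    stop("unknown family label(s): ", paste(unique(bad), collapse = ", "))
  }
  invisible(family)
}
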