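#' The Yfiler 16-locus Y-STR panel
#'
#' Locus names of the AmpFlSTR Yfiler panel in the canonical table order
#' used throughout the package. `DYS385` is a duplicated (multi-copy) locus
#' typed as an unordered pair of alleles; all other loci are nominally
#' single-copy, though duplicated patterns (two alleles) occur in some males
#' and are representable.
#'
#' Sub-panels:
#' \describe{
#'   \item{full}{all 16 loci.}
#'   \item{minimal}{the European minimal haplotype: DYS19, DYS389I,
#'     DYS389II, DYS390, DYS391, DYS392, DYS393 and DYS385.}
#'   \item{swgdam}{the minimal haplotype plus the SWGDAM-recommended
#'     DYS438 and DYS439.}
#' }
#'
#' @param which Panel selector: `"full"` (default), `"minimal"` or
#'   `"swgdam"`.
#' @return Character vector of locus names.
#' @examples
#' ystr_panel()
#' ystr_panel("minimal")
#' @export
ystr_panel <- function(which = c("full", "minimal", "swgdam")) {
  which <- match.arg(which)
  full <- c("DYS456", "DYS389I", "DYS390", "DYS389II", "DYS458", "DYS19",
            "DYS385", "DYS393", "DYS391", "DYS439", "DYS635", "DYS392",
            "YGATAH4", "DYS437", "DYS438", "DYS448")
  minimal <- c("DYS19", "DYS389I", "DYS389II", "DYS390", "DYS391", "DYS392",
               "DYS393", "DYS385")
  switch(which,
         full = full,
         minimal = minimal,
         swgdam = c(minimal, "DYS438", "DYS439"))
}

#' @rdname ystr_panel
#' @export
multi_copy_loci <- function() "DYS385"

# Accepted spellings for locus names (upper-cased, spaces/hyphens stripped).
# Y-GATA-H4 is printed "YGATAH" in some tables.
locus_alias_map <- function() {
  panel <- ystr_panel()
  aliases <- c(stats::setNames(panel, panel),
               YGATAH = "YGATAH4", YGATAH4 = "YGATAH4")
  aliases
}

#' Normalize a locus name to its canonical panel token
#'
#' Accepts the canonical tokens plus common aliases (`"YGATAH"`,
#' `"Y GATA H4"`, `"Y-GATA-H4"` for `YGATAH4`), case-insensitively.
#'
#' @param x Character vector of locus names.
#' @return Character vector of canonical tokens.
#' @export
normalize_locus <- function(x) {
  key <- gsub("[ _-]", "", toupper(as.character(x)))
  map <- locus_alias_map()
  out <- unname(map[key])
  if (anyNA(out)) {
    bad <- unique(x[is.na(out)])
    stop("unknown locus name(s): ", paste(bad, collapse = ", "),
         "; panel loci are ", paste(ystr_panel(), collapse = ", "),
         call. = FALSE)
  }
  out
}
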