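#' Packaged study populations
#'
#' The three haplotype tables of a published O'Brien surname study, shipped
#' as plain CSV in `inst/extdata` and read through [read_population()]:
#' \describe{
#'   \item{obrien}{10 males of Irish paternal descent with surname O'Brien
#'     (OB1--OB9, OB11). OB5/OB6 share one coincidental haplotype; OB9 and
#'     OB11 carry the Dal Riata founder signature (DYS389II excepted). OB9
#'     shows a duplicated pattern \{15,16\} at the nominally single-copy
#'     locus DYS437.}
#'   \item{irish}{10 general-population Irish males (I1--I9, I11); I9
#'     carries the Dal Riata signature (DYS389II excepted).}
#'   \item{control}{22 control males of mixed ancestry (C1--C9, C11--C18,
#'     C20, C23--C25, C28). C17/C18 are a known father--son pair with
#'     identical haplotypes; C6/C7 carry the Dal Riata signature (DYS389II
#'     excepted). C7, C11 and C15 have a single recorded allele at DYS385.}
#' }
#'
#' @param name One of `"obrien"`, `"irish"`, `"control"`.
#' @return A [population()].
#' @examples
#' ob <- ystr_fixture("obrien")
#' length(ob)
#' @export
ystr_fixture <- function(name = c("obrien", "irish", "control")) {
  if (!is.character(name) || length(name) != 1L ||
      !name %in% c("obrien", "irish", "control")) {
    stop("unknown fixture population '", paste(name, collapse = ","),
         "'; valid names are obrien, irish, control", call. = FALSE)
  }
  path <- system.file("extdata", paste0(name, ".csv"), package = "ystrtools",
                      mustWork = TRUE)
  read_population(path, name = name)
}

#' Packaged founder signatures
#'
#' Three founder signatures used to classify samples by ancestral paternal
#' origin:
#' \describe{
#'   \item{dal_riata}{the ancestral haplotype of the Dal Riata, an
#'     early-medieval Gaelic overkingdom (~500 AD):
#'     13-25-14-11-13-16 over DYS393, DYS390, DYS19, DYS391, DYS389I,
#'     DYS389II. The DYS389II value is stored exactly as published even
#'     though study tables report 28--33 at that locus; classification
#'     conventionally ignores DYS389II (see [classify_population()]).}
#'   \item{obrien_footprint}{the 14-locus O'Brien surname-project genetic
#'     footprint 13-24-29-17-14-(11,14)-13-11-11-13-11-15-12-19 over
#'     DYS389I, DYS390, DYS389II, DYS458, DYS19, DYS385, DYS393, DYS391,
#'     DYS439, DYS392, YGATAH4, DYS437, DYS438, DYS448.}
#'   \item{sykes}{the Sykes surname footprint 15-23-11-14 over DYS19,
#'     DYS390, DYS391, DYS393.}
#' }
#'
#' @param name One of `"dal_riata"`, `"obrien_footprint"`, `"sykes"`.
#' @return A [founder_signature()].
#' @examples
#' ystr_signature_fixture("dal_riata")
#' @export
ystr_signature_fixture <- function(name = c("dal_riata", "obrien_footprint",
                                            "sykes")) {
  if (!is.character(name) || length(name) != 1L ||
      !name %in% c("dal_riata", "obrien_footprint", "sykes")) {
    stop("unknown fixture signature '", paste(name, collapse = ","),
         "'; valid names are dal_riata, obrien_footprint, sykes",
         call. = FALSE)
  }
  path <- system.file("extdata", paste0("signature_", name, ".csv"),
                      package = "ystrtools", mustWork = TRUE)
  read_signature(path)
}
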