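#' Construct an allele set
#'
#' An allele set is the multiset of repeat-count alleles observed at one
#' locus in one male: a single allele at a single-copy locus, an unordered
#' pair at the duplicated locus DYS385 or at a single-copy locus showing a
#' duplicated pattern. Allele designations are numeric repeat counts,
#' optionally with a decimal microvariant part (e.g. 13.2). Order is
#' irrelevant: `allele_set(14, 11)` equals `allele_set(11, 14)`.
#'
#' @param ... Numeric allele designations (or a single numeric vector).
#' @return Sorted numeric vector of class `allele_set`.
#' @examples
#' allele_set(11, 14)
#' allele_set(c(15, 16))
#' @export
allele_set <- function(...) {
  x <- unlist(list(...), use.names = FALSE)
  x <- suppressWarnings(as.numeric(x))
  if (length(x) == 0L || anyNA(x) || any(x <= 0)) {
    stop("an allele set is a non-empty set of positive numeric repeat counts",
         call. = FALSE)
  }
  structure(sort(x), class = "allele_set")
}

#' @export
print.allele_set <- function(x, ...) {
  cat("<allele set> {", format_alleles(x, sep = ","), "}\n", sep = "")
  invisible(x)
}

#' @export
format.allele_set <- function(x, ...) format_alleles(x, sep = ",")

# "13" not "13.0"; microvariants keep their decimal part ("13.2")
format_alleles <- function(x, sep = ";") {
  paste(vapply(unclass(x), function(a) {
    if (a == round(a)) sprintf("%d", as.integer(a)) else sub("0+$", "", sprintf("%.4f", a))
  }, character(1)), collapse = sep)
}

# multiset equality, order-insensitive
same_alleles <- function(a, b) {
  a <- sort(as.numeric(a)); b <- sort(as.numeric(b))
  length(a) == length(b) && all(a == b)
}

#' Construct a Y-STR haplotype
#'
#' @param sample_id Sample identifier (non-empty string).
#' @param loci Named list mapping every panel locus to an allele set
#'   (numeric vectors are accepted and converted). All 16 panel loci must be
#'   present; locus names may use accepted aliases.
#' @param metadata Optional named list of free-text sample metadata
#'   (e.g. `surname_group`, `ethnicity`, `paternal_origin_country`,
#'   `paternal_origin_county`, `birthplace`).
#' @return Object of class `ystr_haplotype`.
#' @examples
#' loci <- as.list(stats::setNames(rep(12, 16), ystr_panel()))
#' loci$DYS385 <- c(11, 14)
#' h <- haplotype("S1", loci)
#' @export
haplotype <- function(sample_id, loci, metadata = list()) {
  stopifnot(is.character(sample_id), length(sample_id) == 1L, nzchar(sample_id))
  if (is.null(names(loci)) || any(!nzchar(names(loci)))) {
    stop("'loci' must be a named list", call. = FALSE)
  }
  names(loci) <- normalize_locus(names(loci))
  panel <- ystr_panel()
  missing <- setdiff(panel, names(loci))
  if (length(missing)) {
    stop("haplotype ", sample_id, " is missing panel loci: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  loci <- lapply(loci[panel], function(v) allele_set(v))
  structure(list(sample_id = sample_id, loci = loci,
                 metadata = as.list(metadata)),
            class = "ystr_haplotype")
}

#' @export
print.ystr_haplotype <- function(x, ...) {
  cat("<Y-STR haplotype> ", x$sample_id, "\n", sep = "")
  vals <- vapply(x$loci, format_alleles, character(1), sep = ",")
  cat(paste0("  ", format(names(vals)), "  ", vals), sep = "\n")
  if (length(x$metadata)) {
    keep <- !vapply(x$metadata, function(v) is.null(v) || !nzchar(as.character(v)[1]),
                    logical(1))
    if (any(keep)) {
      cat("  metadata: ",
          paste(names(x$metadata)[keep],
                vapply(x$metadata[keep], as.character, character(1)),
                sep = "=", collapse = "; "), "\n", sep = "")
    }
  }
  invisible(x)
}

#' Construct a population of haplotypes
#'
#' A named, ordered collection of [haplotype()] objects (a study group such
#' as a surname sample, a general-population sample or a control group).
#' Sample identifiers must be unique within a population.
#'
#' @param name Population name.
#' @param members List of `ystr_haplotype` objects.
#' @return Object of class `ystr_population`.
#' @export
population <- function(name, members = list()) {
  stopifnot(is.character(name), length(name) == 1L)
  ok <- vapply(members, inherits, logical(1), what = "ystr_haplotype")
  if (!all(ok)) stop("all members must be ystr_haplotype objects", call. = FALSE)
  ids <- vapply(members, `[[`, character(1), "sample_id")
  if (anyDuplicated(ids)) {
    stop("duplicate sample_id in population '", name, "': ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  structure(list(name = name, members = stats::setNames(members, ids)),
            class = "ystr_population")
}

#' @export
length.ystr_population <- function(x) length(x$members)

#' @rdname population
#' @param x A `ystr_population`.
#' @export
sample_ids <- function(x) {
  stopifnot(inherits(x, "ystr_population"))
  unname(vapply(x$members, `[[`, character(1), "sample_id"))
}

#' @export
print.ystr_population <- function(x, ...) {
  cat("<Y-STR population> ", x$name, ": N = ", length(x), "\n", sep = "")
  if (length(x)) cat("  samples: ", paste(sample_ids(x), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.ystr_population <- function(x, ...) {
  population_to_frame(x, table_dialect())
}

#' Combine populations
#'
#' @param name Name for the combined population.
#' @param ... `ystr_population` objects.
#' @return A `ystr_population` with the members concatenated in order.
#' @export
combine_populations <- function(name, ...) {
  pops <- list(...)
  population(name, unlist(lapply(pops, `[[`, "members"), recursive = FALSE))
}

#' Construct a founder signature
#'
#' A founder signature (or "genetic footprint") is a partial haplotype over
#' a subset of panel loci, characteristic of a founding paternal lineage or
#' surname group, used to classify samples by ancestral origin.
#'
#' @param name Signature name.
#' @param loci Named list mapping a subset of panel loci to allele sets.
#' @return Object of class `ystr_signature`.
#' @examples
#' founder_signature("toy", list(DYS19 = 14, DYS393 = 13))
#' @export
founder_signature <- function(name, loci) {
  stopifnot(is.character(name), length(name) == 1L, length(loci) >= 0L)
  if (length(loci)) {
    names(loci) <- normalize_locus(names(loci))
    if (anyDuplicated(names(loci))) stop("duplicate signature loci", call. = FALSE)
    loci <- lapply(loci, allele_set)
  }
  structure(list(name = name, loci = loci), class = "ystr_signature")
}

#' @export
print.ystr_signature <- function(x, ...) {
  cat("<founder signature> ", x$name, " (", length(x$loci), " loci)\n", sep = "")
  if (length(x$loci)) {
    vals <- vapply(x$loci, format_alleles, character(1), sep = ",")
    cat("  ", paste(names(vals), vals, sep = "=", collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
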