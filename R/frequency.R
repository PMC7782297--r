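#' Counting-method haplotype frequency
#'
#' The "frequentist approach" recommended by the ISFG DNA Commission for
#' Y-chromosome match statistics: the frequency of a haplotype is X/N,
#' where X is the number of database samples carrying an identical
#' haplotype over the panel and N is the database size. No confidence
#' interval and no database augmentation such as (X+1)/(N+1) is applied;
#' the plain counting estimate is reported.
#'
#' @param query A [haplotype()].
#' @param pop Database [population()] to count in (N >= 1).
#' @inheritParams percent_similarity
#' @return Object of class `ystr_frequency` with fields `X`, `N`,
#'   `frequency` and (when X > 0) `one_in_n`, the rounded integer n with
#'   frequency ~ 1/n.
#' @examples
#' ob <- ystr_fixture("obrien")
#' haplotype_frequency(ob$members$OB5, ob)  # X = 2 of N = 10
#' @export
haplotype_frequency <- function(query, pop, panel = "full", mask = character()) {
  stopifnot(inherits(query, "ystr_haplotype"), inherits(pop, "ystr_population"))
  if (length(pop) < 1L) stop("population is empty", call. = FALSE)
  X <- sum(vapply(pop$members, function(h) {
    percent_similarity(query, h, panel = panel, mask = mask)$percent == 100
  }, logical(1)))
  N <- length(pop)
  structure(list(query_id = query$sample_id, population = pop$name,
                 X = X, N = N, frequency = X / N,
                 one_in_n = if (X > 0) as.integer(floor(N / X + 0.5)) else NA_integer_),
            class = "ystr_frequency")
}

#' Format a frequency estimate as "1 in n individuals"
#'
#' @param freq A `ystr_frequency` from [haplotype_frequency()], or a bare
#'   frequency in (0, 1].
#' @return `"1 in n"`, with n = 1/frequency rounded half-up to an integer;
#'   `"not observed"` when the frequency is zero (never a division by zero).
#' @examples
#' format_one_in_n(0.2)  # "1 in 5"
#' @export
format_one_in_n <- function(freq) {
  f <- if (inherits(freq, "ystr_frequency")) freq$frequency else as.numeric(freq)
  stopifnot(length(f) == 1L, !is.na(f), f >= 0, f <= 1)
  if (f == 0) return("not observed")
  paste("1 in", floor(1 / f + 0.5))
}

#' @export
print.ystr_frequency <- function(x, ...) {
  cat(sprintf("<haplotype frequency> %s in '%s': X = %d, N = %d, X/N = %.4g (%s)\n",
              x$query_id, x$population, x$X, x$N, x$frequency,
              format_one_in_n(x)))
  invisible(x)
}

#' Allele frequencies at one locus
#'
#' In `exact` mode, each distinct allele set (e.g. the DYS385 pair
#' \{11,14\}, or a duplicated pattern \{15,16\}) is one key and a sample
#' counts towards the key its whole allele set equals; the percentages sum
#' to 100. In `carrier` mode each single allele is a key and a sample
#' counts towards every allele it carries, so percentages may sum to more
#' than 100 at multi-allele loci.
#'
#' @param pop A [population()] (N >= 1).
#' @param locus A panel locus name.
#' @param mode `"exact"` (default) or `"carrier"`.
#' @return Named numeric vector of percentages (names are allele-set
#'   strings such as `"14"` or `"11;14"` in exact mode, single alleles in
#'   carrier mode), sorted by decreasing percentage with ties broken by
#'   smallest allele value.
#' @examples
#' allele_frequency(ystr_fixture("obrien"), "DYS19")
#' @export
allele_frequency <- function(pop, locus, mode = c("exact", "carrier")) {
  stopifnot(inherits(pop, "ystr_population"))
  if (length(pop) < 1L) stop("population is empty", call. = FALSE)
  mode <- match.arg(mode)
  locus <- normalize_locus(locus)
  N <- length(pop)
  keys <- if (mode == "exact") {
    vapply(pop$members, function(h) format_alleles(h$loci[[locus]]), character(1))
  } else {
    unlist(lapply(pop$members, function(h) {
      unique(vapply(unclass(h$loci[[locus]]), format_alleles, character(1)))
    }), use.names = FALSE)
  }
  counts <- table(keys)
  pct <- 100 * as.numeric(counts) / N
  names(pct) <- names(counts)
  # decreasing percent, ties by smallest leading allele value
  lead <- vapply(strsplit(names(pct), ";", fixed = TRUE),
                 function(v) as.numeric(v[1]), numeric(1))
  pct[order(-pct, lead)]
}

#' Modal allele set at one locus
#'
#' The most common exact-mode allele set, with its percentage of the
#' population; ties are broken by the smallest allele value (deterministic
#' but arbitrary).
#'
#' @inheritParams allele_frequency
#' @return List with `alleles` (an [allele_set()]), `percent`, and `locus`.
#' @examples
#' modal_allele(ystr_fixture("obrien"), "DYS393")  # {13} at 90%
#' @export
modal_allele <- function(pop, locus) {
  freq <- allele_frequency(pop, locus, mode = "exact")
  top <- names(freq)[1]
  list(locus = normalize_locus(locus),
       alleles = allele_set(as.numeric(strsplit(top, ";", fixed = TRUE)[[1]])),
       percent = unname(freq[1]))
}

#' Per-locus allele sharing with a founder signature
#'
#' For every locus the signature covers, the percentage of population
#' members whose allele set at that locus exactly equals the signature's
#' ([locus_match()]); a duplicated pattern such as \{15,16\} does not count
#' as carrying 15. Quantifies how much of a founder "genetic footprint"
#' remains in a sampled group.
#'
#' @param pop A [population()] (N >= 1).
#' @param sig A non-empty [founder_signature()].
#' @return Object of class `ystr_sharing`: list with `signature_name`, `N`,
#'   and `per_locus`, a named numeric vector of percentages over the
#'   signature's loci in signature order.
#' @examples
#' footprint_sharing(ystr_fixture("obrien"), ystr_signature_fixture("obrien_footprint"))
#' @export
footprint_sharing <- function(pop, sig) {
  stopifnot(inherits(pop, "ystr_population"), inherits(sig, "ystr_signature"))
  if (length(pop) < 1L) stop("population is empty", call. = FALSE)
  if (length(sig$loci) == 0L) stop("signature is empty", call. = FALSE)
  per_locus <- vapply(names(sig$loci), function(L) {
    100 * sum(vapply(pop$members, function(h) {
      locus_match(h$loci[[L]], sig$loci[[L]])
    }, logical(1))) / length(pop)
  }, numeric(1))
  structure(list(signature_name = sig$name, N = length(pop),
                 per_locus = per_locus),
            class = "ystr_sharing")
}

#' @export
print.ystr_sharing <- function(x, ...) {
  cat("<footprint sharing> signature '", x$signature_name, "', N = ", x$N,
      "\n", sep = "")
  cat(paste0("  ", format(names(x$per_locus)), "  ",
             sprintf("%g%%", x$per_locus)), sep = "\n")
  invisible(x)
}

#' Does a haplotype match a founder signature?
#'
#' True if and only if every signature locus not listed in `ignore` matches
#' the haplotype exactly (allele-multiset equality). An empty signature
#' matches vacuously.
#'
#' @param h A [haplotype()] covering the signature's loci.
#' @param sig A [founder_signature()].
#' @param ignore Character vector of loci to exclude from the comparison.
#'   Published Dal Riata classifications ignore DYS389II.
#' @return `TRUE` or `FALSE`.
#' @examples
#' ob <- ystr_fixture("obrien")
#' matches_signature(ob$members$OB9, ystr_signature_fixture("dal_riata"),
#'                   ignore = "DYS389II")
#' @export
matches_signature <- function(h, sig, ignore = character()) {
  stopifnot(inherits(h, "ystr_haplotype"), inherits(sig, "ystr_signature"))
  loci <- setdiff(names(sig$loci),
                  if (length(ignore)) normalize_locus(ignore) else character())
  all(vapply(loci, function(L) {
    if (is.null(h$loci[[L]])) stop("haplotype ", h$sample_id,
                                   " does not cover signature locus ", L,
                                   call. = FALSE)
    locus_match(h$loci[[L]], sig$loci[[L]])
  }, logical(1)))
}

#' Classify a population against a founder signature
#'
#' Lists every member for which [matches_signature()] holds.
#'
#' @param pop A [population()].
#' @inheritParams matches_signature
#' @return Object of class `ystr_classification`: list with
#'   `signature_name`, `ignored_loci`, `matching_sample_ids`, `match_count`
#'   and `N`.
#' @examples
#' classify_population(ystr_fixture("control"),
#'                     ystr_signature_fixture("dal_riata"),
#'                     ignore = "DYS389II")
#' @export
classify_population <- function(pop, sig, ignore = character()) {
  stopifnot(inherits(pop, "ystr_population"), inherits(sig, "ystr_signature"))
  hits <- if (length(pop)) {
    vapply(pop$members, matches_signature, logical(1), sig = sig, ignore = ignore)
  } else logical(0)
  ids <- sample_ids(pop)[hits]
  structure(list(signature_name = sig$name,
                 ignored_loci = if (length(ignore)) normalize_locus(ignore) else character(),
                 matching_sample_ids = ids, match_count = length(ids),
                 N = length(pop)),
            class = "ystr_classification")
}

#' @export
print.ystr_classification <- function(x, ...) {
  cat("<signature classification> '", x$signature_name, "': ",
      x$match_count, " of ", x$N, " samples match", sep = "")
  if (length(x$ignored_loci)) {
    cat(" (ignoring ", paste(x$ignored_loci, collapse = ", "), ")", sep = "")
  }
  cat("\n")
  if (x$match_count) {
    cat("  matches: ", paste(x$matching_sample_ids, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
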