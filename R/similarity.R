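#' Locus-level allele-set match
#'
#' Two allele sets match if and only if they are identical as multisets:
#' both alleles of a pair must match, and a duplicated pattern such as
#' \{15,16\} never matches a single allele \{15\}. This binary rule is what
#' pairwise percent similarity, haplotype frequency and signature matching
#' are built on; no partial credit and no mutation-step weighting.
#'
#' @param a,b Allele sets (numeric vectors or [allele_set()] objects).
#' @return `TRUE` or `FALSE`.
#' @examples
#' locus_match(c(11, 14), c(14, 11))  # TRUE: order-insensitive
#' locus_match(c(15, 16), 15)         # FALSE: duplication vs single allele
#' @export
locus_match <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) {
    stop("allele sets must be non-empty", call. = FALSE)
  }
  same_alleles(a, b)
}

# half-up rounding to 2 decimals (round() would round half to even)
round2 <- function(x) floor(x * 100 + 0.5) / 100

resolve_panel <- function(panel) {
  if (is.character(panel) && length(panel) == 1L &&
      panel %in% c("full", "minimal", "swgdam")) {
    ystr_panel(panel)
  } else {
    normalize_locus(panel)
  }
}

#' Pairwise percent similarity of two haplotypes
#'
#' Counts the panel loci at which the two haplotypes carry identical allele
#' sets ([locus_match()]) and reports 100 x matched/compared, rounded
#' half-up to two decimals. On the default 16-locus panel every reachable
#' value is an exact multiple of 6.25, so rounding never changes a result.
#'
#' @param h1,h2 [haplotype()] objects.
#' @param panel Loci to compare: a panel selector (`"full"`, `"minimal"`,
#'   `"swgdam"`) or a character vector of locus names.
#' @param mask Loci to exclude from the comparison; the denominator shrinks
#'   accordingly (a masked locus is not a mismatch).
#' @return Object of class `ystr_similarity` with fields `sample_a`,
#'   `sample_b`, `matched_loci`, `compared_loci`, `percent`.
#' @examples
#' ob <- ystr_fixture("obrien")
#' percent_similarity(ob$members$OB1, ob$members$OB2)
#' @export
percent_similarity <- function(h1, h2, panel = "full", mask = character()) {
  stopifnot(inherits(h1, "ystr_haplotype"), inherits(h2, "ystr_haplotype"))
  panel <- setdiff(resolve_panel(panel),
                   if (length(mask)) normalize_locus(mask) else character())
  if (length(panel) == 0L) stop("empty comparison panel", call. = FALSE)
  absent <- setdiff(panel, union(names(h1$loci), names(h2$loci)))
  if (length(absent)) {
    stop("panel loci absent from haplotype: ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  matched <- sum(vapply(panel, function(L) {
    locus_match(h1$loci[[L]], h2$loci[[L]])
  }, logical(1)))
  structure(list(sample_a = h1$sample_id, sample_b = h2$sample_id,
                 matched_loci = matched, compared_loci = length(panel),
                 percent = round2(100 * matched / length(panel))),
            class = "ystr_similarity")
}

#' @export
print.ystr_similarity <- function(x, ...) {
  cat(sprintf("%s vs %s: %d/%d loci match, %.2f%% similarity\n",
              x$sample_a, x$sample_b, x$matched_loci, x$compared_loci,
              x$percent))
  invisible(x)
}

#' Pairwise percent-similarity matrix of a population
#'
#' @param pop A [population()] with at least one member.
#' @inheritParams percent_similarity
#' @return Object of class `ystr_simmatrix`: a square symmetric numeric
#'   matrix of percent similarities (diagonal 100), with sample identifiers
#'   as dimnames. Printed as a lower triangle, the layout of published
#'   pairwise tables.
#' @examples
#' m <- similarity_matrix(ystr_fixture("obrien"))
#' m["OB5", "OB6"]
#' @export
similarity_matrix <- function(pop, panel = "full", mask = character()) {
  stopifnot(inherits(pop, "ystr_population"))
  n <- length(pop)
  if (n < 1L) stop("population is empty", call. = FALSE)
  ids <- sample_ids(pop)
  m <- matrix(100, n, n, dimnames = list(ids, ids))
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        p <- percent_similarity(pop$members[[i]], pop$members[[j]],
                                panel = panel, mask = mask)$percent
        m[i, j] <- m[j, i] <- p
      }
    }
  }
  structure(m, class = c("ystr_simmatrix", "matrix", "array"))
}

#' @export
print.ystr_simmatrix <- function(x, ...) {
  m <- unclass(x)
  out <- matrix("", nrow(m), ncol(m), dimnames = dimnames(m))
  out[lower.tri(m)] <- sprintf("%.2f", m[lower.tri(m)])
  cat("<pairwise percent similarity> ", nrow(m), " samples\n", sep = "")
  print(as.data.frame(out), right = TRUE)
  invisible(x)
}

#' @export
plot.ystr_simmatrix <- function(x, main = "Pairwise percent similarity", ...) {
  m <- unclass(x)
  n <- nrow(m)
  graphics::image(seq_len(n), seq_len(n), t(m[n:1, , drop = FALSE]),
                  axes = FALSE, xlab = "", ylab = "", zlim = c(0, 100),
                  main = main, ...)
  graphics::axis(1, at = seq_len(n), labels = colnames(m), las = 2, cex.axis = 0.8)
  graphics::axis(2, at = seq_len(n), labels = rev(rownames(m)), las = 2, cex.axis = 0.8)
  invisible(x)
}

#' Partition a population into full-haplotype identity classes
#'
#' Groups samples whose haplotypes are identical over the panel (pairwise
#' similarity 100). In forensic terms this measures how discriminating the
#' panel is in the sampled group: typically all classes are singletons
#' except known paternal relatives or coincidental matches.
#'
#' @inheritParams similarity_matrix
#' @return Object of class `ystr_identity_classes`: list with `classes`
#'   (list of character vectors of sample ids, in first-appearance order),
#'   `n_distinct` (number of distinct haplotypes) and `N`.
#' @examples
#' identity_classes(ystr_fixture("obrien"))
#' @export
identity_classes <- function(pop, panel = "full", mask = character()) {
  stopifnot(inherits(pop, "ystr_population"))
  if (length(pop) < 1L) stop("population is empty", call. = FALSE)
  panel <- setdiff(resolve_panel(panel),
                   if (length(mask)) normalize_locus(mask) else character())
  keys <- vapply(pop$members, function(h) {
    paste(vapply(panel, function(L) format_alleles(h$loci[[L]]), character(1)),
          collapse = "|")
  }, character(1))
  cls <- split(sample_ids(pop), factor(keys, levels = unique(keys)))
  structure(list(classes = unname(cls), n_distinct = length(cls),
                 N = length(pop)),
            class = "ystr_identity_classes")
}

#' @export
print.ystr_identity_classes <- function(x, ...) {
  cat("<identity classes> ", x$n_distinct, " distinct haplotypes among ",
      x$N, " samples\n", sep = "")
  shared <- Filter(function(cl) length(cl) > 1L, x$classes)
  if (length(shared)) {
    for (cl in shared) cat("  shared haplotype: ", paste(cl, collapse = ", "), "\n", sep = "")
  } else {
    cat("  all haplotypes unique\n")
  }
  invisible(x)
}
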