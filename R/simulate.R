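# Evaluate expr under a temporary RNG seed, restoring the caller's stream.
# seed = NULL draws from the current stream (used when a caller has already
# seeded a whole study).
local_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

#' Stepwise mutation model for Y-STR loci
#'
#' Single-step symmetric stepwise mutation: per meiosis each allele copy
#' mutates with its locus-specific probability, and a mutation changes the
#' repeat count by +1 or -1 with equal probability (floored at one repeat).
#' Multi-copy loci mutate each copy independently. The default rate of
#' 0.002 per locus per generation is of the order observed for Y-STRs.
#'
#' @param rate Default mutation probability per locus per meiosis.
#' @param per_locus Optional named numeric vector overriding the rate at
#'   specific loci.
#' @return Object of class `ystr_mutation_model`: named rate vector over
#'   the 16 panel loci.
#' @examples
#' mutation_model(0.002, per_locus = c(DYS458 = 0.006))
#' @export
mutation_model <- function(rate = 0.002, per_locus = NULL) {
  stopifnot(is.numeric(rate), length(rate) == 1L)
  rates <- stats::setNames(rep(rate, 16L), ystr_panel())
  if (!is.null(per_locus)) {
    names(per_locus) <- normalize_locus(names(per_locus))
    rates[names(per_locus)] <- per_locus
  }
  if (any(is.na(rates) | rates < 0 | rates > 1)) {
    stop("mutation rates must lie in [0, 1]", call. = FALSE)
  }
  structure(rates, class = "ystr_mutation_model")
}

#' @export
print.ystr_mutation_model <- function(x, ...) {
  r <- unclass(x)
  cat("<stepwise mutation model> per-locus rates per meiosis\n")
  if (length(unique(r)) == 1L) {
    cat("  uniform rate ", format(r[[1]]), " at all 16 loci\n", sep = "")
  } else {
    cat(paste0("  ", format(names(r)), "  ", format(r)), sep = "\n")
  }
  invisible(x)
}

# star genealogy: each descendant is an independent chain of `generations`
# meioses from the founder; returns the descendant allele matrix
sim_descendants <- function(founder, generations, n, rates) {
  loci <- names(founder$loci)
  copies <- lapply(founder$loci, as.numeric)
  ncop <- vapply(copies, length, integer(1))
  locus_of_copy <- rep(loci, ncop)
  A <- matrix(rep(unlist(copies, use.names = FALSE), each = n), nrow = n)
  rate_of_copy <- unclass(rates)[locus_of_copy]
  for (g in seq_len(generations)) {
    mut <- matrix(stats::runif(length(A)) < rep(rate_of_copy, each = n),
                  nrow = n)
    if (any(mut)) {
      step <- ifelse(stats::runif(sum(mut)) < 0.5, -1, 1)
      A[mut] <- pmax(A[mut] + step, 1)
    }
  }
  list(alleles = A, locus_of_copy = locus_of_copy, loci = loci)
}

#' Simulate a patrilineal lineage under stepwise mutation
#'
#' Generates descendants of a founder haplotype: each descendant's
#' haplotype is the founder's after `generations` independent meioses under
#' the stepwise mutation model (a star genealogy — descendants are
#' independent chains from the founder, not a branching pedigree). With a
#' zero mutation rate every descendant is identical by descent to the
#' founder, which is the premise surname studies rest on.
#'
#' @param founder A full-panel [haplotype()].
#' @param generations Pedigree depth in meioses (>= 0).
#' @param n_descendants Number of descendants to draw (>= 1).
#' @param model A [mutation_model()].
#' @param seed Integer seed for reproducibility; `NULL` continues the
#'   current RNG stream. The caller's RNG state is left untouched when a
#'   seed is given.
#' @param name Population name.
#' @return A [population()] of `n_descendants` haplotypes with ids
#'   `<founder>.1`, `<founder>.2`, ...
#' @examples
#' ob <- ystr_fixture("obrien")
#' simulate_lineage(ob$members$OB1, generations = 5, n_descendants = 3, seed = 7)
#' @export
simulate_lineage <- function(founder, generations, n_descendants,
                             model = mutation_model(), seed = NULL,
                             name = paste0(founder$sample_id, "_lineage")) {
  stopifnot(inherits(founder, "ystr_haplotype"),
            generations >= 0, n_descendants >= 1)
  if (!inherits(model, "ystr_mutation_model")) model <- mutation_model(model)
  local_seed(seed, {
    sim <- sim_descendants(founder, generations, n_descendants, model)
    f <- factor(sim$locus_of_copy, levels = sim$loci)
    members <- lapply(seq_len(n_descendants), function(i) {
      haplotype(paste0(founder$sample_id, ".", i),
                split(sim$alleles[i, ], f),
                metadata = list(founder = founder$sample_id,
                                generations = as.character(generations)))
    })
    population(name, members)
  })
}

#' Per-locus allele frequency tables from a population
#'
#' Counts every allele copy at each locus (both DYS385 copies, and both
#' copies of any duplicated pattern) and normalizes to relative
#' frequencies, giving the sampling tables [simulate_unrelated()] draws
#' from.
#'
#' @param pop A [population()].
#' @return Named list over the panel loci; each element a named numeric
#'   vector of allele relative frequencies (names are allele strings).
#' @export
allele_tables <- function(pop) {
  stopifnot(inherits(pop, "ystr_population"), length(pop) >= 1L)
  out <- lapply(ystr_panel(), function(L) {
    alleles <- unlist(lapply(pop$members, function(h) as.numeric(h$loci[[L]])),
                      use.names = FALSE)
    tab <- table(vapply(alleles, format_alleles, character(1)))
    stats::setNames(as.numeric(tab) / length(alleles), names(tab))
  })
  stats::setNames(out, ystr_panel())
}

#' Simulate unrelated haplotypes from allele frequency tables
#'
#' Each sample draws each locus independently from its frequency table —
#' two independent draws for the duplicated locus DYS385, one for every
#' other locus. This emulates a randomly sampled control population with no
#' shared paternal ancestry structure.
#'
#' @param freqs Per-locus frequency tables as produced by [allele_tables()]
#'   (named list over the panel; named numeric vectors summing to 1).
#' @param n Number of samples (>= 0).
#' @inheritParams simulate_lineage
#' @return A [population()] with ids `U1`, `U2`, ...
#' @examples
#' tabs <- allele_tables(ystr_fixture("obrien"))
#' simulate_unrelated(tabs, n = 4, seed = 1)
#' @export
simulate_unrelated <- function(freqs, n, seed = NULL, name = "unrelated") {
  stopifnot(n >= 0)
  panel <- ystr_panel()
  missing <- setdiff(panel, names(freqs))
  if (length(missing)) {
    stop("no frequency table for panel locus: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (L in panel) {
    f <- freqs[[L]]
    if (length(f) == 0L) stop("empty frequency table at ", L, call. = FALSE)
    if (abs(sum(f) - 1) > 1e-6) {
      stop("frequencies at ", L, " sum to ", sum(f), ", not 1", call. = FALSE)
    }
  }
  if (n == 0) return(population(name, list()))
  local_seed(seed, {
    draws <- lapply(panel, function(L) {
      k <- if (L %in% multi_copy_loci()) 2L else 1L
      vals <- as.numeric(names(freqs[[L]]))
      matrix(vals[sample.int(length(vals), n * k, replace = TRUE,
                             prob = freqs[[L]])],
             nrow = n, ncol = k)
    })
    names(draws) <- panel
    members <- lapply(seq_len(n), function(i) {
      haplotype(paste0("U", i), lapply(draws, function(m) m[i, ]))
    })
    population(name, members)
  })
}

#' Design and run a synthetic surname study
#'
#' `study_design()` bundles the pieces of a surname-study simulation:
#' founder haplotypes with cluster sizes and pedigree depths, a count of
#' unrelated samples with their allele frequency source, a mutation model
#' and a seed. `simulate_surname_study()` runs it: each founder cluster via
#' [simulate_lineage()], the unrelated group via [simulate_unrelated()],
#' all from one seed so the whole study is reproducible.
#'
#' @param founders List of full-panel [haplotype()] founders.
#' @param cluster_sizes Integer vector, one per founder (>= 1).
#' @param generations Integer vector of pedigree depths, one per founder
#'   (>= 0), recycled if length 1.
#' @param n_unrelated Number of unrelated samples (0 to skip).
#' @param freqs Allele frequency source for the unrelated group: a
#'   [population()] (tables derived via [allele_tables()]) or explicit
#'   tables in that format. Required when `n_unrelated > 0`.
#' @param model A [mutation_model()].
#' @param seed Integer seed.
#' @return `study_design()`: an object of class `ystr_design`.
#'   `simulate_surname_study()`: a list of class `ystr_study` with
#'   `clusters` (list of [population()]s, one per founder) and `unrelated`
#'   (a [population()], possibly empty).
#' @examples
#' ob <- ystr_fixture("obrien")
#' d <- study_design(founders = list(ob$members$OB1), cluster_sizes = 5,
#'                   generations = 3, n_unrelated = 5, freqs = ob, seed = 42)
#' simulate_surname_study(d)
#' @export
study_design <- function(founders, cluster_sizes, generations,
                         n_unrelated = 0, freqs = NULL,
                         model = mutation_model(), seed = 1L) {
  stopifnot(length(founders) >= 1L,
            length(cluster_sizes) == length(founders),
            all(cluster_sizes >= 1),
            all(generations >= 0),
            n_unrelated >= 0)
  if (length(generations) == 1L) {
    generations <- rep(generations, length(founders))
  }
  stopifnot(length(generations) == length(founders))
  if (n_unrelated > 0 && is.null(freqs)) {
    stop("an allele frequency source is required when n_unrelated > 0",
         call. = FALSE)
  }
  if (inherits(freqs, "ystr_population")) freqs <- allele_tables(freqs)
  if (!inherits(model, "ystr_mutation_model")) model <- mutation_model(model)
  structure(list(founders = founders, cluster_sizes = as.integer(cluster_sizes),
                 generations = as.integer(generations),
                 n_unrelated = as.integer(n_unrelated), freqs = freqs,
                 model = model, seed = as.integer(seed)),
            class = "ystr_design")
}

#' @rdname study_design
#' @param design A `ystr_design`.
#' @export
simulate_surname_study <- function(design) {
  stopifnot(inherits(design, "ystr_design"))
  local_seed(design$seed, {
    clusters <- lapply(seq_along(design$founders), function(i) {
      f <- design$founders[[i]]
      simulate_lineage(f, design$generations[i], design$cluster_sizes[i],
                       model = design$model, seed = NULL,
                       name = paste0("cluster_", f$sample_id))
    })
    unrelated <- if (design$n_unrelated > 0) {
      simulate_unrelated(design$freqs, design$n_unrelated, seed = NULL)
    } else population("unrelated", list())
    structure(list(clusters = clusters, unrelated = unrelated),
              class = "ystr_study")
  })
}

#' @export
print.ystr_study <- function(x, ...) {
  cat("<synthetic surname study> ", length(x$clusters), " founder cluster(s), ",
      length(x$unrelated), " unrelated sample(s)\n", sep = "")
  for (cl in x$clusters) cat("  ", cl$name, ": N = ", length(cl), "\n", sep = "")
  invisible(x)
}
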