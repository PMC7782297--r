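# Random haplotype/population generators for property-style tests.
# Allele ranges and the occasional microvariant or duplicated pattern mirror
# what Y-STR panels produce.

random_allele <- function(n = 1L) {
  a <- sample(8:32, n, replace = TRUE)
  micro <- runif(n) < 0.05
  a + ifelse(micro, 0.2, 0)
}

random_haplotype <- function(id, p_duplication = 0.05) {
  loci <- lapply(ystr_panel(), function(L) {
    k <- if (L %in% multi_copy_loci()) 2L else if (runif(1) < p_duplication) 2L else 1L
    random_allele(k)
  })
  names(loci) <- ystr_panel()
  meta <- if (runif(1) < 0.5) {
    list(surname_group = sample(c("A", "B", "O'Brien"), 1),
         birthplace = sample(c("Limerick", "West Haven, CT", "x;y"), 1))
  } else list()
  haplotype(id, loci, metadata = meta)
}

random_population <- function(n, name = "random") {
  population(name, lapply(seq_len(n), function(i) {
    random_haplotype(paste0("S", i))
  }))
}

expect_population_equal <- function(a, b) {
  expect_identical(sample_ids(a), sample_ids(b))
  for (id in sample_ids(a)) {
    ha <- a$members[[id]]; hb <- b$members[[id]]
    for (L in ystr_panel()) {
      expect_equal(as.numeric(ha$loci[[L]]), as.numeric(hb$loci[[L]]),
                   label = paste(id, L))
    }
    norm_meta <- function(m) {
      if (length(m) == 0L) return(character(0))
      v <- vapply(m, as.character, character(1))
      v[order(names(v))]
    }
    expect_equal(norm_meta(ha$metadata), norm_meta(hb$metadata),
                 label = paste(id, "metadata"))
  }
}

write_read_roundtrip <- function(pop, dialect = table_dialect()) {
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f))
  write_population(pop, f, dialect = dialect)
  read_population(f, name = pop$name, dialect = dialect)
}
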