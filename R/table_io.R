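#' CSV dialect for Y-STR haplotype tables
#'
#' Haplotype tables are plain CSV: one header row, then one row per male.
#' A `sample_id` column is required; every panel locus has a column (header
#' tokens are case-insensitive and may use accepted aliases such as
#' `YGATAH`); any remaining columns are carried as free-text metadata.
#' Multi-allele cells (DYS385, duplicated patterns) hold the alleles joined
#' by `allele_sep`, smallest first. The default allele separator is a
#' semicolon so that unquoted CSV stays parseable; a comma-separated pair
#' inside a quoted cell (the convention of printed tables, `"11,14"`) is
#' accepted on input.
#'
#' @param delimiter Field delimiter (default `","`).
#' @param allele_sep Separator between alleles within one cell (default
#'   `";"`); must differ from `delimiter`.
#' @param loci Locus column order used when writing (default: full panel in
#'   table order).
#' @return Object of class `ystr_dialect`.
#' @export
table_dialect <- function(delimiter = ",", allele_sep = ";",
                          loci = ystr_panel()) {
  stopifnot(nchar(delimiter) == 1L, nchar(allele_sep) == 1L)
  if (delimiter == allele_sep) {
    stop("the allele separator must differ from the field delimiter",
         call. = FALSE)
  }
  loci <- normalize_locus(loci)
  structure(list(delimiter = delimiter, allele_sep = allele_sep, loci = loci),
            class = "ystr_dialect")
}

parse_allele_cell <- function(cell, dialect, where) {
  # accept the dialect separator and, for quoted printed-table cells, a comma
  pattern <- paste0("[", dialect$allele_sep, ",]")
  tokens <- trimws(strsplit(cell, pattern)[[1]])
  tokens <- tokens[nzchar(tokens)]
  vals <- suppressWarnings(as.numeric(tokens))
  if (length(vals) == 0L || anyNA(vals)) {
    stop("non-numeric allele token in cell '", cell, "' at ", where,
         call. = FALSE)
  }
  vals
}

#' Read a Y-STR haplotype table
#'
#' @param file Path to a CSV file, or a connection.
#' @param name Population name (defaults to the file name).
#' @param dialect A [table_dialect()].
#' @return A [population()] preserving row order.
#' @seealso [write_population()], [ystr_fixture()]
#' @export
read_population <- function(file, name = NULL,
                            dialect = table_dialect()) {
  stopifnot(inherits(dialect, "ystr_dialect"))
  if (is.null(name)) {
    name <- if (is.character(file)) {
      sub("\\.[^.]*$", "", basename(file))
    } else "population"
  }
  df <- utils::read.csv(file, sep = dialect$delimiter, colClasses = "character",
                        check.names = FALSE, fileEncoding = "UTF-8")
  headers <- trimws(names(df))
  key <- gsub("[ _-]", "", toupper(headers))
  map <- locus_alias_map()
  canon <- unname(map[key])
  is_locus <- !is.na(canon)
  id_col <- which(key == "SAMPLE_ID" | key == "SAMPLEID")
  if (length(id_col) != 1L) stop("a single sample_id column is required", call. = FALSE)
  missing <- setdiff(ystr_panel(), canon[is_locus])
  if (length(missing)) {
    stop("missing locus column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  meta_cols <- setdiff(which(!is_locus), id_col)
  ids <- trimws(df[[id_col]])
  if (anyDuplicated(ids)) {
    stop("duplicate sample_id: ", paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  }
  members <- lapply(seq_len(nrow(df)), function(i) {
    loci <- lapply(which(is_locus), function(j) {
      parse_allele_cell(df[i, j],
                        dialect,
                        where = paste0("row ", i, ", column ", headers[j]))
    })
    names(loci) <- canon[is_locus]
    meta <- as.list(df[i, meta_cols, drop = FALSE])
    names(meta) <- headers[meta_cols]
    meta <- meta[nzchar(unlist(meta, use.names = FALSE))]
    haplotype(ids[i], loci, metadata = meta)
  })
  population(name, members)
}

population_to_frame <- function(pop, dialect) {
  loci <- dialect$loci
  cols <- c(list(sample_id = sample_ids(pop)),
            lapply(loci, function(L) {
              vapply(pop$members, function(h) {
                format_alleles(h$loci[[L]], sep = dialect$allele_sep)
              }, character(1), USE.NAMES = FALSE)
            }))
  names(cols)[-1] <- loci
  meta_names <- unique(unlist(lapply(pop$members, function(h) names(h$metadata))))
  for (m in meta_names) {
    cols[[m]] <- vapply(pop$members, function(h) {
      v <- h$metadata[[m]]
      if (is.null(v)) "" else as.character(v)
    }, character(1), USE.NAMES = FALSE)
  }
  as.data.frame(cols, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Write a Y-STR haplotype table
#'
#' Output is deterministic: header then one row per member in population
#' order, multi-allele cells joined smallest-allele-first.
#' `read_population(write_population(pop))` reproduces `pop`.
#'
#' @param pop A [population()].
#' @param file Path or connection (`""` prints to stdout).
#' @inheritParams read_population
#' @return `file`, invisibly.
#' @export
write_population <- function(pop, file = "", dialect = table_dialect()) {
  stopifnot(inherits(pop, "ystr_population"), inherits(dialect, "ystr_dialect"))
  df <- population_to_frame(pop, dialect)
  utils::write.table(df, file, sep = dialect$delimiter, row.names = FALSE,
                     col.names = TRUE, quote = TRUE, qmethod = "double",
                     fileEncoding = "UTF-8")
  invisible(file)
}

#' Read or write a founder signature in the table CSV dialect
#'
#' Signatures use the same one-row CSV layout as haplotype tables but need
#' cover only a subset of loci; a `name` column replaces `sample_id`.
#'
#' @param file Path or connection.
#' @inheritParams read_population
#' @return `read_signature`: a [founder_signature()].
#' @export
read_signature <- function(file, dialect = table_dialect()) {
  df <- utils::read.csv(file, sep = dialect$delimiter, colClasses = "character",
                        check.names = FALSE, fileEncoding = "UTF-8")
  if (nrow(df) != 1L) stop("a signature file holds exactly one row", call. = FALSE)
  headers <- trimws(names(df))
  key <- gsub("[ _-]", "", toupper(headers))
  name_col <- which(key %in% c("NAME", "SIGNATURE", "SAMPLE_ID", "SAMPLEID"))
  if (length(name_col) != 1L) stop("a single name column is required", call. = FALSE)
  map <- locus_alias_map()
  canon <- unname(map[key])
  is_locus <- !is.na(canon)
  loci <- lapply(which(is_locus), function(j) {
    parse_allele_cell(df[1, j], dialect, where = paste0("column ", headers[j]))
  })
  names(loci) <- canon[is_locus]
  founder_signature(df[1, name_col], loci)
}

#' @rdname read_signature
#' @param sig A [founder_signature()].
#' @export
write_signature <- function(sig, file = "", dialect = table_dialect()) {
  stopifnot(inherits(sig, "ystr_signature"))
  loci <- intersect(dialect$loci, names(sig$loci))
  cols <- c(list(name = sig$name),
            stats::setNames(lapply(loci, function(L) {
              format_alleles(sig$loci[[L]], sep = dialect$allele_sep)
            }), loci))
  utils::write.table(as.data.frame(cols, check.names = FALSE), file,
                     sep = dialect$delimiter, row.names = FALSE,
                     col.names = TRUE, quote = TRUE, qmethod = "double",
                     fileEncoding = "UTF-8")
  invisible(file)
}
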