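# Readers and writers for the package's plain-text dialects: per-cell
# transcript-count tables (TSV), gene x sample count matrices (TSV), GMT gene
# sets, two-column gene/category annotations, and yaml configs. All readers
# reject malformed input rather than coercing it; all writers round-trip.

#' Read a per-cell transcript-count table
#'
#' Reads a tab-separated table with header `cell_id<TAB>class<TAB><gene1>...`
#' (the `class` column is optional). Counts must be non-negative integers;
#' malformed cells are rejected with the offending line number.
#'
#' @param path Path to a TSV file.
#' @return A `cell_count_table`: a data.frame with columns `cell_id`,
#'   `class` (latent label, `NA` if absent in the file) and one integer
#'   column per gene, with attribute `genes`.
#' @seealso [write_count_table()], [generate_fish_fixture()]
#' @export
read_count_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", colClasses = "character",
                          check.names = FALSE, quote = "", comment.char = "")
  if (!"cell_id" %in% names(df)) stopf("count table %s lacks a cell_id column", path)
  if (anyDuplicated(df$cell_id)) stopf("duplicate cell_id in %s", path)
  has_class <- "class" %in% names(df)
  genes <- setdiff(names(df), c("cell_id", "class"))
  if (!length(genes)) stopf("count table %s has no gene columns", path)
  counts <- lapply(genes, function(g) {
    v <- suppressWarnings(as.numeric(df[[g]]))
    bad <- which(is.na(v) | v < 0 | v != floor(v))
    if (length(bad)) {
      stopf("non-integer or negative count '%s' for gene %s at line %d of %s",
            df[[g]][bad[1]], g, bad[1] + 1L, path)
    }
    as.integer(v)
  })
  names(counts) <- genes
  out <- data.frame(cell_id = df$cell_id,
                    class = if (has_class) df$class else NA_character_,
                    counts, check.names = FALSE, stringsAsFactors = FALSE)
  new_cell_count_table(out, genes)
}

new_cell_count_table <- function(df, genes) {
  structure(df, genes = genes, class = c("cell_count_table", "data.frame"))
}

#' Write a per-cell count table as TSV
#'
#' @param table A `cell_count_table`.
#' @param path Output path. UTF-8, Unix newlines.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(table, path) {
  stopifnot(inherits(table, "cell_count_table"))
  utils::write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  invisible(path)
}

#' Read a gene x sample count matrix
#'
#' TSV with header `gene<TAB><sample1>...`; integer counts, unique gene ids.
#'
#' @param path Path to a TSV file.
#' @return Integer matrix with gene rownames and sample colnames.
#' @export
read_bulk_matrix <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", colClasses = "character",
                          check.names = FALSE, quote = "")
  if (names(df)[1] != "gene") stopf("bulk matrix %s must start with a 'gene' column", path)
  if (anyDuplicated(df$gene)) stopf("duplicate gene ids in %s", path)
  m <- as.matrix(df[-1])
  v <- suppressWarnings(as.numeric(m))
  bad <- which(is.na(v) | v < 0 | v != floor(v))
  if (length(bad)) {
    stopf("non-integer or negative count at line %d of %s",
          ((bad[1] - 1L) %% nrow(m)) + 2L, path)
  }
  out <- matrix(as.integer(v), nrow = nrow(m), dimnames = list(df$gene, colnames(m)))
  out
}

#' Write a gene x sample count matrix as TSV
#' @param mat Integer matrix with gene rownames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bulk_matrix <- function(mat, path) {
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, eol = "\n")
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' One set per line: `name<TAB>description<TAB>gene1<TAB>gene2...`. Duplicate
#' set names and empty sets are rejected.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nm <- vapply(fields, `[`, character(1), 1L)
  if (anyDuplicated(nm)) stopf("duplicate set name '%s' in %s", nm[anyDuplicated(nm)], path)
  sets <- lapply(seq_along(fields), function(i) {
    f <- fields[[i]]
    if (length(f) < 3L) stopf("empty gene set '%s' at line %d of %s", f[1], i, path)
    unique(f[-(1:2)])
  })
  names(sets) <- nm
  sets
}

#' Write gene sets in GMT format
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional character vector of set descriptions.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a two-column gene/category annotation table
#'
#' TSV with columns `gene`, `category` (header required). Returns the
#' category -> gene-set mapping used by [go_annotation()].
#'
#' @param path Path to a TSV file.
#' @return Named list of character vectors (category id -> genes).
#' @export
read_annotation_pairs <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", colClasses = "character",
                          quote = "")
  if (!all(c("gene", "category") %in% names(df))) {
    stopf("annotation table %s needs 'gene' and 'category' columns", path)
  }
  lapply(split(df$gene, df$category), unique)
}

#' Read a time course of marker-positive fractions
#'
#' TSV with columns `time`, `fraction_positive` and optionally `n_cells`.
#' Times must be strictly increasing and fractions in \[0, 1\].
#'
#' @param path Path to a TSV file.
#' @return A `time_course` object (see [time_course()]).
#' @export
read_time_course <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t")
  if (!all(c("time", "fraction_positive") %in% names(df))) {
    stopf("time course %s needs 'time' and 'fraction_positive' columns", path)
  }
  time_course(df$time, df$fraction_positive,
              n_cells = if ("n_cells" %in% names(df)) df$n_cells else NULL)
}

#' Write a time course as TSV
#' @param tc A `time_course`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_time_course <- function(tc, path) {
  stopifnot(inherits(tc, "time_course"))
  utils::write.table(as.data.frame(unclass(tc)[!vapply(unclass(tc), is.null, TRUE)]),
                     path, sep = "\t", quote = FALSE, row.names = FALSE, eol = "\n")
  invisible(path)
}

#' Load a structured yaml config
#' @param path Path to a yaml file.
#' @return Named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stopf("config %s did not parse to a mapping", path)
  cfg
}
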