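# Threshold classification of single-molecule RNA FISH transcript counts and
# summaries of the resulting nested ("Russian doll") subpopulation structure:
# a cell is negative for a gene iff its count is strictly below the gene's
# cutoff, mirroring the "less than N transcripts per cell" convention used to
# call marker-negative cells.

#' Define per-gene positivity cutoffs
#'
#' @param ... Named positive integer cutoffs in transcripts per cell, e.g.
#'   `threshold_scheme(Nanog = 30, Oct4 = 80)`, or a single named vector/list.
#' @return A `threshold_scheme` (named integer vector). A cell is negative
#'   for a gene iff `count < cutoff`; a count exactly at the cutoff is
#'   positive.
#' @export
threshold_scheme <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.null(names(args)) || (length(args) == 1L && names(args)[1] == "")) {
    args <- as.list(unlist(args[[1]]))
  }
  cutoffs <- unlist(args)
  if (is.null(names(cutoffs)) || any(!nzchar(names(cutoffs)))) {
    stopf("every cutoff must be named by its gene")
  }
  if (any(cutoffs < 1 | cutoffs != floor(cutoffs))) {
    stopf("cutoffs must be positive integers (transcripts per cell)")
  }
  structure(stats::setNames(as.integer(cutoffs), names(cutoffs)),
            class = "threshold_scheme")
}

#' Classify cells as (+)/(-) per gene by transcript-count cutoffs
#'
#' @param table A `cell_count_table` (see [read_count_table()]).
#' @param scheme A [threshold_scheme()]; every scheme gene must be a column
#'   of `table`.
#' @return A `cell_label_table`: the input counts plus one `<gene>_call`
#'   column per scheme gene with values `"+"`/`"-"`, and attributes `genes`
#'   (the classified genes) and `scheme`.
#' @examples
#' tab <- generate_fish_fixture(system.file("extdata", "fig4a.yaml",
#'                                          package = "stemhet"))
#' labels <- classify_cells(tab, threshold_scheme(Nanog = 30, Oct4 = 80))
#' table(labels$Nanog_call)
#' @export
classify_cells <- function(table, scheme) {
  if (!inherits(scheme, "threshold_scheme")) scheme <- threshold_scheme(scheme)
  genes <- names(scheme)
  missing <- setdiff(genes, names(table))
  if (length(missing)) stopf("gene column missing from count table: %s", missing[1])
  out <- as.data.frame(table)
  for (g in genes) {
    counts <- out[[g]]
    if (any(is.na(counts))) stopf("missing counts for gene %s are not imputed", g)
    if (any(counts < 0)) stopf("negative counts for gene %s", g)
    out[[paste0(g, "_call")]] <- ifelse(counts >= scheme[[g]], "+", "-")
  }
  structure(out, genes = genes, scheme = scheme,
            class = c("cell_label_table", "data.frame"))
}

call_vector <- function(labels, gene) {
  col <- paste0(gene, "_call")
  if (!col %in% names(labels)) stopf("gene %s has no calls in the label table", gene)
  labels[[col]]
}

#' Summarize the nested marker-negative hierarchy
#'
#' Counts cells negative for progressively longer prefixes of the nesting:
#' level 0 is all cells, level k counts cells negative for every one of the
#' first k genes. Counts are monotone non-increasing with depth.
#'
#' @param labels A `cell_label_table` from [classify_cells()].
#' @param nesting Ordered character vector of genes (outermost first), e.g.
#'   `c("Nanog", "Oct4")`.
#' @return A `hierarchy_summary`: list with `nesting`, `counts` (length
#'   `length(nesting) + 1`, starting at the total), and `fractions` (each
#'   level over the previous).
#' @export
summarize_hierarchy <- function(labels, nesting) {
  if (!length(nesting)) stopf("nesting must name at least one gene")
  keep <- rep(TRUE, nrow(labels))
  counts <- integer(length(nesting) + 1L)
  counts[1] <- nrow(labels)
  for (k in seq_along(nesting)) {
    keep <- keep & (call_vector(labels, nesting[k]) == "-")
    counts[k + 1L] <- sum(keep)
  }
  fractions <- counts[-1] / pmax(counts[-length(counts)], 1L)
  structure(list(nesting = nesting, counts = counts, fractions = fractions),
            class = "hierarchy_summary")
}

#' @export
print.hierarchy_summary <- function(x, ...) {
  cat("Nested marker-negative hierarchy\n")
  cat(sprintf("  all cells: %d\n", x$counts[1]))
  for (k in seq_along(x$nesting)) {
    cat(sprintf("  (-) for %s: %d (%.1f%% of previous level)\n",
                paste(x$nesting[seq_len(k)], collapse = " & "),
                x$counts[k + 1], 100 * x$fractions[k]))
  }
  invisible(x)
}

#' Cross-tabulate (+)/(-) calls for a gene pair
#'
#' @param labels A `cell_label_table`.
#' @param gene_a,gene_b Two distinct classified genes.
#' @return A `coexpression_table`: list with the 2x2 `counts` matrix (rows =
#'   `gene_a` +/-, columns = `gene_b` +/-), `total`, the two positive
#'   marginals and the double-positive `overlap`.
#' @export
coexpression_contingency <- function(labels, gene_a, gene_b) {
  if (identical(gene_a, gene_b)) stopf("gene_a and gene_b must differ")
  a <- factor(call_vector(labels, gene_a), levels = c("+", "-"))
  b <- factor(call_vector(labels, gene_b), levels = c("+", "-"))
  counts <- table(a, b)
  dimnames(counts) <- stats::setNames(dimnames(counts), c(gene_a, gene_b))
  structure(list(gene_a = gene_a, gene_b = gene_b,
                 counts = unclass(counts), total = length(a),
                 marginal_a = sum(a == "+"), marginal_b = sum(b == "+"),
                 overlap = counts["+", "+"]),
            class = "coexpression_table")
}

#' Hypergeometric tail probability of a co-expression overlap
#'
#' Under an independence null in which `marginal_a` and `marginal_b` cells
#' are positive for the two genes among `total` cells, returns the
#' probability of observing at least the seen double-positive overlap —
#' a measure of whether, e.g., the rare cells positive for one lineage
#' marker being a subset of the cells positive for another could be chance.
#'
#' @param ct A `coexpression_table`, or its fields given directly.
#' @param total,marginal_a,marginal_b,overlap Used when `ct` is missing.
#' @return Probability in \[0, 1\] of an overlap `>=` the observed one.
#' @examples
#' # 2 Tbx6(+) cells all inside the 7 T(+) cells, out of 764:
#' overlap_probability(total = 764, marginal_a = 7, marginal_b = 2, overlap = 2)
#' @export
overlap_probability <- function(ct = NULL, total = NULL, marginal_a = NULL,
                                marginal_b = NULL, overlap = NULL) {
  if (!is.null(ct)) {
    stopifnot(inherits(ct, "coexpression_table"))
    total <- ct$total; marginal_a <- ct$marginal_a
    marginal_b <- ct$marginal_b; overlap <- ct$overlap
  }
  if (marginal_a > total || marginal_b > total) stopf("marginals exceed the total")
  if (overlap > min(marginal_a, marginal_b)) stopf("overlap exceeds a marginal")
  if (overlap <= 0) return(1)
  # P(X >= overlap), X ~ Hypergeometric(total, marginal_a, marginal_b draws)
  stats::phyper(overlap - 1L, m = marginal_a, n = total - marginal_a,
                k = marginal_b, lower.tail = FALSE)
}

#' Fold change of a gene's counts between two cell groups
#'
#' Computes `center(group_a) / center(group_b)` of the raw transcript counts.
#' When either center is zero, a pseudocount of 1 is added to both centers
#' and the result is flagged rather than returning NaN/Inf.
#'
#' @param table A `cell_count_table` of raw counts.
#' @param labels The matching `cell_label_table` (row order preserved).
#' @param gene Gene whose counts are compared.
#' @param group_a,group_b Predicates over label-table rows: either a logical
#'   vector of length `nrow(table)` or a function taking the label table and
#'   returning one (e.g. `function(l) l$Nanog_call == "-"`).
#' @param center `"mean"` (default) or `"median"`.
#' @return A `fold_change` list: `ratio`, the two centers, group sizes and
#'   `pseudocount_used`.
#' @export
subpopulation_fold_change <- function(table, labels, gene, group_a, group_b,
                                      center = c("mean", "median")) {
  center <- match.arg(center)
  resolve <- function(pred, nm) {
    sel <- if (is.function(pred)) pred(labels) else pred
    if (!is.logical(sel) || length(sel) != nrow(table)) {
      stopf("%s must resolve to a logical vector over all cells", nm)
    }
    if (!any(sel)) stopf("%s selects no cells (empty group)", nm)
    sel
  }
  sel_a <- resolve(group_a, "group_a")
  sel_b <- resolve(group_b, "group_b")
  if (!gene %in% names(table)) stopf("gene %s absent from count table", gene)
  fun <- if (center == "mean") mean else stats::median
  ca <- fun(table[[gene]][sel_a])
  cb <- fun(table[[gene]][sel_b])
  pseudo <- (ca == 0 || cb == 0)
  ratio <- if (pseudo) (ca + 1) / (cb + 1) else ca / cb
  structure(list(gene = gene, ratio = ratio, center = center,
                 center_a = ca, center_b = cb,
                 n_a = sum(sel_a), n_b = sum(sel_b),
                 pseudocount_used = pseudo),
            class = "fold_change")
}

#' @export
print.fold_change <- function(x, ...) {
  cat(sprintf("%s: %.3g-fold (%s %0.3g vs %0.3g; n = %d vs %d)%s\n",
              x$gene, x$ratio, x$center, x$center_a, x$center_b, x$n_a, x$n_b,
              if (x$pseudocount_used) " [pseudocount 1 applied]" else ""))
  invisible(x)
}
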