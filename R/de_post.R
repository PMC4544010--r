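# Post-processing of differential-expression comparison tables: step-up FDR
# adjustment and hit calling, joint coherent/incoherent fold-change quadrant
# classification across two contrasts, transcription-factor binding overlap
# fractions, and directional summaries of designated gene sets. Upstream
# testing (how the p-values were produced) is deliberately out of scope: any
# per-gene p-value/fold-change table is accepted.

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Standard step-up procedure: sort the m p-values increasingly, compute
#' `p_(i) * m / i`, take the running minimum from the largest rank down, and
#' clip at 1. NA p-values are excluded from m and returned as NA.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\] (NAs allowed).
#' @return Adjusted p-values, same length and order as the input.
#' @examples
#' benjamini_hochberg(c(0.005, 0.1))   # 0.01, 0.10
#' @export
benjamini_hochberg <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) {
    stopf("p-values must lie in [0, 1]")
  }
  out <- rep(NA_real_, length(pvalues))
  ok <- which(!is.na(pvalues))
  m <- length(ok)
  if (m == 0L) return(out)
  p <- pvalues[ok]
  ord <- order(p, decreasing = TRUE)            # largest first
  stepped <- pmin(1, cummin(p[ord] * m / seq(m, 1)))
  out[ok][ord] <- stepped
  out
}

#' Build a per-gene comparison table for one contrast
#'
#' @param gene Character vector of unique gene ids.
#' @param log2fc Log2 fold changes (positive = higher in the second
#'   condition of the contrast).
#' @param pvalue Raw p-values.
#' @param padj Optional pre-computed adjusted p-values; computed with
#'   [benjamini_hochberg()] when absent.
#' @param fdr FDR threshold used for the hit flag (default 0.10).
#' @return A `comparison_table` data.frame with columns `gene`, `log2fc`,
#'   `pvalue`, `padj`, `hit`.
#' @export
comparison_table <- function(gene, log2fc, pvalue, padj = NULL, fdr = 0.10) {
  if (anyDuplicated(gene)) stopf("duplicate gene ids")
  if (is.null(padj)) padj <- benjamini_hochberg(pvalue)
  df <- data.frame(gene = as.character(gene), log2fc = log2fc,
                   pvalue = pvalue, padj = padj,
                   hit = !is.na(padj) & padj <= fdr,
                   stringsAsFactors = FALSE)
  structure(df, fdr = fdr, class = c("comparison_table", "data.frame"))
}

#' Read a comparison table from TSV
#'
#' Columns `gene`, `log2fc`, `pvalue` and optionally `padj`; the hit flag is
#' (re)derived at the given FDR.
#'
#' @param path Path to a TSV file.
#' @param fdr FDR threshold for hit calling.
#' @return A `comparison_table`.
#' @export
read_comparison_table <- function(path, fdr = 0.10) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t")
  need <- c("gene", "log2fc", "pvalue")
  if (!all(need %in% names(df))) {
    stopf("comparison table %s needs columns gene, log2fc, pvalue", path)
  }
  comparison_table(df$gene, df$log2fc, df$pvalue,
                   padj = if ("padj" %in% names(df)) df$padj else NULL, fdr = fdr)
}

#' Call differential-expression hits at an FDR threshold
#'
#' The boundary is inclusive: a gene with adjusted p exactly at the
#' threshold is a hit.
#'
#' @param table A `comparison_table`.
#' @param fdr FDR threshold (default 0.10).
#' @return The table with its `hit` column recomputed; attribute `n_hits`.
#' @export
call_hits <- function(table, fdr = 0.10) {
  stopifnot(inherits(table, "comparison_table"))
  table$hit <- !is.na(table$padj) & table$padj <= fdr
  attr(table, "fdr") <- fdr
  attr(table, "n_hits") <- sum(table$hit)
  table
}

#' Coherent/incoherent quadrant classification of joint hits
#'
#' Genes that are hits in BOTH contrasts are classified by the signs of
#' their two log2 fold changes: same sign = coherent (both up or both
#' down), opposite signs = incoherent. Joint hits with a zero fold change
#' in either contrast are excluded and counted separately.
#'
#' @param table_a,table_b `comparison_table`s over a shared gene universe
#'   (labels `a`/`b` refer to their order here).
#' @return A `quadrant_summary`: list with `per_gene` (data.frame of joint
#'   hits: gene, both lfcs, quadrant), `counts` (named: coherent_up,
#'   coherent_down, incoherent_a_up, incoherent_b_up, excluded_zero_fc),
#'   `n_joint_hits` and `coherent_fraction` (over classified genes).
#' @export
quadrant_classify <- function(table_a, table_b) {
  stopifnot(inherits(table_a, "comparison_table"), inherits(table_b, "comparison_table"))
  shared <- intersect(table_a$gene, table_b$gene)
  if (!length(shared)) stopf("the two tables share no genes")
  a <- table_a[match(shared, table_a$gene), ]
  b <- table_b[match(shared, table_b$gene), ]
  joint <- a$hit & b$hit
  la <- a$log2fc[joint]; lb <- b$log2fc[joint]
  quad <- character(sum(joint))
  quad[la > 0 & lb > 0] <- "coherent_up"
  quad[la < 0 & lb < 0] <- "coherent_down"
  quad[la > 0 & lb < 0] <- "incoherent_a_up"
  quad[la < 0 & lb > 0] <- "incoherent_b_up"
  quad[la == 0 | lb == 0] <- "excluded_zero_fc"
  levels <- c("coherent_up", "coherent_down", "incoherent_a_up",
              "incoherent_b_up", "excluded_zero_fc")
  counts <- table(factor(quad, levels = levels))
  classified <- sum(counts[1:4])
  structure(list(per_gene = data.frame(gene = shared[joint], log2fc_a = la,
                                       log2fc_b = lb, quadrant = quad,
                                       stringsAsFactors = FALSE),
                 counts = stats::setNames(as.integer(counts), levels),
                 n_joint_hits = sum(joint),
                 coherent_fraction = if (classified > 0)
                   sum(counts[1:2]) / classified else NA_real_),
            class = "quadrant_summary")
}

#' @export
print.quadrant_summary <- function(x, ...) {
  cat(sprintf("Joint hits: %d (coherent fraction %.3f)\n",
              x$n_joint_hits, x$coherent_fraction))
  print(x$counts)
  invisible(x)
}

#' Fraction of TF-bound genes that are hits, per hit type
#'
#' For each transcription factor and each hit set: the number of literature-
#' bound genes that are also hits of that type, divided by the number of
#' bound genes, together with the background fraction of hits in the whole
#' universe for comparison.
#'
#' @param binding Named list: factor -> character vector of bound genes
#'   (subset of the universe).
#' @param hit_sets Named list: hit type -> character vector of hit genes.
#' @param universe Character vector of all genes.
#' @return data.frame with columns `factor`, `hit_type`, `n_bound`,
#'   `n_bound_hits`, `fraction` (NA with `undefined = TRUE` for factors with
#'   zero bound genes), `background` (= |hits| / |universe|).
#' @export
binding_overlap_fraction <- function(binding, hit_sets, universe) {
  universe <- unique(universe)
  for (nm in names(hit_sets)) {
    bad <- setdiff(hit_sets[[nm]], universe)
    if (length(bad)) stopf("hit set %s contains genes outside the universe", nm)
  }
  rows <- list()
  for (f in names(binding)) {
    bound <- intersect(unique(binding[[f]]), universe)
    for (h in names(hit_sets)) {
      hits <- unique(hit_sets[[h]])
      rows[[length(rows) + 1L]] <- data.frame(
        factor = f, hit_type = h, n_bound = length(bound),
        n_bound_hits = length(intersect(bound, hits)),
        fraction = if (length(bound)) length(intersect(bound, hits)) / length(bound)
                   else NA_real_,
        undefined = !length(bound),
        background = length(hits) / length(universe),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Directional summary of a designated gene set
#'
#' For a gene set (e.g. ESC-specific lincRNAs) against one comparison:
#' how many members are hits, how many of those move up versus down, and the
#' directional bias `(up - down) / (up + down)`.
#'
#' @param gene_set Non-empty character vector within the table's genes.
#' @param table A `comparison_table`.
#' @return List with `n_set`, `n_hits`, `hit_fraction`, `n_up`, `n_down`,
#'   `n_zero_fc` (hits with zero fold change) and `bias` in \[-1, 1\]
#'   (NA when no hit has a nonzero fold change).
#' @export
gene_set_directional_summary <- function(gene_set, table) {
  stopifnot(inherits(table, "comparison_table"))
  gene_set <- unique(gene_set)
  if (!length(gene_set)) stopf("empty gene set")
  bad <- setdiff(gene_set, table$gene)
  if (length(bad)) stopf("gene set member outside the table universe: %s", bad[1])
  sub <- table[match(gene_set, table$gene), ]
  hits <- sub[sub$hit, ]
  up <- sum(hits$log2fc > 0); down <- sum(hits$log2fc < 0)
  list(n_set = length(gene_set), n_hits = nrow(hits),
       hit_fraction = nrow(hits) / length(gene_set),
       n_up = up, n_down = down, n_zero_fc = sum(hits$log2fc == 0),
       bias = if (up + down > 0) (up - down) / (up + down) else NA_real_)
}
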