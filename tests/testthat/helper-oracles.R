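# Independent reference implementations used as oracles. These are written
# as literal, step-by-step procedures (index loops over membership matrices)
# on purpose: they share no code with the package implementations they check.

# Literal greedy category selection over a membership matrix.
# categories: named list of gene vectors; must include root_id.
oracle_greedy <- function(categories, root_id, interest, min_size) {
  universe <- sort(unique(unlist(categories)))
  member <- sapply(categories, function(g) universe %in% g)  # gene x category
  rownames(member) <- universe
  orig_size <- colSums(member)
  eligible <- orig_size > min_size
  eligible[root_id] <- TRUE
  in_interest <- universe %in% interest
  removed <- rep(FALSE, length(universe))
  selection <- character(0)
  repeat {
    best_cat <- NA; best_conc <- -1; best_size <- -1
    for (cat_id in sort(colnames(member))) {
      if (!eligible[cat_id] || cat_id %in% selection) next
      rem <- member[, cat_id] & !removed
      sz <- sum(rem)
      if (sz == 0) next
      conc <- sum(rem & in_interest) / sz
      better <- conc > best_conc + 1e-12 ||
        (abs(conc - best_conc) <= 1e-12 && sz > best_size)
      # lexicographic tie-break is implicit: categories scanned in sorted order
      if (better) { best_cat <- cat_id; best_conc <- conc; best_size <- sz }
    }
    if (is.na(best_cat) || best_conc <= 0) { best_cat <- root_id }
    selection <- c(selection, best_cat)
    if (best_cat == root_id) break
    removed <- removed | member[, best_cat]
  }
  selection
}

# Literal earliest-selected-category assignment on original membership.
oracle_assign <- function(selection, categories, root_id, genes) {
  out <- character(length(genes))
  for (i in seq_along(genes)) {
    home <- root_id
    for (cat_id in selection) {
      if (genes[i] %in% categories[[cat_id]]) { home <- cat_id; break }
    }
    out[i] <- home
  }
  names(out) <- genes
  out
}

# Random small annotation universe for oracle cross-checks.
random_universe <- function(n_genes, n_cats, root_id = "ROOT") {
  genes <- sprintf("g%03d", seq_len(n_genes))
  cats <- list()
  for (j in seq_len(n_cats)) {
    sz <- sample(2:max(2, n_genes %/% 2), 1)
    cats[[sprintf("C%02d", j)]] <- sample(genes, min(sz, n_genes))
  }
  cats[[root_id]] <- genes
  cats
}

# Brute-force nested-negative counts by per-cell filtering.
oracle_hierarchy <- function(counts_df, cutoffs, nesting) {
  n <- nrow(counts_df)
  out <- n
  for (k in seq_along(nesting)) {
    keep <- rep(TRUE, n)
    for (i in seq_len(n)) {
      for (g in nesting[seq_len(k)]) {
        if (counts_df[[g]][i] >= cutoffs[[g]]) keep[i] <- FALSE
      }
    }
    out <- c(out, sum(keep))
  }
  out
}

# Exhaustive overlap-probability oracle: enumerate all placements of the two
# positive sets among N cells and count how often the overlap is >= k.
oracle_overlap_enum <- function(N, na, nb, k) {
  cells <- seq_len(N)
  set_a <- utils::combn(cells, na, simplify = FALSE)
  set_b <- utils::combn(cells, nb, simplify = FALSE)
  hits <- 0; total <- 0
  for (a in set_a) for (b in set_b) {
    total <- total + 1
    if (length(intersect(a, b)) >= k) hits <- hits + 1
  }
  hits / total
}

# Random per-cell count table for property tests.
random_count_table <- function(n_cells, genes, max_count = 100) {
  cols <- lapply(genes, function(g) sample(0:max_count, n_cells, replace = TRUE))
  names(cols) <- genes
  df <- data.frame(cell_id = sprintf("c%04d", seq_len(n_cells)),
                   class = NA_character_, cols,
                   check.names = FALSE, stringsAsFactors = FALSE)
  structure(df, genes = genes, class = c("cell_count_table", "data.frame"))
}

# Vectorized per-gene Welch t-test on log2(count+1): the deliberately simple
# simulation driver feeding the FDR-control checks.
naive_gene_pvalues <- function(counts, group) {
  x <- log2(counts + 1)
  g1 <- x[, group == levels(factor(group))[1], drop = FALSE]
  g2 <- x[, group != levels(factor(group))[1], drop = FALSE]
  n1 <- ncol(g1); n2 <- ncol(g2)
  m1 <- rowMeans(g1); m2 <- rowMeans(g2)
  v1 <- apply(g1, 1, var); v2 <- apply(g2, 1, var)
  se2 <- v1 / n1 + v2 / n2
  se2[se2 == 0] <- .Machine$double.eps
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  df[!is.finite(df)] <- n1 + n2 - 2
  2 * pt(abs(tstat), df, lower.tail = FALSE)
}

fixture_path <- function(name) system.file("extdata", name, package = "stemhet")
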