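# Greedy gene-ontology summarization: iteratively select the category with
# the highest concentration of interest genes, remove the claimed genes from
# every category and from the interest set, and repeat until the root
# category is selected. This keeps closely related, heavily overlapping terms
# from crowding an enrichment list. Each gene is then assigned to ("falls
# into") the earliest-selected category annotating it.

#' Build a category -> gene-set annotation map
#'
#' @param categories Named list of character vectors (category id -> genes).
#'   Annotations are consumed pre-propagated; no ontology-graph reasoning is
#'   done here.
#' @param root_id The root category id (e.g. the biological-process root
#'   `GO:0008150`); it must annotate every gene in the universe. If absent
#'   from `categories` it is added as the union of all gene sets.
#' @return A `go_annotation`: list with `categories`, `root_id`,
#'   `original_size` (sizes before any removal) and `universe`.
#' @export
go_annotation <- function(categories, root_id) {
  if (!length(categories)) stopf("no categories supplied")
  if (is.null(names(categories)) || any(!nzchar(names(categories)))) {
    stopf("categories must be named")
  }
  if (anyDuplicated(names(categories))) stopf("duplicate category ids")
  if (any(!vapply(categories, length, integer(1)))) stopf("empty category at load")
  categories <- lapply(categories, unique)
  universe <- sort(unique(unlist(categories, use.names = FALSE)))
  if (!root_id %in% names(categories)) {
    categories[[root_id]] <- universe
  } else if (!all(universe %in% categories[[root_id]])) {
    stopf("root category %s must annotate every gene in the universe", root_id)
  }
  structure(list(categories = categories, root_id = root_id,
                 original_size = vapply(categories, length, integer(1)),
                 universe = universe),
            class = "go_annotation")
}

#' Greedily select a non-redundant ranked list of categories
#'
#' At each step, among categories whose ORIGINAL size exceeds `min_size`
#' (the root is always eligible), the category maximizing the concentration
#' `|remaining genes in category ∩ remaining interest| / |remaining genes in
#' category|` is selected; its remaining genes are removed from all
#' categories and from the interest set. Selection stops when the root wins
#' (which it does immediately once no eligible category contains any
#' remaining interest gene). Ties in concentration break by larger residual
#' category size, then lexicographically smaller category id.
#'
#' @param annot A [go_annotation()].
#' @param interest Character vector of interest genes (e.g. differential
#'   expression hits); must lie within the annotation universe.
#' @param min_size Eligibility threshold on original category size: only
#'   categories annotating more than `min_size` genes compete (default 750).
#' @return A `greedy_selection`: data.frame with columns `category`,
#'   `concentration` (at selection time), `n_claimed`, plus attributes
#'   `claimed` (list of gene vectors claimed at each step), `min_size` and
#'   `interest`.
#' @export
greedy_select <- function(annot, interest, min_size = 750) {
  stopifnot(inherits(annot, "go_annotation"))
  interest <- unique(interest)
  outside <- setdiff(interest, annot$universe)
  if (length(outside)) stopf("interest gene outside the universe: %s", outside[1])
  if (min_size < 1) stopf("min_size must be >= 1")
  root <- annot$root_id
  eligible <- names(annot$categories)[annot$original_size > min_size]
  eligible <- union(eligible, root)

  remaining <- annot$categories
  pool <- interest
  sel_id <- character(0); sel_conc <- numeric(0); claimed <- list()
  repeat {
    sizes <- vapply(remaining[eligible], length, integer(1))
    live <- eligible[sizes > 0L]           # categories emptied by removals are skipped
    conc <- vapply(remaining[live], function(g) sum(g %in% pool) / length(g),
                   numeric(1))
    if (all(conc == 0)) {
      pick <- root
    } else {
      best <- max(conc)
      cand <- live[conc == best]
      if (length(cand) > 1L) {
        rs <- vapply(remaining[cand], length, integer(1))
        cand <- cand[rs == max(rs)]
        cand <- sort(cand)[1]
      }
      pick <- cand[1]
    }
    genes_claimed <- remaining[[pick]]
    sel_id <- c(sel_id, pick)
    sel_conc <- c(sel_conc, if (length(genes_claimed))
      sum(genes_claimed %in% pool) / length(genes_claimed) else 0)
    claimed <- c(claimed, list(genes_claimed))
    if (pick == root) break
    remaining <- lapply(remaining, setdiff, y = genes_claimed)
    pool <- setdiff(pool, genes_claimed)
    eligible <- setdiff(eligible, pick)
  }
  out <- data.frame(category = sel_id, concentration = sel_conc,
                    n_claimed = vapply(claimed, length, integer(1)),
                    stringsAsFactors = FALSE)
  structure(out, claimed = claimed, min_size = min_size, interest = interest,
            class = c("greedy_selection", "data.frame"))
}

#' Assign genes to the earliest-selected category annotating them
#'
#' A gene "falls into" the first category of the greedy ranking whose
#' ORIGINAL annotation contains it; genes annotated only to the root fall to
#' the root. This gives every gene in the universe a unique home category.
#'
#' @param sel A `greedy_selection` from [greedy_select()].
#' @param annot The same [go_annotation()] used for selection.
#' @param genes Character vector of genes to assign (within the universe).
#' @return Named character vector: gene -> category id.
#' @export
assign_genes <- function(sel, annot, genes) {
  stopifnot(inherits(sel, "greedy_selection"), inherits(annot, "go_annotation"))
  genes <- unique(genes)
  outside <- setdiff(genes, annot$universe)
  if (length(outside)) stopf("gene outside the universe: %s", outside[1])
  assignment <- stats::setNames(rep(NA_character_, length(genes)), genes)
  for (cat_id in sel$category) {
    members <- annot$categories[[cat_id]]
    hit <- is.na(assignment) & genes %in% members
    assignment[hit] <- cat_id
  }
  assignment[is.na(assignment)] <- annot$root_id
  assignment
}

#' Per-category hit report over a greedy selection
#'
#' For each selected category: the fraction of its (original) genes that are
#' hits, and the number of hit genes that fell into it under [assign_genes()].
#' Fallen-hit counts across categories sum to the number of assigned hit
#' genes.
#'
#' @param sel A `greedy_selection`.
#' @param annot The matching [go_annotation()].
#' @param hit_genes Character vector of hit genes (within the universe).
#' @return data.frame with columns `category`, `size`, `n_hits_annotated`,
#'   `hit_fraction`, `n_hits_fallen`.
#' @export
category_report <- function(sel, annot, hit_genes) {
  hit_genes <- unique(hit_genes)
  assignment <- assign_genes(sel, annot, hit_genes)
  fallen <- table(factor(assignment, levels = sel$category))
  rows <- lapply(sel$category, function(cat_id) {
    members <- annot$categories[[cat_id]]
    n_hit <- sum(members %in% hit_genes)
    data.frame(category = cat_id, size = length(members),
               n_hits_annotated = n_hit,
               hit_fraction = n_hit / length(members),
               n_hits_fallen = as.integer(fallen[[cat_id]]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
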