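# Seeded generators for every input the analyses consume: per-cell FISH count
# tables with latent nested subpopulations, reporter-infidelity tables, bulk
# negative-binomial count matrices with planted fold changes, and gene-ontology
# universes with planted enriched categories. Class sizes are stratified-exact
# (the printed compositions the fixtures encode are deterministic, not
# multinomial draws) and all randomness flows from one explicit seed per call.

`%||%` <- function(a, b) if (is.null(a)) b else a

DIST_FAMILIES <- c("negative-binomial", "lognormal-rounded", "constant")

validate_dist_spec <- function(spec, gene, class_name) {
  fam <- spec$family
  if (is.null(fam) || !fam %in% DIST_FAMILIES) {
    stopf("unknown distribution family '%s' for gene %s in class %s",
          fam %||% "<missing>", gene, class_name)
  }
  loc <- spec$location
  if (!is.numeric(loc) || length(loc) != 1L || is.na(loc) || loc < 0) {
    stopf("location for gene %s in class %s must be a single number >= 0", gene, class_name)
  }
  if (!is.null(spec$side) && !spec$side %in% c("+", "-")) {
    stopf("guard side for gene %s in class %s must be '+' or '-'", gene, class_name)
  }
  invisible(spec)
}

#' Specify one latent cell class of a FISH fixture
#'
#' A class is a stratum of cells sharing per-gene count distributions. Each
#' gene's distribution spec is a list with `family` (one of
#' `"negative-binomial"` with mean `location` and dispersion `dispersion`
#' where variance = mu + dispersion * mu^2, `"lognormal-rounded"` with median
#' `location` and log-sd `shape`, or `"constant"`), and optionally a guard
#' `side` (`"+"` or `"-"`) marking which side of that gene's cutoff the class
#' sits on.
#'
#' @param class_name Unique class label.
#' @param n_cells Exact number of cells in the stratum.
#' @param per_gene_dist Named list, gene -> distribution spec.
#' @param guard_margin Fraction in \[0, 1): with a guard side declared, counts
#'   are rejection-sampled into `>= ceiling(cutoff * (1 + margin))` for `"+"`
#'   classes and `< cutoff * (1 - margin)` for `"-"` classes, so downstream
#'   threshold classification recovers the latent label exactly.
#' @return A `cell_class_spec` list.
#' @export
cell_class_spec <- function(class_name, n_cells, per_gene_dist, guard_margin = 0) {
  if (!is_count_scalar(n_cells)) stopf("n_cells must be a non-negative integer")
  if (!is.numeric(guard_margin) || guard_margin < 0 || guard_margin >= 1) {
    stopf("guard_margin must lie in [0, 1)")
  }
  for (g in names(per_gene_dist)) validate_dist_spec(per_gene_dist[[g]], g, class_name)
  structure(list(class_name = class_name, n_cells = as.integer(n_cells),
                 per_gene_dist = per_gene_dist, guard_margin = guard_margin),
            class = "cell_class_spec")
}

#' Assemble a FISH fixture configuration
#'
#' @param classes List of [cell_class_spec()] strata (order = row order).
#' @param genes Ordered character vector of gene columns.
#' @param cutoffs Named numeric vector/list of per-gene positivity cutoffs
#'   (transcripts per cell); used both for guard enforcement here and for
#'   downstream classification. Every cutoff gene must have a distribution in
#'   every class.
#' @param seed Integer seed; identical config + seed gives a byte-identical
#'   table.
#' @param name Optional fixture label.
#' @return A `fixture_config` list.
#' @export
fixture_config <- function(classes, genes, cutoffs, seed, name = "fixture") {
  classes <- lapply(classes, function(cl) {
    if (inherits(cl, "cell_class_spec")) cl
    else cell_class_spec(cl$class_name, cl$n_cells, cl$per_gene_dist,
                         cl$guard_margin %||% 0)
  })
  nm <- vapply(classes, function(cl) cl$class_name, character(1))
  if (anyDuplicated(nm)) stopf("class names must be unique")
  cutoffs <- unlist(cutoffs)
  for (cl in classes) {
    missing <- setdiff(names(cutoffs), names(cl$per_gene_dist))
    if (length(missing)) {
      stopf("gene %s has a cutoff but no distribution in class %s",
            missing[1], cl$class_name)
    }
  }
  structure(list(name = name, classes = classes, genes = genes,
                 cutoffs = cutoffs, seed = as.integer(seed)),
            class = "fixture_config")
}

#' Load a fixture configuration from yaml
#'
#' Accepts the shipped fixture dialect: top-level `name`, `seed`, `genes`,
#' `cutoffs` and a `classes` list of class specs.
#'
#' @param path Path to a yaml config (see the files under
#'   `system.file("extdata", package = "stemhet")`).
#' @return A `fixture_config`.
#' @export
load_fixture_config <- function(path) {
  cfg <- read_config(path)
  fixture_config(cfg$classes, genes = unlist(cfg$genes), cutoffs = cfg$cutoffs,
                 seed = cfg$seed, name = cfg$name %||% basename(path))
}

# Draw n counts from one distribution spec, honouring the guard band.
sample_counts <- function(n, spec, cutoff = NULL, margin = 0) {
  draw <- function(m) {
    switch(spec$family,
      "negative-binomial" = {
        alpha <- spec$dispersion %||% 0
        if (alpha <= 0) stats::rpois(m, spec$location)
        else stats::rnbinom(m, mu = spec$location, size = 1 / alpha)
      },
      "lognormal-rounded" = {
        if (spec$location == 0) rep(0L, m)
        else round(stats::rlnorm(m, log(spec$location), spec$shape %||% 0.5))
      },
      "constant" = rep(round(spec$location), m))
  }
  side <- spec$side
  if (n == 0L) return(integer(0))
  if (is.null(side) || is.null(cutoff)) return(as.integer(draw(n)))
  lo <- if (side == "+") ceiling(cutoff * (1 + margin)) else -Inf
  hi <- if (side == "-") cutoff * (1 - margin) else Inf  # accept x < hi
  ok_region <- function(x) x >= lo & x < hi
  if (spec$family == "constant" && !ok_region(round(spec$location))) {
    stopf("constant count %g violates its guard band [%s, %s)",
          spec$location, lo, hi)
  }
  out <- integer(0)
  for (iter in 1:10000) {
    x <- as.integer(draw(max(n, 100L)))
    out <- c(out, x[ok_region(x)])
    if (length(out) >= n) return(out[seq_len(n)])
  }
  stopf("guard band [%s, %s) too improbable for family %s (location %g)",
        lo, hi, spec$family, spec$location)
}

#' Generate a per-cell FISH count table with latent class labels
#'
#' Draws class-conditional transcript counts for each stratum of the config,
#' with exactly the configured number of cells per class, in config order.
#' With a guard margin and declared sides, every count falls strictly on its
#' class's side of the gene's cutoff, so the latent labels are recoverable by
#' thresholding without error.
#'
#' @param config A `fixture_config` (or a path/list accepted by
#'   [load_fixture_config()]).
#' @param seed Integer seed; defaults to the config's own.
#' @return A `cell_count_table` with columns `cell_id`, `class` and one
#'   integer column per gene.
#' @examples
#' cfg <- fixture_config(
#'   classes = list(cell_class_spec("pos", 5, list(
#'     Nanog = list(family = "lognormal-rounded", location = 150,
#'                  shape = 0.4, side = "+"))),
#'     cell_class_spec("neg", 3, list(
#'     Nanog = list(family = "negative-binomial", location = 5,
#'                  dispersion = 0.5, side = "-")))),
#'   genes = "Nanog", cutoffs = c(Nanog = 30), seed = 1)
#' generate_fish_fixture(cfg)
#' @export
generate_fish_fixture <- function(config, seed = NULL) {
  if (is.character(config)) config <- load_fixture_config(config)
  if (!inherits(config, "fixture_config")) {
    config <- fixture_config(config$classes, unlist(config$genes), config$cutoffs,
                             config$seed, config$name %||% "fixture")
  }
  seed <- seed %||% config$seed
  genes <- config$genes
  with_seed(seed, {
    blocks <- lapply(config$classes, function(cl) {
      cols <- lapply(genes, function(g) {
        spec <- cl$per_gene_dist[[g]]
        if (is.null(spec)) return(rep(0L, cl$n_cells))
        sample_counts(cl$n_cells, spec, cutoff = config$cutoffs[[g]],
                      margin = cl$guard_margin)
      })
      names(cols) <- genes
      data.frame(class = rep(cl$class_name, cl$n_cells), cols,
                 check.names = FALSE, stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, blocks)
    df <- data.frame(cell_id = sprintf("cell_%05d", seq_len(nrow(df))), df,
                     check.names = FALSE, stringsAsFactors = FALSE)
    rownames(df) <- NULL
    new_cell_count_table(df, genes)
  })
}

#' Generate a reporter-infidelity table (mRNA vs reporter counts)
#'
#' Models reporter false negatives: each cell carries both the endogenous
#' mRNA count (e.g. Nanog) and a reporter transcript count (e.g. the
#' destabilized-Venus VNP reporter driven from the same locus). Among cells
#' positive for the endogenous mRNA, a Bernoulli(`fn_fraction`) subset has its
#' reporter count redrawn from a below-cutoff distribution while the mRNA
#' count is untouched — false negatives therefore retain the mRNA-positive
#' count distribution exactly.
#'
#' @param config List (or yaml path) with fields `fn_fraction`, `mrna_gene`,
#'   `reporter_gene`, `fn_reporter_dist` (distribution spec for the redrawn
#'   reporter counts) and `base_classes` (a fixture config whose genes include
#'   both markers and whose cutoffs define positivity for each).
#' @param seed Integer seed; defaults to the config's.
#' @return A `cell_count_table` with attribute `reporter_fn` (logical vector
#'   flagging the flipped cells).
#' @export
generate_reporter_table <- function(config, seed = NULL) {
  if (is.character(config)) config <- read_config(config)
  fnf <- config$fn_fraction
  if (!is_prob(fnf)) stopf("fn_fraction must lie in [0, 1]")
  base <- config$base_classes
  base_cfg <- if (inherits(base, "fixture_config")) base else
    fixture_config(base$classes, unlist(base$genes), base$cutoffs,
                   base$seed %||% config$seed %||% 0, base$name %||% "reporter-base")
  mg <- config$mrna_gene
  rg <- config$reporter_gene
  if (!all(c(mg, rg) %in% base_cfg$genes)) {
    stopf("mrna_gene and reporter_gene must both be fixture genes")
  }
  if (!is.null(config$n_cells) &&
      config$n_cells != sum(vapply(base_cfg$classes, `[[`, integer(1), "n_cells"))) {
    stopf("n_cells disagrees with the base class sizes")
  }
  seed <- seed %||% config$seed %||% base_cfg$seed
  fn_spec <- config$fn_reporter_dist
  fn_spec$side <- "-"
  validate_dist_spec(fn_spec, rg, "reporter-fn")
  with_seed(seed, {
    tab <- generate_fish_fixture(base_cfg, seed = floor(stats::runif(1, 1, 2^30)))
    mrna_pos <- tab[[mg]] >= base_cfg$cutoffs[[mg]]
    flip <- mrna_pos & (stats::runif(nrow(tab)) < fnf)
    if (any(flip)) {
      tab[[rg]][flip] <- sample_counts(sum(flip), fn_spec,
                                       cutoff = base_cfg$cutoffs[[rg]])
    }
    attr(tab, "reporter_fn") <- flip
    attr(tab, "cutoffs") <- base_cfg$cutoffs
    tab
  })
}

#' Generate a bulk count matrix with planted differential expression
#'
#' Draws negative-binomial counts for two conditions with replicates; a
#' `de_fraction` of genes get condition-2 mean = baseline * 2^`planted_log2fc`.
#' `dispersion` is the NB alpha (variance = mu + alpha * mu^2); alpha = 0 is
#' the Poisson limit.
#'
#' @param config List with fields `n_genes`, `conditions` (two labels),
#'   `replicates_per_condition` (>= 2), `baseline_mean` (scalar or per-gene
#'   vector), `dispersion`, `de_fraction`, `planted_log2fc`.
#' @param seed Integer seed; defaults to `config$seed`.
#' @return List with `counts` (integer gene x sample matrix) and `truth`
#'   (data.frame of planted genes and their log2 fold changes; empty if
#'   `de_fraction = 0`).
#' @export
generate_bulk_counts <- function(config, seed = NULL) {
  if (is.character(config)) config <- read_config(config)
  n <- config$n_genes
  reps <- config$replicates_per_condition
  conds <- unlist(config$conditions)
  alpha <- config$dispersion %||% 0
  if (!is_count_scalar(n) || n < 1) stopf("n_genes must be a positive integer")
  if (!is_count_scalar(reps) || reps < 2) stopf("replicates_per_condition must be >= 2")
  if (length(conds) != 2L) stopf("exactly two condition labels required")
  if (alpha < 0) stopf("dispersion must be >= 0")
  de_frac <- config$de_fraction %||% 0
  if (!is_prob(de_frac)) stopf("de_fraction must lie in [0, 1]")
  seed <- seed %||% config$seed
  with_seed(seed, {
    base_mu <- rep_len(unlist(config$baseline_mean), n)
    genes <- sprintf("gene_%05d", seq_len(n))
    n_de <- round(de_frac * n)
    de_idx <- if (n_de > 0) sort(sample.int(n, n_de)) else integer(0)
    lfc <- rep(0, n)
    lfc[de_idx] <- config$planted_log2fc %||% 0
    mu2 <- base_mu * 2^lfc
    draw <- function(mu, m) {
      if (alpha <= 0) stats::rpois(m, mu) else stats::rnbinom(m, mu = mu, size = 1 / alpha)
    }
    cols <- c(lapply(seq_len(reps), function(r) draw(rep(base_mu, 1), n)),
              lapply(seq_len(reps), function(r) draw(mu2, n)))
    counts <- matrix(as.integer(unlist(cols)), nrow = n,
                     dimnames = list(genes, c(paste0(conds[1], "_", seq_len(reps)),
                                              paste0(conds[2], "_", seq_len(reps)))))
    truth <- data.frame(gene = genes[de_idx],
                        log2fc = lfc[de_idx], stringsAsFactors = FALSE)
    list(counts = counts, truth = truth)
  })
}

#' Generate a gene-ontology universe with planted enriched categories
#'
#' Builds a root category annotating every gene plus `n_categories - 1`
#' non-root categories of sizes drawn from `size_range`. Planted categories
#' receive exactly `round(concentration * size)` interest genes; remaining
#' genes are interest with probability `interest_rate`. With
#' `overlap_rate = 0` non-root categories are pairwise disjoint.
#'
#' @param config List with fields `n_genes`, `n_categories` (including the
#'   root), `size_range` (length-2), `overlap_rate`, `interest_rate`
#'   (background interest probability, default 0), `planted` (list of
#'   `list(index =, concentration =)` for non-root category indices), and
#'   `root_id` (default `"GO:root"`).
#' @param seed Integer seed; defaults to `config$seed`.
#' @return List with `annot` (a [go_annotation()]) and `interest` (character
#'   vector of interest genes).
#' @export
generate_go_universe <- function(config, seed = NULL) {
  if (is.character(config)) config <- read_config(config)
  n <- config$n_genes
  k <- config$n_categories
  if (!is_count_scalar(n) || n < 1) stopf("n_genes must be a positive integer")
  if (!is_count_scalar(k) || k < 1) stopf("n_categories must be >= 1 (the root)")
  root_id <- config$root_id %||% "GO:root"
  ovl <- config$overlap_rate %||% 0
  bg <- config$interest_rate %||% 0
  if (!is_prob(ovl) || !is_prob(bg)) stopf("rates must lie in [0, 1]")
  sr <- unlist(config$size_range %||% c(1, n))
  if (length(sr) != 2L || sr[1] < 1 || sr[2] < sr[1]) stopf("bad size_range")
  planted <- config$planted %||% list()
  seed <- seed %||% config$seed
  with_seed(seed, {
    genes <- sprintf("g%04d", seq_len(n))
    n_extra <- k - 1L
    cats <- list()
    used <- character(0)
    for (j in seq_len(n_extra)) {
      s <- if (sr[1] == sr[2]) sr[1] else sample(seq(sr[1], sr[2]), 1)
      n_shared <- min(round(ovl * s), length(used))
      fresh_pool <- setdiff(genes, used)
      n_fresh <- s - n_shared
      if (n_fresh > length(fresh_pool)) {
        stopf("not enough unused genes for category %d (need %d fresh, have %d)",
              j, n_fresh, length(fresh_pool))
      }
      members <- c(if (n_shared > 0) sample(used, n_shared),
                   sample(fresh_pool, n_fresh))
      cats[[sprintf("GO:C%03d", j)]] <- sort(members)
      used <- union(used, members)
    }
    interest_flag <- stats::runif(n) < bg
    names(interest_flag) <- genes
    for (p in planted) {
      idx <- p$index
      conc <- p$concentration
      if (!is_count_scalar(idx) || idx < 1 || idx > n_extra) {
        stopf("planted index %s out of range", idx)
      }
      if (!is_prob(conc)) stopf("planted concentration must lie in [0, 1]")
      members <- cats[[idx]]
      n_int <- round(conc * length(members))
      if (n_int > length(members)) stopf("planted concentration infeasible for category size")
      interest_flag[members] <- FALSE
      interest_flag[sample(members, n_int)] <- TRUE
    }
    all_cats <- c(stats::setNames(list(genes), root_id), cats)
    list(annot = go_annotation(all_cats, root_id = root_id),
         interest = names(interest_flag)[interest_flag])
  })
}
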