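test_that("step-up adjustment matches hand-computed examples and handles NAs", {
  expect_equal(benjamini_hochberg(c(0.005, 0.1)), c(0.01, 0.1))
  expect_equal(benjamini_hochberg(0.37), 0.37)                        # m = 1
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")
  out <- benjamini_hochberg(c(0.005, NA, 0.1))
  expect_true(is.na(out[2]))
  expect_equal(out[c(1, 3)], c(0.01, 0.1))                            # NA excluded from m
})

test_that("adjusted p-values equal the independent step-up implementation on random vectors", {
  withr::with_seed(11, {
    for (rep in 1:200) {
      m <- sample(1:80, 1)
      p <- runif(m)^sample(1:3, 1)
      expect_equal(benjamini_hochberg(p), stats::p.adjust(p, method = "BH"),
                   tolerance = 1e-12)
    }
  })
})

test_that("hit calling uses an inclusive boundary and is monotone in the threshold", {
  tab <- comparison_table(gene = c("a", "b", "c", "d"),
                          log2fc = c(1, -1, 2, 0.5),
                          pvalue = c(0.001, 0.5, 0.04, 1),
                          padj = c(0.004, 0.6, 0.10, 1))
  tab <- call_hits(tab, fdr = 0.10)
  expect_true(tab$hit[tab$gene == "c"])        # padj exactly 0.10 is a hit
  expect_equal(attr(tab, "n_hits"), 2L)
  all_one <- call_hits(comparison_table("x", 0, 1), fdr = 0.10)
  expect_equal(attr(all_one, "n_hits"), 0L)
  # lowering the FDR threshold never increases hits
  withr::with_seed(5, {
    p <- runif(300)^2
    big <- comparison_table(sprintf("g%03d", 1:300), rnorm(300), p)
    hits <- vapply(c(0.2, 0.1, 0.05, 0.01),
                   function(f) attr(call_hits(big, f), "n_hits"), integer(1))
    expect_true(all(diff(hits) <= 0))
  })
})

test_that("realized false-discovery proportion stays near the nominal level", {
  # planted bulk simulations scored with the naive per-gene test harness
  fdp <- withr::with_seed(31, vapply(1:30, function(i) {
    sim <- generate_bulk_counts(list(n_genes = 150, conditions = c("stem", "diff"),
                                     replicates_per_condition = 3,
                                     baseline_mean = 200, dispersion = 0.02,
                                     de_fraction = 0.1, planted_log2fc = 3),
                                seed = i)
    grp <- sub("_[0-9]+$", "", colnames(sim$counts))
    pv <- naive_gene_pvalues(sim$counts, grp)
    tab <- comparison_table(rownames(sim$counts), log2fc = rep(1, 150),
                            pvalue = pv, fdr = 0.10)
    hits <- tab$gene[tab$hit]
    if (!length(hits)) return(0)
    mean(!hits %in% sim$truth$gene)
  }, numeric(1)))
  expect_lt(mean(fdp), 0.20)   # within 2x of the nominal 10%
})

test_that("quadrants classify joint hits by fold-change sign agreement", {
  ta <- comparison_table(c("up_up", "dn_dn", "up_dn", "dn_up", "zero", "only_a", "none"),
                         log2fc = c(1, -2, 1.5, -0.5, 0, 2, 1),
                         pvalue = rep(0.001, 7),
                         padj = c(rep(0.01, 6), 0.9))
  tb <- comparison_table(c("up_up", "dn_dn", "up_dn", "dn_up", "zero", "only_a", "none"),
                         log2fc = c(2, -1, -1, 0.7, 1, 2, 1),
                         pvalue = rep(0.001, 7),
                         padj = c(rep(0.01, 5), 0.9, 0.01))
  qs <- quadrant_classify(call_hits(ta), call_hits(tb))
  expect_equal(qs$n_joint_hits, 5L)
  expect_equal(unname(qs$counts), c(1L, 1L, 1L, 1L, 1L))
  expect_equal(qs$coherent_fraction, 0.5)
  # conservation: classified + excluded = joint hits
  expect_equal(sum(qs$counts), qs$n_joint_hits)
  got <- qs$per_gene$quadrant[match(c("up_up", "dn_dn", "up_dn", "dn_up", "zero"),
                                    qs$per_gene$gene)]
  expect_equal(got, c("coherent_up", "coherent_down", "incoherent_a_up",
                      "incoherent_b_up", "excluded_zero_fc"))
  expect_false("only_a" %in% qs$per_gene$gene)   # hit in only one table
  expect_error(quadrant_classify(
    comparison_table("x", 1, 0.01), comparison_table("y", 1, 0.01)), "share no genes")
})

test_that("planted quadrant memberships are recovered exactly", {
  withr::with_seed(17, {
    n <- 200
    genes <- sprintf("g%03d", 1:n)
    lfc_a <- sample(c(-2, -1, 1, 2), n, replace = TRUE)
    lfc_b <- sample(c(-2, -1, 1, 2), n, replace = TRUE)
    hit_a <- runif(n) < 0.6
    hit_b <- runif(n) < 0.6
    ta <- comparison_table(genes, lfc_a, pvalue = ifelse(hit_a, 0.001, 0.9),
                           padj = ifelse(hit_a, 0.01, 0.9))
    tb <- comparison_table(genes, lfc_b, pvalue = ifelse(hit_b, 0.001, 0.9),
                           padj = ifelse(hit_b, 0.01, 0.9))
    qs <- quadrant_classify(ta, tb)
    joint <- hit_a & hit_b
    expect_equal(qs$n_joint_hits, sum(joint))
    expect_equal(qs$counts[["coherent_up"]], sum(joint & lfc_a > 0 & lfc_b > 0))
    expect_equal(qs$counts[["coherent_down"]], sum(joint & lfc_a < 0 & lfc_b < 0))
    expect_equal(qs$counts[["incoherent_a_up"]], sum(joint & lfc_a > 0 & lfc_b < 0))
    expect_equal(qs$counts[["incoherent_b_up"]], sum(joint & lfc_a < 0 & lfc_b > 0))
  })
})

test_that("binding overlap fractions match brute-force set intersection", {
  universe <- sprintf("g%03d", 1:200)
  withr::with_seed(23, {
    binding <- list(Oct4 = sample(universe, 60), Nanog = sample(universe, 40),
                    Empty = character(0))
    hit_sets <- list(up = sample(universe, 50), down = sample(universe, 30))
    res <- binding_overlap_fraction(binding, hit_sets, universe)
    for (i in seq_len(nrow(res))) {
      f <- res$factor[i]; h <- res$hit_type[i]
      if (f == "Empty") {
        expect_true(res$undefined[i] && is.na(res$fraction[i]))
      } else {
        expect_equal(res$fraction[i],
                     length(intersect(binding[[f]], hit_sets[[h]])) / length(binding[[f]]))
      }
      expect_equal(res$background[i], length(hit_sets[[h]]) / length(universe))
    }
    # bound set = universe: fraction equals the background exactly
    res_all <- binding_overlap_fraction(list(All = universe), hit_sets, universe)
    expect_equal(res_all$fraction, res_all$background)
  })
  expect_error(binding_overlap_fraction(list(F1 = "g001"), list(up = "zzz"), universe),
               "outside the universe")
})

test_that("directional gene-set summaries count hits and direction correctly", {
  n <- 300
  genes <- sprintf("g%03d", 1:n)
  withr::with_seed(29, {
    lfc <- rnorm(n)
    padj <- runif(n)
    tab <- comparison_table(genes, lfc, pvalue = padj / 2, padj = padj, fdr = 0.10)
    set <- sample(genes, 80)
    s <- gene_set_directional_summary(set, tab)
    sub <- tab[match(set, tab$gene), ]
    expect_equal(s$n_set, 80)
    expect_equal(s$n_hits, sum(sub$hit))
    expect_equal(s$n_up, sum(sub$hit & sub$log2fc > 0))
    expect_equal(s$n_down, sum(sub$hit & sub$log2fc < 0))
    expect_equal(s$bias, (s$n_up - s$n_down) / (s$n_up + s$n_down))
  })
  # a 166-member set with 76 hits has hit fraction 0.458 (~46%)
  tab2 <- comparison_table(sprintf("linc%03d", 1:166), log2fc = rep(1, 166),
                           pvalue = c(rep(0.001, 76), rep(0.9, 90)),
                           padj = c(rep(0.01, 76), rep(0.9, 90)))
  s2 <- gene_set_directional_summary(sprintf("linc%03d", 1:166), tab2)
  expect_equal(s2$n_hits, 76)
  expect_equal(round(s2$hit_fraction, 3), 0.458)
  expect_equal(s2$bias, 1)   # all hits up
  expect_error(gene_set_directional_summary(character(0), tab2), "empty")
})
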