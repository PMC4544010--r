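test_that("fixtures are stratified-exact, seeded and guard-separated", {
  cfg <- load_fixture_config(fixture_path("fig4a.yaml"))
  tab <- generate_fish_fixture(cfg)
  expect_equal(nrow(tab), 1189)
  expect_equal(as.vector(table(tab$class)[vapply(cfg$classes, `[[`, "", "class_name")]),
               vapply(cfg$classes, `[[`, integer(1), "n_cells"))
  # determinism: identical config + seed => identical table
  expect_identical(generate_fish_fixture(cfg), tab)
  # different seed changes counts but not the strata
  tab2 <- generate_fish_fixture(cfg, seed = 999)
  expect_false(identical(tab2$Nanog, tab$Nanog))
  expect_identical(tab2$class, tab$class)

  # guarded separation, checked by direct scan of the generated table
  for (cl in cfg$classes) {
    rows <- tab$class == cl$class_name
    for (g in cfg$genes) {
      side <- cl$per_gene_dist[[g]]$side
      cut <- cfg$cutoffs[[g]]
      m <- cl$guard_margin
      if (identical(side, "+")) {
        expect_gte(min(tab[[g]][rows]), ceiling(cut * (1 + m)))
      } else {
        expect_lt(max(tab[[g]][rows]), cut * (1 - m))
      }
    }
  }
})

test_that("degenerate and invalid fixture configs behave as documented", {
  cfg <- fixture_config(
    classes = list(cell_class_spec("zero", 10, list(
      Nanog = list(family = "constant", location = 0)))),
    genes = "Nanog", cutoffs = c(Nanog = 30), seed = 1)
  tab <- generate_fish_fixture(cfg)
  expect_equal(tab$Nanog, rep(0L, 10))

  expect_error(cell_class_spec("x", 5, list(Nanog = list(family = "weibull", location = 3))),
               "unknown distribution family")
  expect_error(fixture_config(
    classes = list(cell_class_spec("x", 5, list(Oct4 = list(family = "constant", location = 3)))),
    genes = c("Nanog", "Oct4"), cutoffs = c(Nanog = 30), seed = 1),
    "cutoff but no distribution")
  expect_error(generate_fish_fixture(fixture_config(
    classes = list(cell_class_spec("x", 5, list(
      Nanog = list(family = "constant", location = 10, side = "+"))),
      cell_class_spec("y", 5, list(
      Nanog = list(family = "constant", location = 10, side = "-")))),
    genes = "Nanog", cutoffs = c(Nanog = 30), seed = 1)),
    "guard band")
})

test_that("reporter infidelity flips reporter calls while preserving mRNA counts", {
  cfg <- read_config(fixture_path("reporter.yaml"))
  # fn_fraction = 0: reporter-based and mRNA-based classification agree
  cfg0 <- cfg; cfg0$fn_fraction <- 0
  t0 <- generate_reporter_table(cfg0)
  expect_equal(t0$VNP >= 30, t0$Nanog >= 30)
  # fn_fraction = 1 on an all-positive base: every cell reporter(-) yet mRNA(+)
  cfg1 <- cfg; cfg1$fn_fraction <- 1
  cfg1$n_cells <- 1333
  cfg1$base_classes$classes <- cfg1$base_classes$classes[1]
  t1 <- generate_reporter_table(cfg1)
  expect_true(all(t1$Nanog >= 30))
  expect_true(all(t1$VNP < 30))

  # false negatives retain the mRNA-positive count distribution: the flip
  # only rewrites the reporter column
  tab <- generate_reporter_table(cfg)
  flip <- attr(tab, "reporter_fn")
  expect_true(all(tab$VNP[flip] < 30))          # flipped cells are reporter(-)
  expect_true(all(tab$Nanog[flip] >= 30))       # ... but remain mRNA(+)
  untouched <- !flip & tab$class == "NanogPos"
  expect_true(all(tab$VNP[untouched] >= 30))    # unflipped positives keep high VNP
  expect_true(all(tab$VNP[tab$class == "NanogNeg"] < 30))

  expect_error(generate_reporter_table(within(cfg, fn_fraction <- 1.2)),
               "fn_fraction")
})

test_that("reporter composition matches the config-implied value within binomial error", {
  cfg <- read_config(fixture_path("reporter.yaml"))
  tab <- generate_reporter_table(cfg)
  vnp_neg <- tab$VNP < cfg$base_classes$cutoffs$VNP
  frac <- mean(tab$Nanog[vnp_neg] >= cfg$base_classes$cutoffs$Nanog)
  # implied by the config: fn * n_pos / (n_neg + fn * n_pos)
  n_pos <- 1333; n_neg <- 667
  implied <- cfg$fn_fraction * n_pos / (n_neg + cfg$fn_fraction * n_pos)
  half_width <- stats::qnorm(0.995) * sqrt(implied * (1 - implied) / sum(vnp_neg))
  expect_lt(abs(frac - implied), half_width)
})

test_that("bulk counts have NB moments and honest truth tables", {
  # Poisson limit at zero dispersion
  sim0 <- generate_bulk_counts(list(n_genes = 5, conditions = c("A", "B"),
                                    replicates_per_condition = 200,
                                    baseline_mean = 100, dispersion = 0), seed = 11)
  a_cols <- grepl("^A_", colnames(sim0$counts))
  vm <- apply(sim0$counts[, a_cols], 1, var) / rowMeans(sim0$counts[, a_cols])
  expect_true(all(abs(vm - 1) < 0.45))

  # NB moment formula: var = mu + alpha mu^2 at 1e4 draws, 10% tolerance
  simnb <- generate_bulk_counts(list(n_genes = 1, conditions = c("A", "B"),
                                     replicates_per_condition = 5000,
                                     baseline_mean = 100, dispersion = 0.1), seed = 12)
  draws <- as.numeric(simnb$counts)  # both conditions identical mean (no DE)
  expect_equal(length(draws), 10000)
  expect_lt(abs(var(draws) - (100 + 0.1 * 100^2)) / (100 + 0.1 * 100^2), 0.10)

  # planted genes shift condition-2 means; empty truth at de_fraction 0
  sim <- generate_bulk_counts(list(n_genes = 400, conditions = c("A", "B"),
                                   replicates_per_condition = 50,
                                   baseline_mean = 100, dispersion = 0.05,
                                   de_fraction = 0.1, planted_log2fc = 2), seed = 13)
  expect_equal(nrow(sim$truth), 40)
  de <- rownames(sim$counts) %in% sim$truth$gene
  b_cols <- grepl("^B_", colnames(sim$counts))
  expect_gt(mean(rowMeans(sim$counts[de, b_cols])), 300)
  expect_lt(abs(mean(rowMeans(sim$counts[!de, b_cols])) - 100), 10)
  sim_no <- generate_bulk_counts(list(n_genes = 50, conditions = c("A", "B"),
                                      replicates_per_condition = 2,
                                      baseline_mean = 10, dispersion = 0.1,
                                      de_fraction = 0), seed = 14)
  expect_equal(nrow(sim_no$truth), 0)
})

test_that("GO universes honour the root, planting and disjointness", {
  # root-only universe
  u1 <- generate_go_universe(list(n_genes = 20, n_categories = 1), seed = 3)
  expect_equal(names(u1$annot$categories), "GO:root")
  expect_equal(greedy_select(u1$annot, u1$interest, min_size = 1)$category, "GO:root")

  u <- generate_go_universe(list(n_genes = 300, n_categories = 8,
                                 size_range = c(15, 25), overlap_rate = 0,
                                 interest_rate = 0.1,
                                 planted = list(list(index = 3, concentration = 0.8))),
                            seed = 21)
  cats <- u$annot$categories
  expect_equal(cats[[u$annot$root_id]], u$annot$universe)
  nonroot <- cats[names(cats) != u$annot$root_id]
  for (i in seq_along(nonroot)) for (j in seq_len(i - 1L)) {
    expect_length(intersect(nonroot[[i]], nonroot[[j]]), 0)
  }
  planted <- cats[["GO:C003"]]
  expect_equal(sum(planted %in% u$interest), round(0.8 * length(planted)))
  # reproducible under seed
  expect_identical(generate_go_universe(list(n_genes = 300, n_categories = 8,
                                             size_range = c(15, 25), overlap_rate = 0,
                                             interest_rate = 0.1,
                                             planted = list(list(index = 3, concentration = 0.8))),
                                        seed = 21), u)
})
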