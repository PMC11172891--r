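test_that("rank aggregation is additive, idempotent at species level, and conservative", {
  t <- tiny_taxon_table()
  ph <- aggregate_level(t, "phylum")
  expect_equal(ph$abundances["Actinobacteria", "S1"], 40 + 10)
  expect_equal(ph$abundances["Firmicutes", "S2"], 40 + 20)
  # species-level aggregation of a species table is the identity
  sp <- aggregate_level(t, "species")
  expect_equal(sort(rownames(sp$abundances)),
               sort(sub(".*s__", "", rownames(t$abundances))))
  expect_equal(colSums(sp$abundances), colSums(t$abundances), tolerance = 1e-9)
  # totals preserved at every rank
  for (rank in c("phylum", "genus", "species"))
    expect_equal(colSums(aggregate_level(t, rank)$abundances),
                 colSums(t$abundances), tolerance = 1e-9)
  expect_error(aggregate_level(t, "tribe"), "rank")
})

test_that("aggregation matches a brute-force group-by oracle on random tables", {
  set.seed(61)
  sim <- simulate_microbiome(microbiome_sim_config(seed = 61))
  t <- sim$table
  agg <- aggregate_level(t, "phylum")
  phyla <- sub(".*p__([^|]+).*", "\\1", rownames(t$abundances))
  oracle <- apply(t$abundances, 2, function(col) tapply(col, phyla, sum))
  expect_equal(agg$abundances[rownames(oracle), ], oracle, tolerance = 1e-12)
})

test_that("rare-taxon lumping respects the group-mean rule and conserves mass", {
  t <- tiny_taxon_table()
  ann <- sample_annotation(paste0("S", 1:4), rep(c("patient", "control"), 2))
  lump <- lump_rare(t, ann, threshold_percent = 8)
  # Moraxella (5/5/5/10) is below 8% in both group means; mastitidis
  # (10/0/5/0) is below 8 in both -> both lumped
  expect_true("Under 1%" %in% rownames(lump$abundances))
  expect_false(any(grepl("Moraxella|mastitidis", rownames(lump$abundances))))
  expect_true(any(grepl("acnes", rownames(lump$abundances))))
  # mass balance: lumped row equals total minus retained
  expect_equal(colSums(lump$abundances), colSums(t$abundances),
               tolerance = 1e-9)
  keep <- setdiff(rownames(lump$abundances), "Under 1%")
  expect_equal(lump$abundances["Under 1%", ],
               colSums(t$abundances) - colSums(lump$abundances[keep, ]),
               tolerance = 1e-9)

  # taxon abundant in one group only is retained under the group rule
  x2 <- t$abundances
  x2["k__Bacteria|p__Actinobacteria|g__Corynebacterium|s__Corynebacterium_mastitidis", ] <-
    c(30, 0, 30, 0) # high in patients (S1, S3), absent in controls
  x2 <- sweep(x2, 2, colSums(x2), "/") * 100
  lump2 <- lump_rare(taxon_abundance(x2, "percent"), ann,
                     threshold_percent = 8)
  expect_true(any(grepl("mastitidis", rownames(lump2$abundances))))

  # nothing below threshold: table returned unchanged
  expect_identical(lump_rare(t, ann, threshold_percent = 0.01), t)
})

test_that("diversity comparison: degenerate equality and directional power", {
  # identical composition in every sample: all H equal, p = 1
  X <- matrix(rep(c(0.5, 0.3, 0.2), 6), nrow = 3,
              dimnames = list(c("k__B|p__X|s__a", "k__B|p__X|s__b",
                                "k__B|p__Y|s__c"), paste0("S", 1:6)))
  t <- taxon_abundance(X, "fraction")
  ann <- sample_annotation(paste0("S", 1:6), rep(c("patient", "control"), 3))
  expect_equal(diversity_compare(t, ann)$p_value, 1)

  # groups built with distinct evenness: small p, direction matches
  set.seed(15)
  even <- replicate(8, { p <- rgamma(10, 20); p / sum(p) })
  uneven <- replicate(8, { p <- rgamma(10, 0.3); p / sum(p) })
  X2 <- cbind(even, uneven)
  dimnames(X2) <- list(sprintf("k__B|p__P%d|s__s%d", 1:10, 1:10),
                       paste0("S", 1:16))
  t2 <- taxon_abundance(X2, "fraction")
  ann2 <- sample_annotation(paste0("S", 1:16),
                            rep(c("even", "uneven"), each = 8))
  dc <- diversity_compare(t2, ann2)
  expect_lt(dc$p_value, 0.01)
  expect_gt(dc$group_means[["even"]], dc$group_means[["uneven"]])
})

test_that("presence/absence association reproduces the simulated marker pattern", {
  sim <- simulate_microbiome(microbiome_sim_config(seed = 19))
  res <- presence_absence_test(sim$table, sim$annotation,
                               "Corynebacterium_mastitidis")
  # contingency table matches the simulation truth
  pres <- sim$truth$marker_presence
  grp <- sim$annotation$group
  expect_equal(unname(res$table[1, 1]), sum(pres[grp == "patient"]))
  expect_equal(unname(res$table[2, 1]), sum(pres[grp == "control"]))
  expect_equal(res$p_value, fisher_exact_2x2(res$table))

  # scale invariance at threshold 0
  pct <- taxon_abundance(sim$table$abundances * 100, "percent")
  expect_equal(presence_absence_test(pct, sim$annotation,
                                     "Corynebacterium_mastitidis")$p_value,
               res$p_value)

  # marker restricted to controls at prevalence 7/16 is usually detectable
  ps <- vapply(1:15, function(sd) {
    s <- simulate_microbiome(microbiome_sim_config(seed = sd))
    presence_absence_test(s$table, s$annotation,
                          "Corynebacterium_mastitidis")$p_value
  }, numeric(1))
  expect_lt(median(ps), 0.05)

  expect_error(presence_absence_test(sim$table, sim$annotation, "no_such"),
               "not found")
})

test_that("community comparison separates constructed communities and reproduces", {
  sim <- simulate_microbiome(microbiome_sim_config(seed = 2))
  x <- sim$table$abundances
  grp <- sim$annotation$group == "patient"
  x[1, grp] <- x[1, grp] + 5 # strong compositional shift in patients
  x <- sweep(x, 2, colSums(x), "/")
  t <- taxon_abundance(x, "fraction")
  cc <- community_comparison(t, sim$annotation, n_perm = 199, seed = 3)
  expect_equal(cc$permanova$p_value, 1 / 200)
  expect_equal(dim(cc$pca$scores)[1], 32)

  cc2 <- community_comparison(t, sim$annotation, n_perm = 199, seed = 3)
  expect_identical(cc2$permanova$p_value, cc$permanova$p_value)

  # Bray-Curtis option runs and stays within [0, 1] distances internally
  cb <- community_comparison(t, sim$annotation, n_perm = 99, seed = 4,
                             distance = "bray")
  expect_true(cb$permanova$p_value >= 1 / 100)
})
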