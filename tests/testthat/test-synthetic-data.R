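# Generator: factorial design, taxon archetypes, counts, chemistry.

test_that("default design matches the factorial layout", {
  d <- generate_design()
  expect_equal(nrow(d), 384)
  expect_equal(as.integer(table(d$year)), rep(64L, 6))
  expect_false(anyDuplicated(d$sample_id) > 0)
  # 4 beech + 4 fir per canopy per block-year
  per_cell <- dplyr::count(d, year, block, canopy, tree)
  expect_true(all(per_cell$n == 4))
  # every sample carries exactly one tree species, even on mixed plots
  expect_true(all(d$tree %in% c("beech", "fir")))
  expect_equal(sum(d$mixture), 384 / 2)
})

test_that("design size scales with blocks and years and rejects empties", {
  expect_equal(nrow(generate_design(1, 1)), 16)
  expect_error(generate_design(0, 6), "n_blocks")
  expect_error(generate_design(4, 0), "n_years")
})

test_that("taxon archetypes honour the specialist fraction and Beta law", {
  all_spec <- generate_taxa(100, specialist_fraction = 1, seed = 7)
  expect_true(all(all_spec$pi_tree %in% c(0, 1)))
  expect_true(all(all_spec$pi_canopy %in% c(0, 1)))

  expect_equal(nrow(generate_taxa(0)), 0)

  gen <- generate_taxa(10000, specialist_fraction = 0,
                       affinity_shape = c(2, 2), seed = 1)
  expect_lt(abs(mean(gen$pi_tree) - 0.5), 0.02)
  expect_true(all(gen$sigma > 0) && all(gen$base > 0))
  expect_error(generate_taxa(10, specialist_fraction = 1.5), "proportion")
})

test_that("generator output is reproducible and closed at depth", {
  s <- small_simulation()
  m <- counts_matrix(s$counts)
  expect_true(all(colSums(m) == 1000))
  again <- generate_community_counts(s$design, s$taxa, depth = 1000,
                                     seed = 42)
  expect_identical(s$counts, again$counts)

  other <- generate_community_counts(s$design, s$taxa, depth = 1000,
                                     seed = 43)
  expect_false(identical(s$counts, other$counts))
})

test_that("hard tree specialists never produce reads on the other tree", {
  s <- small_simulation()
  m <- counts_matrix(s$counts)
  fir_samples <- s$design$sample_id[s$design$tree == "fir"]
  beech_only <- s$taxa$taxon_id[s$taxa$pi_tree == 1]
  expect_gt(length(beech_only), 0)
  expect_true(all(m[beech_only, fir_samples] == 0))
})

test_that("counts generator rejects empty taxa and impossible samples", {
  d <- generate_design(1, 1)
  expect_error(generate_community_counts(d, generate_taxa(0), seed = 1),
               "non-empty")
  # a taxon set that cannot occur in open-canopy samples
  taxa <- generate_taxa(3, specialist_fraction = 0, seed = 1)
  taxa$pi_canopy <- 1
  expect_error(generate_community_counts(d, taxa, depth = 100, seed = 1),
               "all-zero expected composition")
})

test_that("noise-free chemistry reproduces the trajectory anchors", {
  d <- generate_design(1, 6)
  ch <- generate_chemistry(d, noise_sd = 0)
  j <- dplyr::left_join(ch, d, by = "sample_id")
  expect_equal(unique(j$ergosterol[j$tree == "beech" & j$year == 1]), 31)
  expect_equal(unique(j$ergosterol[j$tree == "beech" & j$year == 6]), 110)
  expect_equal(unique(j$ergosterol[j$tree == "fir" & j$year == 6]), 48)
  expect_equal(unique(j$ergosterol[j$tree == "fir" & j$year == 5]), 48)
  expect_equal(unique(j$pH[j$year == 6]), 4.0)
  expect_equal(unique(j$pH[j$year == 1]), 5.3)
  expect_equal(unique(j$N[j$tree == "beech" & j$year == 1]), 0.27)
  expect_equal(unique(j$N[j$tree == "fir" & j$year == 1]), 0.16)
  expect_error(generate_chemistry(d, noise_sd = -1), "non-negative")
})

test_that("noisy chemistry stays within physical bounds", {
  d <- generate_design(2, 6)
  ch <- generate_chemistry(d, noise_sd = 2, seed = 3)
  expect_true(all(ch$pH > 0 & ch$pH < 14))
  expect_true(all(ch$ergosterol >= 0))
  expect_true(all(ch$moisture >= 0 & ch$moisture <= 100))
  expect_identical(ch, generate_chemistry(d, noise_sd = 2, seed = 3))
})

test_that("specificity estimates sharpen as sequencing depth grows", {
  design <- generate_design(2, 3)
  err_at_depth <- vapply(c(200, 2000, 20000), function(depth) {
    errs <- vapply(1:6, function(s) {
      taxa <- generate_taxa(50, seed = s)
      sim <- generate_community_counts(design, taxa, depth = depth,
                                       seed = s)
      rel <- relative_abundance(sim$counts)
      sp <- taxon_specificity(rel, design, "tree")
      mean(abs(sp$specificity - taxa$pi_tree), na.rm = TRUE)
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  expect_true(all(diff(err_at_depth) < 0))
})
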