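# Rarefaction, normalisation, species aggregation, filters, guild shares.

test_that("rarefaction closes at depth and never invents reads", {
  s <- small_simulation(depth = 1500)
  rare <- rarefy_counts(s$counts, depth = 500, seed = 1)
  m_in <- counts_matrix(s$counts)
  m_out <- counts_matrix(rare)
  expect_true(all(colSums(m_out) == 500))
  expect_true(all(rownames(m_out) %in% rownames(m_in)))
  expect_true(all(m_out <= m_in[rownames(m_out), colnames(m_out)]))
  # a sample already at depth is returned unchanged
  one <- toy_counts(c(300), c(200), samples = "s1")
  expect_equal(counts_matrix(rarefy_counts(one, depth = 500, seed = 1)),
               counts_matrix(one))
})

test_that("samples below depth are dropped with a warning and logged", {
  tbl <- toy_counts(c(300, 100), c(199, 400)) # s2 sums to 500, s1 to 499
  m <- counts_matrix(tbl)
  expect_equal(unname(colSums(m)), c(499, 500))
  expect_warning(out <- rarefy_counts(tbl, depth = 500, seed = 1), "s1")
  expect_equal(attr(out, "dropped_samples"), "s1")
  expect_equal(setdiff(names(tbl), names(out)), "s1")
  expect_error(rarefy_counts(tbl, depth = 0), "integer")
})

test_that("rarefied counts follow the hypergeometric expectation", {
  # one taxon holds 50% of a 4000-read sample; at depth 2000 its rarefied
  # count is hypergeometric with mean 1000
  tbl <- toy_counts(c(2000), c(2000), samples = "s1")
  draws <- vapply(1:1000, function(s) {
    counts_matrix(rarefy_counts(tbl, depth = 2000, seed = s))[1, 1]
  }, numeric(1))
  n <- 2000; npop <- 4000
  v <- n * 0.5 * 0.5 * (npop - n) / (npop - 1)
  expect_lt(abs(mean(draws) - 1000), 3 * sqrt(v / 1000))
})

test_that("relative abundance and Hellinger have the stated geometry", {
  tbl <- toy_counts(c(1, 4), c(0, 1), c(3, 4))
  rel <- relative_abundance(tbl)
  expect_equal(unname(counts_matrix(rel)[, "s1"]), c(0.25, 0, 0.75))
  expect_equal(unname(colSums(counts_matrix(rel))), c(1, 1))

  h <- counts_matrix(hellinger(tbl))
  expect_equal(unname(h[, "s2"]), c(2 / 3, 1 / 3, 2 / 3))
  expect_equal(unname(sqrt(colSums(h^2))), c(1, 1), tolerance = 1e-9)
  # idempotence of normalisation: hellinger of proportions = of counts
  expect_equal(hellinger(rel), hellinger(tbl))

  zero <- toy_counts(c(0, 1), c(0, 2))
  expect_error(relative_abundance(zero), "s1")
})

test_that("species aggregation merges, demotes and discards correctly", {
  tbl <- toy_counts(c(3, 1), c(5, 2), c(4, 4), c(7, 0), c(2, 9),
                    taxa = paste0("otu", 1:5))
  tax <- tibble::tibble(
    otu_id = paste0("otu", 1:5),
    species = c("Mycena alba", "Mycena alba", NA, "Fagus sp.",
                "Stereum hirsutum"),
    genus = c("Mycena", "Mycena", "Mycena", "Fagus", "Stereum"),
    identity_pct = c(99, 98, 96, 100, 99),
    coverage_pct = c(99, 99, 99, 100, 99),
    kingdom_flag = c("fungal", "fungal", "fungal", "host_plant", "fungal")
  )
  out <- aggregate_to_species(tbl, tax)
  m <- counts_matrix(out)
  expect_setequal(rownames(m), c("Mycena alba", "Mycena sp.",
                                 "Stereum hirsutum"))
  expect_equal(unname(m["Mycena alba", ]), c(8, 3)) # 3+5, 1+2
  expect_equal(unname(m["Mycena sp.", ]), c(4, 4)) # 96% identity demoted
  expect_false("Fagus sp." %in% rownames(m)) # host plant discarded
  # totals of retained fungal OTUs conserved
  expect_equal(colSums(m), colSums(counts_matrix(tbl)[c(1, 2, 3, 5), ]))

  expect_error(aggregate_to_species(tbl, tax[1:3, ]), "otu4")
})

test_that("abundance filter presets follow their definitions", {
  # taxon a: 0.6% in 3 samples (kept by ordination, not specificity);
  # taxon b: 2% in 3 samples (kept by both); taxon c: rare everywhere
  n <- 6
  a <- rep(c(0.006, 0), c(3, 3))
  b <- rep(c(0.02, 0.004), c(3, 3))
  c_ <- rep(0.004, n)
  filler <- 1 - (a + b + c_)
  rel <- toy_counts(a, b, c_, filler, taxa = c("a", "b", "c", "fill"))

  kept2 <- apply_abundance_filter(rel, "ordination")
  expect_true(all(c("a", "b") %in% kept2))
  expect_false("c" %in% kept2)

  kept6 <- apply_abundance_filter(rel, "specificity")
  expect_true("b" %in% kept6)
  expect_false("a" %in% kept6) # never exceeds 1% in any sample
  # specificity subset is nested in the ordination subset
  expect_true(all(kept6 %in% kept2))

  expect_error(apply_abundance_filter(rel, "fig9"), "unknown filter")
  empty <- rel[0, ]
  expect_equal(apply_abundance_filter(empty, "ordination"), character())
})

test_that("succession preset uses yearly treatment means", {
  # taxon a: 1.5% in years 1-3 of one treatment -> kept (3 yearly obs > 1%)
  # taxon b: single-year spike at 3% -> kept via the 2% max clause
  # taxon c: 0.8% everywhere -> dropped
  ids <- paste0("s", 1:6)
  meta <- toy_metadata(ids, year = c(1, 1, 2, 2, 3, 3))
  a <- c(0.015, 0.015, 0.015, 0.015, 0.015, 0.015)
  b <- c(0.03, 0.03, 0, 0, 0, 0)
  c_ <- rep(0.008, 6)
  rel <- toy_counts(a, b, c_, 1 - (a + b + c_), samples = ids,
                    taxa = c("a", "b", "c", "fill"))
  kept <- apply_abundance_filter(rel, "succession", meta)
  expect_true(all(c("a", "b") %in% kept))
  expect_false("c" %in% kept)
  expect_error(apply_abundance_filter(rel, "succession"), "metadata")
})

test_that("guild shares are closed and match hand-computed values", {
  ids <- paste0("s", 1:4)
  meta <- toy_metadata(ids, tree = c("beech", "beech", "fir", "fir"))
  rel <- toy_counts(c(0.25, 0.5, 0.2, 0.9), c(0.75, 0.5, 0.8, 0.1),
                    samples = ids, taxa = c("x1", "x2"))
  tax <- tibble::tibble(otu_id = c("x1", "x2"), species = NA,
                        genus = c("Ga", "Gb"),
                        identity_pct = 99, coverage_pct = 99,
                        kingdom_flag = "fungal")
  gm <- tibble::tibble(genus = "Ga", guild = "white_rot")
  prof <- guild_profile(rel, tax, gm, meta, grouping = "tree")
  shares <- tidyr::pivot_wider(prof, names_from = "guild",
                               values_from = "share")
  expect_equal(shares$white_rot[shares$tree == "beech"], 0.375)
  expect_equal(shares$unclassified[shares$tree == "fir"], 0.45)
  sums <- dplyr::summarise(dplyr::group_by(prof, tree),
                           s = sum(share))
  expect_equal(sums$s, c(1, 1))
})
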