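test_that("self-similarity is 100 and unrelated sequences score 0", {
  set.seed(101)
  g <- rand_dna(800)
  expect_equal(pairwise_intergenomic_similarity(g, g), 100)
  expect_error(pairwise_intergenomic_similarity("", g), "empty")
  # sequences sharing no fragment above the length floor
  h <- rand_dna(800)
  expect_lt(pairwise_intergenomic_similarity(g, h), 5)
  short_share <- paste0(rand_dna(100), substr(g, 1, 20), rand_dna(100))
  expect_equal(pairwise_intergenomic_similarity(substr(g, 1, 20), short_share), 0)
})

test_that("planted identical block matches the exact alignment oracles", {
  set.seed(202)
  a <- chars(rand_dna(1000))
  b <- chars(rand_dna(1000))
  b[251:750] <- a[251:750]
  # force mismatches flanking the block so its boundary is sharp
  bases <- c("A", "C", "G", "T")
  b[250] <- setdiff(bases, a[250])[1]
  b[751] <- setdiff(bases, a[751])[1]
  a <- paste(a, collapse = ""); b <- paste(b, collapse = "")

  oracle <- best_gapless_local(a, b)
  sim <- pairwise_intergenomic_similarity(a, b)
  matches_main <- sim * (1000 + 1000) / 200
  expect_equal(matches_main, oracle$matches)
  expect_gte(oracle$matches, 500)

  # small pair: seed-and-extend agrees with full Smith-Waterman
  set.seed(203)
  x <- chars(rand_dna(240)); y <- chars(rand_dna(240))
  y[61:180] <- x[61:180]
  y[60] <- setdiff(bases, x[60])[1]; y[181] <- setdiff(bases, x[181])[1]
  x <- paste(x, collapse = ""); y <- paste(y, collapse = "")
  sw <- sw_local_matches(x, y)
  main <- pairwise_intergenomic_similarity(x, y) * (240 + 240) / 200
  expect_equal(main, sw$matches)
})

test_that("similarity is symmetric, bounded and insensitive to N", {
  set.seed(303)
  for (i in 1:25) {
    n1 <- sample(200:400, 1); n2 <- sample(200:400, 1)
    a <- rand_dna(n1)
    b <- if (i %% 2 == 0) rand_dna(n2) else
      paste0(substr(a, 1, n1 %/% 2), rand_dna(n2 - n1 %/% 2))
    s1 <- pairwise_intergenomic_similarity(a, b)
    s2 <- pairwise_intergenomic_similarity(b, a)
    expect_equal(s1, s2)
    expect_gte(s1, 0); expect_lte(s1, 100)
  }
  # N never counts as identical
  a <- paste(rep("ACGT", 30), collapse = "")
  b <- a
  substr(b, 50, 54) <- "NNNNN"
  expect_lt(pairwise_intergenomic_similarity(a, b), 100)
})

test_that("similarity matrix holds its invariants on a simulated family", {
  fam <- simulate_phage_family(n_genera = 2, species_per_genus = 2,
                               genomes_per_species = 2,
                               genome_length = 3000, seed = 9)
  m <- similarity_matrix(fam$genomes)
  expect_true(isSymmetric(m))
  expect_true(all(diag(m) == 100))
  expect_true(all(m >= 0 & m <= 100))
  tr <- fam$truth
  for (i in 1:(nrow(tr) - 1)) {
    for (j in (i + 1):nrow(tr)) {
      s <- m[tr$genome_id[i], tr$genome_id[j]]
      if (tr$species[i] == tr$species[j]) expect_gt(s, 95)
      else if (tr$genus[i] == tr$genus[j]) { expect_gt(s, 70); expect_lt(s, 95) }
      else expect_lt(s, 70)
    }
  }
  expect_error(similarity_matrix(fam$genomes[1]), ">= 2 genomes")
})

test_that("complete-linkage genus/species cuts follow the thresholds", {
  # hand-computed complete linkage: AB 96, AC 60, BC 60
  m <- matrix(c(100, 96, 60, 96, 100, 60, 60, 60, 100), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tax <- cluster_taxa(m)
  expect_identical(tax$species_id[1], tax$species_id[2])
  expect_false(tax$species_id[1] == tax$species_id[3])
  expect_identical(tax$genus_id[1], tax$genus_id[2])
  expect_false(tax$genus_id[1] == tax$genus_id[3])
  expect_true(tax$species_singleton[tax$genome_id == "C"])

  # a pair at exactly 71: same genus (>= 70), different species (< 95)
  m2 <- matrix(c(100, 71, 71, 100), 2, 2,
               dimnames = list(c("A", "B"), c("A", "B")))
  tax2 <- cluster_taxa(m2)
  expect_identical(tax2$genus_id[1], tax2$genus_id[2])
  expect_false(tax2$species_id[1] == tax2$species_id[2])

  # all identical: one species, one genus, no singletons
  m3 <- matrix(100, 3, 3, dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  tax3 <- cluster_taxa(m3)
  expect_identical(length(unique(tax3$genus_id)), 1L)
  expect_identical(length(unique(tax3$species_id)), 1L)
  expect_false(any(tax3$species_singleton))
  expect_error(cluster_taxa(m3, genus_threshold = 96, species_threshold = 95),
               "validation error")
})

test_that("species partition always refines the genus partition", {
  set.seed(77)
  for (rep in 1:5) {
    n <- 8
    ids <- sprintf("g%02d", 1:n)
    v <- matrix(runif(n * n, 0, 100), n, n, dimnames = list(ids, ids))
    v <- (v + t(v)) / 2
    diag(v) <- 100
    tax <- cluster_taxa(v)
    # every species wholly inside one genus
    by_species <- split(tax$genus_id, tax$species_id)
    expect_true(all(vapply(by_species, function(x) length(unique(x)) == 1, TRUE)))
  }
})

test_that("SNP distance counts unambiguous differing positions only", {
  expect_identical(snp_distance("ACGTACGT", "ACGTACGT"), 0L)
  expect_identical(snp_distance("ACGTACGT", "ACGAACGA"), 2L)
  expect_identical(snp_distance("AC-TANGT", "ACGAANGT"), 1L)
  # differences only inside gapped/ambiguous columns count zero
  expect_identical(snp_distance("A-N", "AGC"), 0L)
  expect_error(snp_distance("ACG", "AC"), "equal length")
})
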