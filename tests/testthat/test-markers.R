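make_allele_fixture <- function() {
  # 5 target (T) + 5 non-target (N) strains, 3 positions
  alleles <- rbind(
    matrix(rep(c("T", "T", "G"), each = 5), 5, 3),
    matrix(rep(c("A", "A", "G"), each = 5), 5, 3)
  )
  alleles[6, 2] <- "T"     # one non-target carries the alt at position 2
  alleles[5, 3] <- "C"     # position 3: only 1 of 5 targets alt
  rownames(alleles) <- c(paste0("t", 1:5), paste0("n", 1:5))
  list(alleles = alleles, positions = c(10L, 50L, 90L),
       ref = c("A", "A", "G"),
       labels = setNames(rep(c("V1", "V2"), each = 5), rownames(alleles)))
}

test_that("sensitivity and specificity follow their defining ratios", {
  fx <- make_allele_fixture()
  sc <- score_clade_snps(fx$alleles, fx$positions, fx$ref, fx$labels, "V1")
  expect_equal(sc$sensitivity[1], 1.0)
  expect_equal(sc$specificity[1], 1.0)
  expect_equal(sc$sensitivity[2], 1.0)
  expect_equal(sc$specificity[2], 0.8)   # 4 of 5 non-targets lack alt
  expect_equal(sc$sensitivity[3], 0.2)   # 1 of 5 targets carries alt C
  # missing calls drop out of numerator and denominator
  a2 <- fx$alleles; a2[1, 1] <- NA
  sc2 <- score_clade_snps(a2, fx$positions, fx$ref, fx$labels, "V1")
  expect_equal(sc2$sensitivity[1], 1.0)
  expect_identical(sc2$n_target[1], 4L)
  expect_error(score_clade_snps(fx$alleles, fx$positions, fx$ref, fx$labels,
                                "V9"), "absent")
})

test_that("optimal-SNP filtering requires core genes and perfect stats", {
  fx <- make_allele_fixture()
  sc <- score_clade_snps(fx$alleles, fx$positions, fx$ref, fx$labels, "V1")
  kept <- filter_optimal_snps(sc)
  expect_identical(kept$position, 10L)
  # sensitivity 1.0 but specificity 0.99 is removed under the strict default
  sc$specificity[1] <- 0.99
  expect_identical(nrow(filter_optimal_snps(sc)), 0L)
  sc$specificity[1] <- 1
  sc$is_core[1] <- FALSE
  expect_identical(nrow(filter_optimal_snps(sc)), 0L)
  expect_identical(nrow(filter_optimal_snps(sc[0, ])), 0L)
  # relaxation flags
  sc2 <- score_clade_snps(fx$alleles, fx$positions, fx$ref, fx$labels, "V1")
  expect_identical(nrow(filter_optimal_snps(sc2, min_specificity = 0.8)), 2L)
})

test_that("SNP graph edges respect the proximity horizon", {
  sites <- data.frame(position = c(100L, 150L, 450L), replicon = "chr1",
                      stringsAsFactors = FALSE)
  g <- build_snp_graph(sites, horizon = 300)
  expect_identical(nrow(g$edges), 2L)       # 100-150 (50) and 150-450 (300)
  expect_true(all(g$edges$weight <= 300))
  expect_identical(g$edges$weight[1], 50L)
  # boundary: exactly 301 apart with horizon 300 -> no edge
  s2 <- data.frame(position = c(0L, 301L), replicon = "chr1")
  expect_identical(nrow(build_snp_graph(s2, horizon = 300)$edges), 0L)
  s3 <- data.frame(position = c(0L, 300L), replicon = "chr1")
  expect_identical(nrow(build_snp_graph(s3, horizon = 300)$edges), 1L)
  # 6 SNPs within 240 bp form a 15-edge clique
  s4 <- data.frame(position = seq(0L, 240L, by = 48L), replicon = "chr1")
  expect_identical(nrow(build_snp_graph(s4, horizon = 300)$edges), 15L)
  # edges never cross replicons
  s5 <- data.frame(position = c(10L, 20L), replicon = c("chr1", "chr2"))
  expect_identical(nrow(build_snp_graph(s5, horizon = 300)$edges), 0L)
})

test_that("primer design matches brute-force enumeration and validates", {
  set.seed(55)
  ref <- rand_dna(700)
  pos <- c(200L, 210L, 225L, 320L, 430L, 445L, 460L)
  sites <- data.frame(position = pos, replicon = "chr1")
  g <- build_snp_graph(sites)
  out <- design_primers(g, ref)
  expect_gt(nrow(out), 0)
  for (i in seq_len(nrow(out))) {
    expect_true(check_primer_row(out[i, ], pos))
  }
  oracle <- primer_oracle_best(pos, 700L)
  expect_identical(out$fwd_start[1], unname(as.integer(oracle["fs"])))
  expect_identical(out$rev_start[1], unname(as.integer(oracle["rs"])))
  expect_identical(out$fwd_specific[1] + out$rev_specific[1],
                   unname(as.integer(oracle["total"])))
  expect_identical(out$amplicon_length[1], unname(as.integer(oracle["amp"])))

  # invariant to input ordering
  g_shuf <- build_snp_graph(sites[sample(nrow(sites)), , drop = FALSE])
  expect_identical(design_primers(g_shuf, ref), out)

  # single isolated SNP cannot satisfy two specific positions per primer
  g1 <- build_snp_graph(data.frame(position = 300L, replicon = "chr1"))
  expect_identical(nrow(design_primers(g1, ref)), 0L)

  # two dense windows 500 bp apart exceed the 300 bp amplicon cap
  far <- data.frame(position = c(50L, 60L, 70L, 550L, 560L, 570L),
                    replicon = "chr1")
  expect_identical(nrow(design_primers(build_snp_graph(far), rand_dna(800))), 0L)
})

test_that("primer and probe intervals never overlap within a candidate", {
  set.seed(56)
  ref <- rand_dna(600)
  pos <- c(100L, 112L, 124L, 220L, 330L, 342L, 354L)
  out <- design_primers(build_snp_graph(data.frame(position = pos,
                                                   replicon = "chr1")), ref)
  expect_gt(nrow(out), 0)
  for (i in seq_len(nrow(out))) {
    r <- out[i, ]
    expect_lte(r$fwd_end, r$probe_start)
    expect_lte(r$probe_end, r$rev_start)
  }
})

test_that("phage marker families are exactly the private universal ones", {
  m <- matrix(0L, 5, 4, dimnames = list(paste0("p", 1:5), paste0("f", 1:4)))
  m[1:2, 1] <- 1L            # f1: all targets, no others
  m[1:3, 2] <- 1L            # f2: all targets plus one non-target
  m[1, 3] <- 1L              # f3: only some targets
  m[4:5, 4] <- 1L            # f4: non-targets only
  expect_identical(select_phage_marker_genes(m, c("p1", "p2")), "f1")
  expect_error(select_phage_marker_genes(m, character(0)), "empty")
  expect_error(select_phage_marker_genes(m, rownames(m)), "strict subset")
})

test_that("planted diagnostic SNPs are recovered end to end", {
  pop <- simulate_bacterial_population(n_clades = 3, strains_per_clade = 8,
                                       core_genes = 12, seed = 21)
  snps <- call_snps(pop$genomes, pop$reference)
  labels <- setNames(pop$strains$clade, pop$strains$strain)
  for (clade in c("V1", "V2")) {
    sc <- score_clade_snps(snps$alleles, snps$positions, snps$ref, labels,
                           clade, gene_table = pop$genes)
    kept <- filter_optimal_snps(sc)
    planted <- sort(pop$snps$position[pop$snps$clade == clade])
    expect_identical(sort(kept$position), planted)
    expect_true(all(kept$sensitivity == 1))
    expect_true(all(kept$specificity == 1))
    cand <- design_primers(build_snp_graph(kept), pop$reference)
    expect_gt(nrow(cand), 0)
    for (i in seq_len(nrow(cand))) {
      expect_true(check_primer_row(cand[i, ], kept$position))
    }
  }
})
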