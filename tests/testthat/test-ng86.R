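test_that("identical sequences give zero distances", {
  res <- ng86_counting("ATGAAA", "ATGAAA")
  expect_equal(res$dN, 0)
  expect_equal(res$dS, 0)
  expect_true(res$estimable)
})

test_that("a single synonymous difference gives dS > 0, dN = 0, omega 0", {
  # 100 codons, one third-position synonymous change (GGA -> GGG)
  s1 <- paste0(rep("GGA", 100), collapse = "")
  s2 <- paste0(c(rep("GGA", 99), "GGG"), collapse = "")
  res <- ng86_counting(s1, s2)
  expect_equal(res$Nd, 0)
  expect_equal(res$Sd, 1)
  expect_gt(res$dS, 0)
  expect_equal(res$dN, 0)
  expect_equal(res$dn_ds, 0)
})

test_that("pathway averaging matches exhaustive enumeration", {
  # codon pairs with 2 and 3 differences, checked against the brute-force
  # ordering oracle
  pairs <- list(c("TTT", "GTA"), c("ATG", "TGC"), c("AAA", "CCC"),
                c("TTA", "CTC"), c("AGG", "TCT"))
  for (p in pairs) {
    expected <- oracle_pathway_counts(p[1], p[2])
    got <- repevol:::ng86_pathway_diffs(p[1], p[2])
    expect_equal(unname(got), unname(expected), tolerance = 1e-12,
                 label = paste(p, collapse = "-"))
  }

  # 3-codon worked example: accumulate sites and differences by hand
  s1 <- "TTTATGAAA"; s2 <- "GTAATGAAG"
  res <- ng86_counting(s1, s2)
  d1 <- oracle_pathway_counts("TTT", "GTA")
  d3 <- oracle_pathway_counts("AAA", "AAG")
  expect_equal(res$Sd, unname(d1["sd"] + d3["sd"]))
  expect_equal(res$Nd, unname(d1["nd"] + d3["nd"]))
  # site counts averaged over the two sequences
  sites <- function(s) sum(vapply(repevol:::split_codons(s),
                                  repevol:::ng86_syn_sites, numeric(1)))
  expect_equal(res$S, (sites(s1) + sites(s2)) / 2)
  expect_equal(res$N, 9 - res$S)
})

test_that("saturated divergence is flagged not estimable", {
  # maximally different codons at every site push pN beyond the JC domain
  s1 <- paste0(rep("AAA", 5), collapse = "")
  s2 <- paste0(rep("CCC", 5), collapse = "")
  res <- ng86_counting(s1, s2)
  expect_false(res$estimable)
  expect_true(is.na(res$dN))
})

test_that("counting and ML estimates agree in rank order across loci", {
  set.seed(10)
  tr <- signal_tree()
  omegas <- rep(c(0.1, 0.5, 1.5), length.out = 15)
  ml <- ng <- numeric(length(omegas))
  for (i in seq_along(omegas)) {
    aln <- simulate_alignment(300, tr, 2,
                              c(SC = omegas[i], SI = omegas[i], INTERNAL = omegas[i]))
    ml[i] <- fit_m0(aln, tr)$omega[[1]]
    # counting estimate on the most divergent pair (the two SI taxa)
    ng[i] <- ng86_counting(aln$idx["pennellii", ], aln$idx["habrochaites", ])$dn_ds
  }
  ok <- !is.na(ng)
  expect_gt(sum(ok), 10)
  expect_gt(cor(ml[ok], ng[ok], method = "spearman"), 0.8)
})
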