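test_that("TPM normalization follows the length-corrected formula", {
  counts <- tibble::tibble(gene_id = "g1", length = 500, libA = 7)
  expect_equal(tpm_normalize(counts)$libA, 1e6)

  two <- tibble::tibble(gene_id = c("g1", "g2"), length = c(1000, 2000),
                        libA = c(10, 10))
  tpm <- tpm_normalize(two)
  expect_equal(tpm$libA, c(2e6 / 3, 1e6 / 3), tolerance = 1e-9)

  # doubling counts changes nothing; columns sum to one million
  doubled <- two; doubled$libA <- doubled$libA * 2
  expect_equal(tpm_normalize(doubled)$libA, tpm$libA)
  expect_equal(sum(tpm$libA), 1e6, tolerance = 1e-6)

  zero <- two; zero$libA <- 0
  expect_error(tpm_normalize(zero), "libA")
  neg <- two; neg$length[1] <- 0
  expect_error(tpm_normalize(neg), "positive")
})

test_that("tissue means average replicates and respect the availability mask", {
  counts <- tibble::tibble(
    gene_id = c("g1", "g2"), length = c(1000, 1000),
    l1 = c(40, 60), l2 = c(60, 40), l3 = c(10, 90))
  meta <- tibble::tibble(
    library_id = c("l1", "l2", "l3"),
    species = c("lycopersicum", "lycopersicum", "pennellii"),
    tissue = c("leaf", "leaf", "leaf"), replicate = c(1, 2, 1))
  prof <- tissue_means(tpm_normalize(counts), meta)
  lyc <- dplyr::filter(prof, species == "lycopersicum", gene_id == "g1")
  expect_equal(lyc$mean_tpm, mean(c(4e5, 6e5)))
  expect_equal(lyc$n_reps, 2L)
  # no pennellii style rows exist: missing combinations are absent, not 0
  expect_equal(nrow(dplyr::filter(prof, species == "pennellii")), 2L)
  expect_error(tissue_means(tpm_normalize(counts),
                            dplyr::mutate(meta, library_id = c("l1", "l2", "lX"))),
               "lX")
})

test_that("broad classification implements the threshold-and-vote rules", {
  # ovule high, all vegetative silent, in all 3 species -> RP
  expect_equal(classify_broad(full_profile("g", ovule = 10))$broad, "RP")
  # leaf high only -> VG
  expect_equal(classify_broad(full_profile("g", leaf = 10))$broad, "VG")
  # leaf and ovule high in 2 species -> GR
  p <- dplyr::bind_rows(
    make_profile("g", lycopersicum = tpm_vec(leaf = 50, ovule = 50),
                 pennellii = tpm_vec(leaf = 50, ovule = 50),
                 habrochaites = tpm_vec()))
  expect_equal(classify_broad(p)$broad, "GR")
  # gray zone: ovule 10 but leaf at 1.0 fails both the trace rule (RP) and
  # the expression rule (GR)
  expect_equal(classify_broad(full_profile("g", ovule = 10, leaf = 1))$broad,
               "UNCLASSIFIED")
  # boundary values: 2 is not > 2, 0.5 is not < 0.5
  expect_equal(classify_broad(full_profile("g", ovule = 2))$broad, "UNCLASSIFIED")
  expect_equal(classify_broad(full_profile("g", ovule = 10, leaf = 0.5))$broad,
               "UNCLASSIFIED")
  # a single species voting RP is not enough
  one <- make_profile("g", lycopersicum = tpm_vec(ovule = 10),
                      pennellii = tpm_vec(), habrochaites = tpm_vec())
  expect_equal(classify_broad(one)$broad, "UNCLASSIFIED")
})

test_that("masked tissues never vote", {
  # leaf data absent for two species; their RP votes depend on the absent
  # tissue being excluded rather than imputed. The species with leaf data
  # sits in the gray zone and cannot vote, so the label hinges on the mask.
  drop_leaf <- function(df) dplyr::filter(df, tissue != "leaf")
  p <- dplyr::bind_rows(
    make_profile("g", lycopersicum = tpm_vec(ovule = 10, leaf = 1)),
    drop_leaf(make_profile("g", pennellii = tpm_vec(ovule = 10, leaf = 1))),
    drop_leaf(make_profile("g", habrochaites = tpm_vec(ovule = 10, leaf = 1))))
  expect_equal(classify_broad(p)$broad, "RP")
  # with leaf present everywhere the same gene is unclassifiable
  expect_equal(classify_broad(full_profile("g", ovule = 10, leaf = 1))$broad,
               "UNCLASSIFIED")
})

test_that("tissue-specific labels require one expressed tissue and 2 votes", {
  expect_equal(classify_tissue_specific(full_profile("g", style = 30))$tissue_specific,
               "style")
  # two expressed tissues -> none
  expect_true(is.na(classify_tissue_specific(
    full_profile("g", style = 30, ovule = 30))$tissue_specific))
  # expressed in one species only -> insufficient votes
  one <- make_profile("g", lycopersicum = tpm_vec(style = 30),
                      pennellii = tpm_vec(), habrochaites = tpm_vec())
  expect_true(is.na(classify_tissue_specific(one)$tissue_specific))
  # an intermediate (gray-zone) second tissue blocks the vote
  expect_true(is.na(classify_tissue_specific(
    full_profile("g", style = 30, leaf = 1))$tissue_specific))
})

test_that("ploidy classification partitions tissues by generation", {
  expect_equal(classify_ploidy(full_profile("g", pollen = 20, ovule = 5))$ploidy,
               "GAMETOPHYTIC_ONLY")
  r <- classify_ploidy(full_profile("g", ovule = 20, leaf = 20))
  expect_equal(r$ploidy, "GAM_PLUS_SPORO")
  expect_equal(r$ovule_class, "TISSUE_PLUS_SPORO")
  # style is diploid: style-only expression is sporophytic-exclusive
  expect_equal(classify_ploidy(full_profile("g", style = 20))$ploidy,
               "SPOROPHYTIC_ONLY")
  # ovule-only expression is both gametophytic-exclusive and ovule-specific
  r2 <- classify_ploidy(full_profile("g", ovule = 20))
  expect_equal(r2$ploidy, "GAMETOPHYTIC_ONLY")
  expect_equal(r2$ovule_class, "TISSUE_ONLY")
  expect_true(is.na(r2$pollen_class))
})

test_that("expression breadth counts tissues expressed in all species with data", {
  expect_equal(expression_breadth(full_profile("g", base = 10))$breadth, 8L)
  # leaf high in only 2 of 3 species with leaf data: not counted
  p <- make_profile("g", lycopersicum = tpm_vec(leaf = 10, ovule = 10),
                    pennellii = tpm_vec(leaf = 10, ovule = 10),
                    habrochaites = tpm_vec(ovule = 10))
  expect_equal(expression_breadth(p)$breadth, 1L)
  # style counted from the species that have style data
  masked <- dplyr::bind_rows(
    make_profile("g", lycopersicum = tpm_vec(style = 10),
                 pennellii = tpm_vec(style = 10),
                 habrochaites = tpm_vec(style = 10)),
    tibble::tibble(gene_id = "g", species = "pimpinellifolium",
                   tissue = "leaf", mean_tpm = 0, n_reps = 1L))
  expect_equal(expression_breadth(masked)$breadth, 1L)
})

test_that("mean expression averages only the expressed domain", {
  p1 <- make_profile("g", lycopersicum = c(ovule = 7))
  expect_equal(mean_expression(p1)$mean_expr, 7)
  p2 <- make_profile("g", lycopersicum = c(ovule = 10, leaf = 30))
  expect_equal(mean_expression(p2)$mean_expr, 20)
  p3 <- make_profile("g", lycopersicum = c(ovule = 10, leaf = 1))
  expect_equal(mean_expression(p3)$mean_expr, 10)
  p4 <- make_profile("g", lycopersicum = c(ovule = 1))
  expect_equal(mean_expression(p4)$mean_expr, 0)
})

test_that("classification is deterministic and labels are mutually consistent", {
  cfg <- sim_config(seed = 21, n_loci = c(RP = 40, VG = 40, GR = 60))
  sim <- simulate_counts(cfg)
  prof <- tissue_means(tpm_normalize(sim$counts), sim$metadata)
  cls1 <- classify_genes(prof)
  # permuting row order of the profile changes nothing
  set.seed(99)
  cls2 <- classify_genes(prof[sample.int(nrow(prof)), ]) |>
    dplyr::arrange(match(gene_id, cls1$gene_id))
  expect_equal(cls1, cls2)
  # every tissue-specific gene carries an RP or VG broad label
  ts <- dplyr::filter(cls1, !is.na(tissue_specific))
  expect_true(all(ts$broad %in% c("RP", "VG")))
  # generation-exclusive labels are exclusive
  expect_false(any(cls1$ploidy == "GAMETOPHYTIC_ONLY" &
                     cls1$ploidy == "SPOROPHYTIC_ONLY"))
  # planted labels are recovered when thresholds hold with margin
  j <- dplyr::left_join(cls1, sim$truth, by = "gene_id")
  focal <- dplyr::filter(j, !grepl("^bg", gene_id))
  expect_gt(mean(focal$broad == focal$true_class), 0.95)
})
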