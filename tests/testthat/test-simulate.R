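test_that("degenerate simulation limits hold", {
  tr0 <- solanum_tree(rep(0, 5))
  set.seed(40)
  aln <- simulate_alignment(50, tr0)
  expect_true(all(aln$idx == rep(aln$idx[1, ], each = 4)))

  # omega = 0 forbids amino-acid differences among taxa
  set.seed(41)
  tr <- solanum_tree(c(0.2, 0.2, 0.4, 0.4, 0.3))
  aln0 <- simulate_alignment(300, tr, 2, c(SC = 0, SI = 0, INTERNAL = 0))
  aa <- apply(aln0$idx, 1, function(i) paste0(codon_amino_acids()[i], collapse = ""))
  expect_equal(length(unique(aa)), 1L)
  # but synonymous changes do occur at these branch lengths
  expect_gt(sum(aln0$idx[1, ] != aln0$idx[3, ]), 0)
})

test_that("synonymous divergence between SI taxa grows with SI branch length", {
  set.seed(42)
  settings <- c(0.05, 0.15, 0.3)
  med_ds <- vapply(settings, function(len) {
    ds <- replicate(8, {
      tr <- solanum_tree(c(0.002, 0.002, len, len, 0.01))
      aln <- simulate_alignment(800, tr)
      ng86_counting(aln$idx["pennellii", ], aln$idx["habrochaites", ])$dS
    })
    stats::median(ds)
  }, numeric(1))
  expect_true(all(diff(med_ds) > 0))
})

test_that("simulated codon composition matches the stationary distribution", {
  set.seed(43)
  freqs <- rep(1 / 61, 61)
  pvals <- replicate(6, {
    aln <- simulate_alignment(5000, solanum_tree(), codon_freqs = freqs)
    obs <- tabulate(aln$idx[1, ], nbins = 61)
    suppressWarnings(stats::chisq.test(obs, p = freqs)$p.value)
  })
  expect_gte(sum(pvals > 0.01), 5)
})

test_that("planted count tables respect thresholds and are recoverable", {
  # near-noiseless limit: every planted label is recovered
  cfg <- sim_config(seed = 44, n_loci = c(RP = 20, VG = 20, GR = 20),
                    dispersion = 1e4, lib_size = 1e7)
  sim <- simulate_counts(cfg)
  prof <- tissue_means(tpm_normalize(sim$counts), sim$metadata)
  cls <- classify_genes(prof)
  j <- dplyr::inner_join(cls, sim$truth, by = "gene_id") |>
    dplyr::filter(!grepl("^bg", gene_id))
  expect_equal(mean(j$broad == j$true_class), 1)
  # planted GR genes are never called RP or VG
  gr <- dplyr::filter(j, true_class == "GR")
  expect_false(any(gr$broad %in% c("RP", "VG")))
  # missing tissues for pimpinellifolium are really absent
  expect_equal(nrow(dplyr::filter(sim$metadata,
                                  species == "pimpinellifolium",
                                  tissue %in% c("style", "pollen"))), 0L)
})

test_that("study bundles are byte-identical under the same seed", {
  cfg <- sim_config(seed = 45, n_loci = c(RP = 3, VG = 3, GR = 4), n_codons = 80)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_study(cfg, d1)
  simulate_study(cfg, d2)
  files <- list.files(d1, recursive = TRUE)
  expect_true(length(files) > 10)
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  # the bundle loads cleanly end to end
  alns <- read_alignment_batch(file.path(d1, "manifest.tsv"),
                               check_length = FALSE)
  expect_length(alns, 10)
  truth <- utils::read.delim(file.path(d1, "truth.tsv"))
  expect_setequal(truth$gene_id, names(alns))
})
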