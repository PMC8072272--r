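test_that("alignment construction validates taxon count, length and codons", {
  seqs <- c(a = "ATGATG", b = "ATGATG", c = "ATGATG", d = "ATGATG")
  aln <- codon_alignment(seqs)
  expect_s3_class(aln, "codon_alignment")
  expect_equal(aln$n_codons, 2L)

  expect_error(codon_alignment(seqs[1:3]), "exactly 4")
  bad <- seqs; bad[1] <- "ATGATGATG"
  expect_error(codon_alignment(bad), "unequal lengths")
  stopd <- seqs; stopd[2] <- "ATGTAA"
  expect_error(codon_alignment(stopd), "unrecognized codon")
  gapped <- seqs; gapped[3] <- "ATG--G"
  expect_error(codon_alignment(gapped), "unrecognized codon")
})

test_that("FASTA reading cleans columns and enforces the length filter", {
  codons <- sense_codons()
  write_locus <- function(seqs, path) {
    writeLines(unlist(lapply(names(seqs), function(n) c(paste0(">", n), seqs[[n]]))),
               path)
  }
  taxa <- c("lycopersicum", "pimpinellifolium", "pennellii", "habrochaites")

  # 4 x 300 bp clean file -> 100 codons
  set.seed(1)
  base <- paste0(sample(codons, 100, replace = TRUE), collapse = "")
  f1 <- withr::local_tempfile(fileext = ".fasta")
  write_locus(stats::setNames(rep(list(base), 4), taxa), f1)
  aln <- read_alignment_fasta(f1)
  expect_equal(aln$n_codons, 100L)
  expect_equal(attr(aln, "n_dropped"), 0L)

  # one all-gap codon column is dropped -> 99 codons
  gapped <- paste0("---", substr(base, 4, 300))
  f2 <- withr::local_tempfile(fileext = ".fasta")
  write_locus(stats::setNames(rep(list(gapped), 4), taxa), f2)
  aln2 <- read_alignment_fasta(f2)
  expect_equal(aln2$n_codons, 99L)
  expect_equal(attr(aln2, "n_dropped"), 1L)

  # a stop codon or ambiguity code in one taxon also drops the column
  stopseq <- paste0("TAA", substr(base, 4, 300))
  f3 <- withr::local_tempfile(fileext = ".fasta")
  write_locus(stats::setNames(list(stopseq, base, base, base), taxa), f3)
  expect_equal(read_alignment_fasta(f3)$n_codons, 99L)

  # 198 bp does not pass "longer than 200 bp"
  short <- substr(base, 1, 198)
  f4 <- withr::local_tempfile(fileext = ".fasta")
  write_locus(stats::setNames(rep(list(short), 4), taxa), f4)
  expect_error(read_alignment_fasta(f4), "longer than 200")
  # 201 bp passes
  ok201 <- substr(base, 1, 201)
  f5 <- withr::local_tempfile(fileext = ".fasta")
  write_locus(stats::setNames(rep(list(ok201), 4), taxa), f5)
  expect_equal(read_alignment_fasta(f5)$n_codons, 67L)

  # wrong record count
  f6 <- withr::local_tempfile(fileext = ".fasta")
  write_locus(stats::setNames(rep(list(base), 3), taxa[1:3]), f6)
  expect_error(read_alignment_fasta(f6), "expected 4")
})

test_that("concatenation joins columns, keeps order, and records boundaries", {
  set.seed(2)
  tr <- signal_tree()
  a1 <- simulate_alignment(100, tr, locus_id = "l1")
  a2 <- simulate_alignment(100, tr, locus_id = "l2")
  cc <- concatenate_class(list(a1, a2))
  expect_equal(cc$n_codons, 200L)
  expect_identical(cc$idx[, 1:100], a1$idx[cc$taxa, ])
  bounds <- attr(cc, "boundaries")
  expect_equal(bounds$end, c(100L, 200L))

  # concatenating a single locus reproduces it
  one <- concatenate_class(list(a1))
  expect_identical(one$idx, a1$idx)

  # subsetting and ordering by gene id
  cc2 <- concatenate_class(list(a1, a2), gene_ids = c("l2", "l1"))
  expect_identical(cc2$idx[, 1:100], a2$idx[cc2$taxa, ])

  bad <- a2; bad$taxa[1] <- "other"; rownames(bad$idx)[1] <- "other"
  expect_error(concatenate_class(list(a1, bad)), "mismatch")
})

test_that("per-locus lnL adds over a concatenation under shared parameters", {
  set.seed(3)
  tr <- signal_tree()
  alns <- lapply(1:3, function(i) simulate_alignment(50, tr, locus_id = paste0("l", i)))
  params <- codon_model_params(2, c(SC = 0.3, SI = 0.3, INTERNAL = 0.3))
  cc <- concatenate_class(alns)
  expect_equal(log_likelihood(cc, tr, params),
               sum(vapply(alns, log_likelihood, numeric(1), tree = tr,
                          params = params)),
               tolerance = 1e-10)
})
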