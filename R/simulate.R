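# Ground-truthed simulation of the study's two input layers: codon
# alignments evolved on the labeled 4-taxon tree with branch-class-specific
# dN/dS, and replicate-level RNA-seq count tables whose TPM structure plants
# known gene classes.

#' Simulation configuration
#'
#' Bundles every knob of the synthetic study. Defaults describe a small but
#' realistic study: lognormal per-locus dN/dS centered per gene class (so a
#' minority of reproductive loci genuinely exceed 1), branch lengths echoing
#' the strong SC/SI asymmetry of the system (short self-compatible tips),
#' and negative-binomial read counts with planted tissue-expression classes
#' that respect the 2 / 0.5 TPM thresholds with margin.
#'
#' @param seed Integer seed; fully determines all outputs.
#' @param n_loci Named counts of loci per gene class.
#' @param n_codons Codons per locus.
#' @param tree [labeled_tree()] carrying the true branch lengths.
#' @param kappa Transition/transversion ratio.
#' @param omega_class_mean Median of the per-locus lognormal true omega, per
#'   gene class.
#' @param omega_sdlog Lognormal sd of per-locus omega on the log scale
#'   (0 = every locus at its class median).
#' @param sc_shift Additive shift applied to omega on SC branches, per gene
#'   class (models lineage-specific rate differences; default none).
#' @param codon_freqs Stationary codon frequencies (default uniform).
#' @param n_genes Genes in the expression layer per class (defaults to
#'   `n_loci` so both layers describe the same genes).
#' @param tpm_on,tpm_off Planted TPM for expressed / silent tissues; defaults
#'   (30, 0.05) leave wide margins around the 2 and 0.5 thresholds.
#' @param n_replicates RNA-seq replicates per species x tissue.
#' @param dispersion Negative-binomial size parameter (smaller = noisier).
#' @param lib_size Reads per library.
#' @param missing_tissues Named list: species -> tissues with no data
#'   (default style and pollen missing for pimpinellifolium).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_loci = c(RP = 25, VG = 25, GR = 50),
                       n_codons = 200,
                       tree = solanum_tree(),
                       kappa = 2,
                       omega_class_mean = c(RP = 0.3, VG = 0.2, GR = 0.2),
                       omega_sdlog = 0.5,
                       sc_shift = c(RP = 0, VG = 0, GR = 0),
                       codon_freqs = NULL,
                       n_genes = NULL,
                       tpm_on = 30,
                       tpm_off = 0.05,
                       n_replicates = 3,
                       dispersion = 10,
                       lib_size = 2e6,
                       missing_tissues = list(pimpinellifolium = c("style", "pollen"))) {
  if (is.null(codon_freqs)) codon_freqs <- rep(1 / 61, 61)
  if (is.null(n_genes)) n_genes <- n_loci
  stopifnot(all(names(n_loci) %in% names(omega_class_mean)))
  structure(
    list(seed = seed, n_loci = n_loci, n_codons = n_codons, tree = tree,
         kappa = kappa, omega_class_mean = omega_class_mean,
         omega_sdlog = omega_sdlog, sc_shift = sc_shift,
         codon_freqs = codon_freqs, n_genes = n_genes, tpm_on = tpm_on,
         tpm_off = tpm_off, n_replicates = n_replicates,
         dispersion = dispersion, lib_size = lib_size,
         missing_tissues = missing_tissues),
    class = "sim_config"
  )
}

# draw child states given parent states and a transition matrix
sample_children <- function(parents, P) {
  out <- integer(length(parents))
  for (s in unique(parents)) {
    pick <- parents == s
    out[pick] <- sample.int(61, sum(pick), replace = TRUE, prob = P[s, ])
  }
  out
}

#' Simulate one codon alignment on the labeled tree
#'
#' Root codons are drawn from the stationary frequencies at one internal
#' node; each branch then evolves by sampling from its transition matrix
#' (matrix exponential of the branch-class GY94 generator at the branch
#' length). Uses the current RNG state; seed via `set.seed()` or
#' [simulate_study()].
#'
#' @param n_codons Number of codon columns.
#' @param tree [labeled_tree()] with the true branch lengths.
#' @param kappa Transition/transversion ratio.
#' @param omega_by_class Named omega per branch class, e.g.
#'   `c(SC = 0.3, SI = 0.2, INTERNAL = 0.2)`, or a single shared value.
#' @param codon_freqs Stationary frequencies (default uniform).
#' @param locus_id Identifier for the returned alignment.
#' @return A [codon_alignment()]; the true parameters are attached as
#'   attribute `"truth"`.
#' @export
simulate_alignment <- function(n_codons, tree, kappa = 2,
                               omega_by_class = c(SC = 0.2, SI = 0.2, INTERNAL = 0.2),
                               codon_freqs = NULL, locus_id = "sim_locus") {
  if (length(omega_by_class) == 1L && is.null(names(omega_by_class))) {
    omega_by_class <- c(SC = omega_by_class, SI = omega_by_class,
                        INTERNAL = omega_by_class)
  }
  if (is.null(codon_freqs)) codon_freqs <- rep(1 / 61, 61)
  params <- codon_model_params(kappa, omega_by_class, codon_freqs)
  lens <- tree$branches$length
  cls <- tree$branches$class
  Qs <- lapply(stats::setNames(unique(cls), unique(cls)),
               function(cl) build_rate_matrix(params, cl))
  P <- lapply(seq_len(5), function(b) transition_probs(Qs[[cls[b]]], lens[b],
                                                       codon_freqs))
  u <- sample.int(61, n_codons, replace = TRUE, prob = codon_freqs)
  a <- sample_children(u, P[[1]])
  b <- sample_children(u, P[[2]])
  v <- sample_children(u, P[[5]])
  cc <- sample_children(v, P[[3]])
  d <- sample_children(v, P[[4]])
  codons <- sense_codons()
  seqs <- vapply(list(a, b, cc, d), function(s) paste0(codons[s], collapse = ""),
                 character(1))
  names(seqs) <- tree$taxa
  aln <- codon_alignment(seqs, locus_id = locus_id)
  attr(aln, "truth") <- list(kappa = kappa, omega_by_class = omega_by_class,
                             lengths = lens)
  aln
}

#' Simulate a set of loci sharing one parameter setting
#'
#' Equivalent to repeated [simulate_alignment()] calls at identical
#' parameters, but computes the five transition matrices once, so large
#' validation pools are cheap.
#'
#' @inheritParams simulate_alignment
#' @param n_loci Number of loci.
#' @param prefix Locus id prefix (ids are `prefix_1 ... prefix_n`).
#' @return List of [codon_alignment()] objects.
#' @export
simulate_locus_set <- function(n_loci, n_codons, tree, kappa = 2,
                               omega_by_class = c(SC = 0.2, SI = 0.2, INTERNAL = 0.2),
                               codon_freqs = NULL, prefix = "locus") {
  if (is.null(codon_freqs)) codon_freqs <- rep(1 / 61, 61)
  big <- simulate_alignment(n_loci * n_codons, tree, kappa, omega_by_class,
                            codon_freqs, locus_id = prefix)
  lapply(seq_len(n_loci), function(i) {
    cols <- ((i - 1) * n_codons + 1):(i * n_codons)
    structure(
      list(locus_id = paste0(prefix, "_", i), taxa = big$taxa,
           idx = big$idx[, cols, drop = FALSE], n_codons = as.integer(n_codons)),
      class = "codon_alignment"
    )
  })
}

# expressed-tissue sets per planted class; single-tissue draws create the
# tissue-specific subsets naturally
plant_tissue_set <- function(class) {
  switch(class,
    RP = sample(REPRODUCTIVE_TISSUES, sample.int(3, 1)),
    VG = sample(VEGETATIVE_TISSUES, sample.int(2, 1)),
    GR = c(sample(REPRODUCTIVE_TISSUES, 1), sample(VEGETATIVE_TISSUES, 1)),
    stop("unknown planted class: ", class, call. = FALSE)
  )
}

#' Simulate an RNA-seq count table with planted gene classes
#'
#' Per gene x library, counts are negative binomial with mean proportional
#' to planted TPM x gene length x library size; expressed tissues sit at
#' `tpm_on`, silent tissues at `tpm_off`, well clear of the 2 / 0.5
#' classification thresholds. Tissues listed in `missing_tissues` get no
#' libraries for that species, mirroring the incomplete atlas.
#'
#' @param config A [sim_config()].
#' @return List: `counts` (gene_id, length, one column per library),
#'   `metadata` (library_id, species, tissue, replicate) and `truth`
#'   (gene_id, true_class, expressed tissue set as comma-joined string).
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  classes <- rep(names(config$n_genes), config$n_genes)
  n <- length(classes)
  gene_ids <- sprintf("gene_%04d", seq_len(n))
  tissue_sets <- lapply(classes, plant_tissue_set)

  # planted TPM matrix for the focal genes, plus broadly expressed
  # background genes absorbing the rest of each library's one-million TPM
  # budget, so planted values survive within-library normalization
  tpm_mat <- vapply(CLASSIFICATION_TISSUES, function(tis) {
    ifelse(vapply(tissue_sets, function(s) tis %in% s, logical(1)),
           config$tpm_on, config$tpm_off)
  }, numeric(n))
  n_bg <- max(10L, ceiling(n / 10))
  bg_tpm <- vapply(colSums(tpm_mat), function(tot) (1e6 - tot) / n_bg,
                   numeric(1))
  if (any(bg_tpm <= 0)) stop("planted TPM exceeds the per-library budget",
                             call. = FALSE)
  tpm_all <- rbind(tpm_mat, matrix(rep(bg_tpm, each = n_bg), n_bg,
                                   dimnames = list(NULL, CLASSIFICATION_TISSUES)))
  gene_ids_all <- c(gene_ids, sprintf("bg_%04d", seq_len(n_bg)))
  lengths <- round(stats::rlnorm(n + n_bg, log(1200), 0.35))

  species <- config$tree$taxa
  meta <- tidyr::expand_grid(
    species = species, tissue = CLASSIFICATION_TISSUES,
    replicate = seq_len(config$n_replicates)
  )
  for (sp in names(config$missing_tissues)) {
    meta <- dplyr::filter(meta, !(.data$species == sp &
                                    .data$tissue %in% config$missing_tissues[[sp]]))
  }
  meta$library_id <- sprintf("%s_%s_r%d", substr(meta$species, 1, 4),
                             meta$tissue, meta$replicate)

  counts <- tibble::tibble(gene_id = gene_ids_all, length = lengths)
  for (i in seq_len(nrow(meta))) {
    x <- tpm_all[, meta$tissue[i]] * lengths
    mu <- config$lib_size * x / sum(x)
    counts[[meta$library_id[i]]] <- stats::rnbinom(n + n_bg, mu = mu,
                                                   size = config$dispersion)
  }
  truth <- tibble::tibble(
    gene_id = gene_ids_all,
    true_class = c(classes, rep("GR", n_bg)),
    expressed_tissues = c(
      vapply(tissue_sets, paste, character(1), collapse = ","),
      rep(paste(CLASSIFICATION_TISSUES, collapse = ","), n_bg))
  )
  list(counts = counts, metadata = tibble::as_tibble(meta)[,
         c("library_id", "species", "tissue", "replicate")], truth = truth)
}

#' Simulate a complete study bundle on disk
#'
#' Generates per-locus FASTA alignments (one gene class each, true per-locus
#' omega drawn lognormally around the class median, optional SC-branch
#' shift), the matching count table, library metadata, a locus manifest and
#' a ground-truth table, and writes them as plain-text files consumable by
#' [run_pipeline()].
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the bundle paths and the in-memory truth.
#' @export
simulate_study <- function(config, dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(file.path(dir, "loci"), recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)

  classes <- rep(names(config$n_loci), config$n_loci)
  n <- length(classes)
  gene_ids <- sprintf("gene_%04d", seq_len(n))
  true_omega <- config$omega_class_mean[classes] *
    stats::rlnorm(n, 0, config$omega_sdlog)
  shift <- config$sc_shift[classes]

  manifest <- tibble::tibble(locus_id = gene_ids,
                             path = file.path("loci", paste0(gene_ids, ".fasta")))
  truth_rows <- vector("list", n)
  for (i in seq_len(n)) {
    om <- c(SC = unname(true_omega[i] + shift[i]), SI = unname(true_omega[i]),
            INTERNAL = unname(true_omega[i]))
    aln <- simulate_alignment(config$n_codons, config$tree, config$kappa, om,
                              config$codon_freqs, locus_id = gene_ids[i])
    write_fasta(aln, file.path(dir, manifest$path[i]))
    truth_rows[[i]] <- tibble::tibble(
      gene_id = gene_ids[i], true_class = classes[i],
      omega_SC = om[["SC"]], omega_SI = om[["SI"]],
      omega_internal = om[["INTERNAL"]])
  }
  truth_aln <- dplyr::bind_rows(truth_rows)

  # same genes in both layers (class order matches: both expand n_loci in
  # input order); background genes exist only in the expression layer
  expr_cfg <- config
  expr_cfg$n_genes <- config$n_loci
  expr <- simulate_counts(expr_cfg)

  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(expr$counts, file.path(dir, "counts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(expr$metadata, file.path(dir, "libraries.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- dplyr::left_join(truth_aln,
                            dplyr::select(expr$truth, "gene_id", "expressed_tissues"),
                            by = "gene_id")
  utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cfg_out <- config
  cfg_out$tree <- list(taxa = config$tree$taxa,
                       lengths = config$tree$branches$length,
                       classes = config$tree$branches$class)
  yaml::write_yaml(cfg_out, file.path(dir, "config.yaml"))
  invisible(list(dir = dir, manifest = file.path(dir, "manifest.tsv"),
                 counts = file.path(dir, "counts.tsv"),
                 metadata = file.path(dir, "libraries.tsv"),
                 truth = truth))
}

write_fasta <- function(aln, path) {
  codons <- sense_codons()
  lines <- character(0)
  for (tx in aln$taxa) {
    lines <- c(lines, paste0(">", tx),
               paste0(codons[aln$idx[tx, ]], collapse = ""))
  }
  writeLines(lines, path)
}
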