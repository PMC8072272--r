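# End-to-end orchestration over a study bundle: classify genes from counts,
# fit per-locus M0 models, filter, summarize and compare, fit concatenated
# branch models with LRTs, and run the bootstrap null.

#' Run the full analysis pipeline on a study bundle
#'
#' A bundle directory (as written by [simulate_study()], or assembled from
#' real data in the same layout) must contain `manifest.tsv` (locus_id,
#' path), the per-locus FASTA files, `counts.tsv` and `libraries.tsv`.
#'
#' @param dir Bundle directory.
#' @param config A [pipeline_config()] supplying species, thresholds,
#'   bootstrap options and the seed.
#' @param tree A [labeled_tree()]; defaults to the configured topology and
#'   starting lengths.
#' @param out_dir Where to write result tables (default `file.path(dir,
#'   "results")`).
#' @param n_boot_reps,boot_sample_size Bootstrap null settings; the default
#'   scales the resample size to the available loci.
#' @param seed Seed for the bootstrap stage (default from `config`).
#' @param max_omega Exclusion threshold for implausible dN/dS (default from
#'   `config`).
#' @param run_bootstrap Set `FALSE` to skip the (slow) bootstrap stage.
#' @return List of class `pipeline_result`: `classification`, `loci` (per-
#'   locus M0 table joined to classes), `summary` (per-class summary),
#'   `contrasts`, `branch_fits` (per-class concatenated three-ratio fits and
#'   LRTs), `bootstrap` (or `NULL`), `manifest` (stage counts + seed).
#' @export
run_pipeline <- function(dir, config = pipeline_config(),
                         tree = config_tree(config),
                         out_dir = file.path(dir, "results"),
                         n_boot_reps = 200, boot_sample_size = NULL,
                         seed = config$seed, max_omega = config$max_omega,
                         run_bootstrap = TRUE) {
  t0 <- Sys.time()
  # --- expression stage -------------------------------------------------
  counts <- tibble::as_tibble(utils::read.delim(file.path(dir, "counts.tsv")))
  meta <- tibble::as_tibble(utils::read.delim(file.path(dir, "libraries.tsv")))
  profile <- tissue_means(tpm_normalize(counts), meta)
  classification <- classify_genes(profile, config$voting_species,
                                   config$tpm_expressed, config$tpm_trace)

  # --- per-locus codon model stage --------------------------------------
  alignments <- read_alignment_batch(file.path(dir, "manifest.tsv"),
                                     check_length = FALSE)
  loci <- fit_loci_m0(alignments, tree) |>
    dplyr::left_join(classification, by = "gene_id")

  # --- filtering and comparisons ----------------------------------------
  kept <- filter_records(loci, max_omega = max_omega, quiet = TRUE)
  summary_tbl <- summarize_class(kept, "broad")
  contrasts <- if (length(unique(kept$broad)) >= 2 &&
                   min(table(kept$broad)) >= 3) {
    pairwise_contrasts(gamma_glm_identity(kept, "broad"))
  } else NULL

  # --- concatenated branch models per class -----------------------------
  branch_fits <- list()
  lrt_rows <- list()
  for (cl in intersect(c("RP", "VG", "GR"), unique(kept$broad))) {
    ids <- kept$gene_id[kept$broad == cl]
    if (length(ids) < 2) next
    concat <- concatenate_class(alignments[ids], id = cl)
    freqs <- codon_freqs_f3x4(alignments[ids])
    m0 <- fit_m0(concat, tree, codon_freqs = freqs)
    m3 <- fit_branch_model(concat, tree, scheme = "THREE_RATIO",
                           codon_freqs = freqs)
    test <- lrt(m0$lnL, m3$lnL, df = 2)
    branch_fits[[cl]] <- list(m0 = m0, three_ratio = m3, lrt = test)
    lrt_rows[[cl]] <- dplyr::bind_cols(
      tibble::tibble(class = cl, n_genes = length(ids),
                     n_codons = concat$n_codons,
                     lnL_null = m0$lnL, lnL_alt = m3$lnL),
      test,
      tibble::tibble(omega_SI = m3$omega[["omega_SI"]],
                     omega_SC = m3$omega[["omega_SC"]],
                     omega_internal = m3$omega[["omega_internal"]],
                     sc_si_diff = m3$omega[["omega_SC"]] - m3$omega[["omega_SI"]]))
  }
  branch_table <- dplyr::bind_rows(lrt_rows)

  # --- bootstrap null for the SC-SI difference --------------------------
  boot <- NULL
  if (run_bootstrap && "RP" %in% names(branch_fits) &&
      "GR" %in% names(branch_fits)) {
    gr_ids <- kept$gene_id[kept$broad == "GR"]
    if (is.null(boot_sample_size)) {
      boot_sample_size <- max(10L, min(500L, length(gr_ids)))
    }
    observed <- branch_fits$RP$three_ratio$omega[["omega_SC"]] -
      branch_fits$RP$three_ratio$omega[["omega_SI"]]
    boot <- bootstrap_sc_si_null(alignments[gr_ids], tree, observed,
                                 n_reps = n_boot_reps,
                                 sample_size = boot_sample_size, seed = seed,
                                 replace = config$boot_replace)
  }

  # --- write artifacts ---------------------------------------------------
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, f) utils::write.table(x, file.path(out_dir, f), sep = "\t",
                                          quote = FALSE, row.names = FALSE)
  wt(classification, "classification.tsv")
  wt(dplyr::select(loci, -dplyr::any_of("notes")), "loci_m0.tsv")
  wt(summary_tbl, "summary_by_class.tsv")
  if (!is.null(contrasts)) wt(contrasts$contrasts, "contrasts.tsv")
  if (nrow(branch_table)) wt(branch_table, "branch_models.tsv")
  if (!is.null(boot)) wt(boot$diffs, "bootstrap_diffs.tsv")
  manifest <- list(
    seed = seed, n_loci_in = length(alignments),
    n_loci_kept = nrow(kept),
    dropped = as.list(attr(kept, "dropped")),
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  structure(
    list(classification = classification, loci = loci, kept = kept,
         summary = summary_tbl, contrasts = contrasts,
         branch_fits = branch_fits, branch_table = branch_table,
         bootstrap = boot, manifest = manifest),
    class = "pipeline_result"
  )
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> ", x$manifest$n_loci_kept, "/", x$manifest$n_loci_in,
      " loci kept\n", sep = "")
  print(x$summary)
  if (nrow(x$branch_table)) print(x$branch_table)
  invisible(x)
}
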