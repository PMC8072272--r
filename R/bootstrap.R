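# Bootstrap null distribution for the SC-SI rate difference.
#
# With one concatenated estimate per gene class and branch type, parametric
# comparison of the SC-SI difference is impossible; instead the generally
# expressed (GR) loci provide an empirical baseline: resample GR loci,
# re-estimate branch-class dN/dS on each replicate concatenation, and ask
# whether the observed difference for the focal (reproductive) class falls
# outside the 95% interval of the replicate differences.

#' Bootstrap null for the SC minus SI dN/dS difference
#'
#' @param gr_alignments List of [codon_alignment()] objects for the baseline
#'   (generally expressed) gene class.
#' @param tree A [labeled_tree()].
#' @param observed_diff Observed SC minus SI dN/dS difference for the focal
#'   class (from its concatenated branch-model fit).
#' @param n_reps Number of bootstrap replicates (default 1000).
#' @param sample_size Loci drawn per replicate (default 500).
#' @param seed Integer seed; fixes every replicate draw.
#' @param replace Resample with replacement (default `TRUE`); without
#'   replacement requires `sample_size <=` number of loci.
#' @param scheme Branch-model scheme for the per-replicate fits (default
#'   `"THREE_RATIO"`).
#' @param per_replicate What each replicate re-estimates: `"omega"` (default)
#'   re-fits the branch-class omegas with kappa and branch lengths pinned at
#'   the pooled-fit values (they are nuisance parameters shared across
#'   resamples of the same loci); `"full"` re-estimates everything.
#' @param codon_freqs Optional fixed stationary frequencies; default F3x4
#'   from the pooled baseline loci (computed once, shared by all replicates).
#' @param pooled_starts Omega start grid for the pooled anchor fit (default
#'   the full grid; a single start suffices for well-behaved data).
#' @return Object of class `bootstrap_null`: `diffs` (tibble of replicate SC,
#'   SI, diff), `ci95`, `observed`, `percentile_of_observed`, `outside_ci`.
#' @export
bootstrap_sc_si_null <- function(gr_alignments, tree, observed_diff,
                                 n_reps = 1000, sample_size = 500, seed = 1,
                                 replace = TRUE, scheme = "THREE_RATIO",
                                 per_replicate = c("omega", "full"),
                                 codon_freqs = NULL,
                                 pooled_starts = OMEGA_START_GRID) {
  per_replicate <- match.arg(per_replicate)
  n_loci <- length(gr_alignments)
  if (!replace && sample_size > n_loci) {
    stop("sample_size (", sample_size, ") exceeds available loci (", n_loci,
         ") for sampling without replacement", call. = FALSE)
  }
  if (is.null(codon_freqs)) codon_freqs <- codon_freqs_f3x4(gr_alignments)
  set.seed(seed)
  draws <- replicate(n_reps, sample.int(n_loci, sample_size, replace = replace),
                     simplify = FALSE)
  # pooled fit of the whole baseline set warm-starts every replicate;
  # replicate optima sit close to it, so a single medium-precision
  # optimization per replicate suffices
  pooled <- fit_branch_model(concatenate_class(gr_alignments, id = "pooled"),
                             tree, scheme = scheme, codon_freqs = codon_freqs,
                             starts = pooled_starts)
  ok_pooled <- pooled$converged && !anyNA(pooled$omega)
  init <- if (ok_pooled) {
    c(pooled$kappa, unname(pooled$omega), unname(pooled$branch_lengths))
  } else NULL
  fixed <- if (ok_pooled && per_replicate == "omega") {
    list(kappa = pooled$kappa, lengths = unname(pooled$branch_lengths))
  } else NULL

  # all replicates resample the same loci, so a replicate's site-pattern
  # weights are a locus-multiplicity-weighted sum over one pooled pattern
  # table; build that table once
  taxa <- tree$taxa
  keys_list <- lapply(gr_alignments, function(a)
    apply(a$idx[taxa, , drop = FALSE], 2, paste, collapse = "."))
  all_keys <- unique(unlist(keys_list))
  pat_global <- vapply(strsplit(all_keys, ".", fixed = TRUE), as.integer,
                       integer(4))
  Wmat <- matrix(0, length(all_keys), n_loci)
  for (l in seq_len(n_loci)) {
    tb <- table(keys_list[[l]])
    Wmat[match(names(tb), all_keys), l] <- as.numeric(tb)
  }

  res <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    m <- tabulate(draws[[r]], n_loci)
    w <- as.vector(Wmat %*% m)
    keep <- w > 0
    sp <- list(patterns = pat_global[, keep, drop = FALSE], weights = w[keep])
    fit <- fit_codon_model(NULL, tree, scheme, codon_freqs = codon_freqs,
                           starts = if (is.null(init)) OMEGA_START_GRID else numeric(0),
                           init = init, fast = TRUE, fixed = fixed, sp = sp)
    sc <- unname(fit$omega[["omega_SC"]])
    si <- unname(fit$omega[[if (scheme == "THREE_RATIO") "omega_SI" else
      "omega_SI_internal"]])
    res[[r]] <- tibble::tibble(rep = r, omega_SC = sc, omega_SI = si,
                               diff = sc - si, converged = fit$converged)
  }
  diffs <- dplyr::bind_rows(res)
  d <- diffs$diff[diffs$converged & !is.na(diffs$diff)]
  ci95 <- stats::quantile(d, c(0.025, 0.975), names = FALSE, type = 7)
  pct <- 100 * mean(d < observed_diff)
  structure(
    list(diffs = diffs, ci95 = ci95, observed = observed_diff,
         percentile_of_observed = pct,
         outside_ci = observed_diff < ci95[1] || observed_diff > ci95[2],
         n_reps = n_reps, sample_size = sample_size, seed = seed,
         replace = replace, scheme = scheme),
    class = "bootstrap_null"
  )
}

#' @export
print.bootstrap_null <- function(x, ...) {
  cat("<bootstrap_null> ", x$n_reps, " replicates x ", x$sample_size,
      " loci (", if (x$replace) "with" else "without", " replacement)\n", sep = "")
  cat("  95% CI of SC-SI diff: [", signif(x$ci95[1], 4), ", ",
      signif(x$ci95[2], 4), "]\n", sep = "")
  cat("  observed diff ", signif(x$observed, 4), " at percentile ",
      round(x$percentile_of_observed, 1),
      if (x$outside_ci) " (outside CI)" else " (inside CI)", "\n", sep = "")
  invisible(x)
}

#' @export
tidy.bootstrap_null <- function(x, ...) x$diffs

#' @export
glance.bootstrap_null <- function(x, ...) {
  tibble::tibble(
    n_reps = x$n_reps, sample_size = x$sample_size,
    ci_low = x$ci95[1], ci_high = x$ci95[2],
    observed = x$observed, percentile_of_observed = x$percentile_of_observed,
    outside_ci = x$outside_ci
  )
}
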