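# Maximum-likelihood fits of the one-ratio (M0) and multi-ratio branch
# models, and the likelihood-ratio test between them.

OMEGA_BOUNDS <- c(1e-4, 99)
KAPPA_BOUNDS <- c(0.1, 50)
BL_BOUNDS <- c(1e-7, 10)
OMEGA_START_GRID <- c(0.1, 1, 2)

# codon p-distances between taxa give deterministic branch-length starts
start_branch_lengths <- function(pat, wts) {
  tot <- sum(wts)
  pd <- function(i, j) sum(wts[pat[i, ] != pat[j, ]]) / tot
  dAB <- pd(1, 2); dCD <- pd(3, 4)
  cross <- mean(c(pd(1, 3), pd(1, 4), pd(2, 3), pd(2, 4)))
  tint <- max(cross - dAB / 2 - dCD / 2, 1e-3)
  pmax(c(dAB / 2, dAB / 2, dCD / 2, dCD / 2, tint), 1e-3)
}

new_omega_fit <- function(id, model, kappa, omega, branch_lengths, lnL, dN, dS,
                          converged, notes, n_codons, codon_freqs) {
  dn_ds <- if (length(omega) == 1L && !is.na(dS) && dS == 0 && !is.na(dN) && dN == 0) {
    NA_real_
  } else unname(omega[1])
  structure(
    list(id = id, model = model, kappa = kappa, omega = omega,
         branch_lengths = branch_lengths, lnL = lnL, dN = dN, dS = dS,
         dn_ds = if (length(omega) == 1L) dn_ds else unname(omega),
         converged = converged, notes = notes, n_codons = n_codons,
         codon_freqs = codon_freqs),
    class = "omega_fit"
  )
}

# decompose tree length into dN and dS using the fitted synonymous flux
# fraction per branch and the mutational-opportunity fraction at omega = 1
decompose_dn_ds <- function(kappa, omega_per_branch, lengths, codon_freqs) {
  p1 <- codon_model_params(kappa, c(X = 1), codon_freqs)
  fS1 <- synonymous_flux_fraction(p1, "X")
  syn_subs <- 0; nonsyn_subs <- 0
  for (b in seq_along(lengths)) {
    pb <- codon_model_params(kappa, c(X = max(omega_per_branch[b], 0)), codon_freqs)
    rhoS <- synonymous_flux_fraction(pb, "X")
    syn_subs <- syn_subs + lengths[b] * rhoS
    nonsyn_subs <- nonsyn_subs + lengths[b] * (1 - rhoS)
  }
  list(dN = nonsyn_subs / (3 * (1 - fS1)), dS = syn_subs / (3 * fS1))
}

fit_codon_model <- function(aln, tree, scheme, codon_freqs = NULL,
                            starts = OMEGA_START_GRID, init = NULL,
                            fast = FALSE, fixed = NULL, sp = NULL) {
  taxa <- tree$taxa
  if (is.null(sp)) {
    if (!setequal(aln$taxa, taxa)) {
      stop("locus ", aln$locus_id, ": alignment taxa do not match tree taxa",
           call. = FALSE)
    }
    sp <- site_patterns(aln)
    sp$patterns <- sp$patterns[taxa, , drop = FALSE]
    locus_id <- aln$locus_id
    n_codons <- aln$n_codons
  } else {
    # precomputed site patterns (rows already in tree taxon order), e.g.
    # bootstrap replicates sharing one pooled pattern table
    locus_id <- if (!is.null(aln)) aln$locus_id else "patterns"
    n_codons <- as.integer(round(sum(sp$weights)))
  }
  if (is.null(codon_freqs)) codon_freqs <- codon_freqs_f3x4(aln)
  cmap <- scheme_class_map(scheme)
  k_omega <- max(cmap)
  omega_names <- scheme_omega_names(scheme)
  branch_to_par <- unname(cmap[tree$branches$class])

  if (all(sp$patterns == rep(sp$patterns[1, ], each = 4L))) {
    return(new_omega_fit(
      id = locus_id, model = scheme, kappa = NA_real_,
      omega = stats::setNames(rep(NA_real_, k_omega), omega_names),
      branch_lengths = stats::setNames(rep(0, 5), tree$branches$branch),
      lnL = NA_real_, dN = 0, dS = 0, converged = TRUE,
      notes = "degenerate: identical sequences", n_codons = n_codons,
      codon_freqs = codon_freqs))
  }

  pat <- sp$patterns - 1L
  wts <- sp$weights
  ptype <- codon_pair_type()

  # optionally pin kappa and/or branch lengths (nuisance parameters in
  # warm-started replicate refits); the free vector shrinks accordingly
  kappa_free <- is.null(fixed$kappa)
  len_free <- is.null(fixed$lengths)
  off <- as.integer(kappa_free)
  expand <- function(theta) {
    list(
      kappa = if (kappa_free) theta[1] else fixed$kappa,
      omegas = theta[(off + 1):(off + k_omega)],
      lens = if (len_free) theta[(off + k_omega + 1):(off + k_omega + 5)]
             else fixed$lengths
    )
  }
  shrink <- function(full) {
    keep <- c(kappa_free, rep(TRUE, k_omega), rep(len_free, 5))
    full[keep]
  }

  # per-(kappa, omega) decomposition dictionary: single-parameter moves of
  # the optimizer's finite differences re-decompose only what changed
  dc_env <- new.env(parent = emptyenv())
  decomps_for <- function(kappa, omegas) {
    per_branch <- omegas[branch_to_par]
    lapply(per_branch, function(w) {
      key <- paste0(format(kappa, digits = 17), "_", format(w, digits = 17))
      hit <- dc_env[[key]]
      if (is.null(hit)) {
        hit <- gy94_decompose_cpp(codon_freqs, ptype, kappa, w)
        assign(key, hit, envir = dc_env)
      }
      hit
    })
  }
  negll <- function(theta) {
    p <- expand(theta)
    dv <- decomps_for(p$kappa, p$omegas)
    ll <- gy94_loglik_decomp_cpp(pat, wts, codon_freqs, dv, p$lens)
    if (!is.finite(ll)) return(1e12)
    -ll
  }
  # analytic gradient in branch lengths; forward differences for the
  # substitution parameters (which require fresh decompositions anyway)
  grad <- function(theta) {
    p <- expand(theta)
    dv <- decomps_for(p$kappa, p$omegas)
    if (len_free) {
      res <- gy94_loglik_grad_cpp(pat, wts, codon_freqs, dv, p$lens)
      if (!is.finite(res$ll)) return(rep(0, length(theta)))
      f0 <- -res$ll
    } else {
      f0 <- negll(theta)
      if (f0 >= 1e12) return(rep(0, length(theta)))
    }
    g <- numeric(length(theta))
    if (len_free) g[(off + k_omega + 1):(off + k_omega + 5)] <- -res$grad
    for (i in seq_len(off + k_omega)) {
      h <- 1e-5 * max(1, abs(theta[i]))
      th <- theta; th[i] <- th[i] + h
      g[i] <- (negll(th) - f0) / h
    }
    g
  }

  bl0 <- if (len_free) start_branch_lengths(sp$patterns, wts) else fixed$lengths
  lower <- shrink(c(KAPPA_BOUNDS[1], rep(OMEGA_BOUNDS[1], k_omega),
                    rep(BL_BOUNDS[1], 5)))
  upper <- shrink(c(KAPPA_BOUNDS[2], rep(OMEGA_BOUNDS[2], k_omega),
                    rep(BL_BOUNDS[2], 5)))

  start_list <- lapply(starts, function(w0) shrink(c(2, rep(w0, k_omega), bl0)))
  if (!is.null(init)) start_list <- c(list(shrink(init)), start_list)

  # coarse pass from every start, then polish the best optimum; fast mode
  # (warm-started refits, e.g. bootstrap replicates) runs one medium-
  # precision optimization per start instead
  best <- NULL
  any_conv <- FALSE
  for (st in start_list) {
    st <- pmin(pmax(st, lower), upper)
    opt <- tryCatch(
      stats::optim(st, negll, gr = grad, method = "L-BFGS-B", lower = lower,
                   upper = upper,
                   control = list(maxit = if (fast) 300 else 200,
                                  factr = if (fast) 1e9 else 1e10)),
      error = function(e) NULL)
    if (is.null(opt)) next
    if (fast && opt$convergence == 0) any_conv <- TRUE
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (!fast && !is.null(best)) {
    polish <- tryCatch(
      stats::optim(best$par, negll, gr = grad, method = "L-BFGS-B", lower = lower,
                   upper = upper, control = list(maxit = 500, factr = 1e7)),
      error = function(e) NULL)
    if (!is.null(polish) && polish$value <= best$value) best <- polish
    any_conv <- !is.null(polish) && polish$convergence == 0
  }
  if (is.null(best)) {
    return(new_omega_fit(
      id = locus_id, model = scheme, kappa = NA_real_,
      omega = stats::setNames(rep(NA_real_, k_omega), omega_names),
      branch_lengths = stats::setNames(bl0, tree$branches$branch),
      lnL = NA_real_, dN = NA_real_, dS = NA_real_, converged = FALSE,
      notes = "optimizer failed from all starts", n_codons = n_codons,
      codon_freqs = codon_freqs))
  }

  p_hat <- expand(best$par)
  kappa <- p_hat$kappa
  omegas <- stats::setNames(p_hat$omegas, omega_names)
  bl <- stats::setNames(p_hat$lens, tree$branches$branch)
  dd <- decompose_dn_ds(kappa, unname(omegas)[branch_to_par], unname(bl),
                        codon_freqs)
  notes <- character()
  if (dd$dS < 1e-8) notes <- c(notes, "dS~0")
  if (any(omegas >= OMEGA_BOUNDS[2] - 1e-6)) notes <- c(notes, "omega at upper bound")
  new_omega_fit(
    id = locus_id, model = scheme, kappa = kappa, omega = omegas,
    branch_lengths = bl, lnL = -best$value, dN = dd$dN, dS = dd$dS,
    converged = any_conv, notes = paste(notes, collapse = "; "),
    n_codons = n_codons, codon_freqs = codon_freqs)
}

#' Fit the one-ratio (M0) codon model to a locus
#'
#' Jointly maximizes the likelihood over kappa, a single omega shared by all
#' branches, and the five branch lengths, using bounded quasi-Newton
#' (L-BFGS-B) from a fixed grid of omega starting values, so results are
#' deterministic. dN and dS are derived from the fitted tree length
#' partitioned into synonymous and nonsynonymous flux.
#'
#' @param aln A [codon_alignment()].
#' @param tree A [labeled_tree()] giving the topology; its branch lengths are
#'   only used indirectly (lengths are re-estimated).
#' @param codon_freqs Stationary codon frequencies; default F3x4 estimated
#'   from the alignment.
#' @param starts Omega starting grid (default `c(0.1, 1, 2)`).
#' @param fast Single medium-precision optimization per start (see
#'   [fit_branch_model()]).
#' @return An `omega_fit` object; see [glance.omega_fit()].
#' @export
fit_m0 <- function(aln, tree, codon_freqs = NULL, starts = OMEGA_START_GRID,
                   fast = FALSE) {
  fit_codon_model(aln, tree, "M0", codon_freqs, starts, fast = fast)
}

#' Fit a multi-ratio branch model
#'
#' `THREE_RATIO` gives each branch class (SC tips, SI tips, internal branch)
#' its own omega; `TWO_RATIO` merges the internal branch with the SI class.
#' Shared kappa and branch lengths are co-estimated.
#'
#' @inheritParams fit_m0
#' @param scheme `"TWO_RATIO"` or `"THREE_RATIO"`.
#' @param init Optional full parameter start vector
#'   `(kappa, omegas, 5 branch lengths)` used as an additional warm start.
#' @param fast Single medium-precision optimization per start instead of the
#'   coarse-then-polish scheme; intended for warm-started refits such as
#'   bootstrap replicates.
#' @param fixed Optional list pinning nuisance parameters: `kappa` (scalar)
#'   and/or `lengths` (5 branch lengths); pinned values are excluded from
#'   optimization.
#' @return An `omega_fit` with one omega per branch-class group.
#' @export
fit_branch_model <- function(aln, tree, scheme = c("THREE_RATIO", "TWO_RATIO"),
                             codon_freqs = NULL, starts = OMEGA_START_GRID,
                             init = NULL, fast = FALSE, fixed = NULL) {
  scheme <- match.arg(scheme)
  fit_codon_model(aln, tree, scheme, codon_freqs, starts, init, fast, fixed)
}

#' Likelihood-ratio test between nested codon models
#'
#' @param lnL_null,lnL_alt Maximized log-likelihoods of the nested (null) and
#'   richer (alternative) model.
#' @param df Difference in free parameters (1 for two-ratio vs M0, 2 for
#'   three-ratio vs M0).
#' @return One-row tibble with `stat` (2*(lnL_alt - lnL_null), clipped at 0),
#'   `df` and the upper-tail chi-square `p_value`.
#' @export
lrt <- function(lnL_null, lnL_alt, df) {
  stopifnot(df >= 1)
  stat <- 2 * (lnL_alt - lnL_null)
  if (stat < -1e-6) {
    warning("alternative log-likelihood below null; statistic clipped to 0 ",
            "(check optimizer convergence)")
  }
  stat <- max(stat, 0)
  tibble::tibble(stat = stat, df = as.integer(df),
                 p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' @export
print.omega_fit <- function(x, ...) {
  cat("<omega_fit> ", x$id, " [", x$model, "]  lnL = ",
      format(x$lnL, digits = 10), "\n", sep = "")
  cat("  kappa =", signif(x$kappa, 4), " omega =",
      paste(names(x$omega), signif(x$omega, 4), sep = "=", collapse = ", "), "\n")
  cat("  dN =", signif(x$dN, 4), " dS =", signif(x$dS, 4),
      if (nzchar(x$notes)) paste0(" [", x$notes, "]") else "", "\n")
  invisible(x)
}

#' Tidy a codon model fit
#'
#' @param x An `omega_fit`.
#' @param ... Unused.
#' @return Tibble with one row per estimated parameter (term, estimate).
#' @export
tidy.omega_fit <- function(x, ...) {
  tibble::tibble(
    term = c("kappa", names(x$omega), names(x$branch_lengths)),
    estimate = c(x$kappa, unname(x$omega), unname(x$branch_lengths))
  )
}

#' One-row summary of a codon model fit
#'
#' @param x An `omega_fit`.
#' @param ... Unused.
#' @return One-row tibble: id, model, per-class omega columns, kappa, dN, dS,
#'   lnL, n_codons, converged, degenerate flag and notes.
#' @export
glance.omega_fit <- function(x, ...) {
  om <- tibble::as_tibble(as.list(x$omega))
  dplyr::bind_cols(
    tibble::tibble(id = x$id, model = x$model),
    om,
    tibble::tibble(
      kappa = x$kappa, dN = x$dN, dS = x$dS, lnL = x$lnL,
      tree_length = sum(x$branch_lengths), n_codons = x$n_codons,
      converged = x$converged,
      degenerate = grepl("degenerate", x$notes),
      notes = x$notes
    )
  )
}

#' Fit M0 to every locus in a batch
#'
#' Convenience wrapper mapping [fit_m0()] over a list of alignments and
#' binding the one-row summaries into the per-locus table consumed by the
#' statistics layer.
#'
#' @param alignments List of [codon_alignment()] objects.
#' @param tree A [labeled_tree()].
#' @param ... Passed to [fit_m0()].
#' @return Tibble with one row per locus (columns of [glance.omega_fit()],
#'   `id` renamed to `gene_id`, plus `omega` as the M0 point estimate).
#' @export
fit_loci_m0 <- function(alignments, tree, ...) {
  purrr::map_dfr(alignments, function(a) glance(fit_m0(a, tree, ...))) |>
    dplyr::rename(gene_id = "id")
}
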