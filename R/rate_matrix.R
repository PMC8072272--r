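# GY94 codon rate matrices and transition probabilities (pure-R reference
# path; the optimizer's hot loop uses the compiled equivalent).

#' Codon model parameters
#'
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param omega_by_class Named list/vector mapping branch classes to omega
#'   (dN/dS) values; a single unnamed value is treated as the shared M0 omega
#'   for all classes.
#' @param codon_freqs 61 stationary codon frequencies summing to 1; default
#'   uniform. Use [codon_freqs_f3x4()] to derive them from data.
#' @return Object of class `codon_model_params`.
#' @export
codon_model_params <- function(kappa = 2,
                               omega_by_class = c(omega = 0.2),
                               codon_freqs = NULL) {
  if (kappa <= 0) stop("kappa must be positive", call. = FALSE)
  if (is.null(names(omega_by_class)) && length(omega_by_class) == 1L) {
    omega_by_class <- c(SC = omega_by_class, SI = omega_by_class,
                        INTERNAL = omega_by_class)
  }
  if (any(unlist(omega_by_class) < 0)) stop("omega must be non-negative", call. = FALSE)
  if (is.null(codon_freqs)) codon_freqs <- rep(1 / 61, 61)
  if (length(codon_freqs) != 61L || abs(sum(codon_freqs) - 1) > 1e-12) {
    stop("codon_freqs must be 61 values summing to 1", call. = FALSE)
  }
  structure(
    list(kappa = kappa, omega_by_class = as.list(omega_by_class),
         codon_freqs = as.numeric(codon_freqs)),
    class = "codon_model_params"
  )
}

#' F3x4 stationary codon frequencies
#'
#' Estimates position-specific nucleotide frequencies from the alignment and
#' forms codon frequencies as their product, zeroing stop codons and
#' renormalizing — the standard empirical frequency model for GY94 fits.
#'
#' @param aln A [codon_alignment()] (or list of alignments pooled together).
#' @param pseudocount Added to each position-specific nucleotide count to keep
#'   all 61 frequencies positive on short alignments.
#' @return Numeric vector of 61 frequencies summing to 1.
#' @export
codon_freqs_f3x4 <- function(aln, pseudocount = 0.5) {
  alns <- if (inherits(aln, "codon_alignment")) list(aln) else aln
  counts <- matrix(pseudocount, nrow = 3, ncol = 4,
                   dimnames = list(NULL, NUCS))
  codons <- sense_codons()
  for (a in alns) {
    cod <- codons[a$idx]
    for (pos in 1:3) {
      tab <- table(factor(substring(cod, pos, pos), levels = NUCS))
      counts[pos, ] <- counts[pos, ] + as.numeric(tab)
    }
  }
  posfreq <- counts / rowSums(counts)
  f <- vapply(codons, function(cd) {
    prod(posfreq[cbind(1:3, match(strsplit(cd, "")[[1]], NUCS))])
  }, numeric(1))
  unname(f / sum(f))
}

#' Build a GY94 instantaneous rate matrix
#'
#' Off-diagonal rates for single-nucleotide codon changes are
#' `pi_j` (synonymous transversion), `kappa * pi_j` (synonymous transition),
#' `omega * pi_j` (nonsynonymous transversion) and `kappa * omega * pi_j`
#' (nonsynonymous transition); multi-nucleotide changes have rate 0. Rows sum
#' to zero. When `scale = TRUE` the matrix is normalized so the expected
#' number of substitutions per codon per unit time equals 1 at these
#' parameters, making branch lengths expected substitutions per codon.
#'
#' @param params A [codon_model_params()].
#' @param branch_class Branch class whose omega applies (default `"SC"`; any
#'   class present in `params$omega_by_class`).
#' @param scale Normalize total flux to 1 substitution/codon/unit time.
#' @return 61 x 61 rate matrix with codon dimnames.
#' @export
build_rate_matrix <- function(params, branch_class = "SC", scale = TRUE) {
  if (!branch_class %in% names(params$omega_by_class)) {
    stop("no omega configured for branch class ", branch_class, call. = FALSE)
  }
  omega <- params$omega_by_class[[branch_class]]
  type <- codon_pair_type()
  pi <- params$codon_freqs
  mult <- c(0, 1, params$kappa, omega, params$kappa * omega)[type + 1L]
  Q <- matrix(mult, 61, 61) * rep(pi, each = 61)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  if (scale) {
    mu <- -sum(pi * diag(Q))
    if (mu > 0) Q <- Q / mu
  }
  dimnames(Q) <- dimnames(type)
  Q
}

#' Transition probability matrix P(t) = expm(Q t)
#'
#' Uses the spectral decomposition of the reversible generator (symmetrized
#' by the stationary frequencies), so the result is exact to numerical
#' precision and cheap to evaluate at many branch lengths.
#'
#' @param Q Rate matrix from [build_rate_matrix()].
#' @param t Branch length (>= 0).
#' @param pi Stationary frequencies used to build `Q`.
#' @return 61 x 61 probability matrix; rows sum to 1, entries clipped at 0.
#' @export
transition_probs <- function(Q, t, pi) {
  if (t < 0) stop("branch length must be non-negative", call. = FALSE)
  sq <- sqrt(pi)
  B <- (sq %o% (1 / sq)) * Q  # symmetric for reversible Q
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)
  P <- outer(1 / sq, sq) * (eig$vectors %*% (exp(eig$values * t) * t(eig$vectors)))
  if (any(!is.finite(P))) stop("non-finite transition probabilities", call. = FALSE)
  P[P < 0] <- 0
  P <- P / rowSums(P)
  dimnames(P) <- dimnames(Q)
  P
}

# Proportion of total substitution flux that is synonymous, at given params.
# Used to decompose tree length into dN and dS.
synonymous_flux_fraction <- function(params, branch_class = "SC") {
  Q <- build_rate_matrix(params, branch_class, scale = FALSE)
  type <- codon_pair_type()
  pi <- params$codon_freqs
  flux <- pi * Q
  syn <- sum(flux[type == 1L | type == 2L])
  tot <- sum(flux[type != 0L])
  syn / tot
}
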