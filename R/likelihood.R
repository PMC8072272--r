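# Alignment log-likelihood under the GY94 model on the labeled tree.

#' Alignment log-likelihood under the GY94 codon model
#'
#' Felsenstein pruning over the 61 sense-codon states on the fixed unrooted
#' 4-taxon tree, with the root placed on the internal branch and the root
#' state weighted by the stationary frequencies. Under the reversible model
#' the value is invariant to root placement.
#'
#' @param aln A [codon_alignment()].
#' @param tree A [labeled_tree()]; its taxa must match the alignment's.
#' @param params A [codon_model_params()] with an omega for every branch
#'   class appearing in the tree.
#' @return The log-likelihood (numeric scalar).
#' @export
log_likelihood <- function(aln, tree, params) {
  if (!setequal(aln$taxa, tree$taxa)) {
    stop("locus ", aln$locus_id, ": alignment taxa do not match tree taxa",
         call. = FALSE)
  }
  sp <- site_patterns(aln)
  idx <- sp$patterns[tree$taxa, , drop = FALSE]
  gy94_loglik_cpp(
    patterns = idx - 1L,
    weights = sp$weights,
    pi = params$codon_freqs,
    ptype = codon_pair_type(),
    kappa = params$kappa,
    omega_branch = branch_omegas(tree, params$omega_by_class),
    len = tree$branches$length
  )
}
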