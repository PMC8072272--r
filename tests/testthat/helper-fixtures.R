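# Shared fixtures and independent oracles used across test files.

# a tree with enough divergence to carry signal in small simulations,
# keeping the study's SC-short / SI-long asymmetry
signal_tree <- function(scale = 1) {
  solanum_tree(scale * c(0.05, 0.05, 0.1, 0.1, 0.08))
}

toy_codon_aln <- function(seqs, id = "toy") {
  names(seqs) <- c("lycopersicum", "pimpinellifolium", "pennellii",
                   "habrochaites")
  codon_alignment(seqs, locus_id = id)
}

# brute-force pruning oracle: sum over all 61^2 internal-node states using
# the pure-R transition matrices; optionally with the root moved a distance
# `root_at` along the internal branch (pulley check)
brute_force_loglik <- function(aln, tree, params, root_at = NULL) {
  pi <- params$codon_freqs
  cls <- tree$branches$class
  lens <- tree$branches$length
  Qs <- lapply(stats::setNames(unique(cls), unique(cls)),
               function(cl) build_rate_matrix(params, cl))
  P <- lapply(1:5, function(b) transition_probs(Qs[[cls[b]]], lens[b], pi))
  idx <- aln$idx[tree$taxa, , drop = FALSE]
  ll <- 0
  if (is.null(root_at)) {
    for (k in seq_len(ncol(idx))) {
      s <- 0
      for (u in 1:61) {
        lu <- pi[u] * P[[1]][u, idx[1, k]] * P[[2]][u, idx[2, k]]
        if (lu == 0) next
        s <- s + lu * sum(P[[5]][u, ] * P[[3]][, idx[3, k]] * P[[4]][, idx[4, k]])
      }
      ll <- ll + log(s)
    }
  } else {
    Pa <- transition_probs(Qs[[cls[5]]], root_at, pi)
    Pb <- transition_probs(Qs[[cls[5]]], lens[5] - root_at, pi)
    for (k in seq_len(ncol(idx))) {
      lu <- P[[1]][, idx[1, k]] * P[[2]][, idx[2, k]]
      lv <- P[[3]][, idx[3, k]] * P[[4]][, idx[4, k]]
      s <- sum(pi * (Pa %*% lu) * (Pb %*% lv))
      ll <- ll + log(s)
    }
  }
  ll
}

# independent NG86 pathway oracle: enumerate every ordering of the differing
# positions, discard orderings that pass through a stop codon, and average
# the synonymous/nonsynonymous step counts
oracle_pathway_counts <- function(c1, c2) {
  gc <- Biostrings::GENETIC_CODE
  n1 <- strsplit(c1, "")[[1]]; n2 <- strsplit(c2, "")[[1]]
  pos <- which(n1 != n2)
  if (length(pos) == 0) return(c(sd = 0, nd = 0))
  perms <- combinat_perms(pos)
  acc <- NULL
  for (ord in perms) {
    cur <- n1; sd <- 0; nd <- 0; ok <- TRUE
    for (p in ord) {
      nxt <- cur; nxt[p] <- n2[p]
      if (gc[[paste0(nxt, collapse = "")]] == "*") { ok <- FALSE; break }
      if (gc[[paste0(cur, collapse = "")]] == gc[[paste0(nxt, collapse = "")]]) {
        sd <- sd + 1
      } else nd <- nd + 1
      cur <- nxt
    }
    if (ok) acc <- rbind(acc, c(sd, nd))
  }
  c(sd = mean(acc[, 1]), nd = mean(acc[, 2]))
}

combinat_perms <- function(x) {
  if (length(x) == 1) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in combinat_perms(x[-i])) out <- c(out, list(c(x[i], rest)))
  }
  out
}

# small long-format expression profile builder: `...` are named species
# entries, each a named TPM vector over tissues
make_profile <- function(gene_id, ...) {
  sp <- list(...)
  dplyr::bind_rows(lapply(names(sp), function(s) {
    tibble::tibble(gene_id = gene_id, species = s,
                   tissue = names(sp[[s]]), mean_tpm = unname(sp[[s]]),
                   n_reps = 1L)
  }))
}

# uniform TPM vector over the 8 classification tissues with overrides
tpm_vec <- function(..., base = 0) {
  tissues <- c("leaf", "root", "stem", "seed", "meristem", "style", "pollen",
               "ovule")
  v <- stats::setNames(rep(base, 8), tissues)
  ov <- c(...)
  v[names(ov)] <- ov
  v
}

full_profile <- function(gene_id, ..., base = 0) {
  make_profile(gene_id,
               lycopersicum = tpm_vec(..., base = base),
               pennellii = tpm_vec(..., base = base),
               habrochaites = tpm_vec(..., base = base))
}
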