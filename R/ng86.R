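# Nei-Gojobori (1986) pathway-counting estimator of dN and dS with
# Jukes-Cantor correction. Used as a fast, model-free cross-check on the
# maximum-likelihood fits.

# synonymous site count of one codon: each of the 3 positions contributes
# (number of synonymous single-nucleotide alternatives)/3; changes creating
# a stop codon count as nonsynonymous opportunity, so S + N = 3 per codon.
ng86_syn_sites <- function(codon) {
  gc <- Biostrings::GENETIC_CODE
  aa <- gc[[codon]]
  nt <- strsplit(codon, "")[[1]]
  s <- 0
  for (pos in 1:3) {
    for (alt in setdiff(NUCS, nt[pos])) {
      mut <- nt; mut[pos] <- alt
      mut <- paste0(mut, collapse = "")
      if (gc[[mut]] == aa && gc[[mut]] != "*") s <- s + 1 / 3
    }
  }
  s
}

# average syn/nonsyn difference counts over equally weighted mutational
# pathways between two codons; pathways through stop codons are discarded
ng86_pathway_diffs <- function(c1, c2) {
  gc <- Biostrings::GENETIC_CODE
  n1 <- strsplit(c1, "")[[1]]
  n2 <- strsplit(c2, "")[[1]]
  pos <- which(n1 != n2)
  if (!length(pos)) return(c(sd = 0, nd = 0))
  perms <- if (length(pos) == 1L) list(pos) else {
    if (length(pos) == 2L) list(pos, rev(pos)) else {
      p <- pos
      list(p[c(1,2,3)], p[c(1,3,2)], p[c(2,1,3)], p[c(2,3,1)],
           p[c(3,1,2)], p[c(3,2,1)])
    }
  }
  counts <- matrix(NA_real_, length(perms), 2)
  for (k in seq_along(perms)) {
    cur <- n1; sd <- 0; nd <- 0; valid <- TRUE
    for (p in perms[[k]]) {
      nxt <- cur; nxt[p] <- n2[p]
      from <- paste0(cur, collapse = ""); to <- paste0(nxt, collapse = "")
      if (gc[[to]] == "*") { valid <- FALSE; break }
      if (gc[[from]] == gc[[to]]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    if (valid) counts[k, ] <- c(sd, nd)
  }
  ok <- stats::complete.cases(counts)
  if (!any(ok)) ok <- rep(TRUE, nrow(counts))  # all paths cross a stop: keep all
  c(sd = mean(counts[ok, 1], na.rm = TRUE), nd = mean(counts[ok, 2], na.rm = TRUE))
}

#' NG86 counting estimate of dN and dS for a sequence pair
#'
#' Classic pathway counting: synonymous/nonsynonymous sites averaged over the
#' two sequences, observed differences averaged over equally weighted
#' mutational pathways (pathways through stop codons discarded), and the
#' Jukes-Cantor multiple-hit correction applied to both proportions.
#'
#' @param seq1,seq2 In-frame codon sequences (character strings, equal
#'   length, sense codons only) or two rows of a [codon_alignment()] given as
#'   codon-index vectors.
#' @return One-row tibble: `S`, `N` (site counts), `Sd`, `Nd` (difference
#'   counts), `pS`, `pN`, `dS`, `dN`, `dn_ds`, and `estimable` (`FALSE` when
#'   the Jukes-Cantor log argument is non-positive, i.e. saturated).
#' @export
ng86_counting <- function(seq1, seq2) {
  codons <- sense_codons()
  c1 <- if (is.character(seq1) && length(seq1) == 1L) split_codons(toupper(seq1)) else codons[seq1]
  c2 <- if (is.character(seq2) && length(seq2) == 1L) split_codons(toupper(seq2)) else codons[seq2]
  if (length(c1) != length(c2)) stop("sequences differ in codon count", call. = FALSE)
  codon_index(c1); codon_index(c2)  # validates sense codons

  if (is.null(.repevol_cache$ng86_sites)) {
    .repevol_cache$ng86_sites <- vapply(codons, ng86_syn_sites, numeric(1))
  }
  sites <- .repevol_cache$ng86_sites
  S <- (sum(sites[c1]) + sum(sites[c2])) / 2
  N <- 3 * length(c1) - S

  d <- vapply(seq_along(c1), function(i) ng86_pathway_diffs(c1[i], c2[i]),
              numeric(2))
  Sd <- sum(d["sd", ]); Nd <- sum(d["nd", ])
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  jc <- function(p) {
    arg <- 1 - 4 * p / 3
    if (arg <= 0) NA_real_ else -3 / 4 * log(arg)
  }
  dS <- jc(pS); dN <- jc(pN)
  estimable <- !is.na(dS) && !is.na(dN)
  # omega undefined without synonymous signal (dS = 0) or under saturation
  dn_ds <- if (estimable && dS > 0) dN / dS else NA_real_
  tibble::tibble(S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
                 dS = dS, dN = dN, dn_ds = dn_ds, estimable = estimable)
}
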