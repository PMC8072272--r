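# Universal genetic code machinery shared by the rate matrix, the counting
# estimator and the simulator. All state indexing is over the 61 sense codons
# in alphabetical (A < C < G < T) order.

.repevol_cache <- new.env(parent = emptyenv())

NUCS <- c("A", "C", "G", "T")

#' Sense codons of the universal genetic code
#'
#' @return Character vector of the 61 sense codons (stops TAA, TAG, TGA
#'   excluded), in alphabetical order. This ordering defines the state space
#'   of every rate matrix and alignment in the package.
#' @export
sense_codons <- function() {
  if (is.null(.repevol_cache$codons)) {
    all64 <- apply(expand.grid(NUCS, NUCS, NUCS)[, 3:1], 1, paste0, collapse = "")
    all64 <- sort(all64)
    gc <- Biostrings::GENETIC_CODE
    .repevol_cache$codons <- all64[gc[all64] != "*"]
    .repevol_cache$aa <- unname(gc[.repevol_cache$codons])
  }
  .repevol_cache$codons
}

#' Amino acids encoded by the sense codons
#'
#' @return Character vector of one-letter amino acids aligned with
#'   [sense_codons()].
#' @export
codon_amino_acids <- function() {
  sense_codons()
  .repevol_cache$aa
}

is_transition <- function(a, b) {
  (a == "A" & b == "G") | (a == "G" & b == "A") |
    (a == "C" & b == "T") | (a == "T" & b == "C")
}

# 61 x 61 integer matrix classifying single-nucleotide codon pairs:
# 0 = not reachable by one nucleotide change, 1 = synonymous transversion,
# 2 = synonymous transition, 3 = nonsynonymous transversion,
# 4 = nonsynonymous transition.
codon_pair_type <- function() {
  if (!is.null(.repevol_cache$pair_type)) return(.repevol_cache$pair_type)
  codons <- sense_codons()
  aa <- codon_amino_acids()
  n <- length(codons)
  split_mat <- do.call(rbind, strsplit(codons, ""))
  type <- matrix(0L, n, n, dimnames = list(codons, codons))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      diff <- which(split_mat[i, ] != split_mat[j, ])
      if (length(diff) != 1L) next
      ts <- is_transition(split_mat[i, diff], split_mat[j, diff])
      syn <- aa[i] == aa[j]
      type[i, j] <- if (syn && !ts) 1L else if (syn && ts) 2L
                    else if (!syn && !ts) 3L else 4L
    }
  }
  .repevol_cache$pair_type <- type
  type
}

codon_index <- function(codon_vec) {
  idx <- match(codon_vec, sense_codons())
  if (anyNA(idx)) {
    bad <- unique(codon_vec[is.na(idx)])
    stop("unrecognized codon(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  idx
}

split_codons <- function(seq) {
  n <- nchar(seq)
  if (n %% 3L != 0L) stop("sequence length not a multiple of 3", call. = FALSE)
  substring(seq, seq(1L, n, 3L), seq(3L, n, 3L))
}
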