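# Codon alignments: construction, FASTA input with cleaning, and
# class-wise concatenation.

MIN_ALIGNMENT_BP <- 200L  # loci must be strictly longer after cleaning

#' Construct a codon alignment
#'
#' A codon alignment holds in-frame, gap-free coding sequence for the four
#' taxa of the fixed tree, stored as codon-index columns over the 61 sense
#' codons.
#'
#' @param sequences Named character vector of 4 nucleotide sequences (equal
#'   length, multiple of 3, sense codons only).
#' @param locus_id Identifier carried through all downstream tables.
#' @param check_length Enforce the minimum-length filter (alignment strictly
#'   longer than 200 bp)? Disable for toy alignments in unit checks.
#' @return An object of class `codon_alignment` with fields `locus_id`,
#'   `taxa`, `idx` (61-state integer matrix, taxa x codon columns) and
#'   `n_codons`.
#' @export
codon_alignment <- function(sequences, locus_id = "locus", check_length = FALSE) {
  if (length(sequences) != 4L) {
    stop("codon alignment requires exactly 4 sequences, got ", length(sequences),
         call. = FALSE)
  }
  if (is.null(names(sequences)) || anyDuplicated(names(sequences))) {
    stop("sequences must carry unique taxon names", call. = FALSE)
  }
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L) {
    stop("sequences have unequal lengths in locus ", locus_id, call. = FALSE)
  }
  codon_rows <- lapply(toupper(sequences), split_codons)
  idx <- do.call(rbind, lapply(seq_along(codon_rows), function(i) {
    tryCatch(codon_index(codon_rows[[i]]),
             error = function(e) stop("locus ", locus_id, ", taxon ",
                                      names(sequences)[i], ": ", conditionMessage(e),
                                      call. = FALSE))
  }))
  rownames(idx) <- names(sequences)
  n_codons <- ncol(idx)
  if (check_length && n_codons * 3L <= MIN_ALIGNMENT_BP) {
    stop("locus ", locus_id, ": alignment length ", n_codons * 3L,
         " bp is not longer than ", MIN_ALIGNMENT_BP, " bp after cleaning",
         call. = FALSE)
  }
  structure(
    list(locus_id = locus_id, taxa = names(sequences), idx = idx,
         n_codons = n_codons),
    class = "codon_alignment"
  )
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("<codon_alignment> ", x$locus_id, ": ", x$n_codons, " codons, taxa: ",
      paste(x$taxa, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Read and clean a per-locus codon alignment from FASTA
#'
#' Reads a 4-record in-frame FASTA, drops every codon column containing a
#' gap, a stop codon or an ambiguity code in any taxon, and enforces the
#' minimum-length filter (cleaned alignment strictly longer than 200 bp).
#'
#' @param path Path to a FASTA file with exactly 4 records.
#' @param locus_id Locus identifier; defaults to the file name without
#'   extension.
#' @param check_length Enforce the 200 bp filter (default `TRUE`).
#' @return A [codon_alignment()]; the number of dropped codon columns is
#'   attached as attribute `"n_dropped"`.
#' @export
read_alignment_fasta <- function(path, locus_id = NULL, check_length = TRUE) {
  if (is.null(locus_id)) locus_id <- sub("\\.[^.]*$", "", basename(path))
  recs <- Biostrings::readBStringSet(path)
  if (length(recs) != 4L) {
    stop("locus ", locus_id, ": expected 4 FASTA records, found ", length(recs),
         call. = FALSE)
  }
  seqs <- toupper(as.character(recs))
  names(seqs) <- sub("\\s.*$", "", names(recs))
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    stop("locus ", locus_id, ": FASTA records have unequal lengths", call. = FALSE)
  }
  if (unique(lens) %% 3L != 0L) {
    stop("locus ", locus_id, ": alignment length ", unique(lens),
         " is not a multiple of 3", call. = FALSE)
  }
  codon_rows <- do.call(rbind, lapply(seqs, split_codons))
  ok_codon <- matrix(codon_rows %in% sense_codons(), nrow = nrow(codon_rows))
  keep <- apply(ok_codon, 2, all)
  n_dropped <- sum(!keep)
  clean <- apply(codon_rows[, keep, drop = FALSE], 1, paste0, collapse = "")
  names(clean) <- names(seqs)
  if (check_length && sum(keep) * 3L <= MIN_ALIGNMENT_BP) {
    stop("locus ", locus_id, ": ", sum(keep) * 3L,
         " bp after removing gap/stop/ambiguous columns; loci must be longer than ",
         MIN_ALIGNMENT_BP, " bp", call. = FALSE)
  }
  aln <- codon_alignment(clean, locus_id = locus_id, check_length = FALSE)
  attr(aln, "n_dropped") <- n_dropped
  aln
}

#' Read a batch of locus alignments from a manifest
#'
#' @param manifest Path to a TSV with columns `locus_id` and `path`
#'   (relative paths resolved against the manifest's directory).
#' @param check_length Enforce the 200 bp filter per locus; loci failing it
#'   are dropped with a message rather than aborting the batch.
#' @return Named list of [codon_alignment()] objects.
#' @export
read_alignment_batch <- function(manifest, check_length = TRUE) {
  man <- utils::read.delim(manifest, stringsAsFactors = FALSE)
  stopifnot(all(c("locus_id", "path") %in% names(man)))
  base <- dirname(manifest)
  out <- list()
  dropped <- character()
  for (i in seq_len(nrow(man))) {
    p <- man$path[i]
    if (!file.exists(p)) p <- file.path(base, man$path[i])
    aln <- tryCatch(
      read_alignment_fasta(p, locus_id = man$locus_id[i], check_length = check_length),
      error = function(e) {
        dropped <<- c(dropped, paste0(man$locus_id[i], " (", conditionMessage(e), ")"))
        NULL
      })
    if (!is.null(aln)) out[[man$locus_id[i]]] <- aln
  }
  if (length(dropped)) {
    message(length(dropped), " locus/loci dropped during input: ",
            paste(utils::head(dropped, 5), collapse = "; "),
            if (length(dropped) > 5) " ..." else "")
  }
  out
}

#' Concatenate locus alignments column-wise
#'
#' Joins loci of one gene class into a single alignment for concatenated
#' branch-model fits; locus boundaries are recorded so per-locus provenance
#' survives.
#'
#' @param alignments List of [codon_alignment()] objects sharing one taxon set.
#' @param gene_ids Optional subset (character vector of locus ids) selecting
#'   and ordering the loci to concatenate; default keeps the stable input
#'   order of `alignments`.
#' @param id Identifier for the concatenated alignment.
#' @return A [codon_alignment()] with attribute `"boundaries"` (tibble of
#'   locus_id, start and end codon column).
#' @export
concatenate_class <- function(alignments, gene_ids = NULL, id = "concat") {
  if (!is.null(gene_ids)) {
    ids <- vapply(alignments, function(a) a$locus_id, character(1))
    miss <- setdiff(gene_ids, ids)
    if (length(miss)) stop("loci not found: ", paste(miss, collapse = ", "), call. = FALSE)
    alignments <- alignments[match(gene_ids, ids)]
  }
  if (!length(alignments)) stop("no alignments to concatenate", call. = FALSE)
  taxa <- alignments[[1]]$taxa
  for (a in alignments) {
    if (!setequal(a$taxa, taxa)) {
      stop("taxon set mismatch in locus ", a$locus_id, call. = FALSE)
    }
  }
  idx <- do.call(cbind, lapply(alignments, function(a) a$idx[taxa, , drop = FALSE]))
  ends <- cumsum(vapply(alignments, function(a) a$n_codons, integer(1)))
  bounds <- tibble::tibble(
    locus_id = vapply(alignments, function(a) a$locus_id, character(1)),
    start = c(1L, utils::head(ends, -1L) + 1L),
    end = ends
  )
  out <- structure(
    list(locus_id = id, taxa = taxa, idx = idx, n_codons = ncol(idx)),
    class = "codon_alignment"
  )
  attr(out, "boundaries") <- bounds
  out
}

# Collapse an alignment to unique site patterns with multiplicities;
# the likelihood engine works on patterns, not raw columns.
site_patterns <- function(aln) {
  key <- apply(aln$idx, 2, paste, collapse = ".")
  tab <- table(key)
  first <- match(names(tab), key)
  list(
    patterns = aln$idx[, first, drop = FALSE],
    weights = as.numeric(tab)
  )
}
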