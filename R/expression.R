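# Expression quantification and rule-based gene classification.
#
# The atlas covers 8 tissues in up to 4 species; classification votes are
# cast per species (both the expression and the trace condition are
# evaluated within the same species) and a label needs agreement from at
# least 2 of the 3 fully sampled voting species.

REPRODUCTIVE_TISSUES <- c("style", "pollen", "ovule")
VEGETATIVE_TISSUES <- c("leaf", "root", "stem", "seed", "meristem")
CLASSIFICATION_TISSUES <- c(VEGETATIVE_TISSUES, REPRODUCTIVE_TISSUES)
GAMETOPHYTIC_TISSUES <- c("pollen", "ovule")
SPOROPHYTIC_TISSUES <- c("leaf", "root", "stem", "seed", "meristem", "style")
VOTING_SPECIES <- c("lycopersicum", "pennellii", "habrochaites")

TPM_EXPRESSED <- 2    # a gene counts as expressed above this
TPM_TRACE <- 0.5      # and as absent/trace below this

#' TPM-normalize a count table
#'
#' Transcripts per million: counts are divided by gene length (length-
#' normalized abundance) and scaled so each library sums to one million.
#'
#' @param counts Data frame with columns `gene_id`, `length` (bp) and one
#'   numeric column per library.
#' @return Tibble of the same shape with TPM values in the library columns.
#' @export
tpm_normalize <- function(counts) {
  counts <- tibble::as_tibble(counts)
  stopifnot(all(c("gene_id", "length") %in% names(counts)))
  if (any(counts$length <= 0)) stop("gene lengths must be positive", call. = FALSE)
  libs <- setdiff(names(counts), c("gene_id", "length"))
  out <- counts
  for (lib in libs) {
    rate <- counts[[lib]] / counts$length
    tot <- sum(rate)
    if (tot <= 0) stop("library ", lib, " has no mapped reads", call. = FALSE)
    out[[lib]] <- 1e6 * rate / tot
  }
  out
}

#' Replicate-averaged expression profile
#'
#' Averages per-library TPM across replicates within each species x tissue.
#' Species x tissue combinations absent from the metadata stay absent (the
#' availability mask); they are never imputed and never vote downstream.
#'
#' @param tpm Output of [tpm_normalize()].
#' @param metadata Data frame with columns `library_id`, `species`, `tissue`,
#'   `replicate`; `library_id` values must match the library columns of `tpm`.
#' @return Long tibble: `gene_id`, `species`, `tissue`, `mean_tpm`, `n_reps`.
#' @export
tissue_means <- function(tpm, metadata) {
  metadata <- tibble::as_tibble(metadata)
  stopifnot(all(c("library_id", "species", "tissue") %in% names(metadata)))
  libs <- setdiff(names(tpm), c("gene_id", "length"))
  miss <- setdiff(metadata$library_id, libs)
  if (length(miss)) {
    stop("metadata names libraries absent from the TPM table: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  tpm |>
    dplyr::select(-dplyr::any_of("length")) |>
    tidyr::pivot_longer(-"gene_id", names_to = "library_id", values_to = "tpm") |>
    dplyr::inner_join(metadata, by = "library_id") |>
    dplyr::group_by(.data$gene_id, .data$species, .data$tissue) |>
    dplyr::summarise(mean_tpm = mean(.data$tpm), n_reps = dplyr::n(),
                     .groups = "drop")
}

# per-gene x species helper: named TPM vector over available tissues
profile_split <- function(profile, species_keep = NULL, tissues_keep = CLASSIFICATION_TISSUES) {
  profile <- dplyr::filter(profile, .data$tissue %in% tissues_keep)
  if (!is.null(species_keep)) {
    profile <- dplyr::filter(profile, .data$species %in% species_keep)
  }
  profile
}

# Generic 2-of-k species vote over a two-way tissue partition.
# For each species: vote "A" iff max TPM over set_a > expressed AND all TPM
# over set_b < trace; vote "B" mirrored; vote "BOTH" iff both sets have a
# tissue > expressed. Missing tissues are simply absent from the vote.
vote_partition <- function(profile, set_a, set_b, voting_species,
                           labels = c("A", "B", "BOTH", "UNCLASSIFIED"),
                           expressed = TPM_EXPRESSED, trace = TPM_TRACE) {
  prof <- profile_split(profile, voting_species, c(set_a, set_b))
  votes <- prof |>
    dplyr::mutate(in_a = .data$tissue %in% set_a) |>
    dplyr::group_by(.data$gene_id, .data$species) |>
    dplyr::summarise(
      a_on = any(.data$in_a & .data$mean_tpm > expressed),
      a_all_off = all(!.data$in_a | .data$mean_tpm < trace),
      b_on = any(!.data$in_a & .data$mean_tpm > expressed),
      b_all_off = all(.data$in_a | .data$mean_tpm < trace),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      vote = dplyr::case_when(
        a_on & b_all_off ~ labels[1],
        b_on & a_all_off ~ labels[2],
        a_on & b_on ~ labels[3],
        TRUE ~ NA_character_
      )
    )
  votes |>
    dplyr::filter(!is.na(.data$vote)) |>
    dplyr::count(.data$gene_id, .data$vote) |>
    dplyr::filter(.data$n >= 2L) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::slice_max(.data$n, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select("gene_id", "vote") |>
    dplyr::right_join(tibble::tibble(gene_id = unique(profile$gene_id)),
                      by = "gene_id") |>
    dplyr::mutate(vote = dplyr::coalesce(.data$vote, labels[4]))
}

#' Broad expression class: reproductive, vegetative or general
#'
#' A species casts an RP vote when at least one reproductive tissue (style,
#' pollen, ovule) exceeds 2 TPM and every vegetative tissue is below 0.5 TPM;
#' a VG vote is the mirror image; a GR vote when both a reproductive and a
#' vegetative tissue exceed 2 TPM. A gene is labeled when at least two of the
#' three voting species agree, otherwise `UNCLASSIFIED`.
#'
#' @param profile Long profile from [tissue_means()].
#' @param voting_species The species with complete tissue panels (default the
#'   three fully sampled ones).
#' @param expressed,trace TPM thresholds for expression and absence
#'   (defaults 2 and 0.5).
#' @return Tibble `gene_id`, `broad`.
#' @export
classify_broad <- function(profile, voting_species = VOTING_SPECIES,
                           expressed = TPM_EXPRESSED, trace = TPM_TRACE) {
  vote_partition(profile, REPRODUCTIVE_TISSUES, VEGETATIVE_TISSUES,
                 voting_species, labels = c("RP", "VG", "GR", "UNCLASSIFIED"),
                 expressed = expressed, trace = trace) |>
    dplyr::rename(broad = "vote")
}

#' Tissue-specific classification
#'
#' A species votes for a focal tissue when that tissue exceeds 2 TPM and all
#' seven remaining classification tissues are below 0.5 TPM; a tissue label
#' is assigned on agreement of at least two voting species, otherwise `NA`.
#'
#' @inheritParams classify_broad
#' @return Tibble `gene_id`, `tissue_specific` (`NA` when no tissue wins).
#' @export
classify_tissue_specific <- function(profile, voting_species = VOTING_SPECIES,
                                     expressed = TPM_EXPRESSED,
                                     trace = TPM_TRACE) {
  prof <- profile_split(profile, voting_species)
  votes <- prof |>
    dplyr::group_by(.data$gene_id, .data$species) |>
    dplyr::summarise(
      n_on = sum(.data$mean_tpm > expressed),
      n_mid = sum(.data$mean_tpm >= trace & .data$mean_tpm <= expressed),
      focal = if (sum(.data$mean_tpm > expressed) == 1L)
        .data$tissue[which.max(.data$mean_tpm)] else NA_character_,
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_on == 1L, .data$n_mid == 0L, !is.na(.data$focal))
  winners <- votes |>
    dplyr::count(.data$gene_id, .data$focal) |>
    dplyr::filter(.data$n >= 2L) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::slice_max(.data$n, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  tibble::tibble(gene_id = unique(profile$gene_id)) |>
    dplyr::left_join(dplyr::select(winners, "gene_id", tissue_specific = "focal"),
                     by = "gene_id")
}

#' Gametophytic/sporophytic (ploidy) classification
#'
#' Applies the broad-class voting rules to the haploid/diploid tissue
#' partition: gametophytic = pollen and ovule, sporophytic = the six diploid
#' tissues (style included). Also labels ovule and pollen loci as
#' tissue-exclusive versus shared with at least one sporophytic tissue.
#'
#' @inheritParams classify_broad
#' @return Tibble `gene_id`, `ploidy` (GAMETOPHYTIC_ONLY, SPOROPHYTIC_ONLY,
#'   GAM_PLUS_SPORO, UNCLASSIFIED), `ovule_class`, `pollen_class`
#'   (TISSUE_ONLY, TISSUE_PLUS_SPORO or NA).
#' @export
classify_ploidy <- function(profile, voting_species = VOTING_SPECIES,
                            expressed = TPM_EXPRESSED, trace = TPM_TRACE) {
  ploidy <- vote_partition(
    profile, GAMETOPHYTIC_TISSUES, SPOROPHYTIC_TISSUES, voting_species,
    labels = c("GAMETOPHYTIC_ONLY", "SPOROPHYTIC_ONLY", "GAM_PLUS_SPORO",
               "UNCLASSIFIED"),
    expressed = expressed, trace = trace) |>
    dplyr::rename(ploidy = "vote")

  gam_tissue_class <- function(focal) {
    others <- setdiff(CLASSIFICATION_TISSUES, focal)
    prof <- profile_split(profile, voting_species)
    votes <- prof |>
      dplyr::group_by(.data$gene_id, .data$species) |>
      dplyr::summarise(
        focal_on = any(.data$tissue == focal & .data$mean_tpm > expressed),
        others_off = all(.data$tissue == focal | .data$mean_tpm < trace),
        sporo_on = any(.data$tissue %in% SPOROPHYTIC_TISSUES &
                         .data$mean_tpm > expressed),
        .groups = "drop"
      ) |>
      dplyr::mutate(vote = dplyr::case_when(
        focal_on & others_off ~ "TISSUE_ONLY",
        focal_on & sporo_on ~ "TISSUE_PLUS_SPORO",
        TRUE ~ NA_character_
      )) |>
      dplyr::filter(!is.na(.data$vote)) |>
      dplyr::count(.data$gene_id, .data$vote) |>
      dplyr::filter(.data$n >= 2L) |>
      dplyr::group_by(.data$gene_id) |>
      dplyr::slice_max(.data$n, n = 1, with_ties = FALSE) |>
      dplyr::ungroup() |>
      dplyr::select("gene_id", "vote")
    votes
  }
  ov <- gam_tissue_class("ovule") |> dplyr::rename(ovule_class = "vote")
  po <- gam_tissue_class("pollen") |> dplyr::rename(pollen_class = "vote")
  ploidy |>
    dplyr::left_join(ov, by = "gene_id") |>
    dplyr::left_join(po, by = "gene_id")
}

#' Breadth of expression (number of tissues, 0-8)
#'
#' Counts the classification tissues in which a gene exceeds 2 TPM in every
#' species that has data for that tissue (so a tissue missing from one
#' species is judged over the remaining species only).
#'
#' @param profile Long profile from [tissue_means()].
#' @return Tibble `gene_id`, `breadth` (integer 0-8).
#' @export
expression_breadth <- function(profile, expressed = TPM_EXPRESSED) {
  profile_split(profile) |>
    dplyr::group_by(.data$gene_id, .data$tissue) |>
    dplyr::summarise(on_everywhere = all(.data$mean_tpm > expressed),
                     .groups = "drop") |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(breadth = as.integer(sum(.data$on_everywhere)),
                     .groups = "drop")
}

#' Mean expression over the expressed domain
#'
#' Mean TPM across all species x tissue cells in which the gene is expressed
#' (> 2 TPM); 0 when the gene is expressed nowhere by that criterion.
#'
#' @param profile Long profile from [tissue_means()].
#' @return Tibble `gene_id`, `mean_expr`.
#' @export
mean_expression <- function(profile, expressed = TPM_EXPRESSED) {
  profile_split(profile) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      mean_expr = {
        on <- .data$mean_tpm[.data$mean_tpm > expressed]
        if (length(on)) mean(on) else 0
      },
      .groups = "drop")
}

#' Full gene classification table
#'
#' Runs every classification rule over one expression profile and joins the
#' results into the per-gene table consumed by the comparison layer.
#'
#' @inheritParams classify_broad
#' @return Tibble: `gene_id`, `broad`, `tissue_specific`, `ploidy`,
#'   `ovule_class`, `pollen_class`, `breadth`, `mean_expr`.
#' @export
classify_genes <- function(profile, voting_species = VOTING_SPECIES,
                           expressed = TPM_EXPRESSED, trace = TPM_TRACE) {
  classify_broad(profile, voting_species, expressed, trace) |>
    dplyr::left_join(classify_tissue_specific(profile, voting_species,
                                              expressed, trace),
                     by = "gene_id") |>
    dplyr::left_join(classify_ploidy(profile, voting_species, expressed, trace),
                     by = "gene_id") |>
    dplyr::left_join(expression_breadth(profile, expressed), by = "gene_id") |>
    dplyr::left_join(mean_expression(profile, expressed), by = "gene_id")
}
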