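# The fixed unrooted 4-taxon tree with mating-system branch labels.

BRANCH_CLASSES <- c("SC", "SI", "INTERNAL")

#' Construct the labeled four-taxon tree
#'
#' The topology is fixed at ((A,B),(C,D)) with A, B the self-compatible (SC)
#' tips and C, D the self-incompatible (SI) tips, plus one internal branch.
#' Branch lengths are expected substitutions per codon.
#'
#' @param taxa Character vector of 4 taxon names in the order (A, B, C, D).
#' @param lengths Numeric vector of 5 non-negative branch lengths in the
#'   order (tip A, tip B, tip C, tip D, internal).
#' @param classes Branch class labels, default `c("SC","SC","SI","SI","INTERNAL")`.
#' @return Object of class `labeled_tree`: a list with `taxa` and a tibble
#'   `branches` (branch, class, length).
#' @export
labeled_tree <- function(taxa,
                         lengths = c(0.002, 0.002, 0.02, 0.02, 0.01),
                         classes = c("SC", "SC", "SI", "SI", "INTERNAL")) {
  stopifnot(length(taxa) == 4L, length(lengths) == 5L, length(classes) == 5L)
  if (any(lengths < 0)) stop("branch lengths must be non-negative", call. = FALSE)
  if (!all(classes %in% BRANCH_CLASSES)) {
    stop("branch classes must be among ", paste(BRANCH_CLASSES, collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(
      taxa = taxa,
      branches = tibble::tibble(
        branch = c(taxa, "internal"),
        class = classes,
        length = as.numeric(lengths)
      )
    ),
    class = "labeled_tree"
  )
}

#' Default Solanum study tree
#'
#' Topology ((lycopersicum, pimpinellifolium), (pennellii, habrochaites)):
#' the two self-compatible species are sisters, as are the two
#' self-incompatible species. Default lengths echo the strong branch-length
#' asymmetry of the system (short SC tips, long SI tips); they are
#' illustrative starting values, not estimates.
#'
#' @param lengths Optional branch lengths (tip A, B, C, D, internal).
#' @return A [labeled_tree()].
#' @export
solanum_tree <- function(lengths = c(0.002, 0.002, 0.02, 0.02, 0.01)) {
  labeled_tree(
    taxa = c("lycopersicum", "pimpinellifolium", "pennellii", "habrochaites"),
    lengths = lengths
  )
}

#' @export
print.labeled_tree <- function(x, ...) {
  cat("<labeled_tree> ((", x$taxa[1], ",", x$taxa[2], "),(", x$taxa[3], ",",
      x$taxa[4], "))\n", sep = "")
  print(x$branches)
  invisible(x)
}

# omega value for every branch given a scheme-resolved class->omega map
branch_omegas <- function(tree, omega_by_class) {
  cls <- tree$branches$class
  miss <- setdiff(unique(cls), names(omega_by_class))
  if (length(miss)) {
    stop("no omega supplied for branch class(es): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  unname(unlist(omega_by_class[cls]))
}

# Map the branch-model scheme onto per-branch omega-parameter indices.
# M0: one shared omega; TWO_RATIO: {SC} and {SI+INTERNAL};
# THREE_RATIO: {SC}, {SI}, {INTERNAL}.
scheme_class_map <- function(scheme) {
  switch(scheme,
    M0 = c(SC = 1L, SI = 1L, INTERNAL = 1L),
    TWO_RATIO = c(SC = 1L, SI = 2L, INTERNAL = 2L),
    THREE_RATIO = c(SC = 1L, SI = 2L, INTERNAL = 3L),
    stop("unknown scheme: ", scheme, call. = FALSE)
  )
}

scheme_omega_names <- function(scheme) {
  switch(scheme,
    M0 = "omega",
    TWO_RATIO = c("omega_SC", "omega_SI_internal"),
    THREE_RATIO = c("omega_SC", "omega_SI", "omega_internal")
  )
}
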