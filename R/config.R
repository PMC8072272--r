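# Pipeline configuration: one object carrying the fixed facts of the study
# design (species and mating-system labels, tissue categories) and every
# tunable threshold, with a lossless YAML round trip.

#' Pipeline configuration
#'
#' @param species The 4 taxa in tree order (A, B, C, D) with A, B the
#'   self-compatible pair.
#' @param tree_lengths Starting branch lengths for the labeled tree
#'   (tip A, B, C, D, internal), expected substitutions per codon.
#' @param reproductive_tissues,vegetative_tissues Tissue category map for
#'   the broad classification.
#' @param voting_species Species with complete tissue panels that cast
#'   classification votes.
#' @param tpm_expressed,tpm_trace Expression thresholds (TPM); a gene counts
#'   as expressed above the first and absent below the second.
#' @param min_alignment_bp Loci must be strictly longer than this after
#'   cleaning.
#' @param max_omega Per-locus dN/dS above this is treated as an estimation
#'   artifact and excluded from comparisons.
#' @param n_boot_reps,boot_sample_size,boot_replace Bootstrap-null settings
#'   (`boot_sample_size = NULL` scales to the available loci).
#' @param seed Seed fanned out deterministically to the stochastic stages.
#' @return Object of class `pipeline_config` (a validated named list).
#' @export
pipeline_config <- function(species = c("lycopersicum", "pimpinellifolium",
                                        "pennellii", "habrochaites"),
                            tree_lengths = c(0.002, 0.002, 0.02, 0.02, 0.01),
                            reproductive_tissues = REPRODUCTIVE_TISSUES,
                            vegetative_tissues = VEGETATIVE_TISSUES,
                            voting_species = VOTING_SPECIES,
                            tpm_expressed = 2,
                            tpm_trace = 0.5,
                            min_alignment_bp = 200,
                            max_omega = 10,
                            n_boot_reps = 1000,
                            boot_sample_size = NULL,
                            boot_replace = TRUE,
                            seed = 1) {
  cfg <- list(species = species, tree_lengths = as.numeric(tree_lengths),
              reproductive_tissues = reproductive_tissues,
              vegetative_tissues = vegetative_tissues,
              voting_species = voting_species,
              tpm_expressed = tpm_expressed, tpm_trace = tpm_trace,
              min_alignment_bp = as.integer(min_alignment_bp),
              max_omega = max_omega, n_boot_reps = as.integer(n_boot_reps),
              boot_sample_size = if (is.null(boot_sample_size)) NULL
                                 else as.integer(boot_sample_size),
              boot_replace = isTRUE(boot_replace), seed = as.integer(seed))
  validate_pipeline_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_pipeline_config <- function(cfg) {
  if (length(cfg$species) != 4L || anyDuplicated(cfg$species)) {
    stop("config must name 4 distinct species covering the topology",
         call. = FALSE)
  }
  if (!all(cfg$voting_species %in% cfg$species)) {
    stop("voting species must be among the study species", call. = FALSE)
  }
  if (length(cfg$tree_lengths) != 5L || any(cfg$tree_lengths < 0)) {
    stop("tree_lengths must be 5 non-negative branch lengths", call. = FALSE)
  }
  pos <- c(cfg$tpm_expressed, cfg$tpm_trace, cfg$min_alignment_bp,
           cfg$max_omega, cfg$n_boot_reps)
  if (any(pos <= 0)) stop("thresholds must be positive", call. = FALSE)
  if (cfg$tpm_trace >= cfg$tpm_expressed) {
    stop("tpm_trace must lie below tpm_expressed", call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config> ((", x$species[1], ",", x$species[2], "),(",
      x$species[3], ",", x$species[4], ")); TPM thresholds ",
      x$tpm_expressed, "/", x$tpm_trace, "; omega filter > ", x$max_omega,
      "; bootstrap ", x$n_boot_reps, " reps; seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Build the labeled tree a configuration describes
#'
#' @param config A [pipeline_config()].
#' @return A [labeled_tree()] with the configured species and lengths.
#' @export
config_tree <- function(config) {
  labeled_tree(config$species, config$tree_lengths)
}

#' Write / read a pipeline configuration (YAML)
#'
#' The round trip is lossless: `read_pipeline_config(write_pipeline_config(x))`
#' reproduces `x` exactly.
#'
#' @param config A [pipeline_config()].
#' @param path File path.
#' @return `write_pipeline_config()` returns `path` invisibly;
#'   `read_pipeline_config()` returns the validated [pipeline_config()].
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}
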