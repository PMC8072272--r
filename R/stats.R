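# The comparison layer: filtering, gamma GLM with identity link and
# single-step adjusted contrasts, exact/chi-square tests on dN/dS > 1
# proportions, summary tables and the expression-level regression.

#' Filter per-locus records for rate comparisons
#'
#' Drops loci with implausibly large dN/dS (> `max_omega`, an estimation
#' artifact of near-zero synonymous divergence), non-converged fits and
#' degenerate loci; the boundary value itself is retained (strict
#' inequality).
#'
#' @param records Tibble with at least `omega`; optional logical columns
#'   `converged` and `degenerate` are honored when present.
#' @param max_omega Exclusion threshold (default 10).
#' @param quiet Suppress the per-reason drop counts message.
#' @return Filtered tibble; drop counts attached as attribute `"dropped"`.
#' @export
filter_records <- function(records, max_omega = 10, quiet = FALSE) {
  records <- tibble::as_tibble(records)
  conv <- if ("converged" %in% names(records)) records$converged else TRUE
  degen <- if ("degenerate" %in% names(records)) records$degenerate else FALSE
  na_om <- is.na(records$omega)
  high <- !na_om & records$omega > max_omega
  drop <- high | !conv | degen | na_om
  dropped <- c(high_omega = sum(high), not_converged = sum(!conv),
               degenerate = sum(degen), missing_omega = sum(na_om & !degen))
  if (!quiet && any(drop)) {
    message("filter_records: dropped ", sum(drop), " of ", nrow(records),
            " loci (omega>", max_omega, ": ", dropped[["high_omega"]],
            ", not converged: ", dropped[["not_converged"]],
            ", degenerate: ", dropped[["degenerate"]], ")")
  }
  out <- records[!drop, , drop = FALSE]
  attr(out, "dropped") <- dropped
  out
}

#' Gamma GLM with identity link on per-locus dN/dS
#'
#' Fits `omega ~ class` by maximum likelihood with gamma errors and an
#' identity link. Gamma support excludes zero, but counting/ML estimates can
#' be exactly zero; zeros are replaced by half the smallest positive omega
#' (recorded on the fit) before fitting.
#'
#' @param records Tibble with `omega` and the grouping column.
#' @param class_col Name of the grouping column (default `"broad"`).
#' @param formula Optional model formula overriding `omega ~ class`.
#' @return Object of class `gamma_glm` wrapping the underlying [stats::glm()]
#'   fit; supports [tidy()], [glance()] and [pairwise_contrasts()].
#' @export
gamma_glm_identity <- function(records, class_col = "broad", formula = NULL) {
  records <- tibble::as_tibble(records)
  stopifnot("omega" %in% names(records))
  if (any(records$omega < 0, na.rm = TRUE)) {
    stop("negative omega values; filter records first", call. = FALSE)
  }
  n_zero <- sum(records$omega == 0, na.rm = TRUE)
  zero_sub <- NA_real_
  if (n_zero > 0) {
    zero_sub <- min(records$omega[records$omega > 0]) / 2
    records$omega[records$omega == 0] <- zero_sub
  }
  records[[class_col]] <- factor(records[[class_col]])
  if (is.null(formula)) {
    formula <- stats::as.formula(paste("omega ~", class_col))
  }
  # group means are safe identity-link starting values
  mf <- stats::model.frame(formula, records)
  X <- stats::model.matrix(formula, mf)
  mu0 <- tapply(records$omega, records[[class_col]], mean)
  beta0 <- tryCatch(
    stats::coef(stats::lm.fit(X, stats::model.response(mf))),
    error = function(e) NULL)
  fit <- stats::glm(formula, data = records,
                    family = stats::Gamma(link = "identity"),
                    start = beta0, control = stats::glm.control(maxit = 100))
  if (!fit$converged) stop("gamma GLM did not converge", call. = FALSE)
  structure(
    list(fit = fit, class_col = class_col, n_zero = n_zero,
         zero_substitute = zero_sub),
    class = "gamma_glm"
  )
}

#' @export
print.gamma_glm <- function(x, ...) {
  cat("<gamma_glm> identity link,", length(stats::coef(x$fit)), "coefficients")
  if (x$n_zero > 0) {
    cat("; ", x$n_zero, " zero(s) replaced by ", signif(x$zero_substitute, 3), sep = "")
  }
  cat("\n")
  print(stats::coef(x$fit))
  invisible(x)
}

#' @export
tidy.gamma_glm <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(s), estimate = s[, 1], std.error = s[, 2],
                 statistic = s[, 3], p.value = s[, 4])
}

#' @export
glance.gamma_glm <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(
    df.residual = x$fit$df.residual,
    dispersion = s$dispersion,
    deviance = x$fit$deviance,
    AIC = stats::AIC(x$fit),
    n_zero_substituted = x$n_zero
  )
}

#' Single-step adjusted pairwise contrasts
#'
#' All pairwise differences between group means from a [gamma_glm_identity()]
#' fit, with p-values adjusted by the single-step method: each raw z
#' statistic is referred to the maximum-modulus distribution of the jointly
#' normal contrast vector (the adjustment behind Tukey-style post hoc tests
#' on GLMs). A compact letter display summarizes the adjusted tests at
#' `alpha`.
#'
#' @param model A `gamma_glm` fit.
#' @param alpha Significance level for the letter display (default 0.05).
#' @return Object of class `contrast_table`: tibble of contrasts
#'   (`contrast`, `estimate`, `se`, `statistic`, `p_raw`, `p_adj`) with the
#'   per-group letters in attribute `"letters"` (also `$letters`).
#' @export
pairwise_contrasts <- function(model, alpha = 0.05) {
  stopifnot(inherits(model, "gamma_glm"))
  # the max-modulus integral is randomized quasi-Monte Carlo; pin its seed
  # locally so contrast tables are reproducible call-to-call
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)
  set.seed(20260920)
  gl <- multcomp::glht(model$fit, linfct = do.call(multcomp::mcp,
                        stats::setNames(list("Tukey"), model$class_col)))
  ss <- summary(gl, test = multcomp::adjusted("single-step"))
  raw <- summary(gl, test = multcomp::adjusted("none"))
  tab <- tibble::tibble(
    contrast = names(ss$test$coefficients),
    estimate = unname(ss$test$coefficients),
    se = unname(ss$test$sigma),
    statistic = unname(ss$test$tstat),
    p_raw = as.numeric(raw$test$pvalues),
    p_adj = pmax(as.numeric(ss$test$pvalues), as.numeric(raw$test$pvalues))
  )
  letters <- multcomp::cld(ss, level = alpha)$mcletters$Letters
  out <- list(contrasts = tab,
              letters = tibble::tibble(group = names(letters),
                                       letters = unname(letters)))
  class(out) <- "contrast_table"
  out
}

#' @export
print.contrast_table <- function(x, ...) {
  print(x$contrasts)
  cat("letters:", paste(x$letters$group, x$letters$letters, sep = "=",
                        collapse = "  "), "\n")
  invisible(x)
}

#' @export
tidy.contrast_table <- function(x, ...) x$contrasts

#' One-sided Fisher's exact test for enrichment of group 1
#'
#' Upper-tail hypergeometric probability of observing at least `k1` successes
#' in group 1 given the table margins — the one-sided exact test of whether
#' group 1 has a higher success proportion than group 2.
#'
#' @param k1,n1 Successes and total in the focal group.
#' @param k2,n2 Successes and total in the comparison group.
#' @return The one-sided p-value (numeric scalar).
#' @export
fisher_one_sided <- function(k1, n1, k2, n2) {
  stopifnot(k1 >= 0, k2 >= 0, n1 >= k1, n2 >= k2)
  tab <- matrix(c(k1, n1 - k1, k2, n2 - k2), nrow = 2, byrow = TRUE)
  stats::fisher.test(tab, alternative = "greater")$p.value
}

#' Pearson chi-square test of independence
#'
#' @param table A 2 x k matrix of counts (groups in columns or rows).
#' @param correct Apply Yates continuity correction (default `FALSE`).
#' @return One-row tibble: `statistic`, `df`, `p_value`.
#' @export
chi_square_independence <- function(table, correct = FALSE) {
  ct <- stats::chisq.test(table, correct = correct)
  tibble::tibble(statistic = unname(ct$statistic), df = unname(ct$parameter),
                 p_value = ct$p.value)
}

#' Per-class summary of dN/dS and the proportion above 1
#'
#' Reproduces the arithmetic of the headline tables: per group, the number
#' of loci, mean, standard error and median of omega, and the count and
#' proportion of loci with omega > 1.
#'
#' @param records Tibble with `omega` and grouping column(s).
#' @param grouping Character vector of grouping columns (default `"broad"`).
#' @return Tibble with one row per group: `n`, `mean`, `se`, `median`,
#'   `n_gt1`, `prop_gt1`.
#' @export
summarize_class <- function(records, grouping = "broad") {
  tibble::as_tibble(records) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grouping))) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$omega),
      se = stats::sd(.data$omega) / sqrt(dplyr::n()),
      median = stats::median(.data$omega),
      n_gt1 = sum(.data$omega > 1),
      prop_gt1 = sum(.data$omega > 1) / dplyr::n(),
      .groups = "drop"
    )
}

#' Expression-level regression on sqrt(dN/dS)
#'
#' Ordinary least squares of `sqrt(omega)` on mean expression level, broad
#' class and their interaction, reported as a sequential (type I) ANOVA
#' table plus per-class expression slopes with 95% confidence intervals.
#'
#' @param records Tibble with `omega`, `mean_expr` and the class column.
#' @param class_col Grouping column (default `"broad"`).
#' @return List of class `expression_regression`: `fit` (the `lm`), `anova`
#'   (tibble: term, df, sumsq, meansq, statistic, p_value) and `slopes`
#'   (tibble: class, slope, conf_low, conf_high).
#' @export
expression_regression <- function(records, class_col = "broad") {
  records <- tibble::as_tibble(records)
  stopifnot(all(c("omega", "mean_expr") %in% names(records)))
  records[[class_col]] <- factor(records[[class_col]])
  records$.sqrt_omega <- sqrt(records$omega)
  fml <- stats::as.formula(paste(".sqrt_omega ~ mean_expr *", class_col))
  fit <- stats::lm(fml, data = records)
  an <- stats::anova(fit)
  anova_tbl <- tibble::tibble(
    term = rownames(an), df = an$Df, sumsq = an$`Sum Sq`,
    meansq = an$`Mean Sq`, statistic = an$`F value`, p_value = an$`Pr(>F)`
  )
  tr <- emmeans::emtrends(fit, stats::as.formula(paste("~", class_col)),
                          var = "mean_expr")
  trs <- as.data.frame(tr)
  slopes <- tibble::tibble(
    class = as.character(trs[[1]]),
    slope = trs$mean_expr.trend,
    conf_low = trs$lower.CL,
    conf_high = trs$upper.CL
  )
  structure(list(fit = fit, anova = anova_tbl, slopes = slopes),
            class = "expression_regression")
}

#' @export
print.expression_regression <- function(x, ...) {
  cat("<expression_regression> sqrt(omega) ~ expression * class\n")
  print(x$anova)
  print(x$slopes)
  invisible(x)
}

#' @export
tidy.expression_regression <- function(x, ...) x$anova
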