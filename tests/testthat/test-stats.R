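test_that("record filtering drops artifacts with a strict threshold", {
  rec <- tibble::tibble(
    gene_id = letters[1:5],
    omega = c(12, 10, 0.5, 2, NA),
    converged = c(TRUE, TRUE, TRUE, FALSE, TRUE),
    degenerate = c(FALSE, FALSE, FALSE, FALSE, TRUE))
  out <- filter_records(rec, quiet = TRUE)
  expect_equal(out$gene_id, c("b", "c"))  # omega = 10 retained (strict >)
  expect_equal(unname(attr(out, "dropped")["high_omega"]), 1)
  # empty input passes through
  expect_equal(nrow(filter_records(rec[0, ], quiet = TRUE)), 0)
})

test_that("gamma GLM with identity link recovers group means", {
  set.seed(30)
  rec <- tibble::tibble(omega = rgamma(200, shape = 2, scale = 0.1),
                        broad = rep(c("A", "B"), each = 100))
  fit <- gamma_glm_identity(rec)
  cf <- stats::coef(fit$fit)
  means <- tapply(rec$omega, rec$broad, mean)
  # identity-link gamma ML: fitted group means equal sample means
  expect_equal(unname(cf[1]), unname(means["A"]), tolerance = 1e-8)
  expect_equal(unname(cf[1] + cf[2]), unname(means["B"]), tolerance = 1e-8)

  # zeros are shifted to half the smallest positive value before fitting
  rec0 <- rec; rec0$omega[1] <- 0
  fit0 <- gamma_glm_identity(rec0)
  expect_equal(fit0$n_zero, 1)
  expect_equal(fit0$zero_substitute, min(rec0$omega[rec0$omega > 0]) / 2)
  expect_error(gamma_glm_identity(dplyr::mutate(rec, omega = omega - 1)),
               "negative")
})

test_that("group differences are detected with gamma errors", {
  # two groups, gamma shape 2, means 0.2 vs 0.3: the contrast z-test should
  # reject at the 5% level in most replicates
  set.seed(31)
  hits <- 0
  for (i in 1:20) {
    rec <- tibble::tibble(
      omega = c(rgamma(500, 2, scale = 0.1), rgamma(500, 2, scale = 0.15)),
      broad = rep(c("A", "B"), each = 500))
    fit <- gamma_glm_identity(rec)
    p <- tidy(fit)$p.value[2]
    if (p < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 16)  # >= 80% power
})

test_that("single-step adjustment behaves at its boundaries", {
  set.seed(32)
  # two groups: one contrast, adjusted p equals raw p
  rec2 <- tibble::tibble(omega = rgamma(120, 2, scale = 0.1),
                         broad = rep(c("A", "B"), each = 60))
  pc2 <- pairwise_contrasts(gamma_glm_identity(rec2))
  expect_equal(pc2$contrasts$p_adj, pc2$contrasts$p_raw, tolerance = 1e-6)

  # three identical groups: all adjusted p near 1, one shared letter
  rec3 <- tibble::tibble(omega = rep(rgamma(50, 2, scale = 0.1), 3),
                         broad = rep(c("A", "B", "C"), each = 50))
  pc3 <- pairwise_contrasts(gamma_glm_identity(rec3))
  expect_true(all(pc3$contrasts$p_adj > 0.99))
  expect_equal(length(unique(pc3$letters$letters)), 1L)

  # adjusted never below raw; letters split when a contrast is significant
  set.seed(33)
  rec4 <- tibble::tibble(
    omega = c(rgamma(300, 2, scale = 0.1), rgamma(300, 2, scale = 0.25)),
    broad = rep(c("A", "B"), each = 300))
  pc4 <- pairwise_contrasts(gamma_glm_identity(rec4))
  expect_true(all(pc4$contrasts$p_adj >= pc4$contrasts$p_raw - 1e-12))
  expect_equal(length(unique(pc4$letters$letters)), 2L)
})

test_that("GLM contrast on two balanced groups matches the two-sample z-test", {
  set.seed(34)
  rec <- tibble::tibble(omega = rgamma(400, 2, scale = 0.12),
                        broad = rep(c("A", "B"), each = 200))
  fit <- gamma_glm_identity(rec)
  td <- tidy(fit)
  # z statistic from group means and the gamma dispersion estimate
  disp <- summary(fit$fit)$dispersion
  mA <- mean(rec$omega[rec$broad == "A"]); mB <- mean(rec$omega[rec$broad == "B"])
  se <- sqrt(disp * (mA^2 + mB^2) / 200)
  expect_equal(unname(abs(td$statistic[2])), abs(mB - mA) / se,
               tolerance = 1e-6)
})

test_that("one-sided Fisher test equals hypergeometric tail summation", {
  expect_equal(fisher_one_sided(0, 10, 0, 10), 1)
  # oracle: explicit summation over the hypergeometric pmf
  oracle <- function(k1, n1, k2, n2) {
    K <- k1 + k2
    ks <- max(0, K - n2):min(n1, K)
    p <- choose(n1, ks) * choose(n2, K - ks) / choose(n1 + n2, K)
    sum(p[ks >= k1])
  }
  set.seed(35)
  for (i in 1:25) {
    n1 <- sample(2:50, 1); n2 <- sample(2:50, 1)
    k1 <- sample(0:n1, 1); k2 <- sample(0:n2, 1)
    expect_equal(fisher_one_sided(k1, n1, k2, n2), oracle(k1, n1, k2, n2),
                 tolerance = 1e-12,
                 label = sprintf("%d/%d vs %d/%d", k1, n1, k2, n2))
  }
})

test_that("chi-square independence matches the hand formula", {
  tab <- matrix(c(10, 90, 50, 50), 2, byrow = TRUE)
  res <- chi_square_independence(tab)
  # Pearson statistic computed from first principles
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(res$statistic, sum((tab - E)^2 / E), tolerance = 1e-12)
  expect_equal(res$df, 1)
  # invariant to row order; near-identical proportions give p ~ 1
  expect_equal(chi_square_independence(tab[2:1, ])$p_value, res$p_value)
  even <- matrix(c(20, 80, 20, 80), 2, byrow = TRUE)
  expect_gt(chi_square_independence(even)$p_value, 0.99)
})

test_that("class summaries reproduce the headline-table arithmetic", {
  rec <- tibble::tibble(omega = c(0.5, 1.5), broad = "X")
  s <- summarize_class(rec)
  expect_equal(s$mean, 1.0)
  expect_equal(s$prop_gt1, 0.5)
  expect_equal(s$median, 1.0)
  expect_equal(s$se, stats::sd(c(0.5, 1.5)) / sqrt(2))
})

test_that("expression regression decomposes variance correctly", {
  set.seed(36)
  rec <- tibble::tibble(
    omega = rgamma(300, 2, scale = 0.1),
    mean_expr = runif(300, 0, 100),
    broad = sample(c("RP", "VG", "GR"), 300, replace = TRUE))
  er <- expression_regression(rec)
  # sequential sums of squares add to the total sum of squares
  tot <- sum((sqrt(rec$omega) - mean(sqrt(rec$omega)))^2)
  expect_equal(sum(er$anova$sumsq), tot, tolerance = 1e-8)
  expect_equal(nrow(er$slopes), 3L)

  # constant response: all effect sums of squares vanish (R warns about the
  # perfect fit, which is the point of the case)
  flat <- dplyr::mutate(rec, omega = 0.25)
  erf <- suppressWarnings(expression_regression(flat))
  expect_true(all(erf$anova$sumsq[1:3] < 1e-20))
})

test_that("per-class slopes are recovered from planted effects", {
  set.seed(37)
  n <- 1000
  expr <- runif(n, 0, 100)
  cls <- sample(c("GR", "RP"), n, replace = TRUE)
  slope <- ifelse(cls == "GR", -0.002, 0)
  sq <- 0.5 + slope * expr + rnorm(n, 0, 0.1)
  rec <- tibble::tibble(omega = pmax(sq, 0.01)^2, mean_expr = expr, broad = cls)
  er <- expression_regression(rec)
  gr <- er$slopes[er$slopes$class == "GR", ]
  rp <- er$slopes[er$slopes$class == "RP", ]
  expect_lt(gr$conf_high, 0)              # negative GR slope detected
  expect_true(rp$conf_low < 0 && rp$conf_high > 0)  # RP slope CI covers 0
})
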