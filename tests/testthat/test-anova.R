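heats <- chondrocyte_heats()

test_that("group estimates reproduce direct arithmetic on the packaged values", {
  est <- estimate_groups(heats, heat_per_cell_uJ, group)
  expect_equal(attr(est, "k"), 4)
  expect_equal(attr(est, "N"), 32)
  expect_equal(est$n, rep(8L, 4))
  nc <- heats$heat_per_cell_uJ[heats$group == "No Cells"]
  glu <- heats$heat_per_cell_uJ[heats$group == "Cells + Glucose"]
  expect_equal(est$mean[est$group == "No Cells"], mean(nc))
  expect_equal(est$mean[est$group == "No Cells"], 0.3725)
  expect_equal(est$mean[est$group == "Cells + Glucose"], 2.7925)
  expect_equal(est$variance[est$group == "Cells + Glucose"], var(glu))
  expect_equal(round(est$variance[est$group == "Cells + Glucose"], 4), 0.6739)
  expect_equal(est$weight, est$n / est$variance)
})

test_that("degenerate groups are refused rather than regularized", {
  df <- data.frame(y = c(1, 1, 2, 3), g = c("a", "a", "b", "b"))
  expect_error(estimate_groups(df, y, g), "zero within-group variance.*a")
  df2 <- data.frame(y = c(1, 2, 3), g = c("a", "b", "b"))
  expect_error(estimate_groups(df2, y, g), "at least 2")
  df3 <- data.frame(y = c(1, NA, 2, 3), g = c("a", "a", "b", "b"))
  expect_error(estimate_groups(df3, y, g), "missing")
})

test_that("the closed-form Wald F matches an iterative GLS fit with per-group variances", {
  est <- estimate_groups(heats, heat_per_cell_uJ, group)
  ft <- gls_wald_f(est)
  expect_equal(ft$df1, 3)
  expect_equal(ft$df2, 28)
  fit <- nlme::gls(heat_per_cell_uJ ~ group, data = heats,
                   weights = nlme::varIdent(form = ~ 1 | group))
  f_gls <- anova(fit)["group", "F-value"]
  expect_equal(ft$statistic, f_gls, tolerance = 1e-6)
})

test_that("for two groups the Wald F is the squared Welch statistic", {
  set.seed(41)
  for (i in 1:20) {
    y1 <- rnorm(5 + i %% 4, mean = i %% 3, sd = 0.5 + i %% 2)
    y2 <- rnorm(7, mean = 1, sd = 2)
    df <- data.frame(y = c(y1, y2), g = rep(c("a", "b"), c(length(y1), 7)))
    ft <- gls_wald_f(estimate_groups(df, y, g))
    z2 <- (mean(y1) - mean(y2))^2 /
      (var(y1) / length(y1) + var(y2) / length(y2))
    expect_equal(ft$statistic, z2, tolerance = 1e-12)
  }
})

test_that("F is invariant under affine transformation of all observations", {
  set.seed(99)
  base <- gls_wald_f(estimate_groups(heats, heat_per_cell_uJ, group))$statistic
  for (i in 1:10) {
    a <- runif(1, -5, 5); if (abs(a) < 0.1) a <- 1
    b <- runif(1, -10, 10)
    tr <- dplyr::mutate(heats, y = a * heat_per_cell_uJ + b)
    ft <- gls_wald_f(estimate_groups(tr, y, group))
    expect_equal(ft$statistic, base, tolerance = 1e-9)
  }
  # identical group means give F = 0
  df0 <- data.frame(y = c(1, 2, 3, 1.5, 2, 2.5), g = rep(c("a", "b"), each = 3))
  expect_equal(gls_wald_f(estimate_groups(df0, y, g))$statistic, 0)
})

test_that("Games-Howell comparisons are symmetric and monotone in the mean difference", {
  est <- estimate_groups(heats, heat_per_cell_uJ, group)
  pc <- pairwise_tukey(est)
  expect_equal(nrow(pc), 6)
  expect_equal(pc$estimate / pc$std_error, pc$statistic)
  # symmetry: reversing the group coding negates estimates, keeps p
  rev_heats <- dplyr::mutate(heats,
    group = factor(group, levels = rev(levels(group))))
  pc_rev <- pairwise_tukey(estimate_groups(rev_heats, heat_per_cell_uJ, group))
  key <- function(d) paste(pmin(d$group1, d$group2), pmax(d$group1, d$group2))
  m <- match(key(pc), key(pc_rev))
  expect_equal(pc$adj_p_value, pc_rev$adj_p_value[m])
  expect_equal(abs(pc$estimate), abs(pc_rev$estimate[m]))

  # p monotone non-increasing in |estimate| with variances held fixed
  make_est <- function(delta) {
    df <- data.frame(
      y = c(rnorm(8), rnorm(8) + delta),
      g = rep(c("a", "b"), each = 8)
    )
    # force exact means/variances by standardizing within group
    df$y <- unlist(lapply(split(df$y, df$g), function(v) (v - mean(v)) / sd(v)))
    df$y[df$g == "b"] <- df$y[df$g == "b"] * 2 + delta
    estimate_groups(df, y, g)
  }
  set.seed(7)
  ps <- vapply(c(0, 0.5, 1, 2, 4),
               function(d) pairwise_tukey(make_est(d))$adj_p_value, numeric(1))
  expect_true(all(diff(ps) <= 1e-12))
  # two identical groups: estimate 0, adjusted p = 1
  eq <- make_est(0)
  pc_eq <- pairwise_tukey(eq)
  expect_equal(pc_eq$estimate, 0)
  expect_equal(pc_eq$adj_p_value, 1, tolerance = 1e-9)
  expect_error(pairwise_tukey(est, alpha = 1.5), "alpha")
})

test_that("the packaged data reproduce the reported pairwise conclusions", {
  fit <- heat_anova(heats, heat_per_cell_uJ, group)
  pc <- fit$comparisons
  sig_of <- function(a, b) {
    pc$significant[(pc$group1 == a & pc$group2 == b) |
                     (pc$group1 == b & pc$group2 == a)]
  }
  expect_true(sig_of("No Cells", "Cells Only"))
  expect_true(sig_of("No Cells", "Cells + Glucose"))
  expect_true(sig_of("No Cells", "Cells + Glutamine"))
  expect_true(sig_of("Cells Only", "Cells + Glutamine"))
  expect_false(sig_of("Cells + Glucose", "Cells + Glutamine"))
  # the no-cell control shares no letter with any other group
  cld <- fit$cld
  nc <- strsplit(cld$letters[cld$group == "No Cells"], "")[[1]]
  others <- cld$letters[cld$group != "No Cells"]
  expect_false(any(vapply(strsplit(others, ""),
                          function(l) any(l %in% nc), logical(1))))
})

test_that("compact letters handle the fully-separated and null patterns", {
  all_sig <- fake_comparisons(matrix(TRUE, 3, 3))
  cld <- compact_letters(all_sig)
  expect_setequal(cld$letters, c("a", "b", "c"))
  none_sig <- fake_comparisons(matrix(FALSE, 3, 3))
  expect_equal(unique(compact_letters(none_sig)$letters), "a")
  # incomplete pair set is refused
  incomplete <- all_sig[-1, ]
  attr(incomplete, "groups") <- attr(all_sig, "groups")
  class(incomplete) <- class(all_sig)
  expect_error(compact_letters(incomplete), "every pair")
})
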