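test_that("substitution classes follow the six physicochemical groups", {
  expect_equal(classify_substitution("L", "V"), "C")
  expect_equal(classify_substitution("D", "K"), "NC")
  expect_equal(classify_substitution("C", "S"), "NC")  # C is a singleton
  expect_equal(classify_substitution("C", "C"), "C")
  expect_equal(classify_substitution(c("A", "R"), c("G", "H")), c("C", "C"))
  # every ordered pair maps to exactly one class
  grid <- expand.grid(n = quadpot:::AA_ALPHABET, r = quadpot:::AA_ALPHABET,
                      stringsAsFactors = FALSE)
  cl <- classify_substitution(grid$n, grid$r)
  expect_true(all(cl %in% c("C", "NC")))
})

test_that("class mean residuals match an independent group-by mean", {
  df <- tibble::tibble(
    residual_score = c(1, -1, -2, -4, 0.5, -0.5),
    activity = c("U", "U", "A", "A", "U", "A"),
    native = c("L", "D", "L", "A", "C", "F"),
    replacement = c("V", "K", "K", "G", "S", "Y"))
  out <- class_mean_residuals(df)
  expect_equal(out$mean_residual[out$activity == "U" & out$subset == "All"],
               mean(c(1, -1, 0.5)))
  cls <- classify_substitution(df$native, df$replacement)
  manual <- tapply(df$residual_score, paste(df$activity, cls), mean)
  expect_equal(out$mean_residual[out$activity == "A" & out$subset == "NC"],
               unname(manual[["A NC"]]))
  expect_equal(out$mean_residual[out$activity == "U" & out$subset == "C"],
               unname(manual[["U C"]]))
  # single-member and empty subgroups
  one <- df[1, ]
  res <- class_mean_residuals(one)
  expect_equal(res$mean_residual[res$subset == "All"], 1)
  expect_equal(res$n[res$subset == "NC"], 0)
  expect_true(is.na(res$mean_residual[res$subset == "NC"]))
})

test_that("the Welch t-test matches a closed-form computation", {
  x <- c(2.1, 1.8, 2.4, 2.0, 2.6)
  y <- c(1.1, 0.7, 1.5, 0.9)
  out <- two_sample_t_test(x, y)
  # Welch statistic and Satterthwaite df, from the definitions
  se2 <- var(x) / length(x) + var(y) / length(y)
  t_manual <- (mean(x) - mean(y)) / sqrt(se2)
  df_manual <- se2^2 / ((var(x) / length(x))^2 / (length(x) - 1) +
                          (var(y) / length(y))^2 / (length(y) - 1))
  expect_equal(out$statistic, t_manual, tolerance = 1e-12)
  expect_equal(out$df, df_manual, tolerance = 1e-12)
  expect_equal(out$p_value, 2 * stats::pt(-abs(t_manual), df_manual),
               tolerance = 1e-12)
  # identical samples: t = 0, p = 1
  same <- c(1, 1, 1)
  out0 <- two_sample_t_test(same, same)
  expect_equal(out0$statistic, 0)
  expect_equal(out0$p_value, 1)
})

test_that("a two-sigma location shift is detected at n = 50", {
  x <- withr::with_seed(8, stats::rnorm(50, mean = 2, sd = 1))
  y <- withr::with_seed(9, stats::rnorm(50, mean = 0, sd = 1))
  expect_lt(two_sample_t_test(x, y)$p_value, 0.05)
})

test_that("Pearson chi-square follows the O/E formula without correction", {
  out <- pearson_chi_square(matrix(c(10, 20, 20, 10), 2, byrow = TRUE))
  expect_equal(out$statistic, 20 / 3, tolerance = 1e-12)
  expect_equal(out$df, 1)
  # independence gives zero
  expect_equal(pearson_chi_square(matrix(10, 2, 2))$statistic, 0)
  # invariance under row/column permutation
  m <- ts_quadrant_polarity_counts
  s1 <- pearson_chi_square(m)$statistic
  s2 <- pearson_chi_square(m[c(3, 1, 4, 2), c(2, 1, 3)])$statistic
  expect_equal(s1, s2)
  expect_error(pearson_chi_square(matrix(c(1, 0, 2, 0), 2)), "marginal")
})

test_that("Fisher's exact test enumerates small tables and seeds Monte Carlo", {
  out <- fisher_exact_rxc(matrix(c(3, 1, 1, 3), 2, byrow = TRUE))
  expect_equal(out$method, "exact")
  expect_equal(out$p_value, 0.4857, tolerance = 1e-4)
  # all-zero rows are immaterial
  with_zero <- fisher_exact_rxc(matrix(c(3, 1, 0, 1, 3, 0), 2, byrow = TRUE))
  expect_equal(with_zero$p_value, out$p_value)
  # Monte Carlo mode is reproducible and close to the exact answer
  m <- matrix(c(30, 10, 12, 28), 2, byrow = TRUE)
  mc1 <- fisher_exact_rxc(m, max_exact_n = 10, B = 5e4, seed = 4)
  mc2 <- fisher_exact_rxc(m, max_exact_n = 10, B = 5e4, seed = 4)
  expect_equal(mc1$method, "monte_carlo")
  expect_identical(mc1$p_value, mc2$p_value)
  exact <- fisher_exact_rxc(m)$p_value
  expect_equal(mc1$p_value, exact, tolerance = 0.05)
})

test_that("residual-score bins follow the half-open interval convention", {
  b <- bin_residual_scores(c(-1.5, -1, -0.2, 0, 0.7, 1, 3))
  expect_equal(as.character(b),
               c("(-Inf, -1)", "[-1, 0)", "[-1, 0)", "[0, 1)", "[0, 1)",
                 "[1, Inf)", "[1, Inf)"))
  scores <- withr::with_seed(2, stats::rnorm(200))
  expect_equal(sum(table(bin_residual_scores(scores))), 200)
})

test_that("quadrants are sign-determined with zeros on the positive side", {
  expect_equal(assign_quadrant(c(1, -1, -1, 1), c(1, 1, -1, -1)),
               c("Q1", "Q2", "Q3", "Q4"))
  expect_equal(assign_quadrant(0, 0), "Q1")
  expect_equal(assign_quadrant(0, -1), "Q4")
  expect_equal(assign_quadrant(-1, 0), "Q2")
})

test_that("quadrant tables recover planted category distributions", {
  prof <- tibble::tibble(position = 1:8,
                         q = c(1, 2, -1, -2, -1, -3, 2, 4),
                         cmp = c(1, 3, 2, 1, -2, -1, -4, -1))
  cats <- setNames(rep(c("x", "y"), 4), 1:8)
  tab <- quadrant_table(prof, cats)
  expect_equal(as.vector(tab), c(1, 1, 1, 1, 1, 1, 1, 1))
  expect_equal(rownames(tab), c("Q1", "Q2", "Q3", "Q4"))
  # positions missing from the annotation are dropped
  tab2 <- quadrant_table(prof, cats[1:4])
  expect_equal(sum(tab2), 4)
})

test_that("polarity classes cover the alphabet", {
  expect_equal(residue_polarity(c("L", "D", "S")),
               c("apolar", "charged", "polar"))
  expect_equal(sort(as.vector(table(residue_polarity(quadpot:::AA_ALPHABET)))),
               c(5, 6, 9))
})

test_that("CMP-RES regression matches the closed-form Pearson fit", {
  q <- withr::with_seed(3, stats::rnorm(50))
  cmp <- -1.2 * q + withr::with_seed(4, stats::rnorm(50, sd = 0.3))
  out <- cmp_res_regression(q, cmp)
  expect_equal(out$r_squared, stats::cor(q, cmp)^2, tolerance = 1e-12)
  expect_equal(out$slope, stats::cov(q, cmp) / stats::var(q),
               tolerance = 1e-12)
  # perfectly linear
  perfect <- suppressWarnings(cmp_res_regression(1:10, 2 - 3 * (1:10)))
  expect_equal(perfect$r_squared, 1)
  expect_equal(perfect$slope, -3)
  # constant response is flagged
  flat <- cmp_res_regression(1:10, rep(2, 10))
  expect_true(flat$constant_response)
  expect_equal(flat$r_squared, 0)
})

test_that("activity-score tables cross activity with the four bins", {
  df <- tibble::tibble(residual_score = c(-2, -0.5, 0.5, 2, -3, 0.1),
                       activity = c("U", "U", "U", "U", "A", "A"))
  tab <- activity_score_table(df)
  expect_equal(dim(tab), c(2, 4))
  expect_equal(sum(tab), 6)
  expect_equal(as.vector(tab["A", ]), c(1, 0, 1, 0))
})
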