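# Six physicochemical residue groups used to define conservative
# substitutions.
AA_GROUPS <- list(c("A", "S", "T", "G", "P"),
                  c("D", "E", "N", "Q"),
                  c("R", "K", "H"),
                  c("F", "Y", "W"),
                  c("V", "L", "I", "M"),
                  c("C"))

aa_group_id <- function(aa) {
  g <- rep(NA_integer_, length(aa))
  for (k in seq_along(AA_GROUPS)) g[aa %in% AA_GROUPS[[k]]] <- k
  if (anyNA(g)) abort("invalid amino acid letter")
  g
}

#' Conservative vs non-conservative substitution class
#'
#' A replacement within one of the six physicochemical groups
#' `[(A,S,T,G,P), (D,E,N,Q), (R,K,H), (F,Y,W), (V,L,I,M), (C)]` is
#' conservative (`"C"`); replacements across groups are non-conservative
#' (`"NC"`).  Vectorized.
#'
#' @param native,replacement One-letter codes.
#' @return Character vector of `"C"`/`"NC"`.
#' @export
classify_substitution <- function(native, replacement) {
  ifelse(aa_group_id(native) == aa_group_id(replacement), "C", "NC")
}

#' Mean residual scores by activity class and substitution class
#'
#' Group means of the residual scores for the unaffected (U) and affected (A)
#' activity classes, overall and split by conservative/non-conservative
#' substitution.
#'
#' @param variants Tibble with `residual_score`, `activity` and (for the C/NC
#'   split) `native`, `replacement`.
#' @return A tibble `activity`, `subset` (All/C/NC), `n`, `mean_residual`;
#'   empty subgroups are reported with `n = 0` and `NA` mean.
#' @export
class_mean_residuals <- function(variants) {
  stopifnot(all(c("residual_score", "activity") %in% names(variants)))
  variants$subset_class <- classify_substitution(variants$native,
                                                 variants$replacement)
  all_means <- variants |>
    dplyr::group_by(activity = .data$activity) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_residual = mean(.data$residual_score),
                     .groups = "drop") |>
    dplyr::mutate(subset = "All")
  grid <- tidyr::crossing(activity = unique(variants$activity),
                          subset = c("C", "NC"))
  sub_means <- variants |>
    dplyr::group_by(activity = .data$activity,
                    subset = .data$subset_class) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_residual = mean(.data$residual_score),
                     .groups = "drop") |>
    dplyr::right_join(grid, by = c("activity", "subset")) |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L))
  dplyr::bind_rows(all_means, sub_means)[
    c("activity", "subset", "n", "mean_residual")] |>
    dplyr::arrange(.data$activity, .data$subset)
}

#' Welch two-sample t-test of class residual scores
#'
#' @param scores_u,scores_a Residual scores of the two activity classes
#'   (each `n >= 2`).
#' @return A tibble `statistic`, `df`, `p_value`, `mean_u`, `mean_a`.
#' @export
two_sample_t_test <- function(scores_u, scores_a) {
  stopifnot(length(scores_u) >= 2, length(scores_a) >= 2)
  if (isTRUE(all.equal(c(scores_u, scores_a),
                       rep(mean(c(scores_u, scores_a)),
                           length(scores_u) + length(scores_a))))) {
    return(tibble(statistic = 0, df = NA_real_, p_value = 1,
                  mean_u = mean(scores_u), mean_a = mean(scores_a)))
  }
  ht <- stats::t.test(scores_u, scores_a, var.equal = FALSE)
  tibble(statistic = unname(ht$statistic), df = unname(ht$parameter),
         p_value = ht$p.value,
         mean_u = mean(scores_u), mean_a = mean(scores_a))
}

#' Pearson chi-square test of independence
#'
#' No continuity correction; `df = (r - 1)(c - 1)`.
#'
#' @param table A counts matrix or table.
#' @return A tibble `statistic`, `df`, `p_value`.
#' @export
pearson_chi_square <- function(table) {
  m <- as.matrix(table)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    abort("contingency table has a zero marginal")
  }
  ht <- stats::chisq.test(m, correct = FALSE)
  tibble(statistic = unname(ht$statistic), df = unname(ht$parameter),
         p_value = ht$p.value)
}

#' Fisher's exact test for r x c tables
#'
#' Exact network enumeration for small tables (total count up to
#' `max_exact_n`); otherwise a seeded Monte Carlo approximation, with the
#' method used recorded in the output.
#'
#' @param table A counts matrix or table.
#' @param max_exact_n Largest total count for exact enumeration (default 200).
#' @param B Monte Carlo replicates (default 1e6).
#' @param seed Seed for the Monte Carlo mode (default 1).
#' @return A tibble `p_value`, `method`.
#' @export
fisher_exact_rxc <- function(table, max_exact_n = 200, B = 1e6, seed = 1) {
  m <- as.matrix(table)
  m <- m[rowSums(m) > 0, colSums(m) > 0, drop = FALSE]
  if (sum(m) <= max_exact_n) {
    ht <- stats::fisher.test(m, workspace = 2e7)
    return(tibble(p_value = ht$p.value, method = "exact"))
  }
  ht <- withr::with_seed(seed,
    stats::fisher.test(m, simulate.p.value = TRUE, B = B))
  tibble(p_value = ht$p.value, method = "monte_carlo")
}

#' Bin residual scores into the four standard intervals
#'
#' Intervals `(-Inf, -1)`, `[-1, 0)`, `[0, 1)` and `[1, Inf)`.
#'
#' @param scores Numeric residual scores.
#' @param breakpoints Interior breakpoints (default `c(-1, 0, 1)`).
#' @return A factor with one interval label per score.
#' @export
bin_residual_scores <- function(scores, breakpoints = c(-1, 0, 1)) {
  b <- sort(breakpoints)
  labs <- c(sprintf("(-Inf, %g)", b[1]),
            sprintf("[%g, %g)", b[-length(b)], b[-1]),
            sprintf("[%g, Inf)", b[length(b)]))
  cut(scores, breaks = c(-Inf, b, Inf), right = FALSE, labels = labs)
}

#' Activity-by-score-interval contingency table
#'
#' Cross-tabulates U/A activity classes against the four residual-score
#' intervals of [bin_residual_scores()].
#'
#' @param variants Tibble with `residual_score` and `activity`.
#' @param breakpoints Passed to [bin_residual_scores()].
#' @return A 2 x 4 table (rows U, A).
#' @export
activity_score_table <- function(variants, breakpoints = c(-1, 0, 1)) {
  table(factor(variants$activity, levels = c("U", "A")),
        bin_residual_scores(variants$residual_score, breakpoints))
}

#' Quadrant assignment in the environment-score/CMP plane
#'
#' Positions are placed in the Cartesian plane with `x` = native residue
#' environment score and `y` = CMP score, and assigned quadrants numbered
#' counterclockwise from `(+, +)`: Q1 `(x>0, y>0)`, Q2 `(x<0, y>0)`,
#' Q3 `(x<0, y<0)`, Q4 `(x>0, y<0)`.  Zero coordinates count as positive.
#'
#' @param x,y Numeric coordinates.
#' @return Character vector `"Q1"`..`"Q4"`.
#' @export
assign_quadrant <- function(x, y) {
  xp <- x >= 0
  yp <- y >= 0
  dplyr::case_when(xp & yp ~ "Q1", !xp & yp ~ "Q2",
                   !xp & !yp ~ "Q3", TRUE ~ "Q4")
}

#' Quadrant-by-category contingency table
#'
#' Cross-tabulates residue positions, located by quadrant in the
#' (environment score, CMP) plane, against user-supplied residue categories
#' (e.g. side-chain polarity, or structural/functional annotation).
#'
#' @param profile Tibble with `position`, `q`, `cmp` (e.g. from
#'   [comprehensive_mutational_profile()]).
#' @param categories Named vector (names = positions) or tibble `position`,
#'   `category`; positions absent from it are dropped.
#' @return A quadrant x category table (all four quadrant rows retained).
#' @export
quadrant_table <- function(profile, categories) {
  if (!is.data.frame(categories)) {
    categories <- tibble(position = as.integer(names(categories)),
                         category = unname(categories))
  }
  df <- dplyr::inner_join(profile, categories, by = "position")
  quad <- factor(assign_quadrant(df$q, df$cmp),
                 levels = c("Q1", "Q2", "Q3", "Q4"))
  table(quad, factor(df$category))
}

#' Side-chain polarity of residues
#'
#' Apolar (A,V,L,I,M,F,W,P,G), charged (D,E,K,R,H) or polar (S,T,N,Q,C,Y).
#' @param aa One-letter codes.
#' @return Character vector of `"apolar"`, `"charged"`, `"polar"`.
#' @export
residue_polarity <- function(aa) {
  p <- unname(AA_POLARITY[aa])
  if (anyNA(p)) abort("invalid amino acid letter")
  p
}

#' Regression of CMP on environment scores
#'
#' Ordinary least squares of `cmp ~ q`; `R^2` is the squared Pearson
#' correlation.  A constant response is reported as `r_squared = 0` with
#' `constant_response = TRUE`.
#'
#' @param q Native residue environment scores.
#' @param cmp CMP scores (same length, `n >= 3`).
#' @return A tibble `slope`, `intercept`, `r_squared`, `constant_response`.
#' @export
cmp_res_regression <- function(q, cmp) {
  stopifnot(length(q) == length(cmp), length(q) >= 3)
  if (stats::var(cmp) == 0) {
    return(tibble(slope = 0, intercept = mean(cmp), r_squared = 0,
                  constant_response = TRUE))
  }
  fit <- stats::lm(cmp ~ q)
  tibble(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r_squared = summary(fit)$r.squared,
         constant_response = FALSE)
}
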