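#' Pairwise Fisher exact tests on hidden-mutation counts
#'
#' Compares the proportion of hidden mutations between every unordered pair
#' of groups (markers, populations, ...) with a two-sided Fisher exact test
#' on the 2x2 table of hidden vs revealed counts, applying a Bonferroni
#' threshold `family_wise_alpha / choose(k, 2)` over the `k` groups. With 30
#' groups at a family-wise level of 0.05 the per-pair threshold is
#' 0.05/435, about 0.000115.
#'
#' @param hidden_counts integer vector of hidden-mutation counts per group.
#' @param totals integer vector of total simulated mutations per group.
#' @param groups optional group labels; defaults to names of `hidden_counts`
#'   or `g1, g2, ...`.
#' @param family_wise_alpha family-wise significance level, default 0.05.
#' @return A data frame with one row per pair: `group1`, `group2`,
#'   `p_value`, `alpha` (the Bonferroni-adjusted per-pair threshold), and
#'   `significant` (`p_value < alpha`).
#' @examples
#' fisher_pairwise(c(105000, 63000), c(1e6, 1e6), c("trio", "duo"))
#' @export
fisher_pairwise <- function(hidden_counts, totals, groups = NULL,
                            family_wise_alpha = 0.05) {
  k <- length(hidden_counts)
  if (k < 2L) stop("need at least two groups", call. = FALSE)
  if (length(totals) != k)
    stop("'hidden_counts' and 'totals' must have equal length", call. = FALSE)
  if (any(hidden_counts < 0) || any(totals < 1) ||
      any(hidden_counts > totals))
    stop("counts must satisfy 0 <= hidden <= total", call. = FALSE)
  if (is.null(groups)) groups <- names(hidden_counts)
  if (is.null(groups)) groups <- paste0("g", seq_len(k))
  pairs <- utils::combn(k, 2)
  alpha <- family_wise_alpha / ncol(pairs)
  p <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    tab <- matrix(c(hidden_counts[i], totals[i] - hidden_counts[i],
                    hidden_counts[j], totals[j] - hidden_counts[j]),
                  nrow = 2)
    stats::fisher.test(tab)$p.value
  })
  data.frame(group1 = groups[pairs[1, ]], group2 = groups[pairs[2, ]],
             p_value = p, alpha = alpha, significant = p < alpha,
             stringsAsFactors = FALSE)
}

#' Linear fit of hidden-mutation rate on heterozygosity
#'
#' Ordinary least squares of `y` on `x`, reporting the squared Pearson
#' correlation. Typically used to quantify how tightly a set of markers'
#' hidden-mutation rates track their expected heterozygosities.
#'
#' @param x,y numeric vectors of equal length (`>= 2` points); `x` must not
#'   be constant.
#' @return A list with `slope`, `intercept`, and `r_squared`.
#' @examples
#' rate_regression(c(0, 1, 2), c(0, 1, 3))  # r_squared = 27/28
#' @export
rate_regression <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L)
    stop("'x' and 'y' must have equal length >= 2", call. = FALSE)
  if (isTRUE(all.equal(stats::var(x), 0)) || stats::var(x) == 0)
    stop("'x' is constant: slope undefined", call. = FALSE)
  fit <- stats::lm(y ~ x)
  r2 <- if (stats::var(y) == 0) 0 else stats::cor(x, y)^2
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = r2)
}

#' Per-group dispersion of hidden-mutation rates
#'
#' Sample standard deviation of rates within each group — e.g. the spread of
#' marker-specific hidden rates within each population.
#'
#' @param rates numeric vector of rates.
#' @param groups grouping vector of the same length; each group must contain
#'   at least two values.
#' @return A named numeric vector of per-group standard deviations.
#' @examples
#' dispersion_summary(c(0.1, 0.3, 0.2, 0.2), c("a", "a", "b", "b"))
#' @export
dispersion_summary <- function(rates, groups) {
  if (length(rates) != length(groups))
    stop("'rates' and 'groups' must have equal length", call. = FALSE)
  sizes <- table(groups)
  if (any(sizes < 2))
    stop("each group needs at least two values; too small: ",
         paste(names(sizes)[sizes < 2], collapse = ", "), call. = FALSE)
  out <- tapply(rates, groups, stats::sd)
  out[order(names(out))]
}
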