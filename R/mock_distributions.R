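#' Uniform ("constant") mock allele-frequency distribution
#'
#' Alleles are consecutive integers `1..n` (one repeat unit apart, matching
#' the single-step mutation model), each with frequency `1/n`.
#'
#' @param n number of alleles (`n >= 1`).
#' @param marker marker label; defaults to `"constant<n>"`.
#' @return An [allele_freq_dist()].
#' @examples
#' constant_distribution(10)
#' @export
constant_distribution <- function(n, marker = paste0("constant", n)) {
  n <- .check_allele_count(n)
  allele_freq_dist(marker, seq_len(n), rep(1 / n, n))
}

#' Gaussian-shaped mock allele-frequency distribution
#'
#' Frequencies are proportional to a normal density evaluated at allele
#' positions `1..n`, then renormalized to sum to 1. The default spread
#' `sd = n/6` places about three standard deviations on each side of the
#' central mode, giving a unimodal shape that tapers to near zero at the
#' ladder ends.
#'
#' @param n number of alleles (`n >= 1`).
#' @param mean mode position in allele units; default the ladder center
#'   `(n + 1)/2`.
#' @param sd spread in allele units (`> 0`); default `n/6`.
#' @param marker marker label; defaults to `"normal<n>"`.
#' @return An [allele_freq_dist()].
#' @export
normal_distribution <- function(n, mean = (n + 1) / 2, sd = n / 6,
                                marker = paste0("normal", n)) {
  n <- .check_allele_count(n)
  stopifnot(is.numeric(mean), length(mean) == 1L)
  if (!is.numeric(sd) || length(sd) != 1L || sd <= 0)
    stop("'sd' must be a positive number", call. = FALSE)
  w <- stats::dnorm(seq_len(n), mean = mean, sd = sd)
  allele_freq_dist(marker, seq_len(n), w / sum(w))
}

#' Bimodal mock allele-frequency distribution
#'
#' Frequencies are proportional to an equal-weight mixture of two Gaussian
#' densities at positions `1..n`, renormalized. Defaults put the modes at the
#' first and third quartiles of the ladder (`ceiling(n/4)` and
#' `ceiling(3n/4)`) with spread `n/10`, producing two well-separated peaks.
#'
#' @param n number of alleles (`n >= 1`).
#' @param mode1,mode2 mode positions in allele units, within `[1, n]`.
#' @param sd common spread in allele units (`> 0`); default `n/10`.
#' @param marker marker label; defaults to `"bimodal<n>"`.
#' @return An [allele_freq_dist()].
#' @export
bimodal_distribution <- function(n, mode1 = ceiling(n / 4),
                                 mode2 = ceiling(3 * n / 4), sd = n / 10,
                                 marker = paste0("bimodal", n)) {
  n <- .check_allele_count(n)
  if (!is.numeric(sd) || length(sd) != 1L || sd <= 0)
    stop("'sd' must be a positive number", call. = FALSE)
  for (m in c(mode1, mode2))
    if (!is.numeric(m) || length(m) != 1L || m < 1 || m > n)
      stop("modes must lie within [1, n]", call. = FALSE)
  x <- seq_len(n)
  w <- 0.5 * stats::dnorm(x, mode1, sd) + 0.5 * stats::dnorm(x, mode2, sd)
  allele_freq_dist(marker, x, w / sum(w))
}

#' The six-member mock distribution suite
#'
#' Convenience generator for the full grid of mock shapes: normal, bimodal,
#' and constant, each with a narrow (10-allele) and a wide (20-allele)
#' ladder, using each generator's default shape parameters.
#'
#' @return A named list of six [allele_freq_dist()] objects.
#' @examples
#' sapply(mock_suite(), heterozygosity)
#' @export
mock_suite <- function() {
  dists <- list(
    normal10 = normal_distribution(10),
    normal20 = normal_distribution(20),
    bimodal10 = bimodal_distribution(10),
    bimodal20 = bimodal_distribution(20),
    constant10 = constant_distribution(10),
    constant20 = constant_distribution(20)
  )
  dists
}

.check_allele_count <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1 ||
      n != as.integer(n))
    stop("'n' must be a positive integer", call. = FALSE)
  as.integer(n)
}
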