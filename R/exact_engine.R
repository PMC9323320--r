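#' Exact hidden-mutation probability by weighted enumeration
#'
#' Computes, without any random sampling, the probability that a familial
#' configuration carrying exactly one single-step mutation remains
#' Mendelian-compatible, for a given population allele-frequency
#' distribution. This is the deterministic counterpart of
#' [simulate_hidden_rate()] and the default source of `h` for the
#' mutation-rate correction.
#'
#' The finite outcome space (mutating parent's two alleles, transmitted
#' allele, mutation direction, and the partner parent's or population's
#' contribution) is summed with product weights. The sums over the partner
#' side are factorized analytically, so the cost is linear in the ladder
#' size rather than the naive `O(N^4)`; on small ladders the factorized and
#' naive enumerations agree to machine precision (verified in the test
#' suite).
#'
#' Conventions match the simulator exactly: direction up/down with equal
#' probability, mutants may step off the observed ladder (where they carry
#' zero frequency and can never match a sampled allele), and duos expose the
#' `tested_parent` and `random_meiosis` conventions described in
#' [simulate_hidden_rate()].
#'
#' @param dist an [allele_freq_dist()].
#' @param family `"trio"` or `"duo"`.
#' @param duo_convention `"tested_parent"` (default) or `"random_meiosis"`;
#'   ignored for trios.
#' @return The hidden-mutation probability, a number in `[0, 1]`.
#' @examples
#' exact_hidden_rate(constant_distribution(10), "trio")            # 0.1053
#' exact_hidden_rate(constant_distribution(10), "duo",
#'                   duo_convention = "random_meiosis")            # 0.631
#' @export
exact_hidden_rate <- function(dist, family = c("trio", "duo"),
                              duo_convention = c("tested_parent",
                                                 "random_meiosis")) {
  stopifnot(inherits(dist, "allele_freq_dist"))
  family <- match.arg(family)
  duo_convention <- match.arg(duo_convention)

  keys <- .allele_key(dist$alleles)
  p <- dist$frequencies
  # population frequency of a mutant key; 0 off ladder
  pfreq <- function(k) {
    i <- match(k, keys)
    ifelse(is.na(i), 0, p[i])
  }
  S2 <- sum(p^2)
  S3 <- sum(p^3)

  if (family == "trio") {
    # Transmitted allele t ~ p (uniform pick from two i.i.d. draws), second
    # allele a' ~ p of the mutating parent, direction d = +/-1 w.p. 1/2,
    # mutant m = t + d. The child's other allele c is a uniform pick from the
    # partner parent's two i.i.d. draws, so c is in the partner genotype by
    # construction. Compatibility holds iff m equals a' (mutant assigned to
    # the mutating parent) or c is in {t, a'} while m is in the partner
    # genotype. Summing the partner side analytically:
    #   P(m == a')                      = p_m
    #   P(c in {t,a'}, m in partner | a' != m)
    #     summed over a':  p_m * (p_t + S2 - p_t^2 - p_m p_t - p_m^2)
    h <- 0
    for (d in c(-10L, 10L)) {
      m <- keys + d
      pm <- pfreq(m)
      inner <- pm + pm * (p + S2 - p^2 - pm * p - pm^2)
      h <- h + sum(p * 0.5 * inner)
    }
    return(h)
  }

  # Duo, tested parent: parent {t, o} with t ~ p transmitted, o ~ p; mutant
  # m = t + d; child's other allele c ~ p from the population. Compatible iff
  # m == o, or c in {t, o}. By inclusion-exclusion:
  #   P(c in {t, o})          = 2 S2 - S3
  #   P(m == o)               = sum_t p_t 1/2 sum_d p_m
  #   P(both)                 = sum_t p_t 1/2 sum_d p_m (p_t + p_m)
  h_tp <- 2 * S2 - S3
  for (d in c(-10L, 10L)) {
    m <- keys + d
    pm <- pfreq(m)
    h_tp <- h_tp + sum(p * 0.5 * pm * (1 - p - pm))
  }
  if (duo_convention == "tested_parent") return(h_tp)
  # random_meiosis: with probability 1/2 the mutation falls on the unobserved
  # meiosis, where it can never conflict with the tested parent.
  0.5 + 0.5 * h_tp
}

#' Closed-form hidden rate for the uniform ladder
#'
#' Analytic hidden-mutation probability for a uniform (constant) `N`-allele
#' distribution with consecutive alleles, used as an independent cross-check
#' of the enumeration engine:
#' \itemize{
#'   \item trio: `(N-1)/N^2 + (N-1)(2N-3)/N^4`
#'   \item duo, tested parent: `(3N-2)/N^2 - 2(N-1)/N^3`
#'   \item duo, random meiosis: `1/2 + 1/2 *` the tested-parent value
#' }
#'
#' @param n number of alleles (`n >= 1`).
#' @param family `"trio"` or `"duo"`.
#' @param duo_convention `"tested_parent"` or `"random_meiosis"`.
#' @return The hidden-mutation probability.
#' @examples
#' uniform_closed_form(10, "trio")  # 0.1053
#' @export
uniform_closed_form <- function(n, family = c("trio", "duo"),
                                duo_convention = c("tested_parent",
                                                   "random_meiosis")) {
  family <- match.arg(family)
  duo_convention <- match.arg(duo_convention)
  n <- .check_allele_count(n)
  N <- as.numeric(n)
  if (family == "trio")
    return((N - 1) / N^2 + (N - 1) * (2 * N - 3) / N^4)
  tp <- (3 * N - 2) / N^2 - 2 * (N - 1) / N^3
  if (duo_convention == "tested_parent") tp else 0.5 + 0.5 * tp
}
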