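#' Apply a single-step mutation to an allele
#'
#' Under the stepwise mutation model a mutation gains or loses exactly one
#' repeat unit. Microvariant suffixes are preserved (`9.3` steps to `8.3` or
#' `10.3`): the fractional part records an interstitial partial repeat that
#' whole-repeat gains and losses do not touch. The result may lie outside the
#' population's observed ladder; such off-ladder alleles carry zero population
#' frequency and never match a sampled allele.
#'
#' @param allele numeric allele label(s).
#' @param direction `+1` (gain) or `-1` (loss); recycled against `allele`.
#' @return The mutated allele label(s).
#' @examples
#' apply_single_step_mutation(10, +1)   # 11
#' apply_single_step_mutation(9.3, -1)  # 8.3
#' @export
apply_single_step_mutation <- function(allele, direction) {
  stopifnot(is.numeric(allele), all(direction %in% c(-1, 1)))
  .key_to_allele(.allele_key(allele) + as.integer(direction) * 10L)
}

#' Mendelian compatibility of a parent-child duo
#'
#' A duo is compatible when parent and child share at least one allele label;
#' otherwise the configuration would be scored as a Mendelian incompatibility.
#'
#' @param parent,child numeric vectors of length 2 (unordered genotypes; the
#'   two alleles may coincide).
#' @return `TRUE` if compatible.
#' @examples
#' duo_is_compatible(c(10, 11), c(11, 14))  # TRUE, share 11
#' duo_is_compatible(c(10, 11), c(9, 13))   # FALSE
#' @export
duo_is_compatible <- function(parent, child) {
  stopifnot(length(parent) == 2L, length(child) == 2L)
  any(.allele_key(child) %in% .allele_key(parent))
}

#' Mendelian compatibility of a parents-child trio
#'
#' Compatible when the child's two alleles admit an assignment with one
#' allele from each parent. A homozygous child therefore requires its allele
#' to be present in both parents.
#'
#' @param parent1,parent2,child numeric vectors of length 2.
#' @return `TRUE` if compatible.
#' @examples
#' trio_is_compatible(c(10, 11), c(12, 13), c(11, 12))  # TRUE
#' trio_is_compatible(c(10, 11), c(12, 13), c(11, 11))  # FALSE: 11 not in p2
#' @export
trio_is_compatible <- function(parent1, parent2, child) {
  stopifnot(length(parent1) == 2L, length(parent2) == 2L, length(child) == 2L)
  k1 <- .allele_key(parent1); k2 <- .allele_key(parent2)
  x <- .allele_key(child)[1]; y <- .allele_key(child)[2]
  (x %in% k1 && y %in% k2) || (y %in% k1 && x %in% k2)
}

# Vectorized forms of the predicates over parallel replicate vectors of
# integer allele keys; used by the batch simulators.
.duo_compat_vec <- function(p1, p2, c1, c2) {
  c1 == p1 | c1 == p2 | c2 == p1 | c2 == p2
}
.trio_compat_vec <- function(a1, a2, b1, b2, x, y) {
  ((x == a1 | x == a2) & (y == b1 | y == b2)) |
    ((y == a1 | y == a2) & (x == b1 | x == b2))
}

.draw_keys <- function(dist, n) {
  keys <- .allele_key(dist$alleles)
  keys[sample.int(length(keys), n, replace = TRUE, prob = dist$frequencies)]
}

.match_arg2 <- function(arg, choices) match.arg(arg, choices)

#' Monte-Carlo estimate of the hidden-mutation rate
#'
#' Simulates `n` familial configurations (duos or trios), each carrying
#' exactly one single-step mutation, and counts the fraction that remain
#' Mendelian-compatible — the hidden-mutation rate `h` for the marker.
#'
#' For trios, each replicate draws four parental alleles independently from
#' the distribution, picks the mutating parent uniformly, transmits a
#' uniformly chosen allele of that parent mutated by one repeat unit in a
#' uniformly chosen direction, and completes the child with a uniformly
#' chosen allele of the other parent.
#'
#' For duos only one parent is observed, and two conventions are exposed
#' (see the package vignette for why both are needed):
#' \describe{
#'   \item{`tested_parent`}{the mutation always occurs in the observed
#'     parent's meiosis; the child's other allele is drawn from the
#'     population. This is the convention matching mutation-rate studies,
#'     which count mutations per observed meiosis, and is the default for
#'     correction.}
#'   \item{`random_meiosis`}{with probability 1/2 the mutation instead occurs
#'     in the unobserved meiosis contributing the child's population-drawn
#'     allele, the tested parent transmitting unmutated. A mutation on the
#'     unobserved side can never produce an incompatibility with the tested
#'     parent, so the hidden rate equals `0.5 + 0.5 *` the tested-parent
#'     rate.}
#' }
#'
#' Mutation direction is up/down with probability 1/2 each, unconditionally;
#' mutants may leave the observed ladder (no reflection or truncation at the
#' ladder ends). Random draws are made in a fixed vectorized order (parental
#' alleles, meiosis choice, transmitted-allele choice, direction,
#' partner/population allele), so identical `seed` and settings give
#' bit-identical counts.
#'
#' @param dist an [allele_freq_dist()].
#' @param family `"trio"` or `"duo"`.
#' @param n number of replicates (default 1e6).
#' @param seed optional integer seed for reproducibility.
#' @param duo_convention `"tested_parent"` (default) or `"random_meiosis"`;
#'   ignored for trios.
#' @param keep_configs if `TRUE`, attach a data frame of the simulated
#'   genotype configurations (allele labels plus the hidden flag), so each
#'   classification can be audited against the compatibility predicates.
#'   Intended for small `n`.
#' @return An object of class `hidden_estimate`: a list with `hidden_count`,
#'   `total`, `rate`, `std_error` (binomial, `sqrt(rate (1-rate)/n)`),
#'   `method = "monte_carlo"`, `family`, `duo_convention`, and `marker`;
#'   plus `configs` when `keep_configs = TRUE`.
#' @seealso [exact_hidden_rate()] for the enumeration counterpart.
#' @examples
#' simulate_hidden_rate(constant_distribution(10), "trio", n = 1e4, seed = 1)
#' @export
simulate_hidden_rate <- function(dist, family = c("trio", "duo"), n = 1e6,
                                 seed = NULL,
                                 duo_convention = c("tested_parent",
                                                    "random_meiosis"),
                                 keep_configs = FALSE) {
  stopifnot(inherits(dist, "allele_freq_dist"))
  family <- match.arg(family)
  duo_convention <- match.arg(duo_convention)
  n <- as.integer(n)
  if (is.na(n) || n < 1) stop("'n' must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  step <- 10L  # one repeat unit in integer-tenth keys
  if (family == "trio") {
    a1 <- .draw_keys(dist, n); a2 <- .draw_keys(dist, n)
    b1 <- .draw_keys(dist, n); b2 <- .draw_keys(dist, n)
    mut_p1 <- stats::runif(n) < 0.5          # which parent mutates
    t_first <- stats::runif(n) < 0.5         # which of its alleles transmits
    dir_up <- stats::runif(n) < 0.5
    c_first <- stats::runif(n) < 0.5         # partner parent's contribution
    # mutating parent's alleles (ma) and partner parent's (pa)
    ma1 <- ifelse(mut_p1, a1, b1); ma2 <- ifelse(mut_p1, a2, b2)
    pa1 <- ifelse(mut_p1, b1, a1); pa2 <- ifelse(mut_p1, b2, a2)
    m <- ifelse(t_first, ma1, ma2) + ifelse(dir_up, step, -step)
    cpart <- ifelse(c_first, pa1, pa2)
    hidden <- .trio_compat_vec(ma1, ma2, pa1, pa2, m, cpart)
    if (keep_configs)
      configs <- data.frame(
        parent1_a = .key_to_allele(ma1), parent1_b = .key_to_allele(ma2),
        parent2_a = .key_to_allele(pa1), parent2_b = .key_to_allele(pa2),
        child_a = .key_to_allele(m), child_b = .key_to_allele(cpart),
        hidden = hidden)
  } else if (duo_convention == "tested_parent") {
    a1 <- .draw_keys(dist, n); a2 <- .draw_keys(dist, n)
    t_first <- stats::runif(n) < 0.5
    dir_up <- stats::runif(n) < 0.5
    pop <- .draw_keys(dist, n)
    m <- ifelse(t_first, a1, a2) + ifelse(dir_up, step, -step)
    hidden <- .duo_compat_vec(a1, a2, m, pop)
    if (keep_configs)
      configs <- data.frame(
        parent_a = .key_to_allele(a1), parent_b = .key_to_allele(a2),
        child_a = .key_to_allele(m), child_b = .key_to_allele(pop),
        hidden = hidden)
  } else {
    a1 <- .draw_keys(dist, n); a2 <- .draw_keys(dist, n)
    tested_side <- stats::runif(n) < 0.5     # which meiosis mutates
    t_first <- stats::runif(n) < 0.5
    dir_up <- stats::runif(n) < 0.5
    pop <- .draw_keys(dist, n)
    t_allele <- ifelse(t_first, a1, a2)
    d <- ifelse(dir_up, step, -step)
    child1 <- ifelse(tested_side, t_allele + d, t_allele)
    child2 <- ifelse(tested_side, pop, pop + d)
    hidden <- .duo_compat_vec(a1, a2, child1, child2)
    if (keep_configs)
      configs <- data.frame(
        parent_a = .key_to_allele(a1), parent_b = .key_to_allele(a2),
        child_a = .key_to_allele(child1), child_b = .key_to_allele(child2),
        hidden = hidden)
  }

  k <- sum(hidden)
  rate <- k / n
  out <- structure(
    list(hidden_count = k, total = n, rate = rate,
         std_error = sqrt(rate * (1 - rate) / n),
         method = "monte_carlo", family = family,
         duo_convention = if (family == "duo") duo_convention else NA_character_,
         marker = dist$marker),
    class = "hidden_estimate"
  )
  if (keep_configs) out$configs <- configs
  out
}

#' @export
print.hidden_estimate <- function(x, ...) {
  conv <- if (!is.na(x$duo_convention)) paste0(", ", x$duo_convention) else ""
  cat("Hidden-mutation rate estimate (", x$method, ")\n", sep = "")
  cat("  marker: ", x$marker, "  family: ", x$family, conv, "\n", sep = "")
  cat("  rate: ", format(x$rate, digits = 6), sep = "")
  if (x$method == "monte_carlo")
    cat("  (", x$hidden_count, "/", x$total,
        ", SE ", format(x$std_error, digits = 3), ")", sep = "")
  cat("\n")
  invisible(x)
}

#' Simulate a Mendelian-incompatibility mutation-rate study
#'
#' End-to-end harness mirroring a real mutation-rate study based on the
#' Mendelian incompatibilities approach (MIA): families are generated from a
#' population, each transmitted (observed) meiosis independently suffers a
#' single-step mutation with probability `mu`, and the observed
#' incompatibility rate per meiosis is returned. Duos observe one meiosis per
#' family (the tested parent's); trios observe two. Coupling this with the
#' exact hidden rate via [correct_incompatibility_rate()] should recover `mu`
#' up to sampling noise and `O(mu^2)` double-mutation terms.
#'
#' @param dist an [allele_freq_dist()].
#' @param mu per-meiosis single-step mutation probability, in `[0, 1]`.
#' @param family `"trio"` or `"duo"` (duos use the tested-parent convention:
#'   the single observed meiosis is the one that can mutate).
#' @param n number of families (default 1e6).
#' @param seed optional integer seed.
#' @return A list with `incompatible_families`, `families`,
#'   `observed_meioses`, and `incompatibility_rate` (per observed meiosis).
#' @examples
#' simulate_mia_study(constant_distribution(10), mu = 0.01, "trio",
#'                    n = 1e4, seed = 1)
#' @export
simulate_mia_study <- function(dist, mu, family = c("trio", "duo"), n = 1e6,
                               seed = NULL) {
  stopifnot(inherits(dist, "allele_freq_dist"))
  family <- match.arg(family)
  if (!is.numeric(mu) || length(mu) != 1L || is.na(mu) || mu < 0 || mu > 1)
    stop("'mu' must be a probability in [0, 1]", call. = FALSE)
  n <- as.integer(n)
  if (is.na(n) || n < 1) stop("'n' must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  step <- 10L
  if (family == "trio") {
    a1 <- .draw_keys(dist, n); a2 <- .draw_keys(dist, n)
    b1 <- .draw_keys(dist, n); b2 <- .draw_keys(dist, n)
    ta <- ifelse(stats::runif(n) < 0.5, a1, a2)
    tb <- ifelse(stats::runif(n) < 0.5, b1, b2)
    mut_a <- stats::runif(n) < mu
    mut_b <- stats::runif(n) < mu
    da <- ifelse(stats::runif(n) < 0.5, step, -step)
    db <- ifelse(stats::runif(n) < 0.5, step, -step)
    ca <- ifelse(mut_a, ta + da, ta)
    cb <- ifelse(mut_b, tb + db, tb)
    compat <- .trio_compat_vec(a1, a2, b1, b2, ca, cb)
    meioses <- 2L * n
  } else {
    a1 <- .draw_keys(dist, n); a2 <- .draw_keys(dist, n)
    t_allele <- ifelse(stats::runif(n) < 0.5, a1, a2)
    mut <- stats::runif(n) < mu
    d <- ifelse(stats::runif(n) < 0.5, step, -step)
    pop <- .draw_keys(dist, n)
    child1 <- ifelse(mut, t_allele + d, t_allele)
    compat <- .duo_compat_vec(a1, a2, child1, pop)
    meioses <- n
  }
  k <- sum(!compat)
  list(incompatible_families = k, families = n, observed_meioses = meioses,
       incompatibility_rate = k / meioses)
}
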