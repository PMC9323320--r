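# Brute-force enumeration oracle for the hidden-mutation probability.
#
# Walks the full outcome space of one-mutation familial configurations with
# explicit loops and the scalar compatibility predicates, independently of
# the factorized analytic sums in the exact engine. O(N^4) for trios, so use
# small ladders.
oracle_hidden_rate <- function(dist, family,
                               duo_convention = "tested_parent") {
  al <- dist$alleles
  p <- dist$frequencies
  N <- length(al)
  idx <- seq_len(N)
  h <- 0

  if (family == "trio") {
    # mutating parent's genotype (i, j), transmitted pick tc, direction d,
    # partner genotype (k, l), partner's contributed pick cc
    for (i in idx) for (j in idx) for (tc in 1:2) for (d in c(-1, 1)) {
      t_allele <- if (tc == 1) al[i] else al[j]
      m <- apply_single_step_mutation(t_allele, d)
      w1 <- p[i] * p[j] * 0.5 * 0.5  # genotype, pick, direction
      for (k in idx) for (l in idx) for (cc in 1:2) {
        cpart <- if (cc == 1) al[k] else al[l]
        if (trio_is_compatible(c(al[i], al[j]), c(al[k], al[l]),
                               c(m, cpart)))
          h <- h + w1 * p[k] * p[l] * 0.5
      }
    }
    return(h)
  }

  duo_branch <- function(mutate_tested) {
    acc <- 0
    for (i in idx) for (j in idx) for (tc in 1:2) for (d in c(-1, 1)) {
      t_allele <- if (tc == 1) al[i] else al[j]
      w1 <- p[i] * p[j] * 0.5 * 0.5
      for (k in idx) {
        child <- if (mutate_tested)
          c(apply_single_step_mutation(t_allele, d), al[k])
        else
          c(t_allele, apply_single_step_mutation(al[k], d))
        if (duo_is_compatible(c(al[i], al[j]), child))
          acc <- acc + w1 * p[k]
      }
    }
    acc
  }

  if (duo_convention == "tested_parent") return(duo_branch(TRUE))
  0.5 * duo_branch(TRUE) + 0.5 * duo_branch(FALSE)
}

# Random valid distribution: N alleles on a ladder starting at a random
# integer offset, Dirichlet(1) frequencies, optional microvariant suffix.
random_dirichlet_dist <- function(n, microvariant = FALSE,
                                  marker = "random") {
  offset <- sample(5:20, 1)
  alleles <- offset + seq_len(n) - 1
  if (microvariant) alleles <- alleles + 0.3
  w <- stats::rgamma(n, 1)
  allele_freq_dist(marker, alleles, w / sum(w))
}
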