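test_that("single-step mutation preserves microvariant suffix and may leave the ladder", {
  expect_equal(apply_single_step_mutation(10, +1), 11)
  expect_equal(apply_single_step_mutation(9.3, -1), 8.3)
  expect_equal(apply_single_step_mutation(9.3, +1), 10.3)
  # ladder boundary: no reflection or truncation
  expect_equal(apply_single_step_mutation(10, +1), 11)
  expect_equal(apply_single_step_mutation(c(7, 8.1), c(1, -1)), c(8, 7.1))
  expect_error(apply_single_step_mutation(10, 2))
})

test_that("duo compatibility requires a shared allele", {
  expect_true(duo_is_compatible(c(10, 11), c(11, 14)))
  expect_false(duo_is_compatible(c(10, 11), c(9, 13)))
  expect_false(duo_is_compatible(c(10, 10), c(9, 11)))
  expect_true(duo_is_compatible(c(9.3, 10), c(9.3, 12)))
})

test_that("trio compatibility requires one allele from each parent", {
  expect_true(trio_is_compatible(c(10, 11), c(12, 13), c(11, 12)))
  # homozygous child needs the allele in both parents
  expect_false(trio_is_compatible(c(10, 11), c(12, 13), c(11, 11)))
  expect_true(trio_is_compatible(c(11, 12), c(11, 13), c(11, 11)))
  expect_false(trio_is_compatible(c(10, 11), c(12, 13), c(9, 12)))
  # assignment may cross: child order does not matter
  expect_true(trio_is_compatible(c(10, 11), c(12, 13), c(12, 11)))
})

test_that("Monte-Carlo rates agree with the enumeration oracle", {
  set.seed(303)
  cases <- list(
    list(dist = constant_distribution(10), family = "trio", conv = "tested_parent"),
    list(dist = constant_distribution(10), family = "duo", conv = "tested_parent"),
    list(dist = constant_distribution(10), family = "duo", conv = "random_meiosis"),
    list(dist = random_dirichlet_dist(5, microvariant = TRUE), family = "trio",
         conv = "tested_parent"),
    list(dist = random_dirichlet_dist(6), family = "duo", conv = "random_meiosis")
  )
  for (cs in cases) {
    est <- simulate_hidden_rate(cs$dist, cs$family, n = 2e5, seed = 99,
                                duo_convention = cs$conv)
    truth <- oracle_hidden_rate(cs$dist, cs$family, cs$conv)
    expect_lt(abs(est$rate - truth), 4 * est$std_error + 1e-12,
              label = paste("MC vs oracle,", cs$dist$marker, cs$family, cs$conv))
  }
})

test_that("simulation is bit-reproducible under a fixed seed", {
  d <- constant_distribution(10)
  a <- simulate_hidden_rate(d, "trio", n = 5e4, seed = 123)
  b <- simulate_hidden_rate(d, "trio", n = 5e4, seed = 123)
  expect_identical(a$hidden_count, b$hidden_count)
  c2 <- simulate_hidden_rate(d, "trio", n = 5e4, seed = 124)
  expect_false(identical(a$hidden_count, c2$hidden_count))
})

test_that("degenerate single-allele ladder hides everything in duos, nothing in trios", {
  single <- allele_freq_dist("mono", 12, 1)
  expect_identical(simulate_hidden_rate(single, "duo", n = 1e4, seed = 1,
                                        duo_convention = "tested_parent")$rate, 1)
  expect_identical(simulate_hidden_rate(single, "trio", n = 1e4,
                                        seed = 1)$rate, 0)
})

test_that("hidden flags are self-consistent with the compatibility predicates", {
  set.seed(41)
  d <- random_dirichlet_dist(6)
  for (fam in c("trio", "duo")) {
    est <- simulate_hidden_rate(d, fam, n = 1e4, seed = 7,
                                keep_configs = TRUE)
    cfg <- est$configs
    expect_identical(sum(cfg$hidden), est$hidden_count)
    recheck <- if (fam == "trio") {
      vapply(seq_len(nrow(cfg)), function(i) {
        trio_is_compatible(c(cfg$parent1_a[i], cfg$parent1_b[i]),
                           c(cfg$parent2_a[i], cfg$parent2_b[i]),
                           c(cfg$child_a[i], cfg$child_b[i]))
      }, logical(1))
    } else {
      vapply(seq_len(nrow(cfg)), function(i) {
        duo_is_compatible(c(cfg$parent_a[i], cfg$parent_b[i]),
                          c(cfg$child_a[i], cfg$child_b[i]))
      }, logical(1))
    }
    expect_identical(recheck, cfg$hidden)
  }
})

test_that("MIA study produces incompatibilities at rate mu(1 - h)", {
  d <- constant_distribution(10)
  expect_identical(simulate_mia_study(d, mu = 0, "trio", n = 1e4,
                                      seed = 5)$incompatibility_rate, 0)
  res <- simulate_mia_study(d, mu = 0.01, "trio", n = 2e5, seed = 17)
  expected <- 0.01 * (1 - exact_hidden_rate(d, "trio"))
  se <- sqrt(expected * (1 - expected) / res$observed_meioses)
  expect_lt(abs(res$incompatibility_rate - expected), 4 * se)
  expect_identical(res$observed_meioses, 400000L)
  expect_error(simulate_mia_study(d, mu = 2, "trio"), "probability")
})
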