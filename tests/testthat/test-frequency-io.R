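test_that("construction validates and orders alleles", {
  d <- allele_freq_dist("M1", c(11, 10), c(0.5, 0.5))
  expect_equal(d$alleles, c(10, 11))
  expect_equal(sum(d$frequencies), 1)

  expect_error(allele_freq_dist("M1", numeric(0), numeric(0)),
               "at least one allele")
  expect_error(allele_freq_dist("M1", c(10, 10), c(0.5, 0.5)), "duplicate")
  expect_error(allele_freq_dist("M1", c(10, 11), c(-0.1, 1.1)), "negative")
  expect_error(allele_freq_dist("M1", c(10, 11), c(0.5, 0.4)), "malformed")
  expect_warning(d0 <- allele_freq_dist("M1", c(10, 11, 12),
                                        c(0.5, 0.5, 0)),
                 "zero-frequency")
  expect_equal(d0$alleles, c(10, 11))
})

test_that("near-1 frequency sums are renormalized to exactly 1", {
  suppressMessages(
    d <- allele_freq_dist("M1", c(10, 11), c(0.4995, 0.5))
  )
  expect_identical(sum(d$frequencies), 1)
  # within 1e-4: silent
  expect_silent(allele_freq_dist("M1", c(10, 11), c(0.49998, 0.5)))
  # beyond 1e-4 but within 1e-2: message
  expect_message(allele_freq_dist("M1", c(10, 11), c(0.497, 0.5)),
                 "renormalizing")
})

test_that("table reading validates format and splits markers", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("marker\tallele\tfrequency",
               "M2\t9\t0.25", "M1\t10\t0.5", "M1\t11\t0.5",
               "M2\t9.3\t0.5", "M2\t10\t0.25"), tf)
  dists <- read_freq_table(tf)
  expect_named(dists, c("M1", "M2"))
  expect_equal(dists$M1$frequencies, c(0.5, 0.5))
  expect_equal(dists$M2$alleles, c(9, 9.3, 10))

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("marker\tallele", "M1\t10"), bad)
  expect_error(read_freq_table(bad), "missing column")

  writeLines(c("marker\tallele\tfrequency", "M1\t10\tabc"), bad)
  expect_error(read_freq_table(bad), "non-numeric frequency")

  writeLines(c("marker\tallele\tfrequency",
               "M1\t10\t0.5", "M1\t10\t0.5"), bad)
  expect_error(read_freq_table(bad), "duplicate")

  expect_error(read_freq_table("no/such/file.tsv"), "not found")
})

test_that("write/read round trip preserves labels and frequencies", {
  set.seed(7)
  dists <- list(random_dirichlet_dist(8, marker = "A"),
                random_dirichlet_dist(5, microvariant = TRUE, marker = "B"))
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_freq_table(dists, tf)
  back <- read_freq_table(tf)
  for (d in dists) {
    expect_equal(back[[d$marker]]$alleles, d$alleles, tolerance = 1e-12)
    expect_equal(back[[d$marker]]$frequencies, d$frequencies,
                 tolerance = 1e-12)
  }
})

test_that("heterozygosity and PIC match direct evaluation", {
  expect_equal(heterozygosity(constant_distribution(10)), 0.9)
  single <- allele_freq_dist("S", 12, 1)
  expect_equal(heterozygosity(single), 0)
  expect_equal(pic(single), 0)
  d <- allele_freq_dist("M", c(8, 9, 10), c(0.5, 0.3, 0.2))
  expect_equal(heterozygosity(d), 0.62)
  d2 <- allele_freq_dist("M", c(8, 9), c(0.5, 0.5))
  expect_equal(pic(d2), 0.375)  # 1 - 0.5 - 2 * 0.0625
  u10 <- constant_distribution(10)
  expect_lt(pic(u10), heterozygosity(u10))
})

test_that("summary statistics are invariant to input row order and bounded", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(2:12, 1)
    d <- random_dirichlet_dist(n)
    perm <- sample(n)
    d2 <- allele_freq_dist(d$marker, d$alleles[perm], d$frequencies[perm])
    expect_equal(heterozygosity(d2), heterozygosity(d))
    expect_equal(pic(d2), pic(d))
    # 0 <= pic <= H <= 1 - 1/N
    expect_gte(pic(d), 0)
    expect_lte(pic(d), heterozygosity(d))
    expect_lte(heterozygosity(d), 1 - 1 / n + 1e-12)
  }
  # uniform ladder attains the upper bound exactly
  expect_equal(heterozygosity(constant_distribution(7)), 1 - 1 / 7)
})

test_that("allelic span reports range and count", {
  expect_equal(allelic_span(constant_distribution(10)),
               list(min_allele = 1, max_allele = 10, allele_count = 10L))
  d <- allele_freq_dist("TH01ish", c(9, 9.3, 10), c(0.3, 0.3, 0.4))
  expect_equal(allelic_span(d),
               list(min_allele = 9, max_allele = 10, allele_count = 3L))
  s <- marker_summary(d)
  expect_equal(s$allele_count, 3L)
  expect_equal(s$heterozygosity, heterozygosity(d))
})
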