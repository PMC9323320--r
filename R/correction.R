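#' Correct an observed Mendelian-incompatibility rate for hidden mutations
#'
#' Mutation-rate studies based on Mendelian incompatibilities only count the
#' mutations that produce an incompatible genotype configuration; the
#' fraction `h` of mutations that stay compatible ("hidden") is missed. Given
#' an observed per-meiosis incompatibility rate `R` and the hidden-mutation
#' probability `h` for the marker and family design, the unbiased mutation
#' rate estimate is `R / (1 - h)`.
#'
#' @param R observed incompatibility rate per observed meiosis, in `[0, 1]`.
#' @param h hidden-mutation probability, in `[0, 1)`. `h` effectively equal
#'   to 1 (all mutations hidden, e.g. a monomorphic marker observed in duos)
#'   leaves the mutation rate unidentifiable and is an error.
#' @param family optionally record the family design (`"duo"`/`"trio"`).
#' @param duo_convention optionally record the duo convention used for `h`.
#' @return An object of class `correction_result`: a list with
#'   `incompatibility_rate`, `hidden_rate`, `corrected_rate`, `family`,
#'   `duo_convention`.
#' @examples
#' correct_incompatibility_rate(R = 0.002, h = 0.546)  # corrected ~ 0.0044
#' @export
correct_incompatibility_rate <- function(R, h, family = NA_character_,
                                         duo_convention = NA_character_) {
  if (!is.numeric(R) || length(R) != 1L || is.na(R) || R < 0 || R > 1)
    stop("'R' must be a rate in [0, 1]", call. = FALSE)
  if (!is.numeric(h) || length(h) != 1L || is.na(h) || h < 0 || h > 1)
    stop("'h' must be a probability in [0, 1]", call. = FALSE)
  if (h >= 1 - 1e-9)
    stop("correction undefined: hidden rate is (numerically) 1, ",
         "all mutations are hidden", call. = FALSE)
  structure(
    list(incompatibility_rate = R, hidden_rate = h,
         corrected_rate = R / (1 - h),
         family = family, duo_convention = duo_convention),
    class = "correction_result"
  )
}

#' @export
print.correction_result <- function(x, ...) {
  cat("Mutation-rate correction for hidden mutations\n")
  if (!is.na(x$family)) cat("  family:", x$family,
                            if (!is.na(x$duo_convention)) x$duo_convention,
                            "\n")
  cat("  observed incompatibility rate R: ",
      format(x$incompatibility_rate, digits = 6), "\n", sep = "")
  cat("  hidden-mutation rate h:          ",
      format(x$hidden_rate, digits = 6), "\n", sep = "")
  cat("  corrected rate R/(1-h):          ",
      format(x$corrected_rate, digits = 6), "\n", sep = "")
  if (!is.null(x$conf_int))
    cat("  ", format(100 * x$conf_level), "% CI: [",
        format(x$conf_int[1], digits = 6), ", ",
        format(x$conf_int[2], digits = 6), "]\n", sep = "")
  invisible(x)
}

#' Correct an incompatibility rate using a marker's frequency distribution
#'
#' Computes the hidden-mutation probability `h` for the marker by exact
#' enumeration ([exact_hidden_rate()]) and applies the `R / (1 - h)`
#' correction. Only the allele-frequency distribution, the observed
#' incompatibility rate, and the family design are needed.
#'
#' For trios, `R` is expected per observed meiosis (incompatible families
#' divided by twice the number of families), so corrected values are
#' per-meiosis rates comparable across family types.
#'
#' @inheritParams correct_incompatibility_rate
#' @param dist an [allele_freq_dist()].
#' @param family `"trio"` or `"duo"`.
#' @param duo_convention duo convention for `h`; `"tested_parent"` (default)
#'   matches studies that count mutations per observed meiosis.
#' @return A `correction_result`; see [correct_incompatibility_rate()].
#' @examples
#' correct_from_distribution(0.001, constant_distribution(10), "trio")
#' @export
correct_from_distribution <- function(R, dist, family = c("trio", "duo"),
                                      duo_convention = c("tested_parent",
                                                         "random_meiosis")) {
  family <- match.arg(family)
  duo_convention <- match.arg(duo_convention)
  h <- exact_hidden_rate(dist, family, duo_convention)
  correct_incompatibility_rate(
    R, h, family = family,
    duo_convention = if (family == "duo") duo_convention else NA_character_
  )
}

#' Confidence interval for a corrected mutation rate
#'
#' Wilson score interval for the observed incompatibility proportion, scaled
#' by the correction factor `1/(1 - h)`. The hidden rate `h` is treated as
#' known (it is computed by exact enumeration, not estimated).
#'
#' @param incompatible_count number of incompatible meioses observed.
#' @param observed_meioses total observed meioses (`>= 1`).
#' @param h hidden-mutation probability in `[0, 1)`.
#' @param conf_level confidence level, default 0.95.
#' @return A `correction_result` with additional elements `conf_int`
#'   (length-2 numeric) and `conf_level`.
#' @examples
#' correction_interval(12, 10000, h = 0.105)
#' @export
correction_interval <- function(incompatible_count, observed_meioses, h,
                                conf_level = 0.95) {
  if (!is.numeric(incompatible_count) || incompatible_count < 0 ||
      incompatible_count != round(incompatible_count))
    stop("'incompatible_count' must be a non-negative integer", call. = FALSE)
  if (!is.numeric(observed_meioses) || observed_meioses < 1 ||
      observed_meioses != round(observed_meioses))
    stop("'observed_meioses' must be a positive integer", call. = FALSE)
  if (incompatible_count > observed_meioses)
    stop("'incompatible_count' cannot exceed 'observed_meioses'",
         call. = FALSE)
  R <- incompatible_count / observed_meioses
  res <- correct_incompatibility_rate(R, h)
  # prop.test without continuity correction gives the Wilson score interval
  ci <- stats::prop.test(incompatible_count, observed_meioses,
                         conf.level = conf_level, correct = FALSE)$conf.int
  res$conf_int <- as.numeric(ci) / (1 - h)
  res$conf_level <- conf_level
  res
}
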