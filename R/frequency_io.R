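#' Construct a per-marker allele-frequency distribution
#'
#' An `allele_freq_dist` holds the allele ladder of one microsatellite (STR)
#' marker together with the relative frequency of each allele in a population.
#' Allele labels are the usual repeat counts; microvariants carry a
#' one-decimal fractional suffix (e.g. `9.3` for TH01).
#'
#' Frequencies must be strictly positive and are renormalized to sum exactly
#' to 1. Rows with zero frequency are dropped with a warning (an allele absent
#' from the population is representable implicitly: a mutant stepping onto it
#' simply never matches a sampled allele). A frequency sum deviating from 1 by
#' more than `1e-2` signals a malformed table and is a hard error; smaller
#' deviations (typical of published, rounded tables) are renormalized, with a
#' message when the deviation exceeds `1e-4`.
#'
#' @param marker single character label for the marker.
#' @param alleles numeric vector of allele labels (repeat counts, optionally
#'   with one-decimal microvariant suffix). Must be unique; they are stored in
#'   increasing order.
#' @param frequencies numeric vector of relative frequencies, one per allele.
#'
#' @return An object of class `allele_freq_dist`: a list with elements
#'   `marker`, `alleles` (increasing), and `frequencies` (summing to 1).
#'
#' @examples
#' d <- allele_freq_dist("TH01", c(6, 7, 8, 9, 9.3), c(0.2, 0.2, 0.1, 0.2, 0.3))
#' heterozygosity(d)
#' @export
allele_freq_dist <- function(marker, alleles, frequencies) {
  stopifnot(is.character(marker), length(marker) == 1L, !is.na(marker))
  alleles <- as.numeric(alleles)
  frequencies <- as.numeric(frequencies)
  if (length(alleles) == 0L)
    stop("distribution must contain at least one allele", call. = FALSE)
  if (length(alleles) != length(frequencies))
    stop("'alleles' and 'frequencies' must have equal length", call. = FALSE)
  if (anyNA(alleles) || anyNA(frequencies))
    stop("alleles and frequencies must be non-missing numbers", call. = FALSE)
  if (any(frequencies < 0))
    stop("negative allele frequency in marker '", marker, "'", call. = FALSE)
  if (any(frequencies == 0)) {
    warning("dropping ", sum(frequencies == 0), " zero-frequency allele(s) in marker '",
            marker, "'", call. = FALSE)
    keep <- frequencies > 0
    alleles <- alleles[keep]
    frequencies <- frequencies[keep]
    if (length(alleles) == 0L)
      stop("all frequencies are zero in marker '", marker, "'", call. = FALSE)
  }
  if (anyDuplicated(.allele_key(alleles)))
    stop("duplicate allele labels in marker '", marker, "'", call. = FALSE)
  ord <- order(alleles)
  alleles <- alleles[ord]
  frequencies <- frequencies[ord]
  s <- sum(frequencies)
  if (abs(s - 1) > 1e-2)
    stop("frequencies of marker '", marker, "' sum to ", format(s),
         "; deviation from 1 exceeds 0.01 -- malformed table", call. = FALSE)
  if (abs(s - 1) > 1e-4)
    message("renormalizing frequencies of marker '", marker,
            "' (sum was ", format(s), ")")
  frequencies <- frequencies / s
  # absorb any remaining ulp-level residual so the sum is exactly 1
  imax <- which.max(frequencies)
  frequencies[imax] <- frequencies[imax] + (1 - sum(frequencies))
  structure(
    list(marker = marker, alleles = alleles, frequencies = frequencies),
    class = "allele_freq_dist"
  )
}

# Alleles carry at most one decimal (microvariants such as 9.3), so integer
# tenths of a repeat unit are an exact internal representation: equality tests
# and +/- one-repeat steps never suffer floating-point drift.
.allele_key <- function(allele) as.integer(round(allele * 10))

.key_to_allele <- function(key) key / 10

#' @export
print.allele_freq_dist <- function(x, ...) {
  cat("Allele-frequency distribution for marker '", x$marker, "'\n", sep = "")
  cat("  alleles:", length(x$alleles), " span: [",
      min(x$alleles), ", ", max(x$alleles), "]\n", sep = "")
  cat("  heterozygosity: ", format(heterozygosity(x), digits = 4),
      "  PIC: ", format(pic(x), digits = 4), "\n", sep = "")
  invisible(x)
}

#' Read per-marker allele-frequency tables
#'
#' Reads a long-format table with columns `marker`, `allele`, `frequency`
#' (tab-separated by default, UTF-8, dot decimal separator) — the layout of
#' typical forensic frequency exports — and returns one validated
#' [allele_freq_dist()] per distinct marker.
#'
#' @param path path to the table.
#' @param sep field separator, `"\t"` by default.
#'
#' @return A named list of `allele_freq_dist` objects, ordered by marker name;
#'   alleles within each marker in increasing order.
#'
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' write_freq_table(list(constant_distribution(4)), tf)
#' dists <- read_freq_table(tf)
#' dists[[1]]
#' @export
read_freq_table <- function(path, sep = "\t") {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", fileEncoding = "UTF-8",
                           stringsAsFactors = FALSE, check.names = FALSE)
  names(tab) <- tolower(names(tab))
  needed <- c("marker", "allele", "frequency")
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  allele <- suppressWarnings(as.numeric(tab$allele))
  freq <- suppressWarnings(as.numeric(tab$frequency))
  if (anyNA(allele))
    stop("non-numeric allele label(s): ",
         paste(unique(tab$allele[is.na(allele)]), collapse = ", "),
         call. = FALSE)
  if (anyNA(freq))
    stop("non-numeric frequency value(s): ",
         paste(unique(tab$frequency[is.na(freq)]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(paste(tab$marker, .allele_key(allele))))
    stop("duplicate (marker, allele) pair(s) in table", call. = FALSE)
  markers <- sort(unique(tab$marker))
  out <- lapply(markers, function(m) {
    i <- tab$marker == m
    allele_freq_dist(m, allele[i], freq[i])
  })
  names(out) <- markers
  out
}

#' Write allele-frequency distributions to a long-format table
#'
#' Inverse of [read_freq_table()]: emits `marker  allele  frequency` rows
#' with full double precision, so a write/read round trip reproduces labels
#' and frequencies to numerical accuracy.
#'
#' @param dists a single `allele_freq_dist` or a list of them.
#' @param path output path.
#' @param sep field separator, `"\t"` by default.
#' @return Invisibly, `path`.
#' @export
write_freq_table <- function(dists, path, sep = "\t") {
  if (inherits(dists, "allele_freq_dist")) dists <- list(dists)
  stopifnot(all(vapply(dists, inherits, logical(1), "allele_freq_dist")))
  rows <- do.call(rbind, lapply(dists, function(d) {
    data.frame(marker = d$marker,
               allele = format(d$alleles, digits = 15, trim = TRUE),
               frequency = format(d$frequencies, digits = 17, trim = TRUE),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = sep, quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Expected heterozygosity of a marker
#'
#' Computes `1 - sum(p_i^2)`, the probability that two alleles drawn at
#' random from the population differ.
#'
#' @param dist an [allele_freq_dist()].
#' @return A number in `[0, 1 - 1/N]` for an `N`-allele marker.
#' @examples
#' heterozygosity(constant_distribution(10)) # 0.9
#' @export
heterozygosity <- function(dist) {
  stopifnot(inherits(dist, "allele_freq_dist"))
  1 - sum(dist$frequencies^2)
}

#' Polymorphism information content (PIC) of a marker
#'
#' `PIC = 1 - sum(p_i^2) - sum_{i<j} 2 p_i^2 p_j^2`; always at most the
#' expected heterozygosity.
#'
#' @inheritParams heterozygosity
#' @return A number in `[0, heterozygosity(dist)]`.
#' @export
pic <- function(dist) {
  stopifnot(inherits(dist, "allele_freq_dist"))
  p2 <- dist$frequencies^2
  # sum_{i<j} 2 p_i^2 p_j^2 = (sum p^2)^2 - sum p^4
  1 - sum(p2) - (sum(p2)^2 - sum(p2^2))
}

#' Allelic span of a marker
#'
#' @inheritParams heterozygosity
#' @return A list with `min_allele`, `max_allele`, and `allele_count`.
#' @export
allelic_span <- function(dist) {
  stopifnot(inherits(dist, "allele_freq_dist"))
  list(min_allele = min(dist$alleles),
       max_allele = max(dist$alleles),
       allele_count = length(dist$alleles))
}

#' Summarize a marker's distribution
#'
#' @inheritParams heterozygosity
#' @return A one-row data frame with marker id, heterozygosity, PIC, allele
#'   count, and allelic range.
#' @export
marker_summary <- function(dist) {
  sp <- allelic_span(dist)
  data.frame(marker = dist$marker,
             heterozygosity = heterozygosity(dist),
             pic = pic(dist),
             allele_count = sp$allele_count,
             min_allele = sp$min_allele,
             max_allele = sp$max_allele,
             stringsAsFactors = FALSE)
}
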