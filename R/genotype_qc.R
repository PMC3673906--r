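#' Exact test of Hardy-Weinberg equilibrium
#'
#' Exact conditional test for a biallelic locus: given the observed
#' allele counts, the probability of each attainable heterozygote count
#' (those matching the parity of the minor-allele count) is computed by
#' the standard recurrence over heterozygote counts, and the p-value is
#' the sum of probabilities of all configurations at most as probable
#' as the observed one (the cumulative "observed or less probable"
#' form, not the mid-p variant). Monomorphic loci have a single
#' attainable configuration and return 1.
#'
#' @param n_AA,n_AB,n_BB non-negative genotype counts (vectorized).
#' @return Exact p-value(s) in (0, 1].
#' @examples
#' hwe_exact_test(1, 0, 1)
#' hwe_exact_test(100, 120, 40)
#' @export
hwe_exact_test <- function(n_AA, n_AB, n_BB) {
  stopifnot(length(n_AA) == length(n_AB), length(n_AB) == length(n_BB),
            all(n_AA >= 0), all(n_AB >= 0), all(n_BB >= 0))
  mapply(hwe_exact_one, n_AA, n_AB, n_BB)
}

hwe_exact_one <- function(nAA, nAB, nBB) {
  n <- nAA + nAB + nBB
  if (n < 1) stop("at least one called genotype required", call. = FALSE)
  # work with the rarer allele
  nA <- 2 * nAA + nAB
  nB <- 2 * nBB + nAB
  rare <- min(nA, nB)
  if (rare == 0) return(1)
  # attainable heterozygote counts share the parity of the rare count
  het_values <- seq(rare %% 2, rare, by = 2)
  # start from the largest heterozygote count and recurse downward:
  # P(nAB-2) / P(nAB) = nAB (nAB - 1) / (4 (nAA + 1) (nBB + 1))
  i0 <- length(het_values)
  lp <- numeric(i0)         # log-space keeps large-n tails finite
  lp[i0] <- 0
  for (i in rev(seq_len(i0 - 1L))) {
    het <- het_values[i + 1L]
    hom_rare <- (rare - het) / 2
    hom_common <- n - het - hom_rare
    lp[i] <- lp[i + 1L] + log(het) + log(het - 1) -
      log(4) - log(hom_rare + 1) - log(hom_common + 1)
  }
  m <- max(lp)
  probs <- exp(lp - m) / sum(exp(lp - m))
  obs <- which(het_values == nAB)
  if (!length(obs))
    stop("genotype counts inconsistent with allele parity", call. = FALSE)
  min(1, sum(probs[probs <= probs[obs] * (1 + 1e-12)]))
}

#' Apply a call-quality threshold to a genotype matrix
#'
#' Genotype calls whose per-call quality score falls below the
#' threshold are treated as unsuccessful and replaced by NC (no call),
#' mirroring the vendor recommendation of discarding calls with
#' confidence scores below 0.15.
#'
#' @param calls character matrix of genotype calls (AA/AB/BB/NC).
#' @param quality numeric matrix of per-call quality scores in [0, 1],
#'   same dimensions.
#' @param threshold minimum acceptable score (default 0.15).
#' @return The call matrix with sub-threshold calls set to "NC".
#' @export
apply_call_threshold <- function(calls, quality, threshold = 0.15) {
  stopifnot(identical(dim(calls), dim(quality)))
  calls[quality < threshold] <- "NC"
  calls
}

#' Per-locus genotyping QC metrics
#'
#' For each locus of a genotype call matrix computes: the number of
#' called samples and call frequency; genotype counts; minor allele
#' frequency among called genotypes; observed heterozygosity (n_AB /
#' n_called); expected heterozygosity 2pq; the exact
#' Hardy-Weinberg p-value; and the pass/success indicators. A locus is
#' "successful" when its call frequency reaches \code{min_call_rate}
#' and it is polymorphic (MAF > 0). Loci with zero called samples get
#' NA metrics.
#'
#' @param calls character matrix (loci x samples) of AA/AB/BB/NC calls.
#' @param min_call_rate call-frequency threshold for success (default
#'   0.85).
#' @return Data frame with one row per locus: locus_id, n_samples,
#'   n_called, call_frequency, n_AA, n_AB, n_BB, maf, ho, he, hwe_p,
#'   pass_call_rate, polymorphic, successful.
#' @export
locus_qc <- function(calls, min_call_rate = 0.85) {
  stopifnot(is.matrix(calls), ncol(calls) >= 1)
  bad <- !(calls %in% c("AA", "AB", "BB", "NC"))
  if (any(bad)) stop("calls must be AA, AB, BB or NC", call. = FALSE)
  n_samples <- ncol(calls)
  n_AA <- rowSums(calls == "AA")
  n_AB <- rowSums(calls == "AB")
  n_BB <- rowSums(calls == "BB")
  n_called <- n_AA + n_AB + n_BB
  call_frequency <- n_called / n_samples
  p_B <- ifelse(n_called > 0, (2 * n_BB + n_AB) / (2 * n_called), NA)
  maf <- pmin(p_B, 1 - p_B)
  ho <- ifelse(n_called > 0, n_AB / n_called, NA)
  he <- 2 * p_B * (1 - p_B)
  hwe_p <- rep(NA_real_, nrow(calls))
  ok <- n_called > 0
  hwe_p[ok] <- hwe_exact_test(n_AA[ok], n_AB[ok], n_BB[ok])
  ids <- rownames(calls)
  if (is.null(ids)) ids <- sprintf("locus%05d", seq_len(nrow(calls)))
  data.frame(
    locus_id = ids, n_samples = n_samples, n_called = n_called,
    call_frequency = call_frequency, n_AA = n_AA, n_AB = n_AB,
    n_BB = n_BB, maf = maf, ho = ho, he = he, hwe_p = hwe_p,
    pass_call_rate = call_frequency >= min_call_rate,
    polymorphic = !is.na(maf) & maf > 0,
    successful = call_frequency >= min_call_rate & !is.na(maf) & maf > 0,
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Summarize a genotyping-array run
#'
#' Builds the array-level accounting from per-locus QC: counts of
#' attempted, assayed, called (call rate passed) and successful
#' (called and polymorphic) loci; the conversion rates on the attempted
#' and assayed bases; the Bonferroni-corrected per-test
#' Hardy-Weinberg threshold \code{family_alpha / n_successful}; and the
#' number and fraction of successful loci deviating from HWE at that
#' threshold.
#'
#' @param qc per-locus QC from \code{\link{locus_qc}} for the assayed
#'   loci.
#' @param n_attempted number of loci submitted for array manufacture;
#'   defaults to the number assayed.
#' @param family_alpha family-wise error rate for the HWE screen
#'   (default 0.05).
#' @return List of class \code{"array_summary"}: counts, percentage
#'   grid (via \code{\link{array_summary_table}}), bonferroni_alpha,
#'   n_hwe_deviant, pct_hwe_deviant, and the per-locus hwe_flag vector.
#' @export
summarize_array <- function(qc, n_attempted = nrow(qc),
                            family_alpha = 0.05) {
  n_assayed <- nrow(qc)
  n_called <- sum(qc$pass_call_rate)
  n_successful <- sum(qc$successful)
  if (n_successful == 0) {
    warning("no successful loci; Bonferroni threshold undefined")
    bonf <- NA_real_
  } else {
    bonf <- family_alpha / n_successful
  }
  hwe_flag <- qc$successful & !is.na(qc$hwe_p) & qc$hwe_p < bonf
  n_dev <- sum(hwe_flag, na.rm = TRUE)
  structure(list(
    n_attempted = n_attempted, n_assayed = n_assayed,
    n_called = n_called, n_successful = n_successful,
    table = array_summary_table(n_attempted, n_assayed, n_called,
                                n_successful),
    bonferroni_alpha = bonf,
    n_hwe_deviant = n_dev,
    pct_hwe_deviant = if (n_successful > 0) pct(n_dev, n_successful)
                      else NA_real_,
    hwe_flag = hwe_flag), class = "array_summary")
}

#' Array accounting percentage grid
#'
#' Given the four category counts of an array run, recomputes every
#' category's percentage on the attempted and assayed bases, the
#' conversion rates, and the fraction of called loci that are
#' polymorphic, all rounded half away from zero to one decimal.
#'
#' @param n_attempted,n_assayed,n_called,n_successful category counts;
#'   must be non-increasing in that order.
#' @return Data frame with rows attempted/assayed/called/successful and
#'   columns count, pct_of_attempted, pct_of_assayed, plus attribute
#'   \code{pct_called_polymorphic}.
#' @examples
#' array_summary_table(8769, 8067, 7256, 5847)
#' @export
array_summary_table <- function(n_attempted, n_assayed, n_called,
                                n_successful) {
  if (!(n_successful <= n_called && n_called <= n_assayed &&
        n_assayed <= n_attempted))
    stop("counts must satisfy successful <= called <= assayed <= attempted",
         call. = FALSE)
  counts <- c(attempted = n_attempted, assayed = n_assayed,
              called = n_called, successful = n_successful)
  out <- data.frame(
    category = names(counts), count = unname(counts),
    pct_of_attempted = pct(unname(counts), n_attempted),
    pct_of_assayed = pct(unname(counts), n_assayed),
    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "pct_called_polymorphic") <- pct(n_successful, n_called)
  out
}

#' Histogram table of a locus metric
#'
#' Bins a per-locus metric (MAF, observed or expected heterozygosity)
#' into fixed-width bins for summary plots and tables.
#'
#' @param x numeric vector of per-locus values.
#' @param breaks bin edges (default \code{seq(0, 0.5, 0.05)} suits MAF).
#' @return Data frame: bin, count.
#' @export
metric_histogram <- function(x, breaks = seq(0, 0.5, 0.05)) {
  x <- x[!is.na(x)]
  h <- hist(x, breaks = breaks, plot = FALSE, include.lowest = TRUE,
            right = TRUE)
  data.frame(
    bin = sprintf("(%.3g,%.3g]", h$breaks[-length(h$breaks)],
                  h$breaks[-1]),
    count = h$counts, stringsAsFactors = FALSE)
}
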