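#' Parameters for pooled-sample variant calling
#'
#' Bundles the thresholds applied during per-dataset site calling. The
#' defaults reflect common practice for pooled transcriptome resequencing:
#' a minor-allele-frequency boundary of 0.01 and per-base error rate of
#' 0.01 for the composite-null binomial test, a minimum depth of 5 reads
#' and at least 2 alternative-allele reads for a variant to be considered,
#' base and mapping quality floors of 20, and a per-site read cap of
#' 20,000.
#'
#' @param maf_threshold boundary population minor allele frequency of the
#'   composite null hypothesis (theta), in (0, 1).
#' @param error_rate per-base sequencing error probability (e), in (0, 1).
#' @param min_depth minimum total read depth for a site to be callable.
#' @param min_alt minimum number of reads carrying the alternative allele.
#' @param min_baseq minimum base quality (phred); bases below this are
#'   treated as N when qualities are available.
#' @param min_mapq minimum root-mean-square mapping quality for a call.
#' @param max_reads maximum read depth considered at one site; deeper
#'   sites are skipped with a warning.
#' @return A list of class \code{"caller_params"}.
#' @examples
#' p <- caller_params()
#' p$maf_threshold
#' @export
caller_params <- function(maf_threshold = 0.01, error_rate = 0.01,
                          min_depth = 5L, min_alt = 2L,
                          min_baseq = 20L, min_mapq = 20L,
                          max_reads = 20000L) {
  stopifnot(
    is.numeric(maf_threshold), length(maf_threshold) == 1L,
    maf_threshold > 0, maf_threshold < 1,
    is.numeric(error_rate), length(error_rate) == 1L,
    error_rate > 0, error_rate < 1,
    min_depth >= 0, min_alt >= 0, min_baseq >= 0, min_mapq >= 0,
    max_reads >= 1
  )
  structure(
    list(maf_threshold = maf_threshold, error_rate = error_rate,
         min_depth = as.integer(min_depth), min_alt = as.integer(min_alt),
         min_baseq = as.integer(min_baseq), min_mapq = as.integer(min_mapq),
         max_reads = as.integer(max_reads)),
    class = "caller_params"
  )
}

#' Configuration for target-SNP filtering and array candidate selection
#'
#' @param ps_threshold per-dataset SNP probability threshold (P_S) that a
#'   target SNP must beat in at least one dataset; typically 1e-2, 1e-3
#'   or 1e-4.
#' @param min_mapq mapping quality that must be exceeded in at least one
#'   dataset (strictly greater than).
#' @param min_snp_spacing minimum spacing (nt) between two selected SNPs
#'   on the same isotig within the priority set.
#' @param max_snps_per_isotig maximum SNPs selected per isotig for
#'   priority (differentially expressed / annotation-selected) genes.
#' @param min_datasets minimum number of detecting datasets required for
#'   non-priority SNPs.
#' @param min_design_score minimum acceptable assay design score.
#' @param min_mean_reads minimum mean covering-read count across
#'   detecting datasets.
#' @param min_mean_freq minimum mean minor-allele read frequency across
#'   detecting datasets.
#' @param excluded_classes assembly confidence classes whose SNPs are not
#'   considered for the array.
#' @param indel_adjacency_window distance (nt) within which a masked
#'   indel position disqualifies a target SNP.
#' @return A list of class \code{"selection_config"}.
#' @export
selection_config <- function(ps_threshold = 1e-4, min_mapq = 40,
                             min_snp_spacing = 50L,
                             max_snps_per_isotig = 2L,
                             min_datasets = 2L,
                             min_design_score = 0.60,
                             min_mean_reads = 10,
                             min_mean_freq = 0.05,
                             excluded_classes = c("C5", "C6"),
                             indel_adjacency_window = 10L) {
  stopifnot(ps_threshold > 0, min_snp_spacing >= 1, max_snps_per_isotig >= 1,
            min_datasets >= 1, min_design_score >= 0, min_mean_reads >= 0,
            min_mean_freq >= 0, indel_adjacency_window >= 0)
  structure(
    list(ps_threshold = ps_threshold, min_mapq = min_mapq,
         min_snp_spacing = as.integer(min_snp_spacing),
         max_snps_per_isotig = as.integer(max_snps_per_isotig),
         min_datasets = as.integer(min_datasets),
         min_design_score = min_design_score,
         min_mean_reads = min_mean_reads,
         min_mean_freq = min_mean_freq,
         excluded_classes = as.character(excluded_classes),
         indel_adjacency_window = as.integer(indel_adjacency_window)),
    class = "selection_config"
  )
}

# round half away from zero to `digits` decimals (report style)
round_half_up <- function(x, digits = 1L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Percentage of a count over a base, report-rounded
#'
#' Computes \code{100 * num / den} rounded half away from zero to one
#' decimal place, the convention used in the package's summary tables.
#'
#' @param num numerator count.
#' @param den denominator count.
#' @param digits decimal places (default 1).
#' @return Numeric percentage.
#' @examples
#' pct(5847, 8067)  # 72.5
#' @export
pct <- function(num, den, digits = 1L) {
  stopifnot(den != 0)
  round_half_up(100 * num / den, digits)
}

# deterministic child seed from a master seed and a component tag,
# kept below 2^31 so set.seed() accepts it
child_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)) * 131L)
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}
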