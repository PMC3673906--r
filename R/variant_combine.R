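#' Combine per-dataset variant probabilities with Fisher's method
#'
#' Computes X^2 = -2 * sum(ln p_i) over the supplied per-dataset
#' probabilities and evaluates the chi-square upper tail at 2k degrees
#' of freedom (k = number of probabilities) with the even-df closed
#' form: P = exp(-x/2) * sum_{i=0}^{k-1} (x/2)^i / i!, accumulated in
#' log space for stability. With five datasets this is the ten-degree-
#' of-freedom combination used for the pooled across-dataset SNP
#' probability. Datasets with no computed probability at a site are
#' simply omitted, shrinking the degrees of freedom accordingly.
#'
#' @param p_values numeric vector of probabilities in (0, 1]; zeros are
#'   clamped at \code{p_floor} with a warning (ln 0 is undefined).
#' @param p_floor underflow floor for zero probabilities.
#' @return List with \code{chi_sq}, \code{df} (= 2 * length(p_values))
#'   and \code{pooled_p}.
#' @examples
#' fisher_combine(rep(0.5, 5))
#' @export
fisher_combine <- function(p_values, p_floor = 1e-300) {
  p_values <- p_values[!is.na(p_values)]
  if (!length(p_values)) stop("no probabilities to combine", call. = FALSE)
  if (any(p_values > 1) || any(p_values < 0))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (any(p_values == 0)) {
    warning("zero probabilities clamped at the underflow floor")
    p_values <- pmax(p_values, p_floor)
  }
  chi_sq <- -2 * sum(log(p_values))
  k <- length(p_values)
  list(chi_sq = chi_sq, df = 2L * k,
       pooled_p = chisq_upper_even(chi_sq, k))
}

# chi-square upper tail for even df = 2k via the closed-form Poisson sum,
# evaluated in log space: sum_i exp(-x/2 + i*log(x/2) - log(i!))
chisq_upper_even <- function(x, k) {
  if (x <= 0) return(1)
  i <- 0:(k - 1L)
  terms <- -x / 2 + i * log(x / 2) - lgamma(i + 1)
  m <- max(terms)
  min(1, exp(m + log(sum(exp(terms - m)))))
}

#' Merge per-dataset site calls into a combined variant table
#'
#' Joins SNP candidate calls from several datasets on (isotig,
#' position), verifies reference-base consistency, and computes, per
#' variant: the set of per-dataset probabilities (absent datasets
#' omitted), the Fisher combination (\code{chi_sq}, \code{df},
#' \code{pooled_p}), the allele union across datasets, the minimum
#' per-dataset probability, the maximum mapping quality, the number of
#' detecting datasets, and mean covering reads / mean alternative-allele
#' frequency over detecting datasets. Only calls retained by the
#' first-stage filters participate. Indel calls may be merged alongside;
#' indels from datasets listed in \code{indel_untrusted} (e.g. platforms
#' whose homopolymer errors make indel calls unreliable) are dropped
#' before merging.
#'
#' @param snv_calls data frame of per-dataset calls
#'   (\code{\link{call_snvs}} output, possibly row-bound over datasets).
#' @param indel_calls optional data frame from \code{\link{call_indels}}.
#' @param indel_untrusted character vector of dataset_ids whose indel
#'   calls are discarded.
#' @return List with \code{snps} and \code{indels} data frames. The SNP
#'   table has one row per (isotig, pos) with columns isotig, pos, ref,
#'   n_datasets, alleles (comma-joined union including ref), min_p,
#'   mean_p, chi_sq, df, pooled_p, max_mapq, mean_reads, mean_freq, and
#'   one \code{p_<dataset>} column per dataset present in the input.
#' @export
merge_datasets <- function(snv_calls, indel_calls = NULL,
                           indel_untrusted = character()) {
  calls <- snv_calls[snv_calls$retained, , drop = FALSE]
  ds <- sort(unique(snv_calls$dataset_id))
  snps <- merge_variant_track(calls, ds, type = "snp")
  indels <- NULL
  if (!is.null(indel_calls) && nrow(indel_calls)) {
    ic <- indel_calls[indel_calls$retained &
                        !(indel_calls$dataset_id %in% indel_untrusted), ,
                      drop = FALSE]
    indels <- merge_variant_track(ic, ds, type = "indel")
  } else {
    indels <- empty_combined(ds)
  }
  list(snps = snps, indels = indels)
}

empty_combined <- function(ds) {
  base <- data.frame(isotig = character(), pos = integer(),
                     ref = character(), n_datasets = integer(),
                     alleles = character(), min_p = numeric(),
                     mean_p = numeric(), chi_sq = numeric(),
                     df = integer(), pooled_p = numeric(),
                     max_mapq = numeric(), mean_reads = numeric(),
                     mean_freq = numeric(), stringsAsFactors = FALSE)
  for (d in ds) base[[paste0("p_", d)]] <- numeric()
  base
}

merge_variant_track <- function(calls, ds, type = c("snp", "indel")) {
  type <- match.arg(type)
  if (!nrow(calls)) return(empty_combined(ds))
  pcol <- if (type == "snp") "p_snp" else "p_indel"
  acol <- if (type == "snp") "alt" else "indel_seq"
  ccol <- if (type == "snp") "alt_count" else "count"
  key <- paste(calls$isotig, calls$pos, sep = "\r")
  groups <- split(seq_len(nrow(calls)), key)
  out <- vector("list", length(groups))
  for (g in seq_along(groups)) {
    idx <- groups[[g]]
    sub <- calls[idx, , drop = FALSE]
    if (length(unique(sub$ref)) != 1L)
      stop("conflicting reference bases at ", sub$isotig[1], ":",
           sub$pos[1], call. = FALSE)
    pvec <- stats::setNames(rep(NA_real_, length(ds)), ds)
    pvec[sub$dataset_id] <- sub[[pcol]]
    fc <- fisher_combine(pvec[!is.na(pvec)])
    alleles <- sort(unique(c(if (type == "snp") sub$ref[1], sub[[acol]])))
    row <- data.frame(
      isotig = sub$isotig[1], pos = sub$pos[1], ref = sub$ref[1],
      n_datasets = nrow(sub),
      alleles = paste(alleles, collapse = ","),
      min_p = min(sub[[pcol]]), mean_p = mean(sub[[pcol]]),
      chi_sq = fc$chi_sq, df = fc$df, pooled_p = fc$pooled_p,
      max_mapq = if (type == "snp") max(sub$mapq) else NA_real_,
      mean_reads = mean(sub$depth),
      mean_freq = if (type == "snp") mean(sub$freq)
                  else mean(sub$count / sub$depth),
      stringsAsFactors = FALSE)
    for (d in ds) row[[paste0("p_", d)]] <- unname(pvec[d])
    out[[g]] <- row
  }
  res <- do.call(rbind, out)
  res <- res[order(res$isotig, res$pos), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Select flanking variants at a probability threshold
#'
#' A variant qualifies as a flanking variant — a position to be masked
#' before assay-probe design — if its probability beats the flanking
#' threshold P_F in any single dataset, or its Fisher-pooled probability
#' across datasets does. SNP and indel positions are kept in separate
#' tracks.
#'
#' @param combined result of \code{\link{merge_datasets}}.
#' @param pf flanking probability threshold (default 0.10).
#' @return List of class \code{"flanking_mask"} with \code{snps} and
#'   \code{indels} (the qualifying rows of the combined tables) and
#'   \code{pf}.
#' @export
select_flanking_variants <- function(combined, pf = 0.10) {
  keep <- function(tab) {
    if (!nrow(tab)) return(tab)
    tab[tab$min_p < pf | tab$pooled_p < pf, , drop = FALSE]
  }
  structure(list(snps = keep(combined$snps),
                 indels = keep(combined$indels), pf = pf),
            class = "flanking_mask")
}

# IUPAC lookup built from the Biostrings code map: sorted base set -> code
.iupac_rev <- local({
  m <- Biostrings::IUPAC_CODE_MAP
  stats::setNames(names(m),
                  vapply(strsplit(m, ""), function(b)
                    paste(sort(b), collapse = ""), character(1)))
})

#' IUPAC ambiguity code for a set of bases
#'
#' @param bases character vector of bases from A/C/G/T (length 1-4).
#' @return Single-letter IUPAC code, e.g. \code{c("A","G")} gives "R"
#'   and all four bases give "N".
#' @examples
#' iupac_code(c("A", "G"))
#' iupac_code(c("A", "C", "G"))
#' @export
iupac_code <- function(bases) {
  bases <- unique(toupper(bases))
  if (!all(bases %in% BASES))
    stop("bases must be drawn from A/C/G/T", call. = FALSE)
  unname(.iupac_rev[paste(sort(bases), collapse = "")])
}

#' Mask flanking-variant positions in reference sequences with IUPAC codes
#'
#' Replaces each masked SNP position with the IUPAC ambiguity code of
#' its allele set (reference plus observed alternatives), leaving all
#' other positions and the sequence length unchanged. When per-dataset
#' masks are combined, the union of the per-dataset allele sets at each
#' position determines the code. Indel positions have no IUPAC symbol;
#' they are returned as a companion interval track in BED convention
#' (0-based, half-open).
#'
#' @param sequences named character vector of reference sequences.
#' @param mask a \code{"flanking_mask"} from
#'   \code{\link{select_flanking_variants}}, or a data frame with
#'   columns isotig, pos, alleles (comma-joined).
#' @return List with \code{sequences} (masked, same names and lengths)
#'   and \code{indel_bed} (data frame chrom, start, end).
#' @export
build_masked_reference <- function(sequences, mask) {
  snps <- if (inherits(mask, "flanking_mask")) mask$snps else mask
  indels <- if (inherits(mask, "flanking_mask")) mask$indels else NULL
  out <- sequences
  if (!is.null(snps) && nrow(snps)) {
    if (!all(snps$isotig %in% names(sequences)))
      stop("mask references a sequence not in the reference", call. = FALSE)
    if (any(snps$pos < 1) ||
        any(snps$pos > nchar(sequences)[snps$isotig]))
      stop("mask position off the reference", call. = FALSE)
    for (iso in unique(snps$isotig)) {
      sub <- snps[snps$isotig == iso, , drop = FALSE]
      s <- strsplit(out[iso], "")[[1]]
      for (j in seq_len(nrow(sub))) {
        alleles <- strsplit(sub$alleles[j], ",", fixed = TRUE)[[1]]
        alleles <- union(alleles, s[sub$pos[j]])
        alleles <- intersect(alleles, BASES)
        if (!length(alleles)) {
          warning("allele set at ", iso, ":", sub$pos[j],
                  " contains no unambiguous base; masking as N")
          s[sub$pos[j]] <- "N"
        } else {
          s[sub$pos[j]] <- iupac_code(alleles)
        }
      }
      out[iso] <- paste(s, collapse = "")
    }
  }
  bed <- if (!is.null(indels) && nrow(indels)) {
    data.frame(chrom = indels$isotig, start = indels$pos - 1L,
               end = indels$pos, stringsAsFactors = FALSE)
  } else {
    data.frame(chrom = character(), start = integer(), end = integer(),
               stringsAsFactors = FALSE)
  }
  list(sequences = out, indel_bed = bed)
}

#' Combine per-dataset allele sets position-wise
#'
#' Utility for building the combined masked reference from per-dataset
#' masks: unions the allele sets recorded at identical (isotig, pos)
#' keys across mask tables.
#'
#' @param ... data frames with columns isotig, pos, alleles.
#' @return One data frame with the unioned allele sets.
#' @export
union_allele_sets <- function(...) {
  tabs <- list(...)
  all <- do.call(rbind, lapply(tabs, function(t)
    t[, c("isotig", "pos", "alleles")]))
  key <- paste(all$isotig, all$pos, sep = "\r")
  groups <- split(seq_len(nrow(all)), key)
  out <- lapply(groups, function(idx) {
    alleles <- sort(unique(unlist(
      strsplit(all$alleles[idx], ",", fixed = TRUE))))
    data.frame(isotig = all$isotig[idx[1]], pos = all$pos[idx[1]],
               alleles = paste(alleles, collapse = ","),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res <- res[order(res$isotig, res$pos), , drop = FALSE]
  rownames(res) <- NULL
  res
}
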