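#' Filter combined variants into target SNPs
#'
#' Applies the target-SNP cascade to a combined variant table: a SNP is
#' retained iff it (a) lies on the longest isotig of its isogroup, (b)
#' is bi-allelic (exactly two alleles in the across-dataset union), (c)
#' is not near a high-quality indel (no masked indel position within
#' \code{indel_adjacency_window} nt), (d) has mapping quality above
#' \code{min_mapq} in at least one dataset, and (e) beats the target
#' probability threshold P_S in at least one dataset (minimum
#' per-dataset probability below \code{ps_threshold}). A rejection
#' ledger records, per dropped row, the first criterion it failed.
#'
#' @param combined_snps SNP table from \code{\link{merge_datasets}}.
#' @param isogroup_map data frame with columns isotig, isogroup, length.
#' @param indel_positions data frame with columns isotig, pos of masked
#'   indel positions (e.g. \code{mask$indels}); NULL for none.
#' @param config a \code{\link{selection_config}}.
#' @return List with \code{targets} (retained rows plus isogroup and
#'   allele_pair columns) and \code{ledger} (dropped rows with a
#'   \code{reason} column).
#' @export
filter_target_snps <- function(combined_snps, isogroup_map,
                               indel_positions = NULL,
                               config = selection_config()) {
  stopifnot(inherits(config, "selection_config"))
  tab <- combined_snps
  if (!all(tab$isotig %in% isogroup_map$isotig))
    stop("isotig absent from the isogroup map", call. = FALSE)
  im <- isogroup_map
  longest <- unlist(lapply(split(im, im$isogroup), function(g)
    g$isotig[order(-g$length, g$isotig)][1]))
  on_longest <- tab$isotig %in% longest

  n_alleles <- lengths(strsplit(tab$alleles, ",", fixed = TRUE))
  biallelic <- n_alleles == 2L

  near_indel <- rep(FALSE, nrow(tab))
  if (!is.null(indel_positions) && nrow(indel_positions)) {
    w <- config$indel_adjacency_window
    for (iso in unique(indel_positions$isotig)) {
      ip <- indel_positions$pos[indel_positions$isotig == iso]
      sel <- tab$isotig == iso
      if (any(sel))
        near_indel[sel] <- vapply(tab$pos[sel], function(p)
          any(abs(ip - p) <= w), logical(1))
    }
  }
  mapq_ok <- tab$max_mapq > config$min_mapq
  p_ok <- tab$min_p < config$ps_threshold

  reason <- rep(NA_character_, nrow(tab))
  reason[!on_longest] <- "NOT_LONGEST_ISOTIG"
  reason[is.na(reason) & !biallelic] <- "NOT_BIALLELIC"
  reason[is.na(reason) & near_indel] <- "NEAR_INDEL"
  reason[is.na(reason) & !mapq_ok] <- "LOW_MAPQ"
  reason[is.na(reason) & !p_ok] <- "ABOVE_PS"

  keep <- is.na(reason)
  targets <- tab[keep, , drop = FALSE]
  if (nrow(targets)) {
    targets$isogroup <- im$isogroup[match(targets$isotig, im$isotig)]
    targets$allele_pair <- vapply(
      strsplit(targets$alleles, ",", fixed = TRUE),
      function(a) paste(sort(a), collapse = "/"), character(1))
    targets$iupac <- vapply(strsplit(targets$alleles, ",", fixed = TRUE),
                            iupac_code, character(1))
  } else {
    targets$isogroup <- character(0)
    targets$allele_pair <- character(0)
    targets$iupac <- character(0)
  }
  ledger <- tab[!keep, , drop = FALSE]
  ledger$reason <- reason[!keep]
  rownames(targets) <- rownames(ledger) <- NULL
  list(targets = targets, ledger = ledger)
}

# Infinium I chemistry needs two probes: A/T and C/G allele pairs
is_infinium_one <- function(allele_pair) allele_pair %in% c("A/T", "C/G")

#' Select genotyping-array candidates from target SNPs
#'
#' Applies the array-design cascade. (1) SNPs on isotigs in excluded
#' confidence classes are dropped. (2) Priority SNPs — those on
#' differentially expressed or annotation-selected isotigs — are chosen
#' up to \code{max_snps_per_isotig} per isotig with pairwise spacing of
#' at least \code{min_snp_spacing} nt, preferring lower mean
#' probability. (3) Among the remaining (non-priority) SNPs, those not
#' detected in at least \code{min_datasets} datasets are removed, and
#' the single most probable SNP (lowest mean probability; ties broken by
#' position then allele order) is retained per isotig. (4) Final assay
#' filters apply to non-priority rows only: SNPs needing the two-probe
#' Infinium I chemistry (A/T and C/G pairs), design score below
#' \code{min_design_score} (or absent), mean covering reads below
#' \code{min_mean_reads}, or mean frequency below \code{min_mean_freq}
#' are dropped; priority rows are exempt. The rejection ledger records
#' the first failed rule per dropped row, so input rows = selected +
#' ledger.
#'
#' @param targets target-SNP table from \code{\link{filter_target_snps}}
#'   (\code{$targets}).
#' @param confidence data frame isotig_id, class (C1..C7) for every
#'   isotig carrying a target.
#' @param priority_isotigs character vector of isotig ids with
#'   differential-expression or annotation priority.
#' @param design_scores data frame isotig, pos, design_score in [0, 1];
#'   targets without a row are treated as score-absent.
#' @param config a \code{\link{selection_config}}.
#' @return List with \code{selected} (with a \code{priority} column) and
#'   \code{ledger} (with a \code{reason} column).
#' @export
select_array_candidates <- function(targets, confidence,
                                    priority_isotigs = character(),
                                    design_scores = NULL,
                                    config = selection_config()) {
  stopifnot(inherits(config, "selection_config"))
  tab <- targets
  if (!nrow(tab)) {
    tab$priority <- logical(0)
    led <- tab; led$reason <- character(0)
    return(list(selected = tab, ledger = led))
  }
  # canonical order makes the outcome invariant to input row order
  tab <- tab[order(tab$isotig, tab$pos, tab$alleles), , drop = FALSE]
  tab$priority <- tab$isotig %in% priority_isotigs
  tab$design_score <- NA_real_
  if (!is.null(design_scores) && nrow(design_scores)) {
    m <- match(paste(tab$isotig, tab$pos),
               paste(design_scores$isotig, design_scores$pos))
    tab$design_score <- design_scores$design_score[m]
  }
  cls <- confidence$class[match(tab$isotig, confidence$isotig_id)]
  reason <- rep(NA_character_, nrow(tab))
  reason[!is.na(cls) & cls %in% config$excluded_classes] <- "LOW_CONFIDENCE_CLASS"

  sel <- logical(nrow(tab))
  # --- priority set: up to k per isotig, spacing-constrained, by mean_p
  pri_idx <- which(tab$priority & is.na(reason))
  for (iso in unique(tab$isotig[pri_idx])) {
    idx <- pri_idx[tab$isotig[pri_idx] == iso]
    ord <- idx[order(tab$mean_p[idx], tab$pos[idx], tab$alleles[idx])]
    chosen <- integer(0)
    for (i in ord) {
      if (length(chosen) >= config$max_snps_per_isotig) {
        reason[i] <- "ISOTIG_QUOTA"; next
      }
      if (length(chosen) &&
          any(abs(tab$pos[chosen] - tab$pos[i]) < config$min_snp_spacing)) {
        reason[i] <- "TOO_CLOSE"; next
      }
      chosen <- c(chosen, i)
    }
    sel[chosen] <- TRUE
  }
  # --- non-priority: >= min_datasets, then best per isotig
  np_idx <- which(!tab$priority & is.na(reason))
  few <- np_idx[tab$n_datasets[np_idx] < config$min_datasets]
  reason[few] <- "TOO_FEW_DATASETS"
  np_idx <- setdiff(np_idx, few)
  for (iso in unique(tab$isotig[np_idx])) {
    idx <- np_idx[tab$isotig[np_idx] == iso]
    ord <- idx[order(tab$mean_p[idx], tab$pos[idx], tab$alleles[idx])]
    best <- ord[1]
    reason[setdiff(ord, best)] <- "NOT_MOST_PROBABLE"
    # step 4 assay filters, non-priority only
    if (is_infinium_one(tab$allele_pair[best])) {
      reason[best] <- "INFINIUM_I"
    } else if (is.na(tab$design_score[best]) ||
               tab$design_score[best] < config$min_design_score) {
      reason[best] <- "LOW_DESIGN_SCORE"
    } else if (tab$mean_reads[best] < config$min_mean_reads) {
      reason[best] <- "LOW_MEAN_READS"
    } else if (pmin(tab$mean_freq[best], 1 - tab$mean_freq[best]) <
               config$min_mean_freq) {
      reason[best] <- "LOW_FREQUENCY"
    } else {
      sel[best] <- TRUE
    }
  }
  selected <- tab[sel, , drop = FALSE]
  ledger <- tab[!sel, , drop = FALSE]
  ledger$reason <- reason[!sel]
  rownames(selected) <- rownames(ledger) <- NULL
  list(selected = selected, ledger = ledger)
}

#' Extrapolate the size of a genotypable SNP resource
#'
#' Multiplies a candidate count by an empirically determined conversion
#' rate (the fraction of assayed SNPs that yield reliably called,
#' polymorphic markers) and rounds to the nearest whole SNP.
#'
#' @param n_candidates number of candidate SNPs.
#' @param conversion_rate fraction in [0, 1].
#' @return Estimated count of true / genotypable SNPs.
#' @examples
#' extrapolate_resource(278979, 0.725)  # 202260
#' @export
extrapolate_resource <- function(n_candidates, conversion_rate) {
  if (n_candidates < 0 || conversion_rate < 0 || conversion_rate > 1)
    stop("n_candidates must be >= 0 and conversion_rate in [0, 1]",
         call. = FALSE)
  round_half_up(n_candidates * conversion_rate, 0L)
}

#' Extract masked flanking sequence around a target SNP
#'
#' Returns the assay-design string for a SNP: \code{flank} nt of the
#' (IUPAC-masked) reference on each side, with the target written as
#' \code{[X/Y]}.
#'
#' @param masked_sequences named character vector of masked references.
#' @param isotig,pos target location.
#' @param allele_pair "X/Y" allele pair string.
#' @param flank flank length in nt (default 60).
#' @return Design string.
#' @export
flanking_design_sequence <- function(masked_sequences, isotig, pos,
                                     allele_pair, flank = 60L) {
  s <- masked_sequences[[isotig]]
  if (is.null(s)) stop("unknown isotig ", isotig, call. = FALSE)
  L <- nchar(s)
  left <- substr(s, max(1L, pos - flank), pos - 1L)
  right <- substr(s, pos + 1L, min(L, pos + flank))
  paste0(left, "[", allele_pair, "]", right)
}
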