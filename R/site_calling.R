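#' Pooled-sample variant probability
#'
#' One-sided test of the composite null "the population alternative
#' allele frequency is at most theta, given a per-base error rate e",
#' evaluated at the null boundary. The probability of observing at least
#' \code{alt_count} alternative reads among \code{depth} reads is the
#' upper tail of Binomial(depth, p0) with
#' \code{p0 = theta * (1 - e) + (1 - theta) * e}: a read shows the
#' alternative allele either because it carries it and is read
#' correctly, or because it carries the reference allele and is misread.
#' Small values indicate a site unlikely to be monomorphic-plus-error.
#'
#' @param alt_count number of reads supporting the alternative allele
#'   (vectorized).
#' @param depth total read depth (vectorized).
#' @param params a \code{\link{caller_params}} supplying
#'   \code{maf_threshold} (theta) and \code{error_rate} (e).
#' @return Upper-tail probability in [0, 1]; \code{alt_count = 0} gives
#'   exactly 1.
#' @examples
#' pooled_variant_pvalue(1, 1, caller_params())  # 0.0198
#' pooled_variant_pvalue(10, 50, caller_params())
#' @export
pooled_variant_pvalue <- function(alt_count, depth, params = caller_params()) {
  stopifnot(inherits(params, "caller_params"))
  if (any(depth < 1)) stop("depth must be >= 1", call. = FALSE)
  if (any(alt_count < 0) || any(alt_count > depth))
    stop("alt_count must lie in [0, depth]", call. = FALSE)
  theta <- params$maf_threshold
  e <- params$error_rate
  p0 <- theta * (1 - e) + (1 - theta) * e
  stats::pbinom(alt_count - 1, depth, p0, lower.tail = FALSE)
}

FILTER_LEVELS <- c("LOW_DEPTH", "LOW_ALT", "LOW_MAPQ", "FIXED_DIFFERENCE",
                   "MAX_READS")

#' Call SNP candidates from a pileup table
#'
#' For every site with at least one non-reference base read, identifies
#' the alternative allele (the highest-count non-reference base, ties
#' broken in fixed order A < C < G < T), computes its pooled-sample
#' probability via \code{\link{pooled_variant_pvalue}}, and attaches
#' filter flags: \code{LOW_DEPTH} (depth below \code{min_depth}),
#' \code{LOW_ALT} (fewer than \code{min_alt} alternative reads),
#' \code{LOW_MAPQ} (RMS mapping quality below \code{min_mapq}), and
#' \code{FIXED_DIFFERENCE} for sites where the dataset's reads carry a
#' single allele that differs from the reference — such sites are never
#' emitted as SNPs, since without within-dataset polymorphism the
#' difference is treated as a reference/sequencing artifact. N counts
#' never contribute to alleles. Sites deeper than \code{max_reads} are
#' flagged \code{MAX_READS} and skipped with a warning.
#'
#' @param pileup data frame with columns isotig, pos, ref, dataset_id,
#'   countA..countT, countN, indel_events, depth, mapq_rms (the dialect
#'   written by \code{\link{simulate_pileups}}).
#' @param params a \code{\link{caller_params}}.
#' @return Data frame of candidate sites (one row per site with any
#'   alternative reads): isotig, pos, ref, dataset_id, alt, alt_count,
#'   ref_count, depth, freq, p_snp, mapq, flags (comma-joined),
#'   retained (no flags).
#' @export
call_snvs <- function(pileup, params = caller_params()) {
  req <- c("isotig", "pos", "ref", "dataset_id", "countA", "countC",
           "countG", "countT", "countN", "depth", "mapq_rms")
  miss <- setdiff(req, names(pileup))
  if (length(miss))
    stop("pileup is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  cnt <- as.matrix(pileup[, c("countA", "countC", "countG", "countT")])
  if (any(cnt < 0) || any(pileup$countN < 0))
    stop("negative counts in pileup", call. = FALSE)
  base_depth <- rowSums(cnt) + pileup$countN
  if (any(base_depth != pileup$depth))
    stop("depth does not equal the sum of base and N counts",
         call. = FALSE)
  colnames(cnt) <- BASES

  ref_idx <- match(pileup$ref, BASES)
  ref_count <- cnt[cbind(seq_len(nrow(cnt)), ref_idx)]
  alt_cnt <- cnt
  alt_cnt[cbind(seq_len(nrow(cnt)), ref_idx)] <- -1L
  # which.max over columns in fixed A<C<G<T order gives the tie-break
  alt_idx <- max.col(alt_cnt, ties.method = "first")
  alt <- BASES[alt_idx]
  alt_count <- cnt[cbind(seq_len(nrow(cnt)), alt_idx)]

  n_alleles <- rowSums(cnt > 0)
  keep <- alt_count > 0
  df <- data.frame(
    isotig = pileup$isotig[keep], pos = pileup$pos[keep],
    ref = pileup$ref[keep], dataset_id = pileup$dataset_id[keep],
    alt = alt[keep], alt_count = alt_count[keep],
    ref_count = ref_count[keep],
    depth = pileup$depth[keep],
    mapq = pileup$mapq_rms[keep],
    stringsAsFactors = FALSE)
  called_depth <- df$alt_count + df$ref_count  # N excluded from alleles
  df$freq <- ifelse(called_depth > 0, df$alt_count / called_depth, 0)

  over <- df$depth > params$max_reads
  if (any(over))
    warning(sum(over), " site(s) exceed max_reads and were skipped")
  df$p_snp <- rep(NA_real_, nrow(df))
  ok <- !over
  df$p_snp[ok] <- pooled_variant_pvalue(df$alt_count[ok], df$depth[ok],
                                        params)
  f_low_depth <- df$depth < params$min_depth
  f_low_alt <- df$alt_count < params$min_alt
  f_low_mapq <- df$mapq < params$min_mapq
  # a single segregating allele that differs from the reference
  f_fixed <- df$ref_count == 0 & n_alleles[keep] == 1
  df$flags <- vapply(seq_len(nrow(df)), function(i) {
    f <- c("LOW_DEPTH"[f_low_depth[i]], "LOW_ALT"[f_low_alt[i]],
           "LOW_MAPQ"[f_low_mapq[i]], "FIXED_DIFFERENCE"[f_fixed[i]],
           "MAX_READS"[over[i]])
    paste(f[!is.na(f)], collapse = ",")
  }, character(1))
  df$retained <- df$flags == ""
  rownames(df) <- NULL
  df
}

#' Call indel candidates from a pileup table
#'
#' Scores the most frequent indel event at each site with the same
#' binomial-tail probability as SNPs, using its supporting-read count.
#' Unlike SNPs, an indel relative to the reference is recorded even
#' without within-dataset polymorphism. Events with fewer than
#' \code{min_alt} supporting reads, or at sites below \code{min_depth},
#' are flagged.
#'
#' @inheritParams call_snvs
#' @return Data frame: isotig, pos, ref, dataset_id, indel_seq, count,
#'   depth, p_indel, flags, retained. Zero rows if no indel events.
#' @export
call_indels <- function(pileup, params = caller_params()) {
  has <- !is.na(pileup$indel_events) & pileup$indel_events != ""
  sub <- pileup[has, , drop = FALSE]
  if (!nrow(sub)) {
    return(data.frame(isotig = character(), pos = integer(),
                      ref = character(), dataset_id = character(),
                      indel_seq = character(), count = integer(),
                      depth = integer(), p_indel = numeric(),
                      flags = character(), retained = logical(),
                      stringsAsFactors = FALSE))
  }
  best <- t(vapply(strsplit(sub$indel_events, ";", fixed = TRUE),
                   function(evs) {
    parts <- strsplit(evs, ":", fixed = TRUE)
    cnts <- vapply(parts, function(p) as.integer(p[2]), integer(1))
    i <- which.max(cnts)
    c(parts[[i]][1], cnts[i])
  }, character(2)))
  count <- as.integer(best[, 2])
  df <- data.frame(isotig = sub$isotig, pos = sub$pos, ref = sub$ref,
                   dataset_id = sub$dataset_id, indel_seq = best[, 1],
                   count = count, depth = sub$depth,
                   stringsAsFactors = FALSE)
  df$p_indel <- pooled_variant_pvalue(pmin(df$count, df$depth),
                                      pmax(df$depth, 1L), params)
  df$flags <- vapply(seq_len(nrow(df)), function(i) {
    f <- c("LOW_DEPTH"[df$depth[i] < params$min_depth],
           "LOW_ALT"[df$count[i] < params$min_alt])
    paste(f[!is.na(f)], collapse = ",")
  }, character(1))
  df$retained <- df$flags == ""
  rownames(df) <- NULL
  df
}

#' Mask low-quality bases as N
#'
#' Applies the rule that bases below the minimum base quality — in
#' particular Illumina quality-2 bases, which the vendor marks as unfit
#' for downstream analysis — contribute only to the N channel, never to
#' allele counts.
#'
#' @param bases character vector of base calls.
#' @param quals integer vector of phred base qualities, same length.
#' @param min_baseq minimum acceptable quality (default 20).
#' @return \code{bases} with sub-threshold entries replaced by "N".
#' @examples
#' mask_low_quality_bases(c("A", "C", "G"), c(40, 2, 19))
#' @export
mask_low_quality_bases <- function(bases, quals, min_baseq = 20L) {
  stopifnot(length(bases) == length(quals))
  bases[quals < min_baseq] <- "N"
  bases
}

#' Parse samtools-mpileup text into the pileup table dialect
#'
#' Subset parser for the six-column mpileup format (chrom, 1-based pos,
#' ref, depth, base string, quality string). Read-start markers
#' (\code{^} plus mapping quality), read ends (\code{$}), and inline
#' indel strings (\code{+n<seq>}/\code{-n<seq>}) are handled; indels are
#' collected into the indel event channel. \code{.}/\code{,} denote the
#' reference base. Bases whose quality is below \code{min_baseq} are
#' masked to N before counting.
#'
#' @param lines character vector of mpileup lines (or a file path of
#'   length 1 pointing at an existing file).
#' @param dataset_id dataset identifier to stamp on every row.
#' @param min_baseq base-quality floor applied during parsing.
#' @return Pileup data frame in the dialect of
#'   \code{\link{simulate_pileups}} (mapq_rms is NA: mpileup text does
#'   not carry it).
#' @export
parse_mpileup <- function(lines, dataset_id = "ds1", min_baseq = 20L) {
  if (length(lines) == 1L && file.exists(lines))
    lines <- readLines(lines)
  lines <- lines[nzchar(lines)]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 6L) stop("malformed mpileup line: ", lines[i],
                             call. = FALSE)
    ref <- toupper(f[3])
    res <- parse_pileup_bases(f[5], ref)
    quals <- utf8ToInt(f[6]) - 33L
    bases <- res$bases
    if (length(bases) != length(quals))
      stop("base/quality length mismatch at ", f[1], ":", f[2],
           call. = FALSE)
    bases <- mask_low_quality_bases(bases, quals, min_baseq)
    cnt <- table(factor(bases, levels = c(BASES, "N")))
    ev <- ""
    if (length(res$indels)) {
      tab <- table(res$indels)
      ev <- paste(sprintf("%s:%d", names(tab), as.integer(tab)),
                  collapse = ";")
    }
    out[[i]] <- data.frame(
      isotig = f[1], pos = as.integer(f[2]), ref = ref,
      dataset_id = dataset_id,
      countA = as.integer(cnt["A"]), countC = as.integer(cnt["C"]),
      countG = as.integer(cnt["G"]), countT = as.integer(cnt["T"]),
      countN = as.integer(cnt["N"]), indel_events = ev,
      depth = length(bases), mapq_rms = NA_real_,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# walk an mpileup base string; returns per-read base calls and indel strings
parse_pileup_bases <- function(s, ref) {
  chars <- strsplit(s, "")[[1]]
  bases <- character(0); indels <- character(0)
  i <- 1L; n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "^") { i <- i + 2L; next }          # start marker + mapq char
    if (ch == "$") { i <- i + 1L; next }
    if (ch %in% c("+", "-")) {
      j <- i + 1L
      while (j <= n && grepl("[0-9]", chars[j])) j <- j + 1L
      len <- as.integer(paste(chars[(i + 1L):(j - 1L)], collapse = ""))
      seqs <- paste(chars[j:(j + len - 1L)], collapse = "")
      indels <- c(indels, paste0(ch, toupper(seqs)))
      i <- j + len
      next
    }
    if (ch %in% c(".", ",")) bases <- c(bases, ref)
    else if (ch == "*") bases <- c(bases, "N")    # deletion placeholder
    else bases <- c(bases, toupper(ch))
    i <- i + 1L
  }
  list(bases = bases, indels = indels)
}

#' Write per-dataset site calls to TSV
#'
#' @param calls data frame from \code{\link{call_snvs}}.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_site_calls <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
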