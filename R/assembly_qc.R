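#' Classify isotigs by structural relationship to a reference unigene set
#'
#' Assigns each isotig one of seven confidence classes from its homology
#' matches against a related species' unigene catalog. Per isotig, only
#' "countable" matches — hits whose percent identity is within
#' \code{identity_window} of that isotig's best hit — participate.
#' Three criteria drive the class: the number of distinct subjects
#' matched (one vs. two or more), whether any other isotig's countable
#' matches share a subject (partners), and whether the focal isotig's
#' alignment interval on a shared subject intersects a partner's
#' interval there. The mapping is: no match = C7 (Unknown); one subject,
#' no partners = C1 (Highest); multiple subjects, no partners = C2; one
#' subject with non-overlapping partners = C3; multiple subjects,
#' non-overlapping partners = C4; one subject with overlapping partners
#' = C5; multiple subjects with overlapping partners = C6. Lower class
#' numbers indicate simpler relationships and greater confidence that
#' reads were assembled into a single locus.
#'
#' @param matches data frame of matches in BLAST tabular (outfmt-6)
#'   column order — at least qseqid, sseqid, pident, sstart, send.
#' @param all_isotigs optional character vector of every isotig
#'   evaluated; isotigs with no match rows are reported as C7.
#' @param identity_window percent-identity window below the best hit
#'   within which additional matches are counted (default 5).
#' @return Data frame: isotig_id, n_subjects, has_partners,
#'   partners_overlap, class, confidence_label.
#' @export
classify_isotigs <- function(matches, all_isotigs = NULL,
                             identity_window = 5) {
  if (nrow(matches)) {
    stopifnot(all(c("qseqid", "sseqid", "pident", "sstart", "send") %in%
                    names(matches)))
    s1 <- pmin(matches$sstart, matches$send)
    s2 <- pmax(matches$sstart, matches$send)
    matches$sstart <- s1; matches$send <- s2
    if (any(matches$pident < 0 | matches$pident > 100))
      stop("percent identity out of range", call. = FALSE)
    # countable matches: within the identity window of each query's best
    best <- tapply(matches$pident, matches$qseqid, max)
    countable <- matches$pident >= best[matches$qseqid] - identity_window
    cm <- matches[countable, , drop = FALSE]
  } else {
    cm <- matches
  }
  isotigs <- unique(c(if (nrow(matches)) unique(matches$qseqid),
                      all_isotigs))
  labels <- c(C1 = "Highest", C2 = "Higher", C3 = "Higher", C4 = "Medium",
              C5 = "Lower", C6 = "Lowest", C7 = "Unknown")
  out <- lapply(isotigs, function(q) {
    mine <- cm[cm$qseqid == q, , drop = FALSE]
    if (!nrow(mine)) {
      return(data.frame(isotig_id = q, n_subjects = 0L,
                        has_partners = NA, partners_overlap = NA,
                        class = "C7", stringsAsFactors = FALSE))
    }
    n_sub <- length(unique(mine$sseqid))
    partners <- cm[cm$qseqid != q & cm$sseqid %in% mine$sseqid, ,
                   drop = FALSE]
    has_p <- nrow(partners) > 0
    overlap <- FALSE
    if (has_p) {
      for (j in seq_len(nrow(partners))) {
        own <- mine[mine$sseqid == partners$sseqid[j], , drop = FALSE]
        if (any(own$sstart <= partners$send[j] &
                partners$sstart[j] <= own$send)) { overlap <- TRUE; break }
      }
    }
    cls <- if (!has_p) { if (n_sub == 1L) "C1" else "C2"
    } else if (!overlap) { if (n_sub == 1L) "C3" else "C4"
    } else { if (n_sub == 1L) "C5" else "C6" }
    data.frame(isotig_id = q, n_subjects = n_sub, has_partners = has_p,
               partners_overlap = if (has_p) overlap else NA,
               class = cls, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res$confidence_label <- unname(labels[res$class])
  rownames(res) <- NULL
  res
}

#' Infer sequence orientation from stranded mapping counts
#'
#' Given, per reference sequence, the number of unique alignment
#' locations where strand-specific reads mapped as direct sequencer
#' output (D) and as reverse complements (C), tests whether C differs
#' from D with a two-tailed exact binomial test at null proportion 0.5
#' (summing all outcomes at most as probable as the observed one). If
#' significant at \code{alpha}, C > D indicates forward (+) orientation
#' — dUTP strand-specific libraries read the antisense strand — and
#' C < D indicates reverse (-); otherwise the orientation is ambiguous,
#' as it is when no reads mapped at all.
#'
#' @param D,C non-negative integer vectors of direct and
#'   reverse-complement unique alignment location counts.
#' @param alpha significance level (default 0.05).
#' @return Data frame: D, C, p_value, orientation ("+", "-" or
#'   "ambiguous").
#' @examples
#' orient_sequence(10, 0)   # reverse
#' orient_sequence(5, 5)    # ambiguous
#' @export
orient_sequence <- function(D, C, alpha = 0.05) {
  stopifnot(length(D) == length(C), all(D >= 0), all(C >= 0))
  n <- D + C
  p <- vapply(seq_along(D), function(i) {
    if (n[i] == 0) return(1)
    stats::binom.test(C[i], n[i], p = 0.5)$p.value
  }, numeric(1))
  ori <- ifelse(n == 0 | p >= alpha, "ambiguous",
                ifelse(C > D, "+", "-"))
  data.frame(D = D, C = C, p_value = p, orientation = ori,
             stringsAsFactors = FALSE)
}

#' Screen assembled sequences for bacterial/fungal contamination
#'
#' Applies the contaminant decision rule to each sequence's best
#' database hit: the sequence is removed iff the hit's bit-score exceeds
#' 50, its E-value is below 1e-10, and the genus of the subject organism
#' is present in the provided contaminant name set (e.g. bacterial and
#' fungal genus names from a taxonomy database). Sequences without a
#' hit are kept.
#'
#' @param best_hits data frame with columns qseqid, bitscore, evalue and
#'   either \code{genus} or \code{organism} (genus = first
#'   whitespace-delimited token).
#' @param genus_names character vector of contaminant genus names.
#' @param min_bitscore,max_evalue decision-rule gates (defaults 50 and
#'   1e-10).
#' @return Data frame: qseqid, genus, verdict ("keep" or "remove").
#' @export
screen_contaminants <- function(best_hits, genus_names,
                                min_bitscore = 50, max_evalue = 1e-10) {
  if (!nrow(best_hits))
    return(data.frame(qseqid = character(), genus = character(),
                      verdict = character(), stringsAsFactors = FALSE))
  genus <- if ("genus" %in% names(best_hits)) best_hits$genus
           else vapply(strsplit(best_hits$organism, "\\s+"), `[`, "",
                       1)
  remove <- !is.na(best_hits$bitscore) &
    best_hits$bitscore > min_bitscore &
    best_hits$evalue < max_evalue &
    genus %in% genus_names
  data.frame(qseqid = best_hits$qseqid, genus = genus,
             verdict = ifelse(remove, "remove", "keep"),
             stringsAsFactors = FALSE)
}

#' Assembly length statistics
#'
#' Computes the count, mean, median, N50 and total length of a set of
#' sequence lengths. N50 follows the standard convention: the smallest
#' length L such that sequences of length at least L together cover at
#' least half the total assembled nucleotides.
#'
#' @param lengths positive integer vector of sequence lengths.
#' @return List: n_sequences, mean, median, n50, total.
#' @examples
#' assembly_stats(c(2, 3, 4, 5, 6))$n50  # 5
#' @export
assembly_stats <- function(lengths) {
  if (!length(lengths)) {
    warning("empty length set; returning zeros")
    return(list(n_sequences = 0L, mean = 0, median = 0, n50 = 0,
                total = 0))
  }
  stopifnot(all(lengths > 0))
  sl <- sort(lengths, decreasing = TRUE)
  total <- sum(sl)
  n50 <- sl[which(cumsum(sl) >= total / 2)[1]]
  list(n_sequences = length(lengths), mean = mean(lengths),
       median = stats::median(lengths), n50 = n50, total = total)
}

#' Read a BLAST tabular (outfmt 6) match table
#'
#' @param path path to a tab-separated file in the standard 12-column
#'   outfmt-6 order (qseqid sseqid pident length mismatch gapopen
#'   qstart qend sstart send evalue bitscore), without a header.
#' @return Data frame with those column names.
#' @export
read_blast_tab <- function(path) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch",
            "gapopen", "qstart", "qend", "sstart", "send", "evalue",
            "bitscore")
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = cols)
  df
}
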