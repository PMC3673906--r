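#' Configuration for the synthetic-data generator
#'
#' Describes a simulated pooled-resequencing study: a set of reference
#' transcript sequences (isotigs), several pooled sequencing datasets
#' mapped against them, and variants planted at known allele frequencies.
#' Defaults mirror the study design the pipeline targets: five pooled
#' datasets, a per-base error rate of 0.01, and read depths with the
#' overdispersion typical of RNA-seq-derived pileups (negative-binomial
#' per-site coverage).
#'
#' @param n_isotigs number of reference sequences to simulate.
#' @param isotig_length_range integer vector \code{c(min, max)} of
#'   sequence lengths in nt; min must be >= 1.
#' @param n_datasets number of pooled sequencing datasets.
#' @param depth_mean mean per-site read depth.
#' @param depth_dispersion negative-binomial size parameter; smaller
#'   values give more overdispersed coverage.
#' @param error_rate per-base substitution error probability; an erring
#'   read shows each of the three non-true bases with probability
#'   \code{error_rate/3}.
#' @param variant_density expected planted variants per kilobase.
#' @param shared_fraction fraction of planted variants segregating in at
#'   least two datasets.
#' @param indel_fraction fraction of planted variants that are indels.
#' @param n_fraction fraction of read bases emitted as N (exercises the
#'   low-quality-base masking rule); N never counts toward alleles.
#' @param seed master random seed; all component generators derive
#'   deterministic child seeds from it.
#' @return A list of class \code{"sim_config"}.
#' @export
sim_config <- function(n_isotigs = 10L, isotig_length_range = c(500L, 1500L),
                       n_datasets = 5L, depth_mean = 50, depth_dispersion = 5,
                       error_rate = 0.01, variant_density = 2,
                       shared_fraction = 0.6, indel_fraction = 0.1,
                       n_fraction = 0, seed = 1L) {
  if (isotig_length_range[1] < 1)
    stop("isotig_length_range minimum must be >= 1", call. = FALSE)
  stopifnot(
    n_isotigs >= 1, n_datasets >= 1,
    length(isotig_length_range) == 2L,
    isotig_length_range[1] <= isotig_length_range[2],
    depth_mean > 0, depth_dispersion > 0,
    error_rate >= 0, error_rate <= 1,
    variant_density >= 0,
    shared_fraction >= 0, shared_fraction <= 1,
    indel_fraction >= 0, indel_fraction <= 1,
    n_fraction >= 0, n_fraction < 1
  )
  structure(
    list(n_isotigs = as.integer(n_isotigs),
         isotig_length_range = as.integer(isotig_length_range),
         n_datasets = as.integer(n_datasets),
         depth_mean = depth_mean, depth_dispersion = depth_dispersion,
         error_rate = error_rate, variant_density = variant_density,
         shared_fraction = shared_fraction, indel_fraction = indel_fraction,
         n_fraction = n_fraction, seed = as.integer(seed)),
    class = "sim_config"
  )
}

BASES <- c("A", "C", "G", "T")

dataset_ids <- function(n) sprintf("ds%d", seq_len(n))

#' Simulate reference sequences with planted variants
#'
#' Draws random transcript sequences over A/C/G/T and plants SNP and
#' indel variants at Poisson-distributed positions, each with a known
#' alternative allele and per-dataset allele frequency (the ground
#' truth). A variant is "shared" (segregating in two or more randomly
#' chosen datasets) with probability \code{shared_fraction}, otherwise it
#' segregates in a single dataset. Frequencies are drawn uniformly on
#' [0.05, 0.5] for segregating pools and are 0 elsewhere.
#'
#' @param config a \code{\link{sim_config}}.
#' @return A list with \code{sequences} (named character vector of
#'   reference sequences) and \code{truth} (data frame: isotig_id,
#'   position, ref_allele, alt_allele, is_indel, indel_seq, and one
#'   \code{freq_<dataset>} column per dataset).
#' @examples
#' ref <- simulate_reference(sim_config(n_isotigs = 2, seed = 7))
#' nchar(ref$sequences)
#' head(ref$truth)
#' @export
simulate_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(child_seed(config$seed, "reference"))
  lo <- config$isotig_length_range[1]
  hi <- config$isotig_length_range[2]
  lens <- lo + sample.int(hi - lo + 1L, config$n_isotigs,
                          replace = TRUE) - 1L
  ids <- sprintf("isotig%05d", seq_len(config$n_isotigs))
  seqs <- vapply(lens, function(L)
    paste(sample(BASES, L, replace = TRUE), collapse = ""), character(1))
  names(seqs) <- ids

  ds <- dataset_ids(config$n_datasets)
  rows <- list()
  for (i in seq_along(ids)) {
    n_var <- stats::rpois(1, lens[i] * config$variant_density / 1000)
    if (n_var == 0) next
    n_var <- min(n_var, lens[i])
    pos <- sort(sample.int(lens[i], n_var))
    refb <- substring(seqs[i], pos, pos)
    altb <- vapply(refb, function(b) sample(setdiff(BASES, b), 1), character(1))
    is_indel <- stats::runif(n_var) < config$indel_fraction
    indel_seq <- ifelse(
      is_indel,
      vapply(seq_len(n_var), function(j)
        paste(sample(BASES, sample(1:3, 1), replace = TRUE), collapse = ""),
        character(1)),
      "")
    fr <- matrix(0, n_var, length(ds), dimnames = list(NULL, ds))
    for (j in seq_len(n_var)) {
      shared <- stats::runif(1) < config$shared_fraction
      k <- if (shared && length(ds) >= 2) sample(2:length(ds), 1) else 1L
      which_ds <- sample(seq_along(ds), k)
      fr[j, which_ds] <- stats::runif(k, 0.05, 0.5)
    }
    df <- data.frame(isotig_id = ids[i], position = pos,
                     ref_allele = unname(refb), alt_allele = unname(altb),
                     is_indel = is_indel, indel_seq = indel_seq,
                     stringsAsFactors = FALSE)
    colnames(fr) <- paste0("freq_", ds)
    rows[[length(rows) + 1L]] <- cbind(df, as.data.frame(fr))
  }
  truth <- if (length(rows)) do.call(rbind, rows) else
    cbind(data.frame(isotig_id = character(), position = integer(),
                     ref_allele = character(), alt_allele = character(),
                     is_indel = logical(), indel_seq = character(),
                     stringsAsFactors = FALSE),
          stats::setNames(as.data.frame(matrix(numeric(), 0, length(ds))),
                          paste0("freq_", ds)))
  rownames(truth) <- NULL
  list(sequences = seqs, truth = truth)
}

#' Simulate per-dataset pileup tables
#'
#' For every reference position and dataset, draws a read depth from a
#' negative-binomial coverage model and base counts from a multinomial
#' whose probabilities combine the planted allele frequency with the
#' substitution-error model: a read carries the alternative allele with
#' probability \code{f}, sequencing error then replaces the true base by
#' each of the three other bases with probability \code{error_rate/3},
#' and with probability \code{n_fraction} a base is emitted as N. Indel
#' variants contribute supporting-read counts to the site's indel event
#' channel instead of the base counts.
#'
#' @param reference result of \code{\link{simulate_reference}} (or a
#'   named character vector of sequences, with \code{truth} supplied).
#' @param truth planted-variant table; defaults to
#'   \code{reference$truth}.
#' @param config the \code{\link{sim_config}} used.
#' @return Data frame with columns isotig, pos, ref, dataset_id, countA,
#'   countC, countG, countT, countN, indel_events, depth, mapq_rms.
#' @export
simulate_pileups <- function(reference, truth = NULL, config) {
  stopifnot(inherits(config, "sim_config"))
  seqs <- if (is.list(reference)) reference$sequences else reference
  if (is.null(truth)) truth <- reference$truth
  if (nrow(truth) && !all(truth$isotig_id %in% names(seqs)))
    stop("truth references an isotig absent from the reference",
         call. = FALSE)
  bad <- nrow(truth) &&
    any(truth$position > nchar(seqs)[truth$isotig_id] | truth$position < 1)
  if (isTRUE(bad))
    stop("truth position lies outside its reference sequence", call. = FALSE)

  set.seed(child_seed(config$seed, "pileups"))
  ds <- dataset_ids(config$n_datasets)
  e <- config$error_rate
  nf <- config$n_fraction

  out <- vector("list", length(seqs) * length(ds))
  k <- 0L
  for (iso in names(seqs)) {
    L <- nchar(seqs[iso])
    refbases <- strsplit(seqs[iso], "")[[1]]
    tr <- truth[truth$isotig_id == iso, , drop = FALSE]
    for (d in ds) {
      depth <- as.integer(stats::rnbinom(L, size = config$depth_dispersion,
                                         mu = config$depth_mean))
      # per-base emission probabilities: start from pure-reference model
      f <- numeric(L)       # alt frequency at each position (SNPs only)
      altb <- rep(NA_character_, L)
      indel_at <- integer(0); indel_seq_at <- character(0); indel_f <- numeric(0)
      if (nrow(tr)) {
        fcol <- tr[[paste0("freq_", d)]]
        snp <- !tr$is_indel
        f[tr$position[snp]] <- fcol[snp]
        altb[tr$position[snp]] <- tr$alt_allele[snp]
        ind <- tr$is_indel & fcol > 0
        indel_at <- tr$position[ind]
        indel_seq_at <- tr$indel_seq[ind]
        indel_f <- fcol[ind]
      }
      cnt <- matrix(0L, L, 5L)
      colnames(cnt) <- c(BASES, "N")
      for (p in seq_len(L)) {
        dpt <- depth[p]
        if (dpt == 0L) next
        pr <- stats::setNames(rep(e / 3, 4), BASES)
        rb <- refbases[p]; fp <- f[p]
        pr[rb] <- (1 - fp) * (1 - e) + fp * e / 3
        if (fp > 0) pr[altb[p]] <- fp * (1 - e) + (1 - fp) * e / 3
        pr <- c(pr * (1 - nf), N = nf)
        cnt[p, ] <- as.integer(stats::rmultinom(1, dpt, pr))
      }
      indel_events <- rep("", L)
      if (length(indel_at)) {
        for (j in seq_along(indel_at)) {
          supp <- stats::rbinom(1, depth[indel_at[j]], indel_f[j])
          if (supp > 0)
            indel_events[indel_at[j]] <-
              sprintf("+%s:%d", indel_seq_at[j], supp)
        }
      }
      k <- k + 1L
      out[[k]] <- data.frame(
        isotig = iso, pos = seq_len(L), ref = refbases, dataset_id = d,
        countA = cnt[, "A"], countC = cnt[, "C"], countG = cnt[, "G"],
        countT = cnt[, "T"], countN = cnt[, "N"],
        indel_events = indel_events, depth = depth,
        mapq_rms = round(stats::runif(L, 30, 60), 1),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out[seq_len(k)])
  rownames(res) <- NULL
  res
}

#' Simulate strand-specific alignment-location counts
#'
#' Emulates counting, per reference sequence, how many unique alignment
#' locations carry reads mapped as direct sequencer output (D) versus as
#' reverse complements (C). For a forward-oriented reference sequenced
#' with a dUTP strand-specific protocol, reads map predominantly as
#' reverse complements, so C ~ Binomial(reads, 1 - misorientation_rate);
#' the roles swap for a reverse-oriented reference.
#'
#' @param n_refs number of reference sequences.
#' @param orientations character vector of true orientations, "+" or
#'   "-", recycled to length \code{n_refs}.
#' @param reads_per_ref reads mapped per reference.
#' @param misorientation_rate probability a read maps on the unexpected
#'   strand; must be in [0, 0.5).
#' @param seed random seed.
#' @return Data frame with ref_id, D, C, true_orientation.
#' @export
simulate_stranded_counts <- function(n_refs, orientations = "+",
                                     reads_per_ref = 100,
                                     misorientation_rate = 0.1,
                                     seed = 1L) {
  if (misorientation_rate < 0 || misorientation_rate >= 0.5)
    stop("misorientation_rate must be in [0, 0.5)", call. = FALSE)
  stopifnot(n_refs >= 1, reads_per_ref >= 0)
  set.seed(child_seed(seed, "stranded"))
  ori <- rep_len(orientations, n_refs)
  stopifnot(all(ori %in% c("+", "-")))
  C <- integer(n_refs)
  plus <- ori == "+"
  C[plus] <- stats::rbinom(sum(plus), reads_per_ref, 1 - misorientation_rate)
  C[!plus] <- stats::rbinom(sum(!plus), reads_per_ref, misorientation_rate)
  data.frame(ref_id = sprintf("ref%05d", seq_len(n_refs)),
             D = as.integer(reads_per_ref - C), C = C,
             true_orientation = ori, stringsAsFactors = FALSE)
}

#' Simulate a genotyping-array call matrix
#'
#' Draws genotypes for biallelic loci under the inbreeding-adjusted
#' Hardy-Weinberg model: with minor allele frequency q (= maf) and
#' inbreeding coefficient f, P(AA) = p^2 + f p q, P(AB) = 2 p q (1 - f),
#' P(BB) = q^2 + f p q. Calls are independently replaced by NC (no call)
#' at \code{no_call_rate}.
#'
#' @param n_loci number of loci.
#' @param n_samples number of individuals.
#' @param maf_vector per-locus minor allele frequencies in [0, 0.5],
#'   recycled to \code{n_loci}.
#' @param inbreeding_f inbreeding coefficient in [-1, 1]; positive
#'   values deplete heterozygotes.
#' @param no_call_rate per-call failure probability in [0, 1).
#' @param seed random seed.
#' @return A list with \code{calls} (character matrix loci x samples,
#'   values AA/AB/BB/NC) and \code{truth} (data frame of locus_id, maf,
#'   inbreeding_f).
#' @export
simulate_genotypes <- function(n_loci, n_samples, maf_vector = 0.25,
                               inbreeding_f = 0, no_call_rate = 0,
                               seed = 1L) {
  stopifnot(n_loci >= 1, n_samples >= 1,
            all(maf_vector >= 0), all(maf_vector <= 0.5),
            inbreeding_f >= -1, inbreeding_f <= 1,
            no_call_rate >= 0, no_call_rate < 1)
  q <- rep_len(maf_vector, n_loci)
  p <- 1 - q
  pAB <- 2 * p * q * (1 - inbreeding_f)
  pAA <- p^2 + inbreeding_f * p * q
  pBB <- q^2 + inbreeding_f * p * q
  if (any(pAB < -1e-12) || any(pAA < -1e-12) || any(pBB < -1e-12))
    stop("inbreeding_f and maf imply a negative genotype probability",
         call. = FALSE)
  pAB <- pmax(pAB, 0); pAA <- pmax(pAA, 0); pBB <- pmax(pBB, 0)
  set.seed(child_seed(seed, "genotypes"))
  calls <- matrix("", n_loci, n_samples)
  g <- c("AA", "AB", "BB")
  for (i in seq_len(n_loci)) {
    calls[i, ] <- sample(g, n_samples, replace = TRUE,
                         prob = c(pAA[i], pAB[i], pBB[i]))
  }
  if (no_call_rate > 0) {
    nc <- matrix(stats::runif(n_loci * n_samples) < no_call_rate,
                 n_loci, n_samples)
    calls[nc] <- "NC"
  }
  rownames(calls) <- sprintf("locus%05d", seq_len(n_loci))
  colnames(calls) <- sprintf("s%04d", seq_len(n_samples))
  list(calls = calls,
       truth = data.frame(locus_id = rownames(calls), maf = q,
                          inbreeding_f = inbreeding_f,
                          stringsAsFactors = FALSE))
}

#' Simulate a cross-species homology match table realizing planned
#' structural classes
#'
#' Builds a BLAST-tabular-style match table in which each generated
#' isotig realizes exactly one requested structural-relationship class
#' with respect to a set of subject unigenes:
#' \describe{
#'   \item{C1}{one subject match, no other isotig matches that subject}
#'   \item{C2}{two subject matches, no partners on either}
#'   \item{C3}{one shared subject, partner alignments do not overlap}
#'   \item{C4}{two subjects, shared partner, no overlap}
#'   \item{C5}{one shared subject, partner alignments overlap}
#'   \item{C6}{two subjects, shared partner, overlapping}
#'   \item{C7}{no match at all}
#' }
#' Partnered classes are co-located on one shared subject; C3/C4 members
#' occupy disjoint subject intervals while C5/C6 members occupy mutually
#' overlapping intervals. Plans in which a partnered class cannot obtain
#' a partner (e.g. a single C3 with no other partnered isotig, or C5/C6
#' totalling one) are rejected.
#'
#' @param class_plan named integer vector or list, names among C1..C7,
#'   giving the number of isotigs to generate in each class.
#' @param seed random seed (controls identities only; structure is
#'   deterministic).
#' @return List with \code{matches} (data frame in outfmt-6 column
#'   order) and \code{expected} (data frame isotig_id, class).
#' @export
simulate_match_table <- function(class_plan, seed = 1L) {
  plan <- stats::setNames(integer(7), paste0("C", 1:7))
  cp <- unlist(class_plan)
  stopifnot(all(names(cp) %in% names(plan)), all(cp >= 0))
  plan[names(cp)] <- as.integer(cp)
  n34 <- plan["C3"] + plan["C4"]
  n56 <- plan["C5"] + plan["C6"]
  if (n56 == 1L)
    stop("C5/C6 require at least two mutually overlapping isotigs",
         call. = FALSE)
  if (n34 == 1L && n56 == 0L)
    stop("a single C3/C4 isotig has no possible partner", call. = FALSE)
  set.seed(child_seed(seed, "matches"))

  iso_counter <- 0L; sub_counter <- 0L
  new_iso <- function() { iso_counter <<- iso_counter + 1L
    sprintf("iso%04d", iso_counter) }
  new_sub <- function() { sub_counter <<- sub_counter + 1L
    sprintf("unigene%04d", sub_counter) }
  matches <- list(); expected <- list()
  add_match <- function(q, s, sstart, send, pident = 95) {
    len <- send - sstart + 1L
    matches[[length(matches) + 1L]] <<- data.frame(
      qseqid = q, sseqid = s, pident = pident, length = len,
      mismatch = as.integer(round(len * (100 - pident) / 100)),
      gapopen = 0L, qstart = 1L, qend = len,
      sstart = sstart, send = send,
      evalue = 10^-round(stats::runif(1, 20, 60)),
      bitscore = round(stats::runif(1, 100, 500)),
      stringsAsFactors = FALSE)
  }
  add_iso <- function(q, cls) expected[[length(expected) + 1L]] <<-
    data.frame(isotig_id = q, class = cls, stringsAsFactors = FALSE)

  for (i in seq_len(plan["C1"])) {
    q <- new_iso(); add_match(q, new_sub(), 1L, 300L); add_iso(q, "C1")
  }
  for (i in seq_len(plan["C2"])) {
    q <- new_iso()
    add_match(q, new_sub(), 1L, 300L); add_match(q, new_sub(), 1L, 250L)
    add_iso(q, "C2")
  }
  if (n34 + n56 > 0L) {
    shared <- new_sub()
    at <- 1L
    for (i in seq_len(plan["C3"])) {
      q <- new_iso(); add_match(q, shared, at, at + 99L); add_iso(q, "C3")
      at <- at + 200L
    }
    for (i in seq_len(plan["C4"])) {
      q <- new_iso(); add_match(q, shared, at, at + 99L)
      add_match(q, new_sub(), 1L, 200L); add_iso(q, "C4")
      at <- at + 200L
    }
    # overlap cluster: intervals all contain [at, at+49]
    for (i in seq_len(plan["C5"])) {
      q <- new_iso(); add_match(q, shared, at, at + 49L + 10L * i)
      add_iso(q, "C5")
    }
    for (i in seq_len(plan["C6"])) {
      q <- new_iso(); add_match(q, shared, at, at + 49L + 5L * i)
      add_match(q, new_sub(), 1L, 200L); add_iso(q, "C6")
    }
  }
  c7 <- character(plan["C7"])
  for (i in seq_len(plan["C7"])) {
    q <- new_iso(); c7[i] <- q; add_iso(q, "C7")
  }
  m <- if (length(matches)) do.call(rbind, matches) else data.frame(
    qseqid = character(), sseqid = character(), pident = numeric(),
    length = integer(), mismatch = integer(), gapopen = integer(),
    qstart = integer(), qend = integer(), sstart = integer(),
    send = integer(), evalue = numeric(), bitscore = numeric(),
    stringsAsFactors = FALSE)
  list(matches = m,
       expected = if (length(expected)) do.call(rbind, expected) else
         data.frame(isotig_id = character(), class = character(),
                    stringsAsFactors = FALSE),
       all_isotigs = c(unique(m$qseqid), c7))
}

#' Write simulated reference sequences to FASTA
#'
#' @param sequences named character vector of sequences.
#' @param path output FASTA path.
#' @return The path, invisibly.
#' @export
write_reference_fasta <- function(sequences, path) {
  x <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}
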