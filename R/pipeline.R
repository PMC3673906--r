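#' Run the full synthetic SNP-discovery pipeline
#'
#' Orchestrates every stage end to end on simulated data: reference and
#' truth simulation, per-dataset pileups, SNP/indel site calling,
#' across-dataset merging with Fisher combination, flanking-variant
#' selection and IUPAC masking, cross-species confidence
#' classification, strand orientation inference, target-SNP filtering,
#' array candidate selection, genotype simulation for the selected
#' candidates, and array QC. Stage outputs are written as plain-text
#' tables under \code{outdir}, and a reproducibility manifest records
#' the configuration, seeds, per-stage row counts and output-file
#' digests; re-running with the same configuration reproduces the
#' digests byte for byte.
#'
#' @param config a \code{\link{sim_config}} describing the simulated
#'   study.
#' @param outdir output directory (created if absent); NULL runs
#'   in-memory only and records no file digests.
#' @param params a \code{\link{caller_params}}.
#' @param selection a \code{\link{selection_config}}.
#' @param pf flanking probability threshold.
#' @param n_trees number of individuals genotyped on the simulated
#'   array.
#' @param priority_fraction fraction of isotigs granted
#'   differential-expression priority in array selection.
#' @return List with \code{manifest} (config snapshot, counts, digests)
#'   and \code{stages} (the in-memory stage outputs).
#' @export
run_pipeline <- function(config = sim_config(), outdir = NULL,
                         params = caller_params(),
                         selection = selection_config(),
                         pf = 0.10, n_trees = 260L,
                         priority_fraction = 0.2) {
  stopifnot(inherits(config, "sim_config"))
  counts <- list()
  note <- function(stage, n_in, n_out)
    counts[[stage]] <<- list(input = n_in, output = n_out)

  ref <- simulate_reference(config)
  note("simulate_reference", config$n_isotigs, length(ref$sequences))
  pile <- simulate_pileups(ref, config = config)
  note("simulate_pileups", length(ref$sequences), nrow(pile))

  snv <- call_snvs(pile, params)
  note("call_snvs", nrow(pile), sum(snv$retained))
  ind <- call_indels(pile, params)
  note("call_indels", nrow(pile), sum(ind$retained))

  combined <- merge_datasets(snv, ind)
  note("merge_datasets", sum(snv$retained), nrow(combined$snps))
  mask <- select_flanking_variants(combined, pf = pf)
  note("select_flanking_variants", nrow(combined$snps),
       nrow(mask$snps))
  masked <- build_masked_reference(ref$sequences, mask)

  # every simulated isotig is its own isogroup here; real assemblies
  # supply a many-to-one map
  iso_map <- data.frame(isotig = names(ref$sequences),
                        isogroup = sub("isotig", "isogroup",
                                       names(ref$sequences)),
                        length = nchar(ref$sequences),
                        stringsAsFactors = FALSE)

  set.seed(child_seed(config$seed, "pipeline_extras"))
  plan <- c(C1 = max(1L, config$n_isotigs %/% 3),
            C2 = max(1L, config$n_isotigs %/% 5),
            C5 = 2L, C6 = 2L, C7 = max(1L, config$n_isotigs %/% 5))
  mt <- simulate_match_table(plan, seed = config$seed)
  conf_aux <- classify_isotigs(mt$matches, all_isotigs = mt$all_isotigs)
  # map simulated confidence classes onto the pipeline's isotigs
  cls_pool <- rep_len(conf_aux$class, length(iso_map$isotig))
  confidence <- data.frame(isotig_id = iso_map$isotig,
                           class = sample(cls_pool),
                           stringsAsFactors = FALSE)
  note("classify_isotigs", nrow(mt$matches), nrow(conf_aux))

  stranded <- simulate_stranded_counts(
    n_refs = config$n_isotigs,
    orientations = sample(c("+", "-"), config$n_isotigs, replace = TRUE),
    reads_per_ref = 1000L, misorientation_rate = 0.1,
    seed = child_seed(config$seed, "orientation"))
  orientation <- cbind(stranded["ref_id"],
                       orient_sequence(stranded$D, stranded$C),
                       true_orientation = stranded$true_orientation)
  note("orient_sequence", nrow(stranded), nrow(orientation))

  filt <- filter_target_snps(combined$snps, iso_map,
                             indel_positions = mask$indels,
                             config = selection)
  note("filter_target_snps", nrow(combined$snps), nrow(filt$targets))

  n_pri <- max(0L, round(priority_fraction * nrow(iso_map)))
  priority <- if (n_pri > 0) sample(iso_map$isotig, n_pri) else character()
  design <- if (nrow(filt$targets)) data.frame(
    isotig = filt$targets$isotig, pos = filt$targets$pos,
    design_score = round(stats::runif(nrow(filt$targets), 0.3, 1), 3),
    stringsAsFactors = FALSE) else NULL
  arr <- select_array_candidates(filt$targets, confidence, priority,
                                 design, selection)
  note("select_array_candidates", nrow(filt$targets),
       nrow(arr$selected))

  qc_summary <- NULL; qc <- NULL
  if (nrow(arr$selected)) {
    freqs <- pmin(pmax(arr$selected$mean_freq, 0.01), 0.5)
    gt <- simulate_genotypes(
      n_loci = nrow(arr$selected), n_samples = n_trees,
      maf_vector = freqs, no_call_rate = 0.02,
      seed = child_seed(config$seed, "array_genotypes"))
    rownames(gt$calls) <- paste(arr$selected$isotig, arr$selected$pos,
                                sep = "_")
    qc <- locus_qc(gt$calls)
    qc_summary <- summarize_array(qc)
    note("array_qc", nrow(arr$selected), qc_summary$n_successful)
  }

  stages <- list(reference = ref, pileups = pile, snv_calls = snv,
                 indel_calls = ind, combined = combined, mask = mask,
                 masked_reference = masked, confidence = confidence,
                 orientation = orientation, targets = filt,
                 array = arr, locus_qc = qc, array_summary = qc_summary)

  digests <- NULL
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(x, f) {
      p <- file.path(outdir, f)
      utils::write.table(x, p, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      p
    }
    paths <- c(
      {p <- file.path(outdir, "reference.fasta")
       write_reference_fasta(ref$sequences, p); p},
      {p <- file.path(outdir, "masked_reference.fasta")
       write_reference_fasta(masked$sequences, p); p},
      wr(ref$truth, "truth_variants.tsv"),
      wr(snv, "site_calls.tsv"),
      wr(combined$snps, "combined_snps.tsv"),
      wr(mask$snps, "flanking_snps.tsv"),
      wr(masked$indel_bed, "indel_mask.bed"),
      wr(confidence, "confidence.tsv"),
      wr(orientation, "orientation.tsv"),
      wr(filt$targets, "target_snps.tsv"),
      wr(arr$selected, "array_candidates.tsv"),
      if (!is.null(qc)) wr(qc, "locus_qc.tsv"))
    digests <- tools::md5sum(paths)
    names(digests) <- basename(names(digests))
  }

  manifest <- list(config = unclass(config), pf = pf,
                   params = unclass(params),
                   selection = unclass(selection),
                   n_trees = n_trees,
                   priority_fraction = priority_fraction,
                   counts = counts, digests = as.list(digests))
  list(manifest = manifest, stages = stages)
}

#' Write a pipeline manifest as JSON
#'
#' @param manifest manifest from \code{\link{run_pipeline}}.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Human-readable pipeline run report
#'
#' Prints, per stage, the input and output row counts (including zero
#' rejections) and the array accounting table when present, with every
#' percentage recomputable from the printed counts.
#'
#' @param run result of \code{\link{run_pipeline}}.
#' @param file connection to write to (default stdout).
#' @return The report lines, invisibly.
#' @export
pipeline_report <- function(run, file = stdout()) {
  cnt <- run$manifest$counts
  lines <- c("Pipeline run report", "===================", "")
  for (stage in names(cnt)) {
    n_in <- cnt[[stage]]$input; n_out <- cnt[[stage]]$output
    rej <- n_in - n_out
    lines <- c(lines, sprintf(
      "%-28s in: %8d  out: %8d  rejected: %8d", stage,
      as.integer(n_in), as.integer(n_out),
      as.integer(max(rej, 0))))
  }
  s <- run$stages$array_summary
  if (!is.null(s)) {
    lines <- c(lines, "", "Array accounting:")
    tb <- s$table
    for (i in seq_len(nrow(tb)))
      lines <- c(lines, sprintf(
        "  %-12s n = %6d  (%5.1f%% of attempted, %5.1f%% of assayed)",
        tb$category[i], tb$count[i], tb$pct_of_attempted[i],
        tb$pct_of_assayed[i]))
    lines <- c(lines, sprintf(
      "  called loci that are polymorphic: %.1f%%",
      attr(tb, "pct_called_polymorphic")))
    if (!is.na(s$bonferroni_alpha))
      lines <- c(lines, sprintf(
        "  HWE deviants: %d of %d successful (%.1f%%) at alpha = %.2g",
        s$n_hwe_deviant, s$n_successful, s$pct_hwe_deviant,
        s$bonferroni_alpha))
  }
  writeLines(lines, con = file)
  invisible(lines)
}
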