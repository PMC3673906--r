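# Hand-enumerated fixture: combined variants engineered so that one row
# violates each target-SNP rule and the survivors are known by hand.
make_combined <- function(isotig, pos, alleles = "A,G", min_p = 1e-5,
                          mean_p = min_p, max_mapq = 60, n_datasets = 3L,
                          mean_reads = 40, mean_freq = 0.25) {
  data.frame(isotig = isotig, pos = pos, ref = "A",
             n_datasets = n_datasets, alleles = alleles, min_p = min_p,
             mean_p = mean_p, chi_sq = 1, df = 2L * n_datasets,
             pooled_p = min_p, max_mapq = max_mapq,
             mean_reads = mean_reads, mean_freq = mean_freq,
             stringsAsFactors = FALSE)
}

iso_map <- data.frame(
  isotig = c("isoA1", "isoA2", "isoB1"),
  isogroup = c("grpA", "grpA", "grpB"),
  length = c(2000L, 900L, 1500L),
  stringsAsFactors = FALSE)

test_that("target filter applies the full cascade with a complete ledger", {
  tab <- rbind(
    make_combined("isoA1", 100L),                       # keep
    make_combined("isoA2", 100L),                       # not longest isotig
    make_combined("isoA1", 200L, alleles = "A,C,G"),    # tri-allelic
    make_combined("isoA1", 300L),                       # near indel (below)
    make_combined("isoA1", 400L, max_mapq = 35),        # low mapq
    make_combined("isoA1", 500L, min_p = 1e-3),         # above P_S
    make_combined("isoB1", 50L))                        # keep
  indels <- data.frame(isotig = "isoA1", pos = 305L,
                       stringsAsFactors = FALSE)
  res <- filter_target_snps(tab, iso_map, indels,
                            selection_config(ps_threshold = 1e-4))
  expect_identical(paste(res$targets$isotig, res$targets$pos),
                   c("isoA1 100", "isoB1 50"))
  expect_identical(nrow(res$targets) + nrow(res$ledger), nrow(tab))
  expect_setequal(res$ledger$reason,
                  c("NOT_LONGEST_ISOTIG", "NOT_BIALLELIC", "NEAR_INDEL",
                    "LOW_MAPQ", "ABOVE_PS"))
  expect_identical(res$targets$allele_pair, c("A/G", "A/G"))
  expect_identical(res$targets$iupac, c("R", "R"))
  expect_error(filter_target_snps(make_combined("ghost", 1L), iso_map),
               "isogroup")
})

test_that("relaxing the probability threshold never removes a target", {
  set.seed(77)
  n <- 60
  tab <- make_combined(rep("isoA1", n), seq(100L, by = 100L, length.out = n),
                       min_p = 10^runif(n, -8, -1))
  prev <- character(0)
  for (ps in c(1e-4, 1e-3, 1e-2)) {
    res <- filter_target_snps(tab, iso_map,
                              config = selection_config(ps_threshold = ps))
    cur <- paste(res$targets$isotig, res$targets$pos)
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

confidence_ok <- function(isotigs)
  data.frame(isotig_id = isotigs, class = "C1", stringsAsFactors = FALSE)

as_targets <- function(tab, iso = iso_map) {
  filter_target_snps(tab, iso, config = selection_config())$targets
}

test_that("array selection: priority spacing and quota", {
  tab <- rbind(make_combined("isoA1", 100L, mean_p = 1e-6),
               make_combined("isoA1", 130L, mean_p = 1e-7),
               make_combined("isoA1", 200L, mean_p = 1e-5))
  tg <- as_targets(tab)
  res <- select_array_candidates(tg, confidence_ok("isoA1"),
                                 priority_isotigs = "isoA1")
  # two selected; the 100/130 pair (30 nt apart) is never chosen together
  expect_identical(nrow(res$selected), 2L)
  expect_setequal(res$selected$pos, c(130L, 200L))
  expect_identical(res$ledger$reason, "TOO_CLOSE")
  # quota: a third eligible SNP at distance is cut by the 2-per-isotig cap
  tab2 <- rbind(tab, make_combined("isoA1", 300L, mean_p = 1e-4))
  res2 <- select_array_candidates(as_targets(tab2),
                                  confidence_ok("isoA1"),
                                  priority_isotigs = "isoA1")
  expect_identical(nrow(res2$selected), 2L)
  expect_true("ISOTIG_QUOTA" %in% res2$ledger$reason)
})

test_that("array selection: non-priority cascade and assay-type rule", {
  ds <- function(tg) data.frame(isotig = tg$isotig, pos = tg$pos,
                                design_score = 0.9,
                                stringsAsFactors = FALSE)
  # A/T SNP dropped for non-priority, kept under priority
  at <- make_combined("isoA1", 100L, alleles = "A,T")
  at$ref <- "A"
  tg <- as_targets(at)
  non <- select_array_candidates(tg, confidence_ok("isoA1"),
                                 design_scores = ds(tg))
  expect_identical(nrow(non$selected), 0L)
  expect_identical(non$ledger$reason, "INFINIUM_I")
  pri <- select_array_candidates(tg, confidence_ok("isoA1"),
                                 priority_isotigs = "isoA1",
                                 design_scores = ds(tg))
  expect_identical(nrow(pri$selected), 1L)

  # dataset support, best-per-isotig, and final filters
  tab <- rbind(
    make_combined("isoA1", 100L, n_datasets = 1L),         # too few datasets
    make_combined("isoA1", 200L, mean_p = 1e-6),           # best, survives
    make_combined("isoA1", 300L, mean_p = 1e-5),           # not most probable
    make_combined("isoB1", 100L, mean_reads = 5),          # low reads
    make_combined("isoB1", 200L, mean_p = 1))              # placeholder
  tab$min_p <- 1e-6
  tg <- as_targets(tab)
  res <- select_array_candidates(tg, confidence_ok(c("isoA1", "isoB1")),
                                 design_scores = ds(tg))
  expect_identical(paste(res$selected$isotig, res$selected$pos),
                   "isoA1 200")
  expect_identical(nrow(res$selected) + nrow(res$ledger), nrow(tg))
  expect_true(all(c("TOO_FEW_DATASETS", "NOT_MOST_PROBABLE",
                    "LOW_MEAN_READS") %in% res$ledger$reason))

  # absent design score fails the >= 0.60 rule for non-priority SNPs
  lone <- as_targets(make_combined("isoB1", 400L))
  noscore <- select_array_candidates(lone, confidence_ok("isoB1"))
  expect_identical(noscore$ledger$reason, "LOW_DESIGN_SCORE")

  # low-frequency rule uses the minor-allele read frequency
  rare <- as_targets(make_combined("isoB1", 500L, mean_freq = 0.97))
  lowf <- select_array_candidates(rare, confidence_ok("isoB1"),
                                  design_scores = ds(rare))
  expect_identical(lowf$ledger$reason, "LOW_FREQUENCY")
})

test_that("excluded confidence classes are dropped first", {
  tg <- as_targets(make_combined("isoA1", 100L))
  res <- select_array_candidates(
    tg, data.frame(isotig_id = "isoA1", class = "C5",
                   stringsAsFactors = FALSE),
    priority_isotigs = "isoA1")
  expect_identical(nrow(res$selected), 0L)
  expect_identical(res$ledger$reason, "LOW_CONFIDENCE_CLASS")
})

test_that("selection is invariant to input row order", {
  set.seed(31)
  tab <- rbind(
    make_combined("isoA1", c(100L, 180L, 260L, 340L),
                  mean_p = c(1e-6, 1e-7, 1e-5, 1e-4)),
    make_combined("isoB1", c(50L, 400L), mean_p = c(1e-6, 1e-3)))
  tg <- as_targets(tab)
  ds <- data.frame(isotig = tg$isotig, pos = tg$pos, design_score = 0.9,
                   stringsAsFactors = FALSE)
  conf <- confidence_ok(c("isoA1", "isoB1"))
  ref <- select_array_candidates(tg, conf, "isoA1", ds)$selected
  for (i in 1:5) {
    perm <- tg[sample(nrow(tg)), ]
    got <- select_array_candidates(perm, conf, "isoA1", ds)$selected
    expect_identical(got, ref)
  }
})

test_that("resource extrapolation rounds to the nearest SNP", {
  expect_identical(extrapolate_resource(278979, 0.725), 202260)
  expect_identical(extrapolate_resource(150025, 0.725), 108768)
  expect_identical(extrapolate_resource(12345, 0), 0)
  expect_error(extrapolate_resource(-1, 0.5), "n_candidates")
})

test_that("design strings carry masked flanks around the target", {
  seqs <- c(iso1 = paste(rep("A", 200), collapse = ""))
  mask <- data.frame(isotig = "iso1", pos = 95L, alleles = "A,G",
                     stringsAsFactors = FALSE)
  masked <- build_masked_reference(seqs, mask)$sequences
  s <- flanking_design_sequence(masked, "iso1", 100L, "A/C", flank = 10L)
  # flank spans positions 90-99; the masked base at 95 is its 6th char
  expect_identical(s, "AAAAARAAAA[A/C]AAAAAAAAAA")
})
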