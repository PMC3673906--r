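test_that("reference simulation is deterministic and respects config", {
  cfg <- sim_config(n_isotigs = 4, isotig_length_range = c(300L, 600L),
                    seed = 7)
  a <- simulate_reference(cfg)
  b <- simulate_reference(cfg)
  expect_identical(a, b)
  expect_length(a$sequences, 4)
  lens <- nchar(a$sequences)
  expect_true(all(lens >= 300 & lens <= 600))
  expect_true(all(strsplit(paste(a$sequences, collapse = ""), "")[[1]] %in%
                    c("A", "C", "G", "T")))
  # truth consistency
  tr <- a$truth
  expect_true(all(tr$position >= 1))
  expect_true(all(tr$position <= lens[tr$isotig_id]))
  expect_true(all(tr$ref_allele != tr$alt_allele))
  expect_true(all(substring(a$sequences[tr$isotig_id], tr$position,
                            tr$position) == tr$ref_allele))
})

test_that("zero variant density yields an empty truth table", {
  ref <- simulate_reference(sim_config(n_isotigs = 1,
                                       variant_density = 0, seed = 3))
  expect_identical(nrow(ref$truth), 0L)
})

test_that("invalid length range is rejected", {
  expect_error(sim_config(isotig_length_range = c(0L, 100L)),
               "minimum")
})

test_that("planted variant count falls in the Poisson band implied by the
           generator's own length draws", {
  cfg <- sim_config(n_isotigs = 10, isotig_length_range = c(500L, 1000L),
                    variant_density = 2, indel_fraction = 0, seed = 1)
  ref <- simulate_reference(cfg)
  lambda <- sum(nchar(ref$sequences)) * 2 / 1000
  band <- qpois(c(0.005, 0.995), lambda)
  expect_gte(nrow(ref$truth), band[1])
  expect_lte(nrow(ref$truth), band[2])
})

test_that("pileups conserve depth and honor the planted error model", {
  cfg <- sim_config(n_isotigs = 2, isotig_length_range = c(200L, 300L),
                    n_datasets = 2, error_rate = 0, variant_density = 0,
                    seed = 11)
  ref <- simulate_reference(cfg)
  pile <- simulate_pileups(ref, config = cfg)
  cnt <- as.matrix(pile[, c("countA", "countC", "countG", "countT")])
  expect_true(all(rowSums(cnt) + pile$countN == pile$depth))
  # error 0, no variants: every read shows the reference base
  ref_count <- cnt[cbind(seq_len(nrow(cnt)), match(pile$ref, c("A","C","G","T")))]
  expect_true(all(ref_count == pile$depth))
})

test_that("a fixed planted allele with zero error yields alt == depth", {
  cfg <- sim_config(n_isotigs = 1, isotig_length_range = c(50L, 50L),
                    n_datasets = 1, error_rate = 0, variant_density = 0,
                    seed = 5)
  ref <- simulate_reference(cfg)
  truth <- data.frame(isotig_id = names(ref$sequences), position = 10L,
                      ref_allele = substring(ref$sequences, 10, 10),
                      alt_allele = "X", is_indel = FALSE, indel_seq = "",
                      freq_ds1 = 1.0, stringsAsFactors = FALSE)
  truth$alt_allele <- setdiff(c("A","C","G","T"), truth$ref_allele)[1]
  pile <- simulate_pileups(ref$sequences, truth, cfg)
  site <- pile[pile$pos == 10, ]
  altc <- site[[paste0("count", truth$alt_allele)]]
  expect_identical(altc, site$depth)
})

test_that("mean alt fraction matches the generator's closed form", {
  # planted freq 0.2, error e: expected alt fraction f(1-e) + (1-f)e/3
  f <- 0.2; e <- 0.01; n_sites <- 1000L
  cfg <- sim_config(n_isotigs = 1, isotig_length_range = c(n_sites, n_sites),
                    n_datasets = 1, error_rate = e, variant_density = 0,
                    depth_mean = 100, depth_dispersion = 1e6, seed = 23)
  ref <- simulate_reference(cfg)
  refb <- strsplit(ref$sequences[[1]], "")[[1]]
  alt <- vapply(refb, function(b) setdiff(c("A","C","G","T"), b)[1], "")
  truth <- data.frame(isotig_id = names(ref$sequences),
                      position = seq_len(n_sites), ref_allele = refb,
                      alt_allele = alt, is_indel = FALSE, indel_seq = "",
                      freq_ds1 = f, stringsAsFactors = FALSE)
  pile <- simulate_pileups(ref$sequences, truth, cfg)
  cnt <- as.matrix(pile[, c("countA", "countC", "countG", "countT")])
  altc <- cnt[cbind(seq_len(nrow(cnt)), match(alt, c("A","C","G","T")))]
  frac <- sum(altc) / sum(pile$depth)
  expected <- f * (1 - e) + (1 - f) * e / 3
  se <- sqrt(expected * (1 - expected) / sum(pile$depth))
  expect_lt(abs(frac - expected), 3 * se)
})

test_that("pileup simulation rejects truth off the reference", {
  cfg <- sim_config(n_isotigs = 1, seed = 1)
  ref <- simulate_reference(cfg)
  bad <- data.frame(isotig_id = "nope", position = 1L, ref_allele = "A",
                    alt_allele = "C", is_indel = FALSE, indel_seq = "",
                    freq_ds1 = 0.5, freq_ds2 = 0, freq_ds3 = 0,
                    freq_ds4 = 0, freq_ds5 = 0, stringsAsFactors = FALSE)
  expect_error(simulate_pileups(ref$sequences, bad, cfg), "absent")
})

test_that("stranded counts follow the orientation model", {
  expect_error(simulate_stranded_counts(1, misorientation_rate = 0.5),
               "misorientation")
  z <- simulate_stranded_counts(3, "+", reads_per_ref = 50,
                                misorientation_rate = 0, seed = 2)
  expect_true(all(z$D == 0) && all(z$C == 50))
  z0 <- simulate_stranded_counts(2, "+", reads_per_ref = 0, seed = 2)
  expect_true(all(z0$D == 0) && all(z0$C == 0))
  big <- simulate_stranded_counts(1, "+", reads_per_ref = 10000,
                                  misorientation_rate = 0.1, seed = 9)
  frac <- big$C / (big$C + big$D)
  se <- sqrt(0.9 * 0.1 / 10000)
  expect_lt(abs(frac - 0.9), 3 * se)
})

test_that("genotype simulation recovers its parameters", {
  g0 <- simulate_genotypes(5, 20, maf_vector = 0, seed = 4)
  expect_true(all(g0$calls == "AA"))
  g <- simulate_genotypes(1, 10000, maf_vector = 0.5, inbreeding_f = 0,
                          seed = 8)
  ho <- mean(g$calls == "AB")
  se <- sqrt(0.5 * 0.5 / 10000)
  expect_lt(abs(ho - 0.5), 3 * se)
  gn <- simulate_genotypes(1, 10000, maf_vector = 0.25,
                           no_call_rate = 0.2, seed = 12)
  cr <- mean(gn$calls != "NC")
  se <- sqrt(0.8 * 0.2 / 10000)
  expect_lt(abs(cr - 0.8), 3 * se)
  expect_error(simulate_genotypes(1, 10, maf_vector = 0.5,
                                  inbreeding_f = -1.5),
               "inbreeding_f")
})

test_that("match-table plans round-trip through the classifier", {
  plan <- c(C1 = 3, C2 = 2, C3 = 2, C4 = 2, C5 = 2, C6 = 2, C7 = 5)
  mt <- simulate_match_table(plan, seed = 6)
  cls <- classify_isotigs(mt$matches, all_isotigs = mt$all_isotigs)
  got <- cls$class[match(mt$expected$isotig_id, cls$isotig_id)]
  expect_identical(got, mt$expected$class)
  # C7-only plan: no match rows at all
  m7 <- simulate_match_table(c(C7 = 5), seed = 1)
  expect_identical(nrow(m7$matches), 0L)
  expect_length(m7$all_isotigs, 5)
  # C1 plan: distinct subjects, no sharing
  m1 <- simulate_match_table(c(C1 = 3), seed = 1)
  expect_identical(anyDuplicated(m1$matches$sseqid), 0L)
  # infeasible partner plans are rejected
  expect_error(simulate_match_table(c(C5 = 1)), "overlapping")
  expect_error(simulate_match_table(c(C3 = 1)), "partner")
})
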