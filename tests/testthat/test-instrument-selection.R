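# the filter cascade and allele harmonization

test_that("significance filter applies the strict threshold", {
  tab <- make_gwas(n = 3, pvalue = c(1e-9, 1e-7, 1e-8))
  kept <- filter_exposure_significant(tab)
  expect_equal(kept$data$pvalue, c(1e-9, 1e-8))

  all_null <- make_gwas(n = 3, pvalue = rep(0.5, 3))
  expect_warning(out <- filter_exposure_significant(all_null), "no SNPs")
  expect_equal(n_records(out), 0)

  loose <- filter_exposure_significant(tab, selection_config(p_exposure = 1))
  expect_equal(n_records(loose), 3)
})

test_that("greedy clumping keeps the best SNP per LD dependency", {
  tab <- make_gwas(n = 2, pvalue = c(1e-10, 1e-9))
  ld <- ld_from_pairs(data.frame(snp_a = "rs001", snp_b = "rs002", r2 = 0.5))
  out <- clump(tab, ld)
  expect_equal(out$data$snp_id, "rs001")

  indep <- make_gwas(n = 3, pvalue = c(1e-10, 1e-9, 1e-8))
  out2 <- clump(indep, ld_from_pairs(data.frame(snp_a = character(0),
                                                snp_b = character(0),
                                                r2 = numeric(0))))
  expect_equal(n_records(out2), 3)
})

test_that("clumping matches an exhaustive greedy-by-p oracle on an LD block", {
  ids <- sprintf("rs%03d", 1:6)
  p <- c(1e-8, 1e-12, 1e-9, 1e-10, 1e-11, 1e-7)
  pairs <- data.frame(
    snp_a = c("rs001", "rs001", "rs002", "rs003", "rs004"),
    snp_b = c("rs002", "rs003", "rs005", "rs004", "rs006"),
    r2 = c(0.8, 0.4, 0.9, 0.6, 0.3))
  tab <- make_gwas(n = 6, snp_id = ids, pvalue = p)
  ld <- ld_from_pairs(pairs)
  cfg <- selection_config(clump_r2 = 0.25)

  # independent brute-force greedy walk over the same inputs
  r2_of <- function(a, b) {
    hit <- (pairs$snp_a == a & pairs$snp_b == b) | (pairs$snp_a == b & pairs$snp_b == a)
    if (any(hit)) pairs$r2[hit] else 0
  }
  remaining <- ids[order(p, ids)]
  expected <- character(0)
  while (length(remaining)) {
    idx <- remaining[1]
    expected <- c(expected, idx)
    remaining <- remaining[-1]
    remaining <- remaining[vapply(remaining, function(s) r2_of(idx, s) <= 0.25, logical(1))]
  }
  expect_equal(clump(tab, ld, cfg)$data$snp_id, expected)
})

test_that("clumping falls back to the distance window without r2", {
  tab <- make_gwas(n = 3, pvalue = c(1e-10, 1e-9, 1e-8),
                   pos = c(100000, 105000, 200000))
  out <- clump(tab, ld = NULL, cfg = selection_config(clump_window_kb = 10))
  expect_equal(out$data$snp_id, c("rs001", "rs003"))

  no_info <- make_gwas(n = 2, pvalue = c(1e-10, 1e-9), pos = c(NA, NA))
  expect_warning(same <- clump(no_info, ld = NULL), "clumping skipped")
  expect_equal(n_records(same), 2)
})

test_that("outcome-associated SNPs are excluded; unassessable SNPs retained", {
  expo <- make_gwas(n = 4, pvalue = rep(1e-10, 4))
  outc <- make_gwas(n = 3, snp_id = c("rs001", "rs002", "rs003"),
                    pvalue = c(1e-12, 1e-3, 4.9e-8))
  out <- suppressMessages(exclude_outcome_associated(expo, outc))
  # rs001 excluded (1e-12), rs003 excluded (4.9e-8 < 5e-8), rs004 unassessable
  expect_equal(out$data$snp_id, c("rs002", "rs004"))
  expect_message(exclude_outcome_associated(expo, outc), "retained unassessed")
})

test_that("harmonization handles swaps, strand complements and palindromes", {
  expo <- make_gwas(n = 5, snp_id = sprintf("s%d", 1:5),
                    effect_allele = c("A", "A", "A", "A", "A"),
                    other_allele = c("G", "G", "G", "T", "T"),
                    eaf = c(0.3, 0.3, 0.3, 0.10, 0.10),
                    beta = c(0.1, 0.1, 0.1, 0.1, 0.1))
  outc <- make_gwas(n = 5, snp_id = sprintf("s%d", 1:5),
                    effect_allele = c("G", "T", "C", "A", "A"),
                    other_allele = c("A", "C", "T", "T", "T"),
                    eaf = c(0.7, 0.3, 0.7, 0.12, 0.50),
                    beta = c(-0.05, 0.02, -0.03, 0.04, 0.04))
  set <- harmonize(expo, outc)
  rec <- set$records
  # s1: swapped alleles -> Gamma negated
  expect_equal(rec$Gamma[rec$snp_id == "s1"], 0.05)
  expect_true(rec$flipped[rec$snp_id == "s1"])
  expect_equal(rec$eaf_outcome[rec$snp_id == "s1"], 0.3)
  # s2: complementary strand, same orientation -> copied
  expect_equal(rec$Gamma[rec$snp_id == "s2"], 0.02)
  expect_false(rec$flipped[rec$snp_id == "s2"])
  # s3: complementary strand, swapped -> negated
  expect_equal(rec$Gamma[rec$snp_id == "s3"], 0.03)
  # s4: palindromic, EAFs agree (0.10 vs 0.12) -> retained unflipped
  expect_equal(rec$Gamma[rec$snp_id == "s4"], 0.04)
  expect_false(rec$flipped[rec$snp_id == "s4"])
  expect_true(rec$palindromic[rec$snp_id == "s4"])
  # s5: palindromic with outcome MAF 0.50 >= 0.42 -> dropped
  expect_false("s5" %in% rec$snp_id)
  expect_equal(unname(set$provenance["dropped_palindromic_ambiguous_maf"]), 1)
})

test_that("palindromic orientation flips when frequencies disagree", {
  expo <- make_gwas(n = 1, snp_id = "s1", effect_allele = "A", other_allele = "T",
                    eaf = 0.10, beta = 0.1)
  outc <- make_gwas(n = 1, snp_id = "s1", effect_allele = "A", other_allele = "T",
                    eaf = 0.88, beta = 0.04)
  rec <- harmonize(expo, outc)$records
  expect_equal(rec$Gamma, -0.04)
  expect_true(rec$flipped)
  expect_equal(rec$eaf_outcome, 0.12)
})

test_that("harmonize errors on zero overlap and drops incompatible pairs", {
  expo <- make_gwas(n = 2, snp_id = c("a", "b"))
  outc <- make_gwas(n = 2, snp_id = c("c", "d"))
  expect_error(harmonize(expo, outc), "no shared SNPs")

  # A/C shares one allele with the exposure's A/G but matches it under
  # neither orientation nor strand complement (T/G) -> incompatible
  outc2 <- make_gwas(n = 2, snp_id = c("a", "b"),
                     effect_allele = c("A", "A"), other_allele = c("C", "G"))
  set <- harmonize(expo, outc2)
  expect_equal(set$records$snp_id, "b")
  expect_equal(unname(set$provenance["dropped_incompatible_alleles"]), 1)
})

test_that("weak-instrument filter uses F = (beta/se)^2 with strict < 10", {
  iset <- make_iset(gamma = c(0.02, 0.01, 0.01), Gamma = c(0.01, 0.01, 0.01),
                    se_gamma = c(0.005, 0.005, 0.01 / sqrt(10)))
  expect_equal(iset$records$f_stat, c(16, 4, 10), tolerance = 1e-12)
  out <- filter_weak(iset)
  expect_setequal(out$records$snp_id, c("rs001", "rs003"))  # F = 10 kept
})

test_that("filters are idempotent and provenance counts sum", {
  tab <- make_gwas(n = 6, pvalue = c(1e-9, 1e-7, 1e-10, 0.5, 1e-8, 1e-12))
  once <- filter_exposure_significant(tab)
  twice <- filter_exposure_significant(once)
  expect_equal(once$data, twice$data)

  ld <- ld_from_pairs(data.frame(snp_a = "rs003", snp_b = "rs006", r2 = 0.9))
  c1 <- clump(once, ld)
  c2 <- clump(c1, ld)
  expect_equal(c1$data, c2$data)

  outc <- make_gwas(n = 6, beta = rep(0.01, 6), se = rep(0.05, 6),
                    pvalue = c(0.5, 0.5, 0.5, 0.5, 1e-9, 0.5))
  ex <- suppressMessages(exclude_outcome_associated(c1, outc))
  set <- harmonize(ex, outc)
  # every input SNP accounted for: kept + sum of stage drops = input
  drops <- set$provenance[grep("^dropped_", names(set$provenance))]
  expect_equal(unname(set$provenance["input"]), nrow(set$records) + sum(drops))
})

test_that("re-harmonizing a harmonized exposure against the same outcome is stable", {
  set.seed(42)
  sim <- simulate_mediation_gwas(simulation_config(seed = 42))
  cfg <- selection_config()
  sig <- filter_exposure_significant(sim$exposure, cfg)
  set1 <- harmonize(sig, sim$outcome, cfg)
  # rebuild an exposure table restricted to harmonized SNPs; harmonize again
  sub <- sig
  sub$data <- sig$data[sig$data$snp_id %in% set1$records$snp_id, ]
  set2 <- harmonize(sub, sim$outcome, cfg)
  expect_equal(set1$records, set2$records)
})
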