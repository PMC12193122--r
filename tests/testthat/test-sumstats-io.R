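# reading, validating and round-tripping summary-statistics tables

test_that("well-formed tables parse identically regardless of column order", {
  path_ordered <- withr::local_tempfile(fileext = ".tsv")
  path_shuffled <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("SNP\teffect_allele\tother_allele\teaf\tbeta\tse\tpval\tn",
               "rs1\ta\tg\t0.2\t0.05\t0.01\t1e-6\t5000",
               "rs2\tT\tC\t0.4\t-0.03\t0.02\t0.1\t5000",
               "rs3\tG\tA\t0.6\t0.10\t0.02\t1e-8\t5000"), path_ordered)
  writeLines(c("P\tB\tSE\tMARKER\tA1\tA2\tFREQ\tN",
               "1e-6\t0.05\t0.01\trs1\ta\tg\t0.2\t5000",
               "0.1\t-0.03\t0.02\trs2\tT\tC\t0.4\t5000",
               "1e-8\t0.10\t0.02\trs3\tG\tA\t0.6\t5000"), path_shuffled)
  t1 <- read_gwas_table(path_ordered, trait_name = "x")
  t2 <- read_gwas_table(path_shuffled, trait_name = "x",
                        column_map = c(snp_id = "MARKER", effect_allele = "A1",
                                       other_allele = "A2", eaf = "FREQ",
                                       beta = "B", se = "SE", pvalue = "P"))
  expect_equal(n_records(t1), 3)
  expect_equal(t1$data[c("snp_id", "effect_allele", "other_allele", "eaf",
                         "beta", "se", "pvalue")],
               t2$data[c("snp_id", "effect_allele", "other_allele", "eaf",
                         "beta", "se", "pvalue")])
  expect_equal(t1$data$effect_allele[1], "A")  # upper-cased
})

test_that("invalid rows are dropped with a reported count, never silently", {
  df <- data.frame(snp_id = c("a", "b", "c", "d", "e"),
                   effect_allele = c("A", "A", "AT", "A", "A"),
                   other_allele = c("G", "G", "T", "A", "G"),
                   eaf = c(0.5, 0.5, 0.5, 0.5, 0.5),
                   beta = c(0.1, 0.1, 0.1, 0.1, 0.1),
                   se = c(0.05, 0, 0.05, 0.05, 0.05),
                   pvalue = c(0.05, 0.05, 0.05, 0.05, 1.5))
  tab <- suppressWarnings(suppressMessages(gwas_table(df, "t")))
  # b: se = 0; c: indel; d: identical alleles; e: p > 1
  expect_equal(n_records(tab), 1)
  expect_equal(tab$data$snp_id, "a")
  expect_equal(unname(tab$provenance["dropped_invalid"]), 4)
  expect_message(gwas_table(df[1:2, ], "t"), "dropped 1 invalid row")
})

test_that("missing mandatory columns raise an error naming the column", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("SNP\teffect_allele\tother_allele\tbeta\tpval",
               "rs1\tA\tG\t0.1\t0.01"), path)
  expect_error(read_gwas_table(path), "se")
})

test_that("write/read round-trip is the identity, blank-cell EAF included", {
  tab <- make_gwas(n = 5, beta = c(0.11, -0.23, 0.05, 0.999, -1.2),
                   se = c(0.01, 0.2, 0.033, 0.5, 0.7),
                   eaf = c(0.21, 0.5, NA, 0.87, NA))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_gwas_table(tab, path)
  back <- read_gwas_table(path, trait_name = tab$trait_name)
  expect_equal(back$data, tab$data)
  expect_true(all(is.na(back$data$eaf[c(3, 5)])))

  empty <- make_gwas(n = 0)
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_gwas_table(empty, path2)
  expect_equal(length(readLines(path2)), 1)  # header only
  expect_equal(n_records(read_gwas_table(path2)), 0)
})

test_that("inconsistent beta/se vs p pairs warn but are not altered", {
  df <- data.frame(snp_id = "a", effect_allele = "A", other_allele = "G",
                   eaf = 0.5, beta = 0.5, se = 0.1, pvalue = 0.9)
  expect_warning(tab <- gwas_table(df, "t"), "inconsistent")
  expect_equal(tab$data$beta, 0.5)
  expect_equal(tab$data$pvalue, 0.9)
})

test_that("LD lookup is symmetric, defaults to zero, and matrix equals pair list", {
  ld <- ld_from_pairs(data.frame(snp_a = "s1", snp_b = "s2", r2 = 0.5))
  expect_equal(ld_r2(ld, "s1", "s2"), 0.5)
  expect_equal(ld_r2(ld, "s2", "s1"), 0.5)
  expect_equal(ld_r2(ld, "s1", "s3"), 0)
  expect_equal(ld_r2(ld, "s3", "s3"), 1)

  m <- matrix(c(1, 0.5, 0.1, 0.5, 1, 0.2, 0.1, 0.2, 1), nrow = 3,
              dimnames = list(c("s1", "s2", "s3"), c("s1", "s2", "s3")))
  path_m <- withr::local_tempfile(fileext = ".tsv")
  write.table(cbind(snp = rownames(m), as.data.frame(m)), path_m, sep = "\t",
              quote = FALSE, row.names = FALSE)
  path_p <- withr::local_tempfile(fileext = ".tsv")
  write.table(data.frame(snp_a = c("s1", "s1", "s2"), snp_b = c("s2", "s3", "s3"),
                         r2 = c(0.5, 0.1, 0.2)), path_p, sep = "\t",
              quote = FALSE, row.names = FALSE)
  ld_m <- read_ld(path_m)
  ld_p <- read_ld(path_p)
  for (pair in list(c("s1", "s2"), c("s1", "s3"), c("s2", "s3"))) {
    expect_equal(ld_r2(ld_m, pair[1], pair[2]), ld_r2(ld_p, pair[1], pair[2]))
  }
  expect_error(ld_from_pairs(data.frame(snp_a = "a", snp_b = "b", r2 = 1.2)),
               "\\[0, 1\\]")
})
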