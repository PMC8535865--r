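test_that("delimited read maps genotypes and phenotype correctly", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,snp1,snp2,phenotype",
               "s1,CC,AA,0", "s2,CT,AG,1", "s3,TT,AA,1"), path)
  d <- read_genotypes(path)
  expect_identical(dim(d$genotypes), c(3L, 2L))
  expect_identical(d$phenotype, c(0L, 1L, 1L))
  ad <- additive_coding(d)
  expect_identical(unname(ad[, "snp1"]), c(0L, 1L, 2L))
  expect_identical(sort(unique(as.vector(ad))), c(0L, 1L, 2L))
})

test_that("heterozygotes are canonicalised and allele ties broken alphabetically", {
  g <- matrix(c("TC", "CT", "CC", "AA", "GA", "AG"), nrow = 3,
              dimnames = list(NULL, c("x", "y")))
  d <- genotype_data(g, c(0, 1, 0))
  expect_identical(unname(d$genotypes[, "x"]), c("CT", "CT", "CC"))
  expect_identical(unname(d$genotypes[, "y"]), c("AA", "AG", "AG"))
  # x alleles: C x4, T x2 -> major C; y alleles: A x4, G x2 -> major A
  expect_identical(unname(d$allele_map["major", "x"]), "C")
  expect_identical(unname(d$allele_map["major", "y"]), "A")
  # exact 50/50 allele frequency: alphabetical major
  tie <- genotype_data(matrix(c("AG", "AG"), ncol = 1,
                              dimnames = list(NULL, "t")), c(0, 1))
  expect_identical(unname(tie$allele_map["major", "t"]), "A")
})

test_that("malformed tokens and >2 alleles are rejected with location info", {
  g <- matrix(c("CC", "CX"), ncol = 1, dimnames = list(c("a", "b"), "s"))
  expect_error(genotype_data(g, c(0, 1)), "malformed genotype.*'b'")
  g2 <- matrix(c("CC", "AT"), ncol = 1, dimnames = list(NULL, "s"))
  expect_error(genotype_data(g2, c(0, 1)), "distinct alleles")
  expect_error(genotype_data(matrix("CC", 2, 1), c(0, 2)), "binary")
})

test_that("write/read round-trips are bit-identical, including a cohort-scale dataset", {
  d <- toy_dataset(n = 60, seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_genotypes(d, path)
  expect_same_dataset(read_genotypes(path), d)

  big <- make_cohort_dataset(cohort_sim_config(n_snps = 120, seed = 5))
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_genotypes(big, path2)
  expect_equal(length(readLines(path2)), 272L)  # header + samples
  expect_same_dataset(read_genotypes(path2), big)
})

test_that("empty dataset writes a header-only file", {
  d <- genotype_data(matrix(character(), 0, 2,
                            dimnames = list(NULL, c("a", "b"))),
                     integer())
  path <- withr::local_tempfile(fileext = ".csv")
  write_genotypes(d, path)
  expect_identical(readLines(path), "sample_id,a,b,phenotype")
})

test_that("PLINK .raw coding conventions are honoured", {
  path <- withr::local_tempfile(fileext = ".raw")
  writeLines(c("FID IID PAT MAT SEX PHENOTYPE rs1_T rs2_A",
               "f1 s1 0 0 1 1 0 2",
               "f2 s2 0 0 2 2 2 NA"), path)
  d <- read_plink_raw(path)
  expect_identical(d$phenotype, c(0L, 1L))
  ad <- additive_coding(d)
  expect_identical(unname(ad[, "rs1"]), c(0L, 2L))  # 0 = homozygous major
  expect_true(is.na(ad[2, "rs2"]))
  # homozygous major vs homozygous minor genotype categories
  expect_identical(substr(d$genotypes[1, "rs1"], 1, 1),
                   substr(d$genotypes[1, "rs1"], 2, 2))
  expect_false(d$genotypes[1, "rs1"] == d$genotypes[2, "rs1"])
})

test_that("PLINK round trip equals the delimited read of the same dataset", {
  d <- toy_dataset(n = 40, seed = 9, n_snps = 4)
  raw <- withr::local_tempfile(fileext = ".raw")
  csv <- withr::local_tempfile(fileext = ".csv")
  write_plink_raw(d, raw)
  write_genotypes(d, csv)
  from_csv <- read_genotypes(csv)
  from_raw <- read_plink_raw(raw,
                             partner_alleles = setNames(
                               d$allele_map["major", ], d$snp_ids))
  expect_identical(from_raw$genotypes, from_csv$genotypes)
  expect_identical(from_raw$phenotype, from_csv$phenotype)
  # without partner alleles the additive coding still matches exactly
  from_raw2 <- read_plink_raw(raw)
  expect_identical(additive_coding(from_raw2), additive_coding(from_csv))
})

test_that("PLINK format errors are reported", {
  path <- withr::local_tempfile(fileext = ".raw")
  writeLines(c("FID IID PAT MAT SEX rs1_T", "f1 s1 0 0 1 0"), path)
  expect_error(read_plink_raw(path), "PHENOTYPE")
  path2 <- withr::local_tempfile(fileext = ".raw")
  writeLines(c("FID IID PAT MAT SEX PHENOTYPE rs1_T",
               "f1 s1 0 0 1 1 3"), path2)
  expect_error(read_plink_raw(path2), "outside 0/1/2")
})

test_that("additive coding is a per-SNP bijection onto a subset of 0..2", {
  for (seed in 1:5) {
    d <- toy_dataset(n = 50, seed = seed)
    ad <- additive_coding(d)
    for (j in seq_along(d$snp_ids)) {
      cats <- d$genotypes[, j]
      expect_identical(length(unique(cats)), length(unique(ad[, j])))
      expect_true(all(tapply(ad[, j], cats, function(v)
        length(unique(v))) == 1L))
    }
  }
})

test_that("incomplete samples are dropped before analysis", {
  g <- matrix(c("CC", "NN", "CT", "AA", "AG", "AA"), nrow = 3,
              dimnames = list(NULL, c("x", "y")))
  d <- genotype_data(g, c(0, 1, 1))
  d2 <- drop_incomplete_samples(d)
  expect_identical(length(d2$sample_ids), 2L)
  expect_identical(d2$phenotype, c(0L, 1L))
  expect_error(label_cells(d, "x"), "missing genotypes")
})
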