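test_that("unpacked EIGENSTRAT trio reads into the expected dosage matrix", {
  prefix <- file.path(withr::local_tempdir(), "toy")
  # disk digits count reference-allele copies; internal calls are alt dosage
  writeLines(c("20", "09", "22"), paste0(prefix, ".geno"))
  writeLines(c("rs1\t1\t0.001\t100\tA\tC",
               "rs2\t1\t0.002\t200\tA\tC",
               "rs3\t2\t0.001\t100\tG\tT"), paste0(prefix, ".snp"))
  writeLines(c("I1\tM\tPopA", "I2\tF\tPopB"), paste0(prefix, ".ind"))
  ds <- read_eigenstrat(prefix, pseudo_haploid = TRUE)
  expect_identical(unname(ds$calls[1, ]), c(0L, 2L))
  expect_identical(unname(ds$calls[2, ]), c(2L, NA_integer_))
  expect_identical(unname(ds$calls[3, ]), c(0L, 0L))
  expect_equal(ds$variants$chrom, c("1", "1", "2"))
  expect_equal(ds$samples$population, c("PopA", "PopB"))
})

test_that("write/read round-trips are bit-identical for both dialects", {
  ds <- toy_dataset(n_v = 37, n_s = 7, pseudo = FALSE, missing_rate = 0.15)
  for (packed in c(FALSE, TRUE)) {
    prefix <- file.path(withr::local_tempdir(), "rt")
    write_eigenstrat(ds, prefix, packed = packed)
    back <- read_eigenstrat(prefix, pseudo_haploid = FALSE)
    expect_equal(unname(back$calls), unname(ds$calls))
    expect_equal(back$variants$gpos, ds$variants$gpos)
    expect_equal(back$samples, ds$samples[names(back$samples)])
    # byte-level round trip of the .geno file
    prefix2 <- file.path(withr::local_tempdir(), "rt2")
    write_eigenstrat(back, prefix2, packed = packed)
    expect_identical(readBin(paste0(prefix, ".geno"), "raw", 1e6),
                     readBin(paste0(prefix2, ".geno"), "raw", 1e6))
  }
})

test_that("malformed inputs fail with the offending file named", {
  ds <- toy_dataset(n_v = 10, n_s = 4)
  prefix <- file.path(withr::local_tempdir(), "bad")
  write_eigenstrat(ds, prefix)
  # drop one .snp line: dimension mismatch
  snp <- readLines(paste0(prefix, ".snp"))
  writeLines(snp[-1], paste0(prefix, ".snp"))
  expect_error(read_eigenstrat(prefix, pseudo_haploid = FALSE), "\\.geno")
  writeLines(snp, paste0(prefix, ".snp"))
  # corrupt genotype code, with the line number reported
  geno <- readLines(paste0(prefix, ".geno"))
  substr(geno[3], 2, 2) <- "7"
  writeLines(geno, paste0(prefix, ".geno"))
  expect_error(read_eigenstrat(prefix, pseudo_haploid = FALSE), "'7'.*line 3")
  expect_error(read_eigenstrat(file.path(tempdir(), "nope")), "missing")
})

test_that("allele frequencies match direct per-site counting", {
  # two pseudo-haploid samples with calls {0, 2}: p = 0.5 from 2 allele slots
  v <- tibble::tibble(id = "rs1", chrom = "1", pos = 1L, gpos = 0.001,
                      ref = "A", alt = "C")
  s <- tibble::tibble(id = c("a", "b"), population = "P")
  ds <- genotype_dataset(v, s, matrix(c(0L, 2L), 1, 2), pseudo_haploid = TRUE)
  fr <- allele_frequencies(ds)
  expect_equal(unname(fr$freq[1, "P"]), 0.5)
  expect_equal(unname(fr$n[1, "P"]), 2)

  # all-missing variant: frequency undefined with n = 0
  ds2 <- genotype_dataset(
    dplyr::bind_rows(v, dplyr::mutate(v, id = "rs2", pos = 2L, gpos = 0.002)),
    s, matrix(c(0L, NA, 2L, NA), 2, 2), pseudo_haploid = TRUE
  )
  fr2 <- allele_frequencies(ds2)
  expect_true(is.na(fr2$freq[2, "P"]))
  expect_equal(unname(fr2$n[2, "P"]), 0)

  # random diploid dataset vs brute-force loop, incl male X haploid slots
  ds3 <- toy_dataset(n_v = 40, n_s = 10, missing_rate = 0.2, with_x = TRUE)
  fr3 <- allele_frequencies(ds3)
  for (p in fr3$pops) {
    cols <- which(ds3$samples$population == p)
    for (i in seq_len(n_variants(ds3))) {
      alt <- 0; slots <- 0
      for (j in cols) {
        g <- ds3$calls[i, j]
        if (is.na(g)) next
        hap <- ds3$variants$chrom[i] == "X" && ds3$samples$sex[j] == "M"
        slots <- slots + (if (hap) 1 else 2)
        alt <- alt + (if (hap) g / 2 else g)
      }
      expect_equal(unname(fr3$n[i, p]), slots)
      if (slots > 0) expect_equal(unname(fr3$freq[i, p]), alt / slots)
      else expect_true(is.na(fr3$freq[i, p]))
    }
  }
})

test_that("frequencies pool across merged groups at the count level", {
  ds <- toy_dataset(n_v = 30, n_s = 8, missing_rate = 0.1)
  merged <- allele_frequencies(
    ds, setNames(rep("All", n_samples(ds)), ds$samples$id))
  split <- allele_frequencies(ds)
  n_pool <- rowSums(split$n)
  alt_pool <- rowSums(split$freq * split$n, na.rm = TRUE)
  expect_equal(unname(merged$n[, "All"]), unname(n_pool))
  ok <- n_pool > 0
  expect_equal(unname(merged$freq[ok, "All"]), unname(alt_pool[ok] / n_pool[ok]))
})

test_that("restrict filters variants, samples and chromosome classes", {
  ds <- toy_dataset(n_v = 30, n_s = 8, with_x = TRUE)
  auto <- restrict(ds, chrom_class = "autosomes")
  expect_false(any(auto$variants$chrom == "X"))
  xonly <- restrict(ds, chrom_class = "X")
  expect_true(all(xonly$variants$chrom == "X"))
  expect_equal(n_variants(auto) + n_variants(xonly), n_variants(ds))

  ident <- restrict(ds, variants = ds$variants$id, samples = ds$samples$id)
  expect_equal(ident$calls, ds$calls)

  # intersection of two SNP lists behaves as the set operation
  set.seed(9)
  l1 <- sample(ds$variants$id, 20); l2 <- sample(ds$variants$id, 20)
  both <- restrict(restrict(ds, variants = l1), variants = intersect(l1, l2))
  expect_setequal(both$variants$id, intersect(l1, l2))

  expect_error(restrict(ds, variants = "nope"), "unknown variant")
  expect_error(restrict(restrict(ds, chrom_class = "autosomes"),
                        chrom_class = "X"), "no variants")
})

test_that("genetic position unit helpers invert each other", {
  expect_equal(cm_to_morgans(morgans_to_cm(0.137)), 0.137)
  expect_equal(cm_to_morgans(5), 0.05)
})
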