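test_that("read_regions maps BED fields and validates coordinates", {
  bed <- mini_regions(lines = c("chr1\t100\t200\tNPPA", "chr2\t50\t80"))
  reg <- read_regions(bed)
  expect_equal(reg$name, c("NPPA", "chr2:50-80"))
  expect_equal(reg$chrom, c("chr1", "chr2"))
  expect_equal(reg$start, c(100L, 50L))
  expect_equal(reg$end, c(200L, 80L))

  empty <- mini_regions(lines = character(0))
  expect_equal(nrow(read_regions(empty)), 0L)

  bad <- mini_regions(lines = "chr1\t200\t100\tX")
  expect_error(read_regions(bad), "start")
  short <- mini_regions(lines = "chr1\t100")
  expect_error(read_regions(short), "malformed BED line 1")
  dup <- mini_regions(lines = c("chr1\t1\t5\tA", "chr1\t6\t9\tA"))
  expect_error(read_regions(dup), "duplicate")
})

test_that("read_variants restricts to regions and extracts INFO counts", {
  vcf <- write_mini_vcf(tempfile(fileext = ".vcf"), c(
    "chr1\t150\trs1\tA\tG\t.\tPASS\tAA=G;AC_afr=10;AN_afr=100;AC_nfe=5;AN_nfe=50",
    "chr1\t50\trs2\tA\tG\t.\tPASS\tAC_afr=1;AN_afr=100;AC_nfe=1;AN_nfe=50",
    "chr1\t160\trs3\tA\tG\t.\tPASS\tAC_afr=0;AN_afr=0;AC_nfe=2;AN_nfe=50"
  ))
  reg <- read_regions(mini_regions())
  sites <- read_variants(vcf, reg, c("afr", "nfe"))
  expect_equal(sites$id, c("rs1", "rs3"))  # rs2 outside the region
  expect_equal(sites$ac_afr, c(10, 0))
  expect_equal(sites$an_afr, c(100, 0))   # AN=0 retained as (0, 0)
  expect_equal(sites$aa, c("G", NA))

  # chr prefix normalization: region "1" matches VCF "chr1"
  reg2 <- read_regions(mini_regions(lines = "1\t100\t200\tG1"))
  expect_equal(nrow(read_variants(vcf, reg2, "afr")), 2L)
})

test_that("read_variants tallies counts from genotypes via a sample map", {
  vcf <- write_mini_vcf(tempfile(fileext = ".vcf"), c(
    "chr1\t150\trs1\tA\tG\t.\tPASS\t.\tGT\t0|1\t1|1\t0|0",
    "chr1\t160\trs2\tC\tT\t.\tPASS\t.\tGT\t0|0\t.|.\t0|1"
  ), info_ids = "AA", samples = c("s1", "s2", "s3"))
  map <- data.frame(sample = c("s1", "s2", "s3"),
                    pop = c("afr", "afr", "nfe"))
  reg <- read_regions(mini_regions())
  sites <- read_variants(vcf, reg, c("afr", "nfe"), sample_map = map)
  expect_equal(sites$ac_afr, c(3, 0))
  expect_equal(sites$an_afr, c(4, 2))  # missing genotype drops 2 alleles
  expect_equal(sites$ac_nfe, c(0, 1))

  expect_error(read_variants(vcf, reg, "eas", sample_map = map),
               "no samples")
})

test_that("read_variants errors when counts are unavailable", {
  vcf <- write_mini_vcf(tempfile(fileext = ".vcf"),
    "chr1\t150\trs1\tA\tG\t.\tPASS\tAA=G", info_ids = "AA")
  reg <- read_regions(mini_regions())
  expect_error(read_variants(vcf, reg, "afr"), "AC_/AN_")
})

test_that("biallelic SNP filter classifies and conserves records", {
  sites <- data.frame(
    chrom = "1", pos = 1:5, id = paste0("v", 1:5),
    ref = c("A", "A", "AT", "A", "G"),
    alt = c("G", "AT", "A", "C,G", "T"),
    aa = NA_character_,
    ac_afr = 1, an_afr = 10, stringsAsFactors = FALSE
  )
  filt <- filter_biallelic_snps(sites)
  expect_equal(filt$snps$id, c("v1", "v5"))
  expect_equal(filt$n_removed_indels, 2L)
  expect_equal(filt$n_removed_multiallelic, 1L)

  # conservation under random composition
  set.seed(42)
  for (k in 1:20) {
    n <- sample(1:60, 1)
    kind <- sample(c("snp", "indel", "multi"), n, replace = TRUE)
    rs <- data.frame(
      chrom = "1", pos = seq_len(n), id = paste0("x", seq_len(n)),
      ref = ifelse(kind == "indel", "AT", "A"),
      alt = ifelse(kind == "multi", "C,G", "G"),
      aa = NA_character_, ac_afr = 0, an_afr = 2,
      stringsAsFactors = FALSE
    )
    f <- filter_biallelic_snps(rs)
    expect_identical(
      nrow(rs),
      nrow(f$snps) + f$n_removed_indels + f$n_removed_multiallelic)
  }
})

test_that("VCF round-trip preserves alleles, counts and AA tags", {
  dat <- tiny_sim(seed = 5, n_sites = 80, spikes = 4)
  reg <- read_regions(dat$paths$bed)
  codes <- c("afr", "amr", "asj", "eas", "fin", "nfe")
  sites <- read_variants(dat$paths$vcf, reg, codes)
  filt <- filter_biallelic_snps(sites)

  out <- tempfile(fileext = ".vcf")
  write_variants(filt$snps, out)
  again <- read_variants(out, reg, codes)
  expect_equal(again, filt$snps, ignore_attr = TRUE)

  # region extraction is idempotent
  expect_equal(read_variants(out, reg, codes), again, ignore_attr = TRUE)
})
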