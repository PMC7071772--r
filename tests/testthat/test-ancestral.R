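snp_row <- function(ref, alt, aa = NA_character_, pos = 150L,
                    ac = 10, an = 100) {
  data.frame(chrom = "chr1", pos = pos, id = paste0("v", pos),
             ref = ref, alt = alt, aa = aa,
             ac_afr = ac, an_afr = an, stringsAsFactors = FALSE)
}

primates <- function(pos, species, alleles) {
  data.frame(chrom = "chr1", pos = pos, species = species,
             allele = alleles, stringsAsFactors = FALSE)
}

test_that("annotation AA wins and primate consensus backs it up", {
  # valid annotation takes priority over any primate evidence
  call <- assign_ancestral(snp_row("A", "G", aa = "G"),
                           primates(150, c("chimp", "gorilla"), c("A", "A")))
  expect_equal(call$allele, "G")
  expect_equal(call$source, "annotation")

  # lower-case (low-confidence) AA accepted by default, refusable
  expect_equal(assign_ancestral(snp_row("A", "G", aa = "g"))$source,
               "annotation")
  expect_equal(
    assign_ancestral(snp_row("A", "G", aa = "g"),
                     accept_lowercase = FALSE)$source, "unassigned")

  # forced majority among three species
  call <- assign_ancestral(
    snp_row("A", "G"),
    primates(150, c("chimp", "gorilla", "orangutan"), c("G", "G", "T")))
  expect_equal(call$allele, "G")
  expect_equal(call$source, "primate_consensus")

  # AA naming a third allele falls through to the primates (with a note)
  expect_message(
    call <- assign_ancestral(
      snp_row("A", "G", aa = "T"),
      primates(150, c("chimp", "gorilla"), c("G", "G"))),
    "outside")
  expect_equal(call$source, "primate_consensus")
})

test_that("weak or conflicting primate evidence leaves sites unassigned", {
  # tie between two species
  expect_equal(assign_ancestral(
    snp_row("G", "T"),
    primates(150, c("chimp", "gorilla"), c("G", "T")))$source, "unassigned")
  # single supporting species is below the floor
  expect_equal(assign_ancestral(
    snp_row("A", "G"), primates(150, "chimp", "G"))$source, "unassigned")
  # majority allele not in {ref, alt}
  expect_equal(assign_ancestral(
    snp_row("A", "G"),
    primates(150, c("chimp", "gorilla"), c("T", "T")))$source, "unassigned")
  # no evidence at all
  expect_equal(assign_ancestral(snp_row("A", "G"))$source, "unassigned")
})

test_that("polarization flips counts when the derived allele is ref", {
  snp <- snp_row("A", "G", aa = "G", ac = 88, an = 100)
  pol <- polarize(snp, assign_ancestral(snp))
  expect_equal(pol$polarized$derived, "A")
  expect_equal(pol$polarized$dac_afr, 12)
  expect_equal(pol$polarized$daf_afr, 0.12)

  # identity orientation: ancestral = ref
  snp2 <- snp_row("A", "G", aa = "A", ac = 88, an = 100)
  pol2 <- polarize(snp2, assign_ancestral(snp2))
  expect_equal(pol2$polarized$derived, "G")
  expect_equal(pol2$polarized$daf_afr, 0.88)

  # AN = 0 leaves the frequency undefined
  snp3 <- snp_row("A", "G", aa = "A", ac = 0, an = 0)
  expect_true(is.na(polarize(snp3, assign_ancestral(snp3))$polarized$daf_afr))
})

test_that("orientation involution and exclusion accounting hold", {
  set.seed(9)
  n <- 50
  snps <- data.frame(
    chrom = "chr1", pos = 101:150, id = paste0("v", 1:n),
    ref = "A", alt = "G",
    aa = sample(c("A", "G", NA), n, replace = TRUE),
    ac_afr = rbinom(n, 80, 0.3), an_afr = 80,
    stringsAsFactors = FALSE
  )
  calls <- assign_ancestral(snps)
  pol <- polarize(snps, calls)
  # every SNP lands in exactly one of (polarized, excluded)
  expect_setequal(c(pol$polarized$id, pol$excluded$id), snps$id)
  expect_equal(nrow(pol$polarized) + nrow(pol$excluded), n)
  expect_true(all(pol$excluded$reason == "no_ancestral_call"))

  # flipping the ancestral call maps daf -> 1 - daf
  flipped <- calls
  idx <- flipped$source != "unassigned"
  flipped$allele[idx] <- ifelse(flipped$allele[idx] == "A", "G", "A")
  pol_f <- polarize(snps, flipped)
  expect_equal(pol_f$polarized$daf_afr, 1 - pol$polarized$daf_afr)
  # complementarity: derived frequency + ancestral frequency = 1
  expect_equal(pol$polarized$daf_afr +
                 (pol$polarized$an_afr - pol$polarized$dac_afr) /
                 pol$polarized$an_afr,
               rep(1, nrow(pol$polarized)))
})
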