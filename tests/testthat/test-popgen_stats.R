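test_that("Hudson FST hits the boundary cases exactly", {
  # fixed difference
  expect_equal(as.numeric(site_fst(100, 100, 0, 100, "hudson")), 1)
  # both monomorphic for the same allele: denominator 0, undefined
  expect_true(is.na(site_fst(0, 100, 0, 100, "hudson")))
  expect_true(is.na(site_fst(100, 100, 100, 100, "weir_cockerham")))
  expect_error(site_fst(0, 1, 5, 10), "at least 2")
})

test_that("both FST estimators match the formula oracles", {
  expect_equal(as.numeric(site_fst(4, 20, 16, 20, "hudson")),
               oracle_hudson(0.2, 0.8, 20, 20), tolerance = 1e-12)
  set.seed(17)
  for (k in 1:200) {
    an1 <- sample(4:60, 1); an2 <- sample(4:60, 1)
    d1 <- sample(0:an1, 1); d2 <- sample(0:an2, 1)
    h <- as.numeric(site_fst(d1, an1, d2, an2, "hudson"))
    w <- as.numeric(site_fst(d1, an1, d2, an2, "weir_cockerham"))
    ho <- oracle_hudson(d1 / an1, d2 / an2, an1, an2)
    wo <- oracle_wc(d1 / an1, an1 / 2, d2 / an2, an2 / 2)
    expect_equal(h, ho, tolerance = 1e-10)
    expect_equal(w, wo, tolerance = 1e-10)
  }
})

test_that("FST is allele-label invariant and the estimators agree at large n", {
  set.seed(31)
  an <- 1000
  # two populations drifted from a shared ancestral frequency, F = 0.1
  p0 <- runif(200, 0.1, 0.9)
  d1 <- rbinom(200, an, rbeta(200, p0 * 9, (1 - p0) * 9))
  d2 <- rbinom(200, an, rbeta(200, p0 * 9, (1 - p0) * 9))
  hud <- site_fst(d1, rep(an, 200), d2, rep(an, 200), "hudson")
  hud_sw <- site_fst(an - d1, rep(an, 200), an - d2, rep(an, 200), "hudson")
  expect_equal(as.numeric(hud), as.numeric(hud_sw), tolerance = 1e-12)
  wc <- site_fst(d1, rep(an, 200), d2, rep(an, 200), "weir_cockerham")
  ok <- !is.na(hud) & !is.na(wc)
  expect_true(all(abs(hud[ok] - wc[ok]) < 0.02))
})

test_that("LD r2 matches hand counts and flags monomorphic columns", {
  x <- c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0)
  y <- c(1, 1, 1, 1, 0, 1, 0, 0, 0, 0)
  # haplotype classes: AB=4, Ab=1, aB=1, ab=4 -> D = 0.15, r2 = 0.36
  expect_equal(ld_r2(x, y), 0.36)
  expect_equal(ld_r2(x, x), 1)
  expect_true(is.na(ld_r2(x, rep(1, 10))))
  expect_error(ld_r2(x, y[1:5]), "equal length")
  expect_error(ld_r2(c(0, NA), c(0, 1)), "0/1")

  set.seed(12)
  for (k in 1:200) {
    n <- 2 * sample(2:30, 1)
    a <- rbinom(n, 1, runif(1, 0.1, 0.9))
    b <- rbinom(n, 1, runif(1, 0.1, 0.9))
    expect_equal(ld_r2(a, b), oracle_r2(a, b), tolerance = 1e-10)
    expect_equal(ld_r2(a, b), ld_r2(b, a))
    # invariance under 0 <-> 1 flip of either column
    if (!is.na(ld_r2(a, b))) {
      expect_equal(ld_r2(1 - a, b), ld_r2(a, b), tolerance = 1e-12)
    }
  }
})

test_that("window selection trims flanks at the outermost high-LD site", {
  set.seed(44)
  n_hap <- 120
  focal <- rbinom(n_hap, 1, 0.5)
  near <- function(p_copy) {
    ifelse(runif(n_hap) < p_copy, focal, rbinom(n_hap, 1, 0.5))
  }
  # r2 profile around the focal column: low, high, FOCAL, high, low
  mat <- cbind(rbinom(n_hap, 1, 0.4), near(0.9), focal, near(0.9),
               rbinom(n_hap, 1, 0.4))
  haps <- haplotype_matrix(mat, paste0("s", 1:5), seq(100, 500, 100),
                           rep("YRI", n_hap))
  win <- select_window(haps, "s3", r2_max = 0.2)
  expect_equal(c(win$start, win$end), c(2, 4))
  expect_equal(win$n_sites, 3)

  # no flanking site in LD: the window is the focal site alone
  lone <- cbind(rbinom(n_hap, 1, 0.4), focal, rbinom(n_hap, 1, 0.4))
  haps2 <- haplotype_matrix(lone, paste0("s", 1:3), c(100, 200, 300),
                            rep("YRI", n_hap))
  win2 <- select_window(haps2, 2)
  expect_equal(c(win2$start, win2$end), c(2, 2))

  # focal at the matrix edge gives a one-sided window
  edge <- cbind(focal, near(0.95), rbinom(n_hap, 1, 0.4))
  haps3 <- haplotype_matrix(edge, paste0("s", 1:3), c(100, 200, 300),
                            rep("YRI", n_hap))
  win3 <- select_window(haps3, 1)
  expect_equal(win3$start, 1)
  expect_gte(win3$end, 2)

  mono <- cbind(rep(1, n_hap), focal)
  haps4 <- haplotype_matrix(mono, c("a", "b"), c(1, 2), rep("YRI", n_hap))
  expect_error(select_window(haps4, "a"), "monomorphic")
})

test_that("block-structured haplotypes give a block-bounded window", {
  haps <- simulate_haplotypes(n_hap_per_pop = 80, n_sites = 18,
                              block = 7:12, seed = 5)
  win <- select_window(haps, 9, r2_max = 0.2)
  expect_gte(win$start, 7)
  expect_lte(win$end, 12)
  expect_gte(win$n_sites, 3)  # most of the block stays linked
})

test_that("ld_table restricts by sites and populations", {
  haps <- simulate_haplotypes(n_hap_per_pop = 40, n_sites = 6,
                              block = 2:5, seed = 9)
  tab <- ld_table(haps, sites = 2:5, pops = c("YRI"))
  expect_equal(nrow(tab), choose(4, 2))
  expect_true(all(tab$pop_set == "YRI"))
  expect_true(all(is.na(tab$r2) | (tab$r2 >= 0 & tab$r2 <= 1)))
})
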