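test_that("pairwise divergence is the expected allele mismatch", {
  # one site, x fixed derived, y ancestral -> mismatch certain
  tab <- make_sites(c(2, 0, 0, 0))
  expect_equal(pairwise_divergence(tab, "F", "S"), 1)
  # one site, both heterozygous: brute force over the four ordered draws
  # (derived/derived, derived/anc, anc/derived, anc/anc) -> 0.5 mismatch
  tab2 <- make_sites(c(1, 1, 0, 0))
  draws <- expand.grid(x = c(1, 0), y = c(1, 0))
  expect_equal(mean(draws$x != draws$y), 0.5)
  expect_equal(pairwise_divergence(tab2, "F", "S"), 0.5)
  # symmetry in the taxon arguments
  tab3 <- make_sites(sample(0:2, 40, replace = TRUE))
  for (pr in list(c("F", "S"), c("F", "M"), c("S", "A")))
    expect_equal(pairwise_divergence(tab3, pr[1], pr[2]),
                 pairwise_divergence(tab3, pr[2], pr[1]))
  expect_error(pairwise_divergence(make_sites(numeric()), "F", "S"), "empty")
})

test_that("heterozygosity counts heterozygous genotypes and ignores polarization", {
  tab <- make_sites(c(1, 0, 0, 0,
                      1, 2, 0, 0,
                      0, 1, 2, 2))
  expect_equal(pairwise_divergence(tab, "F", "F"), 2)
  expect_equal(pairwise_divergence(tab, "S", "S"), 1)
  expect_equal(pairwise_divergence(tab, "A", "A"), 0)
  # flipping derived/ancestral labels leaves heterozygosity unchanged
  flipped <- make_sites(2 - c(1, 0, 0, 0, 1, 2, 0, 0, 0, 1, 2, 2))
  expect_equal(pairwise_divergence(flipped, "F", "F"), 2)
})

test_that("divergence matrix normalizes by savanna-Asian divergence", {
  set.seed(5)
  tab <- make_sites(sample(0:2, 4 * 60, replace = TRUE, prob = c(.5, .2, .3)),
                    loci = paste0("L", sort(rep(1:6, 10))))
  dm <- divergence_matrix(tab, taxa = ELEPHANTID_TAXA)
  expect_equal(dm$normalized["S", "A"], 1)
  expect_equal(dm$se["S", "A"], 0)            # the normalizer has no uncertainty
  expect_true(isSymmetric(dm$normalized))
  expect_true(all(dm$raw >= 0))
  expect_equal(dm$raw["F", "S"] / dm$t_sa, dm$normalized["F", "S"])
  # identical sequences within each taxon -> zero heterozygosity
  fixed <- make_sites(rep(c(2, 0, 2, 0), 10))
  dm0 <- divergence_matrix(fixed, taxa = ELEPHANTID_TAXA, jackknife = FALSE)
  expect_equal(unname(diag(dm0$raw)), rep(0, 4))
})

test_that("relative rate test: symmetric counts give zero, toy counts give 0.5", {
  # perfectly symmetric configuration between F and S
  sym <- make_sites(c(2, 0, 0, 0,
                      0, 2, 0, 0), loci = c("L1", "L2"))
  rt <- relative_rate_test(sym, "F", "S")
  expect_equal(rt$estimate, 0)
  expect_equal(rt$p, 1)
  # 10-site toy with n_F = 3, n_S = 1 -> statistic (3-1)/(3+1) = 0.5,
  # SE checked against the independent delete-one enumeration
  g <- c(2, 0, 0, 0,  2, 0, 0, 0,  2, 0, 0, 0,  0, 2, 0, 0,
         0, 0, 2, 2,  0, 0, 2, 2,  2, 2, 2, 2,  2, 2, 2, 2,
         0, 0, 1, 0,  0, 0, 0, 1)
  tab <- make_sites(g, loci = paste0("L", rep(1:5, each = 2)))
  rt2 <- relative_rate_test(tab, "F", "S")
  expect_equal(rt2$n_x, 3)
  expect_equal(rt2$n_y, 1)
  expect_equal(rt2$estimate, 0.5)
  stat <- function(tt) {
    fx <- tt$F / 2; fy <- tt$S / 2
    a <- sum(fx * (1 - fy)); b <- sum(fy * (1 - fx))
    if (a + b == 0) 0 else (a - b) / (a + b)
  }
  oracle <- brute_jackknife(stat, tab)
  expect_equal(rt2$se, oracle$se, tolerance = 1e-12)
  # degenerate case: no lineage-specific sites at all
  none <- make_sites(c(2, 2, 2, 2, 1, 1, 2, 2))
  expect_true(relative_rate_test(none, "A", "M")$undefined)
})

test_that("absolute calibration multiplies ratio and fossil window", {
  expect_equal(calibrate_absolute(0.45)[1], 1.89)          # 0.45 x 4.2 Mya
  expect_equal(calibrate_absolute(1), c(4.2, 9.0))
  expect_equal(calibrate_absolute(c(0.45, 0.79)), c(1.89, 7.11))
  expect_error(calibrate_absolute(-1))
  # theta -> N conversion: theta = 4 N mu g
  expect_equal(theta_to_N(0.00238, mu = 3.3e-10, generation_years = 31),
               0.00238 / (4 * 3.3e-10 * 31))
})

test_that("divergence report has the published table shape", {
  set.seed(9)
  tab <- make_sites(sample(0:2, 4 * 80, replace = TRUE, prob = c(.6, .2, .2)),
                    loci = paste0("L", sort(rep(1:8, 10))))
  rep1 <- divergence_report(tab)
  expect_equal(nrow(rep1), 10)  # 6 cross pairs + 4 heterozygosities
  expect_equal(rep1$estimate[rep1$first == "S" & rep1$second == "A"], 1)
  expect_true(all(rep1$se >= 0))
  expect_true(all(is.na(rep1$p_rate[rep1$first == rep1$second])))
})
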