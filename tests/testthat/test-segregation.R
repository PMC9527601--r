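# Pollen inference, segregation tests, recombination estimation, map regression.

test_that("pollen allele inference removes one maternal allele", {
  expect_identical(infer_pollen_allele(c("S_21", "S_C1"), c("S_21", "S_C2")),
                   list(status = "OK", allele = "S_C1"))
  expect_identical(infer_pollen_allele(c("S_8", "S_6"), c("S_8", "S_7")),
                   list(status = "OK", allele = "S_6"))
  amb <- infer_pollen_allele(c("S_1", "S_2"), c("S_1", "S_2"))
  expect_identical(amb$status, "AMBIGUOUS")
  inc <- infer_pollen_allele(c("S_5", "S_6"), c("S_1", "S_2"))
  expect_identical(inc$status, "INCONSISTENT")
  # genotype-string input and a homozygous-looking seed
  expect_identical(infer_pollen_allele("S_1/S_1", c("S_1", "S_2"))$allele, "S_1")
})

test_that("inference is the left inverse of offspring construction", {
  set.seed(21)
  mo <- plant_genotype("mo", haplotype("Sa"), haplotype("Sb"))
  for (rep in 1:200) {
    ovule <- sample(c("Sa", "Sb"), 1)
    pollen <- sample(c("Sb", "Sc", "Sd"), 1)
    seed <- c(ovule, pollen)
    inf <- infer_pollen_allele(seed, mo)
    if (inf$status == "OK") {
      expect_identical(inf$allele, pollen)
    } else {
      # ambiguity can only arise when the pollen allele is itself maternal
      expect_identical(inf$status, "AMBIGUOUS")
      expect_true(pollen %in% c("Sa", "Sb"))
    }
  }
})

test_that("pollen ratio test tallies shared vs non-shared pollen", {
  mo <- plant_genotype("M", haplotype("S_x"), haplotype("S_C1"))
  sc <- seed_genotype_counts("row1", mo,
                             c("S_x/S_y" = 67, "S_C1/S_y" = 44,
                               "S_x/S_C1" = 0, "S_C1/S_C1" = 0))
  t <- pollen_ratio_test(sc, "S_C1")
  expect_identical(t$n_shared, 0)
  expect_identical(t$total, 111)
  expect_lt(t$p_value, 1e-20)

  mo2 <- plant_genotype("M2", haplotype("C"), haplotype("Q"))
  sc2 <- seed_genotype_counts("t", mo2, c("A/C" = 10, "B/C" = 10))
  t2 <- pollen_ratio_test(sc2, "C")
  expect_identical(t2$n_shared, 0)
  expect_identical(t2$total, 20)
})

test_that("a fully-compatible cross shows equal transmission (null holds)", {
  mo <- plant_genotype("mo", haplotype("S1"), haplotype("S2"))
  fa <- plant_genotype("fa", haplotype("S3"), haplotype("S4"))
  sc <- simulate_seed_set(mo, fa, n = 1000, seed = 5)
  t <- pollen_ratio_test(sc, "S3")
  expect_identical(t$total, 1000)
  expect_lt(abs(t$n_shared - 500), 2 * sqrt(1000 * 0.25) + 1)
  expect_gt(t$p_value, 0.05)
})

test_that("ambiguous seeds are excluded and reported", {
  mo <- plant_genotype("mo", haplotype("S1"), haplotype("S2"))
  sc <- seed_genotype_counts("amb", mo,
                             c("S1/S2" = 5, "S1/S3" = 7, "S4/S5" = 2))
  t <- pollen_ratio_test(sc, "S3")
  expect_identical(t$n_ambiguous, 5)
  expect_identical(t$n_inconsistent, 2)
  expect_identical(t$total, 7)
})

test_that("recombination estimation reproduces printed-table arithmetic", {
  par <- mapping_parents()
  est <- estimate_recombination(
    f1_with_counts(par$RW, "S", "KSN", 19, 97), "S", "KSN", "RW")
  expect_identical(est$recombinants, 19L)
  expect_identical(est$total, 97L)
  expect_equal(est$r_hat, 19 / 97)
  expect_equal(est$percent, 20)

  est0 <- estimate_recombination(
    f1_with_counts(par$RW, "S", "KSN", 0, 97), "S", "KSN", "RW")
  expect_equal(est0$r_hat, 0)
  cs <- cosegregation_test(f1_with_counts(par$RW, "S", "KSN", 0, 97),
                           "S", "KSN", "RW")
  expect_identical(cs, list(n = 97L, n_discordant = 0L,
                            perfectly_cosegregating = TRUE))
  cs1 <- cosegregation_test(f1_with_counts(par$RW, "S", "KSN", 1, 97),
                            "S", "KSN", "RW")
  expect_false(cs1$perfectly_cosegregating)
  expect_identical(cs1$n_discordant, 1L)
})

test_that("r_hat recovers the simulated recombination fraction", {
  par <- mapping_parents()
  tab <- simulate_f1(par$TF, par$RW, n = 10000, seed = 17,
                     rmap = recomb_map(KSN = 0.2, AP2 = 0.13))
  est <- estimate_recombination(tab, "S", "KSN", "RW")
  expect_lt(abs(est$r_hat - 0.2), 0.02)
  # unlinked loci segregate independently: r_hat near 0.5
  tab2 <- simulate_f1(par$TF, par$RW, n = 2000, seed = 18)
  est2 <- estimate_recombination(tab2, "S", "KSN", "RW")
  expect_lt(abs(est2$r_hat - 0.5), 0.05)
})

test_that("missing calls are excluded and empty data errors", {
  par <- mapping_parents()
  tab <- f1_with_counts(par$RW, "S", "KSN", 10, 97)
  tab$gametes$KSN[1:7] <- NA
  est <- estimate_recombination(tab, "S", "KSN", "RW")
  expect_identical(est$total, 90L)
  tab$gametes$KSN <- NA_character_
  expect_error(estimate_recombination(tab, "S", "KSN", "RW"), "insufficient")
  expect_error(estimate_recombination(tab, "S", "BAD", "RW"), "not present")
})

test_that("map-position regression interpolates and matches the OLS oracle", {
  two <- data.frame(name = c("a", "b"), cm = c(10, 20), bp = c(1e6, 2e6))
  expect_equal(estimate_physical_position(two, 15)$bp, 1.5e6)

  colinear <- data.frame(name = letters[1:6], cm = seq(10, 60, 10),
                         bp = seq(10, 60, 10) * 1e5)
  est <- estimate_physical_position(colinear, 41.5)
  expect_equal(est$bp, 4.15e6)
  expect_equal(est$slope, 1e5)

  # noisy markers: equals the closed-form OLS oracle on the same flank set
  set.seed(33)
  noisy <- data.frame(name = paste0("m", 1:7), cm = c(5, 12, 20, 31, 38, 47, 55))
  noisy$bp <- 1e5 * noisy$cm + rnorm(7, 0, 2e4)
  est2 <- estimate_physical_position(noisy, 30, k_flank = 3)
  flank <- noisy[noisy$name %in% est2$markers_used$name, ]
  # oracle: closed-form simple-regression coefficients
  bx <- cov(flank$cm, flank$bp) / var(flank$cm)
  ax <- mean(flank$bp) - bx * mean(flank$cm)
  expect_equal(est2$bp, ax + bx * 30, tolerance = 1e-9)
  expect_equal(est2$slope, bx, tolerance = 1e-9)

  # permutation invariance
  perm <- noisy[sample(nrow(noisy)), ]
  expect_equal(estimate_physical_position(perm, 30, k_flank = 3)$bp, est2$bp)

  expect_error(estimate_physical_position(two[1, , drop = FALSE], 15),
               "insufficient")
  nonmono <- data.frame(name = letters[1:4], cm = 1:4, bp = c(1e5, 3e5, 2e5, 4e5))
  expect_warning(estimate_physical_position(nonmono, 2.5), "monotone")
})
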