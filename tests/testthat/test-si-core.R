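# GSI transmission model: gametes, acceptance, cross prediction.

test_that("diploid gamete distribution follows the (1-r)/2, r/2 rule", {
  p <- plant_genotype("P", haplotype("S1", KSN = "ksn_null"),
                           haplotype("S3", KSN = "KSN_W"))
  g <- gamete_distribution(p, recomb_map(KSN = 0.2))
  probs <- sapply(g, `[[`, "prob")
  names(probs) <- sapply(g, function(x) {
    h <- x$haplotypes[[1]]
    paste0(h$s, ":", h$traits[["KSN"]])
  })
  expect_equal(sum(probs), 1, tolerance = 1e-12)
  expect_equal(unname(probs[c("S1:ksn_null", "S3:KSN_W",
                              "S1:KSN_W", "S3:ksn_null")]),
               c(0.4, 0.4, 0.1, 0.1), tolerance = 1e-12)

  # complete linkage: parental haplotypes only, 0.5 each
  g0 <- gamete_distribution(p, recomb_map(KSN = 0))
  expect_length(g0, 2)
  expect_equal(sort(sapply(g0, `[[`, "prob")), c(0.5, 0.5))
  parental <- c("S1.ksn_null", "S3.KSN_W")
  expect_setequal(sapply(g0, function(x) {
    paste(x$haplotypes[[1]]$s, x$haplotypes[[1]]$traits[["KSN"]], sep = ".")
  }), parental)
})

test_that("r = 0.5 makes S and the trait locus independent in the gametes", {
  p <- plant_genotype("P", haplotype("S1", KSN = "ksn_null"),
                           haplotype("S3", KSN = "KSN_W"))
  g <- gamete_distribution(p, recomb_map(KSN = 0.5))
  joint <- sapply(g, `[[`, "prob")
  s_lab <- sapply(g, function(x) x$haplotypes[[1]]$s)
  k_lab <- sapply(g, function(x) x$haplotypes[[1]]$traits[["KSN"]])
  for (i in seq_along(g)) {
    ps <- sum(joint[s_lab == s_lab[i]])
    pk <- sum(joint[k_lab == k_lab[i]])
    expect_equal(joint[i], ps * pk, tolerance = 1e-12)
  }
})

test_that("tetraploid meiosis yields all 6 unordered pairs at 1/6", {
  tp <- plant_genotype("T", haplotype("S1"), haplotype("S2"),
                            haplotype("S3"), haplotype("S4"))
  g <- gamete_distribution(tp)
  # oracle: direct enumeration of the chromosome pairings
  expected <- apply(combn(paste0("S", 1:4), 2), 2, paste, collapse = " / ")
  got <- sapply(g, function(x) {
    paste(sort(sapply(x$haplotypes, `[[`, "s")), collapse = " / ")
  })
  expect_setequal(got, expected)
  expect_equal(sapply(g, `[[`, "prob"), rep(1 / 6, 6), tolerance = 1e-12)
})

test_that("gamete probabilities sum to one across random genotypes", {
  set.seed(42)
  for (i in 1:20) {
    nloci <- sample(0:3, 1)
    loci <- if (nloci) paste0("L", seq_len(nloci)) else character(0)
    p <- random_diploid(paste0("p", i), loci)
    rmap <- if (nloci) {
      do.call(recomb_map, as.list(stats::setNames(runif(nloci, 0, 0.5), loci)))
    } else NULL
    g <- gamete_distribution(p, rmap)
    expect_equal(sum(sapply(g, `[[`, "prob")), 1, tolerance = 1e-12)
  }
})

test_that("unsupported ploidy and bad recombination fractions error", {
  tri <- plant_genotype("T3", haplotype("S1"), haplotype("S2"), haplotype("S3"))
  expect_error(gamete_distribution(tri), "triploid")
  expect_error(recomb_map(KSN = 0.7), "\\[0, 0.5\\]")
  expect_error(recomb_map(KSN = -0.1), "\\[0, 0.5\\]")
})

test_that("pollen acceptance implements non-self recognition", {
  pistil <- plant_genotype("M", haplotype("S_x"), haplotype("S_C1"))
  expect_false(pollen_accepted(list(haplotype("S_C1")), pistil))  # self: rejected
  expect_true(pollen_accepted(list(haplotype("S_y")), pistil))    # anonymous: never matches
  expect_true(pollen_accepted(list(haplotype("S_x")), pistil))    # anonymous pistil allele

  # heteroallelic diploid pollen is unconditionally accepted
  tetra_pistil <- plant_genotype("T", haplotype("S1"), haplotype("S2"))
  expect_true(pollen_accepted(list(haplotype("S1"), haplotype("S2")), tetra_pistil))
  # homoallelic diploid pollen follows the haploid rule
  expect_false(pollen_accepted(list(haplotype("S1"), haplotype("S1")), tetra_pistil))
})

test_that("cross classifies compatibility and predicts offspring", {
  pr <- half_compatible_pair()
  hc <- cross(pr$mother, pr$father)
  expect_identical(hc$compatibility, "HALF_COMPATIBLE")
  expect_equal(hc$accepted_fraction, 0.5, tolerance = 1e-12)
  sg <- s_genotype_distribution(hc)
  expect_setequal(names(sg), c("S_C1/S_y", "S_x/S_y"))
  expect_equal(unname(sg[c("S_x/S_y", "S_C1/S_y")]), c(0.5, 0.5),
               tolerance = 1e-12)
  # the shared allele never arrives through pollen
  pollen_s <- unlist(lapply(hc$pollen, function(cl) {
    sapply(cl$haplotypes, `[[`, "s")
  }))
  expect_false("S_C1" %in% pollen_s)

  selfing <- cross(plant_genotype("A", haplotype("S1"), haplotype("S2")),
                   plant_genotype("B", haplotype("S1"), haplotype("S2")))
  expect_identical(selfing$compatibility, "INCOMPATIBLE")
  expect_length(selfing$offspring, 0)

  full <- cross(plant_genotype("A", haplotype("S1"), haplotype("S2")),
                plant_genotype("B", haplotype("S3"), haplotype("S4")))
  expect_identical(full$compatibility, "FULLY_COMPATIBLE")
  expect_equal(full$accepted_fraction, 1)
  expect_equal(unname(s_genotype_distribution(full)), rep(0.25, 4),
               tolerance = 1e-12)
})

test_that("chromosome doubling breaks down SI (heteroallelic pollen)", {
  diploid <- plant_genotype("D", haplotype("S1"), haplotype("S2"))
  doubled <- plant_genotype("D4", haplotype("S1"), haplotype("S1"),
                                   haplotype("S2"), haplotype("S2"))
  expect_identical(cross(diploid, diploid)$compatibility, "INCOMPATIBLE")
  cr <- cross(diploid, doubled)
  expect_true(cr$accepted_fraction > 0)  # S1/S2 pollen passes
})

test_that("cross offspring match the brute-force enumeration oracle", {
  set.seed(7)
  for (i in 1:25) {
    nloci <- sample(0:3, 1)
    loci <- if (nloci) paste0("L", seq_len(nloci)) else character(0)
    mo <- random_diploid("mo", loci, allele_pool = paste0("S", 1:4))
    fa <- random_diploid("fa", loci, allele_pool = paste0("S", 1:4))
    rmap <- if (nloci) {
      do.call(recomb_map, as.list(stats::setNames(
        round(runif(nloci, 0, 0.5), 2), loci)))
    } else NULL
    orc <- oracle_cross_s_distribution(mo, fa, rmap)
    cr <- cross(mo, fa, rmap)
    expect_equal(cr$accepted_fraction, orc$accepted_fraction, tolerance = 1e-12)
    if (orc$accepted_fraction > 0) {
      got <- cross_genotype_distribution(cr)
      expect_setequal(names(got), names(orc$dist))
      expect_equal(got[names(orc$dist)], orc$dist, tolerance = 1e-12)
    } else {
      expect_length(cr$offspring, 0)
    }
  }
})

test_that("expected CF fraction reproduces the linked-locus predictions", {
  # ksn-homozygous seed parent: CF fraction equals r among accepted pollen
  cc <- cf_breeding_cross(r = 0.2)
  cr <- cross(cc$mother, cc$father, cc$rmap)
  expect_equal(expected_trait_fraction(cr, "KSN"), 0.2, tolerance = 1e-12)

  # both parents heterozygous: half the ovules carry KSN_W, so half of r
  het_mother <- plant_genotype("Hm", haplotype("S1", KSN = "ksn_null"),
                                      haplotype("S2", KSN = "KSN_W"))
  cr2 <- cross(het_mother, cc$father, cc$rmap)
  expect_equal(expected_trait_fraction(cr2, "KSN"), 0.1, tolerance = 1e-12)

  # always-true predicate integrates to 1
  expect_equal(expected_trait_fraction(cr, "KSN",
                                       predicate = function(a, l) TRUE), 1,
               tolerance = 1e-12)
  expect_error(expected_trait_fraction(cr, "AP2"), "absent")
})

test_that("expected CF fraction is strictly increasing in r", {
  rs <- c(0.01, 0.05, 0.1, 0.2, 0.3, 0.4, 0.5)
  fr <- sapply(rs, function(r) {
    cc <- cf_breeding_cross(r)
    expected_trait_fraction(cross(cc$mother, cc$father, cc$rmap), "KSN")
  })
  expect_true(all(diff(fr) > 0))
  expect_equal(fr, rs, tolerance = 1e-12)  # in this design CF fraction = r
})

test_that("anonymizing a non-shared allele never changes the compatibility class", {
  set.seed(11)
  for (i in 1:20) {
    mo <- random_diploid("mo", character(0), allele_pool = paste0("S", 1:5))
    fa <- random_diploid("fa", character(0), allele_pool = paste0("S", 1:5))
    base <- cross(mo, fa)$compatibility
    # replace a pollen-parent allele not present in the mother by an anonymous one
    non_shared <- which(!s_alleles(fa) %in% s_alleles(mo))
    if (!length(non_shared)) next
    haps <- fa$haplotypes
    haps[[non_shared[1]]] <- haplotype("S?anon")
    fa2 <- plant_genotype("fa2", haps)
    expect_identical(cross(mo, fa2)$compatibility, base)
  }
})
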