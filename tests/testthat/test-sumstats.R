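test_that("summary statistics match hand enumeration on toy alignments", {
  aln <- toy_aln(c("AAA", "AAT", "ATT"))
  s <- summary_stats(aln)
  expect_equal(s$S, 2L)
  expect_equal(s$pi, 4 / 3)
  expect_equal(s$k_hap, 3L)

  mono <- toy_aln(rep("ACGT", 4))
  sm <- summary_stats(mono)
  expect_equal(sm$S, 0L)
  expect_equal(sm$pi, 0)
  expect_equal(sm$k_hap, 1L)
  expect_true(is.na(sm$fs))
  expect_true(is.na(sm$tajima_d))
  expect_error(tajimas_d(mono), class = "comdemog_undefined_statistic")
  expect_error(fu_fs(mono), class = "comdemog_undefined_statistic")
})

test_that("duplicating a sequence leaves S unchanged and stats are order-invariant", {
  seqs <- c("ACGTT", "ACGTA", "AGGTA", "ACCTA")
  a <- toy_aln(seqs)
  b <- toy_aln(c(seqs, seqs[2]))
  expect_equal(summary_stats(a)$S, summary_stats(b)$S)

  perm <- toy_aln(seqs[c(3, 1, 4, 2)])
  expect_equal(summary_stats(perm)$S, summary_stats(a)$S)
  expect_equal(summary_stats(perm)$pi, summary_stats(a)$pi)
})

test_that("gap and N sites are skipped pairwise, and haplotypes counted on full strings", {
  a <- toy_aln(c("A-GT", "ANGT", "ACGA"))
  d <- pairwise_diff_matrix(a)
  expect_equal(d[1, 2], 0)  # only sites 1,3,4 shared; identical there
  expect_equal(d[1, 3], 1)  # site 4 differs
  # sequences differing only by N are distinct haplotypes
  expect_equal(summary_stats(a)$k_hap, 3L)
})

test_that("Fu's Fs agrees with the exact Ewens enumeration oracle", {
  # spec-style toy: n = 4, theta = 1.5, k = 3; Stirling row {6, 11, 6, 1}
  expect_equal(stirling_first_exact(4), c(6, 11, 6, 1))
  expect_equal(quiet_fs(n = 4, k_hap = 3, theta = 1.5),
               fs_oracle(4, 3, 1.5), tolerance = 1e-12)

  set.seed(17)
  for (case in 1:100) {
    n <- sample(3:12, 1)
    k <- sample(2:n, 1)
    theta <- runif(1, 0.05, 20)
    expect_equal(quiet_fs(n = n, k_hap = k, theta = theta),
                 fs_oracle(n, k, theta), tolerance = 1e-6)
  }
})

test_that("Fs boundary and large-n paths behave", {
  expect_warning(f <- fu_fs(n = 4, k_hap = 1, theta = 2), "saturated")
  expect_identical(f, Inf)
  # star-like data: all-singleton haplotypes give strongly negative Fs
  star <- quiet_fs(n = 20, k_hap = 20, theta = 1)
  expect_lt(star, 0)
  # n = 80 stays finite and exact-looking (no overflow in the recurrence)
  f80 <- quiet_fs(n = 80, k_hap = 40, theta = 5)
  expect_true(is.finite(f80))
  # tail sums to 1 across k
  expect_equal(sum(ewens_k_distribution(30, 3.7)), 1, tolerance = 1e-12)
})

test_that("Tajima's D matches the textbook coefficient formulas", {
  # n = 4, S = 2, pi = 4/3
  aln <- toy_aln(c("AAA", "AAT", "ATA", "ATT"))
  s <- summary_stats(aln)
  expect_equal(s$S, 2L)
  expect_equal(s$pi, 4 / 3)

  n <- 4; S <- 2; pi <- 4 / 3
  a1 <- sum(1 / (1:(n - 1))); a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  d_exp <- (pi - S / a1) / sqrt((c1 / a1) * S + (c2 / (a1^2 + a2)) * S * (S - 1))
  expect_equal(tajimas_d(aln), d_exp, tolerance = 1e-12)
})

test_that("Tajima's D sign tracks the site frequency spectrum", {
  # singleton excess (each variant private) => negative D
  singletons <- toy_aln(c("AAAAAAAA", "TAAAAAAA", "ATAAAAAA", "AATAAAAA",
                          "AAATAAAA", "AAAATAAA"))
  # intermediate-frequency excess at the same S => positive D
  balanced <- toy_aln(c("AAAAAAAA", "AAAAAAAA", "AAAAAAAA",
                        "TTTTTAAA", "TTTTTAAA", "TTTTTAAA"))
  expect_lt(tajimas_d(singletons), 0)
  expect_gt(tajimas_d(balanced), 0)
})

test_that("constant-size simulations center Fs and D near zero", {
  sc <- demographic_scenario(5e5)
  mod <- substitution_model("HKY", kappa = 2)
  set.seed(23)
  vals <- t(replicate(200, {
    tr <- simulate_genealogy(25, sc)
    aln <- evolve_sequences(tr, mod, 1e-8, 1000)
    c(fs = suppressWarnings(fu_fs(aln)), d = tajimas_d(aln))
  }))
  expect_lt(abs(median(vals[, "fs"])), 1)
  expect_lt(abs(median(vals[, "d"])), 0.3)
})
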