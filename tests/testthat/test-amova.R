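make_structured_aln <- function(n_per_pop, regions_of_pop, n_sites = 30,
                                seed = 1) {
  set.seed(seed)
  pops <- rep(names(n_per_pop), n_per_pop)
  n <- length(pops)
  m <- matrix(sample(c("A", "C", "G", "T"), n * n_sites, TRUE), nrow = n)
  rownames(m) <- paste0("s", seq_len(n))
  meta <- tibble::tibble(sample_id = rownames(m), population = pops,
                         region = regions_of_pop[pops],
                         latitude = 0, longitude = 0)
  hap_alignment(m, meta = meta)
}

test_that("degrees of freedom decompose as regions / populations / samples", {
  # 3 regions, 5 populations, 21 haplotypes -> df (2, 2, 16)
  aln <- make_structured_aln(
    c(p1 = 5L, p2 = 4L, p3 = 4L, p4 = 4L, p5 = 4L),
    c(p1 = "N", p2 = "N", p3 = "C", p4 = "S", p5 = "S"))
  res <- amova(aln, n_perms = 0L)
  expect_equal(res$table$df, c(2L, 2L, 16L))

  # arbitrary unbalanced designs keep the identity and the 100% sum
  set.seed(3)
  for (i in 1:10) {
    n_pops <- sample(3:7, 1)
    sizes <- setNames(sample(2:6, n_pops, TRUE),
                      paste0("p", seq_len(n_pops)))
    n_regs <- sample(2:min(3, n_pops - 1L), 1)
    regs <- setNames(paste0("r", sample(seq_len(n_regs), n_pops, TRUE)),
                     names(sizes))
    regs[1:n_regs] <- paste0("r", seq_len(n_regs))  # every region non-empty
    aln_i <- make_structured_aln(sizes, regs, seed = 100 + i)
    r <- amova(aln_i, n_perms = 0L)
    expect_equal(sum(r$table$df), sum(sizes) - 1L)
    expect_equal(r$table$df[1], length(unique(regs)) - 1L)
    expect_equal(sum(r$table$percent), 100, tolerance = 1e-6)
  }
})

test_that("reciprocally fixed populations give Phi_ST = 1 with nothing within", {
  aln <- toy_aln(c(rep("AAAA", 4), rep("TTTT", 4)),
                 pops = rep(c("p1", "p2"), each = 4),
                 regions = rep("r1", 8))
  res <- amova(aln, n_perms = 0L)
  expect_equal(res$phi$value[res$phi$statistic == "Phi_ST"], 1)
  expect_equal(res$table$percent[3], 0)

  pf <- pairwise_fst(aln)
  expect_equal(pf["p1", "p2"], 1)
})

test_that("identical haplotypes leave the decomposition empty and flagged", {
  aln <- toy_aln(rep("ACGT", 6), pops = rep(c("p1", "p2"), each = 3),
                 regions = "r1")
  expect_warning(res <- amova(aln, n_perms = 0L), "identical")
  expect_equal(res$table$variance, rep(0, 3))
  expect_true(is.na(res$phi$value[3]))
})

test_that("pairwise Phi_ST matches the independent variance-component oracle", {
  set.seed(7)
  for (i in 1:8) {
    sizes <- c(p1 = sample(3:6, 1), p2 = sample(3:6, 1))
    aln <- make_structured_aln(sizes, c(p1 = "r", p2 = "r"),
                               n_sites = 20, seed = 200 + i)
    d2 <- pairwise_diff_matrix(aln)
    got <- pairwise_fst(aln)["p1", "p2"]
    want <- fst_two_pop_oracle(d2, aln$meta$population)
    expect_equal(got, want, tolerance = 1e-9)
    # two-population AMOVA Phi_ST is the same quantity
    am <- amova(aln, n_perms = 0L)
    expect_equal(am$phi$value[3], want, tolerance = 1e-9)
  }
})

test_that("duplicated populations show no positive differentiation", {
  # two populations holding the same four haplotypes: among-population SSD
  # is exactly zero, so the variance-component estimate is the (retained)
  # negative floor -1/(n_c - 1) = -1/3 for balanced sizes of 4
  set.seed(11)
  base <- matrix(sample(c("A", "C", "G", "T"), 4 * 30, TRUE), nrow = 4)
  m <- rbind(base, base)
  rownames(m) <- paste0("s", 1:8)
  aln <- hap_alignment(m, meta = tibble::tibble(
    sample_id = rownames(m), population = rep(c("p1", "p2"), each = 4),
    region = "r1", latitude = 0, longitude = 0))
  fst <- pairwise_fst(aln)["p1", "p2"]
  expect_lte(fst, 0)
  expect_equal(fst, -1 / 3, tolerance = 1e-9)
})

test_that("permutation p-values are reproducible and sensible", {
  aln <- make_structured_aln(
    c(p1 = 4L, p2 = 4L, p3 = 4L, p4 = 4L),
    c(p1 = "N", p2 = "N", p3 = "S", p4 = "S"), seed = 31)
  r1 <- amova(aln, n_perms = 100L, seed = 5)
  r2 <- amova(aln, n_perms = 100L, seed = 5)
  expect_identical(r1$phi$p_value, r2$phi$p_value)
  expect_true(all(r1$phi$p_value > 0 & r1$phi$p_value <= 1, na.rm = TRUE))

  # strong true structure is detected by the Phi_ST permutation test
  strong <- toy_aln(c(rep("AAAAAAAA", 5), rep("TTTTTTTT", 5)),
                    pops = rep(c("p1", "p2"), each = 5), regions = "r1")
  rs <- amova(strong, n_perms = 200L, seed = 6)
  expect_lt(rs$phi$p_value[3], 0.05)

  expect_error(amova(toy_aln(c("AA", "AT"), pops = "p1")),
               class = "comdemog_domain_error")
})

test_that("single-sequence populations are excluded from pairwise Phi_ST", {
  aln <- toy_aln(c("AAAA", "AATA", "TTTT", "TTAT", "CCCC"),
                 pops = c("p1", "p1", "p2", "p2", "p3"), regions = "r1")
  expect_warning(pf <- pairwise_fst(aln), "p3")
  expect_equal(rownames(pf), c("p1", "p2"))
})
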