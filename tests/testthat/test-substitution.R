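test_that("model families collapse into each other as their parameters equalise", {
  jc <- build_rate_matrix(substitution_model("HKY", kappa = 1))
  off <- jc[row(jc) != col(jc)]
  expect_equal(unname(off), rep(1 / 3, 12))

  hky <- build_rate_matrix(substitution_model("HKY", kappa = 7,
                                              base_freqs = c(.1, .2, .3, .4)))
  trn <- build_rate_matrix(substitution_model("TrN", rate_AG = 7, rate_CT = 7,
                                              base_freqs = c(.1, .2, .3, .4)))
  expect_equal(trn, hky, tolerance = 1e-12)

  k81_jc <- build_rate_matrix(substitution_model("K81", kappa = 1,
                                                 rate_tv2 = 1))
  expect_equal(k81_jc, jc, tolerance = 1e-12)
})

test_that("rate matrices are proper scaled reversible generators", {
  models <- list(
    substitution_model("TrN", rate_AG = 65.95, rate_CT = 24.28),
    substitution_model("HKY", kappa = 25.9, base_freqs = c(.4, .1, .2, .3)),
    substitution_model("K81", kappa = 2.81, rate_tv2 = 0.4))
  for (m in models) {
    q <- build_rate_matrix(m)
    expect_equal(rowSums(q), rep(0, 4), tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_equal(-sum(m$base_freqs * diag(q)), 1, tolerance = 1e-12)
    # detailed balance
    pq <- unname(diag(m$base_freqs) %*% q)
    expect_equal(pq, t(pq), tolerance = 1e-12)
  }
})

test_that("transition probabilities match a series-expansion exponential", {
  set.seed(2)
  for (i in 1:5) {
    m <- substitution_model("TrN", rate_AG = runif(1, 1, 50),
                            rate_CT = runif(1, 1, 50),
                            base_freqs = prop.table(runif(4, .5, 2)))
    q <- build_rate_matrix(m)
    t_len <- runif(1, 0.01, 2)
    expect_lt(max(abs(model_transition_probs(m, t_len) -
                        expm_series(q, t_len))), 1e-8)
  }
})

test_that("discrete-gamma categories are mean-one and shape-sensitive", {
  r_flat <- gamma_category_rates(1e6, 4)
  expect_true(all(abs(r_flat - 1) < 0.01))

  r_low <- gamma_category_rates(0.04, 4)
  expect_lt(r_low[1], 1e-4)
  expect_gt(r_low[4], 3)
  expect_equal(mean(r_low), 1, tolerance = 1e-15)
  expect_equal(mean(gamma_category_rates(1.55, 4)), 1, tolerance = 1e-15)

  expect_error(gamma_category_rates(0, 4), class = "comdemog_domain_error")
  expect_error(draw_site_rates(-1, 10), class = "comdemog_domain_error")
  rates <- draw_site_rates(0.5, 1000, 4, seed = 3)
  expect_length(rates, 1000)
  expect_setequal(unique(rates), attr(rates, "category_rates"))
})

test_that("zero branch lengths copy the root sequence unchanged", {
  tr <- ape::read.tree(text = "((a:0,b:0):0,c:0);")
  aln <- evolve_sequences(tr, substitution_model("HKY", kappa = 2),
                          mu = 1e-8, n_sites = 50, seed = 4)
  expect_equal(length(unique(aln_strings(aln))), 1L)
})

test_that("pairwise divergence follows the Jukes-Cantor closed form", {
  jc <- substitution_model("HKY", kappa = 1)
  # saturation: mu * t = 10 => expected 3/4 differing sites
  tr_sat <- ape::read.tree(text = "(a:5,b:5);")
  a_sat <- evolve_sequences(tr_sat, jc, mu = 1, n_sites = 10000, seed = 5)
  p_sat <- pairwise_diff_matrix(a_sat)[1, 2] / 10000
  expect_lt(abs(p_sat - 0.75), 3 * sqrt(0.75 * 0.25 / 10000))

  # moderate divergence: tips at depth d each, p = 3/4 (1 - exp(-8 mu d / 3))
  d <- 0.1
  tr_mod <- ape::read.tree(text = "(a:0.1,b:0.1);")
  a_mod <- evolve_sequences(tr_mod, jc, mu = 1, n_sites = 50000, seed = 6)
  p_obs <- pairwise_diff_matrix(a_mod)[1, 2] / 50000
  p_exp <- 0.75 * (1 - exp(-8 * d / 3))
  expect_lt(abs(p_obs - p_exp), 3 * sqrt(p_exp * (1 - p_exp) / 50000))
})

test_that("long-branch composition converges to the stationary frequencies", {
  freqs <- c(0.4, 0.1, 0.2, 0.3)
  m <- substitution_model("HKY", kappa = 5, base_freqs = freqs)
  tr <- ape::read.tree(text = "(a:50,b:50);")
  aln <- evolve_sequences(tr, m, mu = 1, n_sites = 1e5, seed = 8)
  counts <- table(factor(aln$seq[1, ], levels = c("A", "C", "G", "T")))
  expect_gt(chisq.test(counts, p = freqs)$p.value, 0.01)
})

test_that("gamma heterogeneity inflates among-site mutational variance", {
  # star tree, many tips: per-site allele diversity tracks site rate
  tr <- ape::stree(30, type = "star")
  tr$edge.length <- rep(0.3, 30)
  site_var <- function(alpha, seed) {
    m <- substitution_model("HKY", kappa = 2, alpha = alpha)
    aln <- evolve_sequences(tr, m, mu = 1, n_sites = 400, seed = seed)
    var(apply(aln$seq, 2L, function(col) length(unique(col))))
  }
  wins <- vapply(1:40, function(s) {
    site_var(0.04, seed = s) < site_var(NULL, seed = 1000 + s)
  }, logical(1L))
  # heterogeneous sites split between frozen and saturated: higher variance
  expect_gte(mean(!wins), 0.9)
})

test_that("model constructor enforces its invariants", {
  expect_error(substitution_model("HKY"), class = "comdemog_config_error")
  expect_error(substitution_model("TrN", rate_AG = 1),
               class = "comdemog_config_error")
  expect_error(substitution_model("HKY", kappa = 2, alpha = -1),
               class = "comdemog_config_error")
  expect_error(substitution_model("HKY", kappa = 2,
                                  base_freqs = c(.5, .5, .2, .2)),
               class = "comdemog_config_error")
})
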