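test_that("the default community has the study's shape", {
  cfg <- default_community_config(seed = 42)
  expect_length(cfg$entries, 9L)  # 4 moth species x 2 loci + 1 plant locus
  ns <- vapply(cfg$entries, \(e) sum(e$populations$n_samples), numeric(1L))
  expect_equal(unname(ns), c(25, 54, 32, 58, 24, 43, 31, 49, 79))
  lens <- vapply(cfg$entries, \(e) e$n_sites, integer(1L))
  expect_equal(unname(lens[c(1, 2, 9)]), c(1800L, 490L, 2000L))
  expect_equal(cfg$entries[[9]]$structure, "stepping_stone")
  expect_equal(cfg$entries[[1]]$model$family, "TrN")
  expect_equal(cfg$entries[[1]]$model$alpha, 0.04)
})

test_that("community generation is deterministic and carries provenance", {
  # scaled-down configuration so the full chain runs in seconds
  small_entry <- function(sp, seed_pops = 1) {
    species_config(
      sp, "locA", "mtDNA",
      tibble::tibble(population = c("p1", "p2"), region = c("r1", "r2"),
                     latitude = c(35, 36), longitude = c(-117, -116),
                     n_samples = c(4L, 4L)),
      substitution_model("HKY", kappa = 5, alpha = 0.5),
      n_sites = 200L, mu = 1e-8,
      scenario = demographic_scenario(1e5))
  }
  cfg <- community_config(list(small_entry("spA"), small_entry("spB")),
                          seed = 7)
  out1 <- generate_community(cfg)
  out2 <- generate_community(cfg)
  expect_identical(out1$spA$locA$seq, out2$spA$locA$seq)
  expect_false(identical(out1$spA$locA$seq, out1$spB$locA$seq))
  prov <- attr(out1$spA$locA, "provenance")
  expect_equal(prov$master_seed, 7L)
  expect_equal(prov$species, "spA")

  # byte-identical FASTA under the same master seed
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  m1 <- withr::local_tempfile(); m2 <- withr::local_tempfile()
  write_alignment(out1$spA$locA, f1, m1)
  write_alignment(out2$spA$locA, f2, m2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("configuration errors name the offending field", {
  pops <- tibble::tibble(population = "p1", region = "r1", latitude = 0,
                         longitude = 0, n_samples = 4L)
  expect_error(
    species_config("sp", "l", "mtDNA", pops,
                   substitution_model("HKY", kappa = 2), 100L, -1,
                   demographic_scenario(100)),
    regexp = "mu", class = "comdemog_config_error")
  expect_error(
    species_config("sp", "l", "mtDNA", pops,
                   substitution_model("HKY", kappa = 2), 100L, 1e-8,
                   demographic_scenario(100), structure = "stepping_stone",
                   migration_rate = 0.1),
    class = "comdemog_config_error")  # needs >= 2 demes
})

test_that("panmictic constant-size data calibrate to theta = 2 Ne mu", {
  sc <- demographic_scenario(2e5)
  mod <- substitution_model("HKY", kappa = 2)
  set.seed(19)
  pis <- replicate(200, {
    tr <- simulate_genealogy(10, sc)
    aln <- evolve_sequences(tr, mod, 1e-8, 500)
    d <- pairwise_diff_matrix(aln)
    mean(d[upper.tri(d)]) / 500
  })
  mc_se <- sd(pis) / sqrt(length(pis))
  expect_lt(abs(mean(pis) - 2 * 2e5 * 1e-8), 3 * mc_se)
})

test_that("vanishing migration drives stepping-stone FST towards one", {
  cfg <- default_community_config(seed = 3)
  plant <- cfg$entries[[9]]
  plant$n_sites <- 400L
  plant$migration_rate <- plant$migration_rate / 10  # migration -> 0
  seeds <- 1:50 * 911L
  fsts <- vapply(seeds, function(s) {
    global_fst(comdemog:::simulate_species_locus(plant, seed = s))
  }, numeric(1L))
  expect_gte(mean(fsts > 0.8), 0.9)
})

test_that("structure gating separates stepping-stone from panmictic data", {
  cfg <- default_community_config(seed = 5)
  plant <- cfg$entries[[9]]
  plant$n_sites <- 400L
  panmictic <- plant
  panmictic$structure <- "panmictic"
  gate_for <- function(entry, s) {
    aln <- comdemog:::simulate_species_locus(entry, seed = s)
    mt <- ibd_mantel(aln, n_perms = 99, seed = 1)
    structure_gate(global_fst(aln), mt$p)
  }
  seeds <- 1:15 * 487L
  gates_ss <- vapply(seeds, function(s) gate_for(plant, s), logical(1L))
  gates_pan <- vapply(seeds, function(s) gate_for(panmictic, s), logical(1L))
  expect_gte(mean(gates_ss), 0.9)
  expect_lte(mean(gates_pan), 0.1)
})

test_that("SDM fixtures are deterministic, bounded and maskable", {
  fx <- generate_sdm_fixture(100, 3, seed = 1)
  expect_equal(length(fx$surface$data), 100L)
  expect_true(all(fx$surface$data >= 0 & fx$surface$data <= 1))
  expect_length(fx$current_stack, 3L)
  fx2 <- generate_sdm_fixture(100, 3, seed = 1)
  expect_identical(fx$surface$data, fx2$surface$data)
  expect_identical(fx$presence, fx2$presence)

  # presences come preferentially from suitable cells: AUC above chance
  pres_scores <- fx$surface$data[as.matrix(fx$presence)]
  back_scores <- fx$surface$data[as.matrix(fx$background)]
  expect_gt(roc_auc(pres_scores, back_scores), 0.5)

  # a shifted past variable produces non-analogue cells
  fx3 <- generate_sdm_fixture(64, 2, seed = 2, past_shift = 10)
  mask <- nonanalog_mask(fx3$current_stack, fx3$past_stack)
  expect_gte(sum(mask, na.rm = TRUE), 1)

  expect_error(generate_sdm_fixture(2, 3), class = "comdemog_config_error")
})
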