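#' Null distribution p-value for Fu's Fs under constant size
#'
#' Simulates constant-size coalescent datasets matched to the observed
#' population mutation rate (Ne = theta / (2 mu)), computes Fu's Fs on each,
#' and returns the fraction strictly below the observed value (lower-tail
#' test: expansion pushes Fs negative). Replicates on which Fs is undefined
#' (monomorphic, S = 0) are redrawn and their count reported.
#'
#' @param observed_fs observed Fu's Fs.
#' @param n sample size per replicate.
#' @param theta_match per-site theta the null is matched to.
#' @param model a [substitution_model].
#' @param mu per-site per-generation mutation rate.
#' @param n_sites alignment length.
#' @param n_reps number of replicates (>= 100).
#' @param seed integer seed.
#' @return A `power_result` (see [power_analysis()]) with scenario
#'   `"constant"`; its `proportion_extreme` is the p-value.
#' @export
fs_null_pvalue <- function(observed_fs, n, theta_match, model, mu, n_sites,
                           n_reps = 1000L, seed = 1L) {
  scenario <- demographic_scenario(ne_present = ne_from_theta(theta_match, mu,
                                                              signif_digits = NULL),
                                   ratio_ancestral = 1)
  power_analysis(observed_fs, scenario, model, mu, n, n_sites,
                 n_reps = n_reps, seed = seed, scenario_label = "constant")
}

#' Power analysis: observed statistic against a simulated demographic history
#'
#' The full generative chain, replicated: simulate a coalescent genealogy
#' under the scenario, evolve sequences under the substitution model, compute
#' the statistic (Fu's Fs by default), and report the proportion of simulated
#' values strictly less than the observed one. With an expansion-sensitive
#' statistic this proportion is the probability of obtaining a signature of
#' growth at least as extreme as observed, given that history.
#'
#' @param observed_stat observed statistic value.
#' @param scenario a [demographic_scenario].
#' @param model a [substitution_model].
#' @param mu per-site per-generation mutation rate.
#' @param n sample size per replicate.
#' @param n_sites alignment length.
#' @param n_reps number of replicates (>= 100 enforced, 1000 typical).
#' @param seed integer seed; replicate r uses `seed + r` so runs are
#'   reproducible and extensible.
#' @param statistic function `hap_alignment -> numeric`; defaults to [fu_fs].
#' @param scenario_label label stored in the result.
#' @param max_redraws cap on redraws of undefined-statistic replicates.
#' @return A `power_result`: `observed`, `scenario`, `n_reps`, `sim_values`,
#'   `proportion_extreme`, `n_redrawn`, `seed`.
#' @export
power_analysis <- function(observed_stat, scenario, model, mu, n, n_sites,
                           n_reps = 1000L, seed = 1L, statistic = NULL,
                           scenario_label = "scenario",
                           max_redraws = 100L) {
  if (n_reps < 100L) {
    abort("n_reps must be >= 100.", class = "comdemog_config_error")
  }
  statistic <- statistic %||% function(a) fu_fs(a)
  sim_values <- numeric(n_reps)
  n_redrawn <- 0L
  for (r in seq_len(n_reps)) {
    val <- NA_real_
    draw <- 0L
    while (is.na(val) && draw <= max_redraws) {
      # disjoint seed streams per replicate and per redraw
      set.seed(seed + r + draw * (n_reps + 1L))
      tr <- simulate_genealogy(n, scenario)
      aln <- evolve_sequences(tr, model, mu, n_sites)
      val <- tryCatch(
        suppressWarnings(statistic(aln)),
        comdemog_undefined_statistic = function(e) NA_real_
      )
      if (is.na(val)) {
        n_redrawn <- n_redrawn + 1L
        draw <- draw + 1L
      }
    }
    if (is.na(val)) {
      abort("Too many undefined-statistic replicates; raise theta or n_sites.",
            class = "comdemog_estimation_error")
    }
    sim_values[r] <- val
  }
  structure(
    list(observed = observed_stat, scenario = scenario_label,
         n_reps = n_reps, sim_values = sim_values,
         proportion_extreme = mean(sim_values < observed_stat),
         n_redrawn = n_redrawn, seed = seed),
    class = "power_result"
  )
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf(
    "<power_result> scenario %s: Pr(sim < %.4g) = %.4g (%d reps, %d redrawn)\n",
    x$scenario, x$observed, x$proportion_extreme, x$n_reps, x$n_redrawn))
  invisible(x)
}

#' @export
tidy.power_result <- function(x, ...) {
  tibble(scenario = x$scenario, observed = x$observed,
         proportion_extreme = x$proportion_extreme, n_reps = x$n_reps,
         n_redrawn = x$n_redrawn, seed = x$seed)
}

#' @export
glance.power_result <- function(x, ...) tidy.power_result(x)

#' @export
autoplot.power_result <- function(object, ...) {
  df <- tibble(fs = object$sim_values)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fs)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "firebrick",
                        linetype = "dashed") +
    ggplot2::labs(
      x = "Simulated statistic", y = "Replicates",
      title = sprintf("%s: Pr(sim < observed) = %.3f",
                      object$scenario, object$proportion_extreme)) +
    ggplot2::theme_minimal()
}

#' Recompute the extreme proportion for a stored power result
#'
#' @param result a `power_result`.
#' @param observed a (possibly new) observed value.
#' @return Fraction of stored simulated values strictly below `observed`.
#' @export
proportion_extreme <- function(result, observed = result$observed) {
  mean(result$sim_values < observed)
}
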