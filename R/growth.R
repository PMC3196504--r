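#' Exponential-growth coalescent likelihood fit
#'
#' Maximum-likelihood estimation of the diversity parameter Theta and the
#' growth rate g from a single genealogy, under the exponential-growth
#' coalescent: looking into the past in mutational time u, population
#' diversity is `Theta(u) = Theta exp(-g u)` and the coalescence hazard while
#' k lineages remain is `k (k - 1) exp(g u) / Theta`. This is a deliberate
#' single-genealogy simplification of genealogy-sampling growth estimators:
#' g is interpreted qualitatively (sign and magnitude class), not as an
#' unbiased point estimate, and single-locus estimates of g carry a known
#' upward bias.
#'
#' In `"sequence"` mode, an ultrametric genealogy is first reconstructed from
#' pairwise p-distances by average-linkage (UPGMA) clustering; node heights
#' in substitutions per site are the mutational times.
#'
#' @param x a `phylo` (genealogy mode) or a [hap_alignment] (sequence mode).
#' @param mu_per_site per-site per-generation rate used to convert a
#'   genealogy's branch lengths from generations to mutational units; use 1
#'   if the tree is already in mutational units (e.g. from
#'   [simulate_growth_genealogy()]).
#' @param mode `"genealogy"` or `"sequence"`; inferred from the class of `x`
#'   when missing.
#' @param g_fixed optionally fix g (e.g. 0 for the constant-size null, where
#'   Theta has the closed form `sum k(k-1) w_k / (n-1)`).
#' @param ci compute a profile-likelihood interval for g (delta log-lik 1.92,
#'   approximately 95%).
#' @return A `growth_fit` object: `theta_hat`, `g_hat`, `loglik`, `ci_g`,
#'   `n_tips`.
#' @export
#' @examples
#' tr <- simulate_growth_genealogy(30, theta_present = 0.02, g = 0, seed = 7)
#' fit_growth(tr, mu_per_site = 1)
fit_growth <- function(x, mu_per_site = 1, mode = NULL, g_fixed = NULL,
                       ci = TRUE) {
  mode <- mode %||% if (inherits(x, "hap_alignment")) "sequence" else "genealogy"
  mode <- match.arg(mode, c("genealogy", "sequence"))
  if (mode == "sequence") {
    if (n_seq(x) < 3L) {
      abort("Sequence mode needs >= 3 sequences.",
            class = "comdemog_domain_error")
    }
    if (count_segregating(x$seq) == 0L) {
      abort("Cannot estimate growth from monomorphic data (S = 0).",
            class = "comdemog_estimation_error")
    }
    times <- upgma_coalescence_times(x)
  } else {
    if (mu_per_site <= 0) {
      abort("mu_per_site must be > 0.", class = "comdemog_domain_error")
    }
    times <- coalescence_times(x) * mu_per_site
  }
  n <- length(times) + 1L
  # interval bounds: while k lineages, from s_k to e_k (e_k = k-th coalescence
  # counting from the present)
  starts <- c(0, times[-length(times)])
  ends <- times
  ks <- n:2

  nll <- function(log_theta, g) {
    theta <- exp(log_theta)
    kk1 <- ks * (ks - 1)
    ll_event <- sum(log(kk1 / theta) + g * ends)
    if (abs(g) < 1e-12) {
      ll_int <- sum(kk1 * (ends - starts)) / theta
    } else {
      ll_int <- sum(kk1 * (exp(g * ends) - exp(g * starts))) / (g * theta)
    }
    -(ll_event - ll_int)
  }

  if (!is.null(g_fixed)) {
    theta_hat <- sum(ks * (ks - 1) * (if (abs(g_fixed) < 1e-12) {
      ends - starts
    } else {
      (exp(g_fixed * ends) - exp(g_fixed * starts)) / g_fixed
    })) / (n - 1)
    g_hat <- g_fixed
    ll <- -nll(log(theta_hat), g_hat)
    ci_g <- c(NA_real_, NA_real_)
  } else {
    theta0 <- sum(ks * (ks - 1) * (ends - starts)) / (n - 1)
    opt <- optim(c(log(theta0), 0),
                 function(p) nll(p[1], p[2]),
                 method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-12))
    theta_hat <- exp(opt$par[1])
    g_hat <- opt$par[2]
    ll <- -opt$value
    ci_g <- if (ci) profile_ci_g(nll, g_hat, ll) else c(NA_real_, NA_real_)
  }
  structure(
    list(theta_hat = theta_hat, g_hat = g_hat, loglik = ll,
         ci_g = ci_g, n_tips = n, times = times, mode = mode),
    class = "growth_fit"
  )
}

# profile log-likelihood over g, maximising over Theta at each g
profile_ci_g <- function(nll, g_hat, ll_max, drop = 1.92) {
  prof <- function(g) {
    o <- optimise(function(lt) nll(lt, g), interval = c(-40, 40))
    -o$objective
  }
  target <- ll_max - drop
  half_width <- max(abs(g_hat), 1)
  lower <- tryCatch({
    lo <- g_hat - half_width
    while (prof(lo) > target && lo > g_hat - 64 * half_width) {
      lo <- g_hat - 2 * (g_hat - lo)
    }
    if (prof(lo) > target) NA_real_ else
      uniroot(function(g) prof(g) - target, c(lo, g_hat))$root
  }, error = function(e) NA_real_)
  upper <- tryCatch({
    hi <- g_hat + half_width
    while (prof(hi) > target && hi < g_hat + 64 * half_width) {
      hi <- g_hat + 2 * (hi - g_hat)
    }
    if (prof(hi) > target) NA_real_ else
      uniroot(function(g) prof(g) - target, c(g_hat, hi))$root
  }, error = function(e) NA_real_)
  c(lower, upper)
}

# UPGMA node heights from p-distances; heights/2 are coalescence times in
# substitutions per site
upgma_coalescence_times <- function(aln) {
  d <- pairwise_diff_matrix(aln) / n_sites(aln)
  hc <- hclust(stats::as.dist(d), method = "average")
  ht <- sort(hc$height) / 2
  # strictly increasing times are required by the likelihood; perturb exact
  # ties by a negligible epsilon
  eps <- max(ht) * 1e-9 + 1e-12
  dup <- duplicated(ht)
  if (any(dup)) ht[dup] <- ht[dup] + cumsum(dup)[dup] * eps
  ht
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf(
    "<growth_fit> theta = %.4g, g = %.4g (95%% profile CI %.4g..%.4g), loglik = %.3f, n = %d [%s mode]\n",
    x$theta_hat, x$g_hat, x$ci_g[1], x$ci_g[2], x$loglik, x$n_tips, x$mode))
  invisible(x)
}

#' @export
tidy.growth_fit <- function(x, ...) {
  tibble(term = c("theta", "g"),
         estimate = c(x$theta_hat, x$g_hat),
         conf.low = c(NA_real_, x$ci_g[1]),
         conf.high = c(NA_real_, x$ci_g[2]))
}

#' @export
glance.growth_fit <- function(x, ...) {
  tibble(theta_hat = x$theta_hat, g_hat = x$g_hat, loglik = x$loglik,
         ci_g_low = x$ci_g[1], ci_g_high = x$ci_g[2], n_tips = x$n_tips,
         mode = x$mode)
}

#' @export
autoplot.growth_fit <- function(object, ...) {
  # lineage-through-time style step plot of the fitted history
  u <- seq(0, max(object$times) * 1.05, length.out = 200)
  df <- tibble(u = u,
               theta = object$theta_hat * exp(-object$g_hat * u))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$u, y = .data$theta)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_rug(data = tibble(u = object$times),
                      ggplot2::aes(x = .data$u), inherit.aes = FALSE,
                      sides = "b") +
    ggplot2::labs(x = "Mutational time before present",
                  y = expression(Theta(u)),
                  title = sprintf("Fitted growth history (g = %.3g)",
                                  object$g_hat)) +
    ggplot2::theme_minimal()
}

#' Posterior probability of demographic constancy
#'
#' Post-processing rule for Bayesian skyline output: given the posterior
#' sample of the number of population-size change points (one non-negative
#' integer per post-burn-in generation), the fraction of samples with zero
#' changes is the posterior probability of no change in population size.
#'
#' @param change_counts non-negative integer vector.
#' @return Probability in `[0, 1]`.
#' @export
#' @examples
#' posterior_prob_no_change(c(rep(0, 8), rep(1, 992))) # 0.008
posterior_prob_no_change <- function(change_counts) {
  if (length(change_counts) == 0L) {
    abort("change_counts must be non-empty.", class = "comdemog_domain_error")
  }
  if (any(change_counts < 0) || any(change_counts != round(change_counts))) {
    abort("change_counts must be non-negative integers.",
          class = "comdemog_domain_error")
  }
  mean(change_counts == 0)
}
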