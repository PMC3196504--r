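#' Expected mismatch distribution under sudden expansion
#'
#' Closed-form expected distribution of pairwise differences under the sudden
#' expansion model: a population at diversity `theta0` jumped to `theta1` at
#' time `tau` before present (time in units of 1/(2u), u the per-locus
#' pairwise mutation rate). Conditioning on the coalescence time of a pair
#' (exponential at rate 1/theta1 until tau, then 1/theta0) and integrating
#' the Poisson mutation count gives, via regularised incomplete gamma
#' functions P:
#' \deqn{F_j = \frac{(\theta_1/(\theta_1+1))^j}{\theta_1+1}
#'   P(j+1, \tau c_1) + e^{-\tau/\theta_1 + \tau/\theta_0}
#'   \frac{(\theta_0/(\theta_0+1))^j}{\theta_0+1} (1 - P(j+1, \tau c_0))}
#' with \eqn{c_x = 1 + 1/\theta_x}. At `tau = 0` this is the equilibrium
#' geometric distribution at `theta0`; as `tau` grows it converges to the
#' geometric at `theta1`.
#'
#' @param j vector of difference counts (>= 0).
#' @param tau expansion time parameter (>= 0).
#' @param theta0 pre-expansion diversity (> 0).
#' @param theta1 post-expansion diversity (> 0).
#' @return Probabilities F_j.
#' @export
expected_mismatch <- function(j, tau, theta0, theta1) {
  if (tau < 0 || theta0 <= 0 || theta1 <= 0) {
    abort("tau >= 0 and theta0, theta1 > 0 required.",
          class = "comdemog_domain_error")
  }
  c1 <- 1 + 1 / theta1
  c0 <- 1 + 1 / theta0
  # recent epoch: coalescence more recent than tau (post-expansion)
  a <- exp(j * log(theta1 / (theta1 + 1)) - log(theta1 + 1)) *
    pgamma(tau * c1, shape = j + 1)
  # old epoch: survival to tau then coalescence at rate 1/theta0
  log_tail <- pgamma(tau * c0, shape = j + 1, lower.tail = FALSE, log.p = TRUE)
  b <- exp(-tau / theta1 + tau / theta0 +
             j * log(theta0 / (theta0 + 1)) - log(theta0 + 1) + log_tail)
  a + b
}

#' Observed mismatch distribution
#'
#' Histogram of pairwise nucleotide difference counts over all C(n,2) pairs.
#'
#' @param aln a [hap_alignment].
#' @return A tibble with columns `differences` (0..max) and `count`.
#' @export
mismatch_distribution <- function(aln) {
  d <- pairwise_diff_matrix(aln)
  v <- d[upper.tri(d)]
  tab <- tabulate(v + 1L, nbins = max(v) + 1L)
  tibble(differences = seq_along(tab) - 1L, count = tab)
}

#' Fit the sudden-expansion model to a mismatch distribution
#'
#' Least-squares fit of the [expected_mismatch] curve to the observed
#' relative frequencies of pairwise differences, over `(tau, theta0)` with
#' `theta1` pinned at `1000 * max(theta0, 1)` (effectively infinite
#' post-expansion size, the configuration in which tau dates the expansion).
#' The minimiser is located on a bounded grid and refined by L-BFGS-B.
#'
#' @param aln a [hap_alignment].
#' @param grid_points grid resolution per parameter for the initial search.
#' @return A `mismatch_fit` object: list with `tau_hat`, `theta0_hat`,
#'   `theta1_hat`, `ssd`, and the observed `mismatch` tibble.
#' @export
#' @examples
#' \donttest{
#' tr <- simulate_genealogy(20, demographic_scenario(1e6, 0.01), seed = 1)
#' aln <- evolve_sequences(tr, substitution_model("HKY", kappa = 2),
#'                         mu = 1.5e-8, n_sites = 800, seed = 1)
#' mismatch_tau(aln)
#' }
mismatch_tau <- function(aln, grid_points = 40L) {
  obs <- mismatch_distribution(aln)
  n_pairs <- sum(obs$count)
  freq <- obs$count / n_pairs
  jj <- obs$differences
  max_d <- max(jj)

  if (max_d == 0L) {
    fit <- list(tau_hat = 0, theta0_hat = 0, theta1_hat = 0, ssd = 0,
                mismatch = obs)
    class(fit) <- "mismatch_fit"
    return(fit)
  }

  ssd_fun <- function(par) {
    tau <- par[1]
    theta0 <- par[2]
    theta1 <- 1000 * max(theta0, 1)
    sum((freq - expected_mismatch(jj, tau, theta0, theta1))^2)
  }

  pi_hat <- sum(jj * freq)
  taus <- seq(0, 2 * max_d, length.out = grid_points)
  theta0s <- exp(seq(log(1e-3), log(max(pi_hat, 1) * 2), length.out = grid_points))
  grid <- expand.grid(tau = taus, theta0 = theta0s)
  ssds <- vapply(seq_len(nrow(grid)),
                 function(i) ssd_fun(c(grid$tau[i], grid$theta0[i])),
                 numeric(1L))
  best <- as.numeric(grid[which.min(ssds), ])
  opt <- optim(best, ssd_fun, method = "L-BFGS-B",
               lower = c(0, 1e-6), upper = c(4 * max_d + 1, 1e4))
  theta0_hat <- opt$par[2]
  fit <- list(tau_hat = opt$par[1], theta0_hat = theta0_hat,
              theta1_hat = 1000 * max(theta0_hat, 1), ssd = opt$value,
              mismatch = obs)
  class(fit) <- "mismatch_fit"
  fit
}

#' @export
print.mismatch_fit <- function(x, ...) {
  cat(sprintf("<mismatch_fit> tau = %.4g, theta0 = %.4g, theta1 = %.4g, SSD = %.4g\n",
              x$tau_hat, x$theta0_hat, x$theta1_hat, x$ssd))
  invisible(x)
}

#' @export
tidy.mismatch_fit <- function(x, ...) {
  tibble(term = c("tau", "theta0", "theta1"),
         estimate = c(x$tau_hat, x$theta0_hat, x$theta1_hat))
}

#' @export
glance.mismatch_fit <- function(x, ...) {
  tibble(tau_hat = x$tau_hat, theta0_hat = x$theta0_hat,
         theta1_hat = x$theta1_hat, ssd = x$ssd,
         n_pairs = sum(x$mismatch$count))
}

#' @export
autoplot.mismatch_fit <- function(object, ...) {
  obs <- object$mismatch
  obs$freq <- obs$count / sum(obs$count)
  obs$expected <- expected_mismatch(obs$differences, object$tau_hat,
                                    object$theta0_hat, object$theta1_hat)
  ggplot2::ggplot(obs, ggplot2::aes(x = .data$differences)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$freq), fill = "grey70") +
    ggplot2::geom_line(ggplot2::aes(y = .data$expected), colour = "firebrick") +
    ggplot2::geom_point(ggplot2::aes(y = .data$expected), colour = "firebrick") +
    ggplot2::labs(x = "Pairwise differences", y = "Frequency",
                  title = sprintf("Mismatch distribution (tau = %.3g)",
                                  object$tau_hat)) +
    ggplot2::theme_minimal()
}

#' Convert a mismatch tau to years
#'
#' Converts the expansion parameter tau into calendar years using the
#' per-locus substitution rate per year. Two conventions are exposed and must
#' not be confused: `"classical"` is the textbook `tau = 2 mu t`, so
#' `t = tau / (2 mu)`; `"paper_table"` is `t = tau / mu`, the convention under
#' which the study's printed expansion dates are internally consistent. The
#' two differ by exactly a factor of two.
#'
#' @param tau expansion parameter (>= 0).
#' @param mu_locus_per_year per-locus substitution rate per year (> 0).
#' @param convention `"paper_table"` (default) or `"classical"`.
#' @param signif_digits significant figures in the returned value; `NULL`
#'   for no rounding.
#' @return Time since the size change in years.
#' @export
#' @examples
#' tau_to_years(0.462, 3.01e-5)               # 15300
#' tau_to_years(0.462, 3.01e-5, "classical")  # half that
tau_to_years <- function(tau, mu_locus_per_year,
                         convention = c("paper_table", "classical"),
                         signif_digits = 3) {
  convention <- match.arg(convention)
  if (any(tau < 0)) abort("tau must be >= 0.", class = "comdemog_domain_error")
  if (any(mu_locus_per_year <= 0)) {
    abort("mu_locus_per_year must be > 0.", class = "comdemog_domain_error")
  }
  yr <- switch(convention,
               paper_table = tau / mu_locus_per_year,
               classical = tau / (2 * mu_locus_per_year))
  if (!is.null(signif_digits)) yr <- signif(yr, signif_digits)
  yr
}
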