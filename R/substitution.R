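#' Nucleotide substitution model
#'
#' Container for the substitution models used to evolve sequences: HKY
#' (single transition:transversion ratio kappa), TrN (separate purine A<->G
#' and pyrimidine C<->T transition rates), and K81 (Kimura three-substitution
#' type; here parameterised by a single kappa giving the transition rate
#' relative to both transversion classes, which are held equal unless
#' `rate_tv2` is supplied). Optional discrete-gamma rate heterogeneity with
#' shape `alpha` over `n_categories` equal-probability categories.
#'
#' @param family `"HKY"`, `"TrN"`, or `"K81"`.
#' @param kappa transition/transversion ratio (HKY, K81).
#' @param rate_AG,rate_CT purine and pyrimidine transition rates relative to
#'   transversions (TrN).
#' @param alpha gamma shape; `NULL` means equal rates across sites.
#' @param n_categories number of discrete gamma categories.
#' @param base_freqs stationary base frequencies (A, C, G, T), summing to 1.
#' @param rate_tv2 second transversion class rate for K81 (relative to the
#'   first, which is 1); defaults to 1 (both classes equal).
#' @return A `substitution_model` object.
#' @export
#' @examples
#' substitution_model("TrN", rate_AG = 65.95, rate_CT = 24.28, alpha = 0.04)
substitution_model <- function(family = c("HKY", "TrN", "K81"), kappa = NULL,
                               rate_AG = NULL, rate_CT = NULL, alpha = NULL,
                               n_categories = 4L,
                               base_freqs = rep(0.25, 4), rate_tv2 = 1) {
  family <- match.arg(family)
  if (abs(sum(base_freqs) - 1) > 1e-12 || length(base_freqs) != 4L ||
      any(base_freqs <= 0)) {
    abort("base_freqs must be 4 positive probabilities summing to 1.",
          class = "comdemog_config_error")
  }
  if (family %in% c("HKY", "K81")) {
    if (is.null(kappa) || kappa <= 0) {
      abort(paste0(family, " requires kappa > 0."),
            class = "comdemog_config_error")
    }
  }
  if (family == "TrN") {
    if (is.null(rate_AG) || is.null(rate_CT) || rate_AG <= 0 || rate_CT <= 0) {
      abort("TrN requires rate_AG > 0 and rate_CT > 0.",
            class = "comdemog_config_error")
    }
  }
  if (!is.null(alpha) && alpha <= 0) {
    abort("alpha must be > 0 when present.", class = "comdemog_config_error")
  }
  if (rate_tv2 <= 0) {
    abort("rate_tv2 must be > 0.", class = "comdemog_config_error")
  }
  structure(
    list(family = family, kappa = kappa, rate_AG = rate_AG, rate_CT = rate_CT,
         alpha = alpha, n_categories = as.integer(n_categories),
         base_freqs = setNames(base_freqs, NUC), rate_tv2 = rate_tv2),
    class = "substitution_model"
  )
}

#' @export
print.substitution_model <- function(x, ...) {
  pars <- switch(x$family,
    HKY = sprintf("kappa = %.4g", x$kappa),
    K81 = sprintf("kappa = %.4g, tv2 = %.4g", x$kappa, x$rate_tv2),
    TrN = sprintf("AG = %.4g, CT = %.4g", x$rate_AG, x$rate_CT))
  het <- if (is.null(x$alpha)) "equal rates" else
    sprintf("gamma alpha = %.4g (%d categories)", x$alpha, x$n_categories)
  cat(sprintf("<substitution_model> %s (%s), %s\n", x$family, pars, het))
  invisible(x)
}

#' Instantaneous rate matrix of a substitution model
#'
#' Builds the 4x4 GTR-form rate matrix Q for the model: exchangeabilities per
#' family times stationary frequencies, rows summing to zero, scaled so the
#' expected substitution rate at stationarity is exactly 1 per unit time
#' (branch lengths are then in expected substitutions when multiplied by mu).
#' Detailed balance pi_i Q_ij = pi_j Q_ji holds by construction.
#'
#' @param model a [substitution_model].
#' @return 4x4 matrix with dimnames A, C, G, T.
#' @export
build_rate_matrix <- function(model) {
  if (!inherits(model, "substitution_model")) {
    abort("model must be a substitution_model.",
          class = "comdemog_config_error")
  }
  # exchangeability matrix: symmetric, transversions = 1 (or rate_tv2 for the
  # second K81 class), transitions per family
  ex <- matrix(1, 4, 4, dimnames = list(NUC, NUC))
  r_ag <- switch(model$family, HKY = model$kappa, K81 = model$kappa,
                 TrN = model$rate_AG)
  r_ct <- switch(model$family, HKY = model$kappa, K81 = model$kappa,
                 TrN = model$rate_CT)
  ex["A", "G"] <- ex["G", "A"] <- r_ag
  ex["C", "T"] <- ex["T", "C"] <- r_ct
  if (model$family == "K81") {
    # K81's two transversion classes: A<->C/G<->T vs A<->T/C<->G
    ex["A", "T"] <- ex["T", "A"] <- model$rate_tv2
    ex["C", "G"] <- ex["G", "C"] <- model$rate_tv2
  }
  pi <- model$base_freqs
  q <- ex * rep(pi, each = 4L)
  diag(q) <- 0
  diag(q) <- -rowSums(q)
  # scale: expected rate = -sum_i pi_i q_ii = 1
  scale <- -sum(pi * diag(q))
  q <- q / scale
  q
}

#' Discrete-gamma site rate multipliers
#'
#' Draws per-site rate multipliers from a discretised Gamma(alpha, alpha)
#' distribution with `n_categories` equal-probability categories represented
#' by their category means (renormalised so the category values average to
#' exactly 1).
#'
#' @param alpha gamma shape (> 0).
#' @param n_sites number of sites.
#' @param n_categories number of categories (>= 1).
#' @param seed optional integer seed.
#' @return Numeric vector of length `n_sites`; attribute `category_rates`
#'   holds the category values, `category` the per-site category index.
#' @export
draw_site_rates <- function(alpha, n_sites, n_categories = 4L, seed = NULL) {
  rates <- gamma_category_rates(alpha, n_categories)
  if (!is.null(seed)) set.seed(seed)
  idx <- sample.int(n_categories, n_sites, replace = TRUE)
  out <- rates[idx]
  attr(out, "category_rates") <- rates
  attr(out, "category") <- idx
  out
}

#' @rdname draw_site_rates
#' @export
gamma_category_rates <- function(alpha, n_categories = 4L) {
  if (is.null(alpha) || alpha <= 0) {
    abort("alpha must be > 0.", class = "comdemog_domain_error")
  }
  k <- as.integer(n_categories)
  if (k < 1L) abort("n_categories must be >= 1.", class = "comdemog_domain_error")
  if (k == 1L) return(1)
  # category mean of Gamma(alpha, rate alpha) between quantiles q_{i-1}, q_i:
  # k * [P(q_i; alpha+1) - P(q_{i-1}; alpha+1)] with P the regularised lower
  # incomplete gamma at rate alpha (mean-preserving discretisation)
  bounds <- qgamma(seq(0, 1, length.out = k + 1L), shape = alpha, rate = alpha)
  p_upper <- pgamma(bounds, shape = alpha + 1, rate = alpha)
  rates <- k * diff(p_upper)
  rates / mean(rates)  # exact mean 1 despite tail rounding
}

#' Evolve sequences along a genealogy
#'
#' Simulates an alignment by drawing the root sequence from the stationary
#' frequencies and evolving each site independently down the tree with
#' transition probabilities `expm(Q * mu * r_site * branch_length)`. Site rate
#' multipliers are drawn once per alignment (shared across branches).
#'
#' @param genealogy a `phylo` with branch lengths in generations (or in
#'   mutational units with `mu = 1`).
#' @param model a [substitution_model].
#' @param mu per-site per-generation mutation rate.
#' @param n_sites alignment length.
#' @param seed optional integer seed.
#' @param meta optional metadata tibble passed to [hap_alignment()].
#' @param locus_name,genome passed to [hap_alignment()].
#' @return A [hap_alignment] with one sequence per tip.
#' @export
evolve_sequences <- function(genealogy, model, mu, n_sites, seed = NULL,
                             meta = NULL, locus_name = "locus",
                             genome = c("mtDNA", "nuclear", "cpDNA")) {
  genome <- match.arg(genome)
  if (mu <= 0) abort("mu must be > 0.", class = "comdemog_domain_error")
  if (!is.null(seed)) set.seed(seed)
  q <- build_rate_matrix(model)
  eig <- eigen(symmetrise_q(q, model$base_freqs))
  n_tip <- length(genealogy$tip.label)

  if (is.null(model$alpha)) {
    cat_rates <- 1
    site_cat <- rep(1L, n_sites)
  } else {
    cat_rates <- gamma_category_rates(model$alpha, model$n_categories)
    site_cat <- sample.int(length(cat_rates), n_sites, replace = TRUE)
  }
  n_cat <- length(cat_rates)

  # preorder traversal: states propagated parent -> child
  tr <- ape::reorder.phylo(genealogy, "cladewise")
  root <- n_tip + 1L
  states <- matrix(0L, nrow = n_tip + tr$Nnode, ncol = n_sites)
  states[root, ] <- sample.int(4L, n_sites, replace = TRUE,
                               prob = model$base_freqs)
  u_left <- sqrt(model$base_freqs)   # eigen-basis change, reused per edge
  v_pre <- diag(1 / u_left) %*% eig$vectors
  w_pre <- t(eig$vectors) %*% diag(u_left)
  for (i in seq_len(nrow(tr$edge))) {
    parent <- tr$edge[i, 1L]
    child <- tr$edge[i, 2L]
    len <- tr$edge.length[i] * mu
    if (len <= 0) {
      states[child, ] <- states[parent, ]
      next
    }
    # cumulative transition rows stacked (category, parent state) x target,
    # so one indexed lookup + three comparisons resolve every site at once
    cum <- matrix(0, nrow = 4L * n_cat, ncol = 4L)
    for (ci in seq_len(n_cat)) {
      p <- v_pre %*% (exp(eig$values * len * cat_rates[ci]) * w_pre)
      p[p < 0] <- 0
      p <- p / rowSums(p)
      cum[(ci - 1L) * 4L + 1:4, ] <- t(apply(p, 1L, cumsum))
    }
    idx <- (site_cat - 1L) * 4L + states[parent, ]
    x <- cum[idx, , drop = FALSE]
    u <- runif(n_sites)
    states[child, ] <- 1L + (u > x[, 1L]) + (u > x[, 2L]) + (u > x[, 3L])
  }
  m <- matrix(NUC[states[seq_len(n_tip), , drop = FALSE]], nrow = n_tip)
  rownames(m) <- tr$tip.label
  if (!is.null(meta)) {
    meta <- meta[match(tr$tip.label, meta$sample_id), ]
  }
  hap_alignment(m, meta = meta, locus_name = locus_name, genome = genome)
}

# symmetrised generator B = diag(sqrt(pi)) Q diag(1/sqrt(pi)); reversibility
# makes B symmetric so eigen() is stable and real
symmetrise_q <- function(q, pi) {
  s <- sqrt(pi)
  b <- diag(s) %*% q %*% diag(1 / s)
  (b + t(b)) / 2
}

# P(t) = diag(1/sqrt(pi)) U exp(L t) U' diag(sqrt(pi)); clamped to [0,1]
transition_matrix <- function(eig, pi, t) {
  s <- sqrt(pi)
  p <- diag(1 / s) %*% eig$vectors %*% diag(exp(eig$values * t)) %*%
    t(eig$vectors) %*% diag(s)
  p[p < 0] <- 0
  p <- p / rowSums(p)
  dimnames(p) <- list(NUC, NUC)
  p
}

#' Matrix exponential transition probabilities for a model
#'
#' Convenience wrapper: `P(t) = expm(Q t)` for a model's rate matrix, used for
#' checking against a series-expansion oracle.
#'
#' @param model a [substitution_model].
#' @param t branch length in expected substitutions.
#' @return 4x4 stochastic matrix.
#' @export
model_transition_probs <- function(model, t) {
  q <- build_rate_matrix(model)
  eig <- eigen(symmetrise_q(q, model$base_freqs))
  transition_matrix(eig, model$base_freqs, t)
}
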