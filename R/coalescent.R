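#' Demographic scenario with one instantaneous size change
#'
#' Describes a piecewise-constant haploid population history: constant size
#' `ne_present` from the present back to `t_change_years`, then constant size
#' `ne_present * ratio_ancestral` further into the past. Time is converted to
#' generations with `generations_per_year` (1 for the moths, 1/30 for the
#' plant).
#'
#' @param ne_present present haploid effective size (> 0).
#' @param ratio_ancestral ancestral:present size ratio (> 0). 1 is a constant
#'   history; < 1 means the population grew at the change point (looking
#'   forward in time); > 1 means it declined.
#' @param t_change_years years before present at which the size changed.
#' @param generations_per_year generations per year.
#' @return A `demographic_scenario` object.
#' @export
#' @examples
#' demographic_scenario(1e6, ratio_ancestral = 240 / 432)
demographic_scenario <- function(ne_present, ratio_ancestral = 1,
                                 t_change_years = 13000,
                                 generations_per_year = 1) {
  if (!is.numeric(ne_present) || ne_present <= 0) {
    abort("ne_present must be > 0.", class = "comdemog_config_error")
  }
  if (ratio_ancestral <= 0) {
    abort("ratio_ancestral must be > 0.", class = "comdemog_config_error")
  }
  if (t_change_years < 0) {
    abort("t_change_years must be >= 0.", class = "comdemog_config_error")
  }
  if (generations_per_year <= 0) {
    abort("generations_per_year must be > 0.", class = "comdemog_config_error")
  }
  structure(
    list(ne_present = ne_present, ratio_ancestral = ratio_ancestral,
         t_change_years = t_change_years,
         generations_per_year = generations_per_year),
    class = "demographic_scenario"
  )
}

#' @export
print.demographic_scenario <- function(x, ...) {
  cat(sprintf(
    "<demographic_scenario> Ne = %.4g, ancestral:present = %.4g, change at %.4g yr (%.4g generations)\n",
    x$ne_present, x$ratio_ancestral, x$t_change_years,
    x$t_change_years * x$generations_per_year))
  invisible(x)
}

#' Haploid effective size from a diversity estimate
#'
#' Converts a per-site population mutation parameter Theta into a haploid
#' effective population size via Ne = Theta / (2 mu), reported to three
#' significant figures. For a haploid locus Theta = 2 Ne mu, so this inverts
#' the definition directly; inheritance scaling is folded into the per-locus
#' Theta, not added here.
#'
#' @param theta per-site diversity parameter (>= 0).
#' @param mu per-site per-generation mutation rate (> 0).
#' @param signif_digits significant figures in the returned value (3 matches
#'   conventional reporting); use `NULL` for no rounding.
#' @return Haploid effective size (individuals).
#' @export
#' @examples
#' ne_from_theta(0.03, 1.5e-8) # 1e6
ne_from_theta <- function(theta, mu, signif_digits = 3) {
  if (any(mu <= 0)) abort("mu must be > 0.", class = "comdemog_domain_error")
  if (any(theta < 0)) abort("theta must be >= 0.", class = "comdemog_domain_error")
  ne <- theta / (2 * mu)
  if (!is.null(signif_digits)) ne <- signif(ne, signif_digits)
  ne
}

#' Ancestral:present size ratio from range-cell counts
#'
#' Treats the number of grid cells predicted suitable in a palaeodistribution
#' reconstruction as proportional to population size, so the ancestral:present
#' ratio is `past_cells / current_cells`.
#'
#' @param current_cells predicted-suitable cell count under current climate.
#' @param past_cells predicted-suitable cell count at the hindcast time slice.
#' @return Dimensionless ancestral:present size ratio.
#' @export
#' @examples
#' scenario_ratio_from_cells(432, 240) # ~0.556: present about double the past
scenario_ratio_from_cells <- function(current_cells, past_cells) {
  if (any(current_cells <= 0) || any(past_cells <= 0)) {
    abort("Cell counts must be > 0.", class = "comdemog_domain_error")
  }
  past_cells / current_cells
}

#' Simulate a coalescent genealogy under a one-change history
#'
#' Continuous-time Kingman coalescent with pairwise coalescence rate
#' `1 / N(t)` per generation, where `N(t)` is `ne_present` more recently than
#' the change time (in generations) and `ne_present * ratio_ancestral` beyond
#' it. Returns a rooted, binary, ultrametric `phylo` tree with branch lengths
#' in generations.
#'
#' @param n number of tips (>= 2).
#' @param scenario a [demographic_scenario].
#' @param seed optional integer seed; identical seeds give identical trees.
#' @param tip_labels optional character vector of tip labels.
#' @return An `ape::phylo` object; attribute `coal_times` holds the n-1
#'   coalescence times (generations before present, increasing).
#' @export
simulate_genealogy <- function(n, scenario, seed = NULL, tip_labels = NULL) {
  if (n < 2) abort("n must be >= 2.", class = "comdemog_domain_error")
  if (!is.null(seed)) set.seed(seed)
  t_change <- scenario$t_change_years * scenario$generations_per_year
  n0 <- scenario$ne_present
  n1 <- scenario$ne_present * scenario$ratio_ancestral

  times <- numeric(n - 1L)
  t_now <- 0
  for (i in seq_len(n - 1L)) {
    k <- n - i + 1L
    rate_pair <- k * (k - 1) / 2
    # piecewise-constant hazard: spend exp(1) total hazard across the epochs
    e <- rexp(1L)
    if (t_now < t_change) {
      budget <- (t_change - t_now) * rate_pair / n0
      if (e <= budget) {
        t_now <- t_now + e * n0 / rate_pair
      } else {
        t_now <- t_change + (e - budget) * n1 / rate_pair
      }
    } else {
      t_now <- t_now + e * n1 / rate_pair
    }
    times[i] <- t_now
  }
  build_coalescent_tree(n, times, tip_labels = tip_labels)
}

#' Simulate a genealogy under exponential growth (mutational time units)
#'
#' Coalescent with `Theta(u) = theta_present * exp(-g * u)`, `u` measured in
#' mutational units (expected substitutions per site) increasing into the
#' past: the hazard while `k` lineages remain is `k (k - 1) exp(g u) / Theta`.
#' With `g = 0` this is exactly the constant-Theta coalescent. Branch lengths
#' of the returned tree are in mutational units.
#'
#' @param n number of tips (>= 2).
#' @param theta_present present-day diversity parameter (> 0).
#' @param g growth rate per inverse mutational unit (any sign).
#' @param seed optional integer seed.
#' @return An `ape::phylo`; attribute `coal_times` as in
#'   [simulate_genealogy()], attribute `units = "mutational"`.
#' @export
simulate_growth_genealogy <- function(n, theta_present, g = 0, seed = NULL) {
  if (n < 2) abort("n must be >= 2.", class = "comdemog_domain_error")
  if (theta_present <= 0) {
    abort("theta_present must be > 0.", class = "comdemog_domain_error")
  }
  if (!is.null(seed)) set.seed(seed)
  times <- numeric(n - 1L)
  u <- 0
  for (i in seq_len(n - 1L)) {
    k <- n - i + 1L
    a <- k * (k - 1) / theta_present
    e <- rexp(1L)
    if (abs(g) < 1e-12) {
      u <- u + e / a
    } else {
      # solve int_u^t a exp(g s) ds = e  =>  t = log(exp(g u) + g e / a) / g
      arg <- exp(g * u) + g * e / a
      if (arg <= 0) {
        # g < 0 (shrinking into the past): hazard integral bounded; cannot
        # happen for g < 0 since rates grow, only for pathological underflow
        u <- Inf
      } else {
        u <- log(arg) / g
      }
    }
    times[i] <- u
  }
  tr <- build_coalescent_tree(n, times)
  attr(tr, "units") <- "mutational"
  tr
}

# Assemble an ultrametric phylo from ordered coalescence times by random
# pairwise joins (exchangeable Kingman topology).
build_coalescent_tree <- function(n, times, tip_labels = NULL) {
  tip_labels <- tip_labels %||% paste0("t", seq_len(n))
  n_nodes <- 2L * n - 1L
  # active lineages: node id and the age of the node
  active_id <- seq_len(n)
  active_age <- numeric(n)
  edge <- matrix(0L, nrow = 2L * n - 2L, ncol = 2L)
  edge_len <- numeric(2L * n - 2L)
  e <- 0L
  internal_ids <- seq(from = n + 1L, length.out = n - 1L)
  # ape convention: root is n+1. Oldest (last) coalescence is the root, so
  # assign internal ids in reverse event order.
  ids_for_event <- rev(internal_ids)
  for (i in seq_len(n - 1L)) {
    k <- length(active_id)
    pick <- sample.int(k, 2L)
    parent <- ids_for_event[i]
    for (child_idx in pick) {
      e <- e + 1L
      edge[e, ] <- c(parent, active_id[child_idx])
      edge_len[e] <- times[i] - active_age[child_idx]
    }
    active_id <- c(active_id[-pick], parent)
    active_age <- c(active_age[-pick], times[i])
  }
  tr <- structure(
    list(edge = edge, edge.length = edge_len, tip.label = tip_labels,
         Nnode = n - 1L),
    class = "phylo", order = "unknown"
  )
  tr <- ape::reorder.phylo(tr, "cladewise")
  attr(tr, "coal_times") <- times
  tr
}

#' Coalescence times of a genealogy
#'
#' Node ages (tips at 0, increasing root-ward) of an ultrametric tree, sorted
#' ascending. Uses the cached attribute when the tree came from one of the
#' package's simulators.
#'
#' @param tree a `phylo`.
#' @param tol relative tolerance for the ultrametricity check.
#' @return Numeric vector of n-1 coalescence times.
#' @export
coalescence_times <- function(tree, tol = 1e-6) {
  ct <- attr(tree, "coal_times")
  if (!is.null(ct)) return(sort(ct))
  if (!ape::is.ultrametric(tree, tol = tol)) {
    abort("Tree is not ultrametric.", class = "comdemog_domain_error")
  }
  sort(unname(ape::branching.times(tree)))
}
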