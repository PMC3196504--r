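# Hierarchical haplotypic AMOVA (regions / populations-within-regions /
# within-populations) from pairwise nucleotide difference counts, with
# unequal-sample-size coefficients and permutation tests per statistic.

# sums of squared deviations from a squared-distance matrix for a grouping:
# SSD(group) = sum_{i<j in group} d2_ij / n_group
ssd_groups <- function(d2, groups) {
  tot <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    if (length(idx) > 1L) {
      sub <- d2[idx, idx]
      tot <- tot + sum(sub[upper.tri(sub)]) / length(idx)
    }
  }
  tot
}

amova_components <- function(d2, pops, regions_of_pop) {
  n <- nrow(d2)
  pop_levels <- unique(pops)
  p_count <- length(pop_levels)
  reg_of_sample <- regions_of_pop[pops]
  reg_levels <- unique(regions_of_pop)
  g_count <- length(reg_levels)

  ssd_total <- ssd_groups(d2, rep("all", n))
  ssd_wp <- ssd_groups(d2, pops)              # within populations
  ssd_wr <- ssd_groups(d2, reg_of_sample)     # within regions
  ssd_ap <- ssd_wr - ssd_wp                   # among pops within regions
  ssd_ar <- ssd_total - ssd_wr                # among regions

  df_ar <- g_count - 1L
  df_ap <- p_count - g_count
  df_wp <- n - p_count

  n_p <- table(pops)[pop_levels]
  n_g <- tapply(pops, reg_of_sample, length)[reg_levels]
  sum_np2_by_region <- vapply(reg_levels, function(r) {
    pr <- pop_levels[regions_of_pop[pop_levels] == r]
    sum(as.numeric(n_p[pr])^2) / sum(n_p[pr])
  }, numeric(1L))
  # Excoffier's unequal-size coefficients
  n1 <- (n - sum(sum_np2_by_region)) / df_ap
  n2 <- (sum(sum_np2_by_region) - sum(as.numeric(n_p)^2) / n) / df_ar
  n3 <- (n - sum(as.numeric(n_g)^2) / n) / df_ar

  sigma_c <- if (df_wp > 0) ssd_wp / df_wp else 0
  sigma_b <- if (df_ap > 0) (ssd_ap / df_ap - sigma_c) / n1 else 0
  sigma_a <- if (df_ar > 0) (ssd_ar / df_ar - sigma_c - n2 * sigma_b) / n3 else 0
  total <- sigma_a + sigma_b + sigma_c

  list(
    df = c(df_ar, df_ap, df_wp),
    ssd = c(ssd_ar, ssd_ap, ssd_wp),
    sigma = c(sigma_a, sigma_b, sigma_c),
    total = total,
    phi_ct = if (total != 0) sigma_a / total else NA_real_,
    phi_sc = if ((sigma_b + sigma_c) != 0) sigma_b / (sigma_b + sigma_c)
             else NA_real_,
    phi_st = if (total != 0) (sigma_a + sigma_b) / total else NA_real_
  )
}

#' Hierarchical analysis of molecular variance (AMOVA)
#'
#' Apportions haplotypic variance among regions, among populations within
#' regions, and within populations, following the Excoffier nested
#' variance-component decomposition on squared inter-haplotype distances
#' (here: raw pairwise nucleotide difference counts, the standard haplotypic
#' format). Phi statistics and their permutation p-values use the
#' statistic-specific permutation schemes: haplotypes among all populations
#' for Phi_ST, haplotypes among populations within their region for Phi_SC,
#' and whole populations among regions for Phi_CT. p-values are reported as
#' `(extreme + 1) / (n_perms + 1)`.
#'
#' Negative variance components can arise (and are retained, not truncated);
#' a design with every region containing a single population leaves Phi_CT
#' degenerate, which is flagged by `NA`.
#'
#' @param aln a [hap_alignment]; populations and regions default to its
#'   metadata.
#' @param pops,regions optional overrides: `pops` a character vector per
#'   sequence, `regions` a named vector mapping population -> region.
#' @param n_perms permutations per statistic (0 to skip tests).
#' @param seed integer seed for the permutations.
#' @return An `amova_result`: `table` (tibble with df, sum of squares,
#'   variance component, percent variation per level), `phi` (tibble with
#'   statistic, value, p_value), `n_permutations`, `seed`.
#' @export
amova <- function(aln, pops = NULL, regions = NULL, n_perms = 1000L,
                  seed = 1L) {
  pops <- pops %||% aln$meta$population
  if (is.null(regions)) {
    map <- dplyr::distinct(aln$meta, .data$population, .data$region)
    regions <- setNames(map$region, map$population)
  }
  if (length(unique(pops)) < 2L) {
    abort("AMOVA needs >= 2 populations.", class = "comdemog_domain_error")
  }
  d2 <- pairwise_diff_matrix(aln)
  res <- amova_components(d2, pops, regions)

  if (all(d2 == 0)) {
    warn("All haplotypes identical: variance components are all zero.")
  }
  pops_per_region <- table(regions[unique(pops)])
  if (all(pops_per_region == 1L)) {
    warn("Every region holds a single population; Phi_CT is degenerate.")
  }

  obs <- c(ct = res$phi_ct, sc = res$phi_sc, st = res$phi_st)
  pvals <- c(ct = NA_real_, sc = NA_real_, st = NA_real_)
  if (n_perms > 0L) {
    set.seed(seed)
    n <- nrow(d2)
    cnt <- c(ct = 0L, sc = 0L, st = 0L)
    reg_of_sample <- regions[pops]
    pop_levels <- unique(pops)
    for (b in seq_len(n_perms)) {
      # Phi_ST: permute haplotypes among all populations
      p_st <- sample(pops)
      r_st <- amova_components(d2, p_st, regions)
      if (!is.na(obs["st"]) && !is.na(r_st$phi_st) &&
          r_st$phi_st >= obs["st"]) cnt["st"] <- cnt["st"] + 1L
      # Phi_SC: permute haplotypes among populations within each region
      p_sc <- pops
      for (r in unique(reg_of_sample)) {
        idx <- which(reg_of_sample == r)
        p_sc[idx] <- sample(pops[idx])
      }
      r_sc <- amova_components(d2, p_sc, regions)
      if (!is.na(obs["sc"]) && !is.na(r_sc$phi_sc) &&
          r_sc$phi_sc >= obs["sc"]) cnt["sc"] <- cnt["sc"] + 1L
      # Phi_CT: permute whole populations among regions
      perm_regions <- setNames(sample(regions[pop_levels]), pop_levels)
      r_ct <- amova_components(d2, pops, perm_regions)
      if (!is.na(obs["ct"]) && !is.na(r_ct$phi_ct) &&
          r_ct$phi_ct >= obs["ct"]) cnt["ct"] <- cnt["ct"] + 1L
    }
    pvals <- (cnt + 1L) / (n_perms + 1L)
    pvals[is.na(obs)] <- NA_real_
  }

  pct <- if (res$total != 0) 100 * res$sigma / res$total else rep(NA_real_, 3L)
  tab <- tibble(
    source = c("Among regions", "Among populations within regions",
               "Within populations"),
    df = res$df, sum_sq = res$ssd, variance = res$sigma, percent = pct)
  phi <- tibble(
    statistic = c("Phi_CT", "Phi_SC", "Phi_ST"),
    value = unname(obs), p_value = unname(pvals))
  structure(list(table = tab, phi = phi, n_permutations = n_perms,
                 seed = seed),
            class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  cat("<amova_result>\n")
  print(x$table)
  print(x$phi)
  invisible(x)
}

#' @export
tidy.amova_result <- function(x, ...) x$table

#' @export
glance.amova_result <- function(x, ...) {
  tibble(phi_ct = x$phi$value[1], phi_sc = x$phi$value[2],
         phi_st = x$phi$value[3],
         p_ct = x$phi$p_value[1], p_sc = x$phi$p_value[2],
         p_st = x$phi$p_value[3],
         n_permutations = x$n_permutations)
}

#' Pairwise Phi_ST matrix
#'
#' Phi_ST for every pair of populations from a two-population AMOVA on
#' pairwise nucleotide differences. Slightly negative values are retained.
#' Populations with a single sequence are dropped with a warning.
#'
#' @param aln a [hap_alignment].
#' @param pops optional population vector (defaults to metadata).
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
pairwise_fst <- function(aln, pops = NULL) {
  pops <- pops %||% aln$meta$population
  sizes <- table(pops)
  keep <- names(sizes)[sizes >= 2L]
  if (length(keep) < length(sizes)) {
    warn(paste0("Excluding populations with n < 2: ",
                paste(setdiff(names(sizes), keep), collapse = ", ")))
  }
  if (length(keep) < 2L) {
    abort("Need >= 2 populations with n >= 2.",
          class = "comdemog_domain_error")
  }
  d2 <- pairwise_diff_matrix(aln)
  out <- matrix(0, length(keep), length(keep), dimnames = list(keep, keep))
  for (i in seq_along(keep)[-length(keep)]) {
    for (j in (i + 1L):length(keep)) {
      idx <- which(pops %in% keep[c(i, j)])
      sub_pops <- pops[idx]
      regions <- setNames(rep("all", 2L), keep[c(i, j)])
      res <- amova_components(d2[idx, idx], sub_pops, regions)
      # two populations, one region: Phi_ST = sigma_b / (sigma_b + sigma_c)
      out[i, j] <- out[j, i] <- res$phi_sc
    }
  }
  out
}

#' Mean pairwise Phi_ST ("global F_ST" by averaging)
#'
#' @param aln a [hap_alignment].
#' @param pops optional population vector.
#' @param method `"amova"` (hierarchical Phi_ST, the default used by
#'   [structure_gate()]) or `"mean_pairwise"`.
#' @return Scalar global F_ST.
#' @export
global_fst <- function(aln, pops = NULL, method = c("amova", "mean_pairwise")) {
  method <- match.arg(method)
  if (method == "mean_pairwise") {
    m <- pairwise_fst(aln, pops)
    return(mean(m[upper.tri(m)]))
  }
  res <- suppressWarnings(amova(aln, pops = pops, n_perms = 0L))
  res$phi$value[3]
}
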