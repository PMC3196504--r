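#' Pairwise nucleotide differences
#'
#' Number of differing sites for every pair of sequences, counting only sites
#' where both sequences have an unambiguous base (gaps and `N` are skipped per
#' site pair, i.e. pairwise-complete).
#'
#' @param aln a [hap_alignment].
#' @return Symmetric integer matrix of difference counts.
#' @export
pairwise_diff_matrix <- function(aln) {
  m <- aln$seq
  n <- nrow(m)
  valid <- m %in% NUC
  dim(valid) <- dim(m)
  # differences = pairwise-complete sites - matches; both via crossproducts
  vnum <- matrix(as.numeric(valid), n)
  complete <- tcrossprod(vnum)
  matches <- matrix(0, n, n)
  for (b in NUC) {
    ind <- matrix(as.numeric(m == b), n)
    matches <- matches + tcrossprod(ind)
  }
  d <- complete - matches
  diag(d) <- 0
  dimnames(d) <- list(rownames(m), rownames(m))
  round(d)
}

# sites with >= 2 observed states among A/C/G/T
count_segregating <- function(m) {
  present <- vapply(NUC, function(b) colSums(m == b) > 0L,
                    logical(ncol(m)))
  if (is.null(dim(present))) present <- matrix(present, nrow = 1L)
  sum(rowSums(present) >= 2L)
}

#' Per-locus summary statistics
#'
#' Computes the standard per-locus diversity summaries: segregating sites S,
#' number of distinct haplotypes, mean pairwise differences pi (per locus,
#' over all C(n,2) pairs), Watterson's theta (per locus), Fu's Fs and
#' Tajima's D. The latter two are `NA` (undefined) for monomorphic data.
#' Haplotypes are counted on the full sequence string including gaps and `N`.
#'
#' @param aln a [hap_alignment].
#' @return A one-row tibble with columns `locus`, `n`, `S`, `k_hap`, `pi`,
#'   `theta_w`, `fs`, `tajima_d`.
#' @export
#' @examples
#' aln <- hap_alignment(c(a = "AAA", b = "AAT", c = "ATT"),
#'                      meta = toy_meta(c("a", "b", "c")))
#' summary_stats(aln)
summary_stats <- function(aln) {
  n <- n_seq(aln)
  if (n < 2L) abort("Need >= 2 sequences.", class = "comdemog_domain_error")
  s <- count_segregating(aln$seq)
  d <- pairwise_diff_matrix(aln)
  pi <- mean(d[upper.tri(d)])
  k_hap <- length(unique(aln_strings(aln)))
  a1 <- sum(1 / seq_len(n - 1L))
  fs <- if (s == 0L) NA_real_ else fu_fs(aln)
  td <- if (s == 0L) NA_real_ else tajimas_d(aln)
  tibble(locus = aln$locus_name, n = n, S = s, k_hap = k_hap, pi = pi,
         theta_w = s / a1, fs = fs, tajima_d = td)
}

# log unsigned Stirling numbers of the first kind |s(n, k)|, k = 1..n,
# computed by the recurrence |s(n+1,k)| = n |s(n,k)| + |s(n,k-1)| in log space
log_stirling_first <- local({
  cache <- new.env(parent = emptyenv())
  function(n) {
    key <- as.character(n)
    if (!is.null(cache[[key]])) return(cache[[key]])
    row <- c(0, rep(-Inf, n - 1L))  # n = 1: |s(1,1)| = 1
    if (n > 1L) {
      for (m in seq_len(n - 1L)) {
        # build row for m+1 from row for m
        prev <- row
        row <- numeric(n)
        for (k in seq_len(m + 1L)) {
          a <- if (k <= m) log(m) + prev[k] else -Inf
          b <- if (k >= 2L) prev[k - 1L] else -Inf
          row[k] <- logsumexp2(a, b)
        }
        if (m + 1L < n) row <- c(row[seq_len(m + 1L)], rep(-Inf, n - m - 1L))
      }
    }
    cache[[key]] <- row
    row
  }
})

logsumexp2 <- function(a, b) {
  if (a == -Inf) return(b)
  if (b == -Inf) return(a)
  m <- max(a, b)
  m + log1p(exp(min(a, b) - m))
}

#' Ewens sampling distribution of the number of alleles
#'
#' Probability mass function of the number of distinct alleles K in a sample
#' of size n under the Ewens sampling formula at parameter theta:
#' `P(K = k) = |s(n, k)| theta^k / (theta (theta + 1) ... (theta + n - 1))`,
#' with unsigned Stirling numbers of the first kind, computed in log space so
#' large n stay exact to double precision.
#'
#' @param n sample size.
#' @param theta scaled mutation parameter (> 0).
#' @return Numeric vector of probabilities for k = 1..n.
#' @export
ewens_k_distribution <- function(n, theta) {
  if (theta <= 0) abort("theta must be > 0.", class = "comdemog_domain_error")
  lst <- log_stirling_first(n)
  k <- seq_len(n)
  log_denom <- sum(log(theta + 0:(n - 1L)))
  exp(lst + k * log(theta) - log_denom)
}

#' Fu's Fs
#'
#' The expansion-sensitive neutrality statistic built on the Ewens sampling
#' distribution: with theta estimated by pi (mean pairwise differences) the
#' tail probability `S' = P(K >= k_obs | theta, n)` of seeing at least the
#' observed number of haplotypes is converted to `Fs = ln(S' / (1 - S'))`.
#' Strongly negative values indicate an excess of haplotypes, the signature
#' of recent population expansion. Computed in log space; when `S'`
#' underflows (or reaches 1 numerically) a signed infinity is returned with a
#' warning rather than an error.
#'
#' @param aln a [hap_alignment], or `NULL` if `n`, `k_hap`, `theta` are given
#'   directly.
#' @param n,k_hap,theta sample size, observed haplotype count and diversity
#'   parameter, for direct evaluation without an alignment.
#' @return Fu's Fs (scalar).
#' @export
fu_fs <- function(aln = NULL, n = NULL, k_hap = NULL, theta = NULL) {
  if (!is.null(aln)) {
    n <- n_seq(aln)
    d <- pairwise_diff_matrix(aln)
    theta <- mean(d[upper.tri(d)])
    k_hap <- length(unique(aln_strings(aln)))
    s <- count_segregating(aln$seq)
    if (s == 0L) {
      abort("Fs is undefined for monomorphic data (S = 0).",
            class = "comdemog_undefined_statistic")
    }
  }
  if (k_hap == 1L || theta <= 0) {
    # K >= 1 always: S' = 1
    warn("Fs tail probability saturated at 1; returning +Inf.")
    return(Inf)
  }
  lst <- log_stirling_first(n)
  k <- seq_len(n)
  log_denom <- sum(log(theta + 0:(n - 1L)))
  logp <- lst + k * log(theta) - log_denom
  log_sp <- logsumexp(logp[k >= k_hap])
  log_sp <- min(log_sp, 0)
  if (log_sp < log(1e-300)) {
    warn("Fs tail probability underflowed; returning -Inf.")
    return(-Inf)
  }
  sp <- exp(log_sp)
  if (sp >= 1 - 1e-15) {
    warn("Fs tail probability saturated at 1; returning +Inf.")
    return(Inf)
  }
  # log(S'/(1-S')) computed from log S' for accuracy at tiny S'
  log_sp - log1p(-sp)
}

logsumexp <- function(x) {
  x <- x[x > -Inf]
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Tajima's D
#'
#' Standard Tajima (1989) D: the difference between pi and S/a1 scaled by its
#' estimated standard deviation with the canonical coefficients.
#'
#' @param aln a [hap_alignment].
#' @return Tajima's D (scalar); errors for monomorphic data.
#' @export
tajimas_d <- function(aln) {
  n <- n_seq(aln)
  s <- count_segregating(aln$seq)
  if (s == 0L) {
    abort("Tajima's D is undefined for monomorphic data (S = 0).",
          class = "comdemog_undefined_statistic")
  }
  d <- pairwise_diff_matrix(aln)
  pi <- mean(d[upper.tri(d)])
  i <- seq_len(n - 1L)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pi - s / a1) / sqrt(e1 * s + e2 * s * (s - 1))
}
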