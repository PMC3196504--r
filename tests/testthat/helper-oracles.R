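# Shared fixtures and independent oracles used across test files.

toy_aln <- function(seqs, ids = NULL, pops = "pop1", regions = "region1",
                    lat = 0, lon = 0, ...) {
  if (is.null(ids)) ids <- paste0("s", seq_along(seqs))
  meta <- tibble::tibble(sample_id = ids, population = pops, region = regions,
                         latitude = lat, longitude = lon)
  hap_alignment(stats::setNames(seqs, ids), meta = meta, ...)
}

random_aln <- function(n, n_sites, n_states = 4L) {
  m <- matrix(sample(c("A", "C", "G", "T")[seq_len(n_states)],
                     n * n_sites, replace = TRUE), nrow = n)
  rownames(m) <- paste0("s", seq_len(n))
  hap_alignment(m, meta = toy_meta(rownames(m)))
}

# Exact unsigned Stirling numbers of the first kind via polynomial expansion
# of the rising factorial x(x+1)...(x+n-1); exact in doubles for n <= 18.
stirling_first_exact <- function(n) {
  coef <- c(0, 1)  # x
  if (n > 1L) {
    for (m in seq_len(n - 1L)) {
      # multiply polynomial by (x + m)
      coef <- c(0, coef) + m * c(coef, 0)
    }
  }
  coef[2:(n + 1L)]  # |s(n, k)| for k = 1..n
}

# brute-force Ewens tail probability and Fs
fs_oracle <- function(n, k_obs, theta) {
  st <- stirling_first_exact(n)
  p <- st * theta^(seq_len(n)) / prod(theta + 0:(n - 1L))
  sp <- sum(p[k_obs:n])
  log(sp / (1 - sp))
}

# independent AMOVA sums of squares from first principles (deviation form):
# SSD(group) = sum over pairs within group of d2 / n_group
ssd_oracle <- function(d2, groups) {
  tot <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    for (i in idx) for (j in idx) tot <- tot + d2[i, j] / (2 * length(idx))
  }
  tot
}

# two-population Phi_ST from explicit variance components (independent path)
fst_two_pop_oracle <- function(d2, pops) {
  n <- nrow(d2)
  lv <- unique(pops)
  ssd_total <- ssd_oracle(d2, rep("all", n))
  ssd_w <- ssd_oracle(d2, pops)
  ssd_a <- ssd_total - ssd_w
  df_w <- n - 2L
  nsz <- table(pops)[lv]
  nc <- (n - sum(as.numeric(nsz)^2) / n) / 1
  sig_w <- ssd_w / df_w
  sig_a <- (ssd_a / 1 - sig_w) / nc
  sig_a / (sig_a + sig_w)
}

# trapezoidal ROC integration oracle
auc_trapezoid_oracle <- function(pres, back) {
  thr <- sort(unique(c(pres, back, -Inf, Inf)), decreasing = TRUE)
  sens <- vapply(thr, function(t) mean(pres >= t), numeric(1L))
  fpr <- vapply(thr, function(t) mean(back >= t), numeric(1L))
  sum(diff(fpr) * (head(sens, -1L) + tail(sens, -1L)) / 2)
}

# two-tailed Fisher p by exhaustive hypergeometric enumeration
fisher_oracle <- function(tab) {
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  p_obs <- dhyper(tab[1, 1], rs[1], rs[2], cs[1])
  xs <- max(0, cs[1] - rs[2]):min(rs[1], cs[1])
  ps <- dhyper(xs, rs[1], rs[2], cs[1])
  sum(ps[ps <= p_obs * (1 + 1e-7)])
}

# series-expansion matrix exponential
expm_series <- function(q, t, terms = 60L) {
  out <- diag(4)
  term <- diag(4)
  for (k in seq_len(terms)) {
    term <- term %*% (q * t) / k
    out <- out + term
  }
  out
}

quiet_fs <- function(...) suppressWarnings(fu_fs(...))
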