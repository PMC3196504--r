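#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6371.0 km.
#'
#' @param lat1,lon1,lat2,lon2 coordinates in decimal degrees (vectorised).
#' @return Distance in kilometres.
#' @export
#' @examples
#' great_circle_km(0, 0, 0, 90) # quarter circumference, ~10007.5 km
great_circle_km <- function(lat1, lon1, lat2, lon2) {
  if (any(abs(c(lat1, lat2)) > 90) || any(abs(c(lon1, lon2)) > 180)) {
    abort("Coordinates out of range.", class = "comdemog_domain_error")
  }
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = 6371000) / 1000
}

#' Great-circle distance matrix between populations
#'
#' One row/column per population; a population's coordinates are the mean of
#' its samples' coordinates.
#'
#' @param meta a sample metadata tibble (see [validate_sample_meta()]).
#' @return Symmetric matrix of distances in km.
#' @export
population_distances <- function(meta) {
  cen <- meta |>
    group_by(.data$population) |>
    summarise(latitude = mean(.data$latitude),
              longitude = mean(.data$longitude), .groups = "drop")
  p <- nrow(cen)
  out <- matrix(0, p, p, dimnames = list(cen$population, cen$population))
  for (i in seq_len(p - 1L)) {
    for (j in (i + 1L):p) {
      out[i, j] <- out[j, i] <- great_circle_km(
        cen$latitude[i], cen$longitude[i], cen$latitude[j], cen$longitude[j])
    }
  }
  out
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation over the off-diagonal entries with a one-tailed
#' permutation test: rows/columns of one matrix are co-permuted and the
#' p-value is `(number of permutations with r >= observed + 1) /
#' (n_perms + 1)` (ties count as extreme). Backed by `vegan::mantel()`, which
#' implements exactly this convention.
#'
#' @param dist_a,dist_b square symmetric matrices (or `dist` objects) of
#'   equal dimension >= 3.
#' @param n_perms number of permutations.
#' @param seed integer seed.
#' @return A tibble with `r`, `r_squared`, `p`.
#' @export
mantel_test <- function(dist_a, dist_b, n_perms = 1000L, seed = 1L) {
  a <- as.matrix(dist_a)
  b <- as.matrix(dist_b)
  if (!isTRUE(all.equal(dim(a), dim(b))) || nrow(a) < 3L) {
    abort("Matrices must be square, equal dimension >= 3.",
          class = "comdemog_domain_error")
  }
  if (sd(a[lower.tri(a)]) == 0 || sd(b[lower.tri(b)]) == 0) {
    warn("Zero-variance distance matrix: Mantel r undefined.")
    return(tibble(r = NA_real_, r_squared = NA_real_, p = NA_real_))
  }
  set.seed(seed)
  m <- vegan::mantel(stats::as.dist(a), stats::as.dist(b),
                     method = "pearson", permutations = n_perms)
  tibble(r = unname(m$statistic), r_squared = unname(m$statistic)^2,
         p = unname(m$signif))
}

#' Isolation-by-distance test for an alignment
#'
#' Mantel test of pairwise Phi_ST against great-circle distances between
#' population centroids.
#'
#' @param aln a [hap_alignment] with >= 3 populations of size >= 2.
#' @param n_perms,seed see [mantel_test()].
#' @return A tibble with `r`, `r_squared`, `p`, `n_populations`.
#' @export
ibd_mantel <- function(aln, n_perms = 1000L, seed = 1L) {
  fst <- pairwise_fst(aln)
  geo <- population_distances(aln$meta)
  keep <- rownames(fst)
  geo <- geo[keep, keep]
  res <- mantel_test(geo, fst, n_perms = n_perms, seed = seed)
  res$n_populations <- length(keep)
  res
}

#' Structure gating rule
#'
#' A dataset is treated as showing significant geographic population
#' structure (and so is eligible for phylogeographic reconstruction) if and
#' only if its global F_ST exceeds 0.2 (large divergence) and the Mantel test
#' of F_ST against geographic distance is significant at 0.05.
#'
#' @param global_fst global F_ST (AMOVA Phi_ST by default upstream).
#' @param mantel_p Mantel test p-value.
#' @param fst_threshold,alpha the two cutoffs.
#' @return Logical.
#' @export
#' @examples
#' structure_gate(0.871, 0.0009) # TRUE (the plant's cpDNA pattern)
#' structure_gate(0.12, 0.01)    # FALSE (typical moth pattern)
structure_gate <- function(global_fst, mantel_p, fst_threshold = 0.2,
                           alpha = 0.05) {
  isTRUE(global_fst > fst_threshold) && isTRUE(mantel_p < alpha)
}

#' McDonald-Kreitman test
#'
#' Contrasts synonymous and nonsynonymous changes that are polymorphic within
#' the ingroup against those fixed between the ingroup and an outgroup
#' sequence, in a 2x2 table tested by Fisher's exact test (two-tailed).
#' A variable codon is polymorphic if the ingroup holds more than one codon
#' state; a codon is a fixed difference if the ingroup is invariant and
#' differs from the outgroup. Codons whose states differ at more than one
#' position, or that are both polymorphic and fixed-different, are excluded
#' (counted in `n_excluded`). Sequences must be in frame with no internal
#' stop codons.
#'
#' @param aln ingroup [hap_alignment] of protein-coding sequence (length
#'   divisible by 3, frame 1).
#' @param outgroup a single outgroup sequence string of the same length.
#' @return An `mk_result`: `table` (2x2 matrix: rows fixed/polymorphic,
#'   columns nonsynonymous/synonymous), `odds_ratio`, `p_value`,
#'   `n_excluded`.
#' @export
mk_test <- function(aln, outgroup) {
  len <- n_sites(aln)
  if (len %% 3L != 0L) {
    abort("Alignment length must be divisible by 3.",
          class = "comdemog_data_error")
  }
  outgroup <- toupper(outgroup)
  if (nchar(outgroup) != len) {
    abort("Outgroup length must match the alignment.",
          class = "comdemog_data_error")
  }
  out_codons <- substring(outgroup, seq(1L, len, 3L), seq(3L, len, 3L))
  seq_strings <- aln_strings(aln)
  in_codons <- vapply(seq_strings, function(s) {
    substring(s, seq(1L, len, 3L), seq(3L, len, 3L))
  }, character(len / 3L))
  if (is.null(dim(in_codons))) in_codons <- matrix(in_codons, nrow = 1L)

  stops <- c("TAA", "TAG", "TGA")
  if (any(in_codons %in% stops) || any(out_codons %in% stops)) {
    abort("Internal stop codon found; check the reading frame.",
          class = "comdemog_data_error")
  }

  counts <- matrix(0L, 2L, 2L,
                   dimnames = list(c("fixed", "polymorphic"),
                                   c("nonsynonymous", "synonymous")))
  n_excluded <- 0L
  for (cdn in seq_len(nrow(in_codons))) {
    states <- unique(in_codons[cdn, ])
    states <- states[!grepl("[^ACGT]", states)]
    if (length(states) == 0L) next
    poly <- length(states) > 1L
    fixed_diff <- !poly && states[1L] != out_codons[cdn] &&
      !grepl("[^ACGT]", out_codons[cdn])
    if (!poly && !fixed_diff) next
    if (poly && any(states != out_codons[cdn]) &&
        !(out_codons[cdn] %in% states)) {
      # both polymorphic within and (all states) different from outgroup:
      # ambiguous, excluded
      n_excluded <- n_excluded + 1L
      next
    }
    pairs <- if (poly) combn(states, 2L, simplify = FALSE) else
      list(c(states[1L], out_codons[cdn]))
    cls <- vapply(pairs, classify_codon_pair, character(1L))
    if (any(cls == "multi")) {
      n_excluded <- n_excluded + 1L
      next
    }
    row <- if (poly) "polymorphic" else "fixed"
    for (cl in cls) counts[row, cl] <- counts[row, cl] + 1L
  }

  if (sum(counts["polymorphic", ]) == 0L || sum(counts["fixed", ]) == 0L) {
    warn("A row of the MK table is empty; p-value undefined.")
    return(structure(list(table = counts, odds_ratio = NA_real_,
                          p_value = NA_real_, n_excluded = n_excluded),
                     class = "mk_result"))
  }
  ft <- fisher.test(counts)
  structure(list(table = counts, odds_ratio = unname(ft$estimate),
                 p_value = ft$p.value, n_excluded = n_excluded),
            class = "mk_result")
}

# single-step codon pair -> "synonymous" / "nonsynonymous" / "multi"
classify_codon_pair <- function(pair) {
  a <- strsplit(pair[1L], "")[[1L]]
  b <- strsplit(pair[2L], "")[[1L]]
  ndiff <- sum(a != b)
  if (ndiff == 0L) return("synonymous")
  if (ndiff > 1L) return("multi")
  if (translate_codon(pair[1L]) == translate_codon(pair[2L])) "synonymous"
  else "nonsynonymous"
}

translate_codon <- function(codon) {
  # direct table lookup; translate() would apply initiator-codon rules to a
  # lone codon (CTG -> M)
  unname(Biostrings::GENETIC_CODE[codon])
}

#' @export
print.mk_result <- function(x, ...) {
  cat("<mk_result>\n")
  print(x$table)
  cat(sprintf("odds ratio = %.4g, p = %.4g (%d codons excluded)\n",
              x$odds_ratio, x$p_value, x$n_excluded))
  invisible(x)
}

#' @export
tidy.mk_result <- function(x, ...) {
  as_tibble(as.data.frame(as.table(x$table))) |>
    setNames(c("class", "type", "count"))
}

#' @export
glance.mk_result <- function(x, ...) {
  tibble(odds_ratio = x$odds_ratio, p_value = x$p_value,
         n_excluded = x$n_excluded)
}
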