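#' Rank-based AUC
#'
#' Area under the ROC curve computed as the Mann-Whitney probability that a
#' random presence scores above a random background point, with ties counted
#' one half.
#'
#' @param presence_scores,background_scores numeric score vectors.
#' @return AUC in `[0, 1]`.
#' @export
#' @examples
#' roc_auc(c(0.9, 0.8), c(0.1, 0.2)) # 1
roc_auc <- function(presence_scores, background_scores) {
  np <- length(presence_scores)
  nb <- length(background_scores)
  if (np == 0L || nb == 0L) {
    abort("Both score vectors must be non-empty.",
          class = "comdemog_domain_error")
  }
  r <- rank(c(presence_scores, background_scores), ties.method = "average")
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nb)
}

#' Threshold selection on a suitability surface
#'
#' Chooses a presence/absence threshold for continuous suitability scores by
#' one of the two recommended data-driven criteria: the threshold where
#' sensitivity and specificity are (closest to) equal, or the threshold
#' maximising their sum. Candidate thresholds are the midpoints between
#' adjacent sorted unique scores plus values below and above all scores;
#' prediction is presence iff `score > threshold` (strict). Ties between
#' candidates go to the lower threshold.
#'
#' @param scores numeric suitability scores.
#' @param labels 0/1 (or logical) truth labels, 1 = presence.
#' @param criterion `"equal_sens_spec"` or `"max_sens_plus_spec"`.
#' @return A one-row `threshold_report` tibble: `criterion`, `threshold`,
#'   `sensitivity`, `specificity`, `kappa`, `n_predicted_presence`.
#' @export
find_threshold <- function(scores, labels,
                           criterion = c("equal_sens_spec",
                                         "max_sens_plus_spec")) {
  criterion <- match.arg(criterion)
  labels <- as.integer(as.logical(labels))
  if (length(unique(labels)) < 2L) {
    abort("Both classes must be present in labels.",
          class = "comdemog_domain_error")
  }
  u <- sort(unique(scores))
  cand <- c(u[1L] - 1, (head(u, -1L) + tail(u, -1L)) / 2, u[length(u)] + 1)
  metrics <- purrr::map(cand, function(thr) {
    pred <- as.integer(scores > thr)
    tp <- sum(pred == 1L & labels == 1L)
    fn <- sum(pred == 0L & labels == 1L)
    tn <- sum(pred == 0L & labels == 0L)
    fp <- sum(pred == 1L & labels == 0L)
    tibble(threshold = thr, sensitivity = tp / (tp + fn),
           specificity = tn / (tn + fp),
           kappa = cohens_kappa(tp, fp, fn, tn))
  }) |> bind_rows()
  pick <- switch(criterion,
    equal_sens_spec =
      which.min(abs(metrics$sensitivity - metrics$specificity)),
    max_sens_plus_spec =
      which.max(metrics$sensitivity + metrics$specificity))
  # which.min/which.max already take the first (lowest-threshold) tie
  row <- metrics[pick, ]
  row$criterion <- criterion
  row$n_predicted_presence <- sum(scores > row$threshold)
  class(row) <- c("threshold_report", class(row))
  row[, c("criterion", "threshold", "sensitivity", "specificity", "kappa",
          "n_predicted_presence")]
}

#' Cohen's kappa from a 2x2 confusion matrix
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` with the standard
#' marginal-product expected agreement.
#'
#' @param tp,fp,fn,tn confusion counts (non-negative, total > 0).
#' @return Kappa in `[-1, 1]`, `NA` when the marginals are degenerate
#'   (`p_e = 1`).
#' @export
#' @examples
#' cohens_kappa(40, 10, 10, 40) # 0.6
cohens_kappa <- function(tp, fp, fn, tn) {
  if (any(c(tp, fp, fn, tn) < 0)) {
    abort("Counts must be non-negative.", class = "comdemog_domain_error")
  }
  n <- tp + fp + fn + tn
  if (n == 0) abort("Total count must be > 0.", class = "comdemog_domain_error")
  po <- (tp + tn) / n
  pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  if (abs(1 - pe) < 1e-15) {
    warn("Degenerate marginals (p_e = 1); kappa undefined.")
    return(NA_real_)
  }
  (po - pe) / (1 - pe)
}

#' Count predicted-presence cells on a surface
#'
#' Number of non-NODATA cells whose value strictly exceeds the threshold —
#' the range-size proxy compared between time slices.
#'
#' @param surface an [ascii_grid] or numeric matrix (NA = NODATA).
#' @param threshold probability threshold.
#' @return Integer count.
#' @export
count_range_cells <- function(surface, threshold) {
  m <- if (inherits(surface, "ascii_grid")) surface$data else surface
  sum(m > threshold, na.rm = TRUE)
}

#' Non-analogue climate mask
#'
#' Flags past grid cells whose climate has no current analogue: for each
#' variable the global minimum and maximum over all non-NODATA current cells
#' define the observed interval, and a past cell is flagged iff at least one
#' of its variables falls outside the closed interval for that variable.
#'
#' @param current_stack,past_stack lists of [ascii_grid]s (or matrices), one
#'   per climate variable, sharing grid geometry and variable order.
#' @return Logical matrix, `TRUE` = non-analogue; cells that are NODATA in
#'   the past stack are `NA`.
#' @export
nonanalog_mask <- function(current_stack, past_stack) {
  cur <- purrr::map(current_stack,
                    \(g) if (inherits(g, "ascii_grid")) g$data else g)
  pas <- purrr::map(past_stack,
                    \(g) if (inherits(g, "ascii_grid")) g$data else g)
  if (length(cur) != length(pas)) {
    abort("Stacks must have the same number of variables.",
          class = "comdemog_domain_error")
  }
  if (!all(vapply(c(cur, pas), \(m) identical(dim(m), dim(cur[[1L]])),
                  logical(1L)))) {
    abort("Grid geometry mismatch between stacks.",
          class = "comdemog_domain_error")
  }
  flagged <- matrix(FALSE, nrow(cur[[1L]]), ncol(cur[[1L]]))
  missing_any <- matrix(FALSE, nrow(cur[[1L]]), ncol(cur[[1L]]))
  for (v in seq_along(cur)) {
    lo <- min(cur[[v]], na.rm = TRUE)
    hi <- max(cur[[v]], na.rm = TRUE)
    out <- pas[[v]] < lo | pas[[v]] > hi
    missing_any <- missing_any | is.na(pas[[v]])
    flagged <- flagged | (!is.na(out) & out)
  }
  flagged[missing_any & !flagged] <- NA
  flagged
}

#' Hindcast validation against fossil occurrence cells
#'
#' Measures how well a palaeodistribution surface separates grid cells with
#' dated fossil occurrences from background cells: AUC over the surface
#' values, Cohen's kappa at a supplied threshold, and the number of fossil
#' cells predicted present. The background set must be the same size as the
#' fossil set.
#'
#' @param surface an [ascii_grid] or matrix of suitability values.
#' @param fossil_cells,background_cells two-column matrices/data frames of
#'   (row, col) cell indices.
#' @param threshold probability threshold for presence (`value > threshold`).
#' @return A one-row tibble: `auc`, `kappa`, `n_correct`, `n_fossil`.
#' @export
fossil_validation <- function(surface, fossil_cells, background_cells,
                              threshold) {
  m <- if (inherits(surface, "ascii_grid")) surface$data else surface
  fossil_cells <- as.matrix(fossil_cells)[, 1:2, drop = FALSE]
  background_cells <- as.matrix(background_cells)[, 1:2, drop = FALSE]
  if (nrow(fossil_cells) == 0L || nrow(background_cells) == 0L) {
    abort("Cell sets must be non-empty.", class = "comdemog_domain_error")
  }
  if (nrow(fossil_cells) != nrow(background_cells)) {
    abort("Fossil and background sets must be the same size.",
          class = "comdemog_domain_error")
  }
  fs <- m[fossil_cells]
  bs <- m[background_cells]
  pred_f <- fs > threshold
  pred_b <- bs > threshold
  tibble(
    auc = roc_auc(fs, bs),
    kappa = cohens_kappa(tp = sum(pred_f), fp = sum(pred_b),
                         fn = sum(!pred_f), tn = sum(!pred_b)),
    n_correct = sum(pred_f),
    n_fossil = nrow(fossil_cells)
  )
}

#' Plot a suitability surface
#'
#' @param grid an [ascii_grid].
#' @param threshold optional threshold contoured as predicted presence.
#' @return A ggplot.
#' @export
plot_surface <- function(grid, threshold = NULL) {
  m <- grid$data
  df <- tidyr::expand_grid(row = seq_len(nrow(m)), col = seq_len(ncol(m)))
  df$value <- m[cbind(df$row, df$col)]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = -.data$row,
                                        fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "white") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = "Suitability") +
    ggplot2::theme_void()
  if (!is.null(threshold)) {
    df$pres <- df$value > threshold
    p <- p + ggplot2::geom_tile(
      data = df[!is.na(df$pres) & df$pres, ],
      fill = NA, colour = "red", linewidth = 0.2)
  }
  p
}
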