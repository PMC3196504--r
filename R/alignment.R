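#' Haplotype alignment with sample metadata
#'
#' The central data container: an aligned set of haplotype sequences for one
#' locus together with a metadata table mapping each sequence to a population,
#' a region, and geographic coordinates. Sequences are stored as a character
#' matrix (one row per haplotype, one column per site) over the alphabet
#' `A, C, G, T, -, N`; gaps and `N` are treated as missing by all downstream
#' statistics (pairwise-complete per site pair).
#'
#' @param sequences character vector of equal-length sequence strings, or a
#'   character matrix with one row per sequence.
#' @param meta a data frame with columns `sample_id`, `population`, `region`,
#'   `latitude`, `longitude`, one row per sequence, in the same order as
#'   `sequences` (or matched by `sample_id` if `sequences` is named).
#' @param locus_name name of the locus (e.g. `"mtDNA"`, `"EF1a"`, `"cpDNA"`).
#' @param genome one of `"mtDNA"`, `"nuclear"`, `"cpDNA"`; determines the
#'   default generation-time scaling downstream.
#'
#' @return An object of class `hap_alignment`: a list with elements `seq`
#'   (character matrix), `meta` (tibble), `locus_name`, `genome`.
#' @export
#' @examples
#' aln <- hap_alignment(c(a = "AAT", b = "ACT", c = "ACT"),
#'                      meta = toy_meta(c("a", "b", "c")))
#' n_seq(aln)
hap_alignment <- function(sequences, meta = NULL, locus_name = "locus",
                          genome = c("mtDNA", "nuclear", "cpDNA")) {
  genome <- match.arg(genome)
  if (is.matrix(sequences)) {
    m <- toupper(sequences)
  } else {
    sequences <- toupper(as.character(sequences))
    lens <- nchar(sequences)
    if (length(unique(lens)) > 1L) {
      abort("All sequences in an alignment must have equal length.",
            class = "comdemog_format_error")
    }
    m <- do.call(rbind, strsplit(sequences, "", fixed = TRUE))
    rownames(m) <- names(sequences)
  }
  if (nrow(m) < 2L) {
    abort("An alignment needs at least 2 sequences.",
          class = "comdemog_domain_error")
  }
  bad <- setdiff(unique(as.vector(m)), c(NUC, "-", "N"))
  if (length(bad) > 0L) {
    abort(paste0("Unknown characters in alignment: ",
                 paste(bad, collapse = ", ")),
          class = "comdemog_format_error")
  }
  if (is.null(meta)) {
    ids <- rownames(m) %||% paste0("s", seq_len(nrow(m)))
    meta <- toy_meta(ids)
  }
  meta <- validate_sample_meta(meta)
  if (nrow(meta) != nrow(m)) {
    abort("Metadata rows must match sequences 1:1.",
          class = "comdemog_metadata_error")
  }
  if (!is.null(rownames(m))) {
    if (!setequal(rownames(m), meta$sample_id)) {
      abort("Metadata sample_ids do not match sequence names.",
            class = "comdemog_metadata_error")
    }
    meta <- meta[match(rownames(m), meta$sample_id), , drop = FALSE]
  } else {
    rownames(m) <- meta$sample_id
  }
  structure(
    list(seq = m, meta = as_tibble(meta), locus_name = locus_name,
         genome = genome),
    class = "hap_alignment"
  )
}

#' Validate a sample metadata table
#'
#' Checks the invariants of the per-sample metadata: coordinate ranges,
#' non-empty populations, and that every population belongs to exactly one
#' region.
#'
#' @param meta data frame with columns `sample_id`, `population`, `region`,
#'   `latitude`, `longitude`.
#' @return The metadata as a tibble (invisibly validated).
#' @export
validate_sample_meta <- function(meta) {
  need <- c("sample_id", "population", "region", "latitude", "longitude")
  missing_cols <- setdiff(need, names(meta))
  if (length(missing_cols) > 0L) {
    abort(paste0("Metadata is missing columns: ",
                 paste(missing_cols, collapse = ", ")),
          class = "comdemog_metadata_error")
  }
  meta <- as_tibble(meta)[, need]
  if (anyDuplicated(meta$sample_id)) {
    abort("Duplicate sample_id in metadata.", class = "comdemog_metadata_error")
  }
  if (any(!is.finite(meta$latitude)) || any(abs(meta$latitude) > 90)) {
    abort("latitude must lie in [-90, 90].", class = "comdemog_metadata_error")
  }
  if (any(!is.finite(meta$longitude)) || any(abs(meta$longitude) > 180)) {
    abort("longitude must lie in [-180, 180].", class = "comdemog_metadata_error")
  }
  if (any(is.na(meta$population) | meta$population == "")) {
    abort("population must be nonempty.", class = "comdemog_metadata_error")
  }
  multi <- meta |>
    dplyr::distinct(.data$population, .data$region) |>
    dplyr::count(.data$population) |>
    filter(.data$n > 1L)
  if (nrow(multi) > 0L) {
    abort(paste0("Populations mapped to more than one region: ",
                 paste(multi$population, collapse = ", ")),
          class = "comdemog_metadata_error")
  }
  meta
}

#' Minimal placeholder metadata for bare sequences
#'
#' @param ids sample identifiers.
#' @param population,region labels recycled across samples.
#' @return A metadata tibble with all samples at the origin.
#' @export
toy_meta <- function(ids, population = "pop1", region = "region1") {
  tibble(sample_id = as.character(ids), population = population,
         region = region, latitude = 0, longitude = 0)
}

#' @export
print.hap_alignment <- function(x, ...) {
  cat(sprintf("<hap_alignment> locus %s (%s): %d sequences x %d sites, %d population(s)\n",
              x$locus_name, x$genome, nrow(x$seq), ncol(x$seq),
              length(unique(x$meta$population))))
  invisible(x)
}

#' @rdname hap_alignment
#' @param aln a `hap_alignment`.
#' @export
n_seq <- function(aln) nrow(aln$seq)

#' @rdname hap_alignment
#' @export
n_sites <- function(aln) ncol(aln$seq)

#' Sequences of an alignment as strings
#' @param aln a `hap_alignment`.
#' @return Named character vector of sequence strings.
#' @export
aln_strings <- function(aln) {
  setNames(apply(aln$seq, 1L, paste0, collapse = ""), rownames(aln$seq))
}

#' Read and write haplotype alignments (FASTA + TSV metadata)
#'
#' `read_alignment()` loads a FASTA file and a tab-separated metadata table
#' (columns `sample_id`, `population`, `region`, `latitude`, `longitude`,
#' header required) into a [hap_alignment]; `write_alignment()` is its inverse,
#' so that `read_alignment(write_alignment(x))` reproduces `x`.
#'
#' @param path FASTA file path.
#' @param meta_path TSV metadata file path.
#' @param locus_name,genome see [hap_alignment()].
#' @return `read_alignment()` returns a `hap_alignment`; `write_alignment()`
#'   returns `path` invisibly.
#' @export
read_alignment <- function(path, meta_path, locus_name = "locus",
                           genome = c("mtDNA", "nuclear", "cpDNA")) {
  genome <- match.arg(genome)
  seqs <- Biostrings::readDNAStringSet(path)
  lens <- Biostrings::width(seqs)
  if (length(unique(lens)) > 1L) {
    abort("FASTA records have unequal lengths; not an alignment.",
          class = "comdemog_format_error")
  }
  meta <- readr::read_tsv(meta_path, show_col_types = FALSE,
                          progress = FALSE)
  meta <- validate_sample_meta(meta)
  ids <- names(seqs)
  unknown <- setdiff(ids, meta$sample_id)
  if (length(unknown) > 0L) {
    abort(paste0("FASTA sample_ids missing from metadata: ",
                 paste(unknown, collapse = ", ")),
          class = "comdemog_metadata_error")
  }
  hap_alignment(setNames(as.character(seqs), ids),
                meta = meta[match(ids, meta$sample_id), ],
                locus_name = locus_name, genome = genome)
}

#' @rdname read_alignment
#' @param aln a `hap_alignment` to write.
#' @export
write_alignment <- function(aln, path, meta_path) {
  seqs <- Biostrings::DNAStringSet(aln_strings(aln))
  Biostrings::writeXStringSet(seqs, filepath = path, width = 80L)
  readr::write_tsv(aln$meta, meta_path, progress = FALSE)
  invisible(path)
}
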