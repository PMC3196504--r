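#' Read a pipeline configuration
#'
#' Loads a YAML pipeline configuration and validates it eagerly (fail-fast):
#' every species entry must name a locus, a model family, a mutation rate,
#' an effective size and sample sizes; every scenario must define a ratio.
#' Defaults (when a YAML file is not supplied) are the bundled study-design
#' values: the community of [default_community_config()] and the four
#' scenarios of [scenario_ratios()].
#'
#' @param path YAML file path, or `NULL` for the bundled defaults.
#' @param seed master seed (overrides the file's).
#' @param n_reps replicates for the power stage (overrides the file's).
#' @return A `pipeline_config` list with `community`, `scenarios`,
#'   `n_reps`, `seed`, `hash`.
#' @export
pipeline_config <- function(path = NULL, seed = NULL, n_reps = NULL) {
  if (is.null(path)) {
    raw <- list(seed = 1L, n_reps = 200L,
                scenarios = as.list(scenario_ratios()))
  } else {
    raw <- yaml::read_yaml(path)
    if (is.null(raw$scenarios)) {
      abort("Config must define scenarios.", class = "comdemog_config_error")
    }
  }
  seed <- as.integer(seed %||% raw$seed %||% 1L)
  n_reps <- as.integer(n_reps %||% raw$n_reps %||% 200L)
  community <- if (!is.null(raw$species)) {
    community_from_yaml(raw, seed)
  } else {
    default_community_config(seed = seed)
  }
  cfg <- list(community = community,
              scenarios = unlist(raw$scenarios),
              n_reps = n_reps, seed = seed)
  cfg$hash <- rlang::hash(cfg)
  class(cfg) <- "pipeline_config"
  cfg
}

community_from_yaml <- function(raw, seed) {
  entries <- purrr::map(raw$species, function(sp) {
    for (field in c("name", "locus", "genome", "model", "mu", "ne",
                    "n_sites", "populations")) {
      if (is.null(sp[[field]])) {
        abort(sprintf("Species entry '%s' is missing field '%s'.",
                      sp$name %||% "<unnamed>", field),
              class = "comdemog_config_error")
      }
    }
    model <- substitution_model(
      family = sp$model$family, kappa = sp$model$kappa,
      rate_AG = sp$model$rate_AG, rate_CT = sp$model$rate_CT,
      alpha = sp$model$alpha,
      n_categories = sp$model$n_categories %||% 4L)
    pops <- bind_rows(purrr::map(sp$populations, as_tibble))
    scen <- demographic_scenario(
      ne_present = sp$ne,
      ratio_ancestral = sp$ratio %||% 1,
      t_change_years = sp$t_change_years %||% 13000,
      generations_per_year = sp$generations_per_year %||% 1)
    species_config(sp$name, sp$locus, sp$genome, pops, model,
                   sp$n_sites, sp$mu, scen,
                   structure = sp$structure %||% "panmictic",
                   migration_rate = sp$migration_rate)
  })
  community_config(entries, seed = seed)
}

#' Run the full comparative-demography pipeline
#'
#' Orchestrates the stages over every species x locus entry of the
#' configuration: generate a synthetic dataset, compute summary statistics
#' and the mismatch-tau expansion date, fit the growth likelihood, test the
#' observed Fu's Fs against each demographic scenario (the `constant` column
#' is the null p-value), and, for entries with multiple populations, AMOVA +
#' Mantel structure statistics and the structure gate. Every returned table
#' carries the configuration hash and master seed; failures are isolated per
#' entry and collected in `errors`.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, each table is written as
#'   TSV with a provenance header line.
#' @return A `pipeline_report` list of tibbles: `sumstats`, `power`,
#'   `growth`, `structure`, and `errors`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (!inherits(config, "pipeline_config")) {
    abort("config must be a pipeline_config.", class = "comdemog_config_error")
  }
  data <- generate_community(config$community)
  sumstats <- list(); power <- list(); growth <- list(); structure <- list()
  errors <- list()
  for (entry in config$community$entries) {
    key <- paste(entry$species, entry$locus, sep = ":")
    res <- tryCatch({
      aln <- data[[entry$species]][[entry$locus]]
      ss <- summary_stats(aln)
      mf <- mismatch_tau(aln)
      mu_locus_yr <- entry$mu * entry$n_sites *
        entry$scenario$generations_per_year
      ss <- ss |>
        mutate(species = entry$species, .before = 1L) |>
        mutate(tau_hat = mf$tau_hat,
               expansion_years = tau_to_years(mf$tau_hat, mu_locus_yr))
      gf <- tryCatch(
        glance(fit_growth(aln, mode = "sequence")) |>
          mutate(species = entry$species, locus = entry$locus, .before = 1L),
        error = function(e) NULL)
      pw <- purrr::imap(config$scenarios, function(ratio, label) {
        scen <- demographic_scenario(
          entry$scenario$ne_present, ratio_ancestral = ratio,
          t_change_years = entry$scenario$t_change_years,
          generations_per_year = entry$scenario$generations_per_year)
        pr <- power_analysis(
          ss$fs, scen, entry$model, entry$mu,
          n = sum(entry$populations$n_samples), n_sites = entry$n_sites,
          n_reps = config$n_reps, seed = config$seed + 31L,
          scenario_label = label)
        tidy(pr)
      }) |> bind_rows() |>
        mutate(species = entry$species, locus = entry$locus, .before = 1L)
      st <- NULL
      if (length(unique(aln$meta$population)) >= 3L) {
        am <- suppressWarnings(amova(aln, n_perms = 200L,
                                     seed = config$seed))
        mt <- suppressWarnings(ibd_mantel(aln, n_perms = 200L,
                                          seed = config$seed))
        st <- glance(am) |>
          mutate(species = entry$species, locus = entry$locus, .before = 1L) |>
          mutate(mantel_r2 = mt$r_squared, mantel_p = mt$p,
                 gate = structure_gate(.data$phi_st, mt$p))
      }
      list(ss = ss, pw = pw, gf = gf, st = st)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[key]] <- conditionMessage(res)
    } else {
      sumstats[[key]] <- res$ss
      power[[key]] <- res$pw
      growth[[key]] <- res$gf
      structure[[key]] <- res$st
    }
  }
  report <- list(sumstats = bind_rows(sumstats), power = bind_rows(power),
                 growth = bind_rows(growth),
                 structure = bind_rows(structure),
                 errors = errors,
                 hash = config$hash, seed = config$seed)
  class(report) <- "pipeline_report"
  if (!is.null(out_dir)) write_pipeline_report(report, out_dir)
  report
}

write_pipeline_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in c("sumstats", "power", "growth", "structure")) {
    tab <- report[[nm]]
    if (is.null(tab) || nrow(tab) == 0L) next
    path <- file.path(out_dir, paste0(nm, ".tsv"))
    writeLines(sprintf("# config_hash=%s seed=%d", report$hash, report$seed),
               path)
    readr::write_tsv(tab, path, append = TRUE, col_names = TRUE,
                     progress = FALSE)
  }
  jsonlite::write_json(
    list(hash = report$hash, seed = report$seed, errors = report$errors),
    file.path(out_dir, "provenance.json"), auto_unbox = TRUE)
  invisible(out_dir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> hash %s, seed %d\n", x$hash, x$seed))
  cat(sprintf("  sumstats: %d rows; power: %d rows; growth: %d rows; structure: %d rows; errors: %d\n",
              nrow(x$sumstats), nrow(x$power),
              if (is.null(x$growth)) 0L else nrow(x$growth),
              if (is.null(x$structure)) 0L else nrow(x$structure),
              length(x$errors)))
  invisible(x)
}
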