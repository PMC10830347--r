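#' IUCN threat-status levels, least to most threatened
#'
#' The dummy coding in the trait models uses CR (Critically Endangered) as
#' the reference level; the documented category order is LC < NT < VU < EN <
#' CR.
#' @export
threat_levels <- c("LC", "NT", "VU", "EN", "CR")

continuous_traits <- c("taxonomic_uniqueness", "body_mass", "average_count",
                       "range_size", "species_density", "human_density")

#' Assemble the per-species trait table
#'
#' Combines externally supplied traits (threat status, taxonomic uniqueness,
#' body mass, species density) with traits derived from the analysis data
#' itself: `average_count` from the filtered observations ([average_count()]),
#' `range_size` as the species' gridded range cell count, and `human_density`
#' as the mean human density over the species' range cells.
#'
#' @param species_traits Tibble with columns `species`, `threat_status`,
#'   `taxonomic_uniqueness`, `body_mass`, `species_density`.
#' @param table A filtered [checklist_table()].
#' @param ranges Range table.
#' @param human_density Tibble (`cell`, `density`) of people per km^2 on the
#'   analysis grid.
#' @return A trait tibble with one row per species in `ranges`.
#' @export
assemble_traits <- function(species_traits, table, ranges, human_density) {
  derived <- ranges |>
    dplyr::left_join(human_density, by = "cell") |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(range_size = dplyr::n(),
                     human_density = mean(.data$density),
                     .groups = "drop")
  derived |>
    dplyr::left_join(average_count(table), by = "species") |>
    dplyr::left_join(species_traits, by = "species") |>
    dplyr::select("species", "threat_status", "taxonomic_uniqueness",
                  "body_mass", "average_count", "range_size",
                  "species_density", "human_density")
}

#' Prepare the trait-model design data
#'
#' Natural-log transforms the six continuous predictors (which must be
#' positive), recodes threat status as a factor with CR as reference, joins
#' the adequacy metrics as responses, and excludes — with a recorded reason —
#' every species missing any predictor or any metric, so all three models are
#' fitted on an identical species set (listwise deletion, no imputation).
#'
#' @param traits Trait tibble from [assemble_traits()].
#' @param adequacy Adequacy tibble from [compute_adequacy()].
#' @return A list with
#'   * `data`: tibble of responses (`mic`, `trc`, `csb`) and model terms
#'     (`threat_status` + `log_*` predictors), one row per retained species;
#'   * `exclusions`: tibble (`species`, `reason`) for species dropped.
#' @export
prepare_design <- function(traits, adequacy) {
  df <- dplyr::inner_join(traits, adequacy, by = "species")
  bad_level <- !is.na(df$threat_status) & !(df$threat_status %in% threat_levels)
  if (any(bad_level)) {
    rlang::abort(sprintf("Unknown threat status: %s.",
                         paste(unique(df$threat_status[bad_level]), collapse = ", ")),
                 class = "adequacy_schema_error")
  }
  reasons <- purrr::pmap_chr(df, function(...) {
    r <- list(...)
    miss <- c(
      if (is.na(r$threat_status)) "threat_status",
      unlist(lapply(continuous_traits, function(v) {
        if (is.na(r[[v]]) || r[[v]] <= 0) v
      })),
      unlist(lapply(c("mic", "trc", "csb"), function(v) {
        if (is.na(r[[v]])) v
      })))
    if (length(miss) == 0L) NA_character_
    else paste("missing:", paste(miss, collapse = ","))
  })
  exclusions <- tibble::tibble(species = df$species, reason = reasons) |>
    dplyr::filter(!is.na(.data$reason))
  data <- df[is.na(reasons), ] |>
    dplyr::mutate(
      threat_status = factor(.data$threat_status,
                             levels = c("CR", setdiff(threat_levels, "CR"))),
      dplyr::across(dplyr::all_of(continuous_traits), log,
                    .names = "log_{.col}")) |>
    dplyr::select("species", "mic", "trc", "csb", "threat_status",
                  dplyr::starts_with("log_"))
  if (nrow(data) == 0L) {
    rlang::abort("All species excluded; no data left to fit.",
                 class = "adequacy_empty_design_error")
  }
  list(data = data, exclusions = exclusions)
}

#' Fit the trait model for one adequacy metric
#'
#' Ordinary least squares of one metric on threat status (dummy-coded, CR
#' reference) and the six log-transformed continuous traits: classical
#' standard errors, two-sided t p-values, 95% t-based confidence intervals,
#' R-squared, adjusted R-squared and the overall F statistic.
#'
#' @param design Output of [prepare_design()].
#' @param metric One of `"mic"`, `"trc"`, `"csb"`.
#' @return An object of class `trait_model_fit` wrapping the [stats::lm()]
#'   fit; use [tidy()] and [glance()] to extract results.
#' @export
fit_trait_model <- function(design, metric = c("mic", "trc", "csb")) {
  metric <- match.arg(metric)
  terms <- c("threat_status", paste0("log_", continuous_traits))
  fml <- stats::reformulate(terms, response = metric)
  df <- design$data
  fit <- stats::lm(fml, data = df)
  qrr <- qr(stats::model.matrix(fit))
  if (qrr$rank < ncol(stats::model.matrix(fit))) {
    dropped <- colnames(stats::model.matrix(fit))[-qrr$pivot[seq_len(qrr$rank)]]
    rlang::abort(sprintf("Design is rank deficient; collinear term(s): %s.",
                         paste(dropped, collapse = ", ")),
                 class = "adequacy_collinearity_error")
  }
  structure(list(fit = fit, metric = metric, n_species = nrow(df),
                 exclusions = design$exclusions),
            class = "trait_model_fit")
}

#' Fit the trait models for all three adequacy metrics
#'
#' One OLS fit per metric (MIC, TRC, CSB) on the identical species set — the
#' species complete for every predictor *and* every metric — with a shared
#' exclusion list.
#'
#' @param traits Trait tibble from [assemble_traits()].
#' @param adequacy Adequacy tibble from [compute_adequacy()].
#' @return An object of class `trait_model_set`: list with `fits` (named list
#'   of `trait_model_fit`) and `exclusions`.
#' @export
run_all_models <- function(traits, adequacy) {
  design <- prepare_design(traits, adequacy)
  fits <- purrr::map(setNames(c("mic", "trc", "csb"), c("mic", "trc", "csb")),
                     function(m) fit_trait_model(design, m))
  structure(list(fits = fits, exclusions = design$exclusions),
            class = "trait_model_set")
}

signif_stars <- function(p) {
  dplyr::case_when(p < 0.001 ~ "***", p < 0.01 ~ "**", p < 0.05 ~ "*",
                   TRUE ~ "ns")
}

#' Tidy a trait-model fit
#'
#' @param x A `trait_model_fit`.
#' @param ... Unused.
#' @return A tibble with one row per model term: `term`, `estimate`,
#'   `std_error`, `statistic`, `p_value`, `conf_low`, `conf_high`, `stars`
#'   (the conventional cut-offs `<.001`, `<.01`, `<.05`).
#' @method tidy trait_model_fit
#' @export
tidy.trait_model_fit <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  ci <- stats::confint(x$fit, level = 0.95)
  tibble::tibble(
    metric = x$metric,
    term = rownames(sm),
    estimate = unname(sm[, "Estimate"]),
    std_error = unname(sm[, "Std. Error"]),
    statistic = unname(sm[, "t value"]),
    p_value = unname(sm[, "Pr(>|t|)"]),
    conf_low = unname(ci[, 1]),
    conf_high = unname(ci[, 2]),
    stars = signif_stars(unname(sm[, "Pr(>|t|)"])))
}

#' Fit statistics of a trait-model fit
#'
#' @param x A `trait_model_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `metric`, `r_squared`, `adj_r_squared`,
#'   `f_statistic`, `df1`, `df2`, `p_value`, `n_species`, `n_excluded`.
#' @method glance trait_model_fit
#' @export
glance.trait_model_fit <- function(x, ...) {
  sm <- summary(x$fit)
  f <- sm$fstatistic
  tibble::tibble(
    metric = x$metric,
    r_squared = sm$r.squared,
    adj_r_squared = sm$adj.r.squared,
    f_statistic = unname(f[1]),
    df1 = unname(f[2]),
    df2 = unname(f[3]),
    p_value = stats::pf(f[1], f[2], f[3], lower.tail = FALSE),
    n_species = x$n_species,
    n_excluded = nrow(x$exclusions))
}

#' @method tidy trait_model_set
#' @export
tidy.trait_model_set <- function(x, ...) {
  purrr::map_dfr(x$fits, tidy)
}

#' @method glance trait_model_set
#' @export
glance.trait_model_set <- function(x, ...) {
  purrr::map_dfr(x$fits, glance)
}

#' @export
print.trait_model_fit <- function(x, ...) {
  cat(sprintf("<trait_model_fit> metric %s, n = %d species\n",
              x$metric, x$n_species))
  print(glance(x))
  invisible(x)
}

#' @export
print.trait_model_set <- function(x, ...) {
  cat(sprintf("<trait_model_set> 3 metrics, n = %d species (%d excluded)\n",
              x$fits[[1]]$n_species, nrow(x$exclusions)))
  print(glance(x))
  invisible(x)
}
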