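#' End-to-end sociality analysis of a scan dataset
#'
#' Orchestrates the full pipeline for one or more behaviours: builds the
#' lagged dyad-scan tables, fits the hierarchical model, and assembles the
#' variance decomposition, covariate effects (when fitted), network group
#' metrics and contrasts, and the clique posterior-predictive check into a
#' single bundle of tidy tables. All stochastic stages are seeded, so two
#' runs with the same inputs produce identical tables.
#'
#' @param scans a `scan_events` object.
#' @param individuals individuals tibble.
#' @param behaviours behaviours to analyse.
#' @param include_covariates fit dyad-level covariates.
#' @param chains,iterations,warmup MCMC settings per behaviour.
#' @param n_sims clique simulations per group.
#' @param seed master seed; per-stage seeds are derived from it.
#' @param allow_unconverged keep going when some R-hat exceeds 1.05
#'   (otherwise the offending behaviour is reported with a warning).
#' @return A `sociality_report`: list with `fits`, `diagnostics`,
#'   `variance_table` (components x behaviours, posterior mean and HPDI),
#'   `shares`, `effects`, `metric_summary`, `metric_contrasts`, `cliques`
#'   and a reproducibility `manifest`.
#' @export
sociality_report <- function(scans, individuals,
                             behaviours = scansoc_behaviours,
                             include_covariates = FALSE,
                             chains = 2, iterations = 1500, warmup = 600,
                             n_sims = 200, seed = 1,
                             allow_unconverged = TRUE) {
  stopifnot(inherits(scans, "scan_events"))
  t_start <- proc.time()[["elapsed"]]
  stages <- list()

  fits <- list(); var_summaries <- list(); effects <- list()
  metric_summary <- list(); metric_contrasts <- list(); cliques <- list()
  diagnostics <- list()

  for (b in behaviours) {
    t0 <- proc.time()[["elapsed"]]
    tbl <- build_dyad_scans(scans, individuals, b)
    spec <- model_spec(
      b, include_covariates = include_covariates, chains = chains,
      iterations = iterations, warmup = warmup,
      seed = seed + match(b, scansoc_behaviours)
    )
    fit <- fit_scan_model(tbl, spec)
    fits[[b]] <- fit
    diag <- fit_diagnostics(fit)
    diagnostics[[b]] <- dplyr::mutate(diag, behaviour = b, .before = 1)
    if (any(diag$flag)) {
      msg <- paste0("behaviour ", b, ": R-hat > 1.05 for ",
                    paste(diag$term[diag$flag], collapse = ", "))
      if (allow_unconverged) warn(msg) else abort(msg)
    }
    vs <- variance_summary(fit)
    var_summaries[[b]] <- vs
    if (include_covariates) {
      effects[[b]] <- dplyr::mutate(odds_effects(fit), behaviour = b, .before = 1)
    }
    net <- derive_networks(fit)
    for (metric in c("strength", "clustering")) {
      gmx <- group_metrics(net, metric)
      metric_summary[[paste(b, metric)]] <-
        dplyr::mutate(gmx$summary, behaviour = b, metric = metric, .before = 1)
      metric_contrasts[[paste(b, metric)]] <-
        dplyr::mutate(gmx$contrasts, behaviour = b, metric = metric, .before = 1)
    }
    cliques[[b]] <- dplyr::mutate(
      clique_report(scans, net, n_sims = n_sims, seed = seed * 100 + match(b, scansoc_behaviours)),
      behaviour = b, .before = 1
    )
    stages[[b]] <- proc.time()[["elapsed"]] - t0
  }

  variance_table <- purrr::imap_dfr(var_summaries, function(vs, b) {
    dplyr::mutate(vs$summary, behaviour = b, .before = 1)
  })
  shares <- purrr::imap_dfr(var_summaries, function(vs, b) {
    dplyr::mutate(vs$shares, behaviour = b, .before = 1)
  })

  structure(
    list(
      fits = fits,
      diagnostics = dplyr::bind_rows(diagnostics),
      variance_table = variance_table,
      variance_summaries = var_summaries,
      shares = shares,
      effects = if (length(effects)) dplyr::bind_rows(effects) else NULL,
      metric_summary = dplyr::bind_rows(metric_summary),
      metric_contrasts = dplyr::bind_rows(metric_contrasts),
      cliques = dplyr::bind_rows(cliques),
      manifest = list(
        package_version = as.character(utils::packageVersion("scansoc")),
        seed = seed, behaviours = behaviours, chains = chains,
        iterations = iterations, warmup = warmup, n_sims = n_sims,
        include_covariates = include_covariates,
        stage_runtimes = stages,
        total_runtime = proc.time()[["elapsed"]] - t_start
      )
    ),
    class = "sociality_report"
  )
}

#' @export
print.sociality_report <- function(x, ...) {
  cat("<sociality_report> behaviours: ",
      paste(names(x$fits), collapse = ", "), "\n", sep = "")
  cat("variance components (posterior mean [95% HPDI]):\n")
  wide <- x$variance_table |>
    dplyr::filter(.data$component %in%
                    c("sigma_group", "sigma_ind", "sigma_dyad", "sigma_rec",
                      "ratio_group", "ratio_dyad")) |>
    dplyr::mutate(cell = sprintf("%.3f [%.3f, %.3f]", .data$mean,
                                 .data$lower, .data$upper)) |>
    dplyr::select("behaviour", "component", "cell") |>
    tidyr::pivot_wider(names_from = "behaviour", values_from = "cell")
  print(wide)
  invisible(x)
}

#' Write a sociality report as CSV tables
#'
#' Writes `variance_table.csv`, `shares.csv`, `effects.csv` (when present),
#' `metric_summary.csv`, `metric_contrasts.csv`, `cliques.csv`,
#' `diagnostics.csv` and `manifest.json` into a directory.
#'
#' @param report a `sociality_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "sociality_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(report$variance_table, file.path(dir, "variance_table.csv"))
  readr::write_csv(report$shares, file.path(dir, "shares.csv"))
  if (!is.null(report$effects)) {
    readr::write_csv(report$effects, file.path(dir, "effects.csv"))
  }
  readr::write_csv(report$metric_summary, file.path(dir, "metric_summary.csv"))
  readr::write_csv(report$metric_contrasts, file.path(dir, "metric_contrasts.csv"))
  readr::write_csv(report$cliques, file.path(dir, "cliques.csv"))
  readr::write_csv(report$diagnostics, file.path(dir, "diagnostics.csv"))
  jsonlite::write_json(report$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Percent-variance breakdown plot across behaviours
#'
#' @param report a `sociality_report`.
#' @return a ggplot.
#' @export
plot_variance_shares <- function(report) {
  stopifnot(inherits(report, "sociality_report"))
  df <- report$shares |>
    dplyr::mutate(component = factor(.data$component,
                                     levels = c("group", "individual",
                                                "recipient", "dyad")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$behaviour, y = .data$mean_pct,
                                   fill = .data$component)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::scale_fill_brewer(palette = "Set2") +
    ggplot2::labs(x = NULL, y = "% of log-odds variance", fill = "level") +
    ggplot2::theme_minimal()
}

#' Group network-metric intervals across behaviours
#'
#' @param report a `sociality_report`.
#' @param metric `"strength"` or `"clustering"`.
#' @return a ggplot.
#' @export
plot_group_metrics <- function(report, metric = c("strength", "clustering")) {
  stopifnot(inherits(report, "sociality_report"))
  metric <- match.arg(metric)
  df <- report$metric_summary |> dplyr::filter(.data$metric == !!metric)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$mean)) +
    ggplot2::geom_point(colour = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                           width = 0.15) +
    ggplot2::facet_wrap(~behaviour, scales = "free_y") +
    ggplot2::labs(x = "group", y = paste("mean", metric)) +
    ggplot2::theme_minimal()
}
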