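#' Highest posterior density interval
#'
#' The shortest contiguous interval containing `ceiling(mass * n)` of the
#' sorted draws. Ties between equally short windows are broken by taking the
#' leftmost one (draws are discrete, so exact ties occur).
#'
#' @param draws numeric vector of at least 2 posterior draws.
#' @param mass probability mass in (0, 1); default 0.95.
#' @return named numeric `c(lower, upper)`.
#' @export
hpdi <- function(draws, mass = 0.95) {
  if (length(mass) != 1 || !is.finite(mass) || mass <= 0 || mass >= 1) {
    abort("mass must be a single number in (0, 1)")
  }
  draws <- draws[is.finite(draws)]
  n <- length(draws)
  if (n < 2) abort("need at least 2 finite draws")
  x <- sort(draws)
  m <- ceiling(mass * n)
  if (m >= n) return(c(lower = x[1], upper = x[n]))
  widths <- x[m:n] - x[1:(n - m + 1)]
  t0 <- which.min(widths)  # which.min takes the first minimum
  c(lower = x[t0], upper = x[t0 + m - 1])
}

#' Evidence flag from a posterior difference
#'
#' `TRUE` when the 95% highest posterior density interval of the draws
#' excludes the reference value, the package-wide criterion for inferring a
#' difference (between groups, or of a ratio from 1).
#'
#' @param draws posterior draws of a difference or ratio.
#' @param reference value to exclude (0 for differences, 1 for ratios).
#' @param mass interval mass.
#' @return logical scalar.
#' @export
evidence_flag <- function(draws, reference = 0, mass = 0.95) {
  h <- hpdi(draws, mass)
  reference < h[["lower"]] || reference > h[["upper"]]
}

#' Variance decomposition of a fitted model
#'
#' Per posterior draw, derives the within-group SD, the individual-component
#' SD, the between/within ratio and the dyad/individual ratio, plus the
#' percentage of total log-odds variance attributable to each level; per-draw
#' quantities are then summarised by their posterior mean and 95% HPDI
#' (ratios of SDs are computed draw-wise, never as ratios of summaries).
#'
#' For undirected behaviours the individual component enters twice (once per
#' member), so `sigma_within^2 = 2 sigma_ind^2 + sigma_dyad^2` and
#' `sigma_IND = sqrt(2) sigma_ind`. For grooming the groomer and recipient
#' effects are separate: `sigma_within^2 = sigma_ind^2 + sigma_rec^2 +
#' sigma_dyad^2` and `sigma_IND^2 = sigma_ind^2 + sigma_rec^2`.
#'
#' @param x a `scan_fit`, or a data frame / matrix of posterior draws with
#'   columns `sigma_group`, `sigma_ind`, `sigma_dyad` (and `sigma_rec` when
#'   `directional = TRUE`).
#' @param directional whether the draws come from the directional (grooming)
#'   model; taken from the fit when `x` is a `scan_fit`.
#' @param ... unused.
#' @return A `variance_summary` object: list with tibbles `summary`
#'   (component, posterior mean, HPDI) and `shares` (percent of variance per
#'   level), the per-draw tibble `draws`, and a `degenerate` flag set when
#'   `sigma_IND` is zero in some draws so the dyad/individual ratio is
#'   undefined (reported as missing rather than an error).
#' @export
variance_summary <- function(x, ...) UseMethod("variance_summary")

#' @rdname variance_summary
#' @export
variance_summary.scan_fit <- function(x, ...) {
  variance_summary(as.data.frame(x$draws[, grepl("^sigma_", colnames(x$draws)),
                                         drop = FALSE]),
                   directional = x$directional, ...)
}

#' @rdname variance_summary
#' @export
variance_summary.default <- function(x, directional = FALSE, ...) {
  x <- as.data.frame(x)
  need <- c("sigma_group", "sigma_ind", "sigma_dyad",
            if (directional) "sigma_rec")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("draws lack column(s): ", paste(missing_cols, collapse = ", ")))
  }
  sg <- x$sigma_group; si <- x$sigma_ind; sdy <- x$sigma_dyad
  if (directional) {
    sr <- x$sigma_rec
    s_within <- sqrt(si^2 + sr^2 + sdy^2)
    s_ind_comp <- sqrt(si^2 + sr^2)
    total <- sg^2 + si^2 + sr^2 + sdy^2
    shares <- tibble::tibble(
      component = rep(c("group", "individual", "recipient", "dyad"),
                      each = length(sg)),
      pct = 100 * c(sg^2 / total, si^2 / total, sr^2 / total, sdy^2 / total),
      .draw = rep(seq_along(sg), 4)
    )
  } else {
    sr <- NULL
    s_within <- sqrt(2 * si^2 + sdy^2)
    s_ind_comp <- sqrt(2) * si
    total <- sg^2 + 2 * si^2 + sdy^2
    shares <- tibble::tibble(
      component = rep(c("group", "individual", "dyad"), each = length(sg)),
      pct = 100 * c(sg^2 / total, 2 * si^2 / total, sdy^2 / total),
      .draw = rep(seq_along(sg), 3)
    )
  }
  ratio_group <- ifelse(s_within > 0, sg / s_within, ifelse(sg == 0, 0, Inf))
  ratio_dyad <- ifelse(s_ind_comp > 0, sdy / s_ind_comp,
                       ifelse(sdy == 0, 0, Inf))
  degenerate <- any(!is.finite(ratio_dyad)) || any(!is.finite(ratio_group))

  per_draw <- tibble::tibble(
    sigma_group = sg, sigma_ind = si, sigma_dyad = sdy,
    sigma_rec = if (directional) sr else NA_real_,
    sigma_within = s_within, sigma_IND = s_ind_comp,
    ratio_group = ratio_group, ratio_dyad = ratio_dyad
  )

  summarise_vec <- function(v) {
    if (any(!is.finite(v))) {
      return(tibble::tibble(mean = NA_real_, lower = NA_real_,
                            upper = NA_real_, degenerate = TRUE))
    }
    if (length(v) >= 2) {
      h <- hpdi(v, 0.95)
    } else {
      h <- c(lower = v, upper = v)
    }
    tibble::tibble(mean = mean(v), lower = h[["lower"]], upper = h[["upper"]],
                   degenerate = FALSE)
  }
  comp_names <- c("sigma_group", "sigma_ind", "sigma_dyad",
                  if (directional) "sigma_rec",
                  "sigma_within", "sigma_IND", "ratio_group", "ratio_dyad")
  summary <- purrr::map_dfr(comp_names, function(nm) {
    dplyr::bind_cols(tibble::tibble(component = nm),
                     summarise_vec(per_draw[[nm]]))
  })
  share_summary <- shares |>
    dplyr::group_by(.data$component) |>
    dplyr::summarise(
      mean_pct = mean(.data$pct),
      lower = if (dplyr::n() >= 2) hpdi(.data$pct, 0.95)[["lower"]] else .data$pct[1],
      upper = if (dplyr::n() >= 2) hpdi(.data$pct, 0.95)[["upper"]] else .data$pct[1],
      .groups = "drop"
    ) |>
    dplyr::arrange(match(.data$component, c("group", "individual", "recipient", "dyad")))

  structure(
    list(summary = summary, shares = share_summary, draws = per_draw,
         directional = directional, degenerate = degenerate),
    class = "variance_summary"
  )
}

#' @export
print.variance_summary <- function(x, ...) {
  cat("<variance_summary> (", if (x$directional) "directional" else "undirected",
      ")\n", sep = "")
  print(x$summary)
  cat("percent of total log-odds variance:\n")
  print(x$shares)
  invisible(x)
}

#' Covariate effects on the odds scale
#'
#' Back-transforms each dyad-level covariate coefficient to an odds
#' multiplier (`exp(delta)`, draw-wise) and summarises with the posterior
#' mean and 95% HPDI; the evidence flag marks multipliers whose HPDI
#' excludes 1.
#'
#' @param fit a `scan_fit` fitted with `include_covariates = TRUE`.
#' @param terms optional character vector of covariate names to keep.
#' @return tibble with columns `term`, `odds`, `lower`, `upper`, `evidence`.
#' @export
odds_effects <- function(fit, terms = NULL) {
  stopifnot(inherits(fit, "scan_fit"))
  cols <- grep("^delta_", colnames(fit$draws), value = TRUE)
  if (length(cols) == 0) {
    abort("fit has no covariate coefficients; refit with include_covariates = TRUE")
  }
  if (!is.null(terms)) {
    want <- paste0("delta_", terms)
    missing_terms <- setdiff(want, cols)
    if (length(missing_terms) > 0) {
      abort(paste0("covariate(s) absent from fit: ",
                   paste(sub("^delta_", "", missing_terms), collapse = ", ")))
    }
    cols <- want
  }
  purrr::map_dfr(cols, function(nm) {
    mult <- exp(fit$draws[, nm])
    h <- hpdi(mult, 0.95)
    tibble::tibble(
      term = sub("^delta_", "", nm),
      odds = mean(mult), lower = h[["lower"]], upper = h[["upper"]],
      evidence = evidence_flag(mult, reference = 1)
    )
  })
}

#' @describeIn variance_summary stacked-bar plot of the percent-variance
#'   shares.
#' @param object a `variance_summary`.
#' @export
autoplot.variance_summary <- function(object, ...) {
  df <- object$shares |>
    dplyr::mutate(component = factor(.data$component,
                                     levels = c("group", "individual",
                                                "recipient", "dyad")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$component, y = .data$mean_pct)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                           width = 0.2) +
    ggplot2::labs(x = NULL, y = "% of log-odds variance") +
    ggplot2::theme_minimal()
}
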