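# split-Rhat: chains are split in half and the usual potential scale
# reduction factor is computed over the resulting 2m sequences
split_chains <- function(x, chain) {
  out <- list()
  for (ch in unique(chain)) {
    v <- x[chain == ch]
    n2 <- floor(length(v) / 2)
    out <- c(out, list(v[seq_len(n2)], v[seq_len(n2) + n2]))
  }
  out
}

rhat_split <- function(x, chain) {
  parts <- split_chains(x, chain)
  parts <- parts[lengths(parts) >= 2]
  if (length(parts) < 2) return(NA_real_)
  n <- min(lengths(parts))
  parts <- lapply(parts, function(v) v[seq_len(n)])
  means <- vapply(parts, mean, numeric(1))
  vars <- vapply(parts, var, numeric(1))
  W <- mean(vars)
  B <- n * var(means)
  if (W == 0) return(if (B == 0) 1 else Inf)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# effective sample size via Geyer's initial monotone positive sequence on
# the chain-averaged autocorrelations
ess_basic <- function(x, chain) {
  parts <- split_chains(x, chain)
  parts <- parts[lengths(parts) >= 4]
  if (length(parts) == 0) return(NA_real_)
  n <- min(lengths(parts))
  parts <- lapply(parts, function(v) v[seq_len(n)])
  m <- length(parts)
  means <- vapply(parts, mean, numeric(1))
  vars <- vapply(parts, var, numeric(1))
  W <- mean(vars)
  var_plus <- W * (n - 1) / n + if (m > 1) var(means) else 0
  if (var_plus == 0) return(NA_real_)
  max_lag <- min(n - 1, 1000)
  acov <- sapply(parts, function(v) {
    a <- stats::acf(v, lag.max = max_lag, type = "covariance",
                    plot = FALSE, demean = TRUE)$acf[, 1, 1]
    a
  })
  acov <- rowMeans(acov)
  rho <- 1 - (W - acov[-1]) / var_plus
  # pairwise sums, stop at the first negative, enforce monotonicity
  npair <- floor(length(rho) / 2)
  tau <- 1
  prev <- Inf
  for (t in seq_len(npair)) {
    p <- rho[2 * t - 1] + rho[2 * t]
    if (!is.finite(p) || p < 0) break
    p <- min(p, prev)
    prev <- p
    tau <- tau + 2 * p
  }
  max(m * n / tau, 1e-8)
}

fit_diagnostics_matrix <- function(draws, chain) {
  purrr::map_dfr(colnames(draws), function(nm) {
    tibble::tibble(
      term = nm,
      rhat = rhat_split(draws[, nm], chain),
      ess = ess_basic(draws[, nm], chain)
    )
  }) |>
    dplyr::mutate(flag = !is.na(.data$rhat) & .data$rhat > 1.05)
}

#' Convergence diagnostics for a fitted model
#'
#' Split-R-hat and effective sample size for every scalar parameter (fixed
#' effects, covariate coefficients, SDs). Parameters with R-hat above 1.05
#' are flagged.
#'
#' @param fit a `scan_fit` from [fit_scan_model()].
#' @param pars regular expression selecting parameter columns.
#' @return tibble with columns `term`, `rhat`, `ess`, `flag`.
#' @export
fit_diagnostics <- function(fit, pars = "^(alpha|beta_last|delta_|sigma_)") {
  stopifnot(inherits(fit, "scan_fit"))
  if (fit$spec$chains < 2) {
    abort("convergence diagnostics need at least 2 chains; refit with chains >= 2")
  }
  m <- fit$draws[, grepl(pars, colnames(fit$draws)), drop = FALSE]
  fit_diagnostics_matrix(m, fit$chain)
}
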