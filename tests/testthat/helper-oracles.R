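# Independent reference implementations used as oracles. These deliberately
# use naive loops and stats:: density functions, sharing no code with the
# package's computational paths.

# naive log posterior: row-by-row Bernoulli pmf plus normal/uniform priors
naive_log_posterior <- function(state, tbl, spec) {
  upper <- spec$prior_sigma_upper
  sigmas <- c(state$sigma_group, state$sigma_ind, state$sigma_dyad,
              if (spec$directional) state$sigma_rec)
  if (any(sigmas <= 0 | sigmas > upper)) return(-Inf)
  X <- if (spec$include_covariates) dyad_design_matrix(tbl) else NULL
  lp <- 0
  for (r in seq_len(nrow(tbl))) {
    eta <- state$alpha + state$beta_last * tbl$y_prev[r]
    eta <- eta + state$a[[tbl$group[r]]]
    eta <- eta + state$b[[paste0(tbl$group[r], ":", tbl$i[r])]]
    eta <- eta + if (spec$directional) {
      state$d[[paste0(tbl$group[r], ":", tbl$j[r])]]
    } else {
      state$b[[paste0(tbl$group[r], ":", tbl$j[r])]]
    }
    lo <- min(tbl$i[r], tbl$j[r]); hi <- max(tbl$i[r], tbl$j[r])
    eta <- eta + state$c[[paste0(tbl$group[r], ":", lo, ":", hi)]]
    if (!is.null(X)) {
      for (nm in names(state$delta)) eta <- eta + state$delta[[nm]] * X[r, nm]
    }
    lp <- lp + stats::dbinom(tbl$y[r], 1, stats::plogis(eta), log = TRUE)
  }
  for (v in state$a) lp <- lp + stats::dnorm(v, 0, state$sigma_group, log = TRUE)
  for (v in state$b) lp <- lp + stats::dnorm(v, 0, state$sigma_ind, log = TRUE)
  for (v in state$c) lp <- lp + stats::dnorm(v, 0, state$sigma_dyad, log = TRUE)
  if (spec$directional) {
    for (v in state$d) lp <- lp + stats::dnorm(v, 0, state$sigma_rec, log = TRUE)
  }
  lp <- lp + stats::dnorm(state$alpha, 0, spec$prior_sd_fixed, log = TRUE)
  lp <- lp + stats::dnorm(state$beta_last, 0, spec$prior_sd_fixed, log = TRUE)
  for (v in state$delta %||% numeric(0)) {
    lp <- lp + stats::dnorm(v, 0, spec$prior_sd_fixed, log = TRUE)
  }
  lp + sum(stats::dunif(sigmas, 0, upper, log = TRUE))
}

# random small dyad-scan table plus a random compatible parameter state
random_instance <- function(seed, directional = FALSE, covariates = FALSE) {
  set.seed(seed)
  behaviour <- if (directional) "grooming" else "close_proximity"
  ds <- simulate_scans(sim_config(
    n_groups = 2, group_sizes = c(3L, 3L), days = 2, scans_per_day = 3,
    behaviours = behaviour, visibility = 1,
    params = list(alpha = rnorm(1, -1, 1), beta_last = rnorm(1),
                  sigma_group = runif(1, 0.2, 1), sigma_ind = runif(1, 0.2, 1),
                  sigma_dyad = runif(1, 0.2, 1), sigma_rec = runif(1, 0.2, 1)),
    seed = seed
  ))
  tbl <- build_dyad_scans(ds$scans, ds$individuals, behaviour)
  keep <- sort(sample.int(nrow(tbl), min(nrow(tbl), 12)))
  tbl <- tbl[keep, ]
  groups <- unique(tbl$group)
  ikeys <- unique(c(paste0(tbl$group, ":", tbl$i), paste0(tbl$group, ":", tbl$j)))
  dkeys <- unique(paste0(tbl$group, ":", pmin(tbl$i, tbl$j), ":", pmax(tbl$i, tbl$j)))
  spec <- model_spec(behaviour, include_covariates = covariates,
                     prior_sd_fixed = runif(1, 5, 100),
                     prior_sigma_upper = runif(1, 5, 10))
  delta_names <- colnames(dyad_design_matrix(tbl))
  state <- list(
    alpha = rnorm(1), beta_last = rnorm(1),
    a = setNames(rnorm(length(groups)), groups),
    b = setNames(rnorm(length(ikeys)), ikeys),
    c = setNames(rnorm(length(dkeys)), dkeys),
    d = setNames(rnorm(length(ikeys)), ikeys),
    delta = setNames(rnorm(length(delta_names)), delta_names),
    sigma_group = runif(1, 0.1, 3), sigma_ind = runif(1, 0.1, 3),
    sigma_dyad = runif(1, 0.1, 3), sigma_rec = runif(1, 0.1, 3)
  )
  list(state = state, tbl = tbl, spec = spec)
}

# exhaustive-search HPDI: try every window over the sorted draws
exhaustive_hpdi <- function(draws, mass = 0.95) {
  x <- sort(draws)
  n <- length(x)
  m <- ceiling(mass * n)
  if (m >= n) return(c(lower = x[1], upper = x[n]))
  best <- c(lower = x[1], upper = x[m])
  for (t in seq_len(n - m + 1)) {
    if (x[t + m - 1] - x[t] < best["upper"] - best["lower"]) {
      best <- c(lower = x[t], upper = x[t + m - 1])
    }
  }
  best
}

# naive clustering coefficient: explicit triple enumeration
naive_cluster_coefficient <- function(W, node) {
  n <- nrow(W)
  num <- 0; den <- 0
  for (j in seq_len(n)) {
    if (j == node) next
    for (k in seq_len(n)) {
      if (k == node || k == j) next
      num <- num + W[node, j] * W[j, k] * W[node, k]
      den <- den + W[node, j] * W[node, k]
    }
  }
  if (den == 0) return(NA_real_)
  num / den
}

# long-run occupancy of the two-state chain by direct simulation; many
# chains in parallel so the estimate and its MC standard error are cheap
simulate_chain_occupancy <- function(p0, p1, n_chains = 2000, n_steps = 600,
                                     burn = 100) {
  y <- rbinom(n_chains, 1, p0)
  occ <- numeric(n_chains)
  kept <- 0
  for (s in seq_len(n_steps)) {
    y <- rbinom(n_chains, 1, ifelse(y == 1, p1, p0))
    if (s > burn) {
      occ <- occ + y
      kept <- kept + 1
    }
  }
  rates <- occ / kept
  c(mean = mean(rates), se = sd(rates) / sqrt(n_chains))
}

# brute-force expected row count for an undirected dyad-scan table:
# enumerate scans x eligible pairs, keeping pairs with >= 1 visible member
brute_force_row_count <- function(scans, individuals) {
  total <- 0
  for (r in seq_len(nrow(scans$visibility))) {
    g <- scans$visibility$group[r]
    vis <- scans$visibility$ids[[r]]
    ids <- individuals$id[individuals$group == g]
    ages <- setNames(individuals$age, individuals$id)
    for (a in seq_along(ids)) {
      for (b in seq_along(ids)) {
        if (a >= b) next
        if (ages[ids[a]] < 7 && ages[ids[b]] < 7) next
        if (ids[a] %in% vis || ids[b] %in% vis) total <- total + 1
      }
    }
  }
  total
}

# quick constructor for a minimal scan_fit-like object with given draws
fake_scan_fit <- function(draws, directional = FALSE,
                          behaviour = if (directional) "grooming" else "close_proximity") {
  structure(
    list(draws = draws, chain = rep(1L, nrow(draws)),
         spec = model_spec(behaviour, chains = 2),
         behaviour = behaviour, directional = directional),
    class = "scan_fit"
  )
}
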