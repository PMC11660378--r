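#' Model specification
#'
#' Settings for the hierarchical Bernoulli model of dyadic scan outcomes:
#' `logit P(y = 1) = alpha + beta_last * y_prev + B_ijk (+ x'delta)` where
#' `B_ijk = a_k + b_ik + b_jk + c_ijk` for undirected behaviours and
#' `a_k + b_ik + d_jk + c_ijk` for grooming (ordered groomer -> recipient).
#' Random effects are zero-mean normal with standard deviations
#' `sigma_group`, `sigma_ind`, `sigma_dyad` (and `sigma_rec` for the
#' grooming-recipient effect). Priors are vague: `N(0, prior_sd_fixed^2)`
#' for `alpha`, `beta_last` and each covariate coefficient, and
#' `U(0, prior_sigma_upper)` for every standard deviation.
#'
#' @param behaviour one of the four scan behaviours; grooming is directional.
#' @param include_covariates add dyad-level covariates (age difference,
#'   maternal/paternal kin, sex class) to the linear predictor.
#' @param prior_sd_fixed prior SD of fixed effects (default 100, i.e.
#'   variance 10^4).
#' @param prior_sigma_upper upper bound of the uniform prior on the random
#'   effect SDs.
#' @param chains number of MCMC chains (at least 2 for convergence
#'   diagnostics).
#' @param iterations total iterations per chain, including warmup.
#' @param warmup adaptation iterations discarded from each chain.
#' @param thinning keep every `thinning`-th post-warmup draw.
#' @param seed integer seed; fits are deterministic given `(seed, spec)`.
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(behaviour, include_covariates = FALSE,
                       prior_sd_fixed = 100, prior_sigma_upper = 10,
                       chains = 2, iterations = 2000, warmup = 1000,
                       thinning = 1, seed = 1) {
  check_behaviour(behaviour)
  if (prior_sigma_upper <= 0) abort("prior_sigma_upper must be > 0")
  if (warmup >= iterations) abort("warmup must be smaller than iterations")
  if (chains < 1) abort("chains must be >= 1")
  if (chains < 2) warn("chains < 2: convergence diagnostics will be unavailable")
  structure(
    list(
      behaviour = behaviour, directional = is_directional(behaviour),
      include_covariates = isTRUE(include_covariates),
      prior_sd_fixed = prior_sd_fixed, prior_sigma_upper = prior_sigma_upper,
      chains = as.integer(chains), iterations = as.integer(iterations),
      warmup = as.integer(warmup), thinning = as.integer(thinning),
      seed = as.integer(seed)
    ),
    class = "model_spec"
  )
}

ind_key <- function(group, id) paste0(group, ":", id)
dyad_key <- function(group, i, j) paste0(group, ":", pmin(i, j), ":", pmax(i, j))

# integer (0-based) index structure shared by the sampler and log posterior
build_index <- function(tbl, spec) {
  if (attr(tbl, "behaviour") != spec$behaviour) {
    abort("dyad-scan table was built for a different behaviour than the spec")
  }
  groups <- sort(unique(tbl$group))
  inds <- dplyr::distinct(
    dplyr::bind_rows(
      dplyr::select(tbl, group = "group", id = "i"),
      dplyr::select(tbl, group = "group", id = "j")
    )
  ) |> dplyr::arrange(.data$group, .data$id)
  ikeys <- ind_key(inds$group, inds$id)
  dkeys_all <- dyad_key(tbl$group, tbl$i, tbl$j)
  dyads <- dplyr::distinct(tibble::tibble(key = dkeys_all, group = tbl$group,
                                          i = pmin(tbl$i, tbl$j),
                                          j = pmax(tbl$i, tbl$j))) |>
    dplyr::arrange(.data$key)
  X <- if (spec$include_covariates) dyad_design_matrix(tbl) else
    matrix(0, nrow(tbl), 0)
  list(
    groups = groups,
    inds = inds, ikeys = ikeys,
    dyads = dyads,
    g = match(tbl$group, groups) - 1L,
    i1 = match(ind_key(tbl$group, tbl$i), ikeys) - 1L,
    i2 = match(ind_key(tbl$group, tbl$j), ikeys) - 1L,
    d = match(dkeys_all, dyads$key) - 1L,
    X = X,
    y = as.integer(tbl$y), yprev = as.integer(tbl$y_prev)
  )
}

#' Linear predictor of the dyadic model
#'
#' Evaluates `alpha + beta_last * y_prev + a_k + b_ik + b_jk + c_ijk +
#' x'delta` (undirected) or `alpha + beta_last * y_prev + a_k + b_ik + d_jk
#' + c_ijk + x'delta` (grooming, ordered pair i -> j) for each row of a
#' dyad-scan table, on the log-odds scale.
#'
#' @param state named list with scalars `alpha`, `beta_last`, named vectors
#'   `a` (by group), `b` (by `"group:id"`), `c` (by `"group:i:j"`, unordered),
#'   `d` (grooming recipients, by `"group:id"`) and optionally `delta`
#'   (named by covariate term).
#' @param rows one or more rows of a `dyad_scans` tibble.
#' @param spec a [model_spec()].
#' @return numeric vector of log-odds, one per row.
#' @export
linear_predictor <- function(state, rows, spec) {
  lookup <- function(v, keys, what) {
    if (length(keys) == 0) return(numeric(0))
    out <- v[keys]
    if (anyNA(out)) {
      abort(paste0(what, " not indexed in state: ",
                   paste(head(keys[is.na(out)], 3), collapse = ", ")))
    }
    unname(out)
  }
  eta <- state$alpha + state$beta_last * rows$y_prev +
    lookup(state$a, rows$group, "group") +
    lookup(state$c, dyad_key(rows$group, rows$i, rows$j), "dyad") +
    lookup(state$b, ind_key(rows$group, rows$i), "individual")
  eta <- eta + if (isTRUE(spec$directional)) {
    lookup(state$d, ind_key(rows$group, rows$j), "recipient")
  } else {
    lookup(state$b, ind_key(rows$group, rows$j), "individual")
  }
  if (isTRUE(spec$include_covariates)) {
    X <- dyad_design_matrix(rows)
    delta <- state$delta[colnames(X)]
    if (anyNA(delta)) abort("state$delta lacks required covariate coefficients")
    eta <- eta + drop(X %*% delta)
  }
  eta
}

#' Log posterior of the hierarchical dyadic model
#'
#' Sum of the Bernoulli log likelihood over all rows at the inverse-logit of
#' the linear predictor, the normal log densities of every random effect in
#' `state` given its SD, and the log priors (`N(0, prior_sd_fixed^2)` for
#' fixed effects, `U(0, prior_sigma_upper)` for SDs). Returns `-Inf` (not an
#' error) when any SD lies outside its prior support; random effects present
#' in `state` but absent from the table still contribute their prior
#' density (shrinkage of unobserved dyads).
#'
#' @inheritParams linear_predictor
#' @param tbl a `dyad_scans` tibble built for `spec$behaviour` (may have
#'   zero rows, giving the prior-only value).
#' @return scalar log posterior density (unnormalized).
#' @export
log_posterior <- function(state, tbl, spec) {
  directional <- isTRUE(spec$directional)
  a <- state$a %||% setNames(numeric(0), character(0))
  b <- state$b %||% setNames(numeric(0), character(0))
  cc <- state$c %||% setNames(numeric(0), character(0))
  dd <- state$d %||% setNames(numeric(0), character(0))
  delta <- state$delta %||% numeric(0)

  if (nrow(tbl) > 0) {
    g <- match(tbl$group, names(a)) - 1L
    i1 <- match(ind_key(tbl$group, tbl$i), names(b)) - 1L
    dk <- match(dyad_key(tbl$group, tbl$i, tbl$j), names(cc)) - 1L
    i2 <- if (directional) match(ind_key(tbl$group, tbl$j), names(dd)) - 1L
          else match(ind_key(tbl$group, tbl$j), names(b)) - 1L
    if (anyNA(g) || anyNA(i1) || anyNA(i2) || anyNA(dk)) {
      abort("state does not index every group/individual/dyad in the table")
    }
    X <- if (spec$include_covariates) dyad_design_matrix(tbl)[, names(delta), drop = FALSE]
         else matrix(0, nrow(tbl), length(delta))
    y <- as.integer(tbl$y); yprev <- as.integer(tbl$y_prev)
  } else {
    g <- i1 <- i2 <- dk <- integer(0)
    X <- matrix(0, 0, length(delta))
    y <- yprev <- integer(0)
  }
  cpp_log_posterior(
    y, yprev, g, i1, i2, dk, X,
    state$alpha, state$beta_last, unname(delta),
    unname(a), unname(b), unname(cc), unname(dd),
    state$sigma_group, state$sigma_ind, state$sigma_dyad,
    state$sigma_rec %||% 1,
    directional, spec$prior_sd_fixed, spec$prior_sigma_upper
  )
}

#' Fit the hierarchical dyadic model by MCMC
#'
#' Samples the posterior with an adaptive random-walk Metropolis-within-
#' Gibbs sampler on a non-centred parameterization (each random effect as a
#' standard-normal z-score scaled by its SD), which remains well behaved
#' when an SD is close to zero. Proposal scales adapt during warmup only.
#' Chains are initialized at zero effects and unit SDs with a small
#' seed-controlled jitter.
#'
#' @param tbl a `dyad_scans` tibble from [build_dyad_scans()].
#' @param spec a [model_spec()] for the same behaviour.
#' @return An object of class `scan_fit`: retained draws (natural scale)
#'   with chain labels, the spec, index tables, and the per-edge covariate
#'   design needed to rebuild linear predictors `B_ijk`.
#' @export
fit_scan_model <- function(tbl, spec) {
  stopifnot(inherits(tbl, "dyad_scans"), inherits(spec, "model_spec"))
  idx <- build_index(tbl, spec)
  if (length(idx$groups) < 2) {
    warn("fewer than 2 groups: sigma_group is only weakly identified")
  }
  ng <- length(idx$groups); ni <- nrow(idx$inds); nd <- nrow(idx$dyads)
  p <- ncol(idx$X)
  directional <- spec$directional

  par_names <- c(
    "alpha", "beta_last",
    if (p > 0) paste0("delta_", colnames(idx$X)),
    "sigma_group", "sigma_ind", "sigma_dyad",
    if (directional) "sigma_rec",
    paste0("a[", idx$groups, "]"),
    paste0("b[", ind_key(idx$inds$group, idx$inds$id), "]"),
    paste0("c[", idx$dyads$key, "]"),
    if (directional) paste0("d[", ind_key(idx$inds$group, idx$inds$id), "]")
  )

  moves <- covariate_translation_moves(tbl, idx, spec)

  t0 <- proc.time()[["elapsed"]]
  chains <- purrr::map(seq_len(spec$chains), function(ch) {
    set.seed(spec$seed * 1000L + ch)
    res <- cpp_fit_chain(
      idx$y, idx$yprev, idx$g, idx$i1, idx$i2, idx$d, idx$X,
      ng, ni, nd, directional,
      spec$prior_sd_fixed, spec$prior_sigma_upper,
      spec$iterations, spec$warmup, spec$thinning,
      0.1, moves
    )
    res$draws
  })
  draws <- do.call(rbind, chains)
  colnames(draws) <- par_names
  chain <- rep(seq_len(spec$chains), vapply(chains, nrow, integer(1)))

  structure(
    list(
      draws = draws, chain = chain, spec = spec,
      behaviour = spec$behaviour, directional = directional,
      index = idx[c("groups", "inds", "dyads")],
      edges = fit_edges(tbl, spec),
      n_rows = nrow(tbl),
      runtime = proc.time()[["elapsed"]] - t0
    ),
    class = "scan_fit"
  )
}

# Exact eta-invariant translation moves between sex-role subsets of the
# individual-effect blocks and the fixed effects. A subset qualifies when
# its per-row occupancy count is an exact linear combination of the
# intercept and the covariate columns (e.g. the number of male members of
# an undirected dyad is mixed_sex + 2 * male_male); shifting the subset
# and compensating those coefficients then leaves every linear predictor
# unchanged, so the sampler can traverse the subset-mean/sex-coefficient
# ridge at prior cost only.
covariate_translation_moves <- function(tbl, idx, spec) {
  moves <- list()
  sex_lookup <- attr(tbl, "ind_sex")
  if (!spec$include_covariates || is.null(sex_lookup) || ncol(idx$X) == 0) {
    return(moves)
  }
  ikeys <- ind_key(idx$inds$group, idx$inds$id)
  sexv <- unname(sex_lookup[ikeys])
  if (anyNA(sexv)) return(moves)
  M <- cbind(1, idx$X)
  qrM <- qr(M)
  add_move <- function(blk, members, w, g_row) {
    keep <- w != 0
    if (!any(keep)) return(invisible())
    lam <- qr.coef(qrM, g_row)
    lam[is.na(lam)] <- 0
    if (max(abs(g_row - drop(M %*% lam))) < 1e-8) {
      moves[[length(moves) + 1]] <<- list(
        blk = as.integer(blk[keep]), idx = as.integer(members[keep] - 1L),
        w = as.numeric(w[keep]),
        lambda0 = unname(lam[1]), lambda = unname(lam[-1])
      )
    }
    invisible()
  }
  ni <- nrow(idx$inds)
  # sex-role subsets of the individual blocks (occupancy counts are exact
  # combinations of the sex-class indicators)
  for (s in c("F", "M")) {
    in_s <- sexv == s
    members <- which(in_s)
    if (length(members) == 0 || length(members) == length(sexv)) next
    w1 <- rep(1, length(members))
    if (spec$directional) {
      add_move(rep(0L, length(members)), members, w1,
               as.numeric(in_s[idx$i1 + 1L]))
      add_move(rep(1L, length(members)), members, w1,
               as.numeric(in_s[idx$i2 + 1L]))
    } else {
      add_move(rep(0L, length(members)), members, w1,
               as.numeric(in_s[idx$i1 + 1L]) + as.numeric(in_s[idx$i2 + 1L]))
    }
  }
  # covariate-weighted shifts of the dyad block: a dyad-constant covariate
  # x_j is exactly absorbed by shifting c_d by e * x_j(d), compensated by
  # delta_j; direction-asymmetric covariates fail the exactness check and
  # are skipped (the shared dyad effect cannot absorb them)
  nd <- nrow(idx$dyads)
  first_row <- match(seq_len(nd) - 1L, idx$d)
  for (j in seq_len(ncol(idx$X))) {
    w <- idx$X[first_row, j]
    if (all(w == 0)) next
    add_move(rep(2L, nd), seq_len(nd), w, w[idx$d + 1L])
  }
  # signed (groomer - recipient) age covariate rides on age-linear trends
  # in the groomer and recipient blocks jointly
  age_lookup <- attr(tbl, "ind_age")
  age_std <- attr(tbl, "age_std")
  if (spec$directional && !is.null(age_lookup) &&
      "age_diff" %in% colnames(idx$X)) {
    agev <- unname(age_lookup[ikeys]) / age_std[["scale"]]
    if (!anyNA(agev)) {
      g_row <- agev[idx$i1 + 1L] - agev[idx$i2 + 1L]
      add_move(c(rep(0L, ni), rep(1L, ni)), c(seq_len(ni), seq_len(ni)),
               c(agev, -agev), g_row)
    }
  }
  moves
}

# one row per network edge (ordered pair for grooming, unordered otherwise)
# with its dyad key and covariate design
fit_edges <- function(tbl, spec) {
  cols <- c("group", "i", "j", "age_diff_std", "maternal_kin",
            "paternal_kin", "sex_class")
  edges <- dplyr::distinct(dplyr::as_tibble(tbl)[, cols])
  edges$dyad <- dyad_key(edges$group, edges$i, edges$j)
  etbl <- new_dyad_scans(edges, spec$behaviour, spec$directional,
                         attr(tbl, "age_std"))
  edges_x <- dyad_design_matrix(etbl)
  list(edges = edges, X = edges_x)
}

#' @export
print.scan_fit <- function(x, ...) {
  cat("<scan_fit> ", x$behaviour, ": ", nrow(x$draws), " draws (",
      x$spec$chains, " chains) over ", x$n_rows, " dyad-scan rows; ",
      length(x$index$groups), " groups, ", nrow(x$index$inds),
      " individuals, ", nrow(x$index$dyads), " dyads\n", sep = "")
  invisible(x)
}

#' Posterior draws as a tibble
#'
#' @param fit a `scan_fit`.
#' @param pars optional regular expression selecting parameter columns.
#' @return tibble with `.chain`, `.draw` and one column per parameter.
#' @export
posterior_draws <- function(fit, pars = NULL) {
  stopifnot(inherits(fit, "scan_fit"))
  m <- fit$draws
  if (!is.null(pars)) m <- m[, grepl(pars, colnames(m)), drop = FALSE]
  out <- tibble::as_tibble(m, .name_repair = "minimal")
  dplyr::bind_cols(tibble::tibble(.chain = fit$chain,
                                  .draw = seq_len(nrow(m))), out)
}

#' Persist posterior draws as a columnar CSV with a manifest
#'
#' Writes `draws.csv` (one column per parameter plus `.chain`) and
#' `manifest.json` naming every parameter column, the spec settings and the
#' draw count, so a fit can be archived and re-read without the package.
#'
#' @param fit a `scan_fit`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scan_fit <- function(fit, dir) {
  stopifnot(inherits(fit, "scan_fit"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(posterior_draws(fit), file.path(dir, "draws.csv"))
  jsonlite::write_json(
    list(
      behaviour = fit$behaviour, directional = fit$directional,
      parameters = colnames(fit$draws),
      chains = fit$spec$chains, draws = nrow(fit$draws),
      iterations = fit$spec$iterations, warmup = fit$spec$warmup,
      thinning = fit$spec$thinning, seed = fit$spec$seed,
      prior_sd_fixed = fit$spec$prior_sd_fixed,
      prior_sigma_upper = fit$spec$prior_sigma_upper,
      include_covariates = fit$spec$include_covariates,
      package_version = as.character(utils::packageVersion("scansoc"))
    ),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' @rdname fit_scan_model
#' @param x a `scan_fit` object.
#' @param pars optional regular expression selecting parameters (defaults to
#'   the scalar parameters: fixed effects, covariate coefficients and SDs).
#' @param ... unused.
#' @export
tidy.scan_fit <- function(x, pars = "^(alpha|beta_last|delta_|sigma_)", ...) {
  m <- x$draws[, grepl(pars, colnames(x$draws)), drop = FALSE]
  diag <- fit_diagnostics_matrix(m, x$chain)
  purrr::map_dfr(colnames(m), function(nm) {
    h <- hpdi(m[, nm], 0.95)
    tibble::tibble(
      term = nm, estimate = mean(m[, nm]), std.error = sd(m[, nm]),
      conf.low = h[["lower"]], conf.high = h[["upper"]]
    )
  }) |>
    dplyr::left_join(diag, by = "term")
}

#' @rdname fit_scan_model
#' @export
glance.scan_fit <- function(x, ...) {
  d <- fit_diagnostics(x)
  tibble::tibble(
    behaviour = x$behaviour,
    chains = x$spec$chains,
    draws = nrow(x$draws),
    max_rhat = max(d$rhat, na.rm = TRUE),
    min_ess = min(d$ess, na.rm = TRUE),
    converged = !any(d$flag, na.rm = TRUE)
  )
}
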