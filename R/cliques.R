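#' Connected interaction components within one scan
#'
#' Treats the dyads recorded as interacting in a single scan as edges of a
#' graph (grooming edges undirected) and returns the sizes of the connected
#' components. A component of size 3 or more is the observable signature of
#' a multi-individual interaction clique.
#'
#' @param events tibble of event rows from a single `(group, day, scan)`,
#'   with columns `actor` and `partner`.
#' @return integer vector of component sizes, decreasing; `integer(0)` when
#'   there are no edges.
#' @export
scan_components <- function(events) {
  if (nrow(events) == 0) return(integer(0))
  g <- igraph::graph_from_data_frame(
    events[, c("actor", "partner")], directed = FALSE
  )
  sort(as.integer(igraph::components(g)$csize), decreasing = TRUE)
}

#' Observed clique rate of a group
#'
#' Fraction of a group's scans containing at least one connected component
#' of 3 or more interacting individuals. Only scans with at least
#' `min_visible` individuals in sight are counted: a scan where fewer than
#' three animals were visible cannot show a clique.
#'
#' @param x a `scan_events` object.
#' @param behaviour behaviour to score.
#' @param group group label.
#' @param min_visible minimum number of visible individuals for a scan to
#'   enter the denominator.
#' @return A list with `rate`, the number of qualifying scans `n_scans`, and
#'   `visible_counts` (visible individuals per qualifying scan, used to
#'   match the predictive simulation).
#' @export
observed_clique_rate <- function(x, behaviour, group, min_visible = 3) {
  check_behaviour(behaviour)
  stopifnot(inherits(x, "scan_events"))
  vis <- x$visibility |> dplyr::filter(.data$group == !!group)
  if (nrow(vis) == 0) abort(paste0("no scans recorded for group ", group))
  nvis <- lengths(vis$ids)
  keep <- nvis >= min_visible
  if (!any(keep)) abort(paste0("no scans with >= ", min_visible,
                               " visible individuals in group ", group))
  vis <- vis[keep, ]
  ev <- x$events |>
    dplyr::filter(.data$behaviour == !!behaviour, .data$group == !!group)
  # only scans with >= 2 events can contain a component of size >= 3
  key <- paste(ev$day, ev$scan)
  vkey <- paste(vis$day, vis$scan)
  hits <- 0L
  for (k in unique(key[duplicated(key)])) {
    if (!k %in% vkey) next
    sizes <- scan_components(ev[key == k, ])
    if (length(sizes) > 0 && max(sizes) >= 3) hits <- hits + 1L
  }
  list(rate = hits / nrow(vis), n_scans = nrow(vis),
       visible_counts = nvis[keep])
}

#' Posterior-predictive clique rate under dyadic independence
#'
#' Simulates scans in which every dyad of the group interacts independently
#' with its posterior edge probability, and computes the distribution of the
#' clique rate (fraction of scans with a connected component of size >= 3).
#' Because edges are drawn independently, this is the rate *predicted by the
#' dyadic interaction rates alone*; comparing it with the observed rate
#' quantifies any excess tendency to congregate. Each simulation uses one
#' posterior draw, so the interval reflects both parameter uncertainty and
#' sampling noise at the observed number of scans.
#'
#' For grooming, the two ordered edges of a pair are combined into the
#' probability that the pair interacts in either direction
#' (`1 - (1-w_ij)(1-w_ji)`).
#'
#' @param net a `network_posterior`.
#' @param group group label.
#' @param n_scans scans per simulated dataset (match the observed count).
#' @param n_sims number of simulated datasets (>= 100).
#' @param seed integer seed.
#' @param visible_counts optional integer vector of observed per-scan
#'   visible counts; each simulated scan then restricts interactions to a
#'   random subset of that size, matching observed visibility.
#' @param lag_aware also propagate the fitted within-day autocorrelation by
#'   simulating each dyad as its two-state Markov chain started at
#'   stationarity (scans within a simulated day of length `scans_per_day`).
#' @param scans_per_day day length for the lag-aware variant.
#' @return A `predictive_cliques` object: list with the simulated `rates`,
#'   their `mean`, the central 95% `interval`, and the simulation settings.
#' @export
predictive_clique_rate <- function(net, group, n_scans, n_sims = 200, seed = 1,
                                   visible_counts = NULL, lag_aware = FALSE,
                                   scans_per_day = 10) {
  stopifnot(inherits(net, "network_posterior"))
  if (n_sims < 100) abort("n_sims must be at least 100")
  sel <- which(net$edges$group == group)
  if (length(sel) == 0) abort(paste0("group not in network: ", group))
  ids <- net$nodes[[group]]
  set.seed(seed)
  draw_idx <- sample.int(nrow(net$weights), n_sims, replace = TRUE)

  if (!lag_aware) {
    W <- net$weights[draw_idx, sel, drop = FALSE]
  } else {
    # per-dyad chain simulated within days and scored cross-sectionally:
    # equivalent to drawing the day's first scan at stationarity, then
    # stepping p0/p1; marginally each scan is still stationary, so we can
    # score scans independently with the stationary weight. The lag only
    # matters through scan-to-scan dependence, which the clique statistic
    # (a per-scan property averaged over scans) is insensitive to in mean
    # but not in spread; simulate the chain explicitly.
    return(predictive_clique_rate_lagged(net, group, n_scans, n_sims,
                                         draw_idx, sel, ids, visible_counts,
                                         scans_per_day))
  }
  ei <- net$edges$i[sel]
  ej <- net$edges$j[sel]
  if (net$directional) {
    # combine the two ordered edges of each unordered pair
    key <- paste(pmin(ei, ej), pmax(ei, ej))
    first <- !duplicated(key)
    other <- match(key, key[first])
    Wc <- 1 - (1 - W[, first, drop = FALSE])
    for (e in which(!first)) {
      tgt <- other[e]
      Wc[, tgt] <- 1 - (1 - Wc[, tgt]) * (1 - W[, e])
    }
    W <- Wc
    ei <- ei[first]; ej <- ej[first]
  }
  di <- match(ei, ids) - 1L
  dj <- match(ej, ids) - 1L
  vc <- if (is.null(visible_counts)) integer(0) else as.integer(visible_counts)
  rates <- cpp_clique_rates(W, di, dj, length(ids), as.integer(n_scans), vc)
  new_predictive_cliques(rates, n_scans, n_sims)
}

new_predictive_cliques <- function(rates, n_scans, n_sims) {
  structure(
    list(
      rates = rates, mean = mean(rates),
      interval = unname(quantile(rates, c(0.025, 0.975))),
      n_scans = n_scans, n_sims = n_sims
    ),
    class = "predictive_cliques"
  )
}

predictive_clique_rate_lagged <- function(net, group, n_scans, n_sims,
                                          draw_idx, sel, ids, visible_counts,
                                          scans_per_day) {
  ei <- match(net$edges$i[sel], ids)
  ej <- match(net$edges$j[sel], ids)
  nd <- length(sel)
  n_nodes <- length(ids)
  rates <- numeric(n_sims)
  for (s in seq_len(n_sims)) {
    dr <- draw_idx[s]
    eta0 <- net$eta0[dr, sel]
    p0 <- plogis(eta0)
    p1 <- plogis(eta0 + net$beta_last[dr])
    w <- p0 / (1 - p1 + p0)
    hits <- 0L
    yprev <- rbinom(nd, 1, w)
    for (sc in seq_len(n_scans)) {
      if ((sc - 1) %% scans_per_day == 0) yprev <- rbinom(nd, 1, w)
      else yprev <- rbinom(nd, 1, ifelse(yprev == 1, p1, p0))
      act <- yprev == 1
      if (!is.null(visible_counts)) {
        k <- sample(visible_counts, 1)
        visn <- sample.int(n_nodes, min(k, n_nodes))
        act <- act & ei %in% visn & ej %in% visn
      }
      if (sum(act) >= 2 &&
          max_component_size(ei[act], ej[act], n_nodes) >= 3) hits <- hits + 1L
    }
    rates[s] <- hits / n_scans
  }
  new_predictive_cliques(rates, n_scans, n_sims)
}

# union-find max component size over an edge list
max_component_size <- function(ei, ej, n) {
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  size <- rep(1L, n)
  best <- 1L
  for (e in seq_along(ei)) {
    ra <- find(ei[e]); rb <- find(ej[e])
    if (ra != rb) {
      parent[ra] <- rb
      size[rb] <- size[rb] + size[ra]
      if (size[rb] > best) best <- size[rb]
    }
  }
  best
}

#' @export
print.predictive_cliques <- function(x, ...) {
  cat("<predictive_cliques> mean ", signif(x$mean, 3), ", 95% interval [",
      signif(x$interval[1], 3), ", ", signif(x$interval[2], 3), "] from ",
      x$n_sims, " simulations of ", x$n_scans, " scans\n", sep = "")
  invisible(x)
}

#' Observed-vs-predicted clique excess
#'
#' @param observed result of [observed_clique_rate()] (or a single observed
#'   rate).
#' @param predictive a `predictive_cliques` object.
#' @return one-row tibble: observed rate, predictive mean and 95% interval,
#'   `excess = observed - predictive mean`, and the evidence flag (observed
#'   outside the predictive interval).
#' @export
clique_excess <- function(observed, predictive) {
  stopifnot(inherits(predictive, "predictive_cliques"))
  obs <- if (is.list(observed)) observed$rate else observed
  tibble::tibble(
    observed = obs,
    pred_mean = predictive$mean,
    pred_lower = predictive$interval[1],
    pred_upper = predictive$interval[2],
    excess = obs - predictive$mean,
    evidence = obs < predictive$interval[1] | obs > predictive$interval[2]
  )
}

#' Clique report for every group
#'
#' Runs the observed-vs-predicted clique comparison for each group of a
#' fitted behaviour: the observed rate uses scans with at least 3 visible
#' individuals, and the predictive simulation matches the observed number of
#' scans and per-scan visible counts.
#'
#' @param x the `scan_events` the model was fitted to.
#' @param net the `network_posterior` derived from the fit.
#' @param n_sims simulations per group.
#' @param seed integer seed.
#' @param match_visibility pass the observed visible counts into the
#'   predictive simulation.
#' @return tibble with one row per group.
#' @export
clique_report <- function(x, net, n_sims = 200, seed = 1,
                          match_visibility = TRUE) {
  stopifnot(inherits(x, "scan_events"), inherits(net, "network_posterior"))
  purrr::map_dfr(net$groups, function(g) {
    obs <- observed_clique_rate(x, net$behaviour, g)
    pred <- predictive_clique_rate(
      net, g, n_scans = obs$n_scans, n_sims = n_sims,
      seed = seed + match(g, net$groups),
      visible_counts = if (match_visibility) obs$visible_counts else NULL
    )
    dplyr::bind_cols(tibble::tibble(group = g), clique_excess(obs, pred))
  })
}
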