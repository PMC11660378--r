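#' Stationary probability of a dyad's two-state interaction chain
#'
#' Under the lagged model, a dyad's scan-to-scan series is a two-state
#' Markov chain with `p0 = plogis(alpha + B)` (probability of interacting
#' given it was not at the previous scan) and `p1 = plogis(alpha + B +
#' beta_last)` (given it was). The long-run proportion of time interacting
#' is `p0 / (1 - p1 + p0)`, which is the internally consistent "probability
#' of interacting at a random point in time" and collapses to
#' `plogis(alpha + B)` when `beta_last = 0`.
#'
#' @param alpha population intercept (log-odds).
#' @param beta_last autocorrelation coefficient (log-odds).
#' @param B dyad-specific linear predictor (random effects plus any
#'   covariate contribution).
#' @return numeric in \[0, 1\], vectorized over the inputs.
#' @export
stationary_edge_prob <- function(alpha, beta_last, B) {
  p0 <- plogis(alpha + B)
  p1 <- plogis(alpha + B + beta_last)
  p0 / (1 - p1 + p0)
}

#' Derive posterior social networks from a fitted model
#'
#' For every retained posterior draw and every observed dyad, computes the
#' stationary edge probability from that draw's `alpha`, `beta_last` and
#' dyad linear predictor `B_ijk` (optionally including the dyad-covariate
#' contribution, so the network reflects realized propensities, kin effects
#' included). Grooming networks are directed (one edge per ordered pair);
#' other behaviours give symmetric weights.
#'
#' @param fit a `scan_fit`.
#' @param include_covariates include `x'delta` in the edge predictor (only
#'   possible when the model was fitted with covariates). Set to `FALSE`
#'   for the random-effects-only network.
#' @param ndraws optionally thin to this many evenly spaced draws.
#' @return A `network_posterior`: list with `weights` (draws x edges
#'   matrix), `edges` (tibble `group,i,j`), per-draw `alpha`/`beta_last`/
#'   `eta0` needed for lag-aware simulation, and bookkeeping columns.
#' @export
derive_networks <- function(fit, include_covariates = NULL, ndraws = NULL) {
  stopifnot(inherits(fit, "scan_fit"))
  include_covariates <- include_covariates %||% fit$spec$include_covariates
  if (include_covariates && !fit$spec$include_covariates) {
    abort("fit has no covariate coefficients; refit with include_covariates = TRUE")
  }
  draws <- fit$draws
  if (!is.null(ndraws) && ndraws < nrow(draws)) {
    keep <- unique(round(seq(1, nrow(draws), length.out = ndraws)))
    draws <- draws[keep, , drop = FALSE]
  }
  edges <- fit$edges$edges
  ne <- nrow(edges)
  a_cols <- paste0("a[", edges$group, "]")
  b_cols <- paste0("b[", ind_key(edges$group, edges$i), "]")
  c_cols <- paste0("c[", edges$dyad, "]")
  second <- if (fit$directional) paste0("d[", ind_key(edges$group, edges$j), "]")
            else paste0("b[", ind_key(edges$group, edges$j), "]")
  B <- draws[, a_cols, drop = FALSE] + draws[, b_cols, drop = FALSE] +
    draws[, c_cols, drop = FALSE] + draws[, second, drop = FALSE]
  if (include_covariates) {
    X <- fit$edges$X
    delta <- draws[, paste0("delta_", colnames(X)), drop = FALSE]
    B <- B + delta %*% t(X)
  }
  alpha <- draws[, "alpha"]
  beta <- draws[, "beta_last"]
  eta0 <- sweep(B, 1, alpha, "+")
  W <- stationary_edge_prob(
    matrix(alpha, nrow(B), ne), matrix(beta, nrow(B), ne), B
  )
  nodes <- split(fit$index$inds$id, fit$index$inds$group)
  structure(
    list(
      weights = W, edges = dplyr::select(edges, "group", "i", "j"),
      directional = fit$directional, groups = fit$index$groups,
      nodes = nodes, alpha = alpha, beta_last = beta, eta0 = eta0,
      behaviour = fit$behaviour
    ),
    class = "network_posterior"
  )
}

#' @export
print.network_posterior <- function(x, ...) {
  cat("<network_posterior> ", x$behaviour, ": ", nrow(x$weights), " draws x ",
      ncol(x$weights), " ", if (x$directional) "directed" else "undirected",
      " edges in ", length(x$groups), " groups\n", sep = "")
  invisible(x)
}

#' Edge-weight matrix of one group at one posterior draw
#'
#' @param net a `network_posterior`.
#' @param group group label.
#' @param draw draw index (row of the weights matrix).
#' @return square matrix of edge probabilities (directed for grooming,
#'   symmetric otherwise), zero diagonal, individuals as dimnames.
#' @export
edge_matrix <- function(net, group, draw = 1) {
  ids <- net$nodes[[group]]
  sel <- which(net$edges$group == group)
  W <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  wi <- match(net$edges$i[sel], ids)
  wj <- match(net$edges$j[sel], ids)
  W[cbind(wi, wj)] <- net$weights[draw, sel]
  if (!net$directional) W[cbind(wj, wi)] <- net$weights[draw, sel]
  W
}

#' Node strength
#'
#' Total connection of a node: the sum of its edge weights. For a directed
#' (grooming) matrix, strength is total involvement, out-strength plus
#' in-strength.
#'
#' @param W square weight matrix (rows = source for directed networks).
#' @param node node name or index; `NULL` returns all nodes.
#' @param directional treat `W` as directed.
#' @return named numeric vector (or scalar when `node` is given).
#' @export
node_strength <- function(W, node = NULL, directional = FALSE) {
  s <- if (directional) rowSums(W) + colSums(W) else rowSums(W)
  if (is.null(node)) s else s[[node]]
}

#' Probabilistic clustering coefficient
#'
#' Weighted clustering for edge-probability networks: for node `i`,
#' `C_i = sum_{j,k} w_ij w_jk w_ik / sum_{j != k} w_ij w_ik`, the probability
#' that two random interaction partners of `i` are themselves connected,
#' weighting each partner pair by its joint probability. Equals the binary
#' clustering coefficient when all weights are 0 or 1. Nodes whose
#' denominator is zero (fewer than two positive-probability partners) get
#' `NA`.
#'
#' @param W square symmetric matrix of edge probabilities in \[0, 1\] with
#'   zero diagonal. Directed grooming networks should be symmetrized first
#'   (see [group_metrics()]).
#' @param node node name or index; `NULL` returns all nodes.
#' @return numeric in \[0, 1\] (or `NA` where undefined).
#' @export
cluster_coefficient <- function(W, node = NULL) {
  if (nrow(W) < 3) abort("clustering needs at least 3 nodes")
  if (any(W < 0 | W > 1)) abort("edge weights must lie in [0, 1]")
  diag(W) <- 0
  num <- diag(W %*% W %*% W)
  s <- rowSums(W)
  q <- rowSums(W^2)
  den <- s^2 - q
  cc <- ifelse(den > 0, num / den, NA_real_)
  names(cc) <- rownames(W)
  if (is.null(node)) cc else cc[[node]]
}

#' Posterior group means and contrasts of a network metric
#'
#' For each posterior draw, computes the chosen node metric for every
#' individual and averages within groups; group-level posterior means, 95%
#' HPDIs, and all pairwise between-group differences (with evidence flags
#' when the difference's HPDI excludes zero) are then reported. Grooming
#' clustering is computed on symmetrized weights `(w_ij + w_ji) / 2`.
#'
#' @param net a `network_posterior`.
#' @param metric `"strength"` or `"clustering"`.
#' @return A `group_metrics` object: list with tibbles `summary` (group,
#'   mean, lower, upper) and `contrasts` (group1, group2, mean, lower,
#'   upper, evidence), the per-draw group-mean matrix `draws`, and `metric`.
#' @export
group_metrics <- function(net, metric = c("strength", "clustering")) {
  stopifnot(inherits(net, "network_posterior"))
  metric <- match.arg(metric)
  ndr <- nrow(net$weights)
  groups <- net$groups
  gm <- matrix(NA_real_, ndr, length(groups), dimnames = list(NULL, groups))

  if (metric == "strength") {
    # mean strength over nodes = 2 * (sum of group's edge weights) / n_nodes
    # for both directed (give + receive) and undirected networks
    for (gi in seq_along(groups)) {
      sel <- net$edges$group == groups[gi]
      nn <- length(net$nodes[[groups[gi]]])
      gm[, gi] <- 2 * rowSums(net$weights[, sel, drop = FALSE]) / nn
    }
  } else {
    for (gi in seq_along(groups)) {
      g <- groups[gi]
      ids <- net$nodes[[g]]
      if (length(ids) < 3) {
        warn(paste0("group ", g, " has fewer than 3 nodes: clustering is missing"))
        next
      }
      sel <- which(net$edges$group == g)
      wi <- match(net$edges$i[sel], ids)
      wj <- match(net$edges$j[sel], ids)
      n <- length(ids)
      W <- matrix(0, n, n)
      for (dr in seq_len(ndr)) {
        w <- net$weights[dr, sel]
        W[] <- 0
        if (net$directional) {
          W[cbind(wi, wj)] <- w
          Ws <- (W + t(W)) / 2
        } else {
          W[cbind(wi, wj)] <- w
          W[cbind(wj, wi)] <- w
          Ws <- W
        }
        cc <- cluster_coefficient(Ws)
        gm[dr, gi] <- mean(cc, na.rm = TRUE)
      }
    }
  }

  summary <- purrr::map_dfr(seq_along(groups), function(gi) {
    v <- gm[, gi]
    if (all(is.na(v))) {
      return(tibble::tibble(group = groups[gi], mean = NA_real_,
                            lower = NA_real_, upper = NA_real_))
    }
    h <- hpdi(v, 0.95)
    tibble::tibble(group = groups[gi], mean = mean(v),
                   lower = h[["lower"]], upper = h[["upper"]])
  })
  pairs <- utils::combn(groups, 2)
  contrasts <- purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    g1 <- pairs[1, k]; g2 <- pairs[2, k]
    dv <- gm[, g1] - gm[, g2]
    if (all(is.na(dv))) {
      return(tibble::tibble(group1 = g1, group2 = g2, mean = NA_real_,
                            lower = NA_real_, upper = NA_real_, evidence = NA))
    }
    h <- hpdi(dv, 0.95)
    tibble::tibble(group1 = g1, group2 = g2, mean = mean(dv),
                   lower = h[["lower"]], upper = h[["upper"]],
                   evidence = evidence_flag(dv, 0))
  })
  structure(
    list(summary = summary, contrasts = contrasts, draws = gm,
         metric = metric, behaviour = net$behaviour),
    class = "group_metrics"
  )
}

#' @export
print.group_metrics <- function(x, ...) {
  cat("<group_metrics> ", x$behaviour, " ", x$metric, "\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' Posterior summaries of every network edge
#'
#' @param net a `network_posterior`.
#' @return tibble with `group,i,j,mean,lower,upper` per edge.
#' @export
network_edges <- function(net) {
  stopifnot(inherits(net, "network_posterior"))
  purrr::map_dfr(seq_len(ncol(net$weights)), function(e) {
    w <- net$weights[, e]
    h <- if (length(w) >= 2) hpdi(w, 0.95) else c(lower = w, upper = w)
    tibble::tibble(
      group = net$edges$group[e], i = net$edges$i[e], j = net$edges$j[e],
      mean = mean(w), lower = h[["lower"]], upper = h[["upper"]]
    )
  })
}

#' @describeIn group_metrics interval plot of the group means.
#' @param object a `group_metrics`.
#' @param ... unused.
#' @export
autoplot.group_metrics <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$group, y = .data$mean)) +
    ggplot2::geom_point(size = 2, colour = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                           width = 0.15) +
    ggplot2::labs(x = "group", y = paste("mean", object$metric)) +
    ggplot2::theme_minimal()
}
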