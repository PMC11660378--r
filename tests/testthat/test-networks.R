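test_that("stationary edge probability collapses to plogis without autocorrelation", {
  expect_equal(stationary_edge_prob(-1.2, 0, 0.4), plogis(-0.8))
  expect_lt(stationary_edge_prob(-50, 2, 0), 1e-15)
  expect_gt(stationary_edge_prob(50, 2, 0), 1 - 1e-15)
})

test_that("stationary edge probability matches long-run chain occupancy", {
  # p0 = 0.2, p1 = 0.6 has stationary probability 1/3
  alpha <- qlogis(0.2)
  beta <- qlogis(0.6) - qlogis(0.2)
  expect_equal(stationary_edge_prob(alpha, beta, 0), 1 / 3, tolerance = 1e-12)
  set.seed(21)
  occ <- simulate_chain_occupancy(0.2, 0.6)
  expect_lt(abs(stationary_edge_prob(alpha, beta, 0) - occ["mean"]),
            3 * occ["se"])
})

test_that("stationary edge probability is strictly increasing in B and alpha", {
  B <- seq(-3, 3, length.out = 25)
  v <- stationary_edge_prob(-1, 1.5, B)
  expect_true(all(diff(v) > 0))
  a <- seq(-4, 2, length.out = 25)
  v2 <- stationary_edge_prob(a, 1.5, 0.3)
  expect_true(all(diff(v2) > 0))
})

make_known_fit <- function(alpha = qlogis(0.05), beta = 0) {
  # two groups of three individuals, all random effects zero in the only draw
  inds <- tibble::tibble(group = rep(c("G1", "G2"), each = 3),
                         id = c("A", "B", "C", "D", "E", "F"))
  edges <- dplyr::bind_rows(
    tidyr::crossing(i = c("A", "B", "C"), j = c("A", "B", "C")) |>
      dplyr::filter(i < j) |> dplyr::mutate(group = "G1"),
    tidyr::crossing(i = c("D", "E", "F"), j = c("D", "E", "F")) |>
      dplyr::filter(i < j) |> dplyr::mutate(group = "G2")
  ) |>
    dplyr::mutate(age_diff_std = 0, maternal_kin = 0L, paternal_kin = 0L,
                  sex_class = "FF", dyad = paste0(group, ":", i, ":", j))
  par_names <- c("alpha", "beta_last", "sigma_group", "sigma_ind", "sigma_dyad",
                 paste0("a[", c("G1", "G2"), "]"),
                 paste0("b[", inds$group, ":", inds$id, "]"),
                 paste0("c[", edges$dyad, "]"))
  draws <- matrix(0, 2, length(par_names), dimnames = list(NULL, par_names))
  draws[, "alpha"] <- alpha
  draws[, "beta_last"] <- beta
  draws[, c("sigma_group", "sigma_ind", "sigma_dyad")] <- 0.5
  structure(
    list(draws = draws, chain = c(1L, 2L),
         spec = model_spec("close_proximity", chains = 2),
         behaviour = "close_proximity", directional = FALSE,
         index = list(groups = c("G1", "G2"), inds = inds,
                      dyads = edges[, c("dyad", "group", "i", "j")] |>
                        dplyr::rename(key = "dyad")),
         edges = list(edges = edges,
                      X = matrix(0, nrow(edges), 0)),
         n_rows = 0),
    class = "scan_fit"
  )
}

test_that("with all effects zero every edge equals the intercept probability", {
  fit <- make_known_fit(alpha = qlogis(0.05), beta = 0)
  net <- derive_networks(fit, include_covariates = FALSE)
  expect_true(all(abs(net$weights - 0.05) < 1e-12))
  W <- edge_matrix(net, "G1", draw = 1)
  expect_equal(dim(W), c(3, 3))
  expect_true(all(abs(W[upper.tri(W)] - 0.05) < 1e-12))
  expect_equal(diag(W), setNames(rep(0, 3), c("A", "B", "C")))
  expect_true(isSymmetric(W))
})

test_that("relabelling individuals permutes the edge matrix identically", {
  fit <- make_known_fit()
  fit$draws[1, "b[G1:A]"] <- 1.3
  fit$draws[1, "c[G1:B:C]"] <- -0.8
  net <- derive_networks(fit, include_covariates = FALSE)
  W <- edge_matrix(net, "G1", draw = 1)
  # permute labels in the fit and check the matrix permutes with them
  perm <- c(A = "B", B = "C", C = "A")
  relabel <- function(s) {
    for (old in names(perm)) s <- gsub(paste0(":", old), paste0(":#", perm[[old]]), s, fixed = TRUE)
    gsub("#", "", s, fixed = TRUE)
  }
  fit2 <- fit
  cn <- colnames(fit2$draws)
  cn2 <- cn
  sel <- grepl("G1", cn)
  cn2[sel] <- vapply(cn[sel], relabel, character(1))
  # dyad keys must stay in sorted member order
  fix_key <- function(s) {
    m <- regmatches(s, regexec("^c\\[(G1):([A-Z]):([A-Z])\\]$", s))[[1]]
    if (length(m) == 0) return(s)
    paste0("c[", m[2], ":", min(m[3], m[4]), ":", max(m[3], m[4]), "]")
  }
  cn2 <- vapply(cn2, fix_key, character(1), USE.NAMES = FALSE)
  colnames(fit2$draws) <- cn2
  net2 <- derive_networks(fit2, include_covariates = FALSE)
  W2 <- edge_matrix(net2, "G1", draw = 1)
  ids <- c("A", "B", "C")
  expect_equal(W2[perm[ids], perm[ids]], W[ids, ids], ignore_attr = TRUE)
})

test_that("node strength sums incident edge weights, directed as give + receive", {
  W <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  W["a", "b"] <- 0.2; W["b", "a"] <- 0.2
  W["a", "c"] <- 0.3; W["c", "a"] <- 0.3
  expect_equal(node_strength(W, "a"), 0.5)
  expect_equal(node_strength(W, "b"), 0.2)
  expect_equal(unname(node_strength(W)["c"]), 0.3)
  # directed: out 0.1 + 0.2, in 0.3
  D <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  D["a", "b"] <- 0.1; D["a", "c"] <- 0.2; D["b", "a"] <- 0.3
  expect_equal(node_strength(D, "a", directional = TRUE), 0.6)
  Z <- matrix(0, 3, 3)
  expect_equal(node_strength(Z)[1], 0)
})

test_that("probabilistic clustering hits the binary limits", {
  tri <- matrix(1, 3, 3); diag(tri) <- 0
  expect_equal(unname(cluster_coefficient(tri)), rep(1, 3))
  star <- matrix(0, 3, 3)
  star[1, 2] <- star[2, 1] <- star[1, 3] <- star[3, 1] <- 1
  expect_equal(unname(cluster_coefficient(star, 1)), 0)
  expect_error(cluster_coefficient(matrix(2, 3, 3)), "\\[0, 1\\]")
  expect_error(cluster_coefficient(matrix(0.5, 2, 2)), "3 nodes")
})

test_that("clustering equals exhaustive triple enumeration", {
  W4 <- matrix(0, 4, 4)
  W4[1, 2] <- 0.5; W4[1, 3] <- 0.5; W4[1, 4] <- 0.2
  W4[2, 3] <- 1.0; W4[2, 4] <- 0; W4[3, 4] <- 0.4
  W4 <- W4 + t(W4)
  for (node in 1:4) {
    expect_equal(cluster_coefficient(W4, node),
                 naive_cluster_coefficient(W4, node), tolerance = 1e-12)
  }
  # binary graphs match igraph's transitivity-based local clustering
  set.seed(22)
  A <- matrix(rbinom(36, 1, 0.5), 6, 6); A[lower.tri(A)] <- t(A)[lower.tri(A)]
  diag(A) <- 0
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  ig <- igraph::transitivity(g, type = "local", isolates = "NaN")
  ours <- unname(cluster_coefficient(A))
  expect_equal(ours[!is.na(ours)], ig[!is.na(ours)], tolerance = 1e-12)
})

test_that("group metric posteriors summarise per-draw group means with contrasts", {
  fit <- make_known_fit(alpha = qlogis(0.1), beta = 0)
  fit$draws[2, "a[G2]"] <- 1  # second draw: G2 better connected
  net <- derive_networks(fit, include_covariates = FALSE)
  gm <- group_metrics(net, "strength")
  # draw 1: every edge 0.1, each node has 2 edges -> strength 0.2
  expect_equal(unname(gm$draws[1, "G1"]), 0.2, tolerance = 1e-12)
  w2 <- plogis(qlogis(0.1) + 1)
  expect_equal(unname(gm$draws[2, "G2"]), 2 * w2, tolerance = 1e-12)
  expect_equal(nrow(gm$contrasts), 1)
  # a group against itself would difference to exactly zero
  expect_true(all(gm$draws[, "G1"] - gm$draws[, "G1"] == 0))

  gmc <- group_metrics(net, "clustering")
  # uniform-weight graph: C = w for every node (numerator w^3*2, denom w^2*2)
  expect_equal(unname(gmc$draws[1, "G1"]), 0.1, tolerance = 1e-12)
})

test_that("network edge summaries carry HPD intervals", {
  fit <- make_known_fit()
  net <- derive_networks(fit, include_covariates = FALSE)
  ne <- network_edges(net)
  expect_equal(nrow(ne), 6)
  expect_true(all(ne$lower <= ne$mean & ne$mean <= ne$upper))
})

test_that("requesting covariate networks from a covariate-free fit errors", {
  fit <- make_known_fit()
  expect_error(derive_networks(fit, include_covariates = TRUE),
               "no covariate")
})
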