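test_that("linear_predictor adds up fixed, random and lag terms", {
  tbl <- new_dyad_scans(
    tibble::tibble(group = "G1", i = "A", j = "B", day = as.Date("2013-01-05"),
                   scan = 1L, y = 0L, y_prev = 0L, age_diff_std = 0,
                   maternal_kin = 0L, paternal_kin = 0L, sex_class = "FF"),
    "close_proximity", FALSE
  )
  spec <- model_spec("close_proximity")
  state <- list(alpha = -2, beta_last = 3,
                a = c(G1 = 0.5), b = c(`G1:A` = 0.25, `G1:B` = 0.25),
                c = c(`G1:A:B` = -0.5))
  expect_equal(linear_predictor(state, tbl, spec), -1.5)
  state0 <- list(alpha = -2, beta_last = 3, a = c(G1 = 0),
                 b = c(`G1:A` = 0, `G1:B` = 0), c = c(`G1:A:B` = 0))
  expect_equal(linear_predictor(state0, tbl, spec), -2)
  tbl$y_prev <- 1L
  expect_equal(linear_predictor(state0, tbl, spec), -2 + 3)
})

test_that("prior-only log posterior matches a hand-computed closed form", {
  empty <- new_dyad_scans(
    tibble::tibble(group = character(), i = character(), j = character(),
                   day = as.Date(character()), scan = integer(), y = integer(),
                   y_prev = integer(), age_diff_std = numeric(),
                   maternal_kin = integer(), paternal_kin = integer(),
                   sex_class = character()),
    "close_proximity", FALSE
  )
  spec <- model_spec("close_proximity")
  state <- list(alpha = 0, beta_last = 0,
                a = c(G1 = 0, G2 = 0), b = c(`G1:A` = 0, `G1:B` = 0),
                c = c(`G1:A:B` = 0),
                sigma_group = 1, sigma_ind = 1, sigma_dyad = 1)
  # 5 standard-normal densities at 0, two N(0,100) at 0, three U(0,10)
  expected <- 5 * (-0.5 * log(2 * pi)) +
    2 * (-0.5 * log(2 * pi) - log(100)) + 3 * (-log(10))
  expect_equal(log_posterior(state, empty, spec), expected, tolerance = 1e-12)
})

test_that("log posterior equals the naive per-row oracle on toy tables", {
  inst <- random_instance(101)
  lp <- log_posterior(inst$state, inst$tbl[1:5, ], inst$spec)
  expect_equal(lp, naive_log_posterior(inst$state, inst$tbl[1:5, ], inst$spec),
               tolerance = 1e-9)
})

test_that("SDs outside the uniform prior support give -Inf, not an error", {
  inst <- random_instance(102)
  st <- inst$state
  st$sigma_group <- inst$spec$prior_sigma_upper + 1
  expect_identical(log_posterior(st, inst$tbl, inst$spec), -Inf)
  st$sigma_group <- -0.5
  expect_identical(log_posterior(st, inst$tbl, inst$spec), -Inf)
})

test_that("log posterior is invariant to swapping dyad member labels", {
  inst <- random_instance(103)
  tbl <- inst$tbl
  swapped <- tbl
  swapped$i <- tbl$j
  swapped$j <- tbl$i
  swapped <- new_dyad_scans(swapped, attr(tbl, "behaviour"),
                            attr(tbl, "directional"), attr(tbl, "age_std"))
  expect_equal(log_posterior(inst$state, tbl, inst$spec),
               log_posterior(inst$state, swapped, inst$spec),
               tolerance = 1e-12)
})

test_that("unobserved dyads in the state only contribute prior shrinkage", {
  inst <- random_instance(104)
  st <- inst$state
  lp0 <- log_posterior(st, inst$tbl, inst$spec)
  st$c <- c(st$c, `G9:X:Y` = 0.7)
  lp1 <- log_posterior(st, inst$tbl, inst$spec)
  expect_equal(lp1 - lp0, dnorm(0.7, 0, st$sigma_dyad, log = TRUE),
               tolerance = 1e-10)
})

test_that("short fits respect the SD prior support and are seed-deterministic", {
  ds <- scan_fixture("tiny")
  tbl <- build_dyad_scans(ds$scans, ds$individuals, "close_proximity")
  spec <- model_spec("close_proximity", chains = 2, iterations = 300,
                     warmup = 150, seed = 9)
  fit1 <- fit_scan_model(tbl, spec)
  sig <- fit1$draws[, grepl("^sigma_", colnames(fit1$draws))]
  expect_true(all(sig >= 0 & sig <= 10))
  expect_equal(nrow(fit1$draws), 2 * 150)
  fit2 <- fit_scan_model(tbl, spec)
  expect_identical(fit1$draws, fit2$draws)
})

test_that("the grooming model fits with a recipient effect", {
  ds <- scan_fixture("tiny")
  tbl <- build_dyad_scans(ds$scans, ds$individuals, "grooming")
  spec <- model_spec("grooming", chains = 2, iterations = 300, warmup = 150,
                     seed = 10)
  fit <- fit_scan_model(tbl, spec)
  expect_true("sigma_rec" %in% colnames(fit$draws))
  expect_true(any(grepl("^d\\[", colnames(fit$draws))))
})

test_that("a table built for another behaviour is rejected", {
  ds <- scan_fixture("tiny")
  tbl <- build_dyad_scans(ds$scans, ds$individuals, "play")
  expect_error(fit_scan_model(tbl, model_spec("grooming")),
               "different behaviour")
})

test_that("posterior draws persist to CSV with a complete manifest", {
  ds <- scan_fixture("tiny")
  tbl <- build_dyad_scans(ds$scans, ds$individuals, "close_proximity")
  fit <- fit_scan_model(tbl, model_spec("close_proximity", chains = 2,
                                        iterations = 200, warmup = 100,
                                        seed = 13))
  dir <- tempfile()
  write_scan_fit(fit, dir)
  draws <- readr::read_csv(file.path(dir, "draws.csv"), show_col_types = FALSE)
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(nrow(draws), nrow(fit$draws))
  expect_setequal(unlist(man$parameters), colnames(fit$draws))
  expect_equal(man$chains, 2)
  expect_true(all(colnames(fit$draws) %in% names(draws)))
})

test_that("with no data the sampler reproduces its priors", {
  set.seed(42)
  res <- cpp_fit_chain(integer(0), integer(0), integer(0), integer(0),
                       integer(0), integer(0), matrix(0, 0, 0),
                       2L, 3L, 2L, FALSE, 100, 10,
                       6000L, 1000L, 1L, 0.1, list())
  d <- res$draws
  # columns: alpha, beta, 3 sigmas, 2 group, 3 individual, 2 dyad effects
  sig <- d[, 3:5]
  expect_equal(unname(colMeans(sig)), rep(5, 3), tolerance = 0.1)
  expect_equal(unname(apply(sig, 2, sd)), rep(10 / sqrt(12), 3),
               tolerance = 0.1)
  expect_true(all(sig >= 0 & sig <= 10))
  expect_equal(mean(d[, 1]), 0, tolerance = 8)   # alpha ~ N(0, 100)
  expect_equal(sd(d[, 1]), 100, tolerance = 0.15)
})

test_that("posterior ranks of the truth are calibrated (reduced-scale SBC)", {
  # generate from the same priors the model fits with (narrowed so the
  # simulated data are informative), then check the rank of the true alpha
  # and sigma_group among the posterior draws is not extreme
  n_rep <- 30
  ranks_a <- ranks_sg <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    set.seed(7000 + r)
    truth <- list(alpha = rnorm(1, 0, 1), beta_last = rnorm(1, 0, 1),
                  sigma_group = runif(1, 0, 1.5), sigma_ind = runif(1, 0, 1.5),
                  sigma_dyad = runif(1, 0, 1.5))
    ds <- simulate_scans(sim_config(
      n_groups = 2, group_sizes = c(4L, 4L), days = 4, scans_per_day = 8,
      behaviours = "close_proximity", visibility = 1, params = truth,
      seed = 7000 + r
    ))
    tbl <- build_dyad_scans(ds$scans, ds$individuals, "close_proximity")
    spec <- suppressWarnings(
      model_spec("close_proximity", chains = 1, iterations = 700,
                 warmup = 300, thinning = 4, seed = 7000 + r,
                 prior_sd_fixed = 1, prior_sigma_upper = 1.5)
    )
    fit <- suppressWarnings(fit_scan_model(tbl, spec))
    nd <- nrow(fit$draws)
    # uniform tie-break keeps the rank statistic continuous
    ranks_a[r] <- (sum(fit$draws[, "alpha"] < truth$alpha) + runif(1)) / (nd + 1)
    ranks_sg[r] <- (sum(fit$draws[, "sigma_group"] < truth$sigma_group) +
                      runif(1)) / (nd + 1)
  }
  # uniform ranks: mean near 0.5 and mass in both halves
  expect_gt(stats::ks.test(ranks_a, "punif")$p.value, 1e-3)
  expect_gt(stats::ks.test(ranks_sg, "punif")$p.value, 1e-3)
})
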