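#' Simulation configuration
#'
#' Assembles the generative settings for a synthetic scan-sampling study:
#' group structure, demography, kinship density, sampling effort, the true
#' model parameters and the per-individual visibility probability. Defaults
#' emulate a multi-group zoo study: six groups of 8-16 individuals sampled
#' daily for about three months (~870 scans per group), with a rare baseline
#' behaviour and strong within-day bout persistence.
#'
#' @param n_groups number of groups.
#' @param group_sizes integer vector of length `n_groups`; when `NULL`,
#'   sizes are drawn uniformly from `size_range` under the config seed.
#' @param size_range inclusive range group sizes are drawn from.
#' @param prop_female expected proportion of females per group.
#' @param age_range ages are drawn uniformly from this range (years). The
#'   default starts at 7 so every individual is a focal subject; lower the
#'   minimum to include non-focal juveniles.
#' @param maternal_kin_density probability an individual is assigned a
#'   mother among same-group females at least 12 years older.
#' @param paternal_kin_density as above for fathers among males.
#' @param days observation days per group.
#' @param scans_per_day scans per observation day.
#' @param behaviours behaviours to simulate (all four by default).
#' @param params named list of true parameters: `alpha`, `beta_last`,
#'   `sigma_group`, `sigma_ind`, `sigma_dyad`, `sigma_rec` and optionally a
#'   named `delta` vector of dyad-covariate coefficients (log-odds). Either
#'   one list applied to every behaviour or a named list of such lists, one
#'   per behaviour.
#' @param visibility probability an individual is in sight at a scan.
#'   Individuals engaged in an interaction at a scan are always in sight.
#' @param seed integer seed; the dataset is a deterministic function of the
#'   full configuration.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_groups = 6, group_sizes = NULL, size_range = c(8L, 16L),
                       prop_female = 0.6, age_range = c(7, 40),
                       maternal_kin_density = 0.2, paternal_kin_density = 0.1,
                       days = 87, scans_per_day = 10,
                       behaviours = scansoc_behaviours,
                       params = NULL, visibility = 0.9, seed = 1) {
  params <- params %||% default_sim_params()
  if (!is.null(group_sizes) && length(group_sizes) != n_groups) {
    abort("group_sizes must have length n_groups")
  }
  if (!is.null(group_sizes) && any(group_sizes < 2)) {
    abort("group size < 2: a group needs at least one dyad")
  }
  if (visibility <= 0 || visibility > 1) abort("visibility must be in (0, 1]")
  if (scans_per_day < 1 || days < 1) abort("days and scans_per_day must be >= 1")
  for (b in behaviours) check_behaviour(b)
  cfg <- list(
    n_groups = as.integer(n_groups), group_sizes = group_sizes,
    size_range = as.integer(size_range), prop_female = prop_female,
    age_range = age_range, maternal_kin_density = maternal_kin_density,
    paternal_kin_density = paternal_kin_density,
    days = as.integer(days), scans_per_day = as.integer(scans_per_day),
    behaviours = behaviours, params = params,
    visibility = visibility, seed = as.integer(seed)
  )
  structure(cfg, class = "sim_config")
}

default_sim_params <- function() {
  list(
    alpha = -4, beta_last = 2,
    sigma_group = 0.5, sigma_ind = 0.4, sigma_dyad = 0.8, sigma_rec = 0.6,
    delta = NULL
  )
}

behaviour_params <- function(cfg, behaviour) {
  p <- cfg$params
  if (!is.null(p[[behaviour]]) && is.list(p[[behaviour]])) p <- p[[behaviour]]
  defaults <- default_sim_params()
  for (nm in names(defaults)) p[[nm]] <- p[[nm]] %||% defaults[[nm]]
  stopifnot(p$sigma_group >= 0, p$sigma_ind >= 0, p$sigma_dyad >= 0, p$sigma_rec >= 0)
  p
}

simulate_individuals <- function(cfg) {
  sizes <- cfg$group_sizes %||%
    sample(seq(cfg$size_range[1], cfg$size_range[2]), cfg$n_groups, replace = TRUE)
  if (any(sizes < 2)) abort("group size < 2: a group needs at least one dyad")
  groups <- paste0("G", seq_len(cfg$n_groups))
  purrr::map2_dfr(groups, sizes, function(gname, n) {
    id <- sprintf("%s_%02d", gname, seq_len(n))
    sex <- ifelse(runif(n) < cfg$prop_female, "F", "M")
    age <- runif(n, cfg$age_range[1], cfg$age_range[2])
    mother_id <- rep(NA_character_, n)
    father_id <- rep(NA_character_, n)
    for (t in seq_len(n)) {
      mums <- id[sex == "F" & age >= age[t] + 12]
      if (length(mums) > 0 && runif(1) < cfg$maternal_kin_density) {
        mother_id[t] <- sample(mums, 1)
      }
      dads <- id[sex == "M" & age >= age[t] + 12]
      if (length(dads) > 0 && runif(1) < cfg$paternal_kin_density) {
        father_id[t] <- sample(dads, 1)
      }
    }
    tibble::tibble(id = id, group = gname, sex = sex, age = age,
                   mother_id = mother_id, father_id = father_id)
  }) |>
    validate_individuals()
}

# latent effects + per-dyad linear-predictor pieces for one behaviour
simulate_behaviour_truth <- function(cfg, individuals, behaviour) {
  p <- behaviour_params(cfg, behaviour)
  directional <- is_directional(behaviour)
  dyads <- individuals |>
    dplyr::group_by(.data$group) |>
    dplyr::group_modify(~ eligible_dyads(.x, directional)) |>
    dplyr::ungroup()
  dyads <- dyad_covariates(dyads, directional)

  groups <- sort(unique(individuals$group))
  a <- setNames(rnorm(length(groups), 0, p$sigma_group), groups)
  b <- setNames(rnorm(nrow(individuals), 0, p$sigma_ind), individuals$id)
  d <- setNames(rnorm(nrow(individuals), 0, p$sigma_rec), individuals$id)
  # dyad effect shared across both grooming directions (symmetric bond)
  ukey <- paste(dyads$group, pmin(dyads$i, dyads$j), pmax(dyads$i, dyads$j))
  udyads <- unique(ukey)
  cvec <- setNames(rnorm(length(udyads), 0, p$sigma_dyad), udyads)

  X <- dyad_design_matrix(new_dyad_scans(dyads, behaviour, directional))
  delta <- rep(0, ncol(X))
  names(delta) <- colnames(X)
  if (!is.null(p$delta)) {
    unknown <- setdiff(names(p$delta), colnames(X))
    if (length(unknown) > 0) {
      abort(paste0("unknown covariate coefficient(s): ", paste(unknown, collapse = ", ")))
    }
    delta[names(p$delta)] <- p$delta
  }
  B <- a[dyads$group] + cvec[ukey] + drop(X %*% delta) +
    if (directional) b[dyads$i] + d[dyads$j] else b[dyads$i] + b[dyads$j]
  list(
    params = p, directional = directional,
    dyads = dyads |> dplyr::select("group", "i", "j"),
    eta0 = unname(p$alpha + B),
    group_effects = tibble::tibble(group = groups, a = unname(a)),
    ind_effects = tibble::tibble(id = individuals$id, b = unname(b),
                                 d = if (directional) unname(d) else NA_real_),
    dyad_effects = tibble::tibble(key = udyads, c = unname(cvec))
  )
}

#' Simulate a scan-sampling dataset with known ground truth
#'
#' Generates a full synthetic study from the hierarchical Bernoulli model run
#' forwards: latent group/individual/dyad (and grooming-recipient) effects
#' are drawn from their normal distributions, and each dyad's scan-to-scan
#' series follows a two-state Markov chain on the logit scale (`alpha +
#' beta_last * y_prev + B_ijk + x'delta`), restarted at the first scan of
#' each day. Visibility censoring is applied after outcome generation: an
#' individual is out of sight with probability `1 - visibility` unless it is
#' interacting at that scan; dyads with both members out of sight yield no
#' information (the downstream dyad-scan builder drops those rows rather
#' than recording zeros).
#'
#' @param cfg a [sim_config()].
#' @return A list of class `scan_dataset` with elements `individuals`,
#'   `scans` (a `scan_events` object covering all behaviours), `truth` (per
#'   behaviour: the generating parameters and every latent effect) and
#'   `config`.
#' @export
simulate_scans <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  individuals <- simulate_individuals(cfg)
  groups <- sort(unique(individuals$group))
  days <- as.Date("2013-01-01") + seq_len(cfg$days) - 1
  S <- cfg$scans_per_day

  truth <- purrr::map(setNames(cfg$behaviours, cfg$behaviours),
                      ~ simulate_behaviour_truth(cfg, individuals, .x))

  # outcome matrices: per behaviour, dyads x total scans
  n_scans_total <- cfg$days * S
  ymats <- purrr::map(truth, function(tr) {
    nd <- length(tr$eta0)
    p0 <- plogis(tr$eta0)
    p1 <- plogis(tr$eta0 + tr$params$beta_last)
    y <- matrix(0L, nd, n_scans_total)
    col <- 0L
    for (m in seq_len(cfg$days)) {
      yprev <- rep(0L, nd)
      for (l in seq_len(S)) {
        col <- col + 1L
        pr <- ifelse(yprev == 1L, p1, p0)
        yprev <- rbinom(nd, 1L, pr)
        y[, col] <- yprev
      }
    }
    y
  })

  # per-scan visibility, shared across behaviours; interacting animals are
  # always in sight
  vis <- purrr::map_dfr(groups, function(gname) {
    ids <- individuals$id[individuals$group == gname]
    n <- length(ids)
    seen <- matrix(runif(n * n_scans_total) < cfg$visibility, n, n_scans_total)
    rownames(seen) <- ids
    for (b in cfg$behaviours) {
      tr <- truth[[b]]
      rows <- which(tr$dyads$group == gname)
      if (length(rows) == 0) next
      yb <- ymats[[b]][rows, , drop = FALSE]
      ii <- tr$dyads$i[rows]
      jj <- tr$dyads$j[rows]
      act <- which(yb == 1L, arr.ind = TRUE)
      if (nrow(act) > 0) {
        seen[cbind(match(ii[act[, 1]], ids), act[, 2])] <- TRUE
        seen[cbind(match(jj[act[, 1]], ids), act[, 2])] <- TRUE
      }
    }
    tibble::tibble(
      group = gname,
      day = rep(days, each = S),
      scan = rep(seq_len(S), cfg$days),
      ids = purrr::map(seq_len(n_scans_total), ~ ids[seen[, .x]])
    )
  })

  # event rows from y = 1 cells
  events <- purrr::imap_dfr(ymats, function(y, b) {
    tr <- truth[[b]]
    act <- which(y == 1L, arr.ind = TRUE)
    if (nrow(act) == 0) {
      return(tibble::tibble(group = character(), day = as.Date(character()),
                            scan = integer(), behaviour = character(),
                            actor = character(), partner = character(),
                            direction = character()))
    }
    tibble::tibble(
      group = tr$dyads$group[act[, 1]],
      day = days[(act[, 2] - 1L) %/% S + 1L],
      scan = (act[, 2] - 1L) %% S + 1L,
      behaviour = b,
      actor = tr$dyads$i[act[, 1]],
      partner = tr$dyads$j[act[, 1]],
      direction = if (tr$directional) "actor_grooms_partner" else "undirected"
    )
  })

  # proximity exclusivity: a dyad close in a scan cannot also be distant
  if (all(c("close_proximity", "distant_proximity") %in% cfg$behaviours)) {
    key <- function(e) paste(e$group, e$day, e$scan,
                             pmin(e$actor, e$partner), pmax(e$actor, e$partner))
    close_keys <- key(events[events$behaviour == "close_proximity", ])
    drop <- events$behaviour == "distant_proximity" & key(events) %in% close_keys
    events <- events[!drop, ]
  }

  structure(
    list(
      individuals = individuals,
      scans = scan_events(events, vis),
      truth = truth,
      config = cfg
    ),
    class = "scan_dataset"
  )
}

#' @export
print.scan_dataset <- function(x, ...) {
  cat("<scan_dataset> ", nrow(x$individuals), " individuals in ",
      x$config$n_groups, " groups; ", nrow(x$scans$visibility), " scans; ",
      nrow(x$scans$events), " events (",
      paste(x$config$behaviours, collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Canned simulation fixtures
#'
#' Named configurations with documented seeds used throughout the test
#' suite and examples:
#' * `tiny` - 2 groups of 4, 20 scans, full visibility; runs end-to-end in
#'   seconds.
#' * `paper_like` - 6 groups of 8-16 individuals, 870 scans each (~5220
#'   total), visibility 0.9, kin/sex/age covariate effects switched on.
#' * `null_group` - no group-level variation (`sigma_group = 0`).
#' * `strong_group` - dominant group-level variation (`sigma_group = 1.5`,
#'   other SDs 0.5).
#'
#' @param name fixture name.
#' @param ... overrides passed to [sim_config()] (e.g. a different seed).
#' @return A simulated `scan_dataset`.
#' @export
scan_fixture <- function(name = c("tiny", "paper_like", "null_group", "strong_group"),
                         ...) {
  name <- tryCatch(match.arg(name), error = function(e) {
    abort(paste0("unknown fixture '", name[1], "'; available: tiny, paper_like, ",
                 "null_group, strong_group"))
  })
  args <- switch(name,
    tiny = list(
      n_groups = 2, group_sizes = c(4L, 4L), days = 5, scans_per_day = 4,
      visibility = 1, seed = 101
    ),
    paper_like = list(
      n_groups = 6, days = 87, scans_per_day = 10, visibility = 0.9,
      params = list(
        alpha = -4, beta_last = 2, sigma_group = 0.5, sigma_ind = 0.4,
        sigma_dyad = 0.8, sigma_rec = 0.6,
        delta = c(age_diff = log(0.75), maternal_kin = log(6.1),
                  paternal_kin = log(1.5))
      ),
      seed = 202
    ),
    null_group = list(
      n_groups = 4, group_sizes = rep(6L, 4), days = 25, scans_per_day = 8,
      visibility = 1,
      params = list(alpha = -3, beta_last = 1.5, sigma_group = 0,
                    sigma_ind = 0.4, sigma_dyad = 0.8),
      seed = 303
    ),
    strong_group = list(
      n_groups = 6, group_sizes = rep(8L, 6), days = 25, scans_per_day = 8,
      visibility = 1,
      params = list(alpha = -3, beta_last = 1.5, sigma_group = 1.5,
                    sigma_ind = 0.5, sigma_dyad = 0.5),
      seed = 404
    )
  )
  args <- utils::modifyList(args, list(...))
  simulate_scans(do.call(sim_config, args))
}

#' Write a simulated dataset as the package's CSV interchange formats
#'
#' Writes `individuals.csv`, `events.csv`, `visibility.csv` and a
#' `truth.json` sidecar with the generating parameters and latent effects.
#'
#' @param dataset a `scan_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scan_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "scan_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(dataset$individuals |> dplyr::select(-"is_focal"),
                   file.path(dir, "individuals.csv"))
  readr::write_csv(dataset$scans$events, file.path(dir, "events.csv"))
  vis <- dataset$scans$visibility |>
    dplyr::mutate(visible_ids = purrr::map_chr(.data$ids, paste, collapse = ";")) |>
    dplyr::select("group", "day", "scan", "visible_ids")
  readr::write_csv(vis, file.path(dir, "visibility.csv"))
  truth <- purrr::map(dataset$truth, function(tr) {
    list(
      params = tr$params[c("alpha", "beta_last", "sigma_group", "sigma_ind",
                           "sigma_dyad", "sigma_rec", "delta")],
      group_effects = tr$group_effects,
      ind_effects = tr$ind_effects,
      dyad_effects = tr$dyad_effects
    )
  })
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a dataset written by [write_scan_dataset()]
#'
#' @param dir directory containing `individuals.csv`, `events.csv` and
#'   `visibility.csv`.
#' @return A list with `individuals` and `scans` (a `scan_events` object).
#' @export
read_scan_dataset <- function(dir) {
  individuals <- read_individuals(file.path(dir, "individuals.csv"))
  scans <- read_scan_events(file.path(dir, "events.csv"),
                            file.path(dir, "visibility.csv"))
  list(individuals = individuals, scans = scans)
}
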