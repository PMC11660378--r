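#' Read the individuals table
#'
#' Reads a CSV of study subjects with columns `id,group,sex,age` and optional
#' `mother_id,father_id`. Individuals aged 7 years or more at the study start
#' are flagged as focal subjects: younger animals are retained only as
#' potential interaction partners of focal subjects, never as main actors.
#'
#' @param path path to a CSV file (UTF-8, comma separated).
#' @return A tibble with columns `id`, `group`, `sex` (`"F"`/`"M"`),
#'   `age` (years), `mother_id`, `father_id` (NA when unknown) and the
#'   derived logical `is_focal` (`age >= 7`).
#' @export
read_individuals <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  required <- c("id", "group", "sex", "age")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("individuals file lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (!"mother_id" %in% names(raw)) raw$mother_id <- NA_character_
  if (!"father_id" %in% names(raw)) raw$father_id <- NA_character_
  out <- tibble::tibble(
    id = raw$id,
    group = raw$group,
    sex = raw$sex,
    age = as.numeric(raw$age),
    mother_id = dplyr::na_if(raw$mother_id, ""),
    father_id = dplyr::na_if(raw$father_id, "")
  )
  validate_individuals(out)
}

validate_individuals <- function(ind) {
  bad_sex <- setdiff(unique(ind$sex), c("F", "M"))
  if (length(bad_sex) > 0) {
    abort(paste0("unknown sex code(s): ", paste(bad_sex, collapse = ", "),
                 " (expected F or M)"))
  }
  dup <- ind$id[duplicated(ind$id)]
  if (length(dup) > 0) {
    abort(paste0("duplicate id: ", paste(unique(dup), collapse = ", ")))
  }
  if (any(!is.na(ind$age) & ind$age < 0)) abort("negative age")
  self_parent <- !is.na(ind$mother_id) & ind$mother_id == ind$id |
    !is.na(ind$father_id) & ind$father_id == ind$id
  if (any(self_parent)) {
    abort(paste0("individual listed as own parent: ",
                 paste(ind$id[self_parent], collapse = ", ")))
  }
  ind$is_focal <- ind$age >= 7
  ind
}

#' Read scan-sampling event and visibility tables
#'
#' Reads a long-format table of point-sampled social events, one row per
#' recorded interaction, together with a per-scan visibility table listing
#' which individuals were in sight. Scans are instantaneous group samples;
#' animals out of sight at a scan are only informative about dyads whose
#' other member was visible.
#'
#' @param events_path CSV with columns `group,day,scan,behaviour,actor,partner,direction`.
#'   `day` is an ISO date, `scan` a positive integer ordered within day,
#'   `behaviour` one of `close_proximity`, `distant_proximity`, `play`,
#'   `grooming`, and `direction` either `undirected` or
#'   `actor_grooms_partner`.
#' @param visibility_path CSV with columns `group,day,scan,visible_ids`
#'   where `visible_ids` is a semicolon-separated list of individual ids in
#'   sight at that scan. Every scan performed must appear here, including
#'   scans without any recorded event. May be `NULL` only when
#'   `assume_all_visible = TRUE`.
#' @param individuals individuals tibble from [read_individuals()]; required
#'   when `assume_all_visible = TRUE`.
#' @param assume_all_visible fallback for datasets without explicit
#'   visibility records: every group member is assumed in sight at every
#'   scan appearing in the events table. Scans with no recorded events are
#'   then invisible to the pipeline, so prefer an explicit visibility table.
#' @return A `scan_events` object: a list with tibbles `events` and
#'   `visibility` (the latter with a list-column `ids`).
#' @export
read_scan_events <- function(events_path, visibility_path = NULL,
                             individuals = NULL, assume_all_visible = FALSE) {
  ev <- readr::read_csv(events_path, show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  req <- c("group", "day", "scan", "behaviour", "actor", "partner", "direction")
  missing_cols <- setdiff(req, names(ev))
  if (length(missing_cols) > 0) {
    abort(paste0("events file lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  events <- tibble::tibble(
    group = ev$group,
    day = as.Date(ev$day),
    scan = as.integer(ev$scan),
    behaviour = ev$behaviour,
    actor = ev$actor,
    partner = ev$partner,
    direction = ev$direction
  )
  if (!is.null(visibility_path)) {
    vis_raw <- readr::read_csv(visibility_path, show_col_types = FALSE,
                               col_types = readr::cols(.default = readr::col_character()))
    vreq <- c("group", "day", "scan", "visible_ids")
    missing_cols <- setdiff(vreq, names(vis_raw))
    if (length(missing_cols) > 0) {
      abort(paste0("visibility file lacks column(s): ", paste(missing_cols, collapse = ", ")))
    }
    visibility <- tibble::tibble(
      group = vis_raw$group,
      day = as.Date(vis_raw$day),
      scan = as.integer(vis_raw$scan),
      ids = strsplit(dplyr::coalesce(vis_raw$visible_ids, ""), ";", fixed = TRUE)
    )
  } else {
    if (!assume_all_visible) {
      abort("visibility_path is required unless assume_all_visible = TRUE")
    }
    if (is.null(individuals)) {
      abort("individuals must be supplied when assume_all_visible = TRUE")
    }
    members <- split(individuals$id, individuals$group)
    visibility <- events |>
      dplyr::distinct(.data$group, .data$day, .data$scan) |>
      dplyr::mutate(ids = unname(members[.data$group]))
  }
  scan_events(events, visibility)
}

#' Construct a validated scan_events object
#'
#' Validates the two core invariants of scan sampling: close and distant
#' proximity are mutually exclusive for a dyad within one scan, and every
#' actor/partner of a recorded event must be in that scan's visibility set.
#'
#' @param events tibble of events (see [read_scan_events()]).
#' @param visibility tibble with columns `group,day,scan` and list-column `ids`.
#' @return A `scan_events` object.
#' @export
scan_events <- function(events, visibility) {
  bad_b <- setdiff(unique(events$behaviour), scansoc_behaviours)
  if (length(bad_b) > 0) {
    abort(paste0("unknown behaviour(s) in events: ", paste(bad_b, collapse = ", ")))
  }
  bad_dir <- setdiff(unique(events$direction), c("undirected", "actor_grooms_partner"))
  if (length(bad_dir) > 0) {
    abort(paste0("unknown direction value(s): ", paste(bad_dir, collapse = ", ")))
  }
  # proximity exclusivity per unordered dyad per scan
  prox <- events |>
    dplyr::filter(.data$behaviour %in% c("close_proximity", "distant_proximity")) |>
    dplyr::mutate(
      lo = pmin(.data$actor, .data$partner),
      hi = pmax(.data$actor, .data$partner)
    ) |>
    dplyr::distinct(.data$group, .data$day, .data$scan, .data$lo, .data$hi, .data$behaviour) |>
    dplyr::count(.data$group, .data$day, .data$scan, .data$lo, .data$hi) |>
    dplyr::filter(.data$n > 1)
  if (nrow(prox) > 0) {
    abort(paste0(
      "close and distant proximity recorded for the same dyad in one scan: group ",
      prox$group[1], ", day ", prox$day[1], ", scan ", prox$scan[1],
      " (", prox$lo[1], "-", prox$hi[1], ")"
    ))
  }
  # actor/partner visibility
  vkey <- paste(visibility$group, visibility$day, visibility$scan)
  ekey <- paste(events$group, events$day, events$scan)
  idx <- match(ekey, vkey)
  if (anyNA(idx)) {
    miss <- which(is.na(idx))[1]
    abort(paste0("event at group ", events$group[miss], ", day ", events$day[miss],
                 ", scan ", events$scan[miss], " has no visibility record"))
  }
  in_sight <- mapply(function(a, p, i) {
    a %in% visibility$ids[[i]] && p %in% visibility$ids[[i]]
  }, events$actor, events$partner, idx)
  if (length(in_sight) > 0 && !all(in_sight)) {
    miss <- which(!in_sight)[1]
    abort(paste0("actor or partner not in visibility set: group ", events$group[miss],
                 ", day ", events$day[miss], ", scan ", events$scan[miss],
                 " (", events$actor[miss], "-", events$partner[miss], ")"))
  }
  structure(
    list(
      events = dplyr::as_tibble(events),
      visibility = dplyr::arrange(dplyr::as_tibble(visibility),
                                  .data$group, .data$day, .data$scan)
    ),
    class = "scan_events"
  )
}

#' @export
print.scan_events <- function(x, ...) {
  cat("<scan_events> ", nrow(x$events), " events over ", nrow(x$visibility),
      " scans in ", length(unique(x$visibility$group)), " group(s)\n", sep = "")
  invisible(x)
}

# eligible dyads of one group: at least one focal member; ordered pairs for
# directional behaviour, unordered (i < j by id) otherwise
eligible_dyads <- function(ind, directional) {
  pairs <- tidyr::crossing(i = ind$id, j = ind$id) |>
    dplyr::filter(if (directional) .data$i != .data$j else .data$i < .data$j)
  info <- ind |>
    dplyr::select("id", "sex", "age", "mother_id", "father_id", "is_focal")
  pairs |>
    dplyr::left_join(dplyr::rename_with(info, ~ paste0(.x, "_i")), by = c(i = "id_i")) |>
    dplyr::left_join(dplyr::rename_with(info, ~ paste0(.x, "_j")), by = c(j = "id_j")) |>
    dplyr::filter(.data$is_focal_i | .data$is_focal_j)
}

dyad_covariates <- function(dyads, directional) {
  kin_m <- (!is.na(dyads$mother_id_i) & dyads$mother_id_i == dyads$j) |
    (!is.na(dyads$mother_id_j) & dyads$mother_id_j == dyads$i) |
    (!is.na(dyads$mother_id_i) & !is.na(dyads$mother_id_j) &
       dyads$mother_id_i == dyads$mother_id_j)
  kin_p <- (!is.na(dyads$father_id_i) & dyads$father_id_i == dyads$j) |
    (!is.na(dyads$father_id_j) & dyads$father_id_j == dyads$i) |
    (!is.na(dyads$father_id_i) & !is.na(dyads$father_id_j) &
       dyads$father_id_i == dyads$father_id_j)
  out <- dyads |>
    dplyr::mutate(
      age_diff = if (directional) .data$age_i - .data$age_j
                 else abs(.data$age_i - .data$age_j),
      maternal_kin = as.integer(kin_m),
      paternal_kin = as.integer(kin_p),
      sex_class = if (directional) {
        paste0(.data$sex_i, .data$sex_j)
      } else {
        dplyr::case_when(
          .data$sex_i == "F" & .data$sex_j == "F" ~ "FF",
          .data$sex_i == "M" & .data$sex_j == "M" ~ "MM",
          TRUE ~ "mixed"
        )
      }
    )
  # standardize age difference across all dyads pooled over groups
  mu <- mean(out$age_diff)
  sdv <- sd(out$age_diff)
  if (!is.finite(sdv) || sdv == 0) sdv <- 1
  out$age_diff_std <- (out$age_diff - mu) / sdv
  attr(out, "age_std") <- c(center = mu, scale = sdv)
  out
}

#' Build the lagged dyad-scan table for one behaviour
#'
#' Expands scan events into the binary table the hierarchical model
#' consumes: one row per eligible dyad per retained scan with outcome `y`,
#' the previous scan's outcome `y_prev` (0 at the first scan of each day),
#' and dyad-level covariates. A dyad is eligible when at least one member is
#' a focal subject (aged 7 or more); a scan is retained for a dyad when at
#' least one member was in sight (with both members out of sight the dyad's
#' state is unknown and no row is emitted). Grooming is directional: each
#' unordered pair contributes two ordered rows (groomer -> recipient).
#'
#' @param x a `scan_events` object.
#' @param individuals tibble from [read_individuals()].
#' @param behaviour one of `"close_proximity"`, `"distant_proximity"`,
#'   `"play"`, `"grooming"`.
#' @return A tibble of class `dyad_scans` with columns `group,i,j,day,scan,
#'   y,y_prev,age_diff_std,maternal_kin,paternal_kin,sex_class` and
#'   attributes `behaviour`, `directional` and `age_std`.
#' @export
build_dyad_scans <- function(x, individuals, behaviour) {
  check_behaviour(behaviour)
  stopifnot(inherits(x, "scan_events"))
  individuals <- validate_individuals(individuals)
  directional <- is_directional(behaviour)

  dyads <- individuals |>
    dplyr::group_by(.data$group) |>
    dplyr::group_modify(~ eligible_dyads(.x, directional)) |>
    dplyr::ungroup()
  dyads <- dyad_covariates(dyads, directional)
  age_std <- attr(dyads, "age_std")
  dyads <- dyads |>
    dplyr::select("group", "i", "j", "age_diff_std", "maternal_kin",
                  "paternal_kin", "sex_class")

  ev <- x$events |> dplyr::filter(.data$behaviour == !!behaviour)
  if (!directional) {
    ev <- ev |>
      dplyr::mutate(i = pmin(.data$actor, .data$partner),
                    j = pmax(.data$actor, .data$partner))
  } else {
    ev <- ev |> dplyr::mutate(i = .data$actor, j = .data$partner)
  }
  ev <- ev |> dplyr::distinct(.data$group, .data$day, .data$scan, .data$i, .data$j)

  # long visibility for membership joins
  vis_long <- x$visibility |>
    dplyr::mutate(.scan_rank = scan_rank_within_day(.data$group, .data$day, .data$scan)) |>
    tidyr::unnest_longer(col = "ids", values_to = "id")
  scan_meta <- x$visibility |>
    dplyr::mutate(.scan_rank = scan_rank_within_day(.data$group, .data$day, .data$scan)) |>
    dplyr::select("group", "day", "scan", ".scan_rank")

  tbl <- scan_meta |>
    dplyr::inner_join(dyads, by = "group", relationship = "many-to-many") |>
    dplyr::left_join(
      vis_long |> dplyr::select("group", "day", "scan", "id") |>
        dplyr::mutate(vis_i = TRUE),
      by = c("group", "day", "scan", i = "id")
    ) |>
    dplyr::left_join(
      vis_long |> dplyr::select("group", "day", "scan", "id") |>
        dplyr::mutate(vis_j = TRUE),
      by = c("group", "day", "scan", j = "id")
    ) |>
    dplyr::mutate(vis_i = !is.na(.data$vis_i), vis_j = !is.na(.data$vis_j)) |>
    dplyr::filter(.data$vis_i | .data$vis_j) |>
    dplyr::left_join(ev |> dplyr::mutate(y = 1L),
                     by = c("group", "day", "scan", "i", "j")) |>
    dplyr::mutate(y = dplyr::coalesce(.data$y, 0L))

  # lag within (dyad, day): previous scan's outcome, 0 when the previous
  # scan has no retained row (unknown state counts as non-interaction)
  tbl <- tbl |>
    dplyr::arrange(.data$group, .data$i, .data$j, .data$day, .data$scan) |>
    dplyr::group_by(.data$group, .data$i, .data$j, .data$day) |>
    dplyr::mutate(
      y_prev = dplyr::if_else(
        !is.na(dplyr::lag(.data$.scan_rank)) &
          dplyr::lag(.data$.scan_rank) == .data$.scan_rank - 1L,
        dplyr::lag(.data$y), 0L, missing = 0L
      )
    ) |>
    dplyr::ungroup() |>
    dplyr::select("group", "i", "j", "day", "scan", "y", "y_prev",
                  "age_diff_std", "maternal_kin", "paternal_kin", "sex_class")

  out <- new_dyad_scans(tbl, behaviour, directional, age_std)
  # individual sex/age lookups used by the sampler's interweaving moves
  keys <- paste0(individuals$group, ":", individuals$id)
  attr(out, "ind_sex") <- setNames(individuals$sex, keys)
  attr(out, "ind_age") <- setNames(individuals$age, keys)
  out
}

scan_rank_within_day <- function(group, day, scan) {
  key <- paste(group, day)
  stats::ave(as.numeric(scan), key, FUN = function(s) rank(s, ties.method = "min"))
}

new_dyad_scans <- function(tbl, behaviour, directional, age_std = c(center = 0, scale = 1)) {
  structure(
    dplyr::as_tibble(tbl),
    behaviour = behaviour,
    directional = directional,
    age_std = age_std,
    class = c("dyad_scans", class(dplyr::as_tibble(tbl)))
  )
}

#' Design matrix of dyad-level covariates
#'
#' For undirected behaviours the terms are standardized absolute age
#' difference, maternal/paternal kin indicators, and sex-class indicators
#' `mixed_sex` and `male_male` (female-female reference). For grooming the
#' age difference is signed (groomer minus recipient) and the sex-class
#' indicators are `m_grooms_f`, `f_grooms_m` and `male_male`
#' (female-grooms-female reference).
#'
#' @param tbl a `dyad_scans` tibble.
#' @return numeric matrix with one column per covariate term.
#' @export
dyad_design_matrix <- function(tbl) {
  directional <- attr(tbl, "directional")
  if (isTRUE(directional)) {
    cbind(
      age_diff = tbl$age_diff_std,
      maternal_kin = tbl$maternal_kin,
      paternal_kin = tbl$paternal_kin,
      m_grooms_f = as.integer(tbl$sex_class == "MF"),
      f_grooms_m = as.integer(tbl$sex_class == "FM"),
      male_male = as.integer(tbl$sex_class == "MM")
    )
  } else {
    cbind(
      age_diff = tbl$age_diff_std,
      maternal_kin = tbl$maternal_kin,
      paternal_kin = tbl$paternal_kin,
      mixed_sex = as.integer(tbl$sex_class == "mixed"),
      male_male = as.integer(tbl$sex_class == "MM")
    )
  }
}

#' Raw association and interaction rates
#'
#' Computes descriptive rates without any model: per dyad the proportion of
#' retained scans in which the behaviour occurred; per individual the sum of
#' its dyads' proportions (a raw strength-like total involvement); per group
#' the mean and SD of the individual totals.
#'
#' @param tbl a `dyad_scans` tibble from [build_dyad_scans()].
#' @param individuals optional individuals tibble; when given, eligible
#'   dyads with zero retained scans are reported with a warning.
#' @return A list of tibbles `dyads`, `individuals` and `groups`.
#' @export
compute_raw_rates <- function(tbl, individuals = NULL) {
  if (nrow(tbl) == 0) abort("empty dyad-scan table")
  dyads <- tbl |>
    dplyr::group_by(.data$group, .data$i, .data$j) |>
    dplyr::summarise(n_scans = dplyr::n(), rate = mean(.data$y), .groups = "drop")
  if (!is.null(individuals)) {
    expected <- validate_individuals(individuals) |>
      dplyr::group_by(.data$group) |>
      dplyr::group_modify(~ eligible_dyads(.x, isTRUE(attr(tbl, "directional")))) |>
      dplyr::ungroup() |>
      dplyr::select("group", "i", "j")
    missing_dyads <- dplyr::anti_join(expected, dyads, by = c("group", "i", "j"))
    if (nrow(missing_dyads) > 0) {
      warn(paste0(nrow(missing_dyads),
                  " eligible dyad(s) had zero retained scans and were excluded"))
    }
  }
  inds <- dplyr::bind_rows(
    dyads |> dplyr::select("group", id = "i", "rate"),
    dyads |> dplyr::select("group", id = "j", "rate")
  ) |>
    dplyr::group_by(.data$group, .data$id) |>
    dplyr::summarise(total = sum(.data$rate), .groups = "drop")
  groups <- inds |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(mean = mean(.data$total),
                     sd = sd(.data$total),
                     n = dplyr::n(), .groups = "drop")
  list(dyads = dyads, individuals = inds, groups = groups)
}

#' Write a dyad-scan table to CSV for audit
#'
#' @param tbl a `dyad_scans` tibble.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_dyad_scans <- function(tbl, path) {
  readr::write_csv(dplyr::as_tibble(tbl), path)
  invisible(path)
}
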