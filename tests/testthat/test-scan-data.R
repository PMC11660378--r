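write_tmp_csv <- function(df) {
  path <- tempfile(fileext = ".csv")
  readr::write_csv(df, path, na = "")
  path
}

test_that("read_individuals sets the focal flag at age 7 and keeps kin fields optional", {
  path <- write_tmp_csv(tibble::tibble(
    id = c("A", "B"), group = c("G1", "G1"), sex = c("F", "M"),
    age = c(12, 5), mother_id = c(NA, "A"), father_id = c(NA, NA)
  ))
  ind <- read_individuals(path)
  expect_equal(ind$is_focal, c(TRUE, FALSE))
  expect_true(is.na(ind$mother_id[1]))
  expect_equal(ind$mother_id[2], "A")
})

test_that("read_individuals rejects duplicate ids and unknown sex codes", {
  dup <- write_tmp_csv(tibble::tibble(
    id = c("Kelele", "Kelele"), group = "G1", sex = "F", age = c(10, 12)
  ))
  expect_error(read_individuals(dup), "duplicate id.*Kelele")
  bad <- write_tmp_csv(tibble::tibble(id = "A", group = "G1", sex = "X", age = 10))
  expect_error(read_individuals(bad), "unknown sex")
})

make_events_files <- function(events, visibility) {
  ep <- write_tmp_csv(events)
  vp <- write_tmp_csv(visibility)
  list(events = ep, visibility = vp)
}

base_vis <- function(scans = 1:3, ids = "A;B;C") {
  tibble::tibble(group = "G1", day = "2013-01-05", scan = scans, visible_ids = ids)
}

test_that("read_scan_events round-trips a single event and keeps grooming direction", {
  f <- make_events_files(
    tibble::tibble(group = "G1", day = "2013-01-05", scan = 1,
                   behaviour = c("close_proximity", "grooming"),
                   actor = "A", partner = "B",
                   direction = c("undirected", "actor_grooms_partner")),
    base_vis()
  )
  sc <- read_scan_events(f$events, f$visibility)
  expect_s3_class(sc, "scan_events")
  expect_equal(nrow(sc$events), 2)
  expect_equal(sc$events$direction[sc$events$behaviour == "grooming"],
               "actor_grooms_partner")
  expect_equal(nrow(sc$visibility), 3)
})

test_that("close and distant proximity in one scan for one dyad is rejected, citing the scan", {
  f <- make_events_files(
    tibble::tibble(group = "G1", day = "2013-01-05", scan = 3,
                   behaviour = c("close_proximity", "distant_proximity"),
                   actor = c("A", "B"), partner = c("B", "A"),
                   direction = "undirected"),
    base_vis()
  )
  expect_error(read_scan_events(f$events, f$visibility), "scan 3")
})

test_that("events with an out-of-sight actor or partner are rejected", {
  f <- make_events_files(
    tibble::tibble(group = "G1", day = "2013-01-05", scan = 1,
                   behaviour = "close_proximity", actor = "A", partner = "D",
                   direction = "undirected"),
    base_vis()
  )
  expect_error(read_scan_events(f$events, f$visibility), "not in visibility")
})

three_ind <- tibble::tibble(
  id = c("A", "B", "C"), group = "G1", sex = c("F", "M", "F"),
  age = c(12, 15, 9), mother_id = NA_character_, father_id = NA_character_
)

test_that("build_dyad_scans applies the out-of-sight and zero-fill rules", {
  # one scan: A-B close, C out of sight -> dyads with >= 1 visible member
  # get rows, the unobserved ones as y = 0
  sc <- scan_events(
    tibble::tibble(group = "G1", day = as.Date("2013-01-05"), scan = 1L,
                   behaviour = "close_proximity", actor = "A", partner = "B",
                   direction = "undirected"),
    tibble::tibble(group = "G1", day = as.Date("2013-01-05"), scan = 1L,
                   ids = list(c("A", "B")))
  )
  tbl <- build_dyad_scans(sc, three_ind, "close_proximity")
  expect_equal(nrow(tbl), 3)
  expect_equal(tbl$y[tbl$i == "A" & tbl$j == "B"], 1L)
  expect_equal(sort(tbl$y), c(0L, 0L, 1L))
})

test_that("dyads with both members out of sight contribute no row", {
  sc <- scan_events(
    tibble::tibble(group = character(), day = as.Date(character()),
                   scan = integer(), behaviour = character(),
                   actor = character(), partner = character(),
                   direction = character()),
    tibble::tibble(group = "G1", day = as.Date("2013-01-05"), scan = 1L,
                   ids = list("A"))
  )
  tbl <- build_dyad_scans(sc, three_ind, "close_proximity")
  # only dyads containing A are retained
  expect_equal(nrow(tbl), 2)
  expect_true(all(tbl$i == "A" | tbl$j == "A"))
})

test_that("lag annotation follows scan order and resets at the start of each day", {
  days <- as.Date(c("2013-01-05", "2013-01-05", "2013-01-06"))
  sc <- scan_events(
    tibble::tibble(group = "G1", day = days, scan = c(1L, 2L, 1L),
                   behaviour = "close_proximity", actor = "A", partner = "B",
                   direction = "undirected"),
    tibble::tibble(group = "G1", day = days, scan = c(1L, 2L, 1L),
                   ids = list(c("A", "B"), c("A", "B"), c("A", "B")))
  )
  two_ind <- three_ind[1:2, ]
  tbl <- build_dyad_scans(sc, two_ind, "close_proximity") |>
    dplyr::arrange(day, scan)
  expect_equal(tbl$y, c(1L, 1L, 1L))
  # y_prev: 0 at first scan, 1 at second scan of day 1, reset to 0 on day 2
  expect_equal(tbl$y_prev, c(0L, 1L, 0L))
})

test_that("first scan of every (dyad, day) block has y_prev = 0", {
  ds <- scan_fixture("tiny")
  tbl <- build_dyad_scans(ds$scans, ds$individuals, "play")
  firsts <- tbl |>
    dplyr::group_by(group, i, j, day) |>
    dplyr::slice_min(scan, n = 1) |>
    dplyr::ungroup()
  expect_true(all(firsts$y_prev == 0))
})

test_that("row counts match a brute-force scan x pair enumeration", {
  for (seed in c(11, 12)) {
    ds <- simulate_scans(sim_config(
      n_groups = 2, group_sizes = c(4L, 5L), days = 3, scans_per_day = 4,
      behaviours = "close_proximity", visibility = 0.7,
      age_range = c(4, 30), seed = seed
    ))
    tbl <- build_dyad_scans(ds$scans, ds$individuals, "close_proximity")
    expect_equal(nrow(tbl), brute_force_row_count(ds$scans, ds$individuals))
  }
})

test_that("dyads where both members are under 7 are excluded, mixed dyads kept", {
  ind <- tibble::tibble(
    id = c("A", "B", "C"), group = "G1", sex = "F", age = c(12, 5, 6),
    mother_id = NA_character_, father_id = NA_character_
  )
  sc <- scan_events(
    tibble::tibble(group = character(), day = as.Date(character()),
                   scan = integer(), behaviour = character(),
                   actor = character(), partner = character(),
                   direction = character()),
    tibble::tibble(group = "G1", day = as.Date("2013-01-05"), scan = 1L,
                   ids = list(c("A", "B", "C")))
  )
  tbl <- build_dyad_scans(sc, ind, "close_proximity")
  pairs <- paste(tbl$i, tbl$j)
  expect_setequal(pairs, c("A B", "A C"))  # B-C (both < 7) excluded
})

test_that("the grooming table has exactly twice the rows of the undirected table", {
  ds <- simulate_scans(sim_config(
    n_groups = 2, group_sizes = c(4L, 4L), days = 3, scans_per_day = 4,
    behaviours = c("close_proximity", "grooming"), visibility = 0.8, seed = 21
  ))
  und <- build_dyad_scans(ds$scans, ds$individuals, "close_proximity")
  gro <- build_dyad_scans(ds$scans, ds$individuals, "grooming")
  expect_equal(nrow(gro), 2 * nrow(und))
})

test_that("unknown behaviour is rejected", {
  ds <- scan_fixture("tiny")
  expect_error(build_dyad_scans(ds$scans, ds$individuals, "wrestling"),
               "unknown behaviour")
})

test_that("raw rates aggregate dyad proportions into individual and group summaries", {
  # dyad A-B observed 10 scans with 2 events -> 0.2; A-C 10 with 3 -> 0.3
  days <- as.Date("2013-01-05") + 0:1
  vis <- tidyr::crossing(day = days, scan = 1:5) |>
    dplyr::mutate(group = "G1", ids = list(c("A", "B", "C")))
  ev <- tibble::tibble(
    group = "G1",
    day = rep(days[1], 5),
    scan = c(1L, 2L, 1L, 2L, 3L),
    behaviour = "close_proximity",
    actor = c("A", "A", "A", "A", "A"),
    partner = c("B", "B", "C", "C", "C"),
    direction = "undirected"
  )
  sc <- scan_events(ev, vis)
  tbl <- build_dyad_scans(sc, three_ind, "close_proximity")
  rr <- compute_raw_rates(tbl)
  expect_equal(rr$dyads$rate[rr$dyads$i == "A" & rr$dyads$j == "B"], 0.2)
  expect_equal(rr$dyads$rate[rr$dyads$i == "A" & rr$dyads$j == "C"], 0.3)
  # individual total = sum of its dyads' proportions
  expect_equal(rr$individuals$total[rr$individuals$id == "A"], 0.5)
  # group mean across individuals
  totals <- rr$individuals$total
  expect_equal(rr$groups$mean, mean(totals))
  expect_equal(rr$groups$sd, sd(totals))
})

test_that("the dyad-scan writer produces a readable CSV audit trail", {
  ds <- scan_fixture("tiny")
  tbl <- build_dyad_scans(ds$scans, ds$individuals, "close_proximity")
  path <- tempfile(fileext = ".csv")
  write_dyad_scans(tbl, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(nrow(back), nrow(tbl))
  expect_equal(back$y, tbl$y)
})
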