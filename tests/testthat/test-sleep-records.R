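test_that("cohort round-trips through CSV and keeps empty series", {
  coh <- make_tiny_cohort()
  pf <- withr::local_tempfile(fileext = ".csv")
  nf <- withr::local_tempfile(fileext = ".csv")
  write_cohort(coh, pf, nf)
  back <- read_cohort(pf, nf)
  expect_equal(nrow(back$persons), 2L)
  obs <- observed_nights(back)
  expect_equal(obs$n_observed[obs$person_id == "p1"], 3L)
  expect_equal(obs$n_observed[obs$person_id == "p2"], 0L)
  expect_equal(as.data.frame(back$nights), as.data.frame(coh$nights),
               tolerance = 1e-12)
  expect_equal(as.data.frame(back$persons), as.data.frame(coh$persons),
               tolerance = 1e-12)
})

test_that("read_cohort enforces referential integrity and flags bad fields", {
  coh <- make_tiny_cohort()
  pf <- withr::local_tempfile(fileext = ".csv")
  nf <- withr::local_tempfile(fileext = ".csv")
  bad_nights <- coh$nights
  bad_nights$person_id[1] <- "ghost"
  readr::write_csv(coh$persons, pf)
  readr::write_csv(bad_nights, nf)
  expect_error(read_cohort(pf, nf), "ghost")

  nf2 <- withr::local_tempfile(fileext = ".csv")
  txt <- readr::format_csv(coh$nights)
  txt <- sub("400", "four-hundred", txt)
  writeLines(txt, nf2)
  readr::write_csv(coh$persons, pf)
  expect_error(read_cohort(pf, nf2), "row")
})

test_that("clock times center at midnight with the documented sign", {
  expect_equal(center_clock_time("23:30", FALSE), -30)
  expect_equal(center_clock_time("00:00", TRUE), 0)
  expect_equal(center_clock_time("00:00", FALSE), 0)
  expect_equal(center_clock_time("01:15", TRUE), 75)
  # strictly monotone over a continuous night from 18:00 to noon
  pre <- sprintf("%02d:%02d", rep(18:23, each = 4), c(0, 15, 30, 45))
  post <- sprintf("%02d:%02d", rep(0:11, each = 4), c(0, 15, 30, 45))
  vals <- c(center_clock_time(pre, FALSE), center_clock_time(post, TRUE))
  expect_true(all(diff(vals) > 0))
})

test_that("validity filter masks short series, keeps persons, is idempotent", {
  coh <- make_tiny_cohort()
  # drop p1 to 2 observed nights
  coh$nights$duration_min[3] <- NA
  coh$nights$bedtime_min[3] <- NA
  coh$nights$waketime_min[3] <- NA
  f <- apply_validity_filter(coh, min_nights = 3L)
  expect_equal(nrow(f$persons), 2L)
  expect_false(f$persons$valid_sleep[f$persons$person_id == "p1"])
  expect_true(all(is.na(f$nights$duration_min)))
  # boundary: exactly 3 observed nights is valid and untouched
  coh3 <- make_tiny_cohort()
  f3 <- apply_validity_filter(coh3, min_nights = 3L)
  expect_true(f3$persons$valid_sleep[f3$persons$person_id == "p1"])
  expect_equal(f3$nights$duration_min, coh3$nights$duration_min)
  # empty series: retained, flagged invalid
  expect_false(f3$persons$valid_sleep[f3$persons$person_id == "p2"])
  # idempotence
  f3b <- apply_validity_filter(f3, min_nights = 3L)
  expect_equal(f3b$nights, f3$nights)
  # person count conserved on a generated cohort too
  g <- small_cohort()
  expect_equal(nrow(apply_validity_filter(g)$persons), nrow(g$persons))
})

test_that("person descriptives use sample SD and propagate missingness", {
  persons <- tibble::tibble(person_id = c("a", "b", "c"), age = 15, sex = 0,
                            maternal_education = 14, income_to_needs = 2)
  nights <- tibble::tibble(
    person_id = c("a", "a", "a", "b", "b"),
    night_index = c(0:2, 0:1), weekend = 0,
    duration_min = c(400, 400, 400, 380, 420),
    bedtime_min = NA_real_, waketime_min = NA_real_
  )
  d <- person_descriptives(cohort(persons, nights))
  pa <- d$person[d$person$person_id == "a", ]
  expect_equal(pa$duration_min_mean, 400)
  expect_equal(pa$duration_min_sd, 0)
  pb <- d$person[d$person$person_id == "b", ]
  expect_equal(pb$duration_min_mean, 400)
  expect_equal(pb$duration_min_sd, sd(c(380, 420)))
  expect_equal(round(pb$duration_min_sd, 3), 28.284)
  pc <- d$person[d$person$person_id == "c", ]
  expect_equal(nrow(pc), 1L)
  expect_true(is.na(pc$duration_min_mean) && is.na(pc$duration_min_sd))
})
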