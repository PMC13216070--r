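test_that("meals within a day collapse to a single recall event", {
  meals <- data.frame(
    household_id = c("h1", "h1", "h1", "h2"),
    day = c(1, 1, 2, 1),
    consumed = c(1, 1, 0, 0),
    quantity_kg = c(0.5, 1.0, 0, NA)
  )
  out <- aggregate_within_day(meals)
  d1 <- out[out$household_id == "h1" & out$day == 1, ]
  expect_equal(d1$consumed, 1)              # two meals, one event
  expect_equal(d1$quantity_kg, 1.5)         # 0.5 + 1.0
  d2 <- out[out$household_id == "h1" & out$day == 2, ]
  expect_equal(d2$consumed, 0)
  expect_equal(out[out$household_id == "h2", "consumed"], 0)
})

test_that("negative meal quantities are rejected with a diagnostic", {
  meals <- data.frame(household_id = "h1", day = 1, consumed = 1,
                      quantity_kg = -2)
  expect_warning(out <- aggregate_within_day(meals), "negative")
  expect_equal(nrow(out), 0)
  expect_equal(nrow(attr(out, "rejected")), 1)
})

test_that("frequency conversions follow the categorical and count rules", {
  expect_equal(compute_frequency(category = "monthly"), 12 / 365)
  expect_equal(round(compute_frequency(category = "monthly"), 3), 0.033)
  expect_equal(compute_frequency(category = "weekly"), 52 / 365)
  expect_equal(compute_frequency(category = "daily"), 1)
  expect_equal(compute_frequency(category = "yearly"), 1 / 365)
  expect_equal(round(compute_frequency(2, 6), 2), 0.33)
  expect_equal(compute_frequency(0, 5), 0)
  expect_error(compute_frequency(7, 6), "monitored_days")
  expect_error(compute_frequency(1, 1), "monitored_days >= 2")
  expect_error(compute_frequency(category = "fortnightly"), "unknown")
})

test_that("frequencies and quantities stay in their ranges", {
  set.seed(1)
  ev <- rbinom(50, 20, 0.3); md <- rep(20, 50)
  f <- compute_frequency(ev, md)
  expect_true(all(f >= 0 & f <= 1))
  q <- standardize_daily_quantity(runif(50, 0, 30), sample(1:14, 50, TRUE))
  expect_true(all(q >= 0))
})

test_that("quantities standardize to kg per day", {
  expect_equal(standardize_daily_quantity(12, 3), 4)   # 12 kg over 72 h
  expect_equal(standardize_daily_quantity(2, 1), 2)
  expect_equal(standardize_daily_quantity(0, 7), 0)
  expect_error(standardize_daily_quantity(1, 0.5), "recall_days")
})

test_that("local units convert through carcass fractions and direct factors", {
  tab <- c(duiker = 10, piece = 0.4)
  rec <- data.frame(unit = c("entire", "half", "quarter", "piece", "basket"),
                    count = c(1, 1, 2, 3, 1),
                    species = c("duiker", "duiker", "duiker", NA, NA))
  suppressMessages(kg <- convert_local_units(rec, tab))
  expect_equal(kg[1:4], c(10, 5, 5, 1.2))
  expect_true(is.na(kg[5]))
  expect_equal(attr(kg, "flagged"), c(FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_error(convert_local_units(rec, c(duiker = -1)), "table > 0")
})

test_that("AME combines the age/sex multipliers and is linear in counts", {
  expect_equal(compute_ame(n_adult_male = 2), 2)
  expect_equal(compute_ame(1, 1, 0, 1), 2.71)
  expect_equal(compute_ame(n_child_unspecified = 3), 2.34)
  expect_equal(compute_ame(n_adult_unspecified = 2), 1.86)
  expect_true(is.na(compute_ame(0, 0, 0, 0, 0, 0, 0)))  # unknown, not zero
  expect_error(compute_ame(-1), ">= 0")
  set.seed(7)
  for (i in 1:5) {
    a <- sample(0:4, 7, TRUE); b <- sample(0:4, 7, TRUE)
    expect_equal(do.call(compute_ame, as.list(a + b)),
                 do.call(compute_ame, as.list(a)) +
                   do.call(compute_ame, as.list(b)))
  }
})

test_that("distance matrix is great-circle, symmetric and hollow", {
  loc <- data.frame(location_id = c("a", "b"),
                    lon = c(10, 10), lat = c(0, 1))
  D <- build_distance_matrix(loc)
  expect_equal(D["a", "b"], 111.1949, tolerance = 1e-3)
  set.seed(2)
  loc <- data.frame(lon = runif(8, 10, 20), lat = runif(8, -5, 5))
  D <- build_distance_matrix(loc)
  expect_equal(D, t(D))
  expect_equal(unname(diag(D)), rep(0, 8))
  # triangle inequality on sampled triples
  for (k in 1:20) {
    ijk <- sample(8, 3)
    expect_lte(D[ijk[1], ijk[2]],
               D[ijk[1], ijk[3]] + D[ijk[3], ijk[2]] + 1e-9)
  }
  dup <- data.frame(lon = c(10, 10, 11), lat = c(0, 0, 1))
  expect_message(D2 <- build_distance_matrix(dup), "identical")
  expect_equal(D2[1, 2], 0)
})

test_that("euclidean distances are available for projected coordinates", {
  loc <- data.frame(lon = c(0, 3), lat = c(0, 4))
  D <- build_distance_matrix(loc, method = "euclidean")
  expect_equal(D[1, 2], 5)
})

test_that("ingestion translates missing codes without touching coordinates", {
  studies <- data.frame(study_id = "s1", study_type = 1, period = 1)
  locations <- data.frame(location_id = "l1", lon = 10, lat = -1,
                          location_type = "village",
                          hpd = 5, rem = 0.2, hdi = 0.5, fci = 0.7)
  households <- data.frame(household_id = c("h1", "h2"), location_id = "l1",
                           study_id = "s1", mdays = c(10, 3),
                           frequency = c(0.2, -1),
                           education = c("unknown", "-1"),
                           ame = c(-1, 4.2))
  recalls <- data.frame(recall_id = c("r1", "r2"), household_id = "h1",
                        days = 1, consumed = c(1, 0),
                        quantity_kg = c(0.5, -1), ame = c(-1, -1))
  sv <- ingest_survey(studies, locations, households, recalls)
  expect_equal(sv$locations$lat, -1)               # a legal coordinate
  expect_true(is.na(sv$households$frequency[2]))
  expect_true(is.na(sv$households$ame[1]))
  expect_true(all(is.na(sv$recalls$quantity_kg)) == FALSE)
  expect_true(is.na(sv$recalls$quantity_kg[2]))
  expect_equal(sv$report$flags$missing_ame_households, 1)
})

test_that("ingestion rejects duplicate recall ids and bad invariants", {
  studies <- data.frame(study_id = "s1", study_type = 1, period = 1)
  locations <- data.frame(location_id = "l1", lon = 10, lat = 0,
                          location_type = "village",
                          hpd = 5, rem = 0.2, hdi = 0.5, fci = 0.7)
  households <- data.frame(household_id = c("h1", "h2"), location_id = "l1",
                           mdays = c(10, 1), frequency = c(0.2, 0.4),
                           education = "unknown", ame = c(3, 4))
  recalls <- data.frame(recall_id = c("r1", "r1", "r2", "r3"),
                        household_id = "h1", days = 1,
                        consumed = c(1, 1, 0, 0),
                        quantity_kg = c(0.5, 0.5, 0, 2), ame = 3)
  sv <- ingest_survey(studies, locations, households, recalls)
  # both copies of the duplicated id are dropped and logged
  expect_equal(sv$report$exclusions$recall_duplicate_id, 2)
  # a frequency observed after a single monitored day is invalid
  expect_equal(sv$report$exclusions$household_frequency_needs_mdays2, 1)
  # positive quantity on a non-consumption recall is invalid
  expect_equal(sv$report$exclusions$recall_quantity_without_consumption, 1)
  expect_equal(nrow(sv$recalls), 1)
})

test_that("survey tables round-trip through disk", {
  dir <- withr::local_tempdir()
  sv <- tiny_world()$survey
  write_survey(sv, dir)
  sv2 <- read_survey(dir)
  expect_equal(nrow(sv2$recalls), nrow(sv$recalls))
  expect_equal(sv2$households$frequency, sv$households$frequency)
  expect_true(file.exists(file.path(dir, "ingestion_report.json")))
})
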