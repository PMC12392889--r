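p_default <- default_params()

test_that("a single-residence person reduces to the pathway functions", {
  tc <- make_tiny_cohort()
  dep <- make_dep(cs137 = 22)
  dt <- cohort_doses(tc$cohort, tc$residences, dep, p_default)
  t_end <- followup_horizon_days()
  expect_equal(t_end, 10840)
  for (i in 1:2) {
    sex <- tc$cohort$sex[i]
    expect_equal(dt$d_ext[i], external_dose(dep, sex, t_end, p_default))
    expect_equal(dt$d_cs_ing[i], cs_ingestion_dose(dep, sex, t_end, p_default))
    expect_equal(dt$d_milk[i], milk_iodine_dose(dep, t_end, p_default))
    expect_equal(dt$d_inh[i], inhalation_dose(dep, p_default, t_end = t_end))
  }
  check_dose_additivity(dt)
})

test_that("splitting a residence at identical deposition leaves the dose unchanged", {
  dep <- rbind(make_dep(cs137 = 15, location_id = "A"),
               make_dep(cs137 = 15, location_id = "B"))
  co <- data.frame(person_id = "P1", sex = "M",
                   birth_date = as.Date("1960-01-01"),
                   followup_end = ADMIN_END_DATE,
                   end_reason = "administrative", stringsAsFactors = FALSE)
  res1 <- data.frame(person_id = "P1", location_id = "A",
                     start_date = EPOCH_DATE, end_date = ADMIN_END_DATE,
                     stringsAsFactors = FALSE)
  res2 <- data.frame(person_id = c("P1", "P1"), location_id = c("A", "B"),
                     start_date = c(EPOCH_DATE, as.Date("1999-07-01")),
                     end_date = c(as.Date("1999-07-01"), ADMIN_END_DATE),
                     stringsAsFactors = FALSE)
  d1 <- cohort_doses(co, res1, dep, p_default)
  d2 <- cohort_doses(co, res2, dep, p_default)
  for (cc in c("d_milk", "d_inh", "d_ext", "d_cs_ing", "d_total")) {
    expect_equal(d2[[cc]], d1[[cc]], tolerance = 1e-10)
  }
  # freezing the epoch residence must agree when depositions are equal
  d3 <- cohort_doses(co, res2, dep, p_default, freeze_epoch_residence = TRUE)
  expect_equal(d3$d_total, d1$d_total, tolerance = 1e-10)
})

test_that("migration between unequal depositions follows the residence history", {
  dep <- rbind(make_dep(cs137 = 30, location_id = "hi"),
               make_dep(cs137 = 2, location_id = "lo"))
  co <- data.frame(person_id = "P1", sex = "F",
                   birth_date = as.Date("1970-03-03"),
                   followup_end = ADMIN_END_DATE,
                   end_reason = "administrative", stringsAsFactors = FALSE)
  move <- as.Date("1991-04-28")
  res <- data.frame(person_id = c("P1", "P1"), location_id = c("hi", "lo"),
                    start_date = c(EPOCH_DATE, move),
                    end_date = c(move, ADMIN_END_DATE), stringsAsFactors = FALSE)
  d <- cohort_doses(co, res, dep, p_default)
  t_mv <- days_since_epoch(move)
  t_end <- followup_horizon_days()
  expect_equal(d$d_ext,
               external_dose(dep[1, ], "F", t_mv, p_default) +
                 external_dose(dep[2, ], "F", t_end, p_default, t_start = t_mv),
               tolerance = 1e-12)
  # milk and inhalation come from the epoch residence
  expect_equal(d$d_milk, milk_iodine_dose(dep[1, ], t_end, p_default))
  # frozen mode uses the high-deposition epoch residence throughout
  df <- cohort_doses(co, res, dep, p_default, freeze_epoch_residence = TRUE)
  expect_gt(df$d_ext, d$d_ext)
})

test_that("truncating follow-up never increases any component", {
  dep <- make_dep(cs137 = 11)
  ends <- as.Date(c("1986-10-01", "1996-04-28", "2006-04-28", "2015-12-31"))
  prev <- NULL
  for (e in as.list(ends)) {
    tc <- make_tiny_cohort(followup = e)
    tc$cohort$end_reason <- c("death", "death")
    if (e == ADMIN_END_DATE) tc$cohort$end_reason <- rep("administrative", 2)
    d <- cohort_doses(tc$cohort, tc$residences, dep, p_default)
    if (!is.null(prev)) {
      for (cc in c("d_milk", "d_inh", "d_ext", "d_cs_ing", "d_total")) {
        expect_true(all(d[[cc]] >= prev[[cc]] - 1e-12))
      }
    }
    prev <- d
  }
})

test_that("follow-up ending at the epoch yields zero dose, not an error", {
  tc <- make_tiny_cohort(followup = EPOCH_DATE)
  tc$cohort$end_reason <- c("death", "emigration")
  d <- cohort_doses(tc$cohort, tc$residences, make_dep(), p_default)
  expect_equal(d$d_total, c(0, 0))
})

test_that("cohort evaluation is order-stable and matches person_dose", {
  cfg <- scenario_config(n_locations = 10, n_persons = 60, seed = 7)
  dep <- generate_deposition(cfg)
  cg <- generate_cohort(cfg, dep)
  d <- cohort_doses(cg$cohort, cg$residences, dep, p_default)
  expect_equal(d$person_id, sort(cg$cohort$person_id))
  perm <- sample(nrow(cg$cohort))
  d_perm <- cohort_doses(cg$cohort[perm, ], cg$residences, dep, p_default)
  expect_equal(d_perm, d)
  one <- cg$cohort[17, , drop = FALSE]
  expect_equal(person_dose(one, cg$residences, dep, p_default),
               d[d$person_id == one$person_id, ], ignore_attr = TRUE)
  # mean of totals equals independently recomputed per-person mean
  expect_equal(mean(d$d_total),
               mean(d$d_milk + d$d_inh + d$d_ext + d$d_cs_ing))
})

test_that("unknown residence locations are reported with person context", {
  tc <- make_tiny_cohort()
  tc$residences$location_id <- c("L1", "NOWHERE")
  expect_error(cohort_doses(tc$cohort, tc$residences, make_dep(), p_default),
               "NOWHERE.*P2")
})

test_that("cohort validation rejects broken histories", {
  tc <- make_tiny_cohort()
  bad <- tc
  bad$cohort$birth_date[1] <- as.Date("1990-01-01")
  expect_error(validate_cohort(bad$cohort, bad$residences), "closed cohort")
  bad <- tc
  bad$residences$start_date[2] <- as.Date("1987-01-01")
  expect_error(validate_cohort(bad$cohort, bad$residences), "cover the epoch")
  bad <- tc
  bad$residences <- rbind(bad$residences, data.frame(
    person_id = "P1", location_id = "L1",
    start_date = as.Date("2000-01-01"), end_date = as.Date("1999-01-01"),
    stringsAsFactors = FALSE))
  expect_error(validate_cohort(bad$cohort, bad$residences), "P1")
})

test_that("summaries reproduce order statistics and degenerate inputs", {
  d <- dose_result(person_id = c("a", "b"), d_milk = c(1, 1), d_inh = c(0, 0),
                   d_ext = c(0, 2), d_cs_ing = c(0, 0), sex = c("F", "F"))
  s <- suppressWarnings(summarize_doses(d))
  tot <- s[s$component == "d_total", ]
  expect_equal(tot$mean, 2)
  expect_equal(tot$min, 1)
  expect_equal(tot$max, 3)
  # constant input: every statistic collapses to the constant
  dc <- dose_result(person_id = 1:5, d_milk = rep(0.25, 5),
                    d_inh = rep(0, 5), d_ext = rep(0, 5),
                    d_cs_ing = rep(0, 5), sex = rep("M", 5))
  sc <- suppressWarnings(summarize_doses(dc))
  mm <- sc[sc$component == "d_milk", ]
  expect_equal(unlist(mm[c("mean", "median", "p5", "p95", "min", "max")]),
               rep(0.25, 6), ignore_attr = TRUE)
  # percentiles against an independent sort-based computation
  set.seed(505)
  x <- stats::rlnorm(10000, 0, 0.7)
  dl <- dose_result(person_id = seq_along(x), d_milk = x,
                    d_inh = 0, d_ext = 0, d_cs_ing = 0, sex = "F")
  sl <- suppressWarnings(summarize_doses(dl))
  xs <- sort(x)
  interp <- function(prob) {
    h <- (length(xs) - 1) * prob + 1
    xs[floor(h)] + (h - floor(h)) * (xs[floor(h) + 1] - xs[floor(h)])
  }
  row <- sl[sl$component == "d_milk", ]
  expect_equal(row$p5, interp(0.05))
  expect_equal(row$p95, interp(0.95))
  expect_equal(row$median, interp(0.5))
  # summary invariant: ordering of the order statistics
  expect_true(all(sl$min <= sl$p5 & sl$p5 <= sl$median &
                    sl$median <= sl$p95 & sl$p95 <= sl$max))
})

test_that("missing sex groups are omitted with a warning", {
  d <- dose_result(person_id = "a", d_milk = 1, d_inh = 0, d_ext = 0,
                   d_cs_ing = 0, sex = "F")
  expect_warning(s <- summarize_doses(d), "no persons of sex 'M'")
  expect_true(all(s$sex == "F"))
})

test_that("cumulative curves are monotone and consistent with the summary", {
  cfg <- scenario_config(n_locations = 8, n_persons = 80, seed = 11)
  dep <- generate_deposition(cfg)
  cg <- generate_cohort(cfg, dep)
  grid <- c(0, 30, 182, 365, 1000, 3652, 7305, 10840)
  cv <- cumulative_curves(cg$cohort, cg$residences, dep, p_default, grid)
  expect_true(all(cv$mean_mGy[cv$day == 0] == 0))
  for (s in c("F", "M")) {
    for (cc in unique(cv$component)) {
      y <- cv$mean_mGy[cv$sex == s & cv$component == cc]
      expect_true(all(diff(y) >= -1e-12))
    }
  }
  d <- cohort_doses(cg$cohort, cg$residences, dep, p_default)
  sm <- summarize_doses(d)
  final <- cv[cv$day == 10840, ]
  for (i in seq_len(nrow(final))) {
    expect_equal(final$mean_mGy[i],
                 sm$mean[sm$sex == final$sex[i] &
                           sm$component == final$component[i]],
                 tolerance = 1e-10)
  }
  expect_error(cumulative_curves(cg$cohort, cg$residences, dep, p_default,
                                 c(0, 10, 5)), "increasing")
})

test_that("totals never fall below the iodine floor when deposition is positive", {
  cfg <- scenario_config(n_locations = 6, n_persons = 50, seed = 23)
  dep <- generate_deposition(cfg)
  cg <- generate_cohort(cfg, dep)
  d <- cohort_doses(cg$cohort, cg$residences, dep, p_default)
  expect_true(all(d$d_total >= d$d_milk + d$d_inh - 1e-12))
  alive <- days_since_epoch(cg$cohort$followup_end[order(cg$cohort$person_id)]) > 0
  expect_true(all(d$d_total[alive] > 0))
})

test_that("age factor scales the internal pathways only", {
  tc <- make_tiny_cohort()
  dep <- make_dep(cs137 = 10)
  base <- cohort_doses(tc$cohort, tc$residences, dep, p_default)
  tc$cohort$age_factor <- c(2, 1)
  scaled <- cohort_doses(tc$cohort, tc$residences, dep, p_default)
  expect_equal(scaled$d_milk[1], 2 * base$d_milk[1])
  expect_equal(scaled$d_inh[1], 2 * base$d_inh[1])
  expect_equal(scaled$d_cs_ing[1], 2 * base$d_cs_ing[1])
  expect_equal(scaled$d_ext[1], base$d_ext[1])
  expect_equal(scaled$d_total[2], base$d_total[2])
})
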