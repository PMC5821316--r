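test_that("TDAM is total length over total duration in each window", {
  # constant 100 m per 2-h step: 50 m/h in every window
  st <- step_table(rep(100, 60))
  td <- tdam(st)
  expect_true(all(abs(td$tdam - 50) < 1e-12))
  expect_true(all(td$coverage == 1))

  # hand computation on a gapped track: fixes every 2 h over 80 h with the
  # t = 4 h fix missing, each observed step 60 m
  tt <- setdiff(seq(0, 80, by = 2), 4)
  f <- tibble::tibble(animal_id = "A",
                      t = utc("2016-06-01 00:00:00") + tt * 3600,
                      x = 60 * seq_along(tt), y = 0)
  st2 <- build_steps(f, 2)   # the 4-h gap at t = 4..8 h produces no step
  td2 <- tdam(st2, min_coverage = 0.5)
  w1 <- td2[td2$window_start == f$t[1], ]
  # window [0, 72 h] holds 34 observed steps of 60 m / 2 h
  expect_equal(w1$tdam, (34 * 60) / (34 * 2))
  expect_equal(w1$coverage, 68 / 72)

  # a window with insufficient coverage is missing, not zero
  td3 <- tdam(st2, min_coverage = 0.95)
  expect_true(is.na(td3$tdam[1]))

  expect_error(tdam(st, window_hours = 3), "two fix intervals")
})

test_that("KDE quantile threshold matches the analytic exponential quantile", {
  set.seed(91)
  x <- rexp(10000, 1 / 50)
  # analytic 99.9% quantile of Exp(mean 50) is -50 log(0.001)
  thr <- calfsurv:::.kde_quantile(x, 0.999)
  expect_lt(abs(thr - (-50 * log(0.001))) / (-50 * log(0.001)), 0.10)

  # degenerate single value with vanishing bandwidth collapses to it
  expect_equal(calfsurv:::.kde_quantile(42, 0.999, bw = 1e-9), 42,
               tolerance = 1e-3)

  # monotone in the quantile level
  q <- vapply(c(0.9, 0.99, 0.999), function(p)
    calfsurv:::.kde_quantile(x, p), double(1))
  expect_true(all(diff(q) > 0))
})

test_that("reference thresholds pool the correct periods and females", {
  # two reference females whose post-calving windows carry known values
  set.seed(17)
  mk_female <- function(id, a, bp) {
    f <- simulate_female(id, "parturient_survived", a = a, bp = bp,
                         season = test_season)
    build_steps(f$fixes, 2)
  }
  st <- rbind(mk_female("R1", 200, utc("2016-05-30 11:00:00")),
              mk_female("R2", 300, utc("2016-06-02 13:00:00")))
  attr(st, "nominal_interval") <- 2
  td <- tdam(st)
  status <- tibble::tibble(
    animal_id = c("R1", "R2"),
    parturient = TRUE,
    parturition_date = c(utc("2016-05-30 11:00:00"),
                         utc("2016-06-02 13:00:00")),
    fate = "survived_4wk", mortality_date = as.POSIXct(NA))
  pt <- threshold_from_reference(td, status, "post_calving_3d")
  mt <- threshold_from_reference(td, status, "weeks_2_to_4")
  expect_gt(as.numeric(pt), 0)
  # early post-calving movement is far below the late-recovery level
  expect_lt(as.numeric(pt), as.numeric(mt))
  expect_equal(attr(pt, "n_females"), 2L)

  # a female with an early calf loss is ineligible for the mortality
  # threshold but eligible (calf survived >= 1 wk) for the parturition one
  status2 <- status
  status2$fate[2] <- "mortality"
  status2$mortality_date[2] <- status2$parturition_date[2] + 10 * 86400
  expect_equal(attr(threshold_from_reference(td, status2, "post_calving_3d"),
                    "n_females"), 2L)
  expect_equal(attr(threshold_from_reference(td, status2, "weeks_2_to_4"),
                    "n_females"), 1L)
  status3 <- status2
  status3$fate <- "mortality"
  status3$mortality_date <- status3$parturition_date + 2 * 86400
  expect_error(threshold_from_reference(td, status3, "post_calving_3d"),
               "no eligible")
})

test_that("moving-window classification finds first crossings in order", {
  season <- test_season
  # flat series above both thresholds: no parturition, hence no mortality
  flat <- tdam_table(rep(100, 200))
  r <- classify_pbm(flat, parturition_threshold = 20,
                    mortality_threshold = 150, season = season)
  expect_false(r$parturition)
  expect_true(is.na(r$mortality))

  # drop below the parturition threshold at window 50, spike above the
  # mortality threshold at window 80
  v <- rep(100, 200)
  v[50:70] <- 5
  v[80:90] <- 300
  r2 <- classify_pbm(tdam_table(v), 20, 150, season)
  expect_true(r2$parturition)
  expect_equal(r2$parturition_date, tdam_table(v)$window_start[50])
  expect_true(r2$mortality)
  expect_equal(r2$mortality_date, tdam_table(v)$window_start[80])

  # a spike more than 28 days after the detected parturition is ignored
  v3 <- rep(100, 500)
  v3[10] <- 5
  v3[400] <- 300   # 390 windows * 2 h later = 32.5 d
  r3 <- classify_pbm(tdam_table(v3), 20, 150, season)
  expect_true(r3$parturition)
  expect_false(r3$mortality)
})

test_that("simulated calf-mortality females are classified with dated events", {
  set.seed(23)
  bp <- utc("2016-06-01 07:00:00")
  mp <- utc("2016-06-09 07:00:00")
  f <- simulate_female("M", "parturient_mortality", a = 250, bp = bp,
                       mp = mp, season = test_season, fix_success = 0.95)
  td <- tdam(rarefy_top_steps(build_steps(f$fixes, 2)))
  # thresholds between the movement regimes: 15 m/h sits between the
  # post-calving crawl and adult travel, 60 m/h between the late-recovery
  # ramp and the resumed adult rate (~125 m/h for a = 250 m per 2 h)
  r <- classify_pbm(td, parturition_threshold = 15,
                    mortality_threshold = 60, season = test_season)
  expect_true(r$parturition)
  expect_true(r$mortality)
  # detected dates lead the true events by at most one window (the known
  # early bias of window-start dating) and never trail them by more
  expect_lt(abs(as.numeric(difftime(r$parturition_date, bp, units = "hours"))),
            72 + 2)
  expect_lt(abs(as.numeric(difftime(r$mortality_date, mp, units = "hours"))),
            72 + 2)
})

test_that("classification is monotone in both thresholds", {
  set.seed(29)
  v <- pmax(0, 100 + cumsum(rnorm(300, 0, 10)))
  td <- tdam_table(v)
  part_called <- function(pt) classify_pbm(td, pt, 1e9, test_season)$parturition
  calls <- vapply(c(5, 20, 50, 90, 120), part_called, logical(1))
  expect_true(all(diff(calls) >= 0))  # raising the threshold never un-calls
})

test_that("k-fold enumeration is complete, distinct, and lexicographic", {
  set.seed(37)
  mk <- function(ids) {
    st <- do.call(rbind, lapply(ids, function(id) {
      build_steps(simulate_female(id, "parturient_survived", a = 250,
                                  bp = utc("2016-06-01 05:00:00"),
                                  season = test_season)$fixes, 2)
    }))
    attr(st, "nominal_interval") <- 2
    st
  }
  ids <- sprintf("R%02d", 1:5)
  td <- tdam(mk(ids))
  status <- tibble::tibble(animal_id = ids, parturient = TRUE,
                           parturition_date = utc("2016-06-01 05:00:00"),
                           fate = "survived_4wk",
                           mortality_date = as.POSIXct(NA))
  kf <- kfold_thresholds(td, status, subset_size = 3)
  expect_equal(nrow(kf), choose(5, 3))
  expect_equal(anyDuplicated(vapply(kf$ref_ids, paste, "", collapse = ",")), 0L)
  expect_equal(kf$ref_ids[[1]], ids[1:3])  # lexicographic order

  # the full pool gives a single set equal to the direct thresholds
  kf1 <- kfold_thresholds(td, status)
  expect_equal(nrow(kf1), 1)
  expect_equal(kf1$parturition_threshold,
               as.numeric(threshold_from_reference(td, status,
                                                   "post_calving_3d")))
  expect_error(kfold_thresholds(td, status, subset_size = 9), "exceeds")
})

test_that("pooled predictions reproduce proportion and conclusiveness rules", {
  # 35 sets all calling parturition, mortality split 17/18
  per_set <- tibble::tibble(
    set_id = 1:35, animal_id = "F1", parturition = TRUE,
    parturition_date = utc("2016-06-01") + (1:35) * 3600,
    mortality = c(rep(TRUE, 17), rep(FALSE, 18)),
    mortality_date = utc("2016-06-10"))
  p <- pool_predictions(per_set)
  expect_equal(p$prop_parturition, 1.00)
  expect_equal(p$prop_mortality, 17 / 35, tolerance = 1e-12)
  expect_true(p$parturition_conclusive)
  expect_equal(p$status, "parturition_with_inconclusive_fate")

  # unanimous mortality
  per_set$mortality <- TRUE
  p2 <- pool_predictions(per_set)
  expect_equal(p2$status, "parturition_mortality")
  expect_equal(p2$prop_mortality, 1.00)

  # a single threshold set is conclusive by construction
  p3 <- pool_predictions(per_set[1, ])
  expect_equal(p3$prop_parturition, 1.0)
  expect_true(p3$parturition_conclusive)

  expect_error(pool_predictions(per_set[0, ]), "no per-set")
})

test_that("herd-level PBM holds out reference females from their own sets", {
  set.seed(43)
  h <- simulate_herd(n = 12, seed = 43)
  st <- rarefy_top_steps(build_steps(h$fixes, 2))
  elig <- h$truth$animal_id[h$truth$parturient %in% TRUE &
                              h$truth$fate == "survived_4wk"]
  pool <- sort(elig)[1:4]
  res <- pbm_herd(st, h$truth, test_season, subset_size = 3, pool = pool)
  expect_equal(nrow(res$thresholds), choose(4, 3))
  preds <- res$predictions
  # pool members are scored only against the sets excluding them
  for (id in pool) {
    expect_equal(preds$n_sets[preds$animal_id == id], choose(3, 3))
  }
  # all other animals are scored against every set
  other <- setdiff(preds$animal_id, pool)
  expect_true(all(preds$n_sets[preds$animal_id %in% other] == choose(4, 3)))
})
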