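# Behavioral generator and the cleaning / coding / summary pipeline.

fit_act <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      des <- quick_classic(11)
      fit <- fit_fan_sgns(des, seeds = 1:2, epochs = 8,
                          config = sgns_config(dimension = 30))
      cache <<- list(design = des, act = build_activation_table(fit, des))
    }
    cache
  }
})

test_that("trial counts and schema follow participants x rounds x 48", {
  fa <- fit_act()
  tr <- generate_trials(fa$design, fa$act,
                        generator_params(n_participants = 10, n_rounds = 3,
                                         rng_seed = 1))
  expect_equal(nrow(tr), 10 * 3 * 48)
  expect_named(tr, c("participant_id", "sentence_id", "kind", "fan_condition",
                     "varied_category", "round", "rt_ms", "correct"))
  expect_true(all(tr$rt_ms > 0))
  expect_true(all(tr$fan_condition %in% c(2L, 4L)))
  expect_equal(sum(tr$kind == "target"), sum(tr$kind == "foil"))
  # deterministic under the seed
  tr2 <- generate_trials(fa$design, fa$act,
                         generator_params(n_participants = 10, n_rounds = 3,
                                          rng_seed = 1))
  expect_identical(tr, tr2)
})

test_that("degenerate noise produces the pure linking-function RTs", {
  fa <- fit_act()
  act <- fa$act
  act$shifted_dot <- rep(1.5, nrow(act))
  p <- generator_params(sigma_log = 1e-12, participant_sd = 0,
                        item_sd = 0, n_participants = 2, rng_seed = 3)
  tr <- generate_trials(fa$design, act, p)
  expect_equal(stats::sd(log(tr$rt_ms - p$shift_ms)), 0, tolerance = 1e-6)
  expect_equal(tr$rt_ms[1],
               p$shift_ms + retrieval_time(1.5, p$linking), tolerance = 1e-4)
})

test_that("higher activation gives strictly faster trials when noise is off", {
  fa <- fit_act()
  act <- fa$act
  act$shifted_dot <- ifelse(act$fan_condition == 2, 2.0, 1.0)
  p <- generator_params(sigma_log = 1e-12, participant_sd = 0, item_sd = 0,
                        n_participants = 3, rng_seed = 4)
  tr <- generate_trials(fa$design, act, p)
  tt <- tr[tr$kind == "target", ]
  expect_lt(max(tt$rt_ms[tt$fan_condition == 2]),
            min(tt$rt_ms[tt$fan_condition == 4]))
})

test_that("missing activations are reported by sentence", {
  fa <- fit_act()
  expect_error(generate_trials(fa$design, fa$act[-3, ], generator_params()),
               "missing activation.*3")
})

test_that("absolute RT bounds remove exactly the planted extremes", {
  tr <- toy_trials()
  tr$rt_ms[2] <- 100     # below 200 ms floor
  tr$rt_ms[5] <- 100000  # above 90 s ceiling
  res <- clean_rts(tr, cleaning_config(sd_multiplier = 100))
  expect_equal(nrow(res$trials), 4L)
  expect_equal(res$report$n_removed, c(2L, 0L))
  expect_equal(res$report$pct_removed[1], 100 * 2 / 6)
})

test_that("sd trimming removes exactly a planted outlier, on stage-1 survivors", {
  base <- rep(c(900, 1000, 1100), 40)
  tr <- data.frame(participant_id = "pp1", sentence_id = 1,
                   kind = "target", fan_condition = 2L,
                   varied_category = "person", round = 1L,
                   rt_ms = base, correct = TRUE)
  m <- mean(base)
  s <- stats::sd(c(base, m + 0))  # close enough; recompute exactly below
  s <- stats::sd(base)
  tr$rt_ms[1] <- m + 3.5 * s
  # recompute the post-plant mean/sd the way stage 2 sees them
  m2 <- mean(tr$rt_ms)
  s2 <- stats::sd(tr$rt_ms)
  stopifnot(abs(tr$rt_ms[1] - m2) > 3 * s2)
  res <- clean_rts(tr, cleaning_config())
  expect_equal(res$report$n_removed, c(0L, 1L))
  expect_false(any(res$trials$rt_ms > m + 3 * s))
  # identical RTs: zero sd removes nothing
  flat <- tr
  flat$rt_ms <- 1000
  expect_equal(clean_rts(flat)$report$n_removed, c(0L, 0L))
})

test_that("cleaning report stages sum to the total removed", {
  fa <- fit_act()
  tr <- generate_trials(fa$design, fa$act,
                        generator_params(n_participants = 20, rng_seed = 9))
  tr$rt_ms[c(3, 50)] <- 10
  tr$rt_ms[100] <- 1e6
  res <- clean_rts(tr)
  expect_equal(sum(res$report$n_removed), nrow(tr) - nrow(res$trials))
  expect_gte(res$report$n_removed[1], 3L)
})

test_that("participant exclusion is strict at the threshold", {
  tr <- data.frame(
    participant_id = rep(c("lo", "exact", "hi"), each = 20),
    correct = c(rep(c(TRUE, FALSE), c(11, 9)),   # 0.55
                rep(c(TRUE, FALSE), c(12, 8)),   # 0.60 exactly
                rep(c(TRUE, FALSE), c(18, 2)))   # 0.90
  )
  res <- exclude_participants(tr, threshold = 0.6)
  expect_equal(res$excluded, "lo")
  expect_setequal(unique(res$trials$participant_id), c("exact", "hi"))
})

test_that("a planted low performer is the only exclusion in a synthetic cohort", {
  fa <- fit_act()
  tr <- generate_trials(fa$design, fa$act,
                        generator_params(n_participants = 15, rng_seed = 2))
  bad <- tr$participant_id == "pp007"
  tr$correct[bad] <- rep(c(TRUE, FALSE), length.out = sum(bad))  # 0.5
  res <- exclude_participants(tr, 0.6)
  expect_equal(res$excluded, "pp007")
})

test_that("contrast codes follow the sum-coding rules", {
  tr <- data.frame(kind = c("foil", "target", "target", "foil"),
                   fan_condition = c(4L, 2L, 4L, 2L))
  cc <- code_contrasts(tr)
  expect_equal(cc$fan_target, c(0L, -1L, 1L, 0L))
  expect_equal(cc$fan_foil, c(1L, 0L, 0L, -1L))
  expect_equal(cc$stimulus_type, c(-1L, 1L, 1L, -1L))
  # invariance to rt/correct values
  tr2 <- cbind(tr, rt_ms = c(1, 2, 3, 4), correct = c(TRUE, FALSE, TRUE, TRUE))
  cc2 <- code_contrasts(tr2)
  expect_equal(cc2[, c("fan_target", "fan_foil", "stimulus_type")],
               cc[, c("fan_target", "fan_foil", "stimulus_type")])
})

test_that("condition summaries match hand computation on a toy table", {
  tr <- toy_trials()
  sm <- summarize_conditions(tr, kind = "target")
  # targets: fan2 rts 1000, 1200; person fan4 rts 2000, 1800
  f2 <- sm[sm$fan == 2 & sm$condition == "person", ]
  expect_equal(f2$mean_rt, 1100)
  expect_equal(f2$se_rt, stats::sd(c(1000, 1200)) / sqrt(2))
  expect_equal(f2$mean_accuracy, 1)
  f4 <- sm[sm$fan == 4 & sm$condition == "person", ]
  expect_equal(f4$mean_rt, 1900)
  expect_equal(f4$mean_accuracy, 0.5)
  # fan-2 rows identical across person / location / combined
  rows2 <- sm[sm$fan == 2, c("n", "mean_rt", "se_rt", "mean_accuracy")]
  expect_true(all(vapply(rows2, function(col) length(unique(col)) == 1L,
                         logical(1))))
  # combined fan-4 pools the varied categories; empty cells carry n = 0
  expect_equal(sm$n[sm$condition == "combined" & sm$fan == 4],
               sum(tr$kind == "target" & tr$fan_condition == 4))
  expect_equal(sm$n[sm$condition == "location" & sm$fan == 4], 0L)
  expect_true(is.na(sm$mean_rt[sm$condition == "location" & sm$fan == 4]))
})

test_that("combined fan-4 row pools person- and location-varied trials", {
  tr <- rbind(
    transform(toy_trials(), varied_category = "person"),
    transform(toy_trials(), varied_category = "location")
  )
  sm <- summarize_conditions(tr, kind = "target")
  n_p <- sm$n[sm$condition == "person" & sm$fan == 4]
  n_l <- sm$n[sm$condition == "location" & sm$fan == 4]
  expect_equal(sm$n[sm$condition == "combined" & sm$fan == 4], n_p + n_l)
})

test_that("dot-product split groups trials by the item median", {
  fa <- fit_act()
  act <- fa$act
  # five distinct dots -> 2/3 split under "below (<) vs above (>=)"
  act5 <- act[1:5, ]
  act5$shifted_dot <- 1:5
  tr <- data.frame(participant_id = "pp1",
                   sentence_id = rep(act5$sentence_id, each = 2),
                   kind = "target", fan_condition = 2L,
                   varied_category = "person", round = 1L,
                   rt_ms = rep(c(1500, 1400, 1300, 1200, 1100), each = 2),
                   correct = TRUE)
  sp <- split_by_dot_product(tr, act5)
  expect_equal(sp$n_items, c(2L, 3L))
  expect_match(attr(sp, "split_rule"), "quantile 0.50")
  # RTs decreasing in dot: below-median group has the higher mean RT
  expect_gt(sp$mean_rt[sp$group == "below"], sp$mean_rt[sp$group == "above"])
  # degenerate: all dots equal -> single group with a warning
  act5$shifted_dot <- 2
  expect_warning(one <- split_by_dot_product(tr, act5), "equal")
  expect_equal(nrow(one), 1L)
})

test_that("the dot split recovers the generative RT ordering", {
  fa <- fit_act()
  tr <- generate_trials(fa$design, fa$act,
                        generator_params(n_participants = 40, rng_seed = 6))
  sp <- split_by_dot_product(tr, fa$act)
  expect_gt(sp$mean_rt[sp$group == "below"], sp$mean_rt[sp$group == "above"])
})

test_that("fan-effect recovery is antisymmetric under condition swap", {
  fa <- fit_act()
  act <- fa$act
  act$shifted_dot <- ifelse(act$fan_condition == 2, 2.2, 1.2)
  swapped <- act
  swapped$shifted_dot <- ifelse(act$fan_condition == 2, 1.2, 2.2)
  p <- generator_params(n_participants = 30, rng_seed = 5)
  e1 <- recover_fan_effect(generate_trials(fa$design, act, p), rng_seed = 1)
  e2 <- recover_fan_effect(generate_trials(fa$design, swapped, p), rng_seed = 1)
  expect_gt(e1$estimate, 0)
  expect_lt(e2$estimate, 0)
  expect_lt(e1$ci[1], e1$ci[2])
})

test_that("recovery needs at least two participants", {
  fa <- fit_act()
  tr <- generate_trials(fa$design, fa$act,
                        generator_params(n_participants = 1, rng_seed = 1))
  expect_error(recover_fan_effect(tr), "at least 2 participants")
})

test_that("trial tables round-trip through CSV and accept 0/1 correctness", {
  fa <- fit_act()
  tr <- generate_trials(fa$design, fa$act,
                        generator_params(n_participants = 3, rng_seed = 7))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trials_csv(tr, path)
  back <- read_trials_csv(path)
  expect_equal(back, tr, tolerance = 1e-12)
  # externally deposited tables may code correctness as 0/1
  tr01 <- tr
  tr01$correct <- as.integer(tr01$correct)
  write_trials_csv(tr01, path)
  back01 <- read_trials_csv(path)
  expect_identical(back01$correct, tr$correct)
  expect_error(read_trials_csv(textConnection("a,b\n1,2")), "lacks column")
  # the whole pipeline runs on a re-read table
  cleaned <- clean_rts(exclude_participants(back, 0.6)$trials)
  expect_s3_class(summarize_conditions(code_contrasts(cleaned$trials)),
                  "data.frame")
})
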