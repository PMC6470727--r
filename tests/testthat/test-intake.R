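test_that("product-sum conversion matches hand arithmetic", {
  w <- ffq_weights()
  r <- data.frame(
    subject = c(1, 1, 2, 3, 3),
    item = c("pork", "fish", "pork", "hamburger_ground_beef",
             "beef_lamb_main"),
    frequency = c("per_day_1", "never_rarely", "never_rarely",
                  "per_week_2_3", "per_week_2_3"),
    serving = c("standard", "one_and_half", "half", "one_and_half",
                "one_and_half"))
  out <- product_sum_intake(r, w)
  out <- out[order(out$subject), ]
  # 1/day x 1.0 x 99 g = 99 g/day
  expect_equal(out$pork[out$subject == 1], 99)
  # never or rarely -> 0 regardless of serving
  expect_equal(out$fish[out$subject == 1], 0)
  expect_equal(out$pork[out$subject == 2], 0)
  # two items at 2.5/7 per day x 1.5 x 99 g each
  g3 <- aggregate_groups(out, ffq_food_groups())
  expect_equal(g3$unprocessed_red[g3$subject == 3],
               2 * (2.5 / 7) * 1.5 * 99)
})

test_that("product-sum is linear in the frequency weights", {
  w1 <- ffq_weights()
  w2 <- ffq_weights(frequency_weights = 2 * w1$frequency_weights)
  set.seed(5)
  r <- data.frame(
    subject = rep(1:20, each = 3),
    item = sample(c("pork", "fish", "beef_lamb_main"), 60, TRUE),
    frequency = sample(names(w1$frequency_weights), 60, TRUE),
    serving = sample(c("half", "standard", "one_and_half"), 60, TRUE))
  a <- product_sum_intake(r, w1)
  b <- product_sum_intake(r, w2)
  expect_equal(as.matrix(b[-1]), 2 * as.matrix(a[-1]))
})

test_that("unknown category labels are rejected with the offending label", {
  r <- data.frame(subject = 1, item = "pork", frequency = "sometimes",
                  serving = "standard")
  expect_error(product_sum_intake(r), "sometimes")
  r2 <- data.frame(subject = 1, item = "pork", frequency = "per_day_1",
                   serving = "gigantic")
  expect_error(product_sum_intake(r2), "gigantic")
})

test_that("group aggregation equals brute-force row sums and is disjoint-checked", {
  set.seed(9)
  items <- unlist(ffq_food_groups())
  tab <- data.frame(subject = 1:50)
  for (it in items) tab[[it]] <- runif(50, 0, 40)
  g <- aggregate_groups(tab, ffq_food_groups())
  expect_equal(g$unprocessed_red,
               tab$hamburger_ground_beef + tab$beef_lamb_main)
  expect_equal(g$processed,
               tab$processed_beef_lamb + tab$processed_poultry + tab$pork)
  expect_equal(g$combined_red_processed, g$unprocessed_red + g$processed)
  overlapping <- list(a = c("pork", "fish"), b = c("pork"))
  expect_error(aggregate_groups(tab, overlapping), "disjoint")
})

test_that("residual energy adjustment is orthogonal, mean-preserving, idempotent", {
  set.seed(11)
  energy <- rlnorm(400, 7.5, 0.4)
  intake <- 0.005 * energy + rgamma(400, 2, 0.2)
  adj <- residual_energy_adjust(intake, energy)
  expect_lt(abs(cor(adj, energy)), 1e-10)
  expect_lt(abs(mean(adj) - mean(intake)), 1e-10)
  expect_equal(residual_energy_adjust(adj, energy), adj,
               tolerance = 1e-10)
  # perfectly explained intake collapses to its mean
  adj2 <- residual_energy_adjust(0.01 * energy, energy)
  expect_equal(adj2, rep(mean(0.01 * energy), 400), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_error(residual_energy_adjust(intake, rep(2000, 400)),
               "constant")
})

test_that("exclusion filters count each row once, in order, with exact tallies", {
  co <- data.frame(
    id = 1:20,
    red_ffq = c(NA, rep(10, 19)),                 # row 1: missing dietary
    processed_ffq = c(5, NA, rep(5, 18)),         # row 2: missing dietary
    energy = c(2000, 2000, 450, 4600, 500, 4500, rep(2000, 14)),
    entry_age = c(rep(50, 6), 24, 24.9, rep(50, 12)),
    sex = c(rep("F", 8), NA, rep("F", 11)),
    race = c(rep("b", 9), NA, rep("b", 10)),
    prevalent_cancer = c(rep(FALSE, 10), TRUE, TRUE, rep(FALSE, 8)),
    prevalent_cvd = c(rep(FALSE, 12), TRUE, rep(FALSE, 7)))
  out <- apply_exclusions(co)
  tally <- setNames(out$ledger$n, out$ledger$reason)
  expect_equal(tally[["missing_dietary"]], 2L)
  expect_equal(tally[["energy_out_of_range"]], 2L)  # 450 and 4600 only
  expect_equal(tally[["missing_age_sex_race"]], 2L)
  expect_equal(tally[["age_under_25"]], 2L)
  expect_equal(tally[["prevalent_cancer"]], 2L)
  expect_equal(tally[["prevalent_cvd"]], 1L)
  # boundary energies 500 and 4500 are retained (strict inequalities)
  expect_true(all(c(5, 6) %in% out$cohort$id))
  expect_equal(sum(out$ledger$n), nrow(co) - nrow(out$cohort))
})

test_that("exposure categorisation forms a zero group plus consumer quartiles", {
  set.seed(13)
  x <- c(rep(0, 1000), runif(4000, 1, 100))
  cz <- categorize_exposure(x)
  expect_equal(sum(cz$category == "zero"), 1000)
  counts <- table(cz$category)[c("Q1", "Q2", "Q3", "Q4")]
  expect_true(all(abs(counts - 1000) <= 1))
  expect_equal(unname(cz$medians[["zero"]]), 0)
  expect_true(all(diff(cz$medians) > 0))
  expect_error(categorize_exposure(rep(0, 100)), "distinct nonzero")
  expect_error(categorize_exposure(c(-1, 1, 2, 3, 4, 5)), "nonnegative")
})

test_that("paper-style quartile medians are a valid trend labelling", {
  med <- c(zero = 0, Q1 = 4, Q2 = 9.1, Q3 = 15.6, Q4 = 41.7)
  expect_true(!is.unsorted(med))
  cat5 <- factor(sample(names(med), 200, TRUE), levels = names(med))
  score <- med[as.character(cat5)]
  expect_equal(unname(score[cat5 == "Q2"][1]), 9.1)
})
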