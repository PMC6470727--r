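#' Default FFQ frequency weights, serving multipliers and food groups
#'
#' The quantitative FFQ records, per food item, an ordinal consumption
#' frequency from "never or rarely" up to "2+ per day" and one of three
#' serving sizes (half, standard 3--4 oz, one-and-a-half). `ffq_weights()`
#' returns the mapping used by [product_sum_intake()]: times/day weights per
#' frequency level, serving multipliers, and per-item standard serving
#' grams. The shipped frequency weights map the 9-level scale to
#' `{0, 1/30, 2.5/30, 1/7, 2.5/7, 5.5/7, 1, 1.5, 2.5}` times/day and the
#' default standard serving is 99 g (midpoint of the printed 85--113 g
#' range for a meat serving); both are configuration, not code, and can be
#' overridden per item.
#'
#' `ffq_food_groups()` returns the food-group map: unprocessed red meat is
#' the two beef/lamb items; processed meat is processed beef/lamb,
#' processed poultry, and pork (classified as processed because the pork
#' item is predominantly processed products).
#'
#' @param frequency_weights named numeric, times/day per frequency level,
#'   nonnegative and nondecreasing, with `"never_rarely"` equal to 0.
#' @param serving_multipliers named numeric for half/standard/one-and-half.
#' @param serving_grams default standard-serving grams per item.
#' @return list of class `ffq_weights`.
#' @export
ffq_weights <- function(
    frequency_weights = c(never_rarely = 0, per_month_1 = 1 / 30,
                          per_month_2_3 = 2.5 / 30, per_week_1 = 1 / 7,
                          per_week_2_3 = 2.5 / 7, per_week_4_6 = 5.5 / 7,
                          per_day_1 = 1, per_day_1_5 = 1.5,
                          per_day_2plus = 2.5),
    serving_multipliers = c(half = 0.5, standard = 1.0,
                            one_and_half = 1.5),
    serving_grams = 99) {
  if (any(frequency_weights < 0) || is.unsorted(frequency_weights))
    stop("frequency weights must be nonnegative and nondecreasing")
  if (frequency_weights[[1]] != 0 ||
      names(frequency_weights)[1] != "never_rarely")
    stop("first frequency level must be 'never_rarely' with weight 0")
  structure(list(frequency_weights = frequency_weights,
                 serving_multipliers = serving_multipliers,
                 serving_grams = serving_grams),
            class = "ffq_weights")
}

#' @rdname ffq_weights
#' @export
ffq_food_groups <- function() {
  list(unprocessed_red = c("hamburger_ground_beef", "beef_lamb_main"),
       processed = c("processed_beef_lamb", "processed_poultry", "pork"),
       poultry = c("unprocessed_poultry"),
       fish = c("fish"))
}

#' Product-sum conversion of FFQ responses to g/day
#'
#' Per-item intake is `frequency weight (times/day) x serving multiplier x
#' standard serving grams`. `responses` is a long-format table with one row
#' per subject-item.
#'
#' @param responses data frame with columns `subject`, `item`,
#'   `frequency` (level names of the weight map) and `serving`
#'   (`half`/`standard`/`one_and_half`).
#' @param weights an [ffq_weights()] object; `serving_grams` may be a
#'   single default or a named per-item vector.
#' @return wide data frame: one row per subject, one g/day column per item.
#' @examples
#' r <- data.frame(subject = 1, item = "pork", frequency = "per_day_1",
#'                 serving = "standard")
#' product_sum_intake(r, ffq_weights())  # 1/day x 1.0 x 99 g = 99 g/day
#' @export
product_sum_intake <- function(responses, weights = ffq_weights()) {
  req <- c("subject", "item", "frequency", "serving")
  if (!all(req %in% names(responses)))
    stop("responses must have columns: ", paste(req, collapse = ", "))
  fw <- weights$frequency_weights
  sm <- weights$serving_multipliers
  badf <- !responses$frequency %in% names(fw)
  if (any(badf))
    stop("unknown frequency label at row(s) ",
         paste(head(which(badf), 5), collapse = ", "), ": ",
         paste(unique(responses$frequency[badf]), collapse = ", "))
  bads <- !responses$serving %in% names(sm)
  if (any(bads))
    stop("unknown serving label at row(s) ",
         paste(head(which(bads), 5), collapse = ", "), ": ",
         paste(unique(responses$serving[bads]), collapse = ", "))
  grams <- weights$serving_grams
  item_grams <- if (length(grams) == 1L && is.null(names(grams))) {
    setNames(rep(grams, length(unique(responses$item))),
             unique(responses$item))
  } else {
    missing_items <- setdiff(unique(responses$item), names(grams))
    if (length(missing_items))
      stop("no serving grams for item(s): ",
           paste(missing_items, collapse = ", "))
    grams
  }
  gday <- fw[responses$frequency] * sm[responses$serving] *
    item_grams[responses$item]
  wide <- tapply(gday, list(responses$subject, responses$item), sum,
                 default = 0)
  out <- data.frame(subject = rownames(wide), as.data.frame(unclass(wide)),
                    check.names = FALSE, row.names = NULL)
  out
}

#' Aggregate item intakes into food groups
#'
#' Group intake is the sum of member items; the combined red + processed
#' exposure is the sum of the unprocessed-red and processed groups.
#'
#' @param item_intakes wide data frame from [product_sum_intake()] (first
#'   column `subject`).
#' @param groups named list of item vectors, see [ffq_food_groups()];
#'   groups must be disjoint. Items absent from the table contribute 0.
#' @return data frame with `subject`, one column per group, and
#'   `combined_red_processed` when both meat groups are present.
#' @export
aggregate_groups <- function(item_intakes, groups = ffq_food_groups()) {
  all_items <- unlist(groups)
  if (anyDuplicated(all_items))
    stop("food groups must be disjoint; duplicated item(s): ",
         paste(unique(all_items[duplicated(all_items)]), collapse = ", "))
  out <- data.frame(subject = item_intakes$subject)
  for (g in names(groups)) {
    cols <- intersect(groups[[g]], names(item_intakes))
    out[[g]] <- if (length(cols))
      rowSums(item_intakes[cols]) else 0
  }
  if (all(c("unprocessed_red", "processed") %in% names(out)))
    out$combined_red_processed <- out$unprocessed_red + out$processed
  out
}

#' Energy adjustment by the residual method
#'
#' Regresses intake on total energy by ordinary least squares and returns
#' residual + mean intake, so the adjusted variable has the original mean
#' and is exactly uncorrelated with energy. Adjusting an already-adjusted
#' variable returns it unchanged (idempotence).
#'
#' @param intake numeric vector (g/day).
#' @param total_energy numeric vector (kcal/day), same length.
#' @return numeric vector of energy-adjusted intakes.
#' @export
residual_energy_adjust <- function(intake, total_energy) {
  if (length(intake) != length(total_energy))
    stop("intake and total_energy lengths differ")
  if (length(intake) < 3) stop("need n >= 3 for the residual method")
  if (var(total_energy) == 0)
    stop("degenerate regressor: total energy is constant")
  fit <- lm(intake ~ total_energy)
  residuals(fit) + mean(intake)
}

#' Apply cohort exclusion filters
#'
#' Removes rows failing the baseline eligibility rules, in a fixed order,
#' attributing each excluded row to the first rule it violates: missing
#' dietary exposure data; extreme total energy (strictly below `energy_min`
#' or strictly above `energy_max` kcal/day; the boundary values are
#' retained); missing age, sex or race; age below 25 years at baseline; and
#' prevalent cancer or cardiovascular disease. The returned ledger reports
#' the count removed per reason; counts sum to rows in minus rows out.
#'
#' @param cohort data frame; recognised columns: `energy`, `entry_age`,
#'   `sex`, `race`, `prevalent_cancer`, `prevalent_cvd` (logical/0-1), and
#'   the dietary columns named in `dietary_cols`.
#' @param energy_min,energy_max energy bounds in kcal/day.
#' @param min_age minimum baseline age in years.
#' @param dietary_cols columns whose missingness triggers the
#'   missing-dietary exclusion.
#' @return list with `cohort` (retained rows), `ledger` (data frame
#'   reason/n) and `reason` (per-input-row factor, `NA` for retained rows).
#' @export
apply_exclusions <- function(cohort, energy_min = 500, energy_max = 4500,
                             min_age = 25,
                             dietary_cols = intersect(
                               c("red_ffq", "processed_ffq"),
                               names(cohort))) {
  n <- nrow(cohort)
  reason <- rep(NA_character_, n)
  mark <- function(cond, code) {
    cond[is.na(cond)] <- FALSE
    reason[is.na(reason) & cond] <<- code
  }
  if (length(dietary_cols))
    mark(Reduce(`|`, lapply(cohort[dietary_cols], is.na)),
         "missing_dietary")
  if ("energy" %in% names(cohort))
    mark(is.na(cohort$energy) | cohort$energy < energy_min |
           cohort$energy > energy_max, "energy_out_of_range")
  demo <- intersect(c("entry_age", "sex", "race"), names(cohort))
  if (length(demo))
    mark(Reduce(`|`, lapply(cohort[demo], is.na)), "missing_age_sex_race")
  if ("entry_age" %in% names(cohort))
    mark(cohort$entry_age < min_age, "age_under_25")
  for (v in c("prevalent_cancer", "prevalent_cvd"))
    if (v %in% names(cohort))
      mark(as.logical(cohort[[v]]), sub("prevalent_", "prevalent_", v))
  codes <- c("missing_dietary", "energy_out_of_range",
             "missing_age_sex_race", "age_under_25", "prevalent_cancer",
             "prevalent_cvd")
  tab <- table(factor(reason, levels = codes))
  ledger <- data.frame(reason = names(tab), n = as.integer(tab),
                       row.names = NULL)
  list(cohort = cohort[is.na(reason), , drop = FALSE], ledger = ledger,
       reason = factor(reason, levels = codes))
}

#' Categorise an exposure into zero intake plus consumer quartiles
#'
#' The zero-intake group is all subjects with exactly zero (adjusted)
#' intake; consumers are split at quartile cut-points. With strong
#' zero-inflation, quartiles of the total cohort collapse (several
#' cut-points equal zero), so the default reference set for the cut-points
#' is consumers only; `basis = "total"` uses total-cohort percentiles
#' instead. Per-level intake medians are returned for the trend test
#' ([trend_test()]); the zero level's median is 0.
#'
#' @param intake nonnegative numeric vector.
#' @param basis `"consumers"` (default) or `"total"`: reference set for the
#'   quartile cut-points.
#' @return list with `category` (factor `zero`, `Q1`..`Q4`), `medians`
#'   (named per-level medians), `cutpoints`, `basis`.
#' @export
categorize_exposure <- function(intake, basis = c("consumers", "total")) {
  basis <- match.arg(basis)
  if (any(is.na(intake))) stop("intake contains NA")
  if (any(intake < 0)) stop("intakes must be nonnegative")
  cons <- intake > 0
  if (length(unique(intake[cons])) < 4)
    stop("fewer than 4 distinct nonzero intake values; cannot form ",
         "consumer quartiles")
  ref <- if (basis == "consumers") intake[cons] else intake
  cuts <- quantile(ref, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  if (any(duplicated(c(0, cuts))))
    stop("quartile cut-points collapse at zero under basis = '", basis,
         "'; use basis = 'consumers'")
  lev <- c("zero", "Q1", "Q2", "Q3", "Q4")
  category <- factor(rep("zero", length(intake)), levels = lev)
  qi <- findInterval(intake[cons], cuts, left.open = TRUE) + 1L
  category[cons] <- lev[qi + 1L]
  med <- vapply(lev, function(l) {
    if (l == "zero") 0 else median(intake[category == l])
  }, numeric(1))
  list(category = category, medians = med, cutpoints = cuts, basis = basis)
}
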