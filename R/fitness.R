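#' Female fitness measures from reproductive components
#'
#' A per-plant reproductive record holds counts of flowers and fruit
#' fates: `flowers_total`, `aborted`, `fruits_intact` (undehisced fruits
#' whose seeds were counted, totalling `seeds_counted`), `fruits_dehisced`
#' (spilled before collection, seeds imputed), `fruits_fly` and
#' `fruits_caterpillar` (attacked, zero viable seeds), and
#' `flowers_collected_early` (taken for measurement, seed production
#' imputed). The accounting identity
#' `flowers_total = aborted + intact + dehisced + fly + caterpillar +
#' collected_early` must hold.
#'
#' "Flowers at risk" excludes flowers collected early (they could not set
#' fruit); set `at_risk_includes_early = TRUE` to put them back in the
#' denominator.
#'
#' @name fitness-measures
NULL

component_cols <- c("flowers_total", "aborted", "fruits_intact",
                    "seeds_counted", "fruits_dehisced", "fruits_fly",
                    "fruits_caterpillar", "flowers_collected_early",
                    "eggs_total", "flowers_surveyed")

check_components <- function(rec) {
  miss <- setdiff(component_cols, names(rec))
  if (length(miss)) stop("fitness components lack column(s): ",
                         paste(miss, collapse = ", "))
  counts <- rec[, setdiff(component_cols, "seeds_counted")]
  if (any(counts < 0, na.rm = TRUE)) stop("negative count in components")
  lhs <- rec$flowers_total
  rhs <- rec$aborted + rec$fruits_intact + rec$fruits_dehisced +
    rec$fruits_fly + rec$fruits_caterpillar + rec$flowers_collected_early
  bad <- which(lhs != rhs)
  if (length(bad)) {
    stop("flower accounting identity violated for plant(s): ",
         paste(utils::head(rec$plant_id[bad], 5), collapse = ", "))
  }
  invisible(rec)
}

#' Total seeds produced, with field imputation rules
#'
#' Counted seeds of intact fruits, plus each dehisced fruit imputed at the
#' plant's mean seeds per intact fruit, plus each flower collected early
#' imputed at the plant's mean seed production per flower allowed to set
#' seed. Eaten fruits contribute zero. A plant with dehisced fruits but no
#' intact fruit (imputation impossible) is returned as `NA` with reason
#' `"dehisced_no_intact"`, never as zero.
#'
#' @param rec data.frame of reproductive components (see
#'   [fitness-measures]).
#' @return list `value` (numeric vector) and `reason` (character vector,
#'   NA where defined).
#' @export
total_seeds <- function(rec) {
  check_components(rec)
  n <- nrow(rec)
  value <- rep(NA_real_, n)
  reason <- rep(NA_character_, n)
  mean_intact <- ifelse(rec$fruits_intact > 0,
                        rec$seeds_counted / rec$fruits_intact, NA_real_)
  for (i in seq_len(n)) {
    if (rec$fruits_dehisced[i] > 0 && rec$fruits_intact[i] == 0) {
      reason[i] <- "dehisced_no_intact"
      next
    }
    s <- rec$seeds_counted[i] +
      if (rec$fruits_dehisced[i] > 0) {
        rec$fruits_dehisced[i] * mean_intact[i]
      } else 0
    if (rec$flowers_collected_early[i] > 0) {
      allowed <- rec$flowers_total[i] - rec$flowers_collected_early[i]
      if (allowed == 0) {
        reason[i] <- "all_collected_early"
        next
      }
      s <- s + rec$flowers_collected_early[i] * s / allowed
    }
    value[i] <- s
  }
  list(value = value, reason = reason)
}

#' Seeds initiated per flower
#'
#' (nonaborted fruits / flowers at risk) x (mean seeds per noneaten
#' fruit), the pollination-success component insulated from seed
#' predation: eaten fruits count in the fruit-set numerator but seeds per
#' fruit come from noneaten fruits only. Plants with nonaborted fruits but
#' no counted (intact) fruit are flagged missing.
#'
#' @inheritParams total_seeds
#' @param at_risk_includes_early include early-collected flowers in the
#'   flowers-at-risk denominator (default FALSE).
#' @return list `value`, `reason`.
#' @export
seeds_initiated_per_flower <- function(rec, at_risk_includes_early = FALSE) {
  check_components(rec)
  if (any(rec$flowers_total == 0)) stop("plant with zero flowers")
  at_risk <- rec$flowers_total -
    if (at_risk_includes_early) 0 else rec$flowers_collected_early
  # nonaborted fruits are actual fruits, eaten or not; early-collected
  # flowers never become fruits
  nonaborted <- rec$fruits_intact + rec$fruits_dehisced + rec$fruits_fly +
    rec$fruits_caterpillar
  value <- rep(NA_real_, nrow(rec))
  reason <- rep(NA_character_, nrow(rec))
  for (i in seq_len(nrow(rec))) {
    if (at_risk[i] <= 0) {
      reason[i] <- "no_flowers_at_risk"
      next
    }
    if (nonaborted[i] == 0) {
      value[i] <- 0
      next
    }
    if (rec$fruits_intact[i] == 0) {
      reason[i] <- "no_counted_fruit"
      next
    }
    value[i] <- (nonaborted[i] / at_risk[i]) *
      (rec$seeds_counted[i] / rec$fruits_intact[i])
  }
  list(value = value, reason = reason)
}

#' Proportion of fruits escaping predispersal seed predation
#'
#' 1 minus the proportion of nonaborted fruits attacked by flies or
#' caterpillars. Plants without nonaborted fruits are flagged missing.
#'
#' @inheritParams total_seeds
#' @inheritParams seeds_initiated_per_flower
#' @return list `value`, `reason`.
#' @export
escape_predation <- function(rec, at_risk_includes_early = FALSE) {
  check_components(rec)
  nonaborted <- rec$fruits_intact + rec$fruits_dehisced + rec$fruits_fly +
    rec$fruits_caterpillar
  attacked <- rec$fruits_fly + rec$fruits_caterpillar
  if (any(attacked > nonaborted)) {
    stop("attacked fruits exceed nonaborted fruits for plant(s): ",
         paste(rec$plant_id[attacked > nonaborted], collapse = ", "))
  }
  value <- ifelse(nonaborted >= 1, 1 - attacked / nonaborted, NA_real_)
  reason <- ifelse(nonaborted >= 1, NA_character_, "no_nonaborted_fruit")
  list(value = value, reason = reason)
}

#' Fly eggs per flower
#'
#' Season total of fly eggs divided by the season total of surveyed open
#' flowers and elongated buds (sums, not per-survey means).
#'
#' @inheritParams total_seeds
#' @return list `value`, `reason`.
#' @export
eggs_per_flower <- function(rec) {
  check_components(rec)
  value <- ifelse(rec$flowers_surveyed >= 1,
                  rec$eggs_total / rec$flowers_surveyed, NA_real_)
  reason <- ifelse(rec$flowers_surveyed >= 1, NA_character_,
                   "no_surveyed_flowers")
  list(value = value, reason = reason)
}

#' Relativize a fitness measure
#'
#' Divides by the grand mean over all plants, all years pooled. Missing
#' values propagate (and are excluded from the mean).
#'
#' @param values numeric vector of a fitness measure.
#' @return numeric vector with mean 1 over non-missing entries.
#' @export
relativize <- function(values) {
  m <- mean(values, na.rm = TRUE)
  if (!is.finite(m) || m <= 0) {
    stop("grand mean of fitness is not positive; cannot relativize")
  }
  values / m
}

#' Build the per-plant fitness table
#'
#' Computes the four fitness measures, their relativized versions
#' (relative to the grand mean across all plants and years) and a
#' missingness-reason column per measure.
#'
#' @param components data.frame of reproductive components.
#' @param at_risk_includes_early see [seeds_initiated_per_flower()].
#' @return data.frame with `plant_id`, raw measures (`total_seeds`,
#'   `seeds_per_flower`, `escape_predation`, `eggs_per_flower`),
#'   relativized columns (`rel_` prefix) and `reason_` columns.
#' @export
fitness_table <- function(components, at_risk_includes_early = FALSE) {
  ts <- total_seeds(components)
  sf <- seeds_initiated_per_flower(components, at_risk_includes_early)
  ep <- escape_predation(components)
  ef <- eggs_per_flower(components)
  out <- data.frame(
    plant_id = components$plant_id,
    total_seeds = ts$value,
    seeds_per_flower = sf$value,
    escape_predation = ep$value,
    eggs_per_flower = ef$value,
    stringsAsFactors = FALSE
  )
  for (m in c("total_seeds", "seeds_per_flower", "escape_predation",
              "eggs_per_flower")) {
    out[[paste0("rel_", m)]] <- relativize(out[[m]])
  }
  out$reason_total_seeds <- ts$reason
  out$reason_seeds_per_flower <- sf$reason
  out$reason_escape_predation <- ep$reason
  out$reason_eggs_per_flower <- ef$reason
  out
}
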