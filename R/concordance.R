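#' Plasticity as a fold change of estimated marginal means
#'
#' EMM(new) / EMM(control) from a model of the trait on both treatment
#' factors (so the contrasted factor is adjusted for the other), computed
#' on the measurement scale. The log-scale SE comes from the delta
#' method; `significant` is a Wald test of log fold change = 0.
#'
#' @param data trait table for one year (or pooled), with treatment
#'   factors and grouping columns.
#' @param trait trait column name.
#' @param contrast_factor treatment factor contrasted (e.g.
#'   `"snow_treatment"`).
#' @param new,control levels contrasted (EMM_new / EMM_control).
#' @param other_factor the companion treatment factor kept in the model.
#' @param mixed use the split-plot mixed model (default) or plain lm.
#' @return data.frame: `trait`, `fold_change`, `log_fc`, `log_fc_se`,
#'   `significant`, `p`, `reason` (NA unless undefined).
#' @export
plasticity_fold_change <- function(data, trait, contrast_factor, new,
                                   control,
                                   other_factor = "precip_treatment",
                                   mixed = TRUE) {
  lv <- unique(as.character(data[[contrast_factor]]))
  if (!all(c(new, control) %in% lv)) {
    stop("contrast level(s) absent: ",
         paste(setdiff(c(new, control), lv), collapse = ", "))
  }
  fixed <- stats::as.formula(paste("~", contrast_factor, "+", other_factor))
  mod <- if (mixed) {
    fit_splitplot_lmm(data, fixed, trait)
  } else {
    d <- data
    d$.y <- d[[trait]]
    fit <- stats::lm(stats::as.formula(paste(".y ~", contrast_factor, "+",
                                             other_factor)), d)
    list(fit = fit, data = d,
         fixed = fixed)
  }
  em <- emm_any(mod, contrast_factor, mixed)
  a <- em[em$level == new, ]
  b <- em[em$level == control, ]
  if (nrow(a) != 1 || nrow(b) != 1 || b$emmean <= 0 || a$emmean <= 0) {
    return(data.frame(trait = trait, fold_change = NA_real_,
                      log_fc = NA_real_, log_fc_se = NA_real_,
                      significant = NA, p = NA_real_,
                      reason = "nonpositive_emm",
                      stringsAsFactors = FALSE))
  }
  fc <- a$emmean / b$emmean
  # delta method on log(a) - log(b); EMMs from disjoint rows are treated
  # as independent (their fixed-effect covariance is accounted for below)
  se_log <- sqrt((a$se / a$emmean)^2 + (b$se / b$emmean)^2 -
                   2 * attr(em, "cov_pair") / (a$emmean * b$emmean))
  zst <- log(fc) / se_log
  p <- 2 * stats::pnorm(-abs(zst))
  data.frame(trait = trait, fold_change = fc, log_fc = log(fc),
             log_fc_se = se_log, significant = p < 0.05, p = p,
             reason = NA_character_, stringsAsFactors = FALSE)
}

# EMMs with the covariance of the two level means retained, for both the
# mixed and fixed-effect paths.
emm_any <- function(mod, factor, mixed) {
  if (mixed) {
    em <- emm(mod, factor)
    # recompute covariance of the level means
    V <- as.matrix(stats::vcov(mod$fit))
    b <- lme4::fixef(mod$fit)
  } else {
    V <- stats::vcov(mod$fit)
    b <- stats::coef(mod$fit)
  }
  d <- mod$data
  vars <- all.vars(mod$fixed)
  grid_vars <- lapply(vars, function(v) {
    if (is.factor(d[[v]]) || is.character(d[[v]])) {
      unique(as.character(d[[v]]))
    } else mean(d[[v]], na.rm = TRUE)
  })
  names(grid_vars) <- vars
  grid <- expand.grid(grid_vars, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  for (v in vars) {
    if (is.factor(d[[v]]) || is.character(d[[v]])) {
      grid[[v]] <- base::factor(grid[[v]],
                                levels = levels(base::factor(d[[v]])))
    }
  }
  X <- stats::model.matrix(stats::as.formula(
    paste("~", deparse(mod$fixed[[2]]))), grid)
  X <- X[, names(b), drop = FALSE]
  lv <- grid_vars[[factor]]
  Ls <- lapply(lv, function(l) colMeans(X[grid[[factor]] == l, ,
                                          drop = FALSE]))
  est <- vapply(Ls, function(L) sum(L * b), 0)
  se <- vapply(Ls, function(L) sqrt(drop(t(L) %*% V %*% L)), 0)
  out <- data.frame(level = lv, emmean = est, se = se,
                    stringsAsFactors = FALSE)
  if (length(Ls) >= 2) {
    attr(out, "cov_pair") <- drop(t(Ls[[1]]) %*% V %*% Ls[[2]])
  } else attr(out, "cov_pair") <- 0
  out
}

#' Univariate selection in a treatment x year subset ("new environment")
#'
#' Standardized gradient from `w ~ z` within the subset, with fitness
#' relativized and the trait standardized inside the subset. Subsets
#' smaller than `min_n` return NA.
#'
#' @param z raw trait values; `fitness` raw fitness; `subset_rows`
#'   logical/integer index of the subset.
#' @param min_n minimum subset size.
#' @return data.frame `beta`, `se`, `p`, `n`, `reason`.
#' @export
selection_in_new_env <- function(z, fitness, subset_rows, min_n = 10) {
  zz <- z[subset_rows]; ff <- fitness[subset_rows]
  ok <- stats::complete.cases(zz, ff)
  zz <- zz[ok]; ff <- ff[ok]
  if (length(zz) < min_n) {
    return(data.frame(beta = NA_real_, se = NA_real_, p = NA_real_,
                      n = length(zz), reason = "subset_too_small",
                      stringsAsFactors = FALSE))
  }
  if (stats::sd(zz) == 0) {
    return(data.frame(beta = NA_real_, se = NA_real_, p = NA_real_,
                      n = length(zz), reason = "constant_trait",
                      stringsAsFactors = FALSE))
  }
  w <- relativize(ff)
  zs <- (zz - mean(zz)) / stats::sd(zz)
  if (stats::sd(w) == 0) {
    return(data.frame(beta = 0, se = 0, p = 1, n = length(zz),
                      reason = NA_character_, stringsAsFactors = FALSE))
  }
  cf <- summary(stats::lm(w ~ zs))$coefficients
  data.frame(beta = cf[2, 1], se = cf[2, 2], p = cf[2, 4], n = length(zz),
             reason = NA_character_, stringsAsFactors = FALSE)
}

#' Classify a plastic response as adaptive, maladaptive or neutral
#'
#' Quadrant rule on (log fold change, selection gradient in the new
#' environment): same sign = adaptive (first/third quadrants), opposite
#' sign = maladaptive, either sign exactly zero = neutral. The stringent
#' flag additionally requires significant plasticity, univariate
#' selection p < 0.05, and a nonzero elastic-net direct gradient.
#'
#' @param plasticity one row from [plasticity_fold_change()].
#' @param selection one row from [selection_in_new_env()].
#' @param en_beta elastic-net direct gradient in the same subset (NA if
#'   not computed).
#' @return data.frame `trait`, `log_fc`, `beta`, `classification`,
#'   `stringent`.
#' @export
classify_concordance <- function(plasticity, selection, en_beta = NA) {
  if (is.na(plasticity$fold_change) || is.na(selection$beta)) {
    stop("classify_concordance needs non-missing plasticity and selection")
  }
  s <- sign(plasticity$log_fc) * sign(selection$beta)
  classification <- if (s > 0) "adaptive" else if (s < 0) "maladaptive"
  else "neutral"
  stringent <- isTRUE(plasticity$significant) &&
    !is.na(selection$p) && selection$p < 0.05 &&
    !is.na(en_beta) && en_beta != 0
  data.frame(trait = plasticity$trait, log_fc = plasticity$log_fc,
             beta = selection$beta, classification = classification,
             stringent = stringent, stringsAsFactors = FALSE)
}

#' Test whether adaptive and maladaptive responses are balanced
#'
#' Exact binomial test of adaptive fraction = 0.5 among the non-neutral
#' records, per fitness measure when a `fitness_measure` column is
#' present.
#'
#' @param records data.frame of concordance records with a
#'   `classification` column.
#' @return data.frame `fitness_measure`, `n_adaptive`, `n_maladaptive`,
#'   `prop_adaptive`, `p`.
#' @export
proportion_test <- function(records) {
  grp <- if ("fitness_measure" %in% names(records)) {
    records$fitness_measure
  } else rep("all", nrow(records))
  out <- do.call(rbind, lapply(unique(grp), function(g) {
    r <- records[grp == g, , drop = FALSE]
    na_ <- sum(r$classification == "adaptive")
    nm <- sum(r$classification == "maladaptive")
    if (na_ + nm == 0) {
      return(data.frame(fitness_measure = g, n_adaptive = 0L,
                        n_maladaptive = 0L, prop_adaptive = NA_real_,
                        p = NA_real_, note = "all_neutral",
                        stringsAsFactors = FALSE))
    }
    bt <- stats::binom.test(na_, na_ + nm, 0.5)
    data.frame(fitness_measure = g, n_adaptive = na_, n_maladaptive = nm,
               prop_adaptive = na_ / (na_ + nm), p = bt$p.value,
               note = NA_character_, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Cross-tabulate significance of plasticity and selection
#'
#' @param records concordance records with logical `plast_significant`
#'   and `sel_significant` columns (or a `stringent` column only).
#' @return list `table` (2 x 2 counts), `both` (traits significant in
#'   both).
#' @export
stringent_summary <- function(records) {
  ps <- records$plast_significant
  ss <- records$sel_significant
  if (is.null(ps) || is.null(ss)) {
    stop("records need plast_significant and sel_significant columns")
  }
  tab <- table(factor(ps, c(FALSE, TRUE), c("plast_ns", "plast_sig")),
               factor(ss, c(FALSE, TRUE), c("sel_ns", "sel_sig")))
  list(table = tab,
       both = unique(records$trait[ps & ss & !is.na(ps) & !is.na(ss)]))
}
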