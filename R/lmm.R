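#' Split-plot linear mixed model
#'
#' REML fit (via lme4) of a response on fixed terms with the split-plot
#' random-effect structure: a whole-plot intercept and a
#' subplot-within-plot intercept. Wald t tests of the coefficients use
#' containment-style denominator degrees of freedom: a term whose
#' covariates are constant within whole plots is tested against the
#' plot-level df, a term constant within subplots against the
#' subplot-level df, and anything varying between plants against the
#' residual df. (Satterthwaite approximations need the lmerTest machinery,
#' which is deliberately not a dependency; the containment rule is the
#' classical split-plot ANOVA choice and is configurable.)
#'
#' @param data data.frame with the response, fixed-effect variables and
#'   grouping columns.
#' @param fixed right-hand-side formula of fixed effects, e.g.
#'   `~ year + snow_treatment * precip_treatment`.
#' @param response name of the response column.
#' @param sqrt_scale if TRUE the response is square-root transformed
#'   before fitting (the conventional scale for emission analyses).
#' @param plot,subplot names of the grouping columns.
#' @param ddf `"containment"` (default), `"residual"` or `"normal"`
#'   (z tests).
#' @return list of class `splitplot_lmm`: `fit` (the merMod),
#'   `coefficients` (estimate, se, df, t, p), `varcomp`, `singular`,
#'   `data`, `fixed`, `response`.
#' @export
fit_splitplot_lmm <- function(data, fixed, response, sqrt_scale = FALSE,
                              plot = "plot_id", subplot = "subplot_id",
                              ddf = c("containment", "residual", "normal")) {
  ddf <- match.arg(ddf)
  stopifnot(response %in% names(data), plot %in% names(data),
            subplot %in% names(data))
  # nesting check: each subplot label must belong to exactly one plot
  tab <- unique(data[, c(plot, subplot)])
  if (anyDuplicated(tab[[subplot]])) {
    stop("grouping labels are not nested: subplot label(s) appear in ",
         "more than one plot: ",
         paste(unique(tab[[subplot]][duplicated(tab[[subplot]])]),
               collapse = ", "))
  }
  d <- data
  d$.y <- d[[response]]
  if (sqrt_scale) {
    if (any(d$.y < 0, na.rm = TRUE)) stop("negative response, cannot sqrt")
    d$.y <- sqrt(d$.y)
  }
  d$.plot <- factor(d[[plot]])
  d$.subplot <- factor(paste(d[[plot]], d[[subplot]], sep = "/"))
  form <- stats::as.formula(paste(".y ~", paste(deparse(fixed[[2]]),
                                                collapse = " "),
                                  "+ (1 | .plot) + (1 | .subplot)"))
  # lme4 emits a console message at variance boundaries; the singular
  # flag below carries the same information as structured output
  fit <- suppressMessages(lme4::lmer(form, data = d, REML = TRUE))
  singular <- lme4::isSingular(fit, tol = 1e-4)
  if (singular) {
    warning("singular mixed-model fit: a variance component is ",
            "estimated at zero (reported, not refit)")
  }
  X <- lme4::getME(fit, "X")
  b <- lme4::fixef(fit)
  V <- as.matrix(stats::vcov(fit))
  se <- sqrt(diag(V))
  dfs <- switch(ddf,
    normal = rep(Inf, length(b)),
    residual = rep(nrow(X) - qr(X)$rank, length(b)),
    containment = containment_df(X, d$.plot, d$.subplot)
  )
  tstat <- b / se
  coefs <- data.frame(term = names(b), estimate = unname(b),
                      se = unname(se), df = dfs, t = unname(tstat),
                      p = 2 * stats::pt(-abs(tstat), dfs),
                      stringsAsFactors = FALSE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(fit = fit, coefficients = coefs,
                 varcomp = stats::setNames(vc$vcov, vc$grp),
                 singular = singular, data = d, fixed = fixed,
                 response = response, sqrt_scale = sqrt_scale),
            class = "splitplot_lmm")
}

# Containment denominator df per fixed-effect column: number of groups at
# the finest level the column varies between, minus the rank of the
# model matrix aggregated to that level.
containment_df <- function(X, plot, subplot) {
  n <- nrow(X)
  lvl_rank <- function(g) {
    M <- apply(X, 2, function(col) tapply(col, g, mean))
    qr(as.matrix(M))$rank
  }
  const_within <- function(col, g) {
    all(tapply(col, g, function(v) max(v) - min(v)) < 1e-10)
  }
  df_plot <- nlevels(droplevels(plot)) - lvl_rank(plot)
  df_subplot <- nlevels(droplevels(subplot)) - lvl_rank(subplot) - df_plot
  df_resid <- n - qr(X)$rank - df_plot - df_subplot
  vapply(seq_len(ncol(X)), function(j) {
    if (const_within(X[, j], plot)) max(df_plot, 1)
    else if (const_within(X[, j], subplot)) max(df_subplot, 1)
    else max(df_resid, 1)
  }, 0)
}

#' Estimated marginal means of a factor
#'
#' Model-based group means averaged with equal weights over the levels of
#' the other factors in the fixed part, covariates held at their data
#' means. SEs come from the fixed-effect covariance matrix by the delta
#' method.
#'
#' @param model a [fit_splitplot_lmm()] result (or any list with `fit`,
#'   `data`, `fixed`).
#' @param factor name of the factor whose levels are wanted.
#' @return data.frame `level`, `emmean`, `se`.
#' @export
emm <- function(model, factor) {
  fit <- model$fit
  d <- model$data
  if (!factor %in% names(d)) stop("factor '", factor, "' not in model data")
  if (!is.factor(d[[factor]])) d[[factor]] <- droplevels(base::factor(d[[factor]]))
  vars <- all.vars(model$fixed)
  if (!factor %in% vars) stop("factor '", factor, "' not in fixed terms")
  grid_vars <- lapply(vars, function(v) {
    if (is.factor(d[[v]]) || is.character(d[[v]])) {
      lv <- levels(base::factor(d[[v]]))
      obs <- unique(as.character(d[[v]]))
      lv[lv %in% obs]
    } else mean(d[[v]], na.rm = TRUE)
  })
  names(grid_vars) <- vars
  if (!all(levels(droplevels(base::factor(d[[factor]]))) %in%
             grid_vars[[factor]])) {
    stop("level(s) of '", factor, "' absent from data")
  }
  grid <- expand.grid(grid_vars, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  for (v in vars) {
    if (is.factor(d[[v]]) || is.character(d[[v]])) {
      grid[[v]] <- base::factor(grid[[v]], levels = levels(base::factor(d[[v]])))
    }
  }
  X <- stats::model.matrix(stats::delete.response(stats::terms(
    stats::as.formula(paste("~", deparse(model$fixed[[2]]))))), grid)
  b <- lme4::fixef(fit)
  X <- X[, names(b), drop = FALSE]
  V <- as.matrix(stats::vcov(fit))
  lv <- grid_vars[[factor]]
  out <- do.call(rbind, lapply(lv, function(l) {
    rows <- grid[[factor]] == l
    L <- colMeans(X[rows, , drop = FALSE])
    data.frame(level = l, emmean = sum(L * b),
               se = sqrt(drop(t(L) %*% V %*% L)),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Cohen's d plasticity effect sizes
#'
#' For each trait, d = (mean_new - mean_control) / pooled SD within each
#' year; |d| is then averaged across years. Traits are grouped as
#' volatiles vs other traits and the group mean |d| values are compared
#' with a Welch two-sample test across traits (approximate: traits are
#' treated as independent).
#'
#' @param data data.frame with trait columns, a treatment column and
#'   `year`.
#' @param traits character vector of trait column names.
#' @param treatment name of the treatment factor column.
#' @param new,control the two treatment levels contrasted.
#' @param volatile_traits names of the traits counted as volatiles.
#' @return list `per_trait` (trait, year, d), `trait_mean_abs_d`,
#'   `group_summary` (mean |d| per group), `test` (htest or NULL).
#' @export
plasticity_effect_sizes <- function(data, traits, treatment, new, control,
                                    volatile_traits = character()) {
  rows_new <- data[[treatment]] == new
  rows_ctl <- data[[treatment]] == control
  per <- do.call(rbind, lapply(traits, function(tr) {
    do.call(rbind, lapply(unique(data$year), function(y) {
      a <- data[[tr]][rows_new & data$year == y]
      b <- data[[tr]][rows_ctl & data$year == y]
      a <- a[!is.na(a)]; b <- b[!is.na(b)]
      if (length(a) < 2 || length(b) < 2) return(NULL)
      sp <- sqrt(((length(a) - 1) * stats::var(a) +
                    (length(b) - 1) * stats::var(b)) /
                   (length(a) + length(b) - 2))
      d <- if (sp == 0) NA_real_ else (mean(a) - mean(b)) / sp
      data.frame(trait = tr, year = y, d = d, zero_sd = sp == 0,
                 stringsAsFactors = FALSE)
    }))
  }))
  mean_abs <- tapply(abs(per$d), per$trait, mean, na.rm = TRUE)
  grp <- ifelse(names(mean_abs) %in% volatile_traits, "volatile", "other")
  test <- if (length(unique(grp)) == 2 && all(table(grp) >= 2)) {
    stats::t.test(mean_abs ~ grp)
  } else NULL
  list(per_trait = per,
       trait_mean_abs_d = data.frame(trait = names(mean_abs),
                                     mean_abs_d = unname(mean_abs),
                                     group = grp,
                                     stringsAsFactors = FALSE),
       group_summary = tapply(mean_abs, grp, mean),
       test = test)
}

#' Correlation between two plasticity vectors across volatiles
#'
#' Pearson correlation of per-volatile plasticity to one manipulation
#' (e.g. early snowmelt) against plasticity to another (e.g. reduced
#' precipitation), typically within a year.
#'
#' @param x,y numeric plasticity vectors of equal length (>= 3).
#' @return list `r`, `p`, `n`.
#' @export
plasticity_correlation <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need >= 3 volatiles")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant plasticity vector, correlation undefined")
  }
  ct <- stats::cor.test(x, y)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}
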