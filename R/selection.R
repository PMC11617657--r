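#' Standardize traits to mean 0, SD 1
#'
#' Sample SD (n-1 denominator). Zero-SD traits are an error naming the
#' trait; standardization is always computed over the plants entering the
#' model at hand.
#'
#' @param traits numeric matrix or data.frame, plants x traits.
#' @return list `z` (matrix), `center`, `scale`.
#' @export
standardize_traits <- function(traits) {
  m <- as.matrix(traits)
  mu <- colMeans(m, na.rm = TRUE)
  sd_ <- apply(m, 2, stats::sd, na.rm = TRUE)
  if (any(!is.finite(sd_)) || any(sd_ == 0)) {
    bad <- colnames(m)[!is.finite(sd_) | sd_ == 0]
    stop("zero-SD trait(s), cannot standardize: ",
         paste(bad, collapse = ", "))
  }
  z <- sweep(sweep(m, 2, mu), 2, sd_, "/")
  list(z = z, center = mu, scale = sd_)
}

#' Volatiles eligible for univariate selection analysis
#'
#' Compounds emitted (value > 0) in at least `threshold` of the samples
#' (>=, so a compound at exactly the threshold is included).
#'
#' @param samples sample x compound matrix of emission values (one row per
#'   sample, before plant averaging) or a plant matrix if plant-level
#'   occurrence is wanted.
#' @param threshold minimum occurrence proportion (default 0.75).
#' @return character vector of eligible compound names.
#' @export
eligible_volatiles <- function(samples, threshold = 0.75) {
  m <- as.matrix(samples)
  occ <- colMeans(m > 0)
  colnames(m)[occ >= threshold]
}

#' Selection on compound classes across treatments and years
#'
#' One linear model per fitness measure: relative fitness on the four
#' standardized class totals, the design factors (year, snowmelt,
#' precipitation), and all class x factor interactions. Per-context
#' gradients (the slope of fitness on each class within a year/treatment
#' cell) are derived from the coefficients, and each interaction block is
#' tested marginally (type-II style F via `drop1`).
#'
#' @param w relative fitness vector.
#' @param class_z standardized class-total matrix (plants x classes).
#' @param year,snow,precip design factors aligned with `w`.
#' @return list `fit`, `gradients` (class, year, snow, precip, beta, se),
#'   `interaction_tests` (term, df, F, p).
#' @export
class_selection_model <- function(w, class_z, year, snow, precip) {
  d <- data.frame(w = w, class_z, year = factor(year),
                  snow = factor(snow), precip = factor(precip))
  classes <- colnames(class_z)
  ok <- stats::complete.cases(d)
  d <- d[ok, ]
  env <- "year + snow + precip"
  cls <- paste(classes, collapse = " + ")
  form <- stats::as.formula(paste(
    "w ~", cls, "+", env, "+",
    paste(sapply(classes, function(cl) {
      paste0(cl, ":(", env, ")")
    }), collapse = " + ")))
  fit <- stats::lm(form, data = d)
  # marginal F for each interaction block: explicit nested-model tests
  inter_terms <- attr(stats::terms(fit), "term.labels")
  inter_terms <- inter_terms[grepl(":", inter_terms)]
  it <- do.call(rbind, lapply(inter_terms, function(tm) {
    red <- stats::update(fit, stats::as.formula(paste("~ . -", tm)))
    av <- stats::anova(red, fit)
    data.frame(term = tm, df = av$Df[2], F = av$F[2],
               p = av$`Pr(>F)`[2], stringsAsFactors = FALSE)
  }))
  # per-context gradients: derivative of fitted w wrt each class z in each
  # (year, snow, precip) cell, by finite differencing the model matrix
  cells <- unique(d[, c("year", "snow", "precip")])
  b <- stats::coef(fit)
  V <- stats::vcov(fit)
  grads <- do.call(rbind, lapply(seq_len(nrow(cells)), function(k) {
    do.call(rbind, lapply(classes, function(cl) {
      base <- cells[k, , drop = FALSE]
      for (cl2 in classes) base[[cl2]] <- 0
      plus <- base; plus[[cl]] <- 1
      mm <- stats::model.matrix(stats::delete.response(stats::terms(fit)),
                                rbind(base, plus))
      L <- mm[2, ] - mm[1, ]
      ok_b <- !is.na(b)
      est <- sum(L[ok_b] * b[ok_b])
      se <- sqrt(drop(t(L[ok_b]) %*% V %*% L[ok_b]))
      data.frame(class = cl, year = as.character(base$year),
                 snow = as.character(base$snow),
                 precip = as.character(base$precip),
                 beta = est, se = se, stringsAsFactors = FALSE)
    }))
  }))
  rownames(grads) <- NULL
  list(fit = fit, gradients = grads, interaction_tests = it)
}

#' Univariate selection with environmental interactions and a drop rule
#'
#' Fits `w ~ z + S + P + z:S + z:P` with the environmental variables
#' centred (so the main-effect beta is the gradient at the average
#' environment). If both trait x environment interactions have p > 0.05
#' the model is refit without them and the main effect reported;
#' otherwise both interaction slopes are reported (per day of snowmelt
#' date, per mm of precipitation).
#'
#' @param z standardized trait vector.
#' @param w relative fitness.
#' @param S snowmelt date (day of year).
#' @param P summer precipitation (mm).
#' @param drop_p significance threshold of the drop rule.
#' @return data.frame with one row: `beta`, `se`, `p`,
#'   `interactions_retained`, `slope_melt`, `slope_melt_se`, `slope_melt_p`,
#'   `slope_precip`, `slope_precip_se`, `slope_precip_p`, `n`.
#' @export
univariate_env_selection <- function(z, w, S, P, drop_p = 0.05) {
  ok <- stats::complete.cases(z, w, S, P)
  z <- z[ok]; w <- w[ok]; S <- S[ok]; P <- P[ok]
  if (length(z) < 10) stop("need n >= 10")
  if (stats::sd(S) == 0 || stats::sd(P) == 0) {
    stop("environmental variable does not vary")
  }
  Sc <- S - mean(S); Pc <- P - mean(P)
  if (abs(stats::cor(Sc, Pc)) > 0.95) {
    warning("snowmelt date and precipitation nearly collinear (|r| > 0.95)")
  }
  full <- stats::lm(w ~ z + Sc + Pc + z:Sc + z:Pc)
  cf <- summary(full)$coefficients
  p_int <- cf[c("z:Sc", "z:Pc"), 4]
  if (all(p_int > drop_p)) {
    red <- stats::lm(w ~ z + Sc + Pc)
    cr <- summary(red)$coefficients
    data.frame(beta = cr["z", 1], se = cr["z", 2], p = cr["z", 4],
               interactions_retained = FALSE,
               slope_melt = NA_real_, slope_melt_se = NA_real_,
               slope_melt_p = NA_real_,
               slope_precip = NA_real_, slope_precip_se = NA_real_,
               slope_precip_p = NA_real_, n = length(z))
  } else {
    data.frame(beta = cf["z", 1], se = cf["z", 2], p = cf["z", 4],
               interactions_retained = TRUE,
               slope_melt = cf["z:Sc", 1], slope_melt_se = cf["z:Sc", 2],
               slope_melt_p = cf["z:Sc", 4],
               slope_precip = cf["z:Pc", 1],
               slope_precip_se = cf["z:Pc", 2],
               slope_precip_p = cf["z:Pc", 4], n = length(z))
  }
}

#' Elastic-net configuration
#'
#' @param alpha L1/L2 mixing (0.5 by default).
#' @param lambda_rule `"min_cv"` (CV-error minimiser, the default reading
#'   of "optimum lambda") or `"one_se"`.
#' @param n_folds cross-validation folds (>= 3).
#' @param seed fold-assignment seed.
#' @return list of class `en_config`.
#' @export
en_config <- function(alpha = 0.5, lambda_rule = c("min_cv", "one_se"),
                      n_folds = 10L, seed = 1L) {
  lambda_rule <- match.arg(lambda_rule)
  stopifnot(alpha >= 0, alpha <= 1, n_folds >= 3)
  structure(list(alpha = alpha, lambda_rule = lambda_rule,
                 n_folds = as.integer(n_folds), seed = as.integer(seed)),
            class = "en_config")
}

#' Elastic-net direct selection gradients
#'
#' Penalized regression of relative fitness on standardized traits with
#' mixing alpha = 0.5 and lambda chosen by K-fold cross-validation under a
#' fixed fold seed. Environmental covariates, when supplied, enter
#' unpenalized so shrinkage targets the traits. Coefficients exactly zero
#' mean "not selected"; no SEs or p-values are produced (they are not
#' readily available for the elastic net).
#'
#' @param Z standardized trait matrix (no missing cells).
#' @param w relative fitness.
#' @param env optional matrix/data.frame of environmental covariates
#'   (centred internally).
#' @param config an [en_config()].
#' @return list `coefficients` (data.frame trait, beta, selected),
#'   `lambda`, `cvfit`.
#' @export
elastic_net_gradients <- function(Z, w, env = NULL,
                                  config = en_config()) {
  Z <- as.matrix(Z)
  if (anyNA(Z) || anyNA(w)) stop("missing cells in traits or fitness")
  n <- nrow(Z)
  if (n < config$n_folds) stop("n < n_folds")
  X <- Z
  pf <- rep(1, ncol(Z))
  if (!is.null(env)) {
    E <- scale(as.matrix(env), scale = FALSE)
    X <- cbind(Z, E)
    pf <- c(pf, rep(0, ncol(E)))
  }
  rng <- local_rng(config$seed)
  on.exit(rng())
  foldid <- sample(rep_len(seq_len(config$n_folds), n))
  cvfit <- glmnet::cv.glmnet(X, w, alpha = config$alpha,
                             penalty.factor = pf, foldid = foldid,
                             standardize = FALSE)
  lam <- if (config$lambda_rule == "min_cv") cvfit$lambda.min else
    cvfit$lambda.1se
  co <- as.numeric(stats::coef(cvfit, s = lam))[-1]
  out <- data.frame(trait = colnames(X), beta = co,
                    selected = co != 0,
                    penalized = pf == 1, stringsAsFactors = FALSE)
  list(coefficients = out, lambda = lam, cvfit = cvfit)
}

#' Gradients within year x treatment subsets
#'
#' Univariate (`w ~ z`) and elastic-net gradients estimated separately in
#' each subset, without the continuous environmental variables. Subsets
#' below `min_n` are reported as missing, not zero. Fitness is
#' re-relativized and traits are re-standardized within each subset.
#'
#' @param Z trait matrix (raw scale; standardized within subset).
#' @param fitness raw fitness vector (relativized within subset).
#' @param subset_f factor (or interaction) defining the subsets.
#' @param config [en_config()] for the elastic-net fits.
#' @param min_n minimum subset size (default 10).
#' @param elastic_net also fit the elastic net per subset.
#' @return data.frame `subset`, `trait`, `method`, `beta`, `se`, `p`, `n`
#'   (`se`/`p` NA for elastic-net rows; all NA when the subset is too
#'   small).
#' @export
per_treatment_gradients <- function(Z, fitness, subset_f,
                                    config = en_config(), min_n = 10,
                                    elastic_net = TRUE) {
  Z <- as.matrix(Z)
  subset_f <- factor(subset_f)
  out <- list()
  for (s in levels(subset_f)) {
    rows <- which(subset_f == s & !is.na(fitness) &
                    stats::complete.cases(Z))
    if (length(rows) < min_n) {
      out[[s]] <- data.frame(subset = s, trait = colnames(Z),
                             method = "univariate", beta = NA_real_,
                             se = NA_real_, p = NA_real_,
                             n = length(rows), stringsAsFactors = FALSE)
      next
    }
    wsub <- relativize(fitness[rows])
    zs <- standardize_traits(Z[rows, , drop = FALSE])$z
    uni <- do.call(rbind, lapply(colnames(Z), function(tr) {
      fit <- stats::lm(wsub ~ zs[, tr])
      cf <- summary(fit)$coefficients
      data.frame(subset = s, trait = tr, method = "univariate",
                 beta = cf[2, 1], se = cf[2, 2], p = cf[2, 4],
                 n = length(rows), stringsAsFactors = FALSE)
    }))
    res <- uni
    if (elastic_net && length(rows) >= config$n_folds) {
      enr <- elastic_net_gradients(zs, wsub, env = NULL, config = config)
      res <- rbind(res, data.frame(subset = s,
                                   trait = enr$coefficients$trait,
                                   method = "elastic_net",
                                   beta = enr$coefficients$beta,
                                   se = NA_real_, p = NA_real_,
                                   n = length(rows),
                                   stringsAsFactors = FALSE))
    }
    out[[s]] <- res
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Direct environmental effects on fitness
#'
#' `w ~ S + P` with the trait removed for ease of interpretation. The
#' snowmelt-date coefficient is also expressed as percent change of mean
#' fitness per day of EARLIER melt (sign flipped), and the precipitation
#' coefficient as percent change per mm.
#'
#' @param w relative fitness (mean 1).
#' @param S snowmelt date; `P` summer precipitation.
#' @return data.frame: estimates, SEs, p-values and the percent-scale
#'   effects.
#' @export
env_fitness_effects <- function(w, S, P) {
  ok <- stats::complete.cases(w, S, P)
  fit <- stats::lm(w[ok] ~ S[ok] + P[ok])
  cf <- summary(fit)$coefficients
  data.frame(
    coef_melt = cf[2, 1], se_melt = cf[2, 2], p_melt = cf[2, 4],
    coef_precip = cf[3, 1], se_precip = cf[3, 2], p_precip = cf[3, 4],
    pct_per_day_earlier = -100 * cf[2, 1],
    pct_per_day_earlier_se = 100 * cf[2, 2],
    pct_per_mm = 100 * cf[3, 1],
    pct_per_mm_se = 100 * cf[3, 2],
    n = sum(ok)
  )
}
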