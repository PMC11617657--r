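#' Default catalog of 29 floral volatiles in four biosynthetic classes
#'
#' Names, compound classes, nominal GC retention times (min) and baseline
#' lognormal emission parameters (log ng flower^-1 h^-1). Abundances mimic a
#' scent profile dominated by alpha-pinene with a handful of mid-abundance
#' monoterpenes and aliphatics and a long tail of minor compounds.
#'
#' @return data.frame with columns `compound`, `class`, `rt`, `log_mean`,
#'   `log_sd`.
#' @export
compound_catalog <- function() {
  mk <- function(compound, class, rt, log_mean, log_sd = 0.7) {
    data.frame(compound = compound, class = class, rt = rt,
               log_mean = log_mean, log_sd = log_sd,
               stringsAsFactors = FALSE)
  }
  rbind(
    mk("alpha_pinene",        "monoterpene",   4.1, log(60)),
    mk("camphene",            "monoterpene",   4.5, log(2)),
    mk("sabinene",            "monoterpene",   4.9, log(6)),
    mk("beta_myrcene",        "monoterpene",   5.2, log(5)),
    mk("carene_3",            "monoterpene",   5.6, log(18)),
    mk("limonene",            "monoterpene",   5.9, log(22)),
    mk("Z_beta_ocimene",      "monoterpene",   6.3, log(16)),
    mk("E_beta_ocimene",      "monoterpene",   6.5, log(12)),
    mk("linalool",            "monoterpene",   7.2, log(3)),
    mk("verbenone",           "monoterpene",   8.4, log(2)),
    mk("beta_caryophyllene",  "sesquiterpene", 11.8, log(4)),
    mk("Z_alpha_bergamotene", "sesquiterpene", 12.1, log(3)),
    mk("alpha_humulene",      "sesquiterpene", 12.5, log(1.5)),
    mk("germacrene_D",        "sesquiterpene", 12.9, log(2)),
    mk("delta_cadinene",      "sesquiterpene", 13.4, log(1)),
    mk("EE_farnesol",         "sesquiterpene", 15.2, log(1.2)),
    mk("benzaldehyde",        "benzenoid",     4.3, log(3)),
    mk("benzyl_alcohol",      "benzenoid",     5.1, log(1.5)),
    mk("phenylacetaldehyde",  "benzenoid",     5.8, log(2)),
    mk("methyl_benzoate",     "benzenoid",     6.8, log(2.5)),
    mk("methyl_salicylate",   "benzenoid",     8.1, log(3)),
    mk("indole",              "benzenoid",     9.3, log(1.2)),
    mk("hexanal",             "aliphatic",     3.1, log(2)),
    mk("Z_hex_3_en_1_ol",     "aliphatic",     3.6, log(14)),
    mk("hexan_1_ol",          "aliphatic",     3.8, log(4)),
    mk("E_4_oxohex_2_enal",   "aliphatic",     4.0, log(2)),
    mk("Z_hex_3_enyl_acetate","aliphatic",     6.1, log(3)),
    mk("nonanal",             "aliphatic",     7.6, log(2.5)),
    mk("decanal",             "aliphatic",     8.9, log(1.5))
  )
}

#' Default floral morphology and reward traits
#'
#' @return data.frame with columns `trait`, `mean`, `sd`, `unit`.
#' @export
morphology_catalog <- function() {
  data.frame(
    trait = c("corolla_length", "corolla_width", "style_length",
              "sepal_width", "nectar_production", "nectar_concentration",
              "inflorescence_height"),
    mean = c(28, 3.5, 30, 2.2, 2, 25, 40),
    sd   = c(2, 0.4, 2.5, 0.3, 0.8, 4, 10),
    unit = c("mm", "mm", "mm", "mm", "ul_per_day", "percent", "cm"),
    stringsAsFactors = FALSE
  )
}

#' True parameters of a synthetic study
#'
#' Bundles everything the generator needs: the compound catalog with
#' lognormal baselines, within-class emission correlation, a per-compound
#' detection gate (zero-inflation), plasticity effects, morphology traits,
#' true selection gradients on standardized traits, seed-predator preference
#' coefficients, and the reproductive-component distributions.
#'
#' Selection truth: expected seeds initiated per flower is
#' `seeds_per_flower_base * exp(sum(beta_poll * z))` where `z` is the
#' standardized trait (square-root scale for volatiles); each nonaborted
#' fruit is attacked with probability
#' `plogis(qlogis(attack_baseline) + sum(beta_pred * z))`, and fly eggs are
#' Poisson with mean proportional to the same preference odds.
#' `beta_poll_melt` lets a gradient change linearly with snowmelt date
#' (units: per day, applied to the date centred on its study mean).
#'
#' @param catalog compound catalog, see [compound_catalog()].
#' @param morphology morphology catalog, see [morphology_catalog()].
#' @param within_class_corr common correlation of log emissions within a
#'   compound class (0 <= r < 1).
#' @param detection_prob per-compound probability a plant emits the
#'   compound at all (Bernoulli gate on the lognormal draw); scalar or
#'   named per-compound vector.
#' @param plasticity list of named effect vectors keyed by trait/compound:
#'   `snow_early`, `precip_reduced`, `precip_addition`, `precip_mock` hold
#'   multiplicative effects on the trait mean; `moisture` holds additive
#'   log-scale slopes per %VWC for volatiles (SD units per %VWC for
#'   morphology traits).
#' @param beta_poll,beta_poll_melt,beta_pred named vectors of true
#'   gradients / preference coefficients on standardized traits.
#' @param attack_baseline baseline probability a nonaborted fruit is
#'   attacked (paper's field range is 10--30% of fruits).
#' @param seeds_per_flower_base expected seeds initiated per flower for an
#'   average plant.
#' @param flowers_mu,flowers_size negative-binomial mean and size of
#'   flowers per plant.
#' @param p_abort probability a flower at risk aborts; `p_dehisce`
#'   probability a surviving uneaten fruit dehisces before collection;
#'   `p_early` probability a flower is collected early for measurement.
#' @param fly_share fraction of attacked fruits attacked by flies (rest by
#'   caterpillars); `egg_rate` baseline fly eggs per surveyed flower.
#' @param contaminants compound names treated as ambient contaminants by
#'   [simulate_ambient()].
#' @return object of class `true_params`.
#' @export
true_params <- function(catalog = compound_catalog(),
                        morphology = morphology_catalog(),
                        within_class_corr = 0.5,
                        detection_prob = 0.85,
                        plasticity = list(),
                        beta_poll = numeric(),
                        beta_poll_melt = numeric(),
                        beta_pred = numeric(),
                        attack_baseline = 0.2,
                        seeds_per_flower_base = 4,
                        flowers_mu = 40, flowers_size = 4,
                        p_abort = 0.3, p_dehisce = 0.1, p_early = 0.02,
                        fly_share = 0.875, egg_rate = 0.3,
                        contaminants = character()) {
  stopifnot(within_class_corr >= 0, within_class_corr < 1,
            attack_baseline >= 0, attack_baseline <= 1,
            all(detection_prob >= 0), all(detection_prob <= 1),
            seeds_per_flower_base > 0)
  all_traits <- c(catalog$compound, morphology$trait)
  chk <- function(v, what) {
    if (length(v) && is.null(names(v))) {
      stop(what, " must be a named vector")
    }
    bad <- setdiff(names(v), all_traits)
    if (length(bad)) stop(what, ": unknown trait(s) ",
                          paste(bad, collapse = ", "))
    v
  }
  tp <- list(
    catalog = catalog, morphology = morphology,
    within_class_corr = within_class_corr,
    detection_prob = detection_prob,
    plasticity = plasticity,
    beta_poll = chk(beta_poll, "beta_poll"),
    beta_poll_melt = chk(beta_poll_melt, "beta_poll_melt"),
    beta_pred = chk(beta_pred, "beta_pred"),
    attack_baseline = attack_baseline,
    seeds_per_flower_base = seeds_per_flower_base,
    flowers_mu = flowers_mu, flowers_size = flowers_size,
    p_abort = p_abort, p_dehisce = p_dehisce, p_early = p_early,
    fly_share = fly_share, egg_rate = egg_rate,
    contaminants = contaminants
  )
  class(tp) <- "true_params"
  tp
}

# Effect lookup helpers: multiplicative treatment effect (default 1) and
# additive moisture slope (default 0) for one trait name.
plast_mult <- function(plasticity, key, trait) {
  v <- plasticity[[key]]
  if (is.null(v) || is.na(v[trait])) 1 else unname(v[trait])
}
plast_slope <- function(plasticity, trait) {
  v <- plasticity[["moisture"]]
  if (is.null(v) || is.na(v[trait])) 0 else unname(v[trait])
}

treatment_key <- function(snow, precip) {
  # snow effect applies at the plot level, precip at the subplot level;
  # multipliers multiply when both are non-control
  keys <- character()
  if (snow == "early") keys <- c(keys, "snow_early")
  if (precip != "control") keys <- c(keys, paste0("precip_", precip))
  keys
}

#' Simulate plants: traits, volatile samples and reproductive components
#'
#' Draws plants in each subplot-year of the design, gives each a correlated
#' lognormal volatile profile (within-class correlation, detection gate) and
#' normal morphology traits, applies treatment and soil-moisture plasticity,
#' then generates reproductive components from the true selection gradients:
#' flower number (negative binomial), aborted flowers, fruit fates
#' (fly/caterpillar attack, dehiscence), seed counts of intact fruits, and
#' season totals of fly eggs and surveyed flowers.
#'
#' Floral headspace samples are laid out over several sampling dates per
#' year; a configurable fraction of plants (default 16%) is sampled twice.
#' Sample-level peak areas are the plant's true emission rate times
#' sampling duration times the true calibration slope of its class
#' standard, with lognormal sample noise.
#'
#' @param design output of [build_design()].
#' @param truth a [true_params()] object.
#' @param n_plants_per_subplot plants per subplot-year (default 5, giving
#'   ~360 plants for the default 72 subplot-year design, mirroring the
#'   field study's n = 374 regime).
#' @param seed integer seed.
#' @param n_total optional total plant count; overrides
#'   `n_plants_per_subplot` by distributing plants round-robin over
#'   subplot-years.
#' @param multi_sample_prob fraction of plants measured twice.
#' @param sample_noise_sd lognormal sd of sample-level deviations from the
#'   plant's true emission rate.
#' @param duration_h headspace sampling duration (h).
#' @param dates_per_year number of volatile sampling dates per year.
#' @return list with `trait_table`, `peak_table`, `fitness_components`,
#'   `emissions` (plant x compound true rates), `moisture` (per-plant and
#'   subplot season VWC), `sampling_dates`, and `z` (the standardized trait
#'   matrix the truth gradients acted on).
#' @export
simulate_plants <- function(design, truth = true_params(),
                            n_plants_per_subplot = 5L, seed = 1L,
                            n_total = NULL,
                            multi_sample_prob = 0.16,
                            sample_noise_sd = 0.3,
                            duration_h = 0.25,
                            dates_per_year = 8L) {
  stopifnot(inherits(truth, "true_params"))
  if (is.null(n_total)) {
    if (n_plants_per_subplot <= 0) stop("n_plants_per_subplot must be >= 1")
    alloc <- rep(as.integer(n_plants_per_subplot), nrow(design))
  } else {
    if (n_total <= 0) stop("n_total must be >= 1")
    alloc <- diff(floor(seq(0, n_total, length.out = nrow(design) + 1)))
  }
  rng <- local_rng(seed)
  on.exit(rng())

  cat_ <- truth$catalog
  morph <- truth$morphology
  n_cmp <- nrow(cat_)

  moist <- simulate_soil_moisture_rows(design, alloc)
  drow <- moist$design_row
  n <- length(drow)
  plant_id <- sprintf("%s-%d-p%02d", design$subplot_id[drow],
                      design$year[drow], moist$within)

  # --- volatile emissions: block-correlated lognormal with detection gate
  R <- block_corr(cat_$class, truth$within_class_corr)
  L <- chol(R)
  Zlat <- matrix(stats::rnorm(n * n_cmp), n, n_cmp) %*% L
  det_p <- rep_len(truth$detection_prob, n_cmp)
  logE <- matrix(rep(cat_$log_mean, each = n), n, n_cmp)
  mean_vwc <- mean(moist$vwc)
  for (j in seq_len(n_cmp)) {
    cmpd <- cat_$compound[j]
    mult <- vapply(seq_len(n), function(i) {
      keys <- treatment_key(as.character(design$snow_treatment[drow[i]]),
                            as.character(design$precip_treatment[drow[i]]))
      prod(vapply(keys, plast_mult, 1, plasticity = truth$plasticity,
                  trait = cmpd))
    }, 1)
    logE[, j] <- logE[, j] + log(mult) +
      plast_slope(truth$plasticity, cmpd) * (moist$vwc - mean_vwc) +
      cat_$log_sd[j] * Zlat[, j]
  }
  gate <- matrix(stats::rbinom(n * n_cmp, 1,
                               rep(det_p, each = n)), n, n_cmp)
  emissions <- exp(logE) * gate
  colnames(emissions) <- cat_$compound
  rownames(emissions) <- plant_id

  # --- morphology traits with plasticity
  traits <- matrix(NA_real_, n, nrow(morph),
                   dimnames = list(plant_id, morph$trait))
  for (j in seq_len(nrow(morph))) {
    tr <- morph$trait[j]
    mult <- vapply(seq_len(n), function(i) {
      keys <- treatment_key(as.character(design$snow_treatment[drow[i]]),
                            as.character(design$precip_treatment[drow[i]]))
      prod(vapply(keys, plast_mult, 1, plasticity = truth$plasticity,
                  trait = tr))
    }, 1)
    traits[, j] <- morph$mean[j] * mult +
      morph$sd[j] * plast_slope(truth$plasticity, tr) *
        (moist$vwc - mean_vwc) +
      stats::rnorm(n, 0, morph$sd[j])
  }
  traits[, "nectar_production"] <- pmax(0, traits[, "nectar_production"])

  # --- standardized traits the true gradients act on (sqrt scale for
  #     volatiles, matching the analysis scale)
  z <- scale(cbind(sqrt(emissions), traits))
  z[is.nan(z)] <- 0

  eta <- function(beta, beta_melt = NULL) {
    e <- rep(0, n)
    for (tr in names(beta)) e <- e + beta[[tr]] * z[, tr]
    if (length(beta_melt)) {
      S <- design$snowmelt_date[drow]
      Sc <- S - mean(S)
      for (tr in names(beta_melt)) e <- e + beta_melt[[tr]] * Sc * z[, tr]
    }
    e
  }
  eta_poll <- eta(truth$beta_poll, truth$beta_poll_melt)
  eta_pred <- stats::qlogis(min(max(truth$attack_baseline, 1e-6),
                                1 - 1e-6)) + eta(truth$beta_pred)

  # --- reproductive components
  flowers_total <- 1L + stats::rnbinom(n, mu = truth$flowers_mu,
                                       size = truth$flowers_size)
  collected_early <- stats::rbinom(n, flowers_total, truth$p_early)
  at_risk <- flowers_total - collected_early
  aborted <- stats::rbinom(n, at_risk, truth$p_abort)
  nonaborted <- at_risk - aborted
  p_attack <- stats::plogis(eta_pred)
  attacked <- stats::rbinom(n, nonaborted, p_attack)
  fruits_fly <- stats::rbinom(n, attacked, truth$fly_share)
  fruits_caterpillar <- attacked - fruits_fly
  noneaten <- nonaborted - attacked
  fruits_dehisced <- stats::rbinom(n, noneaten, truth$p_dehisce)
  fruits_intact <- noneaten - fruits_dehisced
  # seeds per fruit scaled so E[seeds initiated per flower] = base*exp(eta)
  mu_fruit <- truth$seeds_per_flower_base * exp(eta_poll) /
    (1 - truth$p_abort)
  seeds_counted <- vapply(seq_len(n), function(i) {
    if (fruits_intact[i] == 0) 0L
    else sum(stats::rpois(fruits_intact[i], mu_fruit[i]))
  }, integer(1))
  flowers_surveyed <- pmax(1L, round(flowers_total *
                                       stats::runif(n, 1.2, 2)))
  # eggs proportional to the attack odds ratio exp(sum beta_pred * z)
  eggs_total <- stats::rpois(n, truth$egg_rate * flowers_surveyed *
                               exp(eta_pred - stats::qlogis(
                                 min(max(truth$attack_baseline, 1e-6),
                                     1 - 1e-6))))

  fitness_components <- data.frame(
    plant_id = plant_id,
    year = design$year[drow],
    flowers_total = flowers_total,
    aborted = aborted,
    fruits_intact = fruits_intact,
    seeds_counted = seeds_counted,
    fruits_dehisced = fruits_dehisced,
    fruits_fly = fruits_fly,
    fruits_caterpillar = fruits_caterpillar,
    flowers_collected_early = collected_early,
    eggs_total = eggs_total,
    flowers_surveyed = flowers_surveyed,
    stringsAsFactors = FALSE
  )

  trait_table <- data.frame(
    plant_id = plant_id,
    year = design$year[drow],
    plot_id = design$plot_id[drow],
    subplot_id = design$subplot_id[drow],
    snow_treatment = design$snow_treatment[drow],
    precip_treatment = design$precip_treatment[drow],
    snowmelt_date = design$snowmelt_date[drow],
    summer_precip = design$summer_precip[drow],
    plant_vwc = moist$vwc,
    season_vwc = moist$season[drow],
    traits,
    stringsAsFactors = FALSE
  )

  # --- headspace samples and peak areas
  dates <- sampling_dates(design, dates_per_year)
  slopes <- true_slopes()
  class_std <- default_standard_map(cat_)
  n_samp <- 1L + stats::rbinom(n, 1, multi_sample_prob)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    yr <- design$year[drow[i]]
    dd <- sample(dates[[as.character(yr)]], n_samp[i],
                 replace = n_samp[i] > length(dates[[as.character(yr)]]))
    for (s in seq_len(n_samp[i])) {
      noise <- exp(stats::rnorm(n_cmp, 0, sample_noise_sd))
      rate <- emissions[i, ] * noise
      area <- rate * duration_h * slopes[class_std[cat_$compound]]
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sprintf("%s-s%d", plant_id[i], s),
        plant_id = plant_id[i],
        year = yr, date = dd[s], sample_type = "floral",
        compound = cat_$compound, retention_time = cat_$rt,
        peak_area = unname(area),
        stringsAsFactors = FALSE
      )
    }
  }
  peak_table <- do.call(rbind, rows)
  rownames(peak_table) <- NULL

  list(trait_table = trait_table, peak_table = peak_table,
       fitness_components = fitness_components,
       emissions = emissions,
       moisture = moist, sampling_dates = dates, z = z)
}

# moisture draws aligned with a per-subplot plant allocation
simulate_soil_moisture_rows <- function(design, alloc) {
  season <- draw_season_vwc(design)
  drow <- rep(seq_len(nrow(design)), times = alloc)
  within <- sequence(alloc)
  vwc <- pmin(15, pmax(0, season[drow] + stats::rnorm(length(drow), 0, 2)))
  list(design_row = drow, within = within, vwc = vwc, season = season)
}

block_corr <- function(classes, r) {
  same <- outer(classes, classes, "==")
  R <- ifelse(same, r, 0)
  diag(R) <- 1
  R
}

sampling_dates <- function(design, dates_per_year) {
  yrs <- sort(unique(design$year))
  out <- lapply(yrs, function(y) {
    melt <- max(design$snowmelt_date[design$year == y])
    round(seq(melt + 30, melt + 75, length.out = dates_per_year))
  })
  names(out) <- as.character(yrs)
  out
}

#' True calibration slopes (peak area per ng) of the seven standards
#' @return named numeric vector.
#' @export
true_slopes <- function() {
  c(alpha_pinene = 1200, beta_caryophyllene = 900, EE_farnesol = 700,
    Z_hex_3_en_1_ol = 1000, indole = 800, linalool = 1100,
    methyl_salicylate = 950)
}

#' Default compound-to-standard map (by compound class)
#'
#' Monoterpenes are quantified with the alpha-pinene standard,
#' sesquiterpenes with beta-caryophyllene, benzenoids with methyl
#' salicylate and aliphatics with (Z)-hex-3-en-1-ol. Fully overridable:
#' seven standards exist for four classes, so alternative maps (e.g.
#' linalool for oxygenated monoterpenes) are legitimate.
#'
#' @param catalog a compound catalog.
#' @return named character vector, compound -> standard.
#' @export
default_standard_map <- function(catalog = compound_catalog()) {
  by_class <- c(monoterpene = "alpha_pinene",
                sesquiterpene = "beta_caryophyllene",
                benzenoid = "methyl_salicylate",
                aliphatic = "Z_hex_3_en_1_ol")
  stats::setNames(by_class[catalog$class], catalog$compound)
}

#' Simulate ambient air control samples
#'
#' One or more ambient samples per sampling date. Ambient peak areas are a
#' small fraction of the mean floral area (scaled by `contamination_level`);
#' compounds listed in `truth$contaminants` instead get ambient areas of
#' half their floral mean, so they fail the 4x floral/ambient filter by
#' construction.
#'
#' @param design design table (used for years).
#' @param truth [true_params()].
#' @param peak_table floral peak table whose per-compound means anchor the
#'   ambient levels; its dates define the sampling dates.
#' @param contamination_level non-negative scalar; 0 means perfectly clean
#'   ambient air (all areas 0).
#' @param seed integer seed.
#' @return data.frame of ambient peak rows (no `plant_id`).
#' @export
simulate_ambient <- function(design, truth, peak_table,
                             contamination_level = 1, seed = 1L) {
  if (contamination_level < 0) stop("contamination_level must be >= 0")
  rng <- local_rng(seed)
  on.exit(rng())
  cat_ <- truth$catalog
  fl_mean <- tapply(peak_table$peak_area, peak_table$compound, mean)
  fl_mean <- fl_mean[cat_$compound]
  base <- ifelse(cat_$compound %in% truth$contaminants,
                 0.5 * fl_mean, 0.02 * fl_mean * contamination_level)
  if (contamination_level == 0) {
    base <- ifelse(cat_$compound %in% truth$contaminants,
                   0.5 * fl_mean, 0)
  }
  dates <- unique(peak_table[, c("year", "date")])
  rows <- lapply(seq_len(nrow(dates)), function(k) {
    noise <- if (contamination_level > 0) {
      exp(stats::rnorm(nrow(cat_), 0, 0.3))
    } else rep(1, nrow(cat_))
    amb <- base * noise
    if (contamination_level == 0) {
      amb[!cat_$compound %in% truth$contaminants] <- 0
    }
    data.frame(
      sample_id = sprintf("amb-%d-%d", dates$year[k], dates$date[k]),
      plant_id = NA_character_,
      year = dates$year[k], date = dates$date[k],
      sample_type = "ambient",
      compound = cat_$compound, retention_time = cat_$rt,
      peak_area = unname(amb),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a calibration dilution series
#'
#' Linear detector response through the origin with multiplicative noise:
#' `area = slope * dosage * (1 + e)`, `e ~ N(0, noise_cv)`.
#'
#' @param standards names of the standards (default: the seven standards of
#'   [true_slopes()]).
#' @param dosages strictly positive, increasing dosages (ng).
#' @param replicates replicate injections per dosage (>= 2; field
#'   calibration series typically run 9--28 per dosage).
#' @param noise_cv coefficient of variation of the detector response.
#' @param seed integer seed.
#' @return data.frame `standard`, `dosage_ng`, `replicate`, `peak_area`;
#'   the true slopes are attached as `attr(, "true_slopes")`.
#' @export
simulate_dilution_series <- function(standards = names(true_slopes()),
                                     dosages = c(0.5, 1, 2, 5, 10, 20),
                                     replicates = 10L, noise_cv = 0.1,
                                     seed = 1L) {
  if (replicates < 2) stop("replicates must be >= 2 (no variance estimate)")
  if (any(dosages <= 0) || is.unsorted(dosages, strictly = TRUE)) {
    stop("dosages must be strictly positive and increasing")
  }
  rng <- local_rng(seed)
  on.exit(rng())
  slopes <- true_slopes()[standards]
  if (anyNA(slopes)) {
    slopes[is.na(slopes)] <- 1000
    names(slopes) <- standards
  }
  grid <- expand.grid(standard = standards, dosage_ng = dosages,
                      replicate = seq_len(replicates),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  e <- stats::rnorm(nrow(grid), 0, noise_cv)
  grid$peak_area <- pmax(0, slopes[grid$standard] * grid$dosage_ng * (1 + e))
  grid <- grid[order(grid$standard, grid$dosage_ng, grid$replicate), ]
  rownames(grid) <- NULL
  attr(grid, "true_slopes") <- slopes
  grid
}

#' Simulate a complete synthetic study
#'
#' Orchestrates [build_design()], [simulate_plants()], [simulate_ambient()]
#' and [simulate_dilution_series()] under a single seed, fanned out
#' deterministically to the four stages.
#'
#' @param config [design_config()].
#' @param truth [true_params()].
#' @param n_plants_per_subplot,n_total plant allocation, see
#'   [simulate_plants()].
#' @param contamination_level ambient contamination scalar.
#' @param seed single integer master seed.
#' @param ... passed to [simulate_plants()].
#' @return list of class `simulated_study` with elements `design`,
#'   `trait_table`, `peak_table` (floral + ambient rows), `fitness_components`,
#'   `dilution_series`, `emissions`, `truth`, `seed`.
#' @export
simulate_study <- function(config = design_config(),
                           truth = true_params(),
                           n_plants_per_subplot = 5L, n_total = NULL,
                           contamination_level = 1, seed = 1L, ...) {
  design <- build_design(config, seed = child_seed(seed, "design"))
  pl <- simulate_plants(design, truth,
                        n_plants_per_subplot = n_plants_per_subplot,
                        n_total = n_total,
                        seed = child_seed(seed, "plants"), ...)
  amb <- simulate_ambient(design, truth, pl$peak_table,
                          contamination_level = contamination_level,
                          seed = child_seed(seed, "ambient"))
  dil <- simulate_dilution_series(seed = child_seed(seed, "dilution"))
  study <- list(design = design,
                trait_table = pl$trait_table,
                peak_table = rbind(pl$peak_table, amb),
                fitness_components = pl$fitness_components,
                dilution_series = dil,
                emissions = pl$emissions,
                z = pl$z,
                truth = truth, seed = as.integer(seed))
  class(study) <- "simulated_study"
  study
}

#' Write a simulated study to CSV files plus a truth.json
#'
#' @param study a `simulated_study`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "simulated_study"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    design = file.path(dir, "design.csv"),
    traits = file.path(dir, "traits.csv"),
    peaks = file.path(dir, "peaks.csv"),
    fitness = file.path(dir, "fitness_components.csv"),
    dilution = file.path(dir, "dilution_series.csv"),
    truth = file.path(dir, "truth.json")
  )
  utils::write.csv(study$design, paths["design"], row.names = FALSE)
  utils::write.csv(study$trait_table, paths["traits"], row.names = FALSE)
  utils::write.csv(study$peak_table, paths["peaks"], row.names = FALSE)
  utils::write.csv(study$fitness_components, paths["fitness"],
                   row.names = FALSE)
  utils::write.csv(study$dilution_series, paths["dilution"],
                   row.names = FALSE)
  tr <- study$truth
  tr$catalog <- NULL; tr$morphology <- NULL
  jsonlite::write_json(
    c(tr, list(seed = study$seed,
               true_slopes = as.list(true_slopes()))),
    paths["truth"], auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(paths)
}
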