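#' Configuration for a synthetic split-plot snowmelt x precipitation design
#'
#' Describes a two-level split-plot field experiment: a snowmelt treatment
#' (early vs control, via shade cloth) applied to whole plots, crossed with
#' four summer-precipitation treatments applied to the subplots nested in
#' each whole plot, repeated over years.
#'
#' Defaults state the emulated world: 3 years, 3 whole plots per snowmelt
#' level (6 plots, 24 subplot-years per year), control snowmelt on days of
#' year 119, 158 and 126, shade cloth advancing snowmelt by 3--11 d (mean
#' 6 d, drawn uniformly per plot-year), and precipitation manipulations of
#' 50% reduction, 200% addition, a mock shelter and an unmanipulated
#' control.
#'
#' @param n_years number of study years.
#' @param plots_per_level whole plots per snowmelt level.
#' @param precip_levels labels of the four subplot precipitation treatments.
#' @param control_melt_doy day-of-year of snowmelt in control plots, one
#'   value per year (recycled if shorter).
#' @param advancement_range range (days) of snowmelt advancement in shaded
#'   plots; draws are uniform on this interval.
#' @param precip_multipliers named multipliers applied to the ambient summer
#'   precipitation of each year; must be non-negative and cover every level
#'   in `precip_levels`.
#' @param base_summer_precip ambient summer precipitation (mm) per year.
#' @return an object of class `design_config` (a validated list).
#' @export
design_config <- function(n_years = 3L,
                          plots_per_level = 3L,
                          precip_levels = c("control", "mock", "reduced",
                                            "addition"),
                          control_melt_doy = c(119, 158, 126),
                          advancement_range = c(3, 11),
                          precip_multipliers = c(control = 1, mock = 1,
                                                 reduced = 0.5, addition = 2),
                          base_summer_precip = c(150, 220, 130)) {
  stopifnot(n_years >= 1, plots_per_level >= 1,
            length(precip_levels) >= 1,
            length(advancement_range) == 2,
            advancement_range[1] <= advancement_range[2])
  if (any(precip_multipliers < 0)) {
    stop("precipitation multipliers must be non-negative")
  }
  missing_mult <- setdiff(precip_levels, names(precip_multipliers))
  if (length(missing_mult)) {
    stop("no precipitation multiplier for level(s): ",
         paste(missing_mult, collapse = ", "))
  }
  cfg <- list(
    n_years = as.integer(n_years),
    plots_per_level = as.integer(plots_per_level),
    precip_levels = precip_levels,
    control_melt_doy = rep_len(control_melt_doy, n_years),
    advancement_range = as.numeric(advancement_range),
    precip_multipliers = precip_multipliers,
    base_summer_precip = rep_len(base_summer_precip, n_years)
  )
  class(cfg) <- "design_config"
  cfg
}

#' Build the experimental design table
#'
#' Expands a [design_config()] into one row per subplot-year, assigning the
#' snowmelt treatment to whole plots, every precipitation level exactly once
#' within each whole plot, the realized snowmelt date (control date minus a
#' uniform 3--11 d advancement for shaded plots) and the estimated summer
#' precipitation (ambient precipitation times the treatment multiplier).
#'
#' @param config a [design_config()].
#' @param seed integer seed controlling the advancement draws.
#' @return a `data.frame` with columns `year`, `plot_id`, `snow_treatment`,
#'   `subplot_id`, `precip_treatment`, `snowmelt_date`, `summer_precip`.
#' @export
build_design <- function(config = design_config(), seed = 1L) {
  stopifnot(inherits(config, "design_config"))
  n_plots <- 2L * config$plots_per_level
  plots <- data.frame(
    plot_id = sprintf("P%d", seq_len(n_plots)),
    snow_treatment = rep(c("early", "control"),
                         each = config$plots_per_level),
    stringsAsFactors = FALSE
  )
  rng <- local_rng(seed)
  out <- vector("list", config$n_years * n_plots)
  k <- 0L
  for (y in seq_len(config$n_years)) {
    for (p in seq_len(n_plots)) {
      k <- k + 1L
      adv <- if (plots$snow_treatment[p] == "early") {
        stats::runif(1, config$advancement_range[1],
                     config$advancement_range[2])
      } else 0
      out[[k]] <- data.frame(
        year = 2017L + y,
        plot_id = plots$plot_id[p],
        snow_treatment = plots$snow_treatment[p],
        subplot_id = sprintf("%s-S%d", plots$plot_id[p],
                             seq_along(config$precip_levels)),
        precip_treatment = config$precip_levels,
        snowmelt_date = config$control_melt_doy[y] - adv,
        summer_precip = config$base_summer_precip[y] *
          unname(config$precip_multipliers[config$precip_levels]),
        stringsAsFactors = FALSE
      )
    }
  }
  rng()
  design <- do.call(rbind, out)
  design$snow_treatment <- factor(design$snow_treatment,
                                  levels = c("control", "early"))
  design$precip_treatment <- factor(design$precip_treatment,
                                    levels = config$precip_levels)
  rownames(design) <- NULL
  design
}

#' Simulate soil volumetric water content for a design
#'
#' Season-average subplot moisture rises monotonically with summer
#' precipitation and with later snowmelt, mapped through a logistic link
#' onto the observed 2--8% VWC range; plant-level snapshots scatter around
#' the subplot season mean and are truncated to the instrument-plausible
#' 0--15% VWC range.
#'
#' @param design output of [build_design()].
#' @param n_plants_per_subplot plant-level draws per subplot-year.
#' @param seed integer seed.
#' @param noise_sd standard deviation of plant-level scatter (% VWC).
#' @return list with `subplot` (design plus `season_vwc`) and `plant`
#'   (long table of plant-level `vwc` draws keyed by subplot row).
#' @export
simulate_soil_moisture <- function(design, n_plants_per_subplot = 5L,
                                   seed = 1L, noise_sd = 2) {
  stopifnot(n_plants_per_subplot >= 1)
  rng <- local_rng(seed)
  on.exit(rng())
  season <- draw_season_vwc(design)
  subplot <- cbind(design, season_vwc = season)
  idx <- rep(seq_len(nrow(design)), each = n_plants_per_subplot)
  plant <- data.frame(
    design_row = idx,
    subplot_id = design$subplot_id[idx],
    year = design$year[idx],
    vwc = pmin(15, pmax(0, season[idx] +
                          stats::rnorm(length(idx), 0, noise_sd)))
  )
  list(subplot = subplot, plant = plant)
}

# Season-average subplot VWC: logistic link from absolute precipitation
# (mm) and snowmelt date (DOY) onto the observed 2-8% range, with
# lognormal-ish noise inside the link so draws stay in range and respond
# monotonically to both drivers.  Anchors (180 mm, day 130) are the
# midpoints of the default scenario.
draw_season_vwc <- function(design) {
  lin <- 0.008 * (design$summer_precip - 180) +
    0.05 * (design$snowmelt_date - 130)
  2 + 6 * stats::plogis(lin + stats::rnorm(nrow(design), 0, 0.3))
}

# Seed scoping: save and restore .Random.seed so generator calls do not
# perturb the caller's RNG stream.  Returns a restore function.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(as.integer(seed))
  function() {
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
    invisible(NULL)
  }
}

# Deterministic fan-out of one user seed into per-stage child seeds,
# kept below 2^31 so they remain valid R integers.
child_seed <- function(seed, stage) {
  h <- digest::digest(list(as.integer(seed), as.character(stage)),
                      algo = "xxhash32")
  as.integer(strtoi(substr(h, 1, 7), base = 16L))
}
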