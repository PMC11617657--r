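#' Filtering configuration for GC-MS peak tables
#'
#' Defaults implement the standard inclusion rules for floral headspace
#' data: retention time within 2--17 min, detection in at least 10% of
#' floral samples, floral mean strictly greater than 4x the ambient-control
#' mean, and removal of named contaminants.
#'
#' @param rt_min,rt_max retention-time window (min).
#' @param min_freq minimum detection frequency among floral samples
#'   (proportion, 0 < min_freq < 1).
#' @param ambient_ratio required fold excess of the floral mean over the
#'   ambient mean (strict inequality).
#' @param contaminants character vector of compound names to drop.
#' @param detection_threshold peak area strictly above which a compound
#'   counts as detected in a sample (default 0).
#' @return list of class `filter_config`.
#' @export
filter_config <- function(rt_min = 2, rt_max = 17, min_freq = 0.10,
                          ambient_ratio = 4.0, contaminants = character(),
                          detection_threshold = 0) {
  stopifnot(rt_min < rt_max, min_freq > 0, min_freq < 1, ambient_ratio > 0)
  structure(list(rt_min = rt_min, rt_max = rt_max, min_freq = min_freq,
                 ambient_ratio = ambient_ratio, contaminants = contaminants,
                 detection_threshold = detection_threshold),
            class = "filter_config")
}

#' Filter compounds in a peak table
#'
#' Applies the four inclusion rules of [filter_config()] and returns both
#' the retained compound list and a complete per-compound audit: every
#' input compound appears exactly once, with the outcome of each rule.
#'
#' The detection-frequency denominator is the number of floral samples
#' only. The ambient-ratio comparison is division-free
#' (`floral_mean > ratio * ambient_mean`), so a compound absent from
#' ambient air (ambient mean 0) passes whenever its floral mean is
#' positive, and a floral mean of exactly `ratio` times the ambient mean
#' is excluded.
#'
#' @param peaks long peak table with columns `sample_id`, `sample_type`
#'   (`"floral"`/`"ambient"`), `compound`, `retention_time`, `peak_area`.
#' @param config a [filter_config()].
#' @return list with `retained` (character vector) and `audit`
#'   (data.frame of per-compound statistics and rule outcomes).
#' @export
filter_compounds <- function(peaks, config = filter_config()) {
  stopifnot(inherits(config, "filter_config"))
  need <- c("sample_id", "sample_type", "compound", "retention_time",
            "peak_area")
  miss <- setdiff(need, names(peaks))
  if (length(miss)) stop("peak table lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (any(peaks$peak_area < 0, na.rm = TRUE)) {
    stop("peak areas must be non-negative")
  }
  floral <- peaks[peaks$sample_type == "floral", ]
  ambient <- peaks[peaks$sample_type == "ambient", ]
  if (nrow(ambient) == 0) {
    stop("no ambient control samples: cannot apply the ambient-ratio ",
         "rule; refusing to filter without it")
  }
  n_floral <- length(unique(floral$sample_id))
  n_ambient <- length(unique(ambient$sample_id))
  compounds <- sort(unique(peaks$compound))
  thr <- config$detection_threshold

  audit <- do.call(rbind, lapply(compounds, function(cmpd) {
    fl <- floral[floral$compound == cmpd, ]
    am <- ambient[ambient$compound == cmpd, ]
    med_rt <- stats::median(peaks$retention_time[peaks$compound == cmpd])
    # a sample not listing the compound counts as a non-detection
    freq <- sum(fl$peak_area > thr) / n_floral
    # means over all samples of the type; absent rows count as zero area
    fl_mean <- if (nrow(fl)) sum(fl$peak_area) / n_floral else 0
    am_mean <- if (nrow(am)) sum(am$peak_area) / n_ambient else 0
    data.frame(
      compound = cmpd, median_rt = med_rt, detection_freq = freq,
      floral_mean = fl_mean, ambient_mean = am_mean,
      pass_rt = med_rt >= config$rt_min & med_rt <= config$rt_max,
      pass_freq = freq >= config$min_freq,
      pass_ratio = fl_mean > config$ambient_ratio * am_mean,
      pass_contaminant = !cmpd %in% config$contaminants,
      stringsAsFactors = FALSE
    )
  }))
  audit$retained <- audit$pass_rt & audit$pass_freq & audit$pass_ratio &
    audit$pass_contaminant
  rownames(audit) <- NULL
  list(retained = audit$compound[audit$retained], audit = audit)
}

#' Fit calibration curves from a dilution series
#'
#' Least squares of peak area on dosage, forced through the origin (zero
#' dosage must give zero area). Detector noise on a dilution series is
#' close to a constant coefficient of variation, so the default weights
#' are 1/dosage^2, which keeps the slope standard error calibrated;
#' `weighting = "uniform"` gives plain OLS. Fit quality is the uncentred
#' R-squared, `1 - RSS / sum(area^2)`.
#'
#' @param series data.frame with columns `standard`, `dosage_ng`,
#'   `peak_area`.
#' @param weighting `"constant_cv"` (weights 1/dosage^2, default) or
#'   `"uniform"`.
#' @return data.frame, one row per standard: `standard`, `slope`
#'   (area per ng), `slope_se`, `n_points`, `r_squared`.
#' @export
fit_calibration <- function(series,
                            weighting = c("constant_cv", "uniform")) {
  weighting <- match.arg(weighting)
  need <- c("standard", "dosage_ng", "peak_area")
  miss <- setdiff(need, names(series))
  if (length(miss)) stop("dilution series lacks column(s): ",
                         paste(miss, collapse = ", "))
  out <- do.call(rbind, lapply(split(series, series$standard), function(d) {
    if (length(unique(d$dosage_ng)) < 2) {
      stop("standard '", d$standard[1],
           "': need >= 2 distinct dosages to fit a line")
    }
    wts <- if (weighting == "constant_cv") 1 / d$dosage_ng^2 else
      rep(1, nrow(d))
    fit <- stats::lm(peak_area ~ 0 + dosage_ng, data = d, weights = wts)
    slope <- unname(stats::coef(fit))
    if (!is.finite(slope) || slope <= 0) {
      stop("standard '", d$standard[1], "': non-positive fitted slope (",
           format(slope), "), curve unusable")
    }
    rss <- sum(stats::resid(fit)^2)
    # suppressWarnings: summary.lm complains on exact (noise-free) fits
    data.frame(standard = d$standard[1], slope = slope,
               slope_se = suppressWarnings(
                 summary(fit)$coefficients[1, 2]),
               n_points = nrow(d),
               r_squared = 1 - rss / sum(d$peak_area^2),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Convert peak areas to emission rates
#'
#' `rate = (area / slope) / duration_h`, in ng flower^-1 h^-1, using the
#' calibration slope of the standard mapped to each compound. The default
#' duration is 0.25 h (15 min of headspace sampling).
#'
#' @param peaks floral peak table (long format).
#' @param curves output of [fit_calibration()].
#' @param standard_map named character vector, compound -> standard.
#' @param duration_h sampling duration in hours.
#' @return `peaks` restricted to mapped compounds, with an added
#'   `emission_rate` column.
#' @export
quantify_samples <- function(peaks, curves, standard_map,
                             duration_h = 0.25) {
  stopifnot(duration_h > 0)
  compounds <- unique(peaks$compound)
  orphans <- setdiff(compounds, names(standard_map))
  std_missing <- setdiff(unname(standard_map[compounds]), curves$standard)
  if (length(orphans) || length(std_missing)) {
    stop("cannot quantify: ",
         if (length(orphans)) paste0("compound(s) without a standard: ",
                                     paste(orphans, collapse = ", ")),
         if (length(orphans) && length(std_missing)) "; ",
         if (length(std_missing)) paste0("standard(s) without a curve: ",
                                         paste(std_missing, collapse = ", ")))
  }
  slopes <- stats::setNames(curves$slope, curves$standard)
  out <- peaks
  out$emission_rate <- out$peak_area /
    slopes[standard_map[out$compound]] / duration_h
  out
}

#' Average repeated samples into a plant x compound emission matrix
#'
#' Arithmetic mean of each plant's sample-level emission rates, one row
#' per plant. Averaging precedes any transformation.
#'
#' @param samples quantified floral peak table (output of
#'   [quantify_samples()]), with `plant_id`, `compound`, `emission_rate`.
#' @return numeric matrix, plants x compounds, with attribute
#'   `scale = "rate"`.
#' @export
plant_means <- function(samples) {
  stopifnot(all(c("plant_id", "compound", "emission_rate") %in%
                  names(samples)))
  if (anyNA(samples$plant_id)) stop("samples contain rows without plant_id")
  agg <- tapply(samples$emission_rate,
                list(samples$plant_id, samples$compound), mean)
  m <- as.matrix(agg)
  m[is.na(m)] <- 0
  attr(m, "scale") <- "rate"
  m
}

#' Square-root transform an emission matrix
#'
#' Elementwise square root, applied after plant averaging (the order
#' matters: mean-then-sqrt differs from sqrt-then-mean). The result is
#' flagged with `attr(, "scale") = "sqrt"` so downstream stages know the
#' scale.
#'
#' @param matrix nonnegative emission matrix.
#' @return transformed matrix.
#' @export
transform_sqrt <- function(matrix) {
  if (any(matrix < 0)) stop("negative emission rates cannot be sqrt-transformed")
  out <- sqrt(matrix)
  attr(out, "scale") <- "sqrt"
  out
}

#' Total emissions per compound class
#'
#' Sums untransformed emission rates into the four biosynthetic classes
#' (monoterpenes, sesquiterpenes, benzenoids, aliphatics) plus a grand
#' total. Compounds with a class outside the four are summed into an
#' `other` column (reported separately, included in the grand total).
#'
#' @param matrix plant x compound emission matrix on the rate scale.
#' @param catalog data.frame with `compound` and `class`.
#' @return matrix plants x (classes, other if present, total).
#' @export
class_totals <- function(matrix, catalog = compound_catalog()) {
  if (identical(attr(matrix, "scale"), "sqrt")) {
    stop("class totals must be computed on untransformed rates")
  }
  classes <- c("monoterpene", "sesquiterpene", "benzenoid", "aliphatic")
  map <- stats::setNames(catalog$class, catalog$compound)
  unknown <- setdiff(colnames(matrix), names(map))
  if (length(unknown)) stop("compound(s) without a class: ",
                            paste(unknown, collapse = ", "))
  cls <- map[colnames(matrix)]
  extra <- setdiff(unique(cls), classes)
  out <- vapply(classes, function(cl) {
    cols <- which(cls == cl)
    if (length(cols)) rowSums(matrix[, cols, drop = FALSE]) else
      rep(0, nrow(matrix))
  }, numeric(nrow(matrix)))
  if (nrow(matrix) == 1) out <- matrix(out, nrow = 1,
                                       dimnames = list(NULL, classes))
  if (length(extra)) {
    other <- rowSums(matrix[, cls %in% extra, drop = FALSE])
    out <- cbind(out, other = other)
  }
  out <- cbind(out, total = rowSums(out))
  rownames(out) <- rownames(matrix)
  out
}

#' Run the full volatile pipeline on a simulated or imported study
#'
#' Filter, calibrate, quantify, average, and total: peak table in,
#' emission matrix and class totals out.
#'
#' @param peak_table long peak table with floral and ambient rows.
#' @param dilution_series calibration dilution series.
#' @param config [filter_config()].
#' @param standard_map compound -> standard map.
#' @param duration_h sampling duration (h).
#' @return list `retained`, `audit`, `curves`, `emissions` (plant matrix),
#'   `class_totals`.
#' @export
volatile_pipeline <- function(peak_table, dilution_series,
                              config = filter_config(),
                              standard_map = default_standard_map(),
                              duration_h = 0.25) {
  flt <- filter_compounds(peak_table, config)
  curves <- fit_calibration(dilution_series)
  floral <- peak_table[peak_table$sample_type == "floral" &
                         peak_table$compound %in% flt$retained, ]
  quant <- quantify_samples(floral, curves, standard_map, duration_h)
  emissions <- plant_means(quant)
  list(retained = flt$retained, audit = flt$audit, curves = curves,
       emissions = emissions,
       class_totals = class_totals(emissions,
                                   catalog_subset(colnames(emissions))))
}

# catalog restricted to observed compounds; unknown compounds raise in
# class_totals
catalog_subset <- function(compounds, catalog = compound_catalog()) {
  catalog[catalog$compound %in% compounds, , drop = FALSE]
}
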