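# Shared fixtures, built in code at test time.

# Toy 6-compound peak table exercising all four filter rules:
#   rt_fail      median RT 1.5 (outside 2-17)
#   rare         detected in 1/20 floral samples (5% < 10%)
#   ambient_high floral mean exactly 3.9x ambient mean (ratio rule fails)
#   contam       clean numbers but on the contaminant list
#   clean_a      passes everything
#   clean_b      passes everything (ambient mean 0)
toy_peak_table <- function() {
  floral_ids <- sprintf("F%02d", 1:20)
  amb_ids <- c("A1", "A2")
  mk <- function(sample_id, type, compound, rt, area) {
    data.frame(sample_id = sample_id,
               plant_id = if (type == "floral") sub("F", "plant", sample_id)
                          else NA_character_,
               sample_type = type, compound = compound,
               retention_time = rt, peak_area = area,
               stringsAsFactors = FALSE)
  }
  rows <- list()
  add <- function(compound, rt, floral_areas, amb_areas) {
    rows[[length(rows) + 1]] <<- mk(floral_ids, "floral", compound, rt,
                                    floral_areas)
    rows[[length(rows) + 1]] <<- mk(amb_ids, "ambient", compound, rt,
                                    amb_areas)
  }
  add("rt_fail", 1.5, rep(100, 20), c(1, 1))
  add("rare", 5, c(100, rep(0, 19)), c(0, 0))
  # floral mean 39, ambient mean 10 -> ratio 3.9 < 4
  add("ambient_high", 6, rep(39, 20), c(10, 10))
  add("contam", 7, rep(100, 20), c(1, 1))
  add("clean_a", 8, rep(50, 20), c(1, 1))
  add("clean_b", 9, rep(50, 20), c(0, 0))
  do.call(rbind, rows)
}

# The worked fitness record: 10 flowers, intact fruits with seeds
# (5, 6, 7), 1 dehisced, 1 fly-eaten, 4 aborted, 1 collected early.
toy_fitness_record <- function() {
  data.frame(plant_id = "toy1", flowers_total = 10L, aborted = 4L,
             fruits_intact = 3L, seeds_counted = 18L, fruits_dehisced = 1L,
             fruits_fly = 1L, fruits_caterpillar = 0L,
             flowers_collected_early = 1L, eggs_total = 6L,
             flowers_surveyed = 12L, stringsAsFactors = FALSE)
}

# The seeds-initiated example: 9 flowers at risk (10 incl. one early),
# 5 nonaborted fruits of which 1 eaten; noneaten seed counts (5, 6, 7, 6).
toy_seeds_initiated_record <- function() {
  data.frame(plant_id = "toy2", flowers_total = 10L, aborted = 4L,
             fruits_intact = 4L, seeds_counted = 24L, fruits_dehisced = 0L,
             fruits_fly = 1L, fruits_caterpillar = 0L,
             flowers_collected_early = 1L, eggs_total = 0L,
             flowers_surveyed = 10L, stringsAsFactors = FALSE)
}

# One moderate-size study cached across test files (null effects).
cached_study <- local({
  st <- NULL
  function() {
    if (is.null(st)) st <<- simulate_study(seed = 20260912)
    st
  }
})
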