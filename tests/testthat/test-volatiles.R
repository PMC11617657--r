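test_that("filter_compounds applies all four rules on the toy table", {
  pk <- toy_peak_table()
  res <- filter_compounds(pk, filter_config(contaminants = "contam"))
  expect_setequal(res$retained, c("clean_a", "clean_b"))
  a <- res$audit
  expect_equal(nrow(a), 6)             # audit completeness
  expect_setequal(a$compound, unique(pk$compound))
  expect_false(a$pass_rt[a$compound == "rt_fail"])
  expect_false(a$pass_freq[a$compound == "rare"])
  expect_false(a$pass_ratio[a$compound == "ambient_high"])
  expect_false(a$pass_contaminant[a$compound == "contam"])
  # every failed compound fails for exactly the expected single reason
  failed <- a[!a$retained, ]
  expect_equal(rowSums(!failed[, c("pass_rt", "pass_freq", "pass_ratio",
                                   "pass_contaminant")]),
               setNames(rep(1, 4), NULL), ignore_attr = TRUE)
})

test_that("ambient-ratio boundary is strict and division-free", {
  pk <- toy_peak_table()
  # floral mean exactly 4.0x ambient mean -> excluded
  pk$peak_area[pk$compound == "ambient_high" &
                 pk$sample_type == "floral"] <- 40
  res <- filter_compounds(pk, filter_config())
  expect_false("ambient_high" %in% res$retained)
  # ambient mean 0, floral mean > 0 -> passes (clean_b in the fixture)
  expect_true("clean_b" %in% res$retained)
  # nudge just above the boundary -> retained
  pk$peak_area[pk$compound == "ambient_high" &
                 pk$sample_type == "floral"] <- 40.01
  expect_true("ambient_high" %in% filter_compounds(pk)$retained)
})

test_that("filtering refuses to run without ambient controls and is idempotent", {
  pk <- toy_peak_table()
  expect_error(filter_compounds(pk[pk$sample_type == "floral", ]),
               "ambient")
  res1 <- filter_compounds(pk, filter_config(contaminants = "contam"))
  pk2 <- pk[pk$compound %in% res1$retained |
              pk$sample_type == "ambient", ]
  res2 <- filter_compounds(pk2, filter_config(contaminants = "contam"))
  expect_setequal(res2$retained, res1$retained)
})

test_that("end-to-end filter on generator output recovers the clean set", {
  truth <- true_params(contaminants = c("benzaldehyde", "nonanal"))
  st <- simulate_study(seed = 313, truth = truth)
  res <- filter_compounds(st$peak_table,
                          filter_config(contaminants = truth$contaminants))
  clean <- setdiff(compound_catalog()$compound, truth$contaminants)
  expect_setequal(res$retained, clean)
})

test_that("calibration fits exact lines and rejects degenerate input", {
  s <- data.frame(standard = "std", dosage_ng = c(1, 2),
                  peak_area = c(1000, 2000))
  fit <- fit_calibration(s)
  expect_equal(fit$slope, 1000)
  expect_equal(fit$r_squared, 1)
  one_dose <- data.frame(standard = "std", dosage_ng = c(1, 1),
                         peak_area = c(900, 1100))
  expect_error(fit_calibration(one_dose), "distinct dosages")
  # all-zero areas: a slope of zero is unusable for quantitation
  dead <- data.frame(standard = "std", dosage_ng = c(1, 2),
                     peak_area = c(0, 0))
  expect_error(fit_calibration(dead), "slope")
})

test_that("quantitation arithmetic, linearity, and orphan errors", {
  curves <- data.frame(standard = "stdA", slope = 1000, slope_se = 1,
                       n_points = 10, r_squared = 0.99)
  pk <- data.frame(sample_id = "s1", plant_id = "p1",
                   sample_type = "floral", compound = "x",
                   retention_time = 5, peak_area = 5000,
                   stringsAsFactors = FALSE)
  q <- quantify_samples(pk, curves, c(x = "stdA"), duration_h = 0.25)
  expect_equal(q$emission_rate, 20)      # 5000/1000/0.25
  # area 0 -> rate 0; doubling duration halves the rate
  pk$peak_area <- 0
  expect_equal(quantify_samples(pk, curves, c(x = "stdA"))$emission_rate, 0)
  pk$peak_area <- 5000
  expect_equal(quantify_samples(pk, curves, c(x = "stdA"),
                                duration_h = 0.5)$emission_rate, 10)
  # scaling all areas by c scales all rates by c
  pk10 <- pk; pk10$peak_area <- pk$peak_area * 10
  expect_equal(quantify_samples(pk10, curves, c(x = "stdA"))$emission_rate,
               10 * quantify_samples(pk, curves, c(x = "stdA"))$emission_rate)
  expect_error(quantify_samples(pk, curves, c(y = "stdA")), "x")
})

test_that("plant averaging and the sqrt transform order", {
  s <- data.frame(plant_id = c("p1", "p1", "p2"),
                  compound = "x", emission_rate = c(10, 20, 7))
  m <- plant_means(s)
  expect_equal(m["p1", "x"], 15)
  expect_equal(m["p2", "x"], 7)          # single-sample identity
  # mean-then-sqrt != sqrt-then-mean for (0, 4): sqrt(2) vs 1
  s2 <- data.frame(plant_id = "p", compound = "x",
                   emission_rate = c(0, 4))
  expect_equal(unname(transform_sqrt(plant_means(s2))[1, 1]), sqrt(2))
  expect_equal(mean(sqrt(s2$emission_rate)), 1)
  expect_equal(attr(transform_sqrt(m), "scale"), "sqrt")
  expect_error(transform_sqrt(matrix(-1)), "negative")
  # generator default: matrix rows = distinct plants, not samples
  st <- cached_study()
  vp <- volatile_pipeline(st$peak_table, st$dilution_series)
  expect_equal(nrow(vp$emissions), length(unique(st$trait_table$plant_id)))
  expect_gt(nrow(st$peak_table[st$peak_table$sample_type == "floral", ]) /
              length(compound_catalog()$compound), nrow(vp$emissions))
})

test_that("class totals sum correctly and reject unknowns", {
  cat_ <- data.frame(compound = c("a", "b", "c", "d"),
                     class = c("monoterpene", "sesquiterpene", "benzenoid",
                               "aliphatic"))
  m <- matrix(c(1, 2, 3, 4), 1, dimnames = list("p1", c("a", "b", "c", "d")))
  ct <- class_totals(m, cat_)
  expect_equal(unname(ct[1, c("monoterpene", "sesquiterpene", "benzenoid",
                              "aliphatic", "total")]),
               c(1, 2, 3, 4, 10))
  # empty class -> 0
  ct2 <- class_totals(m[, 1:3, drop = FALSE], cat_)
  expect_equal(unname(ct2[1, "aliphatic"]), 0)
  # invariant to compound ordering
  perm <- c("d", "b", "a", "c")
  expect_equal(class_totals(m[, perm, drop = FALSE], cat_), ct)
  expect_error(class_totals(matrix(1, 1, 1,
                                   dimnames = list("p", "zz")), cat_),
               "zz")
  expect_error(class_totals(transform_sqrt(m), cat_), "untransformed")
})

test_that("quantified rates recover the generator's true emissions", {
  st <- cached_study()
  vp <- volatile_pipeline(st$peak_table, st$dilution_series)
  common <- intersect(colnames(vp$emissions), colnames(st$emissions))
  plants <- intersect(rownames(vp$emissions), rownames(st$emissions))
  est <- vp$emissions[plants, common]
  tru <- st$emissions[plants, common]
  # sample noise (lognormal sd 0.3) and calibration noise remain; the
  # cross-plant correlation between estimated and true rates is high
  cors <- vapply(common, function(cm) cor(est[, cm], tru[, cm]), 0)
  expect_gt(median(cors), 0.85)
})
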