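test_that("ppv and sensitivity handle defined and undefined cases", {
  expect_equal(ppv(confusion_counts(7, 7, 0)), 0.5)
  expect_equal(round_half_up(ppv(confusion_counts(48, 26, 0)), 2), 0.65)
  expect_true(is.na(ppv(confusion_counts(0, 0, 5))))
  expect_equal(sensitivity(confusion_counts(35, 0, 15)), 0.7)
  expect_equal(sensitivity(confusion_counts(90, 0, 46)), 90 / 136)
  expect_true(is.na(sensitivity(confusion_counts(0, 3, 0))))
  # vectorized over a per-site data frame
  df <- data.frame(tp = c(7, 48, 35), fp = c(7, 26, 28), fn = c(7, 24, 15))
  expect_equal(round_half_up(ppv(df), 2), c(0.50, 0.65, 0.56))
  expect_equal(round_half_up(sensitivity(df), 2), c(0.50, 0.67, 0.70))
})

test_that("macro average is the per-site mean with NA handling", {
  expect_equal(round_half_up(macro_average(c(0.50, 0.65, 0.56)), 2), 0.57)
  expect_equal(macro_average(0.73), 0.73)
  expect_equal(round_half_up(macro_average(c(1.00, 0.92, 0.92)), 2), 0.95)
  expect_warning(m <- macro_average(c(0.5, NA, 0.7)), "excluded")
  expect_equal(m, 0.6)
  expect_true(is.na(macro_average(c(NA_real_, NA_real_))))
  expect_true(is.na(macro_average(numeric(0))))
  # the pooled-count metric is a different quantity than the macro mean
  pooled <- sensitivity(confusion_counts(90, 0, 46))
  expect_false(round_half_up(pooled, 2) ==
                 round_half_up(macro_average(c(0.50, 2 / 3, 0.70)), 2))
})

test_that("road clipping matches analytic values on a toy grid", {
  cfg <- synth_config(n_town_centers = 1, grid_lines = 3,
                      grid_spacing = 1000, n_rural_roads = 0, seed = 3)
  net <- generate_road_network(cfg)
  ctr <- attr(net, "town_centers")[1, ]
  pts <- tibble::tibble(id = c("Z1", "Z2"), x = ctr[1], y = ctr[2])
  # one 500 m disc at the grid centre: the two centre lines cross it along
  # a 1000 m diameter each, the offset lines at 1000 m miss it
  z <- build_zones(list(c("Z1", "Z2")), pts, radius = 500)
  expect_equal(road_length_in_zones(net, z), 2000)
  # a disc covering the whole grid captures the full network
  z_all <- build_zones(list(c("Z1", "Z2")), pts, radius = 5000)
  expect_equal(road_length_in_zones(z = z_all, network = net),
               net$total_length)
  # no zones -> nothing to drive
  expect_equal(road_length_in_zones(net, build_zones(list(), pts, 200)), 0)
})

test_that("cost report reproduces the reference mileage arithmetic", {
  ref <- reference_cost_inputs()
  rep1 <- cost_report(ref$traditional, ref$modified)
  tot <- rep1$totals
  trad <- tot[tot$scenario == "traditional", ]
  expect_equal(trad$driven_miles, 718)
  expect_equal(trad$to_from_miles, 792)
  expect_equal(trad$total_miles, 1510)
  expect_equal(round_half_up(trad$mileage_cost), 406)
  sv <- rep1$savings
  expect_equal(round_half_up(sv$pct[sv$metric == "road_miles"]), 88)
  expect_equal(round_half_up(sv$pct[sv$metric == "trips"]), 50)
  # savings% = 1 - modified/traditional row by row
  expect_equal(sv$pct, 100 * (1 - sv$modified / sv$traditional))
  # cost linearity: doubling the rate doubles dollars, leaves savings% alone
  rep2 <- cost_report(ref$traditional, ref$modified, rate_per_mile = 1.13)
  expect_equal(rep2$totals$mileage_cost, 2 * rep1$totals$mileage_cost)
  expect_equal(rep2$savings$pct, rep1$savings$pct)
  # mismatched sites are rejected
  expect_error(cost_report(ref$traditional, ref$modified[1:2, ]),
               "same sites")
})
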