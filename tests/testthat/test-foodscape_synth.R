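test_that("road network grid length is analytic and re-summable", {
  cfg <- synth_config(n_town_centers = 1, grid_lines = 3,
                      grid_spacing = 1000, n_rural_roads = 0, seed = 7)
  net <- generate_road_network(cfg)
  # 3 horizontal + 3 vertical streets, each 2000 m
  expect_equal(net$total_length, 12000)
  expect_length(net$segments, 6L)
  # total equals independent re-summation of vertex-to-vertex distances
  resum <- sum(vapply(net$segments, function(m) {
    sum(sqrt(rowSums(diff(m)^2)))
  }, numeric(1)))
  expect_equal(net$total_length, resum)
  # with rural roads, the grid-only network is a strict subset
  cfg2 <- synth_config(n_town_centers = 1, grid_lines = 3,
                       grid_spacing = 1000, n_rural_roads = 3, seed = 7)
  expect_gt(generate_road_network(cfg2)$total_length, 12000)
  expect_error(generate_road_network(synth_config(n_town_centers = 0)),
               "at least one town centre")
})

test_that("identical config and seed reproduce identical sites", {
  cfg <- small_synth_config(seed = 123)
  b1 <- generate_site(cfg, "S1")
  b2 <- generate_site(cfg, "S1")
  expect_identical(b1$census, b2$census)
  expect_identical(b1$listing, b2$listing)
  expect_identical(b1$roads$segments, b2$roads$segments)
  # a different seed changes coordinates
  b3 <- generate_site(small_synth_config(seed = 124), "S1")
  expect_false(identical(b1$census$x, b3$census$x))
})

test_that("clustered store spread matches the configured dispersion", {
  cfg <- synth_config(n_town_centers = 1, n_clustered_stores = 100,
                      n_isolated_stores = 0, ineligible_count = 0,
                      cluster_dispersion = 100, seed = 11)
  roads <- generate_road_network(cfg)
  census <- generate_census(cfg, roads)
  ctr <- attr(roads, "town_centers")
  d <- sqrt((census$x - ctr[1, 1])^2 + (census$y - ctr[1, 2])^2)
  # per-axis Gaussian sd 100 => distances are Rayleigh(100)
  expected_mean <- 100 * sqrt(pi / 2)
  se <- 100 * sqrt((4 - pi) / 2) / sqrt(100)
  expect_lt(abs(mean(d) - expected_mean), 3 * se)
})

test_that("census/listing conservation and degenerate configs hold", {
  cfg <- small_synth_config(seed = 5)
  b <- generate_site(cfg, "S1")
  eligible <- b$census[b$census$eligible, ]
  open_records <- sum(b$listing$truth_status == "open")
  omitted <- sum(is.na(eligible$listed_id))
  expect_equal(nrow(eligible), open_records + omitted)
  # zero stores => empty census
  cfg0 <- synth_config(n_clustered_stores = 0, n_isolated_stores = 0,
                       ineligible_count = 0, phantom_in_zone = 0,
                       phantom_out_zone = 0, seed = 5)
  census0 <- generate_census(cfg0, generate_road_network(cfg0))
  expect_equal(nrow(census0), 0L)
  # no errors, no omission => listing is a jittered bijection of the census
  cfg1 <- synth_config(omission_prob = 0, phantom_in_zone = 0,
                       phantom_out_zone = 0, ineligible_count = 0,
                       name_noise_prob = 0, seed = 5)
  b1 <- generate_site(cfg1, "S1")
  expect_equal(nrow(b1$listing), sum(b1$census$eligible))
  expect_setequal(b1$listing$census_id, b1$census$id[b1$census$eligible])
  jit <- sqrt((b1$listing$x - b1$census$x[match(b1$listing$census_id,
                                                b1$census$id)])^2 +
                (b1$listing$y - b1$census$y[match(b1$listing$census_id,
                                                  b1$census$id)])^2)
  expect_true(all(jit < 6 * cfg1$jitter_sd))
})

test_that("out-of-zone phantoms stay mutually and globally isolated", {
  for (seed in c(3, 17, 99)) {
    cfg <- synth_config(phantom_out_zone = 3, seed = seed)
    b <- generate_site(cfg, "S1")
    # the generator places out-of-zone phantoms last
    out_ph <- utils::tail(b$listing, 3)
    pts <- rbind(cbind(out_ph$x, out_ph$y))
    others <- b$listing[seq_len(nrow(b$listing) - 3), ]
    for (k in seq_len(nrow(pts))) {
      d_others <- sqrt((others$x - pts[k, 1])^2 + (others$y - pts[k, 2])^2)
      # exhaustive scan: farther than twice the default buffer radius from
      # every other listed record (so they can never join a cluster)
      expect_true(all(d_others > 2 * 200))
    }
  }
})

test_that("impossible isolation constraints raise a placement error", {
  cfg <- synth_config(n_town_centers = 1, n_isolated_stores = 40,
                      isolation_min_separation = 9000,
                      max_placement_retries = 50, seed = 2)
  roads <- generate_road_network(cfg)
  expect_error(generate_census(cfg, roads), "separation constraints")
})

test_that("fixture strata equal the values forced by the reference counts", {
  ref <- reference_confusion_counts()
  get <- function(lst, s, col) ref[[col]][ref$list == lst & ref$site == s]
  for (s in c("A", "B", "C")) {
    # re-derive each stratum from the confusion-count identities
    loo <- get("assume_open", s, "tp") - get("assume_closed", s, "tp")
    no <- get("assume_open", s, "fn")
    bo <- get("assume_open", s, "fp")
    loi <- get("commercial", s, "tp") - loo
    bi <- get("commercial", s, "fp") - bo
    ni <- get("commercial", s, "fn") - no
    b <- make_reference_fixture(s)
    zones <- build_zones(link_components(b$listing, 400), b$listing, 200)
    lst_in <- point_in_zones(b$listing$x, b$listing$y, zones)
    cen_in <- point_in_zones(b$census$x, b$census$y, zones)
    open_rec <- b$listing$truth_status == "open"
    new_store <- is.na(b$census$listed_id)
    expect_equal(sum(open_rec & lst_in), loi)
    expect_equal(sum(open_rec & !lst_in), loo)
    expect_equal(sum(!open_rec & lst_in), bi)
    expect_equal(sum(!open_rec & !lst_in), bo)
    expect_equal(sum(new_store & cen_in), ni)
    expect_equal(sum(new_store & !cen_in), no)
  }
})
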