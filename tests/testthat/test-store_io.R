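test_that("a written site bundle round-trips losslessly", {
  b <- make_reference_fixture("A")
  dir <- withr::local_tempdir()
  write_site_bundle(b, dir)
  b2 <- read_site_bundle(file.path(dir, "census.csv"),
                         file.path(dir, "listing.csv"),
                         file.path(dir, "roads.geojson"), site_id = "A")
  expect_equal(as.data.frame(b2$census), as.data.frame(b$census))
  expect_equal(as.data.frame(b2$listing), as.data.frame(b$listing))
  expect_equal(b2$roads$total_length, b$roads$total_length)
  expect_equal(b2$roads$segments, b$roads$segments)
  # and a noisy synthetic site too (jittered doubles survive the round trip)
  s <- generate_site(small_synth_config(6), "S1")
  dir2 <- withr::local_tempdir()
  write_site_bundle(s, dir2)
  s2 <- read_site_bundle(file.path(dir2, "census.csv"),
                         file.path(dir2, "listing.csv"),
                         file.path(dir2, "roads.geojson"), site_id = "S1")
  expect_equal(as.data.frame(s2$census), as.data.frame(s$census))
  expect_equal(as.data.frame(s2$listing), as.data.frame(s$listing))
})

test_that("schema violations are reported with row and field", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "census.csv")
  writeLines(c("id,name,category,x,y,eligible",
               "S1,Store One,grocery,10,20,TRUE",
               "S1,Store Two,gas,30,40,TRUE"), p)
  req <- c("id", "name", "category", "x", "y", "eligible")
  expect_error(groundtruthr:::read_csv_checked(p, req), "duplicate id 'S1'")
  writeLines(c("id,name,category,x,y,eligible",
               "S1,Store One,grocery,10,north,TRUE"), p)
  expect_error(groundtruthr:::read_csv_checked(p, req), "non-numeric value 'north'")
  writeLines(c("id,name,x,y", "S1,Store One,10,20"), p)
  expect_error(groundtruthr:::read_csv_checked(p, req), "missing column")
})

test_that("GeoJSON roads parse with analytic segment lengths", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "roads.geojson")
  writeLines(paste0(
    '{"type":"FeatureCollection","features":[{"type":"Feature",',
    '"properties":{},"geometry":{"type":"LineString",',
    '"coordinates":[[0,0],[30,40]]}}]}'), p)
  net <- read_roads_geojson(p)
  expect_length(net$segments, 1L)
  expect_equal(net$total_length, 50)
  writeLines('{"type":"FeatureCollection","features":[]}', p)
  expect_equal(read_roads_geojson(p)$total_length, 0)
})

test_that("zone GeoJSON export carries members and polygon rings", {
  b <- make_reference_fixture("A")
  zones <- build_zones(link_components(b$listing, 400), b$listing, 200)
  dir <- withr::local_tempdir()
  p <- file.path(dir, "zones.geojson")
  write_zones_geojson(zones, p)
  gj <- jsonlite::read_json(p)
  expect_length(gj$features, 1L)
  f <- gj$features[[1]]
  expect_setequal(unlist(f$properties$member_ids),
                  zones$zones[[1]]$member_ids)
  ring <- f$geometry$coordinates[[1]]
  expect_gt(length(ring), 64)
  first <- unlist(ring[[1]]); last <- unlist(ring[[length(ring)]])
  expect_equal(first, last)
})

test_that("report tables render deterministically with NA for missing cells", {
  cc <- reference_confusion_counts()
  t1 <- render_accuracy_table(cc)
  expect_equal(t1$commercial_total,
               c("151", "90", "61", "46", "0.57", "0.62"))
  expect_equal(t1$assume_closed_total,
               c("126", "126", "0", "10", "1.00", "0.95"))
  # byte-identical re-render
  dir <- withr::local_tempdir()
  write_report_tables(list(accuracy = cc), file.path(dir, "r1"))
  write_report_tables(list(accuracy = cc), file.path(dir, "r2"))
  expect_identical(readLines(file.path(dir, "r1", "accuracy_table.csv")),
                   readLines(file.path(dir, "r2", "accuracy_table.csv")))
  # a site absent from one list renders as NA cells, never zeros
  partial <- cc[!(cc$site == "C" & cc$list == "commercial"), ]
  tp <- render_accuracy_table(partial)
  expect_equal(unique(tp$commercial_C), "NA")
  expect_error(write_report_tables(list(), dir), "no results")
})
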