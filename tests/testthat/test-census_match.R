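test_that("fuzzy name tiers reproduce the field matching rules", {
  census <- tibble::tibble(
    id = c("C1", "C2", "C3"),
    name = c("Mizuki Fusion", "Midwest Pizza Group", "Corner Gas"),
    category = c("restaurant", "restaurant", "gas"),
    x = c(0, 500, 1000), y = c(0, 0, 0), eligible = TRUE
  )
  listing <- tibble::tibble(
    id = c("L1", "L2", "L3"),
    name = c("Zhang Ke Mizuki Fusion", "Papa Murphy's", "Corner Gas"),
    category = c("restaurant", "restaurant", "gas"),
    x = c(10, 510, 1000), y = c(0, 0, 0)
  )
  cls <- match_records(listing, census, match_policy("fuzzy"))
  recs <- cls$records
  expect_equal(recs$label, rep("open_found", 3))
  # owner-name prefix: token-set similarity 1 => close, not exact
  expect_equal(recs$tier[recs$id == "L1"], "close")
  # franchise listed under its operating company: same category => lenient
  expect_equal(recs$tier[recs$id == "L2"], "lenient")
  # identical name and location => exact
  expect_equal(recs$tier[recs$id == "L3"], "exact")
  # distance gate: beyond max_match_distance nothing matches
  shifted <- dplyr::mutate(listing, x = x + 10)
  cls_far <- match_records(shifted, census,
                           match_policy("fuzzy", max_match_distance = 5))
  expect_equal(cls_far$records$label, rep("not_found", 3))
  expect_error(
    match_records(dplyr::mutate(listing, name = NA_character_), census,
                  match_policy("fuzzy")),
    "requires listing names")
})

test_that("matching is a partial bijection under every policy", {
  for (seed in c(2, 8)) {
    b <- generate_site(small_synth_config(seed), "S1")
    for (mode in c("id", "fuzzy")) {
      cls <- match_records(b$listing, b$census, match_policy(mode))
      matched <- cls$records$matched_census_id
      matched <- matched[!is.na(matched)]
      expect_false(anyDuplicated(matched) > 0)
      expect_false(anyDuplicated(cls$records$id) > 0)
      expect_true(all(matched %in% b$census$id))
    }
  }
})

test_that("id-based classification recovers the generator's hidden labels", {
  for (seed in c(4, 40, 400)) {
    b <- generate_site(small_synth_config(seed), "S1")
    cls <- match_records(b$listing, b$census, match_policy("id"))
    want <- c(open = "open_found", not_found = "not_found",
              ineligible = "ineligible")[b$listing$truth_status]
    expect_equal(cls$records$label, unname(want))
    # confusion counts equal brute-force enumeration over hidden labels
    cc <- confusion_from_classification(cls)
    expect_equal(cc$tp, sum(b$listing$truth_status == "open"))
    expect_equal(cc$fp, sum(b$listing$truth_status != "open"))
    expect_equal(cc$fn, sum(b$census$eligible & is.na(b$census$listed_id)))
  }
})

test_that("tp + fn is invariant to listing errors", {
  base <- list(n_town_centers = 1, n_clustered_stores = 30,
               n_isolated_stores = 2, seed = 77)
  variants <- list(
    c(base, omission_prob = 0.1, phantom_in_zone = 2),
    c(base, omission_prob = 0.6, phantom_in_zone = 20, phantom_out_zone = 3),
    c(base, omission_prob = 0.34, ineligible_count = 5)
  )
  for (v in variants) {
    b <- generate_site(do.call(synth_config, v), "S1")
    cc <- confusion_from_classification(
      match_records(b$listing, b$census, match_policy("id")))
    expect_equal(cc$tp + cc$fn, sum(b$census$eligible))
  }
  # empty listing and census
  empty_cc <- confusion_from_classification(match_records(
    tibble::tibble(id = character(0), name = character(0),
                   category = character(0), x = numeric(0), y = numeric(0)),
    tibble::tibble(id = character(0), name = character(0),
                   category = character(0), x = numeric(0), y = numeric(0),
                   eligible = logical(0), listed_id = character(0)),
    match_policy("id")))
  expect_equal(c(empty_cc$tp, empty_cc$fp, empty_cc$fn), c(0L, 0L, 0L))
})

test_that("a record matched to an ineligible establishment is a false positive", {
  census <- tibble::tibble(
    id = c("C1", "C2"), name = c("Open Market", "Hospital Cafeteria"),
    category = c("grocery", "restaurant"), x = c(0, 200), y = c(0, 0),
    eligible = c(TRUE, FALSE), listed_id = c("L1", "L2")
  )
  listing <- tibble::tibble(
    id = c("L1", "L2"), name = c("Open Market", "Hospital Cafeteria"),
    category = c("grocery", "restaurant"), x = c(0, 200), y = c(0, 0)
  )
  for (mode in c("id", "fuzzy")) {
    cls <- match_records(listing, census, match_policy(mode))
    expect_equal(cls$records$label, c("open_found", "ineligible"))
    cc <- confusion_from_classification(cls)
    expect_equal(c(cc$tp, cc$fp, cc$fn), c(1L, 1L, 0L))
  }
})
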