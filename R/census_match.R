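# Matching commercial listing records against the ground-truthed store
# census, and tallying the resulting confusion counts.

#' Matching policy
#'
#' Controls how listing records are matched to census stores.  In `"id"`
#' mode the generator's `listed_id` linkage is used directly (the oracle
#' setting for synthetic data).  In `"fuzzy"` mode candidate pairs within
#' `max_match_distance` are scored by name-similarity tier: an *exact* match
#' (normalized names equal) beats a *close* match (token-set similarity at
#' least `close_similarity_threshold`), which beats a *lenient* match (same
#' category code within range, capturing pairs like a franchise name listed
#' under its operating company).  Ties break by distance, then by
#' lexicographic record id.
#'
#' @param mode `"id"` or `"fuzzy"`.
#' @param close_similarity_threshold token-set name similarity in `[0, 1]`
#'   required for a close match.
#' @param lenient_requires_same_category must lenient matches share a
#'   category code? (Default `TRUE`.)
#' @param max_match_distance maximum distance (m) between a listing record
#'   and a census store for any match; proxies the field rule that matches
#'   must sit near the same intersection.
#' @return a `match_policy` object.
#' @export
match_policy <- function(mode = c("id", "fuzzy"),
                         close_similarity_threshold = 0.85,
                         lenient_requires_same_category = TRUE,
                         max_match_distance = 150) {
  mode <- match.arg(mode)
  if (!is.numeric(close_similarity_threshold) ||
      close_similarity_threshold < 0 || close_similarity_threshold > 1) {
    stop("close_similarity_threshold must lie in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(max_match_distance) || max_match_distance <= 0) {
    stop("max_match_distance must be positive", call. = FALSE)
  }
  structure(list(mode = mode,
                 close_similarity_threshold = close_similarity_threshold,
                 lenient_requires_same_category =
                   isTRUE(lenient_requires_same_category),
                 max_match_distance = max_match_distance),
            class = "match_policy")
}

#' Normalize a store name for comparison
#'
#' Case-folds, strips punctuation, and collapses whitespace.
#'
#' @param x character vector of names.
#' @return normalized character vector.
#' @export
normalize_name <- function(x) {
  x <- tolower(x)
  x <- gsub("[^a-z0-9 ]+", " ", x)
  x <- gsub("\\s+", " ", x)
  trimws(x)
}

#' Token-set name similarity
#'
#' Similarity in `[0, 1]` between two names after normalization, computed on
#' word-token sets: the shared tokens are compared against each side's
#' shared-plus-remainder string by normalized edit distance, and the best of
#' the three comparisons wins.  A name whose tokens are a subset of the
#' other's scores 1, which is what makes additions like an owner's name
#' prefixed to a store name score as close matches.
#'
#' @param a,b character scalars.
#' @return numeric similarity in `[0, 1]`.
#' @export
name_similarity <- function(a, b) {
  a <- normalize_name(a)
  b <- normalize_name(b)
  if (a == b) {
    return(1)
  }
  ta <- unique(strsplit(a, " ", fixed = TRUE)[[1]])
  tb <- unique(strsplit(b, " ", fixed = TRUE)[[1]])
  inter <- sort(intersect(ta, tb))
  da <- sort(setdiff(ta, tb))
  db <- sort(setdiff(tb, ta))
  s0 <- paste(inter, collapse = " ")
  s1 <- trimws(paste(s0, paste(da, collapse = " ")))
  s2 <- trimws(paste(s0, paste(db, collapse = " ")))
  edit_sim <- function(p, q) {
    if (nchar(p) == 0 && nchar(q) == 0) return(0)
    1 - utils::adist(p, q)[1, 1] / max(nchar(p), nchar(q))
  }
  if (length(inter) > 0) {
    max(edit_sim(s0, s1), edit_sim(s0, s2), edit_sim(s1, s2))
  } else {
    edit_sim(s1, s2)
  }
}

#' Match listing records to the store census and classify them
#'
#' Produces the four-way field classification: each listing record becomes
#' *open_found* (matched an open eligible census store), *ineligible*
#' (matched a census establishment flagged ineligible), or *not_found*; each
#' eligible census store becomes *matched* or *new_store* (open in the field
#' but absent from the list).  Matching is a partial bijection: no store or
#' record is used twice.
#'
#' @param listing listing data frame (`id`, `name`, `category`, `x`, `y`).
#' @param census census data frame (`id`, `name`, `category`, `x`, `y`,
#'   `eligible`, optionally `listed_id`).
#' @param policy a [match_policy()].
#' @return a `classification` object: list with `records` (tibble: `id`,
#'   `label`, `matched_census_id`, `tier`, `distance`) and `stores` (tibble:
#'   `id`, `label`).
#' @export
match_records <- function(listing, census, policy = match_policy()) {
  stopifnot(inherits(policy, "match_policy"))
  lst <- tibble::as_tibble(listing)
  cen <- tibble::as_tibble(census)
  if (!"eligible" %in% names(cen)) cen$eligible <- TRUE

  pairs <- if (policy$mode == "id") {
    if (!"listed_id" %in% names(cen)) {
      stop("id-based matching requires a listed_id column in the census",
           call. = FALSE)
    }
    idx <- match(cen$listed_id, lst$id)
    keep <- !is.na(idx)
    tibble::tibble(
      record_id = as.character(lst$id[idx[keep]]),
      census_id = as.character(cen$id[keep]),
      tier = "exact",
      distance = sqrt((lst$x[idx[keep]] - cen$x[keep])^2 +
                        (lst$y[idx[keep]] - cen$y[keep])^2)
    )
  } else {
    if (!"name" %in% names(lst) || all(is.na(lst$name))) {
      stop("fuzzy matching requires listing names", call. = FALSE)
    }
    fuzzy_candidate_pairs(lst, cen, policy)
  }

  tier_rank <- c(exact = 3, close = 2, lenient = 1)
  if (nrow(pairs) > 0L) {
    pairs <- pairs[order(-tier_rank[pairs$tier], pairs$distance,
                         pairs$record_id, pairs$census_id), , drop = FALSE]
  }
  rec_taken <- character(0)
  cen_taken <- character(0)
  keep <- logical(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    if (!(pairs$record_id[k] %in% rec_taken) &&
        !(pairs$census_id[k] %in% cen_taken)) {
      keep[k] <- TRUE
      rec_taken <- c(rec_taken, pairs$record_id[k])
      cen_taken <- c(cen_taken, pairs$census_id[k])
    }
  }
  pairs <- pairs[keep, , drop = FALSE]

  m <- match(as.character(lst$id), pairs$record_id)
  matched_cid <- pairs$census_id[m]
  matched_elig <- cen$eligible[match(matched_cid, as.character(cen$id))]
  records <- tibble::tibble(
    id = as.character(lst$id),
    label = ifelse(is.na(matched_cid), "not_found",
                   ifelse(matched_elig, "open_found", "ineligible")),
    matched_census_id = matched_cid,
    tier = pairs$tier[m],
    distance = pairs$distance[m]
  )
  stores <- tibble::tibble(
    id = as.character(cen$id),
    label = ifelse(!cen$eligible, "ineligible",
                   ifelse(as.character(cen$id) %in% pairs$census_id,
                          "matched", "new_store"))
  )
  structure(list(records = records, stores = stores, policy = policy),
            class = "classification")
}

# Candidate pairs for fuzzy matching: all record-store pairs within the
# distance gate, scored into tiers.
fuzzy_candidate_pairs <- function(lst, cen, policy) {
  out <- list()
  lnorm <- normalize_name(lst$name)
  cnorm <- normalize_name(cen$name)
  for (i in seq_len(nrow(lst))) {
    d <- sqrt((cen$x - lst$x[i])^2 + (cen$y - lst$y[i])^2)
    cand <- which(d <= policy$max_match_distance)
    for (j in cand) {
      tier <- NA_character_
      if (lnorm[i] == cnorm[j]) {
        tier <- "exact"
      } else if (name_similarity(lst$name[i], cen$name[j]) >=
                 policy$close_similarity_threshold) {
        tier <- "close"
      } else if (!policy$lenient_requires_same_category ||
                 identical(as.character(lst$category[i]),
                           as.character(cen$category[j]))) {
        tier <- "lenient"
      }
      if (!is.na(tier)) {
        out[[length(out) + 1L]] <- tibble::tibble(
          record_id = as.character(lst$id[i]),
          census_id = as.character(cen$id[j]),
          tier = tier, distance = d[j])
      }
    }
  }
  if (length(out) == 0L) {
    tibble::tibble(record_id = character(0), census_id = character(0),
                   tier = character(0), distance = numeric(0))
  } else {
    dplyr::bind_rows(out)
  }
}

#' @export
print.classification <- function(x, ...) {
  cat("<classification>\n")
  print(table(record_label = x$records$label))
  print(table(store_label = x$stores$label))
  invisible(x)
}

#' Confusion counts
#'
#' @param tp,fp,fn non-negative integer counts of true positives (listed
#'   stores verified open), false positives (listed records not found or
#'   ineligible), and false negatives (open stores missing from the list).
#' @return a `confusion_counts` object.
#' @export
confusion_counts <- function(tp, fp, fn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 fn = as.integer(fn)), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP=%d FP=%d FN=%d\n", x$tp, x$fp, x$fn))
  invisible(x)
}

#' Confusion counts from a classification
#'
#' Open/found records are true positives; not-found and ineligible records
#' are false positives; new stores (open eligible census stores absent from
#' the list) are false negatives.
#'
#' @param cls a `classification` from [match_records()].
#' @return a [confusion_counts()] object.
#' @export
confusion_from_classification <- function(cls) {
  stopifnot(inherits(cls, "classification"))
  confusion_counts(
    tp = sum(cls$records$label == "open_found"),
    fp = sum(cls$records$label %in% c("not_found", "ineligible")),
    fn = sum(cls$stores$label == "new_store")
  )
}
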