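test_that("temporal overlap is shared years over minimum duration", {
  expect_equal(temporal_overlap(c(2004, 2014), c(2006, 2018)), 9 / 11)
  expect_equal(temporal_overlap(c(1973, 1998), c(2004, 2019)), 0)
  expect_equal(temporal_overlap(c(2000, 2010), c(2000, 2010)), 1)
  # containment of the shorter period saturates at 1
  expect_equal(temporal_overlap(c(1973, 2020), c(2004, 2010)), 1)
  expect_error(temporal_overlap(c(2010, 2000), c(2000, 2010)), "invalid")
})

test_that("geographic overlap uses country then continent", {
  us1 <- make_record("a", country = "US")
  us2 <- make_record("b", country = "US")
  uk <- make_record("c", country = "GB")
  nl <- make_record("d", country = "NL")
  expect_equal(geographic_overlap(us1, us2), 1)
  expect_equal(geographic_overlap(uk, nl), 0.5)
  expect_equal(geographic_overlap(us1, uk), 0)
  multi <- make_record("e", country = c("GB", "US"))
  expect_equal(geographic_overlap(multi, us1), 1)
  bad <- make_record("f", country = "XX")
  expect_error(geographic_overlap(bad, us1), "XX")
})

test_that("database overlap is set intersection of registries", {
  expect_equal(database_overlap(make_record(db = "NCDB"),
                                make_record(db = "NCDB")), 1)
  expect_equal(database_overlap(make_record(db = "SEER"),
                                make_record(db = "PALGA")), 0)
  expect_equal(database_overlap(make_record(db = c("NCRAS", "SEER")),
                                make_record(db = "SEER")), 1)
})

test_that("criteria similarity is the Jaccard index", {
  expect_equal(criteria_similarity(c("MAC"), c("MAC")), 1)
  expect_equal(criteria_similarity(c("MAC"), c("MAC", "NMAC")), 0.5)
  expect_equal(criteria_similarity(c("GCA"), c("MAC")), 0)
  expect_error(criteria_similarity(character(), c("MAC")), "non-empty")
})

test_that("overlap probability is the weighted component sum", {
  expect_equal(overlap_probability(1, 1, 1, 1), 1)
  expect_equal(overlap_probability(0, 0, 0, 0), 0)
  expect_equal(overlap_probability(1, 1, 1, 0.5), 0.95)
  expect_error(overlap_probability(1.2, 0, 0, 0), "\\[0, 1\\]")
  # configurable weights
  expect_equal(overlap_probability(1, 0, 0, 0, weights = c(1, 0, 0, 0)), 1)
})

test_that("overlap categories follow the closed/open thresholds and are monotone", {
  expect_equal(classify_overlap(0.70), "high")
  expect_equal(classify_overlap(0.30), "medium")
  expect_equal(classify_overlap(0.10), "low")
  expect_equal(classify_overlap(0.0999), "none")
  o <- sort(runif(50))
  ranks <- c(none = 0, low = 1, medium = 2, high = 3)
  expect_true(all(diff(ranks[classify_overlap(o)]) >= 0))
})

test_that("inverse weights follow 1/(1 + row overlap) with unit no-overlap weight", {
  two <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(unname(inverse_weights(two)), c(0.5, 0.5))
  three <- matrix(0.5, 3, 3); diag(three) <- 0
  expect_equal(unname(inverse_weights(three)), rep(0.5, 3))
  expect_equal(unname(inverse_weights(matrix(0, 1, 1))), 1)
  asym <- matrix(c(0, 0.2, 0.4, 0), 2, 2)
  expect_error(inverse_weights(asym), "symmetric")
})

test_that("overlap probability is monotone in each component", {
  set.seed(11)
  for (rep in 1:25) {
    comp <- runif(4)
    base <- overlap_probability(comp[1], comp[2], comp[3], comp[4])
    for (k in 1:4) {
      bumped <- comp
      bumped[k] <- min(1, bumped[k] + runif(1, 0, 1 - bumped[k]))
      expect_gte(overlap_probability(bumped[1], bumped[2], bumped[3], bumped[4]),
                 base - 1e-12)
    }
  }
})

test_that("ecosystem assessment is symmetric, bounded and matches a brute-force oracle", {
  a <- table1_assessment()
  O <- a$o_matrix
  expect_equal(dim(O), c(18, 18))
  expect_equal(O, t(O))
  expect_equal(unname(diag(O)), rep(0, 18))
  expect_true(all(O >= 0 & O <= 1))
  expect_true(all(a$weights > 0 & a$weights <= 1))

  # NCDB pair with full temporal containment and matching criteria half-set
  row <- a$components[a$components$study_a == "byrne2019" &
                      a$components$study_b == "baron2024" |
                      a$components$study_a == "baron2024" &
                      a$components$study_b == "byrne2019", ]
  expect_equal(row$t, 1)
  expect_equal(row$g, 1)
  expect_equal(row$d, 1)
  expect_equal(row$c, 0.5)
  expect_equal(row$o, 0.95)
  expect_equal(row$category, "high")

  # institutional non-US study cannot reach high overlap against SEER studies
  ansari <- a$components[a$components$study_a == "ansari2016" |
                         a$components$study_b == "ansari2016", ]
  expect_true(all(ansari$d == 0))
  expect_true(all(ansari$o < 0.7))

  # brute-force oracle on random small ecosystems
  set.seed(42)
  for (rep in 1:10) {
    K <- sample(2:6, 1)
    recs <- lapply(seq_len(K), function(i) {
      start <- sample(1990:2010, 1)
      make_record(paste0("r", i),
                  db = sample(c("SEER", "NCDB", "PALGA"), 1),
                  country = sample(c("US", "GB", "NL"), 1),
                  start = start, end = start + sample(3:15, 1),
                  hist = setNames(rep(1 / 2, 2),
                                  sample(c("MAC", "NMAC", "GCA", "NET"), 2)))
    })
    asmt <- suppressWarnings(assess_ecosystem(recs))
    cmap <- setNames(lapply(recs, function(r) names(r$histology_props)),
                     vapply(recs, `[[`, "", "study_id"))
    # independent recomputation from first principles
    cmat <- load_continent_map_test()
    expected_w <- vapply(seq_len(K), function(i) {
      tot <- 0
      for (j in seq_len(K)[-i]) {
        pa <- c(recs[[i]]$period_start, recs[[i]]$period_end)
        pb <- c(recs[[j]]$period_start, recs[[j]]$period_end)
        common <- max(0, min(pa[2], pb[2]) - max(pa[1], pb[1]) + 1)
        tt <- common / min(diff(pa) + 1, diff(pb) + 1)
        gg <- if (recs[[i]]$country == recs[[j]]$country) 1
              else if (cmat[recs[[i]]$country] == cmat[recs[[j]]$country]) 0.5
              else 0
        dd <- as.numeric(identical(recs[[i]]$database, recs[[j]]$database))
        A <- cmap[[i]]; B <- cmap[[j]]
        cc <- length(intersect(A, B)) / length(union(A, B))
        tot <- tot + 0.4 * tt + 0.2 * gg + 0.3 * dd + 0.1 * cc
      }
      1 / (1 + tot)
    }, 0)
    expect_equal(unname(asmt$weights), expected_w, tolerance = 1e-12)
  }
})

test_that("study-level category is the maximum pairwise category and labels are kept verbatim", {
  a <- table1_assessment()
  for (id in a$study_ids) {
    sub <- a$components[a$components$study_a == id |
                        a$components$study_b == id, ]
    expect_equal(unname(a$study_category[id]), classify_overlap(max(sub$o)))
  }
  expect_equal(unname(a$printed_labels["marks2023"]), "MEDIUM")
  # the computed category for the same study reflects the printed formula,
  # which puts heavily overlapping NCDB studies at high risk
  expect_equal(unname(a$study_category["marks2023"]), "high")
})

test_that("missing criteria fall back to histology sets with a warning", {
  recs <- list(make_record("a"), make_record("b", db = "NCDB"))
  w1 <- capture_warnings(assess_ecosystem(recs))
  expect_match(w1, "histology-subtype", all = FALSE)
  no_hist <- list(make_record("a"),
                  study_record("bare", "NCDB", "US", 2000, 2005, 10))
  w2 <- capture_warnings(assess_ecosystem(no_hist))
  expect_match(w2, "all-subtype", all = FALSE)
})

test_that("overlap report files are written", {
  a <- table1_assessment()
  dir <- tempfile()
  paths <- write_overlap_report(a, dir)
  expect_true(all(file.exists(paths)))
  rep <- read.csv(paths[1])
  expect_equal(nrow(rep), 153)
  w <- read.csv(paths[2])
  expect_equal(nrow(w), 18)
  expect_true(all(c("computed_category", "printed_label") %in% names(w)))
})
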