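test_that("score and category maps are fixed and mutually consistent", {
  expect_equal(grade_score(c("P100", "P76_99", "P51_75", "P26_50", "P1_25", "P0")),
               c(1, 0.875, 0.625, 0.375, 0.125, 0))
  expect_identical(grade_category(c("P100", "P76_99", "P26_50", "UNGRADABLE")),
                   c("perfused", "hypoperfused", "nonperfused", "ungradable"))
  expect_error(grade_score("UNGRADABLE"), class = "gridfa_no_score")
  expect_error(grade_score("P42"), class = "gridfa_invalid_argument")
  # nonperfused iff score <= 0.375; hypoperfused iff score in {0.625, 0.875}
  for (g in setdiff(grade_levels(), "UNGRADABLE")) {
    expect_identical(grade_category(g) == "nonperfused", grade_score(g) <= 0.375)
    expect_identical(grade_category(g) == "hypoperfused",
                     grade_score(g) %in% c(0.625, 0.875))
  }
})

test_that("region summaries average scores over gradable cells only", {
  s <- uniform_session("P100")
  expect_equal(region_summary(s, "ENTIRE")$percent_hypoperfusion, 0)
  # three graded cells: 1, 0.875, 0 -> mean 0.625 -> 37.5% hypoperfusion
  sm <- region_summary(grading_session("i", "g", data.frame(
    ring = c(0, 1, 1), sector = c(0, 0, 1),
    grade = c("P100", "P76_99", "P0"))), "ENTIRE")
  expect_equal(sm$mean_perfusion, 0.625)
  expect_equal(sm$percent_hypoperfusion, 37.5)
  expect_identical(sm$n_graded, 3L)
  # an ungradable cell joins the counts but not the mean
  sm2 <- region_summary(grading_session("i", "g", data.frame(
    ring = c(0, 1), sector = c(0, 0),
    grade = c("P100", "UNGRADABLE"))), "ENTIRE")
  expect_equal(sm2$mean_perfusion, 1)
  expect_identical(sm2$n_ungradable, 1L)
  expect_identical(as.integer(sm2$category_counts[["ungradable"]]), 1L)
  # all ungradable: undefined mean, flagged
  sm3 <- region_summary(uniform_session("UNGRADABLE"), "ENTIRE")
  expect_false(sm3$gradable)
  expect_true(is.na(sm3$percent_hypoperfusion))
})

test_that("entire-retina summary is the graded-count-weighted blend of its regions", {
  withr::with_seed(21, {
    for (i in 1:5) {
      truth <- random_truth(seed = i)
      s <- simulate_grader(truth, grader_model(noise_sd = 0.2, seed = i))
      e <- region_summary(s, "ENTIRE")
      c_ <- region_summary(s, "CENTRAL_ETDRS")
      p <- region_summary(s, "PERIPHERAL")
      nc <- c_$n_graded - c_$n_ungradable
      np <- p$n_graded - p$n_ungradable
      expect_equal(e$mean_perfusion,
                   (nc * c_$mean_perfusion + np * p$mean_perfusion) / (nc + np))
    }
  })
})

test_that("sessions validate their cell addresses and exclusions", {
  expect_error(grading_session("i", "g", data.frame(ring = 9, sector = 0,
                                                    grade = "P100")),
               class = "gridfa_invalid_argument")
  expect_error(grading_session("i", "g",
                               data.frame(ring = c(1, 1), sector = c(0, 0),
                                          grade = c("P100", "P0"))),
               class = "gridfa_invalid_argument")
  expect_error(grading_session("i", "g",
                               data.frame(ring = 1, sector = 0, grade = "P100"),
                               excluded = data.frame(ring = 1, sector = 0)),
               class = "gridfa_invalid_argument")
  # excluded cells reduce nothing but the counts
  s <- grading_session("i", "g", data.frame(ring = 0, sector = 0, grade = "P0"),
                       excluded = data.frame(ring = 1, sector = 0:3))
  expect_identical(region_summary(s, "ENTIRE")$n_excluded, 4L)
})

test_that("pairing drops the union of ungradable cells when asked", {
  g1 <- uniform_session("P100", grader_id = "g1",
                        overrides = setNames(rep("UNGRADABLE", 10),
                                             as.character(0:9)))
  g2 <- uniform_session("P100", grader_id = "g2",
                        overrides = setNames(rep("UNGRADABLE", 4),
                                             as.character(6:9)))
  pr <- pair_sessions(g1, g2, drop_if_either_ungradable = TRUE)
  expect_identical(pr$n_common, 289L)
  expect_identical(pr$n_removed, 10L)            # union of {0..9} and {6..9}
  expect_identical(nrow(pr$pairs), 279L)
  pr0 <- pair_sessions(g1, g2, drop_if_either_ungradable = FALSE)
  expect_identical(nrow(pr0$pairs), 289L)
  # survivors never exceed either single-grader filter
  expect_lte(nrow(pr$pairs), sum(g1$grades$grade != "UNGRADABLE"))
  expect_lte(nrow(pr$pairs), sum(g2$grades$grade != "UNGRADABLE"))
  expect_identical(nrow(pr$pairs) + pr$n_removed, pr$n_common)
  expect_error(pair_sessions(g1, g1), class = "gridfa_incompatible_sessions")
  g3 <- uniform_session("P100", image_id = "other", grader_id = "g2")
  expect_error(pair_sessions(g1, g3), class = "gridfa_incompatible_sessions")
})

test_that("category tables report exact counts behind rounded percentages", {
  a <- uniform_session("P100", grader_id = "g1")
  b <- uniform_session("P100", grader_id = "g2")
  tab <- tabulate_categories(pair_sessions(a, b), "ENTIRE")
  expect_equal(tab$table$perfused, c(100, 100))
  expect_true(all(tab$diff == 0))
  # counts reconstructed from exact fractions match the raw counts
  mixed <- uniform_session("P76_99", grader_id = "g2",
                           overrides = setNames(rep("P0", 37),
                                                as.character(0:36)))
  tab2 <- tabulate_categories(pair_sessions(a, mixed), "ENTIRE")
  expect_identical(as.integer(tab2$counts["grader2", c("nonperfused", "hypoperfused")]),
                   c(37L, 252L))
  expect_identical(sum(tab2$counts["grader2", ]), tab2$n_cells)
  # display rounding is half-up on whole percents
  expect_equal(tab2$table$nonperfused[2], round(100 * 37 / 289))
})

test_that("session JSON round-trips semantically", {
  s <- uniform_session("P51_75",
                       overrides = setNames("UNGRADABLE", "12"))
  path <- withr::local_tempfile(fileext = ".json")
  write_session_json(s, path)
  s2 <- read_session_json(path)
  expect_identical(s2$grades, s$grades)
  expect_identical(s2$image_id, s$image_id)
  expect_identical(s2$grid$n_rings, s$grid$n_rings)
})
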