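test_that("census tables load, validate and support column aliases", {
  path <- write_census_file(toy_census())
  rec <- read_census_csv(path)
  expect_equal(nrow(rec), 4)
  expect_true(is.logical(rec$creole_observed))

  # negative count rows are rejected with diagnostics, not fatal
  bad <- toy_census()
  bad$n_free_colored[2] <- -5
  expect_warning(rec2 <- read_census_csv(write_census_file(bad)),
                 "rejected 1 row")
  expect_equal(nrow(rec2), 3)
  expect_equal(nrow(attr(rec2, "rejected")), 1)

  # alias mapping onto the schema
  ali <- toy_census()
  names(ali)[names(ali) == "n_free_colored"] <- "free_blacks"
  expect_error(read_census_csv(write_census_file(ali)), "schema error")
  rec3 <- read_census_csv(write_census_file(ali),
                          aliases = c(free_blacks = "n_free_colored"))
  expect_equal(rec3$n_free_colored, toy_census()$n_free_colored)

  empty <- tempfile(fileext = ".csv")
  writeLines("territory,n_white,n_free_colored,n_slave", empty)
  expect_error(read_census_csv(empty), "empty")
})

test_that("projection onto the demographic plane is correct and scale-free", {
  pt <- to_point(list(n_white = 100, n_free_colored = 50, n_slave = 850))
  expect_equal(pt$x, 50 / 900)
  expect_equal(pt$y, 0.9)

  pt2 <- to_point(list(n_white = 0, n_free_colored = 0, n_slave = 10))
  expect_equal(pt2$x, 0); expect_equal(pt2$y, 1)

  expect_error(to_point(list(n_white = 10, n_free_colored = 0, n_slave = 0)),
               "unclassifiable")

  # multiplying all counts by a constant leaves (x, y) unchanged
  set.seed(13)
  for (i in 1:20) {
    cnt <- as.list(rpois(3, c(500, 200, 2000)) + 1)
    names(cnt) <- c("n_white", "n_free_colored", "n_slave")
    scaled <- lapply(cnt, `*`, 37)
    expect_equal(to_point(cnt), to_point(scaled))
  }
})

test_that("classification against a stripe follows the three-way geometry", {
  s <- toy_stripe()
  pts <- data.frame(x = c(0.1, 0.1, 0.1, 0.1, 0.1),
                    y = c(0.99, 0.10, 0.60, 0.65, 0.55))
  cl <- classify(pts, s)
  expect_equal(cl$verdict,
               c("creole_predicted", "no_creole_predicted", "uncertain",
                 "uncertain",   # exactly on the upper curve: inclusive
                 "uncertain"))  # exactly on the lower curve: inclusive
  expect_equal(cl$distance_to_mid_curve[3], 0)
  expect_error(classify(pts, s[0, ]), "empty stripe")
})

test_that("classification is deterministic given a stripe", {
  s <- toy_stripe()
  pts <- data.frame(x = runif(10, 0.01, 0.6), y = runif(10, 0.05, 0.99))
  expect_identical(classify(pts, s), classify(pts, s))
})

test_that("census classification and evaluation handle labels and borderliners", {
  s <- toy_stripe()
  expect_warning(cl <- classify_census(toy_census(), s), "zero Black")
  expect_true(is.na(cl$verdict[cl$territory == "NoBlacks"]))
  expect_equal(cl$verdict[cl$territory == "HighBlack"], "creole_predicted")
  expect_equal(cl$verdict[cl$territory == "LowBlack"], "no_creole_predicted")
  expect_equal(cl$verdict[cl$territory == "MidStripe"], "uncertain")

  ev <- evaluate_predictions(cl)
  expect_equal(ev$n_correct, 2)
  expect_equal(ev$n_incorrect, 0)
  expect_equal(ev$n_uncertain, 1)
  expect_equal(ev$accuracy, 1)
  expect_equal(ev$borderline$territory, "MidStripe")

  unlab <- cl; unlab$creole_observed <- NA
  expect_error(evaluate_predictions(unlab), "empty evaluation")
})

test_that("synthetic fixtures land on the intended side of the stripe", {
  s <- toy_stripe()
  fix <- synthesize_census(6, 6, margin = 0.05, stripe = s, seed = 1)
  expect_equal(nrow(fix), 12)
  expect_equal(sum(fix$creole_observed), 6)
  cl <- classify_census(fix, s)
  expect_equal(cl$verdict[cl$creole_observed], rep("creole_predicted", 6))
  expect_equal(cl$verdict[!cl$creole_observed], rep("no_creole_predicted", 6))
  expect_equal(evaluate_predictions(cl)$accuracy, 1)

  # determinism and the schema round-trip through CSV
  fix2 <- synthesize_census(6, 6, margin = 0.05, stripe = s, seed = 1)
  expect_identical(fix, fix2)
  rec <- read_census_csv(write_census_file(fix))
  expect_equal(rec$n_slave, fix$n_slave)

  expect_error(synthesize_census(2, 2, margin = 0.9, stripe = s, seed = 1),
               "generation error")
})

test_that("bundled desk-scale stripe and synthetic census agree", {
  stripe <- read_stripe_csv(system.file("extdata", "stripe_desk_scale.csv",
                                        package = "creolegame"))
  expect_true(all(diff(stripe$y_mid) >= 0))       # y* rises with x
  expect_true(all(stripe$y_lower <= stripe$y_mid &
                    stripe$y_mid <= stripe$y_upper))
  census <- read_census_csv(system.file("extdata", "census_synthetic.csv",
                                        package = "creolegame"))
  cl <- suppressWarnings(classify_census(census, stripe))
  expect_equal(cl$verdict[cl$creole_observed] == "creole_predicted",
               rep(TRUE, sum(cl$creole_observed)))
  expect_equal(evaluate_predictions(cl)$accuracy, 1)
})
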