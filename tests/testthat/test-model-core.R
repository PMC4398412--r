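test_that("initial conditions put E on Europeans/Mulattos and A on Bozals", {
  st <- init_population(n_eu = 2, n_m = 1, n_b = 1)
  expect_equal(repertoires(st, "M", 1), "E")
  expect_equal(repertoires(st, "B", 1), "A")
  expect_equal(repertoires(st, "EU", 2), "E")
  expect_equal(st$interactions_elapsed, 0)

  # all-Mulatto population is valid but trivially stays all-E
  st2 <- init_population(0, 3, 0)
  expect_true(all(unlist(repertoires(st2)) == "E"))

  expect_error(init_population(5, 0, 0), "no Mulatto or Bozal")
  expect_error(init_population(0, 0, 0), "zero|no Mulatto")
  expect_error(init_population(-1, 1, 1), "non-negative")
})

test_that("utterance is uniform over the speaker's repertoire", {
  expect_identical(utter("E"), "E")
  expect_error(utter(character(0)), "empty|non-empty")

  set.seed(11)
  draws2 <- replicate(6000, utter(c("A", "E")))
  expect_true(all(draws2 %in% c("A", "E")))
  expect_gt(chisq.test(table(draws2))$p.value, 1e-3)

  draws3 <- replicate(6000, utter(c("A", "E", "C")))
  expect_gt(chisq.test(table(draws3))$p.value, 1e-3)
})

test_that("creolization fires only on repertoires holding both A and E", {
  set.seed(1)
  expect_equal(creolization_check(c("A", "E"), gamma = 1), "C")
  expect_equal(creolization_check(c("A", "E", "C"), gamma = 1), "C")
  expect_equal(sort(creolization_check(c("E", "C"), gamma = 1)), c("C", "E"))
  expect_equal(creolization_check(c("A", "E"), gamma = 0), c("E", "A"))
  # firing frequency tracks gamma
  hits <- mean(replicate(4000, identical(creolization_check(c("A", "E"), 0.4), "C")))
  expect_lt(abs(hits - 0.4), 4 * sqrt(0.4 * 0.6 / 4000))
})

test_that("interaction rules: learning, delta-gated success, collapse", {
  p0 <- model_params(gamma = 0, delta = 1, epsilon = 0.06)
  st <- init_population(1, 1, 1)
  eu <- list(group = "EU", index = 1)
  m1 <- list(group = "M", index = 1)
  b1 <- list(group = "B", index = 1)

  # (a) learning: E uttered to {A} hearer adds E
  r <- apply_interaction(st, eu, b1, "E", p0)
  expect_equal(r$outcome$result, "learned")
  expect_setequal(repertoires(r$state, "B", 1), c("A", "E"))

  # (b) success with A when delta = 1: both collapse to {A}
  st2 <- st; st2$rep_m <- 2L   # M holds {A}
  r2 <- apply_interaction(st2, m1, b1, "A", p0)
  expect_equal(r2$outcome$result, "success")
  expect_equal(repertoires(r2$state, "M", 1), "A")
  expect_equal(repertoires(r2$state, "B", 1), "A")

  # delta = 0 makes every A-to-A exchange fail
  pd0 <- model_params(gamma = 0, delta = 0, epsilon = 0.06)
  r3 <- apply_interaction(st2, m1, b1, "A", pd0)
  expect_equal(r3$outcome$result, "failed_A")
  expect_equal(repertoires(r3$state, "B", 1), "A")

  # E always understood when possessed: {E,C} hearer collapses to {E}
  st4 <- st; st4$rep_b <- 5L   # B holds {E,C}
  r4 <- apply_interaction(st4, eu, b1, "E", p0)
  expect_equal(r4$outcome$result, "success")
  expect_equal(repertoires(r4$state, "B", 1), "E")

  # C uttered to {A}: learning, but no creolization (E absent)
  p1 <- model_params(gamma = 1, delta = 1, epsilon = 0.06)
  st5 <- st; st5$rep_m <- 4L   # M holds {C}
  r5 <- apply_interaction(st5, m1, b1, "C", p1)
  expect_setequal(repertoires(r5$state, "B", 1), c("A", "C"))
  expect_false(r5$outcome$creolized)

  # hearer reaching {A,E} creolizes with gamma = 1
  r6 <- apply_interaction(st, eu, b1, "E", p1)
  expect_true(r6$outcome$creolized)
  expect_equal(repertoires(r6$state, "B", 1), "C")

  expect_error(apply_interaction(st, m1, eu, "E", p0), "topology")
  expect_error(apply_interaction(st, m1, b1, "A", p0), "speaker's repertoire")
})

test_that("pair drawing respects the segregated topology", {
  p <- model_params(epsilon = 0)
  st <- init_population(10, 1, 0)
  set.seed(4)
  for (i in 1:50) {
    pr <- draw_pair(st, p)
    expect_false(pr$null_step)
    expect_false(pr$hearer$group == "EU")  # Europeans never hear
  }

  # epsilon = 0: Eu-B pairs never retained, only null steps or M hearers
  st2 <- init_population(5, 2, 5)
  set.seed(5)
  for (i in 1:200) {
    pr <- draw_pair(st2, p)
    if (!pr$null_step)
      expect_false(pr$speaker$group == "EU" && pr$hearer$group == "B")
  }

  # epsilon = 1: among Eu-speaker draws, B hearers appear at the
  # unconstrained pair frequency n_b / (n_b + n_m)
  p1 <- model_params(epsilon = 1)
  st3 <- init_population(4, 3, 9)
  set.seed(6)
  n_eu_draws <- 0; n_eu_b <- 0
  for (i in 1:4000) {
    pr <- draw_pair(st3, p1)
    if (pr$speaker$group == "EU") {
      n_eu_draws <- n_eu_draws + 1
      if (pr$hearer$group == "B") n_eu_b <- n_eu_b + 1
    }
  }
  p_expect <- 9 / 12
  se <- sqrt(p_expect * (1 - p_expect) / n_eu_draws)
  expect_lt(abs(n_eu_b / n_eu_draws - p_expect), 4 * se)
})

test_that("fraction accounting weights multilingual agents by 1/|repertoire|", {
  st <- init_population(0, 2, 0)
  st$rep_m <- c(1L, 3L)  # {E} and {A,E}
  f <- measure_fractions(st)
  expect_equal(unname(f), c(0.75, 0.25, 0))

  st2 <- init_population(0, 4, 0)
  st2$rep_m <- c(7L, 4L, 4L, 4L)  # {A,E,C}, {C}, {C}, {C}
  f2 <- measure_fractions(st2)
  expect_equal(unname(f2["C"]), (1 / 3 + 3) / 4)
  expect_equal(unname(f2["E"]), 1 / 12)
  expect_equal(sum(f2), 1)

  st3 <- init_population(0, 3, 0)
  st3$rep_m <- c(4L, 4L, 4L)
  expect_equal(unname(measure_fractions(st3)), c(0, 0, 1))
})

test_that("group sizes are conserved and European repertoires immutable", {
  p <- model_params(gamma = 0.5, delta = 0.3, epsilon = 0.5)
  st <- init_population(3, 2, 3)
  set.seed(9)
  for (i in 1:300) {
    st <- step_game(st, p)$state
    reps <- repertoires(st)
    expect_true(all(vapply(reps, length, 1L) >= 1))
    expect_true(all(unlist(reps) %in% c("E", "A", "C")))
  }
  expect_equal(st$n_eu, 3); expect_equal(st$n_m, 2); expect_equal(st$n_b, 3)
  expect_equal(length(st$rep_m), 2); expect_equal(length(st$rep_b), 3)
  expect_equal(repertoires(st, "EU", 1), "E")
  expect_equal(st$interactions_elapsed, 300)
})

test_that("without creolization C never appears; without Bozals all-E absorbs", {
  p <- model_params(gamma = 0, delta = 0.5, epsilon = 0.5,
                    max_interactions_per_agent = 100, seed = 21)
  res <- run_game(init_population(5, 10, 35), p)
  expect_identical(res$summary[["C"]], 0)
  expect_identical(res$creolizations, 0)

  p2 <- model_params(gamma = 0.9, delta = 0.1, epsilon = 0.06,
                     max_interactions_per_agent = 2000, seed = 22)
  res2 <- run_game(init_population(20, 30, 0), p2)
  expect_true(res2$absorbed_all_E)
  expect_identical(res2$summary[["E"]], 1)
  expect_identical(res2$summary[["C"]], 0)
})

test_that("runs are reproducible under a fixed seed", {
  p <- model_params(gamma = 0.8, delta = 0.1, epsilon = 0.06,
                    max_interactions_per_agent = 300, seed = 123)
  r1 <- run_game(init_population(10, 10, 80), p)
  r2 <- run_game(init_population(10, 10, 80), p)
  expect_identical(r1$summary, r2$summary)
  expect_identical(r1$state$rep_b, r2$state$rep_b)
  expect_identical(r1$creolizations, r2$creolizations)
})

test_that("once A is extinct it never reappears and all-E is absorbing", {
  p <- model_params(gamma = 0.8, delta = 0.1, epsilon = 0.2,
                    max_interactions_per_agent = 500, seed = 31)
  res <- run_game(init_population(4, 3, 5), p)
  masks <- c(res$state$rep_m, res$state$rep_b)
  if (res$absorbed_all_E) {
    expect_true(all(masks == 1L))
    # continuing from the absorbed state changes nothing
    p2 <- p; p2$seed <- 32L; p2$max_interactions_per_agent <- 100
    res2 <- run_game(res$state, p2)
    expect_true(all(c(res2$state$rep_m, res2$state$rep_b) == 1L))
    expect_identical(res2$summary[["E"]], 1)
  }
  # a state with no A cannot regrow A or create new C
  st <- init_population(2, 2, 2)
  st$rep_b <- c(1L, 4L)  # {E}, {C}: A extinct
  st$rep_m <- c(1L, 5L)
  p3 <- model_params(gamma = 1, delta = 0.5, epsilon = 0.5,
                     max_interactions_per_agent = 200, seed = 33)
  res3 <- run_game(st, p3)
  expect_identical(res3$creolizations, 0)
  expect_true(all(bitwAnd(c(res3$state$rep_m, res3$state$rep_b), 2L) == 0L))
})
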