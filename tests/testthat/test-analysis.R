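test_that("contrast matrices implement dummy and backwards-difference coding", {
  sch <- contrast_scheme("dummy", c("Int", "Scr1", "Scr3"), reference = "Int")
  C <- contrast_matrix(sch)
  expect_equal(dim(C), c(3, 2))
  expect_equal(unname(C), rbind(c(0, 0), c(1, 0), c(0, 1)))
  bd <- contrast_scheme("backwards_difference", c("Int", "Scr1", "Scr3"))
  B <- contrast_matrix(bd)
  # independent cross-check: successive-differences coding from MASS
  expect_equal(unname(B), unname(MASS::contr.sdif(3)), tolerance = 1e-12)
  expect_error(contrast_scheme("dummy", "Int"), "2 levels")
  expect_error(contrast_scheme("dummy", c("A", "B"), reference = "C"),
               "reference")
})

test_that("fitted backwards-difference contrasts are successive mean differences", {
  # balanced noise-free means (1, 3, 4) -> contrasts (2, 1)
  p <- sim_params(c(L1 = 1, L2 = 3, L3 = 4), n_participants = 4, n_items = 3)
  d <- simulate_responses(c("L1", "L2", "L3"), p, seed = 1)
  bd <- contrast_scheme("backwards_difference", c("L1", "L2", "L3"))
  expect_equal(unname(coef(estimate_effects(d, bd, n_boot = 200, seed = 2))),
               c(2, 1))
  # constant means -> all contrasts zero
  pc <- sim_params(c(L1 = 2, L2 = 2, L3 = 2), n_participants = 4, n_items = 3)
  dc <- simulate_responses(c("L1", "L2", "L3"), pc, seed = 1)
  expect_equal(unname(coef(estimate_effects(dc, bd, n_boot = 200, seed = 2))),
               c(0, 0))
  # dummy coding recovers differences from the reference
  dm <- contrast_scheme("dummy", c("L1", "L2", "L3"), reference = "L1")
  expect_equal(unname(coef(estimate_effects(d, dm, n_boot = 200, seed = 2))),
               c(2, 3))
})

test_that("adding a constant to every response leaves contrasts unchanged", {
  p <- neural_sim_params(n_participants = 12)
  d <- simulate_responses(names(p$condition_means), p, seed = 3)
  sch <- contrast_scheme("dummy", names(p$condition_means), reference = "Int")
  f1 <- estimate_effects(d, sch, n_boot = 300, seed = 4)
  d2 <- d
  d2$value <- d2$value + 100
  f2 <- estimate_effects(d2, sch, n_boot = 300, seed = 4)
  expect_equal(f1$estimates, f2$estimates, tolerance = 1e-10)
})

test_that("the cluster bootstrap is deterministic under its seed", {
  p <- neural_sim_params(n_participants = 10)
  d <- simulate_responses(names(p$condition_means), p, seed = 5)
  sch <- contrast_scheme("dummy", names(p$condition_means), reference = "Int")
  f1 <- estimate_effects(d, sch, n_boot = 500, seed = 6)
  f2 <- estimate_effects(d, sch, n_boot = 500, seed = 6)
  expect_identical(f1$estimates, f2$estimates)
  f3 <- estimate_effects(d, sch, n_boot = 500, seed = 7)
  expect_false(identical(f1$estimates$lower, f3$estimates$lower))
})

test_that("missing participant-condition cells abort with the cell named", {
  p <- sim_params(c(A = 1, B = 2), n_participants = 3, n_items = 2)
  d <- simulate_responses(c("A", "B"), p, seed = 8)
  d <- d[!(d$participant == "p002" & d$condition == "B"), ]
  sch <- contrast_scheme("dummy", c("A", "B"), reference = "A")
  expect_error(estimate_effects(d, sch, n_boot = 200, seed = 1), "p002:B")
})

test_that("small bootstrap sizes trigger a warning", {
  p <- sim_params(c(A = 1, B = 2), n_participants = 3, n_items = 2)
  d <- simulate_responses(c("A", "B"), p, seed = 8)
  sch <- contrast_scheme("dummy", c("A", "B"), reference = "A")
  expect_warning(estimate_effects(d, sch, n_boot = 50, seed = 1), "n_boot")
})

test_that("accuracy contrasts use continuity-corrected log-odds", {
  # an all-correct cell stays finite: log((n + 0.5) / 0.5)
  d <- data.frame(
    participant = rep(c("p1", "p2"), each = 8),
    unit = rep(c("u1", "u2", "u3", "u4"), 4),
    condition = rep(rep(c("A", "B"), each = 4), 2),
    value = c(1, 1, 1, 1, 0, 1, 0, 1,
              1, 1, 1, 1, 1, 0, 1, 1))
  sch <- contrast_scheme("dummy", c("A", "B"), reference = "A")
  fit <- accuracy_summary(d, sch, n_boot = 200, seed = 2)
  lo_A <- log(4.5 / 0.5)
  lo_B <- mean(c(log(2.5 / 2.5), log(3.5 / 1.5)))
  expect_equal(unname(coef(fit)), lo_B - lo_A)
  expect_error(accuracy_summary(transform(d, value = value + 0.5), sch,
                                n_boot = 200, seed = 2), "0/1")
})

test_that("accuracy contrasts recover a simulated word-list deficit", {
  p <- sim_params(c(Int = 2.0, WordList = 0.3), participant_sd = 0.3,
                  n_participants = 16, n_items = 30, family = "binomial")
  d <- simulate_responses(c("Int", "WordList"), p, seed = 14)
  sch <- contrast_scheme("dummy", c("Int", "WordList"), reference = "Int")
  fit <- accuracy_summary(d, sch, n_boot = 1000, seed = 15)
  expect_lt(fit$estimates$estimate, 0)
  expect_lt(fit$estimates$upper, 0)
})
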