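test_that("assisted workflow: always-accept and never-accept limits", {
  pop <- small_pop(render = FALSE)
  obs <- default_observers()
  ai <- simulate_ai_only(pop, ai_error_model(
    fail_prob_normal = 0, fail_prob_cardiomegaly = 0, seed = 5L))

  always <- run_assisted(pop, ai, obs, accept_tol = Inf)
  for (o in c("obs1", "obs2")) {
    v <- always$records[always$records$observer_id == o &
                          always$records$replicate == 1L, ]
    expect_equal(v$ctr[match(ai$case_id, v$case_id)], ai$ctr)
  }
  expect_true(all(always$decisions$decision == "accept"))

  never <- run_assisted(pop, ai, obs, accept_tol = 0)
  expect_true(all(never$decisions$decision == "adjust"))
  # with continuous noise the assisted values equal the observer's own
  # manual draws from the assisted session
  own <- simulate_manual(pop, obs[[1]], replicate = 1L,
                         method = "ai_assisted", seed_offset = 1000003L)
  v <- never$records[never$records$observer_id == "obs1" &
                       never$records$replicate == 1L, ]
  expect_equal(v$ctr, own$ctr)
})

test_that("AI failure triggers the default-line fallback", {
  pop <- small_pop(render = FALSE)
  obs <- default_observers()
  ai <- simulate_ai_only(pop, ai_error_model(
    fail_prob_normal = 1, fail_prob_cardiomegaly = 1, seed = 5L))
  out <- run_assisted(pop, ai, obs, accept_tol = Inf)
  expect_true(all(out$decisions$decision == "fallback"))
  own <- simulate_manual(pop, obs[[2]], replicate = 1L,
                         method = "ai_assisted", seed_offset = 1000003L)
  v <- out$records[out$records$observer_id == "obs2", ]
  expect_equal(v$ctr, own$ctr)
  expect_false(any(out$records$failed))  # the human always yields a value
})

test_that("grading follows the accept/adjust/failure rule and partitions cases", {
  decisions <- data.frame(
    case_id = rep(c("a", "b", "c"), 2),
    observer_id = rep(c("o1", "o2"), each = 3),
    replicate = 1L,
    decision = c("accept", "accept", "fallback",
                 "accept", "adjust", "fallback"))
  ai <- data.frame(case_id = c("a", "b", "c"),
                   failed = c(FALSE, FALSE, TRUE))
  g <- grade_outcomes(decisions, ai)
  expect_equal(g$n_excellent, 1L)  # both accepted "a"
  expect_equal(g$n_good, 1L)       # "b" adjusted by o2
  expect_equal(g$n_poor, 1L)       # "c" failed
  expect_equal(g$n_excellent + g$n_good + g$n_poor, g$n_cases)
  expect_equal(sum(g$proportions), 1)
  expect_equal(g$grades$grade, c("excellent", "good", "poor"))
})

test_that("consensus averaging follows the 2+1 design and exclusion rule", {
  mk <- function(ctr, failed = FALSE)
    data.frame(case_id = "x", method = "manual",
               observer_id = c("o1", "o1", "o2"), replicate = c(1L, 2L, 1L),
               ctr = ctr, failed = failed)
  same <- consensus_values(mk(c(0.5, 0.5, 0.5)), "manual")
  expect_equal(same$values$ctr, 0.5)
  avg <- consensus_values(mk(c(0.50, 0.52, 0.54)), "manual")
  expect_equal(avg$values$ctr, 0.52)
  bad <- mk(c(0.50, 0.52, NA)); bad$failed[3] <- TRUE
  excl <- consensus_values(bad, "manual")
  expect_equal(nrow(excl$values), 0L)
  expect_equal(excl$n_excluded, 1L)
})

test_that("study smoke run has the closed-form record count and is reproducible", {
  pop <- small_pop(n_normal = 5L, n_cardio = 5L, render = FALSE)
  st <- run_study(pop)
  # per case: 1 reference + 3 manual + 1 ai_only + 3 ai_assisted
  expect_equal(nrow(st$measurements), 10L * 8L)
  expect_identical(run_study(small_pop(n_normal = 5L, n_cardio = 5L,
                                       render = FALSE))$measurements,
                   st$measurements)
})

test_that("degenerate zero-noise study: every method exact, all excellent", {
  pop <- small_pop(render = FALSE)
  obs <- list(observer_model("obs1", 0, 0, seed = 1L),
              observer_model("obs2", 0, 0, seed = 2L))
  perfect_ai <- ai_error_model(core_sd = 0, outlier_sd = 0,
                               outlier_prob = 0, fail_prob_normal = 0,
                               fail_prob_cardiomegaly = 0)
  st <- run_study(pop, obs, perfect_ai, accept_tol = 0.01)
  expect_true(all(abs(st$measurements$ctr - pop$cases$true_ctr[
    match(st$measurements$case_id, pop$cases$case_id)]) < 1e-12))
  expect_equal(st$grading$n_excellent, nrow(pop$cases))
})

test_that("increasing accept_tol never decreases the excellent count", {
  pop <- small_pop(n_normal = 40L, n_cardio = 40L, seed = 3L,
                   render = FALSE)
  obs <- default_observers()
  ai <- simulate_ai_only(pop, ai_error_model(seed = 9L))
  n_exc <- vapply(c(0.005, 0.018, 0.05, 0.2), function(tol) {
    out <- run_assisted(pop, ai, obs, accept_tol = tol)
    grade_outcomes(out$decisions, ai)$n_excellent
  }, integer(1))
  expect_true(all(diff(n_exc) >= 0L))
})

test_that("assisted workflow reduces inter-observer variation in expectation", {
  pop <- generate_population(
    population_spec(n_normal = 2500L, n_cardiomegaly = 2500L, seed = 41L),
    test_geometry(), render = FALSE)
  st <- run_study(pop)
  m <- st$measurements
  pick <- function(method, o, r)
    m[m$method == method & m$observer_id == o & m$replicate == r, ]
  man <- merge(pick("manual", "obs1", 1L), pick("manual", "obs2", 1L),
               by = "case_id")
  ast <- merge(pick("ai_assisted", "obs1", 1L),
               pick("ai_assisted", "obs2", 1L), by = "case_id")
  expect_lte(cv_percent(ast$ctr.x, ast$ctr.y),
             cv_percent(man$ctr.x, man$ctr.y))
})
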