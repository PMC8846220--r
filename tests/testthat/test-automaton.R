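test_that("hyperplane functional gives signed sides and crossing criterion", {
  expect_equal(plane_eval(hyperplane(0, c(1, 0)), c(0, 0)), 0)
  expect_equal(plane_eval(hyperplane(-1, c(1, 0)), c(2, 1)), 1)
  expect_error(plane_eval(hyperplane(0, c(1, 0)), c(1, 2, 3)),
               "dimension mismatch")
  expect_error(hyperplane(1, c(0, 0)), "nonzero")
  # sign agrees with a brute-force half-space test by perturbation
  set.seed(42)
  for (i in 1:50) {
    n <- sample(2:5, 1L)
    pl <- hyperplane(rnorm(1L), rnorm(n))
    x <- rnorm(n)
    f <- plane_eval(pl, x)
    # walking along +normal increases f, so sign(f) tells the side
    step <- pl$c / sqrt(sum(pl$c^2)) * 1e-3
    expect_true(plane_eval(pl, x + step) > f)
    if (abs(f) > 1e-6) {
      x_refl <- x - 2 * f * pl$c / sum(pl$c^2)   # mirror point
      expect_lt(f * plane_eval(pl, x_refl), 0)   # opposite sides
    }
  }
})

test_that("simulation handles ray-plane division and records exact jumps", {
  sp <- automaton_spec(
    states = list(grow = c(1, 1)),
    switches = list(),
    division = list(grow = hyperplane(-1, c(0, 1))),
    d = c(-log(2), -log(2)), s_d = "grow")
  tr <- simulate_automaton(sp, c(0, 0), "grow", max_events = 1L)
  expect_equal(tr$event, c("start", "division"))
  expect_equal(tr$time[2L], 1)
  # recorded position is post-division: (1,1) shifted by d
  expect_equal(unlist(tr[2L, c("x1", "x2")]),
               c(x1 = 1 - log(2), x2 = 1 - log(2)))
  # deterministic: bit-identical repeat
  tr2 <- simulate_automaton(sp, c(0, 0), "grow", max_events = 1L)
  expect_identical(tr, tr2)
})

test_that("between events the motion is colinear with the state's growth vector", {
  for (variant in c("cycle", "sensitive")) {
    sp <- toy_single_trigger_spec(variant)
    tr <- simulate_automaton(sp, c(0.75, 1 - log(2)), "1", max_events = 30L)
    for (k in seq_len(nrow(tr) - 1L)) {
      dx <- unlist(tr[k + 1L, c("x1", "x2")]) - unlist(tr[k, c("x1", "x2")])
      if (tr$event[k + 1L] == "division") dx <- dx - sp$d
      a <- sp$states[[tr$state[k]]]
      # cross product of 2D vectors vanishes when colinear
      expect_lt(abs(dx[1L] * a[2L] - dx[2L] * a[1L]), 1e-10)
    }
  }
})

test_that("event sequence matches a dense fixed-step integrator on random 3D specs", {
  set.seed(11)
  for (rep in 1:3) {
    inst <- random_3d_spec()
    tr <- simulate_automaton(inst$spec, inst$x0, inst$s0,
                             max_events = 6L, max_time = 5)
    ev <- tr[tr$event %in% c("switch", "division"), ]
    orc <- fixed_step_oracle(inst$spec, inst$x0, inst$s0,
                             max_events = 6L, h = 1e-4, max_time = 5)
    expect_equal(nrow(ev), length(orc))
    for (k in seq_len(nrow(ev))) {
      expect_equal(ev$event[k], orc[[k]]$type)
      expect_equal(ev$state[k], orc[[k]]$state)
      expect_lt(abs(ev$time[k] - orc[[k]]$t), 2e-4)
    }
  }
})

test_that("toy single-trigger automaton reaches its limit cycle or degenerates", {
  sp <- toy_single_trigger_spec("cycle")
  # birth-plane start with the trigger on: converges to the closed-form
  # fixed point (1 - log 2, 1 - log 2) after one division
  cl <- classify_asymptotics(sp, c(0.3, 1 - log(2)), "1", n_divisions = 30L)
  expect_equal(cl$verdict, "limit_cycle")
  expect_equal(cl$period, 1L)
  expect_equal(unname(cl$fixed_point), rep(1 - log(2), 2L), tolerance = 1e-10)
  expect_setequal(cl$cycle_states, c("0", "1"))
  # same position, trigger off: the trajectory escapes
  cl0 <- classify_asymptotics(sp, c(0.3, 1 - log(2)), "0", n_divisions = 30L)
  expect_equal(cl0$verdict, "divergent")
})

test_that("two limit cycles coexist for different initial intrinsic states", {
  sp <- toy_single_trigger_spec("two_cycles")
  c1 <- classify_asymptotics(sp, c(0, 1 - log(2)), "0", n_divisions = 20L)
  c2 <- classify_asymptotics(sp, c(0, 2 - log(2)), "1", n_divisions = 20L)
  expect_equal(c1$verdict, "limit_cycle")
  expect_equal(c2$verdict, "limit_cycle")
  expect_gt(sqrt(sum((c1$fixed_point - c2$fixed_point)^2)), 0.5)
})

test_that("basin of attraction alternates along the birth hyperplane", {
  sp <- toy_single_trigger_spec("sensitive")
  verdicts <- vapply(c(0.4, 0.75, 1.1), function(u)
    classify_asymptotics(sp, c(u, 1 - log(2)), "1", n_divisions = 400L,
                         diverge_bound = 40)$verdict, character(1L))
  expect_equal(verdicts, c("divergent", "limit_cycle", "divergent"))
})

test_that("cone feasibility matches hand-computable cases", {
  # one growth vector cannot balance a division shift with two components
  r1 <- cone_feasibility(list(c(1, 0)), c(-log(2), -log(2)))
  expect_false(r1$feasible)
  # identity basis: lambda = (log 2, log 2)
  r2 <- cone_feasibility(list(c(1, 0), c(0, 1)), c(-log(2), -log(2)))
  expect_true(r2$feasible)
  expect_equal(r2$lambda, c(log(2), log(2)), tolerance = 1e-10)
  # empty vector list
  expect_false(cone_feasibility(list(), c(-1, -1))$feasible)
  expect_true(cone_feasibility(list(), c(0, 0))$feasible)
})

test_that("cone feasibility agrees with a dense grid-search oracle", {
  set.seed(5)
  n_agree <- 0L
  for (i in 1:40) {
    a1 <- rnorm(3L); a2 <- rnorm(3L)
    if (i %% 2L == 0L) {
      d <- -(runif(1L, 0.5, 8) * a1 + runif(1L, 0.5, 8) * a2)  # feasible
    } else {
      d <- rnorm(3L)   # generic: infeasible with probability 1
    }
    res <- cone_feasibility(list(a1, a2), d)
    grid_min <- cone_grid_oracle(a1, a2, d)
    scale <- max(1, sqrt(sum(d^2)))
    if (res$feasible) expect_lt(grid_min, 0.2 * scale)
    else expect_gt(grid_min, 1e-3 * scale)
    n_agree <- n_agree + 1L
  }
  expect_equal(n_agree, 40L)
})

test_that("automaton JSON round-trip preserves the dynamics", {
  sp <- build_2d_automaton(synthetic_anchor_points())$automaton
  path <- tempfile(fileext = ".json")
  write_automaton_json(sp, path)
  sp2 <- read_automaton_json(path)
  x0 <- synthetic_anchor_points()["x0", ]
  tr1 <- simulate_automaton(sp, x0, "00", max_events = 20L)
  tr2 <- simulate_automaton(sp2, x0, "00", max_events = 20L)
  expect_equal(tr1, tr2, tolerance = 1e-12)
  unlink(path)
})

test_that("stalled and divergent terminations are tagged", {
  sp <- automaton_spec(states = list(halt = c(0, 0), run = c(0, 1)),
                       switches = list(),
                       division = list(run = hyperplane(-1, c(0, 1))),
                       d = c(-0.1, -0.1), s_d = "halt")
  tr <- simulate_automaton(sp, c(0, 0), "halt", max_events = 5L)
  expect_equal(tail(tr$event, 1L), "stalled")
  sp2 <- automaton_spec(states = list(run = c(1, 0)), switches = list(),
                        division = list(run = hyperplane(-1, c(0, 1))),
                        d = c(-0.1, -0.1), s_d = "run")
  tr2 <- simulate_automaton(sp2, c(0, 0), "run", max_events = 5L)
  expect_equal(tail(tr2$event, 1L), "divergent")
})
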