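test_that("constant-rate segments have the textbook closed forms", {
  # pure exponential decay: half-life
  seg <- solve_segment(1, 1, c(kt_S = 0, kd_S = 1, kt_M = 0, kd_M = 1),
                       log(2))
  expect_equal(seg$S_out, 0.5, tolerance = 1e-12)
  # zero degradation: linear growth
  seg2 <- solve_segment(1, 0, c(kt_S = 2, kd_S = 0, kt_M = 0, kd_M = 0), 3)
  expect_equal(seg2$S_out, 7)
  expect_error(solve_segment(1, 1, c(kt_S = 1, kd_S = 1, kt_M = 1,
                                     kd_M = 1), -1), "nonnegative")
})

test_that("closed forms match adaptive ODE integration on random rates", {
  skip_if_not_installed("deSolve")
  set.seed(3)
  for (i in 1:100) {
    rates <- c(kt_S = runif(1L, 0, 5), kd_S = runif(1L, 0, 1),
               kt_M = runif(1L, 0, 5), kd_M = runif(1L, 0, 1))
    S0 <- runif(1L, 0.1, 20); M0 <- runif(1L, 0.1, 20)
    dur <- runif(1L, 0.1, 10)
    seg <- solve_segment(S0, M0, rates, dur)
    orc <- ode_segment_oracle(S0, M0, rates, dur)
    expect_equal(seg$S_out, unname(orc["S"]), tolerance = 1e-8)
    expect_equal(seg$M_out, unname(orc["M"]), tolerance = 1e-8)
  }
})

test_that("the initial state closes the cycle up to the division drops", {
  set.seed(4)
  for (i in 1:100) {
    pr <- random_kinetic_params()
    x0 <- initial_state(pr)
    xT <- chain_segments(pr, x0)
    expect_equal(xT[1L], pr$S_f * x0[["S0"]], tolerance = 1e-8)
    expect_equal(xT[2L], pr$M_f * x0[["M0"]], tolerance = 1e-8)
  }
  # vanishing synthesis gives an empty channel
  pr0 <- kinetic_params(kt_S = 0, kd_S = 0.2, kd_S2 = 0.1, kt_M = 1,
                        kd_M = 0.2, kd_M2 = 0.1, p = 2, S_f = 1.8,
                        M_f = 1.8, T1 = 5, T1s = 5, T2s = 5, Tm = 1)
  expect_equal(initial_state(pr0)[["S0"]], 0)
})

test_that("with no boost the M channel reduces to the single-synthesis form", {
  pr <- kinetic_params(kt_S = 2, kd_S = 0.2, kd_S2 = 0.1, kt_M = 1.5,
                       kd_M = 0.3, kd_M2 = 0.12, p = 1, S_f = 1.7,
                       M_f = 1.9, T1 = 6, T1s = 5, T2s = 4, Tm = 1)
  # p = 1: M synthesizes continuously over T1s + T2s, so M(0) takes the
  # S(0) form with M rates and the merged synthesis epoch
  manual <- with(pr, kt_M / kd_M2 * (exp(kd_M2 * (T1s + T2s)) - 1) /
                   (M_f * exp(kd_M2 * (T1s + T2s + Tm)) - exp(-kd_M * T1)))
  expect_equal(initial_state(pr)[["M0"]], manual, tolerance = 1e-12)
})

test_that("epoch boundaries agree with chained segment solutions", {
  set.seed(6)
  for (i in 1:20) {
    pr <- random_kinetic_params()
    b <- epoch_boundaries(pr)
    sched <- rate_schedule(pr)
    x <- initial_state(pr)
    S <- x[["S0"]]; M <- x[["M0"]]
    for (e in 1:4) {
      seg <- solve_segment(S, M,
                           sched[e, c("kt_S", "kd_S", "kt_M", "kd_M")],
                           sched$duration[e])
      S <- seg$S_out; M <- seg$M_out
      expect_equal(unname(b[e + 1L, ]), c(S, M), tolerance = 1e-10)
    }
  }
})

test_that("degenerate and symmetric epoch durations behave as expected", {
  # near-zero T1 collapses the first two boundary points
  pr <- kinetic_params(kt_S = 2, kd_S = 0.2, kd_S2 = 0.1, kt_M = 1.5,
                       kd_M = 0.3, kd_M2 = 0.1, p = 2, S_f = 1.8,
                       M_f = 1.8, T1 = 1e-12, T1s = 5, T2s = 5, Tm = 1)
  b <- epoch_boundaries(pr)
  expect_equal(b["start", ], b["end_T1", ], tolerance = 1e-9)
  # fully symmetric channels trace identical coordinates
  prs <- kinetic_params(kt_S = 2, kd_S = 0.2, kd_S2 = 0.1, kt_M = 2,
                        kd_M = 0.2, kd_M2 = 0.1, p = 1, S_f = 1.8,
                        M_f = 1.8, T1 = 5, T1s = 5, T2s = 1e-12, Tm = 1)
  bs <- epoch_boundaries(prs)
  expect_equal(unname(bs[, "S"]), unname(bs[, "M"]), tolerance = 1e-9)
})

test_that("each coordinate is monotone within every epoch", {
  set.seed(8)
  for (i in 1:20) {
    pr <- random_kinetic_params()
    Ttot <- with(pr, T1 + T1s + T2s + Tm)
    tr <- kinetic_trajectory(pr, seq(0, Ttot, length.out = 400L))
    for (e in unique(tr$epoch)) {
      sub <- tr[tr$epoch == e, ]
      if (nrow(sub) < 3L) next
      dS <- diff(sub$S); dM <- diff(sub$M)
      expect_true(all(dS >= -1e-12) || all(dS <= 1e-12))
      expect_true(all(dM >= -1e-12) || all(dM <= 1e-12))
    }
  }
})

test_that("13 raw combinations reduce to 11 independent ones", {
  pr <- default_kinetic_params()
  ic <- identifiable_combinations(pr)
  expect_length(ic$combinations, 13L)
  expect_equal(ic$count, 11L)
  # the two duration-ratio relations hold identically for any parameters
  set.seed(9)
  for (i in 1:20)
    expect_equal(unname(identifiable_combinations(
      random_kinetic_params())$relations), c(0, 0))
})

test_that("Jacobian ranks confirm the identifiability count", {
  pr <- default_kinetic_params()
  par0 <- unname(unlist(pr[c("kt_S", "kd_S", "kd_S2", "kt_M", "kd_M",
                             "kd_M2", "p", "S_f", "M_f", "T1", "T1s",
                             "T2s", "Tm")]))
  mk <- function(v) kinetic_params(v[1L], v[2L], v[3L], v[4L], v[5L],
                                   v[6L], v[7L], v[8L], v[9L], v[10L],
                                   v[11L], v[12L], v[13L])
  # 13 combinations as functions of the 13 natural parameters: rank 11
  Jc <- pracma::jacobian(function(v)
    unname(identifiable_combinations(mk(v))$combinations), par0)
  expect_equal(qr(Jc, tol = 1e-7)$rank, 11L)
  # 10 boundary coordinates: rank 10, one short of the combinations --
  # hence one extra constraint is needed for a unique reconstruction
  Jb <- pracma::jacobian(function(v)
    as.numeric(epoch_boundaries(mk(v), log = TRUE)), par0)
  expect_equal(qr(Jb, tol = 1e-7)$rank, 10L)
})

test_that("parameter sets sharing the 11 combinations trace one trajectory", {
  pr <- default_kinetic_params()
  alpha <- 1.7
  # gauge direction: rescale the post-T1 clock, keeping every combination
  pr2 <- kinetic_params(kt_S = pr$kt_S / alpha, kd_S = pr$kd_S,
                        kd_S2 = pr$kd_S2 / alpha, kt_M = pr$kt_M / alpha,
                        kd_M = pr$kd_M, kd_M2 = pr$kd_M2 / alpha,
                        p = pr$p, S_f = pr$S_f, M_f = pr$M_f,
                        T1 = pr$T1, T1s = pr$T1s * alpha,
                        T2s = pr$T2s * alpha, Tm = pr$Tm * alpha)
  expect_equal(identifiable_combinations(pr)$combinations,
               identifiable_combinations(pr2)$combinations,
               tolerance = 1e-12)
  expect_equal(epoch_boundaries(pr), epoch_boundaries(pr2),
               tolerance = 1e-10)
  # paths agree at matched epoch fractions
  fr <- seq(0.05, 0.95, by = 0.1)
  t1 <- with(pr, c(T1 * fr, T1 + T1s * fr, T1 + T1s + T2s * fr,
                   T1 + T1s + T2s + Tm * fr))
  t2 <- with(pr2, c(T1 * fr, T1 + T1s * fr, T1 + T1s + T2s * fr,
                    T1 + T1s + T2s + Tm * fr))
  p1 <- kinetic_trajectory(pr, t1); p2 <- kinetic_trajectory(pr2, t2)
  expect_equal(p1$S, p2$S, tolerance = 1e-10)
  expect_equal(p1$M, p2$M, tolerance = 1e-10)
})
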