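# Independent oracles and random-instance generators used across tests.

# adaptive ODE integration of one constant-rate segment (independent of the
# package's closed forms)
ode_segment_oracle <- function(S_in, M_in, rates, duration) {
  rhs <- function(t, y, parms) {
    list(c(parms$kt_S - parms$kd_S * y[1L],
           parms$kt_M - parms$kd_M * y[2L]))
  }
  out <- deSolve::lsoda(c(S = S_in, M = M_in), c(0, duration), rhs,
                        as.list(rates), rtol = 1e-12, atol = 1e-12)
  out[nrow(out), c("S", "M")]
}

# random valid kinetic parameter draw (log-uniform rates, realistic epochs)
random_kinetic_params <- function() {
  lu <- function(lo, hi) exp(stats::runif(1L, log(lo), log(hi)))
  kinetic_params(kt_S = lu(0.5, 5), kd_S = lu(0.05, 0.5),
                 kd_S2 = lu(0.02, 0.3),
                 kt_M = lu(0.5, 5), kd_M = lu(0.05, 0.5),
                 kd_M2 = lu(0.02, 0.3),
                 p = stats::runif(1L, 1.2, 4), S_f = stats::runif(1L, 1.3, 2),
                 M_f = stats::runif(1L, 1.3, 2),
                 T1 = stats::runif(1L, 2, 10), T1s = stats::runif(1L, 2, 8),
                 T2s = stats::runif(1L, 2, 8), Tm = stats::runif(1L, 0.3, 2))
}

# propagate an initial state through the four epochs with solve_segment
chain_segments <- function(params, x0) {
  sched <- rate_schedule(params)
  S <- x0[[1L]]; M <- x0[[2L]]
  for (i in seq_len(nrow(sched))) {
    seg <- solve_segment(S, M, sched[i, c("kt_S", "kd_S", "kt_M", "kd_M")],
                         sched$duration[i])
    S <- seg$S_out; M <- seg$M_out
  }
  c(S, M)
}

# dense fixed-step automaton integrator with sign-change event detection
fixed_step_oracle <- function(spec, x0, s0, max_events = 6L, h = 1e-4,
                              max_time = 5) {
  x <- x0; s <- s0; t <- 0
  events <- list()
  last_plane <- 0L   # switch plane the previous event landed on (0 = none)
  planes <- function(s) {
    pl <- lapply(spec$switches, `[[`, "plane")
    dv <- spec$division[[s]]
    list(switch = pl, division = dv)
  }
  while (t < max_time && length(events) < max_events) {
    a <- spec$states[[s]]
    pp <- planes(s)
    f0 <- vapply(pp$switch, plane_eval, numeric(1L), x = x)
    fd0 <- if (!is.null(pp$division)) plane_eval(pp$division, x) else NA_real_
    x1 <- x + a * h
    f1 <- vapply(pp$switch, plane_eval, numeric(1L), x = x1)
    fd1 <- if (!is.null(pp$division)) plane_eval(pp$division, x1) else NA_real_
    armed <- abs(f0) > 1e-9 | seq_along(f0) != last_plane
    hit_sw <- which(f0 * f1 < 0 & armed)
    hit_dv <- !is.na(fd0) && fd0 * fd1 < 0
    if (length(hit_sw) || hit_dv) {
      # earliest crossing within the step, smallest plane index on ties
      t_sw <- vapply(hit_sw, function(i) {
        den <- sum(spec$switches[[i]]$plane$c * a)
        -f0[i] / den
      }, numeric(1L))
      t_dv <- if (hit_dv) -fd0 / sum(pp$division$c * a) else Inf
      cand <- c(t_sw, t_dv)
      k <- which.min(cand)
      tc <- cand[k]
      x <- x + a * tc; t <- t + tc
      if (k <= length(t_sw)) {
        i <- hit_sw[k]
        s <- unname(spec$switches[[i]]$map[[s]])
        last_plane <- i
        events[[length(events) + 1L]] <- list(t = t, type = "switch",
                                              state = s)
      } else {
        x <- x + spec$d
        if (!is.null(spec$s_d)) s <- spec$s_d
        last_plane <- 0L
        events[[length(events) + 1L]] <- list(t = t, type = "division",
                                              state = s)
      }
    } else {
      x <- x1; t <- t + h
      if (last_plane && abs(f0[last_plane]) > 1e-6) last_plane <- 0L
    }
  }
  events
}

# random 3D two-state spec whose initial ray is guaranteed to cross planes
random_3d_spec <- function() {
  repeat {
    aA <- stats::rnorm(3L); aB <- stats::rnorm(3L)
    x0 <- stats::rnorm(3L, sd = 0.2)
    mk_plane <- function(t_hit, a) {
      c_vec <- stats::rnorm(3L)
      if (abs(sum(c_vec * a)) < 0.3) return(NULL)
      pt <- x0 + a * t_hit
      hyperplane(-sum(c_vec * pt), c_vec)
    }
    p1 <- mk_plane(0.25, aA)
    p2 <- mk_plane(0.6, aA)
    if (is.null(p1) || is.null(p2)) next
    spec <- automaton_spec(
      states = list(A = aA, B = aB),
      switches = list(list(plane = p1, map = c(A = "B", B = "B")),
                      list(plane = p2, map = c(A = "A", B = "A"))),
      division = list(),
      d = c(-log(2), -log(2), -log(2)), s_d = NULL)
    return(list(spec = spec, x0 = x0, s0 = "A"))
  }
}

# grid-search oracle for 2-vector cone membership, lambda in [0, 10]^2
cone_grid_oracle <- function(a1, a2, d, n_grid = 101L) {
  lam <- seq(0, 10, length.out = n_grid)
  best <- Inf
  for (l1 in lam) {
    v <- outer(rep(1, n_grid), l1 * a1 + d) + outer(lam, a2)
    best <- min(best, min(sqrt(rowSums(v^2))))
  }
  best
}

# small synthetic dataset reused by pipeline tests (module-scale, fast)
small_synth <- function(n_cells = 600L, n_genes = 300L, seed = 7L) {
  generate_cct_counts(synth_config(
    n_cells = n_cells, n_genes = n_genes,
    n_program_genes = min(30L, n_genes %/% 5L), seed = seed))
}
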