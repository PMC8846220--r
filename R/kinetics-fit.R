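#' Turning points of an observed cell cycle trajectory
#'
#' Five anchor coordinates of the closed trajectory in the
#' (log S-score, log G2/M-score) plane: the cycle start `(s0, m0)`, the end
#' of the post-mitotic degradation epoch `(s1, m1)`, the S-maximum
#' `(smax, ms)` at the end of `T1s`, the M-maximum `(sm, mmax)` at the end
#' of `T2s`, and the cycle end `(st, mt)`. In data these are estimated from
#' curvature peaks of the principal curve; here they are an explicit input.
#'
#' @param x A 5 x 2 numeric matrix (rows in cycle order as above, columns
#'   log S / log M).
#' @return The validated matrix with canonical dimnames, class
#'   `cct_turning_points`.
#' @export
turning_points <- function(x) {
  x <- as.matrix(x)
  if (!all(dim(x) == c(5L, 2L)) || any(!is.finite(x)))
    stop("turning points must be a finite 5 x 2 matrix")
  dimnames(x) <- list(c("start", "end_T1", "end_T1s", "end_T2s", "end_T"),
                      c("S", "M"))
  if (which.max(x[, "S"]) != 3L)
    warning("S coordinate is not maximal at the end of T1s")
  if (which.max(x[, "M"]) != 4L)
    warning("M coordinate is not maximal at the end of T2s")
  structure(x, class = c("cct_turning_points", "matrix"))
}

# residual of log epoch boundaries vs turning points
.tp_objective <- function(theta, tp, T1, T1s, Tm) {
  v <- exp(theta)
  pr <- try(kinetic_params(kt_S = v[1L], kd_S = v[2L], kd_S2 = v[3L],
                           kt_M = v[4L], kd_M = v[5L], kd_M2 = v[6L],
                           p = v[7L], S_f = max(1, v[9L]), M_f = max(1, v[10L]),
                           T1 = T1, T1s = T1s, T2s = v[8L], Tm = Tm),
            silent = TRUE)
  if (inherits(pr, "try-error")) return(1e10)
  b <- try(epoch_boundaries(pr, log = TRUE), silent = TRUE)
  if (inherits(b, "try-error") || any(!is.finite(b))) return(1e10)
  sum((b - unclass(tp))^2)
}

#' Fit the kinetic model to observed turning points
#'
#' Recovers kinetic parameters whose analytic epoch boundaries pass as
#' close as possible (unweighted least squares in log coordinates) to five
#' observed turning points. Because the ten boundary coordinates determine
#' only 11 independent parameter combinations, the physical time scale is
#' pinned by fixing `T1` and `T1s` (conventionally to their pseudotime
#' fractions of the trajectory) and the mitosis duration by the ratio
#' `Tm / T1s` (default 0.1: mitosis an order of magnitude faster than the
#' S-phase induction epoch).
#'
#' The fit first inverts the closed forms channel by channel, which is
#' exact on noise-free boundaries, and then refines all parameters jointly
#' by damped least-squares iterations (up to `max_iter`, stopping when the
#' parameter update falls below `tol`).
#'
#' @param tp A [turning_points()] matrix (log coordinates), or a plain
#'   5 x 2 matrix in cycle order.
#' @param T1,T1s Fixed epoch durations (hours).
#' @param tm_over_t1s Fixed ratio `Tm / T1s`.
#' @param refine Run the joint least-squares refinement after the
#'   closed-form inversion (recommended for noisy points)?
#' @param max_iter,tol Iteration cap and parameter-change tolerance for the
#'   refinement.
#' @return A [kinetic_params()] object with attribute `fit`, a list holding
#'   `residual` (sum of squared log-distances), `fitted_boundaries` and
#'   `converged`.
#' @export
fit_turning_points <- function(tp, T1, T1s, tm_over_t1s = 0.1,
                               refine = TRUE, max_iter = 500L, tol = 1e-8) {
  if (!inherits(tp, "cct_turning_points")) tp <- turning_points(tp)
  P <- exp(unclass(tp))
  S <- P[, "S"]; M <- P[, "M"]
  Tm <- tm_over_t1s * T1s
  pos <- function(x) max(x, 1e-8)
  # channel-wise inversion of the closed forms (exact on noiseless points)
  kd_S <- pos(log(S[1L] / S[2L]) / T1)
  kd_M <- pos(log(M[1L] / M[2L]) / T1)
  kd_S2 <- pos(log(S[4L] / S[5L]) / Tm)
  kd_M2 <- pos(log(M[4L] / M[5L]) / Tm)
  T2s <- pos(log(S[3L] / S[4L]) / kd_S2)
  eS <- exp(-kd_S2 * T1s); eM <- exp(-kd_M2 * T1s)
  A_S <- pos((S[3L] - S[2L] * eS) / (1 - eS))
  A_M <- pos((M[3L] - M[2L] * eM) / (1 - eM))
  kt_S <- A_S * kd_S2
  kt_M <- A_M * kd_M2
  eT2 <- exp(-kd_M2 * T2s)
  p <- pos((M[4L] - M[3L] * eT2) / (A_M * (1 - eT2)))
  S_f <- max(1, S[5L] / S[1L])
  M_f <- max(1, M[5L] / M[1L])
  theta <- log(c(kt_S, kd_S, kd_S2, kt_M, kd_M, kd_M2, p, T2s, S_f, M_f))
  obj0 <- .tp_objective(theta, tp, T1, T1s, Tm)
  converged <- TRUE
  if (refine && obj0 > 1e-20) {
    fit <- stats::optim(theta, .tp_objective, tp = tp, T1 = T1, T1s = T1s,
                        Tm = Tm, method = "BFGS",
                        control = list(maxit = as.integer(max_iter),
                                       reltol = tol^2))
    if (fit$value <= obj0) theta <- fit$par
    converged <- fit$convergence == 0L || fit$value < obj0
  }
  v <- exp(theta)
  out <- kinetic_params(kt_S = v[1L], kd_S = v[2L], kd_S2 = v[3L],
                        kt_M = v[4L], kd_M = v[5L], kd_M2 = v[6L],
                        p = v[7L], S_f = max(1, v[9L]), M_f = max(1, v[10L]),
                        T1 = T1, T1s = T1s, T2s = v[8L], Tm = Tm)
  resid <- .tp_objective(theta, tp, T1, T1s, Tm)
  if (!converged)
    warning("turning-point fit did not converge; residual = ", resid)
  attr(out, "fit") <- list(residual = resid,
                           fitted_boundaries = epoch_boundaries(out, log = TRUE),
                           converged = converged)
  out
}

#' Construct the 2D switching automaton from trajectory anchors
#'
#' Builds the four-state piecewise-linear cell cycle model in the
#' (log S, log M) plane from five anchor points in cycle order: the cycle
#' start `x0`, the transcription-minimum point `Bprime`, the S-maximum `C`,
#' the M-maximum `D` and the pre-division point `E`. Thresholds are read
#' off the anchors (`c_min = x_S^{B'} + x_M^{B'}`, `S_max = x_S^C`,
#' `M_max = x_M^D`, `M_e = x_M^E`) and the trigger-level rates are unit
#' difference quotients along the cycle. Intrinsic states are pairs of
#' trigger levels `{2 = synthesis, 1 = decay, 0 = degradation}` for the S
#' and M channels; the trajectory visits `(0,0) -> (2,2) -> (1,2) -> (1,1)`
#' and divides in `(1,1)`, for 4 threshold parameters plus one direction
#' per visited state: 8 free parameters in total.
#'
#' @param anchors A 5 x 2 matrix with rows `x0`, `Bprime`, `C`, `D`, `E`
#'   (log coordinates, columns S, M).
#' @param d Division translation vector; default the observed one,
#'   `x0 - E` (equal to `(-log S_f, -log M_f)`; the idealized value is
#'   `(-log 2, -log 2)`).
#' @return List with `thresholds` (named vector `c_min`, `S_max`, `M_max`,
#'   `M_e`), `rates` (named vector `k0_S`, `k1_S`, `k2_S`, `k0_M`, `k1_M`,
#'   `k2_M`), `free_parameters` (named vector of the 8 free parameters:
#'   4 thresholds + 4 state direction angles), and `automaton`, an
#'   [automaton_spec()] ready for [simulate_automaton()].
#' @export
build_2d_automaton <- function(anchors, d = NULL) {
  anchors <- as.matrix(anchors)
  if (!all(dim(anchors) == c(5L, 2L)))
    stop("anchors must be a 5 x 2 matrix (x0, Bprime, C, D, E)")
  rownames(anchors) <- c("x0", "Bprime", "C", "D", "E")
  x0 <- anchors["x0", ]; Bp <- anchors["Bprime", ]
  C <- anchors["C", ]; D <- anchors["D", ]; E <- anchors["E", ]
  thresholds <- c(c_min = unname(Bp[1L] + Bp[2L]), S_max = unname(C[1L]),
                  M_max = unname(D[2L]), M_e = unname(E[2L]))
  if (thresholds[["c_min"]] >= thresholds[["S_max"]])
    stop("constraint violated: c_min must be below S_max")
  if (thresholds[["M_e"]] >= thresholds[["M_max"]])
    stop("constraint violated: M_e must be below M_max")
  unit <- function(v) v / sqrt(sum(v^2))
  k2 <- unit(C - Bp)       # synthesis of both channels
  k1_S <- unit(D - C)[1L]  # S decay while M still synthesized
  k1_M <- unit(E - D)[2L]  # M decay after its maximum
  k0 <- unit(Bp - x0)      # post-division active degradation
  rates <- c(k0_S = unname(k0[1L]), k1_S = unname(k1_S), k2_S = unname(k2[1L]),
             k0_M = unname(k0[2L]), k1_M = unname(k1_M), k2_M = unname(k2[2L]))
  if (!(rates[["k2_S"]] > 0 && rates[["k2_M"]] > 0))
    stop("constraint violated: synthesis rates k2 must be positive")
  if (!(rates[["k0_S"]] < rates[["k1_S"]] && rates[["k1_S"]] < 0 &&
        rates[["k0_M"]] < rates[["k1_M"]] && rates[["k1_M"]] < 0))
    stop("constraint violated: need k0 < k1 < 0 < k2 per channel")
  if (is.null(d)) d <- unname(x0 - E)
  if (any(d >= 0)) stop("division vector must have negative components")
  states <- list(
    "00" = c(rates[["k0_S"]], rates[["k0_M"]]),
    "22" = c(rates[["k2_S"]], rates[["k2_M"]]),
    "12" = c(rates[["k1_S"]], rates[["k2_M"]]),
    "11" = c(rates[["k1_S"]], rates[["k1_M"]]))
  all_states <- names(states)
  switches <- list(
    # g1: total cell cycle expression dropped to c_min -> synthesis on
    list(plane = hyperplane(-thresholds[["c_min"]], c(1, 1)),
         map = stats::setNames(rep("22", 4L), all_states)),
    # g2: S reached S_max -> S synthesis off
    list(plane = hyperplane(-thresholds[["S_max"]], c(1, 0)),
         map = c("00" = "00", "22" = "12", "12" = "12", "11" = "11")),
    # g3: M reached M_max -> all transcription off
    list(plane = hyperplane(-thresholds[["M_max"]], c(0, 1)),
         map = stats::setNames(rep("11", 4L), all_states)))
  division <- list("11" = hyperplane(thresholds[["M_e"]], c(0, -1)))
  autom <- automaton_spec(states, switches, division, d, s_d = "00")
  angles <- vapply(states, function(a) atan2(a[2L], a[1L]), numeric(1L))
  free <- c(thresholds,
            stats::setNames(angles, paste0("theta_", names(states))))
  list(thresholds = thresholds, rates = rates, free_parameters = free,
       anchors = anchors, automaton = autom)
}

#' Synthetic trajectory anchors for the 2D switch model
#'
#' Anchor points `x0, B', C, D, E` in the (log S, log M) plane taken from
#' the epoch boundaries of [default_kinetic_params()] (with `B'`
#' approximated by the end of the degradation epoch). A synthetic stand-in
#' for anchors that would otherwise be extracted from data via curvature
#' peaks.
#'
#' @return A 5 x 2 matrix of log coordinates.
#' @export
synthetic_anchor_points <- function() {
  b <- epoch_boundaries(default_kinetic_params(), log = TRUE)
  anchors <- rbind(x0 = b["start", ], Bprime = b["end_T1", ],
                   C = b["end_T1s", ], D = b["end_T2s", ],
                   E = b["end_T", ])
  colnames(anchors) <- c("S", "M")
  anchors
}

# Laplace(0, scale) via inverse CDF; deterministic under set.seed
.rlaplace <- function(n, scale) {
  u <- stats::runif(n) - 0.5
  -scale * sign(u) * log(1 - 2 * abs(u))
}

#' Sample a noisy cell population along the analytic trajectory
#'
#' Places `n_cells` cells uniformly in physical time along the closed
#' analytic trajectory of the kinetic model and adds independent Laplace
#' noise to each log coordinate, emulating the scatter of single-cell phase
#' scores around the cell cycle trajectory.
#'
#' @param params A [kinetic_params()] object.
#' @param n_cells Number of cells.
#' @param noise_scale Laplace scale per log coordinate (default 0.05 log
#'   units).
#' @param seed Optional integer seed for reproducibility.
#' @return Data frame with columns `cell_id`, `time`, `epoch`, `S_score`,
#'   `M_score` (noisy log coordinates).
#' @export
simulate_noisy_trajectory <- function(params, n_cells, noise_scale = 0.05,
                                      seed = NULL) {
  stopifnot(inherits(params, "cct_kinetic_params"), n_cells > 0)
  if (noise_scale < 0) stop("noise_scale must be nonnegative")
  if (!is.null(seed)) set.seed(seed)
  Ttot <- with(params, T1 + T1s + T2s + Tm)
  tt <- stats::runif(n_cells) * Ttot
  tr <- kinetic_trajectory(params, tt)
  data.frame(cell_id = sprintf("cell_%04d", seq_len(n_cells)),
             time = tt, epoch = tr$epoch,
             S_score = log(tr$S) + .rlaplace(n_cells, noise_scale),
             M_score = log(tr$M) + .rlaplace(n_cells, noise_scale),
             stringsAsFactors = FALSE)
}

#' Rescale epoch durations of a fitted model
#'
#' Returns a new parameter set with epoch durations multiplied by the given
#' factors; the cycle-closing initial state adapts automatically. Used to
#' explore how trajectory geometry in the score plane depends on the
#' relative durations of the transcriptional epochs (e.g. shortening `T1`
#' and `T1s` produces the anti-correlated score pattern seen in embryonic
#' stem cells).
#'
#' @param params A [kinetic_params()] object.
#' @param T1,T1s,T2s,Tm Positive scale factors applied to the respective
#'   epoch durations.
#' @return A [kinetic_params()] object.
#' @export
perturb_epochs <- function(params, T1 = 1, T1s = 1, T2s = 1, Tm = 1) {
  stopifnot(inherits(params, "cct_kinetic_params"))
  if (any(c(T1, T1s, T2s, Tm) <= 0)) stop("scale factors must be positive")
  kinetic_params(kt_S = params$kt_S, kd_S = params$kd_S,
                 kd_S2 = params$kd_S2, kt_M = params$kt_M,
                 kd_M = params$kd_M, kd_M2 = params$kd_M2,
                 p = params$p, S_f = params$S_f, M_f = params$M_f,
                 T1 = params$T1 * T1, T1s = params$T1s * T1s,
                 T2s = params$T2s * T2s, Tm = params$Tm * Tm)
}
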