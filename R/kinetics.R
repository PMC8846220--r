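#' Parameters of the piecewise-constant-rate kinetic cell cycle model
#'
#' The model follows two lumped extensive quantities, `S` (aggregate
#' expression of S-phase genes) and `M` (aggregate expression of G2/M
#' genes), through one cell cycle of duration `T = T1 + T1s + T2s + Tm`
#' via `dS/dt = kt_S(t) - kd_S(t) S` (and likewise for `M`), with
#' piecewise-constant rates over four transcriptional epochs:
#'
#' * `T1` (post-mitotic): no synthesis, active degradation at `kd_S`,
#'   `kd_M`;
#' * `T1s` (S-phase program on): synthesis `kt_S`, `kt_M`; base decay
#'   `kd_S2`, `kd_M2`;
#' * `T2s` (G2 program): S synthesis off, M synthesis boosted to
#'   `p * kt_M`; base decay;
#' * `Tm` (mitosis): all synthesis off, base decay.
#'
#' Cyclic closure requires `S(T) = S_f * S(0)` and `M(T) = M_f * M(0)`,
#' where the division drops `S_f`, `M_f` are ideally 2 but empirically
#' closer to 1.7–1.8 in droplet scRNA-seq data.
#'
#' @param kt_S,kt_M Synthesis rates (amount/hour), `>= 0`.
#' @param kd_S,kd_M Post-division active degradation rates (1/hour).
#' @param kd_S2,kd_M2 Base decay rates (1/hour).
#' @param p Transcriptional boost of G2/M synthesis during `T2s`
#'   (dimensionless, `> 0`).
#' @param S_f,M_f Division drop factors (dimensionless, `>= 1`).
#' @param T1,T1s,T2s,Tm Epoch durations (hours, `> 0`).
#' @return An object of class `cct_kinetic_params`.
#' @export
kinetic_params <- function(kt_S, kd_S, kd_S2, kt_M, kd_M, kd_M2,
                           p, S_f, M_f, T1, T1s, T2s, Tm) {
  vals <- c(kt_S = kt_S, kd_S = kd_S, kd_S2 = kd_S2, kt_M = kt_M,
            kd_M = kd_M, kd_M2 = kd_M2, p = p, S_f = S_f, M_f = M_f,
            T1 = T1, T1s = T1s, T2s = T2s, Tm = Tm)
  if (any(!is.finite(vals))) stop("all parameters must be finite")
  if (any(vals[c("kt_S", "kd_S", "kd_S2", "kt_M", "kd_M", "kd_M2")] < 0))
    stop("rates must be nonnegative")
  if (p <= 0) stop("boost factor p must be positive")
  if (S_f < 1 || M_f < 1) stop("division drops S_f, M_f must be >= 1")
  if (any(vals[c("T1", "T1s", "T2s", "Tm")] <= 0))
    stop("epoch durations must be positive")
  structure(as.list(vals), class = "cct_kinetic_params")
}

#' @export
print.cct_kinetic_params <- function(x, ...) {
  cat("Kinetic cell cycle model parameters\n")
  cat(sprintf("  S: kt = %.4g, kd (post-div) = %.4g, kd2 (base) = %.4g, drop S_f = %.3g\n",
              x$kt_S, x$kd_S, x$kd_S2, x$S_f))
  cat(sprintf("  M: kt = %.4g, kd (post-div) = %.4g, kd2 (base) = %.4g, drop M_f = %.3g, boost p = %.3g\n",
              x$kt_M, x$kd_M, x$kd_M2, x$M_f, x$p))
  cat(sprintf("  epochs (h): T1 = %.4g, T1s = %.4g, T2s = %.4g, Tm = %.4g (T = %.4g)\n",
              x$T1, x$T1s, x$T2s, x$Tm, x$T1 + x$T1s + x$T2s + x$Tm))
  invisible(x)
}

#' Default synthetic parameter set
#'
#' A realistic parameter set used as the default generating condition for
#' synthetic data and perturbation experiments: a ~20.6 h cycle with
#' `T2s/T1s = 1`, mitosis ten-fold faster than `T1s`, G2/M boost
#' `p = 2.5`, and division drops `S_f = M_f = 1.8` (the empirically
#' observed range is 1.7–1.8 rather than the ideal 2). This is a synthetic
#' stand-in constructed to have the qualitative geometry of a fast-cycling
#' sarcoma line; it is not fitted to any dataset.
#'
#' @return A [kinetic_params()] object.
#' @export
default_kinetic_params <- function() {
  kinetic_params(kt_S = 2, kd_S = 0.15, kd_S2 = 0.1,
                 kt_M = 1.5, kd_M = 0.2, kd_M2 = 0.1,
                 p = 2.5, S_f = 1.8, M_f = 1.8,
                 T1 = 8, T1s = 6, T2s = 6, Tm = 0.6)
}

#' Piecewise-constant rate schedule of the kinetic model
#'
#' @param params A [kinetic_params()] object.
#' @return Data frame with one row per epoch (`T1`, `T1s`, `T2s`, `Tm`)
#'   and columns `epoch`, `duration`, `kt_S`, `kd_S`, `kt_M`, `kd_M`.
#' @export
rate_schedule <- function(params) {
  stopifnot(inherits(params, "cct_kinetic_params"))
  with(params, data.frame(
    epoch = c("T1", "T1s", "T2s", "Tm"),
    duration = c(T1, T1s, T2s, Tm),
    kt_S = c(0, kt_S, 0, 0),
    kd_S = c(kd_S, kd_S2, kd_S2, kd_S2),
    kt_M = c(0, kt_M, p * kt_M, 0),
    kd_M = c(kd_M, kd_M2, kd_M2, kd_M2),
    stringsAsFactors = FALSE))
}

# x(t) for dx/dt = kt - kd * x, constant rates; vectorized in all arguments
.lin_kinetics <- function(x0, kt, kd, t) {
  n <- max(length(x0), length(kt), length(kd), length(t))
  x0 <- rep_len(x0, n); kt <- rep_len(kt, n)
  kd <- rep_len(kd, n); t <- rep_len(t, n)
  out <- x0 + kt * t
  dec <- kd > 0
  if (any(dec))
    out[dec] <- kt[dec] / kd[dec] +
      (x0[dec] - kt[dec] / kd[dec]) * exp(-kd[dec] * t[dec])
  out
}

#' Closed-form solution of one constant-rate segment
#'
#' Solves `dS/dt = kt_S - kd_S S`, `dM/dt = kt_M - kd_M M` with constant
#' rates over `[0, duration]`: `S(t) = kt/kd + (S_in - kt/kd) exp(-kd t)`
#' when `kd > 0`, and `S_in + kt t` when `kd = 0`.
#'
#' @param S_in,M_in Initial amounts.
#' @param rates Numeric vector or list with elements `kt_S`, `kd_S`,
#'   `kt_M`, `kd_M` (all `>= 0`).
#' @param duration Segment duration (`>= 0`).
#' @param n_samples If positive, also return the path sampled at
#'   `n_samples` equispaced times.
#' @return List with `S_out`, `M_out` and (if requested) `path`, a data
#'   frame with columns `t`, `S`, `M`.
#' @export
solve_segment <- function(S_in, M_in, rates, duration, n_samples = 0L) {
  rates <- as.list(rates)
  stopifnot(all(c("kt_S", "kd_S", "kt_M", "kd_M") %in% names(rates)))
  if (any(unlist(rates[c("kt_S", "kd_S", "kt_M", "kd_M")]) < 0))
    stop("rates must be nonnegative")
  if (duration < 0) stop("duration must be nonnegative")
  out <- list(S_out = .lin_kinetics(S_in, rates$kt_S, rates$kd_S, duration),
              M_out = .lin_kinetics(M_in, rates$kt_M, rates$kd_M, duration))
  if (n_samples > 0L) {
    tt <- seq(0, duration, length.out = n_samples)
    out$path <- data.frame(
      t = tt,
      S = .lin_kinetics(S_in, rates$kt_S, rates$kd_S, tt),
      M = .lin_kinetics(M_in, rates$kt_M, rates$kd_M, tt))
  }
  out
}

#' Cycle-closing initial state of the kinetic model
#'
#' Closed forms for `S(0)`, `M(0)` such that propagating through the four
#' epochs satisfies the circular boundary conditions `S(T) = S_f S(0)`,
#' `M(T) = M_f M(0)`:
#' \deqn{S(0) = \frac{k_t^S}{k_d^{S,2}}
#'   \frac{e^{k_d^{S,2} T_{1s}} - 1}
#'        {S_f e^{k_d^{S,2}(T_{1s}+T_{2s}+T_m)} - e^{-k_d^S T_1}}}
#' \deqn{M(0) = \frac{k_t^M}{k_d^{M,2}}
#'   \frac{p\,e^{k_d^{M,2}(T_{1s}+T_{2s})} - (p-1)e^{k_d^{M,2} T_{1s}} - 1}
#'        {M_f e^{k_d^{M,2}(T_{1s}+T_{2s}+T_m)} - e^{-k_d^M T_1}}}
#'
#' @param params A [kinetic_params()] object.
#' @return Numeric vector `c(S0, M0)`.
#' @export
initial_state <- function(params) {
  stopifnot(inherits(params, "cct_kinetic_params"))
  with(params, {
    den_S <- S_f * exp(kd_S2 * (T1s + T2s + Tm)) - exp(-kd_S * T1)
    den_M <- M_f * exp(kd_M2 * (T1s + T2s + Tm)) - exp(-kd_M * T1)
    if (abs(den_S) < 1e-12 || abs(den_M) < 1e-12)
      stop("non-closing cycle: closure denominator vanishes")
    S0 <- if (kt_S == 0) 0 else
      kt_S / kd_S2 * (exp(kd_S2 * T1s) - 1) / den_S
    M0 <- if (kt_M == 0) 0 else
      kt_M / kd_M2 *
        (p * exp(kd_M2 * (T1s + T2s)) - (p - 1) * exp(kd_M2 * T1s) - 1) /
        den_M
    c(S0 = S0, M0 = M0)
  })
}

#' Epoch-boundary coordinates of the cyclic trajectory
#'
#' Closed forms for the `(S, M)` coordinates at the five epoch borders of
#' the closed trajectory: cycle start, end of `T1`, end of `T1s`, end of
#' `T2s`, and end of the cycle (`T`), where the last point equals
#' `(S_f S(0), M_f M(0))` by construction.
#'
#' @param params A [kinetic_params()] object.
#' @param log Return natural-log coordinates (the scale in which the
#'   trajectory is piecewise close to linear)? Default `FALSE`.
#' @return A 5 x 2 matrix with rows `start`, `end_T1`, `end_T1s`,
#'   `end_T2s`, `end_T` and columns `S`, `M`.
#' @export
epoch_boundaries <- function(params, log = FALSE) {
  stopifnot(inherits(params, "cct_kinetic_params"))
  x0 <- initial_state(params)
  b <- with(params, {
    S1 <- x0[["S0"]] * exp(-kd_S * T1)
    M1 <- x0[["M0"]] * exp(-kd_M * T1)
    AS <- kt_S / kd_S2
    AM <- kt_M / kd_M2
    S2 <- AS * (1 - (1 - kd_S2 / kt_S * S1) * exp(-kd_S2 * T1s))
    M2 <- AM * (1 - (1 - kd_M2 / kt_M * M1) * exp(-kd_M2 * T1s))
    S3 <- S2 * exp(-kd_S2 * T2s)
    M3 <- p * AM * (1 - (1 - kd_M2 / (p * kt_M) * M2) * exp(-kd_M2 * T2s))
    S4 <- S3 * exp(-kd_S2 * Tm)
    M4 <- M3 * exp(-kd_M2 * Tm)
    rbind(start = c(x0[["S0"]], x0[["M0"]]), end_T1 = c(S1, M1),
          end_T1s = c(S2, M2), end_T2s = c(S3, M3), end_T = c(S4, M4))
  })
  colnames(b) <- c("S", "M")
  if (log) base::log(b) else b
}

#' Evaluate the analytic trajectory at arbitrary times
#'
#' Propagates the cycle-closing initial state through the rate schedule and
#' returns `S(t)`, `M(t)` at the requested times within one cycle.
#'
#' @param params A [kinetic_params()] object.
#' @param times Numeric vector of times in `[0, T]`.
#' @return Data frame with columns `t`, `S`, `M`, `epoch`.
#' @export
kinetic_trajectory <- function(params, times) {
  stopifnot(inherits(params, "cct_kinetic_params"))
  sched <- rate_schedule(params)
  Ttot <- sum(sched$duration)
  if (any(times < 0 | times > Ttot + 1e-9))
    stop("times must lie within one cycle [0, T]")
  x0 <- initial_state(params)
  starts <- cumsum(c(0, sched$duration[-nrow(sched)]))
  # state at the start of each epoch
  S_b <- numeric(4L); M_b <- numeric(4L)
  S_b[1L] <- x0[["S0"]]; M_b[1L] <- x0[["M0"]]
  for (i in 1:3) {
    S_b[i + 1L] <- .lin_kinetics(S_b[i], sched$kt_S[i], sched$kd_S[i],
                                 sched$duration[i])
    M_b[i + 1L] <- .lin_kinetics(M_b[i], sched$kt_M[i], sched$kd_M[i],
                                 sched$duration[i])
  }
  idx <- findInterval(pmin(times, Ttot), starts, rightmost.closed = TRUE)
  idx[idx < 1L] <- 1L; idx[idx > 4L] <- 4L
  dt <- times - starts[idx]
  data.frame(
    t = times,
    S = .lin_kinetics(S_b[idx], sched$kt_S[idx], sched$kd_S[idx], dt),
    M = .lin_kinetics(M_b[idx], sched$kt_M[idx], sched$kd_M[idx], dt),
    epoch = sched$epoch[idx],
    stringsAsFactors = FALSE)
}

#' Identifiable parameter combinations of the kinetic model
#'
#' The ten trajectory coordinates of the five epoch borders determine the
#' model parameters only through rational combinations: the two synthesis /
#' base-decay ratios, the eight dimensionless decay-duration products, the
#' division drops and the boost `p` (13 raw combinations). Two algebraic
#' relations tie the S- and M-channel duration ratios together
#' (`(kd_S2 T2s)/(kd_S2 T1s) = (kd_M2 T2s)/(kd_M2 T1s)` and likewise for
#' `Tm`), leaving 11 independent combinations.
#'
#' @param params A [kinetic_params()] object.
#' @return List with `combinations` (named numeric vector of the 13 raw
#'   combinations), `relations` (residuals of the two identities, zero by
#'   construction) and `count` (number of independent combinations, 11).
#' @export
identifiable_combinations <- function(params) {
  stopifnot(inherits(params, "cct_kinetic_params"))
  comb <- with(params, c(
    "kt_S/kd_S2" = kt_S / kd_S2,
    "kt_M/kd_M2" = kt_M / kd_M2,
    "kd_S*T1"    = kd_S * T1,
    "kd_M*T1"    = kd_M * T1,
    "kd_S2*T1s"  = kd_S2 * T1s,
    "kd_M2*T1s"  = kd_M2 * T1s,
    "kd_S2*T2s"  = kd_S2 * T2s,
    "kd_M2*T2s"  = kd_M2 * T2s,
    "kd_S2*Tm"   = kd_S2 * Tm,
    "kd_M2*Tm"   = kd_M2 * Tm,
    "S_f"        = S_f,
    "M_f"        = M_f,
    "p"          = p))
  rel <- c(
    T2s_ratio = comb[["kd_S2*T2s"]] / comb[["kd_S2*T1s"]] -
      comb[["kd_M2*T2s"]] / comb[["kd_M2*T1s"]],
    Tm_ratio = comb[["kd_S2*Tm"]] / comb[["kd_S2*T1s"]] -
      comb[["kd_M2*Tm"]] / comb[["kd_M2*T1s"]])
  list(combinations = comb, relations = rel, count = length(comb) - length(rel))
}
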