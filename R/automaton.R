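#' Linear switching hyperplane
#'
#' A hyperplane in `R^n` represented by the linear functional
#' `f(x) = b + <c, x>`. The sign of `f` tells on which side of the plane a
#' point lies; a linear segment crosses the plane iff the functional takes
#' opposite signs at its endpoints.
#'
#' @param b Scalar offset.
#' @param c Numeric normal vector; must have at least one nonzero component.
#' @return An object of class `cct_hyperplane`.
#' @examples
#' h <- hyperplane(-1, c(1, 0))   # the plane x1 = 1
#' plane_eval(h, c(2, 5))         # +1, right of the plane
#' @export
hyperplane <- function(b, c) {
  stopifnot(is.numeric(b), length(b) == 1L, is.numeric(c), length(c) >= 1L)
  if (all(c == 0)) stop("hyperplane normal must have a nonzero component")
  structure(list(b = as.numeric(b), c = as.numeric(c)),
            class = "cct_hyperplane")
}

#' Evaluate the side functional of a hyperplane
#'
#' @param plane A [hyperplane()].
#' @param x Numeric position vector of matching dimension.
#' @return The scalar `b + <c, x>`; zero exactly on the plane.
#' @export
plane_eval <- function(plane, x) {
  stopifnot(inherits(plane, "cct_hyperplane"))
  if (length(x) != length(plane$c))
    stop("dimension mismatch: point has length ", length(x),
         ", plane normal has length ", length(plane$c))
  plane$b + sum(plane$c * x)
}

#' Hybrid cell-cycle automaton specification
#'
#' Defines the deterministic automaton `A(x | s)`: an extrinsic position
#' `x` in `R^n` (log amounts of extensive quantities) moving linearly with
#' the growth vector of the current intrinsic state `s`, intrinsic-state
#' switches triggered by crossing switch hyperplanes, and a division event
#' that translates the position by a strictly negative vector `d`
#' (component `-log 2` when daughters inherit exactly half of each
#' substance) and resets the intrinsic state.
#'
#' @param states Named list of growth vectors, one per intrinsic state;
#'   names are the state labels, each vector has length `n`.
#' @param switches List of switch rules; each is a list with elements
#'   `plane` (a [hyperplane()]) and `map` (named character vector giving the
#'   image state for every state label; must be total).
#' @param division Named list mapping state labels to their division
#'   [hyperplane()]; states absent from the list have no division plane.
#' @param d Division translation vector, all components strictly negative.
#' @param s_d Post-division state label, or `NULL` to keep the intrinsic
#'   state unchanged at division.
#' @return An object of class `cct_automaton`.
#' @seealso [simulate_automaton()], [classify_asymptotics()],
#'   [cone_feasibility()]
#' @export
automaton_spec <- function(states, switches, division, d, s_d = NULL) {
  stopifnot(is.list(states), length(states) >= 1L, !is.null(names(states)))
  labels <- names(states)
  n <- length(states[[1L]])
  for (a in states)
    if (!is.numeric(a) || length(a) != n)
      stop("all growth vectors must be numeric of length ", n)
  for (sw in switches) {
    stopifnot(inherits(sw$plane, "cct_hyperplane"))
    if (length(sw$plane$c) != n) stop("switch plane dimension mismatch")
    if (!all(labels %in% names(sw$map)))
      stop("switch map must be total on the state set")
    if (!all(sw$map %in% labels))
      stop("switch map image outside the state set")
  }
  stopifnot(is.list(division))
  for (lbl in names(division)) {
    if (!lbl %in% labels) stop("division plane for unknown state ", lbl)
    stopifnot(inherits(division[[lbl]], "cct_hyperplane"))
    if (length(division[[lbl]]$c) != n) stop("division plane dimension mismatch")
  }
  stopifnot(is.numeric(d), length(d) == n)
  if (any(d >= 0)) stop("division shift d must have strictly negative components")
  if (!is.null(s_d) && !s_d %in% labels) stop("unknown post-division state ", s_d)
  structure(list(n = n, states = states, switches = switches,
                 division = division, d = as.numeric(d), s_d = s_d),
            class = "cct_automaton")
}

#' @export
print.cct_automaton <- function(x, ...) {
  cat("Hybrid switching automaton: n =", x$n,
      "| states:", paste(names(x$states), collapse = ", "),
      "| switches:", length(x$switches),
      "| division planes:", length(x$division), "\n")
  invisible(x)
}

# First hyperplane crossing along the ray x0 + a t, t > eps.
# Returns +Inf when the ray never crosses the plane ahead of x0, or when
# x0 lies on the plane itself (a plane is armed only once f is nonzero,
# which prevents re-triggering the plane an event just landed on).
.ray_crossing <- function(plane, x0, a, eps = 1e-12) {
  den <- sum(plane$c * a)
  if (abs(den) < .Machine$double.eps) return(Inf)
  f0 <- plane_eval(plane, x0)
  f_scale <- max(1, abs(plane$b) + sum(abs(plane$c * x0)))
  if (abs(f0) < 1e-9 * f_scale) return(Inf)
  t_star <- -f0 / den
  if (t_star > eps) t_star else Inf
}

#' Simulate the switching automaton
#'
#' Moves the automaton along `x(t) = x0 + a_s t` in its current intrinsic
#' state; among all switch hyperplanes and the active division plane, the
#' first crossing (smallest positive time) triggers the corresponding event.
#' Switches change the intrinsic state without moving the position; division
#' translates the position by `d` and sets the post-division state. The
#' trajectory terminates at `max_events`, `max_time`, coordinate overflow
#' (divergence) or when no plane is reachable (stalled).
#'
#' @param spec An [automaton_spec()].
#' @param x0 Initial position (finite numeric vector of length `n`).
#' @param s0 Initial state label.
#' @param max_events Maximum number of switch/division events.
#' @param max_time Maximum simulated time.
#' @param diverge_bound Coordinate magnitude beyond which the trajectory is
#'   declared divergent (log units).
#' @param eps Minimum positive crossing time; prevents re-triggering the
#'   plane the trajectory just landed on.
#' @return A data frame of breakpoints with columns `time`, `x1..xn`,
#'   `state`, `event`. Positions are recorded *after* the event is applied,
#'   so a `division` row already includes the shift by `d`. Event tags:
#'   `start`, `switch`, `division`, `end` (max_time reached), `divergent`,
#'   `stalled`.
#' @examples
#' sp <- automaton_spec(
#'   states = list(grow = c(1, 1)),
#'   switches = list(),
#'   division = list(grow = hyperplane(-1, c(0, 1))),
#'   d = c(-log(2), -log(2)), s_d = "grow")
#' simulate_automaton(sp, c(0, 0), "grow", max_events = 3)
#' @export
simulate_automaton <- function(spec, x0, s0, max_events = 1000L,
                               max_time = Inf, diverge_bound = 1e6,
                               eps = 1e-12) {
  stopifnot(inherits(spec, "cct_automaton"))
  if (!all(is.finite(x0)) || length(x0) != spec$n)
    stop("x0 must be a finite vector of length ", spec$n)
  if (!s0 %in% names(spec$states)) stop("unknown initial state ", s0)

  x <- as.numeric(x0); s <- s0; t_now <- 0
  rows <- vector("list", max_events + 2L)
  rows[[1L]] <- list(time = 0, x = x, state = s, event = "start")
  nr <- 1L
  add_row <- function(time, x, state, event) {
    nr <<- nr + 1L
    rows[[nr]] <<- list(time = time, x = x, state = state, event = event)
  }

  for (ev in seq_len(max_events)) {
    a <- spec$states[[s]]
    # candidate crossings: switch planes in declaration order, division last
    t_sw <- if (length(spec$switches))
      vapply(spec$switches, function(sw) .ray_crossing(sw$plane, x, a, eps),
             numeric(1L)) else numeric(0L)
    dplane <- spec$division[[s]]
    t_dv <- if (!is.null(dplane)) .ray_crossing(dplane, x, a, eps) else Inf
    cand <- c(t_sw, t_dv)
    if (all(!is.finite(cand))) {
      if (is.finite(max_time)) {
        x <- x + a * (max_time - t_now)
        add_row(max_time, x, s, "end")
      } else if (all(a == 0)) {
        add_row(t_now, x, s, "stalled")
      } else {
        # no plane ahead: the ray escapes to infinity
        add_row(t_now, x, s, "divergent")
      }
      break
    }
    t_min <- min(cand)
    # simultaneous crossings (non-general position): smallest plane index wins
    hit <- which(cand <= t_min * (1 + 1e-12))
    if (length(hit) > 1L)
      warning("simultaneous plane crossings at t = ", t_now + t_min,
              "; taking smallest plane index")
    hit <- hit[1L]
    if (t_now + t_min > max_time) {
      x <- x + a * (max_time - t_now)
      add_row(max_time, x, s, "end")
      break
    }
    x <- x + a * t_min
    t_now <- t_now + t_min
    if (hit <= length(t_sw)) {
      s <- unname(spec$switches[[hit]]$map[[s]])
      add_row(t_now, x, s, "switch")
    } else {
      x <- x + spec$d
      if (!is.null(spec$s_d)) s <- spec$s_d
      add_row(t_now, x, s, "division")
    }
    if (any(abs(x) > diverge_bound)) {
      add_row(t_now, x, s, "divergent")
      break
    }
  }
  rows <- rows[seq_len(nr)]
  xs <- do.call(rbind, lapply(rows, `[[`, "x"))
  colnames(xs) <- paste0("x", seq_len(spec$n))
  out <- data.frame(time = vapply(rows, `[[`, numeric(1L), "time"), xs,
                    state = vapply(rows, `[[`, character(1L), "state"),
                    event = vapply(rows, `[[`, character(1L), "event"),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Classify the asymptotic behaviour of the automaton
#'
#' Runs the automaton through `n_divisions` division events and inspects the
#' sequence of post-division positions: if they converge (successive
#' distances below `tol` over a window of 3 divisions) the trajectory is on
#' a limit cycle; if any coordinate exceeds the overflow bound it is
#' divergent; otherwise the behaviour is undecided at the simulated horizon.
#'
#' @inheritParams simulate_automaton
#' @param n_divisions Number of division events to simulate.
#' @param tol Convergence tolerance on post-division position distance.
#' @param max_period Largest division period probed for a cycle.
#' @return A list with `verdict` (`"limit_cycle"`, `"divergent"` or
#'   `"undecided"`), and for limit cycles `period` (divisions per cycle),
#'   `fixed_point` (post-division position) and `cycle_states` (intrinsic
#'   states visited during the last full cycle, in order).
#' @export
classify_asymptotics <- function(spec, x0, s0, n_divisions = 50L,
                                 tol = 1e-8, diverge_bound = 1e6,
                                 max_period = 4L) {
  traj <- simulate_automaton(spec, x0, s0,
                             max_events = 200L * n_divisions,
                             diverge_bound = diverge_bound)
  if (any(traj$event == "divergent"))
    return(list(verdict = "divergent"))
  div_idx <- which(traj$event == "division")
  if (length(div_idx) < 4L) return(list(verdict = "undecided"))
  xcols <- grep("^x", names(traj))
  P <- as.matrix(traj[div_idx, xcols, drop = FALSE])
  k <- nrow(P)
  for (p in seq_len(min(max_period, k - 3L))) {
    gaps <- vapply(0:2, function(j)
      sqrt(sum((P[k - j, ] - P[k - j - p, ])^2)), numeric(1L))
    if (all(gaps < tol)) {
      i0 <- div_idx[k - p]; i1 <- div_idx[k]
      states <- traj$state[i0:(i1 - 1L)]
      return(list(verdict = "limit_cycle", period = p,
                  fixed_point = P[k, ],
                  cycle_states = unique(states)))
    }
  }
  list(verdict = "undecided")
}

#' Convex-cone feasibility of a cyclic trajectory
#'
#' A stable cyclic trajectory of the automaton requires nonnegative dwell
#' times `lambda_i >= 0` with `sum(lambda_i a_i) + d = 0`, i.e. `-d` must
#' lie in the convex cone spanned by the growth vectors. With `m < n`
#' generic growth vectors the condition fails almost surely, which is why
#' the number of intrinsic states must be at least the trajectory
#' dimensionality (`m >= n`). Solved as a nonnegative least-squares
#' feasibility problem.
#'
#' @param growth_vectors List of numeric `n`-vectors (or an `n x m` matrix
#'   with one growth vector per column).
#' @param d Division shift vector of length `n`.
#' @param tol Residual tolerance relative to `max(1, |d|)`.
#' @return List with `feasible` (logical), `lambda` (a nonnegative witness
#'   when feasible, else `NULL`) and `residual` (attained `|A lambda + d|`).
#' @examples
#' cone_feasibility(list(c(1, 0), c(0, 1)), c(-log(2), -log(2)))
#' @export
cone_feasibility <- function(growth_vectors, d, tol = 1e-8) {
  if (is.list(growth_vectors))
    A <- if (length(growth_vectors)) do.call(cbind, growth_vectors)
         else matrix(numeric(0L), nrow = length(d), ncol = 0L)
  else A <- as.matrix(growth_vectors)
  d <- as.numeric(d)
  if (nrow(A) != length(d) && ncol(A) > 0L)
    stop("growth vectors and d must have the same dimension")
  if (ncol(A) == 0L) {
    res <- sqrt(sum(d^2))
    return(list(feasible = res <= tol, lambda = numeric(0L), residual = res))
  }
  fit <- pracma::lsqnonneg(A, -d)
  resid <- sqrt(sum((A %*% fit$x + d)^2))
  feas <- resid <= tol * max(1, sqrt(sum(d^2)))
  list(feasible = feas, lambda = if (feas) as.numeric(fit$x) else NULL,
       residual = resid)
}

#' Serialize / deserialize an automaton specification as JSON
#'
#' The JSON layout is `{"n", "states": [{"label", "a"}], "switches":
#' [{"b", "c", "map"}], "division": [{"state", "b", "c"}], "d", "s_d"}`.
#'
#' @param spec An [automaton_spec()].
#' @param path File path.
#' @return `write_automaton_json` returns `path` invisibly;
#'   `read_automaton_json` returns an [automaton_spec()].
#' @export
write_automaton_json <- function(spec, path) {
  stopifnot(inherits(spec, "cct_automaton"))
  obj <- list(
    n = spec$n,
    states = lapply(names(spec$states), function(l)
      list(label = l, a = spec$states[[l]])),
    switches = lapply(spec$switches, function(sw)
      list(b = sw$plane$b, c = sw$plane$c, map = as.list(sw$map))),
    division = lapply(names(spec$division), function(l)
      list(state = l, b = spec$division[[l]]$b, c = spec$division[[l]]$c)),
    d = spec$d,
    s_d = spec$s_d)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_automaton_json
#' @export
read_automaton_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  states <- stats::setNames(
    lapply(obj$states, function(s) as.numeric(unlist(s$a))),
    vapply(obj$states, function(s) s$label, character(1L)))
  switches <- lapply(obj$switches, function(sw)
    list(plane = hyperplane(sw$b, as.numeric(unlist(sw$c))),
         map = unlist(sw$map)))
  division <- stats::setNames(
    lapply(obj$division, function(dv)
      hyperplane(dv$b, as.numeric(unlist(dv$c)))),
    vapply(obj$division, function(dv) dv$state, character(1L)))
  automaton_spec(states, switches, division, as.numeric(unlist(obj$d)),
                 s_d = obj$s_d)
}

#' Reconstructed single-trigger toy automata
#'
#' Two-dimensional automata with one binary trigger (states `"0"` and `"1"`),
#' two constant switch maps and a division event that keeps the intrinsic
#' state, illustrating the qualitative behaviours of the switching dynamics:
#' convergence to a limit cycle vs divergence, coexistence of two limit
#' cycles, and sensitivity of the outcome to the initial position on the
#' birth hyperplane. The numeric parameters are reconstructions chosen to
#' reproduce these behaviours, not values taken from any dataset.
#'
#' @param variant One of `"cycle"` (single limit cycle, with divergent
#'   initial conditions elsewhere), `"two_cycles"` (outcome depends on the
#'   initial intrinsic state) or `"sensitive"` (an interval of birth
#'   positions converges, flanked by divergent intervals).
#' @return An [automaton_spec()].
#' @export
toy_single_trigger_spec <- function(variant = c("cycle", "two_cycles",
                                                "sensitive")) {
  variant <- match.arg(variant)
  d <- c(-log(2), -log(2))
  if (variant == "two_cycles") {
    # identical growth, state-specific division heights; switches unreachable
    return(automaton_spec(
      states = list("0" = c(1, 1), "1" = c(1, 1)),
      switches = list(
        list(plane = hyperplane(-100, c(1, 0)), map = c("0" = "1", "1" = "1")),
        list(plane = hyperplane(100, c(1, 0)), map = c("0" = "0", "1" = "0"))),
      division = list("0" = hyperplane(-1, c(0, 1)),
                      "1" = hyperplane(-2, c(0, 1))),
      d = d, s_d = NULL))
  }
  if (variant == "sensitive") {
    # State 1 grows up-left; the vertical reset plane x1 = 0.6 re-arms the
    # trigger, x1 = 1 fires it, and x1 = 1.05 is only reachable from far
    # right starts, which then escape. The first division component is tuned
    # so that the post-division map is neutral inside the convergent basin.
    return(automaton_spec(
      states = list("0" = c(1, 0), "1" = c(-0.5, 1)),
      switches = list(
        list(plane = hyperplane(-0.6, c(1, 0)), map = c("0" = "0", "1" = "0")),
        list(plane = hyperplane(-1, c(1, 0)), map = c("0" = "1", "1" = "1")),
        list(plane = hyperplane(-1.05, c(1, 0)), map = c("0" = "0", "1" = "0"))),
      division = list("1" = hyperplane(-1, c(0, 1))),
      d = c(0.1 - 0.5 * (1 - log(2)), -log(2)), s_d = NULL))
  }
  automaton_spec(
    states = list("0" = c(1, 0), "1" = c(0, 1)),
    switches = list(
      # L-: dropping below x2 = 0.5 switches the trigger off
      list(plane = hyperplane(-0.5, c(0, 1)), map = c("0" = "0", "1" = "0")),
      # L+: reaching x1 = 1 switches the trigger on
      list(plane = hyperplane(-1, c(1, 0)), map = c("0" = "1", "1" = "1"))),
    division = list("1" = hyperplane(-1, c(0, 1))),
    d = d, s_d = NULL)
}
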