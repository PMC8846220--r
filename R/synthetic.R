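# closed-form solution of a scalar piecewise-constant-rate cycle:
# dx/dt = kt_i - kd_i x on epoch i, with periodic closure x(T) = drop * x(0)
.periodic_piecewise <- function(kt, kd, dur, drop) {
  stopifnot(length(kt) == length(kd), length(kd) == length(dur))
  prop <- function(x0, i, t) .lin_kinetics(x0, kt[i], kd[i], t)
  alpha <- exp(-sum(kd * dur))
  beta <- 0
  for (i in seq_along(dur)) beta <- prop(beta, i, dur[i])
  if (abs(drop - alpha) < 1e-12) stop("non-closing cycle for program")
  x0 <- beta / (drop - alpha)
  starts <- cumsum(c(0, dur[-length(dur)]))
  xb <- numeric(length(dur)); xb[1L] <- x0
  for (i in seq_along(dur)[-1L]) xb[i] <- prop(xb[i - 1L], i - 1L, dur[i - 1L])
  function(t) {
    i <- pmin(findInterval(t, starts, rightmost.closed = TRUE),
              length(dur))
    i[i < 1L] <- 1L
    dt <- t - starts[i]
    x0i <- xb[i]; kti <- kt[i]; kdi <- kd[i]
    decay <- kdi > 0
    out <- x0i + kti * dt
    if (any(decay))
      out[decay] <- kti[decay] / kdi[decay] +
        (x0i[decay] - kti[decay] / kdi[decay]) * exp(-kdi[decay] * dt[decay])
    out
  }
}

#' Configuration for the synthetic cell cycle count generator
#'
#' Defines the study conditions emulated by [generate_cct_counts()]: a
#' population of cells placed along one analytic cell cycle, with four
#' epoch-specific gene programs (synthesis on only during their epoch, base
#' decay elsewhere), background genes following a rising cell-size trend,
#' totals that increase along the cycle and drop by the division factor
#' (default 1.8, the empirically observed value, rather than the ideal 2),
#' and negative binomial count sampling.
#'
#' @param n_cells,n_genes Matrix dimensions (default 2000 x 1000).
#' @param params Generating [kinetic_params()] (epoch durations and drop
#'   factors are taken from here).
#' @param n_program_genes Genes per epoch program (default 50, 4
#'   programs).
#' @param program_decay Base decay rate of program activities (1/hour).
#' @param mean_expression Log-normal location of per-gene baseline counts.
#' @param dispersion Negative binomial dispersion (variance
#'   `mu + dispersion * mu^2`); 0 gives Poisson sampling.
#' @param dropout Probability of zeroing any count (technical drop-out).
#' @param seed Integer seed.
#' @return List of class `cct_synth_config`.
#' @export
synth_config <- function(n_cells = 2000L, n_genes = 1000L,
                         params = default_kinetic_params(),
                         n_program_genes = 50L, program_decay = 0.15,
                         mean_expression = log(5), dispersion = 0.1,
                         seed = 1L, dropout = 0) {
  stopifnot(inherits(params, "cct_kinetic_params"),
            n_cells > 0, n_genes > 4L * n_program_genes,
            dispersion >= 0, dropout >= 0, dropout <= 1)
  structure(list(n_cells = as.integer(n_cells),
                 n_genes = as.integer(n_genes), params = params,
                 n_program_genes = as.integer(n_program_genes),
                 program_decay = program_decay,
                 mean_expression = mean_expression,
                 dispersion = dispersion, dropout = dropout,
                 seed = as.integer(seed)),
            class = "cct_synth_config")
}

# expected expression matrix (genes x length(t)) on the noiseless cycle
.synth_expected <- function(config, tt, base, program_of) {
  pr <- config$params
  dur <- c(pr$T1, pr$T1s, pr$T2s, pr$Tm)
  drop <- pr$S_f
  acts <- lapply(1:4, function(e) {
    kt <- numeric(4L); kt[e] <- 1
    .periodic_piecewise(kt, rep(config$program_decay, 4L), dur, drop)
  })
  # background follows linear cell growth closing at the same drop factor
  size <- .periodic_piecewise(c(1, 1, 1, 1), rep(0, 4L), dur, drop)
  Ttot <- sum(dur)
  grid <- seq(0, Ttot, length.out = 201L)
  prof <- rbind(t(vapply(acts, function(f) f(tt), numeric(length(tt)))),
                size(tt))
  norms <- c(vapply(acts, function(f) mean(f(grid)), numeric(1L)),
             mean(size(grid)))
  prof <- prof / norms
  base * prof[ifelse(program_of == 0L, 5L, program_of), , drop = FALSE]
}

#' Generate a synthetic cell-cycling count matrix with ground truth
#'
#' Cells are placed uniformly in physical time along the analytic cycle of
#' the generating kinetic parameters. Each of the four epoch programs
#' (`T1`, `T1s`, `T2s`, `Tm`) drives a block of genes whose expected
#' expression rises while the program's epoch is active and decays
#' elsewhere, so the population traces a piecewise-smooth loop in gene
#' space with direction changes at the epoch switches; background genes
#' follow a monotone cell-size trend. Expected totals rise along the cycle
#' and drop by the division factor `S_f` at the start, and counts are
#' sampled per gene and cell from a negative binomial (or Poisson) law
#' with optional drop-out.
#'
#' @param config A [synth_config()].
#' @return List with `counts` (genes x cells integer matrix), `truth`
#'   (per-cell data frame: `cell_id`, `time`, `phase` in `[0,1)`, `epoch`,
#'   `expected_total`), `programs` (gene index list per program),
#'   `switch_phases` (cycle fractions of the epoch boundaries) and
#'   `config`.
#' @export
generate_cct_counts <- function(config = synth_config()) {
  stopifnot(inherits(config, "cct_synth_config"))
  set.seed(config$seed)
  pr <- config$params
  dur <- c(pr$T1, pr$T1s, pr$T2s, pr$Tm)
  Ttot <- sum(dur)
  tt <- sort(stats::runif(config$n_cells) * Ttot)
  npg <- config$n_program_genes
  program_of <- rep(0L, config$n_genes)
  program_of[seq_len(4L * npg)] <- rep(1:4, each = npg)
  base <- stats::rlnorm(config$n_genes, config$mean_expression, 0.5)
  mu <- .synth_expected(config, tt, base, program_of)
  counts <- matrix(0L, config$n_genes, config$n_cells)
  if (config$dispersion > 0) {
    counts[] <- stats::rnbinom(length(mu), mu = as.numeric(mu),
                               size = 1 / config$dispersion)
  } else {
    counts[] <- stats::rpois(length(mu), as.numeric(mu))
  }
  if (config$dropout > 0) {
    keep <- stats::rbinom(length(counts), 1L, 1 - config$dropout)
    counts <- counts * keep
  }
  storage.mode(counts) <- "integer"
  rownames(counts) <- sprintf("gene_%04d", seq_len(config$n_genes))
  colnames(counts) <- sprintf("cell_%04d", seq_len(config$n_cells))
  epoch_names <- c("T1", "T1s", "T2s", "Tm")
  starts <- cumsum(c(0, dur[-4L]))
  epoch <- epoch_names[pmin(findInterval(tt, starts), 4L)]
  truth <- data.frame(cell_id = colnames(counts), time = tt,
                      phase = tt / Ttot,
                      epoch = factor(epoch, levels = epoch_names),
                      expected_total = colSums(mu),
                      stringsAsFactors = FALSE)
  programs <- split(seq_len(4L * npg), rep(epoch_names, each = npg))
  list(counts = counts, truth = truth, programs = programs,
       switch_phases = cumsum(dur)[1:3] / Ttot, config = config)
}

#' Directions of the trajectory segments in expression space
#'
#' Computes, from the noiseless expected trajectory of a synthetic
#' configuration, the unit movement direction of each transcriptional
#' epoch in `ln(x+1)` gene space, plus the division jump direction. By the
#' cyclic closure the five vectors sum to zero, so they span (at most) a
#' four-dimensional subspace: their [effective_rank()] is the expected
#' embedding dimensionality of the trajectory.
#'
#' @param config A [synth_config()].
#' @return A 5 x n_genes matrix of unit row vectors (`T1`, `T1s`, `T2s`,
#'   `Tm`, `division`).
#' @export
epoch_direction_matrix <- function(config = synth_config()) {
  stopifnot(inherits(config, "cct_synth_config"))
  set.seed(config$seed)
  pr <- config$params
  dur <- c(pr$T1, pr$T1s, pr$T2s, pr$Tm)
  npg <- config$n_program_genes
  program_of <- rep(0L, config$n_genes)
  program_of[seq_len(4L * npg)] <- rep(1:4, each = npg)
  base <- stats::rlnorm(config$n_genes, config$mean_expression, 0.5)
  bt <- c(0, cumsum(dur))
  mu <- .synth_expected(config, bt, base, program_of)
  L <- t(log1p(mu))              # 5 boundary points in lognorm space
  segs <- rbind(diff(L), L[1L, ] - L[5L, ])
  segs <- segs / sqrt(rowSums(segs^2))
  rownames(segs) <- c("T1", "T1s", "T2s", "Tm", "division")
  segs
}

#' Generate (optionally jittered) turning points from known parameters
#'
#' Log-scale epoch boundaries of the analytic trajectory, with optional
#' Gaussian jitter, for parameter-recovery experiments with
#' [fit_turning_points()].
#'
#' @param params A [kinetic_params()].
#' @param jitter Gaussian standard deviation added to each log coordinate.
#' @param seed Optional integer seed.
#' @return A [turning_points()] matrix.
#' @export
generate_turning_points <- function(params, jitter = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tp <- epoch_boundaries(params, log = TRUE)
  if (jitter > 0) tp <- tp + stats::rnorm(length(tp), 0, jitter)
  d <- as.matrix(stats::dist(tp))
  diag(d) <- Inf
  if (any(d < 1e-8))
    warning("coincident turning points (degenerate epoch durations)")
  suppressWarnings(turning_points(tp))
}
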