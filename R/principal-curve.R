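#' Fit an elastic principal curve or principal circle
#'
#' Fits a polyline (open) or polygon (closed) with `q` nodes to a point
#' cloud by alternating nearest-node partitioning with a penalized
#' least-squares node update, minimizing
#' \deqn{U = \frac1N\sum_i \|x_i - y_{p(i)}\|^2
#'   + \lambda \sum_{(i,j)\in E} \|y_i - y_j\|^2
#'   + \mu \sum_i \|y_{i-1} - 2y_i + y_{i+1}\|^2,}
#' a stretching penalty on edges plus a bending penalty on node stars.
#' Both steps decrease `U`, so the fit is monotone. An open curve is
#' obtained by first fitting a closed curve with `q + 1` nodes, deleting
#' the node with the fewest projected points, and refitting the resulting
#' `q`-node path without the closing edge.
#'
#' @param points Numeric matrix, one row per data point.
#' @param q Number of nodes (`>= 3`).
#' @param closed Fit a principal circle (`TRUE`) or an open curve?
#' @param lambda Stretching penalty weight.
#' @param mu Bending penalty weight.
#' @param max_iter,tol Iteration cap and relative energy-decrease
#'   tolerance.
#' @return An object of class `cct_principal_curve`: list with `nodes`
#'   (`q x d`), `closed`, `partition` (nearest node per point), `energy`
#'   (trace over iterations), `lambda`, `mu`.
#' @export
fit_principal_curve <- function(points, q = 30L, closed = TRUE,
                                lambda = 0.01, mu = 0.1,
                                max_iter = 100L, tol = 1e-6) {
  points <- as.matrix(points)
  N <- nrow(points)
  if (q < 3L) stop("need at least 3 nodes")
  if (N < q) stop("need at least as many points as nodes")
  if (all(apply(points, 2L, stats::sd) == 0))
    stop("degenerate input: all points identical")
  if (!closed) {
    cfit <- fit_principal_curve(points, q = q + 1L, closed = TRUE,
                                lambda = lambda, mu = mu,
                                max_iter = max_iter, tol = tol)
    tab <- tabulate(cfit$partition, q + 1L)
    drop_i <- which.min(tab)
    keep <- c(seq_len(q + 1L)[-seq_len(drop_i)], seq_len(drop_i - 1L))
    nodes0 <- cfit$nodes[keep, , drop = FALSE]  # open path after the gap
    return(.fit_elastic(points, nodes0, closed = FALSE, lambda = lambda,
                        mu = mu, max_iter = max_iter, tol = tol))
  }
  # initialize on an ellipse in the plane of the two leading PCs
  ctr <- colMeans(points)
  pc <- svd(sweep(points, 2L, ctr), nu = 0L, nv = 2L)
  r1 <- pc$d[1L] / sqrt(N) * sqrt(2)
  r2 <- if (length(pc$d) > 1L) pc$d[2L] / sqrt(N) * sqrt(2) else r1
  ang <- 2 * pi * (seq_len(q) - 1L) / q
  nodes0 <- outer(cos(ang) * r1, pc$v[, 1L]) +
    outer(sin(ang) * r2, pc$v[, min(2L, ncol(pc$v))])
  nodes0 <- sweep(nodes0, 2L, ctr, `+`)
  .fit_elastic(points, nodes0, closed = TRUE, lambda = lambda, mu = mu,
               max_iter = max_iter, tol = tol)
}

# squared distances point rows -> node rows
.sqdist <- function(points, nodes) {
  pn <- rowSums(points^2); nn <- rowSums(nodes^2)
  d2 <- outer(pn, nn, `+`) - 2 * tcrossprod(points, nodes)
  d2[d2 < 0] <- 0
  d2
}

.elastic_matrices <- function(q, closed) {
  if (closed) {
    e1 <- seq_len(q); e2 <- c(2:q, 1L)
  } else {
    e1 <- seq_len(q - 1L); e2 <- 2:q
  }
  Es <- matrix(0, length(e1), q)
  Es[cbind(seq_along(e1), e1)] <- 1
  Es[cbind(seq_along(e1), e2)] <- -1
  ctr <- if (closed) seq_len(q) else 2:(q - 1L)
  Eb <- matrix(0, length(ctr), q)
  for (r in seq_along(ctr)) {
    i <- ctr[r]
    prev <- if (i == 1L) q else i - 1L
    nxt <- if (i == q) 1L else i + 1L
    Eb[r, prev] <- 1; Eb[r, i] <- -2; Eb[r, nxt] <- 1
  }
  list(Ls = crossprod(Es), Lb = crossprod(Eb), Es = Es, Eb = Eb)
}

.fit_elastic <- function(points, nodes, closed, lambda, mu, max_iter, tol) {
  N <- nrow(points); q <- nrow(nodes)
  mats <- .elastic_matrices(q, closed)
  energy <- function(nodes, part) {
    d2 <- rowSums((points - nodes[part, , drop = FALSE])^2)
    mean(d2) + lambda * sum((mats$Es %*% nodes)^2) +
      mu * sum((mats$Eb %*% nodes)^2)
  }
  en <- Inf; trace <- numeric(0L); part <- NULL
  for (it in seq_len(max_iter)) {
    d2 <- .sqdist(points, nodes)
    part <- max.col(-d2, ties.method = "first")
    cnt <- tabulate(part, q)
    B <- matrix(0, q, ncol(points))
    sums <- rowsum(points, part)
    B[as.integer(rownames(sums)), ] <- sums
    Mmat <- diag(cnt / N, q) + lambda * mats$Ls + mu * mats$Lb
    if (any(cnt == 0L) && lambda == 0 && mu == 0)
      diag(Mmat)[cnt == 0L] <- 1e-9
    nodes <- solve(Mmat, B / N)
    e_new <- energy(nodes, part)
    trace <- c(trace, e_new)
    if (is.finite(en) && (en - e_new) <= tol * abs(en)) { en <- e_new; break }
    en <- e_new
  }
  d2 <- .sqdist(points, nodes)
  part <- max.col(-d2, ties.method = "first")
  structure(list(nodes = nodes, closed = closed, partition = part,
                 energy = trace, lambda = lambda, mu = mu),
            class = "cct_principal_curve")
}

#' @export
print.cct_principal_curve <- function(x, ...) {
  cat(sprintf("%s elastic principal curve: %d nodes, %d-dim, final energy %.4g\n",
              if (x$closed) "Closed" else "Open", nrow(x$nodes),
              ncol(x$nodes), utils::tail(x$energy, 1L)))
  invisible(x)
}

#' Total polyline length of a principal curve
#'
#' @param curve A [fit_principal_curve()] object.
#' @return Sum of edge lengths (including the closing edge if closed).
#' @export
curve_length <- function(curve) {
  stopifnot(inherits(curve, "cct_principal_curve"))
  nd <- curve$nodes
  segs <- diff(nd)
  len <- sum(sqrt(rowSums(segs^2)))
  if (curve$closed)
    len <- len + sqrt(sum((nd[1L, ] - nd[nrow(nd), ])^2))
  len
}

#' Continuous pseudotime along a principal curve
#'
#' Projects each point onto its nearest curve edge and measures the
#' geodesic distance from the root node in edge units: integer part = the
#' number of edges from the root, fractional part = position along the
#' projection edge. For an open curve with `q` nodes pseudotime spans
#' `[0, q - 1]`; for a closed curve it spans `[0, q)`. If a per-cell
#' scalar (typically the initial total read count) is supplied, the root
#' and the orientation are chosen so that the scalar increases with
#' pseudotime (largest positive rank correlation); the root of a closed
#' curve defaults to the node just after the steepest drop of the scalar
#' (the division gap).
#'
#' @param curve A [fit_principal_curve()] object.
#' @param points The data matrix used for the fit (or new points).
#' @param root Root node index (1-based). Open curves require an endpoint
#'   (`1` or `q`). `NULL` with `orient_scalar` given = automatic.
#' @param orient_scalar Optional per-cell scalar used to orient the curve.
#' @return Numeric vector of pseudotimes with attributes `root` and
#'   `reversed`.
#' @export
assign_pseudotime <- function(curve, points, root = NULL,
                              orient_scalar = NULL) {
  stopifnot(inherits(curve, "cct_principal_curve"))
  points <- as.matrix(points)
  nd <- curve$nodes; q <- nrow(nd)
  n_edges <- if (curve$closed) q else q - 1L
  edge_from <- seq_len(n_edges)
  edge_to <- if (curve$closed) c(2:q, 1L) else 2:q
  best_d2 <- rep(Inf, nrow(points))
  best_edge <- integer(nrow(points)); best_frac <- numeric(nrow(points))
  for (e in seq_len(n_edges)) {
    a <- nd[edge_from[e], ]; b <- nd[edge_to[e], ]
    ab <- b - a; len2 <- sum(ab^2)
    tt <- if (len2 > 0)
      pmin(1, pmax(0, (sweep(points, 2L, a) %*% ab) / len2)) else
      matrix(0, nrow(points), 1L)
    proj <- sweep(outer(as.numeric(tt), ab), 2L, a, `+`)
    d2 <- rowSums((points - proj)^2)
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]; best_edge[upd] <- e
    best_frac[upd] <- tt[upd]
  }
  s_raw <- (best_edge - 1L) + best_frac   # arc position from node 1
  smax <- if (curve$closed) q else q - 1L
  reroot <- function(s, r) if (curve$closed) (s - (r - 1L)) %% q else s
  flip <- function(s) if (curve$closed) (q - s) %% q else (q - 1L) - s
  pre_flip <- FALSE
  if (is.null(root)) {
    if (!curve$closed || is.null(orient_scalar)) root <- 1L
    else {
      # choose root and traversal direction so that the per-node median of
      # the scalar increases along the cycle (division gap at the root)
      med <- vapply(seq_len(q), function(i) {
        v <- orient_scalar[curve$partition == i]
        if (length(v)) stats::median(v) else NA_real_
      }, numeric(1L))
      med <- stats::approx(seq_len(q)[!is.na(med)], med[!is.na(med)],
                           xout = seq_len(q), rule = 2L)$y
      best <- c(rho = -Inf, r = 1L, dir = 1L)
      for (r in seq_len(q)) for (dir in c(1L, -1L)) {
        ord <- ((r - 1L + dir * (0:(q - 1L))) %% q) + 1L
        rho <- suppressWarnings(
          stats::cor(seq_len(q), med[ord], method = "spearman"))
        if (!is.na(rho) && rho > best[["rho"]])
          best <- c(rho = rho, r = r, dir = dir)
      }
      root <- as.integer(best[["r"]])
      pre_flip <- best[["dir"]] < 0
    }
  }
  if (!curve$closed && !root %in% c(1L, q))
    stop("root of an open curve must be an endpoint node (1 or q)")
  s <- reroot(s_raw, root)
  if (pre_flip) s <- flip(s)
  if (!curve$closed && root == q) s <- flip(s)
  reversed <- FALSE
  if (!is.null(orient_scalar)) {
    cor_fwd <- suppressWarnings(stats::cor(s, orient_scalar,
                                           method = "spearman"))
    cor_rev <- suppressWarnings(stats::cor(flip(s), orient_scalar,
                                           method = "spearman"))
    if (is.na(cor_fwd) || is.na(cor_rev)) {
      # constant scalar: keep forward orientation
    } else {
      if (cor_fwd < 0 && cor_rev < 0)
        warning("ambiguous root: both orientations give negative ",
                "correlation; picking the larger one")
      if (cor_rev > cor_fwd) { s <- flip(s); reversed <- TRUE }
    }
  }
  attr(s, "root") <- root
  attr(s, "reversed") <- reversed
  attr(s, "range") <- c(0, smax)
  s
}

#' Curvature profile of a principal curve
#'
#' Interpolates each node coordinate as a cubic spline function of the
#' natural parameter (node index in edge units, matching pseudotime) and
#' evaluates at each node the Euclidean norm of the second-derivative
#' vector. Sharp turns of the trajectory appear as peaks; for cell cycle
#' trajectories these mark the switches between transcriptional epochs.
#' Closed curves are handled by cyclic padding of the node sequence.
#'
#' @param curve A [fit_principal_curve()] object with at least 5 nodes.
#' @param prominence Peaks must reach this fraction of the maximum
#'   curvature.
#' @param max_peaks Report at most this many peaks.
#' @param normalize Divide the second derivative by squared local speed
#'   (approximate Frenet normalization)? Default `FALSE` (nodes are
#'   approximately equispaced along the curve).
#' @return List with `s` (node pseudotimes `0..q-1`), `curvature`
#'   (nonnegative, length `q`), and `peaks` (pseudotimes of retained local
#'   maxima, decreasing curvature order).
#' @export
curvature_profile <- function(curve, prominence = 0.25, max_peaks = 5L,
                              normalize = FALSE) {
  stopifnot(inherits(curve, "cct_principal_curve"))
  nd <- curve$nodes; q <- nrow(nd)
  if (q < 5L) stop("need at least 5 nodes for curvature estimation")
  if (anyDuplicated(round(nd, 12L)) > 0L)
    stop("duplicate node positions")
  pad <- 3L
  if (curve$closed) {
    idx <- c((q - pad + 1L):q, seq_len(q), seq_len(pad))
    ss <- (-pad):(q + pad - 1L)
    ndp <- nd[idx, , drop = FALSE]
  } else {
    ss <- 0:(q - 1L); ndp <- nd
  }
  d2 <- vapply(seq_len(ncol(nd)), function(k) {
    f <- stats::splinefun(ss, ndp[, k], method = "natural")
    f(0:(q - 1L), deriv = 2L)
  }, numeric(q))
  d2 <- matrix(d2, nrow = q)
  R <- sqrt(rowSums(d2^2))
  if (normalize) {
    d1 <- vapply(seq_len(ncol(nd)), function(k) {
      f <- stats::splinefun(ss, ndp[, k], method = "natural")
      f(0:(q - 1L), deriv = 1L)
    }, numeric(q))
    speed2 <- rowSums(matrix(d1, nrow = q)^2)
    R <- R / pmax(speed2, .Machine$double.eps)
  }
  nxt <- function(i) if (curve$closed) (i %% q) + 1L else pmin(i + 1L, q)
  prv <- function(i) if (curve$closed) ((i - 2L) %% q) + 1L else pmax(i - 1L, 1L)
  is_peak <- vapply(seq_len(q), function(i) {
    if (!curve$closed && (i == 1L || i == q)) return(FALSE)
    R[i] >= R[nxt(i)] && R[i] > R[prv(i)]
  }, logical(1L))
  cand <- which(is_peak & R >= prominence * max(R))
  cand <- cand[order(R[cand], decreasing = TRUE)]
  if (length(cand) > max_peaks) cand <- cand[seq_len(max_peaks)]
  list(s = 0:(q - 1L), curvature = R, peaks = cand - 1L)
}

#' Segment pseudotime into transcriptional epochs
#'
#' Cuts the pseudotime axis at the supplied boundaries (typically
#' curvature peaks) and labels each cell with its segment. For a closed
#' curve the first segment wraps around from the last boundary through 0.
#'
#' @param pseudotime Per-cell pseudotime.
#' @param boundaries Increasing boundary pseudotimes inside the range.
#' @param labels Optional segment labels (length `length(boundaries) + 1`
#'   for open, `length(boundaries)` for closed/cyclic cuts when the first
#'   boundary is 0).
#' @param cyclic Treat the axis as cyclic?
#' @return Factor of per-cell segment labels.
#' @export
segment_epochs <- function(pseudotime, boundaries, labels = NULL,
                           cyclic = TRUE) {
  boundaries <- sort(boundaries)
  if (cyclic) {
    k <- length(boundaries)
    seg <- findInterval(pseudotime, boundaries)
    seg[seg == 0L] <- k    # values before the first boundary wrap around
    if (is.null(labels)) labels <- paste0("seg", seq_len(k))
  } else {
    seg <- findInterval(pseudotime, boundaries) + 1L
    if (is.null(labels)) labels <- paste0("seg", seq_len(length(boundaries) + 1L))
  }
  factor(labels[seg], levels = labels)
}
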