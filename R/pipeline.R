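#' Pool raw counts from k-nearest-neighbour cells
#'
#' Compensates technical drop-out by summing, for every cell, its own raw
#' counts and those of its k nearest neighbours (computed on an initial
#' normalization). The output stays integer-valued.
#'
#' @param counts Genes x cells count matrix (dense or `Matrix` sparse).
#' @param knn List of integer neighbour index vectors, one per cell, not
#'   including the cell itself (it is added implicitly). Empty vectors
#'   leave the cell unpooled.
#' @return Pooled genes x cells matrix of the same class family.
#' @export
pool_neighbor_counts <- function(counts, knn) {
  n_cells <- ncol(counts)
  if (length(knn) != n_cells)
    stop("need one neighbour vector per cell")
  for (i in seq_len(n_cells)) {
    nb <- knn[[i]]
    if (length(nb)) {
      if (any(nb == i)) stop("cell ", i, " lists itself as a neighbour")
      if (any(nb < 1L | nb > n_cells)) stop("neighbour index out of range")
    }
  }
  deg <- lengths(knn)
  A <- Matrix::sparseMatrix(i = c(unlist(knn), seq_len(n_cells)),
                            j = c(rep.int(seq_len(n_cells), deg),
                                  seq_len(n_cells)),
                            x = 1, dims = c(n_cells, n_cells))
  out <- counts %*% A
  dimnames(out) <- dimnames(counts)
  out
}

# brute-force Euclidean kNN on an embedding (rows = cells)
.knn_list <- function(emb, k) {
  d <- as.matrix(stats::dist(emb))
  diag(d) <- Inf
  lapply(seq_len(nrow(emb)), function(i)
    order(d[i, ])[seq_len(min(k, nrow(emb) - 1L))])
}

.row_vars <- function(m) {
  # works for both dense and Matrix classes
  mu <- Matrix::rowMeans(m)
  Matrix::rowMeans(m^2) - mu^2
}

# log-normalize + variable genes + PCA on a counts-like matrix
.embed <- function(mat, n_var_genes, n_pc) {
  logm <- log1p(mat)
  v <- .row_vars(logm)
  vg <- order(v, decreasing = TRUE)[seq_len(min(n_var_genes, nrow(mat)))]
  X <- t(as.matrix(logm[vg, , drop = FALSE]))
  rank <- min(n_pc, ncol(X), nrow(X) - 1L)
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE, rank. = rank)
  list(lognorm = logm, var_genes = vg, embedding = pc$x)
}

#' Initial library-size normalization, embedding and kNN graph
#'
#' First-pass processing of a raw count matrix: scale every cell to the
#' global median total count, `ln(x+1)`-transform, select the most variable
#' genes, reduce by PCA and build a Euclidean kNN graph in the reduced
#' space. The graph feeds [pool_neighbor_counts()]; the raw per-cell totals
#' are kept, as they carry the cell cycle progression signal.
#'
#' @param counts Genes x cells raw count matrix.
#' @param n_var_genes Number of most-variable genes retained (capped at
#'   the gene count; default 10000).
#' @param n_pc Number of principal components (default 30).
#' @param k Number of nearest neighbours (default 10).
#' @return List with `lognorm` (genes x cells), `scale_factors`, `totals`
#'   (raw totals), `var_genes` (indices), `embedding` (cells x n_pc) and
#'   `knn` (list of neighbour indices).
#' @export
initial_normalize <- function(counts, n_var_genes = 10000L, n_pc = 30L,
                              k = 10L) {
  if (ncol(counts) < 2L) stop("need at least 2 cells")
  totals <- Matrix::colSums(counts)
  if (any(totals == 0)) {
    bad <- colnames(counts)[totals == 0]
    if (is.null(bad)) bad <- which(totals == 0)
    stop("all-zero cells: ", paste(bad, collapse = ", "))
  }
  sf <- stats::median(totals) / totals
  scaled <- counts %*% Matrix::Diagonal(x = sf)
  dimnames(scaled) <- dimnames(counts)
  emb <- .embed(scaled, n_var_genes, n_pc)
  list(lognorm = emb$lognorm, scale_factors = sf, totals = totals,
       var_genes = emb$var_genes, embedding = emb$embedding,
       knn = .knn_list(emb$embedding, k))
}

# per-node positions along the rerooted pseudotime axis
.node_positions <- function(q, root, reversed) {
  pos <- (seq_len(q) - root) %% q
  if (reversed) pos <- (q - pos) %% q
  pos
}

#' Trajectory-based library-size renormalization
#'
#' Renormalizes each cell to the smoothed local median total count at its
#' position along the cell cycle trajectory, so that totals keep their
#' rising-then-halving pattern instead of being flattened by global
#' library-size normalization. Steps: (a) the anomalously wide node
#' partition — the one mixing pre-division cells (largest totals) with
#' newborn cells (smallest totals) — is detected by its interquartile
#' range and split at the antimode of its totals distribution between the
#' two neighbouring partitions; (b) per-partition median totals are
#' smoothed along pseudotime with cyclic boundaries; (c) every cell is
#' scaled so its total matches the smoothed median at its pseudotime;
#' (d) counts are re-pooled on a kNN graph recomputed from the
#' renormalized data, `ln(x+1)`-transformed and variable genes reselected.
#'
#' @param counts Raw (or pooled raw) genes x cells counts.
#' @param curve Closed [fit_principal_curve()] object from the initial
#'   pass.
#' @param pseudotime Per-cell pseudotime from [assign_pseudotime()] (with
#'   its `root` / `reversed` attributes).
#' @param totals Per-cell totals used for the split (default raw column
#'   sums of `counts`).
#' @param iqr_factor A partition is "anomalously wide" when its IQR
#'   exceeds `iqr_factor` times the median IQR across partitions.
#' @param smooth_window Cyclic running-mean window (in nodes) for the
#'   median smoothing.
#' @param n_var_genes,n_pc,k As in [initial_normalize()].
#' @return List with `norm_counts` (rescaled counts), `pooled_lognorm`
#'   (after re-pooling and log transform), `scale_factors`, `embedding`,
#'   `knn`, `var_genes`, `node_medians` (raw and smoothed, in pseudotime
#'   order) and `split` (wide node, threshold, sub-partition medians and
#'   their ratio).
#' @export
trajectory_normalize <- function(counts, curve, pseudotime,
                                 totals = NULL, iqr_factor = 3,
                                 smooth_window = 3L,
                                 n_var_genes = 10000L, n_pc = 30L,
                                 k = 10L) {
  stopifnot(inherits(curve, "cct_principal_curve"))
  if (!curve$closed) stop("trajectory normalization expects a closed curve")
  q <- nrow(curve$nodes)
  if (q < 3L) stop("need at least 3 partitions")
  if (is.null(totals)) totals <- Matrix::colSums(counts)
  part <- curve$partition
  root <- attr(pseudotime, "root") %||% 1L
  reversed <- isTRUE(attr(pseudotime, "reversed"))
  pos <- .node_positions(q, root, reversed)

  iqr <- vapply(seq_len(q), function(i) {
    v <- totals[part == i]
    if (length(v) >= 2L) stats::IQR(v) else 0
  }, numeric(1L))
  wide <- which.max(iqr)
  split_info <- list(wide_node = NA_integer_, threshold = NA_real_,
                     median_high = NA_real_, median_low = NA_real_,
                     drop_ratio = NA_real_)
  part2 <- part
  if (iqr[wide] > iqr_factor * stats::median(iqr[-wide])) {
    idx <- which(part == wide)
    v <- totals[idx]
    km <- stats::kmeans(matrix(v), centers = matrix(c(min(v), max(v))))
    lo_cl <- which.min(km$centers)
    thr <- (max(v[km$cluster == lo_cl]) +
              min(v[km$cluster != lo_cl])) / 2
    # neighbours along the cycle; newborn cells go to the side whose
    # cells have the smaller totals
    nb <- c(((wide - 2L) %% q) + 1L, (wide %% q) + 1L)
    nb_med <- vapply(nb, function(j) {
      w <- totals[part == j]
      if (length(w)) stats::median(w) else NA_real_
    }, numeric(1L))
    lo_nb <- nb[which.min(nb_med)]; hi_nb <- nb[which.max(nb_med)]
    part2[idx[v <= thr]] <- lo_nb
    part2[idx[v > thr]] <- hi_nb
    split_info <- list(wide_node = wide, threshold = thr,
                       median_high = stats::median(v[v > thr]),
                       median_low = stats::median(v[v <= thr]),
                       drop_ratio = stats::median(v[v > thr]) /
                         stats::median(v[v <= thr]))
  } else {
    warning("no anomalously wide partition found; skipping the split")
  }

  med <- vapply(seq_len(q), function(i) {
    v <- totals[part2 == i]
    if (length(v)) stats::median(v) else NA_real_
  }, numeric(1L))
  ord <- order(pos)
  med_ord <- med[ord]
  if (anyNA(med_ord)) {   # cyclic interpolation over empty partitions
    ok <- which(!is.na(med_ord))
    med_ord <- stats::approx(c(ok - q, ok, ok + q),
                             rep(med_ord[ok], 3L),
                             xout = seq_len(q), rule = 2L)$y
  }
  w <- as.integer(smooth_window)
  if (w > 1L) {
    half <- w %/% 2L
    sm <- vapply(seq_len(q), function(i) {
      mean(med_ord[((i - 1L + (-half):half) %% q) + 1L])
    }, numeric(1L))
  } else sm <- med_ord
  # target total at each cell via cyclic linear interpolation in pseudotime
  node_s <- pos[ord]
  target <- stats::approx(c(node_s - q, node_s, node_s + q),
                          rep(sm, 3L), xout = as.numeric(pseudotime),
                          rule = 2L)$y
  sf <- target / totals
  norm_counts <- counts %*% Matrix::Diagonal(x = sf)
  dimnames(norm_counts) <- dimnames(counts)

  emb1 <- .embed(norm_counts, n_var_genes, n_pc)
  knn <- .knn_list(emb1$embedding, k)
  pooled <- pool_neighbor_counts(norm_counts, knn)
  emb2 <- .embed(pooled, n_var_genes, n_pc)
  list(norm_counts = norm_counts, pooled_lognorm = emb2$lognorm,
       scale_factors = sf, embedding = emb2$embedding, knn = knn,
       var_genes = emb2$var_genes,
       node_medians = data.frame(node = ord, pseudotime = node_s,
                                 median = med[ord], smoothed = sm),
       split = split_info)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cell cycle phase scores
#'
#' Scores each cell for each phase gene set as the mean of `ln`-scale
#' expression over the marker genes, which corresponds roughly to the log
#' geometric mean of the raw counts.
#'
#' @param lognorm Genes x cells `ln(x+1)` expression matrix with gene
#'   rownames.
#' @param gene_sets Named list of marker gene character vectors.
#' @return Cells x sets matrix of scores.
#' @export
phase_scores <- function(lognorm, gene_sets) {
  stopifnot(is.list(gene_sets), !is.null(names(gene_sets)))
  out <- vapply(names(gene_sets), function(nm) {
    gg <- intersect(gene_sets[[nm]], rownames(lognorm))
    if (!length(gg))
      stop("gene set '", nm, "' has no genes in the matrix")
    Matrix::colMeans(lognorm[gg, , drop = FALSE])
  }, numeric(ncol(lognorm)))
  rownames(out) <- colnames(lognorm)
  out
}

#' Epoch marker genes by in/out log fold change
#'
#' For each transcriptional epoch, ranks genes by the difference between
#' their mean `ln`-scale expression inside and outside the epoch (the log
#' fold change), after discarding genes with low total variance.
#'
#' @param lognorm Genes x cells `ln(x+1)` expression matrix.
#' @param epochs Factor of per-cell epoch labels (`>= 2` levels).
#' @param var_floor Minimum total variance for a gene to be considered.
#' @param top_n Genes retained per epoch (default 20).
#' @return Named list (per epoch) of data frames with `gene`, `lfc`,
#'   `mean_in`, `mean_out`, ordered by decreasing `lfc`.
#' @export
epoch_marker_genes <- function(lognorm, epochs, var_floor = 0,
                               top_n = 20L) {
  epochs <- as.factor(epochs)
  lv <- levels(epochs)[table(epochs) > 0L]
  if (length(lv) < 2L) stop("need at least 2 non-empty epochs")
  v <- .row_vars(lognorm)
  keep <- which(v >= var_floor & v > 0)
  gn <- rownames(lognorm) %||% as.character(seq_len(nrow(lognorm)))
  out <- list()
  for (e in lv) {
    inside <- epochs == e
    if (sum(inside) < 2L) {
      warning("epoch ", e, " has fewer than 2 cells; excluded")
      next
    }
    m_in <- Matrix::rowMeans(lognorm[keep, inside, drop = FALSE])
    m_out <- Matrix::rowMeans(lognorm[keep, !inside, drop = FALSE])
    lfc <- m_in - m_out
    o <- order(lfc, decreasing = TRUE)[seq_len(min(top_n, length(keep)))]
    out[[e]] <- data.frame(gene = gn[keep][o], lfc = lfc[o],
                           mean_in = m_in[o], mean_out = m_out[o],
                           stringsAsFactors = FALSE)
  }
  out
}

#' Effective rank of a set of vectors
#'
#' The number of leading singular values such that the ratio of the
#' largest to the smallest retained value does not exceed the conditioning
#' bound (10), i.e. the dimensionality at which the matrix is still
#' well-conditioned. Used to estimate how many trajectory segment
#' directions are effectively linearly independent.
#'
#' @param m Matrix (e.g. one direction vector per row).
#' @param cond_bound Conditioning bound (default 10).
#' @return Integer effective rank; 0 for a zero matrix.
#' @export
effective_rank <- function(m, cond_bound = 10) {
  m <- as.matrix(m)
  sv <- svd(m, nu = 0L, nv = 0L)$d
  sv <- sv[sv > max(sv) * 1e-12]
  if (!length(sv) || max(sv) == 0) return(0L)
  sum(sv[1L] / sv <= cond_bound)
}

#' Run the full cell cycle trajectory pipeline
#'
#' End-to-end reconstruction from a raw count matrix: initial
#' normalization and kNN pooling, principal circle fit, pseudotime rooted
#' at the division gap, trajectory-based renormalization, refit on the
#' renormalized embedding, curvature segmentation into transcriptional
#' epochs, phase scores and epoch markers.
#'
#' @param counts Genes x cells raw count matrix (integer, rownames =
#'   genes).
#' @param gene_sets Named list of phase marker sets (e.g. `S`, `G2M`);
#'   `NULL` to skip scoring.
#' @param q Number of principal-curve nodes.
#' @param k Pooling neighbourhood size.
#' @param n_var_genes,n_pc Feature selection / PCA dimensions.
#' @param var_floor,top_n Passed to [epoch_marker_genes()].
#' @param seed Integer seed controlling the stochastic steps.
#' @return List with components `curve`, `pseudotime`, `epochs`,
#'   `curvature`, `scores`, `markers`, `normalization` (the
#'   [trajectory_normalize()] output), `initial` (first-pass embedding)
#'   and `cell_table`, a per-cell data frame (`cell_id`, `pseudotime`,
#'   `partition`, `epoch`, `total_counts`, plus one column per score).
#' @export
run_cct_pipeline <- function(counts, gene_sets = NULL, q = 50L, k = 10L,
                             n_var_genes = 10000L, n_pc = 30L,
                             var_floor = 0, top_n = 20L, seed = 0L) {
  set.seed(seed)
  ini <- initial_normalize(counts, n_var_genes, n_pc, k)
  pooled <- pool_neighbor_counts(counts, ini$knn)
  # median-normalize pooled counts before the first trajectory fit
  ptot <- Matrix::colSums(pooled)
  pooled_n <- pooled %*% Matrix::Diagonal(x = stats::median(ptot) / ptot)
  emb0 <- .embed(pooled_n, n_var_genes, n_pc)
  curve0 <- fit_principal_curve(emb0$embedding, q = q, closed = TRUE)
  s0 <- assign_pseudotime(curve0, emb0$embedding,
                          orient_scalar = ini$totals)
  norm <- trajectory_normalize(counts, curve0, s0, totals = ini$totals,
                               n_var_genes = n_var_genes, n_pc = n_pc,
                               k = k)
  curve <- fit_principal_curve(norm$embedding, q = q, closed = TRUE)
  s <- assign_pseudotime(curve, norm$embedding, orient_scalar = ini$totals)
  curv <- curvature_profile(curve)
  bnd <- sort(c(0, curv$peaks))
  epochs <- segment_epochs(s, bnd, cyclic = TRUE)
  scores <- if (!is.null(gene_sets))
    phase_scores(norm$pooled_lognorm, gene_sets) else NULL
  markers <- epoch_marker_genes(norm$pooled_lognorm, epochs,
                                var_floor = var_floor, top_n = top_n)
  tab <- data.frame(
    cell_id = colnames(counts) %||% paste0("cell_", seq_len(ncol(counts))),
    pseudotime = as.numeric(s), partition = curve$partition,
    epoch = epochs, total_counts = ini$totals,
    stringsAsFactors = FALSE)
  if (!is.null(scores)) tab <- cbind(tab, scores)
  list(curve = curve, pseudotime = s, epochs = epochs, curvature = curv,
       scores = scores, markers = markers, normalization = norm,
       initial = ini, cell_table = tab)
}
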