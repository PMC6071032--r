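#' Configuration for the parallel ICA with reference optimizer
#'
#' @param n_components_1,n_components_2 components extracted per modality
#'   (modality 1 = imaging, modality 2 = genomic).
#' @param lambda weight in `[0, 1]` balancing the genomic Infomax term
#'   against the reference-similarity penalty; `lambda = 1` disables the
#'   reference constraint entirely.
#' @param lr_1,lr_2 natural-gradient learning rates per modality.
#' @param lr_f3 learning rate of the cross-modality correlation-enhancement
#'   term; 0 disables it.
#' @param f3_corr_threshold minimum `|r|` a loading pair must reach before
#'   receiving correlation-enhancement updates.
#' @param max_pairs_f3 at most this many pairs are enhanced per epoch.
#' @param batch_size samples (voxels/SNPs) per natural-gradient mini-batch.
#' @param max_iter maximum epochs.
#' @param tol convergence tolerance on the mean absolute unmixing-matrix
#'   change per epoch.
#' @param anneal_factor learning-rate decay applied when the objective
#'   decreases.
#' @param lr_decay deterministic per-epoch learning-rate decay (a standard
#'   cooling schedule so the stochastic rotation noise floor shrinks as the
#'   run progresses); 1 disables it.
#' @param seed integer seed controlling initialization and batch order.
#' @return An object of class `picar_config`.
#' @export
picar_config <- function(n_components_1 = 8, n_components_2 = 8,
                         lambda = 0.9, lr_1 = 0.03, lr_2 = 0.03,
                         lr_f3 = 1, f3_corr_threshold = 0.12,
                         max_pairs_f3 = 2, batch_size = 256,
                         max_iter = 512, tol = 1e-6,
                         anneal_factor = 0.9, lr_decay = 0.995, seed = 1L) {
  stopifnot(lambda >= 0, lambda <= 1, lr_1 > 0, lr_2 > 0, lr_f3 >= 0,
            is_count(max_iter), is_count(batch_size), tol > 0,
            anneal_factor > 0, anneal_factor <= 1,
            lr_decay > 0, lr_decay <= 1)
  structure(list(n_components_1 = as.integer(n_components_1),
                 n_components_2 = as.integer(n_components_2),
                 lambda = lambda, lr_1 = lr_1, lr_2 = lr_2, lr_f3 = lr_f3,
                 f3_corr_threshold = f3_corr_threshold,
                 max_pairs_f3 = as.integer(max_pairs_f3),
                 batch_size = as.integer(batch_size),
                 max_iter = as.integer(max_iter), tol = tol,
                 anneal_factor = anneal_factor, lr_decay = lr_decay,
                 seed = as.integer(seed)),
            class = "picar_config")
}

#' PCA whitening
#'
#' Column-centers `x` and projects onto its top `n_components` subject-space
#' principal axes, scaled to unit covariance (covariance of the output rows
#' over samples is the identity).  The dewhitener maps the reduced component
#' space back to subject space for loading recovery.
#'
#' @param x subjects-by-variables matrix.
#' @param n_components reduced dimension; at most `min(dim(x))` and the
#'   numerical rank.
#' @return `list(xw, whitener, dewhitener, col_means, eigenvalues)`; `xw` is
#'   `n_components` x variables, `whitener` maps subject space down,
#'   `dewhitener` (subjects x components) maps loadings back up.
#' @export
whiten <- function(x, n_components) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  if (n_components > min(n, p))
    stopf("n_components = %d exceeds min(dim) = %d", n_components, min(n, p))
  mu <- colMeans(x)
  xc <- sweep(x, 2L, mu, "-")
  cc <- tcrossprod(xc) / p
  eg <- eigen(cc, symmetric = TRUE)
  ev <- eg$values
  if (ev[n_components] <= max(ev[1], 0) * 1e-10)
    stopf("n_components = %d exceeds the numerical rank", n_components)
  e <- eg$vectors[, seq_len(n_components), drop = FALSE]
  lam <- ev[seq_len(n_components)]
  whitener <- sweep(t(e), 1L, sqrt(lam), "/")       # k x n
  dewhitener <- sweep(e, 2L, sqrt(lam), "*")        # n x k
  list(xw = whitener %*% xc, whitener = whitener, dewhitener = dewhitener,
       col_means = mu, eigenvalues = lam)
}

#' One natural-gradient Infomax update
#'
#' With `U = w batch + bias` and `Y = 1/(1 + exp(-U))`, applies the
#' natural-gradient entropy-maximization update
#' `w' = w + lr (I + (1 - 2Y) U' / B) w` and
#' `bias' = bias + lr rowMeans(1 - 2Y)`.
#'
#' @param w k-by-k unmixing matrix.
#' @param bias length-k offset vector.
#' @param batch k-by-B whitened data block.
#' @param lr learning rate; 0 leaves `(w, bias)` unchanged.
#' @return `list(w, bias, diverged)`; `diverged` signals an annealing retry.
#' @export
infomax_step <- function(w, bias, batch, lr) {
  stopifnot(ncol(batch) >= 1L)
  u <- w %*% batch + bias
  y <- 1 / (1 + exp(-u))
  grad <- (diag(nrow(w)) + tcrossprod(1 - 2 * y, u) / ncol(batch)) %*% w
  w2 <- w + lr * grad
  b2 <- bias + lr * rowMeans(1 - 2 * y)
  diverged <- !all(is.finite(w2)) || max(abs(w2)) > 1e8
  list(w = w2, bias = b2, diverged = diverged)
}

# Gradient of || |s|/||s|| - r ||^2 with respect to the component row w_k,
# where s = w_k %*% z and z holds the reference-locus columns.
.reference_gradient <- function(wk, z, r) {
  s <- as.numeric(wk %*% z)
  a <- abs(s)
  na <- sqrt(sum(a^2))
  if (na < .Machine$double.eps) return(list(grad = rep(0, length(wk)),
                                            dist2 = sum(r^2), row = NA))
  at <- a / na
  dp_da <- -2 / na * (r - sum(at * r) * at)
  dp_ds <- dp_da * sign(s)
  list(grad = as.numeric(dp_ds %*% t(z)),      # d dist^2 / d wk
       dist2 = sum((at - r)^2))
}

# Choose, for one reference vector, the component with the largest
# reference-weighted share of its weight mass at the reference loci.  (A
# plain correlation with r degenerates for uniform reference weights and
# favours flat noise rows; mass concentration is what the constraint is
# meant to locate.)  In whitened space ||s_k||^2 = p * ||w_k||^2, so the
# total mass has a closed form.
.bind_reference <- function(w2, z, r, p_total = ncol(z)) {
  s <- w2 %*% z
  sw <- sweep(s, 2L, r, "*")
  score <- rowSums(sw^2) / (p_total * rowSums(w2^2))
  which.max(score)
}

#' Constrained Infomax update for the genomic modality
#'
#' Blends the natural-gradient Infomax direction (weight `lambda`) with a
#' gradient step on the reference-similarity penalty
#' `|| |s_k| / ||s_k|| - r ||^2` restricted to each reference gene's SNP
#' columns (weight `1 - lambda`).  For each reference vector the constrained
#' component is the one whose absolute weights at the reference loci
#' correlate best with it (rebinding happens at every call).  With
#' `lambda = 1` the update is exactly [infomax_step()].
#'
#' @param w2,bias2 unmixing matrix and offsets of the genomic modality.
#' @param batch k-by-B whitened genomic data block.
#' @param ref_cols named list of k-by-m whitened data restricted to each
#'   reference gene's SNP columns (see [run_picar()]); may be `NULL`.
#' @param ref a [reference_matrix()] aligned with `ref_cols`, or `NULL`.
#' @param lambda Infomax weight in `[0, 1]`.
#' @param lr learning rate.
#' @param binding optional named integer vector fixing which component each
#'   reference gene constrains (the binding is recomputed once per epoch in
#'   [run_picar()]); `NULL` recomputes it here.
#' @return `list(w, bias, diverged, dist2)`; `dist2` holds the per-gene
#'   penalty values at the pre-update weights.
#' @export
reference_step <- function(w2, bias2, batch, ref_cols, ref, lambda, lr,
                           binding = NULL) {
  u <- w2 %*% batch + bias2
  y <- 1 / (1 + exp(-u))
  ginf <- (diag(nrow(w2)) + tcrossprod(1 - 2 * y, u) / ncol(batch)) %*% w2
  dw <- lambda * ginf
  dist2 <- numeric(0)
  if (lambda < 1 && !is.null(ref) && length(ref$genes)) {
    for (g in ref$genes) {
      z <- ref_cols[[g$gene]]
      if (is.null(z) || ncol(z) == 0L) {
        warning(sprintf("reference '%s' has no SNP columns; skipped", g$gene))
        next
      }
      k <- if (is.null(binding)) .bind_reference(w2, z, g$weights)
           else binding[[g$gene]]
      rg <- .reference_gradient(w2[k, ], z, g$weights)
      dw[k, ] <- dw[k, ] - (1 - lambda) * rg$grad
      dist2[g$gene] <- rg$dist2
    }
  }
  w2n <- w2 + lr * dw
  b2n <- bias2 + lr * lambda * rowMeans(1 - 2 * y)
  diverged <- !all(is.finite(w2n)) || max(abs(w2n)) > 1e8
  list(w = w2n, bias = b2n, diverged = diverged, dist2 = dist2)
}

# Analytic gradient of Corr^2(u, v) with respect to u.
.corr2_grad <- function(u, v) {
  uc <- u - mean(u); vc <- v - mean(v)
  suu <- sum(uc^2); svv <- sum(vc^2)
  r <- sum(uc * vc) / sqrt(suu * svv)
  2 * r * (vc - (sum(uc * vc) / suu) * uc) / sqrt(suu * svv)
}

#' Cross-modality correlation-enhancement step
#'
#' Gradient ascent on `Corr^2(A1[, i], A2[, j])` with respect to the paired
#' subject-loading columns, for each supplied pair.  For sufficiently small
#' `lr_f3` the absolute correlation of an updated pair is non-decreasing.
#'
#' @param a1,a2 subjects-by-components loading matrices.
#' @param pairs data frame (or matrix) with columns `comp_1`, `comp_2`
#'   naming the column pairs to enhance; typically pre-filtered to
#'   `|r| >= f3_corr_threshold`, at most `max_pairs_f3` rows.  Empty pairs
#'   leave the loadings untouched.
#' @param lr_f3 learning rate.
#' @return `list(a1, a2)` with the updated loading matrices.
#' @export
correlation_step <- function(a1, a2, pairs, lr_f3) {
  pairs <- as.data.frame(pairs)
  if (nrow(pairs) == 0L || lr_f3 == 0) return(list(a1 = a1, a2 = a2))
  for (r in seq_len(nrow(pairs))) {
    i <- pairs$comp_1[r]; j <- pairs$comp_2[r]
    g1 <- .corr2_grad(a1[, i], a2[, j])
    g2 <- .corr2_grad(a2[, j], a1[, i])
    a1[, i] <- a1[, i] + lr_f3 * g1
    a2[, j] <- a2[, j] + lr_f3 * g2
  }
  list(a1 = a1, a2 = a2)
}

# Infomax entropy proxy: log|det W| + mean_j sum_k log y(1-y).
.entropy_proxy <- function(w, bias, xw) {
  u <- w %*% xw + bias
  y <- 1 / (1 + exp(-u))
  d <- determinant(w, logarithm = TRUE)$modulus
  as.numeric(d) + mean(colSums(log(pmax(y * (1 - y), 1e-300))))
}

# Deterministic per-epoch batch order so that a single-modality run and the
# matching modality of a coupled run draw identical schedules.
.epoch_order <- function(seed, epoch, p) {
  with_seed(derive_seed(seed, 100000L + epoch), sample.int(p))
}

# One modality's epoch of mini-batch updates.  `ref_cols`/`ref` are NULL for
# the unconstrained modality.
.ica_epoch <- function(w, bias, xw, lr, seed, epoch, batch_size,
                       lambda = 1, ref_cols = NULL, ref = NULL) {
  p <- ncol(xw)
  ord <- .epoch_order(seed, epoch, p)
  starts <- seq(1L, p, by = batch_size)
  binding <- NULL
  if (lambda < 1 && !is.null(ref) && length(ref$genes)) {
    # the reference-to-component binding is recomputed once per epoch
    binding <- vapply(ref$genes, function(g)
      .bind_reference(w, ref_cols[[g$gene]], g$weights, p_total = p),
      integer(1))
    names(binding) <- vapply(ref$genes, `[[`, "", "gene")
  }
  for (s in starts) {
    cols <- ord[s:min(s + batch_size - 1L, p)]
    st <- reference_step(w, bias, xw[, cols, drop = FALSE],
                         ref_cols, ref, lambda, lr, binding = binding)
    if (st$diverged) return(list(w = w, bias = bias, diverged = TRUE))
    w <- st$w; bias <- st$bias
  }
  list(w = w, bias = bias, diverged = FALSE, dist2 = st$dist2,
       binding = binding)
}

# The optimizer over pre-whitened data, with restarts: a run that ends with
# near-duplicate component rows (the Infomax row-collapse failure mode) is
# retried at half the learning rates from a fresh seeded initialization.
.picar_engine <- function(wh1, wh2, ref, config) {
  for (attempt in 1:3) {
    res <- .picar_engine_once(wh1, wh2, ref, config)
    dup <- function(s) {
      cm <- abs(stats::cor(t(s)))
      diag(cm) <- 0
      max(cm)
    }
    if (dup(res$s1) < 0.95 && dup(res$s2) < 0.95) break
    config$lr_1 <- config$lr_1 / 2
    config$lr_2 <- config$lr_2 / 2
    config$seed <- derive_seed(config$seed, 990000L + attempt)
  }
  res
}

.picar_engine_once <- function(wh1, wh2, ref, config) {
  k1 <- config$n_components_1; k2 <- config$n_components_2
  seed1 <- derive_seed(config$seed, 11L)
  seed2 <- derive_seed(config$seed, 12L)
  w1 <- with_seed(seed1, diag(k1) + 0.05 * matrix(stats::rnorm(k1 * k1), k1))
  w2 <- with_seed(seed2, diag(k2) + 0.05 * matrix(stats::rnorm(k2 * k2), k2))
  b1 <- rep(0, k1); b2 <- rep(0, k2)
  lr1 <- config$lr_1; lr2 <- config$lr_2; lr3 <- config$lr_f3
  ref_cols <- NULL
  if (!is.null(ref) && config$lambda < 1) {
    ref_cols <- lapply(ref$genes, function(g)
      wh2$xw[, g$indices, drop = FALSE])
    names(ref_cols) <- vapply(ref$genes, `[[`, "", "gene")
  }
  trace <- matrix(NA_real_, config$max_iter, 3,
                  dimnames = list(NULL, c("F1", "F2", "F3")))
  f_prev <- -Inf
  converged <- FALSE
  n_epochs <- 0L
  cm_smooth <- NULL
  for (epoch in seq_len(config$max_iter)) {
    w1_old <- w1; w2_old <- w2
    e1 <- .ica_epoch(w1, b1, wh1$xw, lr1, seed1, epoch, config$batch_size)
    if (e1$diverged) { lr1 <- lr1 / 2; next }
    e2 <- .ica_epoch(w2, b2, wh2$xw, lr2, seed2, epoch, config$batch_size,
                     lambda = config$lambda, ref_cols = ref_cols, ref = ref)
    if (e2$diverged) { lr2 <- lr2 / 2; next }
    # reject epochs that drive an unmixing matrix toward singularity
    # (row collapse is the classic Infomax failure mode); retry cooler
    if (rcond(e1$w) < 1e-8) { lr1 <- lr1 / 2; next }
    if (rcond(e2$w) < 1e-8) { lr2 <- lr2 / 2; next }
    w1 <- e1$w; b1 <- e1$bias; w2 <- e2$w; b2 <- e2$bias

    f3_val <- 0
    if (lr3 > 0) {
      aw1 <- solve(w1); aw2 <- solve(w2)
      a1 <- wh1$dewhitener %*% aw1
      a2 <- wh2$dewhitener %*% aw2
      cm <- suppressWarnings(stats::cor(a1, a2))
      cm[is.na(cm)] <- 0
      # engagement is decided on an epoch-smoothed correlation so that
      # transient mini-batch fluctuations cannot latch the enhancement
      # onto a null pair
      cm_smooth <- if (is.null(cm_smooth)) cm
                   else 0.8 * cm_smooth + 0.2 * cm
      cand <- which(abs(cm_smooth) >= config$f3_corr_threshold,
                    arr.ind = TRUE)
      # with a reference in play, only pairs involving a reference-bound
      # genomic component are enhanced: the constraint nominates the
      # component of interest, and chance pairings of the other
      # components must not be amplified
      if (!is.null(e2$binding) && nrow(cand))
        cand <- cand[cand[, 2] %in% e2$binding, , drop = FALSE]
      if (nrow(cand)) {
        ord <- order(abs(cm_smooth[cand]), decreasing = TRUE)
        cand <- cand[ord[seq_len(min(nrow(cand), config$max_pairs_f3))], ,
                     drop = FALSE]
        pairs <- data.frame(comp_1 = cand[, 1], comp_2 = cand[, 2])
        upd <- correlation_step(a1, a2, pairs, lr3)
        # back-propagate: Aw = (D'D)^-1 D' A, with D'D diagonal (= Lambda)
        aw1 <- diag(1 / wh1$eigenvalues, k1) %*% crossprod(wh1$dewhitener,
                                                           upd$a1)
        aw2 <- diag(1 / wh2$eigenvalues, k2) %*% crossprod(wh2$dewhitener,
                                                           upd$a2)
        w1n <- tryCatch(solve(aw1), error = function(e) NULL)
        w2n <- tryCatch(solve(aw2), error = function(e) NULL)
        if (is.null(w1n) || is.null(w2n)) {
          lr3 <- lr3 / 2                      # singular update: reject step
        } else {
          w1 <- w1n; w2 <- w2n
          cm2 <- stats::cor(upd$a1[, pairs$comp_1, drop = FALSE],
                            upd$a2[, pairs$comp_2, drop = FALSE])
          f3_val <- sum(diag(as.matrix(cm2))^2)
        }
      } else {
        f3_val <- 0
      }
    }

    f1 <- .entropy_proxy(w1, b1, wh1$xw)
    h2 <- .entropy_proxy(w2, b2, wh2$xw)
    f2 <- config$lambda * h2 -
      (1 - config$lambda) * sum(e2$dist2 %||% 0)
    trace[epoch, ] <- c(f1, f2, f3_val)
    f_total <- f1 + f2 + f3_val
    if (is.finite(f_prev) && f_total < f_prev) {
      lr1 <- lr1 * config$anneal_factor
      lr2 <- lr2 * config$anneal_factor
      lr3 <- lr3 * config$anneal_factor
    }
    f_prev <- f_total
    lr1 <- lr1 * config$lr_decay
    lr2 <- lr2 * config$lr_decay
    lr3 <- lr3 * config$lr_decay
    n_epochs <- epoch
    dw <- (mean(abs(w1 - w1_old)) + mean(abs(w2 - w2_old))) / 2
    if (dw < config$tol) { converged <- TRUE; break }
  }

  s1 <- w1 %*% wh1$xw
  s2 <- w2 %*% wh2$xw
  a1 <- wh1$dewhitener %*% solve(w1)
  a2 <- wh2$dewhitener %*% solve(w2)
  # sign convention: largest-|weight| element of each component made positive
  fix_signs <- function(s, a) {
    for (k in seq_len(nrow(s))) {
      m <- which.max(abs(s[k, ]))
      if (s[k, m] < 0) { s[k, ] <- -s[k, ]; a[, k] <- -a[, k] }
    }
    list(s = s, a = a)
  }
  f1s <- fix_signs(s1, a1); f2s <- fix_signs(s2, a2)
  structure(list(s1 = f1s$s, s2 = f2s$s, a1 = f1s$a, a2 = f2s$a,
                 w1 = w1, w2 = w2, bias1 = b1, bias2 = b2,
                 objective_trace = trace[seq_len(n_epochs), , drop = FALSE],
                 converged = converged, n_epochs = n_epochs,
                 pca_whiteners = list(wh1 = wh1[c("whitener", "dewhitener",
                                                  "col_means", "eigenvalues")],
                                      wh2 = wh2[c("whitener", "dewhitener",
                                                  "col_means",
                                                  "eigenvalues")]),
                 config = config),
            class = "decomposition_result")
}

# Standardized numeric matrix from either modality container.
.as_modality_matrix <- function(x, genomic = FALSE) {
  if (inherits(x, "gmc_matrix")) return(x$values)
  if (inherits(x, "genotype_matrix")) {
    d <- x$dosages
    if (anyNA(d)) {           # mean-impute per SNP before standardization
      mu <- colMeans(d, na.rm = TRUE)
      idx <- which(is.na(d), arr.ind = TRUE)
      d[idx] <- mu[idx[, 2]]
    }
    return(standardize_cols(d))
  }
  as.matrix(x)
}

#' Parallel ICA with reference
#'
#' Whitens both modalities, then alternates (i) natural-gradient Infomax
#' updates on the imaging modality, (ii) reference-constrained Infomax on
#' the genomic modality, and (iii) gradient ascent on the squared
#' correlation of the most-correlated loading column pairs, until the mean
#' unmixing change falls below `tol` or `max_iter` epochs elapse.  Genotype
#' dosages enter as centered unit-variance columns (missing calls
#' mean-imputed); each component's sign is fixed so its largest-magnitude
#' weight is positive.
#'
#' @param x1 imaging modality: a [gmc_matrix()] or plain subjects-by-voxel
#'   matrix.
#' @param x2 genomic modality: a [genotype_matrix()] or plain
#'   subjects-by-SNP matrix; subjects must match `x1` row for row.
#' @param ref a [reference_matrix()] or `NULL` for unconstrained parallel
#'   ICA.
#' @param config a [picar_config()].
#' @return A `decomposition_result`: component matrices `s1` (components x
#'   voxels), `s2` (components x SNPs), subject loadings `a1`, `a2`,
#'   unmixing matrices and offsets, the per-epoch `(F1, F2, F3)` objective
#'   trace, a convergence flag, and the PCA whiteners.
#' @export
run_picar <- function(x1, x2, ref = NULL, config = picar_config()) {
  m1 <- .as_modality_matrix(x1)
  m2 <- .as_modality_matrix(x2, genomic = TRUE)
  if (nrow(m1) != nrow(m2))
    stopf("modalities disagree on subjects: %d vs %d", nrow(m1), nrow(m2))
  if (inherits(x1, "gmc_matrix") && inherits(x2, "genotype_matrix") &&
      !identical(x1$subject_ids, x2$subject_ids))
    stopf("modalities carry different subject identifiers or ordering")
  if (!is.null(ref) && !is.null(ref$n_snps) && ref$n_snps != ncol(m2))
    stopf("reference matrix indexed for %d SNPs but modality 2 has %d",
          ref$n_snps, ncol(m2))
  wh1 <- whiten(m1, config$n_components_1)
  wh2 <- whiten(m2, config$n_components_2)
  .picar_engine(wh1, wh2, ref, config)
}

#' Single-modality Infomax ICA
#'
#' The unconstrained special case: whitening followed by natural-gradient
#' Infomax with the same initialization, batch schedule and annealing as the
#' corresponding modality of [run_picar()].  A [run_picar()] call with
#' `lambda = 1` and `lr_f3 = 0` reduces to two of these runs (modality 1
#' uses stream `seed`, modality 2 the stream one derivation later).
#'
#' @param x subjects-by-variables matrix.
#' @param n_components reduced dimension.
#' @param config a [picar_config()]; `seed`, rates and schedule are reused.
#' @param modality which stream convention to follow (1 or 2).
#' @return `list(s, a, w, bias, converged, n_epochs)`.
#' @export
infomax_ica <- function(x, n_components, config = picar_config(),
                        modality = 1L) {
  wh <- whiten(.as_modality_matrix(x, genomic = modality == 2L),
               n_components)
  seed <- derive_seed(config$seed, 10L + as.integer(modality))
  lr <- if (modality == 1L) config$lr_1 else config$lr_2
  w <- with_seed(seed, diag(n_components) +
                   0.05 * matrix(stats::rnorm(n_components^2), n_components))
  bias <- rep(0, n_components)
  f_prev <- -Inf
  converged <- FALSE; n_epochs <- 0L
  for (epoch in seq_len(config$max_iter)) {
    w_old <- w
    e <- .ica_epoch(w, bias, wh$xw, lr, seed, epoch, config$batch_size)
    if (e$diverged || rcond(e$w) < 1e-8) { lr <- lr / 2; next }
    w <- e$w; bias <- e$bias
    f <- .entropy_proxy(w, bias, wh$xw)
    if (is.finite(f_prev) && f < f_prev) lr <- lr * config$anneal_factor
    lr <- lr * (config$lr_decay %||% 1)
    f_prev <- f
    n_epochs <- epoch
    if (mean(abs(w - w_old)) < config$tol) { converged <- TRUE; break }
  }
  s <- w %*% wh$xw
  a <- wh$dewhitener %*% solve(w)
  for (k in seq_len(nrow(s))) {
    m <- which.max(abs(s[k, ]))
    if (s[k, m] < 0) { s[k, ] <- -s[k, ]; a[, k] <- -a[, k] }
  }
  list(s = s, a = a, w = w, bias = bias, converged = converged,
       n_epochs = n_epochs)
}

#' @export
print.decomposition_result <- function(x, ...) {
  cat(sprintf(paste0("decomposition_result: %d x %d components, ",
                     "%d epochs, converged = %s\n"),
              nrow(x$s1), nrow(x$s2), x$n_epochs, x$converged))
  invisible(x)
}
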