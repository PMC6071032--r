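test_that("whitened data has identity covariance over samples", {
  set.seed(11)
  x <- matrix(rnorm(50 * 200), 50, 200)
  wh <- whiten(x, 10)
  cov_out <- tcrossprod(wh$xw) / ncol(x)
  expect_equal(cov_out, diag(10), tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("rank-2 data is reconstructed exactly from 2 components", {
  set.seed(12)
  a <- matrix(rnorm(30 * 2), 30, 2); s <- matrix(rnorm(2 * 80), 2, 80)
  x <- a %*% s
  wh <- whiten(x, 2)
  xhat <- wh$dewhitener %*% wh$xw + matrix(wh$col_means, 30, 80, byrow = TRUE)
  expect_equal(xhat, x, tolerance = 1e-8, ignore_attr = TRUE)
  expect_error(whiten(x, 3), "rank")
})

test_that("infomax_step with zero rate is the identity", {
  set.seed(13)
  w <- diag(3) + 0.1 * matrix(rnorm(9), 3)
  b <- rnorm(3)
  st <- infomax_step(w, b, matrix(rnorm(3 * 64), 3), 0)
  expect_identical(st$w, w)
  expect_identical(st$bias, b)
  expect_false(st$diverged)
})

test_that("Infomax unmixes a super-Gaussian mixture (Amari index < 0.05)", {
  set.seed(14)
  k <- 2; n <- 100; p <- 3000
  s <- supergaussian_sources(k, p)
  x <- matrix(rnorm(n * k), n, k) %*% s
  fit <- infomax_ica(x, k, picar_config(seed = 3, max_iter = 200))
  expect_lt(amari_index(fit$s, s), 0.05)
  # the entropy objective trends upward early in the run
  wh <- whiten(x, k)
  w <- diag(k); b <- rep(0, k)
  f <- numeric(100)
  for (e in seq_len(100)) {
    st <- infomax_step(w, b, wh$xw, 0.02)
    w <- st$w; b <- st$bias
    f[e] <- picafuse:::.entropy_proxy(w, b, wh$xw)
  }
  expect_gt(mean(diff(f) > 0), 0.9)
  expect_gt(f[100], f[1])
})

test_that("reference_step with lambda = 1 is exactly infomax_step", {
  set.seed(15)
  w <- diag(4) + 0.05 * matrix(rnorm(16), 4)
  b <- rnorm(4)
  batch <- matrix(rnorm(4 * 128), 4)
  ref <- reference_matrix(list(G1 = 1:5), n_snps = 200)
  zg <- list(G1 = matrix(rnorm(4 * 5), 4))
  a <- infomax_step(w, b, batch, 0.01)
  bres <- reference_step(w, b, batch, zg, ref, lambda = 1, lr = 0.01)
  expect_identical(a$w, bres$w)
  expect_identical(a$bias, bres$bias)
})

test_that("pure reference gradient drives the component toward the reference", {
  set.seed(16)
  k <- 3; m <- 8
  z <- matrix(rnorm(k * m), k, m)
  r <- abs(rnorm(m)); r <- r / sqrt(sum(r^2))
  w <- diag(k) + 0.05 * matrix(rnorm(k * k), k)
  ref <- reference_matrix(list(G = list(indices = 1:m, weights = r)),
                          n_snps = m)
  dist_trace <- numeric(200)
  for (it in 1:200) {
    st <- reference_step(w, rep(0, k), z, list(G = z), ref,
                         lambda = 0, lr = 0.05,
                         binding = c(G = 1L))
    w <- st$w
    dist_trace[it] <- st$dist2[["G"]]
  }
  expect_lt(dist_trace[200], dist_trace[1])
  expect_gt(mean(diff(dist_trace) <= 1e-12), 0.95)
  # the trace settles: the last 50 iterations barely move
  expect_lt(abs(dist_trace[200] - dist_trace[150]), 1e-4)
})

test_that("correlation_step follows the analytic squared-correlation gradient", {
  set.seed(17)
  n <- 40
  u <- rnorm(n); v <- 0.3 * u + rnorm(n)
  g <- picafuse:::.corr2_grad(u, v)
  num <- vapply(seq_len(n), function(i) {
    h <- 1e-6; up <- u; um <- u
    up[i] <- up[i] + h; um[i] <- um[i] - h
    (cor(up, v)^2 - cor(um, v)^2) / (2 * h)
  }, numeric(1))
  expect_equal(g, num, tolerance = 1e-5)
})

test_that("correlation enhancement increases |r| and is silent when idle", {
  set.seed(18)
  a1 <- matrix(rnorm(60 * 2), 60, 2)
  a2 <- matrix(rnorm(60 * 2), 60, 2)
  a2[, 1] <- 0.3 * a1[, 1] + rnorm(60)
  pairs <- data.frame(comp_1 = 1, comp_2 = 1)
  r_trace <- numeric(50)
  st <- list(a1 = a1, a2 = a2)
  for (i in 1:50) {
    st <- correlation_step(st$a1, st$a2, pairs, lr_f3 = 0.5)
    r_trace[i] <- abs(cor(st$a1[, 1], st$a2[, 1]))
  }
  expect_true(all(diff(c(abs(cor(a1[, 1], a2[, 1])), r_trace)) > 0))
  # at |r| = 1 the gradient vanishes
  b2 <- a1
  g <- picafuse:::.corr2_grad(a1[, 1], b2[, 1])
  expect_lt(max(abs(g)), 1e-10)
  # no eligible pairs: identity
  idle <- correlation_step(a1, a2, pairs[0, ], 0.5)
  expect_identical(idle$a1, a1)
})

test_that("lambda = 1 and lr_f3 = 0 reduce to two independent Infomax runs", {
  co <- small_cohort()
  cfg <- small_config(seed = 9, lambda = 1, lr_f3 = 0)
  dec <- run_picar(co$gmc, co$genotypes, NULL, cfg)
  ica1 <- infomax_ica(co$gmc, 4, cfg, modality = 1)
  ica2 <- infomax_ica(co$genotypes, 4, cfg, modality = 2)
  # identical streams: the components must match one-to-one after alignment
  m1 <- abs(cor(t(dec$s1), t(ica1$s)))
  m2 <- abs(cor(t(dec$s2), t(ica2$s)))
  expect_true(all(apply(m1, 1, max) > 0.99))
  expect_true(all(apply(m2, 1, max) > 0.99))
})

test_that("noiseless four-source mixtures are recovered in both modalities", {
  set.seed(19)
  k <- 4; n <- 120
  s1 <- supergaussian_sources(k, 2500)
  s2 <- supergaussian_sources(k, 2500)
  x1 <- matrix(rnorm(n * k), n, k) %*% s1
  x2 <- matrix(rnorm(n * k), n, k) %*% s2
  cfg <- picar_config(n_components_1 = k, n_components_2 = k,
                      lambda = 1, lr_f3 = 0, max_iter = 200, seed = 4)
  dec <- run_picar(x1, x2, NULL, cfg)
  expect_lt(amari_index(dec$s1, s1), 0.05)
  expect_lt(amari_index(dec$s2, s2), 0.05)
})

test_that("scaling a source and inverting its mixing column leaves the fit invariant", {
  set.seed(20)
  k <- 3; n <- 80
  s <- supergaussian_sources(k, 1500)
  a <- matrix(rnorm(n * k), n, k)
  s2 <- s; a2 <- a
  s2[1, ] <- 2 * s2[1, ]; a2[, 1] <- a2[, 1] / 2
  expect_equal(a %*% s, a2 %*% s2, tolerance = 1e-12)
  cfg <- picar_config(n_components_1 = k, n_components_2 = k, lambda = 1,
                      lr_f3 = 0, max_iter = 150, seed = 5)
  f1 <- infomax_ica(a %*% s, k, cfg)
  f2 <- infomax_ica(a2 %*% s2, k, cfg)
  expect_equal(f1$s, f2$s, tolerance = 1e-8)
})

test_that("the constrained component concentrates weight at the reference loci", {
  co <- small_cohort()
  ref <- cohort_reference(co)
  cfg <- small_config(seed = 6, lambda = 0.8)
  dec <- run_picar(co$gmc, co$genotypes, ref, cfg)
  ntrk2 <- co$reference_snp_indices$NTRK2
  mass <- rowSums(dec$s2[, ntrk2, drop = FALSE]^2) / rowSums(dec$s2^2)
  cfg0 <- small_config(seed = 6, lambda = 1, lr_f3 = 0)
  dec0 <- run_picar(co$gmc, co$genotypes, NULL, cfg0)
  mass0 <- rowSums(dec0$s2[, ntrk2, drop = FALSE]^2) / rowSums(dec0$s2^2)
  expect_gte(max(mass), max(mass0) * 0.9)
})

test_that("the coupled pair is recovered and selected on a small cohort", {
  co <- small_cohort()
  dec <- run_picar(co$gmc, co$genotypes, cohort_reference(co),
                   small_config(seed = 7))
  pair <- select_max_pair(dec)
  i <- which.max(abs(cor(dec$a1, co$truth_a1[, 1])))
  j <- which.max(abs(cor(dec$a2, co$truth_a2[, 1])))
  expect_identical(c(pair$comp_1, pair$comp_2), c(i, j))
  expect_gt(abs(pair$r), 0.25)
})

test_that("select_max_pair matches a brute-force scan and computes the t p-value", {
  set.seed(21)
  a1 <- matrix(rnorm(50 * 3), 50, 3)
  a2 <- matrix(rnorm(50 * 3), 50, 3)
  ps <- select_max_pair(list(a1 = a1, a2 = a2))
  cm <- cor(a1, a2)
  best <- which(abs(cm) == max(abs(cm)), arr.ind = TRUE)
  expect_identical(c(ps$comp_1, ps$comp_2), as.integer(best[1, ]))
  expect_equal(ps$r, cm[best[1, 1], best[1, 2]])
  expect_identical(ps$df, 48L)
  tval <- ps$r * sqrt(48 / (1 - ps$r^2))
  expect_equal(ps$p, 2 * pt(-abs(tval), 48))
  # planted identical columns give r = 1
  a2[, 2] <- a1[, 3]
  ps2 <- select_max_pair(list(a1 = a1, a2 = a2))
  expect_equal(ps2$r, 1)
  expect_lt(ps2$p, 1e-12)
})

test_that("component z-scoring standardizes, is idempotent, and rejects constants", {
  set.seed(22)
  s <- rnorm(500, 3, 7)
  z <- zscore_component(s)
  expect_lt(abs(mean(z)), 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_equal(zscore_component(z), z, tolerance = 1e-12)
  expect_error(zscore_component(rep(1, 10)), "constant")
})

test_that("select_top_snps recovers exactly 61 planted outliers among 5000", {
  set.seed(23)
  # logistic background truncated at 4 SD: the heavy logistic tail would
  # otherwise produce ~4-5 natural 4.25-SD exceedances in 5,000 draws,
  # making exact recovery of the planted set ill-posed
  sdv <- 0.5 * pi / sqrt(3)
  w <- rlogis(20000, location = 0.2, scale = 0.5)
  w <- w[abs(w - 0.2) < 4 * sdv][1:5000]
  out_idx <- sample(5000, 61)
  w[out_idx] <- 0.2 + sample(c(-1, 1), 61, TRUE) * 6 * sdv
  top <- select_top_snps(w, k_sd = 4.25)
  expect_setequal(top$indices, out_idx)
  expect_identical(top$n_selected, 61L)
  expect_equal(top$fit_location, 0.2, tolerance = 0.1)
  expect_identical(select_top_snps(w, k_sd = Inf)$n_selected, 0L)
})

test_that("restricted loadings equal the weight-dosage product", {
  d <- matrix(c(0, 1, 2, 1, 0, 2, 2, 2, 0, 1, 1, 0, 0, 2, 1), 5, 3)
  g <- genotype_matrix(d, data.frame(id = c("a", "b", "c"), chr = 1,
                                     pos = 1:3, a1 = "A", a2 = "G"))
  top <- structure(list(indices = 1:3, weights = c(0.5, -1, 2),
                        n_selected = 3L), class = "top_snp_set")
  expect_equal(unname(restricted_loadings(top, g)),
               as.numeric(d %*% c(0.5, -1, 2)))
  single <- structure(list(indices = 2L, weights = 1, n_selected = 1L),
                      class = "top_snp_set")
  expect_equal(unname(restricted_loadings(single, g)), d[, 2])
})

test_that("restricted loadings track the full loadings on a coupled cohort", {
  co <- small_cohort()
  dec <- run_picar(co$gmc, co$genotypes, cohort_reference(co),
                   small_config(seed = 8))
  pair <- select_max_pair(dec)
  w <- dec$s2[pair$comp_2, ]
  top <- select_top_snps(w, k_sd = 2)
  expect_gt(top$n_selected, 0L)
  rl <- restricted_loadings(top, co$genotypes,
                            full_loadings = dec$a2[, pair$comp_2])
  expect_gt(abs(attr(rl, "cor_full")), 0.5)
})
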