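# Unsupervised outlier scorers: brute-force oracles on tiny instances,
# orientation uniformity, thresholding and the detection driver.

test_that("HBOS matches a hand-rolled log-inverse-density oracle", {
  # 5 points, 1 feature, 2 bins: enumerate densities directly
  x <- matrix(c(0, 0.1, 0.2, 0.9, 1.0), ncol = 1)
  oracle <- {
    edges <- c(0, 0.5, 1)
    counts <- c(sum(x >= 0 & x <= 0.5), sum(x > 0.5 & x <= 1))
    dens <- counts / (5 * 0.5)
    d_of <- ifelse(x <= 0.5, dens[1], dens[2])
    log(1 / (d_of + 1e-12))
  }
  expect_equal(hbos_scores(x, n_bins = 2), as.numeric(oracle), tolerance = 1e-9)
  # a gross outlier gets the top score
  set.seed(30)
  y <- matrix(c(rnorm(99), 10), ncol = 1)
  s <- hbos_scores(y, n_bins = 10)
  expect_equal(which.max(s), 100)
  # identical rows score identically
  z <- matrix(rep(c(1, 2), each = 6), ncol = 2)
  expect_equal(hbos_scores(z, n_bins = 3), rep(hbos_scores(z, n_bins = 3)[1], 6))
  expect_error(hbos_scores(y, n_bins = 1), class = "eegsweep_parameter_error")
})

test_that("dynamic (equal-frequency) HBOS bins still rank the outlier first", {
  set.seed(31)
  y <- matrix(c(rnorm(80), 8), ncol = 1)
  s <- hbos_scores(y, n_bins = 8, dynamic_bins = TRUE)
  # equal-frequency bins tie every member of the wide edge bin, so the
  # outlier shares (but attains) the maximum
  expect_equal(s[81], max(s))
  expect_gt(s[81], stats::median(s))
})

test_that("LOF matches the textbook reachability computation on a 4-point instance", {
  # three points in a tight cluster + one moderately distant, k = 2
  pts <- matrix(c(0, 0, 1, 0, 0, 1, 4, 4), ncol = 2, byrow = TRUE)
  k <- 2
  # independent oracle with explicit loops
  n <- 4
  D <- as.matrix(dist(pts)); diag(D) <- Inf
  kdist <- numeric(n); nbr <- list()
  for (i in 1:n) {
    ds <- sort(D[i, ]); kdist[i] <- ds[k]
    nbr[[i]] <- which(D[i, ] <= kdist[i])
  }
  lrd <- numeric(n)
  for (i in 1:n) {
    reach <- sapply(nbr[[i]], function(j) max(kdist[j], D[i, j]))
    lrd[i] <- 1 / (mean(reach) + 1e-12)
  }
  lof <- sapply(1:n, function(i) mean(lrd[nbr[[i]]]) / lrd[i])
  expect_equal(lof_scores(pts, k_neighbors = 2), lof, tolerance = 1e-9)
  expect_equal(which.max(lof), 4L)
})

test_that("LOF separates a distant point from a uniform grid", {
  g <- as.matrix(expand.grid(1:7, 1:7))
  pts <- rbind(g, c(30, 30))
  s <- lof_scores(pts, k_neighbors = 3)
  expect_equal(which.max(s), nrow(pts))
  expect_gt(s[nrow(pts)], 1)
  # a deep-interior grid point sits at the local-density fixed point
  interior <- which(g[, 1] == 4 & g[, 2] == 4)
  expect_lt(abs(s[interior] - 1), 0.1)
})

test_that("ABOD matches brute-force enumeration and flags narrow-cone points", {
  set.seed(32)
  pts <- matrix(rnorm(10), ncol = 2)
  k <- 4
  s <- abod_scores(pts, k_neighbors = k)
  # independent oracle: explicit double loop over neighbour pairs
  n <- nrow(pts)
  D <- as.matrix(dist(pts)); diag(D) <- Inf
  oracle <- numeric(n)
  for (i in 1:n) {
    nb <- order(D[i, ])[1:k]
    vals <- c()
    for (a in 1:(k - 1)) for (b in (a + 1):k) {
      va <- pts[nb[a], ] - pts[i, ]
      vb <- pts[nb[b], ] - pts[i, ]
      vals <- c(vals, sum(va * vb) / (sum(va^2) * sum(vb^2) + 1e-300))
    }
    oracle[i] <- -var(vals)
  }
  expect_equal(s, oracle, tolerance = 1e-9)
  # far point outside a compact cluster scores highest; the symmetric centre
  # of a regular polygon scores low
  theta <- seq(0, 2 * pi, length.out = 9)[-9]
  poly <- cbind(cos(theta), sin(theta))
  pts2 <- rbind(poly, c(0, 0), c(8, 8))
  s2 <- abod_scores(pts2, k_neighbors = 5)
  expect_equal(which.max(s2), 10L)
  expect_lt(s2[9], stats::median(s2))
})

test_that("one-class SVM scores respect the nu-property and duplicates", {
  set.seed(33)
  blob <- matrix(rnorm(200), ncol = 2)
  pts <- rbind(blob, c(9, 9))
  s <- ocsvm_scores(pts, nu = 0.1)
  expect_equal(which.max(s), 101L)
  # duplicated interior points share a score
  dup <- rbind(blob, blob[1, , drop = FALSE])
  sd_ <- ocsvm_scores(dup, nu = 0.2)
  expect_equal(sd_[1], sd_[101], tolerance = 1e-9)
  # ~nu * n points end up outside/on the margin (score >= 0)
  s2 <- ocsvm_scores(blob, nu = 0.2)
  expect_lt(abs(sum(s2 >= -1e-9) - 20), 5.5)
})

test_that("PCA reconstruction error vanishes on-manifold and not off it", {
  d <- c(1, 2, -1)
  line <- outer(1:20, d)
  v <- c(2, -1, 0)                       # orthogonal to d
  ctr <- colMeans(line)
  # symmetric off-line pair keeps the centroid and principal axis exact
  pts <- rbind(line, ctr + 3 * v, ctr - 3 * v)
  s <- pca_recon_scores(pts, n_components = 1)
  expect_true(all(order(s, decreasing = TRUE)[1:2] %in% 21:22))
  expect_lt(max(s[1:20]), 1e-9)
  # full rank reconstructs everything
  set.seed(34)
  r <- matrix(rnorm(60), ncol = 3)
  expect_lt(max(pca_recon_scores(r, n_components = 3)), 1e-18)
  # rank-2 data + noise: residual equals the energy off the top-2 plane
  base <- matrix(rnorm(40), ncol = 2) %*% matrix(rnorm(8), 2, 4)
  noisy <- base + matrix(rnorm(80, 0, 0.1), ncol = 4)
  s2 <- pca_recon_scores(noisy, n_components = 2)
  ctr <- sweep(noisy, 2, colMeans(noisy))
  sv <- svd(ctr)
  resid <- rowSums((ctr - sv$u[, 1:2] %*% diag(sv$d[1:2]) %*% t(sv$v[, 1:2]))^2)
  expect_equal(s2, resid, tolerance = 1e-9)
})

test_that("autoencoder scores separate off-manifold rows and are seeded", {
  set.seed(35)
  u <- rnorm(40)
  base <- outer(u, c(1, -0.5, 2, 0.3))          # rank-1
  off <- matrix(rnorm(20, 0, 2), ncol = 4)      # 5 off-manifold rows
  m <- rbind(base, off)
  s1 <- autoencoder_scores(m, hidden_sizes = c(8, 1, 8), epochs = 400, seed = 2)
  s2 <- autoencoder_scores(m, hidden_sizes = c(8, 1, 8), epochs = 400, seed = 2)
  expect_identical(s1, s2)
  expect_gt(mean(s1[41:45]), mean(s1[1:40]))
  # a bottleneck as wide as the input reconstructs almost perfectly
  small <- matrix(rnorm(60, 0, 0.5), ncol = 2)
  s3 <- autoencoder_scores(small, hidden_sizes = c(8, 2, 8), epochs = 2000,
                           lr = 5e-3, seed = 3)
  expect_lt(mean(s3), 0.05 * mean(small^2))
})

test_that("VAE scores are deterministic and find off-manifold rows", {
  set.seed(36)
  base <- outer(rnorm(40), c(1, 2, -1, 0.5))
  m <- rbind(base, matrix(rnorm(12, 0, 2), ncol = 4))
  s1 <- vae_scores(m, latent_dim = 1, epochs = 300, seed = 4)
  expect_identical(s1, vae_scores(m, latent_dim = 1, epochs = 300, seed = 4))
  expect_gt(mean(s1[41:43]), mean(s1[1:40]))
})

test_that("LSCP degenerates to its base detector when the ensemble is redundant", {
  set.seed(37)
  m <- rbind(matrix(rnorm(160), ncol = 2), c(7, 7))
  base <- list(detector_config("hbos", n_bins = 10, tol = 0.1),
               detector_config("hbos", n_bins = 10, tol = 0.1))
  s <- lscp_scores(m, base = base, k_local = 10, seed = 1)
  h <- hbos_scores(m, n_bins = 10, tol = 0.1)
  expect_equal(s, (h - mean(h)) / sd(h), tolerance = 1e-9)
  expect_error(lscp_scores(m, base = base[1], k_local = 10),
               class = "eegsweep_parameter_error")
  expect_error(lscp_scores(m, base = base, k_local = 999),
               class = "eegsweep_parameter_error")
})

test_that("contamination thresholding counts and tie-breaks as documented", {
  set.seed(38)
  s <- rnorm(100)
  fl <- threshold_by_contamination(s, 0.1)
  expect_equal(sum(fl), 10)
  expect_true(all(s[fl] >= max(s[!fl])))
  expect_equal(sum(threshold_by_contamination(s, 0)), 0)
  # all-equal scores: the lowest indices win
  fe <- threshold_by_contamination(rep(1, 100), 0.1)
  expect_equal(which(fe), 1:10)
  expect_error(threshold_by_contamination(s, 1.2), class = "eegsweep_parameter_error")
})

test_that("every scorer gives its maximum to an extreme synthetic outlier", {
  set.seed(39)
  # statistical scorers: gaussian cloud + one far point
  m <- rbind(matrix(rnorm(300), ncol = 3), c(12, -12, 12))
  n <- nrow(m)
  for (method in c("hbos", "lof", "abod", "ocsvm")) {
    cfg <- detector_config(method)
    s <- eegsweep:::.detector_scores(m, cfg, seed = 5)
    expect_equal(which.max(s), n, info = method)
  }
  s <- lscp_scores(m, k_local = 20, seed = 5)
  expect_equal(which.max(s), n)
  # reconstruction scorers judge distance from the data manifold, so the
  # outlier must leave the dominant subspace rather than stretch it
  B <- qr.Q(qr(matrix(rnorm(25), 5)))
  scores2 <- cbind(rnorm(100, 0, 2), rnorm(100, 0, 1))
  m2 <- scores2 %*% t(B[, 1:2]) + matrix(rnorm(500, 0, 0.05), ncol = 5)
  m2 <- rbind(m2, 5 * B[, 3])
  expect_equal(which.max(pca_recon_scores(m2, n_components = 2)), 101L)
  expect_equal(which.max(autoencoder_scores(m2, hidden_sizes = c(16, 2, 16),
                                            epochs = 800, seed = 5)), 101L)
  expect_equal(which.max(vae_scores(m2, latent_dim = 2, hidden = 16,
                                    epochs = 800, seed = 5)), 101L)
})

test_that("run_detection partitions flags per subject and validates input", {
  set.seed(40)
  arr <- array(rnorm(200 * 3 * 40), c(200, 3, 40))
  es <- epoch_set(arr, 200, subject_ids = rep(c("a", "b"), each = 100))
  fm <- matrix(rnorm(200 * 5), ncol = 5)
  det <- run_detection(es, fm, "hbos", contamination = 0.1, mode = "per_subject")
  expect_equal(sum(det$flag[det$subject_id == "a"]), 10)
  expect_equal(sum(det$flag[det$subject_id == "b"]), 10)
  # flag-count conservation across partitions
  expect_equal(sum(det$flag), 2 * ceiling(0.1 * 100))
  expect_error(run_detection(es, fm, "nonsense"), "arg")
  # duplicated subjects: aggregated and per-subject agree on symmetric data
  fm2 <- rbind(fm[1:100, ], fm[1:100, ])
  d_ag <- run_detection(es, fm2, "hbos", 0.1, "aggregated")
  d_ps <- run_detection(es, fm2, "hbos", 0.1, "per_subject")
  expect_equal(d_ag$flag, d_ps$flag)
  g <- glance(det)
  expect_equal(g$n_flagged, 20)
  expect_equal(g$mode, "per_subject")
})

test_that("random search explores seeded configurations and returns the argmax", {
  set.seed(41)
  m <- rbind(matrix(rnorm(200), ncol = 2), matrix(rnorm(20, 5), ncol = 2))
  truth <- c(rep(FALSE, 100), rep(TRUE, 10))
  # single-point space returns that point
  one <- random_search(m, truth, "hbos", list(n_bins = 7), n_trials = 3, seed = 1)
  expect_equal(one$best$params$n_bins, 7)
  rs <- random_search(m, truth, "hbos",
                      list(n_bins = c(3, 5, 10, 20, 50), tol = c(0.1, 0.5)),
                      n_trials = 20, seed = 2)
  expect_gte(rs$best_f1, stats::median(rs$log$f1))
  rs2 <- random_search(m, truth, "hbos",
                       list(n_bins = c(3, 5, 10, 20, 50), tol = c(0.1, 0.5)),
                       n_trials = 20, seed = 2)
  expect_equal(rs$log$f1, rs2$log$f1)
})
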