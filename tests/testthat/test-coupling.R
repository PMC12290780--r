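test_that("coupling identities: orthogonal 0, opposite -1, proportional 1", {
  mesh <- toy_mesh(6)
  E <- 2:6                                # patch of vertex 1
  SC <- matrix(0, 6, 6)
  sc_prof <- c(1, 2, 3, 4, 5)
  SC[1, E] <- sc_prof; SC[E, 1] <- sc_prof
  a <- log1p(sc_prof)

  # FC row orthogonal to the log-SC profile over E
  w <- c(1, -1, 0.5, 0.25, 0)
  w <- w - sum(w * a) / sum(a * a) * a
  FC0 <- matrix(0, 6, 6); diag(FC0) <- 1
  FC0[1, E] <- w; FC0[E, 1] <- w
  prof <- list(sc = list(s = SC), fc = list(s = FC0))
  cpl <- compute_coupling(prof, mesh, method = "inner")
  expect_equal(unname(cpl[1, "v01"]), 0, tolerance = 1e-12)

  # FC row = negated SC profile -> -1; proportional -> +1
  FCn <- FC0; FCn[1, E] <- -a; FCn[E, 1] <- -a
  cpl_n <- compute_coupling(list(sc = list(s = SC), fc = list(s = FCn)),
                            mesh)
  expect_equal(unname(cpl_n[1, "v01"]), -1, tolerance = 1e-12)

  FCp <- FC0; FCp[1, E] <- 3 * a; FCp[E, 1] <- 3 * a
  cpl_p <- compute_coupling(list(sc = list(s = SC), fc = list(s = FCp)),
                            mesh)
  expect_equal(unname(cpl_p[1, "v01"]), 1, tolerance = 1e-12)
})

test_that("inner coupling matches a brute-force sum and obeys its invariants", {
  mesh <- toy_mesh(8)
  prof <- toy_profiles(mesh)
  cpl <- compute_coupling(prof, mesh, method = "inner",
                          log_transform_sc = TRUE)
  # brute force, term by term
  for (v in 1:8) {
    E <- setdiff(1:8, v)
    a <- log(1 + prof$sc$s1[v, E])
    b <- prof$fc$s1[v, E]
    num <- 0; na2 <- 0; nb2 <- 0
    for (k in seq_along(E)) {
      num <- num + a[k] * b[k]; na2 <- na2 + a[k]^2; nb2 <- nb2 + b[k]^2
    }
    expect_equal(unname(cpl[1, v]), num / sqrt(na2 * nb2),
                 tolerance = 1e-12)
  }
  # Cauchy-Schwarz bound
  expect_true(all(cpl >= -1 & cpl <= 1))
  # positive rescaling invariance; antisymmetry under negating one profile
  prof2 <- prof; prof2$fc$s1 <- 2.5 * prof$fc$s1
  expect_equal(unclass(compute_coupling(prof2, mesh)), unclass(cpl),
               ignore_attr = TRUE, tolerance = 1e-12)
  prof3 <- prof; prof3$fc$s1 <- -prof$fc$s1
  expect_equal(unclass(compute_coupling(prof3, mesh)), -unclass(cpl),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("pearson and spearman coupling variants behave as correlations", {
  mesh <- toy_mesh(8)
  prof <- toy_profiles(mesh)
  cp <- compute_coupling(prof, mesh, method = "pearson")
  cs <- compute_coupling(prof, mesh, method = "spearman")
  v <- 3; E <- setdiff(1:8, v)
  expect_equal(unname(cp[1, v]),
               cor(log1p(prof$sc$s1[v, E]), prof$fc$s1[v, E]),
               tolerance = 1e-12)
  # spearman is invariant under strictly monotone transforms of a profile
  prof_m <- prof
  prof_m$fc$s1 <- tanh(3 * prof$fc$s1)    # strictly increasing
  cs2 <- compute_coupling(prof_m, mesh, method = "spearman")
  expect_equal(unclass(cs2), unclass(cs), ignore_attr = TRUE,
               tolerance = 1e-12)
})

test_that("masked vertices are excluded and zero profiles yield NA", {
  mesh <- toy_mesh(8, masked = c(2, 5))
  prof <- toy_profiles(mesh)
  cpl <- compute_coupling(prof, mesh)
  expect_equal(ncol(cpl), 6)
  expect_false(any(c("v02", "v05") %in% colnames(cpl)))

  sc0 <- prof; sc0$sc$s1[,] <- 0
  expect_warning(c0 <- compute_coupling(sc0, mesh), "degenerate")
  expect_true(all(is.na(c0)))
})

test_that("kernel smoothing reduces to identity at tiny bandwidth and averages correctly", {
  mesh <- toy_mesh(5)
  SC <- toy_profiles(mesh)$sc$s1
  sm <- smooth_sc(SC, mesh, bandwidth = 1e-6)
  expect_equal(sm, SC, tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(smooth_sc(matrix(0, 5, 5), mesh, 0.5), matrix(0, 5, 5),
               ignore_attr = TRUE)
  expect_error(smooth_sc(SC, mesh, 0), "bandwidth")

  # 3-vertex toy with hand-computed Gaussian weights
  m3 <- data.frame(vertex_id = c("a", "b", "c"),
                   x = c(0, 1, 2), y = 0, z = 0,
                   hemisphere = "L", network = 1L, region = 1L,
                   mask = FALSE, stringsAsFactors = FALSE)
  class(m3) <- c("surface_mesh", "data.frame")
  S <- matrix(c(0, 2, 4, 2, 0, 6, 4, 6, 0), 3, 3)
  bw <- 1
  D <- as.matrix(dist(cbind(m3$x, m3$y, m3$z)))
  W <- exp(-0.5 * (D / bw)^2)
  W <- sweep(W, 2, colSums(W), "/")
  expected <- (S %*% W + t(S %*% W)) / 2
  expect_equal(smooth_sc(S, m3, bw), expected, tolerance = 1e-12)
  # each smoothed row is a convex combination: mass conserved per column
  expect_equal(colSums(W), rep(1, 3) / 1, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("FC from time series is the Pearson correlation matrix", {
  set.seed(61)
  B <- matrix(rnorm(40), 10, 4)
  B[, 2] <- B[, 1]                       # duplicate -> correlation 1
  FC <- fc_from_timeseries(B)
  expect_equal(FC[1, 2], 1)
  B2 <- cbind(B[, 1], -B[, 1], B[, 3:4])
  expect_equal(fc_from_timeseries(B2)[1, 2], -1)
  # 2 vertices, 4 time points, textbook Pearson value
  x <- c(1, 2, 3, 4); y <- c(2, 1, 4, 3)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(fc_from_timeseries(cbind(x, y))[1, 2], r_hand)
  Bc <- B; Bc[, 3] <- 5
  expect_error(fc_from_timeseries(Bc), "constant")
  expect_error(fc_from_timeseries(B[1:2, ]), "3 time points")
})

test_that("simulated connectivity round-trips its coupling targets exactly", {
  co <- make_cohort(n_mz = 3, n_dz = 2, n_fs = 3, n_single = 4,
                    n_snps = 200, seed = 63)
  mesh <- generate_mesh(20, 2, 4, seed = 64)
  prof <- simulate_connectivity(mesh, co$K, h2_coupling = 0.4, seed = 65)
  cpl <- compute_coupling(prof, mesh, method = "inner")
  expect_lt(max(abs(cpl - prof$targets)), 1e-10)
  # coupling column count equals unmasked vertex count
  expect_equal(ncol(cpl), sum(!mesh$mask))
})
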