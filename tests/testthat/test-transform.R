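test_that("split_omega partitions and symmetrizes blocks", {
  expect_equal(split_omega(diag(4))$J, diag(2))
  expect_equal(split_omega(diag(4))$K, matrix(0, 2, 2))
  expect_equal(split_omega(diag(4))$N, diag(2))

  set.seed(12)
  om <- random_spd(6)
  b <- split_omega(om)
  expect_equal(b$J, om[1:3, 1:3])
  expect_equal(b$K, om[1:3, 4:6])
  expect_equal(b$N, om[4:6, 4:6])
  # reassembly reproduces omega
  expect_equal(rbind(cbind(b$J, b$K), cbind(t(b$K), b$N)), om)

  expect_error(split_omega(matrix(rnorm(16), 4)), "not symmetric")
  expect_error(split_omega(diag(3)), "even dimension")
})

test_that("choose_D scales the top eigenvalue and keeps D - J PSD", {
  expect_equal(choose_D(diag(2), 1.1), 1.1 * diag(2))
  D <- choose_D(diag(c(1, 4)), 1.5)
  expect_equal(D, diag(c(6, 6)))
  expect_equal(eigen(D - diag(c(1, 4)), symmetric = TRUE,
                     only.values = TRUE)$values, c(5, 2))
  # boundary delta_c = 1: H singular but PSD
  J <- diag(c(2, 5))
  H <- choose_D(J, 1) - J
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-12)
  expect_lt(min(abs(ev)), 1e-12)
  expect_error(choose_D(diag(2), 0.9), "delta_c")
})

test_that("build_transform zeroes the cross block and diagonalizes block 22", {
  inst <- logistic_augmented_fit(n = 500, d = 5, seed = 101)
  tr <- build_transform(inst$blocks, delta_c = 1.1)
  om <- inst$fit$covariance
  d <- inst$d
  J <- inst$blocks$J; K <- inst$blocks$K; N <- inst$blocks$N
  P <- tr$P; V <- tr$V

  # independence objective: top-right block of Z Omega Z' vanishes
  cross <- J + P %*% t(K) + K %*% t(V) + P %*% N %*% t(V)
  expect_lte(norm(cross, "F"), 1e-8 * norm(om, "F"))
  # diagonal objective: bottom-right block equals D entrywise
  bottom <- J + V %*% t(K) + K %*% t(V) + V %*% N %*% t(V)
  expect_lt(max(abs(bottom - tr$D)), 1e-6)
  # D - J PSD at the default delta_c
  expect_gte(min(eigen(tr$D - J, symmetric = TRUE, only.values = TRUE)$values),
             -1e-10)
  expect_lte(tr$care_residual, 1e-6 * (1 + norm(tr$D - J, "F")))
})

test_that("brute-force Z Omega Z' is block diagonal with diagonal second block", {
  set.seed(55)
  for (seed in c(7, 19, 31)) {
    inst <- logistic_augmented_fit(n = 500, d = 5, seed = seed)
    tr <- build_transform(inst$blocks)
    zoz <- z_omega_z(tr, inst$fit$covariance)
    d <- inst$d
    expect_lte(norm(zoz[1:d, d + 1:d, drop = FALSE], "F"),
               1e-8 * norm(inst$fit$covariance, "F"))
    b22 <- zoz[d + 1:d, d + 1:d]
    expect_lt(max(abs(b22 - diag(diag(b22)))), 1e-6)
    expect_equal(b22, unname(tr$D), tolerance = 1e-6)
  }
})

test_that("apply_transform reproduces hand arithmetic and PSD var1", {
  # theta_2 = 0 => both estimates collapse to theta_1
  inst <- logistic_augmented_fit(n = 300, d = 3, seed = 77)
  tr <- build_transform(inst$blocks)
  th <- c(1.5, -2, 0.25, 0, 0, 0)
  pe <- apply_transform(th, tr, inst$blocks)
  expect_equal(pe$beta1, th[1:3])
  expect_equal(pe$beta2, th[1:3])

  # d = 1 scalar arithmetic
  om <- matrix(c(2, 0.3, 0.3, 1.5), 2)
  b <- split_omega(om)
  tr1 <- build_transform(b, delta_c = 1.2)
  th1 <- c(0.7, -0.4)
  pe1 <- apply_transform(th1, tr1, b)
  expect_equal(pe1$beta1, th1[1] + drop(tr1$P) * th1[2])
  expect_equal(pe1$beta2, th1[1] + drop(tr1$V) * th1[2])
  v1 <- b$J + tr1$P %*% t(b$K) + b$K %*% t(tr1$P) + tr1$P %*% b$N %*% t(tr1$P)
  expect_equal(pe1$var1, (v1 + t(v1)) / 2)
  expect_equal(pe1$var2, tr1$D)

  # var1 PSD across seeded instances
  set.seed(99)
  for (i in 1:100) {
    om <- random_spd(6)
    b <- split_omega(om)
    tr <- build_transform(b)
    pe <- apply_transform(rnorm(6), tr, b)
    expect_gte(min(eigen(pe$var1, symmetric = TRUE, only.values = TRUE)$values),
               -1e-10)
  }
})

test_that("the linear-model choice P = I, V = -I fails for logistic knockoffs", {
  # With heteroskedastic weights the fixed choice no longer decorrelates the
  # paired estimators: the cross block of Z Omega Z' stays bounded away from
  # 0.  Strong same-sign signal makes the weights covary with the
  # covariates, which is exactly what breaks the fixed transform.
  inst <- logistic_augmented_fit(n = 1500, d = 4, rho = 0.25, seed = 13,
                                 beta = c(2, 2, 2, 2),
                                 strategy = "model_x_gaussian")
  d <- inst$d
  naive <- list(P = diag(d), V = -diag(d))
  zoz <- z_omega_z(naive, inst$fit$covariance)
  cross_norm <- norm(zoz[1:d, d + 1:d, drop = FALSE], "F")
  expect_gt(cross_norm, 1e-3 * norm(inst$fit$covariance, "F"))
  # while the Riccati-based transform does decorrelate the same fit
  tr <- build_transform(inst$blocks)
  zoz2 <- z_omega_z(tr, inst$fit$covariance)
  expect_lte(norm(zoz2[1:d, d + 1:d, drop = FALSE], "F"),
             1e-8 * norm(inst$fit$covariance, "F"))
})

test_that("paired estimators are empirically independent under the global null", {
  # Monte-Carlo check of the two decorrelation objectives at the estimator
  # level: across global-null logistic replicates, corr(beta1_j, beta2_k) is
  # null and cov(beta2) is diagonal with diagonal near the average D.
  reps <- 500; n <- 2000; d <- 4
  B1 <- B2 <- matrix(NA_real_, reps, d)
  Dbar <- matrix(0, d, d)
  for (r in 1:reps) {
    X <- gts_sim_design(n, d, 0.5, seed = 5000 + r)
    y <- gts_sim_response(X, rep(0, d), "binomial", seed = 6000 + r)
    aug <- cbind(X, gts_regenerate(X, "row_permutation",
                                   seed = 7000 + r)$matrix)
    fit <- gts_glm_fit(aug, y, "binomial")
    blocks <- split_omega(fit$covariance)
    tr <- build_transform(blocks)
    pe <- apply_transform(fit$coefficients, tr, blocks)
    B1[r, ] <- pe$beta1
    B2[r, ] <- pe$beta2
    Dbar <- Dbar + pe$var2 / reps
  }
  mc_se <- 1 / sqrt(reps)
  cross_cor <- cor(B1, B2)
  expect_lt(max(abs(cross_cor)), 4 * mc_se)
  cov2 <- cov(B2)
  offdiag <- cov2 - diag(diag(cov2))
  # off-diagonal covariance null within 4 MC SEs of a covariance entry
  expect_lt(max(abs(offdiag)), 4 * max(diag(cov2)) / sqrt(reps))
  expect_equal(diag(cov2), diag(Dbar), tolerance = 4 / sqrt(reps))
})
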