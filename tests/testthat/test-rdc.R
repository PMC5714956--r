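# Saupe tensors, RDC prediction, SVD fitting, Q factor, NSP

test_that("saupe_tensor enforces and derives its invariants", {
  t0 <- saupe_from_elements(3, -1, 2, 0.5, -0.7)
  expect_equal(sum(diag(t0$S)), 0, tolerance = 1e-12)
  expect_equal(t0$S, t(t0$S))
  # eigenvalue ordering |Szz| >= |Syy| >= |Sxx| and R in [0, 2/3]
  ev <- t0$eigvals
  expect_true(abs(ev[3]) >= abs(ev[2]) && abs(ev[2]) >= abs(ev[1]))
  expect_gte(t0$rhombicity, 0)
  expect_lte(t0$rhombicity, 2 / 3 + 1e-12)
  expect_equal(t0$Da, ev[3] / 2)

  expect_error(saupe_tensor(matrix(1:9, 3, 3)), "symmetric")
  expect_error(saupe_tensor(diag(3)), "traceless")
})

test_that("predict_rdc closed forms and frame equivalence", {
  # axially symmetric tensor with principal z along lab z
  da <- 7
  t_ax <- saupe_tensor(diag(c(-da, -da, 2 * da)))
  expect_equal(t_ax$rhombicity, 0, tolerance = 1e-12)
  # vector along principal z: theta = 0 -> D = 2 Da
  expect_equal(unname(predict_rdc(data.frame(vx = 0, vy = 0, vz = 1), t_ax)),
               2 * da, tolerance = 1e-12)
  # magic angle: D = 0
  ma <- acos(1 / sqrt(3))
  v_ma <- data.frame(vx = sin(ma), vy = 0, vz = cos(ma))
  expect_equal(unname(predict_rdc(v_ma, t_ax)), 0, tolerance = 1e-10)

  # cartesian and principal-frame formulas agree on random tensors/vectors
  set.seed(31)
  for (k in 1:20) {
    tk <- random_saupe(5)
    vk <- random_unit_vectors(50)
    d1 <- predict_rdc(vk, tk, frame = "cartesian")
    d2 <- predict_rdc(vk, tk, frame = "principal")
    expect_lt(max(abs(d1 - d2)) / max(abs(d1)), 1e-9)
  }

  # isotropic average vanishes (numerical-integration oracle)
  set.seed(8)
  tk <- random_saupe(10)
  vv <- random_unit_vectors(200000)
  d <- predict_rdc(vv, tk)
  expect_lt(abs(mean(d)), 0.05 * sqrt(mean(d^2)))
})

test_that("nh_vectors returns unit vectors and skips prolines", {
  pep <- fixture_peptide()
  v <- nh_vectors(pep, 1)
  expect_equal(rowSums(as.matrix(v[, c("vx", "vy", "vz")])^2),
               rep(1, nrow(v)), tolerance = 1e-9)
  sk <- attr(v, "skipped")
  prolines <- unique(pep$atoms$resno[pep$atoms$resname == "PRO"])
  expect_setequal(sk$resno[sk$reason == "proline"], prolines)
  # one vector per non-proline residue of the chain
  all_res <- unique(pep$atoms$resno)
  expect_equal(nrow(v), length(all_res) - length(prolines))

  # idealized geometry: H 1.02 A from N along +x
  a <- data.frame(model = 1, chain = "A", resno = c(1, 1, 1, 1),
                  resname = "ALA", atom = c("N", "H", "CA", "C"),
                  x = c(0, 1.02, 1, 2), y = c(0, 0, 1, 1), z = 0)
  v1 <- nh_vectors(nmr_structure(a), 1)
  expect_equal(unlist(v1[1, c("vx", "vy", "vz")], use.names = FALSE),
               c(1, 0, 0), tolerance = 1e-12)
})

test_that("fit_saupe equals the brute-force normal-equations solve", {
  set.seed(17)
  for (k in 1:10) {
    v <- random_unit_vectors(15)
    t0 <- random_saupe(8)
    d <- predict_rdc(v, t0) + rnorm(15, 0, 0.5)
    fit <- fit_saupe(v, d)
    # independent oracle: explicit normal equations
    V <- as.matrix(v)
    A <- cbind(V[, 1]^2 - V[, 3]^2, V[, 2]^2 - V[, 3]^2,
               2 * V[, 1] * V[, 2], 2 * V[, 1] * V[, 3], 2 * V[, 2] * V[, 3])
    x <- solve(t(A) %*% A, t(A) %*% d)
    S_oracle <- matrix(c(x[1], x[3], x[4],
                         x[3], x[2], x[5],
                         x[4], x[5], -(x[1] + x[2])), 3, 3)
    expect_lt(max(abs(fit$tensor$S - S_oracle)), 1e-8)
  }
  expect_error(fit_saupe(random_unit_vectors(4), rnorm(4)), ">= 5")
  # degenerate orientations: all vectors identical
  vdeg <- data.frame(vx = rep(1, 6), vy = 0, vz = 0)
  expect_error(fit_saupe(vdeg, rnorm(6)), "degenerate")
})

test_that("fit_tensor_svd round-trips noiseless structural RDCs", {
  pep <- fixture_peptide()
  t0 <- fixture_tensor()
  rdc <- simulate_rdcs(pep, t0, noise = 0)
  fit <- fit_tensor_svd(pep, 1, rdc)
  expect_lt(max(abs(fit$tensor$S - t0$S)), 1e-8)
  expect_lt(fit$q, 1e-9)
  expect_equal(fit$pearson_r, 1, tolerance = 1e-9)
  # back-calculation covers all residues with coordinates, not only fitted
  sub <- rdc[rdc$resno <= 800, ]
  fit2 <- fit_tensor_svd(pep, 1, sub)
  expect_gt(length(fit2$d_calc), nrow(sub))
})

test_that("noisy fit Q matches the analytic in-sample expectation", {
  # with d_exp = d_true + eps, the LS fit absorbs 5 dof:
  # E[Q] ~ sigma * sqrt(1 - 5/N) / rms(d_true)
  set.seed(77)
  sigma <- 1
  n <- 100
  v <- random_unit_vectors(n)
  t0 <- saupe_tensor(diag(c(-10, -10, 20)))  # |D| up to 40, rms ~ 20-ish
  d_true <- predict_rdc(v, t0)
  qs <- replicate(30, {
    d <- d_true + rnorm(n, 0, sigma)
    fit <- fit_saupe(v, d)
    q_factor(d, predict_rdc(v, fit$tensor))
  })
  q_expect <- sigma * sqrt(1 - 5 / n) / sqrt(mean(d_true^2))
  expect_equal(mean(qs), q_expect, tolerance = 0.2)

  # monotonicity: expected Q increases with noise
  mean_q <- function(sig) {
    mean(replicate(25, {
      d <- d_true + rnorm(n, 0, sig)
      fit <- fit_saupe(v, d)
      q_factor(d, predict_rdc(v, fit$tensor))
    }))
  }
  qs_by_sigma <- vapply(c(0, 0.5, 1, 2), mean_q, numeric(1))
  expect_true(all(diff(qs_by_sigma) > 0))
})

test_that("q_factor implements the normalized rms deviation exactly", {
  expect_equal(q_factor(c(10, -10), c(9, -11)), 0.1, tolerance = 1e-12)
  expect_equal(q_factor(c(3, 4), c(3, 4)), 0)
  expect_equal(q_factor(c(3, 4), c(0, 0)), 1)
  expect_error(q_factor(c(0, 0), c(1, 1)), "zero")
})

test_that("Q and r are invariant under joint rotation of structure and tensor", {
  pep <- fixture_peptide()
  t0 <- fixture_tensor()
  rdc <- simulate_rdcs(pep, t0, noise = 1, seed = 5)
  fit0 <- fit_tensor_svd(pep, 1, rdc)

  R <- rotation_matrix(c(2, -1, 1), 61)
  a <- pep$atoms
  a[, c("x", "y", "z")] <- as.matrix(a[, c("x", "y", "z")]) %*% t(R)
  fit1 <- fit_tensor_svd(nmr_structure(a), 1, rdc)
  expect_equal(fit1$q, fit0$q, tolerance = 1e-9)
  expect_equal(fit1$pearson_r, fit0$pearson_r, tolerance = 1e-9)
  # and the fitted tensor co-rotates: R S R'
  expect_lt(max(abs(fit1$tensor$S - R %*% fit0$tensor$S %*% t(R))), 1e-6)
})

test_that("nsp identities and constructed orthogonal pair", {
  t0 <- fixture_tensor()
  expect_equal(nsp(t0, saupe_tensor(2 * t0$S)), 1, tolerance = 1e-12)
  expect_equal(nsp(t0, saupe_tensor(-t0$S)), -1, tolerance = 1e-12)
  # orthogonal pair: diag(1,-1,0)-type and off-diagonal-only tensors have
  # zero Frobenius inner product (verified by the direct elementwise sum)
  t1 <- saupe_tensor(diag(c(1, -1, 0)))
  S2 <- matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3, 3)
  expect_equal(sum(t1$S * S2), 0)
  expect_equal(nsp(t1, saupe_tensor(S2)), 0, tolerance = 1e-12)
  expect_error(nsp(t1, matrix(0, 3, 3)), "zero tensor")
  # symmetry and scale invariance
  t2 <- saupe_from_elements(1, 2, -1, 0.3, 0.9)
  expect_equal(nsp(t0, t2), nsp(t2, t0))
  expect_equal(nsp(saupe_tensor(0.1 * t0$S), t2), nsp(t0, t2),
               tolerance = 1e-12)
})

test_that("RDC TSV I/O round-trips and accepts two-column tables", {
  pep <- fixture_peptide()
  rdc <- simulate_rdcs(pep, fixture_tensor(), noise = 1, seed = 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_rdc_tsv(rdc, path)
  back <- read_rdc_tsv(path)
  expect_equal(back$d_exp, rdc$d_exp, tolerance = 1e-9)

  p2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("resno\td_exp", "786\t3.2", "787\t-1.1"), p2)
  two <- read_rdc_tsv(p2)
  expect_equal(two$d_exp, c(3.2, -1.1))
  expect_equal(two$atom1, c("N", "N"))
})
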