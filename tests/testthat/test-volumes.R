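test_that("rational solves agree with floating-point solves", {
  set.seed(51)
  for (i in 1:50) {
    d <- sample(2:5, 1)
    A <- matrix(sample(-6:6, d * d, replace = TRUE), d)
    if (abs(det(A)) < 0.5) next
    b <- sample(-9:9, d, replace = TRUE)
    x <- gbembed:::q_solve_int(A, b)
    expect_lt(max(abs(x$n / x$d - solve(A, b))), 1e-9)
    # exact residual is identically zero
    for (r in seq_len(d)) {
      res <- gbembed:::q_sub(gbembed:::qv_dot_int(A[r, ], x),
                             gbembed:::qq(b[r]))
      expect_equal(res$n, 0)
    }
  }
})

test_that("exact volume recovers simplices, boxes and known regions", {
  for (d in 1:5) {
    simplex <- polytope(rbind(-diag(d), rep(1, d)), c(rep(0, d), 1))
    v <- exact_volume(simplex)
    expect_equal(v$num, 1)
    expect_equal(v$den, factorial(d))
  }
  box <- polytope(rbind(diag(3), -diag(3)), c(2, 1, 1, 0, 0, 1))
  expect_equal(exact_volume(box)$value, 2 * 1 * 2)
  # interval region of the two-state model: [-1, 1]
  cfn <- eigen_region("CFN", "delta")
  vc <- exact_volume(cfn)
  expect_equal(vc$num, 2)
  expect_equal(vc$den, 1)
  # empty polytope has zero volume
  empty <- polytope(rbind(1, -1), c(-1, 0))
  expect_equal(exact_volume(empty)$value, 0)
})

test_that("vertex enumeration finds the exact vertex set", {
  simplex <- polytope(rbind(-diag(2), rep(1, 2)), c(0, 0, 1))
  V <- polytope_vertices(simplex)
  pts <- apply(V$n / V$d, 2, paste, collapse = ",")
  expect_setequal(pts, c("0,0", "1,0", "0,1"))
})

test_that("linear region volumes match the published exact fractions", {
  # (duplicated at acceptance scale; here the cheap three)
  v <- exact_volume(eigen_region("H3P", "delta"))
  expect_equal(c(v$num, v$den), c(4, 3))
  v <- exact_volume(eigen_region("H3P", "delta_dd"))
  expect_equal(c(v$num, v$den), c(1, 6))
  v <- exact_volume(eigen_region("H7P", "delta"))
  expect_equal(c(v$num, v$den), c(256, 315))
})

test_that("Monte Carlo volume is unbiased, seeded and error-calibrated", {
  always <- function(X) rep(TRUE, nrow(X))
  v <- mc_volume(always, list(lower = 0, upper = 1), 1000, seed = 1)
  expect_equal(v$value, 1)
  expect_equal(v$stderr, 0)
  half <- function(X) X[, 1] < 0.5
  v2 <- mc_volume(half, list(lower = 0, upper = 1), 1e6, seed = 2)
  expect_lt(abs(v2$value - 0.5), 3 * v2$stderr + 1e-12)
  # reproducible and recorded
  v3 <- mc_volume(half, list(lower = 0, upper = 1), 1e6, seed = 2)
  expect_identical(v2$value, v3$value)
  expect_equal(v2$seed, 2)
  expect_equal(v2$n, 1e6)
  # agreement with an exact volume: H3P delta over its bounding box
  p3 <- eigen_region("H3P", "delta")
  ind <- function(X) {
    ok <- rep(TRUE, nrow(X))
    for (i in seq_along(p3$b))
      ok <- ok & (X %*% p3$A[i, ] <= p3$b[i])
    ok
  }
  box <- list(lower = c(-1, -1, -1), upper = c(1, 1, 1))
  vmc <- mc_volume(ind, box, 2e5, seed = 3)
  expect_lt(abs(vmc$value - 4 / 3), 4 * vmc$stderr)
})

test_that("the embeddable-region indicator matches the embeddability test", {
  set.seed(52)
  for (id in c("H7P", "H3P", "CFN")) {
    p <- model_preset(id)
    ind <- embeddable_indicator(p)
    d <- length(p$free_blocks)
    Ki <- inverse_dft_matrix(dft_matrix(p$group))
    X <- matrix(stats::runif(60 * d), 60, d)
    hits <- ind(X)
    for (i in seq_len(nrow(X))) {
      lam <- gbembed:::free_to_spectrum(p, X[i, ])
      f <- as.numeric(Re(Ki %*% lam))
      if (min(f) < 0) next  # outside the model simplex: no matrix to test
      P <- markov_matrix(transition_vector(p$group, f))
      r <- check_embeddable(P, preset = p)
      expect_equal(unname(hits[i]), r$verdict == "embeddable",
                   info = sprintf("%s row %d", id, i))
    }
    # spectra of exponentials are always hits
    for (i in 1:10) {
      rv <- random_rate_vector(p)
      lam <- spectrum(expm_via_dft(rv))$values
      expect_true(ind(gbembed:::spectrum_to_free(p, lam)))
    }
  }
  # every MC hit corresponds to a stochastic matrix (embeddability
  # implies Markov-ness: the point is exp of a model rate matrix)
  p7 <- model_preset("H7P")
  ind7 <- embeddable_indicator(p7)
  X <- matrix(stats::runif(2e5 * 7), ncol = 7)
  H <- X[ind7(X), , drop = FALSE]
  Ki8 <- inverse_dft_matrix(dft_matrix(p7$group))
  for (i in seq_len(nrow(H))) {
    f <- as.numeric(Re(Ki8 %*% c(1, H[i, ])))
    expect_gt(min(f), -1e-12)
  }
})

test_that("H3P embeddable-region quadrature hits the closed-form value", {
  # independent closed form: int_0^1 int_0^sqrt(x) (x y^2)^(1/4) dy dx
  # = int_0^1 (2/3) x dx = 1/3
  v <- h3p_me_volume("me", abs_tol = 1e-7)
  expect_lt(abs(v$value - 1 / 3), 1e-6)
  expect_equal(v$method, "quadrature")
  expect_error(h3p_me_volume("me", abs_tol = 1e-9), "abs_tol")
})

test_that("general Jukes-Cantor intervals follow the closed-form family", {
  s8 <- general_jc_sets(8)
  expect_equal(s8$delta$value[2], 1 / 7)
  expect_equal(s8$delta_plus$value[2], 1 / 8)
  expect_equal(s8$delta_dd$value[2], 1 / 14)
  expect_true(s8$delta_me$right_open)
  expect_equal(s8$delta_me$value[2], 1 / 8)
  s2 <- general_jc_sets(2)
  expect_equal(s2$delta$value[2], 1)
  expect_equal(s2$delta_me$value[2], 1 / 2)
  expect_error(general_jc_sets(1), ">= 2")
  # relative volume V(me)/V(delta) = (n-1)/n, exactly, for all n
  for (n in 2:12) {
    s <- general_jc_sets(n)
    num <- s$delta_me$num[2] * s$delta$den[2]
    den <- s$delta_me$den[2] * s$delta$num[2]
    g <- gbembed:::q_gcd(num, den)
    expect_equal(c(num, den) / g, c(n - 1, n))
  }
})

test_that("volume reports are internally consistent and nested", {
  r3 <- volume_report("H3P")
  v <- stats::setNames(r3$absolute$value, r3$absolute$region)
  expect_true(v["me"] <= v["delta_plus"] + 1e-9)
  expect_true(v["delta_plus"] <= v["delta"])
  expect_true(v["delta_dd"] <= v["delta_plus"] + 1e-9)
  expect_equal(unname(r3$relative$vol_over_delta),
               c(1, 21 / 64, 1 / 8), tolerance = 1e-9)
  rg <- volume_report("GJC:8")
  vg <- stats::setNames(rg$absolute$value, rg$absolute$region)
  expect_true(all(vg["me"] <= vg["delta_plus"],
                  vg["delta_plus"] <= vg["delta"],
                  vg["delta_dd"] <= vg["delta_plus"]))
  expect_equal(unname(rg$relative$me_over_region), c(7 / 8, 1, 1))
})
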