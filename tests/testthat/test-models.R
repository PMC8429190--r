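test_that("rate and Markov matrices follow the convolution pattern", {
  G <- parse_group("Z7")
  rv <- rate_vector(G, example2_psi)
  Q <- rate_matrix(rv)
  expect_equal(unname(Q[1, ]), example2_psi)
  expect_equal(Q, t(Q))
  expect_equal(unname(rowSums(Q)), rep(0, 7))
  # spot entries of the printed 7x7 rate matrix
  expect_equal(Q["0", "3"], 0.25)
  expect_equal(Q["2", "6"], 0.25)   # 6 - 2 = 4
  expect_equal(Q["5", "6"], 0.125)  # difference 1
  # trivial cases
  Gz <- parse_group("Z2")
  expect_equal(unname(rate_matrix(rate_vector(Gz, c(-0.4, 0.4)))),
               matrix(c(-0.4, 0.4, 0.4, -0.4), 2))
  expect_equal(unname(rate_matrix(rate_vector(Gz, c(0, 0)))),
               matrix(0, 2, 2))
  tv <- transition_vector(parse_group("Z2xZ2"), c(1, 0, 0, 0))
  expect_equal(unname(markov_matrix(tv)), diag(4))
})

test_that("model vector validation rejects broken invariants", {
  G <- parse_group("Z2xZ2")
  expect_error(rate_vector(G, c(-1, 0.5, 0.5, 0.5)), "sum to 0")
  expect_error(rate_vector(G, c(0.5, -0.5, 0.5, -0.5)), "non-negative")
  expect_error(transition_vector(G, c(0.5, 0.5, 0.25, -0.25)),
               "non-negative")
  G4 <- parse_group("Z4")
  expect_error(rate_vector(G4, c(-1, 0.5, 0.25, 0.25)), "symmetric")
  L <- general_jc_labeling(G)
  expect_error(rate_vector(G, c(-1, 0.5, 0.25, 0.25), labeling = L),
               "constant on labeling blocks")
})

test_that("spectra match the closed-form eigenvalue formulas", {
  # two states: lambda_1 = a - b
  a <- 0.7; b <- 0.3
  s <- spectrum(transition_vector(parse_group("Z2"), c(a, b)))
  expect_equal(s$values, c(1, a - b))
  # four states, all blocks distinct
  G4 <- parse_group("Z2xZ2")
  f4 <- c(0.4, 0.3, 0.2, 0.1)  # (a, b, c, d) in A,T,C,G order
  s4 <- spectrum(transition_vector(G4, f4))
  expect_equal(s4$values,
               c(1, 0.4 - 0.3 + 0.2 - 0.1, 0.4 + 0.3 - 0.2 - 0.1,
                 0.4 - 0.3 - 0.2 + 0.1))
  # hachimoji 3-parameter: x = a - 4b + c + 2d, y = a + c - 2d, z = a - c
  h3p <- model_preset("H3P")
  abcd <- c(a = 0.5, b = 0.05, c = 0.2, d = 0.05)  # a + 4b + c + 2d = 1
  f8 <- numeric(8)
  f8[h3p$labeling$blocks[[1]]] <- abcd["a"]
  f8[h3p$labeling$blocks[[2]]] <- abcd["b"]
  f8[h3p$labeling$blocks[[3]]] <- abcd["c"]
  f8[h3p$labeling$blocks[[4]]] <- abcd["d"]
  s8 <- spectrum(transition_vector(h3p$group, f8))
  free <- gbembed:::spectrum_to_free(h3p, s8$values)
  expect_equal(unname(free),
               unname(c(abcd["a"] - 4 * abcd["b"] + abcd["c"] + 2 * abcd["d"],
                        abcd["a"] + abcd["c"] - 2 * abcd["d"],
                        abcd["a"] - abcd["c"])))
  expect_equal(s8$values[1], 1)
})

test_that("spectrum agrees with a dense eigendecomposition", {
  set.seed(11)
  for (id in all_presets) {
    p <- model_preset(id)
    rv <- random_rate_vector(p)
    tv <- expm_via_dft(rv)
    lam <- sort(spectrum(tv)$values)
    dense <- sort(eigen(markov_matrix(tv), symmetric = TRUE,
                        only.values = TRUE)$values)
    expect_lt(max(abs(lam - dense)), 1e-8)
    lam_q <- sort(spectrum(rv)$values)
    dense_q <- sort(eigen(rate_matrix(rv), symmetric = TRUE,
                          only.values = TRUE)$values)
    expect_lt(max(abs(lam_q - dense_q)), 1e-8)
  }
})

test_that("Markov spectra lie in [-1, 1] with lambda_0 = 1; rate spectra are non-positive", {
  set.seed(12)
  for (rep in 1:50) {
    G <- parse_group(sample(c("Z2", "Z5", "Z2xZ2", "Z2xZ2xZ2"), 1))
    u <- stats::runif(G$order)
    p <- gbembed:::neg_perm(G)
    u <- (u + u[p]) / 2          # symmetrize
    f <- u / sum(u)
    s <- spectrum(transition_vector(G, f))
    expect_equal(s$values[1], 1)
    expect_true(all(abs(s$values) <= 1 + 1e-12))
    psi <- u; psi[1] <- 0; psi[1] <- -sum(psi)
    sq <- spectrum(rate_vector(G, psi))
    expect_lt(abs(sq$values[1]), 1e-12)
    expect_true(all(sq$values <= 1e-12))
  }
})

test_that("Fourier-basis exponential matches a dense matrix exponential", {
  set.seed(13)
  for (id in all_presets) {
    p <- model_preset(id)
    for (rep in 1:5) {
      rv <- random_rate_vector(p)
      P1 <- markov_matrix(expm_via_dft(rv))
      P2 <- dense_expm(rate_matrix(rv))
      expect_lt(max(abs(P1 - P2)), 1e-8)
    }
  }
  # closed form for two states: f(0) = (1 + exp(-2q)) / 2
  q <- 0.35
  tv <- expm_via_dft(rate_vector(parse_group("Z2"), c(-q, q)))
  expect_equal(tv$f[1], (1 + exp(-2 * q)) / 2)
  # zero rates give the identity
  tv0 <- expm_via_dft(rate_vector(parse_group("Z2xZ2"), rep(0, 4)))
  expect_equal(tv0$f, c(1, 0, 0, 0))
})

test_that("exp followed by principal log recovers the rate vector", {
  set.seed(14)
  for (id in all_presets) {
    p <- model_preset(id)
    worst <- 0
    for (rep in 1:500) {
      rv <- random_rate_vector(p)
      back <- principal_log_via_dft(expm_via_dft(rv))
      worst <- max(worst, max(abs(back$psi - rv$psi)))
    }
    expect_lt(worst, 1e-9)
  }
})

test_that("principal log refuses non-positive spectra", {
  G <- parse_group("Z2")
  tv <- transition_vector(G, c(0.4, 0.6))  # lambda_1 = -0.2
  expect_error(principal_log_via_dft(tv),
               class = "gbembed_domain_error")
  expect_error(principal_log_via_dft(tv), "-0.2")
  # identity maps to the zero rate vector
  id4 <- transition_vector(parse_group("Z2xZ2"), c(1, 0, 0, 0))
  expect_equal(principal_log_via_dft(id4)$psi, rep(0, 4))
})

test_that("structure inference recovers vector, labeling and class", {
  G <- parse_group("Z7")
  tv <- expm_via_dft(rate_vector(G, example2_psi))
  P <- markov_matrix(tv)
  info <- infer_structure(P, G)
  expect_equal(info$kind, "markov")
  # the exponential induces the pair labeling, finer than the input
  expect_equal(format_labeling(info$labeling), "{0}|{1,6}|{2,5}|{3,4}")
  infoq <- infer_structure(rate_matrix(rate_vector(G, example2_psi)), G)
  expect_equal(infoq$kind, "rate")
  expect_equal(format_labeling(infoq$labeling), "{0}|{1,2,5,6}|{3,4}")
  # identity: indicator vector, all non-identity values tie at zero
  id <- diag(7)
  info_id <- infer_structure(id, G)
  expect_equal(info_id$values, c(1, rep(0, 6)))
  expect_equal(format_labeling(info_id$labeling), "{0}|{1,2,3,4,5,6}")
  # a single perturbed entry breaks the pattern loudly
  P2 <- P; P2[3, 5] <- P2[3, 5] + 1e-4
  expect_error(infer_structure(P2, G), "group-convolution pattern")
  expect_error(infer_structure(matrix(0.25, 3, 3), G), "7 x 7")
})
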