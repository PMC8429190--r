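# Shared helpers and fixture data for the test suite.

all_presets <- c("CFN", "JC", "K2P", "K3P", "H1P", "H3P", "H7P")

# draw a random strictly interior rate vector of a preset
random_rate_vector <- function(preset, rate_max = 1) {
  L <- preset$labeling
  psi <- numeric(preset$group$order)
  for (j in preset$free_blocks)
    psi[L$blocks[[j]]] <- stats::runif(1, 1e-3, rate_max)
  psi[1L] <- -sum(psi)
  rate_vector(preset$group, psi, labeling = L)
}

# dense matrix exponential oracle (Pade scaling-and-squaring,
# independent of the Fourier route)
dense_expm <- function(M) {
  if (requireNamespace("Matrix", quietly = TRUE))
    as.matrix(Matrix::expm(Matrix::Matrix(M)))
  else {
    e <- eigen(M, symmetric = TRUE)
    e$vectors %*% (exp(e$values) * t(e$vectors))
  }
}

# published table of symmetric G-compatible labelings, order <= 8
table1_labelings <- list(
  Z2 = "{0}|{1}",
  Z3 = "{0}|{1,2}",
  Z4 = c("{0}|{1,2,3}", "{0}|{1,3}|{2}"),
  Z2xZ2 = c("{(0,0)}|{(0,1),(1,0),(1,1)}",
            "{(0,0)}|{(0,1),(1,0)}|{(1,1)}",
            "{(0,0)}|{(0,1)}|{(1,0)}|{(1,1)}"),
  Z5 = c("{0}|{1,2,3,4}", "{0}|{1,4}|{2,3}"),
  Z2xZ3 = c("{(0,0)}|{(0,1),(0,2),(1,0),(1,1),(1,2)}",
            "{(0,0)}|{(0,1),(0,2)}|{(1,0)}|{(1,1),(1,2)}"),
  Z7 = c("{0}|{1,2,3,4,5,6}", "{0}|{1,6}|{2,5}|{3,4}"),
  Z8 = c("{0}|{1,2,3,4,5,6,7}",
         "{0}|{1,3,5,7}|{2,6}|{4}",
         "{0}|{1,7}|{2,6}|{3,5}|{4}"),
  Z2xZ4 = c(
    "{(0,0)}|{(0,1),(0,2),(0,3),(1,0),(1,1),(1,2),(1,3)}",
    "{(0,0)}|{(0,1),(0,3),(1,1),(1,3)}|{(0,2)}|{(1,0),(1,2)}",
    "{(0,0)}|{(0,1),(0,2),(0,3)}|{(1,0)}|{(1,1),(1,2),(1,3)}",
    "{(0,0)}|{(0,1),(0,3),(1,0)}|{(0,2),(1,1),(1,3)}|{(1,2)}",
    "{(0,0)}|{(0,1),(0,3)}|{(0,2)}|{(1,0)}|{(1,1),(1,3)}|{(1,2)}"),
  Z2xZ2xZ2 = c(
    paste0("{(0,0,0)}|{(0,0,1),(0,1,0),(0,1,1),(1,0,0),(1,0,1),",
           "(1,1,0),(1,1,1)}"),
    "{(0,0,0)}|{(0,0,1)}|{(0,1,0),(1,0,0),(1,1,0)}|{(0,1,1),(1,0,1),(1,1,1)}",
    "{(0,0,0)}|{(0,0,1),(1,0,0),(1,0,1)}|{(0,1,0)}|{(0,1,1),(1,1,0),(1,1,1)}",
    "{(0,0,0)}|{(0,0,1),(0,1,0),(0,1,1)}|{(1,0,0)}|{(1,0,1),(1,1,0),(1,1,1)}",
    "{(0,0,0)}|{(0,0,1),(0,1,0),(1,0,1),(1,1,0)}|{(0,1,1)}|{(1,0,0),(1,1,1)}",
    "{(0,0,0)}|{(0,0,1),(0,1,0),(1,0,0)}|{(0,1,1),(1,0,1),(1,1,0)}|{(1,1,1)}",
    "{(0,0,0)}|{(0,0,1),(1,1,1)}|{(0,1,0),(0,1,1),(1,0,0),(1,0,1)}|{(1,1,0)}",
    "{(0,0,0)}|{(0,0,1),(0,1,1),(1,0,0),(1,1,0)}|{(0,1,0),(1,1,1)}|{(1,0,1)}",
    paste0("{(0,0,0)}|{(0,0,1)}|{(0,1,0),(1,0,0)}|{(0,1,1),(1,0,1)}|",
           "{(1,1,0)}|{(1,1,1)}"),
    paste0("{(0,0,0)}|{(0,0,1),(0,1,0)}|{(0,1,1)}|{(1,0,0)}|",
           "{(1,0,1),(1,1,0)}|{(1,1,1)}"),
    paste0("{(0,0,0)}|{(0,0,1),(1,0,0)}|{(0,1,0)}|{(0,1,1),(1,1,0)}|",
           "{(1,0,1)}|{(1,1,1)}"),
    paste0("{(0,0,0)}|{(0,0,1)}|{(0,1,0)}|{(0,1,1)}|{(1,0,0)}|{(1,0,1)}|",
           "{(1,1,0)}|{(1,1,1)}"))
)

# published Markov matrix of the 7-state worked example: exp of the
# rate matrix with psi(0) = -1, psi(+-1) = psi(+-2) = 0.125,
# psi(+-3) = 0.25, printed to 5-6 significant digits
example2_psi <- c(-1, 0.125, 0.125, 0.25, 0.25, 0.125, 0.125)
example2_f <- c(0.41305, 0.0858551, 0.0834148, 0.124205,
                0.124205, 0.0834148, 0.0858551)
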