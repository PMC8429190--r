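#' Rate and transition vectors of a group-based model
#'
#' A group-based rate matrix is the group convolution \eqn{Q_{g,h} =
#' \psi(h - g)} of a single rate vector \eqn{\psi} with
#' \eqn{\sum_g \psi(g) = 0} and \eqn{\psi(g) \ge 0} off the identity;
#' a group-based Markov matrix is \eqn{P_{g,h} = f(h - g)} with \eqn{f}
#' a probability vector. Both are constrained to be constant on the
#' blocks of the labeling and symmetric (\eqn{\psi(g) = \psi(-g)}), so
#' the matrices are real symmetric with real spectra.
#'
#' @param group An `abelian_group`.
#' @param psi,f Numeric vector of length `group$order` in canonical
#'   element order.
#' @param labeling Optional `labeling`; when supplied the vector must be
#'   constant on its blocks.
#' @param tol Tolerance for the validity checks.
#' @return An object of class `"rate_vector"` or `"transition_vector"`.
#' @export
rate_vector <- function(group, psi, labeling = NULL, tol = 1e-8) {
  v <- validate_model_vector(group, psi, labeling, tol, kind = "rate")
  structure(list(group = group, labeling = labeling, psi = v),
            class = "rate_vector")
}

#' @rdname rate_vector
#' @export
transition_vector <- function(group, f, labeling = NULL, tol = 1e-8) {
  v <- validate_model_vector(group, f, labeling, tol, kind = "markov")
  structure(list(group = group, labeling = labeling, f = v),
            class = "transition_vector")
}

validate_model_vector <- function(group, v, labeling, tol, kind) {
  stopifnot(is_abelian_group(group))
  v <- as.numeric(v)
  n <- group$order
  if (length(v) != n)
    stop(sprintf("vector must have length %d (group order)", n),
         call. = FALSE)
  if (kind == "rate") {
    if (abs(sum(v)) > tol)
      stop(sprintf("rate vector must sum to 0 (got %.3g)", sum(v)),
           call. = FALSE)
    if (any(v[-1L] < -tol))
      stop("rate vector must be non-negative off the identity",
           call. = FALSE)
  } else {
    if (abs(sum(v) - 1) > tol)
      stop(sprintf("transition vector must sum to 1 (got %.3g)", sum(v)),
           call. = FALSE)
    if (any(v < -tol))
      stop("transition vector must be non-negative", call. = FALSE)
  }
  p <- neg_perm(group)
  if (max(abs(v - v[p])) > tol)
    stop("vector must be symmetric: v(g) = v(-g)", call. = FALSE)
  if (!is.null(labeling)) {
    stopifnot(inherits(labeling, "labeling"))
    for (b in labeling$blocks)
      if (diff(range(v[b])) > tol)
        stop("vector must be constant on labeling blocks", call. = FALSE)
  }
  v
}

model_values <- function(v) if (inherits(v, "rate_vector")) v$psi else v$f

#' Assemble the dense matrix of a group-based model vector
#'
#' `rate_matrix` builds \eqn{Q_{g,h} = \psi(h-g)} (rows sum to 0,
#' symmetric); `markov_matrix` builds \eqn{P_{g,h} = f(h-g)} (rows sum
#' to 1, symmetric).
#'
#' @param rv A `rate_vector`.
#' @param tv A `transition_vector`.
#' @return A square numeric matrix with state names as dimnames.
#' @export
rate_matrix <- function(rv) {
  stopifnot(inherits(rv, "rate_vector"))
  convolution_matrix(rv$group, rv$psi)
}

#' @rdname rate_matrix
#' @export
markov_matrix <- function(tv) {
  stopifnot(inherits(tv, "transition_vector"))
  convolution_matrix(tv$group, tv$f)
}

convolution_matrix <- function(group, v) {
  D <- diff_table(group)
  M <- matrix(v[D], group$order, group$order)
  dimnames(M) <- list(group$names, group$names)
  M
}

#' Recover the defining vector and induced labeling of a model matrix
#'
#' Checks that `M` has the group-convolution pattern `M[g,h] = v(h-g)`
#' (the vector is read off row one and verified on all rows; any
#' discrepancy is an error naming the first offending entry, never
#' averaged away). Elements with equal values of `v` (within `value_tol`)
#' are grouped into the induced labeling. The matrix is classified as
#' `"markov"` (rows sum to 1, v >= 0), `"rate"` (rows sum to 0, v >= 0
#' off the identity) or `"neither"`.
#'
#' @param M A square numeric matrix, `group$order` rows.
#' @param group An `abelian_group`.
#' @param tol Absolute tolerance of the structural pattern check.
#' @param value_tol Tolerance used to group equal values into the
#'   induced labeling.
#' @return List with `values` (the recovered vector), `labeling`
#'   (induced `labeling`) and `kind`.
#' @examples
#' G <- parse_group("Z2")
#' infer_structure(matrix(c(.7, .3, .3, .7), 2), G)$kind  # "markov"
#' @export
infer_structure <- function(M, group, tol = 1e-8, value_tol = 1e-7) {
  stopifnot(is_abelian_group(group))
  n <- group$order
  if (!is.matrix(M) || nrow(M) != n || ncol(M) != n)
    stop(sprintf("matrix must be %d x %d for this group", n, n),
         call. = FALSE)
  D <- diff_table(group)
  v <- M[1L, ]
  expected <- matrix(v[D], n, n)
  dev <- abs(M - expected)
  if (max(dev) > tol) {
    w <- which(dev == max(dev), arr.ind = TRUE)[1L, ]
    stop(sprintf(paste0("matrix does not follow the group-convolution ",
                        "pattern: entry (%s, %s) is %.10g, expected %.10g"),
                 group$names[w[1L]], group$names[w[2L]],
                 M[w[1L], w[2L]], expected[w[1L], w[2L]]),
         call. = FALSE)
  }
  # group elements by (toleranced) equal value
  o <- order(v)
  lab <- integer(n)
  cur <- 1L
  lab[o[1L]] <- 1L
  for (i in seq_len(n - 1L)) {
    if (v[o[i + 1L]] - v[o[i]] > value_tol) cur <- cur + 1L
    lab[o[i + 1L]] <- cur
  }
  L <- labeling_from_labels(group, lab)
  rs <- rowSums(M)
  kind <- if (max(abs(rs - 1)) <= tol && all(v >= -tol)) "markov"
          else if (max(abs(rs)) <= tol && all(v[-1L] >= -tol)) "rate"
          else "neither"
  list(values = unname(v), labeling = L, kind = kind)
}

#' Fourier eigenvalue spectrum of a model vector
#'
#' The columns of the DFT matrix are the shared eigenvectors of every
#' group-based model matrix; the eigenvalue attached to element `g` is
#' the discrete Fourier transform \eqn{\check v(g) = \sum_h \hat
#' g(h)\,v(h)}. For symmetric vectors the spectrum is real with
#' \eqn{\check v(g) = \check v(-g)}; a Markov spectrum has
#' \eqn{\lambda_0 = 1}, a rate spectrum has \eqn{\check\psi(0) = 0}.
#'
#' @param v A `rate_vector` or `transition_vector`.
#' @return An object of class `"eigen_spectrum"`: list with `group`,
#'   `values` (real numeric, canonical element order) and `kind`
#'   (`"rate"` or `"markov"`).
#' @export
spectrum <- function(v) {
  UseMethod("spectrum")
}

#' @export
spectrum.rate_vector <- function(v) {
  new_spectrum(v$group, v$psi, "rate")
}

#' @export
spectrum.transition_vector <- function(v) {
  new_spectrum(v$group, v$f, "markov")
}

new_spectrum <- function(group, vals, kind) {
  p <- neg_perm(group)
  if (max(abs(vals - vals[p])) > 1e-8)
    stop("spectrum requires a symmetric vector: v(g) = v(-g)",
         call. = FALSE)
  K <- dft_matrix(group)
  lam <- K %*% vals
  if (is.complex(lam)) {
    if (max(abs(Im(lam))) > 1e-9)
      stop("spectrum of a symmetric vector must be real", call. = FALSE)
    lam <- Re(lam)
  }
  structure(list(group = group, values = as.numeric(lam), kind = kind),
            class = "eigen_spectrum")
}

#' Matrix exponential and principal logarithm in the Fourier basis
#'
#' All exponentials and logarithms are taken on the diagonalized form:
#' \eqn{P = K\,\mathrm{diag}(e^{\check\psi})\,K^{-1}}, so
#' `expm_via_dft` maps a rate vector to the transition vector
#' \eqn{f = K^{-1} \exp(\check\psi)} and `principal_log_via_dft` maps a
#' transition vector with strictly positive spectrum to the candidate
#' rate vector \eqn{\psi = K^{-1} \log(\lambda)}. The log route does
#' *not* assert the rate-vector sign constraints: whether
#' \eqn{\psi(g) \ge 0} off the identity holds is precisely the
#' embeddability question, left to the caller (see
#' [check_embeddable()]).
#'
#' @param rv A `rate_vector`.
#' @param tv A `transition_vector`.
#' @return `expm_via_dft` returns a `transition_vector` (the labeling is
#'   carried over; exponentiation preserves a G-compatible labeling).
#'   `principal_log_via_dft` returns a list of class `"rate_candidate"`
#'   with `group`, `labeling` and unvalidated `psi`.
#' @examples
#' G <- parse_group("Z2")
#' rv <- rate_vector(G, c(-0.3, 0.3))
#' expm_via_dft(rv)$f[1]  # (1 + exp(-0.6)) / 2
#' @export
expm_via_dft <- function(rv) {
  stopifnot(inherits(rv, "rate_vector"))
  lam <- spectrum(rv)
  f <- inverse_dft_real(rv$group, exp(lam$values))
  # a G-compatible labeling is preserved by the exponential; a
  # non-compatible one generally is not (the entries then follow a finer
  # induced labeling), in which case it is dropped rather than asserted
  keep <- rv$labeling
  if (!is.null(keep) &&
      any(vapply(keep$blocks, function(b) diff(range(f[b])) > 1e-12, TRUE)))
    keep <- NULL
  transition_vector(rv$group, f, labeling = keep)
}

#' @rdname expm_via_dft
#' @export
principal_log_via_dft <- function(tv) {
  stopifnot(inherits(tv, "transition_vector"))
  lam <- spectrum(tv)
  bad <- which(lam$values <= 0)
  if (length(bad) > 0L)
    stop(structure(class = c("gbembed_domain_error", "error", "condition"),
                   list(message = sprintf(
                     paste0("principal logarithm undefined: eigenvalue at ",
                            "element %s is %.6g <= 0"),
                     tv$group$names[bad[1L]], lam$values[bad[1L]]),
                     call = NULL, index = bad)))
  psi <- inverse_dft_real(tv$group, log(lam$values))
  structure(list(group = tv$group, labeling = tv$labeling, psi = psi),
            class = "rate_candidate")
}

# inverse DFT of a real symmetric Fourier vector; returns a real vector
inverse_dft_real <- function(group, vals) {
  K <- dft_matrix(group)
  v <- Conj(K) %*% vals / group$order
  if (is.complex(v)) {
    stopifnot(max(abs(Im(v))) < 1e-9)
    v <- Re(v)
  }
  as.numeric(v)
}
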