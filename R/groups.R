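#' Finite abelian groups as direct products of cyclic groups
#'
#' The state space of a group-based substitution model is a finite additive
#' abelian group written as a direct product of cyclic groups
#' \eqn{Z_{n_1} \times \cdots \times Z_{n_k}}. Elements are residue tuples
#' \eqn{(g_1, \ldots, g_k)}, \eqn{0 \le g_i < n_i}, enumerated in
#' lexicographic order (first component slowest). With the usual
#' identification of nucleotides with group elements, this ordering puts
#' the four DNA states in the order A, T, C, G on \eqn{Z_2 \times Z_2}
#' and the eight hachimoji states in the order A, C, T, G, P, Z, S, B on
#' \eqn{Z_2 \times Z_2 \times Z_2}.
#'
#' @param spec Either a character string such as `"Z2"`, `"Z7"`,
#'   `"Z2xZ2xZ2"` (case-insensitive, `x`-separated `Z<n>` tokens with
#'   `n >= 2`), or an integer vector of cyclic orders.
#' @return An object of class `"abelian_group"`: a list with components
#'   `factors` (integer vector of cyclic orders), `order` (group order),
#'   `elements` (an `order x k` integer matrix of residue tuples, one row
#'   per element, in canonical lexicographic order) and `names`
#'   (element labels such as `"(0,1)"`, or `"3"` for a single factor).
#' @examples
#' parse_group("Z2xZ2")$order  # 4
#' parse_group("Z3")$elements
#' @export
parse_group <- function(spec) {
  if (is.numeric(spec)) {
    factors <- as.integer(spec)
    if (length(factors) == 0L || any(is.na(factors)) || any(factors < 2L))
      stop("group factors must be integers >= 2", call. = FALSE)
    return(abelian_group(factors))
  }
  if (!is.character(spec) || length(spec) != 1L || !nzchar(spec))
    stop("group spec must be a single non-empty string such as \"Z2xZ2\"",
         call. = FALSE)
  tokens <- strsplit(spec, "x", fixed = TRUE)[[1]]
  factors <- integer(length(tokens))
  for (i in seq_along(tokens)) {
    tok <- trimws(tokens[i])
    if (!grepl("^[Zz][0-9]+$", tok))
      stop(sprintf("malformed group token '%s' in spec '%s'", tok, spec),
           call. = FALSE)
    n <- as.integer(sub("^[Zz]", "", tok))
    if (is.na(n) || n < 2L)
      stop(sprintf("cyclic order must be >= 2, got '%s'", tok), call. = FALSE)
    factors[i] <- n
  }
  abelian_group(factors)
}

abelian_group <- function(factors) {
  factors <- as.integer(factors)
  k <- length(factors)
  n <- prod(factors)
  # lexicographic enumeration: last component varies fastest
  grids <- lapply(rev(factors), function(m) 0:(m - 1L))
  E <- as.matrix(expand.grid(grids, KEEP.OUT.ATTRS = FALSE))
  E <- E[, rev(seq_len(k)), drop = FALSE]
  dimnames(E) <- NULL
  storage.mode(E) <- "integer"
  nms <- if (k == 1L) as.character(E[, 1L]) else
    apply(E, 1L, function(r) paste0("(", paste(r, collapse = ","), ")"))
  structure(list(factors = factors, order = n, elements = E, names = nms),
            class = "abelian_group")
}

#' @export
print.abelian_group <- function(x, ...) {
  cat(sprintf("<abelian group %s, order %d>\n",
              paste0("Z", x$factors, collapse = " x "), x$order))
  invisible(x)
}

is_abelian_group <- function(x) inherits(x, "abelian_group")

# index (1-based) of an element given its residue tuple; vectorized over rows
el_index <- function(group, residues) {
  if (is.null(dim(residues))) residues <- matrix(residues, nrow = 1L)
  f <- group$factors
  w <- rev(cumprod(rev(c(f[-1L], 1L))))  # mixed-radix weights
  r <- sweep(residues, 2L, f, "%%")
  as.integer(r %*% w + 1L)
}

# permutation p with p[i] = index of -g_i
neg_perm <- function(group) {
  E <- group$elements
  el_index(group, sweep(-E, 2L, group$factors, "%%"))
}

# difference table D[g, h] = index of h - g
diff_table <- function(group) {
  n <- group$order
  E <- group$elements
  D <- matrix(0L, n, n)
  for (g in seq_len(n)) {
    d <- sweep(E, 2L, E[g, ], "-")
    D[g, ] <- el_index(group, d)
  }
  D
}

# index of g + h for single elements
add_index <- function(group, i, j) {
  el_index(group, group$elements[i, ] + group$elements[j, ])
}

#' Character value of a finite abelian group
#'
#' Evaluates the character attached to element `g` at element `h`,
#' \eqn{\hat g(h) = \prod_i \exp(2\pi i\, g_i h_i / n_i)}, a root of unity.
#' Characters satisfy \eqn{\hat g(-h) = \overline{\hat g(h)}} and
#' \eqn{\hat g(h)\hat g(h') = \hat g(h + h')}.
#'
#' @param group An `abelian_group`.
#' @param g,h Elements given as residue vectors (one integer per factor;
#'   reduced modulo the factor orders).
#' @return A complex number of modulus 1.
#' @export
character_value <- function(group, g, h) {
  gr <- as_residues(group, g)
  hr <- as_residues(group, h)
  val <- exp(2i * pi * sum(gr * hr / group$factors))
  if (all(group$factors == 2L)) val <- complex(real = round(Re(val)))
  val
}

as_residues <- function(group, x) {
  k <- length(group$factors)
  if (length(x) != k)
    stop(sprintf("element must be a residue tuple of length %d", k),
         call. = FALSE)
  as.integer(x) %% group$factors
}

#' Discrete Fourier transform matrix (character table)
#'
#' Returns the symmetric matrix \eqn{K} with \eqn{K_{g,h} = \hat g(h)} in
#' canonical element order. For direct products, \eqn{K} is the Kronecker
#' product of the factors' DFT matrices. \eqn{K} diagonalizes every
#' group-convolution matrix; its rows/columns are the shared eigenvectors of
#' all rate and transition matrices of the model. For elementary abelian
#' 2-groups all entries are exactly \eqn{\pm 1} and a real matrix is
#' returned; otherwise the matrix is complex.
#'
#' @param group An `abelian_group`.
#' @return An `order x order` matrix with attribute `"group"`.
#' @examples
#' dft_matrix(parse_group("Z2"))        # [[1,1],[1,-1]]
#' @export
dft_matrix <- function(group) {
  K <- matrix(1, 1L, 1L)
  for (m in group$factors) {
    w <- outer(0:(m - 1L), 0:(m - 1L))
    Km <- if (m == 2L) matrix(c(1, 1, 1, -1), 2L, 2L) else exp(2i * pi * w / m)
    K <- kronecker(K, Km)
  }
  dimnames(K) <- list(group$names, group$names)
  attr(K, "group") <- group
  K
}

#' Inverse discrete Fourier transform matrix
#'
#' \eqn{K^{-1} = K^* / |G|} where \eqn{K^*} is the conjugate transpose;
#' since \eqn{K} is symmetric this is the entrywise conjugate divided by
#' the group order.
#'
#' @param K A DFT matrix as returned by [dft_matrix()].
#' @return The inverse matrix, same storage mode as `K`, with the
#'   `"group"` attribute carried over.
#' @export
inverse_dft_matrix <- function(K) {
  group <- attr(K, "group")
  n <- nrow(K)
  Ki <- Conj(K) / n
  attr(Ki, "group") <- group
  Ki
}
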