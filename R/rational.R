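# Minimal exact rational arithmetic on integer numerator/denominator
# pairs stored in doubles. All inputs in this package have small integer
# coefficients (Fourier coefficients of +-1 scale), so intermediates stay
# far below 2^53; an overflow guard aborts loudly if that ever fails.

q_gcd <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0.5) { t <- a %% b; a <- b; b <- t }
  if (a < 0.5) 1 else a
}

q_guard <- function(x) {
  if (any(abs(x) > 2^51))
    stop("rational arithmetic overflow (intermediate > 2^51)",
         call. = FALSE)
  x
}

# a rational is list(n = numerator, d = denominator > 0), both doubles
# holding exact integers, reduced
qq <- function(n, d = 1) {
  if (d == 0) stop("zero denominator", call. = FALSE)
  if (d < 0) { n <- -n; d <- -d }
  g <- q_gcd(n, d)
  list(n = q_guard(n / g), d = d / g)
}

q_add <- function(a, b) qq(a$n * b$d + b$n * a$d, a$d * b$d)
q_sub <- function(a, b) qq(a$n * b$d - b$n * a$d, a$d * b$d)
q_mul <- function(a, b) qq(a$n * b$n, a$d * b$d)
q_div <- function(a, b) {
  if (b$n == 0) stop("rational division by zero", call. = FALSE)
  qq(a$n * b$d, a$d * b$n)
}
q_neg <- function(a) list(n = -a$n, d = a$d)
q_cmp <- function(a, b) sign(q_guard(a$n * b$d - b$n * a$d))
q_num <- function(a) a$n / a$d
q_zero <- function(a) a$n == 0

# rational vectors as list(n = numeric vector, d = numeric vector)
qv <- function(n, d = rep(1, length(n))) {
  s <- d < 0
  n[s] <- -n[s]; d[s] <- -d[s]
  if (any(d == 0)) stop("zero denominator", call. = FALSE)
  g <- mapply(q_gcd, n, d)
  list(n = q_guard(n / g), d = d / g)
}

qv_get <- function(v, i) list(n = v$n[i], d = v$d[i])
qv_num <- function(v) v$n / v$d

# exact dot product of an integer vector with a rational vector
qv_dot_int <- function(a, v) {
  acc <- list(n = 0, d = 1)
  for (i in seq_along(a)) {
    if (a[i] != 0)
      acc <- q_add(acc, qq(a[i] * v$n[i], v$d[i]))
  }
  acc
}

# exact solve of a d x d integer system A x = b via rational Gaussian
# elimination with partial (first-nonzero) pivoting; returns a rational
# vector, or NULL if singular
q_solve_int <- function(A, b) {
  d <- nrow(A)
  N <- cbind(A, b)            # numerators
  De <- matrix(1, d, d + 1L)  # denominators
  for (col in seq_len(d)) {
    piv <- which(N[col:d, col] != 0)
    if (length(piv) == 0L) return(NULL)
    piv <- piv[1L] + col - 1L
    if (piv != col) {
      N[c(col, piv), ] <- N[c(piv, col), ]
      De[c(col, piv), ] <- De[c(piv, col), ]
    }
    pv <- list(n = N[col, col], d = De[col, col])
    for (r in seq_len(d)) {
      if (r == col || N[r, col] == 0) next
      fac <- q_div(list(n = N[r, col], d = De[r, col]), pv)
      for (cc in col:(d + 1L)) {
        x <- q_sub(list(n = N[r, cc], d = De[r, cc]),
                   q_mul(fac, list(n = N[col, cc], d = De[col, cc])))
        N[r, cc] <- x$n; De[r, cc] <- x$d
      }
    }
  }
  xs_n <- numeric(d); xs_d <- numeric(d)
  for (r in seq_len(d)) {
    x <- q_div(list(n = N[r, d + 1L], d = De[r, d + 1L]),
               list(n = N[r, r], d = De[r, r]))
    xs_n[r] <- x$n; xs_d[r] <- x$d
  }
  list(n = xs_n, d = xs_d)
}
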