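#' Polytopes in eigenvalue coordinates
#'
#' A bounded convex polytope in H-representation \eqn{A x \le b} with
#' integer coefficient data (rational halfspaces are scaled to integers
#' on construction). Used to describe, in the free eigenvalue coordinates
#' of a preset model, the linear matrix regions whose volumes quantify
#' how restrictive the continuous-time hypothesis is.
#'
#' @param A Numeric matrix (m halfspaces x d coordinates) of integer (or
#'   rational, auto-scaled) coefficients.
#' @param b Numeric right-hand side of length m.
#' @param strict Logical vector: which inequalities are strict. Strict
#'   faces have measure zero, so volumes are unaffected; the flag is kept
#'   for reporting.
#' @return Object of class `"polytope"` with integer `A`, `b`,
#'   dimension `d` and `strict`.
#' @export
polytope <- function(A, b, strict = rep(FALSE, length(b))) {
  A <- unname(as.matrix(A))
  b <- unname(b)
  stopifnot(nrow(A) == length(b), nrow(A) == length(strict))
  M <- cbind(A, b)
  # scale each row to integer entries
  for (i in seq_len(nrow(M))) {
    r <- M[i, ]
    for (mult in 1:64) {
      if (max(abs(mult * r - round(mult * r))) < 1e-9) {
        M[i, ] <- round(mult * r)
        break
      }
      if (mult == 64) stop("halfspace coefficients are not rational ",
                           "with denominator <= 64", call. = FALSE)
    }
    g <- Reduce(q_gcd, abs(M[i, M[i, ] != 0]), accumulate = FALSE)
    if (!is.null(g) && length(g) == 1L && g > 1) M[i, ] <- M[i, ] / g
  }
  d <- ncol(A)
  keep <- !duplicated(M)
  structure(list(A = M[keep, seq_len(d), drop = FALSE],
                 b = M[keep, d + 1L], d = d, strict = strict[keep]),
            class = "polytope")
}

#' @export
print.polytope <- function(x, ...) {
  cat(sprintf("<polytope: %d halfspaces in %d dimensions>\n",
              nrow(x$A), x$d))
  invisible(x)
}

#' Exact vertex enumeration of a polytope
#'
#' Enumerates vertices by solving, in exact rational arithmetic, every
#' d-subset of halfspace boundary equations (with a fast floating-point
#' prescreen) and keeping the feasible solutions. Intended for the small
#' (d <= 8) eigenvalue polytopes of the preset models.
#'
#' @param poly A `polytope`.
#' @return List with `n` and `d`: d x k matrices of exact vertex
#'   numerators and denominators, one column per vertex.
#' @export
polytope_vertices <- function(poly) {
  A <- poly$A; b <- poly$b; d <- poly$d
  m <- nrow(A)
  if (d > 8L) stop("vertex enumeration guarded to dimension <= 8",
                   call. = FALSE)
  if (m < d) stop("polytope has fewer halfspaces than dimensions",
                  call. = FALSE)
  combs <- utils::combn(m, d)
  seen <- new.env(parent = emptyenv())
  Vn <- list(); Vd <- list()
  for (ci in seq_len(ncol(combs))) {
    S <- combs[, ci]
    M <- A[S, , drop = FALSE]
    dt <- det(M)
    if (abs(dt) < 0.5) next          # integer det: zero means singular
    x <- solve(M, b[S])
    if (any(A %*% x - b > 1e-6)) next  # float prescreen
    v <- q_solve_int(M, b[S])
    if (is.null(v)) next
    # exact feasibility
    ok <- TRUE
    for (i in seq_len(m)) {
      lhs <- qv_dot_int(A[i, ], v)
      if (q_cmp(lhs, qq(b[i])) > 0) { ok <- FALSE; break }
    }
    if (!ok) next
    key <- paste(v$n, v$d, sep = "/", collapse = ";")
    if (!is.null(seen[[key]])) next
    assign(key, TRUE, envir = seen)
    Vn[[length(Vn) + 1L]] <- v$n
    Vd[[length(Vd) + 1L]] <- v$d
  }
  if (length(Vn) == 0L)
    return(list(n = matrix(0, d, 0L), d = matrix(1, d, 0L)))
  list(n = matrix(unlist(Vn), d), d = matrix(unlist(Vd), d))
}

#' Exact polytope volume by recursive facet decomposition
#'
#' Computes the exact Lebesgue volume of a bounded polytope given by
#' integer halfspaces, entirely in rational arithmetic: vertices are
#' enumerated exactly, the polytope is decomposed into pyramids from one
#' vertex over each facet (divergence-theorem identity), and each facet
#' volume is obtained recursively after eliminating one coordinate along
#' the facet hyperplane. The elimination factors cancel so every
#' intermediate quantity is rational; the result is returned as a
#' reduced fraction.
#'
#' @param poly A `polytope`.
#' @return Object of class `"volume_result"`: list with `value`
#'   (numeric), `num`/`den` (exact reduced fraction) and
#'   `method = "exact"`.
#' @examples
#' # unit simplex in 3 dimensions: volume 1/6
#' p <- polytope(rbind(-diag(3), rep(1, 3)), c(0, 0, 0, 1))
#' exact_volume(p)
#' @export
exact_volume <- function(poly) {
  stopifnot(inherits(poly, "polytope"))
  V <- polytope_vertices(poly)
  k <- ncol(V$n)
  if (k == 0L)
    return(volume_result(0, num = 0, den = 1, method = "exact"))
  if (max(abs(V$n / V$d)) > 1e9)
    stop("polytope appears unbounded", call. = FALSE)
  vol <- facet_volume_rec(V, poly$A, poly$b, poly$d)
  volume_result(q_num(vol), num = vol$n, den = vol$d, method = "exact")
}

# recursive exact volume; V: exact vertices (d x k), A,b integer
facet_volume_rec <- function(V, A, b, d) {
  k <- ncol(V$n)
  if (k < d + 1L) return(qq(0))
  if (d == 1L) {
    vals <- V$n[1L, ] / V$d[1L, ]
    i1 <- which.min(vals); i2 <- which.max(vals)
    return(q_sub(qq(V$n[1L, i2], V$d[1L, i2]),
                 qq(V$n[1L, i1], V$d[1L, i1])))
  }
  m <- nrow(A)
  v0 <- qv_get2(V, 1L)
  total <- qq(0)
  for (i in seq_len(m)) {
    a <- A[i, ]
    # exact incidence of each vertex with hyperplane i
    resid_n <- a %*% (V$n / V$d) - b[i]   # float screen first
    inc <- which(abs(resid_n) < 1e-7)
    inc <- inc[vapply(inc, function(j) {
      q_zero(q_sub(qv_dot_int(a, qv_get2(V, j)), qq(b[i])))
    }, TRUE)]
    if (length(inc) < d) next
    h <- q_sub(qq(b[i]), qv_dot_int(a, v0))
    if (q_zero(h)) next
    j <- which.max(abs(a))
    aij <- a[j]
    # project facet vertices: drop coordinate j
    Fn <- V$n[-j, inc, drop = FALSE]
    Fd <- V$d[-j, inc, drop = FALSE]
    # substitute x_j = (b_i - sum_{k != j} a_k x_k) / a_j into the
    # remaining constraints, scaled by |a_j| to stay integral
    s <- sign(aij)
    A2 <- matrix(0, 0L, d - 1L); b2 <- numeric(0)
    for (r in seq_len(m)) {
      if (r == i) next
      ar <- A[r, ]
      newa <- (ar[-j] * aij - ar[j] * a[-j]) * s
      newb <- (b[r] * aij - ar[j] * b[i]) * s
      if (all(newa == 0)) next
      g <- Reduce(q_gcd, abs(c(newa[newa != 0], if (newb != 0) newb)))
      A2 <- rbind(A2, newa / g); b2 <- c(b2, newb / g)
    }
    dup <- duplicated(cbind(A2, b2))
    A2 <- A2[!dup, , drop = FALSE]; b2 <- b2[!dup]
    sub <- facet_volume_rec(list(n = Fn, d = Fd), A2, b2, d - 1L)
    total <- q_add(total, q_mul(q_div(h, qq(abs(aij))), sub))
  }
  q_div(total, qq(d))
}

qv_get2 <- function(V, j) list(n = V$n[, j], d = V$d[, j])

volume_result <- function(value, num = NULL, den = NULL,
                          method = c("exact", "mc", "quadrature"),
                          stderr = NULL, n = NULL, seed = NULL) {
  structure(list(value = unname(value), num = unname(num),
                 den = unname(den),
                 method = match.arg(method), stderr = stderr, n = n,
                 seed = seed),
            class = "volume_result")
}

#' @export
print.volume_result <- function(x, ...) {
  if (x$method == "exact")
    cat(sprintf("<volume %s/%s = %.10g (exact)>\n",
                format(x$num, scientific = FALSE),
                format(x$den, scientific = FALSE), x$value))
  else if (x$method == "mc")
    cat(sprintf("<volume %.6g +- %.2g (MC, n = %g, seed = %s)>\n",
                x$value, x$stderr, x$n, format(x$seed)))
  else
    cat(sprintf("<volume %.8g (quadrature)>\n", x$value))
  invisible(x)
}

#' Linear matrix regions of a preset model in eigenvalue coordinates
#'
#' Builds the H-representation, in the free eigenvalue coordinates of a
#' preset (see [model_preset()]), of:
#' * `delta` — all Markov matrices of the model (the non-negativity of
#'   the transition probabilities \eqn{f = K^{-1}\lambda \ge 0}, with
#'   \eqn{\lambda_0} eliminated as 1 and repeated eigenvalues collapsed);
#' * `delta_plus` — those with all eigenvalues positive (includes the
#'   multiplicative closure of the continuous-time model);
#' * `delta_dd` — the diagonally dominant ones (no-change probability at
#'   least the total change probability, \eqn{f(0) \ge 1/2}), for which
#'   the Markov generator is identifiable.
#'
#' The model-embeddable region `delta_me` is not linear (except in
#' dimension 1); see [embeddable_indicator()], [mc_volume()] and
#' [h3p_me_volume()].
#'
#' @param model Preset id or `model_preset`.
#' @param region One of `"delta"`, `"delta_plus"`, `"delta_dd"`.
#' @return A `polytope` in the preset's free eigenvalue coordinates.
#' @examples
#' exact_volume(eigen_region("H3P", "delta"))  # 4/3
#' @export
eigen_region <- function(model,
                         region = c("delta", "delta_plus", "delta_dd")) {
  region <- match.arg(region)
  preset <- if (is.character(model)) model_preset(model) else model
  L <- preset$labeling
  G <- preset$group
  K <- dft_matrix(G)
  Rk <- Re(K)
  d <- length(preset$free_blocks)
  # one f >= 0 constraint per labeling block (rows with equal labels
  # aggregate identically for a compatible labeling)
  rows <- vapply(L$blocks, function(bl) bl[1L], 1L)
  C <- matrix(0, length(rows), d)
  for (j in seq_len(d)) {
    bl <- L$blocks[[preset$free_blocks[j]]]
    C[, j] <- rowSums(Rk[rows, bl, drop = FALSE])
  }
  const <- rowSums(Rk[rows, L$blocks[[L$labels[1L]]], drop = FALSE])
  if (max(abs(C - round(C))) > 1e-9 || max(abs(const - round(const))) > 1e-9)
    stop("exact region construction requires integer Fourier ",
         "coefficients for this model", call. = FALSE)
  C <- round(C); const <- round(const)
  A <- -C
  b <- const
  strict <- rep(FALSE, length(b))
  if (region == "delta_plus") {
    A <- rbind(A, -diag(d))
    b <- c(b, rep(0, d))
    strict <- c(strict, rep(TRUE, d))
  } else if (region == "delta_dd") {
    # f(0) >= 1/2 <=> 1 + sum_j |B_j| lambda_j >= n/2
    sizes <- vapply(preset$free_blocks,
                    function(j) length(L$blocks[[j]]), 1L)
    A <- rbind(A, -sizes)
    b <- c(b, const[1L] - G$order / 2)
    strict <- c(strict, FALSE)
  }
  polytope(A, b, strict)
}

#' Indicator of the model-embeddable region in eigenvalue coordinates
#'
#' Returns a vectorized predicate over points in the free eigenvalue
#' coordinates of a preset, evaluating the closed-form embeddability
#' inequalities (positivity plus the log-domain product inequalities)
#' without tolerance: boundary points (slack exactly 0) count as inside,
#' matching the closed description of the embeddable set.
#'
#' @param model Preset id or `model_preset`.
#' @return A function taking an `n x d` matrix (or a length-`d` vector)
#'   and returning a logical vector of hits.
#' @export
embeddable_indicator <- function(model) {
  preset <- if (is.character(model)) model_preset(model) else model
  L <- preset$labeling
  G <- preset$group
  Rk <- Re(dft_matrix(G))
  n <- G$order
  np <- neg_perm(G)
  reps <- which(seq_len(n) != 1L & seq_len(n) <= np)
  d <- length(preset$free_blocks)
  # aggregate Re(K) rows over free blocks (lambda_0 = 1 contributes 0)
  C <- matrix(0, length(reps), d)
  for (j in seq_len(d)) {
    bl <- L$blocks[[preset$free_blocks[j]]]
    C[, j] <- rowSums(Rk[reps, bl, drop = FALSE])
  }
  force(d)
  function(X) {
    if (is.null(dim(X))) X <- matrix(X, ncol = d)
    stopifnot(ncol(X) == d)
    pos <- rowSums(X > 0) == d
    hit <- pos
    if (any(pos)) {
      S <- log(X[pos, , drop = FALSE]) %*% t(C)
      hit[pos] <- rowSums(S >= 0) == ncol(S)
    }
    hit
  }
}

#' Hit-and-miss Monte Carlo volume estimation
#'
#' Draws `n` uniform points in the box, evaluates the indicator, and
#' returns (hit fraction) x (box volume) with the binomial standard
#' error. Reproducible given `(n, seed)`; the seed is recorded in the
#' result.
#'
#' @param indicator Vectorized predicate on row-point matrices, e.g.
#'   from [embeddable_indicator()].
#' @param box List with numeric `lower` and `upper` vectors.
#' @param n Number of sample points.
#' @param seed Integer RNG seed.
#' @param chunk Points per evaluation block (memory control).
#' @return A `volume_result` with `method = "mc"`.
#' @export
mc_volume <- function(indicator, box, n, seed, chunk = 250000L) {
  stopifnot(n >= 1, length(box$lower) == length(box$upper),
            all(box$upper >= box$lower))
  d <- length(box$lower)
  boxvol <- prod(box$upper - box$lower)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  hits <- 0
  left <- n
  while (left > 0) {
    m <- min(left, chunk)
    X <- matrix(runif(m * d), m, d)
    X <- sweep(sweep(X, 2L, box$upper - box$lower, "*"),
               2L, box$lower, "+")
    hits <- hits + sum(indicator(X))
    left <- left - m
  }
  p <- hits / n
  volume_result(p * boxvol, method = "mc",
                stderr = sqrt(p * (1 - p) / n) * boxvol, n = n,
                seed = seed)
}

#' Volume of the H3P model-embeddable region by nested quadrature
#'
#' The embeddable region of the hachimoji 3-parameter model in the
#' eigenvalue coordinates \eqn{(x, y, z)} is the semialgebraic set
#' \eqn{0 < x \le 1}, \eqn{0 < y \le \sqrt x},
#' \eqn{0 < z \le (x y^2)^{1/4}}. `region = "me"` integrates its
#' indicator (closed form \eqn{\int_0^1 \int_0^{\sqrt x} (x y^2)^{1/4}
#' \,dy\,dx = 1/3}); `region = "me_and_dd"` intersects with the
#' diagonal-dominance halfspace \eqn{x + 2y + 4z \ge 3}. Deterministic
#' adaptive quadrature.
#'
#' @param region `"me"` or `"me_and_dd"`.
#' @param abs_tol Absolute tolerance requested from the quadrature
#'   (must be >= 1e-7).
#' @return A `volume_result` with `method = "quadrature"`.
#' @export
h3p_me_volume <- function(region = c("me", "me_and_dd"),
                          abs_tol = 1e-7) {
  region <- match.arg(region)
  stopifnot(abs_tol >= 1e-7)
  zmax <- function(x, y) (x * y^2)^(1 / 4)
  zmin <- if (region == "me") function(x, y) 0
          else function(x, y) pmax(0, (3 - x - 2 * y) / 4)
  height <- function(x, y) pmax(0, zmax(x, y) - zmin(x, y))
  inner <- function(xv) vapply(xv, function(x) {
    stats::integrate(function(y) height(x, y), 0, sqrt(x),
                     rel.tol = 1e-10, abs.tol = abs_tol / 10,
                     subdivisions = 1000L)$value
  }, 1.0)
  res <- tryCatch(
    stats::integrate(inner, 0, 1, rel.tol = 1e-9, abs.tol = abs_tol,
                     subdivisions = 1000L),
    error = function(e) stop("quadrature did not converge: ",
                             conditionMessage(e), call. = FALSE))
  if (res$abs.error > abs_tol)
    stop(sprintf("quadrature tolerance not reached (%.2g > %.2g); ",
                 res$abs.error, abs_tol),
         sprintf("achieved estimate %.8g", res$value), call. = FALSE)
  volume_result(res$value, method = "quadrature")
}

#' Matrix-set intervals of the general Jukes-Cantor model
#'
#' For the one-rate model on a group of order `n`, parameterized by the
#' off-diagonal transition probability `b`, the four matrix sets are
#' intervals: all Markov matrices `[0, 1/(n-1)]`, positive-eigenvalue
#' matrices `[0, 1/n)`, diagonally dominant matrices `[0, 1/(2(n-1))]`,
#' and the model-embeddable set `[0, 1/n)` — embeddability coincides
#' with eigenvalue positivity for this model. Endpoints are exact
#' rationals.
#'
#' @param n Group order (>= 2).
#' @return Named list of intervals (`delta`, `delta_plus`, `delta_dd`,
#'   `delta_me`), each a list with `num`/`den` vectors of the two
#'   endpoints, a `value` numeric of length 2, and `right_open` flag.
#' @export
general_jc_sets <- function(n) {
  if (!is.numeric(n) || n < 2) stop("group order must be >= 2",
                                    call. = FALSE)
  iv <- function(num, den, right_open = FALSE)
    list(num = c(0, num), den = c(1, den), value = c(0, num / den),
         right_open = right_open)
  list(delta = iv(1, n - 1),
       delta_plus = iv(1, n, right_open = TRUE),
       delta_dd = iv(1, 2 * (n - 1)),
       delta_me = iv(1, n, right_open = TRUE))
}

#' Absolute and relative volume report for a preset model
#'
#' Assembles the volumes of the matrix sets of a preset model: the
#' linear regions (`delta`, `delta_plus`, `delta_dd`) exactly by
#' rational vertex enumeration, the model-embeddable region exactly
#' (general Jukes-Cantor), by quadrature (H3P) or by hit-and-miss Monte
#' Carlo (H7P), and the derived relative volumes
#' \eqn{V(\cdot)/V(\Delta)} and
#' \eqn{V(\Delta_{me} \cap \cdot)/V(\cdot)}.
#'
#' @param model `"H7P"`, `"H3P"` or `"GJC:<n>"` (the hachimoji
#'   1-parameter model is `GJC:8`).
#' @param n_mc Monte Carlo sample count (H7P embeddable region).
#' @param seed RNG seed for Monte Carlo estimates.
#' @return List with `absolute` (data frame: model, region, method,
#'   value, stderr, n, seed) and `relative` (data frame: region,
#'   vol_over_delta, me_over_region).
#' @export
volume_report <- function(model, n_mc = 1e6, seed = 1L) {
  preset <- if (is.character(model)) model_preset(model) else model
  id <- preset$id
  if (grepl("^GJC:", id)) {
    n <- preset$group$order
    s <- general_jc_sets(n)
    len <- function(ivl) ivl$value[2L] - ivl$value[1L]
    abs_df <- data.frame(
      model = id,
      region = c("delta", "delta_plus", "delta_dd", "me", "me_and_dd"),
      method = "exact",
      value = c(len(s$delta), len(s$delta_plus), len(s$delta_dd),
                len(s$delta_me), len(s$delta_dd)),
      stderr = NA_real_, n = NA_real_, seed = NA_integer_)
  } else if (id %in% c("H3P", "H7P")) {
    vd <- exact_volume(eigen_region(preset, "delta"))
    vp <- exact_volume(eigen_region(preset, "delta_plus"))
    vdd <- exact_volume(eigen_region(preset, "delta_dd"))
    if (id == "H3P") {
      vme <- h3p_me_volume("me")
      vmedd <- h3p_me_volume("me_and_dd")
    } else {
      ind <- embeddable_indicator(preset)
      d <- length(preset$free_blocks)
      box <- list(lower = rep(0, d), upper = rep(1, d))
      vme <- mc_volume(ind, box, n_mc, seed)
      inddd <- function(X) ind(X) & rowSums(X) >= preset$group$order / 2 - 1
      vmedd <- mc_volume(inddd, box, n_mc, seed + 1L)
    }
    rows <- list(delta = vd, delta_plus = vp, delta_dd = vdd,
                 me = vme, me_and_dd = vmedd)
    abs_df <- data.frame(
      model = id, region = names(rows),
      method = vapply(rows, `[[`, "", "method"),
      value = vapply(rows, `[[`, 1.0, "value"),
      stderr = vapply(rows, function(r)
        if (is.null(r$stderr)) NA_real_ else r$stderr, 1.0),
      n = vapply(rows, function(r)
        if (is.null(r$n)) NA_real_ else r$n, 1.0),
      seed = vapply(rows, function(r)
        if (is.null(r$seed)) NA_integer_ else as.integer(r$seed), 1L))
  } else {
    stop(sprintf("volume report not available for preset '%s'", id),
         call. = FALSE)
  }
  v <- stats::setNames(abs_df$value, abs_df$region)
  rel_df <- data.frame(
    region = c("delta", "delta_plus", "delta_dd"),
    vol_over_delta = c(1, v["delta_plus"] / v["delta"],
                       v["delta_dd"] / v["delta"]),
    me_over_region = c(v["me"] / v["delta"],
                       v["me"] / v["delta_plus"],
                       v["me_and_dd"] / v["delta_dd"]),
    row.names = NULL)
  list(absolute = abs_df, relative = rel_df)
}
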