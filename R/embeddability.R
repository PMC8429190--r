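#' Decide model embeddability of a group-based Markov matrix
#'
#' A Markov matrix following a symmetric G-compatible labeling is *model
#' embeddable* when it is the matrix exponential of a rate matrix that
#' itself respects the group and labeling structure. The decision is made
#' entirely in the Fourier basis: writing \eqn{\lambda} for the (real)
#' eigenvalue vector of `P` indexed by group elements, `P` is embeddable
#' iff
#' \enumerate{
#'   \item \eqn{\lambda_0 = 1},
#'   \item \eqn{\lambda_g > 0} for all \eqn{g},
#'   \item \eqn{\lambda_g = \lambda_h} whenever \eqn{L(g) = L(h)}, and
#'   \item \eqn{\sum_h \mathrm{Re}(K_{g,h}) \log\lambda_h \ge 0} for
#'     every nonzero \eqn{g} (the log form of the product criterion
#'     \eqn{\prod_h \lambda_h^{\mathrm{Re}(K_{g,h})} \ge 1}).
#' }
#' The slack of constraint (iv) at \eqn{g} equals \eqn{|G|\,\psi(g)} of
#' the candidate generator, so on success the unique generator is
#' recovered by the principal logarithm in the Fourier basis and attached
#' to the report. Constraints for \eqn{g} and \eqn{-g} are identical and
#' are collapsed to one per \eqn{\{g, -g\}} pair.
#'
#' A matrix whose entries do not follow the claimed labeling (the entries
#' induce a strictly finer labeling) is reported as a structural error,
#' not as non-embeddable: it is simply not a Markov matrix *of this
#' model*.
#'
#' @param P A square numeric matrix or a `transition_vector`.
#' @param group,labeling The model structure; may be omitted when `P` is
#'   a `transition_vector` carrying them or when `preset` is given.
#' @param preset Optional preset id (see [model_preset()]) or
#'   `model_preset` object.
#' @param tol Tolerance for the \eqn{\lambda_0 = 1} and pattern checks.
#' @param boundary_tol Slack magnitudes below this count as active
#'   constraints (boundary).
#' @return An object of class `"embeddability_report"`: list with
#'   `verdict` (`"embeddable"` or `"not_embeddable"`), `failures` (named
#'   numeric vector of violated-constraint slacks), `slacks` (named
#'   vector of product-inequality slacks, one per \eqn{\{g,-g\}} class;
#'   `NA` when some eigenvalue is non-positive), `lambda` (eigenvalues in
#'   element order), `boundary` (logical) and `generator` (a
#'   `rate_vector`, present iff embeddable).
#' @examples
#' rep <- check_embeddable(matrix(c(.7, .3, .3, .7), 2), preset = "CFN")
#' rep$verdict
#' @export
check_embeddable <- function(P, group = NULL, labeling = NULL,
                             preset = NULL, tol = 1e-8,
                             boundary_tol = 1e-9) {
  if (!is.null(preset)) {
    if (is.character(preset)) preset <- model_preset(preset)
    group <- preset$group
    labeling <- preset$labeling
  }
  if (inherits(P, "transition_vector")) {
    if (is.null(group)) group <- P$group
    if (is.null(labeling)) labeling <- P$labeling
  }
  if (is.null(group) || is.null(labeling))
    stop("group and labeling (or a preset) are required", call. = FALSE)
  if (!is_symmetric(labeling))
    stop("model error: labeling is not symmetric", call. = FALSE)
  if (!is_compatible(labeling))
    stop(paste0("model error: labeling is not G-compatible ",
                "(see is_compatible)"), call. = FALSE)

  if (inherits(P, "transition_vector")) {
    f <- P$f
  } else {
    info <- infer_structure(P, group, tol = tol)
    if (info$kind != "markov")
      stop("structural error: matrix is not row-stochastic non-negative",
           call. = FALSE)
    f <- info$values
  }
  # the claimed labeling must be at least as coarse as the value pattern
  for (b in labeling$blocks)
    if (diff(range(f[b])) > tol)
      stop(sprintf(paste0("structural error: matrix entries are not ",
                          "constant on labeling block %s; the matrix ",
                          "follows a finer labeling than claimed"),
                   paste0("{", paste(group$names[b], collapse = ","), "}")),
           call. = FALSE)
  tv <- transition_vector(group, f, labeling = labeling, tol = 10 * tol)
  lam <- spectrum(tv)$values
  n <- group$order
  np <- neg_perm(group)
  reps <- which(seq_len(n) != 1L & seq_len(n) <= np)  # one per {g,-g}
  class_name <- function(i) {
    if (np[i] == i) group$names[i]
    else paste0(group$names[i], ",", group$names[np[i]])
  }
  failures <- numeric(0)
  if (abs(lam[1L] - 1) > tol)
    failures["lambda_0 = 1"] <- lam[1L] - 1
  pos_bad <- reps[lam[reps] <= 0]
  for (i in pos_bad)
    failures[paste0("lambda > 0 at ", class_name(i))] <- lam[i]
  slacks <- rep(NA_real_, length(reps))
  names(slacks) <- vapply(reps, class_name, "")
  if (all(lam > 0)) {
    K <- dft_matrix(group)
    Rk <- Re(K)
    slacks[] <- as.numeric(Rk[reps, , drop = FALSE] %*% log(lam))
    viol <- which(slacks < -boundary_tol)
    for (j in viol)
      failures[paste0("product inequality at ", names(slacks)[j])] <-
        slacks[j]
  }
  verdict <- if (length(failures) == 0L) "embeddable" else "not_embeddable"
  boundary <- FALSE
  generator <- NULL
  if (verdict == "embeddable") {
    boundary <- any(abs(slacks) <= boundary_tol)
    cand <- principal_log_via_dft(tv)
    generator <- rate_vector(group, cand$psi, labeling = labeling,
                             tol = 1e-6)
  }
  structure(list(verdict = verdict, failures = failures, slacks = slacks,
                 lambda = lam, boundary = boundary, generator = generator,
                 group = group, labeling = labeling,
                 boundary_tol = boundary_tol),
            class = "embeddability_report")
}

#' @export
print.embeddability_report <- function(x, ...) {
  cat(sprintf("<embeddability report: %s%s>\n", x$verdict,
              if (x$boundary) " (boundary)" else ""))
  if (length(x$failures) > 0L) {
    cat("violated constraints:\n")
    for (nm in names(x$failures))
      cat(sprintf("  %s (slack %.3g)\n", nm, x$failures[[nm]]))
  }
  if (!all(is.na(x$slacks))) {
    cat("product-inequality slacks:\n")
    for (nm in names(x$slacks))
      cat(sprintf("  %-16s %.6g\n", nm, x$slacks[[nm]]))
  }
  invisible(x)
}

#' Brute-force embeddability oracle via the dense principal logarithm
#'
#' Computes the principal matrix logarithm of `P` by a dense symmetric
#' eigendecomposition (independent of the Fourier-basis route used by
#' [check_embeddable()]) and directly checks that the result is a valid
#' rate matrix of the model: non-negative off-diagonal, zero row sums,
#' group-convolution pattern, and constancy on the labeling blocks.
#' Intended as an independent cross-check in tests.
#'
#' @inheritParams check_embeddable
#' @param tol Numerical tolerance for the rate-matrix checks.
#' @return Logical: `TRUE` iff a model rate matrix generator exists.
#' @export
oracle_embeddable <- function(P, group = NULL, labeling = NULL,
                              preset = NULL, tol = 1e-9) {
  if (!is.null(preset)) {
    if (is.character(preset)) preset <- model_preset(preset)
    group <- preset$group
    labeling <- preset$labeling
  }
  if (inherits(P, "transition_vector")) {
    if (is.null(group)) group <- P$group
    if (is.null(labeling)) labeling <- P$labeling
    P <- markov_matrix(P)
  }
  e <- eigen(P, symmetric = TRUE)
  if (any(e$values <= 0)) return(FALSE)
  Q <- e$vectors %*% (log(e$values) * t(e$vectors))
  n <- nrow(Q)
  offdiag <- Q[row(Q) != col(Q)]
  if (any(offdiag < -tol)) return(FALSE)
  if (max(abs(rowSums(Q))) > 1e-6) return(FALSE)
  D <- diff_table(group)
  v <- Q[1L, ]
  if (max(abs(Q - matrix(v[D], n, n))) > 1e-6) return(FALSE)
  for (b in labeling$blocks)
    if (diff(range(v[b])) > 1e-6) return(FALSE)
  TRUE
}

#' Closed-form embeddability conditions for preset models
#'
#' Evaluates the model-specific inequality list in the eigenvalue
#' coordinates of a preset (see [model_preset()] for coordinate order):
#' CFN and JC/H1P/GJC require \eqn{0 < \lambda \le 1}; K2P requires
#' \eqn{\lambda_{(0,1)} > 0} and \eqn{1 \ge \lambda_{(1,1)} \ge
#' \lambda_{(0,1)}^2}; K3P requires all eigenvalues positive with each
#' one at least the product of the other two; H3P requires
#' \eqn{1 \ge x > 0}, \eqn{y, z > 0}, \eqn{x \ge y^2},
#' \eqn{x y^2 \ge z^4}; H7P requires positivity plus seven product
#' inequalities pairing complementary eigenvalue subsets. These closed
#' forms agree with the general criterion of [check_embeddable()].
#'
#' @param model Preset id or `model_preset`.
#' @param lambda Numeric vector of free eigenvalue coordinates (one per
#'   nonzero labeling block, in the preset's coordinate order), or an
#'   `eigen_spectrum` of kind `"markov"`.
#' @param boundary_tol Tightness tolerance for the boundary flag.
#' @return A list with `verdict`, `failures` (character vector naming
#'   violated conditions), and `boundary`.
#' @examples
#' preset_conditions("H3P", c(0.81, 0.9, 0.3))  # boundary: x = y^2
#' @export
preset_conditions <- function(model, lambda, boundary_tol = 1e-9) {
  preset <- if (is.character(model)) model_preset(model) else model
  if (inherits(lambda, "eigen_spectrum")) {
    stopifnot(lambda$kind == "markov")
    lambda <- spectrum_to_free(preset, lambda$values)
  }
  d <- length(preset$free_blocks)
  if (length(lambda) != d)
    stop(sprintf("preset %s expects %d eigenvalue coordinates",
                 preset$id, d), call. = FALSE)
  fails <- character(0)
  tight <- FALSE
  ge <- function(lhs, rhs, label) {
    if (lhs < rhs - boundary_tol) fails[[length(fails) + 1L]] <<- label
    else if (lhs - rhs <= boundary_tol) tight <<- TRUE
    invisible()
  }
  gt <- function(x, label) {
    if (x <= boundary_tol) fails[[length(fails) + 1L]] <<- label
    invisible()
  }
  id <- if (grepl("^GJC:", preset$id)) "GJC" else preset$id
  switch(id,
    CFN = , JC = , H1P = , GJC = {
      x <- lambda[1L]
      gt(x, "lambda > 0")
      ge(1, x, "lambda <= 1")
    },
    K2P = {
      l11 <- lambda[1L]; l01 <- lambda[2L]
      gt(l01, "lambda_(0,1) > 0")
      ge(1, l11, "lambda_(1,1) <= 1")
      ge(l11, l01^2, "lambda_(1,1) >= lambda_(0,1)^2")
    },
    K3P = {
      l <- lambda
      for (i in 1:3) gt(l[i], sprintf("lambda_%d > 0", i))
      if (all(l > 0)) {
        ge(l[1L], l[2L] * l[3L], "l01 >= l10*l11")
        ge(l[2L], l[1L] * l[3L], "l10 >= l01*l11")
        ge(l[3L], l[1L] * l[2L], "l11 >= l01*l10")
      }
    },
    H3P = {
      x <- lambda[1L]; y <- lambda[2L]; z <- lambda[3L]
      gt(x, "x > 0"); gt(y, "y > 0"); gt(z, "z > 0")
      ge(1, x, "x <= 1")
      if (x > 0 && y > 0 && z > 0) {
        ge(x, y^2, "x >= y^2")
        ge(x * y^2, z^4, "x*y^2 >= z^4")
      }
    },
    H7P = {
      l <- lambda
      for (i in 1:7) gt(l[i], sprintf("lambda_%d > 0", i))
      if (all(l > 0)) {
        # complementary-subset product inequalities, elements ordered
        # 001,010,011,100,101,110,111
        lhs <- list(c(2, 4, 6), c(1, 4, 5), c(3, 4, 7), c(1, 2, 3),
                    c(2, 5, 7), c(1, 6, 7), c(3, 5, 6))
        for (i in seq_along(lhs)) {
          lo <- lhs[[i]]
          hi <- setdiff(1:7, lo)
          ge(sum(log(l[lo])), sum(log(l[hi])),
             sprintf("product inequality %d", i))
        }
      }
    },
    stop(sprintf("no closed-form conditions for preset '%s'", preset$id),
         call. = FALSE))
  list(verdict = if (length(fails) == 0L) "embeddable" else
         "not_embeddable",
       failures = unlist(fails), boundary = length(fails) == 0L && tight)
}

#' Boundary classification of an embeddable matrix
#'
#' An embeddable matrix lies on the boundary of the model-embeddable set
#' exactly when at least one of the embeddability inequalities holds with
#' equality; equivalently, when some off-identity rate of the recovered
#' generator is zero (the product-inequality slack at `g` equals
#' \eqn{|G| \psi(g)}).
#'
#' @param report An `embeddability_report` with verdict `"embeddable"`.
#' @param tol Tightness tolerance; defaults to the report's own.
#' @return List with `boundary` (logical) and `active` (names of the
#'   active constraints).
#' @export
on_boundary <- function(report, tol = NULL) {
  stopifnot(inherits(report, "embeddability_report"))
  if (report$verdict != "embeddable")
    stop("on_boundary is defined only for embeddable matrices",
         call. = FALSE)
  if (is.null(tol)) tol <- report$boundary_tol
  active <- names(report$slacks)[abs(report$slacks) <= tol]
  list(boundary = length(active) > 0L, active = active)
}
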