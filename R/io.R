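#' Read and write square numeric matrices as plain CSV/TSV
#'
#' Matrices are stored row-major as delimited text with no header by
#' default; states are ordered lexicographically by group-element tuple.
#' The delimiter is inferred from the file extension (`.tsv`/`.txt` tab,
#' otherwise comma) unless given. The writer emits 12 significant
#' digits, enough for an exact read/write round trip at working
#' precision.
#'
#' @param path File path.
#' @param sep Field separator; `NULL` to infer from the extension.
#' @param header Logical: skip/emit a header line of state names.
#' @param group Optional `abelian_group`; when supplied the matrix must
#'   be `order x order`.
#' @return `read_matrix` returns a square numeric matrix.
#' @export
read_matrix <- function(path, sep = NULL, header = FALSE, group = NULL) {
  if (!file.exists(path))
    stop(sprintf("matrix file '%s' does not exist", path), call. = FALSE)
  if (is.null(sep))
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t"
           else ","
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (header) lines <- lines[-1L]
  if (length(lines) == 0L)
    stop(sprintf("matrix file '%s' is empty", path), call. = FALSE)
  rows <- strsplit(lines, sep, fixed = TRUE)
  ncols <- vapply(rows, length, 1L)
  if (length(unique(ncols)) != 1L)
    stop(sprintf("ragged rows in '%s': row %d has %d fields, row 1 has %d",
                 path, which(ncols != ncols[1L])[1L],
                 ncols[which(ncols != ncols[1L])[1L]], ncols[1L]),
         call. = FALSE)
  M <- matrix(NA_real_, length(rows), ncols[1L])
  for (i in seq_along(rows)) {
    v <- suppressWarnings(as.numeric(rows[[i]]))
    if (anyNA(v)) {
      j <- which(is.na(v))[1L]
      stop(sprintf("non-numeric cell at row %d, column %d of '%s': '%s'",
                   i, j, path, rows[[i]][j]), call. = FALSE)
    }
    M[i, ] <- v
  }
  if (nrow(M) != ncol(M))
    stop(sprintf("matrix in '%s' is %d x %d, expected square",
                 path, nrow(M), ncol(M)), call. = FALSE)
  if (!is.null(group) && nrow(M) != group$order)
    stop(sprintf("matrix in '%s' is %d x %d but the group has order %d",
                 path, nrow(M), ncol(M), group$order), call. = FALSE)
  M
}

#' @rdname read_matrix
#' @param M A square numeric matrix.
#' @export
write_matrix <- function(M, path, sep = NULL, header = FALSE) {
  stopifnot(is.matrix(M), nrow(M) == ncol(M))
  if (is.null(sep))
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t"
           else ","
  lines <- apply(M, 1L, function(r)
    paste(sprintf("%.12g", r), collapse = sep))
  if (header && !is.null(colnames(M)))
    lines <- c(paste(colnames(M), collapse = sep), lines)
  writeLines(lines, path)
  invisible(path)
}

#' Seeded fixture generator for preset models
#'
#' Generates reproducible test matrices of a preset model with known
#' expected verdicts:
#' * `embeddable` — off-identity block rates drawn iid uniform on
#'   `(0, rate_max)` and exponentiated; always strictly embeddable.
#' * `boundary` — as `embeddable` but with one randomly chosen block
#'   rate set exactly to zero, which makes the corresponding
#'   product-inequality slack exactly active.
#' * `non_embeddable` — transition vectors rejection-sampled (block
#'   values uniform, normalized) until some embeddability condition
#'   fails; each fixture is tagged with a violated constraint.
#' * `non_markov` — an embeddable matrix with a single entry perturbed,
#'   breaking the convolution pattern.
#'
#' @param model Preset id or `model_preset`.
#' @param n Number of fixtures.
#' @param seed Integer RNG seed.
#' @param kind One of `"embeddable"`, `"boundary"`, `"non_embeddable"`,
#'   `"non_markov"`.
#' @param rate_max Upper bound of the uniform rate draws.
#' @param max_tries Rejection-sampling retry cap per fixture.
#' @return List of fixtures; each is a list with `P` (matrix),
#'   `expected` (the kind) and `info` (kind-specific details such as the
#'   drawn rates or the violated constraint).
#' @export
generate_fixtures <- function(model, n, seed,
                              kind = c("embeddable", "boundary",
                                       "non_embeddable", "non_markov"),
                              rate_max = 1.0, max_tries = 1000L) {
  kind <- match.arg(kind)
  preset <- if (is.character(model)) model_preset(model) else model
  stopifnot(n >= 1)
  set.seed(seed)
  L <- preset$labeling
  G <- preset$group
  nb <- length(preset$free_blocks)
  draw_psi <- function(rates) {
    psi <- numeric(G$order)
    for (j in seq_len(nb))
      psi[L$blocks[[preset$free_blocks[j]]]] <- rates[j]
    psi[1L] <- -sum(psi)
    psi
  }
  out <- vector("list", n)
  for (i in seq_len(n)) {
    if (kind %in% c("embeddable", "boundary", "non_markov")) {
      rates <- stats::runif(nb, 0, rate_max)
      if (kind == "boundary") rates[sample.int(nb, 1L)] <- 0
      rv <- rate_vector(G, draw_psi(rates), labeling = L)
      P <- markov_matrix(expm_via_dft(rv))
      info <- list(rates = rates)
      if (kind == "non_markov") {
        idx <- c(sample.int(G$order, 1L), sample.int(G$order, 1L))
        P[idx[1L], idx[2L]] <- P[idx[1L], idx[2L]] + 0.05
        info$perturbed <- idx
      }
    } else {
      found <- FALSE
      for (try in seq_len(max_tries)) {
        u <- stats::runif(nb + 1L)
        w <- numeric(G$order)
        w[1L] <- u[1L]
        for (j in seq_len(nb))
          w[L$blocks[[preset$free_blocks[j]]]] <- u[j + 1L]
        f <- w / sum(w)
        tv <- transition_vector(G, f, labeling = L)
        cond <- preset_conditions(preset,
                                  spectrum_to_free(preset,
                                                   spectrum(tv)$values))
        if (cond$verdict == "not_embeddable") {
          P <- markov_matrix(tv)
          info <- list(violated = cond$failures)
          found <- TRUE
          break
        }
      }
      if (!found)
        stop(sprintf(paste0("rejection sampling failed to find a ",
                            "non-embeddable %s matrix in %d tries"),
                     preset$id, max_tries), call. = FALSE)
    }
    out[[i]] <- list(P = P, expected = kind, info = info)
  }
  out
}
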