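#' Preset group-based models
#'
#' Bundles the group and labeling of the standard symmetric group-based
#' models, avoiding the state-ordering pitfalls of entering them by hand
#' (the canonical order here is A, T, C, G on \eqn{Z_2 \times Z_2} and
#' A, C, T, G, P, Z, S, B on \eqn{Z_2 \times Z_2 \times Z_2}):
#'
#' * `CFN` — Cavender-Farris-Neyman, two states on \eqn{Z_2}.
#' * `JC` — Jukes-Cantor on \eqn{Z_2 \times Z_2}.
#' * `K2P` — Kimura 2-parameter on \eqn{Z_2 \times Z_2} (blocks
#'   \{(0,0)\}, \{(0,1),(1,0)\}, \{(1,1)\}).
#' * `K3P` — Kimura 3-parameter (all singleton blocks).
#' * `H1P`, `H3P`, `H7P` — the hachimoji 1-, 3- and 7-parameter models
#'   on \eqn{Z_2 \times Z_2 \times Z_2} for eight-letter synthetic DNA;
#'   analogues of JC, K2P and K3P respectively.
#' * `GJC:<n>` — general Jukes-Cantor on \eqn{Z_n}: one rate for every
#'   substitution.
#'
#' The free eigenvalue coordinates of a preset are one per nonzero
#' labeling block, ordered by block size then by minimal element; for
#' `H3P` this yields the conventional \eqn{(x, y, z)} with
#' \eqn{x = \lambda_{(0,1,1)}}, \eqn{y = \lambda_{(1,0,0)}},
#' \eqn{z = \lambda_{(0,0,1)}}.
#'
#' @param id Preset identifier, one of `"CFN"`, `"JC"`, `"K2P"`,
#'   `"K3P"`, `"H1P"`, `"H3P"`, `"H7P"`, `"GJC:<n>"`.
#' @return List of class `"model_preset"` with `id`, `group`,
#'   `labeling`, and `free_blocks` (indices into `labeling$blocks` of
#'   the nonzero blocks in free-coordinate order).
#' @export
model_preset <- function(id) {
  stopifnot(is.character(id), length(id) == 1L)
  idu <- toupper(id)
  if (grepl("^GJC:[0-9]+$", idu)) {
    n <- as.integer(sub("^GJC:", "", idu))
    if (n < 2L) stop("GJC preset requires group order >= 2", call. = FALSE)
    G <- parse_group(paste0("Z", n))
    L <- general_jc_labeling(G)
  } else {
    G <- switch(idu,
      CFN = parse_group("Z2"),
      JC = , K2P = , K3P = parse_group("Z2xZ2"),
      H1P = , H3P = , H7P = parse_group("Z2xZ2xZ2"),
      stop(sprintf("unknown model preset '%s'", id), call. = FALSE))
    L <- switch(idu,
      CFN = general_jc_labeling(G),
      JC = general_jc_labeling(G),
      K2P = labeling(G, list("(0,0)", c("(0,1)", "(1,0)"), "(1,1)")),
      K3P = labeling(G, as.list(seq_len(4L))),
      H1P = general_jc_labeling(G),
      H3P = labeling(G, list("(0,0,0)",
                             c("(0,0,1)", "(0,1,0)", "(1,0,1)", "(1,1,0)"),
                             "(0,1,1)",
                             c("(1,0,0)", "(1,1,1)"))),
      H7P = labeling(G, as.list(seq_len(8L))))
  }
  nz <- which(vapply(L$blocks, function(b) !(1L %in% b), TRUE))
  sizes <- vapply(L$blocks[nz], length, 1L)
  mins <- vapply(L$blocks[nz], min, 1L)
  free_blocks <- nz[order(sizes, mins)]
  structure(list(id = idu, group = G, labeling = L,
                 free_blocks = free_blocks),
            class = "model_preset")
}

#' @export
print.model_preset <- function(x, ...) {
  cat(sprintf("<model preset %s on %s: %s>\n", x$id,
              paste0("Z", x$group$factors, collapse = "x"),
              format_labeling(x$labeling)))
  invisible(x)
}

preset_ids <- function() c("CFN", "JC", "K2P", "K3P", "H1P", "H3P", "H7P")

# expand free eigenvalue coordinates to the full length-n spectrum values
free_to_spectrum <- function(preset, coords) {
  L <- preset$labeling
  stopifnot(length(coords) == length(preset$free_blocks))
  vals <- numeric(preset$group$order)
  vals[L$blocks[[L$labels[1L]]]] <- 1
  for (j in seq_along(preset$free_blocks))
    vals[L$blocks[[preset$free_blocks[j]]]] <- coords[j]
  vals
}

# collapse a full spectrum to free coordinates (block representatives)
spectrum_to_free <- function(preset, values) {
  vapply(preset$free_blocks,
         function(j) values[preset$labeling$blocks[[j]][1L]], 1.0)
}
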