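#' Labeling functions on a finite abelian group
#'
#' A labeling function assigns a label to every group element; elements
#' sharing a label are constrained to share a rate (or transition
#' probability) in the substitution model. A labeling is represented as a
#' set partition of the group elements: two elements carry the same label
#' exactly when they lie in the same block. Blocks are stored in canonical
#' form, each block sorted and blocks ordered by their minimal element in
#' the canonical element order.
#'
#' @param group An `abelian_group`.
#' @param blocks A list of blocks. Each block may be given as a vector of
#'   1-based element indices, a character vector of element names
#'   (`"(0,1)"` style), or a list of residue tuples. The blocks must
#'   partition the group.
#' @return An object of class `"labeling"`: list with `group`, `blocks`
#'   (list of sorted integer index vectors in canonical order) and
#'   `labels` (integer vector mapping each element to its block number).
#' @seealso [parse_labeling()] for the text format, [is_compatible()],
#'   [enumerate_labelings()].
#' @export
labeling <- function(group, blocks) {
  stopifnot(is_abelian_group(group))
  n <- group$order
  idx_blocks <- lapply(blocks, function(b) {
    if (is.character(b)) {
      i <- match(b, group$names)
      if (anyNA(i))
        stop(sprintf("unknown element name '%s'", b[which(is.na(i))[1]]),
             call. = FALSE)
      i
    } else if (is.list(b)) {
      vapply(b, function(r) el_index(group, as_residues(group, r)), 1L)
    } else {
      i <- as.integer(b)
      if (any(i < 1L | i > n))
        stop("element index out of range", call. = FALSE)
      i
    }
  })
  all_el <- sort(unlist(idx_blocks))
  if (length(all_el) != n || any(all_el != seq_len(n)))
    stop("blocks must partition the group elements exactly once",
         call. = FALSE)
  idx_blocks <- lapply(idx_blocks, sort)
  idx_blocks <- idx_blocks[order(vapply(idx_blocks, min, 1L))]
  labels <- integer(n)
  for (j in seq_along(idx_blocks)) labels[idx_blocks[[j]]] <- j
  structure(list(group = group, blocks = idx_blocks, labels = labels),
            class = "labeling")
}

labeling_from_labels <- function(group, labels) {
  labeling(group, split(seq_len(group$order), labels))
}

#' @export
print.labeling <- function(x, ...) {
  cat("<labeling ", format_labeling(x), ">\n", sep = "")
  invisible(x)
}

#' @export
format.labeling <- function(x, ...) format_labeling(x)

#' Parse and format the block text representation of a labeling
#'
#' The text format separates blocks with `|` and lists elements inside
#' braces, e.g. `"{0}|{1,6}|{2,5}|{3,4}"` on \eqn{Z_7} or
#' `"{(0,0)}|{(0,1),(1,0)}|{(1,1)}"` on \eqn{Z_2 \times Z_2}.
#'
#' @param group An `abelian_group`.
#' @param text A single character string in block format.
#' @return `parse_labeling` returns a `labeling`; `format_labeling`
#'   returns the canonical text form.
#' @export
parse_labeling <- function(group, text) {
  stopifnot(is.character(text), length(text) == 1L)
  parts <- strsplit(text, "|", fixed = TRUE)[[1]]
  parts <- trimws(parts)
  blocks <- lapply(parts, function(p) {
    if (!grepl("^\\{.*\\}$", p))
      stop(sprintf("block '%s' is not brace-delimited", p), call. = FALSE)
    inner <- substr(p, 2L, nchar(p) - 1L)
    if (length(group$factors) > 1L) {
      m <- regmatches(inner, gregexpr("\\([0-9, ]*\\)", inner))[[1]]
      if (length(m) == 0L)
        stop(sprintf("no elements found in block '%s'", p), call. = FALSE)
      gsub(" ", "", m)
    } else {
      trimws(strsplit(inner, ",", fixed = TRUE)[[1]])
    }
  })
  labeling(group, blocks)
}

#' @rdname parse_labeling
#' @param L A `labeling`.
#' @export
format_labeling <- function(L) {
  paste(vapply(L$blocks, function(b)
    paste0("{", paste(L$group$names[b], collapse = ","), "}"), ""),
    collapse = "|")
}

#' Symmetry and zero-isolation of labelings
#'
#' `is_symmetric` checks \eqn{L(g) = L(-g)} for all elements; symmetric
#' labelings force real symmetric model matrices and hence real spectra.
#' `zero_isolated` checks that the identity element forms a singleton
#' block, a necessary condition for G-compatibility: no other row of the
#' DFT matrix can aggregate like the all-ones row.
#'
#' @param L A `labeling`.
#' @return Logical scalar.
#' @export
is_symmetric <- function(L) {
  stopifnot(inherits(L, "labeling"))
  p <- neg_perm(L$group)
  all(L$labels == L$labels[p])
}

#' @rdname is_symmetric
#' @export
zero_isolated <- function(L) {
  stopifnot(inherits(L, "labeling"))
  sum(L$labels == L$labels[1L]) == 1L
}

#' G-compatibility of a labeling function
#'
#' A labeling is G-compatible when the DFT matrix preserves the equality
#' pattern of the label vector: whenever \eqn{L(g) = L(h)}, the
#' label-aggregated rows \eqn{g} and \eqn{h} of \eqn{K} coincide, i.e.
#' for every block \eqn{B}, \eqn{\sum_{k \in B} K_{g,k} = \sum_{k \in B}
#' K_{h,k}}. For symmetric labelings checking \eqn{K} alone suffices; for
#' non-symmetric labelings \eqn{K^{-1}} is checked as well.
#' G-compatibility is exactly what guarantees that the matrix exponential
#' of a model rate matrix stays inside the model.
#'
#' @param L A `labeling`.
#' @param tol Absolute tolerance on aggregated complex sums.
#' @return Logical scalar.
#' @examples
#' G <- parse_group("Z2xZ2")
#' is_compatible(general_jc_labeling(G))   # Jukes-Cantor: TRUE
#' @export
is_compatible <- function(L, tol = 1e-9) {
  stopifnot(inherits(L, "labeling"))
  K <- dft_matrix(L$group)
  ok <- aggregated_rows_equal(K, L, tol)
  if (ok && !is_symmetric(L))
    ok <- aggregated_rows_equal(inverse_dft_matrix(K) * L$group$order, L, tol)
  ok
}

aggregated_rows_equal <- function(K, L, tol) {
  n <- nrow(K)
  m <- length(L$blocks)
  Z <- matrix(0, n, m)
  Z[cbind(seq_len(n), L$labels)] <- 1
  A <- K %*% Z
  for (j in seq_len(m)) {
    b <- L$blocks[[j]]
    if (length(b) > 1L) {
      ref <- A[b[1L], ]
      dev <- abs(sweep(A[b, , drop = FALSE], 2L, ref, "-"))
      if (max(dev) > tol) return(FALSE)
    }
  }
  TRUE
}

#' Automorphisms of a finite abelian group
#'
#' Enumerates all group automorphisms as permutations of the canonical
#' element indices, by brute force over images of the standard generators
#' (one per cyclic factor): each generator of order \eqn{n_i} may map to
#' any element whose order divides \eqn{n_i}; the induced homomorphism is
#' kept when it is a bijection. Guarded to groups of order at most 16.
#'
#' @param group An `abelian_group` of order <= 16.
#' @return A list of integer permutation vectors `p` (with `p[i]` the
#'   image of element `i`), closed under composition and containing the
#'   identity.
#' @examples
#' length(automorphisms(parse_group("Z2xZ2")))  # 6, i.e. GL(2, 2)
#' @export
automorphisms <- function(group) {
  stopifnot(is_abelian_group(group))
  if (group$order > 16L)
    stop("automorphism enumeration supported only for group order <= 16",
         call. = FALSE)
  E <- group$elements
  f <- group$factors
  k <- length(f)
  n <- group$order
  ords <- element_orders(group)
  cands <- lapply(seq_len(k), function(j) which(f[j] %% ords == 0L))
  combos <- as.matrix(expand.grid(cands, KEEP.OUT.ATTRS = FALSE))
  out <- vector("list", 0L)
  for (r in seq_len(nrow(combos))) {
    A <- E[combos[r, ], , drop = FALSE]    # row j = image of generator e_j
    img_res <- (E %*% A) %% matrix(f, n, k, byrow = TRUE)
    p <- el_index(group, img_res)
    if (!anyDuplicated(p)) out[[length(out) + 1L]] <- p
  }
  out
}

element_orders <- function(group) {
  E <- group$elements
  f <- group$factors
  apply(E, 1L, function(r) {
    o <- 1L
    for (j in seq_along(f)) {
      oj <- f[j] %/% gcd_int(r[j], f[j])
      o <- o * oj %/% gcd_int(o, oj)
    }
    o
  })
}

gcd_int <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0) { t <- a %% b; a <- b; b <- t }
  max(a, 1L)
}

#' Enumerate symmetric G-compatible labelings
#'
#' Generates all set partitions of the group elements (restricted growth
#' strings, with symmetry and zero-isolation enforced during generation
#' as pruning) and keeps the G-compatible ones. Working with partitions
#' already identifies labeling functions up to renaming of the label set,
#' which is the identification under which the published tables of
#' symmetric G-compatible labelings are stated; note that distinct
#' partitions related by a group automorphism are both listed (the
#' compatible pattern depends on the chosen identification of states
#' with group elements). Set `up_to_automorphism = TRUE` to additionally
#' keep only the lexicographically minimal representative per orbit of
#' the automorphism group acting elementwise. Results are ordered by
#' number of blocks, then lexicographically.
#'
#' @param group An `abelian_group` of order <= 10.
#' @param up_to_automorphism Deduplicate by automorphism orbit
#'   (default `FALSE`).
#' @return List of `labeling` objects.
#' @examples
#' length(enumerate_labelings(parse_group("Z4")))  # 2
#' @export
enumerate_labelings <- function(group, up_to_automorphism = FALSE) {
  stopifnot(is_abelian_group(group))
  n <- group$order
  if (n > 10L)
    stop("labeling enumeration supported only for group order <= 10",
         call. = FALSE)
  np <- neg_perm(group)
  codes <- list()
  rec <- function(code, i, mx) {
    if (i > n) { codes[[length(codes) + 1L]] <<- code; return(invisible()) }
    if (np[i] < i) {
      # symmetric labeling: -g already placed, label is forced
      forced <- code[np[i]]
      code[i] <- forced
      rec(code, i + 1L, mx)
      return(invisible())
    }
    for (v in 2:(mx + 1L)) {  # never reuse label 1 (zero isolated)
      code[i] <- v
      rec(code, i + 1L, max(mx, v))
    }
    invisible()
  }
  if (n == 1L) stop("group order must be >= 2", call. = FALSE)
  rec(c(1L, integer(n - 1L)), 2L, 1L)
  labs <- lapply(codes, function(cd) labeling_from_labels(group, cd))
  labs <- Filter(is_compatible, labs)
  if (up_to_automorphism) {
    auts <- automorphisms(group)
    keys <- character(length(labs))
    reps <- vector("list", length(labs))
    for (i in seq_along(labs)) {
      orb <- orbit_forms(labs[[i]], auts)
      ks <- vapply(orb, `[[`, "", "key")
      best <- which(ks == min(ks))[1L]
      keys[i] <- orb[[best]]$key
      reps[[i]] <- orb[[best]]$labels
    }
    keep <- !duplicated(keys)
    labs <- lapply(which(keep), function(i)
      labeling_from_labels(group, reps[[i]]))
  }
  ord <- order(vapply(labs, function(L) length(L$blocks), 1L),
               vapply(labs, partition_key, ""))
  labs[ord]
}

# canonical restricted-growth key of a partition given by a labels vector
partition_key <- function(L) {
  labels <- if (inherits(L, "labeling")) L$labels else L
  rgs <- match(labels, unique(labels))
  paste(rgs, collapse = ".")
}

orbit_forms <- function(L, auts) {
  lapply(auts, function(p) {
    newlab <- integer(length(L$labels))
    newlab[p] <- L$labels
    list(labels = newlab, key = partition_key(newlab))
  })
}

#' Test whether two labelings are equal up to group automorphism
#'
#' @param L1,L2 Labelings on the same group.
#' @return Logical scalar.
#' @export
same_up_to_automorphism <- function(L1, L2) {
  stopifnot(inherits(L1, "labeling"), inherits(L2, "labeling"))
  if (!identical(L1$group$factors, L2$group$factors))
    return(FALSE)
  auts <- automorphisms(L1$group)
  k2 <- partition_key(L2)
  any(vapply(orbit_forms(L1, auts), `[[`, "", "key") == k2)
}

#' Stock labelings: general Jukes-Cantor and inverse-pair
#'
#' `general_jc_labeling` puts the identity in its own block and all other
#' elements in one block (one substitution rate for every change); it is
#' symmetric and G-compatible for every finite abelian group.
#' `pair_labeling` assigns `g` and `-g` the same label and otherwise
#' distinct labels; it is likewise always G-compatible and is the finest
#' symmetric labeling.
#'
#' @param group An `abelian_group`.
#' @return A `labeling`.
#' @examples
#' format_labeling(pair_labeling(parse_group("Z5")))  # {0}|{1,4}|{2,3}
#' @export
general_jc_labeling <- function(group) {
  n <- group$order
  labeling(group, list(1L, seq_len(n)[-1L]))
}

#' @rdname general_jc_labeling
#' @export
pair_labeling <- function(group) {
  n <- group$order
  p <- neg_perm(group)
  labels <- pmin(seq_len(n), p)
  labeling_from_labels(group, labels)
}
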