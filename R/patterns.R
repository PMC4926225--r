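# Walsh-Hadamard measurement bases and their complementary binary decomposition.

is_pow2 <- function(n) {
  is.numeric(n) && length(n) == 1L && n >= 1 && bitwAnd(as.integer(n), as.integer(n) - 1L) == 0L
}

sign_changes <- function(v) sum(diff(sign(v)) != 0)

#' 1D Walsh-Hadamard vectors
#'
#' Builds the `n` Walsh-Hadamard vectors of length `n` (entries +1/-1) by
#' Sylvester doubling, either in natural (Sylvester) order or in sequency
#' order, where vector `i` (0-based) has exactly `i` sign changes.
#'
#' @param n Length of the vectors; must be a power of two.
#' @param ordering `"natural"` (Sylvester recursion order) or `"sequency"`
#'   (rows sorted by number of sign changes).
#' @return An `n` x `n` matrix whose rows are the Walsh vectors.
#' @examples
#' build_walsh_1d(4, "sequency")
#' @export
build_walsh_1d <- function(n, ordering = c("sequency", "natural")) {
  ordering <- match.arg(ordering)
  if (!is_pow2(n))
    stop("'n' must be a power of two, got ", n)
  n <- as.integer(n)
  H <- matrix(1, 1, 1)
  while (nrow(H) < n)
    H <- rbind(cbind(H, H), cbind(H, -H))
  if (ordering == "sequency" && n > 1L) {
    sc <- apply(H, 1L, sign_changes)
    H <- H[order(sc), , drop = FALSE]
  }
  dimnames(H) <- NULL
  H
}

#' 2D Walsh-Hadamard pattern basis
#'
#' Constructs the complete orthogonal set of `size^2` two-dimensional
#' Walsh-Hadamard functions as separable outer products of 1D Walsh vectors.
#' Each function takes values in {+1, -1}; in sequency ordering the first
#' function is the all-ones (DC) function.  The sequency pair (u, v) of a
#' function counts its sign changes along rows (horizontal, u) and down
#' columns (vertical, v); these act as 2D spatial frequencies.
#'
#' Functions are never materialised all at once: the object stores the 1D
#' matrix and the index map, and [basis_function()] builds any single
#' function on demand, so a 64 x 64 basis (4096 functions) costs the same
#' memory as its 64 x 64 seed matrix.
#'
#' @param size Pixels per image side; must be a power of two.
#' @param ordering `"sequency"` or `"natural"`, passed to [build_walsh_1d()].
#' @return An object of class `wh_basis` with fields `size`, `ordering`,
#'   `W` (the 1D matrix), and `uv` (a `size^2` x 2 integer matrix of
#'   sequency pairs, one row per function).
#' @seealso [basis_function()], [complementary_pair()],
#'   [select_low_sequency_subset()]
#' @examples
#' b <- build_basis_2d(4)
#' basis_function(b, 1)   # DC: all +1
#' @export
build_basis_2d <- function(size, ordering = c("sequency", "natural")) {
  ordering <- match.arg(ordering)
  if (!is_pow2(size))
    stop("'size' must be a power of two, got ", size)
  size <- as.integer(size)
  W <- build_walsh_1d(size, ordering)
  sc <- apply(W, 1L, sign_changes)
  # function i = (a-1)*size + b pairs vertical vector a with horizontal b
  a <- rep(seq_len(size), each = size)
  b <- rep(seq_len(size), times = size)
  uv <- cbind(u = sc[b], v = sc[a])
  structure(
    list(size = size, ordering = ordering, W = W, uv = uv),
    class = "wh_basis"
  )
}

#' @export
print.wh_basis <- function(x, ...) {
  cat(sprintf("<wh_basis> %d x %d, %d functions, %s ordering\n",
              x$size, x$size, x$size^2, x$ordering))
  invisible(x)
}

n_functions <- function(basis) basis$size^2L

check_index <- function(basis, index) {
  if (length(index) != 1L || is.na(index) || index < 1L || index > n_functions(basis))
    stop("pattern index ", index, " out of range 1..", n_functions(basis))
  as.integer(index)
}

#' Materialise one 2D basis function
#'
#' @param basis A [build_basis_2d()] object.
#' @param index Function position, 1-based.
#' @return A `size` x `size` matrix with entries +1/-1.
#' @export
basis_function <- function(basis, index) {
  index <- check_index(basis, index)
  s <- basis$size
  a <- (index - 1L) %/% s + 1L
  b <- (index - 1L) %% s + 1L
  outer(basis$W[a, ], basis$W[b, ])
}

#' Forward 2D Walsh-Hadamard analysis
#'
#' Projects an image on every basis function at once via the separable
#' transform `W X W'`, returning the coefficient vector in basis index
#' order.  `wh_synthesize()` inverts it: `X = W' C W / size^2`.
#'
#' @param basis A [build_basis_2d()] object.
#' @param X Image matrix, `size` x `size`.
#' @return Numeric vector of `size^2` inner products `<X, f_i>`.
#' @export
wh_analyze <- function(basis, X) {
  stopifnot(is.matrix(X), all(dim(X) == basis$size))
  C <- basis$W %*% X %*% t(basis$W)
  as.vector(t(C))  # row-major: index (a-1)*s + b
}

#' @rdname wh_analyze
#' @param coefficients Vector of `size^2` coefficients (basis index order).
#' @export
wh_synthesize <- function(basis, coefficients) {
  s <- basis$size
  stopifnot(length(coefficients) == s^2)
  C <- matrix(coefficients, s, s, byrow = TRUE)
  t(basis$W) %*% C %*% basis$W / s^2
}

#' Complementary binary pattern pair
#'
#' Splits a +/-1 basis function H into the binary pair displayed on the two
#' DMD reflection arms: `plus = (E + H)/2` and `minus = (E - H)/2`, where E
#' is the all-ones matrix.  The pair satisfies `plus + minus = E` and
#' `plus - minus = H` exactly.
#'
#' @inheritParams basis_function
#' @return An object of class `wh_comp_pair`: list with 0/1 matrices
#'   `plus`, `minus` and the `parent_index`.
#' @export
complementary_pair <- function(basis, index) {
  H <- basis_function(basis, index)
  structure(
    list(plus = (1 + H) / 2, minus = (1 - H) / 2, parent_index = index),
    class = "wh_comp_pair"
  )
}

#' Shift-and-rescale binary mask
#'
#' The single-arm binary encoding of a basis function: `(H + 1)/2`, with
#' entries in {0, 1}.  Identical to the `plus` member of
#' [complementary_pair()].
#'
#' @inheritParams basis_function
#' @return A `size` x `size` 0/1 matrix.
#' @export
shift_rescale <- function(basis, index) {
  (basis_function(basis, index) + 1) / 2
}

sequency_key_order <- function(uv) {
  u <- uv[, 1L]; v <- uv[, 2L]
  order(pmax(u, v), u + v, u, v)
}

#' Low-spatial-frequency pattern subset
#'
#' Selects the `ceiling(ratio * size^2)` basis functions with the lowest 2D
#' sequencies, for undersampled (compressive) acquisition.  Functions are
#' ranked by concentric sequency shells: first by `max(u, v)`, ties by
#' `u + v`, then by `(u, v)` lexicographically, so the selection mimics an
#' ideal low-pass window and the DC function always comes first.
#'
#' @param basis A sequency-ordered [build_basis_2d()] object.
#' @param ratio Measurement (compression) ratio in (0, 1]; `ratio = 1`
#'   keeps the complete basis.
#' @return An object of class `pattern_subset`: list with `indices`
#'   (positions into the basis, DC first), `ratio` and `size`.
#' @examples
#' length(select_low_sequency_subset(build_basis_2d(32), 0.2)$indices)  # 205
#' @export
select_low_sequency_subset <- function(basis, ratio) {
  if (!inherits(basis, "wh_basis") || basis$ordering != "sequency")
    stop("subset selection requires a sequency-ordered basis")
  if (!is.numeric(ratio) || length(ratio) != 1L || ratio <= 0 || ratio > 1)
    stop("'ratio' must lie in (0, 1], got ", ratio)
  m <- as.integer(ceiling(ratio * n_functions(basis)))
  idx <- sequency_key_order(basis$uv)[seq_len(m)]
  structure(
    list(indices = idx, ratio = ratio, size = basis$size),
    class = "pattern_subset"
  )
}

#' Full-basis subset helper
#'
#' @param basis A [build_basis_2d()] object.
#' @return A [select_low_sequency_subset()]-style subset covering every
#'   function in basis order (DC first for sequency ordering).
#' @export
full_subset <- function(basis) {
  structure(
    list(indices = seq_len(n_functions(basis)), ratio = 1, size = basis$size),
    class = "pattern_subset"
  )
}

#' Alternative (non-Hadamard) binary mask sets
#'
#' Raster masks switch one pixel on per pattern (classical raster scan);
#' random masks draw i.i.d. Bernoulli(0.5) binary values, reproducibly from
#' `seed`.  Both are directly displayable on a binary mirror device.
#'
#' @param size Image side in pixels (any positive integer).
#' @param kind `"raster"` or `"random"`.
#' @param seed Integer seed; required for `kind = "random"`.
#' @return An object of class `mask_set`: list with `size`, `kind` and
#'   `masks`, a `size^2`-long list of `size` x `size` 0/1 matrices.
#' @export
build_alt_basis <- function(size, kind = c("raster", "random"), seed = NULL) {
  kind <- match.arg(kind)
  stopifnot(size >= 1)
  size <- as.integer(size)
  n <- size^2L
  if (kind == "raster") {
    masks <- lapply(seq_len(n), function(i) {
      m <- matrix(0, size, size)
      m[(i - 1L) %/% size + 1L, (i - 1L) %% size + 1L] <- 1
      m
    })
  } else {
    if (is.null(seed))
      stop("a 'seed' is required for random masks")
    masks <- with_seed(seed, {
      lapply(seq_len(n), function(i)
        matrix(stats::rbinom(size^2, 1L, 0.5), size, size))
    })
  }
  structure(list(size = size, kind = kind, masks = masks), class = "mask_set")
}

#' Export a pattern set as image files plus a manifest
#'
#' Writes each complementary `plus` mask as an 8-bit binary (0/255) PNG or
#' TIFF under `dir`, together with `manifest.csv` listing index and sequency
#' pair.
#'
#' @param basis A [build_basis_2d()] object.
#' @param dir Output directory (created if missing).
#' @param indices Which functions to export; default all.
#' @param format `"png"` or `"tiff"`.
#' @return Invisibly, the manifest data frame.
#' @export
export_patterns <- function(basis, dir, indices = seq_len(n_functions(basis)),
                            format = c("png", "tiff")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writer <- if (format == "png") png::writePNG else tiff::writeTIFF
  for (i in indices) {
    img <- shift_rescale(basis, i)
    writer(img, file.path(dir, sprintf("pattern_%05d.%s", i,
                                       if (format == "png") "png" else "tif")))
  }
  manifest <- data.frame(
    index = indices,
    u = basis$uv[indices, 1L],
    v = basis$uv[indices, 2L],
    ordering = basis$ordering
  )
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

# Run code with a private RNG state so callers' streams are untouched.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}
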