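# Image recovery: exact inverse Walsh-Hadamard synthesis, zero-filled
# synthesis for undersampled records, and total-variation minimization with
# (relaxed) equality constraints.

recon_result <- function(image, method, iterations = 0L, residual = 0,
                         objective = NA_real_, converged = TRUE) {
  structure(
    list(image = image, method = method, iterations = iterations,
         residual = residual, objective = objective, converged = converged),
    class = "spc_recon"
  )
}

#' @export
print.spc_recon <- function(x, ...) {
  cat(sprintf("<spc_recon> %s, %d x %d, iterations %d, residual %.3g\n",
              x$method, nrow(x$image), ncol(x$image), x$iterations, x$residual))
  invisible(x)
}

#' Sensing operator for a pattern subset
#'
#' The M x N linear map from image space to measured coefficient space:
#' row i is the flattened basis function `subset$indices[i]`.  Because the
#' rows are orthogonal with squared norm `size^2`, `phi(adjoint(y)) =
#' size^2 * y`, which makes projection onto the measurement-consistency
#' set a single forward/adjoint pair.
#'
#' @param basis A [build_basis_2d()] object.
#' @param subset A [select_low_sequency_subset()] / [full_subset()] subset.
#' @return Object of class `sensing_operator` with closures `phi` (image
#'   matrix -> length-M vector) and `adjoint` (vector -> image matrix),
#'   plus `M`, `N`, `size`, `indices`.
#' @export
sensing_operator <- function(basis, subset) {
  stopifnot(inherits(basis, "wh_basis"), inherits(subset, "pattern_subset"),
            subset$size == basis$size)
  idx <- subset$indices
  s <- basis$size
  structure(
    list(
      phi = function(x) wh_analyze(basis, x)[idx],
      adjoint = function(y) {
        full <- numeric(s^2)
        full[idx] <- y
        wh_synthesize(basis, full) * s^2
      },
      M = length(idx), N = s^2, size = s, indices = idx
    ),
    class = "sensing_operator"
  )
}

# Coefficients of a record aligned to the basis index space (scene units).
aligned_coefficients <- function(record) {
  y <- signed_coefficients(record)
  list(indices = record$indices, y = y)
}

#' Exact inverse-transform reconstruction
#'
#' Requires a record covering the full basis; synthesizes
#' `X = (1/size^2) sum_i c_i f_i` from the gain/illumination-rescaled
#' coefficients.  With a noiseless, unquantized balanced record this
#' recovers the scene to floating-point accuracy.
#'
#' @param record An [simulate_acquisition()] record covering all `size^2`
#'   patterns.
#' @param basis The [build_basis_2d()] basis used for acquisition.
#' @return An `spc_recon` with `method = "inverse"`.
#' @export
inverse_transform <- function(record, basis) {
  s <- basis$size
  if (length(record$indices) != s^2)
    stop("record covers ", length(record$indices), " of ", s^2,
         " patterns; use zero_fill_reconstruct() for undersampled records")
  al <- aligned_coefficients(record)
  full <- numeric(s^2)
  full[al$indices] <- al$y
  recon_result(wh_synthesize(basis, full), "inverse")
}

#' Zero-filled reconstruction of an undersampled record
#'
#' Unmeasured coefficients are set to zero and the inverse synthesis is
#' applied; no solver runs, so this is the live-display mode.  With a full
#' subset it coincides with [inverse_transform()]; with only the DC
#' pattern it returns the constant image at the scene mean.
#'
#' @inheritParams inverse_transform
#' @param subset The measured subset; defaults to the record's own.
#' @return An `spc_recon` with `method = "zero_fill"`.
#' @export
zero_fill_reconstruct <- function(record, basis, subset = record$subset) {
  s <- basis$size
  if (!all(subset$indices %in% record$indices))
    stop("record does not cover the requested subset")
  al <- aligned_coefficients(record)
  keep <- match(subset$indices, al$indices)
  full <- numeric(s^2)
  full[subset$indices] <- al$y[keep]
  recon_result(wh_synthesize(basis, full), "zero_fill")
}

#' Solver settings for [min_tv_reconstruct()]
#'
#' @param tolerance Relative-change stopping tolerance.
#' @param max_iter Maximum number of primal-dual iterations.
#' @param epsilon Constraint relaxation radius: the solution satisfies
#'   `||phi(x) - y||_2 <= epsilon` (0 = equality constraints).
#' @return A list of settings.
#' @export
tv_params <- function(tolerance = 1e-6, max_iter = 2000, epsilon = 0) {
  stopifnot(tolerance > 0, max_iter >= 1, epsilon >= 0)
  list(tolerance = tolerance, max_iter = as.integer(max_iter), epsilon = epsilon)
}

# Anisotropic discrete gradient with replicate padding: forward differences,
# zero in the last column (horizontal) / row (vertical).
tv_grad <- function(x) {
  s1 <- nrow(x); s2 <- ncol(x)
  gh <- matrix(0, s1, s2); gv <- matrix(0, s1, s2)
  if (s2 > 1) gh[, -s2] <- x[, -1, drop = FALSE] - x[, -s2, drop = FALSE]
  if (s1 > 1) gv[-s1, ] <- x[-1, , drop = FALSE] - x[-s1, , drop = FALSE]
  list(h = gh, v = gv)
}

# Adjoint of tv_grad (negative divergence).
tv_grad_adj <- function(g) {
  gh <- g$h; gv <- g$v
  s1 <- nrow(gh); s2 <- ncol(gh)
  out <- matrix(0, s1, s2)
  if (s2 > 1) {
    out[, 1] <- out[, 1] - gh[, 1]
    out[, s2] <- out[, s2] + gh[, s2 - 1]
    if (s2 > 2)
      out[, 2:(s2 - 1)] <- out[, 2:(s2 - 1)] +
        gh[, 1:(s2 - 2), drop = FALSE] - gh[, 2:(s2 - 1), drop = FALSE]
  }
  if (s1 > 1) {
    out[1, ] <- out[1, ] - gv[1, ]
    out[s1, ] <- out[s1, ] + gv[s1 - 1, ]
    if (s1 > 2)
      out[2:(s1 - 1), ] <- out[2:(s1 - 1), ] +
        gv[1:(s1 - 2), , drop = FALSE] - gv[2:(s1 - 1), , drop = FALSE]
  }
  out
}

#' Anisotropic total variation of an image
#'
#' Sum of absolute horizontal and vertical forward differences with
#' replicate padding at the borders.
#'
#' @param x Image matrix.
#' @return Non-negative scalar.
#' @export
total_variation <- function(x) {
  g <- tv_grad(x)
  sum(abs(g$h)) + sum(abs(g$v))
}

#' Total-variation minimization with (relaxed) equality constraints
#'
#' Solves `min_x TV(x)  subject to  ||phi(x) - y||_2 <= epsilon` (equality
#' constraints when `epsilon = 0`) with a Chambolle-Pock primal-dual
#' splitting.  Every primal iterate is projected exactly onto the
#' constraint set (cheap because the sensing rows are orthogonal), so all
#' iterates are feasible; the returned image is the feasible iterate with
#' the lowest TV seen, which makes the reported objective non-increasing
#' over the run.  The solve is deterministic given the inputs and
#' settings.
#'
#' @param record An [simulate_acquisition()] record.
#' @param operator A [sensing_operator()] for the record's basis/subset.
#' @param params Settings from [tv_params()].
#' @return An `spc_recon` with `method = "min_tv"`, iteration count, final
#'   constraint residual (coefficient units), TV objective, and a
#'   `converged` flag (non-convergence is flagged, never silent).
#' @export
min_tv_reconstruct <- function(record, operator, params = tv_params()) {
  stopifnot(inherits(operator, "sensing_operator"))
  if (!identical(as.integer(operator$indices), as.integer(record$indices)))
    stop("operator subset does not match the record's measured patterns")
  y <- signed_coefficients(record)
  s2 <- operator$size^2

  project_feasible <- function(x) {
    p <- operator$phi(x)
    r <- p - y
    nr <- sqrt(sum(r^2))
    target <- if (params$epsilon == 0) y
              else if (nr > params$epsilon) y + params$epsilon * r / nr
              else p
    x + operator$adjoint(target - p) / s2
  }

  tau <- sigma <- 1 / sqrt(8)  # ||D||^2 <= 8 for the anisotropic gradient
  x <- project_feasible(operator$adjoint(y) / s2)
  xbar <- x
  ph <- matrix(0, operator$size, operator$size)
  pv <- matrix(0, operator$size, operator$size)
  best_x <- x
  best_tv <- total_variation(x)
  converged <- FALSE
  it <- 0L
  while (it < params$max_iter) {
    it <- it + 1L
    g <- tv_grad(xbar)
    ph <- pmin(pmax(ph + sigma * g$h, -1), 1)
    pv <- pmin(pmax(pv + sigma * g$v, -1), 1)
    x_new <- project_feasible(x - tau * tv_grad_adj(list(h = ph, v = pv)))
    tv_new <- total_variation(x_new)
    if (tv_new < best_tv) {
      best_tv <- tv_new
      best_x <- x_new
    }
    delta <- sqrt(sum((x_new - x)^2)) / max(sqrt(sum(x^2)), 1)
    xbar <- 2 * x_new - x
    x <- x_new
    if (delta < params$tolerance) {
      converged <- TRUE
      break
    }
  }
  residual <- sqrt(sum((operator$phi(best_x) - y)^2))
  recon_result(best_x, "min_tv", iterations = it, residual = residual,
               objective = best_tv, converged = converged)
}

#' Display normalization to 8 bits
#'
#' Linear stretch of an image to the 0..255 range (minimum to 0, maximum
#' to 255, round half up); a constant image maps to all zeros by
#' convention.
#'
#' @param image Numeric matrix.
#' @return Integer matrix with values in 0..255.
#' @export
normalize_display <- function(image) {
  rng <- range(image)
  if (rng[1] == rng[2])
    return(matrix(0L, nrow(image), ncol(image)))
  scaled <- (image - rng[1]) / (rng[2] - rng[1]) * 255
  matrix(as.integer(floor(scaled + 0.5)), nrow(image), ncol(image))
}

#' Write a reconstruction to image files plus a diagnostics log
#'
#' Writes `<prefix>.png` (8-bit, display-normalized), `<prefix>.tif`
#' (32-bit float, physical units) and `<prefix>_log.yaml` (method,
#' iterations, residual, objective, convergence flag).
#'
#' @param result An `spc_recon`.
#' @param prefix Output path prefix.
#' @return Invisibly, the prefix.
#' @export
write_reconstruction <- function(result, prefix) {
  dir.create(dirname(prefix), showWarnings = FALSE, recursive = TRUE)
  png::writePNG(normalize_display(result$image) / 255, paste0(prefix, ".png"))
  tiff::writeTIFF(result$image, paste0(prefix, ".tif"),
                  bits.per.sample = 32L, reduce = FALSE)
  yaml::write_yaml(
    list(method = result$method, iterations = result$iterations,
         residual = result$residual, objective = result$objective,
         converged = result$converged),
    paste0(prefix, "_log.yaml"))
  invisible(prefix)
}
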