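# Polynomial background models in coordinates normalized to [-1, 1].
# Normalization keeps the degree-3 Vandermonde systems well conditioned on
# lines and windows hundreds of pixels long.

norm_coord <- function(idx, n) {
  if (n <= 1L) return(rep(0, length(idx)))
  2 * (idx - 1) / (n - 1) - 1
}

vander_1d <- function(u, order) {
  outer(u, 0:order, `^`)
}

# total-degree monomial exponent table for the 2-D basis
monomials_2d <- function(order) {
  ex <- expand.grid(i = 0:order, j = 0:order)
  ex <- ex[ex$i + ex$j <= order, , drop = FALSE]
  ex <- ex[order(ex$i + ex$j, ex$i), , drop = FALSE]
  rownames(ex) <- NULL
  ex
}

vander_2d <- function(u, v, order) {
  ex <- monomials_2d(order)
  X <- matrix(0, length(u), nrow(ex))
  for (k in seq_len(nrow(ex))) X[, k] <- u^ex$i[k] * v^ex$j[k]
  colnames(X) <- paste0("u^", ex$i, "*v^", ex$j)
  X
}

#' Fit a polynomial curve to one scan line with foreground excluded
#'
#' Ordinary least squares on the included (background) samples only, in a
#' power basis over the line coordinate normalized to \eqn{[-1, 1]}. The
#' fitted curve is evaluable at every position of the line, including the
#' excluded foreground, which is what allows the baseline to be subtracted
#' under features.
#'
#' @param values numeric vector, one scan line (heights in nm).
#' @param include logical vector of the same length, `TRUE` = background
#'   sample used in the fit; `NULL` means all.
#' @param order polynomial order (default 3, the usual choice for
#'   tilt/bow backgrounds).
#' @return A `poly_model_1d` with elements `order`, `coeffs`, `n`.
#' @examples
#' y <- 2 - 0.03 * (1:64) + 1e-4 * (1:64)^2
#' fit <- fit_poly_line(y, order = 2)
#' max(abs(predict(fit) - y))
#' @export
fit_poly_line <- function(values, include = NULL, order = 3L) {
  n <- length(values)
  if (is.null(include)) include <- rep(TRUE, n)
  if (length(include) != n)
    stop("`include` must match `values` in length", call. = FALSE)
  if (order < 0L) stop("`order` must be >= 0", call. = FALSE)
  k <- sum(include)
  if (k < order + 2L)
    stop(structure(class = c("afm_insufficient_background", "error", "condition"),
                   list(message = sprintf(
                     "only %d background points for an order-%d fit (need >= %d)",
                     k, order, order + 2L), call = NULL)))
  u <- norm_coord(seq_len(n), n)
  X <- vander_1d(u[include], order)
  coef <- qr.coef(qr(X), values[include])
  structure(list(order = as.integer(order), coeffs = as.numeric(coef), n = n),
            class = "poly_model_1d")
}

#' @export
predict.poly_model_1d <- function(object, positions = NULL, ...) {
  if (is.null(positions)) positions <- seq_len(object$n)
  u <- norm_coord(positions, object$n)
  drop(vander_1d(u, object$order) %*% object$coeffs)
}

#' @export
print.poly_model_1d <- function(x, ...) {
  cat(sprintf("<poly_model_1d> order %d over %d px\n", x$order, x$n))
  cat("  coeffs:", signif(x$coeffs, 6), "\n")
  invisible(x)
}

#' Fit a polynomial surface with foreground excluded
#'
#' Least-squares fit of a total-degree-`order` polynomial surface (10
#' monomials at order 3) over the included pixels, in row/column
#' coordinates normalized to \eqn{[-1, 1]} per axis.
#'
#' @param img a `height_image` or numeric matrix.
#' @param include logical matrix of the same shape (`TRUE` = background
#'   pixel used in the fit), a `foreground_mask` whose complement is used,
#'   or `NULL` for all pixels.
#' @param order total polynomial degree (default 3).
#' @return A `poly_model_2d` with elements `order`, `coeffs`, `dims`,
#'   `monomials`.
#' @export
fit_poly_surface <- function(img, include = NULL, order = 3L) {
  img <- as_height_image(img)
  m <- img$heights
  inc <- as_include_matrix(include, dim(m))
  ex <- monomials_2d(order)
  if (sum(inc) < nrow(ex) + 1L)
    stop(structure(class = c("afm_insufficient_background", "error", "condition"),
                   list(message = sprintf(
                     "only %d background pixels for an order-%d surface (need >= %d)",
                     sum(inc), order, nrow(ex) + 1L), call = NULL)))
  idx <- which(inc, arr.ind = TRUE)
  u <- norm_coord(idx[, 1L], nrow(m))
  v <- norm_coord(idx[, 2L], ncol(m))
  X <- vander_2d(u, v, order)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    deficient <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop(sprintf("rank-deficient surface fit; deficient monomials: %s",
                 paste(deficient, collapse = ", ")), call. = FALSE)
  }
  coef <- qr.coef(qx, m[inc])
  structure(list(order = as.integer(order), coeffs = as.numeric(coef),
                 dims = dim(m), monomials = ex),
            class = "poly_model_2d")
}

#' @export
predict.poly_model_2d <- function(object, ...) {
  nr <- object$dims[1L]; nc <- object$dims[2L]
  u <- norm_coord(seq_len(nr), nr)
  v <- norm_coord(seq_len(nc), nc)
  ex <- object$monomials
  out <- matrix(0, nr, nc)
  for (k in seq_len(nrow(ex)))
    out <- out + object$coeffs[k] * outer(u^ex$i[k], v^ex$j[k])
  out
}

#' @export
print.poly_model_2d <- function(x, ...) {
  cat(sprintf("<poly_model_2d> total degree %d over %d x %d px, %d monomials\n",
              x$order, x$dims[1L], x$dims[2L], length(x$coeffs)))
  invisible(x)
}

# resolve an `include` argument (NULL / logical matrix with TRUE = used /
# foreground_mask whose complement is used) into the background indicator
as_include_matrix <- function(include, dims) {
  if (is.null(include)) return(matrix(TRUE, dims[1L], dims[2L]))
  if (inherits(include, "foreground_mask"))
    return(background_matrix(include, dims))
  if (is.logical(include) && is.matrix(include)) {
    if (!identical(dim(include), as.integer(dims)))
      stop("include shape does not match the image", call. = FALSE)
    return(include)
  }
  stop("include must be a logical matrix, a foreground_mask, or NULL",
       call. = FALSE)
}

# resolve a mask argument (NULL / logical matrix with TRUE = foreground /
# foreground_mask) into the logical BACKGROUND indicator used for fitting
background_matrix <- function(mask, dims) {
  if (is.null(mask)) return(matrix(TRUE, dims[1L], dims[2L]))
  inc <- as_mask_matrix(mask, dims)
  bg <- !inc
  if (!any(bg)) stop("mask excludes every pixel; no background to fit",
                     call. = FALSE)
  bg
}
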