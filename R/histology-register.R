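#' Least-squares transform from paired control points
#'
#' Fits the transform mapping moving-section (trichrome) pixel coordinates
#' onto fixed-section (Ki67) coordinates from manually picked control-point
#' pairs. The default `"similarity"` model (rotation + isotropic scale +
#' translation, no reflection) suits adjacent 4-um sections and is solved
#' exactly in closed form as a complex linear least-squares problem;
#' `"affine"` (6 parameters) is available for shear/anisotropy and is
#' solved by QR. The root-mean-square residual over the control points is
#' reported.
#'
#' @param points data.frame or matrix with columns `x_moving`, `y_moving`,
#'   `x_fixed`, `y_fixed`; >= 2 pairs for similarity, >= 3 for affine.
#' @param model `"similarity"` or `"affine"`.
#' @return A `sectionTransform`: list with 2x2 matrix `A`, translation `t`,
#'   `model`, residual `rmsPx` and `n`.
#' @examples
#' pts <- data.frame(x_moving = c(0, 10, 0), y_moving = c(0, 0, 10),
#'                   x_fixed = c(5, 15, 5), y_fixed = c(-2, -2, 8))
#' fitRegistration(pts)  # pure translation (+5, -2)
#' @export
fitRegistration <- function(points, model = c("similarity", "affine")) {
  model <- match.arg(model)
  points <- as.data.frame(points)
  need <- c("x_moving", "y_moving", "x_fixed", "y_fixed")
  stopIfNot(all(need %in% names(points)),
            paste("control points need columns:", paste(need, collapse = ", ")))
  n <- nrow(points)
  if (anyDuplicated(points[, c("x_fixed", "y_fixed")]))
    stop("duplicate fixed control points", call. = FALSE)
  if (model == "similarity") {
    if (n < 2) stop("similarity needs >= 2 control points", call. = FALSE)
    zm <- complex(real = points$x_moving, imaginary = points$y_moving)
    zf <- complex(real = points$x_fixed, imaginary = points$y_fixed)
    zm0 <- zm - mean(zm); zf0 <- zf - mean(zf)
    denom <- sum(Mod(zm0)^2)
    if (denom == 0) stop("degenerate control points (all moving points coincide)",
                         call. = FALSE)
    a <- sum(Conj(zm0) * zf0) / denom
    b <- mean(zf) - a * mean(zm)
    A <- matrix(c(Re(a), Im(a), -Im(a), Re(a)), 2, 2)
    tvec <- c(Re(b), Im(b))
  } else {
    if (n < 3) stop("affine needs >= 3 control points", call. = FALSE)
    X <- cbind(1, points$x_moving, points$y_moving)
    qrX <- qr(X)
    if (qrX$rank < 3)
      stop("control points are collinear; affine transform is rank-deficient",
           call. = FALSE)
    beta <- qr.coef(qrX, cbind(points$x_fixed, points$y_fixed))
    A <- t(beta[2:3, ])
    tvec <- beta[1, ]
  }
  tf <- structure(list(A = A, t = tvec, model = model, n = n),
                  class = "sectionTransform")
  pred <- applyTransform(tf, cbind(points$x_moving, points$y_moving))
  tf$rmsPx <- sqrt(mean((pred[, 1] - points$x_fixed)^2 +
                        (pred[, 2] - points$y_fixed)^2))
  tf
}

#' @export
print.sectionTransform <- function(x, ...) {
  cat(sprintf("sectionTransform (%s, %d points): RMS residual %.3g px\n",
              x$model, x$n, x$rmsPx))
  invisible(x)
}

#' Apply a section transform to coordinates
#'
#' @param transform a `sectionTransform` from [fitRegistration()].
#' @param xy `n x 2` matrix of (x, y) coordinates in the moving frame.
#' @return `n x 2` matrix of coordinates in the fixed frame.
#' @export
applyTransform <- function(transform, xy) {
  xy <- matrix(as.numeric(xy), ncol = 2)
  sweep(xy %*% t(transform$A), 2, transform$t, `+`)
}

#' Invert a section transform
#'
#' @param transform a `sectionTransform`.
#' @return The inverse `sectionTransform` (fixed -> moving).
#' @export
invertTransform <- function(transform) {
  Ainv <- solve(transform$A)
  structure(list(A = Ainv, t = as.numeric(-Ainv %*% transform$t),
                 model = transform$model, n = transform$n,
                 rmsPx = transform$rmsPx),
            class = "sectionTransform")
}

#' Resample a binary mask into the fixed-section frame
#'
#' Maps a mask defined on the moving (trichrome) raster into the fixed
#' (Ki67) raster through the fitted transform, by nearest-neighbour lookup:
#' each target pixel centre is sent through the inverse transform and takes
#' the value of the nearest source pixel, so binary masks stay binary.
#' Target pixels that map outside the source frame are left unlabelled
#' (`FALSE`).
#'
#' @param mask logical matrix on the moving raster.
#' @param transform `sectionTransform` mapping moving -> fixed coordinates.
#' @param targetShape `c(height, width)` of the fixed raster; defaults to
#'   the mask's own shape.
#' @return Logical matrix of shape `targetShape`.
#' @export
transferMask <- function(mask, transform, targetShape = dim(mask)) {
  stopifnot(is.logical(mask) || all(mask %in% c(0, 1)))
  h <- targetShape[1]; w <- targetShape[2]
  inv <- invertTransform(transform)
  xs <- rep(seq_len(w) - 1, each = h)
  ys <- rep(seq_len(h) - 1, times = w)
  src <- applyTransform(inv, cbind(xs, ys))
  xi <- round(src[, 1]); yi <- round(src[, 2])
  ok <- xi >= 0 & xi <= ncol(mask) - 1 & yi >= 0 & yi <= nrow(mask) - 1
  out <- matrix(FALSE, h, w)
  out[cbind(ys + 1, xs + 1)[ok, , drop = FALSE]] <-
    mask[cbind(yi + 1, xi + 1)[ok, , drop = FALSE]]
  out
}
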