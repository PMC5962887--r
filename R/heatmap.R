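# Hand-activity heatmaps: per-hand 2D grids of accumulated time mass over
# the normalized signing space, blurred with a Gaussian whose width scales
# with the horizontal resolution.

#' Build a hand-activity heatmap for a group of signs
#'
#' Each detected frame of each sign deposits mass into the grid cell under
#' its hand; per sign the deposit is optionally normalized by the sign's
#' detected frame count, so every sign contributes equal total mass (time
#' share) regardless of duration. The per-sign grids are convolved with a
#' Gaussian of `sigma = 0.03125 * resolution_x` cells (truncated at 4 sigma,
#' kernel normalized to unit sum, so mass is conserved away from the grid
#' border) and averaged over signs. Convolution is linear, so it is applied
#' once to the averaged grid — the result is identical to blurring each sign
#' first.
#'
#' @param signs list of [sign_trajectory()].
#' @param resolution_x horizontal cell count `x`; vertical count follows the
#'   bounds' aspect ratio.
#' @param bounds list with `x = c(min, max)`, `y = c(min, max)` in body units.
#'   Default x in [-2, 2] shoulder-widths, y in [-1, 5] nose-neck units
#'   (head to waist, y downward). Frames outside are clipped to the border
#'   cell with a warning.
#' @param blur_sigma Gaussian sigma in cells; default `0.03125 * resolution_x`.
#' @param normalize_time divide each sign's deposits by its detected frame
#'   count (default TRUE); FALSE accumulates raw frame counts.
#' @return object of class `activity_grid`: matrices `left` and `right`
#'   (rows = y cells, cols = x cells), `bounds`, `resolution`, `blur_sigma`,
#'   `n_signs`.
#' @export
build_heatmap <- function(signs, resolution_x = 128,
                          bounds = list(x = c(-2, 2), y = c(-1, 5)),
                          blur_sigma = 0.03125 * resolution_x,
                          normalize_time = TRUE) {
  abort_if(length(signs) < 1, "need at least one trajectory")
  nx <- as.integer(resolution_x)
  ny <- as.integer(round(nx * diff(bounds$y) / diff(bounds$x)))
  accum <- list(left = matrix(0, ny, nx), right = matrix(0, ny, nx))
  clipped <- 0L
  for (traj in signs) {
    w <- 1
    if (normalize_time) {
      nf <- sum(traj$left_detected) + sum(traj$right_detected)
      if (nf == 0L) next
      w <- 1 / nf
    }
    for (hand in c("left", "right")) {
      det <- traj[[paste0(hand, "_detected")]]
      if (!any(det)) next
      xy <- traj[[hand]][det, , drop = FALSE]
      ix <- floor((xy[, 1] - bounds$x[1]) / diff(bounds$x) * nx) + 1L
      iy <- floor((xy[, 2] - bounds$y[1]) / diff(bounds$y) * ny) + 1L
      out <- ix < 1L | ix > nx | iy < 1L | iy > ny
      clipped <- clipped + sum(out)
      ix <- pmin(pmax(ix, 1L), nx)
      iy <- pmin(pmax(iy, 1L), ny)
      for (k in seq_along(ix)) {
        accum[[hand]][iy[k], ix[k]] <- accum[[hand]][iy[k], ix[k]] + w
      }
    }
  }
  if (clipped > 0L) {
    warning(sprintf("%d frame(s) outside heatmap bounds, clipped to border", clipped),
            call. = FALSE)
  }
  n <- length(signs)
  grid <- list(left = gaussian_blur(accum$left / n, blur_sigma),
               right = gaussian_blur(accum$right / n, blur_sigma))
  structure(list(left = grid$left, right = grid$right, bounds = bounds,
                 resolution = c(x = nx, y = ny), blur_sigma = blur_sigma,
                 n_signs = n),
            class = "activity_grid")
}

#' Separable Gaussian blur of a matrix
#'
#' 2D convolution with an isotropic Gaussian kernel of standard deviation
#' `sigma` cells, truncated at 4 sigma and normalized to unit sum. At the
#' matrix border the out-of-range kernel tail is dropped (not renormalized),
#' so total mass is conserved only for deposits at least ~4 sigma from the
#' border.
#'
#' @param m numeric matrix.
#' @param sigma standard deviation in cells; `sigma <= 0` returns `m`.
#' @return blurred matrix of the same shape.
#' @export
gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- ceiling(4 * sigma)
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  conv1 <- function(v) {
    n <- length(v)
    out <- numeric(n)
    nz <- which(v != 0)
    for (i in nz) {
      lo <- max(1L, i - r); hi <- min(n, i + r)
      idx <- lo:hi
      out[idx] <- out[idx] + v[i] * k[idx - i + r + 1L]
    }
    out
  }
  tmp <- apply(m, 2, conv1)          # blur columns (y direction)
  t(apply(tmp, 1, conv1))            # then rows (x direction)
}

#' @export
print.activity_grid <- function(x, ...) {
  cat(sprintf("<activity_grid> %d x %d cells, blur sigma %.2f, %d sign(s), total mass L %.3f / R %.3f\n",
              x$resolution["x"], x$resolution["y"], x$blur_sigma, x$n_signs,
              sum(x$left), sum(x$right)))
  invisible(x)
}

#' Write an activity grid as dense numeric matrices
#'
#' Emits `<stem>_left.csv` and `<stem>_right.csv` (no headers, one row per
#' y cell).
#'
#' @param grid an `activity_grid`.
#' @param stem output path stem.
#' @return the two paths, invisibly.
#' @export
write_grid <- function(grid, stem) {
  paths <- c(paste0(stem, "_left.csv"), paste0(stem, "_right.csv"))
  utils::write.table(grid$left, paths[1], row.names = FALSE, col.names = FALSE,
                     sep = ",")
  utils::write.table(grid$right, paths[2], row.names = FALSE, col.names = FALSE,
                     sep = ",")
  invisible(paths)
}

#' Export an activity grid as a PNG image
#'
#' Left-hand activity is rendered in blue, right-hand in red, on a white
#' background; intensity is scaled to the joint maximum of both grids.
#' Requires a PNG-capable graphics device.
#'
#' @param grid an `activity_grid`.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_heatmap_png <- function(grid, path) {
  if (!capabilities("png")) {
    stop("this R build has no PNG device; use write_grid() instead", call. = FALSE)
  }
  mx <- max(grid$left, grid$right, 1e-12)
  L <- pmin(grid$left / mx, 1)
  R <- pmin(grid$right / mx, 1)
  # white background; left tints toward blue (drops red+green), right toward
  # red (drops green+blue); overlap darkens toward purple
  img <- array(1, dim = c(nrow(L), ncol(L), 3))
  img[, , 1] <- 1 - L
  img[, , 2] <- 1 - pmin(L + R, 1)
  img[, , 3] <- 1 - R
  grDevices::png(path, width = ncol(L), height = nrow(L))
  op <- graphics::par(mar = c(0, 0, 0, 0))
  on.exit({ graphics::par(op); grDevices::dev.off() }, add = TRUE)
  graphics::plot.new()
  graphics::rasterImage(img, 0, 0, 1, 1, interpolate = FALSE)
  invisible(path)
}
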