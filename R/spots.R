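# Dilution spot-assay image quantification: grid split of a plate
# photograph, per-spot particle analysis with a minimum-area threshold, and
# replicate summaries with a rendered composite. Images are numeric matrices
# of 8-bit gray levels (0-255), row = image row. Grid cells are half-open
# [y0, y1) x [x0, x1) pixel intervals with 0-based coordinates.

#' Attach a grid specification to a plate image
#'
#' Tiles the analysis region into `n_rows x n_cols` non-overlapping cells
#' (one strain per grid row, one dilution per grid column).
#'
#' @param image numeric matrix, gray levels in `[0, 255]`.
#' @param n_rows,n_cols grid dimensions.
#' @param region optional `c(y0, y1, x0, x1)` 0-based half-open bounds of the
#'   analysis region (default: the full image).
#' @return object of class `spot_plate` with elements `image` and `grid`
#'   (data.frame `row`, `col`, `y0`, `y1`, `x0`, `x1`).
#' @export
spot_plate <- function(image, n_rows, n_cols, region = NULL) {
  if (!is.matrix(image) || !is.numeric(image)) stop_config("'image' must be a numeric matrix")
  if (n_rows < 1L || n_cols < 1L) stop_config("grid dimensions must be >= 1")
  if (is.null(region)) region <- c(0L, nrow(image), 0L, ncol(image))
  if (region[1L] < 0 || region[3L] < 0 ||
      region[2L] > nrow(image) || region[4L] > ncol(image) ||
      region[2L] <= region[1L] || region[4L] <= region[3L])
    stop_config("grid region falls outside the image bounds")
  yb <- round(seq(region[1L], region[2L], length.out = n_rows + 1L))
  xb <- round(seq(region[3L], region[4L], length.out = n_cols + 1L))
  if (any(diff(yb) <= 0) || any(diff(xb) <= 0))
    stop_config("grid cells would be empty or overlap; use fewer cells")
  grid <- expand.grid(row = seq_len(n_rows), col = seq_len(n_cols))
  grid <- grid[order(grid$row, grid$col), ]
  grid$y0 <- yb[grid$row]; grid$y1 <- yb[grid$row + 1L]
  grid$x0 <- xb[grid$col]; grid$x1 <- xb[grid$col + 1L]
  rownames(grid) <- NULL
  structure(list(image = image, grid = grid), class = "spot_plate")
}

#' Split a gridded plate image into per-spot sub-images
#'
#' Lossless pixel copy of each grid cell.
#'
#' @param plate a [spot_plate()].
#' @return list of sub-image matrices, named `"r<row>c<col>"`.
#' @export
split_grid <- function(plate) {
  stopifnot(inherits(plate, "spot_plate"))
  g <- plate$grid
  out <- lapply(seq_len(nrow(g)), function(i) {
    plate$image[(g$y0[i] + 1L):g$y1[i], (g$x0[i] + 1L):g$x1[i], drop = FALSE]
  })
  names(out) <- sprintf("r%dc%d", g$row, g$col)
  out
}

#' Otsu threshold of an 8-bit image
#'
#' Maximizes the between-class variance over the 256-bin gray-level
#' histogram; pixels strictly above the returned level are foreground.
#'
#' @param img numeric matrix of gray levels in `[0, 255]`.
#' @return threshold gray level.
#' @export
otsu_threshold <- function(img) {
  h <- tabulate(pmin(pmax(floor(img), 0), 255) + 1L, nbins = 256L)
  w <- h / sum(h)
  lev <- 0:255
  omega <- cumsum(w)
  mu <- cumsum(w * lev)
  mu_t <- mu[256L]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  # all thresholds on the plateau are equivalent; take its midpoint
  best <- lev[sigma_b >= max(sigma_b) - 1e-12]
  floor(mean(range(best)))
}

# 8-connected component labeling via a pixel adjacency graph
label_components <- function(binary) {
  fg <- which(binary)
  if (!length(fg)) return(list(sizes = integer(0), labels = integer(0)))
  nr <- nrow(binary)
  nc <- ncol(binary)
  row_i <- (fg - 1L) %% nr + 1L
  col_i <- (fg - 1L) %/% nr + 1L
  inside <- matrix(FALSE, nr, nc)
  inside[fg] <- TRUE
  edges <- list()
  k <- 0L
  for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    r2 <- row_i + off[1L]; c2 <- col_i + off[2L]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    ok[ok] <- inside[cbind(r2[ok], c2[ok])]
    if (any(ok)) {
      k <- k + 1L
      edges[[k]] <- cbind(fg[ok], (c2[ok] - 1L) * nr + r2[ok])
    }
  }
  id <- match(fg, fg)  # 1..length(fg)
  if (k) {
    e <- do.call(rbind, edges)
    g <- igraph::graph_from_edgelist(
      cbind(match(e[, 1L], fg), match(e[, 2L], fg)), directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, length(fg) - igraph::vcount(g)))
    comp <- igraph::components(g)
    list(sizes = as.integer(comp$csize), labels = comp$membership)
  } else {
    list(sizes = rep(1L, length(fg)), labels = seq_along(fg))
  }
}

#' Measure one spot sub-image
#'
#' Binarizes the sub-image (Otsu threshold by default), labels 8-connected
#' foreground components, and reports the largest component's pixel area when
#' it reaches `min_area`; otherwise the cell counts as empty (`detected =
#' FALSE`, area 0). The mean intensity is the arithmetic mean over the whole
#' sub-image histogram by default, or over the particle mask with
#' `intensity_on = "mask"`.
#'
#' A near-uniform sub-image (gray-level range below `min_contrast`) is
#' treated as blank without thresholding, since a data-driven threshold on
#' pure background noise is meaningless.
#'
#' @param img sub-image matrix (gray levels 0-255).
#' @param threshold fixed binarization level; `NULL` (default) for per-image
#'   Otsu.
#' @param min_area minimum particle area in px^2 (default 100).
#' @param intensity_on `"image"` (default) or `"mask"`.
#' @param min_contrast blank guard on the gray-level range (default 8).
#' @return data.frame row (class `spot_measurement`): `area`,
#'   `mean_intensity`, `detected`, `threshold`.
#' @export
measure_spot <- function(img, threshold = NULL, min_area = 100,
                         intensity_on = c("image", "mask"), min_contrast = 8) {
  if (!is.matrix(img) || !length(img)) stop_config("sub-image must be a nonempty matrix")
  intensity_on <- match.arg(intensity_on)
  rng <- diff(range(img))
  if (rng < min_contrast) {
    thr <- NA_real_
    area <- 0L
    detected <- FALSE
    mask <- NULL
  } else {
    thr <- if (is.null(threshold)) otsu_threshold(img) else threshold
    binary <- img > thr
    comp <- label_components(binary)
    if (length(comp$sizes) && max(comp$sizes) >= min_area) {
      area <- max(comp$sizes)
      detected <- TRUE
      lead <- which.max(comp$sizes)
      mask <- matrix(FALSE, nrow(img), ncol(img))
      mask[which(binary)[comp$labels == lead]] <- TRUE
    } else {
      area <- 0L
      detected <- FALSE
      mask <- NULL
    }
  }
  mi <- if (intensity_on == "mask" && !is.null(mask)) mean(img[mask]) else mean(img)
  structure(data.frame(area = as.numeric(area), mean_intensity = mi,
                       detected = detected, threshold = thr),
            class = c("spot_measurement", "data.frame"))
}

#' Measure every cell of a gridded plate
#'
#' @param plate a [spot_plate()].
#' @param ... passed to [measure_spot()].
#' @return data.frame with one row per grid cell: `row`, `col`, `area`,
#'   `mean_intensity`, `detected`, `threshold`.
#' @export
analyze_plate <- function(plate, ...) {
  subs <- split_grid(plate)
  g <- plate$grid
  res <- do.call(rbind, lapply(subs, measure_spot, ...))
  cbind(g[, c("row", "col")], res, row.names = NULL)
}

#' Summarize spot measurements across replicate plates
#'
#' @param measurements data.frame of stacked [analyze_plate()] outputs
#'   (columns `row`, `col`, `area`, `mean_intensity`).
#' @return data.frame per (row, col): `mean_area`, `mean_intensity`,
#'   `n_replicates`.
#' @export
summarize_plate <- function(measurements) {
  need <- c("row", "col", "area", "mean_intensity")
  if (length(setdiff(need, names(measurements))))
    stop_config("measurements need columns: ", paste(need, collapse = ", "))
  key <- interaction(measurements$row, measurements$col, drop = TRUE)
  out <- do.call(rbind, lapply(split(measurements, key), function(d) {
    data.frame(row = d$row[1L], col = d$col[1L],
               mean_area = mean(d$area),
               mean_intensity = mean(d$mean_intensity),
               n_replicates = nrow(d))
  }))
  out <- out[order(out$row, out$col), ]
  rownames(out) <- NULL
  out
}

#' Render a composite image from plate summaries
#'
#' Draws, on a white background, one disk per grid cell with radius
#' `round(sqrt(mean_area / pi))` and gray level `mean_intensity`, visually
#' summarizing replicate plates.
#'
#' @param summary output of [summarize_plate()].
#' @param cell_size cell edge in pixels (default 100).
#' @param background background gray level (default 255).
#' @return numeric image matrix (0-255).
#' @export
compose_plate_image <- function(summary, cell_size = 100, background = 255) {
  n_rows <- max(summary$row); n_cols <- max(summary$col)
  img <- matrix(background, n_rows * cell_size, n_cols * cell_size)
  for (i in seq_len(nrow(summary))) {
    if (summary$mean_area[i] <= 0) next
    r <- round(sqrt(summary$mean_area[i] / pi))
    cy <- (summary$row[i] - 0.5) * cell_size
    cx <- (summary$col[i] - 0.5) * cell_size
    img <- draw_disk(img, cy, cx, r, summary$mean_intensity[i])
  }
  img
}

# paint a filled disk onto an image matrix (pixel centers at k - 0.5)
draw_disk <- function(img, cy, cx, radius, value) {
  ys <- max(1L, floor(cy - radius)):min(nrow(img), ceiling(cy + radius) + 1L)
  xs <- max(1L, floor(cx - radius)):min(ncol(img), ceiling(cx + radius) + 1L)
  dy <- (ys - 0.5) - cy
  dx <- (xs - 0.5) - cx
  inside <- outer(dy^2, dx^2, "+") <= radius^2
  block <- img[ys, xs, drop = FALSE]
  block[inside] <- value
  img[ys, xs] <- block
  img
}

#' Convert an RGB array to 8-bit grayscale by luminance
#'
#' `0.299 R + 0.587 G + 0.114 B`.
#'
#' @param rgb numeric array `height x width x 3` with values in `[0, 255]`.
#' @return grayscale matrix.
#' @export
rgb_to_gray <- function(rgb) {
  if (length(dim(rgb)) != 3L || dim(rgb)[3L] < 3L)
    stop_config("expected a height x width x 3 array")
  0.299 * rgb[, , 1L] + 0.587 * rgb[, , 2L] + 0.114 * rgb[, , 3L]
}
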