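#' Locate the spot grid on a chip image via its corner markers
#'
#' Thresholds the image at half its maximum, labels the bright connected
#' components, assigns one blob to each image corner, and fits an affine map
#' from grid (row, col) coordinates to pixel coordinates through the four
#' marker centroids. All spot centers are then predicted from the fit.
#'
#' @param image a \code{\link{ChipImage}}.
#' @param layout a \code{\link{ChipLayout}}.
#' @param max_residual marker-fit residual (pixels) above which all spots
#'   are flagged \code{weak-marker}.
#' @return data.frame \code{spot_index}, \code{y}, \code{x} (0-based pixel
#'   coordinates) with attributes \code{residual} and \code{weak_marker}.
#' @export
locateGrid <- function(image, layout, max_residual = 2) {
  px <- pixelMatrix(image)
  ny <- nrow(px) - 1; nx <- ncol(px) - 1
  corners_px <- rbind(c(0, 0), c(0, nx), c(ny, 0), c(ny, nx))
  ## progressively lower the intensity threshold until four distinct blobs
  ## can be assigned to the image corners (a single saturated gel spot must
  ## not be allowed to swamp the markers)
  found <- NULL
  for (frac in c(0.5, 0.25, 0.125)) {
    mask <- px > frac * max(px)
    lab <- EBImage::bwlabel(mask)
    nblob <- max(lab)
    if (nblob < 4L) next
    idx <- which(lab > 0, arr.ind = TRUE)
    labs <- lab[lab > 0]
    cy <- tapply(idx[, 1] - 1, labs, mean)
    cx <- tapply(idx[, 2] - 1, labs, mean)
    keep <- tabulate(labs, nblob) >= 5L
    if (sum(keep) < 4L) next
    cy <- cy[keep]; cx <- cx[keep]
    pick <- apply(corners_px, 1, function(p)
      which.min((cy - p[1])^2 + (cx - p[2])^2))
    if (length(unique(pick)) == 4L) {
      found <- list(cy = cy, cx = cx, pick = pick)
      break
    }
  }
  if (is.null(found))
    stop("grid failure: could not detect four distinct corner markers")
  cy <- found$cy; cx <- found$cx; pick <- found$pick
  s <- layoutSpots(layout)
  corner_grid <- rbind(c(1, 1), c(1, layout@grid_cols),
                       c(layout@grid_rows, 1),
                       c(layout@grid_rows, layout@grid_cols))
  fit <- data.frame(row = corner_grid[, 1], col = corner_grid[, 2],
                    y = cy[pick], x = cx[pick])
  my <- stats::lm(y ~ row + col, data = fit)
  mx <- stats::lm(x ~ row + col, data = fit)
  residual <- max(sqrt(stats::residuals(my)^2 + stats::residuals(mx)^2))
  pred <- data.frame(row = s$row, col = s$col)
  centers <- data.frame(spot_index = s$spot_index,
                        y = as.numeric(stats::predict(my, pred)),
                        x = as.numeric(stats::predict(mx, pred)))
  attr(centers, "residual") <- residual
  attr(centers, "weak_marker") <- residual > max_residual
  centers
}

## Dark current: metadata when available, else the mean of the darkest 1%
## of pixels (dark current is a camera property, not a spot property).
darkCurrent <- function(image) {
  i0 <- imageMeta(image)$dark_current
  if (!is.null(i0) && !is.na(i0)) return(i0)
  px <- sort(as.numeric(pixelMatrix(image)))
  mean(px[seq_len(max(1L, ceiling(length(px) * 0.01)))])
}

#' Quantify one spot
#'
#' Interior intensity \code{I_m} is the mean pixel value over the disk of
#' radius \code{0.6 * radius} around the center; background \code{B_m} is
#' the median over the annulus \code{1.2-1.8 * radius}, excluding pixels
#' lying inside a neighboring spot's nominal disk.
#'
#' @param image a \code{\link{ChipImage}}.
#' @param center numeric c(y, x), 0-based pixel coordinates.
#' @param radius nominal spot radius, pixels.
#' @param neighbor_centers optional matrix/data.frame of other spots'
#'   centers (columns y, x) whose interiors are masked out of the annulus.
#' @return list \code{I_m}, \code{B_m}, \code{saturated},
#'   \code{n_interior}, \code{n_annulus}.
#' @export
quantifySpot <- function(image, center, radius, neighbor_centers = NULL) {
  px <- pixelMatrix(image)
  cy <- center[1]; cx <- center[2]
  if (cy < 0 || cx < 0 || cy > nrow(px) - 1 || cx > ncol(px) - 1)
    return(list(I_m = NA_real_, B_m = NA_real_, saturated = FALSE,
                n_interior = 0L, n_annulus = 0L))
  win <- ceiling(1.8 * radius) + 1L
  ys <- max(0, floor(cy - win)):min(nrow(px) - 1, ceiling(cy + win))
  xs <- max(0, floor(cx - win)):min(ncol(px) - 1, ceiling(cx + win))
  d <- sqrt(outer((ys - cy)^2, (xs - cx)^2, "+"))
  vals <- px[ys + 1, xs + 1]
  interior <- d <= 0.6 * radius
  annulus <- d >= 1.2 * radius & d <= 1.8 * radius
  if (!is.null(neighbor_centers) && nrow(neighbor_centers) && any(annulus)) {
    for (j in seq_len(nrow(neighbor_centers))) {
      dn <- sqrt(outer((ys - neighbor_centers[j, 1])^2,
                       (xs - neighbor_centers[j, 2])^2, "+"))
      annulus <- annulus & dn > radius
    }
  }
  if (!any(annulus))
    stop("background undefined: annulus fully overlapped by neighbors")
  mxv <- 2^imageMeta(image)$bit_depth - 1
  list(I_m = mean(vals[interior]), B_m = median(vals[annulus]),
       saturated = mean(vals[interior] >= mxv) > 0.01,
       n_interior = sum(interior), n_annulus = sum(annulus))
}

#' Quantify every occupied spot of a chip image
#'
#' Locates the grid (unless centers are supplied) and quantifies each
#' occupied layout spot, producing a flat per-spot table in the style of
#' scanner quantification output, so that external quantifiers can
#' substitute for this step.
#'
#' @param image a \code{\link{ChipImage}}.
#' @param layout a \code{\link{ChipLayout}}.
#' @param centers optional center table from \code{\link{locateGrid}}.
#' @return data.frame with one row per occupied spot: \code{spot_index},
#'   \code{probe_id}, \code{role}, \code{group_id}, \code{I_m}, \code{B_m},
#'   \code{I0}, \code{qc_flags} (comma-joined, \code{""} when clean).
#' @export
quantifyChip <- function(image, layout, centers = NULL) {
  if (is.null(centers)) centers <- locateGrid(image, layout)
  weak <- isTRUE(attr(centers, "weak_marker"))
  s <- layoutSpots(layout)
  occ <- s[s$role != "empty", , drop = FALSE]
  ctr <- centers[match(occ$spot_index, centers$spot_index), ]
  i0 <- darkCurrent(image)
  ## only neighbors close enough to intrude into the annulus matter
  reach <- 1.8 * layout@radius + layout@radius + 1
  rows <- lapply(seq_len(nrow(occ)), function(i) {
    near <- centers$spot_index != occ$spot_index[i] &
      abs(centers$y - ctr$y[i]) <= reach & abs(centers$x - ctr$x[i]) <= reach
    nb <- as.matrix(centers[near, c("y", "x")])
    q <- quantifySpot(image, c(ctr$y[i], ctr$x[i]), layout@radius, nb)
    flags <- character(0)
    if (is.na(q$I_m)) flags <- c(flags, "off-grid")
    if (isTRUE(q$saturated)) flags <- c(flags, "saturated")
    if (!is.na(q$B_m) && q$B_m <= i0) flags <- c(flags, "low-background")
    if (weak) flags <- c(flags, "weak-marker")
    data.frame(spot_index = occ$spot_index[i], probe_id = occ$probe_id[i],
               role = occ$role[i], group_id = occ$group_id[i],
               I_m = q$I_m, B_m = q$B_m, I0 = i0,
               qc_flags = paste(flags, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "image_id") <- imageMeta(image)$sample_id
  out
}

#' Write / read a spot-quantification table (TSV)
#'
#' @param quant table from \code{\link{quantifyChip}}.
#' @param path TSV path.
#' @export
writeQuantTable <- function(quant, path) {
  write.table(quant, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeQuantTable
#' @export
readQuantTable <- function(path) {
  q <- read.delim(path, stringsAsFactors = FALSE)
  q$qc_flags[is.na(q$qc_flags)] <- ""
  q
}
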