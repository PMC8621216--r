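# shoelace area of a polygon given as an n x 2 (x, y) matrix
.polygonArea <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  n <- nrow(p)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

# proper-intersection test for two closed segments
.segmentsCross <- function(a, b, c, d) {
  orient <- function(p, q, r)
    sign((q[1] - p[1]) * (r[2] - p[2]) - (q[2] - p[2]) * (r[1] - p[1]))
  o1 <- orient(a, b, c); o2 <- orient(a, b, d)
  o3 <- orient(c, d, a); o4 <- orient(c, d, b)
  o1 != o2 && o3 != o4 && all(c(o1, o2, o3, o4) != 0)
}

# naive O(n^2) simplicity check over non-adjacent edges; mask polygons
# are small so this is cheap
.polygonIsSimple <- function(p) {
  n <- nrow(p)
  if (n < 3L) return(FALSE)
  edges <- cbind(seq_len(n), c(seq_len(n)[-1], 1L))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      shared <- length(intersect(edges[i, ], edges[j, ])) > 0
      if (shared) next
      if (.segmentsCross(p[edges[i, 1], ], p[edges[i, 2], ],
                         p[edges[j, 1], ], p[edges[j, 2], ]))
        return(FALSE)
    }
  }
  TRUE
}

#' Construct a beam mask
#'
#' @param polygon an `n x 2` matrix of ordered (x, y) vertices in pixel
#'   coordinates (x = column, y = row, origin top-left).
#' @param width,height dimensions of the images the mask applies to.
#' @return A [BeamMask-class].
#' @export
beamMask <- function(polygon, width, height) {
  colnames(polygon) <- c("x", "y")
  new("BeamMask", polygon = polygon, width = as.integer(width),
      height = as.integer(height))
}

#' Sector-shaped beam mask
#'
#' Builds the fan-shaped polygon of a phased-array scan matching the
#' phantom's sector geometry: two arcs (near and far field) joined by
#' the lateral sector edges.
#'
#' @param height,width image dimensions in pixels.
#' @param sectorAngle full sector opening angle, degrees.
#' @param nArc number of vertices used to discretize each arc.
#' @return A [BeamMask-class].
#' @examples
#' m <- sectorBeamMask(128, 128)
#' mean(maskMatrix(m))
#' @export
sectorBeamMask <- function(height, width, sectorAngle = 70, nArc = 40L) {
  apexRow <- -0.15 * height
  apexCol <- (width + 1) / 2
  a <- sectorAngle * pi / 180
  rmin <- 0.05 * height - apexRow
  rmax <- 1.02 * height - apexRow
  th <- seq(-a / 2, a / 2, length.out = nArc)
  near <- cbind(x = apexCol + rmin * sin(th), y = apexRow + rmin * cos(th))
  far <- cbind(x = apexCol + rmax * sin(rev(th)),
               y = apexRow + rmax * cos(rev(th)))
  beamMask(rbind(near, far), width, height)
}

#' Rasterize a beam mask
#'
#' @param mask a [BeamMask-class].
#' @return A logical `height x width` matrix, TRUE inside the polygon.
#' @export
maskMatrix <- function(mask) {
  H <- mask@height; W <- mask@width
  rows <- matrix(seq_len(H), H, W)
  cols <- matrix(seq_len(W), H, W, byrow = TRUE)
  inside <- pracma::inpolygon(as.vector(cols), as.vector(rows),
                              mask@polygon[, 1], mask@polygon[, 2],
                              boundary = TRUE)
  matrix(inside, H, W)
}

#' Zero everything outside the ultrasound sector
#'
#' Sets pixels outside the mask polygon to 0 and leaves pixels inside
#' unchanged, i.e. strips screen furniture (logos, markers, scales)
#' from a raw frame. Idempotent.
#'
#' @param frame a [LUSFrame-class], numeric matrix, or `H x W x N` array.
#' @param mask a [BeamMask-class] with matching dimensions.
#' @return The masked object, same type as the input.
#' @examples
#' m <- sectorBeamMask(64, 64)
#' x <- matrix(1, 64, 64)
#' sum(applyMask(x, m) == 0) > 0
#' @export
applyMask <- function(frame, mask) {
  stopifnot(is(mask, "BeamMask"))
  mm <- maskMatrix(mask)
  zero <- function(px) {
    if (nrow(px) != mask@height || ncol(px) != mask@width)
      stop("mask dimensions (", mask@height, " x ", mask@width,
           ") do not match the image (", nrow(px), " x ", ncol(px), ")")
    px[!mm] <- 0
    px
  }
  if (is(frame, "LUSFrame")) {
    frame@pixels <- zero(frame@pixels)
    frame
  } else if (is.matrix(frame)) {
    zero(frame)
  } else if (is.array(frame) && length(dim(frame)) == 3L) {
    for (i in seq_len(dim(frame)[3])) frame[, , i] <- zero(frame[, , i])
    frame
  } else stop("frame must be a matrix, 3-D array or LUSFrame")
}

#' Serialize a beam mask to JSON
#'
#' @param mask a [BeamMask-class].
#' @param path output file.
#' @export
writeBeamMask <- function(mask, path) {
  jsonlite::write_json(list(width = mask@width, height = mask@height,
                            x = mask@polygon[, 1], y = mask@polygon[, 2]),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a beam mask from JSON
#'
#' @param path file written by [writeBeamMask()].
#' @return A [BeamMask-class].
#' @export
readBeamMask <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  beamMask(cbind(x = obj$x, y = obj$y), obj$width, obj$height)
}

#' Augmentation ranges
#'
#' Defaults follow common ultrasound training practice: rotation up to
#' 45 degrees either way, shifts up to 10% of each dimension,
#' magnification up to 10% in or out, one-sided counterclockwise shear
#' up to 10 degrees, horizontal reflection, and multiplicative
#' brightness change up to 30%.
#'
#' @param rotationMax,shiftMax,zoomMax,shearMax,horizontalFlip,brightnessMax
#'   see [AugmentationRanges-class].
#' @return An [AugmentationRanges-class].
#' @export
augmentationRanges <- function(rotationMax = 45, shiftMax = 0.10,
                               zoomMax = 0.10, shearMax = 10,
                               horizontalFlip = TRUE,
                               brightnessMax = 0.30) {
  new("AugmentationRanges", rotationMax = rotationMax, shiftMax = shiftMax,
      zoomMax = zoomMax, shearMax = shearMax,
      horizontalFlip = horizontalFlip, brightnessMax = brightnessMax)
}

# 3x3 homogeneous matrices for the affine pieces
.rotM <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}
.shiftM <- function(dx, dy) matrix(c(1, 0, 0, 0, 1, 0, dx, dy, 1), 3, 3)
.zoomM <- function(z) matrix(c(z, 0, 0, 0, z, 0, 0, 0, 1), 3, 3)
.shearM <- function(deg) {
  s <- tan(deg * pi / 180)
  matrix(c(1, 0, 0, s, 1, 0, 0, 0, 1), 3, 3)
}

# compose the sampled parameters into a single input->output affine map
# (applied about the image centre, in the order rotate, shift, zoom, shear)
.augmentAffine <- function(params, width, height) {
  C <- .shiftM((width + 1) / 2, (height + 1) / 2)
  Ci <- .shiftM(-(width + 1) / 2, -(height + 1) / 2)
  T <- .shiftM(params$shiftX, params$shiftY)
  M <- (C %*% .shearM(params$shear) %*% Ci) %*%
       (C %*% .zoomM(params$zoom) %*% Ci) %*%
       T %*%
       (C %*% .rotM(params$rotation) %*% Ci)
  M
}

#' Stochastic training-time augmentation of one frame
#'
#' Applies, in a fixed order, rotation, translation, zoom,
#' counterclockwise shear, optional horizontal reflection and a
#' multiplicative brightness change. The four geometric pieces are
#' composed into one affine map and resampled bilinearly in a single
#' pass (fill value 0 outside the canvas); output dimensions equal the
#' input's and intensities are clipped to \[0, 1\]. Parameters are drawn
#' from the current R random stream unless `params` is supplied, so a
#' fixed seed reproduces the augmentation exactly.
#'
#' @param frame a numeric matrix or [LUSFrame-class].
#' @param ranges an [AugmentationRanges-class].
#' @param params optional explicit parameter list (`rotation`, `shiftX`,
#'   `shiftY` in pixels, `zoom` factor, `shear` degrees, `flip` logical,
#'   `brightness` factor) overriding the random draw.
#' @return The augmented frame, same type and dimensions as the input.
#' @examples
#' x <- matrix(runif(64 * 64), 64, 64)
#' ident <- augmentationRanges(0, 0, 0, 0, FALSE, 0)
#' all.equal(augmentFrame(x, ident), x)
#' @export
augmentFrame <- function(frame, ranges = augmentationRanges(),
                         params = NULL) {
  px <- if (is(frame, "LUSFrame")) frame@pixels else frame
  H <- nrow(px); W <- ncol(px)
  if (is.null(params)) {
    params <- list(
      rotation = runif(1, -ranges@rotationMax, ranges@rotationMax),
      shiftX = runif(1, -ranges@shiftMax, ranges@shiftMax) * W,
      shiftY = runif(1, -ranges@shiftMax, ranges@shiftMax) * H,
      zoom = 1 + runif(1, -ranges@zoomMax, ranges@zoomMax),
      shear = runif(1, 0, ranges@shearMax),
      flip = ranges@horizontalFlip && runif(1) < 0.5,
      brightness = 1 + runif(1, -ranges@brightnessMax,
                             ranges@brightnessMax)
    )
  }
  geomIdentity <- params$rotation == 0 && params$shiftX == 0 &&
    params$shiftY == 0 && params$zoom == 1 && params$shear == 0
  out <- px
  if (!geomIdentity) {
    M <- .augmentAffine(params, W, H)
    # EBImage images index (x, y): transpose in, transpose out
    img <- EBImage::Image(t(px))
    warped <- EBImage::affine(img, m = t(M[1:2, , drop = FALSE]),
                              filter = "bilinear", bg.col = 0,
                              output.dim = c(W, H))
    out <- t(EBImage::imageData(warped))
  }
  if (isTRUE(params$flip)) out <- out[, rev(seq_len(W))]
  out <- pmin(pmax(out * params$brightness, 0), 1)
  if (is(frame, "LUSFrame")) { frame@pixels <- out; frame } else out
}
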