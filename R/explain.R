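#' Grad-CAM heatmap for one frame
#'
#' Gradient-weighted class activation mapping on the network's deepest
#' spatial feature maps (the last convolution of block 3, at 1/4 of the
#' input resolution). Channel weights are the spatially averaged
#' gradients of the target-class logit with respect to those maps;
#' because the head is global average pooling followed by a dense
#' layer, that gradient is the dense weight of the channel divided by
#' the map area. The map is the rectified weighted sum of the feature
#' maps, bilinearly upsampled to the input size and max-normalized to 1
#' whenever any activation is positive.
#'
#' @param model a trained [FrameClassifier-class].
#' @param frame a [LUSFrame-class] or numeric matrix at the model input
#'   size.
#' @param targetClass `"A"` or `"B"`; default is the model's predicted
#'   class for the frame.
#' @return A [Heatmap-class].
#' @export
gradCAM <- function(model, frame, targetClass = NULL) {
  stopifnot(is(model, "FrameClassifier"))
  px <- if (is(frame, "LUSFrame")) frame@pixels else frame
  stopifnot(is.matrix(px))
  x <- .asFrameArray(px, model@inputShape)
  px <- x[, , 1]
  ptr <- .liveNet(model)
  if (is.null(targetClass)) {
    p <- .cnn_forward(ptr, x)
    targetClass <- if (p[1, 2] > p[1, 1]) "B" else "A"
  }
  if (!targetClass %in% c("A", "B"))
    stop("targetClass must be 'A' or 'B'")
  clsIdx <- if (targetClass == "B") 2L else 1L
  A <- .cnn_block_activations(ptr, px)       # Ho x Wo x C, post-ReLU
  d <- dim(A)
  dense <- model@weights[[length(model@weights)]]$W   # C x nClasses
  alpha <- dense[, clsIdx] / (d[1] * d[2])   # d(logit)/d(GAP input)
  m <- matrix(matrix(A, d[1] * d[2], d[3]) %*% alpha, d[1], d[2])
  m <- pmax(m, 0)
  up <- EBImage::resize(EBImage::Image(t(m)), w = ncol(px), h = nrow(px))
  m <- pmax(t(EBImage::imageData(up)), 0)
  if (max(m) > 0) m <- m / max(m)
  new("Heatmap", importance = m, targetClass = targetClass)
}

#' Render a heatmap overlay
#'
#' Alpha-blends a colorized importance map over the grayscale frame.
#' The default `"paper"` convention maps the highest importance to blue
#' and the lowest to red; `"standard"` uses the usual jet ordering
#' (red = highest).
#'
#' @param frame grayscale matrix or [LUSFrame-class]; same size as the
#'   heatmap.
#' @param heatmap a [Heatmap-class].
#' @param convention `"paper"` (blue = highest) or `"standard"`.
#' @param alpha blend weight of the colour layer in \[0, 1\].
#' @param file optional PNG output path.
#' @return An `H x W x 3` RGB array on \[0, 1\], invisibly when `file`
#'   is written.
#' @export
renderOverlay <- function(frame, heatmap,
                          convention = c("paper", "standard"),
                          alpha = 0.45, file = NULL) {
  convention <- match.arg(convention)
  px <- if (is(frame, "LUSFrame")) frame@pixels else frame
  stopifnot(is(heatmap, "Heatmap"))
  imp <- heatmap@importance
  if (!all(dim(px) == dim(imp)))
    stop("frame and heatmap dimensions differ")
  ramp <- c("#7F0000", "#FF0000", "#FFFF00", "#00FF80", "#00FFFF",
            "#0000FF")                        # low -> high, paper style
  if (convention == "standard") ramp <- rev(ramp)
  cr <- colorRamp(ramp)
  rgbv <- cr(as.vector(imp)) / 255
  out <- array(0, c(dim(px), 3))
  w <- alpha * as.vector(imp > 0)             # zero heatmap: pure frame
  for (ch in 1:3)
    out[, , ch] <- (1 - w) * as.vector(px) + w * rgbv[, ch]
  out <- pmin(pmax(out, 0), 1)
  if (!is.null(file)) {
    png::writePNG(out, file)
    return(invisible(out))
  }
  out
}
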