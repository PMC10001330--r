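## Contrast-limited adaptive histogram equalization.
##
## The image is divided into a blockSize[1] x blockSize[2] grid of contextual
## blocks (after reflection padding so the grid divides evenly). Each block's
## histogram is clipped at clipLimit x (block_pixels / nBins); the clipped
## excess is redistributed uniformly in a single pass. Each block yields a CDF
## lookup table; pixels are mapped by bilinear interpolation between the
## tables of the four surrounding block centers.

## Mapping LUT for one block. counts: histogram over nBins bins of [0, 255].
## Returns the mapped intensity for each bin (length nBins), or NULL for the
## identity mapping (degenerate single-bin histogram: equalizing a constant
## region is undefined, and identity avoids brightness drift / guarantees
## idempotence on flat inputs).
claheBlockLUT <- function(counts, clipLimit, nBins) {
  npix <- sum(counts)
  if (sum(counts > 0) <= 1L) return(NULL)
  if (is.finite(clipLimit)) {
    ceilCount <- clipLimit * npix / nBins
    excess <- sum(pmax(counts - ceilCount, 0))
    counts <- pmin(counts, ceilCount) + excess / nBins
  }
  cdf <- cumsum(counts)
  cdfMin <- cdf[which(cdf > 0)[1]]
  if (npix - cdfMin <= 0) {
    # all mass below the first occupied bin: flat clipped histogram edge case
    return(seq(0, 255, length.out = nBins))
  }
  (cdf - cdfMin) / (npix - cdfMin) * 255
}

## Bin index (1-based) of intensities in [0, 255] for nBins bins.
claheBinIndex <- function(x, nBins) {
  pmin(nBins, pmax(1L, as.integer(floor(x / 256 * nBins)) + 1L))
}

## CLAHE on a single channel, values in [0, 255]. Returns same-size matrix.
claheChannel <- function(mat, clipLimit, blockSize, nBins) {
  h <- nrow(mat); w <- ncol(mat)
  gr <- blockSize[1]; gc <- blockSize[2]
  if (gr > h) stop("blockSize rows (", gr, ") exceed image height (", h, ")")
  if (gc > w) stop("blockSize cols (", gc, ") exceed image width (", w, ")")

  # reflection padding so the grid divides evenly
  bh <- ceiling(h / gr); bw <- ceiling(w / gc)
  ph <- bh * gr; pw <- bw * gc
  ridx <- c(seq_len(h), rev(seq_len(h)))[seq_len(ph)]
  cidx <- c(seq_len(w), rev(seq_len(w)))[seq_len(pw)]
  pm <- mat[ridx, cidx, drop = FALSE]

  bins <- matrix(claheBinIndex(pm, nBins), nrow(pm), ncol(pm))

  # per-block LUTs; identity blocks keep value-passthrough via NULL
  luts <- vector("list", gr * gc)
  for (br in seq_len(gr)) {
    for (bc in seq_len(gc)) {
      rows <- ((br - 1) * bh + 1):(br * bh)
      cols <- ((bc - 1) * bw + 1):(bc * bw)
      counts <- tabulate(bins[rows, cols], nbins = nBins)
      luts[(bc - 1) * gr + br] <- list(claheBlockLUT(counts, clipLimit, nBins))
    }
  }
  lutAt <- function(br, bc) luts[[(bc - 1) * gr + br]]
  mapPix <- function(br, bc, binv, rawv) {
    l <- lutAt(br, bc)
    if (is.null(l)) rawv else l[binv]
  }

  # bilinear interpolation between block-center mappings
  py <- matrix(rep(seq_len(nrow(pm)), times = ncol(pm)), nrow(pm))
  px <- matrix(rep(seq_len(ncol(pm)), each = nrow(pm)), nrow(pm))
  centersY <- (seq_len(gr) - 0.5) * bh
  centersX <- (seq_len(gc) - 0.5) * bw

  # fractional block coordinates, clamped to [1, g]
  fy <- (py - centersY[1]) / bh + 1
  fx <- (px - centersX[1]) / bw + 1
  fy <- pmin(pmax(fy, 1), gr)
  fx <- pmin(pmax(fx, 1), gc)
  y0 <- pmin(floor(fy), gr - ifelse(gr > 1, 1, 0)); y1 <- pmin(y0 + 1, gr)
  x0 <- pmin(floor(fx), gc - ifelse(gc > 1, 1, 0)); x1 <- pmin(x0 + 1, gc)
  wy <- fy - y0; wx <- fx - x0

  out <- matrix(0, nrow(pm), ncol(pm))
  for (br in seq_len(gr)) {
    for (bc in seq_len(gc)) {
      # pixels for which this block is one of the four neighbours contribute
      # weight (1-wy or wy) * (1-wx or wx); accumulate per corner role
      sel00 <- y0 == br & x0 == bc
      sel10 <- y1 == br & x0 == bc
      sel01 <- y0 == br & x1 == bc
      sel11 <- y1 == br & x1 == bc
      any00 <- any(sel00); any10 <- any(sel10)
      any01 <- any(sel01); any11 <- any(sel11)
      if (!(any00 || any10 || any01 || any11)) next
      l <- lutAt(br, bc)
      mapped <- if (is.null(l)) pm else matrix(l[bins], nrow(pm), ncol(pm))
      if (any00) out[sel00] <- out[sel00] +
        (1 - wy[sel00]) * (1 - wx[sel00]) * mapped[sel00]
      if (any10) out[sel10] <- out[sel10] +
        wy[sel10] * (1 - wx[sel10]) * mapped[sel10]
      if (any01) out[sel01] <- out[sel01] +
        (1 - wy[sel01]) * wx[sel01] * mapped[sel01]
      if (any11) out[sel11] <- out[sel11] +
        wy[sel11] * wx[sel11] * mapped[sel11]
    }
  }
  pmin(pmax(out[seq_len(h), seq_len(w), drop = FALSE], 0), 255)
}

#' CLAHE contrast enhancement of an image tile
#'
#' Applies contrast-limited adaptive histogram equalization. In the default
#' `lab_l` color mode the tile is converted to CIELAB, only the lightness
#' channel is equalized, and the result is converted back — preserving stain
#' hue, which matters for histopathology. `per_channel` mode equalizes each
#' RGB channel independently.
#'
#' @param tile an [ImageTile-class].
#' @param cfg a [ClaheConfig-class]; `clipLimit` is relative to the uniform
#'   histogram bin height and `blockSize` is the grid of contextual blocks.
#' @return the enhanced [ImageTile-class] (intensities remain in [0, 255]).
#' @examples
#' t <- generateTiles(1, size = 32, seed = 7)[[1]]
#' claheEnhance(t, claheConfig(clipLimit = 2, blockSize = c(2, 2)))
#' @export
claheEnhance <- function(tile, cfg = claheConfig()) {
  px <- tile@pixels
  h <- dim(px)[1]; w <- dim(px)[2]
  if (cfg@colorMode == "per_channel") {
    out <- px
    for (ch in 1:3)
      out[, , ch] <- claheChannel(px[, , ch], cfg@clipLimit, cfg@blockSize,
                                  cfg@nBins)
  } else {
    rgb <- cbind(as.vector(px[, , 1]), as.vector(px[, , 2]),
                 as.vector(px[, , 3])) / 255
    lab <- grDevices::convertColor(rgb, from = "sRGB", to = "Lab")
    lmat <- matrix(lab[, 1] / 100 * 255, h, w)
    leq <- claheChannel(lmat, cfg@clipLimit, cfg@blockSize, cfg@nBins)
    lab[, 1] <- as.vector(leq) / 255 * 100
    rgb2 <- grDevices::convertColor(lab, from = "Lab", to = "sRGB")
    rgb2 <- pmin(pmax(rgb2, 0), 1)
    out <- array(0, dim = dim(px))
    for (ch in 1:3) out[, , ch] <- matrix(rgb2[, ch] * 255, h, w)
  }
  imageTile(out, label = tile@label, sourceId = tile@sourceId)
}
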