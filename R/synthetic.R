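#' Default recipes for the five synthetic tile classes
#'
#' The five classes mimic the lung/colon histology taxonomy (two colon, three
#' lung categories). Classes are separated primarily by base stain color, with
#' class-specific nuclei densities and texture scales providing secondary
#' structure. Colors are loosely eosin-pink / hematoxylin-purple palettes;
#' they are cosmetic, not biologically calibrated.
#'
#' @return data.frame with one row per class: `class` (label), `r`, `g`, `b`
#'   (mean base color, 0-255), `blobDensity` (expected nuclei per tile),
#'   `textureScale` (spatial correlation length, pixels), `noiseSd` (additive
#'   Gaussian noise sd, intensity units).
#' @export
defaultTileRecipes <- function() {
  data.frame(
    class = c("Col_Ad", "Col_Be", "Lun_Ad", "Lun_Be", "Lun_SC"),
    r = c(190, 230, 150, 215, 120),
    g = c(120, 180, 130, 205, 90),
    b = c(170, 210, 200, 180, 160),
    blobDensity = c(40, 10, 30, 8, 50),
    textureScale = c(4, 8, 6, 10, 3),
    noiseSd = c(10, 10, 10, 10, 10),
    stringsAsFactors = FALSE
  )
}

## Smooth correlated texture: white noise blurred by a separable moving
## average of width ~ scale, then rescaled to sd 1.
correlatedTexture <- function(h, w, scale) {
  z <- matrix(rnorm(h * w), h, w)
  if (scale > 1) {
    k <- max(1L, as.integer(round(scale)))
    kern <- rep(1 / k, k)
    z <- apply(z, 2, function(col) stats::filter(col, kern, circular = TRUE))
    z <- t(apply(z, 1, function(row) stats::filter(row, kern, circular = TRUE)))
  }
  s <- stats::sd(z)
  if (s > 0) z <- z / s
  z
}

## Render anti-aliased dark elliptical "nuclei" onto a single channel
## multiplier field (values in (0, 1]; 1 = background untouched).
renderBlobs <- function(h, w, count) {
  field <- matrix(1, h, w)
  if (count < 1L) return(field)
  xs <- matrix(rep(seq_len(w), each = h), h, w)
  ys <- matrix(rep(seq_len(h), times = w), h, w)
  for (i in seq_len(count)) {
    cx <- runif(1, 1, w); cy <- runif(1, 1, h)
    a <- runif(1, 1.5, 4); b <- runif(1, 1.5, 4)
    th <- runif(1, 0, pi)
    dx <- xs - cx; dy <- ys - cy
    u <- (dx * cos(th) + dy * sin(th)) / a
    v <- (-dx * sin(th) + dy * cos(th)) / b
    d2 <- u^2 + v^2
    # soft edge (~1px) gives cheap anti-aliasing
    mask <- 1 / (1 + exp(-(d2 - 1) * 4))
    depth <- runif(1, 0.35, 0.6)
    field <- field * (mask + (1 - mask) * depth)
  }
  field
}

#' Generate labeled synthetic histology-like tiles
#'
#' Each tile is a class base-color field plus Poisson-count elliptical
#' nuclei-like blobs, spatially correlated texture, and clipped Gaussian
#' noise. A pure function of its arguments: the same seed reproduces the same
#' tiles.
#'
#' @param nPerClass tiles per class (>= 1).
#' @param size tile side length in pixels (>= 16).
#' @param recipes recipe data.frame as from [defaultTileRecipes()].
#' @param seed integer RNG seed.
#' @return list of [ImageTile-class], `nrow(recipes) * nPerClass` long,
#'   grouped by class.
#' @export
generateTiles <- function(nPerClass, size = 64L, recipes = defaultTileRecipes(),
                          seed = 1L) {
  stopifnot(nPerClass >= 1L, size >= 16L)
  withLocalSeed(seed, {
    tiles <- vector("list", nrow(recipes) * nPerClass)
    idx <- 1L
    for (ci in seq_len(nrow(recipes))) {
      rec <- recipes[ci, ]
      base <- c(rec$r, rec$g, rec$b)
      for (ti in seq_len(nPerClass)) {
        nBlobs <- if (rec$blobDensity > 0) rpois(1, rec$blobDensity) else 0L
        blobField <- renderBlobs(size, size, nBlobs)
        tex <- if (rec$noiseSd > 0 || rec$textureScale > 0)
          correlatedTexture(size, size, rec$textureScale) else matrix(0, size, size)
        px <- array(0, dim = c(size, size, 3))
        for (ch in 1:3) {
          plane <- base[ch] * blobField + 0.6 * rec$noiseSd * tex +
            rnorm(size * size, sd = rec$noiseSd)
          px[, , ch] <- pmin(255, pmax(0, plane))
        }
        tiles[[idx]] <- imageTile(px, label = rec$class,
                                  sourceId = sprintf("synthetic:%s:%03d", rec$class, ti))
        idx <- idx + 1L
      }
    }
    tiles
  })
}

#' Standard benchmark objectives for optimizer validation
#'
#' @param name one of "sphere", "rastrigin", "rosenbrock".
#' @param d dimension (>= 1).
#' @return list with `fn` (vector -> scalar), `space` (a
#'   [SearchSpace-class] with the conventional bounds), `xopt` (global
#'   minimizer) and `fopt` (its value, 0 for all three).
#' @export
benchmarkObjective <- function(name, d) {
  stopifnot(d >= 1L)
  known <- c("sphere", "rastrigin", "rosenbrock")
  if (!name %in% known)
    stop("unknown objective '", name, "'; options: ", paste(known, collapse = ", "))
  switch(name,
    sphere = list(
      fn = function(x) sum(x^2),
      space = searchSpace(rep(-10, d), rep(10, d)),
      xopt = rep(0, d), fopt = 0),
    rastrigin = list(
      fn = function(x) 10 * length(x) + sum(x^2 - 10 * cos(2 * pi * x)),
      space = searchSpace(rep(-5.12, d), rep(5.12, d)),
      xopt = rep(0, d), fopt = 0),
    rosenbrock = list(
      fn = function(x) {
        if (length(x) == 1L) return((1 - x)^2)
        sum(100 * (x[-1] - x[-length(x)]^2)^2 + (1 - x[-length(x)])^2)
      },
      space = searchSpace(rep(-5, d), rep(10, d)),
      xopt = rep(1, d), fopt = 0)
  )
}
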