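#' Load image tiles from per-class directories
#'
#' Expects `rootDir/<class>/<image>.png|jpg`; the parent directory name
#' becomes the tile label. Files are read in lexicographic order of their
#' full path, so the result is deterministic. Unreadable files are skipped
#' with a warning.
#'
#' @param rootDir directory containing one subdirectory per class.
#' @param pattern filename regular expression (default PNG/JPEG).
#' @return list of [ImageTile-class].
#' @export
loadTiles <- function(rootDir, pattern = "\\.(png|jpe?g)$") {
  if (!dir.exists(rootDir)) stop("directory not found: ", rootDir)
  files <- sort(list.files(rootDir, pattern = pattern, recursive = TRUE,
                           full.names = TRUE, ignore.case = TRUE))
  tiles <- list()
  for (f in files) {
    img <- tryCatch(EBImage::readImage(f), error = function(e) NULL)
    if (is.null(img)) {
      warning("skipping unreadable file: ", f)
      next
    }
    a <- EBImage::imageData(img)   # EBImage: x (width) first, values in [0,1]
    if (length(dim(a)) == 2L) a <- array(rep(a, 3), dim = c(dim(a), 3))
    if (dim(a)[3] > 3L) a <- a[, , 1:3, drop = FALSE]  # drop alpha
    px <- aperm(a, c(2, 1, 3)) * 255
    label <- basename(dirname(f))
    if (identical(normalizePath(dirname(f)), normalizePath(rootDir)))
      label <- NA_character_
    tiles[[length(tiles) + 1L]] <- imageTile(px, label = label, sourceId = f)
  }
  if (length(tiles) == 0L) stop("no images found under ", rootDir)
  tiles
}

#' Write tiles as PNG files in per-class subdirectories
#'
#' Produces the directory layout [loadTiles()] expects.
#'
#' @param tiles list of [ImageTile-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
writeTiles <- function(tiles, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(tiles))
  for (i in seq_along(tiles)) {
    t <- tiles[[i]]
    sub <- if (is.na(t@label)) "unlabeled" else t@label
    d <- file.path(dir, sub)
    dir.create(d, showWarnings = FALSE)
    paths[i] <- file.path(d, sprintf("tile_%04d.png", i))
    png::writePNG(t@pixels / 255, paths[i])
  }
  invisible(paths)
}

#' Extract the label of each tile
#' @param tiles list of [ImageTile-class].
#' @return character vector of labels.
#' @export
tileLabels <- function(tiles) {
  vapply(tiles, function(t) t@label, character(1))
}
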