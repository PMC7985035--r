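#' Read / write an 8-bit RGB image
#'
#' Thin wrappers over the png and tiff packages that present images to
#' the rest of the package as numeric `height x width x 3` arrays with
#' intensities on the 0--255 scale. Grayscale files are replicated to
#' three channels; an alpha channel is dropped.
#'
#' @param path file ending in .png, .tif or .tiff.
#' @return numeric array height x width x 3 in \[0, 255\].
#' @export
read_rgb_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext, " (PNG and TIFF supported)",
         call. = FALSE))
  if (length(dim(img)) == 2L) img <- array(img, dim = c(dim(img), 1L))
  if (dim(img)[3] == 1L) img <- img[, , c(1, 1, 1), drop = FALSE]
  if (dim(img)[3] >= 4L) img <- img[, , 1:3, drop = FALSE]
  img * 255
}

#' @rdname read_rgb_image
#' @param image numeric array height x width x 3, intensities in \[0, 255\].
#' @export
write_rgb_image <- function(image, path) {
  stopifnot(length(dim(image)) == 3L, dim(image)[3] == 3L)
  scaled <- pmin(pmax(image / 255, 0), 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(scaled, path),
    tif = ,
    tiff = tiff::writeTIFF(scaled, path, bits.per.sample = 8L),
    stop("unsupported image format: .", ext, call. = FALSE))
  invisible(path)
}

#' Tile an image and score tile densities
#'
#' Divides the image into non-overlapping `tile_size` x `tile_size`
#' tiles anchored at the top-left corner; partial tiles at the right and
#' bottom margins are discarded, so exactly
#' `floor(H/tile_size) * floor(W/tile_size)` tiles are produced. Each
#' tile's density is the sum of its red, green and blue values
#' (`mode = "sum"`). Taken literally on H&E slides this favours bright,
#' background-heavy tiles (tissue is darker than background);
#' `mode = "inverted-sum"` scores `sum(255 - value)` instead, favouring
#' tissue-dense tiles. The literal sum is the default.
#'
#' @param image numeric array height x width x 3, intensities \[0, 255\].
#' @param tile_size tile edge in pixels (default 1000).
#' @param mode `"sum"` (default) or `"inverted-sum"`.
#' @return data.frame with 0-based pixel origins `row`, `col` and
#'   `density`, in row-major tile order.
#' @export
tile_image <- function(image, tile_size = 1000, mode = c("sum",
                                                         "inverted-sum")) {
  mode <- match.arg(mode)
  stopifnot(length(dim(image)) == 3L, dim(image)[3] == 3L, tile_size >= 1)
  H <- dim(image)[1]; W <- dim(image)[2]
  nr <- H %/% tile_size; nc <- W %/% tile_size
  if (nr == 0 || nc == 0)
    stop("image (", H, "x", W, ") is smaller than one ", tile_size,
         "x", tile_size, " tile", call. = FALSE)
  grid <- expand.grid(tile_row = seq_len(nr) - 1L, tile_col = seq_len(nc) - 1L)
  grid <- grid[order(grid$tile_row, grid$tile_col), ]
  density <- mapply(function(tr, tc) {
    rows <- tr * tile_size + seq_len(tile_size)
    cols <- tc * tile_size + seq_len(tile_size)
    v <- image[rows, cols, ]
    if (mode == "sum") sum(v) else sum(255 - v)
  }, grid$tile_row, grid$tile_col)
  data.frame(row = grid$tile_row * tile_size, col = grid$tile_col * tile_size,
             density = density, row.names = NULL)
}

#' Select the densest tiles
#'
#' Keeps the `k` tiles with the highest density, sorted by decreasing
#' density; ties are broken by (row, col) origin so the selection is
#' deterministic. If fewer than `k` tiles exist, all are returned with a
#' warning.
#'
#' @param tiles data.frame from [tile_image()].
#' @param k number of tiles to keep (default 10).
#' @return data.frame of at most `k` rows.
#' @export
select_top_tiles <- function(tiles, k = 10) {
  stopifnot(k >= 1)
  if (nrow(tiles) == 0)
    stop("no tiles to select from", call. = FALSE)
  ord <- order(-tiles$density, tiles$row, tiles$col)
  if (nrow(tiles) < k) {
    warning("only ", nrow(tiles), " tiles available (k = ", k,
            "); returning all")
    k <- nrow(tiles)
  }
  out <- tiles[ord[seq_len(k)], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Channel-mean colour normalization against a reference image
#'
#' `channel_scale` computes per-channel scaling factors: the reference
#' image's mean red/green/blue intensity divided by the target image's.
#' `apply_channel_scale` multiplies each channel by its factor and clips
#' to \[0, 255\]; before clipping, the scaled image's channel means equal
#' the reference means exactly. Values stay in floating point.
#'
#' @param image,reference numeric arrays height x width x 3 in \[0, 255\].
#' @return for `channel_scale`, a named numeric vector `(r, g, b)` of
#'   strictly positive factors; for `apply_channel_scale`, the scaled
#'   image.
#' @export
channel_scale <- function(image, reference) {
  stopifnot(length(dim(image)) == 3L, length(dim(reference)) == 3L)
  m_img <- apply(image, 3, mean)
  m_ref <- apply(reference, 3, mean)
  if (any(m_img == 0))
    stop("target image has a zero-mean channel; cannot scale", call. = FALSE)
  if (any(m_ref == 0))
    stop("reference image has a zero-mean channel", call. = FALSE)
  stats::setNames(m_ref / m_img, c("r", "g", "b"))
}

#' @rdname channel_scale
#' @param scale factors from [channel_scale()].
#' @export
apply_channel_scale <- function(image, scale) {
  stopifnot(length(scale) == 3L, all(scale > 0))
  out <- image
  for (ch in 1:3) out[, , ch] <- image[, , ch] * scale[ch]
  pmin(pmax(out, 0), 255)
}

#' Aggregate per-tile feature tables to one patient-level vector
#'
#' A patient is represented by the features of several tiles (typically
#' the 10 densest); the patient-level value of each feature is its median
#' across tiles, with missing per-tile values excluded from that
#' feature's median.
#'
#' @param tables a list of single-tile feature tables (1-row data.frames
#'   or named vectors) sharing the same feature columns, or one
#'   data.frame / matrix with one row per tile.
#' @return named numeric vector, one value per feature.
#' @export
aggregate_tile_features <- function(tables) {
  if (is.list(tables) && !is.data.frame(tables)) {
    cols <- lapply(tables, function(t) colnames(as.data.frame(as.list(t))))
    ref <- cols[[1]]
    bad <- which(!vapply(cols, identical, logical(1), y = ref))
    if (length(bad))
      stop("tile tables disagree on feature columns (tables ",
           paste(bad, collapse = ", "), " differ from the first)",
           call. = FALSE)
    m <- do.call(rbind, lapply(tables, function(t)
      as.matrix(as.data.frame(as.list(t)))))
  } else {
    m <- as.matrix(tables)
  }
  apply(m, 2, stats::median, na.rm = TRUE)
}
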