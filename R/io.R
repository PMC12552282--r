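#' Build an ROI mask from a JSON geometry spec
#'
#' Reads a JSON ROI description and rasterizes it onto an image grid.
#' Supported geometries (coordinates are 1-based pixel centers, `cx`/`x`
#' along columns and `cy`/`y` along rows):
#' \describe{
#'   \item{circle}{`{"circle": {"cx": 64, "cy": 64, "r": 20}}` - pixels
#'     with center distance `<= r`.}
#'   \item{polygon}{`{"polygon": {"x": [...], "y": [...]}}` - even-odd
#'     point-in-polygon test on pixel centers.}
#'   \item{mask_csv}{`{"mask_csv": "mask.csv"}` - headerless 0/1 array of
#'     the image dimensions (path relative to the JSON file).}
#' }
#'
#' @param path JSON file path (or an already-parsed list).
#' @param dim integer vector `c(rows, cols)` of the target image.
#' @return Logical mask matrix.
#' @export
roi_mask_from_json <- function(path, dim) {
  spec <- if (is.character(path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else path
  base_dir <- if (is.character(path)) dirname(path) else "."
  n <- dim[1L]; m <- dim[2L]
  if (!is.list(spec) || !length(spec))
    stop("ROI spec must be a JSON object with one of: circle, polygon, mask_csv",
         call. = FALSE)
  kind <- intersect(names(spec), c("circle", "polygon", "mask_csv"))
  if (length(kind) != 1L)
    stop("ROI spec needs exactly one of the keys 'circle', 'polygon' or ",
         "'mask_csv'; got: ", paste(names(spec), collapse = ", "),
         call. = FALSE)
  if (kind == "circle") {
    g <- spec$circle
    for (f in c("cx", "cy", "r"))
      if (is.null(g[[f]]) || !is.numeric(g[[f]]))
        stop("ROI circle spec is missing numeric key '", f, "'",
             call. = FALSE)
    return((row(matrix(0, n, m)) - g$cy)^2 +
             (col(matrix(0, n, m)) - g$cx)^2 <= g$r^2)
  }
  if (kind == "polygon") {
    g <- spec$polygon
    if (is.null(g$x) || is.null(g$y) || length(g$x) != length(g$y) ||
        length(g$x) < 3L)
      stop("ROI polygon spec needs matching 'x' and 'y' arrays (>= 3 points)",
           call. = FALSE)
    return(point_in_polygon(n, m, as.numeric(g$x), as.numeric(g$y)))
  }
  mpath <- spec$mask_csv
  if (!file.exists(mpath)) mpath <- file.path(base_dir, spec$mask_csv)
  msk <- read_array(mpath)$pixels
  if (!identical(dim(msk), c(n, m)))
    stop("ROI mask_csv dimensions do not match the image", call. = FALSE)
  msk > 0.5
}

# Even-odd rule on pixel centers.
#' @noRd
point_in_polygon <- function(n, m, px, py) {
  rows <- as.vector(row(matrix(0, n, m)))
  cols <- as.vector(col(matrix(0, n, m)))
  inside <- rep(FALSE, n * m)
  j <- length(px)
  for (i in seq_along(px)) {
    crosses <- ((py[i] > rows) != (py[j] > rows)) &
      (cols < (px[j] - px[i]) * (rows - py[i]) / (py[j] - py[i]) + px[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  matrix(inside, n, m)
}

#' Write per-tissue quality results as CSV
#'
#' One row per ROI per tissue with the quality metrics and the analysis
#' parameters, the tabular output format of the `iq` pipeline.
#'
#' @param quality an object from [assess_roi()] or a list of them.
#' @param path output CSV path.
#' @param image_id,roi_id identifiers recorded in the rows.
#' @return The written data.frame, invisibly.
#' @export
write_quality_csv <- function(quality, path, image_id = "image",
                              roi_id = "roi") {
  if (inherits(quality, "roi_quality")) quality <- list(quality)
  rows <- do.call(rbind, lapply(seq_along(quality), function(i) {
    q <- quality[[i]]
    df <- as.data.frame(q)
    df <- cbind(image_id = image_id[min(i, length(image_id))],
                roi_id = roi_id[min(i, length(roi_id))], df)
    for (p in names(q$parameters)) df[[p]] <- q$parameters[[p]]
    df
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(rows)
}
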