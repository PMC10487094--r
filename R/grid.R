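#' Grid specification
#'
#' Describes a regular raster grid. Row 1 is the northernmost row; cell
#' \code{(i, j)} covers the half-open box
#' \code{[x_origin + (j-1)*s, x_origin + j*s) x (y_origin - i*s, y_origin - (i-1)*s]}
#' with \code{s = cell_size}, so a cell owns its top and left edges.
#'
#' Two coordinate modes are supported via \code{crs_tag}:
#' \describe{
#'   \item{\code{"equal-area-synthetic"}}{a flat grid in metres; cell areas
#'     are exact, \code{cell_size^2}.}
#'   \item{\code{"lonlat"}}{x = longitude, y = latitude in decimal degrees;
#'     cell areas are approximated with the standard cosine-of-latitude
#'     weighting on a sphere of radius 6371 km.}
#' }
#'
#' @param n_rows,n_cols positive integer grid dimensions.
#' @param x_origin,y_origin map coordinates of the top-left corner.
#' @param cell_size cell edge length (metres or degrees, by \code{crs_tag}).
#' @param crs_tag \code{"equal-area-synthetic"} or \code{"lonlat"}.
#' @return An object of class \code{grid_spec}.
#' @export
grid_spec <- function(n_rows, n_cols, x_origin = 0, y_origin = n_rows * cell_size,
                      cell_size = 1, crs_tag = "equal-area-synthetic") {
  stopifnot(n_rows >= 1, n_cols >= 1, cell_size > 0)
  crs_tag <- match.arg(crs_tag, c("equal-area-synthetic", "lonlat"))
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 x_origin = as.numeric(x_origin), y_origin = as.numeric(y_origin),
                 cell_size = as.numeric(cell_size), crs_tag = crs_tag),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells, cell_size %g, origin (%g, %g), crs %s\n",
              x$n_rows, x$n_cols, x$cell_size, x$x_origin, x$y_origin, x$crs_tag))
  invisible(x)
}

#' @export
all.equal.grid_spec <- function(target, current, ...) {
  all.equal(unclass(target), unclass(current), ...)
}

grids_identical <- function(a, b) {
  isTRUE(all.equal(a, b, tolerance = 1e-12))
}

#' Cell-centre coordinates
#'
#' @param grid a [grid_spec()].
#' @return `cell_centers_x`: numeric vector of length `n_cols`;
#'   `cell_centers_y`: numeric vector of length `n_rows` (row 1 = north).
#' @export
cell_centers_x <- function(grid) grid$x_origin + (seq_len(grid$n_cols) - 0.5) * grid$cell_size

#' @rdname cell_centers_x
#' @export
cell_centers_y <- function(grid) grid$y_origin - (seq_len(grid$n_rows) - 0.5) * grid$cell_size

#' Map coordinates to (row, col) indices
#'
#' Points outside the grid get NA. Top/left edges belong to the cell
#' (half-open convention).
#'
#' @param grid a [grid_spec()].
#' @param x,y numeric coordinate vectors.
#' @return data.frame with integer columns `row`, `col` (NA outside grid).
#' @export
point_to_cell <- function(grid, x, y) {
  s <- grid$cell_size
  col <- floor((x - grid$x_origin) / s) + 1
  row <- floor((grid$y_origin - y) / s) + 1
  # bottom edge of the last row / right edge of the last column are outside
  bad <- col < 1 | col > grid$n_cols | row < 1 | row > grid$n_rows
  col[bad] <- NA_integer_
  row[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' Raster object
#'
#' A single-band raster: a value matrix on a [grid_spec()] plus a nodata
#' mask. `kind` is one of `"continuous"` (suitability in \[0,1\] or any real
#' field), `"binary"` (0/1) or `"categorical"` (integer class codes).
#'
#' @param grid a [grid_spec()].
#' @param values numeric matrix `n_rows x n_cols` (row 1 = north).
#' @param nodata_mask logical matrix, `TRUE` where the cell carries no data.
#' @param kind `"continuous"`, `"binary"` or `"categorical"`.
#' @return Object of class `hs_raster`.
#' @export
make_raster <- function(grid, values, nodata_mask = NULL, kind = "continuous") {
  kind <- match.arg(kind, c("continuous", "binary", "categorical"))
  values <- as.matrix(values)
  if (!identical(dim(values), c(grid$n_rows, grid$n_cols)))
    stop("values must be a ", grid$n_rows, " x ", grid$n_cols, " matrix")
  if (is.null(nodata_mask)) nodata_mask <- is.na(values)
  nodata_mask <- nodata_mask | is.na(values)
  if (kind == "binary") {
    v <- values[!nodata_mask]
    if (length(v) && !all(v %in% c(0, 1)))
      stop("binary raster contains values other than 0/1")
  }
  if (kind == "categorical") {
    v <- values[!nodata_mask]
    if (length(v) && any(v != round(v)))
      stop("categorical raster contains non-integer codes")
    values[] <- round(values)
  }
  structure(list(grid = grid, values = values,
                 nodata_mask = nodata_mask, kind = kind),
            class = "hs_raster")
}

#' @export
print.hs_raster <- function(x, ...) {
  v <- x$values[!x$nodata_mask]
  cat(sprintf("<hs_raster %s> %d x %d, %d nodata, range [%g, %g]\n", x$kind,
              x$grid$n_rows, x$grid$n_cols, sum(x$nodata_mask),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
  invisible(x)
}

#' Read / write rasters as extended ASCII grids
#'
#' The on-disk format is the ESRI ASCII grid (keys `ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`, then `nrows` lines of
#' `ncols` values, northernmost row first) extended with two extra header
#' keys, `kind` and `crs`, so that the full raster object round-trips.
#' Values are written with 17 significant digits; `read_raster(write_raster(r))`
#' reproduces values, mask and grid bit-exactly. Files whose data section
#' holds a whole multiple k > 1 of `nrows * ncols` values are rejected as
#' multi-band with the band count named.
#'
#' @param path file path.
#' @param raster an `hs_raster`.
#' @param nodata_value sentinel written for nodata cells.
#' @return `read_raster`: an `hs_raster`; `write_raster`: `path`, invisibly.
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) stop("cannot read raster: no such file: ", path)
  lines <- readLines(path)
  hdr <- list(kind = "continuous", crs = "equal-area-synthetic",
              NODATA_value = -9999)
  i <- 1
  while (i <= length(lines) && grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    val <- if (kv[1] %in% c("kind", "crs")) kv[2] else as.numeric(kv[2])
    hdr[[kv[1]]] <- val
    i <- i + 1
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("not an ASCII grid: missing header keys: ",
         paste(setdiff(need, names(hdr)), collapse = ", "))
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc) {
    if (length(vals) %% (nr * nc) == 0)
      stop("multi-band input not supported: file contains ",
           length(vals) %/% (nr * nc), " bands")
    stop("data section has ", length(vals), " values, expected ", nr * nc)
  }
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  mask <- m == hdr$NODATA_value
  m[mask] <- NA
  grid <- grid_spec(nr, nc, x_origin = hdr$xllcorner,
                    y_origin = hdr$yllcorner + nr * hdr$cellsize,
                    cell_size = hdr$cellsize, crs_tag = hdr$crs)
  make_raster(grid, m, mask, kind = hdr$kind)
}

#' @rdname read_raster
#' @export
write_raster <- function(raster, path, nodata_value = -9999) {
  g <- raster$grid
  v <- raster$values
  v[raster$nodata_mask] <- nodata_value
  fmt <- function(x) sprintf("%.17g", x)
  hdr <- c(paste("ncols", g$n_cols), paste("nrows", g$n_rows),
           paste("xllcorner", fmt(g$x_origin)),
           paste("yllcorner", fmt(g$y_origin - g$n_rows * g$cell_size)),
           paste("cellsize", fmt(g$cell_size)),
           paste("NODATA_value", fmt(nodata_value)),
           paste("kind", raster$kind), paste("crs", g$crs_tag))
  body <- apply(v, 1, function(r) paste(fmt(r), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Nearest-neighbour resampling
#'
#' Each target cell takes the value of the source cell containing its
#' centre (half-open edge convention); target cells whose centre falls
#' outside the source extent become nodata. `kind` is preserved, so a
#' binary input stays binary and no new values are invented.
#'
#' @param raster source `hs_raster`.
#' @param target target [grid_spec()].
#' @return An `hs_raster` on `target`.
#' @export
resample_nearest <- function(raster, target) {
  src <- raster$grid
  if (!identical(src$crs_tag, target$crs_tag))
    stop("source and target grids use different crs_tag")
  if (grids_identical(src, target)) return(raster)
  cx <- cell_centers_x(target); cy <- cell_centers_y(target)
  col_of <- point_to_cell(src, cx, rep(src$y_origin - src$cell_size / 2, length(cx)))$col
  row_of <- point_to_cell(src, rep(src$x_origin + src$cell_size / 2, length(cy)), cy)$row
  if (all(is.na(col_of)) || all(is.na(row_of)))
    stop("source and target extents are disjoint")
  vals <- matrix(NA_real_, target$n_rows, target$n_cols)
  mask <- matrix(TRUE, target$n_rows, target$n_cols)
  ok_r <- which(!is.na(row_of)); ok_c <- which(!is.na(col_of))
  vals[ok_r, ok_c] <- raster$values[row_of[ok_r], col_of[ok_c], drop = FALSE]
  mask[ok_r, ok_c] <- raster$nodata_mask[row_of[ok_r], col_of[ok_c], drop = FALSE]
  vals[mask] <- NA
  make_raster(target, vals, mask, kind = raster$kind)
}

# per-cell area in km^2, as a vector over rows (constant within a row)
row_cell_areas_km2 <- function(grid) {
  if (grid$crs_tag == "equal-area-synthetic") {
    rep((grid$cell_size / 1000)^2, grid$n_rows)
  } else {
    # spherical approximation: one degree = pi*R/180 km along a meridian,
    # east-west shrunk by cos(latitude of the cell centre)
    klat <- pi * 6371 / 180
    (klat * grid$cell_size)^2 * cos(cell_centers_y(grid) * pi / 180)
  }
}

#' Suitable area of a binary raster, in km^2
#'
#' Equal-area grids: count of 1-cells times the exact cell area. Lonlat
#' grids: cosine-weighted spherical cell areas. Nodata cells never count.
#'
#' @param binary a binary `hs_raster`.
#' @return Area in km^2.
#' @export
area_km2 <- function(binary) {
  if (binary$kind != "binary") stop("area_km2 expects a binary raster")
  a <- row_cell_areas_km2(binary$grid)
  v <- binary$values
  v[binary$nodata_mask] <- 0
  sum(rowSums(v, na.rm = TRUE) * a)
}

#' Cellwise logical AND of two binary rasters
#'
#' Nodata in either input propagates to the output.
#'
#' @param a,b binary `hs_raster`s on identical grids.
#' @return Binary `hs_raster`.
#' @export
overlay_and <- function(a, b) {
  if (a$kind != "binary" || b$kind != "binary")
    stop("overlay_and expects binary rasters")
  if (!grids_identical(a$grid, b$grid)) stop("grid mismatch in overlay_and")
  mask <- a$nodata_mask | b$nodata_mask
  v <- a$values * b$values
  v[mask] <- NA
  make_raster(a$grid, v, mask, kind = "binary")
}

#' Latitudinal area profile of a binary map
#'
#' Sums suitable area into half-open latitude bands
#' `[k*bandwidth, (k+1)*bandwidth)`. The peak band is the band of maximum
#' area; ties resolve to the southernmost band.
#'
#' @param binary a binary `hs_raster` on a lonlat grid.
#' @param bandwidth band width in degrees (default 0.1).
#' @return data.frame with columns `band_lower`, `area_km2`; attributes
#'   `bandwidth`, `peak_band` (lower edge of the peak band) and
#'   `total_km2`.
#' @export
latitudinal_profile <- function(binary, bandwidth = 0.1) {
  if (binary$kind != "binary") stop("latitudinal_profile expects a binary raster")
  if (binary$grid$crs_tag != "lonlat")
    stop("latitudinal_profile needs a lonlat grid (no latitude on synthetic equal-area grids)")
  stopifnot(bandwidth > 0)
  lat <- cell_centers_y(binary$grid)
  a <- row_cell_areas_km2(binary$grid)
  v <- binary$values
  v[binary$nodata_mask] <- 0
  row_area <- rowSums(v, na.rm = TRUE) * a
  band <- floor(lat / bandwidth) * bandwidth
  agg <- tapply(row_area, band, sum)
  out <- data.frame(band_lower = as.numeric(names(agg)), area_km2 = as.numeric(agg))
  out <- out[order(out$band_lower), , drop = FALSE]
  rownames(out) <- NULL
  peak <- if (any(out$area_km2 > 0)) {
    mx <- max(out$area_km2)
    min(out$band_lower[out$area_km2 == mx])
  } else NA_real_
  structure(out, bandwidth = bandwidth, peak_band = peak,
            total_km2 = sum(out$area_km2))
}
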