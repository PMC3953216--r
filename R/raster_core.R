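#' Grid geometry of a raster layer
#'
#' A `grid_spec` describes the geometry shared by all layers in an analysis:
#' a regular grid of square cells. Indexing is 0-based `(row, col)` with row 0
#' at the north (top) edge, matching the row order of the ESRI ASCII grid
#' format.
#'
#' @param n_rows,n_cols Grid dimensions (positive integers).
#' @param cell_size Cell edge length in map units (> 0). Cells are square.
#' @param x_ll,y_ll Map coordinates of the lower-left corner of the grid.
#' @param nodata Sentinel value written for missing cells on disk. In memory
#'   missing cells are `NA`.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(n_rows, n_cols, cell_size = 1, x_ll = 0, y_ll = 0,
                      nodata = -9999) {
  stopifnot(n_rows >= 1, n_cols >= 1, cell_size > 0)
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 cell_size = cell_size, x_ll = x_ll, y_ll = y_ll,
                 nodata = nodata),
            class = "grid_spec")
}

#' @export
format.grid_spec <- function(x, ...) {
  sprintf("<grid_spec %d x %d, cell %g, ll (%g, %g)>",
          x$n_rows, x$n_cols, x$cell_size, x$x_ll, x$y_ll)
}

#' @export
print.grid_spec <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

same_spec <- function(a, b, tol = 1e-9) {
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    abs(a$cell_size - b$cell_size) <= tol &&
    abs(a$x_ll - b$x_ll) <= tol && abs(a$y_ll - b$y_ll) <= tol
}

#' A single raster layer
#'
#' The universal spatial currency of the package: one mapped variable on a
#' [grid_spec()]. Values are stored as an `n_rows x n_cols` numeric matrix,
#' row 1 = north; missing cells are `NA` and are excluded from every
#' aggregate computed by the package.
#'
#' @param values Numeric matrix (or vector reshaped row-major) of cell values.
#' @param spec A [grid_spec()]. If missing, a unit-cell spec matching
#'   `values` is created.
#' @param semantics Free-text concept tag (what the layer maps).
#' @param units Free-text units.
#' @return An object of class `raster_layer`.
#' @export
raster_layer <- function(values, spec = NULL, semantics = "", units = "") {
  if (is.null(spec)) {
    values <- as.matrix(values)
    spec <- grid_spec(nrow(values), ncol(values))
  }
  if (!is.matrix(values))
    values <- matrix(values, nrow = spec$n_rows, ncol = spec$n_cols,
                     byrow = TRUE)
  stopifnot(nrow(values) == spec$n_rows, ncol(values) == spec$n_cols)
  storage.mode(values) <- "double"
  structure(list(spec = spec, values = values, semantics = semantics,
                 units = units),
            class = "raster_layer")
}

#' @export
print.raster_layer <- function(x, ...) {
  cat(sprintf("raster_layer '%s' [%s] %s\n", x$semantics, x$units,
              format(x$spec)))
  invisible(x)
}

#' Sum of non-missing cell values
#' @param layer A [raster_layer()].
#' @return Scalar sum over non-`NA` cells.
#' @export
layer_total <- function(layer) sum(layer$values, na.rm = TRUE)

#' Read an ESRI ASCII grid
#'
#' Parses the `.asc` dialect: a header with keys `ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize` and optional `NODATA_value`
#' (case-insensitive), followed by whitespace-separated values in row-major
#' north-to-south order. Cells equal to the nodata sentinel become `NA`.
#'
#' @param path Path to the file.
#' @param semantics,units Optional tags attached to the returned layer.
#' @return A [raster_layer()].
#' @export
read_ascii_grid <- function(path, semantics = "", units = "") {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- list()
  i <- 1
  while (i <= length(lines)) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(tok) == 2 && grepl("^[a-zA-Z_]", tok[1])) {
      hdr[[tolower(tok[1])]] <- as.numeric(tok[2])
      i <- i + 1
    } else break
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  miss <- setdiff(need, names(hdr))
  if (length(miss) > 0)
    stop("malformed ASCII grid header: missing key(s) ",
         paste(miss, collapse = ", "))
  if (hdr$cellsize <= 0) stop("malformed ASCII grid header: cellsize <= 0")
  nodata <- if ("nodata_value" %in% names(hdr)) hdr$nodata_value else -9999
  body <- as.numeric(unlist(strsplit(trimws(lines[i:length(lines)]), "\\s+")))
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(body) != nr * nc)
    stop(sprintf("ASCII grid body has %d cells, expected %d x %d = %d",
                 length(body), nr, nc, nr * nc))
  vals <- matrix(body, nrow = nr, ncol = nc, byrow = TRUE)
  vals[vals == nodata] <- NA_real_
  spec <- grid_spec(nr, nc, hdr$cellsize, hdr$xllcorner, hdr$yllcorner,
                    nodata = nodata)
  raster_layer(vals, spec, semantics = semantics, units = units)
}

#' Write an ESRI ASCII grid
#'
#' Inverse of [read_ascii_grid()]: values round-trip exactly (shortest
#' round-trip decimal representation, `NA` written as the spec's nodata
#' sentinel).
#'
#' @param layer A [raster_layer()].
#' @param path Destination path.
#' @return Invisibly, `path`.
#' @export
write_ascii_grid <- function(layer, path) {
  s <- layer$spec
  fmt_num <- function(x) format(x, digits = 17, scientific = FALSE, trim = TRUE)
  hdr <- c(paste("ncols", s$n_cols),
           paste("nrows", s$n_rows),
           paste("xllcorner", fmt_num(s$x_ll)),
           paste("yllcorner", fmt_num(s$y_ll)),
           paste("cellsize", fmt_num(s$cell_size)),
           paste("NODATA_value", fmt_num(s$nodata)))
  v <- layer$values
  v[is.na(v)] <- s$nodata
  rows <- apply(v, 1, function(r) paste(vapply(r, fmt_num, ""), collapse = " "))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(hdr, rows), con)
  invisible(path)
}

# Map coordinates of cell centers (row 1 = north).
cell_center_x <- function(spec, col) spec$x_ll + (col - 0.5) * spec$cell_size
cell_center_y <- function(spec, row)
  spec$y_ll + (spec$n_rows - row + 0.5) * spec$cell_size

#' Align raster layers onto a target grid
#'
#' Resamples each layer onto `target`. `"nearest"` assigns the value of the
#' source cell containing each target cell center; `"mean-aggregate"`
#' averages the non-missing source cells whose centers fall inside each
#' target cell. Layers already on `target` are returned unchanged.
#'
#' @param layers A list of [raster_layer()] (a single layer is accepted).
#' @param target A [grid_spec()].
#' @param method `"nearest"` or `"mean-aggregate"`.
#' @return A list of aligned layers (or a single layer if one was given).
#' @export
align <- function(layers, target, method = c("nearest", "mean-aggregate")) {
  method <- match.arg(method)
  single <- inherits(layers, "raster_layer")
  if (single) layers <- list(layers)
  out <- lapply(layers, function(ly) align_one(ly, target, method))
  if (single) out[[1]] else out
}

align_one <- function(layer, target, method) {
  src <- layer$spec
  if (same_spec(src, target)) return(layer)
  # overlap test on bounding boxes
  sx <- c(src$x_ll, src$x_ll + src$n_cols * src$cell_size)
  sy <- c(src$y_ll, src$y_ll + src$n_rows * src$cell_size)
  tx <- c(target$x_ll, target$x_ll + target$n_cols * target$cell_size)
  ty <- c(target$y_ll, target$y_ll + target$n_rows * target$cell_size)
  if (sx[2] <= tx[1] || tx[2] <= sx[1] || sy[2] <= ty[1] || ty[2] <= sy[1])
    stop("layer does not overlap the target grid")
  vals <- matrix(NA_real_, target$n_rows, target$n_cols)
  if (method == "nearest") {
    for (r in seq_len(target$n_rows)) {
      y <- cell_center_y(target, r)
      sr <- src$n_rows - floor((y - src$y_ll) / src$cell_size)
      for (c in seq_len(target$n_cols)) {
        x <- cell_center_x(target, c)
        sc <- floor((x - src$x_ll) / src$cell_size) + 1
        if (sr >= 1 && sr <= src$n_rows && sc >= 1 && sc <= src$n_cols)
          vals[r, c] <- layer$values[sr, sc]
      }
    }
  } else {
    acc <- matrix(0, target$n_rows, target$n_cols)
    cnt <- matrix(0L, target$n_rows, target$n_cols)
    for (r in seq_len(src$n_rows)) {
      y <- cell_center_y(src, r)
      tr <- target$n_rows - floor((y - target$y_ll) / target$cell_size)
      if (tr < 1 || tr > target$n_rows) next
      for (c in seq_len(src$n_cols)) {
        v <- layer$values[r, c]
        if (is.na(v)) next
        x <- cell_center_x(src, c)
        tc <- floor((x - target$x_ll) / target$cell_size) + 1
        if (tc < 1 || tc > target$n_cols) next
        acc[tr, tc] <- acc[tr, tc] + v
        cnt[tr, tc] <- cnt[tr, tc] + 1L
      }
    }
    vals <- ifelse(cnt > 0, acc / pmax(cnt, 1L), NA_real_)
  }
  raster_layer(vals, target, semantics = layer$semantics, units = layer$units)
}

# 8-neighbour offsets, clockwise from East, and their distance factors.
NB8_DR <- c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)
NB8_DC <- c(1L, 1L, 0L, -1L, -1L, -1L, 0L, 1L)
NB8_DIST <- c(1, sqrt(2), 1, sqrt(2), 1, sqrt(2), 1, sqrt(2))

#' Percent slope from a DEM
#'
#' Per-cell slope as `100 * rise / run` of the steepest descent among the 8
#' neighbours (diagonal run = `cell_size * sqrt(2)`). Cells with no lower
#' neighbour (pits, flats) get slope 0. Invariant under adding a constant to
#' the DEM.
#'
#' @param dem A [raster_layer()] of elevations in the same length units as
#'   the cell size.
#' @return A [raster_layer()] with units `"%"`.
#' @export
slope_percent <- function(dem) {
  s <- dem$spec
  z <- dem$values
  out <- matrix(NA_real_, s$n_rows, s$n_cols)
  for (r in seq_len(s$n_rows)) for (c in seq_len(s$n_cols)) {
    z0 <- z[r, c]
    if (is.na(z0)) next
    best <- 0
    for (k in 1:8) {
      rr <- r + NB8_DR[k]; cc <- c + NB8_DC[k]
      if (rr < 1 || rr > s$n_rows || cc < 1 || cc > s$n_cols) next
      zn <- z[rr, cc]
      if (is.na(zn)) next
      g <- (z0 - zn) / (NB8_DIST[k] * s$cell_size)
      if (g > best) best <- g
    }
    out[r, c] <- 100 * best
  }
  raster_layer(out, s, semantics = "slope", units = "%")
}
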