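#' Binary region-of-interest mask
#'
#' A `roi_mask` is a logical height x width matrix marking the pixels of one
#' region within a fixed field of view, plus a free-text label. All geometry in
#' this package is pixel-aligned: a pixel is either in a region or not, and
#' coordinates are 0-based `(row, col)` with the pixel centre at
#' `(row + 0.5, col + 0.5)`.
#'
#' @param mask Logical matrix (height x width). Numeric input is coerced with
#'   `!= 0`.
#' @param label Character identifier for the region.
#' @return An object of class `roi_mask`.
#' @examples
#' m <- matrix(FALSE, 10, 10); m[4:6, 4:6] <- TRUE
#' roi_mask(m, "cell1")
#' @export
roi_mask <- function(mask, label = "roi") {
  if (is.numeric(mask)) mask <- mask != 0
  if (!is.matrix(mask) || !is.logical(mask))
    stop("`mask` must be a logical matrix")
  if (!any(mask)) stop("mask '", label, "' has no set pixels")
  structure(list(mask = mask, label = as.character(label)[1]),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask '%s': %d px in %d x %d field>\n",
              x$label, sum(x$mask), nrow(x$mask), ncol(x$mask)))
  invisible(x)
}

#' Number of pixels in a mask
#' @param x A `roi_mask` or logical matrix.
#' @return Integer pixel count.
#' @export
mask_area <- function(x) {
  if (inherits(x, "roi_mask")) x <- x$mask
  sum(x)
}

#' Area centroid of a mask
#'
#' Mean of the set pixels' centre coordinates, in 0-based `(row, col)`
#' continuous coordinates.
#'
#' @param x A `roi_mask` or logical matrix.
#' @return Numeric length-2 vector `(row, col)`.
#' @export
mask_centroid <- function(x) {
  if (inherits(x, "roi_mask")) x <- x$mask
  idx <- which(x, arr.ind = TRUE)
  c(mean(idx[, 1]) - 0.5, mean(idx[, 2]) - 0.5)
}

## one binary dilation step by matrix shifts; diagonal = FALSE gives the
## 4-connected (cardinal) structuring element, TRUE the diagonal-only one
dilate_step <- function(m, diagonal = FALSE) {
  h <- nrow(m); w <- ncol(m)
  out <- m
  shift <- function(dr, dc) {
    s <- matrix(FALSE, h, w)
    rs <- max(1, 1 + dr):min(h, h + dr)
    cs <- max(1, 1 + dc):min(w, w + dc)
    s[rs, cs] <- m[rs - dr, cs - dc]
    s
  }
  if (diagonal) {
    out <- out | shift(1, 1) | shift(1, -1) | shift(-1, 1) | shift(-1, -1)
  } else {
    out <- out | shift(1, 0) | shift(-1, 0) | shift(0, 1) | shift(0, -1)
  }
  out
}

#' Grow the neuropil ring around a ROI
#'
#' Expands the ROI by binary dilation, alternating a cardinal (4-connected)
#' and a diagonal structuring element (cardinal first), which produces a
#' roughly octagonal expansion. Growth stops at the first iteration where the
#' surrounding ring (expanded mask minus the ROI, minus any exclusions,
#' clipped to the field of view) reaches `area_ratio` times the ROI area. If
#' the field boundary or exclusions exhaust growth first, the largest
#' attainable ring is returned with a warning and attribute
#' `exhausted = TRUE`.
#'
#' @param roi A `roi_mask`.
#' @param area_ratio Target ring area as a multiple of the ROI area
#'   (default 4, matching the default of four subregions each the size of
#'   the ROI).
#' @param exclusions Optional list of `roi_mask` whose pixels are excluded
#'   from the ring (e.g. neighbouring cell ROIs). By default nothing is
#'   excluded.
#' @return A `roi_mask` for the ring (label `"<roi label>.npil"`).
#' @export
grow_neuropil <- function(roi, area_ratio = 4, exclusions = NULL) {
  stopifnot(inherits(roi, "roi_mask"), area_ratio > 0)
  target <- area_ratio * mask_area(roi)
  blocked <- roi$mask
  if (!is.null(exclusions)) {
    if (inherits(exclusions, "roi_mask")) exclusions <- list(exclusions)
    for (ex in exclusions) {
      exm <- if (inherits(ex, "roi_mask")) ex$mask else ex
      blocked <- blocked | exm
    }
  }
  grown <- roi$mask
  diagonal <- FALSE  # cardinal step first
  exhausted <- FALSE
  repeat {
    ring <- grown & !blocked
    if (sum(ring) >= target) break
    nxt <- dilate_step(grown, diagonal)
    diagonal <- !diagonal
    if (identical(nxt, grown)) { exhausted <- TRUE; break }
    grown <- nxt
  }
  ring <- grown & !blocked
  if (!any(ring))
    stop("no neuropil pixels available around ROI '", roi$label, "'")
  if (exhausted && sum(ring) < target)
    warning(sprintf(
      "neuropil growth for ROI '%s' exhausted at %d px (target %.0f px)",
      roi$label, sum(ring), target))
  out <- roi_mask(ring, paste0(roi$label, ".npil"))
  attr(out, "exhausted") <- exhausted
  out
}

#' Split a neuropil ring into equal angular subregions
#'
#' Assigns every ring pixel to one of `n` wedges by the polar angle of its
#' centre about the ROI's area centroid. Wedge 0 starts at angle 0 (the
#' positive column axis) and spans are equal and half-open,
#' `[2*pi*k/n, 2*pi*(k+1)/n)`, with the angle increasing from the positive
#' column axis towards the positive row axis. For rings that surround the
#' ROI symmetrically the wedge areas are equal up to discretisation.
#'
#' @param ring A `roi_mask` for the neuropil ring (see [grow_neuropil()]).
#' @param roi The central `roi_mask`; its centroid defines the polar origin.
#' @param n Number of subregions (default 4).
#' @return A `region_set`: list with elements `roi`, `subregions` (list of
#'   `n` `roi_mask`), `n_subregions` and `centre`.
#' @export
split_subregions <- function(ring, roi, n = 4) {
  stopifnot(inherits(ring, "roi_mask"), inherits(roi, "roi_mask"))
  n <- as.integer(n)
  if (n < 1) stop("`n` must be a positive integer")
  if (!any(ring$mask)) stop("empty neuropil ring")
  if (n > mask_area(ring))
    stop("cannot split a ", mask_area(ring), "-pixel ring into ", n,
         " non-empty subregions")
  ctr <- mask_centroid(roi)
  idx <- which(ring$mask, arr.ind = TRUE)
  theta <- atan2(idx[, 1] - 0.5 - ctr[1], idx[, 2] - 0.5 - ctr[2])
  theta <- theta %% (2 * pi)
  wedge <- pmin(floor(theta / (2 * pi / n)), n - 1)  # guard fp edge at 2*pi
  subregions <- vector("list", n)
  for (k in seq_len(n) - 1L) {
    m <- matrix(FALSE, nrow(ring$mask), ncol(ring$mask))
    sel <- wedge == k
    if (!any(sel))
      stop("subregion ", k, " of ROI '", roi$label,
           "' is empty; use fewer subregions or a larger ring")
    m[idx[sel, , drop = FALSE]] <- TRUE
    subregions[[k + 1L]] <- roi_mask(m, sprintf("%s.npil%d", roi$label, k))
  }
  structure(list(roi = roi, subregions = subregions,
                 n_subregions = n, centre = ctr),
            class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  cat(sprintf("<region_set '%s': ROI %d px + %d subregions of %s px>\n",
              x$roi$label, mask_area(x$roi), x$n_subregions,
              paste(vapply(x$subregions, mask_area, 0L), collapse = "/")))
  invisible(x)
}

#' Build the measurement regions for one ROI
#'
#' Convenience wrapper: grows the neuropil ring to `n * area_ratio_per_region`
#' times the ROI area and splits it into `n` wedges, so that by default each
#' subregion has approximately the same area as the ROI.
#'
#' @inheritParams grow_neuropil
#' @param n Number of neuropil subregions (default 4).
#' @param area_ratio_per_region Ring area per subregion, as a multiple of the
#'   ROI area (default 1).
#' @return A `region_set`.
#' @export
build_regions <- function(roi, n = 4, area_ratio_per_region = 1,
                          exclusions = NULL) {
  ring <- grow_neuropil(roi, area_ratio = n * area_ratio_per_region,
                        exclusions = exclusions)
  split_subregions(ring, roi, n)
}

## ---- ImageJ ROI file format ------------------------------------------------

ij_types <- c(polygon = 0L, rect = 1L, oval = 2L, line = 3L, freeline = 4L,
              polyline = 5L, noroi = 6L, freehand = 7L, traced = 8L,
              angle = 9L, point = 10L)

read_u16 <- function(raw, off) {  # 0-based offset, big-endian unsigned short
  as.integer(raw[off + 1]) * 256L + as.integer(raw[off + 2])
}
read_s16 <- function(raw, off) {
  v <- read_u16(raw, off)
  if (v >= 32768L) v - 65536L else v
}

parse_imagej_roi <- function(raw, label, fov) {
  if (length(raw) < 64 || rawToChar(raw[1:4]) != "Iout")
    stop("'", label, "' is not an ImageJ ROI file")
  type <- as.integer(raw[7])
  top <- read_s16(raw, 8); left <- read_s16(raw, 10)
  bottom <- read_s16(raw, 12); right <- read_s16(raw, 14)
  ncoord <- read_u16(raw, 16)
  h <- fov[1]; w <- fov[2]
  mask <- matrix(FALSE, h, w)
  if (type == ij_types[["rect"]]) {
    rs <- seq.int(top, bottom - 1L); cs <- seq.int(left, right - 1L)
    rs <- rs[rs >= 0 & rs < h]; cs <- cs[cs >= 0 & cs < w]
    if (length(rs) && length(cs)) mask[rs + 1L, cs + 1L] <- TRUE
  } else if (type == ij_types[["oval"]]) {
    cx <- (left + right) / 2; cy <- (top + bottom) / 2
    a <- (right - left) / 2; b <- (bottom - top) / 2
    if (a <= 0 || b <= 0) stop("degenerate oval ROI '", label, "'")
    cc <- matrix(seq_len(w) - 0.5, h, w, byrow = TRUE)
    rr <- matrix(seq_len(h) - 0.5, h, w)
    mask <- ((cc - cx) / a)^2 + ((rr - cy) / b)^2 <= 1
  } else if (type %in% ij_types[c("polygon", "freehand", "traced")]) {
    if (ncoord < 3) stop("ROI '", label, "' has fewer than 3 vertices")
    xs <- vapply(seq_len(ncoord) - 1L,
                 function(i) read_s16(raw, 64 + 2 * i), 0L) + left
    ys <- vapply(seq_len(ncoord) - 1L,
                 function(i) read_s16(raw, 64 + 2 * (ncoord + i)), 0L) + top
    mask <- rasterize_polygon(xs, ys, h, w)
  } else {
    stop("unsupported ImageJ ROI type ", type, " in '", label, "'")
  }
  if (!any(mask))
    stop("ROI '", label, "' lies entirely outside the ", h, " x ", w,
         " field of view")
  roi_mask(mask, label)
}

## even-odd rasterization of a polygon given in (x = col, y = row) corner
## coordinates; a pixel is inside when its centre is inside the polygon
rasterize_polygon <- function(xs, ys, h, w) {
  r0 <- max(0L, floor(min(ys))); r1 <- min(h - 1L, ceiling(max(ys)))
  c0 <- max(0L, floor(min(xs))); c1 <- min(w - 1L, ceiling(max(xs)))
  mask <- matrix(FALSE, h, w)
  if (r0 > r1 || c0 > c1) return(mask)
  nv <- length(xs)
  xj <- c(xs[-1], xs[1]); yj <- c(ys[-1], ys[1])
  for (r in r0:r1) {
    py <- r + 0.5
    crosses <- (ys > py) != (yj > py)
    if (!any(crosses)) next
    xint <- xs[crosses] +
      (py - ys[crosses]) / (yj[crosses] - ys[crosses]) *
        (xj[crosses] - xs[crosses])
    px <- (c0:c1) + 0.5
    inside <- (colSums(outer(xint, px, `>`)) %% 2) == 1
    mask[r + 1L, (c0:c1) + 1L] <- inside
  }
  mask
}

#' Read ImageJ ROIs as binary masks
#'
#' Reads a single `.roi` file, a `.zip` archive of ROIs, or a directory of
#' `.roi` files, and rasterizes each ROI onto the given field of view using
#' pixel-centre containment. Supported ROI subtypes: rectangle, oval,
#' polygon, freehand and traced.
#'
#' @param path Path to a `.roi` file, `.zip` archive, or directory.
#' @param fov Field-of-view shape `c(height, width)` in pixels.
#' @return List of `roi_mask`, in archive order, labelled by file name.
#' @export
read_imagej_rois <- function(path, fov) {
  stopifnot(length(fov) == 2, all(fov >= 1))
  fov <- as.integer(fov)
  if (!file.exists(path)) stop("ROI path not found: ", path)
  read_one <- function(f) {
    raw <- readBin(f, "raw", n = file.info(f)$size)
    parse_imagej_roi(raw, sub("\\.roi$", "", basename(f), ignore.case = TRUE),
                     fov)
  }
  ext <- tolower(tools::file_ext(path))
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.roi$", ignore.case = TRUE,
                        full.names = TRUE)
    if (!length(files)) stop("no .roi files in directory ", path)
    lapply(sort(files), read_one)
  } else if (ext == "zip") {
    listing <- tryCatch(utils::unzip(path, list = TRUE),
                        error = function(e) stop("unreadable zip: ", path))
    names <- listing$Name[grepl("\\.roi$", listing$Name, ignore.case = TRUE)]
    if (!length(names)) stop("zip archive ", path, " contains no .roi entries")
    exdir <- tempfile("ijrois")
    utils::unzip(path, files = names, exdir = exdir, junkpaths = TRUE)
    on.exit(unlink(exdir, recursive = TRUE))
    lapply(file.path(exdir, basename(names)), read_one)
  } else if (ext == "roi") {
    list(read_one(path))
  } else {
    stop("unrecognised ROI path (expected .roi, .zip or directory): ", path)
  }
}

## trace the outer boundary of the largest connected component as a polygon
## on the pixel-corner lattice (crack following, interior kept to the right)
trace_boundary <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  filled <- function(y, x)  # pixel whose top-left corner is (y, x); 0-based
    y >= 0 && y < h && x >= 0 && x < w && mask[y + 1, x + 1]
  start <- which(mask & !rbind(FALSE, mask[-h, , drop = FALSE]),
                 arr.ind = TRUE)
  start <- start[order(start[, 1], start[, 2]), , drop = FALSE][1, ]
  p <- c(start[1] - 1L, start[2] - 1L)   # corner (y, x)
  dirs <- list(E = c(0L, 1L), S = c(1L, 0L), W = c(0L, -1L), N = c(-1L, 0L))
  left_of <- c(E = "N", S = "E", W = "S", N = "W")
  right_of <- c(E = "S", S = "W", W = "N", N = "E")
  ahead_px <- function(d, pt) switch(d,  # list(left pixel, right pixel)
    E = list(c(pt[1] - 1L, pt[2]), c(pt[1], pt[2])),
    S = list(c(pt[1], pt[2]), c(pt[1], pt[2] - 1L)),
    W = list(c(pt[1], pt[2] - 1L), c(pt[1] - 1L, pt[2] - 1L)),
    N = list(c(pt[1] - 1L, pt[2] - 1L), c(pt[1] - 1L, pt[2])))
  d <- "E"
  verts <- list(p)
  repeat {
    p <- p + dirs[[d]]
    if (all(p == verts[[1]]) ) break
    ap <- ahead_px(d, p)
    nd <- if (filled(ap[[1]][1], ap[[1]][2])) left_of[[d]]
          else if (filled(ap[[2]][1], ap[[2]][2])) d
          else right_of[[d]]
    if (nd != d) verts[[length(verts) + 1L]] <- p
    d <- nd
    if (length(verts) > 4 * (h * w)) stop("boundary tracing failed")
  }
  vm <- do.call(rbind, verts)
  list(x = vm[, 2], y = vm[, 1])  # corner-lattice (col, row) coordinates
}

encode_imagej_roi <- function(xs, ys) {
  n <- length(xs)
  top <- min(ys); left <- min(xs); bottom <- max(ys); right <- max(xs)
  con <- rawConnection(raw(0), "wb")
  on.exit(close(con))
  writeBin(charToRaw("Iout"), con)
  writeBin(c(227L, 0L), con, size = 2, endian = "big")  # version, type=polygon
  writeBin(as.integer(c(top, left, bottom, right, n)), con, size = 2,
           endian = "big")
  writeBin(raw(64 - 18), con)
  writeBin(as.integer(xs - left), con, size = 2, endian = "big")
  writeBin(as.integer(ys - top), con, size = 2, endian = "big")
  rawConnectionValue(con)
}

#' Write masks as ImageJ-compatible polygon ROI files
#'
#' Traces the outer boundary of each mask and writes it as an ImageJ polygon
#' `.roi` file into `dir` (created if needed). Masks with holes (e.g. annular
#' cell masks) or several connected components are exported as the filled
#' outer boundary of the component containing the first set pixel; a warning
#' is emitted when this loses pixels on re-rasterization.
#'
#' @param masks A `roi_mask` or list of them.
#' @param dir Output directory; one `<label>.roi` file per mask.
#' @return Invisibly, the paths written.
#' @export
write_imagej_rois <- function(masks, dir) {
  if (inherits(masks, "roi_mask")) masks <- list(masks)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(masks))
  for (i in seq_along(masks)) {
    m <- masks[[i]]
    b <- trace_boundary(m$mask)
    back <- rasterize_polygon(b$x, b$y, nrow(m$mask), ncol(m$mask))
    if (!identical(back, m$mask))
      warning("mask '", m$label, "' is not simply connected; exported ROI ",
              "covers its filled outer boundary")
    paths[i] <- file.path(dir, paste0(m$label, ".roi"))
    writeBin(encode_imagej_roi(b$x, b$y), paths[i])
  }
  invisible(paths)
}

#' Write masks as a multi-page TIFF stack for inspection
#'
#' @param masks A `roi_mask` or list of them.
#' @param path Output TIFF path; one 8-bit page per mask (0/255).
#' @return Invisibly, `path`.
#' @export
write_mask_tiff <- function(masks, path) {
  if (inherits(masks, "roi_mask")) masks <- list(masks)
  pages <- lapply(masks, function(m) (m$mask * 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}
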