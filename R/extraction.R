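#' Calcium imaging movie
#'
#' Wraps a motion-corrected movie as a `height x width x time` array of
#' non-negative intensities plus its frame rate. Movies can be constructed
#' from an in-memory array or from a multi-page TIFF file; TIFF-backed movies
#' can stay on disk (`load_frames = FALSE`) so that traces are computed
#' frame-by-frame without holding the whole stack in memory.
#'
#' Integer TIFFs (8/16 bit) are read at their native integer values;
#' float TIFFs at their stored values. [write_movie_tiff()] stores counts as
#' 16-bit integers, so write/read round trips are exact for intensities in
#' `0..65535`.
#'
#' @param x 3-D array (`height x width x time`) or path to a multi-page TIFF.
#' @param frame_rate Acquisition rate in Hz.
#' @param load_frames For file input: read all frames now (default) or keep a
#'   file-backed movie for streaming extraction.
#' @param loader Optional custom loader: a function `path -> 3-D array`,
#'   for formats this package does not read natively.
#' @return An object of class `movie` with fields `frames` (or `NULL` when
#'   file-backed), `dim` (`c(height, width, n_frames)`), `frame_rate`,
#'   `source`.
#' @export
## internal constructor; `cache` holds lazily computed derived forms of the
## (immutable) frame data -- currently the flattened pixel x time matrix --
## shared by reference so repeated extractions do not re-copy the stack
new_movie <- function(frames, dims, frame_rate, source) {
  structure(list(frames = frames, dim = dims, frame_rate = frame_rate,
                 source = source, cache = new.env(parent = emptyenv())),
            class = "movie")
}

load_movie <- function(x, frame_rate, load_frames = TRUE, loader = NULL) {
  stopifnot(is.numeric(frame_rate), frame_rate > 0)
  if (is.character(x)) {
    path <- x
    if (!file.exists(path)) stop("movie file not found: ", path)
    if (!is.null(loader)) {
      arr <- loader(path)
      return(load_movie(arr, frame_rate))
    }
    if (!load_frames) {
      info <- tiff::readTIFF(path, all = TRUE, payload = FALSE)
      pages <- if (is.data.frame(info)) nrow(info) else length(info)
      first <- read_tiff_frames(path, 1L)
      return(new_movie(NULL, c(dim(first)[1:2], pages), frame_rate, path))
    }
    frames <- read_tiff_frames(path, all = TRUE)
    return(load_movie(frames, frame_rate))
  }
  if (length(dim(x)) != 3)
    stop("movie array must be 3-D (height x width x time); got ",
         length(dim(x)), " dimensions")
  if (anyNA(x) || any(!is.finite(x))) stop("movie contains non-finite values")
  if (any(x < 0)) {
    warning(sum(x < 0), " negative intensities clipped to 0")
    x[x < 0] <- 0
  }
  new_movie(x, dim(x), frame_rate, "in-memory")
}

#' @export
print.movie <- function(x, ...) {
  cat(sprintf("<movie: %d x %d px, %d frames @ %g Hz (%s)>\n",
              x$dim[1], x$dim[2], x$dim[3], x$frame_rate,
              if (is.null(x$frames)) paste0("file-backed: ", x$source)
              else "in memory"))
  invisible(x)
}

## read selected pages (or all) from a multi-page TIFF as an H x W x T array
read_tiff_frames <- function(path, which = NULL, all = FALSE) {
  pages <- if (all) tiff::readTIFF(path, all = TRUE, as.is = TRUE)
           else tiff::readTIFF(path, all = which, as.is = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  arr <- array(0, dim = c(dim(pages[[1]])[1:2], length(pages)))
  for (i in seq_along(pages)) {
    p <- pages[[i]]
    if (length(dim(p)) == 3) p <- p[, , 1]  # drop extra channels
    arr[, , i] <- p
  }
  arr
}

#' Write a movie as a 16-bit multi-page TIFF
#'
#' @param movie A `movie` (in memory) or 3-D array.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_movie_tiff <- function(movie, path) {
  arr <- if (inherits(movie, "movie")) movie$frames else movie
  if (is.null(arr)) stop("movie is file-backed; nothing to write")
  if (any(arr < 0) || any(arr > 65535))
    stop("16-bit TIFF export requires intensities in 0..65535")
  pages <- lapply(seq_len(dim(arr)[3]), function(t) arr[, , t] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Trace matrix of region-mean fluorescence
#'
#' Constructor used internally; row 1 is the ROI, rows 2..(N+1) the neuropil
#' subregions.
#' @param values `(N+1) x T` numeric matrix.
#' @param frame_rate Hz.
#' @param trial_boundaries 0-based start frame of each trial (default one
#'   trial, `0`).
#' @return Object of class `trace_matrix`.
#' @export
trace_matrix <- function(values, frame_rate, trial_boundaries = 0L) {
  stopifnot(is.matrix(values), frame_rate > 0)
  structure(list(values = values, frame_rate = frame_rate,
                 trial_boundaries = as.integer(trial_boundaries)),
            class = "trace_matrix")
}

#' @export
print.trace_matrix <- function(x, ...) {
  cat(sprintf("<trace_matrix: %d regions x %d frames @ %g Hz, %d trial(s)>\n",
              nrow(x$values), ncol(x$values), x$frame_rate,
              length(x$trial_boundaries)))
  invisible(x)
}

#' Extract region-mean traces from a movie
#'
#' Row `r`, frame `t` of the result is the arithmetic mean of the pixel
#' intensities inside region `r` at frame `t`. Regions are the ROI (row 1)
#' followed by the neuropil subregions. For file-backed movies the means are
#' accumulated frame-by-frame in chunks, never holding the full stack.
#'
#' @param movie A `movie`.
#' @param regions A `region_set` (see [split_subregions()]), a `roi_mask`, or
#'   a list of `roi_mask`.
#' @param chunk Frames per read for streaming extraction (default 256).
#' @return A `trace_matrix`.
#' @export
extract_traces <- function(movie, regions, chunk = 256L) {
  stopifnot(inherits(movie, "movie"))
  masks <- if (inherits(regions, "region_set"))
    c(list(regions$roi), regions$subregions)
  else if (inherits(regions, "roi_mask")) list(regions)
  else regions
  h <- movie$dim[1]; w <- movie$dim[2]; tt <- movie$dim[3]
  for (m in masks) {
    if (!all(dim(m$mask) == c(h, w)))
      stop("mask '", m$label, "' shape ", nrow(m$mask), " x ", ncol(m$mask),
           " does not match movie field ", h, " x ", w)
    if (!any(m$mask)) stop("empty mask '", m$label, "'")
  }
  # (H*W) x R matrix of mask indicator columns scaled by 1/area
  mm <- vapply(masks, function(m) as.numeric(m$mask) / sum(m$mask),
               numeric(h * w))
  if (!is.null(movie$frames)) {
    # flatten once per movie: the copy of a long recording is more expensive
    # than the mask product itself, and sweeps extract from the same movie
    # many times
    flat <- if (!is.null(movie$cache)) movie$cache$flat
    if (is.null(flat)) {
      flat <- matrix(movie$frames, h * w, tt)
      if (!is.null(movie$cache)) movie$cache$flat <- flat
    }
    vals <- crossprod(mm, flat)
  } else {
    vals <- matrix(0, length(masks), tt)
    done <- 0L
    while (done < tt) {
      take <- seq.int(done + 1L, min(done + chunk, tt))
      arr <- read_tiff_frames(movie$source, which = take)
      vals[, take] <- crossprod(mm, matrix(arr, h * w, length(take)))
      done <- done + length(take)
    }
  }
  rownames(vals) <- vapply(masks, function(m) m$label, "")
  trace_matrix(vals, movie$frame_rate)
}

#' Concatenate traces from multiple trials
#'
#' Trials recorded from the same cells are concatenated along time before
#' separation, so the demixed signal cannot change identity between trials;
#' [split_trials()] restores the per-trial segmentation afterwards.
#'
#' @param traces List of `trace_matrix` with identical row counts and frame
#'   rates.
#' @return A single `trace_matrix` whose `trial_boundaries` record each
#'   trial's 0-based start frame.
#' @export
concat_trials <- function(traces) {
  stopifnot(length(traces) >= 1)
  if (length(traces) == 1) return(traces[[1]])
  nr <- vapply(traces, function(x) nrow(x$values), 0L)
  if (length(unique(nr)) != 1)
    stop("row-count mismatch across trials: ", paste(nr, collapse = ", "))
  fr <- vapply(traces, function(x) x$frame_rate, 0)
  if (length(unique(fr)) != 1)
    stop("frame-rate mismatch across trials: ", paste(fr, collapse = ", "))
  lens <- vapply(traces, function(x) ncol(x$values), 0L)
  trace_matrix(do.call(cbind, lapply(traces, `[[`, "values")),
               fr[1], cumsum(c(0L, lens[-length(lens)])))
}

#' Split a concatenated trace (or any length-T series) back into trials
#'
#' @param x A `trace_matrix`, matrix, or numeric vector covering the full
#'   concatenated length.
#' @param trial_boundaries 0-based start frames (as stored by
#'   [concat_trials()]); taken from `x` itself when it is a `trace_matrix`.
#' @return List with one element per trial.
#' @export
split_trials <- function(x, trial_boundaries = NULL) {
  if (inherits(x, "trace_matrix")) {
    if (is.null(trial_boundaries)) trial_boundaries <- x$trial_boundaries
    x <- x$values
  }
  stopifnot(!is.null(trial_boundaries))
  tt <- if (is.matrix(x)) ncol(x) else length(x)
  starts <- trial_boundaries + 1L
  ends <- c(trial_boundaries[-1], tt)
  lapply(seq_along(starts), function(i) {
    idx <- seq.int(starts[i], ends[i])
    if (is.matrix(x)) x[, idx, drop = FALSE] else x[idx]
  })
}
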