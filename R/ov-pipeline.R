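#' Construct an optical image stack
#'
#' @param frames List of numeric matrices, all the same shape, one per frame.
#' @param times Frame capture times, seconds, strictly increasing (nominal
#'   spacing 150 s in the standard optical-vulnerability setup).
#' @param pixel_scale Optional um per pixel.
#' @return An `image_stack` object.
#' @export
image_stack <- function(frames, times, pixel_scale = NULL) {
  stopifnot(is.list(frames), length(frames) == length(times))
  if (length(frames) < 2L) stop("an image stack needs at least 2 frames")
  if (is.unsorted(times, strictly = TRUE)) stop("frame times must be strictly increasing")
  dims <- dim(frames[[1L]])
  ok <- vapply(frames, function(f) identical(dim(f), dims), logical(1L))
  if (!all(ok)) stop("all frames must share one shape")
  structure(list(frames = frames, times = as.numeric(times),
                 pixel_scale = pixel_scale), class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames[[1L]])
  cat(sprintf("Image stack: %d frames of %dx%d px, t in [%g, %g] s\n",
              length(x$frames), d[1L], d[2L], min(x$times), max(x$times)))
  invisible(x)
}

#' Successive-frame difference maps
#'
#' Absolute difference of each consecutive frame pair, the primitive of the
#' optical embolism-detection protocol: an embolizing conduit changes local
#' intensity between the two frames bracketing its embolism.
#'
#' @param stack An [image_stack()].
#' @return List of non-negative matrices, one per consecutive pair; attribute
#'   `pair_times` holds the midpoint time of each pair.
#' @export
difference_stack <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  n <- length(stack$frames)
  maps <- lapply(seq_len(n - 1L), function(i)
    abs(stack$frames[[i + 1L]] - stack$frames[[i]]))
  attr(maps, "pair_times") <- (stack$times[-1L] + stack$times[-n]) / 2
  maps
}

# connected-component labeling via breadth-first flood fill
label_components <- function(mask, connectivity = 8L) {
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  seeds <- which(mask)
  if (!length(seeds)) return(lab)
  dr <- c(-1L, 1L, 0L, 0L); dc <- c(0L, 0L, -1L, 1L)
  if (connectivity == 8L) {
    dr <- c(dr, -1L, -1L, 1L, 1L); dc <- c(dc, -1L, 1L, -1L, 1L)
  }
  cur <- 0L
  for (s in seeds) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    lab[s] <- cur
    frontier <- s
    while (length(frontier)) {   # level-synchronous flood fill
      r0 <- ((frontier - 1L) %% nr) + 1L
      c0 <- ((frontier - 1L) %/% nr) + 1L
      rr <- rep(r0, each = length(dr)) + dr
      cc <- rep(c0, each = length(dc)) + dc
      ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
      q <- unique((cc[ok] - 1L) * nr + rr[ok])
      q <- q[mask[q] & lab[q] == 0L]
      lab[q] <- cur
      frontier <- q
    }
  }
  lab
}

#' Robust noise estimate of a difference map
#'
#' Difference maps are absolute values of a (mostly signal-free) noise
#' difference, so the robust sigma of the underlying signed difference is
#' `median(|d|) / qnorm(3/4)` — the median-absolute-deviation estimator
#' taken about zero. Used for the default detection threshold (3 x the
#' noise sigma of the first difference map).
#'
#' @param map A difference map (matrix of absolute differences).
#' @return Robust SD estimate of the signed frame difference.
#' @export
robust_noise_sd <- function(map) stats::median(abs(as.numeric(map))) / stats::qnorm(0.75)

#' Detect embolism events in difference maps
#'
#' Thresholds each difference map, groups super-threshold pixels into
#' connected components, discards components smaller than `min_cluster`, and
#' maintains a running union mask so a pixel is counted at most once over
#' the whole record (re-flickering conduits are not double counted).
#'
#' @param diff_maps As from [difference_stack()].
#' @param threshold Intensity threshold; default `NULL` uses 3 x the robust
#'   noise SD of the first map (floored at a tiny positive value for
#'   noise-free stacks).
#' @param min_cluster Minimum component area, px (default 4).
#' @param connectivity 4 or 8 (default 8).
#' @return An `embolism_events` object: `events` data.frame (`pair`, `time`,
#'   `area_px`, `centroid_row`, `centroid_col`), the final union `mask`, and
#'   the parameters used.
#' @export
detect_events <- function(diff_maps, threshold = NULL, min_cluster = 4L,
                          connectivity = 8L) {
  if (is.null(threshold)) {
    threshold <- 3 * robust_noise_sd(diff_maps[[1L]])
    if (threshold <= 0) threshold <- 1e-9   # noise-free stack
  }
  if (threshold <= 0) stop("threshold must be > 0")
  pair_times <- attr(diff_maps, "pair_times")
  union_mask <- matrix(FALSE, nrow(diff_maps[[1L]]), ncol(diff_maps[[1L]]))
  ev <- list()
  for (i in seq_along(diff_maps)) {
    mask <- diff_maps[[i]] > threshold & !union_mask
    if (!any(mask)) next
    lab <- label_components(mask, connectivity)
    sizes <- tabulate(lab[lab > 0L])
    keep <- which(sizes >= min_cluster)
    for (k in keep) {
      px <- which(lab == k)
      union_mask[px] <- TRUE
      rows <- ((px - 1L) %% nrow(lab)) + 1L
      cols <- ((px - 1L) %/% nrow(lab)) + 1L
      ev[[length(ev) + 1L]] <- data.frame(
        pair = i, time = if (is.null(pair_times)) NA_real_ else pair_times[i],
        area_px = sizes[k], centroid_row = mean(rows), centroid_col = mean(cols))
    }
  }
  events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(pair = integer(0), time = numeric(0), area_px = integer(0),
               centroid_row = numeric(0), centroid_col = numeric(0))
  structure(list(events = events, mask = union_mask,
                 params = list(threshold = threshold, min_cluster = min_cluster,
                               connectivity = connectivity)),
            class = "embolism_events")
}

#' @export
print.embolism_events <- function(x, ...) {
  cat(sprintf("Embolism events: %d clusters, %d px total (threshold %.3g, min %d px, %d-conn)\n",
              nrow(x$events), sum(x$events$area_px), x$params$threshold,
              x$params$min_cluster, x$params$connectivity))
  invisible(x)
}

#' Accumulate embolized area into a percent-vs-Psi series
#'
#' Sums detected event areas per frame pair, accumulates them over time
#' (A_cum), normalizes by the total embolized area at the end of the record
#' (A_max) so that percent = A_cum / A_max x 100, and attaches the water
#' potential at each event's frame-pair midpoint. Percent reaches exactly
#' 100 at the last event by construction; the protocol measures relative,
#' not absolute, embolized area.
#'
#' @param events An `embolism_events` from [detect_events()].
#' @param stack The source [image_stack()].
#' @param timeline A `psi_timeline` for Psi lookup (optional: `psi` is NA
#'   without it).
#' @return An `ov_series` data.frame: `time`, `a_cum`, `a_max`, `percent`,
#'   `psi`, one row per frame pair containing at least one event.
#' @export
accumulate_area <- function(events, stack, timeline = NULL) {
  stopifnot(inherits(events, "embolism_events"), inherits(stack, "image_stack"))
  ev <- events$events
  if (!nrow(ev)) stop("no detected events: degenerate series")
  per_pair <- stats::aggregate(area_px ~ pair, data = ev, FUN = sum)
  per_pair <- per_pair[order(per_pair$pair), ]
  n <- length(stack$times)
  mid <- (stack$times[per_pair$pair] + stack$times[per_pair$pair + 1L]) / 2
  a_cum <- cumsum(per_pair$area_px)
  a_max <- a_cum[length(a_cum)]
  if (a_max <= 0) stop("zero total embolized area: degenerate series")
  psi <- if (is.null(timeline)) rep(NA_real_, length(mid)) else
    suppressWarnings(psi_at(timeline, mid))
  structure(data.frame(time = mid, a_cum = a_cum, a_max = a_max,
                       percent = 100 * a_cum / a_max, psi = psi),
            class = c("ov_series", "data.frame"))
}

#' Run the full optical pipeline on a stack
#'
#' [difference_stack()], [detect_events()], [accumulate_area()] and
#' [fit_vc()] in sequence.
#'
#' @param stack An [image_stack()].
#' @param timeline A `psi_timeline`.
#' @param threshold,min_cluster,connectivity Passed to [detect_events()].
#' @param fit Fit the Weibull curve (default TRUE).
#' @return List with `series` (`ov_series`), `events`, and `fit` (`vc_fit`
#'   or NULL).
#' @export
ov_analyze <- function(stack, timeline, threshold = NULL, min_cluster = 4L,
                       connectivity = 8L, fit = TRUE) {
  maps <- difference_stack(stack)
  events <- detect_events(maps, threshold = threshold,
                          min_cluster = min_cluster, connectivity = connectivity)
  series <- accumulate_area(events, stack, timeline)
  res <- list(series = series, events = events, fit = NULL)
  if (fit) res$fit <- fit_vc(series)
  res
}

## ---- frame I/O ------------------------------------------------------------

write_pgm <- function(mat, path, maxval = 255L) {
  v <- round(pmin(pmax(mat, 0), maxval))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(mat), nrow(mat)), as.character(maxval)), con)
  # one image row per line, row-major as PGM requires
  writeLines(apply(v, 1L, paste, collapse = " "), con)
  invisible(path)
}

read_pgm <- function(path) {
  txt <- readLines(path)
  txt <- txt[!grepl("^#", txt)]
  if (txt[1L] != "P2") stop("only ASCII (P2) PGM is supported: ", path)
  tok <- scan(text = paste(txt[-1L], collapse = " "), what = numeric(),
              quiet = TRUE)
  nc <- tok[1L]; nr <- tok[2L]
  matrix(tok[-(1:3)], nrow = nr, ncol = nc, byrow = TRUE)
}

#' Write an image stack as a frame directory with a manifest
#'
#' Frames go to `dir/frame_0001.<ext>` etc. with a `manifest.csv`
#' (`frame,filename,time_s`). `"png"` writes 8-bit grayscale PNG (intensities
#' clamped to 0-255); `"pgm"` writes plain-text ASCII PGM, useful for
#' human-readable fixtures.
#'
#' @param stack An [image_stack()].
#' @param dir Output directory.
#' @param format `"png"` or `"pgm"`.
#' @export
write_image_stack <- function(stack, dir, format = c("png", "pgm")) {
  format <- match.arg(format)
  stopifnot(inherits(stack, "image_stack"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- sprintf("frame_%04d.%s", seq_along(stack$frames), format)
  for (i in seq_along(stack$frames)) {
    path <- file.path(dir, files[i])
    if (format == "png") {
      png::writePNG(pmin(pmax(stack$frames[[i]], 0), 255) / 255, path)
    } else {
      write_pgm(stack$frames[[i]], path)
    }
  }
  utils::write.csv(data.frame(frame = seq_along(files), filename = files,
                              time_s = stack$times),
                   file.path(dir, "manifest.csv"), row.names = FALSE,
                   quote = FALSE)
  invisible(dir)
}

#' Read an image stack from a frame directory with a manifest
#'
#' @param dir Directory containing `manifest.csv` (`frame,filename,time_s`)
#'   and grayscale PNG or ASCII PGM frames. PNG intensities are rescaled to
#'   0-255; multi-channel PNGs are averaged to grayscale.
#' @param pixel_scale Optional um per pixel to attach.
#' @return An [image_stack()].
#' @export
read_image_stack <- function(dir, pixel_scale = NULL) {
  man <- utils::read.csv(file.path(dir, "manifest.csv"), stringsAsFactors = FALSE)
  if (!all(c("frame", "filename", "time_s") %in% names(man)))
    stop("manifest.csv must have columns frame, filename, time_s")
  man <- man[order(man$time_s), ]
  frames <- lapply(file.path(dir, man$filename), function(p) {
    if (grepl("\\.pgm$", p, ignore.case = TRUE)) return(read_pgm(p))
    a <- png::readPNG(p)
    if (length(dim(a)) == 3L) a <- apply(a, c(1L, 2L), mean)
    a * 255
  })
  image_stack(frames, man$time_s, pixel_scale = pixel_scale)
}
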