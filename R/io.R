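# OME-TIFF and CSV input/output.
#
# Image data are written as a multi-page 16-bit TIFF holding 12-bit values,
# pages ordered z-fastest then channel then time (dimension order XYZCT).
# Acquisition metadata (sizes, channel names, physical pixel size, z step,
# frame interval) travel in a companion OME-XML file next to the TIFF
# (<stem>.companion.ome); the reader refuses files with missing metadata.

series_stem <- function(path) {
  sub("\\.ome\\.tiff?$|\\.tiff?$", "", path)
}

companion_path <- function(path) {
  paste0(series_stem(path), ".companion.ome")
}

#' Write an image series as OME-TIFF with companion metadata
#'
#' @param series An [image_series()] (lazy series are materialized
#'   frame-by-frame).
#' @param path Output TIFF path (`.ome.tiff` recommended).
#' @return `path`, invisibly. Also writes `<stem>.companion.ome`.
#' @export
write_series <- function(series, path) {
  nt <- n_frames(series)
  pages <- vector("list", 0)
  for (t in seq_len(nt)) {
    fr <- get_frame(series, t)  # C x Z x Y x X
    d <- dim(fr)
    for (ci in seq_len(d[1])) {
      for (z in seq_len(d[2])) {
        pages[[length(pages) + 1L]] <- matrix(fr[ci, z, , ], d[3], d[4]) / 65535
      }
    }
  }
  d <- dim(get_frame(series, 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "LZW",
                  reduce = FALSE)
  doc <- xml2::xml_new_root("OME")
  img <- xml2::xml_add_child(doc, "Image", Name = series_stem(basename(path)))
  xml2::xml_add_child(img, "Description",
                      paste0("t0_h=", format(series$t0, digits = 15)))
  px <- xml2::xml_add_child(
    img, "Pixels", DimensionOrder = "XYZCT", Type = "uint16",
    SizeX = d[4], SizeY = d[3], SizeZ = d[2],
    SizeC = d[1], SizeT = nt,
    PhysicalSizeX = series$pixel_size, PhysicalSizeY = series$pixel_size,
    PhysicalSizeZ = series$z_step, PhysicalSizeUnit = "um",
    TimeIncrement = series$dt, TimeIncrementUnit = "h")
  for (ci in seq_len(d[1])) {
    xml2::xml_add_child(px, "Channel", ID = paste0("Channel:", ci - 1),
                        Name = series$channel_names[ci])
  }
  xml2::write_xml(doc, companion_path(path))
  invisible(path)
}

xml_num_attr <- function(node, name, path) {
  v <- xml2::xml_attr(node, name)
  if (is.na(v)) {
    stop("metadata field '", name, "' missing from ", path)
  }
  as.numeric(v)
}

#' Read an OME-TIFF series written by [write_series()]
#'
#' Round-trips bit-exactly: 12-bit values stored in the 16-bit container are
#' recovered unchanged, as are frame interval, z step, pixel size and
#' channel names. Errors explicitly on a missing companion file or any
#' missing metadata field.
#'
#' @param path TIFF path.
#' @return An [image_series()].
#' @export
read_series <- function(path) {
  comp <- companion_path(path)
  if (!file.exists(comp)) {
    stop("companion metadata file not found: ", comp)
  }
  doc <- xml2::read_xml(comp)
  px <- xml2::xml_find_first(doc, ".//Pixels")
  if (inherits(px, "xml_missing")) stop("metadata field 'Pixels' missing from ", comp)
  sx <- xml_num_attr(px, "SizeX", comp); sy <- xml_num_attr(px, "SizeY", comp)
  sz <- xml_num_attr(px, "SizeZ", comp); sc <- xml_num_attr(px, "SizeC", comp)
  st <- xml_num_attr(px, "SizeT", comp)
  dt <- xml_num_attr(px, "TimeIncrement", comp)
  z_step <- xml_num_attr(px, "PhysicalSizeZ", comp)
  pixel_size <- xml_num_attr(px, "PhysicalSizeX", comp)
  ch <- xml2::xml_find_all(px, ".//Channel")
  if (length(ch) != sc) stop("metadata field 'Channel' missing from ", comp)
  channel_names <- xml2::xml_attr(ch, "Name")
  desc <- xml2::xml_text(xml2::xml_find_first(doc, ".//Description"))
  t0 <- 0
  if (!is.na(desc) && grepl("t0_h=", desc)) {
    t0 <- as.numeric(sub(".*t0_h=([-0-9.eE+]+).*", "\\1", desc))
  }
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (length(pages) != st * sc * sz) {
    stop("page count does not match metadata (", length(pages),
         " vs ", st * sc * sz, ")")
  }
  data <- array(0, dim = c(st, sc, sz, sy, sx))
  k <- 1L
  for (t in seq_len(st)) {
    for (ci in seq_len(sc)) {
      for (z in seq_len(sz)) {
        data[t, ci, z, , ] <- pages[[k]]
        k <- k + 1L
      }
    }
  }
  image_series(data, dt = dt, z_step = z_step,
               channel_names = channel_names, pixel_size = pixel_size,
               t0 = t0)
}

#' Write tracks (and merge events) to CSV
#'
#' One row per detection with its track id; merge events go to a sibling
#' file `<stem>_merges.csv`.
#'
#' @param tracks An `agg_tracks` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_tracks_csv <- function(tracks, path) {
  cols <- intersect(c("track_id", "frame", "time_h", "x", "y", "z_best",
                      "channel", "peak", "area", "event"),
                    names(tracks$detections))
  utils::write.csv(tracks$detections[, cols], path, row.names = FALSE)
  utils::write.csv(tracks$merges,
                   paste0(sub("\\.csv$", "", path), "_merges.csv"),
                   row.names = FALSE)
  invisible(path)
}

#' Write traces to tidy CSV
#'
#' @param traces A list of [new_trace()] objects (or a single one).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_traces_csv <- function(traces, path) {
  if (inherits(traces, "agg_trace")) traces <- list(traces)
  df <- do.call(rbind, lapply(traces, as.data.frame))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
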