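# File interfaces: CSV tables, a minimal multi-page TIFF codec for videos
# and label masks, and optional HDF5 writers.
#
# The TIFF codec exists because no TIFF package is available in the target
# environment; it writes/reads the plainest dialect only: little-endian,
# uncompressed, grayscale, 16-bit unsigned, one strip per page.

#' Write a video or label image as multi-page 16-bit TIFF
#'
#' Values are rounded and clamped to `[0, 65535]`.
#'
#' @param video H x W x T numeric array (or H x W matrix for one page).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_video_tiff <- function(video, path) {
  if (length(dim(video)) == 2) dim(video) <- c(dim(video), 1)
  stopifnot(length(dim(video)) == 3)
  H <- dim(video)[1]; W <- dim(video)[2]; nt <- dim(video)[3]
  con <- file(path, "wb")
  on.exit(close(con))
  w2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  entry <- function(tag, type, value) { w2(tag); w2(type); w4(1L)
    if (type == 3L) { w2(value); w2(0L) } else w4(value) }
  writeBin(charToRaw("II"), con); w2(42L); w4(8L)   # first IFD at byte 8
  n_entries <- 9L
  ifd_size <- 2L + 12L * n_entries + 4L
  page_bytes <- 2L * H * W
  pos <- 8L
  for (p in seq_len(nt)) {
    data_off <- pos + ifd_size
    w2(n_entries)
    entry(256L, 4L, W)           # ImageWidth
    entry(257L, 4L, H)           # ImageLength
    entry(258L, 3L, 16L)         # BitsPerSample
    entry(259L, 3L, 1L)          # Compression: none
    entry(262L, 3L, 1L)          # Photometric: BlackIsZero
    entry(273L, 4L, data_off)    # StripOffsets
    entry(277L, 3L, 1L)          # SamplesPerPixel
    entry(278L, 4L, H)           # RowsPerStrip
    entry(279L, 4L, page_bytes)  # StripByteCounts
    nxt <- if (p < nt) data_off + page_bytes else 0L
    w4(nxt)
    v <- round(video[, , p])
    v[v < 0] <- 0; v[v > 65535] <- 65535
    v <- as.integer(t(v))        # TIFF stores rows
    v[v > 32767L] <- v[v > 32767L] - 65536L   # two's complement for writeBin
    w2(v)
    pos <- nxt
  }
  invisible(path)
}

#' Read a multi-page TIFF written by [write_video_tiff()]
#'
#' Supports uncompressed little-endian grayscale 8/16-bit single-strip
#' pages only.
#'
#' @param path TIFF file.
#' @return H x W x T integer array.
#' @export
read_video_tiff <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  r2 <- function() readBin(con, "integer", size = 2, endian = "little",
                           signed = FALSE)
  r4 <- function() readBin(con, "integer", size = 4, endian = "little")
  magic <- rawToChar(readBin(con, "raw", 2))
  if (magic != "II" || r2() != 42L) stop("not a little-endian TIFF")
  off <- r4()
  pages <- list()
  while (off != 0L) {
    seek(con, off)
    n <- r2()
    tags <- list()
    for (i in seq_len(n)) {
      tag <- r2(); type <- r2(); cnt <- r4()
      val <- if (type == 3L) { v <- r2(); r2(); v } else r4()
      if (cnt != 1L) stop("unsupported TIFF: multi-valued tag ", tag)
      tags[[as.character(tag)]] <- val
    }
    off <- r4()
    W <- tags[["256"]]; H <- tags[["257"]]
    bits <- tags[["258"]] %||% 16L
    if ((tags[["259"]] %||% 1L) != 1L) stop("unsupported TIFF: compressed")
    seek(con, tags[["273"]])
    v <- readBin(con, "integer", n = H * W, size = bits / 8,
                 endian = "little", signed = FALSE)
    pages[[length(pages) + 1L]] <- matrix(v, H, W, byrow = TRUE)
  }
  H <- nrow(pages[[1]]); W <- ncol(pages[[1]])
  array(unlist(pages), dim = c(H, W, length(pages)))
}

#' Write a session as CSV files
#'
#' Creates `session.csv` (frame, t, stage, one binary column per event type,
#' B_ne), `epochs.csv` and `trajectory.csv` in `dir`.
#'
#' @param session a `behavior_session`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session_csv <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab <- data.frame(frame = seq_along(session$timestamps) - 1L,
                    t = session$timestamps, stage = session$stage)
  for (e in colnames(session$B)) tab[[paste0("B_", e)]] <- session$B[, e]
  tab$B_ne <- session$B_NE
  data.table::fwrite(tab, file.path(dir, "session.csv"))
  data.table::fwrite(session$epochs, file.path(dir, "epochs.csv"))
  data.table::fwrite(session$trajectory, file.path(dir, "trajectory.csv"))
  invisible(dir)
}

#' Read a session written by [write_session_csv()]
#'
#' @param dir directory holding the CSVs.
#' @return a `behavior_session` (without simulation config).
#' @export
read_session_csv <- function(dir) {
  tab <- as.data.frame(data.table::fread(file.path(dir, "session.csv")))
  epochs <- as.data.frame(data.table::fread(file.path(dir, "epochs.csv")))
  traj_path <- file.path(dir, "trajectory.csv")
  traj <- if (file.exists(traj_path))
    as.data.frame(data.table::fread(traj_path)) else NULL
  bcols <- grep("^B_", names(tab), value = TRUE)
  bcols <- setdiff(bcols, "B_ne")
  B <- as.matrix(tab[, bcols, drop = FALSE])
  colnames(B) <- sub("^B_", "", bcols)
  out <- list(timestamps = tab$t, stage = tab$stage, B = B,
              B_NE = tab$B_ne, epochs = epochs,
              trajectory = if (!is.null(traj))
                trajectory(traj$t, traj$x, traj$y) else NULL,
              targets = NULL, config = NULL)
  class(out) <- "behavior_session"
  out
}

#' Write / read a dF/F matrix as CSV
#'
#' Wide format: a `t` column followed by one column per neuron.
#'
#' @param dff a [dff_matrix()].
#' @param path CSV file.
#' @return `path` / a [dff_matrix()].
#' @export
write_dff_csv <- function(dff, path) {
  tab <- data.frame(t = dff$timestamps)
  M <- t(dff$C)
  colnames(M) <- paste0("n", dff$neuron_ids)
  data.table::fwrite(cbind(tab, as.data.frame(M)), path)
  invisible(path)
}

#' @rdname write_dff_csv
#' @export
read_dff_csv <- function(path) {
  tab <- as.data.frame(data.table::fread(path))
  dff_matrix(t(as.matrix(tab[, -1, drop = FALSE])), tab$t,
             neuron_ids = as.integer(sub("^n", "", names(tab)[-1])))
}

#' Write a dF/F matrix to HDF5 (optional)
#'
#' Requires the `rhdf5` package; errors with a clear message otherwise.
#'
#' @param dff a [dff_matrix()].
#' @param path HDF5 file.
#' @return `path`, invisibly.
#' @export
write_dff_h5 <- function(dff, path) {
  if (!requireNamespace("rhdf5", quietly = TRUE))
    stop("write_dff_h5 requires the 'rhdf5' package; use write_dff_csv()")
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(dff$C, path, "dff")
  rhdf5::h5write(dff$timestamps, path, "timestamps")
  rhdf5::H5close()
  invisible(path)
}

#' Read a pipeline config file (JSON, or YAML when available)
#'
#' @param path config file; extension decides the parser.
#' @return named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  if (grepl("\\.(ya?ml)$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML configs require the 'yaml' package; use JSON")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}
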