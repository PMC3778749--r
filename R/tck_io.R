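#' Write a tractogram in TCK (MRtrix) format
#'
#' Streamline points are stored as little-endian 32-bit float triplets in
#' world mm, with `(NaN, NaN, NaN)` separating streamlines and
#' `(Inf, Inf, Inf)` terminating the file, after a plain-text header.
#' A JSON summary (streamline count, termination-reason histogram) is written
#' alongside when `summary = TRUE`.
#'
#' @param tract a [tractogram()].
#' @param path output `.tck` path.
#' @param summary also write `<path>.json` with counts, default TRUE.
#' @return invisibly, `path`.
#' @export
write_tck <- function(tract, path, summary = TRUE) {
  stopifnot(inherits(tract, "tractogram"))
  n <- length(tract$streamlines)
  header_lines <- c("mrtrix tracks",
                    "datatype: Float32LE",
                    sprintf("count: %d", n))
  # the 'file: . <offset>' line length feeds back into the offset; fix by
  # padding the offset field to a stable width
  offset_field <- 1000L
  repeat {
    lines <- c(header_lines, sprintf("file: . %d", offset_field), "END")
    header <- paste0(paste(lines, collapse = "\n"), "\n")
    need <- nchar(header, type = "bytes")
    if (need <= offset_field) break
    offset_field <- offset_field * 2L
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  pad <- offset_field - nchar(header, type = "bytes")
  if (pad > 0) writeBin(raw(pad), con)
  for (s in tract$streamlines) {
    writeBin(as.numeric(t(s$points)), con, size = 4, endian = "little")
    writeBin(as.numeric(c(NaN, NaN, NaN)), con, size = 4, endian = "little")
  }
  writeBin(as.numeric(c(Inf, Inf, Inf)), con, size = 4, endian = "little")
  if (summary) {
    jsonlite::write_json(
      list(n_streamlines = n,
           termination_reasons = as.list(termination_summary(tract))),
      paste0(path, ".json"), auto_unbox = TRUE)
  }
  invisible(path)
}

#' Read a TCK (MRtrix) streamline file
#'
#' @param path `.tck` path.
#' @param affine,grid_shape reference geometry to attach to the returned
#'   [tractogram()] (the TCK format itself stores world-mm points only).
#' @return a [tractogram()]; seed voxels and termination reasons are not part
#'   of the format and are returned as `NA`.
#' @export
read_tck <- function(path, affine = diag(4), grid_shape = c(1L, 1L, 1L)) {
  if (!file.exists(path)) stop_parse(paste("missing TCK file:", path))
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character(0)
  repeat {
    line <- readLines(con, n = 1, warn = FALSE)
    if (length(line) == 0) stop_parse(sprintf("TCK file '%s': header without END", path))
    header <- c(header, line)
    if (line == "END") break
  }
  if (header[1] != "mrtrix tracks") stop_parse(sprintf("'%s' is not a TCK file", path))
  off_line <- grep("^file: \\.", header, value = TRUE)
  if (length(off_line) != 1) stop_parse(sprintf("TCK file '%s': missing file offset", path))
  offset <- as.integer(sub("^file: \\. ", "", off_line))
  seek(con, offset)
  raw_data <- readBin(con, "numeric", n = file.size(path), size = 4, endian = "little")
  pts <- matrix(raw_data, ncol = 3, byrow = TRUE)
  streamlines <- list()
  current <- list()
  for (i in seq_len(nrow(pts))) {
    p <- pts[i, ]
    if (all(is.infinite(p))) break
    if (all(is.nan(p))) {
      if (length(current)) {
        streamlines[[length(streamlines) + 1L]] <-
          list(points = do.call(rbind, current), seed_voxel = rep(NA_integer_, 3),
               termination_reasons = c(NA_character_, NA_character_))
      }
      current <- list()
    } else {
      current[[length(current) + 1L]] <- p
    }
  }
  tractogram(streamlines, affine, grid_shape)
}
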