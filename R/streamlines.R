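#' Streamline sets and the TCK container
#'
#' A `streamline_set` is a list of n x 3 matrices of ordered 3-D points in
#' world mm. On disk the package uses the MRtrix TCK dialect: a text header
#' (`mrtrix tracks`, `datatype: Float32LE`, `count`, `file: . <offset>`,
#' `END`), then little-endian float32 triplets with each streamline terminated
#' by a NaN triplet and the stream by an Inf triplet. An empty set is a valid
#' container with count 0.
#'
#' @param streamlines list of n x 3 numeric matrices (world mm).
#' @return an object of class `streamline_set`.
#' @export
streamline_set <- function(streamlines) {
  stopifnot(is.list(streamlines))
  for (s in streamlines)
    if (!is.matrix(s) || ncol(s) != 3L)
      stop("each streamline must be an n x 3 matrix")
  structure(streamlines, class = "streamline_set")
}

#' @export
print.streamline_set <- function(x, ...) {
  np <- if (length(x)) vapply(x, nrow, 1L) else integer()
  cat(sprintf("<streamline_set> %d streamlines, %s points each (median %s)\n",
              length(x),
              if (length(np)) paste0(min(np), "-", max(np)) else "0",
              if (length(np)) stats::median(np) else 0))
  invisible(x)
}

#' @export
length.streamline_set <- function(x) length(unclass(x))

#' @rdname streamline_set
#' @param path output TCK file path.
#' @export
write_streamlines <- function(streamlines, path) {
  if (!inherits(streamlines, "streamline_set"))
    streamlines <- streamline_set(streamlines)
  n <- length(streamlines)
  fixed <- c("mrtrix tracks", "datatype: Float32LE",
             sprintf("count: %d", n))
  # the offset names the first binary byte and depends on its own digits
  offset <- 0L
  repeat {
    hdr <- c(fixed, sprintf("file: . %d", offset), "END")
    new_off <- sum(nchar(hdr, type = "bytes")) + length(hdr)  # +\n each
    if (new_off == offset) break
    offset <- new_off
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(fixed, sprintf("file: . %d", offset), "END"), con, sep = "\n")
  for (s in unclass(streamlines)) {
    writeBin(as.numeric(t(s)), con, size = 4L, endian = "little")
    writeBin(rep(NaN, 3), con, size = 4L, endian = "little")
  }
  writeBin(rep(Inf, 3), con, size = 4L, endian = "little")
  invisible(path)
}

#' @rdname streamline_set
#' @export
read_streamlines <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character()
  repeat {
    line <- readLines(con, n = 1L)
    if (!length(line)) stop("truncated TCK header")
    if (line == "END") break
    hdr <- c(hdr, line)
  }
  if (!length(hdr) || hdr[1] != "mrtrix tracks")
    stop("not a TCK streamline file")
  get_field <- function(key) {
    m <- grep(paste0("^", key, ":"), hdr, value = TRUE)
    if (!length(m)) return(NA_character_)
    trimws(sub(paste0("^", key, ":"), "", m[1]))
  }
  dt <- get_field("datatype")
  if (!is.na(dt) && dt != "Float32LE")
    stop("unsupported TCK datatype: ", dt)
  off <- as.integer(sub("^\\.\\s*", "", get_field("file")))
  seek(con, off)
  raw <- readBin(con, numeric(), n = file.size(path), size = 4L,
                 endian = "little")
  pts <- matrix(raw, ncol = 3L, byrow = TRUE)
  out <- list()
  start <- 1L
  for (r in seq_len(nrow(pts))) {
    if (is.infinite(pts[r, 1])) break
    if (is.nan(pts[r, 1])) {
      out[[length(out) + 1L]] <- if (r > start)
        pts[start:(r - 1L), , drop = FALSE] else matrix(numeric(), 0L, 3L)
      start <- r + 1L
    }
  }
  declared <- as.integer(get_field("count"))
  if (!is.na(declared) && declared != length(out))
    stop(sprintf("TCK header declares %d streamlines but %d were read",
                 declared, length(out)))
  streamline_set(out)
}
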