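# Minimal ABIF (Applied Biosystems ".ab1") reader and writer.
#
# Only the tags needed for Quick Quality Control are handled: the analyzed
# trace channels DATA9-DATA12, the primary basecalls PBAS1, the per-call
# peak scan indices PLOC1 and the filter-wheel order FWO_1 that maps the
# four DATA channels to bases. All multi-byte integers are big-endian, as
# required by the format. The writer produces minimal but fully valid files
# so the reader is exercised bit-level by synthetic fixtures.

ABIF_VERSION <- 101L
DIR_ENTRY_SIZE <- 28L

raw_int <- function(x, size) {
  writeBin(as.integer(x), raw(), size = size, endian = "big")
}

dir_entry <- function(name, number, elementtype, elementsize, numelements,
                      datasize, dataoffset_raw) {
  stopifnot(nchar(name) == 4L, length(dataoffset_raw) == 4L)
  c(charToRaw(name), raw_int(number, 4L), raw_int(elementtype, 2L),
    raw_int(elementsize, 2L), raw_int(numelements, 4L),
    raw_int(datasize, 4L), dataoffset_raw, raw_int(0L, 4L))
}

#' Write a minimal ABIF chromatogram file
#'
#' @param traces numeric matrix, scans x 4 channels, columns in filter-wheel
#'   order `fwo` (default `"GATC"`, the usual dye order)
#' @param basecalls character scalar of primary base calls
#' @param peak_locations 0-based scan index of each call's peak
#' @param path output file path (conventionally `.ab1`)
#' @param fwo filter-wheel order: base identity of DATA9..DATA12
#' @return `path`, invisibly
#' @export
write_abif <- function(traces, basecalls, peak_locations, path,
                       fwo = "GATC") {
  stopifnot(is.matrix(traces), ncol(traces) == 4L, nchar(fwo) == 4L,
            nchar(basecalls) == length(peak_locations),
            all(peak_locations >= 0L & peak_locations < nrow(traces)))
  traces <- round(pmin(pmax(traces, 0), 32000))
  nscans <- nrow(traces)
  ncalls <- nchar(basecalls)

  blocks <- list()   # raw data blocks > 4 bytes, in file order
  entries <- list()
  offset <- 128L     # data area starts right after the 128-byte header
  add_entry <- function(name, number, etype, esize, n, data_raw) {
    datasize <- length(data_raw)
    if (datasize <= 4L) {
      off_raw <- c(data_raw, raw(4L - datasize))
    } else {
      off_raw <- raw_int(offset, 4L)
      blocks[[length(blocks) + 1L]] <<- data_raw
      offset <<- offset + datasize
    }
    entries[[length(entries) + 1L]] <<-
      dir_entry(name, number, etype, esize, n, datasize, off_raw)
  }
  for (ch in 1:4) {
    add_entry("DATA", 8L + ch, 4L, 2L, nscans,
              raw_int(traces[, ch], 2L))
  }
  add_entry("PBAS", 1L, 2L, 1L, ncalls, charToRaw(basecalls))
  add_entry("PLOC", 1L, 4L, 2L, ncalls, raw_int(peak_locations, 2L))
  add_entry("FWO_", 1L, 2L, 1L, 4L, charToRaw(toupper(fwo)))

  dir_offset <- offset
  n_entries <- length(entries)
  tdir <- dir_entry("tdir", 1L, 1023L, DIR_ENTRY_SIZE, n_entries,
                    n_entries * DIR_ENTRY_SIZE, raw_int(dir_offset, 4L))
  header <- c(charToRaw("ABIF"), raw_int(ABIF_VERSION, 2L), tdir)
  header <- c(header, raw(128L - length(header)))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(header, do.call(c, blocks), do.call(c, entries)), con)
  invisible(path)
}

read_raw_int <- function(bytes, offset, size, n = 1L, signed = TRUE) {
  readBin(bytes[(offset + 1L):(offset + size * n)], "integer", n = n,
          size = size, endian = "big", signed = signed)
}

#' Read an ABIF chromatogram
#'
#' Parses the ABIF directory and extracts the analyzed traces (DATA9-12),
#' primary basecalls (PBAS1), peak locations (PLOC1) and filter-wheel order
#' (FWO_1). Channel columns are reordered to A/C/G/T regardless of dye
#' order. `channels` holds, for each base call, the four channel intensities
#' at the call's peak scan.
#'
#' @param path an ABIF (`.ab1`) file
#' @return object of class `chromatogram_trace`: `channels` (calls x 4
#'   matrix, columns A, C, G, T), `basecalls`, `peak_locations` (0-based
#'   scan indices), `traces` (scans x 4 matrix, columns A, C, G, T)
#' @export
read_abif <- function(path) {
  bytes <- readBin(path, "raw", n = file.size(path))
  if (length(bytes) < 128L || !identical(rawToChar(bytes[1:4]), "ABIF"))
    stop("not an ABIF chromatogram: ", path, call. = FALSE)
  n_entries <- read_raw_int(bytes, 18L, 4L)
  dir_offset <- read_raw_int(bytes, 26L, 4L)
  if (dir_offset + n_entries * DIR_ENTRY_SIZE > length(bytes))
    stop("not an ABIF chromatogram: truncated directory in ", path,
         call. = FALSE)
  tags <- list()
  for (i in seq_len(n_entries)) {
    off <- dir_offset + (i - 1L) * DIR_ENTRY_SIZE
    name <- rawToChar(bytes[(off + 1L):(off + 4L)])
    number <- read_raw_int(bytes, off + 4L, 4L)
    etype <- read_raw_int(bytes, off + 8L, 2L)
    n <- read_raw_int(bytes, off + 12L, 4L)
    datasize <- read_raw_int(bytes, off + 16L, 4L)
    data_raw <- if (datasize <= 4L)
      bytes[(off + 21L):(off + 20L + datasize)]
    else {
      data_off <- read_raw_int(bytes, off + 20L, 4L)
      if (data_off + datasize > length(bytes))
        stop("not an ABIF chromatogram: truncated data block in ", path,
             call. = FALSE)
      bytes[(data_off + 1L):(data_off + datasize)]
    }
    value <- switch(as.character(etype),
      "2" = rawToChar(data_raw),
      "4" = readBin(data_raw, "integer", n = n, size = 2L, endian = "big"),
      data_raw)
    tags[[paste0(name, number)]] <- value
  }
  needed <- c("DATA9", "DATA10", "DATA11", "DATA12", "PBAS1", "PLOC1")
  if (!all(needed %in% names(tags)))
    stop("not an ABIF chromatogram: missing tag(s) ",
         paste(setdiff(needed, names(tags)), collapse = ", "), call. = FALSE)
  fwo <- if ("FWO_1" %in% names(tags)) tags$FWO_1 else "GATC"
  raw_traces <- cbind(tags$DATA9, tags$DATA10, tags$DATA11, tags$DATA12)
  colnames(raw_traces) <- strsplit(fwo, "")[[1]]
  traces <- raw_traces[, STRICT_BASES, drop = FALSE]
  ploc <- tags$PLOC1
  basecalls <- tags$PBAS1
  if (nchar(basecalls) != length(ploc))
    stop("not an ABIF chromatogram: basecall/peak-location length mismatch",
         call. = FALSE)
  if (any(ploc < 0L | ploc >= nrow(traces)))
    stop("not an ABIF chromatogram: peak location outside trace", call. = FALSE)
  if (any(traces < 0)) stop("negative channel intensities", call. = FALSE)
  channels <- traces[ploc + 1L, , drop = FALSE]
  rownames(channels) <- NULL
  structure(list(channels = channels, basecalls = basecalls,
                 peak_locations = as.integer(ploc), traces = traces),
            class = "chromatogram_trace")
}

#' @export
print.chromatogram_trace <- function(x, ...) {
  cat(sprintf("<chromatogram_trace> %d calls, %d scans\n  %s%s\n",
              nchar(x$basecalls), nrow(x$traces),
              substr(x$basecalls, 1, 50),
              if (nchar(x$basecalls) > 50) "..." else ""))
  invisible(x)
}
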