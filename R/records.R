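#' Sharded binary record store for training patches
#'
#' Training patches are serialised into length-delimited binary shards, one
#' record per patch, holding the 8-bit image bytes together with the file
#' name, height, width and channel count (plus origin and level-0 span so a
#' patch round-trips losslessly). Shards are named
#' `<slide>-<level>-NNNNN.rec` and records are grouped by slide and
#' resolution level in stream order.
#'
#' Images are quantised to 8 bits on write and decoded back to `[0, 1]` as
#' `byte / 255`; inputs whose intensities are already multiples of `1/255`
#' (e.g. anything decoded from PNG) round-trip bit-exactly.
#'
#' @param patches list of `pcead_patch`.
#' @param out_dir writable output directory (created if missing).
#' @param shard_size maximum records per shard (>= 1).
#' @return Character vector of shard paths (empty for an empty input).
#' @export
write_record_shards <- function(patches, out_dir, shard_size = 64L) {
  stopifnot(shard_size >= 1)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (length(patches) == 0L) return(character(0))
  key <- vapply(patches, function(p) paste0(p$slide, "-", p$size), "")
  paths <- character(0)
  for (k in unique(key)) {
    grp <- patches[key == k]
    n_shards <- ceiling(length(grp) / shard_size)
    for (i in seq_len(n_shards)) {
      lo <- (i - 1L) * shard_size + 1L
      hi <- min(i * shard_size, length(grp))
      path <- file.path(out_dir, sprintf("%s-%05d.rec", k, i))
      write_shard(grp[lo:hi], path)
      paths <- c(paths, path)
    }
  }
  paths
}

REC_MAGIC <- "PCDR1"

write_shard <- function(patches, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(REC_MAGIC), con)
  for (p in patches) {
    name <- sprintf("%s_x%d_y%d", p$slide, p$x, p$y)
    nb <- charToRaw(name)
    bytes <- as.raw(pmin(pmax(round(p$image * 255), 0), 255))
    meta <- as.integer(c(p$size, p$size, dim(p$image)[3], p$x, p$y, p$span))
    payload_len <- 2L + length(nb) + 6L * 4L + length(bytes)
    writeBin(payload_len, con, size = 4L, endian = "little")
    writeBin(length(nb), con, size = 2L, endian = "little")
    writeBin(nb, con)
    writeBin(meta, con, size = 4L, endian = "little")
    writeBin(bytes, con)
  }
  invisible(path)
}

#' @rdname write_record_shards
#' @param paths character vector of shard paths.
#' @param level optional resolution level (patch side in pixels); only
#'   records at that level are returned.
#' @return For `read_record_shards()`, a list of `pcead_patch`.
#' @export
read_record_shards <- function(paths, level = NULL) {
  out <- list()
  for (path in paths) {
    raw <- readBin(path, "raw", n = file.size(path))
    if (length(raw) < 5L || rawToChar(raw[1:5]) != REC_MAGIC)
      stop("corrupted record shard (bad magic): ", path)
    pos <- 6L
    rec <- 0L
    while (pos <= length(raw)) {
      rec <- rec + 1L
      bad <- function(why) stop(sprintf(
        "corrupted record shard %s at record %d: %s", path, rec, why))
      if (pos + 3L > length(raw)) bad("truncated length prefix")
      plen <- readBin(raw[pos:(pos + 3L)], "integer", size = 4L,
                      endian = "little")
      pos <- pos + 4L
      if (plen < 26L || pos + plen - 1L > length(raw))
        bad("payload length out of range")
      payload <- raw[pos:(pos + plen - 1L)]
      pos <- pos + plen
      nlen <- readBin(payload[1:2], "integer", size = 2L, signed = FALSE,
                      endian = "little")
      if (2L + nlen + 24L > plen) bad("name length out of range")
      name <- rawToChar(payload[2L + seq_len(nlen)])
      meta <- readBin(payload[(2L + nlen + 1L):(2L + nlen + 24L)],
                      "integer", n = 6L, size = 4L, endian = "little")
      h <- meta[1]; w <- meta[2]; ch <- meta[3]
      nbytes <- h * w * ch
      if (2L + nlen + 24L + nbytes != plen) bad("image byte count mismatch")
      if (!is.null(level) && h != level) next
      bytes <- payload[(2L + nlen + 24L + 1L):plen]
      img <- array(as.integer(bytes) / 255, c(h, w, ch))
      slide <- sub("_x[0-9]+_y[0-9]+$", "", name)
      out[[length(out) + 1L]] <-
        new_patch(img, slide, meta[4], meta[5], span = meta[6])
    }
  }
  out
}

#' List record shards under a directory
#'
#' @param dir directory containing `.rec` shards.
#' @param level optional resolution level filter applied to the file name.
#' @return Character vector of shard paths.
#' @export
list_record_shards <- function(dir, level = NULL) {
  paths <- sort(list.files(dir, pattern = "\\.rec$", full.names = TRUE))
  if (!is.null(level))
    paths <- paths[grepl(sprintf("-%d-[0-9]+\\.rec$", level), paths)]
  paths
}
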