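# Minimal multi-page TIFF I/O for 32-bit float volumes (little-endian,
# uncompressed, one strip per page). No pre-installed R package reads or
# writes TIFF in this stack, so the subset of the format the pipeline needs
# is implemented here; voxel pitch travels in a JSON ImageDescription tag.

TIFF_TAGS <- c(width = 256L, height = 257L, bits = 258L, compression = 259L,
               photometric = 262L, description = 270L, strip_offset = 273L,
               spp = 277L, rows_per_strip = 278L, strip_bytes = 279L,
               sample_format = 339L)

u16le <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
u32le <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

tiff_entry <- function(tag, type, count, value_raw) {
  # value_raw must already be padded to 4 bytes (inline value) or be an offset
  c(u16le(tag), u16le(type), u32le(count), value_raw)
}

#' Write a volume as multi-page TIFF
#'
#' One page per z-slice, 32-bit IEEE float, uncompressed, little-endian;
#' voxel pitch and origin are stored as JSON in the first page's
#' ImageDescription. Byte-exact round trip with [read_volume()].
#'
#' @param volume A `recon_volume` or 3D numeric array (pitch then defaults
#'   to 2 x 2 x 3 um).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  a <- as_volume_array(volume)
  stopifnot(length(dim(a)) == 3)
  pitch <- volume_pitch(volume)
  meta <- jsonlite::toJSON(list(voxel_pitch_um = pitch,
                                origin_um = if (inherits(volume, "recon_volume"))
                                  volume$origin_um else c(0, 0, 0)),
                           auto_unbox = FALSE, digits = NA)
  desc <- c(charToRaw(as.character(meta)), as.raw(0L))
  if (length(desc) %% 2) desc <- c(desc, as.raw(0L))
  d <- dim(a)
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  page_bytes <- nx * ny * 4L
  n_tags <- c(11L, rep(10L, max(0L, nz - 1L)))  # description on page 1 only
  ifd_size <- n_tags * 12L + 2L + 4L
  desc_off <- 8L
  data_off <- desc_off + length(desc)
  page_off <- data_off + (seq_len(nz) - 1L) * page_bytes
  ifd0 <- data_off + nz * page_bytes
  ifd_off <- ifd0 + cumsum(c(0L, ifd_size[-nz]))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(as.raw(0x49), as.raw(0x49), u16le(42L), u32le(ifd_off[1])), con)
  writeBin(desc, con)
  for (k in seq_len(nz))
    writeBin(as.numeric(a[, , k]), con, size = 4, endian = "little")
  for (k in seq_len(nz)) {
    entries <- list(
      tiff_entry(256L, 3L, 1L, c(u16le(nx), u16le(0L))),
      tiff_entry(257L, 3L, 1L, c(u16le(ny), u16le(0L))),
      tiff_entry(258L, 3L, 1L, c(u16le(32L), u16le(0L))),
      tiff_entry(259L, 3L, 1L, c(u16le(1L), u16le(0L))),
      tiff_entry(262L, 3L, 1L, c(u16le(1L), u16le(0L))))
    if (k == 1L)
      entries <- c(entries, list(tiff_entry(270L, 2L, length(desc),
                                            u32le(desc_off))))
    entries <- c(entries, list(
      tiff_entry(273L, 4L, 1L, u32le(page_off[k])),
      tiff_entry(277L, 3L, 1L, c(u16le(1L), u16le(0L))),
      tiff_entry(278L, 3L, 1L, c(u16le(ny), u16le(0L))),
      tiff_entry(279L, 4L, 1L, u32le(page_bytes)),
      tiff_entry(339L, 3L, 1L, c(u16le(3L), u16le(0L)))))
    nxt <- if (k < nz) ifd_off[k + 1L] else 0L
    writeBin(c(u16le(length(entries)), unlist(entries), u32le(nxt)), con)
  }
  invisible(path)
}

rd_u16 <- function(bytes, off) {
  readBin(bytes[(off + 1):(off + 2)], "integer", size = 2, endian = "little",
          signed = FALSE)
}
rd_u32 <- function(bytes, off) {
  v <- readBin(bytes[(off + 1):(off + 4)], "integer", size = 4,
               endian = "little")
  if (v < 0) stop("TIFF offset exceeds supported range", call. = FALSE)
  v
}

#' Read a multi-page TIFF volume
#'
#' Reads the uncompressed 32-bit-float multi-page layout produced by
#' [write_volume()] (and by common writers using one strip per page).
#' Truncated or compressed files raise an error rather than returning
#' silent garbage.
#'
#' @param path File path.
#' @return A `recon_volume` (pitch restored from the embedded metadata when
#'   present, else 2 x 2 x 3 um).
#' @export
read_volume <- function(path) {
  stop_if(!file.exists(path), "file not found: ", path)
  bytes <- readBin(path, "raw", file.info(path)$size)
  stop_if(length(bytes) < 8, "truncated TIFF: ", path)
  stop_if(!(bytes[1] == 0x49 && bytes[2] == 0x49 && rd_u16(bytes, 2) == 42L),
          "not a little-endian TIFF: ", path)
  need <- function(n) stop_if(n > length(bytes), "truncated TIFF: ", path)
  ifd_off <- rd_u32(bytes, 4)
  slices <- list()
  meta <- NULL
  nx <- ny <- NULL
  while (ifd_off != 0) {
    need(ifd_off + 2)
    n_ent <- rd_u16(bytes, ifd_off)
    need(ifd_off + 2 + n_ent * 12 + 4)
    tags <- list()
    for (e in seq_len(n_ent)) {
      base <- ifd_off + 2 + (e - 1) * 12
      tag <- rd_u16(bytes, base)
      type <- rd_u16(bytes, base + 2)
      count <- rd_u32(bytes, base + 4)
      val <- if (type == 3L && count == 1L) rd_u16(bytes, base + 8)
             else rd_u32(bytes, base + 8)
      tags[[as.character(tag)]] <- list(type = type, count = count, value = val)
    }
    gettag <- function(t) tags[[as.character(t)]]
    w <- gettag(256L); h <- gettag(257L)
    stop_if(is.null(w) || is.null(h), "TIFF page missing dimensions")
    bits <- gettag(258L)
    comp <- gettag(259L)
    sf <- gettag(339L)
    stop_if(!is.null(comp) && comp$value != 1L, "compressed TIFF unsupported")
    stop_if(is.null(bits) || bits$value != 32L ||
              is.null(sf) || sf$value != 3L,
            "only 32-bit float TIFF supported")
    off <- gettag(273L)$value
    nbytes <- gettag(279L)$value
    stop_if(nbytes != w$value * h$value * 4L, "strip size mismatch")
    need(off + nbytes)
    px <- readBin(bytes[(off + 1):(off + nbytes)], "double",
                  n = w$value * h$value, size = 4, endian = "little")
    if (is.null(nx)) { nx <- w$value; ny <- h$value }
    stop_if(nx != w$value || ny != h$value, "page shape mismatch")
    slices[[length(slices) + 1L]] <- px
    dsc <- gettag(270L)
    if (!is.null(dsc) && is.null(meta)) {
      need(dsc$value + dsc$count)
      rw <- bytes[(dsc$value + 1):(dsc$value + dsc$count)]
      txt <- rawToChar(rw[rw != as.raw(0)])
      meta <- tryCatch(jsonlite::fromJSON(txt), error = function(e) NULL)
    }
    ifd_off <- rd_u32(bytes, ifd_off + 2 + n_ent * 12)
  }
  stop_if(!length(slices), "TIFF contains no pages")
  amp <- array(unlist(slices), dim = c(nx, ny, length(slices)))
  pitch <- if (!is.null(meta$voxel_pitch_um)) as.numeric(meta$voxel_pitch_um)
           else c(2, 2, 3)
  origin <- if (!is.null(meta$origin_um)) as.numeric(meta$origin_um)
            else c(0, 0, 0)
  new_recon_volume(amp, pitch, origin_um = origin,
                   provenance = list(path = path))
}
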