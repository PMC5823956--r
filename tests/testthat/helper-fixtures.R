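# Fixture builders. The ImageJ ROI bytes and the stored-zip writer are
# constructed here directly from the file-format layouts, independently of
# the package's own reader/writer, so round trips are genuine format checks.

square_mask <- function(h, w, rows, cols, label = "sq") {
  m <- matrix(FALSE, h, w)
  m[rows, cols] <- TRUE
  roi_mask(m, label)
}

# discrete annulus by pixel-centre distance from (cy, cx) (0-based centre)
annulus_mask <- function(h, w, cy, cx, r_in, r_out, label = "ann") {
  rr <- matrix(seq_len(h) - 0.5, h, w)
  cc <- matrix(seq_len(w) - 0.5, h, w, byrow = TRUE)
  d <- sqrt((rr - cy)^2 + (cc - cx)^2)
  roi_mask(d >= r_in & d <= r_out, label)
}

# ---- ImageJ .roi byte layout (big-endian): "Iout", version, type byte at
# offset 6, bbox shorts at 8..15, n at 16, coords (polygon) from offset 64
ij_roi_bytes <- function(type, top, left, bottom, right, xs = NULL,
                         ys = NULL) {
  type_code <- c(polygon = 0L, rect = 1L, oval = 2L, freehand = 7L)[[type]]
  con <- rawConnection(raw(0), "wb")
  on.exit(close(con))
  writeBin(charToRaw("Iout"), con)
  writeBin(227L, con, size = 2, endian = "big")
  writeBin(as.raw(c(type_code, 0L)), con)
  n <- length(xs)
  writeBin(as.integer(c(top, left, bottom, right, n)), con, size = 2,
           endian = "big")
  writeBin(raw(64 - 18), con)
  if (n > 0) {
    writeBin(as.integer(xs - left), con, size = 2, endian = "big")
    writeBin(as.integer(ys - top), con, size = 2, endian = "big")
  }
  rawConnectionValue(con)
}

# ---- minimal ZIP writer (stored entries, no compression) ----
crc32_table <- local({
  tab <- integer(256)
  for (i in 0:255) {
    crc <- i
    for (k in 1:8) {
      crc <- if (bitwAnd(crc, 1L) != 0L)
        bitwXor(bitwShiftR(crc, 1), -306674912L)  # 0xEDB88320 as signed
      else bitwShiftR(crc, 1)                     # bitwShiftR is logical
    }
    tab[i + 1] <- crc
  }
  tab
})

crc32 <- function(bytes) {
  crc <- -1L  # 0xFFFFFFFF
  for (b in as.integer(bytes)) {
    idx <- bitwAnd(bitwXor(crc, b), 255L)
    crc <- bitwXor(bitwShiftR(crc, 8), crc32_table[idx + 1])
  }
  bitwXor(crc, -1L)
}

u32le <- function(x) {  # signed 32-bit int -> 4 little-endian raw bytes
  writeBin(as.integer(x), raw(), size = 4, endian = "little")
}
u16le <- function(x) writeBin(as.integer(x), raw(), size = 2,
                              endian = "little")

# files: named list of raw vectors; writes a stored (uncompressed) zip
write_stored_zip <- function(files, path) {
  out <- raw(0)
  central <- raw(0)
  offsets <- integer(length(files))
  for (i in seq_along(files)) {
    name <- charToRaw(names(files)[i])
    data <- files[[i]]
    crc <- crc32(data)
    offsets[i] <- length(out)
    local_hdr <- c(u32le(67324752L),        # PK\3\4
                   u16le(20), u16le(0), u16le(0), u16le(0), u16le(0),
                   u32le(crc), u32le(length(data)), u32le(length(data)),
                   u16le(length(name)), u16le(0))
    out <- c(out, local_hdr, name, data)
    central <- c(central,
                 u32le(33639248L),          # PK\1\2
                 u16le(20), u16le(20), u16le(0), u16le(0), u16le(0),
                 u16le(0), u32le(crc), u32le(length(data)),
                 u32le(length(data)), u16le(length(name)), u16le(0),
                 u16le(0), u16le(0), u16le(0), u32le(0),
                 u32le(offsets[i]), name)
  }
  cd_off <- length(out)
  eocd <- c(u32le(101010256L),              # PK\5\6
            u16le(0), u16le(0), u16le(length(files)), u16le(length(files)),
            u32le(length(central)), u32le(cd_off), u16le(0))
  writeBin(c(out, central, eocd), path)
  invisible(path)
}

# small fast scene for pipeline-level tests: 20 s movie, coarse field
small_scene <- function(seed = 1, case = "A", duration = 20) {
  benchmark_scene(case, seed = seed, duration = duration)
}
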