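# Minimal NPY (v1.0) and NPZ (stored zip) IO.
#
# No installed package reads or writes NumPy containers, so the subset this
# package needs is implemented here: 1-D arrays and scalars of float64,
# int64 and fixed-width unicode. The zip writer emits stored (uncompressed)
# entries with zeroed timestamps, which makes NPZ output byte-stable for a
# fixed input; reading goes through utils::unzip.

npy_header <- function(descr, shape) {
  shape_str <- if (length(shape) == 0L) "()" else paste0("(", paste0(shape, ",", collapse = " "), ")")
  dict <- sprintf("{'descr': '%s', 'fortran_order': False, 'shape': %s, }", descr, shape_str)
  # pad so total header (magic 10 bytes + dict + newline) is a multiple of 64
  total <- 10L + nchar(dict) + 1L
  pad <- (64L - total %% 64L) %% 64L
  dict <- paste0(dict, strrep(" ", pad), "\n")
  c(as.raw(c(0x93L, utf8ToInt("N"), utf8ToInt("U"), utf8ToInt("M"),
             utf8ToInt("P"), utf8ToInt("Y"), 0x01L, 0x00L)),
    writeBin(nchar(dict), raw(), size = 2L, endian = "little"),
    charToRaw(dict))
}

int64_bytes <- function(x) {
  # non-negative integer-valued doubles -> little-endian int64 bytes
  lo <- x %% 2^32
  hi <- (x - lo) / 2^32
  to_i32 <- function(v) as.integer(v - 2^32 * (v >= 2^31))
  words <- integer(2L * length(x))
  words[seq(1L, by = 2L, length.out = length(x))] <- to_i32(lo)
  words[seq(2L, by = 2L, length.out = length(x))] <- to_i32(hi)
  writeBin(words, raw(), size = 4L, endian = "little")
}

npy_bytes <- function(x, scalar = FALSE) {
  if (is.character(x)) {
    n <- length(x)
    cps <- lapply(x, utf8ToInt)
    width <- max(1L, vapply(cps, length, 1L))
    words <- integer(n * width)
    for (i in seq_len(n)) {
      cp <- cps[[i]]
      if (length(cp)) words[((i - 1L) * width + 1L):((i - 1L) * width + length(cp))] <- cp
    }
    data <- writeBin(words, raw(), size = 4L, endian = "little")
    header <- npy_header(sprintf("<U%d", width), n)
  } else if (is.double(x) && !isTRUE(attr(x, "int64"))) {
    data <- writeBin(as.numeric(x), raw(), size = 8L, endian = "little")
    header <- npy_header("<f8", if (scalar) integer(0) else length(x))
  } else {
    xx <- as.numeric(x)
    data <- int64_bytes(xx)
    header <- npy_header("<i8", if (scalar) integer(0) else length(xx))
  }
  c(header, data)
}

as_int64 <- function(x) {
  x <- as.numeric(x)
  attr(x, "int64") <- TRUE
  x
}

npy_parse <- function(bytes) {
  if (length(bytes) < 10L || !identical(bytes[1:6],
      as.raw(c(0x93L, utf8ToInt("N"), utf8ToInt("U"), utf8ToInt("M"),
               utf8ToInt("P"), utf8ToInt("Y"))))) {
    sm_stop("not an NPY array", type = "format")
  }
  major <- as.integer(bytes[7])
  if (major == 1L) {
    hlen <- readBin(bytes[9:10], integer(), size = 2L, signed = FALSE, endian = "little")
    off <- 10L
  } else {
    hlen <- readBin(bytes[9:12], integer(), size = 4L, endian = "little")
    off <- 12L
  }
  header <- rawToChar(bytes[(off + 1L):(off + hlen)])
  descr <- sub(".*'descr':\\s*'([^']+)'.*", "\\1", header)
  shape_str <- sub(".*'shape':\\s*\\(([^)]*)\\).*", "\\1", header)
  shape <- as.numeric(strsplit(gsub("\\s", "", shape_str), ",")[[1]])
  shape <- shape[!is.na(shape)]
  n <- if (length(shape) == 0L) 1L else prod(shape)
  data <- bytes[(off + hlen + 1L):length(bytes)]
  if (descr %in% c("<f8", "<f4")) {
    sz <- if (descr == "<f8") 8L else 4L
    out <- readBin(data, numeric(), n = n, size = sz, endian = "little")
  } else if (descr %in% c("<i8", "<i4", "<i2")) {
    if (descr == "<i8") {
      words <- readBin(data, integer(), n = 2L * n, size = 4L, endian = "little")
      lo <- words[seq(1L, by = 2L, length.out = n)]
      hi <- words[seq(2L, by = 2L, length.out = n)]
      lo <- ifelse(lo < 0, lo + 2^32, as.numeric(lo))
      out <- as.numeric(hi) * 2^32 + lo
    } else {
      sz <- if (descr == "<i4") 4L else 2L
      out <- as.numeric(readBin(data, integer(), n = n, size = sz, endian = "little"))
    }
  } else if (grepl("^<U", descr)) {
    width <- as.integer(sub("^<U", "", descr))
    words <- readBin(data, integer(), n = n * width, size = 4L, endian = "little")
    out <- vapply(seq_len(n), function(i) {
      cp <- words[((i - 1L) * width + 1L):(i * width)]
      cp <- cp[cp != 0L]
      if (length(cp)) intToUtf8(cp) else ""
    }, character(1))
  } else {
    sm_stop(sprintf("unsupported NPY dtype '%s'", descr), type = "format")
  }
  list(data = out, shape = shape)
}

# ---- CRC32 (IEEE 802.3 polynomial), table-driven ------------------------

crc32_env <- new.env(parent = emptyenv())

crc32_table <- function() {
  if (is.null(crc32_env$tab)) {
    tab <- integer(256L)
    for (n in 0:255) {
      c <- n
      for (k in 1:8) {
        c <- if (bitwAnd(c, 1L) != 0L) {
          bitwXor(-306674912L, bitwShiftR(c, 1L))  # 0xEDB88320
        } else bitwShiftR(c, 1L)
      }
      tab[n + 1L] <- c
    }
    crc32_env$tab <- tab
  }
  crc32_env$tab
}

crc32 <- function(bytes) {
  tab <- crc32_table()
  crc <- -1L
  ints <- as.integer(bytes)
  for (b in ints) {
    crc <- bitwXor(bitwShiftR(crc, 8L), tab[bitwAnd(bitwXor(crc, b), 255L) + 1L])
  }
  bitwXor(crc, -1L)
}

# ---- stored-entry zip writer --------------------------------------------

u16 <- function(v) writeBin(as.integer(v), raw(), size = 2L, endian = "little")
u32 <- function(v) {
  v <- as.numeric(v)
  writeBin(as.integer(v - 2^32 * (v >= 2^31)), raw(), size = 4L, endian = "little")
}

zip_write_stored <- function(path, entries) {
  # entries: named list of raw vectors
  con <- file(path, "wb")
  on.exit(close(con))
  offsets <- numeric(length(entries))
  crcs <- integer(length(entries))
  pos <- 0
  nm <- names(entries)
  for (i in seq_along(entries)) {
    data <- entries[[i]]
    name <- charToRaw(nm[i])
    crcs[i] <- crc32(data)
    offsets[i] <- pos
    hdr <- c(u32(0x04034b50), u16(20L), u16(0L), u16(0L), u16(0L), u16(33L),
             writeBin(crcs[i], raw(), size = 4L, endian = "little"),
             u32(length(data)), u32(length(data)),
             u16(length(name)), u16(0L))
    writeBin(c(hdr, name, data), con)
    pos <- pos + length(hdr) + length(name) + length(data)
  }
  cd_start <- pos
  cd_len <- 0
  for (i in seq_along(entries)) {
    name <- charToRaw(nm[i])
    rec <- c(u32(0x02014b50), u16(20L), u16(20L), u16(0L), u16(0L),
             u16(0L), u16(33L),
             writeBin(crcs[i], raw(), size = 4L, endian = "little"),
             u32(length(entries[[i]])), u32(length(entries[[i]])),
             u16(length(name)), u16(0L), u16(0L), u16(0L), u16(0L),
             u32(0L), u32(offsets[i]))
    writeBin(c(rec, name), con)
    cd_len <- cd_len + length(rec) + length(name)
  }
  eocd <- c(u32(0x06054b50), u16(0L), u16(0L),
            u16(length(entries)), u16(length(entries)),
            u32(cd_len), u32(cd_start), u16(0L))
  writeBin(eocd, con)
  invisible(path)
}

npz_write <- function(path, arrays) {
  entries <- lapply(arrays, function(a) npy_bytes(a$value, scalar = isTRUE(a$scalar)))
  names(entries) <- paste0(names(arrays), ".npy")
  zip_write_stored(path, entries)
}

npz_read <- function(path) {
  if (!file.exists(path)) sm_stop(sprintf("file not found: %s", path), type = "io")
  tmp <- tempfile("npz")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE))
  files <- utils::unzip(path, exdir = tmp)
  out <- list()
  for (f in files) {
    nm <- sub("\\.npy$", "", basename(f))
    out[[nm]] <- npy_parse(readBin(f, raw(), n = file.size(f)))$data
  }
  out
}
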