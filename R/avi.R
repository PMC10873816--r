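# Minimal RIFF/AVI container writer: uncompressed 24-bit RGB ('DIB ') frames,
# bottom-up rows padded to 4 bytes, one video stream, idx1 index. Frame timing
# is carried in dwMicroSecPerFrame and the stream's dwRate/dwScale rational,
# so container duration = n_frames / fps.

write_avi <- function(frame_paths, out_file, fps) {
  stopifnot(length(frame_paths) >= 1, fps > 0)
  frames <- lapply(frame_paths, read_frame_rgb)
  dims <- vapply(frames, dim, integer(3))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("frames differ in size")
  }
  h <- dims[1, 1]; w <- dims[2, 1]
  payloads <- lapply(frames, frame_to_dib)
  frame_bytes <- length(payloads[[1]])
  n <- length(payloads)

  scale_rate <- fps_to_rational(fps)
  u32 <- function(con, x) writeBin(as.integer(round(x)), con, size = 4, endian = "little")
  u16 <- function(con, x) writeBin(as.integer(round(x)), con, size = 2, endian = "little")
  tag <- function(con, s) writeChar(s, con, nchars = 4, eos = NULL)

  chunk_sz <- frame_bytes + (frame_bytes %% 2)       # padded chunk payload
  movi_size <- 4 + n * (8 + chunk_sz)                # 'movi' + chunks
  idx1_size <- n * 16
  hdrl_size <- 4 + (8 + 56) + (8 + (4 + (8 + 56) + (8 + 40)))
  riff_size <- 4 + (8 + hdrl_size) + (8 + movi_size) + (8 + idx1_size)

  con <- file(out_file, "wb")
  on.exit(close(con))
  tag(con, "RIFF"); u32(con, riff_size); tag(con, "AVI ")

  tag(con, "LIST"); u32(con, hdrl_size); tag(con, "hdrl")
  tag(con, "avih"); u32(con, 56)
  u32(con, 1e6 / fps)                 # dwMicroSecPerFrame
  u32(con, frame_bytes * fps)         # dwMaxBytesPerSec
  u32(con, 0)                         # dwPaddingGranularity
  u32(con, 0x10)                      # dwFlags: AVIF_HASINDEX
  u32(con, n)                         # dwTotalFrames
  u32(con, 0); u32(con, 1)            # dwInitialFrames, dwStreams
  u32(con, chunk_sz + 8)              # dwSuggestedBufferSize
  u32(con, w); u32(con, h)
  u32(con, 0); u32(con, 0); u32(con, 0); u32(con, 0)

  strl_size <- 4 + (8 + 56) + (8 + 40)
  tag(con, "LIST"); u32(con, strl_size); tag(con, "strl")
  tag(con, "strh"); u32(con, 56)
  tag(con, "vids"); tag(con, "DIB ")
  u32(con, 0); u16(con, 0); u16(con, 0)          # flags, priority, language
  u32(con, 0)                                    # initial frames
  u32(con, scale_rate[1]); u32(con, scale_rate[2])  # dwScale, dwRate (fps = rate/scale)
  u32(con, 0); u32(con, n)                       # start, length (frames)
  u32(con, chunk_sz + 8); u32(con, 0); u32(con, 0)  # bufsize, quality, samplesize
  u16(con, 0); u16(con, 0); u16(con, w); u16(con, h)  # rcFrame

  tag(con, "strf"); u32(con, 40)
  u32(con, 40); u32(con, w); u32(con, h)
  u16(con, 1); u16(con, 24)                      # planes, bit count
  u32(con, 0); u32(con, frame_bytes)             # BI_RGB, image size
  u32(con, 0); u32(con, 0); u32(con, 0); u32(con, 0)

  tag(con, "LIST"); u32(con, movi_size); tag(con, "movi")
  offsets <- integer(n)
  pos <- 4
  for (i in seq_len(n)) {
    offsets[i] <- pos
    tag(con, "00db"); u32(con, frame_bytes)
    writeBin(payloads[[i]], con)
    if (frame_bytes %% 2 == 1) writeBin(as.raw(0), con)
    pos <- pos + 8 + chunk_sz
  }

  tag(con, "idx1"); u32(con, idx1_size)
  for (i in seq_len(n)) {
    tag(con, "00db"); u32(con, 0x10); u32(con, offsets[i]); u32(con, frame_bytes)
  }
  invisible(out_file)
}

read_frame_rgb <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2) {
    img <- array(rep(img, 3), c(dim(img), 3))
  } else if (dim(img)[3] > 3) {
    img <- img[, , 1:3, drop = FALSE]
  }
  img
}

frame_to_dib <- function(img) {
  h <- dim(img)[1]; w <- dim(img)[2]
  bytes <- array(as.raw(round(pmin(pmax(img, 0), 1) * 255)), dim(img))
  row_bytes <- w * 3
  pad <- (4 - row_bytes %% 4) %% 4
  rows <- lapply(h:1, function(r) {            # bottom-up
    px <- rbind(bytes[r, , 3], bytes[r, , 2], bytes[r, , 1])  # BGR interleave
    c(as.vector(px), raw(pad))
  })
  do.call(c, rows)
}

fps_to_rational <- function(fps) {
  scale <- 1e6
  rate <- round(fps * scale)
  g <- gcd2(rate, scale)
  c(scale / g, rate / g)  # (dwScale, dwRate)
}

gcd2 <- function(a, b) {
  while (b > 0) {
    t <- a %% b
    a <- b
    b <- t
  }
  a
}
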