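# Shared fixtures: seeded random images, a brute-force histogram/entropy
# oracle kept deliberately naive (per-pixel tally loops), and an in-memory
# DICOM byte-stream builder for exercising the reader without binary
# fixture files.

rand_image <- function(n = 64, seed = 1, lo = 0, hi = 255) {
  set.seed(seed)
  matrix(runif(n * n, lo, hi), n, n)
}

circ_shift <- function(m, s_row, s_col = s_row) {
  M <- nrow(m); N <- ncol(m)
  m[((seq_len(M) - 1 - s_row) %% M) + 1, ((seq_len(N) - 1 - s_col) %% N) + 1]
}

# brute-force joint histogram: explicit loop over pixel pairs, clamped
# equal-width binning identical in definition to the package contract
bf_joint <- function(a, b, B, ra = range(a, na.rm = TRUE),
                     rb = range(b, na.rm = TRUE)) {
  counts <- matrix(0, B, B)
  used <- 0
  for (i in seq_along(a)) {
    if (is.na(a[i]) || is.na(b[i])) next
    ia <- floor((a[i] - ra[1]) / (ra[2] - ra[1]) * B)
    ib <- floor((b[i] - rb[1]) / (rb[2] - rb[1]) * B)
    ia <- min(max(ia, 0), B - 1)
    ib <- min(max(ib, 0), B - 1)
    counts[ia + 1, ib + 1] <- counts[ia + 1, ib + 1] + 1
    used <- used + 1
  }
  counts / used
}

bf_entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

bf_nmi <- function(a, b, B, ra = range(a, na.rm = TRUE),
                   rb = range(b, na.rm = TRUE)) {
  j <- bf_joint(a, b, B, ra, rb)
  (bf_entropy(rowSums(j)) + bf_entropy(colSums(j))) / bf_entropy(as.numeric(j))
}

# --- minimal DICOM writer (explicit VR little endian) -----------------

.u16le <- function(x) writeBin(as.integer(x), raw(), size = 2,
                               endian = "little")
.u32le <- function(x) writeBin(as.integer(x), raw(), size = 4,
                               endian = "little")

dcm_element <- function(group, elem, vr, value) {
  if (is.character(value)) {
    v <- charToRaw(value)
    if (length(v) %% 2L == 1L) v <- c(v, charToRaw(" "))
  } else v <- value
  hdr <- c(.u16le(group), .u16le(elem), charToRaw(vr))
  if (vr %in% c("OB", "OW", "SQ", "UN", "UT"))
    c(hdr, as.raw(c(0, 0)), .u32le(length(v)), v)
  else c(hdr, .u16le(length(v)), v)
}

# build a single-frame 16-bit monochrome DICOM byte stream
make_dicom_bytes <- function(px, spacing = c(1.17, 1.17)) {
  pixel_raw <- writeBin(as.integer(t(px)), raw(), size = 2,
                        endian = "little")
  c(raw(128), charToRaw("DICM"),
    dcm_element(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1"),
    dcm_element(0x0008, 0x0060, "CS", "CT"),
    dcm_element(0x0028, 0x0002, "US", .u16le(1)),
    dcm_element(0x0028, 0x0010, "US", .u16le(nrow(px))),
    dcm_element(0x0028, 0x0011, "US", .u16le(ncol(px))),
    dcm_element(0x0028, 0x0030, "DS",
                paste0(spacing[1], "\\", spacing[2])),
    dcm_element(0x0028, 0x0100, "US", .u16le(16)),
    dcm_element(0x0028, 0x0103, "US", .u16le(0)),
    dcm_element(0x7fe0, 0x0010, "OW", pixel_raw))
}

# fast registration config for small functional tests
quick_cfg <- function(...) {
  registrationConfig(optimizer = optimizerConfig(max_iter = 20L), ...)
}
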