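# Fixture builders shared across tests.  Everything is generated in
# code at test time; nothing binary ships with the package.

# A ct_volume with the given array (defaults to a constant block).
fx_volume <- function(arr = array(-800, dim = c(4, 4, 4)),
                      spacing = c(1, 1, 1)) {
  ct_volume(arr, spacing = spacing)
}

fx_mask <- function(dim, true_idx = NULL) {
  flags <- array(FALSE, dim = dim)
  if (is.null(true_idx)) flags[] <- TRUE else flags[true_idx] <- TRUE
  lesion_mask(flags)
}

# quantized_lesion straight from a level array (all voxels in-mask
# unless a mask is supplied)
fx_quantized <- function(levels, n_levels, mask = NULL) {
  levels <- as.array(levels)
  if (is.null(mask)) mask <- fx_mask(dim(levels))
  structure(list(levels = array(as.integer(levels), dim = dim(levels)),
                 n_levels = as.integer(n_levels), mask = mask),
            class = "quantized_lesion")
}

# ---------------------------------------------------------------------
# Minimal explicit-VR little-endian DICOM writer for reader tests.
# Writes one single-frame CT slice per file.

dcm_write_slice <- function(path, pixels, slice_z, series_uid = "1.2.3.4",
                            slope = 1, intercept = -1024,
                            pixel_spacing = c(0.7, 0.7)) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)

  w_u16 <- function(x) writeBin(as.integer(x), con, size = 2,
                                endian = "little")
  w_el_str <- function(group, element, vr, value) {
    if (nchar(value) %% 2 == 1) value <- paste0(value, " ")
    w_u16(group); w_u16(element)
    writeBin(charToRaw(vr), con)
    w_u16(nchar(value))
    writeBin(charToRaw(value), con)
  }
  w_el_us <- function(group, element, value) {
    w_u16(group); w_u16(element)
    writeBin(charToRaw("US"), con)
    w_u16(2)
    w_u16(value)
  }
  # minimal file meta group (explicit VR little endian)
  w_el_str(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1")
  # dataset
  w_el_str(0x0008, 0x0060, "CS", "CT")
  w_el_str(0x0020, 0x000E, "UI", series_uid)
  w_el_str(0x0020, 0x0032, "DS", sprintf("0\\0\\%g", slice_z))
  w_el_str(0x0020, 0x0037, "DS", "1\\0\\0\\0\\1\\0")
  w_el_us(0x0028, 0x0010, nrow(pixels))   # Rows
  w_el_us(0x0028, 0x0011, ncol(pixels))   # Columns
  w_el_str(0x0028, 0x0030, "DS",
           sprintf("%g\\%g", pixel_spacing[1], pixel_spacing[2]))
  w_el_us(0x0028, 0x0100, 16)             # BitsAllocated
  w_el_us(0x0028, 0x0103, 0)              # PixelRepresentation (unsigned)
  w_el_str(0x0028, 0x1052, "DS", sprintf("%g", intercept))
  w_el_str(0x0028, 0x1053, "DS", sprintf("%g", slope))
  # PixelData, OW with 4-byte length: rows written row by row
  npix <- length(pixels)
  w_u16(0x7FE0); w_u16(0x0010)
  writeBin(charToRaw("OW"), con)
  w_u16(0)
  writeBin(as.integer(2 * npix), con, size = 4, endian = "little")
  writeBin(as.integer(t(pixels)), con, size = 2, endian = "little")
  invisible(path)
}

dcm_write_series <- function(dir, n_slices = 3, stored_value = 224,
                             zs = NULL, series_uid = "1.2.3.4",
                             nrow = 4, ncol = 4) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(zs)) zs <- seq_len(n_slices) - 1
  for (k in seq_along(zs)) {
    px <- matrix(stored_value, nrow, ncol)
    dcm_write_slice(file.path(dir, sprintf("slice%02d.dcm", k)), px,
                    slice_z = zs[k], series_uid = series_uid)
  }
  dir
}

# ---------------------------------------------------------------------
# Brute-force GLCM + feature oracle: plain loops and direct summation,
# independent of the package implementation.

oracle_glcm <- function(levels, flags, ng) {
  dm <- dim(levels)
  counts <- matrix(0, ng, ng)
  for (k in seq_len(dm[3])) for (j in seq_len(dm[2]))
    for (i in seq_len(dm[1] - 1)) {
      if (flags[i, j, k] && flags[i + 1, j, k]) {
        a <- levels[i, j, k]; b <- levels[i + 1, j, k]
        counts[a, b] <- counts[a, b] + 1
        counts[b, a] <- counts[b, a] + 1
      }
    }
  counts
}

oracle_glcm_features <- function(p) {
  ng <- nrow(p)
  f <- list()
  px <- rowSums(p); py <- colSums(p)
  mux <- sum((1:ng) * px); muy <- sum((1:ng) * py)
  sx <- sqrt(sum(((1:ng) - mux)^2 * px))
  sy <- sqrt(sum(((1:ng) - muy)^2 * py))
  s_ac <- s_con <- s_dis <- s_en <- s_ent <- s_id <- s_idm <- 0
  s_cs <- s_cp <- s_idn <- s_idmn <- s_cov <- 0
  for (i in 1:ng) for (j in 1:ng) {
    v <- p[i, j]
    s_ac <- s_ac + i * j * v
    s_con <- s_con + (i - j)^2 * v
    s_dis <- s_dis + abs(i - j) * v
    s_en <- s_en + v^2
    if (v > 0) s_ent <- s_ent - v * log(v)
    s_id <- s_id + v / (1 + abs(i - j))
    s_idm <- s_idm + v / (1 + (i - j)^2)
    s_cs <- s_cs + (i + j - mux - muy)^3 * v
    s_cp <- s_cp + (i + j - mux - muy)^4 * v
    s_idn <- s_idn + v / (1 + abs(i - j) / ng)
    s_idmn <- s_idmn + v / (1 + ((i - j) / ng)^2)
    s_cov <- s_cov + (i - mux) * (j - muy) * v
  }
  psum <- sapply(2:(2 * ng), function(kk) {
    s <- 0
    for (i in 1:ng) for (j in 1:ng) if (i + j == kk) s <- s + p[i, j]
    s
  })
  pdiff <- sapply(0:(ng - 1), function(kk) {
    s <- 0
    for (i in 1:ng) for (j in 1:ng) if (abs(i - j) == kk) s <- s + p[i, j]
    s
  })
  ks <- 2:(2 * ng)
  sa <- sum(ks * psum)
  hx <- -sum(ifelse(px > 0, px * log(px), 0))
  hy <- -sum(ifelse(py > 0, py * log(py), 0))
  hxy1 <- 0; hxy2 <- 0
  for (i in 1:ng) for (j in 1:ng) {
    q <- px[i] * py[j]
    if (q > 0) {
      hxy1 <- hxy1 - p[i, j] * log(q)
      hxy2 <- hxy2 - q * log(q)
    }
  }
  mu <- sum((1:ng) * px)
  c(autocorrelation = s_ac, contrast = s_con,
    correlation = if (sx * sy > 0) s_cov / (sx * sy) else 0,
    cluster_prominence = s_cp, cluster_shade = s_cs,
    dissimilarity = s_dis, energy = s_en, entropy = s_ent,
    inverse_difference = s_id, inverse_difference_moment = s_idm,
    maximum_probability = max(p),
    sum_of_squares_variance = sum(((1:ng) - mu)^2 * px),
    sum_average = sa,
    sum_variance = sum((ks - sa)^2 * psum),
    sum_entropy = -sum(ifelse(psum > 0, psum * log(psum), 0)),
    difference_variance = s_con,
    difference_entropy = -sum(ifelse(pdiff > 0, pdiff * log(pdiff), 0)),
    imc1 = if (max(hx, hy) > 0) (s_ent - hxy1) / max(hx, hy) else 0,
    imc2 = sqrt(min(max(1 - exp(-2 * (hxy2 - s_ent)), 0), 1)),
    inverse_difference_normalized = s_idn,
    inverse_difference_moment_normalized = s_idmn)
}

# small separable toy feature table with 26 named columns
fx_toy_table <- function(n_pos = 5, n_neg = 8, sep_feature = "correlation",
                         gap = 5, seed = 42) {
  set.seed(seed)
  n <- n_pos + n_neg
  x <- matrix(rnorm(n * 26), n, 26)
  colnames(x) <- feature_names()
  y <- rep(c("SPCH", "LPA"), c(n_pos, n_neg))
  x[y == "SPCH", sep_feature] <- x[y == "SPCH", sep_feature] + gap
  list(x = x, y = y)
}
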