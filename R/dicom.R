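# Minimal read-only DICOM support: one single-frame CT series per
# directory, Part-10 files in explicit-VR little endian.  Only the tags
# needed to reconstruct an HU volume are interpreted; everything else is
# skipped by its declared length.  Undefined-length sequences are not
# supported and raise an error.

dcm_tag <- function(group, element) sprintf("%04X,%04X", group, element)

dcm_read_file <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 132 || rawToChar(raw[129:132]) != "DICM")
    stop("not a DICOM part-10 file: ", path)
  pos <- 133L
  n <- length(raw)
  u16 <- function(at) readBin(raw[at:(at + 1)], "integer", size = 2,
                              endian = "little", signed = FALSE)
  u32 <- function(at) readBin(raw[at:(at + 3)], "integer", size = 4,
                              endian = "little")
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  elements <- list()
  while (pos + 7 <= n) {
    group <- u16(pos); element <- u16(pos + 2L)
    vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
    if (!grepl("^[A-Z]{2}$", vr))
      stop("unsupported transfer syntax (implicit VR?) in ", path)
    if (vr %in% long_vrs) {
      len <- u32(pos + 8L)
      vstart <- pos + 12L
    } else {
      len <- u16(pos + 6L)
      vstart <- pos + 8L
    }
    if (len < 0 || (vr == "SQ"))
      stop("unsupported DICOM element (sequence or undefined length) in ",
           path)
    key <- dcm_tag(group, element)
    keep <- key %in% c("0020,000E", "0020,0032", "0020,0037", "0028,0010",
                       "0028,0011", "0028,0030", "0028,0100", "0028,0103",
                       "0028,1052", "0028,1053", "7FE0,0010")
    if (keep) {
      val <- if (len > 0) raw[vstart:(vstart + len - 1L)] else raw(0)
      elements[[key]] <- list(vr = vr, bytes = val)
    }
    pos <- vstart + len
  }
  elements
}

dcm_string <- function(el) {
  if (is.null(el)) return(NULL)
  trimws(rawToChar(el$bytes))
}

dcm_numbers <- function(el) {
  if (is.null(el)) return(NULL)
  as.numeric(strsplit(dcm_string(el), "\\\\")[[1]])
}

dcm_us <- function(el) {
  readBin(el$bytes, "integer", size = 2, endian = "little", signed = FALSE)
}

dcm_slice <- function(path) {
  el <- dcm_read_file(path)
  rows <- dcm_us(el[["0028,0010"]])
  cols <- dcm_us(el[["0028,0011"]])
  bits <- dcm_us(el[["0028,0100"]])
  if (bits != 16L)
    stop("only 16-bit DICOM pixel data supported (", path, ")")
  signed <- !is.null(el[["0028,0103"]]) && dcm_us(el[["0028,0103"]]) == 1L
  px <- readBin(el[["7FE0,0010"]]$bytes, "integer", n = rows * cols,
                size = 2, endian = "little", signed = signed)
  slope <- dcm_numbers(el[["0028,1053"]])
  inter <- dcm_numbers(el[["0028,1052"]])
  if (is.null(slope)) slope <- 1
  if (is.null(inter)) inter <- 0
  orient <- dcm_numbers(el[["0020,0037"]])
  if (is.null(orient)) orient <- c(1, 0, 0, 0, 1, 0)
  ipp <- dcm_numbers(el[["0020,0032"]])
  if (is.null(ipp)) stop("missing ImagePositionPatient in ", path)
  ps <- dcm_numbers(el[["0028,0030"]])
  if (is.null(ps)) ps <- c(1, 1)
  normal <- c(orient[2] * orient[6] - orient[3] * orient[5],
              orient[3] * orient[4] - orient[1] * orient[6],
              orient[1] * orient[5] - orient[2] * orient[4])
  list(series = dcm_string(el[["0020,000E"]]),
       # pixel rows are stored column-fastest: dim1 = column axis
       pixels = matrix(slope * px + inter, nrow = cols, ncol = rows),
       position = sum(ipp * normal), ipp = ipp,
       spacing_rc = ps)
}

read_dicom_series <- function(dir, spacing_tol = 0.1) {
  files <- list.files(dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  is_dcm <- vapply(files, function(f) {
    hdr <- readBin(f, "raw", n = 132)
    length(hdr) == 132 && rawToChar(hdr[129:132]) == "DICM"
  }, logical(1))
  files <- files[is_dcm]
  if (length(files) == 0L)
    stop("no DICOM files found in ", dir)
  slices <- lapply(files, dcm_slice)
  series <- unique(vapply(slices, function(s)
    if (is.null(s$series)) "" else s$series, character(1)))
  if (length(series) > 1L)
    stop("mixed DICOM series in one directory: ", paste(series, collapse = ", "))
  ord <- order(vapply(slices, `[[`, numeric(1), "position"))
  slices <- slices[ord]
  pos <- vapply(slices, `[[`, numeric(1), "position")
  if (length(pos) > 1L) {
    gaps <- diff(pos)
    med <- stats::median(gaps)
    if (med <= 0 || any(abs(gaps - med) > spacing_tol * med))
      stop("non-uniform slice spacing: gaps ",
           paste(signif(gaps, 4), collapse = ", "))
    dz <- med
  } else dz <- 1
  dm <- dim(slices[[1]]$pixels)
  vox <- array(0, dim = c(dm[1], dm[2], length(slices)))
  for (k in seq_along(slices)) {
    if (!identical(dim(slices[[k]]$pixels), dm))
      stop("inconsistent slice dimensions in series")
    vox[, , k] <- slices[[k]]$pixels
  }
  ps <- slices[[1]]$spacing_rc   # DICOM order: row spacing, column spacing
  ct_volume(vox, spacing = c(ps[2], ps[1], dz), origin = slices[[1]]$ipp)
}
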