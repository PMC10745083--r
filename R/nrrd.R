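#' Read a text-encoded NRRD volume
#'
#' Minimal reader for the NRRD interchange format restricted to 3-dimensional
#' volumes with `ascii`/`text` encoding, which is the dialect this package
#' writes. Values are returned as a numeric 3D array in raster order (first
#' axis fastest, matching R's column-major layout).
#'
#' @param path file path.
#' @return numeric 3D array; the voxel spacing (micrometres), when present in
#'   the header, is attached as attribute `spacing_um`.
#' @export
read_nrrd <- function(path) {
  if (!file.exists(path)) stop_mesoconn("NRRD file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || !grepl("^NRRD", lines[1])) {
    stop_mesoconn("not an NRRD file (missing magic): ", path)
  }
  blank <- which(lines == "")[1]
  if (is.na(blank)) stop_mesoconn("malformed NRRD header (no blank line): ", path)
  header <- lines[2:(blank - 1)]
  header <- header[!grepl("^#", header)]
  fields <- list()
  for (h in header) {
    kv <- strsplit(h, ": ", fixed = TRUE)[[1]]
    if (length(kv) == 2) fields[[tolower(kv[1])]] <- kv[2]
  }
  enc <- tolower(fields[["encoding"]] %||% "ascii")
  if (!enc %in% c("ascii", "txt", "text")) {
    stop_mesoconn("only text-encoded NRRD is supported, got encoding: ", enc)
  }
  dim_n <- as.integer(fields[["dimension"]] %||% "3")
  sizes <- as.integer(strsplit(fields[["sizes"]], " +")[[1]])
  if (length(sizes) != dim_n) stop_mesoconn("NRRD sizes do not match dimension")
  vals <- scan(text = paste(lines[(blank + 1):length(lines)], collapse = " "),
               what = double(), quiet = TRUE)
  if (length(vals) != prod(sizes)) {
    stop_mesoconn("NRRD data length ", length(vals), " != prod(sizes) ", prod(sizes))
  }
  out <- array(vals, dim = sizes)
  if (!is.null(fields[["spacings"]])) {
    sp <- as.numeric(strsplit(fields[["spacings"]], " +")[[1]])
    attr(out, "spacing_um") <- sp[1]
  }
  out
}

#' Write a volume as text-encoded NRRD
#'
#' @param x numeric 3D array.
#' @param path output file path.
#' @param spacing_um isotropic voxel spacing in micrometres, written to the
#'   `spacings` header field.
#' @return `path`, invisibly.
#' @export
write_nrrd <- function(x, path, spacing_um = 100) {
  if (length(dim(x)) != 3) stop_mesoconn("write_nrrd expects a 3D array")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "NRRD0004",
    "type: double",
    "dimension: 3",
    paste("sizes:", paste(dim(x), collapse = " ")),
    paste("spacings:", paste(rep(spacing_um, 3), collapse = " ")),
    "encoding: ascii",
    ""
  ), con)
  vals <- formatC(as.vector(x), format = "g", digits = 17)
  writeLines(paste(vals, collapse = " "), con)
  invisible(path)
}
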