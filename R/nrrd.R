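# Minimal NRRD raster I/O (ASCII encoding).
#
# The installed imaging stack covers NIfTI but not NRRD, so a small
# reader/writer for the subset of NRRD used here (3-D rasters, space
# directions/origin metadata, ascii encoding) is implemented directly.
# ASCII encoding is deliberate: rasters stay diff-able text files.

#' Write a 3-D raster to an NRRD file
#'
#' Stores the array together with its grid metadata (`sizes`,
#' `space directions`, `space origin`) using ASCII encoding, x-fastest
#' ordering.
#'
#' @param x numeric or logical 3-D array.
#' @param path output file path.
#' @param spacing_mm voxel spacing (length 3, mm).
#' @param origin_mm world coordinate of the first voxel corner (length 3, mm).
#' @param type NRRD sample type, `"double"` or `"uchar"` (for masks).
#' @return `path`, invisibly.
#' @keywords internal
write_nrrd <- function(x, path, spacing_mm, origin_mm, type = "double") {
  stopifnot(length(dim(x)) == 3L)
  dirs <- sprintf("(%g,0,0) (0,%g,0) (0,0,%g)",
                  spacing_mm[1], spacing_mm[2], spacing_mm[3])
  hdr <- c(
    "NRRD0004",
    sprintf("type: %s", type),
    "dimension: 3",
    sprintf("sizes: %d %d %d", dim(x)[1], dim(x)[2], dim(x)[3]),
    "space dimension: 3",
    sprintf("space directions: %s", dirs),
    sprintf("space origin: (%g,%g,%g)", origin_mm[1], origin_mm[2], origin_mm[3]),
    "encoding: ascii",
    ""
  )
  vals <- if (type == "uchar") as.integer(x) else as.vector(x)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(paste(format(vals, scientific = TRUE, digits = 12), collapse = " "), con)
  invisible(path)
}

#' Read a 3-D raster from an NRRD file
#'
#' @param path NRRD file written by [write_nrrd()] (ASCII encoding).
#' @return list with `data` (3-D array), `spacing_mm`, `origin_mm`, `type`.
#' @keywords internal
read_nrrd <- function(path) {
  lines <- readLines(path)
  if (!grepl("^NRRD", lines[1]))
    stop_protonarc(sprintf("'%s' is not an NRRD file", path), "protonarc_format_error")
  blank <- which(lines == "")[1]
  hdr <- lines[2:(blank - 1)]
  field <- function(name) {
    hit <- grep(paste0("^", name, ": "), hdr, value = TRUE)
    if (!length(hit)) return(NULL)
    sub(paste0("^", name, ": "), "", hit[1])
  }
  sizes <- as.integer(strsplit(field("sizes"), " +")[[1]])
  enc <- field("encoding")
  if (!identical(enc, "ascii"))
    stop_protonarc("only ascii-encoded NRRD is supported", "protonarc_format_error")
  nums <- function(s) as.numeric(strsplit(gsub("[()]", "", s), ",")[[1]])
  dirs <- regmatches(field("space directions"),
                     gregexpr("\\([^)]*\\)", field("space directions")))[[1]]
  spacing <- vapply(seq_along(dirs), function(i) nums(dirs[i])[i], numeric(1))
  origin <- nums(field("space origin"))
  vals <- as.numeric(strsplit(paste(lines[(blank + 1):length(lines)], collapse = " "),
                              " +")[[1]])
  vals <- vals[!is.na(vals)]
  if (length(vals) != prod(sizes))
    stop_protonarc(sprintf("NRRD data length %d does not match sizes %s",
                           length(vals), paste(sizes, collapse = "x")),
                   "protonarc_format_error")
  list(data = array(vals, dim = sizes), spacing_mm = spacing,
       origin_mm = origin, type = field("type"))
}
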