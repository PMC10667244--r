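# Minimal NPY v1.0 reader/writer (C-order, little-endian).
# Covers the dtypes single-cell image stacks arrive in: f8, f4, i1..i8, u1.
# Arrays are returned/written with the documented axis convention
# (cell, depth, height, width); NPY files are C-ordered so axes are
# permuted on the way in/out.

npyDtypeMap <- list(
  "<f8" = list(what = "double", size = 8L, signed = TRUE),
  "<f4" = list(what = "double", size = 4L, signed = TRUE),
  "<i8" = list(what = "integer", size = 8L, signed = TRUE),
  "<i4" = list(what = "integer", size = 4L, signed = TRUE),
  "<i2" = list(what = "integer", size = 2L, signed = TRUE),
  "|i1" = list(what = "integer", size = 1L, signed = TRUE),
  "|u1" = list(what = "integer", size = 1L, signed = FALSE)
)

#' Read a NumPy .npy array
#'
#' Supports format version 1.0/2.0, little-endian numeric dtypes, and both
#' C and Fortran element order. Returns an R array with the same axis order
#' as the Python array (\code{a[i, j, k]} matches \code{a[i-1, j-1, k-1]}).
#'
#' @param path path to a \code{.npy} file.
#' @return numeric array (or vector for 1-d arrays).
#' @export
readNpy <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 6L)
  if (!identical(magic, as.raw(c(0x93, charToRaw("NUMPY")))))
    stop("not an NPY file (bad magic): ", path)
  ver <- readBin(con, "integer", 2L, size = 1L, signed = FALSE)
  hlenBytes <- if (ver[1] >= 2L) 4L else 2L
  hlen <- readBin(con, "integer", 1L, size = hlenBytes,
                  signed = FALSE, endian = "little")
  header <- rawToChar(readBin(con, "raw", hlen))
  descr <- sub(".*'descr'\\s*:\\s*'([^']+)'.*", "\\1", header)
  fortran <- grepl("'fortran_order'\\s*:\\s*True", header)
  shapeStr <- sub(".*'shape'\\s*:\\s*\\(([^)]*)\\).*", "\\1", header)
  shape <- as.integer(strsplit(gsub("\\s", "", shapeStr), ",")[[1]])
  shape <- shape[!is.na(shape)]
  dt <- npyDtypeMap[[descr]]
  if (is.null(dt)) stop("unsupported NPY dtype: ", descr)
  n <- if (length(shape)) prod(shape) else 1L
  vals <- readBin(con, dt$what, n, size = dt$size,
                  signed = dt$signed, endian = "little")
  vals <- as.numeric(vals)
  if (length(vals) != n) stop("truncated NPY payload in ", path)
  if (length(shape) <= 1L) return(vals)
  if (fortran) array(vals, shape)
  else aperm(array(vals, rev(shape)), rev(seq_along(shape)))
}

#' Write a NumPy .npy array
#'
#' Writes format version 1.0, dtype \code{<f8}, C element order, so that
#' \code{readNpy(writeNpy(a))} round-trips bit-exactly and the file loads in
#' NumPy with unchanged axis order.
#'
#' @param x numeric array or vector.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeNpy <- function(x, path) {
  shape <- if (is.null(dim(x))) length(x) else dim(x)
  hdr <- sprintf(
    "{'descr': '<f8', 'fortran_order': False, 'shape': (%s), }",
    paste0(paste(shape, collapse = ", "),
           if (length(shape) == 1L) "," else ""))
  # pad with spaces so total header size is a multiple of 64, newline-ended
  base <- 6L + 2L + 2L
  pad <- (64L - (base + nchar(hdr) + 1L) %% 64L) %% 64L
  hdr <- paste0(hdr, strrep(" ", pad), "\n")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x93, charToRaw("NUMPY"))), con)
  writeBin(as.raw(c(1L, 0L)), con)
  writeBin(as.integer(nchar(hdr)), con, size = 2L, endian = "little")
  writeBin(charToRaw(hdr), con)
  vals <- if (is.null(dim(x))) as.numeric(x)
          else as.numeric(aperm(x, rev(seq_along(dim(x)))))
  writeBin(vals, con, size = 8L, endian = "little")
  invisible(path)
}
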