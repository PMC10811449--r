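# Streaming reader for DICOM Part-10 files (explicit and implicit VR little
# endian). Values are decoded per VR; sequence content is parsed recursively;
# pixel data is seeked past, never loaded, so memory use does not depend on
# image resolution.

.dcm_read_u16 <- function(con) {
  v <- readBin(con, integer(), n = 1L, size = 2L, endian = "little",
               signed = FALSE)
  if (length(v) == 0L) NA_integer_ else v
}

.dcm_read_u32 <- function(con) {
  # signed read: 0xFFFFFFFF (undefined length) comes back as -1
  v <- readBin(con, integer(), n = 1L, size = 4L, endian = "little")
  if (length(v) == 0L) NA_integer_ else v
}

.dcm_decode_value <- function(bytes, vr) {
  if (vr %in% .dcm_string_vrs) {
    s <- rawToChar(bytes[bytes != as.raw(0)])
    return(sub("[ ]+$", "", s))
  }
  switch(vr,
    US = readBin(bytes, integer(), n = length(bytes) %/% 2L, size = 2L,
                 endian = "little", signed = FALSE),
    SS = readBin(bytes, integer(), n = length(bytes) %/% 2L, size = 2L,
                 endian = "little", signed = TRUE),
    UL = ,
    SL = readBin(bytes, integer(), n = length(bytes) %/% 4L, size = 4L,
                 endian = "little"),
    FL = readBin(bytes, double(), n = length(bytes) %/% 4L, size = 4L,
                 endian = "little"),
    FD = readBin(bytes, double(), n = length(bytes) %/% 8L, size = 8L,
                 endian = "little"),
    bytes  # OB/OW/OF/UN/AT and anything else stays raw
  )
}

# Parse a run of data elements from `con`.
#   n_bytes: byte budget (NA = until EOF or a delimiter tag)
#   explicit: explicit-VR transfer syntax?
#   stop_tag: c(group, element) delimiter that terminates the run (consumed)
.dcm_parse_elements <- function(con, n_bytes, explicit, depth, skip_pixel,
                                path, stop_tag = NULL, fsize = Inf) {
  out <- list()
  start <- seek(con)
  repeat {
    if (!is.na(n_bytes) && (seek(con) - start) >= n_bytes) break
    group <- .dcm_read_u16(con)
    if (is.na(group)) {
      if (is.na(n_bytes) && is.null(stop_tag)) break
      stop("truncated DICOM stream in ", path, call. = FALSE)
    }
    element <- .dcm_read_u16(con)
    if (!is.null(stop_tag) && group == stop_tag[1] && element == stop_tag[2]) {
      .dcm_read_u32(con)  # delimiter length (always zero)
      break
    }
    if (group == 0xFFFE) {
      stop("unexpected item tag outside a sequence in ", path, call. = FALSE)
    }
    if (explicit) {
      vr <- rawToChar(readBin(con, raw(), n = 2L))
      if (vr %in% .dcm_long_vrs) {
        readBin(con, raw(), n = 2L)  # reserved
        len <- .dcm_read_u32(con)
      } else {
        len <- .dcm_read_u16(con)
      }
    } else {
      vr <- dcm_lookup(group, element)$vr
      if (is.na(vr)) vr <- "UN"
      len <- .dcm_read_u32(con)
    }
    if (is.na(len)) stop("truncated DICOM stream in ", path, call. = FALSE)

    if (identical(vr, "SQ") || (identical(vr, "UN") && len == -1L)) {
      items <- .dcm_parse_items(con, len, explicit, depth, skip_pixel, path,
                                fsize)
      el <- list(group = group, element = element, vr = "SQ",
                 value = items, depth = depth)
    } else if (len == -1L) {
      stop("undefined-length non-sequence element ",
           dcm_tag_label(group, element), " in ", path, call. = FALSE)
    } else {
      is_pixel <- group == 0x7FE0 && element == 0x0010
      if (skip_pixel && is_pixel) {
        seek(con, where = len, origin = "current")
        if (seek(con) > fsize) {
          stop("truncated DICOM stream in ", path, call. = FALSE)
        }
        el <- list(group = group, element = element, vr = vr,
                   value = NULL, byte_length = len, skipped = TRUE,
                   depth = depth)
      } else {
        bytes <- readBin(con, raw(), n = len)
        if (length(bytes) < len) {
          stop("truncated DICOM stream in ", path, call. = FALSE)
        }
        el <- list(group = group, element = element, vr = vr,
                   value = .dcm_decode_value(bytes, vr), depth = depth)
      }
    }
    out[[length(out) + 1L]] <- el
  }
  out
}

.dcm_parse_items <- function(con, sq_len, explicit, depth, skip_pixel, path,
                             fsize = Inf) {
  items <- list()
  start <- seek(con)
  repeat {
    if (sq_len != -1L && (seek(con) - start) >= sq_len) break
    group <- .dcm_read_u16(con)
    element <- .dcm_read_u16(con)
    if (is.na(group) || is.na(element)) {
      stop("truncated sequence in ", path, call. = FALSE)
    }
    if (group == 0xFFFE && element == 0xE0DD) {  # sequence delimiter
      .dcm_read_u32(con)
      break
    }
    if (!(group == 0xFFFE && element == 0xE000)) {
      stop("malformed sequence item in ", path, call. = FALSE)
    }
    item_len <- .dcm_read_u32(con)
    if (item_len == -1L) {
      items[[length(items) + 1L]] <- .dcm_parse_elements(
        con, NA_integer_, explicit, depth + 1L, skip_pixel, path,
        stop_tag = c(0xFFFE, 0xE00D), fsize = fsize)
    } else {
      items[[length(items) + 1L]] <- .dcm_parse_elements(
        con, item_len, explicit, depth + 1L, skip_pixel, path,
        fsize = fsize)
    }
  }
  items
}

#' Read a DICOM Part-10 file into an element tree
#'
#' Parses the preamble, file meta group and main dataset of a Part-10 file.
#' Explicit and implicit VR little endian transfer syntaxes are supported.
#' Pixel data is skipped over by default (its byte length is recorded but the
#' bytes are never read into memory).
#'
#' @param path path to a DICOM file.
#' @param skip_pixel_data if `TRUE` (default) the value of PixelData
#'   (7FE0,0010) is not loaded.
#' @return an object of class `dcm_dataset`: a list with `meta` (file meta
#'   elements), `elements` (the main dataset, sequences nested as lists of
#'   items), `transfer_syntax` and `path`.
#' @seealso [load_dicom_tags()] for the flat two-level tag map used by the
#'   linkage pipeline, [dcm_write()] for the inverse.
#' @export
dcm_read <- function(path, skip_pixel_data = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  preamble <- readBin(con, raw(), n = 132L)
  if (length(preamble) < 132L ||
      !identical(rawToChar(preamble[129:132]), "DICM")) {
    stop("not a DICOM Part-10 file: ", path, call. = FALSE)
  }
  # file meta group is always explicit VR little endian
  meta <- .dcm_parse_meta(con, path)
  ts <- DCM_UID$explicit_vr_le
  for (el in meta) {
    if (el$group == 0x0002 && el$element == 0x0010) ts <- el$value
  }
  explicit <- !identical(ts, DCM_UID$implicit_vr_le)
  elements <- .dcm_parse_elements(con, NA_integer_, explicit, 0L,
                                  skip_pixel_data, path,
                                  fsize = file.size(path))
  structure(list(meta = meta, elements = elements, transfer_syntax = ts,
                 path = path),
            class = "dcm_dataset")
}

# The meta group ends where group 0002 ends; its length element, when
# present, gives the exact budget.
.dcm_parse_meta <- function(con, path) {
  group <- .dcm_read_u16(con)
  element <- .dcm_read_u16(con)
  if (is.na(group) || group != 0x0002) {
    stop("missing file meta group in ", path, call. = FALSE)
  }
  vr <- rawToChar(readBin(con, raw(), n = 2L))
  len <- if (vr %in% .dcm_long_vrs) {
    readBin(con, raw(), n = 2L); .dcm_read_u32(con)
  } else .dcm_read_u16(con)
  first <- list(group = group, element = element, vr = vr,
                value = .dcm_decode_value(readBin(con, raw(), n = len), vr),
                depth = 0L)
  if (element == 0x0000) {
    budget <- first$value[1]
    rest <- .dcm_parse_elements(con, budget, TRUE, 0L, TRUE, path)
    c(list(first), rest)
  } else {
    # no group-length element: fall back to scanning while group == 0002
    stop("file meta group without group length in ", path, call. = FALSE)
  }
}

#' @export
print.dcm_dataset <- function(x, ...) {
  cat("<dcm_dataset> ", basename(x$path %||% "<memory>"),
      " (", x$transfer_syntax, ")\n", sep = "")
  cat("  meta elements: ", length(x$meta),
      ", dataset elements: ", length(x$elements), "\n", sep = "")
  invisible(x)
}

# Depth-first walk over an element tree, applying fn to every element.
# fn(el, depth) -> replacement element (or NULL to keep). Used by masking.
dcm_walk <- function(elements, fn, depth = 0L) {
  lapply(elements, function(el) {
    el2 <- fn(el, depth) %||% el
    if (identical(el2$vr, "SQ") && length(el2$value)) {
      el2$value <- lapply(el2$value, dcm_walk, fn = fn, depth = depth + 1L)
    }
    el2
  })
}
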