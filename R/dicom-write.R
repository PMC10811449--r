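# Serializer for DICOM Part-10 (explicit VR little endian, defined lengths).
# Covers exactly what the reader understands; used by the fixture emitter and
# by the de-identification rewriter.

.dcm_u16 <- function(x) writeBin(as.integer(x), raw(), size = 2L,
                                 endian = "little")
.dcm_u32 <- function(x) writeBin(as.integer(x), raw(), size = 4L,
                                 endian = "little")

.dcm_encode_value <- function(value, vr) {
  if (is.null(value)) return(raw(0))
  if (vr %in% .dcm_string_vrs) {
    s <- paste(as.character(value), collapse = "\\")
    bytes <- charToRaw(s)
    if (length(bytes) %% 2L == 1L) {
      pad <- if (vr == "UI") as.raw(0) else charToRaw(" ")
      bytes <- c(bytes, pad)
    }
    return(bytes)
  }
  bytes <- switch(vr,
    US = ,
    SS = writeBin(as.integer(value), raw(), size = 2L, endian = "little"),
    UL = ,
    SL = writeBin(as.integer(value), raw(), size = 4L, endian = "little"),
    FL = writeBin(as.double(value), raw(), size = 4L, endian = "little"),
    FD = writeBin(as.double(value), raw(), size = 8L, endian = "little"),
    as.raw(value)
  )
  if (length(bytes) %% 2L == 1L) bytes <- c(bytes, as.raw(0))
  bytes
}

.dcm_encode_element <- function(el) {
  vr <- el$vr
  if (identical(vr, "SQ")) {
    body <- unlist(lapply(el$value, function(item) {
      content <- unlist(lapply(item, .dcm_encode_element)) %||% raw(0)
      c(.dcm_u16(0xFFFE), .dcm_u16(0xE000), .dcm_u32(length(content)), content)
    })) %||% raw(0)
    return(c(.dcm_u16(el$group), .dcm_u16(el$element), charToRaw("SQ"),
             as.raw(c(0, 0)), .dcm_u32(length(body)), body))
  }
  bytes <- .dcm_encode_value(el$value, vr)
  header <- c(.dcm_u16(el$group), .dcm_u16(el$element), charToRaw(vr))
  if (vr %in% .dcm_long_vrs) {
    c(header, as.raw(c(0, 0)), .dcm_u32(length(bytes)), bytes)
  } else {
    if (length(bytes) > 65534L) stop("value too long for short VR ", vr)
    c(header, .dcm_u16(length(bytes)), bytes)
  }
}

# Order elements by (group, element) as the standard requires.
.dcm_sort_elements <- function(elements) {
  key <- vapply(elements, function(e) e$group * 2^16 + e$element, numeric(1))
  elements[order(key)]
}

#' Write an element tree as a DICOM Part-10 file
#'
#' Serializes a `dcm_dataset` (or a bare list of elements) with explicit VR
#' little endian encoding and defined lengths. A conformant file meta group
#' is generated from the dataset's SOPClassUID / SOPInstanceUID when the
#' input does not carry one.
#'
#' @param dataset a `dcm_dataset` from [dcm_read()], or a list of element
#'   lists (`group`, `element`, `vr`, `value`).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
dcm_write <- function(dataset, path) {
  elements <- if (inherits(dataset, "dcm_dataset")) dataset$elements else dataset
  elements <- .dcm_sort_elements(elements)
  skipped <- vapply(elements, function(e) isTRUE(e$skipped), logical(1))
  if (any(skipped)) {
    # pixel data was seeked past on read; rewrite it as a zero payload of
    # the recorded length so the census of tags is preserved
    elements[skipped] <- lapply(elements[skipped], function(e) {
      e$value <- raw(e$byte_length %||% 0L)
      e$skipped <- NULL
      e
    })
  }
  get_val <- function(g, e) {
    for (el in elements) if (el$group == g && el$element == e) return(el$value)
    NULL
  }
  sop_class <- get_val(0x0008, 0x0016) %||% "1.2.840.10008.5.1.4.1.1.7"
  sop_inst <- get_val(0x0008, 0x0018) %||% "0"
  meta_els <- list(
    list(group = 0x0002, element = 0x0001, vr = "OB", value = as.raw(c(0, 1))),
    list(group = 0x0002, element = 0x0002, vr = "UI", value = sop_class),
    list(group = 0x0002, element = 0x0003, vr = "UI", value = sop_inst),
    list(group = 0x0002, element = 0x0010, vr = "UI",
         value = DCM_UID$explicit_vr_le),
    list(group = 0x0002, element = 0x0012, vr = "UI",
         value = DCM_UID$implementation)
  )
  meta_body <- unlist(lapply(meta_els, .dcm_encode_element))
  group_len <- .dcm_encode_element(list(group = 0x0002, element = 0x0000,
                                        vr = "UL",
                                        value = length(meta_body)))
  body <- unlist(lapply(elements, .dcm_encode_element)) %||% raw(0)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128L), charToRaw("DICM"), group_len, meta_body, body), con)
  invisible(path)
}

# Convenience constructor: element from keyword or "(gggg,eeee)" spec.
dcm_el <- function(tag, value, vr = NULL) {
  ge <- dcm_resolve_tag(tag)
  if (is.null(ge)) stop("unknown DICOM tag: ", tag, call. = FALSE)
  if (is.null(vr)) {
    vr <- dcm_lookup(ge[1], ge[2])$vr
    if (is.na(vr)) stop("no VR known for tag ", tag, call. = FALSE)
  }
  list(group = ge[1], element = ge[2], vr = vr, value = value)
}

dcm_sq <- function(tag, items) {
  ge <- dcm_resolve_tag(tag)
  if (is.null(ge)) stop("unknown DICOM tag: ", tag, call. = FALSE)
  list(group = ge[1], element = ge[2], vr = "SQ", value = items)
}
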