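# Minimal XLSX writer.
#
# An .xlsx workbook is a zip container of XML parts.  No xlsx-writing package
# is declared as a dependency; instead the container is assembled here
# directly: raw deflate streams come from memCompress() (zlib wrapper
# stripped) and entry checksums from the package's CRC-32 routine.  Cells are
# written as plain numbers or inline strings, which is all the formats used
# by this package require, and is fully readable by readxl.

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

col_letters <- function(j) {
  vapply(j, function(n) {
    s <- ""
    while (n > 0) {
      r <- (n - 1) %% 26
      s <- paste0(LETTERS[r + 1], s)
      n <- (n - 1) %/% 26
    }
    s
  }, character(1))
}

# numbers serialized with 17 significant digits so that write -> read is
# bit-exact for doubles
num_chr <- function(x) {
  out <- vapply(x, function(v) formatC(v, digits = 17, format = "g"), character(1))
  out
}

worksheet_xml <- function(df) {
  nc <- length(df)
  nr <- if (nc) nrow(df) else 0L
  letters <- col_letters(seq_len(nc))
  hdr <- paste0('<c r="', letters, '1" t="inlineStr"><is><t>',
                xml_escape(names(df)), "</t></is></c>")
  rows <- character(nr + 1L)
  rows[1L] <- paste0('<row r="1">', paste(hdr, collapse = ""), "</row>")
  if (nr > 0L) {
    cols <- vector("list", nc)
    for (j in seq_len(nc)) {
      v <- df[[j]]
      ref <- paste0(letters[j], seq_len(nr) + 1L)
      if (is.numeric(v)) {
        cell <- paste0('<c r="', ref, '"><v>', num_chr(v), "</v></c>")
      } else {
        cell <- paste0('<c r="', ref, '" t="inlineStr"><is><t>',
                       xml_escape(as.character(v)), "</t></is></c>")
      }
      cell[is.na(v)] <- ""
      cols[[j]] <- cell
    }
    body <- do.call(paste0, cols)
    rows[-1L] <- paste0('<row r="', seq_len(nr) + 1L, '">', body, "</row>")
  }
  paste0('<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
         '<worksheet xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main">',
         "<sheetData>", paste(rows, collapse = ""), "</sheetData></worksheet>")
}

# zip container with deflate-compressed entries
zip_write <- function(path, entries) {
  con <- file(path, "wb")
  on.exit(close(con))
  u16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  u32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  u32d <- function(x) {  # value possibly >= 2^31, write as two u16
    writeBin(as.integer(c(x %% 65536, x %/% 65536)), con, size = 2,
             endian = "little")
  }
  nms <- names(entries)
  n <- length(entries)
  offs <- numeric(n); crcs <- numeric(n)
  csize <- integer(n); usize <- integer(n)
  pos <- 0
  defl <- vector("list", n)
  for (k in seq_len(n)) {
    data <- entries[[k]]
    if (is.character(data)) data <- charToRaw(paste(data, collapse = "\n"))
    zs <- memCompress(data, "gzip")        # zlib stream: 2-byte header, 4-byte adler
    defl[[k]] <- zs[3:(length(zs) - 4L)]
    crcs[k] <- crc32_cpp(data)
    usize[k] <- length(data)
    csize[k] <- length(defl[[k]])
  }
  for (k in seq_len(n)) {
    fn <- charToRaw(nms[k])
    offs[k] <- pos
    u32(0x04034b50); u16(20); u16(0); u16(8); u16(0); u16(0x21)
    u32d(crcs[k]); u32(csize[k]); u32(usize[k]); u16(length(fn)); u16(0)
    writeBin(fn, con); writeBin(defl[[k]], con)
    pos <- pos + 30 + length(fn) + csize[k]
  }
  cdstart <- pos
  for (k in seq_len(n)) {
    fn <- charToRaw(nms[k])
    u32(0x02014b50); u16(20); u16(20); u16(0); u16(8); u16(0); u16(0x21)
    u32d(crcs[k]); u32(csize[k]); u32(usize[k]); u16(length(fn))
    u16(0); u16(0); u16(0); u16(0); u32(0); u32(offs[k])
    writeBin(fn, con)
    pos <- pos + 46 + length(fn)
  }
  u32(0x06054b50); u16(0); u16(0); u16(n); u16(n)
  u32(pos - cdstart); u32(cdstart); u16(0)
  invisible(path)
}

#' Write data frames to an XLSX workbook
#'
#' Writes one worksheet per element of `sheets`.  Numeric cells are stored at
#' full double precision; character cells as inline strings; `NA` as blank.
#'
#' @param sheets Named list of data frames (names become sheet names).
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_xlsx <- function(sheets, path) {
  stopifnot(is.list(sheets), length(sheets) >= 1L)
  if (is.null(names(sheets)) || any(!nzchar(names(sheets))))
    stop("every sheet must be named")
  n <- length(sheets)
  sheet_entries <- list()
  defs <- rels <- ovr <- character(n)
  for (k in seq_len(n)) {
    sheet_entries[[paste0("xl/worksheets/sheet", k, ".xml")]] <-
      worksheet_xml(as.data.frame(sheets[[k]], stringsAsFactors = FALSE,
                                  check.names = FALSE))
    defs[k] <- sprintf('<sheet name="%s" sheetId="%d" r:id="rId%d"/>',
                       xml_escape(names(sheets)[k]), k, k)
    rels[k] <- sprintf(paste0(
      '<Relationship Id="rId%d" Type="http://schemas.openxmlformats.org/',
      'officeDocument/2006/relationships/worksheet" Target="worksheets/sheet%d.xml"/>'),
      k, k)
    ovr[k] <- sprintf(paste0(
      '<Override PartName="/xl/worksheets/sheet%d.xml" ContentType=',
      '"application/vnd.openxmlformats-officedocument.spreadsheetml.worksheet+xml"/>'), k)
  }
  entries <- c(list(
    "[Content_Types].xml" = paste0(
      '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
      '<Types xmlns="http://schemas.openxmlformats.org/package/2006/content-types">',
      '<Default Extension="rels" ContentType="application/vnd.openxmlformats-package.relationships+xml"/>',
      '<Default Extension="xml" ContentType="application/xml"/>',
      '<Override PartName="/xl/workbook.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.sheet.main+xml"/>',
      paste(ovr, collapse = ""), "</Types>"),
    "_rels/.rels" = paste0(
      '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
      '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
      '<Relationship Id="rId1" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/officeDocument" Target="xl/workbook.xml"/>',
      "</Relationships>"),
    "xl/workbook.xml" = paste0(
      '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
      '<workbook xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main" ',
      'xmlns:r="http://schemas.openxmlformats.org/officeDocument/2006/relationships">',
      "<sheets>", paste(defs, collapse = ""), "</sheets></workbook>"),
    "xl/_rels/workbook.xml.rels" = paste0(
      '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
      '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
      paste(rels, collapse = ""), "</Relationships>")
  ), sheet_entries)
  zip_write(path, entries)
  invisible(path)
}
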