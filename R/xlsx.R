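# Minimal self-contained xlsx (SpreadsheetML in a ZIP container) writer and
# reader. Entries are stored uncompressed; cell strings are inline (no
# shared-string table); numbers are written with full precision. The reader
# understands exactly what the writer produces (plus plain shared-less
# workbooks from other tools that use inline strings or numeric cells).

.crcEnv <- new.env(parent = emptyenv())

.crc32Table <- function() {
  if (!is.null(.crcEnv$table)) return(.crcEnv$table)
  tab <- integer(256)
  for (i in 0:255) {
    c <- i
    for (k in 1:8) {
      c <- if (bitwAnd(c, 1L) != 0L)
        bitwXor(bitwShiftR(c, 1L), -306674912L)  # 0xEDB88320
      else bitwShiftR(c, 1L)
    }
    tab[i + 1] <- c
  }
  .crcEnv$table <- tab
  tab
}

.crc32 <- function(bytes) {
  tab <- .crc32Table()
  crc <- -1L  # 0xFFFFFFFF
  b <- as.integer(bytes)
  for (i in seq_along(b)) {
    crc <- bitwXor(bitwShiftR(crc, 8L),
                   tab[bitwAnd(bitwXor(crc, b[i]), 255L) + 1L])
  }
  bitwXor(crc, -1L)
}

.u16 <- function(x) writeBin(as.integer(x), raw(), size = 2,
                             endian = "little")
.u32 <- function(x) writeBin(as.integer(x), raw(), size = 4,
                             endian = "little")

# write named raw entries into a ZIP archive (stored, no compression)
.zipWrite <- function(entries, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  offsets <- integer(length(entries))
  crcs <- integer(length(entries))
  pos <- 0L
  nms <- names(entries)
  for (i in seq_along(entries)) {
    data <- entries[[i]]
    nameRaw <- charToRaw(nms[i])
    crcs[i] <- .crc32(data)
    offsets[i] <- pos
    hdr <- c(.u32(67324752L),               # local header signature
             .u16(20L), .u16(0L), .u16(0L), # version, flags, method=stored
             .u16(0L), .u16(33L),           # time, date (fixed: 1980-01-01)
             .u32(crcs[i]), .u32(length(data)), .u32(length(data)),
             .u16(length(nameRaw)), .u16(0L), nameRaw)
    writeBin(hdr, con)
    writeBin(data, con)
    pos <- pos + length(hdr) + length(data)
  }
  cdStart <- pos
  for (i in seq_along(entries)) {
    nameRaw <- charToRaw(nms[i])
    cd <- c(.u32(33639248L), .u16(20L), .u16(20L), .u16(0L), .u16(0L),
            .u16(0L), .u16(33L), .u32(crcs[i]),
            .u32(length(entries[[i]])), .u32(length(entries[[i]])),
            .u16(length(nameRaw)), .u16(0L), .u16(0L), .u16(0L), .u16(0L),
            .u32(0L), .u32(offsets[i]), nameRaw)
    writeBin(cd, con)
    pos <- pos + length(cd)
  }
  eocd <- c(.u32(101010256L), .u16(0L), .u16(0L),
            .u16(length(entries)), .u16(length(entries)),
            .u32(pos - cdStart), .u32(cdStart), .u16(0L))
  writeBin(eocd, con)
  invisible(path)
}

.xmlEscape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  x
}

.colRef <- function(j) {
  ref <- ""
  while (j > 0) {
    ref <- paste0(LETTERS[(j - 1) %% 26 + 1], ref)
    j <- (j - 1) %/% 26
  }
  ref
}

# cells: a matrix/data.frame of values (numeric or character; NA = empty)
.sheetXML <- function(cells) {
  cells <- as.matrix(cells)
  rows <- character(nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cs <- character(0)
    for (j in seq_len(ncol(cells))) {
      v <- cells[i, j]
      if (is.na(v) || (is.character(v) && !nzchar(v))) next
      ref <- paste0(.colRef(j), i)
      num <- suppressWarnings(as.numeric(v))
      if (!is.na(num) && !is.na(v) && grepl("^[-+0-9.eE]+$", v)) {
        cs <- c(cs, sprintf('<c r="%s"><v>%s</v></c>', ref, v))
      } else {
        cs <- c(cs, sprintf(
          '<c r="%s" t="inlineStr"><is><t xml:space="preserve">%s</t></is></c>',
          ref, .xmlEscape(v)))
      }
    }
    rows[i] <- sprintf('<row r="%d">%s</row>', i, paste(cs, collapse = ""))
  }
  paste0('<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
         '<worksheet xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main">',
         '<sheetData>', paste(rows, collapse = ""), '</sheetData></worksheet>')
}

#' Write a list of tables to an xlsx workbook
#'
#' Each element of \code{sheets} becomes one worksheet (values written as
#' numbers where numeric-looking, otherwise as inline strings; NA becomes
#' an empty cell). Intended for measurement export; no formatting, charts
#' or formulas.
#'
#' @param sheets named list of data.frames/matrices of cell values
#'   (character or numeric).
#' @param path output .xlsx path.
#' @return \code{path}, invisibly.
#' @export
writeXlsx <- function(sheets, path) {
  stopifnot(length(sheets) >= 1, !is.null(names(sheets)))
  n <- length(sheets)
  ct <- paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Types xmlns="http://schemas.openxmlformats.org/package/2006/content-types">',
    '<Default Extension="rels" ContentType="application/vnd.openxmlformats-package.relationships+xml"/>',
    '<Default Extension="xml" ContentType="application/xml"/>',
    '<Override PartName="/xl/workbook.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.sheet.main+xml"/>',
    paste(sprintf('<Override PartName="/xl/worksheets/sheet%d.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.worksheet+xml"/>',
                  seq_len(n)), collapse = ""),
    '<Override PartName="/xl/styles.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.styles+xml"/>',
    '</Types>')
  rels <- paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    '<Relationship Id="rId1" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/officeDocument" Target="xl/workbook.xml"/>',
    '</Relationships>')
  wb <- paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<workbook xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main" ',
    'xmlns:r="http://schemas.openxmlformats.org/officeDocument/2006/relationships">',
    '<sheets>',
    paste(sprintf('<sheet name="%s" sheetId="%d" r:id="rId%d"/>',
                  .xmlEscape(names(sheets)), seq_len(n), seq_len(n)),
          collapse = ""),
    '</sheets></workbook>')
  wbRels <- paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    paste(sprintf('<Relationship Id="rId%d" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/worksheet" Target="worksheets/sheet%d.xml"/>',
                  seq_len(n), seq_len(n)), collapse = ""),
    sprintf('<Relationship Id="rId%d" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/styles" Target="styles.xml"/>',
            n + 1L),
    '</Relationships>')
  styles <- paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<styleSheet xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main">',
    '<fonts count="1"><font><sz val="11"/><name val="Calibri"/></font></fonts>',
    '<fills count="1"><fill><patternFill patternType="none"/></fill></fills>',
    '<borders count="1"><border/></borders>',
    '<cellStyleXfs count="1"><xf/></cellStyleXfs>',
    '<cellXfs count="1"><xf xfId="0"/></cellXfs>',
    '</styleSheet>')
  entries <- list("[Content_Types].xml" = charToRaw(ct),
                  "_rels/.rels" = charToRaw(rels),
                  "xl/workbook.xml" = charToRaw(wb),
                  "xl/_rels/workbook.xml.rels" = charToRaw(wbRels),
                  "xl/styles.xml" = charToRaw(styles))
  for (i in seq_len(n)) {
    entries[[sprintf("xl/worksheets/sheet%d.xml", i)]] <-
      charToRaw(.sheetXML(sheets[[i]]))
  }
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  .zipWrite(entries, path)
  invisible(path)
}

#' Read an xlsx workbook written by \code{\link{writeXlsx}}
#'
#' @param path .xlsx path.
#' @param sheet sheet name or index.
#' @return Character matrix of cell values ("" for empty cells).
#' @export
readXlsxSheet <- function(path, sheet = 1L) {
  tmp <- tempfile("xlsx")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE))
  utils::unzip(path, exdir = tmp)
  wb <- xml2::read_xml(file.path(tmp, "xl", "workbook.xml"))
  ns <- xml2::xml_ns(wb)
  sheetNodes <- xml2::xml_find_all(wb, ".//d1:sheet", ns)
  nms <- xml2::xml_attr(sheetNodes, "name")
  idx <- if (is.character(sheet)) match(sheet, nms) else as.integer(sheet)
  if (is.na(idx) || idx < 1 || idx > length(nms))
    stop(sprintf("no sheet '%s' in %s", as.character(sheet), path))
  ws <- xml2::read_xml(file.path(tmp, "xl", "worksheets",
                                 sprintf("sheet%d.xml", idx)))
  wns <- xml2::xml_ns(ws)
  rows <- xml2::xml_find_all(ws, ".//d1:row", wns)
  if (!length(rows)) return(matrix(character(0), 0, 0))
  parsed <- lapply(rows, function(r) {
    cells <- xml2::xml_find_all(r, "./d1:c", wns)
    refs <- xml2::xml_attr(cells, "r")
    cols <- vapply(refs, function(ref) {
      letters_ <- gsub("[0-9]+$", "", ref)
      sum((utf8ToInt(letters_) - 64L) *
            26^(rev(seq_along(utf8ToInt(letters_))) - 1L))
    }, 0)
    vals <- vapply(cells, function(cc) {
      if (identical(xml2::xml_attr(cc, "t"), "inlineStr"))
        xml2::xml_text(xml2::xml_find_first(cc, "./d1:is/d1:t", wns))
      else xml2::xml_text(xml2::xml_find_first(cc, "./d1:v", wns))
    }, "")
    list(row = as.integer(xml2::xml_attr(r, "r")), cols = cols, vals = vals)
  })
  nr <- max(vapply(parsed, `[[`, 0L, "row"))
  ncol_ <- max(unlist(lapply(parsed, `[[`, "cols")), 1)
  out <- matrix("", nr, ncol_)
  for (p in parsed) if (length(p$cols)) out[p$row, p$cols] <- p$vals
  out
}
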