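# Minimal single-sheet xlsx writer. An xlsx file is a zip of
# SpreadsheetML parts; numbers are written as native numeric cells and
# everything else as inline strings. No pre-installed package writes
# xlsx, and CSV stays the canonical format, so this mirror is kept
# deliberately small.

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

xlsx_col_letter <- function(j) {
  out <- ""
  while (j > 0L) {
    out <- paste0(LETTERS[(j - 1L) %% 26L + 1L], out)
    j <- (j - 1L) %/% 26L
  }
  out
}

xlsx_cell <- function(ref, value) {
  if (is.numeric(value) && !is.na(value))
    sprintf('<c r="%s"><v>%.17g</v></c>', ref, value)
  else if (is.na(value))
    sprintf('<c r="%s"/>', ref)
  else
    sprintf('<c r="%s" t="inlineStr"><is><t>%s</t></is></c>',
            ref, xml_escape(as.character(value)))
}

write_minimal_xlsx <- function(df, path, sheet = "Sheet1") {
  rows <- character(nrow(df) + 1L)
  header <- vapply(seq_along(df), function(j)
    xlsx_cell(paste0(xlsx_col_letter(j), 1L), names(df)[j]), character(1))
  rows[1L] <- sprintf('<row r="1">%s</row>', paste(header, collapse = ""))
  for (i in seq_len(nrow(df))) {
    cells <- vapply(seq_along(df), function(j)
      xlsx_cell(paste0(xlsx_col_letter(j), i + 1L), df[[j]][i]), character(1))
    rows[i + 1L] <- sprintf('<row r="%d">%s</row>', i + 1L,
                            paste(cells, collapse = ""))
  }
  decl <- '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n'
  parts <- list(
    "[Content_Types].xml" = paste0(decl,
      '<Types xmlns="http://schemas.openxmlformats.org/package/2006/content-types">',
      '<Default Extension="rels" ContentType="application/vnd.openxmlformats-package.relationships+xml"/>',
      '<Default Extension="xml" ContentType="application/xml"/>',
      '<Override PartName="/xl/workbook.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.sheet.main+xml"/>',
      '<Override PartName="/xl/worksheets/sheet1.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.worksheet+xml"/>',
      '</Types>'),
    "_rels/.rels" = paste0(decl,
      '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
      '<Relationship Id="rId1" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/officeDocument" Target="xl/workbook.xml"/>',
      '</Relationships>'),
    "xl/workbook.xml" = paste0(decl,
      '<workbook xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main" ',
      'xmlns:r="http://schemas.openxmlformats.org/officeDocument/2006/relationships">',
      sprintf('<sheets><sheet name="%s" sheetId="1" r:id="rId1"/></sheets>',
              xml_escape(sheet)),
      '</workbook>'),
    "xl/_rels/workbook.xml.rels" = paste0(decl,
      '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
      '<Relationship Id="rId1" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/worksheet" Target="worksheets/sheet1.xml"/>',
      '</Relationships>'),
    "xl/worksheets/sheet1.xml" = paste0(decl,
      '<worksheet xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main">',
      '<sheetData>', paste(rows, collapse = ""), '</sheetData>',
      '</worksheet>')
  )
  stage <- tempfile("xlsx")
  on.exit(unlink(stage, recursive = TRUE), add = TRUE)
  for (name in names(parts)) {
    full <- file.path(stage, name)
    dir.create(dirname(full), recursive = TRUE, showWarnings = FALSE)
    writeLines(parts[[name]], full, sep = "")
  }
  path <- file.path(normalizePath(dirname(path), mustWork = TRUE),
                    basename(path))
  zip::zip(path, files = names(parts), root = stage,
           include_directories = FALSE)
  invisible(path)
}
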