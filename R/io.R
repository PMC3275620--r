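## Readers and writers for binary character matrices (NEXUS standard-datatype
## DATA block, relaxed PHYLIP, headered CSV), trait tables (TSV) and square
## distance matrices. The NEXUS/PHYLIP dialects here are the small binary
## subset used for dominant-marker matrices; parse errors name the offending
## line.

.parseError <- function(path, line, msg) {
  stop(sprintf("parse error in '%s' line %d: %s", path, line, msg),
       call. = FALSE)
}

.rowsToMatrix <- function(labels, rows, path, lineNos) {
  if (anyDuplicated(labels))
    stop(sprintf("duplicate taxon '%s' in '%s'",
                 labels[duplicated(labels)][1L], path), call. = FALSE)
  lens <- nchar(rows)
  if (length(unique(lens)) != 1L)
    .parseError(path, lineNos[which(lens != lens[1L])[1L]],
                "rows have unequal numbers of characters")
  cells <- strsplit(rows, "")
  bad <- vapply(cells, function(z) {
    w <- which(!z %in% c("0", "1", "?"))
    if (length(w)) w[1L] else 0L
  }, integer(1))
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    .parseError(path, lineNos[i],
                sprintf("non-binary symbol '%s'", cells[[i]][bad[i]]))
  }
  m <- do.call(rbind, lapply(cells, function(z) {
    out <- suppressWarnings(as.integer(z))
    out  # "?" becomes NA
  }))
  rownames(m) <- labels
  AFLPMatrix(m)
}

.readMatrixCSV <- function(path) {
  d <- read.csv(path, header = TRUE, check.names = FALSE,
                stringsAsFactors = FALSE)
  if (ncol(d) < 2L)
    .parseError(path, 1L, "CSV needs a taxon column plus >=1 locus column")
  labels <- as.character(d[[1L]])
  m <- as.matrix(d[, -1L, drop = FALSE])
  cells <- suppressWarnings(matrix(as.integer(m), nrow = nrow(m)))
  raw <- trimws(as.character(m))
  isMissing <- raw %in% c("?", "", "NA")
  bad <- which(is.na(cells) & !isMissing)
  if (length(bad))
    stop(sprintf("non-binary symbol '%s' in '%s'", raw[bad[1L]], path),
         call. = FALSE)
  cells[matrix(isMissing, nrow = nrow(m))] <- NA_integer_
  if (any(!is.na(cells) & cells != 0L & cells != 1L))
    stop(sprintf("non-binary value in '%s'", path), call. = FALSE)
  rownames(cells) <- labels
  colnames(cells) <- colnames(d)[-1L]
  if (anyDuplicated(labels))
    stop(sprintf("duplicate taxon '%s' in '%s'",
                 labels[duplicated(labels)][1L], path), call. = FALSE)
  AFLPMatrix(cells)
}

.readMatrixPhylip <- function(path) {
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (!length(nonblank)) .parseError(path, 1L, "empty file")
  hdr <- strsplit(trimws(lines[nonblank[1L]]), "\\s+")[[1L]]
  if (length(hdr) != 2L || anyNA(suppressWarnings(as.integer(hdr))))
    .parseError(path, nonblank[1L], "header must be '<ntax> <nchar>'")
  ntax <- as.integer(hdr[1L]); nchar_ <- as.integer(hdr[2L])
  body <- nonblank[-1L]
  if (length(body) < ntax)
    .parseError(path, length(lines),
                sprintf("expected %d taxon rows, found %d", ntax, length(body)))
  body <- body[seq_len(ntax)]
  labels <- character(ntax); rows <- character(ntax)
  for (i in seq_len(ntax)) {
    ln <- trimws(lines[body[i]])
    sp <- regexpr("\\s", ln)
    if (sp < 0) .parseError(path, body[i], "row lacks character data")
    labels[i] <- substr(ln, 1L, sp - 1L)
    rows[i] <- gsub("\\s+", "", substr(ln, sp + 1L, nchar(ln)))
  }
  x <- .rowsToMatrix(labels, rows, path, body)
  if (nLoci(x) != nchar_)
    .parseError(path, body[1L],
                sprintf("header promises %d characters, rows have %d",
                        nchar_, nLoci(x)))
  x
}

.readMatrixNexus <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !grepl("^#NEXUS", toupper(trimws(lines[1L]))))
    .parseError(path, 1L, "missing #NEXUS header")
  up <- toupper(lines)
  mstart <- grep("^\\s*MATRIX\\s*$", up)
  if (!length(mstart)) .parseError(path, length(lines), "no MATRIX block")
  mstart <- mstart[1L]
  mend <- which(grepl("^\\s*;\\s*$", lines) & seq_along(lines) > mstart)
  if (!length(mend))
    .parseError(path, length(lines), "MATRIX block not terminated by ';'")
  mend <- mend[1L]
  body <- (mstart + 1L):(mend - 1L)
  body <- body[nzchar(trimws(lines[body]))]
  labels <- character(0); rows <- character(0); lineNos <- integer(0)
  for (i in body) {
    ln <- trimws(lines[i])
    if (startsWith(ln, "'")) {
      close <- regexpr("'", substr(ln, 2L, nchar(ln)))
      if (close < 0) .parseError(path, i, "unterminated quoted label")
      lab <- substr(ln, 2L, close)
      rest <- trimws(substr(ln, close + 2L, nchar(ln)))
    } else {
      sp <- regexpr("\\s", ln)
      if (sp < 0) .parseError(path, i, "row lacks character data")
      lab <- substr(ln, 1L, sp - 1L)
      rest <- trimws(substr(ln, sp + 1L, nchar(ln)))
    }
    labels <- c(labels, lab)
    rows <- c(rows, gsub("\\s+", "", rest))
    lineNos <- c(lineNos, i)
  }
  if (!length(labels)) .parseError(path, mstart, "empty MATRIX block")
  .rowsToMatrix(labels, rows, path, lineNos)
}

#' Read a binary AFLP matrix
#'
#' Supported dialects: headered CSV (first column = taxon), relaxed PHYLIP
#' (`<ntax> <nchar>` header, whitespace-separated name then 0/1/? string),
#' and a NEXUS DATA block with `datatype=standard symbols="01" missing=?`.
#'
#' @param path file path.
#' @param format one of "csv", "phylip", "nexus"; default guessed from the
#'   file extension.
#' @return an [AFLPMatrix-class].
#' @export
readAFLPMatrix <- function(path, format = c("auto", "csv", "phylip", "nexus")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", nex = "nexus", nexus = "nexus",
                     phy = "phylip", phylip = "phylip",
                     stop("cannot guess format from extension '", ext, "'",
                          call. = FALSE))
  }
  switch(format,
         csv = .readMatrixCSV(path),
         phylip = .readMatrixPhylip(path),
         nexus = .readMatrixNexus(path))
}

#' Write a binary AFLP matrix
#'
#' Missing cells are written as `?` (NEXUS/PHYLIP) or empty fields (CSV).
#'
#' @param x an [AFLPMatrix-class].
#' @param path output file path.
#' @param format one of "csv", "phylip", "nexus".
#' @return invisibly, `path`.
#' @export
writeAFLPMatrix <- function(x, path, format = c("csv", "phylip", "nexus")) {
  format <- match.arg(format)
  stopifnot(is(x, "AFLPMatrix"))
  validObject(x)
  m <- aflpCharacters(x)
  ch <- matrix(as.character(m), nrow = nrow(m))
  if (format == "csv") {
    d <- data.frame(taxon = rownames(m), ch, check.names = FALSE,
                    stringsAsFactors = FALSE)
    names(d) <- c("taxon", colnames(m))
    write.csv(d, path, row.names = FALSE, quote = FALSE, na = "?")
    return(invisible(path))
  }
  ch[is.na(ch)] <- "?"
  rows <- apply(ch, 1L, paste0, collapse = "")
  labels <- rownames(m)
  if (any(grepl("\\s", labels)))
    stop("taxon labels must not contain whitespace for ", format, " output",
         call. = FALSE)
  if (format == "phylip") {
    writeLines(c(paste(nrow(m), ncol(m)), paste(labels, rows)), path)
  } else {
    writeLines(c(
      "#NEXUS",
      "BEGIN DATA;",
      sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", nrow(m), ncol(m)),
      "  FORMAT DATATYPE=STANDARD SYMBOLS=\"01\" MISSING=?;",
      "  MATRIX",
      paste("   ", labels, rows),
      "  ;",
      "END;"), path)
  }
  invisible(path)
}

#' Read / write a trait table as TSV
#'
#' Columns: `taxon`, `species` (optional), `site` (optional), `care_state`.
#'
#' @param path file path.
#' @param alphabet optional state alphabet; default from the data.
#' @return a [TraitTable-class].
#' @export
readTraitTable <- function(path, alphabet = NULL) {
  d <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                  quote = "")
  stateCol <- if ("care_state" %in% names(d)) "care_state" else "state"
  if (!all(c("taxon", stateCol) %in% names(d)))
    stop("trait TSV needs 'taxon' and 'care_state' (or 'state') columns",
         call. = FALSE)
  TraitTable(taxon = d$taxon, state = d[[stateCol]],
             alphabet = if (is.null(alphabet)) sort(unique(d[[stateCol]]))
                        else alphabet,
             species = if ("species" %in% names(d)) d$species else NULL,
             site = if ("site" %in% names(d)) d$site else NULL)
}

#' @rdname readTraitTable
#' @param x a [TraitTable-class].
#' @export
writeTraitTable <- function(x, path) {
  d <- x@data
  out <- data.frame(taxon = d$taxon,
                    species = if ("species" %in% names(d)) d$species else NA,
                    site = if ("site" %in% names(d)) d$site else NA,
                    care_state = d$state, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a DistanceMatrix in square PHYLIP format
#'
#' @param d a [DistanceMatrix-class].
#' @param path output path.
#' @export
writeDistanceMatrix <- function(d, path) {
  v <- as.matrix(d)
  lines <- c(as.character(nrow(v)),
             paste(rownames(v),
                   apply(v, 1L, function(r)
                     paste(sprintf("%.6f", r), collapse = " "))))
  writeLines(lines, path)
  invisible(path)
}

#' The packaged parental-care sampling table
#'
#' Thirty-seven individuals from the Lake Tanganyika *Xenotilapia* lineage
#' and its Ectodini outgroups, with collection site and parental-care
#' strategy ("Maternal Mouthbrooder" or "Biparental Mouthbrooder") for each
#' individual. Taxon identifiers are synthesized (species abbreviation plus
#' running index); species, site and care strategy follow the published
#' sampling table verbatim.
#'
#' @return a [TraitTable-class] with 37 rows and species/site metadata.
#' @examples
#' tab <- xenotilapiaCareTable()
#' table(traitData(tab)$state)
#' @export
xenotilapiaCareTable <- function() {
  path <- system.file("extdata", "xenotilapia_care_table.tsv",
                      package = "aflphylo", mustWork = TRUE)
  readTraitTable(path,
                 alphabet = c("Biparental Mouthbrooder",
                              "Maternal Mouthbrooder"))
}
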