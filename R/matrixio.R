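#' The twelve compound classes used as binary characters
#'
#' Fertility-linked compounds are grouped into classes corresponding to
#' known or presumed biosynthetic pathways; the presence of at least one
#' fertility-linked compound of a class in a species is one binary
#' character.
#'
#' @return Character vector of the 12 class names.
#' @export
compound_classes <- function() {
  c("linear alkane", "branched alkane", "alkene", "alkadiene",
    "aldehyde", "alcohol", "fatty acid", "keto acid", "ester",
    "terpene", "terpene alcohol", "lactone")
}

#' Construct a binary species-by-character matrix
#'
#' @param x Matrix or data frame coercible to one; rows = species (rownames
#'   or a `species` column), cells 0/1/`NA` (or `"0"/"1"/"?"`).
#' @return A validated numeric matrix with species rownames.
#' @export
character_matrix <- function(x) {
  if (is.data.frame(x)) {
    if ("species" %in% colnames(x)) {
      rn <- as.character(x$species)
      x <- x[, setdiff(colnames(x), "species"), drop = FALSE]
      x <- as.matrix(x)
      rownames(x) <- rn
    } else x <- as.matrix(x)
  }
  if (is.character(x)) {
    x[x == "?"] <- NA
    storage.mode(x) <- "numeric"
  }
  storage.mode(x) <- "numeric"
  validate_character_matrix(x)
}

#' Validate a binary character matrix
#'
#' @param mat Matrix with species rownames; cells must be 0, 1 or `NA`.
#' @return The matrix, invisibly valid (returned for chaining).
#' @export
validate_character_matrix <- function(mat) {
  mat <- as.matrix(mat)
  if (is.character(mat)) {
    mat[mat == "?"] <- NA
    storage.mode(mat) <- "numeric"
  }
  if (is.null(rownames(mat)) && nrow(mat) > 0)
    stop("character matrix must have species rownames")
  if (nrow(mat) > 0 && anyDuplicated(rownames(mat)))
    stop("duplicate species in character matrix: ",
         paste(unique(rownames(mat)[duplicated(rownames(mat))]), collapse = ", "))
  vals <- mat[!is.na(mat)]
  if (length(vals) && !all(vals %in% c(0, 1)))
    stop("character matrix cells must be 0, 1 or ?/NA")
  mat
}

#' Read a binary character matrix (TSV or NEXUS)
#'
#' TSV: first column `species`, remaining columns characters, cells
#' `0`/`1`/`?`. NEXUS: a `DATA`/`CHARACTERS` block with
#' `DATATYPE=STANDARD`, symbols 0/1 and `MISSING=?`; quoted taxon labels
#' (species names with spaces) are supported.
#'
#' @param path Input file; format inferred from the extension
#'   (`.nex`/`.nexus` vs anything else = TSV) unless `format` is given.
#' @param format `"tsv"` or `"nexus"`.
#' @return A validated character matrix.
#' @export
read_character_matrix <- function(path, format = NULL) {
  if (!file.exists(path)) stop("matrix file not found: ", path)
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("nex", "nexus")) "nexus" else "tsv"
  }
  switch(match.arg(format, c("tsv", "nexus")),
    tsv = {
      df <- utils::read.delim(path, check.names = FALSE,
                              colClasses = "character")
      if (!"species" %in% colnames(df))
        stop("TSV matrix must have a 'species' column")
      character_matrix(df)
    },
    nexus = .read_nexus_standard(path)
  )
}

#' Write a binary character matrix (TSV or NEXUS)
#'
#' @param mat A character matrix (see [character_matrix()]).
#' @param path Output file.
#' @param format `"tsv"` or `"nexus"`; default inferred from extension.
#' @export
write_character_matrix <- function(mat, path, format = NULL) {
  mat <- validate_character_matrix(mat)
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("nex", "nexus")) "nexus" else "tsv"
  }
  format <- match.arg(format, c("tsv", "nexus"))
  if (format == "tsv") {
    cells <- matrix(ifelse(is.na(mat), "?", as.character(mat)),
                    nrow(mat), ncol(mat), dimnames = dimnames(mat))
    df <- data.frame(species = rownames(mat), cells, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    .write_nexus_standard(mat, path)
  }
  invisible(path)
}

# Minimal NEXUS STANDARD-datatype matrix writer with properly quoted taxon
# labels (names with spaces break the generic readers/writers available).
.write_nexus_standard <- function(mat, path) {
  quote_taxon <- function(x) {
    needs <- grepl("[^A-Za-z0-9_.+|/-]", x)
    x[needs] <- paste0("'", gsub("'", "''", x[needs]), "'")
    x
  }
  taxa <- quote_taxon(rownames(mat))
  rows <- apply(mat, 1, function(r) paste(ifelse(is.na(r), "?", r), collapse = ""))
  pad <- max(nchar(taxa))
  lines <- c(
    "#NEXUS",
    "BEGIN DATA;",
    sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", nrow(mat), ncol(mat)),
    "  FORMAT DATATYPE=STANDARD SYMBOLS=\"01\" MISSING=? GAP=-;",
    if (!is.null(colnames(mat)))
      sprintf("  [characters: %s]", paste(colnames(mat), collapse = " | ")),
    "  MATRIX",
    sprintf("    %-*s  %s", pad, taxa, rows),
    "  ;",
    "END;"
  )
  writeLines(lines, path)
}

.read_nexus_standard <- function(path) {
  txt <- readLines(path, warn = FALSE)
  if (!grepl("^#NEXUS", txt[1], ignore.case = TRUE))
    stop("not a NEXUS file: ", path)
  # recover optional character names from our comment line
  char_names <- NULL
  cn <- grep("^\\s*\\[characters:", txt, value = TRUE)
  if (length(cn) == 1L) {
    inner <- sub("^\\s*\\[characters:\\s*", "", sub("\\]\\s*$", "", cn))
    char_names <- trimws(strsplit(inner, "\\|")[[1]])
  }
  body <- paste(txt[!grepl("^\\s*\\[", txt)], collapse = "\n")
  m <- regmatches(body, regexpr("(?is)MATRIX(.*?);", body, perl = TRUE))
  if (!length(m)) stop("no MATRIX block found in ", path)
  rows <- strsplit(sub("(?is)^MATRIX", "", m, perl = TRUE), "\n")[[1]]
  rows <- trimws(sub(";\\s*$", "", rows))
  rows <- rows[nzchar(rows)]
  parse_row <- function(r) {
    if (startsWith(r, "'")) {
      # quoted taxon: find closing quote not doubled
      chars <- strsplit(r, "")[[1]]
      j <- 2L
      lab <- character(0)
      while (j <= length(chars)) {
        if (chars[j] == "'") {
          if (j < length(chars) && chars[j + 1L] == "'") { lab <- c(lab, "'"); j <- j + 2L }
          else break
        } else { lab <- c(lab, chars[j]); j <- j + 1L }
      }
      taxon <- paste(lab, collapse = "")
      states <- gsub("\\s", "", substr(r, j + 1L, nchar(r)))
    } else {
      taxon <- sub("\\s.*$", "", r)
      states <- gsub("\\s", "", sub("^\\S+", "", r))
    }
    list(taxon = taxon, states = states)
  }
  parsed <- lapply(rows, parse_row)
  taxa <- vapply(parsed, `[[`, character(1), "taxon")
  states <- vapply(parsed, `[[`, character(1), "states")
  if (length(unique(nchar(states))) != 1L)
    stop("ragged MATRIX rows in ", path)
  cells <- do.call(rbind, strsplit(states, ""))
  cells[cells == "?"] <- NA
  mat <- matrix(suppressWarnings(as.numeric(cells)), nrow = length(taxa))
  rownames(mat) <- taxa
  if (!is.null(char_names) && length(char_names) == ncol(mat))
    colnames(mat) <- char_names
  else colnames(mat) <- paste0("char", seq_len(ncol(mat)))
  validate_character_matrix(mat)
}
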