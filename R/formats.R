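# Distance-matrix serialization in the MEGA (lower-left triangle) and
# PHYLIP (square, 10-character names) dialects, plus minimal readers used to
# verify round-trip fidelity.

matrix_document <- function(dialect, body) {
  structure(list(dialect = dialect, body = body), class = "matrix_document")
}

#' @export
print.matrix_document <- function(x, ...) {
  cat(x$body)
  invisible(x)
}

check_format_matrix <- function(m) {
  d <- unclass(as.matrix(m))
  if (nrow(d) < 2L) stop("matrix output needs at least 2 samples")
  nm <- rownames(d)
  if (is.null(nm)) stop("matrix output needs sample names")
  if (anyDuplicated(nm)) {
    stop("duplicate sample names: ", paste(unique(nm[duplicated(nm)]),
                                           collapse = ", "))
  }
  d
}

#' Write a distance matrix in MEGA format
#'
#' Emits the `#mega` magic line, a `!Title`, a `!Format` declaration
#' (`DataType=Distance DataFormat=LowerLeft`), one `#name` line per taxon,
#' and the lower-left triangle with 6-decimal fixed-point values (row *i*
#' lists its distances to taxa *1..i-1*).
#'
#' @param m Distance matrix with sample names.
#' @param title Text placed in the `!Title` line.
#' @param file Optional output path.
#' @return A `matrix_document` (list of `dialect` and `body`), invisibly when
#'   `file` is given.
#' @export
write_mega <- function(m, title = "Pairwise distances", file = NULL) {
  d <- check_format_matrix(m)
  n <- nrow(d)
  nm <- rownames(d)
  rows <- vapply(2:n, function(i) {
    paste(sprintf("%.6f", d[i, seq_len(i - 1L)]), collapse = " ")
  }, character(1L))
  body <- paste0(paste(c("#mega",
                         paste0("!Title ", title, ";"),
                         sprintf("!Format DataType=Distance DataFormat=LowerLeft NTaxa=%d;", n),
                         "",
                         paste0("#", nm),
                         "",
                         rows), collapse = "\n"), "\n")
  doc <- matrix_document("MEGA", body)
  if (!is.null(file)) {
    cat(body, file = file)
    return(invisible(doc))
  }
  doc
}

#' Write a distance matrix in PHYLIP format
#'
#' First line: right-aligned taxon count. Then one line per taxon: the name
#' padded or truncated to exactly 10 characters, followed by the full square
#' row of 6-decimal fixed-point values. Names that collide after truncation
#' are an error rather than being silently renamed.
#'
#' @inheritParams write_mega
#' @return A `matrix_document`, invisibly when `file` is given.
#' @export
write_phylip <- function(m, file = NULL) {
  d <- check_format_matrix(m)
  n <- nrow(d)
  nm10 <- substr(rownames(d), 1L, 10L)
  if (anyDuplicated(nm10)) {
    stop("sample names collide after truncation to 10 characters: ",
         paste(unique(nm10[duplicated(nm10)]), collapse = ", "))
  }
  lines <- c(sprintf("%5d", n),
             vapply(seq_len(n), function(i) {
               paste0(sprintf("%-10s", nm10[i]),
                      paste(sprintf("%.6f", d[i, ]), collapse = " "))
             }, character(1L)))
  body <- paste0(paste(lines, collapse = "\n"), "\n")
  doc <- matrix_document("PHYLIP", body)
  if (!is.null(file)) {
    cat(body, file = file)
    return(invisible(doc))
  }
  doc
}

# Parse a MEGA lower-left distance document back into a symmetric matrix.
read_mega <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (lines[1L] != "#mega") stop("not a MEGA document")
  taxa <- sub("^#", "", grep("^#", lines[-1L], value = TRUE))
  vals_lines <- lines[!startsWith(lines, "#") & !startsWith(lines, "!")]
  vals <- as.numeric(unlist(strsplit(vals_lines, "\\s+")))
  n <- length(taxa)
  if (length(vals) != n * (n - 1L) / 2L) {
    stop("MEGA triangle has ", length(vals), " values for ", n, " taxa")
  }
  d <- matrix(0, n, n, dimnames = list(taxa, taxa))
  k <- 1L
  for (i in 2:n) {
    for (j in seq_len(i - 1L)) {
      d[i, j] <- d[j, i] <- vals[k]
      k <- k + 1L
    }
  }
  d
}

# Parse a PHYLIP square distance document back into a matrix.
read_phylip <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  lines <- lines[nzchar(trimws(lines))]
  n <- as.integer(trimws(lines[1L]))
  if (length(lines) != n + 1L) stop("PHYLIP document has wrong row count")
  nm <- trimws(substr(lines[-1L], 1L, 10L))
  rows <- lapply(substring(lines[-1L], 11L), function(x) {
    as.numeric(strsplit(trimws(x), "\\s+")[[1L]])
  })
  d <- do.call(rbind, rows)
  dimnames(d) <- list(nm, nm)
  d
}
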