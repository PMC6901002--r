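# Streaming VCF input: line readers, header parsing, per-record genotype
# parsing and record classification. Only CHROM, POS, REF, ALT, QUAL,
# FORMAT(GT[,DP]) and the sample columns are consulted; INFO and FILTER are
# ignored.

#' Open a VCF file as a line stream
#'
#' Opens a plain-text or gzip-compressed VCF file and returns a lightweight
#' reader that yields decoded lines on demand, so arbitrarily large files can
#' be processed with memory independent of file length. Compression is
#' detected from the gzip magic bytes, not the file extension.
#'
#' @param path Path to a VCF file (`.vcf` or `.vcf.gz`; the extension is not
#'   consulted).
#' @return An object of class `vcf_stream` with elements `read_lines(n)`,
#'   a function returning up to `n` further lines (zero-length character at
#'   end of file), `close()`, and `path`.
#' @details The first non-empty line must start with `##` or `#CHROM`;
#'   anything else is rejected as non-VCF content.
#' @examples
#' vcf <- tempfile(fileext = ".vcf")
#' writeLines(c("##fileformat=VCFv4.2",
#'   paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
#'         "FORMAT", "S1", sep = "\t")), vcf)
#' s <- open_vcf_stream(vcf)
#' s$read_lines(1)
#' s$close()
#' @export
open_vcf_stream <- function(path) {
  if (length(path) != 1L || !is.character(path) || !file.exists(path)) {
    stop("cannot open VCF: file not found: ", path)
  }
  magic <- readBin(path, what = "raw", n = 2L)
  is_gz <- length(magic) == 2L && magic[1L] == as.raw(0x1f) && magic[2L] == as.raw(0x8b)
  con <- if (is_gz) gzfile(path, open = "rt") else file(path, open = "rt")

  # Peek at the first non-empty line to reject non-VCF content early.
  first <- NULL
  repeat {
    ln <- tryCatch(readLines(con, n = 1L, warn = FALSE), error = function(e) {
      close(con)
      stop("cannot read from file (is it binary?): ", path, call. = FALSE)
    })
    if (length(ln) == 0L) {
      close(con)
      stop("not a VCF file (no content): ", path)
    }
    if (!validEnc(ln)) {
      close(con)
      stop("not a VCF file (binary content): ", path)
    }
    if (nzchar(trimws(ln))) {
      first <- ln
      break
    }
  }
  if (!(startsWith(first, "##") || startsWith(first, "#CHROM"))) {
    close(con)
    stop("not a VCF file (first line is neither '##' metadata nor a '#CHROM' header): ",
         path)
  }

  buf <- first
  read_lines <- function(n = 1L) {
    out <- character(0)
    if (length(buf) > 0L) {
      take <- min(n, length(buf))
      out <- buf[seq_len(take)]
      buf <<- buf[-seq_len(take)]
      n <- n - take
    }
    if (n > 0L) out <- c(out, readLines(con, n = n, warn = FALSE))
    out
  }
  structure(list(read_lines = read_lines,
                 close = function() close(con),
                 path = path,
                 gzipped = is_gz),
            class = "vcf_stream")
}

#' Extract sample names from a #CHROM header line
#'
#' @param header_line The tab-separated `#CHROM` line of a VCF file.
#' @return Character vector of sample names in file order (columns 10 and
#'   onwards). This order is preserved in every downstream matrix and tree.
#' @export
parse_sample_names <- function(header_line) {
  if (!startsWith(header_line, "#CHROM")) {
    stop("expected a '#CHROM' header line")
  }
  fields <- strsplit(header_line, "\t", fixed = TRUE)[[1L]]
  if (length(fields) < 10L) {
    stop("VCF header has no genotype columns (sites-only VCF): need FORMAT ",
         "and at least one sample column")
  }
  fields[10:length(fields)]
}

#' Construct a SNP filter configuration
#'
#' Thresholds are inclusive lower bounds: a record with `QUAL == min_qual`
#' passes, and a genotype with `DP == min_depth` is kept.
#'
#' @param min_qual Minimum site QUAL (Phred scale); sites below are dropped
#'   entirely.
#' @param min_depth Minimum per-sample read depth (FORMAT/DP); genotypes
#'   below are set to missing for that sample only.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(min_qual = 0, min_depth = 0L) {
  min_qual <- as.numeric(min_qual)
  min_depth <- as.integer(min_depth)
  if (is.na(min_qual) || min_qual < 0) stop("min_qual must be a non-negative number")
  if (is.na(min_depth) || min_depth < 0L) stop("min_depth must be a non-negative integer")
  structure(list(min_qual = min_qual, min_depth = min_depth),
            class = "filter_config")
}

#' Construct a diploid genotype call
#'
#' A call is wholly present (two alleles coded 0 = reference, 1 = alternate)
#' or wholly missing. Half-missing VCF genotypes such as `./1` are treated as
#' missing, since the pairwise distance formulas need both alleles.
#'
#' @param allele_a,allele_b Integer allele codes, or `NA` for a missing call.
#' @param depth Per-sample read depth, or `NA` if the file reports none.
#' @return A list of class `genotype_call`.
#' @export
genotype_call <- function(allele_a, allele_b, depth = NA_integer_) {
  a <- as.integer(allele_a)
  b <- as.integer(allele_b)
  if (is.na(a) != is.na(b)) {
    a <- NA_integer_
    b <- NA_integer_
  }
  structure(list(allele_a = a, allele_b = b, depth = as.integer(depth)),
            class = "genotype_call")
}

#' Is a genotype call missing?
#' @param call A `genotype_call`.
#' @return Logical scalar.
#' @export
is_missing_call <- function(call) is.na(call$allele_a)

# Parse one diploid GT token ("0/1", "0|1", "./.", ".") into an integer pair
# (NA, NA) for missing. Errors on haploid/polyploid genotypes and on allele
# indices beyond the declared ALT alleles.
parse_gt_token <- function(gt, n_alts) {
  if (gt == "." ) return(c(NA_integer_, NA_integer_))
  parts <- strsplit(gt, "[/|]")[[1L]]
  if (length(parts) != 2L) {
    stop("non-diploid genotype '", gt,
         "': pairwise distances require diploid calls")
  }
  if (any(parts == ".")) return(c(NA_integer_, NA_integer_))
  al <- suppressWarnings(as.integer(parts))
  if (anyNA(al)) stop("malformed genotype field '", gt, "'")
  if (any(al > n_alts)) {
    stop("genotype allele index ", max(al), " exceeds the ", n_alts,
         " declared ALT allele(s)")
  }
  al
}

#' Parse one VCF data line
#'
#' Splits a tab-separated data line into a `vcf_record`: position, alleles,
#' QUAL and one `genotype_call` per sample. Both `/` and `|` genotype
#' separators are accepted. If the FORMAT column declares `DP` and a sample's
#' depth falls below `depth_threshold`, that sample's call is demoted to
#' missing (and flagged as such) while the rest of the site is kept.
#'
#' @param line A VCF data line.
#' @param n_samples Number of samples declared in the `#CHROM` header.
#' @param depth_threshold Inclusive minimum per-sample DP; 0 disables the
#'   filter.
#' @return A list of class `vcf_record` with fields `chrom`, `pos`, `ref`,
#'   `alts`, `qual` (`NA` if the file has `.`), `calls` (list of
#'   `genotype_call`) and `demoted` (logical per sample: call present in the
#'   file but below the depth threshold).
#' @export
parse_record <- function(line, n_samples, depth_threshold = 0L) {
  fields <- strsplit(line, "\t", fixed = TRUE)[[1L]]
  if (length(fields) != 9L + n_samples) {
    stop("malformed VCF line: expected ", 9L + n_samples,
         " tab-separated columns, found ", length(fields))
  }
  pos <- suppressWarnings(as.integer(fields[2L]))
  if (is.na(pos) || pos < 1L) stop("malformed POS field '", fields[2L], "'")
  alts <- strsplit(fields[5L], ",", fixed = TRUE)[[1L]]
  qual <- if (fields[6L] == ".") NA_real_ else suppressWarnings(as.numeric(fields[6L]))
  fmt <- strsplit(fields[9L], ":", fixed = TRUE)[[1L]]
  gt_i <- match("GT", fmt)
  if (is.na(gt_i)) stop("FORMAT column lacks a GT field")
  dp_i <- match("DP", fmt)
  n_alts <- length(alts)

  calls <- vector("list", n_samples)
  demoted <- logical(n_samples)
  for (s in seq_len(n_samples)) {
    sub <- strsplit(fields[9L + s], ":", fixed = TRUE)[[1L]]
    al <- parse_gt_token(sub[gt_i], n_alts)
    depth <- NA_integer_
    if (!is.na(dp_i) && length(sub) >= dp_i && sub[dp_i] != ".") {
      depth <- suppressWarnings(as.integer(sub[dp_i]))
    }
    if (!is.na(depth) && depth_threshold > 0L && depth < depth_threshold &&
        !is.na(al[1L])) {
      demoted[s] <- TRUE
      al <- c(NA_integer_, NA_integer_)
    }
    calls[[s]] <- genotype_call(al[1L], al[2L], depth)
  }
  structure(list(chrom = fields[1L], pos = pos, ref = fields[4L], alts = alts,
                 qual = qual, calls = calls, demoted = demoted),
            class = "vcf_record")
}

# Record categories, in the order classification tests them.
RECORD_CLASSES <- c("usable_biallelic_snp", "skip_indel", "skip_multiallelic",
                    "skip_low_qual", "skip_non_snp_other")

#' Classify a parsed VCF record against the SNP filters
#'
#' Only biallelic single-nucleotide sites passing the QUAL filter are usable;
#' everything else is skipped with a reason. Checks are applied in order:
#' symbolic/absent ALT alleles (`*`, `<...>`, `.`), indels (any allele longer
#' than one base), multi-allelic sites, low QUAL. An absent QUAL (`.`) passes
#' the quality filter.
#'
#' @param record A `vcf_record` from [parse_record()].
#' @param config A [filter_config()].
#' @return One of `"usable_biallelic_snp"`, `"skip_indel"`,
#'   `"skip_multiallelic"`, `"skip_low_qual"`, `"skip_non_snp_other"`.
#' @export
classify_record <- function(record, config = filter_config()) {
  alts <- record$alts
  if (length(alts) == 0L || any(alts == "." | alts == "*" | startsWith(alts, "<"))) {
    return("skip_non_snp_other")
  }
  if (nchar(record$ref) != 1L || any(nchar(alts) != 1L)) {
    return("skip_indel")
  }
  if (length(alts) > 1L) {
    return("skip_multiallelic")
  }
  if (!is.na(record$qual) && record$qual < config$min_qual) {
    return("skip_low_qual")
  }
  "usable_biallelic_snp"
}

# ---- vectorised chunk machinery (fast path used by compute_pairwise) ----

# Classify a chunk of data lines held as a character matrix (rows = records).
# Returns a factor-like character vector over RECORD_CLASSES.
classify_chunk <- function(ref, alt, qual, min_qual) {
  cls <- rep.int("usable_biallelic_snp", length(ref))
  other <- alt == "." | alt == "*" | grepl("(^|,)(\\*|<)", alt)
  # indel: REF longer than 1 base, or any ALT allele of 2+ characters
  indel <- !other & (nchar(ref) != 1L | grepl("[^,]{2,}", alt))
  multi <- !other & !indel & grepl(",", alt, fixed = TRUE)
  lowq <- !other & !indel & !multi & !is.na(qual) & qual < min_qual
  cls[other] <- "skip_non_snp_other"
  cls[indel] <- "skip_indel"
  cls[multi] <- "skip_multiallelic"
  cls[lowq] <- "skip_low_qual"
  cls
}

# Lookup table from diploid biallelic GT token to alternate-allele dosage.
GT_DOSAGE <- c("0/0" = 0, "0|0" = 0,
               "0/1" = 1, "1/0" = 1, "0|1" = 1, "1|0" = 1,
               "1/1" = 2, "1|1" = 2)
GT_MISSING <- c("./.", ".|.", ".", "./1", "1/.", "./0", "0/.",
                ".|1", "1|.", ".|0", "0|.")

# Convert the sample-field block of usable biallelic rows into an
# alternate-allele dosage matrix (0/1/2, NA = missing) plus a logical matrix
# of depth-demoted calls. `cells` is an n_rows x n_samples character matrix of
# raw sample fields, `fmt` the FORMAT column for those rows. Falls back to the
# scalar parser for any token the fast lookup does not recognise, so malformed
# genotypes produce the same errors as parse_record().
chunk_dosage <- function(cells, fmt, min_depth, line_offset = 0L) {
  nr <- nrow(cells)
  ns <- ncol(cells)
  gt <- sub(":.*$", "", cells)
  dim(gt) <- dim(cells)
  dos <- GT_DOSAGE[gt]
  dim(dos) <- dim(cells)
  miss <- matrix(gt %in% GT_MISSING, nr, ns)
  bad <- is.na(dos) & !miss
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)
    for (k in seq_len(nrow(idx))) {
      r <- idx[k, 1L]
      tok <- gt[r, idx[k, 2L]]
      # re-raise through the scalar path for a precise message
      res <- tryCatch(parse_gt_token(tok, 1L), error = function(e) e)
      if (inherits(res, "error")) {
        stop("line ", line_offset + r, ": ", conditionMessage(res), call. = FALSE)
      }
      dos[r, idx[k, 2L]] <- sum(res)
      miss[r, idx[k, 2L]] <- anyNA(res)
    }
  }
  dos[miss] <- NA_real_

  demoted <- matrix(FALSE, nr, ns)
  if (min_depth > 0L && nr > 0L) {
    for (f in unique(fmt)) {
      keys <- strsplit(f, ":", fixed = TRUE)[[1L]]
      dp_i <- match("DP", keys)
      if (is.na(dp_i)) next
      rows <- which(fmt == f)
      for (s in seq_len(ns)) {
        parts <- strsplit(cells[rows, s], ":", fixed = TRUE)
        dp <- suppressWarnings(as.integer(vapply(parts, function(p) {
          if (length(p) >= dp_i) p[dp_i] else NA_character_
        }, character(1L))))
        low <- !is.na(dp) & dp < min_depth & !is.na(dos[rows, s])
        demoted[rows[low], s] <- TRUE
      }
    }
    dos[demoted] <- NA_real_
  }
  list(dosage = dos, demoted = demoted)
}
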