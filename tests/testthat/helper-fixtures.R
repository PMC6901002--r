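# Hand-built VCF fixtures and a scalar brute-force re-implementation of the
# distance accumulation, used as the independent oracle against the
# streaming pipeline.

vcf_header_line <- function(samples) {
  paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", samples), collapse = "\t")
}

# rows: character vector of pre-formed data lines (or built via vcf_row)
vcf_lines <- function(samples, rows) {
  c("##fileformat=VCFv4.2", vcf_header_line(samples), rows)
}

vcf_row <- function(pos, ref, alt, qual, gts, fmt = "GT") {
  paste(c("1", pos, ".", ref, alt, qual, "PASS", ".", fmt, gts),
        collapse = "\t")
}

write_tmp_vcf <- function(lines, gz = FALSE) {
  path <- tempfile(fileext = if (gz) ".vcf.gz" else ".vcf")
  con <- if (gz) gzfile(path, "wt") else file(path, "wt")
  writeLines(lines, con)
  close(con)
  path
}

# Brute-force accumulation: parse every line with the scalar record parser,
# classify it, and apply the scalar per-site distance functions in an
# explicit double loop over pairs x sites, tracking the exclusion counters
# independently of the vectorised streaming path.
brute_force_accumulate <- function(path, min_qual = 0, min_depth = 0L,
                                   metric = "genetic", policy = "complete") {
  s <- open_vcf_stream(path)
  on.exit(s$close())
  lines <- character(0)
  repeat {
    chunk <- s$read_lines(1000L)
    if (length(chunk) == 0L) break
    lines <- c(lines, chunk)
  }
  header <- lines[startsWith(lines, "#CHROM")]
  samples <- parse_sample_names(header[1L])
  data <- lines[!startsWith(lines, "#") & nzchar(lines)]
  cfg <- filter_config(min_qual, min_depth)
  n <- length(samples)
  z <- matrix(0, n, n, dimnames = list(samples, samples))
  out <- list(samples = samples, diff_sum = z, used_sites = z,
              excluded_missing = 0L, excluded_filtered = 0L,
              excluded_multiallelic = 0L, excluded_missing_pair = z,
              class_counts = stats::setNames(integer(5L),
                c("usable_biallelic_snp", "skip_indel", "skip_multiallelic",
                  "skip_low_qual", "skip_non_snp_other")))
  site_fun <- if (metric == "genetic") site_genetic_distance else site_drift_distance
  for (line in data) {
    rec <- parse_record(line, n, min_depth)
    cls <- classify_record(rec, cfg)
    out$class_counts[[cls]] <- out$class_counts[[cls]] + 1L
    if (cls == "skip_multiallelic") {
      out$excluded_multiallelic <- out$excluded_multiallelic + 1L
      next
    }
    if (cls == "skip_low_qual") {
      out$excluded_filtered <- out$excluded_filtered + 1L
      next
    }
    if (cls != "usable_biallelic_snp") next
    absent <- vapply(rec$calls, is_missing_call, logical(1L))
    demoted <- rec$demoted
    if (any(demoted)) {
      out$excluded_filtered <- out$excluded_filtered + 1L
    } else if (any(absent)) {
      out$excluded_missing <- out$excluded_missing + 1L
    }
    if (policy == "complete" && any(absent)) next
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        if (absent[i] || absent[j]) {
          if (!any(demoted)) {
            out$excluded_missing_pair[i, j] <-
              out$excluded_missing_pair[j, i] <-
              out$excluded_missing_pair[i, j] + 1L
          }
          next
        }
        d <- site_fun(rec$calls[[i]], rec$calls[[j]])
        out$diff_sum[i, j] <- out$diff_sum[j, i] <- out$diff_sum[i, j] + d
        out$used_sites[i, j] <- out$used_sites[j, i] <- out$used_sites[i, j] + 1L
      }
    }
  }
  out
}

expect_acc_equal <- function(acc, exp) {
  expect_equal(unclass(acc$diff_sum), unclass(exp$diff_sum), tolerance = 0)
  expect_true(all(acc$used_sites == exp$used_sites))
  expect_identical(as.integer(acc$excluded_missing), as.integer(exp$excluded_missing))
  expect_identical(as.integer(acc$excluded_filtered), as.integer(exp$excluded_filtered))
  expect_identical(as.integer(acc$excluded_multiallelic),
                   as.integer(exp$excluded_multiallelic))
  expect_true(all(acc$excluded_missing_pair == exp$excluded_missing_pair))
}
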