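# Pairwise distance accumulation over a stream of biallelic SNP genotypes,
# and transforms of the accumulated counts into raw, p- or Jukes-Cantor
# distance matrices.
#
# Per-site distances are multiples of 1/4 (genetic) or 1/2 (drift), so sums
# are accumulated in integer quarter- and half-units and divided once at the
# end; matrices are therefore bit-for-bit reproducible regardless of chunking
# or summation order.

#' Per-site genetic distance between two diploid genotype calls
#'
#' All four cross-genome allele comparisons are performed and the proportion
#' of mismatches is returned. Two heterozygotes (`0/1` vs `0/1`) therefore
#' have distance 2/4 = 0.5.
#'
#' @param g1,g2 Non-missing [genotype_call()] objects (or length-2 integer
#'   vectors of allele codes).
#' @return A value in `{0, 0.25, 0.5, 0.75, 1}`; for biallelic 0/1 data only
#'   `{0, 0.5, 1}` occur.
#' @seealso [site_drift_distance()]
#' @export
site_genetic_distance <- function(g1, g2) {
  a <- call_alleles(g1)
  b <- call_alleles(g2)
  mean(outer(a, b, "!="))
}

#' Per-site drift distance between two diploid genotype calls
#'
#' Only the dissimilarity of the two genomes' alternate-allele frequencies is
#' measured: `|f1 - f2|` with `f = (alternate-allele dosage) / 2`. Two
#' heterozygotes have identical frequencies, so their drift distance is 0.
#'
#' @inheritParams site_genetic_distance
#' @return A value in `{0, 0.5, 1}`.
#' @export
site_drift_distance <- function(g1, g2) {
  a <- call_alleles(g1)
  b <- call_alleles(g2)
  abs(mean(a) - mean(b))
}

call_alleles <- function(g) {
  al <- if (inherits(g, "genotype_call")) c(g$allele_a, g$allele_b) else as.integer(g)
  if (length(al) != 2L) stop("a diploid genotype has exactly two alleles")
  if (anyNA(al)) {
    stop("missing genotype call: exclude the site before computing a distance")
  }
  al
}

new_accumulator <- function(samples, metric, policy) {
  n <- length(samples)
  if (n < 2L) stop("pairwise distances need at least 2 samples")
  z <- matrix(0, n, n, dimnames = list(samples, samples))
  structure(list(samples = samples, metric = metric, policy = policy,
                 diff_units = z, used_sites = z,
                 excluded_missing = 0L, excluded_filtered = 0L,
                 excluded_multiallelic = 0L,
                 excluded_missing_pair = z,
                 n_records = 0L,
                 class_counts = stats::setNames(integer(length(RECORD_CLASSES)),
                                                RECORD_CLASSES)),
            class = "pairwise_accumulator")
}

# Units per whole difference: genetic distances are quarters, drift halves.
acc_divisor <- function(metric) if (metric == "genetic") 4 else 2

# Fold one chunk of usable biallelic SNP rows into the accumulator.
# `dosage` is rows x samples (0/1/2, NA = missing after depth demotion),
# `demoted` marks calls present in the file but below the depth threshold,
# `orig_missing` marks calls missing in the file itself ("./.").
acc_update <- function(acc, dosage, demoted, orig_missing) {
  nr <- nrow(dosage)
  if (nr == 0L) return(acc)
  n <- length(acc$samples)
  has_dem <- rowSums(demoted) > 0L
  has_miss <- rowSums(orig_missing) > 0L
  # a site with any depth-demoted call counts once as user-filtered; sites
  # excluded only through genuine ./. calls count as missing
  acc$excluded_filtered <- acc$excluded_filtered + sum(has_dem)
  acc$excluded_missing <- acc$excluded_missing + sum(!has_dem & has_miss)

  genetic <- acc$metric == "genetic"
  if (acc$policy == "complete") {
    keep <- rowSums(is.na(dosage)) == 0L
    D <- dosage[keep, , drop = FALSE]
    k <- nrow(D)
    if (k > 0L) {
      for (i in seq_len(n - 1L)) {
        di <- D[, i]
        for (j in (i + 1L):n) {
          dj <- D[, j]
          u <- if (genetic) sum(di * (2 - dj) + (2 - di) * dj) else sum(abs(di - dj))
          acc$diff_units[i, j] <- acc$diff_units[i, j] + u
          acc$diff_units[j, i] <- acc$diff_units[i, j]
          acc$used_sites[i, j] <- acc$used_sites[i, j] + k
          acc$used_sites[j, i] <- acc$used_sites[i, j]
        }
      }
    }
  } else {
    for (i in seq_len(n - 1L)) {
      di <- dosage[, i]
      for (j in (i + 1L):n) {
        dj <- dosage[, j]
        ok <- !is.na(di) & !is.na(dj)
        if (any(ok)) {
          u <- if (genetic) {
            sum(di[ok] * (2 - dj[ok]) + (2 - di[ok]) * dj[ok])
          } else {
            sum(abs(di[ok] - dj[ok]))
          }
          acc$diff_units[i, j] <- acc$diff_units[i, j] + u
          acc$diff_units[j, i] <- acc$diff_units[i, j]
          acc$used_sites[i, j] <- acc$used_sites[i, j] + sum(ok)
          acc$used_sites[j, i] <- acc$used_sites[i, j]
        }
        # per-pair skips count only sites not already globally user-filtered,
        # so effective lengths never subtract a site twice
        skipped <- sum(!ok & !has_dem)
        acc$excluded_missing_pair[i, j] <- acc$excluded_missing_pair[i, j] + skipped
        acc$excluded_missing_pair[j, i] <- acc$excluded_missing_pair[i, j]
      }
    }
  }
  acc
}

acc_finalize <- function(acc) {
  acc$diff_sum <- acc$diff_units / acc_divisor(acc$metric)
  acc$excluded_multiallelic <- unname(acc$class_counts["skip_multiallelic"])
  acc$excluded_filtered <- acc$excluded_filtered +
    unname(acc$class_counts["skip_low_qual"])
  acc
}

#' Accumulate pairwise distances over a VCF file in one streaming pass
#'
#' Reads the file chunk by chunk (memory independent of file length),
#' classifies every record, applies the QUAL and depth filters, and sums the
#' chosen per-site distance over all usable biallelic SNPs for every sample
#' pair.
#'
#' @param path VCF file, plain or gzipped.
#' @param min_qual Site QUAL threshold (inclusive); sites below are dropped.
#' @param min_depth Per-sample DP threshold (inclusive); calls below become
#'   missing for that sample.
#' @param metric `"genetic"` (four-allele-comparison average per site) or
#'   `"drift"` (absolute difference of alternate-allele frequencies).
#' @param policy Missing-data policy: `"complete"` uses only sites called in
#'   every sample; `"pairwise"` uses, for each pair, every site called in
#'   both members of the pair.
#' @param chunk_size Number of lines parsed per chunk.
#' @param progress_every Emit a progress message every this many data lines
#'   (`Inf` to disable).
#' @return A `pairwise_accumulator`: per-pair `diff_sum` and `used_sites`
#'   matrices, global `excluded_missing`, `excluded_filtered` and
#'   `excluded_multiallelic` site counts, per-pair `excluded_missing_pair`
#'   counts, and per-class record tallies in `class_counts`.
#' @examples
#' vcf <- tempfile(fileext = ".vcf")
#' gen <- generate_vcf(sim_spec(n_samples = 4, n_sites = 50, seed = 1), vcf)
#' acc <- compute_pairwise(vcf)
#' acc$diff_sum
#' @export
compute_pairwise <- function(path, min_qual = 0, min_depth = 0L,
                             metric = c("genetic", "drift"),
                             policy = c("complete", "pairwise"),
                             chunk_size = 5000L, progress_every = 1e5) {
  metric <- match.arg(metric)
  policy <- match.arg(policy)
  cfg <- filter_config(min_qual, min_depth)
  stream <- open_vcf_stream(path)
  on.exit(stream$close(), add = TRUE)

  # header: skip ## metadata, grab #CHROM
  samples <- NULL
  line_no <- 0L
  repeat {
    ln <- stream$read_lines(1L)
    if (length(ln) == 0L) stop("no #CHROM header line found in ", path)
    line_no <- line_no + 1L
    if (startsWith(ln, "#CHROM")) {
      samples <- parse_sample_names(ln)
      break
    }
    if (!startsWith(ln, "##")) {
      stop("line ", line_no, ": data line encountered before the #CHROM header")
    }
  }
  acc <- new_accumulator(samples, metric, policy)
  ns <- length(samples)
  next_report <- progress_every

  repeat {
    lines <- stream$read_lines(chunk_size)
    if (length(lines) == 0L) break
    lines <- lines[nzchar(lines)]
    if (length(lines) == 0L) next
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf != 9L + ns)) {
      bad <- which(nf != 9L + ns)[1L]
      stop("malformed VCF line ", line_no + bad, ": expected ", 9L + ns,
           " columns, found ", nf[bad])
    }
    mat <- matrix(unlist(fields, use.names = FALSE), ncol = 9L + ns, byrow = TRUE)
    qual <- suppressWarnings(as.numeric(ifelse(mat[, 6L] == ".", NA, mat[, 6L])))
    cls <- classify_chunk(mat[, 4L], mat[, 5L], qual, cfg$min_qual)
    tab <- table(factor(cls, levels = RECORD_CLASSES))
    acc$class_counts <- acc$class_counts + as.integer(tab)
    acc$n_records <- acc$n_records + length(lines)

    use <- cls == "usable_biallelic_snp"
    if (any(use)) {
      cells <- mat[use, 10L:(9L + ns), drop = FALSE]
      fmt <- mat[use, 9L]
      parsed <- chunk_dosage(cells, fmt, cfg$min_depth, line_offset = line_no)
      orig_missing <- is.na(parsed$dosage) & !parsed$demoted
      acc <- acc_update(acc, parsed$dosage, parsed$demoted, orig_missing)
    }
    line_no <- line_no + length(lines)
    if (acc$n_records >= next_report) {
      message("processed ", acc$n_records, " records")
      next_report <- next_report + progress_every
    }
  }
  acc_finalize(acc)
}

#' Accumulate pairwise distances over already-parsed records
#'
#' In-memory counterpart of [compute_pairwise()] for a list of
#' [parse_record()] results, e.g. records built programmatically. Records are
#' classified with the same rules as the streaming path.
#'
#' @param records List of `vcf_record` objects.
#' @param samples Character vector of sample names, one per genotype column.
#' @param config A [filter_config()]; its `min_depth` is assumed to have been
#'   applied at parse time (as [parse_record()] does), its `min_qual` is
#'   applied here.
#' @inheritParams compute_pairwise
#' @return A `pairwise_accumulator`, as [compute_pairwise()].
#' @export
accumulate_records <- function(records, samples,
                               metric = c("genetic", "drift"),
                               policy = c("complete", "pairwise"),
                               config = filter_config()) {
  metric <- match.arg(metric)
  policy <- match.arg(policy)
  acc <- new_accumulator(samples, metric, policy)
  ns <- length(samples)
  acc$n_records <- length(records)
  if (length(records) == 0L) return(acc_finalize(acc))
  cls <- vapply(records, classify_record, character(1L), config = config)
  tab <- table(factor(cls, levels = RECORD_CLASSES))
  acc$class_counts <- acc$class_counts + as.integer(tab)
  use <- which(cls == "usable_biallelic_snp")
  if (length(use) > 0L) {
    dosage <- matrix(NA_real_, length(use), ns)
    demoted <- matrix(FALSE, length(use), ns)
    for (k in seq_along(use)) {
      rec <- records[[use[k]]]
      if (length(rec$calls) != ns) {
        stop("record at pos ", rec$pos, " has ", length(rec$calls),
             " calls for ", ns, " samples")
      }
      dosage[k, ] <- vapply(rec$calls, function(g) g$allele_a + g$allele_b,
                            numeric(1L))
      if (!is.null(rec$demoted)) demoted[k, ] <- rec$demoted
    }
    orig_missing <- is.na(dosage) & !demoted
    acc <- acc_update(acc, dosage, demoted, orig_missing)
  }
  acc_finalize(acc)
}

#' @export
print.pairwise_accumulator <- function(x, ...) {
  cat("Pairwise", x$metric, "distance accumulator over", length(x$samples),
      "samples (policy:", paste0(x$policy, ")\n"))
  cat("records:", x$n_records, "\n")
  cat("  usable biallelic SNPs:", x$class_counts[["usable_biallelic_snp"]], "\n")
  cat("  skipped: indel", x$class_counts[["skip_indel"]],
      "| multi-allelic", x$class_counts[["skip_multiallelic"]],
      "| low QUAL", x$class_counts[["skip_low_qual"]],
      "| other", x$class_counts[["skip_non_snp_other"]], "\n")
  cat("excluded sites: missing", x$excluded_missing,
      "| filtered", x$excluded_filtered,
      "| multi-allelic", x$excluded_multiallelic, "\n")
  invisible(x)
}

#' Construct a labelled distance matrix
#'
#' @param d Symmetric numeric matrix with zero diagonal.
#' @param samples Sample names (row/column labels).
#' @param scale One of `"raw"`, `"p"`, `"jc"`.
#' @param metric One of `"genetic"`, `"drift"`.
#' @return The matrix with dimnames and class `pop_dist`; the scale and
#'   metric travel along as attributes.
#' @export
dist_matrix <- function(d, samples = rownames(d), scale = "raw",
                        metric = "genetic") {
  d <- as.matrix(d)
  dimnames(d) <- list(samples, samples)
  structure(d, scale = scale, metric = metric,
            class = c("pop_dist", class(d)))
}

#' @export
print.pop_dist <- function(x, ...) {
  cat("Pairwise", attr(x, "metric"), "distances (scale:",
      paste0(attr(x, "scale"), ");"), nrow(x), "samples\n")
  print(unclass(x), ...)
  invisible(x)
}

#' Raw pairwise difference matrix
#'
#' The summed per-site distances for every pair, with no length
#' normalisation ("number of differences").
#'
#' @param acc A `pairwise_accumulator`.
#' @return A `pop_dist` matrix on the raw-differences scale.
#' @export
raw_matrix <- function(acc) {
  dist_matrix(acc$diff_sum, acc$samples, scale = "raw", metric = acc$metric)
}

#' Effective genome length after exclusions
#'
#' Sites excluded for missing genotypes, user filters (QUAL/depth) or more
#' than two alleles are subtracted from the total genome length before
#' converting summed differences to proportions. Under the complete-sites
#' policy the same length applies to every pair; under the pairwise policy
#' each pair subtracts its own missing-site count.
#'
#' @param acc A `pairwise_accumulator`.
#' @param genome_length Total genome length in base pairs.
#' @return A scalar (complete policy) or a full matrix of per-pair lengths
#'   (pairwise policy; diagonal equals the global exclusion-adjusted length).
#' @export
effective_length <- function(acc, genome_length) {
  genome_length <- as.numeric(genome_length)
  if (is.na(genome_length) || genome_length <= 0) {
    stop("genome_length must be a positive number")
  }
  base <- genome_length - acc$excluded_filtered - acc$excluded_multiallelic
  if (acc$policy == "complete") {
    L <- base - acc$excluded_missing
    if (L <= 0) stop("genome length smaller than the number of excluded sites")
    L
  } else {
    L <- base - acc$excluded_missing_pair
    if (any(L <= 0)) stop("genome length smaller than the number of excluded sites")
    L
  }
}

#' Proportion-of-differences (p-distance) matrix
#'
#' Divides each pair's summed differences by its effective genome length
#' (see [effective_length()]).
#'
#' @inheritParams effective_length
#' @return A `pop_dist` matrix with entries in `[0, 1]`.
#' @export
p_matrix <- function(acc, genome_length) {
  L <- effective_length(acc, genome_length)
  p <- acc$diff_sum / L
  if (any(p > 1)) {
    stop("p-distance above 1: genome_length is smaller than the number of ",
         "sites observed")
  }
  dist_matrix(p, acc$samples, scale = "p", metric = acc$metric)
}

#' Jukes-Cantor correction of a p-distance
#'
#' `d = -(3/4) * log(1 - (4/3) * p)`, the multiple-hit correction under an
#' equal-rates substitution model. Saturates (diverges) as `p` approaches
#' 0.75.
#'
#' @param p Proportion(s) of differing sites, each in `[0, 0.75)`.
#' @return Corrected distance(s), non-negative.
#' @export
jc_correct <- function(p) {
  p <- as.numeric(p)
  if (any(is.na(p)) || any(p < 0)) stop("p-distance must be non-negative")
  if (any(p >= 0.75)) {
    stop("Jukes-Cantor correction undefined for p >= 0.75 (saturated distance)")
  }
  -0.75 * log(1 - (4 / 3) * p)
}

#' Jukes-Cantor distance matrix
#'
#' Applies [jc_correct()] to the p-distance matrix of an accumulator.
#'
#' @inheritParams effective_length
#' @return A `pop_dist` matrix on the JC scale.
#' @export
jc_matrix <- function(acc, genome_length) {
  p <- p_matrix(acc, genome_length)
  d <- jc_correct(as.numeric(p))
  dim(d) <- dim(p)
  dist_matrix(d, acc$samples, scale = "jc", metric = acc$metric)
}
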