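# End-to-end runs: one streaming pass over the VCF, then any combination of
# tree and matrix outputs derived from the in-memory accumulator. The
# command-line wrapper installed under exec/ is a thin layer over
# run_config() + pop_run().

#' Assemble and validate a run configuration
#'
#' @param input_path VCF file (plain or gzipped).
#' @param min_qual,min_depth SNP filters, see [compute_pairwise()].
#' @param metric `"genetic"` or `"drift"`.
#' @param policy `"complete"` (sites present in all genomes) or `"pairwise"`
#'   (sites present in each pair of genomes).
#' @param scale `"raw"` (number of differences), `"p"` or `"jc"`; the last
#'   two require `genome_length`.
#' @param genome_length Total genome length in bp, needed for p/JC scales.
#' @param algorithm `"upgma"` or `"nj"`, used when a Newick output is
#'   requested.
#' @param samples Optional character vector restricting the analysis to a
#'   subset of genomes (at least 4 when a tree is requested).
#' @param newick,mega,phylip Optional output paths; `NA` asks for a default
#'   name derived from the input stem (`<stem>.nwk`, `<stem>.meg`,
#'   `<stem>.dist`).
#' @param mega_title Title line for MEGA output.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(input_path, min_qual = 0, min_depth = 0L,
                       metric = c("genetic", "drift"),
                       policy = c("complete", "pairwise"),
                       scale = c("raw", "p", "jc"),
                       genome_length = NULL,
                       algorithm = c("upgma", "nj"),
                       samples = NULL,
                       newick = NULL, mega = NULL, phylip = NULL,
                       mega_title = "Pairwise distances") {
  metric <- match.arg(metric)
  policy <- match.arg(policy)
  scale <- match.arg(scale)
  algorithm <- match.arg(algorithm)
  if (scale != "raw" && is.null(genome_length)) {
    stop("genome size was not entered for calculating p- or JC distance")
  }
  if (!is.null(genome_length)) {
    genome_length <- as.numeric(genome_length)
    if (is.na(genome_length) || genome_length <= 0) {
      stop("genome_length must be a positive number")
    }
  }
  if (!is.null(samples) && anyDuplicated(samples)) {
    stop("duplicate names in the sample subset")
  }
  stem <- sub("\\.gz$", "", input_path)
  stem <- sub("\\.vcf$", "", stem)
  default_path <- function(x, ext) {
    if (is.null(x)) return(NULL)
    if (length(x) == 1L && is.na(x)) paste0(stem, ext) else x
  }
  structure(list(input_path = input_path,
                 min_qual = min_qual, min_depth = min_depth,
                 metric = metric, policy = policy, scale = scale,
                 genome_length = genome_length, algorithm = algorithm,
                 samples = samples,
                 newick = default_path(newick, ".nwk"),
                 mega = default_path(mega, ".meg"),
                 phylip = default_path(phylip, ".dist"),
                 mega_title = mega_title),
            class = "run_config")
}

#' Restrict a distance matrix to a subset of samples
#'
#' @param m Distance matrix with sample names.
#' @param names Distinct sample names to keep, in the desired order.
#' @return The sub-matrix over `names`, preserving scale/metric attributes.
#' @export
subset_matrix <- function(m, names) {
  have <- rownames(m)
  unknown <- setdiff(names, have)
  if (length(unknown) > 0L) {
    stop("unknown genome name(s): ", paste(unknown, collapse = ", "))
  }
  if (anyDuplicated(names)) stop("duplicate names in the sample subset")
  sub <- unclass(as.matrix(m))[names, names, drop = FALSE]
  dist_matrix(sub, names, scale = attr(m, "scale"), metric = attr(m, "metric"))
}

#' Run the full VCF-to-phylogeny pipeline
#'
#' Streams the input once (regardless of how many outputs are requested),
#' builds the distance matrix at the requested scale, optionally subsets the
#' genomes, and derives the requested tree and matrix documents. All output
#' texts are assembled before any file is written, so a failing run leaves no
#' partial output behind.
#'
#' @param config A [run_config()].
#' @param quiet Suppress the summary log messages.
#' @return Invisibly, a list with the `accumulator`, the distance `matrix`,
#'   the `tree` (`NULL` unless Newick output was requested), and the paths of
#'   the `files` written.
#' @export
pop_run <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  acc <- compute_pairwise(config$input_path,
                          min_qual = config$min_qual,
                          min_depth = config$min_depth,
                          metric = config$metric,
                          policy = config$policy,
                          progress_every = if (quiet) Inf else 1e5)
  m <- switch(config$scale,
              raw = raw_matrix(acc),
              p = p_matrix(acc, config$genome_length),
              jc = jc_matrix(acc, config$genome_length))
  if (!is.null(config$samples)) {
    m <- subset_matrix(m, config$samples)
  }
  tree <- NULL
  texts <- list()
  if (!is.null(config$newick)) {
    tree <- switch(config$algorithm, upgma = upgma(m), nj = neighbor_joining(m))
    texts[[config$newick]] <- paste0(to_newick(tree), "\n")
  }
  if (!is.null(config$mega)) {
    texts[[config$mega]] <- write_mega(m, title = config$mega_title)$body
  }
  if (!is.null(config$phylip)) {
    texts[[config$phylip]] <- write_phylip(m)$body
  }
  for (path in names(texts)) cat(texts[[path]], file = path)
  if (!quiet) {
    cc <- acc$class_counts
    message("records: ", acc$n_records,
            " | usable SNPs: ", cc[["usable_biallelic_snp"]],
            " | indels: ", cc[["skip_indel"]],
            " | multi-allelic: ", cc[["skip_multiallelic"]],
            " | low QUAL: ", cc[["skip_low_qual"]],
            " | other: ", cc[["skip_non_snp_other"]],
            " | sites with missing calls: ", acc$excluded_missing)
    for (path in names(texts)) message("wrote ", path)
  }
  invisible(list(accumulator = acc, matrix = m, tree = tree,
                 files = names(texts)))
}
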