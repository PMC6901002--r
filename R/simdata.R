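# Deterministic synthetic multi-sample VCF fixtures with exact expected
# pairwise counts, plus random additive and ultrametric matrices for tree
# round-trip checks.
#
# Determinism: all draws use R's Mersenne-Twister, re-seeded per concern
# (haplotypes, record classes, missing mask, QUAL, DP) with offsets of the
# spec seed, so changing a contaminant rate never perturbs the genotype
# draws of the clean sites.

#' Specify a synthetic VCF fixture
#'
#' Diploid genotypes are simulated down a planted tree: each of the two
#' haplotypes of every genome evolves independently from an all-reference
#' root, flipping its 0/1 allele on each branch with probability equal to the
#' branch length (so branch lengths are per-site flip probabilities and must
#' lie in `[0, 1]`). Contaminant records — indels, multi-allelic sites —
#' replace a site's SNP record at the given rates; missing calls (`./.`) are
#' sprinkled per call; QUAL and per-call DP are drawn uniformly from the
#' given ranges so both sides of the `min_qual`/`min_depth` thresholds occur.
#'
#' @param n_samples Number of diploid genomes (at least 4); ignored when
#'   `planted_tree` is supplied.
#' @param n_sites Number of VCF records to emit.
#' @param planted_tree Optional `pop_tree` with branch lengths in `[0, 1]`;
#'   by default a random binary tree with branch lengths in `[0.02, 0.2]`.
#' @param missing_rate Per-call probability of `./.`.
#' @param indel_rate,multiallelic_rate Per-site probabilities that the record
#'   is an indel or a triallelic site instead of a biallelic SNP (their sum
#'   must be at most 1).
#' @param qual_range,dp_range Ranges for site QUAL (uniform real) and
#'   per-call DP (uniform integer).
#' @param min_qual,min_depth Thresholds assumed when computing the expected
#'   counts in the sidecar.
#' @param seed Integer seed; identical spec + seed give byte-identical VCFs.
#' @return A list of class `sim_spec`.
#' @export
sim_spec <- function(n_samples = 10L, n_sites = 500L, planted_tree = NULL,
                     missing_rate = 0.05, indel_rate = 0.02,
                     multiallelic_rate = 0.02,
                     qual_range = c(10, 80), dp_range = c(2L, 50L),
                     min_qual = 0, min_depth = 0L, seed) {
  if (missing(seed)) stop("sim_spec needs an explicit seed")
  rates <- c(missing_rate, indel_rate, multiallelic_rate)
  if (any(rates < 0) || any(rates > 1)) stop("rates must lie in [0, 1]")
  if (indel_rate + multiallelic_rate > 1) {
    stop("indel_rate + multiallelic_rate must be at most 1")
  }
  if (is.null(planted_tree)) {
    planted_tree <- random_binary_tree(n_samples, seed = seed_offset(seed, 11L),
                                       bl_range = c(0.02, 0.2))
  }
  n_samples <- length(tree_leaves(planted_tree))
  if (n_samples < 4L) stop("need at least 4 genomes")
  if (n_sites < 1L) stop("n_sites must be positive")
  structure(list(n_samples = n_samples, n_sites = as.integer(n_sites),
                 planted_tree = planted_tree, missing_rate = missing_rate,
                 indel_rate = indel_rate, multiallelic_rate = multiallelic_rate,
                 qual_range = qual_range, dp_range = as.integer(dp_range),
                 min_qual = min_qual, min_depth = as.integer(min_depth),
                 seed = as.integer(seed)),
            class = "sim_spec")
}

# Keep derived seeds inside R's 32-bit integer range.
seed_offset <- function(seed, k) as.integer((as.numeric(seed) + k) %% 2147483647)

#' Random rooted binary tree with uniform branch lengths
#'
#' Leaves are labelled `S1..Sn`; topology is built by repeatedly joining two
#' uniformly chosen active nodes; each branch length is drawn uniformly from
#' `bl_range`.
#'
#' @param n Number of leaves.
#' @param seed Integer seed.
#' @param bl_range Branch-length range.
#' @return A `pop_tree`.
#' @export
random_binary_tree <- function(n, seed, bl_range = c(0.1, 2)) {
  set.seed(seed, kind = "Mersenne-Twister")
  nodes <- lapply(paste0("S", seq_len(n)), leaf_node)
  while (length(nodes) > 1L) {
    ij <- sort(sample.int(length(nodes), 2L))
    lens <- stats::runif(2L, bl_range[1L], bl_range[2L])
    merged <- join_nodes(nodes[ij], lens)
    nodes <- c(nodes[-ij], list(merged))
  }
  nodes[[1L]]
}

# Random ultrametric (clock-like) tree: random join order, strictly
# increasing join heights, so UPGMA recovers it exactly.
random_ultrametric_tree <- function(n, seed) {
  set.seed(seed, kind = "Mersenne-Twister")
  nodes <- lapply(paste0("S", seq_len(n)), leaf_node)
  heights <- rep(0, n)
  h <- 0
  while (length(nodes) > 1L) {
    ij <- sort(sample.int(length(nodes), 2L))
    h <- h + stats::runif(1L, 0.1, 1)
    merged <- join_nodes(nodes[ij], h - heights[ij], height = h)
    nodes <- c(nodes[-ij], list(merged))
    heights <- c(heights[-ij], h)
  }
  nodes[[1L]]
}

#' Random additive distance matrix with its generating tree
#'
#' Draws a random binary tree with positive branch lengths and returns the
#' matrix of leaf-to-leaf path sums, which is exactly additive (satisfies the
#' four-point condition), together with the tree. Neighbour-joining on the
#' matrix recovers the generating topology and branch lengths.
#'
#' @param n Number of leaves, between 4 and 20.
#' @param seed Integer seed.
#' @return A list with `tree` (`pop_tree`) and `matrix` (`pop_dist`).
#' @export
generate_additive_matrix <- function(n, seed) {
  if (n < 4L || n > 20L) stop("n must be between 4 and 20")
  tree <- random_binary_tree(n, seed)
  m <- dist_matrix(tree_distances(tree), scale = "raw", metric = "genetic")
  list(tree = tree, matrix = m)
}

#' Random ultrametric distance matrix with its generating tree
#'
#' As [generate_additive_matrix()], but the generating tree is clock-like
#' (all leaves equidistant from the root), so UPGMA recovers it exactly.
#'
#' @inheritParams generate_additive_matrix
#' @return A list with `tree` and `matrix`.
#' @export
generate_ultrametric_matrix <- function(n, seed) {
  if (n < 4L || n > 20L) stop("n must be between 4 and 20")
  tree <- random_ultrametric_tree(n, seed)
  m <- dist_matrix(tree_distances(tree), scale = "raw", metric = "genetic")
  list(tree = tree, matrix = m)
}

# Evolve one haplotype (0/1 per site) for every leaf down the planted tree.
# Returns an n_sites x n_leaves 0/1 matrix with leaf labels as colnames.
sim_haplotype <- function(tree, n_sites) {
  out <- list()
  walk <- function(node, state) {
    if (is_leaf(node)) {
      out[[node$label]] <<- state
      return(invisible())
    }
    for (ch in node$children) {
      p <- ch$length
      if (p < 0 || p > 1) {
        stop("planted-tree branch lengths are flip probabilities and must lie in [0, 1]")
      }
      flips <- stats::rbinom(n_sites, 1L, p)
      walk(ch$node, (state + flips) %% 2L)
    }
  }
  walk(tree, integer(n_sites))
  do.call(cbind, out)
}

# Per-site distances by explicit enumeration over the four allele
# comparisons (genetic) or the dosage frequencies (drift); used only for the
# by-construction sidecar, independently of the pipeline's vectorised
# dosage-product formula.
enum_site_genetic <- function(a1, a2, b1, b2) {
  s <- 0L
  for (x in c(a1, a2)) for (y in c(b1, b2)) if (x != y) s <- s + 1L
  s / 4
}
enum_site_drift <- function(a1, a2, b1, b2) {
  abs((a1 + a2) / 2 - (b1 + b2) / 2)
}

# Expected accumulator for one metric x policy combination, computed from
# the generator's own knowledge of every record (class, QUAL, DP, missing
# mask, haplotypes) with plain double loops.
sidecar_expected <- function(spec, cls, qual, H1, H2, MISS, DP, metric, policy) {
  n <- spec$n_samples
  labs <- colnames(H1)
  z <- matrix(0, n, n, dimnames = list(labs, labs))
  exp <- list(diff_sum = z, used_sites = z, excluded_missing = 0L,
              excluded_filtered = 0L, excluded_multiallelic = 0L,
              excluded_missing_pair = z)
  for (s in seq_len(spec$n_sites)) {
    if (cls[s] == "multiallelic") {
      exp$excluded_multiallelic <- exp$excluded_multiallelic + 1L
      next
    }
    if (cls[s] == "indel") next
    if (qual[s] < spec$min_qual) {
      exp$excluded_filtered <- exp$excluded_filtered + 1L
      next
    }
    demoted <- !MISS[s, ] & DP[s, ] < spec$min_depth
    absent <- MISS[s, ] | demoted
    if (any(demoted)) {
      exp$excluded_filtered <- exp$excluded_filtered + 1L
    } else if (any(MISS[s, ])) {
      exp$excluded_missing <- exp$excluded_missing + 1L
    }
    if (policy == "complete" && any(absent)) next
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        if (absent[i] || absent[j]) {
          if (!any(demoted)) {
            exp$excluded_missing_pair[i, j] <- exp$excluded_missing_pair[i, j] + 1L
            exp$excluded_missing_pair[j, i] <- exp$excluded_missing_pair[i, j]
          }
          next
        }
        d <- if (metric == "genetic") {
          enum_site_genetic(H1[s, i], H2[s, i], H1[s, j], H2[s, j])
        } else {
          enum_site_drift(H1[s, i], H2[s, i], H1[s, j], H2[s, j])
        }
        exp$diff_sum[i, j] <- exp$diff_sum[i, j] + d
        exp$diff_sum[j, i] <- exp$diff_sum[i, j]
        exp$used_sites[i, j] <- exp$used_sites[i, j] + 1L
        exp$used_sites[j, i] <- exp$used_sites[i, j]
      }
    }
  }
  exp
}

#' Generate a synthetic multi-sample VCF with known expected distances
#'
#' Writes a VCF v4.2 text file (optionally gzipped) following the planted
#' tree and contaminant rates of the spec, and returns a sidecar of expected
#' per-pair difference sums, used-site counts and exclusion tallies for every
#' metric and missing-data policy, computed by construction with independent
#' scalar loops.
#'
#' @param spec A [sim_spec()].
#' @param path Output path; `NULL` returns the VCF text lines instead of
#'   writing a file.
#' @param gzip Write gzip-compressed output.
#' @param sidecar Compute the expected-answer sidecar (disable for very large
#'   fixtures where only the file is needed).
#' @param return_genotypes Also return the simulated haplotype matrices
#'   (`H1`, `H2`, sites x samples), e.g. for independent recomputation of
#'   expected distances on fixtures too large for the scalar sidecar loops.
#' @return A list with `path` (or `lines`), `samples`, the `spec`, per-site
#'   `classes`, and `sidecar`: one expected accumulator per
#'   `<metric>_<policy>` combination.
#' @export
generate_vcf <- function(spec, path = NULL, gzip = FALSE, sidecar = TRUE,
                         return_genotypes = FALSE) {
  stopifnot(inherits(spec, "sim_spec"))
  ns <- spec$n_samples
  nsite <- spec$n_sites

  set.seed(spec$seed, kind = "Mersenne-Twister")
  H1 <- sim_haplotype(spec$planted_tree, nsite)
  H2 <- sim_haplotype(spec$planted_tree, nsite)
  labs <- colnames(H1)

  set.seed(seed_offset(spec$seed, 1L), kind = "Mersenne-Twister")
  u <- stats::runif(nsite)
  cls <- ifelse(u < spec$indel_rate, "indel",
                ifelse(u < spec$indel_rate + spec$multiallelic_rate,
                       "multiallelic", "snp"))

  set.seed(seed_offset(spec$seed, 2L), kind = "Mersenne-Twister")
  MISS <- matrix(stats::runif(nsite * ns) < spec$missing_rate, nsite, ns)

  set.seed(seed_offset(spec$seed, 3L), kind = "Mersenne-Twister")
  qual <- round(stats::runif(nsite, spec$qual_range[1L], spec$qual_range[2L]), 2L)

  set.seed(seed_offset(spec$seed, 4L), kind = "Mersenne-Twister")
  DP <- matrix(sample(spec$dp_range[1L]:spec$dp_range[2L], nsite * ns,
                      replace = TRUE), nsite, ns)

  gt <- matrix(paste0(H1, "/", H2), nsite, ns)
  gt[MISS] <- "./."
  cells <- matrix(paste0(gt, ":", DP), nsite, ns)

  ref <- rep("A", nsite)
  alt <- rep("T", nsite)
  ref[cls == "indel"] <- "AT"
  alt[cls == "multiallelic"] <- "T,G"

  header <- c("##fileformat=VCFv4.2",
              "##source=poptree_simdata",
              paste0("##contig=<ID=1,length=", nsite + 1L, ">"),
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", labs), collapse = "\t"))
  body <- do.call(paste, c(list("1", seq_len(nsite), ".", ref, alt,
                                sprintf("%.2f", qual), "PASS", ".", "GT:DP"),
                           lapply(seq_len(ns), function(s) cells[, s]),
                           list(sep = "\t")))
  lines <- c(header, body)

  side <- NULL
  if (sidecar) {
    side <- list()
    for (metric in c("genetic", "drift")) {
      for (policy in c("complete", "pairwise")) {
        side[[paste(metric, policy, sep = "_")]] <-
          sidecar_expected(spec, cls, qual, H1, H2, MISS, DP, metric, policy)
      }
    }
  }

  out <- list(samples = labs, spec = spec, classes = cls, sidecar = side)
  if (return_genotypes) {
    out$H1 <- H1
    out$H2 <- H2
  }
  if (is.null(path)) {
    out$lines <- lines
    return(out)
  }
  con <- if (gzip) gzfile(path, "wt") else file(path, "wt")
  writeLines(lines, con, sep = "\n")
  close(con)
  out$path <- path
  out
}
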