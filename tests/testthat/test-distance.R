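test_that("per-site genetic and drift distances cover every diploid genotype pair", {
  # frozen expectations enumerated by hand over the four allele comparisons
  # (genetic) and the allele-frequency difference (drift)
  cases <- list(
    #      g1      g2      genetic  drift
    list(c(0, 0), c(0, 0), 0.0, 0.0),
    list(c(0, 0), c(0, 1), 0.5, 0.5),
    list(c(0, 0), c(1, 1), 1.0, 1.0),
    list(c(0, 1), c(0, 1), 0.5, 0.0),
    list(c(0, 1), c(1, 1), 0.5, 0.5),
    list(c(1, 1), c(1, 1), 0.0, 0.0),
    list(c(1, 0), c(0, 1), 0.5, 0.0),  # allele order within a call is irrelevant
    list(c(1, 0), c(0, 0), 0.5, 0.5)
  )
  for (cs in cases) {
    g1 <- genotype_call(cs[[1]][1], cs[[1]][2])
    g2 <- genotype_call(cs[[2]][1], cs[[2]][2])
    expect_identical(site_genetic_distance(g1, g2), cs[[3]])
    expect_identical(site_drift_distance(g1, g2), cs[[4]])
    # symmetry
    expect_identical(site_genetic_distance(g2, g1), cs[[3]])
    expect_identical(site_drift_distance(g2, g1), cs[[4]])
    # drift never exceeds genetic
    expect_lte(cs[[4]], cs[[3]])
  }
  miss <- genotype_call(NA, NA)
  expect_error(site_genetic_distance(miss, genotype_call(0, 1)), "missing")
  expect_error(site_drift_distance(genotype_call(0, 1), miss), "missing")
})

test_that("accumulation follows the missing-data policy", {
  samples <- c("A", "B", "C")
  # one site, all heterozygous: every pair at genetic 0.5
  all_het <- write_tmp_vcf(vcf_lines(samples, vcf_row(1, "A", "T", 50,
                                                      c("0/1", "0/1", "0/1"))))
  acc <- compute_pairwise(all_het, progress_every = Inf)
  expect_true(all(acc$diff_sum[upper.tri(acc$diff_sum)] == 0.5))
  expect_true(all(acc$used_sites[upper.tri(acc$used_sites)] == 1))
  expect_true(all(diag(acc$diff_sum) == 0))

  # same site with C missing: complete policy drops it for everyone...
  c_missing <- write_tmp_vcf(vcf_lines(samples, vcf_row(1, "A", "T", 50,
                                                        c("0/1", "0/1", "./."))))
  acc_c <- compute_pairwise(c_missing, policy = "complete", progress_every = Inf)
  expect_true(all(acc_c$used_sites == 0))
  expect_equal(acc_c$excluded_missing, 1L)

  # ...while the pairwise policy keeps it for the called pair only
  acc_p <- compute_pairwise(c_missing, policy = "pairwise", progress_every = Inf)
  expect_equal(acc_p$used_sites["A", "B"], 1)
  expect_equal(acc_p$used_sites["A", "C"], 0)
  expect_equal(acc_p$diff_sum["A", "B"], 0.5)
  expect_equal(acc_p$excluded_missing_pair["A", "C"], 1)
  expect_equal(acc_p$excluded_missing_pair["A", "B"], 0)
})

test_that("policies agree when no call is missing or demoted", {
  vcf <- tempfile(fileext = ".vcf")
  generate_vcf(sim_spec(n_samples = 6, n_sites = 100, missing_rate = 0,
                        indel_rate = 0, multiallelic_rate = 0, seed = 5),
               vcf, sidecar = FALSE)
  for (metric in c("genetic", "drift")) {
    a <- compute_pairwise(vcf, metric = metric, policy = "complete",
                          progress_every = Inf)
    b <- compute_pairwise(vcf, metric = metric, policy = "pairwise",
                          progress_every = Inf)
    expect_identical(a$diff_sum, b$diff_sum)
    expect_true(all(a$used_sites == b$used_sites))
  }
})

test_that("drift differences never exceed genetic differences", {
  vcf <- tempfile(fileext = ".vcf")
  generate_vcf(sim_spec(n_samples = 6, n_sites = 200, missing_rate = 0.1,
                        seed = 9), vcf, sidecar = FALSE)
  gen <- compute_pairwise(vcf, metric = "genetic", progress_every = Inf)
  dri <- compute_pairwise(vcf, metric = "drift", progress_every = Inf)
  expect_true(all(dri$diff_sum <= gen$diff_sum))
  # and per-site sums never exceed the usable-site count
  expect_true(all(gen$diff_sum <= gen$used_sites))
})

test_that("accumulation is invariant to chunking and matches the in-memory path", {
  vcf <- tempfile(fileext = ".vcf")
  generate_vcf(sim_spec(n_samples = 5, n_sites = 97, missing_rate = 0.1,
                        indel_rate = 0.05, multiallelic_rate = 0.05, seed = 21),
               vcf, sidecar = FALSE)
  a <- compute_pairwise(vcf, chunk_size = 7L, progress_every = Inf)
  b <- compute_pairwise(vcf, chunk_size = 5000L, progress_every = Inf)
  expect_identical(a$diff_sum, b$diff_sum)
  expect_identical(a$excluded_missing, b$excluded_missing)

  # accumulate_records on scalar-parsed records agrees with the stream
  s <- open_vcf_stream(vcf)
  lines <- character(0)
  repeat {
    chunk <- s$read_lines(1000L)
    if (length(chunk) == 0L) break
    lines <- c(lines, chunk)
  }
  s$close()
  data <- lines[!startsWith(lines, "#")]
  samples <- parse_sample_names(lines[startsWith(lines, "#CHROM")])
  records <- lapply(data, parse_record, n_samples = length(samples))
  c_acc <- accumulate_records(records, samples)
  expect_identical(c_acc$diff_sum, b$diff_sum)
  expect_true(all(c_acc$used_sites == b$used_sites))
})

test_that("effective length subtracts excluded sites per policy", {
  mk_acc <- function(policy) {
    acc <- accumulate_records(list(), c("A", "B"), policy = policy)
    acc$excluded_missing <- 10L
    acc$excluded_filtered <- 5L
    acc$excluded_multiallelic <- 2L
    acc$excluded_missing_pair[] <- matrix(c(0, 10, 10, 0), 2)
    acc
  }
  expect_equal(effective_length(mk_acc("complete"), 1000), 983)
  expect_equal(effective_length(mk_acc("complete"), 17 + 1), 1)
  expect_error(effective_length(mk_acc("complete"), 17), "smaller")
  expect_error(effective_length(mk_acc("complete"), 10), "smaller")
  Lp <- effective_length(mk_acc("pairwise"), 1000)
  expect_equal(Lp["A", "B"], 1000 - 10 - 5 - 2)
})

test_that("p-distances are proportions over the effective length", {
  samples <- c("A", "B")
  vcf <- write_tmp_vcf(vcf_lines(samples, c(
    vcf_row(1, "A", "T", 50, c("0/1", "0/1")),   # genetic 0.5
    vcf_row(2, "A", "T", 50, c("0/0", "1/1")),   # genetic 1
    vcf_row(3, "A", "T,G", 50, c("0/0", "0/0"))  # multi-allelic, excluded
  )))
  acc <- compute_pairwise(vcf, progress_every = Inf)
  expect_equal(acc$diff_sum["A", "B"], 1.5)
  p <- p_matrix(acc, 1001)  # L_eff = 1001 - 1 multiallelic = 1000
  expect_equal(p["A", "B"], 0.0015)
  expect_equal(attr(p, "scale"), "p")
  expect_equal(p["A", "A"], 0)
  jc <- jc_matrix(acc, 1001)
  expect_equal(jc["A", "B"], -0.75 * log(1 - 4 / 3 * 0.0015))
  expect_error(p_matrix(acc, NA), "positive")
})

test_that("the Jukes-Cantor correction matches its closed form and domain", {
  expect_equal(jc_correct(0), 0)
  # frozen from an independent high-precision evaluation of -(3/4)ln(1-4p/3)
  expect_equal(jc_correct(0.1), 0.107326, tolerance = 5e-6)
  expect_equal(jc_correct(0.5), 0.823959, tolerance = 5e-6)
  # small-p limit: correction factor tends to 1
  expect_equal(jc_correct(1e-6) / 1e-6, 1, tolerance = 1e-4)
  expect_error(jc_correct(0.75), "0.75")
  expect_error(jc_correct(0.9), "0.75")
  expect_error(jc_correct(-0.1), "non-negative")
})
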