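test_that("cohort simulation honours n, sex ratio and determinism", {
  co <- simulate_cohort(160, c(1, 75), 0.5, "blood", seed = 3)
  expect_equal(nrow(co), 160)
  expect_equal(as.vector(table(co$sex)[c("M", "F")]), c(80L, 80L))
  expect_true(all(co$age >= 1 & co$age <= 75))
  expect_identical(co, simulate_cohort(160, c(1, 75), 0.5, "blood", seed = 3))
  expect_equal(nrow(simulate_cohort(0)), 0)
  expect_error(simulate_cohort(-1), "nonnegative")
  expect_error(simulate_cohort(5, c(10, 2)), "lo <= hi")
})

test_that("age-response curves respect direction and closed forms", {
  fns <- default_age_functions(panel, "blood")
  v20 <- true_methylation(20, fns, noise = FALSE)
  v60 <- true_methylation(60, fns, noise = FALSE)
  hyper <- fns$cpg_id[fns$direction == "hyper"]
  hypo <- fns$cpg_id[fns$direction == "hypo" & fns$slope != 0]
  expect_true(all(v60[hyper] >= v20[hyper]))
  expect_true(all(v60[hypo] <= v20[hypo]))
  # MIR29B2CHG hypomethylates with age
  expect_lt(v60[["MIR29B2CHG_C1"]], v20[["MIR29B2CHG_C1"]])
  # power CpGs equal scale * age^exponent (clamped), checked by direct evaluation
  pw <- fns[fns$form == "power", ]
  expect_equal(unname(v60[pw$cpg_id]),
               pmin(100, pmax(0, pw$scale * 60^pw$exponent)))
  expect_true(all(v20 >= 0 & v20 <= 100))
  # bones: MIR29B2CHG C2/C3 are age-flat
  fb <- default_age_functions(panel, "bone")
  b20 <- true_methylation(20, fb, noise = FALSE)
  b60 <- true_methylation(60, fb, noise = FALSE)
  expect_equal(b20[c("MIR29B2CHG_C2", "MIR29B2CHG_C3")],
               b60[c("MIR29B2CHG_C2", "MIR29B2CHG_C3")])
})

test_that("assay distortion bias vanishes at the endpoints and peaks mid-scale", {
  tv <- c(MIR29B2CHG_C1 = 0, MIR29B2CHG_C2 = 100, MIR29B2CHG_C3 = 50)
  d0 <- assay_distortion(bias = c(MIR29B2CHG = 3), duplicate_sd = 0)
  obs <- apply_assay_distortion(tv, d0)
  expect_equal(unname(obs), c(0, 100, 53))
  # sigma = 0, b = 0 is the identity
  dn <- assay_distortion(bias = 0, duplicate_sd = 0)
  x <- c(ELOVL2_C1 = 12.5, FHL2_C2 = 87.2)
  expect_equal(apply_assay_distortion(x, dn), x)
})

test_that("duplicate noise SD reproduces the mean absolute duplicate difference", {
  # E|X1 - X2| = 2*sigma/sqrt(pi) for iid normal duplicates: verified
  # numerically, then the default sigma must map back to 1.9%
  sigma <- 1.9 * sqrt(pi) / 2
  set.seed(99)
  d <- abs(rnorm(2e5, 0, sigma) - rnorm(2e5, 0, sigma))
  expect_equal(mean(d), 2 * sigma / sqrt(pi), tolerance = 0.01)
  expect_equal(2 * sigma / sqrt(pi), 1.9, tolerance = 1e-12)
  expect_equal(assay_distortion()$duplicate_sd, sigma)
})

test_that("simulated counts follow the binomial sampling oracle", {
  tv <- setNames(rep(50, 3), c("MK1_C1", "MK1_C2", "MK2_C1"))
  d <- assay_distortion(bias = 0, duplicate_sd = 0, conversion_prob = 1,
                        seq_error = 0, depth_mean = 10000, depth_size = 1e6)
  cc <- simulate_counts(tv, d, input_ng = 1000, seed = 5)
  frac <- cc$c_reads / (cc$c_reads + cc$t_reads)
  sd_bin <- sqrt(0.5 * 0.5 / cc$depth)
  expect_true(all(abs(frac - 0.5) <= 3 * sd_bin + 0.01))
  # beta = 0 with perfect conversion and no error: no C reads at all
  cc0 <- simulate_counts(setNames(0, "MK1_C1"), d, input_ng = 10, seed = 6)
  expect_equal(cc0$c_reads, 0)
  expect_true(all(cc0$depth == cc0$c_reads + cc0$t_reads + cc0$other_reads))
  expect_error(simulate_counts(tv, d, input_ng = 0), "input_ng")
})

test_that("incomplete conversion leaves the expected unconverted C fraction", {
  d <- assay_distortion(bias = 0, duplicate_sd = 0, conversion_prob = 0.998,
                        seq_error = 0, depth_mean = 2e5, depth_size = 1e6)
  cc <- simulate_counts(setNames(0, "MK1_C1"), d, input_ng = 1000, seed = 7)
  expect_equal(cc$c_reads / cc$depth, 0.002, tolerance = 0.25)
})

test_that("counts-based quantification recovers truth as depth grows", {
  # distortion off: mean absolute calling error at depth 1e6 below 0.2%
  fns <- default_age_functions(panel, "blood")
  tv <- true_methylation(50, fns, noise = FALSE)
  d <- assay_distortion(bias = 0, duplicate_sd = 0, conversion_prob = 1,
                        seq_error = 0, depth_mean = 1e6, depth_size = 1e9)
  cc <- simulate_counts(tv, d, input_ng = 1e5, seed = 8)
  calls <- call_methylation(cc)
  err <- abs(calls$beta - tv[calls$cpg_id])
  expect_lt(mean(err), 0.2)
})

test_that("standard series layouts match the duplicate and extended designs", {
  s <- simulate_standard_series(c(0, 25, 50, 75, 100), replicates = 2, seed = 1)
  expect_equal(nrow(s$samples), 10)
  expect_true(all(s$truth[s$samples$ratio == 0, ] == 0))
  s5 <- simulate_standard_series(c(5, 10, 25, 50, 75), replicates = 2, seed = 1)
  s1 <- simulate_standard_series(c(0, 100), replicates = 1, seed = 2)
  expect_equal(nrow(s5$samples) + nrow(s1$samples), 12)
  expect_true(all(s$observed >= 0 & s$observed <= 100))
  expect_error(simulate_standard_series(c(50, 101)), "\\[0, 100\\]")
})

test_that("read simulation is deterministic and reflects 2x150 coverage geometry", {
  fns <- default_age_functions(panel, "blood")
  obs <- true_methylation(40, fns, noise = FALSE)
  d <- assay_distortion(bias = 0, duplicate_sd = 0, conversion_prob = 1,
                        seq_error = 0)
  r1 <- simulate_reads(obs, panel, n_pairs = 400, distortion = d, seed = 9)
  r2 <- simulate_reads(obs, panel, n_pairs = 400, distortion = d, seed = 9)
  expect_identical(r1, r2)
  expect_error(simulate_reads(obs, panel, read_length = 10, distortion = d),
               "primer")
  # error-free reads differ from the collapsed reference only at Y positions
  refs <- collapsed_references(panel)
  one <- r1[r1$true_marker == "ELOVL2", ][1, ]
  ref <- strsplit(refs[["ELOVL2"]], "")[[1]]
  rd <- strsplit(one$seq1, "")[[1]]
  for (i in seq_along(rd)) {
    if (ref[i] == "Y") expect_true(rd[i] %in% c("C", "T"))
    else expect_equal(rd[i], ref[i])
  }
  # interval arithmetic: a 267 bp amplicon with 2x150 has single-mate
  # coverage in the middle (offsets 150..116 from either end overlap)
  L <- 267; rl <- 150
  both <- sum(seq_len(L) <= rl & seq_len(L) > L - rl)  # covered by both mates
  expect_equal(both, 2 * rl - L)
})

test_that("FASTQ round trip preserves records and malformed files are caught", {
  fns <- default_age_functions(panel, "blood")
  obs <- true_methylation(40, fns, noise = FALSE)
  reads <- simulate_reads(obs, panel, n_pairs = 100, seed = 10)
  prefix <- tempfile("rt")
  write_fastq_pair(reads, prefix)
  back <- read_fastq_pair(paste0(prefix, "_R1.fastq"), paste0(prefix, "_R2.fastq"))
  expect_equal(back$seq1, reads$seq1)
  expect_equal(back$seq2, reads$seq2)
  expect_equal(back$qual1, reads$qual1)
  expect_equal(back$id, reads$id)
  bad <- tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+", "FFFF", "@r2", "ACGT"), bad)
  expect_error(read_fastq_pair(bad, bad), "record")
})

test_that("dilution stochasticity: replicate beta variance falls with DNA input", {
  d <- assay_distortion(bias = 0, conversion_prob = 1, seq_error = 0,
                        depth_mean = 20000, depth_size = 50)
  tv <- setNames(rep(50, 4), paste0("MK", 1:4, "_C1"))
  var_at <- function(ng) {
    betas <- sapply(1:30, function(r) {
      obs <- apply_assay_distortion(tv, d, seed = 1000 * ng + r)
      cc <- simulate_counts(obs, d, input_ng = ng, seed = 2000 * ng + r)
      call_methylation(cc)$beta
    })
    mean(apply(betas, 1, var))
  }
  v <- c(var_at(1), var_at(20), var_at(200))
  expect_true(v[1] > v[2])
  expect_true(v[2] >= v[3] - 0.5)
})
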