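make_reads <- function(n_pairs = 400, beta = 40, conv = 1, err = 0, seed = 21) {
  fns <- default_age_functions(panel, "blood")
  obs <- true_methylation(beta, fns, noise = FALSE)
  d <- assay_distortion(bias = 0, duplicate_sd = 0, conversion_prob = conv,
                        seq_error = err)
  simulate_reads(obs, panel, n_pairs = n_pairs, distortion = d, seed = seed)
}

test_that("error-free simulated reads are fully assigned to their true amplicons", {
  reads <- make_reads(400)
  asg <- assign_reads(reads, panel)
  expect_equal(asg$n_unassigned, 0)
  expect_equal(asg$assignments$marker, reads$true_marker)
  expect_true(all(asg$assignments$mismatch_frac == 0))
})

test_that("random sequences and over-threshold reads stay unassigned", {
  set.seed(31)
  rnd <- data.frame(
    id = paste0("r", 1:20),
    seq1 = replicate(20, paste(sample(c("A", "C", "G", "T"), 150, TRUE), collapse = "")),
    qual1 = strrep("F", 150),
    seq2 = replicate(20, paste(sample(c("A", "C", "G", "T"), 150, TRUE), collapse = "")),
    qual2 = strrep("F", 150), true_marker = NA, stringsAsFactors = FALSE)
  asg <- assign_reads(rnd, panel)
  expect_equal(asg$n_unassigned, 20)
})

test_that("mismatch tolerance admits 1 substitution but rejects 10 on 150 bp", {
  reads <- make_reads(8)[1:8, ]
  mutate_at <- function(s, k) {
    ch <- strsplit(s, "")[[1]]
    idx <- round(seq(3, length(ch) - 2, length.out = k))
    ch[idx] <- ifelse(ch[idx] == "A", "G", "A")
    paste(ch, collapse = "")
  }
  one <- reads[1, ]; one$seq1 <- mutate_at(one$seq1, 1)
  ten <- reads[2, ]; ten$seq1 <- mutate_at(ten$seq1, 10)
  ten$seq2 <- mutate_at(ten$seq2, 10)
  a1 <- assign_reads(one, panel, max_mismatch_frac = 0.05)
  expect_equal(a1$assignments$marker, one$true_marker)
  a10 <- assign_reads(ten, panel, max_mismatch_frac = 0.05)
  expect_true(is.na(a10$assignments$marker))
})

test_that("matcher agrees with the brute-force mismatch oracle", {
  reads <- make_reads(100, conv = 0.99, err = 0.01, seed = 77)
  refs <- collapsed_references(panel)
  asg <- assign_reads(reads, panel, max_mismatch_frac = 1)
  for (i in seq_len(nrow(reads))) {
    fracs <- sapply(names(refs), function(mk) {
      ref <- refs[[mk]]
      rc2 <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(reads$seq2[i])))
      rc1 <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(reads$seq1[i])))
      k <- min(nchar(reads$seq1[i]), nchar(ref))
      f12 <- (oracle_mismatches(reads$seq1[i], ref, "start") +
                oracle_mismatches(rc2, ref, "end")) / (2 * k)
      f21 <- (oracle_mismatches(reads$seq2[i], ref, "start") +
                oracle_mismatches(rc1, ref, "end")) / (2 * k)
      min(f12, f21)
    })
    best <- names(refs)[which.min(fracs)]
    if (sum(fracs == min(fracs)) == 1) {
      expect_equal(asg$assignments$marker[i], best)
      expect_equal(asg$assignments$mismatch_frac[i], unname(min(fracs)))
    }
  }
})

test_that("paired-read counting doubles depth where both mates cover a CpG", {
  # fully methylated, error-free: every covering mate reports C
  fns <- default_age_functions(panel, "blood")
  obs <- setNames(rep(100, 44), fns$cpg_id)
  d <- assay_distortion(bias = 0, duplicate_sd = 0, conversion_prob = 1,
                        seq_error = 0)
  reads <- simulate_reads(obs, panel, n_pairs = rep(1000, 8) |>
                            setNames(panel$markers$marker),
                          distortion = d, seed = 41)
  asg <- assign_reads(reads, panel)
  cc <- count_cpg_bases(asg, panel)
  # ASPA (108 bp < 150): its CpG is covered by both mates of every pair
  aspa <- cc[cc$cpg_id == "ASPA_C1", ]
  expect_equal(aspa$c_reads, 2000)
  expect_equal(aspa$t_reads, 0)
  # fragment-level counting halves it
  cf <- count_cpg_bases(asg, panel, fragment_level = TRUE)
  expect_equal(cf$c_reads[cf$cpg_id == "ASPA_C1"], 1000)
  # ELOVL2 interior CpGs (offsets 117..149 from either end only) get one mate
  mid <- cc[cc$cpg_id == "ELOVL2_C1", ]   # offset 160: rev mate only
  expect_equal(mid$depth, 1000)
})

test_that("base-quality filtering excludes low-quality calls", {
  tp <- toy_panel()
  ref <- tp$markers$reference_seq[1]
  # one perfect read pair over MK1, methylated at C1 (offset 10)
  read_seq <- paste0(substr(chartr("C", "T", ref), 1, 10), "C",
                     substr(chartr("C", "T", ref), 12, 40))
  qual_hi <- strrep("F", 40)
  qual_lo <- paste0(strrep("F", 10), "#", strrep("F", 29))  # Phred 2 at CpG
  mk_read <- function(q) data.frame(
    id = "p1", seq1 = read_seq, qual1 = q,
    seq2 = as.character(Biostrings::reverseComplement(Biostrings::DNAString(read_seq))),
    qual2 = strrep("F", 40), true_marker = "MK1", stringsAsFactors = FALSE)
  cc_hi <- count_cpg_bases(assign_reads(mk_read(qual_hi), tp), tp)
  cc_lo <- count_cpg_bases(assign_reads(mk_read(qual_lo), tp), tp)
  expect_equal(cc_hi$depth[cc_hi$cpg_id == "MK1_C1"], 2)
  expect_equal(cc_lo$depth[cc_lo$cpg_id == "MK1_C1"], 1)
})

test_that("beta arithmetic and the 1,000-read depth threshold behave as specified", {
  cc <- data.frame(sample = "S", cpg_id = c("A_C1", "A_C2", "A_C3", "A_C4"),
                   marker = "A",
                   c_reads = c(500, 250, 0, 400),
                   t_reads = c(500, 750, 0, 599),
                   other_reads = c(0, 0, 0, 0))
  calls <- call_methylation(cc, min_reads = 1000)
  expect_equal(calls$beta, c(50, 25, NA, 100 * 400 / 999))
  expect_equal(calls$pass_depth, c(TRUE, TRUE, FALSE, FALSE))
  # depth 999 fails but beta is still reported
  expect_false(is.na(calls$beta[4]))
  # other reads are excluded from the beta denominator
  cc2 <- data.frame(sample = "S", cpg_id = "A_C1", marker = "A",
                    c_reads = 500, t_reads = 500, other_reads = 1000)
  expect_equal(call_methylation(cc2)$beta, 50)
  # scale invariance / depth monotonicity
  cc3 <- cc; cc3[, c("c_reads", "t_reads", "other_reads")] <-
    cc[, c("c_reads", "t_reads", "other_reads")] * 5
  calls3 <- call_methylation(cc3, min_reads = 1000)
  expect_equal(calls3$beta, calls$beta)
  expect_true(all(calls3$pass_depth >= calls$pass_depth, na.rm = TRUE))
})

test_that("conversion efficiency and misincorporation recover simulated rates", {
  reads <- make_reads(2000, conv = 1, err = 0, seed = 51)
  asg <- assign_reads(reads, panel)
  qc <- qc_metrics(asg, panel)
  expect_equal(qc$conversion_efficiency, 100)
  expect_true(all(qc$misincorporation$misincorporation == 0))
  reads2 <- make_reads(3000, conv = 0.998, err = 0, seed = 52)
  qc2 <- qc_metrics(assign_reads(reads2, panel), panel)
  expect_equal(qc2$conversion_efficiency, 99.8, tolerance = 0.001)
  # constructed counts: 1% other bases at a CpG -> misincorporation 1.0%
  cc <- data.frame(sample = "S", cpg_id = "A_C1", marker = "A",
                   c_reads = 495, t_reads = 495, other_reads = 10)
  calls <- call_methylation(cc)
  expect_equal(100 * calls$other_reads / calls$depth, 1.0)
})

test_that("normalized read depth sums to one and matches hand arithmetic", {
  cc <- data.frame(sample = "S",
                   cpg_id = paste(panel$markers$marker, "C1", sep = "_"),
                   marker = panel$markers$marker,
                   c_reads = 500, t_reads = 500, other_reads = 0)
  cc$depth <- cc$c_reads + cc$t_reads + cc$other_reads
  cov <- coverage_summary(cc, panel)
  expect_equal(cov$normalized_depth, rep(0.125, 8))
  expect_equal(sum(cov$normalized_depth), 1, tolerance = 1e-9)
  cc$depth <- c(7, 1, 0, 0, 0, 0, 0, 0)
  cov2 <- coverage_summary(cc, panel)
  expect_equal(cov2$normalized_depth, c(0.875, 0.125, 0, 0, 0, 0, 0, 0))
  cc$depth <- rep(0, 8)
  cov0 <- coverage_summary(cc, panel)
  expect_true(all(is.na(cov0$normalized_depth)))
})

test_that("measurement comparison reports differences and within-amplicon spread", {
  a <- data.frame(sample = "s1",
                  cpg_id = c("M1_C1", "M1_C2", "M1_C3", "M2_C1"),
                  marker = c("M1", "M1", "M1", "M2"),
                  beta = c(48, 51, 52, 30))
  ident <- compare_measurements(a, a)
  expect_true(all(ident$per_marker$mean_abs_diff == 0))
  b <- a; b$beta <- a$beta + 2
  cmp <- compare_measurements(a, b)
  expect_equal(cmp$per_marker$mean_abs_diff, c(2, 2))
  expect_equal(unname(cmp$overall["sd"]), 0)
  expect_equal(cmp$spread$spread[cmp$spread$marker == "M1"], 4)
  bad <- a; bad$cpg_id <- paste0("X", bad$cpg_id); bad$beta <- NA
  expect_error(compare_measurements(a, bad), "no overlapping")
})
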