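# Shared fixtures and independent oracles for the test suite.

panel <- bundled_panel()

# A two-marker toy panel built in code, for tests that need full control
# over reference sequences and CpG placement.
toy_panel <- function() {
  dir <- tempfile("toypanel")
  dir.create(dir)
  m <- data.frame(
    marker = c("MK1", "MK2"), chrom = c("chr1", "chr2"),
    start = c(101L, 501L), end = c(140L, 560L), strand = c("+", "+"),
    amplicon_size = c(40L, 60L),
    fwd_primer = c("ACGT", "TTGA"), rev_primer = c("ACGT", "TGGA"),
    primer_conc_uM = c(0.2, 0.4),
    reference_seq = c(synthetic_reference(40, c(10, 20), seed = 7),
                      synthetic_reference(60, c(15, 30, 45), seed = 8)),
    stringsAsFactors = FALSE)
  cp <- data.frame(
    marker = c("MK1", "MK1", "MK2", "MK2", "MK2"),
    label = c("C1", "C2", "C1", "C2", "C3"),
    genomic_pos = c(111L, 121L, 516L, 531L, 546L),
    amplicon_offset = c(10L, 20L, 15L, 30L, 45L),
    array_id = "", stringsAsFactors = FALSE)
  write.table(m, file.path(dir, "markers.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(cp, file.path(dir, "cpgs.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  load_panel(file.path(dir, "markers.tsv"), file.path(dir, "cpgs.tsv"))
}

# Brute-force mismatch count between an amplicon-oriented read and a
# collapsed reference, anchored at the start or end: the oracle for the
# vectorised matcher.
oracle_mismatches <- function(read, ref, anchor = "start") {
  r <- strsplit(read, "")[[1]]
  f <- strsplit(ref, "")[[1]]
  k <- min(length(r), length(f))
  f <- if (anchor == "start") f[1:k] else f[(length(f) - k + 1):length(f)]
  r <- r[1:k]
  sum(!(r == f | (f == "Y" & r %in% c("C", "T"))))
}

# Exhaustive best-subset search maximising adjusted R^2 (oracle for
# stepwise selection; feasible up to ~10 candidates).
oracle_best_subset_adjr2 <- function(X, y) {
  p <- ncol(X)
  best <- -Inf
  n <- length(y)
  tss <- sum((y - mean(y))^2)
  for (mask in 1:(2^p - 1)) {
    cols <- which(bitwAnd(mask, 2^(0:(p - 1))) > 0)
    fit <- stats::lm.fit(cbind(1, X[, cols, drop = FALSE]), y)
    r2 <- 1 - sum(fit$residuals^2) / tss
    adj <- 1 - (1 - r2) * (n - 1) / (n - length(cols) - 1)
    if (adj > best) best <- adj
  }
  best
}

# Ten-candidate synthetic screening dataset: `k_informative` CpGs carry an
# age signal, the rest are age-flat noise; measurement noise via the
# default assay distortion.
make_screen_data <- function(n = 112, k_informative = 2, k_flat = 8,
                             seed = 1) {
  fns <- data.frame(
    cpg_id = sprintf("MKS%d_C1", seq_len(k_informative + k_flat)),
    marker = sprintf("MKS%d", seq_len(k_informative + k_flat)),
    label = "C1",
    form = "linear",
    intercept = c(rep(c(15, 70), length.out = k_informative), rep(40, k_flat)),
    slope = c(rep(c(0.6, -0.5), length.out = k_informative), rep(0, k_flat)),
    scale = 0, exponent = 1,
    direction = c(rep(c("hyper", "hypo"), length.out = k_informative),
                  rep("hyper", k_flat)),
    bio_sd = 2, stringsAsFactors = FALSE)
  cohort <- simulate_cohort(n, c(1, 75), tissue = "blood", seed = seed)
  meth <- simulate_methylation_matrix(cohort, fns, assay_distortion(bias = 0),
                                      seed = seed + 1)
  list(cohort = cohort, meth = meth,
       informative = fns$cpg_id[fns$slope != 0])
}
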