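#' Assay distortion parameters
#'
#' Bundles the measurement artifacts the simulator imposes on true
#' methylation: marker-specific PCR bias, duplicate (technical) noise,
#' incomplete bisulfite conversion, sequencing error, amplicon amplification
#' imbalance, a read-depth model, and the template bottleneck governing
#' input-DNA dilution behaviour.
#'
#' Defaults: the bias term vanishes at 0 and 100 percent true methylation
#' and peaks (at `bias` percent) at 50 percent; its default signs encode the
#' observed overestimation at MIR29B2CHG and EDARADD and underestimation at
#' ELOVL2 (+/-3 percent amplitude, a free parameter). The duplicate noise SD
#' defaults to `1.9 * sqrt(pi) / 2` (~1.68) so the expected absolute
#' difference between two technical duplicates, `2 * sigma / sqrt(pi)`,
#' equals the 1.9 percent mean duplicate difference of the optimized assay.
#' Conversion probability defaults to 0.998 per cytosine and sequencing
#' error to 6e-4 per base (giving a ~0.04 percent misincorporation rate).
#' The template model (300 diploid copies/ng, 60 percent bisulfite recovery)
#' controls how few molecules survive at low DNA input.
#'
#' @param bias Named numeric vector of signed bias amplitudes (percent) per
#'   marker; markers not named get 0.
#' @param duplicate_sd Technical noise SD in percent (scalar or named per
#'   marker).
#' @param conversion_prob Per-cytosine bisulfite conversion probability.
#' @param seq_error Per-base sequencing substitution probability.
#' @param amplicon_weights Named positive relative amplification
#'   efficiencies per marker; unnamed markers get 1.
#' @param depth_mean,depth_size Negative-binomial mean and size for the
#'   per-amplicon read depth (paired reads) before weighting.
#' @param template_molecules_per_ng Amplifiable diploid copies per ng input.
#' @param bisulfite_recovery Fraction of templates surviving conversion.
#' @return An `assay_distortion` object (a list).
#' @export
assay_distortion <- function(bias = c(MIR29B2CHG = 3, EDARADD = 3, ELOVL2 = -3),
                             duplicate_sd = 1.9 * sqrt(pi) / 2,
                             conversion_prob = 0.998,
                             seq_error = 6e-4,
                             amplicon_weights = numeric(0),
                             depth_mean = 40000, depth_size = 8,
                             template_molecules_per_ng = 300,
                             bisulfite_recovery = 0.6) {
  stopifnot(conversion_prob >= 0, conversion_prob <= 1,
            seq_error >= 0, seq_error <= 1,
            all(amplicon_weights > 0), depth_mean > 0,
            bisulfite_recovery > 0, bisulfite_recovery <= 1)
  structure(list(bias = bias, duplicate_sd = duplicate_sd,
                 conversion_prob = conversion_prob, seq_error = seq_error,
                 amplicon_weights = amplicon_weights,
                 depth_mean = depth_mean, depth_size = depth_size,
                 template_molecules_per_ng = template_molecules_per_ng,
                 bisulfite_recovery = bisulfite_recovery),
            class = "assay_distortion")
}

marker_param <- function(x, markers, default) {
  out <- rep(default, length(markers))
  names(out) <- markers
  if (length(x)) {
    if (is.null(names(x)) && length(x) == 1) out[] <- x
    else out[names(x)[names(x) %in% markers]] <- x[names(x) %in% markers]
  }
  out
}

#' Simulate a cohort of samples
#'
#' Draws sample ages uniformly over a range (or from a user-supplied
#' sampler) with a fixed sex ratio, as the donor cohorts of a tissue study.
#'
#' @param n Number of samples.
#' @param age_range `c(lo, hi)` in years.
#' @param sex_ratio Fraction of male samples (0.5 gives an even split).
#' @param tissue Tissue label (`blood`, `buccal`, `bone`, ...).
#' @param seed RNG seed; the same seed reproduces the cohort exactly.
#' @param age_sampler Optional `function(n)` returning ages, overriding the
#'   uniform draw.
#' @return Data frame with `sample_id`, `age`, `sex`, `tissue`, `split`.
#' @export
simulate_cohort <- function(n, age_range = c(1, 75), sex_ratio = 0.5,
                            tissue = "blood", seed = NULL,
                            age_sampler = NULL) {
  if (!is_count(n)) stopf("n must be a nonnegative integer")
  if (length(age_range) != 2 || age_range[1] > age_range[2])
    stopf("age_range must be c(lo, hi) with lo <= hi")
  if (n == 0)
    return(data.frame(sample_id = character(0), age = numeric(0),
                      sex = character(0), tissue = character(0),
                      split = character(0)))
  with_seed(seed, {
    ages <- if (is.null(age_sampler)) {
      stats::runif(n, age_range[1], age_range[2])
    } else age_sampler(n)
    n_m <- round(n * sex_ratio)
    sex <- sample(c(rep("M", n_m), rep("F", n - n_m)))
    data.frame(sample_id = sprintf("%s_%04d", tissue, seq_len(n)),
               age = ages, sex = sex, tissue = tissue, split = "none",
               stringsAsFactors = FALSE)
  })
}

#' Apply assay distortion to a true methylation vector
#'
#' Observed value = `clamp(true + b_m * 4 * t * (1 - t) + eps)` with
#' `t = true/100` and `eps ~ N(0, sigma_m)`: a marker-specific bias that is
#' largest mid-scale and vanishes at fully (un)methylated sites, plus
#' technical duplicate noise.
#'
#' @param true_vec Named percent vector (names = `cpg_id`, prefix = marker).
#' @param distortion An [assay_distortion()].
#' @param seed RNG seed.
#' @return Percent vector of observed methylation.
#' @export
apply_assay_distortion <- function(true_vec, distortion = assay_distortion(),
                                   seed = NULL) {
  stopifnot(inherits(distortion, "assay_distortion"),
            all(true_vec >= 0 & true_vec <= 100))
  markers <- sub("_C[0-9]+$", "", names(true_vec))
  b <- marker_param(distortion$bias, unique(markers), 0)[markers]
  s <- marker_param(distortion$duplicate_sd, unique(markers),
                    if (length(distortion$duplicate_sd) == 1)
                      distortion$duplicate_sd else 0)[markers]
  t <- true_vec / 100
  with_seed(seed, {
    eps <- stats::rnorm(length(true_vec), 0, s)
    out <- clamp(true_vec + b * 4 * t * (1 - t) + eps)
    names(out) <- names(true_vec)
    out
  })
}

#' Simulate per-CpG C/T counts
#'
#' Generates a CpG count table for one sample without simulating individual
#' reads. The input-DNA bottleneck is modelled first: `M = round(input_ng *
#' template_molecules_per_ng * bisulfite_recovery)` template molecules, with
#' the per-CpG methylated-template fraction drawn binomially from the
#' observed methylation - this is what makes low-input quantification noisy
#' regardless of sequencing depth. Read depth per amplicon is negative
#' binomial scaled by the amplicon weight; C/T/other reads are multinomial
#' given the template fraction, conversion failures on unmethylated
#' cytosines, and sequencing error.
#'
#' @param observed_vec Named percent vector (names = `cpg_id`).
#' @param distortion An [assay_distortion()].
#' @param input_ng DNA input to bisulfite conversion, ng (> 0).
#' @param sample_id Sample label for the output table.
#' @param seed RNG seed.
#' @return Data frame `sample, cpg_id, marker, c_reads, t_reads,
#'   other_reads, depth` (one row per CpG).
#' @export
simulate_counts <- function(observed_vec, distortion = assay_distortion(),
                            input_ng = 200, sample_id = "S1", seed = NULL) {
  stopifnot(inherits(distortion, "assay_distortion"))
  if (!is.numeric(input_ng) || input_ng <= 0) stopf("input_ng must be > 0")
  markers <- sub("_C[0-9]+$", "", names(observed_vec))
  umark <- unique(markers)
  w <- marker_param(distortion$amplicon_weights, umark, 1)
  M <- max(1L, round(input_ng * distortion$template_molecules_per_ng *
                       distortion$bisulfite_recovery))
  conv <- distortion$conversion_prob
  e <- distortion$seq_error
  with_seed(seed, {
    depth_m <- stats::rnbinom(length(umark), size = distortion$depth_size,
                              mu = distortion$depth_mean * w)
    names(depth_m) <- umark
    rows <- lapply(seq_along(observed_vec), function(i) {
      p <- observed_vec[i] / 100
      f <- stats::rbinom(1, M, p) / M        # template bottleneck
      p_c0 <- f + (1 - f) * (1 - conv)       # unconverted unmethylated C
      p_c <- p_c0 * (1 - e) + (1 - p_c0) * e / 3
      p_t <- (1 - p_c0) * (1 - e) + p_c0 * e / 3
      p_o <- 2 * e / 3
      d <- depth_m[markers[i]]
      cnt <- if (d > 0) stats::rmultinom(1, d, c(p_c, p_t, p_o))[, 1]
             else c(0L, 0L, 0L)
      data.frame(sample = sample_id, cpg_id = names(observed_vec)[i],
                 marker = markers[i], c_reads = cnt[1], t_reads = cnt[2],
                 other_reads = cnt[3], depth = sum(cnt),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Simulate paired bisulfite amplicon reads
#'
#' Produces primer-anchored paired-end reads: mate 1 is the first
#' `read_length` bases of each bisulfite-converted amplicon molecule, mate 2
#' the reverse complement of the last `read_length` bases. With 2 x 150
#' geometry, interior positions of amplicons longer than twice the read
#' length are covered by only one mate, reproducing the coverage dip seen on
#' the longest amplicons. Per molecule, each CpG cytosine is methylated with
#' probability equal to its observed methylation; unmethylated and non-CpG
#' cytosines convert to T with `conversion_prob`; every base is substituted
#' with probability `seq_error`. Quality strings are constant Phred 37.
#'
#' @param observed_vec Named percent vector over the panel's CpGs.
#' @param panel A `panel_definition` with reference sequences.
#' @param n_pairs Total read pairs to generate across amplicons (allocated
#'   by amplicon weight), or a named per-marker vector.
#' @param read_length Read length in bp.
#' @param distortion An [assay_distortion()].
#' @param sample_id Prefix for read names.
#' @param seed RNG seed.
#' @return A `read_pairs` data frame with columns `id, seq1, qual1, seq2,
#'   qual2, true_marker`.
#' @export
simulate_reads <- function(observed_vec, panel, n_pairs = 8000,
                           read_length = 150,
                           distortion = assay_distortion(),
                           sample_id = "S1", seed = NULL) {
  stopifnot(inherits(panel, "panel_definition"),
            inherits(distortion, "assay_distortion"))
  markers <- panel$markers$marker
  longest_primer <- max(nchar(panel$markers$fwd_primer),
                        nchar(panel$markers$rev_primer))
  if (read_length < longest_primer)
    stopf("read_length %d shorter than longest primer (%d bp)",
          read_length, longest_primer)
  w <- marker_param(distortion$amplicon_weights, markers, 1)
  if (length(n_pairs) == 1 && is.null(names(n_pairs))) {
    alloc <- round(n_pairs * w / sum(w))
  } else {
    alloc <- marker_param(n_pairs, markers, 0)
  }
  conv <- distortion$conversion_prob
  e <- distortion$seq_error
  bases <- c("A", "C", "G", "T")
  qconst <- function(n) strrep(rawToChar(as.raw(33 + 37)), n)
  with_seed(seed, {
    per_marker <- lapply(markers, function(m) {
      n <- alloc[m]
      if (n == 0) return(NULL)
      row <- panel$markers[panel$markers$marker == m, ]
      ref <- strsplit(row$reference_seq, "")[[1]]
      L <- length(ref)
      offs <- panel$cpgs$amplicon_offset[panel$cpgs$marker == m]
      cpg_ids <- panel$cpgs$cpg_id[panel$cpgs$marker == m]
      beta <- observed_vec[cpg_ids] / 100
      mat <- matrix(ref, nrow = L, ncol = n)
      noncpg_c <- setdiff(which(ref == "C"), offs + 1L)
      # bisulfite conversion of non-CpG cytosines
      if (length(noncpg_c)) {
        sel <- matrix(stats::runif(length(noncpg_c) * n) < conv,
                      nrow = length(noncpg_c))
        mat[noncpg_c, ][sel] <- "T"
      }
      # CpG cytosines: methylated stay C, unmethylated convert with conv
      for (j in seq_along(offs)) {
        meth <- stats::runif(n) < beta[j]
        unconv <- stats::runif(n) >= conv
        mat[offs[j] + 1L, ] <- ifelse(meth | unconv, "C", "T")
      }
      if (e > 0) {
        hit <- which(stats::runif(L * n) < e)
        if (length(hit)) {
          shift <- sample(1:3, length(hit), replace = TRUE)
          old <- match(mat[hit], bases)
          mat[hit] <- bases[((old - 1 + shift) %% 4) + 1]
        }
      }
      amp <- do.call(paste0, lapply(seq_len(L), function(i) mat[i, ]))
      r1 <- substr(amp, 1, read_length)
      r2 <- revcomp_chr(substr(amp, pmax(1, L - read_length + 1), L))
      data.frame(id = sprintf("%s_%s_%06d", sample_id, m, seq_len(n)),
                 seq1 = r1, qual1 = qconst(nchar(r1)),
                 seq2 = r2, qual2 = qconst(nchar(r2)),
                 true_marker = m, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, per_marker)
    class(out) <- c("read_pairs", "data.frame")
    out
  })
}

#' Simulate a methylated DNA standard series
#'
#' DNA methylation standards mixed to fixed ratios: every CpG of the panel
#' carries the same true methylation, one record per ratio per replicate.
#'
#' @param ratios Percent methylation levels, each in \[0, 100\].
#' @param replicates Technical replicates per ratio (2 = duplicates).
#' @param distortion An [assay_distortion()]; applied per replicate to give
#'   the observed vectors.
#' @param n_cpgs Number of CpGs (use the panel census total).
#' @param cpg_ids Optional CpG names for the truth vectors.
#' @param seed RNG seed.
#' @return A list with `samples` (data frame: `sample_id, tissue, ratio,
#'   replicate`) and matrices `truth` and `observed` (samples x CpGs,
#'   percent).
#' @export
simulate_standard_series <- function(ratios, replicates = 2,
                                     distortion = assay_distortion(),
                                     n_cpgs = 44, cpg_ids = NULL,
                                     seed = NULL) {
  if (any(ratios < 0 | ratios > 100)) stopf("ratios must lie in [0, 100]")
  if (is.null(cpg_ids)) cpg_ids <- sprintf("CpG%02d", seq_len(n_cpgs))
  grid <- expand.grid(replicate = seq_len(replicates), ratio = ratios)[, 2:1]
  samples <- data.frame(
    sample_id = sprintf("std%g_r%d", grid$ratio, grid$replicate),
    tissue = "standard", ratio = grid$ratio, replicate = grid$replicate,
    stringsAsFactors = FALSE)
  truth <- matrix(rep(grid$ratio, each = length(cpg_ids)),
                  nrow = nrow(grid), byrow = TRUE,
                  dimnames = list(samples$sample_id, cpg_ids))
  seeds <- derive_seeds(seed, nrow(grid))
  observed <- truth
  for (i in seq_len(nrow(grid))) {
    tv <- truth[i, ]
    names(tv) <- cpg_ids
    observed[i, ] <- apply_assay_distortion(tv, distortion, seed = seeds[[i]])
  }
  list(samples = samples, truth = truth, observed = observed)
}

#' Observed methylation matrix for a cohort
#'
#' Convenience wrapper: evaluates the true methylation of every sample at
#' its age and applies assay distortion, yielding the matrix the modelling
#' layer consumes.
#'
#' @param cohort Data frame from [simulate_cohort()].
#' @param functions Data frame from [default_age_functions()].
#' @param distortion An [assay_distortion()], or `NULL` for truth only.
#' @param seed RNG seed (per-sample substreams are derived from it).
#' @return Numeric matrix (samples x CpGs, percent), rownames = sample ids.
#' @export
simulate_methylation_matrix <- function(cohort, functions, distortion = NULL,
                                        seed = NULL) {
  seeds <- derive_seeds(seed, 2 * nrow(cohort))
  out <- matrix(NA_real_, nrow(cohort), nrow(functions),
                dimnames = list(cohort$sample_id, functions$cpg_id))
  for (i in seq_len(nrow(cohort))) {
    tv <- true_methylation(cohort$age[i], functions, seed = seeds[[i]])
    if (!is.null(distortion))
      tv <- apply_assay_distortion(tv, distortion,
                                   seed = seeds[[nrow(cohort) + i]])
    out[i, ] <- tv
  }
  out
}
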