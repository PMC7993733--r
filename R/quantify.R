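# Read assignment and per-CpG counting in bisulfite space.
#
# Reads are matched end-anchored and ungapped against bisulfite-collapsed
# amplicon references (alphabet A/G/T/Y). Matching rule, in amplicon
# orientation: a read base matches an identical reference base; at a Y
# (target CpG) the read may carry C or T; a read C anywhere else is a
# mismatch (an unconverted cytosine). This deliberately emulates alignment
# against a custom reference of only the targeted sequences; it is not a
# general aligner.

RAW_C <- charToRaw("C"); RAW_T <- charToRaw("T"); RAW_Y <- charToRaw("Y")

# Character matrix as raw bytes: one column per (equal-length) string.
raw_mat <- function(x) {
  n <- unique(nchar(x))
  stopifnot(length(n) == 1)
  matrix(charToRaw(paste(x, collapse = "")), nrow = n)
}

# Mismatch count of each column of `mat` against refraw, anchored at the
# reference start (anchor = "start") or end (anchor = "end").
mm_count <- function(mat, refraw, anchor = c("start", "end")) {
  anchor <- match.arg(anchor)
  K <- min(nrow(mat), length(refraw))
  r <- if (anchor == "start") refraw[seq_len(K)]
       else refraw[seq(length(refraw) - K + 1, length(refraw))]
  sub <- mat[seq_len(K), , drop = FALSE]
  eq <- sub == r                      # r recycles down columns
  okY <- (r == as.vector(RAW_Y)) & (sub == as.vector(RAW_C) | sub == as.vector(RAW_T))
  list(mm = colSums(!(eq | okY)), bases = K)
}

#' Assign paired reads to panel amplicons
#'
#' Matches each read pair against every bisulfite-collapsed reference,
#' end-anchored and ungapped, trying both mate orientations (mate 1 at the
#' amplicon 5' end with mate 2 reverse-complemented at the 3' end, and the
#' swap). A pair is assigned to the unique reference with the smallest
#' mismatch fraction, provided that fraction does not exceed
#' `max_mismatch_frac`; ties between references leave the pair unassigned.
#' The mismatch-fraction threshold plus the unique-best-hit requirement
#' stand in for a mapping-quality filter.
#'
#' @param reads A `read_pairs` data frame ([simulate_reads()] or
#'   [read_fastq_pair()]).
#' @param panel A `panel_definition` (collapsed references are derived from
#'   it), or a named character vector of collapsed references.
#' @param max_mismatch_frac Maximum tolerated mismatch fraction.
#' @return A `read_assignment` list: `assignments` (per pair: `id`,
#'   `marker` or NA, `mismatch_frac`, `orientation`), `groups` (per marker:
#'   data frame of amplicon-oriented reads `fwd_seq, fwd_qual, rev_seq,
#'   rev_qual`), `n_unassigned`, and `ref_len` per marker.
#' @export
assign_reads <- function(reads, panel, max_mismatch_frac = 0.05) {
  refs <- if (inherits(panel, "panel_definition")) collapsed_references(panel)
          else panel
  refraw <- lapply(refs, charToRaw)
  n <- nrow(reads)
  rc1 <- revcomp_chr(reads$seq1)
  rc2 <- revcomp_chr(reads$seq2)
  rq1 <- vapply(reads$qual1, function(q)
    paste(rev(strsplit(q, "")[[1]]), collapse = ""), character(1), USE.NAMES = FALSE)
  rq2 <- vapply(reads$qual2, function(q)
    paste(rev(strsplit(q, "")[[1]]), collapse = ""), character(1), USE.NAMES = FALSE)

  best_marker <- rep(NA_character_, n)
  best_frac <- rep(Inf, n)
  best_orient <- rep(NA_character_, n)
  tie <- rep(FALSE, n)

  len_groups <- split(seq_len(n), paste(nchar(reads$seq1), nchar(reads$seq2)))
  for (idx in len_groups) {
    m1 <- raw_mat(reads$seq1[idx]); m2 <- raw_mat(reads$seq2[idx])
    mr1 <- raw_mat(rc1[idx]);       mr2 <- raw_mat(rc2[idx])
    for (mk in names(refraw)) {
      rr <- refraw[[mk]]
      # orientation "12": mate1 5'-anchored, revcomp(mate2) 3'-anchored
      a <- mm_count(m1, rr, "start"); b <- mm_count(mr2, rr, "end")
      f12 <- (a$mm + b$mm) / (a$bases + b$bases)
      # orientation "21": mate2 5'-anchored, revcomp(mate1) 3'-anchored
      a2 <- mm_count(m2, rr, "start"); b2 <- mm_count(mr1, rr, "end")
      f21 <- (a2$mm + b2$mm) / (a2$bases + b2$bases)
      f <- pmin(f12, f21)
      orient <- ifelse(f12 <= f21, "12", "21")
      newbest <- f < best_frac[idx]
      newtie <- f == best_frac[idx]
      tie[idx][newtie] <- TRUE
      tie[idx][newbest] <- FALSE
      best_orient[idx][newbest] <- orient[newbest]
      best_marker[idx][newbest] <- mk
      best_frac[idx][newbest] <- f[newbest]
    }
  }
  assigned <- !tie & is.finite(best_frac) & best_frac <= max_mismatch_frac
  best_marker[!assigned] <- NA_character_

  groups <- list()
  for (mk in names(refs)) {
    sel <- which(assigned & best_marker == mk)
    if (!length(sel)) next
    o12 <- best_orient[sel] == "12"
    groups[[mk]] <- data.frame(
      fwd_seq = ifelse(o12, reads$seq1[sel], reads$seq2[sel]),
      fwd_qual = ifelse(o12, reads$qual1[sel], reads$qual2[sel]),
      rev_seq = ifelse(o12, rc2[sel], rc1[sel]),
      rev_qual = ifelse(o12, rq2[sel], rq1[sel]),
      stringsAsFactors = FALSE)
  }
  structure(list(
    assignments = data.frame(id = reads$id, marker = best_marker,
                             mismatch_frac = ifelse(assigned, best_frac, NA),
                             orientation = ifelse(assigned, best_orient, NA),
                             stringsAsFactors = FALSE),
    groups = groups,
    n_unassigned = sum(!assigned),
    ref_len = vapply(refs, nchar, integer(1))),
    class = "read_assignment")
}

# Tally bases observed at one amplicon position p (1-based) across a read
# group, respecting base quality. Both mates contribute where they cover p
# (paired-read counting; depths are in mate units).
bases_at_position <- function(group, p, ref_len, min_base_qual) {
  out <- character(0)
  k1 <- nchar(group$fwd_seq)
  cov1 <- p <= k1
  if (any(cov1)) {
    b <- substring(group$fwd_seq[cov1], p, p)
    q <- utf8ToInt(paste(substring(group$fwd_qual[cov1], p, p), collapse = "")) - 33L
    out <- c(out, b[q >= min_base_qual])
  }
  k2 <- nchar(group$rev_seq)
  pos2 <- p - (ref_len - k2)          # position within the 3'-anchored string
  cov2 <- pos2 >= 1
  if (any(cov2)) {
    b <- substring(group$rev_seq[cov2], pos2[cov2], pos2[cov2])
    q <- utf8ToInt(paste(substring(group$rev_qual[cov2], pos2[cov2], pos2[cov2]),
                         collapse = "")) - 33L
    out <- c(out, b[q >= min_base_qual])
  }
  out
}

#' Count C/T/other bases at target CpGs
#'
#' For every target CpG, tallies the bases observed at its amplicon offset
#' across all assigned reads with base quality at or above the threshold.
#' Mates overlapping a CpG each contribute one count (depths are reported in
#' paired reads); set `fragment_level = TRUE` to count each pair at most
#' once (mate 1 wins where both cover).
#'
#' @param assignment A `read_assignment` from [assign_reads()].
#' @param panel A `panel_definition`.
#' @param min_base_qual Minimum Phred base quality (default 30).
#' @param sample_id Sample label for the output rows.
#' @param fragment_level Count fragments instead of mates.
#' @return A CpG count table: data frame `sample, cpg_id, marker, c_reads,
#'   t_reads, other_reads, depth`.
#' @export
count_cpg_bases <- function(assignment, panel, min_base_qual = 30,
                            sample_id = "S1", fragment_level = FALSE) {
  stopifnot(inherits(assignment, "read_assignment"),
            inherits(panel, "panel_definition"))
  rows <- lapply(seq_len(nrow(panel$cpgs)), function(i) {
    cp <- panel$cpgs[i, ]
    g <- assignment$groups[[cp$marker]]
    L <- assignment$ref_len[[cp$marker]]
    b <- character(0)
    if (!is.null(g)) {
      if (fragment_level) {
        # mate 1 takes precedence where both mates cover the position
        p <- cp$amplicon_offset + 1L
        cov1 <- p <= nchar(g$fwd_seq)
        g2 <- g
        g2$rev_seq[cov1] <- ""
        g2$rev_qual[cov1] <- ""
        b <- bases_at_position(g2, p, L, min_base_qual)
      } else {
        b <- bases_at_position(g, cp$amplicon_offset + 1L, L, min_base_qual)
      }
    }
    data.frame(sample = sample_id, cpg_id = cp$cpg_id, marker = cp$marker,
               c_reads = sum(b == "C"), t_reads = sum(b == "T"),
               other_reads = sum(!(b %in% c("C", "T"))),
               depth = length(b), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Call percent beta values from a CpG count table
#'
#' Beta = 100 * C / (C + T); reads carrying any other base are excluded from
#' the denominator. A CpG passes depth QC when its total depth
#' (C + T + other) reaches `min_reads`; failing CpGs keep their beta and a
#' fail flag so QC decisions stay auditable.
#'
#' @param counts CpG count table ([count_cpg_bases()] or
#'   [simulate_counts()], or a TSV read with [read_counts_tsv()]).
#' @param min_reads Minimum accepted read depth (default 1000).
#' @return A `methylation_calls` data frame: the counts plus `beta`
#'   (percent, NA when C + T = 0) and `pass_depth`.
#' @export
call_methylation <- function(counts, min_reads = 1000) {
  need <- c("cpg_id", "c_reads", "t_reads", "other_reads")
  miss <- setdiff(need, names(counts))
  if (length(miss)) stopf("count table missing column(s): %s",
                          paste(miss, collapse = ", "))
  ct <- counts$c_reads + counts$t_reads
  counts$depth <- counts$c_reads + counts$t_reads + counts$other_reads
  counts$beta <- ifelse(ct > 0, 100 * counts$c_reads / ct, NA_real_)
  counts$pass_depth <- counts$depth >= min_reads
  class(counts) <- c("methylation_calls", "data.frame")
  counts
}

#' Quality-control metrics from assigned reads
#'
#' Bisulfite conversion efficiency: at every non-CpG cytosine of every
#' reference, the reversed beta T / (C + T) is computed across covering
#' reads; the sample-level efficiency is 100 times the mean over all such
#' positions (markers without non-CpG cytosines simply contribute none).
#' Misincorporation per CpG: 100 * other_reads / depth, bases that are
#' neither C nor T at a target CpG.
#'
#' @param assignment A `read_assignment`.
#' @param panel A `panel_definition` (original reference sequences are
#'   needed to locate non-CpG cytosines).
#' @param min_base_qual Minimum Phred base quality.
#' @return List with `conversion_efficiency` (percent, scalar),
#'   `misincorporation` (data frame `cpg_id, marker, misincorporation`), and
#'   `n_positions` (non-CpG cytosines used).
#' @export
qc_metrics <- function(assignment, panel, min_base_qual = 30) {
  stopifnot(inherits(assignment, "read_assignment"))
  rev_betas <- numeric(0)
  for (i in seq_len(nrow(panel$markers))) {
    m <- panel$markers[i, ]
    g <- assignment$groups[[m$marker]]
    if (is.null(g)) next
    ref <- strsplit(m$reference_seq, "")[[1]]
    offs <- panel$cpgs$amplicon_offset[panel$cpgs$marker == m$marker]
    noncpg_c <- setdiff(which(ref == "C"), offs + 1L)
    L <- length(ref)
    for (p in noncpg_c) {
      b <- bases_at_position(g, p, L, min_base_qual)
      ct <- sum(b == "C") + sum(b == "T")
      if (ct > 0) rev_betas <- c(rev_betas, sum(b == "T") / ct)
    }
  }
  counts <- count_cpg_bases(assignment, panel, min_base_qual)
  mis <- data.frame(cpg_id = counts$cpg_id, marker = counts$marker,
                    misincorporation = ifelse(counts$depth > 0,
                                              100 * counts$other_reads / counts$depth,
                                              NA_real_),
                    stringsAsFactors = FALSE)
  list(conversion_efficiency = if (length(rev_betas)) 100 * mean(rev_betas) else NA_real_,
       misincorporation = mis,
       n_positions = length(rev_betas))
}

#' Per-amplicon coverage summary
#'
#' One representative CpG per amplicon (default label C1) provides the
#' amplicon's read depth; total coverage is the sum over amplicons and the
#' normalized depth is each amplicon's share of it (1/8 = 0.125 per marker
#' under a perfectly balanced multiplex of eight).
#'
#' @param counts A CpG count table.
#' @param panel A `panel_definition`.
#' @param representative_label CpG label used per amplicon (default "C1").
#' @return Data frame `marker, depth, normalized_depth` with attribute
#'   `total_coverage`; normalized depths are NA (flagged) when total
#'   coverage is 0.
#' @export
coverage_summary <- function(counts, panel, representative_label = "C1") {
  reps <- paste(panel$markers$marker, representative_label, sep = "_")
  depth <- counts$depth[match(reps, counts$cpg_id)]
  depth[is.na(depth)] <- 0
  total <- sum(depth)
  out <- data.frame(marker = panel$markers$marker, depth = depth,
                    normalized_depth = if (total > 0) depth / total else NA_real_,
                    stringsAsFactors = FALSE)
  attr(out, "total_coverage") <- total
  out
}

#' Compare two methylation call sets
#'
#' Duplicates mode: per-marker mean and SD of the absolute beta difference
#' over matched CpGs (and samples, when both sets carry a `sample` column
#' with common values). Reference mode: set_a is averaged per CpG (over its
#' replicates) before taking per-CpG absolute differences to the reference
#' betas in set_b. Both modes also report the within-amplicon spread: the
#' max minus min beta across the CpGs of one marker in one sample of set_a.
#'
#' @param set_a,set_b Data frames with columns `cpg_id`, `marker`, `beta`
#'   (optionally `sample`), e.g. `methylation_calls`.
#' @param scope `"duplicates"` or `"to_reference"`.
#' @return List with `per_marker` (`marker, mean_abs_diff, sd_abs_diff,
#'   n_cpgs`), `overall` (mean +/- sd across markers), and `spread`
#'   (`marker, sample, spread`).
#' @export
compare_measurements <- function(set_a, set_b,
                                 scope = c("duplicates", "to_reference")) {
  scope <- match.arg(scope)
  key <- c("cpg_id", "marker")
  use_sample <- scope == "duplicates" &&
    "sample" %in% names(set_a) && "sample" %in% names(set_b) &&
    length(intersect(set_a$sample, set_b$sample)) > 0
  if (use_sample) key <- c("sample", key)
  a <- set_a[, c(key, "beta")]
  if (scope == "to_reference") {
    a <- stats::aggregate(beta ~ cpg_id + marker, data = set_a, FUN = mean)
  }
  merged <- merge(a, set_b[, c(intersect(key, names(set_b)), "beta")],
                  by = intersect(key, c("sample", "cpg_id", "marker")),
                  suffixes = c("_a", "_b"))
  merged <- merged[!is.na(merged$beta_a) & !is.na(merged$beta_b), ]
  if (nrow(merged) == 0) stopf("no overlapping CpGs with defined beta values")
  merged$adiff <- abs(merged$beta_a - merged$beta_b)
  per <- do.call(rbind, lapply(split(merged, merged$marker), function(d) {
    data.frame(marker = d$marker[1], mean_abs_diff = mean(d$adiff),
               sd_abs_diff = stats::sd(d$adiff), n_cpgs = nrow(d),
               stringsAsFactors = FALSE)
  }))
  rownames(per) <- NULL
  sa <- set_a
  if (!"sample" %in% names(sa)) sa$sample <- "a"
  spread <- do.call(rbind, lapply(split(sa, list(sa$marker, sa$sample),
                                        drop = TRUE), function(d) {
    b <- d$beta[!is.na(d$beta)]
    if (length(b) < 2) return(NULL)
    data.frame(marker = d$marker[1], sample = d$sample[1],
               spread = max(b) - min(b), stringsAsFactors = FALSE)
  }))
  if (!is.null(spread)) rownames(spread) <- NULL
  list(per_marker = per,
       overall = c(mean = mean(merged$adiff), sd = stats::sd(merged$adiff)),
       spread = spread)
}

#' Read / write count and call tables
#'
#' Plain TSV interchange: counts tables (`sample cpg_id marker c_reads
#' t_reads other_reads depth`) and call tables (counts plus
#' `beta pass_depth`).
#'
#' @param path File path.
#' @param x Table to write.
#' @return `read_counts_tsv()` returns the counts data frame.
#' @export
read_counts_tsv <- function(path) {
  if (!file.exists(path)) stopf("counts file not found: %s", path)
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "cpg_id", "c_reads", "t_reads", "other_reads")
  miss <- setdiff(need, names(d))
  if (length(miss)) stopf("counts TSV missing column(s): %s",
                          paste(miss, collapse = ", "))
  if (!"marker" %in% names(d)) d$marker <- sub("_C[0-9]+$", "", d$cpg_id)
  if (!"depth" %in% names(d)) d$depth <- d$c_reads + d$t_reads + d$other_reads
  d
}

#' @rdname read_counts_tsv
#' @export
write_table_tsv <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
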