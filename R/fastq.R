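# FASTQ IO for paired amplicon reads (Phred+33). Biostrings does the heavy
# lifting; a light structural pre-check gives record-indexed errors on
# malformed files.

check_fastq_structure <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) %% 4 != 0)
    stopf("malformed FASTQ %s: %d lines (not a multiple of 4), truncated near record %d",
          path, length(lines), length(lines) %/% 4 + 1)
  heads <- lines[seq(1, length(lines), by = 4)]
  seps <- lines[seq(3, length(lines), by = 4)]
  bad <- which(!startsWith(heads, "@") | !startsWith(seps, "+"))
  if (length(bad))
    stopf("malformed FASTQ %s at record %d", path, bad[1])
  invisible(length(lines) %/% 4)
}

#' Write / read paired FASTQ files
#'
#' `write_fastq_pair()` writes a `read_pairs` object (as produced by
#' [simulate_reads()]) to `<prefix>_R1.fastq` / `<prefix>_R2.fastq`;
#' `read_fastq_pair()` reads such a pair back.
#'
#' @param reads A `read_pairs` data frame.
#' @param prefix Output path prefix.
#' @return `write_fastq_pair()`: the two paths, invisibly.
#'   `read_fastq_pair()`: a `read_pairs` data frame.
#' @export
write_fastq_pair <- function(reads, prefix) {
  p1 <- paste0(prefix, "_R1.fastq")
  p2 <- paste0(prefix, "_R2.fastq")
  for (mate in 1:2) {
    s <- Biostrings::DNAStringSet(reads[[paste0("seq", mate)]])
    names(s) <- paste0(reads$id, "/", mate)
    q <- Biostrings::BStringSet(reads[[paste0("qual", mate)]])
    Biostrings::writeXStringSet(s, if (mate == 1) p1 else p2,
                                format = "fastq", qualities = q)
  }
  invisible(c(p1, p2))
}

#' @rdname write_fastq_pair
#' @param r1,r2 Paths to the mate-1 and mate-2 FASTQ files.
#' @export
read_fastq_pair <- function(r1, r2) {
  for (p in c(r1, r2)) {
    if (!file.exists(p)) stopf("FASTQ file not found: %s", p)
    check_fastq_structure(p)
  }
  read_qs <- function(p) {
    # the reader parks qualities in mcols and notes their removal; harmless
    withCallingHandlers(
      Biostrings::readQualityScaledDNAStringSet(p),
      warning = function(w) {
        if (grepl("metadata columns", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
  }
  s1 <- read_qs(r1)
  s2 <- read_qs(r2)
  if (length(s1) != length(s2))
    stopf("mate files differ in record count (%d vs %d)", length(s1), length(s2))
  out <- data.frame(
    id = sub("/1$", "", names(s1)),
    seq1 = as.character(s1), qual1 = as.character(Biostrings::quality(s1)),
    seq2 = as.character(s2), qual2 = as.character(Biostrings::quality(s2)),
    true_marker = NA_character_, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("read_pairs", "data.frame")
  out
}
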