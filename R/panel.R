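#' Load an amplicon panel definition
#'
#' Reads the marker table and companion CpG table describing a targeted
#' bisulfite amplicon panel: marker coordinates (GRCh38, 1-based fully
#' closed), strand, primer sequences in bisulfite space, and the target CpG
#' sites with their genomic positions and 0-based amplicon offsets.
#'
#' @param path Path to the tab-separated marker table with columns
#'   `marker chrom start end strand amplicon_size fwd_primer rev_primer
#'   primer_conc_uM reference_seq`.
#' @param cpg_path Path to the tab-separated CpG table with columns
#'   `marker label genomic_pos amplicon_offset array_id` (an optional
#'   `coord_source` column distinguishes coordinates printed in the source
#'   tables from synthetic in-amplicon placements).
#' @return A `panel_definition` object: a list with data frames `markers` and
#'   `cpgs`, marker order preserved from the file.
#' @seealso [bundled_panel()] for the eight-marker, 44-CpG fixture that ships
#'   with the package; [validate_panel()]; [cpg_census()].
#' @export
load_panel <- function(path, cpg_path) {
  for (p in c(path, cpg_path)) {
    if (!file.exists(p)) stopf("panel file not found: %s", p)
  }
  markers <- utils::read.delim(path, stringsAsFactors = FALSE,
                               colClasses = "character")
  need <- c("marker", "chrom", "start", "end", "strand", "amplicon_size",
            "fwd_primer", "rev_primer", "primer_conc_uM", "reference_seq")
  miss <- setdiff(need, names(markers))
  if (length(miss)) stopf("panel table missing column(s): %s",
                          paste(miss, collapse = ", "))
  if (nrow(markers) == 0) stopf("no markers in panel file %s", path)
  for (col in c("start", "end", "amplicon_size")) {
    v <- suppressWarnings(as.numeric(markers[[col]]))
    bad <- which(is.na(v) | v != floor(v) | v <= 0)
    if (length(bad)) stopf("malformed %s in panel row %d (marker %s)",
                           col, bad[1], markers$marker[bad[1]])
    markers[[col]] <- as.integer(v)
  }
  markers$primer_conc_uM <- as.numeric(markers$primer_conc_uM)
  dup <- markers$marker[duplicated(markers$marker)]
  if (length(dup)) stopf("duplicate marker name: %s", dup[1])
  bad <- which(markers$end < markers$start)
  if (length(bad)) stopf("end < start for marker %s", markers$marker[bad[1]])
  if (!all(markers$strand %in% c("+", "-"))) {
    stopf("strand must be + or - (marker %s)",
          markers$marker[which(!markers$strand %in% c("+", "-"))[1]])
  }

  cpgs <- utils::read.delim(cpg_path, stringsAsFactors = FALSE,
                            colClasses = "character")
  need_c <- c("marker", "label", "genomic_pos", "amplicon_offset", "array_id")
  miss <- setdiff(need_c, names(cpgs))
  if (length(miss)) stopf("CpG table missing column(s): %s",
                          paste(miss, collapse = ", "))
  cpgs$genomic_pos <- as.integer(cpgs$genomic_pos)
  cpgs$amplicon_offset <- as.integer(cpgs$amplicon_offset)
  orphan <- setdiff(cpgs$marker, markers$marker)
  if (length(orphan)) stopf("CpG table references unknown marker: %s", orphan[1])
  for (m in unique(cpgs$marker)) {
    lab <- cpgs$label[cpgs$marker == m]
    if (anyDuplicated(lab)) stopf("duplicate CpG label in marker %s", m)
  }
  cpgs$cpg_id <- paste(cpgs$marker, cpgs$label, sep = "_")

  structure(list(markers = markers, cpgs = cpgs), class = "panel_definition")
}

#' @export
print.panel_definition <- function(x, ...) {
  cen <- cpg_census(x)
  cat(sprintf("Amplicon panel: %d markers, %d target CpGs\n",
              nrow(x$markers), cen$total))
  df <- data.frame(marker = x$markers$marker,
                   span = sprintf("%s:%d-%d", x$markers$chrom,
                                  x$markers$start, x$markers$end),
                   strand = x$markers$strand,
                   size_bp = x$markers$amplicon_size,
                   n_cpg = as.integer(cen$per_marker[x$markers$marker]))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Path to / loading of the bundled eight-marker panel fixture
#'
#' The fixture reproduces the published eight-marker multiplex: marker spans,
#' strands, amplicon sizes and primer sequences, plus all 44 target CpGs.
#' The 15 CpGs that appear in the published model tables carry their printed
#' GRCh38 coordinates (`coord_source = "paper"`); the remaining 29 carry
#' synthetic in-amplicon offsets (`coord_source = "synthetic"`) consistent
#' with the per-marker CpG counts. Reference sequences are synthetic, with
#' CpG dinucleotides only at the target offsets.
#'
#' @return `bundled_panel()` returns the loaded `panel_definition`;
#'   `bundled_panel_paths()` returns the two file paths.
#' @export
bundled_panel <- function() {
  p <- bundled_panel_paths()
  load_panel(p["markers"], p["cpgs"])
}

#' @rdname bundled_panel
#' @export
bundled_panel_paths <- function() {
  c(markers = system.file("extdata", "age_panel_markers.tsv",
                          package = "ampage", mustWork = TRUE),
    cpgs = system.file("extdata", "age_panel_cpgs.tsv",
                       package = "ampage", mustWork = TRUE))
}

#' Validate panel geometry
#'
#' Checks every marker for coordinate-span vs declared amplicon size
#' (1-based fully-closed convention: `end - start + 1 == amplicon_size`),
#' CpG containment within the marker span and within the amplicon, primer
#' sanity (length not exceeding the amplicon, IUPAC DNA alphabet), and
#' reference sequence length. Failures are report rows, not errors.
#'
#' @param panel A `panel_definition`.
#' @return A data frame with columns `marker`, `check`, `pass`, `detail`.
#' @export
validate_panel <- function(panel) {
  stopifnot(inherits(panel, "panel_definition"))
  rows <- list()
  add <- function(marker, check, pass, detail = "") {
    rows[[length(rows) + 1L]] <<- data.frame(marker = marker, check = check,
                                             pass = pass, detail = detail,
                                             stringsAsFactors = FALSE)
  }
  iupac <- "^[ACGTRYSWKMBDHVN]+$"
  for (i in seq_len(nrow(panel$markers))) {
    m <- panel$markers[i, ]
    span <- m$end - m$start + 1L
    add(m$marker, "span_equals_declared_size", span == m$amplicon_size,
        sprintf("span %d vs declared %d", span, m$amplicon_size))
    add(m$marker, "primers_fit_amplicon",
        nchar(m$fwd_primer) <= m$amplicon_size &&
          nchar(m$rev_primer) <= m$amplicon_size,
        sprintf("fwd %d bp, rev %d bp", nchar(m$fwd_primer), nchar(m$rev_primer)))
    add(m$marker, "primers_iupac",
        grepl(iupac, m$fwd_primer) && grepl(iupac, m$rev_primer))
    if (nzchar(m$reference_seq)) {
      add(m$marker, "reference_length",
          nchar(m$reference_seq) == m$amplicon_size,
          sprintf("ref %d bp vs declared %d", nchar(m$reference_seq),
                  m$amplicon_size))
    }
    cp <- panel$cpgs[panel$cpgs$marker == m$marker, ]
    if (nrow(cp)) {
      add(m$marker, "cpg_positions_in_span",
          all(cp$genomic_pos >= m$start & cp$genomic_pos <= m$end),
          sprintf("%d CpGs", nrow(cp)))
      add(m$marker, "cpg_offsets_in_amplicon",
          all(cp$amplicon_offset >= 0 & cp$amplicon_offset < m$amplicon_size))
      if (nzchar(m$reference_seq)) {
        ref <- strsplit(m$reference_seq, "")[[1]]
        at_c <- ref[cp$amplicon_offset + 1L] == "C"
        at_g <- ref[pmin(cp$amplicon_offset + 2L, length(ref))] == "G"
        add(m$marker, "cpg_dinucleotide_at_offset", all(at_c & at_g))
      }
    }
  }
  do.call(rbind, rows)
}

#' Census of target CpGs per marker
#'
#' @param panel A `panel_definition`.
#' @return A list with `per_marker` (named integer vector in marker order)
#'   and `total`. The bundled fixture totals 44.
#' @export
cpg_census <- function(panel) {
  stopifnot(inherits(panel, "panel_definition"))
  per <- vapply(panel$markers$marker,
                function(m) sum(panel$cpgs$marker == m), integer(1))
  list(per_marker = per, total = sum(per))
}

#' Bisulfite-collapse a reference sequence
#'
#' Converts an amplicon reference into the bisulfite read space used for read
#' assignment: a C at a target CpG offset becomes Y (methylation-dependent,
#' reads may carry C or T), every other C becomes T (assumed unmethylated and
#' converted), all other bases are unchanged.
#'
#' @param seq A DNA string over A/C/G/T.
#' @param cpg_offsets Integer vector of 0-based offsets of target CpG
#'   cytosines within `seq`.
#' @return A string of the same length over A/G/T/Y.
#' @export
collapse_reference <- function(seq, cpg_offsets = integer(0)) {
  stopifnot(is.character(seq), length(seq) == 1L)
  ch <- strsplit(seq, "")[[1]]
  if (!all(ch %in% c("A", "C", "G", "T"))) {
    stopf("reference contains non-ACGT base(s): %s",
          paste(unique(setdiff(ch, c("A", "C", "G", "T"))), collapse = ","))
  }
  idx <- as.integer(cpg_offsets) + 1L
  if (any(idx < 1L | idx > length(ch))) stopf("CpG offset outside sequence")
  is_c <- ch == "C"
  ch[is_c] <- "T"
  at_cpg <- intersect(idx, which(is_c))
  ch[at_cpg] <- "Y"
  paste(ch, collapse = "")
}

# Collapsed reference for every marker, in sequencing orientation.
#' Collapsed references for all panel markers
#' @param panel A `panel_definition` with non-empty `reference_seq`.
#' @return Named character vector (marker -> collapsed sequence over AGTY).
#' @export
collapsed_references <- function(panel) {
  stopifnot(inherits(panel, "panel_definition"))
  out <- vapply(seq_len(nrow(panel$markers)), function(i) {
    m <- panel$markers[i, ]
    if (!nzchar(m$reference_seq)) stopf("marker %s has no reference_seq", m$marker)
    offs <- panel$cpgs$amplicon_offset[panel$cpgs$marker == m$marker]
    collapse_reference(m$reference_seq, offs)
  }, character(1))
  names(out) <- panel$markers$marker
  out
}

#' Export collapsed references as FASTA
#'
#' One record per marker, sequencing orientation, alphabet A/G/T/Y.
#' @param panel A `panel_definition`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_collapsed_fasta <- function(panel, path) {
  refs <- collapsed_references(panel)
  set <- Biostrings::DNAStringSet(refs)
  Biostrings::writeXStringSet(set, filepath = path)
  invisible(path)
}

#' Generate a synthetic amplicon reference sequence
#'
#' Random DNA of a given length carrying a CpG dinucleotide exactly at each
#' requested 0-based offset and nowhere else, so that every other cytosine is
#' a non-CpG cytosine usable for bisulfite conversion QC.
#'
#' @param length Sequence length in bp.
#' @param cpg_offsets 0-based offsets of CpG cytosines (pairwise distance
#'   at least 2, at most `length - 2`).
#' @param seed Integer RNG seed.
#' @return A DNA string.
#' @export
synthetic_reference <- function(length, cpg_offsets = integer(0), seed = 1L) {
  stopifnot(is_count(length), length >= 2)
  offs <- sort(as.integer(cpg_offsets))
  if (any(offs < 0 | offs > length - 2)) stopf("CpG offset out of range")
  if (any(diff(offs) < 2)) stopf("CpG offsets overlap")
  with_seed(seed, {
    ch <- sample(c("A", "C", "G", "T"), length, replace = TRUE)
    ch[offs + 1L] <- "C"
    ch[offs + 2L] <- "G"
    # demote accidental CpGs: a G after a non-target C becomes A
    cg <- which(ch[-length] == "C" & ch[-1] == "G")
    cg <- setdiff(cg, offs + 1L)
    ch[cg + 1L] <- "A"
    paste(ch, collapse = "")
  })
}

#' Export panel CpG positions as BED
#'
#' Converts the panel's 1-based fully-closed CpG coordinates to 0-based
#' half-open BED intervals (one per CpG cytosine).
#' @param panel A `panel_definition`.
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
write_cpg_bed <- function(panel, path) {
  chrom <- panel$markers$chrom[match(panel$cpgs$marker, panel$markers$marker)]
  bed <- data.frame(chrom = chrom,
                    start = panel$cpgs$genomic_pos - 1L,
                    end = panel$cpgs$genomic_pos,
                    name = panel$cpgs$cpg_id)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
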