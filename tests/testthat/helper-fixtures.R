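# Hand-built alignment tibbles for fixture tests. Quality "D" is Phred 35.

Q35 <- "D"

test_read <- function(qname = "r1", contig = "chr1", pos = 0L, mapq = 60L,
                      cigar = "10M", seq = strrep("A", 10),
                      qual = strrep(Q35, nchar(seq)), tlen = 0L,
                      paired = TRUE, proper_pair = TRUE, unmapped = FALSE,
                      mate_unmapped = FALSE, reverse = FALSE,
                      mate_reverse = FALSE, first_in_pair = TRUE,
                      duplicate = FALSE) {
  spans <- ffpeqc:::cigar_spans(cigar, unmapped)
  tibble::tibble(
    qname = qname, contig = if (unmapped) NA_character_ else contig,
    pos = if (unmapped) NA_integer_ else as.integer(pos),
    mapq = as.integer(mapq), cigar = cigar, seq = seq, qual = qual,
    tlen = as.integer(tlen), paired = paired, proper_pair = proper_pair,
    unmapped = unmapped, mate_unmapped = mate_unmapped, reverse = reverse,
    mate_reverse = mate_reverse, first_in_pair = first_in_pair,
    duplicate = duplicate,
    left_clip = spans$left_clip, m_len = spans$m_len,
    right_clip = spans$right_clip)
}

test_reads <- function(..., contigs = c(chr1 = 1000L)) {
  reads <- dplyr::bind_rows(...)
  reads <- reads[order(reads$unmapped, reads$contig, reads$pos), ]
  attr(reads, "contigs") <- contigs
  class(reads) <- c("ffpeqc_reads", class(reads))
  reads
}

# a clean proper pair: mate1 forward at pos1, mate2 reverse, insert bp apart
test_pair <- function(qname, pos1, insert, read_len = 10L, contig = "chr1",
                      seq1 = strrep("A", min(read_len, insert)),
                      seq2 = strrep("A", min(read_len, insert)), ...) {
  m <- min(read_len, insert)
  dplyr::bind_rows(
    test_read(qname = qname, contig = contig, pos = pos1, seq = seq1,
              cigar = paste0(m, "M"), tlen = insert, first_in_pair = TRUE,
              mate_reverse = TRUE, ...),
    test_read(qname = qname, contig = contig, pos = pos1 + insert - m,
              seq = seq2, cigar = paste0(m, "M"), tlen = -insert,
              first_in_pair = FALSE, reverse = TRUE, ...))
}

# small deterministic library builders shared across test files
quick_config <- function(seed = 1, sample_type = "ffpe", ...) {
  defaults <- list(contig_length = 20000L, mean_depth = 30)
  do.call(sim_config, c(list(seed = seed, sample_type = sample_type),
                        utils::modifyList(defaults, list(...))))
}

quick_library <- function(seed = 1, sample_type = "ffpe", ...) {
  cfg <- quick_config(seed = seed, sample_type = sample_type, ...)
  g <- generate_reference(cfg)
  simulate_library(g, plant_variants(g, cfg), cfg)
}

# brute-force pileup oracle: per-read, per-base recount honoring all filters
naive_pileup <- function(reads, thresholds) {
  tall <- list()
  for (i in seq_len(nrow(reads))) {
    r <- reads[i, ]
    if (r$unmapped || r$duplicate || r$mapq < thresholds$min_mapq || r$m_len == 0) next
    for (k in seq_len(r$m_len)) {
      b <- substr(r$seq, r$left_clip + k, r$left_clip + k)
      q <- utf8ToInt(substr(r$qual, r$left_clip + k, r$left_clip + k)) - 33L
      if (q < thresholds$min_baseq || !b %in% c("A", "C", "G", "T")) next
      tall[[length(tall) + 1L]] <- tibble::tibble(
        contig = r$contig, pos = r$pos + k - 1L, base = b)
    }
  }
  if (!length(tall)) {
    return(tibble::tibble(contig = character(), pos = integer(),
                          A = integer(), C = integer(), G = integer(),
                          T = integer()))
  }
  df <- dplyr::bind_rows(tall)
  out <- dplyr::count(df, contig, pos, base)
  out <- tidyr::pivot_wider(out, names_from = "base", values_from = "n",
                            values_fill = 0L)
  for (b in c("A", "C", "G", "T")) if (is.null(out[[b]])) out[[b]] <- 0L
  dplyr::arrange(out[c("contig", "pos", "A", "C", "G", "T")], contig, pos)
}
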