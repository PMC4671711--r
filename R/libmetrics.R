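#' Insert-size distribution of properly paired reads
#'
#' Uses `|TLEN|` of properly paired reads, one contribution per pair (the
#' first-in-pair mate with positive `TLEN`). Discordant and unmapped reads are
#' excluded. FFPE libraries typically show medians around 100 bp against
#' 150-200 bp for frozen libraries.
#'
#' @param reads An alignment tibble.
#' @return An object of class `insert_summary`: list with `histogram`
#'   (tibble `insert`, `n`), `median`, `n_pairs`. With zero qualifying pairs,
#'   `n_pairs` is 0 and `median` is `NA` (an explicit empty-summary signal).
#' @export
insert_size_distribution <- function(reads) {
  sel <- reads$proper_pair & !reads$unmapped & reads$first_in_pair & reads$tlen > 0L
  ins <- reads$tlen[sel]
  if (!length(ins)) {
    return(structure(list(histogram = tibble(insert = integer(), n = integer()),
                          median = NA_real_, n_pairs = 0L),
                     class = "insert_summary"))
  }
  hist <- dplyr::count(tibble(insert = ins), .data$insert, name = "n")
  structure(list(histogram = hist, median = stats::median(ins),
                 n_pairs = length(ins)),
            class = "insert_summary")
}

#' @export
print.insert_summary <- function(x, ...) {
  cat(sprintf("<insert_summary> %d pairs, median insert %.0f bp\n",
              x$n_pairs, x$median))
  invisible(x)
}

#' Mate-overlap (double-sequenced) bases
#'
#' For each properly mapped pair, the overlap is the intersection of the two
#' mates' aligned (`M`) reference spans; soft clips shrink it. When the insert
#' is no longer than the read length the whole insert is sequenced twice.
#' By default the redundant copy is counted once and divided by all sequenced
#' bases of the pairs, so the fraction cannot exceed 0.5 and reads as "the
#' fraction of data that is redundant"; `denominator = "both"` counts both
#' copies instead.
#'
#' @param reads An alignment tibble.
#' @param read_length Optional nominal read length, recorded in the summary.
#' @param denominator `"once"` (default) or `"both"`.
#' @return An object of class `overlap_summary`: list with
#'   `total_sequenced_bases`, `overlap_bases`, `double_fraction`,
#'   `per_pair_overlaps` (tibble `overlap`, `n`), `n_pairs`,
#'   `n_unpaired_skipped`.
#' @export
double_sequenced <- function(reads, read_length = NULL,
                             denominator = c("once", "both")) {
  denominator <- match.arg(denominator)
  pr <- reads[reads$proper_pair & !reads$unmapped, ]
  first <- pr[pr$first_in_pair, ]
  second <- pr[!pr$first_in_pair, ]
  mate <- match(first$qname, second$qname)
  skipped <- sum(is.na(mate)) + nrow(second) - sum(!is.na(mate))
  ok <- !is.na(mate)
  f <- first[ok, ]
  s <- second[mate[ok], ]
  ov <- pmax(0L, pmin(f$pos + f$m_len, s$pos + s$m_len) - pmax(f$pos, s$pos))
  total <- sum(nchar(f$seq)) + sum(nchar(s$seq))
  mult <- if (denominator == "once") 1L else 2L
  structure(list(
    total_sequenced_bases = total,
    overlap_bases = sum(mult * ov),
    double_fraction = if (total > 0) sum(mult * ov) / total else NA_real_,
    per_pair_overlaps = dplyr::count(tibble(overlap = ov), .data$overlap, name = "n"),
    n_pairs = nrow(f),
    n_unpaired_skipped = skipped,
    denominator = denominator
  ), class = "overlap_summary")
}

#' @export
print.overlap_summary <- function(x, ...) {
  cat(sprintf("<overlap_summary> %d pairs: %.1f%% of sequenced bases double-sequenced (%s copies)\n",
              x$n_pairs, 100 * x$double_fraction,
              if (x$denominator == "once") "redundant" else "both"))
  invisible(x)
}

#' Soft-clip metrics over mapped reads
#'
#' Counts CIGAR `S` bases over mapped reads; unmapped reads are excluded from
#' numerator and denominator.
#'
#' @param reads An alignment tibble.
#' @return An object of class `softclip_summary`: list with `clipped_bases`,
#'   `total_bases_in_mapped_reads`, `clip_fraction`, `reads_with_clip`,
#'   `n_mapped_reads`.
#' @export
soft_clip_metrics <- function(reads) {
  m <- reads[!reads$unmapped, ]
  clipped <- sum(m$left_clip) + sum(m$right_clip)
  total <- sum(nchar(m$seq))
  structure(list(
    clipped_bases = clipped,
    total_bases_in_mapped_reads = total,
    clip_fraction = if (total > 0) clipped / total else NA_real_,
    reads_with_clip = sum(m$left_clip > 0L | m$right_clip > 0L),
    n_mapped_reads = nrow(m)
  ), class = "softclip_summary")
}

#' @export
print.softclip_summary <- function(x, ...) {
  cat(sprintf("<softclip_summary> %.1f%% of bases in %d mapped reads soft-clipped (%d reads with a clip)\n",
              100 * x$clip_fraction, x$n_mapped_reads, x$reads_with_clip))
  invisible(x)
}

#' Mapping-status counts and fractions
#'
#' Applies [classify_read()] to non-duplicate records; fractions are over
#' unique (non-duplicate) reads and sum to 1.
#'
#' @param reads An alignment tibble.
#' @return A tibble with `mapping_category`, `n`, `fraction`.
#' @export
mapping_stats <- function(reads) {
  r <- classify_read(reads[!reads$duplicate, ])
  out <- dplyr::count(r, .data$mapping_category, name = "n", .drop = FALSE)
  out$fraction <- if (sum(out$n) > 0) out$n / sum(out$n) else NA_real_
  out
}

#' Target-coverage summary
#'
#' Depth is computed from aligned (`M`) spans of mapped, non-duplicate reads.
#' Targets are merged internally; flanks are the 100 bp on each side of the
#' merged targets, target-excluded. Off-target aligned bases are those falling
#' in neither targets nor flanks. Short FFPE templates concentrate near the
#' capture probes, which lowers the off-target fraction relative to frozen
#' libraries.
#'
#' @param reads An alignment tibble.
#' @param targets Target tibble (`contig`, `start`, `end`, 0-based half-open),
#'   e.g. from [read_bed()].
#' @param flank Flank width in bp (default 100).
#' @return An object of class `coverage_summary`: list with
#'   `covered_target_fraction` (target bases with depth >= 1),
#'   `on_target_mean_depth`, `flanking_mean_depth`, `off_target_base_fraction`,
#'   plus the underlying base tallies (`target_bases`, `flank_bases`,
#'   `aligned_bases_on_target`, `aligned_bases_on_flank`,
#'   `aligned_bases_total`).
#' @export
target_coverage <- function(reads, targets, flank = 100L) {
  if (is.null(targets) || !nrow(targets)) abort("`targets` is empty: a non-empty BED is required")
  r <- reads[!reads$unmapped & !reads$duplicate & reads$m_len > 0L, ]
  tallies <- list(target_bases = 0, flank_bases = 0, covered_target = 0,
                  on_target = 0, on_flank = 0, total = sum(as.numeric(r$m_len)))
  for (cn in unique(targets$contig)) {
    tt <- targets[targets$contig == cn, ]
    tir <- IRanges::reduce(IRanges::IRanges(tt$start + 1L, tt$end))
    fir <- IRanges::setdiff(
      IRanges::reduce(IRanges::IRanges(pmax(1L, IRanges::start(tir) - flank),
                                       IRanges::end(tir) + flank)),
      tir)
    rc <- r[r$contig == cn & !is.na(r$contig), ]
    maxend <- max(c(IRanges::end(tir), IRanges::end(fir),
                    if (nrow(rc)) max(rc$pos + rc$m_len) else 0L))
    cov <- if (nrow(rc)) {
      IRanges::coverage(IRanges::IRanges(rc$pos + 1L, rc$pos + rc$m_len),
                        width = maxend)
    } else {
      S4Vectors::Rle(0L, maxend)
    }
    tallies$target_bases <- tallies$target_bases + sum(IRanges::width(tir))
    tallies$flank_bases <- tallies$flank_bases + sum(IRanges::width(fir))
    tallies$on_target <- tallies$on_target + sum(sum(IRanges::Views(cov, tir)))
    if (length(fir)) {
      tallies$on_flank <- tallies$on_flank + sum(sum(IRanges::Views(cov, fir)))
    }
    tallies$covered_target <- tallies$covered_target +
      sum(sum(IRanges::Views(cov > 0L, tir)))
  }
  structure(list(
    covered_target_fraction = tallies$covered_target / tallies$target_bases,
    on_target_mean_depth = tallies$on_target / tallies$target_bases,
    flanking_mean_depth = if (tallies$flank_bases > 0)
      tallies$on_flank / tallies$flank_bases else NA_real_,
    off_target_base_fraction = if (tallies$total > 0)
      (tallies$total - tallies$on_target - tallies$on_flank) / tallies$total
    else NA_real_,
    target_bases = tallies$target_bases,
    flank_bases = tallies$flank_bases,
    aligned_bases_on_target = tallies$on_target,
    aligned_bases_on_flank = tallies$on_flank,
    aligned_bases_total = tallies$total,
    flank = flank
  ), class = "coverage_summary")
}

#' @export
print.coverage_summary <- function(x, ...) {
  cat(sprintf("<coverage_summary> %.1f%% of target covered, %.1fx on-target, %.1fx flanking, %.1f%% off-target bases\n",
              100 * x$covered_target_fraction, x$on_target_mean_depth,
              x$flanking_mean_depth, 100 * x$off_target_base_fraction))
  invisible(x)
}

#' Base-quality histograms by mapping status
#'
#' Tallies Phred base qualities separately for mapped and unmapped reads,
#' normalizes each histogram, and reports the fractions of bases at Q >= 30
#' and Q <= 20. In blood/frozen libraries the unmapped reads typically carry a
#' heavier low-quality tail; in FFPE libraries mapping failure is also driven
#' by fixation-induced base alterations, so the contrast is attenuated.
#'
#' @param reads An alignment tibble.
#' @return An object of class `quality_summary`: list with `histogram`
#'   (tibble `status`, `quality`, `n`, `freq`) and `summary` (tibble `status`,
#'   `n_bases`, `frac_ge_q30`, `frac_le_q20`).
#' @export
quality_by_mapping_status <- function(reads) {
  status <- ifelse(reads$unmapped, "unmapped", "mapped")
  lens <- nchar(reads$qual)
  q <- qual_ints(reads$qual)
  st <- rep(status, lens)
  hist <- dplyr::count(tibble(status = st, quality = q),
                       .data$status, .data$quality, name = "n")
  hist <- dplyr::mutate(dplyr::group_by(hist, .data$status),
                        freq = .data$n / sum(.data$n))
  hist <- dplyr::ungroup(hist)
  summ <- dplyr::summarise(
    dplyr::group_by(hist, .data$status),
    n_bases = sum(.data$n),
    frac_ge_q30 = sum(.data$n[.data$quality >= 30L]) / sum(.data$n),
    frac_le_q20 = sum(.data$n[.data$quality <= 20L]) / sum(.data$n))
  structure(list(histogram = hist, summary = summ), class = "quality_summary")
}

#' @export
print.quality_summary <- function(x, ...) {
  print(x$summary)
  invisible(x)
}
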