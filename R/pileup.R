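#' Quality-filter thresholds for pileups and site selection
#'
#' The two regimes used throughout are the lenient site-defining filter
#' (mapping and base quality >= 20, depth >= 50) and the stringent
#' discrepancy-counting filter (mapping quality >= 60, base quality >= 30,
#' no depth requirement).
#'
#' @param min_mapq Minimum mapping quality for a read to contribute.
#' @param min_baseq Minimum Phred base quality for a base to contribute.
#' @param min_depth Minimum depth for a column to count as adequately covered
#'   (columns below it are emitted but flagged).
#' @return An object of class `filter_thresholds`.
#' @examples
#' lenient_thresholds()
#' stringent_thresholds()
#' @export
filter_thresholds <- function(min_mapq = 20L, min_baseq = 20L, min_depth = 0L) {
  stopifnot(min_mapq >= 0, min_baseq >= 0, min_depth >= 0)
  structure(list(min_mapq = as.integer(min_mapq),
                 min_baseq = as.integer(min_baseq),
                 min_depth = as.integer(min_depth)),
            class = "filter_thresholds")
}

#' @rdname filter_thresholds
#' @export
lenient_thresholds <- function() filter_thresholds(20L, 20L, 50L)

#' @rdname filter_thresholds
#' @export
stringent_thresholds <- function() filter_thresholds(60L, 30L, 0L)

#' @export
print.filter_thresholds <- function(x, ...) {
  cat(sprintf("<filter_thresholds> MQ >= %d, BQ >= %d, depth >= %d\n",
              x$min_mapq, x$min_baseq, x$min_depth))
  invisible(x)
}

#' Build quality-filtered pileup columns
#'
#' Tallies aligned bases per reference position, stratified by the active
#' thresholds: a base contributes to column `(contig, pos)` iff its read is
#' mapped, not a duplicate, has `mapq >= min_mapq`, the base quality is
#' `>= min_baseq`, and the CIGAR places it in the aligned (`M`) block over
#' that position. Soft-clipped bases never contribute. Both mates of an
#' overlapping pair contribute independently by default (`mode = "mates"`:
#' every sequenced base counted once, the naive regime in which
#' double-sequencing inflates allele evidence); `mode = "fragment"` counts
#' each template position once per fragment, keeping a random mate's base, to
#' quantify that inflation.
#'
#' @param reads A coordinate-sorted alignment tibble.
#' @param thresholds A [filter_thresholds()].
#' @param region Optional `"contig:start-end"` string (1-based inclusive) or
#'   tibble with `contig`, `start`, `end` (0-based half-open) restricting the
#'   output.
#' @param mode `"mates"` (default) or `"fragment"` (see above).
#' @return A tibble of class `ffpeqc_pileup` with columns `contig`, `pos`
#'   (0-based), `A`, `C`, `G`, `T`, `depth`, `consensus` (`NA` on ties) and
#'   `below_min_depth`; only covered columns (depth >= 1) are emitted.
#'   Attributes `thresholds` and `mode` record how it was built.
#' @examples
#' cfg <- sim_config(seed = 1, contig_length = 2000, mean_depth = 8)
#' g <- generate_reference(cfg)
#' lib <- simulate_library(g, plant_variants(g, cfg), cfg)
#' pu <- pileup(lib$reads, filter_thresholds(20, 20, 5))
#' head(pu)
#' @export
pileup <- function(reads, thresholds = filter_thresholds(),
                   region = NULL, mode = c("mates", "fragment")) {
  mode <- match.arg(mode)
  stopifnot(inherits(thresholds, "filter_thresholds"))
  use <- !reads$unmapped & !reads$duplicate &
    reads$mapq >= thresholds$min_mapq & reads$m_len > 0L
  r <- reads[use, ]
  # require coordinate order within contig among the reads used
  if (nrow(r) > 1) {
    by_contig <- split(r$pos, r$contig)
    if (any(vapply(by_contig, is.unsorted, logical(1)))) {
      abort("reads must be coordinate-sorted; sort them (e.g. with write_sam()) first")
    }
  }
  cols <- purrr::map_dfr(unique(r$contig), function(cn) {
    rc <- r[r$contig == cn, ]
    m <- rc$m_len
    nb <- sum(m)
    if (!nb) return(NULL)
    refpos <- rep(rc$pos, m) + (sequence(m) - 1L)
    qoff <- rep(rc$left_clip, m) + sequence(m)
    lens <- nchar(rc$seq)
    goff <- rep(cumsum(lens) - lens, m) + qoff
    codes <- base_codes(rc$seq)[goff]
    q <- qual_ints(rc$qual)[goff]
    keep <- q >= thresholds$min_baseq & !is.na(codes) & codes > 0L
    refpos <- refpos[keep]
    codes <- codes[keep]
    if (mode == "fragment") {
      pair_id <- rep(match(rc$qname, unique(rc$qname)), m)[keep]
      ord <- sample.int(length(refpos))
      key <- paste0(pair_id[ord], ":", refpos[ord])
      sel <- ord[!duplicated(key)]
      refpos <- refpos[sel]
      codes <- codes[sel]
    }
    if (!length(refpos)) return(NULL)
    L <- max(refpos) + 1L
    tab <- tabulate(refpos * 4L + codes, nbins = 4L * L)
    cmat <- matrix(tab, nrow = 4L)
    covered <- which(colSums(cmat) > 0L)
    cm <- cmat[, covered, drop = FALSE]
    depth <- colSums(cm)
    mx <- pmax(cm[1L, ], cm[2L, ], cm[3L, ], cm[4L, ])
    n_at_max <- colSums(cm == rep(mx, each = 4L))
    consensus <- ifelse(n_at_max == 1L,
                        BASES[max.col(t(cm), ties.method = "first")],
                        NA_character_)
    tibble(contig = cn, pos = covered - 1L,
           A = cm[1L, ], C = cm[2L, ], G = cm[3L, ], T = cm[4L, ],
           depth = as.integer(depth), consensus = consensus,
           below_min_depth = depth < thresholds$min_depth)
  })
  if (is.null(cols) || !nrow(cols)) {
    cols <- tibble(contig = character(), pos = integer(), A = integer(),
                   C = integer(), G = integer(), T = integer(),
                   depth = integer(), consensus = character(),
                   below_min_depth = logical())
  }
  if (!is.null(region)) cols <- restrict_region(cols, region)
  attr(cols, "thresholds") <- thresholds
  attr(cols, "mode") <- mode
  class(cols) <- c("ffpeqc_pileup", class(cols))
  cols
}

#' @noRd
restrict_region <- function(cols, region) {
  if (is.character(region) && length(region) == 1L) {
    m <- stringr::str_match(region, "^([^:]+):([0-9]+)-([0-9]+)$")
    if (is.na(m[1, 1])) abort(sprintf("cannot parse region \"%s\" (expected contig:start-end, 1-based inclusive)", region))
    region <- tibble(contig = m[1, 2],
                     start = as.integer(m[1, 3]) - 1L,
                     end = as.integer(m[1, 4]))
  }
  keep <- rep(FALSE, nrow(cols))
  for (i in seq_len(nrow(region))) {
    keep <- keep | (cols$contig == region$contig[i] &
                      cols$pos >= region$start[i] & cols$pos < region$end[i])
  }
  cols[keep, ]
}
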