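#' Read a plain-text SAM file into an alignment tibble
#'
#' Parses the eleven mandatory SAM columns into the package's alignment
#' layout: one row per alignment line with decoded flag fields and
#' pre-computed CIGAR spans. Only `M` and `S` CIGAR operations are supported
#' (the downstream analyses are SNV-only); any other operation is rejected by
#' name. Soft clips may flank a single aligned block (`xS yM zS`).
#'
#' @param path Path to a headered SAM file.
#' @return A tibble of class `ffpeqc_reads` with columns `qname`, `contig`
#'   (`NA` for unmapped), `pos` (0-based leftmost aligned position), `mapq`,
#'   `cigar`, `seq`, `qual` (Phred+33 string), `tlen`, decoded flags
#'   (`paired`, `proper_pair`, `unmapped`, `mate_unmapped`, `reverse`,
#'   `mate_reverse`, `first_in_pair`, `duplicate`) and CIGAR spans
#'   (`left_clip`, `m_len`, `right_clip`). Attribute `contigs`: named integer
#'   vector of reference lengths from the header.
#' @examples
#' \dontrun{
#' reads <- read_alignments("library.sam")
#' }
#' @export
read_alignments <- function(path) {
  if (!file.exists(path)) abort(sprintf("SAM file not found: %s", path))
  lines <- readLines(path)
  is_hdr <- startsWith(lines, "@")
  if (!any(is_hdr)) abort(sprintf("%s: missing SAM header", path))
  sq <- lines[is_hdr][startsWith(lines[is_hdr], "@SQ")]
  contigs <- integer(0)
  if (length(sq)) {
    sn <- stringr::str_match(sq, "SN:([^\t]+)")[, 2]
    ln <- as.integer(stringr::str_match(sq, "LN:([0-9]+)")[, 2])
    contigs <- stats::setNames(ln, sn)
  }
  aln <- lines[!is_hdr]
  lineno <- which(!is_hdr)
  if (!length(aln)) {
    return(empty_reads(contigs))
  }
  fields <- strsplit(aln, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 11L)) {
    bad <- which(nf < 11L)[1]
    abort(sprintf("%s: malformed SAM line %d (%d fields, expected >= 11)",
                  path, lineno[bad], nf[bad]))
  }
  off <- cumsum(c(0L, nf[-length(nf)]))
  v <- unlist(fields, use.names = FALSE)
  flag <- suppressWarnings(as.integer(v[off + 2L]))
  pos1 <- suppressWarnings(as.integer(v[off + 4L]))
  mapq <- suppressWarnings(as.integer(v[off + 5L]))
  tlen <- suppressWarnings(as.integer(v[off + 9L]))
  if (anyNA(flag) || anyNA(pos1) || anyNA(mapq) || anyNA(tlen)) {
    bad <- which(is.na(flag) | is.na(pos1) | is.na(mapq) | is.na(tlen))[1]
    abort(sprintf("%s: malformed SAM line %d (non-numeric FLAG/POS/MAPQ/TLEN)",
                  path, lineno[bad]))
  }
  rname <- v[off + 3L]
  cigar <- v[off + 6L]
  seq <- v[off + 10L]
  qual <- v[off + 11L]
  unmapped <- bitwAnd(flag, 4L) > 0L

  spans <- cigar_spans(cigar, unmapped, path, lineno)
  bad_len <- !unmapped &
    (spans$left_clip + spans$m_len + spans$right_clip) != nchar(seq)
  if (any(bad_len)) {
    b <- which(bad_len)[1]
    abort(sprintf("%s: line %d: CIGAR length (%s) does not match sequence length %d",
                  path, lineno[b], cigar[b], nchar(seq[b])))
  }
  reads <- tibble(
    qname = v[off + 1L],
    contig = ifelse(unmapped | rname == "*", NA_character_, rname),
    pos = ifelse(unmapped, NA_integer_, pos1 - 1L),
    mapq = mapq,
    cigar = cigar,
    seq = seq,
    qual = qual,
    tlen = tlen,
    paired = bitwAnd(flag, 1L) > 0L,
    proper_pair = bitwAnd(flag, 2L) > 0L,
    unmapped = unmapped,
    mate_unmapped = bitwAnd(flag, 8L) > 0L,
    reverse = bitwAnd(flag, 16L) > 0L,
    mate_reverse = bitwAnd(flag, 32L) > 0L,
    first_in_pair = bitwAnd(flag, 64L) > 0L,
    duplicate = bitwAnd(flag, 1024L) > 0L,
    left_clip = spans$left_clip,
    m_len = spans$m_len,
    right_clip = spans$right_clip
  )
  attr(reads, "contigs") <- contigs
  class(reads) <- c("ffpeqc_reads", class(reads))
  reads
}

#' @noRd
empty_reads <- function(contigs = integer(0)) {
  reads <- tibble(
    qname = character(), contig = character(), pos = integer(),
    mapq = integer(), cigar = character(), seq = character(),
    qual = character(), tlen = integer(), paired = logical(),
    proper_pair = logical(), unmapped = logical(), mate_unmapped = logical(),
    reverse = logical(), mate_reverse = logical(), first_in_pair = logical(),
    duplicate = logical(), left_clip = integer(), m_len = integer(),
    right_clip = integer())
  attr(reads, "contigs") <- contigs
  class(reads) <- c("ffpeqc_reads", class(reads))
  reads
}

# Decompose CIGARs of the form [nS] nM [nS] (or "*" for unmapped) into spans.
# Any operation other than M/S is rejected by name.
#' @noRd
cigar_spans <- function(cigar, unmapped, path = "<input>", lineno = seq_along(cigar)) {
  left_clip <- integer(length(cigar))
  m_len <- integer(length(cigar))
  right_clip <- integer(length(cigar))
  todo <- !(unmapped & cigar == "*")
  if (any(todo)) {
    mm <- stringr::str_match(
      cigar[todo], "^(?:([0-9]+)S)?([0-9]+)M(?:([0-9]+)S)?$")
    bad <- is.na(mm[, 1])
    if (any(bad)) {
      b <- which(todo)[which(bad)[1]]
      ops <- stringr::str_match_all(cigar[b], "[0-9]+([A-Za-z=])")[[1]][, 2]
      unsupported <- setdiff(ops, c("M", "S"))
      if (length(unsupported)) {
        abort(sprintf("%s: line %d: unsupported CIGAR operation \"%s\" in \"%s\" (only M and S are supported)",
                      path, lineno[b], unsupported[1], cigar[b]))
      }
      abort(sprintf("%s: line %d: cannot parse CIGAR \"%s\" (expected [nS]nM[nS])",
                    path, lineno[b], cigar[b]))
    }
    lc <- as.integer(mm[, 2]); lc[is.na(lc)] <- 0L
    rc <- as.integer(mm[, 4]); rc[is.na(rc)] <- 0L
    left_clip[todo] <- lc
    m_len[todo] <- as.integer(mm[, 3])
    right_clip[todo] <- rc
  }
  list(left_clip = left_clip, m_len = m_len, right_clip = right_clip)
}

#' Write an alignment tibble as a coordinate-sorted SAM file
#'
#' Emits a headered SAM with `@SQ` lines from the `contigs` attribute (or the
#' `contigs` argument), mapped reads sorted by coordinate and unmapped reads
#' at the end. Mate fields (`RNEXT`/`PNEXT`) are reconstructed by pairing
#' reads on `qname`.
#'
#' @param reads An alignment tibble.
#' @param path Output path.
#' @param contigs Named integer vector of contig lengths; defaults to the
#'   tibble's `contigs` attribute.
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, path, contigs = NULL) {
  contigs <- contigs %||% attr(reads, "contigs")
  if (is.null(contigs)) abort("contig lengths are required to write a SAM header")
  reads <- sort_reads(reads)
  flag <- 0L +
    1L * reads$paired + 2L * reads$proper_pair + 4L * reads$unmapped +
    8L * reads$mate_unmapped + 16L * reads$reverse + 32L * reads$mate_reverse +
    64L * reads$first_in_pair + 128L * (reads$paired & !reads$first_in_pair) +
    1024L * reads$duplicate
  # mate coordinates via qname pairing
  key <- paste0(reads$qname, "/", ifelse(reads$first_in_pair, 2L, 1L))
  mate <- match(key, paste0(reads$qname, "/", ifelse(reads$first_in_pair, 1L, 2L)))
  mate_contig <- reads$contig[mate]
  mate_pos <- reads$pos[mate]
  rnext <- dplyr::case_when(
    !reads$paired | is.na(mate) | is.na(mate_contig) ~ "*",
    mate_contig == reads$contig & !is.na(reads$contig) ~ "=",
    TRUE ~ mate_contig)
  pnext <- ifelse(is.na(mate) | is.na(mate_pos), 0L, mate_pos + 1L)
  lines <- paste(
    reads$qname, flag,
    ifelse(is.na(reads$contig), "*", reads$contig),
    ifelse(is.na(reads$pos), 0L, reads$pos + 1L),
    reads$mapq, reads$cigar, rnext, pnext, reads$tlen, reads$seq, reads$qual,
    sep = "\t")
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(contigs), contigs),
           "@PG\tID:ffpeqc\tPN:ffpeqc")
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Classify reads by mapping status
#'
#' Adds a `mapping_category` column: `unmapped` (unmapped flag set),
#' `properly_paired` (mapped with the proper-pair flag), or `discordant`
#' (mapped without it). The categories are exhaustive and disjoint.
#'
#' @param reads An alignment tibble.
#' @return The tibble with a `mapping_category` factor column.
#' @export
classify_read <- function(reads) {
  reads$mapping_category <- factor(
    dplyr::case_when(
      reads$unmapped ~ "unmapped",
      reads$proper_pair ~ "properly_paired",
      TRUE ~ "discordant"),
    levels = c("properly_paired", "discordant", "unmapped"))
  reads
}

#' Flag duplicate reads
#'
#' Among mapped reads sharing `(contig, pos, strand, tlen)`, all but the read
#' with the highest mean base quality are flagged as duplicates (ties broken
#' by input order). Unmapped reads are never flagged.
#'
#' @param reads A coordinate-sorted alignment tibble.
#' @return The tibble with the `duplicate` column updated.
#' @export
mark_duplicates <- function(reads) {
  if (!nrow(reads)) return(reads)
  mapped <- which(!reads$unmapped)
  if (!length(mapped)) return(reads)
  lens <- nchar(reads$qual[mapped])
  q <- qual_ints(reads$qual[mapped])
  grp <- rep(seq_along(mapped), lens)
  meanq <- as.vector(rowsum(as.numeric(q), grp)) / lens
  key <- paste(reads$contig[mapped], reads$pos[mapped],
               reads$reverse[mapped], reads$tlen[mapped], sep = ":")
  ord <- order(key, -meanq)
  dup_sorted <- duplicated(key[ord])
  dup <- logical(length(mapped))
  dup[ord] <- dup_sorted
  reads$duplicate[mapped] <- dup
  reads
}
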