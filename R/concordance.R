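#' Minimal tumor-normal LOD somatic caller
#'
#' A deliberately small Bayesian-classifier-style caller used as plumbing for
#' concordance analyses (external call sets with a LOD annotation can be
#' ingested instead via [read_calls_vcf()]). At each site covered in both
#' pileups, the reference allele is the normal sample's consensus; for every
#' alternate allele seen in the tumor the evidence is scored as
#' \deqn{LOD_T = \log_{10} \frac{L(k \mid f = k/n)}{L(k \mid f = 0)}}
#' with a binomial read model in which an alt read arises with probability
#' `f (1 - e) + (1 - f) e/3` under allele fraction `f` and `e/3` under the
#' null, `e` being the per-base miscall rate. A site is emitted when
#' `LOD_T >= lod_threshold` and the normal pileup's alt count is consistent
#' with absence (one-sided binomial test against `e/3` at level `alpha`).
#'
#' @param tumor_columns,normal_columns `ffpeqc_pileup`s over the same region
#'   (typically built with the stringent thresholds, which approximates
#'   artifact-masking caller filters).
#' @param error_rate Per-base miscall probability `e`.
#' @param lod_threshold Emission threshold (default 6.3).
#' @param alpha Level of the normal-consistency test (default 0.01).
#' @return A tibble of class `ffpeqc_calls`: `contig`, `pos` (0-based),
#'   `ref`, `alt`, `lod_t`, `alt_count`, `depth`, `normal_alt_count`,
#'   `normal_depth`.
#' @export
call_somatic_minimal <- function(tumor_columns, normal_columns,
                                 error_rate = 1e-3, lod_threshold = 6.3,
                                 alpha = 0.01) {
  stopifnot(inherits(tumor_columns, "ffpeqc_pileup"),
            inherits(normal_columns, "ffpeqc_pileup"))
  nm <- as_tibble(normal_columns)[c("contig", "pos", "A", "C", "G", "T",
                                    "depth", "consensus")]
  names(nm) <- c("contig", "pos", "nA", "nC", "nG", "nT", "n_depth", "ref")
  j <- dplyr::inner_join(as_tibble(tumor_columns), nm, by = c("contig", "pos"))
  j <- j[!is.na(j$ref) & j$depth > 0L, ]
  if (!nrow(j)) return(empty_calls())
  calls <- purrr::map_dfr(BASES, function(alt) {
    rows <- j[j$ref != alt & j[[alt]] > 0L, ]
    if (!nrow(rows)) return(NULL)
    k <- rows[[alt]]
    n <- rows$depth
    lod <- lod_t_score(k, n, error_rate)
    kn <- rows[[paste0("n", alt)]]
    nn <- rows$n_depth
    # one-sided binomial evidence that the normal carries the allele
    p_normal <- pbinom(kn - 1L, nn, error_rate / 3, lower.tail = FALSE)
    keep <- lod >= lod_threshold & p_normal > alpha
    tibble(contig = rows$contig[keep], pos = rows$pos[keep],
           ref = rows$ref[keep], alt = alt, lod_t = lod[keep],
           alt_count = k[keep], depth = n[keep],
           normal_alt_count = kn[keep], normal_depth = nn[keep])
  })
  if (is.null(calls) || !nrow(calls)) return(empty_calls())
  calls <- dplyr::arrange(calls, .data$contig, .data$pos, .data$alt)
  class(calls) <- c("ffpeqc_calls", class(calls))
  calls
}

#' @noRd
lod_t_score <- function(k, n, error_rate) {
  f <- k / n
  p1 <- f * (1 - error_rate) + (1 - f) * error_rate / 3
  p0 <- error_rate / 3
  (dbinom(k, n, p1, log = TRUE) - dbinom(k, n, p0, log = TRUE)) / log(10)
}

#' @noRd
empty_calls <- function() {
  calls <- tibble(contig = character(), pos = integer(), ref = character(),
                  alt = character(), lod_t = double(), alt_count = integer(),
                  depth = integer(), normal_alt_count = integer(),
                  normal_depth = integer())
  class(calls) <- c("ffpeqc_calls", class(calls))
  calls
}

#' Concordance sweep over LOD thresholds
#'
#' At each cutoff `t`, both call sets are restricted to `lod_t >= t`; the
#' overlap is keyed on `(contig, pos, ref, alt)` and the overlap fraction is
#' `n_overlap / n_frozen` (the frozen-call denominator). A zero denominator
#' yields an `NA` fraction, flagged in `undefined`.
#'
#' @param calls_ffpe,calls_frozen `ffpeqc_calls` tibbles on the same
#'   coordinate system.
#' @param thresholds Ascending LOD cutoffs; the default grid spans 6.3-250.
#' @return A tibble of class `concordance_curve`: `threshold`, `n_ffpe`,
#'   `n_frozen`, `n_overlap`, `overlap_fraction`, `undefined`; attributes
#'   `mode = "strict"` and `denominator = "frozen"`.
#' @export
sweep_concordance <- function(calls_ffpe, calls_frozen,
                              thresholds = c(6.3, 10, 20, 30, 50, 100, 150, 200, 250)) {
  key <- c("contig", "pos", "ref", "alt")
  curve <- purrr::map_dfr(sort(thresholds), function(t) {
    fa <- calls_ffpe[calls_ffpe$lod_t >= t, ]
    fr <- calls_frozen[calls_frozen$lod_t >= t, ]
    ov <- nrow(dplyr::inner_join(as_tibble(fa)[key], as_tibble(fr)[key], by = key))
    tibble(threshold = t, n_ffpe = nrow(fa), n_frozen = nrow(fr),
           n_overlap = ov,
           overlap_fraction = if (nrow(fr) > 0) ov / nrow(fr) else NA_real_,
           undefined = nrow(fr) == 0L)
  })
  attr(curve, "mode") <- "strict"
  attr(curve, "denominator") <- "frozen"
  class(curve) <- c("concordance_curve", class(curve))
  curve
}

#' Concordance with one-supporting-read rescue
#'
#' An FFPE call counts as concordant at threshold `t` if it appears in the
#' frozen call set at `t` *or* the frozen pileup shows at least one passing
#' alternate-allele base at the site. The fraction is over FFPE calls at `t`
#' (the FFPE-call denominator), and the rescue curve dominates the strict
#' curve pointwise. Call positions absent from the frozen pileup are counted
#' unsupported (their number is recorded in the `n_positions_missing`
#' attribute).
#'
#' @param calls_ffpe,calls_frozen `ffpeqc_calls` tibbles.
#' @param frozen_columns `ffpeqc_pileup` of the frozen sample covering the
#'   FFPE call positions.
#' @param thresholds Ascending LOD cutoffs.
#' @return A tibble of class `concordance_curve` with `mode = "rescue"`,
#'   `denominator = "ffpe"`.
#' @export
rescue_by_read_support <- function(calls_ffpe, calls_frozen, frozen_columns,
                                   thresholds = c(6.3, 10, 20, 30, 50, 100, 150, 200, 250)) {
  stopifnot(inherits(frozen_columns, "ffpeqc_pileup"))
  key <- c("contig", "pos", "ref", "alt")
  pu <- as_tibble(frozen_columns)[c("contig", "pos", "A", "C", "G", "T")]
  withpu <- dplyr::left_join(as_tibble(calls_ffpe)[c("contig", "pos", "alt")],
                             pu, by = c("contig", "pos"))
  cm <- as.matrix(withpu[c("A", "C", "G", "T")])
  alt_count <- cm[cbind(seq_len(nrow(withpu)), match(withpu$alt, BASES))]
  missing_pos <- is.na(withpu$A)
  alt_count[is.na(alt_count)] <- 0L
  supported <- alt_count >= 1L
  curve <- purrr::map_dfr(sort(thresholds), function(t) {
    sel <- calls_ffpe$lod_t >= t
    fa <- calls_ffpe[sel, ]
    fr <- calls_frozen[calls_frozen$lod_t >= t, ]
    in_frozen <- !is.na(vctrs_match(as_tibble(fa)[key], as_tibble(fr)[key]))
    conc <- sum(in_frozen | supported[sel])
    tibble(threshold = t, n_ffpe = nrow(fa), n_frozen = nrow(fr),
           n_overlap = conc,
           overlap_fraction = if (nrow(fa) > 0) conc / nrow(fa) else NA_real_,
           undefined = nrow(fa) == 0L)
  })
  attr(curve, "mode") <- "rescue"
  attr(curve, "denominator") <- "ffpe"
  attr(curve, "n_positions_missing") <- sum(missing_pos)
  class(curve) <- c("concordance_curve", class(curve))
  curve
}

# row-wise match of two key data frames
#' @noRd
vctrs_match <- function(x, table) {
  kx <- do.call(paste, c(x, sep = "\r"))
  kt <- do.call(paste, c(table, sep = "\r"))
  match(kx, kt)
}

#' @export
print.concordance_curve <- function(x, ...) {
  cat(sprintf("<concordance_curve: %s> overlap fraction over %s calls\n",
              attr(x, "mode") %||% "?", attr(x, "denominator") %||% "?"))
  print(as_tibble(x))
  invisible(x)
}

#' Write somatic calls as VCF 4.2
#'
#' Emits a minimal VCF with the LOD score, allele counts and depth in INFO.
#'
#' @param calls An `ffpeqc_calls` tibble.
#' @param path Output path.
#' @param lod_field INFO key used for the LOD score (default `TLOD`).
#' @param contigs Optional named integer vector of contig lengths for
#'   `##contig` header lines.
#' @return `path`, invisibly.
#' @export
write_calls_vcf <- function(calls, path, lod_field = "TLOD", contigs = NULL) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##INFO=<ID=%s,Number=1,Type=Float,Description=\"Tumor log odds score\">", lod_field),
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Tumor depth\">",
    "##INFO=<ID=AC,Number=1,Type=Integer,Description=\"Tumor alt read count\">",
    if (!is.null(contigs)) sprintf("##contig=<ID=%s,length=%d>", names(contigs), contigs),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  lines <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s=%.4f;DP=%d;AC=%d",
                   calls$contig, calls$pos + 1L, calls$ref, calls$alt,
                   lod_field, calls$lod_t, calls$depth, calls$alt_count)
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Read a VCF call set with a LOD annotation
#'
#' Ingests SNV records from a VCF (e.g. an external caller's output) into the
#' package's call-set layout, taking the confidence score from the given INFO
#' field. Non-SNV records are dropped with a message.
#'
#' @param path VCF path.
#' @param lod_field INFO key holding the LOD score (default `TLOD`).
#' @return An `ffpeqc_calls` tibble (0-based `pos`; `alt_count`/`depth` from
#'   `AC`/`DP` INFO fields when present, else `NA`).
#' @export
read_calls_vcf <- function(path, lod_field = "TLOD") {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (nrow(v@fix) == 0L) return(empty_calls())
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  lod <- suppressWarnings(as.numeric(vcfR::extract.info(v, lod_field)))
  dp <- suppressWarnings(as.integer(vcfR::extract.info(v, "DP")))
  ac <- suppressWarnings(as.integer(vcfR::extract.info(v, "AC")))
  snv <- nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    fix$REF %in% BASES & fix$ALT %in% BASES
  if (any(!snv)) message(sum(!snv), " non-SNV record(s) dropped from ", path)
  calls <- tibble(contig = fix$CHROM[snv],
                  pos = as.integer(fix$POS[snv]) - 1L,
                  ref = fix$REF[snv], alt = fix$ALT[snv],
                  lod_t = lod[snv],
                  alt_count = if (length(ac)) ac[snv] else NA_integer_,
                  depth = if (length(dp)) dp[snv] else NA_integer_,
                  normal_alt_count = NA_integer_, normal_depth = NA_integer_)
  if (anyNA(calls$lod_t)) {
    abort(sprintf("INFO field \"%s\" missing or non-numeric in %s", lod_field, path))
  }
  class(calls) <- c("ffpeqc_calls", class(calls))
  calls
}
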