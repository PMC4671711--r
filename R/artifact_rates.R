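SUBSTITUTION_CLASSES <- {
  g <- expand.grid(alt = BASES, ref = BASES, stringsAsFactors = FALSE)
  g <- g[g$ref != g$alt, c("ref", "alt")]
  g <- g[order(g$ref, g$alt), ]
  paste0(g$ref, ">", g$alt)
}

#' Select homozygous sites from a lenient pileup
#'
#' A site enters the set iff its column reached `min_depth` (default 50) and
#' shows exactly one allele — any second allele, however rare, excludes it.
#' The pileup must have been built with the same mapping/base-quality
#' thresholds (the lenient site-defining regime, MQ/BQ >= 20), so that rare
#' true second alleles are not filtered away before the single-allele test.
#'
#' @param columns An `ffpeqc_pileup`.
#' @param thresholds The [filter_thresholds()] the pileup was built with
#'   (checked against the pileup's record; mismatch is an error).
#' @return A tibble of class `ffpeqc_hom_sites` with `contig`, `pos`,
#'   `allele`; attribute `thresholds`.
#' @export
find_homozygous_sites <- function(columns, thresholds = lenient_thresholds()) {
  stopifnot(inherits(columns, "ffpeqc_pileup"))
  built <- attr(columns, "thresholds")
  if (built$min_mapq != thresholds$min_mapq ||
      built$min_baseq != thresholds$min_baseq) {
    abort(sprintf(
      "pileup was built with MQ >= %d / BQ >= %d but thresholds specify MQ >= %d / BQ >= %d; rebuild the pileup with matching thresholds",
      built$min_mapq, built$min_baseq, thresholds$min_mapq, thresholds$min_baseq))
  }
  cm <- cbind(columns$A, columns$C, columns$G, columns$T)
  n_alleles <- rowSums(cm > 0L)
  keep <- columns$depth >= thresholds$min_depth & n_alleles == 1L
  sites <- tibble(contig = columns$contig[keep], pos = columns$pos[keep],
                  allele = columns$consensus[keep])
  attr(sites, "thresholds") <- thresholds
  class(sites) <- c("ffpeqc_hom_sites", class(sites))
  sites
}

#' Count discrepant bases over a homozygous site set
#'
#' At each site with defining allele X, every passing base Y != X in the
#' counting sample increments substitution class X>Y; every passing base
#' (X included) increments the X-source denominator. Rates are per Mb of the
#' class-source denominator by default (`denominator = "class"`: C>T is
#' normalized by bases sequenced at homozygous-C sites, making each rate a
#' per-opportunity probability); `denominator = "aggregate"` divides every
#' class by the total passing bases over all sites. Sites where the counting
#' sample's own consensus differs from the defining allele (germline
#' mismatch, e.g. loss of heterozygosity) are excluded entirely.
#'
#' @param columns An `ffpeqc_pileup` of the counting sample, built with the
#'   stringent thresholds (MQ >= 60, BQ >= 30 by default).
#' @param sites An `ffpeqc_hom_sites` from the other sample
#'   (cross-direction).
#' @param thresholds The stringent [filter_thresholds()] (checked against the
#'   pileup's record).
#' @param denominator `"class"` (default) or `"aggregate"`.
#' @return A tibble of class `ffpeqc_spectrum` with one row per ordered
#'   substitution class: `class`, `ref`, `alt`, `discrepant`, `denominator`,
#'   `rate_per_mb` (`NA` with `undefined = TRUE` when the denominator is 0),
#'   plus `n_sites_used`, `n_sites_excluded` attributes.
#' @export
count_discrepant <- function(columns, sites,
                             thresholds = stringent_thresholds(),
                             denominator = c("class", "aggregate")) {
  denominator <- match.arg(denominator)
  stopifnot(inherits(columns, "ffpeqc_pileup"))
  if (!nrow(sites)) abort("empty homozygous site set")
  built <- attr(columns, "thresholds")
  if (built$min_mapq != thresholds$min_mapq ||
      built$min_baseq != thresholds$min_baseq) {
    abort(sprintf(
      "pileup was built with MQ >= %d / BQ >= %d but thresholds specify MQ >= %d / BQ >= %d; rebuild the pileup with matching thresholds",
      built$min_mapq, built$min_baseq, thresholds$min_mapq, thresholds$min_baseq))
  }
  j <- dplyr::inner_join(as_tibble(sites)[c("contig", "pos", "allele")],
                         as_tibble(columns),
                         by = c("contig", "pos"))
  mismatch <- !is.na(j$consensus) & j$consensus != j$allele
  n_excluded <- sum(mismatch)
  j <- j[!mismatch, ]
  counts <- matrix(0, nrow = 4L, ncol = 4L,
                   dimnames = list(ref = BASES, alt = BASES))
  denom_by_ref <- stats::setNames(numeric(4L), BASES)
  for (x in BASES) {
    rows <- j[j$allele == x, ]
    for (y in BASES) counts[x, y] <- sum(rows[[y]])
    denom_by_ref[x] <- sum(rows$depth)
  }
  spec <- purrr::map_dfr(BASES, function(x) {
    alts <- setdiff(BASES, x)
    den <- if (denominator == "class") denom_by_ref[[x]] else sum(denom_by_ref)
    tibble(class = paste0(x, ">", alts), ref = x, alt = alts,
           discrepant = as.integer(counts[x, alts]), denominator = as.numeric(den))
  })
  spec$undefined <- spec$denominator == 0
  spec$rate_per_mb <- ifelse(spec$undefined, NA_real_,
                             1e6 * spec$discrepant / spec$denominator)
  attr(spec, "thresholds") <- thresholds
  attr(spec, "denominator_mode") <- denominator
  attr(spec, "n_sites_used") <- nrow(j)
  attr(spec, "n_sites_excluded") <- n_excluded
  class(spec) <- c("ffpeqc_spectrum", class(spec))
  spec
}

#' @noRd
two_pass_spectrum <- function(site_reads, count_reads, lenient, stringent,
                              denominator, direction, mode = "mates") {
  sites <- find_homozygous_sites(pileup(site_reads, lenient, mode = mode), lenient)
  if (!nrow(sites)) abort("no homozygous sites found in the site-defining sample")
  spec <- count_discrepant(pileup(count_reads, stringent, mode = mode), sites,
                           stringent, denominator = denominator)
  attr(spec, "direction") <- direction
  spec
}

#' Background sequencing-error spectrum
#'
#' First pass of the two-pass estimate: homozygous sites are defined in the
#' tumor sample (frozen-tumor or FFPE) under the lenient filter, and
#' discrepant bases are counted in the matched control (blood / normal
#' frozen) under the stringent filter. Since control DNA is assumed intact,
#' the resulting per-class rates estimate sequencing error plus background
#' DNA damage.
#'
#' @param tumor_reads Alignment tibble of the site-defining (tumor) sample.
#' @param control_reads Alignment tibble of the counted control sample.
#' @param lenient,stringent [filter_thresholds()] for the two passes.
#' @param denominator `"class"` or `"aggregate"`, see [count_discrepant()].
#' @param mode Pileup mate handling, see [pileup()].
#' @return An `ffpeqc_spectrum` (direction `"background"`).
#' @export
background_error_rate <- function(tumor_reads, control_reads,
                                  lenient = lenient_thresholds(),
                                  stringent = stringent_thresholds(),
                                  denominator = c("class", "aggregate"),
                                  mode = c("mates", "fragment")) {
  two_pass_spectrum(tumor_reads, control_reads, lenient, stringent,
                    match.arg(denominator), "background", match.arg(mode))
}

#' Overall base-alteration spectrum
#'
#' Second pass, run in the direction opposite to the background estimate:
#' homozygous sites are defined in the control (blood) sample and discrepant
#' bases are counted in the assay (frozen or FFPE) sample. The resulting
#' rates capture preservation artifacts plus sequencing error / background
#' damage.
#'
#' @param control_reads Alignment tibble of the site-defining control sample.
#' @param assay_reads Alignment tibble of the counted frozen/FFPE sample.
#' @inheritParams background_error_rate
#' @return An `ffpeqc_spectrum` (direction `"overall"`).
#' @export
overall_transition_rate <- function(control_reads, assay_reads,
                                    lenient = lenient_thresholds(),
                                    stringent = stringent_thresholds(),
                                    denominator = c("class", "aggregate"),
                                    mode = c("mates", "fragment")) {
  two_pass_spectrum(control_reads, assay_reads, lenient, stringent,
                    match.arg(denominator), "overall", match.arg(mode))
}

#' FFPE-induced base-alteration spectrum
#'
#' Subtracts the background spectrum from the overall spectrum per class;
#' a rate is non-negative by definition, so negative differences are floored
#' at zero and flagged (`floored`, with the signed difference kept in
#' `rate_difference` for diagnostics). Classes undefined in either input
#' propagate as undefined. In FFPE samples the C>T and G>A classes carry the
#' fixation signal; the other ten classes should be near zero.
#'
#' @param overall `ffpeqc_spectrum` from [overall_transition_rate()].
#' @param background `ffpeqc_spectrum` from [background_error_rate()].
#' @return An `ffpeqc_spectrum` (direction `"induced"`) with columns `class`,
#'   `ref`, `alt`, `discrepant` (overall counts), `discrepant_background`,
#'   `denominator` (overall), `rate_per_mb` (floored difference),
#'   `rate_difference`, `floored`, `undefined`.
#' @export
ffpe_induced_rate <- function(overall, background) {
  stopifnot(inherits(overall, "ffpeqc_spectrum"),
            inherits(background, "ffpeqc_spectrum"))
  if (!identical(overall$class, background$class)) {
    abort("`overall` and `background` must be defined on the same class set")
  }
  diff <- overall$rate_per_mb - background$rate_per_mb
  out <- tibble(
    class = overall$class, ref = overall$ref, alt = overall$alt,
    discrepant = overall$discrepant,
    discrepant_background = background$discrepant,
    denominator = overall$denominator,
    undefined = overall$undefined | background$undefined,
    rate_difference = diff,
    floored = !is.na(diff) & diff < 0,
    rate_per_mb = ifelse(is.na(diff), NA_real_, pmax(0, diff))
  )
  out <- out[c("class", "ref", "alt", "discrepant", "discrepant_background",
               "denominator", "rate_per_mb", "rate_difference", "floored",
               "undefined")]
  attr(out, "direction") <- "induced"
  class(out) <- c("ffpeqc_spectrum", class(out))
  out
}

#' @export
print.ffpeqc_spectrum <- function(x, ...) {
  dir <- attr(x, "direction") %||% "spectrum"
  cat(sprintf("<ffpeqc_spectrum: %s> rates per Mb over 12 substitution classes\n", dir))
  print(as_tibble(x))
  invisible(x)
}
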