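#' Configuration for one synthetic exome library
#'
#' Collects every knob of the simulator: reference composition, germline and
#' somatic variant rates, fragment-length distribution, deamination and miscall
#' rates, base-quality profile, soft-clip injection and mapping-fate fractions.
#' Defaults emulate a 2x100-bp Illumina exome run; the per-sample-type defaults
#' reflect the contrast between blood/frozen libraries (insert medians around
#' 185-200 bp, essentially artifact-free) and FFPE libraries (median insert
#' ~100 bp, template-level C>T/G>A deamination, abundant soft clips, elevated
#' unmapped/discordant fractions).
#'
#' @param seed Integer seed; identical config (including seed) gives
#'   byte-identical simulated output.
#' @param sample_type One of `"blood"`, `"frozen"`, `"ffpe"`. Chooses the
#'   per-type defaults below and controls which artifacts may be injected.
#' @param n_contigs,contig_length Number and length (bp) of reference contigs.
#' @param gc_fraction Expected GC content of the reference.
#' @param target_regions `"auto"` (400-bp windows tiled with 400-bp gaps) or a
#'   tibble with columns `contig`, `start`, `end` (0-based half-open).
#' @param het_snp_rate Per-base probability of a heterozygous germline SNV,
#'   shared by all three sample types.
#' @param somatic_mutation_rate Per-base probability of a somatic SNV, present
#'   only in tumor (frozen/ffpe) libraries.
#' @param somatic_vaf Variant allele fraction of somatic SNVs within tumor
#'   cells; the observed VAF is `somatic_vaf * tumor_purity`.
#' @param tumor_purity Fraction of tumor-derived fragments in tumor libraries.
#' @param read_length Read length (bp) of each mate.
#' @param mean_depth Expected mean sequenced-base depth over the contigs.
#' @param insert_median Median template (insert) length, bp. Default 200
#'   (blood), 185 (frozen), 100 (ffpe).
#' @param insert_log_sigma Log-scale shape of the log-normal insert-length
#'   distribution. Draws are clamped to `[read_length/2, 10 * insert_median]`,
#'   which leaves the median at `insert_median`.
#' @param deamination_rate Per-fragment probability that a given reference C
#'   is read as T (and, symmetrically, G as A): the formalin-lesion rate.
#'   Non-zero only for FFPE (default 1e-3 for ffpe, 0 otherwise). Alterations
#'   are template-level: both mates of an overlapping pair carry them.
#' @param miscall_rate Per-sequenced-base miscall probability, distributed
#'   uniformly over the three alternative bases and independent between mates.
#' @param qual_high,qual_low,low_qual_fraction Base-quality profile: a point
#'   mass at `qual_high` with a `low_qual_fraction` tail at `qual_low`.
#' @param unmapped_low_qual_fraction Low-quality tail used for unmapped reads
#'   (defaults to `low_qual_fraction`); lets unmapped reads carry a heavier
#'   low-quality tail, as seen in blood/frozen libraries.
#' @param clip_probability Per-read probability of a soft-clipped end.
#'   Default 0.6 (ffpe), 0.02 otherwise.
#' @param clip_length_mean Mean soft-clip length, bp. Clip lengths are drawn
#'   from a geometric distribution truncated at `read_length - 20`, with rate
#'   calibrated so the truncated mean equals `clip_length_mean`; at least 20
#'   aligned bases always remain.
#' @param unmapped_fraction Fraction of read pairs emitted unmapped.
#'   Default 0.05 (ffpe), 0.005 otherwise.
#' @param discordant_fraction Fraction of read pairs emitted mapped but not
#'   properly paired. Default 0.04 (ffpe), 0.005 otherwise.
#' @param mapq Mapping quality assigned to mapped reads (default 60, the
#'   unique-mapping cap of common short-read aligners).
#'
#' @return An object of class `sim_config` (a validated named list).
#' @examples
#' cfg <- sim_config(seed = 1, sample_type = "ffpe", contig_length = 1e4)
#' cfg$insert_median
#' @export
sim_config <- function(seed = 1L,
                       sample_type = c("blood", "frozen", "ffpe"),
                       n_contigs = 1L,
                       contig_length = 3e5,
                       gc_fraction = 0.45,
                       target_regions = "auto",
                       het_snp_rate = 1e-3,
                       somatic_mutation_rate = 5e-5,
                       somatic_vaf = 0.4,
                       tumor_purity = 0.75,
                       read_length = 100L,
                       mean_depth = 100,
                       insert_median = NULL,
                       insert_log_sigma = 0.55,
                       deamination_rate = NULL,
                       miscall_rate = 6e-4,
                       qual_high = 35L,
                       qual_low = 11L,
                       low_qual_fraction = 0.02,
                       unmapped_low_qual_fraction = NULL,
                       clip_probability = NULL,
                       clip_length_mean = 50,
                       unmapped_fraction = NULL,
                       discordant_fraction = NULL,
                       mapq = 60L) {
  sample_type <- match.arg(sample_type)
  insert_median <- insert_median %||%
    switch(sample_type, blood = 200, frozen = 185, ffpe = 100)
  deamination_rate <- deamination_rate %||%
    switch(sample_type, blood = 0, frozen = 0, ffpe = 1e-3)
  clip_probability <- clip_probability %||%
    switch(sample_type, blood = 0.02, frozen = 0.02, ffpe = 0.6)
  unmapped_fraction <- unmapped_fraction %||%
    switch(sample_type, blood = 0.005, frozen = 0.005, ffpe = 0.05)
  discordant_fraction <- discordant_fraction %||%
    switch(sample_type, blood = 0.005, frozen = 0.005, ffpe = 0.04)
  unmapped_low_qual_fraction <- unmapped_low_qual_fraction %||% low_qual_fraction

  cfg <- list(
    seed = as.integer(seed), sample_type = sample_type,
    n_contigs = as.integer(n_contigs), contig_length = as.integer(contig_length),
    gc_fraction = gc_fraction, target_regions = target_regions,
    het_snp_rate = het_snp_rate, somatic_mutation_rate = somatic_mutation_rate,
    somatic_vaf = somatic_vaf, tumor_purity = tumor_purity,
    read_length = as.integer(read_length), mean_depth = mean_depth,
    insert_median = insert_median, insert_log_sigma = insert_log_sigma,
    deamination_rate = deamination_rate, miscall_rate = miscall_rate,
    qual_high = as.integer(qual_high), qual_low = as.integer(qual_low),
    low_qual_fraction = low_qual_fraction,
    unmapped_low_qual_fraction = unmapped_low_qual_fraction,
    clip_probability = clip_probability, clip_length_mean = clip_length_mean,
    unmapped_fraction = unmapped_fraction,
    discordant_fraction = discordant_fraction,
    mapq = as.integer(mapq)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

#' @noRd
validate_sim_config <- function(cfg) {
  bad <- character(0)
  probs <- c("gc_fraction", "het_snp_rate", "somatic_mutation_rate",
             "somatic_vaf", "tumor_purity", "deamination_rate", "miscall_rate",
             "low_qual_fraction", "unmapped_low_qual_fraction",
             "clip_probability", "unmapped_fraction", "discordant_fraction")
  for (p in probs) {
    if (!is_prob(cfg[[p]])) bad <- c(bad, sprintf("`%s` must be a probability in [0, 1]", p))
  }
  for (p in c("n_contigs", "contig_length", "read_length")) {
    if (!is_count(cfg[[p]])) bad <- c(bad, sprintf("`%s` must be a positive integer", p))
  }
  if (!is.numeric(cfg$insert_median) || cfg$insert_median < 1)
    bad <- c(bad, "`insert_median` must be >= 1")
  if (!is.numeric(cfg$mean_depth) || cfg$mean_depth <= 0)
    bad <- c(bad, "`mean_depth` must be > 0")
  if (!is.numeric(cfg$insert_log_sigma) || cfg$insert_log_sigma < 0)
    bad <- c(bad, "`insert_log_sigma` must be >= 0")
  if (is.numeric(cfg$read_length) && is.numeric(cfg$clip_length_mean) &&
      cfg$clip_length_mean >= cfg$read_length)
    bad <- c(bad, sprintf("`clip_length_mean` (%s) must be smaller than `read_length` (%s)",
                          cfg$clip_length_mean, cfg$read_length))
  if (cfg$unmapped_fraction + cfg$discordant_fraction > 1)
    bad <- c(bad, "`unmapped_fraction` + `discordant_fraction` must not exceed 1")
  if (!identical(cfg$target_regions, "auto") && !is.data.frame(cfg$target_regions))
    bad <- c(bad, "`target_regions` must be \"auto\" or a data frame (contig, start, end)")
  if (length(bad)) {
    abort(c("Invalid simulation configuration:", stats::setNames(bad, rep("x", length(bad)))),
          class = "ffpeqc_config_error")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> sample_type =", x$sample_type,
      "| seed =", x$seed, "\n")
  cat(sprintf("  reference: %d contig(s) x %d bp, GC %.2f\n",
              x$n_contigs, x$contig_length, x$gc_fraction))
  cat(sprintf("  reads: 2 x %d bp, mean depth %.0fx, insert median %.0f (log-sigma %.2f)\n",
              x$read_length, x$mean_depth, x$insert_median, x$insert_log_sigma))
  cat(sprintf("  artifacts: deamination %.2g, miscall %.2g, clip p %.2g (mean %.0f bp)\n",
              x$deamination_rate, x$miscall_rate, x$clip_probability, x$clip_length_mean))
  invisible(x)
}
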