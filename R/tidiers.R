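#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an insert-size summary
#'
#' @param x An `insert_summary`.
#' @param ... Unused.
#' @return The histogram as a tibble (`insert`, `n`).
#' @method tidy insert_summary
#' @export
tidy.insert_summary <- function(x, ...) x$histogram

#' @rdname tidy.insert_summary
#' @method glance insert_summary
#' @export
glance.insert_summary <- function(x, ...) {
  tibble(median_insert = x$median, n_pairs = x$n_pairs)
}

#' Tidy a mate-overlap summary
#'
#' @param x An `overlap_summary`.
#' @param ... Unused.
#' @return The per-pair overlap histogram (`overlap`, `n`).
#' @method tidy overlap_summary
#' @export
tidy.overlap_summary <- function(x, ...) x$per_pair_overlaps

#' @rdname tidy.overlap_summary
#' @method glance overlap_summary
#' @export
glance.overlap_summary <- function(x, ...) {
  tibble(double_fraction = x$double_fraction,
         overlap_bases = x$overlap_bases,
         total_sequenced_bases = x$total_sequenced_bases,
         n_pairs = x$n_pairs,
         n_unpaired_skipped = x$n_unpaired_skipped)
}

#' One-row summary of soft-clip metrics
#'
#' @param x A `softclip_summary`.
#' @param ... Unused.
#' @method glance softclip_summary
#' @export
glance.softclip_summary <- function(x, ...) {
  tibble(clip_fraction = x$clip_fraction, clipped_bases = x$clipped_bases,
         total_bases_in_mapped_reads = x$total_bases_in_mapped_reads,
         reads_with_clip = x$reads_with_clip, n_mapped_reads = x$n_mapped_reads)
}

#' One-row summary of target coverage
#'
#' @param x A `coverage_summary`.
#' @param ... Unused.
#' @method glance coverage_summary
#' @export
glance.coverage_summary <- function(x, ...) {
  tibble(covered_target_fraction = x$covered_target_fraction,
         on_target_mean_depth = x$on_target_mean_depth,
         flanking_mean_depth = x$flanking_mean_depth,
         off_target_base_fraction = x$off_target_base_fraction)
}

#' Tidy a quality-by-mapping-status summary
#'
#' @param x A `quality_summary`.
#' @param ... Unused.
#' @return The normalized per-status Phred histogram.
#' @method tidy quality_summary
#' @export
tidy.quality_summary <- function(x, ...) x$histogram

#' @rdname tidy.quality_summary
#' @method glance quality_summary
#' @export
glance.quality_summary <- function(x, ...) {
  tidyr::pivot_wider(x$summary, names_from = "status",
                     values_from = c("n_bases", "frac_ge_q30", "frac_le_q20"))
}

#' Tidy a substitution spectrum
#'
#' @param x An `ffpeqc_spectrum`.
#' @param ... Unused.
#' @return A plain tibble of the per-class rows, with a `direction` column.
#' @method tidy ffpeqc_spectrum
#' @export
tidy.ffpeqc_spectrum <- function(x, ...) {
  out <- as_tibble(x)
  out$direction <- attr(x, "direction") %||% NA_character_
  out
}

#' @rdname tidy.ffpeqc_spectrum
#' @method glance ffpeqc_spectrum
#' @export
glance.ffpeqc_spectrum <- function(x, ...) {
  deam <- x$class %in% c("C>T", "G>A")
  tibble(direction = attr(x, "direction") %||% NA_character_,
         total_discrepant = sum(x$discrepant),
         max_rate_per_mb = if (all(is.na(x$rate_per_mb))) NA_real_
         else max(x$rate_per_mb, na.rm = TRUE),
         mean_ct_ga_rate = mean(x$rate_per_mb[deam]),
         mean_other_rate = mean(x$rate_per_mb[!deam]),
         n_undefined = sum(x$undefined))
}

#' Tidy a concordance curve
#'
#' @param x A `concordance_curve`.
#' @param ... Unused.
#' @return A plain tibble with a `mode` column.
#' @method tidy concordance_curve
#' @export
tidy.concordance_curve <- function(x, ...) {
  out <- as_tibble(x)
  out$mode <- attr(x, "mode") %||% NA_character_
  out
}

#' @rdname tidy.concordance_curve
#' @method glance concordance_curve
#' @export
glance.concordance_curve <- function(x, ...) {
  tibble(mode = attr(x, "mode") %||% NA_character_,
         denominator = attr(x, "denominator") %||% NA_character_,
         n_thresholds = nrow(x),
         min_fraction = suppressWarnings(min(x$overlap_fraction, na.rm = TRUE)),
         max_fraction = suppressWarnings(max(x$overlap_fraction, na.rm = TRUE)))
}

#' One-row summary of a simulated library
#'
#' Reports the realized artifact counts as rates, directly comparable to the
#' configured injection rates.
#'
#' @param x A `sim_library`.
#' @param ... Unused.
#' @method glance sim_library
#' @export
glance.sim_library <- function(x, ...) {
  r <- x$realized
  tibble(
    sample_type = x$config$sample_type,
    n_reads = nrow(x$reads),
    realized_deamination_ct = r$deamination$n_ct / r$deamination$n_c,
    realized_deamination_ga = r$deamination$n_ga / r$deamination$n_g,
    realized_miscall_rate = r$miscalls$n_miscalls / r$miscalls$n_bases,
    realized_clip_fraction = r$clips$n_clipped_bases / r$clips$n_bases,
    realized_unmapped_fraction = r$mapping_fates$n_unmapped_pairs / r$mapping_fates$n_pairs,
    realized_discordant_fraction = r$mapping_fates$n_discordant_pairs / r$mapping_fates$n_pairs
  )
}
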