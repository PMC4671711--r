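#' @importFrom rlang %||% abort warn
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   left_join inner_join anti_join bind_rows n row_number case_when across
#'   distinct pull rename count
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom stats median rlnorm runif rbinom rgeom dbinom pbinom setNames
#'   uniroot
#' @importFrom utils head tail
NULL

# Internal nucleotide coding: A=1 C=2 G=3 T=4.
BASES <- c("A", "C", "G", "T")

.base_code <- local({
  m <- integer(128L)
  m[utf8ToInt("A")] <- 1L
  m[utf8ToInt("C")] <- 2L
  m[utf8ToInt("G")] <- 3L
  m[utf8ToInt("T")] <- 4L
  m
})

#' @noRd
base_codes <- function(x) {
  # x: character vector of nucleotide strings -> integer codes, concatenated
  .base_code[utf8ToInt(paste(x, collapse = ""))]
}

#' @noRd
codes_to_strings <- function(codes, lens) {
  # inverse of base_codes given per-element lengths
  big <- intToUtf8(utf8ToInt(paste(BASES, collapse = ""))[codes])
  ends <- cumsum(lens)
  substring(big, ends - lens + 1L, ends)
}

#' @noRd
phred_to_strings <- function(q, lens) {
  big <- intToUtf8(q + 33L)
  ends <- cumsum(lens)
  substring(big, ends - lens + 1L, ends)
}

#' @noRd
qual_ints <- function(qual_strings) {
  utf8ToInt(paste(qual_strings, collapse = "")) - 33L
}

# Deterministic derived seed streams, kept inside 32-bit integer range.
#' @noRd
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) + 1000003 * stream) %% 2147483629)
}

#' @noRd
is_prob <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x <= 1

#' @noRd
is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 1 && x == floor(x)
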