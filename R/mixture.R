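# Two-population contamination mixture model.
#
# A bulk total-sperm sample is a cell mixture: a fraction f of
# histone-replacement-uncompleted sperm (HRunCS) with per-cell histone content
# h_un, and (1 - f) of completed sperm (HRCS) with content h_c. With bulk
# measurements normalized per cell, the total:HRCS bulk histone ratio is
#   R = (1 - f) + f * (h_un / h_c).
# With f = 0.10 and R = 5 (the western-blot 5:1), the per-cell ratio is 41 and
# the contamination share f * 41 / 5 = 0.82: most bulk histone comes from the
# 10% contaminating cells.

#' Mixture specification for the contamination model
#'
#' @param f HRunCS cell fraction, in `[0, 1]` (default 0.10).
#' @param h_un_over_h_c Per-cell HRunCS:HRCS histone content ratio (>= 0,
#'   default 41).
#' @param h_c Per-cell HRCS histone content in arbitrary units (> 0, default
#'   1).
#' @param total_mapped_reads Optional declared depth for mixed coverage
#'   tracks; if `NULL`, the mixed depth is the same linear combination of the
#'   component depths.
#' @return Object of class `mixture_spec`.
#' @export
mixture_spec <- function(f = 0.10, h_un_over_h_c = 41, h_c = 1,
                         total_mapped_reads = NULL) {
  if (length(f) != 1 || f < 0 || f > 1) stop("mixture_spec: f must be in [0, 1]")
  if (h_un_over_h_c < 0) stop("mixture_spec: h_un_over_h_c must be >= 0")
  if (h_c <= 0) stop("mixture_spec: h_c must be > 0")
  structure(list(f = f, h_un_over_h_c = h_un_over_h_c, h_c = h_c,
                 h_un = h_un_over_h_c * h_c,
                 total_mapped_reads = total_mapped_reads),
            class = "mixture_spec")
}

#' Forward mixture ratio
#'
#' Bulk total:HRCS histone ratio `R = (1 - f) + f * ratio` for a HRunCS cell
#' fraction `f` and per-cell content ratio `ratio = h_un / h_c`.
#'
#' @param f HRunCS cell fraction in `[0, 1]`.
#' @param h_un_over_h_c Per-cell content ratio (>= 0).
#' @return The bulk ratio `R`.
#' @examples
#' forward_ratio(0.10, 41) # 5
#' @export
forward_ratio <- function(f, h_un_over_h_c) {
  if (any(f < 0 | f > 1)) stop("forward_ratio: f must be in [0, 1]")
  if (any(h_un_over_h_c < 0)) stop("forward_ratio: ratio must be >= 0")
  (1 - f) + f * h_un_over_h_c
}

#' Invert the mixture ratio
#'
#' Given the cell fraction `f` and a measured bulk ratio `R`, recovers the
#' per-cell content ratio and the share of bulk histone contributed by the
#' contaminating cells.
#'
#' @param f HRunCS cell fraction, in `(0, 1]` (f = 0 is non-identifiable).
#' @param R Measured bulk total:HRCS ratio; must satisfy `R >= 1 - f`.
#' @return List with `h_un_over_h_c = (R - (1 - f)) / f` and
#'   `contamination_share = f * h_un_over_h_c / R` (in `[0, 1]`).
#' @examples
#' invert_ratio(0.10, 5) # ratio 41, share 0.82
#' @export
invert_ratio <- function(f, R) {
  if (length(f) != 1 || f <= 0 || f > 1) {
    stop("invert_ratio: f must be in (0, 1]; f = 0 is non-identifiable")
  }
  if (R < 1 - f) {
    stop("invert_ratio: inconsistent measurement (R < 1 - f)")
  }
  ratio <- (R - (1 - f)) / f
  share <- if (R > 0) f * ratio / R else 0
  list(h_un_over_h_c = ratio, contamination_share = share)
}

#' Recover the per-cell ratio from noisy replicate bulk measurements
#'
#' Point estimate from the mean replicate `R`; uncertainty by percentile
#' bootstrap over replicates. Deterministic under `seed`.
#'
#' @param R_replicates Numeric vector of >= 3 replicate bulk ratios.
#' @param f HRunCS cell fraction, in `(0, 1]`.
#' @param n_boot Bootstrap draws (default 1000).
#' @param conf Interval coverage (default 0.95).
#' @param seed Integer seed for the bootstrap resampling.
#' @return List: `h_un_over_h_c`, `contamination_share`, `ci` (percentile
#'   interval for the ratio), `R_mean`, `n`.
#' @export
recover_from_noisy <- function(R_replicates, f, n_boot = 1000, conf = 0.95,
                               seed = 1) {
  if (length(R_replicates) < 3) {
    stop("recover_from_noisy: need at least 3 replicates")
  }
  if (all(R_replicates < 1 - f)) {
    stop("recover_from_noisy: all replicates inconsistent (R < 1 - f)")
  }
  Rm <- mean(R_replicates)
  est <- invert_ratio(f, max(Rm, 1 - f))
  set.seed(seed)
  boot <- vapply(seq_len(n_boot), function(b) {
    Rb <- mean(sample(R_replicates, replace = TRUE))
    (max(Rb, 1 - f) - (1 - f)) / f
  }, numeric(1))
  a <- (1 - conf) / 2
  list(h_un_over_h_c = est$h_un_over_h_c,
       contamination_share = est$contamination_share,
       ci = stats::quantile(boot, c(a, 1 - a), names = FALSE),
       R_mean = Rm, n = length(R_replicates))
}

#' Mix component coverage tracks into a bulk total-sperm track
#'
#' Bin value = `(1 - f) * h_c * hrcs + f * h_un * hruncs`. The declared depth
#' of the result is `spec$total_mapped_reads` if given; otherwise the same
#' linear combination of the component depths, which preserves bulk signal
#' ratios (flat unit tracks with f = 0.1, h_un/h_c = 41 give a total:HRCS
#' signal ratio of 5).
#'
#' @param hrcs_track,hruncs_track [coverage_track()]s on identical bin grids.
#' @param spec A [mixture_spec()].
#' @return The mixed [coverage_track()].
#' @export
mix_total_sperm <- function(hrcs_track, hruncs_track, spec) {
  stopifnot(inherits(hrcs_track, "coverage_track"),
            inherits(hruncs_track, "coverage_track"),
            inherits(spec, "mixture_spec"))
  if (hrcs_track$bin_width != hruncs_track$bin_width ||
      !identical(names(hrcs_track$counts), names(hruncs_track$counts)) ||
      !all(lengths(hrcs_track$counts) == lengths(hruncs_track$counts))) {
    stop("mix_total_sperm: component tracks are not on identical bin grids")
  }
  wc <- (1 - spec$f) * spec$h_c
  wu <- spec$f * spec$h_un
  counts <- stats::setNames(lapply(names(hrcs_track$counts), function(ch) {
    wc * hrcs_track$counts[[ch]] + wu * hruncs_track$counts[[ch]]
  }), names(hrcs_track$counts))
  total <- spec$total_mapped_reads
  if (is.null(total)) {
    total <- wc * hrcs_track$total_mapped_reads +
      wu * hruncs_track$total_mapped_reads
  }
  if (total <= 0) total <- NULL  # degenerate f/h combinations: fall back to sum
  coverage_track(counts, hrcs_track$bin_width, total)
}
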