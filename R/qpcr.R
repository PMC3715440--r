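# The qPCR relative-quantification chain: dilution-series standard curves,
# inversion of Cq values to copy numbers, and the normalized ratios used to
# express excision frequency (empty attachment site per chromosome,
# normalized to a cured strain = 100% excision), circle:empty-site ratios
# (normalized to wild type) and integration ratios (normalized to a
# positive-control strain).

#' Fit a qPCR standard curve
#'
#' Ordinary least squares of Cq on log10 input copies over a dilution
#' series: Cq = slope * log10(copies) + intercept.  Amplification
#' efficiency is 10^(-1/slope) - 1 (1.0 for perfect per-cycle doubling,
#' slope -1/log10(2) = -3.3219).
#'
#' @param log10_copies Numeric vector of known log10 input copies, or a
#'   data.frame with columns `log10_copies` and `cq`.
#' @param cq Measured quantification cycles (ignored when a data.frame is
#'   given).
#' @return An object of class `standard_curve`: slope, intercept,
#'   r_squared, efficiency, n, cq_max (largest observed dilution-series
#'   Cq, used as the detection anchor), and `efficiency_ok` (TRUE when the
#'   slope is negative and efficiency lies in 0.5..1.5).
#' @examples
#' fit_standard_curve(5:1, 5 + (5:1) * (-1 / log10(2)))$efficiency  # 1
#' @export
fit_standard_curve <- function(log10_copies, cq) {
  if (is.data.frame(log10_copies)) {
    cq <- log10_copies$cq
    log10_copies <- log10_copies$log10_copies
  }
  if (length(log10_copies) < 3L || length(cq) != length(log10_copies)) {
    stop("a standard curve needs >= 3 (log10_copies, cq) points")
  }
  if (stats::var(log10_copies) == 0) {
    stop("dilution series has zero spread in log10 copies")
  }
  if (diff(range(log10_copies)) < 2) {
    warning("dilution series spans < 2 logs; the fit may be unstable")
  }
  fit <- stats::lm(cq ~ log10_copies)
  slope <- unname(stats::coef(fit)[2L])
  intercept <- unname(stats::coef(fit)[1L])
  efficiency <- 10^(-1 / slope) - 1
  ok <- is.finite(efficiency) && slope < 0 &&
    efficiency >= 0.5 && efficiency <= 1.5
  if (!ok) {
    warning("standard curve outside the expected band ",
            "(slope < 0, efficiency 0.5..1.5): slope = ",
            signif(slope, 4))
  }
  structure(
    list(slope = slope,
         intercept = intercept,
         r_squared = 1 - sum(stats::residuals(fit)^2) /
           sum((cq - mean(cq))^2),
         efficiency = efficiency,
         efficiency_ok = ok,
         n = length(cq),
         cq_max = max(cq)),
    class = "standard_curve"
  )
}

#' Construct a standard curve from known parameters
#'
#' Used by the synthetic-data generators and wherever a curve is specified
#' rather than fitted.
#'
#' @param slope Cq change per log10 copies (negative for a valid assay).
#' @param intercept Cq at log10(copies) = 0.
#' @param cq_max Optional largest dilution-series Cq (detection anchor for
#'   the below-LOD rule); NA disables the rule.
#' @return A `standard_curve`.
#' @export
standard_curve <- function(slope, intercept, cq_max = NA_real_) {
  if (!is.numeric(slope) || slope == 0) {
    stop("slope must be nonzero")
  }
  efficiency <- 10^(-1 / slope) - 1
  structure(
    list(slope = slope, intercept = intercept,
         r_squared = NA_real_, efficiency = efficiency,
         efficiency_ok = slope < 0 && efficiency >= 0.5 &&
           efficiency <= 1.5,
         n = NA_integer_, cq_max = cq_max),
    class = "standard_curve"
  )
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "standard_curve: Cq = %.4f * log10(copies) + %.4f  (eff %.3f%s)\n",
    x$slope, x$intercept, x$efficiency,
    if (isTRUE(x$efficiency_ok)) "" else ", flagged"))
  invisible(x)
}

#' Invert Cq replicates to copy numbers
#'
#' Per replicate, copies = 10^((Cq - intercept) / slope); replicates are
#' combined by geometric mean (equivalently, arithmetic mean of Cq under
#' the log-linear model, since Cq noise is additive on the log scale).
#' Dispersion is the geometric standard deviation across replicates.  A
#' sample whose mean Cq exceeds the curve's largest dilution-series Cq by
#' more than `lod_cycles` is flagged below the limit of detection rather
#' than extrapolated.
#'
#' @param cq Numeric vector of replicate Cq values (>= 1 replicate).
#' @param curve A `standard_curve`.
#' @param lod_cycles Cycles beyond `curve$cq_max` that trigger the
#'   below-LOD flag (default 2); inactive when `cq_max` is NA.
#' @return An object of class `quantification`: `copies` (geometric mean),
#'   `gsd` (geometric SD, NA for a single replicate), `replicate_copies`,
#'   `n`, `below_lod`.
#' @export
quantify <- function(cq, curve, lod_cycles = 2) {
  if (!inherits(curve, "standard_curve")) {
    stop("quantify() expects a standard_curve")
  }
  if (curve$slope == 0) {
    stop("degenerate curve: slope is zero")
  }
  if (length(cq) < 1L || any(!is.finite(cq))) {
    stop("at least one finite replicate Cq is required")
  }
  rep_copies <- 10^((cq - curve$intercept) / curve$slope)
  copies <- exp(mean(log(rep_copies)))
  gsd <- if (length(cq) > 1L) exp(stats::sd(log(rep_copies))) else NA_real_
  below <- !is.na(curve$cq_max) && mean(cq) > curve$cq_max + lod_cycles
  structure(
    list(copies = copies, gsd = gsd,
         replicate_copies = rep_copies, n = length(cq),
         below_lod = below),
    class = "quantification"
  )
}

#' @export
print.quantification <- function(x, ...) {
  cat(sprintf("quantification: %.4g copies (gsd %.3f, n = %d)%s\n",
              x$copies, x$gsd, x$n,
              if (x$below_lod) "  [below LOD]" else ""))
  invisible(x)
}

# Accept a bare copy number or a quantification object.
as_copies <- function(x, what) {
  if (inherits(x, "quantification")) {
    x <- x$copies
  }
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(what, " must be a single positive copy number")
  }
  x
}

#' Excision frequency from empty-site and reference copy numbers
#'
#' The empty attachment site per chromosome, normalized to a cured strain
#' representing 100% excision:
#' f = (empty/reference)_sample / (empty/reference)_cured.  Scale-invariant
#' in each sample's absolute copies; the cured strain self-normalizes to 1.
#'
#' @param sample_empty,sample_reference Empty-site and reference-gene
#'   copies in the induced sample (numbers or `quantification`s).
#' @param cured_empty,cured_reference Same pair for the cured strain.
#' @return Excision frequency (unitless fraction).
#' @export
excision_frequency <- function(sample_empty, sample_reference,
                               cured_empty, cured_reference) {
  (as_copies(sample_empty, "sample_empty") /
     as_copies(sample_reference, "sample_reference")) /
    (as_copies(cured_empty, "cured_empty") /
       as_copies(cured_reference, "cured_reference"))
}

#' Circle-to-empty-site ratio normalized to wild type
#'
#' The relative amount of the excised circular element (per reference
#' gene) divided by the relative amount of the empty attachment site (per
#' reference gene), then normalized to the same ratio in the wild type.
#' Values near 1 mean the circle is as stable as in the wild type; values
#' well below 1 indicate loss of the excised circle (as seen for
#' heteroduplex-forming insertions).
#'
#' @param circle,empty,reference Sample copy numbers (or
#'   `quantification`s) of the circle junction, empty site and reference
#'   gene.
#' @param wt_circle,wt_empty,wt_reference The same triple for wild type.
#' @return Unitless ratio; 1 when sample equals wild type.
#' @export
circle_to_empty_ratio <- function(circle, empty, reference,
                                  wt_circle, wt_empty, wt_reference) {
  s <- (as_copies(circle, "circle") / as_copies(reference, "reference")) /
    (as_copies(empty, "empty") / as_copies(reference, "reference"))
  w <- (as_copies(wt_circle, "wt_circle") /
          as_copies(wt_reference, "wt_reference")) /
    (as_copies(wt_empty, "wt_empty") /
       as_copies(wt_reference, "wt_reference"))
  s / w
}

#' Integration ratio relative to a positive control
#'
#' Quantifies how often an element integrated at a given site in a pooled
#' population: the site junction per reference gene in the pool, divided
#' by the same ratio in a control strain carrying the insertion in every
#' cell (100% integration).  When either junction quantification is
#' flagged below the limit of detection, the result is flagged rather
#' than reported as a number.
#'
#' @param junction,reference Pool copy numbers (or `quantification`s) of
#'   the site junction and reference gene.
#' @param control_junction,control_reference Same pair for the
#'   positive-control strain.
#' @return A list with `ratio` (fraction of the control, NA when below
#'   LOD) and `below_lod`.
#' @export
integration_ratio <- function(junction, reference,
                              control_junction, control_reference) {
  below <- (inherits(junction, "quantification") && junction$below_lod) ||
    (inherits(control_junction, "quantification") &&
       control_junction$below_lod)
  if (below) {
    return(list(ratio = NA_real_, below_lod = TRUE))
  }
  r <- (as_copies(junction, "junction") /
          as_copies(reference, "reference")) /
    (as_copies(control_junction, "control_junction") /
       as_copies(control_reference, "control_reference"))
  list(ratio = r, below_lod = FALSE)
}

#' Fold difference between relative excision and relative mating
#'
#' If the excised circle is stable, mating efficiency should be
#' proportional to excision frequency, making this fold near 1.  Large
#' values indicate loss of the excised circle between excision and
#' transfer (e.g. 0.15 relative excision with 0.002 relative mating gives
#' a 75-fold discrepancy, the signature of heteroduplex circle loss).
#'
#' @param relative_excision Excision frequency as a fraction of the
#'   primary-site strain's.
#' @param relative_mating Mating efficiency as a fraction of the
#'   primary-site strain's.
#' @return Fold difference (excision / mating).
#' @export
mating_excision_fold <- function(relative_excision, relative_mating) {
  if (!is.numeric(relative_excision) || !is.numeric(relative_mating) ||
      any(relative_excision <= 0) || any(relative_mating <= 0)) {
    stop("both inputs must be positive")
  }
  relative_excision / relative_mating
}

#' Estimate excision frequency from a Cq table
#'
#' Convenience wrapper running the full chain on a long-format Cq table:
#' technical replicates are combined per (sample, target) by [quantify()]
#' and the normalized frequency computed by [excision_frequency()].  The
#' default combines replicate Cq first (geometric mean of copies); set
#' `combine = "after"` to normalize per replicate and average the
#' frequencies instead.
#'
#' @param cq_table Data.frame with columns `sample_id`, `target`
#'   (`"empty"` and `"reference"` rows are used), `replicate`, `cq`.
#' @param curve A `standard_curve` applied to both targets, or a named
#'   list of curves keyed by target.
#' @param sample_id,cured_id Sample identifiers of the induced sample and
#'   of the cured (100% excision) normalizer.
#' @param lod_cycles Passed to [quantify()].
#' @param combine Combine technical replicates `"before"` (default) or
#'   `"after"` normalization.
#' @return A list with `frequency`, `below_lod`, and the four component
#'   `quantification`s.
#' @export
estimate_excision <- function(cq_table, curve, sample_id, cured_id,
                              lod_cycles = 2,
                              combine = c("before", "after")) {
  combine <- match.arg(combine)
  need <- c("sample_id", "target", "cq")
  if (!all(need %in% names(cq_table))) {
    stop("cq_table must have columns: ", paste(need, collapse = ", "))
  }
  curve_for <- function(target) {
    if (inherits(curve, "standard_curve")) curve else curve[[target]]
  }
  pick <- function(id, target) {
    cq <- cq_table$cq[cq_table$sample_id == id & cq_table$target == target]
    if (length(cq) == 0L) {
      stop("no Cq rows for sample '", id, "', target '", target, "'")
    }
    quantify(cq, curve_for(target), lod_cycles = lod_cycles)
  }
  se <- pick(sample_id, "empty")
  sr <- pick(sample_id, "reference")
  ce <- pick(cured_id, "empty")
  cr <- pick(cured_id, "reference")
  below <- se$below_lod || ce$below_lod
  freq <- if (below && se$below_lod) {
    NA_real_
  } else if (combine == "before") {
    excision_frequency(se, sr, ce, cr)
  } else {
    n <- min(se$n, sr$n, ce$n, cr$n)
    mean(vapply(seq_len(n), function(i) {
      excision_frequency(se$replicate_copies[i], sr$replicate_copies[i],
                         ce$replicate_copies[i], cr$replicate_copies[i])
    }, numeric(1)))
  }
  list(frequency = freq, below_lod = below,
       sample_empty = se, sample_reference = sr,
       cured_empty = ce, cured_reference = cr)
}
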