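# Insertion catalogs: tables of independent transconjugant insertions keyed
# by (locus, orientation).  Orientation is relative to the direction of the
# chromosomal replication forks: "co-directional" when element replication
# runs with the fork, "head-on" when against it.  The same locus in
# opposite orientations presents two different target sequences, so the
# two count as distinct sites.

ORIENTATIONS <- c("co-directional", "head-on")

#' Round half away from zero
#'
#' Integer reporting convention for catalog percentages (11/27 -> 41%),
#' as opposed to base R's round-half-to-even.
#' @param x Non-negative numeric.
#' @keywords internal
round_half_up <- function(x) floor(x + 0.5)

#' Build an insertion-record table
#'
#' @param locus Character vector of gene/region names.
#' @param orientation `"co-directional"` or `"head-on"` relative to
#'   chromosomal replication.
#' @param occurrences Positive integer count of independent transconjugants
#'   per site (default 1).
#' @param core_sequence Optional 17-base core per site (NA when unknown).
#' @param mismatches Optional integer mismatch count versus the primary
#'   site core (NA when unknown).
#' @return A data.frame of insertion records.
#' @export
insertion_records <- function(locus, orientation, occurrences = 1L,
                              core_sequence = NA_character_,
                              mismatches = NA_integer_) {
  orientation <- match.arg(orientation, ORIENTATIONS, several.ok = TRUE)
  rec <- data.frame(locus = as.character(locus),
                    orientation = orientation,
                    occurrences = as.integer(occurrences),
                    core_sequence = core_sequence,
                    mismatches = as.integer(mismatches),
                    stringsAsFactors = FALSE)
  if (any(rec$occurrences < 1L)) {
    stop("occurrences must be >= 1")
  }
  bad <- !is.na(rec$mismatches) &
    (rec$mismatches < 0L | rec$mismatches > CORE_WIDTH)
  if (any(bad)) {
    stop("mismatches must lie in 0..", CORE_WIDTH)
  }
  rec
}

#' Tally an insertion catalog into site-usage statistics
#'
#' Distinct sites are keyed by (locus, orientation); the same locus hit in
#' both orientations yields two sites.  Occurrences are summed within a
#' site, and each site's share of the total is reported as a percentage
#' rounded to the nearest integer (half away from zero).
#'
#' @param records Data.frame with columns `locus`, `orientation` and
#'   (optionally) `occurrences`; rows without `occurrences` count once.
#' @return An object of class `site_tally`: list with `sites` (data.frame
#'   of locus, orientation, occurrences, percent, ordered by decreasing
#'   occurrences then locus), `n_sites`, `total_insertions`, and
#'   `modal_site` (the first row of `sites`).
#' @examples
#' tally_sites(secondary_site_catalog())
#' @export
tally_sites <- function(records) {
  if (is.null(records) || nrow(as.data.frame(records)) == 0L) {
    stop("tally_sites() needs a nonempty record table")
  }
  records <- as.data.frame(records)
  if (!all(c("locus", "orientation") %in% names(records))) {
    stop("records must have 'locus' and 'orientation' columns")
  }
  if (is.null(records$occurrences)) {
    records$occurrences <- 1L
  }
  if (any(is.na(records$occurrences)) || any(records$occurrences < 1)) {
    stop("occurrences must be positive")
  }
  agg <- stats::aggregate(occurrences ~ locus + orientation,
                          data = records, FUN = sum)
  total <- sum(agg$occurrences)
  agg$percent <- round_half_up(100 * agg$occurrences / total)
  agg <- agg[order(-agg$occurrences, agg$locus, agg$orientation), ]
  rownames(agg) <- NULL
  structure(
    list(sites = agg,
         n_sites = nrow(agg),
         total_insertions = total,
         modal_site = agg[1L, ]),
    class = "site_tally"
  )
}

#' @export
print.site_tally <- function(x, ...) {
  cat(x$n_sites, "distinct sites over", x$total_insertions,
      "independent insertions\n")
  cat("modal site:", x$modal_site$locus,
      paste0("(", x$modal_site$orientation, ")"),
      paste0(x$modal_site$percent, "%"), "\n\n")
  print(x$sites, ...)
  invisible(x)
}

#' Reference catalog of ICEBs1 secondary-site insertions
#'
#' The occurrence table of 27 independent ICEBs1 transconjugants across 15
#' distinct secondary attachment sites in the *Bacillus subtilis*
#' chromosome (primary site absent): 11 insertions in `yrkM`, 3 in `mmsA`,
#' one in `yqhG` in each orientation, and 11 sites hit once.  Mismatch
#' counts versus the primary attB core are carried where reported for the
#' characterized sites; the 17-bp core sequences themselves are
#' user-supplied inputs and are left NA here.  Ten of the 15 sites are
#' co-directional with chromosomal replication; which specific singleton
#' sites are co-directional is a representative assignment (the tally
#' statistics depend only on site distinctness).
#'
#' @return A data.frame of insertion records (one row per site, with an
#'   `occurrences` column), suitable for [tally_sites()].
#' @export
secondary_site_catalog <- function() {
  insertion_records(
    locus = c("yrkM", "mmsA", "yqhG", "yqhG",
              "srfAA", "yycJ", "yisQ", "ykrP", "yghL", "spoVD",
              "ydbJ", "yomR", "yvbT", "yobJ", "ygxA-rrnD"),
    orientation = c("co-directional", "co-directional",
                    "co-directional", "head-on",
                    "co-directional", "co-directional", "co-directional",
                    "head-on", "co-directional", "co-directional",
                    "co-directional", "co-directional", "head-on",
                    "head-on", "head-on"),
    occurrences = c(11L, 3L, 1L, 1L, rep(1L, 11L)),
    mismatches = c(2L, 3L, NA, NA,
                   3L, 7L, NA, 12L, NA, 8L,
                   NA, NA, 11L, NA, NA)
  )
}
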