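# Structural constants of the attachment-site core: a 17 bp stem-loop with
# 5 bp inverted-repeat arms flanking the 7 bp spacer (crossover region).
CORE_WIDTH <- 17L
ARM_WIDTH <- 5L
SPACER_WIDTH <- 7L
SPACER_POSITIONS <- 6:12
ARM_POSITIONS <- c(1:5, 13:17)

#' Reverse complement of plain nucleotide strings
#'
#' Thin convenience over the usual byte-level complement-and-reverse, for
#' code paths where a full `Biostrings::DNAString` would be overhead.
#'
#' @param x Character vector of A/C/G/T strings.
#' @return Character vector of reverse complements.
#' @keywords internal
revcomp <- function(x) {
  vapply(x, function(s) {
    rawToChar(rev(charToRaw(chartr("ACGTacgt", "TGCAtgca", s))))
  }, character(1), USE.NAMES = FALSE)
}

#' Attachment-site core
#'
#' Decomposes a 17-base attachment-site core into its fixed 5 + 7 + 5
#' partition: a 5 bp left arm, the 7 bp spacer in which integrase-mediated
#' strand exchange (the crossover) occurs, and a 5 bp right arm.  For the
#' primary site the two arms form an inverted repeat (a perfect stem when
#' the core folds as a stem-loop); secondary sites need not satisfy this,
#' so the `perfect_stem` flag is informational, never an error.
#'
#' @param sequence A single 17-base string over A/C/G/T (case-insensitive),
#'   a `Biostrings::DNAString`, or an existing `att_core` (returned as-is).
#' @return An object of class `att_core`: a list with elements `sequence`,
#'   `left_arm`, `spacer`, `right_arm` and logical `perfect_stem` (TRUE iff
#'   the right arm is the reverse complement of the left arm).
#' @examples
#' core <- att_core("AAAAACCCCCCCTTTTT")
#' core$spacer        # "CCCCCCC"
#' core$perfect_stem  # TRUE: TTTTT is the reverse complement of AAAAA
#' @export
att_core <- function(sequence) {
  if (inherits(sequence, "att_core")) {
    return(sequence)
  }
  if (methods::is(sequence, "XString") || methods::is(sequence, "XStringSet")) {
    sequence <- as.character(sequence)
    if (length(sequence) != 1L) {
      stop("att_core() expects a single sequence, got ", length(sequence))
    }
  }
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence)) {
    stop("att_core() expects a single character string")
  }
  sequence <- toupper(sequence)
  if (nchar(sequence) != CORE_WIDTH) {
    stop("attachment-site core must be exactly ", CORE_WIDTH,
         " bases, got ", nchar(sequence))
  }
  if (grepl("[^ACGT]", sequence)) {
    stop("attachment-site core contains bases outside A/C/G/T ",
         "(ambiguity codes are rejected): ", sequence)
  }
  left <- substr(sequence, 1L, ARM_WIDTH)
  spacer <- substr(sequence, ARM_WIDTH + 1L, ARM_WIDTH + SPACER_WIDTH)
  right <- substr(sequence, ARM_WIDTH + SPACER_WIDTH + 1L, CORE_WIDTH)
  structure(
    list(sequence = sequence,
         left_arm = left,
         spacer = spacer,
         right_arm = right,
         perfect_stem = identical(right, revcomp(left))),
    class = "att_core"
  )
}

#' @export
as.character.att_core <- function(x, ...) x$sequence

#' @export
print.att_core <- function(x, ...) {
  cat("att_core:", x$left_arm, "|", x$spacer, "|", x$right_arm,
      if (x$perfect_stem) "(perfect stem)" else "(imperfect stem)", "\n")
  invisible(x)
}

#' Mismatch count between two attachment-site cores
#'
#' Hamming distance over the 17 core positions, the measure used to relate
#' secondary attachment sites to the primary site attB.
#'
#' @param site,reference 17-base strings or `att_core` objects.
#' @return Integer number of differing positions (0 iff identical).
#' @examples
#' mismatch_count("AAAAACCCCCCCTTTTT", "AAAAACCCCCCCTTTTT")  # 0
#' @export
mismatch_count <- function(site, reference) {
  a <- att_core(site)$sequence
  b <- att_core(reference)$sequence
  sum(charToRaw(a) != charToRaw(b))
}

#' Predict heteroduplex formation on the excised circle
#'
#' When an element integrates into a site whose 7 bp crossover spacer
#' differs from the element's own, chromosomal replication resolves the
#' mispaired spacer so that attL and attR carry different crossover
#' sequences; excision then produces a circular element with a heteroduplex
#' in its attachment site.  Arm differences alone never trigger this: the
#' crossover occurs only within the spacer.
#'
#' @param target Chromosomal target site core (`att_core` or string).
#' @param element_att The element's own attachment-site core.
#' @return TRUE iff the two spacers differ.
#' @export
predict_heteroduplex <- function(target, element_att) {
  att_core(target)$spacer != att_core(element_att)$spacer
}

#' Junction pair after integration
#'
#' @param attL_core,attR_core `att_core` objects for the left and right
#'   chromosome-element junctions.
#' @return An object of class `junction_pair`.
#' @export
junction_pair <- function(attL_core, attR_core) {
  structure(list(attL = att_core(attL_core), attR = att_core(attR_core)),
            class = "junction_pair")
}

#' @export
print.junction_pair <- function(x, ...) {
  cat("junction_pair\n  attL:", x$attL$sequence,
      "\n  attR:", x$attR$sequence, "\n")
  invisible(x)
}

#' Integrate an element into a (possibly secondary) target site
#'
#' Models site-specific integration followed by replication-resolution of
#' any spacer mispairing.  Arms follow provenance: attL is the junction
#' whose outer (left) arm comes from the chromosome and inner (right) arm
#' from the element; attR is the reverse.  The crossover spacers of attL
#' and attR end up different whenever target and element spacers differ;
#' which junction inherits which spacer is a resolution convention, set by
#' `attL_spacer` (default: attL carries the chromosomal target spacer, attR
#' the element spacer).  All downstream heteroduplex logic depends only on
#' spacer inequality, so the convention is isolated here.
#'
#' @param target Chromosomal target site core.
#' @param element_att The element's attachment-site core.
#' @param attL_spacer Which spacer the left junction inherits:
#'   `"chromosome"` (default) or `"element"`.
#' @return A `junction_pair`.
#' @seealso [excise_site()], [predict_heteroduplex()]
#' @export
integrate_site <- function(target, element_att,
                           attL_spacer = c("chromosome", "element")) {
  attL_spacer <- match.arg(attL_spacer)
  t <- att_core(target)
  e <- att_core(element_att)
  if (attL_spacer == "chromosome") {
    sL <- t$spacer
    sR <- e$spacer
  } else {
    sL <- e$spacer
    sR <- t$spacer
  }
  junction_pair(
    attL_core = paste0(t$left_arm, sL, e$right_arm),
    attR_core = paste0(e$left_arm, sR, t$right_arm)
  )
}

#' Excise an integrated element from its junction pair
#'
#' Recombination between attL and attR releases a circular element carrying
#' a reconstituted attachment site (element-provenance arms) and leaves a
#' restored "empty" chromosomal site (chromosome-provenance arms).  If the
#' two junction spacers differ, the circle's attachment site is a
#' heteroduplex: its two strands disagree in the crossover region.
#'
#' Spacer composition is recorded by the same convention as
#' [integrate_site()]: the empty site takes the attL spacer and the circle
#' takes the attR spacer, so with default conventions
#' `excise_site(integrate_site(t, e))` reconstructs `t` as the empty site
#' and `e` as the circle attachment site.
#'
#' @param junctions A `junction_pair`.
#' @return An object of class `excision_products`: list with `circle_att`
#'   (`att_core`), `empty_site` (`att_core`) and logical `heteroduplex`
#'   (TRUE iff the attL and attR spacers differ).
#' @export
excise_site <- function(junctions) {
  if (!inherits(junctions, "junction_pair")) {
    stop("excise_site() expects a junction_pair")
  }
  attL <- junctions$attL
  attR <- junctions$attR
  structure(
    list(
      circle_att = att_core(paste0(attR$left_arm, attR$spacer, attL$right_arm)),
      empty_site = att_core(paste0(attL$left_arm, attL$spacer, attR$right_arm)),
      heteroduplex = attL$spacer != attR$spacer
    ),
    class = "excision_products"
  )
}

#' @export
print.excision_products <- function(x, ...) {
  cat("excision products\n  circle att:", x$circle_att$sequence,
      if (x$heteroduplex) "(heteroduplex)" else "(homoduplex)",
      "\n  empty site:", x$empty_site$sequence, "\n")
  invisible(x)
}
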