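# Direct-repeat analysis at deletion junctions.
#
# Large mtDNA deletions are thought to arise from mismatched pairing between
# two homologous sequence tracts, one at each breakpoint. When the tracts
# pair in register, the repeat is the longest run of positions i at which
# the base at bp5 + i equals the base at (bp3 - 1) + i: the 5' copy sits at
# the end of the retained 5' segment, the homologous copy at the end of the
# deleted segment. This in-register (single-diagonal) definition reproduces
# published junction repeat lengths and their allele-induced changes.

#' Maximal perfect direct repeat at a deletion junction
#'
#' With breakpoints `bp5`/`bp3` (last retained and first retained base), the
#' two homologous tracts are anchored at `bp5` and at `bp3 - 1` (the last
#' deleted base). The repeat is the longest consecutive run of offsets `i`
#' in `[-window, window]` with identical bases at `bp5 + i` and
#' `bp3 - 1 + i` (case-insensitive; `N` never matches). Ties are broken by
#' the run closest to the junction (offset 0), then by the leftmost run.
#'
#' @param genome A `mito_genome`.
#' @param bp5 Last retained base on the 5' side of the junction (1-based).
#' @param bp3 First retained base on the 3' side.
#' @param window Offset half-width in bp around the junction anchors
#'   (default 15).
#' @return A `repeat_assessment`: list with `bp5`, `bp3`, `repeat_length`,
#'   `copy5_span`, `copy3_span` (integer `c(start, end)`), `repeat_sequence`.
#'   A junction with no matching offset yields `repeat_length` 0.
#' @examples
#' mt <- rcrs_genome()
#' max_direct_repeat(mt, 8471, 13449)$repeat_length  # the 13-bp repeat
#' @export
max_direct_repeat <- function(genome, bp5, bp3, window = 15L) {
  stopifnot(inherits(genome, "mito_genome"), window >= 1L)
  gl <- genome$length
  a5 <- bp5          # anchor of the 5' copy
  a3 <- bp3 - 1L     # anchor of the homologous copy (last deleted base)
  if (a5 - window < 1L || a3 - window < 1L ||
      a5 + window > gl || a3 + window > gl) {
    stop("window extends past genome bounds (circular wrap in windows is ",
         "not enabled)", call. = FALSE)
  }
  offs <- -window:window
  s5 <- strsplit(toupper(substr(genome$sequence, a5 - window, a5 + window)),
                 "")[[1L]]
  s3 <- strsplit(toupper(substr(genome$sequence, a3 - window, a3 + window)),
                 "")[[1L]]
  ok <- s5 == s3 & s5 != "N"
  # longest run of TRUE; ties by proximity to offset 0, then leftmost
  best <- list(len = 0L, dist = Inf, start = NA_integer_)
  run_start <- NA_integer_
  for (k in seq_along(ok)) {
    if (ok[k] && is.na(run_start)) run_start <- k
    if ((!ok[k] || k == length(ok)) && !is.na(run_start)) {
      run_end <- if (ok[k]) k else k - 1L
      len <- run_end - run_start + 1L
      lo <- offs[run_start]; hi <- offs[run_end]
      dist <- if (lo <= 0L && hi >= 0L) 0L else min(abs(lo), abs(hi))
      if (len > best$len || (len == best$len && dist < best$dist)) {
        best <- list(len = len, dist = dist, start = run_start)
      }
      run_start <- NA_integer_
    }
  }
  if (best$len == 0L) {
    return(structure(
      list(bp5 = bp5, bp3 = bp3, repeat_length = 0L,
           copy5_span = c(NA_integer_, NA_integer_),
           copy3_span = c(NA_integer_, NA_integer_),
           repeat_sequence = ""),
      class = "repeat_assessment"
    ))
  }
  i0 <- offs[best$start]
  i1 <- i0 + best$len - 1L
  structure(
    list(
      bp5 = bp5, bp3 = bp3, repeat_length = best$len,
      copy5_span = c(a5 + i0, a5 + i1),
      copy3_span = c(a3 + i0, a3 + i1),
      repeat_sequence = substr(genome$sequence, a5 + i0, a5 + i1)
    ),
    class = "repeat_assessment"
  )
}

#' @export
print.repeat_assessment <- function(x, ...) {
  cat("junction", paste0(x$bp5, "-", x$bp3), ": repeat",
      x$repeat_length, "bp", x$repeat_sequence, "\n")
  cat("  copy5", paste(x$copy5_span, collapse = "-"),
      " copy3", paste(x$copy3_span, collapse = "-"), "\n")
  invisible(x)
}

#' Repeat-length change induced by an allele substitution
#'
#' Computes the maximal junction repeat on the reference genome and again
#' after substituting the alternate allele, returning both lengths.
#'
#' @param genome A `mito_genome` (reference state).
#' @param bp5,bp3 Junction breakpoints as in [max_direct_repeat()].
#' @param substitution A list or data.frame row with `position`, `ref`,
#'   `alt` (see [allele_substitution()]).
#' @param window Offset half-width (default 15).
#' @return Named numeric vector `c(ref_length, alt_length)`.
#' @export
repeat_delta <- function(genome, bp5, bp3, substitution, window = 15L) {
  pos <- substitution$position
  observed <- substr(genome$sequence, pos, pos)
  if (!identical(toupper(observed), toupper(substitution$ref))) {
    stop("substitution ref allele '", substitution$ref,
         "' does not match genome base '", observed, "' at position ", pos,
         call. = FALSE)
  }
  if (min(abs(pos - bp5), abs(pos - (bp3 - 1L))) > window) {
    warning("substitution at ", pos, " lies outside both junction windows",
            call. = FALSE)
  }
  ref_len <- max_direct_repeat(genome, bp5, bp3, window)$repeat_length
  alt_genome <- substitute_allele(genome, pos, substitution$alt)
  alt_len <- max_direct_repeat(alt_genome, bp5, bp3, window)$repeat_length
  c(ref_length = ref_len, alt_length = alt_len)
}

#' Construct an allele substitution
#'
#' @param position 1-based position.
#' @param ref,alt Reference and alternate bases (must differ).
#' @param label Optional label such as `"T14798C"`; derived from the alleles
#'   when missing.
#' @return A list with class `allele_substitution`.
#' @export
allele_substitution <- function(position, ref, alt, label = NULL) {
  ref <- toupper(ref); alt <- toupper(alt)
  stopifnot(ref %in% c("A", "C", "G", "T"), alt %in% c("A", "C", "G", "T"))
  if (ref == alt) stop("ref and alt alleles must differ", call. = FALSE)
  if (is.null(label)) label <- paste0(ref, position, alt)
  structure(list(position = position, ref = ref, alt = alt, label = label),
            class = "allele_substitution")
}

#' Classify a repeat-length change
#'
#' @param ref_length,alt_length Repeat lengths under the reference and
#'   alternate allele.
#' @return `"lengthens"`, `"shortens"` or `"neutral"`.
#' @export
classify_delta <- function(ref_length, alt_length) {
  stopifnot(ref_length >= 0, alt_length >= 0)
  if (alt_length > ref_length) "lengthens"
  else if (alt_length < ref_length) "shortens"
  else "neutral"
}
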