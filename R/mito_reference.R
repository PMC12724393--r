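# Circular mitochondrial reference genome and the rCRS feature catalog.
#
# All coordinates are 1-based inclusive, following rCRS convention.
# Spans with start > end wrap through the origin (position length -> 1).

#' Load a circular mitochondrial reference genome
#'
#' Reads a single-record FASTA file and returns a `mito_genome` object with
#' circular semantics. The sequence is uppercased and restricted to the
#' alphabet A/C/G/T/N.
#'
#' @param fasta Path to a FASTA file containing exactly one record.
#' @return A `mito_genome` object: a list with elements `name`, `sequence`
#'   (uppercase character scalar), `length` (bp) and `circular` (always
#'   `TRUE`).
#' @examples
#' mt <- load_genome(rcrs_fasta())
#' mt$length
#' @export
load_genome <- function(fasta) {
  set <- Biostrings::readDNAStringSet(fasta)
  if (length(set) != 1L) {
    stop("ambiguous reference: FASTA contains ", length(set),
         " records, expected exactly 1", call. = FALSE)
  }
  seq <- toupper(as.character(set[[1L]]))
  bad <- setdiff(unique(strsplit(seq, "")[[1L]]), c("A", "C", "G", "T", "N"))
  if (length(bad) > 0L) {
    stop("alphabet error: sequence contains characters outside {A,C,G,T,N}: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(
    list(name = names(set)[1L], sequence = seq, length = nchar(seq),
         circular = TRUE),
    class = "mito_genome"
  )
}

#' @export
print.mito_genome <- function(x, ...) {
  cat("mito_genome:", x$name, "(", x$length, "bp, circular )\n")
  invisible(x)
}

#' Path to the vendored rCRS reference FASTA
#'
#' Returns the installed path of the revised Cambridge Reference Sequence
#' (rCRS, NC_012920.1, 16,569 bp), the coordinate system for every annotation
#' in this package.
#'
#' @return Path to the FASTA file.
#' @export
rcrs_fasta <- function() {
  system.file("extdata", "rCRS_NC_012920.fasta", package = "mtaging",
              mustWork = TRUE)
}

#' Load the vendored rCRS genome
#'
#' @return A `mito_genome` for the rCRS (length 16,569 bp).
#' @export
rcrs_genome <- function() {
  load_genome(rcrs_fasta())
}

#' Substitute a single allele in a genome
#'
#' Returns a copy of the genome differing only at `position`, used to assess
#' how an alternate allele changes junction repeat structure.
#'
#' @param genome A `mito_genome`.
#' @param position 1-based position to change.
#' @param base Replacement base, one of A/C/G/T.
#' @return A `mito_genome` copy carrying the substitution.
#' @export
substitute_allele <- function(genome, position, base) {
  stopifnot(inherits(genome, "mito_genome"))
  if (length(position) != 1L || is.na(position) || position < 1L ||
      position > genome$length) {
    stop("position out of range [1, ", genome$length, "]", call. = FALSE)
  }
  base <- toupper(base)
  if (!base %in% c("A", "C", "G", "T")) {
    stop("invalid base '", base, "': must be one of A, C, G, T",
         call. = FALSE)
  }
  out <- genome
  substr(out$sequence, position, position) <- base
  out
}

## ---------------------------------------------------------------------------
## rCRS feature catalog
## ---------------------------------------------------------------------------

# Standard rCRS gene coordinates (NC_012920.1 annotation). The respiratory
# chain complex totals these imply: III = 1141 bp, IV = 3010 bp, V = 888 bp,
# I = 6356 bp. Microprotein spans: mtALTND4 11557-11856, SHMOOSE 12234-12410,
# gau 6288-6590; humanin, MOTS-c and the SHLP family lie inside the two rRNA
# genes between 1343 and 3052.
.rcrs_features <- function() {
  p <- function(name, start, end, complex) {
    data.frame(name = name, category = "protein", start = start, end = end,
               complex = complex, stringsAsFactors = FALSE)
  }
  t <- function(name, start, end) {
    data.frame(name = name, category = "tRNA", start = start, end = end,
               complex = NA_character_, stringsAsFactors = FALSE)
  }
  o <- function(name, category, start, end) {
    data.frame(name = name, category = category, start = start, end = end,
               complex = NA_character_, stringsAsFactors = FALSE)
  }
  rbind(
    ## 13 protein-coding genes with complex assignment
    p("MT-ND1",  3307,  4262, "I"),
    p("MT-ND2",  4470,  5511, "I"),
    p("MT-CO1",  5904,  7445, "IV"),
    p("MT-CO2",  7586,  8269, "IV"),
    p("MT-ATP8", 8366,  8572, "V"),
    p("MT-ATP6", 8527,  9207, "V"),
    p("MT-CO3",  9207,  9990, "IV"),
    p("MT-ND3", 10059, 10404, "I"),
    p("MT-ND4L", 10470, 10766, "I"),
    p("MT-ND4", 10760, 12137, "I"),
    p("MT-ND5", 12337, 14148, "I"),
    p("MT-ND6", 14149, 14673, "I"),
    p("MT-CYB", 14747, 15887, "III"),
    ## 22 tRNAs
    t("MT-TF",   577,   647),
    t("MT-TV",  1602,  1670),
    t("MT-TL1", 3230,  3304),
    t("MT-TI",  4263,  4331),
    t("MT-TQ",  4329,  4400),
    t("MT-TM",  4402,  4469),
    t("MT-TW",  5512,  5579),
    t("MT-TA",  5587,  5655),
    t("MT-TN",  5657,  5729),
    t("MT-TC",  5761,  5826),
    t("MT-TY",  5826,  5891),
    t("MT-TS1", 7446,  7514),
    t("MT-TD",  7518,  7585),
    t("MT-TK",  8295,  8364),
    t("MT-TG",  9991, 10058),
    t("MT-TR", 10405, 10469),
    t("MT-TH", 12138, 12206),
    t("MT-TS2", 12207, 12265),
    t("MT-TL2", 12266, 12336),
    t("MT-TE", 14674, 14742),
    t("MT-TT", 15888, 15953),
    t("MT-TP", 15956, 16023),
    ## 2 rRNAs
    o("MT-RNR1", "rRNA",  648, 1601),
    o("MT-RNR2", "rRNA", 1671, 3229),
    ## replication origins
    o("OH", "origin",  110,  441),
    o("OL", "origin", 5721, 5798),
    ## control region wraps the origin of the coordinate system
    o("control_region", "control_region", 16024, 576),
    ## 11 mitochondrial-derived microproteins. mtALTND4, SHMOOSE and gau use
    ## their published spans; humanin, MOTS-c and SHLP1-6 use literature open
    ## reading frames inside MT-RNR1/MT-RNR2 (all within 1343-3052).
    o("MOTS-c",  "MDP", 1343, 1393),
    o("SHLP2",   "MDP", 1764, 1844),
    o("SHLP3",   "MDP", 1982, 2095),
    o("SHLP4",   "MDP", 2061, 2141),
    o("SHLP1",   "MDP", 2485, 2559),
    o("humanin", "MDP", 2634, 2707),
    o("SHLP5",   "MDP", 2863, 2937),
    o("SHLP6",   "MDP", 2992, 3052),
    o("gau",     "MDP", 6288, 6590),
    o("mtALTND4", "MDP", 11557, 11856),
    o("SHMOOSE", "MDP", 12234, 12410)
  )
}

#' The hard-coded rCRS feature catalog
#'
#' Returns the annotation catalog used for deletion impact prediction: the 13
#' protein-coding genes with their respiratory-chain complex assignments
#' (Complex I: 7 genes, III: 1, IV: 3, V: 2), 22 tRNAs, 2 rRNAs, the heavy-
#' and light-strand replication origins, the control region, and 11
#' mitochondrial-derived microproteins (MDPs). Each feature is additionally
#' labelled `major` or `minor` arc: positions between the heavy-strand origin
#' region and the light-strand origin (OL, 5721-5798) form the minor arc;
#' everything else is major arc. A feature's arc is the arc holding the
#' majority of its bases.
#'
#' @param genome_length Genome length in bp (default 16569, the rCRS).
#' @return A `mito_catalog`: a data.frame with columns `name`, `category`,
#'   `start`, `end`, `complex`, `arc`, and attribute `genome_length`.
#' @examples
#' cat <- default_catalog()
#' subset(cat, category == "MDP")
#' @export
default_catalog <- function(genome_length = 16569L) {
  feats <- .rcrs_features()
  # minor arc: from the heavy-strand origin region (start of OH) through the
  # end of OL; the rest of the circle (holding most deletions) is major arc
  minor_lo <- 110L
  minor_hi <- 5798L
  in_minor <- function(start, end) {
    pieces <- .span_pieces(start, end, genome_length)
    pos_in <- sum(pmax(0L, pmin(pieces[, 2L], minor_hi) -
                         pmax(pieces[, 1L], minor_lo) + 1L))
    width <- sum(pieces[, 2L] - pieces[, 1L] + 1L)
    pos_in > width / 2
  }
  feats$arc <- ifelse(mapply(in_minor, feats$start, feats$end),
                      "minor", "major")
  structure(feats, genome_length = genome_length,
            class = c("mito_catalog", "data.frame"))
}

#' Total mtDNA-encoded length of a respiratory-chain complex
#'
#' Sums the widths of the member protein genes of one complex: Complex III
#' (MT-CYB) totals 1141 bp, Complex IV (MT-CO1/2/3) 3010 bp, Complex V
#' (MT-ATP6/8) 888 bp, and Complex I (the seven ND genes) 6356 bp under
#' standard rCRS coordinates.
#'
#' @param catalog A `mito_catalog`.
#' @param complex_id One of `"I"`, `"III"`, `"IV"`, `"V"`.
#' @return Total length in bp.
#' @export
complex_length <- function(catalog, complex_id) {
  if (!complex_id %in% c("I", "III", "IV", "V")) {
    stop("unknown complex id '", complex_id, "'", call. = FALSE)
  }
  members <- catalog[!is.na(catalog$complex) & catalog$complex == complex_id, ]
  sum(members$end - members$start + 1L)
}

# decompose a circular span into 1 or 2 linear pieces; returns a 2-col matrix
.span_pieces <- function(start, end, genome_length) {
  if (start <= end) {
    matrix(c(start, end), ncol = 2L)
  } else {
    matrix(c(start, genome_length, 1L, end), ncol = 2L, byrow = TRUE)
  }
}

# bases shared between two circular spans
.circular_overlap <- function(s1, e1, s2, e2, genome_length) {
  a <- .span_pieces(s1, e1, genome_length)
  b <- .span_pieces(s2, e2, genome_length)
  total <- 0L
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      total <- total + max(0L, min(a[i, 2L], b[j, 2L]) -
                             max(a[i, 1L], b[j, 1L]) + 1L)
    }
  }
  total
}

#' Features overlapping a (possibly wrapping) span
#'
#' Returns every catalog feature sharing at least one base with the query
#' span, tagged `removed` when fully contained in the span or `truncated`
#' when partially overlapping. A span with `start > end` wraps through the
#' origin. Passing `NA` for both bounds (the empty-span sentinel) returns an
#' empty result.
#'
#' @param catalog A `mito_catalog`.
#' @param span_start,span_end 1-based inclusive bounds of the query span, or
#'   both `NA` for an empty span.
#' @return A data.frame with the catalog columns plus `impact`
#'   (`"removed"`/`"truncated"`) and `overlap_bp`.
#' @export
features_in_span <- function(catalog, span_start, span_end) {
  gl <- attr(catalog, "genome_length")
  empty <- catalog[0L, , drop = FALSE]
  empty$impact <- character(0)
  empty$overlap_bp <- integer(0)
  if (is.na(span_start) && is.na(span_end)) {
    return(empty)
  }
  if (any(c(span_start, span_end) < 1L) || any(c(span_start, span_end) > gl)) {
    stop("span positions out of range [1, ", gl, "]", call. = FALSE)
  }
  ov <- mapply(function(s, e) {
    .circular_overlap(span_start, span_end, s, e, gl)
  }, catalog$start, catalog$end)
  hit <- ov > 0L
  out <- catalog[hit, , drop = FALSE]
  width <- out$end - out$start + 1L
  width[out$start > out$end] <- gl - out$start[out$start > out$end] + 1L +
    out$end[out$start > out$end]
  out$impact <- ifelse(ov[hit] == width, "removed", "truncated")
  out$overlap_bp <- as.integer(ov[hit])
  rownames(out) <- NULL
  out
}

## ---------------------------------------------------------------------------
## catalog export
## ---------------------------------------------------------------------------

# catalog as GRanges; wrap features are split into two ranges sharing a name
.catalog_granges <- function(catalog, seqname = "chrM") {
  gl <- attr(catalog, "genome_length")
  rows <- lapply(seq_len(nrow(catalog)), function(i) {
    pieces <- .span_pieces(catalog$start[i], catalog$end[i], gl)
    data.frame(start = pieces[, 1L], end = pieces[, 2L],
               name = catalog$name[i], category = catalog$category[i],
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = seqname,
    ranges = IRanges::IRanges(start = df$start, end = df$end),
    name = df$name, type = df$category
  )
  GenomicRanges::seqinfo(gr) <- GenomeInfoDb::Seqinfo(
    seqnames = seqname, seqlengths = gl, isCircular = TRUE
  )
  gr
}

#' Export the feature catalog as BED or GFF3
#'
#' Internal 1-based inclusive coordinates are converted to the conventions of
#' each format (0-based half-open for BED). Features wrapping the origin are
#' split into two records sharing the feature name.
#'
#' @param catalog A `mito_catalog`.
#' @param file Output path; the format is chosen by `format`.
#' @param format `"bed"` or `"gff3"`.
#' @return The output path, invisibly.
#' @export
export_catalog <- function(catalog, file, format = c("bed", "gff3")) {
  format <- match.arg(format)
  gr <- .catalog_granges(catalog)
  if (format == "bed") {
    rtracklayer::export.bed(gr, file)
  } else {
    rtracklayer::export.gff3(gr, file)
  }
  invisible(file)
}
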