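# Large mtDNA deletion tables, burden metrics and impact annotation.
#
# Breakpoint convention: bp5 and bp3 are the last and first *retained* bases,
# so the deleted span is [bp5 + 1, bp3 - 1] and the deletion size is
# bp3 - bp5 - 1. Under this convention the canonical "common deletion"
# junction 8471-13449 removes 4977 bp.

.COMMON_DELETION <- c(8471L, 13449L)

#' Read a per-sample deletion breakpoint table
#'
#' Parses a tab-delimited table in the style of a junction caller's
#' unfiltered large-deletion output. Required columns (case-insensitive,
#' flexible naming): sample id, 5' breakpoint, 3' breakpoint, supporting
#' reads, deletion read percent, benchmark coverage. Rows violating the call
#' invariants are rejected with row-numbered diagnostics. Junctions wrapping
#' the origin (bp3 <= bp5) are accepted but flagged in the `wraps` column.
#'
#' @param tsv Path to the table.
#' @return Data.frame of deletion calls: `sample_id`, `bp5`, `bp3`,
#'   `supporting_reads`, `read_pct`, `benchmark_coverage`, `wraps`.
#' @export
read_deletion_table <- function(tsv) {
  raw <- utils::read.delim(tsv, stringsAsFactors = FALSE, check.names = FALSE)
  cols <- tolower(gsub("[^a-z0-9]", "", tolower(names(raw))))
  pick <- function(options, what) {
    idx <- which(cols %in% options)[1L]
    if (is.na(idx)) {
      stop("deletion table is missing a ", what, " column", call. = FALSE)
    }
    raw[[idx]]
  }
  out <- data.frame(
    sample_id = as.character(pick(c("sample", "sampleid", "id"), "sample id")),
    bp5 = as.integer(pick(c("bp5", "break5", "5breakpoint", "fiveprime",
                            "deletionstart"), "5' breakpoint")),
    bp3 = as.integer(pick(c("bp3", "break3", "3breakpoint", "threeprime",
                            "deletionend"), "3' breakpoint")),
    supporting_reads = as.numeric(pick(c("reads", "supportingreads",
                                         "deletionreads"),
                                       "supporting reads")),
    read_pct = as.numeric(pick(c("readpct", "deletionreadpct", "readrate",
                                 "deletionread"), "deletion read %")),
    benchmark_coverage = as.numeric(pick(c("benchmarkcoverage", "benchmark",
                                           "mtbenchmarkcoverage"),
                                         "benchmark coverage")),
    stringsAsFactors = FALSE
  )
  if (nrow(out) == 0L) {
    out$wraps <- logical(0)
    return(out)
  }
  out$wraps <- out$bp3 <= out$bp5
  bad <- which(is.na(out$bp5) | is.na(out$bp3) |
                 (!out$wraps & out$bp3 <= out$bp5 + 1L) |
                 is.na(out$read_pct) | out$read_pct < 0 |
                 is.na(out$benchmark_coverage) | out$benchmark_coverage <= 0)
  if (length(bad) > 0L) {
    stop("invalid deletion rows (1-based, excluding header): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  out
}

#' Deleted bases of a junction
#'
#' With bp5/bp3 the last/first retained bases, the size is
#' `bp3 - bp5 - 1`; wrapped junctions are measured circularly.
#'
#' @param bp5,bp3 Breakpoints (vectorised).
#' @param genome_length Genome length for circular sizes (default 16569).
#' @return Integer vector of deletion sizes in bp.
#' @examples
#' deletion_size(8471, 13449)  # the 4977-bp common deletion
#' @export
deletion_size <- function(bp5, bp3, genome_length = 16569L) {
  ifelse(bp3 > bp5, bp3 - bp5 - 1L, genome_length - (bp5 - bp3) - 1L)
}

#' Predicted impact of one deletion
#'
#' Annotates the deleted span `[bp5 + 1, bp3 - 1]` against the feature
#' catalog: impacted genes with removed/truncated status, the respiratory
#' complexes those genes belong to, impacted tRNAs and microproteins, and
#' whether the light-strand replication origin is removed or truncated.
#'
#' @param bp5,bp3 Junction breakpoints (last/first retained bases).
#' @param catalog A `mito_catalog`.
#' @return An `impact_annotation`: list with `genes` (data.frame of name and
#'   impact), `complexes`, `tRNAs`, `MDPs`, `removes_OL`.
#' @examples
#' ann <- annotate_impact(8471, 13449, default_catalog())
#' ann$complexes
#' @export
annotate_impact <- function(bp5, bp3, catalog) {
  gl <- attr(catalog, "genome_length")
  size <- deletion_size(bp5, bp3, gl)
  if (size <= 0L) {
    hits <- features_in_span(catalog, NA, NA)
  } else {
    del_start <- if (bp5 == gl) 1L else bp5 + 1L
    del_end <- if (bp3 == 1L) gl else bp3 - 1L
    hits <- features_in_span(catalog, del_start, del_end)
  }
  genes <- hits[hits$category == "protein", c("name", "impact", "complex")]
  rownames(genes) <- NULL
  structure(
    list(
      genes = genes,
      complexes = sort(unique(genes$complex)),
      tRNAs = hits$name[hits$category == "tRNA"],
      MDPs = hits$name[hits$category == "MDP"],
      removes_OL = "OL" %in% hits$name
    ),
    class = "impact_annotation"
  )
}

#' The default Top-30 junction catalog
#'
#' Cumulative "Top 30" burden is measured against a catalog of frequently
#' observed, validated junctions from prior work. Only the common deletion
#' junction (8471-13449) is fixed by this package; the remaining entries of
#' the full published catalog live in that publication's supplement, so the
#' default here ships the common deletion plus a clearly labelled synthetic
#' placeholder list, and analyses of real data should supply the published
#' catalog via `top30`.
#'
#' @return Data.frame with columns `bp5`, `bp3`.
#' @export
default_top30_catalog <- function() {
  path <- system.file("extdata", "top30_catalog_synthetic.tsv",
                      package = "mtaging", mustWork = TRUE)
  utils::read.delim(path, comment.char = "#")
}

#' Per-sample deletion burden metrics
#'
#' Computes the normalised burden metrics for one sample: unique deletions
#' per 10,000x benchmark coverage, cumulative deletion read %, the same
#' stratified by size (< 1000 bp vs >= 1000 bp), cumulative read % of Top-30
#' catalog junctions, read % of the common deletion (8471-13449), and
#' cumulative read % impacting each respiratory complex, tRNA and
#' microprotein.
#'
#' Unique deletions are distinct (bp5, bp3) junctions regardless of read
#' support; a minimum supporting-read filter can be applied via `min_reads`.
#'
#' @param calls Deletion calls for a single sample
#'   (see [read_deletion_table()]).
#' @param catalog A `mito_catalog`.
#' @param top30 Data.frame of Top-30 junctions (`bp5`, `bp3`); default
#'   [default_top30_catalog()].
#' @param min_reads Minimum supporting reads for a call to count (default 0,
#'   no filter).
#' @return One-row data.frame of metrics; per-feature columns are prefixed
#'   `cplx_`, `trna_`, `mdp_`.
#' @export
sample_metrics <- function(calls, catalog, top30 = default_top30_catalog(),
                           min_reads = 0) {
  gl <- attr(catalog, "genome_length")
  if (nrow(calls) > 0L) {
    if (length(unique(calls$sample_id)) > 1L) {
      stop("sample_metrics expects calls from a single sample", call. = FALSE)
    }
    if (length(unique(calls$benchmark_coverage)) > 1L) {
      stop("inconsistent benchmark coverage within a sample", call. = FALSE)
    }
    calls <- calls[calls$supporting_reads >= min_reads, , drop = FALSE]
  }
  complexes <- c("I", "III", "IV", "V")
  trnas <- catalog$name[catalog$category == "tRNA"]
  mdps <- catalog$name[catalog$category == "MDP"]
  zero <- function(names, prefix) {
    stats::setNames(rep(0, length(names)),
                    paste0(prefix, gsub("[^A-Za-z0-9]", "_", names)))
  }
  base <- data.frame(
    deletions_per_10k = 0, cumulative_read_pct = 0,
    read_pct_lt1000 = 0, read_pct_ge1000 = 0,
    top30_read_pct = 0, common_del_read_pct = 0
  )
  per_feat <- c(zero(complexes, "cplx_"), zero(trnas, "trna_"),
                zero(mdps, "mdp_"))
  if (nrow(calls) == 0L) {
    return(cbind(base, as.data.frame(as.list(per_feat))))
  }
  sizes <- deletion_size(calls$bp5, calls$bp3, gl)
  junction <- paste(calls$bp5, calls$bp3)
  base$deletions_per_10k <-
    length(unique(junction)) / calls$benchmark_coverage[1L] * 10000
  base$cumulative_read_pct <- sum(calls$read_pct)
  base$read_pct_lt1000 <- sum(calls$read_pct[sizes < 1000L])
  base$read_pct_ge1000 <- sum(calls$read_pct[sizes >= 1000L])
  base$top30_read_pct <-
    sum(calls$read_pct[junction %in% paste(top30$bp5, top30$bp3)])
  base$common_del_read_pct <-
    sum(calls$read_pct[calls$bp5 == .COMMON_DELETION[1L] &
                         calls$bp3 == .COMMON_DELETION[2L]])
  for (i in seq_len(nrow(calls))) {
    ann <- annotate_impact(calls$bp5[i], calls$bp3[i], catalog)
    for (cx in ann$complexes) {
      nm <- paste0("cplx_", cx)
      per_feat[nm] <- per_feat[nm] + calls$read_pct[i]
    }
    for (tr in ann$tRNAs) {
      nm <- paste0("trna_", gsub("[^A-Za-z0-9]", "_", tr))
      per_feat[nm] <- per_feat[nm] + calls$read_pct[i]
    }
    for (md in ann$MDPs) {
      nm <- paste0("mdp_", gsub("[^A-Za-z0-9]", "_", md))
      per_feat[nm] <- per_feat[nm] + calls$read_pct[i]
    }
  }
  cbind(base, as.data.frame(as.list(per_feat)))
}

#' Cohort-level metric summary by region
#'
#' Joins per-sample metrics to sample metadata and summarises each metric per
#' region (mean and SD), with the fold change of region means relative to the
#' reference region.
#'
#' @param metrics Data.frame of per-sample metrics with a `sample_id` column
#'   (one row per sample, remaining columns numeric).
#' @param metadata Data.frame with `sample_id` and `region`.
#' @param reference_region Region used as the fold-change denominator
#'   (default `"CER"`).
#' @return Long data.frame: `metric`, one `mean_`/`sd_` column pair per
#'   region, and `fold_change` (= mean of the non-reference region divided by
#'   the reference mean; `NA` when the reference mean is 0).
#' @export
cohort_summary <- function(metrics, metadata, reference_region = "CER") {
  merged <- merge(metrics, metadata[, c("sample_id", "region")],
                  by = "sample_id")
  regions <- unique(metadata$region)
  empty <- setdiff(regions, unique(merged$region))
  if (length(empty) > 0L) {
    stop("region with zero samples: ", paste(empty, collapse = ", "),
         call. = FALSE)
  }
  metric_cols <- setdiff(names(metrics), "sample_id")
  out <- data.frame(metric = metric_cols, stringsAsFactors = FALSE)
  for (r in regions) {
    sub <- merged[merged$region == r, metric_cols, drop = FALSE]
    out[[paste0("mean_", r)]] <- vapply(sub, mean, numeric(1))
    out[[paste0("sd_", r)]] <- vapply(sub, stats::sd, numeric(1))
  }
  other <- setdiff(regions, reference_region)
  if (reference_region %in% regions && length(other) == 1L) {
    ref_mean <- out[[paste0("mean_", reference_region)]]
    out$fold_change <- ifelse(ref_mean == 0, NA_real_,
                              out[[paste0("mean_", other)]] / ref_mean)
  }
  out
}

#' Long-format impact table for a set of deletion calls
#'
#' One row per (sample, junction, impacted feature) for export alongside the
#' per-sample metrics.
#'
#' @param calls Deletion calls (any number of samples).
#' @param catalog A `mito_catalog`.
#' @return Data.frame: `sample_id`, `bp5`, `bp3`, `feature`, `category`,
#'   `impact`.
#' @export
impact_table <- function(calls, catalog) {
  rows <- lapply(seq_len(nrow(calls)), function(i) {
    size <- deletion_size(calls$bp5[i], calls$bp3[i],
                          attr(catalog, "genome_length"))
    if (size <= 0L) return(NULL)
    hits <- features_in_span(catalog, calls$bp5[i] + 1L, calls$bp3[i] - 1L)
    if (nrow(hits) == 0L) return(NULL)
    data.frame(sample_id = calls$sample_id[i], bp5 = calls$bp5[i],
               bp3 = calls$bp3[i], feature = hits$name,
               category = hits$category, impact = hits$impact,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(sample_id = character(0), bp5 = integer(0),
                      bp3 = integer(0), feature = character(0),
                      category = character(0), impact = character(0))
  }
  out
}
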