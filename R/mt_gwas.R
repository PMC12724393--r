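# Mitochondrial genome-wide SNP:deletion association scan (MT-GWAS).
#
# Pairs a binary homoplasmic SNP genotype with the read % of one deletion
# junction, under three eligibility filters applied within each region:
# the deletion must occur in >= 10 subjects, both SNP allele classes must
# have >= 10 carriers, and the SNP must lie within 10 bp of a deletion
# breakpoint.

# variant keys are "<pos><ref>><alt>"
.variant_position <- function(keys) {
  as.integer(sub("^([0-9]+).*$", "\\1", keys))
}

#' Eligible SNP:deletion pairs for the association scan
#'
#' @param geno Binary genotype matrix from [genotype_matrix()] (samples x
#'   variants).
#' @param deletion_calls Deletion calls covering the same samples.
#' @param metadata Data.frame with `sample_id` and `region`.
#' @param region Region to scan (e.g. `"FC"`).
#' @param min_carriers Minimum subjects per deletion and per SNP allele class
#'   (default 10).
#' @param max_distance Maximum SNP distance to the nearer breakpoint in bp
#'   (default 10).
#' @return Data.frame of pairs: `snp`, `snp_position`, `bp5`, `bp3`,
#'   `region`, `n_snp_carriers`, `n_deletion_carriers`,
#'   `min_breakpoint_distance`.
#' @export
eligible_pairs <- function(geno, deletion_calls, metadata, region,
                           min_carriers = 10L, max_distance = 10L) {
  samples <- metadata$sample_id[metadata$region == region]
  if (length(samples) == 0L) {
    stop("empty cohort for region '", region, "'", call. = FALSE)
  }
  samples <- intersect(samples, rownames(geno))
  g <- geno[samples, , drop = FALSE]
  carriers <- colSums(g)
  snp_ok <- which(carriers >= min_carriers &
                    (nrow(g) - carriers) >= min_carriers)
  dels <- deletion_calls[deletion_calls$sample_id %in% samples &
                           deletion_calls$supporting_reads >= 1, ,
                         drop = FALSE]
  if (nrow(dels) == 0L || length(snp_ok) == 0L) {
    return(data.frame(snp = character(0), snp_position = integer(0),
                      bp5 = integer(0), bp3 = integer(0),
                      region = character(0), n_snp_carriers = integer(0),
                      n_deletion_carriers = integer(0),
                      min_breakpoint_distance = integer(0)))
  }
  junc <- unique(dels[, c("bp5", "bp3")])
  junc$n_deletion_carriers <- mapply(function(b5, b3) {
    length(unique(dels$sample_id[dels$bp5 == b5 & dels$bp3 == b3]))
  }, junc$bp5, junc$bp3)
  junc <- junc[junc$n_deletion_carriers >= min_carriers, , drop = FALSE]
  if (nrow(junc) == 0L) {
    return(data.frame(snp = character(0), snp_position = integer(0),
                      bp5 = integer(0), bp3 = integer(0),
                      region = character(0), n_snp_carriers = integer(0),
                      n_deletion_carriers = integer(0),
                      min_breakpoint_distance = integer(0)))
  }
  snp_pos <- .variant_position(colnames(g)[snp_ok])
  rows <- list()
  for (i in seq_along(snp_ok)) {
    d5 <- abs(snp_pos[i] - junc$bp5)
    d3 <- abs(snp_pos[i] - junc$bp3)
    dist <- pmin(d5, d3)
    keep <- which(dist <= max_distance)
    if (length(keep) > 0L) {
      rows[[length(rows) + 1L]] <- data.frame(
        snp = colnames(g)[snp_ok[i]], snp_position = snp_pos[i],
        bp5 = junc$bp5[keep], bp3 = junc$bp3[keep], region = region,
        n_snp_carriers = unname(carriers[snp_ok[i]]),
        n_deletion_carriers = junc$n_deletion_carriers[keep],
        min_breakpoint_distance = dist[keep],
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(snp = character(0), snp_position = integer(0),
                      bp5 = integer(0), bp3 = integer(0),
                      region = character(0), n_snp_carriers = integer(0),
                      n_deletion_carriers = integer(0),
                      min_breakpoint_distance = integer(0))
  }
  rownames(out) <- NULL
  out
}

#' Run the per-pair association models for one region
#'
#' For each eligible pair fits
#' `SNP presence/absence ~ deletion read % + covariates` by ordinary least
#' squares over the region's full cohort; samples without the deletion
#' contribute read % 0. The genome-wide threshold is `alpha` divided by the
#' number of eligible pairs in the region. Pairs with a constant response
#' after filtering are reported as untestable but still count toward the
#' number of tests. Setting `reverse_model = TRUE` instead regresses deletion
#' read % on the genotype (sensitivity analysis).
#'
#' @param pairs Output of [eligible_pairs()] for one region.
#' @param geno Binary genotype matrix.
#' @param deletion_calls Deletion calls (all samples).
#' @param covariates Data.frame with `sample_id` plus covariate columns
#'   (e.g. `benchmark_coverage`, `age`, `sex`), restricted or restrictable to
#'   the region samples.
#' @param metadata Data.frame with `sample_id` and `region`.
#' @param alpha Family-wise error rate (default 0.05).
#' @param reverse_model Swap response and deletion read % (default FALSE).
#' @return Data.frame: pair columns plus `beta`, `p`, `n`, `n_tests`,
#'   `threshold`, `significant`, `untestable`.
#' @export
run_mtgwas <- function(pairs, geno, deletion_calls, covariates, metadata,
                       alpha = 0.05, reverse_model = FALSE) {
  if (nrow(pairs) == 0L) stop("no eligible pairs", call. = FALSE)
  region <- unique(pairs$region)
  if (length(region) != 1L) {
    stop("run_mtgwas expects pairs from a single region; thresholds are ",
         "never pooled across regions", call. = FALSE)
  }
  samples <- intersect(metadata$sample_id[metadata$region == region],
                       rownames(geno))
  covar <- covariates[match(samples, covariates$sample_id), , drop = FALSE]
  if (any(is.na(covar$sample_id))) {
    stop("covariates missing for some region samples", call. = FALSE)
  }
  covar_cols <- setdiff(names(covar), "sample_id")
  n_tests <- nrow(pairs)
  threshold <- bonferroni(alpha, n_tests)
  out <- pairs
  out$beta <- NA_real_; out$p <- NA_real_; out$n <- length(samples)
  out$n_tests <- n_tests; out$threshold <- threshold
  out$untestable <- FALSE
  for (k in seq_len(n_tests)) {
    snp <- pairs$snp[k]
    sel <- deletion_calls$bp5 == pairs$bp5[k] &
      deletion_calls$bp3 == pairs$bp3[k] &
      deletion_calls$sample_id %in% samples
    read_pct <- stats::setNames(rep(0, length(samples)), samples)
    hits <- deletion_calls[sel, , drop = FALSE]
    if (nrow(hits) > 0L) {
      agg <- tapply(hits$read_pct, hits$sample_id, sum)
      read_pct[names(agg)] <- agg
    }
    y <- geno[samples, snp]
    design <- cbind(data.frame(deletion_read_pct = unname(read_pct)),
                    covar[covar_cols])
    if (reverse_model) {
      resp <- design$deletion_read_pct
      design$deletion_read_pct <- y
      names(design)[1L] <- "snp_presence"
      y <- resp
      term <- "snp_presence"
    } else {
      term <- "deletion_read_pct"
    }
    if (length(unique(y)) == 1L || length(unique(design[[1L]])) == 1L) {
      out$untestable[k] <- TRUE
      next
    }
    # covariates that are constant in this region carry no information
    keep_col <- c(TRUE, vapply(design[-1L], function(v) {
      length(unique(v)) > 1L
    }, logical(1)))
    fit <- ols_fit(y, design[keep_col])
    out$beta[k] <- unname(fit$coefficients[term])
    out$p[k] <- unname(fit$p_values[term])
  }
  out$significant <- !is.na(out$p) & out$p < out$threshold
  out
}

#' Join association results with junction repeat-length changes
#'
#' Annotates each association with the direction of the repeat-length change
#' induced by the alternate allele and flags mechanistic consistency: a
#' positive association should pair with an allele that lengthens the
#' junction repeat, a negative association with one that shortens it.
#'
#' @param results Output of [run_mtgwas()].
#' @param repeat_deltas Data.frame with `snp`, `bp5`, `bp3`, `ref_length`,
#'   `alt_length` covering at least every significant pair.
#' @return `results` with `ref_length`, `alt_length`, `delta_class` and
#'   `consistent` columns.
#' @export
gwas_report <- function(results, repeat_deltas) {
  key <- function(d) paste(d$snp, d$bp5, d$bp3)
  idx <- match(key(results), key(repeat_deltas))
  sig_missing <- results$significant & is.na(idx)
  if (any(sig_missing)) {
    stop("missing repeat assessment for significant pair(s): ",
         paste(key(results)[sig_missing], collapse = "; "), call. = FALSE)
  }
  results$ref_length <- repeat_deltas$ref_length[idx]
  results$alt_length <- repeat_deltas$alt_length[idx]
  results$delta_class <- ifelse(
    is.na(idx), NA_character_,
    mapply(classify_delta, results$ref_length, results$alt_length)
  )
  results$consistent <- ifelse(
    is.na(results$beta) | is.na(results$delta_class), NA,
    (results$beta > 0) == (results$delta_class == "lengthens")
  )
  results
}
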