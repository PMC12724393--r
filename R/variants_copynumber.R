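# SNV classification, genotype matrices, haplogroup dichotomy and mtDNA copy
# number.
#
# Variant allele frequencies are taken as reported by the upstream caller
# (mutserve "VariantLevel"); the homoplasmy rule operates on that frequency.

#' Classify a variant by allele frequency
#'
#' A variant is homoplasmic when its allele frequency is at least 0.9,
#' heteroplasmic when strictly between 0.1 and 0.9, and excluded at or below
#' 0.1 (indistinguishable from noise at typical depths).
#'
#' @param vaf Numeric vector of variant allele frequencies in `[0, 1]`.
#' @return Character vector: `"homoplasmic"`, `"heteroplasmic"` or
#'   `"excluded"`.
#' @examples
#' classify_snv(c(0.95, 0.90, 0.5, 0.10, 0.05))
#' @export
classify_snv <- function(vaf) {
  if (any(is.na(vaf)) || any(vaf < 0) || any(vaf > 1)) {
    stop("vaf must lie in [0, 1]", call. = FALSE)
  }
  ifelse(vaf >= 0.9, "homoplasmic",
         ifelse(vaf > 0.1, "heteroplasmic", "excluded"))
}

#' Read a mutserve-style SNV table
#'
#' Expects a tab-delimited file with columns for sample id (`ID` or
#' `sample_id`), `Pos`, `Ref`, `Variant` and `VariantLevel` (case
#' insensitive). Rows with equal ref and alt alleles or frequencies outside
#' `[0, 1]` are rejected with row-numbered diagnostics.
#'
#' @param tsv Path to the table.
#' @return Data.frame with columns `sample_id`, `position`, `ref`, `alt`,
#'   `vaf`.
#' @export
read_snv_table <- function(tsv) {
  raw <- utils::read.delim(tsv, stringsAsFactors = FALSE, check.names = FALSE)
  cols <- tolower(names(raw))
  pick <- function(options, what) {
    idx <- which(cols %in% options)[1L]
    if (is.na(idx)) {
      stop("SNV table is missing a ", what, " column (looked for ",
           paste(options, collapse = "/"), ")", call. = FALSE)
    }
    raw[[idx]]
  }
  out <- data.frame(
    sample_id = as.character(pick(c("id", "sample", "sample_id"), "sample id")),
    position = as.integer(pick(c("pos", "position"), "position")),
    ref = toupper(as.character(pick(c("ref"), "ref allele"))),
    alt = toupper(as.character(pick(c("variant", "alt"), "alt allele"))),
    vaf = as.numeric(pick(c("variantlevel", "vaf", "af"), "allele frequency")),
    stringsAsFactors = FALSE
  )
  bad <- which(is.na(out$vaf) | out$vaf < 0 | out$vaf > 1 |
                 is.na(out$position) | out$ref == out$alt)
  if (length(bad) > 0L) {
    stop("invalid SNV rows (1-based, excluding header): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  out
}

#' Binary homoplasmic genotype matrix
#'
#' Builds a sample-by-variant presence/absence matrix: an entry is 1 when the
#' sample carries a homoplasmic call (allele frequency >= 0.9) for that
#' variant, and 0 otherwise (including samples with no call). Variants are
#' keyed as `"<position><ref>><alt>"`.
#'
#' @param snv_calls Data.frame as returned by [read_snv_table()].
#' @param samples Character vector of sample ids defining the rows (samples
#'   absent from the calls get all-zero rows).
#' @return Integer matrix with `samples` as rownames and variant keys as
#'   colnames.
#' @export
genotype_matrix <- function(snv_calls, samples) {
  key <- paste0(snv_calls$position, snv_calls$ref, ">", snv_calls$alt)
  dup <- duplicated(paste(snv_calls$sample_id, snv_calls$position, key))
  conflict <- duplicated(paste(snv_calls$sample_id, snv_calls$position,
                               snv_calls$alt)) & !dup
  if (any(dup)) {
    stop("duplicate conflicting calls for the same (sample, position, alt)",
         call. = FALSE)
  }
  variants <- sort(unique(key))
  m <- matrix(0L, nrow = length(samples), ncol = length(variants),
              dimnames = list(samples, variants))
  homo <- classify_snv(snv_calls$vaf) == "homoplasmic" &
    snv_calls$sample_id %in% samples
  if (any(homo)) {
    m[cbind(match(snv_calls$sample_id[homo], samples),
            match(key[homo], variants))] <- 1L
  }
  m
}

#' HV versus Non-HV haplogroup category
#'
#' Haplogroup labels whose top-level letter is H or V (including the HV
#' precursor lineages) are grouped as `"HV"`; every other label is
#' `"NonHV"`. The rule is purely label-based: lineages such as K, J, T and U
#' remain Non-HV regardless of phylogenetic ancestry.
#'
#' @param haplogroup_label Character vector of haplogroup labels, e.g.
#'   `"H1a"`, `"U5b1"`.
#' @return Character vector of `"HV"` / `"NonHV"`.
#' @export
hv_category <- function(haplogroup_label) {
  if (any(is.na(haplogroup_label) | !nzchar(haplogroup_label))) {
    stop("empty haplogroup label", call. = FALSE)
  }
  ifelse(grepl("^(H|V)", toupper(haplogroup_label)), "HV", "NonHV")
}

#' Per-sample variant profile
#'
#' Counts homoplasmic and heteroplasmic variants for one sample (distinct
#' variant positions; multi-allelic records count once per alternate allele;
#' excluded calls are not counted) and attaches the haplogroup category.
#'
#' @param snv_calls Calls for a single sample.
#' @param haplogroup_label The sample's haplogroup label.
#' @return A one-row data.frame: `homoplasmic_count`, `heteroplasmic_count`,
#'   `haplogroup_label`, `hv_category`.
#' @export
variant_profile <- function(snv_calls, haplogroup_label) {
  if (nrow(snv_calls) > 0L &&
      length(unique(snv_calls$sample_id)) != 1L) {
    stop("variant_profile expects calls from a single sample", call. = FALSE)
  }
  if (nrow(snv_calls) > 0L) {
    dedup <- !duplicated(paste(snv_calls$position, snv_calls$alt))
    cls <- classify_snv(snv_calls$vaf[dedup])
  } else {
    cls <- character(0)
  }
  data.frame(
    homoplasmic_count = sum(cls == "homoplasmic"),
    heteroplasmic_count = sum(cls == "heteroplasmic"),
    haplogroup_label = haplogroup_label,
    hv_category = hv_category(haplogroup_label),
    stringsAsFactors = FALSE
  )
}

#' mtDNA copy number from relative coverage
#'
#' Estimates mitochondrial genome copies per diploid cell as twice the ratio
#' of mean mitochondrial to mean autosomal sequencing depth.
#'
#' @param mt_mean_depth Mean depth over the mitochondrial genome.
#' @param autosomal_mean_depth Mean autosomal depth (must be positive).
#' @return Copies per diploid cell (numeric, vectorised).
#' @examples
#' mtdna_copy_number(3400, 34)   # 200 copies
#' @export
mtdna_copy_number <- function(mt_mean_depth, autosomal_mean_depth) {
  if (any(autosomal_mean_depth <= 0)) {
    stop("autosomal mean depth must be positive", call. = FALSE)
  }
  if (any(mt_mean_depth < 0)) {
    stop("mt mean depth must be non-negative", call. = FALSE)
  }
  2 * mt_mean_depth / autosomal_mean_depth
}

#' Read a coverage summary table
#'
#' @param tsv Tab-delimited file with columns `sample_id`, `mt_mean_depth`,
#'   `autosomal_mean_depth`.
#' @return Data.frame with those columns.
#' @export
read_coverage_table <- function(tsv) {
  out <- utils::read.delim(tsv, stringsAsFactors = FALSE)
  need <- c("sample_id", "mt_mean_depth", "autosomal_mean_depth")
  missing <- setdiff(need, names(out))
  if (length(missing) > 0L) {
    stop("coverage table is missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out[need]
}
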