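# End-to-end pipeline orchestration: annotate -> metrics -> copy number ->
# SNV profiles -> MT-GWAS -> junction repeats -> cohort summary, with a run
# manifest recording inputs, outputs, checksums and the seed.

#' Build and validate a pipeline run configuration
#'
#' All referenced paths must exist at validation time; validation failures
#' abort before any stage runs.
#'
#' @param reference_fasta Reference genome FASTA (default the vendored rCRS).
#' @param deletions_tsv,snvs_tsv,metadata_tsv,coverage_tsv Input tables (see
#'   the corresponding readers).
#' @param out_dir Output directory.
#' @param seed Integer seed recorded in the manifest (the pipeline itself is
#'   deterministic; the seed also feeds any downstream simulation).
#' @param run_gwas Run the MT-GWAS stage (requires SNVs; default TRUE).
#' @param alpha Family-wise error rate for the GWAS (default 0.05).
#' @param min_reads Minimum supporting reads per deletion call (default 0).
#' @param gwas_min_carriers,gwas_max_distance MT-GWAS eligibility filters
#'   (defaults 10 and 10).
#' @param repeat_window Junction repeat search half-window (default 15).
#' @return A validated `pipeline_config`.
#' @export
pipeline_config <- function(reference_fasta = rcrs_fasta(),
                            deletions_tsv, snvs_tsv = NULL, metadata_tsv,
                            coverage_tsv, out_dir, seed = 1L,
                            run_gwas = TRUE, alpha = 0.05, min_reads = 0,
                            gwas_min_carriers = 10L, gwas_max_distance = 10L,
                            repeat_window = 15L) {
  paths <- c(reference_fasta = reference_fasta, deletions_tsv = deletions_tsv,
             metadata_tsv = metadata_tsv, coverage_tsv = coverage_tsv)
  if (run_gwas) {
    if (is.null(snvs_tsv)) {
      stop("validation failure: GWAS enabled but no SNV table configured",
           call. = FALSE)
    }
    paths <- c(paths, snvs_tsv = snvs_tsv)
  }
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0L) {
    stop("validation failure: missing input file(s): ",
         paste(names(missing), "=", missing, collapse = "; "), call. = FALSE)
  }
  structure(list(paths = as.list(paths), out_dir = out_dir, seed = seed,
                 run_gwas = run_gwas, alpha = alpha, min_reads = min_reads,
                 gwas_min_carriers = gwas_min_carriers,
                 gwas_max_distance = gwas_max_distance,
                 repeat_window = repeat_window),
            class = "pipeline_config")
}

.write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

.pipeline_dictionary <- function() {
  data.frame(
    column = c("deletions_per_10k", "cumulative_read_pct", "read_pct_lt1000",
               "read_pct_ge1000", "top30_read_pct", "common_del_read_pct",
               "cplx_*", "trna_*", "mdp_*", "copy_number", "age",
               "benchmark_coverage", "homoplasmic_count",
               "heteroplasmic_count", "beta", "p", "threshold",
               "ref_length", "alt_length"),
    unit = c("unique junctions per 10,000x benchmark coverage",
             "percent (0-100)", "percent (0-100)", "percent (0-100)",
             "percent (0-100)", "percent (0-100)", "percent (0-100)",
             "percent (0-100)", "percent (0-100)",
             "mtDNA copies per diploid cell", "years", "reads (mean depth)",
             "count of variant positions", "count of variant positions",
             "change in SNP presence per unit deletion read %",
             "two-sided p-value", "Bonferroni alpha / n_tests", "bp", "bp"),
    stringsAsFactors = FALSE
  )
}

#' Run the full analysis pipeline
#'
#' Executes every stage over the configured inputs and writes per-sample
#' metrics, cohort summaries, regression results, the MT-GWAS table with
#' repeat-delta annotation, a machine-readable data dictionary and a
#' manifest (`manifest.json`) recording the package version, seed, and MD5
#' checksums of all inputs and outputs. Outputs are a pure function of
#' (inputs, config, seed). Any stage failure aborts with a stage-tagged
#' error.
#'
#' @param config A `pipeline_config`.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  log <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  ## load
  genome <- stage("reference", load_genome(config$paths$reference_fasta))
  catalog <- default_catalog(genome$length)
  deletions <- stage("read_deletions",
                     read_deletion_table(config$paths$deletions_tsv))
  metadata <- stage("read_metadata", {
    m <- utils::read.delim(config$paths$metadata_tsv,
                           stringsAsFactors = FALSE)
    need <- c("sample_id", "region", "age", "sex")
    if (!all(need %in% names(m))) {
      stop("metadata needs columns ", paste(need, collapse = ", "))
    }
    m
  })
  coverage <- stage("read_coverage",
                    read_coverage_table(config$paths$coverage_tsv))
  log$n_samples <- nrow(metadata)
  log$n_deletion_rows <- nrow(deletions)

  ## per-sample deletion metrics
  metrics <- stage("metrics", {
    per <- lapply(metadata$sample_id, function(s) {
      calls <- deletions[deletions$sample_id == s, , drop = FALSE]
      cbind(data.frame(sample_id = s, stringsAsFactors = FALSE),
            sample_metrics(calls, catalog, min_reads = config$min_reads))
    })
    do.call(rbind, per)
  })
  outputs <- c(outputs, .write_tsv(metrics,
                                   file.path(config$out_dir,
                                             "sample_metrics.tsv")))

  ## impact annotations (long format)
  impacts <- stage("annotate", impact_table(deletions, catalog))
  outputs <- c(outputs, .write_tsv(impacts,
                                   file.path(config$out_dir,
                                             "impact_annotations.tsv")))

  ## cohort summary with fold changes
  summary_tab <- stage("cohort_summary", cohort_summary(metrics, metadata))
  outputs <- c(outputs, .write_tsv(summary_tab,
                                   file.path(config$out_dir,
                                             "cohort_summary.tsv")))

  ## copy number and per-region age regressions
  cn_tab <- stage("copy_number", {
    data.frame(sample_id = coverage$sample_id,
               copy_number = mtdna_copy_number(coverage$mt_mean_depth,
                                               coverage$autosomal_mean_depth))
  })
  outputs <- c(outputs, .write_tsv(cn_tab,
                                   file.path(config$out_dir,
                                             "copy_number.tsv")))
  regressions <- stage("regressions", {
    dat <- merge(merge(metrics, metadata, by = "sample_id"), cn_tab,
                 by = "sample_id")
    dat$sex_male <- as.integer(dat$sex == "M")
    bench <- deletions$benchmark_coverage[
      match(dat$sample_id, deletions$sample_id)]
    dat$benchmark_coverage <- ifelse(is.na(bench), 0, bench)
    res <- list()
    for (r in unique(dat$region)) {
      sub <- dat[dat$region == r, ]
      cn_fit <- ols_fit(sub$copy_number,
                        sub[, c("age", "sex_male"), drop = FALSE])
      res[[paste0("cn_age_", r)]] <- list(
        model = "ols", region = r, response = "copy_number",
        coefficients = as.list(cn_fit$coefficients),
        p_values = as.list(cn_fit$p_values),
        delta_per_15y = bin_delta(cn_fit, 30, 15))
      for (metric in c("deletions_per_10k", "cumulative_read_pct",
                       "read_pct_ge1000")) {
        fit <- exp_regression(sub[[metric]], sub$age,
                              sub[, c("benchmark_coverage", "sex_male")])
        res[[paste0(metric, "_age_", r)]] <- list(
          model = "log_linear", region = r, response = metric,
          coefficients = as.list(fit$coefficients),
          p_values = as.list(fit$p_values))
      }
    }
    res
  })
  reg_path <- file.path(config$out_dir, "regressions.json")
  jsonlite::write_json(regressions, reg_path, auto_unbox = TRUE, digits = NA)
  outputs <- c(outputs, reg_path)

  ## SNV profiles and GWAS
  if (config$run_gwas) {
    snv <- stage("read_snvs", read_snv_table(config$paths$snvs_tsv))
    profiles <- stage("snv_profiles", {
      per <- lapply(metadata$sample_id, function(s) {
        calls <- snv[snv$sample_id == s, , drop = FALSE]
        hap <- metadata$haplogroup[metadata$sample_id == s][1L]
        cbind(data.frame(sample_id = s, stringsAsFactors = FALSE),
              variant_profile(calls, hap))
      })
      do.call(rbind, per)
    })
    outputs <- c(outputs, .write_tsv(profiles,
                                     file.path(config$out_dir,
                                               "snv_profiles.tsv")))
    gwas_out <- stage("mtgwas", {
      geno <- genotype_matrix(snv, metadata$sample_id)
      bench <- deletions$benchmark_coverage[
        match(metadata$sample_id, deletions$sample_id)]
      covar <- data.frame(
        sample_id = metadata$sample_id,
        benchmark_coverage = ifelse(is.na(bench), 0, bench),
        age = metadata$age,
        sex_male = as.integer(metadata$sex == "M"),
        stringsAsFactors = FALSE
      )
      all_res <- list()
      for (r in unique(metadata$region)) {
        pairs <- eligible_pairs(geno, deletions, metadata, r,
                                config$gwas_min_carriers,
                                config$gwas_max_distance)
        if (nrow(pairs) == 0L) next
        all_res[[r]] <- run_mtgwas(pairs, geno, deletions, covar, metadata,
                                   config$alpha)
      }
      if (length(all_res) == 0L) NULL else
        do.call(rbind, c(all_res, list(make.row.names = FALSE)))
    })
    if (!is.null(gwas_out)) {
      deltas <- stage("repeats", {
        uniq <- unique(gwas_out[, c("snp", "snp_position", "bp5", "bp3")])
        uniq$ref_length <- NA_real_; uniq$alt_length <- NA_real_
        for (k in seq_len(nrow(uniq))) {
          alleles <- sub("^[0-9]+", "", uniq$snp[k])
          ref <- sub(">.*$", "", alleles); alt <- sub("^.*>", "", alleles)
          genome_base <- substr(genome$sequence, uniq$snp_position[k],
                                uniq$snp_position[k])
          if (!identical(genome_base, ref)) next  # allele not on reference
          d <- repeat_delta(genome, uniq$bp5[k], uniq$bp3[k],
                            allele_substitution(uniq$snp_position[k], ref,
                                                alt),
                            config$repeat_window)
          uniq$ref_length[k] <- d[["ref_length"]]
          uniq$alt_length[k] <- d[["alt_length"]]
        }
        uniq
      })
      gwas_ann <- stage("gwas_report", {
        ok <- !is.na(deltas$ref_length)
        gwas_report(gwas_out, deltas[ok, , drop = FALSE])
      })
      outputs <- c(outputs, .write_tsv(gwas_ann,
                                       file.path(config$out_dir,
                                                 "mtgwas.tsv")))
    }
  }

  ## data dictionary and manifest
  outputs <- c(outputs, .write_tsv(.pipeline_dictionary(),
                                   file.path(config$out_dir,
                                             "data_dictionary.tsv")))
  manifest <- list(
    package = "mtaging",
    version = as.character(utils::packageVersion("mtaging")),
    seed = config$seed,
    inputs = as.list(tools::md5sum(unlist(config$paths))),
    outputs = as.list(tools::md5sum(outputs)),
    rows = log
  )
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE)
  invisible(manifest)
}
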