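# Seeded synthetic cohort generator.
#
# Emulates the data structure of a two-brain-region aging WGS study: sample
# metadata (age, sex, region, haplogroup), per-sample deletion junction
# tables with coverage normalisation, mutserve-style SNV tables, and coverage
# summaries for copy-number estimation. Default parameters are anchored to
# published cohort summaries: region copy-number means/SDs, deletion burden
# means, haplogroup-dependent homoplasmic SNV counts and HV fractions.
# The generator defines the study conditions; it is not a tuning knob.

#' Default synthetic cohort configuration
#'
#' Region conventions: `FC` (frontal cortex-like, high copy number and high
#' deletion burden) and `CER` (cerebellum-like). Ages are uniform on
#' `age_range`; each catalog junction is carried by a sample with a
#' zipf-weighted, age-increasing probability, and a carried junction's read
#' percent follows `exp(b0_j + b_age * age + eps) - pseudo` truncated at
#' zero; copy number is Normal around a region mean with a linear age slope.
#'
#' @param n_per_region Named vector of sample counts (default
#'   `c(FC = 143, CER = 149)`).
#' @param seed Integer seed.
#' @return A `cohort_config` list; see the fields in the source for units.
#' @export
cohort_config <- function(n_per_region = c(FC = 143L, CER = 149L),
                          seed = 1L) {
  structure(list(
    n_per_region = n_per_region,
    age_range = c(0.4, 100),
    p_female = 0.5,
    hv_fraction = c(FC = 60 / 143, CER = 72 / 149),
    autosomal_depth = c(mean = 34.28, sd = 4.04),
    # copy number: per-region mean/SD and change per year of age
    cn_params = list(
      FC = c(mean = 4536.805, sd = 1376.705, slope = -193.23 / 15),
      CER = c(mean = 1367.205, sd = 687.661, slope = -37.14 / 15)
    ),
    # deletion burden: ln-scale age slopes (read % per junction and
    # junction-count), ln-scale noise SD, cohort mean targets for deletions
    # per 10k coverage and cumulative read %, and the share of carried
    # junctions that are >= 1000 bp
    deletion_params = list(
      FC = list(age_slope = 0.025, count_age_slope = 0.015, sdlog = 0.6,
                dp10k_mean = 9.759, cum_read_pct_mean = 0.780,
                p_large = 0.80),
      CER = list(age_slope = 0.018, count_age_slope = 0.010, sdlog = 0.6,
                 dp10k_mean = 3.189, cum_read_pct_mean = 0.135,
                 p_large = 0.20)
    ),
    pseudo_count = 0.01,
    # homoplasmic SNV count (Normal, rounded, floored at 0) by region and
    # haplogroup category; heteroplasmic counts Poisson with an
    # age-increasing rate in FC only
    snv_params = list(
      homoplasmic = list(
        FC = list(HV = c(mean = 11.93, sd = 3.49),
                  NonHV = c(mean = 33.89, sd = 5.25)),
        CER = list(HV = c(mean = 11.71, sd = 3.00),
                   NonHV = c(mean = 31.03, sd = 7.75))
      ),
      het_base = c(FC = 0.8, CER = 2.0),
      het_age_slope = c(FC = 0.012, CER = 0)
    ),
    # common SNPs with population alternate-allele frequencies; the first
    # three sit within 10 bp of a catalog junction breakpoint
    snp_catalog = data.frame(
      position = c(14798L, 12372L, 14766L, 13451L, 8470L, 10398L, 4216L),
      ref = c("T", "G", "C", "A", "A", "A", "T"),
      alt = c("C", "A", "T", "G", "G", "G", "C"),
      freq = c(0.30, 0.35, 0.60, 0.20, 0.15, 0.40, 0.25),
      stringsAsFactors = FALSE
    ),
    planted_association = NULL,
    seed = seed
  ), class = "cohort_config")
}

# Deterministic junction catalog: four named junctions (the canonical common
# deletion plus three with breakpoint-proximal catalog SNPs) followed by
# arithmetically generated junctions in both size classes. Zipf weights make
# the leading junctions common enough for association eligibility while the
# tail supplies per-sample junction diversity.
.junction_catalog <- function(n_large = 600L, n_small = 600L) {
  mk <- function(i, size) {
    bp5 <- 600L + (i * 89L) %% 14800L
    bp3 <- bp5 + size + 1L
    shift <- pmax(bp3 - 16500L, 0L)
    data.frame(bp5 = bp5 - shift, bp3 = bp3 - shift)
  }
  i_l <- seq_len(n_large - 4L)
  i_s <- seq_len(n_small)
  large <- rbind(
    data.frame(bp5 = c(8471L, 7816L, 12369L, 8775L),
               bp3 = c(13449L, 14807L, 14004L, 14771L)),
    mk(i_l, 1000L + (i_l * 613L) %% 8000L)
  )
  small <- mk(i_s * 7L + 3L, 60L + (i_s * 151L) %% 930L)
  large$size_class <- "large"
  small$size_class <- "small"
  out <- rbind(large, small)
  out <- out[!duplicated(out[, c("bp5", "bp3")]), ]
  out$size <- deletion_size(out$bp5, out$bp3)
  stopifnot(all(out$size[out$size_class == "large"] >= 1000L),
            all(out$size[out$size_class == "small"] < 1000L),
            all(out$bp5 >= 2L), all(out$bp3 <= 16568L))
  # heavy head so the canonical junctions are present in nearly every
  # sample, near-flat tail supplying per-sample junction diversity
  out$weight <- c(40, 25, 18, 18,
                  (seq_len(nrow(out) - 4L) + 4L)^(-1 / 5))
  rownames(out) <- NULL
  out
}

# mean of exp(b * A) for A ~ Uniform(lo, hi)
.mean_exp_unif <- function(b, lo, hi) {
  if (abs(b) < 1e-12) return(1)
  (exp(b * hi) - exp(b * lo)) / (b * (hi - lo))
}

# scale carry probabilities p = s * w so that the expected number of
# junctions surviving the detection floor, sum(pmin(s * w, cap) * surv),
# matches `mass`; the cap is handled by fixed-point iteration
.scaled_probs <- function(w, mass, surv = rep(1, length(w)), cap = 0.98) {
  eff <- w * surv
  if (sum(eff) <= 0) return(rep(0, length(w)))
  s <- mass / sum(eff)
  for (k in 1:40) {
    p <- pmin(s * w, cap)
    excess <- mass - sum(p * surv)
    free <- s * w < cap
    if (!any(free) || abs(excess) < 1e-9) break
    s <- s * (1 + excess / sum((s * w * surv)[free]))
  }
  pmin(s * w, cap)
}

# probability that a carried junction survives the read-support floor:
# read % = exp(b0 + la + eps) - pc with eps ~ N(0, sd); detected when the
# implied supporting reads round to >= 1
.survival <- function(b0, la, floor_pct, pc, sdlog) {
  stats::pnorm((b0 + la - log(floor_pct + pc)) / sdlog)
}

# expected observed read % contribution of a carried junction (truncated
# lognormal mean minus the pseudo-count mass above the floor)
.mean_observed <- function(b0, la, floor_pct, pc, sdlog) {
  z <- (log(floor_pct + pc) - b0 - la) / sdlog
  exp(b0 + la + sdlog^2 / 2) * stats::pnorm(sdlog - z) -
    pc * stats::pnorm(-z)
}

#' Simulate a synthetic cohort
#'
#' Generates metadata, deletion tables, SNV tables and coverage summaries
#' under the configured study conditions. Output is a pure function of the
#' configuration (including its seed): the same config yields identical
#' cohorts.
#'
#' @param config A `cohort_config`.
#' @return A `synthetic_cohort`: list with `metadata`, `deletions`, `snvs`,
#'   `coverage`, `ground_truth` (the generating parameters) and
#'   `junction_catalog`.
#' @examples
#' cohort <- simulate_cohort(cohort_config(c(FC = 20, CER = 20), seed = 7))
#' head(cohort$metadata)
#' @export
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  catalog <- .junction_catalog()
  lo <- config$age_range[1L]; hi <- config$age_range[2L]
  mean_age <- (lo + hi) / 2
  regions <- names(config$n_per_region)
  meta <- list(); dels <- list(); snvs <- list(); cov <- list()
  derived_slopes <- list()
  for (r in regions) {
    n <- config$n_per_region[[r]]
    ids <- sprintf("%s_%03d", r, seq_len(n))
    age <- stats::runif(n, lo, hi)
    sex <- ifelse(stats::rbinom(n, 1L, config$p_female) == 1L, "F", "M")
    hv <- stats::rbinom(n, 1L, config$hv_fraction[[r]]) == 1L
    haplo <- ifelse(hv,
                    sample(c("H1", "H3", "V1", "HV0"), n, replace = TRUE),
                    sample(c("U5b1", "K1a", "J1c", "T2b", "L3e2", "X2b"),
                           n, replace = TRUE))
    ## coverage and copy number
    auto <- pmax(stats::rnorm(n, config$autosomal_depth[["mean"]],
                              config$autosomal_depth[["sd"]]), 5)
    cnp <- config$cn_params[[r]]
    var_age <- (hi - lo)^2 / 12
    resid_sd <- sqrt(max(cnp[["sd"]]^2 - cnp[["slope"]]^2 * var_age,
                         (0.5 * cnp[["sd"]])^2))
    cn <- pmax(cnp[["mean"]] + cnp[["slope"]] * (age - mean_age) +
                 stats::rnorm(n, 0, resid_sd), 50)
    mt_depth <- cn * auto / 2
    benchmark <- round(mt_depth)
    ## deletions
    dp <- config$deletion_params[[r]]
    # read % growth and junction-count growth with age are separate
    # processes; cumulative read % grows at roughly their sum
    read_factor <- exp(dp$age_slope * (age - mean_age)) /
      .mean_exp_unif(dp$age_slope, lo - mean_age, hi - mean_age)
    count_factor <- exp(dp$count_age_slope * (age - mean_age)) /
      .mean_exp_unif(dp$count_age_slope, lo - mean_age, hi - mean_age)
    is_large <- catalog$size_class == "large"
    # Junction sampling weights: within each size class the zipf weights are
    # normalised and the classes are mixed at the region's large-deletion
    # share, so FC-like samples draw mostly kilobase-scale junctions
    w_tilt <- numeric(nrow(catalog))
    w_tilt[is_large] <- dp$p_large * catalog$weight[is_large] /
      sum(catalog$weight[is_large])
    w_tilt[!is_large] <- (1 - dp$p_large) * catalog$weight[!is_large] /
      sum(catalog$weight[!is_large])
    # Read % model: observed read % of a drawn junction follows
    # exp(b0_j + b_age * (age - mean_age) + eps) - pseudo, conditioned on
    # clearing the detection floor (supporting reads round to >= 1).
    # The canonical junctions carry boosted means, mirroring published
    # per-junction read fractions; b0 is calibrated so the cohort mean
    # cumulative read % matches the configured target.
    boost <- rep(1, nrow(catalog))
    boost[1:4] <- c(7, 5, 4, 4)
    mean_benchmark <- cnp[["mean"]] * config$autosomal_depth[["mean"]] / 2
    mean_unique <- dp$dp10k_mean * mean_benchmark / 10000
    floor_mean <- 50 / mean_benchmark
    pc <- config$pseudo_count
    # inclusion probabilities of weighted without-replacement sampling,
    # via the conditional-Poisson approximation: solve c so the expected
    # number of included junctions equals the draw count
    cc <- stats::uniroot(function(lc) {
      sum(1 - exp(-exp(lc) * w_tilt)) - min(mean_unique, nrow(catalog) - 1)
    }, c(-5, 25), tol = 1e-9)$root
    incl <- 1 - exp(-exp(cc) * w_tilt)
    age_grid <- seq(lo + 2, hi - 2, length.out = 9)
    rf_grid <- exp(dp$age_slope * (age_grid - mean_age)) /
      .mean_exp_unif(dp$age_slope, lo - mean_age, hi - mean_age)
    cf_grid <- exp(dp$count_age_slope * (age_grid - mean_age)) /
      .mean_exp_unif(dp$count_age_slope, lo - mean_age, hi - mean_age)
    calib <- function(log_kappa) {
      b0 <- log_kappa + log(boost) - dp$sdlog^2 / 2
      cum <- vapply(seq_along(age_grid), function(g) {
        la <- log(rf_grid[g])
        surv <- .survival(b0, la, floor_mean, pc, dp$sdlog)
        cond_mean <- ifelse(surv > 0,
                            .mean_observed(b0, la, floor_mean, pc,
                                           dp$sdlog) / surv, 0)
        sum(incl * cf_grid[g] * cond_mean)
      }, numeric(1))
      mean(cum) - dp$cum_read_pct_mean
    }
    log_kappa <- stats::uniroot(calib, c(-16, 6), tol = 1e-9)$root
    b0_j <- log_kappa + log(boost) - dp$sdlog^2 / 2
    # The detection floor left-truncates the read % distribution, so the
    # expected log-scale age slope of an observed junction metric is
    # slightly below the raw b_age parameter. Record the estimand the
    # generating process implies for the common-deletion metric: the OLS
    # slope of E[log(obs + pc) | carrier, age] over the age distribution,
    # with the truncated-normal (inverse-Mills) mean correction.
    la_grid <- log(rf_grid)
    z_grid <- (log(floor_mean + pc) - b0_j[1L] - la_grid) / dp$sdlog
    mills <- stats::dnorm(z_grid) / stats::pnorm(z_grid, lower.tail = FALSE)
    elog <- b0_j[1L] + la_grid + dp$sdlog * mills
    derived_slopes[[r]] <- unname(stats::coef(
      stats::lm(elog ~ age_grid))[2L])
    for (i in seq_len(n)) {
      mass <- dp$dp10k_mean * benchmark[i] / 10000 * count_factor[i]
      k <- min(stats::rpois(1L, mass), nrow(catalog))
      if (k == 0L) next
      drawn <- sample.int(nrow(catalog), k, prob = w_tilt)
      la <- log(read_factor[i])
      floor_i <- 50 / benchmark[i]
      # inverse-CDF draw from the floor-conditioned lognormal
      z <- (log(floor_i + pc) - b0_j[drawn] - la) / dp$sdlog
      qlo <- stats::pnorm(z)
      eps <- dp$sdlog * stats::qnorm(stats::runif(k, qlo, 1))
      read_pct <- exp(b0_j[drawn] + la + eps) - pc
      reads <- pmax(round(read_pct / 100 * benchmark[i]), 1)
      dels[[length(dels) + 1L]] <- data.frame(
        sample_id = ids[i],
        bp5 = catalog$bp5[drawn], bp3 = catalog$bp3[drawn],
        supporting_reads = reads,
        read_pct = read_pct,
        benchmark_coverage = benchmark[i],
        stringsAsFactors = FALSE
      )
    }
    ## SNVs: common SNPs (homoplasmic when carried), haplogroup-dependent
    ## homoplasmic background, age-increasing heteroplasmies in FC
    sp <- config$snv_params
    hp <- sp$homoplasmic[[r]]
    marker_pool <- setdiff(as.integer(seq(520, 16000, by = 130)),
                           config$snp_catalog$position)
    ref_pool <- c("A", "C", "G", "T")
    for (i in seq_len(n)) {
      cat_i <- if (hv[i]) "HV" else "NonHV"
      carried <- stats::rbinom(nrow(config$snp_catalog), 1L,
                               config$snp_catalog$freq) == 1L
      k_bg <- max(0L, round(stats::rnorm(1L, hp[[cat_i]][["mean"]],
                                         hp[[cat_i]][["sd"]])) - sum(carried))
      bg_pos <- sample(marker_pool, min(k_bg, length(marker_pool)))
      k_het <- stats::rpois(1L, max(sp$het_base[[r]] +
                                      sp$het_age_slope[[r]] *
                                        (age[i] - mean_age), 0.01))
      het_pos <- sample(setdiff(seq(100L, 16500L),
                                c(config$snp_catalog$position, bg_pos)),
                        k_het)
      mk <- function(pos, ref, alt, vaf) {
        if (length(pos) == 0L) return(NULL)
        data.frame(sample_id = ids[i], position = pos, ref = ref, alt = alt,
                   vaf = vaf, stringsAsFactors = FALSE)
      }
      alt_of <- function(ref) {
        vapply(ref, function(b) sample(setdiff(ref_pool, b), 1L), "")
      }
      bg_ref <- sample(ref_pool, length(bg_pos), replace = TRUE)
      het_ref <- sample(ref_pool, length(het_pos), replace = TRUE)
      snvs[[length(snvs) + 1L]] <- rbind(
        mk(config$snp_catalog$position[carried],
           config$snp_catalog$ref[carried], config$snp_catalog$alt[carried],
           stats::runif(sum(carried), 0.95, 1.0)),
        mk(bg_pos, bg_ref, alt_of(bg_ref),
           stats::runif(length(bg_pos), 0.92, 1.0)),
        mk(het_pos, het_ref, alt_of(het_ref),
           stats::runif(length(het_pos), 0.15, 0.85))
      )
    }
    meta[[r]] <- data.frame(sample_id = ids, region = r, age = age,
                            sex = sex, haplogroup = haplo,
                            stringsAsFactors = FALSE)
    cov[[r]] <- data.frame(sample_id = ids, mt_mean_depth = mt_depth,
                           autosomal_mean_depth = auto,
                           benchmark_coverage = benchmark,
                           stringsAsFactors = FALSE)
  }
  cohort <- structure(list(
    metadata = do.call(rbind, c(meta, list(make.row.names = FALSE))),
    deletions = if (length(dels) > 0L)
      do.call(rbind, c(dels, list(make.row.names = FALSE)))
    else data.frame(sample_id = character(0), bp5 = integer(0),
                    bp3 = integer(0), supporting_reads = numeric(0),
                    read_pct = numeric(0), benchmark_coverage = numeric(0)),
    snvs = do.call(rbind, c(snvs, list(make.row.names = FALSE))),
    coverage = do.call(rbind, c(cov, list(make.row.names = FALSE))),
    junction_catalog = catalog,
    ground_truth = config,
    derived = list(common_deletion_log_slope = derived_slopes)
  ), class = "synthetic_cohort")
  if (!is.null(config$planted_association)) {
    pa <- config$planted_association
    cohort <- plant_association(cohort, pa$snp_position, pa$bp5, pa$bp3,
                                pa$effect_sd)
  }
  cohort
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("synthetic_cohort:", nrow(x$metadata), "samples,",
      nrow(x$deletions), "deletion calls,", nrow(x$snvs), "SNV calls\n")
  invisible(x)
}

#' Plant a SNP:deletion association into a cohort
#'
#' Shifts the read % of one junction upward by `effect_sd` times that
#' junction's cohort read-percent SD in every sample carrying the alternate
#' allele of the SNP (adding the junction to carriers that lack it, with
#' support recomputed from coverage). All other junctions and samples are
#' untouched.
#'
#' @param cohort A `synthetic_cohort`.
#' @param snp_position Position of the catalog SNP whose carriers are
#'   shifted.
#' @param bp5,bp3 Junction to associate.
#' @param effect_sd Effect size in junction-SD units (0 leaves the cohort
#'   unchanged).
#' @return The modified `synthetic_cohort`.
#' @export
plant_association <- function(cohort, snp_position, bp5, bp3, effect_sd) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  cat_ok <- any(cohort$junction_catalog$bp5 == bp5 &
                  cohort$junction_catalog$bp3 == bp3)
  snp_ok <- snp_position %in% cohort$ground_truth$snp_catalog$position
  if (!cat_ok || !snp_ok) {
    stop("unknown snp or junction for plant_association", call. = FALSE)
  }
  if (effect_sd == 0) return(cohort)
  carriers <- unique(cohort$snvs$sample_id[
    cohort$snvs$position == snp_position & cohort$snvs$vaf >= 0.9])
  sel <- cohort$deletions$bp5 == bp5 & cohort$deletions$bp3 == bp3
  per_sample <- stats::setNames(rep(0, nrow(cohort$metadata)),
                                cohort$metadata$sample_id)
  if (any(sel)) {
    agg <- tapply(cohort$deletions$read_pct[sel],
                  cohort$deletions$sample_id[sel], sum)
    per_sample[names(agg)] <- agg
  }
  shift <- effect_sd * max(stats::sd(per_sample), 1e-3)
  upd <- sel & cohort$deletions$sample_id %in% carriers
  cohort$deletions$read_pct[upd] <- cohort$deletions$read_pct[upd] + shift
  have <- unique(cohort$deletions$sample_id[sel])
  need <- setdiff(carriers, have)
  if (length(need) > 0L) {
    cv <- cohort$coverage[match(need, cohort$coverage$sample_id), ]
    cohort$deletions <- rbind(cohort$deletions, data.frame(
      sample_id = need, bp5 = bp5, bp3 = bp3,
      supporting_reads = pmax(round(shift / 100 * cv$benchmark_coverage), 1),
      read_pct = shift, benchmark_coverage = cv$benchmark_coverage,
      stringsAsFactors = FALSE
    ))
  }
  cohort$deletions$supporting_reads[upd] <-
    pmax(round(cohort$deletions$read_pct[upd] / 100 *
                 cohort$deletions$benchmark_coverage[upd]), 1)
  cohort
}

#' Write a synthetic cohort as TSV files
#'
#' Writes `metadata.tsv`, `deletions.tsv`, `snvs.tsv` and `coverage.tsv` in
#' the dialects the package readers consume.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(d, f) {
    utils::write.table(d, file.path(dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  w(cohort$metadata, "metadata.tsv")
  w(cohort$deletions, "deletions.tsv")
  snv <- cohort$snvs
  names(snv) <- c("ID", "Pos", "Ref", "Variant", "VariantLevel")
  w(snv, "snvs.tsv")
  w(cohort$coverage, "coverage.tsv")
  invisible(dir)
}
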