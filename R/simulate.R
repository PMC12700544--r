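# Every generator is a pure function of (parameters, seed). A master seed is
# split deterministically into independent per-component streams so that
# adding draws to one component never perturbs another.
split_seed <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

#' Build a default synthetic gene annotation
#'
#' Genes are laid out uniformly along each chromosome with small fixed gene
#' lengths; centromere positions sit at 40% of each chromosome length. Used
#' by the cohort simulator and by tests needing a genome scaffold.
#'
#' @param n_genes Total number of genes.
#' @param chromosomes Chromosome names (normalized to "chr" prefix).
#' @param n_region_genes Named integer vector fixing gene counts per
#'   chromosome (e.g. `c(chr8 = 300)`); remaining genes are spread evenly.
#' @param chrom_length Chromosome length in bp (default 1.2e8).
#' @return list with `annotation` (data.frame) and `centromeres` (data.frame).
#' @export
synthetic_annotation <- function(n_genes = 2000,
                                 chromosomes = paste0("chr", 1:20),
                                 n_region_genes = NULL,
                                 chrom_length = 1.2e8) {
  chromosomes <- normalize_chromosome(chromosomes)
  counts <- stats::setNames(rep(0L, length(chromosomes)), chromosomes)
  if (!is.null(n_region_genes)) {
    names(n_region_genes) <- normalize_chromosome(names(n_region_genes))
    stopifnot(all(names(n_region_genes) %in% chromosomes))
    counts[names(n_region_genes)] <- as.integer(n_region_genes)
  }
  rest <- n_genes - sum(counts)
  if (rest < 0) stop("n_region_genes exceeds n_genes")
  free <- names(counts)[counts == 0L]
  if (length(free)) {
    base <- rest %/% length(free)
    counts[free] <- base
    extra <- rest - base * length(free)
    if (extra > 0) counts[free[seq_len(extra)]] <- counts[free[seq_len(extra)]] + 1L
  }
  ann <- do.call(rbind, lapply(chromosomes, function(ch) {
    k <- counts[[ch]]
    if (k == 0L) return(NULL)
    starts <- round(seq(1, chrom_length - 2e4, length.out = k))
    data.frame(gene_id = sprintf("%s_g%04d", ch, seq_len(k)),
               chromosome = ch, start = starts, end = starts + 1e4,
               stringsAsFactors = FALSE)
  }))
  cen <- data.frame(chromosome = chromosomes,
                    position = round(0.4 * chrom_length),
                    stringsAsFactors = FALSE)
  list(annotation = ann, centromeres = cen)
}

#' Simulate an expression + CNV + survival cohort with a planted driver
#'
#' Emulates a tumor cohort in which whole-region copy-number gains (or
#' losses) act multiplicatively on the expression of the genes they carry,
#' and survival hazard is tied to a single planted driver gene:
#' \itemize{
#' \item expression\[g, s\] = gene baseline + `dosage_effect` * alteration
#'   indicator (sign flipped for losses) + Normal(0, `noise_sd`), log2 scale;
#' \item alterations are sample-level whole-region events, drawn
#'   independently per region with the prevalences in `prevalence`;
#' \item survival times are exponential proportional-hazards:
#'   hazard_i = `baseline_hazard` * exp(`driver_log_hr` * z_i) with z_i the
#'   cohort-standardized driver expression; censoring is independent
#'   Uniform(0, cmax) with cmax solved so the expected censored fraction is
#'   approximately `censor_rate`.
#' }
#'
#' @param n_samples Cohort size.
#' @param annotation Gene annotation data.frame (see
#'   [synthetic_annotation()]); the driver gene must be present.
#' @param prevalence Named numeric vector of alteration prevalences per
#'   region, e.g. `c(chr8 = 0.5, chr1q = 0.15)`. Arm regions require
#'   `centromeres`.
#' @param direction Named character vector ("gain"/"loss") per region;
#'   default "gain" everywhere.
#' @param dosage_effect Log2 expression shift per altered region (default
#'   `log2(3/2)`, one extra copy of a disomic chromosome).
#' @param driver_gene Gene id whose expression drives hazard; default the
#'   first chr8 gene.
#' @param driver_log_hr Log hazard ratio per SD of driver expression.
#' @param baseline_hazard Events per month at z = 0 (default 0.02).
#' @param censor_rate Target censored fraction (default 0.3).
#' @param noise_sd Residual expression SD (default 1.0).
#' @param centromeres Centromere table, needed for arm regions.
#' @param seed Master seed (mandatory).
#' @return list of class `synthetic_cohort`: `expression`, `cnv_truth`
#'   (long CNV table), `clinical`, `driver_gene_id`, `params`.
#' @export
simulate_cohort <- function(n_samples, annotation,
                            prevalence = c(chr8 = 0.5),
                            direction = NULL,
                            dosage_effect = log2(3 / 2),
                            driver_gene = NULL,
                            driver_log_hr = 0.7,
                            baseline_hazard = 0.02,
                            censor_rate = 0.3,
                            noise_sd = 1.0,
                            centromeres = NULL,
                            seed) {
  stopifnot(n_samples >= 2)
  if (missing(seed)) stop("seed is mandatory")
  annotation <- validate_annotation(annotation)
  names(prevalence) <- normalize_chromosome(names(prevalence))
  if (any(prevalence < 0 | prevalence > 1)) stop("prevalence outside [0,1]")
  if (is.null(direction)) {
    direction <- stats::setNames(rep("gain", length(prevalence)), names(prevalence))
  } else {
    names(direction) <- normalize_chromosome(names(direction))
  }
  stopifnot(all(direction %in% c("gain", "loss")))

  regions <- names(prevalence)
  arm_regions <- grepl("[pq]$", regions)
  sets <- build_chromosome_genesets(annotation, centromeres,
                                    arms = any(arm_regions))
  miss <- setdiff(regions, names(sets))
  if (length(miss)) stop("region(s) absent from annotation: ",
                         paste(miss, collapse = ", "))
  if (is.null(driver_gene)) {
    if (!"chr8" %in% names(sets)) stop("no chr8 genes to pick a driver from")
    driver_gene <- sets[["chr8"]][1L]
  }
  if (!driver_gene %in% annotation$gene_id) {
    stop("driver gene absent from annotation: ", driver_gene)
  }

  seeds <- split_seed(seed, 4L)
  genes <- annotation$gene_id
  samples <- sprintf("S%03d", seq_len(n_samples))

  baseline <- with_seed(seeds[1L], stats::rnorm(length(genes), mean = 8, sd = 1.5))
  names(baseline) <- genes

  status <- with_seed(seeds[2L], {
    m <- vapply(regions, function(r) {
      stats::rbinom(n_samples, 1L, prevalence[[r]])
    }, integer(n_samples))
    if (n_samples == 1L) m <- matrix(m, nrow = 1L)
    m
  })
  dimnames(status) <- list(samples, regions)

  shift <- matrix(0, length(genes), n_samples, dimnames = list(genes, samples))
  for (r in regions) {
    members <- intersect(sets[[r]], genes)
    sgn <- if (direction[[r]] == "gain") 1 else -1
    shift[members, ] <- shift[members, ] +
      sgn * dosage_effect * rep(status[, r], each = length(members))
  }
  noise <- with_seed(seeds[3L], matrix(stats::rnorm(length(genes) * n_samples,
                                                    sd = noise_sd),
                                       length(genes), n_samples))
  expr <- baseline + shift + noise
  dimnames(expr) <- list(genes, samples)

  z <- as.numeric(scale(expr[driver_gene, ]))
  hazard <- baseline_hazard * exp(driver_log_hr * z)
  clinical <- with_seed(seeds[4L], {
    t_event <- stats::rexp(n_samples, rate = hazard)
    c_time <- if (censor_rate <= 0) {
      rep(Inf, n_samples)
    } else {
      stats::runif(n_samples, 0, censor_cmax(hazard, censor_rate))
    }
    data.frame(sample_id = samples,
               time = pmax(pmin(t_event, c_time), 1e-6),
               event = as.integer(t_event <= c_time),
               stringsAsFactors = FALSE)
  })

  cnv_truth <- expand.grid(sample_id = samples, region = regions,
                           KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cnv_truth$status <- ifelse(status[cbind(cnv_truth$sample_id, cnv_truth$region)] == 1L,
                             direction[cnv_truth$region], "neutral")
  cnv_truth <- cnv_truth[order(cnv_truth$sample_id, cnv_truth$region), ]
  rownames(cnv_truth) <- NULL

  structure(list(
    expression = expr,
    cnv_truth = cnv_truth,
    clinical = clinical,
    driver_gene_id = driver_gene,
    params = list(prevalence = prevalence, direction = direction,
                  dosage_effect = dosage_effect, driver_log_hr = driver_log_hr,
                  baseline_hazard = baseline_hazard, censor_rate = censor_rate,
                  noise_sd = noise_sd, seed = seed)
  ), class = "synthetic_cohort")
}

# For C ~ U(0, c) and T ~ Exp(lambda_i): P(censored) averaged over samples is
# mean_i [ (1 - (1 - exp(-lambda_i c)) / (lambda_i c)) ]... derived from
# P(C < T) = (1/c) * integral_0^c exp(-lambda t) dt applied per subject.
censor_cmax <- function(hazard, censor_rate) {
  if (censor_rate <= 0) return(Inf)
  if (censor_rate >= 1) stop("censor_rate must be in [0, 1)")
  f <- function(cc) {
    mean((1 - exp(-hazard * cc)) / (hazard * cc)) - censor_rate
  }
  # censored fraction decreases from 1 (c -> 0) to 0 (c -> Inf)
  stats::uniroot(f, lower = 1e-6, upper = 1e6, tol = 1e-8)$root
}

#' Simulate paired knockdown proteome/transcriptome profiles
#'
#' Emulates a pulsed metabolic-labeling proteomics experiment with parallel
#' transcriptome arrays: `n_blocks` cell-line blocks, each with control and
#' knockdown replicate groups of size `n_reps`. A planted subset of features
#' is shifted by `protein_effect` at the protein layer in every block and by
#' `mrna_effect` (default 0, i.e. translational-only regulation) at the mRNA
#' layer. Missing values are injected completely at random into the protein
#' layer only.
#'
#' @param n_features Number of features (proteins == transcripts, shared ids).
#' @param n_targets Number of planted translational targets.
#' @param n_blocks Cell-line blocks (default 3).
#' @param n_reps Replicates per group (default 4).
#' @param protein_effect Log2 shift (knockdown - control) for targets at the
#'   protein layer (default -1: synthesis drops on knockdown).
#' @param mrna_effect Log2 shift at the mRNA layer (default 0).
#' @param missing_rate MCAR missingness rate in the protein layer (default 0.1).
#' @param noise_sd Residual SD, both layers (default 0.3).
#' @param feature_ids Optional feature ids of length `n_features` (e.g. the
#'   gene ids of a simulated cohort, so proteins map onto transcripts);
#'   default synthetic protein ids.
#' @param target_ids Optional explicit planted-target ids (length
#'   `n_targets`, must be among the feature ids); default a seeded random
#'   draw.
#' @param seed Master seed.
#' @return list of class `synthetic_omics_pair`: `protein`, `mrna` (lists of
#'   matrices per block), `design` (per-block column groups), `truth`
#'   (target feature ids), `params`.
#' @export
simulate_knockdown_omics <- function(n_features, n_targets, n_blocks = 3,
                                     n_reps = 4, protein_effect = -1,
                                     mrna_effect = 0, missing_rate = 0.1,
                                     noise_sd = 0.3, feature_ids = NULL,
                                     target_ids = NULL, seed) {
  stopifnot(n_targets <= n_features, n_reps >= 2)
  if (missing_rate >= 1 || missing_rate < 0) stop("missing_rate must be in [0, 1)")
  if (missing(seed)) stop("seed is mandatory")
  seeds <- split_seed(seed, 2L + 2L * n_blocks)
  features <- if (is.null(feature_ids)) {
    sprintf("P%05d", seq_len(n_features))
  } else {
    stopifnot(length(feature_ids) == n_features, !anyDuplicated(feature_ids))
    feature_ids
  }
  targets <- if (is.null(target_ids)) {
    with_seed(seeds[1L], sort(sample(features, n_targets)))
  } else {
    stopifnot(length(target_ids) == n_targets, all(target_ids %in% features))
    sort(target_ids)
  }
  prot_base <- with_seed(seeds[2L], stats::rnorm(n_features, 25, 2))
  mrna_base <- prot_base / 3 + 2  # arbitrary but fixed layer offset

  blocks <- sprintf("line%d", seq_len(n_blocks))
  groups <- rep(c("control", "knockdown"), each = n_reps)
  make_block <- function(b, base, effect, s, miss) {
    cols <- sprintf("%s_%s_r%d", blocks[b], groups, rep(seq_len(n_reps), 2L))
    eff <- matrix(0, n_features, 2L * n_reps,
                  dimnames = list(features, cols))
    kd <- groups == "knockdown"
    eff[targets, kd] <- effect
    with_seed(s, {
      m <- base + eff + matrix(stats::rnorm(n_features * 2L * n_reps,
                                            sd = noise_sd),
                               n_features, 2L * n_reps)
      if (miss > 0) m[matrix(stats::runif(length(m)) < miss, nrow(m))] <- NA_real_
      dimnames(m) <- list(features, cols)
      m
    })
  }
  protein <- lapply(seq_len(n_blocks), function(b) {
    make_block(b, prot_base, protein_effect, seeds[2L + b], missing_rate)
  })
  mrna <- lapply(seq_len(n_blocks), function(b) {
    make_block(b, mrna_base, mrna_effect, seeds[2L + n_blocks + b], 0)
  })
  names(protein) <- names(mrna) <- blocks
  design <- lapply(protein, function(m) {
    stats::setNames(rep(c("control", "knockdown"), each = n_reps), colnames(m))
  })
  structure(list(protein = protein, mrna = mrna, design = design,
                 truth = targets,
                 params = list(n_features = n_features, n_targets = n_targets,
                               n_blocks = n_blocks, n_reps = n_reps,
                               protein_effect = protein_effect,
                               mrna_effect = mrna_effect,
                               missing_rate = missing_rate,
                               noise_sd = noise_sd, seed = seed)),
            class = "synthetic_omics_pair")
}

#' Simulate a four-parameter logistic dose-response series
#'
#' viability(d) = bottom + (top - bottom) / (1 + (d / ic50)^hill)
#' + Normal(0, noise_sd), per replicate and dose.
#'
#' @param top,bottom Upper/lower viability asymptotes (fractions of control).
#' @param ic50 Half-maximal concentration (> 0, same units as `doses`).
#' @param hill Hill slope (> 0 for decreasing curves).
#' @param doses Strictly positive, strictly increasing concentrations.
#' @param noise_sd Additive noise SD (default 0).
#' @param n_reps Replicates per dose (default 1).
#' @param drug,condition Labels carried into the output table.
#' @param seed Seed (required when `noise_sd > 0`).
#' @return data.frame: `drug`, `condition`, `replicate`, `dose`, `viability`.
#' @export
simulate_dose_response <- function(top = 1, bottom = 0, ic50, hill = 1,
                                   doses, noise_sd = 0, n_reps = 1,
                                   drug = "drug", condition = "A",
                                   seed = NULL) {
  if (any(doses <= 0)) stop("doses must be strictly positive")
  if (is.unsorted(doses, strictly = TRUE)) stop("doses must be strictly increasing")
  if (ic50 <= 0) stop("ic50 must be positive")
  mu <- bottom + (top - bottom) / (1 + (doses / ic50)^hill)
  out <- data.frame(
    drug = drug, condition = condition,
    replicate = rep(seq_len(n_reps), each = length(doses)),
    dose = rep(doses, n_reps),
    viability = rep(mu, n_reps),
    stringsAsFactors = FALSE
  )
  if (noise_sd > 0) {
    if (is.null(seed)) stop("seed required when noise_sd > 0")
    out$viability <- out$viability +
      with_seed(seed, stats::rnorm(nrow(out), sd = noise_sd))
  }
  out
}
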