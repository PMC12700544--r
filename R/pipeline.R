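#' Validate a pipeline run configuration
#'
#' The configuration is a named list (typically read from YAML with
#' [read_run_config()]). Required fields: input paths (`expression`,
#' `annotation`, `centromeres`, `clinical`, `gene_sets`), `out_dir`, and
#' `seed`. Errors are aggregated, never silently defaulted for required
#' fields.
#'
#' @details Optional fields and their ranges: `fdr` in (0,1),
#'   `min_abs_lfc >= 0`, `decile` in (0,1], `survival_alpha` in (0,1),
#'   `adj_p_threshold` in (0,1), `n_perm >= 100`, `stratify_mode` in
#'   median/quartile, `alpha >= 0`; optional inputs `cnv`,
#'   `drug_response`, `omics_dir` (paths), `target_gene`, `focus_region`,
#'   `confounder_regions`, `association_set` (a set name in `gene_sets`).
#'
#' @param config Named list.
#' @return Character vector of error messages (length 0 when valid).
#' @export
validate_config <- function(config) {
  errs <- character()
  req_paths <- c("expression", "annotation", "centromeres", "clinical",
                 "gene_sets")
  for (f in req_paths) {
    if (is.null(config[[f]])) {
      errs <- c(errs, sprintf("missing required field: %s", f))
    } else if (!file.exists(config[[f]])) {
      errs <- c(errs, sprintf("%s: file not found (%s)", f, config[[f]]))
    }
  }
  for (f in c("cnv", "drug_response", "omics_dir")) {
    if (!is.null(config[[f]]) && !file.exists(config[[f]])) {
      errs <- c(errs, sprintf("%s: file not found (%s)", f, config[[f]]))
    }
  }
  if (is.null(config$out_dir)) errs <- c(errs, "missing required field: out_dir")
  if (is.null(config$seed)) {
    errs <- c(errs, "missing required field: seed (mandatory for stochastic stages)")
  }
  in_open <- function(x) is.numeric(x) && length(x) == 1L && x > 0 && x < 1
  if (!is.null(config$fdr) && !in_open(config$fdr)) {
    errs <- c(errs, "fdr must be in (0,1)")
  }
  if (!is.null(config$survival_alpha) && !in_open(config$survival_alpha)) {
    errs <- c(errs, "survival_alpha must be in (0,1)")
  }
  if (!is.null(config$adj_p_threshold) && !in_open(config$adj_p_threshold)) {
    errs <- c(errs, "adj_p_threshold must be in (0,1)")
  }
  if (!is.null(config$min_abs_lfc) &&
      (!is.numeric(config$min_abs_lfc) || config$min_abs_lfc < 0)) {
    errs <- c(errs, "min_abs_lfc must be >= 0")
  }
  if (!is.null(config$decile) &&
      (!is.numeric(config$decile) || config$decile <= 0 || config$decile > 1)) {
    errs <- c(errs, "decile must be in (0,1]")
  }
  if (!is.null(config$n_perm) && config$n_perm < 100) {
    errs <- c(errs, "n_perm must be >= 100")
  }
  if (!is.null(config$stratify_mode) &&
      !config$stratify_mode %in% c("median", "quartile")) {
    errs <- c(errs, "stratify_mode must be 'median' or 'quartile'")
  }
  errs
}

#' Read a YAML run configuration
#' @param path YAML file; relative input paths are resolved against its
#'   directory.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  config <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  for (f in c("expression", "annotation", "centromeres", "clinical",
              "gene_sets", "cnv", "drug_response", "omics_dir")) {
    if (!is.null(config[[f]]) && !grepl("^/", config[[f]])) {
      config[[f]] <- file.path(base, config[[f]])
    }
  }
  config
}

default_config_params <- function(config) {
  defaults <- list(fdr = 0.05, min_abs_lfc = 0.5, decile = 0.10,
                   survival_alpha = 0.05, adj_p_threshold = 0.05,
                   n_perm = 1000, stratify_mode = "median", alpha = 0.25,
                   protein_fdr = 0.05, mrna_floor = 0.05, d0 = 4,
                   focus_region = "chr8")
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  config
}

#' Write / read a paired-omics experiment as a directory of TSV files
#'
#' One `protein_<block>.tsv` and `mrna_<block>.tsv` matrix (first column
#' `feature_id`; missing values as NA) plus one `design_<block>.tsv`
#' (`sample_id`, `group`) per block.
#'
#' @param omics List with `protein`, `mrna`, `design` (see
#'   [simulate_knockdown_omics()]).
#' @param dir Output directory (created).
#' @return The directory path (write) / the omics list (read).
#' @export
write_omics_dir <- function(omics, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (b in names(omics$protein)) {
    for (layer in c("protein", "mrna")) {
      m <- omics[[layer]][[b]]
      df <- data.frame(feature_id = rownames(m), m, check.names = FALSE)
      write_tsv_plain(df, file.path(dir, sprintf("%s_%s.tsv", layer, b)))
    }
    write_tsv_plain(data.frame(sample_id = names(omics$design[[b]]),
                               group = unname(omics$design[[b]])),
                    file.path(dir, sprintf("design_%s.tsv", b)))
  }
  invisible(dir)
}

#' @rdname write_omics_dir
#' @export
read_omics_dir <- function(dir) {
  designs <- sort(list.files(dir, pattern = "^design_.*\\.tsv$"))
  if (!length(designs)) stop("no design_<block>.tsv files in ", dir)
  blocks <- sub("^design_(.*)\\.tsv$", "\\1", designs)
  read_mat <- function(path) {
    df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                            stringsAsFactors = FALSE, check.names = FALSE,
                            fileEncoding = "UTF-8")
    m <- as.matrix(df[-1L])
    rownames(m) <- df[[1L]]
    storage.mode(m) <- "double"
    m
  }
  protein <- list(); mrna <- list(); design <- list()
  for (b in blocks) {
    protein[[b]] <- read_mat(file.path(dir, sprintf("protein_%s.tsv", b)))
    mrna[[b]] <- read_mat(file.path(dir, sprintf("mrna_%s.tsv", b)))
    d <- utils::read.table(file.path(dir, sprintf("design_%s.tsv", b)),
                           header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
    design[[b]] <- stats::setNames(d$group, d$sample_id)
  }
  list(protein = protein, mrna = mrna, design = design)
}

#' Run the full analysis pipeline
#'
#' Stage order mirrors the analysis chain: (1) expression-based
#' chromosome-gain inference (per-sample enrichment scores, two-group
#' clustering, CNV concordance when calls are supplied, differential
#' expression, position enrichment, exclusive-gain subsetting);
#' (2) survival analyses (group Kaplan-Meier + log-rank, quartile
#' stratification of the target gene, genome-wide batch screen);
#' (3) preranked enrichment triad and Venn intersection; (4) paired-omics
#' integration and candidate cascade when `omics_dir` is supplied;
#' (5) dose-response fitting and IC50-shift ranking when `drug_response`
#' is supplied. Each stage writes TSV/JSON outputs to `out_dir` and
#' appends to `pipeline.log`; the returned manifest carries per-file md5
#' checksums, so an identical config + seed reproduces byte-identical
#' outputs (the log is excluded from the manifest).
#'
#' @param config Configuration list (see [validate_config()]).
#' @return list: `manifest` (data.frame stage, file, md5), `stages`.
#' @export
run_full_pipeline <- function(config) {
  errs <- validate_config(config)
  if (length(errs)) stop("invalid config:\n  ", paste(errs, collapse = "\n  "))
  config <- default_config_params(config)
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out, "pipeline.log")
  cat(sprintf("pipeline start, seed %d\n", config$seed), file = log_path)
  files <- list()
  run_stage <- function(stage, code) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(code, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE)
    })
    cat(sprintf("stage %s done (%.1f s)\n", stage,
                proc.time()[["elapsed"]] - t0),
        file = log_path, append = TRUE)
    res
  }
  emit <- function(stage, name, writer) {
    writer(file.path(out, name))
    files[[name]] <<- stage
  }

  expr <- read_expression_tsv(config$expression)
  annotation <- read_annotation_tsv(config$annotation)
  centromeres <- read_centromeres_tsv(config$centromeres)
  clinical <- read_clinical_tsv(config$clinical)
  sets <- read_gmt(config$gene_sets)
  cnv <- if (!is.null(config$cnv)) read_cnv_tsv(config$cnv) else NULL
  seeds <- split_seed(config$seed, 4L)
  focus <- normalize_chromosome(config$focus_region)

  # ---- stage 1: chromosome-gain inference -----------------------------
  strat <- run_stage("cnv_inference", {
    ann_expr <- annotation[annotation$gene_id %in% rownames(expr), ]
    chrom_sets <- build_chromosome_genesets(ann_expr, centromeres)
    focus_set <- if (focus %in% names(sets)) sets[[focus]] else chrom_sets[[focus]]
    scores <- ssgsea_scores(expr, focus_set, alpha = config$alpha)
    st <- stratify_two_groups(scores)
    emit("cnv_inference", "ssgsea_scores.tsv", function(p) {
      write_tsv_plain(data.frame(sample_id = names(scores), score = scores), p)
    })
    emit("cnv_inference", "stratification.tsv", function(p) {
      write_tsv_plain(data.frame(sample_id = names(st$labels),
                                 label = as.character(st$labels)), p)
    })
    if (!is.null(cnv)) {
      conc <- cnv_concordance(st, cnv, region = focus)
      emit("cnv_inference", "cnv_concordance.json", function(p) {
        jsonlite::write_json(list(accuracy = conc$accuracy,
                                  fisher_p = conc$fisher_p, n = conc$n),
                             p, auto_unbox = TRUE, digits = NA)
      })
      if (!is.null(config$confounder_regions) &&
          length(config$confounder_regions)) {
        sub <- exclusive_cnv_subset(cnv, focus, config$confounder_regions)
        emit("cnv_inference", "exclusive_subset.tsv",
             function(p) write_tsv_plain(sub, p))
      }
    }
    deg <- differential_expression(expr, st$labels, fdr = config$fdr,
                                   min_abs_lfc = config$min_abs_lfc)
    emit("cnv_inference", "deg.tsv", function(p) write_tsv_plain(deg, p))
    pos <- position_enrichment(deg, ann_expr)
    emit("cnv_inference", "position_enrichment.tsv",
         function(p) write_tsv_plain(pos, p))
    st
  })

  # ---- stage 2: survival ----------------------------------------------
  screen <- run_stage("survival", {
    common <- intersect(names(strat$labels), clinical$sample_id)
    cl <- clinical[match(common, clinical$sample_id), ]
    lab <- strat$labels[common]
    lr <- logrank_test(cl$time, cl$event, lab)
    emit("survival", "logrank_groups.json", function(p) {
      jsonlite::write_json(lr[c("chisq", "df", "p")], p, auto_unbox = TRUE,
                           digits = NA)
    })
    emit("survival", "km_groups.tsv", function(p) {
      km <- do.call(rbind, lapply(levels(lab), function(lv) {
        fit <- km_estimate(cl$time[lab == lv], cl$event[lab == lv])
        if (nrow(fit)) cbind(group = lv, as.data.frame(fit)) else NULL
      }))
      write_tsv_plain(km, p)
    })
    sc <- survival_batch_screen(expr, clinical, mode = config$stratify_mode)
    emit("survival", "survival_screen.tsv",
         function(p) write_tsv_plain(sc$results, p))
    target <- config$target_gene %||% sc$results$gene_id[1L]
    q <- expression_stratify(expr[target, common], mode = "quartile")
    lrq <- logrank_test(cl$time, cl$event, q)
    emit("survival", "target_quartile_logrank.json", function(p) {
      jsonlite::write_json(c(list(target = target),
                             lrq[c("chisq", "df", "p")]),
                           p, auto_unbox = TRUE, digits = NA)
    })
    c(sc, list(target = target))
  })

  # ---- stage 3: enrichment triad --------------------------------------
  run_stage("enrichment", {
    test_sets <- sets[vapply(sets, function(s) {
      k <- length(intersect(s, rownames(expr)))
      k >= 2L && k < nrow(expr)
    }, TRUE)]
    if (length(test_sets)) {
      ranked_cor <- rank_by_correlation(expr, screen$target)
      ranked_strat <- rank_by_foldchange(expr, strat$labels)
      ranked_fc <- if (!is.null(cnv)) {
        gain <- cnv$sample_id[cnv$region == focus & cnv$status == "gain"]
        lab <- factor(ifelse(colnames(expr) %in% gain, "gain", "no_gain"),
                      levels = c("no_gain", "gain"))
        rank_by_foldchange(expr, lab)
      } else ranked_strat
      g <- list(
        correlation = gsea_preranked(ranked_cor, test_sets,
                                     n_perm = config$n_perm, seed = seeds[1L]),
        foldchange_cnv = gsea_preranked(ranked_fc, test_sets,
                                        n_perm = config$n_perm, seed = seeds[2L]),
        foldchange_signature = gsea_preranked(ranked_strat, test_sets,
                                              n_perm = config$n_perm,
                                              seed = seeds[3L])
      )
      for (nm in names(g)) {
        emit("enrichment", sprintf("gsea_%s.tsv", nm), local({
          res <- g[[nm]]$results
          function(p) write_tsv_plain(res, p)
        }))
      }
      venn <- intersect_significant(g[[1L]], g[[2L]], g[[3L]],
                                    adj_p_threshold = config$adj_p_threshold)
      emit("enrichment", "gsea_intersection.json", function(p) {
        jsonlite::write_json(list(counts = as.list(venn$counts),
                                  regions = venn$regions),
                             p, auto_unbox = TRUE, digits = NA)
      })
    }
    NULL
  })

  # ---- stage 4: omics integration + cascade ---------------------------
  if (!is.null(config$omics_dir)) {
    run_stage("integration", {
      omics <- read_omics_dir(config$omics_dir)
      ostats <- omics_pair_stats(omics, d0 = config$d0)
      emit("integration", "protein_pooled_stats.tsv",
           function(p) write_tsv_plain(ostats$pooled, p))
      tt <- translational_targets(ostats, protein_fdr = config$protein_fdr,
                                  mrna_floor = config$mrna_floor)
      emit("integration", "translational_candidates.tsv", function(p) {
        write_tsv_plain(data.frame(feature_id = tt$candidates), p)
      })
      assoc <- if (!is.null(config$association_set) &&
                   config$association_set %in% names(sets)) {
        sets[[config$association_set]]
      } else character()
      cascade <- prioritize_candidates(ostats, assoc, screen,
                                       decile = config$decile,
                                       survival_alpha = config$survival_alpha)
      emit("integration", "cascade.json", function(p) {
        jsonlite::write_json(list(counts = as.list(cascade$counts),
                                  stages = cascade$stages),
                             p, auto_unbox = TRUE, digits = NA)
      })
      NULL
    })
  }

  # ---- stage 5: drug response -----------------------------------------
  if (!is.null(config$drug_response)) {
    run_stage("drugs", {
      dr <- read_dose_response_tsv(config$drug_response)
      conds <- sort(unique(dr$condition))
      if (length(conds) != 2L) stop("drug_response needs exactly 2 conditions")
      rk <- ic50_shift_ranking(dr[dr$condition == conds[1L], ],
                               dr[dr$condition == conds[2L], ])
      emit("drugs", "ic50_ranking.tsv",
           function(p) write_tsv_plain(rk$ranking, p))
      NULL
    })
  }

  manifest <- data.frame(stage = unname(unlist(files)), file = names(files),
                         stringsAsFactors = FALSE)
  manifest <- manifest[order(manifest$file), ]
  manifest$md5 <- unname(tools::md5sum(file.path(out, manifest$file)))
  rownames(manifest) <- NULL
  cat("pipeline complete\n", file = log_path, append = TRUE)
  list(manifest = manifest, stages = unique(manifest$stage))
}
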