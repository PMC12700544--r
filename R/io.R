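# Chromosome names are normalized to a single internal dialect: "chr"-prefixed
# strings ("8" -> "chr8", "chr8" unchanged). Arm suffixes p/q are preserved.
normalize_chromosome <- function(x) {
  x <- as.character(x)
  ifelse(grepl("^chr", x), x, paste0("chr", x))
}

#' Read a genes-by-samples expression matrix from TSV
#'
#' Expects a header row of sample ids and a first column of gene ids; all
#' remaining cells must be numeric (log2-scale values). Values are consumed as
#' given: the pipeline never renormalizes.
#'
#' @param path Path to a tab-separated file.
#' @return Numeric matrix, genes in rows, samples in columns.
#' @export
read_expression_tsv <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 2L) stop("expression table needs a header and >=1 gene row")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol_expected <- length(fields[[1L]])
  ragged <- which(vapply(fields, length, 1L) != ncol_expected)
  if (length(ragged)) {
    stop(sprintf("ragged row in expression table at line %d", ragged[1L]))
  }
  samples <- fields[[1L]][-1L]
  if (anyDuplicated(samples)) {
    stop("duplicate sample id: ", samples[duplicated(samples)][1L])
  }
  body <- fields[-1L]
  genes <- vapply(body, `[`, "", 1L)
  if (anyDuplicated(genes)) {
    stop("duplicate gene id: ", genes[duplicated(genes)][1L])
  }
  vals <- suppressWarnings(
    vapply(body, function(f) as.numeric(f[-1L]), numeric(ncol_expected - 1L))
  )
  mat <- if (is.null(dim(vals))) matrix(vals, nrow = 1L) else t(vals)
  if (anyNA(mat)) stop("non-numeric or missing cell in expression table")
  dimnames(mat) <- list(genes, samples)
  mat
}

#' Write an expression matrix to TSV
#'
#' @param mat Numeric matrix with gene rownames and sample colnames.
#' @param path Output path.
#' @export
write_expression_tsv <- function(mat, path) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv_plain(df, path)
}

# Deterministic TSV writer: UTF-8, "." decimal, full double precision.
write_tsv_plain <- function(df, path) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) format(x, digits = 15, trim = TRUE,
                                                scientific = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read / write gene-set collections in GMT format
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then members. Member order is preserved; round-trips are lossless.
#'
#' @param path File path.
#' @return Named list of character vectors (set name -> gene ids).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, 1L) < 3L)
  if (length(short)) stop(sprintf("GMT parse error at line %d: fewer than 3 fields", short[1L]))
  nms <- vapply(fields, `[`, "", 1L)
  if (anyDuplicated(nms)) stop("duplicate set name: ", nms[duplicated(nms)][1L])
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- nms
  validate_genesets(sets)
  sets
}

#' @rdname read_gmt
#' @param sets Named list of character vectors.
#' @param descriptions Optional named character descriptions (default "na").
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  validate_genesets(sets)
  lines <- vapply(names(sets), function(nm) {
    desc <- if (!is.null(descriptions) && nm %in% names(descriptions)) {
      descriptions[[nm]]
    } else "na"
    paste(c(nm, desc, sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

validate_genesets <- function(sets) {
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop("gene sets must be named")
  }
  empty <- names(sets)[vapply(sets, length, 1L) == 0L]
  if (length(empty)) stop("empty gene set: ", empty[1L])
  dup <- names(sets)[vapply(sets, anyDuplicated, 1L) > 0L]
  if (length(dup)) stop("duplicate members within set: ", dup[1L])
  invisible(sets)
}

#' Read a gene annotation table
#'
#' Columns: `gene_id`, `chromosome`, `start`, `end` (1-based inclusive bp).
#' Chromosome names are normalized to "chr"-prefixed strings.
#'
#' @param path TSV path.
#' @return data.frame with the four columns above.
#' @export
read_annotation_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "",
                          fileEncoding = "UTF-8")
  need <- c("gene_id", "chromosome", "start", "end")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("annotation table missing column(s): ",
                         paste(miss, collapse = ", "))
  validate_annotation(df[need])
}

validate_annotation <- function(annotation) {
  if (anyDuplicated(annotation$gene_id)) {
    stop("duplicate gene id in annotation: ",
         annotation$gene_id[duplicated(annotation$gene_id)][1L])
  }
  if (any(annotation$start > annotation$end)) {
    stop("annotation with start > end for gene ",
         annotation$gene_id[annotation$start > annotation$end][1L])
  }
  annotation$chromosome <- normalize_chromosome(annotation$chromosome)
  annotation
}

#' Read a centromere position table (columns: `chromosome`, `position`)
#' @param path TSV path.
#' @return data.frame with normalized chromosome names.
#' @export
read_centromeres_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  stopifnot(all(c("chromosome", "position") %in% names(df)))
  df$chromosome <- normalize_chromosome(df$chromosome)
  df
}

#' Build whole-chromosome and arm gene sets from annotation
#'
#' One whole-chromosome set per annotated chromosome, plus arm sets
#' `<chr>p` (gene end strictly before the centromere) and `<chr>q` (gene
#' start strictly after it). A gene spanning the centromere belongs to the
#' whole-chromosome set only. The annotation supplied here defines the gene
#' universe of each signature: restricting it to assay-represented genes
#' yields assay-matched sets.
#'
#' @param annotation data.frame as from [read_annotation_tsv()].
#' @param centromeres data.frame with `chromosome`, `position`; required for
#'   every chromosome when `arms = TRUE`.
#' @param arms Build arm sets (default TRUE).
#' @return Named list of gene-id vectors.
#' @export
build_chromosome_genesets <- function(annotation, centromeres = NULL,
                                      arms = TRUE) {
  annotation <- validate_annotation(annotation)
  chroms <- unique(annotation$chromosome)
  sets <- split(annotation$gene_id, annotation$chromosome)[chroms]
  if (arms) {
    if (is.null(centromeres)) stop("centromere table required for arm sets")
    centromeres$chromosome <- normalize_chromosome(centromeres$chromosome)
    miss <- setdiff(chroms, centromeres$chromosome)
    if (length(miss)) stop("missing centromere entry for chromosome: ",
                           paste(miss, collapse = ", "))
    cen <- stats::setNames(centromeres$position, centromeres$chromosome)
    for (ch in chroms) {
      sub <- annotation[annotation$chromosome == ch, ]
      p <- sub$gene_id[sub$end < cen[[ch]]]
      q <- sub$gene_id[sub$start > cen[[ch]]]
      if (length(p)) sets[[paste0(ch, "p")]] <- p
      if (length(q)) sets[[paste0(ch, "q")]] <- q
    }
  }
  sets
}

#' Read / write a clinical table (`sample_id`, `time` in months, `event` 0/1)
#' @param path TSV path.
#' @return data.frame with the three columns.
#' @export
read_clinical_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("sample_id", "time", "event")
  stopifnot(all(need %in% names(df)))
  df <- df[need]
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample id in clinical table: ",
         df$sample_id[duplicated(df$sample_id)][1L])
  }
  if (any(!is.finite(df$time)) || any(df$time <= 0)) {
    stop("clinical times must be finite and positive")
  }
  if (!all(df$event %in% c(0, 1))) stop("event indicator must be 0/1")
  df
}

#' @rdname read_clinical_tsv
#' @param clinical data.frame with `sample_id`, `time`, `event`.
#' @export
write_clinical_tsv <- function(clinical, path) {
  write_tsv_plain(clinical[c("sample_id", "time", "event")], path)
}

#' Read / write a long-format CNV call table
#'
#' Columns `sample_id`, `region`, `status` with status in
#' gain / neutral / loss and at most one record per (sample, region).
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_cnv_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("sample_id", "region", "status")
  stopifnot(all(need %in% names(df)))
  df <- df[need]
  df$region <- normalize_chromosome(df$region)
  if (!all(df$status %in% c("gain", "neutral", "loss"))) {
    stop("CNV status must be gain/neutral/loss")
  }
  if (anyDuplicated(df[c("sample_id", "region")])) {
    stop("duplicate (sample, region) record in CNV table")
  }
  df
}

#' @rdname read_cnv_tsv
#' @param cnv data.frame with `sample_id`, `region`, `status`.
#' @export
write_cnv_tsv <- function(cnv, path) {
  write_tsv_plain(cnv[c("sample_id", "region", "status")], path)
}

#' Read / write dose-response tables
#'
#' Long format: `drug`, `condition`, `replicate`, `dose`, `viability`.
#' Doses are positive concentrations; viability is a fraction of vehicle
#' control (normalization is assumed done upstream).
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_dose_response_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("drug", "condition", "replicate", "dose", "viability")
  stopifnot(all(need %in% names(df)))
  df <- df[need]
  if (any(df$dose <= 0)) stop("doses must be strictly positive")
  df
}

#' @rdname read_dose_response_tsv
#' @param dr data.frame in the long format above.
#' @export
write_dose_response_tsv <- function(dr, path) {
  write_tsv_plain(dr[c("drug", "condition", "replicate", "dose", "viability")],
                  path)
}
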