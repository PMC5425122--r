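#' Construct a validated expression matrix
#'
#' An expression matrix is a plain numeric matrix with probes in rows and
#' samples in columns, carrying its measurement scale (\code{"log2"} for
#' log2 intensities, the microarray convention, or \code{"linear"}) as an
#' attribute. All downstream stages operate on this representation.
#'
#' @param values numeric matrix, probes x samples.
#' @param probe_ids character vector of unique probe(set) identifiers; taken
#'   from \code{rownames(values)} when missing.
#' @param sample_ids character vector of unique sample identifiers; taken
#'   from \code{colnames(values)} when missing.
#' @param scale measurement scale, \code{"log2"} (default) or \code{"linear"}.
#' @return the matrix with dimnames set and a \code{"scale"} attribute.
#' @export
expression_matrix <- function(values, probe_ids = rownames(values),
                              sample_ids = colnames(values),
                              scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  if (!is.numeric(values))
    stop("expression values must be numeric")
  if (is.null(probe_ids) || is.null(sample_ids))
    stop("probe and sample identifiers are required")
  if (length(probe_ids) != nrow(values) || length(sample_ids) != ncol(values))
    stop("identifier lengths do not match matrix dimensions")
  if (anyDuplicated(probe_ids))
    stop("duplicate probe ids: ",
         paste(unique(probe_ids[duplicated(probe_ids)]), collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    stop("non-finite value at probe '", probe_ids[bad[1]],
         "', sample '", sample_ids[bad[2]], "'")
  }
  dimnames(values) <- list(probe_ids, sample_ids)
  attr(values, "scale") <- scale
  values
}

#' Measurement scale of an expression matrix
#' @param x an expression matrix.
#' @return \code{"log2"} or \code{"linear"} (\code{"log2"} assumed when unset).
#' @export
expr_scale <- function(x) {
  s <- attr(x, "scale")
  if (is.null(s)) "log2" else s
}

validate_metadata <- function(metadata) {
  required <- c("sample_id", "age")
  missing <- setdiff(required, names(metadata))
  if (length(missing))
    stop("sample metadata lacks column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(metadata$sample_id))
    stop("duplicate sample ids in metadata: ",
         paste(unique(metadata$sample_id[duplicated(metadata$sample_id)]),
               collapse = ", "))
  if (anyNA(metadata$age))
    stop("missing age for sample(s): ",
         paste(metadata$sample_id[is.na(metadata$age)], collapse = ", "))
  if (!is.numeric(metadata$age) || any(metadata$age < 0 | metadata$age > 130))
    stop("ages must be numeric years within [0, 130]")
  if (is.null(metadata$cohort)) metadata$cohort <- "discovery"
  metadata
}

#' Read an expression bundle from TSV files
#'
#' Reads a probe x sample expression matrix (first column \code{probe_id},
#' remaining columns one per sample), per-sample metadata
#' (\code{sample_id}, \code{age}, optional \code{cohort}) and, optionally,
#' probe annotation (\code{probe_id}, \code{sncRNA_class}, optional
#' \code{species_tag}). The three are cross-validated: every matrix sample
#' must have exactly one age, and (when given) every probe an annotation.
#'
#' @param matrix_path path to the expression TSV.
#' @param metadata_path path to the sample metadata TSV.
#' @param annotation_path optional path to the probe annotation TSV.
#' @param scale measurement scale of the stored values.
#' @return a list of class \code{"expr_bundle"} with elements \code{expr},
#'   \code{metadata} and \code{annotation} (possibly \code{NULL}).
#' @export
read_expression <- function(matrix_path, metadata_path, annotation_path = NULL,
                            scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  raw <- utils::read.delim(matrix_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (names(raw)[1] != "probe_id")
    stop("expression matrix must have 'probe_id' as its first column")
  vals <- raw[, -1, drop = FALSE]
  numeric_ok <- vapply(vals, is.numeric, logical(1))
  if (!all(numeric_ok))
    stop("non-numeric cells in sample column(s): ",
         paste(names(vals)[!numeric_ok], collapse = ", "))
  expr <- expression_matrix(as.matrix(vals), probe_ids = raw$probe_id,
                            sample_ids = names(vals), scale = scale)

  metadata <- validate_metadata(
    utils::read.delim(metadata_path, stringsAsFactors = FALSE))
  absent <- setdiff(colnames(expr), metadata$sample_id)
  if (length(absent))
    stop("sample(s) absent from metadata: ", paste(absent, collapse = ", "))
  metadata <- metadata[match(colnames(expr), metadata$sample_id), ,
                       drop = FALSE]
  rownames(metadata) <- NULL

  annotation <- NULL
  if (!is.null(annotation_path)) {
    annotation <- utils::read.delim(annotation_path, stringsAsFactors = FALSE)
    if (!all(c("probe_id", "sncRNA_class") %in% names(annotation)))
      stop("probe annotation needs columns probe_id and sncRNA_class")
    unannotated <- setdiff(rownames(expr), annotation$probe_id)
    if (length(unannotated))
      stop("probe(s) without annotation: ",
           paste(utils::head(unannotated, 5), collapse = ", "))
  }
  structure(list(expr = expr, metadata = metadata, annotation = annotation),
            class = "expr_bundle")
}

#' Write an expression matrix to TSV
#'
#' Inverse of the matrix part of [read_expression()]; values are written at
#' full double precision so that a write/read round trip is lossless well
#' below 1e-9.
#'
#' @param expr expression matrix.
#' @param path output path.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(probe_id = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Order sample metadata by age, stably
#'
#' Window membership depends on the age ordering, so ties must be broken
#' reproducibly: samples with equal ages keep their input order.
#'
#' @param metadata sample metadata data frame.
#' @return the metadata reordered by nondecreasing age.
#' @export
order_by_age <- function(metadata) {
  metadata <- validate_metadata(metadata)
  out <- metadata[order(metadata$age, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Load a bundled reference table
#'
#' The package ships four plain-text reference tables used by the
#' fixtures-mode pipeline and the candidate cascade:
#' \describe{
#'   \item{table1}{the sliding-window correlation screen hit list (69 rows:
#'     probeset, sncRNA type, Pearson R vs window mean age, last/first window
#'     fold change, trend).}
#'   \item{table2}{the young-vs-elder differential expression hit list
#'     (57 rows: probeset, type, BH-adjusted p, elder/young fold change,
#'     direction).}
#'   \item{table3}{sncRNAs previously associated with aging (one row per
#'     literature report; deduplicate with [prior_aging_set()]).}
#'   \item{table5}{the five qPCR-validated candidate miRNAs with relative
#'     quantification and rank-sum p-values in both cohorts.}
#' }
#'
#' @param table_id one of \code{"table1"}, \code{"table2"}, \code{"table3"},
#'   \code{"table5"}.
#' @return a data frame of typed records.
#' @export
load_fixture <- function(table_id = c("table1", "table2", "table3", "table5")) {
  table_id <- match.arg(table_id)
  file <- switch(table_id,
                 table1 = "table1_correlation_screen.tsv",
                 table2 = "table2_diffexp.tsv",
                 table3 = "table3_prior_aging.tsv",
                 table5 = "table5_validation.tsv")
  path <- system.file("extdata", file, package = "snctrends", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Read a GMT gene-set collection
#'
#' Standard MSigDB dialect: one set per line, fields tab-separated as
#' name, description, gene, gene, ... Duplicate genes within a line are
#' collapsed.
#'
#' @param path path to a .gmt file.
#' @return a named list of character vectors of gene symbols, with a
#'   \code{"descriptions"} attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(fields, length, integer(1)) < 3
  if (any(short))
    stop("GMT line(s) with fewer than 3 fields: line ",
         paste(which(short), collapse = ", "))
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, character(1), 1)
  if (anyDuplicated(names(sets)))
    stop("duplicate gene-set names in GMT")
  if (any(vapply(sets, length, integer(1)) == 0L))
    stop("empty gene set in GMT")
  attr(sets, "descriptions") <- vapply(fields, `[[`, character(1), 2)
  sets
}

#' Write a gene-set collection as GMT
#' @param sets named list of character gene vectors.
#' @param path output path.
#' @param descriptions optional character vector, recycled from the
#'   \code{"descriptions"} attribute or \code{"na"}.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions))
    descriptions <- attr(sets, "descriptions")
  if (is.null(descriptions))
    descriptions <- rep("na", length(sets))
  lines <- mapply(function(nm, desc, genes)
    paste(c(nm, desc, genes), collapse = "\t"),
    names(sets), descriptions, sets)
  writeLines(unname(lines), path)
  invisible(path)
}

#' Read a miRNA-target interaction (MTI) table
#'
#' Headered TSV with columns \code{mirna}, \code{target_gene},
#' \code{evidence} (\code{"strong"} for experimentally validated
#' interactions, \code{"weak"} otherwise). Exact duplicate records are
#' dropped with a warning.
#'
#' @param path path to the TSV.
#' @return a data frame of interactions.
#' @export
read_mti <- function(path) {
  mti <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("mirna", "target_gene", "evidence")
  if (!all(needed %in% names(mti)))
    stop("MTI table needs columns: ", paste(needed, collapse = ", "))
  if (!all(mti$evidence %in% c("strong", "weak")))
    stop("MTI evidence must be 'strong' or 'weak'")
  dup <- duplicated(mti[needed])
  if (any(dup)) {
    warning(sum(dup), " exact duplicate MTI record(s) dropped")
    mti <- mti[!dup, , drop = FALSE]
  }
  rownames(mti) <- NULL
  mti
}

#' Read a Cq table for qPCR analysis
#'
#' Headered TSV with columns \code{sample_id}, \code{assay}, \code{cq}
#' (quantification cycle). Cq values must lie in (0, 45) and each
#' (sample, assay) pair must be unique.
#'
#' @param path path to the TSV.
#' @return a data frame of Cq records.
#' @export
read_cq <- function(path) {
  cq <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_cq(cq)
}

validate_cq <- function(cq) {
  needed <- c("sample_id", "assay", "cq")
  if (!all(needed %in% names(cq)))
    stop("Cq table needs columns: ", paste(needed, collapse = ", "))
  if (!is.numeric(cq$cq) || any(!is.finite(cq$cq)) ||
      any(cq$cq <= 0 | cq$cq >= 45))
    stop("Cq values must be finite and within (0, 45)")
  key <- paste(cq$sample_id, cq$assay, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (sample, assay) pair(s): ",
         paste(unique(sub("\r", " / ", key[duplicated(key)])), collapse = ", "))
  cq
}

#' Build a prior-aging sncRNA set from literature records
#'
#' The bundled table3 lists one row per literature report, so the same
#' sncRNA can appear several times (once per source). This collapses to one
#' record per unique name, keeping the reported direction and concatenating
#' tissues and sources.
#'
#' @param records a data frame with columns \code{name}, \code{direction},
#'   \code{tissue}, \code{reference} (as from \code{load_fixture("table3")}),
#'   or \code{NULL} to use the bundled table.
#' @return a data frame of class \code{"prior_aging_set"}, one row per name.
#' @export
prior_aging_set <- function(records = NULL) {
  if (is.null(records)) records <- load_fixture("table3")
  if (!"name" %in% names(records))
    stop("prior-aging records need a 'name' column")
  nm <- unique(records$name)
  collapse <- function(col) {
    if (!col %in% names(records)) return(rep(NA_character_, length(nm)))
    vapply(nm, function(x)
      paste(unique(records[[col]][records$name == x]), collapse = "; "),
      character(1))
  }
  out <- data.frame(name = nm,
                    direction_reported = collapse("direction"),
                    tissue = collapse("tissue"),
                    source = collapse("reference"),
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("prior_aging_set", "data.frame")
  out
}
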