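#' Per-sample delta-Cq against a reference assay
#'
#' For every sample and assay, delta-Cq = Cq(target) - Cq(reference). Every
#' sample must carry a Cq for the reference assay; the reference assay
#' itself yields delta-Cq 0. Larger delta-Cq means lower expression
#' relative to the reference.
#'
#' @param cq long Cq table (sample_id, assay, cq).
#' @param reference_assay name of the reference (normalizer) assay.
#' @return a data frame: sample_id, assay, delta_cq (reference rows
#'   excluded).
#' @export
delta_cq <- function(cq, reference_assay = "miR-191") {
  cq <- validate_cq(cq)
  ref <- cq[cq$assay == reference_assay, , drop = FALSE]
  if (!nrow(ref))
    stop("reference assay '", reference_assay, "' not present")
  no_ref <- setdiff(unique(cq$sample_id), ref$sample_id)
  if (length(no_ref))
    stop("sample(s) missing a reference Cq: ",
         paste(no_ref, collapse = ", "))
  tgt <- cq[cq$assay != reference_assay, , drop = FALSE]
  ref_cq <- ref$cq[match(tgt$sample_id, ref$sample_id)]
  data.frame(sample_id = tgt$sample_id, assay = tgt$assay,
             delta_cq = tgt$cq - ref_cq,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Wilcoxon rank-sum test p-value
#'
#' Two-sided rank-sum comparison of two samples: the exact permutation
#' distribution of the rank sum when the combined sample size is at most
#' 20 and there are no ties, and otherwise the normal approximation with
#' tie and continuity corrections (via \code{stats::wilcox.test}).
#'
#' @param x,y numeric vectors, each non-empty.
#' @return the two-sided p-value.
#' @export
rank_sum_test <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  exact <- (length(x) + length(y) <= 20) && !anyDuplicated(c(x, y))
  stats::wilcox.test(x, y, exact = exact, correct = TRUE)$p.value
}

#' Group-level relative quantification (2^-ddCq)
#'
#' Livak relative quantification at the group level: for each target
#' assay, delta-delta-Cq is the elder-group mean delta-Cq minus the
#' young-group mean, and the relative quantification is
#' RQ = 2^-ddCq (RQ < 1: lower expression in the elder group). Group
#' difference in per-sample delta-Cq is tested with [rank_sum_test()].
#'
#' @param dcq delta-Cq table from [delta_cq()].
#' @param groups group assignment: a factor/character named by sample id,
#'   or a data frame (sample_id, group); levels young/elder (the labels
#'   young/old are accepted as synonyms).
#' @return an object of class \code{"rq_result"}: a data frame with one
#'   row per assay (assay, n_young, n_elder, dcq_young, dcq_elder, ddcq,
#'   rq, p_value).
#' @export
relative_quantification <- function(dcq, groups) {
  if (is.data.frame(groups)) {
    g <- groups$group
    names(g) <- groups$sample_id
    groups <- g
  }
  nm <- names(groups)
  groups <- as.character(groups)
  groups[groups == "old"] <- "elder"
  names(groups) <- nm
  miss <- setdiff(unique(dcq$sample_id), names(groups))
  if (length(miss))
    stop("sample(s) without a group label: ", paste(miss, collapse = ", "))
  g <- groups[dcq$sample_id]
  if (!all(g %in% c("young", "elder")))
    stop("group labels must be young/elder (or old)")
  rows <- lapply(split(seq_len(nrow(dcq)), dcq$assay), function(idx) {
    gy <- dcq$delta_cq[idx][g[idx] == "young"]
    ge <- dcq$delta_cq[idx][g[idx] == "elder"]
    if (!length(gy) || !length(ge))
      stop("empty group for assay ", dcq$assay[idx[1]])
    ddcq <- mean(ge) - mean(gy)
    data.frame(assay = dcq$assay[idx[1]], n_young = length(gy),
               n_elder = length(ge), dcq_young = mean(gy),
               dcq_elder = mean(ge), ddcq = ddcq, rq = 2^(-ddcq),
               p_value = rank_sum_test(gy, ge),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("rq_result", "data.frame")
  out
}

#' @export
print.rq_result <- function(x, ...) {
  cat("Relative quantification, elder vs young (RQ = 2^-ddCq)\n")
  df <- as.data.frame(unclass(x))
  df$rq <- round(df$rq, 3)
  df$ddcq <- round(df$ddcq, 3)
  df$p_value <- signif(df$p_value, 3)
  print(df[c("assay", "n_young", "n_elder", "ddcq", "rq", "p_value")],
        row.names = FALSE)
  invisible(x)
}

#' Assign samples to closed age bins
#'
#' Bins are closed intervals [lo, hi] in years and must not overlap.
#' Samples whose age falls in no bin get \code{NA} and are reported with a
#' warning.
#'
#' @param metadata sample metadata (sample_id, age).
#' @param bins list of numeric length-2 vectors, default the five ranges
#'   24-40, 41-60, 61-70, 71-80, 81-90.
#' @return a list: \code{membership} (sample_id, age, bin label) and
#'   \code{summary} (bin, n, mean_age).
#' @export
bin_by_age <- function(metadata,
                       bins = list(c(24, 40), c(41, 60), c(61, 70),
                                   c(71, 80), c(81, 90))) {
  metadata <- validate_metadata(metadata)
  lo <- vapply(bins, `[`, numeric(1), 1)
  hi <- vapply(bins, `[`, numeric(1), 2)
  if (any(lo > hi)) stop("each bin needs lo <= hi")
  ord <- order(lo)
  if (any(lo[ord][-1] <= hi[ord][-length(ord)]))
    stop("bins overlap")
  labels <- paste0(lo, "-", hi)
  bin <- rep(NA_character_, nrow(metadata))
  for (i in seq_along(bins))
    bin[metadata$age >= lo[i] & metadata$age <= hi[i]] <- labels[i]
  if (anyNA(bin))
    warning(sum(is.na(bin)), " sample(s) fall outside all bins")
  membership <- data.frame(sample_id = metadata$sample_id,
                           age = metadata$age, bin = bin,
                           stringsAsFactors = FALSE)
  inb <- membership[!is.na(bin), , drop = FALSE]
  summary <- data.frame(
    bin = labels,
    n = vapply(labels, function(l) sum(inb$bin == l), integer(1)),
    mean_age = vapply(labels, function(l) {
      v <- inb$age[inb$bin == l]
      if (length(v)) mean(v) else NA_real_
    }, numeric(1)), stringsAsFactors = FALSE, row.names = NULL)
  list(membership = membership, summary = summary)
}

#' Full qPCR validation analysis
#'
#' Convenience orchestrator: computes per-sample delta-Cq against the
#' reference assay, splits the cohort at the age cutoff, runs group-level
#' relative quantification with rank-sum tests, and (optionally) reports
#' mean delta-Cq per age bin and assay.
#'
#' @param cq long Cq table (sample_id, assay, cq).
#' @param metadata sample metadata (sample_id, age) covering all Cq
#'   samples.
#' @param reference_assay reference (normalizer) assay name.
#' @param cutoff young/elder age cutoff in years.
#' @param bins optional age-bin list as in [bin_by_age()]; \code{NULL}
#'   skips binning.
#' @return an \code{"rq_result"} data frame, with the per-bin mean
#'   delta-Cq table (assay x bin) attached as attribute \code{"by_bin"}
#'   when bins are requested.
#' @export
rq_analysis <- function(cq, metadata, reference_assay = "miR-191",
                        cutoff = 50, bins = NULL) {
  dcq <- delta_cq(cq, reference_assay = reference_assay)
  miss <- setdiff(unique(dcq$sample_id), metadata$sample_id)
  if (length(miss))
    stop("Cq sample(s) missing from metadata: ",
         paste(miss, collapse = ", "))
  groups <- split_groups(metadata[metadata$sample_id %in% dcq$sample_id, ,
                                  drop = FALSE], cutoff = cutoff)
  res <- relative_quantification(dcq, groups)
  if (!is.null(bins)) {
    mem <- bin_by_age(metadata, bins)$membership
    dcq$bin <- mem$bin[match(dcq$sample_id, mem$sample_id)]
    keep <- !is.na(dcq$bin)
    by_bin <- tapply(dcq$delta_cq[keep],
                     list(dcq$assay[keep], dcq$bin[keep]), mean)
    attr(res, "by_bin") <- by_bin
  }
  res
}
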