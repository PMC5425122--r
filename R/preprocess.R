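#' Quantile-normalize an expression matrix
#'
#' Forces every sample column to share the same value distribution: values
#' are ranked within each column and replaced by the across-sample mean of
#' the sorted values at each rank; tied values receive the mean of the tied
#' ranks' reference values. Delegates to \code{limma::normalizeQuantiles}.
#'
#' The transform is idempotent and leaves all column means equal.
#'
#' @param expr expression matrix with at least 2 samples and no missing
#'   values.
#' @return the normalized matrix (dimnames and scale preserved).
#' @export
quantile_normalize <- function(expr) {
  if (ncol(expr) < 2) stop("quantile normalization needs >= 2 samples")
  if (anyNA(expr)) stop("missing values are not supported")
  out <- limma::normalizeQuantiles(expr, ties = TRUE)
  dimnames(out) <- dimnames(expr)
  attr(out, "scale") <- expr_scale(expr)
  out
}

#' Filter probes by species tag or explicit keep-list
#'
#' Mirrors the pre-screen filtering step of sncRNA arrays, which carry
#' probesets for several species: only probes whose annotated species tag
#' matches \code{keep_species} are retained, in their original order.
#' Alternatively an explicit \code{keep_probes} list (e.g. a pre-made
#' above-background call set) can be supplied.
#'
#' @param expr expression matrix.
#' @param annotation probe annotation data frame with columns
#'   \code{probe_id} and \code{species_tag} (required unless
#'   \code{keep_probes} is given).
#' @param keep_species species tag to retain (default \code{"human"}).
#' @param keep_probes optional character vector of probe ids to retain,
#'   bypassing the species filter.
#' @return the filtered matrix.
#' @export
filter_probes <- function(expr, annotation = NULL, keep_species = "human",
                          keep_probes = NULL) {
  if (is.null(keep_probes)) {
    if (is.null(annotation))
      stop("either annotation or keep_probes must be supplied")
    if (!all(c("probe_id", "species_tag") %in% names(annotation)))
      stop("annotation needs columns probe_id and species_tag")
    missing <- setdiff(rownames(expr), annotation$probe_id)
    if (length(missing))
      stop("probe(s) without annotation: ",
           paste(utils::head(missing, 5), collapse = ", "))
    tags <- annotation$species_tag[match(rownames(expr), annotation$probe_id)]
    keep_probes <- rownames(expr)[tags == keep_species]
  }
  keep <- rownames(expr) %in% keep_probes
  if (!any(keep))
    stop("no probes retained; the species/keep-list filter is too strict")
  out <- expr[keep, , drop = FALSE]
  attr(out, "scale") <- expr_scale(expr)
  out
}
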