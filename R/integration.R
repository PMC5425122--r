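#' Normalize a miRNA/sncRNA probe name to a canonical form
#'
#' Array probeset names decorate the underlying sncRNA name with platform
#' suffixes. Normalization strips the trailing \code{_st} / \code{_x_st} /
#' \code{_s_st} suffix, rewrites the \code{-star} decoration to the
#' \code{*} (minor-arm) convention, and finally applies a static alias
#' table mapping historical miRNA names to their current form (names
#' without an alias pass through unchanged). The package bundles a small
#' alias snapshot; supply your own table to track another nomenclature
#' release.
#'
#' @param name character vector of probeset or miRNA names.
#' @param alias_table data frame with columns \code{alias},
#'   \code{canonical}, or \code{NULL} for the bundled table, or \code{NA}
#'   to skip aliasing.
#' @return canonical names, same length as the input.
#' @examples
#' normalize_mirna_name(c("hsa-miR-93-star_st", "hsa-let-7g_st", "U43_x_st"))
#' @export
normalize_mirna_name <- function(name, alias_table = NULL) {
  out <- sub("(_[xs])?_st$", "", name)
  out <- sub("-star$", "*", out)
  if (is.null(alias_table))
    alias_table <- utils::read.delim(
      system.file("extdata", "mirna_alias_table.tsv", package = "snctrends",
                  mustWork = TRUE), stringsAsFactors = FALSE)
  if (is.data.frame(alias_table)) {
    hit <- match(out, alias_table$alias)
    out[!is.na(hit)] <- alias_table$canonical[hit[!is.na(hit)]]
  }
  out
}

# Species-prefix-insensitive key used when matching probes against
# literature name lists written without the "hsa-" prefix.
mirna_match_key <- function(name) sub("^hsa-", "", name)

#' Set algebra between two hit lists
#'
#' @param a,b character vectors of probeset ids (compared verbatim).
#' @return a list with n_a, n_b, n_intersect, n_union and
#'   pct_overlap_of_union (= 100 * intersection / union).
#' @export
set_overlap <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  ni <- length(intersect(a, b))
  nu <- length(union(a, b))
  list(n_a = length(a), n_b = length(b), n_intersect = ni, n_union = nu,
       pct_overlap_of_union = if (nu) 100 * ni / nu else NA_real_)
}

#' Compare the sliding-window and differential-expression screens
#'
#' Exact string-match set algebra on probeset ids, reported separately for
#' miRNA probes and all other sncRNA classes (snoRNA family). Inputs can be
#' the screen tables (with \code{probeset} and \code{type} columns, where
#' any type other than \code{"miRNA"} counts as snoRNA) or bare vectors
#' plus an annotation.
#'
#' @param trend_table data frame with columns probeset, type (e.g. the
#'   trend screen's hit list).
#' @param de_table data frame with columns probeset, type (e.g. the
#'   differential-expression hit list).
#' @return a data frame of class \code{"overlap_report"}: one row per class
#'   (miRNA, snoRNA) with n_a, n_b, n_intersect, n_union,
#'   pct_overlap_of_union.
#' @export
compare_screens <- function(trend_table, de_table) {
  for (tb in list(trend_table, de_table))
    if (!all(c("probeset", "type") %in% names(tb)))
      stop("both tables need columns probeset and type")
  cls_of <- function(type) ifelse(type == "miRNA", "miRNA", "snoRNA")
  rows <- lapply(c("miRNA", "snoRNA"), function(cls) {
    a <- trend_table$probeset[cls_of(trend_table$type) == cls]
    b <- de_table$probeset[cls_of(de_table$type) == cls]
    ov <- set_overlap(a, b)
    data.frame(class = cls, ov, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("overlap_report", "data.frame")
  out
}

#' Two-stage candidate-selection cascade
#'
#' Stage 1 keeps screen hits with a last/first window fold change of at
#' least \code{fc_cut} (up) or at most \code{1/fc_cut} (down). Stage 2
#' keeps those whose normalized name (suffixes stripped, species prefix
#' ignored) appears in a prior-aging set of sncRNAs already reported as
#' age-associated.
#'
#' @param trend_table data frame with columns probeset and fc_last_first
#'   (e.g. a trend screen's hit rows).
#' @param fc_cut fold-change cutoff (> 1).
#' @param prior a \code{"prior_aging_set"} (or data frame with a
#'   \code{name} column); \code{NULL} uses the bundled literature set.
#' @param alias_table passed to [normalize_mirna_name()].
#' @return a list: \code{stage1} (the fold-change-filtered rows, with a
#'   \code{name} column of normalized names) and \code{candidates} (the
#'   prior-supported subset, ordered as in stage 1).
#' @export
candidate_filter <- function(trend_table, fc_cut = 2.0, prior = NULL,
                             alias_table = NA) {
  if (fc_cut <= 1) stop("fc_cut must exceed 1")
  if (!all(c("probeset", "fc_last_first") %in% names(trend_table)))
    stop("trend_table needs columns probeset and fc_last_first")
  if (is.null(prior)) prior <- prior_aging_set()
  fc <- trend_table$fc_last_first
  keep <- fc >= fc_cut | fc <= 1 / fc_cut
  stage1 <- trend_table[keep, , drop = FALSE]
  stage1$name <- mirna_match_key(
    normalize_mirna_name(stage1$probeset, alias_table = alias_table))
  prior_keys <- mirna_match_key(prior$name)
  candidates <- stage1[stage1$name %in% prior_keys, , drop = FALSE]
  rownames(stage1) <- rownames(candidates) <- NULL
  list(stage1 = stage1, candidates = candidates)
}

#' Filter miRNA-target interactions and collect unique target genes
#'
#' Restricts an MTI table to the given miRNAs at the given evidence level
#' and returns the unique target genes, optionally split by each miRNA's
#' trend direction. miRNA names on both sides are normalized via
#' [normalize_mirna_name()] before matching; queried miRNAs absent from
#' the table yield empty sets and are reported via \code{message}.
#'
#' @param mti MTI data frame (mirna, target_gene, evidence).
#' @param mirnas character vector of miRNA names to query.
#' @param evidence evidence level to keep (default \code{"strong"}).
#' @param direction optional character vector parallel to \code{mirnas}
#'   (e.g. increasing/decreasing); when given, one gene set per direction
#'   is returned.
#' @param alias_table passed to [normalize_mirna_name()].
#' @return when \code{direction} is \code{NULL}, a character vector of
#'   unique target genes; otherwise a named list of such vectors, one per
#'   direction level.
#' @export
filter_mti <- function(mti, mirnas, evidence = "strong", direction = NULL,
                       alias_table = NA) {
  key_tab <- normalize_mirna_name(mti$mirna, alias_table = alias_table)
  key_q <- normalize_mirna_name(mirnas, alias_table = alias_table)
  sub <- mti[mti$evidence == evidence, , drop = FALSE]
  key_sub <- key_tab[mti$evidence == evidence]
  absent <- setdiff(key_q, key_tab)
  if (length(absent))
    message("miRNA(s) absent from the MTI table: ",
            paste(absent, collapse = ", "))
  pick <- function(keys) unique(sub$target_gene[key_sub %in% keys])
  if (is.null(direction)) return(pick(key_q))
  out <- lapply(split(key_q, direction), pick)
  out
}

#' Hypergeometric overlap tail probability
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): the chance of drawing at
#' least k marked genes when n genes are drawn without replacement from a
#' universe of N containing K marked ones. This is the standard gene-set
#' overlap statistic; computed via \code{stats::phyper} on the upper tail
#' for numerical stability.
#'
#' @param k observed overlap (0 <= k <= min(K, n)).
#' @param K gene-set size.
#' @param n query-list size.
#' @param N universe size.
#' @return the tail probability in (0, 1].
#' @export
hypergeom_overlap <- function(k, K, n, N) {
  if (any(c(k, K, n, N) < 0) || k > min(K, n) || K > N || n > N)
    stop("inconsistent counts: need 0 <= k <= min(K, n) <= N")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Gene-set overlap enrichment of a query gene list
#'
#' Tests each set in a GMT collection for overlap with the query by the
#' hypergeometric tail, BH-adjusts across all sets, and returns the sets
#' significant at the given FDR, sorted by p-value and truncated to
#' \code{top_k}. The universe defaults to the unique genes of the
#' collection; query genes outside the universe are dropped with a
#' message.
#'
#' @param query_genes character vector of gene symbols (non-empty).
#' @param gmt gene-set collection from [read_gmt()] (named list).
#' @param universe_N universe size; default the number of unique genes in
#'   \code{gmt}.
#' @param fdr FDR threshold for reporting (default 0.05).
#' @param top_k maximum number of rows returned (default 20).
#' @return a data frame: set_name, K, k, n, N, k_over_K, p, q.
#' @export
enrich <- function(query_genes, gmt, universe_N = NULL, fdr = 0.05,
                   top_k = 20) {
  if (!length(query_genes)) stop("empty query gene list")
  query_genes <- unique(query_genes)
  universe <- unique(unlist(gmt, use.names = FALSE))
  dropped <- setdiff(query_genes, universe)
  if (length(dropped))
    message(length(dropped), " query gene(s) outside the universe dropped")
  query <- intersect(query_genes, universe)
  N <- if (is.null(universe_N)) length(universe) else universe_N
  n <- length(query)
  K <- vapply(gmt, length, integer(1))
  k <- vapply(gmt, function(s) length(intersect(s, query)), integer(1))
  p <- mapply(hypergeom_overlap, k = k, K = K,
              MoreArgs = list(n = n, N = N))
  q <- bh_adjust(p)
  out <- data.frame(set_name = names(gmt), K = K, k = k, n = n, N = N,
                    k_over_K = k / K, p = p, q = q,
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[out$q < fdr, , drop = FALSE]
  out <- out[order(out$p, out$set_name), , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, top_k)
}
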