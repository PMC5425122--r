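#' Split a cohort into young and elder groups at an age cutoff
#'
#' Young means age <= cutoff; elder means age > cutoff (the boundary sample
#' is young).
#'
#' @param metadata sample metadata (sample_id, age).
#' @param cutoff age cutoff in years (default 50).
#' @return a factor with levels young, elder, named by sample id.
#' @export
split_groups <- function(metadata, cutoff = 50) {
  metadata <- validate_metadata(metadata)
  g <- factor(ifelse(metadata$age <= cutoff, "young", "elder"),
              levels = c("young", "elder"))
  names(g) <- metadata$sample_id
  counts <- table(g)
  if (any(counts < 2))
    stop("group(s) with fewer than 2 samples at cutoff ", cutoff, ": ",
         paste(names(counts)[counts < 2], collapse = ", "))
  g
}

# Invert trigamma by Newton iteration (monotone decreasing on (0, Inf)).
trigamma_inverse <- function(x) {
  out <- x
  out[x > 1e7] <- 1 / sqrt(x[x > 1e7])
  out[x < 1e-6] <- 1 / x[x < 1e-6]
  idx <- which(x <= 1e7 & x >= 1e-6)
  if (length(idx)) {
    y <- 0.5 + 1 / x[idx]
    for (i in 1:50) {
      tri <- trigamma(y)
      dif <- tri * (1 - tri / x[idx]) / psigamma(y, deriv = 2)
      y <- y + dif
      if (max(abs(dif / y)) < 1e-10) break
    }
    out[idx] <- y
  }
  out
}

# Fit a scaled F (inverse-chi-square prior) to sample variances s2 with df
# degrees of freedom each, by moments on log(s2): returns the prior df d0
# (possibly Inf) and prior variance s02.
fit_variance_prior <- function(s2, df) {
  s2 <- pmax(s2, 1e-12 * stats::median(s2[s2 > 0]))
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- stats::var(e) - trigamma(df / 2)
  if (is.na(evar) || evar <= 0)
    return(list(d0 = Inf, s02 = mean(s2)))
  d0 <- 2 * trigamma_inverse(evar)
  s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s02 = s02)
}

#' Moderated two-group t-statistics
#'
#' Per-probe equal-variance two-sample t-statistics (elder minus young) in
#' which the pooled residual variance is shrunk towards a common prior by
#' empirical Bayes: the prior degrees of freedom d0 and prior variance s0^2
#' are fitted by moments on the log residual variances, each probe's
#' variance becomes the weighted combination
#' \deqn{s^2_{mod} = (d_0 s_0^2 + d s^2) / (d_0 + d)}
#' and p-values come from the t distribution with d0 + d degrees of
#' freedom. With \code{prior_df_mode = "none"} no shrinkage is applied and
#' the result is the classical pooled t.
#'
#' @param expr expression matrix (log2 scale assumed for the statistics).
#' @param labels factor of group labels with levels young, elder (as from
#'   [split_groups()]), aligned with the matrix columns by name.
#' @param prior_df_mode \code{"eb"} (empirical-Bayes shrinkage, default) or
#'   \code{"none"}.
#' @return a data frame with per-probe mean_young, mean_elder, t, df,
#'   p_raw; the fitted hyperparameters are attached as attributes
#'   \code{"d0"} and \code{"s02"}.
#' @export
moderated_t <- function(expr, labels, prior_df_mode = c("eb", "none")) {
  prior_df_mode <- match.arg(prior_df_mode)
  if (!is.null(names(labels))) {
    if (!all(colnames(expr) %in% names(labels)))
      stop("labels missing for sample(s): ",
           paste(setdiff(colnames(expr), names(labels)), collapse = ", "))
    labels <- labels[colnames(expr)]
  }
  labels <- factor(labels, levels = c("young", "elder"))
  n1 <- sum(labels == "young")
  n2 <- sum(labels == "elder")
  if (n1 < 2 || n2 < 2) stop("need >= 2 samples per group")
  y <- expr[, labels == "young", drop = FALSE]
  e <- expr[, labels == "elder", drop = FALSE]
  m1 <- rowMeans(y)
  m2 <- rowMeans(e)
  ss <- rowSums((y - m1)^2) + rowSums((e - m2)^2)
  d <- n1 + n2 - 2
  if (d < 1) stop("zero residual degrees of freedom")
  s2 <- ss / d

  if (prior_df_mode == "eb") {
    prior <- fit_variance_prior(s2, d)
    if (is.finite(prior$d0)) {
      s2_mod <- (prior$d0 * prior$s02 + d * s2) / (prior$d0 + d)
    } else {
      s2_mod <- rep(prior$s02, length(s2))
    }
    # information cannot exceed pooling the residuals of every probe
    df_total <- min(prior$d0 + d, length(s2) * d)
  } else {
    prior <- list(d0 = 0, s02 = NA_real_)
    s2_mod <- s2
    df_total <- d
  }
  tstat <- (m2 - m1) / sqrt(s2_mod * (1 / n1 + 1 / n2))
  p <- 2 * stats::pt(-abs(tstat), df = df_total)
  out <- data.frame(probeset = rownames(expr), mean_young = m1,
                    mean_elder = m2, t = tstat, df = df_total, p_raw = p,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "d0") <- prior$d0
  attr(out, "s02") <- prior$s02
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values controlling the false discovery rate,
#' delegated to \code{stats::p.adjust(method = "BH")} after validating the
#' input range.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted p-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Young-vs-elder differential expression
#'
#' Splits the cohort at the age cutoff, computes moderated t-statistics
#' (see [moderated_t()]), BH-adjusts the p-values and reports per-probe
#' elder/young fold changes (2^(mean_elder - mean_young) on the log2
#' scale). A probe is UP when adjusted p < alpha and fold change > 1, DOWN
#' when adjusted p < alpha and fold change < 1, otherwise unchanged.
#'
#' @param expr expression matrix (log2).
#' @param metadata sample metadata (sample_id, age).
#' @param cutoff age cutoff in years between young and elder.
#' @param alpha FDR level for calling direction.
#' @param prior_df_mode passed to [moderated_t()].
#' @return an object of class \code{"de_fit"} with elements \code{table}
#'   (probeset, mean_young, mean_elder, fc_elder_young, t, p_raw, p_adj,
#'   direction), \code{groups}, and the parameters.
#' @export
diff_expression <- function(expr, metadata, cutoff = 50, alpha = 0.05,
                            prior_df_mode = "eb") {
  if (expr_scale(expr) != "log2")
    stop("differential expression expects a log2 matrix")
  groups <- split_groups(metadata, cutoff = cutoff)
  mt <- moderated_t(expr, groups, prior_df_mode = prior_df_mode)
  p_adj <- bh_adjust(mt$p_raw)
  fc <- 2^(mt$mean_elder - mt$mean_young)
  direction <- rep("none", nrow(mt))
  direction[p_adj < alpha & fc > 1] <- "UP"
  direction[p_adj < alpha & fc < 1] <- "DOWN"
  table <- data.frame(mt[c("probeset", "mean_young", "mean_elder")],
                      fc_elder_young = fc, t = mt$t, p_raw = mt$p_raw,
                      p_adj = p_adj, direction = direction,
                      stringsAsFactors = FALSE, row.names = NULL)
  structure(list(table = table, groups = groups,
                 params = list(cutoff = cutoff, alpha = alpha,
                               prior_df_mode = prior_df_mode,
                               d0 = attr(mt, "d0"), s02 = attr(mt, "s02"))),
            class = "de_fit")
}

#' @export
print.de_fit <- function(x, ...) {
  n_up <- sum(x$table$direction == "UP")
  n_down <- sum(x$table$direction == "DOWN")
  cat("Young vs elder differential expression (cutoff ", x$params$cutoff,
      " y, FDR ", x$params$alpha, ")\n", sep = "")
  cat("  groups: young ", sum(x$groups == "young"), ", elder ",
      sum(x$groups == "elder"), "\n", sep = "")
  if (x$params$prior_df_mode == "eb")
    cat("  prior df d0 = ", signif(x$params$d0, 4), ", prior variance = ",
        signif(x$params$s02, 4), "\n", sep = "")
  cat("  ", n_up, " UP, ", n_down, " DOWN of ", nrow(x$table),
      " probes\n", sep = "")
  invisible(x)
}

#' @export
summary.de_fit <- function(object, ...) {
  print(object)
  hits <- object$table[object$table$direction != "none", , drop = FALSE]
  if (nrow(hits)) {
    hits <- hits[order(hits$p_adj), ]
    cat("\nTop hits by adjusted p:\n")
    print(utils::head(hits[c("probeset", "fc_elder_young", "p_adj",
                             "direction")], 10),
          row.names = FALSE, digits = 3)
  }
  invisible(object$table)
}

#' @export
as.data.frame.de_fit <- function(x, ...) x$table
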