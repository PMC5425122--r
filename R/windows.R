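#' Build age-ordered sliding windows
#'
#' Samples are ordered by age (stable sort: ties keep input order) and
#' grouped into overlapping windows of \code{w} consecutive samples, sliding
#' by \code{step}. With n samples the natural window count is
#' floor((n - w)/step) + 1; \code{n_windows} or \code{drop_last} can reduce
#' it, e.g. to match an analysis that stopped one window short.
#'
#' @param metadata sample metadata (sample_id, age).
#' @param w window size (number of samples per window).
#' @param step slide in samples between consecutive windows.
#' @param n_windows optional cap on the number of windows.
#' @param drop_last drop the final window.
#' @return a list of class \code{"window_series"}: \code{windows} (list of
#'   sample-id vectors), \code{mean_age}, \code{w}, \code{step}.
#' @export
build_windows <- function(metadata, w = 10, step = 1, n_windows = NULL,
                          drop_last = FALSE) {
  metadata <- order_by_age(metadata)
  n <- nrow(metadata)
  if (n < w) stop("need at least w = ", w, " samples, got ", n)
  if (step < 1) stop("step must be >= 1")
  k <- floor((n - w) / step) + 1
  if (drop_last) k <- k - 1
  if (!is.null(n_windows)) {
    if (n_windows < 1 || n_windows > k)
      stop("n_windows must be between 1 and ", k)
    k <- n_windows
  }
  if (k < 1) stop("no windows left")
  windows <- lapply(seq_len(k), function(i) {
    idx <- ((i - 1) * step + 1):((i - 1) * step + w)
    metadata$sample_id[idx]
  })
  mean_age <- vapply(seq_len(k), function(i) {
    idx <- ((i - 1) * step + 1):((i - 1) * step + w)
    mean(metadata$age[idx])
  }, numeric(1))
  structure(list(windows = windows, mean_age = mean_age, w = w, step = step),
            class = "window_series")
}

#' Per-window mean expression
#'
#' @param expr expression matrix.
#' @param windows a \code{"window_series"} from [build_windows()].
#' @return probes x windows matrix of arithmetic means (on the stored
#'   scale), with the window mean ages as a \code{"mean_age"} attribute.
#' @export
window_means <- function(expr, windows) {
  missing <- setdiff(unique(unlist(windows$windows)), colnames(expr))
  if (length(missing))
    stop("window member(s) absent from matrix: ",
         paste(missing, collapse = ", "))
  wm <- vapply(windows$windows,
               function(ids) rowMeans(expr[, ids, drop = FALSE]),
               numeric(nrow(expr)))
  wm <- matrix(wm, nrow = nrow(expr),
               dimnames = list(rownames(expr), NULL))
  attr(wm, "mean_age") <- windows$mean_age
  attr(wm, "scale") <- expr_scale(expr)
  wm
}

#' Row-wise z-scores across windows
#'
#' Standardizes each probe's window-mean series to mean 0 and population
#' (n-denominator) standard deviation 1. Constant rows cannot be
#' standardized; they become all-zero and are flagged in the
#' \code{"constant"} attribute (a logical vector).
#'
#' @param wm probes x windows matrix (>= 2 windows).
#' @return the z-scored matrix with attributes \code{"constant"} and
#'   \code{"mean_age"} (carried over when present).
#' @export
zscore_rows <- function(wm) {
  if (ncol(wm) < 2) stop("z-scoring needs >= 2 windows")
  ctr <- wm - rowMeans(wm)
  sd_pop <- sqrt(rowMeans(ctr^2))
  constant <- sd_pop < .Machine$double.eps^0.5 * (1 + abs(rowMeans(wm)))
  z <- ctr / ifelse(constant, 1, sd_pop)
  z[constant, ] <- 0
  attr(z, "constant") <- constant
  attr(z, "mean_age") <- attr(wm, "mean_age")
  z
}

#' Pearson product-moment correlation
#'
#' Thin validated wrapper around \code{stats::cor} used by the screen;
#' constant inputs have no defined correlation and return \code{NA} with a
#' warning (the screen classifies such probes as trendless).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return correlation in [-1, 1], or NA for constant input.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 points")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant input: correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y)
}

#' Last-window / first-window fold change
#'
#' The screen's effect-size measure: the ratio of the last window's mean
#' expression to the first window's. On the log2 scale this is
#' 2^(m_last - m_first); on the linear scale the direct ratio (positive
#' first-window means required).
#'
#' @param wm probes x windows matrix (>= 2 windows).
#' @param scale \code{"log2"} or \code{"linear"}; defaults to the matrix's
#'   stored scale.
#' @return per-probe fold-change vector.
#' @export
fold_change_last_first <- function(wm, scale = NULL) {
  if (ncol(wm) < 2) stop("need >= 2 windows")
  if (is.null(scale)) scale <- expr_scale(wm)
  first <- wm[, 1]
  last <- wm[, ncol(wm)]
  if (scale == "log2") return(2^(last - first))
  if (any(first <= 0))
    stop("linear-scale fold change needs positive first-window means")
  last / first
}

#' Classify probes into age trends from correlation and fold change
#'
#' A probe is \code{increasing} when its correlation with window mean age
#' reaches \code{r_threshold} and its last/first fold change, rounded to
#' \code{rounding} decimals, reaches \code{fc_threshold}; \code{decreasing}
#' symmetrically with r <= -r_threshold and rounded fold change <=
#' round(1/fc_threshold, rounding); otherwise \code{none}. The rounding
#' matches reporting at fixed precision, where e.g. a fold change printed
#' as 1.50 passes a 1.5 cutoff.
#'
#' @param r per-probe Pearson correlation (NA allowed, classified as none).
#' @param fc per-probe last/first fold change.
#' @param r_threshold correlation cutoff in (0, 1].
#' @param fc_threshold fold-change cutoff (> 1).
#' @param rounding decimals used when comparing fold changes.
#' @return character vector in \{increasing, decreasing, none\}.
#' @export
classify_trend <- function(r, fc, r_threshold = 0.75, fc_threshold = 1.5,
                           rounding = 2) {
  if (r_threshold <= 0 || r_threshold > 1)
    stop("r_threshold must be in (0, 1]")
  if (fc_threshold <= 1) stop("fc_threshold must exceed 1")
  fc_r <- round(fc, rounding)
  lo <- round(1 / fc_threshold, rounding)
  trend <- rep("none", length(r))
  trend[!is.na(r) & r >= r_threshold & fc_r >= fc_threshold] <- "increasing"
  trend[!is.na(r) & r <= -r_threshold & fc_r <= lo] <- "decreasing"
  trend
}

#' Sliding-window age-trend screen
#'
#' The core screen: samples are ordered by age and grouped into overlapping
#' windows; each probe's per-window mean expression is z-scored across
#' windows and correlated (Pearson) with the window mean ages; probes with
#' a strong correlation and a sufficient last/first window fold change are
#' classified as increasing or decreasing with age.
#'
#' @param expr expression matrix (log2 intensities by default).
#' @param metadata sample metadata (sample_id, age).
#' @param w,step,n_windows,drop_last window construction, see
#'   [build_windows()].
#' @param r_threshold,fc_threshold,rounding classification, see
#'   [classify_trend()].
#' @param scale overrides the matrix's stored scale for fold changes.
#' @return an object of class \code{"trend_screen"}: \code{table} (data
#'   frame probeset / pearson_r / fc_last_first / trend), \code{windows},
#'   \code{window_means}, \code{zscores}, and the parameters used.
#' @examples
#' sim <- simulate_cohort(seed = 1)
#' scr <- age_trend_screen(sim$expr, sim$metadata)
#' summary(scr)
#' @export
age_trend_screen <- function(expr, metadata, w = 10, step = 1,
                             r_threshold = 0.75, fc_threshold = 1.5,
                             rounding = 2, scale = NULL,
                             n_windows = NULL, drop_last = FALSE) {
  windows <- build_windows(metadata, w = w, step = step,
                           n_windows = n_windows, drop_last = drop_last)
  wm <- window_means(expr, windows)
  if (ncol(wm) < 3)
    stop("screen needs at least 3 windows; reduce w or add samples")
  z <- zscore_rows(wm)
  constant <- attr(z, "constant")
  ages <- windows$mean_age
  r <- rep(NA_real_, nrow(z))
  r[!constant] <- as.vector(stats::cor(t(z[!constant, , drop = FALSE]), ages))
  fc <- fold_change_last_first(wm, scale = scale)
  trend <- classify_trend(r, fc, r_threshold = r_threshold,
                          fc_threshold = fc_threshold, rounding = rounding)
  table <- data.frame(probeset = rownames(expr), pearson_r = r,
                      fc_last_first = fc, trend = trend,
                      stringsAsFactors = FALSE, row.names = NULL)
  structure(list(table = table, windows = windows, window_means = wm,
                 zscores = z,
                 params = list(w = w, step = step, r_threshold = r_threshold,
                               fc_threshold = fc_threshold,
                               rounding = rounding)),
            class = "trend_screen")
}

#' @export
print.trend_screen <- function(x, ...) {
  tab <- table(factor(x$table$trend,
                      levels = c("increasing", "decreasing", "none")))
  cat("Sliding-window age-trend screen\n")
  cat("  ", nrow(x$table), " probes, ", length(x$windows$windows),
      " windows of ", x$windows$w, " samples (step ", x$windows$step, ")\n",
      sep = "")
  cat("  thresholds: |r| >= ", x$params$r_threshold, ", FC >= ",
      x$params$fc_threshold, " or <= ",
      round(1 / x$params$fc_threshold, x$params$rounding), "\n", sep = "")
  cat("  increasing ", tab[["increasing"]], ", decreasing ",
      tab[["decreasing"]], ", none ", tab[["none"]], "\n", sep = "")
  invisible(x)
}

#' @export
summary.trend_screen <- function(object, ...) {
  print(object)
  hits <- object$table[object$table$trend != "none", , drop = FALSE]
  if (nrow(hits)) {
    hits <- hits[order(-abs(hits$pearson_r)), ]
    cat("\nTop hits by |r|:\n")
    print(utils::head(hits, 10), row.names = FALSE, digits = 3)
  }
  invisible(object$table)
}

#' @export
as.data.frame.trend_screen <- function(x, ...) x$table

#' @export
plot.trend_screen <- function(x, ...) {
  pair <- mean_trajectories(x)
  plot(pair, ...)
}
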