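#' Mean z-score trajectories of increasing and decreasing probes
#'
#' Averages (unweighted) the z-scored window-mean rows of all probes
#' classified as increasing, and separately of those classified as
#' decreasing, over the window mean ages. The point where the two mean
#' curves meet is the cohort's candidate "critical age".
#'
#' @param screen a \code{"trend_screen"} object, or a z-score matrix (then
#'   \code{trend} and \code{mean_age} are required).
#' @param trend per-probe trend labels (for the matrix form).
#' @param mean_age window mean ages (for the matrix form).
#' @return a list of class \code{"trajectory_pair"}: \code{ages},
#'   \code{mean_z_increasing}, \code{mean_z_decreasing}, and the member
#'   counts.
#' @export
mean_trajectories <- function(screen, trend = NULL, mean_age = NULL) {
  if (inherits(screen, "trend_screen")) {
    z <- screen$zscores
    trend <- screen$table$trend
    mean_age <- screen$windows$mean_age
  } else {
    z <- screen
    if (is.null(trend) || is.null(mean_age))
      stop("trend and mean_age are required with a plain matrix")
  }
  for (cls in c("increasing", "decreasing"))
    if (!any(trend == cls))
      stop("no probes in class '", cls, "'")
  inc <- colMeans(z[trend == "increasing", , drop = FALSE])
  dec <- colMeans(z[trend == "decreasing", , drop = FALSE])
  structure(list(ages = mean_age, mean_z_increasing = unname(inc),
                 mean_z_decreasing = unname(dec),
                 n_increasing = sum(trend == "increasing"),
                 n_decreasing = sum(trend == "decreasing")),
            class = "trajectory_pair")
}

#' Crossing age(s) of the increasing and decreasing trajectories
#'
#' Finds where the difference d = mean_z_increasing - mean_z_decreasing
#' changes sign over window mean age. Each sign change is located by linear
#' interpolation between the flanking window ages; an exact zero reports
#' that window's age itself. The first (youngest) crossing is the primary
#' one.
#'
#' @param pair a \code{"trajectory_pair"}.
#' @return a list of class \code{"crossing_report"}: \code{crossing_ages}
#'   (possibly empty), \code{primary_crossing} (NA when there is none).
#' @export
crossing_age <- function(pair) {
  stopifnot(inherits(pair, "trajectory_pair"))
  d <- pair$mean_z_increasing - pair$mean_z_decreasing
  a <- pair$ages
  if (length(d) < 2) stop("need at least 2 windows")
  crossings <- numeric(0)
  for (k in seq_along(d)) {
    if (d[k] == 0) {
      crossings <- c(crossings, a[k])
    } else if (k < length(d) && d[k + 1] != 0 && sign(d[k]) != sign(d[k + 1])) {
      crossings <- c(crossings,
                     a[k] + (a[k + 1] - a[k]) * d[k] / (d[k] - d[k + 1]))
    }
  }
  crossings <- unique(crossings)
  structure(list(crossing_ages = crossings,
                 primary_crossing = if (length(crossings)) crossings[1]
                                    else NA_real_),
            class = "crossing_report")
}

#' @export
print.crossing_report <- function(x, ...) {
  if (!length(x$crossing_ages)) {
    cat("No crossing of the mean trajectories\n")
  } else {
    cat("Trajectory crossing age(s):",
        paste(round(x$crossing_ages, 1), collapse = ", "), "years\n")
    cat("  primary (youngest):", round(x$primary_crossing, 1), "years\n")
  }
  invisible(x)
}

#' Steepest-change (acceleration) age interval
#'
#' Formalizes "the period where the age trend is most pronounced": the
#' absolute slope of d = mean_z_increasing - mean_z_decreasing over age is
#' estimated per window by central differences (one-sided at the ends), and
#' the interval is the age span of the longest contiguous run of windows
#' whose slope reaches the given quantile of all slopes. When all slopes
#' are (numerically) equal there is no distinguished interval: the full age
#' range is returned with \code{flat = TRUE}.
#'
#' @param pair a \code{"trajectory_pair"} with >= 3 windows.
#' @param quantile slope quantile defining "steep" (default 0.75).
#' @return a list: \code{age_lo}, \code{age_hi}, \code{flat}.
#' @export
steepest_change_interval <- function(pair, quantile = 0.75) {
  stopifnot(inherits(pair, "trajectory_pair"))
  d <- pair$mean_z_increasing - pair$mean_z_decreasing
  a <- pair$ages
  m <- length(d)
  if (m < 3) stop("need at least 3 windows")
  s <- numeric(m)
  s[1] <- abs(d[2] - d[1]) / abs(a[2] - a[1])
  s[m] <- abs(d[m] - d[m - 1]) / abs(a[m] - a[m - 1])
  mid <- 2:(m - 1)
  s[mid] <- abs(d[mid + 1] - d[mid - 1]) / abs(a[mid + 1] - a[mid - 1])
  if (diff(range(s)) < 1e-12 * (1 + max(abs(s))))
    return(list(age_lo = min(a), age_hi = max(a), flat = TRUE))
  thr <- stats::quantile(s, quantile, names = FALSE)
  steep <- s >= thr
  runs <- rle(steep)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  hit <- which(runs$values)
  best <- hit[which.max(runs$lengths[hit])]
  list(age_lo = a[starts[best]], age_hi = a[ends[best]], flat = FALSE)
}

#' @export
print.trajectory_pair <- function(x, ...) {
  cat("Mean z-score trajectories over", length(x$ages), "windows\n")
  cat("  increasing set:", x$n_increasing, "probes; decreasing set:",
      x$n_decreasing, "probes\n")
  cat("  window mean ages:", round(min(x$ages), 1), "-",
      round(max(x$ages), 1), "years\n")
  invisible(x)
}

#' Plot the increasing/decreasing mean trajectories
#'
#' @param x a \code{"trajectory_pair"}.
#' @param mark_crossing draw the primary crossing age.
#' @param ... passed to \code{matplot}.
#' @export
plot.trajectory_pair <- function(x, mark_crossing = TRUE, ...) {
  graphics::matplot(x$ages,
                    cbind(x$mean_z_increasing, x$mean_z_decreasing),
                    type = "l", lty = 1, lwd = 2, col = c("firebrick",
                                                          "steelblue"),
                    xlab = "window mean age (years)", ylab = "mean z-score",
                    ...)
  graphics::legend("topleft", bty = "n", lwd = 2,
                   col = c("firebrick", "steelblue"),
                   legend = c(paste0("increasing (n=", x$n_increasing, ")"),
                              paste0("decreasing (n=", x$n_decreasing, ")")))
  if (mark_crossing) {
    cr <- crossing_age(x)
    if (!is.na(cr$primary_crossing))
      graphics::abline(v = cr$primary_crossing, lty = 2, col = "grey40")
  }
  invisible(x)
}
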