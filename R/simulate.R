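#' Simulate a cross-sectional expression cohort with age trends
#'
#' Generates a probe x sample log2 expression matrix in which a fraction of
#' probes follow a sigmoidal (logistic) trajectory over age and the rest are
#' flat, plus Gaussian measurement noise. The logistic shape encodes the
#' working model of progressive age-related change: expression drifts slowly
#' in early adulthood, changes fastest around an inflection age \code{a0},
#' and plateaus later - which also makes the mean z-score curves of
#' increasing and decreasing probes cross near \code{a0}.
#'
#' For probe i with class s (+1 increasing, -1 decreasing, 0 null), sample j
#' with age a_j:
#' \deqn{x_{ij} = b_i + s A \,\mathrm{logistic}((a_j - a_0)/\tau) + \epsilon_{ij},
#'   \quad \epsilon_{ij} \sim N(0, \sigma^2)}
#' with baselines b_i uniform on \code{baseline_range}.
#'
#' Defaults mirror the study conditions the pipeline targets: 38 donors aged
#' 24-79, inflection at 50 years, a 4-year logistic scale, an amplitude of
#' 1 log2 unit (an expected last/first fold change near 2), and 0.3 log2
#' units of noise.
#'
#' @param n_samples number of donors (>= 2).
#' @param age_range numeric length-2, youngest and oldest possible age;
#'   ages are drawn uniformly unless \code{ages} is supplied.
#' @param ages optional explicit age vector (overrides \code{n_samples} and
#'   \code{age_range}), e.g. to match an observed age histogram.
#' @param n_probes total number of probes.
#' @param frac_increasing,frac_decreasing fractions of truly increasing and
#'   decreasing probes; the remainder is null. Must sum to <= 1.
#' @param a0 inflection age in years (inside \code{age_range}).
#' @param tau logistic scale in years (> 0).
#' @param amplitude trajectory amplitude A in log2 units.
#' @param noise_sd Gaussian noise sd in log2 units (> 0).
#' @param baseline_range range of per-probe baselines (log2 units).
#' @param seed optional integer seed; identical seeds give identical output.
#' @return a list of class \code{"sim_cohort"}: \code{expr} (log2 expression
#'   matrix), \code{metadata} (sample_id, age, cohort = "synthetic") and
#'   \code{truth} (probe_id, class, amplitude).
#' @export
simulate_cohort <- function(n_samples = 38, age_range = c(24, 79),
                            ages = NULL, n_probes = 500,
                            frac_increasing = 0.10, frac_decreasing = 0.05,
                            a0 = 50, tau = 4, amplitude = 1.0,
                            noise_sd = 0.3, baseline_range = c(4, 10),
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(ages)) {
    if (n_samples < 2) stop("n_samples must be >= 2")
    if (diff(age_range) <= 0) stop("degenerate age_range")
    ages <- stats::runif(n_samples, age_range[1], age_range[2])
  } else {
    n_samples <- length(ages)
    if (n_samples < 2) stop("need at least 2 samples")
    age_range <- range(ages)
  }
  if (frac_increasing < 0 || frac_decreasing < 0 ||
      frac_increasing + frac_decreasing > 1)
    stop("trend fractions must be nonnegative and sum to <= 1")
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  if (tau <= 0) stop("tau must be positive")
  if (a0 < age_range[1] || a0 > age_range[2])
    stop("inflection age a0 must lie inside age_range")

  n_inc <- round(n_probes * frac_increasing)
  n_dec <- round(n_probes * frac_decreasing)
  cls <- rep(c("increasing", "decreasing", "null"),
             c(n_inc, n_dec, n_probes - n_inc - n_dec))
  sign <- c(increasing = 1, decreasing = -1, null = 0)[cls]
  amp <- ifelse(cls == "null", 0, amplitude)

  probe_ids <- sprintf("probe_%04d", seq_len(n_probes))
  sample_ids <- sprintf("S%02d", seq_len(n_samples))
  baseline <- stats::runif(n_probes, baseline_range[1], baseline_range[2])
  traj <- outer(sign * amp, stats::plogis((ages - a0) / tau)) + baseline
  x <- traj + matrix(stats::rnorm(n_probes * n_samples, sd = noise_sd),
                     n_probes, n_samples)
  expr <- expression_matrix(x, probe_ids, sample_ids, scale = "log2")

  structure(list(
    expr = expr,
    metadata = data.frame(sample_id = sample_ids, age = ages,
                          cohort = "synthetic", stringsAsFactors = FALSE),
    truth = data.frame(probe_id = probe_ids, class = cls, amplitude = amp,
                       stringsAsFactors = FALSE)),
    class = "sim_cohort")
}

#' Simulate per-sample Cq values for a two-group qPCR experiment
#'
#' Each sample gets a reference-assay Cq drawn from N(20, sd^2) and a
#' target-assay Cq equal to the reference Cq plus a baseline delta-Cq, plus
#' \code{ddcq_true} for the old group, plus independent noise. The expected
#' relative quantification of old vs young is therefore
#' \code{2^-ddcq_true}.
#'
#' @param n_young,n_old group sizes (>= 1).
#' @param ddcq_true true group-level delta-delta-Cq (old minus young); a
#'   positive value means lower expression in the old group.
#' @param sd Gaussian Cq noise sd (> 0), applied to both assays.
#' @param baseline_dcq baseline target-minus-reference delta-Cq.
#' @param target_assay,reference_assay assay names.
#' @param seed optional integer seed.
#' @return a list: \code{cq} (long Cq table: sample_id, assay, cq) and
#'   \code{groups} (sample_id, group in \{young, old\}).
#' @export
simulate_cq <- function(n_young, n_old, ddcq_true = 1, sd = 0.3,
                        baseline_dcq = 3, target_assay = "miR-target",
                        reference_assay = "miR-191", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_young < 1 || n_old < 1) stop("group sizes must be positive")
  if (sd <= 0) stop("sd must be positive")
  n <- n_young + n_old
  sample_ids <- sprintf("V%02d", seq_len(n))
  group <- rep(c("young", "old"), c(n_young, n_old))
  ref <- stats::rnorm(n, mean = 20, sd = sd)
  target <- ref + baseline_dcq + ifelse(group == "old", ddcq_true, 0) +
    stats::rnorm(n, sd = sd)
  cq <- data.frame(
    sample_id = rep(sample_ids, 2),
    assay = rep(c(reference_assay, target_assay), each = n),
    cq = c(ref, target), stringsAsFactors = FALSE)
  list(cq = validate_cq(cq),
       groups = data.frame(sample_id = sample_ids, group = group,
                           stringsAsFactors = FALSE))
}

#' @export
print.sim_cohort <- function(x, ...) {
  tab <- table(x$truth$class)
  cat("Synthetic age-trend cohort:", nrow(x$expr), "probes x",
      ncol(x$expr), "samples\n")
  cat("  ages:", round(min(x$metadata$age), 1), "-",
      round(max(x$metadata$age), 1), "years\n")
  cat("  truth:", paste(names(tab), tab, sep = " = ", collapse = ", "), "\n")
  invisible(x)
}
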