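#' Default pipeline configuration
#'
#' The stage parameters default to the screening protocol the package
#' implements: windows of 10 samples sliding by 1, correlation threshold
#' 0.75 with a 1.5-fold last/first change, a young/elder cutoff at 50
#' years, FDR 0.05, a 2-fold candidate cutoff and top-20 enrichment
#' reporting.
#'
#' @return a named list understood by [run_full()].
#' @export
default_config <- function() {
  list(
    mode = "matrix", seed = 1, out_dir = NULL,
    matrix_path = NULL, metadata_path = NULL, annotation_path = NULL,
    gmt_path = NULL, mti_path = NULL, cq_path = NULL,
    simulate = TRUE, sim = list(),
    normalize = TRUE,
    w = 10, step = 1, r_threshold = 0.75, fc_threshold = 1.5,
    cutoff = 50, alpha = 0.05, fc_cut = 2.0, fdr = 0.05, top_k = 20,
    steep_quantile = 0.75, reference_assay = "miR-191")
}

#' Read / write a pipeline configuration as YAML
#'
#' Unset fields fall back to [default_config()]; unknown fields are
#' rejected.
#'
#' @param path YAML file path.
#' @return for \code{read_config}, the completed configuration list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  complete_config(user)
}

#' @rdname read_config
#' @param config configuration list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

complete_config <- function(config) {
  defaults <- default_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  # modifyList would delete fields a YAML file leaves null; treat null as unset
  config <- config[!vapply(config, is.null, logical(1))]
  utils::modifyList(defaults, config)
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", stage, "': ", conditionMessage(e), call. = FALSE))
}

sncrna_types <- function(probe_ids, annotation = NULL) {
  if (!is.null(annotation) && "sncRNA_class" %in% names(annotation)) {
    cls <- annotation$sncRNA_class[match(probe_ids, annotation$probe_id)]
    return(ifelse(is.na(cls), "other", cls))
  }
  ifelse(grepl("^hsa-", probe_ids), "miRNA", "snoRNA")
}

#' Run the full age-trend analysis pipeline
#'
#' Two execution modes:
#' \describe{
#'   \item{matrix}{the complete pipeline from an expression matrix (read
#'     from TSV, or simulated with [simulate_cohort()] when
#'     \code{simulate} is TRUE): probe filtering (when annotation with
#'     species tags is available), quantile normalization, the
#'     sliding-window trend screen, trajectory crossing and acceleration
#'     analysis, young/elder differential expression, screen comparison,
#'     the candidate cascade, and optionally miRNA-target enrichment (GMT
#'     + MTI inputs) and qPCR relative quantification (Cq input).}
#'   \item{fixtures}{set algebra and the candidate cascade over the
#'     bundled reference hit lists (see [load_fixture()]), requiring no
#'     expression matrix.}
#' }
#' With \code{out_dir} set, stage outputs are written as TSV and the
#' summary as JSON; identical configurations and seeds give byte-identical
#' files.
#'
#' @param config a configuration list (see [default_config()]) or the path
#'   to a YAML file.
#' @return an object of class \code{"run_report"}: stage results plus a
#'   \code{summary} list of headline counts.
#' @export
run_full <- function(config = default_config()) {
  if (is.character(config)) config <- read_config(config)
  cfg <- complete_config(config)
  report <- if (cfg$mode == "fixtures") run_fixtures_mode(cfg)
            else if (cfg$mode == "matrix") run_matrix_mode(cfg)
            else stop("mode must be 'matrix' or 'fixtures'")
  report$config <- cfg
  class(report) <- "run_report"
  if (!is.null(cfg$out_dir)) write_report(report, cfg$out_dir)
  report
}

run_fixtures_mode <- function(cfg) {
  t1 <- with_stage("load_fixtures", load_fixture("table1"))
  t2 <- with_stage("load_fixtures", load_fixture("table2"))
  prior <- with_stage("load_fixtures", prior_aging_set())
  overlap <- with_stage("compare", compare_screens(t1, t2))
  cand <- with_stage("candidates",
                     candidate_filter(t1, fc_cut = cfg$fc_cut,
                                      prior = prior))
  ovl <- function(cls, col) overlap[[col]][overlap$class == cls]
  summary <- list(
    trend_total = nrow(t1),
    trend_mirna = sum(t1$type == "miRNA"),
    trend_snorna = sum(t1$type != "miRNA"),
    trend_increasing = sum(t1$pearson_r > 0),
    trend_decreasing = sum(t1$pearson_r < 0),
    de_total = nrow(t2),
    de_up = sum(t2$direction == "UP"),
    de_down = sum(t2$direction == "DOWN"),
    de_mirna = sum(t2$type == "miRNA"),
    de_snorna = sum(t2$type != "miRNA"),
    mirna_intersection = ovl("miRNA", "n_intersect"),
    mirna_union = ovl("miRNA", "n_union"),
    mirna_pct_of_union = ovl("miRNA", "pct_overlap_of_union"),
    snorna_intersection = ovl("snoRNA", "n_intersect"),
    snorna_union = ovl("snoRNA", "n_union"),
    snorna_pct_of_union = ovl("snoRNA", "pct_overlap_of_union"),
    candidates_after_fc = nrow(cand$stage1),
    candidates_final = nrow(cand$candidates),
    candidate_names = sort(cand$candidates$name))
  list(trend_table = t1, de_table = t2, overlap = overlap,
       candidates = cand, summary = summary)
}

run_matrix_mode <- function(cfg) {
  truth <- NULL
  annotation <- NULL
  if (isTRUE(cfg$simulate)) {
    sim <- with_stage("simulate",
                      do.call(simulate_cohort,
                              c(cfg$sim, list(seed = cfg$seed))))
    expr <- sim$expr
    metadata <- sim$metadata
    truth <- sim$truth
  } else {
    if (is.null(cfg$matrix_path) || is.null(cfg$metadata_path))
      stop("stage 'read': config fields matrix_path and metadata_path are ",
           "required in matrix mode without simulation")
    bundle <- with_stage("read",
                         read_expression(cfg$matrix_path, cfg$metadata_path,
                                         cfg$annotation_path))
    expr <- bundle$expr
    metadata <- bundle$metadata
    annotation <- bundle$annotation
  }
  if (!is.null(annotation) && "species_tag" %in% names(annotation))
    expr <- with_stage("filter", filter_probes(expr, annotation))
  if (isTRUE(cfg$normalize))
    expr <- with_stage("normalize", quantile_normalize(expr))

  screen <- with_stage("screen",
                       age_trend_screen(expr, metadata, w = cfg$w,
                                        step = cfg$step,
                                        r_threshold = cfg$r_threshold,
                                        fc_threshold = cfg$fc_threshold))
  pair <- with_stage("trajectory", mean_trajectories(screen))
  crossing <- with_stage("trajectory", crossing_age(pair))
  interval <- with_stage("trajectory",
                         steepest_change_interval(pair, cfg$steep_quantile))
  de <- with_stage("de", diff_expression(expr, metadata, cutoff = cfg$cutoff,
                                         alpha = cfg$alpha))

  types <- sncrna_types(rownames(expr), annotation)
  trend_hits <- screen$table[screen$table$trend != "none", , drop = FALSE]
  trend_hits$type <- types[match(trend_hits$probeset, rownames(expr))]
  de_hits <- de$table[de$table$direction != "none", , drop = FALSE]
  de_hits$type <- types[match(de_hits$probeset, rownames(expr))]
  overlap <- with_stage("compare", compare_screens(trend_hits, de_hits))
  cand <- with_stage("candidates",
                     candidate_filter(trend_hits, fc_cut = cfg$fc_cut))

  enrichment <- NULL
  if (!is.null(cfg$gmt_path) && !is.null(cfg$mti_path)) {
    enrichment <- with_stage("enrich", {
      gmt <- read_gmt(cfg$gmt_path)
      mti <- read_mti(cfg$mti_path)
      mirna_hits <- trend_hits[trend_hits$type == "miRNA", , drop = FALSE]
      targets <- filter_mti(mti, mirna_hits$probeset,
                            direction = mirna_hits$trend)
      lapply(targets, function(gs)
        if (length(gs)) enrich(gs, gmt, fdr = cfg$fdr, top_k = cfg$top_k)
        else NULL)
    })
  }
  rq <- NULL
  if (!is.null(cfg$cq_path))
    rq <- with_stage("qpcr",
                     rq_analysis(read_cq(cfg$cq_path), metadata,
                                 reference_assay = cfg$reference_assay,
                                 cutoff = cfg$cutoff))

  summary <- list(
    n_probes = nrow(expr), n_samples = ncol(expr),
    n_windows = length(screen$windows$windows),
    trend_increasing = sum(screen$table$trend == "increasing"),
    trend_decreasing = sum(screen$table$trend == "decreasing"),
    de_up = sum(de$table$direction == "UP"),
    de_down = sum(de$table$direction == "DOWN"),
    crossing_age = crossing$primary_crossing,
    acceleration_lo = interval$age_lo,
    acceleration_hi = interval$age_hi,
    candidates_after_fc = nrow(cand$stage1),
    candidates_final = nrow(cand$candidates))
  if (!is.null(truth)) {
    truth_trend <- truth$class != "null"
    found <- screen$table$trend[match(truth$probe_id,
                                      screen$table$probeset)]
    summary$screen_sensitivity <-
      mean((found == truth$class)[truth_trend])
    summary$screen_fpr <- mean((found != "none")[!truth_trend])
  }
  list(screen = screen, trajectory = pair, crossing = crossing,
       interval = interval, de = de, overlap = overlap, candidates = cand,
       enrichment = enrichment, rq = rq, truth = truth, summary = summary)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  s <- report$summary
  if (!is.null(report$screen)) {
    tab <- report$screen$table
    tab$type <- sncrna_types(tab$probeset)
    write_tsv(tab[c("probeset", "type", "pearson_r", "fc_last_first",
                    "trend")],
              file.path(out_dir, "trend_table.tsv"))
    write_tsv(data.frame(window_mean_age = report$trajectory$ages,
                         mean_z_inc = report$trajectory$mean_z_increasing,
                         mean_z_dec = report$trajectory$mean_z_decreasing),
              file.path(out_dir, "trajectory.tsv"))
    jsonlite::write_json(list(crossing_ages =
                                report$crossing$crossing_ages,
                              primary_crossing =
                                report$crossing$primary_crossing,
                              acceleration = c(report$interval$age_lo,
                                               report$interval$age_hi)),
                         file.path(out_dir, "crossing.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(report$de)) {
    tab <- report$de$table
    tab$type <- sncrna_types(tab$probeset)
    write_tsv(data.frame(probeset = tab$probeset, type = tab$type,
                         adj_p = tab$p_adj,
                         fc_elder_young = tab$fc_elder_young,
                         direction = tab$direction),
              file.path(out_dir, "de_table.tsv"))
  }
  if (!is.null(report$overlap))
    write_tsv(as.data.frame(report$overlap),
              file.path(out_dir, "overlap.tsv"))
  if (!is.null(report$rq))
    write_tsv(as.data.frame(unclass(report$rq)),
              file.path(out_dir, "rq.tsv"))
  jsonlite::write_json(s, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.run_report <- function(x, ...) {
  cat("Age-trend pipeline run (mode: ", x$config$mode, ")\n", sep = "")
  s <- x$summary
  for (nm in names(s)) {
    v <- s[[nm]]
    if (is.numeric(v)) v <- round(v, 3)
    cat("  ", nm, ": ", paste(v, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
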