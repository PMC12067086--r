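#' Compare a metric between groups
#'
#' Two groups are compared by an unpaired two-tailed Student's t-test;
#' more than two by one-way ANOVA with Tukey's pairwise multiple
#' comparisons. Normality (Shapiro-Wilk, per group) and equality of
#' variance (Brown-Forsythe, i.e. Levene on median-centred values) are
#' reported as QC flags rather than gatekeepers.
#'
#' @param values_by_group named list of numeric vectors, one per group,
#'   each with at least two samples.
#' @param design `"auto"` picks the test from the group count;
#'   `"t_test"`/`"anova_tukey"` force one.
#' @param metric optional metric name carried into the result.
#' @param alpha significance level used for the star annotation.
#' @return a `group_comparison` list; for two groups it contains
#'   `mean_difference` (group2 - group1), `sem`, `ci95`, `p_value`; for
#'   more, the ANOVA p-value and a `tukey` table of pairwise contrasts.
#' @export
compare_groups <- function(values_by_group,
                           design = c("auto", "t_test", "anova_tukey"),
                           metric = NULL, alpha = 0.05) {
  design <- match.arg(design)
  if (length(values_by_group) < 2) stop("need at least 2 groups")
  if (is.null(names(values_by_group)) || any(names(values_by_group) == ""))
    stop("groups must be named")
  ns <- lengths(values_by_group)
  if (any(ns < 2))
    stop("singleton group: ", paste(names(values_by_group)[ns < 2],
                                    collapse = ", "))
  if (design == "auto")
    design <- if (length(values_by_group) == 2) "t_test" else "anova_tukey"

  qc <- list(
    shapiro_p = vapply(values_by_group, function(v) {
      if (length(v) >= 3 && length(v) <= 5000 && sd(v) > 0)
        shapiro.test(v)$p.value else NA_real_
    }, numeric(1)),
    brown_forsythe_p = tryCatch({
      df <- data.frame(
        value = unlist(values_by_group, use.names = FALSE),
        group = factor(rep(names(values_by_group), ns)))
      # degenerate (zero-variance) metrics make the F-test complain; the
      # QC value is still reported
      suppressWarnings(
        car::leveneTest(value ~ group, data = df,
                        center = median)[1, "Pr(>F)"])
    }, error = function(e) NA_real_))

  if (design == "t_test") {
    if (length(values_by_group) != 2)
      stop("t_test design requires exactly 2 groups")
    g1 <- values_by_group[[1]]; g2 <- values_by_group[[2]]
    tt <- t.test(g2, g1, var.equal = TRUE)
    n1 <- length(g1); n2 <- length(g2)
    sp2 <- ((n1 - 1) * var(g1) + (n2 - 1) * var(g2)) / (n1 + n2 - 2)
    sem <- sqrt(sp2 * (1 / n1 + 1 / n2))
    out <- list(metric = metric, test = "t_test",
                groups = names(values_by_group),
                n = ns,
                mean_difference = unname(mean(g2) - mean(g1)),
                sem = sem,
                ci95 = unname(tt$conf.int),
                p_value = tt$p.value,
                significant = tt$p.value <= alpha,
                qc = qc)
  } else {
    df <- data.frame(value = unlist(values_by_group, use.names = FALSE),
                     group = factor(rep(names(values_by_group), ns)))
    fit <- aov(value ~ group, data = df)
    p_overall <- summary(fit)[[1]][["Pr(>F)"]][1]
    tk <- TukeyHSD(fit)$group
    out <- list(metric = metric, test = "anova_tukey",
                groups = names(values_by_group),
                n = ns,
                p_value = p_overall,
                tukey = data.frame(contrast = rownames(tk),
                                   diff = tk[, "diff"],
                                   lwr = tk[, "lwr"], upr = tk[, "upr"],
                                   p_adj = tk[, "p adj"],
                                   row.names = NULL),
                significant = p_overall <= alpha,
                qc = qc)
  }
  structure(out, class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: %s, p = %.4g%s\n",
              if (is.null(x$metric)) "(metric)" else x$metric,
              x$test, x$p_value, if (isTRUE(x$significant)) " *" else ""))
  if (x$test == "t_test")
    cat(sprintf("  mean difference (%s - %s) = %.4g +/- %.4g, 95%% CI [%.4g, %.4g]\n",
                x$groups[2], x$groups[1], x$mean_difference, x$sem,
                x$ci95[1], x$ci95[2]))
  invisible(x)
}

#' Run the phantom-to-metrics pipeline over groups of regions
#'
#' For every phantom spec of every group: generate, segment (fetal recipe
#' unless configured otherwise), skeletonize, extract the vessel graph and
#' compute the geometric (radius, length, density), fractal (box-count
#' dimension, lacunarity) and topological (Betti 1, entropy, average
#' lifetime) metrics. Metrics are then compared between groups, each
#' imaged region being one statistical unit. Provenance (config hash,
#' seeds, package version) is attached so a run can be re-executed.
#'
#' @param config list with elements `groups` (named list; each group a
#'   list of [vessel_phantom_spec()]s), optional `seg_config`
#'   (a [segmentation_config()]), optional `use_truth_mask` (skip
#'   segmentation and use the generator truth mask) and optional
#'   `output_dir` to write CSV/JSON outputs.
#' @return a `pipeline_result`: `metrics` (data.frame, one row per region),
#'   `comparisons` (list of [compare_groups()] results per metric),
#'   `provenance`.
#' @export
run_pipeline <- function(config) {
  if (is.null(config$groups) || length(config$groups) < 1)
    stop("config$groups must name at least one group of phantom specs")
  seg <- config$seg_config
  if (is.null(seg)) seg <- segmentation_config("fetal")
  use_truth <- isTRUE(config$use_truth_mask)

  rows <- list()
  for (gname in names(config$groups)) {
    specs <- config$groups[[gname]]
    for (si in seq_along(specs)) {
      spec <- specs[[si]]
      ph <- if (is.list(spec) && !is.null(spec$stack)) spec
            else generate_vessel_phantom(spec)
      mask <- if (use_truth) ph$truth$mask else
        suppressWarnings(segment_vessels(ph$stack, seg))
      if (!any(mask))
        stop("stage segmentation: empty vessel mask for group ", gname,
             " region ", si)
      sk <- skeletonize(mask)
      gr <- extract_graph(sk, mask)
      tissue <- binary_mask(array(TRUE, dim = dim(mask)), spacing_um(mask))
      geo <- geometry_report(gr, tissue)
      bc <- box_count_dimension(mask)
      lac <- lacunarity(mask)
      topo <- topology_report(gr)
      rows[[length(rows) + 1]] <- data.frame(
        group = gname, region = si,
        mean_radius_um = geo$mean_radius_um,
        mean_branch_length_um = geo$mean_branch_length_um,
        branch_density_per_mm3 = geo$branch_density_per_mm3,
        n_branches = geo$n_branches,
        fractal_dimension = bc$dimension,
        lacunarity = lac$lacunarity,
        betti1 = topo$betti1,
        betti1_filtered = topo$betti1_filtered,
        persistence_entropy = topo$persistence_entropy,
        average_lifetime_um = topo$average_lifetime_um,
        cycle_rank = topo$cycle_rank)
    }
  }
  metrics <- do.call(rbind, rows)

  comparisons <- list()
  metric_cols <- setdiff(names(metrics), c("group", "region"))
  groups <- unique(metrics$group)
  if (length(groups) >= 2 && all(table(metrics$group) >= 2)) {
    for (mc in metric_cols) {
      vals <- split(metrics[[mc]], metrics$group)
      vals <- vals[groups]
      comparisons[[mc]] <- tryCatch(
        compare_groups(vals, metric = mc),
        error = function(e) NULL)
    }
  } else if (length(groups) >= 2) {
    warning("some group has a single region: comparisons skipped")
  }

  provenance <- list(config_hash = .hash_obj(config),
                     package_version = as.character(utils::packageVersion("renovasc")),
                     seeds = lapply(config$groups, function(g)
                       vapply(g, function(s)
                         if (is.null(s$seed)) NA_integer_
                         else as.integer(s$seed), integer(1))))
  res <- structure(list(metrics = metrics, comparisons = comparisons,
                        provenance = provenance),
                   class = "pipeline_result")
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(metrics, file.path(config$output_dir, "metrics.csv"),
              row.names = FALSE)
    jsonlite::write_json(
      list(provenance = provenance,
           comparisons = lapply(comparisons, function(cmp)
             cmp[c("metric", "test", "p_value", "mean_difference", "sem")])),
      file.path(config$output_dir, "report.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE)
  }
  res
}

#' Hash of the result tables of a pipeline run
#'
#' Stable digest of the metric table and comparison p-values; two runs of
#' [run_pipeline()] with identical config hash identically.
#'
#' @param result a `pipeline_result`.
#' @return md5 string.
#' @export
result_hash <- function(result) {
  .hash_obj(list(metrics = result$metrics,
                 p = lapply(result$comparisons, function(x) x$p_value)))
}
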