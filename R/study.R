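#' Run the full villous-tree study pipeline
#'
#' Reproduces the complete analysis flow on a cohort: read every traced
#' tree named in the manifest, measure all branches, aggregate per
#' specimen and terminal distance order, split the clinically normal
#' specimens into high-/low-tortuosity subgroups at the bT1 cutoff, and
#' compare the groups: for every metric (mean planar angle, tortuosity,
#' length, surface area, volume) and order, a two-group comparison
#' (IUGR vs normal; pooled t and Kruskal-Wallis) and a three-group
#' Kruskal-Wallis with Dunn's pairwise contrasts (IUGR, HT-normal,
#' LT-normal).  Terminal branching angles additionally get, per group, a
#' rose histogram, kernel mode detection and the dip test of
#' unimodality.  Specimens whose tree file cannot be read or parsed are
#' excluded with a logged reason.
#'
#' @param manifest path to a cohort manifest CSV with columns
#'   `specimen_id`, `group` (`IUGR` or `normal`) and `swc_path`
#'   (relative paths are resolved against the manifest's directory).
#' @param out_dir optional output directory; when given,
#'   [write_study_report()] is called on the result.
#' @param threshold bT1 tortuosity cutoff for the HT/LT split.
#' @param orders terminal distance orders analyzed.
#' @param adjust Dunn multiplicity adjustment (`"bonferroni"`, `"holm"`,
#'   `"none"`).
#' @param rose_bin rose histogram sector width, degrees.
#' @param bandwidth kernel bandwidth for mode detection, degrees.
#' @param dip_n_boot Monte-Carlo sample count for the dip test null.
#' @param seed integer seed for the dip test draws.
#' @return An object of class `villous_study`: list with `aggregates`
#'   (per-specimen table including the `subgroup` column),
#'   `branch_metrics`, `tests` (per metric x order), `angular` (per
#'   group), `exclusions`, and `config`.
#' @export
run_study <- function(manifest, out_dir = NULL, threshold = 1.2,
                      orders = 0:2, adjust = "bonferroni", rose_bin = 10,
                      bandwidth = 4, dip_n_boot = 10000, seed = 1) {
  man <- read.csv(manifest, stringsAsFactors = FALSE)
  need <- c("specimen_id", "group", "swc_path")
  if (!all(need %in% names(man)))
    stop("manifest must have columns ", paste(need, collapse = ", "))
  base <- dirname(normalizePath(manifest))
  paths <- ifelse(grepl("^(/|[A-Za-z]:)", man$swc_path), man$swc_path,
                  file.path(base, man$swc_path))

  metrics <- vector("list", nrow(man))
  excl <- list()
  for (i in seq_len(nrow(man))) {
    res <- tryCatch({
      tree <- read_swc(paths[i], tree_id = man$specimen_id[i])
      cbind(specimen_id = man$specimen_id[i], group = man$group[i],
            tree_id = tree$tree_id, measure_tree(tree),
            stringsAsFactors = FALSE)
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) {
      excl[[length(excl) + 1L]] <-
        data.frame(specimen_id = man$specimen_id[i], reason = res)
      warning("specimen ", man$specimen_id[i], " excluded: ", res)
    } else metrics[[i]] <- res
  }
  metrics <- do.call(rbind, metrics)
  if (is.null(metrics)) stop("no specimen could be read")
  excl <- if (length(excl)) do.call(rbind, excl) else
    data.frame(specimen_id = character(), reason = character())

  agg <- aggregate_specimens(metrics, orders = orders)
  agg$subgroup <- split_ht_lt(agg, threshold = threshold)

  metric_names <- c(mpa = "mean planar angle (deg)",
                    mt = "mean tortuosity",
                    ml = "mean length (um)",
                    msa = "mean surface area (um2)",
                    mv = "mean volume (um3)")
  tests <- list()
  for (nm in names(metric_names)) {
    for (k in orders) {
      col <- paste0(nm, "_bT", k)
      v <- agg[[col]]
      two <- three <- NULL
      ok2 <- !is.na(v)
      g2 <- agg$group[ok2]
      if (length(unique(g2)) == 2L && all(table(g2) >= 2L)) {
        two <- list(
          t = two_sample_t(v[ok2][g2 == "IUGR"], v[ok2][g2 == "normal"]),
          kw = kruskal_wallis(v[ok2], g2))
      }
      ok3 <- !is.na(v) & !is.na(agg$subgroup)
      g3 <- agg$subgroup[ok3]
      if (length(unique(g3)) == 3L && all(table(g3) >= 2L)) {
        three <- list(
          kw = kruskal_wallis(v[ok3], g3),
          dunn = dunn_posthoc(v[ok3], g3, adjust = adjust))
      }
      tests[[col]] <- list(metric = nm, order = k,
                           label = metric_names[[nm]],
                           n = sum(ok2), two_group = two,
                           three_group = three)
    }
  }

  ang_groups <- list(IUGR = agg$group == "IUGR",
                     normal = agg$group == "normal",
                     `HT-normal` = !is.na(agg$subgroup) &
                       agg$subgroup == "HT-normal",
                     `LT-normal` = !is.na(agg$subgroup) &
                       agg$subgroup == "LT-normal")
  angular <- list()
  gi <- 0L
  for (gn in names(ang_groups)) {
    gi <- gi + 1L
    a <- agg$mpa_bT0[ang_groups[[gn]]]
    a <- a[!is.na(a)]
    if (length(a) < 4L) next
    angular[[gn]] <- list(
      n = length(a),
      rose = rose_histogram(a, bin_width = rose_bin),
      modes = angular_modes(a, bandwidth = bandwidth),
      dip = dip_test(a, n_boot = dip_n_boot, seed = seed + gi))
  }

  study <- structure(list(
    aggregates = agg, branch_metrics = metrics, tests = tests,
    angular = angular, exclusions = excl,
    config = list(manifest = manifest, threshold = threshold,
                  orders = orders, adjust = adjust, rose_bin = rose_bin,
                  bandwidth = bandwidth, dip_n_boot = dip_n_boot,
                  seed = seed,
                  package_version = as.character(utils::packageVersion("villomorph")),
                  input_md5 = unname(tools::md5sum(paths[file.exists(paths)])))),
    class = "villous_study")
  if (!is.null(out_dir)) write_study_report(study, out_dir)
  study
}

#' @export
print.villous_study <- function(x, ...) {
  agg <- x$aggregates
  cat("<villous_study> ", nrow(agg), " specimens (",
      sum(agg$group == "IUGR"), " IUGR, ",
      sum(agg$group == "normal"), " normal; HT ",
      sum(agg$subgroup == "HT-normal", na.rm = TRUE), ", LT ",
      sum(agg$subgroup == "LT-normal", na.rm = TRUE), ")\n", sep = "")
  if (nrow(x$exclusions))
    cat("  excluded: ", nrow(x$exclusions), " specimen(s)\n", sep = "")
  key <- c("mt_bT1", "mpa_bT0")
  for (k in key) {
    ts <- x$tests[[k]]
    if (is.null(ts)) next
    cat("  ", k, ": ", sep = "")
    if (!is.null(ts$two_group))
      cat("IUGR vs normal KW p = ",
          signif(ts$two_group$kw$p.value, 3), "; ", sep = "")
    if (!is.null(ts$three_group))
      cat("3-group KW p = ", signif(ts$three_group$kw$p.value, 3), sep = "")
    cat("\n")
  }
  invisible(x)
}

#' @export
summary.villous_study <- function(object, ...) {
  rows <- lapply(object$tests, function(ts) {
    data.frame(metric = ts$metric, order = ts$order, n = ts$n,
      p_two_t = if (!is.null(ts$two_group)) ts$two_group$t$p.value else NA,
      p_two_kw = if (!is.null(ts$two_group)) ts$two_group$kw$p.value else NA,
      p_three_kw = if (!is.null(ts$three_group))
        ts$three_group$kw$p.value else NA)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab$stars_three <- significance_stars(tab$p_three_kw)
  tab
}

#' Plot per-group specimen values of one metric
#'
#' Scatter of the per-specimen means by subgroup with group mean and
#' standard deviation bars, the standard presentation for cohort
#' morphometry panels.
#'
#' @param x a `villous_study`.
#' @param metric aggregate column to plot (e.g. `"mt_bT1"`).
#' @param ... ignored.
#' @export
plot.villous_study <- function(x, metric = "mt_bT1", ...) {
  agg <- x$aggregates
  ok <- !is.na(agg[[metric]]) & !is.na(agg$subgroup)
  v <- agg[[metric]][ok]
  g <- factor(agg$subgroup[ok], levels = c("IUGR", "HT-normal", "LT-normal"))
  at <- as.integer(g)
  jit <- ((seq_along(at) * 7919L) %% 23L) / 23 * 0.24 - 0.12  # deterministic
  plot(at + jit, v, pch = 16,
       col = "#00000066", xaxt = "n", xlab = "", ylab = metric,
       xlim = c(0.5, 3.5), main = metric)
  axis(1, at = 1:3, labels = levels(g))
  for (i in 1:3) {
    vi <- v[at == i]
    if (!length(vi)) next
    segments(i - 0.22, mean(vi), i + 0.22, mean(vi), lwd = 2, col = "red3")
    segments(i, mean(vi) - sd(vi), i, mean(vi) + sd(vi), col = "red3")
  }
  invisible(x)
}

#' Write the study report to disk
#'
#' Writes the machine-readable analysis report: `report.json` (tests,
#' angular summaries, configuration and input digests), the per-specimen
#' and per-branch tables as CSV, per-metric scatter figures and
#' per-group rose diagrams as PNG.  No timestamps are written, so a
#' rerun with identical inputs and configuration is byte-identical.
#'
#' @param study a `villous_study`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_study_report <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(report = file.path(dir, "report.json"),
             aggregates = file.path(dir, "aggregates.csv"),
             branches = file.path(dir, "branch_metrics.csv"))
  write.csv(study$aggregates, paths["aggregates"], row.names = FALSE)
  write.csv(study$branch_metrics, paths["branches"], row.names = FALSE)

  fmt_htest <- function(h) if (is.null(h)) NULL else
    list(statistic = unname(h$statistic), p_value = h$p.value,
         method = h$method)
  rep <- list(
    config = study$config[setdiff(names(study$config), "input_md5")],
    input_md5 = study$config$input_md5,
    n_specimens = nrow(study$aggregates),
    subgroup_counts = as.list(table(study$aggregates$subgroup)),
    exclusions = study$exclusions,
    tests = lapply(study$tests, function(ts) list(
      metric = ts$metric, order = ts$order, n = ts$n,
      two_group = if (!is.null(ts$two_group)) list(
        t = fmt_htest(ts$two_group$t), kruskal = fmt_htest(ts$two_group$kw)),
      three_group = if (!is.null(ts$three_group)) list(
        kruskal = fmt_htest(ts$three_group$kw),
        dunn = ts$three_group$dunn$table))),
    angular_mpa_bT0 = lapply(study$angular, function(a) list(
      n = a$n, modes = a$modes, counts = a$rose$counts,
      bin_breaks = a$rose$breaks,
      dip = unname(a$dip$statistic), dip_p = a$dip$p.value)))
  jsonlite::write_json(rep, paths["report"], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows")

  for (m in unique(vapply(study$tests, `[[`, "", "metric"))) {
    for (k in study$config$orders) {
      col <- paste0(m, "_bT", k)
      if (all(is.na(study$aggregates[[col]]))) next
      f <- file.path(dir, paste0("scatter_", col, ".png"))
      png(f, width = 600, height = 500)
      plot(study, metric = col)
      dev.off()
      paths[paste0("scatter_", col)] <- f
    }
  }
  for (gn in names(study$angular)) {
    f <- file.path(dir, paste0("rose_", gsub("[^A-Za-z0-9]", "_", gn), ".png"))
    png(f, width = 500, height = 500)
    plot(study$angular[[gn]]$rose,
         main = paste0("mpa bT0, ", gn, " (n = ", study$angular[[gn]]$n, ")"))
    dev.off()
    paths[paste0("rose_", gn)] <- f
  }
  invisible(paths)
}
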