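#' Write an analysis report to disk
#'
#' Serialises a [run_analysis()] report. The JSON file carries the full
#' numeric results (statistic fields, thresholds, degrees of freedom,
#' smoothness, resels, clusters, severities) at full double precision so a
#' re-read reproduces the statistic fields bit-exactly. CSV severity maps
#' go through [write_severity_csv()]; optional PNG heatmaps reproduce the
#' cascaded bar layout (multivariate bar on top, one row per component
#' below). A manifest lists every artifact with its component coordinates.
#'
#' @param report a `"gait_report"`.
#' @param out_dir output directory (created if needed).
#' @param formats subset of `c("json", "csv", "png")`.
#' @return The manifest, a `data.frame` with columns `file`, `format`,
#'   `measure`, `limb`, `joint`, `comparison`, `component` — invisibly
#'   written to `manifest.csv` as well.
#' @export
serialize_report <- function(report, out_dir,
                             formats = c("json", "csv")) {
  stopifnot(inherits(report, "gait_report"))
  formats <- match.arg(formats, c("json", "csv", "png"), several.ok = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- data.frame(file = character(0), format = character(0),
                         measure = character(0), limb = character(0),
                         joint = character(0), comparison = character(0),
                         component = character(0))
  add <- function(file, format, key, comparison, component) {
    manifest <<- rbind(manifest, data.frame(
      file = file, format = format, measure = key$measure, limb = key$limb,
      joint = key$joint, comparison = comparison, component = component))
  }

  if ("json" %in% formats) {
    path <- file.path(out_dir, "report.json")
    # digits = I(17): significant digits, exact IEEE double round-trip
    jsonlite::write_json(report_to_list(report), path, auto_unbox = TRUE,
                         digits = I(17), na = "null", pretty = TRUE)
    for (r in report) for (cpn in names(r$comparisons))
      add("report.json", "json", r$key, cpn, "all")
  }
  if ("csv" %in% formats) {
    for (r in report) for (cpn in names(r$comparisons)) {
      cp <- r$comparisons[[cpn]]
      stem <- paste(r$key$measure, r$key$limb, r$key$joint, cpn, sep = "_")
      f <- paste0("severity_", stem, "_3D.csv")
      write_severity_csv(cp$multivariate$severity, file.path(out_dir, f))
      add(f, "csv", r$key, cpn, "3D")
      for (d in names(cp$per_component)) {
        f <- paste0("severity_", stem, "_", d, ".csv")
        write_severity_csv(cp$per_component[[d]]$severity,
                           file.path(out_dir, f))
        add(f, "csv", r$key, cpn, d)
      }
    }
  }
  if ("png" %in% formats) {
    for (r in report) for (cpn in names(r$comparisons)) {
      cp <- r$comparisons[[cpn]]
      stem <- paste(r$key$measure, r$key$limb, r$key$joint, cpn, sep = "_")
      f <- paste0("heatmap_", stem, ".png")
      grDevices::png(file.path(out_dir, f), width = 900, height = 240)
      tryCatch(plot_severity_bars(cp, title = gsub("_", " ", stem)),
               finally = grDevices::dev.off())
      add(f, "png", r$key, cpn, "all")
    }
  }
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

# plain-list view of a report (JSON-friendly, full precision)
report_to_list <- function(report) {
  one_spm <- function(s) list(
    stat_kind = s$stat_kind, z = s$z, df = s$df, p = s$p, alpha = s$alpha,
    fwhm = s$fwhm, resels = s$resels, z_star = s$z_star,
    two_sided = s$two_sided, inference = s$inference, n = s$n,
    clusters = s$clusters, valid_mask = s$valid_mask, notes = s$notes)
  one_pair <- function(pr) list(spm = one_spm(pr$spm),
                                severity = list(
                                  values = pr$severity$values,
                                  masked = pr$severity$masked,
                                  kind = pr$severity$kind,
                                  max_fold = pr$severity$max_fold))
  list(
    mode = attr(report, "mode"), alpha = attr(report, "alpha"),
    inference = attr(report, "inference"),
    joints = lapply(unname(as.list(report)), function(r) list(
      measure = r$key$measure, limb = r$key$limb, joint = r$key$joint,
      p = r$p, notes = r$notes,
      comparisons = lapply(r$comparisons, function(cp) list(
        label = cp$label, p = cp$p, dimensions = cp$dimensions,
        multivariate = one_pair(cp$multivariate),
        per_component = lapply(cp$per_component, one_pair))))))
}

#' Cascaded severity heatmap for one joint comparison
#'
#' Draws the multivariate severity bar above one bar per movement
#' component, on the legend colour scale, x axis in percent of gait cycle.
#' Masked nodes are grey.
#'
#' @param cp one comparison entry of a `"gait_report"` joint.
#' @param title plot title.
#' @return `NULL`, invisibly.
#' @export
plot_severity_bars <- function(cp, title = cp$label) {
  bars <- c(list(`3D` = cp$multivariate$severity),
            lapply(cp$per_component, function(x) x$severity))
  nb <- length(bars)
  scale <- bars[[1L]]$scale
  cols <- severity_colors(scale, scale$n_levels)
  graphics::par(mar = c(3.5, 4, 2, 1))
  graphics::plot(NULL, xlim = c(0, 100), ylim = c(0, nb), xlab = "",
                 ylab = "", yaxt = "n", main = title)
  graphics::mtext("gait cycle (%)", side = 1, line = 2.2, cex = 0.9)
  graphics::axis(2, at = seq_len(nb) - 0.5, labels = rev(names(bars)),
                 las = 1, tick = FALSE)
  for (i in seq_len(nb)) {
    sev <- bars[[i]]
    lev <- discretize_severity(sev)
    Q <- length(lev)
    xs <- (seq_len(Q) - 1L) / (Q - 1L) * 100
    fill <- ifelse(lev < 0L, "grey85",
                   ifelse(lev == 0L, "white", cols[pmax(lev, 1L)]))
    y0 <- nb - i
    graphics::rect(xs - 50 / (Q - 1L), y0 + 0.08, xs + 50 / (Q - 1L),
                   y0 + 0.92, col = fill, border = NA)
  }
  invisible(NULL)
}
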