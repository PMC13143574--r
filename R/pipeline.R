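#' Pipeline configuration
#'
#' Bundles every tunable parameter of the two indices and the batch
#' pipeline, with the study's defaults: 0.5 m minimum voxel for the box
#' dimension; 0.2 m KDE bandwidth, 1 m layers and alpha = 0.05 for canopy
#' entropy; 15 m plot side.
#'
#' @param min_voxel minimum box-counting voxel side (m).
#' @param bandwidth KDE bandwidth (m).
#' @param layer_width SDB layer thickness (m).
#' @param alpha SDB trend-test significance level, in (0, 1).
#' @param growth SDB voxel growth factor per iteration (> 1).
#' @param grid_step KDE grid step (m).
#' @param plot_side plot window side for optional cropping (m).
#' @param seed RNG seed recorded with the run.
#' @return list of class \code{run_config}.
#' @export
run_config <- function(min_voxel = 0.5, bandwidth = 0.2, layer_width = 1.0,
                       alpha = 0.05, growth = 1.10, grid_step = 0.1,
                       plot_side = 15, seed = 1L) {
  vals <- list(min_voxel = min_voxel, bandwidth = bandwidth,
               layer_width = layer_width, alpha = alpha, growth = growth,
               grid_step = grid_step, plot_side = plot_side,
               seed = as.integer(seed))
  num <- unlist(vals[c("min_voxel", "bandwidth", "layer_width", "alpha",
                       "growth", "grid_step", "plot_side")])
  if (!all(is.finite(num)) || any(num <= 0)) {
    stop("all run_config parameters must be positive and finite")
  }
  if (alpha >= 1) stop("alpha must lie in (0, 1)")
  structure(vals, class = "run_config")
}

#' Compute both indices for a batch of point clouds
#'
#' For every input cloud: read, optionally crop to a centred square plot
#' window, compute the box dimension and canopy entropy, and time each
#' stage with a monotonic clock. Per-cloud failures are logged to stderr
#' and skipped, so one corrupt file does not abort a large batch.
#'
#' @param inputs character vector of file paths and/or directories
#'   (directories are scanned for .las/.laz/.xyz/.txt), or a list of
#'   \code{point_cloud} objects.
#' @param config a \code{\link{run_config}}.
#' @param crop if TRUE, crop each cloud to a \code{plot_side} square
#'   around its xy centroid before computing indices.
#' @param out optional CSV path; when given the record table is written
#'   with \code{\link{write_index_records}}.
#' @return data frame of index records (one row per successful cloud) with
#'   the columns \code{source_id, n_points, db, ce, ce_xy, ce_xz, ce_yz,
#'   sdb_detected, final_voxel_size, t_db, t_ce, t_read}.
#' @export
run_compute <- function(inputs, config = run_config(), crop = FALSE,
                        out = NULL) {
  stopifnot(inherits(config, "run_config"))
  clouds <- resolve_inputs(inputs)
  if (length(clouds) == 0L) stop("pipeline error: no readable inputs")
  rows <- list()
  for (item in clouds) {
    rec <- tryCatch(compute_one(item, config, crop),
                    error = function(e) {
                      message("skipping ", item$label, ": ", conditionMessage(e))
                      NULL
                    })
    if (!is.null(rec)) rows[[length(rows) + 1L]] <- rec
  }
  if (length(rows) == 0L) stop("pipeline error: no cloud processed successfully")
  records <- do.call(rbind, rows)
  if (!is.null(out)) write_index_records(records, out)
  records
}

resolve_inputs <- function(inputs) {
  if (inherits(inputs, "point_cloud")) inputs <- list(inputs)
  if (is.list(inputs)) {
    return(lapply(inputs, function(cl) {
      stopifnot(inherits(cl, "point_cloud"))
      list(cloud = cl, path = NULL, label = cl$source_id)
    }))
  }
  paths <- character(0)
  for (p in inputs) {
    if (dir.exists(p)) {
      paths <- c(paths, list.files(p, pattern = "\\.(las|laz|xyz|txt)$",
                                   ignore.case = TRUE, full.names = TRUE))
    } else {
      paths <- c(paths, p)
    }
  }
  lapply(paths, function(p) list(cloud = NULL, path = p, label = p))
}

compute_one <- function(item, config, crop) {
  t0 <- proc.time()[["elapsed"]]
  cloud <- if (is.null(item$cloud)) read_point_cloud(item$path) else item$cloud
  t_read <- proc.time()[["elapsed"]] - t0
  if (crop) {
    bb <- bounding_box(cloud)
    center <- (bb$min_corner[1:2] + bb$max_corner[1:2]) / 2
    cloud <- crop_to_plot(cloud, center, config$plot_side)
  }
  t0 <- proc.time()[["elapsed"]]
  db <- box_dimension(cloud, min_voxel = config$min_voxel)
  t_db <- proc.time()[["elapsed"]] - t0
  t0 <- proc.time()[["elapsed"]]
  ce <- canopy_entropy(cloud, bandwidth = config$bandwidth,
                       layer_width = config$layer_width,
                       alpha = config$alpha, grid_step = config$grid_step,
                       growth = config$growth)
  t_ce <- proc.time()[["elapsed"]] - t0
  data.frame(source_id = cloud$source_id, n_points = n_points(cloud),
             db = db$db, ce = ce$ce, ce_xy = ce$ce_xy, ce_xz = ce$ce_xz,
             ce_yz = ce$ce_yz, sdb_detected = ce$sdb$biased_initially,
             final_voxel_size = ce$sdb$final_voxel_size,
             t_db = round(t_db, 3), t_ce = round(t_ce, 3),
             t_read = round(t_read, 3))
}

#' Statistical comparison of the two indices over a batch
#'
#' Runs the full comparison on a per-cloud index table: Pearson
#' correlation between Db and CE, the range-ratio error ratio delta,
#' the pooled Deming regression of CE on Db with jackknife confidence
#' intervals, per-site Deming fits when a \code{site} column is present,
#' and zero-intercept power-law fits of both runtimes against cloud size
#' when timing columns are present and positive.
#'
#' @param table data frame of index records (or a CSV path readable by
#'   \code{\link{read_index_records}}) with at least columns \code{db},
#'   \code{ce}; optionally \code{site}, \code{n_points}, \code{t_db},
#'   \code{t_ce}.
#' @param out optional JSON path for the report.
#' @param delta_policy passed to \code{\link{per_group_deming}}.
#' @return list of class \code{comparison_report} with elements
#'   \code{n}, \code{pearson_r}, \code{pearson_p}, \code{delta},
#'   \code{pooled} (deming_fit), \code{translation} (coefficients of both
#'   regression directions), \code{per_site}, \code{scaling_db},
#'   \code{scaling_ce}.
#' @export
run_compare <- function(table, out = NULL,
                        delta_policy = c("global", "per-group")) {
  delta_policy <- match.arg(delta_policy)
  if (is.character(table)) table <- read_index_records(table)
  stopifnot(all(c("db", "ce") %in% names(table)))
  table <- table[!is.na(table$db) & !is.na(table$ce), , drop = FALSE]
  if (nrow(table) < 3L) stop("comparison needs >= 3 rows with both indices")
  cor_res <- pearson(table$db, table$ce)
  delta <- error_ratio(table$db, table$ce)
  pooled <- deming_regression(table$db, table$ce, delta)
  # the symmetric fit supports translation in both directions
  translation <- list(
    ce_from_db = c(slope = pooled$slope, intercept = pooled$intercept),
    db_from_ce = c(slope = 1 / pooled$slope,
                   intercept = -pooled$intercept / pooled$slope)
  )
  per_site <- if ("site" %in% names(table) &&
                  length(unique(table$site)) >= 1L) {
    per_group_deming(table, delta_policy)
  } else NULL
  scaling <- list(db = NULL, ce = NULL)
  if (all(c("n_points", "t_db", "t_ce") %in% names(table))) {
    ok_db <- table$t_db > 0 & table$n_points > 0
    ok_ce <- table$t_ce > 0 & table$n_points > 0
    if (sum(ok_db) >= 3L) {
      scaling$db <- tryCatch(fit_power_scaling(table$t_db[ok_db],
                                               table$n_points[ok_db]),
                             error = function(e) NULL)
    }
    if (sum(ok_ce) >= 3L) {
      scaling$ce <- tryCatch(fit_power_scaling(table$t_ce[ok_ce],
                                               table$n_points[ok_ce]),
                             error = function(e) NULL)
    }
  }
  report <- structure(list(n = nrow(table), pearson_r = cor_res$r,
                           pearson_p = cor_res$p_value, delta = delta,
                           pooled = pooled, translation = translation,
                           per_site = per_site,
                           scaling_db = scaling$db, scaling_ce = scaling$ce),
                      class = "comparison_report")
  if (!is.null(out)) {
    jsonlite::write_json(comparison_report_list(report), out,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

comparison_report_list <- function(rep) {
  fit_list <- function(f) if (is.null(f)) NULL else list(
    slope = f$slope, intercept = f$intercept,
    se_slope = f$se_slope, se_intercept = f$se_intercept,
    ci_slope = as.list(stats::setNames(f$ci_slope, c("low", "high"))),
    ci_intercept = as.list(stats::setNames(f$ci_intercept, c("low", "high"))),
    delta = f$delta, n = f$n)
  scaling_list <- function(f) if (is.null(f)) NULL else list(
    a = f$a, b = f$b, se_a = f$se_a, se_b = f$se_b, r_squared = f$r_squared)
  list(n = rep$n, pearson_r = rep$pearson_r, pearson_p = rep$pearson_p,
       delta = rep$delta, pooled = fit_list(rep$pooled),
       translation = rep$translation,
       per_site = if (is.null(rep$per_site)) NULL else
         lapply(rep$per_site, fit_list),
       scaling_db = scaling_list(rep$scaling_db),
       scaling_ce = scaling_list(rep$scaling_ce))
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("Index comparison over %d clouds\n", x$n))
  cat(sprintf("  Pearson r = %.3f (p = %.3g)\n", x$pearson_r, x$pearson_p))
  cat(sprintf("  error ratio delta = %.4f\n", x$delta))
  print(x$pooled)
  if (!is.null(x$per_site)) {
    cat("  per-site slopes:",
        paste(sprintf("%s=%.2f", names(x$per_site),
                      vapply(x$per_site, `[[`, numeric(1L), "slope")),
              collapse = ", "), "\n")
  }
  if (!is.null(x$scaling_db)) { cat("  Db "); print(x$scaling_db) }
  if (!is.null(x$scaling_ce)) { cat("  CE "); print(x$scaling_ce) }
  invisible(x)
}
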