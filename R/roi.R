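#' Define a region of interest
#'
#' An ROI is an axial (optionally also radial) annular band of the pump, such
#' as the stator, bearing, impeller-shroud gap, blade, or lower-impeller
#' regions.  Intervals are half-open, `[min, max)`, so adjacent regions
#' partition space with no double counting.
#'
#' @param label region name (unique within a set).
#' @param z_min,z_max axial interval in metres, `z_max > z_min`.
#' @param r_min,r_max optional radial interval in metres.
#' @return An object of class `dte_roi`.
#' @export
roi_definition <- function(label, z_min, z_max, r_min = NULL, r_max = NULL) {
  if (!nzchar(label)) dte_stop("ROI label must be non-empty")
  if (label == "unassigned") dte_stop("'unassigned' is a reserved ROI label")
  if (!(z_max > z_min)) dte_stop("z_max must exceed z_min")
  if (xor(is.null(r_min), is.null(r_max))) {
    dte_stop("supply both r_min and r_max, or neither")
  }
  if (!is.null(r_min) && !(r_max > r_min)) dte_stop("r_max must exceed r_min")
  structure(list(label = label, z_min = z_min, z_max = z_max,
                 r_min = r_min, r_max = r_max),
            class = "dte_roi")
}

#' Build an ordered, validated set of ROIs
#'
#' @param ... `dte_roi` objects (or a single list of them).
#' @return An object of class `dte_roi_set`.  Construction fails if labels are
#'   duplicated or any two regions overlap in (z, r) space (an absent radial
#'   bound spans all radii).
#' @export
roi_set <- function(...) {
  regions <- list(...)
  if (length(regions) == 1L && !inherits(regions[[1L]], "dte_roi")) {
    regions <- regions[[1L]]
  }
  for (r in regions) stopifnot(inherits(r, "dte_roi"))
  labels <- vapply(regions, `[[`, character(1), "label")
  if (anyDuplicated(labels)) {
    dte_stop(sprintf("duplicated ROI label(s): %s",
                     paste(unique(labels[duplicated(labels)]), collapse = ", ")))
  }
  if (length(regions) > 1L) {
    for (i in seq_len(length(regions) - 1L)) {
      for (j in seq(i + 1L, length(regions))) {
        if (rois_overlap(regions[[i]], regions[[j]])) {
          dte_stop(sprintf("ROIs '%s' and '%s' overlap", labels[i], labels[j]),
                   class = "dte_validation_error")
        }
      }
    }
  }
  structure(list(regions = regions), class = "dte_roi_set")
}

rois_overlap <- function(a, b) {
  z_olap <- a$z_min < b$z_max && b$z_min < a$z_max
  if (!z_olap) return(FALSE)
  if (is.null(a$r_min) || is.null(b$r_min)) return(TRUE)  # full radial span
  a$r_min < b$r_max && b$r_min < a$r_max
}

#' @export
print.dte_roi_set <- function(x, ...) {
  cat(sprintf("<dte_roi_set> %d region(s)\n", length(x$regions)))
  for (r in x$regions) {
    cat(sprintf("  %-20s z [%g, %g)%s\n", r$label, r$z_min, r$z_max,
                if (!is.null(r$r_min)) sprintf(", r [%g, %g)", r$r_min, r$r_max) else ""))
  }
  invisible(x)
}

#' Read an ROI set from a YAML config file
#'
#' Expected structure: a top-level `rois:` list of mappings with keys
#' `label`, `z_min`, `z_max` and optional `r_min`, `r_max` (metres).
#'
#' @param path YAML file.
#' @return A `dte_roi_set`.
#' @export
read_roi_set <- function(path) {
  cfg <- yaml::read_yaml(path)
  entries <- cfg$rois %||% cfg
  roi_set(lapply(entries, function(e) {
    roi_definition(e$label, e$z_min, e$z_max, e$r_min, e$r_max)
  }))
}

# label per sample: position-based (geometric) or zone-column passthrough
assign_labels <- function(samples, rois, mode = c("geometric", "zone")) {
  mode <- match.arg(mode)
  labels <- vapply(rois$regions, `[[`, character(1), "label")
  if (mode == "zone") {
    lab <- ifelse(is.na(samples$zone) | !(samples$zone %in% labels),
                  "unassigned", samples$zone)
    return(lab)
  }
  lab <- rep("unassigned", nrow(samples))
  r <- sqrt(samples$x^2 + samples$y^2)
  for (roi in rois$regions) {
    inside <- samples$z >= roi$z_min & samples$z < roi$z_max
    if (!is.null(roi$r_min)) {
      inside <- inside & r >= roi$r_min & r < roi$r_max
    }
    lab[inside] <- roi$label   # regions are disjoint: at most one hit
  }
  lab
}

#' Assign trajectory samples to regions of interest
#'
#' Each sample belongs to at most one ROI — by its position (geometric mode,
#' half-open intervals) or by its `zone` column (zone mode, for CFD exports
#' that carry solver cell-zone labels).  Samples outside every ROI fall under
#' the reserved label `"unassigned"`.  Contiguous runs of samples in the same
#' region are reported as index intervals.
#'
#' @param trajectory a `dte_trajectory`.
#' @param rois a `dte_roi_set`.
#' @param mode `"geometric"` (default) or `"zone"`.
#' @return Named list: for each label touched by the trajectory, a two-column
#'   matrix of `start`, `end` sample indices (inclusive).
#' @export
assign_segments <- function(trajectory, rois, mode = c("geometric", "zone")) {
  mode <- match.arg(mode)
  s <- trajectory$samples
  lab <- assign_labels(s, rois, mode)
  runs <- rle(lab)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  out <- list()
  for (k in seq_along(runs$values)) {
    v <- runs$values[k]
    out[[v]] <- rbind(out[[v]], c(start = starts[k], end = ends[k]))
  }
  out
}

#' Per-ROI stress accumulation of one trajectory
#'
#' Splits the SA sum of [stress_accumulation()] by region: each left-rectangle
#' step \eqn{\sigma_i \Delta t_i} is credited to the region containing its
#' starting sample.  The values over all labels (including `"unassigned"`)
#' sum to the global SA by construction; repeated visits to a region
#' accumulate into a single value.
#'
#' @inheritParams assign_segments
#' @param method quadrature rule; only `"rectangle"` admits an exact
#'   partition, and is the default and tested contract.
#' @return Named numeric vector of SA in dyne·s/cm2 (labels with zero
#'   residence are absent; `"unassigned"` present only if touched).
#' @export
roi_sa <- function(trajectory, rois, mode = c("geometric", "zone"),
                   method = "rectangle") {
  mode <- match.arg(mode)
  stopifnot(identical(method, "rectangle"))
  s <- trajectory$samples
  if (nrow(s) < 2L) {
    dte_stop("at least 2 samples are required to accumulate stress",
             class = "dte_validation_error")
  }
  dtv <- diff(s$t)
  if (any(dtv <= 0)) {
    dte_stop("sample times must be strictly increasing",
             class = "dte_validation_error")
  }
  sigma <- scalar_stress_samples(s)
  lab <- assign_labels(s, rois, mode)
  n <- nrow(s)
  contrib <- sigma[-n] * dtv          # step i starts at sample i
  step_lab <- lab[-n]
  out <- vapply(split(contrib, step_lab), sum, numeric(1))
  if (identical(trajectory$stress_unit, "Pa")) out <- out * PA_TO_DYNE_CM2
  out
}

#' Per-ROI SA ensembles and footprints
#'
#' For each region, collects one SA value per trajectory that entered it
#' (cumulative over repeated visits) and builds a footprint.  All footprints
#' share the same evaluation grid and bandwidth so curves are comparable
#' across regions and devices.
#'
#' @param ensemble a `dte_ensemble`.
#' @param rois a `dte_roi_set`.
#' @param mode assignment mode, see [assign_segments()].
#' @param grid_spec shared `c(min, max, points)` grid; `NULL` spans all
#'   per-ROI SA values.
#' @param bandwidth shared bandwidth; `"silverman"` computes one common value
#'   from all per-ROI SA values pooled.
#' @param include_unassigned include the reserved `"unassigned"` region.
#' @param ... further arguments to [build_footprint()] (e.g. `bootstrap`,
#'   `seed`).
#' @return List with `sa` (named list of `dte_sa` per region) and
#'   `footprints` (named list of `dte_footprint`).  Regions entered by zero
#'   trajectories are omitted with a warning.
#' @export
roi_footprints <- function(ensemble, rois, mode = c("geometric", "zone"),
                           grid_spec = NULL, bandwidth = "silverman",
                           include_unassigned = FALSE, ...) {
  mode <- match.arg(mode)
  stopifnot(inherits(ensemble, "dte_ensemble"), inherits(rois, "dte_roi_set"))
  ss <- copy(ensemble$samples)
  ss[, sigma := scalar_stress_samples(ss)]
  lab_all <- assign_labels(ss, rois, mode)
  ss[, lab := lab_all]
  # credit each left-rectangle step to the region of its starting sample;
  # same arithmetic as roi_sa(), vectorized over the whole ensemble
  steps <- ss[, if (.N >= 2L) .(lab = head(lab, -1L),
                                contrib = head(sigma, -1L) * diff(t)),
              by = particle_id]
  per <- steps[, .(sa = sum(contrib)), by = .(particle_id, lab)]
  if (identical(ensemble$stress_unit, "Pa")) per[, sa := sa * PA_TO_DYNE_CM2]
  labels <- vapply(rois$regions, `[[`, character(1), "label")
  if (include_unassigned) labels <- c(labels, "unassigned")
  sa_list <- list()
  for (lb in labels) {
    sub <- per[lab == lb]
    v <- setNames(sub$sa, sub$particle_id)
    if (length(v) == 0L) {
      warning(sprintf("ROI '%s' entered by zero trajectories; omitted", lb))
      next
    }
    sa_list[[lb]] <- sa_values(v, n_seeded = n_particles(ensemble),
                               label = ensemble$label, roi = lb)
  }
  if (length(sa_list) == 0L) dte_stop("no ROI entered by any trajectory")
  all_v <- unlist(lapply(sa_list, `[[`, "values"), use.names = FALSE)
  bw <- if (is.numeric(bandwidth)) bandwidth else silverman_bw(all_v)
  if (is.null(grid_spec)) {
    grid_spec <- c(max(0, min(all_v) - 3 * bw), max(all_v) + 3 * bw, 512)
  }
  fps <- lapply(sa_list, function(sa_i) {
    fp <- build_footprint(sa_i, grid_spec = grid_spec, bandwidth = bw, ...)
    fp$label <- paste0(ensemble$label, if (nzchar(ensemble$label)) " / " else "",
                       sa_i$roi)
    fp
  })
  list(sa = sa_list, footprints = fps)
}
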