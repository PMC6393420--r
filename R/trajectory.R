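#' Construct a Lagrangian trajectory ensemble
#'
#' The central data container of the package: a table of time-stamped particle
#' positions with the six components of the viscous stress tensor recorded at
#' each sample, plus per-particle bookkeeping (whether the particle exited the
#' flow domain before the simulation ended).  Typically produced by
#' [advect()] or read from a CFD export with [read_trajectories()].
#'
#' @param samples data.frame with columns `particle_id`, `t` (s), `x`, `y`,
#'   `z` (m), `tau11`, `tau22`, `tau33`, `tau12`, `tau13`, `tau23` (stress in
#'   `stress_unit`) and optionally `zone` (character cell-zone label).
#' @param exited named logical vector, one entry per particle id, `TRUE` if the
#'   particle left the domain.  Particles present in `samples` but absent here
#'   default to `FALSE`.
#' @param stress_unit unit of the stored tensor components, `"Pa"` or
#'   `"dyne/cm2"`.
#' @param label device or run name.
#' @param meta named list of run metadata (rpm, flow rate, time step, seed, ...).
#'
#' @return An object of class `dte_ensemble`.
#' @export
trajectory_ensemble <- function(samples, exited = NULL, stress_unit = "Pa",
                                label = "", meta = list()) {
  stress_unit <- match_stress_unit(stress_unit)
  samples <- as.data.table(samples)
  missing_cols <- setdiff(setdiff(TRAJ_COLS, "zone"), names(samples))
  if (length(missing_cols) > 0L) {
    dte_stop(sprintf("trajectory table is missing required column(s): %s",
                     paste(missing_cols, collapse = ", ")),
             class = "dte_format_error")
  }
  if (!"zone" %in% names(samples)) samples[, zone := NA_character_]
  samples[, particle_id := as.character(particle_id)]
  num_cols <- setdiff(TRAJ_COLS, c("particle_id", "zone"))
  for (cc in num_cols) {
    v <- samples[[cc]]
    if (!is.numeric(v)) dte_stop(sprintf("column '%s' must be numeric", cc),
                                 class = "dte_format_error")
  }
  bad_tau <- !is.finite(as.matrix(samples[, TAU_COLS, with = FALSE]))
  if (any(bad_tau)) {
    dte_stop("non-finite stress tensor components in trajectory table",
             class = "dte_validation_error")
  }
  if (any(!is.finite(samples$t)) || any(samples$t < 0)) {
    dte_stop("sample times must be finite and non-negative",
             class = "dte_validation_error")
  }
  setkey(samples, particle_id, t)
  dup <- samples[, any(duplicated(t)), by = particle_id]
  if (any(dup$V1)) {
    dte_stop(sprintf(
      "duplicated or non-increasing sample times for particle(s): %s",
      paste(head(dup$particle_id[dup$V1], 5L), collapse = ", ")),
      class = "dte_validation_error")
  }
  ids <- unique(samples$particle_id)
  ex <- setNames(rep(FALSE, length(ids)), ids)
  if (!is.null(exited) && length(exited) > 0L) {
    if (is.null(names(exited))) {
      dte_stop("'exited' must be a named logical vector keyed by particle_id")
    }
    keep <- intersect(names(exited), ids)
    ex[keep] <- as.logical(exited[keep])
  }
  structure(list(samples = samples, exited = ex, stress_unit = stress_unit,
                 label = label, meta = meta),
            class = "dte_ensemble")
}

match_stress_unit <- function(unit) {
  u <- gsub("\\s", "", tolower(unit))
  if (u %in% c("pa", "pascal")) return("Pa")
  if (u %in% c("dyne/cm2", "dyn/cm2", "dyne/cm^2", "dyn/cm^2", "dynecm-2")) {
    return("dyne/cm2")
  }
  dte_stop(sprintf("unknown stress unit '%s' (supported: Pa, dyne/cm2)", unit))
}

#' @export
print.dte_ensemble <- function(x, ...) {
  cat(sprintf("<dte_ensemble> %s\n", if (nzchar(x$label)) x$label else "(unlabelled)"))
  cat(sprintf("  particles: %d (%d exited), samples: %d, stress unit: %s\n",
              n_particles(x), sum(x$exited), nrow(x$samples), x$stress_unit))
  invisible(x)
}

#' Number of seeded particles in an ensemble
#' @param ensemble a `dte_ensemble`.
#' @return integer count.
#' @export
n_particles <- function(ensemble) length(ensemble$exited)

#' Extract a single trajectory from an ensemble
#'
#' @param ensemble a `dte_ensemble`.
#' @param id particle identifier.
#' @return A `dte_trajectory`: the particle's time-ordered samples plus the
#'   exited flag and the stress unit inherited from the ensemble.
#' @export
get_trajectory <- function(ensemble, id) {
  id <- as.character(id)
  s <- ensemble$samples[J(id), nomatch = NULL]
  if (nrow(s) == 0L) dte_stop(sprintf("no particle '%s' in ensemble", id))
  structure(list(particle_id = id, samples = s,
                 exited = unname(ensemble$exited[id]),
                 stress_unit = ensemble$stress_unit),
            class = "dte_trajectory")
}

#' @export
print.dte_trajectory <- function(x, ...) {
  cat(sprintf("<dte_trajectory> particle %s: %d samples over %.4g s, exited=%s\n",
              x$particle_id, nrow(x$samples),
              diff(range(x$samples$t)), x$exited))
  invisible(x)
}

#' Convert the stress unit of an ensemble
#'
#' SI pascals and CGS dyne/cm2 differ by an exact factor of 10; each
#' conversion is a single multiplication or division by 10, so converting
#' there and back restores the original values to within one unit in the last
#' place (exactly, for most values).
#'
#' @param ensemble a `dte_ensemble`.
#' @param target `"Pa"` or `"dyne/cm2"`.
#' @return The ensemble with all tensor components expressed in `target`.
#' @export
convert_stress_units <- function(ensemble, target) {
  target <- match_stress_unit(target)
  if (identical(target, ensemble$stress_unit)) return(ensemble)
  s <- copy(ensemble$samples)
  if (ensemble$stress_unit == "Pa") {         # Pa -> dyne/cm2
    s[, (TAU_COLS) := lapply(.SD, function(v) v * PA_TO_DYNE_CM2),
      .SDcols = TAU_COLS]
  } else {                                    # dyne/cm2 -> Pa
    s[, (TAU_COLS) := lapply(.SD, function(v) v / PA_TO_DYNE_CM2),
      .SDcols = TAU_COLS]
  }
  out <- ensemble
  out$samples <- s
  out$stress_unit <- target
  out
}

#' Read a trajectory ensemble from disk
#'
#' Two dialects are supported.  `"dte-tsv"` is a tab-delimited text table with
#' header line
#' `particle_id t x y z tau11 tau22 tau33 tau12 tau13 tau23 zone`, one row per
#' (particle, time step); lines starting with `#` are metadata comments and a
#' `# stress_unit=` comment is required.  `"arrow"` is an Apache Arrow/Feather
#' binary container with the same logical schema, for large ensembles
#' (requires the `arrow` package).
#'
#' Rows are grouped by particle and sorted by time on read, so row order in
#' the file does not matter.  Malformed rows are reported with their line
#' numbers; duplicated `(particle_id, t)` pairs are a validation error naming
#' the particle.
#'
#' @param path file to read.
#' @param dialect `"dte-tsv"` (default) or `"arrow"`.
#' @return A validated `dte_ensemble`.
#' @seealso [write_trajectories()]
#' @export
read_trajectories <- function(path, dialect = c("dte-tsv", "arrow")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    dte_stop(sprintf("trajectory file not found: %s", path), class = "dte_io_error")
  }
  if (dialect == "arrow") return(read_trajectories_arrow(path))

  lines <- readLines(path)
  is_comment <- startsWith(trimws(lines), "#")
  header <- parse_header_comments(lines[is_comment])
  if (is.null(header$stress_unit)) {
    dte_stop("dte-tsv file lacks the required '# stress_unit=' header comment",
             class = "dte_format_error")
  }
  body_idx <- which(!is_comment & nzchar(trimws(lines)))
  if (length(body_idx) == 0L) {
    dte_stop("dte-tsv file has no header line", class = "dte_format_error")
  }
  header_line <- body_idx[1L]
  data_idx <- body_idx[-1L]
  tab <- fread(text = lines[c(header_line, data_idx)], sep = "\t",
               colClasses = list(character = c("particle_id", "zone")),
               na.strings = c("", "NA"))
  missing_cols <- setdiff(setdiff(TRAJ_COLS, "zone"), names(tab))
  if (length(missing_cols) > 0L) {
    dte_stop(sprintf("dte-tsv file missing required column(s): %s",
                     paste(missing_cols, collapse = ", ")),
             class = "dte_format_error")
  }
  num_cols <- setdiff(TRAJ_COLS, c("particle_id", "zone"))
  bad_rows <- rep(FALSE, nrow(tab))
  for (cc in num_cols) bad_rows <- bad_rows | !is.finite(tab[[cc]])
  if (any(bad_rows)) {
    dte_stop(sprintf(
      "malformed (non-numeric or missing) values at line(s): %s",
      paste(head(data_idx[bad_rows], 10L), collapse = ", ")),
      class = "dte_format_error")
  }
  trajectory_ensemble(tab,
                      exited = header$exited,
                      stress_unit = header$stress_unit,
                      label = header$label %||% "",
                      meta = header$meta %||% list())
}

parse_header_comments <- function(comment_lines) {
  out <- list(stress_unit = NULL, label = NULL, exited = NULL, meta = NULL)
  for (ln in comment_lines) {
    body <- sub("^\\s*#\\s*", "", ln)
    if (grepl("^stress_unit=", body)) {
      out$stress_unit <- sub("^stress_unit=", "", body)
    } else if (grepl("^label=", body)) {
      out$label <- sub("^label=", "", body)
    } else if (grepl("^exited=", body)) {
      ids <- strsplit(sub("^exited=", "", body), ",", fixed = TRUE)[[1L]]
      ids <- ids[nzchar(ids)]
      out$exited <- setNames(rep(TRUE, length(ids)), ids)
    } else if (grepl("^meta=", body)) {
      out$meta <- jsonlite::fromJSON(sub("^meta=", "", body),
                                     simplifyVector = TRUE)
    }
  }
  out
}

#' Write a trajectory ensemble to disk
#'
#' Inverse of [read_trajectories()]: metadata (stress unit, label, exited
#' flags, meta map) is carried in `#` header comments of the dte-tsv dialect,
#' so a read of the written file reproduces the ensemble up to float printing
#' precision (17 significant digits, i.e. exact for doubles).
#'
#' @param ensemble a `dte_ensemble`.
#' @param path output file.
#' @param dialect `"dte-tsv"` (default) or `"arrow"`.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(ensemble, path, dialect = c("dte-tsv", "arrow")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(ensemble, "dte_ensemble"))
  if (dialect == "arrow") return(write_trajectories_arrow(ensemble, path))
  con <- try(file(path, "w"), silent = TRUE)
  if (inherits(con, "try-error")) {
    dte_stop(sprintf("cannot open '%s' for writing", path), class = "dte_io_error")
  }
  on.exit(close(con))
  writeLines(c(
    sprintf("# stress_unit=%s", ensemble$stress_unit),
    sprintf("# label=%s", ensemble$label),
    sprintf("# exited=%s",
            paste(names(ensemble$exited)[ensemble$exited], collapse = ",")),
    sprintf("# meta=%s",
            as.character(jsonlite::toJSON(ensemble$meta, auto_unbox = TRUE,
                                          digits = NA)))
  ), con)
  tab <- ensemble$samples[, TRAJ_COLS, with = FALSE]
  # 17 significant digits: lossless round trip for IEEE doubles
  fmt <- function(v) formatC(v, format = "g", digits = 17)
  body <- do.call(paste, c(list(tab$particle_id),
                           lapply(setdiff(TRAJ_COLS, c("particle_id", "zone")),
                                  function(cc) fmt(tab[[cc]])),
                           list(ifelse(is.na(tab$zone), "", tab$zone)),
                           sep = "\t"))
  writeLines(c(paste(TRAJ_COLS, collapse = "\t"), body), con)
  invisible(path)
}

read_trajectories_arrow <- function(path) {
  if (!requireNamespace("arrow", quietly = TRUE)) {
    dte_stop("the 'arrow' package is required for the arrow dialect")
  }
  raw <- arrow::read_feather(path, as_data_frame = FALSE)
  tab <- as.data.frame(raw)
  hdr <- jsonlite::fromJSON(raw$metadata$dte %||% "{}", simplifyVector = TRUE)
  ex <- NULL
  if (length(hdr$exited) > 0L) ex <- setNames(rep(TRUE, length(hdr$exited)), hdr$exited)
  trajectory_ensemble(tab, exited = ex,
                      stress_unit = hdr$stress_unit %||% "Pa",
                      label = hdr$label %||% "",
                      meta = as.list(hdr$meta) %||% list())
}

write_trajectories_arrow <- function(ensemble, path) {
  if (!requireNamespace("arrow", quietly = TRUE)) {
    dte_stop("the 'arrow' package is required for the arrow dialect")
  }
  hdr <- jsonlite::toJSON(list(
    stress_unit = ensemble$stress_unit, label = ensemble$label,
    exited = names(ensemble$exited)[ensemble$exited],
    meta = ensemble$meta), auto_unbox = TRUE, digits = NA)
  tab <- arrow::arrow_table(as.data.frame(ensemble$samples[, TRAJ_COLS, with = FALSE]))
  tab$metadata$dte <- as.character(hdr)
  arrow::write_feather(tab, path)
  invisible(path)
}
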