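#' Scalar stress from viscous stress tensor components
#'
#' Collapses the six independent components of a symmetric stress tensor into
#' a single von-Mises-type rotational invariant
#' \deqn{\sigma = \sqrt{\frac{\tau_{11}^2+\tau_{22}^2+\tau_{33}^2
#'   -\tau_{11}\tau_{22}-\tau_{11}\tau_{33}-\tau_{22}\tau_{33}
#'   +3(\tau_{12}^2+\tau_{13}^2+\tau_{23}^2)}{3}}}{
#'   sigma = sqrt((t11^2+t22^2+t33^2 - t11 t22 - t11 t33 - t22 t33
#'   + 3 (t12^2+t13^2+t23^2)) / 3)}
#' so that a pure shear \eqn{\tau_{12}=\tau} gives \eqn{\sigma=\tau} and any
#' hydrostatic (isotropic) part cancels exactly.  All arguments are vectorized.
#'
#' @param tau11,tau22,tau33 normal components.
#' @param tau12,tau13,tau23 shear components.
#' @return Scalar stress, same unit as the inputs; always non-negative.
#' @examples
#' scalar_stress(0, 0, 0, 5, 0, 0)   # pure shear -> 5
#' scalar_stress(3, 0, 0, 0, 0, 0)   # uniaxial -> 3/sqrt(3)
#' @export
scalar_stress <- function(tau11, tau22, tau33, tau12, tau13, tau23) {
  comps <- cbind(tau11, tau22, tau33, tau12, tau13, tau23)
  if (any(!is.finite(comps))) {
    dte_stop("non-finite stress tensor components", class = "dte_validation_error")
  }
  q <- (tau11^2 + tau22^2 + tau33^2
        - tau11 * tau22 - tau11 * tau33 - tau22 * tau33
        + 3 * (tau12^2 + tau13^2 + tau23^2)) / 3
  # q is a positive semi-definite quadratic form; clamp fp noise at zero
  sqrt(pmax(q, 0))
}

scalar_stress_samples <- function(samples) {
  scalar_stress(samples$tau11, samples$tau22, samples$tau33,
                samples$tau12, samples$tau13, samples$tau23)
}

# core quadrature shared by stress_accumulation() and sa_ensemble();
# sigma in the trajectory's stored unit, returns SA in (unit)*s
sa_quadrature <- function(t, sigma, method = "rectangle") {
  n <- length(t)
  dtv <- diff(t)
  if (any(dtv <= 0)) {
    dte_stop("sample times must be strictly increasing",
             class = "dte_validation_error")
  }
  if (method == "trapezoid") {
    sum((sigma[-1] + sigma[-n]) * dtv) / 2
  } else {
    sum(sigma[-n] * dtv)   # left-rectangle: final sample contributes nothing
  }
}

#' Stress accumulation (SA) along one trajectory
#'
#' The per-platelet thrombogenic dose: the time integral of scalar stress
#' along the trajectory, \eqn{SA = \sum_i \sigma_i \Delta t_i}, evaluated by
#' the left-rectangle rule (each sample's scalar stress times the step to the
#' next sample; the final sample contributes nothing).  Non-uniform steps are
#' supported.  The result is reported in dyne·s/cm2 regardless of the unit the
#' trajectory stores its tensor in.
#'
#' @param trajectory a `dte_trajectory` (see [get_trajectory()]), or any list
#'   with `samples`, `stress_unit`.
#' @param method `"rectangle"` (default, the defining sum) or `"trapezoid"`.
#' @return SA in dyne·s/cm2 (non-negative scalar).
#' @export
stress_accumulation <- function(trajectory, method = c("rectangle", "trapezoid")) {
  method <- match.arg(method)
  s <- trajectory$samples
  if (is.null(s) || nrow(s) < 2L) {
    dte_stop("at least 2 samples are required to accumulate stress",
             class = "dte_validation_error")
  }
  sigma <- scalar_stress_samples(s)
  sa <- sa_quadrature(s$t, sigma, method)
  if (identical(trajectory$stress_unit, "Pa")) sa <- sa * PA_TO_DYNE_CM2
  sa
}

#' Construct an SA ensemble object
#'
#' @param values SA values in dyne·s/cm2, one per scored trajectory.
#' @param n_seeded number of particles originally seeded.
#' @param label device/run name.
#' @param roi optional ROI label (`NULL` = whole device).
#' @return An object of class `dte_sa`.
#' @export
sa_values <- function(values, n_seeded = length(values), label = "", roi = NULL) {
  nm <- names(values)
  values <- as.numeric(values)
  names(values) <- nm
  if (any(!is.finite(values)) || any(values < 0)) {
    dte_stop("SA values must be finite and non-negative",
             class = "dte_validation_error")
  }
  if (length(values) > n_seeded) {
    dte_stop("n_scored cannot exceed n_seeded", class = "dte_validation_error")
  }
  structure(list(values = values, n_seeded = as.integer(n_seeded),
                 n_scored = length(values), label = label, roi = roi),
            class = "dte_sa")
}

#' @export
print.dte_sa <- function(x, ...) {
  cat(sprintf("<dte_sa> %s%s: %d of %d particles scored, SA range [%.3g, %.3g] dyne.s/cm2\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              if (!is.null(x$roi)) paste0(" / ", x$roi) else "",
              x$n_scored, x$n_seeded,
              if (x$n_scored) min(x$values) else NA,
              if (x$n_scored) max(x$values) else NA))
  invisible(x)
}

#' Stress accumulation for every trajectory of an ensemble
#'
#' Computes one SA value per scoreable trajectory (at least two samples).
#' Particles with a single recorded sample are retained in the seeding count
#' but excluded from scoring, with a warning.
#'
#' @param ensemble a `dte_ensemble`.
#' @param completed_only if `TRUE`, only trajectories flagged as having exited
#'   the domain contribute values.  By default all trajectories contribute the
#'   SA accumulated up to their last recorded sample.
#' @param method quadrature rule, see [stress_accumulation()].
#' @return A `dte_sa` with `particle_id` names on `values`.
#' @export
sa_ensemble <- function(ensemble, completed_only = FALSE,
                        method = c("rectangle", "trapezoid")) {
  method <- match.arg(method)
  stopifnot(inherits(ensemble, "dte_ensemble"))
  if (n_particles(ensemble) == 0L) {
    dte_stop("empty ensemble", class = "dte_validation_error")
  }
  s <- ensemble$samples
  if (completed_only) {
    keep <- names(ensemble$exited)[ensemble$exited]
    if (length(keep) == 0L) {
      dte_stop("completed_only = TRUE but no trajectory has exited",
               class = "dte_validation_error")
    }
    s <- s[J(keep), nomatch = NULL]
  }
  counts <- s[, .N, by = particle_id]
  short <- counts$particle_id[counts$N < 2L]
  if (length(short) > 0L) {
    warning(sprintf("%d trajectory(ies) with < 2 samples excluded from SA scoring",
                    length(short)))
    s <- s[!J(short)]
  }
  if (nrow(s) == 0L) dte_stop("no scoreable trajectories", class = "dte_validation_error")
  ss <- copy(s)
  ss[, sigma := scalar_stress_samples(ss)]
  per <- ss[, .(sa = sa_quadrature(t, sigma, method)), by = particle_id]
  vals <- per$sa
  if (identical(ensemble$stress_unit, "Pa")) vals <- vals * PA_TO_DYNE_CM2
  sa_values(setNames(vals, per$particle_id),
            n_seeded = n_particles(ensemble), label = ensemble$label)
}

#' Fraction of seeded particles that exited the domain
#'
#' The simulation-duration criterion of the DTE protocol requires this to
#' reach at least 0.9 before trajectories are scored.
#'
#' @param ensemble a `dte_ensemble`.
#' @return Fraction in \[0, 1\].
#' @export
exit_fraction <- function(ensemble) {
  stopifnot(inherits(ensemble, "dte_ensemble"))
  n <- n_particles(ensemble)
  if (n == 0L) dte_stop("ensemble has no seeded particles", class = "dte_validation_error")
  sum(ensemble$exited) / n
}

#' Highest-SA trajectories of an ensemble
#'
#' Identifies the top-k thrombogenic "hot" trajectories (e.g. platelets
#' entrapped around the impeller), sorted by SA descending; ties broken by
#' particle id ascending.
#'
#' @param ensemble a `dte_ensemble`.
#' @param k how many trajectories to return (if larger than the number scored,
#'   all are returned with a warning).
#' @param ... passed to [sa_ensemble()].
#' @return data.frame with columns `particle_id`, `sa`.
#' @export
top_sa_trajectories <- function(ensemble, k = 10, ...) {
  if (k < 1) dte_stop("k must be >= 1")
  sa <- sa_ensemble(ensemble, ...)
  ids <- names(sa$values)
  ord <- order(-sa$values, ids)
  if (k > length(ord)) {
    warning(sprintf("k = %d exceeds the %d scored trajectories; returning all",
                    k, length(ord)))
    k <- length(ord)
  }
  idx <- ord[seq_len(k)]
  data.frame(particle_id = ids[idx], sa = unname(sa$values[idx]),
             stringsAsFactors = FALSE)
}

#' Write / read an SA ensemble as CSV
#'
#' Columns `particle_id, sa_dyn_s_cm2`; ensemble metadata is carried in `#`
#' header comments.
#'
#' @param sa a `dte_sa`.
#' @param path file path.
#' @return `path` (write) or a `dte_sa` (read).
#' @export
write_sa_csv <- function(sa, path) {
  stopifnot(inherits(sa, "dte_sa"))
  ids <- names(sa$values) %||% as.character(seq_along(sa$values))
  lines <- c(
    sprintf("# label=%s", sa$label),
    sprintf("# roi=%s", sa$roi %||% ""),
    sprintf("# n_seeded=%d", sa$n_seeded),
    "particle_id,sa_dyn_s_cm2",
    paste(ids, formatC(unname(sa$values), format = "g", digits = 17), sep = ",")
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_sa_csv
#' @export
read_sa_csv <- function(path) {
  lines <- readLines(path)
  is_comment <- startsWith(trimws(lines), "#")
  hdr <- parse_header_comments(lines[is_comment])
  tab <- fread(text = lines[!is_comment],
               colClasses = list(character = "particle_id"))
  n_seeded <- nrow(tab)
  for (ln in lines[is_comment]) {
    if (grepl("^#\\s*n_seeded=", ln)) n_seeded <- as.integer(sub("^#\\s*n_seeded=", "", ln))
  }
  roi <- hdr$roi
  for (ln in lines[is_comment]) {
    if (grepl("^#\\s*roi=", ln)) {
      v <- sub("^#\\s*roi=", "", ln)
      roi <- if (nzchar(v)) v else NULL
    }
  }
  sa_values(setNames(tab$sa_dyn_s_cm2, tab$particle_id), n_seeded = n_seeded,
            label = hdr$label %||% "", roi = roi)
}
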