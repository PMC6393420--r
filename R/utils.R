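#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stop with a classed dtekit error
#' @noRd
dte_stop <- function(msg, class = "dte_error", ...) {
  stop(structure(
    class = c(class, "dte_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

#' Trapezoid integral on an (irregular) grid
#' @noRd
trapz <- function(x, y) {
  n <- length(x)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

# stress tensor column names, canonical order
TAU_COLS <- c("tau11", "tau22", "tau33", "tau12", "tau13", "tau23")

TRAJ_COLS <- c("particle_id", "t", "x", "y", "z", TAU_COLS, "zone")

# conversion factor Pa -> dyne/cm^2 (1 Pa = 10 dyne/cm^2)
PA_TO_DYNE_CM2 <- 10
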