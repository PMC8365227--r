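#' Packaged fixture: the published device-matrix table
#'
#' The 10-row table of measured MCRs and systolic hemodynamic parameters
#' (energy loss, average neck velocity, inflow rate, each with its printed
#' reduction rate) for the control and the nine stented configurations, as
#' printed in the source study. Values are transcribed once at the exact
#' printed significant digits and integrity-checked against a frozen
#' checksum.
#'
#' @return A 10-row data.frame with columns `device`, `mcr_pct`, `el`,
#'   `el_reduction_pct`, `avg_velocity`, `vel_reduction_pct`, `inflow_rate`,
#'   `inflow_reduction_pct`. The printed Pearson row is available from
#'   [table1_printed_correlations()].
#' @export
table1_fixture <- function() {
  path <- system.file("extdata", "table1.csv", package = "aneuflow",
                      mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(tab) != 10L) {
    stop("packaging error: device-matrix fixture must have 10 rows",
         call. = FALSE)
  }
  chk <- sum(vapply(tab[-1], sum, numeric(1)))
  if (abs(chk - 3114.20519) > 1e-5) {
    stop("packaging error: device-matrix fixture checksum mismatch",
         call. = FALSE)
  }
  tab
}

#' Printed Pearson correlation row of the packaged table
#'
#' @return data.frame with `parameter`, `r` (printed coefficient) and
#'   `p_label` (printed p-value, verbatim).
#' @export
table1_printed_correlations <- function() {
  data.frame(parameter = c("el", "avg_velocity", "inflow_rate"),
             r = c(-0.961, -0.82, -0.805),
             p_label = c("<=0.001", "0.004", "<=0.001"),
             stringsAsFactors = FALSE)
}

#' Construct an analytic validation case
#'
#' Closed-form flow cases used to validate the solver without external
#' data (the original bench PIV comparison is replaced by these analytic
#' substitutes):
#' \describe{
#'   \item{`poiseuille`}{Steady plane Poiseuille channel flow. Params:
#'     `mean_velocity`, `height`, `length`, `spacing`, `fluid`.}
#'   \item{`womersley_single_harmonic`}{Single-harmonic oscillatory channel
#'     flow. Params: as above plus `period`, `amplitude`, `phase`.}
#'   \item{`zero_flow`}{Quiescent fluid; everything zero.}
#'   \item{`taylor_green`}{Decaying Taylor-Green vortex in a periodic box
#'     (evaluator only; the solver's boundaries are not periodic). Params:
#'     `u0`, `box`, `k` (wavenumber), `fluid`.}
#' }
#' Each case returns an `evaluator(x, y, t)` exact to floating precision
#' and, where applicable, the matching solver configuration (`grid`,
#' `waveform`, `fluid`) so the solver can be run against it.
#'
#' @param case_id One of the ids above.
#' @param params Named list of case parameters (defaults provided).
#' @return An `analytic_case` list with `case_id`, `params`, `evaluator`,
#'   and optionally `grid`, `waveform`, `fluid`.
#' @export
make_case <- function(case_id = c("poiseuille", "womersley_single_harmonic",
                                  "zero_flow", "taylor_green"),
                      params = list()) {
  case_id <- match.arg(case_id)
  p <- params
  dflt <- function(name, val) if (is.null(p[[name]])) val else p[[name]]

  if (case_id == "zero_flow") {
    ev <- function(x, y, t = 0) list(u = 0 * x, v = 0 * x)
    return(structure(list(case_id = case_id, params = list(),
                          evaluator = ev), class = "analytic_case"))
  }

  if (case_id == "taylor_green") {
    u0 <- dflt("u0", 1); box <- dflt("box", 1); kw <- dflt("k", 2 * pi / box)
    fl <- dflt("fluid", fluid_properties("blood"))
    nu <- fl$viscosity / fl$density
    ev <- function(x, y, t = 0) {
      dec <- exp(-2 * nu * kw^2 * t)
      list(u = u0 * cos(kw * x) * sin(kw * y) * dec,
           v = -u0 * sin(kw * x) * cos(kw * y) * dec)
    }
    return(structure(
      list(case_id = case_id,
           params = list(u0 = u0, box = box, k = kw, fluid = fl),
           evaluator = ev,
           kinetic_energy = function(t) {
             # mean KE density over the box: (u0^2/4) rho exp(-4 nu k^2 t)
             0.25 * fl$density * u0^2 * exp(-4 * nu * kw^2 * t)
           }),
      class = "analytic_case"))
  }

  H <- dflt("height", 4e-3); L <- dflt("length", 12e-3)
  sp <- dflt("spacing", 1e-4)
  fl <- dflt("fluid", fluid_properties("blood"))
  U0 <- dflt("mean_velocity", 0.25)

  if (case_id == "poiseuille") {
    wf <- pulsatile_waveform(period = dflt("period", 1), mean_velocity = U0,
                             harmonics = data.frame(amplitude = 0, phase = 0))
    ev <- function(x, y, t = 0) {
      a <- H / 2
      list(u = 1.5 * U0 * (1 - ((y - a) / a)^2), v = 0 * y)
    }
  } else {
    wf <- pulsatile_waveform(
      period = dflt("period", 1), mean_velocity = U0,
      harmonics = data.frame(amplitude = dflt("amplitude", 0.4 * U0),
                             phase = dflt("phase", 0)))
    ev <- function(x, y, t = 0) {
      list(u = womersley_inlet_profile(wf, fl, H, t, y), v = 0 * y)
    }
  }
  structure(list(case_id = case_id,
                 params = list(height = H, length = L, spacing = sp,
                               mean_velocity = U0, fluid = fl),
                 evaluator = ev,
                 grid = channel_grid(L, H, sp),
                 waveform = wf, fluid = fl),
            class = "analytic_case")
}
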