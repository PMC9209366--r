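#' The 25-channel particle size grid
#'
#' The model discretizes the 10 nm - 2.5 um diameter range into 25 size
#' channels, matching the channel midpoints of the condensation particle
#' counter / optical sizer combination the filter-efficiency table is keyed
#' to. Each channel is represented by its midpoint aerodynamic diameter;
#' no within-channel integration is performed because the filter table and
#' the balance equations operate on discrete channels.
#'
#' @param midpoints_nm strictly increasing vector of channel midpoint
#'   diameters in nm. Defaults to the canonical 25-channel grid.
#' @return an object of class `cabin_size_grid` (numeric vector of midpoints
#'   with the class attribute).
#' @export
#' @examples
#' g <- size_grid()
#' length(g)   # 25
#' range(g)    # 10, 2530 nm
size_grid <- function(midpoints_nm = c(10, 14, 19, 27, 37, 52, 72, 100, 139,
                                       193, 253, 298, 352, 414, 488, 576, 679,
                                       800, 943, 1112, 1310, 1545, 1821, 2146,
                                       2530)) {
  midpoints_nm <- as.numeric(midpoints_nm)
  if (anyNA(midpoints_nm) || any(midpoints_nm <= 0))
    stop("size grid midpoints must be positive and non-missing")
  if (is.unsorted(midpoints_nm, strictly = TRUE))
    stop("size grid midpoints must be strictly increasing")
  structure(midpoints_nm, class = "cabin_size_grid")
}

#' Channel edges of a size grid
#'
#' Edges are the geometric means of adjacent midpoints, extrapolated
#' geometrically at both ends. Used when discretizing continuous size
#' distributions onto the grid.
#'
#' @param grid a [size_grid()].
#' @return numeric vector of length `length(grid) + 1`, in nm.
#' @export
size_grid_edges <- function(grid) {
  mid <- as.numeric(grid)
  inner <- sqrt(mid[-1] * mid[-length(mid)])
  lower <- mid[1]^2 / inner[1]
  upper <- mid[length(mid)]^2 / inner[length(inner)]
  c(lower, inner, upper)
}

#' Size-resolved concentration distribution
#'
#' Per-channel particle concentrations on a [size_grid()], on either a count
#' basis (N/cm3 per channel) or a mass basis (ug/m3 per channel).
#'
#' @param values non-negative numeric vector, one value per grid channel.
#' @param basis `"count"` (N/cm3) or `"mass"` (ug/m3).
#' @param grid a [size_grid()]; defaults to the canonical grid.
#' @return an object of class `cabin_size_distribution`.
#' @export
size_distribution <- function(values, basis = c("count", "mass"),
                              grid = size_grid()) {
  basis <- match.arg(basis)
  values <- as.numeric(values)
  if (length(values) == 1L) values <- rep(values, length(grid))
  if (length(values) != length(grid))
    stop("need one concentration per size channel (", length(grid), ")")
  if (anyNA(values) || any(values < 0))
    stop("concentrations must be non-negative and non-missing")
  structure(list(values = values, basis = basis, grid = grid),
            class = "cabin_size_distribution")
}

#' @export
print.cabin_size_distribution <- function(x, ...) {
  unit <- if (x$basis == "count") "N/cm3" else "ug/m3"
  cat(sprintf("<size distribution: %d channels, %s basis>\n",
              length(x$grid), x$basis))
  cat(sprintf("  total: %.4g %s", sum(x$values), unit))
  if (x$basis == "mass") {
    cat(sprintf("  (PM2.5 = %.4g ug/m3)\n", aggregate_distribution(x, "pm25")))
  } else {
    cat(sprintf("  (UFP = %.4g N/cm3)\n", aggregate_distribution(x, "ufp")))
  }
  invisible(x)
}

#' Cabin-filter removal efficiency specification
#'
#' Size-dependent filter removal efficiency, with upper and lower limits
#' spanning the range observed across component tests of the same filter
#' model, keyed by filter age and pre-ionization status.
#'
#' The packaged efficiency table contains one printed cell (new filter,
#' ionization off, 352 nm) where the lower limit exceeds the upper limit by
#' 0.01; the table is shipped verbatim, so bound ordering is checked with a
#' warning rather than an error.
#'
#' @param status `"new"` or `"aged_500h"` (end of service interval).
#' @param ionization `"on"` or `"off"`.
#' @param eta_upper,eta_lower per-channel efficiencies in \[0, 1\].
#' @param grid a [size_grid()].
#' @return an object of class `cabin_filter_spec`.
#' @seealso [load_filter_fixture()] for the packaged efficiency table.
#' @export
filter_spec <- function(status = c("new", "aged_500h"),
                        ionization = c("off", "on"),
                        eta_upper, eta_lower, grid = size_grid()) {
  status <- match.arg(status)
  ionization <- match.arg(ionization)
  eta_upper <- as.numeric(eta_upper)
  eta_lower <- as.numeric(eta_lower)
  if (length(eta_upper) != length(grid) || length(eta_lower) != length(grid))
    stop("need one efficiency per size channel (", length(grid), ")")
  if (any(eta_upper < 0 | eta_upper > 1) || any(eta_lower < 0 | eta_lower > 1))
    stop("filter efficiencies must lie in [0, 1]")
  if (any(eta_lower > eta_upper))
    warning("eta_lower exceeds eta_upper in channel(s) ",
            paste(as.numeric(grid)[eta_lower > eta_upper], collapse = ", "),
            " nm (kept as given)")
  structure(list(status = status, ionization = ionization,
                 eta_upper = eta_upper, eta_lower = eta_lower, grid = grid),
            class = "cabin_filter_spec")
}

#' Load the packaged filter-efficiency table
#'
#' Reads the packaged CSV of size-dependent removal efficiencies for the
#' four (filter status, ionization) combinations, each with an upper and a
#' lower limit spanning the component-test range. Values are transcribed
#' verbatim from the supplier component tests (performed at 288 m3/h).
#'
#' @param status `"new"` or `"aged_500h"`.
#' @param ionization `"off"` or `"on"`.
#' @param path optional path to an alternative efficiency CSV with columns
#'   `status`, `ionization`, `bound`, then one column per channel midpoint.
#' @return a [filter_spec()].
#' @export
#' @examples
#' f <- load_filter_fixture("new", "off")
#' f$eta_upper[1]   # 0.79 at 10 nm
load_filter_fixture <- function(status = c("new", "aged_500h"),
                                ionization = c("off", "on"),
                                path = NULL) {
  status <- match.arg(status)
  ionization <- match.arg(ionization)
  if (is.null(path))
    path <- system.file("extdata", "filter_efficiency.csv",
                        package = "cabinaer", mustWork = TRUE)
  tab <- utils::read.csv(path, check.names = FALSE)
  mid <- as.numeric(names(tab)[-(1:3)])
  sel <- tab$status == status & tab$ionization == ionization
  if (sum(sel) != 2L)
    stop("no efficiency data for status = '", status,
         "', ionization = '", ionization, "'")
  up <- as.numeric(tab[sel & tab$bound == "upper", -(1:3)])
  lo <- as.numeric(tab[sel & tab$bound == "lower", -(1:3)])
  suppressWarnings(
    filter_spec(status, ionization, eta_upper = up, eta_lower = lo,
                grid = size_grid(mid)))
}

#' Vehicle envelope and deposition parameters
#'
#' Static parameters of the modelled vehicle: cabin volume, the leakage
#' power law (`kf`, `n`), the aerodynamic surface-pressure curve
#' (`a`, `b`, `kp`), the reverse-leakage correction `Frev`, the crack
#' penetration loss `alpha`, and per-channel deposition rates `beta`.
#'
#' @param Vcabin cabin volume, m3.
#' @param kf leakage flow coefficient, m3/h per Pa^n.
#' @param n leakage pressure exponent (dimensionless).
#' @param a aerodynamic pressure scale, Pa.
#' @param b aerodynamic pressure speed coefficient, per km/h.
#' @param kp aerodynamic pressure shape coefficient (dimensionless).
#' @param Frev reverse-leakage correction factor in \[0, 1\].
#' @param beta per-channel deposition rate, 1/h; a scalar is broadcast, or
#'   `NULL` for the size-dependent default profile (see
#'   [default_deposition_rates()]).
#' @param alpha crack penetration loss coefficient in \[0, 1\];
#'   the customary value 0.6 is the default.
#' @param grid a [size_grid()].
#' @return an object of class `cabin_vehicle_spec`.
#' @export
vehicle_spec <- function(Vcabin = 4.1, kf = 18.78, n = 0.66, a = 1.0,
                         b = 0.03, kp = 0.5, Frev = 0.8, beta = NULL,
                         alpha = 0.6, grid = size_grid()) {
  if (Vcabin <= 0) stop("Vcabin must be positive")
  if (kf <= 0 || n <= 0) stop("leakage parameters kf and n must be positive")
  if (Frev < 0 || Frev > 1) stop("Frev must lie in [0, 1]")
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  if (is.null(beta)) beta <- default_deposition_rates(grid)
  beta <- as.numeric(beta)
  if (length(beta) == 1L) beta <- rep(beta, length(grid))
  if (length(beta) != length(grid))
    stop("beta must be scalar or one value per size channel")
  if (any(beta < 0)) stop("deposition rates must be non-negative")
  structure(list(Vcabin = Vcabin, kf = kf, n = n, a = a, b = b, kp = kp,
                 Frev = Frev, beta = beta, alpha = alpha, grid = grid),
            class = "cabin_vehicle_spec")
}

#' Default size-dependent deposition-rate profile
#'
#' Indoor deposition loss rates are governed by Brownian diffusion for the
#' smallest particles and gravitational settling plus impaction for the
#' largest, giving the familiar U (or V) shape with a minimum in the
#' accumulation mode near 0.1-0.3 um. The default profile is a log-diameter
#' parabola with its minimum at 250 nm, spanning 0.9-11.9 1/h, inside the
#' 0.5-12.6 1/h envelope reported for vehicle cabins.
#'
#' @param grid a [size_grid()].
#' @param beta_min,beta_max deposition rate (1/h) at the minimum of the
#'   profile and at the small-diameter end of the grid.
#' @param d_min_nm diameter of minimal deposition, nm.
#' @return per-channel deposition rates, 1/h.
#' @export
default_deposition_rates <- function(grid = size_grid(), beta_min = 0.9,
                                     beta_max = 11.9, d_min_nm = 250) {
  mid <- as.numeric(grid)
  span <- log10(d_min_nm) - log10(min(mid))
  beta_min + (beta_max - beta_min) * ((log10(mid) - log10(d_min_nm)) / span)^2
}

#' Occupant CO2 source parameters
#'
#' Respiration is the in-cabin CO2 source: `N` occupants each exhale `Vbr`
#' litres of air per minute containing a CO2 volume fraction of `Cbr` ppm.
#'
#' @param N number of occupants (integer >= 0).
#' @param Vbr minute ventilation, L/min. The default is the midpoint of the
#'   5-8 L/min range reported for seated adults at rest (see
#'   [default_minute_ventilation()]).
#' @param Cbr exhaled-air CO2 concentration, ppm (default 40000).
#' @return an object of class `cabin_occupant_load`.
#' @export
occupant_load <- function(N = 2, Vbr = default_minute_ventilation(),
                          Cbr = 40000) {
  if (N < 0 || N != round(N)) stop("N must be a non-negative integer")
  if (N > 0 && Vbr <= 0) stop("Vbr must be positive when occupants are present")
  if (Cbr <= 0) stop("Cbr must be positive")
  structure(list(N = as.integer(N), Vbr = Vbr, Cbr = Cbr),
            class = "cabin_occupant_load")
}

#' Reference minute ventilation for seated occupants
#'
#' Minute ventilation of adults sitting at rest lies between 5 and 8 L/min;
#' the midpoint is used as the default breath volume.
#'
#' @param range_lmin the resting range, L/min.
#' @return midpoint of the range, L/min.
#' @export
default_minute_ventilation <- function(range_lmin = c(5, 8)) {
  mean(range_lmin)
}

# unit factor: N/cm3 * (pi/6) d[m]^3 * rho[kg/m3] -> ug/m3
.mass_per_count <- function(d_nm, density) {
  (pi / 6) * (d_nm * 1e-9)^3 * density * 1e15
}

#' Convert between count and mass concentration bases
#'
#' Assuming all particles in a channel share the channel-midpoint
#' aerodynamic diameter and a common density, the per-channel mass
#' concentration is `count * (pi/6) * d^3 * density` with units arranged so
#' N/cm3 maps to ug/m3. The two conversions are exact inverses.
#'
#' @param dist a [size_distribution()] on the count (for `count_to_mass`) or
#'   mass (for `mass_to_count`) basis.
#' @param density particle density, kg/m3. Defaults to unit density
#'   (1000 kg/m3) since effective density is rarely known.
#' @return a [size_distribution()] on the other basis.
#' @export
#' @examples
#' g <- size_grid()
#' d <- size_distribution(replace(numeric(25), 8, 1000), "count")  # 100 nm
#' count_to_mass(d)$values[8]  # 0.5236 ug/m3
count_to_mass <- function(dist, density = 1000) {
  stopifnot(inherits(dist, "cabin_size_distribution"))
  if (dist$basis != "count") stop("input must be on the count basis")
  if (density <= 0) stop("density must be positive")
  size_distribution(dist$values * .mass_per_count(as.numeric(dist$grid), density),
                    basis = "mass", grid = dist$grid)
}

#' @rdname count_to_mass
#' @export
mass_to_count <- function(dist, density = 1000) {
  stopifnot(inherits(dist, "cabin_size_distribution"))
  if (dist$basis != "mass") stop("input must be on the mass basis")
  if (density <= 0) stop("density must be positive")
  size_distribution(dist$values / .mass_per_count(as.numeric(dist$grid), density),
                    basis = "count", grid = dist$grid)
}

#' Aggregate a size distribution to PM2.5 or UFP
#'
#' On the mass basis the grid covers 10 nm - 2.5 um, so the sum over all
#' channels is the modelled PM2.5 (ug/m3). On the count basis the ultrafine
#' (UFP) total is the sum over channels with midpoint diameter strictly
#' below the cutoff (default 100 nm, so the 100 nm channel is excluded,
#' consistent with UFP = particles smaller than 100 nm).
#'
#' @param dist a [size_distribution()].
#' @param quantity `"pm25"` (mass basis) or `"ufp"` (count basis).
#' @param ufp_cutoff_nm upper diameter bound for the UFP sum, nm.
#' @return scalar concentration (ug/m3 for PM2.5, N/cm3 for UFP).
#' @export
aggregate_distribution <- function(dist, quantity = c("pm25", "ufp"),
                                   ufp_cutoff_nm = 100) {
  stopifnot(inherits(dist, "cabin_size_distribution"))
  quantity <- match.arg(quantity)
  if (quantity == "pm25") {
    if (dist$basis != "mass")
      stop("PM2.5 requires a mass-basis distribution; see count_to_mass()")
    sum(dist$values)
  } else {
    if (dist$basis != "count")
      stop("UFP counts require a count-basis distribution")
    sum(dist$values[as.numeric(dist$grid) < ufp_cutoff_nm])
  }
}

#' Read and write size distributions as CSV
#'
#' Two dialects are read: long form with columns `midpoint_nm` and `value`
#' (one row per channel), and wide form with one row and one column per
#' channel named by its midpoint. The wide form is written.
#'
#' @param path CSV file path.
#' @param basis concentration basis of the stored values.
#' @param dist a [size_distribution()].
#' @return `read_size_distribution` returns a [size_distribution()];
#'   `write_size_distribution` returns `path` invisibly.
#' @export
read_size_distribution <- function(path, basis = c("count", "mass")) {
  basis <- match.arg(basis)
  tab <- utils::read.csv(path, check.names = FALSE)
  if (all(c("midpoint_nm", "value") %in% names(tab))) {
    ord <- order(tab$midpoint_nm)
    size_distribution(tab$value[ord], basis,
                      grid = size_grid(tab$midpoint_nm[ord]))
  } else {
    mid <- suppressWarnings(as.numeric(names(tab)))
    if (anyNA(mid) || nrow(tab) != 1L)
      stop("unrecognized size-distribution CSV dialect in ", path)
    size_distribution(as.numeric(tab[1, ]), basis, grid = size_grid(mid))
  }
}

#' @rdname read_size_distribution
#' @export
write_size_distribution <- function(dist, path) {
  stopifnot(inherits(dist, "cabin_size_distribution"))
  row <- as.data.frame(as.list(stats::setNames(dist$values,
                                               as.numeric(dist$grid))),
                       check.names = FALSE)
  utils::write.csv(row, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
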