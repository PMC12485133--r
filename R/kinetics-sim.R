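ode_solve <- function(network, init, times, rtol = 1e-8) {
  totals <- conservation_totals(network, init)
  atol <- 1e-12 * max(min(totals[totals > 0]), 1e-9)
  out <- deSolve::lsoda(
    y = unname(init), times = times, parms = pack_network(network),
    func = "ma_derivs", jacfunc = "ma_jac", jactype = "fullusr",
    initfunc = "ma_init", dllname = "allogap",
    rtol = rtol, atol = atol, maxsteps = 50000)
  if (attr(out, "istate")[1] < 0) {
    abort(sprintf("ODE integration failed (istate %d) for construct %s",
                  attr(out, "istate")[1], network$condition$construct))
  }
  colnames(out) <- c("time", network$species$name)
  out
}

conservation_totals <- function(network, init) {
  vapply_dbl(network$groups, function(g) sum(init[g]))
}

#' Simulate a trajectory of the reaction network
#'
#' @param network A `reaction_network` from [build_network()].
#' @param enzyme_conc Total enzyme concentration (M), loaded into the
#'   network's free-enzyme species.
#' @param times Output times (s).
#' @return Tibble with `time` and one concentration column per species.
#' @export
simulate_trajectory <- function(network, enzyme_conc,
                                times = seq(0, network$condition$endpoint,
                                            length.out = 61)) {
  init <- network$init0
  init[network$enzyme_species] <- enzyme_conc
  as_tibble(as.data.frame(ode_solve(network, init, times)))
}

#' Fraction of GTP hydrolyzed at the assay endpoint
#'
#' Integrates the network to the condition's endpoint; the fraction is the
#' Arf.GDP total over total Arf. There is no intrinsic (enzyme-free)
#' hydrolysis, so enzyme 0 returns exactly 0.
#'
#' @param network A `reaction_network`.
#' @param enzyme_conc Total enzyme concentration (M).
#' @return Fraction hydrolyzed in `[0, 1]`.
#' @export
simulate_endpoint <- function(network, enzyme_conc) {
  if (enzyme_conc == 0) return(0)
  init <- network$init0
  init[network$enzyme_species] <- enzyme_conc
  out <- ode_solve(network, init, c(0, network$condition$endpoint))
  frac <- out[nrow(out), "ArfGDP"] / network$condition$arf_total
  unname(min(max(frac, 0), 1))
}

#' Endpoint titration curve
#'
#' Maps [simulate_endpoint()] over the condition's enzyme concentration list.
#'
#' @param network A `reaction_network`.
#' @param titration Optional concentration vector overriding the condition's.
#' @return Tibble with `conc` (M) and `fraction`.
#' @export
titration_curve <- function(network, titration = NULL) {
  conc <- titration %||% network$condition$titration
  tibble(conc = conc,
         fraction = vapply_dbl(conc, function(e) simulate_endpoint(network, e)))
}

#' Half-maximal enzyme concentration of a titration curve
#'
#' Log-linear interpolation between the two points bracketing 50% hydrolysis;
#' with multiple crossings (noisy data) the first crossing from low
#' concentration is used; an exact 0.5 sample is returned as is.
#'
#' @param curve Tibble with `conc` and `fraction` (as from
#'   [titration_curve()]).
#' @param level Crossing level (default 0.5).
#' @return Concentration in M.
#' @export
c50 <- function(curve, level = 0.5) {
  curve <- arrange(curve, .data$conc)
  f <- curve$fraction
  if (max(f) < level || min(f) > level) {
    abort("titration curve does not cross the 50% level")
  }
  exact <- which(f == level)
  if (length(exact) > 0) return(curve$conc[exact[1]])
  i <- which(f[-1] >= level & f[-length(f)] < level)[1]
  if (is.na(i)) i <- which(f >= level)[1] - 1
  x1 <- log10(curve$conc[i]); x2 <- log10(curve$conc[i + 1])
  10^(x1 + (level - f[i]) / (f[i + 1] - f[i]) * (x2 - x1))
}

#' Catalytic efficiency from the initial-rate regime
#'
#' Simulates the network at a low enzyme concentration (default 1% of total
#' Arf), locates the time of 1% substrate turnover on a logarithmic time
#' grid, and converts it to an initial rate; efficiency is
#' `v0 / (enzyme * Arf.GTP)` in M^-1 s^-1.
#'
#' @param network A `reaction_network`.
#' @param enzyme_conc Enzyme concentration (M); must not exceed 1% of Arf.
#' @param turnover_fraction Substrate fraction defining the initial-rate
#'   window.
#' @return Catalytic efficiency (M^-1 s^-1).
#' @export
catalytic_efficiency <- function(network, enzyme_conc = NULL,
                                 turnover_fraction = 0.01) {
  a0 <- network$condition$arf_total
  enzyme_conc <- enzyme_conc %||% (a0 / 100)
  if (enzyme_conc > a0 / 100 + 1e-15) {
    abort("initial-rate protocol requires enzyme <= arf_total / 100")
  }
  init <- network$init0
  init[network$enzyme_species] <- enzyme_conc
  times <- c(0, 10^seq(-6, 10, by = 0.05))
  out <- ode_solve(network, init, times)
  frac <- out[, "ArfGDP"] / a0
  if (max(frac) < turnover_fraction) {
    abort("no measurable turnover within the simulated window")
  }
  i <- which(frac >= turnover_fraction)[1]
  # log-time interpolation of the crossing
  t1 <- out[i - 1, "time"]; t2 <- out[i, "time"]
  f1 <- frac[i - 1]; f2 <- frac[i]
  t_star <- if (t1 <= 0) t2 else {
    10^(log10(t1) + (turnover_fraction - f1) / (f2 - f1) * (log10(t2) - log10(t1)))
  }
  v0 <- -log(1 - turnover_fraction) / t_star * a0
  unname(v0 / (enzyme_conc * a0))
}

#' Check mass conservation along a trajectory
#'
#' @param network A `reaction_network`.
#' @param enzyme_conc Enzyme concentration (M).
#' @param times Output times.
#' @return Tibble with one row per conservation group: initial total and the
#'   maximum relative drift along the trajectory.
#' @export
conservation_drift <- function(network, enzyme_conc,
                               times = seq(0, network$condition$endpoint,
                                           length.out = 61)) {
  init <- network$init0
  init[network$enzyme_species] <- enzyme_conc
  out <- ode_solve(network, init, times)
  res <- lapply(names(network$groups), function(g) {
    cols <- network$groups[[g]]
    tot <- rowSums(out[, cols, drop = FALSE])
    t0 <- sum(init[cols])
    drift <- if (t0 > 0) max(abs(tot - t0)) / t0 else max(abs(tot))
    tibble(group = g, total = t0, max_rel_drift = drift)
  })
  bind_rows(res)
}
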