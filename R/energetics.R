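# ATP-equivalent conversion and the NADPH-balancing construction of the
# NADPH-FADH2 axis. Ledgers stay exact rationals; ATP equivalents are plain
# doubles, which is still exact under the default dyadic P/O ratios (2.5 and
# 1.5), so the headline -19 and +32 ATP/glucose are exact numbers, not
# approximations.

#' Energetics configuration
#'
#' @param po_nadh ATP formed per NADH oxidized by the respiratory chain
#'   (default 2.5).
#' @param po_fadh2 ATP formed per FADH2 oxidized via the
#'   electron-transferring flavoprotein route (default 1.5).
#' @param gtp_as_atp fold GTP/GDP turnover into the ATP total (default
#'   \code{TRUE}).
#' @param nadph_respirable treat NADPH as respirable at the NADH P/O ratio
#'   (default \code{FALSE}; NADPH is an anabolic, non-respirable carrier).
#' @return an object of class \code{"energetics_config"}.
#' @export
energetics_config <- function(po_nadh = 2.5, po_fadh2 = 1.5,
                              gtp_as_atp = TRUE, nadph_respirable = FALSE) {
  stopifnot(po_nadh > 0, po_fadh2 > 0,
            is.logical(gtp_as_atp), is.logical(nadph_respirable))
  structure(list(po_nadh = po_nadh, po_fadh2 = po_fadh2,
                 gtp_as_atp = gtp_as_atp, nadph_respirable = nadph_respirable),
            class = "energetics_config")
}

#' Net ATP equivalents of a ledger
#'
#' \code{net(ATP) + po_nadh * net(NADH) + po_fadh2 * net(FADH2)}, with GTP
#' folded into ATP when \code{gtp_as_atp} and NADPH credited at the NADH
#' ratio only when \code{nadph_respirable}.
#'
#' @param x a \code{\link{ledger}}.
#' @param config an \code{\link{energetics_config}}.
#' @return a single numeric ATP-equivalent value.
#' @export
atp_equivalents <- function(x, config = energetics_config()) {
  stopifnot(inherits(x, "cofactor_ledger"), inherits(config, "energetics_config"))
  total <- as.numeric(ledger_entry(x, "ATP")) +
    config$po_nadh * as.numeric(ledger_entry(x, "NADH")) +
    config$po_fadh2 * as.numeric(ledger_entry(x, "FADH2"))
  if (config$gtp_as_atp)
    total <- total + as.numeric(ledger_entry(x, "GTP"))
  if (config$nadph_respirable)
    total <- total + config$po_nadh * as.numeric(ledger_entry(x, "NADPH"))
  total
}

#' Construct the NADPH-FADH2 axis by balancing NADPH
#'
#' Couples the pentose phosphate pathway (per glucose) to fatty-acid cycling
#' at the unique cycling multiplicity n that makes the combined NADPH net
#' exactly zero. In idealized mode this is 12 acetyl-CoA units per glucose
#' (12 NADPH produced, 1 consumed per unit cycled) and the axis ledger is
#' \{ATP: -37, FAD: -12, FADH2: +12\}; in exact palmitate mode it is two C16
#' cycles (16 acetyl-CoA units) with a -2 NADH edge effect.
#'
#' @param library an \code{axis_library}.
#' @param mode \code{"idealized"} or \code{"exact_c16"}.
#' @param config an \code{\link{energetics_config}}.
#' @param ppp_multiplicity exact multiplicity of the pentose phosphate
#'   pathway term (glucose entering the axis), default 1.
#' @return an object of class \code{"axis_solution"}: \code{balancing_cofactor},
#'   \code{n_acetyl_coa} (exact \code{\link{rat}}), \code{cycle_multiplicity}
#'   (multiplicity of the cycling pathway term), \code{composition},
#'   \code{axis_ledger}, \code{y_axis}, \code{y_std}, \code{cycling_atp}
#'   (ATP consumed by the cycling terms alone, a positive quantity) and
#'   \code{config}.
#' @export
solve_axis <- function(library = axis_library(),
                       mode = c("idealized", "exact_c16"),
                       config = energetics_config(),
                       ppp_multiplicity = 1) {
  mode <- match.arg(mode)
  ppp_multiplicity <- rat(ppp_multiplicity)
  if (!(ppp_multiplicity > rat(0))) stop("ppp_multiplicity must be > 0")

  ppp <- get_pathway("ppp", "idealized", library = library)
  cyc <- get_pathway("fa_cycling", mode, library = library)
  produced <- ledger_entry(ppp$ledger, "NADPH") * ppp_multiplicity
  per_cycle <- ledger_entry(cyc$ledger, "NADPH")
  if (!(produced > rat(0)) || !(per_cycle < rat(0)))
    stop("no positive cycling multiplicity balances NADPH: PPP yields ",
         format(produced), ", cycling nets ", format(per_cycle),
         " NADPH per unit (check the library and energetics configuration)")
  n_cycles <- produced / (rat(0) - per_cycle)
  acetyl_per_cycle <- if (mode == "idealized") rat(1) else rat(8)

  cyc_id <- if (mode == "idealized") "fa_cycling" else "fa_cycling_c16"
  comp <- composition(c("ppp", cyc_id), c(ppp_multiplicity, n_cycles))
  axis_ledger <- net_ledger(comp, library)
  stopifnot(ledger_entry(axis_ledger, "NADPH") == rat(0))

  y_axis <- atp_equivalents(axis_ledger, config)
  y_std <- atp_equivalents(
    get_pathway("glycolysis_tca", "idealized", library = library)$ledger, config)
  # ATP consumed by the cycling terms alone, as a positive quantity
  # (36 at the idealized balance point; the PPP contributes 1 more)
  cycling_atp <- -as.numeric(ledger_entry(cyc$ledger, "ATP") * n_cycles)

  structure(list(balancing_cofactor = "NADPH",
                 mode = mode,
                 n_acetyl_coa = n_cycles * acetyl_per_cycle,
                 cycle_multiplicity = n_cycles,
                 composition = comp,
                 axis_ledger = axis_ledger,
                 y_axis = y_axis,
                 y_std = y_std,
                 cycling_atp = cycling_atp,
                 config = config),
            class = "axis_solution")
}

#' @export
print.axis_solution <- function(x, ...) {
  cat("NADPH-FADH2 axis solution (", x$mode, " mode)\n", sep = "")
  cat("  balancing cofactor: ", x$balancing_cofactor,
      "; acetyl-CoA units cycled per glucose: ", format(x$n_acetyl_coa), "\n", sep = "")
  cat("  axis ledger: ", format(x$axis_ledger), "\n", sep = "")
  cat("  ATP/glucose via axis: ", x$y_axis,
      "; via glycolysis+TCA: ", sprintf("%+g", x$y_std), "\n", sep = "")
  invisible(x)
}

#' ATP yield of a glucose mixture routed partly through the axis
#'
#' @param f fraction of glucose routed through the NADPH-FADH2 axis, in
#'   [0, 1].
#' @param solution an \code{\link{solve_axis}} result.
#' @return \code{f * y_axis + (1 - f) * y_std}, ATP per glucose.
#' @export
mixture_yield <- function(f, solution) {
  stopifnot(inherits(solution, "axis_solution"))
  if (any(f < 0 | f > 1)) stop("fraction f must lie in [0, 1]")
  f * solution$y_axis + (1 - f) * solution$y_std
}

#' Glucose fraction routed through the axis implied by metabolic inefficiency
#'
#' An animal eating r times the control intake at unchanged ATP output
#' satisfies the energy-balance closure
#' \code{r * (f * y_axis + (1 - f) * y_std) = y_std}, giving
#' \code{f = y_std * (1 - 1/r) / (y_std - y_axis)}. At the default yields
#' (+32 and -19 ATP/glucose) a relative intake of 1.5 gives f = 32/153,
#' about 20 percent of ingested glucose.
#'
#' @param intake_ratio relative food consumption versus control (r >= 1).
#' @param solution an \code{\link{solve_axis}} result (needs
#'   \code{y_std > y_axis}).
#' @return an object of class \code{"inefficiency_estimate"} with
#'   \code{intake_ratio}, \code{fraction} (raw f), \code{percent} (100 f) and
#'   \code{rounded_percent} (nearest multiple of ten).
#' @export
inefficiency_fraction <- function(intake_ratio, solution) {
  stopifnot(inherits(solution, "axis_solution"))
  if (intake_ratio < 1) stop("intake_ratio must be >= 1")
  if (solution$y_std <= solution$y_axis)
    stop("inefficiency estimate requires y_std > y_axis")
  f <- solution$y_std * (1 - 1 / intake_ratio) / (solution$y_std - solution$y_axis)
  if (f > 1) {
    # f reaches 1 only if y_axis > 0; then r_max = y_std / y_axis
    r_max <- solution$y_std / solution$y_axis
    stop("intake ratio ", intake_ratio, " is infeasible for these yields; ",
         "the maximal feasible ratio is ", format(r_max))
  }
  structure(list(intake_ratio = intake_ratio,
                 fraction = f,
                 percent = 100 * f,
                 rounded_percent = round(100 * f / 10) * 10),
            class = "inefficiency_estimate")
}

#' @export
print.inefficiency_estimate <- function(x, ...) {
  cat("Glucose routed through the NADPH-FADH2 axis at intake ratio ",
      x$intake_ratio, ":\n  f = ", format(x$fraction), " (",
      format(x$percent), "%), rounded to the nearest ten percent: ",
      x$rounded_percent, "%\n", sep = "")
  invisible(x)
}
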