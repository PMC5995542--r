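#' Named simulation scenarios
#'
#' Each scenario bundles a [kinetic_scheme()], an [emission_model()], mixture
#' weights for kinetic subpopulations, and defaults for trace count and
#' duration. The scenarios emulate the smFRET experiments of bacterial
#' translation termination:
#'
#' * **Subunit rotation** (S6/L9 dye pair): non-rotated (N, FRET 0.73) and
#'   rotated (R, FRET 0.52) states of the ribosome.
#'   - `prehc_s6l9`: pre-hydrolysis complex, N-dominant with slow exchange.
#'     The exchange rates are design values (k_N_to_R = 0.1, k_R_to_N =
#'     0.4 1/s, stationary N fraction 0.8); only the FRET means are measured
#'     quantities.
#'   - `posthc_s6l9`: post-hydrolysis complex fluctuating in the 0.5-2.6 1/s
#'     range (design values 1.0 and 1.5 1/s).
#'   - `rf3_prehc_rotation`: RF3-GTP bound to the pre-hydrolysis complex;
#'     k_R_to_N = 2.2 1/s is a measured value, k_N_to_R = 4.4 1/s is a design
#'     value chosen to make the R state dominant (2/3 occupancy).
#'   - `rf1gaq_rf3_rotation`: RF1(GAQ) + RF3, a 70/30 mixture of fast
#'     (k_N_to_R = 5.9, k_R_to_N = 2.9 1/s) and slow (1.30, 0.80 1/s)
#'     subpopulations.
#' * **L1 stalk / P-site tRNA** (`l1_trna_rf3`): open (FRET 0.32) and closed
#'   (FRET 0.74) states with k_closed_to_open = 6.0 1/s (measured) and
#'   k_open_to_closed = 2.0 1/s (design value; the closed state is sampled
#'   transiently).
#' * **Release-factor binding** (L11 dye pair; the factor carries the
#'   acceptor, so the unbound state is dark): `l11_rf1` (bound FRET 0.72,
#'   dissociation below the photobleaching detection limit; design
#'   k_off = 0.01 1/s), `l11_rf2` (0.65, k_off = 1.0 1/s), `l11_rf3_prehc`
#'   (0.62, 5.9 1/s), `l11_rf3_posthc` (0.64, 5.4 1/s), `l11_rf3_rf1gaq`
#'   (0.51, 1.3 1/s), `l11_rf3_gdpnp` (0.71, 0.34 1/s). The association rate
#'   is a design value (k_on = 0.5 1/s) in all binding scenarios; binding
#'   traces start in the dark state.
#' * **`bleach_calibration`**: a synthetic static high-FRET complex (single
#'   bound state, FRET 0.70, no transitions) used to estimate the dye-pair
#'   photobleaching rate from non-fluctuating trajectories.
#'
#' All scenarios share the default [emission_model()] (bleed-through 0.13,
#' combined bleach rate 0.1 1/s) and a 30 frames/s recording rate.
#'
#' @param name scenario name; see `list_scenarios()` for the available set.
#' @return `scenario_fixture()` returns an object of class
#'   `scenario_fixture` with elements `name`, `schemes` (list of
#'   [kinetic_scheme()], one per subpopulation), `weights`, `emission`,
#'   `kind` (`"conformational"` or `"binding"`), `n_traces`, `duration`
#'   (s) and `design_values` (character vector naming the rate constants
#'   that are design choices rather than measured quantities).
#' @examples
#' fx <- scenario_fixture("prehc_s6l9")
#' fx$schemes[[1]]$fret_mean
#' list_scenarios()
#' @export
scenario_fixture <- function(name) {
  reg <- fixture_registry()
  if (!name %in% names(reg)) {
    stop(
      "unknown scenario '", name, "'; available scenarios: ",
      paste(names(reg), collapse = ", ")
    )
  }
  reg[[name]]
}

#' @rdname scenario_fixture
#' @export
list_scenarios <- function() {
  names(fixture_registry())
}

two_state <- function(ids, means, k12, k21, sds = c(0.05, 0.05),
                      dark = character(), initial = NULL) {
  kinetic_scheme(
    state_ids = ids,
    fret_mean = means,
    fret_sd = sds,
    rates = matrix(c(0, k12, k21, 0), 2, 2, byrow = TRUE),
    initial_probs = initial,
    dark_states = dark
  )
}

binding_scheme <- function(e_bound, k_on, k_off) {
  # Binding traces start unbound (factor arrives from solution); the dark
  # state nominally sits at FRET 0 but is flagged dark so the renderer
  # suppresses acceptor signal regardless of its nominal mean.
  two_state(
    ids = c("dark", "bound"),
    means = c(0, e_bound),
    k12 = k_on, k21 = k_off,
    dark = "dark",
    initial = c(1, 0)
  )
}

make_fixture <- function(name, schemes, weights, kind,
                         design_values = character(),
                         emission = emission_model(),
                         n_traces = 300, duration = 20) {
  stopifnot(abs(sum(weights) - 1) < 1e-9, length(schemes) == length(weights))
  structure(
    list(
      name = name, schemes = schemes, weights = weights,
      emission = emission, kind = kind, design_values = design_values,
      n_traces = n_traces, duration = duration
    ),
    class = "scenario_fixture"
  )
}

fixture_registry <- function() {
  rot <- function(k_nr, k_rn) {
    # state 1 = R (0.52), state 2 = N (0.73); rates[2,1] = k_N_to_R
    kinetic_scheme(
      state_ids = c("R", "N"),
      fret_mean = c(0.52, 0.73),
      fret_sd = c(0.05, 0.05),
      rates = matrix(c(0, k_rn, k_nr, 0), 2, 2, byrow = TRUE)
    )
  }
  list(
    prehc_s6l9 = make_fixture(
      "prehc_s6l9", list(rot(0.1, 0.4)), 1, "conformational",
      design_values = c("k_N_to_R", "k_R_to_N")
    ),
    posthc_s6l9 = make_fixture(
      "posthc_s6l9", list(rot(1.0, 1.5)), 1, "conformational",
      design_values = c("k_N_to_R", "k_R_to_N")
    ),
    rf3_prehc_rotation = make_fixture(
      "rf3_prehc_rotation", list(rot(4.4, 2.2)), 1, "conformational",
      design_values = "k_N_to_R"
    ),
    rf1gaq_rf3_rotation = make_fixture(
      "rf1gaq_rf3_rotation",
      list(rot(5.9, 2.9), rot(1.30, 0.80)),
      c(0.7, 0.3), "conformational"
    ),
    l1_trna_rf3 = make_fixture(
      "l1_trna_rf3",
      list(two_state(c("open", "closed"), c(0.32, 0.74),
                     k12 = 2.0, k21 = 6.0)),
      1, "conformational",
      design_values = "k_open_to_closed"
    ),
    l11_rf1 = make_fixture(
      "l11_rf1", list(binding_scheme(0.72, 0.5, 0.01)), 1, "binding",
      design_values = c("k_on", "k_off")
    ),
    l11_rf2 = make_fixture(
      "l11_rf2", list(binding_scheme(0.65, 0.5, 1.0)), 1, "binding",
      design_values = "k_on"
    ),
    l11_rf3_prehc = make_fixture(
      "l11_rf3_prehc", list(binding_scheme(0.62, 0.5, 5.9)), 1, "binding",
      design_values = "k_on"
    ),
    l11_rf3_posthc = make_fixture(
      "l11_rf3_posthc", list(binding_scheme(0.64, 0.5, 5.4)), 1, "binding",
      design_values = "k_on"
    ),
    l11_rf3_rf1gaq = make_fixture(
      "l11_rf3_rf1gaq", list(binding_scheme(0.51, 0.5, 1.3)), 1, "binding",
      design_values = "k_on"
    ),
    l11_rf3_gdpnp = make_fixture(
      "l11_rf3_gdpnp", list(binding_scheme(0.71, 0.5, 0.34)), 1, "binding",
      design_values = "k_on"
    ),
    bleach_calibration = make_fixture(
      "bleach_calibration",
      list(kinetic_scheme(
        state_ids = "bound", fret_mean = 0.70, fret_sd = 0.05,
        rates = matrix(0, 1, 1)
      )),
      1, "conformational",
      design_values = character(), duration = 30
    )
  )
}

#' @export
print.scenario_fixture <- function(x, ...) {
  cat("Scenario fixture '", x$name, "' (", x$kind, ")\n", sep = "")
  cat("Subpopulations:", length(x$schemes),
      "with weights", paste(x$weights, collapse = "/"), "\n")
  for (i in seq_along(x$schemes)) {
    cat("-- subpopulation", i, "--\n")
    print(x$schemes[[i]])
  }
  if (length(x$design_values)) {
    cat("Design (non-measured) rate constants:",
        paste(x$design_values, collapse = ", "), "\n")
  }
  invisible(x)
}
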