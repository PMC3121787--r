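# Shared fixtures: small generating truths and stub fits, all built in code.

oc_ref <- function() one_compartment_params(16, 8, log(log(2) / 9))

noiseless_trajectory <- function(params = oc_ref(),
                                 days = default_schedule()) {
  tibble::tibble(day = days,
                 delta_permil = predict_one_compartment(params, days))
}

plasma_c_truth <- function(...) {
  trajectory_truth("plasma", "d13C", phi1 = -18.5, phi2 = -24.5,
                   half_life = 9, ...)
}

# minimal object understood by select_model()/aic_table()
stub_fit <- function(aic, n_params, n_fixed = 0L, n_random = 1L,
                     converged = TRUE) {
  structure(list(aic = aic, converged = converged,
                 complexity = c(n_params = n_params, n_fixed = n_fixed,
                                n_random = n_random),
                 fixed_effects = character(n_fixed),
                 random_effects = character(n_random),
                 n_params = n_params),
            class = "turnover_fit")
}
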