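# Shared fixtures built in code.

# A small single-site recovery experiment over sub-optimal temperatures,
# fully released seeds, no empties.
recovery_design <- function(temps = c(5, 10, 15, 20), dishes = 4,
                            seeds = 100) {
  germination_design(sites = "S1", pretreatments = 90,
                     temperatures = temps, dishes = dishes,
                     seeds_per_dish = seeds)
}

recovery_params <- function(rng_seed = 1L, T_b_true = 1,
                            theta50_true = 120, sigma_theta = 0.2) {
  sim_params(T_b_true = T_b_true, theta50_true = theta50_true,
             sigma_theta = sigma_theta, T_opt_hi = 20.5, T_ceiling = 30,
             strat_half = 45, strat_slope = 5, p_empty = 0,
             schedule = 1:120, rng_seed = rng_seed)
}

# Hand-built single-dish record in the long CSV dialect.
make_dish <- function(site = "A", strat = 90, temp = 15, dish = 1,
                      day, cum, sown = 25, empty = 0) {
  final <- cum[length(cum)]
  data.frame(site = site, pretreatment_days = strat, temperature_c = temp,
             dish = dish, day = day, cum_germinated = cum, sown = sown,
             empty = empty,
             viable_ungerminated = sown - empty - final,
             stringsAsFactors = FALSE)
}
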