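# shared fixtures: sequences, parameter sets, unit conversions

wt_cs <- charge_sequence(builtin_sequence("caprin1_wt"))
py_cs <- charge_sequence(builtin_sequence("py_caprin1"))

params_wt <- energy_params(v2 = 2.4)                  # Caprin1 fit
params_py <- energy_params(v2 = 2.4, eps_s = -1.5)    # pY-Caprin1 fit

M_to_b3 <- function(x) convert_conc(x, "M", "b-3")

# random charge sequence of length n with charges in {0, +1, -1, -2}
random_cs <- function(n, seed) {
  set.seed(seed)
  sig <- sample(c(0L, 1L, -1L, -2L), n, replace = TRUE,
                prob = c(0.6, 0.2, 0.15, 0.05))
  structure(list(sigma = sig, Q = sum(sig), N = n,
                 name = paste0("rand", seed)),
            class = "ChargeSequence")
}

# tiny MD configurations used across cgmd tests
dimer_config <- function(r, species = c("G", "G"), bonded = TRUE,
                         box = c(200, 200, 200)) {
  snapshot(rbind(c(50, 50, 50), c(50 + r, 50, 50)), species,
           chain = if (bonded) c(1L, 1L) else c(NA_integer_, NA_integer_),
           box = box)
}
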