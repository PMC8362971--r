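# Shared fixtures, built in code.

# Reported mean egg-to-adult development times (days) at four constant
# temperatures for the reference parasitoid dataset; their reciprocals are
# the mean development rates used throughout the fitting tests.
reference_dev_times <- c(`15` = 69.11, `20` = 32.31, `25` = 19.75,
                         `30` = 17.24)

reference_rates <- function() {
  list(temperature = as.numeric(names(reference_dev_times)),
       rate = unname(1 / reference_dev_times))
}

# One shared truth model set (construction is cheap but used everywhere).
truth_models <- longicaudata_models()

# A small deterministic life-table schedule with all reproduction
# concentrated at one age: rm has the closed form log(R0)/age.
point_schedule <- function(age, r0) {
  structure(data.frame(x = c(0, age), lx = c(1, 1), mx = c(0, r0)),
            class = c("life_table", "data.frame"))
}
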