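table1_riders <- function() load_fixture("riders_table1")

rider_by_name <- function(riders, name) {
  riders[[which(vapply(riders, `[[`, character(1), "name") == name)]]
}

# OLS slope of P/m^x on m via lm(); independent route used as oracle
slope_at_exponent <- function(x, v, incline, env = ride_environment()) {
  curve <- required_power_curve(v, incline, env)
  unname(coef(stats::lm(I(curve$power / curve$mass^x) ~ curve$mass))[2])
}
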