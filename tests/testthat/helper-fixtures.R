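# Shared fixtures: all synthetic, built in code.

# A minimal hand-written well-formed observation data frame.
tiny_obs_df <- function(n = 3) {
  data.frame(
    carotenoid = rep("lutein", n),
    packaging = rep("glass", n),
    condition = rep("dark", n),
    temperature_C = rep(10, n),
    exposure = seq(0, by = 7, length.out = n),
    exposure_unit = rep("day", n),
    replicate = rep(1L, n),
    concentration_ug_per_g = seq(0.59, by = -0.01, length.out = n),
    stringsAsFactors = FALSE
  )
}

# A randomised valid study table for property tests (own RNG stream).
random_study_table <- function(seed) {
  set.seed(seed)
  temps <- sort(sample(c(5, 10, 20, 35, 45), 3))
  exposures <- sort(c(0, runif(4, 1, 40)))
  rows <- expand.grid(temperature_C = temps, exposure = exposures,
                      replicate = 1:2)
  rows$carotenoid <- sample(c("lutein", "beta-carotene"), 1)
  rows$packaging <- sample(c("glass", "PET"), 1)
  rows$condition <- "dark"
  rows$exposure_unit <- "day"
  rows$concentration_ug_per_g <- round(runif(nrow(rows), 0.01, 2), 6)
  study_table(rows, axis = "time_days")
}

# Noiseless single-group tables from published truth parameters.
noiseless_group <- function(order = "zero", scenario = "dark",
                            carotenoid = "antheraxanthin") {
  make_paper_fixture(scenario, "glass", noise = NULL,
                     carotenoids = carotenoid)
}
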