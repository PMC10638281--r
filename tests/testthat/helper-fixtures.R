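# Shared test helpers.

# Independent monoisotopic-mass oracle: per-atom summation against a second
# isotope table (CODATA/AME2020 values, more digits than the package table).
oracle_mass <- function(formula_string) {
  table2 <- c(C = 12.0, H = 1.00782503207, D = 2.01410177785,
              N = 14.0030740048, O = 15.99491461956,
              S = 31.97207100, P = 30.97376163, Na = 22.9897692809)
  total <- 0
  s <- formula_string
  while (nzchar(s)) {
    m <- regmatches(s, regexec("^([A-Z][a-z]?)([0-9]*)", s))[[1]]
    n <- if (nzchar(m[3])) as.integer(m[3]) else 1L
    for (k in seq_len(n)) total <- total + table2[[m[2]]]  # one atom at a time
    s <- substring(s, nchar(m[1]) + 1L)
  }
  total
}

# exact calibration with chosen k, b, built through the public fitting API
make_calibration <- function(k = 0.5, b = 2, carbons = 20:30) {
  fit_ri_calibration(data.frame(carbon_number = carbons,
                                rt_min = k * carbons + b))
}

# a single-Gaussian trace on a uniform grid
gaussian_trace <- function(id = "fam|light", apex = 10, height = 1000,
                           sigma = 0.05, step = 0.01, span = 20,
                           noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  t <- seq(0, span, by = step)
  y <- height * exp(-0.5 * ((t - apex) / sigma)^2)
  if (noise_sd > 0) y <- pmax(0, y + rnorm(length(t), 0, noise_sd))
  mrm_trace(id, t, y)
}

# fabricate a detect_peaks-style peak table row
peak_row <- function(apex_rt, height) {
  data.frame(apex_rt = apex_rt, height = height, area = height * 0.1,
             left_rt = apex_rt - 0.1, right_rt = apex_rt + 0.1)
}
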