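# Synthetic chromatogram generation with known ground truth.
#
# The generator emulates what the screening and annotation stages assume
# about real runs: every planted regioisomer produces co-eluting Gaussian
# peaks of ~1:1 height in the light and heavy channels of its family, at
# the retention time its RI prediction model implies through the RT <-> RI
# calibration line; decoy signals (single-channel, or pairs at a skewed
# ratio) and additive baseline noise provide the negatives.  Everything is
# driven by one seed so runs are byte-identical.

#' Simulation configuration
#'
#' @param seed integer; fixes every random draw.
#' @param k,b calibration line RT = k * carbon + b (minutes per carbon,
#'   minutes).  The defaults place the C20-C30 calibrants at 10-14.5 min
#'   inside the 31-min gradient window.
#' @param peak_sigma Gaussian peak width (standard deviation), minutes.
#' @param noise_sd baseline noise standard deviation as a fraction of the
#'   largest peak height in a trace; `0` for noise-free data.
#' @param ratio_jitter log-normal standard deviation of the heavy/light
#'   height ratio around 1 (the 1:1 derivative mix).
#' @param sampling_step chromatogram sampling interval, minutes.
#' @param gradient_span end of the acquisition window, minutes (peaks are
#'   rejected outside `[0, gradient_span]`).
#' @param calibrant_height apex height of calibrant peaks, counts.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, k = 0.45, b = 1.0, peak_sigma = 0.03,
                       noise_sd = 0.01, ratio_jitter = 0.05,
                       sampling_step = 0.01, gradient_span = 31,
                       calibrant_height = 1e4) {
  stopifnot(k > 0, peak_sigma > 0, noise_sd >= 0, ratio_jitter >= 0,
            sampling_step > 0, gradient_span > 0, calibrant_height > 0)
  structure(
    list(seed = as.integer(seed), k = k, b = b, peak_sigma = peak_sigma,
         noise_sd = noise_sd, ratio_jitter = ratio_jitter,
         sampling_step = sampling_step, gradient_span = gradient_span,
         calibrant_height = calibrant_height),
    class = "sim_config"
  )
}

# calibration object matching a config's true line (for RI <-> RT plumbing)
.cfg_calibration <- function(cfg) {
  obs <- data.frame(carbon_number = 20:30, rt_min = cfg$k * (20:30) + cfg$b)
  fit_ri_calibration(obs)
}

.time_grid <- function(cfg) seq(0, cfg$gradient_span, by = cfg$sampling_step)

# add a Gaussian peak to an intensity vector
.add_peak <- function(y, t, rt, height, sigma) {
  y + height * exp(-0.5 * ((t - rt) / sigma)^2)
}

.finish_trace <- function(channel_id, t, y, cfg, family = NULL, channel = NULL) {
  if (cfg$noise_sd > 0 && max(y) > 0) {
    y <- y + stats::rnorm(length(y), 0, cfg$noise_sd * max(y))
    y[y < 0] <- 0
  }
  mrm_trace(channel_id, t, y, family = family, channel = channel)
}

#' Generate a calibrant run
#'
#' One trace per C20-C30 saturated fatty-acid calibrant, each with a
#' single Gaussian peak at RT = k * n + b on the configured line, plus
#' baseline noise.  The true line is returned so recovery can be scored.
#'
#' @param cfg a [sim_config()].
#' @param carbons calibrant carbon numbers.
#' @return list with `traces` (list of [mrm_trace], channel ids
#'   `"cal-C<n>"`), `truth` (`k`, `b`) and `observations` (the noiseless
#'   calibrant table).
#' @export
generate_calibrant_run <- function(cfg = sim_config(), carbons = 20:30) {
  set.seed(cfg$seed)
  t <- .time_grid(cfg)
  traces <- lapply(carbons, function(n) {
    rt <- cfg$k * n + cfg$b
    if (rt <= 0 || rt >= cfg$gradient_span) {
      stop("calibrant C", n, " elutes at ", round(rt, 2),
           " min, outside the gradient window")
    }
    y <- .add_peak(numeric(length(t)), t, rt, cfg$calibrant_height, cfg$peak_sigma)
    .finish_trace(sprintf("cal-C%d", n), t, y, cfg)
  })
  list(
    traces = traces,
    truth = c(k = cfg$k, b = cfg$b),
    observations = data.frame(carbon_number = carbons,
                              rt_min = cfg$k * carbons + cfg$b)
  )
}

#' Sample a ground-truth FAHFA composition
#'
#' Draws regioisomers from the coverage of the RI prediction models:
#' `n_families` families sampled without replacement from the models'
#' family grid, `positions_per_family` distinct ester positions per family
#' from each model's position range.  Each family draws a log-uniform
#' abundance between `abundance_range[1]` and `abundance_range[2]` counts;
#' regioisomers within a family vary around it by a log-uniform factor in
#' [0.5, 2], mirroring the comparable responses of a regioisomer ladder
#' while keeping the dynamic range within one MRM channel moderate.
#'
#' @param n_families number of families to plant.
#' @param positions_per_family regioisomers per family.
#' @param seed integer seed.
#' @param models list of `ri_model`s defining the coverage.
#' @param abundance_range log-uniform abundance bounds, counts.
#' @param n_single_channel,n_bad_ratio decoy counts: peaks present in only
#'   the light channel, and light/heavy pairs planted at a 5:1 ratio.
#' @return list of class `ground_truth` with `entries` (data frame:
#'   `family`, `hfa`, `fa_carbon`, `ester_position`, `ri`, `abundance`)
#'   and `decoys` (data frame: `family`, `channel`, `rt`, `height`,
#'   `kind`).
#' @export
generate_ground_truth <- function(n_families, positions_per_family, seed = 1L,
                                  models = shipped_ri_models(),
                                  abundance_range = c(1e4, 1e6),
                                  n_single_channel = 0L, n_bad_ratio = 0L) {
  set.seed(seed)
  coverage <- do.call(rbind, lapply(models, function(m) {
    data.frame(hfa = m$hfa_key,
               fa_carbon = seq(m$fa_carbon_range[1], m$fa_carbon_range[2]))
  }))
  if (n_families > nrow(coverage)) {
    stop("requested ", n_families, " families but the models cover only ",
         nrow(coverage))
  }
  if (n_families == 0L) {
    entries <- data.frame(family = character(0), hfa = character(0),
                          fa_carbon = integer(0), ester_position = integer(0),
                          ri = numeric(0), abundance = numeric(0),
                          stringsAsFactors = FALSE)
  } else {
    fam_rows <- coverage[sample(nrow(coverage), n_families), , drop = FALSE]
    entries <- do.call(rbind, lapply(seq_len(nrow(fam_rows)), function(i) {
      m <- models[[fam_rows$hfa[i]]]
      pos_range <- seq(m$position_range[1], m$position_range[2])
      if (positions_per_family > length(pos_range)) {
        stop("requested ", positions_per_family,
             " positions but the model covers only ", length(pos_range))
      }
      pos <- sort(sample(pos_range, positions_per_family))
      fam_abundance <- 10^stats::runif(1, log10(abundance_range[1]),
                                       log10(abundance_range[2]))
      chain <- parse_shorthand(fam_rows$hfa[i])
      data.frame(
        family = family_key(fatty_acyl(fam_rows$fa_carbon[i], 0L), chain),
        hfa = fam_rows$hfa[i],
        fa_carbon = fam_rows$fa_carbon[i],
        ester_position = pos,
        ri = predict_ri(m, fam_rows$fa_carbon[i], pos),
        abundance = fam_abundance *
          2^stats::runif(positions_per_family, -1, 1),
        stringsAsFactors = FALSE
      )
    }))
    rownames(entries) <- NULL
  }
  n_dec <- n_single_channel + n_bad_ratio
  if (n_dec > 0L && nrow(entries) == 0L) {
    stop("decoys need at least one planted family to host their channels")
  }
  decoys <- if (n_dec > 0L) {
    fams <- sample(unique(entries$family), n_dec, replace = TRUE)
    data.frame(
      family = fams,
      channel = "light",
      rt = stats::runif(n_dec, 1, 9),  # early window, clear of analyte RTs
      height = 10^stats::runif(n_dec, log10(abundance_range[1]),
                               log10(abundance_range[2])),
      kind = rep(c("single_channel", "bad_ratio"),
                 c(n_single_channel, n_bad_ratio)),
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(family = character(0), channel = character(0), rt = numeric(0),
               height = numeric(0), kind = character(0), stringsAsFactors = FALSE)
  }
  structure(list(entries = entries, decoys = decoys), class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d regioisomers in %d families, %d decoys\n",
              nrow(x$entries), length(unique(x$entries$family)), nrow(x$decoys)))
  invisible(x)
}

#' Generate a sample run from a ground-truth composition
#'
#' Builds one light and one heavy trace per planted family.  Each
#' regioisomer appears in both channels as a Gaussian peak at
#' `ri_to_rt(ri)` under the configured calibration; the light height is
#' the abundance and the heavy height the abundance times a log-normal
#' jitter around 1.  Single-channel decoys appear only in the light
#' channel; bad-ratio decoys appear in both at 5:1.  Baseline Gaussian
#' noise is added per trace.
#'
#' @param truth a [generate_ground_truth()] object.
#' @param cfg a [sim_config()].
#' @return list with `traces` (list of [mrm_trace]) and `truth_table`
#'   (data frame: `family`, `fa_carbon`, `ester_position`, `ri`, `rt`,
#'   `light_height`, `heavy_height`).
#' @export
generate_sample_run <- function(truth, cfg = sim_config()) {
  stopifnot(inherits(truth, "ground_truth"))
  set.seed(cfg$seed)
  cal <- .cfg_calibration(cfg)
  entries <- truth$entries
  if (nrow(entries)) {
    entries$rt <- ri_to_rt(entries$ri, cal)
    bad <- entries$rt <= 0 | entries$rt >= cfg$gradient_span
    if (any(bad)) {
      stop(sum(bad), " planted regioisomer(s) elute outside [0, ",
           cfg$gradient_span, "] min under this calibration")
    }
    entries$light_height <- entries$abundance
    entries$heavy_height <- entries$abundance *
      stats::rlnorm(nrow(entries), 0, cfg$ratio_jitter)
  }
  t <- .time_grid(cfg)
  fams <- unique(c(entries$family, truth$decoys$family))
  traces <- list()
  for (fam in fams) {
    yl <- numeric(length(t)); yh <- numeric(length(t))
    er <- entries[entries$family == fam, , drop = FALSE]
    for (i in seq_len(nrow(er))) {
      yl <- .add_peak(yl, t, er$rt[i], er$light_height[i], cfg$peak_sigma)
      yh <- .add_peak(yh, t, er$rt[i], er$heavy_height[i], cfg$peak_sigma)
    }
    dr <- truth$decoys[truth$decoys$family == fam, , drop = FALSE]
    for (i in seq_len(nrow(dr))) {
      yl <- .add_peak(yl, t, dr$rt[i], dr$height[i], cfg$peak_sigma)
      if (dr$kind[i] == "bad_ratio") {
        yh <- .add_peak(yh, t, dr$rt[i], dr$height[i] / 5, cfg$peak_sigma)
      }
    }
    traces[[paste0(fam, "|light")]] <-
      .finish_trace(paste0(fam, "|light"), t, yl, cfg)
    traces[[paste0(fam, "|heavy")]] <-
      .finish_trace(paste0(fam, "|heavy"), t, yh, cfg)
  }
  tt <- if (nrow(entries)) {
    entries[c("family", "fa_carbon", "ester_position", "ri", "rt",
              "light_height", "heavy_height")]
  } else {
    data.frame(family = character(0), fa_carbon = integer(0),
               ester_position = integer(0), ri = numeric(0), rt = numeric(0),
               light_height = numeric(0), heavy_height = numeric(0))
  }
  list(traces = unname(traces), truth_table = tt)
}

#' Write a ground-truth table for scoring
#' @param run a [generate_sample_run()] result.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_truth_table <- function(run, path) {
  utils::write.csv(run$truth_table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
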