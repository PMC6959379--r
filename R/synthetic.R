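#' Synthetic data with known ground truth
#'
#' Every downstream stage of the pipeline (NEXAFS deconvolution, isotope mass
#' balance, FTIR fingerprinting, OTU community processing) is exercised
#' against generated inputs whose true parameters are known, so parameter
#' recovery can be measured exactly. The generators are the inverse of the
#' analysis models: spectra are sums of the same Gaussian/step components the
#' fitter uses, chemistry tables follow the one-compartment decay and
#' two-pool mixing models, and OTU tables are multinomial draws from a shared
#' per-sample composition.
#'
#' @name synthetic_data
NULL

#' Ground truth for a synthetic NEXAFS spectrum
#'
#' @param edge `"C1s"` or `"N1s"`.
#' @param true_relative_abundances named fractions over the edge's canonical
#'   pi* labels (see [default_component_model]); must sum to 1.
#' @param edge_jump_height step height (intensity units); sigma-resonance
#'   amplitudes scale with it. May be 0 for a pure pi* mixture.
#' @param noise_sd standard deviation of additive i.i.d. Gaussian noise.
#' @param seed integer seed.
#' @return list of class `nexafs_truth`.
#' @export
nexafs_truth <- function(edge = c("C1s", "N1s"), true_relative_abundances,
                         edge_jump_height = 1, noise_sd = 0, seed = 1) {
  edge <- match.arg(edge)
  ab <- true_relative_abundances
  model <- default_component_model(edge)
  pi_labels <- model$label[model$kind == "gaussian_pi"]
  bad <- setdiff(names(ab), pi_labels)
  if (length(bad)) {
    stop(sprintf("unknown %s pi* component label(s): %s", edge,
                 paste(bad, collapse = ", ")))
  }
  if (abs(sum(ab) - 1) > 1e-9) stop("true_relative_abundances must sum to 1")
  if (any(ab < 0 | ab > 1)) stop("abundance fractions must lie in [0, 1]")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (edge_jump_height < 0) stop("edge_jump_height must be >= 0")
  structure(list(edge = edge, true_relative_abundances = ab,
                 edge_jump_height = edge_jump_height,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "nexafs_truth")
}

# generator shape parameters: total pi* area shared among components; sigma
# resonances at 0.3 x jump height with 4 eV FWHM (only their presence, not
# their exact shape, matters for pi* recovery); step width 0.8 eV
SYN_PI_AREA <- 2.0
SYN_SIGMA_HEIGHT_FRAC <- 0.3
SYN_SIGMA_FWHM <- 4
SYN_STEP_WIDTH <- 0.8

#' Generate a synthetic NEXAFS spectrum
#'
#' The spectrum is the sum of pi* Gaussians at the edge's canonical centers
#' (1.2 eV FWHM) with areas proportional to the true abundances (total pi*
#' area 2 intensity x eV), an error-function edge jump, two broad sigma
#' resonances, and additive Gaussian noise. Identical seeds give bitwise
#' identical spectra.
#'
#' @param truth a [nexafs_truth].
#' @param grid energy grid (eV); default covers the edge's recorded range
#'   (C: 275-320 eV, N: 390-430 eV) at 0.1 eV steps.
#' @return list with elements `spectrum` ([spectrum]) and `truth` (the input
#'   truth augmented with the generator's shape parameters).
#' @export
gen_nexafs_spectrum <- function(truth, grid = NULL) {
  stopifnot(inherits(truth, "nexafs_truth"))
  rng <- edge_ranges(truth$edge)
  if (is.null(grid)) grid <- seq(rng$range[1], rng$range[2], by = 0.1)
  if (min(grid) > rng$range[1] || max(grid) < rng$range[2]) {
    stop(sprintf("grid must cover the %s recorded range [%g, %g] eV",
                 truth$edge, rng$range[1], rng$range[2]))
  }
  model <- default_component_model(truth$edge)
  y <- numeric(length(grid))
  for (lab in names(truth$true_relative_abundances)) {
    i <- match(lab, model$label)
    area <- SYN_PI_AREA * truth$true_relative_abundances[[lab]]
    height <- area / (fwhm_to_sigma(PI_FWHM) * sqrt(2 * pi))
    y <- y + height * gauss_peak(grid, model$center[i], PI_FWHM)
  }
  h <- truth$edge_jump_height
  step_center <- model$center[model$kind == "edge_step"]
  y <- y + h * edge_step_curve(grid, step_center, SYN_STEP_WIDTH)
  for (i in which(model$kind == "gaussian_sigma")) {
    y <- y + SYN_SIGMA_HEIGHT_FRAC * h *
      gauss_peak(grid, model$center[i], SYN_SIGMA_FWHM)
  }
  if (truth$noise_sd > 0) {
    y <- y + withr::with_seed(truth$seed,
                              stats::rnorm(length(grid), 0, truth$noise_sd))
  }
  truth$pi_area_total <- SYN_PI_AREA
  truth$step_width <- SYN_STEP_WIDTH
  s <- spectrum(grid, y, axis_kind = "energy_eV",
                meta = list(edge = truth$edge, synthetic = TRUE,
                            seed = truth$seed))
  list(spectrum = s, truth = truth)
}

#' Generate a synthetic FTIR spectrum
#'
#' A spectrum on 900-1850 cm-1 composed of one broad Gaussian per weighted
#' vibrational band (centered at the band midpoint, FWHM = half the band
#' width so ~95% of each peak's mass falls inside its band) plus additive
#' noise. With all-zero weights and zero noise a flat zero spectrum is
#' returned with a warning and `meta$flat_zero = TRUE`.
#'
#' @param band_weights named non-negative weights over the six default band
#'   labels (see [default_ftir_bands]).
#' @param noise_sd additive Gaussian noise standard deviation.
#' @param seed integer seed.
#' @param grid wavenumber grid (cm-1).
#' @return a [spectrum] with the weights recorded in `meta$band_weights`.
#' @export
gen_ftir_spectrum <- function(band_weights, noise_sd = 0, seed = 1,
                              grid = seq(900, 1850, by = 1)) {
  bands <- default_ftir_bands()
  bad <- setdiff(names(band_weights), bands$label)
  if (length(bad)) {
    stop(sprintf("unknown FTIR band label(s): %s", paste(bad, collapse = ", ")))
  }
  if (any(band_weights < 0)) stop("band weights must be >= 0")
  y <- numeric(length(grid))
  for (lab in names(band_weights)) {
    i <- match(lab, bands$label)
    mid <- (bands$lo[i] + bands$hi[i]) / 2
    fw <- (bands$hi[i] - bands$lo[i]) / 2
    y <- y + band_weights[[lab]] * gauss_peak(grid, mid, fw)
  }
  flat <- all(y == 0) && noise_sd == 0
  if (noise_sd > 0) {
    y <- y + withr::with_seed(as.integer(seed),
                              stats::rnorm(length(grid), 0, noise_sd))
  }
  if (flat) warning("all band weights zero with no noise: flat zero spectrum")
  spectrum(grid, y, axis_kind = "wavenumber_cm1",
           meta = list(band_weights = band_weights, seed = as.integer(seed),
                       flat_zero = flat, synthetic = TRUE))
}

#' Scenario for synthetic mesh-bag chemistry tables
#'
#' Defaults reproduce the study conditions of the field experiment the
#' pipeline targets: 3 plots per treatment, composted C4 (maize) material
#' with initial C 12.1 and N 1.02 g kg-1, per-horizon first-order decay
#' (humus 0.11, mineral 0.29 yr-1, the unfertilized-plot rates), delta 13C
#' end-members -13.36 (compost) and -25.82 per mil (in-grown mycelium), 15%
#' new carbon after incubation and a 21% C/N-ratio increase.
#'
#' @param n_plots_per_treatment plots per treatment level.
#' @param initial_C,initial_N g kg-1 of the initial material.
#' @param horizon_decay_rates named yr-1 rates, one per horizon.
#' @param delta13c_c4,delta13c_new end-member delta 13C (per mil); the C4
#'   end-member must be heavier (less negative).
#' @param new_c_fraction fraction of final C that is new (C3, fungal) carbon.
#' @param cn_increase fractional C/N increase of incubated vs initial material.
#' @param between_plot_sd named sds: relative (lognormal) for `C` and `N`,
#'   absolute for `delta13C` and `pH`. Zero gives exact closed-form values.
#' @param seed integer seed.
#' @return list of class `chemistry_scenario`.
#' @export
chemistry_scenario <- function(n_plots_per_treatment = 3,
                               initial_C = 12.1, initial_N = 1.02,
                               horizon_decay_rates = c(humus = 0.11,
                                                       mineral = 0.29),
                               delta13c_c4 = -13.36, delta13c_new = -25.82,
                               new_c_fraction = 0.15, cn_increase = 0.21,
                               between_plot_sd = c(C = 0.07, N = 0.07,
                                                   delta13C = 0.35,
                                                   pH = 0.05),
                               seed = 1) {
  if (initial_C <= 0 || initial_N <= 0) {
    stop("initial C and N must be positive")
  }
  if (any(horizon_decay_rates < 0)) stop("decay rates must be >= 0")
  if (new_c_fraction < 0 || new_c_fraction > 1) {
    stop("new_c_fraction must lie in [0, 1]")
  }
  if (delta13c_c4 <= delta13c_new) {
    stop("the C4 end-member must be isotopically heavier than new carbon")
  }
  structure(list(n_plots_per_treatment = as.integer(n_plots_per_treatment),
                 initial_C = initial_C, initial_N = initial_N,
                 horizon_decay_rates = horizon_decay_rates,
                 delta13c_c4 = delta13c_c4, delta13c_new = delta13c_new,
                 new_c_fraction = new_c_fraction, cn_increase = cn_increase,
                 between_plot_sd = between_plot_sd, seed = as.integer(seed)),
            class = "chemistry_scenario")
}

#' Generate a synthetic chemistry table
#'
#' One row per plot x horizon x treatment. Final C follows the
#' one-compartment model `C_final = C_initial * exp(-k t)` with the horizon's
#' rate and multiplicative lognormal plot noise; delta 13C comes from the
#' two-pool mixing model at the scenario's new-C fraction; N is drawn so the
#' C/N ratio exceeds the initial ratio by the scenario's `cn_increase`.
#'
#' @param scn a [chemistry_scenario].
#' @param t_years incubation time (yr), > 0.
#' @return data frame with columns `plot`, `horizon`, `treatment`, `C`, `N`,
#'   `delta13C`, `pH`; ground-truth parameters and noise-free values in
#'   `attr(, "truth")`.
#' @export
gen_chemistry_table <- function(scn, t_years) {
  stopifnot(inherits(scn, "chemistry_scenario"))
  if (t_years <= 0) stop("t_years must be > 0")
  horizons <- names(scn$horizon_decay_rates)
  treatments <- c("control", "fertilized")
  sd <- function(v) {
    if (v %in% names(scn$between_plot_sd)) scn$between_plot_sd[[v]] else 0
  }
  cn_init <- scn$initial_C / scn$initial_N
  # noise-free targets, identical across plots
  grid <- expand.grid(plot = seq_len(scn$n_plots_per_treatment),
                      horizon = horizons, treatment = treatments,
                      stringsAsFactors = FALSE)
  k <- scn$horizon_decay_rates[grid$horizon]
  c_true <- scn$initial_C * exp(-k * t_years)
  d13_true <- mix_delta13c(scn$new_c_fraction, scn$delta13c_c4,
                           scn$delta13c_new)
  cn_final <- cn_init * (1 + scn$cn_increase)
  withr::with_seed(scn$seed, {
    n <- nrow(grid)
    C <- c_true * exp(stats::rnorm(n, 0, sd("C")))
    N <- (C / cn_final) * exp(stats::rnorm(n, 0, sd("N")))
    d13 <- d13_true + stats::rnorm(n, 0, sd("delta13C"))
    pH <- 4.2 + stats::rnorm(n, 0, sd("pH"))
  })
  out <- data.frame(plot = paste0("plot", grid$plot), horizon = grid$horizon,
                    treatment = grid$treatment, C = C, N = N,
                    delta13C = d13, pH = pH, stringsAsFactors = FALSE)
  attr(out, "truth") <- list(scenario = scn, t_years = t_years,
                             c_final_true = stats::setNames(
                               scn$initial_C *
                                 exp(-scn$horizon_decay_rates * t_years),
                               horizons),
                             delta13c_true = d13_true,
                             cn_final_true = cn_final)
  out
}

# delta 13C of a mixture with fraction f_new of new (C3) carbon
mix_delta13c <- function(f_new, d_c4, d_new) {
  (1 - f_new) * d_c4 + f_new * d_new
}

#' Scenario for synthetic OTU sequencing experiments
#'
#' Emulates the sequencing design of the mesh-bag study: each biological
#' sample is sequenced as three technical replicates with uneven read depths,
#' and community composition is dominated by saprotrophs and ectomycorrhizal
#' fungi. Default guild proportions (ECM 0.37, saprotroph 0.57, pathogen
#' 0.02, unknown 0.04) sit inside the ranges the study design anticipates;
#' the depth range matches the reported 13,810-24,843 reads per sample.
#'
#' @param n_otus number of OTUs (>= number of guilds).
#' @param n_samples number of biological samples.
#' @param n_tech_reps technical replicates per biological sample.
#' @param guild_proportions named fractions summing to 1.
#' @param depth_range integer (min, max) reads per replicate column.
#' @param rare_otu_fraction fraction of OTUs engineered to fail the rare-OTU
#'   filter (< 10 total reads, present in a single sample).
#' @param seed integer seed.
#' @return list of class `otu_scenario`.
#' @export
otu_scenario <- function(n_otus = 50, n_samples = 6, n_tech_reps = 3,
                         guild_proportions = c(ECM = 0.37, saprotroph = 0.57,
                                               pathogen = 0.02,
                                               unknown = 0.04),
                         depth_range = c(13810L, 24843L),
                         rare_otu_fraction = 0.1, seed = 1) {
  if (abs(sum(guild_proportions) - 1) > 1e-9) {
    stop("guild_proportions must sum to 1")
  }
  if (n_otus < length(guild_proportions)) {
    stop("need at least one OTU per guild")
  }
  if (depth_range[1] < 1) stop("read depth must be at least 1")
  if (depth_range[1] > depth_range[2]) stop("depth_range must be min <= max")
  if (rare_otu_fraction < 0 || rare_otu_fraction >= 1) {
    stop("rare_otu_fraction must lie in [0, 1)")
  }
  structure(list(n_otus = as.integer(n_otus),
                 n_samples = as.integer(n_samples),
                 n_tech_reps = as.integer(n_tech_reps),
                 guild_proportions = guild_proportions,
                 depth_range = as.integer(depth_range),
                 rare_otu_fraction = rare_otu_fraction,
                 seed = as.integer(seed)),
            class = "otu_scenario")
}

#' Generate a synthetic OTU experiment
#'
#' Per biological sample a composition is drawn (lognormal OTU abundances,
#' floored so no common OTU can fail the rare-OTU filter by chance) and each
#' technical replicate is an independent multinomial draw from it at a
#' uniform random depth — replicates differ only by sampling noise, matching
#' their later averaging. `rare_otu_fraction` of the OTUs are then planted as
#' filter targets: each receives < 10 total reads confined to one biological
#' sample.
#'
#' @param scn an [otu_scenario].
#' @return list with `table` (an [otu_table] with replicate groups and guild
#'   annotations) and `truth` (per-sample intended compositions, the planted
#'   filter-target OTU ids, guild assignment).
#' @export
gen_otu_experiment <- function(scn) {
  stopifnot(inherits(scn, "otu_scenario"))
  withr::with_seed(scn$seed, {
    otus <- sprintf("OTU%03d", seq_len(scn$n_otus))
    guilds <- names(scn$guild_proportions)
    # guild assignment: proportional blocks, at least one OTU per guild
    n_per <- pmax(1L, round(scn$guild_proportions * scn$n_otus))
    guild_of <- stats::setNames(rep(guilds, times = n_per)[seq_len(scn$n_otus)],
                                otus)
    guild_of[is.na(guild_of)] <- guilds[length(guilds)]

    n_rare <- round(scn$rare_otu_fraction * scn$n_otus)
    rare_ids <- if (n_rare > 0) sample(otus, n_rare) else character(0)
    common <- setdiff(otus, rare_ids)

    base <- exp(stats::rnorm(length(common), 0, 1.2))
    samples <- sprintf("S%02d", seq_len(scn$n_samples))
    comp <- sapply(samples, function(s) {
      p <- base * exp(stats::rnorm(length(common), 0, 0.4))
      p <- p / sum(p)
      pmax(p, 0.002) / sum(pmax(p, 0.002))  # floor keeps common OTUs common
    })
    rownames(comp) <- common

    cols <- as.vector(t(outer(samples, seq_len(scn$n_tech_reps),
                              function(s, r) paste0(s, "_rep", r))))
    rep_groups <- stats::setNames(rep(samples, each = scn$n_tech_reps), cols)
    counts <- matrix(0L, nrow = scn$n_otus, ncol = length(cols),
                     dimnames = list(otus, cols))
    for (j in seq_along(cols)) {
      depth <- sample(scn$depth_range[1]:scn$depth_range[2], 1)
      counts[common, j] <- stats::rmultinom(1, depth, comp[, rep_groups[j]])
    }
    # plant filter targets: < 10 total reads, confined to one biological sample
    for (o in rare_ids) {
      s <- sample(samples, 1)
      reps <- names(rep_groups)[rep_groups == s]
      total <- sample(1:9, 1)
      counts[o, reps] <- as.vector(stats::rmultinom(1, total,
                                                    rep(1, length(reps))))
    }
  })
  tab <- otu_table(counts, replicate_groups = rep_groups, guild = guild_of)
  list(table = tab,
       truth = list(compositions = comp, filter_targets = sort(rare_ids),
                    guild = guild_of, scenario = scn))
}
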