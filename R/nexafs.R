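#' NEXAFS component models and spectral deconvolution
#'
#' C and N K-edge spectra of soil organic matter are modelled as a sum of
#' pre-edge pi* Gaussians at literature positions, broad sigma-resonance
#' Gaussians above the edge, and a Gaussian-broadened step (scaled error
#' function) for the edge jump. Fitted pi* peak areas, expressed relative to
#' the sum of all pi* areas, index the abundance of each carbon or nitrogen
#' bonding class.
#'
#' @name nexafs
NULL

# FWHM of a Gaussian -> standard deviation
fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

# unit-height Gaussian and unit-height broadened step
gauss_peak <- function(x, center, fwhm) {
  exp(-(x - center)^2 / (2 * fwhm_to_sigma(fwhm)^2))
}
edge_step_curve <- function(x, center, width) {
  0.5 * (1 + erf((x - center) / (width * sqrt(2))))
}

# canonical component tables ------------------------------------------------

PI_FWHM <- 1.2   # eV, fixed width of all pre-edge pi* Gaussians

c1s_components <- function() {
  data.frame(
    label = c("quinone-C", "substituted-aromatic-C", "aromatic-C",
              "phenolic-C", "aliphatic-C", "carboxyl-C", "O-alkyl-C",
              "sigma1", "sigma2", "edge-step"),
    kind = c(rep("gaussian_pi", 7), "gaussian_sigma", "gaussian_sigma",
             "edge_step"),
    center = c(284.3, 285.3, 286.0, 286.6, 287.4, 288.4, 289.3,
               294.3, 298.8, 289.9),
    fwhm = c(rep(PI_FWHM, 7), NA, NA, NA),
    stringsAsFactors = FALSE
  )
}

n1s_components <- function() {
  data.frame(
    label = c("heterocyclic-N", "nitrile-aromatic-N", "amidic-N",
              "pyrrolic-N", "nitrate-N", "sigma1", "sigma2", "edge-step"),
    kind = c(rep("gaussian_pi", 5), "gaussian_sigma", "gaussian_sigma",
             "edge_step"),
    center = c(398.8, 400, 401.4, 402.7, 405.4, 406, 412.1, 403.2),
    fwhm = c(rep(PI_FWHM, 5), NA, NA, NA),
    stringsAsFactors = FALSE
  )
}

#' Default component model for an absorption edge
#'
#' The C1s model has 7 pi* Gaussians (quinone-C 284.3, substituted
#' aromatic-C 285.3, aromatic-C 286.0, phenolic-C 286.6, aliphatic-C 287.4,
#' carboxyl-C 288.4, O-alkyl-C 289.3 eV), two sigma resonances (294.3,
#' 298.8 eV) and an edge step at 289.9 eV. The N1s model has 5 pi* Gaussians
#' (heterocyclic-N 398.8, nitrile/aromatic-N 400, amidic-N 401.4, pyrrolic-N
#' 402.7, nitrate/ammonium-N 405.4 eV), sigma resonances at 406 and 412.1 eV
#' and a step at 403.2 eV. pi* widths are fixed at 1.2 eV FWHM; sigma widths
#' are free. Classification as pi* or sigma follows the declared kind, not
#' position relative to the step (nitrate-N at 405.4 eV sits above the
#' 403.2 eV step yet counts as a pi* transition).
#'
#' @param edge `"C1s"` or `"N1s"`.
#' @param center_policy `"fixed"` pins pi* centers at the canonical values;
#'   `"bounded"` lets them float within +/- 0.2 eV.
#' @return data frame with columns `label`, `kind`, `center`, `fwhm`,
#'   `center_policy`; class `component_model`.
#' @export
default_component_model <- function(edge = c("C1s", "N1s"),
                                    center_policy = c("fixed", "bounded")) {
  edge <- match.arg(edge)
  center_policy <- match.arg(center_policy)
  comp <- if (edge == "C1s") c1s_components() else n1s_components()
  comp$center_policy <- ifelse(comp$kind == "gaussian_pi", center_policy,
                               "fixed")
  attr(comp, "edge") <- edge
  class(comp) <- c("component_model", "data.frame")
  comp
}

#' @export
print.component_model <- function(x, ...) {
  cat(sprintf("<component_model> %s edge: %d components (%d pi*)\n",
              attr(x, "edge"), nrow(x), sum(x$kind == "gaussian_pi")))
  print.data.frame(x)
  invisible(x)
}

# recorded ranges and default normalization windows per edge
edge_ranges <- function(edge) {
  switch(edge,
    C1s = list(range = c(275, 320), pre = c(275, 282), post = c(310, 320)),
    N1s = list(range = c(390, 430), pre = c(390, 396), post = c(420, 430)),
    stop(sprintf("unknown edge '%s'", edge))
  )
}

#' Normalize a NEXAFS spectrum to unit edge jump
#'
#' Subtracts the mean intensity over the pre-edge region and divides by the
#' jump (post-edge mean minus pre-edge mean), so the pre-edge baseline is 0
#' and the edge jump is 1. A purely linear transform; idempotent.
#'
#' @param s a [spectrum] on an energy axis.
#' @param pre_region,post_region length-2 numeric intervals (eV). Defaults
#'   come from `s$meta$edge` when set: C1s pre 275-282 / post 310-320 eV,
#'   N1s pre 390-396 / post 420-430 eV.
#' @return the normalized [spectrum]; the applied offset and scale are stored
#'   in `meta$normalization`.
#' @export
normalize_edge_jump <- function(s, pre_region = NULL, post_region = NULL) {
  stopifnot(is_spectrum(s))
  if (is.null(pre_region) || is.null(post_region)) {
    edge <- s$meta$edge
    if (is.null(edge)) {
      stop("no pre/post regions given and spectrum meta carries no edge")
    }
    win <- edge_ranges(edge)
    if (is.null(pre_region)) pre_region <- win$pre
    if (is.null(post_region)) post_region <- win$post
  }
  in_pre <- s$axis >= pre_region[1] & s$axis <= pre_region[2]
  in_post <- s$axis >= post_region[1] & s$axis <= post_region[2]
  if (sum(in_pre) < 5 || sum(in_post) < 5) {
    stop("pre- and post-edge regions must each contain at least 5 grid points")
  }
  pre_mean <- mean(s$intensity[in_pre])
  post_mean <- mean(s$intensity[in_post])
  jump <- post_mean - pre_mean
  if (jump <= 0) {
    stop("non-absorbing or inverted spectrum: post-edge mean <= pre-edge mean")
  }
  out <- s
  out$intensity <- (s$intensity - pre_mean) / jump
  out$meta$normalization <- list(pre_region = pre_region,
                                 post_region = post_region,
                                 offset = pre_mean, jump = jump)
  out
}

# model evaluation ----------------------------------------------------------

# p: named parameter vector. Gaussians: height_<label> (+ fwhm_<label> for
# sigma components, + center_<label> when the center policy is bounded);
# step: step_height, step_width.
eval_component_model <- function(p, model, x) {
  y <- numeric(length(x))
  for (i in seq_len(nrow(model))) {
    lab <- model$label[i]
    if (model$kind[i] == "edge_step") {
      y <- y + p[["step_height"]] *
        edge_step_curve(x, model$center[i], p[["step_width"]])
    } else {
      fw <- if (model$kind[i] == "gaussian_pi") model$fwhm[i]
            else p[[paste0("fwhm_", lab)]]
      ce <- if (!is.null(p[[paste0("center_", lab)]]))
              p[[paste0("center_", lab)]] else model$center[i]
      y <- y + p[[paste0("height_", lab)]] * gauss_peak(x, ce, fw)
    }
  }
  y
}

fit_start_and_bounds <- function(model, step_height) {
  p <- c(step_height = step_height, step_width = 0.8)
  lo <- c(step_height = 0, step_width = 0.2)
  hi <- c(step_height = Inf, step_width = 2)
  for (i in which(model$kind != "edge_step")) {
    lab <- model$label[i]
    p[paste0("height_", lab)] <- 0.1
    lo[paste0("height_", lab)] <- 0
    hi[paste0("height_", lab)] <- Inf
    if (model$kind[i] == "gaussian_sigma") {
      p[paste0("fwhm_", lab)] <- 4
      lo[paste0("fwhm_", lab)] <- 1
      hi[paste0("fwhm_", lab)] <- 12
    }
    if (model$kind[i] == "gaussian_pi" && model$center_policy[i] == "bounded") {
      p[paste0("center_", lab)] <- model$center[i]
      lo[paste0("center_", lab)] <- model$center[i] - 0.2
      hi[paste0("center_", lab)] <- model$center[i] + 0.2
    }
  }
  list(start = p, lower = lo, upper = hi)
}

#' Fit a component model to a normalized spectrum
#'
#' Two-stage bounded least squares mirroring the usual deconvolution
#' protocol: the error-function edge jump is fitted first on the regions
#' clear of any Gaussian component (all Gaussian amplitudes suppressed), then
#' all amplitudes are released and the full model refined by
#' Levenberg-Marquardt with box constraints ([minpack.lm::nls.lm]):
#' amplitudes >= 0, pi* widths fixed at 1.2 eV FWHM, sigma widths free in
#' [1, 12] eV, step width in [0.2, 2] eV. Up to 3 restarts from jittered
#' amplitudes are attempted when the optimizer reports a poor exit;
#' non-convergence is flagged in the result, never silent.
#'
#' @param s a normalized [spectrum] (see [normalize_edge_jump]).
#' @param model a `component_model`, e.g. [default_component_model()].
#' @param restarts maximum jittered restarts after a poor exit.
#' @return `nexafs_fit` object: `areas` (named, intensity x eV; Gaussian
#'   components only), `params`, `rss`, `relative_pi` (see
#'   [relative_pi_abundances]), `converged`, `model`.
#' @export
fit_spectrum <- function(s, model, restarts = 3) {
  stopifnot(is_spectrum(s), inherits(model, "component_model"))
  x <- s$axis
  y <- s$intensity
  if (all(abs(y) < .Machine$double.eps)) {
    stop("all-zero spectrum cannot be fitted")
  }
  gcent <- model$center[model$kind != "edge_step"]
  if (min(gcent) < min(x) || max(gcent) > max(x)) {
    stop("component model extends outside the spectrum axis range")
  }

  # stage 1: step alone on points far from every Gaussian center
  step_center <- model$center[model$kind == "edge_step"]
  clear <- rowSums(outer(x, gcent, function(a, b) abs(a - b) < 3)) == 0
  if (sum(clear) < 10) clear <- rep(TRUE, length(x))
  st1 <- minpack.lm::nls.lm(
    par = c(step_height = max(mean(y[x > max(gcent)]), 0.1), step_width = 0.8),
    lower = c(0, 0.2), upper = c(Inf, 2),
    fn = function(p) {
      y[clear] - p[1] * edge_step_curve(x[clear], step_center, p[2])
    },
    control = minpack.lm::nls.lm.control(ftol = 1e-10, maxiter = 200)
  )

  # stage 2: release all amplitudes
  sb <- fit_start_and_bounds(model, step_height = stats::coef(st1)[["step_height"]])
  sb$start["step_width"] <- stats::coef(st1)[["step_width"]]
  resid_fn <- function(p) {
    y - eval_component_model(as.list(p), model, x)
  }
  run_fit <- function(start) {
    minpack.lm::nls.lm(par = start, lower = sb$lower, upper = sb$upper,
                       fn = resid_fn,
                       control = minpack.lm::nls.lm.control(
                         ftol = 1e-10, ptol = 1e-10, maxiter = 500))
  }
  fit <- run_fit(sb$start)
  ok_codes <- 1:4   # nls.lm info codes indicating a converged solution
  tries <- 0
  best <- fit
  while (!(fit$info %in% ok_codes) && tries < restarts) {
    tries <- tries + 1
    jit <- sb$start
    amp <- grep("^height_", names(jit))
    jit[amp] <- jit[amp] * stats::runif(length(amp), 0.2, 5)
    fit <- run_fit(jit)
    if (fit$deviance < best$deviance) best <- fit
  }
  if (fit$info %in% ok_codes) best <- fit
  converged <- best$info %in% ok_codes

  p <- as.list(stats::coef(best))
  areas <- numeric(0)
  for (i in which(model$kind != "edge_step")) {
    lab <- model$label[i]
    fw <- if (model$kind[i] == "gaussian_pi") model$fwhm[i]
          else p[[paste0("fwhm_", lab)]]
    areas[lab] <- p[[paste0("height_", lab)]] * fwhm_to_sigma(fw) * sqrt(2 * pi)
  }
  res <- structure(list(areas = areas, params = unlist(p),
                        rss = best$deviance, converged = converged,
                        restarts_used = tries, model = model),
                   class = "nexafs_fit")
  res$relative_pi <- tryCatch(relative_pi_abundances(res), error = function(e) NULL)
  res
}

#' @export
print.nexafs_fit <- function(x, ...) {
  cat(sprintf("<nexafs_fit> %s, rss = %.3g, converged: %s\n",
              attr(x$model, "edge"), x$rss, x$converged))
  if (!is.null(x$relative_pi)) {
    cat("relative pi* abundances:\n")
    print(round(x$relative_pi, 4))
  }
  invisible(x)
}

#' Relative pi* abundances from a fit
#'
#' Each pi* component's fitted area divided by the sum of all pi* areas;
#' sigma resonances and the edge step are excluded from the denominator.
#'
#' @param fit a `nexafs_fit` from [fit_spectrum].
#' @return named numeric vector of fractions summing to 1.
#' @export
relative_pi_abundances <- function(fit) {
  stopifnot(inherits(fit, "nexafs_fit"))
  pi_labels <- fit$model$label[fit$model$kind == "gaussian_pi"]
  a <- fit$areas[pi_labels]
  if (sum(a) <= 0) {
    stop("no pi* signal: all pi* component areas are zero")
  }
  a / sum(a)
}
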