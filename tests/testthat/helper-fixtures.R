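# shared fixture builders; all synthetic, generated in code

# small OTU table: counts given as OTU x sample matrix
toy_otu <- function(counts, reps = NULL, guild = NULL) {
  if (is.null(rownames(counts))) {
    rownames(counts) <- paste0("OTU", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- paste0("S", seq_len(ncol(counts)))
  }
  otu_table(counts, replicate_groups = reps, guild = guild)
}

# noise-free two-Gaussian toy spectrum over a known step, for fit oracles
toy_two_gauss <- function(a1 = 0.8, a2 = 0.4) {
  x <- seq(275, 320, by = 0.1)
  model <- default_component_model("C1s")
  step <- edge_step_height_curve(x)
  y <- step +
    a1 * exp(-(x - 285.3)^2 / (2 * (1.2 / (2 * sqrt(2 * log(2))))^2)) +
    a2 * exp(-(x - 288.4)^2 / (2 * (1.2 / (2 * sqrt(2 * log(2))))^2))
  list(spectrum = spectrum(x, y, "energy_eV", meta = list(edge = "C1s")),
       x = x, step = step, a = c(a1, a2), model = model)
}

# unit step at the canonical C1s position with 0.8 eV width:
# 0.5 * (1 + erf((x - c) / (w * sqrt(2)))) == pnorm((x - c) / w)
edge_step_height_curve <- function(x) {
  pnorm((x - 289.9) / 0.8)
}

# independent trapezoidal integral over the grid points inside [lo, hi]
spectrum_area_for_test <- function(s, lo, hi) {
  idx <- s$axis >= lo & s$axis <= hi
  x <- s$axis[idx]
  y <- s$intensity[idx]
  sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
}

# balanced null community: iid multinomial samples from a shared composition
null_community <- function(n_samples = 12, n_otus = 30, depth = 2000) {
  counts <- sapply(seq_len(n_samples),
                   function(j) rmultinom(1, depth, rep(1 / n_otus, n_otus)))
  rownames(counts) <- paste0("O", seq_len(n_otus))
  colnames(counts) <- paste0("S", seq_len(n_samples))
  counts
}
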