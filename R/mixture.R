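#' Simulate the three pure-state contact curves
#'
#' Simulates a homopolymer in each of the model's three stable regimes —
#' binder-free coil, strongly bound disordered globule, and high
#' concentration / high affinity ordered globule — checks each run lands in
#' the intended phase, and returns the equilibrium P(s) of each regime on a
#' common separation grid. These are the basis curves of the pure-state
#' mixture decomposition of an observed P(s).
#'
#' Results are cached to `cache_dir` keyed by the generating parameters, so
#' repeated fits do not re-simulate.
#'
#' @param n_beads homopolymer length (>= 32 recommended).
#' @param seeds integer seeds, one replica per seed and regime.
#' @param threshold contact capture radius used for P(s), in bead diameters
#'   (the Hi-C-like default of 3.5 reproduces the established coil decay
#'   exponent of about -2.1 and keeps the three regimes' curve shapes well
#'   separated).
#' @param steps_scale multiplies the per-regime default step counts; raise
#'   it if the phase check reports non-equilibrated runs.
#' @param cache_dir directory for cached curves, or `NULL` to disable.
#' @param check_phase verify each regime's phase label; an error names the
#'   offending regime.
#' @return An object of class `pure_state_curves`: common grid `s` and a
#'   `curves` list with entries `coil`, `disordered_globule`,
#'   `ordered_globule`.
#' @export
estimate_pure_curves <- function(n_beads, seeds = 1:5, threshold = 3.5,
                                 steps_scale = 1, cache_dir = NULL,
                                 check_phase = TRUE) {
  key <- sprintf("pure_N%d_seeds%s_th%g_sc%g", n_beads,
                 paste(seeds, collapse = "-"), threshold, steps_scale)
  if (!is.null(cache_dir)) {
    cache_file <- file.path(cache_dir, paste0(key, ".tsv"))
    if (file.exists(cache_file)) {
      tab <- utils::read.table(cache_file, header = TRUE, sep = "\t")
      return(structure(list(s = tab$s, n_beads = n_beads,
                            curves = list(coil = tab$coil,
                                          disordered_globule = tab$disordered_globule,
                                          ordered_globule = tab$ordered_globule),
                            provenance = list(key = key, cached = TRUE)),
                       class = "pure_state_curves"))
    }
  }
  regimes <- pure_state_regimes(n_beads, steps_scale)
  homo <- make_block_profile(n_beads, list(c(0, n_beads, 0)))
  curves <- list()
  for (nm in names(regimes)) {
    rg <- regimes[[nm]]
    ens <- run_ensemble(homo, rg$binders, rg$params, length(seeds), seeds,
                        start = rg$start)
    if (check_phase) {
      ph <- classify_phase(ens, rg$binders)
      if (ph$label != nm)
        stop(sprintf("regime '%s' classified as '%s' (nu = %.3f); adjust steps_scale or regime parameters",
                     nm, ph$label, ph$diagnostics$nu_estimate))
    }
    cm <- contact_map_from_ensemble(ens, threshold = threshold,
                                    discard_fraction = 0.5)
    curves[[nm]] <- contact_curve(cm)$p
  }
  out <- structure(list(s = seq_len(n_beads - 1L), n_beads = n_beads,
                        curves = curves,
                        provenance = list(key = key, cached = FALSE,
                                          threshold = threshold,
                                          seeds = seeds)),
                   class = "pure_state_curves")
  if (!is.null(cache_dir)) {
    dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
    tab <- data.frame(s = out$s, coil = curves$coil,
                      disordered_globule = curves$disordered_globule,
                      ordered_globule = curves$ordered_globule)
    utils::write.table(tab, file.path(cache_dir, paste0(key, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  out
}

# per-regime homopolymer settings. The coil equilibrates from a grown SAW;
# the globule regimes sample from a pre-collapsed start (liquid-like local
# rearrangement is fast, while a coil-to-globule quench coarsens slowly).
pure_state_regimes <- function(n_beads, steps_scale = 1) {
  n <- n_beads
  coil_steps <- round(steps_scale * max(20000, 1200 * n))
  glob_steps <- round(steps_scale * max(40000, 600 * n))
  list(
    coil = list(
      binders = NULL, start = "saw",
      params = sim_params(n_steps = coil_steps, save_stride = 250)),
    disordered_globule = list(
      binders = binder_spec(counts = n, affinities = 4), start = "compact",
      params = sim_params(n_steps = glob_steps, timestep = 0.008,
                          save_stride = 400)),
    ordered_globule = list(
      binders = binder_spec(counts = 2 * n, affinities = 9), start = "compact",
      params = sim_params(n_steps = round(glob_steps * 0.6), timestep = 0.004,
                          save_stride = 400))
  )
}

#' @export
print.pure_state_curves <- function(x, ...) {
  cat(sprintf("pure_state_curves: N = %d, s = 1..%d (%s)\n", x$n_beads,
              max(x$s), if (isTRUE(x$provenance$cached)) "cached" else "simulated"))
  invisible(x)
}

# log-log interpolation of a pure curve onto fractional separations x = s/N
interp_pure <- function(s_grid, p, n_grid, x_target) {
  ok <- p > 0
  xg <- log(s_grid[ok] / n_grid)
  yg <- log(p[ok])
  out <- approx(xg, yg, xout = log(x_target), rule = 1)$y
  exp(out)
}

#' Fit an observed P(s) as a mixture of pure states
#'
#' Decomposes an observed contact-probability decay as a non-negative linear
#' combination of the three pure-state curves. The overall amplitude is a
#' free positive scale (raw Hi-C is count-valued), so only the state
#' fractions matter; separations are rescaled to fractional chain length
#' `s / N` before matching curves simulated at a different N. Weighted least
#' squares uses weights uniform in log s, so every decade of genomic
#' separation contributes equally.
#'
#' Observed and basis curves are averaged over the same geometrically
#' spaced separation bins before fitting (the standard log-binning of P(s)
#' curves), which equalizes the leverage of each decade and suppresses the
#' entrywise noise of raw curves.
#'
#' @param observed a `contact_curve`.
#' @param pure a [estimate_pure_curves] result.
#' @param fit_range `c(s_min, s_max)` window of observed separations.
#' @param bin_factor geometric spacing of the separation bins (1 disables
#'   binning).
#' @return An object of class `mixture_fit`: `fractions` (coil,
#'   disordered_globule, ordered_globule; non-negative, summing to 1),
#'   `scale`, `chi_squared` (sum of (obs - model)^2 / model over the fit
#'   range), and a `residuals` data.frame.
#' @export
fit_mixture <- function(observed, pure, fit_range = NULL, bin_factor = 1.3) {
  if (is.null(fit_range)) fit_range <- c(2, observed$n_beads - 1)
  keep <- observed$s >= fit_range[1] & observed$s <= fit_range[2] &
    observed$p > 0
  s <- observed$s[keep]
  y <- observed$p[keep]
  x <- s / observed$n_beads
  basis <- vapply(pure$curves, function(p)
    interp_pure(pure$s, p, pure$n_beads, x), numeric(length(x)))
  usable <- stats::complete.cases(basis) & is.finite(y)
  if (sum(usable) < 4)
    stop("fewer than 4 usable separations overlap the pure curves; widen fit_range")
  s <- s[usable]; y <- y[usable]; basis <- basis[usable, , drop = FALSE]
  wbin <- rep(1, length(s))
  if (bin_factor > 1) {
    bin <- floor(log(s / s[1]) / log(bin_factor))
    wbin <- as.numeric(table(bin))     # raw separations averaged per bin
    s <- as.numeric(tapply(s, bin, mean))
    y <- as.numeric(tapply(y, bin, mean))
    basis <- apply(basis, 2, function(col) as.numeric(tapply(col, bin, mean)))
    if (length(s) < 4)
      stop("fewer than 4 separation bins in fit_range; reduce bin_factor")
  }
  # Non-negative least squares gives the starting point; the final fit
  # minimizes residuals of log P(s), matching the multiplicative
  # (scale-free) error structure of contact data.
  fit <- pracma::lsqnonneg(basis / sqrt(length(s)), y / sqrt(length(s)))
  wts <- fit$x
  if (sum(wts) <= 0) stop("degenerate fit: all mixture weights zero")
  obj <- function(theta) {
    model <- as.numeric(basis %*% exp(theta))
    sum(wbin * (log(y) - log(model))^2)   # inverse-variance bin weights
  }
  opt <- stats::optim(log(pmax(wts, 1e-8 * sum(wts))), obj,
                      method = "BFGS", control = list(maxit = 500))
  wts <- exp(opt$par)
  fractions <- setNames(wts / sum(wts), names(pure$curves))
  model <- as.numeric(basis %*% wts)
  chi2 <- sum((y - model)^2 / model)
  structure(list(fractions = fractions, scale = sum(wts),
                 chi_squared = chi2,
                 residuals = data.frame(s = s, observed = y, fitted = model),
                 fit_range = fit_range),
            class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("mixture_fit: coil %.3f | disordered %.3f | ordered %.3f (chi2 = %.3g)\n",
              x$fractions[1], x$fractions[2], x$fractions[3], x$chi_squared))
  invisible(x)
}
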