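#' Polymer chain model for a flexible inter-domain linker
#'
#' Desk-scale stand-in for an all-atom simulation of the cleavable linker:
#' the peptide backbone is coarse-grained to virtual bonds between
#' consecutive C-alpha atoms (0.38 nm each), and the end-to-end distance is
#' sampled from either a freely jointed chain (FJC) or a discretised
#' worm-like (Kratky-Porod) chain. Fixed offsets can be added at each
#' terminus, along the end-to-end direction, to account for the donor ion and
#' acceptor chromophore sitting beyond the linker termini.
#'
#' @param n_segments Number of virtual bonds (default 19, one per residue of
#'   a 19-residue linker).
#' @param bond_length Virtual bond length in nm (default 0.38, the C-alpha
#'   to C-alpha distance of an extended peptide unit).
#' @param model `"freely_jointed"` (default) or `"worm_like"`.
#' @param persistence_length Persistence length in nm; required for
#'   `"worm_like"`.
#' @param end_offsets Length-2 nonnegative offsets in nm added at the two
#'   termini (default `c(0, 0)`).
#' @return Object of class `chain_model`.
#' @export
chain_model <- function(n_segments = 19, bond_length = 0.38,
                        model = c("freely_jointed", "worm_like"),
                        persistence_length = NULL,
                        end_offsets = c(0, 0)) {
  model <- match.arg(model)
  if (n_segments < 1) stop("n_segments must be >= 1")
  if (bond_length <= 0) stop("bond_length must be positive")
  if (model == "worm_like") {
    if (is.null(persistence_length) || persistence_length <= 0)
      stop("worm_like model requires a positive persistence_length")
  }
  if (length(end_offsets) != 2L || any(end_offsets < 0))
    stop("end_offsets must be two nonnegative numbers")
  structure(list(n_segments = as.integer(n_segments),
                 bond_length = bond_length, model = model,
                 persistence_length = persistence_length,
                 end_offsets = end_offsets),
            class = "chain_model")
}

# n random unit vectors as an n x 3 matrix
runif_sphere <- function(n) {
  m <- matrix(stats::rnorm(3 * n), ncol = 3)
  m / sqrt(rowSums(m^2))
}

#' Sample linker end-to-end distances from a chain model
#'
#' FJC: each conformation is the sum of `n_segments` independent uniformly
#' oriented bond vectors of length `bond_length` (so the mean squared
#' end-to-end distance is exactly `n_segments * bond_length^2`). Worm-like:
#' successive bond directions are correlated with
#' `<cos(theta)> = exp(-bond_length / persistence_length)`, each bend drawn
#' from the equilibrium Kratky-Porod angular density. End offsets are added
#' along the end-to-end direction. Reproducible for a fixed seed.
#'
#' @param chain A [chain_model()].
#' @param n_samples Number of conformations to draw (>= 1).
#' @param seed Integer seed (required; the sampler is seeded locally and does
#'   not disturb the caller's RNG state).
#' @return A [distance_ensemble()] of `n_samples` distances (nm).
#' @examples
#' ens <- sample_linker_distances(chain_model(), 1000, seed = 1)
#' mean(ens$distances^2)  # ~ 19 * 0.38^2
#' @export
sample_linker_distances <- function(chain, n_samples, seed) {
  if (!inherits(chain, "chain_model")) stop("chain must be a chain_model")
  if (n_samples < 1) stop("n_samples must be >= 1")
  if (missing(seed) || !is.numeric(seed)) stop("an integer seed is required")
  r <- with_local_seed(seed, {
    n <- chain$n_segments; b <- chain$bond_length
    if (chain$model == "freely_jointed") {
      ends <- matrix(0, n_samples, 3)
      for (i in seq_len(n)) ends <- ends + runif_sphere(n_samples)
      sqrt(rowSums((b * ends)^2))
    } else {
      k <- chain$persistence_length / b  # stiffness of each joint
      ends <- t(vapply(seq_len(n_samples), function(s) {
        dir <- runif_sphere(1)[1, ]
        pos <- dir
        if (n > 1) for (j in 2:n) {
          dir <- propagate_wlc(dir, k)
          pos <- pos + dir
        }
        pos
      }, numeric(3)))
      sqrt(rowSums((b * ends)^2))
    }
  })
  distance_ensemble(r + sum(chain$end_offsets))
}

# One Kratky-Porod step: rotate `dir` by a bend angle drawn from the density
# p(cos t) ~ exp(k cos t) on [-1, 1] (von Mises-Fisher), uniform azimuth.
propagate_wlc <- function(dir, k) {
  u <- stats::runif(1)
  ct <- if (k < 1e-8) 2 * u - 1 else 1 + log(u + (1 - u) * exp(-2 * k)) / k
  st <- sqrt(max(0, 1 - ct^2))
  phi <- stats::runif(1, 0, 2 * pi)
  # orthonormal frame around dir
  ref <- if (abs(dir[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * dir) * dir
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(dir[2] * e1[3] - dir[3] * e1[2],
          dir[3] * e1[1] - dir[1] * e1[3],
          dir[1] * e1[2] - dir[2] * e1[1])
  ct * dir + st * (cos(phi) * e1 + sin(phi) * e2)
}

# Run expr under a local RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Gaussian band/line catalogue for the synthetic spectra. Amplitude units
# depend on kind (extinction: M^-1 cm^-1; absorbance: OD; emission: a.u.).
.synth_bands <- list(
  tb_emission = data.frame(
    center = c(490, 545, 585, 620),
    sigma = c(4, 4, 4, 4),
    amplitude = c(0.55, 1.00, 0.35, 0.15)),
  rfp_extinction = data.frame(center = 555, sigma = 18, amplitude = 1e5),
  rfp_absorbance = data.frame(center = 555, sigma = 18, amplitude = 0.30),
  rfp_emission = data.frame(center = 584, sigma = 16, amplitude = 1.0))

.synth_kind <- c(tb_emission = "emission", rfp_extinction = "extinction",
                 rfp_absorbance = "absorbance", rfp_emission = "emission")

#' Synthetic sensor spectra
#'
#' Analytic Gaussian emulations of the sensor's spectral components: narrow
#' Tb3+ emission lines (490/545/585/620 nm), the acceptor protein's
#' absorption/extinction band (555 nm) and its emission band (584 nm).
#' The band parameters are recorded in attribute `bands` so every overlap
#' integral over these spectra has a closed form for cross-checking.
#'
#' @param kind One of `"tb_emission"`, `"rfp_extinction"`,
#'   `"rfp_absorbance"`, `"rfp_emission"`.
#' @param wavelengths Wavelength grid in nm (default `seq(400, 750, by = 1)`).
#' @param peak Optional scalar rescaling the catalogue amplitudes so the
#'   tallest band has this peak value.
#' @return A [spectrum()] with attribute `bands` (data frame `center`,
#'   `sigma`, `amplitude`).
#' @export
synth_spectra <- function(kind, wavelengths = seq(400, 750, by = 1),
                          peak = NULL) {
  if (!kind %in% names(.synth_bands))
    stop("unknown synthetic spectrum kind: ", kind)
  bands <- .synth_bands[[kind]]
  if (!is.null(peak)) {
    if (peak <= 0) stop("peak must be positive")
    bands$amplitude <- bands$amplitude * peak / max(bands$amplitude)
  }
  v <- gaussian_mixture(wavelengths, bands)
  out <- spectrum(wavelengths, v, kind = .synth_kind[[kind]])
  attr(out, "bands") <- bands
  out
}

gaussian_mixture <- function(x, bands) {
  v <- numeric(length(x))
  for (i in seq_len(nrow(bands)))
    v <- v + bands$amplitude[i] *
      exp(-(x - bands$center[i])^2 / (2 * bands$sigma[i]^2))
  v
}

#' Design of a synthetic saturation-binding titration
#'
#' @param concentrations Increasing positive Tb3+ concentrations, uM.
#'   Default: a 12-point grid spanning 1-50 uM.
#' @param true_Kd Generating dissociation constant, uM (default 17).
#' @param true_Imax Generating plateau intensity, a.u. (default 95).
#' @param noise_sd Gaussian noise standard deviation, a.u. (default 0).
#' @param seed Integer seed for the noise draws.
#' @return Object of class `titration_design`.
#' @export
titration_design <- function(concentrations = c(1, 2.5, 5, 7.5, 10, 15, 20,
                                                25, 30, 35, 40, 50),
                             true_Kd = 17, true_Imax = 95,
                             noise_sd = 0, seed = NULL) {
  if (any(concentrations <= 0) || is.unsorted(concentrations, strictly = TRUE))
    stop("concentrations must be positive and strictly increasing")
  if (true_Kd <= 0 || true_Imax <= 0) stop("true_Kd and true_Imax must be positive")
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  if (noise_sd > 0 && is.null(seed)) stop("noisy designs require a seed")
  structure(list(concentrations = concentrations, true_Kd = true_Kd,
                 true_Imax = true_Imax, noise_sd = noise_sd, seed = seed),
            class = "titration_design")
}

#' Simulate a saturation-binding titration
#'
#' Forward model of the one-site binding isotherm,
#' \eqn{I_i = I_{max} c_i / (K_d + c_i) + \epsilon_i}, with seeded Gaussian
#' noise; negative draws are clamped to 0.
#'
#' @param design A [titration_design()].
#' @return A [titration_series()].
#' @export
synth_titration <- function(design) {
  if (!inherits(design, "titration_design")) stop("design must be a titration_design")
  ideal <- with(design, true_Imax * concentrations / (true_Kd + concentrations))
  if (design$noise_sd > 0) {
    noise <- with_local_seed(design$seed,
                             stats::rnorm(length(ideal), 0, design$noise_sd))
    ideal <- pmax(ideal + noise, 0)
  }
  titration_series(design$concentrations, ideal)
}

#' Decay component of a multi-exponential luminescence decay
#'
#' @param amplitude Amplitude at t = 0 (a.u.), >= 0.
#' @param lifetime Decay constant tau in microseconds, > 0 (0.003 us = 3 ns
#'   prompt fluorescence; 190 us = 0.19 ms lanthanide-linked emission).
#' @return Object of class `decay_component`.
#' @export
decay_component <- function(amplitude, lifetime) {
  if (amplitude < 0) stop("amplitude must be nonnegative")
  if (lifetime <= 0) stop("lifetime must be positive")
  structure(list(amplitude = amplitude, lifetime = lifetime),
            class = "decay_component")
}

#' Evaluate a multi-exponential decay on a time grid
#'
#' \eqn{S(t) = \sum_k A_k e^{-t/\tau_k}}, optionally with seeded Poisson
#' counting noise (each grid value replaced by a Poisson draw with that mean).
#'
#' @param components A `decay_component` or list of them.
#' @param t_grid Nondecreasing times >= 0, microseconds.
#' @param poisson_noise If `TRUE`, apply Poisson noise (requires `seed`).
#' @param seed Integer seed for the noise.
#' @return Data frame with columns `time` (us) and `signal` (a.u.).
#' @export
synth_decay <- function(components, t_grid, poisson_noise = FALSE, seed = NULL) {
  components <- as_component_list(components)
  if (length(t_grid) == 0L || any(t_grid < 0) || is.unsorted(t_grid))
    stop("t_grid must be nondecreasing and nonnegative")
  s <- numeric(length(t_grid))
  for (cp in components) s <- s + cp$amplitude * exp(-t_grid / cp$lifetime)
  if (poisson_noise) {
    if (is.null(seed)) stop("poisson_noise requires a seed")
    s <- with_local_seed(seed, stats::rpois(length(s), s))
  }
  data.frame(time = t_grid, signal = s)
}

as_component_list <- function(components) {
  if (inherits(components, "decay_component")) components <- list(components)
  if (length(components) == 0L) stop("at least one decay component required")
  for (cp in components)
    if (!inherits(cp, "decay_component"))
      stop("components must be decay_component objects")
  components
}

#' Closed-form overlap integral for Gaussian synthetic spectra
#'
#' Analytic oracle for [overlap_integral()] on spectra built by
#' [synth_spectra()]: for Gaussian donor bands \eqn{F_j} and acceptor bands
#' \eqn{\varepsilon_k}, each product integral
#' \eqn{\int F_j \varepsilon_k \lambda^4 d\lambda} is the Gaussian-product
#' integral times the 4th-moment polynomial of the product Gaussian,
#' evaluated exactly. The donor is area-normalised analytically.
#'
#' @param donor_bands,acceptor_bands Data frames with columns `center`,
#'   `sigma`, `amplitude` (e.g. `attr(synth_spectra(kind), "bands")`).
#' @return Overlap integral J in M^-1 cm^-1 nm^4 (acceptor amplitudes in
#'   M^-1 cm^-1).
#' @export
gaussian_overlap_closed_form <- function(donor_bands, acceptor_bands) {
  donor_area <- sum(donor_bands$amplitude * donor_bands$sigma * sqrt(2 * pi))
  total <- 0
  for (j in seq_len(nrow(donor_bands))) {
    for (k in seq_len(nrow(acceptor_bands))) {
      m1 <- donor_bands$center[j]; s1 <- donor_bands$sigma[j]
      m2 <- acceptor_bands$center[k]; s2 <- acceptor_bands$sigma[k]
      a <- donor_bands$amplitude[j] * acceptor_bands$amplitude[k]
      s2p <- 1 / (1 / s1^2 + 1 / s2^2)            # product variance
      mp <- s2p * (m1 / s1^2 + m2 / s2^2)          # product mean
      pref <- a * exp(-(m1 - m2)^2 / (2 * (s1^2 + s2^2))) *
        sqrt(2 * pi * s2p)
      # E[x^4] of N(mp, s2p): mp^4 + 6 mp^2 s2p + 3 s2p^2
      total <- total + pref * (mp^4 + 6 * mp^2 * s2p + 3 * s2p^2)
    }
  }
  total / donor_area
}
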