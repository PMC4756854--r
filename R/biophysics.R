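# Exact statistical mechanics of nucleosomes as hard rods on a lattice.
#
# A nucleosome is a rod covering `a` bp (default 147). Chromosomes are
# finite lattices with hard-wall boundaries. The grand-canonical ensemble is
# parameterized by a per-start formation energy u(s) in units of kT and a
# dimensionless chemical potential beta*mu; the statistical weight of a rod
# at start s is exp(beta*mu - u(s)). Lower u means more favorable formation.
# All external coordinates are 0-based: valid starts are s = 0..L-a, and the
# dyad of a rod at start s sits at s + (a-1)/2.

#' Construct an energy landscape
#'
#' @param u Named list of numeric vectors, one per chromosome, giving the
#'   nucleosome formation energy (kT) for every valid start position
#'   (vector length must be chromosome length - a + 1).
#' @param a Nucleosome footprint in bp (default 147).
#' @param beta_mu Dimensionless chemical potential.
#' @param chrom_sizes Optional named chromosome lengths; inferred from the
#'   vector lengths when omitted.
#' @return An \code{energy_landscape} object.
#' @export
energy_landscape <- function(u, a = 147L, beta_mu = 0,
                             chrom_sizes = NULL) {
  if (a < 1) stop("footprint a must be >= 1")
  if (is.null(names(u)) || any(!nzchar(names(u))))
    stop("u must be a named list (one vector per chromosome)")
  if (is.null(chrom_sizes))
    chrom_sizes <- vapply(u, length, integer(1)) + a - 1L
  for (ch in names(u)) {
    if (length(u[[ch]]) != chrom_sizes[[ch]] - a + 1L)
      stop("u[['", ch, "']] must have length L - a + 1")
    if (any(is.infinite(u[[ch]]) & u[[ch]] < 0))
      stop("u must not contain -Inf")
  }
  structure(list(u = lapply(u, as.numeric), a = as.integer(a),
                 beta_mu = beta_mu, chrom_sizes = chrom_sizes),
            class = "energy_landscape")
}

#' @export
print.energy_landscape <- function(x, ...) {
  cat(sprintf(
    "energy_landscape: a=%d, beta_mu=%.4g, %d chromosome(s), %d bp\n",
    x$a, x$beta_mu, length(x$u), sum(x$chrom_sizes)))
  invisible(x)
}

# occupancy O(i) (prob bp i covered) from start probabilities n, footprint a
.occupancy_from_starts <- function(n, a, L) {
  n_ext <- c(n, numeric(L - length(n)))   # invalid starts carry 0
  cs <- c(0, cumsum(n_ext))
  i <- seq_len(L)
  lo <- pmax(i - a + 1L, 1L)
  cs[i + 1L] - cs[lo]
}

#' Construct a start-density object
#'
#' Holds per-chromosome probabilities n(s) that a nucleosome starts at s,
#' together with derived occupancy O(i) (probability that bp i is covered).
#'
#' @param n Named list of start-probability vectors (length L - a + 1).
#' @param a Footprint in bp.
#' @param chrom_sizes Optional named chromosome lengths.
#' @return A \code{start_density} object with elements n, O, a.
#' @export
start_density <- function(n, a = 147L, chrom_sizes = NULL) {
  if (is.null(names(n)) || any(!nzchar(names(n))))
    stop("n must be a named list")
  if (is.null(chrom_sizes))
    chrom_sizes <- vapply(n, length, integer(1)) + a - 1L
  O <- lapply(names(n), function(ch) {
    if (any(n[[ch]] < 0)) stop("start probabilities must be >= 0")
    .occupancy_from_starts(n[[ch]], a, chrom_sizes[[ch]])
  })
  names(O) <- names(n)
  structure(list(n = lapply(n, as.numeric), O = O, a = as.integer(a),
                 chrom_sizes = chrom_sizes),
            class = "start_density")
}

#' @export
print.start_density <- function(x, ...) {
  cat(sprintf("start_density: a=%d, %d chromosome(s), mean coverage %.3f\n",
              x$a, length(x$n), mean_coverage(x)))
  invisible(x)
}

#' Genome-wide mean nucleosome coverage
#'
#' @param density A \code{start_density}.
#' @return Mean of the occupancy O over all bp of all chromosomes.
#' @export
mean_coverage <- function(density) {
  stopifnot(inherits(density, "start_density"))
  tot <- sum(vapply(density$O, sum, numeric(1)))
  tot / sum(density$chrom_sizes)
}

#' Equilibrium nucleosome distribution for an energy landscape
#'
#' Solves the one-dimensional hard-rod (Tonks gas) model exactly by
#' forward/backward partition-function recursions, carried out in the log
#' domain so chromosome-scale lattices cannot overflow.
#'
#' @param landscape An \code{energy_landscape}.
#' @return A \code{start_density}; attribute "logZ" stores the per-chromosome
#'   log partition functions.
#' @export
forward_solve <- function(landscape) {
  stopifnot(inherits(landscape, "energy_landscape"))
  a <- landscape$a
  logZ <- numeric(0)
  n <- lapply(names(landscape$u), function(ch) {
    u <- landscape$u[[ch]]
    L <- landscape$chrom_sizes[[ch]]
    logw <- landscape$beta_mu - u
    logn <- .hardrod_log_density(logw, a, L)
    logZ[[ch]] <<- attr(logn, "logZ")
    exp(as.numeric(logn))
  })
  names(n) <- names(landscape$u)
  out <- start_density(n, a = a, chrom_sizes = landscape$chrom_sizes)
  attr(out, "logZ") <- logZ
  out
}

#' Conditional start probabilities of a start density
#'
#' p(s) = n(s) / (1 - O(s) + n(s)): the probability that a nucleosome starts
#' at s given that s is not covered by a nucleosome starting earlier.
#'
#' @param density A \code{start_density}.
#' @param o_cap Cap applied to O to keep 1 - O bounded away from 0.
#' @return Named list of p vectors (one value per valid start).
#' @export
start_p <- function(density, o_cap = 1 - 1e-6) {
  stopifnot(inherits(density, "start_density"))
  out <- lapply(names(density$n), function(ch) {
    nn <- density$n[[ch]]
    O <- pmin(density$O[[ch]][seq_along(nn)], o_cap)
    nn / (1 - O + nn)
  })
  names(out) <- names(density$n)
  out
}

#' Closed-form inversion: energies from an observed start density
#'
#' Recovers the energy landscape that reproduces a given equilibrium start
#' density under the hard-rod model:
#' \deqn{u(s) = \beta\mu - \ln p(s) + \sum_{j=s}^{s+a-1} \ln(1 - p(j)),}
#' with p(j) = 0 for invalid starts. The defining contract is the roundtrip:
#' \code{forward_solve(invert_density(d, bm))} reproduces d.
#'
#' Regularization: n is floored at 1e-12 of its chromosome mean (floored
#' positions are reported in attribute "floored"), and O is capped at
#' 1 - 1e-6. Densities with O >= 1 anywhere are rejected as unphysical.
#'
#' @param density A \code{start_density}.
#' @param beta_mu Chemical potential assumed for the inversion; changing it
#'   only shifts all energies by a constant (gauge freedom).
#' @return An \code{energy_landscape}.
#' @export
invert_density <- function(density, beta_mu = 0) {
  stopifnot(inherits(density, "start_density"))
  a <- density$a
  floored <- list()
  u <- lapply(names(density$n), function(ch) {
    nn <- density$n[[ch]]
    L <- density$chrom_sizes[[ch]]
    if (any(density$O[[ch]] >= 1))
      stop("occupancy >= 1 on ", ch, ": unphysical density")
    eps <- 1e-12 * mean(nn)
    if (eps <= 0) stop("all-zero density on ", ch)
    fl <- nn < eps
    floored[[ch]] <<- which(fl) - 1L   # 0-based starts
    nn <- pmax(nn, eps)
    O <- pmin(.occupancy_from_starts(nn, a, L)[seq_along(nn)], 1 - 1e-6)
    p <- nn / (1 - O + nn)
    p_ext <- c(p, numeric(L - length(p)))  # p = 0 at invalid starts
    cl <- c(0, cumsum(log1p(-p_ext)))
    s <- seq_along(nn)
    beta_mu - log(p) + (cl[s + a] - cl[s])
  })
  names(u) <- names(density$n)
  out <- energy_landscape(u, a = a, beta_mu = beta_mu,
                          chrom_sizes = density$chrom_sizes)
  attr(out, "floored") <- floored
  out
}

#' Shift a dyad-indexed track to start coordinates (and back)
#'
#' For an odd footprint the dyad of a rod at start s is s + (a-1)/2; both
#' operations are pure index shifts that preserve mass.
#'
#' @param dyad_track Numeric vector over all L bp, indexed by dyad position.
#' @param a Odd footprint (default 147).
#' @return For \code{dyad_to_start}: vector over valid starts
#'   (length L - a + 1). For \code{start_to_dyad}: vector over all L bp with
#'   zeros where no valid dyad exists.
#' @export
dyad_to_start <- function(dyad_track, a = 147L) {
  if (a %% 2 == 0) stop("footprint must be odd for an exact dyad")
  h <- (a - 1L) %/% 2L
  L <- length(dyad_track)
  if (L < a) stop("track shorter than footprint")
  dyad_track[(h + 1L):(L - h)]
}

#' @rdname dyad_to_start
#' @param start_track Numeric vector over valid starts (length L - a + 1).
#' @param L Chromosome length in bp.
#' @export
start_to_dyad <- function(start_track, a = 147L, L = length(start_track) + a - 1L) {
  if (a %% 2 == 0) stop("footprint must be odd for an exact dyad")
  h <- (a - 1L) %/% 2L
  out <- numeric(L)
  out[(h + 1L):(h + length(start_track))] <- start_track
  out
}

#' Convert a normalized dyad profile to an absolute start density
#'
#' A normalized dyad track has per-chromosome mean 1, whereas an absolute
#' start density has mean coverage / a per bp, so the track is shifted to
#' start coordinates and scaled by coverage / a. Because observed profiles
#' are relative enrichments, hot regions can imply occupancy >= 1 at the
#' assumed genome-wide coverage, which the exact inversion cannot accept.
#' When \code{o_max} is set, only the offending positions are clamped: each
#' start whose footprint covers a bp with occupancy above \code{o_max} is
#' scaled down by the smallest ratio o_max / O over its footprint. A single
#' pass brings every occupancy to at most \code{o_max} without perturbing
#' the rest of the genome (occupancy is monotone in the start density, so
#' no new violations arise). The achieved genome-wide mean occupancy is
#' reported in attribute "effective_coverage". With \code{o_max = NULL} an
#' unphysical density is an error.
#'
#' @param profile Normalized \code{bp_profile} of kind "dyad" (or a named
#'   list of per-chromosome dyad-density vectors).
#' @param a Footprint in bp.
#' @param coverage Assumed genome-wide nucleosome coverage.
#' @param o_max Occupancy ceiling in (0, 1), or NULL to disable clamping.
#' @return A \code{start_density}.
#' @export
dyad_profile_to_density <- function(profile, a = 147L, coverage = 0.8,
                                    o_max = 0.98) {
  values <- if (inherits(profile, "bp_profile")) profile$values else profile
  n <- lapply(values, function(v) dyad_to_start(v, a) * coverage / a)
  den <- start_density(n, a = a)
  peak <- max(unlist(den$O, use.names = FALSE))
  if (is.null(o_max)) {
    if (peak >= 1)
      stop("density implies occupancy >= 1; lower the assumed coverage ",
           "or set o_max")
    attr(den, "effective_coverage") <- mean_coverage(den)
    return(den)
  }
  stopifnot(o_max > 0, o_max < 1)
  if (peak > o_max) {
    n <- lapply(names(n), function(ch) {
      v <- n[[ch]]
      O <- den$O[[ch]]
      bad <- which(O > o_max)
      if (length(bad)) {
        f <- rep(1, length(v))
        for (i in bad) {
          seg <- max(1L, i - a + 1L):min(length(v), i)
          f[seg] <- pmin(f[seg], o_max / O[i])
        }
        v <- v * f
      }
      v
    })
    names(n) <- names(values)
    den <- start_density(n, a = a)
  }
  attr(den, "effective_coverage") <- mean_coverage(den)
  den
}

#' Sample exact equilibrium nucleosome configurations
#'
#' Draws statistically exact snapshots of the hard-rod ensemble by
#' sequential sampling from the backward partition functions: walking left
#' to right, a nucleosome starts at a free position s with probability
#' w(s) Z(s+a..L) / Z(s..L). The marginal start frequency across many
#' configurations equals the equilibrium start density. Uses R's RNG (set a
#' seed for reproducibility).
#'
#' @param landscape An \code{energy_landscape}.
#' @param k Number of configurations (genome snapshots) to draw.
#' @return Named list (per chromosome) of data.frames with columns start
#'   (0-based) and config (1..k).
#' @export
sample_configurations <- function(landscape, k) {
  stopifnot(inherits(landscape, "energy_landscape"), k >= 1)
  a <- landscape$a
  out <- lapply(names(landscape$u), function(ch) {
    logw <- landscape$beta_mu - landscape$u[[ch]]
    res <- .hardrod_sample_configs(logw, a, landscape$chrom_sizes[[ch]], k)
    data.frame(start = res$start - 1L, config = res$config)
  })
  names(out) <- names(landscape$u)
  out
}

#' Calibrate the chemical potential to a target coverage
#'
#' Mean occupancy is monotone increasing in beta*mu, so a bisection on
#' beta*mu in [-30, 30] converges to the target mean coverage.
#'
#' @param landscape An \code{energy_landscape} (its own beta_mu is ignored).
#' @param target_coverage Desired genome-wide mean occupancy in (0, 1);
#'   nucleosomes typically cover 75--90\% of genomic DNA, so 0.8 is a
#'   sensible default.
#' @param tol Absolute tolerance on the achieved coverage.
#' @return The calibrated beta_mu (numeric scalar), with attribute
#'   "coverage" giving the achieved value.
#' @export
calibrate_mu <- function(landscape, target_coverage = 0.8, tol = 1e-4) {
  stopifnot(inherits(landscape, "energy_landscape"),
            target_coverage > 0, target_coverage < 1)
  cov_at <- function(bm) {
    landscape$beta_mu <- bm
    mean_coverage(forward_solve(landscape))
  }
  lo <- -30; hi <- 30
  c_lo <- cov_at(lo); c_hi <- cov_at(hi)
  if (target_coverage < c_lo || target_coverage > c_hi)
    stop("target coverage unreachable for beta_mu in [-30, 30]")
  mid <- NA_real_; c_mid <- NA_real_
  for (iter in seq_len(200)) {
    mid <- (lo + hi) / 2
    c_mid <- cov_at(mid)
    if (abs(c_mid - target_coverage) < tol) break
    if (c_mid < target_coverage) lo <- mid else hi <- mid
  }
  if (abs(c_mid - target_coverage) >= tol)
    stop("bisection failed to reach target coverage")
  structure(mid, coverage = c_mid)
}

#' Solve the model over a grid of chemical potentials
#'
#' @param landscape An \code{energy_landscape}.
#' @param beta_mu_grid Nonempty numeric vector of beta*mu values.
#' @return Named list mapping each beta_mu (as character) to its
#'   \code{start_density}.
#' @export
sweep_mu <- function(landscape, beta_mu_grid) {
  stopifnot(inherits(landscape, "energy_landscape"))
  if (length(beta_mu_grid) == 0) stop("beta_mu grid must be nonempty")
  out <- lapply(beta_mu_grid, function(bm) {
    landscape$beta_mu <- bm
    forward_solve(landscape)
  })
  names(out) <- as.character(beta_mu_grid)
  out
}

#' Thermal energy in kcal/mol
#'
#' @param temperature_celsius Temperature in degrees Celsius.
#' @return R*T in kcal/mol (gas constant R = 1.98720425e-3 kcal/(mol K)).
#' @export
thermal_energy_kcal_per_mol <- function(temperature_celsius) {
  T_kelvin <- temperature_celsius + 273.15
  if (any(T_kelvin <= 0)) stop("temperature must be above absolute zero")
  1.98720425e-3 * T_kelvin
}
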