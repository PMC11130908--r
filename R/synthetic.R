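## Synthetic cell-line data generator.
##
## Observed modification levels are generated as exact closed-form steady
## states of the model under a chosen ground-truth structure and
## parameter set, optionally perturbed by multiplicative log-normal noise
## (levels are positive and span orders of magnitude, so an additive
## error model would be ill-suited).  Enzyme profiles are sampled
## log-uniformly within per-enzyme bounds bracketing the ranges observed
## in transcript-level measurements of human cell lines.

#' Default ground-truth rate parameters
#'
#' A parameter preset on the `kDNMT1 = 1, C = 1` scale chosen under two
#' constraints.  First, the generated steady states reproduce the
#' qualitative ordering of modification levels in real genomic DNA:
#' 5-mdC far above 5-hmdC, which is far above 5-fdC and 5-cadC (roughly
#' comparable to each other), with small 5-hmdU and dU pools.  Second,
#' each TET that is active in a reaction carries a comparable share of
#' that reaction's flux at typical (geometric-mean) enzyme levels —
#' affinities are scaled inversely to the enzyme's abundance range, so
#' low-abundance TET3 gets proportionally large coefficients.  Without
#' this balance an active enzyme can contribute a negligible flux share,
#' and the generating structure would be indistinguishable from the
#' substructure lacking that enzyme: no recovery study could then resolve
#' it even in principle.  The AID affinity is tied across its two
#' substrates, matching the default estimation convention.
#'
#' @return A [rate_parameters()] vector.
#' @export
default_true_params <- function() {
  rate_parameters(kDNMT1 = 1,
                  k1TET1 = 2e-5, k1TET2 = 1e-5, k1TET3 = 0,
                  k2TET1 = 6e-4, k2TET2 = 0,    k2TET3 = 3e-2,
                  k3TET1 = 0,    k3TET2 = 3e-2, k3TET3 = 3,
                  k4 = 5e-3, k5 = 1e-2,
                  kAID_hmdC = 2e-3, kAID_C = 2e-3,
                  kSMUG = 2e-3, kTDG = 2e-4)
}

#' Default ground-truth structure
#'
#' TET1+TET2 on 5-mdC oxidation, TET1+TET3 on 5-hmdC oxidation, TET2+TET3
#' on 5-fdC oxidation — a structure in which no reaction uses all three
#' TETs, so recovery is non-trivial.
#'
#' @return A [model_structure()].
#' @export
default_true_structure <- function() {
  model_structure(c("TET1", "TET2"), c("TET1", "TET3"), c("TET2", "TET3"))
}

#' Default enzyme-level sampling bounds
#'
#' Log-uniform sampling bounds per enzyme (relative transcript units),
#' bracketing the ranges observed across measured human cell lines —
#' e.g. TET3 spanning about 1e-4..3e-2 and TET2 about 4e-2..7.5e-1.
#'
#' @return A 7 x 2 matrix (`lower`, `upper`), rows in canonical enzyme
#'   order.
#' @export
default_enzyme_bounds <- function() {
  b <- rbind(DNMT1 = c(3e-2, 3e-1),
             TET1  = c(3e-2, 2e-1),
             TET2  = c(4e-2, 7.5e-1),
             TET3  = c(1e-4, 3e-2),
             AID   = c(1e-3, 1e-1),
             SMUG1 = c(3e-1, 2e1),
             TDG   = c(3e-2, 5e-1))
  colnames(b) <- c("lower", "upper")
  b[ENZYME_NAMES, ]
}

#' Configuration of the synthetic-data generator
#'
#' @param structure Ground-truth [model_structure()].
#' @param params Ground-truth [rate_parameters()] on the `kDNMT1 = 1`
#'   scale.
#' @param n_lines Number of cell lines (>= 2; default 5, the size of the
#'   motivating study).
#' @param enzyme_bounds 7 x 2 matrix of positive log-uniform bounds, rows
#'   in canonical enzyme order.
#' @param cv Coefficient of variation of the multiplicative log-normal
#'   noise on each observed level (default 0.05; 0 = noiseless).
#' @param seed Optional integer seed; identical seeds give identical
#'   datasets.
#' @param profiles Optional data frame of enzyme profiles (rows = cell
#'   lines) used verbatim instead of sampling — e.g.
#'   `read_enzyme_table(transcript_levels_path())` for the packaged
#'   measured profiles.
#' @param C Cytidine pool constant.
#' @return A list of class `"generator_config"`.
#' @export
generator_config <- function(structure = default_true_structure(),
                             params = default_true_params(),
                             n_lines = 5,
                             enzyme_bounds = default_enzyme_bounds(),
                             cv = 0.05, seed = NULL, profiles = NULL,
                             C = 1) {
  params <- as_rate_parameters(params)
  stopifnot(inherits(structure, "model_structure"))
  if (!is.null(profiles)) n_lines <- nrow(profiles)
  if (n_lines < 2) stop("n_lines must be >= 2", call. = FALSE)
  if (cv < 0) stop("noise cv must be >= 0", call. = FALSE)
  eb <- enzyme_bounds[ENZYME_NAMES, , drop = FALSE]
  if (any(!is.finite(eb)) || any(eb <= 0) || any(eb[, 1] > eb[, 2]))
    stop("enzyme bounds must be positive with lower <= upper", call. = FALSE)
  out <- list(structure = structure, params = params, n_lines = n_lines,
              enzyme_bounds = eb, cv = cv, seed = seed, profiles = profiles,
              C = C)
  class(out) <- "generator_config"
  out
}

## Two profiles are nearly proportional when the log-ratio across enzymes
## is nearly constant; such pairs add no information to the design.
nearly_proportional <- function(p, q, tol = 0.1) {
  stats::sd(log(p) - log(q)) < tol
}

#' Sample enzyme profiles
#'
#' Draws `n_lines` enzyme profiles log-uniformly within the configured
#' per-enzyme bounds.  Profiles that are nearly proportional to an
#' already-drawn one are resampled (nearly collinear profiles would make
#' the flux-balance design rank-deficient).  With `config$profiles` set,
#' those profiles are returned verbatim (pass-through mode).
#'
#' @param config A [generator_config()].
#' @return Data frame, rows = cell lines (`line01`, ...), canonical
#'   enzyme columns.
#' @export
sample_enzyme_profiles <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  if (!is.null(config$profiles)) {
    prof <- as.data.frame(config$profiles)[, ENZYME_NAMES]
    return(prof)
  }
  eb <- config$enzyme_bounds
  with_seed(config$seed, {
    draw <- function() exp(stats::runif(7, log(eb[, "lower"]),
                                        log(eb[, "upper"])))
    profs <- list()
    tries <- 0
    while (length(profs) < config$n_lines) {
      p <- draw()
      tries <- tries + 1
      if (tries > 100 * config$n_lines)
        stop("could not sample mutually non-proportional profiles",
             call. = FALSE)
      if (any(vapply(profs, nearly_proportional, logical(1), q = p))) next
      profs[[length(profs) + 1]] <- p
    }
    prof <- as.data.frame(do.call(rbind, profs))
    names(prof) <- ENZYME_NAMES
    rownames(prof) <- sprintf("line%02d", seq_len(config$n_lines))
    prof
  })
}

#' Generate a synthetic cell-line dataset
#'
#' For each sampled (or supplied) enzyme profile, computes the exact
#' closed-form steady state under the ground-truth structure and
#' parameters, then applies independent multiplicative log-normal noise
#' with the configured coefficient of variation to every state variable
#' (`sdlog = sqrt(log(1 + cv^2))`, `meanlog = 0`, so the expected
#' log-observed level equals the log-true level).  The ground truth
#' (structure, parameters, noiseless states) is attached for validation.
#'
#' @param config A [generator_config()].
#' @return A [cell_line_dataset()] with attribute `"ground_truth"`, a
#'   list with `structure`, `params`, `noiseless` (matrix of exact steady
#'   states), `cv`, `seed`; retrieve it with [ground_truth()].
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  with_seed(config$seed, {
    profiles <- local({
      cfg <- config; cfg$seed <- NULL   # already inside the seeded block
      sample_enzyme_profiles(cfg)
    })
    noiseless <- matrix(NA_real_, nrow(profiles), 6,
                        dimnames = list(rownames(profiles), STATE_NAMES))
    for (line in rownames(profiles)) {
      ss <- steady_state(as_enzyme_profile(profiles[line, ]), config$params,
                         config$structure, C = config$C)
      noiseless[line, ] <- unclass(ss)
    }
    states <- noiseless
    if (config$cv > 0) {
      sdlog <- sqrt(log(1 + config$cv^2))
      noise <- matrix(stats::rlnorm(length(states), meanlog = 0,
                                    sdlog = sdlog),
                      nrow(states), ncol(states))
      states <- states * noise
    }
    ds <- cell_line_dataset(profiles, as.data.frame(states))
    attr(ds, "ground_truth") <- list(structure = config$structure,
                                     params = config$params,
                                     noiseless = noiseless,
                                     cv = config$cv, seed = config$seed)
    ds
  })
}

#' @rdname generate_dataset
#' @param dataset A dataset produced by [generate_dataset()].
#' @export
ground_truth <- function(dataset) attr(dataset, "ground_truth")

#' Measured-profile preset dataset (synthetic)
#'
#' Convenience wrapper: the packaged measured transcript profiles of the
#' five human cell lines combined with the default ground-truth structure
#' and parameters.  The modification levels are synthetic model steady
#' states (plus optional noise) — they emulate, and must not be mistaken
#' for, real mass-spectrometry measurements.
#'
#' @param cv Noise coefficient of variation (default 0.05).
#' @param seed Optional seed.
#' @return A [cell_line_dataset()] with ground truth attached.
#' @export
preset_dataset <- function(cv = 0.05, seed = NULL) {
  generate_dataset(generator_config(
    profiles = read_enzyme_table(transcript_levels_path()),
    cv = cv, seed = seed))
}
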