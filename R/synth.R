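#' Synthetic ERP specification
#'
#' Describes an exchangeable null pool of single-trial epochs: every trial is
#' an independent draw of spatially mixed, temporally AR(1)-smoothed noise, so
#' any split of the pool into two pseudo-conditions satisfies the null
#' hypothesis exactly.  Channels are placed on a 2-D grid montage and spatial
#' correlation between channels follows a Gaussian kernel in grid distance;
#' the montage also yields the default adjacency graph (k-nearest neighbours,
#' symmetrised).
#'
#' The defaults mirror a 128-electrode recording at 250 Hz with 201-sample
#' epochs starting at -300 ms.  Temporal smoothing (`ar = 0.8`), spatial
#' kernel scale (1.5 inter-electrode spacings) and single-trial noise
#' (`noise_sd = 10` microvolts) are fixed, field-realistic choices; the
#' realised FWER of max-statistic corrections depends only on exchangeability,
#' not on these correlation details.
#'
#' @param n_channels,n_timepoints,n_trials array dimensions.
#' @param sampling_rate Hz.
#' @param epoch_start ms.
#' @param ar lag-1 autocorrelation of the AR(1) temporal smoothing, in
#'   `[0, 1)`; 0 gives temporally white noise.
#' @param spatial_scale Gaussian kernel scale for between-channel correlation,
#'   in units of the montage grid spacing; 0 gives spatially white noise.
#' @param noise_sd marginal standard deviation per point, microvolts.
#' @param noise `"gaussian"` (default) or `"student"` for heavier tails
#'   (scaled to unit variance; a robustness option).
#' @param noise_df degrees of freedom for `noise = "student"`.
#' @param k_neighbors neighbour count for the montage adjacency.
#' @param seed integer seed.
#' @return A `synth_spec` object.
#' @export
synth_spec <- function(n_channels = 128, n_timepoints = 201, n_trials = 1000,
                       sampling_rate = 250, epoch_start = -300, ar = 0.8,
                       spatial_scale = 1.5, noise_sd = 10,
                       noise = c("gaussian", "student"), noise_df = 5,
                       k_neighbors = 4, seed = 1) {
  noise <- match.arg(noise)
  n_channels <- check_count(n_channels, "n_channels")
  n_timepoints <- check_count(n_timepoints, "n_timepoints")
  n_trials <- check_count(n_trials, "n_trials")
  check_scalar_number(ar, "ar", lower = 0, upper = 1, strict_upper = TRUE)
  check_scalar_number(spatial_scale, "spatial_scale", lower = 0)
  check_scalar_number(noise_sd, "noise_sd", lower = 0, strict_lower = TRUE)
  if (noise == "student" && noise_df <= 2)
    stop_validation("`noise_df` must exceed 2 so the variance exists")
  structure(list(n_channels = n_channels, n_timepoints = n_timepoints,
                 n_trials = n_trials, sampling_rate = sampling_rate,
                 epoch_start = epoch_start, ar = ar,
                 spatial_scale = spatial_scale, noise_sd = noise_sd,
                 noise = noise, noise_df = noise_df,
                 k_neighbors = check_count(k_neighbors, "k_neighbors"),
                 seed = check_count(seed, "seed", min = 0L)),
            class = "synth_spec")
}

# channels laid out row-wise on a near-square unit grid
montage_coords <- function(n_channels) {
  ncol <- ceiling(sqrt(n_channels))
  i <- seq_len(n_channels) - 1L
  cbind(x = i %% ncol, y = i %/% ncol)
}

#' Adjacency graph of the synthetic grid montage
#'
#' k-nearest-neighbour graph (Euclidean grid distance, symmetrised) over the
#' montage used by [generate_null_trials()].
#'
#' @param n_channels channel count.
#' @param k neighbours per channel before symmetrisation (default 4).
#' @return An [build_adjacency()] graph.
#' @export
montage_adjacency <- function(n_channels, k = 4) {
  xy <- montage_coords(n_channels)
  d <- as.matrix(stats::dist(xy))
  diag(d) <- Inf
  k <- min(k, n_channels - 1L)
  if (k < 1L || n_channels == 1L)
    return(build_adjacency(matrix(integer(0), ncol = 2), n_channels))
  nn <- t(apply(d, 1L, function(r) order(r)[seq_len(k)]))
  edges <- cbind(rep(seq_len(n_channels), each = k), as.integer(t(nn)))
  build_adjacency(edges, n_channels)
}

# run expr with a locally-seeded RNG, restoring the caller's stream after
with_local_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

#' Generate an exchangeable null trial pool
#'
#' Draws `spec$n_trials` independent trials of spatially mixed, AR(1)-smoothed
#' noise (see [synth_spec()]).  The marginal standard deviation is
#' `spec$noise_sd` at every point, the lag-1 temporal autocorrelation is
#' `spec$ar` on every channel, and between-channel correlation at lag 0
#' follows the Gaussian kernel `exp(-d^2 / (2 * spatial_scale^2))`.
#'
#' @param spec a [synth_spec()].
#' @return list with `epochs` (an [epochs_set()]) and `adjacency` (the
#'   montage graph).
#' @export
#' @examples
#' pool <- generate_null_trials(synth_spec(n_channels = 9, n_timepoints = 20,
#'                                         n_trials = 12))
#' dim(pool$epochs$data)
generate_null_trials <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  nc <- spec$n_channels; nt <- spec$n_timepoints; ntr <- spec$n_trials
  arr <- with_local_seed(spec$seed, {
    n <- nc * nt * ntr
    eps <- if (spec$noise == "gaussian") stats::rnorm(n)
           else stats::rt(n, df = spec$noise_df) /
                sqrt(spec$noise_df / (spec$noise_df - 2))
    # spatial mixing: channels x (time * trials) gemm with a Cholesky factor
    e <- matrix(eps, nc, nt * ntr)
    if (spec$spatial_scale > 0 && nc > 1L) {
      xy <- montage_coords(nc)
      d2 <- as.matrix(stats::dist(xy))^2
      cc <- exp(-d2 / (2 * spec$spatial_scale^2))
      l <- t(chol(cc + diag(1e-9, nc)))
      e <- l %*% e
    }
    # AR(1) along time, stationary start, applied jointly over trials
    x <- array(e, c(nc, nt, ntr))
    if (spec$ar > 0 && nt > 1L) {
      w <- sqrt(1 - spec$ar^2)
      for (t in 2:nt) x[, t, ] <- spec$ar * x[, t - 1, ] + w * x[, t, ]
    }
    x * spec$noise_sd
  })
  list(epochs = epochs_set(arr, spec$sampling_rate, spec$epoch_start),
       adjacency = montage_adjacency(nc, spec$k_neighbors))
}

#' Specification of an injected condition effect
#'
#' A constant (or raised-cosine-windowed) potential shift added to a subset of
#' channels within a time window, on the trials of one condition.
#'
#' @param channels channel indices carrying the effect.
#' @param window_ms length-2 numeric, effect window in ms (inclusive).
#' @param amplitude shift in microvolts.
#' @param shape `"rectangular"` (default) or `"raised_cosine"` (Hann taper
#'   peaking at `amplitude` mid-window).
#' @return An `effect_spec` object.
#' @export
effect_spec <- function(channels, window_ms, amplitude,
                        shape = c("rectangular", "raised_cosine")) {
  shape <- match.arg(shape)
  channels <- as.integer(channels)
  if (length(channels) < 1L || anyNA(channels) || any(channels < 1L))
    stop_validation("`channels` must be positive channel indices")
  if (length(window_ms) != 2L || window_ms[1] > window_ms[2])
    stop_validation("`window_ms` must be an increasing length-2 interval")
  check_scalar_number(amplitude, "amplitude")
  structure(list(channels = channels, window_ms = as.numeric(window_ms),
                 amplitude = amplitude, shape = shape), class = "effect_spec")
}

#' Add condition effects to selected trials
#'
#' Adds each effect's amplitude profile to the target channels within the time
#' window, on the selected trials only; every other sample is untouched.
#'
#' @param epochs an [epochs_set()].
#' @param trials integer indices of the trials receiving the effects (the
#'   "condition" being caricatured).
#' @param effects list of [effect_spec()] objects (possibly empty).
#' @return The modified `epochs_set`.
#' @export
inject_effects <- function(epochs, trials, effects) {
  stopifnot(inherits(epochs, "epochs_set"))
  if (inherits(effects, "effect_spec")) effects <- list(effects)
  d <- dim(epochs$data)
  trials <- as.integer(trials)
  if (any(trials < 1L) || any(trials > d[3]))
    stop_validation("trial index out of range 1..%d", d[3])
  tms <- times_ms(epochs)
  out <- epochs
  for (ef in effects) {
    stopifnot(inherits(ef, "effect_spec"))
    if (any(ef$channels > d[1]))
      stop_validation("effect channel index out of range 1..%d", d[1])
    if (ef$window_ms[1] < min(tms) - 1e-9 || ef$window_ms[2] > max(tms) + 1e-9)
      stop_validation("effect window [%g, %g] ms lies outside the epoch [%g, %g] ms",
                      ef$window_ms[1], ef$window_ms[2], min(tms), max(tms))
    sel <- which(tms >= ef$window_ms[1] & tms <= ef$window_ms[2])
    profile <- if (ef$shape == "rectangular") rep(ef$amplitude, length(sel))
               else ef$amplitude * 0.5 *
                    (1 - cos(2 * pi * seq(0, 1, length.out = length(sel))))
    out$data[ef$channels, sel, trials] <-
      out$data[ef$channels, sel, trials] +
      rep(profile, each = length(ef$channels))
  }
  out
}

#' Stylised two-effect example study
#'
#' Builds a pair of synthetic conditions illustrating how the cluster
#' attributes weight effects differently: condition B carries one *transient*
#' high-amplitude effect (+25 microvolts over 3 channels in a short window)
#' and one *sustained* low-amplitude effect (+7 microvolts over 8 channels in
#' a long window).  Cluster extent ranks the sustained effect above the
#' transient one, cluster height ranks them the other way round, and
#' cluster-mass and TFCE sit in between.
#'
#' @param spec a [synth_spec()] describing the noise pool; needs at least
#'   `2 * n_per_condition` trials and 11 channels.
#' @param n_per_condition trials per condition (default 50).
#' @return list with `cond_a`, `cond_b` (epochs), `adjacency`, and the
#'   `effects` list (transient first).
#' @export
two_effect_demo <- function(spec = synth_spec(n_channels = 16,
                                              n_timepoints = 100,
                                              n_trials = 100, seed = 7),
                            n_per_condition = 50) {
  stopifnot(inherits(spec, "synth_spec"))
  if (spec$n_trials < 2 * n_per_condition)
    stop_validation("spec must provide at least %d trials", 2 * n_per_condition)
  if (spec$n_channels < 11)
    stop_validation("the demo needs at least 11 channels")
  pool <- generate_null_trials(spec)
  tms <- times_ms(pool$epochs)
  span <- range(tms)
  mid <- mean(span)
  wid <- diff(span)
  # effect channels from opposite corners of the grid montage
  xy <- montage_coords(spec$n_channels)
  d_far <- sqrt((xy[, 1] - max(xy[, 1]))^2 + (xy[, 2] - max(xy[, 2]))^2)
  d_near <- sqrt(xy[, 1]^2 + xy[, 2]^2)
  transient_ch <- order(d_far)[1:3]
  sustained_ch <- setdiff(order(d_near), transient_ch)[1:8]
  effects <- list(
    transient = effect_spec(transient_ch, mid + c(-0.05, 0.05) * wid, 25),
    sustained = effect_spec(sustained_ch, mid + c(-0.35, 0.35) * wid, 7))
  idx_a <- seq_len(n_per_condition)
  idx_b <- n_per_condition + seq_len(n_per_condition)
  cond_a <- epochs_subset(pool$epochs, idx_a)
  cond_b <- inject_effects(epochs_subset(pool$epochs, idx_b),
                           seq_len(n_per_condition), effects)
  list(cond_a = cond_a, cond_b = cond_b, adjacency = pool$adjacency,
       effects = effects)
}
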