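# Synthetic band-limited coupled oscillators with known ground-truth coupling
# topology. The model is deliberately a phase model, not a neural-mass model:
# the quantities the downstream pipeline estimates are phase-lag statistics,
# so ground truth only needs to pin the phase structure.

with_preserved_rng <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# deterministic substream seed fan-out; keeps results < 2^31
substream_seed <- function(seed, k) {
  (as.numeric(seed) * 1009 + as.numeric(k) * 7919 + 104729) %% 2147483647
}

#' Specification of a coupled-oscillator epoch generator
#'
#' Defines a set of narrowband oscillators (one per channel) whose
#' instantaneous phases are partially entrained to coupled neighbours at an
#' imposed nonzero phase lag, so the Phase Lag Index of generated channel
#' pairs has a known ordering: it increases with coupling strength, and
#' uncoupled or common-source (zero-lag) pairs stay low.
#'
#' @param n_channels Number of channels.
#' @param fs Sampling rate in Hz.
#' @param n_samples Samples per epoch; must cover at least two cycles of the
#'   lowest carrier-band frequency.
#' @param n_epochs Number of epochs.
#' @param carrier_band Numeric `(low, high)` Hz; oscillators run at the band
#'   centre with a mean-reverting phase deviation that keeps the signal
#'   inside the band.
#' @param coupling Symmetric `n x n` matrix of coupling strengths in `[0, 1]`,
#'   zero diagonal. Strength c means a coupled channel's core phase is the
#'   convex mixture `(1 - c) * own + c * neighbour`; see [generate_epochs()]
#'   for how the lags are realized.
#' @param lag Symmetric matrix of imposed phase offsets in radians; must lie
#'   in the open interval `(0, pi)` wherever `coupling > 0` (a zero or pi lag
#'   would be invisible to the PLI by construction).
#' @param noise_sd Standard deviation of additive broadband white noise
#'   (signal amplitude is 1).
#' @param phase_dev_sd Stationary standard deviation (radians) of each
#'   oscillator's phase deviation, an Ornstein-Uhlenbeck (mean-reverting
#'   random-walk) process around the carrier phase.
#' @param phase_tau Correlation time of the phase deviation in seconds; the
#'   phase of uncoupled channels decorrelates on this time scale, so an
#'   epoch holds roughly `n_samples / (fs * phase_tau)` independent phase
#'   observations.
#' @param seed Integer seed; generation is deterministic given the spec.
#' @param channel_labels Optional labels (default `ch01`, `ch02`, ...).
#' @return An object of class `oscillator_spec`.
#' @seealso [generate_epochs()], [chain_coupling()], [star_coupling()]
#' @export
oscillator_spec <- function(n_channels, fs = 512, n_samples = 4096L,
                            n_epochs = 4L, carrier_band = c(8, 13),
                            coupling = NULL, lag = pi / 2, noise_sd = 0.25,
                            phase_dev_sd = 3, phase_tau = 0.25, seed = 1L,
                            channel_labels = NULL) {
  n_channels <- as.integer(n_channels)
  stopifnot(n_channels >= 1L, fs > 0, n_samples >= 2L, n_epochs >= 0L)
  carrier_band <- as.numeric(carrier_band)
  stopifnot(length(carrier_band) == 2L, carrier_band[1] > 0,
            carrier_band[2] > carrier_band[1], carrier_band[2] < fs / 2)
  if (is.null(coupling))
    coupling <- matrix(0, n_channels, n_channels)
  coupling <- as.matrix(coupling)
  if (!isTRUE(all.equal(coupling, t(coupling))))
    stop("coupling matrix must be symmetric")
  if (any(diag(coupling) != 0)) stop("coupling diagonal must be zero")
  if (any(coupling < 0 | coupling > 1))
    stop("coupling strengths must lie in [0, 1]")
  if (length(lag) == 1L) lag <- matrix(lag, n_channels, n_channels)
  lag <- as.matrix(lag)
  if (!isTRUE(all.equal(lag, t(lag)))) stop("lag matrix must be symmetric")
  bad <- coupling > 0 & (lag <= 0 | lag >= pi)
  if (any(bad))
    stop("lag must be in (0, pi) wherever coupling > 0")
  min_len <- 2 * fs / carrier_band[1]
  if (n_samples < min_len)
    stop("n_samples (", n_samples, ") below two cycles of the slowest ",
         "carrier component (need >= ", ceiling(min_len), ")")
  stopifnot(phase_dev_sd > 0, phase_tau > 0)
  if (is.null(channel_labels))
    channel_labels <- sprintf("ch%02d", seq_len(n_channels))
  stopifnot(length(channel_labels) == n_channels)
  structure(list(n_channels = n_channels, fs = fs,
                 n_samples = as.integer(n_samples),
                 n_epochs = as.integer(n_epochs),
                 carrier_band = carrier_band, coupling = coupling, lag = lag,
                 noise_sd = noise_sd, phase_dev_sd = phase_dev_sd,
                 phase_tau = phase_tau, seed = as.integer(seed),
                 channel_labels = as.character(channel_labels)),
            class = "oscillator_spec")
}

# Per-channel emission phase offsets realizing the pairwise lags: offsets are
# propagated over the maximum spanning forest of the coupling matrix (root of
# each component = its lowest-index node, offset 0; child offset = parent
# offset + lag). Every backbone (forest) edge then carries exactly the
# specified lag, and two channels driven by a common source at equal depth
# meet at a zero-centred phase difference -- which the PLI suppresses, like
# volume conduction.
emission_offsets <- function(coupling, lag) {
  n <- nrow(coupling)
  delta <- numeric(n)
  if (n < 2L || all(coupling == 0)) return(delta)
  # Kruskal forest on descending coupling, lexicographic index tie-break
  idx <- which(upper.tri(coupling) & coupling > 0, arr.ind = TRUE)
  ord <- order(-coupling[idx], idx[, 1L], idx[, 2L])
  idx <- idx[ord, , drop = FALSE]
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  adj <- vector("list", n)
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1L]; j <- idx[r, 2L]
    ri <- find(i); rj <- find(j)
    if (ri != rj) {
      parent[ri] <- rj
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  visited <- logical(n)
  for (root in seq_len(n)) {
    if (visited[root]) next
    visited[root] <- TRUE
    queue <- root
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      for (u in adj[[v]]) if (!visited[u]) {
        visited[u] <- TRUE
        delta[u] <- delta[v] + lag[v, u]
        queue <- c(queue, u)
      }
    }
  }
  delta
}

#' Generate epochs of phase-coupled narrowband signals
#'
#' Each channel's base phase is a constant-frequency carrier (the band
#' centre) plus a mean-reverting Ornstein-Uhlenbeck phase deviation; all
#' channels of an epoch share one uniform epoch-start phase, so channel
#' individuality lives entirely in the deviations. Coupling acts on core
#' phases in channel-index order -- channel `j`'s core phase is the convex
#' mixture `p_j = (1 - s) * theta_j + sum_i c_ij * p_i` over its
#' lower-indexed coupled neighbours -- and the imposed pairwise lags are
#' realized as per-channel emission offsets propagated over the coupling
#' backbone (see Details). The emitted signal is `cos(p_j + delta_j)` plus
#' white noise.
#'
#' @details
#' Realizing the symmetric coupling matrix directionally (lower index drives
#' higher) is what lets a fully coupled pair carry a *constant* nonzero lag:
#' mutual symmetric mixing would cancel it. Applying lags as emission
#' offsets, rather than inside the mixture, keeps them from compounding
#' along coupling chains; offsets follow the maximum spanning forest of the
#' coupling matrix, so every backbone edge carries exactly its specified
#' lag, while channels that merely share a driver meet at a phase difference
#' centred on zero -- the volume-conduction-like signature the PLI
#' deliberately suppresses. Estimated PLI therefore tracks direct coupling,
#' not common drive. The realized lag of coupled pairs *off* the backbone
#' forest is the difference of their offsets.
#'
#' @param spec An [oscillator_spec()].
#' @return An [epoch_set()] (broadband; downstream band-pass applies).
#' @examples
#' sp <- oscillator_spec(3, n_samples = 1024, n_epochs = 1,
#'                       coupling = chain_coupling(3, 0.8), seed = 42)
#' generate_epochs(sp)
#' @export
generate_epochs <- function(spec) {
  stopifnot(inherits(spec, "oscillator_spec"))
  n <- spec$n_channels
  ns <- spec$n_samples
  f0 <- mean(spec$carrier_band)
  a <- exp(-1 / (spec$phase_tau * spec$fs))
  sigma_step <- spec$phase_dev_sd * sqrt(1 - a^2)
  trend <- 2 * pi * f0 * (seq_len(ns) - 1L) / spec$fs
  delta <- emission_offsets(spec$coupling, spec$lag)
  with_preserved_rng(spec$seed, {
    eps <- lapply(seq_len(spec$n_epochs), function(k) {
      phi0 <- stats::runif(1, 0, 2 * pi)
      theta <- matrix(0, n, ns)
      for (i in seq_len(n)) {
        dev <- stats::filter(stats::rnorm(ns, 0, sigma_step), a,
                             method = "recursive",
                             init = stats::rnorm(1, 0, spec$phase_dev_sd))
        theta[i, ] <- phi0 + trend + as.numeric(dev)
      }
      core <- matrix(0, n, ns)
      core[1, ] <- theta[1, ]
      if (n > 1L) for (j in 2:n) {
        # mixture weights toward lower-indexed neighbours, renormalized if a
        # row's lower-triangle couplings exceed total weight 1
        w <- spec$coupling[j, seq_len(j - 1L)]
        s <- sum(w)
        if (s > 1) w <- w / s
        mix <- (1 - min(s, 1)) * theta[j, ]
        for (i in which(w > 0))
          mix <- mix + w[i] * core[i, ]
        core[j, ] <- mix
      }
      x <- cos(core + delta)
      if (spec$noise_sd > 0)
        x <- x + matrix(stats::rnorm(n * ns, 0, spec$noise_sd), n, ns)
      x
    })
    epoch_set(eps, spec$fs, spec$channel_labels)
  })
}

#' Chain (path) coupling backbone
#'
#' Couples consecutive channels `(i, i + 1)` at a common strength; the
#' ground-truth maximum spanning tree of such a system is the path, with
#' leaf number 2 and maximal diameter.
#'
#' @param n Number of channels.
#' @param strength Coupling strength in `[0, 1]` on each chain edge.
#' @return Symmetric `n x n` coupling matrix.
#' @export
chain_coupling <- function(n, strength = 0.9) {
  m <- matrix(0, n, n)
  if (n > 1L) for (i in seq_len(n - 1L)) m[i, i + 1L] <- m[i + 1L, i] <- strength
  m
}

#' Star (hub) coupling backbone
#'
#' Couples one hub channel to every other channel; the ground-truth maximum
#' spanning tree is the star, with maximal leaf number and diameter 2.
#'
#' @param n Number of channels.
#' @param strength Coupling strength in `[0, 1]` on each hub edge.
#' @param center Hub channel index (default 1).
#' @return Symmetric `n x n` coupling matrix.
#' @export
star_coupling <- function(n, strength = 0.9, center = 1L) {
  m <- matrix(0, n, n)
  for (i in setdiff(seq_len(n), center)) m[center, i] <- m[i, center] <- strength
  m
}

#' Convex interpolation between chain and star backbones
#'
#' `star_frac = 0` gives the pure chain, `1` the pure star; intermediate
#' values mix both edge sets, realizing a continuous path-like-to-star-like
#' topology axis. The shared edge (1, 2) keeps the full strength at every
#' mixture, so the resulting coupling stays within `[0, strength]`.
#'
#' @param n Number of channels.
#' @param star_frac Mixture parameter in `[0, 1]`.
#' @param strength Total backbone strength in `[0, 1]`.
#' @return Symmetric `n x n` coupling matrix.
#' @export
interpolate_topology <- function(n, star_frac, strength = 0.85) {
  stopifnot(star_frac >= 0, star_frac <= 1, strength >= 0, strength <= 1)
  (1 - star_frac) * chain_coupling(n, strength) +
    star_frac * star_coupling(n, strength)
}

#' Sample a backbone tree on the path-to-star axis
#'
#' Builds a coupling backbone by sequential attachment: node 2 attaches to
#' node 1 (the hub); each further node attaches to the hub with probability
#' `star_frac` and to its predecessor otherwise. `star_frac = 0` gives the
#' path (2 leaves, maximal diameter), `1` the star (n - 1 leaves, diameter
#' 2), and the expected leaf number interpolates smoothly in between --
#' giving a continuous, directly interpretable topology axis with natural
#' realization-level variability. Draws from the current RNG state.
#'
#' @param n Number of channels.
#' @param star_frac Hub-attachment probability in `[0, 1]`.
#' @param strength Coupling strength on every backbone edge.
#' @return Symmetric `n x n` coupling matrix whose positive edges form a
#'   spanning tree.
#' @export
sample_backbone <- function(n, star_frac, strength = 0.85) {
  stopifnot(n >= 2L, star_frac >= 0, star_frac <= 1,
            strength >= 0, strength <= 1)
  m <- matrix(0, n, n)
  m[1L, 2L] <- m[2L, 1L] <- strength
  if (n > 2L) for (j in 3:n) {
    to <- if (stats::runif(1) < star_frac) 1L else j - 1L
    m[to, j] <- m[j, to] <- strength
  }
  m
}

#' Programmed routine-to-sleep-deprived topology shift
#'
#' Parameterizes how each group's coupling backbone moves along the
#' chain-to-star axis between the two recording conditions. Defaults encode
#' the contrast under study: both groups start intermediate at the routine
#' recording; after sleep deprivation patients shift toward the chain
#' (path-like, low leaf number) and controls toward the star (hub-like, high
#' leaf number).
#'
#' @param patient_routine,patient_sleep_deprived Star fraction of the patient
#'   backbone in each condition.
#' @param control_routine,control_sleep_deprived Same for controls.
#' @param subject_sd Subject-level Gaussian jitter of the star fraction
#'   (clipped to `[0, 1]`).
#' @return An object of class `topology_shift`.
#' @export
topology_shift <- function(patient_routine = 0.5, patient_sleep_deprived = 0.1,
                           control_routine = 0.5, control_sleep_deprived = 0.9,
                           subject_sd = 0.08) {
  vals <- c(patient_routine, patient_sleep_deprived,
            control_routine, control_sleep_deprived)
  stopifnot(all(vals >= 0 & vals <= 1), subject_sd >= 0)
  structure(list(patient = c(routine = patient_routine,
                             sleep_deprived = patient_sleep_deprived),
                 control = c(routine = control_routine,
                             sleep_deprived = control_sleep_deprived),
                 subject_sd = subject_sd),
            class = "topology_shift")
}

#' Null topology shift (no condition effect)
#'
#' @param star_frac Common star fraction for both groups and conditions.
#' @param subject_sd Subject-level jitter.
#' @return A [topology_shift()] with identical backbones everywhere.
#' @export
null_topology_shift <- function(star_frac = 0.5, subject_sd = 0.08) {
  topology_shift(star_frac, star_frac, star_frac, star_frac, subject_sd)
}

#' Specification of a synthetic two-group, two-condition cohort
#'
#' Mirrors the study design the package targets: a patient group and a
#' control group, each subject recorded under a routine and a sleep-deprived
#' condition, with a programmed group-by-condition change in coupling
#' topology.
#'
#' @param n_patients,n_controls Group sizes (>= 2 each).
#' @param n_channels,fs,n_samples,n_epochs,carrier_band,noise_sd,lag,phase_dev_sd,phase_tau
#'   Oscillator settings shared by all subjects; see [oscillator_spec()].
#' @param coupling_strength Backbone strength handed to
#'   [interpolate_topology()].
#' @param shift A [topology_shift()].
#' @param added_value_fraction Fraction of patients flagged as having a
#'   diagnostically informative sleep-deprived recording (metadata only).
#' @param channel_labels Optional channel labels; defaults to the retained
#'   channels of [default_montage()] when `n_channels` is 17.
#' @param seed Global seed; fans out to per-subject substreams.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 21L, n_controls = 17L, n_channels = 17L,
                        fs = 512, n_samples = 4096L, n_epochs = 4L,
                        carrier_band = c(8, 13), coupling_strength = 0.85,
                        lag = pi / 2, noise_sd = 0.25, phase_dev_sd = 3,
                        phase_tau = 0.25, shift = topology_shift(),
                        added_value_fraction = 15 / 21,
                        channel_labels = NULL, seed = 1L) {
  n_patients <- as.integer(n_patients); n_controls <- as.integer(n_controls)
  if (n_patients < 2L || n_controls < 2L)
    stop("need at least 2 subjects per group")
  stopifnot(inherits(shift, "topology_shift"),
            added_value_fraction >= 0, added_value_fraction <= 1,
            coupling_strength >= 0, coupling_strength <= 1)
  if (is.null(channel_labels) && n_channels == 17L)
    channel_labels <- montage_channels(default_montage())
  structure(list(n_patients = n_patients, n_controls = n_controls,
                 n_channels = as.integer(n_channels), fs = fs,
                 n_samples = as.integer(n_samples),
                 n_epochs = as.integer(n_epochs),
                 carrier_band = carrier_band,
                 coupling_strength = coupling_strength, lag = lag,
                 noise_sd = noise_sd, phase_dev_sd = phase_dev_sd,
                 phase_tau = phase_tau,
                 shift = shift, added_value_fraction = added_value_fraction,
                 channel_labels = channel_labels, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic cohort
#'
#' Draws, for every subject and condition, a star fraction from the group's
#' programmed value plus subject-level jitter, builds the corresponding
#' coupling backbone and generates epochs from a per-subject-condition
#' deterministic substream of the global seed.
#'
#' @param spec A [cohort_spec()].
#' @return A list of class `synthetic_cohort` with elements `manifest` (a
#'   data.frame: subject_id, group, condition, added_value, star_frac) and
#'   `epoch_sets` (named list, `"<subject_id>.<condition>"`).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  subjects <- data.frame(
    subject_id = c(sprintf("P%02d", seq_len(spec$n_patients)),
                   sprintf("C%02d", seq_len(spec$n_controls))),
    group = rep(c("patient", "control"), c(spec$n_patients, spec$n_controls)),
    stringsAsFactors = FALSE)
  n_added <- round(spec$added_value_fraction * spec$n_patients)
  subjects$added_value <- c(seq_len(spec$n_patients) <= n_added,
                            rep(FALSE, spec$n_controls))
  conditions <- c("routine", "sleep_deprived")
  rows <- list()
  sets <- list()
  k <- 0L
  for (si in seq_len(nrow(subjects))) {
    for (cond in conditions) {
      k <- k + 1L
      sub_seed <- substream_seed(spec$seed, k)
      drawn <- with_preserved_rng(sub_seed, {
        lambda <- min(max(spec$shift[[subjects$group[si]]][[cond]] +
                            stats::rnorm(1, 0, spec$shift$subject_sd), 0), 1)
        list(lambda = lambda,
             coupling = sample_backbone(spec$n_channels, lambda,
                                        spec$coupling_strength))
      })
      lambda <- drawn$lambda
      osc <- oscillator_spec(
        spec$n_channels, fs = spec$fs, n_samples = spec$n_samples,
        n_epochs = spec$n_epochs, carrier_band = spec$carrier_band,
        coupling = drawn$coupling,
        lag = spec$lag, noise_sd = spec$noise_sd,
        phase_dev_sd = spec$phase_dev_sd, phase_tau = spec$phase_tau,
        seed = substream_seed(sub_seed, 1L),
        channel_labels = spec$channel_labels)
      es <- generate_epochs(osc)
      es$subject_id <- subjects$subject_id[si]
      es$condition <- cond
      key <- paste(subjects$subject_id[si], cond, sep = ".")
      sets[[key]] <- es
      rows[[k]] <- data.frame(subject_id = subjects$subject_id[si],
                              group = subjects$group[si], condition = cond,
                              added_value = subjects$added_value[si],
                              star_frac = lambda, stringsAsFactors = FALSE)
    }
  }
  structure(list(manifest = do.call(rbind, rows), epoch_sets = sets,
                 spec = spec),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d patients + %d controls x 2 conditions\n",
              x$spec$n_patients, x$spec$n_controls))
  invisible(x)
}

#' Write a synthetic cohort to disk as ASCII matrices plus a CSV manifest
#'
#' Each subject-condition record is written as one tab-separated samples x
#' channels matrix (epochs concatenated back-to-back, so [select_epochs()]
#' with the generating epoch length recovers them bit-exactly), alongside a
#' `manifest.csv` that [read_manifest()] accepts.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- cohort$manifest
  man$file <- sprintf("%s_%s.txt", man$subject_id, man$condition)
  for (i in seq_len(nrow(man))) {
    key <- paste(man$subject_id[i], man$condition[i], sep = ".")
    es <- cohort$epoch_sets[[key]]
    rec <- eeg_record(do.call(cbind, es$epochs), es$channel_labels, es$fs)
    write_ascii_eeg(rec, file.path(dir, man$file[i]))
  }
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(man[, c("subject_id", "group", "condition", "file",
                           "added_value")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
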