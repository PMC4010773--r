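alpha_band <- band_definition("alpha", 8, 13)

test_that("oscillator specs are validated", {
  co <- chain_coupling(4, 0.8)
  bad <- co; bad[1, 2] <- 0.5
  expect_error(oscillator_spec(4, coupling = bad), "symmetric")
  expect_error(oscillator_spec(4, coupling = co, lag = 0), "lag")
  neg <- co; neg[co > 0] <- -0.5
  expect_error(oscillator_spec(4, coupling = neg), "\\[0, 1\\]")
  expect_error(oscillator_spec(4, n_samples = 100, carrier_band = c(1, 4)),
               "two cycles")
})

test_that("generation is deterministic given the seed", {
  sp <- oscillator_spec(5, n_samples = 512, n_epochs = 2,
                        coupling = chain_coupling(5, 0.7), noise_sd = 0.2,
                        seed = 123)
  e1 <- generate_epochs(sp)
  e2 <- generate_epochs(sp)
  expect_identical(e1$epochs, e2$epochs)
})

test_that("uncoupled channels show near-zero PLI", {
  sp <- oscillator_spec(4, n_samples = 4096, n_epochs = 4, noise_sd = 0.3,
                        seed = 2)
  W <- pli_matrix(bandpass(generate_epochs(sp), alpha_band))$weights
  expect_lt(mean(W[upper.tri(W)]), 0.15)
})

test_that("full coupling at a quarter-cycle lag saturates the PLI", {
  # narrow phase-deviation regime, where the analytic phase tracks the model
  # phase closely and the imposed constant lag is exact
  co <- matrix(0, 2, 2); co[1, 2] <- co[2, 1] <- 1
  sp <- oscillator_spec(2, n_samples = 2048, n_epochs = 2, coupling = co,
                        lag = pi / 2, noise_sd = 0, phase_dev_sd = 0.4,
                        phase_tau = 0.5, seed = 3)
  W <- pli_matrix(bandpass(generate_epochs(sp), alpha_band))$weights
  expect_gt(W[1, 2], 0.999)
})

test_that("a six-channel chain backbone is recovered as the spanning tree", {
  sp <- oscillator_spec(6, fs = 512, n_samples = 4096, n_epochs = 4,
                        coupling = chain_coupling(6, 0.9), noise_sd = 0.1,
                        seed = 1)
  W <- pli_matrix(bandpass(generate_epochs(sp), alpha_band))
  tr <- maximum_spanning_tree(W)
  tm <- tree_measures(tr)
  expect_equal(tm$leaf_number, 2L)
  expect_equal(tm$diameter, 5L)
  got <- apply(tr$edges[, 1:2], 1, function(e) paste(sort(e), collapse = "-"))
  want <- sprintf("ch%02d-ch%02d", 1:5, 2:6)
  expect_setequal(got, want)
})

test_that("noiseless strongly coupled backbones are recovered exactly", {
  set.seed(51)
  for (co in list(chain_coupling(17, 0.85), star_coupling(17, 0.85))) {
    sp <- oscillator_spec(17, n_samples = 4096, n_epochs = 4, coupling = co,
                          noise_sd = 0, seed = 77)
    W <- pli_matrix(bandpass(generate_epochs(sp), alpha_band))
    tr <- maximum_spanning_tree(W)
    got <- apply(tr$edges[, 1:2], 1, function(e) paste(sort(e), collapse = "-"))
    truth <- which(upper.tri(co) & co > 0, arr.ind = TRUE)
    labels <- sp$channel_labels
    want <- apply(truth, 1, function(e)
      paste(sort(labels[e]), collapse = "-"))
    expect_setequal(got, want)
  }
})

test_that("estimated PLI is monotone in coupling strength", {
  grid <- c(0, 0.25, 0.5, 0.75, 1)
  means <- vapply(grid, function(cc) {
    co <- matrix(0, 2, 2); co[1, 2] <- co[2, 1] <- cc
    mean(vapply(1:20, function(s) {
      sp <- oscillator_spec(2, n_samples = 4096, n_epochs = 4, coupling = co,
                            noise_sd = 0.1, seed = s)
      pli_matrix(bandpass(generate_epochs(sp), alpha_band))$weights[1, 2]
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) > -0.02))
  expect_gt(means[5], means[1] + 0.5)
})

test_that("uncoupled pairs exceed a block sign-flip null at the nominal rate", {
  # 45 uncoupled pairs; each pair's PLI is compared with the 95th percentile
  # of a null built by flipping the sign of the phase-difference series in
  # blocks longer than its correlation time
  sp <- oscillator_spec(10, n_samples = 4096, n_epochs = 2, noise_sd = 0.3,
                        seed = 4)
  es <- bandpass(generate_epochs(sp), alpha_band)
  set.seed(52)
  block <- 512L
  n_null <- 100L
  hits <- 0L; total <- 0L
  phases <- lapply(seq_len(10), function(i)
    lapply(es$epochs, function(e)
      instantaneous_phase(e[i, ], es$fs, band_low = 8)))
  for (i in 1:9) for (j in (i + 1):10) {
    obs <- mean(vapply(1:2, function(k)
      pli(phases[[i]][[k]], phases[[j]][[k]]), numeric(1)))
    null <- vapply(seq_len(n_null), function(r) {
      mean(vapply(1:2, function(k) {
        pa <- phases[[i]][[k]]; pb <- phases[[j]][[k]]
        ne <- max(pa$n_edge, pb$n_edge)
        keep <- seq.int(ne + 1L, length(pa$phase) - ne)
        d <- pa$phase[keep] - pb$phase[keep]
        d <- d - 2 * pi * floor((d + pi) / (2 * pi))
        s <- sign(d)
        nb <- ceiling(length(s) / block)
        flips <- rep(sample(c(-1, 1), nb, replace = TRUE),
                     each = block)[seq_along(s)]
        abs(mean(s * flips))
      }, numeric(1)))
    }, numeric(1))
    hits <- hits + (obs > quantile(null, 0.95))
    total <- total + 1L
  }
  rate <- hits / total
  expect_gte(rate, 0)
  expect_lte(rate, 0.2)
})

test_that("sampled backbones span the path-to-star axis", {
  set.seed(53)
  b0 <- sample_backbone(17, 0)
  expect_equal(sum(colSums(b0 > 0) == 1), 2L)      # path: two leaves
  b1 <- sample_backbone(17, 1)
  expect_equal(sum(b1[1, ] > 0), 16L)              # star: full hub
  for (lam in c(0.3, 0.7)) {
    b <- sample_backbone(17, lam)
    g <- igraph::graph_from_adjacency_matrix(b > 0, mode = "undirected")
    expect_true(igraph::is_connected(g))
    expect_equal(sum(b[upper.tri(b)] > 0), 16L)    # spanning tree
  }
})

test_that("cohorts are deterministic and reject tiny groups", {
  spec <- cohort_spec(n_patients = 3, n_controls = 3, n_channels = 5,
                      n_samples = 512, n_epochs = 1, seed = 9)
  c1 <- generate_cohort(spec)
  c2 <- generate_cohort(spec)
  expect_identical(c1$manifest, c2$manifest)
  expect_identical(c1$epoch_sets[["P01.routine"]]$epochs,
                   c2$epoch_sets[["P01.routine"]]$epochs)
  expect_equal(nrow(c1$manifest), 12L)  # 6 subjects x 2 conditions
  expect_true(all(table(c1$manifest$subject_id) == 2L))
  expect_error(cohort_spec(n_patients = 1), "at least 2")
})

test_that("the programmed topology shift moves leaf number as designed", {
  # reduced cohort: patients shift toward the path, controls toward the star
  spec <- cohort_spec(n_patients = 6, n_controls = 6, n_channels = 10,
                      n_samples = 2048, n_epochs = 2,
                      shift = topology_shift(0.5, 0.05, 0.5, 0.95,
                                             subject_sd = 0.05),
                      seed = 11)
  co <- generate_cohort(spec)
  res <- run_pipeline(co, out_dir = withr::local_tempdir(),
                      bands = list(alpha = alpha_band), power_bands = NULL,
                      n_surrogates = 0, seed = 11)
  it <- res$tables$interaction
  leaf <- it[it$measure == "leaf_number" & it$scope == "all", ]
  expect_lt(leaf$mean_diff_patient, 0)
  expect_gt(leaf$mean_diff_control, 0)
  expect_lt(leaf$p, 0.05)
})

test_that("cohorts round-trip through the ASCII export", {
  spec <- cohort_spec(n_patients = 2, n_controls = 2, n_channels = 4,
                      n_samples = 512, n_epochs = 2, seed = 21)
  co <- generate_cohort(spec)
  dir <- withr::local_tempdir()
  man_path <- write_cohort(co, dir)
  man <- read_manifest(man_path)
  expect_equal(nrow(man), 8L)
  rec <- read_ascii_eeg(man$file[1], spec$fs)
  es <- select_epochs(rec, n_epochs = 2, epoch_len = 512)
  key <- paste(man$subject_id[1], man$condition[1], sep = ".")
  expect_equal(es$epochs[[1]], co$epoch_sets[[key]]$epochs[[1]],
               tolerance = 1e-4)  # ASCII export rounds to 6 decimals
})
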