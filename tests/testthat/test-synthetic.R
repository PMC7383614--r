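test_that("generation is deterministic and replica substreams are stable", {
  spec <- ensemble_spec(p_RR = 15, p_SS = 5, n_replicas = 3,
                        frame_interval_ps = 0.1, seed = 77)
  a <- generate_ensemble(spec)
  b <- generate_ensemble(spec)
  expect_identical(a$ensemble$replicas, b$ensemble$replicas)
  expect_identical(a$ground_truth$states, b$ground_truth$states)
  # replica 1 is unchanged when more replicas are requested
  spec5 <- ensemble_spec(p_RR = 15, p_SS = 5, n_replicas = 5,
                         frame_interval_ps = 0.1, seed = 77)
  c5 <- generate_ensemble(spec5)
  expect_identical(c5$ensemble$replicas[[1]], a$ensemble$replicas[[1]])
})

test_that("spec validation rejects impossible ground truths", {
  expect_error(ensemble_spec(60, 50), "p_RR")
  expect_error(ensemble_spec(10, 5, persistence = 1), "persistence")
  expect_error(ensemble_spec(10, 5, n_replicas = 0), "replica")
})

test_that("zero-occupancy specs yield purely non-reactive ensembles", {
  out <- generate_ensemble(ensemble_spec(p_RR = 0, p_SS = 0, n_replicas = 2,
                                         frame_interval_ps = 0.2, seed = 1))
  expect_true(all(unlist(out$ground_truth$states) == "nonreactive"))
  tab <- classify_frames(out$ensemble)
  expect_false(any(tab$proRR))
  expect_false(any(tab$proSS))
})

test_that("intended state labels are recovered exactly at zero noise", {
  set.seed(99)
  states <- sample(c("proRR", "proSS", "nonreactive"), 300, replace = TRUE)
  for (st in states) {
    cl <- classify_frame(realize_geometry(st))
    expect_identical(cl$is_proRR, st == "proRR")
    expect_identical(cl$is_proSS, st == "proSS")
  }
})

test_that("infeasible criterion windows raise a construction error", {
  # theta1B >= 178 requires theta1A <= ~123 given the 59-degree ring angle,
  # which lies outside the theta1A window: no placement exists
  impossible <- nac_definition(theta1B_range = c(178, 180))
  set.seed(1)
  expect_error(realize_geometry("proRR", impossible), "infeasible")
})

test_that("empirical state frequencies obey the Markov-chain CLT", {
  p <- 20; rho <- 0.5
  out <- generate_ensemble(ensemble_spec(p_RR = p, p_SS = 0,
                                         persistence = rho, n_replicas = 1,
                                         replica_length_ps = 50,
                                         frame_interval_ps = 0.005,
                                         seed = 123))
  L <- 1e4
  expect_length(out$ground_truth$states[[1]], L)
  emp <- out$ground_truth$empirical_freq[["proRR"]]
  # asymptotic variance of the occupancy fraction under a single
  # persistence parameter: pi(1-pi) (1+rho)/(1-rho) / L
  sigma <- sqrt(0.2 * 0.8 * (1 + rho) / (1 - rho) / L) * 100
  expect_lt(abs(emp - p), 3 * sigma)
  # classification reproduces the labels exactly
  st <- nac_frequencies(out$ensemble)
  expect_equal(st$pooled_freq_RR, emp)
})

test_that("library mutations use only the design positions and alphabet", {
  lib <- generate_library(60, seed = 14)
  expect_equal(nrow(lib$manifest), 60L)
  expect_length(lib$specs, 60L)
  for (m in lib$manifest$mutations) {
    parsed <- parse_mutations(strsplit(m, "_")[[1]])
    expect_true(all(parsed$new %in% design_alphabet()))
    expect_true(all(as.character(parsed$position) %in%
                      names(design_positions())))
    expect_true(all(parsed$wt ==
                      design_positions()[as.character(parsed$position)]))
    expect_true(all(parsed$wt != parsed$new))
  }
  lib2 <- generate_library(60, seed = 14)
  expect_identical(lib$manifest, lib2$manifest)
  expect_equal(lib$manifest$target,
               ifelse(lib$manifest$p_RR >= lib$manifest$p_SS, "RR", "SS"))
})

test_that("the synthetic provider extends cumulative replicas in place", {
  lib <- generate_library(2, function(n)
    data.frame(p_RR = rep(10, n), p_SS = rep(1, n)),
    seed = 4, frame_interval_ps = 0.2)
  prov <- make_synthetic_provider(lib)
  e3 <- prov("D001", 3L, 10, TRUE)
  e6 <- prov("D001", 6L, 10, TRUE)
  expect_length(e6$replicas, 6L)
  expect_identical(e6$replicas[1:3], e3$replicas)
  # standalone requests use a disjoint substream namespace
  s3 <- prov("D001", 3L, 10, FALSE)
  expect_false(identical(s3$replicas[[1]]$coords, e3$replicas[[1]]$coords))
  expect_error(prov("nope", 3L, 10, TRUE), "unknown design")
})
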