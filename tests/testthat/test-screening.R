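test_that("vectorised classification agrees per frame with classify_frame", {
  out <- generate_ensemble(ensemble_spec(p_RR = 30, p_SS = 30,
                                         n_replicas = 2,
                                         frame_interval_ps = 1, noise = 0.1,
                                         seed = 13))
  ens <- out$ensemble
  tab <- classify_frames(ens)
  for (i in seq_len(nrow(tab))) {
    lf <- label_frame(get_frame(ens, tab$replica_id[i], tab$frame[i]),
                      default_role_map())
    cl <- classify_frame(lf)
    expect_identical(tab$proRR[i], cl$is_proRR)
    expect_identical(tab$proSS[i], cl$is_proSS)
  }
})

test_that("NAC frequencies respect binomial sampling bounds", {
  out <- generate_ensemble(ensemble_spec(p_RR = 20, p_SS = 0,
                                         n_replicas = 5,
                                         frame_interval_ps = 0.1, seed = 31))
  st <- nac_frequencies(out$ensemble)
  expect_equal(st$n_frames_total, 500L)
  bound <- 3 * sqrt(0.2 * 0.8 / 500) * 100   # 5.37 points
  expect_lt(abs(st$freq_RR - 20), bound)
  expect_equal(st$freq_SS, 0)
  # frequency equals the realised ground-truth frequency exactly at noise 0
  expect_equal(st$pooled_freq_RR,
               unname(out$ground_truth$empirical_freq["proRR"]))
})

test_that("counts are conserved across replicas and zero when non-reactive", {
  out <- generate_ensemble(ensemble_spec(p_RR = 12, p_SS = 7,
                                         n_replicas = 4,
                                         frame_interval_ps = 0.2, seed = 8))
  st <- nac_frequencies(out$ensemble)
  per_rep_counts <- st$per_replica_freq_RR / 100 * st$n_frames_per_replica
  expect_equal(sum(per_rep_counts), st$n_nac_RR)
  expect_equal(st$pooled_freq_RR, 100 * st$n_nac_RR / st$n_frames_total)
  none <- generate_ensemble(ensemble_spec(p_RR = 0, p_SS = 0,
                                          n_replicas = 2,
                                          frame_interval_ps = 0.5, seed = 2))
  st0 <- nac_frequencies(none$ensemble)
  expect_equal(st0$freq_RR, 0)
  expect_equal(st0$freq_SS, 0)
})

test_that("the ee predictor follows the normalised-difference formula", {
  expect_equal(ee_from_nac(5.63, 0), 100)
  expect_equal(ee_from_nac(7, 7), 0)
  p <- predict_ee(list(freq_RR = 7, freq_SS = 7))
  expect_equal(p$ee_rounded, 0)
  expect_equal(p$preferred, "none")
  expect_equal(p$nac_pref, 7)
  expect_error(ee_from_nac(0, 0), "undefined")
  expect_error(predict_ee(list(freq_RR = 0, freq_SS = 0)), "undefined")
  # antisymmetry and bounds under random inputs
  set.seed(12)
  for (i in 1:200) {
    a <- runif(1, 0, 50); b <- runif(1, 0, 50)
    if (a + b == 0) next
    ee <- ee_from_nac(a, b)
    expect_equal(ee, -ee_from_nac(b, a))
    expect_lte(abs(ee), 100)
  }
})

test_that("reported rounding is half-away-from-zero to integer percent", {
  expect_equal(round_half_away(98.5), 99)
  expect_equal(round_half_away(-98.5), -99)
  expect_equal(round_half_away(96.49), 96)
  p <- predict_ee(list(freq_RR = 3.86, freq_SS = 0.040))
  expect_equal(p$ee_rounded, 98)
  expect_equal(p$preferred, "RR")
})

test_that("cascade semantics: elimination is permanent and sets are nested", {
  lib <- generate_library(10, function(n)
    data.frame(p_RR = c(rep(20, 3), rep(6, 7)),
               p_SS = c(rep(0.05, 3), rep(6, 7))),
    seed = 6, frame_interval_ps = 0.05)
  prov <- make_synthetic_provider(lib)
  cfg <- cascade_config(data.frame(
    label = c("r1", "r2", "r3"), n_replicas = c(3L, 5L, 8L),
    replica_length_ps = 10, ee_threshold = 95,
    nac_pref_threshold = NA_real_, cumulative = TRUE))
  res <- run_cascade(lib$manifest, cfg, prov)
  expect_true(all(diff(res$counts$n_surviving) <= 0))
  for (r in 2:3) {
    expect_true(all(res$survivors[[r]] %in% res$survivors[[r - 1]]))
    evaluated_r <- res$audit$design_id[res$audit$round == r]
    expect_true(all(evaluated_r %in% res$survivors[[r - 1]]))
  }
  # every survivor's audit trail passes every earlier round
  for (id in res$survivors[[3]]) {
    trail <- res$audit[res$audit$design_id == id, ]
    expect_true(all(trail$pass))
  }
})

test_that("an empty library yields an empty cascade result", {
  cfg <- default_cascade_config("1a")
  res <- run_cascade(data.frame(design_id = character(0),
                                target = character(0)),
                     cfg, function(...) stop("never called"))
  expect_equal(res$initial, 0L)
  expect_length(res$survivors, 0L)
})

test_that("provider failures mark designs not-evaluated, not surviving", {
  lib <- generate_library(3, function(n)
    data.frame(p_RR = rep(20, n), p_SS = rep(0.1, n)),
    seed = 3, frame_interval_ps = 0.1)
  prov0 <- make_synthetic_provider(lib)
  prov <- function(id, n, len, cum) {
    if (id == "D002") stop("engine crashed")
    prov0(id, n, len, cum)
  }
  cfg <- cascade_config(data.frame(
    label = "r1", n_replicas = 5L, replica_length_ps = 10,
    ee_threshold = 90, nac_pref_threshold = NA_real_, cumulative = TRUE))
  res <- run_cascade(lib$manifest, cfg, prov)
  expect_equal(res$not_evaluated, "D002")
  expect_false("D002" %in% res$survivors[[1]])
  expect_equal(res$initial, 2L)
})

test_that("cascade pass fractions follow the printed-percentage convention", {
  expect_equal(summarize_cascade(4125, 63), 1.5)
  expect_equal(summarize_cascade(4732, 181), 3.8)
  expect_equal(summarize_cascade(6232, 442), 7.1)
  expect_equal(summarize_cascade(250, 250), 100.0)
  expect_error(summarize_cascade(0, 0), "positive")
  expect_error(summarize_cascade(10, 11), "exceed")
})

test_that("selection ranks by [NAC]pref with documented tie-breaks", {
  ref <- leh_reference_designs()
  stil <- ref[ref$substrate == "3a" & ref$target == "RR", ]
  cand <- data.frame(design_id = stil$design_id,
                     ee_pred = ee_from_nac(stil$nac_rr, stil$nac_ss),
                     nac_pref = pmax(stil$nac_rr, stil$nac_ss))
  top3 <- select_top_designs(cand, 3, target = "RR", ee_min = 97)
  expect_equal(top3$design_id, c("51A", "52A", "60A"))
  expect_equal(top3$nac_pref, c(28.2, 24.9, 22.7))
  # wrong-sign candidates are excluded
  cand2 <- rbind(cand, data.frame(design_id = "neg", ee_pred = -99,
                                  nac_pref = 99))
  expect_false("neg" %in%
                 select_top_designs(cand2, 5, "RR", ee_min = 0)$design_id)
  # exact nac_pref tie: larger |ee| first, then design_id
  tied <- data.frame(design_id = c("b", "a", "c"),
                     ee_pred = c(98, 99, 98), nac_pref = 10)
  sel <- select_top_designs(tied, 3, "RR")
  expect_equal(sel$design_id, c("a", "b", "c"))
  expect_warning(short <- select_top_designs(tied, 5, "RR"), "eligible")
  expect_true(attr(short, "short_selection"))
  expect_equal(nrow(short), 3L)
})

test_that("cavity-volume deltas match hand summation and triage correctly", {
  vols <- aa_volumes()
  d0 <- delta_cavity_volume(character(0))
  expect_equal(d0$delta_volume, 0)
  expect_false(d0$flagged)
  d1 <- delta_cavity_volume("M32L")
  expect_equal(d1$delta_volume, unname(vols["M"] - vols["L"]))
  # mutant 60A set: positive enlargement of order tens of A^3
  d60 <- delta_cavity_volume(c("M32L", "L35G", "I80W", "L103V", "F139L"))
  hand <- (vols["M"] - vols["L"]) + (vols["L"] - vols["G"]) +
    (vols["I"] - vols["W"]) + (vols["L"] - vols["V"]) +
    (vols["F"] - vols["L"])
  expect_equal(d60$delta_volume, unname(hand))
  expect_gt(d60$delta_volume, 10)
  expect_lt(d60$delta_volume, 100)
  expect_false(d60$flagged)
  big <- delta_cavity_volume(c("W32A", "F35G"))
  expect_true(big$flagged)                      # 269 A^3 enlargement
  expect_error(delta_cavity_volume("M32X"), "unknown residue")
})

test_that("mutation parsing and design-variant validation work", {
  p <- parse_mutations(c("M32L", "F139W"))
  expect_equal(p$position, c(32L, 139L))
  expect_error(parse_mutations("32L"), "unparseable")
  expect_error(parse_mutations("M999L"), "outside")
  v <- design_variant("60A", c("M32L", "L35G"), target = "RR")
  expect_s3_class(v, "design_variant")
  expect_error(design_variant("x", "A10G", target = "RR"),
               "outside the design set")
  expect_silent(design_variant("y", "A10G", target = "RR",
                               library_design = FALSE))
})

test_that("report tables are deterministic and round-trip parseable", {
  ref <- leh_reference_designs()
  sub <- ref[ref$substrate == "1a", ]
  designs <- data.frame(design_id = sub$design_id,
                        mutations = sub$mutations,
                        freq_RR = sub$nac_rr, freq_SS = sub$nac_ss)
  path <- tempfile(fileext = ".tsv")
  write_design_table(designs, path)
  back <- read.delim(path)
  expect_equal(nrow(back), 10L)
  expect_equal(back$ee_pred, sub$ee_reported)

  lib <- generate_library(4, function(n)
    data.frame(p_RR = rep(25, n), p_SS = rep(0.05, n)),
    seed = 5, frame_interval_ps = 0.1)
  cfg <- cascade_config(data.frame(
    label = c("r1", "r2"), n_replicas = c(2L, 4L), replica_length_ps = 10,
    ee_threshold = 95, nac_pref_threshold = NA_real_, cumulative = TRUE))
  res <- run_cascade(lib$manifest, cfg, make_synthetic_provider(lib))
  cpath <- tempfile(fileext = ".tsv")
  write_cascade_table(res, cfg, cpath)
  ctab <- read.delim(cpath)
  expect_equal(nrow(ctab), 3L)   # two rounds + pass-percentage row
  expect_equal(ctab$n_surviving[1:2], res$counts$n_surviving)
  expect_equal(ctab$n_surviving[3],
               summarize_cascade(res$initial, res$counts$n_surviving[2]))
})
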