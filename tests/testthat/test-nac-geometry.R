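test_that("a frame built inside the proRR windows classifies as proRR only", {
  lf <- make_geom_frame(d1 = 2.8, t1a = 145, t1b = 145, hb = 2.9,
                        attacked = "RR")
  # verify the construction with the distance/angle primitives first
  xyz <- lf$role_xyz
  expect_equal(dist3d(xyz["WAT_O", ], xyz["C_RR", ]), 2.8, tolerance = 1e-9)
  expect_equal(angle3d(xyz["WAT_O", ], xyz["C_RR", ], xyz["O_EPOX", ]), 145,
               tolerance = 1e-9)
  expect_equal(angle3d(xyz["WAT_O", ], xyz["C_RR", ], xyz["C_SS", ]), 145,
               tolerance = 1e-9)
  cl <- classify_frame(lf)
  expect_true(cl$is_proRR)
  expect_false(cl$is_proSS)
  expect_length(cl$failed_criteria$proRR, 0L)
  expect_gt(length(cl$failed_criteria$proSS), 0L)
})

test_that("window bounds are inclusive", {
  lf <- make_geom_frame(d1 = 2.8, t1a = 128, t1b = 145)
  expect_true(classify_frame(lf)$is_proRR)
  lf2 <- make_geom_frame(d1 = 3.22, t1a = 145, t1b = 145)
  expect_true(classify_frame(lf2)$is_proRR)
  # upper angle bound: 163 is attainable only with theta1A below ~138
  # (the two attack angles share the 59-degree epoxide ring angle)
  lf4 <- make_geom_frame(d1 = 2.8, t1a = 133, t1b = 163)
  expect_true(classify_frame(lf4)$is_proRR)
  lf3 <- make_geom_frame(d1 = 2.8, t1a = 127.9, t1b = 145)
  cl3 <- classify_frame(lf3)
  expect_false(cl3$is_proRR)
  expect_true("theta1A" %in% cl3$failed_criteria$proRR)
})

test_that("water far from both carbons fails both modes on distance", {
  lf <- make_geom_frame(water_at = c(0.735, 10, 0))
  cl <- classify_frame(lf)
  expect_false(cl$is_proRR)
  expect_false(cl$is_proSS)
  expect_true("d1" %in% cl$failed_criteria$proRR)
  expect_true("d1" %in% cl$failed_criteria$proSS)
})

test_that("swapping the C_RR/C_SS roles swaps the two flags", {
  set.seed(42)
  swapped <- role_map(local({
    m <- unclass(default_role_map())
    tmp <- m[["C_RR"]]; m[["C_RR"]] <- m[["C_SS"]]; m[["C_SS"]] <- tmp
    m
  }))
  states <- sample(c("proRR", "proSS", "nonreactive"), 60, replace = TRUE)
  for (st in states) {
    lf <- realize_geometry(st)
    cl <- classify_frame(lf)
    lf2 <- label_frame(lf$frame, swapped)
    cl2 <- classify_frame(lf2)
    expect_identical(cl$is_proRR, cl2$is_proSS)
    expect_identical(cl$is_proSS, cl2$is_proRR)
  }
})

test_that("widening any criterion window never turns a flag off", {
  set.seed(77)
  base <- nac_definition()
  wider <- list(
    nac_definition(d1_range = c(0, 4.5)),
    nac_definition(theta1A_range = c(100, 180)),
    nac_definition(theta1B_range = c(100, 180)),
    nac_definition(hbond_dist_range = c(0, 5))
  )
  for (i in 1:40) {
    st <- sample(c("proRR", "proSS", "nonreactive"), 1)
    lf <- realize_geometry(st, noise = 0.15)
    cl <- classify_frame(lf, base)
    for (w in wider) {
      clw <- classify_frame(lf, w)
      if (cl$is_proRR) expect_true(clw$is_proRR)
      if (cl$is_proSS) expect_true(clw$is_proSS)
    }
  }
})

test_that("nac_definition validates its windows and pair count", {
  expect_error(nac_definition(d1_range = c(3, 1)), "range")
  expect_error(nac_definition(hbond_pairs = default_hbond_pairs()[1:4]),
               "five")
  expect_error(nac_definition(hbond_mode = "hydrogen"), "hydrogen role")
})

test_that("NAC definitions round-trip through YAML", {
  defn <- nac_definition(d1_range = c(0, 3.0), theta1A_range = c(130, 160))
  path <- tempfile(fileext = ".yml")
  write_nac_definition(defn, path)
  back <- read_nac_definition(path)
  expect_equal(back$d1_range, c(0, 3.0))
  expect_equal(back$theta1A_range, c(130, 160))
  expect_equal(back$hbond_pairs, defn$hbond_pairs)
})

test_that("an idealized designed pose passes the static validator", {
  # free-coordinate pose: water on the attack line at 1.8 A, linear attack
  # angle, non-attacked carbon beyond 3.8 A, all H-bonds formed (the pose
  # validator checks pure geometry, not bonding realism)
  w <- c(-1.8, 0, 0)
  coords <- rbind(w,
                  c(0, 0, 0),        # C_RR (attacked)
                  c(2.5, 0, 0),      # C_SS -> d(W, C_SS) = 4.3
                  c(1.43, 0, 0),     # O_EPOX -> attack angle 180
                  c(1.43, 2.9, 0), c(1.43, -2.9, 0),
                  w + c(0, 2.9, 0), w + c(0, -2.9, 0), w + c(0, 0, 2.9))
  lf <- label_frame(frame(unclass(default_role_map()), coords),
                    default_role_map())
  rep <- validate_design_pose(lf, attacked = "RR")
  expect_true(attr(rep, "overall"))
  expect_true(all(rep$pass))
  expect_equal(rep$measured[rep$constraint == "attack_angle"], 180)
  expect_gt(rep$measured[rep$constraint == "min_dist_nonattacked"], 3.8)
})

test_that("a too-close non-attacked carbon fails that constraint", {
  cst <- design_pose_constraints()
  w <- c(-1.8, 0, 0)                # 1.8 A from C_RR, 3.27 A from C_SS
  lf <- make_geom_frame(water_at = w)
  d_other <- dist3d(w, c(1.47, 0, 0))
  rep <- validate_design_pose(lf, cst, attacked = "RR")
  expect_false(attr(rep, "overall"))
  expect_false(rep$pass[rep$constraint == "min_dist_nonattacked"])
  expect_equal(rep$measured[rep$constraint == "min_dist_nonattacked"],
               d_other)
})

test_that("random poses agree with an independent per-constraint oracle", {
  set.seed(55)
  cst <- design_pose_constraints()
  for (i in 1:50) {
    w <- rnorm(3, sd = 2.5)
    lf <- make_geom_frame(water_at = w, hb = runif(1, 2.0, 4.5))
    rep <- validate_design_pose(lf, cst, attacked = "SS")
    xyz <- lf$role_xyz
    expect_equal(rep$pass[rep$constraint == "attack_distance"],
                 abs(dist3d(xyz["WAT_O", ], xyz["C_SS", ]) - 1.8) <= 0.4)
    expect_equal(rep$pass[rep$constraint == "attack_angle"],
                 abs(angle3d(xyz["WAT_O", ], xyz["C_SS", ],
                             xyz["O_EPOX", ]) - 180) <= 15)
    expect_equal(rep$pass[rep$constraint == "min_dist_nonattacked"],
                 dist3d(xyz["WAT_O", ], xyz["C_RR", ]) > 3.8)
    expect_equal(rep$pass[rep$constraint == "hbond_WAT_O_Y53_OH"],
                 dist3d(xyz["WAT_O", ], xyz["Y53_OH", ]) <= 3.5)
    expect_equal(attr(rep, "overall"), all(rep$pass))
  }
})
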