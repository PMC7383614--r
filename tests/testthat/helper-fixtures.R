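# Test-side inverse construction of an active-site frame, independent of the
# package generator: epoxide triangle (C-C 1.47 A, C-O 1.43 A) with the
# water oxygen placed at prescribed attack distance/angles and every H-bond
# acceptor at a prescribed distance from its donor.
make_geom_frame <- function(d1 = 2.8, t1a = 145, t1b = 145, hb = 2.9,
                            attacked = "RR", water_at = NULL) {
  c_rr <- c(0, 0, 0)
  c_ss <- c(1.47, 0, 0)
  oe <- c(0.735, sqrt(1.43^2 - 0.735^2), 0)
  c_att <- if (attacked == "RR") c_rr else c_ss
  c_oth <- if (attacked == "RR") c_ss else c_rr
  if (is.null(water_at)) {
    e1 <- (oe - c_att); e1 <- e1 / sqrt(sum(e1^2))
    e2 <- (c_oth - c_att); e2 <- e2 / sqrt(sum(e2^2))
    cg <- sum(e1 * e2)
    f <- e2 - cg * e1; f <- f / sqrt(sum(f^2))
    x <- cos(t1a * pi / 180)
    y <- (cos(t1b * pi / 180) - x * cg) / sqrt(1 - cg^2)
    z2 <- 1 - x^2 - y^2
    stopifnot(z2 >= -1e-12)
    u <- x * e1 + y * f + sqrt(max(0, z2)) * pracma_cross(e1, f)
    w <- c_att + d1 * u
  } else {
    w <- water_at
  }
  unit <- function(v) v / sqrt(sum(v^2))
  coords <- rbind(
    w,                                  # OW:300
    c_rr, c_ss, oe,                     # C1, C2, OE :201
    oe + hb * c(0, 0, 1),               # OD1:101
    oe + hb * c(0, 0, -1),              # OD2:101
    w + hb * c(0, 0, 1),                # OD1:132
    w + hb * c(0, 0, -1),               # OH:53
    w + hb * unit(c(1, 1, 1)))          # ND2:55
  label_frame(frame(unclass(default_role_map()), coords),
              default_role_map())
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Planted occupancy sampler for the separable-library cascade scenario:
# 20 strongly (R,R)-selective designs among 80 unselective ones.
planted_sampler <- function(n) {
  stopifnot(n == 100L)
  data.frame(p_RR = c(rep(15, 20), rep(5, 80)),
             p_SS = c(rep(0.1, 20), rep(5, 80)))
}

# Uniform-threshold cascade used for the planted-recovery scenario.
planted_cascade_config <- function() {
  cascade_config(data.frame(
    label = c("5x10ps", "10x10ps", "20x10ps", "40x10ps", "80x10ps",
              "5x100ps"),
    n_replicas = c(5L, 10L, 20L, 40L, 80L, 5L),
    replica_length_ps = c(10, 10, 10, 10, 10, 100),
    ee_threshold = 97,
    nac_pref_threshold = c(NA, NA, NA, NA, 5, 5),
    cumulative = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE)))
}
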