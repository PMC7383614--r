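#' Classify one frame's attack mode(s)
#'
#' Tests a labeled frame against a [nac_definition()] for both attack modes.
#' For mode `m` with attacked carbon `C_m` (`C_RR` for proRR, `C_SS` for
#' proSS) the mode flag is true iff
#' `d1 = |WAT_O - C_m|` lies in `d1_range`, the attack angles
#' `theta1A = angle(WAT_O, C_m, O_EPOX)` and
#' `theta1B = angle(WAT_O, C_m, C_other)` lie in their windows, and all five
#' H-bond criteria hold.  The two flags are independent: a frame may be a
#' NAC for both modes or for neither; all bounds are inclusive.
#'
#' @param lf A [label_frame()]ed frame.
#' @param defn A [nac_definition()].
#' @return An `attack_classification`: fields `is_proRR`, `is_proSS` and
#'   `failed_criteria` (a list with one character vector of criterion labels
#'   per mode, empty exactly when the mode flag is true).
#' @export
classify_frame <- function(lf, defn = nac_definition()) {
  stopifnot(inherits(lf, "nac_labeled_frame"), inherits(defn, "nac_definition"))
  xyz <- lf$role_xyz
  need <- unique(c("WAT_O", "C_RR", "C_SS", "O_EPOX",
                   unlist(defn$hbond_pairs)))
  missing <- setdiff(need, rownames(xyz))
  if (length(missing))
    stop("classify_frame(): unresolved role(s): ",
         paste(missing, collapse = ", "), call. = FALSE)

  hb_failed <- character(0)
  for (i in seq_along(defn$hbond_pairs)) {
    p <- defn$hbond_pairs[[i]]
    d <- dist3d(xyz[p[1L], ], xyz[p[2L], ])
    if (!.in_range(d, defn$hbond_dist_range))
      hb_failed <- c(hb_failed, sprintf("hbond%d_dist", i))
    if (defn$hbond_mode == "hydrogen") {
      ang <- angle3d(xyz[p[1L], ], xyz[p[3L], ], xyz[p[2L], ])
      if (!.in_range(ang, defn$hbond_angle_range))
        hb_failed <- c(hb_failed, sprintf("hbond%d_angle", i))
    }
  }

  eval_mode <- function(c_att, c_other) {
    failed <- character(0)
    d1 <- dist3d(xyz["WAT_O", ], xyz[c_att, ])
    if (!.in_range(d1, defn$d1_range)) failed <- c(failed, "d1")
    t1a <- angle3d(xyz["WAT_O", ], xyz[c_att, ], xyz["O_EPOX", ])
    if (!.in_range(t1a, defn$theta1A_range)) failed <- c(failed, "theta1A")
    t1b <- angle3d(xyz["WAT_O", ], xyz[c_att, ], xyz[c_other, ])
    if (!.in_range(t1b, defn$theta1B_range)) failed <- c(failed, "theta1B")
    c(failed, hb_failed)
  }
  f_rr <- eval_mode("C_RR", "C_SS")
  f_ss <- eval_mode("C_SS", "C_RR")
  structure(list(is_proRR = !length(f_rr), is_proSS = !length(f_ss),
                 failed_criteria = list(proRR = f_rr, proSS = f_ss)),
            class = "attack_classification")
}

# Vectorized classification of one replica coordinate block.
# coords: L x n_atoms x 3 array; role_idx: named integer index into atoms.
# Returns list(proRR =, proSS = logical vectors of length L).
.classify_block <- function(coords, role_idx, defn) {
  g <- function(role) coords[, role_idx[[role]], , drop = FALSE][, 1L, ]
  L <- dim(coords)[1L]
  as_mat <- function(m) if (is.null(dim(m))) matrix(m, nrow = 1L) else m
  W <- as_mat(g("WAT_O")); CR <- as_mat(g("C_RR")); CS <- as_mat(g("C_SS"))
  OE <- as_mat(g("O_EPOX"))

  hb_ok <- rep(TRUE, L)
  for (i in seq_along(defn$hbond_pairs)) {
    p <- defn$hbond_pairs[[i]]
    d <- .dist_rows(as_mat(g(p[1L])), as_mat(g(p[2L])))
    hb_ok <- hb_ok & .in_range(d, defn$hbond_dist_range)
    if (defn$hbond_mode == "hydrogen") {
      ang <- .angle_rows(as_mat(g(p[1L])), as_mat(g(p[3L])), as_mat(g(p[2L])))
      hb_ok <- hb_ok & .in_range(ang, defn$hbond_angle_range)
    }
  }
  mode_ok <- function(CA, CO) {
    ok <- .in_range(.dist_rows(W, CA), defn$d1_range)
    ok <- ok & .in_range(.angle_rows(W, CA, OE), defn$theta1A_range)
    ok <- ok & .in_range(.angle_rows(W, CA, CO), defn$theta1B_range)
    ok & hb_ok
  }
  list(proRR = mode_ok(CR, CS), proSS = mode_ok(CS, CR))
}

# Resolve role atom indices for an ensemble; errors name the role.
.role_indices <- function(ens, roles) {
  if (!inherits(roles, "nac_role_map")) roles <- role_map(roles)
  idx <- match(unclass(roles), ens$atom_ids)
  if (anyNA(idx)) {
    bad <- names(roles)[is.na(idx)]
    stop("role(s) not resolvable in ensemble: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  setNames(as.integer(idx), names(roles))
}

#' Classify every frame of an ensemble
#'
#' Vectorized equivalent of [classify_frame()] over all replicas; exact
#' per-frame agreement with [classify_frame()] is an invariant of the
#' package.
#'
#' @param ens A [ensemble()].
#' @param roles A [role_map()].
#' @param defn A [nac_definition()].
#' @return A data frame with columns `replica_id`, `frame`, `proRR`, `proSS`.
#' @export
classify_frames <- function(ens, roles = default_role_map(),
                            defn = nac_definition()) {
  stopifnot(inherits(ens, "nac_ensemble"))
  role_idx <- .role_indices(ens, roles)
  out <- lapply(ens$replicas, function(rep) {
    cl <- .classify_block(rep$coords, role_idx, defn)
    data.frame(replica_id = rep$replica_id,
               frame = seq_len(dim(rep$coords)[1L]),
               proRR = cl$proRR, proSS = cl$proSS)
  })
  do.call(rbind, out)
}

#' Validate a static designed pose
#'
#' Checks a designed (pre-MD) pose against [design_pose_constraints()]:
#' attack distance, attack-angle linearity, minimum distance to the
#' non-attacked carbon, and formation of the four catalytic H-bonds.
#'
#' @param lf A [label_frame()]ed frame.
#' @param cst A [design_pose_constraints()].
#' @param attacked `"RR"` or `"SS"`: which oxirane carbon the water attacks.
#' @return A data frame (class `pose_report`) with one row per constraint:
#'   `constraint`, `measured`, `pass`; attribute `overall` is `TRUE` iff all
#'   constraints pass.
#' @export
validate_design_pose <- function(lf, cst = design_pose_constraints(),
                                 attacked = c("RR", "SS")) {
  stopifnot(inherits(lf, "nac_labeled_frame"),
            inherits(cst, "design_pose_constraints"))
  attacked <- match.arg(attacked)
  xyz <- lf$role_xyz
  c_att <- if (attacked == "RR") "C_RR" else "C_SS"
  c_other <- if (attacked == "RR") "C_SS" else "C_RR"
  need <- unique(c("WAT_O", c_att, c_other, "O_EPOX",
                   unlist(cst$required_hbonds)))
  missing <- setdiff(need, rownames(xyz))
  if (length(missing))
    stop("validate_design_pose(): unresolved role(s): ",
         paste(missing, collapse = ", "), call. = FALSE)

  rows <- list()
  d_att <- dist3d(xyz["WAT_O", ], xyz[c_att, ])
  rows[[1L]] <- data.frame(
    constraint = "attack_distance", measured = d_att,
    pass = abs(d_att - cst$water_attack_distance) <= cst$attack_dist_tolerance)
  ang <- angle3d(xyz["WAT_O", ], xyz[c_att, ], xyz["O_EPOX", ])
  rows[[2L]] <- data.frame(
    constraint = "attack_angle", measured = ang,
    pass = abs(ang - cst$attack_angle_target) <= cst$attack_angle_tolerance)
  d_other <- dist3d(xyz["WAT_O", ], xyz[c_other, ])
  rows[[3L]] <- data.frame(
    constraint = "min_dist_nonattacked", measured = d_other,
    pass = d_other > cst$min_dist_nonattacked)
  for (i in seq_along(cst$required_hbonds)) {
    p <- cst$required_hbonds[[i]]
    d <- dist3d(xyz[p[1L], ], xyz[p[2L], ])
    rows[[3L + i]] <- data.frame(
      constraint = sprintf("hbond_%s_%s", p[1L], p[2L]), measured = d,
      pass = d <= cst$hbond_max_dist)
  }
  report <- do.call(rbind, rows)
  class(report) <- c("pose_report", class(report))
  attr(report, "overall") <- all(report$pass)
  attr(report, "attacked") <- attacked
  report
}

#' @export
print.pose_report <- function(x, ...) {
  cat(sprintf("Design-pose validation (attacked carbon: %s): %s\n",
              attr(x, "attacked"),
              if (attr(x, "overall")) "PASS" else "FAIL"))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
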