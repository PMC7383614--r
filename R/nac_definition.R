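#' Reactive-pose (near-attack-conformation) definition
#'
#' A frame counts as a NAC for an attack mode when the nucleophilic-attack
#' geometry at the attacked oxirane carbon and the catalytic hydrogen-bond
#' network all fall inside closed windows.  The defaults are the windows used
#' to screen LEH designs: attack angles theta1A (water-carbon-epoxide oxygen)
#' and theta1B (water-carbon-other carbon) of 128-163 degrees, attack
#' distance d1 of 0-3.22 A, and for the five H-bonds 120-180 degrees and
#' 0-3.50 A.  All bounds are inclusive (the windows are closed ranges).
#'
#' The five H-bond pairs are configurable; the default set is the catalytic
#' network: epoxide oxygen to both Asp101 carboxylate oxygens, and the water
#' oxygen to Asp132, Tyr53 and Asn55.  In the default `"heavy"` mode the
#' H-bond criterion is the donor-heavy-atom to acceptor-heavy-atom distance
#' window only (no protons required); in `"hydrogen"` mode a hydrogen role
#' must be supplied per pair and the donor-H-acceptor angle window is checked
#' as well.
#'
#' @param theta1A_range,theta1B_range Attack-angle windows, degrees.
#' @param d1_range Attack-distance window, Angstrom.
#' @param hbond_angle_range H-bond angle window, degrees (used in
#'   `"hydrogen"` mode).
#' @param hbond_dist_range H-bond heavy-atom distance window, Angstrom.
#' @param hbond_pairs List of exactly five character vectors
#'   `c(donor_role, acceptor_role)` or `c(donor, acceptor, hydrogen_role)`.
#' @param hbond_mode `"heavy"` (default) or `"hydrogen"`.
#' @return A `nac_definition` object.
#' @export
nac_definition <- function(theta1A_range = c(128, 163),
                           theta1B_range = c(128, 163),
                           d1_range = c(0, 3.22),
                           hbond_angle_range = c(120, 180),
                           hbond_dist_range = c(0, 3.50),
                           hbond_pairs = default_hbond_pairs(),
                           hbond_mode = c("heavy", "hydrogen")) {
  hbond_mode <- match.arg(hbond_mode)
  chk_range <- function(r, what) {
    if (length(r) != 2L || !all(is.finite(r)) || r[1L] > r[2L])
      stop("nac_definition(): ", what, " must be a non-empty range",
           call. = FALSE)
    as.numeric(r)
  }
  if (length(hbond_pairs) != 5L)
    stop("nac_definition(): exactly five H-bond pairs required",
         call. = FALSE)
  hbond_pairs <- lapply(hbond_pairs, function(p) {
    p <- as.character(p)
    if (!length(p) %in% c(2L, 3L))
      stop("nac_definition(): each H-bond pair is (donor, acceptor[, hydrogen])",
           call. = FALSE)
    p
  })
  if (hbond_mode == "hydrogen" &&
      any(vapply(hbond_pairs, length, integer(1L)) < 3L))
    stop("nac_definition(): hydrogen mode requires a hydrogen role per pair",
         call. = FALSE)
  structure(list(
    theta1A_range = chk_range(theta1A_range, "theta1A_range"),
    theta1B_range = chk_range(theta1B_range, "theta1B_range"),
    d1_range = chk_range(d1_range, "d1_range"),
    hbond_angle_range = chk_range(hbond_angle_range, "hbond_angle_range"),
    hbond_dist_range = chk_range(hbond_dist_range, "hbond_dist_range"),
    hbond_pairs = hbond_pairs,
    hbond_mode = hbond_mode
  ), class = "nac_definition")
}

#' @rdname nac_definition
#' @export
default_hbond_pairs <- function() {
  list(c("O_EPOX", "D101_OD1"),
       c("WAT_O",  "D132_OD1"),
       c("WAT_O",  "Y53_OH"),
       c("WAT_O",  "N55_ND2"),
       c("O_EPOX", "D101_OD2"))
}

#' Static design-pose constraints
#'
#' Geometric restraints a designed (pre-MD) enzyme-substrate pose must
#' satisfy: the water oxygen close to the attacked oxirane carbon (1.8 A,
#' checked with a distance tolerance), a near-linear attack angle
#' (water oxygen - attacked carbon - epoxide oxygen close to 180 degrees),
#' the water at least 3.8 A from the non-attacked carbon, and the four
#' catalytic H-bonds formed (epoxide oxygen to Asp101; water to Asp132,
#' Tyr53 and Asn55).
#'
#' @param water_attack_distance Target water-to-attacked-carbon distance, A.
#' @param attack_dist_tolerance Allowed deviation from
#'   `water_attack_distance`, A.
#' @param attack_angle_target Target attack angle, degrees.
#' @param attack_angle_tolerance Allowed deviation from the target, degrees.
#' @param min_dist_nonattacked Minimum water distance to the non-attacked
#'   carbon, A.
#' @param hbond_max_dist Maximum heavy-atom distance for a formed H-bond, A.
#' @param required_hbonds List of `c(donor_role, acceptor_role)` pairs.
#' @return A `design_pose_constraints` object.
#' @export
design_pose_constraints <- function(water_attack_distance = 1.8,
                                    attack_dist_tolerance = 0.4,
                                    attack_angle_target = 180,
                                    attack_angle_tolerance = 15,
                                    min_dist_nonattacked = 3.8,
                                    hbond_max_dist = 3.5,
                                    required_hbonds = list(
                                      c("O_EPOX", "D101_OD1"),
                                      c("WAT_O",  "D132_OD1"),
                                      c("WAT_O",  "Y53_OH"),
                                      c("WAT_O",  "N55_ND2"))) {
  if (min_dist_nonattacked <= water_attack_distance)
    stop("design_pose_constraints(): min_dist_nonattacked must exceed ",
         "water_attack_distance", call. = FALSE)
  structure(list(water_attack_distance = water_attack_distance,
                 attack_dist_tolerance = attack_dist_tolerance,
                 attack_angle_target = attack_angle_target,
                 attack_angle_tolerance = attack_angle_tolerance,
                 min_dist_nonattacked = min_dist_nonattacked,
                 hbond_max_dist = hbond_max_dist,
                 required_hbonds = required_hbonds),
            class = "design_pose_constraints")
}

#' Read/write a NAC definition as a YAML config
#'
#' @param path YAML file with keys matching the [nac_definition()] arguments.
#' @return [read_nac_definition()] returns a [nac_definition()].
#' @export
read_nac_definition <- function(path) {
  cfg <- yaml::read_yaml(path)
  args <- cfg[intersect(names(cfg), names(formals(nac_definition)))]
  if (!is.null(args$hbond_pairs))
    args$hbond_pairs <- lapply(args$hbond_pairs, unlist)
  do.call(nac_definition, args)
}

#' @rdname read_nac_definition
#' @param defn A [nac_definition()].
#' @export
write_nac_definition <- function(defn, path) {
  stopifnot(inherits(defn, "nac_definition"))
  out <- unclass(defn)
  out$hbond_pairs <- lapply(out$hbond_pairs, as.list)
  yaml::write_yaml(out, path)
  invisible(path)
}
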