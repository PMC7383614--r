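#' Specification of a synthetic conformational ensemble
#'
#' Describes the ground truth for the stochastic active-site generator: the
#' per-frame probabilities of the proRR-reactive and proSS-reactive states
#' (the remainder is non-reactive), the temporal persistence of the hidden
#' state (a Markov self-transition probability; 0 gives i.i.d. frames), the
#' replica structure, and the geometric noise.  The generator emulates the
#' replica structure of high-throughput multiple independent MD (many short,
#' independently initialised trajectories per design) without any physics:
#' states are sampled from a 3-state Markov chain with stationary
#' distribution `(p_RR, p_SS, 1 - p_RR - p_SS)` and coordinates are built by
#' inverse geometry inside (or outside) the criterion windows.
#'
#' @param p_RR,p_SS Ground-truth per-frame NAC probabilities, percent.
#' @param persistence Markov self-transition probability in `[0, 1)`.
#' @param n_replicas Number of independently seeded replicas.
#' @param replica_length_ps Simulated length per replica, ps.
#' @param frame_interval_ps Time between stored frames, ps (default 0.005:
#'   frames scored essentially on the fly).
#' @param noise Gaussian jitter (standard deviation, Angstrom) added to all
#'   coordinates after construction; at 0 the intended state label is
#'   recovered exactly by [classify_frame()].
#' @param seed Master seed; replica `r` uses an independent substream
#'   derived from it (see Details).
#' @details Replica substreams are derived as
#'   `(seed * 48271 + r * 9973) mod (2^31 - 2) + 1`, so ensembles are
#'   reproducible across platforms and a replica's frames do not change when
#'   more replicas are requested.
#' @return An `ensemble_spec` object.
#' @export
ensemble_spec <- function(p_RR, p_SS, persistence = 0, n_replicas = 5L,
                          replica_length_ps = 10,
                          frame_interval_ps = 0.005, noise = 0, seed = 1L) {
  if (p_RR < 0 || p_SS < 0 || p_RR + p_SS > 100)
    stop("ensemble_spec(): need p_RR, p_SS >= 0 and p_RR + p_SS <= 100",
         call. = FALSE)
  if (persistence < 0 || persistence >= 1)
    stop("ensemble_spec(): persistence must lie in [0, 1)", call. = FALSE)
  L <- as.integer(round(replica_length_ps / frame_interval_ps))
  if (n_replicas < 1L || L < 1L)
    stop("ensemble_spec(): need at least one replica and one frame",
         call. = FALSE)
  structure(list(p_RR = p_RR, p_SS = p_SS, persistence = persistence,
                 n_replicas = as.integer(n_replicas),
                 replica_length_ps = replica_length_ps,
                 frame_interval_ps = frame_interval_ps,
                 frames_per_replica = L, noise = noise,
                 seed = as.integer(seed)),
            class = "ensemble_spec")
}

# Deterministic per-replica substream seed.
.sub_seed <- function(seed, r) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(r) * 9973) %%
               2147483646) + 1L
}

.STATES <- c("proRR", "proSS", "nonreactive")

# Sample L states of the 3-state chain with stationary pi and a single
# self-transition (persistence) parameter: with probability rho repeat the
# previous state, otherwise draw fresh from pi.  Stationary distribution is
# pi for any rho in [0, 1).
.markov_states <- function(L, pi3, rho) {
  fresh <- sample.int(3L, L, replace = TRUE, prob = pi3)
  if (rho > 0 && L > 1L) {
    keep <- c(TRUE, runif(L - 1L) >= rho)  # TRUE = take a fresh draw
    idx <- cummax(ifelse(keep, seq_len(L), 0L))
    fresh <- fresh[idx]
  }
  .STATES[fresh]
}

# Abstract active-site scaffold: epoxide triangle with C-C 1.47 A and
# C-O 1.43 A.  All role atoms are placed in this frame; no full protein.
.scaffold <- function() {
  list(C_RR = c(-0.735, 0, 0),
       C_SS = c(0.735, 0, 0),
       O_EPOX = c(0, sqrt(1.43^2 - 0.735^2), 0))
}

.rand_units <- function(n) {
  m <- matrix(rnorm(3L * n), n, 3L)
  m / sqrt(rowSums(m^2))
}

# Place the water oxygen for n reactive frames of one attack mode:
# uniform sampling of (d1, theta1A, theta1B) inside the windows, rejecting
# draws that are geometrically infeasible or leave the water inside the
# other mode's d1 window.  Returns an n x 3 matrix.
.place_water <- function(n, c_att, c_other, c_oe, defn) {
  e1 <- (c_oe - c_att); e1 <- e1 / sqrt(sum(e1^2))
  ab <- c_other - c_att
  d_ab <- sqrt(sum(ab^2))
  e2 <- ab / d_ab
  cos_g <- sum(e1 * e2)
  f <- e2 - cos_g * e1
  f <- f / sqrt(sum(f^2))
  nrm <- c(e1[2L] * f[3L] - e1[3L] * f[2L],
           e1[3L] * f[1L] - e1[1L] * f[3L],
           e1[1L] * f[2L] - e1[2L] * f[1L])
  sin_g <- sqrt(max(0, 1 - cos_g^2))
  excl <- defn$d1_range[2L]
  out <- matrix(NA_real_, n, 3L)
  todo <- seq_len(n)
  for (iter in seq_len(200L)) {
    m <- length(todo)
    if (!m) break
    d1 <- runif(m, defn$d1_range[1L], defn$d1_range[2L])
    a <- runif(m, defn$theta1A_range[1L], defn$theta1A_range[2L]) * pi / 180
    b <- runif(m, defn$theta1B_range[1L], defn$theta1B_range[2L]) * pi / 180
    x <- cos(a)
    y <- (cos(b) - cos(a) * cos_g) / sin_g
    z2 <- 1 - x^2 - y^2
    d_other2 <- d1^2 + d_ab^2 - 2 * d1 * d_ab * cos(b)
    ok <- z2 >= 0 & d_other2 > excl^2 + 1e-9
    if (any(ok)) {
      z <- sqrt(pmax(0, z2[ok])) * sample(c(-1, 1), sum(ok), replace = TRUE)
      u <- cbind(x[ok], y[ok], z)
      w <- u %*% rbind(e1, f, nrm)
      out[todo[ok], ] <- sweep(w, 2L, c_att, `+`)
      todo <- todo[!ok]
    }
  }
  if (length(todo))
    stop("realize_geometry(): infeasible window combination - could not ",
         "place the water inside the requested criterion windows",
         call. = FALSE)
  out
}

# Build coordinates for a vector of state labels.  Returns an
# L x 9 x 3 array in the atom order of default_role_map().
.realize_block <- function(states, defn, noise = 0) {
  if (defn$hbond_mode == "hydrogen")
    stop("the synthetic generator places heavy atoms only; use the default ",
         "heavy-atom H-bond mode", call. = FALSE)
  sc <- .scaffold()
  L <- length(states)
  arr <- array(NA_real_, dim = c(L, 9L, 3L))
  for (i in 1:3) {
    arr[, 2L, i] <- sc$C_RR[i]
    arr[, 3L, i] <- sc$C_SS[i]
    arr[, 4L, i] <- sc$O_EPOX[i]
  }
  is_rr <- states == "proRR"
  is_ss <- states == "proSS"
  is_nr <- !is_rr & !is_ss
  if (any(is_rr))
    arr[is_rr, 1L, ] <- .place_water(sum(is_rr), sc$C_RR, sc$C_SS,
                                     sc$O_EPOX, defn)
  if (any(is_ss))
    arr[is_ss, 1L, ] <- .place_water(sum(is_ss), sc$C_SS, sc$C_RR,
                                     sc$O_EPOX, defn)
  if (any(is_nr)) {
    n <- sum(is_nr)
    centroid <- (sc$C_RR + sc$C_SS) / 2
    r <- runif(n, defn$d1_range[2L] + 1.5, defn$d1_range[2L] + 5)
    arr[is_nr, 1L, ] <- sweep(.rand_units(n) * r, 2L, centroid, `+`)
  }
  # H-bond partners: each acceptor placed around its donor inside the upper
  # part of the distance window (lower 70 % excluded as steric overlap).
  role_atom <- setNames(1:9, required_roles())
  hb_lo <- max(defn$hbond_dist_range[1L], 0.7 * defn$hbond_dist_range[2L])
  hb_hi <- defn$hbond_dist_range[2L]
  placed <- c(TRUE, TRUE, TRUE, TRUE, rep(FALSE, 5L))
  for (p in defn$hbond_pairs) {
    di <- role_atom[[p[1L]]]; ai <- role_atom[[p[2L]]]
    if (!placed[di])
      stop("realize_geometry(): H-bond donor ", p[1L],
           " has no defined position", call. = FALSE)
    r <- runif(L, hb_lo, hb_hi)
    arr[, ai, ] <- arr[, di, ] + .rand_units(L) * r
    placed[ai] <- TRUE
  }
  if (any(!placed))  # roles untouched by the H-bond pair set: park far away
    for (ai in which(!placed)) arr[, ai, ] <- rep(c(8, 8, 8), each = L)
  if (noise > 0)
    arr <- arr + array(rnorm(length(arr), 0, noise), dim = dim(arr))
  arr
}

#' Realize the geometry of one frame with a known state label
#'
#' Inverse construction: for a reactive state the water oxygen is placed by
#' sampling the attack distance and both attack angles uniformly inside
#' their windows (outside the other mode's distance window), and every
#' H-bond acceptor is placed inside the distance window around its donor;
#' for `"nonreactive"` the water is displaced beyond the attack-distance
#' window of both carbons.  Only the nine catalytic role atoms are placed,
#' in an abstract active-site frame - classification touches nothing else.
#' Uses the current RNG state.
#'
#' @param state `"proRR"`, `"proSS"` or `"nonreactive"`.
#' @param defn A [nac_definition()] (heavy-atom H-bond mode).
#' @param noise Gaussian coordinate jitter, Angstrom.
#' @return A [label_frame()]ed frame.
#' @export
realize_geometry <- function(state = c("proRR", "proSS", "nonreactive"),
                             defn = nac_definition(), noise = 0) {
  state <- match.arg(state)
  arr <- .realize_block(state, defn, noise)
  label_frame(frame(unclass(default_role_map()), arr[1L, , ]),
              default_role_map())
}

# One replica of a synthetic ensemble (deterministic given seed).
.gen_replica <- function(p_RR, p_SS, persistence, L, noise, defn,
                         seed, replica_id) {
  withr::with_seed(seed, {
    states <- .markov_states(L, c(p_RR, p_SS, 100 - p_RR - p_SS) / 100,
                             persistence)
    coords <- .realize_block(states, defn, noise)
    list(replica = new_replica(replica_id, coords, seed_tag = seed),
         states = states)
  })
}

#' Generate a replica-structured synthetic ensemble with ground truth
#'
#' @param spec An [ensemble_spec()].
#' @param defn The [nac_definition()] whose windows the construction targets.
#' @return A list with `ensemble` (a [ensemble()]) and `ground_truth`: the
#'   per-replica state labels and the realised empirical state frequencies
#'   (percent).
#' @examples
#' out <- generate_ensemble(ensemble_spec(p_RR = 20, p_SS = 0,
#'                                        n_replicas = 2,
#'                                        frame_interval_ps = 0.1, seed = 7))
#' nac_frequencies(out$ensemble)
#' @export
generate_ensemble <- function(spec, defn = nac_definition()) {
  stopifnot(inherits(spec, "ensemble_spec"))
  reps <- vector("list", spec$n_replicas)
  states <- vector("list", spec$n_replicas)
  for (r in seq_len(spec$n_replicas)) {
    g <- .gen_replica(spec$p_RR, spec$p_SS, spec$persistence,
                      spec$frames_per_replica, spec$noise, defn,
                      .sub_seed(spec$seed, r), r)
    reps[[r]] <- g$replica
    states[[r]] <- g$states
  }
  ens <- ensemble(reps, unclass(default_role_map()),
                  frame_interval_ps = spec$frame_interval_ps,
                  metadata = list(synthetic = TRUE, spec = spec))
  all_states <- unlist(states)
  emp <- 100 * c(proRR = mean(all_states == "proRR"),
                 proSS = mean(all_states == "proSS"),
                 nonreactive = mean(all_states == "nonreactive"))
  list(ensemble = ens,
       ground_truth = list(states = states, empirical_freq = emp,
                           spec = spec))
}

#' Generate a synthetic design library with known occupancies
#'
#' Emulates a primary design library: each design gets an id, a random
#' mutation list over the eleven active-site design positions (new residues
#' drawn from the nine-letter hydrophobic alphabet `AFGILMPVW`), a target
#' enantiomer matching its larger ground-truth occupancy, and an
#' [ensemble_spec()] carrying its planted `(p_RR, p_SS)`.
#'
#' @param n_designs Number of designs.
#' @param occupancy_sampler Function `n -> data.frame(p_RR, p_SS)` in
#'   percent; the default draws a mildly selective library (uniform
#'   `p_RR` in 0-30, `p_SS` in 0-5).
#' @param seed Master seed; design `i` derives its own substream.
#' @param n_replicas,replica_length_ps,frame_interval_ps,persistence,noise
#'   Passed to each design's [ensemble_spec()].
#' @return A `design_library`: `manifest` (data frame with `design_id`,
#'   `target`, `mutations`, `p_RR`, `p_SS`, `design_seed`) and `specs`
#'   (named list of [ensemble_spec()]).
#' @export
generate_library <- function(n_designs,
                             occupancy_sampler = function(n)
                               data.frame(p_RR = runif(n, 0, 30),
                                          p_SS = runif(n, 0, 5)),
                             seed = 1L, n_replicas = 5L,
                             replica_length_ps = 10,
                             frame_interval_ps = 0.005,
                             persistence = 0, noise = 0) {
  stopifnot(n_designs >= 1L)
  withr::with_seed(seed, {
    occ <- occupancy_sampler(n_designs)
    stopifnot(all(c("p_RR", "p_SS") %in% names(occ)),
              nrow(occ) == n_designs)
    pos <- design_positions()
    muts <- character(n_designs)
    for (i in seq_len(n_designs)) {
      k <- sample(3:7, 1L)
      at <- sort(sample(seq_along(pos), k))
      new_aa <- vapply(at, function(j)
        sample(setdiff(design_alphabet(), pos[[j]]), 1L), character(1L))
      muts[i] <- paste0(pos[at], names(pos)[at], new_aa, collapse = "_")
    }
  })
  manifest <- data.frame(
    design_id = sprintf("D%03d", seq_len(n_designs)),
    target = ifelse(occ$p_RR >= occ$p_SS, "RR", "SS"),
    mutations = muts,
    p_RR = occ$p_RR, p_SS = occ$p_SS,
    design_seed = vapply(seq_len(n_designs), function(i)
      .sub_seed(seed, 100000L + i), integer(1L)))
  specs <- lapply(seq_len(n_designs), function(i)
    ensemble_spec(p_RR = occ$p_RR[i], p_SS = occ$p_SS[i],
                  persistence = persistence, n_replicas = n_replicas,
                  replica_length_ps = replica_length_ps,
                  frame_interval_ps = frame_interval_ps, noise = noise,
                  seed = manifest$design_seed[i]))
  names(specs) <- manifest$design_id
  structure(list(manifest = manifest, specs = specs),
            class = "design_library")
}

#' Ensemble provider backed by the synthetic generator
#'
#' Returns a function with the [run_cascade()] provider contract.  For
#' cumulative (10-ps) requests the replicas are generated once per design
#' from fixed substreams and cached, so a later round extends the earlier
#' replica set without altering it; standalone (100-ps) requests use a
#' disjoint substream namespace.
#'
#' @param library A `design_library` from [generate_library()].
#' @param defn The [nac_definition()] the construction targets.
#' @return `function(design_id, n_replicas, replica_length_ps, cumulative)`
#'   returning a [ensemble()].
#' @export
make_synthetic_provider <- function(library, defn = nac_definition()) {
  stopifnot(inherits(library, "design_library"))
  cache <- new.env(parent = emptyenv())
  specs <- library$specs
  function(design_id, n_replicas, replica_length_ps, cumulative) {
    spec <- specs[[design_id]]
    if (is.null(spec))
      stop("provider: unknown design ", design_id, call. = FALSE)
    L <- as.integer(round(replica_length_ps / spec$frame_interval_ps))
    if (cumulative) {
      key <- paste0(design_id, "@", replica_length_ps)
      reps <- if (exists(key, cache)) get(key, cache) else list()
      if (length(reps) < n_replicas) {
        for (r in (length(reps) + 1L):n_replicas)
          reps[[r]] <- .gen_replica(spec$p_RR, spec$p_SS, spec$persistence,
                                    L, spec$noise, defn,
                                    .sub_seed(spec$seed, r), r)$replica
        assign(key, reps, cache)
      }
      use <- reps[seq_len(n_replicas)]
    } else {
      use <- lapply(seq_len(n_replicas), function(r)
        .gen_replica(spec$p_RR, spec$p_SS, spec$persistence, L, spec$noise,
                     defn, .sub_seed(spec$seed, 500000L + r), r)$replica)
    }
    ensemble(use, unclass(default_role_map()),
             frame_interval_ps = spec$frame_interval_ps,
             metadata = list(design_id = design_id))
  }
}
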