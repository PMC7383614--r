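#' Catalytic atom roles
#'
#' The scoring functions never address atoms by position in the file; every
#' criterion is written against a named catalytic role.  The required roles
#' are the nucleophilic water oxygen (`WAT_O`), the two oxirane carbons
#' (`C_RR`, attack yields the (R,R)-diol; `C_SS`, attack yields the
#' (S,S)-diol), the epoxide oxygen (`O_EPOX`) and the five hydrogen-bond
#' partner atoms of the catalytic network: the two Asp101 carboxylate oxygens
#' (which protonate the epoxide oxygen), one Asp132 carboxylate oxygen (which
#' abstracts a proton from the water), the Tyr53 hydroxyl oxygen and the
#' Asn55 side-chain amide nitrogen (which position the water).
#'
#' @param mapping Named character vector or list, role name -> atom identifier.
#'   Atom identifiers are `"NAME:RESNO"` strings as produced by the readers.
#' @return A `nac_role_map` object (named character vector).
#' @seealso [default_role_map()], [label_frame()]
#' @export
role_map <- function(mapping) {
  mapping <- unlist(mapping)
  if (is.null(names(mapping)) || any(!nzchar(names(mapping))))
    stop("role_map(): every entry must be named by its role", call. = FALSE)
  mapping <- vapply(mapping, as.character, character(1L))
  missing <- setdiff(required_roles(), names(mapping))
  if (length(missing))
    stop("role_map(): required role(s) missing: ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (anyDuplicated(names(mapping)))
    stop("role_map(): a role maps to two atoms: ",
         paste(unique(names(mapping)[duplicated(names(mapping))]),
               collapse = ", "), call. = FALSE)
  structure(mapping, class = "nac_role_map")
}

#' @rdname role_map
#' @export
required_roles <- function() {
  c("WAT_O", "C_RR", "C_SS", "O_EPOX",
    "D101_OD1", "D101_OD2", "D132_OD1", "Y53_OH", "N55_ND2")
}

#' @rdname role_map
#' @export
default_role_map <- function() {
  role_map(c(
    WAT_O    = "OW:300",
    C_RR     = "C1:201",
    C_SS     = "C2:201",
    O_EPOX   = "OE:201",
    D101_OD1 = "OD1:101",
    D101_OD2 = "OD2:101",
    D132_OD1 = "OD1:132",
    Y53_OH   = "OH:53",
    N55_ND2  = "ND2:55"
  ))
}

#' Single conformational snapshot
#'
#' @param atom_ids Character vector of atom identifiers, unique within the
#'   frame.
#' @param coords Numeric matrix, one row per atom, columns x/y/z (Angstrom).
#' @param frame_index Integer position of the snapshot within its replica.
#' @param replica_id Integer id of the trajectory replica the frame belongs to.
#' @return A `nac_frame` object.
#' @export
frame <- function(atom_ids, coords, frame_index = 1L, replica_id = 1L) {
  atom_ids <- as.character(atom_ids)
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (ncol(coords) != 3L)
    stop("frame(): coords must have three columns", call. = FALSE)
  if (nrow(coords) != length(atom_ids))
    stop("frame(): coords and atom_ids lengths differ", call. = FALSE)
  if (anyDuplicated(atom_ids))
    stop("frame(): duplicated atom identifier(s): ",
         paste(unique(atom_ids[duplicated(atom_ids)]), collapse = ", "),
         call. = FALSE)
  if (!all(is.finite(coords)))
    stop("frame(): non-finite coordinates", call. = FALSE)
  structure(list(atom_ids = atom_ids, coords = coords,
                 frame_index = as.integer(frame_index),
                 replica_id = as.integer(replica_id)),
            class = "nac_frame")
}

#' Bind catalytic roles to a frame's coordinates
#'
#' Resolves every required role of a [role_map()] to a coordinate triple of
#' the frame.  All scoring operations take the resulting labeled frame.
#'
#' @param frm A [frame()].
#' @param roles A [role_map()].
#' @return A `nac_labeled_frame`: the frame plus a `role_xyz` matrix with one
#'   row per role.
#' @export
label_frame <- function(frm, roles) {
  stopifnot(inherits(frm, "nac_frame"))
  if (!inherits(roles, "nac_role_map")) roles <- role_map(roles)
  idx <- match(unclass(roles), frm$atom_ids)
  if (anyNA(idx)) {
    bad <- names(roles)[is.na(idx)]
    stop("label_frame(): role(s) not resolvable in frame: ",
         paste(sprintf("%s -> %s", bad, unclass(roles)[is.na(idx)]),
               collapse = ", "), call. = FALSE)
  }
  xyz <- frm$coords[idx, , drop = FALSE]
  rownames(xyz) <- names(roles)
  structure(list(frame = frm, role_xyz = xyz, roles = roles),
            class = "nac_labeled_frame")
}

# Replica record: block of frames stored as an L x n_atoms x 3 array.
new_replica <- function(replica_id, coords, seed_tag = NA_integer_) {
  stopifnot(length(dim(coords)) == 3L, dim(coords)[3L] == 3L)
  list(replica_id = as.integer(replica_id), coords = coords,
       seed_tag = seed_tag)
}

#' Replica-structured conformational ensemble
#'
#' Frames are grouped explicitly by replica (one independently initialised
#' trajectory each); frames are never pooled across replicas implicitly,
#' because the design-level NAC frequency is the unweighted mean over
#' replicas.
#'
#' @param replicas List of replica records as built by the readers or the
#'   generator; each holds `replica_id` and an `L x n_atoms x 3` coordinate
#'   array.
#' @param atom_ids Character vector of atom identifiers shared by all frames.
#' @param frame_interval_ps Time between stored frames, picoseconds.
#' @param metadata Optional named list (design id, substrate id, ...).
#' @return A `nac_ensemble` object.
#' @export
ensemble <- function(replicas, atom_ids, frame_interval_ps = 0.005,
                     metadata = list()) {
  if (!length(replicas))
    stop("ensemble(): at least one replica required", call. = FALSE)
  ids <- vapply(replicas, function(r) r$replica_id, integer(1L))
  if (anyDuplicated(ids))
    stop("ensemble(): duplicated replica_id(s)", call. = FALSE)
  nat <- length(atom_ids)
  for (r in replicas) {
    if (dim(r$coords)[1L] < 1L)
      stop("ensemble(): replica ", r$replica_id, " has no frames",
           call. = FALSE)
    if (dim(r$coords)[2L] != nat)
      stop("ensemble(): replica ", r$replica_id,
           " atom count differs from atom_ids", call. = FALSE)
  }
  structure(list(replicas = replicas, atom_ids = as.character(atom_ids),
                 frame_interval_ps = frame_interval_ps, metadata = metadata),
            class = "nac_ensemble")
}

#' @rdname ensemble
#' @param x A `nac_ensemble`.
#' @export
n_frames <- function(x) {
  stopifnot(inherits(x, "nac_ensemble"))
  sum(vapply(x$replicas, function(r) dim(r$coords)[1L], integer(1L)))
}

#' Extract one frame from an ensemble
#'
#' @param x A [ensemble()].
#' @param replica_id Replica to read from.
#' @param i Frame index within the replica.
#' @return A [frame()].
#' @export
get_frame <- function(x, replica_id, i) {
  stopifnot(inherits(x, "nac_ensemble"))
  ids <- vapply(x$replicas, function(r) r$replica_id, integer(1L))
  k <- match(as.integer(replica_id), ids)
  if (is.na(k))
    stop("get_frame(): no replica with id ", replica_id, call. = FALSE)
  rep <- x$replicas[[k]]
  if (i < 1L || i > dim(rep$coords)[1L])
    stop("get_frame(): frame index out of range", call. = FALSE)
  frame(x$atom_ids, rep$coords[i, , ], frame_index = i,
        replica_id = rep$replica_id)
}

# Build an ensemble from a flat list of nac_frame objects, grouping by
# replica_id and preserving order.
ensemble_from_frames <- function(frames, frame_interval_ps = 0.005,
                                 metadata = list()) {
  if (!length(frames)) stop("no frames supplied", call. = FALSE)
  ids0 <- frames[[1L]]$atom_ids
  for (f in frames)
    if (!identical(f$atom_ids, ids0))
      stop("frames do not share a common atom list", call. = FALSE)
  rep_ids <- vapply(frames, function(f) f$replica_id, integer(1L))
  replicas <- lapply(unique(rep_ids), function(rid) {
    sel <- frames[rep_ids == rid]
    arr <- array(NA_real_, dim = c(length(sel), length(ids0), 3L))
    for (i in seq_along(sel)) arr[i, , ] <- sel[[i]]$coords
    new_replica(rid, arr)
  })
  ensemble(replicas, ids0, frame_interval_ps, metadata)
}

#' @export
print.nac_ensemble <- function(x, ...) {
  cat(sprintf(
    "<nac_ensemble> %d replica(s), %d frames total, %d atoms, %.4g ps/frame\n",
    length(x$replicas), n_frames(x), length(x$atom_ids),
    x$frame_interval_ps))
  invisible(x)
}

#' @export
print.nac_frame <- function(x, ...) {
  cat(sprintf("<nac_frame> replica %d, index %d, %d atoms\n",
              x$replica_id, x$frame_index, length(x$atom_ids)))
  invisible(x)
}
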