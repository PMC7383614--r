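#' Read a conformational trajectory file
#'
#' Reads one trajectory file into a single-replica [ensemble()].  Two text
#' formats are supported:
#'
#' * `"pdb"`: fixed-column wwPDB `ATOM`/`HETATM` records; frames delimited by
#'   `MODEL`/`ENDMDL` (a file without `MODEL` records is one frame).  Chain
#'   and altLoc columns are ignored after role resolution.  Atom identifiers
#'   are `"NAME:RESNO"`.
#' * `"xyz"`: concatenated XYZ blocks (atom-count line, comment line, one
#'   atom per line).  Atom-name tokens written by this package encode the
#'   residue number as `NAME_RESNO` and are mapped back to `"NAME:RESNO"`;
#'   plain element tokens get an occurrence suffix (`"O1"`, `"O2"`, ...).
#'
#' Replica membership is explicit: one trajectory file per replica, or a
#' manifest (see [read_ensemble()]).  Frames are never pooled across files
#' implicitly.
#'
#' @param path File to read.
#' @param format `"pdb"` or `"xyz"`.
#' @param roles Optional [role_map()]; when given, role resolution is checked
#'   on the first frame and a role-resolution error names the missing role.
#' @param replica_id Replica id to assign to the file's frames.
#' @param frame_interval_ps Time between stored frames (picoseconds).
#' @return A [ensemble()] with one replica.
#' @export
read_frames <- function(path, format = c("pdb", "xyz"), roles = NULL,
                        replica_id = 1L, frame_interval_ps = 0.005) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop("read_frames(): file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  parsed <- switch(format,
                   pdb = .parse_pdb(lines, path),
                   xyz = .parse_xyz(lines, path))
  arr <- array(NA_real_, dim = c(length(parsed$frames),
                                 length(parsed$atom_ids), 3L))
  for (i in seq_along(parsed$frames)) arr[i, , ] <- parsed$frames[[i]]
  ens <- ensemble(list(new_replica(replica_id, arr)), parsed$atom_ids,
                  frame_interval_ps = frame_interval_ps,
                  metadata = list(source = path, format = format))
  if (!is.null(roles))
    label_frame(get_frame(ens, replica_id, 1L), roles)  # errors name the role
  ens
}

.parse_pdb <- function(lines, path) {
  frames <- list()
  atom_names <- character(0)
  cur_xyz <- NULL
  cur_ids <- character(0)
  in_model <- FALSE
  saw_model <- any(startsWith(lines, "MODEL"))
  flush_frame <- function() {
    if (is.null(cur_xyz) || !nrow(cur_xyz)) return()
    if (length(frames)) {
      if (!identical(cur_ids, attr(frames[[1L]], "ids")))
        stop("read_frames(): atom list changes between models in ", path,
             call. = FALSE)
    }
    m <- cur_xyz
    attr(m, "ids") <- cur_ids
    frames[[length(frames) + 1L]] <<- m
  }
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    rec <- substr(ln, 1L, 6L)
    if (startsWith(rec, "MODEL")) {
      flush_frame()
      cur_xyz <- NULL; cur_ids <- character(0); in_model <- TRUE
    } else if (startsWith(rec, "ENDMDL")) {
      flush_frame()
      cur_xyz <- NULL; cur_ids <- character(0); in_model <- FALSE
    } else if (rec == "ATOM  " || rec == "HETATM") {
      if (nchar(ln) < 54L)
        stop(sprintf("read_frames(): malformed %s record at line %d of %s",
                     trimws(rec), i, path), call. = FALSE)
      name <- trimws(substr(ln, 13L, 16L))
      resno <- suppressWarnings(as.integer(trimws(substr(ln, 23L, 26L))))
      xyz <- suppressWarnings(as.numeric(c(substr(ln, 31L, 38L),
                                           substr(ln, 39L, 46L),
                                           substr(ln, 47L, 54L))))
      if (anyNA(xyz) || is.na(resno))
        stop(sprintf("read_frames(): unparseable coordinates at line %d of %s",
                     i, path), call. = FALSE)
      cur_ids <- c(cur_ids, paste0(name, ":", resno))
      cur_xyz <- rbind(cur_xyz, xyz)
    }
  }
  flush_frame()
  if (!length(frames))
    stop("read_frames(): no frames found in ", path,
         if (!saw_model) " (no MODEL or ATOM records)", call. = FALSE)
  ids <- attr(frames[[1L]], "ids")
  if (anyDuplicated(ids))
    stop("read_frames(): duplicated atom identifier(s) within a model in ",
         path, call. = FALSE)
  list(frames = lapply(frames, function(m) {
    dimnames(m) <- NULL; attr(m, "ids") <- NULL; m
  }), atom_ids = ids)
}

.parse_xyz <- function(lines, path) {
  frames <- list()
  atom_ids0 <- NULL
  i <- 1L
  n_lines <- length(lines)
  while (i <= n_lines) {
    if (!nzchar(trimws(lines[[i]]))) { i <- i + 1L; next }
    nat <- suppressWarnings(as.integer(trimws(lines[[i]])))
    if (is.na(nat) || nat < 1L)
      stop(sprintf("read_frames(): expected atom count at line %d of %s",
                   i, path), call. = FALSE)
    if (i + 1L + nat > n_lines)
      stop(sprintf("read_frames(): truncated XYZ block starting at line %d of %s",
                   i, path), call. = FALSE)
    tokens <- character(nat)
    xyz <- matrix(NA_real_, nat, 3L)
    for (k in seq_len(nat)) {
      ln <- i + 1L + k
      parts <- strsplit(trimws(lines[[ln]]), "[[:space:]]+")[[1L]]
      if (length(parts) < 4L)
        stop(sprintf("read_frames(): malformed atom line at line %d of %s",
                     ln, path), call. = FALSE)
      val <- suppressWarnings(as.numeric(parts[2:4]))
      if (anyNA(val))
        stop(sprintf("read_frames(): unparseable coordinates at line %d of %s",
                     ln, path), call. = FALSE)
      tokens[k] <- parts[1L]
      xyz[k, ] <- val
    }
    ids <- ifelse(grepl("_", tokens, fixed = TRUE),
                  sub("_", ":", tokens), tokens)
    if (anyDuplicated(ids))
      ids <- paste0(ids, ave(ids, ids, FUN = seq_along))
    if (is.null(atom_ids0)) atom_ids0 <- ids
    else if (!identical(ids, atom_ids0))
      stop(sprintf("read_frames(): atom list changes at XYZ block near line %d of %s",
                   i, path), call. = FALSE)
    frames[[length(frames) + 1L]] <- xyz
    i <- i + 2L + nat
  }
  if (!length(frames))
    stop("read_frames(): no frames found in ", path, call. = FALSE)
  list(frames = frames, atom_ids = atom_ids0)
}

#' Write a trajectory file
#'
#' Inverse of [read_frames()].  A single replica is written per file; use
#' [write_ensemble()] for a multi-replica ensemble plus manifest.  PDB
#' coordinates carry three decimals (0.001 A); XYZ carries six.
#'
#' @param ens A single-replica [ensemble()].
#' @param path Output file.
#' @param format `"pdb"` or `"xyz"`.
#' @return `path`, invisibly.
#' @export
write_frames <- function(ens, path, format = c("pdb", "xyz")) {
  format <- match.arg(format)
  stopifnot(inherits(ens, "nac_ensemble"))
  if (length(ens$replicas) != 1L)
    stop("write_frames(): one replica per file; use write_ensemble()",
         call. = FALSE)
  coords <- ens$replicas[[1L]]$coords
  ids <- ens$atom_ids
  name <- sub(":.*$", "", ids)
  resno <- suppressWarnings(as.integer(sub("^[^:]*:?", "", ids)))
  resno[is.na(resno)] <- 1L
  con <- file(path, "w")
  on.exit(close(con))
  L <- dim(coords)[1L]
  if (format == "pdb") {
    resname <- .default_resname(name, resno)
    elem <- substr(name, 1L, 1L)
    for (f in seq_len(L)) {
      writeLines(sprintf("MODEL     %4d", f), con)
      writeLines(sprintf(
        "HETATM%5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
        seq_along(ids), name, resname, resno,
        coords[f, , 1L], coords[f, , 2L], coords[f, , 3L], elem), con)
      writeLines("ENDMDL", con)
    }
    writeLines("END", con)
  } else {
    token <- paste0(name, "_", resno)
    for (f in seq_len(L)) {
      writeLines(as.character(length(ids)), con)
      writeLines(sprintf("frame %d replica %d", f,
                         ens$replicas[[1L]]$replica_id), con)
      writeLines(sprintf("%-8s %14.6f %14.6f %14.6f", token,
                         coords[f, , 1L], coords[f, , 2L], coords[f, , 3L]),
                 con)
    }
  }
  invisible(path)
}

# Residue names for the abstract active-site frame written by the package.
.default_resname <- function(name, resno) {
  out <- rep("UNK", length(name))
  out[name == "OW"] <- "HOH"
  out[name %in% c("C1", "C2", "OE")] <- "EPX"
  out[resno %in% c(101L, 132L)] <- "ASP"
  out[resno == 53L] <- "TYR"
  out[resno == 55L] <- "ASN"
  out
}

#' Write a multi-replica ensemble with manifest
#'
#' Writes one trajectory file per replica plus a TSV manifest
#' (`file`, `replica_id`) that [read_ensemble()] consumes.
#'
#' @param ens A [ensemble()].
#' @param dir Output directory (created if absent).
#' @param format `"pdb"` or `"xyz"`.
#' @param prefix File-name prefix.
#' @return Path of the manifest file, invisibly.
#' @export
write_ensemble <- function(ens, dir, format = c("pdb", "xyz"),
                           prefix = "replica") {
  format <- match.arg(format)
  stopifnot(inherits(ens, "nac_ensemble"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(length(ens$replicas))
  for (k in seq_along(ens$replicas)) {
    rep <- ens$replicas[[k]]
    sub <- ensemble(list(rep), ens$atom_ids, ens$frame_interval_ps)
    files[k] <- file.path(dir, sprintf("%s_%03d.%s", prefix, rep$replica_id,
                                       format))
    write_frames(sub, files[k], format)
  }
  manifest <- data.frame(
    file = basename(files),
    replica_id = vapply(ens$replicas, function(r) r$replica_id, integer(1L)))
  mpath <- file.path(dir, paste0(prefix, "_manifest.tsv"))
  write.table(manifest, mpath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(mpath)
}

#' Read a multi-replica ensemble via a manifest
#'
#' @param manifest Path to a TSV manifest with columns `file` and
#'   `replica_id`; file paths are taken relative to the manifest's directory.
#' @param format `"pdb"` or `"xyz"`.
#' @param roles Optional [role_map()] checked on the first frame.
#' @param frame_interval_ps Time between stored frames (picoseconds).
#' @return A [ensemble()].
#' @export
read_ensemble <- function(manifest, format = c("pdb", "xyz"), roles = NULL,
                          frame_interval_ps = 0.005) {
  format <- match.arg(format)
  man <- read.delim(manifest, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("file", "replica_id") %in% names(man)))
    stop("read_ensemble(): manifest needs 'file' and 'replica_id' columns",
         call. = FALSE)
  base <- dirname(manifest)
  parts <- lapply(seq_len(nrow(man)), function(i) {
    read_frames(file.path(base, man$file[i]), format,
                replica_id = man$replica_id[i],
                frame_interval_ps = frame_interval_ps)
  })
  replicas <- lapply(parts, function(e) e$replicas[[1L]])
  ids0 <- parts[[1L]]$atom_ids
  for (e in parts)
    if (!identical(e$atom_ids, ids0))
      stop("read_ensemble(): atom lists differ between replica files",
           call. = FALSE)
  ens <- ensemble(replicas, ids0, frame_interval_ps,
                  metadata = list(manifest = manifest))
  if (!is.null(roles))
    label_frame(get_frame(ens, replicas[[1L]]$replica_id, 1L), roles)
  ens
}

#' Read/write a role map as a YAML config
#'
#' The config schema is a single `roles:` mapping from role name to atom
#' identifier.
#'
#' @param path YAML file.
#' @return [read_role_map()] returns a [role_map()].
#' @export
read_role_map <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$roles))
    stop("read_role_map(): config has no 'roles' mapping", call. = FALSE)
  role_map(cfg$roles)
}

#' @rdname read_role_map
#' @param roles A [role_map()].
#' @export
write_role_map <- function(roles, path) {
  stopifnot(inherits(roles, "nac_role_map"))
  yaml::write_yaml(list(roles = as.list(unclass(roles))), path)
  invisible(path)
}
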