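#' Parse point-mutation strings
#'
#' Mutations are written `<wt><position><new>` in one-letter code, e.g.
#' `"M32L"`.
#'
#' @param mutations Character vector of mutation strings.
#' @param max_position Highest valid residue position (LEH has 149 residues).
#' @return Data frame with columns `wt`, `position`, `new`.
#' @export
parse_mutations <- function(mutations, max_position = 149L) {
  mutations <- as.character(mutations)
  m <- regmatches(mutations,
                  regexec("^([A-Z])([0-9]+)([A-Z])$", mutations))
  bad <- mutations[vapply(m, length, integer(1L)) != 4L]
  if (length(bad))
    stop("parse_mutations(): unparseable mutation(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  out <- data.frame(
    wt = vapply(m, `[`, character(1L), 2L),
    position = as.integer(vapply(m, `[`, character(1L), 3L)),
    new = vapply(m, `[`, character(1L), 4L))
  aa <- names(aa_volumes())
  unknown <- setdiff(c(out$wt, out$new), aa)
  if (length(unknown))
    stop("parse_mutations(): unknown residue code(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  if (any(out$position < 1L | out$position > max_position))
    stop("parse_mutations(): position(s) outside 1-", max_position,
         call. = FALSE)
  out
}

#' The eleven LEH active-site design positions
#'
#' Positions around the LEH active site that the design libraries randomise,
#' with their wild-type residues.
#'
#' @return Named character vector, position -> wild-type one-letter code.
#' @export
design_positions <- function() {
  c(`32` = "M", `35` = "L", `74` = "L", `78` = "M", `80` = "I", `83` = "V",
    `103` = "L", `114` = "L", `116` = "I", `134` = "F", `139` = "F")
}

#' @rdname design_positions
#' @export
design_alphabet <- function() strsplit("AFGILMPVW", "")[[1L]]

#' A designed enzyme variant
#'
#' @param design_id Identifier, e.g. `"60A"`.
#' @param mutations Character vector of `<wt><pos><new>` mutations.
#' @param target Target product enantiomer, `"RR"` or `"SS"`.
#' @param substrate Substrate identifier (free text, e.g. `"3a"`).
#' @param library_design If `TRUE`, mutated positions must be among the
#'   eleven design positions.
#' @return A `design_variant` object; screening results are accumulated in
#'   its `rounds` field by the cascade.
#' @export
design_variant <- function(design_id, mutations = character(0),
                           target = c("RR", "SS"), substrate = NA_character_,
                           library_design = TRUE) {
  target <- match.arg(target)
  parsed <- if (length(mutations)) parse_mutations(mutations) else
    data.frame(wt = character(0), position = integer(0), new = character(0))
  if (library_design && nrow(parsed)) {
    pos_ok <- as.character(parsed$position) %in% names(design_positions())
    if (!all(pos_ok))
      stop("design_variant(): mutated position(s) outside the design set: ",
           paste(parsed$position[!pos_ok], collapse = ", "), call. = FALSE)
  }
  structure(list(design_id = as.character(design_id),
                 mutations = as.character(mutations), parsed = parsed,
                 target = target, substrate = substrate,
                 library_design = library_design, rounds = list()),
            class = "design_variant")
}

#' Amino-acid volume table
#'
#' Mean residue volumes (Angstrom cubed) from Chothia (1975); in mutation
#' volume differences the backbone contribution cancels, so these deltas
#' equal side-chain volume deltas.  Override by passing any named positive
#' vector over the one-letter codes.
#'
#' @return Named numeric vector, one-letter code -> volume in Angstrom cubed.
#' @references Chothia, C. (1975) Structural invariants in protein folding.
#'   Nature 254, 304-308.
#' @export
aa_volumes <- function() {
  c(A = 88.6, R = 173.4, N = 114.1, D = 111.1, C = 108.5, Q = 143.8,
    E = 138.4, G = 60.1, H = 153.2, I = 166.7, L = 166.7, K = 168.6,
    M = 162.9, F = 189.9, P = 112.7, S = 89.0, T = 116.1, W = 227.8,
    Y = 193.6, V = 140.0)
}

#' Cavity-volume change of a mutation set
#'
#' The predicted change in active-site cavity volume is the summed decrease
#' in side-chain volume over all mutations,
#' `delta = sum(vol(wt) - vol(new))` (positive = cavity enlarged).  Designs
#' whose predicted enlargement exceeds the triage threshold (default
#' 100 Angstrom cubed) tend to be too spacious and catalytically poor, and
#' are flagged for removal.
#'
#' @param mutations Character vector of `<wt><pos><new>` mutations.
#' @param table Volume table as from [aa_volumes()].
#' @param triage_threshold Flagging threshold in Angstrom cubed.
#' @return A `cavity_delta`: `delta_volume` (Angstrom cubed), `flagged`
#'   (`delta_volume > triage_threshold`), `per_mutation` breakdown,
#'   `triage_threshold`.
#' @examples
#' delta_cavity_volume(c("M32L", "L35G", "I80W", "L103V", "F139L"))
#' @export
delta_cavity_volume <- function(mutations, table = aa_volumes(),
                                triage_threshold = 100) {
  if (any(table <= 0) || is.null(names(table)))
    stop("delta_cavity_volume(): volume table must be named and positive",
         call. = FALSE)
  if (!length(mutations)) {
    return(structure(list(delta_volume = 0, flagged = FALSE,
                          per_mutation = numeric(0),
                          triage_threshold = triage_threshold),
                     class = "cavity_delta"))
  }
  parsed <- parse_mutations(mutations)
  unknown <- setdiff(c(parsed$wt, parsed$new), names(table))
  if (length(unknown))
    stop("delta_cavity_volume(): residue(s) missing from volume table: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  per <- setNames(table[parsed$wt] - table[parsed$new], mutations)
  delta <- sum(per)
  structure(list(delta_volume = delta, flagged = delta > triage_threshold,
                 per_mutation = per, triage_threshold = triage_threshold),
            class = "cavity_delta")
}

#' @export
print.cavity_delta <- function(x, ...) {
  cat(sprintf("<cavity_delta> %+.1f A^3 (%d mutation(s))%s\n",
              x$delta_volume, length(x$per_mutation),
              if (x$flagged) sprintf(" FLAGGED: > %g A^3 enlargement",
                                     x$triage_threshold) else ""))
  invisible(x)
}
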