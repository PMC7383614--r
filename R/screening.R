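#' Replica-averaged NAC frequencies
#'
#' Counts NAC frames per attack mode within each replica and aggregates over
#' replicas.  The per-replica frequency is `100 * n_NAC / n_frames`; the
#' design-level frequency is the unweighted mean over replicas (equal to
#' pooled counting when replicas have equal length, which is how the
#' generator and the cascade produce them); the spread over replicas is
#' reported as a standard deviation.
#'
#' @param ens A [ensemble()].
#' @param roles A [role_map()].
#' @param defn A [nac_definition()].
#' @return A `nac_stats` object: `per_replica_freq_RR`, `per_replica_freq_SS`
#'   (percent), `freq_RR`, `freq_SS` (mean percent), `sd_RR`, `sd_SS`,
#'   `pooled_freq_RR`, `pooled_freq_SS`, `n_frames_total`,
#'   `n_frames_per_replica`, `replica_ids`.
#' @export
nac_frequencies <- function(ens, roles = default_role_map(),
                            defn = nac_definition()) {
  stopifnot(inherits(ens, "nac_ensemble"))
  role_idx <- .role_indices(ens, roles)
  R <- length(ens$replicas)
  f_rr <- f_ss <- n_rr <- n_ss <- numeric(R)
  n_f <- integer(R)
  for (k in seq_len(R)) {
    rep <- ens$replicas[[k]]
    L <- dim(rep$coords)[1L]
    if (L < 1L)
      stop("nac_frequencies(): replica ", rep$replica_id, " is empty",
           call. = FALSE)
    cl <- .classify_block(rep$coords, role_idx, defn)
    n_f[k] <- L
    n_rr[k] <- sum(cl$proRR); n_ss[k] <- sum(cl$proSS)
    f_rr[k] <- 100 * n_rr[k] / L
    f_ss[k] <- 100 * n_ss[k] / L
  }
  structure(list(
    per_replica_freq_RR = f_rr, per_replica_freq_SS = f_ss,
    freq_RR = mean(f_rr), freq_SS = mean(f_ss),
    sd_RR = if (R > 1L) sd(f_rr) else NA_real_,
    sd_SS = if (R > 1L) sd(f_ss) else NA_real_,
    pooled_freq_RR = 100 * sum(n_rr) / sum(n_f),
    pooled_freq_SS = 100 * sum(n_ss) / sum(n_f),
    n_nac_RR = sum(n_rr), n_nac_SS = sum(n_ss),
    n_frames_total = sum(n_f), n_frames_per_replica = n_f,
    replica_ids = vapply(ens$replicas, function(r) r$replica_id, integer(1L))
  ), class = "nac_stats")
}

#' @export
print.nac_stats <- function(x, ...) {
  cat(sprintf(
    "<nac_stats> %d replicas, %d frames\n  [NAC]proRR = %.3f%% (sd %.3f)\n  [NAC]proSS = %.3f%% (sd %.3f)\n",
    length(x$per_replica_freq_RR), x$n_frames_total,
    x$freq_RR, x$sd_RR, x$freq_SS, x$sd_SS))
  invisible(x)
}

#' Predicted enantiomeric excess from NAC frequencies
#'
#' The predicted ee of the diol product is the normalised difference of the
#' two attack-mode NAC frequencies,
#' `ee = 100 * (fRR - fSS) / (fRR + fSS)` percent.  Positive values predict
#' (R,R)-diol preference, negative values (S,S).  The table-reporting
#' convention rounds to the nearest integer percent, half away from zero;
#' the unrounded value is retained.
#'
#' @param stats A `nac_stats` object (from [nac_frequencies()]), or a list
#'   with elements `freq_RR` and `freq_SS` in percent.
#' @return An `ee_prediction`: `ee_pred` (unrounded signed percent),
#'   `ee_rounded` (integer percent), `preferred` (`"RR"`, `"SS"` or
#'   `"none"`), and `nac_pref` (the NAC frequency of the preferred mode,
#'   `max(freq_RR, freq_SS)`).
#' @seealso [ee_from_nac()] for the vectorised frequency form.
#' @export
predict_ee <- function(stats) {
  f_rr <- stats$freq_RR
  f_ss <- stats$freq_SS
  ee <- ee_from_nac(f_rr, f_ss)
  structure(list(
    ee_pred = ee,
    ee_rounded = round_half_away(ee),
    preferred = if (ee > 0) "RR" else if (ee < 0) "SS" else "none",
    nac_pref = max(f_rr, f_ss),
    freq_RR = f_rr, freq_SS = f_ss
  ), class = "ee_prediction")
}

#' @export
print.ee_prediction <- function(x, ...) {
  cat(sprintf(
    "<ee_prediction> ee_pred = %+d%% (unrounded %+.2f), preferred %s, [NAC]pref = %.3f%%\n",
    x$ee_rounded, x$ee_pred, x$preferred, x$nac_pref))
  invisible(x)
}

#' @rdname predict_ee
#' @param freq_RR,freq_SS NAC frequencies in percent (vectorised).
#' @export
ee_from_nac <- function(freq_RR, freq_SS) {
  if (any(freq_RR < 0 | freq_SS < 0))
    stop("ee_from_nac(): frequencies must be non-negative", call. = FALSE)
  tot <- freq_RR + freq_SS
  if (any(tot == 0))
    stop("ee_from_nac(): undefined selectivity, both NAC frequencies zero",
         call. = FALSE)
  100 * (freq_RR - freq_SS) / tot
}

#' @rdname predict_ee
#' @param x Numeric vector.
#' @export
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Elimination-cascade configuration
#'
#' An ordered list of screening rounds.  Rounds of 10-ps replicas are
#' cumulative: each later round extends the earlier replica set (the
#' provider must return the earlier replicas unchanged as a prefix); the
#' 100-ps round is evaluated on its own standalone replicas.  A design
#' survives a round iff `|ee_pred| > ee_threshold` (strict) with the sign
#' matching its target enantiomer, and `nac_pref > nac_pref_threshold`
#' (strict) when that threshold is set.
#'
#' @param rounds Data frame with columns `label`, `n_replicas`
#'   (cumulative for 10-ps rounds), `replica_length_ps`, `ee_threshold`
#'   (percent), `nac_pref_threshold` (percent or `NA`), `cumulative`
#'   (logical).
#' @return A `cascade_config` object.
#' @export
cascade_config <- function(rounds) {
  need <- c("label", "n_replicas", "replica_length_ps", "ee_threshold",
            "nac_pref_threshold", "cumulative")
  if (!all(need %in% names(rounds)))
    stop("cascade_config(): rounds needs columns ",
         paste(need, collapse = ", "), call. = FALSE)
  thr <- c(rounds$ee_threshold, rounds$nac_pref_threshold)
  if (any(!is.na(thr) & (thr < 0 | thr > 100)))
    stop("cascade_config(): thresholds must lie in [0, 100]", call. = FALSE)
  cum <- rounds[rounds$cumulative, ]
  if (nrow(cum) > 1L && any(diff(cum$n_replicas) < 0))
    stop("cascade_config(): cumulative rounds need non-decreasing n_replicas",
         call. = FALSE)
  structure(list(rounds = rounds), class = "cascade_config")
}

#' Default MD-budget elimination scheme
#'
#' The screening scheme used for the LEH design libraries: rounds of 5, 10,
#' 20, 40 and 80 cumulative 10-ps replicas with ee thresholds of 97, 97, 97,
#' 98 and 98 percent, a `[NAC]pref` threshold at the 80-replica round (5
#' percent for the smaller epoxides, 10 percent for the bulky cis-stilbene
#' oxide), and a final standalone round of five 100-ps replicas at
#' `ee > 98` percent (`[NAC]pref > 5` percent for cis-stilbene oxide).
#'
#' @param substrate `"1a"` (cyclopentene oxide), `"2a"` (cis-2,3-butene
#'   oxide) or `"3a"` (cis-stilbene oxide); selects the per-substrate
#'   `[NAC]pref` thresholds.
#' @return A [cascade_config()].
#' @export
default_cascade_config <- function(substrate = c("1a", "2a", "3a")) {
  substrate <- match.arg(substrate)
  nac80 <- if (substrate == "3a") 10 else 5
  nac100 <- if (substrate == "3a") 5 else NA_real_
  cascade_config(data.frame(
    label = c("5x10ps", "10x10ps", "20x10ps", "40x10ps", "80x10ps",
              "5x100ps"),
    n_replicas = c(5L, 10L, 20L, 40L, 80L, 5L),
    replica_length_ps = c(10, 10, 10, 10, 10, 100),
    ee_threshold = c(97, 97, 97, 98, 98, 98),
    nac_pref_threshold = c(NA, NA, NA, NA, nac80, nac100),
    cumulative = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE)))
}

#' Run the stepwise elimination cascade over a design library
#'
#' Designs are eliminated as soon as they fail a round's criteria; a design
#' that fails never reappears in a later round, so survivor sets are nested
#' for fixed trajectories.  Statistics for cumulative rounds are recomputed
#' on the full cumulative replica set.
#'
#' @param library Data frame with columns `design_id` and `target`
#'   (`"RR"` or `"SS"`), or a list of [design_variant()] objects.
#' @param cfg A [cascade_config()].
#' @param provider Function `(design_id, n_replicas, replica_length_ps,
#'   cumulative)` returning a [ensemble()]; must be deterministic given its
#'   seed and, for cumulative requests, return earlier replicas unchanged as
#'   a prefix.  See [make_synthetic_provider()].
#' @param roles,defn Role map and NAC definition used for scoring.
#' @return A `cascade_result`: `audit` (one row per design x evaluated
#'   round with frequencies, ee and verdict), `survivors` (list of design-id
#'   vectors per round), `counts` (per-round survivor counts),
#'   `not_evaluated` (design ids whose provider failed), `initial` (library
#'   size).
#' @export
run_cascade <- function(library, cfg, provider, roles = default_role_map(),
                        defn = nac_definition()) {
  stopifnot(inherits(cfg, "cascade_config"))
  if (is.data.frame(library)) {
    lib <- library
  } else {
    lib <- do.call(rbind, lapply(library, function(v)
      data.frame(design_id = v$design_id, target = v$target)))
  }
  if (is.null(lib) || !nrow(lib)) {
    return(structure(list(audit = data.frame(), survivors = list(),
                          counts = data.frame(), not_evaluated = character(0),
                          initial = 0L),
                     class = "cascade_result"))
  }
  stopifnot(all(c("design_id", "target") %in% names(lib)),
            all(lib$target %in% c("RR", "SS")))
  alive <- as.character(lib$design_id)
  target <- setNames(as.character(lib$target), alive)
  audit <- list()
  survivors <- list()
  failed_provider <- character(0)
  for (r in seq_len(nrow(cfg$rounds))) {
    rnd <- cfg$rounds[r, ]
    still <- character(0)
    for (id in alive) {
      res <- tryCatch({
        ens <- provider(id, rnd$n_replicas, rnd$replica_length_ps,
                        rnd$cumulative)
        nac_frequencies(ens, roles, defn)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        failed_provider <- union(failed_provider, id)
        audit[[length(audit) + 1L]] <- data.frame(
          design_id = id, round = r, label = rnd$label,
          n_replicas = rnd$n_replicas, freq_RR = NA_real_,
          freq_SS = NA_real_, ee_pred = NA_real_, nac_pref = NA_real_,
          pass = NA, note = conditionMessage(res))
        next
      }
      pred <- tryCatch(predict_ee(res), error = function(e) NULL)
      if (is.null(pred)) {           # both frequencies zero: no selectivity
        ee <- NA_real_; nac_pref <- 0; pass <- FALSE
      } else {
        ee <- pred$ee_pred
        nac_pref <- pred$nac_pref
        sign_ok <- (target[[id]] == "RR" && ee > 0) ||
          (target[[id]] == "SS" && ee < 0)
        pass <- sign_ok && abs(ee) > rnd$ee_threshold &&
          (is.na(rnd$nac_pref_threshold) ||
             nac_pref > rnd$nac_pref_threshold)
      }
      audit[[length(audit) + 1L]] <- data.frame(
        design_id = id, round = r, label = rnd$label,
        n_replicas = rnd$n_replicas, freq_RR = res$freq_RR,
        freq_SS = res$freq_SS, ee_pred = ee, nac_pref = nac_pref,
        pass = pass, note = "")
      if (isTRUE(pass)) still <- c(still, id)
    }
    alive <- still
    survivors[[rnd$label]] <- alive
  }
  counts <- data.frame(round = seq_len(nrow(cfg$rounds)),
                       label = cfg$rounds$label,
                       n_surviving = vapply(survivors, length, integer(1L)))
  structure(list(audit = do.call(rbind, audit), survivors = survivors,
                 counts = counts, not_evaluated = failed_provider,
                 initial = nrow(lib) - length(failed_provider)),
            class = "cascade_result")
}

#' @export
print.cascade_result <- function(x, ...) {
  cat(sprintf("<cascade_result> %d design(s) entered\n", x$initial))
  if (nrow(x$counts)) print.data.frame(x$counts, row.names = FALSE)
  if (length(x$not_evaluated))
    cat("not evaluated (provider failure):",
        paste(x$not_evaluated, collapse = ", "), "\n")
  invisible(x)
}

#' Fraction of a library passing the full cascade
#'
#' @param initial_unique Number of unique designs entering the cascade.
#' @param final_survivors Number passing all criteria.
#' @return Percentage, one decimal.
#' @examples
#' summarize_cascade(4125, 63)  # 1.5
#' @export
summarize_cascade <- function(initial_unique, final_survivors) {
  if (initial_unique <= 0)
    stop("summarize_cascade(): initial count must be positive", call. = FALSE)
  if (any(final_survivors > initial_unique))
    stop("summarize_cascade(): survivors exceed initial designs",
         call. = FALSE)
  round(100 * final_survivors / initial_unique, 1)
}

#' Rank and select top designs for a target enantiomer
#'
#' Candidates whose predicted ee has the sign of the target enantiomer and
#' magnitude at least `ee_min` are ranked with the highest `[NAC]pref`
#' first; ties are broken by larger `|ee_pred|`, then lexicographic
#' `design_id`.
#'
#' @param candidates Data frame with columns `design_id`, `ee_pred`
#'   (signed percent) and `nac_pref` (percent).
#' @param k Number of designs to return.
#' @param target `"RR"` or `"SS"`.
#' @param ee_min Minimum `|ee_pred|` (percent).
#' @return The selected rows in rank order; if fewer than `k` candidates are
#'   eligible, all eligible rows are returned with attribute
#'   `short_selection = TRUE` and a warning.
#' @export
select_top_designs <- function(candidates, k, target = c("RR", "SS"),
                               ee_min = 0) {
  target <- match.arg(target)
  stopifnot(k >= 1L,
            all(c("design_id", "ee_pred", "nac_pref") %in% names(candidates)))
  sgn <- if (target == "RR") 1 else -1
  elig <- candidates[sign(candidates$ee_pred) == sgn &
                       abs(candidates$ee_pred) >= ee_min, , drop = FALSE]
  ord <- order(-elig$nac_pref, -abs(elig$ee_pred),
               as.character(elig$design_id))
  elig <- elig[ord, , drop = FALSE]
  short <- nrow(elig) < k
  if (short)
    warning(sprintf("select_top_designs(): only %d eligible candidate(s) for k = %d",
                    nrow(elig), k), call. = FALSE)
  out <- head(elig, k)
  rownames(out) <- NULL
  attr(out, "short_selection") <- short
  out
}

#' Write cascade and design tables as TSV
#'
#' `write_cascade_table()` mirrors the screening-summary layout (one row per
#' round: label, criteria, surviving designs, plus the final pass
#' percentage); `write_design_table()` mirrors the design-table layout
#' (design, mutations, NAC percent for both modes, rounded predicted ee).
#' Both files are deterministic and round-trip parseable with
#' [utils::read.delim()].
#'
#' @param result A `cascade_result` from [run_cascade()].
#' @param cfg The [cascade_config()] used.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_cascade_table <- function(result, cfg, path) {
  stopifnot(inherits(result, "cascade_result"), inherits(cfg, "cascade_config"))
  criteria <- sprintf("ee_pred > %g%%%s", cfg$rounds$ee_threshold,
                      ifelse(is.na(cfg$rounds$nac_pref_threshold), "",
                             sprintf(" + [NAC]pref > %g%%",
                                     cfg$rounds$nac_pref_threshold)))
  tab <- data.frame(round = result$counts$label, criteria = criteria,
                    n_surviving = result$counts$n_surviving)
  final <- utils::tail(result$counts$n_surviving, 1L)
  tab <- rbind(tab, data.frame(
    round = "passing_all_criteria_pct", criteria = "",
    n_surviving = if (result$initial > 0)
      summarize_cascade(result$initial, final) else NA_real_))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cascade_table
#' @param designs Data frame with columns `design_id`, `mutations`,
#'   `freq_RR`, `freq_SS` (percent).
#' @export
write_design_table <- function(designs, path) {
  need <- c("design_id", "mutations", "freq_RR", "freq_SS")
  stopifnot(all(need %in% names(designs)))
  out <- designs[, need]
  out$ee_pred <- round_half_away(ee_from_nac(out$freq_RR, out$freq_SS))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
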