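#' Published LEH redesign reference table
#'
#' The literature-reported MD screening results for 30 characterised LEH
#' redesigns (three meso-epoxide substrates, five designs per target
#' enantiomer; two designs were selected for two substrates): mutation
#' lists, the replica-averaged NAC frequencies of both attack modes
#' (percent) and the reported rounded predicted ee.  Used as worked-example
#' input for the ee predictor, the ranking rule and the cavity-volume
#' triage.
#'
#' @return Data frame with columns `substrate` (`1a` cyclopentene oxide,
#'   `2a` cis-2,3-butene oxide, `3a` cis-stilbene oxide), `target`,
#'   `design_id`, `mutations`, `nac_rr`, `nac_ss`, `ee_reported`.
#' @export
leh_reference_designs <- function() {
  path <- system.file("extdata", "leh_design_table.tsv",
                      package = "nacscreen", mustWork = TRUE)
  read.delim(path, sep = "\t", stringsAsFactors = FALSE,
             colClasses = c(rep("character", 4L), rep("numeric", 3L)))
}
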