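#' Catalogue of the 23 social and cognitive input variables
#'
#' The modelled cohort is assessed with five instruments: the Brief
#' Assessment of Cognition in Schizophrenia (BACS, 9 variables), the
#' High-Risk Social Challenge task (HiSoC, 4), the Snakes-in-the-grass
#' attention task (SNK, 6), the Perceptual Closure test (PC, 3) and the
#' Continuous Performance Task (CPT, 1).  The catalogue fixes variable ids
#' 1--23, their instrument and the cognitive or social domain each taps.
#'
#' @return data.frame with columns `variable_id`, `name`, `instrument`,
#'   `domain`; exactly 23 rows with contiguous ids.
#' @export
variable_catalog <- function() {
  cat <- data.frame(
    variable_id = 1:23,
    name = c(
      "list_learning", "digit_sequencing", "token_motor_task",
      "semantic_fluency_animals", "semantic_fluency_fruits",
      "semantic_fluency_vegetables", "semantic_fluency_raw",
      "symbol_coding", "tower_of_london",
      "affect", "odd_behaviour_language", "social_interpersonal",
      "social_total",
      "snk_target_rt", "snk_target_accuracy", "snk_distractor_rt",
      "snk_distractor_accuracy", "snk_total_rt", "snk_total_accuracy",
      "pc_filtered", "pc_averaged", "pc_accuracy",
      "cpt_total"
    ),
    instrument = c(
      rep("BACS", 9), rep("HiSoC", 4), rep("SNK", 6), rep("PC", 3), "CPT"
    ),
    domain = c(
      "verbal memory", "working memory", "motor speed",
      "processing speed", "processing speed", "processing speed",
      "processing speed", "attention and processing speed",
      "executive function",
      "affect and speech fluency", "nonverbal affect and gaze",
      "communication and appearance", "total social score",
      "visual attention", "visual attention", "inhibition",
      "inhibition", "speed of processing", "attentional bias",
      "arousal", "attention to whole figure", "set maintenance",
      "sustained and selective attention"
    ),
    stringsAsFactors = FALSE
  )
  validate_catalog(cat)
  cat
}

validate_catalog <- function(cat) {
  stopifnot(
    is.data.frame(cat),
    nrow(cat) == 23,
    identical(cat$variable_id, 1:23),
    all(c("variable_id", "name", "instrument", "domain") %in% names(cat))
  )
  counts <- table(cat$instrument)
  expected <- c(BACS = 9L, CPT = 1L, HiSoC = 4L, PC = 3L, SNK = 6L)
  if (!identical(as.integer(counts[names(expected)]), unname(expected)))
    stop("catalogue instrument counts must be BACS=9, HiSoC=4, SNK=6, PC=3, CPT=1")
  invisible(cat)
}

#' Write / read the variable catalogue as CSV
#'
#' @param catalog data.frame from [variable_catalog()].
#' @param path file path.
#' @return `read_catalog` returns the validated catalogue.
#' @export
write_catalog <- function(catalog, path) {
  validate_catalog(catalog)
  write.csv(catalog, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_catalog
#' @export
read_catalog <- function(path) {
  cat <- read.csv(path, stringsAsFactors = FALSE)
  validate_catalog(cat)
  cat
}
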