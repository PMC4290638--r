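#' The 37-measure neuropsychological and mood test battery
#'
#' Returns the ordered catalogue of the 37 cognitive and mood measures used
#' throughout the package: baseline scores from the MMSE, Logical Memory
#' (WMS, story 1), CVLT-II, Rey Complex Figure Test, D-KEFS verbal fluency,
#' Boston Naming Test, WAIS-III subtests, the Victoria Stroop task, Clock
#' Drawing, WTAR, CDR Sum of Boxes and HADS.  Feature `k` of every genome,
#' cohort column `vk` and model term `vk` refer to row `k` of this table.
#'
#' Measures normed as z-scores carry `score_kind = "z"`; measures kept on
#' their raw scale (counts, time, IQ, totals) carry `"raw"`.  Exactly one
#' measure, the Logical Memory Pass/Fail flag (index 4), is binary.
#'
#' @return A data.frame with columns `index` (1..37), `name`, `source`
#'   (instrument acronym), `score_kind` (`"z"` or `"raw"`) and `value_kind`
#'   (`"continuous"` or `"binary"`).
#' @examples
#' b <- default_battery()
#' b[b$index %in% c(3, 5, 18), ]
#' @export
default_battery <- function() {
  b <- data.frame(
    index = 1:37,
    name = c(
      "Mini Mental State Exam",
      "Logical Memory I",
      "Logical Memory II",
      "Logical Memory Pass/Fail",
      "Total Learning (List A Trials 1-5)",
      "List A T6 Retention",
      "List A 30 min Delayed Recall",
      "List A Recognition",
      "List A False Positives",
      "Total Recognition d'",
      "Rey Complex Figure Copy",
      "Rey Complex Figure Copy time",
      "Rey Complex Figure 3 min delay",
      "Rey Complex Figure 30 min delay",
      "Rey Complex Figure Recog",
      "Letter Fluency",
      "Category Fluency",
      "Category Switching Total",
      "Category Switching (switches)",
      "No Cue Australian",
      "No Cue US",
      "Digit span",
      "Digit symbol-Coding",
      "UK Pred Full Score IQ",
      "US Pred Full Score IQ",
      "Dots time",
      "Dots errs",
      "Words time",
      "Words errs",
      "Colours time",
      "Colours errs",
      "C/D",
      "Clock score",
      "WTAR IQ score",
      "CDR Sum of Boxes",
      "Depression",
      "Anxiety"),
    source = c(
      "MMSE", "LM", "LM", "LM",
      rep("CVLT-II", 6),
      rep("RCFT", 5),
      rep("D-KEFS", 4),
      "BNT", "BNT",
      rep("WAIS-III", 4),
      rep("Stroop", 7),
      "CDT", "WTAR", "CDRSoB",
      "HADS", "HADS"),
    stringsAsFactors = FALSE
  )
  raw <- c(1, 2, 3, 5, 16:19, 22:25, 33:37)
  b$score_kind <- ifelse(b$index %in% raw, "raw", "z")
  b$score_kind[4] <- "raw"
  b$value_kind <- ifelse(b$index == 4, "binary", "continuous")
  class(b) <- c("feature_battery", "data.frame")
  b
}

#' Size of the feature search space
#'
#' The number of candidate feature subsets over an `n`-bit genome, `2^n`
#' (about 1.37e11 for the default 37-measure battery).
#'
#' @param n_bits genome length; defaults to the battery size.
#' @return a double, `2^n_bits`.
#' @export
search_space_size <- function(n_bits = 37L) 2^n_bits

# Column labels v1..v37 in battery order.
feature_columns <- function(battery = default_battery()) {
  paste0("v", battery$index)
}
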