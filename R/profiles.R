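# Published per-group mean of each battery measure.  Columns: the three
# baseline clinical groups (HC, MCI, AD) and, for each prediction task, the
# 36-month non-converter and converter subgroups.
.group_means <- local({
  m <- matrix(c(
    # HC     MCI     AD     HC_nc   HC_c    MCI_nc  MCI_c
    28.84,  26.20,  19.10,  28.96,  28.23,  27.37,  25.79,   # v1
    12.90,   6.51,   3.24,  13.24,   9.84,   7.53,   5.91,   # v2
    11.38,   3.79,   1.02,  11.80,   7.10,   5.03,   3.04,   # v3
     0.92,   0.31,   0.09,   0.07,   0.27,   0.60,   0.70,   # v4
    60.55,  38.30,  26.56,  61.35,  51.23,  41.07,  35.40,   # v5
     0.87,  -1.37,  -2.21,   0.95,  -0.03,  -1.18,  -1.81,   # v6
     0.79,  -1.62,  -2.53,   0.89,  -0.05,  -1.38,  -2.02,   # v7
     0.09,  -1.16,  -1.90,   0.12,   0.21,  -0.98,  -1.22,   # v8
    -0.21,   1.16,   2.14,  -0.26,   0.58,   0.72,   1.65,   # v9
     0.46,  -1.21,  -2.06,   0.52,  -0.10,  -0.70,  -1.52,   # v10
    -0.54,  -1.49,  -3.23,  -0.49,  -0.84,  -1.42,  -1.61,   # v11
    -1.01,  -0.78,  -0.49,  -1.00,  -1.00,  -0.76,  -0.76,   # v12
     0.48,  -0.82,  -1.92,   0.50,   0.06,  -0.52,  -1.13,   # v13
     0.53,  -1.02,  -2.15,   0.56,   0.06,  -0.58,  -1.39,   # v14
     0.31,  -1.15,  -2.91,   0.33,   0.34,  -0.36,  -1.88,   # v15
    12.04,  10.04,   7.32,  12.17,  11.06,   9.23,   9.57,   # v16
    12.38,   9.03,   5.31,  12.50,  11.87,   9.23,   8.83,   # v17
    12.13,   8.25,   4.46,  12.33,   9.71,   8.87,   7.57,   # v18
    12.15,   8.60,   4.89,  12.34,   9.87,   9.33,   7.59,   # v19
     0.74,   0.18,  -1.12,   0.78,   0.72,   0.44,   0.03,   # v20
     0.72,   0.27,  -0.82,   0.76,   0.66,   0.50,   0.27,   # v21
    12.00,  11.11,   9.10,  12.11,  12.06,  10.73,  11.09,   # v22
    11.68,   9.85,   6.53,  11.76,  10.65,  10.13,   9.33,   # v23
   108.33, 105.92, 100.84, 108.46, 107.32, 103.47, 107.53,   # v24
   111.62, 108.91, 104.22, 111.82, 110.32, 106.60, 110.32,   # v25
    -0.05,   0.48,   2.10,  -0.03,   0.08,   0.63,   0.38,   # v26
     0.02,   0.08,   0.28,   0.03,   0.06,   0.26,   0.04,   # v27
     0.06,   0.94,   4.57,   0.02,   0.64,   0.90,   1.09,   # v28
     0.08,   0.17,   0.64,   0.07,   0.23,   0.19,   0.29,   # v29
    -0.34,   0.35,   1.83,  -0.36,   0.13,   0.31,   0.39,   # v30
     0.73,   1.55,   3.08,   0.67,   1.06,   1.00,   1.76,   # v31
    -0.32,   0.05,   0.57,  -0.34,  -0.02,  -0.10,   0.02,   # v32
     9.75,   9.31,   7.22,   9.79,   9.90,   9.60,   9.33,   # v33
    43.12,  40.48,  36.32,  43.31,  41.84,  38.40,  41.79,   # v34
     0.04,   1.21,   5.74,   0.03,   0.15,   0.73,   1.37,   # v35
     2.62,   3.71,   4.06,   2.56,   3.07,   3.90,   3.24,   # v36
     4.33,   4.94,   4.98,   4.28,   4.20,   4.97,   4.52),  # v37
    nrow = 37, byrow = TRUE)
  colnames(m) <- c("HC", "MCI", "AD",
                   "HC-nonconverter", "HC-converter",
                   "MCI-nonconverter", "MCI-converter")
  rownames(m) <- paste0("v", 1:37)
  m
})

#' Published mean profile of a clinical group
#'
#' Per-measure baseline means for one of the seven clinical groups: the
#' three diagnostic categories (`"HC"`, `"MCI"`, `"AD"`) or the 36-month
#' converter / non-converter subgroups of the two prediction tasks.
#'
#' @param group one of `"HC"`, `"MCI"`, `"AD"`, `"HC-converter"`,
#'   `"HC-nonconverter"`, `"MCI-converter"`, `"MCI-nonconverter"`.
#' @return a `group_profile`: named numeric vector of 37 means (`v1`..`v37`)
#'   with attribute `group`.
#' @export
group_profile <- function(group) {
  group <- match.arg(group, colnames(.group_means))
  p <- .group_means[, group]
  structure(p, group = group, class = c("group_profile", "numeric"))
}

#' Default converter / non-converter profiles for a prediction task
#'
#' The two class-mean profiles the cohort simulator uses: for the
#' `"hc-conversion"` task the HC participants who did / did not progress to
#' MCI or AD within 36 months, and for `"mci-conversion"` the MCI
#' participants who did / did not progress to AD.
#'
#' @param task `"hc-conversion"` or `"mci-conversion"`.
#' @return a list with elements `converter` and `nonconverter`, each a
#'   [group_profile()].
#' @examples
#' p <- default_profiles("hc-conversion")
#' p$converter[["v3"]]     # 7.10
#' p$nonconverter[["v3"]]  # 11.80
#' @export
default_profiles <- function(task = c("hc-conversion", "mci-conversion")) {
  task <- match.arg(task)
  pre <- if (task == "hc-conversion") "HC" else "MCI"
  list(converter = group_profile(paste0(pre, "-converter")),
       nonconverter = group_profile(paste0(pre, "-nonconverter")))
}

#' Default per-measure standard deviations
#'
#' SDs are not part of the published group summaries, so the simulator uses
#' a fixed convention: 1.0 for z-scored measures and, for raw-scale
#' measures, half the HC-to-AD mean gap (floored at 0.5).  This scales
#' between-group separations to plausible magnitudes: e.g. Logical Memory II
#' gets SD 5.18, so the HC-task converter gap of 4.7 points is ~0.9 SD.
#'
#' @param battery a [default_battery()] table.
#' @return named numeric vector of 37 SDs.
#' @export
default_sds <- function(battery = default_battery()) {
  sds <- rep(1, nrow(battery))
  raw <- battery$score_kind == "raw" & battery$value_kind == "continuous"
  gap <- abs(.group_means[, "HC"] - .group_means[, "AD"]) / 2
  sds[raw] <- pmax(gap[raw], 0.5)
  names(sds) <- paste0("v", battery$index)
  sds
}
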