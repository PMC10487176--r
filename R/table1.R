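#' Published per-limb regression table of the equine cadaver study
#'
#' The packaged transcription of the published per-horse, per-limb slope,
#' slope standard error and Pearson r of the voxel-wise BMD-PI regressions
#' (six thoroughbred racehorses, limbs LF/RF/LH/RH; the right forelimb of
#' horse 1 was excluded for metallic implants, leaving 23 analyzable
#' specimens). Slopes are in PI % per BMD unit.
#'
#' @return A tibble with columns `horse`, `limb`, `slope`, `slope_se`, `r`,
#'   `excluded`.
#' @examples
#' t1 <- table1()
#' mean(t1$r[!t1$excluded])
#' @export
table1 <- function() {
  path <- system.file("extdata", "table1.csv", package = "porindex", mustWork = TRUE)
  tbl <- tibble::as_tibble(read.csv(path))
  tbl$limb <- as.character(tbl$limb)
  tbl
}

#' Reproduce the published study summary from the packaged table
#'
#' Runs [build_study_table()] on [table1()], yielding the overall mean/SD of
#' r and slope, the eight group mean r values, and the four group t-tests.
#'
#' @param variant t-test variant.
#' @return A `pi_study`.
#' @examples
#' reproduce_table1()
#' @export
reproduce_table1 <- function(variant = c("student", "welch")) {
  build_study_table(table1(), variant = match.arg(variant))
}
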