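# Canonical block designs of the task localizers, reconstructed from their
# stated block timings. The facial-expression and grasping designs rebuild
# their printed run lengths exactly (185 and 305 volumes at TR 2 s); the
# taste/distaste/vestibular designs take the printed run length explicitly
# because their stated blocks under-fill it (the builder logs the gap).

#' Facial-expression localizer design
#'
#' Five start volumes, then three repeats of lip-smacking (30 s) - fixation
#' (10 s) - scrambled (30 s) - fixation (10 s) - fixation (30 s) - fixation
#' (10 s): 185 volumes at TR 2 s.
#'
#' @param tr_seconds TR (default 2).
#' @return A `block_design`.
#' @export
facial_expression_design <- function(tr_seconds = 2) {
  blocks <- data.frame(
    condition = c("lipsmack", "fix", "scrambled", "fix", "fix", "fix"),
    duration_s = c(30, 10, 30, 10, 30, 10))
  build_block_design(blocks, tr_seconds, start_volumes = 5L, repeats = 3L)
}

#' Grasping execution localizer design
#'
#' Five start volumes, then a ten-block sequence of 30 s each (three grasp
#' sizes, reach-only and fixation baseline, each followed by fixation),
#' presented twice: 305 volumes at TR 2 s.
#'
#' @param tr_seconds TR (default 2).
#' @return A `block_design`.
#' @export
grasping_design <- function(tr_seconds = 2) {
  blocks <- data.frame(
    condition = c("grasp16", "fix", "grasp40", "fix", "grasp23", "fix",
                  "reach", "fix", "baseline", "fix"),
    duration_s = rep(30, 10))
  build_block_design(blocks, tr_seconds, start_volumes = 5L, repeats = 2L)
}

#' Resting-state run design
#'
#' A 10-minute run of 300 volumes at TR 2 s with no events.
#'
#' @param tr_seconds TR (default 2).
#' @return A `block_design`.
#' @export
resting_design <- function(tr_seconds = 2) {
  build_block_design(NULL, tr_seconds, start_volumes = 300L)
}

#' Taste localizer design (explicit run length)
#'
#' Blocks of 20 s tastant (sweet, sour, water) each followed by 10 s water
#' rinse, repeated three times; the printed run length of 185 volumes is
#' supplied explicitly since the stated blocks alone fill 135 volumes.
#'
#' @param tr_seconds TR (default 2).
#' @return A `block_design` (with a nonzero `length_discrepancy`).
#' @export
taste_design <- function(tr_seconds = 2) {
  blocks <- data.frame(
    condition = rep(c("sweet", "rinse", "sour", "rinse", "water", "rinse"),
                    length.out = 6L),
    duration_s = rep(c(20, 10), 3L))
  build_block_design(blocks, tr_seconds, start_volumes = 0L, repeats = 3L,
                     n_volumes = 185L)
}

#' Galvanic vestibular stimulation design
#'
#' Alternating 18 s blocks of stimulation and no stimulation, six cycles,
#' within the printed 145-volume run (BOLD, anesthetized).
#'
#' @param tr_seconds TR (default 1.5).
#' @return A `block_design`.
#' @export
vestibular_design <- function(tr_seconds = 1.5) {
  blocks <- data.frame(condition = c("stimulation", "nostim"),
                       duration_s = c(18, 18))
  build_block_design(blocks, tr_seconds, start_volumes = 0L, repeats = 6L,
                     n_volumes = 145L)
}
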