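#' Degeneration schedule for progressive dendritic atrophy
#'
#' Maps disease stages to numbers of truncation steps. At each step one
#' dendritic segment of `step_length` µm is truncated at every terminal,
#' so stages accumulate distal loss: 0, 10, 20 and 30 steps for PD0-PD3.
#'
#' @param step_length length removed per terminal per step, µm.
#' @param resample_resolution sampling resolution required before
#'   truncation, µm.
#' @param stage_steps named integer vector of steps per stage.
#' @return A list of class `degeneration_schedule`.
#' @export
degeneration_schedule <- function(step_length = 3, resample_resolution = 3,
                                  stage_steps = c(PD0 = 0L, PD1 = 10L,
                                                  PD2 = 20L, PD3 = 30L)) {
  stopifnot(step_length > 0, resample_resolution > 0)
  if (is.unsorted(stage_steps)) stop("stage_steps must be non-decreasing")
  structure(list(step_length = step_length,
                 resample_resolution = resample_resolution,
                 stage_steps = stage_steps),
            class = "degeneration_schedule")
}

#' Apply one dendritic truncation step
#'
#' Every dendritic terminal loses `step_length` µm of path length,
#' removed tip-first. A terminal branch shorter than the step is removed
#' entirely and truncation stops at the branch point (no borrowing from
#' the parent section within the same step); the branch point becomes a
#' terminal eligible from the next step on. A primary dendrite consumed
#' down to the soma is deleted. Axonal and somatic nodes are untouched.
#' Node ids of surviving nodes are preserved (a truncated terminal node
#' keeps its id but moves toward its parent).
#'
#' @param morph a [morphology()], resampled at a resolution no coarser
#'   than `step_length`.
#' @param step_length µm removed per terminal, default 3.
#' @return The truncated [morphology()].
#' @export
degenerate_step <- function(morph, step_length = 3) {
  stopifnot(step_length > 0)
  n <- nrow(morph)
  pidx <- parent_index(morph)
  seg <- segment_lengths(morph)
  nchild0 <- child_counts(morph)        # child counts at step start
  root <- which(is.na(pidx))
  dend <- is_dendrite_type(morph$type)
  terminals <- which(dend & nchild0 == 0L)
  if (!length(terminals)) return(morph)

  drop <- rep(FALSE, n)
  newxyz <- as.matrix(morph[, c("x", "y", "z")])
  for (t in terminals) {
    rem <- step_length
    i <- t
    repeat {
      p <- pidx[i]
      L <- seg[i]
      if (L > rem + 1e-12) {
        # shift the tip toward its parent by the remaining amount
        frac <- (L - rem) / L
        newxyz[i, ] <- newxyz[p, ] + (newxyz[i, ] - newxyz[p, ]) * frac
        break
      }
      drop[i] <- TRUE
      rem <- rem - L
      if (rem <= 1e-12) break
      # continue only into an unbranched dendritic parent
      if (p == root || nchild0[p] != 1L || !dend[p]) break
      i <- p
    }
  }
  out <- morph
  out$x <- newxyz[, 1]; out$y <- newxyz[, 2]; out$z <- newxyz[, 3]
  out <- out[!drop, , drop = FALSE]
  rownames(out) <- NULL
  morphology(out)
}

#' Degenerate a morphology to a disease stage
#'
#' Applies [degenerate_step()] the number of times the schedule assigns
#' to `stage`. PD0 is the identity. If the dendritic sampling is coarser
#' than the schedule's resolution, the morphology is resampled first
#' (note this renumbers node ids; morphologies produced by
#' [generate_morphology()] are already sampled at 3 µm and keep their
#' ids).
#'
#' @param morph a [morphology()].
#' @param stage one of the names in `schedule$stage_steps` ("PD0".."PD3").
#' @param schedule a [degeneration_schedule()].
#' @return The degenerated [morphology()].
#' @export
degenerate <- function(morph, stage, schedule = degeneration_schedule()) {
  if (!stage %in% names(schedule$stage_steps)) stop("unknown stage: ", stage)
  steps <- schedule$stage_steps[[stage]]
  if (steps == 0L) return(morph)
  seg <- segment_lengths(morph)
  dend <- is_dendrite_type(morph$type)
  maxseg <- suppressWarnings(max(seg[dend], na.rm = TRUE))
  if (is.finite(maxseg) && maxseg > schedule$resample_resolution + 1e-9) {
    morph <- resample(morph, schedule$resample_resolution)
  }
  for (k in seq_len(steps)) morph <- degenerate_step(morph, schedule$step_length)
  morph
}
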