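#' Specification of axonal terminal outgrowth
#'
#' Parameters for the persistent-random-walk extension applied to every
#' axonal terminal. Each terminal gains exactly `extension_per_terminal`
#' µm of path length, laid down in steps of `segment_step` µm whose
#' heading is the previous heading blended with an isotropic random
#' direction (`tortuosity` is the persistence weight: 1 = straight,
#' 0 = uncorrelated). With `radius_cap` set, the walk reflects at that
#' Euclidean distance from the soma, so the arbor becomes denser without
#' extending its spatial envelope.
#'
#' @param extension_per_terminal path length added per terminal, µm.
#' @param tortuosity persistence of the growth walk in `[0, 1]`.
#' @param radius_cap optional reflective bound on distance from soma, µm;
#'   `NA` (default) for unbounded growth.
#' @param segment_step step size of the walk, µm.
#' @param seed integer seed for the walk directions.
#' @return A list of class `growth_spec`.
#' @export
growth_spec <- function(extension_per_terminal = 61, tortuosity = 0.8,
                        radius_cap = NA_real_, segment_step = 3, seed = 1L) {
  stopifnot(extension_per_terminal > 0, tortuosity >= 0, tortuosity <= 1,
            segment_step > 0)
  structure(list(extension_per_terminal = extension_per_terminal,
                 tortuosity = tortuosity, radius_cap = radius_cap,
                 segment_step = segment_step, seed = as.integer(seed)),
            class = "growth_spec")
}

random_unit_vector <- function() {
  repeat {
    v <- stats::rnorm(3)
    nv <- sqrt(sum(v^2))
    if (nv > 1e-9) return(v / nv)
  }
}

#' Extend every axonal terminal by a fixed path length
#'
#' Models activity-dependent axonal sprouting: each axonal terminal is
#' extended by exactly `spec$extension_per_terminal` µm of path length
#' via a persistent random walk (see [growth_spec()]). Dendrites and
#' soma are untouched; new nodes get fresh ids above the current
#' maximum, so existing node ids remain valid anchors.
#'
#' @param morph a [morphology()] with at least one axonal terminal.
#' @param spec a [growth_spec()].
#' @return The grown [morphology()]. If no axon is present the input is
#'   returned unchanged with a warning.
#' @export
grow_axon_terminals <- function(morph, spec = growth_spec()) {
  validate_morphology(morph)
  nchild <- child_counts(morph)
  axon <- is_axon_type(morph$type)
  terminals <- which(axon & nchild == 0L)
  if (!length(terminals)) {
    warning("morphology has no axonal terminals; returning unchanged")
    return(morph)
  }
  pidx <- parent_index(morph)
  soma <- soma_position(morph)
  cap <- spec$radius_cap
  step <- spec$segment_step
  total <- spec$extension_per_terminal
  # step lengths: full steps plus an exact remainder so the added path
  # length is exactly `total`
  nfull <- floor(total / step)
  steps <- c(rep(step, nfull), total - nfull * step)
  steps <- steps[steps > 1e-12]

  old <- withr_seed(spec$seed)
  on.exit(restore_seed(old), add = TRUE)

  next_id <- max(morph$id)
  pieces <- list(morph)
  for (t in terminals) {
    pos <- c(morph$x[t], morph$y[t], morph$z[t])
    prev <- if (!is.na(pidx[t])) {
      p <- pidx[t]
      d <- pos - c(morph$x[p], morph$y[p], morph$z[p])
      n <- sqrt(sum(d^2))
      if (n > 1e-9) d / n else random_unit_vector()
    } else random_unit_vector()
    ids <- next_id + seq_along(steps)
    next_id <- next_id + length(steps)
    xyz <- matrix(0, length(steps), 3)
    for (k in seq_along(steps)) {
      h <- spec$tortuosity * prev + (1 - spec$tortuosity) * random_unit_vector()
      nh <- sqrt(sum(h^2))
      h <- if (nh > 1e-9) h / nh else random_unit_vector()
      cand <- pos + h * steps[k]
      if (is.finite(cap)) {
        r <- cand - soma
        if (sqrt(sum(r^2)) > cap) {
          # reflect the radial component of the heading inward
          rad <- (pos - soma)
          nr <- sqrt(sum(rad^2))
          if (nr > 1e-9) {
            rad <- rad / nr
            h <- h - 2 * sum(h * rad) * rad
            cand <- pos + h * steps[k]
          }
        }
      }
      xyz[k, ] <- cand
      prev <- h
      pos <- cand
    }
    pieces[[length(pieces) + 1L]] <- data.frame(
      id = ids, type = SWC_AXON, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      radius = morph$radius[t], parent = c(morph$id[t], ids[-length(ids)]))
  }
  out <- do.call(rbind, lapply(pieces, as.data.frame))
  rownames(out) <- NULL
  morphology(out)
}

# Seed handling: save/restore .Random.seed so seeded helpers do not
# disturb the caller's RNG stream.
withr_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
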