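#' Placement configuration for a cubic striatal volume
#'
#' Defaults follow the striatal census: 80,500 neurons/mm3, 95% SPNs
#' split equally between dSPN and iSPN, and 3.2% modeled interneurons.
#' The interneuron split (FS 1.3%, ChIN 1.1%, LTS 0.8%) is an assumption
#' (the published total is 3.2% without a printed subtype breakdown).
#' The remaining fraction is placed as type `"other"`: it occupies
#' volume in the census but carries no morphology and makes no synapses.
#'
#' @param cube_side side of the cube, µm.
#' @param density neurons per mm3.
#' @param composition named fractions per cell type (must sum to <= 1).
#' @param seed integer seed.
#' @param morph_variants number of morphology variants per cell type the
#'   placement cycles through (must match the morphology library).
#' @return A list of class `placement_config`.
#' @export
placement_config <- function(cube_side = 300, density = 80500,
                             composition = c(dSPN = 0.475, iSPN = 0.475,
                                             FS = 0.013, ChIN = 0.011,
                                             LTS = 0.008),
                             seed = 1L, morph_variants = 1L) {
  stopifnot(density > 0, all(composition >= 0))
  if (sum(composition) > 1 + 1e-9) stop("composition fractions must sum to <= 1")
  structure(list(cube_side = cube_side, density = density,
                 composition = composition, seed = as.integer(seed),
                 morph_variants = as.integer(morph_variants)),
            class = "placement_config")
}

# uniform random rotation matrices via normalized quaternions
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Place neurons uniformly in a cube
#'
#' Neuron count is `round(density * volume)`; positions are i.i.d.
#' uniform in the cube and orientations uniform random rotations. Type
#' counts follow the composition fractions by largest remainder; the
#' unassigned remainder is placed as type `"other"` (no morphology).
#' Deterministic per seed.
#'
#' @param config a [placement_config()].
#' @return A list of class `placement`: `instances` (data.frame `id`,
#'   `cell_type`, `morph_ref`, `x`, `y`, `z`) and `rotations` (list of
#'   3x3 matrices), with the cube side as attribute `cube_side`.
#' @export
place_neurons <- function(config) {
  old <- withr_seed(config$seed)
  on.exit(restore_seed(old), add = TRUE)
  vol_mm3 <- (config$cube_side / 1000)^3
  n <- round(config$density * vol_mm3)
  if (n == 0) {
    inst <- data.frame(id = integer(0), cell_type = character(0),
                       morph_ref = character(0), x = numeric(0),
                       y = numeric(0), z = numeric(0))
    out <- structure(list(instances = inst, rotations = list()),
                     class = "placement")
    attr(out, "cube_side") <- config$cube_side
    return(out)
  }
  # largest-remainder apportionment of type counts
  frac <- config$composition
  exact <- frac * n
  base <- floor(exact)
  extra <- round(sum(exact)) - sum(base)
  if (extra > 0) {
    ord <- order(exact - base, decreasing = TRUE)
    base[ord[seq_len(extra)]] <- base[ord[seq_len(extra)]] + 1
  }
  types <- c(rep(names(frac), base), rep("other", n - sum(base)))
  types <- sample(types, n)
  variant <- integer(n)
  for (ct in unique(types)) {
    idx <- which(types == ct)
    variant[idx] <- ((seq_along(idx) - 1L) %% config$morph_variants) + 1L
  }
  inst <- data.frame(
    id = seq_len(n), cell_type = types,
    morph_ref = ifelse(types == "other", NA_character_,
                       paste0(types, "_", variant)),
    x = stats::runif(n, 0, config$cube_side),
    y = stats::runif(n, 0, config$cube_side),
    z = stats::runif(n, 0, config$cube_side))
  rotations <- replicate(n, random_rotation(), simplify = FALSE)
  out <- structure(list(instances = inst, rotations = rotations),
                   class = "placement")
  attr(out, "cube_side") <- config$cube_side
  out
}

#' @export
print.placement <- function(x, ...) {
  cat(sprintf("<placement> %d neurons in a %.0f um cube\n",
              nrow(x$instances), attr(x, "cube_side")))
  print(table(x$instances$cell_type))
  invisible(x)
}
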