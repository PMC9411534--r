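#' A labelled 3D niche volume
#'
#' Holds the glial membrane intensity channel and the stem-cell label
#' image on congruent `Z x Y x X` grids. Stem-cell detection itself is
#' not performed here: labels (and any manual corrections) are inputs.
#'
#' @param membrane Numeric `Z x Y x X` array (or `Y x X` matrix) of
#'   membrane-channel intensities.
#' @param nsc_labels Integer array of the same shape; value `i > 0` marks
#'   pixels of stem cell `i`, 0 is background.
#' @param pixel_size Pixel size in \eqn{\mu m}.
#' @param chamber_assignment Optional tibble (`nsc`, `chamber`) mapping
#'   stem cells to membrane chambers.
#' @return An object of class `niche_volume`.
#' @export
niche_volume <- function(membrane, nsc_labels, pixel_size,
                         chamber_assignment = NULL) {
  if (is.matrix(membrane)) membrane <- array(membrane, c(1L, dim(membrane)))
  if (is.matrix(nsc_labels)) {
    nsc_labels <- array(nsc_labels, c(1L, dim(nsc_labels)))
  }
  if (!identical(dim(membrane), dim(nsc_labels))) {
    abort("`membrane` and `nsc_labels` must have identical dimensions.")
  }
  stopifnot_scalar_number(pixel_size, "pixel_size", min = 1e-12)
  structure(
    list(membrane = membrane, nsc_labels = nsc_labels,
         pixel_size = pixel_size, chamber_assignment = chamber_assignment),
    class = "niche_volume"
  )
}

#' Place sampling cubes in a niche volume
#'
#' Samples `n` non-overlapping cubes of footprint `xy x xy` pixels,
#' extending in z from the first plane down to `z_limit` (the neuropile
#' boundary), at seeded random positions, optionally avoiding an
#' exclusion mask (e.g. trachea or nerve signal).
#'
#' @param volume A [niche_volume()].
#' @param n Number of cubes (default 6).
#' @param xy Cube footprint side in pixels (default 150).
#' @param z_limit Last z plane included (default: full depth).
#' @param seed Integer seed.
#' @param exclusion_mask Optional logical `Y x X` mask; cubes overlapping
#'   `TRUE` pixels are rejected.
#' @param max_tries Placement attempts before giving up.
#' @return Tibble with one row per cube: `cube`, `y0`, `x0`, `z0`, `z1`,
#'   `side`.
#' @export
sample_cubes <- function(volume, n = 6L, xy = 150L, z_limit = NULL,
                         seed = 1L, exclusion_mask = NULL,
                         max_tries = 10000L) {
  d <- dim(volume$membrane)
  z_limit <- z_limit %||% d[1]
  if (z_limit < 1 || z_limit > d[1]) abort("`z_limit` out of range.")
  if (xy > d[2] || xy > d[3]) {
    abort("Cube footprint exceeds the volume extent.")
  }
  max_r <- d[2] - xy + 1L
  max_c <- d[3] - xy + 1L
  sat_excl <- if (!is.null(exclusion_mask)) {
    summed_area_table(exclusion_mask * 1)
  }
  with_seed(seed, {
    placed <- matrix(integer(0), ncol = 2)
    tries <- 0L
    while (nrow(placed) < n) {
      tries <- tries + 1L
      if (tries > max_tries) {
        abort(sprintf("Could not place %d non-overlapping cubes.", n))
      }
      r <- sample.int(max_r, 1L)
      c <- sample.int(max_c, 1L)
      if (!is.null(sat_excl) &&
          square_means(sat_excl, r, c, xy) > 0) next
      overlap <- nrow(placed) > 0 &&
        any(abs(placed[, 1] - r) < xy & abs(placed[, 2] - c) < xy)
      if (!overlap) placed <- rbind(placed, c(r, c))
    }
    tibble(cube = seq_len(n), y0 = placed[, 1], x0 = placed[, 2],
           z0 = 1L, z1 = as.integer(z_limit), side = as.integer(xy))
  })
}

#' Segment membrane signal by 1-D k-means intensity clustering
#'
#' Clusters the intensity histogram of a block into `k` classes with a
#' deterministic, quantile-initialised weighted Lloyd iteration (the
#' k-means step used as an intensity threshold by the original
#' quantification); membrane pixels are those in the highest-mean
#' cluster(s). With `k = 2` the resulting split minimises the two-class
#' within-cluster variance of the histogram.
#'
#' @param block Numeric array of intensities (any shape).
#' @param k 2 or 4; keep `k` constant between control and samples of the
#'   same experiment.
#' @param top_clusters How many of the highest-mean clusters count as
#'   membrane (default 1).
#' @param n_bins Histogram resolution (default 256).
#' @return Logical array of the same shape (`TRUE` = membrane). A
#'   constant block yields an all-`FALSE` mask with a warning.
#' @export
segment_membrane <- function(block, k = 2L, top_clusters = 1L,
                             n_bins = 256L) {
  if (!k %in% c(2L, 4L)) abort("`k` must be 2 or 4.")
  dims <- dim(block)
  shape <- function(v) if (is.null(dims)) v else array(v, dim = dims)
  x <- as.vector(block)
  if (max(x) - min(x) < .Machine$double.eps * max(abs(x), 1)) {
    warn("Constant intensity block: returning an empty mask.")
    return(shape(rep(FALSE, length(x))))
  }
  # weighted histogram
  brk <- seq(min(x), max(x), length.out = n_bins + 1L)
  mid <- (brk[-1] + brk[-length(brk)]) / 2
  bin <- pmin(n_bins, pmax(1L, findInterval(x, brk, rightmost.closed = TRUE)))
  w <- tabulate(bin, n_bins)
  keep <- w > 0
  v <- mid[keep]; w <- w[keep]
  # quantile initialisation, then weighted Lloyd on bin centres
  centres <- unname(quantile(x, probs = (2 * seq_len(k) - 1) / (2 * k)))
  if (anyDuplicated(centres)) {
    centres <- centres + seq_len(k) * 1e-9 * diff(range(x))
  }
  assign_bins <- function(centres) {
    d <- abs(outer(v, centres, `-`))
    max.col(-d, ties.method = "first")
  }
  for (iter in seq_len(200L)) {
    cl <- assign_bins(centres)
    new_c <- vapply(seq_len(k), function(j) {
      if (any(cl == j)) sum(v[cl == j] * w[cl == j]) / sum(w[cl == j])
      else centres[j]
    }, numeric(1))
    if (max(abs(new_c - centres)) < 1e-12 * diff(range(x))) {
      centres <- new_c
      break
    }
    centres <- new_c
  }
  cl <- assign_bins(centres)
  ord <- order(centres, decreasing = TRUE)
  top <- ord[seq_len(top_clusters)]
  member_bins <- which(keep)[cl %in% top]
  shape(bin %in% member_bins)
}

#' Membrane signal per stem cell across sampling cubes
#'
#' For each cube, the segmented membrane pixel count divided by the
#' number of stem cells in the cube; the mean over cubes estimates the
#' membrane-per-stem-cell ratio of one brain.
#'
#' @param volume A [niche_volume()].
#' @param cubes Cube table from [sample_cubes()].
#' @param k Passed to [segment_membrane()].
#' @param drop_empty Drop cubes containing zero stem cells (default
#'   `FALSE`: such a cube raises an error so the caller must opt in).
#' @param ... Further arguments for [segment_membrane()].
#' @return A list with `cubes` (tibble cube, membrane_px, nsc, ratio) and
#'   `mean_ratio`.
#' @export
membrane_per_nsc <- function(volume, cubes, k = 2L, drop_empty = FALSE,
                             ...) {
  res <- purrr::pmap_dfr(cubes, function(cube, y0, x0, z0, z1, side) {
    ys <- y0:(y0 + side - 1L); xs <- x0:(x0 + side - 1L)
    block <- volume$membrane[z0:z1, ys, xs, drop = FALSE]
    labs <- volume$nsc_labels[z0:z1, ys, xs]
    mask <- segment_membrane(block, k = k, ...)
    nsc <- dplyr::n_distinct(labs[labs > 0])
    tibble(cube = cube, membrane_px = sum(mask), nsc = nsc)
  })
  if (any(res$nsc == 0)) {
    if (!drop_empty) {
      abort("Cube(s) with zero stem cells; set drop_empty = TRUE to skip.")
    }
    res <- res[res$nsc > 0, , drop = FALSE]
    if (!nrow(res)) abort("All cubes are empty of stem cells.")
  }
  res$ratio <- res$membrane_px / res$nsc
  list(cubes = res, mean_ratio = mean(res$ratio))
}

#' Percentage of individually ensheathed stem cells
#'
#' From the total stem-cell count and the per-chamber counts of chambers
#' housing more than one cell, the number of individually ensheathed
#' cells is `total - sum(multi)` and the ensheathing percentage is their
#' share of the population.
#'
#' @param total_nsc Total stem cells in the volume.
#' @param multi_chambers Integer vector of per-chamber counts, each >= 2;
#'   empty means every cell is housed singly.
#' @return One-row tibble with `total_nsc`, `individually_ensheathed`,
#'   `percentage`, and list-column `chamber_sizes`.
#' @examples
#' ensheathing_percentage(100, c(2, 2, 3))$percentage # 93
#' @export
ensheathing_percentage <- function(total_nsc, multi_chambers = integer()) {
  if (length(multi_chambers) && any(multi_chambers < 2)) {
    abort("`multi_chambers` entries must be >= 2.")
  }
  excess <- sum(multi_chambers)
  if (excess > total_nsc) {
    abort("Chamber counts exceed the total stem-cell population.")
  }
  individually <- total_nsc - excess
  tibble(total_nsc = total_nsc,
         individually_ensheathed = individually,
         percentage = 100 * individually / total_nsc,
         chamber_sizes = list(as.integer(multi_chambers)))
}

#' Build a synthetic niche volume with planted ground truth
#'
#' A small labelled volume for testing: stem cells as labelled squares
#' on a grid, membrane as a bright grid of lines between them over a dim
#' background, plus optional Gaussian noise. The planted membrane pixel
#' count and stem-cell count per region are recorded so ratio metrics
#' can be checked exactly.
#'
#' @param nz,ny,nx Volume dimensions.
#' @param n_cells_side Stem cells per side of the grid.
#' @param membrane_width Membrane line width in pixels.
#' @param noise_sd Gaussian noise sd added to the membrane channel.
#' @param seed Integer seed.
#' @return A [niche_volume()] with attribute `truth` (membrane mask and
#'   planted counts).
#' @export
make_niche_volume <- function(nz = 4L, ny = 160L, nx = 160L,
                              n_cells_side = 4L, membrane_width = 2L,
                              noise_sd = 0, seed = 1L) {
  cell <- floor(min(ny, nx) / n_cells_side)
  membrane_mask <- array(FALSE, c(nz, ny, nx))
  labels <- array(0L, c(nz, ny, nx))
  lab <- 0L
  for (i in seq_len(n_cells_side)) {
    for (j in seq_len(n_cells_side)) {
      lab <- lab + 1L
      y0 <- (i - 1L) * cell + membrane_width + 1L
      y1 <- i * cell - membrane_width
      x0 <- (j - 1L) * cell + membrane_width + 1L
      x1 <- j * cell - membrane_width
      # nucleus blob in the chamber centre
      cy <- (y0 + y1) %/% 2L; cx <- (x0 + x1) %/% 2L
      labels[, (cy - 3L):(cy + 3L), (cx - 3L):(cx + 3L)] <- lab
      # membrane lines around the chamber
      membrane_mask[, (y0 - membrane_width):(y0 - 1L), x0:x1] <- TRUE
      membrane_mask[, (y1 + 1L):(y1 + membrane_width), x0:x1] <- TRUE
      membrane_mask[, y0:y1, (x0 - membrane_width):(x0 - 1L)] <- TRUE
      membrane_mask[, y0:y1, (x1 + 1L):(x1 + membrane_width)] <- TRUE
    }
  }
  membrane <- array(10, c(nz, ny, nx))
  membrane[membrane_mask] <- 100
  if (noise_sd > 0) {
    membrane <- membrane +
      with_seed(seed, array(rnorm(length(membrane), 0, noise_sd),
                            dim = dim(membrane)))
  }
  vol <- niche_volume(membrane, labels, pixel_size = 0.3)
  attr(vol, "truth") <- list(membrane_mask = membrane_mask,
                             n_cells = lab,
                             membrane_px = sum(membrane_mask))
  vol
}
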