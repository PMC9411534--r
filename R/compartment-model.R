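#' Build a compartment graph
#'
#' A compartment graph is the ground-truth object behind every synthetic
#' movie: nodes are well-mixed fluorescent compartments (syncytial
#' territories or sub-compartments of the glial network), edges are
#' cytoplasmic exchange bridges with first-order exchange rates. Fast
#' intra-compartment diffusion is assumed, so each compartment carries a
#' single concentration per fluorescent species.
#'
#' @param nodes Data frame with columns `id` (unique character), `volume`
#'   (\eqn{\mu m^3}, > 0), `nuclei` (integer count, >= 0) and one numeric
#'   column per fluorescent species giving its initial concentration
#'   (arbitrary units, >= 0).
#' @param edges Data frame with columns `from`, `to` (node ids), `rate`
#'   (exchange rate \eqn{k} in s\eqn{^{-1}}, >= 0) and optionally `open`
#'   (logical, default `TRUE`). `NULL` means no bridges. Edges are
#'   undirected; `(a, b)` and `(b, a)` denote the same bridge.
#' @param species Character vector of species names. Defaults to every
#'   column of `nodes` other than `id`, `volume`, `nuclei`.
#' @return An object of class `compartment_graph`.
#' @examples
#' g <- compartment_graph(
#'   nodes = tibble::tibble(id = c("a", "b"), volume = 1000, nuclei = 1L,
#'                          green = 1),
#'   edges = tibble::tibble(from = "a", to = "b", rate = 0.05)
#' )
#' @export
compartment_graph <- function(nodes, edges = NULL, species = NULL) {
  nodes <- as_tibble(nodes)
  if (!all(c("id", "volume", "nuclei") %in% names(nodes))) {
    abort("`nodes` needs columns id, volume, nuclei plus one per species.")
  }
  nodes$id <- as.character(nodes$id)
  if (anyDuplicated(nodes$id)) abort("Node ids must be unique.")
  if (any(nodes$volume <= 0)) abort("Node volumes must be positive.")
  if (any(nodes$nuclei < 0)) abort("Nuclei counts must be non-negative.")
  species <- species %||% setdiff(names(nodes), c("id", "volume", "nuclei"))
  if (length(species) == 0L) abort("At least one species column is required.")
  missing_sp <- setdiff(species, names(nodes))
  if (length(missing_sp)) {
    abort(paste0("Species columns missing from `nodes`: ",
                 paste(missing_sp, collapse = ", ")))
  }
  init <- as.matrix(nodes[species])
  if (any(init < 0)) abort("Initial concentrations must be non-negative.")
  rownames(init) <- nodes$id
  if (is.null(edges)) {
    edges <- tibble(from = character(), to = character(),
                    rate = numeric(), open = logical())
  }
  edges <- as_tibble(edges)
  if (!"open" %in% names(edges)) edges$open <- TRUE
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  if (nrow(edges)) {
    bad <- setdiff(c(edges$from, edges$to), nodes$id)
    if (length(bad)) {
      abort(paste0("Edges reference unknown nodes: ",
                   paste(unique(bad), collapse = ", ")))
    }
    if (any(edges$rate < 0)) abort("Exchange rates must be non-negative.")
    if (any(edges$from == edges$to)) abort("Self-edges are not allowed.")
  }
  structure(
    list(nodes = nodes[c("id", "volume", "nuclei")], init = init,
         edges = edges, species = species),
    class = "compartment_graph"
  )
}

#' @export
print.compartment_graph <- function(x, ...) {
  cat("<compartment_graph> ", nrow(x$nodes), " nodes, ",
      nrow(x$edges), " bridges, species: ",
      paste(x$species, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Describe an acquisition and photomanipulation protocol
#'
#' Encodes a FLIP or photoconversion time-lapse: `pre_frames` baseline
#' acquisitions, `event_frames` acquisitions during which the laser acts on
#' `target_node` (continuous bleaching, or one conversion pulse per frame),
#' then `post_frames` follow-up acquisitions. Imaging-related photobleaching
#' is modelled as a per-acquisition multiplicative decay.
#'
#' @param pre_frames,event_frames,post_frames Non-negative frame counts.
#' @param frame_interval Seconds between acquisitions (> 0).
#' @param event_kind One of `"none"`, `"bleach"`, `"convert"`.
#' @param target_node Node id the laser acts on (required unless `"none"`).
#' @param event_rate Bleach rate \eqn{\beta} or conversion rate
#'   \eqn{\gamma}, s\eqn{^{-1}} >= 0, active during event frames.
#' @param event_species For `"bleach"`, the bleached species; for
#'   `"convert"`, length-2 vector `c(native, converted)`. Defaults:
#'   `"green"` and `c("kaede_native", "kaede_converted")`.
#' @param imaging_decay Fraction of signal lost per acquired frame per
#'   channel, in `[0, 1)`; scalar or named per-species vector.
#' @return An object of class `photo_protocol`.
#' @export
photo_protocol <- function(pre_frames, event_frames, post_frames,
                           frame_interval,
                           event_kind = c("none", "bleach", "convert"),
                           target_node = NULL, event_rate = 0,
                           event_species = NULL, imaging_decay = 0) {
  event_kind <- match.arg(event_kind)
  for (nm in c("pre_frames", "event_frames", "post_frames")) {
    stopifnot_scalar_number(get(nm), nm, min = 0)
  }
  stopifnot_scalar_number(frame_interval, "frame_interval", min = 1e-12)
  stopifnot_scalar_number(event_rate, "event_rate", min = 0)
  if (any(imaging_decay < 0) || any(imaging_decay >= 1)) {
    abort("`imaging_decay` must lie in [0, 1).")
  }
  if (event_kind != "none" && is.null(target_node)) {
    abort("`target_node` is required when event_kind is not \"none\".")
  }
  if (is.null(event_species)) {
    event_species <- switch(event_kind,
      none = character(),
      bleach = "green",
      convert = c("kaede_native", "kaede_converted")
    )
  }
  if (event_kind == "convert" && length(event_species) != 2L) {
    abort("`event_species` must be c(native, converted) for conversion.")
  }
  structure(
    list(pre_frames = as.integer(pre_frames),
         event_frames = as.integer(event_frames),
         post_frames = as.integer(post_frames),
         frame_interval = frame_interval, event_kind = event_kind,
         target_node = target_node, event_rate = event_rate,
         event_species = event_species, imaging_decay = imaging_decay),
    class = "photo_protocol"
  )
}

n_frames <- function(protocol) {
  protocol$pre_frames + protocol$event_frames + protocol$post_frames
}

#' Integrate fluorescence dynamics on a compartment graph
#'
#' Solves the linear exchange system with explicit fixed-step RK4. For each
#' open bridge `(a, b)` with rate `k`, species `s` obeys the symmetric flux
#' `dC_a/dt += k (C_b - C_a)` (equal-volume convention; volumes enter only
#' conservation accounting). During event frames, bleaching removes the
#' target species in the target node at rate \eqn{\beta}; conversion
#' transfers native to converted Kaede at rate \eqn{\gamma}. Imaging decay
#' multiplies every compartment by `1 - alpha` once per acquired frame
#' (frame 0 is the unattenuated initial state).
#'
#' @param graph A [compartment_graph()].
#' @param protocol A [photo_protocol()].
#' @param solver_dt RK4 step in seconds; must be at most
#'   `frame_interval / 10`. Default `frame_interval / 100`.
#' @return A `concentration_series`: times (s) and a
#'   node x species x frame array of concentrations. [tidy()] converts it
#'   to a long tibble.
#' @export
integrate_dynamics <- function(graph, protocol,
                               solver_dt = protocol$frame_interval / 100) {
  stopifnot(inherits(graph, "compartment_graph"),
            inherits(protocol, "photo_protocol"))
  if (solver_dt > protocol$frame_interval / 10 + 1e-12) {
    abort("`solver_dt` must be <= frame_interval / 10.")
  }
  sp <- graph$species
  if (protocol$event_kind != "none") {
    if (!all(protocol$event_species %in% sp)) {
      abort(paste0("Protocol species not in graph: ",
                   paste(setdiff(protocol$event_species, sp), collapse = ", ")))
    }
    if (!protocol$target_node %in% graph$nodes$id) {
      abort("`target_node` is not a node of the graph.")
    }
  }
  ids <- graph$nodes$id
  n <- length(ids)
  # exchange operator: dC = -L C, one shared Laplacian for all species
  L <- matrix(0, n, n, dimnames = list(ids, ids))
  ed <- graph$edges[graph$edges$open & graph$edges$rate > 0, , drop = FALSE]
  if (nrow(ed)) {
    for (i in seq_len(nrow(ed))) {
      a <- ed$from[i]; b <- ed$to[i]; k <- ed$rate[i]
      L[a, a] <- L[a, a] + k; L[b, b] <- L[b, b] + k
      L[a, b] <- L[a, b] - k; L[b, a] <- L[b, a] - k
    }
  }
  decay <- protocol$imaging_decay
  if (length(decay) == 1L && is.null(names(decay))) {
    decay <- setNames(rep(decay, length(sp)), sp)
  } else {
    decay <- setNames(ifelse(sp %in% names(decay), decay[sp], 0), sp)
  }
  tgt <- match(protocol$target_node %||% ids[1], ids)
  kind <- protocol$event_kind
  beta <- protocol$event_rate
  esp <- match(protocol$event_species, sp)

  deriv <- function(C, event_on) {
    d <- -L %*% C
    if (event_on && beta > 0) {
      if (kind == "bleach") {
        d[tgt, esp[1]] <- d[tgt, esp[1]] - beta * C[tgt, esp[1]]
      } else if (kind == "convert") {
        flux <- beta * C[tgt, esp[1]]
        d[tgt, esp[1]] <- d[tgt, esp[1]] - flux
        d[tgt, esp[2]] <- d[tgt, esp[2]] + flux
      }
    }
    d
  }

  nf <- n_frames(protocol)
  if (nf < 1L) abort("Protocol has no frames.")
  values <- array(0, dim = c(n, length(sp), nf),
                  dimnames = list(ids, sp, NULL))
  C <- graph$init[, sp, drop = FALSE]
  values[, , 1L] <- C
  dt_frame <- protocol$frame_interval
  nsteps <- max(1L, as.integer(ceiling(dt_frame / solver_dt - 1e-9)))
  h <- dt_frame / nsteps
  ev_lo <- protocol$pre_frames           # event active on [ev_lo, ev_hi)
  ev_hi <- protocol$pre_frames + protocol$event_frames
  for (f in seq_len(nf - 1L)) {
    event_on <- (f - 1L) >= ev_lo && (f - 1L) < ev_hi
    for (s in seq_len(nsteps)) {
      k1 <- deriv(C, event_on)
      k2 <- deriv(C + h / 2 * k1, event_on)
      k3 <- deriv(C + h / 2 * k2, event_on)
      k4 <- deriv(C + h * k3, event_on)
      C <- C + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    C <- sweep(C, 2L, 1 - decay, `*`)
    C[C < 0] <- 0
    values[, , f + 1L] <- C
  }
  structure(
    list(times = (seq_len(nf) - 1) * dt_frame, values = values,
         nodes = ids, species = sp,
         volumes = setNames(graph$nodes$volume, ids)),
    class = "concentration_series"
  )
}

#' @export
print.concentration_series <- function(x, ...) {
  cat("<concentration_series> ", length(x$nodes), " nodes x ",
      length(x$species), " species x ", length(x$times), " frames\n",
      sep = "")
  invisible(x)
}

#' @rdname integrate_dynamics
#' @param x A `concentration_series`.
#' @param ... Unused.
#' @export
tidy.concentration_series <- function(x, ...) {
  grid <- tidyr::expand_grid(
    frame = seq_along(x$times) - 1L,
    species = x$species,
    node = x$nodes
  )
  grid$time_s <- x$times[grid$frame + 1L]
  grid$concentration <- as.vector(x$values[
    cbind(match(grid$node, x$nodes), match(grid$species, x$species),
          grid$frame + 1L)])
  dplyr::arrange(grid[c("node", "species", "frame", "time_s",
                        "concentration")],
                 .data$node, .data$species, .data$frame)
}

#' Closed-form two-compartment FLIP solution
#'
#' Analytic solution (by eigen-decomposition) of the two-compartment
#' bleach system `dC1/dt = k (C2 - C1) - beta C1`,
#' `dC2/dt = k (C1 - C2)` with `C1(0) = C2(0) = 1`: compartment 1 is
#' bleached continuously at rate `beta` and exchanges with compartment 2
#' at rate `k`. Serves as the exact reference for the numerical
#' integrator.
#'
#' @param k Exchange rate, s\eqn{^{-1}} >= 0.
#' @param beta Bleach rate, s\eqn{^{-1}} >= 0.
#' @param t Vector of times in seconds.
#' @return Tibble with columns `time_s`, `c1`, `c2`.
#' @examples
#' closed_form_two_compartment(k = 0, beta = 0.1, t = 10)
#' @export
closed_form_two_compartment <- function(k, beta, t) {
  stopifnot_scalar_number(k, "k", min = 0)
  stopifnot_scalar_number(beta, "beta", min = 0)
  if (any(t < 0)) abort("`t` must be non-negative.")
  A <- matrix(c(-(k + beta), k, k, -k), 2, 2, byrow = TRUE)
  eg <- eigen(A)
  V <- eg$vectors
  coef <- solve(V, c(1, 1))
  out <- vapply(t, function(tt) {
    Re(V %*% (coef * exp(eg$values * tt)))
  }, numeric(2))
  tibble(time_s = t, c1 = out[1, ], c2 = out[2, ])
}

#' Geometry of the imaged field
#'
#' Maps pixels to compartments. `label_image` is a `Z x Y x X` (or `Y x X`
#' for a single plane) integer array; value `i > 0` means the pixel
#' belongs to `node_ids[i]`, 0 is background.
#'
#' @param label_image Integer array (`Y x X` matrix or `Z x Y x X` array).
#' @param pixel_size Pixel size in \eqn{\mu m} (> 0).
#' @param node_ids Character vector mapping label values to node ids.
#' @return An object of class `field_geometry`.
#' @export
field_geometry <- function(label_image, pixel_size, node_ids) {
  if (is.matrix(label_image)) {
    label_image <- array(label_image, dim = c(1L, dim(label_image)))
  }
  if (length(dim(label_image)) != 3L) {
    abort("`label_image` must be Y x X or Z x Y x X.")
  }
  stopifnot_scalar_number(pixel_size, "pixel_size", min = 1e-12)
  labs <- sort(unique(as.vector(label_image)))
  labs <- labs[labs > 0]
  if (length(labs) && max(labs) > length(node_ids)) {
    abort("`label_image` contains labels without a matching node id.")
  }
  structure(
    list(label_image = label_image, pixel_size = pixel_size,
         node_ids = as.character(node_ids)),
    class = "field_geometry"
  )
}

#' Render a noisy synthetic movie from a concentration series
#'
#' Converts ground-truth compartment concentrations into a
#' `T x Z x Y x X x C` intensity movie: pixel value =
#' `background + gain * C_node(t)` plus optional shot (Poisson) and
#' additive Gaussian noise; background pixels receive
#' `background + noise` only. Deterministic given `seed`.
#'
#' @param series A `concentration_series`.
#' @param geometry A [field_geometry()] whose labels map to series nodes.
#' @param gain Intensity per concentration unit.
#' @param background Constant offset added everywhere.
#' @param gaussian_sd Additive Gaussian noise standard deviation.
#' @param poisson If `TRUE`, pixel signal is drawn from a Poisson with the
#'   noiseless mean before Gaussian noise is added.
#' @param seed Integer seed controlling all rendering noise.
#' @return An object of class `synthetic_movie` with fields `data`,
#'   `channels`, `pixel_size` (\eqn{\mu m}), `frame_interval` (s),
#'   `geometry` and `truth` (graph/protocol/series when available).
#' @export
render_movie <- function(series, geometry, gain = 1, background = 0,
                         gaussian_sd = 0, poisson = FALSE, seed = 1L) {
  stopifnot(inherits(series, "concentration_series"),
            inherits(geometry, "field_geometry"))
  labs <- sort(unique(as.vector(geometry$label_image)))
  labs <- labs[labs > 0]
  ids <- geometry$node_ids[labs]
  if (!all(ids %in% series$nodes)) {
    abort(paste0("Geometry references nodes absent from the series: ",
                 paste(setdiff(ids, series$nodes), collapse = ", ")))
  }
  dims <- dim(geometry$label_image)
  nf <- length(series$times)
  nc <- length(series$species)
  lab_vec <- as.vector(geometry$label_image)
  node_of_lab <- match(geometry$node_ids, series$nodes)
  data <- array(0, dim = c(nf, dims, nc))
  npix <- prod(dims)
  with_seed(seed, {
    for (f in seq_len(nf)) {
      for (ch in seq_len(nc)) {
        conc <- c(0, series$values[node_of_lab, ch, f])[lab_vec + 1L]
        img <- gain * conc
        if (poisson) img <- rpois(npix, img)
        img <- img + background
        if (gaussian_sd > 0) img <- img + rnorm(npix, 0, gaussian_sd)
        data[f, , , , ch] <- array(img, dim = dims)
      }
    }
  })
  structure(
    list(data = data, channels = series$species,
         pixel_size = geometry$pixel_size,
         frame_interval = diff(series$times[1:2]),
         geometry = geometry,
         truth = list(series = series)),
    class = "synthetic_movie"
  )
}

#' @export
print.synthetic_movie <- function(x, ...) {
  d <- dim(x$data)
  cat("<synthetic_movie> ", d[1], " frames x ", d[2], "z x ", d[3], "y x ",
      d[4], "x x ", d[5], " channels (", paste(x$channels, collapse = ", "),
      "), pixel ", x$pixel_size, " um, interval ", x$frame_interval, " s\n",
      sep = "")
  invisible(x)
}
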