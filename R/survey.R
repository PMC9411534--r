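# Pairwise bleach surveys: simulate one FLIP experiment per compartment
# and turn the zone-wise significance calls into relation evidence.

#' Per-zone mean intensity traces from the label geometry
#'
#' Mean intensity over every labelled compartment of the movie's own
#' geometry, per frame, for one channel.
#'
#' @param movie A `synthetic_movie` carrying a `field_geometry`.
#' @param channel Channel name.
#' @param plane Z plane (default 1).
#' @return Tibble `zone`, `frame`, `time_s`, `i_mean`.
#' @export
zone_traces <- function(movie, channel, plane = 1L) {
  if (is.null(movie$geometry)) abort("Movie carries no label geometry.")
  ch <- match(channel, movie$channels)
  if (is.na(ch)) abort(sprintf("Unknown channel \"%s\".", channel))
  lab <- movie$geometry$label_image[plane, , ]
  ids <- movie$geometry$node_ids
  nf <- dim(movie$data)[1]
  idx <- lapply(seq_along(ids), function(i) which(lab == i))
  present <- which(lengths(idx) > 0)
  purrr::map_dfr(present, function(i) {
    v <- vapply(seq_len(nf), function(f) {
      mean(movie$data[f, plane, , , ch][idx[[i]]])
    }, numeric(1))
    tibble(zone = ids[i], frame = seq_len(nf) - 1L,
           time_s = (seq_len(nf) - 1L) * movie$frame_interval,
           i_mean = v)
  })
}

#' Random compartment-graph fixture with rendered geometry
#'
#' Draws a connectivity ground truth for recovery experiments: `n_nodes`
#' compartments laid out on a grid, each pair of grid neighbours carrying
#' a bridge that is open with probability `open_prob` (closed bridges are
#' full diffusion barriers). Two channels (`green` bleached, `red`
#' unbleached reference) with the fixture imaging-decay asymmetry.
#'
#' @param n_nodes 2-8 compartments.
#' @param open_prob Probability a neighbouring pair is openly connected.
#' @param seed Integer seed.
#' @param zone_px Zone side in pixels (default 30).
#' @param pixel_size Pixel size in um (default 0.2).
#' @return List with `graph`, `geometry` and the truth `components`
#'   (integer membership vector by node id).
#' @export
make_random_graph_fixture <- function(n_nodes, open_prob = 0.5, seed = 1L,
                                      zone_px = 30L, pixel_size = 0.2) {
  if (n_nodes < 2L || n_nodes > 8L) abort("`n_nodes` must be in 2..8.")
  with_seed(seed, {
    ids <- paste0("z", seq_len(n_nodes))
    ncol_grid <- ceiling(sqrt(n_nodes))
    row <- (seq_len(n_nodes) - 1L) %/% ncol_grid
    col <- (seq_len(n_nodes) - 1L) %% ncol_grid
    # grid-neighbour pairs
    pairs <- list()
    for (i in seq_len(n_nodes - 1L)) for (j in (i + 1L):n_nodes) {
      if (abs(row[i] - row[j]) + abs(col[i] - col[j]) == 1L) {
        pairs[[length(pairs) + 1L]] <- c(i, j)
      }
    }
    pairs <- do.call(rbind, pairs)
    open <- runif(nrow(pairs)) < open_prob
    graph <- compartment_graph(
      nodes = tibble(id = ids, volume = 1000,
                     nuclei = sample(1:5, n_nodes, replace = TRUE),
                     green = 1, red = 1),
      edges = tibble(from = ids[pairs[, 1]], to = ids[pairs[, 2]],
                     rate = 0.05, open = open)
    )
    margin <- 26L; gap <- 2L
    ny <- 2L * margin + ncol_grid * (zone_px + gap)
    nx <- ny
    zones <- lapply(seq_len(n_nodes), function(i) {
      y0 <- margin + row[i] * (zone_px + gap) + 1L
      x0 <- margin + col[i] * (zone_px + gap) + 1L
      list(id = ids[i], y0 = y0, y1 = y0 + zone_px - 1L,
           x0 = x0, x1 = x0 + zone_px - 1L)
    })
    geometry <- rect_geometry(ny, nx, zones, pixel_size, ids)
    g_open <- igraph::graph_from_data_frame(
      graph$edges[graph$edges$open, c("from", "to")], directed = FALSE,
      vertices = data.frame(name = ids))
    comp <- igraph::components(g_open)$membership
    list(graph = graph, geometry = geometry, components = comp)
  })
}

#' Run a full pairwise bleach survey over a compartment graph
#'
#' Simulates one FLIP experiment per compartment (continuous bleaching of
#' the bleach channel in that compartment), renders each movie with the
#' requested noise, derives the per-movie Monte-Carlo threshold from the
#' unbleached reference channel, and emits one evidence record per
#' (experiment, observed zone). All zones are treated as mutually
#' adjacent for barrier evidence (the rendered zones share borders).
#'
#' @param graph,geometry Ground truth, e.g. from
#'   [make_random_graph_fixture()].
#' @param noise_sd Gaussian noise sd in intensity units (gain is 100).
#' @param seed Integer seed (per-experiment seeds are derived from it).
#' @param bleach_channel,null_channel Channel names.
#' @param bleach_rate Bleach rate s\eqn{^{-1}}.
#' @param pre,event,post Frame counts; `frame_interval` seconds apart.
#' @param frame_interval Seconds between frames.
#' @param n_null Null squares per movie (>= 1000).
#' @param confidence Threshold confidence level.
#' @param imaging_decay Named per-channel per-frame decay.
#' @return Evidence tibble ready for [accumulate_evidence()].
#' @export
run_bleach_survey <- function(graph, geometry, noise_sd = 0, seed = 1L,
                              bleach_channel = "green",
                              null_channel = "red",
                              bleach_rate = 0.4, pre = 3L, event = 40L,
                              post = 10L, frame_interval = 2,
                              n_null = 1000L, confidence = 0.95,
                              imaging_decay = c(green = 0.001,
                                                red = 0.002)) {
  ids <- graph$nodes$id
  purrr::map_dfr(seq_along(ids), function(i) {
    target <- ids[i]
    protocol <- photo_protocol(pre, event, post, frame_interval,
                               event_kind = "bleach",
                               target_node = target,
                               event_rate = bleach_rate,
                               event_species = bleach_channel,
                               imaging_decay = imaging_decay)
    series <- integrate_dynamics(graph, protocol,
                                 solver_dt = frame_interval / 10)
    movie <- render_movie(series, geometry, gain = 100, background = 10,
                          gaussian_sd = noise_sd,
                          seed = derive_seed(seed, i))
    null <- monte_carlo_null(movie, null_channel, n_squares = n_null,
                             confidence = confidence,
                             seed = derive_seed(seed, 1000L + i),
                             t_start = seq_len(pre) - 1L)
    traces <- zone_traces(movie, bleach_channel)
    purrr::map_dfr(setdiff(unique(traces$zone), target), function(z) {
      tr <- traces[traces$zone == z, , drop = FALSE]
      pfl <- percent_fluorescence_loss(tr, t_start = seq_len(pre) - 1L)
      evidence_record(
        experiment = paste0("bleach_", target),
        bleached_zone = target, observed_zone = z,
        channel = bleach_channel,
        percent_loss = pfl$percent_loss, threshold = null$threshold,
        adjacent = TRUE)
    })
  })
}
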