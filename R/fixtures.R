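# Seeded, documented synthetic fixtures with embedded ground truth.

# Rectangular label geometry helper: zones is a list of
# list(id, y0, y1, x0, x1) in 1-based inclusive pixel coordinates.
rect_geometry <- function(ny, nx, zones, pixel_size, node_ids) {
  lab <- matrix(0L, ny, nx)
  for (i in seq_along(zones)) {
    z <- zones[[i]]
    lab[z$y0:z$y1, z$x0:z$x1] <- match(z$id, node_ids)
  }
  field_geometry(lab, pixel_size, node_ids)
}

#' Build a named synthetic FLIP fixture movie
#'
#' Returns a seeded movie with embedded ground truth, used throughout the
#' tests and examples:
#' \describe{
#'   \item{`two_open`}{Two compartments joined by an open bridge
#'     (k = 0.05 s\eqn{^{-1}}); green continuously bleached in `n1`. The
#'     unbleached compartment shows a significant fluorescence loss.}
#'   \item{`two_closed`}{Same layout with the bridge closed (k = 0); the
#'     neighbour trace stays flat up to imaging decay and noise.}
#'   \item{`chain3`}{Three compartments in a row, both bridges open;
#'     bleaching one end drains the whole chain. Nuclei counts 2/3/4.}
#'   \item{`fig6_like`}{Five zones reproducing the connectivity pattern of
#'     a partially fused pair of units: a green-only zone continuous with
#'     a high-green and (separately) a low-green overlap zone, a barrier
#'     between the two overlap sub-zones, one red zone isolated and one
#'     red zone continuous with the low-green sub-zone.}
#' }
#'
#' All fixtures are rendered at pixel size 0.2 um, frame interval 2 s,
#' 100 frames (5 pre-bleach), gain 100, background 10 and Gaussian noise
#' sd 2 (2\% of signal). Imaging decay is per channel: 0.1\% per frame
#' for green, 0.2\% for red — the unbleached fluorophore is the less
#' photostable one, which is exactly why per-fluorophore thresholds are
#' derived from the unbleached channel.
#'
#' @param name One of `"two_open"`, `"two_closed"`, `"chain3"`,
#'   `"fig6_like"`.
#' @param seed Integer seed; identical name + seed gives identical arrays.
#' @return A `synthetic_movie` whose `truth` field also carries the graph
#'   and protocol.
#' @export
make_fixture <- function(name = c("two_open", "two_closed", "chain3",
                                  "fig6_like"),
                         seed = 1L) {
  name <- match.arg(name)
  pixel_size <- 0.2
  pre <- 5L; event <- 60L; post <- 35L
  gain <- 100; background <- 10; noise_sd <- 2
  decay <- c(green = 0.001, red = 0.002)
  if (name %in% c("two_open", "two_closed")) {
    k <- if (name == "two_open") 0.05 else 0
    graph <- compartment_graph(
      nodes = tibble(id = c("n1", "n2"), volume = 1000, nuclei = c(3L, 4L),
                     green = 1, red = 1),
      edges = tibble(from = "n1", to = "n2", rate = k, open = k > 0)
    )
    geometry <- rect_geometry(
      ny = 80L, nx = 144L,
      zones = list(list(id = "n1", y0 = 11, y1 = 70, x0 = 11, x1 = 70),
                   list(id = "n2", y0 = 11, y1 = 70, x0 = 75, x1 = 134)),
      pixel_size = pixel_size, node_ids = c("n1", "n2")
    )
    protocol <- photo_protocol(pre, event, post, frame_interval = 2,
                               event_kind = "bleach", target_node = "n1",
                               event_rate = 0.4, event_species = "green",
                               imaging_decay = decay)
  } else if (name == "chain3") {
    graph <- compartment_graph(
      nodes = tibble(id = c("n1", "n2", "n3"), volume = 1000,
                     nuclei = c(2L, 3L, 4L), green = 1, red = 1),
      edges = tibble(from = c("n1", "n2"), to = c("n2", "n3"), rate = 0.05)
    )
    geometry <- rect_geometry(
      ny = 80L, nx = 200L,
      zones = list(list(id = "n1", y0 = 11, y1 = 70, x0 = 11, x1 = 70),
                   list(id = "n2", y0 = 11, y1 = 70, x0 = 73, x1 = 132),
                   list(id = "n3", y0 = 11, y1 = 70, x0 = 135, x1 = 194)),
      pixel_size = pixel_size, node_ids = c("n1", "n2", "n3")
    )
    protocol <- photo_protocol(pre, event, post, frame_interval = 2,
                               event_kind = "bleach", target_node = "n1",
                               event_rate = 0.4, event_species = "green",
                               imaging_decay = decay)
  } else { # fig6_like
    ids <- c("GFP", "H_GFP", "L_GFP", "mCherry1", "mCherry2")
    graph <- compartment_graph(
      nodes = tibble(id = ids, volume = 1000,
                     nuclei = c(3L, 2L, 2L, 3L, 3L),
                     green = c(1, 1, 0.4, 0, 0),
                     red = c(0, 1, 1, 1, 1)),
      edges = tibble(
        from = c("GFP", "GFP", "L_GFP", "H_GFP", "H_GFP"),
        to = c("H_GFP", "L_GFP", "mCherry2", "L_GFP", "mCherry1"),
        rate = c(0.05, 0.02, 0.03, 0, 0),
        open = c(TRUE, TRUE, TRUE, FALSE, FALSE)
      )
    )
    geometry <- rect_geometry(
      ny = 130L, nx = 130L,
      zones = list(
        list(id = "GFP", y0 = 8, y1 = 62, x0 = 8, x1 = 62),
        list(id = "H_GFP", y0 = 8, y1 = 62, x0 = 66, x1 = 122),
        list(id = "L_GFP", y0 = 68, y1 = 122, x0 = 8, x1 = 62),
        list(id = "mCherry1", y0 = 8, y1 = 35, x0 = 124, x1 = 129),
        list(id = "mCherry2", y0 = 68, y1 = 122, x0 = 66, x1 = 122)
      ),
      pixel_size = pixel_size, node_ids = ids
    )
    protocol <- photo_protocol(pre, event, post, frame_interval = 2,
                               event_kind = "bleach", target_node = "GFP",
                               event_rate = 0.4, event_species = "green",
                               imaging_decay = decay)
  }
  series <- integrate_dynamics(graph, protocol)
  movie <- render_movie(series, geometry, gain = gain,
                        background = background, gaussian_sd = noise_sd,
                        seed = seed)
  movie$truth$graph <- graph
  movie$truth$protocol <- protocol
  movie$name <- name
  movie
}

#' Simulate a uniform null movie with no FLIP event
#'
#' A single-compartment movie covering the whole field: uniform signal,
#' per-frame imaging decay and additive Gaussian noise but no
#' photomanipulation. This is the reference input for calibrating and
#' checking the Monte-Carlo %FL threshold.
#'
#' @param ny,nx Field size in pixels.
#' @param frames Number of acquisitions.
#' @param decay Imaging decay fraction per frame.
#' @param noise_sd Gaussian noise sd, in intensity units (the uniform
#'   signal is `gain`).
#' @param gain Intensity of the uniform field at frame 0.
#' @param pixel_size Pixel size in \eqn{\mu m}.
#' @param frame_interval Frame interval in seconds.
#' @param seed Integer seed.
#' @return A `synthetic_movie` with one channel `"green"`.
#' @export
make_null_movie <- function(ny = 512L, nx = 512L, frames = 100L,
                            decay = 0.002, noise_sd = 3, gain = 100,
                            pixel_size = 0.2, frame_interval = 2,
                            seed = 1L) {
  graph <- compartment_graph(
    nodes = tibble(id = "field", volume = 1000, nuclei = 0L, green = 1)
  )
  protocol <- photo_protocol(frames, 0L, 0L, frame_interval,
                             event_kind = "none", imaging_decay = decay)
  series <- integrate_dynamics(graph, protocol)
  geometry <- field_geometry(matrix(1L, ny, nx), pixel_size, "field")
  movie <- render_movie(series, geometry, gain = gain, background = 0,
                        gaussian_sd = noise_sd, seed = seed)
  movie$truth$graph <- graph
  movie$truth$protocol <- protocol
  movie
}

#' Simulate one photoconversion trial across a bridge
#'
#' Two compartments expressing native Kaede, joined by one bridge; pulsed
#' UV conversion in the proximal compartment, then follow-up frames during
#' which converted Kaede may (bridge open) or may not (closed) reach the
#' distal compartment. The rendered movie carries native and converted
#' channels plus background for detection statistics.
#'
#' @param k Bridge exchange rate, s\eqn{^{-1}}.
#' @param open Whether the bridge is open.
#' @param pulses Number of conversion pulses (one per event frame).
#' @param frame_interval Seconds per frame.
#' @param post_frames Follow-up frames after the pulse train.
#' @param noise_sd Gaussian noise sd as a fraction of the rendered signal
#'   gain (default 0.02, i.e. 2\% of signal).
#' @param seed Integer seed.
#' @return A `synthetic_movie` with channels `kaede_native`,
#'   `kaede_converted`.
#' @export
make_conversion_trial <- function(k = 0.05, open = TRUE, pulses = 20L,
                                  frame_interval = 2, post_frames = 30L,
                                  noise_sd = 0.02, seed = 1L) {
  gain <- 100
  graph <- compartment_graph(
    nodes = tibble(id = c("proximal", "distal"), volume = 1000,
                   nuclei = c(2L, 2L),
                   kaede_native = 1, kaede_converted = 0),
    edges = tibble(from = "proximal", to = "distal", rate = k, open = open)
  )
  protocol <- photo_protocol(2L, pulses, post_frames, frame_interval,
                             event_kind = "convert",
                             target_node = "proximal", event_rate = 0.5,
                             imaging_decay = 0.002)
  geometry <- rect_geometry(
    ny = 80L, nx = 144L,
    zones = list(list(id = "proximal", y0 = 11, y1 = 70, x0 = 11, x1 = 70),
                 list(id = "distal", y0 = 11, y1 = 70, x0 = 75, x1 = 134)),
    pixel_size = 0.2, node_ids = c("proximal", "distal")
  )
  series <- integrate_dynamics(graph, protocol)
  movie <- render_movie(series, geometry, gain = gain, background = 10,
                        gaussian_sd = noise_sd * gain, seed = seed)
  movie$truth$graph <- graph
  movie$truth$protocol <- protocol
  movie
}
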