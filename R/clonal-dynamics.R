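#' Event schedule for the glial clonal simulator
#'
#' Defines the developmental time axis (hours after larval hatching, h
#' ALH) and the stochastic events acting on founder glial cells:
#' endoreplication (genome replication without nuclear division, doubling
#' the number of label-construct copies per nucleus), acytokinetic
#' mitosis (nuclear division without abscission, duplicating a nucleus
#' within its syncytial unit) and homotypic fusion between adjacent
#' units. Events run in hourly steps inside their windows; per-step event
#' probabilities are `expm1(rate)` so that the expected per-step growth
#' matches the continuous rate (mean nuclei per unit after a
#' mitosis-only window of length `w` is `exp(rate * w)`).
#'
#' @param horizon Simulation end, h ALH.
#' @param n_founders Number of founder units at time 0.
#' @param endo_window,mitosis_window Length-2 `[start, end)` windows in h
#'   ALH within `[0, horizon]`.
#' @param endo_rate,mitosis_rate Per-nucleus event rates, h\eqn{^{-1}}.
#' @param fusion_rate Per adjacent unit pair fusion rate, h\eqn{^{-1}},
#'   active over the whole horizon.
#' @param neighbour_radius Radius of the random geometric adjacency graph
#'   over founder positions in the unit square.
#' @return An object of class `event_schedule`.
#' @export
event_schedule <- function(horizon = 96, n_founders = 10L,
                           endo_window = c(8, 48), endo_rate = 0.04,
                           mitosis_window = c(48, 90),
                           mitosis_rate = 0.045,
                           fusion_rate = 0.002,
                           neighbour_radius = 0.4) {
  check_window <- function(w, nm) {
    if (length(w) != 2L || w[1] > w[2] || w[1] < 0 || w[2] > horizon) {
      abort(sprintf("`%s` must be [start, end] within [0, horizon].", nm))
    }
  }
  check_window(endo_window, "endo_window")
  check_window(mitosis_window, "mitosis_window")
  for (nm in c("endo_rate", "mitosis_rate", "fusion_rate")) {
    stopifnot_scalar_number(get(nm), nm, min = 0)
  }
  if (n_founders < 1L) abort("Need at least one founder.")
  structure(
    list(horizon = horizon, n_founders = as.integer(n_founders),
         endo_window = endo_window, endo_rate = endo_rate,
         mitosis_window = mitosis_window, mitosis_rate = mitosis_rate,
         fusion_rate = fusion_rate, neighbour_radius = neighbour_radius),
    class = "event_schedule"
  )
}

#' The canonical endoreplication-then-mitosis schedule
#'
#' Default study conditions for the case classifier: endoreplication
#' window preceding the mitosis window on a 96 h horizon, mirroring the
#' observed ordering of proliferative strategies in the developing
#' niche.
#'
#' @param ... Overrides passed to [event_schedule()].
#' @export
canonical_schedule <- function(...) event_schedule(...)

step_prob <- function(rate) min(1, expm1(rate))

#' Simulate a clonal glial population
#'
#' Discrete-time (1 h steps) stochastic simulation of `n_founders`
#' syncytial units from 0 to `horizon` h ALH. Within each step events are
#' applied in the order endoreplication, mitosis, fusion. Endoreplication
#' doubles a nucleus's construct copies (genome replication without
#' nuclear division); mitosis duplicates a nucleus within its unit — S
#' phase replicates every construct copy before division, so each
#' daughter carries one replica of each parental copy and the per-nucleus
#' copy number and colour combination are conserved; fusion merges two
#' adjacent units into one, pooling their nuclei. Everything is logged,
#' so label induction can be replayed at any time point and all
#' statistics can be recounted from the log.
#'
#' @param schedule An [event_schedule()].
#' @param seed Integer seed; identical seeds give identical histories.
#' @return An object of class `cg_population`: tibbles `units`
#'   (unit, founder, final unit after fusion), `nuclei` (nucleus, unit,
#'   copies, list-column `colours`), `adjacency` (unit pairs), `events`
#'   (time, type, ids), plus the schedule and seed. Colours are all
#'   `"uncoloured"` until [induce_labels()] is applied.
#' @export
simulate_population <- function(schedule, seed = 1L) {
  stopifnot(inherits(schedule, "event_schedule"))
  events <- with_seed(seed, sim_event_log(schedule))
  pop <- replay_population(schedule, events, induction = NULL)
  pop$seed <- as.integer(seed)
  pop
}

# Draw the full event history (no colours involved).
sim_event_log <- function(schedule) {
  n0 <- schedule$n_founders
  pos <- cbind(runif(n0), runif(n0))
  adj <- which(
    as.matrix(stats::dist(pos)) < schedule$neighbour_radius &
      upper.tri(matrix(0, n0, n0)),
    arr.ind = TRUE
  )
  p_endo <- step_prob(schedule$endo_rate)
  p_mit <- step_prob(schedule$mitosis_rate)
  p_fus <- step_prob(schedule$fusion_rate)
  nuclei_unit <- seq_len(n0)        # unit of each nucleus
  unit_alive <- rep(TRUE, n0)
  unit_map <- seq_len(n0)           # unit -> merged-into unit
  next_nuc <- n0 + 1L
  ev <- list()
  push <- function(time, type, nucleus = NA_integer_,
                   daughter = NA_integer_, unit_keep = NA_integer_,
                   unit_gone = NA_integer_) {
    ev[[length(ev) + 1L]] <<- tibble(
      time = time, type = type, nucleus = nucleus, daughter = daughter,
      unit_keep = unit_keep, unit_gone = unit_gone)
  }
  in_window <- function(t, w) t >= w[1] && t < w[2]
  for (t in seq_len(schedule$horizon) - 1L) {
    if (in_window(t, schedule$endo_window) && p_endo > 0) {
      hit <- which(runif(length(nuclei_unit)) < p_endo)
      if (length(hit)) {
        ev[[length(ev) + 1L]] <- tibble(
          time = t, type = "endoreplication", nucleus = hit,
          daughter = NA_integer_, unit_keep = NA_integer_,
          unit_gone = NA_integer_)
      }
    }
    if (in_window(t, schedule$mitosis_window) && p_mit > 0) {
      hit <- which(runif(length(nuclei_unit)) < p_mit)
      if (length(hit)) {
        daughters <- next_nuc + seq_along(hit) - 1L
        nuclei_unit[daughters] <- nuclei_unit[hit]
        next_nuc <- next_nuc + length(hit)
        ev[[length(ev) + 1L]] <- tibble(
          time = t, type = "mitosis", nucleus = hit, daughter = daughters,
          unit_keep = NA_integer_, unit_gone = NA_integer_)
      }
    }
    if (p_fus > 0 && nrow(adj)) {
      hit <- which(runif(nrow(adj)) < p_fus)
      for (e in hit) {
        a <- unit_map[adj[e, 1]]; b <- unit_map[adj[e, 2]]
        if (a == b) next
        keep <- min(a, b); gone <- max(a, b)
        unit_map[unit_map == gone] <- keep
        unit_alive[gone] <- FALSE
        nuclei_unit[nuclei_unit == gone] <- keep
        push(t, "fusion", unit_keep = keep, unit_gone = gone)
      }
    }
  }
  list(log = if (length(ev)) dplyr::bind_rows(ev) else
         tibble(time = numeric(), type = character(),
                nucleus = integer(), daughter = integer(),
                unit_keep = integer(), unit_gone = integer()),
       adjacency = tibble(unit_a = as.integer(adj[, 1]),
                          unit_b = as.integer(adj[, 2])),
       positions = pos)
}

# Replay the event log, optionally colouring construct copies at an
# induction time. Returns the population at the horizon.
replay_population <- function(schedule, events, induction) {
  n0 <- schedule$n_founders
  unit_of <- seq_len(n0)
  unit_map <- seq_len(n0)
  founder_of <- seq_len(n0)                # founder lineage of each nucleus
  colours <- rep(list("uncoloured"), n0)   # per nucleus: one colour per copy
  log <- events$log
  fusion_detect <- list()
  apply_induction <- function(colours, eff, ind_seed) {
    with_seed(ind_seed, {
      lapply(colours, function(cc) {
        hit <- cc == "uncoloured" & runif(length(cc)) < eff
        cc[hit] <- sample(paste0("c", 1:4), sum(hit), replace = TRUE)
        cc
      })
    })
  }
  induced <- FALSE
  ind_time <- if (!is.null(induction)) induction$time else Inf
  times <- c(log$time, Inf)
  rows <- seq_len(nrow(log))
  combo_of_unit <- function(u) {
    cc <- unlist(colours[unit_of == u])
    sort(unique(cc[cc != "uncoloured"]))
  }
  maybe_induce <- function(t_next) {
    if (!induced && !is.null(induction) && ind_time <= t_next) {
      colours <<- apply_induction(colours, induction$efficiency,
                                  induction$seed)
      induced <<- TRUE
    }
  }
  for (r in rows) {
    maybe_induce(log$time[r])
    switch(log$type[r],
      endoreplication = {
        # copies double; each new copy inherits its template's colour
        i <- log$nucleus[r]
        colours[[i]] <- c(colours[[i]], colours[[i]])
      },
      mitosis = {
        # S phase replicates every copy before division, so each daughter
        # receives one replica of each parental copy: copy number and
        # colour combination are conserved through mitosis
        i <- log$nucleus[r]; d <- log$daughter[r]
        colours[[d]] <- colours[[i]]
        unit_of[d] <- unit_of[i]
        founder_of[d] <- founder_of[i]
      },
      fusion = {
        keep <- log$unit_keep[r]; gone <- log$unit_gone[r]
        fusion_detect[[length(fusion_detect) + 1L]] <- tibble(
          time = log$time[r], unit_keep = keep, unit_gone = gone,
          induced = induced,
          combo_keep = list(combo_of_unit(keep)),
          combo_gone = list(combo_of_unit(gone))
        )
        unit_of[unit_of == gone] <- keep
        unit_map[unit_map == gone] <- keep
      }
    )
  }
  maybe_induce(Inf)
  nuclei <- tibble(
    nucleus = seq_along(colours),
    unit = unit_of,
    founder = founder_of,
    copies = lengths(colours),
    colours = colours
  )
  units <- tibble(unit = seq_len(n0), founder = seq_len(n0),
                  merged_into = unit_map)
  fus <- if (length(fusion_detect)) dplyr::bind_rows(fusion_detect) else
    tibble(time = numeric(), unit_keep = integer(), unit_gone = integer(),
           induced = logical(), combo_keep = list(), combo_gone = list())
  structure(
    list(units = units, nuclei = nuclei, adjacency = events$adjacency,
         positions = events$positions, events = log, fusions = fus,
         schedule = schedule,
         induction = induction),
    class = "cg_population"
  )
}

#' @export
print.cg_population <- function(x, ...) {
  cat("<cg_population> ", dplyr::n_distinct(x$nuclei$unit), " units, ",
      nrow(x$nuclei), " nuclei, ",
      sum(x$events$type == "fusion"), " fusion event(s)",
      if (!is.null(x$induction))
        sprintf("; labels induced at %g h ALH", x$induction$time) else
        "; unlabelled",
      "\n", sep = "")
  invisible(x)
}

#' Induce multicolour labels at a developmental time
#'
#' Replays the population's event history and, at `time` h ALH, lets each
#' uncoloured construct copy recombine independently with probability
#' `efficiency`; a recombined copy commits to one of four colours chosen
#' uniformly. Copies created by later endoreplication inherit the
#' parental copy's colour; mitotic daughters inherit the copies (and
#' colours) they are dealt. The event history itself is unchanged —
#' induction is an observation overlay, exactly as the genetic label is.
#'
#' @param population A `cg_population` from [simulate_population()].
#' @param time Induction time in h ALH, within `[0, horizon]`.
#' @param mode `"NLS"` (nuclear label) or `"CAAX"` (membrane label); kept
#'   as metadata for downstream counting rules.
#' @param efficiency Per-copy recombination probability in `[0, 1]`.
#' @param seed Integer seed for the colour draws.
#' @return The population with colours set and induction metadata.
#' @export
induce_labels <- function(population, time, mode = c("NLS", "CAAX"),
                          efficiency = 1, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(population, "cg_population"))
  if (time > population$schedule$horizon || time < 0) {
    abort("Induction time must lie within [0, horizon].")
  }
  if (efficiency < 0 || efficiency > 1) {
    abort("`efficiency` must lie in [0, 1].")
  }
  induction <- list(time = time, mode = mode, efficiency = efficiency,
                    seed = as.integer(seed))
  events <- list(log = population$events, adjacency = population$adjacency,
                 positions = population$positions)
  pop <- replay_population(population$schedule, events, induction)
  pop$seed <- population$seed
  pop
}

# Colour combination (sorted, uncoloured dropped) of a colour vector.
combo_key <- function(cc) {
  cc <- sort(unique(cc[cc != "uncoloured"]))
  if (!length(cc)) NA_character_ else paste(cc, collapse = "+")
}

#' Clone statistics of a labelled population
#'
#' Clones are maximal groups of contiguous labelled nuclei sharing an
#' identical colour combination. With `identity = "lineage"` (default)
#' the simulator's ground-truth founder lineage resolves contiguity:
#' nuclei from different founders never merge even when fusion has mixed
#' them into one unit — the observable proxy cannot tell such same-combo
#' groups apart, ground truth can. With `identity = "colour"` grouping
#' uses the observable proxy (current unit + combination), optionally
#' merging identical combinations across adjacent units via
#' `merge_adjacent`. Nuclei whose copies are all unlabelled are
#' invisible and excluded.
#'
#' @param population An induced `cg_population`.
#' @param identity `"lineage"` (ground truth, default) or `"colour"`
#'   (observable proxy).
#' @param merge_adjacent For `identity = "colour"`: merge identical
#'   combinations across adjacent units (default `FALSE`).
#' @return An object of class `cg_stats`: tibble `clones` (clone,
#'   n_nuclei, n_colours, combo, units) plus scalar summaries
#'   `n_clones`, `mean_size`, `multicoloured_fraction`, `fusion_events`
#'   (logged fusions at or after induction), `events_per_clone`.
#' @export
compute_clone_stats <- function(population,
                                identity = c("lineage", "colour"),
                                merge_adjacent = FALSE) {
  identity <- match.arg(identity)
  stopifnot(inherits(population, "cg_population"))
  if (is.null(population$induction)) {
    abort("Labels have not been induced; call induce_labels() first.")
  }
  nuc <- population$nuclei
  nuc$combo <- vapply(nuc$colours, combo_key, character(1))
  nuc <- nuc[!is.na(nuc$combo), , drop = FALSE]
  if (!nrow(nuc)) abort("No labelled nuclei in the population.")
  grp <- if (identity == "lineage") {
    paste(nuc$founder, nuc$combo)
  } else {
    paste(nuc$unit, nuc$combo)
  }
  if (identity == "colour" && merge_adjacent) {
    # union same-combo groups across adjacent (merged) units
    umap <- population$units$merged_into
    adj <- population$adjacency
    adj$ua <- umap[adj$unit_a]; adj$ub <- umap[adj$unit_b]
    key <- unique(grp)
    parent <- seq_along(key)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (r in seq_len(nrow(adj))) {
      combos <- unique(nuc$combo[nuc$unit %in% c(adj$ua[r], adj$ub[r])])
      for (cb in combos) {
        ka <- match(paste(adj$ua[r], cb), key)
        kb <- match(paste(adj$ub[r], cb), key)
        if (!is.na(ka) && !is.na(kb)) {
          ra <- find(ka); rb <- find(kb)
          if (ra != rb) parent[rb] <- ra
        }
      }
    }
    roots <- vapply(seq_along(key), find, integer(1))
    grp <- key[roots][match(grp, key)]
  }
  clones <- nuc |>
    dplyr::mutate(clone_key = grp) |>
    dplyr::group_by(.data$clone_key) |>
    dplyr::summarise(
      n_nuclei = dplyr::n(),
      combo = dplyr::first(.data$combo),
      n_colours = length(strsplit(dplyr::first(.data$combo), "+",
                                  fixed = TRUE)[[1]]),
      units = list(sort(unique(.data$unit))),
      .groups = "drop"
    ) |>
    dplyr::mutate(clone = dplyr::row_number(), .before = 1) |>
    dplyr::select(-"clone_key")
  fusion_events <- sum(population$fusions$induced)
  n_clones <- nrow(clones)
  structure(
    list(clones = clones, n_clones = n_clones,
         mean_size = mean(clones$n_nuclei),
         multicoloured_fraction = mean(clones$n_colours > 1),
         colour_distribution = table(factor(clones$n_colours,
                                            levels = 1:4)),
         fusion_events = fusion_events,
         events_per_clone = fusion_events / n_clones,
         induction = population$induction),
    class = "cg_stats"
  )
}

#' @export
print.cg_stats <- function(x, ...) {
  cat(sprintf(
    "<cg_stats> %d clones, mean size %.2f nuclei, %.0f%% multicoloured, %d fusion event(s) (%.3f per clone)\n",
    x$n_clones, x$mean_size, 100 * x$multicoloured_fraction,
    x$fusion_events, x$events_per_clone))
  invisible(x)
}

#' @rdname compute_clone_stats
#' @param x A `cg_stats`.
#' @param ... Unused.
#' @export
tidy.cg_stats <- function(x, ...) x$clones

#' @rdname compute_clone_stats
#' @export
glance.cg_stats <- function(x, ...) {
  tibble(n_clones = x$n_clones, mean_size = x$mean_size,
         multicoloured_fraction = x$multicoloured_fraction,
         fusion_events = x$fusion_events,
         events_per_clone = x$events_per_clone,
         induction_time = x$induction$time)
}

#' Classify an induction outcome into cases 1-4
#'
#' Compares clone statistics at some induction time against the baseline
#' (induction at t = 0 on the same history). The two decision axes are
#' the multicoloured clone fraction (endoreplication signature: several
#' construct copies per nucleus at induction commit to independent
#' colours) and the clone number relative to baseline (mitosis
#' signature: nuclei labelled after divisions fragment a unit into many
#' small clones):
#' case 1 — few multicoloured, clone number near baseline (induction
#' before both mechanisms); case 2 — multicoloured shift, number/size
#' near baseline (after endoreplication, before mitosis); case 3 — few
#' multicoloured but many smaller clones (after mitosis, before
#' endoreplication); case 4 — multicoloured and many smaller clones
#' (after the start of both).
#'
#' @param stats,baseline `cg_stats` for the test induction and for
#'   induction at t = 0 on the same schedule/seed family.
#' @param multi_threshold Multicoloured-fraction cut (default 0.2).
#' @param count_band Relative band around the baseline clone number
#'   (default 0.2; "higher numbers" means > 1.2 x baseline).
#' @param size_band Relative band around the baseline clone size
#'   (default `count_band`; "smaller sizes" means < 0.8 x baseline).
#'   Fragmentation (cases 3/4) requires both more and smaller clones.
#' @return One-row tibble with `case` (integer 1-4) and the evidence
#'   columns used for the decision.
#' @export
classify_induction_case <- function(stats, baseline,
                                    multi_threshold = 0.2,
                                    count_band = 0.2,
                                    size_band = count_band) {
  stopifnot(inherits(stats, "cg_stats"), inherits(baseline, "cg_stats"))
  n_ratio <- stats$n_clones / baseline$n_clones
  size_ratio <- stats$mean_size / baseline$mean_size
  multi <- stats$multicoloured_fraction
  more_clones <- n_ratio > 1 + count_band && size_ratio < 1 - size_band
  case <- if (multi < multi_threshold && !more_clones) 1L
    else if (multi >= multi_threshold && !more_clones) 2L
    else if (multi < multi_threshold) 3L
    else 4L
  tibble(case = case, multicoloured_fraction = multi,
         n_clones = stats$n_clones, baseline_clones = baseline$n_clones,
         clone_number_ratio = n_ratio, clone_size_ratio = size_ratio)
}

#' Count colour-overlap (fusion) events detectable with membrane labels
#'
#' With membrane-targeted labels, a fusion between two units is
#' detectable as a colour overlap only when their colour combinations
#' differ; fusions between same-colour units leave no visible trace.
#' Counts logged fusion events occurring at or after induction.
#'
#' @param population An induced `cg_population`.
#' @param mode Must be `"CAAX"`; overlaps are defined on membranes.
#' @return Tibble with `detectable` and `undetectable` counts.
#' @export
count_overlap_events <- function(population, mode = "CAAX") {
  if (!identical(mode, "CAAX")) {
    abort("Overlap events are defined for membrane (CAAX) labels only.")
  }
  if (is.null(population$induction)) {
    abort("Labels have not been induced; call induce_labels() first.")
  }
  fus <- population$fusions[population$fusions$induced, , drop = FALSE]
  differs <- purrr::map2_lgl(fus$combo_keep, fus$combo_gone,
                             ~ !identical(.x, .y))
  tibble(detectable = sum(differs), undetectable = sum(!differs))
}
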