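#' Evidence records from pairwise bleaching experiments
#'
#' One record per (experiment, observed zone): the zone that was bleached,
#' the observed zone, whether the two share a border, and the significance
#' call for the observed loss. Helper around a plain tibble so records can
#' be built inline or accumulated with [dplyr::bind_rows()].
#'
#' @param experiment Experiment identifier.
#' @param bleached_zone,observed_zone Zone names (must differ).
#' @param channel Channel the loss was measured in.
#' @param percent_loss Measured \%FL (fraction).
#' @param threshold Null threshold used for the call.
#' @param significant Logical call; if missing, derived as
#'   `percent_loss > threshold`.
#' @param adjacent Do the two zones share a border? Barrier evidence
#'   requires adjacency (absence of loss in a distant zone is weak).
#' @return One-row tibble of class-compatible evidence.
#' @export
evidence_record <- function(experiment, bleached_zone, observed_zone,
                            channel, percent_loss, threshold,
                            significant = percent_loss > threshold,
                            adjacent = TRUE) {
  if (bleached_zone == observed_zone) {
    abort("Relation evidence needs observed_zone != bleached_zone.")
  }
  if (is.na(significant)) abort("Evidence carries an unresolved call.")
  tibble(experiment = experiment, bleached_zone = bleached_zone,
         observed_zone = observed_zone, channel = channel,
         percent_loss = percent_loss, threshold = threshold,
         significant = significant, adjacent = adjacent)
}

#' Accumulate pairwise relations from bleach evidence
#'
#' Applies the FLIP interpretation rules per unordered zone pair:
#' a significant loss in the observed zone means the pair is `connected`;
#' a non-significant loss in a zone bordering the bleached zone means a
#' diffusion `barrier`; pairs never probed are `untested` (as are
#' non-significant losses in non-adjacent zones, which are weak
#' evidence); pairs with conflicting records across experiments are
#' marked `dynamic`, the signature of connectivity remodelling over time.
#'
#' @param records Tibble of evidence rows (see [evidence_record()]).
#' @param zones Optional character vector of all zones; defaults to the
#'   zones seen in `records`. Unprobed pairs are reported `untested`.
#' @return Tibble with columns `zone_a`, `zone_b` (sorted within pair),
#'   `relation` in `c("connected", "barrier", "dynamic", "untested")`,
#'   `n_records`, `evidence` (list of experiment ids).
#' @export
accumulate_evidence <- function(records, zones = NULL) {
  zones <- zones %||%
    sort(unique(c(records$bleached_zone, records$observed_zone)))
  if (length(zones) < 2L) abort("Need at least two zones.")
  if (nrow(records) && any(is.na(records$significant))) {
    abort("Evidence carries an unresolved call.")
  }
  pairs <- t(utils::combn(zones, 2L))
  out <- purrr::pmap_dfr(
    list(pairs[, 1], pairs[, 2]),
    function(a, b) {
      rec <- records[(records$bleached_zone == a & records$observed_zone == b) |
                     (records$bleached_zone == b & records$observed_zone == a), ,
                     drop = FALSE]
      votes <- character()
      if (nrow(rec)) {
        votes <- dplyr::case_when(
          rec$significant ~ "connected",
          !rec$significant & rec$adjacent ~ "barrier",
          TRUE ~ "untested"
        )
      }
      votes <- votes[votes != "untested"]
      relation <- if (!length(votes)) {
        "untested"
      } else if (all(votes == "connected")) {
        "connected"
      } else if (all(votes == "barrier")) {
        "barrier"
      } else {
        "dynamic"
      }
      tibble(zone_a = a, zone_b = b, relation = relation,
             n_records = nrow(rec), evidence = list(rec$experiment))
    }
  )
  attr(out, "zones") <- zones
  out
}

#' Build a compartment map from pairwise relations
#'
#' Merges zones along `connected` relations (union-find over the
#' connected edges only) and flags violations: `barrier` pairs whose two
#' zones nevertheless end up in one merged block. A violation is read as
#' evidence of temporally dynamic connectivity — exchange that is partial
#' in space and changing in time — rather than measurement error.
#'
#' @param relations Tibble from [accumulate_evidence()].
#' @return Object of class `compartment_map` with fields `zones`,
#'   `relations`, `blocks` (tibble zone/block), `violations` (tibble of
#'   offending barrier pairs).
#' @export
build_map <- function(relations) {
  zones <- attr(relations, "zones") %||%
    sort(unique(c(relations$zone_a, relations$zone_b)))
  conn <- relations[relations$relation == "connected", , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    conn[c("zone_a", "zone_b")], directed = FALSE,
    vertices = data.frame(name = zones)
  )
  comp <- igraph::components(g)$membership
  blocks <- tibble(zone = names(comp), block = as.integer(comp))
  barr <- relations[relations$relation == "barrier", , drop = FALSE]
  same_block <- comp[barr$zone_a] == comp[barr$zone_b]
  violations <- barr[same_block, c("zone_a", "zone_b"), drop = FALSE]
  structure(
    list(zones = zones, relations = relations, blocks = blocks,
         violations = as_tibble(violations)),
    class = "compartment_map"
  )
}

#' @export
print.compartment_map <- function(x, ...) {
  cat("<compartment_map> ", length(x$zones), " zones, ",
      dplyr::n_distinct(x$blocks$block), " merged blocks, ",
      nrow(x$violations), " violation(s)\n", sep = "")
  invisible(x)
}

#' @rdname build_map
#' @param x A `compartment_map`.
#' @param ... Unused.
#' @export
tidy.compartment_map <- function(x, ...) {
  dplyr::left_join(
    x$relations[c("zone_a", "zone_b", "relation", "n_records")],
    dplyr::rename(x$blocks, zone_a = "zone", block_a = "block"),
    by = "zone_a"
  ) |>
    dplyr::left_join(
      dplyr::rename(x$blocks, zone_b = "zone", block_b = "block"),
      by = "zone_b"
    )
}

#' @rdname build_map
#' @export
glance.compartment_map <- function(x, ...) {
  tibble(
    n_zones = length(x$zones),
    n_blocks = dplyr::n_distinct(x$blocks$block),
    n_connected = sum(x$relations$relation == "connected"),
    n_barrier = sum(x$relations$relation == "barrier"),
    n_dynamic = sum(x$relations$relation == "dynamic"),
    n_untested = sum(x$relations$relation == "untested"),
    n_violations = nrow(x$violations),
    min_compartments = count_distinct_compartments(x)
  )
}

#' Minimum number of distinct compartments consistent with the evidence
#'
#' Exhaustive search over partitions of the zones for the smallest number
#' of blocks such that (i) no block contains a barrier (or dynamic) pair
#' and (ii) every block is internally connected through `connected`
#' relations (zones are only merged on positive connectivity evidence;
#' dynamic pairs are excluded from both edge sets). With up to 10 zones
#' the search is exact; beyond that a lower bound derived from the merged
#' blocks and violations is returned with an error.
#'
#' @param map A `compartment_map`.
#' @return Integer minimum compartment count.
#' @export
count_distinct_compartments <- function(map) {
  zones <- map$zones
  n <- length(zones)
  if (n > 10L) {
    lb <- dplyr::n_distinct(map$blocks$block) + nrow(map$violations)
    abort(sprintf(
      "Exact search refused for > 10 zones; lower bound from violations: %d.",
      lb))
  }
  rel <- map$relations
  conn <- matrix(FALSE, n, n, dimnames = list(zones, zones))
  forb <- matrix(FALSE, n, n, dimnames = list(zones, zones))
  for (i in seq_len(nrow(rel))) {
    a <- rel$zone_a[i]; b <- rel$zone_b[i]
    if (rel$relation[i] == "connected") {
      conn[a, b] <- conn[b, a] <- TRUE
    } else if (rel$relation[i] %in% c("barrier", "dynamic")) {
      forb[a, b] <- forb[b, a] <- TRUE
    }
  }
  best <- n
  # assign zones one at a time to an existing block or a new one
  recurse <- function(i, blocks) {
    if (length(blocks) >= best) return(invisible())
    if (i > n) {
      # every block must induce a connected subgraph of `conn`
      ok <- all(vapply(blocks, function(bl) {
        if (length(bl) == 1L) return(TRUE)
        sub <- conn[bl, bl, drop = FALSE]
        g <- igraph::graph_from_adjacency_matrix(sub, mode = "undirected")
        igraph::is_connected(g)
      }, logical(1)))
      if (ok) best <<- min(best, length(blocks))
      return(invisible())
    }
    z <- i
    for (b in seq_along(blocks)) {
      if (!any(forb[z, blocks[[b]]])) {
        nb <- blocks
        nb[[b]] <- c(nb[[b]], z)
        recurse(i + 1L, nb)
      }
    }
    recurse(i + 1L, c(blocks, list(z)))
  }
  recurse(2L, list(1L))
  as.integer(best)
}
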