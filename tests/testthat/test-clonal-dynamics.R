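# Clonal growth simulator, label induction and case classification.

quiet_schedule <- function(...) {
  event_schedule(horizon = 10, n_founders = 4L, endo_window = c(0, 5),
                 endo_rate = 0, mitosis_window = c(5, 10),
                 mitosis_rate = 0, fusion_rate = 0, ...)
}

test_that("with all rates zero nothing happens", {
  pop <- simulate_population(quiet_schedule(), seed = 1)
  expect_equal(nrow(pop$nuclei), 4L)
  expect_equal(pop$nuclei$copies, rep(1L, 4))
  expect_equal(nrow(pop$events), 0L)
  expect_true(all(pop$units$merged_into == pop$units$unit))
})

test_that("identical seeds reproduce identical histories", {
  sch <- canonical_schedule()
  a <- simulate_population(sch, seed = 7)
  b <- simulate_population(sch, seed = 7)
  expect_identical(a$events, b$events)
  expect_identical(a$nuclei, b$nuclei)
  ia <- induce_labels(a, 48, seed = 3)
  ib <- induce_labels(b, 48, seed = 3)
  expect_identical(ia$nuclei, ib$nuclei)
})

test_that("mitosis-only growth matches the branching-process mean", {
  sch <- event_schedule(horizon = 20, n_founders = 5L,
                        endo_window = c(0, 1), endo_rate = 0,
                        mitosis_window = c(0, 20), mitosis_rate = 0.05,
                        fusion_rate = 0)
  counts <- unlist(lapply(1:200, function(s) {
    pop <- simulate_population(sch, seed = s)
    as.integer(table(factor(pop$nuclei$unit, levels = 1:5)))
  }))
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - exp(0.05 * 20)), 3 * se)
})

test_that("fusion rate zero leaves every unit unfused", {
  pop <- simulate_population(
    event_schedule(fusion_rate = 0), seed = 3)
  expect_equal(sum(pop$events$type == "fusion"), 0L)
  expect_true(all(pop$units$merged_into == pop$units$unit))
})

test_that("label induction follows the four-colour single-copy rules", {
  pop <- simulate_population(quiet_schedule(), seed = 2)
  # efficiency 0: everything stays uncoloured
  p0 <- induce_labels(pop, 5, efficiency = 0, seed = 1)
  expect_true(all(unlist(p0$nuclei$colours) == "uncoloured"))
  expect_error(compute_clone_stats(p0), "labelled")
  # single-copy nuclei at full efficiency: every clone one colour
  p1 <- induce_labels(pop, 0, efficiency = 1, seed = 1)
  st <- compute_clone_stats(p1)
  expect_equal(st$n_clones, 4L)
  expect_true(all(st$clones$n_colours == 1L))
  expect_error(induce_labels(pop, 99, seed = 1), "horizon")
})

test_that("single-colour probability follows 4^(1-m), against enumeration", {
  # enumeration oracle agrees exactly with the closed form
  for (m in 1:4) {
    expect_equal(enumerate_single_colour_prob(m), 4^(1 - m))
  }
  # simulated fractions for m in {1, 2, 4} copies within 3 SE at n = 10,000
  for (doublings in 0:2) {
    m <- 2^doublings
    sch <- event_schedule(horizon = 3, n_founders = 10000L,
                          endo_window = c(0, doublings), endo_rate = 10,
                          mitosis_window = c(0, 1), mitosis_rate = 0,
                          fusion_rate = 0)
    pop <- induce_labels(simulate_population(sch, seed = doublings + 1),
                         3, seed = 50 + doublings)
    expect_true(all(pop$nuclei$copies == m))
    single <- mean(vapply(pop$nuclei$colours,
                          function(cc) length(unique(cc)) == 1L,
                          logical(1)))
    p <- 4^(1 - m)
    if (p == 1) {
      expect_equal(single, 1)   # one copy can only be single-coloured
    } else {
      expect_lt(abs(single - p), 3 * sqrt(p * (1 - p) / 10000))
    }
  }
})

test_that("recombined copy colours are uniform over the four choices", {
  sch <- event_schedule(horizon = 2, n_founders = 10000L,
                        endo_window = c(0, 2), endo_rate = 10,
                        mitosis_window = c(0, 1), mitosis_rate = 0,
                        fusion_rate = 0)
  pop <- induce_labels(simulate_population(sch, seed = 4), 2, seed = 9)
  draws <- unlist(pop$nuclei$colours)
  expect_gte(length(draws), 1e5 / 3)
  tab <- table(draws)
  expect_gt(stats::chisq.test(tab)$p.value, 0.001)
})

test_that("clone statistics equal an independent recount from the log", {
  for (s in c(5, 17, 31)) {
    pop <- induce_labels(simulate_population(canonical_schedule(), seed = s),
                         60, seed = s + 100)
    st <- compute_clone_stats(pop)
    oracle <- recount_clones(pop)
    expect_equal(st$n_clones, oracle$n_clones)
    expect_equal(sort(st$clones$n_nuclei), oracle$sizes)
    expect_equal(st$events_per_clone, st$fusion_events / st$n_clones)
  }
})

test_that("clone statistics are invariant to colour relabelling", {
  pop <- induce_labels(simulate_population(canonical_schedule(), seed = 8),
                       48, seed = 20)
  st <- compute_clone_stats(pop)
  perm <- c(c1 = "c3", c2 = "c1", c3 = "c4", c4 = "c2",
            uncoloured = "uncoloured")
  pop2 <- pop
  pop2$nuclei$colours <- lapply(pop$nuclei$colours,
                                function(cc) unname(perm[cc]))
  pop2$fusions$combo_keep <- lapply(pop$fusions$combo_keep,
                                    function(cc) sort(unname(perm[cc])))
  pop2$fusions$combo_gone <- lapply(pop$fusions$combo_gone,
                                    function(cc) sort(unname(perm[cc])))
  st2 <- compute_clone_stats(pop2)
  expect_equal(st2$n_clones, st$n_clones)
  expect_equal(sort(st2$clones$n_nuclei), sort(st$clones$n_nuclei))
  expect_equal(st2$events_per_clone, st$events_per_clone)
  expect_equal(st2$multicoloured_fraction, st$multicoloured_fraction)
})

test_that("induction timing classifies as cases 1, 2 and 4 on the canonical schedule", {
  hits <- c(case1 = 0, case2 = 0, case4 = 0)
  n <- 20
  for (s in 1:n) {
    pop <- simulate_population(canonical_schedule(), seed = s)
    base <- compute_clone_stats(induce_labels(pop, 0, seed = 1000 + s))
    mid <- compute_clone_stats(induce_labels(pop, 48, seed = 2000 + s))
    late <- compute_clone_stats(induce_labels(pop, 92, seed = 3000 + s))
    hits <- hits + c(classify_induction_case(base, base)$case == 1,
                     classify_induction_case(mid, base)$case == 2,
                     classify_induction_case(late, base)$case == 4)
  }
  expect_gte(hits[["case1"]] / n, 0.95)
  expect_gte(hits[["case2"]] / n, 0.95)
  expect_gte(hits[["case4"]] / n, 0.95)
})

test_that("mitosis-before-endoreplication induction between windows is case 3", {
  sch3 <- event_schedule(endo_window = c(50, 90), endo_rate = 0.04,
                         mitosis_window = c(8, 48), mitosis_rate = 0.045)
  hits <- 0
  for (s in 1:10) {
    pop <- simulate_population(sch3, seed = s)
    base <- compute_clone_stats(induce_labels(pop, 0, seed = 1000 + s))
    mid <- compute_clone_stats(induce_labels(pop, 49, seed = 2000 + s))
    hits <- hits + (classify_induction_case(mid, base)$case == 3)
  }
  expect_gte(hits / 10, 0.9)
})

test_that("overlap events count colour-differing fusions only", {
  pop0 <- induce_labels(simulate_population(quiet_schedule(), seed = 1),
                        0, mode = "CAAX", seed = 1)
  expect_equal(count_overlap_events(pop0)$detectable, 0L)
  expect_error(count_overlap_events(pop0, mode = "NLS"), "CAAX")
  # log-filter oracle on fused populations
  sch <- event_schedule(fusion_rate = 0.01)
  for (s in 1:5) {
    pop <- induce_labels(simulate_population(sch, seed = s), 0,
                         mode = "CAAX", seed = s)
    ov <- count_overlap_events(pop)
    fus <- pop$fusions[pop$fusions$induced, ]
    oracle <- sum(purrr::map2_lgl(fus$combo_keep, fus$combo_gone,
                                  ~ !identical(.x, .y)))
    expect_equal(ov$detectable, oracle)
    expect_equal(ov$detectable + ov$undetectable, nrow(fus))
  }
})
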