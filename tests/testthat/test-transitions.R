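test_that("pe onsets are filtered by spacing and by co-active behaviors", {
  # two pe bouts whose locations are 0.3 mm apart: the second is dropped
  loc <- matrix(0, 60, 2)
  loc[31:60, 1] <- 0.3
  e <- make_ethogram(list(pe = list(c(5, 8), c(40, 43))), 60, location = loc)
  s <- extract_start_sequence(e, min_pe_spacing = 0.5)
  expect_equal(sum(s$items$label == "pe"), 1)
  # far enough apart: both kept
  loc[31:60, 1] <- 0.8
  e2 <- make_ethogram(list(pe = list(c(5, 8), c(40, 43))), 60,
                      location = loc)
  s2 <- extract_start_sequence(e2, min_pe_spacing = 0.5)
  expect_equal(sum(s2$items$label == "pe"), 2)

  # pe onset while another behavior is active is omitted
  e3 <- make_ethogram(list(groom = list(c(10, 20)), pe = list(c(12, 15))), 30)
  s3 <- extract_start_sequence(e3, min_pe_spacing = 0)
  expect_false("pe" %in% s3$items$label)

  # missing location track: filter skipped with a warning
  e4 <- make_ethogram(list(pe = list(c(5, 8), c(40, 43))), 60)
  expect_warning(s4 <- extract_start_sequence(e4), "location")
  expect_equal(sum(s4$items$label == "pe"), 2)
})

test_that("bend onset is scored once across aborted-and-restarted burrowing", {
  e <- make_ethogram(list(bend = list(c(0, 100)),
                          burrow = list(c(10, 20), c(40, 60))), 100)
  s <- extract_start_sequence(e, min_pe_spacing = 0)
  expect_equal(sum(s$items$label == "bend"), 1)
  expect_equal(sum(s$items$label == "burrow"), 2)
  expect_equal(s$items$label, c("bend", "burrow", "burrow"))

  empty <- ethogram(matrix(FALSE, 5, 7,
                           dimnames = list(NULL, behavior_labels())))
  expect_equal(nrow(extract_start_sequence(empty)$items), 0)
})

test_that("transition estimation matches a brute-force pair tally", {
  s <- make_sequence(c("walk", "pe", "walk", "pe"))
  tm <- estimate_transitions(list(s))
  expect_equal(tm$probs["walk", "pe"], 1)
  expect_equal(tm$probs["pe", "walk"], 1)

  # self-transition: behavior started, stopped and started again
  tm2 <- estimate_transitions(list(make_sequence(c("burrow", "burrow"))))
  expect_equal(tm2$counts["burrow", "burrow"], 1L)

  set.seed(7)
  labs <- behavior_labels()
  seqs <- lapply(1:8, function(i)
    make_sequence(sample(labs, sample(3:12, 1), replace = TRUE)))
  tm3 <- estimate_transitions(seqs)
  expect_equal(unname(tm3$counts), unname(naive_transition_counts(seqs)))
  # row stochasticity (or all-zero rows)
  rs <- rowSums(tm3$probs)
  expect_true(all(abs(rs - 1) < 1e-12 | rs == 0))
})

test_that("pre/post phases split at egg_out and pool the right pairs", {
  s <- make_sequence(c("walk", "bend", "burrow", "egg_out", "detach",
                       "groom"))
  pre <- estimate_transitions(list(s), phase = "pre")
  post <- estimate_transitions(list(s), phase = "post")
  expect_equal(sum(pre$counts), 3)  # walk->bend->burrow->egg_out
  expect_equal(pre$counts["burrow", "egg_out"], 1L)
  expect_equal(sum(post$counts), 2)  # egg_out->detach->groom
  expect_equal(post$counts["egg_out", "detach"], 1L)
  expect_equal(estimate_transitions(list(s), phase = "all")$counts |> sum(),
               5)
})

test_that("permutation p-values are deterministic, extreme for a rigid chain, and floored", {
  s <- make_sequence(rep(c("pe", "walk"), 21))  # pe,walk alternating
  tm <- estimate_transitions(list(s))
  p1 <- permutation_test(tm, list(s), n_perm = 199, seed = 5)
  p2 <- permutation_test(tm, list(s), n_perm = 199, seed = 5)
  expect_identical(p1$pvals, p2$pvals)
  # a deterministic alternation is as extreme as a permutation can get
  expect_equal(p1$pvals["pe", "walk"], 1 / 200)
  expect_equal(p1$pvals["walk", "pe"], 1 / 200)

  # low-probability cells are never significant regardless of p
  seqs <- list(make_sequence(c(rep(c("pe", "walk"), 30), "pe", "bend")))
  tmf <- estimate_transitions(seqs)
  expect_lt(tmf$probs["pe", "bend"], 0.04)
  pf <- permutation_test(tmf, seqs, n_perm = 99, seed = 1,
                         alpha = 0.5, prob_floor = 0.04)
  expect_false(pf$significant["pe", "bend"])

  expect_error(permutation_test(tm, list(s), n_perm = 0), "n_perm")
  expect_error(permutation_test(tm, list(s), n_perm = 10, alpha = 1),
               "alpha")
})

test_that("first-occurrence ordering excludes incomplete events and tallies ranks", {
  all7 <- c("pe", "walk", "bend", "burrow", "egg_out", "detach", "groom")
  seqs <- list(make_sequence(all7),
               make_sequence(c("walk", "pe", all7[3:7])),
               make_sequence(all7[-7]))  # lacks groom: excluded
  fo <- first_occurrence_order(seqs)
  expect_equal(fo$n_events, 2)
  expect_equal(fo$fractions["pe", "pos1"], 0.5)
  expect_equal(fo$fractions["walk", "pos1"], 0.5)
  expect_equal(fo$fractions["bend", "pos3"], 1)
  expect_true(all(abs(rowSums(fo$fractions) - 1) < 1e-12))
  expect_error(first_occurrence_order(list(make_sequence(c("pe", "walk")))),
               "seven")
})

test_that("behavior time course aligns to egg_out", {
  e1 <- make_ethogram(list(burrow = list(c(10, 41)),
                           egg_out = list(c(40, 41)),
                           bend = list(c(5, 42))), 80, egg_out_frame = 40)
  tc1 <- behavior_time_course(list(e1), window_s = 1)
  i0 <- which(tc1$time_s == 0)
  expect_equal(unname(tc1$fraction["egg_out", i0]), 1)
  # single event: the matrix is the event's own activity window
  expect_equal(unname(tc1$fraction["bend", ]),
               as.numeric(e1$activity[(40 - 20):(40 + 20) + 1, "bend"]))

  # one of two events active at t = -1 s -> fraction 0.5
  e2 <- make_ethogram(list(egg_out = list(c(40, 41))), 80,
                      egg_out_frame = 40)
  tc2 <- behavior_time_course(list(e1, e2), window_s = 1)
  im1 <- which(tc2$time_s == -1)
  expect_equal(unname(tc2$fraction["burrow", im1]), 0.5)

  # simulated cohort: egg_out fraction at t = 0 equals 1
  sim <- simulate_ethogram(n_events = 10, seed = 2)
  tc <- behavior_time_course(sim$ethograms, window_s = 5)
  expect_equal(unname(tc$fraction["egg_out", which(tc$time_s == 0)]), 1)
  expect_true(all(tc$fraction >= 0 & tc$fraction <= 1))
  expect_error(behavior_time_course(list(make_ethogram(list(), 10))),
               "egg_out")
})

test_that("progression probabilities are per fly with a minimum-bout filter", {
  mk <- function(fly, nb, nhit) {
    spec <- list(bend = lapply(seq_len(nb), function(i)
      c(i * 50, i * 50 + 30)))
    spec$burrow <- lapply(seq_len(nhit), function(i)
      c(i * 50 + 5, i * 50 + 20))
    make_ethogram(spec, 50 * nb + 50, fly_id = fly)
  }
  es <- list(mk("A", 4, 3), mk("B", 2, 2))
  pp <- progression_probability(es, "bend", "burrow", min_bouts = 3)
  expect_equal(nrow(pp), 1)  # fly B has only 2 bend bouts
  expect_equal(pp$probability, 0.75)
  pp2 <- progression_probability(es, "bend", "burrow", min_bouts = 2)
  expect_equal(pp2$probability[pp2$fly_id == "B"], 1)

  # burrow -> egg_out: every burrow bout contains egg_out -> 1.0
  e <- make_ethogram(list(burrow = list(c(10, 30)),
                          egg_out = list(c(25, 26))), 50,
                     egg_out_frame = 25, fly_id = "C")
  pe <- progression_probability(list(e), "burrow", "egg_out", min_bouts = 1)
  expect_equal(pe$probability, 1)
  expect_error(progression_probability(es, "walk", "groom"), "unsupported")
})
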