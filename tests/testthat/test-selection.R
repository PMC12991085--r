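test_that("threshold container validates bounds", {
  expect_error(qc_thresholds(com_max = -1), "> 0")
  expect_error(qc_thresholds(fraction_required = 0), "fraction_required")
  expect_error(qc_thresholds(fraction_required = 1.2), "fraction_required")
  th <- qc_thresholds()
  expect_equal(th$com_max, 2.0)
  expect_equal(th$rmsd_max, 3.0)
  expect_equal(th$hbond_dist_max, 3.0)
})

test_that("replicates pass or fail on the published bounds", {
  th <- qc_thresholds(fraction_required = 0.9)
  good <- list(com_displacement = const_series("com_displacement", 1.5),
               ligand_rmsd = const_series("ligand_rmsd", 2.0))
  rep <- evaluate_replicate(good, th, replicate_id = "r1")
  expect_true(rep$overall)
  expect_true(all(rep$criteria$verdict == "pass"))
  # a COM series at 2.5 A violates the 2 A bound
  bad <- modifyList(good, list(com_displacement =
                                 const_series("com_displacement", 2.5)))
  rep2 <- evaluate_replicate(bad, th, replicate_id = "r2")
  expect_false(rep2$overall)
  tab <- rep2$criteria
  expect_equal(tab$verdict[tab$metric == "com_displacement"], "fail")
  expect_equal(tab$verdict[tab$metric == "ligand_rmsd"], "pass")
})

test_that("the required fraction is counted, not eyeballed", {
  # 85% of frames below 2 A: fails at 0.9, passes at 0.8
  v <- c(rep(1.0, 17), rep(2.5, 3))
  m <- list(com_displacement = metric_series("com_displacement", v),
            ligand_rmsd = const_series("ligand_rmsd", 1.0))
  expect_false(evaluate_replicate(m, qc_thresholds(fraction_required = 0.9))$overall)
  expect_true(evaluate_replicate(m, qc_thresholds(fraction_required = 0.8))$overall)
})

test_that("production window and optional criteria behave", {
  n <- 20
  v <- c(rep(5, 10), rep(1, 10))    # noisy restrained span, calm production
  m <- list(com_displacement = metric_series("com_displacement", v),
            ligand_rmsd = const_series("ligand_rmsd", 1, n))
  expect_false(evaluate_replicate(m, qc_thresholds())$overall)
  expect_true(evaluate_replicate(m, qc_thresholds(),
                                 production_start = 10)$overall)
  expect_error(evaluate_replicate(m, qc_thresholds(),
                                  production_start = 100),
               "production_start")
  # lid criterion only runs when both series and threshold exist
  rep <- evaluate_replicate(m, qc_thresholds(), production_start = 10)
  expect_true(any(grepl("lid_distance.*skipped", rep$notes)))
  m$lid_distance <- metric_series("lid_distance", rep(c(8, 8.4), 10))
  rep2 <- evaluate_replicate(m, qc_thresholds(lid_excursion_max = 1),
                             production_start = 10)
  expect_true("lid_distance" %in% rep2$criteria$metric)
  expect_true(rep2$overall)
  rep3 <- evaluate_replicate(m, qc_thresholds(lid_excursion_max = 0.1),
                             production_start = 10)
  expect_false(rep3$overall)
})

test_that("tightening thresholds never converts a fail into a pass", {
  set.seed(55)
  for (i in 1:100) {
    m <- list(
      com_displacement = metric_series("com_displacement",
                                       abs(rnorm(30, runif(1, 0.5, 3), 0.6))),
      ligand_rmsd = metric_series("ligand_rmsd",
                                  abs(rnorm(30, runif(1, 1, 4), 0.8))),
      lid_distance = metric_series("lid_distance",
                                   rnorm(30, 8, runif(1, 0.1, 2))))
    loose <- qc_thresholds(com_max = 2.0, rmsd_max = 3.0,
                           lid_excursion_max = 2.0,
                           fraction_required = 0.8)
    tight <- qc_thresholds(com_max = 1.5, rmsd_max = 2.5,
                           lid_excursion_max = 1.0,
                           fraction_required = 0.9)
    r_loose <- evaluate_replicate(m, loose)
    r_tight <- evaluate_replicate(m, tight)
    if (!r_loose$overall) expect_false(r_tight$overall)
    # per-criterion monotonicity as well
    for (k in seq_len(nrow(r_loose$criteria))) {
      if (r_loose$criteria$verdict[k] == "fail") {
        expect_equal(r_tight$criteria$verdict[k], "fail")
      }
    }
  }
})

test_that("reports are deterministic for identical inputs", {
  m <- list(com_displacement = const_series("com_displacement", 1.2),
            ligand_rmsd = const_series("ligand_rmsd", 2.2))
  r1 <- evaluate_replicate(m, qc_thresholds(), replicate_id = "a")
  r2 <- evaluate_replicate(m, qc_thresholds(), replicate_id = "a")
  expect_identical(serialize(r1, NULL), serialize(r2, NULL))
})

test_that("ranking orders by the composite score with stable tie-breaks", {
  mk <- function(id, com, rmsd) {
    evaluate_replicate(
      list(com_displacement = const_series("com_displacement", com),
           ligand_rmsd = const_series("ligand_rmsd", rmsd)),
      qc_thresholds(), replicate_id = id)
  }
  # dominance: strictly lower on both metrics ranks first
  expect_equal(rank_replicates(list(mk("b", 1.5, 2.5), mk("a", 0.5, 1.0)), 2),
               c("a", "b"))
  # identical metrics: alphabetical by id
  expect_equal(rank_replicates(list(mk("z", 1, 1), mk("m", 1, 1),
                                    mk("c", 1, 1)), 3),
               c("c", "m", "z"))
  # randomized fixtures match an independent sort oracle
  set.seed(66)
  for (i in 1:10) {
    ids <- sprintf("rep%02d", sample(1:20, 6))
    com <- runif(6, 0.2, 1.9)
    rmsd <- runif(6, 0.5, 2.9)
    reports <- lapply(seq_along(ids), function(j) mk(ids[j], com[j], rmsd[j]))
    oracle <- ids[order(com / 2.0 + rmsd / 3.0, ids)]
    expect_equal(rank_replicates(reports, 6), oracle)
  }
  # shortfall is reported
  expect_error(rank_replicates(list(mk("a", 5, 5)), 1), "0 passing")
})
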