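test_that("mutation respects rates, preserves length without indels, and is seed-reproducible", {
  s <- random_seq(200)
  expect_identical(mutate_sequence(s, 0, 0), s)
  heavy <- mutate_sequence(s, 0.9, 0, seed = 4)
  expect_equal(nchar(heavy), nchar(s)) # substitutions never change length
  expect_identical(
    mutate_sequence(s, 0.05, 0.02, seed = 7),
    mutate_sequence(s, 0.05, 0.02, seed = 7)
  )
  expect_error(mutate_sequence(s, 1), "rates")
  # substitutions always change the base
  set.seed(5)
  m <- mutate_sequence(strrep("A", 500), 0.5)
  ch <- strsplit(m, "")[[1]]
  expect_true(all(ch %in% c("A", "C", "G", "T")))
  expect_gt(sum(ch != "A"), 150)
})

test_that("a recorded mutation fixture is reproduced byte-for-byte", {
  # run-and-record fixture: seed 99 draws the input, seed 7 mutates it
  set.seed(99)
  input <- random_seq(100)
  expect_identical(
    input,
    "TATCCAGCCCTCTATTGTACTCCTATCTCAGCGCCTATGCCACTTCGACTGCGCGGTTAGGAGCAATAAGATGTGCGTGGGCGCATGGGAGGCGCTGGCC"
  )
  expect_identical(
    mutate_sequence(input, 0.05, seed = 7),
    "TATCCAGCCCTCTATTGAACTCCTATCTCAGCGCCTATGCCACTTCGACTGCGCGGTTAGGAGCAATAAGATGTGCGTGGGCGCATGGGAGACGCTGGCC"
  )
})

test_that("noise-free simulated loci are exact truncated copies with consistent truth", {
  model <- toy_model()
  cfg <- locus_sim_config(
    model,
    n = 40, substitution_rate = 0, indel_rate = 0,
    frac_tether_truncated = 0, frac_decoy = 0
  )
  sim <- simulate_loci(cfg, seed = 5)
  q <- sim$query
  for (i in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[i, ]
    lab <- if (tr$bin == "M11+") "M11" else tr$bin
    p <- query_position(q, lab, tr$offset)
    expect_identical(sim$sequences[[tr$locus_id]], substr(q$sequence, p, nchar(q$sequence)))
  }
  # forced construction: fixed count 2, offset 1 -> exact M2-M1-T sequence
  cfg2 <- locus_sim_config(
    model,
    n = 5, count_probs = c(0, 1, rep(0, 9)),
    hotspots = data.frame(offset = 1L, weight = 0.999999),
    substitution_rate = 0, frac_tether_truncated = 0, frac_decoy = 0
  )
  sim2 <- simulate_loci(cfg2, seed = 1)
  m2m1t <- paste0(model$monomers[1], model$monomers[2], model$tether)
  expect_true(all(sim2$sequences == m2m1t))
  expect_true(all(sim2$truth$bin == "M2"))
  expect_true(all(sim2$truth$monomer_count == 2.0))
})

test_that("identical configs and seeds reproduce identical FASTA and truth bytes", {
  model <- toy_model()
  cfg <- locus_sim_config(model, n = 30)
  a <- simulate_loci(cfg, seed = 9)
  b <- simulate_loci(cfg, seed = 9)
  expect_identical(a$sequences, b$sequences)
  expect_identical(a$truth, b$truth)
  tmp1 <- withr::local_tempfile()
  tmp2 <- withr::local_tempfile()
  write_fasta(a$sequences, tmp1)
  write_fasta(b$sequences, tmp2)
  expect_identical(readLines(tmp1), readLines(tmp2))
  c_ <- simulate_loci(cfg, seed = 10)
  expect_false(identical(a$sequences, c_$sequences))
})

test_that("all tether-truncated loci fail the tether-tail filter", {
  model <- tf_like_model()
  cfg <- locus_sim_config(
    model,
    n = 40, frac_tether_truncated = 1, frac_decoy = 0
  )
  sim <- simulate_loci(cfg, seed = 3)
  res <- annotate_loci(model, sim$sequences)
  expect_equal(nrow(res$calls), 0L)
  failed <- res$hits[!res$hits$pass, ]
  expect_true(all(failed$reason == "tether-3'-truncated"))
})

test_that("simulated plates recover strengths exactly in the noise-free case", {
  cfg <- plate_sim_config(
    strengths = c(ctrl = 1, X = 50),
    control = "ctrl", efficiency_cv = 0, noise_cv = 0
  )
  sim <- simulate_plate(cfg, seed = 1)
  norm <- normalize_plate(sim$wells, "ctrl")
  s <- norm$summaries
  expect_equal(s$mean_activity[s$construct == "X"], 50)
  expect_equal(s$sem, c(0, 0))
  # saturation cancels in the ratio: activities still exact
  cfg2 <- plate_sim_config(
    strengths = c(ctrl = 1, X = 50), control = "ctrl",
    efficiency_cv = 0, noise_cv = 0, doses = c(5, 10, 25), sat_K = 30
  )
  sim2 <- simulate_plate(cfg2, seed = 1)
  norm2 <- normalize_plate(sim2$wells, "ctrl")
  expect_equal(
    norm2$summaries$mean_activity[norm2$summaries$construct == "X"], 50
  )
  # but the raw signals do saturate
  tit <- summarize_titration(sim2$wells[sim2$wells$construct == "X", ],
    fit_doses = 5
  )
  dev <- tit$linearity[tit$linearity$signal == "fluc", ]
  expect_lt(dev$rel_deviation[dev$dose == 25], -0.3)
})

test_that("plate simulation is seed-reproducible and validates its config", {
  cfg <- plate_sim_config()
  expect_identical(simulate_plate(cfg, 2)$wells, simulate_plate(cfg, 2)$wells)
  expect_error(plate_sim_config(strengths = c(a = 1), control = "b"), "control")
  expect_error(plate_sim_config(strengths = c(a = -1, b = 1), control = "b"), "> 0")
  expect_error(
    locus_sim_config(toy_model(), n = 10, substitution_rate = 1),
    "rates"
  )
  expect_error(
    locus_sim_config(toy_model(), n = 10, count_probs = rep(1, 11)),
    "probability"
  )
})
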