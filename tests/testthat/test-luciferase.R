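make_wells <- function(constructs, ratios, rluc = 1000) {
  data.frame(
    plate = "p1",
    well = sprintf("w%02d", seq_along(constructs)),
    construct = constructs,
    fluc = ratios * rluc,
    rluc = rluc,
    stringsAsFactors = FALSE
  )
}

test_that("plate normalization sets the control mean to exactly 1 and scales constructs", {
  wells <- make_wells(
    c(rep("ctrl", 4), rep("prom", 4)),
    c(2, 2, 2, 2, 4, 4, 4, 4)
  )
  norm <- normalize_plate(wells, "ctrl")
  s <- norm$summaries
  expect_identical(s$mean_activity[s$construct == "ctrl"], 1)
  expect_equal(s$mean_activity[s$construct == "prom"], 2)
  expect_equal(s$sem[s$construct == "prom"], 0)
  expect_equal(s$mean_ratio[s$construct == "ctrl"], 2)
})

test_that("normalization is invariant to rescaling rluc and scales with fluc", {
  set.seed(31)
  wells <- make_wells(
    rep(c("ctrl", "a", "b"), each = 4),
    runif(12, 0.5, 5)
  )
  base <- normalize_plate(wells, "ctrl")$summaries
  wells10 <- wells
  wells10$rluc <- wells10$rluc * 10
  wells10$fluc <- wells10$fluc * 10 # same ratios
  expect_equal(normalize_plate(wells10, "ctrl")$summaries, base)
  # multiplying all rluc alone rescales every raw ratio but leaves
  # normalized activities unchanged (the control rescales identically)
  wellsr <- wells
  wellsr$rluc <- wellsr$rluc * 7
  got <- normalize_plate(wellsr, "ctrl")$summaries
  expect_equal(got$mean_activity, base$mean_activity)
  expect_equal(got$mean_ratio, base$mean_ratio / 7)
  # multiplying all fluc rescales raw ratios but not normalized activity
  wellsf <- wells
  wellsf$fluc <- wellsf$fluc * 3
  gotf <- normalize_plate(wellsf, "ctrl")$summaries
  expect_equal(gotf$mean_activity, base$mean_activity)
  expect_equal(gotf$mean_ratio, base$mean_ratio * 3)
})

test_that("raw ratio reproduces the published firefly/Renilla quotient", {
  # one well with the printed mean raw signals of the positive control
  wells <- data.frame(
    plate = "p", well = c("w1", "w2", "w3"),
    construct = c("pCH117", "ctrl", "ctrl"),
    fluc = c(124238, 500, 500), rluc = c(25159, 1000, 1000),
    stringsAsFactors = FALSE
  )
  norm <- normalize_plate(wells, "ctrl")
  ratio <- norm$wells$ratio[norm$wells$construct == "pCH117"]
  expect_equal(round(ratio, 3), 4.938)
})

test_that("invalid wells and missing controls are errors, not silent drops", {
  wells <- make_wells(c("ctrl", "ctrl", "a", "a"), c(1, 1, 2, 2))
  wells$rluc[3] <- 0
  expect_error(normalize_plate(wells, "ctrl"), "w03")
  expect_error(normalize_plate(make_wells("a", 1), "ctrl"), "missing control")
})

test_that("pairwise tests equal a hand-computed pooled-SD and BH step-up oracle", {
  set.seed(33)
  values <- c(rnorm(4, 1), rnorm(4, 2.5), rnorm(4, 2.6))
  groups <- rep(c("bg", "p1", "p2"), each = 4)
  got <- pairwise_tests(values, groups)
  ref <- pairwise_oracle(values, groups)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  m <- match(key(got$construct_a, got$construct_b), key(ref$a, ref$b))
  expect_equal(got$p_raw, ref$p_raw[m])
  expect_equal(got$p_adj, ref$p_adj[m])
  # BH properties
  expect_true(all(got$p_adj >= got$p_raw))
  expect_true(all(got$p_adj <= 1))
  expect_true(all(diff(got$p_adj[order(got$p_raw)]) >= -1e-15))
})

test_that("identical groups give p = 1 and a single pair is unadjusted", {
  got <- pairwise_tests(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(got$p_raw, 1)
  expect_equal(got$p_adj, got$p_raw)
  expect_error(
    pairwise_tests(c(1, 2, 3), c("a", "a", "b")),
    "insufficient replicates"
  )
  expect_error(pairwise_tests(c(1, 2), c("a", "a")), "insufficient groups")
})

test_that("relative activity reporting matches the published percentages", {
  expect_equal(relative_activity(106.2, 914), 11.6)
  expect_equal(relative_activity(10.1, 189), 5.3)
  expect_equal(relative_activity(5, 5), 100.0)
  expect_error(relative_activity(1, 0), "reference")
  # summary rows work directly
  s <- data.frame(construct = c("as", "s"), mean_activity = c(106.2, 914))
  expect_equal(relative_activity(s[1, ], s[2, ]), 11.6)
})

test_that("titration summaries detect saturation as deviation from the origin line", {
  doses <- c(5, 10, 15, 20, 25, 30)
  lin <- do.call(rbind, lapply(doses, function(d) {
    data.frame(
      construct = "c", dose = d,
      fluc = rep(1000 * d, 3), rluc = rep(200 * d, 3)
    )
  }))
  res <- summarize_titration(lin)
  expect_equal(res$linearity$rel_deviation, rep(0, 12))
  expect_equal(res$summary$ratio_mean, rep(5, 6))

  # saturating: V*d/(K+d) with K = 30 ng
  sat <- lin
  f <- sat$dose / (30 + sat$dose)
  sat$fluc <- 1000 * f
  sat$rluc <- 200 * f
  res2 <- summarize_titration(sat, fit_doses = c(5, 10))
  dev <- res2$linearity[res2$linearity$signal == "fluc", ]
  expect_gt(abs(dev$rel_deviation[dev$dose == 25]), abs(dev$rel_deviation[dev$dose == 10]))
  # common saturation cancels in the ratio
  expect_equal(res2$summary$ratio_mean, rep(5, 6))
  expect_error(summarize_titration(lin[lin$dose == 5, ]), "insufficient doses")
})
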