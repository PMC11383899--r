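# Migration quantification, donor QC and induction calling.

test_that("beads_to_count applies the counting-bead ratio", {
  expect_equal(beads_to_count(500, 20000, 20000), 500)
  expect_equal(beads_to_count(500, 10000, 20000), 1000)
  expect_equal(beads_to_count(0, 5000, 20000), 0)
  expect_error(beads_to_count(100, 0, 20000), "unquantifiable")
})

test_that("donor_qc includes the boundary ratio and handles zero controls", {
  expect_true(donor_qc(250, 100))   # exactly 2.5 is not "less than 2.5"
  expect_false(donor_qc(249, 100))
  expect_true(donor_qc(100, 0))     # limit of the ratio rule
  expect_warning(keep <- donor_qc(0, 0), "degenerate")
  expect_false(keep)
  expect_false(donor_qc(249.9, 100, ratio_cutoff = 2.5))
  expect_true(donor_qc(200, 100, ratio_cutoff = 2))
})

test_that("call_active applies the mean + 2 SD rule, including SD = 0", {
  zero_sd <- call_active(10, c(10, 10, 10))
  expect_false(zero_sd$induced)
  expect_true(call_active(10.1, c(10, 10, 10))$induced)
  mid <- call_active(c(15, 15), c(8, 10, 12))
  expect_equal(mid$threshold, 14)
  expect_true(mid$induced)
  expect_false(call_active(c(13, 13), c(8, 10, 12))$induced)
  expect_error(call_active(numeric(0), c(1, 2)), "attractant")
  expect_error(call_active(5, 3), "negative-control")
})

test_that("the induction rule is scale-equivariant and monotone", {
  set.seed(1)
  for (i in 1:50) {
    att <- stats::runif(4, 0, 100)
    neg <- stats::runif(3, 0, 50)
    base <- call_active(att, neg)$induced
    expect_identical(call_active(att * 7.3, neg * 7.3)$induced, base)
    # raising every attractant replicate never turns induced off
    if (base) expect_true(call_active(att + 5, neg)$induced)
  }
})

test_that("normalize_percent maps the positive control to 100", {
  expect_equal(normalize_percent(480, 480), 100)
  expect_equal(normalize_percent(0, 480), 0)
  expect_equal(normalize_percent(120, 480), 25)
  expect_error(normalize_percent(10, 0), "normalization")
})

test_that("summarize_experiment calls a single planted attractant", {
  rows <- donor_block("D1", neg = c(10, 10, 12, 12), pos = rep(100, 4),
    attractants = list(
      well_row("A", "tme_medium", "D1",
               list(cDC1 = c(11, 11), cDC2 = c(55, 55))),
      well_row("B", "tme_medium", "D1",
               list(cDC1 = c(10, 12), cDC2 = c(10, 12)))))
  wells <- make_wells(rows)
  calls <- summarize_experiment(wells)
  tme <- calls[calls$attractant_class == "tme_medium", ]
  induced <- tme[!is.na(tme$induced) & tme$induced, ]
  expect_equal(nrow(induced), 1)
  expect_equal(induced$attractant_id, "A")
  expect_equal(induced$subset, "cDC2")
  # positive control normalizes to exactly 100
  pos <- calls[calls$attractant_id == "POS", ]
  expect_equal(pos$normalized_percent, c(100, 100))
  # a dataset where every attractant equals the negative control
  flat <- make_wells(donor_block("D1", neg = c(10, 10, 10, 10),
    pos = rep(100, 4),
    attractants = list(well_row("A", "tme_medium", "D1",
                                list(cDC1 = c(10, 10), cDC2 = c(10, 10))))))
  fc <- summarize_experiment(flat)
  expect_false(any(fc$induced[fc$attractant_class == "tme_medium"],
                   na.rm = TRUE))
})

test_that("summarize_experiment is invariant to well-row order and excluded donors", {
  rows <- c(
    donor_block("D1", neg = c(10, 12, 10, 12), pos = rep(90, 4),
      attractants = list(well_row("A", "tme_medium", "D1",
                                  list(cDC1 = c(40, 44), cDC2 = c(70, 74))))),
    donor_block("D2", neg = c(20, 22, 20, 22), pos = rep(30, 4),  # fails QC
      attractants = list(well_row("A", "tme_medium", "D2",
                                  list(cDC1 = c(90, 90), cDC2 = c(90, 90))))))
  wells <- make_wells(rows)
  calls <- summarize_experiment(wells)
  shuffled <- summarize_experiment(wells[sample(nrow(wells)), ])
  expect_equal(calls, shuffled)
  # dropping the excluded donor's wells changes nothing
  kept <- summarize_experiment(wells[wells$donor_id == "D1", ])
  a1 <- calls[calls$attractant_id == "A", ]
  a2 <- kept[kept$attractant_id == "A", ]
  rownames(a1) <- rownames(a2) <- NULL
  expect_equal(a1, a2)
})

test_that("an attractant with every donor excluded yields an absent call", {
  rows <- donor_block("D1", neg = c(50, 52, 50, 52), pos = rep(60, 4),
    attractants = list(well_row("A", "tme_medium", "D1",
                                list(cDC1 = c(90, 90), cDC2 = c(90, 90)))))
  calls <- summarize_experiment(make_wells(rows))
  a <- calls[calls$attractant_id == "A", ]
  expect_equal(a$n_replicates, c(0L, 0L))
  expect_true(all(is.na(a$induced)))
})

test_that("donor_pooling = 'separate' reports per-donor rows", {
  rows <- c(
    donor_block("D1", neg = c(10, 10, 12, 12), pos = rep(100, 4),
      attractants = list(well_row("A", "tme_medium", "D1",
                                  list(cDC1 = c(50, 50), cDC2 = c(50, 50))))),
    donor_block("D2", neg = c(10, 10, 12, 12), pos = rep(200, 4),
      attractants = list(well_row("A", "tme_medium", "D2",
                                  list(cDC1 = c(50, 50), cDC2 = c(50, 50))))))
  sep <- summarize_experiment(make_wells(rows), donor_pooling = "separate")
  a <- sep[sep$attractant_id == "A" & sep$subset == "cDC1", ]
  expect_equal(nrow(a), 2)
  expect_setequal(a$normalized_percent, c(50, 25))
  pooled <- summarize_experiment(make_wells(rows))
  ap <- pooled[pooled$attractant_id == "A" & pooled$subset == "cDC1", ]
  expect_equal(ap$normalized_percent, mean(c(50, 25)))
})

test_that("hpv_contingency reproduces the 7/8-vs-0/3 contingency", {
  calls <- data.frame(
    attractant_id = sprintf("CL%02d", 1:11),
    attractant_class = "cell_line",
    subset = "cDC2",
    induced = c(rep(TRUE, 7), FALSE, rep(FALSE, 3)),
    hpv_status = c(rep("negative", 8), rep("positive", 3)),
    stringsAsFactors = FALSE)
  res <- hpv_contingency(calls, "cDC2")
  expect_equal(unname(res$table), matrix(c(7, 1, 0, 3), 2, byrow = TRUE))
  expect_equal(round(res$test$p_value, 2), 0.02)
  # all induced -> p = 1
  calls$induced <- TRUE
  expect_equal(hpv_contingency(calls, "cDC2")$test$p_value, 1)
  # balanced 4/4/4/4 table is symmetric
  calls16 <- data.frame(
    attractant_id = sprintf("CL%02d", 1:16),
    attractant_class = "cell_line", subset = "cDC2",
    induced = rep(c(TRUE, FALSE), 8),
    hpv_status = rep(c("negative", "positive"), each = 8),
    stringsAsFactors = FALSE)
  expect_equal(hpv_contingency(calls16, "cDC2")$test$p_value, 1)
  calls$hpv_status[1] <- NA
  expect_error(hpv_contingency(calls, "cDC2"), "HPV")
})

test_that("compare_paired tests matched arms with the signed-rank test", {
  tot <- stats::setNames(c(80, 60, 90, 40, 70, 55), paste0("S", 1:6))
  identical_arms <- compare_paired(tot, tot)
  expect_equal(identical_arms$p_value, 1)
  expect_true(identical_arms$degenerate)
  depl <- tot * 0.5
  res <- compare_paired(tot, depl)
  expect_equal(res$p_value, 2 / 64)
  swapped <- compare_paired(depl, tot)
  expect_equal(swapped$p_value, res$p_value)
  names(depl)[1] <- "other"
  expect_error(compare_paired(tot, depl), "pairing")
})

test_that("induction calling has high sensitivity and a controlled false-call rate", {
  # known generating effect: attractant mean = k * negative mean,
  # CV 0.2, 4 replicates each
  set.seed(99)
  sims <- function(k, n = 500) {
    hits <- 0
    for (i in seq_len(n)) {
      neg <- stats::rnorm(4, 100, 20)
      att <- stats::rnorm(4, 100 * k, 20 * k)
      if (call_active(att, neg)$induced) hits <- hits + 1
    }
    hits / n
  }
  expect_gte(sims(3), 0.95)
  expect_lte(sims(1), 0.05)
})
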