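test_that("top-k accuracy counts true sites among k*n_true top predictions", {
  n <- 200
  labels <- integer(n)
  set.seed(51)
  donors <- sample(n, 10)
  acceptors <- sample(setdiff(seq_len(n), donors), 10)
  labels[donors] <- 2L
  labels[acceptors] <- 1L

  # perfect scorer: 10 true per class, k = 1 examines 10 + 10 = 20
  scores <- matrix(0.01, n, 3)
  scores[donors, 3] <- 0.99
  scores[acceptors, 2] <- 0.99
  res <- topk_accuracy(scores, labels, k = 1)
  expect_equal(sum(res$n_examined), 20)
  expect_equal(res$accuracy, c(1, 1))

  # k = 2 examines 20 per class, 40 total
  res2 <- topk_accuracy(scores, labels, k = 2)
  expect_equal(res2$n_examined, c(20, 20))
  expect_equal(sum(res2$n_examined), 40)

  # constructed: 7 of 10 true donors in the top 10
  s3 <- matrix(0.0, n, 3)
  s3[donors[1:7], 3] <- 0.9
  decoys <- setdiff(seq_len(n), c(donors, acceptors))[1:3]
  s3[decoys, 3] <- 0.8
  s3[donors[8:10], 3] <- 0.1
  s3[acceptors, 2] <- 0.9
  res3 <- topk_accuracy(s3, labels, k = 1)
  expect_equal(res3$accuracy[res3$class == "donor"], 0.7)

  only_d <- integer(50); only_d[5] <- 2L
  expect_warning(topk_accuracy(matrix(0.1, 50, 3), only_d), "no true sites")
})

test_that("top-k accuracy is invariant under monotone score transforms", {
  set.seed(52)
  n <- 300
  labels <- integer(n)
  labels[sample(n, 12)] <- 2L
  labels[sample(which(labels == 0), 12)] <- 1L
  scores <- matrix(runif(3 * n), n, 3)
  base <- topk_accuracy(scores, labels, k = 1)
  mono <- topk_accuracy(plogis(3 * scores - 1), labels, k = 1)
  expect_equal(base$accuracy, mono$accuracy)
})

test_that("threshold metrics implement the standard confusion definitions", {
  # perfect predictions (the acceptor class is empty here, so its
  # undefined metrics warn; the donor metrics are under test)
  labels <- c(rep(2L, 5), rep(0L, 15))
  perfect <- matrix(0, 20, 3)
  perfect[labels == 2L, 3] <- 1
  res <- suppressWarnings(threshold_metrics(perfect, labels))
  d <- res[res$class == "donor", ]
  expect_equal(c(d$accuracy, d$precision, d$recall, d$f1), rep(1, 4))

  # TP=8 FP=2 FN=2 TN=88 -> precision 0.8, recall 0.8, F1 0.8
  n <- 100
  labels2 <- c(rep(2L, 10), rep(0L, 90))
  s <- matrix(0, n, 3)
  s[c(1:8, 11:12), 3] <- 0.9
  res2 <- suppressWarnings(threshold_metrics(s, labels2))
  d2 <- res2[res2$class == "donor", ]
  expect_equal(c(d2$tp, d2$fp, d2$fn, d2$tn), c(8, 2, 2, 88))
  expect_equal(c(d2$precision, d2$recall, d2$f1), c(0.8, 0.8, 0.8))

  # no positive predictions: precision 0 with a warning
  w <- capture_warnings(res3 <- threshold_metrics(matrix(0, 20, 3), labels))
  expect_true(any(grepl("precision", w)))
  expect_equal(res3$precision[res3$class == "donor"], 0)
})

test_that("AUPRC equals a brute-force threshold sweep", {
  brute_force_auprc <- function(scores, labels) {
    labels <- as.logical(labels)
    ts <- sort(unique(scores), decreasing = TRUE)
    prev_r <- 0
    area <- 0
    for (t in ts) {
      pred <- scores >= t
      tp <- sum(pred & labels)
      p <- tp / sum(pred)
      r <- tp / sum(labels)
      area <- area + p * (r - prev_r)
      prev_r <- r
    }
    area
  }

  expect_equal(auprc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)

  # 5-point toy vector vs the sweep
  s5 <- c(0.9, 0.6, 0.6, 0.4, 0.2)
  y5 <- c(1, 0, 1, 0, 1)
  expect_equal(auprc(s5, y5), brute_force_auprc(s5, y5), tolerance = 1e-9)

  set.seed(53)
  for (i in 1:25) {
    n <- sample(5:100, 1)
    scores <- round(runif(n), 2) # force ties
    labels <- runif(n) < 0.3
    if (!any(labels)) labels[1] <- TRUE
    expect_equal(auprc(scores, labels), brute_force_auprc(scores, labels),
                 tolerance = 1e-9)
  }

  # label-independent scores approach the class prevalence
  set.seed(54)
  n <- 20000
  scores <- runif(n)
  labels <- runif(n) < 0.3
  prev <- mean(labels)
  se <- sqrt(prev * (1 - prev) / n)
  expect_lt(abs(auprc(scores, labels) - prev), 3 * se + 0.01)

  expect_error(auprc(runif(5), rep(FALSE, 5)), "positive")
})

test_that("ISM importance matches its averaging conventions", {
  fx <- shared_fixture()
  mock <- shared_mock()
  g <- Filter(function(x) x$strand == "+" && length(x$donors) > 0,
              fx$genes)[[1]]
  prof <- ism_importance(mock, g$seq, g$donors[1], "donor", window = 10)
  expect_length(prof$importance, 21)

  # positions outside the consensus window leave the score unchanged
  outside <- abs(prof$offsets) > 8
  expect_true(all(abs(prof$importance[outside]) < 1e-6))
  # the GT dinucleotide (offsets +1, +2) is consensus-critical
  gt <- prof$offsets %in% c(1, 2)
  expect_true(all(prof$importance[gt] > 0.9 * max(prof$importance)))

  # hand value: S_ref 1.0 with substitution scores 0.2/0.4/0.6 -> 0.6
  expect_equal(1.0 - mean(c(0.2, 0.4, 0.6)), 0.6)
  # the four-base average scales importance by 3/4
  prof4 <- ism_importance(mock, g$seq, g$donors[1], "donor", window = 10,
                          average = "four")
  expect_equal(prof4$importance, prof$importance * 3 / 4, tolerance = 1e-12)

  expect_error(ism_importance(mock, substr(g$seq, 1, 40), 5, "donor",
                              window = 10), "too close")
})

test_that("logo aggregation is the elementwise profile mean and is linear", {
  fx <- shared_fixture()
  mock <- shared_mock()
  plus <- Filter(function(x) x$strand == "+" && length(x$donors) > 0,
                 fx$genes)
  profs <- list()
  for (g in plus) {
    for (d in g$donors) {
      p <- tryCatch(ism_importance(mock, g$seq, d, "donor", window = 8),
                    error = function(e) NULL)
      if (!is.null(p)) profs[[length(profs) + 1L]] <- p
    }
  }
  expect_gte(length(profs), 2)

  single <- aggregate_logo(profs[1])
  expect_equal(single$decrease, profs[[1]]$decrease)

  pair <- aggregate_logo(profs[1:2])
  expect_equal(pair$decrease,
               (profs[[1]]$decrease + profs[[2]]$decrease) / 2)

  # linearity: grand mean equals the weighted mean of sub-aggregates
  all_logo <- aggregate_logo(profs)
  k <- length(profs)
  a <- aggregate_logo(profs[1:2])
  b <- aggregate_logo(profs[3:k])
  expect_equal(all_logo$decrease,
               (2 * a$decrease + (k - 2) * b$decrease) / k,
               tolerance = 1e-12)

  # the donor GT dinucleotide columns carry maximal aggregate signal,
  # and positions outside the consensus carry essentially none
  col_mass <- colSums(abs(all_logo$decrease))
  gt_cols <- which(all_logo$offsets %in% c(1, 2))
  expect_true(all(col_mass[gt_cols] > 0.95 * max(col_mass)))
  outside <- which(abs(all_logo$offsets) > 8)
  expect_true(all(col_mass[outside] < 0.05 * max(col_mass)))

  other <- ism_importance(mock, plus[[1]]$seq, plus[[1]]$donors[1],
                          "donor", window = 5)
  expect_error(aggregate_logo(c(profs[1], list(other))), "geometries")
})

test_that("profile correlation behaves at its boundary cases", {
  x <- c(0.1, 0.5, 0.9, 0.2)
  expect_equal(profile_correlation(x, x), 1)
  expect_equal(profile_correlation(x, -x), -1)
  expect_warning(r <- profile_correlation(x, rep(1, 4)), "zero-variance")
  expect_true(is.na(r))

  set.seed(55)
  r_ind <- profile_correlation(rnorm(5001), rnorm(5001))
  expect_lt(abs(r_ind), 0.05)
})
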