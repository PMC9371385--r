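two_clouds <- function(n = 30, sep = 10, seed = 1) {
  set.seed(seed)
  m <- rbind(matrix(rnorm(n * 2), n, 2),
             matrix(rnorm(n * 2) + sep, n, 2))
  colnames(m) <- c("f1", "f2")
  make_fm(m)
}

test_that("all three algorithms recover well-separated clouds deterministically", {
  fm <- two_clouds()
  truth <- rep(1:2, each = 30)
  for (alg in c("kmeans", "gmm", "ward")) {
    lab <- cluster_windows(fm, cluster_config(alg, seed = 7))
    expect_false(lab$degenerate)
    expect_setequal(unique(lab$cluster), 1:2)
    # agreement up to id swap
    agree <- max(mean(lab$cluster == truth), mean(lab$cluster == 3 - truth))
    expect_equal(agree, 1)
    lab2 <- cluster_windows(fm, cluster_config(alg, seed = 7))
    expect_identical(lab$cluster, lab2$cluster)
  }
  expect_error(cluster_windows(make_fm(matrix(1, 1, 2)), cluster_config()),
               "at least 2")
})

test_that("identical rows are flagged degenerate and map to Not_Skiing", {
  fm <- make_fm(matrix(1, 10, 3))
  expect_warning(lab <- cluster_windows(fm, cluster_config("kmeans")),
                 "degenerate")
  expect_true(lab$degenerate)
  mapped <- map_clusters_to_classes(lab, make_fm(
    matrix(1, 10, 3, dimnames = list(NULL, c("acc_x__raw__energy",
                                             "acc_y__raw__energy",
                                             "acc_z__raw__energy")))))
  expect_true(all(mapped$class == "Not_Skiing"))
})

test_that("the higher-energy cluster is named Skiing, ties go to the minority", {
  raw <- make_fm(matrix(c(rep(100, 3 * 4), rep(1, 3 * 6)), 10, 3, byrow = TRUE,
                        dimnames = list(NULL, c("acc_x__raw__energy",
                                                "acc_y__raw__energy",
                                                "acc_z__raw__energy"))))
  lab <- make_labeling(0:9, 1:10, rep("Not_Skiing", 10))
  lab$cluster <- rep(c(1L, 2L), c(4L, 6L))
  mapped <- map_clusters_to_classes(lab, raw)
  expect_equal(mapped$class, rep(c("Skiing", "Not_Skiing"), c(4, 6)))

  # swap raw cluster ids: final classes unchanged
  lab$cluster <- 3L - lab$cluster
  expect_equal(map_clusters_to_classes(lab, raw)$class, mapped$class)

  # engineered tie: minority cluster becomes Skiing
  tie <- make_fm(matrix(5, 10, 3, dimnames = dimnames(raw)))
  lab$cluster <- rep(c(1L, 2L), c(3L, 7L))
  expect_equal(map_clusters_to_classes(lab, tie)$class,
               rep(c("Skiing", "Not_Skiing"), c(3, 7)))
})

test_that("window voting produces a partition of the covered span", {
  times <- seq(0, 4, by = 0.01)
  lab <- make_labeling(0:3, 1:4, c("Skiing", "Skiing", "Not_Skiing", "Skiing"))
  seg <- windows_to_segments(lab, times)
  expect_equal(seg$label, c("Skiing", "Not_Skiing", "Skiing"))
  expect_equal(seg$start, c(0, 2, 3), tolerance = 1e-9)
  expect_equal(seg$end, c(2, 3, 4), tolerance = 1e-9)
  expect_equal(seg$start[-1], seg$end[-nrow(seg)])  # partition

  # overlapping windows disagreeing 1-1 resolve to Not_Skiing
  lab2 <- make_labeling(c(0, 1), c(2, 3), c("Skiing", "Not_Skiing"))
  seg2 <- windows_to_segments(lab2, times)
  cls <- per_sample_classes(1.5, seg2)
  expect_equal(cls, "Not_Skiing")

  lab3 <- make_labeling(0:2, 1:3, rep("Skiing", 3))
  expect_equal(nrow(windows_to_segments(lab3, times)), 1L)
})

test_that("the 30-s rule relabels short skiing segments and merges neighbours", {
  segs <- activity_segments(c(0, 50, 70, 120, 160), c(50, 70, 120, 160, 200),
                            c("Not_Skiing", "Skiing", "Not_Skiing", "Skiing",
                              "Not_Skiing"))
  out <- drop_short(segs, 30)
  # the 20-s segment is relabeled and absorbed; the 40-s one is kept
  expect_equal(out$label, c("Not_Skiing", "Skiing", "Not_Skiing"))
  expect_equal(out$start, c(0, 120, 160))
  expect_equal(count_activities(out), 1L)

  kept <- drop_short(activity_segments(c(0, 10), c(10, 40),
                                       c("Not_Skiing", "Skiing")), 30)
  expect_equal(count_activities(kept), 1L)  # exactly 30 s: closed bound

  expect_equal(count_activities(drop_short(activity_segments())), 0L)
})

test_that("random segment lists never keep a short skiing segment", {
  set.seed(77)
  for (i in 1:300) {
    k <- sample(1:12, 1)
    bounds <- sort(c(0, runif(k - 1, 0, 300), 300))
    labs <- sample(c("Skiing", "Not_Skiing"), k, replace = TRUE)
    out <- drop_short(activity_segments(bounds[-(k + 1)], bounds[-1], labs), 30)
    ski <- out[out$label == "Skiing", ]
    if (nrow(ski)) expect_true(all(ski$end - ski$start >= 30))
    # relabeling keeps the timeline covered
    expect_equal(sum(out$end - out$start), 300, tolerance = 1e-9)
    if (nrow(out) > 1) expect_true(all(out$label[-1] != out$label[-nrow(out)]))
  }
})
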