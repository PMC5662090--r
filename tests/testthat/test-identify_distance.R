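make_dm <- function(D) bc_dist_from_matrix(D)

# 6 individuals, 2 species x 3, all intra < all inter
toy6 <- local({
  ids <- c("a1", "a2", "a3", "b1", "b2", "b3")
  D <- matrix(0.05, 6, 6, dimnames = list(ids, ids))
  D[1:3, 1:3] <- 0.002
  D[4:6, 4:6] <- 0.003
  diag(D) <- 0
  info <- data.frame(individual_id = ids, genus = "Poa",
                     species = rep(c("annua", "alpina"), each = 3))
  list(dm = make_dm(D), info = info)
})

test_that("nearest neighbour scores true/false and handles ties", {
  res <- identify_all(toy6$dm, toy6$info, "species", "NN")
  expect_true(all(res$category == "true"))
  # tie between one conspecific and one allospecific at minimal distance
  ids <- c("q", "same", "other")
  D <- matrix(c(0, .01, .01, .01, 0, .02, .01, .02, 0), 3,
              dimnames = list(ids, ids))
  info <- data.frame(individual_id = ids, genus = "G",
                     species = c("x", "x", "y"))
  expect_equal(nearest_neighbour("q", make_dm(D), info, "species")$category,
               "false")
  # all-undefined distances
  D2 <- D; D2["q", -1] <- NA; D2[-1, "q"] <- NA
  expect_equal(nearest_neighbour("q", make_dm(D2), info, "species")$category,
               "unidentifiable")
})

test_that("best close match applies the threshold and tie rules", {
  ids <- c("q", "same", "far")
  D <- matrix(0, 3, 3, dimnames = list(ids, ids))
  D["q", "same"] <- D["same", "q"] <- 0.0010   # 0.10%
  D["q", "far"] <- D["far", "q"] <- 0.0500
  D["same", "far"] <- D["far", "same"] <- 0.0500
  info <- data.frame(individual_id = ids, genus = "G",
                     species = c("x", "x", "y"))
  expect_equal(best_close_match("q", make_dm(D), info, "species", 0.16)$category,
               "correct")
  # nearest beyond the threshold
  D2 <- D; D2["q", "same"] <- D2["same", "q"] <- 0.0030  # 0.30%
  expect_equal(best_close_match("q", make_dm(D2), info, "species", 0.16)$category,
               "no_identification")
  # tied nearest mixes species within threshold
  ids3 <- c("q", "same", "other")
  D3 <- matrix(0.001, 3, 3, dimnames = list(ids3, ids3)); diag(D3) <- 0
  info3 <- data.frame(individual_id = ids3, genus = "G",
                      species = c("x", "x", "y"))
  expect_equal(best_close_match("q", make_dm(D3), info3, "species", 0.16)$category,
               "ambiguous")
})

test_that("threshold ID classifies from the whole within-threshold set", {
  ids <- c("q", "c1", "c2", "other")
  D <- matrix(0.05, 4, 4, dimnames = list(ids, ids))
  D["q", "c1"] <- D["c1", "q"] <- 0.001
  D["q", "c2"] <- D["c2", "q"] <- 0.002
  diag(D) <- 0
  info <- data.frame(individual_id = ids, genus = "G",
                     species = c("x", "x", "x", "y"))
  expect_equal(threshold_id("q", make_dm(D), info, "species", 0.5)$category,
               "correct")
  D["q", "other"] <- D["other", "q"] <- 0.003
  expect_equal(threshold_id("q", make_dm(D), info, "species", 0.5)$category,
               "ambiguous")
  expect_equal(threshold_id("q", make_dm(D), info, "species", 0.0001)$category,
               "no_identification")
})

test_that("classifiers agree with the set-builder oracle on random instances", {
  set.seed(202)
  for (rep in 1:150) {
    inst <- random_instance()
    dm <- make_dm(inst$D)
    info <- info_from_labels(inst$labels)
    labels <- taxon_labels(info, "species")
    for (q in inst$ids) {
      expect_identical(nearest_neighbour(q, dm, info, "species")$category,
                       oracle_classify("NN", q, inst$D, inst$labels))
      expect_identical(
        best_close_match(q, dm, info, "species", inst$thr)$category,
        oracle_classify("BCM", q, inst$D, inst$labels, inst$thr))
      expect_identical(
        threshold_id(q, dm, info, "species", inst$thr)$category,
        oracle_classify("TID", q, inst$D, inst$labels, inst$thr))
    }
  }
})

test_that("BCM at infinite threshold reduces to NN", {
  set.seed(7)
  for (rep in 1:25) {
    inst <- random_instance()
    dm <- make_dm(inst$D)
    info <- info_from_labels(inst$labels)
    for (q in inst$ids) {
      nn <- nearest_neighbour(q, dm, info, "species")$category
      bcm <- best_close_match(q, dm, info, "species", Inf)$category
      if (nn == "unidentifiable") expect_equal(bcm, "no_identification")
      else expect_equal(bcm == "correct", nn == "true")
    }
  }
})

test_that("TID category counts are monotone in the threshold", {
  set.seed(8)
  inst <- random_instance(n_min = 10, n_max = 15)
  dm <- make_dm(inst$D)
  info <- info_from_labels(inst$labels)
  grid <- seq(0, 3.5, by = 0.25)
  noid <- vapply(grid, function(t) {
    res <- identify_all(dm, info, "species", "TID", t)
    sum(res$category == "no_identification")
  }, numeric(1))
  expect_true(all(diff(noid) <= 0))
})

test_that("threshold optimization finds the gap and applies the tie rule", {
  # clean gap: intra <= 0.2%, inter >= 1.0%
  ids <- sprintf("i%d", 1:6)
  D <- matrix(0.012, 6, 6, dimnames = list(ids, ids))
  D[1:3, 1:3] <- 0.0015
  D[4:6, 4:6] <- 0.0020
  diag(D) <- 0
  info <- data.frame(individual_id = ids, genus = "G",
                     species = rep(c("x", "y"), each = 3))
  prof <- optimize_threshold(make_dm(D), info, "species")
  inside <- prof$profile$threshold > 0.2 & prof$profile$threshold < 1.0
  expect_true(all(prof$profile$cumulative[inside] == 0))
  zero <- prof$profile$threshold[prof$profile$cumulative == 0]
  expect_equal(prof$optimum, max(zero))
  expect_equal(prof$profile$cumulative, prof$profile$fp + prof$profile$fn)

  # all individuals identical: no FN anywhere, optimum at the grid maximum
  D0 <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  info0 <- data.frame(individual_id = letters[1:4], genus = "G",
                      species = c("x", "x", "y", "y"))
  p0 <- optimize_threshold(make_dm(D0), info0, "species",
                           grid = seq(0.1, 1, by = 0.1))
  expect_true(all(p0$profile$fn == 0))
  # every query ties with one conspecific and two allospecifics -> ambiguous
  expect_true(all(p0$profile$fp == 4))
  expect_equal(p0$optimum, 1)
  expect_error(optimize_threshold(make_dm(D0), info0, "species",
                                  grid = numeric(0)), "empty")
})

test_that("optimization equals a brute-force per-grid-point recomputation", {
  set.seed(33)
  grid <- seq(0.05, 2.5, by = 0.1)
  for (rep in 1:8) {
    inst <- random_instance(n_min = 6, n_max = 14)
    dm <- make_dm(inst$D)
    info <- info_from_labels(inst$labels)
    prof <- optimize_threshold(dm, info, "species", grid = grid)
    orc <- oracle_profile(inst$D, inst$labels, grid)
    expect_equal(prof$profile$fp, orc$fp)
    expect_equal(prof$profile$fn, orc$fn)
    expect_equal(prof$optimum, orc$optimum)
  }
})

test_that("success tables report category percentages", {
  res <- data.frame(query = sprintf("q%d", 1:10), method = "NN",
                    rank = "species",
                    category = c(rep("true", 9), "false"))
  st <- success_table(res)
  expect_equal(st$percent[st$category == "true"], 90)
  expect_equal(st$percent[st$category == "false"], 10)
  expect_equal(sum(st$percent), 100)
  expect_equal(attr(st, "denominator"), 10)
  expect_error(success_table(res[0, ]), "no results")
})
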